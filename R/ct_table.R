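#' Ct tables: replicate-level RT-qPCR measurements
#'
#' A `ct_table` is a long-format data frame with one row per PCR replicate:
#' columns `sample_id`, `gene`, `run_id` (one RT-qPCR experiment), `replicate`
#' (index within a run), `ct` (threshold cycle; `NA` when censored),
#' `censored` (logical: no amplification by the cycle cap, recorded in input
#' files as an empty field or the literal `"Undetermined"`), `input_ng`
#' (nominal RNA mass per reaction) and `group` (e.g. `BrMV`, `CDB`).
#'
#' @param df A data frame with at least `sample_id`, `gene`, `run_id`,
#'   `replicate` and `ct` columns. `input_ng` and `group` are optional and
#'   filled with `NA` when absent.
#' @return A `ct_table` (a data frame subclass).
#' @details The replicate key `(sample_id, gene, run_id, replicate)` must be
#'   unique; non-censored Ct values must be finite and positive.
#' @examples
#' df <- data.frame(sample_id = "S1", gene = "Actb", run_id = "r1",
#'                  replicate = 1:2, ct = c(15.2, 15.4))
#' as_ct_table(df)
#' @export
as_ct_table <- function(df) {
  required <- c("sample_id", "gene", "run_id", "replicate", "ct")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$gene <- as.character(df$gene)
  df$run_id <- as.character(df$run_id)
  df$replicate <- as.integer(df$replicate)
  df$ct <- as.numeric(df$ct)
  if (!"censored" %in% names(df)) df$censored <- is.na(df$ct)
  df$censored <- as.logical(df$censored) | is.na(df$ct)
  df$ct[df$censored] <- NA_real_
  if (!"input_ng" %in% names(df)) df$input_ng <- NA_real_
  if (!"group" %in% names(df)) df$group <- NA_character_

  ok <- df$censored | (is.finite(df$ct) & df$ct > 0)
  if (!all(ok)) {
    stop("non-censored ct values must be finite and > 0 (",
         sum(!ok), " offending row(s))", call. = FALSE)
  }
  key <- paste(df$sample_id, df$gene, df$run_id, df$replicate, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    stop("duplicate replicate key(s) (sample_id, gene, run_id, replicate): ",
         paste(utils::head(gsub("\r", "/", dup), 5L), collapse = "; "),
         if (length(dup) > 5L) " ..." else "", call. = FALSE)
  }
  out <- df[c("sample_id", "gene", "run_id", "replicate", "ct", "censored",
              "input_ng", "group")]
  rownames(out) <- NULL
  class(out) <- c("ct_table", "data.frame")
  out
}

#' Read a Ct table from CSV
#'
#' Reads a long-format, comma-separated Ct file (header row required, UTF-8).
#' A missing `ct` is encoded as an empty field or the literal `"Undetermined"`
#' (case-insensitive) and becomes a censored measurement.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names (`sample_id`, `gene`, `run_id`, `replicate`, `ct`, `input_ng`,
#'   `group`) to the column names used in the file.
#' @return A [as_ct_table()] object; the attribute `"n_censored"` carries the
#'   number of censored rows.
#' @export
read_ct_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      file_col <- schema[[canon]]
      if (!file_col %in% names(raw)) {
        stop("missing required column(s): ", file_col, call. = FALSE)
      }
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  required <- c("sample_id", "gene", "run_id", "replicate", "ct")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ct_chr <- trimws(raw$ct)
  censored <- is.na(ct_chr) | ct_chr == "" | tolower(ct_chr) == "undetermined"
  ct_num <- suppressWarnings(as.numeric(ct_chr))
  bad <- !censored & is.na(ct_num)
  if (any(bad)) {
    stop("unparseable ct value(s): ",
         paste(utils::head(unique(ct_chr[bad]), 5L), collapse = ", "),
         call. = FALSE)
  }
  raw$ct <- ct_num
  raw$censored <- censored
  if ("input_ng" %in% names(raw)) raw$input_ng <- as.numeric(raw$input_ng)
  out <- as_ct_table(raw)
  attr(out, "n_censored") <- sum(out$censored)
  out
}

#' Write a Ct table to CSV
#'
#' Censored measurements are written as the literal `"Undetermined"`, the
#' same encoding [read_ct_table()] accepts, so write-then-read round-trips.
#'
#' @param table A `ct_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(table, path) {
  df <- as.data.frame(table)
  df$ct <- ifelse(df$censored, "Undetermined", format(df$ct, digits = 15L, trim = TRUE))
  df$censored <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("Ct table: %d replicate rows, %d samples, %d genes, %d censored\n",
              nrow(x), length(unique(x$sample_id)), length(unique(x$gene)),
              sum(x$censored)))
  NextMethod()
}
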