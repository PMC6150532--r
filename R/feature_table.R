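#' @name feature_table
#' @title Per-vocalization feature tables
#'
#' @description
#' The pipeline's central tabular artifact: one row per vocal signal with its
#' emitter, the seven acoustic features, the behavioral context and the
#' session. Columns (canonical order and units):
#' `session_id`, `voc_number`, `emitter`, `bandwidth_hz`, `duration_ms`,
#' `high_freq_hz`, `low_freq_hz`, `mean_freq_hz`, `slope_hz_per_s`,
#' `amplitude_mv`, `context`. The layout is compatible with published
#' per-vocalization supplementary tables (date, vocalization number, emitter,
#' bandwidth (Hz), duration (ms), high/low frequency (Hz), mean fundamental
#' frequency (Hz), slope (Hz/s), amplitude, context), whose headers are
#' mapped case-insensitively on read.
NULL

feature_table_columns <- c(
  "session_id", "voc_number", "emitter", "bandwidth_hz", "duration_ms",
  "high_freq_hz", "low_freq_hz", "mean_freq_hz", "slope_hz_per_s",
  "amplitude_mv", "context"
)

feature_numeric_columns <- c(
  "bandwidth_hz", "duration_ms", "high_freq_hz", "low_freq_hz",
  "mean_freq_hz", "slope_hz_per_s", "amplitude_mv"
)

# normalized-header -> canonical column lookup
map_feature_column <- function(nm) {
  key <- gsub("[^a-z0-9]", "", tolower(nm))
  if (grepl("date|session", key)) return("session_id")
  if (grepl("voc.*number|number", key)) return("voc_number")
  if (grepl("emitter|mouse|animal", key)) return("emitter")
  if (grepl("bandwidth", key)) return("bandwidth_hz")
  if (grepl("duration", key)) return("duration_ms")
  if (grepl("highfreq", key)) return("high_freq_hz")
  if (grepl("lowfreq", key)) return("low_freq_hz")
  if (grepl("mean.*freq|fundamental", key)) return("mean_freq_hz")
  if (grepl("slope", key)) return("slope_hz_per_s")
  if (grepl("amplitude", key)) return("amplitude_mv")
  if (grepl("context|behavio", key)) return("context")
  NA_character_
}

normalize_context <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("not close", "notclose", "not-close")] <- "not_close"
  x[is.na(x) | x == ""] <- NA_character_
  x
}

#' Construct/validate a feature table
#'
#' @param df data frame carrying at least the seven feature columns and
#'   `emitter`; missing bookkeeping columns are filled.
#' @return a `feature_table` (a data.frame subclass).
#' @export
as_feature_table <- function(df) {
  for (col in setdiff(feature_table_columns, names(df))) {
    df[[col]] <- rep(if (col %in% feature_numeric_columns) NA_real_ else
      NA_character_, nrow(df))
  }
  df <- df[feature_table_columns]
  for (col in feature_numeric_columns) df[[col]] <- as.numeric(df[[col]])
  df$emitter <- as.character(df$emitter)
  df$emitter[is.na(df$emitter) | trimws(df$emitter) == ""] <- "unassigned"
  df$context <- normalize_context(df$context)
  df$session_id <- as.character(df$session_id)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Read an S1-compatible feature table (CSV or XLSX)
#'
#' Column headers are matched case-insensitively against the canonical
#' schema; units are taken as stored (Hz, ms, Hz/s, mV). Rows without an
#' emitter label are kept and flagged `"unassigned"`.
#'
#' @param path a `.csv` or `.xlsx` file with a header row.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop_usv("reading XLSX requires the 'readxl' package",
               class = "usvdyad_schema_error")
    }
    as.data.frame(readxl::read_excel(path))
  } else {
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  mapped <- vapply(names(raw), map_feature_column, character(1))
  keep <- !is.na(mapped) & !duplicated(mapped)
  df <- raw[keep]
  names(df) <- mapped[keep]
  mandatory <- c("emitter", feature_numeric_columns)
  missing <- setdiff(mandatory, names(df))
  if (length(missing)) {
    stop_usv("feature table is missing mandatory columns: %s",
             paste(missing, collapse = ", "), class = "usvdyad_schema_error")
  }
  as_feature_table(df)
}

#' Write a feature table as CSV
#'
#' Canonical column order, full numeric precision (17 significant digits, so
#' values round-trip exactly), byte-identical output for identical input.
#'
#' @param table a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  table <- as_feature_table(as.data.frame(table))
  out <- table
  for (col in feature_numeric_columns) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.17g", out[[col]]))
  }
  con <- file(path, "wb")  # binary mode: fixed newlines across platforms
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, quote = TRUE, eol = "\n", na = "")
  invisible(path)
}

#' @export
print.feature_table <- function(x, ...) {
  n_assigned <- sum(x$emitter != "unassigned")
  cat(sprintf("<feature_table: %d vocalizations (%d assigned)>\n",
              nrow(x), n_assigned))
  NextMethod()
}
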