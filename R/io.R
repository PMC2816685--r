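# Delimited-text I/O for labeling time courses. The canonical schema is a
# comma-separated file with a header row and columns:
#   subject, time_days, frac_labeled, T_days
# (one row per measurement; T_days is the subject's labeling duration and
# must be constant within a subject).

fail_parse <- function(msg) {
  stop(errorCondition(msg, class = c("parse_error", "error", "condition")))
}

#' Read labeling datasets from a delimited text file
#'
#' @param path path to a CSV file with header columns `subject`,
#'   `time_days`, `frac_labeled` and `T_days`.
#' @param percent if `TRUE`, `frac_labeled` is given in percent and is
#'   divided by 100 on read (published labeling figures use both
#'   conventions).
#' @return List of [labeling_dataset()] objects, one per subject, with
#'   times sorted. Malformed rows, fractions outside the valid range,
#'   duplicate (subject, time) pairs and inconsistent labeling durations
#'   raise a parse error naming the offending data line (line 1 is the
#'   header).
#' @export
read_datasets <- function(path, percent = FALSE) {
  if (!file.exists(path)) fail_parse(sprintf("file not found: %s", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) fail_parse(paste("cannot parse", path, ":",
                                                      conditionMessage(e))))
  if (nrow(df) == 0L) fail_parse(sprintf("no data rows in %s", path))
  need <- c("subject", "time_days", "frac_labeled", "T_days")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    fail_parse(paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  line_no <- seq_len(nrow(df)) + 1L  # header is line 1
  num_bad <- !vapply(df$time_days, is.numeric, TRUE) |
    !is.finite(suppressWarnings(as.numeric(df$time_days))) |
    !is.finite(suppressWarnings(as.numeric(df$frac_labeled))) |
    !is.finite(suppressWarnings(as.numeric(df$T_days)))
  if (any(num_bad))
    fail_parse(sprintf("non-numeric value on line %d", line_no[which(num_bad)[1L]]))
  frac <- as.numeric(df$frac_labeled)
  if (percent) frac <- frac / 100
  bad <- frac < 0 | frac > 1
  if (any(bad))
    fail_parse(sprintf("frac_labeled out of [0, 1] on line %d",
                       line_no[which(bad)[1L]]))
  dup <- duplicated(df[, c("subject", "time_days")])
  if (any(dup))
    fail_parse(sprintf("duplicate (subject, time) row on line %d",
                       line_no[which(dup)[1L]]))
  out <- list()
  for (s in unique(df$subject)) {
    sel <- df$subject == s
    Tl <- unique(as.numeric(df$T_days[sel]))
    if (length(Tl) != 1L)
      fail_parse(sprintf("subject '%s' has inconsistent T_days", s))
    ord <- order(as.numeric(df$time_days[sel]))
    out[[as.character(s)]] <- labeling_dataset(
      s, as.numeric(df$time_days[sel])[ord], frac[sel][ord], Tl)
  }
  out
}

#' Write labeling datasets to a delimited text file
#'
#' Inverse of [read_datasets()]: writes the canonical CSV schema so that
#' reading the file back yields semantically identical datasets.
#'
#' @param datasets a [labeling_dataset()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_datasets <- function(datasets, path) {
  datasets <- as_dataset_list(datasets)
  df <- do.call(rbind, lapply(datasets, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
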