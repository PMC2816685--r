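#' A single subject's labeling time course
#'
#' Container for one deuterium-labeling experiment: measurement times in
#' days since the start of label administration, the measured fraction of
#' labeled DNA at each time, and the labeling duration.
#'
#' @param subject subject identifier (coerced to character).
#' @param times numeric vector of measurement times in days, >= 0,
#'   strictly increasing.
#' @param fractions labeled-DNA fractions in `[0, 1]`, same length as
#'   `times`.
#' @param T_label labeling duration in days, > 0.
#' @return An object of class `labeling_dataset`.
#' @export
labeling_dataset <- function(subject, times, fractions, T_label) {
  fail_in <- function(msg)
    stop(errorCondition(msg, class = c("invalid_input", "error", "condition")))
  if (length(times) != length(fractions))
    fail_in("'times' and 'fractions' must have the same length")
  if (length(times) == 0L) fail_in("dataset must contain at least one observation")
  if (any(!is.finite(times)) || any(times < 0)) fail_in("'times' must be finite and >= 0")
  if (is.unsorted(times, strictly = TRUE)) fail_in("'times' must be strictly increasing")
  if (any(!is.finite(fractions)) || any(fractions < 0) || any(fractions > 1))
    fail_in("'fractions' must lie in [0, 1]")
  structure(list(subject = as.character(subject)[1L],
                 times = as.numeric(times),
                 fractions = as.numeric(fractions),
                 T_label = check_scalar(T_label, "T_label", 0, Inf, open_lower = TRUE)),
            class = "labeling_dataset")
}

#' @export
print.labeling_dataset <- function(x, ...) {
  cat("<labeling_dataset> subject", x$subject, "-",
      length(x$times), "timepoints, labeling period", x$T_label, "days\n")
  print(data.frame(time_days = x$times, frac_labeled = x$fractions),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.labeling_dataset <- function(x, ...) {
  data.frame(subject = x$subject, time_days = x$times,
             frac_labeled = x$fractions, T_days = x$T_label,
             stringsAsFactors = FALSE)
}

# accept a single dataset or a list of them
as_dataset_list <- function(datasets) {
  if (inherits(datasets, "labeling_dataset")) datasets <- list(datasets)
  stopifnot(is.list(datasets), length(datasets) >= 1L,
            all(vapply(datasets, inherits, TRUE, "labeling_dataset")))
  datasets
}
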