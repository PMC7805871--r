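# Classed error helper so callers can condition on failure type.
wfh_abort <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "wfh_error")))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Standard error of the mean; 0 (with attribute flag) for a single value.
sem <- function(x) {
  n <- length(x)
  if (n < 2L) return(structure(0, single_value = TRUE))
  stats::sd(x) / sqrt(n)
}
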