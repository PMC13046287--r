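#' Truncated probability mass function over counts 0..n_max
#'
#' A `pmf_vector` stores nonnegative probabilities for counts `0..n_max`
#' together with the untracked tail mass `1 - sum(probs)`. Constructors in
#' this package auto-extend `n_max` until the tail mass drops below
#' `tail_tol` (default `1e-10`).
#'
#' @param probs numeric vector of probabilities for counts `0, 1, ..., n_max`.
#' @param tail_tol maximum allowed tail mass before a warning is raised.
#' @param check if `TRUE`, validate nonnegativity and tail mass.
#' @return An object of class `pmf_vector`.
#' @export
pmf_vector <- function(probs, tail_tol = 1e-10, check = TRUE) {
  probs <- as.numeric(probs)
  tail_mass <- 1 - sum(probs)
  if (check) {
    if (any(!is.finite(probs))) stop("pmf contains non-finite entries")
    if (any(probs < 0)) {
      if (min(probs) < -1e-12) stop("pmf contains negative entries")
      probs[probs < 0] <- 0
      tail_mass <- 1 - sum(probs)
    }
  }
  structure(list(probs = probs, n_max = length(probs) - 1L,
                 tail_mass = tail_mass, tail_tol = tail_tol),
            class = "pmf_vector")
}

#' @export
print.pmf_vector <- function(x, ...) {
  cat(sprintf("pmf over counts 0..%d (tail mass %.3g)\n", x$n_max, x$tail_mass))
  invisible(x)
}

#' Mean and variance of a truncated pmf
#'
#' @param pmf a `pmf_vector`.
#' @return `pmf_mean`: the mean; `pmf_var`: the variance (both over the
#'   truncated support).
#' @export
pmf_mean <- function(pmf) {
  n <- seq_along(pmf$probs) - 1
  sum(n * pmf$probs)
}

#' @rdname pmf_mean
#' @export
pmf_var <- function(pmf) {
  n <- seq_along(pmf$probs) - 1
  m <- sum(n * pmf$probs)
  sum(n^2 * pmf$probs) - m^2
}

# Default truncation point: mean + 10 sd, floored at 10 counts.
default_nmax <- function(mean, variance) {
  max(10L, as.integer(ceiling(mean + 10 * sqrt(max(variance, 0)))))
}

# Evaluate `fn(nmax)` (a vector of probs for 0..nmax), extending nmax until
# the tail mass is below tail_tol. Gives up after `max_rounds` doublings.
autoextend_pmf <- function(fn, nmax0, tail_tol = 1e-10, max_rounds = 12L) {
  nmax <- nmax0
  for (i in seq_len(max_rounds)) {
    probs <- fn(nmax)
    if (1 - sum(probs) < tail_tol) return(pmf_vector(probs, tail_tol))
    nmax <- as.integer(ceiling(nmax * 1.5)) + 10L
  }
  warning(sprintf("pmf tail mass %.3g above tail_tol after extension",
                  1 - sum(probs)))
  pmf_vector(probs, tail_tol)
}

# Attach provenance so model fitting can recognize when a candidate family
# contains the ground truth exactly (MLE is then analytic: KL = 0).
tag_pmf <- function(pmf, family, theta, capture = NULL) {
  attr(pmf, "family") <- family
  attr(pmf, "theta") <- theta
  attr(pmf, "capture") <- capture
  pmf
}

#' Write / read a pmf as two-column TSV (n, probability)
#'
#' @param pmf a `pmf_vector`.
#' @param path file path.
#' @return `read_pmf_tsv` returns a `pmf_vector`.
#' @export
write_pmf_tsv <- function(pmf, path) {
  df <- data.frame(n = seq_along(pmf$probs) - 1L, probability = pmf$probs)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pmf_tsv
#' @export
read_pmf_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  pmf_vector(df$probability)
}
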