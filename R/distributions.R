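#' Steady-state telegraph (Beta-Poisson) pmf
#'
#' Probability mass function of mRNA counts under the two-state telegraph
#' model at steady state,
#' \deqn{P(n) = \frac{\rho^n}{n!}
#'   \frac{(\sigma_{on})_n}{(\sigma_{on}+\sigma_{off})_n}\,
#'   {}_1F_1(\sigma_{on}+n, \sigma_{on}+\sigma_{off}+n, -\rho),}
#' where \eqn{(x)_n} is the rising factorial and \eqn{{}_1F_1} the Kummer
#' confluent hypergeometric function. Evaluation uses the Kummer transform
#' \eqn{{}_1F_1(a,b,-\rho) = e^{-\rho}\,{}_1F_1(b-a,b,\rho)} so that the
#' series has only positive terms; a Beta-Poisson quadrature fallback is used
#' if the series result is not finite.
#'
#' @param params a [telegraph_params()] object.
#' @param n_max truncation point; `NULL` (default) chooses
#'   `ceiling(mean + 10 sd)` and auto-extends until the tail mass is below
#'   `tail_tol`.
#' @param tail_tol tail-mass tolerance (default `1e-10`).
#' @return A [pmf_vector()].
#' @examples
#' p <- telegraph_params(rho = 15, sigma_on = 3, sigma_off = 7)
#' pmf <- telegraph_pmf(p)
#' sum(pmf$probs)  # ~1
#' @export
telegraph_pmf <- function(params, n_max = NULL, tail_tol = 1e-10) {
  stopifnot(inherits(params, "telegraph_params"))
  mv <- telegraph_moments(params)
  fn <- function(nm) {
    probs <- tele_pmf_cpp(params$rho, params$sigma_on, params$sigma_off, nm)
    if (any(!is.finite(probs))) probs <- tele_pmf_quad(params, nm)
    probs
  }
  out <- if (is.null(n_max)) {
    autoextend_pmf(fn, default_nmax(mv[1], mv[2]), tail_tol)
  } else {
    pmf_vector(fn(as.integer(n_max)), tail_tol)
  }
  tag_pmf(out, "telegraph", params)
}

# Adaptive-quadrature fallback: P(n) = E_x~Beta(son,soff)[dpois(n, rho x)].
tele_pmf_quad <- function(params, nmax) {
  vapply(0:nmax, function(n) {
    integrate(function(x)
      stats::dbeta(x, params$sigma_on, params$sigma_off) *
        dpois(n, params$rho * x),
      0, 1, rel.tol = 1e-12, abs.tol = 1e-14)$value
  }, numeric(1))
}

#' Mean and variance of the telegraph model
#'
#' Closed-form first two moments: mean
#' \eqn{\rho\sigma_{on}/(\sigma_{on}+\sigma_{off})} and variance
#' \deqn{\frac{\rho\sigma_{on}\left[(\sigma_{on}+\sigma_{off})
#'   (\sigma_{on}+\sigma_{off}+1)+\rho\sigma_{off}\right]}
#'   {(\sigma_{on}+\sigma_{off})^2(\sigma_{on}+\sigma_{off}+1)}.}
#'
#' @param params a [telegraph_params()] object.
#' @return Named numeric vector `c(mean =, variance =)`.
#' @export
telegraph_moments <- function(params) {
  stopifnot(inherits(params, "telegraph_params"))
  ns <- params$N_sigma
  m <- params$rho * params$sigma_on / ns
  v <- params$rho * params$sigma_on *
    (ns * (ns + 1) + params$rho * params$sigma_off) / (ns^2 * (ns + 1))
  c(mean = m, variance = v)
}

#' Moment-matched effective negative binomial
#'
#' The NB distribution whose first two moments equal those of the telegraph
#' model exactly:
#' \deqn{r_e = \frac{\sigma_{on}(\sigma_{on}+\sigma_{off}+1)}{\sigma_{off}},
#'   \quad
#'   p_e = \frac{(\sigma_{on}+\sigma_{off})(\sigma_{on}+\sigma_{off}+1)}
#'   {(\sigma_{on}+\sigma_{off})(\sigma_{on}+\sigma_{off}+1)
#'    +\rho\sigma_{off}}.}
#'
#' @param params a [telegraph_params()] object with `rho > 0`.
#' @return An [nb_params()] object.
#' @export
effective_nb_params <- function(params) {
  stopifnot(inherits(params, "telegraph_params"))
  if (params$rho <= 0)
    stop("effective NB undefined at rho = 0 (no over-dispersion to match)")
  ns <- params$N_sigma
  re <- params$sigma_on * (ns + 1) / params$sigma_off
  pe <- ns * (ns + 1) / (ns * (ns + 1) + params$rho * params$sigma_off)
  nb_params(re, pe)
}

#' Negative binomial and Poisson pmfs as pmf_vector objects
#'
#' Thin wrappers over [stats::dnbinom()] / [stats::dpois()] returning the
#' package's truncated-pmf container with auto-extended support.
#'
#' @param params an [nb_params()] or [poisson_params()] object.
#' @param n_max truncation point (`NULL` to auto-extend).
#' @param tail_tol tail-mass tolerance.
#' @return A [pmf_vector()].
#' @export
nb_pmf <- function(params, n_max = NULL, tail_tol = 1e-10) {
  stopifnot(inherits(params, "nb_params"))
  fn <- function(nm) dnbinom(0:nm, size = params$r, prob = params$p)
  out <- if (is.null(n_max)) {
    autoextend_pmf(fn, default_nmax(params$mean, params$variance), tail_tol)
  } else pmf_vector(fn(as.integer(n_max)), tail_tol)
  tag_pmf(out, "nb", params)
}

#' @rdname nb_pmf
#' @export
poisson_pmf <- function(params, n_max = NULL, tail_tol = 1e-10) {
  stopifnot(inherits(params, "poisson_params"))
  fn <- function(nm) dpois(0:nm, params$lam)
  out <- if (is.null(n_max)) {
    autoextend_pmf(fn, default_nmax(params$lam, params$lam), tail_tol)
  } else pmf_vector(fn(as.integer(n_max)), tail_tol)
  tag_pmf(out, "poisson", params)
}

#' Sample counts from the telegraph model
#'
#' Uses the compound Beta-Poisson representation: `x ~ Beta(sigma_on,
#' sigma_off)`, `n ~ Poisson(rho * x)`. Fully reproducible given `seed`.
#'
#' @param params a [telegraph_params()] object.
#' @param n_samples number of i.i.d. counts to draw.
#' @param seed integer seed (required; no global state is consumed).
#' @return Integer vector of counts.
#' @export
sample_telegraph <- function(params, n_samples, seed) {
  stopifnot(inherits(params, "telegraph_params"), n_samples >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  x <- rbeta(n_samples, params$sigma_on, params$sigma_off)
  rpois(n_samples, params$rho * x)
}

# Seed hygiene: set a local RNG state and restore the caller's afterwards.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Kullback-Leibler divergence between two truncated pmfs
#'
#' \eqn{\sum_n P(n)\ln[P(n)/Q(n)]} over the common truncated support.
#' Requires `Q(n) > 0` wherever `P(n) > 0`.
#'
#' @param P,Q [pmf_vector()] objects (`P` is the reference/left argument).
#' @return Nonnegative scalar (0 iff `P == Q` on the support).
#' @export
kl_divergence <- function(P, Q) {
  stopifnot(inherits(P, "pmf_vector"), inherits(Q, "pmf_vector"))
  n <- min(P$n_max, Q$n_max)
  p <- P$probs[1:(n + 1)]
  q <- Q$probs[1:(n + 1)]
  sup <- p > 0
  if (any(q[sup] <= 0))
    stop("Q has zero mass on the support of P; KL divergence undefined")
  sum(p[sup] * log(p[sup] / q[sup]))
}
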