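#' Telegraph model parameters
#'
#' Constructs the parameter triple of the two-state (telegraph) model of gene
#' expression: transcription rate `rho`, promoter activation rate `sigma_on`
#' and inactivation rate `sigma_off`, all normalized by the mRNA degradation
#' rate. The derived quantities `N_sigma = sigma_on + sigma_off` (switching
#' timescale relative to mRNA turnover) and `f_on = sigma_on / N_sigma`
#' (fraction of time spent active) are stored alongside.
#'
#' @param rho transcription rate (> 0, or 0 for the silent-gene limit).
#' @param sigma_on activation rate (> 0).
#' @param sigma_off inactivation rate (> 0).
#' @return An object of class `telegraph_params`.
#' @seealso [telegraph_params_from_fon()] for the `(f_on, N_sigma)`
#'   parameterization.
#' @examples
#' p <- telegraph_params(rho = 15, sigma_on = 3, sigma_off = 7)
#' p$f_on      # 0.3
#' p$N_sigma   # 10
#' @export
telegraph_params <- function(rho, sigma_on, sigma_off) {
  stopifnot(is.numeric(rho), is.numeric(sigma_on), is.numeric(sigma_off),
            length(rho) == 1, length(sigma_on) == 1, length(sigma_off) == 1)
  if (!is.finite(rho) || !is.finite(sigma_on) || !is.finite(sigma_off))
    stop("telegraph rates must be finite")
  if (rho < 0) stop("rho must be >= 0")
  if (sigma_on <= 0 || sigma_off <= 0)
    stop("sigma_on and sigma_off must be > 0")
  structure(
    list(rho = rho, sigma_on = sigma_on, sigma_off = sigma_off,
         N_sigma = sigma_on + sigma_off,
         f_on = sigma_on / (sigma_on + sigma_off)),
    class = "telegraph_params"
  )
}

#' Telegraph parameters from the (f_on, N_sigma) reparameterization
#'
#' `sigma_on = f_on * N_sigma`, `sigma_off = (1 - f_on) * N_sigma`. The
#' round trip between the two parameterizations is exact.
#'
#' @param rho transcription rate.
#' @param f_on fraction of time in the active state, in (0, 1).
#' @param N_sigma sum of switching rates, > 0.
#' @return A `telegraph_params` object.
#' @export
telegraph_params_from_fon <- function(rho, f_on, N_sigma) {
  stopifnot(length(f_on) == 1, length(N_sigma) == 1)
  if (!is.finite(f_on) || f_on <= 0 || f_on >= 1)
    stop("f_on must lie strictly in (0, 1)")
  if (!is.finite(N_sigma) || N_sigma <= 0) stop("N_sigma must be > 0")
  telegraph_params(rho, f_on * N_sigma, (1 - f_on) * N_sigma)
}

#' @export
print.telegraph_params <- function(x, ...) {
  cat(sprintf(
    "telegraph parameters: rho = %g, sigma_on = %g, sigma_off = %g\n",
    x$rho, x$sigma_on, x$sigma_off))
  cat(sprintf("  (N_sigma = %g, f_on = %g, mean = %g)\n",
              x$N_sigma, x$f_on, x$rho * x$f_on))
  invisible(x)
}

#' Negative binomial parameters
#'
#' `NB(r, p)` with dispersion/success parameter `r > 0` and success
#' probability `p` in (0, 1]; mean `r(1-p)/p`, variance `r(1-p)/p^2`.
#'
#' @param r dispersion parameter (> 0).
#' @param p success probability in (0, 1].
#' @return An object of class `nb_params` with `mean` and `variance` fields.
#' @export
nb_params <- function(r, p) {
  stopifnot(length(r) == 1, length(p) == 1)
  if (!is.finite(r) || r <= 0) stop("r must be > 0")
  if (!is.finite(p) || p <= 0 || p > 1) stop("p must lie in (0, 1]")
  m <- r * (1 - p) / p
  v <- r * (1 - p) / p^2
  structure(list(r = r, p = p, mean = m, variance = v), class = "nb_params")
}

#' @export
print.nb_params <- function(x, ...) {
  cat(sprintf("NB parameters: r = %g, p = %g (mean %g, variance %g)\n",
              x$r, x$p, x$mean, x$variance))
  invisible(x)
}

#' Poisson parameters
#'
#' @param lam mean count (>= 0).
#' @return An object of class `poisson_params`.
#' @export
poisson_params <- function(lam) {
  stopifnot(length(lam) == 1)
  if (!is.finite(lam) || lam < 0) stop("lam must be >= 0")
  structure(list(lam = lam), class = "poisson_params")
}

#' @export
print.poisson_params <- function(x, ...) {
  cat(sprintf("Poisson parameters: lam = %g\n", x$lam))
  invisible(x)
}
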