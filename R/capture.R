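#' Capture-probability models
#'
#' Describes the distribution across cells of the per-cell transcript capture
#' probability `pcap`: a point mass (every cell identical), a Beta(a, b)
#' distribution, or an empirical density estimated from data (see
#' [capture_empirical()]).
#'
#' @param pcap point-mass capture probability in (0, 1].
#' @return A `capture_model` object with fields `variant`, the defining
#'   parameters, and the first two moments `mean`, `m2` and the coefficient
#'   of variation `cv`.
#' @examples
#' capture_beta(15, 35)   # mean 0.3, CV 0.21
#' @export
capture_point <- function(pcap) {
  stopifnot(length(pcap) == 1)
  if (!is.finite(pcap) || pcap <= 0 || pcap > 1)
    stop("pcap must lie in (0, 1]")
  structure(list(variant = "point", pcap = pcap,
                 mean = pcap, m2 = pcap^2, cv = 0),
            class = "capture_model")
}

#' @rdname capture_point
#' @param a,b Beta shape parameters (> 0); mean `a/(a+b)`, CV
#'   `sqrt(b / (a (a + b + 1)))`.
#' @export
capture_beta <- function(a, b) {
  stopifnot(length(a) == 1, length(b) == 1)
  if (!is.finite(a) || a <= 0 || !is.finite(b) || b <= 0)
    stop("Beta shape parameters must be > 0")
  m <- a / (a + b)
  m2 <- a * (a + 1) / ((a + b) * (a + b + 1))
  structure(list(variant = "beta", a = a, b = b,
                 mean = m, m2 = m2, cv = sqrt(m2 - m^2) / m),
            class = "capture_model")
}

#' Empirical capture-probability model from samples
#'
#' Gaussian kernel density estimate (Silverman's rule bandwidth by default)
#' of per-cell capture probabilities or normalization factors, clipped to the
#' observed sample range and renormalized so it integrates to 1 on its
#' bounds.
#'
#' @param samples positive per-cell values (capture probabilities or
#'   normalization factors).
#' @param bw bandwidth passed to [stats::density()] (default `"nrd0"`,
#'   Silverman's rule).
#' @return A `capture_model` with `variant = "empirical"`, a vectorized
#'   `density` function, and `lower`/`upper` bounds.
#' @export
capture_empirical <- function(samples, bw = "nrd0") {
  samples <- as.numeric(samples)
  if (length(samples) < 2 || any(!is.finite(samples)) || any(samples <= 0))
    stop("need >= 2 finite positive samples")
  lo <- min(samples); hi <- max(samples)
  if (lo == hi) stop("degenerate samples; use capture_point() instead")
  kde <- density(samples, bw = bw)
  f0 <- approxfun(kde$x, kde$y, yleft = 0, yright = 0)
  # trapezoid integrals: the KDE is piecewise linear, quadrature can stall
  xs <- seq(lo, hi, length.out = 4096L)
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(xs))
  z <- trap(f0(xs))
  f <- function(x) ifelse(x >= lo & x <= hi, f0(x) / z, 0)
  m <- trap(xs * f(xs))
  m2 <- trap(xs^2 * f(xs))
  structure(list(variant = "empirical", density = f, lower = lo, upper = hi,
                 mean = m, m2 = m2, cv = sqrt(max(m2 - m^2, 0)) / m),
            class = "capture_model")
}

#' Empirical capture model backed by an explicit density function
#'
#' Like [capture_empirical()] but from a user-supplied density on given
#' bounds (must integrate to 1 within `1e-6`).
#'
#' @param density vectorized density function.
#' @param lower,upper support bounds (`lower >= 0`, `lower < upper`).
#' @return A `capture_model` with `variant = "empirical"`.
#' @export
capture_density <- function(density, lower, upper) {
  stopifnot(is.function(density), lower >= 0, lower < upper)
  z <- integrate(density, lower, upper, rel.tol = 1e-10,
                 subdivisions = 500L)$value
  if (abs(z - 1) > 1e-6)
    stop(sprintf("density integrates to %.8f on [%g, %g], not 1",
                 z, lower, upper))
  m <- integrate(function(x) x * density(x), lower, upper,
                 rel.tol = 1e-10)$value
  m2 <- integrate(function(x) x^2 * density(x), lower, upper,
                  rel.tol = 1e-10)$value
  structure(list(variant = "empirical", density = density,
                 lower = lower, upper = upper,
                 mean = m, m2 = m2, cv = sqrt(max(m2 - m^2, 0)) / m),
            class = "capture_model")
}

#' @export
print.capture_model <- function(x, ...) {
  desc <- switch(x$variant,
    point = sprintf("Dirac(%g)", x$pcap),
    beta = sprintf("Beta(%g, %g)", x$a, x$b),
    empirical = sprintf("empirical on [%g, %g]", x$lower, x$upper))
  cat(sprintf("capture model: %s (mean %.4g, CV %.4g)\n", desc, x$mean, x$cv))
  invisible(x)
}

capture_equal <- function(x, y) {
  if (is.null(x) && is.null(y)) return(TRUE)
  if (is.null(x) || is.null(y)) return(FALSE)
  if (x$variant != y$variant) return(FALSE)
  switch(x$variant,
         point = isTRUE(all.equal(x$pcap, y$pcap)),
         beta = isTRUE(all.equal(c(x$a, x$b), c(y$a, y$b))),
         FALSE)
}

#' Binomial downsampling of true transcript counts
#'
#' Each observed count is `Binomial(true count, pcap)` with the per-cell
#' capture probability; technical noise of UMI-based scRNA-seq.
#'
#' @param true_counts nonnegative integer vector or genes-by-cells matrix.
#' @param pcap_per_cell capture probability per cell, in `[0, 1]`; length 1
#'   or one value per cell (matrix column).
#' @param seed integer seed.
#' @return Thinned counts with the shape of `true_counts`.
#' @export
downsample_counts <- function(true_counts, pcap_per_cell, seed) {
  if (any(true_counts < 0) || any(true_counts != round(true_counts)))
    stop("true_counts must be nonnegative integers")
  if (any(pcap_per_cell < 0 | pcap_per_cell > 1))
    stop("pcap values must lie in [0, 1]")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  if (is.matrix(true_counts)) {
    nc <- ncol(true_counts)
    p <- rep(pcap_per_cell, length.out = nc)
    obs <- rbinom(length(true_counts), size = as.vector(true_counts),
                  prob = rep(p, each = nrow(true_counts)))
    matrix(obs, nrow = nrow(true_counts), dimnames = dimnames(true_counts))
  } else {
    p <- rep(pcap_per_cell, length.out = length(true_counts))
    rbinom(length(true_counts), size = true_counts, prob = p)
  }
}

# Moments of the observed (capture-thinned) counts for each base model,
# by the law of total mean/variance with pcap moments <p> and <p^2>.
observed_moments <- function(kind, params, capture) {
  m1 <- capture$mean; m2 <- capture$m2
  if (kind == "telegraph") {
    ns <- params$N_sigma
    mu <- m1 * params$rho * params$f_on
    v <- m2 * params$rho^2 * params$sigma_on * (1 + params$sigma_on) /
      (ns * (1 + ns)) + mu - mu^2
  } else if (kind == "nb") {
    q <- (1 - params$p) / params$p
    mu <- m1 * params$r * q
    v <- m2 * q^2 * params$r * (params$r + 1) + mu - mu^2
  } else if (kind == "poisson") {
    mu <- m1 * params$lam
    v <- m2 * params$lam^2 + mu - mu^2
  } else stop("unknown model kind")
  c(mean = mu, variance = v)
}

#' Observed-count pmf: telegraph model under Beta-distributed capture
#'
#' Closed-form pmf of observed counts when true counts follow the telegraph
#' model and each cell's capture probability is `Beta(a, b)`:
#' \deqn{P(n) = \frac{\rho^n}{n!}
#'  \frac{(\sigma_{on})_n (a)_n}{(\sigma_{on}+\sigma_{off})_n (a+b)_n}\,
#'  {}_2F_2(a+n, \sigma_{on}+n; a+b+n, \sigma_{on}+\sigma_{off}+n; -\rho),}
#' evaluated as a Kummer-regularized all-positive double series. A point-mass
#' capture model is also accepted (equivalent to rescaling `rho` by `pcap`),
#' and an empirical capture model falls back to quadrature marginalization.
#'
#' @param params a [telegraph_params()] object.
#' @param capture a [capture_beta()] (or [capture_point()] /
#'   [capture_empirical()]) model.
#' @param n_max truncation (`NULL` to auto-extend).
#' @param tail_tol tail-mass tolerance.
#' @return A [pmf_vector()].
#' @export
observed_pmf_telegraph_beta <- function(params, capture, n_max = NULL,
                                        tail_tol = 1e-10) {
  stopifnot(inherits(params, "telegraph_params"),
            inherits(capture, "capture_model"))
  if (capture$variant == "point") {
    thinned <- telegraph_params(params$rho * capture$pcap,
                                params$sigma_on, params$sigma_off)
    return(tag_pmf(telegraph_pmf(thinned, n_max, tail_tol),
                   "telegraph", params, capture))
  }
  if (capture$variant == "empirical") {
    return(marginal_pmf_over_density("telegraph", params, capture,
                                     n_max = n_max))
  }
  mv <- observed_moments("telegraph", params, capture)
  fn <- function(nm) tele_beta_pmf_cpp(params$rho, params$sigma_on,
                                       params$sigma_off,
                                       capture$a, capture$b, nm)
  out <- if (is.null(n_max)) {
    autoextend_pmf(fn, default_nmax(mv[1], mv[2]), tail_tol)
  } else pmf_vector(fn(as.integer(n_max)), tail_tol)
  tag_pmf(out, "telegraph", params, capture)
}

#' Observed-count pmf: NB model under Beta-distributed capture
#'
#' Closed-form pmf of observed counts when true counts are `NB(r, p)` and
#' capture is `Beta(a, b)`; with `q = (1-p)/p`,
#' \deqn{P(n) = \frac{q^n}{n!}\frac{(r)_n (a)_n}{(a+b)_n}\,
#'  {}_2F_1(a+n, r+n; a+b+n; -q),}
#' evaluated through the Pfaff transform (argument `1-p`, all terms
#' positive). Point capture gives the binomially thinned NB directly.
#'
#' @inheritParams observed_pmf_telegraph_beta
#' @param params an [nb_params()] object.
#' @return A [pmf_vector()].
#' @export
observed_pmf_nb_beta <- function(params, capture, n_max = NULL,
                                 tail_tol = 1e-10) {
  stopifnot(inherits(params, "nb_params"),
            inherits(capture, "capture_model"))
  if (capture$variant == "point") {
    return(tag_pmf(nb_pmf(thinned_nb_params(params, capture$pcap),
                          n_max, tail_tol), "nb", params, capture))
  }
  if (capture$variant == "empirical") {
    return(marginal_pmf_over_density("nb", params, capture, n_max = n_max))
  }
  mv <- observed_moments("nb", params, capture)
  fn <- function(nm) nb_beta_pmf_cpp(params$r, params$p,
                                     capture$a, capture$b, nm)
  out <- if (is.null(n_max)) {
    autoextend_pmf(fn, default_nmax(mv[1], mv[2]), tail_tol)
  } else pmf_vector(fn(as.integer(n_max)), tail_tol)
  tag_pmf(out, "nb", params, capture)
}

#' Binomial thinning of an NB distribution
#'
#' Thinning `NB(r, p)` by fixed capture probability `pcap` yields
#' `NB(r, p / (p + pcap (1 - p)))` (probability-generating-function
#' substitution).
#'
#' @param params an [nb_params()] object.
#' @param pcap capture probability in (0, 1].
#' @return An [nb_params()] object.
#' @export
thinned_nb_params <- function(params, pcap) {
  nb_params(params$r, params$p / (params$p + pcap * (1 - params$p)))
}

#' Observed-count pmf: Poisson model under Beta-distributed capture
#'
#' \deqn{P(n) = \frac{\lambda^n}{n!}\frac{(a)_n}{(a+b)_n}\,
#'  {}_1F_1(a+n, a+b+n, -\lambda),}
#' evaluated via the Kummer transform. Point capture rescales the mean.
#'
#' @inheritParams observed_pmf_telegraph_beta
#' @param params a [poisson_params()] object.
#' @return A [pmf_vector()].
#' @export
observed_pmf_poisson_beta <- function(params, capture, n_max = NULL,
                                      tail_tol = 1e-10) {
  stopifnot(inherits(params, "poisson_params"),
            inherits(capture, "capture_model"))
  if (capture$variant == "point") {
    return(tag_pmf(poisson_pmf(poisson_params(params$lam * capture$pcap),
                               n_max, tail_tol), "poisson", params, capture))
  }
  if (capture$variant == "empirical") {
    return(marginal_pmf_over_density("poisson", params, capture,
                                     n_max = n_max))
  }
  mv <- observed_moments("poisson", params, capture)
  fn <- function(nm) pois_beta_pmf_cpp(params$lam, capture$a, capture$b, nm)
  out <- if (is.null(n_max)) {
    autoextend_pmf(fn, default_nmax(mv[1], mv[2]), tail_tol)
  } else pmf_vector(fn(as.integer(n_max)), tail_tol)
  tag_pmf(out, "poisson", params, capture)
}

#' Moments of observed telegraph counts under a capture model
#'
#' Mean, variance and Fano factor of the measured count distribution when the
#' true counts follow the telegraph model and capture is a point mass or
#' Beta distributed. The Fano factor decomposes as
#' \deqn{F = 1 + \frac{\langle p_{cap}\rangle \rho \sigma_{off}}
#'  {(\sigma_{on}+\sigma_{off})(1+\sigma_{on}+\sigma_{off})}
#'  + \mathrm{CV}^2_{p_{cap}}
#'  \frac{\langle p_{cap}\rangle \rho (1+\sigma_{on})}
#'  {1+\sigma_{on}+\sigma_{off}},}
#' so variability in the capture probability strictly increases the Fano
#' factor at fixed mean capture.
#'
#' @param params a [telegraph_params()] object.
#' @param capture a [capture_point()] or [capture_beta()] model.
#' @return Named vector `c(mean =, variance =, fano =)`.
#' @export
observed_moments_telegraph_beta <- function(params, capture) {
  stopifnot(inherits(params, "telegraph_params"),
            inherits(capture, "capture_model"))
  if (!capture$variant %in% c("point", "beta"))
    stop("closed-form moments need a point or Beta capture model")
  mv <- observed_moments("telegraph", params, capture)
  if (mv["mean"] == 0) stop("observed mean is zero; Fano factor undefined")
  c(mv, fano = unname(mv["variance"] / mv["mean"]))
}

#' Gauss-Legendre quadrature specification
#'
#' @param n_nodes number of nodes (>= 2; default 64).
#' @param bounds length-2 numeric `(lower, upper)` of the latent capture /
#'   normalization variable.
#' @return A `quadrature_spec` object.
#' @export
quadrature_spec <- function(n_nodes = 64L, bounds) {
  stopifnot(n_nodes >= 2, length(bounds) == 2,
            bounds[1] >= 0, bounds[1] < bounds[2])
  structure(list(n_nodes = as.integer(n_nodes),
                 lower = bounds[1], upper = bounds[2]),
            class = "quadrature_spec")
}

# Nodes/weights on [lower, upper] (pracma returns them already rescaled).
quad_nodes <- function(quad) {
  gl <- pracma::gaussLegendre(quad$n_nodes, quad$lower, quad$upper)
  list(x = gl$x, w = gl$w)
}

# pmf of count model `kind` at latent scale factor beta (multiplies the
# rate-like parameter: rho, the NB odds (1-p)/p, or lambda).
model_pmf_at_scale <- function(kind, params, beta, nmax) {
  if (kind == "telegraph") {
    tele_pmf_cpp(params$rho * beta, params$sigma_on, params$sigma_off, nmax)
  } else if (kind == "nb") {
    q <- (1 - params$p) / params$p
    dnbinom(0:nmax, size = params$r, prob = 1 / (1 + q * beta))
  } else if (kind == "poisson") {
    dpois(0:nmax, params$lam * beta)
  } else stop("unknown model kind")
}

#' Marginalize a count model over an arbitrary capture / scale density
#'
#' Gauss-Legendre approximation of
#' \deqn{P(n) \approx \frac{\beta_{max}-\beta_{min}}{2}
#'  \sum_j w_j P(n \mid \beta_{x_j}, \theta)\, p(\beta_{x_j}),}
#' where the latent variable multiplies the model's rate-like parameter
#' (`rho` for the telegraph model, the NB odds `(1-p)/p`, `lambda` for
#' Poisson). The result is renormalized; the normalization defect at finite
#' nodes is recorded as attribute `"defect"`.
#'
#' @param model_kind one of `"telegraph"`, `"nb"`, `"poisson"`.
#' @param theta a [telegraph_params()], [nb_params()] or [poisson_params()]
#'   object.
#' @param capture a `capture_model` with an explicit density
#'   ([capture_empirical()] / [capture_density()]; a Beta model is also
#'   accepted and marginalized over its own density).
#' @param quad a [quadrature_spec()]; default 64 nodes on the capture bounds.
#' @param n_max truncation (`NULL` to auto-extend).
#' @param strict if `TRUE`, a normalization defect above `1e-3` is an error
#'   rather than a warning.
#' @return A [pmf_vector()] with attribute `"defect"`.
#' @export
marginal_pmf_over_density <- function(model_kind, theta, capture,
                                      quad = NULL, n_max = NULL,
                                      strict = FALSE) {
  stopifnot(inherits(capture, "capture_model"))
  if (capture$variant == "beta") {
    dens <- function(x) stats::dbeta(x, capture$a, capture$b)
    lo <- 0; hi <- 1
  } else if (capture$variant == "empirical") {
    dens <- capture$density
    lo <- capture$lower; hi <- capture$upper
  } else stop("marginalization needs a density-type capture model")
  if (is.null(quad)) quad <- quadrature_spec(64L, c(lo, hi))
  gl <- quad_nodes(quad)
  px <- dens(gl$x)
  if (any(px < 0)) stop("capture density is negative at a quadrature node")
  params <- theta
  base_mean <- switch(model_kind,
    telegraph = params$rho * params$f_on,
    nb = params$r * (1 - params$p) / params$p,
    poisson = params$lam)
  mu <- capture$mean * base_mean
  fn <- function(nm) {
    mat <- vapply(seq_along(gl$x), function(j)
      model_pmf_at_scale(model_kind, params, gl$x[j], nm) * gl$w[j] * px[j],
      numeric(nm + 1))
    rowSums(mat)
  }
  nm <- if (is.null(n_max)) default_nmax(mu, 4 * mu^2 + mu) else
    as.integer(n_max)
  probs <- fn(nm)
  # extend support until the raw quadrature mass stops growing materially
  repeat {
    total <- sum(probs)
    probs2 <- fn(as.integer(ceiling(nm * 1.5)) + 10L)
    if (sum(probs2) - total < 1e-12) break
    nm <- as.integer(ceiling(nm * 1.5)) + 10L
    probs <- probs2
  }
  defect <- abs(1 - sum(probs))
  if (defect > 1e-3) {
    msg <- sprintf("quadrature normalization defect %.3g exceeds 1e-3", defect)
    if (strict) stop(msg) else warning(msg)
  }
  out <- pmf_vector(probs / sum(probs), check = TRUE)
  attr(out, "defect") <- defect
  tag_pmf(out, model_kind, params, capture)
}
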