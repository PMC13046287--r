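#' Candidate model descriptor
#'
#' @param kind one of `"telegraph"`, `"nb"`, `"poisson"`.
#' @param corrected whether the candidate pmf is integrated over a capture
#'   model (capture parameters are treated as known and not counted).
#' @return A `candidate_model` with `n_params` 3/2/1 for
#'   telegraph/NB/Poisson.
#' @export
candidate_model <- function(kind = c("telegraph", "nb", "poisson"),
                            corrected = FALSE) {
  kind <- match.arg(kind)
  structure(list(kind = kind, corrected = corrected,
                 n_params = switch(kind, telegraph = 3L, nb = 2L,
                                   poisson = 1L)),
            class = "candidate_model")
}

# truncated support of a truth pmf: counts up to cumulative mass 1 - 1e-10
truth_support <- function(truth_pmf, mass_tol = 1e-10) {
  cs <- cumsum(truth_pmf$probs)
  idx <- which(cs > 1 - mass_tol)
  if (length(idx) == 0) truth_pmf$n_max else min(idx[1] - 1L, truth_pmf$n_max)
}

#' Cross-entropy between a model pmf and a ground-truth pmf
#'
#' \eqn{\epsilon_c = -\sum_n P_G(n) \ln P_M(n)} over the truth's truncated
#' support (counts up to cumulative truth mass `1 - 1e-10`). Satisfies the
#' decomposition `cross_entropy = entropy(truth) + KL(model || truth)`.
#' Returns `+Inf` (not an error) if the model assigns zero probability to a
#' supported count.
#'
#' @param model_pmf,truth_pmf [pmf_vector()] objects on a common support
#'   (the model pmf must extend at least to the truth's truncation point).
#' @return Scalar cross-entropy in nats.
#' @export
cross_entropy <- function(model_pmf, truth_pmf) {
  stopifnot(inherits(model_pmf, "pmf_vector"),
            inherits(truth_pmf, "pmf_vector"))
  ns <- truth_support(truth_pmf)
  if (model_pmf$n_max < ns)
    stop("model pmf truncated short of the truth support")
  t <- truth_pmf$probs[1:(ns + 1)]
  m <- model_pmf$probs[1:(ns + 1)]
  sup <- t > 0
  if (any(m[sup] <= 0)) return(Inf)
  -sum(t[sup] * log(m[sup]))
}

#' Shannon entropy of a truncated pmf
#'
#' @param pmf a [pmf_vector()].
#' @return Entropy in nats over the truncated support.
#' @export
pmf_entropy <- function(pmf) {
  ns <- truth_support(pmf)
  p <- pmf$probs[1:(ns + 1)]
  p <- p[p > 0]
  -sum(p * log(p))
}

fit_result <- function(model, theta, cross_entropy, method,
                       converged = TRUE, criterion = NA_real_) {
  structure(list(model = model, theta = theta,
                 cross_entropy = cross_entropy, criterion = criterion,
                 method = method, converged = converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "%s%s fit (%s): cross-entropy/NLL = %.6g, criterion = %.6g, converged = %s\n",
    if (x$model$corrected) "corrected " else "", x$model$kind, x$method,
    x$cross_entropy, x$criterion, x$converged))
  invisible(x)
}

# candidate pmf for given theta / capture, truncated at nmax
candidate_pmf <- function(kind, theta, capture, nmax) {
  if (is.null(capture)) {
    switch(kind,
      telegraph = telegraph_pmf(theta, n_max = nmax),
      nb = nb_pmf(theta, n_max = nmax),
      poisson = poisson_pmf(theta, n_max = nmax))
  } else {
    switch(kind,
      telegraph = observed_pmf_telegraph_beta(theta, capture, n_max = nmax),
      nb = observed_pmf_nb_beta(theta, capture, n_max = nmax),
      poisson = observed_pmf_poisson_beta(theta, capture, n_max = nmax))
  }
}

# Exact mean/variance of a truth pmf: closed forms when the pmf carries its
# generating parameters (avoids truncation bias), truncated sums otherwise.
truth_moments <- function(truth_pmf) {
  fam <- attr(truth_pmf, "family")
  th <- attr(truth_pmf, "theta")
  cap <- attr(truth_pmf, "capture")
  if (!is.null(fam) && !is.null(th)) {
    if (is.null(cap)) cap <- list(mean = 1, m2 = 1)
    mv <- observed_moments(fam, th, cap)
    return(c(mean = unname(mv["mean"]), variance = unname(mv["variance"])))
  }
  c(mean = pmf_mean(truth_pmf), variance = pmf_var(truth_pmf))
}

# Moment-matched theta for a candidate given the truth pmf's mean/variance.
# For corrected candidates the observed-moment equations are inverted, which
# for NB reproduces the effective-NB parameters when the truth is a
# (capture-integrated) telegraph pmf -- the inferred (r, p) are independent
# of the capture parameters.
mom_theta <- function(kind, truth_pmf, capture) {
  mv <- truth_moments(truth_pmf)
  M <- unname(mv["mean"]); V <- unname(mv["variance"])
  m1 <- if (is.null(capture)) 1 else capture$mean
  m2 <- if (is.null(capture)) 1 else capture$m2
  if (kind == "poisson") return(poisson_params(M / m1))
  if (kind == "nb") {
    # observed: mean = m1 r q, var = m2 q^2 r (r+1) + mean - mean^2
    s <- (V - M + M^2) / m2 - (M / m1)^2   # = q^2 r
    if (s <= 0) return(NULL)               # at/below the Poisson boundary
    q <- s * m1 / M
    r <- M / (m1 * q)
    return(nb_params(r, 1 / (1 + q)))
  }
  stop("moment matching not defined for the telegraph candidate")
}

# Nelder-Mead cross-entropy minimization for the telegraph candidate
# (3 deterministic starts on log-parameters).
fit_tele_mle <- function(truth_pmf, capture, reltol = 1e-10,
                         maxit = 2000L) {
  ns <- truth_support(truth_pmf)
  t <- truth_pmf$probs[1:(ns + 1)]
  sup <- t > 0
  M <- pmf_mean(truth_pmf); V <- pmf_var(truth_pmf)
  m1 <- if (is.null(capture)) 1 else capture$mean
  obj <- function(lpar) {
    if (any(abs(lpar) > 15)) return(1e10)
    th <- exp(lpar)
    probs <- if (is.null(capture)) {
      tele_pmf_cpp(th[1], th[2], th[3], ns)
    } else if (capture$variant == "beta") {
      tele_beta_pmf_cpp(th[1], th[2], th[3], capture$a, capture$b, ns)
    } else if (capture$variant == "point") {
      tele_pmf_cpp(th[1] * capture$pcap, th[2], th[3], ns)
    } else {
      p <- telegraph_params(th[1], th[2], th[3])
      marginal_pmf_over_density("telegraph", p, capture,
                                n_max = ns)$probs[1:(ns + 1)]
    }
    m <- probs[sup]
    if (any(m <= 0) || any(!is.finite(m))) return(1e10)
    -sum(t[sup] * log(m))
  }
  # starts: bursting-like (from NB moments), balanced switching, slow gene
  Me <- M / m1; Ve <- (V - M + M^2) / (if (is.null(capture)) 1 else capture$m2) - Me^2
  Ve <- max(Ve, 1e-3)                       # excess variance q^2 r proxy
  r0 <- max(Me^2 / Ve, 1e-2); q0 <- max(Ve / Me, 1e-2)
  starts <- list(
    log(c(max(q0 * max(2 * r0, 5), 0.5), max(r0, 0.05), max(2 * r0, 5))),
    log(c(max(2 * Me, 0.5), 1, 1)),
    log(c(max(3 * Me, 0.5), 0.3, 0.7)))
  best <- NULL
  for (s in starts) {
    res <- optim(s, obj, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = maxit))
    if (is.null(best) || res$value < best$value) best <- res
  }
  th <- exp(best$par)
  list(theta = telegraph_params(th[1], th[2], th[3]), value = best$value,
       converged = best$convergence == 0 && best$value < 1e9)
}

#' Fit a candidate model to a ground-truth pmf
#'
#' Population-level fitting: `method = "mle"` minimizes the cross-entropy
#' between candidate and truth (for candidate families that contain the
#' tagged truth exactly, the minimum is analytic -- the truth itself, with
#' cross-entropy equal to the truth entropy); `method = "mom"` matches
#' moments (mean for Poisson; mean and variance for NB, reproducing the
#' effective-NB parameters when the truth is a telegraph pmf). The telegraph
#' candidate always uses numerical cross-entropy minimization when the truth
#' is outside its family.
#'
#' @param model a [candidate_model()].
#' @param truth_pmf ground-truth [pmf_vector()].
#' @param method `"mle"` or `"mom"` (`"mom"` falls back to `"mle"` for the
#'   telegraph candidate, whose first two moments under-determine it).
#' @param capture optional `capture_model` for corrected candidates.
#' @return A `fit_result`.
#' @export
fit_model_to_pmf <- function(model, truth_pmf, method = c("mle", "mom"),
                             capture = NULL) {
  stopifnot(inherits(model, "candidate_model"),
            inherits(truth_pmf, "pmf_vector"))
  method <- match.arg(method)
  kind <- model$kind
  ns <- truth_support(truth_pmf)

  # analytic MLE when the candidate family contains the tagged truth
  if (method == "mle" || kind == "telegraph") {
    sf <- self_fit_theta(kind, truth_pmf, capture)
    if (!is.null(sf)) {
      return(fit_result(model, sf, pmf_entropy(truth_pmf), "mle"))
    }
  }

  if (kind == "telegraph") {
    fit <- fit_tele_mle(truth_pmf, capture)
    return(fit_result(model, fit$theta, fit$value, "mle",
                      converged = fit$converged))
  }

  theta <- mom_theta(kind, truth_pmf, capture)
  if (is.null(theta)) {  # NB at the Poisson boundary: no over-dispersion
    return(fit_result(model, NULL, Inf, method, converged = FALSE))
  }
  if (method == "mom") {
    mp <- candidate_pmf(kind, theta, capture, ns)
    return(fit_result(model, theta, cross_entropy(mp, truth_pmf), "mom"))
  }
  # numeric MLE from the moment-matched start
  t <- truth_pmf$probs[1:(ns + 1)]; sup <- t > 0
  if (kind == "poisson") {
    obj <- function(llam) {
      p <- candidate_pmf("poisson", poisson_params(exp(llam)), capture,
                         ns)$probs[sup]
      if (any(p <= 0)) return(1e10)
      -sum(t[sup] * log(p))
    }
    res <- optimize(obj, log(theta$lam) + c(-2, 2), tol = 1e-10)
    theta <- poisson_params(exp(res$minimum))
    return(fit_result(model, theta, res$objective, "mle"))
  }
  obj <- function(lpar) {
    if (any(abs(lpar) > 15)) return(1e10)
    r <- exp(lpar[1]); p <- 1 / (1 + exp(lpar[2]))
    mpv <- candidate_pmf("nb", nb_params(r, p), capture, ns)$probs[sup]
    if (any(mpv <= 0) || any(!is.finite(mpv))) return(1e10)
    -sum(t[sup] * log(mpv))
  }
  start <- c(log(theta$r), log((1 - theta$p) / theta$p))
  res <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 2000))
  theta <- nb_params(exp(res$par[1]), 1 / (1 + exp(res$par[2])))
  fit_result(model, theta, res$value, "mle",
             converged = res$convergence == 0)
}

# If candidate (kind, capture) can represent the tagged truth exactly,
# return the representing theta, else NULL. KL >= 0 makes this the MLE.
self_fit_theta <- function(kind, truth_pmf, capture) {
  fam <- attr(truth_pmf, "family")
  if (is.null(fam) || fam != kind) return(NULL)
  th <- attr(truth_pmf, "theta")
  tcap <- attr(truth_pmf, "capture")
  eff_rate <- function(cap) if (is.null(cap)) 1
    else if (cap$variant == "point") cap$pcap else NA_real_
  if (capture_equal(tcap, capture)) return(th)
  # point/absent capture mismatches can be absorbed into the rate parameter
  rt <- eff_rate(tcap); rc <- eff_rate(capture)
  if (is.na(rt) || is.na(rc)) return(NULL)
  scale <- rt / rc
  switch(kind,
    telegraph = telegraph_params(th$rho * scale, th$sigma_on, th$sigma_off),
    poisson = poisson_params(th$lam * scale),
    nb = {  # thinning by rt/rc maps q -> q * rt / rc
      q <- (1 - th$p) / th$p * scale
      nb_params(th$r, 1 / (1 + q))
    })
}

#' Approximate expected BIC (aeBIC)
#'
#' `aeBIC(M, nc) = |M| ln(nc) + 2 nc cross_entropy`, an upper bound on (and
#' fast surrogate for) the expectation of the sample BIC over repeated
#' datasets of size `nc` drawn from the ground truth.
#'
#' @param fit a `fit_result` from [fit_model_to_pmf()].
#' @param nc sample size (number of cells), >= 2.
#' @return Scalar aeBIC value.
#' @export
aebic <- function(fit, nc) {
  stopifnot(inherits(fit, "fit_result"), nc >= 2)
  if (!fit$converged) stop("fit did not converge; aeBIC undefined")
  fit$model$n_params * log(nc) + 2 * nc * fit$cross_entropy
}

#' Sample-based BIC with maximum-likelihood fitting
#'
#' `BIC = |M| ln(nc) - 2 max log-likelihood` on an observed count vector.
#' Poisson uses the closed-form MLE (sample mean); NB profiles out the mean
#' (its MLE is the sample mean) and optimizes the dispersion in 1-D; the
#' telegraph model uses Nelder-Mead from three deterministic starts.
#' Corrected candidates maximize the capture-integrated likelihood.
#'
#' @param model a [candidate_model()].
#' @param counts nonnegative integer vector.
#' @param capture optional `capture_model` for corrected candidates.
#' @return A `fit_result` with `criterion` = BIC and `cross_entropy` = the
#'   negative mean log-likelihood is stored as total NLL.
#' @export
bic <- function(model, counts, capture = NULL) {
  stopifnot(inherits(model, "candidate_model"), length(counts) >= 1)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  nc <- length(counts)
  tab <- tabulate(counts + 1L, nbins = max(counts) + 1L)
  nmax <- max(counts)
  nll_of <- function(kind, theta) {
    p <- candidate_pmf(kind, theta, capture, nmax)$probs
    if (any(p[tab > 0] <= 0)) return(Inf)
    -sum(tab[tab > 0] * log(p[tab > 0]))
  }
  kind <- model$kind
  xbar <- mean(counts)
  if (all(counts == 0)) {
    if (kind == "telegraph")
      return(fit_result(model, NULL, Inf, "mle", converged = FALSE))
    theta <- if (kind == "poisson") poisson_params(0) else
      nb_params(1, 1 - 1e-12)
    return(fit_result(model, theta, 0, "mle",
                      criterion = model$n_params * log(nc)))
  }
  if (kind == "poisson") {
    if (is.null(capture) || capture$variant == "point") {
      scale <- if (is.null(capture)) 1 else capture$pcap
      theta <- poisson_params(xbar / scale)
      nll <- nll_of("poisson", theta)
    } else {
      res <- optimize(function(l) nll_of("poisson", poisson_params(exp(l))),
                      log(xbar / capture$mean) + c(-3, 3), tol = 1e-10)
      theta <- poisson_params(exp(res$minimum)); nll <- res$objective
    }
  } else if (kind == "nb") {
    v <- var(counts) * (nc - 1) / nc
    if (is.null(capture) || capture$variant == "point") {
      # MLE of mu is the sample mean; profile the dispersion
      res <- optimize(function(lr) {
        r <- exp(lr)
        -sum(tab[tab > 0] *
               dnbinom(which(tab > 0) - 1L, size = r, mu = xbar, log = TRUE))
      }, c(-10, 15), tol = 1e-10)
      r <- exp(res$minimum)
      theta0 <- nb_params(r, r / (r + xbar))
      theta <- if (is.null(capture)) theta0 else {
        q <- (1 - theta0$p) / theta0$p / capture$pcap
        nb_params(r, 1 / (1 + q))
      }
      nll <- res$objective
    } else {
      q0 <- max((v - xbar) / xbar, 1e-3) / capture$mean
      r0 <- max(xbar / capture$mean / q0, 1e-2)
      res <- optim(c(log(r0), log(q0)), function(lp) {
        if (any(abs(lp) > 15)) return(1e10)
        nll_of("nb", nb_params(exp(lp[1]), 1 / (1 + exp(lp[2]))))
      }, method = "Nelder-Mead",
      control = list(reltol = 1e-10, maxit = 2000))
      theta <- nb_params(exp(res$par[1]), 1 / (1 + exp(res$par[2])))
      nll <- res$value
    }
  } else {
    # telegraph: Nelder-Mead on log-parameters, three deterministic starts
    v <- max(var(counts) * (nc - 1) / nc, xbar + 1e-3)
    m1 <- if (is.null(capture)) 1 else capture$mean
    q0 <- max((v - xbar) / xbar, 0.05); r0 <- max(xbar / q0, 0.05)
    starts <- list(
      log(c(max(q0 * max(2 * r0, 5) / m1, 0.5), r0, max(2 * r0, 5))),
      log(c(max(2 * xbar / m1, 0.5), 1, 1)),
      log(c(max(3 * xbar / m1, 0.5), 0.3, 0.7)))
    best <- NULL
    for (s in starts) {
      res <- optim(s, function(lp) {
        if (any(abs(lp) > 15)) return(1e10)
        nll_of("telegraph",
               telegraph_params(exp(lp[1]), exp(lp[2]), exp(lp[3])))
      }, method = "Nelder-Mead",
      control = list(reltol = 1e-10, maxit = 2000))
      if (is.null(best) || res$value < best$value) best <- res
    }
    th <- exp(best$par)
    theta <- telegraph_params(th[1], th[2], th[3])
    nll <- best$value
    if (best$value >= 1e9)
      return(fit_result(model, theta, nll, "mle", converged = FALSE))
  }
  fit_result(model, theta, nll, "mle",
             criterion = model$n_params * log(nc) + 2 * nll)
}

#' Monte-Carlo estimate of the expected BIC
#'
#' Draws `n_trials` independent samples of size `nc` from the ground-truth
#' pmf, computes the sample BIC for the candidate model on each, and returns
#' the mean and standard error. Used as the oracle against which the aeBIC
#' surrogate is validated.
#'
#' @param truth_pmf ground-truth [pmf_vector()].
#' @param model a [candidate_model()].
#' @param nc sample size per trial.
#' @param n_trials number of trials (>= 2).
#' @param seed integer seed.
#' @param capture optional `capture_model`.
#' @return Named vector `c(mean =, se =)`.
#' @export
expected_bic_mc <- function(truth_pmf, model, nc, n_trials, seed,
                            capture = NULL) {
  if (n_trials < 2) stop("n_trials must be >= 2 for a standard error")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  support <- 0:truth_pmf$n_max
  vals <- vapply(seq_len(n_trials), function(i) {
    x <- sample(support, nc, replace = TRUE, prob = truth_pmf$probs)
    bic(model, x, capture)$criterion
  }, numeric(1))
  c(mean = mean(vals), se = stats::sd(vals) / sqrt(n_trials))
}

#' Select the best candidate model by aeBIC
#'
#' Fits each candidate to the ground-truth pmf and returns the one with the
#' smallest aeBIC; ties are broken in favor of fewer parameters.
#'
#' @param truth_pmf ground-truth [pmf_vector()].
#' @param nc sample size entering the aeBIC.
#' @param candidates list of [candidate_model()] objects (>= 2).
#' @param method fitting method: `"auto"` (moment matching for NB/Poisson,
#'   cross-entropy MLE for the telegraph model), `"mle"`, or `"mom"`.
#' @param capture optional `capture_model` shared by corrected candidates.
#' @return List with elements `best` (a `candidate_model`), `fits`, and
#'   `aebic` (named numeric).
#' @export
select_best <- function(truth_pmf, nc, candidates = default_candidates(),
                        method = "auto", capture = NULL) {
  stopifnot(length(candidates) >= 2)
  fits <- lapply(candidates, function(cm) {
    mth <- if (method == "auto") {
      if (cm$kind == "telegraph") "mle" else "mom"
    } else method
    cap <- if (cm$corrected) capture else NULL
    fit_model_to_pmf(cm, truth_pmf, method = mth, capture = cap)
  })
  ok <- vapply(fits, function(f) f$converged, logical(1))
  if (!any(ok)) stop("all candidate fits failed")
  crit <- rep(Inf, length(fits))
  crit[ok] <- vapply(fits[ok], aebic, numeric(1), nc = nc)
  names(crit) <- vapply(candidates, function(cm) cm$kind, character(1))
  npar <- vapply(candidates, function(cm) cm$n_params, integer(1))
  best_i <- order(crit, npar)[1]
  list(best = candidates[[best_i]], fits = fits, aebic = crit)
}

#' @rdname select_best
#' @param corrected build the three standard (`FALSE`) or capture-corrected
#'   (`TRUE`) candidates.
#' @export
default_candidates <- function(corrected = FALSE) {
  list(candidate_model("telegraph", corrected),
       candidate_model("nb", corrected),
       candidate_model("poisson", corrected))
}
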