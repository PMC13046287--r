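#' Burst size and frequency implied by the effective NB fit
#'
#' Interpreting the best-fitting (capture-corrected) NB distribution
#' `NB(re, pe)` as the steady-state solution of the bursty expression scheme
#' (geometric burst sizes arriving at a constant frequency) gives
#' \deqn{\hat\beta_f = r_e = \frac{f_{on}(1+N_\sigma)}{1-f_{on}}, \qquad
#'   \hat\beta_s = \frac{1}{p_e}-1 = \frac{\rho(1-f_{on})}{1+N_\sigma}.}
#'
#' @param fon fraction of active time, in (0, 1); vectorized.
#' @param N_sigma sum of switching rates, > 0; vectorized.
#' @param rho transcription rate.
#' @return Data frame with columns `beta_f`, `beta_s`.
#' @export
burst_from_effective_nb <- function(fon, N_sigma, rho) {
  if (any(fon <= 0 | fon >= 1)) stop("fon must lie strictly in (0, 1)")
  if (any(N_sigma <= 0) || any(rho <= 0)) stop("N_sigma and rho must be > 0")
  data.frame(beta_f = fon * (1 + N_sigma) / (1 - fon),
             beta_s = rho * (1 - fon) / (1 + N_sigma))
}

#' Ground-truth burst parameters of the telegraph model
#'
#' True burst frequency `sigma_on = fon * N_sigma` and true burst size
#' `rho / sigma_off = rho / ((1 - fon) N_sigma)`.
#'
#' @inheritParams burst_from_effective_nb
#' @return Data frame with columns `beta_f`, `beta_s`.
#' @export
burst_truth <- function(fon, N_sigma, rho) {
  data.frame(beta_f = fon * N_sigma,
             beta_s = rho / ((1 - fon) * N_sigma))
}

#' Analytic relative errors of the NB-based burst estimates
#'
#' \deqn{RE(\hat\beta_s) = 1 - \frac{(1-f_{on})^2 N_\sigma}{1+N_\sigma},
#'  \qquad RE(\hat\beta_f) = \frac{1+f_{on} N_\sigma}{(1-f_{on}) N_\sigma}.}
#' Both equal `|estimate - truth| / truth` computed from
#' [burst_from_effective_nb()] and [burst_truth()]; note `RE(beta_s) < 1`
#' always, while `RE(beta_f)` is unbounded. Independent of `rho`.
#'
#' @inheritParams burst_from_effective_nb
#' @return Data frame with columns `re_size`, `re_freq`.
#' @export
burst_relative_errors <- function(fon, N_sigma) {
  if (any(fon <= 0 | fon >= 1)) stop("fon must lie strictly in (0, 1)")
  if (any(N_sigma <= 0)) stop("N_sigma must be > 0")
  data.frame(re_size = 1 - (1 - fon)^2 * N_sigma / (1 + N_sigma),
             re_freq = (1 + fon * N_sigma) / ((1 - fon) * N_sigma))
}

#' Rank gene pairs by estimated burst parameters
#'
#' Implements the pairwise ranking protocol: sample pairs of `(f_on,
#' N_sigma)` parameter sets uniformly from a region (typically the
#' NB-optimal mask of a corrected-candidate [phase_scan()]), compute true
#' burst parameters and their effective-NB estimates, form the ground-truth
#' ratio `r_true = min/max < 1` and the estimated ratio preserving the same
#' pair order, and classify each pair as flipped (`r_est > 1`),
#' distance-overestimating (`r_est <= 1`, `r_est > r_true`) or
#' distance-underestimating (`r_est <= 1`, `r_est <= r_true`). Ties count as
#' correctly ordered.
#'
#' @param region data frame with columns `f_on` and `N_sigma` (the sampling
#'   mask); must be nonempty.
#' @param rho transcription rate (default 15).
#' @param n_pairs number of gene pairs to sample.
#' @param seed integer seed.
#' @return A `ranking_result`: per-parameter percentage correctly ordered,
#'   category counts, and relative-error summaries for correctly ranked
#'   pairs.
#' @export
rank_gene_pairs <- function(region, rho = 15, n_pairs = 1000, seed = 1) {
  stopifnot(is.data.frame(region),
            all(c("f_on", "N_sigma") %in% names(region)), n_pairs >= 1)
  if (nrow(region) == 0) stop("empty region mask")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  i1 <- sample.int(nrow(region), n_pairs, replace = TRUE)
  i2 <- sample.int(nrow(region), n_pairs, replace = TRUE)
  g1 <- region[i1, ]; g2 <- region[i2, ]
  tr1 <- burst_truth(g1$f_on, g1$N_sigma, rho)
  tr2 <- burst_truth(g2$f_on, g2$N_sigma, rho)
  es1 <- burst_from_effective_nb(g1$f_on, g1$N_sigma, rho)
  es2 <- burst_from_effective_nb(g2$f_on, g2$N_sigma, rho)
  classify <- function(t1, t2, e1, e2) {
    swap <- t1 > t2                       # put the smaller truth on top
    r_true <- ifelse(swap, t2 / t1, t1 / t2)
    r_est <- ifelse(swap, e2 / e1, e1 / e2)
    cat3 <- ifelse(r_est > 1, "flipped",
                   ifelse(r_est > r_true, "overestimated", "underestimated"))
    list(r_true = r_true, r_est = r_est, category = cat3,
         correct = r_est <= 1)
  }
  freq <- classify(tr1$beta_f, tr2$beta_f, es1$beta_f, es2$beta_f)
  size <- classify(tr1$beta_s, tr2$beta_s, es1$beta_s, es2$beta_s)
  re1 <- burst_relative_errors(g1$f_on, g1$N_sigma)
  cats <- function(cl) table(factor(cl$category,
    levels = c("flipped", "overestimated", "underestimated")))
  structure(list(
    n_pairs = n_pairs,
    pct_correct_freq = 100 * mean(freq$correct),
    pct_correct_size = 100 * mean(size$correct),
    categories_freq = cats(freq),
    categories_size = cats(size),
    re_correct_freq = re1$re_freq[freq$correct],
    re_correct_size = re1$re_size[size$correct],
    ratios = data.frame(r_true_freq = freq$r_true, r_est_freq = freq$r_est,
                        r_true_size = size$r_true, r_est_size = size$r_est)),
    class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf(
    "gene-pair ranking over %d pairs: burst frequency %.1f%% correct, burst size %.1f%% correct\n",
    x$n_pairs, x$pct_correct_freq, x$pct_correct_size))
  invisible(x)
}

#' Per-cell normalization factors from total counts
#'
#' Uses each cell's total UMI count as a proxy for its relative capture
#' probability: `beta_i = V_i / mean(V)`, so `mean(beta) = 1` exactly. If
#' the mean capture probability is known (e.g. from spike-ins), supply
#' `mean_pcap` to place the factors on the absolute capture scale; without
#' it, downstream rate-like estimates (`rho`, NB `b`, `lambda`) are
#' effectively scaled by the unknown mean capture probability.
#'
#' @param total_counts_per_cell positive totals, one per cell.
#' @param mean_pcap optional known mean capture probability.
#' @return Numeric vector of normalization factors.
#' @export
normalization_factors <- function(total_counts_per_cell, mean_pcap = NULL) {
  v <- as.numeric(total_counts_per_cell)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("zero or invalid cell total; such cells should be QC-filtered first")
  beta <- v / mean(v)
  if (!is.null(mean_pcap)) beta <- beta * mean_pcap
  beta
}

#' Maximum-likelihood fit of one gene's counts with capture marginalization
#'
#' Minimizes the negative log-likelihood `J = -sum_i log P(n_i | theta)`
#' where the per-count likelihood marginalizes over the per-cell
#' normalization factor via Gauss-Legendre quadrature against a kernel
#' density estimate of the factors ([marginal_pmf_over_density()]).
#' Parameterizations: telegraph `(rho, sigma_on, sigma_off)` with the latent
#' factor multiplying `rho`; NB `(r, b)` with success probability
#' `1/(1 + b beta)`; Poisson `lambda beta`. Optimization is Nelder-Mead from
#' three deterministic moment-based starts (no internal randomness).
#'
#' @param counts nonnegative integer vector (one gene across cells).
#' @param model a [candidate_model()].
#' @param beta_density a `capture_model` with a density (from
#'   [capture_empirical()] on the normalization factors) or a
#'   [capture_beta()] model.
#' @param quad a [quadrature_spec()] (default 64 nodes on the density
#'   bounds).
#' @param maxit,reltol Nelder-Mead controls.
#' @return A `fit_result` with `cross_entropy` holding the total negative
#'   log-likelihood.
#' @export
fit_gene_mle <- function(counts, model, beta_density, quad = NULL,
                         maxit = 1000L, reltol = 1e-12) {
  stopifnot(inherits(model, "candidate_model"),
            inherits(beta_density, "capture_model"))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (beta_density$variant == "beta") {
    dens <- function(x) stats::dbeta(x, beta_density$a, beta_density$b)
    lo <- 1e-8; hi <- 1
  } else if (beta_density$variant == "empirical") {
    dens <- beta_density$density
    lo <- beta_density$lower; hi <- beta_density$upper
  } else stop("beta_density must carry a density (empirical or beta)")
  if (is.null(quad)) quad <- quadrature_spec(64L, c(lo, hi))
  gl <- quad_nodes(quad)
  px <- dens(gl$x)
  wpx <- gl$w * px
  nmax <- max(counts)
  tab <- tabulate(counts + 1L, nbins = nmax + 1L)
  kind <- model$kind
  marg_probs <- function(params) {
    acc <- numeric(nmax + 1)
    for (j in seq_along(gl$x))
      acc <- acc + wpx[j] * model_pmf_at_scale(kind, params, gl$x[j], nmax)
    s <- sum(acc)
    if (s <= 0 || !is.finite(s)) return(NULL)
    acc / s
  }
  nll <- function(params) {
    p <- marg_probs(params)
    if (is.null(p) || any(p[tab > 0] <= 0)) return(1e10)
    -sum(tab[tab > 0] * log(p[tab > 0]))
  }
  xbar <- mean(counts)
  v <- max(var(counts), xbar * 1.001)
  mb <- beta_density$mean
  if (kind == "poisson") {
    res <- optimize(function(l) nll(poisson_params(exp(l))),
                    log(max(xbar / mb, 1e-6)) + c(-3, 3), tol = 1e-10)
    return(fit_result(model, poisson_params(exp(res$minimum)),
                      res$objective, "mle"))
  }
  if (kind == "nb") {
    q0 <- max((v - xbar) / xbar, 0.05) / mb
    r0 <- max(xbar / (mb * q0), 1e-2)
    starts <- list(c(log(r0), log(q0)),
                   c(log(2 * r0), log(q0 / 2)),
                   c(log(r0 / 2), log(2 * q0)))
    obj <- function(lp) {
      if (any(abs(lp) > 15)) return(1e10)
      nll(nb_params(exp(lp[1]), 1 / (1 + exp(lp[2]))))
    }
  } else {
    rho0 <- 2 * xbar / 0.5
    starts <- list(c(log(max(rho0 / mb, 0.1)), 0, 0),
                   c(log(max(rho0 / mb, 0.1)), log(0.3), log(0.7)),
                   c(log(max(2 * rho0 / mb, 0.1)), log(2), log(2)))
    obj <- function(lp) {
      if (any(abs(lp) > 15)) return(1e10)
      nll(telegraph_params(exp(lp[1]), exp(lp[2]), exp(lp[3])))
    }
  }
  best <- NULL
  for (s in starts) {
    res <- optim(s, obj, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = maxit))
    if (is.null(best) || res$value < best$value) best <- res
  }
  theta <- if (kind == "nb") {
    nb_params(exp(best$par[1]), 1 / (1 + exp(best$par[2])))
  } else {
    telegraph_params(exp(best$par[1]), exp(best$par[2]), exp(best$par[3]))
  }
  fit_result(model, theta, best$value, "mle",
             converged = best$convergence == 0 && best$value < 1e9)
}

#' BIC model selection and burst-parameter extraction for one gene
#'
#' Given capture-corrected fits of the telegraph, NB and Poisson models to
#' one gene's counts (from [fit_gene_mle()]), computes each model's BIC
#' (`|M| ln nc + 2 J`), selects the minimum among converged fits, and
#' extracts burst estimates: telegraph `beta_f = sigma_on`, `beta_s =
#' rho / sigma_off`; NB `beta_f = r`, `beta_s = b = (1-p)/p`.
#'
#' @param fits named list of `fit_result`s with names among `"telegraph"`,
#'   `"nb"`, `"poisson"`.
#' @param nc number of cells the fits used.
#' @param gene optional gene identifier.
#' @return A `gene_fit`: selected model kind, per-model BIC, and a data
#'   frame of burst estimates per model where defined.
#' @export
classify_and_extract <- function(fits, nc, gene = NA_character_) {
  stopifnot(is.list(fits), length(fits) >= 2)
  ok <- vapply(fits, function(f) f$converged, logical(1))
  if (sum(ok) < 2) {
    return(structure(list(gene = gene, selected = NA_character_,
                          bic = NULL, fits = fits, bursts = NULL,
                          flagged = TRUE), class = "gene_fit"))
  }
  bics <- vapply(fits, function(f)
    if (f$converged) f$model$n_params * log(nc) + 2 * f$cross_entropy
    else Inf, numeric(1))
  selected <- names(which.min(bics))
  bursts <- do.call(rbind, lapply(names(fits), function(k) {
    f <- fits[[k]]
    if (!f$converged) return(NULL)
    if (k == "telegraph") {
      data.frame(model = k, beta_f = f$theta$sigma_on,
                 beta_s = f$theta$rho / f$theta$sigma_off)
    } else if (k == "nb") {
      data.frame(model = k, beta_f = f$theta$r,
                 beta_s = (1 - f$theta$p) / f$theta$p)
    } else NULL
  }))
  structure(list(gene = gene, selected = selected, bic = bics,
                 fits = fits, bursts = bursts, flagged = FALSE),
            class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  cat(sprintf("gene %s: selected %s\n", x$gene, x$selected))
  invisible(x)
}

#' Evaluate burst inference against simulation ground truth
#'
#' Computes relative-error distributions of the burst estimates per model
#' and the percentage of randomly sampled gene pairs whose estimated burst
#' frequency / size ordering matches the true ordering, restricted to
#' NB-selected genes.
#'
#' @param gene_fits list of `gene_fit` objects (from
#'   [classify_and_extract()]).
#' @param truths data frame with one row per gene: columns `beta_f`,
#'   `beta_s` (true values, e.g. from [burst_truth()]).
#' @param seed integer seed for pair sampling.
#' @param n_sets number of gene pairs to sample.
#' @return List with per-model relative-error data frames and ranking
#'   percentages.
#' @export
evaluate_inference <- function(gene_fits, truths, seed = 1, n_sets = 1000) {
  stopifnot(length(gene_fits) == nrow(truths))
  est <- function(model) {
    do.call(rbind, lapply(seq_along(gene_fits), function(i) {
      gf <- gene_fits[[i]]
      if (gf$flagged || is.null(gf$bursts)) return(NULL)
      row <- gf$bursts[gf$bursts$model == model, ]
      if (nrow(row) != 1) return(NULL)
      data.frame(gene = i, beta_f = row$beta_f, beta_s = row$beta_s,
                 re_f = abs(row$beta_f - truths$beta_f[i]) / truths$beta_f[i],
                 re_s = abs(row$beta_s - truths$beta_s[i]) / truths$beta_s[i],
                 selected = gf$selected)
    }))
  }
  re <- list(telegraph = est("telegraph"), nb = est("nb"))
  nb_sel <- which(vapply(gene_fits, function(g)
    !g$flagged && identical(g$selected, "nb"), logical(1)))
  ranking <- NULL
  if (length(nb_sel) >= 2) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    rank_pct <- function(tab) {
      i1 <- sample(tab$gene, n_sets, replace = TRUE)
      i2 <- sample(tab$gene, n_sets, replace = TRUE)
      ef <- setNames(tab$beta_f, tab$gene); es <- setNames(tab$beta_s, tab$gene)
      ok_f <- sign(ef[as.character(i1)] - ef[as.character(i2)]) *
        sign(truths$beta_f[i1] - truths$beta_f[i2]) >= 0
      ok_s <- sign(es[as.character(i1)] - es[as.character(i2)]) *
        sign(truths$beta_s[i1] - truths$beta_s[i2]) >= 0
      c(freq = 100 * mean(ok_f), size = 100 * mean(ok_s))
    }
    ranking <- lapply(re, function(tab) {
      if (is.null(tab)) return(NULL)
      tab <- tab[tab$gene %in% nb_sel, ]
      if (nrow(tab) < 2) return(NULL)
      rank_pct(tab)
    })
  } else {
    warning("fewer than 2 NB-selected genes; ranking skipped")
  }
  list(relative_errors = re, ranking = ranking, n_nb_selected = length(nb_sel))
}
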