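#' Default phase-diagram grid
#'
#' 206 log-spaced values of `N_sigma` in `[0.1, 1000]` crossed with 100
#' linearly spaced values of `f_on` in `(0.005, 0.995)` -- about
#' `2.06e4` grid points.
#'
#' @param n_nsigma,n_fon grid resolutions.
#' @param nsigma_range,fon_range axis ranges.
#' @return List with numeric vectors `nsigma` and `fon`.
#' @export
phase_grid <- function(n_nsigma = 206L, n_fon = 100L,
                       nsigma_range = c(0.1, 1000),
                       fon_range = c(0.005, 0.995)) {
  list(nsigma = 10^seq(log10(nsigma_range[1]), log10(nsigma_range[2]),
                       length.out = n_nsigma),
       fon = seq(fon_range[1], fon_range[2], length.out = n_fon))
}

#' Scan the (N_sigma, f_on) plane for the aeBIC-optimal model
#'
#' At every grid point the ground truth is the telegraph model pmf with the
#' given `rho` (optionally downsampled through `truth_capture`); the three
#' candidate models (telegraph, NB, Poisson; standard or capture-corrected)
#' are fitted and the aeBIC winner recorded for each requested sample size.
#' Because the fitted cross-entropies do not depend on the sample size, a
#' single scan yields winner maps for any number of `nc` values.
#'
#' Fitting follows the package default: moment matching for NB and Poisson,
#' cross-entropy MLE for the telegraph candidate (analytic when the truth
#' lies inside the candidate family, Nelder-Mead otherwise).
#'
#' @param grid a [phase_grid()] list.
#' @param rho transcription rate (fixed across the scan; default 15).
#' @param nc numeric vector of sample sizes.
#' @param truth_capture `NULL` (no technical noise) or a `capture_model`
#'   through which the ground truth is downsampled.
#' @param candidates `"standard"` (candidates ignore capture) or
#'   `"corrected"` (candidate pmfs are integrated over `truth_capture`,
#'   whose parameters are treated as known).
#' @param verbose print progress every few hundred points.
#' @return A `phase_diagram`: grid data frame with per-model cross-entropies,
#'   winner strings per `nc`, and per-model area fractions (percent).
#' @examples
#' \donttest{
#' pd <- phase_scan(phase_grid(40, 20), rho = 15, nc = 100)
#' phase_fractions(pd, 100)
#' }
#' @export
phase_scan <- function(grid = phase_grid(), rho = 15, nc = 100,
                       truth_capture = NULL,
                       candidates = c("standard", "corrected"),
                       verbose = FALSE) {
  candidates <- match.arg(candidates)
  if (candidates == "corrected" && is.null(truth_capture))
    stop("corrected candidates require a capture model")
  stopifnot(all(nc >= 2))
  pts <- expand.grid(N_sigma = grid$nsigma, f_on = grid$fon,
                     KEEP.OUT.ATTRS = FALSE)
  npt <- nrow(pts)
  cand_cap <- if (candidates == "corrected") truth_capture else NULL
  # Is the telegraph candidate family guaranteed to contain the truth?
  tele_in_family <- is.null(truth_capture) ||
    truth_capture$variant == "point" ||
    (candidates == "corrected")
  eps <- matrix(NA_real_, npt, 3,
                dimnames = list(NULL, c("telegraph", "nb", "poisson")))
  valid <- rep(TRUE, npt)
  nb_model <- candidate_model("nb", candidates == "corrected")
  po_model <- candidate_model("poisson", candidates == "corrected")
  for (i in seq_len(npt)) {
    pars <- telegraph_params_from_fon(rho, pts$f_on[i], pts$N_sigma[i])
    truth <- if (is.null(truth_capture)) telegraph_pmf(pars) else
      observed_pmf_telegraph_beta(pars, truth_capture)
    ns <- truth_support(truth)
    eps[i, "telegraph"] <- if (tele_in_family) pmf_entropy(truth) else {
      ft <- fit_tele_mle(truth, NULL)
      if (!ft$converged) { valid[i] <- FALSE; NA_real_ } else ft$value
    }
    fnb <- fit_model_to_pmf(nb_model, truth, method = "mom",
                            capture = cand_cap)
    eps[i, "nb"] <- if (fnb$converged) fnb$cross_entropy else Inf
    fpo <- fit_model_to_pmf(po_model, truth, method = "mom",
                            capture = cand_cap)
    eps[i, "poisson"] <- fpo$cross_entropy
    if (verbose && i %% 500 == 0)
      message(sprintf("phase_scan: %d / %d points", i, npt))
  }
  npar <- c(telegraph = 3, nb = 2, poisson = 1)
  winners <- matrix(NA_character_, npt, length(nc),
                    dimnames = list(NULL, paste0("nc_", nc)))
  for (j in seq_along(nc)) {
    crit <- sweep(2 * nc[j] * eps, 2, npar * log(nc[j]), `+`)
    w <- apply(crit, 1, function(z) {
      if (any(is.na(z))) return(NA_character_)
      # minimal criterion; ties broken toward fewer parameters
      ord <- order(z, npar)
      names(z)[ord[1]]
    })
    winners[, j] <- w
  }
  fractions <- do.call(rbind, lapply(seq_along(nc), function(j) {
    wv <- winners[valid, j]
    data.frame(nc = nc[j],
               telegraph = 100 * mean(wv == "telegraph"),
               nb = 100 * mean(wv == "nb"),
               poisson = 100 * mean(wv == "poisson"))
  }))
  structure(list(grid = cbind(pts, as.data.frame(eps), valid = valid),
                 nc = nc, winners = winners, fractions = fractions,
                 rho = rho, truth_capture = truth_capture,
                 candidates = candidates),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("phase diagram: %d points, rho = %g, %s candidates\n",
              nrow(x$grid), x$rho, x$candidates))
  print(x$fractions, row.names = FALSE)
  invisible(x)
}

#' Per-model area fractions of a phase diagram
#'
#' @param pd a `phase_diagram` from [phase_scan()].
#' @param nc one of the sample sizes the scan was computed for.
#' @return Named numeric vector of percentages (telegraph, nb, poisson).
#' @export
phase_fractions <- function(pd, nc) {
  stopifnot(inherits(pd, "phase_diagram"))
  row <- pd$fractions[pd$fractions$nc == nc, ]
  if (nrow(row) != 1) stop("nc not present in this scan")
  c(telegraph = row$telegraph, nb = row$nb, poisson = row$poisson)
}

#' Grid points won by a given model
#'
#' @param pd a `phase_diagram`.
#' @param nc sample size column to use.
#' @param kind winning model kind (default `"nb"`, the mask used for burst
#'   gene-pair ranking).
#' @return Data frame with columns `f_on`, `N_sigma`.
#' @export
phase_region <- function(pd, nc, kind = "nb") {
  stopifnot(inherits(pd, "phase_diagram"))
  col <- paste0("nc_", nc)
  if (!col %in% colnames(pd$winners)) stop("nc not present in this scan")
  sel <- pd$winners[, col] == kind & pd$grid$valid
  sel[is.na(sel)] <- FALSE
  pd$grid[sel, c("f_on", "N_sigma")]
}

#' Write a phase diagram as TSV (+ JSON fractions sidecar)
#'
#' Columns: `N_sigma`, `f_on`, `winner`, and the per-model aeBIC values at
#' the requested `nc`. Fractions go to `<path>.fractions.json`.
#'
#' @param pd a `phase_diagram`.
#' @param path output TSV path.
#' @param nc sample size used for the winner/aeBIC columns (default: first).
#' @return `path`, invisibly.
#' @export
write_phase_tsv <- function(pd, path, nc = pd$nc[1]) {
  col <- paste0("nc_", nc)
  npar <- c(telegraph = 3, nb = 2, poisson = 1)
  eps <- as.matrix(pd$grid[, c("telegraph", "nb", "poisson")])
  crit <- sweep(2 * nc * eps, 2, npar * log(nc), `+`)
  out <- data.frame(N_sigma = pd$grid$N_sigma, f_on = pd$grid$f_on,
                    winner = pd$winners[, col],
                    aeBIC_tele = crit[, "telegraph"],
                    aeBIC_nb = crit[, "nb"],
                    aeBIC_pois = crit[, "poisson"])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    as.list(setNames(as.data.frame(pd$fractions), names(pd$fractions))),
    paste0(path, ".fractions.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
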