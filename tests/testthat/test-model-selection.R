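test_that("cross-entropy reduces to entropy and decomposes exactly", {
  p <- telegraph_params(15, 3, 7)
  tpmf <- telegraph_pmf(p)
  expect_lt(abs(cross_entropy(tpmf, tpmf) - pmf_entropy(tpmf)), 1e-12)

  # decomposition: cross-entropy = entropy(truth) + KL(truth || model)
  set.seed(5)
  for (i in 1:10) {
    a <- runif(12); a <- a / sum(a)
    b <- runif(12); b <- b / sum(b)
    G <- pmf_vector(a); M <- pmf_vector(b)
    expect_lt(abs(cross_entropy(M, G) -
                    (pmf_entropy(G) + kl_divergence(G, M))), 1e-10)
  }

  # direct-summation oracle on a 10-point toy pmf
  g <- (1:10) / sum(1:10); m <- rev(g)
  expect_lt(abs(cross_entropy(pmf_vector(m), pmf_vector(g)) -
                  (-sum(g * log(m)))), 1e-14)

  # zero model mass on supported counts gives +Inf, not an error
  expect_identical(cross_entropy(pmf_vector(c(1, 0)),
                                 pmf_vector(c(0.5, 0.5))), Inf)
})

test_that("population fits: self-fit, moment matching, MLE vs MOM", {
  p <- telegraph_params_from_fon(15, 0.3, 10)
  truth <- telegraph_pmf(p)

  # telegraph self-fit attains the entropy bound
  ft <- fit_model_to_pmf(candidate_model("telegraph"), truth, "mle")
  expect_lt(abs(ft$cross_entropy - pmf_entropy(truth)), 1e-8)

  # NB moment matching reproduces the effective-NB parameters
  fnb <- fit_model_to_pmf(candidate_model("nb"), truth, "mom")
  e <- effective_nb_params(p)
  expect_lt(abs(fnb$theta$r - e$r), 1e-8)
  expect_lt(abs(fnb$theta$p - e$p), 1e-10)

  # MLE improves on MOM by less than 1e-3 nats across the fast-switching
  # regime where the NB candidate is a plausible model
  pars <- expand.grid(fon = c(0.15, 0.35, 0.55, 0.75),
                      nsigma = c(10, 30, 100, 300, 1000))
  for (i in seq_len(nrow(pars))) {
    tp <- telegraph_params_from_fon(15, pars$fon[i], pars$nsigma[i])
    tr <- telegraph_pmf(tp)
    fm <- fit_model_to_pmf(candidate_model("nb"), tr, "mom")
    fl <- fit_model_to_pmf(candidate_model("nb"), tr, "mle")
    expect_lt(fm$cross_entropy - fl$cross_entropy, 1e-3)
    expect_gte(fm$cross_entropy - fl$cross_entropy, -1e-8)
  }
})

test_that("aeBIC closed form, upper-bound property and sample-size scaling", {
  p <- telegraph_params_from_fon(15, 0.3, 10)
  truth <- telegraph_pmf(p)
  f <- fit_model_to_pmf(candidate_model("nb"), truth, "mle")
  # difference across sample sizes follows the closed form
  d <- aebic(f, 1000) - aebic(f, 100)
  expect_equal(d, 2 * log(10) + 2 * 900 * f$cross_entropy, tolerance = 1e-10)

  # aeBIC >= E[BIC] within Monte-Carlo error, and the gap is small
  for (kind in c("poisson", "nb")) {
    cm <- candidate_model(kind)
    ff <- fit_model_to_pmf(cm, truth, "mle")
    mc <- expected_bic_mc(truth, cm, nc = 100, n_trials = 300, seed = 5)
    expect_gte(aebic(ff, 100) - mc["mean"], -3 * mc["se"])
    expect_lt(abs(aebic(ff, 100) - mc["mean"]) / mc["mean"], 0.01)
  }
  expect_error(expected_bic_mc(truth, candidate_model("nb"), 100, 1, 1),
               "n_trials")
})

test_that("sample BIC: nested-model behavior and determinism", {
  set.seed(42)
  x <- rpois(10000, 5)
  bp <- bic(candidate_model("poisson"), x)
  bn <- bic(candidate_model("nb"), x)
  expect_lt(bp$criterion, bn$criterion)  # penalty dominates for true submodel
  expect_lt(abs(bp$theta$lam - mean(x)), 1e-12)

  # BIC difference equals the likelihood-ratio statistic plus the penalty gap
  lr <- 2 * (-bn$cross_entropy - (-bp$cross_entropy))
  expect_equal(bp$criterion - bn$criterion, lr - log(length(x)),
               tolerance = 1e-8)

  # determinism on identical input
  y <- sample_telegraph(telegraph_params(15, 1, 2), 500, seed = 8)
  b1 <- bic(candidate_model("telegraph"), y)
  b2 <- bic(candidate_model("telegraph"), y)
  expect_identical(b1$criterion, b2$criterion)

  # degenerate all-zero data
  z <- rep(0L, 50)
  expect_false(bic(candidate_model("telegraph"), z)$converged)
  expect_true(is.finite(bic(candidate_model("poisson"), z)$criterion))
})

test_that("aeBIC selection follows the switching-speed regimes", {
  # fast switching: Poisson preferred at moderate sample size
  fast <- telegraph_pmf(telegraph_params_from_fon(15, 0.3, 300))
  expect_identical(select_best(fast, 100)$best$kind, "poisson")

  # slow switching (bimodal): telegraph preferred at large sample size
  slow <- telegraph_pmf(telegraph_params_from_fon(15, 0.3, 0.3))
  expect_identical(select_best(slow, 1e4)$best$kind, "telegraph")

  # exact NB truth: NB wins over telegraph by the parameter penalty
  nbtruth <- nb_pmf(nb_params(2, 0.3))
  expect_identical(select_best(nbtruth, 100)$best$kind, "nb")
  expect_identical(select_best(nbtruth, 1e4)$best$kind, "nb")
})

test_that("phase scan fractions are complete and grid-stable", {
  pd1 <- phase_scan(phase_grid(52, 25), rho = 15, nc = 100)
  fr1 <- phase_fractions(pd1, 100)
  expect_equal(sum(fr1), 100, tolerance = 1e-9)

  pd2 <- phase_scan(phase_grid(103, 50), rho = 15, nc = 100)
  fr2 <- phase_fractions(pd2, 100)
  expect_lt(max(abs(fr1 - fr2)), 1)  # < 1 pp under grid doubling

  # region accessor and TSV writer
  reg <- phase_region(pd1, 100, "nb")
  expect_true(all(c("f_on", "N_sigma") %in% names(reg)))
  expect_lt(abs(nrow(reg) - fr1[["nb"]] / 100 * nrow(pd1$grid)), 1.5)
  tf <- tempfile(fileext = ".tsv")
  write_phase_tsv(pd1, tf)
  tab <- read.table(tf, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), nrow(pd1$grid))
  expect_true(file.exists(paste0(tf, ".fractions.json")))
})
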