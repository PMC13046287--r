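test_that("burst estimates from the effective NB and their exact errors", {
  # direct substitution
  est <- burst_from_effective_nb(0.3, 10, 15)
  expect_equal(est$beta_f, 0.3 * 11 / 0.7)
  expect_equal(est$beta_s, 15 * 0.7 / 11)

  # identity with the effective NB parameters across a sweep
  pars <- rand_tele_params(20, seed = 3)
  for (i in seq_len(nrow(pars))) {
    tp <- telegraph_params_from_fon(pars$rho[i], pars$fon[i], pars$nsigma[i])
    e <- effective_nb_params(tp)
    b <- burst_from_effective_nb(tp$f_on, tp$N_sigma, tp$rho)
    expect_lt(abs(b$beta_f - e$r) / e$r, 1e-12)
    expect_lt(abs(b$beta_s - (1 - e$p) / e$p) / b$beta_s, 1e-12)
  }

  # bursting regime: estimates converge to the truth
  b <- burst_from_effective_nb(1e-4, 1e4, 15)
  tr <- burst_truth(1e-4, 1e4, 15)
  expect_lt(abs(b$beta_f - tr$beta_f) / tr$beta_f, 1e-3)
  expect_lt(abs(b$beta_s - tr$beta_s) / tr$beta_s, 1e-3)

  expect_error(burst_from_effective_nb(1, 10, 15))
})

test_that("analytic relative errors equal brute-force arithmetic", {
  pars <- rand_tele_params(30, seed = 19)
  re <- burst_relative_errors(pars$fon, pars$nsigma)
  est <- burst_from_effective_nb(pars$fon, pars$nsigma, pars$rho)
  tr <- burst_truth(pars$fon, pars$nsigma, pars$rho)
  expect_lt(max(abs(re$re_size - abs(est$beta_s - tr$beta_s) / tr$beta_s)),
            1e-12)
  expect_lt(max(abs(re$re_freq - abs(est$beta_f - tr$beta_f) / tr$beta_f)),
            1e-12)

  # burst size error is always below 1; both vanish for fon->0, Nsigma->inf
  expect_true(all(re$re_size < 1))
  lim <- burst_relative_errors(1e-6, 1e6)
  expect_lt(lim$re_size, 1e-3)
  expect_lt(lim$re_freq, 1e-3)
})

test_that("corrected-NB moment inversion is capture-independent", {
  # inferred (r, p) equal the effective NB regardless of Beta(a,b)
  p <- telegraph_params_from_fon(15, 0.4, 20)
  e <- effective_nb_params(p)
  set.seed(8)
  for (i in 1:8) {
    a <- runif(1, 2, 100); b <- runif(1, 5, 250)
    cb <- capture_beta(a, b)
    truth <- observed_pmf_telegraph_beta(p, cb)
    f <- fit_model_to_pmf(candidate_model("nb", corrected = TRUE), truth,
                          "mom", capture = cb)
    expect_lt(abs(f$theta$r - e$r) / e$r, 1e-8)
    expect_lt(abs(f$theta$p - e$p) / e$p, 1e-10)
  }
})

test_that("gene-pair ranking protocol: partition, ties and percentages", {
  # identical genes: ratio 1, counted correctly ordered
  reg1 <- data.frame(f_on = 0.3, N_sigma = 12)
  rk1 <- rank_gene_pairs(reg1, rho = 15, n_pairs = 10, seed = 2)
  expect_equal(rk1$pct_correct_freq, 100)
  expect_equal(rk1$pct_correct_size, 100)

  set.seed(6)
  reg <- data.frame(f_on = runif(200, 0.1, 0.8),
                    N_sigma = 10^runif(200, 0.5, 2))
  rk <- rank_gene_pairs(reg, rho = 15, n_pairs = 500, seed = 9)
  expect_equal(sum(rk$categories_freq), 500)
  expect_equal(sum(rk$categories_size), 500)
  expect_true(rk$pct_correct_freq >= 0 && rk$pct_correct_freq <= 100)
  # flipped category matches the complement of the correct percentage
  expect_equal(100 - rk$pct_correct_freq,
               100 * rk$categories_freq[["flipped"]] / 500)
  expect_error(rank_gene_pairs(reg[0, ], 15, 10, 1), "empty")
})

test_that("normalization factors proxy the capture probability", {
  expect_equal(normalization_factors(c(5, 5, 5)), c(1, 1, 1))
  b <- normalization_factors(c(2, 4, 9, 1))
  expect_equal(mean(b), 1)
  expect_equal(normalization_factors(c(5, 5), mean_pcap = 0.3), c(0.3, 0.3))
  expect_error(normalization_factors(c(3, 0)))

  # simulated genome: totals correlate strongly with true pcap
  ds <- simulate_genome(genome_config(n_cells = 200, genes_per_fon = 60,
                                      seed = 12))
  betas <- normalization_factors(colSums(ds$observed_counts))
  expect_gt(cor(betas, ds$pcap_per_cell), 0.9)
})

test_that("per-gene MLE with capture marginalization", {
  # Poisson candidate with beta = 1: MLE is the sample mean
  set.seed(30)
  x <- rpois(500, 4)
  capn <- capture_density(function(z)
    ifelse(z >= 0.999 & z <= 1.001, 500, 0), 0.999, 1.001)
  f <- fit_gene_mle(x, candidate_model("poisson", TRUE), capn)
  expect_lt(abs(f$theta$lam - mean(x)) / mean(x), 1e-3)

  # deterministic given fixed starts
  ds <- simulate_genome(genome_config(n_cells = 250, fon_set = 0.3,
                                      genes_per_fon = 40, seed = 44))
  betas <- normalization_factors(colSums(ds$observed_counts))
  bd <- capture_empirical(betas)
  cnts <- ds$observed_counts[1, ]
  f1 <- fit_gene_mle(cnts, candidate_model("nb", TRUE), bd)
  f2 <- fit_gene_mle(cnts, candidate_model("nb", TRUE), bd)
  expect_identical(f1$cross_entropy, f2$cross_entropy)
  expect_true(f1$converged)
})

test_that("BIC selection per gene and inference evaluation", {
  # counts from an exact corrected-Poisson truth select Poisson
  set.seed(50)
  pc <- rbeta(800, 15, 35)
  x <- rpois(800, 10 * pc)
  bd <- capture_beta(15, 35)
  fits <- list(
    telegraph = fit_gene_mle(x, candidate_model("telegraph", TRUE), bd),
    nb = fit_gene_mle(x, candidate_model("nb", TRUE), bd),
    poisson = fit_gene_mle(x, candidate_model("poisson", TRUE), bd))
  gf <- classify_and_extract(fits, length(x), "toy")
  expect_identical(gf$selected, "poisson")
  expect_identical(gf$selected, names(which.min(gf$bic)))

  # perfect estimates give zero flips and zero relative error
  mk_fit <- function(bf, bs) {
    structure(list(gene = NA, selected = "nb", flagged = FALSE,
                   bursts = data.frame(model = "nb", beta_f = bf,
                                       beta_s = bs)),
              class = "gene_fit")
  }
  truths <- data.frame(beta_f = c(1, 2, 3, 4), beta_s = c(4, 3, 2, 1))
  gfs <- lapply(1:4, function(i) mk_fit(truths$beta_f[i], truths$beta_s[i]))
  ev <- evaluate_inference(gfs, truths, seed = 1, n_sets = 100)
  expect_equal(unname(ev$ranking$nb["freq"]), 100)
  expect_equal(unname(ev$ranking$nb["size"]), 100)
  expect_true(all(ev$relative_errors$nb$re_f == 0))
})
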