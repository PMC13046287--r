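test_that("binomial downsampling identities and thinning property", {
  m <- matrix(rpois(60, 5), nrow = 6,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  storage.mode(m) <- "integer"
  expect_identical(downsample_counts(m, rep(1, 10), seed = 1), m)
  expect_true(all(downsample_counts(m, rep(0, 10), seed = 1) == 0))
  expect_error(downsample_counts(m, rep(1.5, 10), seed = 1))

  # thinning a telegraph sample at fixed pcap = rescaling rho by pcap
  p <- telegraph_params(15, 3, 7)
  x <- sample_telegraph(p, 1e6, seed = 31)
  y <- downsample_counts(x, 0.3, seed = 32)
  thinned <- telegraph_pmf(telegraph_params(0.3 * 15, 3, 7))
  expect_lt(tv_to_counts(thinned, y), 5e-3)
})

test_that("Beta-capture closed forms agree with the mixture quadrature", {
  # telegraph under Beta(60,140)
  p <- telegraph_params(15, 3, 7)
  got <- observed_pmf_telegraph_beta(p, capture_beta(60, 140))
  orc <- beta_mixture_oracle(function(pc, nm)
    telegraph_pmf(telegraph_params(15 * pc, 3, 7), n_max = nm)$probs,
    60, 140, got$n_max)
  expect_lt(max(abs(got$probs - orc)), 1e-8)
  expect_lt(abs(1 - sum(got$probs)), 1e-10)

  # NB under Beta(15,35)
  nbp <- nb_params(4.7, 0.51)
  gn <- observed_pmf_nb_beta(nbp, capture_beta(15, 35))
  on <- beta_mixture_oracle(function(pc, nm) {
    q <- (1 - 0.51) / 0.51 * pc
    dnbinom(0:nm, size = 4.7, prob = 1 / (1 + q))
  }, 15, 35, gn$n_max)
  expect_lt(max(abs(gn$probs - on)), 1e-8)

  # Poisson under Beta(15,35)
  gp <- observed_pmf_poisson_beta(poisson_params(8), capture_beta(15, 35))
  op <- beta_mixture_oracle(function(pc, nm) dpois(0:nm, 8 * pc),
                            15, 35, gp$n_max)
  expect_lt(max(abs(gp$probs - op)), 1e-8)
  expect_lt(abs(pmf_mean(gp) - 8 * 15 / 50), 1e-9)

  # randomized sweep over parameters and Beta shapes
  pars <- rand_tele_params(8, seed = 13)
  set.seed(14)
  ab <- cbind(runif(8, 2, 80), runif(8, 5, 200))
  for (i in 1:8) {
    tp <- telegraph_params_from_fon(pars$rho[i], pars$fon[i], pars$nsigma[i])
    cb <- capture_beta(ab[i, 1], ab[i, 2])
    got <- observed_pmf_telegraph_beta(tp, cb, n_max = 25)
    orc <- beta_mixture_oracle(function(pc, nm)
      telegraph_pmf(telegraph_params(tp$rho * pc, tp$sigma_on,
                                     tp$sigma_off), n_max = nm)$probs,
      cb$a, cb$b, 25)
    expect_lt(max(abs(got$probs - orc)), 1e-8)
  }
})

test_that("degenerate and limiting capture models reduce correctly", {
  p <- telegraph_params(15, 3, 7)
  # near-degenerate Beta concentrates at alpha = 0.3
  cc <- 1e6
  nearly_point <- capture_beta(0.3 * cc, 0.7 * cc)
  got <- observed_pmf_telegraph_beta(p, nearly_point, n_max = 30)
  ref <- telegraph_pmf(telegraph_params(0.3 * 15, 3, 7), n_max = 30)
  expect_lt(max(abs(got$probs - ref$probs)), 1e-6)

  # NB point capture equals the PGF-substitution thinned NB
  nbp <- nb_params(3, 0.4)
  th <- thinned_nb_params(nbp, 0.3)
  gotn <- observed_pmf_nb_beta(nbp, nearly_point, n_max = 30)
  expect_lt(max(abs(gotn$probs - dnbinom(0:30, size = 3, prob = th$p))), 1e-6)

  # NB -> Poisson limit at fixed mean under the same Beta capture
  mean_fix <- 4
  r_big <- 1e6
  gnb <- observed_pmf_nb_beta(nb_params(r_big, r_big / (r_big + mean_fix)),
                              capture_beta(15, 35), n_max = 25)
  gpo <- observed_pmf_poisson_beta(poisson_params(mean_fix),
                                   capture_beta(15, 35), n_max = 25)
  expect_lt(max(abs(gnb$probs - gpo$probs)), 1e-6)

  # capture mean -> 1 recovers the plain Poisson
  gp1 <- observed_pmf_poisson_beta(poisson_params(4),
                                   capture_beta(1e6, 1), n_max = 25)
  expect_lt(max(abs(gp1$probs - dpois(0:25, 4))), 1e-4)
})

test_that("observed moments and Fano factor under capture variability", {
  p <- telegraph_params(15, 3, 7)
  cb <- capture_beta(60, 140)
  mo <- observed_moments_telegraph_beta(p, cb)
  expect_lt(abs(mo["fano"] - mo["variance"] / mo["mean"]), 1e-10)

  # CV = 0 (point capture) reduces to 1 + <pcap> rho soff / (Ns (1 + Ns))
  mo0 <- observed_moments_telegraph_beta(p, capture_point(0.3))
  expect_equal(unname(mo0["fano"]),
               1 + 0.3 * 15 * 7 / (10 * 11), tolerance = 1e-12)

  # Fano strictly increases with CV at fixed mean capture 0.3
  cvs <- vapply(list(capture_point(0.3), capture_beta(60, 140),
                     capture_beta(15, 35)), function(cm)
    unname(observed_moments_telegraph_beta(p, cm)["fano"]), numeric(1))
  expect_true(all(diff(cvs) > 0))

  # simulation oracle within 3 standard errors
  set.seed(77)
  pc <- rbeta(1e6, 60, 140)
  y <- rbinom(1e6, rpois(1e6, 15 * rbeta(1e6, 3, 7)), pc)
  expect_lt(abs(mean(y) - mo["mean"]), 3 * sqrt(mo["variance"] / 1e6))
  expect_lt(abs(var(y) - mo["variance"]), 0.02 * mo["variance"])

  expect_error(observed_moments_telegraph_beta(telegraph_params(0, 1, 1),
                                               cb))
})

test_that("quadrature marginalization matches closed forms and converges", {
  p <- telegraph_params(15, 3, 7)
  capd <- capture_density(function(x) dbeta(x, 60, 140), 0, 1)
  m64 <- marginal_pmf_over_density("telegraph", p, capd)
  closed <- observed_pmf_telegraph_beta(p, capture_beta(60, 140),
                                        n_max = m64$n_max)
  expect_lt(max(abs(m64$probs - closed$probs[1:(m64$n_max + 1)])), 1e-6)

  m128 <- marginal_pmf_over_density("telegraph", p, capd,
                                    quad = quadrature_spec(128L, c(0, 1)),
                                    n_max = m64$n_max)
  expect_lt(max(abs(m64$probs - m128$probs)), 1e-8)

  # narrow density behaves like a point mass
  lo <- 0.2999; hi <- 0.3001
  capn <- capture_density(function(x)
    ifelse(x >= lo & x <= hi, 1 / (hi - lo), 0), lo, hi)
  mn <- marginal_pmf_over_density("poisson", poisson_params(8), capn,
                                  n_max = 20)
  expect_lt(max(abs(mn$probs - dpois(0:20, 8 * 0.3))), 1e-5)

  # rho and the capture argument enter only through their product
  sc <- 2
  cap1 <- capture_density(function(x)
    ifelse(x >= 0.2 & x <= 0.4, 1 / 0.2, 0), 0.2, 0.4)
  cap2 <- capture_density(function(x)
    ifelse(x >= 0.1 & x <= 0.2, sc / 0.2, 0), 0.1, 0.2)
  a1 <- marginal_pmf_over_density("telegraph", telegraph_params(15, 3, 7),
                                  cap1, n_max = 20)
  a2 <- marginal_pmf_over_density("telegraph",
                                  telegraph_params(15 * sc, 3, 7),
                                  cap2, n_max = 20)
  expect_lt(max(abs(a1$probs - a2$probs)), 1e-10)
})
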