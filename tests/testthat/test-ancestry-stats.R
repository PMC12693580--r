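test_that("conditional allele frequencies tabulate carriers by ancestry", {
  # 4 haplotypes at one variant: calls (1,1,0,0), alleles (1,0,1,1)
  x <- hap_panel(matrix(c(1L, 1L), 2, 1), matrix(c(0L, 1L), 2, 1))
  la <- la_panel(matrix(c(1L, 0L), 2, 1), matrix(c(1L, 0L), 2, 1))
  fr <- conditional_allele_frequencies(x, la)
  expect_equal(fr$f_afr, 0.5)
  expect_equal(fr$f_eur, 1)

  # single-ancestry carriers: the missing side is NA
  x <- hap_panel(matrix(1L, 2, 1), matrix(1L, 2, 1))
  la <- la_panel(matrix(1L, 2, 1), matrix(1L, 2, 1))
  fr <- conditional_allele_frequencies(x, la)
  expect_equal(fr$f_afr, 1)
  expect_true(is.na(fr$f_eur))
})

test_that("the LD estimator matches its closed form and symmetries", {
  co <- test_cohort(n = 2000, p = 20)

  # perfect LD: a panel against itself
  expect_equal(estimate_ld(co$haps, co$haps, co$la, "afr"), rep(1, 20))

  # independently generated alleles: lambda ~ 0
  x2 <- sample_haplotypes(co$la, co$freqs, seed = 100)
  lam <- estimate_ld(co$haps, x2, co$la, "eur")
  expect_lt(max(abs(lam)), 0.12)
  expect_lt(abs(mean(lam)), 0.03)

  # hand-evaluated formula: P(1,1)=0.2, f=0.4, f'=0.3
  expect_equal((0.2 - 0.4 * 0.3) / sqrt(0.4 * 0.6 * 0.3 * 0.7),
               0.3563, tolerance = 1e-3)

  # symmetric in the two panels
  expect_equal(estimate_ld(co$haps, x2, co$la, "afr"),
               estimate_ld(x2, co$haps, co$la, "afr"))

  # invariant to swapping allele labels at both loci simultaneously
  flip <- function(p_) hap_panel(1L - p_$h1, 1L - p_$h2, role = p_$role)
  expect_equal(estimate_ld(flip(co$haps), flip(x2), co$la, "afr"),
               estimate_ld(co$haps, x2, co$la, "afr"))

  # monomorphic stratum is an error
  xm <- hap_panel(matrix(1L, 50, 1), matrix(1L, 50, 1))
  lam_ <- la_panel(matrix(1L, 50, 1), matrix(0L, 50, 1))
  expect_error(estimate_ld(xm, xm, lam_, "afr"), "monomorphic")
})

test_that("conditional average effects reduce correctly under each model", {
  set.seed(11)
  g <- sample_global_ancestry(60, seed = 12)
  la <- sample_local_ancestry(g, p = 10, seed = 13)
  eff <- list(beta_eur = rnorm(10), beta_afr = rnorm(10))

  # local model: exactly the ancestry-specific effects
  avg <- conditional_average_effects(individual_effects("local", eff, la), la)
  expect_equal(avg$avg_afr, eff$beta_afr)
  expect_equal(avg$avg_eur, eff$beta_eur)

  # global model with shared abar = m: both averages collapse to the blend
  la_m <- uniform_ancestry_cohort(30, 10, ancestry = 1L, abar = rep(0.6, 30))
  la_m$h1[, 1:5] <- 0L  # mix calls so both ancestries have carriers
  avg <- conditional_average_effects(individual_effects("global", eff, la_m),
                                     la_m)
  blend <- 0.4 * eff$beta_eur + 0.6 * eff$beta_afr
  expect_equal(avg$avg_afr[1:5], blend[1:5])
  expect_equal(avg$avg_eur[1:5], blend[1:5])

  # naive double-loop oracle on a small cohort, global model
  fld <- individual_effects("global", eff, la)
  j <- 3
  num_a <- 0; den_a <- 0; num_e <- 0; den_e <- 0
  for (i in 1:60) for (h in 1:2) {
    a <- if (h == 1) la$h1[i, j] else la$h2[i, j]
    b <- if (h == 1) fld$h1[i, j] else fld$h2[i, j]
    if (a == 1) { num_a <- num_a + b; den_a <- den_a + 1 }
    else { num_e <- num_e + b; den_e <- den_e + 1 }
  }
  avg <- conditional_average_effects(fld, la)
  expect_equal(avg$avg_afr[j], num_a / den_a)
  expect_equal(avg$avg_eur[j], num_e / den_e)
})

test_that("omega weights are carrier averages of global ancestry", {
  set.seed(14)
  # constant abar = m
  la_m <- uniform_ancestry_cohort(20, 6, ancestry = 1L, abar = rep(0.7, 20))
  la_m$h1[, ] <- rbinom(120, 1, 0.5)
  om <- omega_weights(la_m)
  expect_equal(om$w2, rep(0.7, 6))
  expect_equal(om$w1, rep(0.3, 6))
  expect_equal(om$w4, rep(0.7, 6))

  co <- test_cohort(n = 500, p = 40)
  om <- omega_weights(co$la)
  expect_equal(om$w1 + om$w2, rep(1, 40))
  expect_equal(om$w3 + om$w4, rep(1, 40))
  expect_true(all(om$w1 >= 0 & om$w1 <= 1))

  # identity: omega blend reproduces the global-model carrier averages
  eff <- list(beta_eur = rnorm(40), beta_afr = rnorm(40))
  avg <- conditional_average_effects(individual_effects("global", eff, co$la),
                                     co$la)
  expect_equal(avg$avg_afr, eff$beta_eur * om$w1 + eff$beta_afr * om$w2)
  expect_equal(avg$avg_eur, eff$beta_eur * om$w3 + eff$beta_afr * om$w4)
})

test_that("closed-form average-effect covariance matches Monte Carlo", {
  g <- sample_global_ancestry(400, seed = 21)
  la <- sample_local_ancestry(g, 30, seed = 22)
  fr <- sample_ancestral_frequencies(30, seed = 23)
  cov <- base_covariance(fr, 0.4, 0.5)
  pr <- prop1_covariance(omega_weights(la), cov)

  R <- 1e4
  aa <- matrix(NA_real_, R, 30); ae <- matrix(NA_real_, R, 30)
  set.seed(99)
  for (k in seq_len(R)) {
    eff <- draw_ancestral_effects(cov, 30)
    avg <- conditional_average_effects(individual_effects("global", eff, la),
                                       la)
    aa[k, ] <- avg$avg_afr; ae[k, ] <- avg$avg_eur
  }
  rel <- function(est, truth) mean(abs(est - truth) / abs(truth))
  expect_lt(rel(apply(aa, 2, var), pr$u), 0.03)
  expect_lt(rel(apply(ae, 2, var), pr$v), 0.03)
  expect_lt(rel(vapply(1:30, function(j) cov(aa[, j], ae[, j]), 0), pr$w),
            0.03)
})

test_that("per-variant correlation hits 1 in the degenerate extremes", {
  set.seed(15)
  eff_cov <- base_covariance(ancestry_freqs(rep(0.5, 5), rep(0.5, 5)),
                             0.4, 0.3)
  # shared global ancestry: u = v = w
  la_m <- uniform_ancestry_cohort(50, 5, ancestry = 1L, abar = rep(0.8, 50))
  la_m$h1[, ] <- rbinom(250, 1, 0.5)
  pr <- prop1_covariance(omega_weights(la_m), eff_cov)
  expect_equal(pr$laacor, rep(1, 5))
  expect_equal(pr$u, pr$v)
  expect_equal(pr$u, pr$w)

  # rho = 1 with equal variances
  co <- test_cohort(n = 300, p = 5)
  fr_sym <- ancestry_freqs(co$freqs$f_afr, co$freqs$f_afr)
  pr <- prop1_covariance(omega_weights(co$la),
                         base_covariance(fr_sym, 0.4, 1))
  expect_equal(pr$laacor, rep(1, 5))
})

test_that("genome-wide pooled correlation behaves as designed", {
  set.seed(16)
  # identical omegas and rho = 1 pool to exactly 1
  fr_sym <- ancestry_freqs(rep(0.4, 10), rep(0.4, 10))
  la_m <- uniform_ancestry_cohort(40, 10, ancestry = 1L, abar = rep(0.75, 40))
  la_m$h1[, ] <- rbinom(400, 1, 0.5)
  pr <- prop1_covariance(omega_weights(la_m), base_covariance(fr_sym, 0.4, 1))
  expect_equal(genome_wide_laacor(pr), 1)

  # local model: empirical pooled value recovers rho
  co <- test_cohort(n = 1000, p = 2000)
  cov <- base_covariance(co$freqs, 0.4, 0.6)
  emp <- empirical_laacor(co$la, cov, "local", n_redraws = 10, seed = 31)
  expect_lt(abs(emp$mean - 0.6), 0.02)

  # empirical matches the closed-form pooled parameter, global model
  cov <- base_covariance(co$freqs, 0.4, 0.5)
  rep_ <- laacor_report(co$la, cov, "global", n_redraws = 15, seed = 32)
  emp <- empirical_laacor(co$la, cov, "global", n_redraws = 15, seed = 32)
  expect_lt(abs(emp$mean - rep_$pooled_closed), 3 * max(emp$se, 1e-5) + 2e-4)

  expect_error(genome_wide_laacor(data.frame(u = 1, v = 1, w = 1)),
               "at least 2")
})

test_that("averaging over local ancestry can only raise similarity", {
  # per-variant global-model correlation >= rho across cohorts and rho grid
  for (seed in 1:3) {
    co <- test_cohort(n = 400, p = 50, seed = seed)
    for (rho in c(0, 0.2, 0.5, 0.9)) {
      pr <- prop1_covariance(omega_weights(co$la),
                             base_covariance(co$freqs, 0.4, rho))
      expect_true(all(pr$laacor >= rho - 1e-9))
    }
  }
})

test_that("tagging-scope correlation is depressed by discordant LD", {
  # local model: average tagging effects are theta-scaled ancestral effects;
  # their correlation equals rho when theta_eur = theta_afr and drops when
  # LD differs between ancestries
  p <- 5000
  cf <- ancestry_freqs(rep(0.4, p), rep(0.4, p))
  tf <- ancestry_freqs(rep(0.4, p), rep(0.4, p), role = "tagging")
  cov <- base_covariance(cf, 0.4, 0.7)
  eff <- draw_ancestral_effects(cov, p, seed = 41)

  same <- tagging_effects(eff, data.frame(lambda_afr = 0.9, lambda_eur = 0.9),
                          cf, tf)
  expect_lt(abs(cor(same$tag_beta_eur, same$tag_beta_afr) - 0.7), 0.03)

  # ancestry-discordant lambda with variant-to-variant spread
  set.seed(42)
  lam_a <- runif(p, 0.3, 1)
  disc <- tagging_effects(eff, data.frame(lambda_afr = lam_a,
                                          lambda_eur = 0.9), cf, tf)
  expect_lt(cor(disc$tag_beta_eur, disc$tag_beta_afr),
            cor(same$tag_beta_eur, same$tag_beta_afr) - 0.02)
})
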