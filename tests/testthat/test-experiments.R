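test_that("the fast per-draw core agrees with the public score pipeline", {
  co <- test_cohort(n = 300, p = 80)
  pre <- admixpgs:::cohort_precompute(co)
  pre$tot_pgs <- pre$tot
  pre$par_pgs <- pre$par
  cov <- base_covariance(co$freqs, 0.4, 0.5)
  eff <- draw_ancestral_effects(cov, 80, seed = 1)

  for (model in c("global", "local")) {
    set.seed(7)
    d <- admixpgs:::draw_scores_r2(pre, eff, model, groups = co$subgroups)

    fld <- individual_effects(model, eff, co$la)
    dm <- demean_haplotypes(co$haps, co$la)
    set.seed(7)
    ph <- simulate_phenotype(fld, dm)
    tot <- total_pgs(co$haps, co$la, eff$beta_eur)
    par <- partial_pgs(co$haps, co$la, eff$beta_eur)
    expect_equal(d$tot[["overall"]], cor(tot, ph$y)^2, tolerance = 1e-10)
    expect_equal(d$par[["overall"]], cor(par, ph$y)^2, tolerance = 1e-10)
    r2g <- pgs_phenotype_r2(tot, ph, co$subgroups)
    expect_equal(unname(d$tot[-1]), r2g$r2[-1], tolerance = 1e-10)
  }
})

test_that("study 1 is reproducible and hits the rho = 1 endpoint", {
  cfg <- experiment_config(n = 600, p = 200, n_seeds = 2, n_draws = 25,
                           rho_grid = 1, r2_grid = 0.4, master_seed = 3)
  res <- run_sim_study1(cfg)
  expect_identical(res, run_sim_study1(cfg))

  # rho = 1: TotPGS r2 ~ r2 in every subgroup under both models
  tot <- res[res$score_type == "tot", ]
  expect_true(all(abs(tot$mean_r2 - 0.4) < 0.05))
  expect_true(all(tot$ci_lo <= tot$ci_hi))
  expect_true(all(tot$n_draws == 25))
})

test_that("study 1 separates models through the partial score only", {
  cfg <- experiment_config(n = 1000, p = 300, n_seeds = 1, n_draws = 40,
                           rho_grid = 0.2, r2_grid = 0.4, master_seed = 4)
  res <- run_sim_study1(cfg)
  ov <- res[res$subgroup == "overall", ]
  pick <- function(st, m) ov[ov$score_type == st & ov$model == m, ]
  z <- function(a, b) (a$mean_r2 - b$mean_r2) / sqrt(a$se^2 + b$se^2)
  expect_lt(abs(z(pick("tot", "global"), pick("tot", "local"))), 3)
  expect_lt(z(pick("par", "global"), pick("par", "local")), -3)

  # cohort mean African ancestry ~0.79 and rho = 0.2 sits below the
  # advantage threshold 0.31: under the local model the partial score is
  # the better predictor
  loc <- ov[ov$model == "local", ]
  expect_gt(loc$mean_r2[loc$score_type == "par"],
            loc$mean_r2[loc$score_type == "tot"])
})

test_that("theory comparison flags no systematic departures at rho = 1", {
  cfg <- experiment_config(n = 800, p = 200, n_seeds = 1, n_draws = 30,
                           rho_grid = 1, r2_grid = c(0.1, 0.4),
                           master_seed = 5)
  res <- run_sim_study1(cfg)
  co <- simulate_cohort(cfg$n, cfg$p, seed = derive_seed(5, "cohort", 1L))
  ab <- c(overall = mean(co$global),
          stats::setNames(co$subgroups$group_means, 1:4))
  cmp <- compare_to_theory(res, ab)
  expect_true(all(c("predicted", "residual", "z") %in% names(cmp)))
  # TotPGS at rho = 1 predicts r2 exactly; residuals are Monte Carlo noise
  tot <- cmp[cmp$score_type == "tot" & cmp$subgroup == "overall", ]
  expect_true(all(abs(tot$z) < 3))
  expect_error(compare_to_theory(res, c(overall = 0.8)), "missing subgroup")
})

test_that("tagging study shrinks predictive power relative to causal study", {
  cfg1 <- experiment_config(n = 800, p = 200, n_seeds = 1, n_draws = 30,
                            rho_grid = c(0.5, 1), r2_grid = 0.4,
                            master_seed = 6)
  res1 <- run_sim_study1(cfg1)
  cfg2 <- experiment_config(n = 800, p = 200, n_seeds = 1, n_draws = 30,
                            rho_grid = c(0.5, 1), r2_grid = 0.4,
                            scenario = "tagging", master_seed = 6)
  res2 <- run_sim_study2(cfg2, n_eur = 2000)
  expect_identical(res2, run_sim_study2(cfg2, n_eur = 2000))

  ov1 <- res1[res1$subgroup == "overall", ]
  ov2 <- res2[res2$subgroup == "overall", ]
  for (st in c("tot", "par")) for (m in c("global", "local")) {
    for (rho in c(0.5, 1)) {
      a <- ov1[ov1$score_type == st & ov1$model == m & ov1$rho == rho, ]
      b <- ov2[ov2$score_type == st & ov2$model == m & ov2$rho == rho, ]
      expect_lt(b$mean_r2, a$mean_r2 + 3 * sqrt(a$se^2 + b$se^2))
    }
  }
  # global model: partial never beats total, and the shrinkage stays above
  # the causal-known floor 1 - abar
  co <- simulate_cohort(800, 200, seed = derive_seed(6, "cohort", 1L))
  floor_ <- 1 - mean(co$global)
  for (rho in c(0.5, 1)) {
    p_ <- ov2[ov2$model == "global" & ov2$rho == rho, ]
    ratio <- p_$mean_r2[p_$score_type == "par"] /
      p_$mean_r2[p_$score_type == "tot"]
    expect_lt(ratio, 1)
    expect_gt(ratio, floor_ - 0.1)
  }
})

test_that("perfect matched LD collapses the tagging study onto causal", {
  p <- 150
  cf <- sample_ancestral_frequencies(p, seed = 61)
  prof <- list(causal_freqs = cf,
               tagging_freqs = ancestry_freqs(cf$f_afr, cf$f_eur,
                                              role = "tagging"),
               lambda_afr = rep(1, p), lambda_eur = rep(1, p))
  cfg <- experiment_config(n = 600, p = p, n_seeds = 1, n_draws = 30,
                           rho_grid = 0.5, r2_grid = 0.4,
                           scenario = "tagging", master_seed = 7)
  res <- run_sim_study2(cfg, ld_profile = prof, use_truth = TRUE)
  ov <- res[res$subgroup == "overall" & res$score_type == "tot" &
              res$model == "global", ]
  pred <- expected_r2_totpgs(0.4, 0.5, 0.79)
  expect_lt(abs(ov$mean_r2 - pred), 0.04)
})

test_that("Monte Carlo standard errors shrink like 1/sqrt(draws)", {
  base <- experiment_config(n = 500, p = 100, n_seeds = 1, n_draws = 20,
                            rho_grid = 0.5, r2_grid = 0.4, master_seed = 8)
  big <- experiment_config(n = 500, p = 100, n_seeds = 1, n_draws = 80,
                           rho_grid = 0.5, r2_grid = 0.4, master_seed = 8)
  se1 <- run_sim_study1(base); se4 <- run_sim_study1(big)
  m1 <- mean(se1$se[se1$subgroup == "overall"])
  m4 <- mean(se4$se[se4$subgroup == "overall"])
  expect_equal(m1 / m4, 2, tolerance = 0.8)
})

test_that("the distinguishability grid has power where models differ", {
  cfg <- experiment_config(n = 500, p = 150, n_draws = 40,
                           rho_grid = 0.2, r2_grid = 0.4, master_seed = 9)
  g <- distinguishability_grid(cfg, n_reps = 5)
  par_row <- g[g$score_type == "par", ]
  expect_equal(par_row$prop_significant, 1)
  expect_identical(g, distinguishability_grid(cfg, n_reps = 5))
})

test_that("feasible LD profiles respect the Frechet bounds", {
  cf <- sample_ancestral_frequencies(500, seed = 71)
  prof <- feasible_lambda_profile(cf, seed = 72)
  expect_true(all(prof$lambda_eur <= 1 & prof$lambda_eur >= 0))
  # every pair admits a valid joint distribution
  expect_silent(admixpgs:::bernoulli_p11(cf$f_eur, prof$tagging_freqs$f_eur,
                                         prof$lambda_eur))
  expect_silent(admixpgs:::bernoulli_p11(cf$f_afr, prof$tagging_freqs$f_afr,
                                         prof$lambda_afr))
})
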