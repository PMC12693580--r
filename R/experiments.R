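## Monte Carlo experiment drivers: simulation studies on synthetic admixed
## cohorts, comparison of simulated polygenic-score accuracy to the closed
## forms, and the Wilcoxon rank-sum model-distinguishability grid.

#' Experiment configuration
#'
#' Scaled-down default sizes (n = 2,000 individuals, p = 1,000 variants,
#' 5 cohort replicates, 100 effect/phenotype redraws per cohort) chosen so a
#' full study runs on a desktop in minutes; all sizes are configurable.
#'
#' @param n,p Cohort size and variant count.
#' @param n_seeds Number of cohort replicates.
#' @param n_draws Effect/phenotype redraws per cohort and parameter setting.
#' @param rho_grid,r2_grid Parameter grids.
#' @param scenario "causal_known" or "tagging".
#' @param alpha Significance level for the distinguishability test.
#' @param master_seed Integer master seed; all substreams derive from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n = 2000, p = 1000, n_seeds = 5, n_draws = 100,
                              rho_grid = c(0.2, 0.5, 0.9, 1),
                              r2_grid = c(0.1, 0.4),
                              scenario = c("causal_known", "tagging"),
                              alpha = 0.01, master_seed = 1L) {
  scenario <- match.arg(scenario)
  if (!length(rho_grid) || !length(r2_grid)) stop_param("parameter grids must be non-empty")
  if (alpha <= 0 || alpha >= 1) stop_param("alpha must lie in (0, 1)")
  structure(list(n = n, p = p, n_seeds = n_seeds, n_draws = n_draws,
                 rho_grid = rho_grid, r2_grid = r2_grid,
                 scenario = scenario, alpha = alpha,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

## Cohort precomputations shared across effect redraws. The design matrices
## reproduce total_pgs / partial_pgs and the model genetic components
## exactly (asserted in the test suite), but turn each redraw into two
## matrix-vector products.
cohort_precompute <- function(cohort, freq_source = "sample_conditional") {
  la <- cohort$la
  xhat <- demean_haplotypes(cohort$haps, la, cohort$freqs, freq_source)
  list(la = la,
       abar = la$global,
       tot = xhat$h1 + xhat$h2,
       par = xhat$h1 * (1 - la$h1) + xhat$h2 * (1 - la$h2),
       afr = xhat$h1 * la$h1 + xhat$h2 * la$h2,
       subgroups = cohort$subgroups)
}

## One effect + phenotype redraw: returns per-score, per-group r2.
## `beta_pgs` are the European weights used in both scores (causal effects
## in the causal_known scenario, tagging effects otherwise).
draw_scores_r2 <- function(pre, eff, model, beta_pgs = NULL, groups = NULL) {
  if (is.null(beta_pgs)) beta_pgs <- eff$beta_eur
  if (model == "global") {
    g <- (1 - pre$abar) * drop(pre$tot %*% eff$beta_eur) +
      pre$abar * drop(pre$tot %*% eff$beta_afr)
  } else {
    g <- drop(pre$par %*% eff$beta_eur) + drop(pre$afr %*% eff$beta_afr)
  }
  nv <- max(0, 1 - stats::var(g))
  y <- g + stats::rnorm(length(g), 0, sqrt(nv))
  tot <- drop(pre$tot_pgs %*% beta_pgs)
  par <- drop(pre$par_pgs %*% beta_pgs)
  r2g <- function(s) {
    out <- c(overall = stats::cor(s, y)^2)
    if (!is.null(groups)) {
      for (g_ in sort(unique(groups$labels))) {
        idx <- groups$labels == g_
        out[as.character(g_)] <- stats::cor(s[idx], y[idx])^2
      }
    }
    out
  }
  list(tot = r2g(tot), par = r2g(par))
}

summarize_draws <- function(mat) {
  ## mat: n_draws x groups
  m <- colMeans(mat)
  se <- apply(mat, 2, stats::sd) / sqrt(nrow(mat))
  data.frame(subgroup = colnames(mat), mean_r2 = m, se = se,
             ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se,
             n_draws = nrow(mat), row.names = NULL)
}

#' Simulation study: causal variants known
#'
#' For each cohort replicate, model and (rho, r2) pair: draw ancestry-specific
#' causal effects, simulate the phenotype, compute total and partial
#' polygenic scores on the causal variants with the European effects, and
#' record mean squared score-phenotype correlations with Monte Carlo
#' standard errors, overall and by global-ancestry quartile subgroup.
#'
#' @param cfg An [experiment_config()] with `scenario = "causal_known"`.
#' @return data.frame keyed by (seed, model, rho, r2, score_type, subgroup)
#'   with `mean_r2`, `se`, `ci_lo`, `ci_hi`, `n_draws`.
#' @export
run_sim_study1 <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (cfg$scenario != "causal_known") stop_param("study 1 requires scenario = causal_known")
  rows <- list()
  for (s in seq_len(cfg$n_seeds)) {
    cohort <- simulate_cohort(cfg$n, cfg$p,
                              seed = derive_seed(cfg$master_seed, "cohort", s))
    pre <- cohort_precompute(cohort)
    pre$tot_pgs <- pre$tot
    pre$par_pgs <- pre$par
    groups <- cohort$subgroups
    for (rho in cfg$rho_grid) for (r2 in cfg$r2_grid) {
      cov <- base_covariance(cohort$freqs, r2, rho)
      for (model in c("global", "local")) {
        dseed <- derive_seed(cfg$master_seed,
                             paste("draws", model, rho, r2), s)
        draws <- with_seed(dseed, {
          lapply(seq_len(cfg$n_draws), function(k) {
            eff <- draw_ancestral_effects(cov, cfg$p)
            draw_scores_r2(pre, eff, model, groups = groups)
          })
        })
        for (st in c("tot", "par")) {
          mat <- do.call(rbind, lapply(draws, `[[`, st))
          sm <- summarize_draws(mat)
          sm <- cbind(data.frame(seed = s, scenario = "causal_known",
                                 model = model, rho = rho, r2 = r2,
                                 score_type = st), sm)
          rows[[length(rows) + 1L]] <- sm
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Draw a feasible ancestry-specific LD profile
#'
#' Tagging frequencies for tightly linked pairs are generated by jittering
#' the causal frequencies; target lambdas are drawn uniformly from the given
#' ranges and clipped to the largest value admitting a valid joint Bernoulli
#' distribution (clipping count is returned, not hidden).
#'
#' @param causal_freqs Causal [ancestry_freqs].
#' @param lambda_eur_range,lambda_afr_range Ranges of target haplotypic
#'   correlations (defaults: European lambda^2 >= 0.81; African lambda
#'   discordant, spread over 0.5-1).
#' @param jitter_sd SD of the frequency jitter.
#' @param seed Optional integer seed.
#' @return List with `tagging_freqs`, `lambda_afr`, `lambda_eur`,
#'   `n_clipped`.
#' @export
feasible_lambda_profile <- function(causal_freqs,
                                    lambda_eur_range = c(0.9, 0.99),
                                    lambda_afr_range = c(0.5, 1),
                                    jitter_sd = 0.02, seed = NULL) {
  p <- length(causal_freqs$f_afr)
  with_seed(seed, {
    clip <- function(x) pmin(pmax(x, 0.01), 0.99)
    tf <- ancestry_freqs(clip(causal_freqs$f_afr + stats::rnorm(p, 0, jitter_sd)),
                         clip(causal_freqs$f_eur + stats::rnorm(p, 0, jitter_sd)),
                         role = "tagging")
    lmax <- function(f, fp) {
      (pmin(f, fp) - f * fp) / sqrt(f * (1 - f) * fp * (1 - fp))
    }
    le <- stats::runif(p, lambda_eur_range[1], lambda_eur_range[2])
    la_ <- stats::runif(p, lambda_afr_range[1], lambda_afr_range[2])
    me <- lmax(causal_freqs$f_eur, tf$f_eur)
    ma <- lmax(causal_freqs$f_afr, tf$f_afr)
    n_clipped <- sum(le > me) + sum(la_ > ma)
    list(tagging_freqs = tf,
         lambda_afr = pmin(la_, ma), lambda_eur = pmin(le, me),
         n_clipped = n_clipped)
  })
}

#' Simulation study: tagging variants only
#'
#' Phenotypes are simulated from causal variants under each model, while
#' both polygenic scores are computed on linked tagging variants with
#' European tagging effects (causal effect scaled by the European LD and
#' frequency ratio). By default the European frequencies and LD are
#' re-estimated from a separately simulated ancestrally homogeneous
#' European panel, mirroring how score weights come from an external
#' European cohort; `use_truth = TRUE` plugs in the generating values.
#'
#' @param cfg An [experiment_config()] with `scenario = "tagging"`.
#' @param ld_profile Optional profile from [feasible_lambda_profile()];
#'   generated per cohort replicate when `NULL`. May carry a
#'   `causal_freqs` element to pin the causal frequencies the profile was
#'   built against.
#' @param n_eur Size of the simulated European reference panel.
#' @param use_truth Use generating frequencies/lambdas for the tagging
#'   effect scaling instead of the European-panel estimates.
#' @return data.frame in the same layout as [run_sim_study1()].
#' @export
run_sim_study2 <- function(cfg, ld_profile = NULL, n_eur = 5000,
                           use_truth = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (cfg$scenario != "tagging") stop_param("study 2 requires scenario = tagging")
  rows <- list()
  for (s in seq_len(cfg$n_seeds)) {
    cseed <- derive_seed(cfg$master_seed, "cohort", s)
    global <- sample_global_ancestry(cfg$n, seed = derive_seed(cseed, "abar"))
    la <- sample_local_ancestry(global, cfg$p, seed = derive_seed(cseed, "la"))
    causal_freqs <- if (!is.null(ld_profile$causal_freqs)) {
      ld_profile$causal_freqs
    } else {
      sample_ancestral_frequencies(cfg$p, role = "causal",
                                   seed = derive_seed(cseed, "freq"))
    }
    prof <- if (is.null(ld_profile)) {
      feasible_lambda_profile(causal_freqs, seed = derive_seed(cseed, "ld"))
    } else {
      ld_profile
    }
    linked <- sample_linked_pairs(causal_freqs, prof$tagging_freqs,
                                  prof$lambda_afr, prof$lambda_eur, la,
                                  seed = derive_seed(cseed, "hap"))
    groups <- split_subgroups(global)

    ## scaling of European tagging effects: generating truth or estimates
    ## from a simulated homogeneous European panel
    if (use_truth) {
      cf_eur <- causal_freqs$f_eur
      tf_eur <- prof$tagging_freqs$f_eur
      lam_eur <- prof$lambda_eur
    } else {
      la_eur <- la_panel(matrix(0L, n_eur, cfg$p), matrix(0L, n_eur, cfg$p),
                         global = rep(0, n_eur))
      eur <- sample_linked_pairs(causal_freqs, prof$tagging_freqs,
                                 prof$lambda_afr, prof$lambda_eur, la_eur,
                                 seed = derive_seed(cseed, "eurpanel"))
      cf_hat <- conditional_allele_frequencies(eur$causal, la_eur)
      tf_hat <- conditional_allele_frequencies(eur$tagging, la_eur)
      cf_eur <- pmin(pmax(cf_hat$f_eur, 0.005), 0.995)
      tf_eur <- pmin(pmax(tf_hat$f_eur, 0.005), 0.995)
      lam_eur <- estimate_ld(eur$causal, eur$tagging, la_eur, "eur")
    }
    theta_eur <- lam_eur * sqrt(cf_eur * (1 - cf_eur) / (tf_eur * (1 - tf_eur)))

    cohort <- list(la = la, haps = linked$causal, freqs = causal_freqs,
                   subgroups = groups)
    pre <- cohort_precompute(cohort)
    xhat_tag <- demean_haplotypes(linked$tagging, la)
    pre$tot_pgs <- xhat_tag$h1 + xhat_tag$h2
    pre$par_pgs <- xhat_tag$h1 * (1 - la$h1) + xhat_tag$h2 * (1 - la$h2)

    for (rho in cfg$rho_grid) for (r2 in cfg$r2_grid) {
      cov <- base_covariance(causal_freqs, r2, rho)
      for (model in c("global", "local")) {
        dseed <- derive_seed(cfg$master_seed,
                             paste("draws2", model, rho, r2), s)
        draws <- with_seed(dseed, {
          lapply(seq_len(cfg$n_draws), function(k) {
            eff <- draw_ancestral_effects(cov, cfg$p)
            draw_scores_r2(pre, eff, model,
                           beta_pgs = eff$beta_eur * theta_eur,
                           groups = groups)
          })
        })
        for (st in c("tot", "par")) {
          mat <- do.call(rbind, lapply(draws, `[[`, st))
          sm <- summarize_draws(mat)
          sm <- cbind(data.frame(seed = s, scenario = "tagging",
                                 model = model, rho = rho, r2 = r2,
                                 score_type = st), sm)
          rows[[length(rows) + 1L]] <- sm
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Wilcoxon model-distinguishability grid
#'
#' For each (rho, r2) cell: simulate `n_draws` per-draw score-phenotype
#' squared correlations under the local model and under the global model,
#' compare the two sets with a two-sided Wilcoxon rank-sum test (separately
#' for the total and partial score), and record significance at `alpha`.
#' Repeating this `n_reps` times gives the proportion of comparisons deemed
#' significant per cell. With `null = TRUE` both arms are simulated under
#' the same model, giving the test's null calibration (expected rejection
#' proportion `alpha`).
#'
#' @param cfg An [experiment_config()].
#' @param n_reps Number of repeated comparisons per cell.
#' @param null Calibrate under the null (both arms from the same model)?
#' @param null_model Model used for both arms when `null = TRUE`.
#' @return data.frame with columns `rho`, `r2`, `score_type`,
#'   `prop_significant`, `n_reps`.
#' @export
distinguishability_grid <- function(cfg, n_reps = 10, null = FALSE,
                                    null_model = "global") {
  stopifnot(inherits(cfg, "experiment_config"))
  if (cfg$n_draws < 20) stop_param("need at least 20 draws per arm")
  cohort <- simulate_cohort(cfg$n, cfg$p,
                            seed = derive_seed(cfg$master_seed, "cohort", 1L))
  pre <- cohort_precompute(cohort)
  pre$tot_pgs <- pre$tot
  pre$par_pgs <- pre$par
  rows <- list()
  for (rho in cfg$rho_grid) for (r2 in cfg$r2_grid) {
    cov <- base_covariance(cohort$freqs, r2, rho)
    models <- if (null) c(null_model, null_model) else c("local", "global")
    sig <- matrix(NA, n_reps, 2, dimnames = list(NULL, c("tot", "par")))
    gseed <- derive_seed(cfg$master_seed, paste("grid", rho, r2))
    with_seed(gseed, {
      for (rep_ in seq_len(n_reps)) {
        arm <- lapply(models, function(m) {
          vals <- vapply(seq_len(cfg$n_draws), function(k) {
            eff <- draw_ancestral_effects(cov, cfg$p)
            d <- draw_scores_r2(pre, eff, m)
            c(d$tot[["overall"]], d$par[["overall"]])
          }, numeric(2))
          list(tot = vals[1, ], par = vals[2, ])
        })
        for (st in c("tot", "par")) {
          a <- arm[[1]][[st]]; b <- arm[[2]][[st]]
          if (length(unique(c(a, b))) == 1L) next  # all tied: skipped
          pv <- stats::wilcox.test(a, b, exact = FALSE)$p.value
          sig[rep_, st] <- pv < cfg$alpha
        }
      }
    })
    for (st in c("tot", "par")) {
      rows[[length(rows) + 1L]] <-
        data.frame(rho = rho, r2 = r2, score_type = st,
                   prop_significant = mean(sig[, st], na.rm = TRUE),
                   n_reps = sum(!is.na(sig[, st])))
    }
  }
  do.call(rbind, rows)
}

#' Compare simulated means to the closed-form predictions
#'
#' Joins a [run_sim_study1()]-style table with the closed forms evaluated at
#' each subgroup's mean African global ancestry and reports residuals with
#' z-scores against the Monte Carlo standard error.
#'
#' @param results data.frame from [run_sim_study1()] (overall and subgroup
#'   rows).
#' @param abar_by_group Named numeric vector mapping subgroup labels
#'   (including "overall") to mean African global ancestry.
#' @return The results table with added `predicted`, `residual`, `z`.
#' @export
compare_to_theory <- function(results, abar_by_group) {
  need <- c("model", "rho", "r2", "score_type", "subgroup", "mean_r2", "se")
  if (!all(need %in% names(results))) stop_param("results table is missing required columns")
  if (!all(results$subgroup %in% names(abar_by_group))) {
    stop_param("abar_by_group is missing subgroup keys")
  }
  ab <- abar_by_group[results$subgroup]
  pred <- ifelse(results$score_type == "tot",
                 expected_r2_totpgs(results$r2, results$rho, ab),
          ifelse(results$model == "global",
                 expected_r2_parpgs_global(results$r2, results$rho, ab),
                 expected_r2_parpgs_local(results$r2, results$rho, ab)))
  results$predicted <- as.numeric(pred)
  results$residual <- results$mean_r2 - results$predicted
  results$z <- results$residual / results$se
  results
}
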