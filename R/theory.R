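## Closed-form predictions for expected PGS-phenotype squared correlations
## when causal variants are known, as functions of r2, rho and the cohort
## mean African global ancestry abar. The approximations assume: (A) allele
## frequencies identical across markers within an ancestry, (B) a shared
## local-ancestry distribution across individuals, (C) concordant ancestry
## between an individual's two haplotypes, (D) small ancestry frequency
## gaps, and (E) approximately independent alleles across haplotypes. They
## hold qualitatively well beyond these conditions.

check_theory_inputs <- function(r2, rho, abar) {
  check_prob(r2, "r2")
  if (any(abs(rho) > 1)) stop_param("rho must lie in [-1, 1]")
  check_prob(abar, "abar")
  invisible(TRUE)
}

#' Expected squared correlation of the total PGS with the phenotype
#'
#' `r2 * (1 - abar + rho * abar)^2`, the same under the local and global
#' models — the total score cannot distinguish them.
#'
#' @param r2 Variance explained by genetic effects.
#' @param rho Cross-ancestry causal-effect correlation.
#' @param abar Mean African global ancestry of the cohort.
#' @return Expected squared correlation.
#' @export
expected_r2_totpgs <- function(r2, rho, abar) {
  check_theory_inputs(r2, rho, abar)
  r2 * (1 - abar + rho * abar)^2
}

#' Expected squared correlation of the partial PGS, global model
#'
#' `r2 * (1 - abar) * (1 - abar + rho * abar)^2`: the total-score value
#' shrunk by the global European ancestry `1 - abar`, independent of r2 and
#' rho.
#'
#' @inheritParams expected_r2_totpgs
#' @return Expected squared correlation.
#' @export
expected_r2_parpgs_global <- function(r2, rho, abar) {
  check_theory_inputs(r2, rho, abar)
  r2 * (1 - abar) * (1 - abar + rho * abar)^2
}

#' Expected squared correlation of the partial PGS, local model
#'
#' `r2 * (1 - abar)`, independent of rho.
#'
#' @inheritParams expected_r2_totpgs
#' @return Expected squared correlation.
#' @export
expected_r2_parpgs_local <- function(r2, rho, abar) {
  check_theory_inputs(r2, rho, abar)
  r2 * (1 - abar)
}

#' Threshold on rho below which the partial PGS beats the total PGS
#'
#' Under the local model the partial score is more predictive than the
#' total score exactly when `1 - abar >= (rho / (1 - rho))^2`; solving the
#' boundary gives the supremum
#' `rho* = sqrt(1 - abar) / (1 + sqrt(1 - abar))`. At `abar = 0.8` this is
#' 0.31 to two decimals; it approaches 0.5 as `abar -> 0` and 0 as
#' `abar -> 1`.
#'
#' @param abar Mean African global ancestry, strictly in (0, 1).
#' @return The threshold correlation rho*.
#' @export
parpgs_advantage_threshold <- function(abar) {
  if (any(abar <= 0 | abar >= 1)) stop_param("abar must lie strictly in (0, 1)")
  s <- sqrt(1 - abar)
  s / (1 + s)
}

#' Predictive power of the partial PGS relative to the total PGS
#'
#' Local model: `(1 - abar) / (1 - abar + rho * abar)^2`, strictly
#' decreasing in rho and exceeding 1 below the advantage threshold. Global
#' model: exactly `1 - abar`, independent of rho and r2.
#'
#' @param model "local" or "global".
#' @inheritParams expected_r2_totpgs
#' @return The ratio of expected squared correlations.
#' @export
relative_predictive_power <- function(model = c("local", "global"),
                                      rho, abar) {
  model <- match.arg(model)
  check_theory_inputs(0, rho, abar)
  if (model == "global") return((1 - abar) + 0 * rho)
  denom <- (1 - abar + rho * abar)^2
  if (any(denom == 0)) stop_param("degenerate: zero denominator")
  (1 - abar) / denom
}

#' Theory curves over a parameter grid
#'
#' Expected squared correlations of both scores under both models over the
#' cross product of the supplied parameter values.
#'
#' @param abar,rho,r2 Numeric vectors of parameter values.
#' @return data.frame with columns `abar`, `rho`, `r2`, `e_tot`,
#'   `e_par_global`, `e_par_local`.
#' @export
theory_curves <- function(abar, rho, r2) {
  grid <- expand.grid(abar = abar, rho = rho, r2 = r2,
                      KEEP.OUT.ATTRS = FALSE)
  grid$e_tot <- expected_r2_totpgs(grid$r2, grid$rho, grid$abar)
  grid$e_par_global <- expected_r2_parpgs_global(grid$r2, grid$rho, grid$abar)
  grid$e_par_local <- expected_r2_parpgs_local(grid$r2, grid$rho, grid$abar)
  grid
}

#' Diagnostics for the closed-form validity conditions
#'
#' Reports how strongly a cohort departs from the simplifying conditions
#' behind the closed forms; nothing is enforced, since the approximations
#' are known to degrade gracefully.
#'
#' @param x Causal [hap_panel].
#' @param la Matching [la_panel].
#' @return data.frame with one row per condition: `condition`,
#'   `statistic`, `value`. Statistics: (A) coefficient of variation of
#'   ancestry-conditional frequencies across markers; (B) SD of global
#'   ancestry across individuals; (C) mean within-individual haplotype
#'   ancestry concordance; (D) max |f_afr - f_eur|; (E) mean absolute
#'   inter-haplotype allele correlation.
#' @export
conditions_diagnostics <- function(x, la) {
  fr <- conditional_allele_frequencies(x, la)
  cv <- function(v) stats::sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE)
  concord <- mean(la$h1 == la$h2)
  hapcor <- mean(abs(vapply(seq_len(n_var(x)), function(j) {
    if (stats::var(x$h1[, j]) == 0 || stats::var(x$h2[, j]) == 0) return(0)
    stats::cor(x$h1[, j], x$h2[, j])
  }, numeric(1))))
  data.frame(
    condition = c("A", "B", "C", "D", "E"),
    statistic = c("cv of ancestry-conditional frequencies across markers",
                  "sd of global ancestry across individuals",
                  "mean haplotype ancestry concordance",
                  "max |f_afr - f_eur|",
                  "mean |cor| of alleles between haplotypes"),
    value = c(mean(c(cv(fr$f_afr), cv(fr$f_eur))),
              stats::sd(la$global),
              concord,
              max(abs(fr$f_afr - fr$f_eur), na.rm = TRUE),
              hapcor)
  )
}
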