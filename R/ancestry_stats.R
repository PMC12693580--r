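## Conditional average effects by local ancestry and their correlation.
##
## The key population quantity is LAACor: the correlation, across variants,
## of average effects conditioned on African vs European local ancestry.
## Under the local model this equals the base cross-ancestry correlation
## rho; under the global model it is given in closed form by the
## omega-weighted covariance below and is typically much closer to 1.

#' Local-ancestry-conditioned allele frequencies
#'
#' Per variant and ancestry, the mean allele among haplotypes whose call is
#' that ancestry. Variants without carriers of an ancestry get `NA` on that
#' side (downstream operations must skip or handle them).
#'
#' @param x A [hap_panel].
#' @param la The matching [la_panel].
#' @return An [ancestry_freqs] (values may be 0, 1 or `NA`).
#' @export
conditional_allele_frequencies <- function(x, la) {
  check_same_shape(x, la)
  n_afr <- colSums(la$h1) + colSums(la$h2)
  n_eur <- 2 * n_ind(x) - n_afr
  s_afr <- colSums(x$h1 * la$h1) + colSums(x$h2 * la$h2)
  s_eur <- colSums(x$h1 * (1 - la$h1)) + colSums(x$h2 * (1 - la$h2))
  f_afr <- ifelse(n_afr > 0, s_afr / n_afr, NA_real_)
  f_eur <- ifelse(n_eur > 0, s_eur / n_eur, NA_real_)
  out <- list(f_afr = f_afr, f_eur = f_eur, role = x$role)
  class(out) <- "ancestry_freqs"
  out
}

#' Ancestry-specific haplotypic LD between paired variants
#'
#' lambda = (P(X=1, X'=1) - f f') / sqrt(f(1-f) f'(1-f')), computed on
#' haplotypes whose local ancestry at both members of the pair is the
#' requested ancestry, with f, f' the conditional allele frequencies on the
#' same haplotype set.
#'
#' @param xc,xt Causal and tagging [hap_panel]s (pair j in `xc` is tagged by
#'   variant j in `xt`).
#' @param la The [la_panel] (shared by both members of each pair).
#' @param ancestry "afr" or "eur".
#' @return Numeric lambda-hat per pair; `NA` where fewer than 2 qualifying
#'   haplotypes exist. Monomorphic variants within the stratum raise an
#'   error.
#' @export
estimate_ld <- function(xc, xt, la, ancestry = c("afr", "eur")) {
  ancestry <- match.arg(ancestry)
  check_same_shape(xc, la); check_same_shape(xt, la)
  mask1 <- if (ancestry == "afr") la$h1 else 1 - la$h1
  mask2 <- if (ancestry == "afr") la$h2 else 1 - la$h2
  m <- colSums(mask1) + colSums(mask2)
  f  <- (colSums(xc$h1 * mask1) + colSums(xc$h2 * mask2)) / m
  fp <- (colSums(xt$h1 * mask1) + colSums(xt$h2 * mask2)) / m
  p11 <- (colSums(xc$h1 * xt$h1 * mask1) + colSums(xc$h2 * xt$h2 * mask2)) / m
  ok <- m >= 2
  mono <- ok & (f %in% c(0, 1) | fp %in% c(0, 1))
  if (any(mono)) {
    stop_param("monomorphic variant within the ", ancestry,
               " stratum at pair(s) ",
               paste(utils::head(which(mono), 5L), collapse = ", "),
               ": LD undefined")
  }
  lam <- (p11 - f * fp) / sqrt(f * (1 - f) * fp * (1 - fp))
  lam[!ok] <- NA_real_
  lam
}

#' Average effects conditioned on local ancestry
#'
#' Per variant, the haplotype-level average of the individual effect field
#' over carrier haplotypes of each ancestry call (a diploid individual with
#' two African calls at the variant contributes both haplotypes). Under the
#' local model these averages are exactly the ancestry-specific causal
#' effects.
#'
#' @param field An `effect_field` from [individual_effects()].
#' @param la The causal-variant [la_panel].
#' @return List of class `cond_avg_effects` with `avg_afr`, `avg_eur` and
#'   carrier haplotype counts `n_afr`, `n_eur` (averages are `NA` where no
#'   carriers exist).
#' @export
conditional_average_effects <- function(field, la) {
  if (!identical(dim(field$h1), dim(la$h1))) {
    stop_param("effect field and ancestry panel disagree in shape")
  }
  n_afr <- colSums(la$h1) + colSums(la$h2)
  n_eur <- 2 * nrow(la$h1) - n_afr
  s_afr <- colSums(field$h1 * la$h1) + colSums(field$h2 * la$h2)
  s_eur <- colSums(field$h1 * (1 - la$h1)) + colSums(field$h2 * (1 - la$h2))
  structure(list(avg_afr = ifelse(n_afr > 0, s_afr / n_afr, NA_real_),
                 avg_eur = ifelse(n_eur > 0, s_eur / n_eur, NA_real_),
                 n_afr = n_afr, n_eur = n_eur),
            class = "cond_avg_effects")
}

#' Carrier-average ancestry weights (omega)
#'
#' Per variant: `w1` and `w2` are the means of `(1 - abar_i)` and `abar_i`
#' over African-call carrier haplotypes, `w3` and `w4` the same means over
#' European-call carriers. Each pair sums to 1. Substituting them into
#' `beta_eur * w1 + beta_afr * w2` (resp. `w3`, `w4`) reproduces the
#' global-model conditional average effects exactly.
#'
#' @param la The causal-variant [la_panel].
#' @param global Optional global-ancestry vector (defaults to `la$global`).
#' @return data.frame with columns `w1`..`w4` and carrier counts (`NA`
#'   where an ancestry has no carriers).
#' @export
omega_weights <- function(la, global = NULL) {
  if (is.null(global)) global <- la$global
  n_afr <- colSums(la$h1) + colSums(la$h2)
  n_eur <- 2 * nrow(la$h1) - n_afr
  s2 <- drop(crossprod(la$h1, global) + crossprod(la$h2, global))
  s4 <- drop(crossprod(1 - la$h1, global) + crossprod(1 - la$h2, global))
  w2 <- ifelse(n_afr > 0, s2 / n_afr, NA_real_)
  w4 <- ifelse(n_eur > 0, s4 / n_eur, NA_real_)
  data.frame(w1 = 1 - w2, w2 = w2, w3 = 1 - w4, w4 = w4,
             n_afr = n_afr, n_eur = n_eur)
}

#' Closed-form covariance of global-model conditional average effects
#'
#' Per variant:
#' `u = s2e w1^2 + 2 tau w1 w2 + s2a w2^2`,
#' `v = s2e w3^2 + 2 tau w3 w4 + s2a w4^2`,
#' `w = s2e w1 w3 + tau (w2 w3 + w1 w4) + s2a w2 w4`,
#' with (s2e, s2a, tau) the base effect covariance. The per-variant
#' correlation of African- vs European-conditioned average effects is then
#' `w / sqrt(u v)`.
#'
#' @param omega data.frame from [omega_weights()].
#' @param cov A [base_covariance()] object.
#' @return data.frame with columns `u`, `v`, `w`, `laacor` per variant.
#' @export
prop1_covariance <- function(omega, cov) {
  s2e <- cov$sigma2_eur; s2a <- cov$sigma2_afr; tau <- cov$tau
  u <- s2e * omega$w1^2 + 2 * tau * omega$w1 * omega$w2 + s2a * omega$w2^2
  v <- s2e * omega$w3^2 + 2 * tau * omega$w3 * omega$w4 + s2a * omega$w4^2
  w <- s2e * omega$w1 * omega$w3 + tau * (omega$w2 * omega$w3 + omega$w1 * omega$w4) +
    s2a * omega$w2 * omega$w4
  if (any(u <= 0 | v <= 0, na.rm = TRUE)) {
    stop_param("degenerate variance: u or v non-positive")
  }
  data.frame(u = u, v = v, w = w, laacor = w / sqrt(u * v))
}

#' Genome-wide pooled LAACor
#'
#' Pools per-variant covariance terms into a single correlation,
#' `sum(w) / sqrt(sum(u) * sum(v))` — the population value of the
#' across-variant sample correlation of the mean-zero conditional average
#' effects. Variants with missing terms (single-ancestry carriers) are
#' excluded.
#'
#' @param report data.frame with columns `u`, `v`, `w` (from
#'   [prop1_covariance()]).
#' @return A single pooled correlation.
#' @export
genome_wide_laacor <- function(report) {
  ok <- stats::complete.cases(report[, c("u", "v", "w")])
  if (sum(ok) < 2) stop_param("need at least 2 variants with defined covariance terms")
  sum(report$w[ok]) / sqrt(sum(report$u[ok]) * sum(report$v[ok]))
}

#' Empirical genome-wide LAACor from simulated effect redraws
#'
#' Monte Carlo counterpart of the pooled parameter: for each redraw, draw
#' ancestry-specific effects, expand them under `model`, compute conditional
#' average effects by local ancestry, and record the across-variant sample
#' correlation of (avg_afr, avg_eur). Variants lacking carriers of either
#' ancestry are dropped.
#'
#' @param la The causal-variant [la_panel].
#' @param cov A [base_covariance()] object.
#' @param model "local" or "global".
#' @param n_redraws Number of effect redraws.
#' @param seed Optional integer seed.
#' @return List with `mean` (mean correlation across redraws), `per_redraw`
#'   and `se`.
#' @export
empirical_laacor <- function(la, cov, model = c("global", "local"),
                             n_redraws = 20, seed = NULL) {
  model <- match.arg(model)
  p <- n_var(la)
  with_seed(seed, {
    vals <- vapply(seq_len(n_redraws), function(k) {
      eff <- draw_ancestral_effects(cov, p)
      fld <- individual_effects(model, eff, la)
      avg <- conditional_average_effects(fld, la)
      ok <- !is.na(avg$avg_afr) & !is.na(avg$avg_eur)
      stats::cor(avg$avg_afr[ok], avg$avg_eur[ok])
    }, numeric(1))
    list(mean = mean(vals), per_redraw = vals,
         se = stats::sd(vals) / sqrt(n_redraws))
  })
}

#' Full LAACor report for a cohort
#'
#' Combines the closed-form per-variant terms (global model) with the
#' pooled parameter and, optionally, the empirical pooled correlation from
#' effect redraws.
#'
#' @param la The causal-variant [la_panel].
#' @param cov A [base_covariance()] object.
#' @param model "local" or "global".
#' @param n_redraws Effect redraws for the empirical estimate (0 to skip).
#' @param seed Optional integer seed.
#' @return List of class `laacor_report`: `per_variant` (global model only),
#'   `pooled_closed`, `pooled_empirical`, `model`, `params`.
#' @export
laacor_report <- function(la, cov, model = c("global", "local"),
                          n_redraws = 20, seed = NULL) {
  model <- match.arg(model)
  per_variant <- NULL
  if (model == "global") {
    om <- omega_weights(la)
    per_variant <- prop1_covariance(om, cov)
    pooled_closed <- genome_wide_laacor(per_variant)
  } else {
    ## local model: conditional averages are the base effects themselves,
    ## so every per-variant and pooled correlation equals rho
    pooled_closed <- cov$rho
  }
  pooled_empirical <- if (n_redraws > 0) {
    empirical_laacor(la, cov, model, n_redraws, seed)$mean
  } else {
    NA_real_
  }
  structure(list(per_variant = per_variant, pooled_closed = pooled_closed,
                 pooled_empirical = pooled_empirical, model = model,
                 params = cov),
            class = "laacor_report")
}
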