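## Ancestry-specific causal effects and their individual-level expansion.
##
## The base model draws per-variant European/African causal effect pairs
## from a mean-zero bivariate normal whose covariance is set by two
## interpretable parameters: r2, the phenotypic variance explained by genetic
## effects, and rho, the cross-ancestry correlation of causal effects.
## Tagging effects follow by the classic LD/frequency scaling.

#' Base bivariate covariance of causal effects
#'
#' With causal allele frequencies f'_Eur, f'_Afr across `p` variants:
#' \deqn{\sigma'^2_{Eur} = r^2 / (2 \sum_j f'_{Eur,j}(1-f'_{Eur,j}))}
#' and analogously for the African variance, with covariance
#' \deqn{\tau' = r^2 \rho / (2 \sqrt{\sum_j f'_{Eur,j}(1-f'_{Eur,j})
#'   \sum_j f'_{Afr,j}(1-f'_{Afr,j})}).}
#' This normalization makes the genetic variance of an ancestrally
#' homogeneous cohort approximately `r2`.
#'
#' @param freqs Causal [ancestry_freqs], strictly in (0, 1).
#' @param r2 Variance explained by genetic effects, in `[0, 1]`.
#' @param rho Cross-ancestry correlation of causal effects, in `[-1, 1]`.
#' @return List of class `base_cov`: `sigma2_eur`, `sigma2_afr`, `tau`,
#'   plus the generating `r2` and `rho`.
#' @export
base_covariance <- function(freqs, r2, rho) {
  check_prob(r2, "r2")
  if (abs(rho) > 1) stop_param("rho must lie in [-1, 1]")
  check_prob(freqs$f_eur, "f_eur", open = TRUE)
  check_prob(freqs$f_afr, "f_afr", open = TRUE)
  he <- sum(freqs$f_eur * (1 - freqs$f_eur))
  ha <- sum(freqs$f_afr * (1 - freqs$f_afr))
  structure(list(sigma2_eur = r2 / (2 * he),
                 sigma2_afr = r2 / (2 * ha),
                 tau = r2 * rho / (2 * sqrt(he * ha)),
                 r2 = r2, rho = rho),
            class = "base_cov")
}

#' Draw ancestry-specific causal effects
#'
#' Per-variant pairs (beta'_Eur, beta'_Afr) are i.i.d. bivariate normal with
#' the given covariance; at `rho = 1` the two vectors are exactly
#' proportional.
#'
#' @param cov A [base_covariance()] object.
#' @param p Number of variants.
#' @param seed Optional integer seed.
#' @return List of class `ancestral_effects` with `beta_eur`, `beta_afr`
#'   (causal) and `params`.
#' @export
draw_ancestral_effects <- function(cov, p, seed = NULL) {
  s2e <- cov$sigma2_eur; s2a <- cov$sigma2_afr; tau <- cov$tau
  if (s2e < 0 || s2a < 0 || abs(tau) > sqrt(s2e * s2a) + 1e-12) {
    stop_param("invalid covariance: |tau| exceeds sqrt(sigma2_eur * sigma2_afr)")
  }
  with_seed(seed, {
    z1 <- stats::rnorm(p); z2 <- stats::rnorm(p)
    beta_eur <- sqrt(s2e) * z1
    ## conditional decomposition keeps the rho = 1 case exactly proportional
    rho <- if (s2e > 0 && s2a > 0) tau / sqrt(s2e * s2a) else 0
    beta_afr <- sqrt(s2a) * (rho * z1 + sqrt(max(0, 1 - rho^2)) * z2)
    structure(list(beta_eur = beta_eur, beta_afr = beta_afr,
                   params = cov),
              class = "ancestral_effects")
  })
}

#' LD/frequency scaling factors from causal to tagging variants
#'
#' theta = lambda * sqrt(f'(1 - f') / (f(1 - f))), per ancestry, where
#' primes denote causal quantities. theta = 1 when lambda = 1 and the
#' causal and tagging frequencies coincide.
#'
#' @param causal_freqs,tagging_freqs [ancestry_freqs] per pair.
#' @param lambda_afr,lambda_eur Haplotypic correlations per pair.
#' @return List with `theta_eur`, `theta_afr`.
#' @export
theta_scaling <- function(causal_freqs, tagging_freqs, lambda_afr, lambda_eur) {
  check_prob(causal_freqs$f_eur, "causal f_eur", open = TRUE)
  check_prob(causal_freqs$f_afr, "causal f_afr", open = TRUE)
  check_prob(tagging_freqs$f_eur, "tagging f_eur", open = TRUE)
  check_prob(tagging_freqs$f_afr, "tagging f_afr", open = TRUE)
  het <- function(f) f * (1 - f)
  list(theta_eur = lambda_eur * sqrt(het(causal_freqs$f_eur) / het(tagging_freqs$f_eur)),
       theta_afr = lambda_afr * sqrt(het(causal_freqs$f_afr) / het(tagging_freqs$f_afr)))
}

#' Convert causal effects to tagging effects
#'
#' beta_tag = beta_causal * theta per ancestry, with theta from
#' [theta_scaling()]. An optional additive noise standard deviation models
#' imperfect effect estimation; the default assumes effects are known
#' without bias.
#'
#' @param effects An `ancestral_effects` object (causal part).
#' @param pairs data.frame with `lambda_afr`, `lambda_eur` per pair (as
#'   returned by [sample_linked_pairs()]).
#' @param causal_freqs,tagging_freqs [ancestry_freqs] per pair.
#' @param est_noise_sd Optional standard deviation of additive estimation
#'   noise (default 0).
#' @param seed Optional integer seed (used only when `est_noise_sd > 0`).
#' @return The `ancestral_effects` object with `tag_beta_eur`,
#'   `tag_beta_afr` and `theta` filled in.
#' @export
tagging_effects <- function(effects, pairs, causal_freqs, tagging_freqs,
                            est_noise_sd = 0, seed = NULL) {
  th <- theta_scaling(causal_freqs, tagging_freqs,
                      pairs$lambda_afr, pairs$lambda_eur)
  effects$tag_beta_eur <- effects$beta_eur * th$theta_eur
  effects$tag_beta_afr <- effects$beta_afr * th$theta_afr
  if (est_noise_sd > 0) {
    with_seed(seed, {
      p <- length(effects$tag_beta_eur)
      effects$tag_beta_eur <- effects$tag_beta_eur + stats::rnorm(p, 0, est_noise_sd)
      effects$tag_beta_afr <- effects$tag_beta_afr + stats::rnorm(p, 0, est_noise_sd)
    })
  }
  effects$theta <- th
  effects
}

#' Expand ancestral effects into an individual-level effect field
#'
#' Local model: the effect on a haplotype is the causal effect of the
#' haplotype's local ancestry at that variant. Global model: the effect is
#' the global-ancestry-weighted convex combination
#' `beta_eur * (1 - abar_i) + beta_afr * abar_i`, identical on both
#' haplotypes.
#'
#' @param model "local" or "global".
#' @param effects An `ancestral_effects` object (causal part used).
#' @param la The causal-variant [la_panel].
#' @return List of class `effect_field`: `model` and n x p matrices `h1`,
#'   `h2` (the global model stores one shared matrix in both slots).
#' @export
individual_effects <- function(model = c("local", "global"), effects, la) {
  model <- match.arg(model)
  p <- n_var(la)
  if (length(effects$beta_eur) != p) stop_param("effects/panel shape mismatch")
  be <- effects$beta_eur; ba <- effects$beta_afr
  if (model == "local") {
    field <- function(a) {
      sweep(1 - a, 2, be, "*") + sweep(a, 2, ba, "*")
    }
    h1 <- field(la$h1); h2 <- field(la$h2)
  } else {
    abar <- la$global
    h1 <- outer(1 - abar, be) + outer(abar, ba)
    h2 <- h1
  }
  structure(list(model = model, h1 = h1, h2 = h2), class = "effect_field")
}
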