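## Synthetic two-way admixed cohorts (African/European), emulating the
## structure of a recently admixed African American biobank cohort: Beta
## distributed global African ancestry with mean ~0.79, binary local-ancestry
## mosaics, Balding-Nichols ancestry-specific allele frequencies, and
## causal-tagging variant pairs with ancestry-specific haplotypic LD.

## Beta shapes fitted offline (least squares on the quartile means of the
## Beta distribution) so that ranking the cohort by global ancestry and
## cutting it into quartiles gives subgroup means close to
## (0.61, 0.79, 0.85, 0.92).
ABAR_SHAPE_A <- 7.48
ABAR_SHAPE_B <- 1.94

#' Sample global African ancestry proportions
#'
#' Draws per-individual global African ancestry i.i.d. from a Beta
#' distribution. The default shape parameters are calibrated so that
#' quartile-subgroup means approximate (0.61, 0.79, 0.85, 0.92), the
#' structure of a large African American hospital biobank cohort.
#'
#' @param n Number of individuals (at least 4).
#' @param shape_a,shape_b Positive Beta shape parameters.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n` with values in `[0, 1]`.
#' @export
sample_global_ancestry <- function(n, shape_a = ABAR_SHAPE_A,
                                   shape_b = ABAR_SHAPE_B, seed = NULL) {
  if (n < 4) stop_param("n must be at least 4")
  if (shape_a <= 0 || shape_b <= 0) stop_param("Beta shape parameters must be positive")
  with_seed(seed, stats::rbeta(n, shape_a, shape_b))
}

#' Sample local-ancestry haplotype mosaics
#'
#' Two generating modes. `independent`: each call is Bernoulli(abar_i)
#' independently across variants and haplotypes, the clean analogue of a
#' panel of approximately independent markers. `tract`: each haplotype is a
#' two-state Markov chain along the genetic map with total relaxation rate
#' `generations` per Morgan and stationary African probability abar_i (the
#' standard pulse-admixture approximation; the default of 15 generations
#' matches African American admixture history).
#'
#' @param global Numeric vector of global African ancestry proportions.
#' @param p Number of variants.
#' @param mode "independent" or "tract".
#' @param map_length Genetic map length in Morgans (tract mode).
#' @param generations Admixture age in generations (tract mode, >= 1).
#' @param seed Optional integer seed.
#' @return An [la_panel] whose `global` slot holds the stationary
#'   probabilities used to generate the mosaic.
#' @export
sample_local_ancestry <- function(global, p, mode = c("independent", "tract"),
                                  map_length = 1, generations = 15,
                                  seed = NULL) {
  mode <- match.arg(mode)
  if (length(global) == 0) stop_param("global ancestry vector is empty")
  check_prob(global, "global ancestry")
  if (p < 1) stop_param("p must be at least 1")
  n <- length(global)
  with_seed(seed, {
    if (mode == "independent") {
      h1 <- matrix(stats::rbinom(n * p, 1L, rep(global, p)), n, p)
      h2 <- matrix(stats::rbinom(n * p, 1L, rep(global, p)), n, p)
      positions <- rep(0, p)
    } else {
      if (map_length <= 0) stop_param("map_length must be positive")
      if (generations < 1) stop_param("generations must be at least 1")
      positions <- seq(0, map_length, length.out = p)
      d <- diff(positions)
      decay <- exp(-generations * d)
      sample_hap <- function(abar) {
        calls <- integer(p)
        calls[1] <- stats::rbinom(1L, 1L, abar)
        ## P(stay) = pi_state + (1 - pi_state) * exp(-g d)
        u <- stats::runif(p - 1L)
        for (j in 2:p) {
          pi_cur <- if (calls[j - 1L] == 1L) abar else 1 - abar
          stay <- pi_cur + (1 - pi_cur) * decay[j - 1L]
          calls[j] <- if (u[j - 1L] <= stay) calls[j - 1L] else 1L - calls[j - 1L]
        }
        calls
      }
      h1 <- t(vapply(global, sample_hap, integer(p)))
      h2 <- t(vapply(global, sample_hap, integer(p)))
      if (p == 1L) { h1 <- matrix(h1, n, 1); h2 <- matrix(h2, n, 1) }
    }
    la_panel(h1, h2, positions = positions, global = global)
  })
}

#' Sample ancestry-specific allele frequencies (Balding-Nichols)
#'
#' For each variant an ancestral frequency q is drawn from `base_dist`
#' (default Uniform(0.05, 0.95)); African and European frequencies are then
#' drawn independently from Beta(q(1-fst)/fst, (1-q)(1-fst)/fst). The default
#' `fst = 0.15` is typical of African-European differentiation. Frequencies
#' are clipped to `[0.01, 0.99]` to protect downstream `1/sqrt(f(1-f))`
#' scalings.
#'
#' @param p Number of variants.
#' @param fst Differentiation parameter, strictly in (0, 1).
#' @param base_dist Function of one argument returning that many ancestral
#'   frequencies.
#' @param role "causal" or "tagging" (carried as metadata).
#' @param seed Optional integer seed.
#' @return A list of class `ancestry_freqs` with numeric vectors `f_afr`,
#'   `f_eur` and the `role`.
#' @export
sample_ancestral_frequencies <- function(p, fst = 0.15,
                                         base_dist = function(k) stats::runif(k, 0.05, 0.95),
                                         role = c("causal", "tagging"),
                                         seed = NULL) {
  role <- match.arg(role)
  if (fst <= 0 || fst >= 1) stop_param("fst must lie strictly in (0, 1)")
  if (p < 1) stop_param("p must be at least 1")
  with_seed(seed, {
    q <- base_dist(p)
    check_prob(q, "ancestral frequencies")
    a <- q * (1 - fst) / fst
    b <- (1 - q) * (1 - fst) / fst
    clip <- function(x) pmin(pmax(x, 0.01), 0.99)
    ancestry_freqs(clip(stats::rbeta(p, a, b)), clip(stats::rbeta(p, a, b)),
                   role = role)
  })
}

#' Bundle ancestry-specific allele frequencies
#'
#' @param f_afr,f_eur Frequencies per variant on the African and European
#'   background, strictly in (0, 1).
#' @param role "causal" or "tagging".
#' @return A list of class `ancestry_freqs`.
#' @export
ancestry_freqs <- function(f_afr, f_eur, role = c("causal", "tagging")) {
  role <- match.arg(role)
  if (length(f_afr) != length(f_eur)) stop_param("frequency vectors differ in length")
  structure(list(f_afr = as.numeric(f_afr), f_eur = as.numeric(f_eur),
                 role = role),
            class = "ancestry_freqs")
}

#' Sample phased haplotypes conditional on local ancestry
#'
#' Each allele is Bernoulli with the frequency of its haplotype's local
#' ancestry: `f_afr[j]` where the call is African (1), `f_eur[j]` where
#' European (0), independently across individuals, variants and haplotypes.
#'
#' @param la An [la_panel].
#' @param freqs An [ancestry_freqs] with one frequency pair per variant.
#' @param seed Optional integer seed.
#' @return A [hap_panel] with the role of `freqs`.
#' @export
sample_haplotypes <- function(la, freqs, seed = NULL) {
  if (length(freqs$f_afr) != n_var(la)) stop_param("frequency/panel shape mismatch")
  n <- n_ind(la); p <- n_var(la)
  f_afr <- matrix(freqs$f_afr, n, p, byrow = TRUE)
  f_eur <- matrix(freqs$f_eur, n, p, byrow = TRUE)
  with_seed(seed, {
    draw <- function(a) {
      prob <- ifelse(a == 1, f_afr, f_eur)
      matrix(stats::rbinom(n * p, 1L, prob), n, p)
    }
    hap_panel(draw(la$h1), draw(la$h2), role = freqs$role)
  })
}

## P(X = 1, X' = 1) implied by frequencies and haplotypic correlation lambda;
## must respect the Frechet bounds for a valid bivariate Bernoulli.
bernoulli_p11 <- function(f, fp, lambda) {
  p11 <- f * fp + lambda * sqrt(f * (1 - f) * fp * (1 - fp))
  lo <- pmax(0, f + fp - 1)
  hi <- pmin(f, fp)
  bad <- which(p11 < lo - 1e-12 | p11 > hi + 1e-12)
  if (length(bad)) {
    stop_param("infeasible (f, f', lambda) triple at pair(s) ",
               paste(utils::head(bad, 5L), collapse = ", "),
               ": joint P(1,1) violates the Frechet bounds")
  }
  pmin(pmax(p11, lo), hi)
}

#' Sample jointly-linked causal and tagging haplotypes
#'
#' For each variant pair, causal and tagging alleles on a haplotype are drawn
#' from the bivariate Bernoulli determined by the ancestry-appropriate
#' frequencies and target haplotypic correlation lambda, so the realized
#' ancestry-specific LD converges to the target as the cohort grows.
#'
#' @param causal_freqs,tagging_freqs [ancestry_freqs] for the paired variants.
#' @param target_lambda_afr,target_lambda_eur Target haplotypic correlations
#'   per pair (recycled if scalar), each admitting a valid joint distribution.
#' @param la An [la_panel] (the same mosaic applies to both members of a
#'   tightly linked pair).
#' @param seed Optional integer seed.
#' @return List with `causal` and `tagging` [hap_panel]s and `pairs`, a
#'   data.frame of pair indices and target lambdas.
#' @export
sample_linked_pairs <- function(causal_freqs, tagging_freqs,
                                target_lambda_afr, target_lambda_eur,
                                la, seed = NULL) {
  p <- n_var(la); n <- n_ind(la)
  if (length(causal_freqs$f_afr) != p || length(tagging_freqs$f_afr) != p) {
    stop_param("frequency/panel shape mismatch")
  }
  lam_afr <- rep_len(target_lambda_afr, p)
  lam_eur <- rep_len(target_lambda_eur, p)
  ## feasibility first, so errors name pairs before any draw
  p11_afr <- bernoulli_p11(causal_freqs$f_afr, tagging_freqs$f_afr, lam_afr)
  p11_eur <- bernoulli_p11(causal_freqs$f_eur, tagging_freqs$f_eur, lam_eur)
  with_seed(seed, {
    draw <- function(a) {
      f  <- ifelse(a == 1, matrix(causal_freqs$f_afr, n, p, byrow = TRUE),
                   matrix(causal_freqs$f_eur, n, p, byrow = TRUE))
      p11 <- ifelse(a == 1, matrix(p11_afr, n, p, byrow = TRUE),
                    matrix(p11_eur, n, p, byrow = TRUE))
      fp  <- ifelse(a == 1, matrix(tagging_freqs$f_afr, n, p, byrow = TRUE),
                    matrix(tagging_freqs$f_eur, n, p, byrow = TRUE))
      xc <- matrix(stats::rbinom(n * p, 1L, f), n, p)
      ## P(x' = 1 | x) from the joint law
      cond <- ifelse(xc == 1, p11 / f, (fp - p11) / (1 - f))
      xt <- matrix(stats::rbinom(n * p, 1L, pmin(pmax(cond, 0), 1)), n, p)
      list(xc = xc, xt = xt)
    }
    d1 <- draw(la$h1); d2 <- draw(la$h2)
    list(causal = hap_panel(d1$xc, d2$xc, role = "causal"),
         tagging = hap_panel(d1$xt, d2$xt, role = "tagging"),
         pairs = data.frame(causal = seq_len(p), tagging = seq_len(p),
                            lambda_afr = lam_afr, lambda_eur = lam_eur))
  })
}

#' Split a cohort into global-ancestry subgroups
#'
#' Individuals are ranked by global African ancestry and cut into
#' `n_groups` equal-size (within 1) groups with non-decreasing means.
#'
#' @param global Numeric global-ancestry vector.
#' @param n_groups Number of groups (default 4, quartiles).
#' @return List with integer `labels` (1..n_groups, 1 = least African) and
#'   `group_means`.
#' @export
split_subgroups <- function(global, n_groups = 4) {
  n <- length(global)
  if (n_groups < 1) stop_param("n_groups must be at least 1")
  if (n < n_groups) stop_param("fewer individuals than groups")
  rk <- rank(global, ties.method = "first")
  labels <- as.integer(ceiling(rk * n_groups / n))
  means <- as.numeric(tapply(global, labels, mean))
  list(labels = labels, group_means = means)
}

#' Global ancestry as the genome-wide mean of local ancestry
#'
#' @param la An [la_panel].
#' @return Numeric vector: for each individual the mean of its `2p`
#'   local-ancestry calls.
#' @export
compute_global_ancestry <- function(la) {
  p <- n_var(la)
  if (p < 1) stop_param("panel has no variants")
  (rowSums(la$h1) + rowSums(la$h2)) / (2 * p)
}

#' Generate a complete synthetic admixed cohort
#'
#' Convenience wrapper tying the samplers together: global ancestry, a
#' local-ancestry mosaic, causal allele frequencies, and causal haplotypes.
#'
#' @param n,p Cohort size and variant count.
#' @param mode Local-ancestry mode, see [sample_local_ancestry()].
#' @param fst Allele-frequency differentiation, see
#'   [sample_ancestral_frequencies()].
#' @param shape_a,shape_b Beta shapes for global ancestry.
#' @param seed Optional integer master seed; substreams are derived per
#'   component.
#' @return List with `global`, `la`, `freqs`, `haps`, `subgroups`.
#' @export
simulate_cohort <- function(n, p, mode = "independent", fst = 0.15,
                            shape_a = ABAR_SHAPE_A, shape_b = ABAR_SHAPE_B,
                            seed = NULL) {
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL, NULL) else {
    lapply(c("abar", "la", "freq", "hap"), derive_seed, master = seed)
  }
  global <- sample_global_ancestry(n, shape_a, shape_b, seed = seeds[[1]])
  la <- sample_local_ancestry(global, p, mode = mode, seed = seeds[[2]])
  freqs <- sample_ancestral_frequencies(p, fst = fst, seed = seeds[[3]])
  haps <- sample_haplotypes(la, freqs, seed = seeds[[4]])
  list(global = global, la = la, freqs = freqs, haps = haps,
       subgroups = split_subgroups(global))
}
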