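## Phenotype simulation and polygenic scores.
##
## Haplotype dosages are demeaned by the allele frequency of their local
## ancestry before entering the phenotype or any score, which makes all
## cumulative genetic quantities invariant to the labeling of alleles.

#' Demean haplotype dosages by local-ancestry-matched allele frequency
#'
#' xhat = (x - f_afr) where the call is African, (x - f_eur) where European.
#' With `freq_source = "sample_conditional"` the frequencies are first
#' re-estimated from the panel by [conditional_allele_frequencies()] (the
#' default analysis choice); `"true_generating"` uses `freqs` as given
#' (useful for oracle checks against the generative truth).
#'
#' @param x A [hap_panel].
#' @param la The matching [la_panel].
#' @param freqs [ancestry_freqs] used directly in `true_generating` mode.
#' @param freq_source "sample_conditional" or "true_generating".
#' @return List of class `demeaned_haps` with real-valued matrices `h1`,
#'   `h2` and the `frequencies_used`.
#' @export
demean_haplotypes <- function(x, la, freqs = NULL,
                              freq_source = c("sample_conditional",
                                              "true_generating")) {
  freq_source <- match.arg(freq_source)
  check_same_shape(x, la)
  if (freq_source == "sample_conditional") {
    freqs <- conditional_allele_frequencies(x, la)
    if (anyNA(freqs$f_afr) || anyNA(freqs$f_eur)) {
      ## variants with a single-ancestry carrier set: fall back to the
      ## pooled frequency on the missing side so demeaning stays defined
      pooled <- (colSums(x$h1) + colSums(x$h2)) / (2 * n_ind(x))
      freqs$f_afr[is.na(freqs$f_afr)] <- pooled[is.na(freqs$f_afr)]
      freqs$f_eur[is.na(freqs$f_eur)] <- pooled[is.na(freqs$f_eur)]
    }
  } else if (is.null(freqs)) {
    stop_param("freqs must be supplied in true_generating mode")
  }
  n <- n_ind(x); p <- n_var(x)
  fa <- matrix(freqs$f_afr, n, p, byrow = TRUE)
  fe <- matrix(freqs$f_eur, n, p, byrow = TRUE)
  dm <- function(xm, am) (xm - fa) * am + (xm - fe) * (1 - am)
  structure(list(h1 = dm(x$h1, la$h1), h2 = dm(x$h2, la$h2),
                 frequencies_used = freqs),
            class = "demeaned_haps")
}

#' Simulate a phenotype from an effect field
#'
#' y_i = sum_j (beta_ij^(1) xhat_ij^(1) + beta_ij^(2) xhat_ij^(2)) + eps_i,
#' with eps i.i.d. normal. The noise variance is calibrated per draw to
#' max(0, 1 - sample variance of the genetic component) so the phenotype has
#' approximately unit variance; a genetic variance above 1 triggers a
#' warning and a noise floor of 0.
#'
#' @param field An `effect_field` from [individual_effects()].
#' @param xhat A `demeaned_haps` on the causal variants.
#' @param seed Optional integer seed for the noise draw.
#' @return List of class `phenotype_set`: `y`, `genetic`, `noise_variance`,
#'   `model`.
#' @export
simulate_phenotype <- function(field, xhat, seed = NULL) {
  if (!identical(dim(field$h1), dim(xhat$h1))) {
    stop_param("effect field and demeaned haplotypes disagree in shape")
  }
  g <- rowSums(field$h1 * xhat$h1 + field$h2 * xhat$h2)
  vg <- stats::var(g)
  if (vg > 1) warning("sample genetic variance exceeds 1; noise variance floored at 0")
  nv <- max(0, 1 - vg)
  y <- with_seed(seed, g + stats::rnorm(length(g), 0, sqrt(nv)))
  structure(list(y = y, genetic = g, noise_variance = nv,
                 model = field$model),
            class = "phenotype_set")
}

pgs_design <- function(x, la, freqs, freq_source) {
  xhat <- demean_haplotypes(x, la, freqs, freq_source)
  list(tot = xhat$h1 + xhat$h2,
       par = xhat$h1 * (1 - la$h1) + xhat$h2 * (1 - la$h2))
}

#' Total polygenic score
#'
#' European-ancestry effect sizes applied to every demeaned allele
#' regardless of local ancestry:
#' `TotPGS_i = sum_j beta_Eur_j (xhat_ij^(1) + xhat_ij^(2))`.
#'
#' @param x Tagging (or causal) [hap_panel].
#' @param la Matching [la_panel].
#' @param beta_eur European effect sizes per variant.
#' @param freqs,freq_source Demeaning frequencies, see
#'   [demean_haplotypes()].
#' @return Numeric score per individual.
#' @export
total_pgs <- function(x, la, beta_eur, freqs = NULL,
                      freq_source = "sample_conditional") {
  if (length(beta_eur) != n_var(x)) stop_param("effects/panel shape mismatch")
  d <- pgs_design(x, la, freqs, freq_source)
  drop(d$tot %*% beta_eur)
}

#' Partial polygenic score
#'
#' European-ancestry effect sizes applied only to haplotypes whose local
#' ancestry at the variant is European (call = 0):
#' `ParPGS_i = sum_j beta_Eur_j [(1-a_ij^(1)) xhat_ij^(1) +
#' (1-a_ij^(2)) xhat_ij^(2)]`. Equals the total score when no African calls
#' exist and is identically 0 when all calls are African.
#'
#' @inheritParams total_pgs
#' @return Numeric score per individual.
#' @export
partial_pgs <- function(x, la, beta_eur, freqs = NULL,
                        freq_source = "sample_conditional") {
  if (length(beta_eur) != n_var(x)) stop_param("effects/panel shape mismatch")
  d <- pgs_design(x, la, freqs, freq_source)
  drop(d$par %*% beta_eur)
}

#' Squared correlation of a score with the phenotype, by subgroup
#'
#' @param scores Numeric score per individual.
#' @param y Phenotype vector or `phenotype_set`.
#' @param groups Optional subgroup assignment from [split_subgroups()].
#' @return data.frame with rows `overall` and one per subgroup: `group`,
#'   `n`, `r2`.
#' @export
pgs_phenotype_r2 <- function(scores, y, groups = NULL) {
  if (inherits(y, "phenotype_set")) y <- y$y
  if (length(scores) != length(y)) stop_param("scores and phenotype differ in length")
  one <- function(s, yy) {
    if (stats::var(s) == 0 || stats::var(yy) == 0) {
      stop_param("undefined correlation: zero-variance input")
    }
    stats::cor(s, yy)^2
  }
  out <- data.frame(group = "overall", n = length(y), r2 = one(scores, y),
                    stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    for (g in sort(unique(groups$labels))) {
      idx <- groups$labels == g
      if (sum(idx) < 3) stop_param("subgroup with fewer than 3 individuals")
      out <- rbind(out, data.frame(group = as.character(g), n = sum(idx),
                                   r2 = one(scores[idx], y[idx])))
    }
  }
  out
}
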