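## Haplotype and local-ancestry panels.
##
## A cohort of n diploid individuals typed at p phased variants is held as a
## pair of n x p binary matrices, one per haplotype. This mirrors the stacked
## haplotype representation [X(1) | X(2)] used throughout: hap-level
## operations are plain matrix algebra and never copy a 3-d slice.

#' Construct a phased haplotype panel
#'
#' @param h1,h2 Binary n x p matrices of allele dosages, one per haplotype.
#' @param role Either "causal" or "tagging".
#' @param variant_ids Optional variant labels (defaults to v1..vp).
#' @return An object of class `hap_panel`: a list with elements `h1`, `h2`,
#'   `role`, `variant_ids`.
#' @export
hap_panel <- function(h1, h2, role = c("causal", "tagging"),
                      variant_ids = NULL) {
  role <- match.arg(role)
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  if (!identical(dim(h1), dim(h2))) stop_param("haplotype matrices differ in shape")
  if (!all(h1 %in% c(0, 1)) || !all(h2 %in% c(0, 1))) {
    stop_param("haplotype alleles must be exactly 0 or 1")
  }
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(ncol(h1)))
  if (length(variant_ids) != ncol(h1)) stop_param("variant_ids length mismatch")
  structure(list(h1 = h1, h2 = h2, role = role, variant_ids = variant_ids),
            class = "hap_panel")
}

#' Construct a local-ancestry panel
#'
#' Ancestry coding is fixed throughout the package: 1 = African, 0 = European.
#'
#' @param h1,h2 Binary n x p matrices of local-ancestry calls per haplotype.
#' @param positions Optional genetic-map positions in Morgans (length p).
#' @param global Optional per-individual global African ancestry; when `NULL`
#'   it is derived as the mean of the individual's `2p` calls.
#' @return An object of class `la_panel` with elements `h1`, `h2`,
#'   `positions`, `global`.
#' @export
la_panel <- function(h1, h2, positions = NULL, global = NULL) {
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  if (!identical(dim(h1), dim(h2))) stop_param("ancestry matrices differ in shape")
  if (!all(h1 %in% c(0, 1)) || !all(h2 %in% c(0, 1))) {
    stop_param("local-ancestry calls must be exactly 0 or 1")
  }
  if (is.null(positions)) positions <- seq_len(ncol(h1)) * 0
  if (length(positions) != ncol(h1)) stop_param("positions length mismatch")
  obj <- structure(list(h1 = h1, h2 = h2, positions = positions,
                        global = global),
                   class = "la_panel")
  if (is.null(global)) obj$global <- compute_global_ancestry(obj)
  if (length(obj$global) != nrow(h1)) stop_param("global length mismatch")
  check_prob(obj$global, "global ancestry")
  obj
}

n_ind <- function(panel) nrow(panel$h1)
n_var <- function(panel) ncol(panel$h1)

check_same_shape <- function(x, la) {
  if (!identical(dim(x$h1), dim(la$h1))) {
    stop_param("haplotype and local-ancestry panels disagree in shape")
  }
  invisible(TRUE)
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("<hap_panel> %d individuals x %d %s variants (phased)\n",
              n_ind(x), n_var(x), x$role))
  invisible(x)
}

#' @export
print.la_panel <- function(x, ...) {
  cat(sprintf("<la_panel> %d individuals x %d variants; mean global African ancestry %.3f\n",
              n_ind(x), n_var(x), mean(x$global)))
  invisible(x)
}
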