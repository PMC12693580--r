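# Small fixture builders used across test files.

# Deterministic 4-haplotype toy: 2 individuals x 2 variants.
toy_panels <- function() {
  x <- hap_panel(h1 = matrix(c(1L, 0L, 1L, 1L), 2, 2),
                 h2 = matrix(c(0L, 1L, 1L, 0L), 2, 2))
  la <- la_panel(h1 = matrix(c(1L, 0L, 1L, 0L), 2, 2),
                 h2 = matrix(c(1L, 0L, 0L, 1L), 2, 2))
  list(x = x, la = la)
}

# Mid-size synthetic cohort shared by several statistical tests.
test_cohort <- function(n = 1500, p = 400, seed = 42) {
  simulate_cohort(n, p, seed = seed)
}

# Cohort with every call set to one ancestry.
uniform_ancestry_cohort <- function(n, p, ancestry = 0L, abar = NULL) {
  if (is.null(abar)) abar <- rep(as.numeric(ancestry), n)
  m <- matrix(as.integer(ancestry), n, p)
  la_panel(m, m, global = abar)
}
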