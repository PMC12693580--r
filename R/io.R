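## I/O: phased VCF export/import, local-ancestry tables (RFMix msp and long
## formats), tab-separated result tables with a JSON run manifest.
## Conventions: VCF positions are 1-based; ancestry coding 1 = African,
## 0 = European everywhere; msp windows are closed intervals on position.

#' Export a cohort as a phased VCF plus local-ancestry sidecar
#'
#' Writes `cohort.vcf` (GT field, "|"-separated), `local_ancestry.tsv`
#' (long format: individual, variant, hap1_anc, hap2_anc with 1 = AFR) and
#' `frequencies.tsv` to `dir`.
#'
#' @param x A [hap_panel].
#' @param la The matching [la_panel].
#' @param freqs Optional [ancestry_freqs] for the sidecar.
#' @param dir Output directory (created if missing).
#' @param positions Optional integer base-pair positions (default 1..p).
#' @return Invisibly, the paths written.
#' @export
write_cohort_vcf <- function(x, la, freqs = NULL, dir, positions = NULL) {
  check_same_shape(x, la)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- n_ind(x); p <- n_var(x)
  if (is.null(positions)) positions <- seq_len(p)
  vcf_path <- file.path(dir, "cohort.vcf")
  ids <- sprintf("ind%04d", seq_len(n))
  header <- c("##fileformat=VCFv4.2",
              "##source=admixpgs",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  gt <- matrix(paste0(t(x$h1), "|", t(x$h2)), nrow = p)  # p x n
  body <- vapply(seq_len(p), function(j) {
    paste(c("1", positions[j], x$variant_ids[j], "A", "G", ".", "PASS", ".",
            "GT", gt[j, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), vcf_path)

  la_path <- file.path(dir, "local_ancestry.tsv")
  la_tab <- data.table::data.table(
    individual = rep(ids, times = p),
    variant = rep(x$variant_ids, each = n),
    hap1_anc = as.integer(la$h1),
    hap2_anc = as.integer(la$h2))
  data.table::fwrite(la_tab, la_path, sep = "\t")

  paths <- c(vcf = vcf_path, local_ancestry = la_path)
  if (!is.null(freqs)) {
    fr_path <- file.path(dir, "frequencies.tsv")
    data.table::fwrite(data.table::data.table(
      variant = x$variant_ids, f_afr = freqs$f_afr, f_eur = freqs$f_eur,
      role = freqs$role), fr_path, sep = "\t")
    paths["frequencies"] <- fr_path
  }
  invisible(paths)
}

#' Read phased haplotypes from a VCF
#'
#' Accepts biallelic, fully phased records only; unphased or multi-allelic
#' records raise an error naming the offending record.
#'
#' @param path Path to a VCF file.
#' @param role "causal" or "tagging".
#' @return A [hap_panel] (individuals x variants x 2 haplotypes).
#' @export
read_phased_haplotypes <- function(path, role = c("causal", "tagging")) {
  role <- match.arg(role)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    stop_param("multi-allelic record(s): ",
               paste(utils::head(vcfR::getID(v)[multi], 5L), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")  # variants x samples
  unphased <- matrix(grepl("/", gt), nrow = nrow(gt))
  if (any(unphased)) {
    bad <- rownames(gt)[apply(unphased, 1, any)]
    stop_param("unphased genotype(s) at record(s): ",
               paste(utils::head(bad, 5L), collapse = ", "))
  }
  h1 <- t(matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt)))
  h2 <- t(matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt)))
  hap_panel(h1, h2, role = role, variant_ids = vcfR::getID(v))
}

#' Read local-ancestry calls
#'
#' Two dialects. `long_table`: one row per (individual, variant) with
#' columns `individual`, `variant`, `hap1_anc`, `hap2_anc` (1 = African).
#' `msp`: RFMix msp.tsv window format (columns `#chm`, `spos`, `epos`, ...,
#' then two columns per sample, `<id>.0` and `<id>.1`); windows are
#' expanded to the variants they span, positions treated as closed
#' intervals. A variant falling outside every window is an error.
#'
#' @param path Path to the table.
#' @param dialect "long_table" or "msp".
#' @param variant_positions For `msp`: integer positions of the variants to
#'   align (required).
#' @param variant_ids Optional variant labels.
#' @return An [la_panel].
#' @export
read_local_ancestry <- function(path, dialect = c("long_table", "msp"),
                                variant_positions = NULL, variant_ids = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "long_table") {
    tab <- data.table::fread(path, sep = "\t")
    need <- c("individual", "variant", "hap1_anc", "hap2_anc")
    if (!all(need %in% names(tab))) stop_param("long table missing columns")
    inds <- unique(tab$individual)
    vars <- unique(tab$variant)
    key <- match(paste(tab$individual, tab$variant),
                 paste(rep(inds, times = length(vars)),
                       rep(vars, each = length(inds))))
    h1 <- matrix(NA_integer_, length(inds), length(vars))
    h2 <- h1
    h1[key] <- tab$hap1_anc
    h2[key] <- tab$hap2_anc
    if (anyNA(h1) || anyNA(h2)) stop_param("long table does not cover all (individual, variant) pairs")
    return(la_panel(h1, h2))
  }
  ## msp dialect
  if (is.null(variant_positions)) stop_param("msp dialect requires variant_positions")
  hdr <- readLines(path, n = 2L)
  skip <- if (startsWith(hdr[1], "#Subpopulation")) 1L else 0L
  tab <- data.table::fread(path, skip = skip, sep = "\t")
  names(tab)[1] <- sub("^#", "", names(tab)[1])
  samp_cols <- names(tab)[grepl("\\.(0|1)$", names(tab))]
  samples <- unique(sub("\\.(0|1)$", "", samp_cols))
  p <- length(variant_positions)
  win <- vapply(variant_positions, function(pos) {
    w <- which(tab$spos <= pos & pos <= tab$epos)
    if (!length(w)) {
      stop_param("variant at position ", pos, " falls outside all ancestry windows")
    }
    w[1]
  }, integer(1))
  h1 <- t(vapply(samples, function(s) as.integer(tab[[paste0(s, ".0")]][win]),
                 integer(p)))
  h2 <- t(vapply(samples, function(s) as.integer(tab[[paste0(s, ".1")]][win]),
                 integer(p)))
  if (p == 1L) { h1 <- matrix(h1, ncol = 1); h2 <- matrix(h2, ncol = 1) }
  dimnames(h1) <- NULL; dimnames(h2) <- NULL
  la_panel(h1, h2)
}

#' Write result tables with a run manifest
#'
#' Each named element of `tables` is written as `<name>.tsv` (stable column
#' order, full precision) together with `manifest.json` recording the
#' parameters, master seed and package version; re-reading reproduces the
#' values bit-exactly.
#'
#' @param tables Named list of data.frames.
#' @param dir Output directory (created if missing).
#' @param params List of run parameters for the manifest.
#' @param master_seed Integer master seed.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, dir, params = list(), master_seed = NA) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stopifnot(is.list(tables), !is.null(names(tables)))
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    data.table::fwrite(tables[[nm]], path, sep = "\t")
    paths[nm] <- path
  }
  manifest <- list(parameters = params, master_seed = master_seed,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   artifact_version = as.character(utils::packageVersion("admixpgs")))
  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths["manifest"] <- man_path
  invisible(paths)
}
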