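#' Bundled candidate-gene panel table
#'
#' The curated candidate-gene NSV panel of the turbot study system: 22
#' genes with their chromosome, variant position, reference/alternate
#' alleles, amino-acid substitution notation and selection-criteria
#' annotations (DEG evidence for pathogen resistance, QTL associations for
#' growth and resistance, outlier markers within the gene or at < 500 kb,
#' and other-species evidence).
#'
#' @return Data frame with columns `gene`, `chrom`, `start`, `ref`, `alt`,
#'   `aa_substitution`, `criteria`.
#' @export
candidate_gene_table <- function() {
  path <- system.file("extdata", "candidate_genes.tsv", package = "nsvatlas")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Count candidate genes per selection-criterion tag
#'
#' Tokenizes the criteria annotations of [candidate_gene_table()] and counts
#' the genes carrying each tag (a gene is counted once per tag however often
#' the tag appears). Pathogen tags: ES (Enteromyxum scophthalmi), AS
#' (Aeromonas salmonicida), PD (Philasterides dicentrarchi); VHSV viral
#' haemorrhagic septicaemia virus.
#'
#' @param tags Tags to count.
#' @param table Candidate table (defaults to the bundled panel).
#' @return Named integer vector of gene counts.
#' @export
criteria_gene_counts <- function(tags = c("ES", "AS", "PD"),
                                 table = candidate_gene_table()) {
  token_sets <- lapply(table$criteria, function(s) {
    unique(strsplit(gsub("[(),;]", " ", s), "\\s+")[[1L]])
  })
  vapply(tags, function(tag) {
    sum(vapply(token_sets, function(tk) tag %in% tk, TRUE))
  }, 0L)
}

#' Per-locus allele-frequency profiles by population
#'
#' Frequency table behind allele-frequency-profile figures: one row per
#' (population, locus), populations in their fixed geographic order (the
#' order they appear in the genotype matrix, wild samples first, then
#' farms).
#'
#' @param x A `genotype_matrix`.
#' @param loci Locus ids (default all).
#' @return Data frame: `locus`, `pop`, `group`, `n`, `freq_ref`,
#'   `freq_alt`.
#' @export
render_frequency_profiles <- function(x, loci = x$loci$locus) {
  cts <- genotype_counts(x)
  j <- match(loci, x$loci$locus)
  if (anyNA(j)) stop("unknown locus id")
  out <- expand.grid(pop = cts$pops, locus = loci, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  idx <- cbind(match(out$pop, cts$pops), j[match(out$locus, loci)])
  n <- cts$n[idx]
  p_alt <- ifelse(n > 0, cts$nalt[idx] / (2 * n), NA_real_)
  out$group <- cts$group[match(out$pop, cts$pops)]
  out$n <- n
  out$freq_ref <- 1 - p_alt
  out$freq_alt <- p_alt
  out[, c("locus", "pop", "group", "n", "freq_ref", "freq_alt")]
}

#' Write the per-locus panel summary as TSV
#'
#' [locus_summary()] with the outlier-scan classifications merged in,
#' written with a provenance header.
#'
#' @param x A `genotype_matrix`.
#' @param path Output path.
#' @param scans Named list of `outlier_scan` results to merge (names used
#'   as column prefixes, e.g. `all`, `wild`, `hier`).
#' @param seed Seed recorded in the header.
#' @return The summary data.frame, invisibly.
#' @export
write_locus_summary <- function(x, path, scans = list(), seed = NA) {
  summ <- locus_summary(x)
  for (nm in names(scans)) {
    calls <- scans[[nm]]$calls
    m <- match(summ$locus, calls$locus)
    summ[[paste0("p_", nm)]] <- calls$p_upper[m]
    summ[[paste0("class_", nm)]] <- calls$classification[m]
    summ[[paste0("tier_", nm)]] <- calls$tier[m]
  }
  write_tsv_report(summ, path, seed = seed, config = list(loci = summ$locus))
  invisible(summ)
}
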