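# Independent oracles used across test files. These deliberately re-derive
# quantities by routes different from the package implementation.

# brute-force effect classification: translate the full mutated CDS and
# diff the protein sequences
oracle_classify <- function(gene, pos, ref, alt, genome) {
  chrom_seq <- genome[[gene$chrom]]
  stopifnot(substr(chrom_seq, pos + 1, pos + 1) == ref)
  mutated <- chrom_seq
  substr(mutated, pos + 1, pos + 1) <- alt
  splice <- function(seqs) {
    parts <- vapply(seq_len(nrow(gene$cds)), function(i) {
      s <- substr(seqs, gene$cds[i, "start"] + 1, gene$cds[i, "end"])
      if (gene$strand == "-") {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      } else s
    }, "")
    paste(parts, collapse = "")
  }
  cds_ref <- splice(chrom_seq)
  cds_alt <- splice(mutated)
  if (cds_ref == cds_alt) return(list(class = "noncoding", notation = NA))
  aa_ref <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(cds_ref), if.fuzzy.codon = "X",
    no.init.codon = TRUE)), "")[[1]]
  aa_alt <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(cds_alt), if.fuzzy.codon = "X",
    no.init.codon = TRUE)), "")[[1]]
  diff <- which(aa_ref != aa_alt)
  if (length(diff) == 0) {
    # protein unchanged: synonymous; recover the codon index from the DNA diff
    nt <- which(strsplit(cds_ref, "")[[1]] != strsplit(cds_alt, "")[[1]])
    i <- (nt - 1) %/% 3 + 1
    return(list(class = "synonymous",
                notation = paste0(aa_ref[i], i, aa_ref[i])))
  }
  i <- diff[1]
  cls <- if (i == 1 && aa_ref[1] == "M" &&
             substr(cds_alt, 1, 3) != "ATG") "start_lost"
  else if (aa_alt[i] == "*") "stop_gained"
  else if (aa_ref[i] == "*") "stop_lost"
  else "missense"
  list(class = cls, notation = paste0(aa_ref[i], i, aa_alt[i]))
}

# exact HWE p by direct enumeration of genotype configurations, weighting
# each by its count of ordered allele arrangements (not the closed form
# used by the implementation)
oracle_hwe_p <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  if (n == 0 || nA == 0 || nA == 2 * n) return(1)
  weight <- function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb)) * 2^h
  }
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  w <- vapply(hs, weight, 0)
  pr <- w / sum(w)
  p_obs <- pr[match(nAa, hs)]
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

# flat (population/individual/allele) method-of-moments nested ANOVA:
# independent transcription of the variance-component estimator
oracle_flat_anova <- function(n, nalt, nhet) {
  keep <- n > 0
  n <- n[keep]; nalt <- nalt[keep]; nhet <- nhet[keep]
  Np <- 2 * n; N <- sum(Np); nind <- sum(n); P <- length(n)
  ybar_p2 <- nalt^2 / Np
  ybar_t2 <- sum(nalt)^2 / N
  sum_yi2 <- (nalt - nhet) / 2 + nhet / 4
  ss_pops <- sum(ybar_p2) - ybar_t2
  ss_ind <- sum(2 * sum_yi2 - ybar_p2)
  ss_w <- 0.5 * sum(nhet)
  M <- rbind(c(N - sum(Np^2) / N, 2 * P - 2, P - 1),
             c(0, N - 2 * P, nind - P),
             c(0, 0, nind))
  sig <- solve(M, c(ss_pops, ss_ind, ss_w))
  list(a = sig[1], b = sig[2], c = sig[3], theta = sig[1] / sum(sig))
}

# small genotype_matrix builder from a dosage matrix
make_gm <- function(geno, pop, group = rep("wild", length(pop)),
                    loci = NULL) {
  geno <- as.matrix(geno)
  if (is.null(loci)) {
    loci <- data.frame(locus = sprintf("L%02d", seq_len(ncol(geno))),
                       chrom = "chr1", pos = seq_len(ncol(geno)) * 1000L,
                       ref = "A", alt = "G", stringsAsFactors = FALSE)
  }
  ind <- data.frame(id = sprintf("i%03d", seq_len(nrow(geno))),
                    pop = pop, group = group, stringsAsFactors = FALSE)
  genotype_matrix(loci, ind, geno)
}
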