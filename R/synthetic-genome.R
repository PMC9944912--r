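#' Generate a random annotated toy genome
#'
#' Builds random chromosomes carrying non-overlapping multi-exon
#' protein-coding genes on both strands. Every gene has an ATG start, a
#' stop codon, no internal stop, and CDS length divisible by 3 (unless
#' deliberately corrupted via `n_low_quality`, which appends a frame-breaking
#' base to emulate low-quality annotations). All generators are pure
#' functions of their configuration and seed.
#'
#' @param n_chrom Number of chromosomes.
#' @param n_genes Total number of genes (spread across chromosomes).
#' @param seed RNG seed.
#' @param codon_range Range of CDS length in codons (including start/stop).
#' @param exon_range Range of CDS segment counts per gene.
#' @param intron_range Range of intron lengths (bp).
#' @param gap Minimum gap between genes and to chromosome ends (bp).
#' @param n_low_quality Number of genes flagged as low-quality annotations.
#' @return List: `genome` (named character vector), `genes` (named list of
#'   [gene_model()]), `truth` (data.frame: gene_id, chrom, strand,
#'   n_codons, low_quality).
#' @export
gen_annotated_genome <- function(n_chrom = 2L, n_genes = 12L, seed = 1L,
                                 codon_range = c(40L, 120L),
                                 exon_range = c(1L, 3L),
                                 intron_range = c(50L, 200L),
                                 gap = 300L, n_low_quality = 0L) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    stops <- c("TAA", "TAG", "TGA")
    codons <- apply(expand.grid(bases, bases, bases), 1L, paste, collapse = "")
    sense <- setdiff(codons, c(stops, "ATG"))
    per_chrom <- diff(round(seq(0, n_genes, length.out = n_chrom + 1L)))
    genome <- character(0)
    genes <- list()
    truth <- list()
    gi <- 0L
    for (ci in seq_len(n_chrom)) {
      chrom <- paste0("chr", ci)
      seq_parts <- list(paste(sample(bases, gap, replace = TRUE),
                              collapse = ""))
      cursor <- gap
      for (k in seq_len(per_chrom[ci])) {
        gi <- gi + 1L
        gene_id <- sprintf("g%03d", gi)
        n_codons <- sample(codon_range[1L]:codon_range[2L], 1L)
        coding <- paste0("ATG",
                         paste(sample(sense, n_codons - 2L, replace = TRUE),
                               collapse = ""),
                         sample(stops, 1L))
        low_q <- gi <= n_low_quality
        if (low_q) {
          coding <- paste0(coding, sample(bases, 1L))  # break the frame
        }
        len <- nchar(coding)
        n_exon <- sample(exon_range[1L]:exon_range[2L], 1L)
        n_exon <- min(n_exon, len %/% 10L)
        cuts <- if (n_exon > 1L) {
          sort(sample(seq_len(len - 1L), n_exon - 1L))
        } else integer(0)
        seg_len <- diff(c(0L, cuts, len))
        strand <- sample(c("+", "-"), 1L)
        chunks <- substring(coding, c(1L, cuts + 1L), c(cuts, len))
        # on '-', transcription order runs from high to low genomic coords
        if (strand == "-") {
          chunks <- rev(vapply(chunks, revcomp, ""))
          seg_len <- rev(seg_len)
        }
        seg_start <- integer(n_exon)
        for (s in seq_len(n_exon)) {
          seg_start[s] <- cursor
          seq_parts[[length(seq_parts) + 1L]] <- chunks[s]
          cursor <- cursor + seg_len[s]
          if (s < n_exon) {
            ilen <- sample(intron_range[1L]:intron_range[2L], 1L)
            seq_parts[[length(seq_parts) + 1L]] <-
              paste(sample(bases, ilen, replace = TRUE), collapse = "")
            cursor <- cursor + ilen
          }
        }
        seq_parts[[length(seq_parts) + 1L]] <-
          paste(sample(bases, gap, replace = TRUE), collapse = "")
        cursor <- cursor + gap
        genes[[gene_id]] <- gene_model(
          gene_id, chrom, strand,
          cds = cbind(seg_start, seg_start + seg_len))
        truth[[gene_id]] <- data.frame(
          gene_id = gene_id, chrom = chrom, strand = strand,
          n_codons = n_codons, low_quality = low_q, stringsAsFactors = FALSE)
      }
      genome[chrom] <- paste(unlist(seq_parts), collapse = "")
    }
    list(genome = genome, genes = genes, truth = do.call(rbind, truth))
  })
}

# genomic positions (0-based) of the CDS in transcription order
cds_positions <- function(gene) {
  unlist(lapply(seq_len(nrow(gene$cds)), function(i) {
    s <- gene$cds[i, "start"]; e <- gene$cds[i, "end"]
    if (gene$strand == "+") s:(e - 1L) else (e - 1L):s
  }))
}

#' Spike variants of known effect into a toy genome
#'
#' Plants variants with exact generator-side truth: for coding classes the
#' truth effect and notation are computed directly from the affected codon
#' (independently of the annotation machinery under test). Planted variants
#' are spaced more than `spacing` bp apart so the flanking-cleanliness
#' criterion holds, except for deliberately planted flank-violating pairs.
#' Discovery-cohort genotypes are simulated for `n_ind` diploids with a
#' planted alternate-allele count per site (all-heterozygote configurations
#' for Hardy-Weinberg violations, singletons for low-MAF sites).
#'
#' @param sim A genome from [gen_annotated_genome()].
#' @param spec Named counts of planted classes: `missense`, `synonymous`,
#'   `stop_gained`, `triallelic`, `flank_pair` (pairs 50 bp apart),
#'   `noncoding`, `lowqual` (QUAL 20 missense), `hwe_violation`,
#'   `low_maf`.
#' @param seed RNG seed.
#' @param n_ind Discovery-cohort size (diploids).
#' @param spacing Minimum spacing between planted variants (bp).
#' @return List: `variants` (data.frame `chrom,pos,ref,alts,qual`),
#'   `gt` (site x individual genotype strings), `truth` (data.frame with
#'   planted class, notation, tag, alt-allele count `k_alt`).
#' @export
spike_variants <- function(sim,
                           spec = list(missense = 10L, synonymous = 5L,
                                       stop_gained = 2L, triallelic = 1L,
                                       flank_pair = 1L, noncoding = 2L,
                                       lowqual = 0L, hwe_violation = 0L,
                                       low_maf = 0L),
                           seed = 1L, n_ind = 10L, spacing = 201L) {
  with_seed(seed, {
    defaults <- list(missense = 0L, synonymous = 0L, stop_gained = 0L,
                     triallelic = 0L, flank_pair = 0L, noncoding = 0L,
                     lowqual = 0L, hwe_violation = 0L, low_maf = 0L)
    spec <- utils::modifyList(defaults, as.list(spec))
    genes <- sim$genes[!vapply(sim$genes, function(g) g$low_quality, TRUE)]
    used <- list()  # per chrom: planted positions
    ok_pos <- function(chrom, pos, min_d = spacing) {
      u <- used[[chrom]]
      is.null(u) || all(abs(u - pos) >= min_d)
    }
    note <- function(chrom, pos) used[[chrom]] <<- c(used[[chrom]], pos)
    rows <- list()
    bases <- c("A", "C", "G", "T")

    add_row <- function(chrom, pos, ref, alts, qual, gene_id, class,
                        notation, tag, k_alt) {
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = chrom, pos = pos, ref = ref, alts = alts, qual = qual,
        gene_id = gene_id, class = class, notation = notation, tag = tag,
        k_alt = k_alt, stringsAsFactors = FALSE)
    }

    # pick a coding site whose substitution realizes `target_class`
    plant_coding <- function(target_class, qual = 60, tag = target_class,
                             k_alt = NULL, min_d = spacing) {
      for (try in seq_len(2000L)) {
        g <- genes[[sample(length(genes), 1L)]]
        cds <- spliced_cds(g, sim$genome)
        n_codons <- nchar(cds) %/% 3L
        codon_i <- sample(seq(2L, n_codons - 1L), 1L)  # skip start & stop
        within <- sample(0:2, 1L)
        off <- (codon_i - 1L) * 3L + within
        ref_codon <- substr(cds, (codon_i - 1L) * 3L + 1L, (codon_i - 1L) * 3L + 3L)
        coding_ref <- substr(ref_codon, within + 1L, within + 1L)
        alts_ok <- character(0)
        for (b in setdiff(bases, coding_ref)) {
          alt_codon <- ref_codon
          substr(alt_codon, within + 1L, within + 1L) <- b
          ref_aa <- translate_codon(ref_codon)
          alt_aa <- translate_codon(alt_codon)
          cls <- if (ref_aa == alt_aa) "synonymous"
          else if (alt_aa == "*") "stop_gained"
          else if (ref_aa == "*") "stop_lost"
          else "missense"
          if (cls == target_class) alts_ok <- c(alts_ok, b)
        }
        if (length(alts_ok) == 0L) next
        gpos <- cds_positions(g)[off + 1L]
        if (!ok_pos(g$chrom, gpos, min_d)) next
        coding_alt <- sample(alts_ok, 1L)
        ref_b <- if (g$strand == "-") comp_base(coding_ref) else coding_ref
        alt_b <- if (g$strand == "-") comp_base(coding_alt) else coding_alt
        alt_codon <- ref_codon
        substr(alt_codon, within + 1L, within + 1L) <- coding_alt
        notation <- paste0(translate_codon(ref_codon), codon_i,
                           translate_codon(alt_codon))
        note(g$chrom, gpos)
        if (is.null(k_alt)) k_alt <- sample(2:10, 1L)
        add_row(g$chrom, gpos, ref_b, alt_b, qual, g$gene_id,
                target_class, notation, tag, k_alt)
        return(invisible(TRUE))
      }
      stop("could not place a ", target_class, " variant")
    }

    for (i in seq_len(spec$missense)) plant_coding("missense")
    for (i in seq_len(spec$synonymous)) plant_coding("synonymous")
    for (i in seq_len(spec$stop_gained)) plant_coding("stop_gained")
    for (i in seq_len(spec$lowqual)) {
      plant_coding("missense", qual = 20, tag = "lowqual")
    }
    for (i in seq_len(spec$hwe_violation)) {
      plant_coding("missense", tag = "hwe_violation", k_alt = n_ind)
    }
    for (i in seq_len(spec$low_maf)) {
      plant_coding("missense", tag = "low_maf", k_alt = 1L)
    }
    for (i in seq_len(spec$triallelic)) {
      plant_coding("missense", tag = "triallelic")
      r <- rows[[length(rows)]]
      second <- sample(setdiff(bases, c(r$ref, r$alts)), 1L)
      rows[[length(rows)]]$alts <- paste(r$alts, second, sep = ",")
    }
    for (i in seq_len(spec$flank_pair)) {
      plant_coding("missense", tag = "flank_violation")
      r <- rows[[length(rows)]]
      # companion variant 50 bp away (any effect) spoiling the flank
      pos2 <- r$pos + 50L
      ref2 <- substr(sim$genome[[r$chrom]], pos2 + 1L, pos2 + 1L)
      note(r$chrom, pos2)
      add_row(r$chrom, pos2, ref2, sample(setdiff(bases, ref2), 1L), 60,
              NA_character_, "companion", NA_character_, "flank_companion",
              sample(2:10, 1L))
    }
    for (i in seq_len(spec$noncoding)) {
      for (try in seq_len(2000L)) {
        chrom <- sample(names(sim$genome), 1L)
        pos <- sample(nchar(sim$genome[[chrom]]), 1L) - 1L
        in_gene <- any(vapply(sim$genes, function(g) {
          sp <- gene_span(g)
          g$chrom == chrom && pos >= sp[1L] && pos < sp[2L]
        }, TRUE))
        if (in_gene || !ok_pos(chrom, pos)) next
        ref <- substr(sim$genome[[chrom]], pos + 1L, pos + 1L)
        note(chrom, pos)
        add_row(chrom, pos, ref, sample(setdiff(bases, ref), 1L), 60,
                NA_character_, "noncoding", NA_character_, "noncoding",
                sample(2:10, 1L))
        break
      }
    }

    truth <- do.call(rbind, rows)
    ord <- order(truth$chrom, truth$pos)
    truth <- truth[ord, , drop = FALSE]
    rownames(truth) <- NULL
    # discovery genotypes realizing the planted alt-allele counts
    gt <- matrix(NA_character_, nrow(truth), n_ind,
                 dimnames = list(NULL, sprintf("ind%02d", seq_len(n_ind))))
    for (i in seq_len(nrow(truth))) {
      k <- truth$k_alt[i]
      d <- integer(n_ind)
      if (truth$tag[i] == "hwe_violation") {
        d[] <- 1L  # every individual heterozygous
      } else {
        # random pairing of allele copies: Hardy-Weinberg-consistent draw
        copies <- sample(rep(c(1L, 0L), c(k, 2L * n_ind - k)))
        d <- copies[seq(1L, 2L * n_ind, by = 2L)] +
          copies[seq(2L, 2L * n_ind, by = 2L)]
      }
      gt[i, d == 0L] <- "0/0"
      gt[i, d == 1L] <- "0/1"
      gt[i, d == 2L] <- "1/1"
    }
    variants <- truth[, c("chrom", "pos", "ref", "alts", "qual")]
    list(variants = variants, gt = gt, truth = truth)
  })
}

#' Discovery-cohort genotype matrix from spiked variants
#'
#' Converts the `gt`/`truth` output of [spike_variants()] into a
#' [genotype_matrix()] keyed by site, for use as the discovery cohort in
#' [run_cascade()]. Tri-allelic sites use the first alternate allele.
#'
#' @param spiked Output of [spike_variants()].
#' @return A `genotype_matrix`.
#' @export
spiked_genotype_matrix <- function(spiked) {
  tr <- spiked$truth
  alt1 <- vapply(strsplit(tr$alts, ",", fixed = TRUE), `[`, "", 1L)
  loci <- data.frame(locus = site_key(tr$chrom, tr$pos), chrom = tr$chrom,
                     pos = tr$pos, ref = tr$ref, alt = alt1,
                     stringsAsFactors = FALSE)
  n_ind <- ncol(spiked$gt)
  dosage <- t(matrix(c(`0/0` = 0L, `0/1` = 1L, `1/1` = 2L)[spiked$gt],
                     nrow(tr), n_ind))
  genotype_matrix(loci,
                  data.frame(id = colnames(spiked$gt),
                             pop = "discovery", group = "wild",
                             stringsAsFactors = FALSE),
                  dosage)
}
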