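#' Map a genomic position to a CDS offset
#'
#' Walks the CDS segments of a gene model in transcription order and returns
#' the 0-based offset of a genomic position within the spliced coding
#' sequence, measured on the coding strand (for `-` strand genes, genomic
#' 3'->5' is coding 5'->3'). Returns `NA` when the position falls outside
#' every CDS segment.
#'
#' @param gene A [gene_model()].
#' @param gpos 0-based genomic position.
#' @return Integer CDS offset (0-based) or `NA`.
#' @export
map_genomic_to_cds <- function(gene, gpos) {
  off <- 0L
  for (i in seq_len(nrow(gene$cds))) {
    s <- gene$cds[i, "start"]; e <- gene$cds[i, "end"]
    if (gpos >= s && gpos < e) {
      return(unname(off + if (gene$strand == "+") gpos - s else e - 1L - gpos))
    }
    off <- off + (e - s)
  }
  NA_integer_
}

# spliced CDS on the coding strand
spliced_cds <- function(gene, genome) {
  chrom_seq <- genome[[gene$chrom]]
  if (is.null(chrom_seq)) stop("chromosome ", gene$chrom, " not in genome")
  parts <- vapply(seq_len(nrow(gene$cds)), function(i) {
    s <- substr(chrom_seq, gene$cds[i, "start"] + 1L, gene$cds[i, "end"])
    if (gene$strand == "-") revcomp(s) else s
  }, "")
  paste(parts, collapse = "")
}

#' Reverse-complement a DNA string
#'
#' @param s DNA string over `A,C,G,T,N`.
#' @return Reverse complement.
#' @export
revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[[b]]

translate_codon <- function(codon) {
  if (grepl("N", codon, fixed = TRUE)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify the coding effect of a SNV against one gene model
#'
#' Extracts the affected codon from the spliced CDS, substitutes the
#' alternate base (reverse-complemented for `-` strand genes), translates
#' both codons with the standard nuclear genetic code and assigns an effect
#' class: `synonymous`, `missense`, `stop_gained`, `stop_lost`, `start_lost`
#' (codon 1 ATG lost), `noncoding` (outside the CDS) or `unresolvable`
#' (ambiguous `N` in the reference codon). Amino-acid substitution notation
#' follows the `"A44T"` convention (reference residue, 1-based codon index,
#' alternate residue).
#'
#' @param gene A [gene_model()].
#' @param chrom,pos,ref,alt Variant coordinates (0-based `pos`) and alleles.
#' @param genome Named character vector of chromosome sequences.
#' @return One-row data.frame: `chrom`, `pos`, `ref`, `alt`, `gene_id`,
#'   `effect_class`, `aa_pos`, `ref_aa`, `alt_aa`, `notation`, `transition`.
#' @export
classify_variant <- function(gene, chrom, pos, ref, alt, genome) {
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    gene_id = gene$gene_id, effect_class = "noncoding",
                    aa_pos = NA_integer_, ref_aa = NA_character_,
                    alt_aa = NA_character_, notation = NA_character_,
                    transition = is_transition(ref, alt),
                    stringsAsFactors = FALSE)
  if (chrom != gene$chrom) return(out)
  genome_base <- substr(genome[[chrom]], pos + 1L, pos + 1L)
  if (genome_base != ref) {
    stop("reference_mismatch: variant ", chrom, ":", pos + 1L, " ref ", ref,
         " but genome has ", genome_base)
  }
  off <- map_genomic_to_cds(gene, pos)
  if (is.na(off)) return(out)
  cds <- spliced_cds(gene, genome)
  codon_i <- off %/% 3L
  within <- off %% 3L
  ref_codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  alt_base <- if (gene$strand == "-") comp_base(alt) else alt
  if (substr(ref_codon, within + 1L, within + 1L) !=
      (if (gene$strand == "-") comp_base(ref) else ref)) {
    stop("internal error: CDS extraction inconsistent with genome")
  }
  alt_codon <- ref_codon
  substr(alt_codon, within + 1L, within + 1L) <- alt_base
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  if (is.na(ref_aa) || is.na(alt_aa)) {
    out$effect_class <- "unresolvable"
    return(out)
  }
  aa_pos <- codon_i + 1L
  cls <-
    if (aa_pos == 1L && ref_codon == "ATG" && alt_codon != "ATG") "start_lost"
    else if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gained"
    else if (ref_aa == "*") "stop_lost"
    else "missense"
  out$effect_class <- cls
  out$aa_pos <- aa_pos
  out$ref_aa <- ref_aa
  out$alt_aa <- alt_aa
  out$notation <- paste0(ref_aa, aa_pos, alt_aa)
  out
}

#' Annotate a variant set against a collection of gene models
#'
#' Emits one effect call per (variant, alternate allele, overlapping gene).
#' Variants overlapping no CDS-bearing gene are classified `noncoding`
#' against a `NA` gene id. Genes flagged `low_quality` (CDS length not a
#' multiple of 3) are excluded from annotation and their skipped-call count
#' is recorded in the `n_lowqual_gene_calls` attribute.
#'
#' @param vs A `variant_set` from [read_vcf()], or its `variants` data.frame.
#' @param genes Named list of [gene_model()] objects.
#' @param genome Named character vector of chromosome sequences.
#' @return Data frame of effect calls (columns as in [classify_variant()]
#'   plus `qual` and `n_alt` when available).
#' @export
classify_variants <- function(vs, genes, genome) {
  variants <- if (inherits(vs, "variant_set")) vs$variants else vs
  usable <- genes[!vapply(genes, function(g) g$low_quality, TRUE)]
  spans <- if (length(usable) > 0L) {
    data.frame(gene = names(usable),
               chrom = vapply(usable, function(g) g$chrom, ""),
               start = vapply(usable, function(g) gene_span(g)[[1L]], 0L),
               end = vapply(usable, function(g) gene_span(g)[[2L]], 0L),
               stringsAsFactors = FALSE)
  } else data.frame(gene = character(0), chrom = character(0),
                    start = integer(0), end = integer(0))
  n_lowq <- 0L
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(variants))) {
    alts <- strsplit(variants$alts[i], ",", fixed = TRUE)[[1L]]
    hit <- spans$gene[spans$chrom == variants$chrom[i] &
                        spans$start <= variants$pos[i] &
                        spans$end > variants$pos[i]]
    # count calls that would have landed on a low-quality model
    for (g in genes[vapply(genes, function(g) g$low_quality &&
                             g$chrom == variants$chrom[i], TRUE)]) {
      sp <- gene_span(g)
      if (variants$pos[i] >= sp[1L] && variants$pos[i] < sp[2L]) {
        n_lowq <- n_lowq + length(alts)
      }
    }
    for (alt in alts) {
      calls <- if (length(hit) == 0L) {
        list(data.frame(chrom = variants$chrom[i], pos = variants$pos[i],
                        ref = variants$ref[i], alt = alt,
                        gene_id = NA_character_, effect_class = "noncoding",
                        aa_pos = NA_integer_, ref_aa = NA_character_,
                        alt_aa = NA_character_, notation = NA_character_,
                        transition = is_transition(variants$ref[i], alt),
                        stringsAsFactors = FALSE))
      } else {
        lapply(hit, function(g) {
          classify_variant(genes[[g]], variants$chrom[i], variants$pos[i],
                           variants$ref[i], alt, genome)
        })
      }
      for (cl in calls) {
        cl$qual <- if ("qual" %in% names(variants)) variants$qual[i] else NA_real_
        cl$n_alt <- length(alts)
        rows[[length(rows) + 1L]] <- cl
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene_id = character(0), effect_class = character(0),
                      aa_pos = integer(0), ref_aa = character(0),
                      alt_aa = character(0), notation = character(0),
                      transition = logical(0), qual = numeric(0),
                      n_alt = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_lowqual_gene_calls") <- n_lowq
  out
}

#' Is a base substitution a transition?
#'
#' Transitions are purine-purine or pyrimidine-pyrimidine changes, i.e. the
#' unordered pairs A/G and C/T; all other substitutions are transversions.
#'
#' @param ref,alt Single bases, `ref != alt`.
#' @return Logical.
#' @export
is_transition <- function(ref, alt) {
  stopifnot(all(ref %in% c("A", "C", "G", "T")),
            all(alt %in% c("A", "C", "G", "T")), all(ref != alt))
  purine <- c("A", "G")
  (ref %in% purine) == (alt %in% purine)
}

#' Transition/transversion summary of a set of SNVs
#'
#' Tallies biallelic substitutions by unordered base pair; transitions are
#' the A/G and C/T classes.
#'
#' @param variants Data frame with `ref` and `alt` columns (single bases).
#' @return List with `pairs` (named counts for A/G, C/T, A/C, A/T, C/G,
#'   G/T), `ts`, `tv` and `total`.
#' @export
tstv_summary <- function(variants) {
  classes <- c("A/G", "C/T", "A/C", "A/T", "C/G", "G/T")
  counts <- stats::setNames(integer(6L), classes)
  if (nrow(variants) > 0L) {
    key <- vapply(seq_len(nrow(variants)), function(i) {
      paste(sort(c(variants$ref[i], variants$alt[i])), collapse = "/")
    }, "")
    tab <- table(factor(key, levels = classes))
    counts[names(tab)] <- as.integer(tab)
  }
  list(pairs = counts, ts = unname(counts["A/G"] + counts["C/T"]),
       tv = unname(sum(counts[c("A/C", "A/T", "C/G", "G/T")])),
       total = sum(counts))
}
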