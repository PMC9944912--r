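#' Filter-cascade configuration
#'
#' Thresholds of the NSV prioritisation cascade. Defaults follow the study
#' design this package supports: site quality >= 30; genes carrying 3 or
#' more NSVs discarded as putative pseudogenes; +/- 100 bp of variation-free
#' flank required for assay primer annealing; Hardy-Weinberg exclusion at
#' P < 0.01; minimum MAF 0.10 in the discovery cohort; candidate-marker
#' proximity < 500 kb; stop-gain (truncating) variants dropped.
#'
#' @param min_qual Minimum Phred site quality.
#' @param max_nsv_per_gene Maximum NSVs per gene before the gene is dropped
#'   as a putative pseudogene (genes with more are discarded entirely).
#' @param flank_window_bp Half-width of the flanking window that must be
#'   free of other variation (inclusive: a variant at exactly this distance
#'   fails).
#' @param hwe_alpha Hardy-Weinberg exclusion level.
#' @param maf_min Minimum minor allele frequency (inclusive).
#' @param proximity_bp Candidate-marker linking distance (strict `<`).
#' @param drop_stop_gained Drop stop-gained calls (default `TRUE`).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_qual = 30, max_nsv_per_gene = 2L,
                          flank_window_bp = 100L, hwe_alpha = 0.01,
                          maf_min = 0.10, proximity_bp = 500000L,
                          drop_stop_gained = TRUE) {
  stopifnot(min_qual > 0, max_nsv_per_gene > 0, flank_window_bp > 0,
            hwe_alpha > 0, maf_min > 0, maf_min <= 0.5, proximity_bp > 0)
  structure(list(min_qual = min_qual, max_nsv_per_gene = max_nsv_per_gene,
                 flank_window_bp = flank_window_bp, hwe_alpha = hwe_alpha,
                 maf_min = maf_min, proximity_bp = proximity_bp,
                 drop_stop_gained = drop_stop_gained),
            class = "filter_config")
}

nsv_classes <- c("missense", "stop_gained", "stop_lost", "start_lost")

#' Count NSVs per gene
#'
#' Counts missense calls per gene (the non-synonymous-variant definition
#' used by the pseudogene heuristic). Genes with no missense calls are
#' absent from the result.
#'
#' @param calls Effect-call data.frame (from [classify_variants()]).
#' @return Named integer vector, gene id -> missense count.
#' @export
count_nsv_per_gene <- function(calls) {
  mis <- calls[calls$effect_class == "missense" & !is.na(calls$gene_id), ]
  if (nrow(mis) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(mis$gene_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Pseudogene filter
#'
#' Conservative pseudogene heuristic: genes carrying 3 or more NSVs
#' (missense calls; threshold `max_nsv_per_gene + 1`) are discarded — all of
#' a dropped gene's calls are removed together.
#'
#' @param calls Effect-call data.frame.
#' @param config A [filter_config()].
#' @return Logical vector: `TRUE` where the call survives.
#' @export
pseudogene_filter <- function(calls, config = filter_config()) {
  counts <- count_nsv_per_gene(calls)
  dropped <- names(counts)[counts > config$max_nsv_per_gene]
  !(calls$gene_id %in% dropped)
}

#' Nonsense filter
#'
#' Removes stop-gained calls (truncated proteins). `stop_lost` and
#' `start_lost` calls are retained but flagged via the `nonsense_like`
#' attribute on the result.
#'
#' @inheritParams pseudogene_filter
#' @return Logical keep vector with attribute `nonsense_like` (logical
#'   flag per call).
#' @export
nonsense_filter <- function(calls, config = filter_config()) {
  keep <- !(config$drop_stop_gained & calls$effect_class == "stop_gained")
  attr(keep, "nonsense_like") <-
    calls$effect_class %in% c("stop_lost", "start_lost")
  keep
}

#' Tri-allelic filter
#'
#' Removes calls at sites with two or more alternate alleles.
#'
#' @param calls Effect-call data.frame with an `n_alt` column.
#' @return Logical keep vector.
#' @export
triallelic_filter <- function(calls) calls$n_alt < 2L

#' Flanking-region cleanliness filter
#'
#' A call fails when any other variant (of any type, from the full
#' pre-cascade variant set, including indels and synonymous sites) lies
#' within `window` bp on the same chromosome — such variation compromises
#' genotyping-primer annealing. The window is inclusive: a neighbour at
#' exactly `window` bp fails, at `window + 1` passes.
#'
#' @param calls Effect-call data.frame.
#' @param all_variants Data frame of all pre-filter variant positions
#'   (`chrom`, `pos`).
#' @param window Half-window in bp.
#' @return Logical keep vector.
#' @export
flanking_clear_filter <- function(calls, all_variants, window = 100L) {
  vapply(seq_len(nrow(calls)), function(i) {
    same <- all_variants$chrom == calls$chrom[i]
    d <- abs(all_variants$pos[same] - calls$pos[i])
    !any(d > 0L & d <= window)
  }, TRUE)
}

#' Hardy-Weinberg filter
#'
#' Removes calls whose site deviates from Hardy-Weinberg proportions in the
#' discovery cohort at `p < alpha` (exact test, [hwe_exact_p()]). Sites
#' without genotype data are kept.
#'
#' @param calls Effect-call data.frame.
#' @param genotypes `genotype_matrix` of the discovery cohort; locus ids
#'   `chrom:pos1` (1-based) are matched against the calls.
#' @param alpha Exclusion level.
#' @return Logical keep vector.
#' @export
hwe_filter <- function(calls, genotypes, alpha = 0.01) {
  p <- site_hwe_p(calls, genotypes)
  is.na(p) | p >= alpha
}

site_key <- function(chrom, pos) paste0(chrom, ":", pos + 1L)

site_hwe_p <- function(calls, genotypes) {
  keys <- site_key(calls$chrom, calls$pos)
  lkeys <- site_key(genotypes$loci$chrom, genotypes$loci$pos)
  j <- match(keys, lkeys)
  vapply(seq_along(j), function(i) {
    if (is.na(j[i])) return(NA_real_)
    g <- genotypes$geno[, j[i]]
    g <- g[!is.na(g)]
    hwe_exact_p(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, 0)
}

site_maf <- function(calls, genotypes) {
  keys <- site_key(calls$chrom, calls$pos)
  lkeys <- site_key(genotypes$loci$chrom, genotypes$loci$pos)
  j <- match(keys, lkeys)
  vapply(seq_along(j), function(i) {
    if (is.na(j[i])) return(NA_real_)
    g <- genotypes$geno[, j[i]]
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(NA_real_)
    p <- sum(g) / (2 * length(g))
    min(p, 1 - p)
  }, 0)
}

#' Deleterious-substitution filter
#'
#' Removes calls whose (gene, amino-acid substitution) matches a row with a
#' `deleterious` verdict in an externally scored substitution table (scores
#' are consumed, not computed). Unmatched calls are untouched.
#'
#' @param calls Effect-call data.frame.
#' @param table Data frame with columns `gene_id`, `notation`, `verdict`
#'   (`"deleterious"` or `"neutral"`); may be empty or `NULL`.
#' @return Logical keep vector.
#' @export
deleterious_filter <- function(calls, table) {
  if (is.null(table) || nrow(table) == 0L) return(rep(TRUE, nrow(calls)))
  stopifnot(all(grepl("^[A-Z*][0-9]+[A-Z*]$", table$notation)))
  del <- table[table$verdict == "deleterious", ]
  !(paste(calls$gene_id, calls$notation) %in%
      paste(del$gene_id, del$notation))
}

#' Link genes to annotated markers by proximity
#'
#' A marker is linked `within_gene` when its position falls inside the gene
#' span, and `lt_500kb` (more generally, closer than `proximity_bp`) when
#' the minimum distance from the marker to the gene span is strictly below
#' the threshold (a marker at exactly `proximity_bp` is not linked).
#'
#' @param genes Named list of [gene_model()] objects (or a data.frame with
#'   `gene_id`, `chrom`, `start`, `end`).
#' @param markers Data frame with `marker_id`, `chrom`, `pos` (0-based) and
#'   `categories` (semicolon-separated tags).
#' @param proximity_bp Linking distance (strict `<`).
#' @return Data frame of links: `gene_id`, `marker_id`, `distance_bp`,
#'   `relation`, `categories`.
#' @export
proximity_link <- function(genes, markers, proximity_bp = 500000L) {
  spans <- if (is.data.frame(genes)) genes else {
    data.frame(gene_id = vapply(genes, function(g) g$gene_id, ""),
               chrom = vapply(genes, function(g) g$chrom, ""),
               start = vapply(genes, function(g) gene_span(g)[[1L]], 0L),
               end = vapply(genes, function(g) gene_span(g)[[2L]], 0L),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(spans))) {
    same <- which(markers$chrom == spans$chrom[i])
    for (k in same) {
      pos <- markers$pos[k]
      d <- if (pos >= spans$start[i] && pos < spans$end[i]) 0L
      else min(abs(pos - spans$start[i]), abs(pos - (spans$end[i] - 1L)))
      if (d == 0L || d < proximity_bp) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = spans$gene_id[i], marker_id = markers$marker_id[k],
          distance_bp = d,
          relation = if (d == 0L) "within_gene" else "lt_500kb",
          categories = markers$categories[k], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(0), marker_id = character(0),
                      distance_bp = integer(0), relation = character(0),
                      categories = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Per-gene MAF maximisation
#'
#' Final panel-selection step: among a gene's surviving calls with discovery
#' MAF at or above `maf_min`, keep the call with the highest MAF; ties are
#' broken by smallest genomic position. Calls below the MAF floor (or
#' without genotype data) are dropped.
#'
#' @param calls Effect-call data.frame.
#' @param genotypes Discovery-cohort `genotype_matrix`.
#' @param maf_min MAF floor (inclusive).
#' @return Logical keep vector.
#' @export
maf_top_per_gene <- function(calls, genotypes, maf_min = 0.10) {
  maf <- site_maf(calls, genotypes)
  eligible <- !is.na(maf) & maf >= maf_min - 1e-12
  keep <- rep(FALSE, nrow(calls))
  for (g in unique(calls$gene_id[eligible])) {
    idx <- which(eligible & calls$gene_id == g)
    best <- idx[order(-maf[idx], calls$pos[idx])][1L]
    keep[best] <- TRUE
  }
  keep
}

#' Run the full NSV filter cascade
#'
#' Applies, in order: NSV selection (missense/nonsense classes only), site
#' quality, pseudogene heuristic, nonsense removal, tri-allelic exclusion,
#' flanking-region cleanliness, Hardy-Weinberg screening, deleterious
#' exclusion, candidate-gene targeting (a gene survives if any marker lies
#' within it or links at < `proximity_bp`), and per-gene MAF maximisation.
#' Every removed call receives exactly one first-failure reason code, and
#' the ledger records `count_in`/`count_out`/`drop_pct` (one decimal,
#' relative to the immediately previous step) for every step.
#'
#' @param calls Annotated effect calls ([classify_variants()] output).
#' @param genotypes Discovery-cohort `genotype_matrix` (sites keyed by
#'   chrom:pos).
#' @param markers Marker-annotation data.frame (see [proximity_link()]);
#'   `NULL` skips candidate targeting.
#' @param deleterious Deleterious-substitution table (see
#'   [deleterious_filter()]); `NULL` skips that step.
#' @param all_variants Full pre-cascade variant set for the flanking check
#'   (defaults to the distinct sites of `calls`).
#' @param config A [filter_config()].
#' @return List of class `cascade_result`: `panel` (surviving calls),
#'   `ledger` (data.frame of steps), `removed` (calls with `reason`),
#'   `links` (candidate links used).
#' @export
run_cascade <- function(calls, genotypes = NULL, markers = NULL,
                        deleterious = NULL, all_variants = NULL,
                        config = filter_config()) {
  if (is.null(all_variants)) {
    all_variants <- unique(calls[, c("chrom", "pos")])
  }
  cur <- calls
  cur$.reason <- NA_character_
  ledger <- list()
  removed <- list()
  apply_step <- function(name, keep) {
    n_in <- nrow(cur)
    drop <- cur[!keep, , drop = FALSE]
    if (nrow(drop) > 0L) {
      drop$.reason <- name
      removed[[length(removed) + 1L]] <<- drop
    }
    cur <<- cur[keep, , drop = FALSE]
    n_out <- nrow(cur)
    ledger[[length(ledger) + 1L]] <<- data.frame(
      step = name, count_in = n_in, count_out = n_out,
      drop_pct = if (n_in > 0) round(100 * (n_in - n_out) / n_in, 1) else 0,
      stringsAsFactors = FALSE)
  }

  apply_step("nsv", cur$effect_class %in% nsv_classes)
  apply_step("qual", !is.na(cur$qual) & cur$qual >= config$min_qual)
  apply_step("pseudogene", pseudogene_filter(cur, config))
  apply_step("nonsense", nonsense_filter(cur, config))
  apply_step("triallelic", triallelic_filter(cur))
  apply_step("flanking",
             flanking_clear_filter(cur, all_variants, config$flank_window_bp))
  if (!is.null(genotypes)) {
    apply_step("hwe", hwe_filter(cur, genotypes, config$hwe_alpha))
  }
  if (!is.null(deleterious)) {
    apply_step("deleterious", deleterious_filter(cur, deleterious))
  }
  links <- NULL
  if (!is.null(markers)) {
    spans <- unique(cur[!is.na(cur$gene_id), c("gene_id", "chrom")])
    gene_bounds <- do.call(rbind, lapply(seq_len(nrow(spans)), function(i) {
      rows <- cur$gene_id == spans$gene_id[i] & !is.na(cur$gene_id)
      data.frame(gene_id = spans$gene_id[i], chrom = spans$chrom[i],
                 start = min(cur$pos[rows]), end = max(cur$pos[rows]) + 1L,
                 stringsAsFactors = FALSE)
    }))
    links <- proximity_link(gene_bounds, markers, config$proximity_bp)
    apply_step("candidate", cur$gene_id %in% links$gene_id)
  }
  if (!is.null(genotypes)) {
    apply_step("maf_top", maf_top_per_gene(cur, genotypes, config$maf_min))
  }

  removed <- if (length(removed) > 0L) do.call(rbind, removed) else
    cur[0L, , drop = FALSE]
  names(removed)[names(removed) == ".reason"] <- "reason"
  cur$.reason <- NULL
  structure(list(panel = cur, ledger = do.call(rbind, ledger),
                 removed = removed, links = links, config = config),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("NSV filter cascade\n")
  cat(format_ledger(x$ledger), sep = "\n")
  invisible(x)
}

#' Render a filter ledger as a text funnel
#'
#' @param ledger Ledger data.frame from [run_cascade()].
#' @return Character vector of lines.
#' @export
format_ledger <- function(ledger) {
  c(sprintf("  %-12s %7s -> %7s  (%5.1f%% drop)", ledger$step,
            ledger$count_in, ledger$count_out, ledger$drop_pct),
    sprintf("  final panel: %d call(s)", ledger$count_out[nrow(ledger)]))
}

#' Gene-level spans of gene models when full models are available
#'
#' Candidate-gene proximity normally uses true gene spans; [run_cascade()]
#' falls back to call-derived spans when models are not supplied. This
#' helper builds the span table from gene models for callers that have
#' them.
#'
#' @param genes Named list of [gene_model()] objects.
#' @return Data frame `gene_id`, `chrom`, `start`, `end` (0-based half-open).
#' @export
gene_spans <- function(genes) {
  data.frame(gene_id = vapply(genes, function(g) g$gene_id, ""),
             chrom = vapply(genes, function(g) g$chrom, ""),
             start = vapply(genes, function(g) gene_span(g)[[1L]], 0L),
             end = vapply(genes, function(g) gene_span(g)[[2L]], 0L),
             stringsAsFactors = FALSE)
}
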