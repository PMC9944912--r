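#' Read a FASTA file into a named vector of uppercase DNA sequences
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that enforces the
#' package conventions: sequence ids must be unique and non-empty, sequences
#' are uppercased, input order is preserved.
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return Named character vector; names are sequence ids, values uppercase
#'   DNA strings over `A,C,G,T,N`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no sequences")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA file contains an empty sequence id")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a gene model
#'
#' A gene model is a single-transcript CDS description. CDS segments use the
#' package-internal 0-based half-open convention and are stored in
#' transcription order: ascending genomic coordinates on the `+` strand,
#' descending on `-`. Models whose total CDS length is not a multiple of 3
#' are flagged `low_quality` rather than rejected; downstream annotation
#' excludes them as low-quality annotations.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome/contig name.
#' @param strand `"+"` or `"-"`.
#' @param cds Two-column matrix (`start`, `end`), 0-based half-open, one row
#'   per CDS segment, any order (sorted internally).
#' @param name Optional gene symbol (defaults to `gene_id`).
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, cds, name = gene_id) {
  stopifnot(is.character(gene_id), nzchar(gene_id), strand %in% c("+", "-"))
  cds <- matrix(as.integer(cds), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  if (any(cds[, "end"] <= cds[, "start"])) {
    stop("gene ", gene_id, ": CDS segment with end <= start")
  }
  ord <- order(cds[, "start"])
  cds <- cds[ord, , drop = FALSE]
  if (nrow(cds) > 1L &&
      any(cds[-1L, "start"] < cds[-nrow(cds), "end"])) {
    stop("gene ", gene_id, ": overlapping CDS segments")
  }
  if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
  len <- sum(cds[, "end"] - cds[, "start"])
  structure(
    list(gene_id = gene_id, name = name, chrom = chrom, strand = strand,
         cds = cds, cds_length = len, low_quality = (len %% 3L) != 0L),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s  %d CDS segment(s), %d bp%s\n",
              x$gene_id, x$name, x$chrom, x$strand, nrow(x$cds),
              x$cds_length, if (x$low_quality) " [low_quality]" else ""))
  invisible(x)
}

#' Genomic span of a gene model
#'
#' @param gene A `gene_model`.
#' @return Integer `c(start, end)`, 0-based half-open, covering all CDS.
#' @export
gene_span <- function(gene) {
  c(start = min(gene$cds[, "start"]), end = max(gene$cds[, "end"]))
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`/`mRNA`/`CDS` rows of a GFF3 file (1-based inclusive
#' coordinates) into [gene_model()] objects (0-based half-open, transcription
#' order). CDS rows are grouped by their parent gene, resolving one level of
#' `mRNA` parentage; one CDS model per gene is assumed. Genes whose CDS
#' length is not a multiple of 3 are flagged `low_quality`, not dropped.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of `gene_model` objects (names are gene ids).
#' @export
read_gff3_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("GFF3 file '", path, "' has no feature rows")
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(f) != 9L
  if (any(bad)) stop("malformed GFF3 row(s): ", which(bad)[1L])
  f <- do.call(rbind, f)
  type <- f[, 3L]
  attr_field <- f[, 9L]
  get_attr <- function(s, key) {
    m <- regmatches(s, regexec(paste0("(?:^|;)", key, "=([^;]+)"), s))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
  }
  id <- get_attr(attr_field, "ID")
  parent <- get_attr(attr_field, "Parent")
  name <- get_attr(attr_field, "Name")

  # map mRNA id -> gene id
  mrna <- type == "mRNA"
  mrna_parent <- stats::setNames(parent[mrna], id[mrna])
  gene_rows <- which(type == "gene")
  gene_ids <- id[gene_rows]
  gene_name <- ifelse(is.na(name[gene_rows]), gene_ids, name[gene_rows])
  names(gene_name) <- gene_ids

  cds_rows <- which(type == "CDS")
  if (length(cds_rows) == 0L) stop("GFF3 file has no CDS rows")
  cds_parent <- parent[cds_rows]
  resolved <- ifelse(cds_parent %in% names(mrna_parent),
                     mrna_parent[cds_parent], cds_parent)
  orphan <- !(resolved %in% gene_ids)
  if (any(orphan)) {
    stop("CDS row(s) without a parent gene: parent '",
         resolved[which(orphan)[1L]], "'")
  }
  out <- lapply(gene_ids, function(g) {
    rows <- cds_rows[resolved == g]
    if (length(rows) == 0L) return(NULL)
    strand <- unique(f[rows, 7L])
    if (length(strand) != 1L || !strand %in% c("+", "-")) {
      stop("gene ", g, ": inconsistent or missing strand on CDS rows")
    }
    start1 <- as.integer(f[rows, 4L])
    end1 <- as.integer(f[rows, 5L])
    gene_model(g, chrom = unique(f[rows, 1L])[1L], strand = strand,
               cds = cbind(start1 - 1L, end1), name = gene_name[[g]])
  })
  names(out) <- gene_ids
  out[!vapply(out, is.null, TRUE)]
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff3_genes()] for the package's restricted dialect
#' (gene/mRNA/CDS rows, 1-based inclusive coordinates on output).
#'
#' @param genes Named list of `gene_model` objects.
#' @param path Output path.
#' @export
write_gff3_genes <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    span <- gene_span(g)
    row <- function(type, s0, e0, attrs) {
      paste(g$chrom, "nsvatlas", type, s0 + 1L, e0, ".", g$strand, ".",
            attrs, sep = "\t")
    }
    writeLines(row("gene", span[1L], span[2L],
                   sprintf("ID=%s;Name=%s", g$gene_id, g$name)), con)
    mrna_id <- paste0(g$gene_id, ".t1")
    writeLines(row("mRNA", span[1L], span[2L],
                   sprintf("ID=%s;Parent=%s", mrna_id, g$gene_id)), con)
    cds <- g$cds[order(g$cds[, "start"]), , drop = FALSE]
    for (i in seq_len(nrow(cds))) {
      writeLines(row("CDS", cds[i, "start"], cds[i, "end"],
                     sprintf("ID=%s.cds%d;Parent=%s", g$gene_id, i, mrna_id)),
                 con)
    }
  }
  invisible(path)
}
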