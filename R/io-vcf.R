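#' Read SNVs from a VCF file
#'
#' Reads a VCF 4.x file (via \pkg{vcfR} when available, else a built-in
#' parser for plain-text VCF), keeps single-nucleotide variants only and
#' applies the site-quality filter: sites with Phred-scaled `QUAL` below
#' `min_qual` are discarded (`QUAL >= min_qual` keeps; the default threshold
#' of 30 removes sites with quality below 30). Indels and multi-nucleotide
#' variants are skipped and counted, not errors. VCF 1-based `POS` is
#' converted to the package-internal 0-based convention.
#'
#' @param path Path to a VCF file.
#' @param min_qual Minimum Phred site quality retained (default 30).
#' @return Object of class `variant_set`: a list with
#'   `variants` (data.frame: `chrom`, `pos` 0-based, `id`, `ref`,
#'   `alts` comma-joined, `qual`, `n_alt`), `gt` (character matrix
#'   sites x samples of normalized unordered genotypes `"a/b"`, `NA`
#'   missing), `n_indel_skipped`, `n_lowqual_skipped`.
#' @export
read_vcf <- function(path, min_qual = 30) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    gt <- if (ncol(v@gt) > 1L) {
      vcfR::extract.gt(v, element = "GT")
    } else {
      matrix(character(0), nrow = nrow(fix), ncol = 0L)
    }
  } else {
    parsed <- parse_vcf_lines(readLines(path))
    fix <- parsed$fix
    gt <- parsed$gt
  }
  chrom <- fix$CHROM
  pos1 <- as.integer(fix$POS)
  ref <- fix$REF
  alt <- fix$ALT
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  id <- if ("ID" %in% names(fix)) fix$ID else rep(".", length(chrom))

  alt_list <- strsplit(alt, ",", fixed = TRUE)
  is_snv <- nchar(ref) == 1L &
    vapply(alt_list, function(a) all(nchar(a) == 1L) && all(a != "*"), TRUE)
  n_indel <- sum(!is_snv)
  keep_q <- is_snv & !is.na(qual) & qual >= min_qual
  n_lowqual <- sum(is_snv & (!is.na(qual) & qual < min_qual))

  gt <- gt[keep_q, , drop = FALSE]
  gt[] <- normalize_gt(gt)
  variants <- data.frame(
    chrom = chrom[keep_q], pos = pos1[keep_q] - 1L, id = id[keep_q],
    ref = ref[keep_q], alts = alt[keep_q], qual = qual[keep_q],
    n_alt = lengths(alt_list)[keep_q], stringsAsFactors = FALSE
  )
  rownames(gt) <- NULL
  structure(list(variants = variants, gt = gt,
                 n_indel_skipped = n_indel, n_lowqual_skipped = n_lowqual),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d SNVs x %d samples (skipped: %d indel/MNV, %d low-qual)\n",
              nrow(x$variants), ncol(x$gt), x$n_indel_skipped,
              x$n_lowqual_skipped))
  invisible(x)
}

# fallback parser for plain-text VCF 4.x (used when vcfR is unavailable)
parse_vcf_lines <- function(lines) {
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("malformed VCF: missing #CHROM header line")
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t", fixed = TRUE)[[1L]]
  body <- lines[seq_along(lines) > hdr]
  body <- body[nzchar(body)]
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) != length(cols))) stop("malformed VCF data row")
  f <- do.call(rbind, f)
  colnames(f) <- cols
  fix <- as.data.frame(f[, 1:8, drop = FALSE], stringsAsFactors = FALSE)
  samples <- cols[-(1:9)]
  if (length(samples) > 0L) {
    fmt <- strsplit(f[, "FORMAT"], ":", fixed = TRUE)
    gt_idx <- vapply(fmt, function(x) match("GT", x), 0L)
    if (anyNA(gt_idx)) stop("malformed VCF: FORMAT without GT field")
    gt <- f[, samples, drop = FALSE]
    for (j in seq_len(ncol(gt))) {
      parts <- strsplit(gt[, j], ":", fixed = TRUE)
      gt[, j] <- mapply(function(p, k) p[[k]], parts, gt_idx)
    }
  } else {
    gt <- matrix(character(0), nrow = nrow(fix), ncol = 0L)
  }
  list(fix = fix, gt = gt)
}

# "0/1", "1|0", "./." -> sorted unordered "0/1" or NA; errors on junk
normalize_gt <- function(gt) {
  g <- gsub("|", "/", as.character(gt), fixed = TRUE)
  g <- sub(":.*$", "", g)
  out <- rep(NA_character_, length(g))
  ok <- grepl("^[0-9]+/[0-9]+$", g)
  miss <- is.na(g) | g %in% c("./.", ".", ".|.")
  if (any(!ok & !miss)) {
    stop("malformed genotype field: '", g[which(!ok & !miss)[1L]], "'")
  }
  parts <- strsplit(g[ok], "/", fixed = TRUE)
  out[ok] <- vapply(parts, function(p) {
    p <- sort(as.integer(p))
    paste(p, collapse = "/")
  }, "")
  out
}

#' Write a minimal VCF 4.2 file
#'
#' Writer used by the synthetic-data generators to emit spiked variant sets;
#' accepts the `variants`/`gt` layout produced by [read_vcf()] (0-based
#' `pos`, converted back to 1-based `POS` on output).
#'
#' @param variants Data frame with `chrom`, `pos` (0-based), `ref`, `alts`,
#'   `qual` (and optionally `id`).
#' @param path Output path.
#' @param gt Optional genotype matrix (sites x samples, `"a/b"` strings or
#'   `NA`).
#' @param sample_names Sample names for the genotype columns.
#' @export
write_vcf <- function(variants, path, gt = NULL, sample_names = colnames(gt)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=nsvatlas",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  hdr <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  has_gt <- !is.null(gt) && ncol(gt) > 0L
  if (has_gt) hdr <- c(hdr, "FORMAT", sample_names)
  writeLines(paste(hdr, collapse = "\t"), con)
  id <- if ("id" %in% names(variants)) variants$id else rep(".", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    row <- c(variants$chrom[i], variants$pos[i] + 1L, id[i], variants$ref[i],
             variants$alts[i], format(variants$qual[i]), "PASS", ".")
    if (has_gt) {
      gti <- gt[i, ]
      gti[is.na(gti)] <- "./."
      row <- c(row, "GT", gti)
    }
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}
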