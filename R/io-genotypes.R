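#' Construct a genotype matrix
#'
#' Container for panel genotypes: diploid biallelic calls for a set of
#' individuals at a set of loci, with a population label and a wild/farm
#' group label per individual. Calls are stored as alternate-allele dosage
#' (0, 1, 2; `NA` missing), which is sufficient for unordered biallelic
#' genotypes.
#'
#' @param loci Data frame with columns `locus`, `chrom`, `pos` (0-based),
#'   `ref`, `alt` (single bases).
#' @param ind Data frame with columns `id`, `pop`, `group` (each `pop`
#'   maps to exactly one `group`).
#' @param geno Integer matrix `nrow(ind)` x `nrow(loci)` of alt-allele
#'   dosages in `{0, 1, 2, NA}`.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(loci, ind, geno) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  ind <- as.data.frame(ind, stringsAsFactors = FALSE)
  stopifnot(all(c("locus", "chrom", "pos", "ref", "alt") %in% names(loci)),
            all(c("id", "pop", "group") %in% names(ind)))
  geno <- matrix(as.integer(geno), nrow = nrow(ind),
                 dimnames = list(ind$id, loci$locus))
  if (ncol(geno) != nrow(loci)) stop("geno columns must match loci rows")
  if (!all(geno %in% c(0L, 1L, 2L, NA))) {
    stop("genotype dosages must be 0, 1, 2 or NA")
  }
  map <- unique(ind[, c("pop", "group")])
  if (anyDuplicated(map$pop)) {
    stop("a population maps to more than one group label")
  }
  if (anyDuplicated(loci$locus)) stop("duplicate locus ids")
  if (anyDuplicated(ind$id)) stop("duplicate individual ids")
  structure(list(loci = loci, ind = ind, geno = geno,
                 n_missing = sum(is.na(geno))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d individuals x %d loci, %d populations (%s), %d missing call(s)\n",
    nrow(x$geno), ncol(x$geno), length(unique(x$ind$pop)),
    paste(sprintf("%s: %d", names(table(x$ind$group)), table(x$ind$group)),
          collapse = ", "),
    x$n_missing))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by population or locus
#'
#' @param x A `genotype_matrix`.
#' @param pops Population labels to keep (default all).
#' @param loci Locus ids to keep (default all).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, pops = NULL, loci = NULL) {
  keep_i <- if (is.null(pops)) rep(TRUE, nrow(x$geno)) else x$ind$pop %in% pops
  keep_l <- if (is.null(loci)) rep(TRUE, ncol(x$geno)) else x$loci$locus %in% loci
  genotype_matrix(x$loci[keep_l, , drop = FALSE],
                  x$ind[keep_i, , drop = FALSE],
                  x$geno[keep_i, keep_l, drop = FALSE])
}

#' Read a wide genotype table (TSV)
#'
#' The package's genotype-table dialect: header comment lines
#' `## locus=<id> chrom=<chrom> pos=<1-based pos> ref=<base> alt=<base>`
#' describing each locus, then a tab-separated table with columns
#' `individual`, `population`, `group` and one column per locus holding
#' two-letter genotypes (e.g. `"AG"`) or `"--"` for missing. When locus
#' header lines are absent, `ref`/`alt` are inferred from the data (major
#' allele as `ref`).
#'
#' @param path Path to the TSV file.
#' @return A [genotype_matrix()].
#' @export
read_genotype_table <- function(path) {
  lines <- readLines(path)
  meta <- lines[grepl("^## locus=", lines)]
  tab <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(tab, "\t", fixed = TRUE)
  header <- f[[1L]]
  if (!identical(header[1:3], c("individual", "population", "group"))) {
    stop("genotype table must start with columns individual, population, group")
  }
  locus_ids <- header[-(1:3)]
  body <- do.call(rbind, f[-1L])
  ind <- data.frame(id = body[, 1L], pop = body[, 2L], group = body[, 3L],
                    stringsAsFactors = FALSE)
  cells <- body[, -(1:3), drop = FALSE]

  get_kv <- function(s, key) {
    m <- regmatches(s, regexec(paste0(key, "=([^ ]+)"), s))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
  }
  if (length(meta) > 0L) {
    loci <- data.frame(
      locus = get_kv(meta, "locus"), chrom = get_kv(meta, "chrom"),
      pos = as.integer(get_kv(meta, "pos")) - 1L,
      ref = get_kv(meta, "ref"), alt = get_kv(meta, "alt"),
      stringsAsFactors = FALSE
    )
    loci <- loci[match(locus_ids, loci$locus), , drop = FALSE]
    if (anyNA(loci$locus)) stop("locus header lines do not match table columns")
  } else {
    infer <- function(j) {
      g <- cells[, j]
      letters <- unlist(strsplit(g[g != "--"], ""))
      tab <- sort(table(letters), decreasing = TRUE)
      al <- names(tab)
      if (length(al) > 2L) stop("locus ", locus_ids[j], ": >2 alleles in table")
      c(al[1L], if (length(al) == 2L) al[2L] else "N")
    }
    al <- vapply(seq_along(locus_ids), infer, character(2L))
    loci <- data.frame(locus = locus_ids, chrom = NA_character_,
                       pos = NA_integer_, ref = al[1L, ], alt = al[2L, ],
                       stringsAsFactors = FALSE)
  }
  geno <- matrix(NA_integer_, nrow(ind), length(locus_ids))
  for (j in seq_along(locus_ids)) {
    g <- cells[, j]
    known <- g != "--"
    a1 <- substr(g[known], 1L, 1L)
    a2 <- substr(g[known], 2L, 2L)
    ok <- a1 %in% c(loci$ref[j], loci$alt[j]) &
      a2 %in% c(loci$ref[j], loci$alt[j])
    if (any(!ok)) {
      stop("locus ", locus_ids[j], ": genotype letter not in {ref,alt} (",
           g[known][!ok][1L], ")")
    }
    geno[known, j] <- (a1 == loci$alt[j]) + (a2 == loci$alt[j])
  }
  genotype_matrix(loci, ind, geno)
}

#' Write a genotype matrix as a wide TSV table
#'
#' Inverse of [read_genotype_table()]: `read_genotype_table(write_genotype_table(m))`
#' reproduces `m` exactly, including missing cells.
#'
#' @param x A `genotype_matrix`.
#' @param path Output path.
#' @export
write_genotype_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (j in seq_len(nrow(x$loci))) {
    writeLines(sprintf("## locus=%s chrom=%s pos=%d ref=%s alt=%s",
                       x$loci$locus[j], x$loci$chrom[j], x$loci$pos[j] + 1L,
                       x$loci$ref[j], x$loci$alt[j]), con)
  }
  writeLines(paste(c("individual", "population", "group", x$loci$locus),
                   collapse = "\t"), con)
  code <- function(d, j) {
    r <- x$loci$ref[j]; a <- x$loci$alt[j]
    out <- c(paste0(r, r), paste0(r, a), paste0(a, a))[d + 1L]
    out[is.na(d)] <- "--"
    out
  }
  cells <- vapply(seq_len(ncol(x$geno)),
                  function(j) code(x$geno[, j], j),
                  character(nrow(x$geno)))
  cells <- matrix(cells, nrow = nrow(x$geno))
  for (i in seq_len(nrow(x$geno))) {
    writeLines(paste(c(x$ind$id[i], x$ind$pop[i], x$ind$group[i], cells[i, ]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a genotype matrix in Genepop format
#'
#' Two-digit allele codes: ref = `01`, alt = `02`, missing = `0000`.
#' Populations are emitted as Genepop `POP` blocks in the order they first
#' appear; individual labels are preserved. Group labels are not part of
#' the Genepop dialect and are not written.
#'
#' @param x A `genotype_matrix`.
#' @param path Output path.
#' @param title Title line (first line of the file).
#' @export
write_genepop <- function(x, path, title = "nsvatlas genotype export") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(x$loci$locus, con)
  codes <- c("0101", "0102", "0202")
  for (p in unique(x$ind$pop)) {
    writeLines("POP", con)
    for (i in which(x$ind$pop == p)) {
      g <- codes[x$geno[i, ] + 1L]
      g[is.na(x$geno[i, ])] <- "0000"
      writeLines(paste0(x$ind$id[i], " ,  ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a Genepop file written by [write_genepop()]
#'
#' Recovers allele counts exactly; population labels are regenerated as
#' `POP1`, `POP2`, ... and group labels are `NA` (the Genepop dialect does
#' not carry them). Locus `chrom`/`pos` metadata is likewise absent; `ref`
#' and `alt` letters default to `A`/`B` placeholders.
#'
#' @param path Path to a Genepop file (2-digit allele codes).
#' @return A [genotype_matrix()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pop_rows <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (length(pop_rows) == 0L) stop("not a Genepop file: no POP line")
  loci <- lines[2:(pop_rows[1L] - 1L)]
  loci <- trimws(unlist(strsplit(loci, ",")))
  ids <- character(0); pops <- character(0); rows <- list()
  pop_i <- 0L
  for (k in seq_along(lines)) {
    if (k %in% pop_rows) { pop_i <- pop_i + 1L; next }
    if (k <= pop_rows[1L] - 1L) next
    parts <- strsplit(lines[k], ",", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed Genepop individual line: ", lines[k])
    g <- strsplit(trimws(parts[2L]), "\\s+")[[1L]]
    if (length(g) != length(loci)) stop("Genepop row with wrong locus count")
    a1 <- as.integer(substr(g, 1L, 2L))
    a2 <- as.integer(substr(g, 3L, 4L))
    d <- ifelse(a1 == 0L | a2 == 0L, NA_integer_, (a1 == 2L) + (a2 == 2L))
    ids <- c(ids, trimws(parts[1L]))
    pops <- c(pops, paste0("POP", pop_i))
    rows[[length(rows) + 1L]] <- d
  }
  genotype_matrix(
    loci = data.frame(locus = loci, chrom = NA_character_, pos = NA_integer_,
                      ref = "A", alt = "B", stringsAsFactors = FALSE),
    ind = data.frame(id = ids, pop = pops, group = NA_character_,
                     stringsAsFactors = FALSE),
    geno = do.call(rbind, rows)
  )
}
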