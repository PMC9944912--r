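#' Unbiased expected heterozygosity
#'
#' Nei's small-sample-corrected gene diversity,
#' `H_E = 2n/(2n-1) * (1 - sum(p_i^2))`, where `n` is the number of diploid
#' individuals sampled. The plug-in (uncorrected) estimator is available via
#' `unbiased = FALSE`.
#'
#' @param p Allele frequencies: either a vector summing to 1, or a single
#'   frequency of one allele of a biallelic locus.
#' @param n Number of diploid individuals.
#' @param unbiased Apply the `2n/(2n-1)` correction (default `TRUE`).
#' @return Expected heterozygosity in `[0, 1]`; 0 for a monomorphic locus.
#' @export
expected_het_unbiased <- function(p, n, unbiased = TRUE) {
  if (length(p) == 1L) p <- c(p, 1 - p)
  he <- 1 - sum(p^2)
  if (unbiased && n > 0) he <- he * 2 * n / (2 * n - 1)
  max(0, he)
}

#' Within-population fixation index
#'
#' `F_IS = 1 - H_O / H_E`; negative values indicate heterozygote excess.
#' Undefined (`NA`) for monomorphic cells (`H_E == 0`).
#'
#' @param ho Observed heterozygosity.
#' @param he Expected heterozygosity.
#' @return `F_IS` or `NA`.
#' @export
fis <- function(ho, he) ifelse(he > 0, 1 - ho / he, NA_real_)

#' Exact Hardy-Weinberg test (Levene's conditional distribution)
#'
#' Exact conditional distribution of the heterozygote count given the
#' allele counts: configurations with `h` heterozygotes (same parity as the
#' minor-allele count) have probability proportional to
#' `n! / (nAA! nAa! naa!) * 2^h`. The two-sided p-value sums the
#' probabilities of all configurations no more probable than the observed
#' one (probability ordering). `midp = TRUE` counts the observed
#' configuration with weight 1/2.
#'
#' @param nAA,nAa,naa Genotype counts.
#' @param midp Use the mid-p variant (default `FALSE`).
#' @return Exact p-value in `(0, 1]`; 1 for monomorphic samples.
#' @export
hwe_exact_p <- function(nAA, nAa, naa, midp = FALSE) {
  n <- nAA + nAa + naa
  nA <- 2L * nAA + nAa
  if (n == 0L || nA == 0L || nA == 2L * n) return(1)
  hs <- seq.int(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
  logp <- lfactorial(n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial(n - (nA + hs) / 2) + hs * log(2) +
    lfactorial(nA) + lfactorial(2L * n - nA) - lfactorial(2L * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(nAa, hs)]
  le <- pr <= p_obs * (1 + 1e-9)
  p <- sum(pr[le])
  if (midp) p <- p - 0.5 * p_obs
  min(1, p)
}

#' Per-population genotype counts for every locus
#'
#' @param x A `genotype_matrix`.
#' @return List of three `pop x locus` matrices: `n` (non-missing diploid
#'   individuals), `nalt` (alternate allele count) and `nhet` (heterozygote
#'   count), plus `pops` and `group` (group label per population).
#' @export
genotype_counts <- function(x) {
  pop <- factor(x$ind$pop, levels = unique(x$ind$pop))
  g <- x$geno
  n <- rowsum(1L * !is.na(g), pop)
  gz <- g; gz[is.na(gz)] <- 0L
  nalt <- rowsum(gz, pop)
  nhet <- rowsum(1L * (!is.na(g) & g == 1L), pop)
  map <- x$ind$group[match(levels(pop), x$ind$pop)]
  list(n = n, nalt = nalt, nhet = nhet, pops = levels(pop), group = map)
}

#' Per-locus, per-population diversity statistics
#'
#' @param x A `genotype_matrix`.
#' @return Data frame with one row per (population, locus): `n`, `n_ref`,
#'   `n_alt` allele counts, `maf`, `na_observed` (alleles seen), `ho`,
#'   `he` (unbiased), `fis`, `hwe_p`.
#' @export
locus_pop_stats <- function(x) {
  cts <- genotype_counts(x)
  out <- expand.grid(pop = cts$pops, locus = x$loci$locus,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- cbind(match(out$pop, cts$pops), match(out$locus, x$loci$locus))
  n <- cts$n[idx]; nalt <- cts$nalt[idx]; nhet <- cts$nhet[idx]
  p_alt <- ifelse(n > 0, nalt / (2 * n), NA_real_)
  out$n <- n
  out$n_ref <- 2L * n - nalt
  out$n_alt <- nalt
  out$maf <- pmin(p_alt, 1 - p_alt)
  out$na_observed <- (out$n_ref > 0L) + (out$n_alt > 0L)
  out$ho <- ifelse(n > 0, nhet / n, NA_real_)
  out$he <- vapply(seq_len(nrow(out)), function(i) {
    if (n[i] == 0L) return(NA_real_)
    expected_het_unbiased(p_alt[i], n[i])
  }, 0)
  out$fis <- fis(out$ho, out$he)
  out$hwe_p <- vapply(seq_len(nrow(out)), function(i) {
    if (n[i] == 0L) return(NA_real_)
    hwe_exact_p((nalt[i] - nhet[i]) %/% 2L, nhet[i],
                n[i] - (nalt[i] + nhet[i]) %/% 2L)
  }, 0)
  out
}

#' Weir-Cockerham variance components for a matrix of loci
#'
#' Vectorized computation of the three variance components of the
#' Weir-Cockerham unbiased F_ST estimator (`a` among populations, `b` among
#' individuals within populations, `c` within individuals) from
#' per-population counts. Rows are loci (or simulated loci), columns
#' populations; populations with `n = 0` at a locus are excluded from that
#' locus.
#'
#' @param n Matrix of diploid sample sizes (loci x pops).
#' @param nalt Matrix of alternate-allele counts.
#' @param nhet Matrix of heterozygote counts.
#' @return Data frame with columns `a`, `b`, `c`, `theta` (one row per
#'   locus). `theta = a / (a + b + c)`, `NA` for monomorphic loci.
#' @export
wc_components <- function(n, nalt, nhet) {
  n <- as.matrix(n); nalt <- as.matrix(nalt); nhet <- as.matrix(nhet)
  r <- rowSums(n > 0)
  sum_n <- rowSums(n)
  nbar <- sum_n / r
  p <- ifelse(n > 0, nalt / (2 * n), 0)
  h <- ifelse(n > 0, nhet / n, 0)
  nc <- (sum_n - rowSums(n^2) / sum_n) / (r - 1)
  pbar <- rowSums(n * p) / sum_n
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / sum_n
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(abs(denom) > 0, a / denom, NA_real_)
  data.frame(a = a, b = b, c = cc, theta = theta)
}

#' Weir-Cockerham theta for one locus of a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param locus Locus id (default: all loci).
#' @return Data frame of components (`a`, `b`, `c`, `theta`), one row per
#'   requested locus.
#' @export
wc_theta <- function(x, locus = x$loci$locus) {
  cts <- genotype_counts(x)
  j <- match(locus, x$loci$locus)
  if (anyNA(j)) stop("unknown locus id")
  res <- wc_components(t(cts$n[, j, drop = FALSE]),
                       t(cts$nalt[, j, drop = FALSE]),
                       t(cts$nhet[, j, drop = FALSE]))
  rownames(res) <- locus
  res
}

#' Multilocus Weir-Cockerham theta (ratio of sums)
#'
#' Combines per-locus variance components as `sum(a) / sum(a + b + c)`
#' (ratio of sums, not mean of per-locus ratios).
#'
#' @param x A `genotype_matrix`, or a data.frame of components from
#'   [wc_components()].
#' @return Scalar multilocus theta.
#' @export
multilocus_theta <- function(x) {
  comp <- if (inherits(x, "genotype_matrix")) wc_theta(x) else x
  sum(comp$a) / sum(comp$a + comp$b + comp$c)
}

#' Pairwise multilocus F_ST between populations
#'
#' @param x A `genotype_matrix`.
#' @return Symmetric population x population matrix of multilocus theta
#'   (diagonal 0).
#' @export
pairwise_fst <- function(x) {
  pops <- unique(x$ind$pop)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_len(i - 1L)) {
      sub <- subset_genotypes(x, pops = c(pops[i], pops[j]))
      m[i, j] <- m[j, i] <- multilocus_theta(sub)
    }
  }
  m
}

# nested ANOVA (groups / populations / individuals / allele copies) on
# allele-count indicators; method-of-moments variance components.
# n, nalt, nhet: per-pop vectors for one locus; group: group label per pop.
nested_components <- function(n, nalt, nhet, group) {
  keep <- n > 0
  n <- n[keep]; nalt <- nalt[keep]; nhet <- nhet[keep]
  group <- factor(group[keep])
  if (length(unique(group)) < 2L || length(n) < 2L) {
    stop("hierarchical components need >= 2 groups with sampled populations")
  }
  Np <- 2 * n
  Ng <- as.vector(rowsum(Np, group))
  Ntot <- sum(Np)
  nind <- sum(n)
  P <- length(n); G <- nlevels(group)
  sum_p <- nalt                       # per-pop allele-count sums
  sum_g <- as.vector(rowsum(sum_p, group))
  ybar_p2 <- sum_p^2 / Np
  ybar_g2 <- sum_g^2 / Ng
  ybar_t2 <- sum(sum_p)^2 / Ntot
  n_homalt <- (nalt - nhet) / 2
  sum_yi2 <- n_homalt + nhet / 4      # per-pop sum of individual means^2

  ss_groups <- sum(ybar_g2) - ybar_t2
  ss_pops <- sum(ybar_p2) - sum(ybar_g2)
  ss_ind <- sum(2 * sum_yi2 - ybar_p2)
  ss_within <- 0.5 * sum(nhet)

  # expected-SS coefficients for the unbalanced nested random-effects model
  k_t_a <- sum(Ng^2) / Ntot
  k_t_b <- sum(Np^2) / Ntot
  k_g_b <- sum(rowsum(Np^2, group) / Ng)
  M <- rbind(
    c(Ntot - k_t_a, k_g_b - k_t_b, 2 * G - 2, G - 1),
    c(0, Ntot - k_g_b, 2 * P - 2 * G, P - G),
    c(0, 0, Ntot - 2 * P, nind - P),
    c(0, 0, 0, nind)
  )
  sig <- solve(M, c(ss_groups, ss_pops, ss_ind, ss_within))
  names(sig) <- c("sig_a", "sig_b", "sig_c", "sig_d")
  sig
}

#' Hierarchical F-statistics (groups / populations / individuals / alleles)
#'
#' Four-level nested analysis of variance on allele-count indicators,
#' yielding method-of-moments variance components and the hierarchical
#' fixation indices: `F_CT` (among groups), `F_SC` (among populations
#' within groups) and `F_ST` (total, populations-and-groups over total).
#' Multilocus indices combine per-locus components by ratio of sums.
#'
#' @param x A `genotype_matrix` whose individuals carry group labels.
#' @return List with `per_locus` (data.frame: locus, sig_a, sig_b, sig_c,
#'   sig_d, fct, fsc, fst) and multilocus `fct`, `fsc`, `fst`.
#' @export
hierarchical_f <- function(x) {
  cts <- genotype_counts(x)
  if (any(is.na(cts$group))) stop("group labels required for hierarchical F")
  per <- t(vapply(seq_len(ncol(cts$n)), function(j) {
    nested_components(cts$n[, j], cts$nalt[, j], cts$nhet[, j], cts$group)
  }, numeric(4L)))
  per <- as.data.frame(per)
  names(per) <- c("sig_a", "sig_b", "sig_c", "sig_d")
  tot <- per$sig_a + per$sig_b + per$sig_c + per$sig_d
  per <- cbind(locus = x$loci$locus, per,
               fct = ifelse(abs(tot) > 0, per$sig_a / tot, NA_real_),
               fsc = ifelse(abs(tot - per$sig_a) > 0,
                            per$sig_b / (tot - per$sig_a), NA_real_),
               fst = ifelse(abs(tot) > 0,
                            (per$sig_a + per$sig_b) / tot, NA_real_))
  sums <- colSums(per[, c("sig_a", "sig_b", "sig_c", "sig_d")])
  stot <- sum(sums)
  list(per_locus = per,
       fct = sums[["sig_a"]] / stot,
       fsc = sums[["sig_b"]] / (stot - sums[["sig_a"]]),
       fst = (sums[["sig_a"]] + sums[["sig_b"]]) / stot)
}

#' Per-locus panel summary (diversity and differentiation)
#'
#' One row per locus: mean observed allele number and mean unbiased expected
#' heterozygosity across population samples (unweighted), global
#' Weir-Cockerham theta over all populations, theta over the wild
#' populations only, and the hierarchical among-group index (`F_CT`) for
#' the wild-versus-farm contrast (when both groups are present). Outlier
#' scan p-values can be merged in afterwards.
#'
#' @param x A `genotype_matrix`.
#' @param wild_group,farm_group Group labels (defaults `"wild"`, `"farm"`).
#' @return Data frame with columns `locus`, `na_mean`, `he_mean`,
#'   `fst_all`, `fst_wild`, `fct_farm_wild`.
#' @export
locus_summary <- function(x, wild_group = "wild", farm_group = "farm") {
  stats <- locus_pop_stats(x)
  agg <- function(v) {
    tapply(v, factor(stats$locus, levels = x$loci$locus),
           function(z) mean(z, na.rm = TRUE))
  }
  out <- data.frame(locus = x$loci$locus,
                    na_mean = as.vector(agg(stats$na_observed)),
                    he_mean = as.vector(agg(stats$he)))
  out$fst_all <- wc_theta(x)$theta
  wild <- unique(x$ind$pop[x$ind$group == wild_group])
  out$fst_wild <- if (length(wild) >= 2L) {
    wc_theta(subset_genotypes(x, pops = wild))$theta
  } else NA_real_
  has_both <- all(c(wild_group, farm_group) %in% x$ind$group)
  out$fct_farm_wild <- if (has_both) {
    hierarchical_f(x)$per_locus$fct
  } else NA_real_
  out
}
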