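#' Default sampling design of the turbot panel study system
#'
#' The bundled sampling design: 13 wild turbot populations spanning the
#' Baltic, Atlantic, Mediterranean and Black Sea genetic regions plus three
#' farm broodstocks — 355 individuals in total. Used as the default
#' population layout of [panel_sim_config()].
#'
#' @return Data frame with columns `location`, `pop`, `size`, `region`,
#'   `group`.
#' @export
panel_design <- function() {
  path <- system.file("extdata", "panel_design.tsv", package = "nsvatlas")
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$group <- ifelse(d$region == "Domestic", "farm", "wild")
  d
}

#' Configuration for the structured-panel generator
#'
#' Defaults emulate the study design the package targets: 16 population
#' samples (13 wild, 3 farm; 355 individuals) genotyped at 18 unlinked
#' biallelic loci, island-model structure at background F_ST 0.05, a
#' minority of loci with inflated (divergent) or deflated (balancing)
#' differentiation, ancestral minor-allele frequencies spanning 0.01-0.5,
#' and farm samples derived from an Atlantic wild source by a founder
#' bottleneck followed by binomial drift.
#'
#' @param pop_sizes Named integer vector of diploid sample sizes.
#' @param groups Named character vector, group label per population.
#' @param n_loci Number of loci.
#' @param background_f Background (neutral) locus F.
#' @param frac_divergent,frac_balancing Fractions of loci with divergent /
#'   balancing locus-specific F.
#' @param f_divergent,f_balancing Locus-specific F for those classes.
#' @param maf_bounds Ancestral minor-allele frequency bounds.
#' @param farm_founder_size Diploid founder count per farm broodstock.
#' @param farm_drift_generations Generations of binomial drift after
#'   founding.
#' @param farm_source Named character vector: source wild population per
#'   farm.
#' @param n_group_divergent Number of loci with a planted wild-versus-farm
#'   frequency shift (emulating artificial selection).
#' @param group_shift Size of that planted farm allele-frequency shift.
#' @return List of class `panel_sim_config`.
#' @export
panel_sim_config <- function(pop_sizes = NULL, groups = NULL, n_loci = 18L,
                             background_f = 0.05,
                             frac_divergent = 2 / 18, frac_balancing = 2 / 18,
                             f_divergent = 0.25, f_balancing = 0.005,
                             maf_bounds = c(0.01, 0.5),
                             farm_founder_size = 25L,
                             farm_drift_generations = 5L,
                             farm_source = NULL,
                             n_group_divergent = 0L, group_shift = 0.4) {
  if (is.null(pop_sizes)) {
    d <- panel_design()
    pop_sizes <- stats::setNames(d$size, d$pop)
    groups <- stats::setNames(d$group, d$pop)
  }
  if (is.null(groups)) {
    groups <- stats::setNames(rep("wild", length(pop_sizes)), names(pop_sizes))
  }
  stopifnot(all(pop_sizes > 0), frac_divergent + frac_balancing <= 1,
            length(maf_bounds) == 2L, maf_bounds[1L] > 0,
            maf_bounds[2L] <= 0.5)
  farms <- names(pop_sizes)[groups == "farm"]
  if (is.null(farm_source) && length(farms) > 0L) {
    wild_atl <- names(pop_sizes)[groups == "wild"]
    src <- if ("SP-W" %in% wild_atl) "SP-W" else wild_atl[1L]
    farm_source <- stats::setNames(rep(src, length(farms)), farms)
  }
  structure(list(pop_sizes = pop_sizes, groups = groups, n_loci = n_loci,
                 background_f = background_f, frac_divergent = frac_divergent,
                 frac_balancing = frac_balancing, f_divergent = f_divergent,
                 f_balancing = f_balancing, maf_bounds = maf_bounds,
                 farm_founder_size = farm_founder_size,
                 farm_drift_generations = farm_drift_generations,
                 farm_source = farm_source,
                 n_group_divergent = n_group_divergent,
                 group_shift = group_shift),
            class = "panel_sim_config")
}

# Balding-Nichols draw of a population frequency around ancestral p at
# inbreeding-like parameter f (f -> 0 degenerates to p itself)
bn_draw <- function(n, p, f) {
  if (f < 1e-9) return(rep(p, n))
  stats::rbeta(n, p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Generate a structured genotype panel with known truth
#'
#' Per locus, an ancestral minor-allele frequency is drawn uniformly within
#' the configured MAF bounds; wild-population frequencies follow the
#' Balding-Nichols model at the locus-specific F (background, divergent or
#' balancing); genotypes are binomial draws under within-population
#' Hardy-Weinberg equilibrium. Farm populations resample a founder pool of
#' configured size from their designated wild source population, then drift
#' binomially for the configured number of generations; planted
#' group-divergent loci additionally shift the farm allele frequency
#' (emulating artificial selection).
#'
#' @param config A [panel_sim_config()].
#' @param seed RNG seed.
#' @return List: `matrix` (a [genotype_matrix()]) and `truth` (data.frame:
#'   `locus`, `class`, `f_locus`, `p_ancestral`; the matrix of true
#'   per-population frequencies in attribute `pop_freq`).
#' @export
gen_structured_panel <- function(config = panel_sim_config(), seed = 1L) {
  with_seed(seed, {
    pops <- names(config$pop_sizes)
    wild <- pops[config$groups == "wild"]
    farms <- pops[config$groups == "farm"]
    L <- config$n_loci
    n_div <- round(config$frac_divergent * L)
    n_bal <- round(config$frac_balancing * L)
    n_gdiv <- min(config$n_group_divergent, L - n_div - n_bal)
    class <- rep("neutral", L)
    slots <- sample(L)
    if (n_div > 0L) class[slots[seq_len(n_div)]] <- "divergent"
    if (n_bal > 0L) class[slots[n_div + seq_len(n_bal)]] <- "balancing"
    if (n_gdiv > 0L) {
      class[slots[n_div + n_bal + seq_len(n_gdiv)]] <- "group_divergent"
    }
    f_locus <- c(neutral = config$background_f,
                 divergent = config$f_divergent,
                 balancing = config$f_balancing,
                 group_divergent = config$background_f)[class]
    p0 <- stats::runif(L, config$maf_bounds[1L], config$maf_bounds[2L])

    freq <- matrix(NA_real_, length(pops), L, dimnames = list(pops, NULL))
    for (j in seq_len(L)) {
      freq[wild, j] <- bn_draw(length(wild), p0[j], f_locus[j])
    }
    for (fm in farms) {
      src <- config$farm_source[[fm]]
      n_founder_alleles <- 2L * config$farm_founder_size
      for (j in seq_len(L)) {
        p <- freq[src, j]
        for (g in seq_len(config$farm_drift_generations + 1L)) {
          p <- stats::rbinom(1L, n_founder_alleles, p) / n_founder_alleles
        }
        if (class[j] == "group_divergent") {
          p <- min(0.95, p + config$group_shift)
        }
        freq[fm, j] <- p
      }
    }

    ind <- data.frame(
      id = unlist(lapply(pops, function(p) {
        sprintf("%s_%02d", p, seq_len(config$pop_sizes[[p]]))
      })),
      pop = rep(pops, config$pop_sizes),
      group = rep(config$groups[pops], config$pop_sizes),
      stringsAsFactors = FALSE)
    geno <- matrix(NA_integer_, nrow(ind), L)
    for (j in seq_len(L)) {
      geno[, j] <- stats::rbinom(nrow(ind), 2L, freq[ind$pop, j])
    }
    allele_pairs <- t(vapply(seq_len(L), function(j) {
      sample(c("A", "C", "G", "T"), 2L)
    }, character(2L)))
    loci <- data.frame(locus = sprintf("L%02d", seq_len(L)),
                       chrom = sprintf("chr%d", ((seq_len(L) - 1L) %% 2L) + 1L),
                       pos = 1000000L * seq_len(L),
                       ref = allele_pairs[, 1L], alt = allele_pairs[, 2L],
                       stringsAsFactors = FALSE)
    truth <- data.frame(locus = loci$locus, class = class,
                        f_locus = f_locus, p_ancestral = p0,
                        stringsAsFactors = FALSE)
    attr(truth, "pop_freq") <- freq
    list(matrix = genotype_matrix(loci, ind, geno), truth = truth)
  })
}

#' Mask genotype calls at random
#'
#' Each call is masked independently with the given rate. The default rate
#' reflects the near-perfect genotyping the package's target assays attain
#' (about one missing call per 6,390 genotypes).
#'
#' @param x A `genotype_matrix`.
#' @param rate Per-call missingness probability.
#' @param seed RNG seed.
#' @return A `genotype_matrix` with calls masked.
#' @export
gen_missingness <- function(x, rate = 1 / 6390, seed = 1L) {
  with_seed(seed, {
    if (rate > 0) {
      mask <- matrix(stats::runif(length(x$geno)) < rate, nrow(x$geno))
      x$geno[mask] <- NA_integer_
      x$n_missing <- sum(is.na(x$geno))
    }
    x
  })
}
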