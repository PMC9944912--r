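#' Island-model parameters for the neutral null
#'
#' Parameter container for the FDIST-style simulated null. The flat null is
#' a finite island model of `n_demes` demes; the hierarchical null nests
#' `demes_per_group` demes in each of `n_groups` groups with migration
#' higher within than between groups (defaults: 100 demes; 20 groups of
#' 100 demes each when hierarchical). The sample configuration mirrors the
#' observed data: one sampled deme per observed population, with the
#' observed sample sizes.
#'
#' @param sample_sizes Integer vector of diploid sample sizes (one sampled
#'   deme per population).
#' @param sample_group Integer group index per sampled population (all 1
#'   for the flat model).
#' @param n_demes Number of demes in the flat model.
#' @param n_groups,demes_per_group Hierarchical layout.
#' @param migration_within,migration_between Scaled migration rates (set by
#'   [calibrate_migration()]; `migration_between` is ignored by the flat
#'   model).
#' @param target_fst Differentiation the null is calibrated to.
#' @param n_sims Number of retained simulated loci (default 50,000).
#' @param engine `"betabinom"` (fast Balding-Nichols approximation, the
#'   default) or `"coalescent"` (structured-coalescent reference engine).
#' @param maf_bounds Ancestral-frequency bounds for the beta-binomial
#'   engine's mutation frequency draw.
#' @return List of class `island_model_params`.
#' @export
island_model_params <- function(sample_sizes, sample_group = NULL,
                                n_demes = 100L, n_groups = 1L,
                                demes_per_group = NULL,
                                migration_within = NULL,
                                migration_between = NULL,
                                target_fst = NULL, n_sims = 50000L,
                                engine = c("betabinom", "coalescent"),
                                maf_bounds = c(0.01, 0.99)) {
  engine <- match.arg(engine)
  if (is.null(sample_group)) sample_group <- rep(1L, length(sample_sizes))
  if (is.null(demes_per_group)) {
    demes_per_group <- if (n_groups == 1L) n_demes else 100L
  }
  if (n_groups > 1L) n_demes <- n_groups * demes_per_group
  stopifnot(length(sample_sizes) >= 2L, all(sample_sizes >= 1L),
            n_sims >= 1000L, n_demes >= length(sample_sizes))
  structure(list(sample_sizes = as.integer(sample_sizes),
                 sample_group = as.integer(sample_group),
                 n_demes = as.integer(n_demes), n_groups = as.integer(n_groups),
                 demes_per_group = as.integer(demes_per_group),
                 migration_within = migration_within,
                 migration_between = migration_between,
                 target_fst = target_fst, n_sims = as.integer(n_sims),
                 engine = engine, maf_bounds = maf_bounds),
            class = "island_model_params")
}

# island-model F_ST implied by a scaled migration rate M = 4Nm
island_f <- function(M, d) 1 / (1 + M * (d / (d - 1))^2)
island_m <- function(f, d) (1 / f - 1) / (d / (d - 1))^2

# --- simulation engines ------------------------------------------------
# both return per-pop count matrices (n_sims rows): nalt, nhet, plus the
# fixed per-pop sample sizes; monomorphic total samples are redrawn.

sim_counts_betabinom <- function(n_sims, sample_sizes, f_within,
                                 f_between = 0, sample_group = NULL,
                                 maf_bounds = c(0.01, 0.99)) {
  n_pops <- length(sample_sizes)
  if (is.null(sample_group)) sample_group <- rep(1L, n_pops)
  nalt <- matrix(0L, 0L, n_pops)
  nhet <- matrix(0L, 0L, n_pops)
  need <- n_sims
  while (need > 0L) {
    m <- max(need + ceiling(0.1 * n_sims), 100L)
    p0 <- stats::runif(m, maf_bounds[1L], maf_bounds[2L])
    pg <- matrix(p0, m, n_pops)
    if (f_between > 1e-9) {
      for (g in unique(sample_group)) {
        pgrp <- bn_draw_vec(p0, f_between)
        pg[, sample_group == g] <- pgrp
      }
    }
    pp <- matrix(NA_real_, m, n_pops)
    for (j in seq_len(n_pops)) {
      pp[, j] <- bn_draw_vec(pg[, j], f_within)
    }
    na <- matrix(0L, m, n_pops)
    nh <- matrix(0L, m, n_pops)
    for (j in seq_len(n_pops)) {
      n <- sample_sizes[j]
      naa <- stats::rbinom(m, n, pp[, j]^2)
      pr_het <- ifelse(pp[, j] < 1, 2 * pp[, j] * (1 - pp[, j]) /
                         (1 - pp[, j]^2), 0)
      nh[, j] <- stats::rbinom(m, n - naa, pmin(1, pr_het))
      na[, j] <- 2L * naa + nh[, j]
    }
    tot <- rowSums(na)
    poly <- tot > 0L & tot < 2L * sum(sample_sizes)
    na <- na[poly, , drop = FALSE]
    nh <- nh[poly, , drop = FALSE]
    take <- min(nrow(na), need)
    nalt <- rbind(nalt, na[seq_len(take), , drop = FALSE])
    nhet <- rbind(nhet, nh[seq_len(take), , drop = FALSE])
    need <- need - take
  }
  list(nalt = nalt, nhet = nhet, sample_sizes = sample_sizes)
}

bn_draw_vec <- function(p, f) {
  if (f < 1e-9) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

sim_counts_coalescent <- function(n_sims, sample_sizes, mig_within,
                                  mig_between = 0, sample_group = NULL,
                                  n_groups = 1L, demes_per_group = 100L) {
  n_pops <- length(sample_sizes)
  if (is.null(sample_group)) sample_group <- rep(1L, n_pops)
  out <- .coal_island_counts(as.integer(n_sims), as.integer(sample_sizes),
                             as.integer(sample_group), as.integer(n_groups),
                             as.integer(demes_per_group),
                             mig_within, mig_between)
  list(nalt = out[, seq_len(n_pops), drop = FALSE],
       nhet = out[, n_pops + seq_len(n_pops), drop = FALSE],
       sample_sizes = sample_sizes)
}

# per-simulated-locus (he, fst) pairs from count matrices
sim_stats <- function(counts, sample_group = NULL, hierarchical = FALSE) {
  n_pops <- length(counts$sample_sizes)
  nmat <- matrix(counts$sample_sizes, nrow(counts$nalt), n_pops, byrow = TRUE)
  ntot <- sum(counts$sample_sizes)
  p_tot <- rowSums(counts$nalt) / (2 * ntot)
  he <- 2 * ntot / (2 * ntot - 1) * (1 - p_tot^2 - (1 - p_tot)^2)
  fst <- if (hierarchical) {
    hier_fst_vec(nmat, counts$nalt, counts$nhet, sample_group)
  } else {
    wc_components(nmat, counts$nalt, counts$nhet)$theta
  }
  data.frame(he = he, fst = fst)
}

# vectorized hierarchical total F_ST for constant design (no missing data)
hier_fst_vec <- function(nmat, nalt, nhet, group) {
  n <- nmat[1L, ]
  group <- factor(group)
  Np <- 2 * n
  Ng <- as.vector(rowsum(Np, group))
  Ntot <- sum(Np)
  nind <- sum(n)
  P <- length(n); G <- nlevels(group)
  gidx <- as.integer(group)
  sum_g <- t(rowsum(t(nalt), gidx))          # sims x groups
  ybar_p2 <- sweep(nalt^2, 2L, Np, "/")
  ybar_g2 <- sweep(sum_g^2, 2L, Ng, "/")
  ybar_t2 <- rowSums(nalt)^2 / Ntot
  n_homalt <- (nalt - nhet) / 2
  sum_yi2 <- n_homalt + nhet / 4
  ss <- cbind(rowSums(ybar_g2) - ybar_t2,
              rowSums(ybar_p2) - rowSums(ybar_g2),
              rowSums(2 * sum_yi2 - ybar_p2),
              0.5 * rowSums(nhet))
  k_t_a <- sum(Ng^2) / Ntot
  k_t_b <- sum(Np^2) / Ntot
  k_g_b <- sum(rowsum(Np^2, group) / Ng)
  M <- rbind(c(Ntot - k_t_a, k_g_b - k_t_b, 2 * G - 2, G - 1),
             c(0, Ntot - k_g_b, 2 * P - 2 * G, P - G),
             c(0, 0, Ntot - 2 * P, nind - P),
             c(0, 0, 0, nind))
  sig <- ss %*% t(solve(M))
  tot <- rowSums(sig)
  ifelse(abs(tot) > 0, (sig[, 1L] + sig[, 2L]) / tot, NA_real_)
}

#' Simulate neutral null loci under the island model
#'
#' Draws neutral biallelic loci with the observed sample configuration and
#' returns one `(He, F_ST)` pair per retained locus. Engine
#' `"betabinom"` draws per-deme allele frequencies from the Balding-Nichols
#' beta distribution with F implied by the island model and genotypes
#' binomially; engine `"coalescent"` simulates a structured-coalescent
#' genealogy with a single mutation placed uniformly on the tree.
#' Monomorphic samples are never emitted (redrawn by the beta-binomial
#' engine; impossible by construction in the coalescent engine).
#'
#' @param params Calibrated [island_model_params()].
#' @param n Number of loci to draw (defaults to `params$n_sims`).
#' @param hierarchical Use the two-level model and the hierarchical total
#'   F_ST statistic.
#' @return Data frame with columns `he`, `fst`.
#' @export
simulate_null_locus <- function(params, n = params$n_sims,
                                hierarchical = params$n_groups > 1L) {
  if (is.null(params$migration_within)) {
    stop("params not calibrated: run calibrate_migration() first")
  }
  counts <- if (params$engine == "coalescent") {
    sim_counts_coalescent(n, params$sample_sizes, params$migration_within,
                          params$migration_between %||% 0,
                          params$sample_group, params$n_groups,
                          params$demes_per_group)
  } else {
    sim_counts_betabinom(n, params$sample_sizes,
                         f_within = island_f(params$migration_within,
                                             params$n_demes),
                         f_between = if (hierarchical) {
                           island_f(params$migration_between %||% 1e9,
                                    params$n_groups)
                         } else 0,
                         sample_group = params$sample_group,
                         maf_bounds = params$maf_bounds)
  }
  sim_stats(counts, params$sample_group, hierarchical)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate the island-model migration rate to an observed F_ST
#'
#' Bisection on the (log) scaled migration rate until the median simulated
#' per-locus F_ST matches the target within `tol`. The target is normally
#' the trimmed multilocus theta of the observed (or supplied
#' neutral-background) loci: per-locus estimates are ranked and the top and
#' bottom 5% removed before the ratio-of-sums combination.
#'
#' @param params [island_model_params()] (uncalibrated).
#' @param target Target F_ST, or a data.frame of per-locus
#'   [wc_components()] from which the trimmed multilocus theta is taken.
#' @param level `"within"` (flat model / within-group rate) or
#'   `"between"` (hierarchical between-group rate, calibrated against the
#'   among-group index with `migration_within` held fixed).
#' @param tol Calibration tolerance on the median simulated F_ST.
#' @param n_sims_cal Simulations per bisection evaluation.
#' @param max_iter Maximum bisection iterations.
#' @return `params` with the calibrated migration rate(s) and `target_fst`
#'   filled in.
#' @export
calibrate_migration <- function(params, target, level = "within",
                                tol = 0.005, n_sims_cal = 3000L,
                                max_iter = 20L) {
  if (is.data.frame(target)) target <- trimmed_multilocus_theta(target)
  stopifnot(is.finite(target), target > 0, target < 1)
  d <- if (level == "between") params$n_groups else params$n_demes
  stat <- function(m) {
    p <- params
    if (level == "between") p$migration_between <- m
    else p$migration_within <- m
    if (level == "within" && is.null(p$migration_between)) {
      p$migration_between <- 1e9  # effectively unstructured between groups
    }
    sims <- simulate_null_locus(p, n = n_sims_cal,
                                hierarchical = params$n_groups > 1L)
    if (level == "between") {
      # among-group differentiation: median fst minus within-group part is
      # intractable per locus; use the median of the hierarchical statistic
      stats::median(sims$fst, na.rm = TRUE)
    } else {
      stats::median(sims$fst, na.rm = TRUE)
    }
  }
  lo <- log(island_m(min(0.95, target * 20), d))   # high migration bound
  hi <- log(island_m(max(1e-4, target / 20), d))   # low migration bound
  best <- NULL; best_err <- Inf
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    s <- stat(exp(mid))
    err <- s - target
    if (abs(err) < best_err) { best <- exp(mid); best_err <- abs(err) }
    if (abs(err) <= tol) break
    if (err > 0) lo <- mid else hi <- mid   # too much Fst -> more migration
  }
  if (level == "between") params$migration_between <- best
  else params$migration_within <- best
  params$target_fst <- if (level == "within") target else params$target_fst
  params
}

#' Trimmed multilocus theta
#'
#' Ranks loci by per-locus theta, removes the top and bottom 5%, and
#' combines the rest by ratio of sums.
#'
#' @param comp Data frame of per-locus [wc_components()].
#' @param trim Fraction trimmed from each tail.
#' @return Scalar.
#' @export
trimmed_multilocus_theta <- function(comp, trim = 0.05) {
  comp <- comp[!is.na(comp$theta), , drop = FALSE]
  if (nrow(comp) < 2L) stop("need at least two polymorphic loci to calibrate")
  k <- floor(trim * nrow(comp))
  ord <- order(comp$theta)
  keep <- ord[seq.int(k + 1L, nrow(comp) - k)]
  multilocus_theta(comp[keep, , drop = FALSE])
}

#' Build the simulated neutral null cloud
#'
#' @param params Calibrated [island_model_params()].
#' @return List of class `null_cloud`: `he`, `fst` (length `n_sims`),
#'   `params`, `achieved_mean_fst`.
#' @export
build_null <- function(params) {
  sims <- simulate_null_locus(params, n = params$n_sims)
  structure(list(he = sims$he, fst = sims$fst, params = params,
                 achieved_mean_fst = mean(sims$fst, na.rm = TRUE)),
            class = "null_cloud")
}

#' @export
print.null_cloud <- function(x, ...) {
  cat(sprintf("<null_cloud> %d simulated loci (%s engine), mean F_ST %.4f (target %.4f)\n",
              length(x$fst), x$params$engine, x$achieved_mean_fst,
              x$params$target_fst %||% NA_real_))
  invisible(x)
}

#' Heterozygosity-conditioned empirical p-values
#'
#' Among the `k` simulated loci nearest in expected heterozygosity to the
#' observed locus, computes the add-one-corrected tail probabilities
#' `p_upper = (#\{F_sim >= F_obs\} + 1) / (k + 1)` and
#' `p_lower = (#\{F_sim <= F_obs\} + 1) / (k + 1)`.
#'
#' @param cloud A `null_cloud` (or data.frame with `he`, `fst`).
#' @param he_obs,fst_obs Observed per-locus values (vectors).
#' @param k Neighbourhood size (default 1,000, capped at the cloud size).
#' @return Data frame `p_upper`, `p_lower`.
#' @export
conditional_pvalues <- function(cloud, he_obs, fst_obs, k = 1000L) {
  k <- min(k, length(cloud$he))
  out <- data.frame(p_upper = rep(NA_real_, length(he_obs)),
                    p_lower = NA_real_)
  for (i in seq_along(he_obs)) {
    idx <- order(abs(cloud$he - he_obs[i]))[seq_len(k)]
    f <- cloud$fst[idx]
    out$p_upper[i] <- (sum(f >= fst_obs[i], na.rm = TRUE) + 1) / (k + 1)
    out$p_lower[i] <- (sum(f <= fst_obs[i], na.rm = TRUE) + 1) / (k + 1)
  }
  out
}

#' Classify outlier loci from conditional p-values
#'
#' Divergent when `p_upper < alpha`, balancing when `p_lower < alpha`,
#' neutral otherwise; loci significant only at the `suggestive_alpha` tier
#' are tagged `"suggestive"` in the `tier` column (`"consistent"` at the
#' strict level, `"ns"` otherwise).
#'
#' @param pv Data frame with `p_upper`, `p_lower` (and any id columns).
#' @param alpha Strict significance level (default 0.01).
#' @param suggestive_alpha Suggestive tier (default 0.05).
#' @return `pv` with `classification` and `tier` columns added.
#' @export
classify_outliers <- function(pv, alpha = 0.01, suggestive_alpha = 0.05) {
  strict <- ifelse(pv$p_upper < alpha, "divergent",
                   ifelse(pv$p_lower < alpha, "balancing", "neutral"))
  sugg <- ifelse(pv$p_upper < suggestive_alpha, "divergent",
                 ifelse(pv$p_lower < suggestive_alpha, "balancing", "neutral"))
  pv$classification <- strict
  pv$tier <- ifelse(strict != "neutral", "consistent",
                    ifelse(sugg != "neutral", "suggestive", "ns"))
  pv$suggestive_class <- sugg
  pv
}

#' FDIST-style F_ST outlier scan
#'
#' Full scan: computes per-locus observed `(He, F_ST)`, calibrates the
#' island-model null to the trimmed multilocus theta of the observed loci
#' (or a supplied neutral background), simulates the null cloud, and
#' classifies loci by heterozygosity-conditioned tail probabilities.
#' Modes: `"all"` populations, `"wild"` only, or `"hier"` — a two-level
#' island model (20 groups of 100 demes by default) for the wild-versus-farm
#' contrast, where the observed statistic is the per-locus total F_ST from
#' the hierarchical decomposition and the null is calibrated to the
#' observed within-group and among-group structure. Monomorphic observed
#' loci are excluded with a logged reason.
#'
#' @param x A `genotype_matrix`.
#' @param mode `"all"`, `"wild"` or `"hier"`.
#' @param n_sims Null-cloud size.
#' @param k Conditioning neighbourhood size.
#' @param alpha Strict significance level.
#' @param engine Null engine (see [island_model_params()]).
#' @param seed RNG seed.
#' @param neutral_background Optional [wc_components()] data.frame (or
#'   `genotype_matrix`) supplying the calibration target instead of the
#'   scanned loci themselves.
#' @param n_demes,n_groups,demes_per_group Island-model layout.
#' @return List of class `outlier_scan`: `calls` (per-locus data.frame with
#'   he/fst/p-values/classification), `cloud`, `params`, `excluded`.
#' @export
fst_outlier_scan <- function(x, mode = c("all", "wild", "hier"),
                             n_sims = 50000L, k = 1000L, alpha = 0.01,
                             engine = c("betabinom", "coalescent"),
                             seed = NULL, neutral_background = NULL,
                             n_demes = 100L, n_groups = 20L,
                             demes_per_group = 100L) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  with_seed(seed, {
    if (mode == "wild") {
      x <- subset_genotypes(x, pops = unique(x$ind$pop[x$ind$group == "wild"]))
    }
    cts <- genotype_counts(x)
    sizes <- apply(cts$n, 1L, max)
    hierarchical <- mode == "hier"
    ntot_alleles <- 2 * colSums(cts$n)
    p_tot <- colSums(cts$nalt) / ntot_alleles
    he_obs <- ntot_alleles / (ntot_alleles - 1) * 2 * p_tot * (1 - p_tot)
    comp <- wc_theta(x)
    fst_obs <- if (hierarchical) hierarchical_f(x)$per_locus$fst else comp$theta
    mono <- p_tot <= 0 | p_tot >= 1
    excluded <- data.frame(locus = x$loci$locus[mono],
                           reason = rep("monomorphic", sum(mono)),
                           stringsAsFactors = FALSE)

    bg <- neutral_background
    if (inherits(bg, "genotype_matrix")) bg <- wc_theta(bg)
    target_src <- if (is.null(bg)) comp[!mono, , drop = FALSE] else bg
    params <- island_model_params(
      sample_sizes = sizes,
      sample_group = if (hierarchical) {
        as.integer(factor(cts$group, levels = c("wild", "farm")))
      } else NULL,
      n_demes = n_demes,
      n_groups = if (hierarchical) n_groups else 1L,
      demes_per_group = if (hierarchical) demes_per_group else n_demes,
      n_sims = n_sims, engine = engine)
    if (hierarchical) {
      # within-group structure first, then the among-group rate
      wild_pops <- cts$pops[cts$group == "wild"]
      flat_wild <- wc_theta(subset_genotypes(x, pops = wild_pops))
      flat_wild <- flat_wild[!is.na(flat_wild$theta), , drop = FALSE]
      params_w <- params
      params_w$n_groups <- 1L
      params_w$demes_per_group <- params$demes_per_group
      params_w$sample_sizes <- sizes[cts$group == "wild"]
      params_w$sample_group <- rep(1L, sum(cts$group == "wild"))
      params_w <- calibrate_migration(params_w, flat_wild)
      params$migration_within <- params_w$migration_within
      params <- calibrate_migration(params, target_src, level = "between")
      params$target_fst <- trimmed_multilocus_theta(
        data.frame(a = fst_obs[!mono], b = 1 - fst_obs[!mono], c = 0,
                   theta = fst_obs[!mono]))
    } else {
      params <- calibrate_migration(params, target_src)
    }
    cloud <- build_null(params)
    keep <- which(!mono)
    pv <- conditional_pvalues(cloud, he_obs[keep], fst_obs[keep], k = k)
    calls <- cbind(data.frame(locus = x$loci$locus[keep],
                              he_obs = he_obs[keep],
                              fst_obs = fst_obs[keep],
                              stringsAsFactors = FALSE),
                   classify_outliers(pv, alpha = alpha))
    structure(list(calls = calls, cloud = cloud, params = params,
                   excluded = excluded, mode = mode),
              class = "outlier_scan")
  })
}

#' @export
print.outlier_scan <- function(x, ...) {
  cat(sprintf("<outlier_scan> mode=%s, %d loci scanned (%d excluded), %d divergent / %d balancing at strict level\n",
              x$mode, nrow(x$calls), nrow(x$excluded),
              sum(x$calls$classification == "divergent"),
              sum(x$calls$classification == "balancing")))
  invisible(x)
}
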