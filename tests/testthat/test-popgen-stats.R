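test_that("unbiased expected heterozygosity matches the closed form", {
  expect_equal(expected_het_unbiased(0.5, 10), 20 / 19 * 0.5,
               tolerance = 1e-12)
  expect_equal(round(expected_het_unbiased(0.5, 10), 5), 0.52632)
  expect_equal(round(expected_het_unbiased(0.1, 10), 5), 0.18947)
  expect_equal(expected_het_unbiased(0, 10), 0)
  expect_equal(expected_het_unbiased(1, 25), 0)
  expect_equal(expected_het_unbiased(0.5, 10, unbiased = FALSE), 0.5)
})

test_that("F_IS reflects heterozygote deficit and excess", {
  expect_equal(fis(0.3, 0.3), 0)
  expect_equal(fis(0, 0.4), 1)
  expect_lt(fis(0.5, 0.4), 0)     # heterozygote excess
  expect_true(is.na(fis(0, 0)))   # monomorphic: undefined
})

test_that("exact HWE test equals Levene enumeration on the worked cases", {
  expect_equal(hwe_exact_p(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact_p(0, 2, 0), 1, tolerance = 1e-12)
  expect_equal(hwe_exact_p(5, 0, 0), 1)
  expect_equal(hwe_exact_p(0, 0, 7), 1)
})

test_that("exact HWE test equals exhaustive enumeration for all 2n <= 20", {
  worst <- 0
  for (n in 1:10) {
    for (nA in 0:(2 * n)) {
      hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
      for (h in hs) {
        nAA <- (nA - h) / 2
        naa <- n - nAA - h
        got <- hwe_exact_p(nAA, h, naa)
        want <- oracle_hwe_p(nAA, h, naa)
        worst <- max(worst, abs(got - want))
      }
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("mid-p variant subtracts half the observed configuration", {
  expect_equal(hwe_exact_p(1, 0, 1, midp = TRUE), 1 / 3 - 0.5 * 1 / 3,
               tolerance = 1e-12)
})

test_that("Weir-Cockerham theta is 1 for fixed opposite populations", {
  gm <- make_gm(rbind(matrix(2L, 10, 1), matrix(0L, 10, 1)),
                pop = rep(c("P1", "P2"), each = 10))
  expect_equal(wc_theta(gm)$theta, 1)
})

test_that("theta is centred on zero for a panmictic pool", {
  set.seed(7)
  p <- runif(10000, 0.1, 0.9)
  n <- matrix(30L, 10000, 2)
  naa <- matrix(rbinom(20000, 30, rep(p, 2)^2), ncol = 2)
  nhet <- matrix(rbinom(20000, 30 - naa,
                        pmin(1, 2 * p * (1 - p) / (1 - p^2))), ncol = 2)
  nalt <- 2L * naa + nhet
  comp <- wc_components(n, nalt, nhet)
  expect_lt(abs(sum(comp$a) / sum(comp$a + comp$b + comp$c)), 0.005)
})

test_that("components equal an independently coded nested-ANOVA estimator", {
  set.seed(8)
  for (rep in 1:20) {
    r <- sample(3:16, 1)
    n <- sample(5:30, r, replace = TRUE)
    p <- runif(r, 0.05, 0.95)
    naa <- rbinom(r, n, p^2)
    nhet <- rbinom(r, n - naa, pmin(1, 2 * p * (1 - p) / (1 - p^2)))
    nalt <- 2L * naa + nhet
    got <- wc_components(matrix(n, 1), matrix(nalt, 1), matrix(nhet, 1))
    want <- oracle_flat_anova(n, nalt, nhet)
    expect_equal(got$a, want$a, tolerance = 1e-10)
    expect_equal(got$b, want$b, tolerance = 1e-10)
    expect_equal(got$c, want$c, tolerance = 1e-10)
  }
})

test_that("multilocus theta is the ratio of sums, not the mean of ratios", {
  comp <- data.frame(a = c(0.1, 0.3), b = c(0.2, 0.1), c = c(0.2, 0.4))
  comp$theta <- comp$a / (comp$a + comp$b + comp$c)
  expect_equal(multilocus_theta(comp), 0.4 / 1.3, tolerance = 1e-12)
  one <- comp[1, ]
  expect_equal(multilocus_theta(one), one$theta)
})

test_that("theta is invariant under allele relabeling and pop permutation", {
  pan <- gen_structured_panel(seed = 51)
  gm <- pan$matrix
  t1 <- wc_theta(gm)$theta
  flipped <- gm
  flipped$geno <- 2L - flipped$geno
  t2 <- wc_theta(flipped)$theta
  expect_equal(t2, t1, tolerance = 1e-12)
  perm <- sample(nrow(gm$geno))
  permuted <- genotype_matrix(gm$loci, gm$ind[perm, ], gm$geno[perm, ])
  expect_equal(multilocus_theta(permuted), multilocus_theta(gm),
               tolerance = 1e-12)
})

test_that("Balding-Nichols panels recover the generating F", {
  for (f in c(0.02, 0.10)) {
    thetas <- vapply(1:5, function(s) {
      cfg <- panel_sim_config(
        pop_sizes = setNames(rep(25L, 16), paste0("P", 1:16)),
        n_loci = 200L, background_f = f,
        frac_divergent = 0, frac_balancing = 0)
      multilocus_theta(gen_structured_panel(cfg, seed = 700 + s)$matrix)
    }, 0)
    expect_lt(max(abs(thetas - f)), 0.02)
  }
})

test_that("pairwise F_ST is symmetric, zero on the diagonal, near zero for a duplicated population", {
  set.seed(61)
  g1 <- matrix(rbinom(25 * 8, 2, 0.4), 25, 8)
  g2 <- matrix(rbinom(25 * 8, 2, 0.4), 25, 8)
  gm <- make_gm(rbind(g1, g2), pop = rep(c("P1", "P2"), each = 25))
  m <- pairwise_fst(gm)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), c(0, 0))
  expect_lt(abs(m["P1", "P2"]), 0.03)
})

test_that("pairwise F_ST grows with simulated divergence", {
  fsts <- vapply(c(0.02, 0.1, 0.25), function(f) {
    cfg <- panel_sim_config(pop_sizes = setNames(rep(25L, 2), c("A", "B")),
                            n_loci = 100L, background_f = f,
                            frac_divergent = 0, frac_balancing = 0)
    pan <- gen_structured_panel(cfg, seed = 71)
    pairwise_fst(pan$matrix)["A", "B"]
  }, 0)
  expect_true(all(diff(fsts) > 0))
})

test_that("hierarchical F_CT is near zero for identical groups and one for fixed group difference", {
  set.seed(81)
  p <- runif(40, 0.2, 0.8)
  geno <- vapply(p, function(pp) rbinom(100, 2, pp), integer(100))
  gm <- make_gm(geno, pop = rep(paste0("P", 1:4), each = 25),
                group = rep(c("wild", "farm"), each = 50))
  h <- hierarchical_f(gm)
  expect_lt(abs(h$fct), 0.01)
  expect_lt(abs(h$fsc), 0.01)

  gm2 <- make_gm(cbind(rep(c(0L, 2L), each = 20)),
                 pop = rep(paste0("P", 1:4), each = 10),
                 group = rep(c("wild", "farm"), each = 20))
  h2 <- hierarchical_f(gm2)
  expect_equal(h2$fct, 1)
})

test_that("hierarchical components sum to the total variance", {
  pan <- gen_structured_panel(seed = 91)
  h <- hierarchical_f(pan$matrix)
  per <- h$per_locus
  tot <- per$sig_a + per$sig_b + per$sig_c + per$sig_d
  # total variance of an allele indicator: p(1-p) scale; must be positive
  # for polymorphic loci and decompose exactly into the four components
  expect_true(all(tot[!is.na(per$fst)] > 0))
  expect_equal(per$fct + (1 - per$fct) * per$fsc, per$fst, tolerance = 1e-9)
})

test_that("locus summary has the panel report schema", {
  pan <- gen_structured_panel(seed = 95)
  gm <- pan$matrix
  gm$geno[, 1] <- 0L  # force a monomorphic locus
  s <- locus_summary(gm)
  expect_named(s, c("locus", "na_mean", "he_mean", "fst_all", "fst_wild",
                    "fct_farm_wild"))
  expect_equal(s$na_mean[1], 1)
  expect_equal(s$he_mean[1], 0)
  expect_true(is.na(s$fst_all[1]))
  expect_true(all(s$na_mean >= 1 & s$na_mean <= 2))
  expect_true(all(s$he_mean >= 0 & s$he_mean <= 1))
})

test_that("per-population statistics respect their invariants", {
  pan <- gen_structured_panel(seed = 97)
  gm <- gen_missingness(pan$matrix, rate = 0.05, seed = 98)
  s <- locus_pop_stats(gm)
  expect_true(all(s$ho >= 0 & s$ho <= 1, na.rm = TRUE))
  expect_true(all(s$he >= 0 & s$he <= 1, na.rm = TRUE))
  expect_true(all(s$maf <= 0.5 + 1e-12, na.rm = TRUE))
  mono <- s$he == 0
  expect_true(all(is.na(s$fis[mono])))
  expect_true(all(s$hwe_p[mono] == 1, na.rm = TRUE))
})

test_that("5% missingness leaves multilocus theta unbiased", {
  cfg <- panel_sim_config(pop_sizes = setNames(rep(25L, 16), paste0("P", 1:16)),
                          n_loci = 300L, background_f = 0.1,
                          frac_divergent = 0, frac_balancing = 0)
  pan <- gen_structured_panel(cfg, seed = 99)
  full <- multilocus_theta(pan$matrix)
  masked <- multilocus_theta(gen_missingness(pan$matrix, 0.05, seed = 100))
  expect_lt(abs(masked - full), 0.01)
})
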