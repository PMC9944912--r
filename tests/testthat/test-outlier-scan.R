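flat_params <- function(n_sims = 3000, engine = "betabinom", sizes = rep(20L, 8)) {
  p <- island_model_params(sizes, n_demes = 100, n_sims = n_sims,
                           engine = engine)
  p$migration_within <- nsvatlas:::island_m(0.05, 100)
  p
}

test_that("null draws are reproducible bit-exactly under a fixed seed", {
  p <- flat_params()
  set.seed(42); a <- simulate_null_locus(p, n = 500)
  set.seed(42); b <- simulate_null_locus(p, n = 500)
  expect_identical(a, b)
  pc <- flat_params(engine = "coalescent")
  set.seed(43); ca <- simulate_null_locus(pc, n = 50)
  set.seed(43); cb <- simulate_null_locus(pc, n = 50)
  expect_identical(ca, cb)
})

test_that("simulated null loci are never monomorphic", {
  p <- flat_params()
  set.seed(44)
  s <- simulate_null_locus(p, n = 2000)
  expect_true(all(s$he > 0))
  pc <- flat_params(engine = "coalescent")
  set.seed(45)
  sc <- simulate_null_locus(pc, n = 300)
  expect_true(all(sc$he > 0))
})

test_that("the null cloud honors its requested size and records its mean", {
  p <- flat_params(n_sims = 2000)
  set.seed(46)
  cloud <- build_null(p)
  expect_length(cloud$fst, 2000)
  expect_length(cloud$he, 2000)
  expect_equal(cloud$achieved_mean_fst, mean(cloud$fst, na.rm = TRUE))
})

test_that("calibration hits the target median within tolerance", {
  p <- island_model_params(rep(20L, 8), n_demes = 100, n_sims = 2000)
  set.seed(47)
  p <- calibrate_migration(p, 0.05, n_sims_cal = 3000)
  set.seed(48)
  s <- simulate_null_locus(p, n = 10000)
  expect_gt(median(s$fst), 0.04)
  expect_lt(median(s$fst), 0.06)
  expect_equal(p$target_fst, 0.05)
})

test_that("achieved differentiation falls as migration rises", {
  p <- flat_params()
  meds <- vapply(c(2, 10, 50), function(m) {
    p$migration_within <- m
    set.seed(49)
    median(simulate_null_locus(p, n = 2000)$fst)
  }, 0)
  expect_true(all(diff(meds) < 0))
})

test_that("degenerate single-locus input cannot calibrate", {
  p <- island_model_params(rep(20L, 8), n_sims = 2000)
  one <- data.frame(a = 0.1, b = 0.4, c = 0.5, theta = 0.1)
  expect_error(calibrate_migration(p, one), "two polymorphic loci")
})

test_that("conditional p-values equal a brute-force neighborhood recount", {
  set.seed(50)
  cloud <- list(he = runif(5000, 0.05, 0.5), fst = rbeta(5000, 2, 30))
  he_obs <- c(0.1, 0.3, 0.45)
  fst_obs <- c(0.02, 0.25, 0.08)
  got <- conditional_pvalues(cloud, he_obs, fst_obs, k = 800)
  for (i in 1:3) {
    idx <- order(abs(cloud$he - he_obs[i]))[1:800]
    expect_equal(got$p_upper[i],
                 (sum(cloud$fst[idx] >= fst_obs[i]) + 1) / 801)
    expect_equal(got$p_lower[i],
                 (sum(cloud$fst[idx] <= fst_obs[i]) + 1) / 801)
  }
  # an observation above every neighbour gets the minimum attainable p
  top <- conditional_pvalues(cloud, 0.3, 1, k = 800)
  expect_equal(top$p_upper, 1 / 801)
  expect_equal(top$p_lower, 1)
})

test_that("tail p-values are insensitive to the neighborhood size on a large cloud", {
  p <- flat_params(n_sims = 50000)
  set.seed(51)
  cloud <- build_null(p)
  # decision-relevant points: observations near the conditional 1% tails
  he_obs <- seq(0.1, 0.5, by = 0.05)
  fst_obs <- vapply(he_obs, function(h) {
    idx <- order(abs(cloud$he - h))[1:2000]
    unname(quantile(cloud$fst[idx], 0.99))
  }, 0)
  p500 <- conditional_pvalues(cloud, he_obs, fst_obs, k = 500)
  p2000 <- conditional_pvalues(cloud, he_obs, fst_obs, k = 2000)
  d_up <- abs(p500$p_upper - p2000$p_upper)
  low_obs <- vapply(he_obs, function(h) {
    idx <- order(abs(cloud$he - h))[1:2000]
    unname(quantile(cloud$fst[idx], 0.01))
  }, 0)
  q500 <- conditional_pvalues(cloud, he_obs, low_obs, k = 500)
  q2000 <- conditional_pvalues(cloud, he_obs, low_obs, k = 2000)
  d_lo <- abs(q500$p_lower - q2000$p_lower)
  # typical shift within +-0.005; individual points bounded by the k=500
  # binomial noise floor
  expect_lt(median(c(d_up, d_lo)), 0.005)
  expect_lt(max(c(d_up, d_lo)), 0.015)
})

test_that("classification follows the strict and suggestive tiers", {
  pv <- data.frame(p_upper = c(0.009, 0.5, 0.97, 0.03),
                   p_lower = c(0.992, 0.5, 0.03, 0.98))
  out <- classify_outliers(pv, alpha = 0.01)
  expect_equal(out$classification,
               c("divergent", "neutral", "neutral", "neutral"))
  expect_equal(out$tier, c("consistent", "ns", "suggestive", "suggestive"))
  expect_equal(out$suggestive_class,
               c("divergent", "neutral", "balancing", "divergent"))
})

test_that("monomorphic observed loci are excluded with a reason", {
  pan <- gen_structured_panel(seed = 52)
  gm <- pan$matrix
  gm$geno[, 3] <- 2L
  sc <- fst_outlier_scan(gm, n_sims = 2000, k = 300, seed = 53)
  expect_equal(sc$excluded$locus, "L03")
  expect_equal(sc$excluded$reason, "monomorphic")
  expect_false("L03" %in% sc$calls$locus)
})

test_that("a full scan is reproducible under identical seed and params", {
  pan <- gen_structured_panel(seed = 54)
  a <- fst_outlier_scan(pan$matrix, n_sims = 2000, k = 300, seed = 55)
  b <- fst_outlier_scan(pan$matrix, n_sims = 2000, k = 300, seed = 55)
  expect_identical(a$calls, b$calls)
  expect_identical(a$cloud$fst, b$cloud$fst)
})

test_that("a two-level null with equal migration collapses onto the flat null", {
  sizes <- rep(20L, 8)
  m <- nsvatlas:::island_m(0.05, 100)
  flat <- island_model_params(sizes, n_demes = 100, n_sims = 4000)
  flat$migration_within <- m
  hier <- island_model_params(sizes, n_groups = 4L, demes_per_group = 25L,
                              sample_group = rep(1:4, each = 2), n_sims = 4000)
  # equal within/between migration in the beta-binomial engine: no extra
  # group-level variance
  hier$migration_within <- m
  hier$migration_between <- 1e9
  set.seed(56); sf <- simulate_null_locus(flat, n = 4000)
  set.seed(57); sh <- simulate_null_locus(hier, n = 4000, hierarchical = FALSE)
  expect_lt(abs(median(sf$fst) - median(sh$fst)), 0.01)
  expect_lt(abs(quantile(sf$fst, 0.95) - quantile(sh$fst, 0.95)), 0.02)
})

test_that("hierarchical scan flags a planted group-divergent locus", {
  cfg <- panel_sim_config(n_group_divergent = 2, group_shift = 0.6,
                          frac_divergent = 0, frac_balancing = 0)
  pan <- gen_structured_panel(cfg, seed = 58)
  sc <- fst_outlier_scan(pan$matrix, mode = "hier", n_sims = 5000, k = 500,
                         seed = 59)
  m <- merge(sc$calls, pan$truth, by = "locus")
  planted <- m[m$class == "group_divergent", ]
  expect_true(all(planted$p_upper < 0.05))
  neutral_fpr <- mean(m$classification[m$class == "neutral"] == "divergent")
  expect_lt(neutral_fpr, 0.2)
})

test_that("wild-only mode drops the farm samples before scanning", {
  pan <- gen_structured_panel(seed = 60)
  sc <- fst_outlier_scan(pan$matrix, mode = "wild", n_sims = 2000, k = 300,
                         seed = 61)
  expect_length(sc$params$sample_sizes, 13)
})
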