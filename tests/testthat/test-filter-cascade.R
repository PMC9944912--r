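# shared spiked fixture with planted violations of every rule
cascade_fixture <- function() {
  sim <- gen_annotated_genome(n_chrom = 2, n_genes = 14, seed = 201)
  sp <- spike_variants(sim, spec = list(missense = 10, synonymous = 5,
                                        stop_gained = 2, triallelic = 1,
                                        flank_pair = 1, noncoding = 2,
                                        lowqual = 1, hwe_violation = 1,
                                        low_maf = 1),
                       seed = 202)
  calls <- classify_variants(sp$variants, sim$genes, sim$genome)
  list(sim = sim, sp = sp, calls = calls, gm = spiked_genotype_matrix(sp))
}

test_that("NSV counting covers missense calls only", {
  calls <- data.frame(gene_id = c("g1", "g1", "g1", "g2"),
                      effect_class = c("missense", "missense", "synonymous",
                                       "missense"))
  counts <- count_nsv_per_gene(calls)
  expect_equal(counts[["g1"]], 2L)
  expect_equal(counts[["g2"]], 1L)
  expect_false("g3" %in% names(counts))
})

test_that("pseudogene heuristic drops whole genes with 3+ NSVs", {
  calls <- data.frame(gene_id = c(rep("g1", 3), rep("g2", 2), "g2"),
                      effect_class = c(rep("missense", 5), "synonymous"))
  keep <- pseudogene_filter(calls)
  expect_equal(keep, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("pseudogene survivors equal the brute-force set difference", {
  fx <- cascade_fixture()
  calls <- fx$calls
  keep <- pseudogene_filter(calls)
  mis <- calls[calls$effect_class == "missense", ]
  bad_genes <- names(which(table(mis$gene_id) >= 3))
  expect_equal(keep, !(calls$gene_id %in% bad_genes))
})

test_that("nonsense filter removes stop-gains and flags stop/start loss", {
  calls <- data.frame(gene_id = "g", effect_class =
                        c("stop_gained", "missense", "stop_lost", "start_lost"))
  keep <- nonsense_filter(calls)
  expect_equal(as.logical(keep), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(attr(keep, "nonsense_like"), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("tri-allelic sites are removed", {
  calls <- data.frame(n_alt = c(1L, 2L, 1L))
  expect_equal(triallelic_filter(calls), c(TRUE, FALSE, TRUE))
})

test_that("flanking window is inclusive at the boundary", {
  call <- data.frame(chrom = "chr1", pos = 1000L)
  near <- data.frame(chrom = "chr1", pos = c(1000L, 1050L))
  far <- data.frame(chrom = "chr1", pos = c(1000L, 1101L))
  other_chrom <- data.frame(chrom = c("chr1", "chr2"), pos = c(1000L, 1050L))
  exact <- data.frame(chrom = "chr1", pos = c(1000L, 1100L))
  expect_false(flanking_clear_filter(call, near, 100L))
  expect_true(flanking_clear_filter(call, far, 100L))
  expect_true(flanking_clear_filter(call, other_chrom, 100L))
  expect_false(flanking_clear_filter(call, exact, 100L))
})

test_that("flanking filter equals a brute-force pairwise distance check", {
  set.seed(203)
  av <- data.frame(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                   pos = sample(1:5000, 300))
  calls <- av[sample(300, 60), ]
  got <- flanking_clear_filter(calls, av, 100L)
  want <- vapply(seq_len(nrow(calls)), function(i) {
    d <- abs(av$pos[av$chrom == calls$chrom[i]] - calls$pos[i])
    sum(d <= 100) == sum(d == 0)
  }, TRUE)
  expect_equal(got, want)
})

test_that("HWE filter removes sites below alpha in the discovery cohort", {
  fx <- cascade_fixture()
  calls <- fx$calls
  keep <- hwe_filter(calls, fx$gm, alpha = 0.01)
  viol <- fx$sp$truth[fx$sp$truth$tag == "hwe_violation", ]
  is_viol <- paste(calls$chrom, calls$pos) %in% paste(viol$chrom, viol$pos)
  expect_true(all(!keep[is_viol]))
  # all-heterozygote configuration in 10 diploids: p below 0.01
  expect_lt(hwe_exact_p(0, 10, 0), 0.01)
})

test_that("deleterious filter matches on gene and substitution notation", {
  calls <- data.frame(gene_id = c("g1", "g1", "g2"),
                      notation = c("A44T", "V78I", "A44T"))
  tab <- data.frame(gene_id = c("g1", "g1"), notation = c("A44T", "V78I"),
                    verdict = c("deleterious", "neutral"))
  expect_equal(deleterious_filter(calls, tab), c(FALSE, TRUE, TRUE))
  expect_equal(deleterious_filter(calls, NULL), rep(TRUE, 3))
  expect_error(deleterious_filter(calls,
                                  data.frame(gene_id = "g", notation = "bad1",
                                             verdict = "deleterious")))
})

test_that("marker proximity uses strict < 500 kb and within-gene relations", {
  genes <- data.frame(gene_id = "g", chrom = "chr1",
                      start = 1400000L, end = 1410000L)
  mk <- function(pos) data.frame(marker_id = "m", chrom = "chr1", pos = pos,
                                 categories = "QTL-growth")
  linked <- proximity_link(genes, mk(1000000L))
  expect_equal(nrow(linked), 1L)
  expect_equal(linked$distance_bp, 400000L)
  expect_equal(linked$relation, "lt_500kb")
  expect_equal(nrow(proximity_link(genes, mk(900000L))), 0L)  # exactly 500 kb
  inside <- proximity_link(genes, mk(1405000L))
  expect_equal(inside$relation, "within_gene")
  expect_equal(inside$distance_bp, 0L)
})

test_that("per-gene MAF maximisation keeps the most diverse eligible SNP", {
  gm <- make_gm(
    cbind(c(rep(1L, 2), rep(0L, 8)),      # maf 0.1
          c(rep(1L, 6), rep(0L, 4)),      # maf 0.3
          c(rep(1L, 4), rep(0L, 6)),      # maf 0.2 (tie partner)
          c(rep(1L, 4), rep(0L, 6)),      # maf 0.2
          c(1L, rep(0L, 9))),             # maf 0.05: ineligible
    pop = rep("D", 10))
  gm$loci$chrom <- "chr1"
  gm$loci$pos <- c(100L, 200L, 400L, 300L, 500L)
  calls <- data.frame(chrom = "chr1", pos = gm$loci$pos,
                      gene_id = c("g1", "g1", "g2", "g2", "g3"))
  keep <- maf_top_per_gene(calls, gm, maf_min = 0.10)
  # g1: maf 0.3 wins; g2: tie 0.2/0.2 broken by smaller position (300)
  expect_equal(keep, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  # boundary: maf exactly 0.10 is eligible
  expect_true(any(keep[1:2]))
})

test_that("the cascade ledger is monotone, consistent and fully reasoned", {
  fx <- cascade_fixture()
  res <- run_cascade(fx$calls, genotypes = fx$gm,
                     markers = data.frame(marker_id = "m1", chrom = "chr1",
                                          pos = 500L,
                                          categories = "QTL-growth"),
                     deleterious = NULL,
                     all_variants = fx$sp$variants)
  led <- res$ledger
  expect_true(all(led$count_out <= led$count_in))
  expect_equal(led$count_in[-1], led$count_out[-nrow(led)])
  expect_equal(led$count_in[1], nrow(fx$calls))
  expect_equal(led$count_out[nrow(led)], nrow(res$panel))
  expect_equal(led$drop_pct,
               round(100 * (led$count_in - led$count_out) / led$count_in, 1))
  # every removed call carries exactly one first-failure reason, and the
  # per-reason counts reconcile with the ledger deltas
  expect_equal(nrow(res$removed) + nrow(res$panel), nrow(fx$calls))
  deltas <- setNames(led$count_in - led$count_out, led$step)
  reasons <- table(res$removed$reason)
  for (step in names(deltas)[deltas > 0]) {
    expect_equal(unname(reasons[[step]]), unname(deltas[[step]]))
  }
})

test_that("planted rule violations fail at their first failing step", {
  fx <- cascade_fixture()
  res <- run_cascade(fx$calls, genotypes = fx$gm, markers = NULL,
                     deleterious = NULL, all_variants = fx$sp$variants)
  rm_key <- paste(res$removed$chrom, res$removed$pos, res$removed$alt)
  reason_of <- function(tag) {
    tr <- fx$sp$truth[fx$sp$truth$tag == tag, ]
    res$removed$reason[match(paste(tr$chrom, tr$pos, sub(",.*", "", tr$alts)),
                             rm_key)]
  }
  expect_true(all(reason_of("lowqual") == "qual"))
  expect_true(all(reason_of("stop_gained") == "nonsense" |
                    reason_of("stop_gained") == "pseudogene"))
  tri <- reason_of("triallelic")
  expect_true(all(tri %in% c("pseudogene", "triallelic")))
  expect_true(all(reason_of("hwe_violation") %in%
                    c("pseudogene", "flanking", "hwe")))
})

test_that("the cascade is idempotent apart from the flanking step", {
  fx <- cascade_fixture()
  res1 <- run_cascade(fx$calls, genotypes = fx$gm,
                      all_variants = fx$sp$variants)
  # re-running on the surviving panel (flanking judged against the panel
  # itself, as documented) changes nothing
  res2 <- run_cascade(res1$panel, genotypes = fx$gm,
                      all_variants = res1$panel[, c("chrom", "pos")])
  expect_equal(res2$panel, res1$panel, ignore_attr = TRUE)
})

test_that("per-site predicate steps commute (hwe vs triallelic)", {
  fx <- cascade_fixture()
  calls <- fx$calls
  k1 <- triallelic_filter(calls) & hwe_filter(calls, fx$gm, 0.01)
  a <- calls[hwe_filter(calls, fx$gm, 0.01), ]
  k2 <- calls[triallelic_filter(calls), ]
  ab <- a[triallelic_filter(a), ]
  ba <- k2[hwe_filter(k2, fx$gm, 0.01), ]
  expect_equal(ab, ba, ignore_attr = TRUE)
  expect_equal(nrow(ab), sum(k1))
})

test_that("drop percentages use the previous step as denominator", {
  calls <- data.frame(chrom = "chr1", pos = 1:100 * 1000L, ref = "A",
                      alt = "G", gene_id = paste0("g", 1:100),
                      effect_class = "missense", aa_pos = 2L, ref_aa = "A",
                      alt_aa = "T", notation = "A2T", transition = FALSE,
                      qual = c(rep(60, 17), rep(10, 83)), n_alt = 1L)
  res <- run_cascade(calls, genotypes = NULL, markers = NULL,
                     deleterious = NULL)
  qual_row <- res$ledger[res$ledger$step == "qual", ]
  expect_equal(qual_row$count_in, 100L)
  expect_equal(qual_row$count_out, 17L)
  expect_equal(qual_row$drop_pct, 83.0)
})

test_that("an all-clean input passes every step untouched", {
  calls <- data.frame(chrom = "chr1", pos = c(1000L, 5000L), ref = "A",
                      alt = "G", gene_id = c("g1", "g2"),
                      effect_class = "missense", aa_pos = 2L, ref_aa = "A",
                      alt_aa = "T", notation = "A2T", transition = FALSE,
                      qual = 60, n_alt = 1L)
  res <- run_cascade(calls)
  expect_equal(nrow(res$panel), 2L)
  expect_true(all(res$ledger$drop_pct == 0))
})
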