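test_that("epoch subsets follow the membership rules", {
  # all unknown: every subset equals the full set
  snvs <- make_snvs(c(10, 20, 30), epoch = "unknown")
  subs <- build_epoch_subsets(snvs)
  expect_equal(nrow(subs$early), 3L)
  expect_equal(nrow(subs$late), 3L)
  expect_equal(nrow(subs$subclonal), 3L)

  # mixed labels, sizes derived by hand
  snvs <- make_snvs(c(10, 20, 30, 40),
                    epoch = c("early_clonal", "early_clonal",
                              "clonal_unspecified", "subclonal"))
  subs <- build_epoch_subsets(snvs)
  expect_equal(nrow(subs$early), 3L)      # 2 early + 1 unspecified
  expect_equal(nrow(subs$late), 1L)       # 1 unspecified
  expect_equal(nrow(subs$subclonal), 1L)

  subs <- build_epoch_subsets(make_snvs(numeric(0)))
  expect_true(all(vapply(subs, nrow, integer(1)) == 0L))
})

test_that("burden_threshold follows the closed form with its cap", {
  # d* ~ 1231 bp exceeds the 1 kbp cap
  expect_equal(burden_threshold(20000, 3.1e9, 0.01), 1000)
  d_star <- 3.1e9 * 0.01^(1 / 3) / 20000^(4 / 3)
  expect_gt(d_star, 1000)
  # below the cap the closed form is returned as-is
  expect_equal(burden_threshold(1e5, 3.1e9, 0.01),
               3.1e9 * 0.01^(1 / 3) / 1e5^(4 / 3))
  expect_equal(burden_threshold(0), 1000)
  expect_equal(burden_threshold(3), 1000)
  # non-increasing in the SNV burden
  n <- c(10, 100, 1e3, 1e4, 1e5, 1e6)
  thr <- vapply(n, burden_threshold, numeric(1))
  expect_true(all(diff(thr) <= 0))
})

test_that("call_candidates emits maximal runs of >= 4 SNVs under threshold", {
  # 3 tightly spaced SNVs: below the minimum, no candidate
  pos <- c(seq(1e6, by = 1e6, length.out = 20), 5.05e6 + c(0, 100, 200))
  cand <- call_candidates(make_snvs(sort(pos)), "early", genome_length = 3e9)
  expect_equal(nrow(cand), 0L)

  # 6 SNVs spaced 100 bp inside sparse background: exactly one 6-SNV candidate
  pos <- cluster_in_background(n_bg = 60, cluster_size = 6, cluster_gap = 100)
  cand <- call_candidates(make_snvs(pos), "early", genome_length = 3e9)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$n_snvs, 6L)
  expect_equal(cand$span_bp, 501)
  expect_lt(cand$max_adjusted_imd, cand$threshold_bp)
  # member SNVs are the cluster, consecutive in position order
  expect_equal(diff(cand$snvs[[1]]$pos), rep(100, 5))

  expect_equal(nrow(call_candidates(make_snvs(numeric(0)), "early")), 0L)

  # duplicate positions collapse with a count
  pos2 <- c(pos, pos[5])
  cand2 <- call_candidates(make_snvs(sort(pos2)), "early", genome_length = 3e9)
  expect_equal(attr(cand2, "n_duplicates"), 1L)
  expect_equal(nrow(cand2), 1L)
})

test_that("candidates satisfy their own invariants and translation invariance", {
  cfg <- sim_config(n_samples = 2, genome_model = small_genome(),
                    n_events = 6, n_svs = 10)
  sim <- simulate_cohort(cfg, seed = 5)
  cand <- call_kataegis(sim$snvs, genome_length = 1e8)
  expect_true(all(cand$n_snvs >= 4))
  expect_true(all(cand$max_adjusted_imd < cand$threshold_bp))
  expect_true(all(cand$end >= cand$start))

  # shifting every position by a constant shifts candidates, nothing else
  shifted <- data.table::copy(sim$snvs)[, pos := pos + 5000]
  cand_s <- call_kataegis(shifted, genome_length = 1e8)
  expect_equal(cand_s$start, cand$start + 5000)
  expect_equal(cand_s$n_snvs, cand$n_snvs)
  expect_equal(cand_s$epoch_tag, cand$epoch_tag)

  # determinism: identical input, identical output
  cand2 <- call_kataegis(sim$snvs, genome_length = 1e8)
  expect_identical(cand[, !"snvs"], cand2[, !"snvs"])
})

test_that("dedup_early_late keeps the larger of SNV-sharing pairs", {
  shared <- make_snvs(c(1000, 1200, 1400, 1600), epoch = "clonal_unspecified")
  early_extra <- make_snvs(c(600, 800), epoch = "early_clonal")
  e_cand <- make_candidate(rbind(early_extra, shared), epoch_tag = "early")
  l_cand <- make_candidate(shared, epoch_tag = "late", event_id = "K0002")

  # early has 6 members, late 4, sharing 4 unspecified: late dropped
  dd <- dedup_early_late(e_cand, l_cand)
  expect_equal(nrow(dd$candidates), 1L)
  expect_equal(dd$candidates$epoch_tag, "early")
  expect_equal(dd$n_epoch_duplicates_removed, 1L)

  # tie on size: early retained
  e_tie <- make_candidate(shared, epoch_tag = "early")
  l_tie <- make_candidate(shared, epoch_tag = "late", event_id = "K0002")
  dd <- dedup_early_late(e_tie, l_tie)
  expect_equal(dd$candidates$epoch_tag, "early")

  # no shared SNVs anywhere: union unchanged
  l_far <- make_candidate(make_snvs(c(9e6, 9.0002e6, 9.0004e6, 9.0006e6),
                                    epoch = "late_clonal"),
                          epoch_tag = "late", event_id = "K0003")
  dd <- dedup_early_late(e_cand, l_far)
  expect_equal(nrow(dd$candidates), 2L)
  expect_equal(dd$n_epoch_duplicates_removed, 0L)
  expect_false(any(dd$candidates$sequential_pair))

  # overlapping spans without shared SNVs: both kept, flagged sequential
  inter <- make_snvs(c(1100, 1300, 1500, 1700), epoch = "late_clonal")
  l_seq <- make_candidate(inter, epoch_tag = "late", event_id = "K0004")
  dd <- dedup_early_late(e_cand, l_seq)
  expect_equal(nrow(dd$candidates), 2L)
  expect_true(all(dd$candidates$sequential_pair))
})
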