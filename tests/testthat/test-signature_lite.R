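test_that("build_sbs96 classifies and strand-normalizes", {
  expect_equal(sum(grepl("^[ACGT]\\[C>T\\][ACGT]$", sbs96_classes())), 16L)
  expect_equal(length(unique(sbs96_classes())), 96L)

  # C>T at ACA
  cat1 <- build_sbs96(make_snvs(100, ref = "C", alt = "T", tricontext = "ACA"))
  expect_equal(unname(cat1["A[C>T]A"]), 1L)
  expect_equal(sum(cat1), 1L)
  # G>A at TGT is the reverse strand of the same class
  cat2 <- build_sbs96(make_snvs(100, ref = "G", alt = "A", tricontext = "TGT"))
  expect_equal(cat2, cat1)

  # 10-SNV hand table
  snvs <- make_snvs(1:10 * 100,
                    ref = c("C", "C", "C", "T", "G", "G", "A", "T", "C", "C"),
                    alt = c("T", "T", "G", "A", "A", "C", "G", "C", "A", "T"),
                    tricontext = c("TCA", "TCT", "TCA", "ATA", "TGT", "AGA",
                                   "CAC", "GTG", "CCC", "GCG"))
  cat10 <- build_sbs96(snvs)
  expect_equal(sum(cat10), 10L)
  want <- c("T[C>T]A" = 1L, "T[C>T]T" = 1L, "T[C>G]A" = 1L, "A[T>A]A" = 1L,
            "A[C>T]A" = 1L, "T[C>G]T" = 1L, "G[T>C]G" = 2L,
            "C[C>A]C" = 1L, "G[C>T]G" = 1L)
  for (k in names(want)) expect_equal(unname(cat10[k]), unname(want[k]), label = k)

  # N context skipped with count; missing context errors
  catN <- suppressMessages(build_sbs96(
    make_snvs(c(1, 2), ref = "C", alt = "T", tricontext = c("ACA", "NCA"))))
  expect_equal(sum(catN), 1L)
  expect_equal(attr(catN, "n_skipped"), 1L)
  expect_error(build_sbs96(make_snvs(1, ref = "C", alt = "T")), "context")
  expect_error(build_sbs96(make_snvs(1, ref = "C", alt = "T", tricontext = "ATA")),
               "disagrees")
})

test_that("build_sv32 bins sizes and assigns clustering by breakend spacing", {
  expect_equal(length(sv32_classes()), 32L)

  # a single isolated 50 kb deletion
  cat1 <- build_sv32(make_svs(1e6, pos2 = 1e6 + 5e4))
  expect_equal(unname(cat1["DEL:10-100kb:non-clustered"]), 1L)
  expect_equal(sum(cat1), 1L)

  # 10 TRAs with chr1 breakends packed within 100 kb amid scattered SVs
  tras <- make_svs(seq(5e6, by = 1e3, length.out = 10), chrom2 = "chr9",
                   pos2 = seq(1e6, by = 3e6, length.out = 10), sv_type = "TRA")
  bg <- make_svs(seq(1e7, by = 5e6, length.out = 12),
                 pos2 = seq(1e7, by = 5e6, length.out = 12) + 5e4)
  cat2 <- build_sv32(rbind(tras, bg), cluster_quantile = 0.3)
  expect_equal(unname(cat2["TRA:clustered"]), 10L)
  expect_equal(sum(cat2), 22L)

  # COMPLEX is excluded with a count; catalog sum tracks the rest
  cx <- make_svs(2e6, pos2 = 3e6, sv_type = "COMPLEX")
  cat3 <- build_sv32(rbind(make_svs(1e6, pos2 = 1e6 + 5e4), cx))
  expect_equal(sum(cat3), 1L)
  expect_equal(attr(cat3, "n_skipped"), 1L)
})

test_that("fit_exposures recovers constructed mixtures and applies the cosine rule", {
  ref <- synthetic_signature_reference()
  expect_equal(colSums(ref), c(SBS1 = 1, SBS2 = 1, SBS5 = 1, SBS13 = 1))

  # pure signature: exact representation
  fit <- fit_exposures(100 * ref[, "SBS2"], ref)
  expect_equal(unname(fit$exposures["SBS2"]), 100, tolerance = 1e-6)
  expect_equal(sum(fit$exposures[c("SBS1", "SBS5", "SBS13")]), 0, tolerance = 1e-6)
  expect_equal(fit$cosine, 1, tolerance = 1e-9)
  expect_false(fit$excluded)

  # noiseless 70/30 mixture recovered within 1%
  mix <- 70 * ref[, "SBS2"] + 30 * ref[, "SBS5"]
  fit <- fit_exposures(mix, ref)
  expect_equal(unname(fit$exposures["SBS2"]), 70, tolerance = 0.01)
  expect_equal(unname(fit$exposures["SBS5"]), 30, tolerance = 0.01)

  # catalog concentrated where every reference signature is flat/absent:
  # poor reconstruction, excluded by the 0.5 cosine rule
  odd <- stats::setNames(numeric(96), sbs96_classes())
  odd["A[T>A]A"] <- 100
  fit <- fit_exposures(odd, ref[, c("SBS2", "SBS13")])
  expect_lt(fit$cosine, 0.5)
  expect_true(fit$excluded)

  # NNLS sanity: exposures non-negative, residual never beats the zero fit
  set.seed(4)
  for (r in 1:20) {
    catal <- rmultinom(1, 300, ref %*% runif(4))[, 1]
    fit <- fit_exposures(catal, ref)
    expect_true(all(fit$exposures >= 0))
    expect_lte(sum((catal - fit$reconstruction)^2), sum(catal^2) + 1e-8)
  }
  expect_error(fit_exposures(1:10, ref), "dimension")
})

test_that("apobec_summary computes fractions and cohort medians", {
  ex <- data.frame(sample = c("a", "b"), SBS2 = c(40, 0), SBS13 = c(40, 0),
                   SBS5 = c(20, 50), risk = c("HR", "LR"))
  s <- apobec_summary(ex)
  expect_equal(s$per_unit$apobec_fraction, c(0.8, 0))
  expect_equal(s$per_unit$sbs2_share, c(0.5, NA))
  expect_equal(s$medians_by_risk[risk == "HR", median_apobec_fraction], 0.8)

  # generator round trip: cohort planted at APOBEC event probability 0.8
  ref <- synthetic_signature_reference()
  cfg <- sim_config(n_samples = 20, genome_model = small_genome(2e8),
                    n_events = 6, n_svs = 0, apobec_event_prob = 0.8)
  sim <- simulate_cohort(cfg, seed = 31)
  # pooled kataegic catalog: APOBEC exposure share tracks the planted rate
  keep <- rep(FALSE, nrow(sim$snvs))
  for (j in seq_len(nrow(sim$truth)))
    keep <- keep | (sim$snvs$sample_id == sim$truth$sample_id[j] &
                      sim$snvs$chrom == sim$truth$chrom[j] &
                      sim$snvs$pos >= sim$truth$start[j] &
                      sim$snvs$pos <= sim$truth$end[j])
  fit <- fit_exposures(build_sbs96(sim$snvs[keep]), ref)
  frac <- unname((fit$exposures["SBS2"] + fit$exposures["SBS13"]) /
                   sum(fit$exposures))
  snv_apobec <- sum(sim$truth[apobec == TRUE, n_snvs]) / sum(sim$truth$n_snvs)
  expect_lt(abs(frac - snv_apobec), 0.1)
})
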