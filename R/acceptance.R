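## Validation harness: each function recomputes one cohort-independent
## performance quantity from scratch on synthetic data. The thresholds
## themselves live in the test suite; these functions only measure.

# exhaustive-search PCF oracle, independent of the DP implementation
.brute_pcf_cost <- function(x, gamma, kmin = 1L) {
  n <- length(x)
  best <- Inf
  for (m in 0:(2^(n - 1) - 1)) {
    bp <- which(bitwAnd(m, 2^(0:(n - 2))) > 0)
    starts <- c(1, bp + 1)
    ends <- c(bp, n)
    if (any(ends - starts + 1 < kmin)) next
    sse <- sum(mapply(function(s, e) sum((x[s:e] - mean(x[s:e]))^2), starts, ends))
    cost <- sse + gamma * (length(starts) - 1)
    if (cost < best) best <- cost
  }
  best
}

#' Acceptance check: exact-PCF oracle agreement
#'
#' Compares the dynamic-programming cost against exhaustive enumeration on
#' random series (length <= 12, values U(0, 10), gamma in {0.5, 5, 50}).
#'
#' @param n_series Number of random series (default 200).
#' @param seed RNG seed.
#' @return List: `agreement_pct`, `n`.
#' @export
acceptance_pcf_oracle <- function(n_series = 200L, seed = 1L) {
  set.seed(as.integer(seed))
  ok <- 0L
  for (r in seq_len(n_series)) {
    n <- sample(4:12, 1)
    x <- stats::runif(n, 0, 10)
    gamma <- sample(c(0.5, 5, 50), 1)
    dp <- exact_pcf(x, gamma, kmin = 1L)$cost
    if (abs(dp - .brute_pcf_cost(x, gamma, 1L)) < 1e-8) ok <- ok + 1L
  }
  list(agreement_pct = 100 * ok / n_series, n = n_series)
}

#' Acceptance check: planted-event recovery
#'
#' Simulates genomes with 1 SNV/Mbp background and 20 planted events each
#' (>= 6 SNVs, member spacing <= 200 bp), runs the epoch-stratified caller,
#' and scores sensitivity and precision against the planted truth.
#'
#' @param n_genomes Number of simulated genomes (default 50).
#' @param seed RNG seed.
#' @return List: `sensitivity`, `precision`, `n` (planted events).
#' @export
acceptance_planted_recovery <- function(n_genomes = 50L, seed = 1L) {
  cfg <- sim_config(n_samples = n_genomes, n_events = 20L,
                    size_range = c(6L, 33L), max_gap = 200L, n_svs = 40L,
                    background_rate = 1e-6)
  sim <- simulate_cohort(cfg, seed = seed)
  cand <- call_kataegis(sim$snvs)
  tm <- truth_match(cand, sim$truth, sim$snvs)
  list(sensitivity = tm$sensitivity, precision = tm$precision,
       n = nrow(sim$truth))
}

#' Acceptance check: null false-call control
#'
#' Background-only genomes of 10,000 SNVs each; any emitted candidate is a
#' false call.
#'
#' @param n_genomes Number of genomes (default 100).
#' @param seed RNG seed.
#' @param alpha Burden-threshold alpha (default 0.01).
#' @return List: `mean_false_per_genome`, `n`.
#' @export
acceptance_null_control <- function(n_genomes = 100L, seed = 1L, alpha = 0.01) {
  gm <- default_genome_model()
  cfg <- sim_config(n_samples = n_genomes,
                    background_rate = 10000 / sum(gm$length),
                    n_events = 0L, n_svs = 0L)
  sim <- simulate_cohort(cfg, seed = seed)
  cand <- call_kataegis(sim$snvs, alpha = alpha)
  list(mean_false_per_genome = nrow(cand) / n_genomes, n = n_genomes)
}

#' Acceptance check: SV-enrichment calibration under the null
#'
#' In each null cohort the "observed" events are drawn by the same
#' matched-control mechanism as the controls (anchor at a random somatic
#' variant, event-sized span), against a dense SV world chosen so the
#' within-10-kbp cells are large (~0.4 near fraction; 150 deletions on a
#' 10 Mbp chromosome, 182 events as in a cohort-scale run). The within-10-kbp
#' exact test should reject at alpha = 0.05 at close to its nominal rate.
#'
#' @param n_cohorts Number of simulated cohorts (default 1000).
#' @param seed RNG seed.
#' @return List: `rejection_pct`, `n`.
#' @export
acceptance_sv_calibration <- function(n_cohorts = 1000L, seed = 1L) {
  set.seed(as.integer(seed))
  base <- sample.int(2^20, 1L)
  rej <- 0L
  for (r in seq_len(n_cohorts)) {
    set.seed(base + r)
    G <- 1e7
    n_sv <- 150L
    pos1 <- sort(sample.int(G - 6e4, n_sv))
    d <- round(10^stats::runif(n_sv, 3, 4.5))
    svs <- data.table::data.table(sample_id = "S1", chrom1 = "chr1",
                                  pos1 = pos1, chrom2 = "chr1",
                                  pos2 = pos1 + d, sv_type = "DEL",
                                  size_bp = d)
    pool <- data.table::data.table(sample_id = "S1", chrom = "chr1",
                                   pos = sample.int(G, 2000))
    spans <- pmin(round(10^stats::rnorm(182, log10(2700), 0.42)), 35300)
    tmpl <- data.table::data.table(event_id = sprintf("E%03d", 1:182),
                                   sample_id = "S1", start = 1, end = spans)
    obs <- generate_matched_controls(tmpl, pool, seed = base + 2L * r)
    ctl <- generate_matched_controls(tmpl, pool, seed = base + 2L * r + 1L)
    do <- nearest_sv_distance(obs, svs)$nearest_distance_bp
    dc <- nearest_sv_distance(ctl, svs)$nearest_distance_bp
    if (proximity_enrichment(do, dc, "within_10kb")$p_value < 0.05)
      rej <- rej + 1L
  }
  list(rejection_pct = 100 * rej / n_cohorts, n = n_cohorts)
}

#' Acceptance check: signature-refit mixture recovery
#'
#' Random two-signature mixtures from the synthetic reference, observed as
#' a 500-mutation multinomial draw, refit by NNLS; a trial succeeds when
#' both recovered fractions are within 0.1 of the truth.
#'
#' @param n_trials Number of mixtures (default 200).
#' @param n_mutations Catalog size per trial (default 500).
#' @param seed RNG seed.
#' @return List: `recovered_pct`, `orthogonal_excluded` (logical), `n`.
#' @export
acceptance_signature_recovery <- function(n_trials = 200L, n_mutations = 500L,
                                          seed = 1L) {
  set.seed(as.integer(seed))
  ref <- synthetic_signature_reference()
  ok <- 0L
  for (r in seq_len(n_trials)) {
    pair <- sample(colnames(ref), 2L)
    w <- stats::runif(1, 0.1, 0.9)
    p <- w * ref[, pair[1]] + (1 - w) * ref[, pair[2]]
    catal <- stats::rmultinom(1, n_mutations, p)[, 1]
    fit <- fit_exposures(catal, ref)
    fr <- fit$exposures / sum(fit$exposures)
    if (abs(fr[pair[1]] - w) <= 0.1 && abs(fr[pair[2]] - (1 - w)) <= 0.1)
      ok <- ok + 1L
  }
  odd <- stats::setNames(numeric(96), sbs96_classes())
  odd[grepl("\\[T>A\\]", sbs96_classes())] <- 10
  orth <- fit_exposures(odd, ref[, c("SBS2", "SBS13")])
  list(recovered_pct = 100 * ok / n_trials,
       orthogonal_excluded = orth$excluded, n = n_trials)
}

#' Acceptance check: stepwise-GLM covariate recovery
#'
#' Logistic simulations with one true covariate (beta = 1.5) and three
#' pure-noise covariates; measures how often stepwise AIC selection keeps
#' the true covariate.
#'
#' @param n_reps Replicates (default 100).
#' @param n Observations per replicate (default 300).
#' @param seed RNG seed.
#' @return List: `true_selected_pct`, `n`.
#' @export
acceptance_glm_recovery <- function(n_reps = 100L, n = 300L, seed = 1L) {
  set.seed(as.integer(seed))
  hit <- 0L
  for (r in seq_len(n_reps)) {
    d <- data.frame(x1 = stats::rnorm(n), x2 = stats::rnorm(n),
                    x3 = stats::rnorm(n), x4 = stats::rnorm(n))
    d$y <- stats::rbinom(n, 1, stats::plogis(-0.5 + 1.5 * d$x1))
    fit <- stepwise_glm(d, "y", "logistic", c("x1", "x2", "x3", "x4"))
    if ("x1" %in% fit$selected) hit <- hit + 1L
  }
  list(true_selected_pct = 100 * hit / n_reps, n = n_reps)
}

#' Self-contained cohort count statistics
#'
#' Percentages derivable by arithmetic from published per-cohort counts:
#' kataegis prevalence (positive patients / patients), clonal predominance
#' (clonal events / events) and the fraction of high-risk events within
#' 1 kbp of an SV breakend. A counts table matching the studied cohort is
#' shipped at `system.file("extdata", "cohort_counts.tsv", package =
#' "kataegion")`.
#'
#' @param counts One-row `data.frame` with columns `n_patients`,
#'   `n_kataegis_positive`, `n_events`, `n_clonal_events`, `n_hr_events`,
#'   `n_hr_events_within_1kb`.
#' @return List: `prevalence_pct`, `clonal_pct`, `sv1kb_pct`.
#' @export
kataegis_count_summary <- function(counts) {
  need <- c("n_patients", "n_kataegis_positive", "n_events", "n_clonal_events",
            "n_hr_events", "n_hr_events_within_1kb")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("missing count column(s): ", paste(miss, collapse = ", "))
  list(
    prevalence_pct = 100 * counts$n_kataegis_positive / counts$n_patients,
    clonal_pct = 100 * counts$n_clonal_events / counts$n_events,
    sv1kb_pct = 100 * counts$n_hr_events_within_1kb / counts$n_hr_events)
}
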