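#' Default genome model for simulations
#'
#' Approximate autosome lengths (GRCh38-like, rounded to the nearest Mbp)
#' totalling ~2.9 Gbp. Tests typically override this with one short
#' chromosome for speed.
#' @return `data.table` with `chrom` and `length`.
#' @export
default_genome_model <- function() {
  data.table::data.table(
    chrom = paste0("chr", 1:22),
    length = c(249, 242, 198, 190, 182, 171, 159, 145, 138, 134, 135, 133,
               114, 107, 102, 90, 83, 80, 59, 64, 47, 51) * 1e6)
}

#' Simulation configuration for synthetic kataegis cohorts
#'
#' Defaults state the cohort the generator emulates: kataegis events with
#' a median of 6 member SNVs (range 4-33, truncated-geometric sizes) and a
#' median span of ~2.7 kbp (log-normal, truncated to 200-35,300 bp); about
#' half the events placed within 1 kbp of an SV breakend and a further
#' fifth 0.1-10 Mbp away; 31% of events phase-informative; APOBEC-style
#' C>T/C>G at TpC substitutions for 80% of events (a single substitution
#' process per event, so planted events are type-consistent by
#' construction); clonal epochs predominating (~70% of events).
#'
#' @param n_samples Number of tumours (default 10).
#' @param genome_model `data.table` with `chrom`, `length`.
#' @param background_rate Background SNVs per bp (default 1e-6, i.e.
#'   1 SNV/Mbp).
#' @param n_events Planted kataegis events per sample (default 4).
#' @param size_q Truncated-geometric decay for event sizes on 4..33
#'   (default 0.75, giving median 6).
#' @param span_meanlog,span_sdlog log10-normal span parameters (defaults
#'   log10(2700) and 0.42; truncated to `span_range`).
#' @param span_range Allowed span range in bp (default c(200, 35300)).
#' @param apobec_event_prob Probability a planted event is APOBEC-type
#'   (default 0.8).
#' @param epoch_mix Event epoch probabilities over
#'   (early_clonal, late_clonal, subclonal) (default 0.40/0.30/0.30).
#' @param background_epoch_mix Background-SNV epoch probabilities over all
#'   five labels (default 0.25/0.25/0.15/0.25/0.10).
#' @param phasing_completeness Probability an event's SNVs share a phase
#'   group (default 0.31).
#' @param n_svs SVs per sample (default 80).
#' @param frac_sv_linked Fraction of events planted within 1 kbp of a
#'   breakend (default 0.5).
#' @param frac_distal Fraction planted 0.1-10 Mbp from a breakend
#'   (default 0.2; the rest are placed independently).
#' @param sv_type_mix Named probabilities over SV types.
#' @param mask Optional `GRanges` exclusion mask.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 10L,
                       genome_model = default_genome_model(),
                       background_rate = 1e-6,
                       n_events = 4L,
                       size_q = 0.75,
                       size_range = c(4L, 33L),
                       max_gap = NULL,
                       span_meanlog = log10(2700),
                       span_sdlog = 0.42,
                       span_range = c(200, 35300),
                       apobec_event_prob = 0.8,
                       epoch_mix = c(early_clonal = 0.40, late_clonal = 0.30,
                                     subclonal = 0.30),
                       background_epoch_mix = c(early_clonal = 0.25,
                                                late_clonal = 0.25,
                                                clonal_unspecified = 0.15,
                                                subclonal = 0.25,
                                                unknown = 0.10),
                       phasing_completeness = 0.31,
                       n_svs = 80L,
                       frac_sv_linked = 0.5,
                       frac_distal = 0.2,
                       sv_type_mix = c(DEL = 0.35, DUP = 0.20, INV = 0.15,
                                       TRA = 0.15, TRA_INV = 0.05,
                                       COMPLEX = 0.10),
                       mask = NULL) {
  stopifnot(frac_sv_linked + frac_distal <= 1,
            frac_sv_linked >= 0, frac_distal >= 0,
            phasing_completeness >= 0, phasing_completeness <= 1,
            apobec_event_prob >= 0, apobec_event_prob <= 1,
            background_rate >= 0, n_events >= 0)
  genome_model <- data.table::as.data.table(genome_model)
  stopifnot(all(c("chrom", "length") %in% names(genome_model)))
  structure(as.list(environment()), class = "sim_config")
}

.draw_event_sizes <- function(n, q = 0.75, range = c(4L, 33L)) {
  sizes <- range[1]:range[2]
  w <- q^(sizes - range[1])
  sample(sizes, n, replace = TRUE, prob = w)
}

.draw_spans <- function(n, meanlog, sdlog, range) {
  out <- numeric(0)
  while (length(out) < n) {
    s <- 10^stats::rnorm(n, meanlog, sdlog)
    out <- c(out, s[s >= range[1] & s <= range[2]])
  }
  round(out[seq_len(n)])
}

.rand_positions <- function(n, genome, mask, max_tries = 100L) {
  # uniform genome positions avoiding the mask, by rejection
  probs <- genome$length / sum(genome$length)
  res_chrom <- character(0); res_pos <- numeric(0)
  tries <- 0L
  while (length(res_pos) < n) {
    m <- n - length(res_pos)
    ch <- sample(genome$chrom, m, replace = TRUE, prob = probs)
    pos <- floor(stats::runif(m, 1, genome$length[match(ch, genome$chrom)] + 1))
    if (!is.null(mask) && length(mask) > 0L) {
      keep <- !mask_member(mask, ch, pos)
      ch <- ch[keep]; pos <- pos[keep]
    }
    res_chrom <- c(res_chrom, ch); res_pos <- c(res_pos, pos)
    tries <- tries + 1L
    if (tries > max_tries) stop("could not place positions outside the mask")
  }
  data.table::data.table(chrom = res_chrom, pos = res_pos)
}

.apobec_snv <- function(n) {
  # C>T or C>G (equal odds) at TpC; 3' flank uniform
  alt <- sample(c("T", "G"), n, replace = TRUE)
  p3 <- sample(.BASES, n, replace = TRUE)
  data.table::data.table(ref = "C", alt = alt,
                         tricontext = paste0("T", "C", p3))
}

.uniform_snv <- function(n) {
  sub <- sample(.SUBS, n, replace = TRUE)
  ref <- substr(sub, 1, 1)
  alt <- substr(sub, 3, 3)
  p5 <- sample(.BASES, n, replace = TRUE)
  p3 <- sample(.BASES, n, replace = TRUE)
  # reference strand chosen at random: half are reported as the purine
  flip <- stats::runif(n) < 0.5
  ctx <- paste0(p5, ref, p3)
  ref[flip] <- unname(.PYR_COMP[substr(sub, 1, 1)])[flip]
  alt[flip] <- unname(.PYR_COMP[substr(sub, 3, 3)])[flip]
  ctx[flip] <- .revcomp(ctx[flip])
  data.table::data.table(ref = ref, alt = alt, tricontext = ctx)
}

#' Simulate a synthetic cohort with planted kataegis and ground truth
#'
#' Per sample: background SNVs from a homogeneous point process at
#' `background_rate` outside the mask; `n_svs` SVs with uniformly placed
#' breakends of typed classes (intra-chromosomal partner breakends at a
#' log-uniform 1 kbp-10 Mbp distance); planted kataegis events anchored
#' near an SV breakend (within 1 kbp for the SV-linked fraction, at
#' 0.1-10 Mbp for the distal fraction) or uniformly otherwise. Each event
#' draws a size and a span, places its member SNVs uniformly within the
#' span (strictly increasing, minimum 1 bp gaps), draws one epoch and one
#' substitution process for all members, and is phase-informative with
#' probability `phasing_completeness`. Fully reproducible under `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List of class `"sim_cohort"`: `snvs`, `svs`, `truth`
#'   (per-event table: `sample_id`, `event_id`, `chrom`, `start`, `end`,
#'   `n_snvs`, `epoch`, `apobec`, `phased`, `placement`,
#'   `distance_to_sv`), and `config`.
#' @export
simulate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  genome <- config$genome_model
  snv_out <- list(); sv_out <- list(); truth_out <- list()
  ev_counter <- 0L

  for (s in seq_len(config$n_samples)) {
    sid <- sprintf("S%03d", s)

    ## SVs
    svs <- NULL
    if (config$n_svs > 0L) {
      a <- .rand_positions(config$n_svs, genome, config$mask)
      type_mix <- config$sv_type_mix
      if (nrow(genome) < 2L) {
        # translocations impossible on a single-chromosome genome model
        type_mix <- type_mix[!names(type_mix) %in% c("TRA", "TRA_INV")]
        if (!length(type_mix)) type_mix <- c(DEL = 1)
      }
      ty <- sample(names(type_mix), config$n_svs, replace = TRUE,
                   prob = type_mix)
      inter <- ty %in% c("TRA", "TRA_INV")
      chrom2 <- a$chrom; pos2 <- numeric(config$n_svs)
      intra_d <- round(10^stats::runif(config$n_svs, 3, 7))
      len <- genome$length[match(a$chrom, genome$chrom)]
      pos2 <- pmin(a$pos + intra_d, len)
      if (any(inter)) {
        b <- .rand_positions(sum(inter), genome, config$mask)
        # partner must land on a different chromosome
        same <- b$chrom == a$chrom[inter]
        tries <- 0L
        while (any(same)) {
          tries <- tries + 1L
          if (tries > 100L) stop("could not place translocation partner on ",
                                 "a different chromosome")
          rb <- .rand_positions(sum(same), genome, config$mask)
          b$chrom[same] <- rb$chrom; b$pos[same] <- rb$pos
          same <- b$chrom == a$chrom[inter]
        }
        chrom2[inter] <- b$chrom; pos2[inter] <- b$pos
      }
      svs <- data.table::data.table(
        sample_id = sid, chrom1 = a$chrom, pos1 = a$pos,
        chrom2 = chrom2, pos2 = pos2, sv_type = ty)
      svs <- .validate_svs(svs)
      sv_out[[sid]] <- svs
    }

    ## background SNVs
    n_bg <- stats::rpois(1, config$background_rate * sum(genome$length))
    bg <- NULL
    if (n_bg > 0L) {
      bp <- .rand_positions(n_bg, genome, config$mask)
      cls <- .uniform_snv(n_bg)
      bg <- data.table::data.table(
        sample_id = sid, chrom = bp$chrom, pos = bp$pos,
        ref = cls$ref, alt = cls$alt,
        epoch = sample(names(config$background_epoch_mix), n_bg, replace = TRUE,
                       prob = config$background_epoch_mix),
        phase_group = NA_character_, tricontext = cls$tricontext)
    }

    ## planted events
    planted <- list()
    if (config$n_events > 0L) {
      sizes <- .draw_event_sizes(config$n_events, config$size_q,
                                 config$size_range)
      spans <- .draw_spans(config$n_events, config$span_meanlog,
                           config$span_sdlog, config$span_range)
      u <- stats::runif(config$n_events)
      placement <- ifelse(u < config$frac_sv_linked, "sv_linked",
                          ifelse(u < config$frac_sv_linked + config$frac_distal,
                                 "distal", "independent"))
      if (is.null(svs) || nrow(svs) == 0L) placement[] <- "independent"
      for (e in seq_len(config$n_events)) {
        size <- sizes[e]
        # cap the span so mean member spacing respects the <1 kbp rule that
        # operationally defines kataegis (otherwise the plant is not an event)
        span <- min(spans[e], (size - 1L) * 900L)
        gaps <- NULL
        if (!is.null(config$max_gap)) {
          # tight-spacing mode: every member gap <= max_gap by construction
          gaps <- sample.int(config$max_gap, size - 1L, replace = TRUE)
          span <- sum(gaps) + 1L
        }
        tries <- 0L
        repeat {
          tries <- tries + 1L
          if (tries > 100L) stop("could not place event (span ", span, " bp)")
          if (placement[e] == "independent") {
            anch <- .rand_positions(1L, genome, config$mask)
            ch <- anch$chrom; start <- anch$pos
          } else {
            be <- sv_breakends(svs)
            i <- sample.int(nrow(be), 1L)
            off <- if (placement[e] == "sv_linked")
              sample(0:1000, 1L) else round(10^stats::runif(1, 5, 7))
            ch <- be$chrom[i]
            start <- be$pos[i] + sample(c(-1, 1), 1L) * off
          }
          chlen <- genome$length[match(ch, genome$chrom)]
          if (is.na(chlen) || start < 1 || start + span - 1 > chlen) next
          if (!is.null(config$mask) && length(config$mask) > 0L &&
              any(mask_member(config$mask, ch, c(start, start + span - 1)))) next
          break
        }
        # member positions: first and last at the span endpoints (so the
        # realized span equals the drawn span), the rest uniform inside
        offs <- if (is.null(gaps)) {
          inner <- if (size > 2L && span > 2L)
            sort(sample(2:(span - 1L), size - 2L)) else integer(0)
          c(1L, inner, span)
        } else cumsum(c(1L, gaps))
        pos <- start + offs - 1L
        apo <- stats::runif(1) < config$apobec_event_prob
        cls <- if (apo) .apobec_snv(size) else {
          one <- .uniform_snv(1L)
          one[rep(1L, size)]
        }
        epoch <- sample(names(config$epoch_mix), 1L, prob = config$epoch_mix)
        ev_counter <- ev_counter + 1L
        phased <- stats::runif(1) < config$phasing_completeness
        pg <- if (phased) sprintf("PS%05d", ev_counter) else NA_character_
        planted[[e]] <- data.table::data.table(
          sample_id = sid, chrom = ch, pos = pos, ref = cls$ref, alt = cls$alt,
          epoch = epoch, phase_group = pg, tricontext = cls$tricontext)
        d_sv <- if (!is.null(svs) && nrow(svs) > 0L) {
          be <- sv_breakends(svs)[chrom == ch]
          if (nrow(be)) min(.dist_to_span(pos[1], pos[size], be$pos)) else Inf
        } else NA_real_
        truth_out[[ev_counter]] <- data.table::data.table(
          sample_id = sid, event_id = sprintf("T%04d", ev_counter),
          chrom = ch, start = pos[1], end = pos[size], n_snvs = size,
          epoch = epoch, apobec = apo, phased = phased,
          placement = placement[e], distance_to_sv = d_sv)
      }
    }
    snv_out[[sid]] <- data.table::rbindlist(c(list(bg), planted),
                                            use.names = TRUE, fill = TRUE)
  }

  snvs <- data.table::rbindlist(snv_out[!vapply(snv_out, is.null, logical(1))],
                                fill = TRUE)
  if (nrow(snvs)) data.table::setorder(snvs, sample_id, chrom, pos)
  svs <- if (length(sv_out)) data.table::rbindlist(sv_out) else
    data.table::data.table(sample_id = character(), chrom1 = character(),
                           pos1 = numeric(), chrom2 = character(),
                           pos2 = numeric(), sv_type = character(),
                           size_bp = numeric())
  truth <- if (length(truth_out)) data.table::rbindlist(truth_out) else
    data.table::data.table(sample_id = character(), event_id = character(),
                           chrom = character(), start = numeric(),
                           end = numeric(), n_snvs = integer(),
                           epoch = character(), apobec = logical(),
                           phased = logical(), placement = character(),
                           distance_to_sv = numeric())
  structure(list(snvs = snvs, svs = svs, truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$config$n_samples, "sample(s),",
      nrow(x$snvs), "SNVs,", nrow(x$svs), "SVs,",
      nrow(x$truth), "planted kataegis event(s)\n")
  invisible(x)
}

#' Match called kataegis events against planted truth
#'
#' A called event matches a truth event of the same sample when their
#' spans overlap and the called event contains at least `min_snv_share` of
#' the truth event's member SNV positions. Sensitivity is the fraction of
#' truth events matched by at least one call; precision is the fraction of
#' calls matching at least one truth event (duplicate calls of one truth
#' event from different epoch subsets count as matching, not as false
#' positives).
#'
#' @param called Candidate/event `data.table` with `sample_id`, `chrom`,
#'   `start`, `end` and a `snvs` list-column of member tables.
#' @param truth Truth table from [simulate_cohort()].
#' @param snvs Cohort SNV table (used to recover each truth event's member
#'   positions by span).
#' @param min_snv_share Minimum shared fraction of truth SNVs
#'   (default 0.5).
#' @return List: `tp`, `fp`, `fn`, `sensitivity`, `precision`,
#'   `matched_truth_ids`.
#' @export
truth_match <- function(called, truth, snvs, min_snv_share = 0.5) {
  called <- data.table::as.data.table(called)
  truth <- data.table::as.data.table(truth)
  snvs <- data.table::as.data.table(snvs)
  n_truth <- nrow(truth)
  n_called <- nrow(called)
  if (n_called == 0L)
    return(list(tp = 0L, fp = 0L, fn = n_truth, sensitivity = 0,
                precision = NA_real_, matched_truth_ids = character(0)))
  key_ct <- paste(called$sample_id, called$chrom)
  key_tt <- paste(truth$sample_id, truth$chrom)
  snv_key <- paste(snvs$sample_id, snvs$chrom)
  snv_by_key <- split(snvs$pos, snv_key)
  truth_members <- lapply(seq_len(n_truth), function(j) {
    p <- snv_by_key[[key_tt[j]]]
    p[p >= truth$start[j] & p <= truth$end[j]]
  })
  cand_by_key <- split(seq_len(n_called), key_ct)
  called_matched <- rep(FALSE, n_called)
  truth_matched <- rep(FALSE, n_truth)
  c_start <- called$start; c_end <- called$end
  c_pos <- lapply(called$snvs, `[[`, "pos")
  for (j in seq_len(n_truth)) {
    for (i in cand_by_key[[key_tt[j]]]) {
      if (truth$start[j] > c_end[i] || c_start[i] > truth$end[j]) next
      share <- mean(truth_members[[j]] %in% c_pos[[i]])
      if (is.finite(share) && share >= min_snv_share) {
        called_matched[i] <- TRUE
        truth_matched[j] <- TRUE
      }
    }
  }
  tp <- sum(truth_matched)
  fp <- sum(!called_matched)
  list(tp = tp, fp = fp, fn = n_truth - tp,
       sensitivity = if (n_truth) tp / n_truth else NA_real_,
       precision = 1 - fp / n_called,
       matched_truth_ids = truth$event_id[truth_matched])
}
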