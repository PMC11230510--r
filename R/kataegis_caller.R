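#' Build the three epoch-stratified SNV subsets of one genome
#'
#' Kataegis is assumed to arise from a single mutational process acting in
#' one evolutionary epoch, so candidates are called separately from three
#' per-genome subsets rather than from the pooled catalog:
#' * `early`: `early_clonal`, `clonal_unspecified` and `unknown` SNVs;
#' * `late`: `late_clonal`, `clonal_unspecified` and `unknown` SNVs;
#' * `subclonal`: `subclonal` and `unknown` SNVs.
#'
#' Unspecified clonal SNVs belong to both clonal subsets; SNVs of unknown
#' timing belong to all three.
#'
#' @param snvs SNV `data.table` (see [read_snvs()]); one sample.
#' @return Named list of three `data.table`s (`early`, `late`,
#'   `subclonal`), each sorted by (chrom, pos).
#' @export
build_epoch_subsets <- function(snvs) {
  snvs <- data.table::as.data.table(snvs)
  .check_epoch(snvs$epoch)
  pick <- function(labels) {
    sub <- snvs[epoch %in% labels]
    data.table::setorder(sub, chrom, pos)
    sub[]
  }
  list(
    early = pick(c("early_clonal", "clonal_unspecified", "unknown")),
    late = pick(c("late_clonal", "clonal_unspecified", "unknown")),
    subclonal = pick(c("subclonal", "unknown"))
  )
}

#' Burden-adjusted kataegis distance threshold
#'
#' The fixed 1 kbp inter-mutation cutoff would over-call in heavily mutated
#' genomes, so the cutoff is tightened with the subset's mutational burden:
#' under a uniform model with genome-wide rate `lambda = n_snvs /
#' genome_length`, the expected number of chance runs of four SNVs packed
#' within distance d is approximately `n_snvs * (lambda * d)^3`. The
#' threshold is the d* at which this expectation equals `alpha`, capped at
#' `max_threshold` (1 kbp). In closed form
#' `d* = genome_length * alpha^(1/3) / n_snvs^(4/3)`.
#'
#' Subsets with fewer than four SNVs (no run possible) get the cap.
#'
#' @param n_snvs Total SNVs in the epoch subset (genome-wide).
#' @param genome_length Callable genome length in bp (default 3.1e9).
#' @param alpha Tolerated expected number of chance 4-SNV runs per genome
#'   (default 0.01).
#' @param max_threshold Cap in bp (default 1000).
#' @return Threshold in bp.
#' @examples
#' burden_threshold(20000, 3.1e9, 0.01)  # cap: d* ~ 1231 bp > 1000
#' @export
burden_threshold <- function(n_snvs, genome_length = 3.1e9, alpha = 0.01,
                             max_threshold = 1000) {
  stopifnot(n_snvs >= 0, genome_length > 0, alpha > 0, alpha < 1)
  if (n_snvs < 4) return(max_threshold)
  d_star <- genome_length * alpha^(1 / 3) / n_snvs^(4 / 3)
  min(max_threshold, d_star)
}

#' Call kataegis candidates from one epoch subset
#'
#' Per chromosome, duplicate positions are collapsed (first record kept,
#' count logged), inter-mutation distances are smoothed with
#' [pcf_adjusted_imd()], and a candidate is a maximal run of consecutive
#' SNVs whose every connecting adjusted distance is below the
#' burden-adjusted threshold. Runs of at least `min_snvs` SNVs are emitted.
#'
#' @param subset One epoch subset of one sample (sorted SNV `data.table`).
#' @param epoch_tag Label stored on the candidates (`"early"`, `"late"`,
#'   `"subclonal"`, or `"genomewide"` for the no-timing mode).
#' @param gamma,kmin PCF parameters (defaults 25 and 2 on log10 gaps).
#' @param genome_length,alpha,max_threshold See [burden_threshold()].
#' @param min_snvs Minimum SNVs per event (default 4).
#' @return Candidate `data.table`: `sample_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `epoch_tag`, `n_snvs`, `span_bp`,
#'   `max_adjusted_imd`, `threshold_bp` and a `snvs` list-column with the
#'   member records. Attribute `n_duplicates` counts collapsed positions.
#' @export
call_candidates <- function(subset, epoch_tag, gamma = 25, kmin = 2L,
                            genome_length = 3.1e9, alpha = 0.01,
                            max_threshold = 1000, min_snvs = 4L) {
  subset <- data.table::as.data.table(subset)
  empty <- data.table::data.table(
    sample_id = character(), chrom = character(), start = numeric(),
    end = numeric(), epoch_tag = character(), n_snvs = integer(),
    span_bp = numeric(), max_adjusted_imd = numeric(),
    threshold_bp = numeric(), snvs = list())
  if (nrow(subset) == 0L) {
    attr(empty, "n_duplicates") <- 0L
    return(empty)
  }
  if (length(unique(subset$sample_id)) > 1L)
    stop("call_candidates expects one sample at a time")
  data.table::setorder(subset, chrom, pos)
  thr <- burden_threshold(nrow(subset), genome_length, alpha, max_threshold)

  n_dup <- 0L
  rows <- list()
  for (ch in unique(subset$chrom)) {
    dt <- subset[chrom == ch]
    dup <- duplicated(dt$pos)
    n_dup <- n_dup + sum(dup)
    dt <- dt[!dup]
    n <- nrow(dt)
    if (n < min_snvs) next
    adj <- pcf_adjusted_imd(dt$pos, gamma = gamma, kmin = kmin)
    ok <- adj < thr
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= (min_snvs - 1L))) {
      i0 <- starts[k]           # first gap index -> SNVs i0 .. ends[k]+1
      i1 <- ends[k] + 1L
      members <- dt[i0:i1]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        sample_id = members$sample_id[1L], chrom = ch,
        start = members$pos[1L], end = members$pos[nrow(members)],
        epoch_tag = epoch_tag, n_snvs = nrow(members),
        span_bp = members$pos[nrow(members)] - members$pos[1L] + 1,
        max_adjusted_imd = max(adj[i0:(i1 - 1L)]),
        threshold_bp = thr, snvs = list(members))
    }
  }
  out <- if (length(rows)) data.table::rbindlist(rows) else empty
  attr(out, "n_duplicates") <- n_dup
  out[]
}

.member_keys <- function(candidate_snvs, epochs = NULL) {
  m <- candidate_snvs
  if (!is.null(epochs)) m <- m[m$epoch %in% epochs, , drop = FALSE]
  paste(m$chrom, format(m$pos, scientific = FALSE, trim = TRUE))
}

#' Resolve duplicated early/late clonal candidates
#'
#' Because unspecified clonal (and unknown) SNVs enter both clonal subsets,
#' the same physical cluster can be called once from the early and once
#' from the late subset. When an early and a late candidate of one sample
#' share at least one `clonal_unspecified` or `unknown` member SNV, only
#' the candidate with more member SNVs is kept (ties keep the early one);
#' the dropped one is recorded with reason `epoch_duplicate`. Overlapping
#' early/late candidates that share no member SNV are genuinely distinct
#' sequential events: both are kept and flagged `sequential_pair`.
#'
#' @param early,late Candidate tables from [call_candidates()] for the
#'   early and late subsets of one sample.
#' @return List with `candidates` (merged table, extra logical column
#'   `sequential_pair`) and `n_epoch_duplicates_removed`.
#' @export
dedup_early_late <- function(early, late) {
  early <- data.table::copy(data.table::as.data.table(early))
  late <- data.table::copy(data.table::as.data.table(late))
  if (nrow(early) == 0L || nrow(late) == 0L) {
    out <- data.table::rbindlist(list(early, late), fill = TRUE)
    if (nrow(out)) out[, sequential_pair := FALSE]
    return(list(candidates = out[], n_epoch_duplicates_removed = 0L))
  }
  shared_labels <- c("clonal_unspecified", "unknown")
  drop_early <- rep(FALSE, nrow(early))
  drop_late <- rep(FALSE, nrow(late))
  seq_early <- rep(FALSE, nrow(early))
  seq_late <- rep(FALSE, nrow(late))
  for (i in seq_len(nrow(early))) {
    ki <- .member_keys(early$snvs[[i]], shared_labels)
    ki_all <- .member_keys(early$snvs[[i]])
    for (j in seq_len(nrow(late))) {
      if (early$chrom[i] != late$chrom[j]) next
      overlap_span <- early$start[i] <= late$end[j] && late$start[j] <= early$end[i]
      kj <- .member_keys(late$snvs[[j]], shared_labels)
      if (length(intersect(ki, kj)) > 0L) {
        if (late$n_snvs[j] > early$n_snvs[i]) drop_early[i] <- TRUE
        else drop_late[j] <- TRUE       # ties keep early
      } else if (overlap_span &&
                 length(intersect(ki_all, .member_keys(late$snvs[[j]]))) == 0L) {
        seq_early[i] <- TRUE
        seq_late[j] <- TRUE
      }
    }
  }
  early[, sequential_pair := seq_early]
  late[, sequential_pair := seq_late]
  out <- data.table::rbindlist(list(early[!drop_early], late[!drop_late]),
                               fill = TRUE)
  list(candidates = out[],
       n_epoch_duplicates_removed = sum(drop_early) + sum(drop_late))
}

#' Call kataegis candidates for a whole cohort
#'
#' Runs [build_epoch_subsets()], [call_candidates()] per subset and sample
#' (the burden threshold is computed per sample and subset), and
#' [dedup_early_late()]; subclonal candidates are appended unchanged. With
#' `stratify_epochs = FALSE` (public-cohort mode, timing unavailable) a
#' single genome-wide subset per sample is used instead.
#'
#' @param snvs Cohort SNV `data.table` (multiple samples allowed).
#' @param stratify_epochs Call per epoch subset (default TRUE).
#' @inheritParams call_candidates
#' @return Candidate `data.table` with `event_id`, plus attributes
#'   `n_duplicates` (collapsed duplicate positions) and
#'   `n_epoch_duplicates_removed`.
#' @export
call_kataegis <- function(snvs, gamma = 25, kmin = 2L, genome_length = 3.1e9,
                          alpha = 0.01, max_threshold = 1000, min_snvs = 4L,
                          stratify_epochs = TRUE) {
  snvs <- data.table::as.data.table(snvs)
  res <- list()
  n_dup <- 0L
  n_epoch_dup <- 0L
  for (sid in unique(snvs$sample_id)) {
    one <- snvs[sample_id == sid]
    cc <- function(sub, tag) {
      out <- call_candidates(sub, tag, gamma = gamma, kmin = kmin,
                             genome_length = genome_length, alpha = alpha,
                             max_threshold = max_threshold, min_snvs = min_snvs)
      n_dup <<- n_dup + attr(out, "n_duplicates")
      out
    }
    if (stratify_epochs) {
      subs <- build_epoch_subsets(one)
      dd <- dedup_early_late(cc(subs$early, "early"), cc(subs$late, "late"))
      n_epoch_dup <- n_epoch_dup + dd$n_epoch_duplicates_removed
      sub_cand <- cc(subs$subclonal, "subclonal")
      if (nrow(sub_cand)) sub_cand[, sequential_pair := FALSE]
      res[[sid]] <- data.table::rbindlist(list(dd$candidates, sub_cand),
                                          fill = TRUE)
    } else {
      out <- cc(one, "genomewide")
      if (nrow(out)) out[, sequential_pair := FALSE]
      res[[sid]] <- out
    }
  }
  out <- data.table::rbindlist(res, fill = TRUE)
  if (nrow(out)) {
    data.table::setorder(out, sample_id, chrom, start, epoch_tag)
    out[, event_id := sprintf("K%04d", .I)]
  } else {
    out <- data.table::data.table(
      sample_id = character(), chrom = character(), start = numeric(),
      end = numeric(), epoch_tag = character(), n_snvs = integer(),
      span_bp = numeric(), max_adjusted_imd = numeric(),
      threshold_bp = numeric(), snvs = list(), sequential_pair = logical(),
      event_id = character())
  }
  attr(out, "n_duplicates") <- n_dup
  attr(out, "n_epoch_duplicates_removed") <- n_epoch_dup
  out[]
}
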