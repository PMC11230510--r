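#' Flatten SVs to a breakend table
#'
#' Each SV contributes two breakends (one per anchor).
#' @param svs SV `data.table` from [read_svs()].
#' @return `data.table`: `sample_id`, `chrom`, `pos`, `sv_type`.
#' @export
sv_breakends <- function(svs) {
  svs <- data.table::as.data.table(svs)
  be <- data.table::rbindlist(list(
    svs[, .(sample_id, chrom = chrom1, pos = pos1, sv_type)],
    svs[, .(sample_id, chrom = chrom2, pos = pos2, sv_type)]))
  data.table::setorder(be, sample_id, chrom, pos)
  be[]
}

.dist_to_span <- function(start, end, pos) {
  ifelse(pos >= start & pos <= end, 0, pmin(abs(start - pos), abs(pos - end)))
}

#' Nearest SV-breakend distance per kataegis event
#'
#' Distance is measured from the event span: 0 when a breakend lies inside
#' `[start, end]`, otherwise the gap to the nearer span boundary. Only
#' breakends of the same sample and chromosome are considered; an event on
#' a chromosome without breakends gets `Inf` (counted as "far" by the band
#' tests), and events of samples with no SVs at all get `NA` and are
#' excluded from tests (logged by the caller). Ties across SV types go to
#' the breakend with the smallest coordinate.
#'
#' @param events Event `data.table` (`event_id`, `sample_id`, `chrom`,
#'   `start`, `end`, optionally `epoch_tag`).
#' @param svs SV `data.table`.
#' @return `data.table`: `event_id`, `nearest_distance_bp`,
#'   `nearest_sv_type`, `epoch_tag`.
#' @export
nearest_sv_distance <- function(events, svs) {
  events <- data.table::as.data.table(events)
  be <- sv_breakends(svs)
  has_sv <- unique(be$sample_id)
  be_pos <- split(be$pos, paste(be$sample_id, be$chrom))
  be_type <- split(be$sv_type, paste(be$sample_id, be$chrom))
  n <- nrow(events)
  dist <- rep(NA_real_, n)
  type <- rep(NA_character_, n)
  key <- paste(events$sample_id, events$chrom)
  for (i in seq_len(n)) {
    if (!events$sample_id[i] %in% has_sv) next
    p <- be_pos[[key[i]]]
    if (is.null(p)) { dist[i] <- Inf; next }
    d <- .dist_to_span(events$start[i], events$end[i], p)
    hit <- which(d == min(d))
    hit <- hit[which.min(p[hit])]
    dist[i] <- d[hit]
    type[i] <- be_type[[key[i]]][hit]
  }
  data.table::data.table(
    event_id = events$event_id,
    nearest_distance_bp = dist,
    nearest_sv_type = type,
    epoch_tag = if ("epoch_tag" %in% names(events)) events$epoch_tag
                else NA_character_)
}

#' Matched random-region controls for SV-proximity testing
#'
#' For each observed event one control region is drawn: a somatic small
#' variant of the same sample is chosen uniformly at random (excluding
#' masked regions), and the control takes that anchor as its start with
#' the same span length as the event. Reproducible under `seed`.
#'
#' @param events Event `data.table` (needs `event_id`, `sample_id`,
#'   `start`, `end`).
#' @param small_variants Per-sample somatic small-variant table
#'   (`sample_id`, `chrom`, `pos`); typically the full SNV catalog.
#' @param mask `GRanges` exclusion mask (may be empty).
#' @param seed Integer RNG seed.
#' @param k Controls per event (default 1; pooled downstream).
#' @return `data.table`: `event_id`, `control_idx`, `sample_id`, `chrom`,
#'   `start`, `end` with `end - start` equal to the matched event's.
#' @export
generate_matched_controls <- function(events, small_variants, mask = NULL,
                                      seed = 1L, k = 1L) {
  events <- data.table::as.data.table(events)
  sv <- data.table::as.data.table(small_variants)
  if (!is.null(mask) && length(mask) > 0L) {
    keep <- !mask_member(mask, sv$chrom, sv$pos)
    sv <- sv[keep]
  }
  set.seed(as.integer(seed))
  pool_chrom <- split(sv$chrom, sv$sample_id)
  pool_pos <- split(sv$pos, sv$sample_id)
  n <- nrow(events)
  chrom <- character(n * k); start <- numeric(n * k)
  for (i in seq_len(n)) {
    sid <- events$sample_id[i]
    pp <- pool_pos[[sid]]
    if (is.null(pp) || length(pp) == 0L)
      stop("no eligible small variant outside the mask for sample ", sid)
    idx <- sample.int(length(pp), k, replace = TRUE)
    at <- (i - 1L) * k + seq_len(k)
    chrom[at] <- pool_chrom[[sid]][idx]
    start[at] <- pp[idx]
  }
  span <- rep(events$end - events$start, each = k)
  data.table::data.table(
    event_id = rep(events$event_id, each = k),
    control_idx = rep(seq_len(k), n),
    sample_id = rep(events$sample_id, each = k),
    chrom = chrom, start = start, end = start + span)
}

#' Kataegis/SV proximity enrichment in a distance band
#'
#' Compares observed events against matched controls in a 2x2 table of
#' near vs far counts. Bands: `"within_10kb"` tests distance <= 10 kbp vs
#' > 10 kbp (the 1 kbp proximity peak); `"band_0.1_to_10Mb"` tests
#' 0.1-10 Mbp vs > 10 Mbp (the distal ~1 Mbp peak; events nearer than
#' 0.1 Mbp are outside both classes and excluded). The p-value is the
#' two-sided exact hypergeometric probability ([fisher_exact_2x2()]); the
#' odds ratio is the cross-product with a 0.5 continuity correction when
#' any cell is zero. `NA` distances (samples without SVs) are dropped and
#' counted in `n_excluded`.
#'
#' @param obs_dist,ctl_dist Numeric distance vectors (bp) for observed
#'   events and controls; `Inf` allowed (always "far").
#' @param band `"within_10kb"` or `"band_0.1_to_10Mb"`.
#' @return List of class `"enrichment_table"`: `table` (2x2 matrix),
#'   `odds_ratio`, `p_value`, `band`, `n_excluded`.
#' @export
proximity_enrichment <- function(obs_dist, ctl_dist,
                                 band = c("within_10kb", "band_0.1_to_10Mb")) {
  band <- match.arg(band)
  n_excluded <- sum(is.na(obs_dist)) + sum(is.na(ctl_dist))
  obs_dist <- obs_dist[!is.na(obs_dist)]
  ctl_dist <- ctl_dist[!is.na(ctl_dist)]
  if (length(obs_dist) == 0L) stop("empty observed event set")
  classify <- function(d) {
    if (band == "within_10kb") ifelse(d <= 1e4, "near", "far")
    else ifelse(d > 1e5 & d <= 1e7, "near", ifelse(d > 1e7, "far", NA_character_))
  }
  co <- classify(obs_dist)
  cc <- classify(ctl_dist)
  n_excluded <- n_excluded + sum(is.na(co)) + sum(is.na(cc))
  tab <- matrix(c(sum(co == "near", na.rm = TRUE), sum(co == "far", na.rm = TRUE),
                  sum(cc == "near", na.rm = TRUE), sum(cc == "far", na.rm = TRUE)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("observed", "control"), c("near", "far")))
  ft <- fisher_exact_2x2(tab)
  structure(list(table = tab, odds_ratio = ft$odds_ratio, p_value = ft$p_value,
                 band = band, n_excluded = n_excluded),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("SV-proximity enrichment (", x$band, ")\n", sep = "")
  print(x$table)
  cat("odds ratio =", format(x$odds_ratio, digits = 4),
      ", exact p =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' Per-SV-type, per-epoch distance profile
#'
#' For each event, the nearest breakend distance is computed separately
#' per SV type (types absent from the sample/chromosome are omitted for
#' that event). The long table supports the type-by-epoch distance
#' histograms; `log10_distance` uses `log10(distance + 1)`.
#'
#' @param events Event `data.table`.
#' @param svs SV `data.table`.
#' @return `data.table`: `event_id`, `epoch_tag`, `sv_type`,
#'   `distance_bp`, `log10_distance`.
#' @export
sv_type_distance_profile <- function(events, svs) {
  events <- data.table::as.data.table(events)
  be <- sv_breakends(svs)
  out <- list()
  for (i in seq_len(nrow(events))) {
    e <- events[i]
    b <- be[sample_id == e$sample_id & chrom == e$chrom]
    if (nrow(b) == 0L) next
    d <- .dist_to_span(e$start, e$end, b$pos)
    per_type <- b[, .(distance_bp = min(.dist_to_span(e$start, e$end, pos))),
                  by = sv_type]
    per_type[, `:=`(event_id = e$event_id,
                    epoch_tag = e$epoch_tag %||% NA_character_)]
    out[[length(out) + 1L]] <- per_type
  }
  if (!length(out))
    return(data.table::data.table(event_id = character(), epoch_tag = character(),
                                  sv_type = character(), distance_bp = numeric(),
                                  log10_distance = numeric()))
  prof <- data.table::rbindlist(out)
  prof[, log10_distance := log10(distance_bp + 1)]
  data.table::setcolorder(prof, c("event_id", "epoch_tag", "sv_type",
                                  "distance_bp", "log10_distance"))
  prof[]
}
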