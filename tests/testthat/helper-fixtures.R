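# in-code fixture builders shared across test files

make_snvs <- function(pos, chrom = "chr1", sample_id = "S1", ref = "C",
                      alt = "T", epoch = "unknown", phase_group = NA_character_,
                      tricontext = NA_character_) {
  n <- length(pos)
  data.table::data.table(
    sample_id = rep_len(sample_id, n), chrom = rep_len(chrom, n),
    pos = as.numeric(pos), ref = rep_len(ref, n), alt = rep_len(alt, n),
    epoch = rep_len(epoch, n), phase_group = rep_len(phase_group, n),
    tricontext = rep_len(tricontext, n))
}

# background positions spaced ~1 Mbp with a tight cluster in the middle
cluster_in_background <- function(n_bg = 60, bg_gap = 1e6, cluster_size = 6,
                                  cluster_gap = 100) {
  bg <- seq(1e6, by = bg_gap, length.out = n_bg)
  mid <- bg[n_bg %/% 2] + 5e5
  cl <- seq(mid, by = cluster_gap, length.out = cluster_size)
  sort(c(bg, cl))
}

make_svs <- function(pos1, pos2 = pos1 + 5e4, chrom1 = "chr1", chrom2 = chrom1,
                     sv_type = "DEL", sample_id = "S1") {
  n <- length(pos1)
  dt <- data.table::data.table(
    sample_id = rep_len(sample_id, n), chrom1 = rep_len(chrom1, n),
    pos1 = as.numeric(pos1), chrom2 = rep_len(chrom2, n),
    pos2 = as.numeric(pos2), sv_type = rep_len(sv_type, n))
  dt[, size_bp := ifelse(chrom1 == chrom2, pos2 - pos1, NA_real_)]
  dt[]
}

make_candidate <- function(members, sample_id = "S1", chrom = "chr1",
                           epoch_tag = "early", event_id = "K0001") {
  data.table::data.table(
    sample_id = sample_id, chrom = chrom,
    start = min(members$pos), end = max(members$pos), epoch_tag = epoch_tag,
    n_snvs = nrow(members), span_bp = max(members$pos) - min(members$pos) + 1,
    max_adjusted_imd = NA_real_, threshold_bp = 1000,
    snvs = list(members), event_id = event_id)
}

# exhaustive PCF search: minimum penalized cost over all segmentations
brute_pcf_cost <- function(x, gamma, kmin = 1L) {
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

small_genome <- function(len = 1e8, chrom = "chr1") {
  data.table::data.table(chrom = chrom, length = len)
}
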