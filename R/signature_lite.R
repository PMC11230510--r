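.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.BASES <- c("A", "C", "G", "T")

.revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(s, ""), function(x) paste(rev(x), collapse = ""),
                character(1)))
}

#' The 96 SBS classes in conventional order
#'
#' Six pyrimidine substitutions (C>A, C>G, C>T, T>A, T>C, T>G) crossed with
#' the 16 combinations of 5' and 3' flanking bases, formatted `A[C>T]G`.
#' @return Character vector of length 96.
#' @export
sbs96_classes <- function() {
  out <- character(0)
  for (s in .SUBS) for (p5 in .BASES) for (p3 in .BASES)
    out <- c(out, paste0(p5, "[", s, "]", p3))
  out
}

#' Build a 96-channel SBS catalog from SNVs
#'
#' Each SNV needs its reference-strand trinucleotide context (`tricontext`
#' column); SNVs with a purine reference base are reverse-complemented to
#' the pyrimidine classes. SNVs whose context contains N or is missing are
#' skipped with a logged count; a context whose middle base contradicts
#' the `ref` allele is an error.
#'
#' @param snvs SNV `data.table` with `ref`, `alt`, `tricontext`.
#' @return Named integer vector over [sbs96_classes()]; attribute
#'   `n_skipped`.
#' @export
build_sbs96 <- function(snvs) {
  snvs <- data.table::as.data.table(snvs)
  classes <- sbs96_classes()
  counts <- stats::setNames(integer(96), classes)
  if (nrow(snvs) == 0L) {
    attr(counts, "n_skipped") <- 0L
    return(counts)
  }
  ctx <- snvs$tricontext
  if (is.null(ctx) || all(is.na(ctx)))
    stop("trinucleotide context unavailable: supply a `tricontext` column ",
         "or fetch contexts from an indexed FASTA upstream")
  bad <- is.na(ctx) | nchar(ctx) != 3L | grepl("N", ctx)
  n_skipped <- sum(bad)
  dt <- snvs[!bad]
  ctx <- ctx[!bad]
  if (any(substr(ctx, 2, 2) != dt$ref))
    stop("tricontext middle base disagrees with ref allele at row ",
         which(substr(ctx, 2, 2) != dt$ref)[1])
  flip <- dt$ref %in% c("A", "G")
  ref <- ifelse(flip, unname(.PYR_COMP[dt$ref]), dt$ref)
  alt <- ifelse(flip, unname(.PYR_COMP[dt$alt]), dt$alt)
  ctx[flip] <- .revcomp(ctx[flip])
  cls <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
  tab <- table(factor(cls, levels = classes))
  counts[] <- as.integer(tab)
  if (n_skipped > 0L) message("build_sbs96: skipped ", n_skipped,
                              " SNV(s) with unusable context")
  attr(counts, "n_skipped") <- as.integer(n_skipped)
  counts
}

.SV_BINS <- c("1-10kb", "10-100kb", "100kb-1Mb", "1-10Mb", ">10Mb")

#' The 32 SV classes
#'
#' DEL, DUP and INV crossed with five size bins and a clustered /
#' non-clustered flag (30 classes), plus clustered / non-clustered
#' translocations.
#' @return Character vector of length 32, e.g. `"DEL:1-10kb:clustered"`.
#' @export
sv32_classes <- function() {
  out <- character(0)
  for (cl in c("clustered", "non-clustered")) {
    for (ty in c("DEL", "DUP", "INV")) for (b in .SV_BINS)
      out <- c(out, paste(ty, b, cl, sep = ":"))
    out <- c(out, paste("TRA", cl, sep = ":"))
  }
  out
}

.sv_size_bin <- function(size) {
  # sizes below 1 kb are lumped into the smallest bin
  cut(size, breaks = c(-Inf, 1e4, 1e5, 1e6, 1e7, Inf), labels = .SV_BINS)
}

#' Build a 32-channel SV catalog
#'
#' Intra-chromosomal SVs are binned by size; every SV is flagged clustered
#' or non-clustered from the spacing of breakends: per chromosome the
#' log10 inter-breakend distances are segmented with [exact_pcf()] and a
#' breakend is clustered when its adjacent smoothed distance falls below
#' the `cluster_quantile` quantile of the sample's genome-wide
#' inter-breakend distances; an SV is clustered when either breakend is.
#' TRA and TRA_INV both feed the translocation channels; COMPLEX calls are
#' excluded with a logged count (they are composite, not a single class).
#'
#' @param svs SV `data.table` for one sample.
#' @param cluster_quantile Quantile defining "clustered" spacing
#'   (default 0.1).
#' @param gamma,kmin PCF parameters (defaults 25, 2).
#' @return Named integer vector over [sv32_classes()]; attribute
#'   `n_skipped` (COMPLEX calls).
#' @export
build_sv32 <- function(svs, cluster_quantile = 0.1, gamma = 25, kmin = 2L) {
  svs <- data.table::as.data.table(svs)
  classes <- sv32_classes()
  counts <- stats::setNames(integer(length(classes)), classes)
  n_skipped <- sum(svs$sv_type == "COMPLEX")
  svs <- svs[sv_type != "COMPLEX"]
  if (nrow(svs) == 0L) {
    attr(counts, "n_skipped") <- as.integer(n_skipped)
    return(counts)
  }
  svs[, sv_id := .I]
  be <- data.table::rbindlist(list(
    svs[, .(sv_id, chrom = chrom1, pos = pos1)],
    svs[, .(sv_id, chrom = chrom2, pos = pos2)]))
  data.table::setorder(be, chrom, pos)
  all_gaps <- unlist(lapply(split(be$pos, be$chrom),
                            function(p) if (length(p) > 1) pmax(diff(p), 1)
                                        else numeric(0)))
  clustered_be <- rep(FALSE, nrow(be))
  if (length(all_gaps) >= 2L) {
    thr <- stats::quantile(all_gaps, cluster_quantile, names = FALSE)
    idx0 <- 0L
    for (ch in unique(be$chrom)) {
      sel <- which(be$chrom == ch)
      p <- be$pos[sel]
      if (length(p) < 2L) next
      d <- pmax(diff(p), 1)   # coincident breakends: treat as 1 bp apart
      seg <- exact_pcf(log10(d), gamma = gamma,
                       kmin = min(as.integer(kmin), length(d)))
      adj <- 10^rep(seg$means, seg$lengths)
      # breakend touches the gap before and after it
      left <- c(Inf, adj)
      right <- c(adj, Inf)
      clustered_be[sel] <- pmin(left, right) < thr
    }
  }
  sv_clustered <- tapply(clustered_be, be$sv_id, any)
  svs[, clustered := as.logical(sv_clustered[as.character(sv_id)])]
  svs[, cl := ifelse(clustered, "clustered", "non-clustered")]
  is_tra <- svs$sv_type %in% c("TRA", "TRA_INV")
  key <- character(nrow(svs))
  key[is_tra] <- paste("TRA", svs$cl[is_tra], sep = ":")
  if (any(!is_tra)) {
    sz <- svs$size_bp[!is_tra]
    key[!is_tra] <- paste(svs$sv_type[!is_tra],
                          as.character(.sv_size_bin(sz)), svs$cl[!is_tra],
                          sep = ":")
  }
  tab <- table(factor(key, levels = classes))
  counts[] <- as.integer(tab)
  attr(counts, "n_skipped") <- as.integer(n_skipped)
  counts
}

# non-negative least squares by cyclic coordinate descent; the problems
# here are tiny (<= 96 rows, a handful of signatures) so this converges to
# machine precision in a few sweeps
.nnls <- function(A, b, max_iter = 5000L, tol = 1e-12) {
  k <- ncol(A)
  x <- rep(0, k)
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(k)) {
      if (AtA[j, j] == 0) next
      xj_new <- max(0, x[j] + (Atb[j] - sum(AtA[j, ] * x)) / AtA[j, j])
      delta <- max(delta, abs(xj_new - x[j]))
      x[j] <- xj_new
    }
    if (delta < tol * (1 + max(abs(x)))) break
  }
  x
}

#' Refit a mutation catalog against reference signatures
#'
#' Solves `min || catalog - S %*% e ||_2` subject to `e >= 0` where the
#' columns of `S` are reference signature probability vectors over the
#' catalog's classes. Reports the cosine similarity between the catalog
#' and its reconstruction; fits with cosine below `exclude_cosine`
#' (default 0.5) are marked excluded, the rule used to drop tumours whose
#' catalog the reference cannot represent.
#'
#' @param catalog Named non-negative count vector (96 or 32 channels).
#' @param signatures Matrix (channels x signatures) with column names; row
#'   order must match `catalog`.
#' @param exclude_cosine Exclusion threshold on reconstruction cosine.
#' @return List of class `"exposure_fit"`: `exposures` (named, >= 0),
#'   `reconstruction`, `cosine`, `excluded`.
#' @export
fit_exposures <- function(catalog, signatures, exclude_cosine = 0.5) {
  signatures <- as.matrix(signatures)
  if (length(catalog) != nrow(signatures))
    stop("dimension mismatch: catalog has ", length(catalog),
         " classes, signatures have ", nrow(signatures), " rows")
  if (!is.null(names(catalog)) && !is.null(rownames(signatures)) &&
      !identical(names(catalog), rownames(signatures)))
    signatures <- signatures[names(catalog), , drop = FALSE]
  b <- as.numeric(catalog)
  if (sum(b) == 0) stop("empty catalog")
  e <- .nnls(signatures, b)
  names(e) <- colnames(signatures)
  fit <- as.numeric(signatures %*% e)
  cosine <- if (sum(fit^2) == 0) 0 else
    sum(b * fit) / sqrt(sum(b^2) * sum(fit^2))
  structure(list(exposures = e, reconstruction = fit, cosine = cosine,
                 excluded = cosine < exclude_cosine),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("Signature refit: cosine =", format(x$cosine, digits = 4),
      if (x$excluded) "(EXCLUDED, cosine < threshold)" else "", "\n")
  print(round(x$exposures, 3))
  invisible(x)
}

#' Summarize APOBEC signature attribution
#'
#' For each row of per-event (or per-sample) exposures, computes
#' `apobec_fraction = (SBS2 + SBS13) / total exposure` and `sbs2_share =
#' SBS2 / (SBS2 + SBS13)` (NA when the APOBEC exposure is zero). When a
#' `risk` column is present, cohort medians are returned per risk group.
#'
#' @param exposures `data.frame` with numeric columns `SBS2` and `SBS13`,
#'   any other numeric columns treated as further signatures, and optional
#'   id/`risk` columns.
#' @return List: `per_unit` (`data.table` with `apobec_fraction`,
#'   `sbs2_share`), `medians_by_risk` (or overall median when no risk
#'   column).
#' @export
apobec_summary <- function(exposures) {
  dt <- data.table::as.data.table(exposures)
  if (!all(c("SBS2", "SBS13") %in% names(dt)))
    stop("exposures must contain SBS2 and SBS13 columns")
  sig_cols <- names(dt)[vapply(dt, is.numeric, logical(1))]
  tot <- rowSums(dt[, ..sig_cols])
  apo <- dt$SBS2 + dt$SBS13
  dt[, apobec_fraction := ifelse(tot > 0, apo / tot, NA_real_)]
  dt[, sbs2_share := ifelse(apo > 0, SBS2 / apo, NA_real_)]
  if ("risk" %in% names(dt)) {
    med <- dt[, .(median_apobec_fraction = stats::median(apobec_fraction, na.rm = TRUE),
                  median_sbs2_share = stats::median(sbs2_share, na.rm = TRUE)),
              by = risk]
  } else {
    med <- dt[, .(median_apobec_fraction = stats::median(apobec_fraction, na.rm = TRUE),
                  median_sbs2_share = stats::median(sbs2_share, na.rm = TRUE))]
  }
  list(per_unit = dt[], medians_by_risk = med[])
}

#' Synthetic reference signature matrix (stand-in, not COSMIC)
#'
#' Builds a small column-stochastic 96-channel reference with four
#' caricature signatures: `SBS2` (C>T at TpC), `SBS13` (C>G at TpC),
#' `SBS1` (C>T at CpG) and `SBS5` (flat). These are synthetic stand-ins
#' shaped like their COSMIC namesakes for testing and simulation; they are
#' not the COSMIC profiles.
#'
#' @param leak Probability mass spread uniformly over all 96 channels of
#'   the peaked signatures (default 0.05).
#' @return 96 x 4 matrix, rows named by [sbs96_classes()], columns
#'   `SBS1`, `SBS2`, `SBS5`, `SBS13`.
#' @export
synthetic_signature_reference <- function(leak = 0.05) {
  classes <- sbs96_classes()
  peak <- function(pattern) {
    v <- rep(leak / 96, 96)
    hit <- grepl(pattern, classes)
    v[hit] <- v[hit] + (1 - leak) / sum(hit)
    v / sum(v)
  }
  m <- cbind(
    SBS1 = peak("^[ACGT]\\[C>T\\]G$"),
    SBS2 = peak("^T\\[C>T\\][ACGT]$"),
    SBS5 = rep(1 / 96, 96),
    SBS13 = peak("^T\\[C>G\\][ACGT]$"))
  rownames(m) <- classes
  m
}
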