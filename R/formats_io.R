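#' @import data.table
#' @importFrom stats median quantile complete.cases setNames cor
#' @importFrom utils combn head capture.output
NULL

# closed epoch vocabulary; anything else is an error, never coerced
.EPOCHS <- c("early_clonal", "late_clonal", "clonal_unspecified",
             "subclonal", "unknown")

.SV_TYPES <- c("DEL", "DUP", "INV", "TRA", "TRA_INV", "COMPLEX")

#' Allowed evolutionary epoch labels
#'
#' The per-SNV timing vocabulary: `early_clonal`, `late_clonal`,
#' `clonal_unspecified`, `subclonal`, `unknown`. SNVs without a label
#' default to `unknown`.
#' @return Character vector of the five labels.
#' @export
snv_epochs <- function() .EPOCHS

#' Allowed structural-variant type labels
#' @return Character vector: DEL, DUP, INV, TRA, TRA_INV, COMPLEX.
#' @export
sv_types <- function() .SV_TYPES

.check_epoch <- function(epoch) {
  epoch[is.na(epoch) | epoch == ""] <- "unknown"
  bad <- setdiff(unique(epoch), .EPOCHS)
  if (length(bad))
    stop("unknown epoch label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.EPOCHS, collapse = ", "))
  epoch
}

.validate_snvs <- function(dt) {
  bases <- c("A", "C", "G", "T")
  bad <- which(!(dt$ref %in% bases) | !(dt$alt %in% bases) |
                 dt$ref == dt$alt | dt$pos < 1)
  if (length(bad))
    stop("malformed SNV row(s) (ref/alt not a distinct single base, or pos < 1): row ",
         paste(head(bad, 5), collapse = ", "))
  dt$epoch <- .check_epoch(dt$epoch)
  dt
}

#' Read somatic SNVs from a TSV table or a VCF
#'
#' The TSV dialect expects a header with at least `chrom`, `pos`, `ref`,
#' `alt`; optional columns `sample_id`, `epoch`, `phase_group`,
#' `tricontext`. The VCF dialect (parsed with VariantAnnotation) takes the
#' epoch and phase group from INFO keys named by `epoch_key` / `phase_key`,
#' since no standard VCF field carries timing labels. Non-SNV rows (indels,
#' multi-allelic sites) are skipped; the skipped count is attached as
#' attribute `n_skipped` and messaged.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param sample_id Sample label used when the file has no sample column.
#' @param epoch_key,phase_key,context_key INFO keys (VCF) or column names
#'   (TSV) for the epoch label, phase-group ID and trinucleotide context.
#' @return `data.table` with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `epoch`, `phase_group`, `tricontext`, sorted by
#'   (sample, chrom, pos); attribute `n_skipped`.
#' @export
read_snvs <- function(path, dialect = c("tsv", "vcf"), sample_id = NULL,
                      epoch_key = "epoch", phase_key = "phase_group",
                      context_key = "tricontext") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    raw <- data.table::fread(path, sep = "\t", header = TRUE,
                             colClasses = list(character = "chrom"))
    need <- c("chrom", "pos", "ref", "alt")
    miss <- setdiff(need, names(raw))
    if (length(miss)) stop("TSV missing column(s): ", paste(miss, collapse = ", "))
    if (nrow(raw) == 0L) {
      out <- .empty_snvs()
      attr(out, "n_skipped") <- 0L
      return(out)
    }
    is_snv <- nchar(raw$ref) == 1L & nchar(raw$alt) == 1L &
      raw$ref %in% c("A", "C", "G", "T") & raw$alt %in% c("A", "C", "G", "T")
    n_skipped <- sum(!is_snv)
    raw <- raw[is_snv]
    dt <- data.table::data.table(
      sample_id = if ("sample_id" %in% names(raw)) as.character(raw$sample_id)
                  else rep(sample_id %||% "sample1", nrow(raw)),
      chrom = as.character(raw$chrom),
      pos = as.numeric(raw$pos),
      ref = as.character(raw$ref),
      alt = as.character(raw$alt),
      epoch = if (epoch_key %in% names(raw)) as.character(raw[[epoch_key]])
              else rep("unknown", nrow(raw)),
      phase_group = if (phase_key %in% names(raw)) {
        pg <- as.character(raw[[phase_key]]); pg[pg == ""] <- NA_character_; pg
      } else rep(NA_character_, nrow(raw)),
      tricontext = if (context_key %in% names(raw)) {
        tc <- as.character(raw[[context_key]]); tc[tc == ""] <- NA_character_; tc
      } else rep(NA_character_, nrow(raw))
    )
  } else {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop("VCF dialect needs the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altl <- VariantAnnotation::alt(vcf)
    n_alt <- S4Vectors::elementNROWS(altl)
    alt1 <- rep(NA_character_, length(ref))
    alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
    is_snv <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
      ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
    n_skipped <- sum(!is_snv)
    info <- VariantAnnotation::info(vcf)
    get_info <- function(key) {
      if (key %in% names(info)) as.character(info[[key]]) else
        rep(NA_character_, length(ref))
    }
    dt <- data.table::data.table(
      sample_id = rep(sample_id %||% "sample1", length(ref)),
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = as.numeric(GenomicRanges::start(rr)),
      ref = ref, alt = alt1,
      epoch = get_info(epoch_key),
      phase_group = get_info(phase_key),
      tricontext = get_info(context_key)
    )[is_snv]
  }
  dt$epoch[is.na(dt$epoch)] <- "unknown"
  dt <- .validate_snvs(dt)
  data.table::setorder(dt, sample_id, chrom, pos)
  if (n_skipped > 0L)
    message("read_snvs: skipped ", n_skipped, " non-SNV row(s)")
  attr(dt, "n_skipped") <- as.integer(n_skipped)
  dt[]
}

.empty_snvs <- function() {
  data.table::data.table(
    sample_id = character(), chrom = character(), pos = numeric(),
    ref = character(), alt = character(), epoch = character(),
    phase_group = character(), tricontext = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write somatic SNVs as a TSV table
#' @param snvs `data.table` as returned by [read_snvs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snvs <- function(snvs, path) {
  data.table::fwrite(snvs, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read somatic SVs from a BEDPE file
#'
#' BEDPE anchors are 0-based half-open; each anchor is converted to a
#' single 1-based breakend point, either the interval start (`start + 1`,
#' default) or the midpoint. Expected columns: chrom1, start1, end1,
#' chrom2, start2, end2, then the SV type, then optionally the sample ID.
#' Inter-chromosomal records must be typed TRA or TRA_INV and vice versa.
#'
#' @param path BEDPE file (plain text, no header or `#`-prefixed header).
#' @param sample_id Sample label used when the file lacks a sample column.
#' @param breakend `"start"` or `"midpoint"` anchor-to-point rule.
#' @return `data.table` with `sample_id`, `chrom1`, `pos1`, `chrom2`,
#'   `pos2`, `sv_type`, `size_bp` (NA for inter-chromosomal), sorted.
#' @export
read_svs <- function(path, sample_id = NULL, breakend = c("start", "midpoint")) {
  breakend <- match.arg(breakend)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- data.table::fread(path, header = FALSE, sep = "\t")
  raw <- raw[!startsWith(as.character(raw[[1L]]), "#")]
  if (nrow(raw) == 0L || ncol(raw) < 7L)
    stop("BEDPE needs >= 7 columns: chrom1 start1 end1 chrom2 start2 end2 type [sample]")
  pt <- function(s, e) if (breakend == "start") s + 1 else floor((s + e) / 2) + 1
  dt <- data.table::data.table(
    sample_id = if (ncol(raw) >= 8L) as.character(raw[[8L]])
                else rep(sample_id %||% "sample1", nrow(raw)),
    chrom1 = as.character(raw[[1L]]),
    pos1 = pt(as.numeric(raw[[2L]]), as.numeric(raw[[3L]])),
    chrom2 = as.character(raw[[4L]]),
    pos2 = pt(as.numeric(raw[[5L]]), as.numeric(raw[[6L]])),
    sv_type = as.character(raw[[7L]])
  )
  .validate_svs(dt)
}

.validate_svs <- function(dt) {
  bad <- setdiff(unique(dt$sv_type), .SV_TYPES)
  if (length(bad))
    stop("unknown SV type(s): ", paste(bad, collapse = ", "))
  inter <- dt$chrom1 != dt$chrom2
  tra <- dt$sv_type %in% c("TRA", "TRA_INV")
  if (any(inter & !tra))
    stop("inter-chromosomal SV typed ", dt$sv_type[which(inter & !tra)[1]],
         " (must be TRA or TRA_INV)")
  if (any(!inter & tra))
    stop("intra-chromosomal SV typed TRA/TRA_INV")
  flip <- !inter & dt$pos1 > dt$pos2
  if (any(flip)) {
    tmp <- dt$pos1[flip]; dt$pos1[flip] <- dt$pos2[flip]; dt$pos2[flip] <- tmp
  }
  dt$size_bp <- ifelse(inter, NA_real_, dt$pos2 - dt$pos1)
  data.table::setorder(dt, sample_id, chrom1, pos1)
  dt[]
}

#' Write somatic SVs as BEDPE
#'
#' Inverse of [read_svs()] under the `"start"` breakend rule: each 1-based
#' breakend point p becomes the 0-based half-open interval `[p-1, p)`.
#' @param svs `data.table` as returned by [read_svs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_svs <- function(svs, path) {
  out <- data.table::data.table(
    chrom1 = svs$chrom1, start1 = format(svs$pos1 - 1, scientific = FALSE, trim = TRUE),
    end1 = format(svs$pos1, scientific = FALSE, trim = TRUE),
    chrom2 = svs$chrom2, start2 = format(svs$pos2 - 1, scientific = FALSE, trim = TRUE),
    end2 = format(svs$pos2, scientific = FALSE, trim = TRUE),
    sv_type = svs$sv_type, sample_id = svs$sample_id)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genome exclusion mask from BED
#'
#' @param path BED file (0-based half-open), e.g. HLA/ALT regions.
#' @return A reduced `GRanges` (1-based inclusive internally).
#' @export
read_mask <- function(path) {
  raw <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(raw) == 0L) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(raw[[1L]]),
    ranges = IRanges::IRanges(start = as.numeric(raw[[2L]]) + 1,
                              end = as.numeric(raw[[3L]])))
  GenomicRanges::reduce(gr)
}

#' Genome-mask membership
#'
#' @param mask `GRanges` from [read_mask()] (or any GRanges).
#' @param chrom,pos Parallel vectors of 1-based query positions.
#' @return Logical vector: TRUE where the position falls inside the mask.
#' @export
mask_member <- function(mask, chrom, pos) {
  if (length(mask) == 0L) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  GenomicRanges::countOverlaps(q, mask) > 0L
}

#' Total masked length in bp
#' @param mask `GRanges` mask.
#' @return Numeric scalar.
#' @export
mask_width <- function(mask) sum(as.numeric(GenomicRanges::width(mask)))

#' Annotate event spans against named intervals
#'
#' Labels each event with the names of all overlapping intervals (e.g.
#' genes or regulatory regions). Event spans are 1-based inclusive;
#' `intervals` read from BED should be converted with [read_bed_intervals()]
#' which handles the half-open convention, so an event ending where an
#' interval begins does not overlap it.
#'
#' @param events `data.frame` with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param intervals `GRanges` with a `name` metadata column, or a
#'   `data.frame` with `chrom`, `start`, `end` (1-based inclusive), `name`.
#' @return List (one element per event) of character vectors of overlapping
#'   interval names; `character(0)` when none.
#' @export
annotate_intervals <- function(events, intervals) {
  if (is.data.frame(intervals)) {
    intervals <- GenomicRanges::GRanges(
      intervals$chrom,
      IRanges::IRanges(intervals$start, intervals$end),
      name = intervals$name)
  }
  if (nrow(events) == 0L) return(list())
  ev <- GenomicRanges::GRanges(events$chrom,
                               IRanges::IRanges(events$start, events$end))
  hits <- GenomicRanges::findOverlaps(ev, intervals)
  out <- rep(list(character(0)), nrow(events))
  if (length(hits)) {
    sp <- split(intervals$name[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    for (k in names(sp)) out[[as.integer(k)]] <- unique(sp[[k]])
  }
  out
}

#' Read named intervals from a BED file
#' @param path BED file (0-based half-open; column 4 = name).
#' @return `GRanges` with a `name` column, 1-based inclusive.
#' @export
read_bed_intervals <- function(path) {
  raw <- data.table::fread(path, header = FALSE, sep = "\t")
  GenomicRanges::GRanges(
    as.character(raw[[1L]]),
    IRanges::IRanges(start = as.numeric(raw[[2L]]) + 1, end = as.numeric(raw[[3L]])),
    name = if (ncol(raw) >= 4L) as.character(raw[[4L]])
           else paste0("iv", seq_len(nrow(raw))))
}

#' Write kataegis events as TSV (all fields) and optionally BED
#'
#' The TSV keeps every column including a comma-separated member-SNV
#' position list; the BED companion (0-based half-open) carries
#' sample/epoch in the name column for genome-browser use.
#'
#' @param events Event `data.table` (candidates or filtered events).
#' @param path Output TSV path.
#' @param bed_path Optional BED output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, bed_path = NULL) {
  flat <- data.table::copy(data.table::as.data.table(events))
  if ("snvs" %in% names(flat)) {
    pull <- function(m, col, fmt = identity) {
      v <- if (col %in% names(m)) m[[col]] else rep(NA, nrow(m))
      v <- as.character(fmt(v))
      v[is.na(v)] <- "."        # strsplit drops trailing empties; "." marks NA
      paste(v, collapse = ",")
    }
    nfmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
    flat[, member_pos := vapply(snvs, pull, character(1), "pos", nfmt)]
    flat[, member_ref := vapply(snvs, pull, character(1), "ref")]
    flat[, member_alt := vapply(snvs, pull, character(1), "alt")]
    flat[, member_epoch := vapply(snvs, pull, character(1), "epoch")]
    flat[, member_phase := vapply(snvs, pull, character(1), "phase_group")]
    flat[, member_context := vapply(snvs, pull, character(1), "tricontext")]
    flat[, snvs := NULL]
  }
  member_cols <- grep("^member_", names(flat), value = TRUE)
  data.table::setcolorder(flat, c(setdiff(names(flat), member_cols), member_cols))
  data.table::fwrite(flat, path, sep = "\t", na = "", quote = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.table::data.table(
      chrom = events$chrom,
      start = format(events$start - 1, scientific = FALSE, trim = TRUE),
      end = format(events$end, scientific = FALSE, trim = TRUE),
      name = paste(events$sample_id, events$epoch_tag, sep = "|"))
    data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read kataegis events written by [write_events()]
#' @param path TSV path.
#' @return Event `data.table`; the `member_pos` column is expanded back to
#'   a `snvs` list-column of position tables.
#' @export
read_events <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "chrom"))
  if ("member_pos" %in% names(dt) && nrow(dt) > 0L) {
    members <- lapply(seq_len(nrow(dt)), function(i) {
      grab <- function(col) {
        if (!col %in% names(dt)) return(NULL)
        v <- strsplit(as.character(dt[[col]][i]), ",", fixed = TRUE)[[1]]
        v[v %in% c("", ".")] <- NA_character_
        v
      }
      pos <- as.numeric(grab("member_pos"))
      sid <- if ("sample_id" %in% names(dt)) dt$sample_id[i] else NA_character_
      ch <- if ("chrom" %in% names(dt)) dt$chrom[i] else NA_character_
      m <- data.table::data.table(
        sample_id = rep(sid, length(pos)), chrom = rep(ch, length(pos)),
        pos = pos)
      for (col in c("ref", "alt", "epoch", "phase_group", "tricontext")) {
        src <- c(ref = "member_ref", alt = "member_alt", epoch = "member_epoch",
                 phase_group = "member_phase", tricontext = "member_context")[[col]]
        v <- grab(src)
        if (!is.null(v) && length(v) == length(pos))
          data.table::set(m, j = col, value = v)
      }
      m
    })
    data.table::set(dt, j = "snvs", value = list(members))
  }
  dt[]
}
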