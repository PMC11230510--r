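.PYR_COMP <- c(A = "T", C = "G", G = "C", T = "A")

# strand-normalize a substitution to a pyrimidine (C or T) reference
.normalize_sub <- function(ref, alt) {
  flip <- ref %in% c("A", "G")
  data.frame(
    ref = ifelse(flip, unname(.PYR_COMP[ref]), ref),
    alt = ifelse(flip, unname(.PYR_COMP[alt]), alt),
    stringsAsFactors = FALSE)
}

#' Substitution-type consistency of a kataegis candidate
#'
#' A kataegis event produced by one mutational process mutates one strand,
#' so its member SNVs share the strand-normalized reference base. Under the
#' default `"reference_base"` rule the candidate is consistent when all
#' members are C:G sites or all are T:A sites after pyrimidine
#' normalization; this admits the canonical APOBEC C>T / C>G mixture. The
#' stricter `"substitution"` rule requires one identical normalized
#' substitution class.
#'
#' @param members Member-SNV `data.frame` with `ref` and `alt` (one
#'   candidate's `snvs[[i]]`), or a candidate row's member table.
#' @param rule `"reference_base"` (default) or `"substitution"`.
#' @return Logical scalar.
#' @export
is_type_consistent <- function(members, rule = c("reference_base", "substitution")) {
  rule <- match.arg(rule)
  norm <- .normalize_sub(members$ref, members$alt)
  if (rule == "reference_base") length(unique(norm$ref)) == 1L
  else length(unique(paste(norm$ref, norm$alt, sep = ">"))) == 1L
}

#' Phasing support (in-cis) of a kataegis candidate
#'
#' TRUE when at least two member SNVs carry the same non-missing
#' phase-group ID, i.e. they are read-backed to the same chromosomal
#' homolog.
#'
#' @param members Member-SNV `data.frame` with a `phase_group` column.
#' @return Logical scalar.
#' @export
is_in_cis <- function(members) {
  pg <- members$phase_group
  pg <- pg[!is.na(pg) & pg != ""]
  length(pg) >= 2L && any(duplicated(pg))
}

#' Filter kataegis candidates on the two kataegis characteristics
#'
#' In `"phased"` mode a candidate is kept when it shows at least one of the
#' two characteristics: substitution-type consistency, or members in cis
#' (shared phase group). In `"consecutiveness_only"` mode (public cohorts
#' without phasing) only type consistency is available, so only consistent
#' candidates are kept. Every drop is accounted for: the returned ledger
#' counts sum exactly to input minus output.
#'
#' @param candidates Candidate `data.table` from [call_kataegis()].
#' @param mode `"phased"` or `"consecutiveness_only"`.
#' @param rule Consistency rule passed to [is_type_consistent()].
#' @return List with `events` (kept rows plus `type_consistent`, `in_cis`,
#'   `kept`, `drop_reason` columns on all rows in `all`), `all` (annotated
#'   input) and `ledger` (named integer drop counts).
#' @export
apply_filters <- function(candidates, mode = c("phased", "consecutiveness_only"),
                          rule = c("reference_base", "substitution")) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  cand <- data.table::copy(data.table::as.data.table(candidates))
  if (nrow(cand) == 0L) {
    cand[, `:=`(type_consistent = logical(), in_cis = logical(),
                kept = logical(), drop_reason = character())]
    return(list(events = cand[], all = cand[], ledger = integer(0)))
  }
  cand[, type_consistent := vapply(snvs, is_type_consistent, logical(1), rule = rule)]
  cand[, in_cis := vapply(snvs, is_in_cis, logical(1))]
  if (mode == "phased") {
    cand[, kept := type_consistent | in_cis]
  } else {
    cand[, kept := type_consistent]
  }
  cand[, drop_reason := ifelse(kept, NA_character_, "inconsistent_and_unphased")]
  ledger <- table(cand$drop_reason[!cand$kept])
  ledger <- stats::setNames(as.integer(ledger), names(ledger))
  stopifnot(nrow(cand) == sum(cand$kept) + sum(ledger))
  list(events = cand[kept == TRUE][], all = cand[], ledger = ledger)
}
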