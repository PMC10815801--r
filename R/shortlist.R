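#' Cell-line binding phenotype
#'
#' The recognition pattern an aptamer panel shows across cell lines: lines
#' it recognizes (candidate targets must be overexpressed there) and lines
#' it does not (candidates must be under-expressed there).
#'
#' @param recognized character vector of recognized cell-line labels.
#' @param unrecognized character vector of unrecognized cell-line labels.
#' @return Object of class `binding_phenotype`.
#' @export
binding_phenotype <- function(recognized, unrecognized) {
  recognized <- as.character(recognized)
  unrecognized <- as.character(unrecognized)
  if (!length(recognized) || !length(unrecognized))
    stop("both recognized and unrecognized line sets must be nonempty")
  if (length(intersect(recognized, unrecognized)))
    stop("recognized and unrecognized line sets must be disjoint")
  structure(list(recognized = recognized, unrecognized = unrecognized),
            class = "binding_phenotype")
}

.validate_protein_records <- function(records) {
  need <- c("protein_id", "abundance_target", "abundance_control")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("protein records missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$protein_id))
    stop("duplicate protein ids")
  if (any(records$abundance_target < 0) || any(records$abundance_control < 0))
    stop("abundances must be nonnegative")
  invisible(TRUE)
}

#' Fold-change filter on target vs control abundance
#'
#' A protein survives iff
#' `(abundance_target + pc) / (abundance_control + pc) >= factor`. The
#' default pseudocount `pc` is 0 when every abundance is positive (so a
#' ratio of exactly `factor` survives — "at least n-fold" is inclusive) and
#' otherwise the smallest positive abundance in the table, guarding the
#' zero-denominator case.
#'
#' @param records data frame with `protein_id`, `abundance_target`,
#'   `abundance_control` (plus any further columns, carried through).
#' @param factor minimum fold increase, `>= 1`; default 2.
#' @param pseudocount override the default pseudocount.
#' @return The surviving rows, with the pseudocount used recorded in
#'   attribute `pseudocount`.
#' @export
fold_change_filter <- function(records, factor = 2, pseudocount = NULL) {
  .validate_protein_records(records)
  if (factor < 1) stop("factor must be >= 1")
  if (!NROW(records)) {
    attr(records, "pseudocount") <- 0
    return(records)
  }
  ab <- c(records$abundance_target, records$abundance_control)
  if (is.null(pseudocount)) {
    pseudocount <- if (any(ab == 0)) {
      pos <- ab[ab > 0]
      if (length(pos)) min(pos) else 1
    } else 0
  }
  ratio <- (records$abundance_target + pseudocount) /
    (records$abundance_control + pseudocount)
  out <- records[ratio >= factor, , drop = FALSE]
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Membrane-evidence filter
#'
#' A protein survives iff it appears in the membrane-proteome evidence set
#' (`membrane_evidence` TRUE) AND its predicted localization is the plasma
#' membrane — both lines of evidence conjointly.
#'
#' @param records data frame with logical `membrane_evidence` and character
#'   `predicted_localization` columns (`"plasma_membrane"` or `"other"`).
#' @return Surviving rows.
#' @export
membrane_filter <- function(records) {
  need <- c("membrane_evidence", "predicted_localization")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  keep <- as.logical(records$membrane_evidence) &
    records$predicted_localization == "plasma_membrane"
  records[keep %in% TRUE, , drop = FALSE]
}

#' Expression-phenotype filter
#'
#' A protein survives iff its published expression status is `"over"` in
#' every recognized cell line and `"under"` in every unrecognized line.
#' In strict mode (default) an `"unknown"` status fails the requirement; in
#' lenient mode unknown lines are ignored.
#'
#' @param records data frame with one status column per cell line
#'   (values `over`/`under`/`unknown`).
#' @param phenotype a [binding_phenotype].
#' @param strict fail on unknown status (default TRUE).
#' @return Surviving rows.
#' @export
phenotype_filter <- function(records, phenotype, strict = TRUE) {
  stopifnot(inherits(phenotype, "binding_phenotype"))
  lines <- c(phenotype$recognized, phenotype$unrecognized)
  miss <- setdiff(lines, names(records))
  if (length(miss))
    stop("phenotype line(s) absent from records: ",
         paste(miss, collapse = ", "))
  if (!NROW(records)) return(records)
  ok_line <- function(status, want) {
    status <- as.character(status)
    if (strict) status == want else status == want | status == "unknown"
  }
  keep <- rep(TRUE, nrow(records))
  for (l in phenotype$recognized) keep <- keep & ok_line(records[[l]], "over")
  for (l in phenotype$unrecognized) keep <- keep & ok_line(records[[l]], "under")
  records[keep, , drop = FALSE]
}

#' Run the target-shortlisting cascade
#'
#' Applies, in order: the fold-change filter (target vs control lineage),
#' the membrane filter (membrane-proteome evidence + plasma-membrane
#' localization), and the expression-phenotype filter, and reports survivor
#' counts per stage with the final shortlist of protein ids.
#'
#' @param records merged protein records (see the individual filters for
#'   required columns).
#' @param phenotype a [binding_phenotype].
#' @param factor fold-change factor (default 2).
#' @param pseudocount see [fold_change_filter()].
#' @param strict see [phenotype_filter()].
#' @return Object of class `shortlist_cascade`: list with `stage_counts`
#'   (named: input, fold_change, membrane, phenotype), `shortlist`
#'   (character vector of protein ids), `stages` (surviving records per
#'   stage) and `pseudocount`.
#' @export
run_cascade <- function(records, phenotype, factor = 2, pseudocount = NULL,
                        strict = TRUE) {
  .validate_protein_records(records)
  s1 <- fold_change_filter(records, factor = factor,
                           pseudocount = pseudocount)
  s2 <- membrane_filter(s1)
  s3 <- phenotype_filter(s2, phenotype, strict = strict)
  structure(list(stage_counts = c(input = nrow(records),
                                  fold_change = nrow(s1),
                                  membrane = nrow(s2),
                                  phenotype = nrow(s3)),
                 shortlist = as.character(s3$protein_id),
                 stages = list(fold_change = s1, membrane = s2,
                               phenotype = s3),
                 pseudocount = attr(s1, "pseudocount")),
            class = "shortlist_cascade")
}

#' @export
print.shortlist_cascade <- function(x, ...) {
  cat("target shortlist cascade:\n")
  cat(sprintf("  input: %d -> fold-change: %d -> membrane: %d -> phenotype: %d\n",
              x$stage_counts[["input"]], x$stage_counts[["fold_change"]],
              x$stage_counts[["membrane"]], x$stage_counts[["phenotype"]]))
  cat("  shortlist:",
      if (length(x$shortlist)) paste(x$shortlist, collapse = ", ")
      else "(empty)", "\n")
  if (x$pseudocount > 0)
    cat("  fold-change pseudocount:", x$pseudocount, "\n")
  invisible(x)
}

#' Derive over/under expression calls from abundances
#'
#' Optional helper for when per-line published calls are unavailable:
#' a line is called `over` when its abundance is at least `fold` times the
#' reference, `under` when at most `1/fold` times, otherwise `unknown`.
#'
#' @param abundance named numeric vector, abundance per cell line.
#' @param reference reference abundance (e.g. control lineage).
#' @param fold call threshold (default 2).
#' @return Named character vector of `over`/`under`/`unknown` calls.
#' @export
derive_expression_status <- function(abundance, reference, fold = 2) {
  if (reference <= 0) stop("reference abundance must be positive")
  ratio <- abundance / reference
  out <- ifelse(ratio >= fold, "over",
                ifelse(ratio <= 1 / fold, "under", "unknown"))
  stats::setNames(out, names(abundance))
}
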