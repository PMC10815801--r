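.cohort_meta_cols <- c("sample_id", "class", "subtype", "stage", "grade",
                       "tnm")
.cohort_classes <- c("adjacent", "primary_tumor", "metastatic")

#' Aptamer intensity columns of a cohort
#'
#' A recognition cohort is a plain data frame with one row per tissue
#' sample: metadata columns `sample_id`, `class` (one of `adjacent`,
#' `primary_tumor`, `metastatic`), `subtype`, `stage`, `grade`, `tnm`, plus
#' one ordinal staining-intensity column per aptamer, coded
#' 0 = none, 1 = (+), 2 = (++), 3 = (+++).
#'
#' @param cohort a cohort data frame.
#' @return Character vector of aptamer column names.
#' @export
aptamer_names <- function(cohort) {
  setdiff(names(cohort), .cohort_meta_cols)
}

.validate_cohort <- function(cohort) {
  if (!NROW(cohort)) stop("empty cohort")
  if (!"class" %in% names(cohort)) stop("cohort must have a 'class' column")
  bad <- setdiff(unique(as.character(cohort$class)), .cohort_classes)
  if (length(bad))
    stop("unknown sample class value(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Combined panel intensity (union rule)
#'
#' A sample's panel intensity is the maximum intensity over the member
#' aptamers, so the sample is panel-positive iff any member stains it at or
#' above the positivity threshold.
#'
#' @param cohort cohort data frame (see [aptamer_names()]).
#' @param aptamers nonempty character vector of member aptamer names.
#' @return Integer vector of combined per-sample intensities.
#' @export
panel_union <- function(cohort, aptamers) {
  if (!length(aptamers)) stop("panel must contain at least one aptamer")
  missing <- setdiff(aptamers, names(cohort))
  if (length(missing))
    stop("unknown aptamer name(s): ", paste(missing, collapse = ", "))
  m <- as.matrix(cohort[, aptamers, drop = FALSE])
  as.integer(apply(m, 1L, max))
}

#' Contingency counts for an aptamer or panel on a labeled cohort
#'
#' A sample is positive iff its staining intensity (panel-combined via the
#' union rule for multi-aptamer input) is at least `threshold`. Samples of a
#' tumor class contribute TP/FN; adjacent (non-tumor) samples contribute
#' FP/TN.
#'
#' @param cohort cohort data frame.
#' @param aptamers one aptamer name or a character vector (a panel).
#' @param threshold positivity threshold on the ordinal scale, in
#'   `{1, 2, 3}`; default 1 (any staining).
#' @param tumor_classes which classes count as tumor; default both
#'   `primary_tumor` and `metastatic`.
#' @return An object of class `contingency_counts`: named integer vector
#'   with `TP`, `FP`, `FN`, `TN`.
#' @export
build_contingency <- function(cohort, aptamers, threshold = 1L,
                              tumor_classes = c("primary_tumor",
                                                "metastatic")) {
  .validate_cohort(cohort)
  if (!threshold %in% 1:3) stop("threshold must be in {1, 2, 3}")
  if (!all(tumor_classes %in% c("primary_tumor", "metastatic")))
    stop("tumor_classes must be a subset of {primary_tumor, metastatic}")
  intensity <- panel_union(cohort, aptamers)
  pos <- intensity >= threshold
  tumor <- as.character(cohort$class) %in% tumor_classes
  nontumor <- as.character(cohort$class) == "adjacent"
  structure(c(TP = sum(pos & tumor), FP = sum(pos & nontumor),
              FN = sum(!pos & tumor), TN = sum(!pos & nontumor)),
            class = "contingency_counts")
}

# round half away from zero, the convention behind the printed
# integer-percent tables (e.g. 12.5% -> 13%)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Diagnostic indices from contingency counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(FP+TN)` and accuracy
#' `(TP+TN)/(TP+FP+FN+TN)`, with integer-percent renderings using
#' round-half-away-from-zero. An index with a zero denominator is flagged
#' undefined (`NA`), never fabricated.
#'
#' @param counts a [build_contingency()] result or named vector with
#'   `TP`, `FP`, `FN`, `TN`.
#' @return Object of class `diagnostic_indices`: list with fractional
#'   `sensitivity`, `specificity`, `accuracy`, integer-percent counterparts
#'   (`*_pct`), and the input `counts`.
#' @export
diagnostic_indices <- function(counts) {
  c_ <- unclass(counts)
  stopifnot(all(c("TP", "FP", "FN", "TN") %in% names(c_)))
  if (any(c_ < 0)) stop("counts must be nonnegative")
  tp <- c_[["TP"]]; fp <- c_[["FP"]]; fn <- c_[["FN"]]; tn <- c_[["TN"]]
  total <- tp + fp + fn + tn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
  acc <- if (total > 0) (tp + tn) / total else NA_real_
  pct <- function(x) if (is.na(x)) NA_real_ else round_half_up(100 * x)
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 sensitivity_pct = pct(sens), specificity_pct = pct(spec),
                 accuracy_pct = pct(acc), counts = c_),
            class = "diagnostic_indices")
}

#' @export
print.diagnostic_indices <- function(x, ...) {
  fmt <- function(v, p) if (is.na(v)) "undefined" else
    sprintf("%d%% (%.3f)", as.integer(p), v)
  cat("sensitivity:", fmt(x$sensitivity, x$sensitivity_pct), "\n")
  cat("specificity:", fmt(x$specificity, x$specificity_pct), "\n")
  cat("accuracy:   ", fmt(x$accuracy, x$accuracy_pct), "\n")
  invisible(x)
}

#' Evaluate aptamer panels on a cohort
#'
#' Applies [panel_union()], [build_contingency()] and
#' [diagnostic_indices()] per panel. With `exhaustive = TRUE` all
#' `2^k - 1` nonempty subsets of the cohort's aptamers are evaluated and
#' ranked by sensitivity, ties by specificity (both descending).
#'
#' @param cohort cohort data frame.
#' @param panels list of character vectors (one per panel); ignored when
#'   `exhaustive = TRUE`.
#' @param threshold positivity threshold.
#' @param tumor_classes as in [build_contingency()].
#' @param exhaustive evaluate every nonempty aptamer subset.
#' @return Data frame with one row per panel: `panel`, `n_aptamers`,
#'   TP/FP/FN/TN, and the three indices as fractions and integer percents.
#' @export
evaluate_panels <- function(cohort, panels = NULL, threshold = 1L,
                            tumor_classes = c("primary_tumor", "metastatic"),
                            exhaustive = FALSE) {
  if (exhaustive) {
    apts <- aptamer_names(cohort)
    k <- length(apts)
    if (k > 16L) stop("exhaustive search limited to 16 aptamers")
    panels <- unlist(lapply(seq_len(k), function(m)
      utils::combn(apts, m, simplify = FALSE)), recursive = FALSE)
  }
  if (!length(panels)) stop("no panels supplied")
  rows <- lapply(panels, function(p) {
    cc <- build_contingency(cohort, p, threshold, tumor_classes)
    di <- diagnostic_indices(cc)
    data.frame(panel = paste(p, collapse = "+"), n_aptamers = length(p),
               TP = cc[["TP"]], FP = cc[["FP"]], FN = cc[["FN"]],
               TN = cc[["TN"]],
               sensitivity = di$sensitivity, specificity = di$specificity,
               accuracy = di$accuracy,
               sensitivity_pct = di$sensitivity_pct,
               specificity_pct = di$specificity_pct,
               accuracy_pct = di$accuracy_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (exhaustive)
    out <- out[order(-out$sensitivity, -out$specificity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recognition stratified by a clinical variable
#'
#' Per-stratum recognized/total counts, percent recognition and the maximum
#' staining intensity observed among recognized samples, mirroring
#' tissue-microarray summary tables.
#'
#' @param cohort cohort data frame.
#' @param aptamers aptamer (or panel) to evaluate.
#' @param stratify_by one of `class`, `subtype`, `stage`, `grade`, `tnm`.
#' @param threshold positivity threshold.
#' @param classes restrict to these sample classes first (default: tumor
#'   samples only when stratifying by a tumor variable; pass `NULL` to keep
#'   all).
#' @param percent_digits decimals in the percent column (0 = integer
#'   percent; 1 matches mixed one-decimal usage).
#' @return Data frame: `stratum`, `recognized`, `total`, `percent`
#'   (`NA`-flagged for empty strata) and `max_intensity`.
#' @export
stratified_recognition <- function(cohort, aptamers,
                                   stratify_by = c("class", "subtype",
                                                   "stage", "grade", "tnm"),
                                   threshold = 1L,
                                   classes = c("primary_tumor",
                                               "metastatic"),
                                   percent_digits = 0) {
  stratify_by <- match.arg(stratify_by)
  .validate_cohort(cohort)
  if (!is.null(classes) && stratify_by != "class")
    cohort <- cohort[as.character(cohort$class) %in% classes, , drop = FALSE]
  if (!NROW(cohort)) stop("no samples left after class restriction")
  intensity <- panel_union(cohort, aptamers)
  pos <- intensity >= threshold
  strata <- as.character(cohort[[stratify_by]])
  levs <- unique(strata)
  rows <- lapply(levs, function(s) {
    in_s <- strata == s
    n <- sum(in_s)
    rec <- sum(pos & in_s)
    data.frame(stratum = s, recognized = rec, total = n,
               percent = if (n > 0)
                 round_half_up(100 * rec / n, percent_digits) else NA_real_,
               max_intensity = if (rec > 0)
                 max(intensity[pos & in_s]) else 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rebuild a cohort from published marginal recognition counts
#'
#' Constructs a cohort whose per-aptamer, per-stratum positive counts match
#' a table of marginals. Strata are defined by whichever metadata columns
#' are present among `class`, `subtype`, `stage`, `grade`, `tnm` (at least
#' `class`); each distinct stratum contributes `total` samples (totals must
#' agree across aptamers). Positives are assigned to the first samples of
#' each stratum, so marginals are exact but the joint structure across
#' aptamers is arbitrary: only individual-aptamer indices are meaningful on
#' such a cohort, never panel combinations.
#'
#' @param marginals data frame with columns `aptamer`, `positive`, `total`,
#'   at least one of the metadata columns, and optionally `intensity`
#'   (ordinal level given to positives, default 1).
#' @return A cohort data frame.
#' @export
cohort_from_counts <- function(marginals) {
  stopifnot(all(c("aptamer", "positive", "total") %in% names(marginals)))
  strat_cols <- intersect(.cohort_meta_cols[-1], names(marginals))
  if (!"class" %in% strat_cols)
    stop("marginals must include a 'class' column")
  bad <- setdiff(unique(as.character(marginals$class)), .cohort_classes)
  if (length(bad)) stop("unknown class value(s): ",
                        paste(bad, collapse = ", "))
  key <- do.call(paste, c(marginals[strat_cols], sep = "\r"))
  strata <- marginals[!duplicated(key), strat_cols, drop = FALSE]
  skey <- key[!duplicated(key)]
  totals <- vapply(skey, function(k) {
    tot <- unique(marginals$total[key == k])
    if (length(tot) != 1L)
      stop("stratum totals disagree across aptamers")
    as.integer(tot)
  }, 0L)
  n <- sum(totals)
  cohort <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                       stringsAsFactors = FALSE)
  stratum_of <- rep(skey, totals)
  for (col in .cohort_meta_cols[-1])
    cohort[[col]] <- if (col %in% strat_cols)
      rep(as.character(strata[[col]]), totals) else "unknown"
  for (a in unique(marginals$aptamer)) {
    v <- integer(n)
    sub_idx <- which(marginals$aptamer == a)
    for (i in sub_idx) {
      if (marginals$positive[i] > marginals$total[i])
        stop("positive exceeds total for ", a, " / ", key[i])
      idx <- which(stratum_of == key[i])[seq_len(marginals$positive[i])]
      lev <- if ("intensity" %in% names(marginals))
        marginals$intensity[i] else 1L
      v[idx] <- as.integer(lev)
    }
    cohort[[a]] <- v
  }
  cohort
}
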