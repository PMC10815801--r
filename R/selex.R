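#' Quality-scored read sets
#'
#' A `quality_reads` object is the package's in-memory representation of a
#' FASTQ file: parallel vectors of read ids, sequences over `{A,C,G,T,N}`,
#' and per-base Phred quality scores (integer vectors, one per read).
#'
#' @param id character vector of read identifiers.
#' @param sequence character vector of read sequences.
#' @param quality list of integer vectors of per-base Phred scores, one per
#'   read, each the same length as its sequence. Values must lie in
#'   `[0, 93]` (the printable Phred+33 range).
#' @return An object of class `quality_reads`.
#' @examples
#' r <- quality_reads("r1", "ACGT", list(c(30L, 30L, 30L, 30L)))
#' length(r)
#' @export
quality_reads <- function(id = character(), sequence = character(),
                          quality = list()) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence) || length(id) != length(quality))
    stop("id, sequence and quality must have equal length")
  quality <- lapply(quality, function(q) as.integer(q))
  lens_ok <- mapply(function(s, q) nchar(s) == length(q), sequence, quality,
                    USE.NAMES = FALSE)
  if (length(lens_ok) && !all(lens_ok))
    stop("sequence/quality length mismatch at read ",
         which(!lens_ok)[1L])
  flat_q <- unlist(quality, use.names = FALSE)
  if (length(flat_q) && (min(flat_q) < 0L || max(flat_q) > 93L))
    stop("Phred values must lie in [0, 93]")
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop("sequence contains non-ACGTN characters at read ", which(bad)[1L])
  structure(list(id = id, sequence = sequence, quality = quality),
            class = "quality_reads")
}

#' @export
length.quality_reads <- function(x) length(x$id)

#' @export
`[.quality_reads` <- function(x, i) {
  quality_reads(x$id[i], x$sequence[i], x$quality[i])
}

#' @export
print.quality_reads <- function(x, ...) {
  n <- length(x)
  cat("quality_reads:", n, "read(s)\n")
  if (n) {
    lens <- nchar(x$sequence)
    cat("  lengths:", min(lens), "-", max(lens), "nt\n")
    show <- seq_len(min(3L, n))
    for (i in show)
      cat("  ", x$id[i], " ", substr(x$sequence[i], 1, 40),
          if (nchar(x$sequence[i]) > 40) "..." else "", "\n", sep = "")
    if (n > 3L) cat("  ...\n")
  }
  invisible(x)
}

#' Read a FASTQ file into a quality_reads object
#'
#' Parses 4-line FASTQ records with Phred+33 quality encoding. Parsing is
#' delegated to Biostrings; malformed records (truncated, length-mismatched,
#' out-of-range encoding) raise an error.
#'
#' @param path path to an (uncompressed or gzipped) FASTQ file.
#' @return A [quality_reads] object, record order preserved.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  # structural validation first: Biostrings is lenient about short quality
  # lines, but a malformed record must fail loudly, naming the record
  con <- gzfile(path, "r")
  lines <- readLines(con, warn = FALSE)
  close(con)
  n_complete <- length(lines) %/% 4L
  if (n_complete) {
    full <- seq_len(n_complete * 4L)
    hdr <- lines[full][seq(1L, n_complete * 4L, 4L)]
    seqs <- lines[full][seq(2L, n_complete * 4L, 4L)]
    plus <- lines[full][seq(3L, n_complete * 4L, 4L)]
    quals <- lines[full][seq(4L, n_complete * 4L, 4L)]
    bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
    if (length(bad))
      stop("malformed FASTQ in ", path, ": bad record ", bad[1L])
    bad_len <- which(nchar(seqs) != nchar(quals))
    if (length(bad_len))
      stop("malformed FASTQ in ", path,
           ": sequence/quality length mismatch at record ", bad_len[1L])
    if (any(nzchar(quals))) {
      qr <- range(utf8ToInt(paste(quals, collapse = "")))
      if (qr[1] < 33L || qr[2] > 126L)
        stop("malformed FASTQ in ", path, ": quality encoding out of range")
    }
  }
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ in ", path, ": truncated record ",
         n_complete + 1L)
  tryCatch({
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(
      path, quality.scoring = "phred"))
    quals <- methods::as(Biostrings::quality(x), "IntegerList")
    quality_reads(id = names(x),
                  sequence = as.character(x),
                  quality = as.list(quals))
  }, error = function(e) stop("malformed FASTQ in ", path, ": ",
                              conditionMessage(e), call. = FALSE))
}

#' Write a quality_reads object as FASTQ (Phred+33)
#'
#' @param reads a [quality_reads] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "quality_reads"))
  if (!length(reads)) {
    file.create(path)
    return(invisible(path))
  }
  qual_chr <- vapply(reads$quality,
                     function(q) rawToChar(as.raw(q + 33L)), "")
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::PhredQuality(qual_chr))
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Sliding-window trimming policy
#'
#' Mirrors the Trimmomatic-style `SLIDINGWINDOW:4:20` + `MINLEN:74`
#' settings commonly used for SELEX libraries. Note the trimming threshold
#' is a window *mean* quality, and the semantics are fully defined by
#' [sliding_window_trim()] so results are reproducible without the external
#' tool.
#'
#' @param window window width in bases (default 4).
#' @param mean_quality_threshold minimum window mean Phred quality
#'   (default 20, i.e. the "4:20" option).
#' @param min_length minimum surviving read length (default 74).
#' @return An object of class `trim_policy`.
#' @export
trim_policy <- function(window = 4L, mean_quality_threshold = 20,
                        min_length = 74L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1")
  if (min_length < 0) stop("min_length must be >= 0")
  structure(list(window = window,
                 mean_quality_threshold = as.numeric(mean_quality_threshold),
                 min_length = as.integer(min_length)),
            class = "trim_policy")
}

# Kept prefix length of one quality vector under the window rule.
.sw_keep_length <- function(q, w, thr) {
  n <- length(q)
  if (n == 0L) return(0L)
  if (n < w) return(if (mean(q) >= thr) n else 0L)
  cs <- cumsum(c(0, q))
  starts <- seq_len(n - w + 1L)
  wmean <- (cs[starts + w] - cs[starts]) / w
  fail <- which(wmean < thr)
  keep <- if (length(fail)) fail[1L] - 1L else n
  # drop trailing low-quality bases of the truncated prefix
  if (keep < n) {
    while (keep > 0L && q[keep] < thr) keep <- keep - 1L
  }
  keep
}

#' Sliding-window quality trimming
#'
#' Scans windows of `policy$window` bases left to right; at the first window
#' whose mean Phred quality falls below the threshold the read is truncated
#' immediately before that window's first base, and trailing bases of the
#' kept prefix with quality below the threshold are then dropped. Reads
#' shorter than the window are kept whole iff their overall mean quality
#' meets the threshold. The output read is always a prefix of the input.
#'
#' @param reads a [quality_reads] object (any length, possibly 1).
#' @param policy a [trim_policy]; `min_length` is not applied here (see
#'   [length_filter()]).
#' @return A [quality_reads] object of trimmed (possibly empty) reads.
#' @export
sliding_window_trim <- function(reads, policy = trim_policy()) {
  stopifnot(inherits(reads, "quality_reads"), inherits(policy, "trim_policy"))
  if (!length(reads)) return(reads)
  keep <- vapply(reads$quality, .sw_keep_length, 0L,
                 w = policy$window, thr = policy$mean_quality_threshold)
  quality_reads(reads$id,
                substr(reads$sequence, 1L, keep),
                mapply(function(q, k) q[seq_len(k)], reads$quality, keep,
                       SIMPLIFY = FALSE))
}

#' Minimum-length read filter
#'
#' @param reads a [quality_reads] object, typically already trimmed.
#' @param min_length minimum surviving length in bases.
#' @return A list with `reads` (the survivors) and `report`, a named integer
#'   vector with `input`, `surviving` and `discarded` counts.
#' @export
length_filter <- function(reads, min_length = 74L) {
  stopifnot(inherits(reads, "quality_reads"))
  lens <- nchar(reads$sequence)
  keep <- lens >= min_length
  list(reads = reads[keep],
       report = c(input = length(reads),
                  surviving = sum(keep),
                  discarded = sum(!keep)))
}

#' Per-round sequence frequency table
#'
#' Exact-string counting of full surviving read sequences, one column per
#' selection round. Sequences absent from a round get count 0; frequencies
#' are normalized within each round.
#'
#' @param rounds a named list, one element per round in round order; each
#'   element is a [quality_reads] object or a character vector of sequences.
#' @return An object of class `enrichment_table`: a list with integer matrix
#'   `counts` (sequence x round), numeric matrix `freqs`, `rounds` (ordered
#'   labels) and `totals` (reads per round).
#' @export
count_frequencies <- function(rounds) {
  if (is.null(names(rounds)) || any(!nzchar(names(rounds))))
    stop("rounds must be a named list (round labels)")
  seqs_by_round <- lapply(rounds, function(r) {
    if (inherits(r, "quality_reads")) r$sequence else as.character(r)
  })
  all_seqs <- sort(unique(unlist(seqs_by_round, use.names = FALSE)))
  counts <- vapply(seqs_by_round, function(s) {
    tab <- table(factor(s, levels = all_seqs))
    as.integer(tab)
  }, integer(length(all_seqs)))
  counts <- matrix(counts, nrow = length(all_seqs),
                   dimnames = list(all_seqs, names(rounds)))
  totals <- colSums(counts)
  freqs <- sweep(counts, 2L, pmax(totals, 1L), "/")
  freqs[, totals == 0L] <- 0
  structure(list(counts = counts, freqs = freqs,
                 rounds = names(rounds), totals = totals),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, n = 6L, ...) {
  cat("enrichment_table:", nrow(x$counts), "distinct sequence(s),",
      length(x$rounds), "round(s)\n")
  cat("  reads per round:", paste(x$rounds, x$totals, sep = "=",
                                  collapse = ", "), "\n")
  if (nrow(x$counts)) {
    ord <- order(x$counts[, ncol(x$counts)], decreasing = TRUE)
    show <- head(ord, n)
    print(x$counts[show, , drop = FALSE])
  }
  invisible(x)
}

#' Nominate top-k candidate aptamers from an enrichment table
#'
#' Candidates are ranked by descending count in the final round, ties broken
#' lexicographically by sequence. Each candidate carries its full per-round
#' count/frequency trajectory and round-over-round enrichment ratios
#' (frequency ratio vs the previous round; `NA` where the previous-round
#' frequency is zero).
#'
#' @param table an [count_frequencies()] result.
#' @param final_round round label to rank on; defaults to the last round.
#' @param k number of candidates (default 5).
#' @return An object of class `aptamer_candidates`: list with `sequences`
#'   (ordered character vector), `counts` and `freqs` (k x rounds matrices),
#'   `ratios` (k x rounds-1), `final_round`, and `note` (set when fewer than
#'   `k` distinct sequences exist).
#' @export
rank_candidates <- function(table, final_round = NULL, k = 5L) {
  stopifnot(inherits(table, "enrichment_table"))
  if (k < 1L) stop("k must be >= 1")
  if (is.null(final_round)) final_round <- table$rounds[length(table$rounds)]
  if (!final_round %in% table$rounds)
    stop("final_round '", final_round, "' not present in table")
  note <- NULL
  n_seq <- nrow(table$counts)
  if (k > n_seq) {
    note <- sprintf("only %d distinct sequences; returning all", n_seq)
    k <- n_seq
  }
  fc <- table$counts[, final_round]
  ord <- order(-fc, rownames(table$counts))
  top <- head(ord, k)
  seqs <- rownames(table$counts)[top]
  freqs <- table$freqs[top, , drop = FALSE]
  nr <- length(table$rounds)
  ratios <- if (nr > 1L) {
    prev <- freqs[, -nr, drop = FALSE]
    cur <- freqs[, -1L, drop = FALSE]
    r <- cur / prev
    r[prev == 0] <- NA_real_
    colnames(r) <- paste(table$rounds[-1L], table$rounds[-nr], sep = "/")
    r
  } else matrix(numeric(0), nrow = k, ncol = 0)
  structure(list(sequences = seqs,
                 counts = table$counts[top, , drop = FALSE],
                 freqs = freqs, ratios = ratios,
                 final_round = final_round, note = note),
            class = "aptamer_candidates")
}

#' @export
print.aptamer_candidates <- function(x, ...) {
  cat("aptamer_candidates: top", length(x$sequences),
      "by count in", x$final_round, "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  df <- data.frame(sequence = x$sequences,
                   final_count = x$counts[, x$final_round],
                   final_freq = signif(x$freqs[, x$final_round], 4),
                   row.names = NULL)
  print(df)
  invisible(x)
}

#' FastQC-style summary statistics for a read set
#'
#' Read counts, length distribution and GC content, reported but imposing no
#' filtering.
#'
#' @param reads a [quality_reads] object.
#' @return A list with `n_reads`, `length_range`, `mean_length`,
#'   `gc_content` (fraction) and `mean_quality`.
#' @export
qc_report <- function(reads) {
  stopifnot(inherits(reads, "quality_reads"))
  if (!length(reads))
    return(list(n_reads = 0L, length_range = c(NA_integer_, NA_integer_),
                mean_length = NA_real_, gc_content = NA_real_,
                mean_quality = NA_real_))
  lens <- nchar(reads$sequence)
  bases <- strsplit(paste(reads$sequence, collapse = ""), "")[[1]]
  list(n_reads = length(reads),
       length_range = range(lens),
       mean_length = mean(lens),
       gc_content = mean(bases %in% c("G", "C")),
       mean_quality = mean(unlist(reads$quality, use.names = FALSE)))
}

#' Run the full SELEX read-processing chain
#'
#' Convenience wrapper: trim each round with [sliding_window_trim()], apply
#' [length_filter()], count frequencies and nominate candidates.
#'
#' @param rounds named list of [quality_reads] per round, in round order.
#' @param policy a [trim_policy].
#' @param k number of candidates to nominate.
#' @return A list with `table` (enrichment table), `candidates`, and
#'   `filter_report` (per-round survival counts).
#' @export
selex_pipeline <- function(rounds, policy = trim_policy(), k = 5L) {
  processed <- lapply(rounds, function(r) {
    length_filter(sliding_window_trim(r, policy), policy$min_length)
  })
  reads <- lapply(processed, `[[`, "reads")
  report <- t(vapply(processed, `[[`, c(input = 0, surviving = 0,
                                        discarded = 0), "report"))
  tab <- count_frequencies(reads)
  list(table = tab,
       candidates = rank_candidates(tab, k = k),
       filter_report = report)
}
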