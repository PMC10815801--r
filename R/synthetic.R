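# Seed discipline: every generator consumes its own substream derived from
# one global seed by a fixed per-generator offset, so adding a generator
# never perturbs the draws of another. RNG state of the caller is restored.
.gen_offsets <- c(selex = 101L, binding = 202L, cohort = 303L,
                  proteome = 404L, trajectory = 505L)

with_substream <- function(seed, generator, code) {
  stopifnot(generator %in% names(.gen_offsets))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + .gen_offsets[[generator]]) %% .Machine$integer.max)
  force(code)
}

# ---------------------------------------------------------------- SELEX ----

#' Configuration for the SELEX round simulator
#'
#' The defaults emulate a whole-cell SELEX campaign: a 76-nt ssDNA library
#' with a 30-nt random region between constant primer-binding flanks,
#' 12 selection rounds, and planted "winner" sequences whose frequency grows
#' geometrically (per-round enrichment factor) against a diverse uniform
#' background. Per-base Phred qualities are Gaussian, truncated to
#' `[2, 41]`, with an optional linear 3' degradation.
#'
#' @param n_rounds number of selection rounds (default 12).
#' @param reads_per_round reads sequenced per round (default 5000).
#' @param library_length full read length in nt (default 76).
#' @param flank5,flank3 constant flanking sequences; their lengths plus the
#'   planted/random region must equal `library_length`.
#' @param planted_sequences list of `list(sequence=, factor=)` entries:
#'   a variable-region sequence and its per-round enrichment factor
#'   (`> 0`; enrichment requires `> 1`).
#' @param planted_initial_frac initial frequency of each planted sequence
#'   relative to the pool (default 0.005).
#' @param background_diversity number of distinct random background
#'   sequences (default 1000).
#' @param quality_mean,quality_sd per-base Phred mean and sd (defaults
#'   36, 3).
#' @param degrade_rate linear 3' quality loss in Phred units per base beyond
#'   `degrade_start` (default 0 = clean reads).
#' @param degrade_start first position affected by tail degradation.
#' @param seed integer seed.
#' @return Object of class `selex_sim_config`.
#' @export
selex_sim_config <- function(n_rounds = 12L, reads_per_round = 5000L,
                             library_length = 76L,
                             flank5 = "GGCAGGAAGACAAACACGATGGG",
                             flank3 = "GGTCTGTGGTGCTGTCGGTCGAT",
                             planted_sequences = list(),
                             planted_initial_frac = 0.005,
                             background_diversity = 1000L,
                             quality_mean = 36, quality_sd = 3,
                             degrade_rate = 0, degrade_start = 50L,
                             seed = 1L) {
  if (n_rounds < 1L) stop("n_rounds must be positive")
  if (reads_per_round < 0L) stop("reads_per_round must be nonnegative")
  if (library_length < 1L) stop("library_length must be positive")
  region_len <- library_length - nchar(flank5) - nchar(flank3)
  if (region_len < 1L) stop("flanks leave no room for a variable region")
  for (p in planted_sequences) {
    if (is.null(p$sequence) || is.null(p$factor))
      stop("each planted sequence needs 'sequence' and 'factor'")
    if (p$factor <= 0) stop("enrichment factors must be > 0")
    if (nchar(p$sequence) + nchar(flank5) + nchar(flank3) > library_length)
      stop("planted sequence longer than the library allows")
  }
  if (planted_initial_frac <= 0 || planted_initial_frac >= 1)
    stop("planted_initial_frac must be in (0, 1)")
  structure(list(n_rounds = as.integer(n_rounds),
                 reads_per_round = as.integer(reads_per_round),
                 library_length = as.integer(library_length),
                 flank5 = flank5, flank3 = flank3,
                 planted_sequences = planted_sequences,
                 planted_initial_frac = planted_initial_frac,
                 background_diversity = as.integer(background_diversity),
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 degrade_rate = degrade_rate,
                 degrade_start = as.integer(degrade_start),
                 seed = as.integer(seed)),
            class = "selex_sim_config")
}

.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
}

.sim_qualities <- function(n_reads, len, cfg) {
  pos_mean <- rep(cfg$quality_mean, len)
  if (cfg$degrade_rate > 0) {
    tail_pos <- which(seq_len(len) > cfg$degrade_start)
    pos_mean[tail_pos] <- cfg$quality_mean -
      cfg$degrade_rate * (tail_pos - cfg$degrade_start)
  }
  q <- matrix(stats::rnorm(n_reads * len,
                           mean = rep(pos_mean, each = n_reads),
                           sd = cfg$quality_sd), nrow = n_reads)
  q <- round(pmin(pmax(q, 2), 41))
  q
}

#' Simulate per-round SELEX read collections with known ground truth
#'
#' Round `r` draws `reads_per_round` reads from a pool in which planted
#' sequence `i` has unnormalized weight
#' `planted_initial_frac * factor_i^(r-1)` and the background (uniform over
#' `background_diversity` distinct random sequences) has total weight 1, so
#' planted frequencies grow geometrically in expectation. Planted variable
#' regions are embedded between the constant flanks at full library length.
#'
#' @param config a [selex_sim_config].
#' @return List with `rounds` (named list of [quality_reads], labels
#'   `R1..Rn`), `truth` (data frame: sequence, round, count, true_freq for
#'   each planted full-length sequence) and `config`. Deterministic given
#'   the config seed.
#' @export
gen_selex_rounds <- function(config) {
  stopifnot(inherits(config, "selex_sim_config"))
  cfg <- config
  with_substream(cfg$seed, "selex", {
    region_len <- cfg$library_length - nchar(cfg$flank5) - nchar(cfg$flank3)
    planted_full <- vapply(cfg$planted_sequences, function(p) {
      pad <- region_len - nchar(p$sequence)
      paste0(cfg$flank5, p$sequence,
             if (pad > 0) paste(rep("A", pad), collapse = "") else "",
             cfg$flank3)
    }, "")
    factors <- vapply(cfg$planted_sequences, `[[`, 0, "factor")
    bg <- unique(.random_dna(cfg$background_diversity, region_len))
    bg_full <- paste0(cfg$flank5, bg, cfg$flank3)
    labels <- paste0("R", seq_len(cfg$n_rounds))
    rounds <- vector("list", cfg$n_rounds)
    names(rounds) <- labels
    truth <- list()
    for (r in seq_len(cfg$n_rounds)) {
      w_planted <- cfg$planted_initial_frac * factors^(r - 1)
      w_bg <- rep(1 / max(length(bg_full), 1L), length(bg_full))
      w <- c(w_planted, w_bg)
      pool <- c(planted_full, bg_full)
      if (cfg$reads_per_round > 0L && length(pool)) {
        counts <- as.integer(stats::rmultinom(1L, cfg$reads_per_round,
                                              prob = w))
      } else counts <- integer(length(pool))
      seqs <- rep(pool, counts)
      n <- length(seqs)
      if (n > 1L) {
        ord <- sample.int(n)
        seqs <- seqs[ord]
      }
      quals <- if (n > 0L) {
        qm <- .sim_qualities(n, cfg$library_length, cfg)
        lapply(seq_len(n), function(i) as.integer(qm[i, ]))
      } else list()
      rounds[[r]] <- quality_reads(
        id = if (n) sprintf("%s_read%05d", labels[r], seq_len(n)) else
          character(),
        sequence = seqs, quality = quals)
      if (length(planted_full))
        truth[[r]] <- data.frame(
          sequence = planted_full, round = labels[r],
          count = counts[seq_along(planted_full)],
          true_freq = w_planted / sum(w), stringsAsFactors = FALSE)
    }
    list(rounds = rounds,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(sequence = character(), round = character(),
                      count = integer(), true_freq = numeric()),
         config = cfg)
  })
}

#' Write simulated SELEX rounds as per-round FASTQ files
#'
#' @param sim a [gen_selex_rounds()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_selex_fastq <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(sim$rounds), function(lab) {
    p <- file.path(dir, paste0(lab, ".fastq"))
    write_fastq(sim$rounds[[lab]], p)
    p
  }, "")
  paths
}

# -------------------------------------------------------------- binding ----

#' Configuration for the saturation-binding simulator
#'
#' Defaults mirror the assay design: doses 25-400 nM, three independent
#' replicates, and additive Gaussian response noise.
#'
#' @param true_params a [binding_params].
#' @param doses strictly increasing positive concentrations in nM.
#' @param replicates number of replicates (default 3).
#' @param noise_sd response-unit noise SD (default 0).
#' @param library_control_dose dose of the initial-library nonspecific
#'   control (default 400 nM; `NA` to omit).
#' @param seed integer seed.
#' @return Object of class `binding_sim_config`.
#' @export
binding_sim_config <- function(true_params,
                               doses = c(25, 50, 100, 200, 400),
                               replicates = 3L, noise_sd = 0,
                               library_control_dose = 400, seed = 1L) {
  stopifnot(inherits(true_params, "binding_params"))
  if (any(doses <= 0) || is.unsorted(doses, strictly = TRUE))
    stop("doses must be strictly positive and strictly increasing")
  if (replicates < 1L) stop("replicates must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(true_params = true_params, doses = as.numeric(doses),
                 replicates = as.integer(replicates),
                 noise_sd = as.numeric(noise_sd),
                 library_control_dose = library_control_dose,
                 seed = as.integer(seed)),
            class = "binding_sim_config")
}

#' Simulate a dose-response table from known binding parameters
#'
#' Response at dose X is `Bmax*X/(X+Kd) + NS*X + Background` plus
#' `Normal(0, noise_sd)` per replicate. Zero-aptamer control rows
#' (response = Background + noise) and, when configured, an initial-library
#' control (nonspecific + background response at the control dose) are
#' included per replicate.
#'
#' @param config a [binding_sim_config].
#' @return List with `data` (columns `dose_nM`, `response`, `replicate`,
#'   `control_type`) and `truth` (the true [binding_params]).
#' @export
gen_binding_curve <- function(config) {
  stopifnot(inherits(config, "binding_sim_config"))
  cfg <- config
  with_substream(cfg$seed, "binding", {
    p <- cfg$true_params
    rows <- list()
    for (rep_i in seq_len(cfg$replicates)) {
      mu <- model_response(cfg$doses, p)
      rows[[length(rows) + 1L]] <- data.frame(
        dose_nM = cfg$doses,
        response = mu + stats::rnorm(length(mu), 0, cfg$noise_sd),
        replicate = rep_i, control_type = NA_character_,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        dose_nM = 0,
        response = p[["Background"]] + stats::rnorm(1, 0, cfg$noise_sd),
        replicate = rep_i, control_type = "no_aptamer",
        stringsAsFactors = FALSE)
      if (is.finite(cfg$library_control_dose)) {
        lc <- cfg$library_control_dose
        rows[[length(rows) + 1L]] <- data.frame(
          dose_nM = lc,
          response = p[["NS"]] * lc + p[["Background"]] +
            stats::rnorm(1, 0, cfg$noise_sd),
          replicate = rep_i, control_type = "library",
          stringsAsFactors = FALSE)
      }
    }
    list(data = do.call(rbind, rows), truth = p)
  })
}

# --------------------------------------------------------------- cohort ----

#' Configuration for the recognition-cohort simulator
#'
#' Defaults emulate a breast-tissue microarray cohort: 10 adjacent
#' non-tumoral, 50 primary-tumor and 40 metastatic samples, with molecular
#' subtypes in proportions matching the primary-tumor worked example
#' (28 luminal / 7 HER2 / 10 triple-negative / 5 unknown out of 50).
#'
#' @param n_adjacent,n_primary,n_metastatic stratum sizes.
#' @param subtype_proportions named probabilities over
#'   `luminal`, `HER2`, `triple_negative`, `unknown`; must sum to 1
#'   (tolerance 1e-9).
#' @param true_positive_rate,false_positive_rate named per-aptamer
#'   probabilities that a tumor (resp. adjacent) sample stains positive;
#'   names define the aptamer panel.
#' @param intensity_distribution probabilities of ordinal levels
#'   `1`, `2`, `3` given a positive stain.
#' @param seed integer seed.
#' @return Object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_adjacent = 10L, n_primary = 50L,
                              n_metastatic = 40L,
                              subtype_proportions = c(luminal = 0.56,
                                                      HER2 = 0.14,
                                                      triple_negative = 0.20,
                                                      unknown = 0.10),
                              true_positive_rate = c(Apta1 = 0.5),
                              false_positive_rate = c(Apta1 = 0.1),
                              intensity_distribution = c(`1` = 0.3,
                                                         `2` = 0.3,
                                                         `3` = 0.4),
                              seed = 1L) {
  if (min(n_adjacent, n_primary, n_metastatic) < 0)
    stop("stratum sizes must be nonnegative")
  if (abs(sum(subtype_proportions) - 1) > 1e-9)
    stop("subtype proportions must sum to 1")
  probs <- c(true_positive_rate, false_positive_rate,
             intensity_distribution, subtype_proportions)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!identical(sort(names(true_positive_rate)),
                 sort(names(false_positive_rate))))
    stop("true/false positive rates must name the same aptamers")
  if (abs(sum(intensity_distribution) - 1) > 1e-9)
    stop("intensity distribution must sum to 1")
  structure(list(n_adjacent = as.integer(n_adjacent),
                 n_primary = as.integer(n_primary),
                 n_metastatic = as.integer(n_metastatic),
                 subtype_proportions = subtype_proportions,
                 true_positive_rate = true_positive_rate,
                 false_positive_rate = false_positive_rate,
                 intensity_distribution = intensity_distribution,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

.sample_largest_remainder <- function(n, props) {
  # deterministic stratum sizes: largest-remainder apportionment
  raw <- n * props
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Simulate a labeled recognition cohort with known contingencies
#'
#' Each sample receives a class, subtype, stage, grade and TNM string; each
#' aptamer stains tumor samples positive with its true-positive rate and
#' adjacent samples with its false-positive rate, drawing the ordinal
#' intensity from `intensity_distribution` when positive. The per-aptamer
#' TP/FP/FN/TN realized in the draw are recorded as ground truth.
#'
#' @param config a [cohort_sim_config].
#' @return List with `cohort` (data frame, see [aptamer_names()]) and
#'   `truth` (list per aptamer of named TP/FP/FN/TN counts at threshold 1).
#' @export
gen_recognition_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  cfg <- config
  with_substream(cfg$seed, "cohort", {
    classes <- c(rep("adjacent", cfg$n_adjacent),
                 rep("primary_tumor", cfg$n_primary),
                 rep("metastatic", cfg$n_metastatic))
    n <- length(classes)
    if (!n) stop("empty cohort configuration")
    subtype_n <- .sample_largest_remainder(n, cfg$subtype_proportions)
    subtypes <- sample(rep(names(subtype_n), subtype_n))
    stages <- sample(c("I", "II", "III", "unknown"), n, replace = TRUE,
                     prob = c(0.09, 0.78, 0.07, 0.06))
    grades <- sample(c("I", "II", "III", "unknown"), n, replace = TRUE,
                     prob = c(0.17, 0.60, 0.19, 0.04))
    tnm <- sample(c("T1N0M0", "T2N0M0", "T2N1M0", "T3N0M0", "T4N0M0",
                    "unknown"), n, replace = TRUE,
                  prob = c(0.08, 0.58, 0.12, 0.08, 0.08, 0.06))
    cohort <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                         class = classes, subtype = subtypes,
                         stage = stages, grade = grades, tnm = tnm,
                         stringsAsFactors = FALSE)
    truth <- list()
    tumor <- classes != "adjacent"
    levels_int <- as.integer(names(cfg$intensity_distribution))
    for (a in names(cfg$true_positive_rate)) {
      p_pos <- ifelse(tumor, cfg$true_positive_rate[[a]],
                      cfg$false_positive_rate[[a]])
      pos <- stats::rbinom(n, 1L, p_pos) == 1L
      intensity <- integer(n)
      if (any(pos))
        intensity[pos] <- sample(levels_int, sum(pos), replace = TRUE,
                                 prob = cfg$intensity_distribution)
      cohort[[a]] <- intensity
      truth[[a]] <- c(TP = sum(pos & tumor), FP = sum(pos & !tumor),
                      FN = sum(!pos & tumor), TN = sum(!pos & !tumor))
    }
    list(cohort = cohort, truth = truth)
  })
}

# ------------------------------------------------------------- proteome ----

#' Simulate proteomic tables with a planted shortlist
#'
#' Constructs protein records such that the shortlist cascade
#' ([run_cascade()]) recovers exactly the planted targets: planted proteins
#' pass all three filters by construction; membrane decoys pass fold-change
#' and membrane filters but violate the expression phenotype; non-membrane
#' decoys pass fold-change but fail the membrane filter; fold-change decoys
#' fail the first stage. All abundances are kept positive.
#'
#' @param planted_targets character vector of protein ids to plant
#'   (duplicates rejected).
#' @param n_membrane_decoys membrane-localized decoys failing the phenotype
#'   filter (default 36).
#' @param n_nonmembrane_decoys fold-change survivors failing the membrane
#'   filter (default 249).
#' @param n_foldfail_decoys proteins failing the fold-change filter
#'   (default 100).
#' @param phenotype a [binding_phenotype]; defaults to recognized
#'   `MDA-MB-468`, `BT-474`, `MCF-7` vs unrecognized `HCC-1937`.
#' @param seed integer seed.
#' @return List with `records` (merged table ready for [run_cascade()]),
#'   the three constituent tables (`abundance`, `membrane`, `status`) and
#'   `truth` (the planted ids).
#' @export
gen_proteomic_tables <- function(planted_targets,
                                 n_membrane_decoys = 36L,
                                 n_nonmembrane_decoys = 249L,
                                 n_foldfail_decoys = 100L,
                                 phenotype = binding_phenotype(
                                   c("MDA-MB-468", "BT-474", "MCF-7"),
                                   "HCC-1937"),
                                 seed = 1L) {
  planted_targets <- as.character(planted_targets)
  if (anyDuplicated(planted_targets)) stop("duplicate protein ids")
  with_substream(seed, "proteome", {
    ids <- c(planted_targets,
             if (n_membrane_decoys) sprintf("DECOYM%03d",
                                            seq_len(n_membrane_decoys)),
             if (n_nonmembrane_decoys) sprintf("DECOYN%03d",
                                               seq_len(n_nonmembrane_decoys)),
             if (n_foldfail_decoys) sprintf("DECOYF%03d",
                                            seq_len(n_foldfail_decoys)))
    if (anyDuplicated(ids)) stop("duplicate protein ids")
    n <- length(ids)
    if (!n)
      return(list(records = data.frame(protein_id = character(),
                                       abundance_target = numeric(),
                                       abundance_control = numeric()),
                  abundance = data.frame(), membrane = data.frame(),
                  status = data.frame(), truth = character()))
    kind <- c(rep("planted", length(planted_targets)),
              rep("mem_decoy", n_membrane_decoys),
              rep("nonmem_decoy", n_nonmembrane_decoys),
              rep("foldfail_decoy", n_foldfail_decoys))
    control <- stats::runif(n, 5, 50)
    fold <- ifelse(kind == "foldfail_decoy",
                   stats::runif(n, 0.3, 1.8), stats::runif(n, 2.5, 8))
    target <- control * fold
    membrane_evidence <- kind %in% c("planted", "mem_decoy")
    localization <- ifelse(kind %in% c("planted", "mem_decoy"),
                           "plasma_membrane", "other")
    # non-membrane decoys may still carry one (but not both) lines of
    # membrane evidence
    if (any(kind == "nonmem_decoy")) {
      i <- which(kind == "nonmem_decoy")
      half <- i[stats::runif(length(i)) < 0.5]
      membrane_evidence[half] <- TRUE          # localization stays "other"
    }
    lines <- c(phenotype$recognized, phenotype$unrecognized)
    status <- matrix("unknown", n, length(lines),
                     dimnames = list(NULL, lines))
    status[kind == "planted", phenotype$recognized] <- "over"
    status[kind == "planted", phenotype$unrecognized] <- "under"
    other_rows <- which(kind != "planted")
    for (i in other_rows) {
      status[i, ] <- sample(c("over", "under", "unknown"), length(lines),
                            replace = TRUE)
    }
    # force every decoy to violate the phenotype in at least one line
    for (i in which(kind == "mem_decoy")) {
      ok <- all(status[i, phenotype$recognized] == "over") &&
        all(status[i, phenotype$unrecognized] == "under")
      if (ok) {
        l <- sample(lines, 1L)
        status[i, l] <- if (l %in% phenotype$recognized)
          sample(c("under", "unknown"), 1L) else
            sample(c("over", "unknown"), 1L)
      }
    }
    abundance <- data.frame(protein_id = ids, abundance_target = target,
                            abundance_control = control,
                            stringsAsFactors = FALSE)
    membrane <- data.frame(protein_id = ids,
                           membrane_evidence = membrane_evidence,
                           predicted_localization = localization,
                           stringsAsFactors = FALSE)
    status_df <- data.frame(protein_id = ids, status,
                            check.names = FALSE, stringsAsFactors = FALSE)
    records <- merge(merge(abundance, membrane, by = "protein_id"),
                     status_df, by = "protein_id", sort = FALSE)
    list(records = records, abundance = abundance, membrane = membrane,
         status = status_df, truth = planted_targets)
  })
}

# ----------------------------------------------------------- trajectory ----

#' Configuration for the trajectory simulator
#'
#' Frames are jittered copies of planted conformational centers (random
#' Gaussian point clouds regenerated until pairwise superposed RMSD exceeds
#' twice the clustering cutoff), split round-robin across centers within
#' each replicate. Planted hydrogen bonds occupy dedicated atom triples
#' whose donor-acceptor geometry is satisfied in exactly a designated
#' fraction of frames.
#'
#' @param n_frames frames per replicate (default 50).
#' @param n_replicates number of replicates (default 3).
#' @param n_atoms atoms per frame (default 40; must leave room for the
#'   hbond triples).
#' @param n_clusters number of planted centers (default 2), ignored when
#'   `planted_cluster_centers` is supplied.
#' @param planted_cluster_centers optional list of `n_atoms x 3` matrices.
#' @param jitter_sd per-coordinate Gaussian jitter in Angstroms
#'   (default 0.2).
#' @param cluster_cutoff the clustering cutoff the centers must respect
#'   (centers pairwise farther apart than twice this; default 2.5).
#' @param planted_hbonds list of `list(occupancy=)` entries, occupancy in
#'   `[0, 1]`; each consumes three dedicated atoms at the end of the atom
#'   list.
#' @param seed integer seed.
#' @return Object of class `trajectory_sim_config`.
#' @export
trajectory_sim_config <- function(n_frames = 50L, n_replicates = 3L,
                                  n_atoms = 40L, n_clusters = 2L,
                                  planted_cluster_centers = NULL,
                                  jitter_sd = 0.2, cluster_cutoff = 2.5,
                                  planted_hbonds = list(), seed = 1L) {
  if (n_frames < 1L || n_replicates < 1L) stop("need frames and replicates")
  for (h in planted_hbonds) {
    if (is.null(h$occupancy) || h$occupancy < 0 || h$occupancy > 1)
      stop("hbond occupancies must lie in [0, 1]")
  }
  if (n_atoms < 3L + 3L * length(planted_hbonds))
    stop("n_atoms too small for the planted hbond triples")
  if (jitter_sd < 0) stop("jitter_sd must be nonnegative")
  structure(list(n_frames = as.integer(n_frames),
                 n_replicates = as.integer(n_replicates),
                 n_atoms = as.integer(n_atoms),
                 n_clusters = as.integer(n_clusters),
                 planted_cluster_centers = planted_cluster_centers,
                 jitter_sd = jitter_sd, cluster_cutoff = cluster_cutoff,
                 planted_hbonds = planted_hbonds,
                 seed = as.integer(seed)),
            class = "trajectory_sim_config")
}

#' Simulate a trajectory with planted clusters and hydrogen bonds
#'
#' @param config a [trajectory_sim_config].
#' @return List with `traj` (a [trajectory]), and `truth`: `assignment`
#'   (planted cluster per frame), `centers`, `hbond_specs` (ready-made
#'   [hbond_spec]s addressing the dedicated atoms), `hbond_frames` (list of
#'   frame indices in which each planted bond is satisfied),
#'   `overlap_warning` (TRUE when jitter/center geometry risks cluster
#'   overlap at the stated cutoff).
#' @export
gen_trajectory <- function(config) {
  stopifnot(inherits(config, "trajectory_sim_config"))
  cfg <- config
  with_substream(cfg$seed, "trajectory", {
    n_hb <- length(cfg$planted_hbonds)
    n_struct <- cfg$n_atoms - 3L * n_hb    # atoms carrying the fold signal
    centers <- cfg$planted_cluster_centers
    k <- if (is.null(centers)) cfg$n_clusters else length(centers)
    if (is.null(centers)) {
      make_center <- function() matrix(stats::rnorm(n_struct * 3, 0, 6),
                                       ncol = 3)
      for (attempt in 1:50) {
        centers <- replicate(k, make_center(), simplify = FALSE)
        ok <- TRUE
        if (k > 1L) for (i in 1:(k - 1)) for (j in (i + 1):k) {
          if (.rmsd_fit(centers[[i]], centers[[j]]) <=
              2 * cfg$cluster_cutoff) ok <- FALSE
        }
        if (ok) break
      }
    } else {
      centers <- lapply(centers, function(cm) as.matrix(cm)[seq_len(n_struct), ,
                                                            drop = FALSE])
    }
    min_sep <- Inf
    if (k > 1L) for (i in 1:(k - 1)) for (j in (i + 1):k)
      min_sep <- min(min_sep, .rmsd_fit(centers[[i]], centers[[j]]))
    # expected jitter-induced RMSD between two frames of one cluster is
    # ~ jitter_sd * sqrt(2) per coordinate axis; flag overlap risk
    overlap_warning <- is.finite(min_sep) &&
      (min_sep <= 2 * cfg$cluster_cutoff ||
         cfg$jitter_sd * sqrt(6) > cfg$cluster_cutoff)
    nf_total <- cfg$n_frames * cfg$n_replicates
    assignment <- ((seq_len(nf_total) - 1L) %% k) + 1L
    coords <- array(NA_real_, dim = c(nf_total, cfg$n_atoms, 3L))
    for (i in seq_len(nf_total)) {
      base <- centers[[assignment[i]]]
      coords[i, seq_len(n_struct), ] <- base +
        matrix(stats::rnorm(n_struct * 3, 0, cfg$jitter_sd), ncol = 3)
    }
    # dedicated hbond triples: donor fixed, hydrogen 1 A away, acceptor at
    # 2.9 A (satisfied, angle 180 deg) or 6 A (unsatisfied)
    hbond_specs <- list(); hbond_frames <- list()
    for (h in seq_len(n_hb)) {
      a0 <- n_struct + 3L * (h - 1L)
      di <- a0 + 1L; hi <- a0 + 2L; ai <- a0 + 3L
      p0 <- c(30 + 10 * h, 0, 0)   # well away from the structural cloud
      occ <- cfg$planted_hbonds[[h]]$occupancy
      m <- round(occ * nf_total)
      sat_frames <- if (m > 0) sort(sample.int(nf_total, m)) else integer(0)
      for (i in seq_len(nf_total)) {
        d <- if (i %in% sat_frames) 2.9 else 6.0
        coords[i, di, ] <- p0
        coords[i, hi, ] <- p0 + c(1, 0, 0)
        coords[i, ai, ] <- p0 + c(d, 0, 0)
      }
      hbond_specs[[h]] <- hbond_spec(donor = di, hydrogen = hi,
                                     acceptor = ai)
      hbond_frames[[h]] <- sat_frames
    }
    traj <- trajectory(coords,
                       replicate = rep(seq_len(cfg$n_replicates),
                                       each = cfg$n_frames))
    list(traj = traj,
         truth = list(assignment = assignment, centers = centers,
                      hbond_specs = hbond_specs,
                      hbond_frames = hbond_frames,
                      overlap_warning = overlap_warning))
  })
}
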