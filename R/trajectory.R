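#' Trajectory container
#'
#' An ordered set of coordinate frames over a fixed atom list, with
#' replicate bookkeeping. Coordinates are in Angstroms.
#'
#' @param coords numeric array `frames x atoms x 3`, or a list of
#'   `atoms x 3` matrices (one per frame).
#' @param atoms data frame with columns `name` and `resid` (atom labels);
#'   defaults to `A1..An` in residue 1.
#' @param replicate integer vector assigning each frame to a replicate
#'   (non-decreasing); default all frames in replicate 1.
#' @param dt_ns time between frames in ns (metadata; default `NA`).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(coords, atoms = NULL, replicate = NULL, dt_ns = NA) {
  if (is.list(coords) && !is.array(coords)) {
    nat <- unique(vapply(coords, nrow, 0L))
    if (length(nat) != 1L) stop("all frames must have the same atom count")
    arr <- array(NA_real_, dim = c(length(coords), nat, 3L))
    for (i in seq_along(coords)) arr[i, , ] <- as.matrix(coords[[i]])
    coords <- arr
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  if (is.null(atoms))
    atoms <- data.frame(name = paste0("A", seq_len(na)), resid = 1L,
                        stringsAsFactors = FALSE)
  stopifnot(nrow(atoms) == na, all(c("name", "resid") %in% names(atoms)))
  if (is.null(replicate)) replicate <- rep(1L, nf)
  replicate <- as.integer(replicate)
  if (length(replicate) != nf) stop("one replicate id per frame required")
  if (is.unsorted(replicate)) stop("replicate ids must be non-decreasing")
  structure(list(coords = coords, atoms = atoms, replicate = replicate,
                 dt_ns = dt_ns),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", n_frames(x), "frame(s),", n_atoms(x), "atom(s),",
      length(unique(x$replicate)), "replicate(s)\n")
  invisible(x)
}

#' @rdname trajectory
#' @param traj a trajectory.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

# frame i as an atoms x 3 matrix
frame_coords <- function(traj, i) traj$coords[i, , , drop = TRUE]

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares superposition of coordinate set `Q` onto `P` using the
#' SVD-based Kabsch algorithm; reflections are excluded (proper rotation
#' only). RMSD is the root mean squared deviation over atoms after the fit.
#'
#' @param P,Q numeric `n x 3` matrices with the same `n >= 3`, in matched
#'   atom order. Near-degenerate (collinear) sets raise an error.
#' @return List with `rotation` (3x3), `translation` (length 3, applied to
#'   `Q` after rotation), `rmsd` (Angstroms) and `Qfit` (the superposed
#'   copy of `Q`).
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("P and Q must have equal dimensions")
  if (nrow(P) < 3L) stop("need at least 3 atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  H <- crossprod(Q0, P0)
  sv <- svd(H)
  # guard degenerate (collinear) configurations: rotation not unique
  if (sv$d[2] <= 1e-10 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) coordinates: superposition not unique")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Qfit <- Q0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((P0 - Qfit)^2)))
  Qfit <- sweep(Qfit, 2L, cp, "+")
  list(rotation = R, translation = as.numeric(cp - R %*% cq),
       rmsd = rmsd, Qfit = Qfit)
}

# rmsd after superposition; identical frames (common in constant or
# duplicated-frame trajectories) short-circuit to 0 since any rotation is
# optimal there and kabsch_superpose rejects rank-deficient input
.rmsd_fit <- function(P, Q) {
  if (max(abs(P - Q)) < 1e-12) return(0)
  kabsch_superpose(P, Q)$rmsd
}

#' Per-frame RMSD series against a reference frame
#'
#' Superposes every frame onto the reference frame and reports the RMSD,
#' with replicate labels honoring the trajectory's replicate boundaries.
#'
#' @param traj a [trajectory].
#' @param reference reference frame index (default 1).
#' @return Data frame with `frame`, `replicate`, `time_ns` (NA when frame
#'   spacing is unknown) and `rmsd_A`.
#' @export
rmsd_series <- function(traj, reference = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (reference < 1L || reference > nf) stop("reference frame out of range")
  ref <- frame_coords(traj, reference)
  r <- vapply(seq_len(nf), function(i)
    if (i == reference) 0 else .rmsd_fit(ref, frame_coords(traj, i)), 0)
  data.frame(frame = seq_len(nf), replicate = traj$replicate,
             time_ns = if (is.na(traj$dt_ns)) NA_real_ else
               (seq_len(nf) - 1L) * traj$dt_ns,
             rmsd_A = r)
}

#' Pairwise superposed-RMSD matrix
#'
#' RMSD between every pair of frames, each pair superposed independently
#' (no shared reference), as required by GROMOS clustering.
#'
#' @param traj a [trajectory].
#' @return Symmetric `frames x frames` matrix of RMSD values (Angstroms).
#' @export
pairwise_rmsd <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  m <- matrix(0, nf, nf)
  if (nf < 2L) return(m)
  frames <- lapply(seq_len(nf), function(i) frame_coords(traj, i))
  for (i in seq_len(nf - 1L)) {
    for (j in seq.int(i + 1L, nf)) {
      m[i, j] <- m[j, i] <- .rmsd_fit(frames[[i]], frames[[j]])
    }
  }
  m
}

#' GROMOS conformational clustering
#'
#' Greedy neighbor-count clustering on the pairwise superposed-RMSD matrix:
#' repeatedly, the unassigned frame with the most unassigned neighbors
#' within `cutoff` (ties broken by lowest frame index) becomes the next
#' cluster's centroid, and it plus its neighbors are removed; iteration ends
#' when every frame is assigned. Clusters are relabeled in decreasing size
#' (ties keep extraction order), so cluster 1 is the largest and its
#' centroid the representative structure reported first.
#'
#' @param traj a [trajectory], or a precomputed pairwise RMSD matrix.
#' @param cutoff RMSD neighbor cutoff in Angstroms (default 2.5).
#' @return Object of class `cluster_result`: list with `assignment`
#'   (integer per frame), `centroids` (representative frame index per
#'   cluster), `sizes` (descending) and `cutoff`.
#' @export
gromos_cluster <- function(traj, cutoff = 2.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  m <- if (inherits(traj, "trajectory")) {
    if (!n_frames(traj)) stop("empty trajectory")
    pairwise_rmsd(traj)
  } else as.matrix(traj)
  nf <- nrow(m)
  if (!nf) stop("empty trajectory")
  neighbor <- m <= cutoff
  diag(neighbor) <- FALSE
  unassigned <- rep(TRUE, nf)
  assignment <- integer(nf)
  centroids <- integer(0)
  k <- 0L
  while (any(unassigned)) {
    idx <- which(unassigned)
    counts <- vapply(idx, function(i) sum(neighbor[i, idx]), 0L)
    center <- idx[which.max(counts)]          # which.max: lowest index wins ties
    members <- c(center, idx[neighbor[center, idx]])
    k <- k + 1L
    assignment[members] <- k
    centroids[k] <- center
    unassigned[members] <- FALSE
  }
  sizes <- tabulate(assignment, k)
  ord <- order(-sizes, seq_len(k))     # descending size, extraction order ties
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  structure(list(assignment = relabel[assignment],
                 centroids = centroids[ord],
                 sizes = sizes[ord], cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("GROMOS clustering (cutoff", x$cutoff, "A):",
      length(x$sizes), "cluster(s)\n")
  df <- data.frame(cluster = seq_along(x$sizes), size = x$sizes,
                   representative_frame = x$centroids)
  print(utils::head(df, 10))
  if (length(x$sizes) > 10) cat("  ...\n")
  invisible(x)
}

#' Hydrogen-bond specification
#'
#' A donor-hydrogen-acceptor triple with geometric cutoffs. A frame
#' satisfies the bond iff the donor-acceptor distance is at most
#' `distance_cutoff` and the donor-hydrogen-acceptor angle (at the
#' hydrogen) is at least `angle_cutoff`.
#'
#' @param donor,hydrogen,acceptor atom labels (matched against
#'   `name` or `name_resid` of the trajectory's atom table) or 1-based atom
#'   indices.
#' @param distance_cutoff donor-acceptor distance cutoff in Angstroms
#'   (default 3.5).
#' @param angle_cutoff D-H-A angle cutoff in degrees, in `(0, 180]`
#'   (default 135).
#' @return Object of class `hbond_spec`.
#' @export
hbond_spec <- function(donor, hydrogen, acceptor, distance_cutoff = 3.5,
                       angle_cutoff = 135) {
  if (distance_cutoff <= 0) stop("distance_cutoff must be positive")
  if (angle_cutoff <= 0 || angle_cutoff > 180)
    stop("angle_cutoff must be in (0, 180]")
  structure(list(donor = donor, hydrogen = hydrogen, acceptor = acceptor,
                 distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff),
            class = "hbond_spec")
}

.resolve_atom <- function(label, atoms) {
  if (is.numeric(label)) {
    i <- as.integer(label)
    if (i < 1L || i > nrow(atoms)) stop("atom index out of range: ", label)
    return(i)
  }
  lab <- as.character(label)
  full <- paste(atoms$name, atoms$resid, sep = "_")
  hit <- which(full == lab)
  if (!length(hit)) hit <- which(atoms$name == lab)
  if (!length(hit)) stop("unknown atom label: ", lab)
  if (length(hit) > 1L) stop("ambiguous atom label: ", lab)
  hit
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Occupancy is the percentage of frames (pooled across replicates) in which
#' a bond's geometric criterion holds; a per-replicate breakdown is also
#' returned. The report retains only bonds with occupancy above
#' `min_occupancy` percent, sorted descending.
#'
#' @param traj a [trajectory].
#' @param specs a single [hbond_spec] or a list of them.
#' @param min_occupancy report threshold in percent (default 20).
#' @return List with `table` (all bonds: atom labels, cutoffs used,
#'   `occupancy_pct`, satisfied-frame count), `report` (bonds with occupancy
#'   above the threshold, descending), `per_replicate` (occupancy matrix
#'   bond x replicate) and `frames` (list of satisfied frame indices per
#'   bond).
#' @export
hbond_occupancy <- function(traj, specs, min_occupancy = 20) {
  stopifnot(inherits(traj, "trajectory"))
  if (inherits(specs, "hbond_spec")) specs <- list(specs)
  nf <- n_frames(traj)
  reps <- traj$replicate
  rep_levels <- sort(unique(reps))
  rows <- list(); per_rep <- list(); frames <- list()
  for (s in specs) {
    di <- .resolve_atom(s$donor, traj$atoms)
    hi <- .resolve_atom(s$hydrogen, traj$atoms)
    ai <- .resolve_atom(s$acceptor, traj$atoms)
    D <- traj$coords[, di, , drop = TRUE]
    H <- traj$coords[, hi, , drop = TRUE]
    A <- traj$coords[, ai, , drop = TRUE]
    if (nf == 1L) { D <- rbind(D); H <- rbind(H); A <- rbind(A) }
    dist_da <- sqrt(rowSums((D - A)^2))
    v1 <- D - H; v2 <- A - H
    cosang <- rowSums(v1 * v2) /
      pmax(sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)), .Machine$double.eps)
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    sat <- dist_da <= s$distance_cutoff & ang >= s$angle_cutoff
    lab <- function(x, i) if (is.numeric(x))
      paste(traj$atoms$name[i], traj$atoms$resid[i], sep = "_") else
        as.character(x)
    rows[[length(rows) + 1L]] <- data.frame(
      donor = lab(s$donor, di), hydrogen = lab(s$hydrogen, hi),
      acceptor = lab(s$acceptor, ai),
      distance_cutoff = s$distance_cutoff, angle_cutoff = s$angle_cutoff,
      n_satisfied = sum(sat), n_frames = nf,
      occupancy_pct = 100 * sum(sat) / nf, stringsAsFactors = FALSE)
    per_rep[[length(per_rep) + 1L]] <- vapply(rep_levels, function(r)
      100 * mean(sat[reps == r]), 0)
    frames[[length(frames) + 1L]] <- which(sat)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  pr <- do.call(rbind, per_rep)
  colnames(pr) <- paste0("replicate_", rep_levels)
  report <- tab[tab$occupancy_pct > min_occupancy, , drop = FALSE]
  report <- report[order(-report$occupancy_pct), , drop = FALSE]
  rownames(report) <- NULL
  list(table = tab, report = report, per_replicate = pr, frames = frames)
}

#' Read a multi-model PDB file as a trajectory
#'
#' MODEL/ENDMDL records become frames; parsing is delegated to \pkg{bio3d}.
#'
#' @param path PDB file path.
#' @param replicate optional per-frame replicate assignment.
#' @param dt_ns frame spacing metadata.
#' @return A [trajectory].
#' @export
read_trajectory_pdb <- function(path, replicate = NULL, dt_ns = NA) {
  p <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- p$xyz
  nf <- nrow(xyz); na <- ncol(xyz) / 3L
  coords <- array(NA_real_, dim = c(nf, na, 3L))
  for (i in seq_len(nf))
    coords[i, , ] <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
  atoms <- data.frame(name = trimws(p$atom$elety),
                      resid = p$atom$resno, stringsAsFactors = FALSE)
  trajectory(coords, atoms = atoms, replicate = replicate, dt_ns = dt_ns)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [trajectory].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj); na <- n_atoms(traj)
  xyz <- matrix(NA_real_, nf, na * 3L)
  for (i in seq_len(nf))
    xyz[i, ] <- as.numeric(t(traj$coords[i, , ]))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = traj$atoms$resid,
                   resid = rep("UNK", na),
                   elety = traj$atoms$name)
  invisible(path)
}

#' Read/write a plain whitespace-delimited frames table
#'
#' Columns: `frame`, `atom`, `x`, `y`, `z`; atom order must be identical in
#' every frame.
#'
#' @param path file path.
#' @param replicate optional per-frame replicate assignment.
#' @param dt_ns frame spacing metadata.
#' @return A [trajectory] (`read_frames_table`) or `path` invisibly.
#' @export
read_frames_table <- function(path, replicate = NULL, dt_ns = NA) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("frame", "atom", "x", "y", "z") %in% names(d)))
  frames <- sort(unique(d$frame))
  atoms0 <- d$atom[d$frame == frames[1]]
  coords <- array(NA_real_, dim = c(length(frames), length(atoms0), 3L))
  for (i in seq_along(frames)) {
    sub <- d[d$frame == frames[i], , drop = FALSE]
    if (!identical(sub$atom, atoms0))
      stop("atom order differs at frame ", frames[i])
    coords[i, , ] <- as.matrix(sub[, c("x", "y", "z")])
  }
  trajectory(coords,
             atoms = data.frame(name = atoms0, resid = 1L,
                                stringsAsFactors = FALSE),
             replicate = replicate, dt_ns = dt_ns)
}

#' @rdname read_frames_table
#' @param traj a [trajectory] to write.
#' @export
write_frames_table <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj); na <- n_atoms(traj)
  d <- data.frame(frame = rep(seq_len(nf), each = na),
                  atom = rep(traj$atoms$name, nf),
                  x = as.numeric(t(traj$coords[, , 1])),
                  y = as.numeric(t(traj$coords[, , 2])),
                  z = as.numeric(t(traj$coords[, , 3])))
  utils::write.table(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
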