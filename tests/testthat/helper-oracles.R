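# Independent oracles used across test files. These deliberately do not
# share code paths with the package implementation.

# one read with uniform quality
make_read <- function(seq, qual) {
  quality_reads("r", seq, list(rep(as.integer(qual), nchar(seq))))
}

# brute-force top-k: full sort of (count desc, sequence asc)
oracle_topk <- function(counts_named, k) {
  df <- data.frame(seq = names(counts_named), n = as.integer(counts_named),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n, df$seq), ]
  head(df$seq, k)
}

# brute-force GROMOS clustering from a precomputed distance matrix:
# written as an explicit set-manipulation loop
oracle_gromos <- function(m, cutoff) {
  nf <- nrow(m)
  pool <- seq_len(nf)
  assign <- integer(nf)
  cent <- integer(0)
  cl <- 0L
  while (length(pool)) {
    nb <- lapply(pool, function(i)
      setdiff(pool[m[i, pool] <= cutoff], i))
    sizes <- lengths(nb)
    pick <- which(sizes == max(sizes))[1L]  # lowest index on ties
    members <- union(pool[pick], nb[[pick]])
    cl <- cl + 1L
    assign[members] <- cl
    cent <- c(cent, pool[pick])
    pool <- setdiff(pool, members)
  }
  sizes <- tabulate(assign, cl)
  ord <- order(-sizes, seq_len(cl))
  relab <- integer(cl); relab[ord] <- seq_len(cl)
  list(assignment = relab[assign], centroids = cent[ord],
       sizes = sizes[ord])
}

# pairwise superposed-RMSD matrix through bio3d (independent of the
# package's Kabsch code)
oracle_rmsd_matrix <- function(traj) {
  nf <- dim(traj$coords)[1]
  xyz <- t(vapply(seq_len(nf), function(i)
    as.numeric(t(traj$coords[i, , ])), numeric(dim(traj$coords)[2] * 3)))
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) for (j in (i + 1):nf)
    m[i, j] <- m[j, i] <- bio3d::rmsd(xyz[i, ], xyz[j, ], fit = TRUE)
  m
}

# brute-force rigid-superposition RMSD by scanning Euler angles
oracle_grid_rmsd <- function(P, Q, n_angle = 40) {
  rot <- function(a, b, g) {
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                 byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Rz %*% Ry %*% Rz2
  }
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  angles <- seq(0, 2 * pi, length.out = n_angle)
  betas <- seq(0, pi, length.out = n_angle %/% 2)
  best <- Inf
  for (a in angles) for (b in betas) for (g in angles) {
    R <- rot(a, b, g)
    r <- sqrt(mean(rowSums((P0 - Q0 %*% t(R))^2)))
    if (r < best) best <- r
  }
  best
}

# cohort with known per-sample intensities for panel tests
tiny_cohort <- function(intensities, classes) {
  n <- length(classes)
  co <- data.frame(sample_id = paste0("s", seq_len(n)), class = classes,
                   subtype = "unknown", stage = "unknown",
                   grade = "unknown", tnm = "unknown",
                   stringsAsFactors = FALSE)
  for (a in names(intensities)) co[[a]] <- intensities[[a]]
  co
}

# random recognition cohort for property tests
random_cohort <- function(n_samples, n_aptamers, seed) {
  set.seed(seed)
  classes <- sample(c("adjacent", "primary_tumor", "metastatic"),
                    n_samples, replace = TRUE,
                    prob = c(0.3, 0.4, 0.3))
  ints <- stats::setNames(
    lapply(seq_len(n_aptamers), function(i)
      sample(0:3, n_samples, replace = TRUE)),
    paste0("A", seq_len(n_aptamers)))
  tiny_cohort(ints, classes)
}

default_phenotype <- function() {
  binding_phenotype(c("MDA-MB-468", "BT-474", "MCF-7"), "HCC-1937")
}

planted_ids <- c("CSKP", "TMEM205", "CD151", "TM9S3")
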