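# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package code.

# Quaternion (Horn) superposition: optimal RMSD from the largest eigenvalue
# of the 4x4 key matrix built from the cross-covariance. Independent of the
# SVD-based Kabsch route.
quaternion_rmsd <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  S <- crossprod(P0, Q0)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P0^2) + sum(Q0^2) - 2 * lambda) / nrow(P)
  sqrt(max(0, msd))
}

# Brute-force Hodgkin index: explicit loop over mask points.
hodgkin_brute <- function(a, b, mask) {
  num <- 0; da <- 0; db <- 0
  for (k in which(mask$included)) {
    num <- num + a$values[k] * b$values[k]
    da <- da + a$values[k]^2
    db <- db + b$values[k]^2
  }
  2 * num / (da + db)
}

# Exhaustive complete-linkage agglomeration: at every step, inter-cluster
# distances are recomputed from scratch as the max over all cross pairs of
# leaf distances (no Lance-Williams update). Valid for distinct distances.
complete_linkage_brute <- function(dist) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  labels <- rownames(dist)
  if (is.null(labels)) labels <- paste0("L", seq_len(n))
  clusters <- as.list(seq_len(n))
  merges <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL; best_d <- Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      d <- max(dist[clusters[[i]], clusters[[j]]])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    merges[[length(merges) + 1]] <-
      list(set = sort(labels[merged]), height = best_d)
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# Random symmetric distance matrix with distinct off-diagonal entries.
random_distinct_dist <- function(n, seed) {
  set.seed(seed)
  vals <- sample(seq_len(n * (n - 1) / 2)) + stats::runif(n * (n - 1) / 2)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  rownames(d) <- colnames(d) <- paste0("L", seq_len(n))
  d
}

# Tiny ad-hoc grid/mask builders for similarity tests.
toy_spec <- function(dims = c(4, 4, 4), spacing = 1) {
  grid_spec(origin = c(0, 0, 0), spacing = spacing, dims = dims)
}

toy_grid <- function(values, spec, label = "g") {
  structure(list(spec = spec, values = values, label = label),
            class = "mep_grid")
}

toy_mask <- function(included, spec) {
  structure(list(spec = spec, included = included, count = sum(included)),
            class = "mep_mask")
}

# Three-complex toy set: A and A2 share a charge motif, C carries its
# negation; used for sign-structure checks.
toy_triplet <- function(jitter = 0, seed = 5) {
  m <- motif_spec(c(1, 0, -1, 0, 1, 0, -1, 0, 1), jitter = jitter)
  mneg <- motif_spec(-m$charges, jitter = jitter)
  lv <- mepsim:::.charge_levels(c(m$charges, mneg$charges))
  list(A  = generate_toy_complex(m, seed = seed, label = "A", levels = lv),
       A2 = generate_toy_complex(m, seed = seed + 1, label = "A2",
                                 levels = lv),
       C  = generate_toy_complex(mneg, seed = seed + 2, label = "C",
                                 levels = lv))
}

# Small shared grid + masks + potential grids for a list of toy structures.
toy_pipeline_pieces <- function(structs, spacing = 2, radius = 18,
                                length = 14) {
  ref <- reference_structure()
  cyl <- place_cylinder(ref, radius = radius, length = length)
  spec <- build_grid_spec(cyl, spacing = spacing, padding = 4)
  params <- elec_params()
  grids <- lapply(structs, compute_potential_grid, spec = spec,
                  params = params)
  skins <- lapply(structs, compute_skin_mask, spec = spec)
  list(spec = spec, cyl = cylinder_mask(spec, cyl), grids = grids,
       skins = skins)
}

# A valid fixed-column PDB snippet with three atoms in two chains.
sample_pdb_lines <- function() {
  c("REMARK  synthetic test snippet",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.0           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 10.0           C",
    "HETATM    3  O   HOH B   2       1.000   2.000   3.000  1.00  0.0           O",
    "TER",
    "END")
}
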