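# Molecular electrostatic potential on a shared lattice.
#
# Potentials are evaluated with a Debye-Hueckel screened Coulomb model on a
# uniform dielectric: phi(r) = (C/eps) * sum_i q_i * exp(-kappa*d_i)/d_i,
# d_i = max(|r - r_i|, floor). This keeps the comparison statistic (the
# Hodgkin index over a skin well away from the atoms) driven by charge
# geometry while staying analytic; a Poisson-Boltzmann solver can be slotted
# in behind the same grid interface.

# Coulomb constant in kcal mol^-1 Angstrom e^-2.
COULOMB_KCAL <- 332.0637

#' Electrostatics parameters
#'
#' @param dielectric Relative dielectric constant (default 78.4, water).
#' @param ionic_strength Ionic strength in mol/L (default 0.05); the inverse
#'   Debye length is derived from it, `kappa = 0` when it is 0.
#' @param temperature Kelvin (default 298.15).
#' @param floor_dist Singularity floor in Angstrom (default 0.5): distances
#'   are clamped below at this value so lattice points near atom centres
#'   stay finite (skin masking removes those points anyway).
#' @return List of class `mep_elec_params`, including the derived `kappa`
#'   (1/Angstrom).
#' @export
elec_params <- function(dielectric = 78.4, ionic_strength = 0.05,
                        temperature = 298.15, floor_dist = 0.5) {
  stopifnot(dielectric > 0, ionic_strength >= 0, temperature > 0,
            floor_dist > 0)
  kappa <- if (ionic_strength == 0) 0 else
    50.29158649 * sqrt(ionic_strength / (dielectric * temperature))
  structure(list(dielectric = dielectric, ionic_strength = ionic_strength,
                 temperature = temperature, coulomb = COULOMB_KCAL,
                 floor_dist = floor_dist, kappa = kappa),
            class = "mep_elec_params")
}

#' Grid specification
#'
#' A regular axis-aligned lattice shared by every complex in a run.
#'
#' @param origin Length-3 numeric, Angstrom (position of the first point).
#' @param spacing Uniform spacing in Angstrom (> 0).
#' @param dims Integer vector (nx, ny, nz).
#' @export
grid_spec <- function(origin, spacing, dims) {
  stopifnot(length(origin) == 3, length(dims) == 3)
  if (spacing <= 0) abort("grid spacing must be > 0")
  dims <- as.integer(dims)
  if (any(dims < 1)) abort("grid dims must be positive")
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dims, n = prod(dims)),
            class = "mep_grid_spec")
}

#' @export
print.mep_grid_spec <- function(x, ...) {
  cat(sprintf("<mep_grid_spec> %d x %d x %d @ %g A, origin (%g, %g, %g)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

same_spec <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) && a$spacing == b$spacing &&
    all(a$dims == b$dims)
}

#' Lattice point coordinates
#'
#' @param spec A `mep_grid_spec`.
#' @return n x 3 matrix of point coordinates, x varying fastest.
#' @export
grid_points <- function(spec) {
  ax <- lapply(1:3, function(k) {
    spec$origin[k] + spec$spacing * (seq_len(spec$dims[k]) - 1)
  })
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

#' Build the shared grid around the focus cylinder
#'
#' Axis-aligned lattice that fully contains the cylinder dilated by
#' `padding`.
#'
#' @param cylinder A [cylinder_region()].
#' @param spacing Lattice spacing, Angstrom (default 1).
#' @param padding Dilation, Angstrom (default 5).
#' @return A [grid_spec()].
#' @export
build_grid_spec <- function(cylinder, spacing = 1, padding = 5) {
  if (spacing <= 0) abort("grid spacing must be > 0")
  a <- cylinder$axis
  # bounding half-extent of a finite cylinder along each coordinate axis
  half <- abs(a) * cylinder$length / 2 +
    cylinder$radius * sqrt(pmax(0, 1 - a^2))
  lo <- cylinder$center - half - padding
  extent <- 2 * (half + padding)
  dims <- floor(extent / spacing) + 1
  grid_spec(origin = lo, spacing = spacing, dims = dims)
}

#' Evaluate the potential grid of a structure
#'
#' Screened-Coulomb sum over all charged atoms at every lattice point.
#'
#' @param s A `mep_structure` with charges assigned.
#' @param spec Shared [grid_spec()].
#' @param params [elec_params()].
#' @return List of class `mep_grid`: `spec`, `values` (length `spec$n`,
#'   kcal mol^-1 e^-1, x fastest), `label`.
#' @export
compute_potential_grid <- function(s, spec, params = elec_params()) {
  stopifnot(inherits(spec, "mep_grid_spec"))
  pts <- grid_points(spec)
  qi <- which(s$charge != 0)
  if (length(qi) == 0) {
    warn(sprintf("structure '%s' carries no charge; potential grid is zero",
                 structure_label(s)))
  }
  phi <- numeric(spec$n)
  pref <- params$coulomb / params$dielectric
  xyz <- coords(s)
  for (i in qi) {
    d <- sqrt((pts[, 1] - xyz[i, 1])^2 + (pts[, 2] - xyz[i, 2])^2 +
                (pts[, 3] - xyz[i, 3])^2)
    d <- pmax(d, params$floor_dist)
    phi <- phi + pref * s$charge[i] *
      (if (params$kappa > 0) exp(-params$kappa * d) / d else 1 / d)
  }
  structure(list(spec = spec, values = unname(phi),
                 label = structure_label(s)),
            class = "mep_grid")
}

#' @export
print.mep_grid <- function(x, ...) {
  cat(sprintf("<mep_grid> '%s', %d points, range [%.4g, %.4g] kcal/mol/e\n",
              x$label, x$spec$n, min(x$values), max(x$values)))
  invisible(x)
}

#' Monopole and dipole summary of a charge distribution
#'
#' Net charge Q and dipole vector about the charge centroid (absolute-charge
#' weighted; geometric centroid when all charges are zero).
#'
#' @param s A `mep_structure` with charges assigned.
#' @return List of class `mep_multipole`: `Q` (e), `mu` (length-3, e
#'   Angstrom), `center` (expansion centre, Angstrom).
#' @export
multipole_summary <- function(s) {
  xyz <- coords(s)
  w <- abs(s$charge)
  center <- if (sum(w) > 0) colSums(xyz * w) / sum(w) else colMeans(xyz)
  rel <- sweep(xyz, 2, center)
  structure(list(Q = sum(s$charge),
                 mu = colSums(rel * s$charge),
                 center = center),
            class = "mep_multipole")
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Analytic monopole-dipole similarity prescreen
#'
#' Fast grid-free screen: the truncated (monopole + dipole) potentials of
#' two summaries are sampled on a deterministic spherical shell about the
#' shared-frame origin and compared with the Hodgkin formula. Advisory
#' output only; final clustering always uses grid-based indices.
#'
#' @param a,b `mep_multipole` summaries.
#' @param shell_radius Sampling shell radius, Angstrom (default 30).
#' @param n_points Number of shell points (default 256, minimum 12).
#' @return Approximate similarity index in \[-1, 1\].
#' @export
prescreen_similarity <- function(a, b, shell_radius = 30, n_points = 256) {
  stopifnot(shell_radius > 0, n_points >= 12)
  zero <- function(m) m$Q == 0 && all(m$mu == 0)
  if (zero(a) && zero(b)) {
    abort("similarity undefined: both multipole summaries are zero")
  }
  pts <- fibonacci_sphere(n_points) * shell_radius
  trunc_phi <- function(m) {
    r <- sqrt(rowSums(pts^2))
    m$Q / r + as.vector(pts %*% m$mu) / r^3
  }
  pa <- trunc_phi(a); pb <- trunc_phi(b)
  2 * sum(pa * pb) / (sum(pa^2) + sum(pb^2))
}

#' Export a grid (or mask) as an OpenDX scalar field
#'
#' @param values Numeric vector of length `spec$n` (x fastest) or a
#'   `mep_grid` / `mep_mask`.
#' @param spec `mep_grid_spec`; taken from `values` when it is a grid/mask.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(values, spec = NULL, path) {
  if (inherits(values, "mep_grid")) {
    spec <- values$spec; values <- values$values
  } else if (inherits(values, "mep_mask")) {
    spec <- values$spec; values <- as.numeric(values$included)
  }
  stopifnot(inherits(spec, "mep_grid_spec"), length(values) == spec$n)
  d <- spec$dims
  # DX convention: data listed with z varying fastest
  arr <- array(values, dim = d)
  vals <- as.vector(aperm(arr, c(3, 2, 1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", spec$origin[1], spec$origin[2],
            spec$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", spec$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", spec$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", spec$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            spec$n)), con)
  pad <- ceiling(length(vals) / 3) * 3
  vals <- c(vals, rep(NA_real_, pad - length(vals)))
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r) {
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " ")
  })
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
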