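# Focus-region masks: the molecular "skin" (a shell strictly outside the
# solvent-accessible surface but within a set thickness of it) intersected
# with a cylinder over the peptide-binding cleft. Only lattice points inside
# both skins of a pair and the cylinder enter the similarity index.

#' Skin parameters
#'
#' @param probe Probe radius sigma in Angstrom (default 1): the
#'   solvent-accessible surface sits at (atom radius + sigma) from each atom
#'   centre.
#' @param thickness Skin thickness delta in Angstrom (default 25): points
#'   further than delta beyond the surface are excluded.
#' @export
skin_params <- function(probe = 1, thickness = 25) {
  stopifnot(probe >= 0)
  if (thickness <= 0) abort("skin thickness must be > 0")
  structure(list(probe = probe, thickness = thickness),
            class = "mep_skin_params")
}

#' Cylindrical focus region
#'
#' Default dimensions 40 Angstrom radius x 33 Angstrom length, sized to
#' encompass a pMHC-I cleft; the axis is the cleft-top normal, so the
#' radius (larger than the length) spans the cleft plane.
#'
#' @param center Length-3 numeric, Angstrom.
#' @param axis Length-3 direction (normalized internally).
#' @param radius Angstrom (default 40).
#' @param length Angstrom (default 33).
#' @export
cylinder_region <- function(center, axis = c(0, 0, 1), radius = 40,
                            length = 33) {
  stopifnot(length(center) == 3, length(axis) == 3)
  if (radius <= 0 || length <= 0) abort("cylinder radius and length must be > 0")
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) abort("cylinder axis must be non-zero")
  structure(list(center = as.numeric(center), axis = as.numeric(axis) / nrm,
                 radius = radius, length = length),
            class = "mep_cylinder")
}

#' @export
print.mep_cylinder <- function(x, ...) {
  cat(sprintf(
    "<mep_cylinder> r %g A x L %g A, center (%.2f, %.2f, %.2f), axis (%.3f, %.3f, %.3f)\n",
    x$radius, x$length, x$center[1], x$center[2], x$center[3],
    x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

new_mask <- function(spec, included) {
  structure(list(spec = spec, included = included, count = sum(included)),
            class = "mep_mask")
}

#' @export
print.mep_mask <- function(x, ...) {
  cat(sprintf("<mep_mask> %d / %d points included\n", x$count, x$spec$n))
  invisible(x)
}

#' Molecular skin mask
#'
#' A lattice point g is included iff
#' `0 < min_i(|g - r_i| - (R_i + probe)) <= thickness`: strictly outside the
#' solvent-accessible surface (open bound) but within the skin thickness of
#' it (closed bound).
#'
#' @param s A `mep_structure` with radii assigned.
#' @param spec Shared [grid_spec()].
#' @param params [skin_params()].
#' @return A `mep_mask`.
#' @export
compute_skin_mask <- function(s, spec, params = skin_params()) {
  pts <- grid_points(spec)
  xyz <- coords(s)
  m <- rep(Inf, spec$n)
  for (i in seq_len(nrow(s))) {
    d <- sqrt((pts[, 1] - xyz[i, 1])^2 + (pts[, 2] - xyz[i, 2])^2 +
                (pts[, 3] - xyz[i, 3])^2) - (s$radius[i] + params$probe)
    m <- pmin(m, d)
  }
  inc <- m > 0 & m <= params$thickness
  if (!any(inc)) {
    abort(sprintf("empty skin for structure '%s' on this grid",
                  structure_label(s)))
  }
  new_mask(spec, inc)
}

#' Place the focus cylinder on the cleft
#'
#' Auto-placement from the reference structure: centre = centroid of the
#' peptide-chain atoms; axis = unit normal of the least-squares plane
#' through the peptide CA atoms (the cleft-top normal). Explicit `center` /
#' `axis` values override the automatic ones verbatim.
#'
#' @param reference Reference `mep_structure` (peptide chain identifiable).
#' @param center,axis Optional explicit values (length-3).
#' @param radius,length Cylinder dimensions, Angstrom.
#' @param chain Optional peptide chain override.
#' @return A [cylinder_region()].
#' @export
place_cylinder <- function(reference, center = NULL, axis = NULL,
                           radius = 40, length = 33, chain = NULL) {
  if (is.null(center) || is.null(axis)) {
    ch <- peptide_chain(reference, override = chain)
    pep <- reference[reference$chain_id == ch, , drop = FALSE]
    if (is.null(center)) center <- colMeans(coords(pep))
    if (is.null(axis)) {
      ca <- pep[pep$atom_name == "CA", , drop = FALSE]
      if (nrow(ca) < 3) ca <- pep
      m <- sweep(coords(ca), 2, colMeans(coords(ca)))
      sv <- svd(m)
      # a near-collinear peptide leaves the plane normal undetermined; fall
      # back to the platform plane of the whole complex (the cleft floor)
      if (sv$d[2] < 1e-6 * sv$d[1]) {
        all_xyz <- coords(reference)
        sv <- svd(sweep(all_xyz, 2, colMeans(all_xyz)))
      }
      axis <- sv$v[, 3]
      # orient deterministically: first non-zero component positive
      nz <- which(abs(axis) > 1e-12)[1]
      if (axis[nz] < 0) axis <- -axis
    }
  }
  cylinder_region(center = center, axis = axis, radius = radius,
                  length = length)
}

#' Cylinder mask
#'
#' A point is included iff its radial distance from the axis is at most the
#' radius and its axial offset from the centre is at most length/2 (closed
#' bounds on the surface).
#'
#' @param spec Shared [grid_spec()].
#' @param cyl A [cylinder_region()].
#' @return A `mep_mask`.
#' @export
cylinder_mask <- function(spec, cyl) {
  pts <- grid_points(spec)
  rel <- sweep(pts, 2, cyl$center)
  ax <- as.vector(rel %*% cyl$axis)
  rad2 <- rowSums(rel^2) - ax^2
  inc <- rad2 <= cyl$radius^2 + 1e-9 & abs(ax) <= cyl$length / 2 + 1e-9
  if (!any(inc)) abort("cylinder mask is empty on this grid")
  new_mask(spec, inc)
}

#' Pairwise comparison mask
#'
#' Logical AND of the two skins and the cylinder: the points over which a
#' pair of potential grids is compared.
#'
#' @param skin_a,skin_b Skin `mep_mask` objects of the two complexes.
#' @param cyl Cylinder `mep_mask` on the same spec.
#' @param labels Optional pair labels for error messages.
#' @return A `mep_mask`.
#' @export
pair_mask <- function(skin_a, skin_b, cyl, labels = c("a", "b")) {
  for (m in list(skin_b, cyl)) {
    if (!same_spec(skin_a$spec, m$spec)) {
      abort("masks with different grid specs cannot be combined")
    }
  }
  inc <- skin_a$included & skin_b$included & cyl$included
  if (!any(inc)) {
    abort(sprintf("empty comparison region for pair (%s, %s)",
                  labels[1], labels[2]))
  }
  new_mask(skin_a$spec, inc)
}
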