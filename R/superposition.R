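# Rigid-body superposition of complexes onto a common reference frame.
# All potential grids downstream live in the reference frame, so every
# structure is fitted (twice) before any mask or grid is built.

#' Pair atoms between two structures
#'
#' Atoms are paired on the (chain_id, residue_number, atom_name) key;
#' `selection = "calpha"` restricts to CA atoms first. Pairs are ordered by
#' key so the pairing is independent of atom order in either file.
#'
#' @param mobile,reference `mep_structure` objects.
#' @param selection `"calpha"` (default) or `"all"`.
#' @return List with matrices `P` (mobile) and `Q` (reference), n x 3 each.
#' @keywords internal
pair_atoms <- function(mobile, reference, selection = c("calpha", "all")) {
  selection <- match.arg(selection)
  pick <- function(s) {
    if (selection == "calpha") s <- s[s$atom_name == "CA", , drop = FALSE]
    k <- paste(s$chain_id, s$residue_number, s$atom_name)
    keep <- !duplicated(k)
    list(key = k[keep], s = s[keep, , drop = FALSE])
  }
  a <- pick(mobile); b <- pick(reference)
  common <- sort(intersect(a$key, b$key))
  if (length(common) < 3) {
    abort(sprintf(
      "cannot pair structure '%s' with reference: %d shared atoms (>= 3 required)",
      structure_label(mobile), length(common)))
  }
  P <- coords(a$s)[match(common, a$key), , drop = FALSE]
  Q <- coords(b$s)[match(common, b$key), , drop = FALSE]
  list(P = P, Q = Q, n = length(common))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid transform of `mobile` onto `reference` over paired
#' atoms, via SVD of the cross-covariance with the usual reflection
#' correction, so the returned rotation is proper (det = +1).
#'
#' @inheritParams pair_atoms
#' @return A list of class `mep_fit`: `rotation` (3 x 3), `translation`
#'   (length-3, Angstrom), `rmsd` (Angstrom over paired atoms), `n_paired`.
#'   The fitted position of a point p is `rotation %*% p + translation`.
#' @export
kabsch_fit <- function(mobile, reference, selection = c("calpha", "all")) {
  pr <- pair_atoms(mobile, reference, selection)
  P <- pr$P; Q <- pr$Q
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  # collinearity check: rank of the centered mobile set
  if (sum(svd(P0)$d > 1e-8 * max(1, max(abs(P0)))) < 2) {
    abort("degenerate fit: paired atoms are collinear")
  }
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- qc - as.vector(R %*% pc)
  fitted <- P %*% t(R) + matrix(tr, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd,
                 n_paired = pr$n),
            class = "mep_fit")
}

#' @export
print.mep_fit <- function(x, ...) {
  cat(sprintf("<mep_fit> %d paired atoms, rmsd %.4g A\n", x$n_paired, x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to a structure
#'
#' @param s A `mep_structure`.
#' @param fit A `mep_fit`.
#' @return Transformed structure (same atoms and order).
#' @export
apply_transform <- function(s, fit) {
  xyz <- coords(s) %*% t(fit$rotation) +
    matrix(fit$translation, nrow(s), 3, byrow = TRUE)
  s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
  s
}

#' Fit all structures onto a reference, twice
#'
#' Each structure is superposed onto the reference and the fit applied, then
#' the superposition is repeated on the result; the RMSD after each pass is
#' reported. For an exact least-squares optimum the second pass is a fixed
#' point, so pass-2 RMSD never exceeds pass-1 RMSD.
#'
#' @param structures List of `mep_structure` objects.
#' @param reference Reference `mep_structure` (untouched).
#' @inheritParams pair_atoms
#' @return List with `structures` (fitted, input order) and `rmsd`, a tibble
#'   with columns `label`, `n_paired`, `rmsd_pass1`, `rmsd_pass2`.
#' @export
fit_all <- function(structures, reference, selection = c("calpha", "all")) {
  selection <- match.arg(selection)
  fitted <- vector("list", length(structures))
  rows <- vector("list", length(structures))
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    f1 <- kabsch_fit(s, reference, selection)
    s1 <- apply_transform(s, f1)
    f2 <- kabsch_fit(s1, reference, selection)
    fitted[[i]] <- apply_transform(s1, f2)
    rows[[i]] <- tibble(label = structure_label(s), n_paired = f2$n_paired,
                        rmsd_pass1 = f1$rmsd, rmsd_pass2 = f2$rmsd)
  }
  list(structures = fitted, rmsd = dplyr::bind_rows(rows))
}
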