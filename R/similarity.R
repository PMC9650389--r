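# Hodgkin similarity indices over pairwise comparison masks.
#
# SI(a, b) = 2 * sum_k phi_a(k) phi_b(k) / (sum_k phi_a(k)^2 + sum_k
# phi_b(k)^2), k over mask points; SI = 1 for identical fields, -1 for
# sign-flipped ones. The electrostatic distance D = sqrt(2 - 2 SI) maps
# [1, -1] onto [0, 2].

#' Hodgkin similarity index of two potential grids over a mask
#'
#' @param a,b `mep_grid` objects on the same spec.
#' @param mask A `mep_mask` on that spec with at least one included point.
#' @return SI in \[-1, 1\].
#' @export
hodgkin_index <- function(a, b, mask) {
  if (!same_spec(a$spec, b$spec) || !same_spec(a$spec, mask$spec)) {
    abort("grids and mask must share one grid spec")
  }
  if (mask$count < 1) abort("comparison mask is empty")
  va <- a$values[mask$included]
  vb <- b$values[mask$included]
  denom <- sum(va^2) + sum(vb^2)
  if (denom == 0) {
    abort(sprintf(
      "similarity undefined: grids '%s' and '%s' are both zero on the mask",
      a$label, b$label))
  }
  2 * sum(va * vb) / denom
}

#' Electrostatic distance from a similarity index
#'
#' `D = sqrt(2 - 2 SI)`, strictly decreasing in SI, in \[0, 2\]. Values of
#' SI outside \[-1, 1\] by at most 1e-9 are clamped; larger excursions are
#' an error.
#'
#' @param si Numeric vector of similarity indices.
#' @return Distances, same length.
#' @export
si_to_distance <- function(si) {
  tol <- 1e-9
  if (any(si > 1 + tol | si < -1 - tol)) {
    abort("similarity index outside [-1, 1]")
  }
  si <- pmin(1, pmax(-1, si))
  sqrt(2 - 2 * si)
}

#' All-pairs similarity matrix
#'
#' Computes the Hodgkin index for every pair of complexes over the
#' pair-specific mask (skin_i AND skin_j AND cylinder). Because the mask is
#' pair-specific, the SI matrix need not be positive semi-definite.
#'
#' @param grids List of `mep_grid` (>= 3, congruent specs).
#' @param skins List of skin `mep_mask`, same order.
#' @param cyl Cylinder `mep_mask`.
#' @return Object of class `mep_simmat`: `labels`, `SI` (symmetric,
#'   diagonal 1), `D` (`sqrt(2 - 2 SI)`, diagonal 0), `points_used`
#'   (pair-mask counts; diagonal = own skin-in-cylinder count).
#' @export
similarity_matrix <- function(grids, skins, cyl) {
  n <- length(grids)
  if (n < 3) abort("at least three complexes are required")
  if (length(skins) != n) abort("grids and skins must have the same length")
  labels <- unname(vapply(grids, function(g) g$label, character(1)))
  if (anyDuplicated(labels)) abort("complex labels must be unique")
  SI <- diag(1, n)
  PU <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    PU[i, i] <- pair_mask(skins[[i]], skins[[i]], cyl,
                          labels = labels[c(i, i)])$count
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m <- pair_mask(skins[[i]], skins[[j]], cyl, labels = labels[c(i, j)])
      SI[i, j] <- SI[j, i] <- hodgkin_index(grids[[i]], grids[[j]], m)
      PU[i, j] <- PU[j, i] <- m$count
    }
  }
  dimnames(SI) <- dimnames(PU) <- list(labels, labels)
  D <- matrix(si_to_distance(as.vector(SI)), n, n, dimnames = dimnames(SI))
  diag(D) <- 0
  structure(list(labels = labels, SI = SI, D = D, points_used = PU),
            class = "mep_simmat")
}

#' @export
print.mep_simmat <- function(x, ...) {
  cat(sprintf("<mep_simmat> %d complexes; SI range [%.3f, %.3f] off-diagonal\n",
              length(x$labels),
              min(x$SI[upper.tri(x$SI)]), max(x$SI[upper.tri(x$SI)])))
  invisible(x)
}

#' Tidy a similarity matrix into long form
#'
#' @param x A `mep_simmat`.
#' @param ... Unused.
#' @return Tibble with one row per unordered pair: `label_a`, `label_b`,
#'   `si`, `distance`, `points_used`.
#' @export
tidy.mep_simmat <- function(x, ...) {
  n <- length(x$labels)
  ij <- which(upper.tri(x$SI), arr.ind = TRUE)
  tibble(label_a = x$labels[ij[, 1]],
         label_b = x$labels[ij[, 2]],
         si = x$SI[ij],
         distance = x$D[ij],
         points_used = x$points_used[ij])
}

#' Heat-map of a similarity matrix
#'
#' @param object A `mep_simmat`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mep_simmat <- function(object, ...) {
  df <- tidyr::expand_grid(label_a = object$labels,
                           label_b = object$labels)
  df$si <- as.vector(t(object$SI))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label_b, y = .data$label_a,
                                   fill = .data$si)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "SI") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Hodgkin similarity of cleft potentials") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

write_labeled_matrix <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
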