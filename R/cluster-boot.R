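# Hierarchical clustering with multiscale-bootstrap support.
#
# Complexes are clustered by complete linkage on correlation distances
# between their similarity profiles (columns of the SI matrix; rows act as
# the resampling units). Branch support is estimated by the multiscale
# bootstrap: rows are resampled with replacement at several relative sample
# sizes r, each replicate is reclustered, and the per-scale frequency BP_r
# with which a reference branch reappears is recorded. The approximately
# unbiased p-value AU corrects BP for the curvature of the cluster boundary
# by fitting psi(r) = qnorm(1 - BP_r) = v*sqrt(r) + c/sqrt(r) across scales
# (weighted least squares) and setting AU = 1 - pnorm(v - c).

#' Correlation distance between columns
#'
#' `d(i, j) = 1 - Pearson(col_i, col_j)`; range \[0, 2\].
#'
#' @param data Numeric matrix, one column per complex (>= 3 columns).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
correlation_distance <- function(data) {
  data <- as.matrix(data)
  if (ncol(data) < 3) abort("at least three columns (complexes) are required")
  sds <- apply(data, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(data)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    abort(paste0("zero-variance similarity profile for: ",
                 paste(bad, collapse = ", ")))
  }
  d <- 1 - stats::cor(data)
  diag(d) <- 0
  d
}

# Correlation distance tolerant of degenerate bootstrap resamples: columns
# that become constant under resampling get correlation 0 (distance 1).
.cor_distance_safe <- function(data) {
  d <- 1 - suppressWarnings(stats::cor(data))
  d[!is.finite(d)] <- 1
  diag(d) <- 0
  d
}

#' Complete-linkage agglomerative clustering
#'
#' Merges the closest pair of clusters, where inter-cluster distance is the
#' maximum pairwise member distance. Ties are broken deterministically by
#' the lexicographically smallest pair of sorted leaf-label sets, so the
#' tree is bit-reproducible.
#'
#' @param dist Symmetric distance matrix with labeled rows/columns
#'   (unlabeled matrices get `L1, L2, ...`).
#' @return Object of class `mep_tree`: `labels`; `merge` (hclust encoding);
#'   `height`; `order`; `leaf_sets`, a list giving for every internal node
#'   (merge order) the sorted labels under it.
#' @export
complete_linkage <- function(dist) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n < 2) abort("at least two items are required")
  if (max(abs(dist - t(dist))) > 1e-9) {
    abort("distance matrix is not symmetric")
  }
  labels <- rownames(dist)
  if (is.null(labels)) labels <- paste0("L", seq_len(n))

  # active clusters: id (hclust encoding: -leaf or +merge index), members
  ids <- -seq_len(n)
  members <- as.list(seq_len(n))
  keys <- lapply(seq_len(n), function(i) labels[i])
  D <- dist
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  leaf_sets <- vector("list", n - 1)

  for (step in seq_len(n - 1)) {
    k <- length(ids)
    # find minimal distance; ties -> lexicographically smallest leaf-set pair
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dij <- D[i, j]
        if (dij > best_d + 1e-15) next
        kp <- sort(c(paste(sort(keys[[i]]), collapse = "\1"),
                     paste(sort(keys[[j]]), collapse = "\1")))
        kp <- paste(kp, collapse = "\2")
        if (dij < best_d - 1e-15 ||
            (abs(dij - best_d) <= 1e-15 && kp < best_key)) {
          best <- c(i, j); best_d <- dij; best_key <- kp
        }
      }
    }
    i <- best[1]; j <- best[2]
    pair <- sort(c(ids[i], ids[j]))
    merge[step, ] <- pair
    height[step] <- best_d
    new_members <- c(members[[i]], members[[j]])
    leaf_sets[[step]] <- sort(labels[new_members])

    # complete linkage update: distance to the union is the max
    newd <- pmax(D[i, ], D[j, ])[-c(i, j)]
    keep <- setdiff(seq_len(k), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    D <- rbind(cbind(D, newd), c(newd, 0))
    ids <- c(ids[keep], step)
    members <- c(members[keep], list(new_members))
    keys <- c(keys[keep], list(sort(labels[new_members])))
  }

  order <- .tree_order(merge, n)
  structure(list(labels = labels, merge = merge, height = height,
                 order = order, leaf_sets = leaf_sets),
            class = "mep_tree")
}

# leaf ordering by left-to-right traversal of the merge structure
.tree_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' @export
print.mep_tree <- function(x, ...) {
  cat(sprintf("<mep_tree> %d leaves, %d merges, heights [%.4g, %.4g]\n",
              length(x$labels), nrow(x$merge),
              min(x$height), max(x$height)))
  invisible(x)
}

#' Convert to a base-R hclust object
#' @param x A `mep_tree`.
#' @param ... Unused.
#' @return An `hclust` object.
#' @export
as.hclust.mep_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "complete",
                 call = match.call(), dist.method = "correlation"),
            class = "hclust")
}

.canonical_set <- function(labs) paste(sort(labs), collapse = "\1")

# deterministic per-replicate seed stream: changing nboot must not reshuffle
# earlier replicates, so each (scale, replicate) gets its own seed.
.replicate_seed <- function(seed, scale_idx, b) {
  (abs(seed) + scale_idx * 1000003 + b * 791) %% 2147483647L
}

#' Multiscale bootstrap of the clustering
#'
#' For each relative scale r, `round(r * n_rows)` rows of `data` are drawn
#' with replacement `nboot` times; each resample is reclustered (correlation
#' distance + complete linkage) and each reference branch's leaf set is
#' counted. `BP_r` at r = 1 is the ordinary bootstrap probability. The run
#' is bit-reproducible given (seed, scales, nboot): every replicate uses its
#' own derived seed.
#'
#' @param data Numeric matrix, columns = complexes, rows = resampling units.
#' @param scales Relative sample sizes r (default 0.5 to 1.4 by 0.1).
#' @param nboot Replicates per scale (default 1000).
#' @param seed Master seed (integer).
#' @return List: `tree` (reference `mep_tree`) and `table`, a tibble of
#'   class `mep_boottable` with columns `node`, `leaf_set` (list), `scale`,
#'   `nboot`, `count`, `bp`.
#' @export
multiscale_bootstrap <- function(data, scales = seq(0.5, 1.4, by = 0.1),
                                 nboot = 1000, seed = 1) {
  data <- as.matrix(data)
  if (nboot < 1) abort("nboot must be >= 1")
  n_rows <- nrow(data)
  sizes <- round(scales * n_rows)
  if (any(sizes < 2)) {
    abort(sprintf("resample size < 2 rows at scale %g",
                  scales[which(sizes < 2)[1]]))
  }
  tree <- complete_linkage(correlation_distance(data))
  node_keys <- vapply(tree$leaf_sets, .canonical_set, character(1))

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })

  counts <- matrix(0L, length(node_keys), length(scales))
  for (si in seq_along(scales)) {
    m <- sizes[si]
    for (b in seq_len(nboot)) {
      set.seed(.replicate_seed(seed, si, b))
      idx <- sample.int(n_rows, m, replace = TRUE)
      d <- .cor_distance_safe(data[idx, , drop = FALSE])
      rt <- complete_linkage(d)
      hit <- node_keys %in% vapply(rt$leaf_sets, .canonical_set,
                                   character(1))
      counts[, si] <- counts[, si] + hit
    }
  }

  tab <- tidyr::expand_grid(node = seq_along(node_keys),
                            scale_idx = seq_along(scales))
  tab$leaf_set <- tree$leaf_sets[tab$node]
  tab$scale <- scales[tab$scale_idx]
  tab$nboot <- nboot
  tab$count <- counts[cbind(tab$node, tab$scale_idx)]
  tab$bp <- tab$count / nboot
  tab$scale_idx <- NULL
  tab <- tab[, c("node", "leaf_set", "scale", "nboot", "count", "bp")]
  class(tab) <- c("mep_boottable", class(tab))
  list(tree = tree, table = tab)
}

#' AU p-values from a multiscale bootstrap table
#'
#' Per node, fits `qnorm(1 - BP_r) = v*sqrt(r) + c/sqrt(r)` by weighted
#' least squares over the scales with BP strictly inside (0, 1), with
#' weights `nboot * dnorm(psi)^2 / (BP (1 - BP))`, and reports
#' `AU = 1 - pnorm(v - c)`. Degenerate nodes: BP = 1 at all scales gives
#' AU = 1; BP = 0 at all scales gives AU = 0; otherwise fewer than two
#' usable scales gives `NA` with a warning.
#'
#' @param table A `mep_boottable`.
#' @return Tibble, one row per node: `node`, `leaf_set`, `au`, `bp`
#'   (ordinary bootstrap probability at the scale closest to 1), `v`, `c`.
#' @export
au_from_bp <- function(table) {
  split_tab <- split(as.data.frame(table[, c("node", "scale", "nboot",
                                             "count", "bp")]),
                     table$node)
  leaf_sets <- table$leaf_set[!duplicated(table$node)]
  nodes <- table$node[!duplicated(table$node)]

  one <- function(d) {
    bp1 <- d$bp[which.min(abs(d$scale - 1))]
    if (all(d$bp == 1)) return(c(au = 1, bp = bp1, v = NA, c = NA))
    if (all(d$bp == 0)) return(c(au = 0, bp = bp1, v = NA, c = NA))
    use <- d$bp > 0 & d$bp < 1
    if (sum(use) < 2) {
      warn(sprintf("node %d: fewer than 2 usable scales for the AU fit",
                   d$node[1]))
      return(c(au = NA, bp = bp1, v = NA, c = NA))
    }
    r <- d$scale[use]; bp <- d$bp[use]; nb <- d$nboot[use]
    psi <- stats::qnorm(1 - bp)
    w <- nb * stats::dnorm(psi)^2 / (bp * (1 - bp))
    X <- cbind(sqrt(r), 1 / sqrt(r))
    coef <- solve(crossprod(X * sqrt(w)), crossprod(X * sqrt(w), psi * sqrt(w)))
    v <- coef[1]; cc <- coef[2]
    c(au = 1 - stats::pnorm(v - cc), bp = bp1, v = v, c = cc)
  }

  res <- t(vapply(split_tab, one, numeric(4)))
  # split() orders groups by factor level (node as character); realign
  ord <- match(as.character(nodes), rownames(res))
  out <- tibble(node = nodes, leaf_set = leaf_sets,
                au = res[ord, "au"], bp = res[ord, "bp"],
                v = res[ord, "v"], c = res[ord, "c"])
  out[order(out$node), ]
}

#' Cluster complexes with bootstrap support
#'
#' End-to-end clustering stage: builds the data matrix from a similarity
#' matrix (columns = complexes' similarity profiles), clusters with
#' complete linkage on correlation distances, runs the multiscale bootstrap
#' and attaches AU/BP to every internal node.
#'
#' @param x A `mep_simmat`, or a plain numeric matrix (columns = complexes).
#' @param input Which matrix to cluster when `x` is a `mep_simmat`:
#'   `"si"` (default) or `"d"`.
#' @param scales,nboot,seed Passed to [multiscale_bootstrap()].
#' @param au_threshold Flagging threshold (default 0.95; strict `>`).
#' @return Object of class `mep_ptree`: `tree` (`mep_tree`), `nodes`
#'   (tibble: `node`, `leaf_set`, `height`, `au`, `bp`, `flagged`),
#'   `table` (the `mep_boottable`), `params`.
#' @export
cluster_with_bootstrap <- function(x, input = c("si", "d"),
                                   scales = seq(0.5, 1.4, by = 0.1),
                                   nboot = 1000, seed = 1,
                                   au_threshold = 0.95) {
  input <- match.arg(input)
  data <- if (inherits(x, "mep_simmat")) {
    if (input == "si") x$SI else x$D
  } else as.matrix(x)
  boot <- multiscale_bootstrap(data, scales = scales, nboot = nboot,
                               seed = seed)
  au <- au_from_bp(boot$table)
  nodes <- au
  nodes$height <- boot$tree$height[nodes$node]
  nodes <- nodes[, c("node", "leaf_set", "height", "au", "bp")]
  root <- which.max(vapply(boot$tree$leaf_sets, length, integer(1)))
  nodes$flagged <- !is.na(nodes$au) & nodes$au > au_threshold &
    nodes$node != root
  structure(list(tree = boot$tree, nodes = nodes, table = boot$table,
                 params = list(scales = scales, nboot = nboot, seed = seed,
                               au_threshold = au_threshold, input = input)),
            class = "mep_ptree")
}

#' @export
print.mep_ptree <- function(x, ...) {
  cat(sprintf(
    "<mep_ptree> %d leaves; %d/%d internal nodes flagged at AU > %g\n",
    length(x$tree$labels), sum(x$nodes$flagged), nrow(x$nodes),
    x$params$au_threshold))
  invisible(x)
}

#' Significant clusters of a supported tree
#'
#' Nodes whose AU p-value exceeds the threshold (strict inequality), the
#' root excluded.
#'
#' @param ptree A `mep_ptree`.
#' @param threshold AU threshold (default the one used at fit time, 0.95).
#' @return List of character vectors (leaf sets of flagged nodes).
#' @export
significant_clusters <- function(ptree, threshold = NULL) {
  if (is.null(threshold)) threshold <- ptree$params$au_threshold
  root <- which.max(vapply(ptree$tree$leaf_sets, length, integer(1)))
  idx <- which(!is.na(ptree$nodes$au) & ptree$nodes$au > threshold &
                 ptree$nodes$node != root)
  ptree$nodes$leaf_set[idx]
}

#' Partition induced by the flagged clusters
#'
#' Each leaf is assigned to the maximal flagged cluster containing it (the
#' largest supported, non-root branch it belongs to); leaves inside no
#' flagged cluster become singletons. Because nested sub-branches of a
#' tight group are typically also well supported, the maximal rule reads
#' out the coarsest supported grouping as a flat partition comparable to an
#' external labeling (e.g. by adjusted Rand index).
#'
#' @param ptree A `mep_ptree`.
#' @param threshold Optional AU threshold override.
#' @return Named integer vector: cluster membership per leaf label.
#' @export
flagged_partition <- function(ptree, threshold = NULL) {
  labels <- ptree$tree$labels
  sets <- significant_clusters(ptree, threshold)
  sets <- sets[order(vapply(sets, length, integer(1)), decreasing = TRUE)]
  part <- rep(NA_integer_, length(labels))
  names(part) <- labels
  next_id <- 1L
  for (s in sets) {
    free <- is.na(part[s])
    if (any(free)) {
      part[s][free] <- next_id
      next_id <- next_id + 1L
    }
  }
  for (l in labels[is.na(part)]) {
    part[l] <- next_id
    next_id <- next_id + 1L
  }
  part
}

#' Tidy a supported tree
#' @param x A `mep_ptree`.
#' @param ... Unused.
#' @return Tibble of internal nodes: `node`, `height`, `au`, `bp`,
#'   `flagged`, `n_leaves`, `leaves` (collapsed label string).
#' @export
tidy.mep_ptree <- function(x, ...) {
  tibble(node = x$nodes$node,
         height = x$nodes$height,
         au = x$nodes$au,
         bp = x$nodes$bp,
         flagged = x$nodes$flagged,
         n_leaves = vapply(x$nodes$leaf_set, length, integer(1)),
         leaves = vapply(x$nodes$leaf_set, paste, character(1),
                         collapse = ","))
}

#' One-row summary of a supported tree
#' @param x A `mep_ptree`.
#' @param ... Unused.
#' @return Tibble: leaf count, flagged-node count, min/max AU, nboot, seed.
#' @export
glance.mep_ptree <- function(x, ...) {
  tibble(n_leaves = length(x$tree$labels),
         n_flagged = sum(x$nodes$flagged),
         min_au = min(x$nodes$au, na.rm = TRUE),
         max_au = max(x$nodes$au, na.rm = TRUE),
         nboot = x$params$nboot,
         seed = x$params$seed)
}

#' Dendrogram with AU support
#'
#' Segment-based dendrogram; internal nodes are annotated with AU (in %),
#' flagged nodes highlighted.
#'
#' @param object A `mep_ptree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mep_ptree <- function(object, ...) {
  tree <- object$tree
  n <- length(tree$labels)
  leaf_x <- match(seq_len(n), tree$order)
  node_x <- numeric(n - 1)
  segs <- list()
  xpos <- function(id) if (id < 0) leaf_x[-id] else node_x[id]
  ypos <- function(id) if (id < 0) 0 else tree$height[id]
  for (k in seq_len(n - 1)) {
    l <- tree$merge[k, 1]; r <- tree$merge[k, 2]
    node_x[k] <- (xpos(l) + xpos(r)) / 2
    h <- tree$height[k]
    segs[[k]] <- tibble(
      x = c(xpos(l), xpos(r), xpos(l)),
      xend = c(xpos(l), xpos(r), xpos(r)),
      y = c(ypos(l), ypos(r), h),
      yend = c(h, h, h))
  }
  segs <- dplyr::bind_rows(segs)
  ann <- tibble(x = node_x, y = tree$height,
                au = object$nodes$au[order(object$nodes$node)],
                flagged = object$nodes$flagged[order(object$nodes$node)])
  leaves <- tibble(x = leaf_x, label = tree$labels)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_label(data = ann,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = sprintf("%.0f", 100 * .data$au),
                                     colour = .data$flagged),
                        size = 3, label.size = 0.1) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey40"),
                                 guide = "none") +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.3, 0.1))) +
    ggplot2::labs(y = "complete-linkage height (correlation distance)",
                  x = NULL, title = "Cluster support (AU %, red = flagged)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Write a supported tree as Newick
#'
#' Internal-node labels carry the AU value scaled to 0-100.
#'
#' @param ptree A `mep_ptree`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(ptree, path) {
  phy <- ape::as.phylo(as.hclust(ptree$tree))
  # match internal phylo nodes to merge-order nodes by their tip sets
  pp <- ape::prop.part(phy)
  keys <- vapply(pp, function(tips) .canonical_set(attr(pp, "labels")[tips]),
                 character(1))
  node_keys <- vapply(ptree$tree$leaf_sets, .canonical_set, character(1))
  au <- ptree$nodes$au[match(keys, node_keys[ptree$nodes$node])]
  phy$node.label <- ifelse(is.na(au), "", sprintf("%.1f", 100 * au))
  ape::write.tree(phy, file = path)
  invisible(path)
}
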