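#' Structure-space analyses: distance matrices, MDS, heatmaps, trees
#'
#' All downstream analyses run on an N x N distance matrix D with
#' `D_ij = 1 - S_ij` (scaled similarity complement), zero diagonal, and
#' missing pairs set to the maximal dissimilarity 1 so that proximity in
#' any visualization always reflects an actually observed similarity.
#'
#' @name structure_viz
#' @keywords internal
NULL

#' Build a distance matrix from a score column
#'
#' `D_ij = 1 - S_ij`, diagonal 0, missing entries 1; asymmetric leftovers
#' (possible with asymmetric external methods) are symmetrized by
#' averaging the two orientations.
#'
#' @param view wide data.frame (a view of an `mcpsc_result`, or any
#'   frame with `domain1`, `domain2` and the score column).
#' @param column score column name (a method, `m1`..`m5`, or `median`).
#' @param domains optional full domain id vector (defaults to ids seen
#'   in `view`).
#' @return symmetric N x N matrix with domain ids as dimnames, entries
#'   in \[0, 1\].
#' @export
build_distance_matrix <- function(view, column, domains = NULL) {
  if (!column %in% names(view)) stop("unknown score column: ", column)
  if (is.null(domains)) domains <- sort(unique(c(view$domain1, view$domain2)))
  n <- length(domains)
  S <- matrix(NA_real_, n, n, dimnames = list(domains, domains))
  S[cbind(match(view$domain1, domains), match(view$domain2, domains))] <- view[[column]]
  A <- 1 - S
  At <- t(A)
  # mean of the two orientations where both exist, the present one where
  # only one exists, max dissimilarity (1) where neither does
  D <- ifelse(!is.na(A) & !is.na(At), (A + At) / 2,
              ifelse(!is.na(A), A, ifelse(!is.na(At), At, 1)))
  diag(D) <- 0
  pmin(pmax(D, 0), 1)
}

#' 2-D embedding by metric MDS (stress majorization)
#'
#' Iterative SMACOF stress majorization from seeded random starts:
#' repeatedly applies the Guttman transform, which never increases the
#' raw stress, stopping when the relative stress decrease falls below
#' `tol`. Several restarts (seeds `seed`, `seed + 1`, ...) guard against
#' local minima; the lowest-stress configuration is returned, so the
#' result is deterministic given `seed` and `n_starts`. The reported
#' stress is the normalized form
#' `sqrt(sum((d - delta)^2) / sum(delta^2))` over the lower triangle
#' (delta = target distances, d = configuration distances).
#'
#' @param D symmetric distance matrix (N >= 3).
#' @param seed base RNG seed for the random starts.
#' @param n_starts number of restarts.
#' @param max_iter per-start iteration cap; if the relative stress
#'   decrease never drops below `tol` the best iterate is returned with
#'   a warning.
#' @param tol relative convergence tolerance on the raw-stress decrease.
#' @return list with `coords` (N x 2, rownames = domain ids), `stress`
#'   (normalized), `iterations`.
#' @export
mds_embed_2d <- function(D, seed = 1, n_starts = 4, max_iter = 2000,
                         tol = 1e-12) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(n >= 3, isTRUE(all.equal(D, t(D))))
  lower <- lower.tri(D)
  denom <- sum(D[lower]^2)
  raw_stress <- function(X) {
    d <- as.matrix(stats::dist(X))
    sum((d[lower] - D[lower])^2)
  }
  one_start <- function(s) {
    X <- with_seed(s, matrix(stats::rnorm(n * 2), n, 2))
    prev <- raw_stress(X)
    iter <- 0L
    converged <- FALSE
    while (iter < max_iter) {
      iter <- iter + 1L
      d <- as.matrix(stats::dist(X))
      B <- ifelse(d > 0, -D / d, 0)
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X <- B %*% X / n                  # Guttman transform (unit weights)
      cur <- raw_stress(X)
      if (cur == 0 || prev - cur <= tol * prev) {
        converged <- TRUE; prev <- cur; break
      }
      prev <- cur
    }
    list(X = X, raw = prev, iterations = iter, converged = converged)
  }
  runs <- lapply(seed + seq_len(n_starts) - 1L, one_start)
  best <- runs[[which.min(vapply(runs, `[[`, 0, "raw"))]]
  if (!best$converged)
    warning("MDS did not converge in ", max_iter,
            " iterations; returning best iterate")
  X <- best$X
  rownames(X) <- rownames(D)
  list(coords = X, stress = sqrt(best$raw / denom),
       iterations = best$iterations)
}

#' Aggregate a domain distance matrix to group level
#'
#' Entry (F, G) is the mean distance over domain pairs with the first
#' domain in group F and the second in group G (label prefix at the
#' chosen level, default 2 = fold); self pairs are excluded on the
#' diagonal. Singleton groups get a diagonal entry of 0, flagged in the
#' `singleton` attribute.
#'
#' @param D domain distance matrix with id dimnames.
#' @param labels named character vector: domain id -> label.
#' @param level hierarchy level defining the groups.
#' @return G x G matrix, groups sorted by label prefix.
#' @export
fold_aggregate_matrix <- function(D, labels, level = 2) {
  ids <- rownames(D)
  grp <- vapply(strsplit(labels[ids], ".", fixed = TRUE),
                function(p) paste(p[seq_len(level)], collapse = "."), "")
  groups <- sort(unique(grp))
  G <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  singleton <- character()
  for (a in seq_along(groups)) {
    ia <- which(grp == groups[a])
    for (b in seq_along(groups)) {
      ib <- which(grp == groups[b])
      if (a == b) {
        if (length(ia) == 1) { singleton <- c(singleton, groups[a]); next }
        block <- D[ia, ib, drop = FALSE]
        G[a, b] <- mean(block[row(block) != col(block)])
      } else {
        G[a, b] <- mean(D[ia, ib])
      }
    }
  }
  if (length(singleton)) attr(G, "singleton") <- unique(singleton)
  G
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining (via ape); exact on additive
#' distances. Negative branch lengths are clamped to 0.
#'
#' @param D symmetric distance matrix with id dimnames, finite entries.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (any(!is.finite(D))) stop("non-finite distances")
  stopifnot(nrow(D) >= 3)
  tree <- ape::nj(D)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo` tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# deterministic class -> color map (sorted class names)
class_palette <- function(classes) {
  classes <- sort(unique(classes))
  stats::setNames(grDevices::hcl.colors(max(3, length(classes)), "Dark 3")[
    seq_along(classes)], classes)
}

top_class <- function(labels) sub("\\..*$", "", labels)

#' Render a heatmap of a (domain- or group-level) distance matrix
#'
#' @param matrix square matrix.
#' @param path output PNG path.
#' @param cluster reorder rows/columns by hierarchical clustering
#'   (`TRUE`) or keep label order (`FALSE`, default).
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
heatmap_render <- function(matrix, path, cluster = FALSE, main = "") {
  stopifnot(nrow(matrix) == ncol(matrix))
  show_names <- nrow(matrix) <= 60
  grDevices::png(path, width = 900, height = 800)
  on.exit(grDevices::dev.off())
  pheatmap::pheatmap(matrix, cluster_rows = cluster, cluster_cols = cluster,
                     show_rownames = show_names, show_colnames = show_names,
                     main = main)
  invisible(path)
}

#' Render a circular unrooted tree colored by class
#'
#' @param tree a `phylo` tree whose tips are domain ids.
#' @param labels named character vector: domain id -> 4-level label
#'   (level-1 prefix gives the color class).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
tree_render <- function(tree, labels, path) {
  cls <- top_class(labels[tree$tip.label])
  pal <- class_palette(cls)
  grDevices::png(path, width = 900, height = 900)
  on.exit(grDevices::dev.off())
  ape::plot.phylo(tree, type = "unrooted", lab4ut = "axial",
                  tip.color = pal[cls], cex = 0.7)
  graphics::legend("topright", legend = names(pal), col = pal, pch = 19,
                   title = "class", bty = "n")
  invisible(path)
}

#' Render an MDS scatterplot colored by class
#'
#' @param coords N x 2 coordinate matrix from [mds_embed_2d()] (rownames
#'   = domain ids).
#' @param labels named character vector: domain id -> label.
#' @param path output PNG path.
#' @param title plot title.
#' @return `path`, invisibly.
#' @export
mds_scatter_render <- function(coords, labels, path, title = "MDS of domain distances") {
  df <- data.frame(x = coords[, 1], y = coords[, 2],
                   class = top_class(labels[rownames(coords)]))
  pal <- class_palette(df$class)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        color = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_manual(values = pal) +
    ggplot2::labs(title = title, x = "MDS 1", y = "MDS 2", color = "class") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 7, height = 6, dpi = 120)
  invisible(path)
}
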