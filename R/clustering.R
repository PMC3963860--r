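#' Pairwise distance between cell-type expression signatures
#'
#' Builds one feature vector per cell type: the negated normalized Ct (the
#' log2-abundance scale, so a few very high expressors cannot dominate) over a
#' retained gene set; genes that did not amplify contribute -40 (absence is
#' signal). Default metric is 1 - Pearson correlation, the conventional
#' choice for expression-signature clustering; Euclidean distance is also
#' available.
#'
#' @param profiles An `expression_profile` tibble.
#' @param genes Character vector of genes to use (typically the union set from
#'   [filter_expressed()]); default all genes in the profile.
#' @param metric `"one_minus_pearson"` (default) or `"euclidean"`.
#' @return A `dist_matrix`: list with `labels`, symmetric matrix `d`, and
#'   `metric`.
#' @export
expression_distance <- function(profiles, genes = NULL,
                                metric = c("one_minus_pearson", "euclidean")) {
  metric <- match.arg(metric)
  df <- tibble::as_tibble(profiles)
  if (is.null(genes)) genes <- sort(unique(df$gene_symbol))
  df <- df[df$gene_symbol %in% genes, ]
  wide <- tidyr::pivot_wider(df[c("gene_symbol", "cell_type", "ct")],
                             names_from = "cell_type", values_from = "ct")
  feat <- -as.matrix(wide[-1])  # genes x cell types, -Ct scale
  if (nrow(feat) < 2 || ncol(feat) < 2) {
    rlang::abort("Need at least 2 genes and 2 cell types",
                 class = "receptoire_parameter_error")
  }
  if (anyNA(feat)) {
    rlang::abort("Every gene must have a Ct in every cell type",
                 class = "receptoire_parameter_error")
  }
  labels <- colnames(feat)
  if (metric == "one_minus_pearson") {
    if (any(apply(feat, 2, stats::sd) == 0)) {
      rlang::abort("Zero-variance feature vector under correlation metric",
                   class = "receptoire_degenerate_error")
    }
    d <- 1 - stats::cor(feat)
  } else {
    d <- as.matrix(stats::dist(t(feat)))
  }
  diag(d) <- 0
  structure(list(labels = labels, d = d, metric = metric),
            class = "dist_matrix")
}

#' Agglomerative average-linkage (UPGMA) clustering
#'
#' From-scratch agglomeration: repeatedly merges the two closest clusters;
#' the distance from a merged cluster to any other is the size-weighted mean
#' of its parts' distances (average linkage). Ties are broken
#' deterministically by the lexicographically smallest pair of cluster labels
#' (a cluster is labelled by its smallest leaf). Average linkage is monotone;
#' non-decreasing merge heights are asserted during the merge.
#'
#' @param dist A `dist_matrix` from [expression_distance()], or a plain
#'   symmetric matrix with dimnames.
#' @param linkage Only `"average"` is implemented.
#' @return A `upgma_tree`: list with `labels` and `merges`, a tibble of
#'   (step, left, right, height, members) where left/right are the labels of
#'   the merged clusters and members the comma-joined leaves of the new
#'   cluster.
#' @export
agglomerate <- function(dist, linkage = "average") {
  stopifnot(identical(linkage, "average"))
  if (inherits(dist, "dist_matrix")) {
    d <- dist$d
    labels <- dist$labels
  } else {
    d <- as.matrix(dist)
    labels <- rownames(d)
  }
  if (!all(is.finite(d))) {
    rlang::abort("Non-finite distances", class = "receptoire_parameter_error")
  }
  n <- length(labels)
  clusters <- as.list(labels)          # leaves of each active cluster
  names(clusters) <- labels            # cluster label = smallest leaf
  sizes <- stats::setNames(rep(1L, n), labels)
  dm <- d
  dimnames(dm) <- list(labels, labels)
  merges <- vector("list", n - 1)
  last_height <- -Inf
  for (step in seq_len(n - 1)) {
    act <- names(clusters)
    # find min-distance pair with lexicographic tie-break
    best <- NULL
    for (i in seq_along(act)[-length(act)]) {
      for (j in (i + 1):length(act)) {
        a <- act[i]; b <- act[j]
        pair <- sort(c(a, b))
        dij <- dm[a, b]
        if (is.null(best) || dij < best$d ||
            (dij == best$d &&
             (pair[1] < best$pair[1] ||
              (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
          best <- list(d = dij, pair = pair)
        }
      }
    }
    a <- best$pair[1]; b <- best$pair[2]
    stopifnot(best$d >= last_height)  # monotone heights for average linkage
    last_height <- best$d
    new_leaves <- sort(c(clusters[[a]], clusters[[b]]))
    new_label <- new_leaves[1]
    merges[[step]] <- tibble::tibble(
      step = step, left = a, right = b, height = best$d,
      members = paste(new_leaves, collapse = ",")
    )
    others <- setdiff(act, c(a, b))
    na <- sizes[a]; nb <- sizes[b]
    new_d <- (na * dm[a, others] + nb * dm[b, others]) / (na + nb)
    keep <- c(others, new_label)
    dm2 <- matrix(0, length(keep), length(keep), dimnames = list(keep, keep))
    if (length(others) > 0) {
      dm2[others, others] <- dm[others, others, drop = FALSE]
      dm2[new_label, others] <- new_d
      dm2[others, new_label] <- new_d
    }
    dm <- dm2
    clusters[[a]] <- NULL
    clusters[[b]] <- NULL
    clusters[[new_label]] <- new_leaves
    sizes <- c(sizes[setdiff(names(sizes), c(a, b))],
               stats::setNames(na + nb, new_label))
  }
  structure(list(labels = labels, merges = dplyr::bind_rows(merges)),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("<upgma_tree>", length(x$labels), "leaves\n")
  print(x$merges)
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' Applies the first n - k merges and returns the resulting partition of the
#' leaves.
#'
#' @param tree A `upgma_tree` from [agglomerate()].
#' @param k Number of clusters (1 <= k <= number of leaves).
#' @return List of k character vectors (sorted leaf labels), ordered by their
#'   smallest member.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "upgma_tree"))
  n <- length(tree$labels)
  if (k < 1 || k > n) {
    rlang::abort("k must be between 1 and the number of leaves",
                 class = "receptoire_parameter_error")
  }
  parent <- stats::setNames(tree$labels, tree$labels)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  n_merge <- n - k
  if (n_merge > 0) {
    for (i in seq_len(n_merge)) {
      m <- tree$merges[i, ]
      ra <- find(m$left); rb <- find(m$right)
      root <- min(ra, rb)
      parent[[ra]] <- root
      parent[[rb]] <- root
    }
  }
  roots <- vapply(tree$labels, find, character(1))
  parts <- unname(split(tree$labels, factor(roots, levels = unique(roots))))
  # order clusters (and members) by first appearance among the leaf labels:
  # deterministic and independent of the session's collation locale
  parts <- lapply(parts, function(p) p[order(match(p, tree$labels))])
  parts[order(vapply(parts, function(p) match(p[1], tree$labels), integer(1)))]
}

#' Newick string for a UPGMA tree
#'
#' Branch lengths place each leaf at depth height/2 of its cluster (an
#' ultrametric tree).
#'
#' @param tree A `upgma_tree`.
#' @return Newick string, terminated by `";"`.
#' @export
tree_newick <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  node_str <- stats::setNames(tree$labels, tree$labels)
  node_h <- stats::setNames(rep(0, length(tree$labels)), tree$labels)
  last <- NULL
  for (i in seq_len(nrow(tree$merges))) {
    m <- tree$merges[i, ]
    h <- m$height / 2
    s <- sprintf("(%s:%.12g,%s:%.12g)",
                 node_str[[m$left]], h - node_h[[m$left]],
                 node_str[[m$right]], h - node_h[[m$right]])
    new_label <- min(strsplit(m$members, ",", fixed = TRUE)[[1]])
    node_str[[new_label]] <- s
    node_h[[new_label]] <- h
    last <- s
  }
  paste0(last, ";")
}
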