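#' Jaccard similarity between OGU assemblages
#'
#' J(u, v) = |A_u intersect A_v| / |A_u union A_v| over the species sets of
#' the two OGUs.  OGUs with empty assemblages are flagged in the
#' `"empty_ogus"` attribute, and pairs with an empty union (two OGUs
#' holding no species) get J = 0 and are flagged in `"empty_pairs"`; the
#' diagonal
#' is 1 for non-empty OGUs and 0 for empty ones (an empty assemblage is not
#' similar to itself in any meaningful sense, and keeping it at 0 makes the
#' derived distance maximal, which is what flag-and-keep clustering wants).
#'
#' @param m an [incidence_matrix()]
#' @return object of class `similarity_matrix`: list with `ogus` and the
#'   symmetric `values` matrix in `[0, 1]`
#' @export
jaccard_similarity <- function(m) {
  cells <- m$cells
  if (!nrow(cells) || !ncol(cells)) stop("empty incidence matrix")
  inter <- crossprod(cells)                       # OGU x OGU shared species
  sizes <- colSums(cells)
  uni <- outer(sizes, sizes, "+") - inter
  values <- ifelse(uni > 0, inter / uni, 0)
  empty <- which(uni == 0 & upper.tri(uni), arr.ind = TRUE)
  dimnames(values) <- list(colnames(cells), colnames(cells))
  structure(list(ogus = colnames(cells), values = values),
            class = "similarity_matrix",
            empty_ogus = colnames(cells)[sizes == 0],
            empty_pairs = if (nrow(empty))
              cbind(colnames(cells)[empty[, 1]], colnames(cells)[empty[, 2]])
            else NULL)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d OGUs, mean J = %.3f\n",
              length(x$ogus), mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Write a similarity matrix to CSV
#' @param s a `similarity_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_similarity <- function(s, path) {
  utils::write.csv(s$values, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' UPGMA clustering of OGUs
#'
#' Average-linkage agglomeration on the distance D = 1 - J.  At each step
#' the pair of clusters with the smallest average distance merges; the
#' distance of the merged cluster to any other is the size-weighted
#' arithmetic mean of the parts.  Ties are broken by the lexicographically
#' smallest pair of cluster labels (a cluster is labelled by its smallest
#' member id), so results are identical across platforms.
#'
#' @param s a [jaccard_similarity()] result, or a symmetric distance
#'   matrix if `is_distance = TRUE`
#' @param is_distance set `TRUE` to pass a distance matrix directly
#' @return object of class `zr_dendrogram`: `merge` (hclust convention),
#'   `height` (merge distances), `labels` (leaf ids), `sizes`
#' @export
upgma <- function(s, is_distance = FALSE) {
  D <- if (is_distance) as.matrix(s) else 1 - s$values
  labs <- rownames(D)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 OGUs")
  stopifnot(!is.null(labs))
  # active cluster bookkeeping: id < 0 => leaf -id, id > 0 => merge row
  active <- as.list(seq_len(n))           # member leaf indices
  ids <- -seq_len(n)                      # hclust-style ids
  key <- labs                             # label = smallest member id
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  alive <- rep(TRUE, n)
  D0 <- D
  for (step in seq_len(n - 1L)) {
    idx <- which(alive)
    best <- NULL
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        i <- idx[a]; j <- idx[b]
        d <- D[i, j]
        pair <- sort(c(key[i], key[j]))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (pair[1] < best$pair[1] ||
              (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
          best <- list(i = i, j = j, d = d, pair = pair)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- best$d
    # size-weighted average update, stored in slot i
    for (k in idx) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
    }
    active[[i]] <- c(active[[i]], active[[j]])
    size[i] <- size[i] + size[j]
    key[i] <- min(key[i], key[j])
    ids[i] <- step
    alive[j] <- FALSE
  }
  structure(list(merge = merge, height = height, labels = labs,
                 n = n, distance = D0),
            class = "zr_dendrogram")
}

#' @export
print.zr_dendrogram <- function(x, ...) {
  cat(sprintf("<zr_dendrogram> %d leaves, heights %.3f..%.3f\n",
              x$n, min(x$height), max(x$height)))
  invisible(x)
}

#' Convert to a base hclust object
#' @param d a `zr_dendrogram`
#' @return an object of class `hclust`
#' @export
as_hclust <- function(d) {
  structure(list(merge = d$merge, height = d$height,
                 order = dendro_order(d), labels = d$labels,
                 method = "average", call = match.call(),
                 dist.method = "1 - Jaccard"),
            class = "hclust")
}

dendro_order <- function(d) {
  leaves <- function(id) {
    if (id < 0) return(-id)
    c(leaves(d$merge[id, 1]), leaves(d$merge[id, 2]))
  }
  leaves(d$n - 1L)
}

#' Members below each merge node
#' @param d a `zr_dendrogram`
#' @return list: for each merge row, integer leaf indices
#' @keywords internal
merge_members <- function(d) {
  out <- vector("list", d$n - 1L)
  for (k in seq_len(d$n - 1L)) {
    mem <- integer()
    for (child in d$merge[k, ]) {
      mem <- c(mem, if (child < 0) -child else out[[child]])
    }
    out[[k]] <- mem
  }
  out
}

#' Cophenetic distances of a dendrogram
#'
#' The cophenetic distance of two leaves is the merge height of the
#' smallest cluster containing both.
#'
#' @param d a `zr_dendrogram`
#' @return symmetric numeric matrix with leaf labels
#' @export
cophenetic_distances <- function(d) {
  n <- d$n
  M <- matrix(0, n, n, dimnames = list(d$labels, d$labels))
  mem <- merge_members(d)
  for (k in seq_len(n - 1L)) {
    a <- d$merge[k, 1]; b <- d$merge[k, 2]
    ma <- if (a < 0) -a else mem[[a]]
    mb <- if (b < 0) -b else mem[[b]]
    M[ma, mb] <- d$height[k]
    M[mb, ma] <- d$height[k]
  }
  M
}

#' Export a dendrogram as a Newick string
#'
#' Ultrametric branch lengths: a child hanging from a merge at height h has
#' length (h - h_child) / 2, so every leaf sits at depth h_root / 2 and the
#' cophenetic structure round-trips through standard tree parsers.
#'
#' @param d a `zr_dendrogram`
#' @return Newick string (terminated by ";")
#' @export
to_newick <- function(d) {
  rec <- function(id, parent_h) {
    if (id < 0) {
      sprintf("%s:%g", d$labels[-id], parent_h / 2)
    } else {
      h <- d$height[id]
      sprintf("(%s,%s):%g",
              rec(d$merge[id, 1], h), rec(d$merge[id, 2], h),
              (parent_h - h) / 2)
    }
  }
  root <- d$n - 1L
  h <- d$height[root]
  sprintf("(%s,%s);", rec(d$merge[root, 1], h), rec(d$merge[root, 2], h))
}

#' Rebuild a dendrogram from an ultrametric Newick string
#' @param text Newick string (as produced by [to_newick()])
#' @return a `zr_dendrogram`
#' @export
from_newick <- function(text) {
  phy <- ape::read.tree(text = text)
  # patristic distances of an ultrametric tree are its cophenetic distances;
  # UPGMA on an ultrametric matrix reproduces the tree exactly
  M <- stats::cophenetic(phy)
  ord <- sort(rownames(M))
  upgma(M[ord, ord], is_distance = TRUE)
}
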