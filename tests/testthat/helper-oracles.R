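# shared fixtures and independent oracles

toy_matrix <- function(cells, species = NULL, ogus = NULL) {
  incidence_matrix(cells, species, ogus)
}

# small named incidence matrix from a list of species ranges
matrix_from_ranges <- function(ranges, ogus) {
  cells <- matrix(0L, length(ranges), length(ogus),
                  dimnames = list(names(ranges), ogus))
  for (sp in names(ranges)) cells[sp, ranges[[sp]]] <- 1L
  incidence_matrix(cells)
}

line_graph <- function(ids) {
  adjacency_graph(ids, cbind(ids[-length(ids)], ids[-1]))
}

complete_graph <- function(ids) {
  adjacency_graph(ids, t(utils::combn(ids, 2)))
}

# independent naive O(n^3) size-weighted average-linkage oracle
naive_upgma <- function(D) {
  labs <- rownames(D)
  clusters <- as.list(seq_along(labs))
  sizes <- rep(1, length(labs))
  act <- seq_along(labs)
  merges <- list()
  avg_dist <- function(a, b) {
    mean(D[clusters[[a]], clusters[[b]]])
  }
  while (length(act) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(act)) for (j in seq_len(i - 1)) {
      d <- avg_dist(act[i], act[j])
      if (d < best[1] - 1e-12) best <- c(d, act[j], act[i])
    }
    a <- best[2]; b <- best[3]
    merges[[length(merges) + 1]] <-
      list(members = sort(c(clusters[[a]], clusters[[b]])), height = best[1])
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    act <- setdiff(act, b)
  }
  merges
}

# heights of the naive oracle keyed by member sets
naive_heights <- function(D) {
  m <- naive_upgma(D)
  stats::setNames(
    vapply(m, `[[`, 0, "height"),
    vapply(m, function(x) paste(x$members, collapse = ","), ""))
}

dendro_heights <- function(d) {
  mem <- zooregion:::merge_members(d)
  stats::setNames(
    d$height,
    vapply(mem, function(x) paste(sort(x), collapse = ","), ""))
}

# exhaustive-minimum SSD over all k-partitions of sorted values
exhaustive_jenks_ssd <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  ssd <- function(x) sum((x - mean(x))^2)
  best <- Inf
  # compositions of n into k ordered positive parts
  comp <- function(rem, parts, start) {
    if (parts == 1) {
      idx <- c(start, rem)
      return(idx)
    }
    NULL
  }
  # recursive enumeration
  rec <- function(pos, left, acc) {
    if (left == 1) {
      bounds <- c(acc, n)
      s <- 0; prev <- 0
      for (b in bounds) {
        s <- s + ssd(v[(prev + 1):b]); prev <- b
      }
      best <<- min(best, s)
      return()
    }
    for (b in pos:(n - left + 1)) rec(b + 1, left - 1, c(acc, b))
  }
  rec(1, k, integer())
  best
}

rand_incidence <- function(n_sp, n_ogu, p = 0.4,
                           sp = sprintf("s%02d", seq_len(n_sp)),
                           og = sprintf("O%02d", seq_len(n_ogu))) {
  cells <- matrix(stats::rbinom(n_sp * n_ogu, 1, p), n_sp, n_ogu,
                  dimnames = list(sp, og))
  incidence_matrix(cells)
}
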