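#' Phenon scheme
#'
#' An ordered list of (level name, similarity threshold) pairs.  Levels run
#' from the coarsest (dominion) to the finest (district); thresholds must be
#' strictly increasing, since a deeper rank is cut at a higher similarity.
#'
#' @param thresholds named numeric vector, names from
#'   `c("dominion", "subdominion", "province", "subprovince", "district")`
#'   (other names are allowed but discouraged), values in `[0, 1]`,
#'   strictly increasing
#' @return object of class `phenon_scheme`
#' @export
phenon_scheme <- function(thresholds) {
  if (is.null(names(thresholds)) || any(names(thresholds) == ""))
    stop("thresholds must be named by level")
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]")
  if (length(thresholds) > 1 && any(diff(thresholds) <= 0))
    stop("phenon thresholds must be strictly increasing with level depth")
  structure(list(levels = names(thresholds),
                 thresholds = unname(thresholds)),
            class = "phenon_scheme")
}

#' Propose phenon thresholds from dendrogram height gaps
#'
#' The study drew its phenon lines by eye; for reproducibility this helper
#' proposes `k` cut similarities at the `k` largest gaps between consecutive
#' distinct merge heights, placing each cut at the gap midpoint, and returns
#' them in increasing similarity order under the requested level names.
#'
#' @param d a `zr_dendrogram`
#' @param levels level names, coarsest first
#' @return a [phenon_scheme()]
#' @export
propose_phenon_scheme <- function(d,
                                  levels = c("dominion", "province",
                                             "district")) {
  k <- length(levels)
  h <- sort(unique(round(d$height, 10)), decreasing = TRUE)
  gaps <- h[-length(h)] - h[-1]
  if (length(gaps) < k)
    stop("not enough distinct merge heights for the requested levels")
  # a line in the extreme tails either isolates single units or lumps
  # everything; require a few merges on each side of every cut
  hv <- d$height
  margin <- max(1L, ceiling(0.05 * length(hv)))
  mid <- (h[-length(h)] + h[-1]) / 2
  ok <- vapply(mid, function(cc)
    sum(hv > cc) >= margin && sum(hv < cc) >= margin, TRUE)
  if (sum(ok) < k) ok <- rep(TRUE, length(gaps))
  gaps[!ok] <- -Inf
  pick <- order(gaps, decreasing = TRUE)[seq_len(k)]
  cuts <- (h[pick] + h[pick + 1]) / 2         # cut heights inside the gaps
  sims <- sort(1 - cuts)                      # increasing similarity
  phenon_scheme(stats::setNames(sims, levels))
}

#' Cut a dendrogram at a phenon (similarity) line
#'
#' Clusters are the maximal subtrees whose root merge similarity
#' (1 - height) is at least `threshold`.
#'
#' @param d a `zr_dendrogram`
#' @param threshold similarity in `[0, 1]`
#' @return named list of character vectors (cluster id -> member OGU ids),
#'   in order of first member
#' @export
cut_phenon <- function(d, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  hmax <- 1 - threshold + 1e-12
  n <- d$n
  grp <- seq_len(n)
  mem <- merge_members(d)
  for (k in seq_len(n - 1L)) {
    if (d$height[k] <= hmax) grp[mem[[k]]] <- n + k
  }
  parts <- split(d$labels, grp)
  parts <- parts[order(vapply(parts, function(p) min(match(p, d$labels)),
                              1L))]
  names(parts) <- sprintf("C%02d", seq_along(parts))
  parts
}

#' Split clusters into contiguous cores and orphan OGUs
#'
#' Each cluster is decomposed into the connected components it induces on
#' the adjacency graph.  The largest component is the cluster's core (ties
#' broken by total species count, then by smallest member label); OGUs in
#' all other components become orphans.
#'
#' @param partition named list of OGU-id vectors
#' @param g an [adjacency_graph()]
#' @param m optional [incidence_matrix()] used for the species-count
#'   tie-break
#' @return list with `cores` (named list of OGU-id vectors) and `orphans`
#'   (character vector)
#' @export
enforce_contiguity <- function(partition, g, m = NULL) {
  cores <- list()
  orphans <- character()
  for (nm in names(partition)) {
    comps <- induced_components(g, partition[[nm]])
    if (length(comps) == 1L) {
      cores[[nm]] <- sort(comps[[1]])
      next
    }
    sizes <- lengths(comps)
    nsp <- vapply(comps, function(cp) {
      if (is.null(m)) 0L else sum(m$cells[, cp, drop = FALSE])
    }, 0L)
    minlab <- vapply(comps, min, "")
    ord <- order(-sizes, -nsp, minlab)
    cores[[nm]] <- sort(comps[[ord[1]]])
    orphans <- c(orphans, unlist(comps[ord[-1]], use.names = FALSE))
  }
  list(cores = cores, orphans = sort(orphans))
}

#' Dissolve orphan OGUs into cores
#'
#' Each orphan joins, among the cores containing one of its graph
#' neighbours (geographic nearness), the one with the highest mean Jaccard
#' similarity between the orphan and the core members (ecological
#' closeness).  Orphans with no core neighbour are assigned by hop
#' distance, similarity breaking ties.  Assignments are recorded as
#' `dissolved`, never as clustering evidence.  Orphans whose only
#' neighbours are other orphans are resolved iteratively once those join a
#' core.
#'
#' @param orphans character vector of OGU ids
#' @param cores named list of OGU-id vectors
#' @param g an [adjacency_graph()]
#' @param s a [jaccard_similarity()] result
#' @return named list: per core, `members` (core) and `dissolved`
#' @export
dissolve_orphans <- function(orphans, cores, g, s) {
  assigned <- stats::setNames(vector("list", length(cores)), names(cores))
  for (nm in names(cores)) assigned[[nm]] <- character()
  region_of <- stats::setNames(rep(names(cores), lengths(cores)),
                               unlist(cores))
  pending <- sort(orphans)
  mean_sim <- function(o, members)
    mean(s$values[o, setdiff(members, o)])
  while (length(pending)) {
    placed <- character()
    for (o in pending) {
      nb <- ogu_neighbors(g, o)
      cand <- unique(region_of[intersect(nb, names(region_of))])
      if (!length(cand)) next
      sims <- vapply(cand, function(r)
        mean_sim(o, c(cores[[r]], assigned[[r]])), 0)
      best <- cand[order(-sims, cand)][1]
      assigned[[best]] <- c(assigned[[best]], o)
      region_of[o] <- best
      placed <- c(placed, o)
    }
    if (!length(placed)) break
    pending <- setdiff(pending, placed)
  }
  if (length(pending)) {
    # no path through already-assigned units: fall back to hop distance
    for (o in pending) {
      targets <- vapply(names(cores), function(r)
        min(hop_distances(g, o, c(cores[[r]], assigned[[r]]))), 0)
      if (all(!is.finite(targets)))
        stop(sprintf("orphan OGU '%s' has no path to any core", o))
      cand <- names(cores)[targets == min(targets)]
      sims <- vapply(cand, function(r)
        mean_sim(o, c(cores[[r]], assigned[[r]])), 0)
      best <- cand[order(-sims, cand)][1]
      assigned[[best]] <- c(assigned[[best]], o)
      region_of[o] <- best
    }
  }
  lapply(stats::setNames(names(cores), names(cores)), function(r)
    list(members = cores[[r]], dissolved = sort(assigned[[r]])))
}

#' Build a nested, contiguous regionalisation
#'
#' For each level of the phenon scheme, the dendrogram is cut at the
#' level's similarity, the cut is intersected with each parent region
#' (top-down nesting), contiguity is enforced on the adjacency graph, and
#' orphans are dissolved into the geographically nearest, ecologically
#' closest core of the same parent.
#'
#' @param d a `zr_dendrogram`
#' @param scheme a [phenon_scheme()]
#' @param g an [adjacency_graph()]
#' @param s a [jaccard_similarity()] result
#' @param m optional [incidence_matrix()] for contiguity tie-breaks
#' @return object of class `region_hierarchy`: list of levels, each a named
#'   list of regions with `members` (all OGUs incl. dissolved), `core`,
#'   `dissolved`, `parent`
#' @export
build_hierarchy <- function(d, scheme, g, s, m = NULL) {
  stopifnot(inherits(scheme, "phenon_scheme"))
  levels_out <- list()
  parents <- list(ROOT = list(members = d$labels, core = d$labels,
                              dissolved = character(), parent = NA))
  for (li in seq_along(scheme$levels)) {
    lev <- scheme$levels[li]
    thr <- scheme$thresholds[li]
    cut <- cut_phenon(d, thr)
    regions <- list()
    idx <- 0L
    for (pname in names(parents)) {
      pmem <- parents[[pname]]$members
      sub <- lapply(cut, intersect, pmem)
      sub <- sub[lengths(sub) > 0]
      if (!length(sub)) next
      names(sub) <- sprintf("tmp%02d", seq_along(sub))
      ec <- enforce_contiguity(sub, g, m)
      frag <- dissolve_orphans(ec$orphans, ec$cores, g, s)
      for (rn in names(frag)) {
        idx <- idx + 1L
        nm <- sprintf("%s_%02d", lev, idx)
        regions[[nm]] <- list(
          members = sort(c(frag[[rn]]$members, frag[[rn]]$dissolved)),
          core = frag[[rn]]$members,
          dissolved = frag[[rn]]$dissolved,
          parent = pname)
      }
    }
    levels_out[[lev]] <- regions
    parents <- regions
  }
  structure(list(levels = levels_out, scheme = scheme),
            class = "region_hierarchy")
}

#' @export
print.region_hierarchy <- function(x, ...) {
  for (lev in names(x$levels))
    cat(sprintf("%-12s %d region(s)\n", lev, length(x$levels[[lev]])))
  invisible(x)
}

#' Flat membership table of a hierarchy level
#' @param h a `region_hierarchy`
#' @param level level name (default: the finest level)
#' @return named character vector OGU -> region name
#' @export
level_partition <- function(h, level = NULL) {
  if (is.null(level)) level <- utils::tail(names(h$levels), 1)
  regs <- h$levels[[level]]
  stats::setNames(rep(names(regs), vapply(regs, function(r)
    length(r$members), 0L)),
    unlist(lapply(regs, `[[`, "members")))
}

#' Write a hierarchy report TSV
#' @param h a `region_hierarchy`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_hierarchy <- function(h, path) {
  rows <- do.call(rbind, lapply(names(h$levels), function(lev) {
    regs <- h$levels[[lev]]
    do.call(rbind, lapply(names(regs), function(nm) {
      data.frame(level = lev, region = nm,
                 members = paste(regs[[nm]]$members, collapse = ","),
                 dissolved = paste(regs[[nm]]$dissolved, collapse = ","),
                 parent = regs[[nm]]$parent,
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Adjusted Rand index between two labelings
#'
#' Used to compare a recovered partition with planted truth.
#'
#' @param a,b label vectors of equal length (any atomic type)
#' @return numeric scalar in `[-1, 1]`, 1 iff identical partitions
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
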