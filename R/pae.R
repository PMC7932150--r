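#' Prepare a PAE matrix
#'
#' Parsimony analysis of endemicity treats OGUs as taxa and species as
#' binary characters.  Empty OGUs are dropped (they behave like redundant
#' outgroups), constant characters and single-OGU characters
#' (autapomorphies) are removed, and an all-zero hypothetical root taxon
#' `ROOT` is appended to root the area cladogram, following standard PAE
#' practice.  Removed singleton species are kept in the report so they can
#' be reconsidered during AOE extraction.
#'
#' @param m an [incidence_matrix()]
#' @return object of class `pae_matrix`: `taxa` (OGU ids + "ROOT"),
#'   `characters` (species ids), `cells` (taxa x characters 0/1),
#'   `report` (`empty_ogus`, `constant_species`, `singleton_species` with
#'   their OGU)
#' @export
prepare_pae_matrix <- function(m) {
  pr <- prune_matrix(m, drop_empty_ogus = TRUE,
                     drop_uninformative_species = TRUE)
  cells <- t(pr$matrix$cells)                  # OGU x species
  if (nrow(cells) < 4)
    stop(sprintf("only %d informative OGUs remain; need at least 4",
                 nrow(cells)))
  singles <- pr$report$singleton_species
  single_ogu <- vapply(singles, function(sp) species_range(m, sp), "")
  cells <- rbind(cells, ROOT = 0L)
  structure(list(taxa = rownames(cells), characters = colnames(cells),
                 cells = cells,
                 report = list(empty_ogus = pr$report$empty_ogus,
                               constant_species = pr$report$constant_species,
                               singleton_species = single_ogu)),
            class = "pae_matrix")
}

#' @export
print.pae_matrix <- function(x, ...) {
  cat(sprintf("<pae_matrix> %d taxa (incl. ROOT) x %d characters\n",
              length(x$taxa), length(x$characters)))
  invisible(x)
}

#' Export a PAE matrix as NEXUS
#' @param pm a `pae_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pae_nexus <- function(pm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                       length(pm$taxa), length(pm$characters)),
               "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
               "  MATRIX"), con)
  for (i in seq_along(pm$taxa))
    writeLines(sprintf("    %-12s %s", pm$taxa[i],
                       paste(pm$cells[i, ], collapse = "")), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}

# ---- internal unrooted-tree machinery -------------------------------------
# A search tree is list(edge = E x 2 integer matrix of node ids, n_tip).
# Leaves are 1..n_tip (indexing pm$taxa); internal nodes are n_tip+1 ...
# Unrooted binary: internal degree 3, E = 2 n - 3.

tree_adjacency <- function(edge, n_nodes) {
  adj <- vector("list", n_nodes)
  for (r in seq_len(nrow(edge))) {
    a <- edge[r, 1]; b <- edge[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Fitch parsimony steps of an unrooted binary tree.
# X: n_tip x n_char matrix of state codes (1 = {0}, 2 = {1}).
fitch_steps <- function(edge, n_tip, X) {
  n_nodes <- max(edge)
  adj <- tree_adjacency(edge, n_nodes)
  root <- 1L                                   # traverse from leaf 1
  parent <- integer(n_nodes)
  order <- integer(n_nodes)
  order[1] <- root; parent[root] <- 0L
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- order[head]; head <- head + 1L
    for (w in adj[[v]]) {
      if (w == parent[v]) next
      parent[w] <- v
      tail <- tail + 1L
      order[tail] <- w
    }
  }
  S <- matrix(0L, n_nodes, ncol(X))
  S[seq_len(n_tip), ] <- X
  cnt <- 0L
  for (v in order[n_nodes:1]) {
    if (v <= n_tip) next
    kids <- adj[[v]][adj[[v]] != parent[v]]
    a <- S[kids[1], ]; b <- S[kids[2], ]
    inter <- bitwAnd(a, b)
    z <- inter == 0L
    cnt <- cnt + sum(z)
    inter[z] <- bitwOr(a[z], b[z])
    S[v, ] <- inter
  }
  v <- adj[[root]][1]                          # close the root edge
  cnt + sum(bitwAnd(S[root, ], S[v, ]) == 0L)
}

state_codes <- function(pm) {
  X <- pm$cells + 1L
  storage.mode(X) <- "integer"
  X
}

# split an unrooted tree at edge ei; returns the two parts with their
# attachment information (either a lone leaf or an edge list with the
# suppressed node id available for reuse)
split_at_edge <- function(tree, ei) {
  e <- tree$edge[ei, ]
  rem <- tree$edge[-ei, , drop = FALSE]
  n_nodes <- max(tree$edge)
  adj <- tree_adjacency(rem, n_nodes)
  part_of <- function(start) {
    seen <- logical(n_nodes)
    stack <- start; seen[start] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
    }
    which(seen)
  }
  mk_part <- function(p) {
    nodes <- part_of(p)
    edges <- rem[rem[, 1] %in% nodes, , drop = FALSE]
    if (length(nodes) == 1L)
      return(list(single = p, edges = NULL, spare = NULL))
    # suppress p (now degree 2)
    inc <- which(edges[, 1] == p | edges[, 2] == p)
    if (length(inc) == 2L) {
      x <- setdiff(edges[inc[1], ], p)
      y <- setdiff(edges[inc[2], ], p)
      edges <- rbind(edges[-inc, , drop = FALSE], c(x, y))
      list(single = NULL, edges = edges, spare = p)
    } else {
      # p is a leaf inside a larger part (edge was internal on other side)
      list(single = NULL, edges = edges, spare = NULL)
    }
  }
  list(a = mk_part(e[1]), b = mk_part(e[2]))
}

# reattach: subdivide edge `at` of part using node id `spare`, or return the
# lone leaf id; gives (edges, attach_node)
attach_part <- function(part, at) {
  if (!is.null(part$single))
    return(list(edges = NULL, node = part$single))
  edge <- part$edges[at, ]
  edges <- part$edges[-at, , drop = FALSE]
  edges <- rbind(edges, c(edge[1], part$spare), c(part$spare, edge[2]))
  list(edges = edges, node = part$spare)
}

# Directed-edge Fitch views of a tree-like edge set: for every edge, the
# Fitch state sets and subtree step totals of both sides, combined into the
# per-edge "rooted here" step base `b` and root state vector `R`.  This is
# the classic two-pass trick that lets a whole TBR neighbourhood be scored
# without rebuilding any candidate tree: joining attachment edges f1, f2 of
# the two bisection parts costs b1 + b2 + #(chars whose root states are
# disjoint).
edge_views <- function(edges, n_tip, X) {
  nmax <- max(edges)
  nch <- ncol(X)
  adj <- vector("list", nmax)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  nodes <- sort(unique(as.vector(edges)))
  deg <- lengths(adj)
  root <- nodes[deg[nodes] == 1L & nodes <= n_tip][1]
  parent <- integer(nmax); order <- integer(length(nodes))
  order[1] <- root; head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- order[head]; head <- head + 1L
    for (w in adj[[v]]) if (w != parent[v]) {
      parent[w] <- v; tail <- tail + 1L; order[tail] <- w
    }
  }
  D <- matrix(0L, nmax, nch); cD <- numeric(nmax)
  U <- matrix(0L, nmax, nch); cU <- numeric(nmax)
  children <- vector("list", nmax)
  for (v in nodes) if (v != root) {
    p <- parent[v]
    children[[p]] <- c(children[[p]], v)
  }
  for (v in order[length(nodes):1]) {
    if (v == root) next
    k <- children[[v]]
    if (!length(k)) {
      D[v, ] <- X[v, ]
    } else {
      inter <- bitwAnd(D[k[1], ], D[k[2], ])
      z <- inter == 0L
      inter[z] <- bitwOr(D[k[1], z], D[k[2], z])
      D[v, ] <- inter
      cD[v] <- cD[k[1]] + cD[k[2]] + sum(z)
    }
  }
  for (v in order[-1]) {
    p <- parent[v]
    if (p == root) {
      U[v, ] <- X[root, ]
      cU[v] <- 0
    } else {
      s <- children[[p]][children[[p]] != v]
      inter <- bitwAnd(U[p, ], D[s, ])
      z <- inter == 0L
      inter[z] <- bitwOr(U[p, z], D[s, z])
      U[v, ] <- inter
      cU[v] <- cU[p] + cD[s] + sum(z)
    }
  }
  b <- numeric(nrow(edges))
  R <- matrix(0L, nrow(edges), nch)
  for (r in seq_len(nrow(edges))) {
    v <- if (parent[edges[r, 2]] == edges[r, 1]) edges[r, 2] else edges[r, 1]
    inter <- bitwAnd(D[v, ], U[v, ])
    z <- inter == 0L
    inter[z] <- bitwOr(D[v, z], U[v, z])
    R[r, ] <- inter
    b[r] <- cD[v] + cU[v] + sum(z)
  }
  list(b = b, R = R)
}

part_views <- function(part, X) {
  if (!is.null(part$single))
    return(list(b = 0, R = X[part$single, , drop = FALSE], single = TRUE))
  n_tip <- nrow(X)
  v <- edge_views(part$edges, n_tip, X)
  v$single <- FALSE
  v
}

# best TBR move over the whole neighbourhood, by two-pass scoring
scan_tbr <- function(tree, X, collect_len = NA, max_collect = 0L) {
  best <- list(len = Inf)
  ties <- list()
  for (ei in seq_len(nrow(tree$edge))) {
    sp <- split_at_edge(tree, ei)
    va <- part_views(sp$a, X)
    vb <- part_views(sp$b, X)
    BT <- t(vb$R)
    nb <- nrow(vb$R)
    for (i in seq_len(nrow(va$R))) {
      ev <- colSums(matrix(bitwAnd(as.vector(BT), va$R[i, ]),
                           nrow = nrow(BT)) == 0L)
      lens <- va$b[i] + vb$b + ev
      j <- which.min(lens)
      if (lens[j] < best$len)
        best <- list(len = lens[j], ei = ei, i = i, j = j)
      if (!is.na(collect_len) && length(ties) < max_collect) {
        for (jj in which(lens == collect_len))
          ties[[length(ties) + 1L]] <- c(ei, i, jj)
      }
    }
  }
  best$ties <- ties
  best
}

rebuild_tbr <- function(tree, ei, i, j) {
  sp <- split_at_edge(tree, ei)
  pa <- attach_part(sp$a, i)
  pb <- attach_part(sp$b, j)
  list(edge = rbind(pa$edges, pb$edges, c(pa$node, pb$node)),
       n_tip = tree$n_tip)
}

tbr_candidates <- function(tree, ei) {
  sp <- split_at_edge(tree, ei)
  na <- if (is.null(sp$a$single)) nrow(sp$a$edges) else 1L
  nb <- if (is.null(sp$b$single)) nrow(sp$b$edges) else 1L
  out <- vector("list", na * nb)
  k <- 0L
  for (i in seq_len(na)) {
    pa <- attach_part(sp$a, i)
    for (j in seq_len(nb)) {
      pb <- attach_part(sp$b, j)
      k <- k + 1L
      out[[k]] <- list(edge = rbind(pa$edges, pb$edges, c(pa$node, pb$node)),
                       n_tip = tree$n_tip)
    }
  }
  out
}

# canonical key: sorted non-trivial splits (side not containing leaf 1)
tree_key <- function(tree) {
  n_tip <- tree$n_tip
  n_nodes <- max(tree$edge)
  adj <- tree_adjacency(tree$edge, n_nodes)
  parent <- integer(n_nodes); order <- integer(n_nodes)
  order[1] <- 1L
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- order[head]; head <- head + 1L
    for (w in adj[[v]]) if (w != parent[v]) {
      parent[w] <- v; tail <- tail + 1L; order[tail] <- w
    }
  }
  below <- vector("list", n_nodes)
  for (v in order[n_nodes:1]) {
    below[[v]] <- if (v <= n_tip) v else
      sort(unlist(lapply(adj[[v]][adj[[v]] != parent[v]], function(w)
        below[[w]])))
  }
  splits <- vapply(setdiff(order, 1L), function(v) {
    s <- below[[v]]
    if (length(s) <= 1L || length(s) >= n_tip - 1L) ""
    else paste(s, collapse = ",")
  }, "")
  paste(sort(unique(splits[splits != ""])), collapse = ";")
}

# stepwise random addition under Fitch (two-pass scored insertions)
random_addition_tree <- function(pm, X, order_taxa) {
  n <- length(pm$taxa)
  root_i <- match("ROOT", pm$taxa)
  first <- c(root_i, order_taxa[1:2])
  nxt <- n + 1L
  tree <- list(edge = rbind(c(first[1], nxt), c(first[2], nxt),
                            c(first[3], nxt)), n_tip = n)
  nxt <- nxt + 1L
  for (tx in order_taxa[-(1:2)]) {
    vw <- edge_views(tree$edge, n, X)
    ev <- colSums(matrix(bitwAnd(as.vector(t(vw$R)), X[tx, ]),
                         nrow = ncol(X)) == 0L)
    lens <- vw$b + ev
    ei <- which.min(lens)
    e <- tree$edge[ei, ]
    tree <- list(edge = rbind(tree$edge[-ei, , drop = FALSE],
                              c(e[1], nxt), c(nxt, e[2]), c(tx, nxt)),
                 n_tip = n)
    nxt <- nxt + 1L
  }
  tree
}

#' Fitch parsimony length of a tree
#'
#' Sum over characters of the Fitch (unordered, binary) step counts.
#'
#' @param tree an `ape::phylo` tree (binary; rooted or unrooted) whose tip
#'   labels equal the PAE matrix taxa
#' @param pm a [prepare_pae_matrix()] result
#' @return integer parsimony length
#' @export
fitch_length <- function(tree, pm) {
  if (!setequal(tree$tip.label, pm$taxa))
    stop("tree leaf set does not match PAE matrix taxa")
  utree <- ape::unroot(tree)
  if (!ape::is.binary(utree)) stop("tree must be binary")
  n <- length(pm$taxa)
  # map ape node ids onto search ids (tips reindexed to pm$taxa order)
  tipmap <- match(utree$tip.label, pm$taxa)
  edge <- utree$edge
  relab <- function(v) ifelse(v <= n, tipmap[v], v)
  edge <- cbind(relab(edge[, 1]), relab(edge[, 2]))
  fitch_steps(edge, n, state_codes(pm))
}

search_tree_to_phylo <- function(tree, taxa) {
  root_i <- match("ROOT", taxa)
  n_nodes <- max(tree$edge)
  adj <- tree_adjacency(tree$edge, n_nodes)
  rec <- function(v, from) {
    if (v <= tree$n_tip) return(taxa[v])
    kids <- adj[[v]][adj[[v]] != from]
    sprintf("(%s)", paste(vapply(kids, rec, "", from = v), collapse = ","))
  }
  v <- adj[[root_i]][1]
  txt <- sprintf("(%s,%s);", taxa[root_i], rec(v, root_i))
  ape::read.tree(text = txt)
}

#' Heuristic most-parsimonious tree search
#'
#' Random-addition starting trees followed by tree-bisection-reconnection
#' (TBR) branch swapping to a local optimum, per replicate; the pool of
#' equally most-parsimonious trees found across replicates is returned, up
#' to `max_trees`.  Deterministic given `seed`.
#'
#' @param pm a [prepare_pae_matrix()] result
#' @param n_replicates random-addition replicates (default 5)
#' @param seed integer seed
#' @param max_trees cap on the returned tree pool (default 1000)
#' @param max_rounds cap on TBR improvement rounds per replicate
#' @return object of class `pae_search`: `trees` (`multiPhylo`, rooted at
#'   ROOT), `length` (best Fitch length), `n_found`
#' @export
heuristic_search <- function(pm, n_replicates = 5, seed = 1,
                             max_trees = 1000, max_rounds = 30) {
  X <- state_codes(pm)
  n <- length(pm$taxa)
  root_i <- match("ROOT", pm$taxa)
  pool <- list(); pool_keys <- character(); pool_len <- Inf
  add_pool <- function(tree, len) {
    if (len > pool_len) return()
    if (len < pool_len) { pool <<- list(); pool_keys <<- character()
      pool_len <<- len }
    if (length(pool) >= max_trees) return()
    key <- tree_key(tree)
    if (key %in% pool_keys) return()
    pool[[length(pool) + 1L]] <<- tree
    pool_keys <<- c(pool_keys, key)
  }
  for (rep in seq_len(n_replicates)) {
    set.seed(seed + rep)
    ord <- sample(setdiff(seq_len(n), root_i))
    tree <- random_addition_tree(pm, X, ord)
    len <- fitch_steps(tree$edge, n, X)
    for (round in seq_len(max_rounds)) {
      mv <- scan_tbr(tree, X)
      if (mv$len >= len) break
      tree <- rebuild_tbr(tree, mv$ei, mv$i, mv$j)
      len <- mv$len
    }
    # local optimum: harvest equally parsimonious neighbours
    add_pool(tree, len)
    if (len <= pool_len && length(pool) < max_trees) {
      mv <- scan_tbr(tree, X, collect_len = pool_len,
                     max_collect = 4L * max_trees)
      for (tie in mv$ties) {
        if (length(pool) >= max_trees) break
        add_pool(rebuild_tbr(tree, tie[1], tie[2], tie[3]), pool_len)
      }
    }
  }
  trees <- lapply(pool, search_tree_to_phylo, taxa = pm$taxa)
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, length = pool_len, n_found = length(trees)),
            class = "pae_search")
}

#' @export
print.pae_search <- function(x, ...) {
  cat(sprintf("<pae_search> %d tree(s) of length %d\n", x$n_found, x$length))
  invisible(x)
}

#' Strict consensus of a tree pool
#'
#' Retains exactly the clades present in every input tree.
#'
#' @param trees a `multiPhylo` (or list of `phylo`) with identical leaf sets
#' @return a `phylo` consensus tree rooted at ROOT if present
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("no trees given")
  tips <- trees[[1]]$tip.label
  same <- vapply(trees, function(t) setequal(t$tip.label, tips), TRUE)
  if (!all(same)) stop("trees have differing leaf sets")
  if (length(trees) == 1L) return(trees[[1]])
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1, rooted = TRUE)
}

#' Extract areas of endemism from a consensus area cladogram
#'
#' Clades (excluding ROOT) that are geographically contiguous and supported
#' by at least `min_support` species endemic to the clade, with at least one
#' pair of supporting species co-occurring in a member OGU (sympatry at the
#' OGU grain), become AOEs.  Additionally, single OGUs holding at least
#' `min_support` of the singleton species removed during matrix preparation
#' become singleton AOEs.
#'
#' @param consensus a `phylo` over OGU taxa (plus ROOT)
#' @param m the full (unpruned) [incidence_matrix()]
#' @param g an [adjacency_graph()]
#' @param singleton_report named character vector species -> OGU from
#'   [prepare_pae_matrix()]'s report
#' @param min_support minimum supporting endemics (default 2)
#' @param nested `"minimal"` (default) keeps only qualifying clades with no
#'   qualifying proper descendant; in a well-resolved consensus every union
#'   of qualifying clades also "harbours" their endemics, but no two
#'   species are congruent with the union, so such unions are not areas of
#'   endemism.  `"all"` keeps every qualifying clade.
#' @return object of class `aoe_set`: list of AOEs with `members`,
#'   `species`, `provenance`
#' @export
extract_aoes <- function(consensus, m, g, singleton_report = character(),
                         min_support = 2, nested = c("minimal", "all")) {
  nested <- match.arg(nested)
  tips <- setdiff(consensus$tip.label, "ROOT")
  parts <- ape::prop.part(consensus)
  labels <- attr(parts, "labels")
  aoes <- list()
  seen <- character()
  qualify <- function(members) {
    comps <- induced_components(g, members)
    if (length(comps) > 1L) return(NULL)
    cl <- classify_endemics(m, members)
    endem <- cl$status$species_id[cl$status$status == "endemic"]
    if (length(endem) < min_support) return(NULL)
    sub <- m$cells[endem, members, drop = FALSE]
    if (!any(colSums(sub) >= 2)) return(NULL)   # sympatry at OGU grain
    endem
  }
  consider <- function(members, provenance, species = NULL) {
    key <- paste(sort(members), collapse = ",")
    if (key %in% seen) return()
    if (is.null(species)) species <- qualify(members)
    if (is.null(species)) return()
    seen <<- c(seen, key)
    aoes[[length(aoes) + 1L]] <<- list(members = sort(members),
                                       species = species,
                                       provenance = provenance)
  }
  clades <- Filter(function(mem)
    length(mem) >= 2L && length(mem) < length(tips),
    lapply(parts, function(p) setdiff(labels[p], "ROOT")))
  support <- lapply(clades, qualify)
  ok <- !vapply(support, is.null, TRUE)
  clades <- clades[ok]; support <- support[ok]
  if (nested == "minimal" && length(clades)) {
    has_desc <- vapply(seq_along(clades), function(i)
      any(vapply(seq_along(clades), function(j)
        j != i && all(clades[[j]] %in% clades[[i]]), TRUE)), TRUE)
    clades <- clades[!has_desc]; support <- support[!has_desc]
  }
  for (i in seq_along(clades))
    consider(clades[[i]], "consensus_clade", support[[i]])
  if (length(singleton_report)) {
    for (og in unique(singleton_report)) {
      sp <- names(singleton_report)[singleton_report == og]
      if (length(sp) >= min_support) {
        key <- og
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          aoes[[length(aoes) + 1L]] <- list(members = og, species = sp,
                                            provenance = "singleton_ogu")
        }
      }
    }
  }
  structure(list(aoes = aoes), class = "aoe_set")
}

#' @export
print.aoe_set <- function(x, ...) {
  cat(sprintf("<aoe_set> %d AOE(s)\n", length(x$aoes)))
  for (a in x$aoes)
    cat(sprintf("  [%s] %d species (%s)\n",
                paste(a$members, collapse = ","), length(a$species),
                a$provenance))
  invisible(x)
}
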