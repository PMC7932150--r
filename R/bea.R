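#' Pairwise range distances between species
#'
#' Distances between species' occupied-OGU sets.  The Kulczynski distance
#' d(A,B) = 1 - (|A∩B|/|A| + |A∩B|/|B|) / 2 is the default (the
#' convention of biotic element analysis); Jaccard d = 1 - |A∩B|/|A∪B| is
#' available for sensitivity analysis.
#'
#' @param m an [incidence_matrix()]
#' @param metric `"kulczynski"` (default) or `"jaccard"`
#' @return object of class `range_distance_matrix`: `species`, symmetric
#'   `values` in `[0, 1]`, `metric`
#' @export
range_distance <- function(m, metric = c("kulczynski", "jaccard")) {
  metric <- match.arg(metric)
  cells <- m$cells
  sizes <- rowSums(cells)
  if (any(sizes == 0))
    stop(sprintf("species with empty range: %s",
                 paste(rownames(cells)[sizes == 0], collapse = ", ")))
  inter <- tcrossprod(cells)
  values <- if (metric == "kulczynski") {
    1 - (inter / sizes + t(inter / sizes)) / 2
  } else {
    uni <- outer(sizes, sizes, "+") - inter
    1 - inter / uni
  }
  diag(values) <- 0
  dimnames(values) <- list(rownames(cells), rownames(cells))
  structure(list(species = rownames(cells), values = values,
                 metric = metric),
            class = "range_distance_matrix")
}

#' @export
print.range_distance_matrix <- function(x, ...) {
  cat(sprintf("<range_distance_matrix> %d species, %s\n",
              length(x$species), x$metric))
  invisible(x)
}

#' The distratio clustering statistic
#'
#' t = mean of the smallest `ceiling(prop * N)` pairwise distances divided
#' by the mean of the largest `ceiling(prop * N)`, over the N off-diagonal
#' distances.  Clustered range sets produce many small and many large
#' distances, hence small t; t = 1 when all distances are equal.
#'
#' @param d a [range_distance()] result (or a numeric distance vector)
#' @param prop fraction of distances in each tail (default 0.25)
#' @return numeric statistic in `(0, 1]`
#' @export
distratio <- function(d, prop = 0.25) {
  stopifnot(prop > 0, prop <= 0.5)
  dv <- if (inherits(d, "range_distance_matrix"))
    d$values[lower.tri(d$values)] else as.numeric(d)
  if (length(dv) < ceiling(1 / prop))
    stop("too few pairwise distances for the requested prop")
  if (all(dv == 0)) stop("all distances are zero; distratio undefined")
  k <- ceiling(prop * length(dv))
  s <- sort(dv)
  mean(s[seq_len(k)]) / mean(s[seq.int(length(s) - k + 1L, length(s))])
}

grow_connected_range <- function(g, size, nodes, adj) {
  cur <- sample.int(length(nodes), 1L)
  members <- cur
  if (size > 1L) {
    in_range <- logical(length(nodes))
    in_range[cur] <- TRUE
    frontier <- adj[[cur]][!in_range[adj[[cur]]]]
    while (length(members) < size) {
      pick <- frontier[sample.int(length(frontier), 1L)]
      members <- c(members, pick)
      in_range[pick] <- TRUE
      frontier <- unique(c(frontier, adj[[pick]]))
      frontier <- frontier[!in_range[frontier]]
      if (!length(frontier)) break
    }
  }
  nodes[members]
}

#' Simulate null incidence matrices with spatially autocorrelated ranges
#'
#' The null model of the clustering test: each replicate keeps the observed
#' multiset of range sizes exactly, but regrows every range as a connected
#' set on the adjacency graph, starting from a uniform random OGU and
#' expanding to uniform random frontier neighbours.  Ranges are therefore
#' spatially autocorrelated but placed independently of each other.
#'
#' @param m an [incidence_matrix()]
#' @param g an [adjacency_graph()] covering (at least) the matrix OGUs,
#'   connected
#' @param n_sim number of replicates
#' @param seed integer seed
#' @return list of [incidence_matrix()] replicates
#' @export
simulate_null_ranges <- function(m, g, n_sim, seed) {
  nodes <- ogu_ids(m)
  miss <- setdiff(nodes, x_nodes(g))
  if (length(miss))
    stop(sprintf("OGU(s) missing from graph: %s", paste(miss, collapse = ", ")))
  if (igraph::components(
        igraph::induced_subgraph(g$graph, nodes))$no != 1L)
    stop("adjacency graph must be connected over the matrix OGUs")
  sizes <- rowSums(m$cells)
  if (any(sizes > length(nodes)))
    stop("range size exceeds number of OGUs")
  idx <- lapply(nodes, function(v)
    match(names(igraph::neighbors(g$graph, v)), nodes))
  idx <- lapply(idx, function(v) v[!is.na(v)])
  set.seed(seed)
  lapply(seq_len(n_sim), function(b) {
    cells <- matrix(0L, nrow(m$cells), ncol(m$cells),
                    dimnames = dimnames(m$cells))
    for (i in seq_len(nrow(cells))) {
      if (sizes[i] == 0L) next
      rng <- grow_connected_range(g, sizes[i], nodes, idx)
      cells[i, rng] <- 1L
    }
    incidence_matrix(cells)
  })
}

#' Monte-Carlo test for clustering of distribution ranges
#'
#' Computes the observed distratio statistic and its null distribution
#' under [simulate_null_ranges()]; the one-sided p-value for small t uses
#' the (1 + B) / (1 + n) correction, so it can never be exactly zero.
#'
#' @param m an [incidence_matrix()]
#' @param g an [adjacency_graph()]
#' @param n_sim null replicates (default 1000)
#' @param seed integer seed
#' @param prop tail fraction for [distratio()] (default 0.25)
#' @param metric range distance metric (default `"kulczynski"`)
#' @return object of class `clustering_test`: `t_observed`, `t_simulated`,
#'   `p_value`, `n_sim`, `prop`, `metric`
#' @export
clustering_test <- function(m, g, n_sim = 1000, seed = 1, prop = 0.25,
                            metric = "kulczynski") {
  t_obs <- distratio(range_distance(m, metric), prop)
  sims <- simulate_null_ranges(m, g, n_sim, seed)
  t_sim <- vapply(sims, function(s)
    distratio(range_distance(s, metric), prop), 0)
  p <- (1 + sum(t_sim <= t_obs)) / (1 + n_sim)
  structure(list(t_observed = t_obs, t_simulated = t_sim, p_value = p,
                 n_sim = n_sim, prop = prop, metric = metric),
            class = "clustering_test")
}

#' @export
print.clustering_test <- function(x, ...) {
  cat(sprintf("Clustering test: t = %.3f (null mean %.3f, range %.3f-%.3f), p = %.3g\n",
              x$t_observed, mean(x$t_simulated), min(x$t_simulated),
              max(x$t_simulated), x$p_value))
  invisible(x)
}

#' Nonmetric multidimensional scaling of range distances
#'
#' Kruskal stress-1 NMDS via iterative majorization with monotone
#' regression (vegan's `monoMDS` engine), best of `n_restarts` random
#' starts; deterministic given `seed`.
#'
#' @param d a [range_distance()] result
#' @param dims embedding dimensions (default 2)
#' @param n_restarts random restarts (default 8)
#' @param seed integer seed
#' @return list: `coords` (species x dims), `stress` (Kruskal stress-1,
#'   in `[0, 1]`)
#' @export
nmds <- function(d, dims = 2, n_restarts = 8, seed = 1) {
  if (length(d$species) < dims + 1)
    stop("need at least dims + 1 species")
  dd <- stats::as.dist(d$values)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- matrix(stats::rnorm(length(d$species) * dims),
                   ncol = dims)
    fit <- vegan::monoMDS(dd, y = init, k = dims, model = "global")
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- best$points
  rownames(coords) <- d$species
  colnames(coords) <- paste0("NMDS", seq_len(dims))
  list(coords = coords, stress = best$stress)
}

# ---- Gaussian mixture with uniform noise component ------------------------

gmm_noise_em <- function(x, k, noise = TRUE, max_iter = 300, tol = 1e-7,
                         ridge = 1e-6) {
  n <- nrow(x); p <- ncol(x)
  vol <- prod(apply(x, 2, function(v) diff(range(v)) + 1e-9))
  # initialise the noise component by nearest-neighbour denoising: points
  # whose 2nd-NN distance is far beyond the bulk start as noise, everything
  # else seeds the Gaussians.  Starting the noise weight near its true
  # fraction keeps EM in the intended local optimum instead of letting a
  # tightly-supported uniform leech the tails of a clean cluster.
  dm <- as.matrix(stats::dist(x))
  nnd <- apply(dm, 1, function(r) sort(r)[min(3, n)])
  thr <- 2 * stats::quantile(nnd, 0.9)
  flagged <- noise & nnd > thr
  clean <- which(!flagged)
  if (length(clean) < 2 * k) {
    flagged[] <- FALSE
    clean <- seq_len(n)
  }
  # the denoising step decides whether a noise component exists at all;
  # a uniform over the sample bounding box would otherwise leech the
  # tails of a clean cluster (its support is data-dependent)
  if (!any(flagged)) noise <- FALSE
  km <- stats::kmeans(x[clean, , drop = FALSE], centers = k, nstart = 10,
                      iter.max = 50)
  mu <- km$centers
  sig <- lapply(seq_len(k), function(j) {
    pts <- x[clean[km$cluster == j], , drop = FALSE]
    s <- if (nrow(pts) > p) stats::cov(pts) else diag(p) * stats::var(as.vector(x))
    s + diag(p) * ridge
  })
  n_comp <- k + as.integer(noise)
  w <- if (noise) {
    f <- max(sum(flagged) / n, 0.5 / n)
    c(rep((1 - f) * tabulate(km$cluster, k) / length(clean), 1), f)
  } else rep(1 / k, k)
  dens <- function() {
    D <- matrix(0, n, n_comp)
    for (j in seq_len(k)) {
      ch <- chol(sig[[j]])
      z <- forwardsolve(t(ch), t(x) - mu[j, ])
      D[, j] <- exp(-colSums(z^2) / 2) / ((2 * pi)^(p / 2) * prod(diag(ch)))
    }
    if (noise) D[, k + 1] <- 1 / vol
    D
  }
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    D <- dens()
    wd <- sweep(D, 2, w, "*")
    rowsum_ <- rowSums(wd)
    rowsum_[rowsum_ == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_))
    R <- wd / rowsum_
    w <- colMeans(R)
    for (j in seq_len(k)) {
      rj <- R[, j]; sw <- sum(rj)
      if (sw < 1e-8) next
      mu[j, ] <- colSums(x * rj) / sw
      xc <- sweep(x, 2, mu[j, ])
      sig[[j]] <- crossprod(xc * sqrt(rj)) / sw + diag(p) * ridge
    }
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  n_par <- k * (p + p * (p + 1) / 2) + (n_comp - 1)
  bic <- -2 * ll + n_par * log(n)
  post <- sweep(dens(), 2, w, "*")
  assign <- max.col(post, ties.method = "first")
  list(k = k, loglik = ll, bic = bic, assignment = assign,
       noise_label = if (noise) k + 1L else NA_integer_)
}

#' Cluster species into biotic elements
#'
#' Gaussian-mixture clustering of the NMDS coordinates with an added
#' uniform "noise" component absorbing species that belong to no element;
#' the number of elements K is chosen by BIC over `1..max_k`.
#' Deterministic given `seed`.
#'
#' @param coords numeric matrix (species x dims), e.g. from [nmds()]
#' @param max_k largest number of elements tried (default 9)
#' @param seed integer seed
#' @param noise include the uniform noise component (default TRUE)
#' @return object of class `biotic_elements`: `assignment` (named vector,
#'   `1..K` or `"noise"`), `k`, `bic` (per candidate K), `coords`
#' @export
cluster_elements <- function(coords, max_k = 9, seed = 1, noise = TRUE) {
  stopifnot(all(is.finite(coords)))
  max_k <- min(max_k, nrow(coords) - 1L)
  set.seed(seed)
  fits <- lapply(seq_len(max_k), function(k)
    gmm_noise_em(coords, k, noise = noise))
  bics <- vapply(fits, `[[`, 0, "bic")
  best <- fits[[which.min(bics)]]
  lab <- as.character(best$assignment)
  if (noise) lab[best$assignment == best$noise_label] <- "noise"
  names(lab) <- rownames(coords)
  structure(list(assignment = lab, k = best$k,
                 bic = stats::setNames(bics, seq_len(max_k)),
                 coords = coords),
            class = "biotic_elements")
}

#' @export
print.biotic_elements <- function(x, ...) {
  tab <- table(x$assignment)
  cat(sprintf("<biotic_elements> K = %d (+%d noise)\n", x$k,
              sum(x$assignment == "noise")))
  print(tab)
  invisible(x)
}

#' Per-element OGU shading classes
#'
#' For each element and OGU, the proportion of the element's species
#' present there, classed by the thresholds used for element maps: class 1
#' for > 30 %, 2 for > 45 %, 3 for > 60 %, and class 4 when *all* species
#' of the element are present (the "100 %" class); 0 means unshaded.
#'
#' @param elements a [cluster_elements()] result
#' @param m an [incidence_matrix()]
#' @param thresholds lower bounds of classes 1..3 (strictly exceeded)
#' @return list per element: data.frame (ogu, proportion, class)
#' @export
element_maps <- function(elements, m,
                         thresholds = c(0.30, 0.45, 0.60)) {
  labs <- setdiff(sort(unique(elements$assignment)), "noise")
  out <- lapply(labs, function(el) {
    sp <- names(elements$assignment)[elements$assignment == el]
    prop <- colSums(m$cells[sp, , drop = FALSE]) / length(sp)
    cls <- ifelse(prop == 1, 4L,
                  ifelse(prop > thresholds[3], 3L,
                         ifelse(prop > thresholds[2], 2L,
                                ifelse(prop > thresholds[1], 1L, 0L))))
    data.frame(ogu = ogu_ids(m), proportion = unname(prop),
               class = unname(cls), stringsAsFactors = FALSE)
  })
  stats::setNames(out, paste0("element_", labs))
}
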