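#' Synthetic scenario specification
#'
#' A stated world for testing the whole pipeline: a planar lattice of OGUs
#' with lognormal areas, a partition of the lattice into `k_regions`
#' planted contiguous "true" regions, and a species pool whose ranges grow
#' as connected sets inside their home region, with tunable leakage,
#' region-free noise species, and planted single-OGU endemics.
#'
#' @param n_ogus number of OGUs (arranged on an `nrow_lattice` x
#'   `n_ogus / nrow_lattice` lattice)
#' @param nrow_lattice lattice rows (default 5)
#' @param n_species total species count
#' @param k_regions planted vicariant regions (contiguous column bands)
#' @param leakage probability that a presence is relocated outside the home
#'   region
#' @param p_noise fraction of species with region-free random connected
#'   ranges
#' @param n_singletons planted single-OGU endemics (placed two per
#'   designated OGU)
#' @param range_geom_p geometric parameter of the range-size law (P(size =
#'   k) prop (1-p)^(k-1) p, truncated); 0.35 gives the strong
#'   narrow-endemism skew typical of land snails
#' @param n_backbone per planted region, the number of characteristic
#'   species whose range spans the whole region; real provinces are held
#'   together by such widespread endemics, and they make planted regions
#'   recoverable at zero leakage
#' @param core_affinity probability that a regional species' range grows
#'   outward from the region's core OGU (a shared refugium) rather than
#'   from a uniform OGU of the region; congruent, core-nested ranges are
#'   what makes a vicariant pool a detectable biotic element (0 makes
#'   range placement match the clustering-test null model)
#' @param area_meanlog,area_sdlog lognormal OGU-area parameters (km2)
#' @param seed integer seed
#' @return object of class `synthetic_scenario`
#' @export
synthetic_scenario <- function(n_ogus = 40, nrow_lattice = 5,
                               n_species = 73, k_regions = 5,
                               leakage = 0.05, p_noise = 0.15,
                               n_singletons = 6, range_geom_p = 0.35,
                               n_backbone = 2, core_affinity = 0.8,
                               area_meanlog = log(5000), area_sdlog = 0.6,
                               seed = 1) {
  stopifnot(n_ogus >= 4, n_ogus %% nrow_lattice == 0,
            leakage >= 0, leakage <= 1, p_noise >= 0, p_noise <= 1,
            k_regions >= 1, n_singletons >= 0,
            range_geom_p > 0, range_geom_p < 1,
            core_affinity >= 0, core_affinity <= 1)
  structure(as.list(environment()), class = "synthetic_scenario")
}

#' Named scenario presets
#'
#' `vicariant_clean` (no leakage, no noise: every range sits inside one
#' planted region), `vicariant_leaky` (moderate leakage and noise),
#' `null_random` (a single region: ranges follow the null model itself),
#' and `paperlike40x73` (40 OGUs, 73 species, 5 regions, mild leakage --
#' the shape of the study system; a synthetic stand-in, not its data).
#'
#' @param name preset name
#' @param seed integer seed
#' @return a [synthetic_scenario()]
#' @export
scenario_preset <- function(name = c("vicariant_clean", "vicariant_leaky",
                                     "null_random", "paperlike40x73"),
                            seed = 1) {
  name <- match.arg(name)
  switch(name,
    vicariant_clean = synthetic_scenario(leakage = 0, p_noise = 0,
                                         n_singletons = 0, seed = seed),
    vicariant_leaky = synthetic_scenario(leakage = 0.10, p_noise = 0.15,
                                         seed = seed),
    null_random = synthetic_scenario(k_regions = 1, leakage = 0,
                                     p_noise = 0, n_singletons = 0,
                                     n_backbone = 0, core_affinity = 0,
                                     seed = seed),
    paperlike40x73 = synthetic_scenario(seed = seed))
}

#' Generate the OGU system of a scenario
#'
#' Builds the lattice adjacency (rook neighbourhoods, always connected),
#' samples lognormal areas, and partitions the lattice into `k_regions`
#' contiguous column bands (the planted regions).
#'
#' @param scenario a [synthetic_scenario()]
#' @return list: `ogus` (registry data.frame with `region` truth column),
#'   `graph` (an [adjacency_graph()])
#' @export
generate_ogus <- function(scenario) {
  s <- scenario
  nr <- s$nrow_lattice
  nc <- s$n_ogus / nr
  ids <- sprintf("U%02d", seq_len(s$n_ogus))    # row-major: (r, c)
  at <- function(r, c) (r - 1) * nc + c
  edges <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (c < nc) edges <- rbind(edges, c(at(r, c), at(r, c + 1)))
    if (r < nr) edges <- rbind(edges, c(at(r, c), at(r + 1, c)))
  }
  g <- adjacency_graph(ids, cbind(ids[edges[, 1]], ids[edges[, 2]]))
  set.seed(s$seed)
  areas <- stats::rlnorm(s$n_ogus, s$area_meanlog, s$area_sdlog)
  # contiguous column bands as planted regions
  band <- sort(rep_len(seq_len(s$k_regions), nc))
  col_of <- rep(seq_len(nc), nr)
  region <- sprintf("R%d", band[col_of])
  ogus <- data.frame(ogu_id = ids, name = ids,
                     area_km2 = round(areas, 1),
                     region = region, stringsAsFactors = FALSE)
  list(ogus = ogus, graph = g)
}

#' Generate a synthetic incidence matrix with truth labels
#'
#' Each non-noise, non-singleton species gets a home region; its range
#' grows as a connected set inside the home region, with a size drawn from
#' the truncated geometric range-size law, and each presence is then
#' relocated outside the region with probability `leakage`.  Noise species
#' grow region-free connected ranges.  Singletons are placed two per
#' designated OGU (spread across regions) so they form candidate centres
#' of narrow endemism.
#'
#' @param scenario a [synthetic_scenario()]
#' @return list: `matrix` (an [incidence_matrix()]), `ogus`, `graph`,
#'   `truth` (per-species home region / noise / singleton labels, per-OGU
#'   planted region)
#' @export
generate_species <- function(scenario) {
  s <- scenario
  sys <- generate_ogus(s)
  g <- sys$graph
  ids <- sys$ogus$ogu_id
  region_of <- stats::setNames(sys$ogus$region, ids)
  regions <- split(ids, sys$ogus$region)
  adj_idx <- lapply(ids, function(v)
    match(names(igraph::neighbors(g$graph, v)), ids))
  set.seed(s$seed + 1L)
  n_noise <- round(s$p_noise * (s$n_species - s$n_singletons))
  n_regional <- s$n_species - s$n_singletons - n_noise
  draw_size <- function(cap) {
    repeat {
      k <- stats::rgeom(1, s$range_geom_p) + 1L
      if (k <= cap) return(k)
    }
  }
  grow_in <- function(members_pool, seed_ogu = NULL) {
    pool_idx <- match(members_pool, ids)
    sub_adj <- lapply(pool_idx, function(i)
      intersect(adj_idx[[i]], pool_idx))
    size <- draw_size(length(pool_idx))
    cur <- if (!is.null(seed_ogu)) match(match(seed_ogu, ids), pool_idx)
      else sample(seq_along(pool_idx), 1L)
    got <- cur
    while (length(got) < size) {
      frontier <- setdiff(unlist(sub_adj[got]), pool_idx[got])
      if (!length(frontier)) break
      pick <- frontier[sample.int(length(frontier), 1L)]
      got <- c(got, match(pick, pool_idx))
    }
    ids[pool_idx[got]]
  }
  cells <- matrix(0L, s$n_species, s$n_ogus,
                  dimnames = list(sprintf("sp%03d", seq_len(s$n_species)),
                                  ids))
  truth_sp <- character(s$n_species)
  i <- 0L
  backbone_home <- rep(names(regions), min(s$n_backbone,
                                           n_regional %/% max(1, length(regions))))
  n_free <- n_regional - length(backbone_home)
  home_seq <- c(backbone_home, sample(rep_len(names(regions), n_free)))
  for (j in seq_len(n_regional)) {
    i <- i + 1L
    home <- home_seq[j]
    core <- regions[[home]][ceiling(length(regions[[home]]) / 2)]
    rng <- if (j <= length(backbone_home)) regions[[home]] else
      grow_in(regions[[home]],
              seed_ogu = if (stats::runif(1) < s$core_affinity) core)
    if (s$leakage > 0) {
      outside <- setdiff(ids, regions[[home]])
      for (k in seq_along(rng)) {
        if (length(outside) && stats::runif(1) < s$leakage)
          rng[k] <- sample(outside, 1L)
      }
      rng <- unique(rng)
    }
    cells[i, rng] <- 1L
    truth_sp[i] <- home
  }
  for (j in seq_len(n_noise)) {
    i <- i + 1L
    cells[i, grow_in(ids)] <- 1L
    truth_sp[i] <- "noise"
  }
  if (s$n_singletons > 0) {
    hosts <- regions[rep_len(seq_along(regions),
                             ceiling(s$n_singletons / 2))]
    host_ogus <- vapply(hosts, function(r) r[ceiling(length(r) / 2)], "")
    host_seq <- rep(host_ogus, each = 2L)[seq_len(s$n_singletons)]
    for (og in host_seq) {
      i <- i + 1L
      cells[i, og] <- 1L
      truth_sp[i] <- "singleton"
    }
  }
  m <- incidence_matrix(cells,
                        species = data.frame(species_id = rownames(cells),
                                             stringsAsFactors = FALSE),
                        ogus = sys$ogus)
  list(matrix = m, ogus = sys$ogus, graph = g,
       truth = list(species = stats::setNames(truth_sp, rownames(cells)),
                    ogu_region = region_of))
}
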