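test_that("range distances match set arithmetic", {
  m <- matrix_from_ranges(
    list(a = c("U1", "U2"), b = c("U2", "U3"), sub = "U1",
         twin = c("U1", "U2")),
    c("U1", "U2", "U3"))
  k <- range_distance(m, "kulczynski")$values
  expect_equal(k["a", "b"], 0.5)            # 1 - (1/2 + 1/2)/2
  expect_equal(k["sub", "a"], 0.25)         # 1 - (1 + 1/2)/2
  expect_equal(k["a", "twin"], 0)
  j <- range_distance(m, "jaccard")$values
  expect_equal(j["a", "b"], 1 - 1 / 3)
  expect_equal(j["a", "twin"], 0)
  empty <- matrix_from_ranges(list(a = "U1", b = character()), c("U1"))
  expect_error(range_distance(empty), "empty range.*b")
})

test_that("distratio: sort oracle, scale invariance, bounds, errors", {
  expect_equal(distratio(c(1, 2, 3, 4), 0.25), 0.25)
  expect_equal(distratio(rep(0.3, 10)), 1)
  set.seed(51)
  dv <- runif(40)
  t1 <- distratio(dv, 0.25)
  expect_equal(distratio(dv * 7, 0.25), t1)      # scale invariant
  expect_gt(t1, 0); expect_lte(t1, 1)
  expect_error(distratio(rep(0, 10)), "zero")
  expect_error(distratio(c(1, 2), 0.25), "too few")
})

test_that("null ranges conserve sizes, connectivity and determinism", {
  gen <- generate_species(scenario_preset("vicariant_leaky", seed = 6))
  m <- gen$matrix; g <- gen$graph
  sims <- simulate_null_ranges(m, g, 3, seed = 9)
  for (s in sims) {
    expect_equal(sort(rowSums(s$cells)), sort(rowSums(m$cells)))
    for (sp in species_ids(s)) {
      rng <- species_range(s, sp)
      if (length(rng) > 1)
        expect_length(induced_components(g, rng), 1)
    }
  }
  sims2 <- simulate_null_ranges(m, g, 3, seed = 9)
  expect_identical(lapply(sims, `[[`, "cells"), lapply(sims2, `[[`, "cells"))
  big <- incidence_matrix(matrix(1L, 1, 2,
                                 dimnames = list("sp", c("U01", "U02"))))
  expect_error(simulate_null_ranges(big, line_graph(c("U01", "U03")), 1, 1),
               "missing")
})

test_that("on a complete graph, null occupancy is uniform across OGUs", {
  ids <- sprintf("K%02d", 1:8)
  g <- complete_graph(ids)
  m <- matrix_from_ranges(stats::setNames(
    lapply(1:10, function(i) ids[seq_len(1 + (i %% 4))]),
    sprintf("s%02d", 1:10)), ids)
  sims <- simulate_null_ranges(m, g, 500, seed = 13)
  counts <- Reduce(`+`, lapply(sims, function(s) colSums(s$cells)))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("clustering test: p bounds, determinism, and power on planted blocks", {
  gen <- generate_species(scenario_preset("vicariant_clean", seed = 8))
  ct <- clustering_test(gen$matrix, gen$graph, n_sim = 200, seed = 15)
  expect_gt(ct$p_value, 0)
  expect_lte(ct$p_value, 1)
  expect_lte(ct$p_value, 0.05)              # planted vicariance is detected
  expect_lt(ct$t_observed, mean(ct$t_simulated))
  ct2 <- clustering_test(gen$matrix, gen$graph, n_sim = 200, seed = 15)
  expect_identical(ct2$t_simulated, ct$t_simulated)
})

test_that("nmds recovers embeddable configurations", {
  # three equidistant points embed exactly in 2-D
  D <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D) <- 0
  rd <- structure(list(species = letters[1:3], values = D,
                       metric = "kulczynski"),
                  class = "range_distance_matrix")
  fit <- nmds(rd, dims = 2, n_restarts = 4, seed = 3)
  expect_lt(fit$stress, 1e-3)
  # distances already Euclidean in 2-D are recovered
  set.seed(61)
  pts <- matrix(rnorm(24), ncol = 2)
  D2 <- as.matrix(stats::dist(pts))
  dimnames(D2) <- list(paste0("p", 1:12), paste0("p", 1:12))
  rd2 <- structure(list(species = rownames(D2), values = D2,
                        metric = "kulczynski"),
                   class = "range_distance_matrix")
  fit2 <- nmds(rd2, dims = 2, n_restarts = 6, seed = 5)
  expect_lt(fit2$stress, 0.01)
  expect_error(nmds(rd, dims = 3), "dims")
})

test_that("cluster_elements separates blobs and flags outliers as noise", {
  set.seed(71)
  blob1 <- matrix(rnorm(60, mean = 0, sd = .12), ncol = 2)
  blob2 <- matrix(rnorm(60, mean = 4, sd = .12), ncol = 2)
  out <- matrix(c(-6, 9, 9, -6, -8, -2), ncol = 2, byrow = TRUE)
  coords <- rbind(blob1, blob2, out)
  rownames(coords) <- sprintf("s%02d", seq_len(nrow(coords)))
  el <- cluster_elements(coords, max_k = 5, seed = 2)
  expect_equal(el$k, 2)
  expect_equal(sum(el$assignment == "noise"), 3)
  expect_setequal(names(el$assignment)[el$assignment == "noise"],
                  rownames(coords)[61:63])
  # members of one blob share one label
  expect_length(unique(el$assignment[1:30]), 1)
  # a single tight cloud: K = 1, nothing in the noise class
  one <- matrix(rnorm(50, sd = .1), ncol = 2,
                dimnames = list(sprintf("t%d", 1:25), NULL))
  el1 <- cluster_elements(one, max_k = 4, seed = 2)
  expect_equal(el1$k, 1)
  expect_equal(sum(el1$assignment == "noise"), 0)
})

test_that("element maps class by the stated thresholds", {
  m <- matrix_from_ranges(
    list(a = c("U1", "U2"), b = c("U1", "U2", "U3"), c = "U1",
         d = c("U1", "U4")),
    c("U1", "U2", "U3", "U4", "U5"))
  el <- structure(list(assignment = c(a = "1", b = "1", c = "1", d = "1")),
                  class = "biotic_elements")
  mp <- element_maps(el, m)$element_1
  cls <- stats::setNames(mp$class, mp$ogu)
  expect_equal(unname(cls["U1"]), 4L)       # all four species: top class
  expect_equal(unname(cls["U2"]), 2L)       # 2/4 = 50% -> "> 45%" class
  expect_equal(unname(cls["U3"]), 0L)       # 25%: below the lowest bound
  expect_equal(unname(cls["U5"]), 0L)       # empty: unshaded
  prop <- stats::setNames(mp$proportion, mp$ogu)
  expect_equal(unname(prop["U2"]), 0.5)
})
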