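three_leaf_dendro <- function() {
  # merge similarities 0.8 (x,y) then 0.4
  D <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  upgma(D, is_distance = TRUE)
}

test_that("phenon scheme validates threshold ordering", {
  expect_error(phenon_scheme(c(dominion = .5, district = .3)),
               "strictly increasing")
  expect_error(phenon_scheme(c(dominion = -.1)), "\\[0, 1\\]")
  s <- phenon_scheme(c(dominion = .1, province = .4, district = .6))
  expect_equal(s$levels, c("dominion", "province", "district"))
})

test_that("cut_phenon matches the similarity semantics", {
  d <- three_leaf_dendro()
  expect_length(cut_phenon(d, 0), 1)                 # one cluster
  expect_length(cut_phenon(d, 1), 3)                 # all singletons
  mid <- cut_phenon(d, 0.6)
  expect_length(mid, 2)
  expect_setequal(mid[[1]], c("x", "y"))
  expect_setequal(mid[[2]], "z")
})

test_that("cuts at increasing thresholds refine each other", {
  set.seed(11)
  D <- as.matrix(stats::dist(matrix(runif(20), 10)))
  dimnames(D) <- list(paste0("u", 1:10), paste0("u", 1:10))
  d <- upgma(D, is_distance = TRUE)
  for (pair in list(c(.2, .5), c(.4, .8), c(0, .99))) {
    coarse <- cut_phenon(d, pair[1])
    fine <- cut_phenon(d, pair[2])
    for (cl in fine) {
      holders <- Filter(function(cc) any(cl %in% cc), coarse)
      expect_length(holders, 1)
      expect_true(all(cl %in% holders[[1]]))
    }
  }
})

test_that("enforce_contiguity splits non-contiguous clusters", {
  g <- line_graph(c("A", "B", "C", "D"))
  ec <- enforce_contiguity(list(c1 = c("A", "B")), g)
  expect_length(ec$orphans, 0)
  ec <- enforce_contiguity(list(c1 = c("A", "B", "D")), g)
  expect_setequal(ec$cores$c1, c("A", "B"))
  expect_identical(ec$orphans, "D")
  expect_error(enforce_contiguity(list(c1 = "Z"), g), "missing")
})

test_that("contiguity ties break by species count then label", {
  g <- adjacency_graph(c("A", "B", "C", "D"),
                       rbind(c("A", "B"), c("C", "D")))
  m <- matrix_from_ranges(list(s1 = c("C", "D"), s2 = "C"),
                          c("A", "B", "C", "D"))
  # two components of equal size; {C,D} holds 3 presences
  ec <- enforce_contiguity(list(c1 = c("A", "B", "C", "D")), g, m)
  expect_setequal(ec$cores$c1, c("C", "D"))
  # without species info the tie falls to the smaller label
  ec2 <- enforce_contiguity(list(c1 = c("A", "B", "C", "D")), g)
  expect_setequal(ec2$cores$c1, c("A", "B"))
})

test_that("orphans dissolve into the nearest, most similar core", {
  ids <- c("A", "B", "C", "D", "O")
  g <- adjacency_graph(ids, rbind(c("A", "B"), c("C", "D"),
                                  c("B", "O"), c("D", "O")))
  m <- matrix_from_ranges(list(s1 = c("A", "B", "O"), s2 = c("C", "D")),
                          ids)
  s <- jaccard_similarity(m)
  frag <- dissolve_orphans("O", list(R1 = c("A", "B"), R2 = c("C", "D")),
                           g, s)
  expect_identical(frag$R1$dissolved, "O")     # mean J 0.67 beats 0
  expect_length(frag$R2$dissolved, 0)
  # single adjacent core wins regardless of similarity
  g2 <- adjacency_graph(ids, rbind(c("A", "B"), c("C", "D"), c("D", "O")))
  frag2 <- dissolve_orphans("O", list(R1 = c("A", "B"), R2 = c("C", "D")),
                            g2, s)
  expect_identical(frag2$R2$dissolved, "O")
  # isolated orphan errors
  g3 <- adjacency_graph(ids, rbind(c("A", "B"), c("C", "D")))
  expect_error(dissolve_orphans("O", list(R1 = c("A", "B")), g3, s),
               "no path")
})

test_that("dissolution changes membership, never the number of cores", {
  set.seed(21)
  gen <- generate_species(scenario_preset("vicariant_leaky", seed = 5))
  sim <- jaccard_similarity(gen$matrix)
  d <- upgma(sim)
  part <- cut_phenon(d, 0.35)
  ec <- enforce_contiguity(part, gen$graph, gen$matrix)
  frag <- dissolve_orphans(ec$orphans, ec$cores, gen$graph, sim)
  expect_length(frag, length(ec$cores))
  got <- unlist(lapply(frag, function(r) c(r$members, r$dissolved)))
  expect_setequal(got, unlist(part))
})

test_that("build_hierarchy nests levels and keeps regions connected", {
  gen <- generate_species(scenario_preset("vicariant_leaky", seed = 3))
  sim <- jaccard_similarity(gen$matrix)
  d <- upgma(sim)
  sch <- propose_phenon_scheme(d, c("province", "district"))
  h <- build_hierarchy(d, sch, gen$graph, sim, gen$matrix)
  prov <- level_partition(h, "province")
  dist <- level_partition(h, "district")
  expect_setequal(names(prov), ogu_ids(gen$matrix))
  # nesting: each district lies inside one province
  for (dn in unique(dist)) {
    members <- names(dist)[dist == dn]
    expect_length(unique(prov[members]), 1)
  }
  # contiguity after dissolution (all orphans here are core-adjacent)
  for (lev in names(h$levels)) {
    for (r in h$levels[[lev]]) {
      comps <- induced_components(gen$graph, r$members)
      expect_length(comps, 1)
    }
  }
  # one-level scheme at threshold 0: a single dominion
  h0 <- build_hierarchy(d, phenon_scheme(c(dominion = 0)), gen$graph, sim)
  expect_length(h0$levels$dominion, 1)
  expect_setequal(h0$levels$dominion[[1]]$members, ogu_ids(gen$matrix))
})

test_that("planted regions are recovered exactly at zero leakage", {
  gen <- generate_species(scenario_preset("vicariant_clean", seed = 4))
  sim <- jaccard_similarity(gen$matrix)
  d <- upgma(sim)
  h <- build_hierarchy(d, propose_phenon_scheme(d, "province"),
                       gen$graph, sim, gen$matrix)
  p <- level_partition(h, "province")
  expect_equal(adjusted_rand_index(p[ogu_ids(gen$matrix)],
                                   gen$truth$ogu_region[ogu_ids(gen$matrix)]),
               1)
})

test_that("adjusted_rand_index behaves", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 1, 1)), 0)
  set.seed(2)
  a <- sample(3, 60, TRUE); b <- sample(3, 60, TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.3)
})
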