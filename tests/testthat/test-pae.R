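pm_from_ranges <- function(ranges, ogus) {
  prepare_pae_matrix(matrix_from_ranges(ranges, ogus))
}

test_that("prepare_pae_matrix filters and roots correctly", {
  pm <- pm_from_ranges(
    list(single = "A", wide = c("A", "B", "C", "D", "E"),
         inf1 = c("A", "B"), inf2 = c("C", "D"), inf3 = c("B", "C")),
    c("A", "B", "C", "D", "E", "F"))
  expect_setequal(pm$report$empty_ogus, c("E", "F"))
  expect_equal(unname(pm$report$singleton_species["single"]), "A")
  expect_true("wide" %in% pm$report$constant_species)  # constant after drop
  expect_setequal(pm$characters, c("inf1", "inf2", "inf3"))
  expect_true("ROOT" %in% pm$taxa)
  expect_true(all(pm$cells["ROOT", ] == 0))
  expect_error(pm_from_ranges(list(a = c("A", "B"), b = c("A", "B")),
                              c("A", "B", "C")), "at least 4")
})

test_that("fitch_length matches hand computations", {
  pm <- pm_from_ranges(
    list(ch = c("A", "B"), pad1 = c("A", "C"), pad2 = c("B", "D")),
    c("A", "B", "C", "D"))
  t1 <- ape::read.tree(text = "((A,B),(C,D),ROOT);")
  t2 <- ape::read.tree(text = "((A,C),(B,D),ROOT);")
  # character {A,B}: one origin on t1, two on t2
  only_ch <- pm
  only_ch$cells <- pm$cells[, "ch", drop = FALSE]
  only_ch$characters <- "ch"
  expect_equal(fitch_length(t1, only_ch), 1)
  expect_equal(fitch_length(t2, only_ch), 2)
  # all-zero character contributes nothing
  zero <- only_ch
  zero$cells[, 1] <- 0L
  expect_equal(fitch_length(t1, zero), 0)
  expect_error(fitch_length(ape::read.tree(text = "((A,B),(C,X),ROOT);"),
                            only_ch), "leaf set")
})

test_that("fitch_length agrees with the phangorn oracle on random trees", {
  skip_if_not_installed("phangorn")
  set.seed(17)
  for (rep in 1:10) {
    repeat {
      m <- rand_incidence(8, 6, p = 0.45)
      pm <- try(prepare_pae_matrix(m), silent = TRUE)
      if (!inherits(pm, "try-error")) break
    }
    tr <- ape::rtree(length(pm$taxa), tip.label = sample(pm$taxa))
    dat <- phangorn::phyDat(pm$cells, type = "USER", levels = c(0, 1))
    expect_equal(fitch_length(tr, pm),
                 as.integer(phangorn::parsimony(tr, dat)))
  }
})

test_that("heuristic_search is deterministic and beats supplied trees", {
  set.seed(23)
  repeat {
    m <- rand_incidence(10, 7, p = 0.4)
    pm <- try(prepare_pae_matrix(m), silent = TRUE)
    if (!inherits(pm, "try-error")) break
  }
  a <- heuristic_search(pm, n_replicates = 3, seed = 5, max_trees = 50)
  b <- heuristic_search(pm, n_replicates = 3, seed = 5, max_trees = 50)
  expect_equal(a$length, b$length)
  expect_equal(lapply(a$trees, ape::write.tree),
               lapply(b$trees, ape::write.tree))
  for (rep in 1:5) {
    rnd <- ape::rtree(length(pm$taxa), tip.label = sample(pm$taxa))
    expect_lte(a$length, fitch_length(rnd, pm))
  }
  # perfectly compatible (laminar) matrix: length = number of characters
  clean <- pm_from_ranges(
    list(c1 = c("A", "B"), c2 = c("A", "B", "C"), c3 = c("D", "E"),
         pad = c("C", "D")),
    c("A", "B", "C", "D", "E"))
  compat <- clean
  compat$cells <- clean$cells[, c("c1", "c2", "c3"), drop = FALSE]
  compat$characters <- c("c1", "c2", "c3")
  s <- heuristic_search(compat, n_replicates = 2, seed = 1)
  expect_equal(s$length, 3L)
})

test_that("search attains the exhaustive minimum (phangorn enumeration)", {
  skip_if_not_installed("phangorn")
  set.seed(29)
  for (rep in 1:8) {
    nt <- sample(4:6, 1)
    repeat {
      m <- rand_incidence(8, nt, p = 0.45)
      pm <- try(prepare_pae_matrix(m), silent = TRUE)
      if (!inherits(pm, "try-error")) break
    }
    srch <- heuristic_search(pm, n_replicates = 5, seed = rep,
                             max_trees = 20)
    dat <- phangorn::phyDat(pm$cells, type = "USER", levels = c(0, 1))
    best <- min(vapply(phangorn::allTrees(length(pm$taxa),
                                          tip.label = pm$taxa),
                       function(t) phangorn::parsimony(t, dat), 0))
    expect_equal(srch$length, as.integer(best))
  }
})

clade_sets <- function(phy) {
  parts <- ape::prop.part(phy)
  labs <- attr(parts, "labels")
  sets <- lapply(parts, function(p) sort(labs[p]))
  unique(vapply(sets, paste, "", collapse = ","))
}

test_that("strict consensus keeps exactly the shared clades", {
  t1 <- ape::read.tree(text = "(ROOT,((A,B),(C,D)));")
  expect_setequal(clade_sets(strict_consensus(c(t1, t1))), clade_sets(t1))
  t2 <- ape::read.tree(text = "(ROOT,((A,B),(C,E),D));")
  expect_error(strict_consensus(c(t1, t2)), "leaf sets")
  t3 <- ape::read.tree(text = "(ROOT,(((A,B),C),D));")
  cons <- strict_consensus(c(t1, t3))
  clades <- clade_sets(cons)
  expect_true("A,B" %in% clades)
  expect_false("C,D" %in% clades)
  # consensus clades are a subset of every input tree's clades
  expect_true(all(clades %in% clade_sets(t1)))
  expect_true(all(clades %in% clade_sets(t3)))
  # fully incompatible pair collapses to no resolution below the root
  s1 <- ape::read.tree(text = "(ROOT,((A,B),(C,D),E));")
  s2 <- ape::read.tree(text = "(ROOT,((A,C),(B,E),D));")
  star <- strict_consensus(c(s1, s2))
  nontrivial <- Filter(function(cl) {
    n <- length(strsplit(cl, ",")[[1]])
    n >= 2 && n <= 4
  }, clade_sets(star))
  expect_length(nontrivial, 0)
})

test_that("extract_aoes applies contiguity, sympatry and singleton rules", {
  ids <- c("A", "B", "C", "D", "E")
  g <- line_graph(ids)
  m <- matrix_from_ranges(
    list(e1 = c("A", "B"), e2 = c("A", "B"),            # sympatric pair
         f1 = c("C", "D"), f2 = "D",                    # no co-occurrence? f1,f2 share D
         g1 = "E", g2 = "E",                            # singleton pair
         bg = c("A", "C", "E")),
    ids)
  cons <- ape::read.tree(text = "(ROOT,((A,B),(C,D),E));")
  aoes <- extract_aoes(cons, m, g,
                       singleton_report = c(g1 = "E", g2 = "E"))
  mem <- lapply(aoes$aoes, `[[`, "members")
  expect_true(any(vapply(mem, function(x) setequal(x, c("A", "B")), TRUE)))
  expect_true(any(vapply(mem, function(x) setequal(x, "E"), TRUE)))
  prov <- vapply(aoes$aoes, `[[`, "", "provenance")
  expect_true("singleton_ogu" %in% prov)
  # sympatry failure: two endemics of {C,D} that never co-occur
  m2 <- matrix_from_ranges(
    list(e1 = c("A", "B"), e2 = c("A", "B"), f1 = "C", f2 = "D",
         bg = c("A", "C", "E")),
    ids)
  aoes2 <- extract_aoes(cons, m2, g)
  mem2 <- lapply(aoes2$aoes, `[[`, "members")
  expect_false(any(vapply(mem2, function(x) setequal(x, c("C", "D")), TRUE)))
  # non-contiguous clade is rejected
  cons3 <- ape::read.tree(text = "(ROOT,((A,C),B,(D,E)));")
  aoes3 <- extract_aoes(cons3, matrix_from_ranges(
    list(h1 = c("A", "C"), h2 = c("A", "C"), bg = c("B", "D")), ids), g)
  mem3 <- lapply(aoes3$aoes, `[[`, "members")
  expect_false(any(vapply(mem3, function(x) setequal(x, c("A", "C")), TRUE)))
})

test_that("nested qualifying clades collapse to minimal AOEs by default", {
  ids <- c("A", "B", "C", "D")
  g <- line_graph(ids)
  m <- matrix_from_ranges(
    list(e1 = c("A", "B"), e2 = c("A", "B"),
         u1 = c("C", "D"), u2 = c("C", "D")),
    ids)
  cons <- ape::read.tree(text = "(ROOT,(((A,B),C),D));")
  # {A,B} qualifies; {A,B,C} also 'harbours' e1,e2 but is not minimal
  mins <- extract_aoes(cons, m, g)
  expect_length(mins$aoes, 1)
  expect_setequal(mins$aoes[[1]]$members, c("A", "B"))
  alls <- extract_aoes(cons, m, g, nested = "all")
  expect_length(alls$aoes, 2)
})

test_that("NEXUS export is well-formed", {
  pm <- pm_from_ranges(
    list(a = c("A", "B"), b = c("C", "D"), c = c("B", "C")),
    c("A", "B", "C", "D"))
  f <- withr::local_tempfile(fileext = ".nex")
  write_pae_nexus(pm, f)
  txt <- readLines(f)
  expect_equal(txt[1], "#NEXUS")
  expect_true(any(grepl(sprintf("NTAX=%d NCHAR=%d", length(pm$taxa),
                                length(pm$characters)), txt)))
  expect_true(any(grepl("^    ROOT", txt)))
})
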