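test_that("incidence round-trips through CSV bit-identically", {
  cells <- matrix(c(1L, 0L, 0L, 1L, 1L, 1L), 3, 2, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), c("X", "Y")))
  m <- incidence_matrix(cells)
  expect_equal(unname(rowSums(m$cells)), c(1, 1, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_incidence(m, f)
  m2 <- read_incidence(f)
  expect_identical(m2$cells, m$cells)
  # tab dialect sniffing
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_incidence(m, f2, sep = "\t")
  expect_identical(read_incidence(f2)$cells, m$cells)
})

test_that("read_incidence validation names the offender", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sp,NCB,NCB", "a,1,0"), f)
  expect_error(read_incidence(f), "NCB")
  writeLines(c("sp,A,B", "a,1,2"), f)
  expect_error(read_incidence(f), "non-binary.*'a'.*'B'")
  writeLines(c("sp,A,B", "a,1,0", "a,0,1"), f)
  expect_error(read_incidence(f), "duplicate species")
})

test_that("prune_matrix removes uninformative rows/columns and is idempotent", {
  m <- matrix_from_ranges(
    list(wide = c("A", "B", "C"), single = "A", pair1 = c("A", "B"),
         pair2 = c("B", "C"), nowhere = character()),
    c("A", "B", "C", "D"))
  pr <- prune_matrix(m)
  expect_setequal(pr$report$empty_ogus, "D")
  expect_true("single" %in% pr$report$singleton_species)
  # 'wide' becomes constant once the empty OGU is gone; pruning cascades
  expect_true(all(c("wide", "nowhere") %in% pr$report$constant_species))
  expect_setequal(species_ids(pr$matrix), c("pair1", "pair2"))
  pr2 <- prune_matrix(pr$matrix)
  expect_identical(pr2$matrix$cells, pr$matrix$cells)
  expect_length(unlist(pr2$report), 0)
  # a species present in every OGU is a constant character
  m2 <- matrix_from_ranges(list(all1 = c("A", "B", "C"), keep1 = c("A", "B"),
                                keep2 = c("B", "C")),
                           c("A", "B", "C"))
  pr3 <- prune_matrix(m2, drop_uninformative_species = TRUE)
  expect_true("all1" %in% pr3$report$constant_species)
  expect_setequal(species_ids(pr3$matrix), c("keep1", "keep2"))
})

occ_fixture <- function(records, totals) {
  qds_occupancy(do.call(rbind, lapply(records, function(r)
    data.frame(species = r[[1]], ogu = r[[2]], qds = r[[3]],
               position = r[[4]], coast = r[[5]],
               margin_neighbor = r[[6]], stringsAsFactors = FALSE))),
    totals)
}

test_that("score_presence implements the four-clause rule", {
  totals <- c(OG1 = 50, OG2 = 20)
  # clause 1: one interior QDS is enough
  occ <- occ_fixture(list(list("sp", "OG1", "q1", "interior", "inland", NA)),
                     totals)
  expect_true(score_presence(occ, "sp", "OG1"))
  # clause 2: marginal-only but > 10% of the OGU
  recs <- lapply(1:6, function(i)
    list("sp", "OG1", paste0("q", i), "marginal", "inland", "OG2"))
  occ <- occ_fixture(recs, totals)           # 6/50 = 12%
  expect_true(score_presence(occ, "sp", "OG1",
                             c(OG2 = TRUE), threshold = 0.10))
  # clause 3: 4% marginal, absent from the neighbour -> present
  occ <- occ_fixture(list(
    list("sp", "OG1", "q1", "marginal", "inland", "OG2"),
    list("sp", "OG1", "q2", "marginal", "inland", "OG2")), totals)
  expect_true(score_presence(occ, "sp", "OG1", c(OG2 = FALSE)))
  # present in neighbour, inland -> absent
  expect_false(score_presence(occ, "sp", "OG1", c(OG2 = TRUE)))
  # clause 4: coastal margin of the range -> present despite neighbour
  occ <- occ_fixture(list(
    list("sp", "OG1", "q1", "marginal", "coastal", "OG2")), totals)
  expect_true(score_presence(occ, "sp", "OG1", c(OG2 = TRUE)))
  # strictness: exactly 10% is not enough
  recs <- lapply(1:5, function(i)
    list("sp", "OG1", paste0("q", i), "marginal", "inland", "OG2"))
  occ <- occ_fixture(recs, totals)           # 5/50 = 10%
  expect_false(score_presence(occ, "sp", "OG1", c(OG2 = TRUE)))
})

test_that("score_presence error paths demand what they need", {
  occ <- occ_fixture(list(
    list("sp", "OG1", "q1", "marginal", "inland", NA)), c(OG1 = 50))
  expect_error(score_presence(occ, "sp", "OG1"), "adjacency")
  expect_error(score_presence(occ, "nope", "OG1"), "unknown species")
  expect_error(score_presence(occ, "sp", "OGX"), "unknown OGU")
})

test_that("adding an interior QDS never flips present to absent", {
  totals <- c(OG1 = 50, OG2 = 10)
  base <- list(
    list("sp", "OG1", "q1", "marginal", "inland", "OG2"),
    list("sp", "OG1", "q2", "marginal", "inland", "OG2"))
  for (nb in c(TRUE, FALSE)) {
    before <- score_presence(occ_fixture(base, totals), "sp", "OG1",
                             c(OG2 = nb))
    grown <- c(base, list(list("sp", "OG1", "q9", "interior", "inland", NA)))
    after <- score_presence(occ_fixture(grown, totals), "sp", "OG1",
                            c(OG2 = nb))
    expect_true(after >= before)
    expect_true(after)
  }
})

test_that("taxon ledger: identity, union semantics, and validation", {
  m <- matrix_from_ranges(list(a = c("A", "B"), b = c("B", "C"), c = "C"),
                          c("A", "B", "C"))
  expect_identical(apply_taxon_ledger(m, taxon_ledger())$cells, m$cells)
  led <- taxon_ledger(list(list(kind = "merge_complex",
                                members = c("a", "b"), new_name = "ab")))
  out <- apply_taxon_ledger(m, led)
  expect_setequal(species_range(out, "ab"), c("A", "B", "C"))
  expect_equal(attr(out, "n_taxa"), 2)
  # per-OGU presence of the merged taxon is the OR of its members
  expect_equal(unname(out$cells["ab", ]),
               unname(as.integer(m$cells["a", ] | m$cells["b", ])))
  expect_error(apply_taxon_ledger(m, taxon_ledger(list(
    list(kind = "exclude", name = "zzz")))), "unknown name")
  expect_error(taxon_ledger(list(
    list(kind = "exclude", name = "a"),
    list(kind = "synonymise", junior = "a", senior = "b"))),
    "conflicting")
})

test_that("packaged ledger yields 73 analysis taxa with the stated tallies", {
  reg <- read_species_registry()
  expect_equal(nrow(reg), 79)
  out <- apply_taxon_ledger(reg, packaged_taxon_ledger())
  expect_equal(attr(out, "n_taxa"), 73)
  tallies <- table(out$genus)
  expect_equal(as.integer(tallies[c("Prestonella", "Nata", "Kerkophorus",
                                    "Sheldonia", "Selatodryas")]),
               c(2L, 5L, 19L, 13L, 1L))
  expect_equal(as.integer(tallies[c("Chlamydephorus", "Microkerkus",
                                    "Natalina")]), c(9L, 10L, 6L))
})
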