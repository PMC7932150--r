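#' Path to a packaged fixture
#'
#' The package ships small plain-text fixtures transcribed from the study
#' system's published summary tables: the raw species registry
#' (`species_registry_raw.csv`, 79 names including synonyms and complex
#' members), the taxon ledger (`taxon_ledger.json`), the per-region
#' endemism table (`table2_status.tsv` + `table2_presence.tsv`) and the
#' centres-of-endemism table (`table3_centres.tsv`).
#'
#' @param file fixture file name
#' @return absolute path
#' @export
zr_fixture <- function(file) {
  p <- system.file("extdata", file, package = "zooregion")
  if (p == "") stop(sprintf("no packaged fixture '%s'", file))
  p
}

#' Read the packaged raw species registry
#' @return data.frame (species_id, name, genus, family)
#' @export
read_species_registry <- function() {
  utils::read.csv(zr_fixture("species_registry_raw.csv"),
                  stringsAsFactors = FALSE)
}

#' The packaged taxon ledger
#' @return a [taxon_ledger()]
#' @export
packaged_taxon_ledger <- function() {
  read_taxon_ledger(zr_fixture("taxon_ledger.json"))
}

#' Read the packaged per-region endemism fixture
#' @return list: `status` (species x region endemic flags, with `family`
#'   and `note` columns), `presence` (per-region species-present counts)
#' @export
read_endemism_table <- function() {
  status <- utils::read.table(zr_fixture("table2_status.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE,
                              quote = "", na.strings = NULL)
  status$note[is.na(status$note)] <- ""
  presence <- utils::read.table(zr_fixture("table2_presence.tsv"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  list(status = status, presence = presence)
}

#' Summarise a pre-classified endemism table
#'
#' The per-species endemism flags give the endemic totals; the companion
#' presence counts give the denominators for percentage endemicity (the
#' underlying incidence matrix is not published, so presences per region
#' are transcription, not computation).
#'
#' @param tab result of [read_endemism_table()]
#' @return data.frame: region, n_endemic, n_present, pct_endemicity
#' @export
summarise_endemism_table <- function(tab = read_endemism_table()) {
  regions <- tab$presence$region
  n_end <- vapply(regions, function(r) sum(tab$status[[r]]), 0L)
  data.frame(region = regions,
             n_endemic = unname(n_end),
             n_present = tab$presence$n_present,
             pct_endemicity = round(100 * unname(n_end) /
                                      tab$presence$n_present, 1),
             stringsAsFactors = FALSE)
}

#' Read the packaged centres-of-endemism fixture
#' @return data.frame, one row per COE-restricted species, with the
#'   centre, its member OGUs, the species' occupied OGUs, the fraction of
#'   the centre's extent it covers, any nested CONE, overrides, and the
#'   label printed in the source table
#' @export
read_centres_table <- function() {
  utils::read.table(zr_fixture("table3_centres.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE, quote = "",
                    na.strings = NULL)
}

#' Classify the packaged centre endemics as characteristic or narrow
#'
#' Reconstructs, per centre, a minimal incidence matrix from the fixture's
#' occupied-OGU lists and runs [classify_characteristic_narrow()] with the
#' fixture's extent fractions and overrides.
#'
#' @param tab result of [read_centres_table()]
#' @return the fixture with a `label` column appended (the classifier's
#'   output)
#' @export
classify_centres_table <- function(tab = read_centres_table()) {
  out <- NULL
  for (coe in unique(tab$coe)) {
    rows <- tab[tab$coe == coe, , drop = FALSE]
    members <- strsplit(rows$coe_members[1], ",")[[1]]
    cells <- matrix(0L, nrow(rows), length(members),
                    dimnames = list(rows$species_id, members))
    for (i in seq_len(nrow(rows)))
      cells[i, strsplit(rows$occupied_ogus[i], ",")[[1]]] <- 1L
    m <- incidence_matrix(cells)
    centre <- list(name = coe, members = members,
                   endemics = rows$species_id)
    cone_members <- unique(unlist(
      strsplit(rows$occupied_ogus[rows$cone != ""], ",")))
    ov <- rows$override[rows$override != "none"]
    names(ov) <- rows$species_id[rows$override != "none"]
    lab <- classify_characteristic_narrow(
      centre, m,
      area_fraction = stats::setNames(rows$area_fraction, rows$species_id),
      cone_members = cone_members,
      overrides = if (length(ov)) ov else NULL)
    rows$label <- lab$label[match(rows$species_id, lab$species_id)]
    out <- rbind(out, rows)
  }
  out
}
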