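#' Classify species endemism relative to a region
#'
#' A species is *endemic* to a region when every OGU it occupies lies
#' inside the region; *near-endemic* when at most a `spillover` fraction of
#' its occupied OGUs falls outside (only when `spillover > 0`); otherwise
#' *non-endemic*.  Species absent from the region never enter the region's
#' species-present denominator.
#'
#' @param m an [incidence_matrix()]
#' @param region character vector of OGU ids (subset of the matrix OGUs)
#' @param spillover allowed outside fraction for near-endemics (default 0)
#' @return list with `status` (data.frame species_id, status), `n_endemic`,
#'   `n_present`, `pct_endemicity` (100 * endemics / present)
#' @export
classify_endemics <- function(m, region, spillover = 0) {
  if (!length(region)) stop("empty region")
  unknown <- setdiff(region, ogu_ids(m))
  if (length(unknown))
    stop(sprintf("region OGU(s) not in matrix: %s",
                 paste(unknown, collapse = ", ")))
  inside <- rowSums(m$cells[, region, drop = FALSE])
  total <- rowSums(m$cells)
  out_frac <- ifelse(total > 0, (total - inside) / total, NA)
  status <- rep("non_endemic", nrow(m$cells))
  status[total > 0 & inside == total] <- "endemic"
  if (spillover > 0)
    status[status == "non_endemic" & inside > 0 &
             out_frac <= spillover] <- "near_endemic"
  status[inside == 0] <- "non_endemic"
  present <- inside > 0
  list(status = data.frame(species_id = rownames(m$cells), status = status,
                           stringsAsFactors = FALSE),
       n_endemic = sum(status == "endemic"),
       n_present = sum(present),
       pct_endemicity = if (sum(present)) 100 * sum(status == "endemic") /
         sum(present) else NA_real_)
}

#' Identify centres of endemism (COEs)
#'
#' Every district (finest hierarchy level unless another level is named)
#' harbouring at least `min_endemics` endemic species becomes a COE.
#'
#' @param h a `region_hierarchy`
#' @param m an [incidence_matrix()]
#' @param min_endemics minimum endemics for COE status (default 4)
#' @param level hierarchy level to scan (default: finest)
#' @return object of class `centre_set` with `kind = "COE"` centres: each a
#'   list of `name`, `members`, `endemics`
#' @export
identify_coes <- function(h, m, min_endemics = 4, level = NULL) {
  if (is.null(level)) level <- utils::tail(names(h$levels), 1)
  regs <- h$levels[[level]]
  if (is.null(regs)) stop(sprintf("no level '%s' in hierarchy", level))
  centres <- list()
  for (nm in names(regs)) {
    cl <- classify_endemics(m, regs[[nm]]$members)
    end <- cl$status$species_id[cl$status$status == "endemic"]
    if (length(end) >= min_endemics)
      centres[[nm]] <- list(name = nm, kind = "COE",
                            members = regs[[nm]]$members, endemics = end)
  }
  structure(list(centres = centres, kind = "COE"), class = "centre_set")
}

#' Identify centres of narrow endemism (CONEs)
#'
#' Candidate units are single OGUs plus within-district subclusters cut at
#' a similarity above the district phenon line.  A candidate holding at
#' least `min_narrow` narrow-flagged species whose whole ranges lie inside
#' it becomes a CONE.  Candidates nested inside an accepted larger CONE are
#' dropped.
#'
#' @param d a `zr_dendrogram`
#' @param m an [incidence_matrix()]
#' @param narrow_flags named logical vector per species (see
#'   [narrow_endemism_flags()]); unnamed species count as not narrow
#' @param min_narrow minimum narrow endemics (default 2)
#' @param similarity cut similarity defining "tight" clusters (must exceed
#'   the district phenon line)
#' @param max_ogus maximum extent of a CONE in OGUs (default 3)
#' @return a `centre_set` with `kind = "CONE"`
#' @export
identify_cones <- function(d, m, narrow_flags, min_narrow = 2,
                           similarity = 0.5, max_ogus = 3) {
  clusters <- cut_phenon(d, similarity)
  cand <- c(clusters[lengths(clusters) <= max_ogus & lengths(clusters) > 1],
            lapply(ogu_ids(m), function(o) o))
  cand <- unique(lapply(cand, sort))
  narrow_sp <- names(narrow_flags)[narrow_flags]
  qualifies <- function(unit) {
    cl <- classify_endemics(m, unit)
    end <- cl$status$species_id[cl$status$status == "endemic"]
    intersect(end, narrow_sp)
  }
  supported <- lapply(cand, qualifies)
  ok <- lengths(supported) >= min_narrow
  cand <- cand[ok]; supported <- supported[ok]
  ord <- order(-lengths(cand), vapply(cand, min, ""))
  centres <- list()
  for (i in ord) {
    nested <- any(vapply(centres, function(cn)
      all(cand[[i]] %in% cn$members), TRUE))
    if (nested) next
    nm <- sprintf("CONE_%s", paste(cand[[i]], collapse = "-"))
    centres[[nm]] <- list(name = nm, kind = "CONE", members = cand[[i]],
                          endemics = supported[[i]])
  }
  structure(list(centres = centres, kind = "CONE"), class = "centre_set")
}

#' @export
print.centre_set <- function(x, ...) {
  cat(sprintf("<centre_set> %d %s(s)\n", length(x$centres), x$kind))
  for (cn in x$centres)
    cat(sprintf("  %s [%s]: %d endemics\n", cn$name,
                paste(cn$members, collapse = ","), length(cn$endemics)))
  invisible(x)
}

#' Label a centre's endemics as characteristic or narrow
#'
#' A *characteristic* endemic roughly fills its centre: with extent data it
#' is a species covering more than half the centre's extent
#' (`area_fraction > 1/2`); without extent data, one occupying more than
#' two-thirds of the centre's OGUs.  A *narrow* endemic is confined to a
#' single OGU, a nested CONE, or less than half the centre's extent.  When
#' extent data is available it dominates the OGU-count rule (a species can
#' sit in both OGUs of a two-OGU centre yet cover a sliver of it).
#' Per-species ledger overrides (`override_narrow`, `override_not_narrow`)
#' take precedence over everything.
#'
#' @param centre one centre (list with `members`, `endemics`) from a
#'   `centre_set`
#' @param m an [incidence_matrix()]
#' @param area_fraction optional named numeric: per species, the fraction
#'   of the centre's extent (area) its range covers
#' @param cone_members optional character vector of OGUs belonging to CONEs
#'   nested in this centre
#' @param overrides optional named character vector per species with values
#'   `"narrow"` or `"not_narrow"`
#' @return data.frame with `species_id` and `label` in
#'   `c("characteristic", "narrow", "other")`
#' @export
classify_characteristic_narrow <- function(centre, m, area_fraction = NULL,
                                           cone_members = character(),
                                           overrides = NULL) {
  members <- centre$members
  labs <- vapply(centre$endemics, function(sp) {
    rng <- species_range(m, sp)
    ogu_frac <- length(intersect(rng, members)) / length(members)
    af <- if (!is.null(area_fraction) && sp %in% names(area_fraction))
      area_fraction[[sp]] else NA_real_
    ov <- if (!is.null(overrides) && sp %in% names(overrides))
      overrides[[sp]] else NA_character_
    if (!is.na(ov)) {
      if (ov == "narrow") return("narrow")
      # overridden away from narrow: characteristic if it fills the centre
      if (!is.na(af) && af > 0.5) return("characteristic")
      return(if (ogu_frac > 2 / 3) "characteristic" else "other")
    }
    if (!is.na(af)) {
      if (af > 0.5) return("characteristic")
      return("narrow")                        # < half the centre's extent
    }
    if (ogu_frac > 2 / 3) return("characteristic")
    if (length(rng) == 1L || all(rng %in% cone_members)) return("narrow")
    if (ogu_frac < 0.5) return("narrow")
    "other"
  }, "")
  data.frame(species_id = centre$endemics, label = labs,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarise endemism over a set of named regions
#'
#' Produces a Table-2-style summary: one row per species with endemic flags
#' per region, plus totals (endemics, species present) and percentage rows.
#'
#' @param m an [incidence_matrix()]
#' @param regions named list of OGU-id vectors
#' @return list with `flags` (species x region 0/1 data.frame),
#'   `totals` (per region: n_endemic, n_present, pct_endemicity)
#' @export
summarise_endemism <- function(m, regions) {
  if (!length(regions)) stop("no regions given")
  cls <- lapply(regions, function(r) classify_endemics(m, r))
  flags <- as.data.frame(lapply(cls, function(cl)
    as.integer(cl$status$status == "endemic")))
  rownames(flags) <- species_ids(m)
  totals <- data.frame(
    region = names(regions),
    n_endemic = vapply(cls, `[[`, 0L, "n_endemic"),
    n_present = vapply(cls, `[[`, 0L, "n_present"),
    pct_endemicity = round(vapply(cls, `[[`, 0, "pct_endemicity"), 1),
    row.names = NULL, stringsAsFactors = FALSE)
  list(flags = flags, totals = totals)
}
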