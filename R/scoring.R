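#' QDS-level occupancy records
#'
#' Fine-grid occupancy used to score OGU-level presence.  Each record is one
#' occupied quarter-degree square (QDS) of one species in one OGU, tagged by
#' position within the OGU (`interior`/`marginal`) and by coastal status of
#' that square within the species' range (`coastal`/`inland`).  Marginal
#' squares may carry the id of the OGU across the shared margin
#' (`margin_neighbor`), which clause 3 of the scoring rule needs.
#'
#' @param records data.frame with columns `species`, `ogu`, `qds`,
#'   `position` (`interior`|`marginal`), `coast` (`coastal`|`inland`) and
#'   optionally `margin_neighbor` (OGU id or NA)
#' @param ogu_n_qds named integer vector: total QDS count per OGU
#' @return object of class `qds_occupancy`
#' @export
qds_occupancy <- function(records, ogu_n_qds) {
  need <- c("species", "ogu", "qds", "position", "coast")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop(sprintf("occupancy records missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (!all(records$position %in% c("interior", "marginal")))
    stop("position tags must be 'interior' or 'marginal'")
  if (!all(records$coast %in% c("coastal", "inland")))
    stop("coast tags must be 'coastal' or 'inland'")
  if (is.null(records$margin_neighbor))
    records$margin_neighbor <- NA_character_
  unk <- setdiff(records$ogu, names(ogu_n_qds))
  if (length(unk))
    stop(sprintf("no QDS total for OGU(s): %s", paste(unk, collapse = ", ")))
  structure(list(records = records, ogu_n_qds = ogu_n_qds),
            class = "qds_occupancy")
}

#' Read QDS occupancy from a long-format CSV
#' @param path CSV with the columns of [qds_occupancy()]
#' @param ogu_n_qds named integer vector of per-OGU QDS totals
#' @return a `qds_occupancy`
#' @export
read_qds_occupancy <- function(path, ogu_n_qds) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  qds_occupancy(df, ogu_n_qds)
}

#' Score OGU-level presence from QDS occupancy
#'
#' Implements the four-clause presence rule used when collapsing fine-grid
#' records to OGU incidence:
#' 1. any occupied *interior* QDS makes the species present;
#' 2. with only marginal QDSs, the species is present if it occupies more
#'    than `threshold` (strictly) of the OGU's QDSs;
#' 3. otherwise it is present if it is absent from the neighbouring OGU(s)
#'    across the occupied margins;
#' 4. otherwise it is present if an occupied marginal QDS lies on the
#'    coastal margin of the species' range.
#' Anything else scores absent.
#'
#' @param occ a [qds_occupancy()]
#' @param species species id
#' @param ogu OGU id
#' @param neighbor_presence named logical vector: is the species present in
#'   each (relevant) neighbouring OGU?
#' @param threshold marginal-occupancy fraction above which presence is
#'   granted regardless of neighbours (strict `>`, default 0.10)
#' @return logical scalar
#' @export
score_presence <- function(occ, species, ogu, neighbor_presence = logical(),
                           threshold = 0.10) {
  stopifnot(inherits(occ, "qds_occupancy"),
            threshold > 0, threshold < 1)
  if (!ogu %in% names(occ$ogu_n_qds))
    stop(sprintf("unknown OGU '%s'", ogu))
  if (!species %in% occ$records$species)
    stop(sprintf("unknown species '%s'", species))
  rec <- occ$records[occ$records$species == species &
                       occ$records$ogu == ogu, , drop = FALSE]
  if (!nrow(rec)) return(FALSE)
  if (any(rec$position == "interior")) return(TRUE)           # clause 1
  frac <- nrow(rec) / occ$ogu_n_qds[[ogu]]
  if (frac > threshold) return(TRUE)                          # clause 2
  nb <- unique(rec$margin_neighbor[!is.na(rec$margin_neighbor)])
  if (!length(nb))
    stop(sprintf(paste0("species '%s' in OGU '%s': marginal QDSs without ",
                        "recorded margin neighbours; adjacency needed for ",
                        "clause 3"), species, ogu))
  known <- nb %in% names(neighbor_presence)
  if (!all(known))
    stop(sprintf("no neighbour presence given for OGU(s): %s",
                 paste(nb[!known], collapse = ", ")))
  if (!any(unlist(neighbor_presence[nb]))) return(TRUE)       # clause 3
  any(rec$coast == "coastal")                                 # clause 4
}

#' Score a full incidence matrix from QDS occupancy
#'
#' Applies [score_presence()] to every (species, OGU) pair with occupancy
#' records.  Neighbour presence for clause 3 is resolved by a fixed point:
#' start from "present wherever any QDS is occupied", then re-score until
#' stable (marginal-only occurrences can only switch off, so this
#' terminates).
#'
#' @param occ a [qds_occupancy()]
#' @param species_ids,ogu_ids row/column universe of the output matrix
#' @param threshold see [score_presence()]
#' @return an [incidence_matrix()]
#' @export
score_incidence <- function(occ, species_ids = NULL, ogu_ids = NULL,
                            threshold = 0.10) {
  rec <- occ$records
  if (is.null(species_ids)) species_ids <- sort(unique(rec$species))
  if (is.null(ogu_ids)) ogu_ids <- sort(unique(names(occ$ogu_n_qds)))
  cells <- matrix(0L, length(species_ids), length(ogu_ids),
                  dimnames = list(species_ids, ogu_ids))
  cells[cbind(rec$species, rec$ogu)] <- 1L
  repeat {
    changed <- FALSE
    for (sp in species_ids) {
      for (og in ogu_ids) {
        if (cells[sp, og] == 0L) next
        nbp <- as.logical(cells[sp, ])
        names(nbp) <- ogu_ids
        val <- score_presence(occ, sp, og, nbp, threshold)
        if (!val) {
          cells[sp, og] <- 0L
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  incidence_matrix(cells)
}
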