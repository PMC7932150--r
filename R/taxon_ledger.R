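#' Declarative taxon ledger
#'
#' Taxonomic decisions (exclusions, synonymies, species-complex merges) are
#' data, not code, so alternative taxonomies stay testable.  A ledger is a
#' list of rules; each rule is a list with a `kind` field:
#' \describe{
#'   \item{exclude}{`list(kind = "exclude", name = "x")` removes a taxon.}
#'   \item{synonymise}{`list(kind = "synonymise", junior = "x", senior =
#'     "y")` folds the junior name into the senior; ranges are unioned.}
#'   \item{merge_complex}{`list(kind = "merge_complex", members = c("a",
#'     "b"), new_name = "a-b")` replaces the members by one complex whose
#'     range is the union of the member ranges.}
#' }
#'
#' @param rules list of rule lists as described above
#' @return object of class `taxon_ledger`
#' @export
taxon_ledger <- function(rules = list()) {
  kinds <- vapply(rules, function(r) r$kind %||% "", "")
  ok <- kinds %in% c("exclude", "synonymise", "merge_complex")
  if (length(rules) && !all(ok))
    stop(sprintf("unknown ledger rule kind(s): %s",
                 paste(unique(kinds[!ok]), collapse = ", ")))
  touched <- unlist(lapply(rules, function(r)
    switch(r$kind, exclude = r$name, synonymise = r$junior,
           merge_complex = r$members)))
  dup <- unique(touched[duplicated(touched)])
  if (length(dup))
    stop(sprintf("conflicting ledger rules on name(s): %s",
                 paste(dup, collapse = ", ")))
  structure(list(rules = rules), class = "taxon_ledger")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a taxon ledger from JSON
#' @param path JSON file: array of rule objects
#' @return a [taxon_ledger()]
#' @export
read_taxon_ledger <- function(path) {
  taxon_ledger(jsonlite::fromJSON(path, simplifyDataFrame = FALSE))
}

#' Apply a taxon ledger to a registry or incidence matrix
#'
#' Applied to an `incidence_matrix`, merged or synonymised taxa union their
#' ranges (per-OGU logical OR) and excluded taxa are dropped; applied to a
#' registry `data.frame`, only the name list is transformed.  Rules
#' referencing names absent from the registry are an error.
#'
#' @param x an [incidence_matrix()] or a species registry `data.frame`
#'   (with a `species_id` column)
#' @param ledger a [taxon_ledger()]
#' @return object of the same type as `x`, with a `"n_taxa"` attribute
#'   giving the resulting taxon count
#' @export
apply_taxon_ledger <- function(x, ledger) {
  stopifnot(inherits(ledger, "taxon_ledger"))
  is_mat <- inherits(x, "incidence_matrix")
  reg <- if (is_mat) x$species else x
  if (is.null(reg$species_id)) stop("registry needs a species_id column")
  ids <- reg$species_id
  cells <- if (is_mat) x$cells else NULL

  need <- function(nm) {
    absent <- setdiff(nm, ids)
    if (length(absent))
      stop(sprintf("ledger rule references unknown name(s): %s",
                   paste(absent, collapse = ", ")))
  }
  for (r in ledger$rules) {
    switch(r$kind,
      exclude = {
        need(r$name)
        keep <- ids != r$name
        reg <- reg[keep, , drop = FALSE]
        if (!is.null(cells)) cells <- cells[keep, , drop = FALSE]
        ids <- ids[keep]
      },
      synonymise = {
        need(c(r$junior, r$senior))
        if (!is.null(cells))
          cells[r$senior, ] <- pmax(cells[r$senior, ], cells[r$junior, ])
        keep <- ids != r$junior
        reg <- reg[keep, , drop = FALSE]
        if (!is.null(cells)) cells <- cells[keep, , drop = FALSE]
        ids <- ids[keep]
      },
      merge_complex = {
        members <- unlist(r$members)
        need(members)
        if (length(members) < 2) stop("merge_complex needs >= 2 members")
        first <- match(members[1], ids)
        if (!is.null(cells)) {
          merged <- as.integer(colSums(cells[members, , drop = FALSE]) > 0)
          cells[first, ] <- merged
        }
        reg$species_id[first] <- r$new_name
        if (!is.null(reg$name)) reg$name[first] <- r$new_name
        if (!is.null(reg$status_flags))
          reg$status_flags[first] <- "merged_complex"
        keep <- !(ids %in% members[-1])
        reg <- reg[keep, , drop = FALSE]
        if (!is.null(cells)) {
          rownames(cells)[first] <- r$new_name
          cells <- cells[keep, , drop = FALSE]
        }
        ids <- reg$species_id
      })
    ids <- reg$species_id
  }
  rownames(reg) <- NULL
  out <- if (is_mat) {
    incidence_matrix(cells, species = reg, ogus = x$ogus)
  } else reg
  attr(out, "n_taxa") <- nrow(reg)
  out
}
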