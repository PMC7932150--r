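#' Binary species x OGU incidence matrix
#'
#' The central container of the package: a binary matrix recording the
#' presence (1) or absence (0) of each species in each operational
#' geographic unit (OGU), together with a species registry and an OGU
#' registry.  Rows are species, columns are OGUs; row and column order is
#' preserved exactly as given, so files round-trip bit-identically.
#'
#' @param cells binary matrix (species x OGU) with rownames (species ids)
#'   and colnames (OGU ids); values must be 0/1.
#' @param species optional species registry `data.frame` with at least a
#'   `species_id` column matching `rownames(cells)`; extra columns (`name`,
#'   `genus`, `family`, `status_flags`) are carried along.
#' @param ogus optional OGU registry `data.frame` with at least an `ogu_id`
#'   column matching `colnames(cells)`; optional `name`, `area_km2`,
#'   `n_qds` columns.
#' @return an object of class `incidence_matrix`.
#' @export
incidence_matrix <- function(cells, species = NULL, ogus = NULL) {
  cells <- as.matrix(cells)
  # R drops zero-length dimnames; tolerate them on empty margins
  if ((nrow(cells) > 0L && is.null(rownames(cells))) ||
      (ncol(cells) > 0L && is.null(colnames(cells))))
    stop("cells must have species rownames and OGU colnames")
  storage.mode(cells) <- "integer"
  bad <- which(!(cells %in% c(0L, 1L)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(cells)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(cells)) + 1L
    stop(sprintf("non-binary cell at species '%s', OGU '%s'",
                 rownames(cells)[i], colnames(cells)[j]))
  }
  check_unique(rownames(cells), "species id")
  check_unique(colnames(cells), "OGU id")
  if (is.null(species))
    species <- data.frame(species_id = rownames(cells),
                          stringsAsFactors = FALSE)
  if (is.null(ogus))
    ogus <- data.frame(ogu_id = colnames(cells), stringsAsFactors = FALSE)
  chr0 <- function(x) as.character(if (is.null(x)) character() else x)
  stopifnot(identical(chr0(species$species_id), chr0(rownames(cells))),
            identical(chr0(ogus$ogu_id), chr0(colnames(cells))))
  if (!is.null(ogus$area_km2) && any(ogus$area_km2 < 0, na.rm = TRUE))
    stop("OGU areas must be nonnegative")
  structure(list(cells = cells, species = species, ogus = ogus),
            class = "incidence_matrix")
}

check_unique <- function(x, what) {
  d <- unique(x[duplicated(x)])
  if (length(d))
    stop(sprintf("duplicate %s: %s", what, paste(d, collapse = ", ")))
  invisible(x)
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("<incidence_matrix> %d species x %d OGUs, %d presences\n",
              nrow(x$cells), ncol(x$cells), sum(x$cells)))
  invisible(x)
}

#' @export
dim.incidence_matrix <- function(x) dim(x$cells)

#' Species ids of an incidence matrix
#' @param m an `incidence_matrix`
#' @return character vector of species ids
#' @export
species_ids <- function(m) rownames(m$cells)

#' OGU ids of an incidence matrix
#' @param m an `incidence_matrix`
#' @return character vector of OGU ids
#' @export
ogu_ids <- function(m) colnames(m$cells)

#' Occupied OGU set (range) of one species
#' @param m an `incidence_matrix`
#' @param species species id
#' @return character vector of OGU ids where the species is present
#' @export
species_range <- function(m, species) {
  if (!species %in% rownames(m$cells))
    stop(sprintf("unknown species '%s'", species))
  colnames(m$cells)[m$cells[species, ] == 1L]
}

#' Read an incidence matrix from a delimited file
#'
#' The file must have OGU ids in the header and species ids in the first
#' column.  The delimiter is sniffed (comma or tab) unless given.  Cell
#' tokens listed in `truthy`/`falsy` are mapped to 1/0; anything else is an
#' error naming the offending row and column.
#'
#' @param path file path
#' @param sep field separator; `NULL` (default) sniffs comma vs tab from the
#'   header line
#' @param truthy,falsy character vectors of tokens read as presence/absence
#' @return an [incidence_matrix()]
#' @export
read_incidence <- function(path, sep = NULL, truthy = "1", falsy = "0") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  ogu <- as.character(raw[1, -1])
  sp <- as.character(raw[-1, 1])
  check_unique(ogu, "OGU id")
  check_unique(sp, "species id")
  body <- as.matrix(raw[-1, -1, drop = FALSE])
  cells <- matrix(NA_integer_, nrow = length(sp), ncol = length(ogu),
                  dimnames = list(sp, ogu))
  cells[body %in% truthy] <- 1L
  cells[body %in% falsy] <- 0L
  if (anyNA(cells)) {
    idx <- which(is.na(cells), arr.ind = TRUE)[1, ]
    stop(sprintf("non-binary cell '%s' at species '%s', OGU '%s'",
                 body[idx[1], idx[2]], sp[idx[1]], ogu[idx[2]]))
  }
  incidence_matrix(cells)
}

#' Write an incidence matrix to a delimited file
#' @param m an `incidence_matrix`
#' @param path output path
#' @param sep field separator (default comma)
#' @return `path`, invisibly
#' @export
write_incidence <- function(m, path, sep = ",") {
  df <- data.frame(species = rownames(m$cells), m$cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Prune an incidence matrix
#'
#' Removes rows and columns that carry no grouping information: species
#' present everywhere or nowhere and (optionally) species restricted to a
#' single OGU are uninformative characters; OGUs with no recorded species
#' can be dropped before clustering.  A report lists every removal by id.
#'
#' @param m an `incidence_matrix`
#' @param drop_empty_ogus drop OGUs with zero presences
#' @param drop_uninformative_species drop constant and single-OGU species
#' @return list with elements `matrix` (pruned `incidence_matrix`) and
#'   `report` (lists `empty_ogus`, `constant_species`, `singleton_species`)
#' @export
prune_matrix <- function(m, drop_empty_ogus = TRUE,
                         drop_uninformative_species = TRUE) {
  cells <- m$cells
  report <- list(empty_ogus = character(), constant_species = character(),
                 singleton_species = character())
  # dropping an OGU can render a species constant and vice versa; iterate
  # to the fixed point so pruning is idempotent
  repeat {
    changed <- FALSE
    if (drop_empty_ogus && ncol(cells)) {
      empty <- colSums(cells) == 0L
      if (any(empty)) {
        report$empty_ogus <- c(report$empty_ogus, colnames(cells)[empty])
        cells <- cells[, !empty, drop = FALSE]
        changed <- TRUE
      }
    }
    if (drop_uninformative_species && nrow(cells)) {
      rs <- rowSums(cells)
      const <- rs == 0L | rs == ncol(cells)
      single <- rs == 1L & !const
      if (any(const | single)) {
        report$constant_species <- c(report$constant_species,
                                     rownames(cells)[const])
        report$singleton_species <- c(report$singleton_species,
                                      rownames(cells)[single])
        cells <- cells[!(const | single), , drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (nrow(cells) == 0L || ncol(cells) == 0L)
    warning("pruning produced an empty matrix")
  out <- incidence_matrix(cells,
                          species = m$species[match(rownames(cells),
                                                    m$species$species_id), ,
                                              drop = FALSE],
                          ogus = m$ogus[match(colnames(cells),
                                              m$ogus$ogu_id), , drop = FALSE])
  rownames(out$species) <- NULL
  rownames(out$ogus) <- NULL
  list(matrix = out, report = report)
}
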