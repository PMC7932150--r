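#' Per-OGU metric surface
#'
#' A named per-OGU numeric layer with min-max normalisation and (optional)
#' natural-breaks class assignment.
#'
#' @param metric_name short name
#' @param values named numeric vector (OGU -> raw value)
#' @param k number of classes for Fisher-Jenks classing; `NA` entries are
#'   excluded from normalisation and classing and get class `NA`
#' @return object of class `metric_surface` (data.frame: ogu, value,
#'   normalised, class)
#' @export
metric_surface <- function(metric_name, values, k = 5) {
  ok <- !is.na(values)
  v <- values[ok]
  normalised <- rep(NA_real_, length(values))
  if (length(v)) {
    rng <- range(v)
    normalised[ok] <- if (rng[2] > rng[1])
      (v - rng[1]) / (rng[2] - rng[1]) else 0
  }
  cls <- rep(NA_integer_, length(values))
  kk <- min(k, length(unique(v)))
  if (length(v) && kk >= 1)
    cls[ok] <- jenks_breaks(v, kk)$class
  out <- data.frame(ogu = names(values), value = unname(values),
                    normalised = normalised, class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "metric_name") <- metric_name
  class(out) <- c("metric_surface", "data.frame")
  out
}

#' Species richness per OGU
#' @param m an [incidence_matrix()]
#' @param k classes for Jenks classing (default 5)
#' @return a [metric_surface()]
#' @export
species_richness <- function(m, k = 5) {
  metric_surface("richness", colSums(m$cells), k = k)
}

#' Dominion endemism per OGU
#'
#' Per OGU, the count of present species whose entire range lies within
#' the dominion.  With `dominion` equal to all OGUs this reduces to species
#' richness.
#'
#' @param m an [incidence_matrix()]
#' @param dominion character vector of OGU ids
#' @param within restrict the output surface to dominion OGUs (default
#'   TRUE, matching the study's maps); otherwise all OGUs are reported
#' @param k classes for Jenks classing
#' @return a [metric_surface()]
#' @export
dominion_endemism <- function(m, dominion, within = TRUE, k = 5) {
  cl <- classify_endemics(m, dominion)
  endem <- cl$status$status == "endemic"
  counts <- colSums(m$cells[endem, , drop = FALSE])
  if (within) counts <- counts[dominion]
  metric_surface("dominion_endemism", counts, k = k)
}

#' Narrow-endemic species flags
#'
#' A species is narrow when (in rule order) it is restricted to a single
#' OGU (`single_ogu`), its range lies inside a CONE (`cone_restricted`),
#' or it is endemic to a COE and occupies less than half of that centre's
#' range (`half_coe_range`); explicit ledger overrides win
#' (`override`).
#'
#' @param m an [incidence_matrix()]
#' @param cones optional CONE `centre_set`
#' @param coes optional COE `centre_set`
#' @param coe_area_fraction optional named numeric: species -> fraction of
#'   its COE's extent covered (used instead of the OGU-count proxy)
#' @param overrides named character vector, values `"narrow"`/`"not_narrow"`
#' @return data.frame: species_id, narrow (logical), provenance
#' @export
narrow_endemism_flags <- function(m, cones = NULL, coes = NULL,
                                  coe_area_fraction = NULL,
                                  overrides = NULL) {
  if (!is.null(overrides)) {
    bad <- names(overrides)[duplicated(names(overrides))]
    if (length(bad))
      stop(sprintf("conflicting overrides for: %s", paste(bad, collapse = ", ")))
  }
  cone_units <- if (!is.null(cones))
    lapply(cones$centres, `[[`, "members") else list()
  coe_units <- if (!is.null(coes))
    lapply(coes$centres, `[[`, "members") else list()
  res <- lapply(species_ids(m), function(sp) {
    rng <- species_range(m, sp)
    narrow <- FALSE; prov <- NA_character_
    if (length(rng) == 1L) {
      narrow <- TRUE; prov <- "single_ogu"
    } else if (length(rng) &&
               any(vapply(cone_units, function(u) all(rng %in% u), TRUE))) {
      narrow <- TRUE; prov <- "cone_restricted"
    } else if (length(rng)) {
      for (u in coe_units) {
        if (!all(rng %in% u)) next
        frac <- if (!is.null(coe_area_fraction) &&
                    sp %in% names(coe_area_fraction))
          coe_area_fraction[[sp]] else length(rng) / length(u)
        if (frac < 0.5) { narrow <- TRUE; prov <- "half_coe_range"; break }
      }
    }
    if (!is.null(overrides) && sp %in% names(overrides)) {
      narrow <- overrides[[sp]] == "narrow"
      prov <- "override"
    }
    data.frame(species_id = sp, narrow = narrow, provenance = prov,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Narrow endemism per OGU
#'
#' Count of narrow-flagged species present in each OGU.
#'
#' @param m an [incidence_matrix()]
#' @param flags result of [narrow_endemism_flags()] (or a named logical)
#' @param within optional OGU subset (e.g. the dominion)
#' @param k classes for Jenks classing
#' @return a [metric_surface()]
#' @export
narrow_endemism <- function(m, flags, within = NULL, k = 5) {
  fl <- if (is.data.frame(flags))
    stats::setNames(flags$narrow, flags$species_id) else flags
  fl <- fl[species_ids(m)]
  fl[is.na(fl)] <- FALSE
  counts <- colSums(m$cells[fl, , drop = FALSE])
  if (!is.null(within)) counts <- counts[within]
  metric_surface("narrow_endemism", counts, k = k)
}

#' Weighted endemism per OGU
#'
#' WE(u) is the sum over species present in u of the reciprocal of the
#' species' range size (number of occupied OGUs), so a single-OGU endemic
#' contributes 1 and a widespread species very little.  Summed over all
#' OGUs, WE equals the number of species with non-empty ranges.
#'
#' @param m an [incidence_matrix()]
#' @param within optional OGU subset for the output surface
#' @param k classes for Jenks classing
#' @return a [metric_surface()]
#' @export
weighted_endemism <- function(m, within = NULL, k = 5) {
  rs <- rowSums(m$cells)
  w <- ifelse(rs > 0, 1 / rs, 0)
  we <- colSums(m$cells * w)
  if (!is.null(within)) we <- we[within]
  metric_surface("weighted_endemism", we, k = k)
}

#' Corrected weighted endemism per OGU
#'
#' CWE(u) = WE(u) / richness(u), the mean range-restriction of the local
#' assemblage; lies in (0, 1] wherever richness is positive and is 1 for an
#' OGU holding only single-OGU endemics.  Zero-richness OGUs are undefined
#' and reported as `NA` (excluded from normalisation and classing).
#'
#' @param we a [weighted_endemism()] surface
#' @param richness a [species_richness()] surface over the same OGUs
#' @param k classes for Jenks classing
#' @return a [metric_surface()]
#' @export
corrected_weighted_endemism <- function(we, richness, k = 5) {
  stopifnot(identical(we$ogu, richness$ogu))
  cwe <- ifelse(richness$value > 0, we$value / richness$value, NA_real_)
  metric_surface("corrected_weighted_endemism",
                 stats::setNames(cwe, we$ogu), k = k)
}

#' Fisher-Jenks natural breaks
#'
#' Optimal 1-D classification minimising the total within-class sum of
#' squared deviations, by dynamic programming over the distinct sorted
#' values (so tied values can never be split across classes).
#'
#' @param values numeric vector
#' @param k number of classes (at most the number of distinct values)
#' @return list: `breaks` (k+1 boundaries, min..max), `class` (per input
#'   value, 1..k in increasing value order), `ssd` (total within-class SSD)
#' @export
jenks_breaks <- function(values, k) {
  stopifnot(k >= 1)
  tab <- sort(unique(values))
  nd <- length(tab)
  if (k > nd) stop(sprintf("k = %d exceeds %d distinct values", k, nd))
  w <- as.numeric(tabulate(match(values, tab), nbins = nd))
  # prefix sums for weighted SSD of value ranges
  cw <- cumsum(w); cwx <- cumsum(w * tab); cwx2 <- cumsum(w * tab^2)
  seg <- function(i, j) {        # weighted SSD of distinct values i..j
    W <- cw[j] - if (i > 1) cw[i - 1] else 0
    S <- cwx[j] - if (i > 1) cwx[i - 1] else 0
    S2 <- cwx2[j] - if (i > 1) cwx2[i - 1] else 0
    S2 - S^2 / W
  }
  cost <- matrix(Inf, k, nd)
  back <- matrix(0L, k, nd)
  for (j in seq_len(nd)) cost[1, j] <- seg(1, j)
  if (k > 1) {
    for (cls in 2:k) {
      for (j in cls:nd) {
        for (i in cls:j) {
          cand <- cost[cls - 1, i - 1] + seg(i, j)
          if (cand < cost[cls, j] - 1e-12) {
            cost[cls, j] <- cand
            back[cls, j] <- i
          }
        }
      }
    }
  }
  # recover class boundaries over distinct values
  bounds <- integer(k + 1); bounds[k + 1] <- nd
  j <- nd
  if (k > 1) {
    for (cls in k:2) {
      i <- back[cls, j]
      bounds[cls] <- i - 1L
      j <- i - 1L
    }
  }
  bounds[1] <- 0L
  cls_of_distinct <- rep(seq_len(k), diff(bounds))
  class_assign <- cls_of_distinct[match(values, tab)]
  breaks <- c(tab[1], tab[bounds[2:(k + 1)]])
  list(breaks = breaks, class = class_assign, ssd = cost[k, nd])
}
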