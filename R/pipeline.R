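#' Default pipeline configuration
#'
#' A nested list with every tunable of the full analysis.  All seeds are
#' explicit.  Fields: `phenon` (named thresholds or `"auto"` levels),
#' `coe` (`min_endemics`), `cone` (`min_narrow`, `similarity`, `max_ogus`),
#' `pae` (`n_replicates`, `max_trees`, `max_rounds`, `seed`),
#' `bea` (`metric`, `prop`, `n_sim`, `seed`, `dims`, `n_restarts`,
#' `max_k`, `neighbor_cap`), `metrics` (`k_classes`).
#'
#' @param seed master seed; stage seeds default to offsets of it
#' @return a config list
#' @export
default_config <- function(seed = 1) {
  list(
    phenon = list(auto_levels = c("dominion", "province", "district")),
    coe = list(min_endemics = 4),
    cone = list(min_narrow = 2, similarity = NA_real_, max_ogus = 3),
    pae = list(n_replicates = 3, max_trees = 200, max_rounds = 30,
               seed = seed + 100),
    bea = list(metric = "kulczynski", prop = 0.25, n_sim = 199,
               seed = seed + 200, dims = 2, n_restarts = 8,
               max_k = 9, neighbor_cap = NA_integer_),
    metrics = list(k_classes = 5),
    seed = seed)
}

#' Validate a pipeline configuration
#'
#' @param config a config list as from [default_config()]
#' @return `TRUE` invisibly, or stops with an aggregated error message
#' @export
validate_config <- function(config) {
  errs <- character()
  ph <- config$phenon
  if (!is.null(ph$thresholds)) {
    if (length(ph$thresholds) > 1 && any(diff(ph$thresholds) <= 0))
      errs <- c(errs, "phenon thresholds must be strictly increasing")
    if (any(ph$thresholds < 0 | ph$thresholds > 1))
      errs <- c(errs, "phenon thresholds must lie in [0, 1]")
  }
  if (!is.null(config$bea$prop) &&
      (config$bea$prop <= 0 || config$bea$prop > 0.5))
    errs <- c(errs, "bea$prop must lie in (0, 0.5]")
  if (!is.null(config$coe$min_endemics) && config$coe$min_endemics < 1)
    errs <- c(errs, "coe$min_endemics must be >= 1")
  if (!is.null(config$metrics$k_classes) &&
      (config$metrics$k_classes < 1 || config$metrics$k_classes > 5))
    errs <- c(errs, "metrics$k_classes must be in 1..5")
  if (length(errs)) stop(paste(errs, collapse = "; "))
  invisible(TRUE)
}

pipeline_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full analysis pipeline
#'
#' Incidence -> Jaccard/UPGMA -> phenon regionalisation -> centres of
#' endemism -> PAE -> BEA -> endemism surfaces, writing every artifact to
#' `out_dir` and returning the results in memory with a manifest of files,
#' seeds and checksums.
#'
#' @param m an [incidence_matrix()]
#' @param g an [adjacency_graph()]
#' @param out_dir output directory (created if missing)
#' @param config a config list, see [default_config()]
#' @param quiet suppress progress messages
#' @return list of stage results plus `manifest`
#' @export
run_pipeline <- function(m, g, out_dir = tempfile("zooregion_"),
                         config = default_config(), quiet = FALSE) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  gg <- if (!is.na(config$bea$neighbor_cap %||% NA))
    cap_neighbors(g, config$bea$neighbor_cap) else g

  pipeline_log(quiet, "[similarity] %d OGUs", length(ogu_ids(m)))
  sim <- stage("similarity", jaccard_similarity(m))
  write_similarity(sim, art("similarity.csv"))
  dend <- stage("upgma", upgma(sim))
  writeLines(to_newick(dend), art("dendrogram.nwk"))

  scheme <- stage("phenon", {
    if (!is.null(config$phenon$thresholds))
      phenon_scheme(config$phenon$thresholds)
    else propose_phenon_scheme(dend, config$phenon$auto_levels)
  })
  pipeline_log(quiet, "[regionalise] levels: %s",
               paste(sprintf("%s=%.3f", scheme$levels, scheme$thresholds),
                     collapse = ", "))
  hier <- stage("regionalise", build_hierarchy(dend, scheme, g, sim, m))
  write_hierarchy(hier, art("hierarchy.tsv"))

  pipeline_log(quiet, "[centres]")
  coes <- stage("centres", identify_coes(hier, m,
                                         config$coe$min_endemics))
  cone_sim <- config$cone$similarity
  if (is.na(cone_sim))
    cone_sim <- min(1, utils::tail(scheme$thresholds, 1) + 0.15)
  flags0 <- narrow_endemism_flags(m)          # stage 1: single-OGU rule
  cones <- stage("centres", identify_cones(dend, m,
    stats::setNames(flags0$narrow, flags0$species_id),
    config$cone$min_narrow, cone_sim, config$cone$max_ogus))
  flags <- narrow_endemism_flags(m, cones = cones, coes = coes)
  centre_rows <- do.call(rbind, lapply(c(coes$centres, cones$centres),
    function(cn) data.frame(centre = cn$name, kind = cn$kind,
                            members = paste(cn$members, collapse = ","),
                            n_endemics = length(cn$endemics),
                            endemics = paste(cn$endemics, collapse = ","),
                            stringsAsFactors = FALSE)))
  if (is.null(centre_rows))
    centre_rows <- data.frame(centre = character(), kind = character(),
                              members = character(), n_endemics = integer(),
                              endemics = character())
  utils::write.table(centre_rows, art("centres.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  pipeline_log(quiet, "[endemism summary]")
  finest <- level_partition(hier)
  regions <- split(names(finest), finest)
  summ <- stage("summary", summarise_endemism(m, regions))
  utils::write.table(
    cbind(species = rownames(summ$flags), summ$flags), art("endemism.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)

  pipeline_log(quiet, "[pae]")
  pae_res <- stage("pae", {
    pm <- prepare_pae_matrix(m)
    write_pae_nexus(pm, art("pae_matrix.nex"))
    srch <- heuristic_search(pm, config$pae$n_replicates, config$pae$seed,
                             config$pae$max_trees, config$pae$max_rounds)
    cons <- strict_consensus(srch$trees)
    ape::write.tree(cons, art("pae_consensus.nwk"))
    aoes <- extract_aoes(cons, m, g, pm$report$singleton_species)
    aoe_rows <- do.call(rbind, lapply(aoes$aoes, function(a)
      data.frame(members = paste(a$members, collapse = ","),
                 n_species = length(a$species),
                 species = paste(a$species, collapse = ","),
                 provenance = a$provenance, stringsAsFactors = FALSE)))
    if (is.null(aoe_rows))
      aoe_rows <- data.frame(members = character(), n_species = integer(),
                             species = character(), provenance = character())
    utils::write.table(aoe_rows, art("aoes.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    list(pm = pm, search = srch, consensus = cons, aoes = aoes)
  })

  pipeline_log(quiet, "[bea]")
  bea_res <- stage("bea", {
    m_occ <- prune_matrix(m, drop_empty_ogus = FALSE,
                          drop_uninformative_species = FALSE)$matrix
    keep <- rowSums(m_occ$cells) > 0
    m_occ <- incidence_matrix(m_occ$cells[keep, , drop = FALSE])
    test <- clustering_test(m_occ, gg, config$bea$n_sim, config$bea$seed,
                            config$bea$prop, config$bea$metric)
    rd <- range_distance(m_occ, config$bea$metric)
    emb <- nmds(rd, config$bea$dims, config$bea$n_restarts,
                config$bea$seed + 1)
    elems <- cluster_elements(emb$coords, config$bea$max_k,
                              config$bea$seed + 2)
    jsonlite::write_json(list(t_observed = test$t_observed,
                              null_mean = mean(test$t_simulated),
                              null_range = range(test$t_simulated),
                              p_value = test$p_value, n_sim = test$n_sim,
                              prop = test$prop, metric = test$metric,
                              seed = config$bea$seed,
                              nmds_stress = emb$stress,
                              k_elements = elems$k),
                         art("bea.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(
      data.frame(species = names(elems$assignment),
                 element = elems$assignment,
                 emb$coords, stringsAsFactors = FALSE),
      art("elements.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    list(test = test, nmds = emb, elements = elems)
  })

  pipeline_log(quiet, "[metrics]")
  metrics <- stage("metrics", {
    k <- config$metrics$k_classes
    dominion <- ogu_ids(m)
    h1 <- hier$levels[[1]]
    if (length(h1) > 1) {
      # dominion = level-1 region with the most species
      nsp <- vapply(h1, function(r) sum(m$cells[, r$members]), 0)
      dominion <- h1[[which.max(nsp)]]$members
    }
    rich <- species_richness(m, k)
    dome <- dominion_endemism(m, dominion, k = k)
    nar <- narrow_endemism(m, flags, within = dominion, k = k)
    we <- weighted_endemism(m, within = dominion, k = k)
    rich_dom <- species_richness(
      incidence_matrix(m$cells[, dominion, drop = FALSE]), k)
    cwe <- corrected_weighted_endemism(we, rich_dom, k)
    for (srf in list(rich, dome, nar, we, cwe))
      utils::write.table(srf,
        art(sprintf("metric_%s.tsv", attr(srf, "metric_name"))),
        sep = "\t", row.names = FALSE, quote = FALSE)
    list(richness = rich, dominion_endemism = dome, narrow_endemism = nar,
         weighted_endemism = we, corrected_weighted_endemism = cwe,
         dominion = dominion)
  })

  files <- sort(list.files(out_dir))
  manifest <- list(
    package = "zooregion",
    version = as.character(utils::packageVersion("zooregion")),
    seeds = list(pae = config$pae$seed, bea = config$bea$seed),
    artifacts = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE)
  pipeline_log(quiet, "[done] %d artifacts in %s", length(files) + 1, out_dir)

  invisible(list(similarity = sim, dendrogram = dend, scheme = scheme,
                 hierarchy = hier, coes = coes, cones = cones,
                 narrow_flags = flags, summary = summ, pae = pae_res,
                 bea = bea_res, metrics = metrics, manifest = manifest,
                 out_dir = out_dir))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `pipeline`.  `simulate` writes the synthetic
#' CSVs (incidence, adjacency, OGU registry, truth labels) for a preset;
#' `pipeline` runs [run_pipeline()] on an incidence CSV and adjacency CSV.
#' Exit is by condition: errors propagate (non-zero status under Rscript).
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`
#' @return invisibly, the subcommand's result
#' @export
zr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: zooregion <simulate|pipeline> [options]",
    "  simulate --preset NAME --seed N --out DIR",
    "  pipeline --incidence FILE --adjacency FILE --seed N --out DIR [--quiet]",
    sep = "\n")
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (!length(i)) return(default)
    if (i == length(args)) stop(sprintf("missing value for --%s", name))
    args[i + 1]
  }
  flag <- function(name) any(args == paste0("--", name))
  seed <- as.integer(opt("seed", "1"))
  out <- opt("out", "zooregion_out")
  switch(cmd,
    simulate = {
      preset <- opt("preset", "paperlike40x73")
      gen <- generate_species(scenario_preset(preset, seed))
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_incidence(gen$matrix, file.path(out, "incidence.csv"))
      el <- igraph::as_edgelist(gen$graph$graph)
      utils::write.csv(data.frame(ogu_a = el[, 1], ogu_b = el[, 2]),
                       file.path(out, "adjacency.csv"), row.names = FALSE,
                       quote = FALSE)
      utils::write.csv(gen$ogus, file.path(out, "ogus.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.table(
        data.frame(species = names(gen$truth$species),
                   home = gen$truth$species),
        file.path(out, "truth.tsv"), sep = "\t", row.names = FALSE,
        quote = FALSE)
      message(sprintf("wrote synthetic '%s' data to %s", preset, out))
      invisible(gen)
    },
    pipeline = {
      m <- read_incidence(opt("incidence"))
      g <- read_adjacency(opt("adjacency"), nodes = ogu_ids(m))
      invisible(run_pipeline(m, g, out, default_config(seed),
                             quiet = flag("quiet")))
    },
    stop(usage, call. = FALSE))
}
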