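## End-to-end pipeline: simulate or ingest -> essentiality screen ->
## profiles -> distances -> ordination/clustering -> regression report.
##
## Every stage writes diff-stable TSV/JSON files into the output directory,
## every table carries the canonical (sorted) organism order, and a rerun
## with an identical configuration reproduces identical bytes. Stages
## communicate only through these declared files/objects, so each can also
## be run standalone from intermediate files.

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate a community) or `"provided"` (read
#'   models, tree and taxonomy from `paths`).
#' @param sim a [sim_config()] (synthetic mode).
#' @param paths named list for provided mode: `models_dir`, `tree`,
#'   `taxonomy`, optional `annotations` (a binary matrix TSV).
#' @param screen a [screen_config()].
#' @param ordination list: `axes`, `top_n`, `perplexity` (NULL = auto),
#'   `tsne_seed`.
#' @param clustering list: `k` for the global complete-linkage cut, and
#'   optional `contrast = c(a, b)` cluster ids to tabulate differential
#'   reactions for.
#' @param regression list: `subsets` (`"auto"` or list of `"rank:label"`),
#'   `rmse_scale`, `window_fraction`.
#' @export
pipeline_config <- function(mode = c("synthetic", "provided"),
                            sim = sim_config(),
                            paths = list(),
                            screen = screen_config(),
                            ordination = list(axes = 2, top_n = 200,
                                              perplexity = NULL, tsne_seed = 42),
                            clustering = list(k = 5, contrast = NULL),
                            regression = list(subsets = "auto",
                                              rmse_scale = "log",
                                              window_fraction = 0.05)) {
  mode <- match.arg(mode)
  if (mode == "provided") {
    for (p in c("models_dir", "tree", "taxonomy")) {
      if (is.null(paths[[p]]))
        stop_validation("pipeline_config: provided mode requires paths$%s", p)
      if (!file.exists(paths[[p]]))
        stop_validation("pipeline_config: missing input %s: %s", p, paths[[p]])
    }
  }
  structure(list(mode = mode, sim = sim, paths = paths, screen = screen,
                 ordination = ordination, clustering = clustering,
                 regression = regression),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat per-stage keys mirroring [pipeline_config()] arguments; every CLI
#' flag has a config twin and CLI values override the file.
#' @param path YAML (or JSON) configuration file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop_validation("config file does not exist: %s", path)
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  screen_args <- y$screen %||% list()
  pipeline_config(
    mode = y$mode %||% "synthetic",
    sim = do.call(sim_config, sim_args),
    paths = y$paths %||% list(),
    screen = do.call(screen_config, screen_args),
    ordination = utils::modifyList(
      list(axes = 2, top_n = 200, perplexity = NULL, tsne_seed = 42),
      y$ordination %||% list()),
    clustering = utils::modifyList(list(k = 5, contrast = NULL),
                                   y$clustering %||% list()),
    regression = utils::modifyList(
      list(subsets = "auto", rmse_scale = "log", window_fraction = 0.05),
      y$regression %||% list()))
}

## per-class labels with >= 3 members plus the 3 best-populated genera
auto_subsets <- function(taxonomy) {
  subs <- character()
  if ("class" %in% colnames(taxonomy)) {
    tb <- table(taxonomy$class)
    subs <- c(subs, paste0("class:", names(tb)[tb >= 3]))
  }
  if ("genus" %in% colnames(taxonomy)) {
    tb <- sort(table(taxonomy$genus), decreasing = TRUE)
    tb <- tb[tb >= 3]
    subs <- c(subs, paste0("genus:", names(utils::head(tb, 3))))
  }
  as.list(subs)
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) a `report_bundle` list of file paths and in-memory
#'   results.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  log_lines <- character()
  logit <- function(msg, ...) {
    line <- sprintf(msg, ...)
    log_lines <<- c(log_lines, line)
    message("[microrep] ", line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_runtime("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  ## ---- inputs ---------------------------------------------------------
  annotations <- NULL
  if (config$mode == "synthetic") {
    community <- stage("simulate", simulate_community(config$sim))
    collection <- community$models
    tree <- community$tree
    taxonomy <- community$taxonomy
    stage("write_inputs", {
      write_model_dir(collection, p("models"))
      ape::write.tree(tree, p("tree.newick"))
      write_tsv_stable(taxonomy, p("taxonomy.tsv"))
      write_profile_tsv(community$profiles, p("profiles.tsv"))
      write_profile_tsv(truth_essential_profile(community), p("truth_essential.tsv"))
    })
    logit("simulated community: %d organisms, seed %d",
          config$sim$n_organisms, config$sim$seed)
  } else {
    collection <- stage("read_models", read_model_dir(config$paths$models_dir))
    tree <- stage("read_tree", read_newick(config$paths$tree))
    taxonomy <- stage("read_taxonomy", read_tsv_plain(config$paths$taxonomy))
    if (!"organism" %in% colnames(taxonomy))
      stop_runtime("pipeline stage 'read_taxonomy' failed: no 'organism' column")
    if (!is.null(config$paths$annotations)) {
      annotations <- tryCatch(
        read_profile_tsv(config$paths$annotations, "annotation"),
        error = function(e) {
          logit("optional annotation matrix skipped: %s", conditionMessage(e))
          NULL
        })
    }
    logit("loaded %d models", length(collection$models))
  }

  ## ---- essentiality screen -------------------------------------------
  screen <- stage("essentiality_screen", {
    lapply(collection$models, essential_nutrients, config = config$screen)
  })
  nutrient_ids <- sort(unique(unlist(lapply(screen, function(s) names(s$growth)))))
  orgs <- organism_ids(collection)
  ess_mat <- matrix(0L, length(orgs), length(nutrient_ids),
                    dimnames = list(orgs, nutrient_ids))
  growth_rows <- list()
  for (o in orgs) {
    ess_mat[o, screen[[o]]$essential] <- 1L
    growth_rows[[o]] <- data.frame(organism = o,
                                   metabolite = names(screen[[o]]$growth),
                                   growth_rate = unname(screen[[o]]$growth),
                                   essential = as.integer(names(screen[[o]]$growth)
                                                          %in% screen[[o]]$essential),
                                   stringsAsFactors = FALSE)
  }
  ess_profile <- binary_profile(ess_mat, "essential_nutrient")
  write_profile_tsv(ess_profile, p("essential_nutrients.tsv"))
  write_tsv_stable(do.call(rbind, c(growth_rows, make.row.names = FALSE)),
                   p("screen_growth.tsv"))
  logit("essentiality screen: %d organisms x %d nutrients",
        length(orgs), length(nutrient_ids))

  ## ---- profiles and distances ----------------------------------------
  presence <- stage("presence_matrix", build_presence_matrix(collection))
  write_profile_tsv(presence, p("reaction_presence.tsv"))

  d_met <- stage("distances", jaccard_distance(presence))
  d_phe <- jaccard_distance(ess_profile)
  d_phy <- cophenetic_distance(tree)
  aligned <- align_organisms(d_met, d_phy, d_phe)
  d_met <- aligned[[1]]; d_phy <- aligned[[2]]; d_phe <- aligned[[3]]
  write_dist_tsv(d_met, p("dist_metabolic.tsv"))
  write_dist_tsv(d_phe, p("dist_phenotypic.tsv"))
  write_dist_tsv(d_phy, p("dist_phylogenetic.tsv"))
  d_ann <- NULL
  if (!is.null(annotations)) {
    d_ann <- jaccard_distance(annotations)
    write_dist_tsv(d_ann, p("dist_annotation.tsv"))
  }

  ## ---- ordination -----------------------------------------------------
  ord <- stage("pcoa", pcoa(d_met, n_axes = config$ordination$axes))
  coords <- data.frame(organism = rownames(ord$coordinates), ord$coordinates,
                       stringsAsFactors = FALSE)
  write_tsv_stable(coords, p("pcoa_coordinates.tsv"))
  write_tsv_stable(
    data.frame(axis = seq_along(ord$explained_fraction),
               eigenvalue = ord$eigenvalues[seq_along(ord$explained_fraction)],
               explained_fraction = ord$explained_fraction),
    p("pcoa_eigenvalues.tsv"))
  loadings <- stage("loadings",
                    feature_loadings(presence, ord,
                                     top_n = config$ordination$top_n))
  write_tsv_stable(loadings, p("pcoa_loadings.tsv"))
  logit("PCoA: axis 1+2 explain %.1f%% (negative mass %.2g)",
        100 * sum(ord$explained_fraction[1:min(2, length(ord$explained_fraction))]),
        ord$negative_eigenvalue_mass)

  emb <- stage("tsne", tsne_embed(d_met,
                                  perplexity = config$ordination$perplexity,
                                  seed = config$ordination$tsne_seed))
  write_tsv_stable(data.frame(organism = rownames(emb$coordinates),
                              emb$coordinates, stringsAsFactors = FALSE),
                   p("tsne_coordinates.tsv"))

  ## ---- clustering -----------------------------------------------------
  clusters <- stage("clustering", hcluster(d_met, k = config$clustering$k))
  write_tsv_stable(data.frame(organism = names(clusters$labels),
                              cluster = unname(clusters$labels),
                              stringsAsFactors = FALSE),
                   p("cluster_labels.tsv"))
  if (!is.null(config$clustering$contrast)) {
    ct <- config$clustering$contrast
    contrast <- stage("contrast",
                      subtype_contrast(presence, clusters, ct[1], ct[2]))
    write_tsv_stable(contrast, p("subtype_contrast.tsv"))
  }

  ## ---- regressions ----------------------------------------------------
  pairs <- stage("pair_table", pair_table(d_met, d_phy, d_phe))
  write_tsv_stable(as.data.frame(pairs), p("pairs.tsv"))
  subsets <- config$regression$subsets
  if (identical(subsets, "auto")) subsets <- auto_subsets(taxonomy)
  fit_table <- stage("fits",
                     fit_summary_table(taxonomy, pairs, subsets,
                                       rmse_scale = config$regression$rmse_scale))
  write_tsv_stable(fit_table, p("fit_summary.tsv"))
  fits <- list(exponential = fit_exponential(pairs,
                                             rmse_scale = config$regression$rmse_scale),
               linear = fit_linear(pairs))
  writeLines(jsonlite::toJSON(lapply(fits, unclass), auto_unbox = TRUE,
                              digits = NA, pretty = 2),
             p("fits.json"))
  for (resp in c("y", "z")) {
    ma <- moving_average(pairs, resp,
                         window_fraction = config$regression$window_fraction)
    write_tsv_stable(ma, p(sprintf("moving_average_%s.tsv", resp)))
  }
  logit("regressions: Spearman(x, y) = %.3f, Pearson(x, z) = %.3f over %d pairs",
        fits$exponential$correlation, fits$linear$correlation, nrow(pairs))

  ## ---- run log --------------------------------------------------------
  writeLines(c(sprintf("microrep %s", as.character(utils::packageVersion("microrep"))),
               sprintf("mode: %s", config$mode),
               sprintf("seed: %s", if (config$mode == "synthetic")
                 config$sim$seed else "n/a"),
               sprintf("tsne_seed: %s", config$ordination$tsne_seed),
               "", "config:",
               yaml::as.yaml(serializable_config(config))),
             p("run_log.txt"))

  invisible(structure(list(outdir = outdir, collection = collection,
                           screen = screen, presence = presence,
                           essential = ess_profile,
                           distances = list(metabolic = d_met,
                                            phenotypic = d_phe,
                                            phylogenetic = d_phy,
                                            annotation = d_ann),
                           ordination = ord, loadings = loadings,
                           tsne = emb, clusters = clusters,
                           pairs = pairs, fit_table = fit_table, fits = fits,
                           log = log_lines),
                      class = "report_bundle"))
}

serializable_config <- function(config) {
  list(mode = config$mode,
       sim = unclass(config$sim),
       screen = unclass(config$screen),
       ordination = config$ordination,
       clustering = config$clustering,
       regression = config$regression,
       paths = config$paths)
}
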