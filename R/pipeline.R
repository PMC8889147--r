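# Pipeline orchestration: one reproducible run directory from a single
# flat configuration, stages executed in dependency order with seeds and
# a parameter hash recorded in every output.

#' Pipeline configuration
#'
#' Flat configuration for [run_pipeline()]. `sim` takes any argument of
#' [sim_config()]; the remaining fields parameterize the analysis stages.
#'
#' @param mode stage(s) to run: one of `simulate`, `dge`, `gsa`,
#'   `connect`, `repurpose`, `quantify`, `cluster`, `all`.
#' @param seed master integer seed (stage seeds derive from it).
#' @param sim named list of [sim_config()] overrides.
#' @param contrasts list of `c(test, control)` status pairs analyzed.
#' @param gsa_B,gsa_alpha,gsa_methods,gsa_min_size GSA parameters.
#' @param screen_B,screen_alpha,tag_size connectivity-screen parameters.
#' @param clin_policy clinical pathway-group combination rule
#'   (`"union"` or `"intersection"`).
#' @param steatogens compound ids used as the in vitro steatogen panel;
#'   `NULL` uses the mimicker compounds recorded in the simulation
#'   manifest.
#' @param cluster_k k for the proteomics stage (`NULL` = silhouette).
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = "all", seed = 1L, sim = list(),
                            contrasts = list(c("NAFL", "Healthy"),
                                             c("NASH", "Healthy")),
                            gsa_B = 999L, gsa_alpha = 0.05,
                            gsa_methods = GSA_METHODS, gsa_min_size = 5L,
                            screen_B = 999L, screen_alpha = 0.05,
                            tag_size = 50L,
                            clin_policy = "union", steatogens = NULL,
                            cluster_k = 4L) {
  modes <- c("simulate", "dge", "gsa", "connect", "repurpose", "quantify",
             "cluster", "all")
  if (!mode %in% modes) {
    stop("unknown mode '", mode, "'; valid: ", paste(modes, collapse = ", "))
  }
  structure(list(mode = mode, seed = as.integer(seed), sim = sim,
                 contrasts = contrasts, gsa_B = as.integer(gsa_B),
                 gsa_alpha = gsa_alpha, gsa_methods = gsa_methods,
                 gsa_min_size = as.integer(gsa_min_size),
                 screen_B = as.integer(screen_B),
                 screen_alpha = screen_alpha,
                 tag_size = as.integer(tag_size),
                 clin_policy = clin_policy, steatogens = steatogens,
                 cluster_k = cluster_k),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  rlang::hash(unclass(config)[sort(names(unclass(config)))])
}

contrast_tag <- function(contrast) paste(contrast, collapse = "_vs_")

need_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop("missing upstream artifact '", basename(path),
         "': run stage '", stage, "' first")
  }
  path
}

stage_log <- function(name, expr, verbose) {
  t0 <- Sys.time()
  out <- expr
  if (verbose) {
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  invisible(out)
}

sim_from_config <- function(config) {
  args <- config$sim
  args$seed <- config$seed
  do.call(sim_config, args)
}

#' Run the repositioning pipeline
#'
#' Executes the requested stage (or all stages) in dependency order under
#' `outdir`. Every tabular output carries the run's parameter hash as a
#' header comment; `run_manifest.json` records the package version,
#' seeds, parameter hash and record counts. Identical configuration and
#' seed give byte-identical outputs.
#'
#' Stages and artifacts: `simulate` writes the synthetic universe
#' (expression, metadata, GMT, knowledgebase, signature library, truth
#' manifest); `dge` writes one gene-statistics TSV per contrast; `gsa`
#' one GSA class TSV per contrast; `connect` one connectivity-screen TSV
#' per contrast; `repurpose` the candidate table, network (JSON + SIF)
#' and summary; `quantify` segments a generated two-channel image;
#' `cluster` clusters a generated proteomic panel.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @param outdir run directory (created if needed).
#' @param verbose log stage wall-times.
#' @return the run directory, invisibly.
#' @export
run_pipeline <- function(config, outdir, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  cmt <- paste0("param_hash: ", hash)
  p <- function(...) file.path(outdir, ...)
  mode <- config$mode
  want <- function(stage) mode %in% c(stage, "all")
  counts <- list()

  if (want("simulate")) stage_log("simulate", {
    uni <- gen_universe(sim_from_config(config))
    write_expression(uni$dataset, p("expression.tsv"), p("metadata.tsv"),
                     comment = cmt)
    write_gmt(uni$sets, p("gene_sets.gmt"))
    write_compound_kb(uni$kb, p("compound_kb.tsv"), comment = cmt)
    write_signature_library(uni$library, p("signature_library.tsv"),
                            comment = cmt)
    jsonlite::write_json(
      list(planted_genes = uni$truth$planted_genes,
           planted_pathways = uni$truth$planted_pathways,
           roles = as.list(uni$truth$roles),
           tox_flagged = uni$truth$tox_flagged,
           param_hash = hash),
      p("truth_manifest.json"), dataframe = "columns", auto_unbox = TRUE)
    counts$n_genes <- nrow(uni$dataset$values)
    counts$n_compounds <- length(uni$library$profiles)
  }, verbose)

  if (want("dge")) stage_log("dge", {
    dataset <- read_expression(need_artifact(p("expression.tsv"),
                                             "simulate"),
                               need_artifact(p("metadata.tsv"), "simulate"))
    for (ct in config$contrasts) {
      st <- gene_stats(dataset, ct)
      write_gene_stats(st, p(sprintf("gene_stats_%s.tsv",
                                     contrast_tag(ct))), comment = cmt)
    }
  }, verbose)

  if (want("gsa")) stage_log("gsa", {
    sets <- read_gmt(need_artifact(p("gene_sets.gmt"), "simulate"))
    for (ct in config$contrasts) {
      st <- read_gene_stats(need_artifact(
        p(sprintf("gene_stats_%s.tsv", contrast_tag(ct))), "dge"))
      res <- run_gsa(st, sets, methods = config$gsa_methods,
                     B = config$gsa_B, seed = config$seed,
                     min_size = config$gsa_min_size,
                     alpha = config$gsa_alpha)
      write_tsv_c(res$classes, p(sprintf("gsa_%s.tsv", contrast_tag(ct))),
                  comment = cmt)
    }
  }, verbose)

  if (want("connect")) stage_log("connect", {
    lib <- read_signature_library(need_artifact(
      p("signature_library.tsv"), "simulate"))
    for (ct in config$contrasts) {
      st <- read_gene_stats(need_artifact(
        p(sprintf("gene_stats_%s.tsv", contrast_tag(ct))), "dge"))
      query <- query_signature(st, tag_size = config$tag_size)
      write_query_signature(query, p(sprintf("query_%s.json",
                                             contrast_tag(ct))))
      res <- screen_library(lib, query, alpha = config$screen_alpha,
                            B = config$screen_B, seed = config$seed)
      write_tsv_c(res, p(sprintf("connectivity_%s.tsv",
                                 contrast_tag(ct))), comment = cmt)
    }
  }, verbose)

  if (want("repurpose")) stage_log("repurpose", {
    sets <- read_gmt(need_artifact(p("gene_sets.gmt"), "simulate"))
    kb <- read_compound_kb(need_artifact(p("compound_kb.tsv"), "simulate"))
    clinical <- lapply(config$contrasts, function(ct) {
      d <- read_tsv_c(need_artifact(p(sprintf("gsa_%s.tsv",
                                              contrast_tag(ct))), "gsa"))
      d$set[d$best_p_adj <= config$gsa_alpha]
    })
    steatogens <- config$steatogens
    if (is.null(steatogens)) {
      manifest <- jsonlite::read_json(need_artifact(
        p("truth_manifest.json"), "simulate"), simplifyVector = TRUE)
      steatogens <- names(manifest$roles)[manifest$roles == "mimicker"]
    }
    if (length(steatogens) == 0L) stop("no steatogen compounds configured")
    groups <- build_pathway_groups(clinical, steatogens, kb, sets,
                                   policy = config$clin_policy)
    screens <- lapply(config$contrasts, function(ct) {
      read_tsv_c(need_artifact(p(sprintf("connectivity_%s.tsv",
                                         contrast_tag(ct))), "connect"))
    })
    cand <- select_candidates(screens, kb, sets, groups)
    filt <- apply_tox_filter(cand)
    write_tsv_c(filt$table, p("candidates.tsv"), comment = cmt)
    export_network(filt$table, kb, sets, groups,
                   json_path = p("network.json"), sif_path = p("network.sif"))
    jsonlite::write_json(
      list(param_hash = hash,
           n_pathways_to_target = length(groups$target),
           pathways_to_target = sort(groups$target),
           n_candidates = sum(filt$table$status != "rejected"),
           n_excluded_tox = filt$n_excluded,
           n_retained = filt$n_retained),
      p("summary.json"), auto_unbox = TRUE)
    counts$n_candidates <- nrow(filt$table)
  }, verbose)

  if (want("quantify")) stage_log("quantify", {
    img <- gen_microscopy_image(sim_from_config(config))
    write_image_channels(img$image, p("image_01"))
    nuc <- segment_nuclei(img$image$nuclei)
    drp <- segment_droplets(img$image$droplets)
    write_tsv_c(data.frame(image = "image_01", n_nuclei = nuc$count,
                           n_droplets = drp$count,
                           droplet_area = drp$total_area,
                           droplet_intensity = drp$intensity,
                           intensity_per_cell =
                             if (nuc$count > 0)
                               drp$intensity / nuc$count else NA_real_),
                p("image_measurements.tsv"), comment = cmt)
  }, verbose)

  if (want("cluster")) stage_log("cluster", {
    panel <- gen_proteomic_panel(seed = config$seed)
    cl <- cluster_treatments(panel$matrix, k = config$cluster_k,
                             seed = config$seed)
    write_tsv_c(data.frame(treatment = rownames(panel$matrix),
                           cluster = cl$labels,
                           true_cluster = panel$labels),
                p("cluster_labels.tsv"), comment = cmt)
    jsonlite::write_json(list(param_hash = hash, k = cl$k,
                              var_frac = cl$embedding$var_frac),
                         p("variance_fractions.json"), auto_unbox = TRUE)
  }, verbose)

  jsonlite::write_json(
    list(package = "steatoscreen",
         version = as.character(utils::packageVersion("steatoscreen")),
         mode = mode, seed = config$seed, param_hash = hash,
         counts = counts),
    p("run_manifest.json"), auto_unbox = TRUE, null = "null")
  invisible(outdir)
}
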