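# Synthetic universe: seeded generators for every input the pipeline
# consumes, each paired with a ground-truth manifest so recovery can be
# scored without regeneration.

#' Simulation configuration
#'
#' Builds the configuration object consumed by all `gen_*()` generators.
#' Defaults emulate a three-group liver biopsy cohort (Healthy / NAFL /
#' NASH) profiled on a log2-intensity microarray, an MSigDB-like gene-set
#' collection with a handful of disease pathways planted, a compound
#' signature library containing signature reversers and mimickers among
#' random decoys, a compound knowledgebase with toxicity flags, and the
#' imaging / plate geometry of a high-content screen.
#'
#' @param n_genes number of genes in the universe.
#' @param group_sizes integer triple, samples per status
#'   (Healthy, NAFL, NASH); each must be >= 2.
#' @param n_gene_sets total number of gene sets generated.
#' @param set_size_range integer interval for set sizes.
#' @param n_planted_pathways number of pathways carrying planted
#'   differential expression.
#' @param n_de_per_pathway planted DE genes per planted pathway.
#' @param planted_filler_frac filler genes added to each planted pathway,
#'   as a fraction of its DE genes (default 0.25, so planted pathways are
#'   predominantly, but not purely, differentially expressed).
#' @param effect_log2fc absolute planted shift (log2 units) in the NAFL and
#'   NASH groups.
#' @param pathway_directions optional vector of +1/-1 giving the planted
#'   direction of each planted pathway; default alternates up/down.
#' @param variance_prior pair `c(d0, s0_sq)`: prior degrees of freedom and
#'   prior variance of the scaled inverse-chi-square law that per-gene true
#'   variances are drawn from.
#' @param n_library_compounds,n_reversers,n_mimickers signature library
#'   composition; the remainder are decoys (uniform random rankings).
#' @param signature_strength,signature_noise mean shift and sd (score
#'   units) used when planting reverser/mimicker rankings.
#' @param tag_size query tag size (top/bottom genes by moderated t).
#' @param n_targets_decoy targets per decoy compound in the knowledgebase.
#' @param tox_fraction fraction of compounds flagged hepatotoxic.
#' @param image_width,image_height canvas size in pixels.
#' @param n_nuclei,n_droplets objects per synthetic image.
#' @param nucleus_radius,droplet_radius nucleus disk radius (px) and
#'   droplet radius range (px).
#' @param nucleus_intensity,droplet_intensity peak intensities in `[0,1]`.
#' @param image_noise_sd additive Gaussian noise sd on each channel.
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000L,
                       group_sizes = c(Healthy = 10L, NAFL = 10L, NASH = 10L),
                       n_gene_sets = 50L,
                       set_size_range = c(10L, 40L),
                       n_planted_pathways = 11L,
                       n_de_per_pathway = 10L,
                       planted_filler_frac = 0.25,
                       effect_log2fc = 1.5,
                       pathway_directions = NULL,
                       variance_prior = c(d0 = 4, s0_sq = 0.25),
                       n_library_compounds = 110L,
                       n_reversers = 5L,
                       n_mimickers = 5L,
                       signature_strength = 5,
                       signature_noise = 1,
                       tag_size = 50L,
                       n_targets_decoy = 3L,
                       tox_fraction = 0.25,
                       image_width = 384L,
                       image_height = 384L,
                       n_nuclei = 12L,
                       n_droplets = 40L,
                       nucleus_radius = 14,
                       droplet_radius = c(2, 4),
                       nucleus_intensity = 0.8,
                       droplet_intensity = 0.9,
                       image_noise_sd = 0.01,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), group_sizes = group_sizes,
    n_gene_sets = as.integer(n_gene_sets),
    set_size_range = as.integer(set_size_range),
    n_planted_pathways = as.integer(n_planted_pathways),
    n_de_per_pathway = as.integer(n_de_per_pathway),
    planted_filler_frac = planted_filler_frac,
    effect_log2fc = effect_log2fc,
    pathway_directions = pathway_directions,
    variance_prior = variance_prior,
    n_library_compounds = as.integer(n_library_compounds),
    n_reversers = as.integer(n_reversers),
    n_mimickers = as.integer(n_mimickers),
    signature_strength = signature_strength,
    signature_noise = signature_noise,
    tag_size = as.integer(tag_size),
    n_targets_decoy = as.integer(n_targets_decoy),
    tox_fraction = tox_fraction,
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    n_nuclei = as.integer(n_nuclei), n_droplets = as.integer(n_droplets),
    nucleus_radius = nucleus_radius, droplet_radius = droplet_radius,
    nucleus_intensity = nucleus_intensity,
    droplet_intensity = droplet_intensity,
    image_noise_sd = image_noise_sd,
    seed = as.integer(seed)
  )
  if (length(cfg$group_sizes) != 3L) {
    stop("group_sizes must be a triple (Healthy, NAFL, NASH)")
  }
  if (is.null(names(cfg$group_sizes))) {
    names(cfg$group_sizes) <- c("Healthy", "NAFL", "NASH")
  }
  if (any(cfg$group_sizes < 2L)) {
    stop("invalid config: every group size must be >= 2")
  }
  if (cfg$n_genes < 1L) stop("invalid config: n_genes must be positive")
  if (cfg$tag_size >= cfg$n_genes) {
    stop("invalid config: tag_size must be smaller than n_genes")
  }
  if (cfg$set_size_range[1] < 2L || cfg$set_size_range[2] > cfg$n_genes ||
      cfg$set_size_range[1] > cfg$set_size_range[2]) {
    stop("invalid config: set sizes must lie within [2, n_genes]")
  }
  if (cfg$n_reversers + cfg$n_mimickers > cfg$n_library_compounds) {
    stop("invalid config: n_reversers + n_mimickers > n_library_compounds")
  }
  if (cfg$tox_fraction < 0 || cfg$tox_fraction > 1) {
    stop("invalid config: tox_fraction must be in [0,1]")
  }
  if (any(cfg$variance_prior <= 0)) {
    stop("invalid config: variance prior (d0, s0_sq) must be positive")
  }
  if (!is.null(cfg$pathway_directions) &&
      length(cfg$pathway_directions) != cfg$n_planted_pathways) {
    stop("pathway_directions length must equal n_planted_pathways")
  }
  class(cfg) <- "sim_config"
  cfg
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

planted_directions <- function(config) {
  if (!is.null(config$pathway_directions)) return(config$pathway_directions)
  if (config$n_planted_pathways == 0L) return(integer(0))
  rep_len(c(1L, -1L), config$n_planted_pathways)
}

# Planted layout is a deterministic function of (config, seed) and shared by
# the cohort, gene-set and library generators so their ground truths agree.
planted_layout <- function(config) {
  set.seed(config$seed)
  genes <- gene_ids(config$n_genes)
  npp <- config$n_planted_pathways
  ndp <- config$n_de_per_pathway
  if (npp * ndp > config$n_genes) {
    stop("invalid config: more planted DE genes than genes in the universe")
  }
  dirs <- planted_directions(config)
  if (npp > 0L) {
    de_genes <- sample(genes, npp * ndp)
    planted <- data.frame(
      gene = de_genes,
      pathway = rep(sprintf("planted_%02d", seq_len(npp)), each = ndp),
      sign = rep(dirs, each = ndp),
      stringsAsFactors = FALSE
    )
  } else {
    planted <- data.frame(gene = character(0), pathway = character(0),
                          sign = integer(0), stringsAsFactors = FALSE)
  }
  list(genes = genes, planted = planted,
       planted_pathways = unique(planted$pathway))
}

#' Generate a synthetic three-group expression cohort
#'
#' Simulates log2-scale expression for a Healthy / NAFL / NASH cohort.
#' Per-gene true residual variances are drawn from a scaled
#' inverse-chi-square law `s0_sq * d0 / chisq(d0)` so that downstream
#' empirical-Bayes shrinkage has a testable target; genes planted in
#' disease pathways are shifted by `effect_log2fc` (with the pathway's
#' sign) in both disease groups.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (an `expression_dataset`) and `truth`
#'   (ground-truth manifest: planted gene table, planted pathway ids,
#'   per-gene true variances and baselines).
#' @export
gen_expression_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- planted_layout(config)
  set.seed(config$seed + 1L)
  G <- config$n_genes
  sizes <- config$group_sizes
  status <- rep(names(sizes), times = sizes)
  sample_ids <- sprintf("s%03d", seq_along(status))
  baseline <- stats::rnorm(G, mean = 7, sd = 1)
  d0 <- config$variance_prior[[1]]
  s0 <- config$variance_prior[[2]]
  true_var <- s0 * d0 / stats::rchisq(G, df = d0)
  effect <- numeric(G)
  names(effect) <- layout$genes
  if (nrow(layout$planted) > 0L) {
    effect[layout$planted$gene] <- config$effect_log2fc * layout$planted$sign
  }
  diseased <- status != "Healthy"
  mu <- matrix(baseline, nrow = G, ncol = length(status))
  mu[, diseased] <- mu[, diseased] + effect
  values <- mu + matrix(stats::rnorm(G * length(status), sd = sqrt(true_var)),
                        nrow = G)
  dimnames(values) <- list(layout$genes, sample_ids)
  dataset <- expression_dataset(values, status)
  truth <- list(
    planted_genes = layout$planted,
    planted_pathways = layout$planted_pathways,
    true_variance = stats::setNames(true_var, layout$genes),
    baseline = stats::setNames(baseline, layout$genes),
    effect = effect,
    config_seed = config$seed
  )
  list(dataset = dataset, truth = truth)
}

#' Generate a gene-set collection with planted disease pathways
#'
#' Planted pathways contain their planted DE genes plus filler genes;
#' non-planted (decoy) sets draw members only from non-planted genes, so
#' recovery of the planted pathways can be scored exactly.
#'
#' @param config a [sim_config()].
#' @return list with `sets` (a named list of gene-id vectors, GMT-writable)
#'   and `truth` (planted pathway identifiers and membership).
#' @export
gen_gene_sets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- planted_layout(config)
  set.seed(config$seed + 2L)
  rng <- config$set_size_range
  npp <- config$n_planted_pathways
  if (npp > config$n_gene_sets) {
    stop("invalid config: more planted pathways than gene sets")
  }
  nonplanted_genes <- setdiff(layout$genes, layout$planted$gene)
  if (rng[2] > config$n_genes) stop("set_size_range infeasible for n_genes")
  sets <- list()
  for (p in layout$planted_pathways) {
    members <- layout$planted$gene[layout$planted$pathway == p]
    n_fill <- floor(config$planted_filler_frac * length(members))
    fill <- if (n_fill > 0L) sample(nonplanted_genes, n_fill) else character(0)
    sets[[p]] <- c(members, fill)
  }
  n_decoy <- config$n_gene_sets - npp
  if (n_decoy > 0L && length(nonplanted_genes) < rng[1]) {
    stop("set_size_range infeasible: not enough non-planted genes")
  }
  for (i in seq_len(n_decoy)) {
    size <- sample(seq(rng[1], min(rng[2], length(nonplanted_genes))), 1L)
    sets[[sprintf("decoy_set_%03d", i)]] <- sample(nonplanted_genes, size)
  }
  list(sets = sets,
       truth = list(planted_pathways = layout$planted_pathways,
                    planted_genes = layout$planted))
}

#' Generate a compound signature library
#'
#' Each compound is a complete ranking of the gene universe (rank 1 = most
#' up-regulated under that compound). Reversers rank the disease up-genes
#' near the bottom and the down-genes near the top (rank inversion of the
#' planted signature plus Gaussian score jitter); mimickers the converse;
#' decoys are uniform random permutations.
#'
#' @param truth ground-truth manifest from [gen_expression_cohort()].
#' @param config a [sim_config()].
#' @return list with `library` (a `signature_library`: universe plus a
#'   named list of rank vectors) and `truth` (compound roles).
#' @export
gen_signature_library <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  genes <- names(truth$true_variance)
  G <- length(genes)
  n <- config$n_library_compounds
  nr <- config$n_reversers
  nm <- config$n_mimickers
  if (nr + nm > n) stop("n_reversers + n_mimickers > n_library_compounds")
  roles <- c(rep("reverser", nr), rep("mimicker", nm),
             rep("decoy", n - nr - nm))
  ids <- sprintf("cmpd_%03d", seq_len(n))
  signed <- truth$effect  # planted signature: +effect up, -effect down
  profiles <- vector("list", n)
  names(profiles) <- ids
  for (i in seq_len(n)) {
    score <- stats::rnorm(G)
    if (roles[i] == "reverser") {
      score <- score * config$signature_noise -
        sign(signed) * config$signature_strength
    } else if (roles[i] == "mimicker") {
      score <- score * config$signature_noise +
        sign(signed) * config$signature_strength
    }
    ord <- order(score, decreasing = TRUE)
    rk <- integer(G)
    rk[ord] <- seq_len(G)
    profiles[[i]] <- stats::setNames(rk, genes)
  }
  lib <- structure(list(universe = genes, profiles = profiles),
                   class = "signature_library")
  list(library = lib,
       truth = list(roles = stats::setNames(roles, ids)))
}

#' Generate a compound knowledgebase (targets + toxicity flags)
#'
#' Reverser and mimicker compounds receive one planted DE gene per planted
#' pathway as targets (so their affected-pathway sets cover the planted
#' pathways); decoys receive random non-planted targets. `tox_fraction`
#' of all compounds are flagged hepatotoxic, reproducibly under the seed.
#'
#' @param truth combined truth: needs `planted_genes` (from the cohort) and
#'   `roles` (from the library).
#' @param config a [sim_config()].
#' @return list with `kb` (data.frame: compound, targets, tox_flag) and
#'   `truth` (flagged compound ids).
#' @export
gen_compound_knowledgebase <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  roles <- truth$roles
  planted <- truth$planted_genes
  genes <- gene_ids(config$n_genes)
  nonplanted_genes <- setdiff(genes, planted$gene)
  targets <- lapply(names(roles), function(id) {
    if (roles[[id]] %in% c("reverser", "mimicker") && nrow(planted) > 0L) {
      vapply(split(planted$gene, planted$pathway),
             function(g) sample(g, 1L), character(1))
    } else {
      sample(nonplanted_genes, min(config$n_targets_decoy,
                                   length(nonplanted_genes)))
    }
  })
  n <- length(roles)
  n_tox <- floor(config$tox_fraction * n)
  tox_ids <- if (n_tox > 0L) sample(names(roles), n_tox) else character(0)
  kb <- data.frame(
    compound = names(roles),
    targets = vapply(targets, paste, character(1), collapse = ";"),
    tox_flag = as.integer(names(roles) %in% tox_ids),
    stringsAsFactors = FALSE
  )
  list(kb = kb, truth = list(tox_flagged = tox_ids))
}

soft_disk <- function(width, height, cx, cy, r, intensity, edge = 1) {
  xs <- matrix(seq_len(width), nrow = height, ncol = width, byrow = TRUE)
  ys <- matrix(seq_len(height), nrow = height, ncol = width)
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  intensity / (1 + exp((d - r) / edge))
}

#' Generate a two-channel synthetic microscopy image
#'
#' Emulates a Hoechst nuclei channel and a Nile-Red lipid-droplet channel:
#' nuclei are large smooth disks with enforced minimum center separation
#' (unless `touching_pair = TRUE`, which plants exactly one overlapping
#' pair), droplets are small bright disks; both channels get additive
#' Gaussian noise and are clipped to `[0, 1]`.
#'
#' @param config a [sim_config()].
#' @param touching_pair plant one pair of nuclei whose disks overlap.
#' @return list with `image` (list of `nuclei` and `droplets` matrices) and
#'   `truth` (nuclei centers, droplet records, noiseless total droplet
#'   intensity).
#' @export
gen_microscopy_image <- function(config, touching_pair = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 5L)
  w <- config$image_width; h <- config$image_height
  r <- config$nucleus_radius
  margin <- r + 3
  min_sep <- 2 * r + 4
  n_free <- config$n_nuclei - if (touching_pair) 2L else 0L
  if (n_free < 0L) stop("touching_pair needs n_nuclei >= 2")
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(centers) < n_free) {
    tries <- tries + 1L
    if (tries > 1000L * max(1L, config$n_nuclei)) {
      stop("nucleus placement infeasible in canvas")
    }
    cand <- c(stats::runif(1, margin, w - margin),
              stats::runif(1, margin, h - margin))
    if (nrow(centers) == 0L ||
        all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                           byrow = TRUE))^2)) >= min_sep)) {
      centers <- rbind(centers, cand)
    }
  }
  pair_idx <- integer(0)
  if (touching_pair) {
    repeat {
      base <- c(stats::runif(1, margin + r, w - margin - r),
                stats::runif(1, margin, h - margin))
      second <- base + c(1.4 * r, 0)
      ok_margin <- second[1] <= w - margin
      sep_ok <- nrow(centers) == 0L ||
        all(sqrt(rowSums((centers - matrix(base, nrow(centers), 2,
                                           byrow = TRUE))^2)) >= min_sep) &&
        all(sqrt(rowSums((centers - matrix(second, nrow(centers), 2,
                                           byrow = TRUE))^2)) >= min_sep)
      if (ok_margin && sep_ok) {
        pair_idx <- nrow(centers) + 1:2
        centers <- rbind(centers, base, second)
        break
      }
    }
  }
  nuc <- matrix(0, h, w)
  for (i in seq_len(nrow(centers))) {
    nuc <- nuc + soft_disk(w, h, centers[i, 1], centers[i, 2], r,
                           config$nucleus_intensity)
  }
  nuc <- pmin(nuc, 1)
  drops <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
                      intensity = numeric(0))
  drop_ch <- matrix(0, h, w)
  drop_sep <- 2 * config$droplet_radius[2] + 3  # keep droplets resolvable
  tries <- 0L
  while (nrow(drops) < config$n_droplets) {
    tries <- tries + 1L
    if (tries > 1000L * max(1L, config$n_droplets)) {
      stop("droplet placement infeasible in canvas")
    }
    dr <- stats::runif(1, config$droplet_radius[1], config$droplet_radius[2])
    cx <- stats::runif(1, dr + 2, w - dr - 2)
    cy <- stats::runif(1, dr + 2, h - dr - 2)
    if (nrow(drops) > 0L &&
        any(sqrt((drops$x - cx)^2 + (drops$y - cy)^2) < drop_sep)) next
    disk <- soft_disk(w, h, cx, cy, dr, config$droplet_intensity, edge = 0.5)
    drop_ch <- pmax(drop_ch, disk)
    drops <- rbind(drops, data.frame(x = cx, y = cy, r = dr,
                                     intensity = config$droplet_intensity))
  }
  total_intensity <- sum(drop_ch)
  if (config$image_noise_sd > 0) {
    nuc <- nuc + matrix(stats::rnorm(h * w, sd = config$image_noise_sd), h, w)
    drop_ch <- drop_ch +
      matrix(stats::rnorm(h * w, sd = config$image_noise_sd), h, w)
  }
  nuc <- pmin(pmax(nuc, 0), 1)
  drop_ch <- pmin(pmax(drop_ch, 0), 1)
  list(image = list(nuclei = nuc, droplets = drop_ch),
       truth = list(n_nuclei = config$n_nuclei, centers = centers,
                    touching_pair = pair_idx,
                    droplets = drops, n_droplets = config$n_droplets,
                    total_droplet_intensity = total_intensity))
}

#' Four-parameter logistic curve
#'
#' `y = d + (a - d) / (1 + (x / c)^b)`: `a` is the top asymptote (response
#' at zero dose), `d` the bottom asymptote, `c` the inflection dose and `b`
#' the Hill slope.
#'
#' @param x dose (same units as `c`).
#' @param a,d,c,b curve parameters.
#' @export
four_pl <- function(x, a, d, c, b) d + (a - d) / (1 + (x / c)^b)

#' Generate a dose-response plate table
#'
#' Viability responses on a 4PL curve plus Gaussian noise, with replicates.
#'
#' @param params named vector/list with `a`, `d`, `c`, `b`.
#' @param doses positive dose levels (>= 5).
#' @param noise_sd Gaussian noise sd (viability % units).
#' @param n_replicates replicates per dose.
#' @param seed integer seed.
#' @return data.frame: dose, replicate, viability.
#' @export
gen_dose_response <- function(params, doses, noise_sd = 0, n_replicates = 3L,
                              seed = 1L) {
  if (length(doses) < 5L) stop("need at least 5 dose levels")
  if (any(doses <= 0)) stop("doses must be positive")
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(n_replicates), dose = doses)
  mu <- four_pl(grid$dose, params[["a"]], params[["d"]],
                params[["c"]], params[["b"]])
  data.frame(dose = grid$dose, replicate = grid$replicate,
             viability = mu + stats::rnorm(nrow(grid), sd = noise_sd))
}

#' Generate a synthetic proteomic panel
#'
#' Treatment-by-analyte measurements drawn from `k` centroids plus
#' isotropic Gaussian noise, emulating a multiplexed phospho-protein /
#' cytokine fold-change panel with distinct treatment modes of action.
#'
#' @param n_treatments rows (treatments).
#' @param n_analytes columns (analytes).
#' @param k number of true clusters (>= 1).
#' @param separation distance between adjacent cluster centroids, in the
#'   same units as `noise_sd`. Centroids are placed equally spaced on a
#'   circle inside a random 2-D subspace of analyte space, so the cluster
#'   structure is low-rank — the situation a PC1/PC2 mode-of-action plot
#'   depicts.
#' @param noise_sd within-cluster (isotropic) noise sd.
#' @param seed integer seed.
#' @return list with `matrix` (treatments x analytes) and `labels`
#'   (true cluster of each treatment).
#' @export
gen_proteomic_panel <- function(n_treatments = 24L, n_analytes = 20L,
                                k = 4L, separation = 5, noise_sd = 0.5,
                                seed = 1L) {
  if (k < 1L) stop("k must be >= 1")
  if (n_analytes < 2L) stop("need >= 2 analytes")
  if (n_treatments < k) stop("need at least k treatments")
  set.seed(seed)
  if (k == 1L) {
    centroids <- matrix(0, 1L, n_analytes)
  } else {
    radius <- separation / (2 * sin(pi / k))
    angles <- 2 * pi * (seq_len(k) - 1L) / k
    plane <- qr.Q(qr(matrix(stats::rnorm(n_analytes * 2L),
                            ncol = 2L)))   # random orthonormal 2-frame
    centroids <- radius * cbind(cos(angles), sin(angles)) %*% t(plane)
  }
  labels <- sort(rep_len(seq_len(k), n_treatments))
  m <- centroids[labels, , drop = FALSE] +
    matrix(stats::rnorm(n_treatments * n_analytes, sd = noise_sd),
           nrow = n_treatments)
  dimnames(m) <- list(sprintf("treatment_%02d", seq_len(n_treatments)),
                      sprintf("analyte_%02d", seq_len(n_analytes)))
  list(matrix = m, labels = labels)
}

#' Generate the full synthetic universe
#'
#' Convenience wrapper running the cohort, gene-set, signature-library and
#' knowledgebase generators with one config, merging their ground truths
#' into a single manifest.
#'
#' @param config a [sim_config()].
#' @return list: `dataset`, `sets`, `library`, `kb`, `truth`.
#' @export
gen_universe <- function(config) {
  cohort <- gen_expression_cohort(config)
  gs <- gen_gene_sets(config)
  lib <- gen_signature_library(cohort$truth, config)
  truth <- c(cohort$truth, lib$truth,
             list(planted_pathway_sets = gs$sets[gs$truth$planted_pathways]))
  kb <- gen_compound_knowledgebase(
    c(truth, list(planted_genes = cohort$truth$planted_genes)), config)
  truth$tox_flagged <- kb$truth$tox_flagged
  list(dataset = cohort$dataset, sets = gs$sets, library = lib$library,
       kb = kb$kb, truth = truth)
}
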