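# Generators: determinism, planted structure, the variance law, library
# roles, knowledgebase flags, image geometry and plate tables.

test_that("configs are validated", {
  expect_error(sim_config(group_sizes = c(1, 5, 5)), ">= 2")
  expect_error(sim_config(tag_size = 2000, n_genes = 2000), "tag_size")
  expect_error(sim_config(set_size_range = c(1, 10)), "set sizes")
  expect_error(sim_config(tox_fraction = 1.5), "tox_fraction")
  expect_error(sim_config(n_reversers = 8, n_mimickers = 8,
                          n_library_compounds = 10), "n_library_compounds")
  expect_error(sim_config(variance_prior = c(d0 = -1, s0_sq = 1)),
               "positive")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_cohort_config(seed = 101)
  a <- gen_universe(cfg)
  b <- gen_universe(cfg)
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$sets, b$sets)
  expect_identical(a$library$profiles, b$library$profiles)
  expect_identical(a$kb, b$kb)
  img_cfg <- small_image_config(seed = 102)
  expect_identical(gen_microscopy_image(img_cfg)$image,
                   gen_microscopy_image(img_cfg)$image)
  expect_identical(gen_dose_response(c(a = 100, d = 0, c = 1, b = 1),
                                     1:5, 1, seed = 3),
                   gen_dose_response(c(a = 100, d = 0, c = 1, b = 1),
                                     1:5, 1, seed = 3))
  expect_identical(gen_proteomic_panel(seed = 4),
                   gen_proteomic_panel(seed = 4))
})

test_that("a null configuration plants no effect", {
  cfg <- small_cohort_config(seed = 103, effect_log2fc = 0)
  u <- gen_expression_cohort(cfg)
  expect_equal(max(abs(u$truth$effect)), 0)
})

test_that("true variances follow the scaled inverse-chi-square law", {
  cfg <- sim_config(n_genes = 5000L, variance_prior = c(d0 = 4, s0_sq = 2),
                    seed = 104)
  u <- gen_expression_cohort(cfg)
  lv <- log(u$truth$true_variance)
  expect_lt(abs(var(lv) - trigamma(2)) / trigamma(2), 0.10)
  expect_lt(abs(mean(lv) - (log(2 * 4 / 2) - digamma(2))) /
              abs(log(4) - digamma(2)), 0.25)
})

test_that("gene sets carry the planted genes and round-trip through GMT", {
  cfg <- small_cohort_config(seed = 105)
  gs <- gen_gene_sets(cfg)
  expect_length(gs$truth$planted_pathways, 3L)
  expect_true(all(lengths(gs$sets) > 0))
  # every planted gene belongs to >= 1 planted pathway
  planted <- gs$truth$planted_genes
  for (i in seq_len(nrow(planted))) {
    expect_true(planted$gene[i] %in% gs$sets[[planted$pathway[i]]])
  }
  # decoy sets never contain planted genes (recovery is scoreable exactly)
  decoys <- gs$sets[setdiff(names(gs$sets), gs$truth$planted_pathways)]
  expect_false(any(unlist(decoys) %in% planted$gene))
  path <- tempfile(fileext = ".gmt")
  write_gmt(gs$sets, path)
  expect_equal(unclass(read_gmt(path))[names(gs$sets)], unclass(gs$sets),
               ignore_attr = TRUE)
  # zero planted pathways
  none <- gen_gene_sets(small_cohort_config(seed = 1,
                                            n_planted_pathways = 0L))
  expect_length(none$truth$planted_pathways, 0L)
})

test_that("eleven planted pathways are listed in the manifest", {
  cfg <- sim_config(seed = 106)   # default plants 11 pathways
  gs <- gen_gene_sets(cfg)
  expect_length(unique(gs$truth$planted_pathways), 11L)
})

test_that("library roles have the planted connectivity signs", {
  cfg <- small_cohort_config(seed = 107)
  u <- gen_expression_cohort(cfg)
  lib <- gen_signature_library(u$truth, cfg)
  st <- gene_stats(u$dataset, c("NASH", "Healthy"))
  q <- query_signature(st, tag_size = 20)
  scores <- vapply(names(lib$library$profiles), function(id) {
    connectivity_score(lib$library$profiles[[id]], q)$score
  }, numeric(1))
  roles <- lib$truth$roles
  expect_true(all(scores[roles == "reverser"] < 0))
  expect_true(all(scores[roles == "mimicker"] > 0))
  # decoy compounds score near zero on average
  expect_lt(abs(mean(scores[roles == "decoy"])), 0.1)
  # noise-free reverser sits near the attainable extreme
  cfg0 <- small_cohort_config(seed = 108, signature_noise = 0)
  u0 <- gen_expression_cohort(cfg0)
  lib0 <- gen_signature_library(u0$truth, cfg0)
  st0 <- gene_stats(u0$dataset, c("NASH", "Healthy"))
  # tags no larger than the planted down-gene count stay fully planted
  q0 <- query_signature(st0, tag_size = 6)
  rev0 <- names(lib0$truth$roles)[lib0$truth$roles == "reverser"][1]
  s0 <- connectivity_score(lib0$library$profiles[[rev0]], q0)$score
  expect_lt(s0, -0.9)
  # empty library is representable
  cfg_empty <- small_cohort_config(seed = 1, n_library_compounds = 0L,
                                   n_reversers = 0L, n_mimickers = 0L)
  lib_empty <- gen_signature_library(u$truth, cfg_empty)
  expect_length(lib_empty$library$profiles, 0L)
})

test_that("knowledgebase flags and targets follow the config", {
  cfg <- small_cohort_config(seed = 109)
  uni <- gen_universe(cfg)
  n_tox <- floor(cfg$tox_fraction * cfg$n_library_compounds)
  expect_equal(sum(uni$kb$tox_flag), n_tox)
  # reverser target pathways intersect the planted pathways
  rev1 <- names(uni$truth$roles)[uni$truth$roles == "reverser"][1]
  expect_gt(length(intersect(compound_pathways(uni$kb, uni$sets, rev1),
                             uni$truth$planted_pathways)), 0)
  none <- gen_compound_knowledgebase(
    c(uni$truth, list(planted_genes = uni$truth$planted_genes)),
    small_cohort_config(seed = 109, tox_fraction = 0))
  expect_equal(sum(none$kb$tox_flag), 0L)
  all_f <- gen_compound_knowledgebase(
    c(uni$truth, list(planted_genes = uni$truth$planted_genes)),
    small_cohort_config(seed = 109, tox_fraction = 1))
  expect_equal(sum(all_f$kb$tox_flag), 20L)
})

test_that("image truth records geometry, including the touching pair", {
  img <- gen_microscopy_image(small_image_config(seed = 110,
                                                 image_noise_sd = 0))
  expect_equal(nrow(img$truth$centers), img$truth$n_nuclei)
  expect_equal(nrow(img$truth$droplets), img$truth$n_droplets)
  expect_equal(img$truth$total_droplet_intensity,
               sum(img$image$droplets))
  # all-background blank
  blank <- gen_microscopy_image(small_image_config(
    seed = 111, n_nuclei = 0L, n_droplets = 0L, image_noise_sd = 0))
  expect_equal(max(blank$image$nuclei), 0)
  expect_equal(max(blank$image$droplets), 0)
  # the touching pair overlaps; all other pairs are separated
  pair <- gen_microscopy_image(small_image_config(seed = 112),
                               touching_pair = TRUE)
  r <- small_image_config(seed = 112)$nucleus_radius
  centers <- pair$truth$centers
  dmat <- as.matrix(dist(centers))
  diag(dmat) <- Inf
  overlapping <- which(dmat < 2 * r, arr.ind = TRUE)
  expect_equal(sort(unique(as.vector(overlapping))),
               sort(pair$truth$touching_pair))
  # infeasible placement errors out
  expect_error(gen_microscopy_image(sim_config(
    image_width = 64L, image_height = 64L, n_nuclei = 50L)), "infeasible")
})

test_that("dose-response tables sit on the curve at zero noise", {
  doses <- c(0.1, 1, 3, 10, 30)
  dr <- gen_dose_response(c(a = 100, d = 0, c = 10, b = 1), doses,
                          noise_sd = 0, seed = 1)
  expect_equal(dr$viability,
               four_pl(dr$dose, 100, 0, 10, 1))
  flat <- gen_dose_response(c(a = 100, d = 0, c = 10, b = 0), doses,
                            noise_sd = 0, seed = 1)
  expect_true(all(flat$viability == flat$viability[1]))
  expect_error(gen_dose_response(c(a = 1, d = 0, c = 1, b = 1), 1:3), "5")
})

test_that("proteomic panels respect the requested cluster structure", {
  one <- gen_proteomic_panel(k = 1, seed = 5)
  expect_equal(unique(one$labels), 1L)
  expect_error(gen_proteomic_panel(k = 0), "k must")
  expect_error(gen_proteomic_panel(n_analytes = 1), "2 analytes")
})
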