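# Pathway groups, candidate selection, toxicity exclusion, network export
# and screening summaries.

toy_kb <- data.frame(
  compound = c("drugA", "drugB", "drugC"),
  targets = c("g1;g2", "g9", ""),
  tox_flag = c(0L, 1L, 0L), stringsAsFactors = FALSE)

toy_sets <- list(pw1 = c("g1", "g5"), pw2 = c("g2", "g6"),
                 pw3 = c("g7", "g8"))

test_that("compound pathways are the sets containing any target gene", {
  expect_setequal(compound_pathways(toy_kb, toy_sets, "drugA"),
                  c("pw1", "pw2"))
  expect_length(compound_pathways(toy_kb, toy_sets, "drugB"), 0)
  expect_length(compound_pathways(toy_kb, toy_sets, "drugC"), 0)
  expect_error(compound_pathways(toy_kb, toy_sets, "nope"), "unknown")
  expect_warning(
    out <- compound_pathways(toy_kb, toy_sets, "drugB",
                             universe = paste0("g", 1:8)),
    "g9")
  expect_length(out, 0)
})

test_that("pathway groups intersect clinical and steatogenic pathways", {
  g <- build_pathway_groups(list(c("pw1", "pw3")), "drugA", toy_kb,
                            toy_sets)
  expect_setequal(g$clinical, c("pw1", "pw3"))
  expect_setequal(g$steatogenic, c("pw1", "pw2"))
  expect_equal(g$target, "pw1")
  # disjoint groups warn
  expect_warning(g0 <- build_pathway_groups(list("pw3"), "drugA", toy_kb,
                                            toy_sets), "no pathways")
  expect_length(g0$target, 0)
  # union vs intersection policies across datasets
  gu <- build_pathway_groups(list("pw1", "pw2"), "drugA", toy_kb, toy_sets)
  expect_setequal(gu$clinical, c("pw1", "pw2"))
  expect_warning(
    gi <- build_pathway_groups(list("pw1", "pw2"), "drugA", toy_kb,
                               toy_sets, policy = "intersection"),
    "no pathways")
  expect_length(gi$clinical, 0)
})

test_that("pathways-to-target do not depend on the screened library", {
  g1 <- build_pathway_groups(list("pw1"), "drugA", toy_kb, toy_sets)
  kb2 <- rbind(toy_kb, data.frame(compound = "drugZ", targets = "g7",
                                  tox_flag = 0L))
  g2 <- build_pathway_groups(list("pw1"), "drugA", kb2, toy_sets)
  expect_identical(g1$target, g2$target)
})

test_that("candidate selection requires both a significant score and overlap", {
  screen <- data.frame(
    compound = c("drugA", "drugB", "drugC"),
    es_up = 0, es_down = 0,
    score = c(-0.8, 0.7, -0.9),
    p = c(0.001, 0.002, 0.5),
    selected = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  groups <- build_pathway_groups(list(c("pw1", "pw2")), "drugA", toy_kb,
                                 toy_sets)
  cand <- select_candidates(list(screen), toy_kb, toy_sets, groups)
  expect_equal(cand$status[cand$compound == "drugA"], "candidate")
  expect_equal(cand$status[cand$compound == "drugB"], "rejected")
  expect_false("drugC" %in% cand$compound)
  # ranking: |score| desc
  expect_equal(cand$compound, c("drugA", "drugB"))
  # empty target set gives an empty table
  suppressWarnings(
    g0 <- build_pathway_groups(list("pw3"), "drugA", toy_kb, toy_sets))
  expect_equal(nrow(select_candidates(list(screen), toy_kb, toy_sets, g0)),
               0L)
})

test_that("toxicity exclusion reproduces the 46 -> 25 -> 21 worked example", {
  cand <- make_candidates(46, 25)
  filt <- apply_tox_filter(cand)
  expect_equal(filt$n_excluded, 25L)
  expect_equal(filt$n_retained, 21L)
  expect_equal(sum(filt$table$status == "excluded-tox"), 25L)
  # no flags: all retained
  expect_equal(apply_tox_filter(make_candidates(10, 0))$n_retained, 10L)
  # all flagged: none retained, with a warning
  expect_warning(all_out <- apply_tox_filter(make_candidates(5, 5)),
                 "all candidates")
  expect_equal(all_out$n_retained, 0L)
})

test_that("screening summary floors the hit rate to one decimal", {
  outcomes <- data.frame(
    compound = sprintf("c%02d", 1:21),
    outcome = c(rep("positive", 6), rep("negative", 12),
                rep("aggravating", 3)), stringsAsFactors = FALSE)
  s <- screening_summary(outcomes)
  expect_equal(s$hit_rate, 28.5)    # floor(100 * 6/21 * 10)/10
  expect_equal(s$counts$positive, 6L)
  expect_equal(screening_summary(
    data.frame(compound = 1:10, outcome = rep("negative", 10)))$hit_rate, 0)
  expect_equal(screening_summary(
    data.frame(compound = 1:10, outcome = rep("positive", 10)))$hit_rate,
    100)
  expect_error(screening_summary(data.frame(compound = character(0),
                                            outcome = character(0))),
               "zero")
})

test_that("network export is typed, deterministic and connected", {
  screen <- data.frame(compound = "drugA", es_up = 0.8, es_down = -0.7,
                       score = 0.75, p = 0.001, selected = TRUE,
                       stringsAsFactors = FALSE)
  groups <- build_pathway_groups(list("pw1"), "drugA", toy_kb, toy_sets)
  cand <- select_candidates(list(screen), toy_kb, toy_sets, groups)
  net <- export_network(cand, toy_kb, toy_sets, groups)
  expect_equal(nrow(net$nodes), 3L)   # pathway pw1, drugA, gene g1
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$nodes$type, c("pathway", "compound", "gene"))
  # empty candidates: pathways-to-target only
  empty <- cand[0, ]
  net0 <- export_network(empty, toy_kb, toy_sets, groups)
  expect_equal(net0$nodes$type, "pathway")
  expect_equal(nrow(net0$edges), 0L)
  # every candidate reaches a pathway-to-target through one of its genes
  for (cp in net$nodes$id[net$nodes$type == "compound"]) {
    gs <- net$edges$to[net$edges$from == cp & net$edges$type == "targets"]
    expect_true(any(net$edges$from %in% gs &
                      net$edges$type == "member-of"))
  }
})

test_that("relaxing the screen alpha only grows the candidate set", {
  cfg <- small_cohort_config(seed = 61)
  uni <- gen_universe(cfg)
  st <- gene_stats(uni$dataset, c("NASH", "Healthy"))
  q <- query_signature(st, tag_size = 20)
  strict <- screen_library(uni$library, q, alpha = 0.01, B = 199, seed = 6)
  loose <- screen_library(uni$library, q, alpha = 0.10, B = 199, seed = 6)
  expect_true(all(strict$compound[strict$selected] %in%
                    loose$compound[loose$selected]))
})
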