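# Shared fixtures: small configurations and hand-built tables used across
# the suite. Everything is generated in code; nothing is read from disk.

small_cohort_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_genes = 300L,
         group_sizes = c(Healthy = 5L, NAFL = 5L, NASH = 5L),
         n_gene_sets = 12L, set_size_range = c(8L, 15L),
         n_planted_pathways = 3L, n_de_per_pathway = 6L,
         n_library_compounds = 20L, n_reversers = 2L, n_mimickers = 2L,
         tag_size = 20L, seed = seed),
    list(...))
  do.call(sim_config, args)
}

small_image_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(image_width = 256L, image_height = 256L, n_nuclei = 8L,
         n_droplets = 20L, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# Minimal gene-statistics table with chosen t and two-sided p values.
stats_table <- function(t, p = NULL, genes = NULL) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_along(t))
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(t))
  data.frame(gene = genes, t_mod = t, p = p, stringsAsFactors = FALSE)
}

# Candidate table of the shape produced by select_candidates().
make_candidates <- function(n, n_tox) {
  data.frame(compound = sprintf("c%03d", seq_len(n)),
             score = seq(0.9, 0.4, length.out = n),
             sign = 1L, p = 0.01, n_overlap = 1L, overlap = "pw1",
             tox_flag = as.integer(seq_len(n) <= n_tox),
             status = "candidate", stringsAsFactors = FALSE)
}

# Independent K-S enrichment oracle: empirical-CDF formulation evaluated
# only at the tag values, distinct from the rank-walk in the package.
ks_oracle <- function(v, n) {
  Ft <- function(x) mean(v <= x)
  a <- max(vapply(v, function(x) Ft(x) - x / n, numeric(1)))
  b <- max(vapply(v, function(x) x / n - (Ft(x) - 1 / length(v)),
                  numeric(1)))
  if (a >= b - 1e-12) a else -b
}

# Combined score as screen_library computes it, for brute-force nulls.
combined_score <- function(eu, ed) if (eu * ed >= 0) 0 else (eu - ed) / 2
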