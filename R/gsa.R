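# Directional gene-set analysis: nine set-level statistics, gene-sampling
# permutation nulls, five directionality classes (distinct up, mixed up,
# non-directional, mixed down, distinct down) and cross-method consensus
# ranking.

#' @rdname run_gsa
#' @format NULL
#' @export
GSA_METHODS <- c("mean", "median", "sum", "maxmean",
                 "fisher", "stouffer", "reporter", "tailstrength",
                 "wilcoxon")

#' @rdname run_gsa
#' @format NULL
#' @export
GSA_CLASSES <- c("distinct_up", "mixed_up", "non_directional",
                 "mixed_down", "distinct_down")

p_based <- function(method) {
  method %in% c("fisher", "stouffer", "reporter", "tailstrength")
}

check_method <- function(method) {
  if (!method %in% GSA_METHODS) {
    stop("unknown method '", method, "'; valid methods: ",
         paste(GSA_METHODS, collapse = ", "))
  }
}

# Per-gene inputs for every method/direction variant, derived once from a
# gene-statistics table. One-sided p-values are reconstructed from the
# two-sided p and the sign of t so that negating every t swaps the up and
# down inputs exactly.
gene_level_inputs <- function(stats) {
  t <- stats$t_mod
  p <- pmax(stats$p, .Machine$double.xmin)
  p_up <- ifelse(t > 0, p / 2, 1 - p / 2)
  p_down <- ifelse(t < 0, p / 2, 1 - p / 2)
  n <- length(t)
  list(n = n, gene = stats$gene,
       up = list(t = t, p = p_up, r = rank(t)),
       down = list(t = -t, p = p_down, r = rank(-t)),
       nd = list(t = abs(t), p = p, r = rank(abs(t))))
}

# Set statistic for a B x m matrix of member rows; `inp` is one variant
# slot of gene_level_inputs(). Larger values = stronger enrichment in the
# variant's direction for every method (right-tail tests throughout).
row_set_stat <- function(method, inp, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  m <- ncol(idx)
  if (method %in% c("mean", "median", "sum", "maxmean")) {
    X <- matrix(inp$t[idx], ncol = m)
    switch(method,
      mean = rowMeans(X),
      sum = rowSums(X),
      median = apply(X, 1, stats::median),
      maxmean = {
        sp <- rowMeans(pmax(X, 0))
        sn <- rowMeans(pmax(-X, 0))
        ifelse(sp >= sn, sp, -sn)
      })
  } else if (p_based(method)) {
    P <- matrix(inp$p[idx], ncol = m)
    P <- pmin(pmax(P, .Machine$double.xmin), 1 - 1e-16)
    switch(method,
      fisher = -2 * rowSums(log(P)),
      stouffer = rowSums(stats::qnorm(P, lower.tail = FALSE)) / sqrt(m),
      reporter = apply(stats::qnorm(P, lower.tail = FALSE), 1,
                       stats::median),
      tailstrength = {
        Ps <- t(apply(P, 1, sort))
        if (m == 1L) Ps <- matrix(Ps, ncol = 1)
        rowMeans(1 - sweep(Ps, 2, (m + 1) / seq_len(m), `*`))
      })
  } else if (method == "wilcoxon") {
    n <- length(inp$r)
    W <- rowSums(matrix(inp$r[idx], ncol = m))
    (W - m * (n + 1) / 2) / sqrt(m * (n - m) * (n + 1) / 12)
  } else {
    check_method(method)
  }
}

#' Set-level statistic
#'
#' Computes one of the nine configured gene-set statistics on the member
#' genes of a set. Directional methods (`mean`, `median`, `sum`,
#' `maxmean`) operate on the signed moderated t; p-value methods
#' (`fisher`, `stouffer`, `reporter`, `tailstrength`) on the table's gene
#' p-values; `wilcoxon` on the ranks of t in the whole analyzed universe.
#'
#' @param stats gene-statistics data.frame (needs `gene`, `t_mod`, `p`).
#' @param set character vector of member gene ids.
#' @param method one of `GSA_METHODS`.
#' @return the statistic (a single number).
#' @export
set_statistic <- function(stats, set, method) {
  check_method(method)
  idx <- match(set, stats$gene)
  if (anyNA(idx)) stop("set members absent from the gene universe: ",
                       paste(set[is.na(idx)], collapse = ", "))
  if (length(idx) < 1L) stop("empty set")
  inp <- list(t = stats$t_mod,
              p = pmax(stats$p, .Machine$double.xmin),
              r = rank(stats$t_mod))
  row_set_stat(method, inp, matrix(idx, nrow = 1))
}

# Null index matrices (and per-method null statistics) cached by set size.
# The draw for size m depends only on (seed, m), so identical p-values are
# obtained regardless of evaluation order, and the same null sets are
# reused across methods and classes (this makes the sign-flip symmetry of
# the up/down p-values exact).
make_null_cache <- function(seed, n_universe, B) {
  cache <- new.env(parent = emptyenv())
  cache$seed <- seed; cache$n <- n_universe; cache$B <- B
  cache
}

null_indices <- function(cache, m) {
  key <- paste0("idx_", m)
  if (is.null(cache[[key]])) {
    set.seed(cache$seed + m)
    cache[[key]] <- t(vapply(seq_len(cache$B),
                             function(i) sample.int(cache$n, m),
                             integer(m)))
  }
  cache[[key]]
}

null_stats <- function(cache, method, variant, inp, m) {
  key <- paste("ns", method, variant, m, sep = "_")
  if (is.null(cache[[key]])) {
    cache[[key]] <- row_set_stat(method, inp, null_indices(cache, m))
  }
  cache[[key]]
}

emp_p <- function(null, obs) (1 + sum(null >= obs)) / (length(null) + 1)

#' Five directionality-class permutation p-values for one set
#'
#' Builds gene-sampling nulls (random gene sets of matched size) and
#' returns one empirical p-value per directionality class:
#' distinct-up/down from the signed statistic evaluated in each direction;
#' non-directional from the absolute-value (or two-sided-p) statistic;
#' mixed-up/down from the non-directional statistic restricted to the
#' up-moving (`t > 0`) / down-moving subset of the set, against
#' subset-size-matched nulls. Empirical p-values are floored at
#' `1/(B + 1)`; a set whose up (down) subset is empty gets mixed-up
#' (mixed-down) p of 1.
#'
#' With `exact = TRUE` the null enumerates every same-size subset of the
#' universe (feasible only for small universes) and the p-value is the
#' exact tail fraction `#\{null >= obs\}/N`.
#'
#' @param stats gene-statistics data.frame.
#' @param set character vector of member gene ids.
#' @param method one of `GSA_METHODS`.
#' @param B number of permutations (>= 99).
#' @param seed integer seed for the null draws.
#' @param cache optional shared null cache (internal use by [run_gsa()]).
#' @param inputs optional precomputed [gene_level_inputs()].
#' @param exact enumerate all subsets instead of sampling.
#' @return named numeric vector of five p-values (`GSA_CLASSES` order).
#' @export
permutation_class_p <- function(stats, set, method, B = 999L, seed = 1L,
                                cache = NULL, inputs = NULL, exact = FALSE) {
  check_method(method)
  if (!exact && B < 99L) stop("B must be >= 99 for a stable empirical p")
  if (is.null(inputs)) inputs <- gene_level_inputs(stats)
  idx <- match(set, stats$gene)
  if (anyNA(idx)) stop("set members absent from the gene universe: ",
                       paste(set[is.na(idx)], collapse = ", "))
  if (is.null(cache)) cache <- make_null_cache(seed, inputs$n, B)
  t_set <- stats$t_mod[idx]
  idx_up <- idx[t_set > 0]
  idx_down <- idx[t_set < 0]

  one_p <- function(variant, sub_idx) {
    m <- length(sub_idx)
    if (m == 0L) return(1)
    obs <- row_set_stat(method, inputs[[variant]], matrix(sub_idx, nrow = 1))
    if (exact) {
      all_sets <- utils::combn(inputs$n, m)
      null <- row_set_stat(method, inputs[[variant]], t(all_sets))
      sum(null >= obs) / length(null)
    } else {
      emp_p(null_stats(cache, method, variant, inputs[[variant]], m), obs)
    }
  }
  c(distinct_up = one_p("up", idx),
    mixed_up = one_p("nd", idx_up),
    non_directional = one_p("nd", idx),
    mixed_down = one_p("nd", idx_down),
    distinct_down = one_p("down", idx))
}

#' Assign a directionality class from five class p-values
#'
#' The label is the class with the smallest p-value. Empirical p-values
#' are floored at `1/(B + 1)`, so a strongly coherent set ties at the
#' floor across several classes; ties are therefore resolved by
#' directional specificity: a tie containing exactly one distinct class
#' takes that class, else a tie containing exactly one mixed class takes
#' it, and any tie whose direction is ambiguous (both distinct classes,
#' or both mixed classes, or neither) falls back to `non_directional`.
#'
#' @param p5 numeric vector of five p-values in `GSA_CLASSES` order.
#' @return one of `GSA_CLASSES`.
#' @export
classify_directionality <- function(p5) {
  stopifnot(length(p5) == 5L)
  names(p5) <- GSA_CLASSES
  winners <- names(p5)[p5 == min(p5)]
  if (length(winners) == 1L) return(winners)
  distinct <- intersect(winners, c("distinct_up", "distinct_down"))
  if (length(distinct) == 1L) return(distinct)
  if (length(distinct) == 2L) return("non_directional")
  mixed <- intersect(winners, c("mixed_up", "mixed_down"))
  if (length(mixed) == 1L) return(mixed)
  "non_directional"
}

#' Cross-method consensus ranks and p-values
#'
#' Within each directionality class, sets are ranked per method by p-value
#' (ascending, ties by average rank); the consensus rank is the median
#' rank across methods and the consensus p the median p across methods.
#'
#' @param long data.frame with columns `set`, `method`, `class`, `p`.
#' @return data.frame: set, class, consensus_rank, consensus_p.
#' @export
consensus_rank <- function(long) {
  out <- do.call(rbind, lapply(split(long, long$class), function(d) {
    d$rank <- stats::ave(d$p, d$method, FUN = rank)
    agg <- function(v) stats::aggregate(v, by = list(set = d$set),
                                        FUN = stats::median)
    r <- agg(d$rank); p <- agg(d$p)
    data.frame(set = r$set, class = d$class[1],
               consensus_rank = r$x, consensus_p = p$x,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the directional gene-set analysis
#'
#' For every gene set (within the size bounds), computes the five
#' directionality-class permutation p-values under each configured
#' method, the cross-method consensus rank and p per class, the assigned
#' class (argmin of consensus p, ties toward non-directional) and a
#' class-wise BH-adjusted significance call.
#'
#' @param stats gene-statistics data.frame from [gene_stats()].
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()] or
#'   [gen_gene_sets()]).
#' @param methods subset of `GSA_METHODS` (default all nine).
#' @param B permutations per null (>= 99).
#' @param seed integer seed.
#' @param min_size,max_fraction size bounds: sets with fewer than
#'   `min_size` resolvable members, or more than `max_fraction` of the
#'   universe, are skipped with a warning.
#' @param alpha significance level for the BH-adjusted consensus p.
#' @return object of class `gsa_result`: `table` (set x method x class
#'   long p-values), `consensus` (per set x class consensus rank/p and
#'   BH-adjusted p), `classes` (assigned class and significance per set),
#'   `params`.
#' @export
run_gsa <- function(stats, sets, methods = GSA_METHODS, B = 999L, seed = 1L,
                    min_size = 5L, max_fraction = 0.5, alpha = 0.05) {
  for (m in methods) check_method(m)
  inputs <- gene_level_inputs(stats)
  sizes <- vapply(sets, function(s) sum(s %in% stats$gene), integer(1))
  keep <- sizes >= min_size & sizes <= max_fraction * inputs$n
  if (any(!keep)) {
    warning(sum(!keep), " set(s) outside size bounds skipped: ",
            paste(utils::head(names(sets)[!keep], 5), collapse = ", "))
  }
  sets <- sets[keep]
  if (length(sets) == 0L) stop("no gene set within the size bounds")
  cache <- make_null_cache(seed, inputs$n, B)
  rows <- list()
  for (s in names(sets)) {
    member <- intersect(sets[[s]], stats$gene)
    for (m in methods) {
      p5 <- permutation_class_p(stats, member, m, B = B, seed = seed,
                                cache = cache, inputs = inputs)
      rows[[length(rows) + 1L]] <-
        data.frame(set = s, method = m, class = GSA_CLASSES, p = unname(p5),
                   stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  cons <- consensus_rank(long)
  cons$p_adj <- stats::ave(cons$consensus_p, cons$class,
                           FUN = function(p) stats::p.adjust(p, "BH"))
  classes <- do.call(rbind, lapply(split(cons, cons$set), function(d) {
    d <- d[match(GSA_CLASSES, d$class), ]
    lab <- classify_directionality(d$consensus_p)
    data.frame(set = d$set[1], class = lab,
               best_p = min(d$consensus_p),
               best_p_adj = min(d$p_adj),
               significant = min(d$p_adj) <= alpha,
               stringsAsFactors = FALSE)
  }))
  rownames(classes) <- NULL
  structure(list(table = long, consensus = cons, classes = classes,
                 params = list(methods = methods, B = B, seed = seed,
                               min_size = min_size,
                               max_fraction = max_fraction, alpha = alpha)),
            class = "gsa_result")
}

#' @export
print.gsa_result <- function(x, ...) {
  cat("gsa_result:", length(unique(x$classes$set)), "sets,",
      length(x$params$methods), "methods, B =", x$params$B, "\n")
  print(table(x$classes$class))
  invisible(x)
}

#' Significant pathways from a GSA result
#'
#' Sets whose best class-wise BH-adjusted consensus p is at most `alpha`,
#' annotated with their assigned directionality class.
#'
#' @param result a `gsa_result`.
#' @param alpha significance level.
#' @return character vector of set names with a `classes` attribute
#'   (named assigned classes).
#' @export
significant_pathways <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "gsa_result"))
  sel <- result$classes[result$classes$best_p_adj <= alpha, , drop = FALSE]
  structure(sel$set, classes = stats::setNames(sel$class, sel$set))
}
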