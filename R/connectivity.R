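# Kolmogorov-Smirnov connectivity scoring of query signatures against
# ranked compound profiles: the enrichment score (ES) lives in [-1, 1],
# positive when the tag genes concentrate at the top of the profile
# (similar signatures), negative when they concentrate at the bottom
# (reversed signatures).

#' K-S enrichment score of a tag set in a ranked profile
#'
#' For tag ranks `V(1..t)` (sorted ascending) in a universe of `n` ranks,
#' computes `a = max_j (j/t - V(j)/n)` and
#' `b = max_j (V(j)/n - (j-1)/t)`; the enrichment score is `a` if
#' `a >= b`, else `-b`. ES is 1 - 1/n for a single tag at the top and -1
#' for a single tag at the bottom.
#'
#' Profiles must be strict rankings (permutations). Real-world profiles
#' with tied expression values must be pre-ranked before use: break ties
#' by average rank, then round to a strict order by stable (first-seen)
#' position.
#'
#' @param ranks integer tag ranks, distinct, in `[1, n]`.
#' @param n universe size.
#' @return the enrichment score, in `[-1, 1]`.
#' @export
ks_enrichment <- function(ranks, n) {
  t <- length(ranks)
  if (t == 0L) stop("empty tag set")
  if (t > n) stop("more tags than genes in the universe")
  if (anyDuplicated(ranks) || any(ranks < 1) || any(ranks > n)) {
    stop("tag ranks must be distinct integers in [1, n]")
  }
  v <- sort(ranks)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  # a and b can tie up to floating-point error; ties resolve to a
  if (a >= b - 1e-12) a else -b
}

#' Combined connectivity score of a query signature against a profile
#'
#' Scores the up-tag and down-tag of the query separately with
#' [ks_enrichment()]; when the two enrichment scores have the same sign
#' (or either is zero) the signature shows no coherent relation to the
#' profile and the combined score is 0, otherwise it is
#' `(ES_up - ES_down) / 2`. The combined score is positive for a profile
#' similar to the query signature and negative for a reversed one, and
#' always lies in `[-1, 1]`.
#'
#' @param profile named integer vector: rank of every universe gene
#'   (rank 1 = most up-regulated), a permutation.
#' @param query list with `up` and `down` character vectors of tag genes
#'   (disjoint, each non-empty).
#' @return list: `es_up`, `es_down`, `score`.
#' @export
connectivity_score <- function(profile, query) {
  stopifnot(is.list(query), !is.null(query$up), !is.null(query$down))
  if (length(intersect(query$up, query$down)) > 0L) {
    stop("up and down tags must be disjoint")
  }
  n <- length(profile)
  for (tag in c(query$up, query$down)) {
    if (is.na(match(tag, names(profile)))) {
      stop("tag gene absent from the profile universe: ", tag)
    }
  }
  es_up <- ks_enrichment(unname(profile[query$up]), n)
  es_down <- ks_enrichment(unname(profile[query$down]), n)
  score <- if (es_up * es_down >= 0) 0 else (es_up - es_down) / 2
  list(es_up = es_up, es_down = es_down, score = score)
}

null_connectivity_scores <- function(n, t_up, t_down, B, seed) {
  set.seed(seed)
  vapply(seq_len(B), function(i) {
    picks <- sample.int(n, t_up + t_down)
    up <- sort(picks[seq_len(t_up)])
    down <- sort(picks[t_up + seq_len(t_down)])
    eu <- ks_enrichment(up, n)
    ed <- ks_enrichment(down, n)
    if (eu * ed >= 0) 0 else (eu - ed) / 2
  }, numeric(1))
}

#' Permutation p-value for a connectivity score
#'
#' The null draws random disjoint up/down tag sets of the observed sizes
#' on the same profile and rescores; the two-sided empirical p-value is
#' `(1 + #\{|null| >= |observed|\}) / (B + 1)`.
#'
#' @param profile named rank vector (see [connectivity_score()]).
#' @param tag_sizes integer pair `c(t_up, t_down)`.
#' @param observed observed combined score.
#' @param B number of null draws (>= 99).
#' @param seed integer seed.
#' @param null optional precomputed null score vector (used by
#'   [screen_library()] to share one null across compounds).
#' @return empirical p-value in `(0, 1]`.
#' @export
permutation_p <- function(profile, tag_sizes, observed, B = 999L, seed = 1L,
                          null = NULL) {
  if (is.null(null)) {
    if (B < 99L) stop("B must be >= 99 for a stable empirical p")
    null <- null_connectivity_scores(length(profile), tag_sizes[1],
                                     tag_sizes[2], B, seed)
  }
  (1 + sum(abs(null) >= abs(observed))) / (length(null) + 1)
}

#' Build a query signature from a gene-statistics table
#'
#' The up-tag is the top `tag_size` genes by moderated t, the down-tag
#' the bottom `tag_size`; this is the disease (or steatogen) signature
#' submitted to the connectivity screen.
#'
#' @param stats gene-statistics data.frame.
#' @param tag_size genes per tag (default 50).
#' @return list with `up` and `down` character vectors.
#' @export
query_signature <- function(stats, tag_size = 50L) {
  if (2L * tag_size > nrow(stats)) stop("tag_size too large for universe")
  ord <- order(stats$t_mod, decreasing = TRUE)
  list(up = stats$gene[ord[seq_len(tag_size)]],
       down = stats$gene[rev(ord)[seq_len(tag_size)]])
}

#' Screen a signature library against a query signature
#'
#' Scores every compound profile in the library against the query and
#' attaches a permutation p-value. Because every profile is a permutation
#' of the same universe, the null distribution of the combined score for
#' random tags is identical across profiles; one null of size `B` is
#' therefore drawn and shared by all compounds. A compound is `selected`
#' when `p < alpha` and its score is non-zero — both signs are retained
#' (similar and reversed modes of action).
#'
#' @param library a `signature_library` (universe + named rank vectors).
#' @param query list with `up`/`down` tag gene vectors.
#' @param alpha selection level.
#' @param B null draws (>= 99).
#' @param seed integer seed.
#' @return data.frame of class `connectivity_result`: compound, es_up,
#'   es_down, score, p, selected.
#' @export
screen_library <- function(library, query, alpha = 0.05, B = 999L,
                           seed = 1L) {
  stopifnot(inherits(library, "signature_library"))
  if (length(library$profiles) == 0L) {
    warning("empty signature library")
    out <- data.frame(compound = character(0), es_up = numeric(0),
                      es_down = numeric(0), score = numeric(0),
                      p = numeric(0), selected = logical(0))
    class(out) <- c("connectivity_result", "data.frame")
    return(out)
  }
  if (B < 99L) stop("B must be >= 99 for a stable empirical p")
  n <- length(library$universe)
  null <- null_connectivity_scores(n, length(query$up), length(query$down),
                                   B, seed)
  rows <- lapply(names(library$profiles), function(id) {
    cs <- connectivity_score(library$profiles[[id]], query)
    p <- permutation_p(NULL, NULL, cs$score, null = null)
    data.frame(compound = id, es_up = cs$es_up, es_down = cs$es_down,
               score = cs$score, p = p,
               selected = p < alpha & cs$score != 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("connectivity_result", "data.frame")
  out
}
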