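# Pathway-group construction and candidate selection: intersect the
# clinically deregulated pathways with the pathways hit by in vitro
# steatogens into the pathways-to-target, trace screened compounds back to
# them, exclude hepatotoxic candidates and summarize screening outcomes.

parse_targets <- function(x) {
  if (length(x) == 0L || is.na(x) || x == "") return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

kb_targets <- function(kb, compound) {
  i <- match(compound, kb$compound)
  if (is.na(i)) stop("unknown compound: ", compound)
  parse_targets(kb$targets[i])
}

#' Pathways affected by a compound
#'
#' All gene sets containing at least one of the compound's target genes
#' (membership, not enrichment: a drug-target lookup mapped onto the
#' pathway knowledgebase).
#'
#' @param kb compound knowledgebase data.frame (`compound`, `targets`
#'   semicolon-separated, `tox_flag`).
#' @param sets named list of gene-id vectors.
#' @param compound compound identifier.
#' @param universe optional gene universe; targets outside it are dropped
#'   with a warning.
#' @return character vector of pathway names.
#' @export
compound_pathways <- function(kb, sets, compound, universe = NULL) {
  targets <- kb_targets(kb, compound)
  if (!is.null(universe)) {
    bad <- setdiff(targets, universe)
    if (length(bad) > 0L) {
      warning("unresolvable target gene(s) dropped for ", compound, ": ",
              paste(bad, collapse = ", "))
      targets <- intersect(targets, universe)
    }
  }
  if (length(targets) == 0L) return(character(0))
  names(sets)[vapply(sets, function(s) any(targets %in% s), logical(1))]
}

#' Build the three pathway groups and the pathways-to-target
#'
#' `clinical` is the group of pathways significantly deregulated in the
#' patient cohorts (one significant-pathway vector per dataset/contrast,
#' combined by `policy`); `steatogenic` is the union of the pathways
#' affected by the in vitro steatogens; the pathways-to-target are their
#' intersection.
#'
#' @param clinical list of character vectors of significant pathways (one
#'   per dataset x contrast, e.g. from [significant_pathways()]).
#' @param steatogens compound identifiers of the in vitro steatogens.
#' @param kb compound knowledgebase.
#' @param sets named list of gene sets.
#' @param policy how to combine the clinical results: `"union"` (default)
#'   or `"intersection"`.
#' @return list of class `pathway_groups`: `clinical`, `steatogenic`,
#'   `per_steatogen`, `target`.
#' @export
build_pathway_groups <- function(clinical, steatogens, kb, sets,
                                 policy = c("union", "intersection")) {
  policy <- match.arg(policy)
  stopifnot(length(clinical) >= 1L, length(steatogens) >= 1L)
  clinical <- lapply(clinical, as.character)
  p_clin <- if (policy == "union") Reduce(union, clinical) else
    Reduce(intersect, clinical)
  per_stea <- lapply(stats::setNames(steatogens, steatogens),
                     function(cp) compound_pathways(kb, sets, cp))
  p_stea <- Reduce(union, per_stea, accumulate = FALSE)
  p_target <- intersect(p_clin, p_stea)
  if (length(p_target) == 0L) warning("no pathways-to-target")
  structure(list(clinical = p_clin, steatogenic = p_stea,
                 per_steatogen = per_stea, target = p_target),
            class = "pathway_groups")
}

#' Select and rank candidate compounds
#'
#' A compound enters the candidate table when it was selected in at least
#' one connectivity screen (significant non-zero score); its status is
#' `candidate` when its affected pathways intersect the
#' pathways-to-target and `rejected` otherwise. Candidates are ranked by
#' best absolute score (descending), then pathway-overlap size
#' (descending), then identifier.
#'
#' @param screens list of `connectivity_result` data.frames (one per
#'   steatogen query).
#' @param kb compound knowledgebase.
#' @param sets named list of gene sets.
#' @param groups a `pathway_groups` object.
#' @return data.frame of class `candidate_table`: compound, score, sign,
#'   p, n_overlap, overlap (semicolon-joined), tox_flag, status.
#' @export
select_candidates <- function(screens, kb, sets, groups) {
  stopifnot(inherits(groups, "pathway_groups"), length(screens) >= 1L)
  if (length(groups$target) == 0L) {
    out <- data.frame(compound = character(0), score = numeric(0),
                      sign = integer(0), p = numeric(0),
                      n_overlap = integer(0), overlap = character(0),
                      tox_flag = integer(0), status = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("candidate_table", "data.frame")
    return(out)
  }
  all_res <- do.call(rbind, lapply(screens, as.data.frame))
  sel <- all_res[all_res$selected, , drop = FALSE]
  rows <- lapply(unique(sel$compound), function(cp) {
    d <- sel[sel$compound == cp, , drop = FALSE]
    best <- d[which.max(abs(d$score)), ]
    overlap <- intersect(compound_pathways(kb, sets, cp), groups$target)
    tox <- kb$tox_flag[match(cp, kb$compound)]
    data.frame(compound = cp, score = best$score,
               sign = as.integer(sign(best$score)), p = best$p,
               n_overlap = length(overlap),
               overlap = paste(sort(overlap), collapse = ";"),
               tox_flag = as.integer(tox),
               status = if (length(overlap) > 0L) "candidate" else
                 "rejected",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(compound = character(0), score = numeric(0),
                      sign = integer(0), p = numeric(0),
                      n_overlap = integer(0), overlap = character(0),
                      tox_flag = integer(0), status = character(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(-abs(out$score), -out$n_overlap, out$compound), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Exclude hepatotoxic candidates
#'
#' Candidates with a toxicity flag get status `excluded-tox`; the
#' remainder move on to in vitro screening.
#'
#' @param candidates a `candidate_table`.
#' @return list: `table` (updated statuses), `retained` (the retained
#'   candidate rows), `n_excluded`, `n_retained`.
#' @export
apply_tox_filter <- function(candidates) {
  stopifnot(is.data.frame(candidates))
  is_cand <- candidates$status == "candidate"
  flag <- is_cand & candidates$tox_flag == 1L
  candidates$status[flag] <- "excluded-tox"
  retained <- candidates[candidates$status == "candidate", , drop = FALSE]
  if (sum(is_cand) > 0L && nrow(retained) == 0L) {
    warning("all candidates excluded by the toxicity filter")
  }
  list(table = candidates, retained = retained,
       n_excluded = sum(flag), n_retained = nrow(retained))
}

#' Export the compound-gene-pathway network
#'
#' Nodes are typed `compound`, `gene` and `pathway` (pathways-to-target
#' carry role `pathway-to-target`); edges are `targets` (compound ->
#' gene) and `member-of` (gene -> pathway, restricted to the candidate
#' targets). Ordering is deterministic (sorted identifiers).
#'
#' @param candidates a `candidate_table`.
#' @param kb compound knowledgebase.
#' @param sets named list of gene sets.
#' @param groups a `pathway_groups`.
#' @param json_path,sif_path optional output files (network JSON and SIF).
#' @return list with `nodes` and `edges` data.frames.
#' @export
export_network <- function(candidates, kb, sets, groups,
                           json_path = NULL, sif_path = NULL) {
  keep <- candidates[candidates$status %in% c("candidate", "excluded-tox"),
                     , drop = FALSE]
  nodes <- data.frame(id = sort(groups$target), type = "pathway",
                      role = "pathway-to-target", stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      type = character(0), stringsAsFactors = FALSE)
  for (cp in sort(keep$compound)) {
    nodes <- rbind(nodes, data.frame(id = cp, type = "compound",
                                     role = "candidate",
                                     stringsAsFactors = FALSE))
    for (g in sort(kb_targets(kb, cp))) {
      in_target <- names(sets)[vapply(sets, function(s) g %in% s,
                                      logical(1))]
      in_target <- intersect(in_target, groups$target)
      if (length(in_target) == 0L) next
      if (!g %in% nodes$id) {
        nodes <- rbind(nodes, data.frame(id = g, type = "gene",
                                         role = "target",
                                         stringsAsFactors = FALSE))
      }
      edges <- rbind(edges, data.frame(from = cp, to = g,
                                       type = "targets",
                                       stringsAsFactors = FALSE))
      edges <- rbind(edges, data.frame(from = g, to = sort(in_target),
                                       type = "member-of",
                                       stringsAsFactors = FALSE))
    }
  }
  edges <- unique(edges)
  edges <- edges[order(edges$from, edges$to, edges$type), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  if (!is.null(json_path)) {
    jsonlite::write_json(list(nodes = nodes, edges = edges), json_path,
                         dataframe = "rows", auto_unbox = TRUE)
  }
  if (!is.null(sif_path)) {
    writeLines(sprintf("%s\t%s\t%s", edges$from, edges$type, edges$to),
               sif_path)
  }
  list(nodes = nodes, edges = edges)
}

#' Summarize in vitro screening outcomes
#'
#' Counts outcomes per category and reports the hit rate
#' `100 * positives / screened`, truncated (floored) to one decimal
#' place — the printed convention for screening hit rates.
#'
#' @param outcomes data.frame with columns `compound` and `outcome`
#'   (values among `positive`, `negative`, `aggravating`).
#' @return list: `n_screened`, `counts` (named), `hit_rate` (percent,
#'   one decimal, floored).
#' @export
screening_summary <- function(outcomes) {
  stopifnot(is.data.frame(outcomes), "outcome" %in% names(outcomes))
  n <- nrow(outcomes)
  if (n == 0L) stop("zero screened compounds")
  counts <- table(factor(outcomes$outcome,
                         levels = c("positive", "negative", "aggravating")))
  hit <- floor(1000 * unname(counts["positive"]) / n) / 10
  list(n_screened = n, counts = as.list(counts), hit_rate = hit)
}
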