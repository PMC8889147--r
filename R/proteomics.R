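# Mode-of-action clustering of treatments from proteomic and phenotypic
# fold changes: per-analyte fold-change assembly, [0,1] fraction
# normalization, PCA, k-means and concordance scoring.

#' Assemble a treatment-by-analyte fold-change matrix
#'
#' Divides each treatment's analyte readings by its designated control's
#' readings.
#'
#' @param values data.frame with columns `treatment`, `analyte`, `value`.
#' @param control_map data.frame with columns `treatment`, `control`
#'   (control treatment id for each treatment).
#' @return numeric matrix, rows = treatments, columns = analytes.
#' @export
fold_change_matrix <- function(values, control_map) {
  stopifnot(all(c("treatment", "analyte", "value") %in% names(values)),
            all(c("treatment", "control") %in% names(control_map)))
  wide <- stats::xtabs(value ~ treatment + analyte, data = values)
  wide <- matrix(wide, nrow = nrow(wide), dimnames = dimnames(wide))
  treatments <- setdiff(rownames(wide), unique(control_map$control))
  out <- matrix(NA_real_, length(treatments), ncol(wide),
                dimnames = list(treatments, colnames(wide)))
  for (tr in treatments) {
    ctrl <- control_map$control[match(tr, control_map$treatment)]
    if (is.na(ctrl)) stop("missing control mapping for treatment: ", tr)
    if (!ctrl %in% rownames(wide)) {
      stop("control treatment absent from values: ", ctrl)
    }
    cv <- wide[ctrl, ]
    if (any(cv == 0)) {
      stop("zero control value for analyte: ",
           colnames(wide)[which(cv == 0)[1]])
    }
    out[tr, ] <- wide[tr, ] / cv
  }
  out
}

#' Fraction-normalize columns to the [0, 1] scale
#'
#' Per column, `x' = (x - min) / (max - min)`. A constant column carries
#' no contrast and is set to all zeros with a warning.
#'
#' @param m numeric matrix with >= 2 rows.
#' @return matrix of the same shape with every non-constant column
#'   spanning exactly `[0, 1]`.
#' @export
fraction_normalize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need >= 2 rows")
  out <- apply(m, 2, function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0, length(x)) else (x - r[1]) / diff(r)
  })
  if (any(apply(m, 2, function(x) diff(range(x)) == 0))) {
    warning("constant column(s) normalized to all zeros")
  }
  dimnames(out) <- dimnames(m)
  out
}

#' PCA embedding of a treatment feature matrix
#'
#' Columns are centered (scaling off by default: fraction normalization
#' already bounds the scale). Component signs are fixed by making the
#' largest-magnitude loading of each component positive, so embeddings
#' are deterministic.
#'
#' @param m numeric matrix (rows = treatments).
#' @param n_components number of components to keep.
#' @param scale. also scale columns to unit variance.
#' @return list: `scores` (rows x components), `var_frac` (variance
#'   fraction per kept component), `rotation`.
#' @export
pca_embed <- function(m, n_components = 2L, scale. = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) < n_components + 1L) {
    stop("need more rows than components")
  }
  keep_scale <- scale. && all(apply(m, 2, stats::sd) > 0)
  pc <- stats::prcomp(m, center = TRUE, scale. = keep_scale)
  k <- min(n_components, ncol(pc$x))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sc <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sc[, j] <- -sc[, j]
    }
  }
  var_all <- pc$sdev^2
  list(scores = sc, var_frac = var_all[seq_len(k)] / sum(var_all),
       rotation = rot)
}

#' k-means clustering of an embedding
#'
#' Best-of-`n_init` k-means (smallest within-cluster sum of squares),
#' deterministic under the seed.
#'
#' @param embedding numeric matrix (rows = treatments) — PC scores or the
#'   full normalized feature matrix.
#' @param k number of clusters.
#' @param n_init random restarts.
#' @param seed integer seed.
#' @return list: `labels`, `centers`, `withinss` (total), `k`.
#' @export
kmeans_cluster <- function(embedding, k = 4L, n_init = 50L, seed = 1L) {
  embedding <- as.matrix(embedding)
  if (k > nrow(embedding)) stop("k exceeds the number of rows")
  if (k == 1L) {
    return(list(labels = rep(1L, nrow(embedding)),
                centers = matrix(colMeans(embedding), 1L),
                withinss = sum(scale(embedding, scale = FALSE)^2), k = 1L))
  }
  set.seed(seed)
  km <- stats::kmeans(embedding, centers = k, nstart = n_init,
                      iter.max = 100L)
  list(labels = unname(km$cluster), centers = km$centers,
       withinss = km$tot.withinss, k = k)
}

#' Choose k by mean silhouette width
#'
#' Runs [kmeans_cluster()] over `k_range` and returns the k with the
#' largest mean silhouette width.
#'
#' @inheritParams kmeans_cluster
#' @param k_range candidate cluster counts (each < rows).
#' @return the chosen k, with attribute `silhouette` (named mean widths).
#' @export
choose_k <- function(embedding, k_range = 2:8, n_init = 50L, seed = 1L) {
  embedding <- as.matrix(embedding)
  k_range <- k_range[k_range < nrow(embedding)]
  if (length(k_range) == 0L) stop("no feasible k in k_range")
  d <- stats::dist(embedding)
  sil <- vapply(k_range, function(k) {
    labels <- kmeans_cluster(embedding, k = k, n_init = n_init,
                             seed = seed)$labels
    mean(cluster::silhouette(labels, d)[, "sil_width"])
  }, numeric(1))
  structure(k_range[which.max(sil)],
            silhouette = stats::setNames(sil, k_range))
}

#' Adjusted Rand index between two clusterings
#'
#' Chance-corrected agreement in `[-1, 1]`; 1 for identical labelings, 0
#' in expectation for unrelated ones.
#'
#' @param labels,reference integer/character label vectors of equal
#'   length.
#' @return the adjusted Rand index.
#' @export
cluster_concordance <- function(labels, reference) {
  if (length(labels) != length(reference)) {
    stop("label vectors must have equal length")
  }
  mclust::adjustedRandIndex(labels, reference)
}

#' Proteomic mode-of-action clustering pipeline
#'
#' Fraction-normalizes the feature matrix, embeds it with PCA and
#' clusters the first `n_components` scores with k-means (or the full
#' normalized matrix with `use_pca = FALSE`).
#'
#' @param m treatment-by-analyte matrix (fold changes plus phenotype
#'   columns).
#' @param k clusters (default 4); `k = NULL` chooses k by silhouette.
#' @param n_components PCA components used for clustering.
#' @param use_pca cluster on PC scores (default) or the full matrix.
#' @param n_init,seed forwarded to [kmeans_cluster()].
#' @return list: `normalized`, `embedding` (scores + var_frac), `k`,
#'   `labels`, `centers`.
#' @export
cluster_treatments <- function(m, k = 4L, n_components = 2L,
                               use_pca = TRUE, n_init = 50L, seed = 1L) {
  norm <- fraction_normalize(m)
  emb <- pca_embed(norm, n_components = n_components)
  feat <- if (use_pca) emb$scores else norm
  if (is.null(k)) k <- as.integer(choose_k(feat, n_init = n_init,
                                           seed = seed))
  km <- kmeans_cluster(feat, k = k, n_init = n_init, seed = seed)
  list(normalized = norm, embedding = emb, k = km$k, labels = km$labels,
       centers = km$centers)
}
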