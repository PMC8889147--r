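# Gene-level statistics: two-group linear contrasts, empirical-Bayes
# variance shrinkage (moment matching on log variances), moderated t-tests
# and volcano classification.

#' Expression dataset container
#'
#' A genes-by-samples log2-intensity matrix with a health-status label per
#' sample (Healthy / NAFL / NASH by convention, but any label vocabulary
#' is accepted here; readers may restrict it).
#'
#' @param values numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param status character vector of per-sample status labels.
#' @return an object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, status) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (length(status) != ncol(values)) {
    stop("one status label required per sample")
  }
  if (anyNA(values)) stop("expression matrix contains missing values")
  structure(list(values = values,
                 status = stats::setNames(as.character(status),
                                          colnames(values))),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  print(table(x$status))
  invisible(x)
}

#' Fit per-gene two-group linear contrasts
#'
#' For each gene, the contrast effect is the difference of group means on
#' the log2 scale (test minus control), with the pooled residual variance
#' of the two groups.
#'
#' @param dataset an [expression_dataset()].
#' @param contrast character pair `c(test, control)` of status labels,
#'   e.g. `c("NASH", "Healthy")`.
#' @return data.frame with columns gene, log2FC, s2 (pooled residual
#'   variance), df (residual degrees of freedom `n1 + n2 - 2`) and v
#'   (unscaled variance of the contrast, `1/n1 + 1/n2`).
#' @export
fit_gene_models <- function(dataset, contrast) {
  stopifnot(inherits(dataset, "expression_dataset"), length(contrast) == 2L)
  for (lab in contrast) {
    if (!any(dataset$status == lab)) {
      stop("contrast group absent from dataset: ", lab)
    }
  }
  x1 <- dataset$values[, dataset$status == contrast[1], drop = FALSE]
  x2 <- dataset$values[, dataset$status == contrast[2], drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 + n2 < 3L) stop("need n1 + n2 >= 3 samples for a residual df")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  rss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2L
  data.frame(gene = rownames(dataset$values),
             log2FC = m1 - m2,
             s2 = rss / df,
             df = df,
             v = 1 / n1 + 1 / n2,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used to solve the method-of-moments equation for the prior df.
trigamma_inverse <- function(x, tol = 1e-8, max_iter = 100L) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in seq_len(max_iter)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < tol) break
  }
  y
}

#' Empirical-Bayes variance shrinkage
#'
#' Estimates a scaled inverse-chi-square prior (`d0`, `s0_sq`) for the
#' per-gene residual variances by moment matching on the log variances
#' (digamma/trigamma equations, trigamma inverted numerically), then
#' shrinks each variance to its posterior mean
#' `(d0 * s0_sq + df * s2) / (d0 + df)`. When the spread of the log
#' variances is no larger than the sampling noise the trigamma equation
#' has no finite solution; `d0` is then flagged infinite and the posterior
#' equals `s0_sq` for every gene.
#'
#' Genes with zero residual variance take part in the posterior formula
#' but are excluded from the log-moment estimation.
#'
#' @param s2 per-gene residual variances.
#' @param df per-gene residual degrees of freedom (scalar or vector).
#' @return list: `d0`, `s0_sq`, `s2_post`, `d0_infinite`.
#' @export
squeeze_variances <- function(s2, df) {
  df <- rep_len(df, length(s2))
  usable <- which(df >= 1 & s2 > 0)
  if (sum(df >= 1) < 10L) {
    stop("insufficient genes: need >= 10 genes with df >= 1")
  }
  if (all(s2 == 0)) stop("all residual variances are zero")
  z <- log(s2[usable])
  dg <- df[usable]
  if (stats::var(z) == 0) {
    # zero spread: no evidence of gene-to-gene variance heterogeneity;
    # complete shrinkage to the common observed variance
    s0_sq <- s2[usable][1]
    return(list(d0 = Inf, s0_sq = s0_sq,
                s2_post = rep(s0_sq, length(s2)), d0_infinite = TRUE))
  }
  e <- z - digamma(dg / 2) + log(dg / 2)
  evar <- stats::var(e) - mean(trigamma(dg / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
    d0_inf <- FALSE
  } else {
    d0 <- Inf
    s0_sq <- exp(mean(e))
    s2_post <- rep(s0_sq, length(s2))
    d0_inf <- TRUE
  }
  list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post, d0_infinite = d0_inf)
}

# Log posterior odds of differential expression under the hierarchical
# model: alternative scales the moderated t by sqrt((v + v0)/v). Optional
# diagnostic column; drives no downstream decision.
log_odds_de <- function(t_mod, df_total, v, prior_prop = 0.01,
                        effect_var_ratio = 9) {
  s <- sqrt(1 + effect_var_ratio)
  log(prior_prop / (1 - prior_prop)) +
    stats::dt(t_mod / s, df = df_total, log = TRUE) - log(s) -
    stats::dt(t_mod, df = df_total, log = TRUE)
}

#' Moderated t-tests
#'
#' Combines fitted gene models with the shrinkage result into moderated
#' t-statistics `log2FC / (s_post * sqrt(v))` referred to a Student t
#' distribution on `d0 + df` degrees of freedom (capped at 1e6 when `d0`
#' is infinite), with Benjamini-Hochberg adjustment across genes.
#'
#' @param models output of [fit_gene_models()].
#' @param shrink output of [squeeze_variances()] on `models$s2`.
#' @param compute_lods add a `lods` column (log posterior odds of
#'   differential expression at prior proportion 0.01).
#' @return a gene-statistics data.frame: gene, log2FC, s2, df, s2_post,
#'   t_mod, p, p_adj, de_class (filled by [classify_volcano()]), plus
#'   df_total and optionally lods.
#' @export
moderated_t_test <- function(models, shrink, compute_lods = TRUE) {
  s_post <- sqrt(shrink$s2_post)
  se <- s_post * sqrt(models$v)
  df_total <- pmin(shrink$d0 + models$df, 1e6)
  t_mod <- ifelse(se > 0, models$log2FC / se,
                  ifelse(models$log2FC == 0, 0,
                         sign(models$log2FC) * Inf))
  if (any(se == 0 & models$log2FC != 0)) {
    warning("zero posterior variance: moderated t reported as infinite")
  }
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[is.infinite(t_mod)] <- 0
  p[t_mod == 0 & se == 0] <- 1
  out <- data.frame(gene = models$gene,
                    log2FC = models$log2FC,
                    s2 = models$s2,
                    df = models$df,
                    s2_post = shrink$s2_post,
                    t_mod = t_mod,
                    p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    de_class = NA_character_,
                    df_total = df_total,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (compute_lods) {
    out$lods <- log_odds_de(t_mod, df_total, models$v)
  }
  out$de_class <- classify_volcano(out)
  out
}

#' Volcano classification of differential expression
#'
#' A gene is `up` iff `log2FC > fc_cut` (strict) and `p <= p_cut`
#' (inclusive), `down` iff `log2FC < -fc_cut` and `p <= p_cut`, else
#' `not`. The raw p-value, not the adjusted one, feeds the rule.
#'
#' @param stats gene-statistics data.frame with `log2FC` and `p`.
#' @param fc_cut log2 fold-change limit (default 1).
#' @param p_cut p-value limit (default 0.05).
#' @return character vector of classes.
#' @export
classify_volcano <- function(stats, fc_cut = 1, p_cut = 0.05) {
  ifelse(stats$log2FC > fc_cut & stats$p <= p_cut, "up",
         ifelse(stats$log2FC < -fc_cut & stats$p <= p_cut, "down", "not"))
}

#' Gene-level statistics pipeline
#'
#' One-call wrapper: fit contrasts, shrink variances, compute moderated t
#' and classify the volcano.
#'
#' @inheritParams fit_gene_models
#' @inheritParams classify_volcano
#' @param compute_lods passed to [moderated_t_test()].
#' @return gene-statistics data.frame (see [moderated_t_test()]) with an
#'   attribute `shrinkage` holding the (d0, s0_sq) estimates.
#' @export
gene_stats <- function(dataset, contrast, fc_cut = 1, p_cut = 0.05,
                       compute_lods = TRUE) {
  models <- fit_gene_models(dataset, contrast)
  shrink <- squeeze_variances(models$s2, models$df)
  out <- moderated_t_test(models, shrink, compute_lods = compute_lods)
  out$de_class <- classify_volcano(out, fc_cut = fc_cut, p_cut = p_cut)
  attr(out, "shrinkage") <- shrink[c("d0", "s0_sq", "d0_infinite")]
  out
}
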