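# Experimental-arm computations: lipid-droplet image quantification,
# ROS normalization, BCA protein quantification, viability dose-response
# with IC10 extrapolation, and ANOVA/Tukey group comparison.

as_ebimage <- function(channel) {
  if (!is.matrix(channel) || !is.numeric(channel)) {
    stop("image channel must be a 2-D numeric matrix")
  }
  if (any(!is.finite(channel))) stop("image intensities must be finite")
  EBImage::Image(pmin(pmax(channel, 0), 1))
}

filter_label_size <- function(lab, min_area, max_area = Inf) {
  areas <- tabulate(lab)
  bad <- which(areas < min_area | areas > max_area)
  if (length(bad) > 0L) lab <- EBImage::rmObjects(lab, bad)
  lab
}

#' Segment nuclei in a fluorescence channel
#'
#' Pipeline: 3x3 median filter, white top-hat background subtraction
#' (disk radius `r_bg`), Otsu threshold, hole filling, removal of objects
#' below `min_area`, then a distance-transform watershed to split
#' touching nuclei.
#'
#' @param channel 2-D numeric matrix (intensities in `[0, 1]`).
#' @param r_bg top-hat disk radius in pixels (default 25).
#' @param min_area minimum nucleus area in pixels (default 100).
#' @param watershed_tolerance minimum height of an object in the distance
#'   map for it to be split (default 1).
#' @return list: `labels` (integer label matrix), `count`.
#' @export
segment_nuclei <- function(channel, r_bg = 25, min_area = 100,
                           watershed_tolerance = 1) {
  img <- as_ebimage(channel)
  if (diff(range(img)) == 0) {
    return(list(labels = matrix(0L, nrow(channel), ncol(channel)),
                count = 0L))
  }
  sm <- EBImage::medianFilter(img, 1L)
  th <- EBImage::whiteTopHat(sm, EBImage::makeBrush(2L * r_bg + 1L, "disc"))
  if (diff(range(th)) == 0) {
    return(list(labels = matrix(0L, nrow(channel), ncol(channel)),
                count = 0L))
  }
  bin <- th > EBImage::otsu(th)
  bin <- EBImage::fillHull(bin)
  lab <- filter_label_size(EBImage::bwlabel(bin), min_area)
  if (max(lab) == 0) {
    return(list(labels = matrix(0L, nrow(channel), ncol(channel)),
                count = 0L))
  }
  ws <- EBImage::watershed(EBImage::distmap(lab > 0),
                           tolerance = watershed_tolerance)
  ws <- filter_label_size(ws, min_area)
  list(labels = EBImage::imageData(ws), count = max(ws))
}

#' Segment lipid droplets in a fluorescence channel
#'
#' Pipeline: white top-hat background subtraction (disk radius `r_bg`),
#' Otsu threshold, removal of objects outside
#' `[min_area, max_area]`. The integrated intensity is the sum of the
#' original (pre-filter) pixel values under the droplet mask.
#'
#' @param channel 2-D numeric matrix.
#' @param r_bg top-hat disk radius in pixels (default 5).
#' @param min_area,max_area droplet area bounds in pixels (defaults 2 and
#'   500).
#' @param dilate_radius dilation (pixels) applied to the droplet mask
#'   before integrating intensity, so the smoothed droplet edges below
#'   the threshold are still counted (default 2; 0 disables).
#' @return list: `labels`, `count`, `total_area` (pixels, undilated),
#'   `intensity` (integrated over the dilated mask).
#' @export
segment_droplets <- function(channel, r_bg = 5, min_area = 2,
                             max_area = 500, dilate_radius = 2) {
  img <- as_ebimage(channel)
  empty <- list(labels = matrix(0L, nrow(channel), ncol(channel)),
                count = 0L, total_area = 0L, intensity = 0)
  if (diff(range(img)) == 0) return(empty)
  th <- EBImage::whiteTopHat(img, EBImage::makeBrush(2L * r_bg + 1L, "disc"))
  if (diff(range(th)) == 0) return(empty)
  bin <- th > EBImage::otsu(th)
  lab <- filter_label_size(EBImage::bwlabel(bin), min_area, max_area)
  mask <- lab > 0
  imask <- mask
  if (dilate_radius > 0 && max(lab) > 0) {
    imask <- EBImage::dilate(mask,
                             EBImage::makeBrush(2L * dilate_radius + 1L,
                                                "disc"))
  }
  list(labels = EBImage::imageData(lab), count = max(lab),
       total_area = sum(mask),
       intensity = sum(channel[EBImage::imageData(imask) > 0]))
}

#' Per-nucleus circular association of droplets
#'
#' Optional droplet-to-cell assignment: each droplet centroid is assigned
#' to the nearest nucleus centroid within `radius` pixels (unassigned
#' droplets get 0). Off by default in the quantification pipeline.
#'
#' @param nucleus_labels,droplet_labels label matrices from the
#'   segmenters.
#' @param radius association radius in pixels.
#' @return integer vector: the owning nucleus of each droplet (0 = none).
#' @export
associate_droplets <- function(nucleus_labels, droplet_labels, radius = 60) {
  centroid <- function(lab) {
    ids <- sort(unique(lab[lab > 0]))
    t(vapply(ids, function(i) {
      w <- which(lab == i, arr.ind = TRUE)
      colMeans(w)
    }, numeric(2)))
  }
  nc <- centroid(nucleus_labels)
  dc <- centroid(droplet_labels)
  if (nrow(dc) == 0L) return(integer(0))
  if (nrow(nc) == 0L) return(rep(0L, nrow(dc)))
  vapply(seq_len(nrow(dc)), function(i) {
    d <- sqrt(rowSums((nc - matrix(dc[i, ], nrow(nc), 2, byrow = TRUE))^2))
    j <- which.min(d)
    if (d[j] <= radius) j else 0L
  }, integer(1))
}

image_lipid_metric <- function(image, normalize_by, ...) {
  nuc <- segment_nuclei(image$nuclei, ...)
  if (nuc$count == 0L) return(NA_real_)
  drp <- segment_droplets(image$droplets)
  if (normalize_by == "count") {
    drp$intensity / nuc$count
  } else {
    nuc_int <- sum(image$nuclei[nuc$labels > 0])
    if (nuc_int == 0) NA_real_ else drp$intensity / nuc_int
  }
}

#' Lipid-droplet fold change of treated over control images
#'
#' The per-image metric is the integrated droplet-channel intensity over
#' the droplet masks divided by the nuclei count (or, optionally, by the
#' integrated nuclear intensity); the fold change is the ratio of the
#' treated to the control mean metric. Images without detected nuclei are
#' excluded with a warning.
#'
#' @param treated,control lists of two-channel images (each a list with
#'   `nuclei` and `droplets` matrices).
#' @param normalize_by `"count"` (default) or `"nuclear_intensity"`.
#' @param ... segmentation parameters forwarded to [segment_nuclei()].
#' @return the fold change (a single number).
#' @export
lipid_fold_change <- function(treated, control, normalize_by = "count",
                              ...) {
  stopifnot(length(treated) >= 1L, length(control) >= 1L)
  metr <- function(images) {
    m <- vapply(images, image_lipid_metric, numeric(1),
                normalize_by = normalize_by, ...)
    if (anyNA(m)) {
      warning(sum(is.na(m)), " image(s) without nuclei excluded")
      m <- m[!is.na(m)]
    }
    if (length(m) == 0L) stop("all images excluded: no nuclei detected")
    m
  }
  mt <- metr(treated)
  mc <- metr(control)
  if (mean(mc) == 0) stop("zero control signal")
  mean(mt) / mean(mc)
}

#' ROS fold change normalized per microgram protein
#'
#' `FC = (RFU_sample / protein_sample) / (RFU_control / protein_control)`.
#'
#' @param rfu_sample,protein_sample,rfu_control,protein_control scalar
#'   fluorescence (RFU) and protein (ug) readings.
#' @return the fold change.
#' @export
ros_fold_change <- function(rfu_sample, protein_sample,
                            rfu_control, protein_control) {
  if (protein_sample <= 0 || protein_control <= 0) {
    stop("protein mass must be positive")
  }
  (rfu_sample / protein_sample) / (rfu_control / protein_control)
}

#' Protein quantification from a BCA standard curve
#'
#' Fits an ordinary least-squares line absorbance ~ concentration to the
#' standards and inverts it for the samples; negative inversions are
#' clipped to zero with a warning.
#'
#' @param absorbances sample absorbances.
#' @param standards data.frame with columns `conc` and `absorbance`
#'   (>= 3 standards).
#' @return estimated concentrations (same units as the standards).
#' @export
quantify_protein <- function(absorbances, standards) {
  stopifnot(is.data.frame(standards),
            all(c("conc", "absorbance") %in% names(standards)))
  if (nrow(standards) < 3L) stop("need at least 3 standards")
  if (stats::sd(standards$conc) == 0) {
    stop("degenerate standards: no concentration spread")
  }
  fit <- stats::lm(absorbance ~ conc, data = standards)
  b <- stats::coef(fit)
  conc <- (absorbances - b[[1]]) / b[[2]]
  if (any(conc < 0)) {
    warning("negative inversion(s) clipped to 0")
    conc <- pmax(conc, 0)
  }
  unname(conc)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `y = d + (a - d) / (1 + (x/c)^b)` with bounded
#' parameters (`a` in `[50, 150]`, `d` in `[-20, 80]`, `b > 0`, `c`
#' within the tested dose range times `[0.01, 100]`). A flat response —
#' the 4PL not improving on a constant fit at the 5% level (partial
#' F-test) — yields status `"flat"` and no IC10.
#'
#' @param doses positive dose levels (>= 5 distinct values).
#' @param viability viability, percent of untreated control.
#' @return object of class `dose_response_fit`: `par` (a, d, c, b),
#'   `sigma` (residual sd), `status` (`"ok"` or `"flat"`), `doses`.
#' @export
fit_dose_response <- function(doses, viability) {
  stopifnot(length(doses) == length(viability))
  if (length(unique(doses)) < 5L) stop("need at least 5 dose levels")
  if (any(doses <= 0)) stop("doses must be positive")
  n <- length(doses)
  rss0 <- sum((viability - mean(viability))^2)
  start <- list(a = min(max(viability), 150),
                d = max(min(viability), -20),
                c = exp(mean(log(range(doses)))), b = 1)
  lower <- c(a = 50, d = -20, c = 0.01 * min(doses), b = 1e-3)
  upper <- c(a = 150, d = 80, c = 100 * max(doses), b = 50)
  fit <- try(minpack.lm::nlsLM(
    viability ~ d + (a - d) / (1 + (dose / c)^b),
    data = data.frame(dose = doses, viability = viability),
    start = start, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(par = NULL, sigma = NA_real_, status = "flat",
                          doses = range(doses)),
                     class = "dose_response_fit"))
  }
  par <- stats::coef(fit)
  rss1 <- sum(stats::resid(fit)^2)
  flat <- if (rss1 == 0) rss0 == 0 else {
    f <- ((rss0 - rss1) / 3) / (rss1 / (n - 4))
    p_f <- stats::pf(f, 3, n - 4, lower.tail = FALSE)
    !is.finite(f) || p_f > 0.05
  }
  structure(list(par = par,
                 sigma = sqrt(rss1 / max(1, n - 4)),
                 status = if (flat) "flat" else "ok",
                 doses = range(doses)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("dose_response_fit status:", x$status, "\n")
  if (!is.null(x$par)) print(round(x$par, 4))
  invisible(x)
}

#' IC10 from a fitted 4PL curve
#'
#' The dose where the fitted viability crosses `level` percent of control
#' (default 90, i.e. a 10% viability reduction in absolute terms), solved
#' in closed form: `x = c * ((a - level) / (level - d))^(1/b)`. Undefined
#' (NA) for a flat fit or when the curve never crosses `level`; the
#' `extrapolated` attribute flags an IC10 outside the tested dose range.
#'
#' @param fit a `dose_response_fit`.
#' @param level target viability in percent (default 90).
#' @return the IC10 dose with attribute `extrapolated`, or `NA` with
#'   attribute `status` when undefined.
#' @export
ic10 <- function(fit, level = 90) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (fit$status != "ok") {
    return(structure(NA_real_, status = fit$status))
  }
  a <- fit$par[["a"]]; d <- fit$par[["d"]]
  cc <- fit$par[["c"]]; b <- fit$par[["b"]]
  if (!(a > level && level > d)) {
    return(structure(NA_real_, status = "no-crossing"))
  }
  x <- cc * ((a - level) / (level - d))^(1 / b)
  structure(x, extrapolated = x < fit$doses[1] || x > fit$doses[2])
}

#' One-way ANOVA with Tukey HSD multiple comparisons
#'
#' Ordinary one-way ANOVA across the groups followed by Tukey's honestly
#' significant difference test (studentized-range adjustment) for all
#' pairwise comparisons.
#'
#' @param groups named list of numeric vectors, each with >= 2 values.
#' @return list: `F`, `p`, `tukey` (data.frame comparison, diff, p_adj).
#' @export
anova_tukey <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) < 2L)) stop("every group needs n >= 2")
  d <- data.frame(value = unlist(groups, use.names = FALSE),
                  group = factor(rep(names(groups), lengths(groups))))
  fit <- stats::aov(value ~ group, data = d)
  tab <- summary(fit)[[1]]
  fval <- tab$`F value`[1]
  pval <- tab$`Pr(>F)`[1]
  if (is.na(fval) || tab$`Mean Sq`[1] == 0) {  # identical groups
    fval <- 0; pval <- 1
  }
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  if (fval == 0) tukey$p_adj <- 1
  list(F = fval, p = pval, tukey = tukey)
}
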