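# Image segmentation, lipid/ROS fold changes, BCA protein quantification,
# 4PL dose-response with IC10, and ANOVA/Tukey.

test_that("noise-free synthetic images segment to the planted counts", {
  img <- gen_microscopy_image(small_image_config(seed = 71,
                                                 image_noise_sd = 0))
  nuc <- segment_nuclei(img$image$nuclei)
  drp <- segment_droplets(img$image$droplets)
  expect_equal(nuc$count, img$truth$n_nuclei)
  expect_equal(drp$count, img$truth$n_droplets)
  expect_lt(abs(drp$intensity / img$truth$total_droplet_intensity - 1),
            0.05)
  expect_error(segment_nuclei(array(0, c(4, 4, 2))), "2-D")
})

test_that("blank images yield zero counts", {
  blank <- gen_microscopy_image(small_image_config(seed = 72, n_nuclei = 0L,
                                                   n_droplets = 0L,
                                                   image_noise_sd = 0))
  expect_equal(segment_nuclei(blank$image$nuclei)$count, 0L)
  d <- segment_droplets(blank$image$droplets)
  expect_equal(d$count, 0L)
  expect_equal(d$intensity, 0)
})

test_that("the watershed splits a planted touching pair", {
  img <- gen_microscopy_image(small_image_config(seed = 73,
                                                 image_noise_sd = 0),
                              touching_pair = TRUE)
  expect_length(img$truth$touching_pair, 2L)
  nuc <- segment_nuclei(img$image$nuclei)
  expect_equal(nuc$count, img$truth$n_nuclei)
})

test_that("single-pixel objects are removed by the minimum-area filter", {
  ch <- matrix(0, 64, 64)
  ch[cbind(c(10, 30, 50), c(10, 30, 50))] <- 0.9
  expect_equal(segment_droplets(ch, min_area = 2)$count, 0L)
})

test_that("segmentation counts are invariant to intensity rescaling", {
  img <- gen_microscopy_image(small_image_config(seed = 74))
  for (k in c(0.4, 0.8)) {
    expect_equal(segment_droplets(img$image$droplets * k)$count,
                 segment_droplets(img$image$droplets)$count)
    expect_equal(segment_nuclei(img$image$nuclei * k)$count,
                 segment_nuclei(img$image$nuclei)$count)
  }
})

test_that("lipid fold change is 1 on identical sets and recovers a 3x ratio", {
  imgs <- lapply(75:76, function(s) {
    gen_microscopy_image(small_image_config(seed = s))$image
  })
  expect_equal(lipid_fold_change(imgs, imgs), 1.0)
  ctrl <- lapply(77:78, function(s) gen_microscopy_image(
    small_image_config(seed = s, droplet_intensity = 0.3))$image)
  trt <- lapply(77:78, function(s) gen_microscopy_image(
    small_image_config(seed = s, droplet_intensity = 0.9))$image)
  fc <- lipid_fold_change(trt, ctrl)
  expect_gt(fc, 2.7); expect_lt(fc, 3.3)
  # zero-nuclei images excluded with a warning; zero control errors
  blank <- gen_microscopy_image(small_image_config(
    seed = 79, n_nuclei = 0L, n_droplets = 0L, image_noise_sd = 0))$image
  expect_warning(expect_error(lipid_fold_change(trt, list(blank)),
                              "no nuclei"))
  nodrops <- gen_microscopy_image(small_image_config(
    seed = 80, n_droplets = 0L, image_noise_sd = 0))$image
  expect_error(lipid_fold_change(trt, list(nodrops)),
               "zero control signal")
})

test_that("ROS fold change normalizes fluorescence per microgram protein", {
  expect_equal(ros_fold_change(100, 5, 100, 5), 1.0)
  expect_equal(ros_fold_change(200, 5, 100, 5), 2.0)
  expect_equal(ros_fold_change(100, 10, 100, 5), 0.5)
  expect_error(ros_fold_change(100, 0, 100, 5), "positive")
})

test_that("BCA inversion recovers concentrations from the standard line", {
  std <- data.frame(conc = c(0, 5, 10, 20), absorbance = NA)
  std$absorbance <- 0.1 + 0.04 * std$conc
  expect_equal(quantify_protein(0.1 + 0.04 * 7.5, std), 7.5)
  expect_warning(out <- quantify_protein(0.05, std), "clipped")
  expect_equal(out, 0)
  expect_error(quantify_protein(0.3, std[1:2, ]), "3 standards")
  expect_error(quantify_protein(0.3, data.frame(conc = c(5, 5, 5),
                                                absorbance = c(1, 2, 3))),
               "degenerate")
  # noisy standards: slope recovered within its confidence interval
  set.seed(81)
  stdn <- data.frame(conc = rep(c(0, 5, 10, 20, 40), 3))
  stdn$absorbance <- 0.1 + 0.04 * stdn$conc + rnorm(nrow(stdn), sd = 0.01)
  ci <- confint(lm(absorbance ~ conc, stdn))["conc", ]
  expect_gt(0.04, ci[1]); expect_lt(0.04, ci[2])
})

test_that("4PL fitting inverts to the known IC10 in closed form", {
  doses <- c(0.1, 0.3, 1, 3, 10, 30, 100)
  dr <- gen_dose_response(c(a = 100, d = 0, c = 10, b = 1), doses,
                          noise_sd = 0, seed = 1)
  fit <- fit_dose_response(dr$dose, dr$viability)
  expect_equal(fit$status, "ok")
  x10 <- ic10(fit)
  expect_equal(as.numeric(x10), 10 / 9, tolerance = 1e-6)
  expect_false(attr(x10, "extrapolated"))
  # closed form agrees with numerical root finding on the fitted curve
  froot <- uniroot(function(x) {
    four_pl(x, fit$par[["a"]], fit$par[["d"]], fit$par[["c"]],
            fit$par[["b"]]) - 90
  }, c(1e-6, 1e6), tol = 1e-12)$root
  expect_equal(as.numeric(x10), froot, tolerance = 1e-9)
})

test_that("flat responses take the fit-failure path", {
  doses <- c(0.1, 1, 3, 10, 30)
  flat <- gen_dose_response(c(a = 100, d = 0, c = 10, b = 0), doses,
                            noise_sd = 1, seed = 2)
  fit <- fit_dose_response(flat$dose, flat$viability)
  expect_equal(fit$status, "flat")
  expect_true(is.na(ic10(fit)))
  expect_equal(attr(ic10(fit), "status"), "flat")
  expect_error(fit_dose_response(c(1, 2, 3), c(1, 2, 3)), "5 dose")
  expect_error(fit_dose_response(c(-1, 1, 2, 3, 4), rep(1, 5)), "positive")
})

test_that("noisy 4PL curves recover parameters within 10%", {
  doses <- 10^seq(-1.5, 2, length.out = 8)
  truth <- c(a = 100, d = 5, c = 8, b = 1.3)
  dr <- gen_dose_response(truth, doses, noise_sd = 2, n_replicates = 3,
                          seed = 3)
  fit <- fit_dose_response(dr$dose, dr$viability)
  expect_equal(fit$status, "ok")
  for (pn in c("a", "c", "b")) {
    expect_lt(abs(fit$par[[pn]] - truth[[pn]]) / truth[[pn]], 0.10)
  }
  true_ic10 <- truth[["c"]] *
    ((truth[["a"]] - 90) / (90 - truth[["d"]]))^(1 / truth[["b"]])
  expect_lt(abs(as.numeric(ic10(fit)) - true_ic10) / true_ic10, 0.10)
})

test_that("identical groups give a null ANOVA and unit Tukey p-values", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- anova_tukey(g)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_true(all(res$tukey$p_adj == 1))
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("two-group Tukey equals the pooled-variance t-test", {
  set.seed(82)
  g <- list(a = rnorm(6), b = rnorm(6, 1))
  res <- anova_tukey(g)
  tt <- t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(res$tukey$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(res$p, tt$p.value, tolerance = 1e-9)
})

test_that("three-group Tukey p matches studentized-range integration", {
  set.seed(83)
  g <- list(a = rnorm(5), b = rnorm(5, 0.8), c = rnorm(5, 2))
  res <- anova_tukey(g)
  # independent numerical oracle: studentized-range CDF by integration
  ptukey_num <- function(q, k, df) {
    inner <- function(s) vapply(s, function(si) {
      k * integrate(function(z) {
        dnorm(z) * (pnorm(z) - pnorm(z - q * si))^(k - 1)
      }, -8, 8)$value
    }, numeric(1))
    dens <- function(s) {
      exp(log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
            (df - 1) * log(s) - df * s^2 / 2)
    }
    integrate(function(s) dens(s) * inner(s), 0, 6)$value
  }
  d <- data.frame(value = unlist(g),
                  group = factor(rep(names(g), lengths(g))))
  ms_err <- summary(aov(value ~ group, d))[[1]]$`Mean Sq`[2]
  for (i in seq_len(nrow(res$tukey))) {
    pair <- strsplit(res$tukey$comparison[i], "-")[[1]]
    q <- abs(mean(g[[pair[1]]]) - mean(g[[pair[2]]])) /
      sqrt(ms_err / 5)
    expect_equal(res$tukey$p_adj[i], 1 - ptukey_num(q, 3, 12),
                 tolerance = 1e-4)
  }
})
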