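test_that("per-detector CV follows the two-point formula and matches recomputation", {
  m <- rbind(flat = c(2, 2, 2, 2), twopt = c(1, 3, 1, 3))
  colnames(m) <- paste0("s", 1:4)
  res <- cv_per_detector(m)
  expect_equal(res$cv[res$detector == "flat"], 0)
  expect_equal(cv_per_detector(rbind(x = c(1, 3)))$cv, sqrt(2) / 2, tolerance = 1e-12)

  m2 <- random_rq_matrix(5, 4, seed = 6)
  expect_equal(cv_per_detector(m2)$cv,
               unname(apply(m2, 1, sd) / rowMeans(m2)), tolerance = 1e-12)
})

test_that("CV reduction summary builds comparable ECDFs and detects dominance", {
  m <- random_rq_matrix(8, 6, seed = 13)
  same <- cv_reduction_summary(m, list(copy = m))
  expect_equal(same$summary$fraction_reduced[same$summary$scheme == "copy"], 0)
  expect_true(same$summary$dominates_raw[same$summary$scheme == "copy"])
  expect_equal(
    same$ecdf$ecdf[same$ecdf$scheme == "copy"],
    same$ecdf$ecdf[same$ecdf$scheme == "raw"])

  # scaling noise removed by the true factors: median CV strictly lower
  signal <- random_rq_matrix(10, 8, seed = 14)
  fac <- 2^rnorm(8, 0, 1.5)
  noisy <- sweep(signal, 2, fac, `*`)
  red <- cv_reduction_summary(noisy, list(true_nf = signal))
  s <- red$summary
  expect_lt(s$median_cv[s$scheme == "true_nf"], s$median_cv[s$scheme == "raw"])

  expect_error(cv_reduction_summary(m, list(bad = m[1:3, ])),
               class = "mirnorm_input_error")
})

test_that("autoscaling standardizes each detector row of log10 values", {
  m <- rbind(a = c(1, 10, 100), b = c(2, 4, 16))
  colnames(m) <- paste0("s", 1:3)
  arq <- autoscale(rq_tbl(m))
  w <- mirnorm:::arq_wide(arq)
  expect_equal(unname(w["a", ]), c(-1, 0, 1))
  expect_equal(unname(rowMeans(w)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(w, 1, sd)), c(1, 1), tolerance = 1e-12)

  mc <- rbind(m, flat = c(5, 5, 5))
  expect_warning(a2 <- autoscale(rq_tbl(mc)), "flat")
  expect_false("flat" %in% attr(a2, "detectors"))
  only_flat <- matrix(5, 1, 3, dimnames = list("flat", paste0("s", 1:3)))
  expect_error(autoscale(rq_tbl(only_flat)), class = "mirnorm_data_error")

  # adding a constant to every log10 value of a detector leaves ARQ unchanged
  m3 <- m; m3["a", ] <- m["a", ] * 1000
  expect_equal(mirnorm:::arq_wide(autoscale(rq_tbl(m3))), w, tolerance = 1e-12)
})

test_that("detector PCA matches an eigendecomposition oracle with a fixed sign convention", {
  # rank-1 matrix: one component carries everything
  r1 <- outer(c(1, 2, 3, 4), c(1, 0.5, 2))
  dimnames(r1) <- list(paste0("d", 1:4), paste0("s", 1:3))
  p1 <- pca_detectors(r1, scaled = FALSE)
  expect_equal(p1$explained$proportion[1], 1, tolerance = 1e-10)

  set.seed(20)
  m <- matrix(rnorm(160), 20, 8,
              dimnames = list(sprintf("d%02d", 1:20), paste0("s", 1:8)))
  p <- pca_detectors(m, scaled = FALSE)
  centred <- sweep(m, 2, colMeans(m))
  ev <- eigen(stats::cov(centred))$values
  expect_equal(p$explained$proportion[1:7], (ev / sum(ev))[1:7], tolerance = 1e-10)

  # scores reproduce prcomp up to the deterministic sign flip
  pr <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  got <- as.matrix(p$scores[, -1])
  ref <- pr$x[, 1:ncol(got)]
  for (c in seq_len(ncol(got))) {
    expect_equal(abs(unname(got[, c])), abs(unname(ref[, c])), tolerance = 1e-8)
    j <- which.max(abs(p$loadings[[c + 1]]))
    expect_gte(p$loadings[[c + 1]][j], 0)  # sign convention
  }
})

test_that("the separation statistic contrasts cluster tightness", {
  scores <- tibble::tibble(
    detector = c("t1", "t2", "t3", "b1", "b2", "b3", "c1", "c2", "c3"),
    PC1 = c(0, 0, 0, -5, 5, 0, 5, 15, 10),
    PC2 = c(1, 1, 1, 0, 0, 8, 20, 20, 28)
  )
  pca <- structure(list(scores = scores,
                        explained = tibble::tibble(component = c("PC1", "PC2"),
                                                   proportion = c(0.6, 0.4)),
                        scaled = TRUE), class = "detector_pca")
  # a point-mass top set has zero spread
  expect_equal(stability_separation(pca, c("t1", "t2", "t3"), c("b1", "b2", "b3")), 0)
  # congruent clouds (b* translated) have equal spread
  expect_equal(stability_separation(pca, c("c1", "c2", "c3"), c("b1", "b2", "b3")), 1)
  expect_error(stability_separation(pca, c("t1", "b1"), c("b1", "b2")),
               class = "mirnorm_input_error")
  expect_error(stability_separation(pca, character(0), "b1"),
               class = "mirnorm_input_error")
})

test_that("designed-stable detectors cluster more tightly than designed-variable ones", {
  for (s in 1:5) {
    sim <- simulate_ct(sim_config(), seed = s)
    rq <- censor_ct(sim$ct, 35) |>
      compute_rq_spike("spike_in") |>
      filter_detection(sim$annotation, 2 / 3) |>
      impute_knn(10) |>
      suppressMessages()
    pca <- pca_detectors(rq, scaled = TRUE)
    cls <- sim$truth$detectors
    stable <- intersect(cls$detector[cls$class == "stable"], pca$scores$detector)
    varc <- intersect(cls$detector[cls$class == "variable"], pca$scores$detector)
    expect_lt(stability_separation(pca, stable, varc), 1)
  }
})
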