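make_ct <- function(m, status = NULL) ct_tbl(m, status)

test_that("censoring is strict above the threshold and identity otherwise", {
  m <- matrix(c(36.2, 35.0, 30, 20, 34.9, 25), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  ct <- censor_ct(make_ct(m), threshold = 35)
  st <- mirnorm:::ct_wide(ct, "status")
  expect_equal(st["a", "s1"], "above_threshold")
  expect_equal(st["b", "s1"], "observed")  # exactly at threshold kept
  expect_true(all(st[, "s2"] == "observed"))

  low <- make_ct(matrix(c(20, 25, 30, 31), 2, 2,
                        dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_identical(mirnorm:::ct_wide(censor_ct(low, 35), "status"),
                   mirnorm:::ct_wide(low, "status"))
})

test_that("low-Ct outliers are flagged and user exclusions always win", {
  m <- matrix(c(3.1, 25, 12, 26), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_message(ct <- flag_low_ct_outliers(make_ct(m), floor = 10), "1")
  st <- mirnorm:::ct_wide(ct, "status")
  expect_equal(st["a", "s1"], "flagged_outlier")
  expect_equal(st["b", "s1"], "observed")

  ct2 <- exclude_cells(make_ct(m), data.frame(detector = "b", sample = "s2"))
  expect_equal(mirnorm:::ct_wide(ct2, "status")["b", "s2"], "excluded_by_user")
})

test_that("spike-referenced RQs follow 2^-(Ct - Ct_spike) and propagate missingness", {
  m <- matrix(c(30, 25, 25, 25, NA, 24), 3, 2, byrow = TRUE,
              dimnames = list(c("tgt", "eq", "gap"), c("s1", "s2")))
  st <- matrix("observed", 3, 2); st[3, 1] <- "undetermined"
  spike <- matrix(c(25, 24), 1, 2, dimnames = list("spike", c("s1", "s2")))
  ct <- ct_tbl(rbind(m, spike), rbind(st, matrix("observed", 1, 2)))
  rq <- compute_rq_spike(ct, "spike")
  w <- mirnorm:::rq_wide(rq)
  expect_equal(w["tgt", "s1"], 2^-5)           # Ct 30 vs spike 25
  expect_equal(w["eq", "s1"], 1)               # equal to spike
  expect_true(is.na(w["gap", "s1"]))           # missing propagates
  expect_false("spike" %in% rownames(w))       # spike removed from candidates

  expect_error(compute_rq_spike(ct, "nope"), class = "mirnorm_config_error")
  st2 <- st; ct2m <- rbind(m, spike)
  stsp <- rbind(st, matrix(c("undetermined", "observed"), 1, 2))
  ct2 <- ct_tbl(ct2m, stsp)
  expect_error(compute_rq_spike(ct2, "spike"), "s1", class = "mirnorm_data_error")
})

test_that("shifting all Ct values of a sample (spike included) leaves its RQs unchanged", {
  set.seed(7)
  base <- matrix(runif(20, 20, 30), 5, 4,
                 dimnames = list(c(paste0("d", 1:4), "spike"), paste0("s", 1:4)))
  rq1 <- mirnorm:::rq_wide(compute_rq_spike(ct_tbl(base), "spike"))
  shifted <- base
  shifted[, 2] <- shifted[, 2] + 3.7
  rq2 <- mirnorm:::rq_wide(compute_rq_spike(ct_tbl(shifted), "spike"))
  expect_equal(rq1, rq2, tolerance = 1e-12)
})

test_that("min-Ct referencing picks the lowest-mean fully observed detector with id tie-break", {
  m <- matrix(c(20, 22, 25, 27, 20, 22), 3, 2, byrow = TRUE,
              dimnames = list(c("b-ref", "tgt", "a-ref"), c("s1", "s2")))
  rq <- compute_rq_min_ct(ct_tbl(m))
  expect_equal(attr(rq, "reference_id"), "a-ref")  # tie with b-ref, smaller id wins
  w <- mirnorm:::rq_wide(rq)
  expect_equal(unname(w["a-ref", ]), c(1, 1))
  expect_equal(w["tgt", "s1"], 2^-5)

  # only fully observed detectors are eligible
  st <- matrix("observed", 3, 2); st[3, 2] <- "undetermined"
  rq2 <- compute_rq_min_ct(ct_tbl(m, st))
  expect_equal(attr(rq2, "reference_id"), "b-ref")

  st_all <- matrix("undetermined", 3, 2)
  st_all[1, 1] <- "observed"; st_all[2, 2] <- "observed"
  expect_error(compute_rq_min_ct(ct_tbl(m, st_all)), class = "mirnorm_data_error")
})

test_that("detection filter enforces the per-group ceiling rule", {
  set.seed(1)
  m <- 2^matrix(rnorm(40), 10, 4 + 4)
  rownames(m) <- sprintf("d%02d", 1:10)
  colnames(m) <- sprintf("s%d", 1:8)
  ann <- test_annotation(colnames(m), rep(c("A", "B"), each = 4))
  # scripted missingness: per-detector count of missing cells in group A
  miss_a <- c(0, 1, 2, 3, 4, 0, 1, 2, 0, 1)
  for (i in 1:10) if (miss_a[i] > 0) m[i, seq_len(miss_a[i])] <- NA
  rq <- rq_tbl(m)
  # ceil(2/3 * 4) = 3 present needed per group -> detectors with >=2 missing in A fail
  expected_keep <- rownames(m)[4 - miss_a >= 3]
  filt <- suppressMessages(filter_detection(rq, ann, 2 / 3))
  expect_identical(attr(filt, "detectors"), expected_keep)

  # the rule applies to every group, not any
  m2 <- m[1:3, ]
  m2[2, 5:7] <- NA  # fine in A, only 1/4 in B... actually 1 present
  rq2 <- rq_tbl(m2)
  filt2 <- suppressMessages(filter_detection(rq2, ann, 2 / 3))
  expect_false("d02" %in% attr(filt2, "detectors"))
})

test_that("lowering the detection fraction never removes a retained detector", {
  set.seed(11)
  m <- 2^matrix(rnorm(96), 12, 8)
  dimnames(m) <- list(sprintf("d%02d", 1:12), sprintf("s%d", 1:8))
  m[sample(length(m), 30)] <- NA
  m[1, ] <- 2  # keep at least one complete detector
  ann <- test_annotation(colnames(m), rep(c("A", "B"), each = 4))
  kept <- function(fr) tryCatch(
    attr(suppressMessages(filter_detection(rq_tbl(m), ann, fr)), "detectors"),
    error = function(e) character(0))
  for (fr in c(1, 0.9, 0.75, 0.5, 0.25)) {
    expect_true(all(kept(1) %in% kept(fr)))
  }
  expect_true(all(kept(0.75) %in% kept(0.5)))
})

test_that("KNN imputation reproduces hand-computed weighted means and is identity when complete", {
  set.seed(3)
  m <- 2^matrix(rnorm(24, 0, 1), 6, 4,
                dimnames = list(sprintf("d%d", 1:6), sprintf("s%d", 1:4)))
  expect_identical(mirnorm:::rq_wide(impute_knn(rq_tbl(m))), m)

  # duplicated row, one copy masked, k = 1 -> zero-distance neighbour copies
  m2 <- rbind(m, dup = m[1, ])
  m2["dup", 2] <- NA
  out <- mirnorm:::rq_wide(impute_knn(rq_tbl(m2), k = 1))
  expect_equal(out["dup", 2], m[1, 2])

  # mask one cell of a complete matrix; brute-force the weighted-mean formula
  m3 <- m
  m3[2, 3] <- NA
  out3 <- mirnorm:::rq_wide(impute_knn(rq_tbl(m3), k = 3))
  y <- log2(m3)
  d <- apply(y[-2, ], 1, function(r) sqrt(sum((r[-3] - y[2, -3])^2)))
  nb <- names(sort(d))[1:3]
  w <- 1 / sort(d)[1:3]
  expected <- 2^(sum(w * y[nb, 3]) / sum(w))
  expect_equal(out3[2, 3], expected, tolerance = 1e-12)
  expect_equal(out3[-2, ], m[-2, ])  # observed untouched
})

test_that("pseudo-detectors append the three central tendencies exactly once", {
  m <- matrix(c(1, 4, 2, 8), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  rq <- add_pseudo_detectors(rq_tbl(m))
  w <- mirnorm:::rq_wide(rq)
  expect_equal(unname(w["pseudo_mean", "s1"]), 2.5)     # mean(1, 4)
  expect_equal(unname(w["pseudo_geomean", "s1"]), 2.0)  # geomean(1, 4)
  expect_equal(unname(w["pseudo_median", "s1"]), 2.5)
  expect_equal(unname(w["pseudo_mean", "s2"]), 5)
  expect_true(all(mirnorm:::pseudo_flags(rq)[c("pseudo_mean", "pseudo_geomean", "pseudo_median")]))

  # all-identical column: all three tendencies equal it
  mc <- matrix(3, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  wc <- mirnorm:::rq_wide(add_pseudo_detectors(rq_tbl(mc)))
  expect_equal(unname(wc[3:5, ]), matrix(3, 3, 2), tolerance = 1e-12)

  expect_error(add_pseudo_detectors(rq), class = "mirnorm_input_error")
  mi <- m; mi[1, 1] <- NA
  expect_error(add_pseudo_detectors(rq_tbl(mi)), "impute", class = "mirnorm_input_error")
})
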