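test_that("CV score reproduces the hand-computed share examples", {
  m <- rbind(A = c(1, 2), B = c(3, 6))
  colnames(m) <- c("s1", "s2")
  res <- cv_score(rq_tbl(m))
  expect_equal(res$cv, c(0, 0), tolerance = 1e-12)  # constant shares

  m2 <- rbind(A = c(1, 2), B = c(3, 2))
  colnames(m2) <- c("s1", "s2")
  res2 <- cv_score(rq_tbl(m2))
  expect_equal(res2$cv[res2$detector == "A"], sd(c(0.25, 0.5)) / 0.375,
               tolerance = 1e-10)
  expect_equal(res2$cv[res2$detector == "A"], 0.4714045, tolerance = 1e-6)
  expect_equal(res2$cv[res2$detector == "B"], 0.2828427, tolerance = 1e-6)
})

test_that("CV score is invariant to per-sample scaling and scores pseudo rows against real sums", {
  m <- random_rq_matrix(6, 8, seed = 2)
  sc <- m %*% diag(runif(8, 0.1, 10))
  dimnames(sc) <- dimnames(m)
  expect_equal(cv_score(rq_tbl(m))$cv, cv_score(rq_tbl(sc))$cv, tolerance = 1e-12)

  rq <- add_pseudo_detectors(rq_tbl(m))
  res <- cv_score(rq)
  # the arithmetic-mean pseudo-detector's share of the real total is constant
  expect_equal(res$cv[res$detector == "pseudo_mean"], 0, tolerance = 1e-12)
  # real-detector scores unaffected by the appended rows
  expect_equal(res$cv[!res$pseudo], cv_score(rq_tbl(m))$cv, tolerance = 1e-12)
})

test_that("SSS is the Euclidean norm of the three scores with id tie-breaks", {
  g <- c(a = 0.3, b = 0, c = 0.1)
  r <- c(a = 0.4, b = 0, c = 0.1)
  cv <- c(a = 0, b = 0, c = 0.1)
  tab <- sss_combine(g, r, cv)
  expect_equal(tab$sss[tab$detector == "a"], 0.5, tolerance = 1e-12)  # 3-4-5
  expect_equal(tab$sss[tab$detector == "b"], 0)
  expect_equal(tab$rank[tab$detector == "b"], 1)
  expect_equal(tab$sss, sqrt(tab$genorm_m^2 + tab$normfinder_rho^2 + tab$cv_score^2),
               tolerance = 1e-12)

  # permuting the input order changes nothing
  perm <- sss_combine(g[c(3, 1, 2)], r[c(2, 3, 1)], cv)
  expect_equal(as.data.frame(perm), as.data.frame(tab))

  # ties broken lexicographically
  tied <- sss_combine(c(z = 1, y = 1), c(z = 0, y = 0), c(z = 0, y = 0))
  expect_equal(tied$detector[tied$rank == 1], "y")

  expect_error(sss_combine(g, r[1:2], cv), class = "mirnorm_input_error")
})

test_that("dominance on all three scores implies a strictly smaller SSS", {
  set.seed(12)
  for (i in 1:20) {
    s <- abs(rnorm(3)); eps <- abs(rnorm(3)) * c(1, 0, 1) + c(0, 1e-3, 0)
    tab <- sss_combine(c(a = s[1], b = s[1] + eps[1]),
                       c(a = s[2], b = s[2] + eps[2]),
                       c(a = s[3], b = s[3] + eps[3]))
    expect_lt(tab$sss[tab$detector == "a"], tab$sss[tab$detector == "b"])
  }
})

test_that("reference selection walks ranks with family and pseudo skips", {
  tab <- sss_combine(
    c(A = 0.1, B = 0.2, C = 0.3, pseudo_mean = 0.05),
    c(A = 0, B = 0, C = 0, pseudo_mean = 0),
    tibble::tibble(detector = c("A", "B", "C", "pseudo_mean"),
                   cv = c(0, 0, 0, 0),
                   pseudo = c(FALSE, FALSE, FALSE, TRUE)),
    families = tibble::tibble(detector = c("A", "B", "C", "pseudo_mean"),
                              family = c("fam1", "fam1", "fam2", "pseudo_mean"))
  )
  expect_equal(select_references(tab, 2), c("A", "C"))  # B skipped: family taken
  expect_equal(select_references(tab, 1), "A")          # pseudo ranked 1st is skipped
  err <- expect_error(select_references(tab, 3), class = "mirnorm_selection_error")
  expect_match(conditionMessage(err), "2")
})

test_that("cross-platform combination rescales, averages and intersects", {
  t1 <- sss_combine(c(A = 0.1, B = 0.5, C = 0.9), c(A = 0, B = 0, C = 0),
                    c(A = 0, B = 0, C = 0), platform = "TM")
  t2 <- sss_combine(c(A = 0.2, B = 0.6, C = 1.0, D = 2), c(A = 0, B = 0, C = 0, D = 0),
                    c(A = 0, B = 0, C = 0, D = 0), platform = "EX")
  comb <- combine_platforms(list(t1, t2))
  expect_false("D" %in% comb$detector)              # not assayed on both
  expect_equal(comb$combined_score[comb$detector == "A"], 0)  # best everywhere
  expect_equal(comb$rank[comb$detector == "A"], 1)

  # identical tables reproduce the single-platform ordering
  same <- combine_platforms(list(t1, t1))
  expect_equal(same$detector[order(same$rank)],
               t1$detector[order(t1$rank)][t1$detector[order(t1$rank)] %in% same$detector])

  expect_error(combine_platforms(list(t1)), class = "mirnorm_input_error")
})

test_that("all stability scores and the SSS are invariant to per-sample scaling", {
  m <- random_rq_matrix(7, 10, seed = 44)
  ann <- test_annotation(colnames(m), rep(c("A", "B"), each = 5))
  fac <- runif(10, 0.1, 10)
  sc <- sweep(m, 2, fac, `*`)
  t1 <- stability_scores(rq_tbl(m), ann)
  t2 <- stability_scores(rq_tbl(sc), ann)
  expect_equal(t1$sss, t2$sss, tolerance = 1e-8)
  expect_identical(t1$detector, t2$detector)
  expect_identical(t1$rank, t2$rank)
})
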