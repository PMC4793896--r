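#' geNorm-style stability analysis by iterative elimination
#'
#' For every pair of detectors the pairwise variation `V(j,k)` is the sample
#' standard deviation (n-1 denominator) over samples of
#' `log2(rq_j / rq_k)`; a detector's `M` value is the mean of its pairwise
#' variations with all remaining detectors. The detector with the highest
#' `M` is removed (ties: the lexicographically larger id goes first) and the
#' cycle repeats until the two most stable detectors remain. Because
#' expression ratios cancel any per-sample factor, `M` is invariant to
#' sample-wise rescaling.
#'
#' Each detector's *stepwise* `M` — its value in the round of its
#' elimination (for the final pair, the last round) — is the canonical
#' stability score; the first round also provides the single-pass full-set
#' `M` for every detector.
#'
#' @param rq An [rq_tbl] or positive numeric matrix (detectors x samples),
#'   complete, with at least 3 detectors and 2 samples.
#' @return An object of class `genorm_fit` with elements:
#'   `stepwise_m` (tibble `detector`, `m`, `round`), `fullset_m` (tibble of
#'   round-1 `M` values), `elimination` (ids in removal order, the final
#'   pair last), `final_pair`, `ranking` (most stable first) and `rounds`
#'   (per-round `M` table).
#' @export
genorm <- function(rq) {
  m <- as_rq_matrix(rq)
  if (nrow(m) < 3) stop_input("geNorm needs at least 3 detectors")
  if (ncol(m) < 2) stop_input("geNorm needs at least 2 samples")
  if (anyNA(m)) stop_input("geNorm needs a complete matrix; impute first")
  if (any(m <= 0)) stop_input("relative quantities must be strictly positive")

  y <- log2(m)
  active <- rownames(y)
  elim <- character(0)
  step_m <- numeric(0)
  rounds <- list()
  r <- 0L
  repeat {
    r <- r + 1L
    M <- genorm_m_values(y[active, , drop = FALSE])
    rounds[[r]] <- tibble(round = r, detector = names(M), m = unname(M))
    if (length(active) == 2) {
      pair <- sort(active)
      step_m[pair] <- M[pair]
      elim <- c(elim, pair)
      break
    }
    worst <- names(M)[M == max(M)]
    out <- sort(worst, decreasing = TRUE)[1]  # tie: larger id removed first
    step_m[out] <- M[[out]]
    elim <- c(elim, out)
    active <- setdiff(active, out)
  }
  structure(list(
    stepwise_m = tibble(
      detector = elim,
      m = unname(step_m[elim]),
      round = c(seq_len(length(elim) - 2L), rep(length(rounds), 2L))
    ),
    fullset_m = rounds[[1]][, c("detector", "m")],
    elimination = elim,
    final_pair = sort(utils::tail(elim, 2)),
    ranking = rev(elim),
    rounds = dplyr::bind_rows(rounds)
  ), class = "genorm_fit")
}

# Mean pairwise log-ratio SD per detector; V(a,b) via the covariance of the
# log profiles: Var(y_a - y_b) = C_aa + C_bb - 2 C_ab.
genorm_m_values <- function(y) {
  C <- stats::cov(t(y))
  v2 <- outer(diag(C), diag(C), `+`) - 2 * C
  v2[v2 < 0] <- 0
  V <- sqrt(v2)
  diag(V) <- NA
  rowMeans(V, na.rm = TRUE)
}

#' Pairwise variation series for choosing the number of references
#'
#' `V(n, n+1)` is the SD over samples of `log2(NF_n / NF_{n+1})` where
#' `NF_n` is the per-sample geometric mean of the `n` most stable
#' detectors. A small `V(n, n+1)` means adding the (n+1)-th reference
#' changes the normalization factor little; the number of references is
#' user-defined and this series informs the choice.
#'
#' @param rq An [rq_tbl] or positive matrix.
#' @param ranking Detector ids ordered most stable first; defaults to the
#'   ranking of a [genorm()] fit passed directly.
#' @return Tibble with columns `n`, `v` for `n = 2 .. m-1`.
#' @export
genorm_pairwise_v <- function(rq, ranking = NULL) {
  m <- as_rq_matrix(rq)
  if (inherits(ranking, "genorm_fit")) ranking <- ranking$ranking
  ranking <- ranking %||% genorm(m)$ranking
  if (!setequal(ranking, rownames(m)) || anyDuplicated(ranking)) {
    stop_input("`ranking` must order the matrix detectors exactly once each")
  }
  if (length(ranking) < 3) stop_input("need at least 3 detectors for a V(n,n+1) series")
  y <- log2(m)[ranking, , drop = FALSE]
  nf_log <- apply(y, 2, cumsum) / seq_len(nrow(y))  # log2 geomean of top-n
  ns <- 2:(nrow(y) - 1)
  v <- vapply(ns, function(n) stats::sd(nf_log[n, ] - nf_log[n + 1, ]), numeric(1))
  tibble(n = ns, v = v)
}

#' @export
print.genorm_fit <- function(x, ...) {
  cat("geNorm stability fit\n")
  cat("  detectors:", length(x$elimination), "\n")
  cat("  most stable pair:", paste(x$final_pair, collapse = ", "),
      sprintf("(M = %.4g)\n", x$stepwise_m$m[x$stepwise_m$detector == x$final_pair[1]]))
  invisible(x)
}

#' @describeIn genorm Tidy the stepwise M values (one row per detector,
#'   most stable first).
#' @param x A `genorm_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.genorm_fit <- function(x, ...) {
  out <- x$stepwise_m[rev(seq_len(nrow(x$stepwise_m))), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' @describeIn genorm One-row fit summary.
#' @exportS3Method generics::glance
glance.genorm_fit <- function(x, ...) {
  tibble(
    n_detectors = length(x$elimination),
    n_rounds = max(x$rounds$round),
    final_pair = paste(x$final_pair, collapse = "+"),
    min_m = min(x$stepwise_m$m)
  )
}

#' @describeIn genorm Plot stepwise M against stability rank.
#' @param object A `genorm_fit`.
#' @exportS3Method ggplot2::autoplot
autoplot.genorm_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$m)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "stability rank (1 = most stable)",
                  y = "stepwise geNorm M") +
    ggplot2::theme_minimal()
}
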