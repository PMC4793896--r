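# Independent brute-force oracles and small fixture builders. These are kept
# deliberately naive (explicit loops, direct formulas) so they share no code
# path with the package implementation.

random_rq_matrix <- function(m, n, seed) {
  set.seed(seed)
  mat <- 2^matrix(rnorm(m * n, 0, 1), m, n)
  rownames(mat) <- sprintf("d%02d", seq_len(m))
  colnames(mat) <- sprintf("s%02d", seq_len(n))
  mat
}

# Naive geNorm: recompute every pairwise SD of log ratios with sd() at every
# round, eliminate the highest-M detector (ties: lexicographically larger id
# first), record stepwise M values.
oracle_genorm <- function(mat) {
  y <- log2(mat)
  active <- rownames(y)
  elim <- character(0)
  stepwise <- numeric(0)
  repeat {
    M <- sapply(active, function(a) {
      vs <- sapply(setdiff(active, a), function(b) sd(y[a, ] - y[b, ]))
      mean(vs)
    })
    if (length(active) == 2) {
      pair <- sort(active)
      stepwise[pair] <- M[pair]
      elim <- c(elim, pair)
      break
    }
    worst <- names(M)[M == max(M)]
    out <- sort(worst, decreasing = TRUE)[1]
    stepwise[out] <- M[[out]]
    elim <- c(elim, out)
    active <- setdiff(active, out)
  }
  list(elimination = elim, stepwise = stepwise, final_pair = sort(tail(elim, 2)))
}

# Naive V(n, n+1) series from an explicit ranking.
oracle_pairwise_v <- function(mat, ranking) {
  y <- log2(mat)
  sapply(2:(nrow(mat) - 1), function(n) {
    nf_n <- apply(y[ranking[1:n], , drop = FALSE], 2, mean)
    nf_n1 <- apply(y[ranking[1:(n + 1)], , drop = FALSE], 2, mean)
    sd(nf_n - nf_n1)
  })
}

# Draw one replicate of the one-group two-way additive model
# y_ij = a_i + b_j + e_ij with per-detector error SDs `sigma`.
draw_two_way <- function(sigma, n, a = NULL, b = NULL) {
  I <- length(sigma)
  a <- if (is.null(a)) rnorm(I, 5, 1) else a
  b <- if (is.null(b)) rnorm(n, 0, 1) else b
  outer(a, rep(1, n)) + outer(rep(1, I), b) +
    matrix(rnorm(I * n, 0, rep(sigma, n)), I, n)
}

as_test_rq <- function(mat, ...) rq_tbl(mat, ...)

test_annotation <- function(samples, groups) {
  tibble::tibble(sample_id = samples,
                 group = factor(groups, levels = unique(groups)))
}
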