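#' Model-based stability estimation (intra/intergroup variance decomposition)
#'
#' Fits, per biological group, the additive model
#' `y_igj = alpha_ig + beta_gj + e_igj` on `y = log2(rq)` (detector `i`,
#' group `g`, sample `j`), where the sample effect `beta_gj` absorbs any
#' per-sample scaling. The detector-specific intragroup variance is
#' estimated from the two-way centred residuals with a bias correction that
#' accounts for the variance contributed by the other detectors:
#'
#' \deqn{\hat\sigma^2_{ig} = \max\left(0,\ \frac{I}{I-2}\Big(u_{ig} -
#'   \frac{\sum_{i'} u_{i'g}}{I(I-1)}\Big)\right),\quad
#'   u_{ig} = \frac{\sum_j r_{igj}^2}{n_g - 1}.}
#'
#' With a single group the stability value is
#' \eqn{\rho_i = \hat\sigma_{i1}}. With two or more groups the per-group
#' deviation of a detector's mean from the panel average,
#' \eqn{\hat d_{ig}}, yields an intergroup variance
#' \eqn{\hat\gamma^2_i} (method-of-moments, truncated at zero); the
#' deviations are shrunk by
#' \eqn{\hat\gamma^2_i / (\hat\gamma^2_i + \hat\sigma^2_{ig}/n_g)} and
#' combined with the posterior uncertainty into
#' \deqn{\rho_i = \frac{1}{G}\sum_g \left(|\tilde d_{ig}| +
#'   \sqrt{\frac{\hat\gamma^2_i\,\hat\sigma^2_{ig}/n_g}
#'   {\hat\gamma^2_i + \hat\sigma^2_{ig}/n_g} +
#'   \frac{\hat\sigma^2_{ig}}{n_g}}\right).}
#'
#' Lower \eqn{\rho} means more stable: low within-group noise and no
#' systematic between-group shift.
#'
#' @param rq An [rq_tbl] or positive complete matrix with >= 3 detectors.
#' @param ann Sample annotation with `sample_id` and `group`; every sample
#'   of `rq` must appear. Each group needs >= 2 samples.
#' @return Tibble with columns `detector`, `rho`, and `intragroup_sd` (the
#'   root mean intragroup variance across groups).
#' @export
normfinder <- function(rq, ann) {
  m <- as_rq_matrix(rq)
  if (nrow(m) < 3) stop_input("model-based stability needs at least 3 detectors")
  if (anyNA(m)) stop_input("matrix must be complete; impute first")
  if (any(m <= 0)) stop_input("relative quantities must be strictly positive")
  smp <- colnames(m)
  miss <- setdiff(smp, ann$sample_id)
  if (length(miss)) {
    stop_consistency(paste0("sample(s) absent from annotation: ",
                            paste(miss, collapse = ", ")))
  }
  grp <- factor(ann$group[match(smp, ann$sample_id)])
  G <- nlevels(grp)
  I <- nrow(m)
  y <- log2(m)

  sigma2 <- matrix(NA_real_, I, G, dimnames = list(rownames(m), levels(grp)))
  n_g <- integer(G)
  ybar_ig <- matrix(NA_real_, I, G)
  for (g in seq_len(G)) {
    cols <- which(grp == levels(grp)[g])
    n_g[g] <- length(cols)
    if (n_g[g] < 2) {
      stop_input(paste0("group '", levels(grp)[g], "' has fewer than 2 samples"))
    }
    yg <- y[, cols, drop = FALSE]
    ri <- rowMeans(yg)
    cj <- colMeans(yg)
    r <- yg - outer(ri, rep(1, n_g[g])) - outer(rep(1, I), cj) + mean(yg)
    u <- rowSums(r^2) / (n_g[g] - 1)
    sigma2[, g] <- pmax(0, (I / (I - 2)) * (u - sum(u) / (I * (I - 1))))
    ybar_ig[, g] <- ri
  }

  if (G == 1) {
    rho <- sqrt(sigma2[, 1])
  } else {
    ybar_i <- rowMeans(y)
    d <- sweep(ybar_ig, 2, colMeans(ybar_ig)) - (ybar_i - mean(ybar_i))
    noise <- sweep(sigma2, 2, n_g, `/`)  # sigma^2_ig / n_g
    gamma2 <- pmax(0, rowSums(d^2) / (G - 1) - rowMeans(noise))
    denom <- gamma2 + noise
    shrink <- ifelse(denom > 0, gamma2 / denom, 0)
    d_tilde <- d * shrink
    spread <- sqrt(ifelse(denom > 0, gamma2 * noise / denom, 0) + noise)
    rho <- rowMeans(abs(d_tilde) + spread)
  }
  tibble(
    detector = rownames(m),
    rho = unname(rho),
    intragroup_sd = unname(sqrt(rowMeans(sigma2)))
  )
}
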