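#' Per-detector coefficient of variation on the linear scale
#'
#' `CV_i = sd(row_i) / mean(row_i)` over the non-missing values, on the
#' linear RQ/NRQ scale.
#'
#' @param x An [rq_tbl], `mirnorm_normalization`, or positive matrix.
#' @return Tibble with columns `detector`, `cv`.
#' @export
cv_per_detector <- function(x) {
  m <- as_rq_matrix(x)
  if (any(m <= 0, na.rm = TRUE)) stop_input("values must be strictly positive")
  cv <- apply(m, 1, function(r) {
    r <- r[!is.na(r)]
    stats::sd(r) / mean(r)
  })
  tibble(detector = rownames(m), cv = unname(cv))
}

#' Summarize CV reduction across normalization schemes
#'
#' Computes the per-detector CV under each scheme and compares their
#' empirical cumulative distributions on a shared 100-point grid spanning
#' the pooled CV range. A left-shifted (here: everywhere not-lower) ECDF
#' relative to the raw data means the scheme reduced variability across the
#' panel; `dominates_raw` records whether that holds at every grid point.
#'
#' @param raw Unnormalized data ([rq_tbl] or matrix).
#' @param normalized Named list of normalized data
#'   (`mirnorm_normalization`, `rq_tbl` or matrix), same detector set as
#'   `raw`.
#' @param grid_n Number of grid points (default 100).
#' @return A `cv_reduction` object with elements `cv` (long tibble
#'   `scheme`, `detector`, `cv`), `ecdf` (tibble `scheme`, `grid`, `ecdf`)
#'   and `summary` (tibble `scheme`, `median_cv`, `fraction_reduced`,
#'   `dominates_raw`).
#' @export
cv_reduction_summary <- function(raw, normalized, grid_n = 100) {
  if (is.null(names(normalized)) || any(!nzchar(names(normalized)))) {
    stop_input("`normalized` must be a named list")
  }
  cvs <- c(list(raw = cv_per_detector(raw)),
           lapply(normalized, cv_per_detector))
  base <- sort(cvs$raw$detector)
  for (nm in names(cvs)) {
    if (!setequal(cvs[[nm]]$detector, base)) {
      stop_input(paste0("scheme '", nm, "' has a different detector set"))
    }
  }
  long <- dplyr::bind_rows(cvs, .id = "scheme")
  grid <- seq(min(long$cv), max(long$cv), length.out = grid_n)
  ecdf_tbl <- dplyr::bind_rows(lapply(names(cvs), function(nm) {
    f <- stats::ecdf(cvs[[nm]]$cv)
    tibble(scheme = nm, grid = grid, ecdf = f(grid))
  }))
  raw_cv <- stats::setNames(cvs$raw$cv, cvs$raw$detector)
  raw_ecdf <- ecdf_tbl$ecdf[ecdf_tbl$scheme == "raw"]
  summary <- dplyr::bind_rows(lapply(names(cvs), function(nm) {
    v <- cvs[[nm]]$cv
    tibble(
      scheme = nm,
      median_cv = stats::median(v),
      fraction_reduced = mean(stats::setNames(v, cvs[[nm]]$detector)[names(raw_cv)] < raw_cv),
      dominates_raw = all(ecdf_tbl$ecdf[ecdf_tbl$scheme == nm] >= raw_ecdf)
    )
  }))
  structure(list(cv = long, ecdf = ecdf_tbl, summary = summary),
            class = "cv_reduction")
}

#' @export
print.cv_reduction <- function(x, ...) {
  cat("CV reduction summary\n")
  print(x$summary)
  invisible(x)
}

#' @describeIn cv_reduction_summary ECDF curves of the per-detector CV per
#'   scheme; left-shifted curves indicate reduced variability.
#' @param object A `cv_reduction`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_reduction <- function(object, ...) {
  ggplot2::ggplot(object$ecdf,
                  ggplot2::aes(x = .data$grid, y = .data$ecdf,
                               colour = .data$scheme)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "per-detector CV", y = "cumulative fraction of detectors",
                  colour = "scheme") +
    ggplot2::theme_minimal()
}

#' Autoscale relative quantities per detector
#'
#' `ARQ_ij = (log10 rq_ij - mean_i) / sd_i`, where the mean and sample SD
#' are taken across samples of detector `i`'s log10 values. Every retained
#' row has mean 0 and SD 1; constant rows (zero SD) carry no direction
#' information and are dropped with a warning.
#'
#' @param rq A complete, positive [rq_tbl] or matrix.
#' @return A long tibble (`detector`, `sample`, `arq`) of class `arq_tbl`,
#'   with detector/sample order attributes.
#' @export
autoscale <- function(rq) {
  m <- as_rq_matrix(rq)
  if (anyNA(m)) stop_input("matrix must be complete; impute first")
  if (any(m <= 0)) stop_input("values must be strictly positive")
  l <- log10(m)
  sds <- apply(l, 1, stats::sd)
  drop <- sds == 0
  if (all(drop)) stop_data("all detector rows are constant; nothing to autoscale")
  if (any(drop)) {
    rlang::warn(paste0("excluding constant detector row(s): ",
                       paste(rownames(m)[drop], collapse = ", ")))
  }
  l <- l[!drop, , drop = FALSE]
  a <- sweep(sweep(l, 1, rowMeans(l)), 1, sds[!drop], `/`)
  out <- tibble(
    detector = rep(rownames(a), each = ncol(a)),
    sample = rep(colnames(a), times = nrow(a)),
    arq = as.vector(t(a))
  )
  attr(out, "detectors") <- rownames(a)
  attr(out, "samples") <- colnames(a)
  class(out) <- c("arq_tbl", class(out))
  out
}

arq_wide <- function(x) {
  det <- attr(x, "detectors")
  smp <- attr(x, "samples")
  m <- matrix(NA_real_, length(det), length(smp), dimnames = list(det, smp))
  m[cbind(match(x$detector, det), match(x$sample, smp))] <- x$arq
  m
}

#' PCA of detectors in expression space
#'
#' Detectors are the observations (points); samples are the variables. The
#' input is autoscaled log10 RQ (`scaled = TRUE`; per-detector location and
#' scale removed, so PC1 vs PC2 reads out profile shape and is the useful
#' view for reference validation) or plain log10 RQ (`scaled = FALSE`;
#' abundance dominates PC1, so PC2 vs PC3 are the informative components).
#' Computed by singular value decomposition of the column-centred
#' observation matrix, with a deterministic sign convention: each loading
#' vector's largest-magnitude entry is non-negative.
#'
#' @param x An [rq_tbl] (transformed internally according to `scaled`), an
#'   `arq_tbl` from [autoscale()], or a ready numeric matrix (detectors x
#'   variables, used as-is).
#' @param scaled Use autoscaled data (default `TRUE`).
#' @return A `detector_pca` object with `scores` (tibble, one row per
#'   detector), `loadings` (tibble, one row per sample), `explained`
#'   (tibble `component`, `proportion`, `cumulative`) and `scaled`.
#' @export
pca_detectors <- function(x, scaled = TRUE) {
  m <- if (inherits(x, "arq_tbl")) {
    arq_wide(x)
  } else if (inherits(x, "rq_tbl") || is.data.frame(x)) {
    if (scaled) arq_wide(autoscale(x)) else log10(as_rq_matrix(x))
  } else {
    x
  }
  if (nrow(m) < 2 || ncol(m) < 2) stop_data("need at least 2 detectors and 2 samples")
  centred <- sweep(m, 2, colMeans(m))
  if (all(abs(centred) < .Machine$double.eps * 100)) {
    stop_data("fewer than 2 non-constant detectors")
  }
  sv <- svd(centred)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  k <- max(k, 1L)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {  # sign convention
    j <- which.max(abs(loadings[, c]))
    if (loadings[j, c] < 0) {
      loadings[, c] <- -loadings[, c]
      scores[, c] <- -scores[, c]
    }
  }
  pcs <- paste0("PC", seq_len(k))
  prop <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  score_tbl <- as_tibble(stats::setNames(as.data.frame(scores), pcs))
  score_tbl <- dplyr::bind_cols(tibble(detector = rownames(m)), score_tbl)
  load_tbl <- as_tibble(stats::setNames(as.data.frame(loadings), pcs))
  load_tbl <- dplyr::bind_cols(tibble(sample = colnames(m)), load_tbl)
  structure(list(
    scores = score_tbl,
    loadings = load_tbl,
    explained = tibble(component = pcs, proportion = prop,
                       cumulative = cumsum(prop)),
    scaled = scaled
  ), class = "detector_pca")
}

#' @export
print.detector_pca <- function(x, ...) {
  cat(sprintf("Detector PCA (%s data): %d detectors, %d components\n",
              if (x$scaled) "autoscaled" else "unscaled",
              nrow(x$scores), nrow(x$explained)))
  top <- utils::head(x$explained, 3)
  cat("  explained:",
      paste(sprintf("%s %.1f%%", top$component, 100 * top$proportion),
            collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn pca_detectors Detector scores, one row per detector.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.detector_pca <- function(x, ...) x$scores

#' @describeIn pca_detectors One-row summary with explained-variance
#'   fractions of PC1-PC3.
#' @exportS3Method generics::glance
glance.detector_pca <- function(x, ...) {
  p <- x$explained$proportion
  tibble(
    n_detectors = nrow(x$scores),
    n_components = nrow(x$explained),
    prop_pc1 = p[1],
    prop_pc2 = if (length(p) >= 2) p[2] else NA_real_,
    prop_pc3 = if (length(p) >= 3) p[3] else NA_real_
  )
}

#' @describeIn pca_detectors Score plot of two components, optionally
#'   highlighting detector sets (e.g. most/least stable).
#' @param object A `detector_pca`.
#' @param components Two components to plot (default the informative pair
#'   for the scaling used).
#' @param highlight Optional named list of detector-id vectors to colour.
#' @exportS3Method ggplot2::autoplot
autoplot.detector_pca <- function(object, components = NULL, highlight = NULL, ...) {
  components <- components %||% if (object$scaled) c(1, 2) else c(2, 3)
  pcs <- paste0("PC", components)
  d <- object$scores
  d$set <- "other"
  if (!is.null(highlight)) {
    for (nm in names(highlight)) d$set[d$detector %in% highlight[[nm]]] <- nm
  }
  prop <- object$explained$proportion
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]],
                                  colour = .data$set)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", pcs[1], 100 * prop[components[1]]),
      y = sprintf("%s (%.1f%%)", pcs[2], 100 * prop[components[2]])
    ) +
    ggplot2::theme_minimal()
}

#' Cluster-tightness ratio of stable versus variable detectors
#'
#' In the detector PCA plane, stable candidates should collapse into the
#' narrow end of the funnel-shaped cloud. The statistic is the mean
#' distance of the top-set points from their centroid divided by the mean
#' distance of the bottom-set points from theirs; values below 1 mean the
#' designated stable set clusters more tightly than the variable set.
#'
#' @param pca_out A `detector_pca`.
#' @param top_set,bottom_set Disjoint, non-empty detector-id vectors.
#' @param components Components used (default PC1-PC2 for autoscaled data,
#'   PC2-PC3 otherwise).
#' @return The separation statistic (single number).
#' @export
stability_separation <- function(pca_out, top_set, bottom_set,
                                 components = NULL) {
  if (length(top_set) == 0 || length(bottom_set) == 0) {
    stop_input("both detector sets must be non-empty")
  }
  if (length(intersect(top_set, bottom_set))) {
    stop_input("top and bottom sets must be disjoint")
  }
  components <- components %||% if (pca_out$scaled) c(1, 2) else c(2, 3)
  components <- components[components <= nrow(pca_out$explained)]
  pcs <- paste0("PC", components)
  s <- pca_out$scores
  missing_ids <- setdiff(c(top_set, bottom_set), s$detector)
  if (length(missing_ids)) {
    stop_input(paste0("detector(s) absent from PCA: ",
                      paste(missing_ids, collapse = ", ")))
  }
  spread <- function(ids) {
    p <- as.matrix(s[match(ids, s$detector), pcs, drop = FALSE])
    centroid <- colMeans(p)
    mean(sqrt(rowSums(sweep(p, 2, centroid)^2)))
  }
  spread(top_set) / spread(bottom_set)
}
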