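#' Per-sample normalization factor from selected references
#'
#' `NF_j` is the geometric mean of the selected references' relative
#' quantities in sample `j`. Every reference must be present (non-missing)
#' in every sample.
#'
#' @param rq An [rq_tbl].
#' @param refs Ordered character vector of reference detector ids.
#' @return Tibble with columns `sample`, `nf`.
#' @export
normalization_factor <- function(rq, refs) {
  if (length(refs) < 1) stop_input("`refs` must name at least one detector")
  m <- as_rq_matrix(rq)
  absent <- setdiff(refs, rownames(m))
  if (length(absent)) {
    stop_input(paste0("reference detector(s) not in matrix: ",
                      paste(absent, collapse = ", ")))
  }
  sub <- m[refs, , drop = FALSE]
  if (anyNA(sub)) {
    idx <- which(is.na(sub), arr.ind = TRUE)
    stop_data(sprintf("reference '%s' missing in sample '%s'",
                      rownames(sub)[idx[1, 1]], colnames(sub)[idx[1, 2]]))
  }
  tibble(sample = colnames(m), nf = unname(exp(colMeans(log(sub)))))
}

#' Global per-sample normalization factor
#'
#' The per-sample central tendency (arithmetic mean, geometric mean or
#' median) of all real expressed detectors, used when no explicit reference
#' set is chosen.
#'
#' @param rq A complete [rq_tbl].
#' @param method One of `"geometric"`, `"arithmetic"`, `"median"`.
#' @return Tibble with columns `sample`, `nf`.
#' @export
global_nf <- function(rq, method = c("geometric", "arithmetic", "median")) {
  method <- match.arg(method)
  m <- as_rq_matrix(rq)
  if (inherits(rq, "rq_tbl")) m <- m[!pseudo_flags(rq)[rownames(m)], , drop = FALSE]
  if (nrow(m) == 0) stop_input("no real detectors to build a global factor from")
  if (anyNA(m)) stop_input("matrix must be complete over real detectors; impute first")
  nf <- switch(method,
    arithmetic = colMeans(m),
    geometric = exp(colMeans(log(m))),
    median = apply(m, 2, stats::median)
  )
  tibble(sample = colnames(m), nf = unname(nf))
}

#' Normalize relative quantities by per-sample factors
#'
#' `NRQ_ij = RQ_ij / NF_j`. When the factors come from
#' [normalization_factor()], the per-sample geometric mean of the
#' references' NRQ equals 1 by construction.
#'
#' @param rq An [rq_tbl].
#' @param nf Per-sample factors: a tibble (`sample`, `nf`), a named vector,
#'   or an unnamed vector in sample order. All factors must be positive.
#' @param method Label recorded in the result (e.g. `"references"`,
#'   `"global_geometric"`).
#' @param reference_set Reference ids recorded in the result.
#' @return A `mirnorm_normalization` object with elements `nrq` (an
#'   `rq_tbl`), `nf` (tibble), `method`, `reference_set`.
#' @export
normalize_rq <- function(rq, nf, method = "custom", reference_set = character(0)) {
  m <- as_rq_matrix(rq)
  v <- nf_vector(nf, colnames(m))
  if (any(!is.finite(v) | v <= 0)) stop_input("normalization factors must be positive and finite")
  nrq_mat <- sweep(m, 2, v, `/`)
  nrq <- if (inherits(rq, "rq_tbl")) rebuild_rq(rq, nrq_mat) else rq_tbl(nrq_mat)
  structure(list(
    nrq = nrq,
    nf = tibble(sample = colnames(m), nf = unname(v)),
    method = method,
    reference_set = reference_set
  ), class = "mirnorm_normalization")
}

nf_vector <- function(nf, samples) {
  if (is.data.frame(nf)) {
    if (!all(c("sample", "nf") %in% names(nf))) {
      stop_input("`nf` tibble needs columns 'sample' and 'nf'")
    }
    idx <- match(samples, nf$sample)
    if (anyNA(idx)) stop_input("`nf` does not cover every sample")
    return(nf$nf[idx])
  }
  if (!is.null(names(nf))) {
    idx <- match(samples, names(nf))
    if (anyNA(idx)) stop_input("`nf` does not cover every sample")
    return(unname(nf[idx]))
  }
  if (length(nf) != length(samples)) stop_input("`nf` length must match the sample count")
  nf
}

#' Normalize by a selected reference set
#'
#' Convenience wrapper: computes the geometric-mean normalization factor of
#' `refs` and applies it.
#'
#' @inheritParams normalization_factor
#' @return A `mirnorm_normalization`.
#' @export
normalize_by_references <- function(rq, refs) {
  normalize_rq(rq, normalization_factor(rq, refs),
               method = "references", reference_set = refs)
}

#' Normalize by a global central tendency
#'
#' @inheritParams global_nf
#' @return A `mirnorm_normalization`.
#' @export
normalize_global <- function(rq, method = c("geometric", "arithmetic", "median")) {
  method <- match.arg(method)
  normalize_rq(rq, global_nf(rq, method), method = paste0("global_", method))
}

#' @export
print.mirnorm_normalization <- function(x, ...) {
  cat("Normalization result\n")
  cat("  method:", x$method, "\n")
  if (length(x$reference_set)) {
    cat("  references:", paste(x$reference_set, collapse = ", "), "\n")
  }
  cat(sprintf("  %d detectors x %d samples; NF range [%.4g, %.4g]\n",
              length(attr(x$nrq, "detectors")), nrow(x$nf),
              min(x$nf$nf), max(x$nf$nf)))
  invisible(x)
}

#' @describeIn normalize_rq Long tibble of normalized relative quantities.
#' @param x A `mirnorm_normalization`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mirnorm_normalization <- function(x, ...) {
  as_tibble(x$nrq)
}

#' @describeIn normalize_rq One-row summary of the normalization.
#' @exportS3Method generics::glance
glance.mirnorm_normalization <- function(x, ...) {
  tibble(
    method = x$method,
    n_references = length(x$reference_set),
    n_detectors = length(attr(x$nrq, "detectors")),
    n_samples = nrow(x$nf),
    nf_min = min(x$nf$nf),
    nf_max = max(x$nf$nf)
  )
}
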