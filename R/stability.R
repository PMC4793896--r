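#' Coefficient-of-variation stability score
#'
#' Each sample's column sum over the *real* detectors is a surrogate of its
#' total miRNA amount. The share matrix `X_ij = rq_ij / sum_i(real) rq_ij`
#' therefore removes differences in input amount, and
#' `CV_i = sd(X_i) / mean(X_i)` (sample SD, n-1) measures how constant a
#' detector's share of the total is across samples — the lower, the better
#' the candidate normalizer. Pseudo-detectors are scored against the
#' real-detector column sums but never contribute to them.
#'
#' @param rq An [rq_tbl] or positive complete matrix.
#' @return Tibble with columns `detector`, `cv`, `pseudo`.
#' @export
cv_score <- function(rq) {
  m <- as_rq_matrix(rq)
  if (anyNA(m)) stop_input("matrix must be complete; impute first")
  if (any(m <= 0)) stop_input("relative quantities must be strictly positive")
  pf <- if (inherits(rq, "rq_tbl")) pseudo_flags(rq)[rownames(m)] else
    stats::setNames(rep(FALSE, nrow(m)), rownames(m))
  tot <- colSums(m[!pf, , drop = FALSE])
  if (any(tot == 0)) stop_data("zero column sum over real detectors")
  X <- sweep(m, 2, tot, `/`)
  cv <- apply(X, 1, function(r) stats::sd(r) / mean(r))
  tibble(detector = rownames(m), cv = unname(cv), pseudo = unname(pf))
}

#' Combine the three stability scores into the summarized stability score
#'
#' The summarized stability score (SSS) of a detector is its Euclidean
#' distance from the origin in the space spanned by the three stability
#' scores: `sss = sqrt(M^2 + rho^2 + cv^2)`. Scores enter on their raw
#' scales by default; `rescale = TRUE` min-max rescales each score to
#' \[0, 1\] across detectors before combining, for users worried about scale
#' mismatch between methods. Detectors are ranked by ascending SSS (1 = most
#' stable), ties broken by detector id.
#'
#' @param genorm_scores Tibble with columns `detector`, `m` (e.g.
#'   `tidy(genorm(rq))`), or a named numeric vector.
#' @param normfinder_scores Tibble with `detector`, `rho`, or named vector.
#' @param cv_scores Tibble with `detector`, `cv` (and optionally `pseudo`),
#'   or named vector.
#' @param families Optional total family map (`detector`, `family`);
#'   defaults to singleton families.
#' @param rescale Min-max rescale each score to \[0, 1\] before combining
#'   (default `FALSE`).
#' @param platform Optional platform label stored in the table.
#' @return A `stability_tbl` tibble with columns `detector`, `genorm_m`,
#'   `normfinder_rho`, `cv_score`, `sss`, `rank`, `family`, `pseudo`,
#'   `platform`, ordered by rank.
#' @export
sss_combine <- function(genorm_scores, normfinder_scores, cv_scores,
                        families = NULL, rescale = FALSE,
                        platform = NA_character_) {
  gm <- score_vector(genorm_scores, "m")
  rho <- score_vector(normfinder_scores, "rho")
  cv <- score_vector(cv_scores, "cv")
  ids <- names(gm)
  if (!setequal(ids, names(rho)) || !setequal(ids, names(cv))) {
    stop_input("the three score sets must cover the same detectors")
  }
  ids <- sort(ids)
  s1 <- gm[ids]; s2 <- rho[ids]; s3 <- cv[ids]
  if (rescale) {
    s1 <- minmax01(s1); s2 <- minmax01(s2); s3 <- minmax01(s3)
  }
  pseudo <- rep(FALSE, length(ids))
  if (is.data.frame(cv_scores) && "pseudo" %in% names(cv_scores)) {
    pseudo <- as.logical(cv_scores$pseudo[match(ids, cv_scores$detector)])
  }
  fam <- complete_families(families, ids)
  out <- tibble(
    detector = ids,
    genorm_m = unname(s1),
    normfinder_rho = unname(s2),
    cv_score = unname(s3),
    sss = sqrt(unname(s1)^2 + unname(s2)^2 + unname(s3)^2),
    family = fam$family[match(ids, fam$detector)],
    pseudo = pseudo,
    platform = platform
  )
  out <- out[order(out$sss, out$detector), ]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("detector", "genorm_m", "normfinder_rho", "cv_score",
                 "sss", "rank", "family", "pseudo", "platform")]
  class(out) <- c("stability_tbl", class(out))
  out
}

score_vector <- function(x, col) {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  if (is.data.frame(x) && all(c("detector", col) %in% names(x))) {
    return(stats::setNames(x[[col]], x$detector))
  }
  stop_input(paste0("expected a named vector or a tibble with columns 'detector' and '",
                    col, "'"))
}

minmax01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(stats::setNames(rep(0, length(x)), names(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' One-call stability scoring of an RQ matrix
#'
#' Runs [genorm()], [normfinder()] and [cv_score()] on the same (filtered,
#' imputed, pseudo-augmented) matrix and combines them with [sss_combine()].
#'
#' @param rq A complete [rq_tbl].
#' @param ann Sample annotation (`sample_id`, `group`).
#' @param families Optional family map.
#' @param rescale Passed to [sss_combine()].
#' @param genorm_variant `"stepwise"` (M at elimination round, the default)
#'   or `"fullset"` (single-pass M on the full candidate set).
#' @return A `stability_tbl`.
#' @export
stability_scores <- function(rq, ann, families = NULL, rescale = FALSE,
                             genorm_variant = c("stepwise", "fullset")) {
  genorm_variant <- match.arg(genorm_variant)
  fit <- genorm(rq)
  gm <- if (genorm_variant == "stepwise") fit$stepwise_m else fit$fullset_m
  sss_combine(gm, normfinder(rq, ann), cv_score(rq),
              families = families, rescale = rescale,
              platform = attr(rq, "platform"))
}

#' Select references from a ranked stability table
#'
#' Walks the ranking from most to least stable, skipping pseudo-detectors
#' and any detector whose miRNA family is already represented (family
#' members share seed sequences and hence possibly overlapping regulation,
#' so only one per family is taken), until `k` references are collected.
#'
#' @param tab A `stability_tbl` from [sss_combine()] or
#'   [stability_scores()].
#' @param k Number of references to select.
#' @return Character vector of `k` detector ids, most stable first.
#' @export
select_references <- function(tab, k) {
  if (!is.numeric(k) || k < 1) stop_input("`k` must be >= 1")
  tab <- tab[order(tab$rank), ]
  chosen <- character(0)
  fams <- character(0)
  for (i in seq_len(nrow(tab))) {
    if (tab$pseudo[i]) next
    if (tab$family[i] %in% fams) next
    chosen <- c(chosen, tab$detector[i])
    fams <- c(fams, tab$family[i])
    if (length(chosen) == k) return(chosen)
  }
  mirnorm_abort(sprintf(
    "only %d admissible detector(s) available, %d requested",
    length(chosen), k), "mirnorm_selection_error")
}

#' Combine stability tables across profiling platforms
#'
#' Restricted to the real detectors present in every table (assayable and
#' detected with all platforms), each platform's SSS is min-max rescaled to
#' \[0, 1\] to make platforms commensurable, and the combined score is the
#' arithmetic mean of the rescaled scores, ranked ascending (ties broken by
#' detector id).
#'
#' @param tabs List of >= 2 `stability_tbl` objects; names (or the tables'
#'   platform labels) identify the platforms.
#' @return Tibble with one row per shared detector: per-platform `sss_*`
#'   and `scaled_*` columns, `combined_score` and `rank`.
#' @export
combine_platforms <- function(tabs) {
  if (!is.list(tabs) || length(tabs) < 2) stop_input("need at least 2 stability tables")
  labels <- names(tabs)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(seq_along(tabs), function(i) {
      p <- unique(tabs[[i]]$platform)
      if (length(p) == 1 && !is.na(p)) p else paste0("platform", i)
    }, character(1))
  }
  real <- lapply(tabs, function(t) t$detector[!t$pseudo])
  shared <- Reduce(intersect, real)
  if (length(shared) == 0) stop_data("no detector shared by all platforms")
  shared <- sort(shared)
  out <- tibble(detector = shared)
  scaled <- matrix(NA_real_, length(shared), length(tabs))
  for (i in seq_along(tabs)) {
    s <- tabs[[i]]$sss[match(shared, tabs[[i]]$detector)]
    out[[paste0("sss_", labels[i])]] <- s
    scaled[, i] <- minmax01(s)
    out[[paste0("scaled_", labels[i])]] <- scaled[, i]
  }
  out$combined_score <- rowMeans(scaled)
  out <- out[order(out$combined_score, out$detector), ]
  out$rank <- seq_len(nrow(out))
  out
}
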