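#' Censor Ct values above a detection threshold
#'
#' Observed wells with Ct strictly greater than `threshold` become missing
#' with reason `above_threshold`. Values exactly at the threshold are kept
#' (the rule is `Ct > threshold`, as conventional on 40-cycle platforms where
#' anything beyond ~35 cycles is unreliable).
#'
#' @param ct A [ct_tbl].
#' @param threshold Censoring threshold in cycles (default 35).
#' @return A `ct_tbl` with censored cells marked.
#' @export
censor_ct <- function(ct, threshold = 35) {
  if (!is.numeric(threshold) || threshold <= 0) stop_input("`threshold` must be > 0")
  ctm <- ct_wide(ct, "ct")
  stm <- ct_wide(ct, "status")
  hit <- stm == "observed" & !is.na(ctm) & ctm > threshold
  stm[hit] <- "above_threshold"
  rebuild_ct(ct, ctm, stm)
}

#' Flag implausibly low Ct values as amplification-artifact outliers
#'
#' Extreme low Ct values typically arise from non-exponential amplification
#' artefacts that cross the fluorescence threshold early without reflecting
#' real template abundance. Observed wells with Ct below `floor` are flagged
#' as `flagged_outlier`; the count of flagged wells is reported via a
#' message.
#'
#' @param ct A [ct_tbl].
#' @param floor Lower plausibility bound in cycles (default 10).
#' @return A `ct_tbl` with flagged cells marked.
#' @export
flag_low_ct_outliers <- function(ct, floor = 10) {
  if (!is.numeric(floor) || floor <= 0) stop_input("`floor` must be > 0")
  ctm <- ct_wide(ct, "ct")
  stm <- ct_wide(ct, "status")
  hit <- stm == "observed" & !is.na(ctm) & ctm < floor
  if (any(hit)) {
    rlang::inform(sprintf("flagged %d low-Ct outlier cell(s) below %g cycles",
                          sum(hit), floor))
  }
  stm[hit] <- "flagged_outlier"
  rebuild_ct(ct, ctm, stm)
}

#' Exclude specific wells by user decision
#'
#' Marks the listed detector/sample cells as `excluded_by_user` regardless of
#' their value — the programmatic stand-in for manual curation of
#' amplification curves.
#'
#' @param ct A [ct_tbl].
#' @param cells Data frame with columns `detector`, `sample`.
#' @return A `ct_tbl` with the cells excluded.
#' @export
exclude_cells <- function(ct, cells) {
  stm <- ct_wide(ct, "status")
  ctm <- ct_wide(ct, "ct")
  i <- match(as.character(cells$detector), rownames(stm))
  j <- match(as.character(cells$sample), colnames(stm))
  if (anyNA(i) || anyNA(j)) stop_input("exclusion mask names unknown detectors or samples")
  stm[cbind(i, j)] <- "excluded_by_user"
  rebuild_ct(ct, ctm, stm)
}

#' Relative quantities against a spike-in reference
#'
#' Computes `RQ = 2^-(Ct_miRNA - Ct_spike)` per well, referencing each
#' sample's wells to its exogenous spike-in Ct. If several spike wells are
#' given their Ct values are averaged on the Ct scale first. The spike
#' row(s) are removed from the candidate set. Missing Ct propagates to
#' missing RQ.
#'
#' @param ct A [ct_tbl].
#' @param spike_id Detector id(s) of the spike-in assay.
#' @return An [rq_tbl] with `reference_mode = "spike"`.
#' @export
compute_rq_spike <- function(ct, spike_id) {
  det <- attr(ct, "detectors")
  if (length(spike_id) < 1) stop_config("`spike_id` must name at least one detector")
  absent <- setdiff(spike_id, det)
  if (length(absent)) {
    stop_config(paste0("spike detector(s) not in table: ", paste(absent, collapse = ", ")))
  }
  ctm <- ct_wide(ct, "ct")
  spike <- ctm[spike_id, , drop = FALSE]
  if (anyNA(spike)) {
    bad <- colnames(spike)[colSums(is.na(spike)) > 0]
    stop_data(paste0("spike-in not observed in sample(s): ", paste(bad, collapse = ", ")))
  }
  spike_ct <- colMeans(spike)
  keep <- setdiff(det, spike_id)
  rqm <- 2^(-sweep(ctm[keep, , drop = FALSE], 2, spike_ct, `-`))
  rq_tbl(rqm, reference_mode = "spike", reference_id = spike_id,
         platform = attr(ct, "platform"))
}

#' Relative quantities against the highest-expressed detector
#'
#' For panels without a shared spike-in (e.g. cross-platform comparisons),
#' RQs are referenced to the most abundant detector: the one with the lowest
#' arithmetic-mean Ct among detectors observed in every sample (ties broken
#' toward the lexicographically smaller id). The reference row is retained
#' with RQ = 1 in all samples.
#'
#' @param ct A [ct_tbl].
#' @return An [rq_tbl] with `reference_mode = "min_ct"`.
#' @export
compute_rq_min_ct <- function(ct) {
  ctm <- ct_wide(ct, "ct")
  full <- rownames(ctm)[rowSums(is.na(ctm)) == 0]
  if (length(full) == 0) stop_data("no detector observed in all samples")
  means <- rowMeans(ctm[full, , drop = FALSE])
  ref <- sort(full[means == min(means)])[1]
  rqm <- 2^(-sweep(ctm, 2, ctm[ref, ], `-`))
  rq_tbl(rqm, reference_mode = "min_ct", reference_id = ref,
         platform = attr(ct, "platform"))
}

#' Per-group detection filter
#'
#' A detector is retained only if it is detected (present RQ) in at least
#' `fraction` of the samples of *every* biological group: a candidate
#' normalizer must be stably detectable across all groups, not just overall.
#' The count threshold is `ceiling(fraction * n_g)` ("at least" a fraction).
#'
#' @param rq An [rq_tbl].
#' @param ann Sample annotation (tibble with `sample_id`, `group`).
#' @param fraction Required detected fraction per group, in (0, 1]
#'   (default 2/3).
#' @return A filtered `rq_tbl`; removed detectors are reported via a message.
#' @export
filter_detection <- function(rq, ann, fraction = 2 / 3) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop_input("`fraction` must be in (0, 1]")
  }
  m <- rq_wide(rq)
  smp <- colnames(m)
  miss_ann <- setdiff(smp, ann$sample_id)
  if (length(miss_ann)) {
    stop_consistency(paste0("sample(s) absent from annotation: ",
                            paste(miss_ann, collapse = ", ")))
  }
  grp <- ann$group[match(smp, ann$sample_id)]
  keep <- rep(TRUE, nrow(m))
  for (g in levels(factor(grp))) {
    cols <- which(grp == g)
    need <- ceiling(fraction * length(cols))
    keep <- keep & rowSums(!is.na(m[, cols, drop = FALSE])) >= need
  }
  pf <- pseudo_flags(rq)
  removed <- rownames(m)[!keep]
  if (!any(keep & !pf[rownames(m)])) {
    stop_data("no real detector passes the detection filter")
  }
  if (length(removed)) {
    rlang::inform(sprintf("detection filter removed %d detector(s): %s",
                          length(removed), paste(removed, collapse = ", ")))
  }
  rebuild_rq(rq, m[keep, , drop = FALSE])
}

#' K-nearest-neighbour imputation of missing relative quantities
#'
#' Residual missing wells (after detection filtering) are imputed on the
#' log2 scale, where qPCR noise is approximately additive: for detector `i`
#' missing sample `j`, the `k` nearest detectors by Euclidean distance over
#' jointly observed samples that carry a value in `j` contribute a
#' 1/distance-weighted mean of their log2 values, which is back-transformed.
#' Zero-distance neighbours get equal weights among themselves. Observed
#' values are never changed.
#'
#' @param rq An [rq_tbl].
#' @param k Neighbour count (default 10, capped at #detectors - 1).
#' @return A complete `rq_tbl`.
#' @export
impute_knn <- function(rq, k = 10) {
  if (!is.numeric(k) || k < 1) stop_input("`k` must be >= 1")
  m <- rq_wide(rq)
  if (!anyNA(m)) return(rq)
  y <- log2(m)
  det <- rownames(y)
  k <- min(k, nrow(y) - 1)
  for (i in which(rowSums(is.na(y)) > 0)) {
    obs_i <- !is.na(y[i, ])
    d <- rep(NA_real_, nrow(y))
    for (o in seq_len(nrow(y))) {
      if (o == i) next
      joint <- obs_i & !is.na(y[o, ])
      if (!any(joint)) next
      d[o] <- sqrt(sum((y[i, joint] - y[o, joint])^2))
    }
    if (all(is.na(d))) {
      stop_data(paste0("detector '", det[i],
                       "' shares no observed samples with any other detector"))
    }
    for (j in which(is.na(y[i, ]))) {
      cand <- which(!is.na(d) & !is.na(y[, j]))
      if (length(cand) == 0) {
        stop_data(paste0("no neighbour with an observed value for detector '",
                         det[i], "', sample '", colnames(y)[j], "'"))
      }
      cand <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      dd <- d[cand]
      w <- if (any(dd == 0)) as.numeric(dd == 0) else 1 / dd
      y[i, j] <- sum(w * y[cand, j]) / sum(w)
    }
  }
  out <- 2^y
  out[!is.na(m)] <- m[!is.na(m)]  # observed cells bit-identical
  rebuild_rq(rq, out)
}

#' Append central-tendency pseudo-detectors
#'
#' Adds three synthetic candidate rows — the per-sample arithmetic mean,
#' geometric mean and median of the real detectors' RQs — that compete with
#' real miRNAs in the stability ranking. They are flagged `pseudo` and are
#' never selectable as references nor counted in column totals.
#'
#' @param rq A complete [rq_tbl] (impute first).
#' @return An `rq_tbl` with rows `pseudo_mean`, `pseudo_geomean`,
#'   `pseudo_median` appended.
#' @export
add_pseudo_detectors <- function(rq) {
  if (any(pseudo_flags(rq))) stop_input("pseudo-detectors already present")
  m <- rq_wide(rq)
  if (anyNA(m)) stop_input("matrix must be complete before adding pseudo-detectors; impute first")
  extra <- rbind(
    pseudo_mean = colMeans(m),
    pseudo_geomean = apply(m, 2, geomean),
    pseudo_median = apply(m, 2, stats::median)
  )
  rebuild_rq(rq, rbind(m, extra),
             pseudo = c(rep(FALSE, nrow(m)), rep(TRUE, 3)))
}
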