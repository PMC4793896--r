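#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

ct_reasons <- c(
  "observed", "undetermined", "above_threshold",
  "flagged_outlier", "excluded_by_user"
)

new_ct_tbl <- function(data, detectors, samples, platform = NA_character_) {
  out <- tibble::new_tibble(as.data.frame(data, stringsAsFactors = FALSE),
                            nrow = nrow(data), class = "ct_tbl")
  attr(out, "detectors") <- detectors
  attr(out, "samples") <- samples
  attr(out, "platform") <- platform
  out
}

validate_ct_tbl <- function(x) {
  det <- attr(x, "detectors")
  smp <- attr(x, "samples")
  if (anyDuplicated(det)) {
    stop_format(paste0("duplicate detector id(s): ",
                       paste(unique(det[duplicated(det)]), collapse = ", ")))
  }
  if (anyDuplicated(smp)) {
    stop_format(paste0("duplicate sample id(s): ",
                       paste(unique(smp[duplicated(smp)]), collapse = ", ")))
  }
  bad <- !x$status %in% ct_reasons
  if (any(bad)) stop_format(paste0("unknown missing-reason code: ",
                                   paste(unique(x$status[bad]), collapse = ", ")))
  obs <- x$status == "observed"
  if (any(obs & (!is.finite(x$ct) | x$ct <= 0))) {
    stop_format("observed Ct values must be finite and positive")
  }
  if (any(!obs & !is.na(x$ct))) {
    stop_format("non-observed cells must not carry a Ct value")
  }
  x
}

#' Build a Ct table from a detectors-by-samples matrix
#'
#' Constructs the long-format threshold-cycle container used throughout the
#' package. Each row is one well: a detector/sample pair with either an
#' observed Ct value or a missing-reason code (`undetermined`,
#' `above_threshold`, `flagged_outlier`, `excluded_by_user`).
#'
#' @param ct Numeric matrix, detectors as rows and samples as columns, with
#'   row and column names. `NA` cells are recorded as `undetermined` unless a
#'   `status` matrix says otherwise.
#' @param status Optional character matrix of the same shape with
#'   missing-reason codes.
#' @param platform Free-text platform label.
#' @return A tibble of class `ct_tbl` with columns `detector`, `sample`,
#'   `ct`, `status`, carrying detector/sample order and the platform label as
#'   attributes.
#' @export
ct_tbl <- function(ct, status = NULL, platform = NA_character_) {
  if (!is.matrix(ct) || is.null(rownames(ct)) || is.null(colnames(ct))) {
    stop_input("`ct` must be a matrix with detector rownames and sample colnames")
  }
  detectors <- rownames(ct)
  samples <- colnames(ct)
  if (is.null(status)) {
    status <- matrix("observed", nrow(ct), ncol(ct))
    status[is.na(ct)] <- "undetermined"
  }
  vals <- as.vector(t(ct))
  stat <- as.vector(t(status))
  vals[stat != "observed"] <- NA_real_
  out <- new_ct_tbl(
    tibble(
      detector = rep(detectors, each = length(samples)),
      sample = rep(samples, times = length(detectors)),
      ct = vals,
      status = stat
    ),
    detectors, samples, platform
  )
  validate_ct_tbl(out)
}

#' Coerce a wide data frame of Ct values to a `ct_tbl`
#'
#' @param x Data frame whose first column holds detector ids and remaining
#'   columns one sample each (numeric; `NA` becomes `undetermined`).
#' @inheritParams ct_tbl
#' @return A `ct_tbl`.
#' @export
as_ct_tbl <- function(x, platform = NA_character_) {
  if (inherits(x, "ct_tbl")) return(x)
  x <- as.data.frame(x)
  det <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- det
  ct_tbl(m, platform = platform)
}

# Wide views -----------------------------------------------------------------

ct_wide <- function(x, what = c("ct", "status")) {
  what <- match.arg(what)
  det <- attr(x, "detectors")
  smp <- attr(x, "samples")
  fill <- if (what == "ct") NA_real_ else NA_character_
  m <- matrix(fill, length(det), length(smp), dimnames = list(det, smp))
  m[cbind(match(x$detector, det), match(x$sample, smp))] <- x[[what]]
  m
}

rebuild_ct <- function(template, ct_mat, status_mat) {
  validate_ct_tbl(new_ct_tbl(
    tibble(
      detector = rep(rownames(ct_mat), each = ncol(ct_mat)),
      sample = rep(colnames(ct_mat), times = nrow(ct_mat)),
      ct = {
        v <- as.vector(t(ct_mat))
        v[as.vector(t(status_mat)) != "observed"] <- NA_real_
        v
      },
      status = as.vector(t(status_mat))
    ),
    rownames(ct_mat), colnames(ct_mat), attr(template, "platform")
  ))
}

# Relative-quantity container -------------------------------------------------

new_rq_tbl <- function(data, detectors, samples, reference_mode, reference_id,
                       platform = NA_character_) {
  out <- tibble::new_tibble(as.data.frame(data, stringsAsFactors = FALSE),
                            nrow = nrow(data), class = "rq_tbl")
  attr(out, "detectors") <- detectors
  attr(out, "samples") <- samples
  attr(out, "reference_mode") <- reference_mode
  attr(out, "reference_id") <- reference_id
  attr(out, "platform") <- platform
  out
}

validate_rq_tbl <- function(x) {
  present <- !is.na(x$rq)
  if (any(present & (!is.finite(x$rq) | x$rq <= 0))) {
    stop_format("present relative quantities must be strictly positive and finite")
  }
  x
}

#' Build a relative-quantity table from a detectors-by-samples matrix
#'
#' Low-level constructor, mostly useful for simulations and tests; pipelines
#' normally obtain `rq_tbl` objects from [compute_rq_spike()] or
#' [compute_rq_min_ct()]. Values are linear-scale relative quantities
#' (strictly positive); `NA` marks a censored/undetected well.
#'
#' @param rq Numeric matrix with detector rownames and sample colnames.
#' @param reference_mode How the quantities were referenced:
#'   `"spike"`, `"min_ct"` or `"none"`.
#' @param reference_id Identifier of the reference detector(s), if any.
#' @param pseudo Logical vector (one per detector) flagging appended
#'   central-tendency pseudo-detectors; default all `FALSE`.
#' @param platform Free-text platform label.
#' @return A tibble of class `rq_tbl` with columns `detector`, `sample`,
#'   `rq`, `pseudo`.
#' @export
rq_tbl <- function(rq, reference_mode = "none", reference_id = NA_character_,
                   pseudo = NULL, platform = NA_character_) {
  if (!is.matrix(rq) || is.null(rownames(rq)) || is.null(colnames(rq))) {
    stop_input("`rq` must be a matrix with detector rownames and sample colnames")
  }
  detectors <- rownames(rq)
  samples <- colnames(rq)
  if (anyDuplicated(detectors)) stop_format("duplicate detector ids")
  if (anyDuplicated(samples)) stop_format("duplicate sample ids")
  pseudo <- pseudo %||% rep(FALSE, length(detectors))
  out <- new_rq_tbl(
    tibble(
      detector = rep(detectors, each = length(samples)),
      sample = rep(samples, times = length(detectors)),
      rq = as.vector(t(rq)),
      pseudo = rep(pseudo, each = length(samples))
    ),
    detectors, samples, reference_mode, reference_id, platform
  )
  validate_rq_tbl(out)
}

rq_wide <- function(x) {
  det <- attr(x, "detectors")
  smp <- attr(x, "samples")
  m <- matrix(NA_real_, length(det), length(smp), dimnames = list(det, smp))
  m[cbind(match(x$detector, det), match(x$sample, smp))] <- x$rq
  m
}

pseudo_flags <- function(x) {
  det <- attr(x, "detectors")
  p <- x$pseudo[match(det, x$detector)]
  names(p) <- det
  p
}

rebuild_rq <- function(template, rq_mat, pseudo = NULL) {
  if (is.null(pseudo)) {
    pseudo <- unname(pseudo_flags(template)[rownames(rq_mat)])
    pseudo[is.na(pseudo)] <- FALSE
  }
  validate_rq_tbl(new_rq_tbl(
    tibble(
      detector = rep(rownames(rq_mat), each = ncol(rq_mat)),
      sample = rep(colnames(rq_mat), times = nrow(rq_mat)),
      rq = as.vector(t(rq_mat)),
      pseudo = rep(pseudo, each = ncol(rq_mat))
    ),
    rownames(rq_mat), colnames(rq_mat),
    attr(template, "reference_mode"), attr(template, "reference_id"),
    attr(template, "platform")
  ))
}

# Accept an rq_tbl, ct-free wide matrix, or normalization result.
as_rq_matrix <- function(x) {
  if (inherits(x, "rq_tbl")) return(rq_wide(x))
  if (inherits(x, "mirnorm_normalization")) return(rq_wide(x$nrq))
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) return(rq_wide(rq_tbl_from_df(x)))
  stop_input("expected an rq_tbl, a normalization result, or a matrix")
}

rq_tbl_from_df <- function(x) {
  det <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- det
  # recognize the package-generated central-tendency rows after a TSV round trip
  rq_tbl(m, pseudo = det %in% c("pseudo_mean", "pseudo_geomean", "pseudo_median"))
}

#' @export
print.ct_tbl <- function(x, ...) {
  cat(sprintf("# Ct table: %d detectors x %d samples (platform: %s)\n",
              length(attr(x, "detectors")), length(attr(x, "samples")),
              attr(x, "platform")))
  tbl <- table(factor(x$status, levels = ct_reasons))
  cat("# cells: ", paste(sprintf("%s=%d", names(tbl), tbl), collapse = ", "), "\n")
  NextMethod()
}

#' @export
print.rq_tbl <- function(x, ...) {
  cat(sprintf(
    "# RQ table: %d detectors (%d pseudo) x %d samples [reference: %s %s]\n",
    length(attr(x, "detectors")), sum(pseudo_flags(x)),
    length(attr(x, "samples")), attr(x, "reference_mode"),
    paste(attr(x, "reference_id"), collapse = "+")))
  NextMethod()
}
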