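#' Read a wide-format Ct table
#'
#' Reads a CSV/TSV table with detector ids in the first column and one column
#' per sample. Cells must be numeric Ct values or a missing token. The wide
#' orientation (detectors as rows) is the canonical one and is never guessed:
#' a transposed file will simply fail downstream consistency checks against
#' the sample annotation rather than being silently flipped.
#'
#' Token matching is case-insensitive after trimming whitespace. Besides the
#' user-configurable `undetermined_tokens`, cells equal to one of the
#' missing-reason codes (`above_threshold`, `flagged_outlier`,
#' `excluded_by_user`) are read back as that reason, which makes
#' [write_ct_table()] / `read_ct_table()` a lossless round trip.
#'
#' @param path Path to a CSV or TSV file (delimiter sniffed from the
#'   extension, `,` for `.csv` and tab otherwise; override with `delim`).
#' @param undetermined_tokens Character vector of tokens read as
#'   `undetermined` (default `"Undetermined"`, `"NA"`, `""`).
#' @param delim Optional delimiter override.
#' @param platform Free-text platform label attached to the result.
#' @return A [ct_tbl] object.
#' @export
read_ct_table <- function(path,
                          undetermined_tokens = c("Undetermined", "NA", ""),
                          delim = NULL, platform = NA_character_) {
  raw <- read_delim_chr(path, delim)
  if (ncol(raw) < 2) stop_format("Ct table needs a detector column plus >=1 sample column")
  detectors <- trimws(raw[[1]])
  samples <- names(raw)[-1]
  if (anyDuplicated(detectors)) {
    stop_format(paste0("duplicate detector id(s): ",
                       paste(unique(detectors[duplicated(detectors)]), collapse = ", ")))
  }
  if (anyDuplicated(samples)) {
    stop_format(paste0("duplicate sample id(s): ",
                       paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  tok <- tolower(trimws(undetermined_tokens))
  reason_tok <- c("above_threshold", "flagged_outlier", "excluded_by_user")

  n <- length(samples)
  ctm <- matrix(NA_real_, length(detectors), n, dimnames = list(detectors, samples))
  stm <- matrix("observed", length(detectors), n, dimnames = list(detectors, samples))
  for (j in seq_len(n)) {
    cell <- trimws(raw[[j + 1]])
    cell[is.na(cell)] <- ""
    low <- tolower(cell)
    is_und <- low %in% tok
    is_reason <- low %in% reason_tok
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is_und & !is_reason & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1]
      stop_format(sprintf(
        "non-numeric cell '%s' at detector '%s', sample '%s'",
        cell[i], detectors[i], samples[j]))
    }
    stm[is_und, j] <- "undetermined"
    if (any(is_reason)) {
      stm[cbind(which(is_reason), rep(j, sum(is_reason)))] <- low[is_reason]
    }
    keep <- !is_und & !is_reason
    ctm[keep, j] <- num[keep]
  }
  ct_tbl(ctm, stm, platform = platform)
}

#' Write a Ct table in wide format
#'
#' Observed values are written with 17 significant digits so that re-reading
#' with [read_ct_table()] reproduces them bit-exactly; non-observed cells are
#' written as their reason token (`Undetermined` for `undetermined`).
#'
#' @param x A [ct_tbl].
#' @param path Output path; delimiter sniffed from the extension.
#' @param delim Optional delimiter override.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, delim = NULL) {
  ctm <- ct_wide(x, "ct")
  stm <- ct_wide(x, "status")
  cells <- matrix(sprintf("%.17g", ctm), nrow(ctm), ncol(ctm))
  cells[stm == "undetermined"] <- "Undetermined"
  other <- stm != "observed" & stm != "undetermined"
  cells[other] <- stm[other]
  df <- data.frame(detector = rownames(ctm), cells,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("detector", colnames(ctm))
  readr::write_delim(df, path, delim = sniff_delim(path, delim), progress = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Expects columns `sample_id` and `group`, optionally `batch` and
#' `platform`. Group levels are preserved in file order. Consistency with a
#' companion Ct table is checked at pairing time by the functions that take
#' both (e.g. [filter_detection()], [normfinder()]).
#'
#' @param path Path to CSV/TSV.
#' @param delim Optional delimiter override.
#' @return A tibble with `sample_id`, `group` (factor, levels in file
#'   order) and any optional columns present.
#' @export
read_sample_annotation <- function(path, delim = NULL) {
  raw <- read_delim_chr(path, delim)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop_format(paste0("annotation is missing column(s): ",
                                       paste(miss, collapse = ", ")))
  grp <- trimws(raw$group)
  if (any(is.na(raw$group)) || any(grp == "")) {
    bad <- trimws(raw$sample_id)[is.na(raw$group) | grp == ""]
    stop_format(paste0("missing group value for sample(s): ",
                       paste(bad, collapse = ", ")))
  }
  ann <- tibble(
    sample_id = trimws(raw$sample_id),
    group = factor(grp, levels = unique(grp))
  )
  if (anyDuplicated(ann$sample_id)) {
    stop_format("duplicate sample_id in annotation")
  }
  for (opt in c("batch", "platform")) {
    if (opt %in% names(raw)) ann[[opt]] <- trimws(raw[[opt]])
  }
  ann
}

#' Read a miRNA family annotation and complete it over a detector set
#'
#' The input file (two columns: detector id, family id) may cover only a
#' subset of detectors; uncovered detectors are assigned singleton families
#' named after themselves, so the returned map is total. Families feed the
#' one-per-family rule of [select_references()].
#'
#' @param path Path to CSV/TSV, or `NULL`/nonexistent-free empty mapping.
#' @param detectors Character vector of detector ids to complete over.
#' @param delim Optional delimiter override.
#' @return A tibble with columns `detector`, `family` covering every
#'   detector exactly once.
#' @export
read_family_annotation <- function(path, detectors, delim = NULL) {
  if (is.null(path) || !nzchar(path) || file.info(path)$size == 0 || is.na(file.info(path)$size)) {
    if (!is.null(path) && nzchar(path) && !file.exists(path)) {
      stop_input(paste0("file not found: ", path))
    }
    return(complete_families(NULL, detectors))
  }
  raw <- read_delim_chr(path, delim)
  if (nrow(raw) == 0) return(complete_families(NULL, detectors))
  if (ncol(raw) < 2) stop_format("family annotation needs two columns: detector id, family id")
  map <- tibble(detector = trimws(raw[[1]]), family = trimws(raw[[2]]))
  complete_families(map, detectors)
}

#' Complete a detector-to-family map over a detector set
#'
#' @param map Tibble/data frame with columns `detector`, `family`, or `NULL`.
#' @param detectors Detector ids the map must cover.
#' @return A total family map (tibble `detector`, `family`).
#' @export
complete_families <- function(map, detectors) {
  if (is.null(map) || nrow(map) == 0) {
    return(tibble(detector = detectors, family = detectors))
  }
  map <- tibble(detector = as.character(map$detector),
                family = as.character(map$family))
  map <- dplyr::distinct(map)
  dup <- map$detector[duplicated(map$detector)]
  if (length(dup)) {
    stop_format(paste0("detector(s) mapped to conflicting families: ",
                       paste(unique(dup), collapse = ", ")))
  }
  fam <- map$family[match(detectors, map$detector)]
  fam[is.na(fam)] <- detectors[is.na(fam)]
  tibble(detector = detectors, family = fam)
}
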