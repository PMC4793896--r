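#' Run the full reference-selection and normalization pipeline
#'
#' Executes the fixed stage order: quality control (low-Ct flagging,
#' censoring) -> relative quantification (spike or minimum-Ct reference) ->
#' per-group detection filter -> KNN imputation -> pseudo-detectors ->
#' stability scores and SSS ranking -> reference selection (one per family)
#' -> normalization (selected references plus the three global central
#' tendencies) -> evaluation (CV reduction, autoscaled PCA, cluster
#' separation). Inputs come either from files or from the built-in
#' simulator; all randomness flows from the single configured seed, so the
#' same config and seed reproduce byte-identical outputs.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Recognized blocks/keys: `simulation` (passed to [sim_config()])
#'   *or* `input` (`ct`, `annotation`, optional `families`, optional
#'   `undetermined_tokens`); `preprocess` (`ct_threshold`, `low_ct_floor`,
#'   `detection_fraction`, `knn_k`, `reference_mode` = `"spike"` or
#'   `"min_ct"`, `spike_id`); `stability` (`n_references`, `rescale`,
#'   `genorm_variant`); `seed`.
#' @param seed Optional seed overriding the config.
#' @param out_dir Optional output directory; when given, writes
#'   `stability.tsv`, `nrq.tsv`, `nf.tsv`, `evaluation.tsv`, `ecdf.tsv`,
#'   `pca_scores.tsv` and `report.json`.
#' @return A `mirnorm_run` list: the run report (config echo, seed, stage
#'   counts with removed detector ids, selected references, per-scheme
#'   median CVs, file inventory, warnings) plus the result objects
#'   (`stability`, `normalized`, `evaluation`, `pca`, `rq`).
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  pre <- cfg$preprocess %||% list()
  stab <- cfg$stability %||% list()
  seed <- seed %||% cfg$seed %||% cfg$simulation$seed %||% 1L

  reference_mode <- pre$reference_mode %||%
    (if (is.null(cfg$simulation) && is.null(pre$spike_id)) "min_ct" else "spike")
  if (reference_mode == "spike" && is.null(pre$spike_id) && is.null(cfg$simulation)) {
    stop_config("reference_mode 'spike' requires `preprocess$spike_id`")
  }
  if (!reference_mode %in% c("spike", "min_ct")) {
    stop_config("`reference_mode` must be 'spike' or 'min_ct'")
  }

  stages <- list()
  warn_log <- character(0)
  note <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }

  # --- inputs ---------------------------------------------------------------
  if (!is.null(cfg$simulation)) {
    note("simulate", sprintf("generating synthetic panel (seed %d)", seed))
    simargs <- cfg$simulation
    simargs$seed <- NULL
    sim <- simulate_ct(do.call(sim_config, simargs), seed = seed)
    ct <- sim$ct
    ann <- sim$annotation
    fam <- complete_families(NULL, attr(ct, "detectors"))
    truth <- sim$truth
    spike_id <- pre$spike_id %||% "spike_in"
  } else {
    inp <- cfg$input %||% stop_config("config needs a `simulation` or `input` block")
    note("read", inp$ct)
    ct <- read_ct_table(inp$ct,
                        undetermined_tokens = inp$undetermined_tokens %||%
                          c("Undetermined", "NA", ""))
    ann <- read_sample_annotation(inp$annotation)
    fam <- read_family_annotation(inp$families %||% NULL, attr(ct, "detectors"))
    truth <- NULL
    spike_id <- pre$spike_id
  }
  stages$input <- list(detectors = length(attr(ct, "detectors")),
                       samples = length(attr(ct, "samples")))

  # --- QC -------------------------------------------------------------------
  ct <- flag_low_ct_outliers(ct, floor = pre$low_ct_floor %||% 10)
  ct <- censor_ct(ct, threshold = pre$ct_threshold %||% 35)
  stm <- ct_wide(ct, "status")
  stages$qc <- list(
    flagged_low_ct = sum(stm == "flagged_outlier"),
    censored_above_threshold = sum(stm == "above_threshold")
  )
  note("qc", sprintf("%d low-Ct flagged, %d censored",
                     stages$qc$flagged_low_ct, stages$qc$censored_above_threshold))

  # --- relative quantities --------------------------------------------------
  rq <- if (reference_mode == "spike") {
    compute_rq_spike(ct, spike_id)
  } else {
    compute_rq_min_ct(ct)
  }
  note("rq", sprintf("reference mode %s (%s)", reference_mode,
                     paste(attr(rq, "reference_id"), collapse = "+")))

  # --- filter / impute / pseudo --------------------------------------------
  before <- attr(rq, "detectors")
  rq <- withCallingHandlers(
    filter_detection(rq, ann, fraction = pre$detection_fraction %||% 2 / 3),
    message = function(m) invokeRestart("muffleMessage"))
  removed <- setdiff(before, attr(rq, "detectors"))
  stages$detection_filter <- list(kept = length(attr(rq, "detectors")),
                                  removed = removed)
  note("filter", sprintf("%d detector(s) removed", length(removed)))

  n_missing <- sum(is.na(rq$rq))
  rq <- impute_knn(rq, k = pre$knn_k %||% 10)
  stages$imputation <- list(imputed_cells = n_missing)
  note("impute", sprintf("%d cell(s) imputed", n_missing))
  rq <- add_pseudo_detectors(rq)

  # --- stability ------------------------------------------------------------
  tab <- stability_scores(rq, ann, families = fam,
                          rescale = isTRUE(stab$rescale),
                          genorm_variant = stab$genorm_variant %||% "stepwise")
  k_ref <- stab$n_references %||% 3
  refs <- select_references(tab, k = k_ref)
  note("rank", sprintf("selected references: %s", paste(refs, collapse = ", ")))
  stages$selection <- list(n_references = k_ref, references = refs)

  # --- normalization --------------------------------------------------------
  norms <- list(
    references = normalize_by_references(rq, refs),
    global_arithmetic = normalize_global(rq, "arithmetic"),
    global_geometric = normalize_global(rq, "geometric"),
    global_median = normalize_global(rq, "median")
  )

  # --- evaluation (real detectors only) ------------------------------------
  real <- attr(rq, "detectors")[!pseudo_flags(rq)]
  raw_real <- rebuild_rq(rq, rq_wide(rq)[real, , drop = FALSE])
  norm_real <- lapply(norms, function(nr) rq_wide(nr$nrq)[real, , drop = FALSE])
  evaluation <- cv_reduction_summary(raw_real, norm_real)
  pca <- withCallingHandlers(
    pca_detectors(raw_real, scaled = TRUE),
    warning = function(w) {
      warn_log <<- c(warn_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  real_tab <- tab[!tab$pseudo & tab$detector %in% pca$scores$detector, ]
  real_tab <- real_tab[order(real_tab$rank), ]
  n_half <- min(10, floor(nrow(real_tab) / 2))
  separation <- if (n_half >= 1) {
    stability_separation(pca,
                         utils::head(real_tab$detector, n_half),
                         utils::tail(real_tab$detector, n_half))
  } else NA_real_
  note("evaluate", sprintf("median CV raw %.3f vs references %.3f; separation %.3f",
                           evaluation$summary$median_cv[evaluation$summary$scheme == "raw"],
                           evaluation$summary$median_cv[evaluation$summary$scheme == "references"],
                           separation))

  # --- outputs --------------------------------------------------------------
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) {
      p <- file.path(out_dir, name)
      readr::write_tsv(x, p, progress = FALSE)
      files <<- c(files, p)
    }
    wr(as_tibble(tab), "stability.tsv")
    wr(tidy(norms$references), "nrq.tsv")
    wr(dplyr::bind_rows(lapply(norms, function(n) n$nf), .id = "scheme"), "nf.tsv")
    wr(evaluation$cv, "evaluation.tsv")
    wr(evaluation$ecdf, "ecdf.tsv")
    wr(tidy(pca), "pca_scores.tsv")
  }

  report <- list(
    config = cfg,
    seed = seed,
    stages = stages,
    references = refs,
    median_cv = stats::setNames(as.list(evaluation$summary$median_cv),
                                evaluation$summary$scheme),
    separation_statistic = separation,
    files = files,
    warnings = warn_log,
    versions = list(mirnorm = as.character(utils::packageVersion("mirnorm")),
                    r = paste(R.version$major, R.version$minor, sep = "."))
  )
  if (!is.null(out_dir)) {
    p <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    report$files <- c(files, p)
  }

  structure(list(
    report = report, stability = tab, references = refs, rq = rq,
    normalized = norms, evaluation = evaluation, pca = pca,
    separation = separation, truth = truth
  ), class = "mirnorm_run")
}

#' @export
print.mirnorm_run <- function(x, ...) {
  cat("mirnorm pipeline run (seed", x$report$seed, ")\n")
  cat("  references:", paste(x$references, collapse = ", "), "\n")
  cat("  median CV:",
      paste(sprintf("%s %.3f", names(x$report$median_cv),
                    unlist(x$report$median_cv)), collapse = ", "), "\n")
  cat(sprintf("  separation statistic: %.3f\n", x$separation))
  invisible(x)
}
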