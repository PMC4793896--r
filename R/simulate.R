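#' Simulation configuration for synthetic serum-miRNA qPCR panels
#'
#' The generator emulates the main nonbiological variability sources of
#' circulating-miRNA qPCR experiments: per-miRNA baseline abundance,
#' per-sample multiplicative scaling (extraction yield / input amount),
#' group-specific differential expression, detection censoring above a Ct
#' threshold, and a fixed-concentration spike-in with small technical
#' noise. All noise is Normal on the log2/Ct scale, where multiplicative
#' biology is additive.
#'
#' @param m_stable,m_variable,m_de Detector counts in the stable, variable
#'   and differential classes (defaults 5, 15, 10).
#' @param n_per_group Samples per group (default 8).
#' @param groups Number of biological groups (default 2).
#' @param baseline_ct_range Range of per-detector baseline Ct in cycles
#'   (default 20-32).
#' @param stable_sd,variable_sd Log2-scale intragroup SDs of the stable and
#'   variable classes (defaults 0.05 and 0.5). Differential detectors use
#'   `variable_sd` plus the group shift.
#' @param de_effect Log2 fold-change applied to differential detectors in
#'   the last group (default 1.0).
#' @param sample_scaling_sd Log2 SD of the per-sample scaling factors
#'   (default 1.0).
#' @param spike_noise_sd Log2 SD of the spike-in technical noise (default
#'   0.05).
#' @param spike_baseline_ct Baseline Ct of the spike-in (default 22,
#'   an abundant fixed-concentration spike).
#' @param ct_threshold Censoring threshold in cycles (default 35).
#' @param seed Integer seed (default 1).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(m_stable = 5, m_variable = 15, m_de = 10,
                       n_per_group = 8, groups = 2,
                       baseline_ct_range = c(20, 32),
                       stable_sd = 0.05, variable_sd = 0.5,
                       de_effect = 1.0, sample_scaling_sd = 1.0,
                       spike_noise_sd = 0.05, spike_baseline_ct = 22,
                       ct_threshold = 35, seed = 1) {
  cfg <- list(
    m_stable = m_stable, m_variable = m_variable, m_de = m_de,
    n_per_group = n_per_group, groups = groups,
    baseline_ct_range = baseline_ct_range,
    stable_sd = stable_sd, variable_sd = variable_sd,
    de_effect = de_effect, sample_scaling_sd = sample_scaling_sd,
    spike_noise_sd = spike_noise_sd, spike_baseline_ct = spike_baseline_ct,
    ct_threshold = ct_threshold, seed = seed
  )
  sds <- c(stable_sd, variable_sd, sample_scaling_sd, spike_noise_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) stop_config("all SDs must be >= 0")
  if (any(c(m_stable, m_variable, m_de) < 0)) stop_config("class counts must be >= 0")
  if (m_stable + m_variable + m_de < 3) stop_config("need at least 3 detectors in total")
  if (n_per_group < 1 || groups < 1) stop_config("need at least 1 sample and 1 group")
  if (length(baseline_ct_range) != 2 || diff(baseline_ct_range) < 0) {
    stop_config("`baseline_ct_range` must be an increasing pair of cycles")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a circulating-miRNA qPCR experiment with known ground truth
#'
#' Generates `Ct_ij = baseline_i - a_ij - s_j` for endogenous detectors,
#' where `a_ij` is class-specific log2 abundance noise (plus the `de_effect`
#' shift in the last group for differential detectors) and
#' `s_j ~ N(0, sample_scaling_sd)` is the per-sample scaling factor shared
#' by all detectors of a sample. The spike-in is added to the lysis buffer
#' before extraction, so it is co-extracted and receives the same `s_j`,
#' plus its own small technical noise — spike-referenced RQs therefore
#' remove `s_j` by design. Wells with Ct above `ct_threshold` are censored
#' to `undetermined`. The draw is fully reproducible from `seed`.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed overriding `cfg$seed`.
#' @return List with elements `ct` (a [ct_tbl] including the `spike_in`
#'   row), `annotation` (sample/group tibble) and `truth` (a `sim_truth`
#'   list: `detectors` tibble with `detector`, `class`, `baseline_ct`;
#'   `samples` tibble with `sample_id`, `log2_scaling`; `seed`).
#' @export
simulate_ct <- function(cfg = sim_config(), seed = NULL) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  seed <- seed %||% cfg$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  classes <- rep(c("stable", "variable", "de"),
                 times = c(cfg$m_stable, cfg$m_variable, cfg$m_de))
  ids <- c(
    sprintf("mir-stable-%02d", seq_len(cfg$m_stable)),
    sprintf("mir-var-%02d", seq_len(cfg$m_variable)),
    sprintf("mir-de-%02d", seq_len(cfg$m_de))
  )
  m <- length(ids)
  n <- cfg$n_per_group * cfg$groups
  grp <- rep(paste0("group", seq_len(cfg$groups)), each = cfg$n_per_group)
  smp <- sprintf("g%d-s%02d", rep(seq_len(cfg$groups), each = cfg$n_per_group),
                 rep(seq_len(cfg$n_per_group), cfg$groups))

  baseline <- stats::runif(m, cfg$baseline_ct_range[1], cfg$baseline_ct_range[2])
  s_j <- stats::rnorm(n, 0, cfg$sample_scaling_sd)
  class_sd <- ifelse(classes == "stable", cfg$stable_sd, cfg$variable_sd)
  a <- matrix(stats::rnorm(m * n, 0, rep(class_sd, n)), m, n)
  de_rows <- classes == "de"
  last_group <- grp == paste0("group", cfg$groups)
  if (any(de_rows) && cfg$groups >= 2) {
    a[de_rows, last_group] <- a[de_rows, last_group] + cfg$de_effect
  }
  ctm <- sweep(sweep(-a, 1, baseline, `+`), 2, s_j, `-`)
  spike <- cfg$spike_baseline_ct - s_j + stats::rnorm(n, 0, cfg$spike_noise_sd)
  ctm <- rbind(ctm, spike)
  rownames(ctm) <- c(ids, "spike_in")
  colnames(ctm) <- smp

  status <- matrix("observed", nrow(ctm), ncol(ctm))
  status[ctm > cfg$ct_threshold] <- "undetermined"
  ct <- ct_tbl(ctm, status, platform = "simulated")

  list(
    ct = ct,
    annotation = tibble(sample_id = smp,
                        group = factor(grp, levels = unique(grp))),
    truth = structure(list(
      detectors = tibble(detector = ids, class = classes,
                         baseline_ct = baseline),
      samples = tibble(sample_id = smp, log2_scaling = s_j),
      seed = seed
    ), class = "sim_truth")
  )
}

#' Recovery of designed-stable detectors by a stability ranking
#'
#' @param tab A `stability_tbl`.
#' @param truth A `sim_truth` from [simulate_ct()].
#' @param top_k Size of the top list examined (default 10); ranks are
#'   recomputed over real (non-pseudo) detectors only.
#' @return One-row tibble: `top_k`, `n_stable`, `recovered` (designed
#'   stable detectors inside the top `top_k`) and `mean_stable_rank`.
#' @export
truth_recovery <- function(tab, truth, top_k = 10) {
  real <- tab[!tab$pseudo, ]
  unknown <- setdiff(real$detector, truth$detectors$detector)
  if (length(unknown)) {
    stop_input(paste0("detector(s) unknown to the simulation truth: ",
                      paste(unknown, collapse = ", ")))
  }
  if (top_k > nrow(real)) stop_input("`top_k` exceeds the number of real detectors")
  real <- real[order(real$rank), ]
  real$real_rank <- seq_len(nrow(real))
  stable_ids <- truth$detectors$detector[truth$detectors$class == "stable"]
  stable_ids <- intersect(stable_ids, real$detector)
  top <- real$detector[seq_len(top_k)]
  tibble(
    top_k = top_k,
    n_stable = length(stable_ids),
    recovered = length(intersect(stable_ids, top)),
    mean_stable_rank = mean(real$real_rank[real$detector %in% stable_ids])
  )
}
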