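#' Pipeline run configuration
#'
#' Exactly one of `simulation` (a [cohort_spec()]) or `manifest` (path to a
#' cohort manifest CSV with columns `observer_id`, `case_id`, `phase`,
#' `structure`, `mask_path`) must be given. With a manifest, `reference`
#' must name one reference NIfTI mask per structure (a named character
#' vector, or a single path when there is one structure).
#'
#' @param simulation Optional [cohort_spec()].
#' @param manifest Optional manifest CSV path.
#' @param reference Reference mask path(s) (manifest mode only).
#' @param likert Optional Likert CSV path (columns `observer_id`,
#'   `item_id`, `pre`, `post`) or a tibble.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed (mandatory in simulation mode).
#' @param alpha Normality-gate level for [paired_compare()].
#' @param hd_percentile Hausdorff percentile (default 95).
#' @param correlate Compute Likert-vs-metric correlation matrices?
#' @param mapping Optional item-to-structure mapping table.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = NULL, manifest = NULL, reference = NULL,
                       likert = NULL, out_dir, seed = NULL, alpha = 0.05,
                       hd_percentile = 95, correlate = TRUE, mapping = NULL) {
  if (is.null(simulation) == is.null(manifest))
    err_invalid_parameter("provide exactly one of simulation or manifest")
  if (!is.null(simulation) && is.null(seed))
    err_invalid_parameter("simulation mode requires a master seed")
  if (!is.null(manifest) && is.null(reference))
    err_invalid_parameter("manifest mode requires reference mask path(s)")
  structure(list(simulation = simulation, manifest = manifest,
                 reference = reference, likert = likert, out_dir = out_dir,
                 seed = seed, alpha = alpha, hd_percentile = hd_percentile,
                 correlate = correlate, mapping = mapping),
            class = "run_config")
}

load_manifest_cohort <- function(config) {
  man <- readr::read_csv(config$manifest, show_col_types = FALSE)
  needed <- c("observer_id", "case_id", "phase", "structure", "mask_path")
  if (!all(needed %in% names(man)))
    err_invalid_parameter(sprintf("manifest lacks columns: %s",
                                  paste(setdiff(needed, names(man)), collapse = ", ")))
  refs <- config$reference
  structures <- unique(man$structure)
  if (is.null(names(refs))) {
    if (length(refs) != 1 || length(structures) != 1)
      err_invalid_parameter("reference must be named per structure when several structures are present")
    names(refs) <- structures
  }
  references <- lapply(refs, read_mask)
  man$mask <- lapply(man$mask_path, function(p)
    tryCatch(read_mask(p), error = function(e) NULL)) # NULLs are QC'd out
  list(cohort = man[, c(needed[1:4], "mask")], references = references)
}

#' Per-record contour evaluation
#'
#' Scores every mask of a QC-retained cohort against the reference for its
#' structure, returning the tidy metric table that feeds the statistics
#' stage.
#'
#' @param cohort Cohort tibble (`observer_id`, `case_id`, `phase`,
#'   `structure`, `mask` list-column).
#' @param references Named list of reference [voxel_mask]s, one per
#'   structure (a bare `voxel_mask` is accepted for single-structure
#'   cohorts).
#' @param hd_percentile Hausdorff percentile.
#' @return Tibble with columns `observer_id`, `case_id`, `phase`,
#'   `structure`, `dsc`, `ci`, `inclusion`, `rvd`, `asd_mm`, `dc_mm`,
#'   `hd95_mm`, `volume_cm3`.
#' @export
evaluate_cohort <- function(cohort, references, hd_percentile = 95) {
  if (is_voxel_mask(references)) {
    references <- stats::setNames(list(references), unique(cohort$structure)[1])
  }
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    st <- cohort$structure[i]
    ref <- references[[st]]
    if (is.null(ref))
      err_invalid_parameter(sprintf("no reference mask for structure '%s'", st))
    ms <- metric_set(cohort$mask[[i]], ref, hd_p = hd_percentile)
    dplyr::bind_cols(
      tibble::tibble(observer_id = cohort$observer_id[i],
                     case_id = cohort$case_id[i], phase = cohort$phase[i],
                     structure = st),
      metric_row(ms))
  })
  dplyr::bind_rows(rows)
}

#' Paired pre/post comparison of every metric
#'
#' For each (case, structure, metric), pairs the retained observers' pre and
#' post values and runs the distribution-gated comparison, alongside the
#' descriptive summaries reports are built from.
#'
#' @param metrics Tidy metric table from [evaluate_cohort()].
#' @param alpha Normality-gate level.
#' @return Tibble with one row per (case, structure, metric): descriptives
#'   (mean/sd/min/max per phase), `n`, `test_used`, `statistic`, `z`,
#'   `p_value`, `effect_kind`, `effect_size`.
#' @export
compare_cohort <- function(metrics, alpha = 0.05) {
  metric_cols <- c("dsc", "ci", "inclusion", "rvd", "asd_mm", "dc_mm",
                   "hd95_mm", "volume_cm3")
  out <- list()
  for (cs in unique(metrics$case_id)) {
    for (st in unique(metrics$structure[metrics$case_id == cs])) {
      sub <- metrics[metrics$case_id == cs & metrics$structure == st, ]
      pre <- sub[sub$phase == "pre", ]
      post <- sub[sub$phase == "post", ]
      obs <- intersect(pre$observer_id, post$observer_id)
      if (length(obs) < 2) next
      pre <- pre[match(obs, pre$observer_id), ]
      post <- post[match(obs, post$observer_id), ]
      for (mc in metric_cols) {
        res <- paired_compare(pre[[mc]], post[[mc]], metric_name = mc,
                              alpha = alpha)
        out[[length(out) + 1L]] <- tibble::tibble(
          case_id = cs, structure = st, metric = mc, n = res$n,
          pre_mean = mean(pre[[mc]]), pre_sd = sd(pre[[mc]]),
          pre_min = min(pre[[mc]]), pre_max = max(pre[[mc]]),
          post_mean = mean(post[[mc]]), post_sd = sd(post[[mc]]),
          post_min = min(post[[mc]]), post_max = max(post[[mc]]),
          test_used = res$test_used, statistic = res$statistic, z = res$z,
          p_value = res$p_value, effect_kind = res$effect_kind,
          effect_size = res$effect_size)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Interobserver-variability tables per phase
#'
#' @param metrics Tidy metric table from [evaluate_cohort()].
#' @return Tibble with one row per (case, structure, phase) holding the
#'   [iov_summary()] fields of the observers' volumes.
#' @export
iov_table <- function(metrics) {
  out <- list()
  groups <- unique(metrics[, c("case_id", "structure", "phase")])
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    vols <- metrics$volume_cm3[metrics$case_id == g$case_id &
                                 metrics$structure == g$structure &
                                 metrics$phase == g$phase]
    s <- iov_summary(vols)
    out[[length(out) + 1L]] <- tibble::tibble(
      case_id = g$case_id, structure = g$structure, phase = g$phase,
      n = s$n, mean_volume = s$mean_volume, sd = s$sd, cv = s$cv,
      vmax = s$vmax, vmin = s$vmin, mvr = s$mvr)
  }
  dplyr::bind_rows(out)
}

#' Run the full evaluation pipeline
#'
#' Simulate (or load) the cohort, apply QC exclusions, score every contour,
#' run the paired statistics and IOV summaries, optionally compute the
#' Likert correlation matrices (pre, post and delta modes), and write all
#' tables plus a run manifest to `out_dir`: `metrics.csv`,
#' `comparisons.csv`, `iov.csv`, `correlations.csv`, `exclusions.csv`,
#' `run_manifest.json`. A second run with an identical configuration
#' reproduces every number exactly.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the tables (`metrics`, `comparisons`,
#'   `iov`, `correlations`, `exclusions`) and the retained cohort.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) err_invalid_parameter("config must be a run_config")
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)

  if (!is.null(config$simulation)) {
    message("simulating cohort (seed ", config$seed, ")")
    sim <- simulate_cohort(config$simulation, seed = config$seed)
    cohort <- sim$cohort
    references <- stats::setNames(list(sim$reference),
                                  unique(cohort$structure)[1])
    likert <- sim$likert
  } else {
    message("loading cohort manifest ", config$manifest)
    loaded <- load_manifest_cohort(config)
    cohort <- loaded$cohort
    references <- loaded$references
    likert <- NULL
  }
  if (!is.null(config$likert)) {
    likert <- if (is.character(config$likert))
      readr::read_csv(config$likert, show_col_types = FALSE)
    else config$likert
  }

  qc <- qc_filter(cohort, likert = likert, reference = references[[1]])
  message(nrow(qc$exclusions), " exclusion(s); ",
          length(unique(qc$cohort$observer_id)), " observer(s) retained")
  if (nrow(qc$cohort) == 0) ce_error("no observers survive QC", "ce_empty_cohort")

  metrics <- evaluate_cohort(qc$cohort, references,
                             hd_percentile = config$hd_percentile)
  comparisons <- compare_cohort(metrics, alpha = config$alpha)
  iov <- iov_table(metrics)

  correlations <- NULL
  if (isTRUE(config$correlate) && !is.null(qc$likert) && nrow(qc$likert) > 0) {
    correlations <- tryCatch({
      dplyr::bind_rows(lapply(c("pre", "post", "delta"), function(mode)
        dplyr::bind_cols(tibble::tibble(mode = mode),
                         correlation_matrix(qc$likert, metrics, mode = mode,
                                            mapping = config$mapping,
                                            on_constant = "na"))))
    }, error = function(e) {
      message("correlation stage skipped: ", conditionMessage(e))
      NULL
    })
  }

  readr::write_csv(metrics, file.path(config$out_dir, "metrics.csv"))
  readr::write_csv(comparisons, file.path(config$out_dir, "comparisons.csv"))
  readr::write_csv(iov, file.path(config$out_dir, "iov.csv"))
  readr::write_csv(qc$exclusions, file.path(config$out_dir, "exclusions.csv"))
  if (!is.null(correlations))
    readr::write_csv(correlations, file.path(config$out_dir, "correlations.csv"))

  manifest <- list(
    package_version = as.character(packageVersion("contoureval")),
    seed = config$seed, alpha = config$alpha,
    hd_percentile = config$hd_percentile,
    mode = if (is.null(config$simulation)) "manifest" else "simulation",
    n_observers_retained = length(unique(qc$cohort$observer_id)),
    n_exclusions = nrow(qc$exclusions))
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(metrics = metrics, comparisons = comparisons, iov = iov,
                 correlations = correlations, exclusions = qc$exclusions,
                 cohort = qc$cohort, likert = qc$likert))
}

#' Format a comparison table for reporting
#'
#' Renders each metric's row in the conventional journal layout:
#' `mean +/- SD (min-max)` per phase, the test statistic, the p-value with a
#' single-star significance marker at p < 0.05, and the effect size labelled
#' with its kind (`d` for paired t, `r` for Wilcoxon).
#'
#' @param comparisons Output of [compare_cohort()].
#' @param digits Decimal places for descriptives.
#' @return Tibble of formatted character columns.
#' @export
summarize_table <- function(comparisons, digits = 2) {
  if (nrow(comparisons) == 0) err_insufficient_data("no comparison results")
  fmt <- function(m, s, lo, hi)
    sprintf("%.*f ± %.*f (%.*f–%.*f)", digits, m, digits, s,
            digits, lo, digits, hi)
  stat <- ifelse(comparisons$test_used == "wilcoxon",
                 sprintf("Z = %.3f", comparisons$z),
                 sprintf("t = %.3f", comparisons$statistic))
  tibble::tibble(
    case_id = comparisons$case_id, structure = comparisons$structure,
    metric = comparisons$metric,
    pre = fmt(comparisons$pre_mean, comparisons$pre_sd, comparisons$pre_min,
              comparisons$pre_max),
    post = fmt(comparisons$post_mean, comparisons$post_sd,
               comparisons$post_min, comparisons$post_max),
    statistic = stat,
    p = paste0(sprintf("%.3f", comparisons$p_value),
               ifelse(comparisons$p_value < 0.05, "*", "")),
    effect = sprintf("%s = %.3f", comparisons$effect_kind,
                     comparisons$effect_size),
    test = comparisons$test_used)
}

#' Correlation heatmap
#'
#' Tile heatmap of directionally adjusted Spearman correlations (items on
#' the x axis, metrics on the y axis): red for positive (improvement aligns
#' with self-assessment), blue for negative, with significance stars
#' (* p <= 0.05, ** p <= 0.01).
#'
#' @param corr Output of [correlation_matrix()] (optionally with a `mode`
#'   column, which is faceted).
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(corr) {
  stars <- ifelse(corr$p_value <= 0.01, "**",
                  ifelse(corr$p_value <= 0.05, "*", ""))
  corr$label <- sprintf("%.2f%s", corr$rho_adjusted, stars)
  p <- ggplot2::ggplot(corr, ggplot2::aes(x = .data$item_id, y = .data$metric,
                                          fill = .data$rho_adjusted)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1),
                                  name = "adjusted rho") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if ("mode" %in% names(corr)) p <- p + ggplot2::facet_wrap(~mode)
  p
}
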