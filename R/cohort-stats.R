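#' Interobserver volume-variability summary
#'
#' Dispersion of one structure's volume across an observer cohort: sample
#' standard deviation (n - 1 denominator), coefficient of variation
#' (SD / mean) and the maximum-to-minimum volume ratio (MVR), together with
#' the extremes.
#'
#' @param volumes Numeric vector of structure volumes (cm^3), one per
#'   observer; at least two, all strictly positive.
#' @return An `iov_summary` object with fields `n`, `mean_volume`, `sd`,
#'   `cv`, `vmax`, `vmin`, `mvr`.
#' @examples
#' iov_summary(c(1, 2, 3)) # sd 1, cv 0.5, mvr 3
#' @export
iov_summary <- function(volumes) {
  volumes <- as.numeric(volumes)
  if (anyNA(volumes)) err_invalid_data("volumes contain missing values")
  if (length(volumes) < 2)
    err_insufficient_data("at least two observer volumes are required")
  if (any(volumes <= 0))
    err_invalid_data("volumes must be strictly positive")
  m <- mean(volumes)
  structure(list(
    n = length(volumes), mean_volume = m, sd = sd(volumes),
    cv = sd(volumes) / m, vmax = max(volumes), vmin = min(volumes),
    mvr = max(volumes) / min(volumes)
  ), class = "iov_summary")
}

#' @export
print.iov_summary <- function(x, ...) {
  cat(sprintf(
    "<iov_summary> n %d | mean %.2f | sd %.2f | cv %.3f | range %.2f-%.2f | mvr %.2f\n",
    x$n, x$mean_volume, x$sd, x$cv, x$vmin, x$vmax, x$mvr))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired pre/post values
#'
#' Two-sided test on the differences `pre - post`, using the tie-corrected
#' normal approximation without continuity correction; zero differences are
#' dropped before ranking. The reported `W` is the sum of ranks of positive
#' differences, and `z` carries the sign of the rank-sum difference, so an
#' improvement on an increasing metric (post > pre) yields a negative `z` —
#' the sign convention of mainstream statistics software. Swapping the
#' arguments negates `z` and leaves `p` unchanged.
#'
#' @param pre,post Paired numeric vectors of equal length; at least five
#'   non-zero differences must remain.
#' @return List with `W`, `z`, `p_value` and `n` (non-zero pairs used).
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  if (length(pre) != length(post))
    err_invalid_parameter("pre and post must have equal length")
  d <- as.numeric(pre) - as.numeric(post)
  if (anyNA(d)) err_invalid_data("paired values contain missing values")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) err_degenerate_data("all paired differences are zero")
  if (n < 5)
    err_insufficient_data("need at least 5 non-zero paired differences")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_counts <- as.numeric(table(r)) # group via ranks: exact float equality
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_counts^3 - tie_counts) / 48
  if (sigma2 <= 0) err_degenerate_data("zero variance in signed ranks")
  z <- (w_plus - mu) / sqrt(sigma2)
  list(W = w_plus, z = z, p_value = min(1, 2 * pnorm(-abs(z))), n = n)
}

#' Paired t-test for pre/post values
#'
#' Standard paired t statistic on differences `pre - post` (so that an
#' improvement on an increasing metric gives a negative `t`), two-sided p.
#'
#' @inheritParams wilcoxon_signed_rank
#' @return List with `t`, `p_value`, `df` and `n`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post))
    err_invalid_parameter("pre and post must have equal length")
  if (length(pre) < 2) err_insufficient_data("need at least 2 pairs")
  d <- as.numeric(pre) - as.numeric(post)
  if (anyNA(d)) err_invalid_data("paired values contain missing values")
  if (sd(d) == 0)
    err_degenerate_data("paired differences have zero variance")
  tt <- t.test(pre, post, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), n = length(pre))
}

#' Effect size r for a Wilcoxon signed-rank test
#'
#' \eqn{r = |Z| / \sqrt{n}}, where n is the number of paired participants.
#'
#' @param z Normal-approximation statistic of the test.
#' @param n Number of pairs (>= 1).
#' @return Non-negative unitless effect size.
#' @export
effect_size_r <- function(z, n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    err_invalid_parameter("n must be a count >= 1")
  abs(z) / sqrt(n)
}

#' Effect size d for a paired t-test
#'
#' `d = |t| / sqrt(n)`, where n is the number of paired participants.
#'
#' @param t t statistic of the paired test.
#' @inheritParams effect_size_r
#' @return Non-negative unitless effect size.
#' @export
effect_size_d <- function(t, n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    err_invalid_parameter("n must be a count >= 1")
  abs(t) / sqrt(n)
}

#' Distribution-gated paired comparison
#'
#' Chooses the paired test from the distribution of the paired differences:
#' a Shapiro-Wilk test at level `alpha` selects the paired t-test when
#' normality is not rejected and the Wilcoxon signed-rank test otherwise
#' (constant non-zero differences, on which Shapiro-Wilk is undefined, fall
#' back to Wilcoxon). The effect size uses the formula matching the selected
#' test: \eqn{d = |t|/\sqrt{n}} or \eqn{r = |Z|/\sqrt{n}}, with n the number of paired
#' observations entering the comparison.
#'
#' @inheritParams wilcoxon_signed_rank
#' @param metric_name Label carried into the result.
#' @param alpha Normality-gate level (default 0.05).
#' @return A `paired_test_result` object: `metric_name`, `n`, `test_used`
#'   (`"paired_t"` or `"wilcoxon"`), `statistic` (t or W), `z` (Wilcoxon
#'   only, else `NA`), `p_value`, `effect_size`, `effect_kind` (`"d"` or
#'   `"r"`).
#' @export
paired_compare <- function(pre, post, metric_name = "metric", alpha = 0.05) {
  if (length(pre) != length(post))
    err_invalid_parameter("pre and post must have equal length")
  n <- length(pre)
  d <- as.numeric(pre) - as.numeric(post)
  if (anyNA(d)) err_invalid_data("paired values contain missing values")
  if (all(d == 0)) err_degenerate_data("all paired differences are zero")
  sw_p <- tryCatch(shapiro.test(d)$p.value, error = function(e) 0)
  if (sw_p >= alpha) {
    res <- paired_t(pre, post)
    out <- list(metric_name = metric_name, n = n, test_used = "paired_t",
                statistic = res$t, z = NA_real_, p_value = res$p_value,
                effect_size = effect_size_d(res$t, n), effect_kind = "d")
  } else {
    res <- wilcoxon_signed_rank(pre, post)
    out <- list(metric_name = metric_name, n = n, test_used = "wilcoxon",
                statistic = res$W, z = res$z, p_value = res$p_value,
                effect_size = effect_size_r(res$z, n), effect_kind = "r")
  }
  structure(out, class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  stat <- if (x$test_used == "wilcoxon")
    sprintf("W = %.1f, Z = %.3f", x$statistic, x$z)
  else sprintf("t = %.3f", x$statistic)
  cat(sprintf("<paired_test_result> %s: %s (n = %d), p = %.4g, %s = %.3f\n",
              x$metric_name, stat, x$n, x$p_value, x$effect_kind,
              x$effect_size))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, with a two-sided p-value
#' from the asymptotic t approximation.
#'
#' @param x,y Numeric vectors of equal length (>= 3); neither may be
#'   constant.
#' @return List with `rho`, `p_value` and `n`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    err_invalid_parameter("x and y must have equal length")
  if (length(x) < 3) err_insufficient_data("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) err_invalid_data("inputs contain missing values")
  if (sd(x) == 0 || sd(y) == 0)
    err_undefined_cor("correlation is undefined for a constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

# metrics whose sign is flipped so that "better contour" is always positive
.negated_metrics <- c("hd95", "asd", "dc", "rvd")
.positive_metrics <- c("dsc", "ci", "inclusion")

#' Directional adjustment of a correlation coefficient
#'
#' Quality metrics disagree on direction: higher Dice/conformity/inclusion
#' is better, while lower Hausdorff/average-surface/centroid distance and
#' volume difference are better. To make correlation heatmaps readable, the
#' coefficients of the "lower is better" metrics (`hd95`, `asd`, `dc`,
#' `rvd`) are negated so that improvement always maps to positive values;
#' `dsc`, `ci` and `inclusion` pass through unchanged.
#'
#' @param metric_name One of `dsc`, `ci`, `inclusion`, `rvd`, `asd`, `dc`,
#'   `hd95` (unit suffixes such as `asd_mm` are accepted).
#' @param rho Correlation coefficient.
#' @return The adjusted coefficient.
#' @export
directional_adjust <- function(metric_name, rho) {
  key <- sub("_(mm|cm3)$", "", tolower(metric_name))
  if (key %in% .negated_metrics) return(-rho)
  if (key %in% .positive_metrics) return(rho)
  err_invalid_parameter(sprintf("unknown metric '%s'", metric_name))
}

#' Correlation matrix between Likert self-assessment and contour quality
#'
#' For every (questionnaire item, objective metric) pair, the Spearman
#' correlation across observers between the item's score and the metric's
#' value, on the selected phase (`"pre"`, `"post"`) or on per-observer
#' changes (`"delta"`, post minus pre for both sides), directionally
#' adjusted with [directional_adjust()]. When an observer has the metric on
#' several cases the values are averaged before correlating. Items are
#' joined to structures through `mapping`; by default an item whose id
#' matches a structure label is paired with that structure and every other
#' item with the whole-target structure (`"CTV"` if present, else the first
#' structure).
#'
#' @param likert Tibble with columns `observer_id`, `item_id`, `pre`,
#'   `post` (integer scores 1-5).
#' @param metrics Tidy cohort metric table: columns `observer_id`,
#'   `case_id`, `phase`, `structure` and the metric columns `dsc`, `ci`,
#'   `inclusion`, `rvd`, `asd_mm`, `dc_mm`, `hd95_mm`.
#' @param mode One of `"pre"`, `"post"`, `"delta"`.
#' @param mapping Optional tibble with columns `item_id`, `structure`.
#' @param on_constant `"error"` (default) raises an undefined-correlation
#'   error when either side of a cell is constant; `"na"` records `NA` for
#'   that cell instead (used by the reporting pipeline so one degenerate
#'   cell cannot void a whole matrix).
#' @return Tibble with columns `item_id`, `metric`, `n`, `rho`, `p_value`,
#'   `rho_adjusted`.
#' @export
correlation_matrix <- function(likert, metrics, mode = c("pre", "post", "delta"),
                               mapping = NULL, on_constant = c("error", "na")) {
  mode <- match.arg(mode)
  on_constant <- match.arg(on_constant)
  check_likert(likert)
  metric_cols <- c("dsc", "ci", "inclusion", "rvd", "asd_mm", "dc_mm", "hd95_mm")
  needed <- c("observer_id", "case_id", "phase", "structure", metric_cols)
  if (!all(needed %in% names(metrics)))
    err_invalid_parameter(sprintf(
      "metrics table lacks columns: %s",
      paste(setdiff(needed, names(metrics)), collapse = ", ")))
  structures <- unique(metrics$structure)
  items <- unique(likert$item_id)
  if (is.null(mapping)) {
    default_struct <- if ("CTV" %in% structures) "CTV" else structures[1]
    mapping <- tibble::tibble(
      item_id = items,
      structure = ifelse(items %in% structures, items, default_struct))
  }
  if (!all(c("item_id", "structure") %in% names(mapping)))
    err_invalid_parameter("mapping must have columns item_id and structure")

  # per-observer metric value in the requested mode, averaged over cases
  wide <- tidyr::pivot_longer(metrics, dplyr::all_of(metric_cols),
                              names_to = "metric", values_to = "value")
  wide <- dplyr::summarise(
    dplyr::group_by(wide, .data$observer_id, .data$structure, .data$metric,
                    .data$phase),
    value = mean(.data$value), .groups = "drop")
  wide <- tidyr::pivot_wider(wide, names_from = "phase", values_from = "value")
  if (!all(c("pre", "post") %in% names(wide)))
    err_insufficient_data("metrics table must contain both phases")
  wide$metric_value <- switch(mode,
    pre = wide$pre, post = wide$post, delta = wide$post - wide$pre)

  lik <- likert
  lik$likert_value <- switch(mode,
    pre = lik$pre, post = lik$post, delta = lik$post - lik$pre)

  out <- list()
  for (it in items) {
    structure_for_item <- mapping$structure[match(it, mapping$item_id)]
    lvals <- lik[lik$item_id == it, c("observer_id", "likert_value")]
    for (met in sub("_(mm|cm3)$", "", metric_cols)) {
      mvals <- wide[wide$structure == structure_for_item &
                      sub("_(mm|cm3)$", "", wide$metric) == met,
                    c("observer_id", "metric_value")]
      joined <- merge(lvals, mvals, by = "observer_id")
      if (nrow(joined) < 3)
        err_insufficient_data(sprintf(
          "fewer than 3 observers with both questionnaire and metric data for item '%s'", it))
      sp <- if (on_constant == "na")
        tryCatch(spearman_rho(joined$likert_value, joined$metric_value),
                 ce_undefined_correlation = function(e)
                   list(rho = NA_real_, p_value = NA_real_, n = nrow(joined)))
      else spearman_rho(joined$likert_value, joined$metric_value)
      out[[length(out) + 1L]] <- tibble::tibble(
        item_id = it, metric = met, n = sp$n, rho = sp$rho,
        p_value = sp$p_value,
        rho_adjusted = if (is.na(sp$rho)) NA_real_
                       else directional_adjust(met, sp$rho))
    }
  }
  dplyr::bind_rows(out)
}

check_likert <- function(likert) {
  if (!all(c("observer_id", "item_id", "pre", "post") %in% names(likert)))
    err_invalid_parameter(
      "likert table needs columns observer_id, item_id, pre, post")
  scores <- c(likert$pre, likert$post)
  if (anyNA(scores) || any(scores != round(scores)) ||
      any(scores < 1) || any(scores > 5))
    err_invalid_data("Likert scores must be integers in 1..5")
  invisible(likert)
}

#' Quality-control exclusion filter
#'
#' Applies the usual delineation-study inclusion rules to a mask cohort and a questionnaire
#' table, producing the retained records plus a machine-readable exclusion
#' log. An observer is removed from the delineation cohort when (checked in
#' this order, one log line per excluded observer):
#' \describe{
#'   \item{invalid_mask}{any mask is missing/unreadable (`NULL`), empty, or
#'     on a different grid than the reference;}
#'   \item{missing_phase}{any (case, structure) lacks the pre or the post
#'     contour;}
#'   \item{identical_submission}{the pre and post masks are voxel-for-voxel
#'     identical for every (case, structure).}
#' }
#' Independently, an observer whose pre-training scores are all at the scale
#' maximum is removed from the questionnaire table (`ceiling`: no measurable
#' improvement is possible). Filtering is total: problems never raise, they
#' land in the log.
#'
#' @param cohort Tibble with columns `observer_id`, `case_id`, `phase`
#'   (`"pre"`/`"post"`), `structure` and a `mask` list-column of
#'   [voxel_mask] objects (`NULL` marks an unreadable file).
#' @param likert Optional Likert table (see [correlation_matrix()]).
#' @param reference Optional [voxel_mask] used for the grid-compatibility
#'   check.
#' @return List with `cohort`, `likert` and `exclusions` (tibble with
#'   columns `observer_id`, `scope`, `reason`, `detail`).
#' @export
qc_filter <- function(cohort, likert = NULL, reference = NULL) {
  needed <- c("observer_id", "case_id", "phase", "structure", "mask")
  if (!all(needed %in% names(cohort)))
    err_invalid_parameter(sprintf(
      "cohort lacks columns: %s", paste(setdiff(needed, names(cohort)), collapse = ", ")))
  log <- list()
  drop <- character()

  for (obs in unique(cohort$observer_id)) {
    rows <- cohort[cohort$observer_id == obs, ]
    reason <- NULL; detail <- NULL

    bad <- vapply(seq_len(nrow(rows)), function(i) {
      m <- rows$mask[[i]]
      if (!is_voxel_mask(m)) return(TRUE)
      if (n_foreground(m) == 0) return(TRUE)
      if (!is.null(reference)) {
        ok <- tryCatch({ assert_same_grid(m, reference); TRUE },
                       error = function(e) FALSE)
        if (!ok) return(TRUE)
      }
      FALSE
    }, logical(1))
    if (any(bad)) {
      reason <- "invalid_mask"
      detail <- sprintf("%d unreadable/empty/grid-mismatched mask(s)", sum(bad))
    } else {
      groups <- split(rows, paste(rows$case_id, rows$structure, sep = "\r"))
      incomplete <- vapply(groups, function(g)
        !setequal(g$phase, c("pre", "post")), logical(1))
      if (any(incomplete)) {
        g1 <- groups[[which(incomplete)[1]]]
        missing <- setdiff(c("pre", "post"), g1$phase)
        reason <- "missing_phase"
        detail <- sprintf("missing %s contour for %s/%s",
                          paste(missing, collapse = "+"),
                          g1$case_id[1], g1$structure[1])
      } else {
        same <- vapply(groups, function(g) {
          identical(g$mask[[which(g$phase == "pre")]]$occupancy,
                    g$mask[[which(g$phase == "post")]]$occupancy)
        }, logical(1))
        if (all(same)) {
          reason <- "identical_submission"
          detail <- "pre and post masks voxelwise identical for all structures"
        }
      }
    }
    if (!is.null(reason)) {
      drop <- c(drop, obs)
      log[[length(log) + 1L]] <- tibble::tibble(
        observer_id = obs, scope = "delineation", reason = reason,
        detail = detail)
    }
  }
  retained <- cohort[!(cohort$observer_id %in% drop), ]

  likert_retained <- likert
  if (!is.null(likert)) {
    check_likert(likert)
    drop_l <- character()
    for (obs in unique(likert$observer_id)) {
      pre_scores <- likert$pre[likert$observer_id == obs]
      if (all(pre_scores == 5)) {
        drop_l <- c(drop_l, obs)
        log[[length(log) + 1L]] <- tibble::tibble(
          observer_id = obs, scope = "questionnaire", reason = "ceiling",
          detail = "all pre-training scores at scale maximum")
      }
    }
    likert_retained <- likert[!(likert$observer_id %in% drop_l), ]
  }

  exclusions <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(observer_id = character(), scope = character(),
                   reason = character(), detail = character())
  list(cohort = retained, likert = likert_retained, exclusions = exclusions)
}
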