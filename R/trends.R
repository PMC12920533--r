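# Longitudinal trend statistics: Theil-Sen slopes, residual-bootstrap
# confidence intervals, directional-trend classification, and
# cross-sectional correlations.

#' Theil-Sen slope and intercept
#'
#' The robust non-parametric trend estimate: the median of all pairwise
#' slopes `(y_j - y_i) / (t_j - t_i)` over pairs with distinct times (an
#' even count of pairs takes the mean of the two central order statistics),
#' with intercept `median(y - slope * t)`. Missing values are dropped
#' pairwise.
#'
#' @param times Numeric time points (weeks).
#' @param values Numeric measurements, `NA` allowed.
#' @return A list with `slope`, `intercept`, `n` (points used).
#' @export
theil_sen <- function(times, values) {
  ok <- !is.na(values) & !is.na(times)
  t <- as.numeric(times[ok]); y <- as.numeric(values[ok])
  n <- length(t)
  if (n < 3L) stop("Theil-Sen estimation needs at least 3 non-missing points")
  if (length(unique(t)) < 2L) stop("all time points are equal; slope undefined")
  dt <- outer(t, t, `-`)
  dy <- outer(y, y, `-`)
  use <- upper.tri(dt) & dt != 0
  slope <- median(dy[use] / dt[use])
  list(slope = slope, intercept = median(y - slope * t), n = n)
}

#' Residual-bootstrap confidence interval for the Theil-Sen slope
#'
#' Fits the Theil-Sen line, resamples the residuals with replacement, adds
#' them back to the fitted trajectory, and re-estimates the slope for each
#' bootstrap sample; the CI is the (alpha/2, 1-alpha/2) percentile pair of
#' the bootstrap slope distribution.
#'
#' @param times,values As in [theil_sen()].
#' @param n_boot Number of resamples (default 1000).
#' @param alpha Two-sided level (default 0.05 for a 95% CI).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @return A list of class `trend_estimate` with `slope`, `intercept`,
#'   `ci_low`, `ci_high`, `n`, `n_boot`, `alpha`, `seed`, `boot_slopes`,
#'   and `classification` (see [classify_trend()]).
#' @export
residual_bootstrap_ci <- function(times, values, n_boot = 1000L,
                                  alpha = 0.05, seed = 1L) {
  if (n_boot < 1L) stop("n_boot must be at least 1")
  ok <- !is.na(values) & !is.na(times)
  t <- as.numeric(times[ok]); y <- as.numeric(values[ok])
  fit <- theil_sen(t, y)
  fitted <- fit$intercept + fit$slope * t
  res <- y - fitted
  n <- length(t)
  dt <- outer(t, t, `-`)
  use <- upper.tri(dt) & dt != 0
  dtu <- dt[use]
  boot_slopes <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ystar <- fitted + sample(res, n, replace = TRUE)
      median(outer(ystar, ystar, `-`)[use] / dtu)
    }, numeric(1))
  })
  ci <- unname(quantile(boot_slopes, c(alpha / 2, 1 - alpha / 2)))
  est <- structure(list(
    slope = fit$slope, intercept = fit$intercept,
    ci_low = ci[1], ci_high = ci[2], n = n,
    n_boot = as.integer(n_boot), alpha = alpha, seed = as.integer(seed),
    boot_slopes = boot_slopes, classification = NA_character_
  ), class = "trend_estimate")
  est$classification <- classify_trend(est)
  est
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf("<trend_estimate> slope %.3f /week (95%% CI %.3f to %.3f), n=%d, %s\n",
              x$slope, x$ci_low, x$ci_high, x$n, x$classification))
  invisible(x)
}

#' Directional-trend classification
#'
#' A trend is predominantly unidirectional when at least
#' `unidirectional_frac` of the bootstrap slopes share the sign of the
#' point estimate — the operational form of "the 95% CI lies predominantly
#' on one side of zero, possibly marginally crossing it". Otherwise no
#' clear direction is inferred.
#'
#' @param estimate A `trend_estimate` from [residual_bootstrap_ci()].
#' @param unidirectional_frac Same-sign bootstrap fraction threshold
#'   (default 0.90).
#' @return `"predominantly_unidirectional"` or `"no_clear_direction"`.
#' @export
classify_trend <- function(estimate, unidirectional_frac = 0.90) {
  s <- sign(estimate$slope)
  if (s == 0) return("no_clear_direction")
  frac <- mean(sign(estimate$boot_slopes) == s)
  if (frac >= unidirectional_frac) "predominantly_unidirectional"
  else "no_clear_direction"
}

#' Cross-sectional correlation between two longitudinal series
#'
#' Aligns the series on shared sessions (missing values dropped pairwise)
#' and correlates them. In `auto` mode a Shapiro-Wilk normality check at
#' alpha = 0.05 on both variables selects Pearson (both pass) or Spearman
#' (otherwise); Spearman uses average ranks for ties.
#'
#' @param x,y Numeric vectors aligned on the same sessions (`NA` allowed).
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return A list with `estimate`, `method` (method actually used), `n`.
#' @export
correlate_series <- function(x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need at least 3 shared non-missing points")
  xs <- x[ok]; ys <- y[ok]
  if (sd(xs) == 0 || sd(ys) == 0) {
    return(list(estimate = NA_real_, method = method, n = sum(ok),
                flag = "constant_series"))
  }
  if (method == "auto") {
    normal <- function(v) {
      if (length(unique(v)) < 3L) return(FALSE)
      shapiro.test(v)$p.value >= 0.05
    }
    method <- if (normal(xs) && normal(ys)) "pearson" else "spearman"
  }
  list(estimate = unname(cor(xs, ys, method = method)), method = method,
       n = sum(ok), flag = "ok")
}

#' Map study session labels to weeks post-infarction
#'
#' Sessions are named pre, post, 72hrs, 1W ... 11W. Post-MI sessions map to
#' weeks 0, 3/7, 1, 2, 3, 4, 5, 7, 11. The baseline (pre) session has no
#' defined week on this scale and maps to `NA` unless `pre_week` is given;
#' trend estimation excludes it by default.
#'
#' @param sessions Character vector of session labels.
#' @param pre_week Optional numeric week to assign to the pre session.
#' @return Numeric weeks (NA for pre unless `pre_week` is given).
#' @export
session_to_weeks <- function(sessions, pre_week = NA_real_) {
  map <- c(pre = pre_week, post = 0, `72hrs` = 3 / 7,
           `1W` = 1, `2W` = 2, `3W` = 3, `4W` = 4, `5W` = 5,
           `7W` = 7, `11W` = 11)
  unknown <- setdiff(unique(sessions), names(map))
  if (length(unknown)) {
    stop("unknown session labels: ", paste(unknown, collapse = ", "))
  }
  unname(map[sessions])
}

#' Trend estimates for every series of a long-format measurement table
#'
#' Takes a table with columns `pig`, `variable`, `region`, `session`,
#' `value` (the layout of the study's longitudinal tables), maps sessions
#' to weeks, and runs [residual_bootstrap_ci()] per (pig, variable, region)
#' series. Series with fewer than 3 usable points are skipped.
#'
#' @param data Long-format tibble/data.frame.
#' @param n_boot,alpha Bootstrap parameters.
#' @param seed Base seed; each series uses a distinct deterministic
#'   sub-seed.
#' @param include_pre If `TRUE`, the pre session is included at
#'   `pre_week`.
#' @param pre_week Week assigned to pre when included.
#' @return A tibble with one row per series: slope, CI, classification.
#' @export
fit_trend_table <- function(data, n_boot = 1000L, alpha = 0.05, seed = 1L,
                            include_pre = FALSE, pre_week = NA_real_) {
  stopifnot(all(c("pig", "variable", "region", "session", "value") %in%
                  names(data)))
  data$week <- session_to_weeks(data$session,
                                pre_week = if (include_pre) pre_week else NA_real_)
  keys <- unique(data[, c("pig", "variable", "region")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    rows <- data$pig == keys$pig[i] & data$variable == keys$variable[i] &
      (data$region == keys$region[i] |
         (is.na(data$region) & is.na(keys$region[i])))
    sub <- data[rows & !is.na(data$week) & !is.na(data$value), ]
    if (nrow(sub) < 3L) next
    est <- residual_bootstrap_ci(sub$week, sub$value, n_boot = n_boot,
                                 alpha = alpha, seed = seed + i)
    out[[i]] <- tibble::tibble(
      pig = keys$pig[i], variable = keys$variable[i],
      region = keys$region[i], n = est$n,
      slope = est$slope, ci_low = est$ci_low, ci_high = est$ci_high,
      classification = est$classification)
  }
  dplyr::bind_rows(out)
}

#' Load the packaged longitudinal measurement table
#'
#' Long-format table of the study's tabulated longitudinal variables (LGE
#' extent, native T1, ECV, T2, global function, strain, VVC angle, E/A
#' ratio and regional vorticity) for both animals across the ten MRI
#' sessions; `NA` marks sessions excluded for image quality.
#'
#' @return A tibble with columns `pig`, `variable`, `region`, `session`,
#'   `value`.
#' @export
load_study_measurements <- function() {
  path <- system.file("extdata", "longitudinal_measurements.csv",
                      package = "lvflow", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    pig = readr::col_character(),
                    variable = readr::col_character(),
                    region = readr::col_character(),
                    session = readr::col_character(),
                    value = readr::col_double()))
}
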