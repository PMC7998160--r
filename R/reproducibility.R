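#' Dice similarity coefficient of two masks
#'
#' DSC = 2|A n B| / (|A| + |B|): 1 for identical non-empty masks, 0 for
#' disjoint ones. Two empty masks have no defined overlap and return `NA`.
#'
#' @param a,b [mask3d()] objects on the same grid.
#' @return DSC in `[0, 1]`, or `NA_real_` when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "mask3d"), inherits(b, "mask3d"))
  if (!geom_equal(a$geometry, b$geometry)) {
    stop_geometry_conflict("masks")
  }
  na <- sum(a$voxels)
  nb <- sum(b$voxels)
  if (na + nb == 0) return(NA_real_)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Classify an agreement value on the standard qualitative scale
#'
#' Bands: poor (< 0.50), modest (0.50 to < 0.75), good (0.75 to < 0.90),
#' excellent (>= 0.90). Applies to both DSC and ICC values.
#'
#' @param value Numeric vector of agreement values in `[-1, 1]`.
#' @return Factor with levels poor < modest < good < excellent.
#' @examples
#' classify_agreement(c(0.40, 0.55, 0.78, 0.96))
#' @export
classify_agreement <- function(value) {
  if (any(!is.na(value) & (value < -1 | value > 1))) {
    stop("invalid agreement value: must lie in [-1, 1]", call. = FALSE)
  }
  cut(value, breaks = c(-Inf, 0.50, 0.75, 0.90, Inf),
      labels = c("poor", "modest", "good", "excellent"),
      right = FALSE, ordered_result = TRUE)
}

ba_tau <- function(abs_d, means) {
  if (length(abs_d) < 3 || stats::sd(abs_d) == 0 || stats::sd(means) == 0) {
    return(list(tau = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(abs_d, means, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p = ct$p.value)
}

new_ba_result <- function(d, means, mode) {
  bias <- mean(d)
  sdd <- stats::sd(d)
  tau <- ba_tau(abs(d), means)
  structure(
    list(bias = bias, sd_diff = sdd,
         loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
         n_pairs = length(d), tau_b = tau$tau, tau_p = tau$p, mode = mode,
         data = tibble::tibble(mean = means, diff = d)),
    class = "ba_result"
  )
}

#' Bland-Altman agreement of paired measurements
#'
#' In `percent` mode (the convention for Mean_ADC reproducibility) the
#' per-pair difference is d_i = 100 (x1_i - x2_i) / ((x1_i + x2_i) / 2);
#' in `absolute` mode d_i = x1_i - x2_i. Bias is the mean difference and the
#' 95% limits of agreement are bias +/- 1.96 sd(d) (sample sd). Dependence of
#' the absolute differences on the pair means (proportional bias) is
#' summarized by Kendall's tau-b with its two-sided p-value.
#'
#' @param x1,x2 Equal-length numeric vectors of paired measurements (>= 2
#'   pairs). Percent mode requires every pair mean to be positive.
#' @param mode `"percent"` (default) or `"absolute"`.
#' @return A `ba_result` with elements `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n_pairs`, `tau_b`, `tau_p`, `mode` and the per-pair `data`.
#' @export
bland_altman <- function(x1, x2, mode = c("percent", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(x1), is.numeric(x2))
  if (length(x1) != length(x2)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (length(x1) < 2) stop("insufficient pairs: need >= 2", call. = FALSE)
  means <- (x1 + x2) / 2
  if (mode == "percent") {
    if (any(means <= 0)) {
      stop("undefined percentage difference: non-positive pair mean",
           call. = FALSE)
    }
    d <- 100 * (x1 - x2) / means
  } else {
    d <- x1 - x2
  }
  new_ba_result(d, means, mode)
}

#' @export
print.ba_result <- function(x, ...) {
  unit <- if (x$mode == "percent") "%" else ""
  cat(sprintf(
    "<ba_result> bias %.3g%s, 95%% LoA (%.3g%s, %.3g%s), n = %d pairs; tau_b = %.3g (p = %.3g)\n",
    x$bias, unit, x$loa_low, unit, x$loa_high, unit, x$n_pairs,
    x$tau_b, x$tau_p))
  invisible(x)
}

#' @method tidy ba_result
#' @export
tidy.ba_result <- function(x, ...) x$data

#' @method glance ba_result
#' @export
glance.ba_result <- function(x, ...) {
  tibble::tibble(bias = x$bias, loa_low = x$loa_low, loa_high = x$loa_high,
                 sd_diff = x$sd_diff, n_pairs = x$n_pairs,
                 tau_b = x$tau_b, tau_p = x$tau_p, mode = x$mode)
}

#' Bland-Altman plot
#'
#' @param object A `ba_result`.
#' @param ... Unused.
#' @return A ggplot object: per-pair differences against pair means with the
#'   bias and 95% limits of agreement drawn.
#' @method autoplot ba_result
#' @export
autoplot.ba_result <- function(object, ...) {
  ylab <- if (object$mode == "percent") "difference (%)" else "difference"
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "red3") +
    ggplot2::labs(x = "pair mean", y = ylab) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

as_measurement_matrix <- function(table) {
  if (inherits(table, "data.frame")) {
    num <- vapply(table, is.numeric, logical(1))
    table <- as.matrix(table[, num, drop = FALSE])
  }
  if (!is.matrix(table) || !is.numeric(table)) {
    stop("measurement table must be a numeric matrix or data frame",
         call. = FALSE)
  }
  if (anyNA(table)) {
    stop("measurement table contains missing values", call. = FALSE)
  }
  table
}

#' Pooled pairwise inter-observer Bland-Altman
#'
#' For a subjects-by-observers table, computes differences for all C(k, 2)
#' observer pairs (sign convention: lower observer index minus higher),
#' pools them over subjects and pairs, and summarizes bias and limits of
#' agreement as in [bland_altman()]. With k = 2 this reduces exactly to
#' [bland_altman()] on the single pair.
#'
#' @param table Numeric matrix or data frame, rows = subjects, numeric
#'   columns = observers (k >= 2).
#' @param mode `"percent"` or `"absolute"`.
#' @return A `ba_result` pooled over all pairs.
#' @export
pooled_pairwise_ba <- function(table, mode = c("percent", "absolute")) {
  mode <- match.arg(mode)
  m <- as_measurement_matrix(table)
  k <- ncol(m)
  if (k < 2) stop("need >= 2 observers", call. = FALSE)
  pairs <- utils::combn(k, 2)
  x1 <- as.vector(m[, pairs[1, ]])
  x2 <- as.vector(m[, pairs[2, ]])
  if (length(x1) < 2) stop("insufficient pairs: need >= 2", call. = FALSE)
  means <- (x1 + x2) / 2
  if (mode == "percent") {
    if (any(means <= 0)) {
      stop("undefined percentage difference: non-positive pair mean",
           call. = FALSE)
    }
    d <- 100 * (x1 - x2) / means
  } else {
    d <- x1 - x2
  }
  new_ba_result(d, means, mode)
}

#' Two-way mixed-effects absolute-agreement single-measure ICC
#'
#' ICC(A,1) from the two-way ANOVA decomposition of an n-subjects by
#' k-raters table:
#'
#'   ICC = (MSR - MSE) / (MSR + (k - 1) MSE + (k / n)(MSC - MSE))
#'
#' where MSR, MSC, MSE are the mean squares for rows (subjects), columns
#' (raters) and residual error. The 95% confidence interval is the F-based
#' interval for single-rater absolute agreement (McGraw-Wong), using a
#' Satterthwaite-type degrees-of-freedom for the denominator. A table with
#' zero total variance is degenerate and returns an `NA`-flagged result.
#'
#' @param table Numeric matrix or data frame: rows = subjects (n >= 2),
#'   numeric columns = raters (k >= 2), complete (no missing values).
#' @param conf_level Confidence level for the interval, default 0.95.
#' @return An `icc_result`: `estimate`, `ci_low`, `ci_high`, mean squares
#'   `msr`, `msc`, `mse`, sizes `n`, `k`, and the qualitative `label` from
#'   [classify_agreement()].
#' @export
icc_a1 <- function(table, conf_level = 0.95) {
  m <- as_measurement_matrix(table)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop("need n >= 2 subjects and k >= 2 raters",
                           call. = FALSE)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  if (sst <= .Machine$double.eps * max(1, abs(grand))^2 * n * k) {
    res <- list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                msr = msr, msc = msc, mse = mse, n = n, k = k,
                conf_level = conf_level, label = NA)
    return(structure(res, class = "icc_result"))
  }

  est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  r <- est
  a <- (k * r) / (n * (1 - r))
  b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  # the F interval can leak outside [-1, 1] or cross the estimate at tiny n
  ci_low <- max(-1, min(ci_low, est))
  ci_high <- min(1, max(ci_high, est))

  structure(
    list(estimate = est, ci_low = ci_low, ci_high = ci_high,
         msr = msr, msc = msc, mse = mse, n = n, k = k,
         conf_level = conf_level,
         label = as.character(classify_agreement(max(-1, min(1, est))))),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "<icc_result> ICC(A,1) = %.3f, %g%% CI (%.3f, %.3f), n = %d, k = %d [%s]\n",
    x$estimate, 100 * x$conf_level, x$ci_low, x$ci_high, x$n, x$k,
    if (is.na(x$label)) "degenerate" else x$label))
  invisible(x)
}

#' @method tidy icc_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, ci_low = x$ci_low,
                 ci_high = x$ci_high, label = x$label)
}

#' @method glance icc_result
#' @export
glance.icc_result <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, ci_low = x$ci_low,
                 ci_high = x$ci_high, msr = x$msr, msc = x$msc, mse = x$mse,
                 n = x$n, k = x$k, conf_level = x$conf_level, label = x$label)
}

#' Rank correlations (Spearman and Kendall tau-b)
#'
#' Convenience wrapper returning Spearman's rho and Kendall's tau-b (tie
#' corrected) with two-sided p-values. Constant inputs are undefined and
#' return `NA`s.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return A one-row tibble: `spearman_rho`, `spearman_p`, `kendall_tau_b`,
#'   `kendall_p`.
#' @export
rank_correlations <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors with >= 3 observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(spearman_rho = NA_real_, spearman_p = NA_real_,
                          kendall_tau_b = NA_real_, kendall_p = NA_real_))
  }
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  kd <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall",
                    exact = length(x) < 10 && !anyDuplicated(c(x, y))))
  tibble::tibble(spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
                 kendall_tau_b = unname(kd$estimate), kendall_p = kd$p.value)
}

#' Reproducibility summary over a tidy measurement table
#'
#' Given long-format feature measurements (one row per subject, observer,
#' session and feature), computes for every feature and session the
#' inter-observer pooled Bland-Altman bias and limits of agreement and the
#' ICC(A,1) with 95% CI, plus the intra-observer Bland-Altman (session 1
#' versus session 2, pooled over observers) when both sessions are present.
#'
#' @param data Data frame with columns `subject`, `observer`, `session`,
#'   `feature`, `value`.
#' @param mode Bland-Altman mode passed through (`"percent"` default).
#' @return A tibble with one row per (feature, session/contrast) and columns
#'   `feature`, `analysis`, `session`, `bias`, `loa_low`, `loa_high`,
#'   `icc`, `icc_low`, `icc_high`, `icc_label`.
#' @export
repro_summary <- function(data, mode = c("percent", "absolute")) {
  mode <- match.arg(mode)
  need <- c("subject", "observer", "session", "feature", "value")
  if (!all(need %in% names(data))) {
    stop("data must have columns subject, observer, session, feature, value",
         call. = FALSE)
  }
  data <- dplyr::as_tibble(data)

  inter <- data |>
    dplyr::group_by(.data$feature, .data$session) |>
    dplyr::group_modify(function(df, key) {
      wide <- tidyr::pivot_wider(df, id_cols = "subject",
                                 names_from = "observer",
                                 values_from = "value")
      m <- as_measurement_matrix(wide[, -1, drop = FALSE])
      ba <- pooled_pairwise_ba(m, mode)
      ic <- icc_a1(m)
      tibble::tibble(analysis = "inter-observer",
                     bias = ba$bias, loa_low = ba$loa_low,
                     loa_high = ba$loa_high,
                     icc = ic$estimate, icc_low = ic$ci_low,
                     icc_high = ic$ci_high, icc_label = ic$label)
    }) |>
    dplyr::ungroup()

  sessions <- sort(unique(data$session))
  intra <- NULL
  if (length(sessions) == 2) {
    intra <- data |>
      dplyr::group_by(.data$feature) |>
      dplyr::group_modify(function(df, key) {
        wide <- tidyr::pivot_wider(df, id_cols = c("subject", "observer"),
                                   names_from = "session",
                                   values_from = "value")
        s1 <- wide[[as.character(sessions[1])]]
        s2 <- wide[[as.character(sessions[2])]]
        keep <- !is.na(s1) & !is.na(s2)
        ba <- bland_altman(s1[keep], s2[keep], mode)
        ic <- icc_a1(cbind(s1[keep], s2[keep]))
        tibble::tibble(analysis = "intra-observer", session = NA,
                       bias = ba$bias, loa_low = ba$loa_low,
                       loa_high = ba$loa_high,
                       icc = ic$estimate, icc_low = ic$ci_low,
                       icc_high = ic$ci_high, icc_label = ic$label)
      }) |>
      dplyr::ungroup()
  }
  dplyr::bind_rows(inter, intra) |>
    dplyr::relocate("feature", "analysis", "session")
}
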