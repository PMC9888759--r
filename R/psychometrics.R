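.reliability_result <- function(method, value, threshold, note = NULL) {
  out <- list(method = method, value = value, threshold_used = threshold,
              pass = is.finite(value) && value > threshold, note = note)
  class(out) <- "hdrps_reliability"
  out
}

#' @export
print.hdrps_reliability <- function(x, digits = 3, ...) {
  cat(sprintf("%s = %s (threshold %s): %s\n", x$method,
              format(round(x$value, digits)), format(x$threshold_used),
              if (x$pass) "PASS" else "fail"))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

.as_rating_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("rating matrix must be numeric", call. = FALSE)
  drop <- apply(x, 1L, anyNA)
  if (any(drop)) {
    message("dropping ", sum(drop), " row(s) with missing cells")
    x <- x[!drop, , drop = FALSE]
  }
  x
}

#' Cronbach's alpha of a rating panel
#'
#' Internal-consistency reliability
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#' For rating-panel consistency the *raters* play the role of the scale's
#' items (default, `items = "raters"` with raters in rows and rated pictures
#' in columns); set `items = "columns"` for the conventional orientation
#' (respondents in rows, scale items in columns).
#'
#' @param x Numeric matrix; with `items = "raters"`, raters x pictures.
#' @param items Whether rows (`"raters"`) or `"columns"` are the alpha items.
#' @param threshold Pass floor; default `0.5`, the minimum acceptable level.
#' @return An `hdrps_reliability` result; `value` is `NA` (with a note) when
#'   the total-score variance is zero.
#' @export
cronbach_alpha <- function(x, items = c("raters", "columns"), threshold = 0.5) {
  items <- match.arg(items)
  x <- .as_rating_matrix(x)
  if (items == "raters") x <- t(x)  # columns are now the alpha "items"
  k <- ncol(x)
  if (k < 2L || nrow(x) < 2L) {
    stop("need at least 2 items and 2 observations", call. = FALSE)
  }
  total_var <- stats::var(rowSums(x))
  if (total_var == 0) {
    return(.reliability_result("cronbach_alpha", NA_real_, threshold,
                               "total-score variance is zero; alpha undefined"))
  }
  item_var <- apply(x, 2L, stats::var)
  alpha <- k / (k - 1) * (1 - sum(item_var) / total_var)
  .reliability_result("cronbach_alpha", alpha, threshold)
}

#' Mean item-total reliability of a rating panel
#'
#' For each rater (row), the Pearson correlation between that rater's rating
#' vector and the across-rater mean vector; the reliability is the mean of
#' these correlations. Raters with constant rating vectors have undefined
#' correlations and are excluded with a warning. Used where Cronbach's alpha
#' is unavailable (e.g. a single-item dynamic scale whose five rounds play
#' the role of raters).
#'
#' @param x Numeric matrix, raters x items; needs >= 2 raters and >= 3 items.
#' @param threshold Pass floor; default `0.5`.
#' @return An `hdrps_reliability` result with per-rater correlations in
#'   `$per_rater`.
#' @export
mean_item_total_reliability <- function(x, threshold = 0.5) {
  x <- .as_rating_matrix(x)
  if (nrow(x) < 2L || ncol(x) < 3L) {
    stop("need at least 2 raters and 3 items", call. = FALSE)
  }
  overall <- colMeans(x)
  if (stats::sd(overall) == 0) {
    return(.reliability_result("mean_item_total_r", NA_real_, threshold,
                               "overall rating vector is constant"))
  }
  r <- apply(x, 1L, function(row) {
    if (stats::sd(row) == 0) NA_real_ else stats::cor(row, overall)
  })
  if (anyNA(r)) {
    warning(sum(is.na(r)), " rater(s) with constant ratings excluded from ",
            "the item-total reliability", call. = FALSE)
  }
  out <- .reliability_result("mean_item_total_r", mean(r, na.rm = TRUE), threshold)
  out$per_rater <- r
  out
}

#' Concurrent and discriminant validity by Pearson correlation
#'
#' Pearson correlation between the new scale's scores and a calibration
#' instrument. Concurrent validity (same construct) passes when `r > 0.45`;
#' discriminant validity (different construct) passes when `r < 0.45`. Both
#' inequalities are strict: `r = 0.45` exactly passes neither.
#'
#' @param x,y Equal-length paired numeric series, `n >= 3`.
#' @param kind `"concurrent"` or `"discriminant"`.
#' @param cutoff Validity cutoff; default `0.45`.
#' @return An `hdrps_validity` result: `kind`, `pearson_r`, `n`, `pass`.
#' @export
pearson_validity <- function(x, y, kind = c("concurrent", "discriminant"),
                             cutoff = 0.45) {
  kind <- match.arg(kind)
  if (length(x) != length(y)) stop("series must be paired", call. = FALSE)
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- list(kind = kind, pearson_r = NA_real_, n = length(x),
                cutoff = cutoff, pass = FALSE,
                note = "zero variance in a series; r undefined")
    class(out) <- "hdrps_validity"
    return(out)
  }
  r <- stats::cor(x, y)
  pass <- if (kind == "concurrent") r > cutoff else r < cutoff
  out <- list(kind = kind, pearson_r = r, n = length(x), cutoff = cutoff,
              pass = pass, note = NULL)
  class(out) <- "hdrps_validity"
  out
}

#' @export
print.hdrps_validity <- function(x, digits = 3, ...) {
  cat(sprintf("%s validity: r = %s (n = %d, cutoff %s): %s\n", x$kind,
              format(round(x$pearson_r, digits)), x$n, format(x$cutoff),
              if (x$pass) "PASS" else "fail"))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Paired pre/post comparison
#'
#' Standard paired t-test on `post - pre`, reporting the mean difference, its
#' SD, standard error, 95% confidence interval and two-tailed p value. With
#' `p > 0.05` the pre and post series are judged not significantly different.
#' Zero-variance differences are degenerate: the test statistic is undefined
#' unless the mean difference is also zero, and the result is flagged rather
#' than computed.
#'
#' @param pre,post Equal-length paired numeric series, `n >= 2`.
#' @param conf_level Confidence level, default `0.95`.
#' @return An `hdrps_paired_test` list: `mean_diff`, `sd_diff`, `sem`,
#'   `conf_int`, `t`, `df`, `p_value`, `n`, `degenerate`.
#' @export
paired_pre_post_test <- function(pre, post, conf_level = 0.95) {
  if (length(pre) != length(post)) stop("series must be paired", call. = FALSE)
  ok <- !(is.na(pre) | is.na(post))
  pre <- pre[ok]; post <- post[ok]
  n <- length(pre)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  d <- post - pre
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    out <- list(mean_diff = m, sd_diff = 0, sem = 0,
                conf_int = c(m, m), t = if (m == 0) 0 else NA_real_,
                df = n - 1L, p_value = if (m == 0) 1 else NA_real_,
                n = n, degenerate = m != 0, conf_level = conf_level)
  } else {
    tt <- stats::t.test(post, pre, paired = TRUE, conf.level = conf_level)
    out <- list(mean_diff = m, sd_diff = s, sem = s / sqrt(n),
                conf_int = as.numeric(tt$conf.int),
                t = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, n = n, degenerate = FALSE,
                conf_level = conf_level)
  }
  class(out) <- "hdrps_paired_test"
  out
}

#' @export
print.hdrps_paired_test <- function(x, digits = 3, ...) {
  cat("Paired pre/post test (post - pre), n =", x$n, "\n")
  if (x$degenerate) {
    cat("  degenerate: zero-variance differences with nonzero mean",
        format(round(x$mean_diff, digits)), "\n")
    return(invisible(x))
  }
  cat(sprintf("  mean diff %s, SD %s, SEM %s, %d%% CI [%s, %s]\n",
              format(round(x$mean_diff, digits)), format(round(x$sd_diff, digits)),
              format(round(x$sem, digits)), round(100 * x$conf_level),
              format(round(x$conf_int[1], digits)),
              format(round(x$conf_int[2], digits))))
  cat(sprintf("  t(%s) = %s, two-tailed p = %s -> %s\n", format(x$df),
              format(round(x$t, digits)), format(round(x$p_value, 4)),
              if (x$p_value > 0.05) "no significant pre/post difference"
              else "significant difference"))
  invisible(x)
}
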