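#' Picture-emotion reflection check
#'
#' Verifies that taking the picture scale reflects rather than induces
#' affect: (i) a paired pre/post test on the SAM valence ratings taken
#' immediately before and after the trial (no significant difference is
#' expected when the scale merely reflects affect), and (ii) the fraction of
#' administrations whose affect change stays below a percentage threshold.
#' The percent change of one administration is `|post - pre| / 8 * 100`, the
#' absolute change relative to the 9-point scale's span.
#'
#' @param sam_pre,sam_post Paired integer SAM valence ratings (1-9);
#'   incomplete pairs are dropped.
#' @param threshold Change threshold in percentage points (default 10): an
#'   administration counts as "changed" when its percent change is >= the
#'   threshold.
#' @return List of class `hdrps_reflection`: `paired` (an
#'   `hdrps_paired_test`), `pct_change` (per administration),
#'   `fraction_below` (fraction with change < threshold), `threshold`, `n`.
#' @export
reflection_check <- function(sam_pre, sam_post, threshold = 10) {
  ok <- !(is.na(sam_pre) | is.na(sam_post))
  pre <- sam_pre[ok]; post <- sam_post[ok]
  if (length(pre) == 0L) stop("no complete pre/post pairs", call. = FALSE)
  pct <- abs(post - pre) / 8 * 100
  out <- list(paired = paired_pre_post_test(pre, post),
              pct_change = pct,
              fraction_below = mean(pct < threshold),
              threshold = threshold, n = length(pre))
  class(out) <- "hdrps_reflection"
  out
}

#' @export
print.hdrps_reflection <- function(x, digits = 3, ...) {
  cat("Picture-emotion reflection check, n =", x$n, "\n")
  print(x$paired, digits = digits)
  cat(sprintf("  %.2f%% of administrations changed less than %s%% of the scale span\n",
              100 * x$fraction_below, format(x$threshold)))
  invisible(x)
}

#' Label consistency between SAM ratings and trial labels
#'
#' Converts each paired SAM valence rating to its affect label and returns
#' the fraction of trials whose picture-scale label matches it. Unpaired
#' trials (missing either side) are dropped with a warning.
#'
#' @param sam Integer SAM valence ratings (1-9), one per trial.
#' @param trial_labels Character trial labels (`negative`/`neutral`/
#'   `positive`), paired with `sam`.
#' @return Fraction in `[0, 1]`.
#' @export
consistency_accuracy <- function(sam, trial_labels) {
  if (length(sam) != length(trial_labels)) {
    stop("sam and trial_labels must be paired", call. = FALSE)
  }
  ok <- !(is.na(sam) | is.na(trial_labels))
  if (any(!ok)) warning(sum(!ok), " unpaired trial(s) dropped", call. = FALSE)
  sam <- sam[ok]; trial_labels <- trial_labels[ok]
  if (length(sam) == 0L) stop("no paired trials", call. = FALSE)
  mean(valence_rating_to_label(sam) == trial_labels)
}

#' Root mean successive squared difference
#'
#' `rmssd(x) = sqrt(mean((x[t+1] - x[t])^2))`, the standard affective
#' instability statistic of a repeated-measures score series: 0 for a
#' constant series, large when successive scores jump.
#'
#' @param x Numeric series ordered by measurement time, length >= 2.
#' @return Non-negative numeric.
#' @examples
#' rmssd(c(1, 2, 1, 2))  # 1
#' @export
rmssd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) {
    stop("rmssd needs a series of length >= 2", call. = FALSE)
  }
  sqrt(mean(diff(x)^2))
}

#' Per-participant rMSSD of a long-format score series
#'
#' @param data Data frame with a participant id column, a time-order column
#'   and a score column.
#' @param value Name of the score column.
#' @param id Name of the participant id column (default `participant_id`).
#' @param order Name of the time-order column (default `trial`).
#' @return Data frame (`participant_id`, `rmssd`, `n_obs`); participants with
#'   fewer than 2 observations get `NA`.
#' @export
rmssd_by_participant <- function(data, value, id = "participant_id",
                                 order = "trial") {
  pieces <- split(data, data[[id]])
  rows <- lapply(pieces, function(p) {
    p <- p[base::order(p[[order]]), , drop = FALSE]
    x <- p[[value]][!is.na(p[[value]])]
    data.frame(participant_id = p[[id]][1L],
               rmssd = if (length(x) >= 2L) rmssd(x) else NA_real_,
               n_obs = length(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlates of affective instability
#'
#' Pearson-correlates each instrument's per-participant rMSSD with each
#' covariate (ordinal covariates integer-coded), starring coefficients at the
#' two-tailed 0.05 (`*`) and 0.01 (`**`) levels. Covariates with zero
#' variance get `NA` with a note.
#'
#' @param instability Data frame: one row per participant, one numeric column
#'   per instrument's rMSSD (plus an optional `participant_id` column, which
#'   is ignored).
#' @param covariates Data frame of numeric/integer-coded covariates, rows
#'   aligned with `instability`.
#' @return Object of class `hdrps_instability`: list with matrices `r`
#'   (correlations, covariates x instruments), `p` (two-tailed p values) and
#'   `stars`.
#' @export
instability_correlates <- function(instability, covariates) {
  inst <- instability[, setdiff(names(instability), "participant_id"),
                      drop = FALSE]
  if (nrow(inst) != nrow(covariates)) {
    stop("instability and covariates must have aligned rows", call. = FALSE)
  }
  if (sum(stats::complete.cases(inst)) < 3L) {
    stop("need >= 3 participants with valid rMSSD", call. = FALSE)
  }
  r <- p <- matrix(NA_real_, nrow = ncol(covariates), ncol = ncol(inst),
                   dimnames = list(names(covariates), names(inst)))
  for (i in seq_len(ncol(covariates))) {
    cv <- as.numeric(covariates[[i]])
    for (j in seq_len(ncol(inst))) {
      y <- inst[[j]]
      ok <- !(is.na(cv) | is.na(y))
      if (sum(ok) < 3L || stats::sd(cv[ok]) == 0 || stats::sd(y[ok]) == 0) next
      ct <- stats::cor.test(cv[ok], y[ok])
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  stars <- ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  out <- list(r = r, p = p, stars = stars)
  class(out) <- "hdrps_instability"
  out
}

#' @export
print.hdrps_instability <- function(x, digits = 3, ...) {
  cat("Affective-instability correlates (Pearson r, * p<0.05, ** p<0.01)\n")
  disp <- matrix(paste0(format(round(x$r, digits)), x$stars),
                 nrow = nrow(x$r), dimnames = dimnames(x$r))
  disp[is.na(x$r)] <- "NA (constant)"
  print(disp, quote = FALSE)
  invisible(x)
}
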