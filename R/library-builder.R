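#' Modal affect label and identity ratio of a rating set
#'
#' The identity ratio of a picture is the fraction of raters whose individual
#' rating bins to the picture's modal affect label. When two labels tie at the
#' maximal frequency there is no dominant label: the modal label is `NA` and
#' the picture cannot pass screening.
#'
#' @param scores Integer vector of 9-point ratings for one picture on one
#'   dimension.
#' @param dimension `"valence"` or `"arousal"`.
#' @return A list with `label` (modal label, `NA` on a tie), `ratio`
#'   (modal count / number of raters), `n` and the full label `counts`.
#' @examples
#' identity_ratio(c(2, 2, 3, 8, 5, 5, 2), "valence")  # negative, 4/7
#' @export
identity_ratio <- function(scores, dimension = c("valence", "arousal")) {
  dimension <- match.arg(dimension)
  if (length(scores) == 0L) stop("scores must be non-empty", call. = FALSE)
  labels <- .rating_to_label(scores, dimension)
  levels <- if (dimension == "valence") .valence_levels else .arousal_levels
  counts <- table(factor(labels, levels = levels))
  top <- max(counts)
  modal <- names(counts)[counts == top]
  list(label = if (length(modal) == 1L) modal else NA_character_,
       ratio = as.numeric(top) / length(scores),
       n = length(scores),
       counts = counts)
}

.check_ratings <- function(ratings) {
  needed <- c("rater_id", "image_id", "dimension", "score")
  missing <- setdiff(needed, names(ratings))
  if (length(missing)) {
    stop("ratings table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(ratings$dimension %in% c("valence", "arousal"))) {
    stop("dimension must be 'valence' or 'arousal'", call. = FALSE)
  }
  invisible(.check_scores(ratings$score, "rating score"))
  ratings
}

#' Screen rated pictures by identity ratio
#'
#' Applies the modal-label identity-ratio screen to a round of ratings: a
#' picture is retained iff on *both* dimensions a unique modal label reaches
#' the identity-ratio threshold (default 60%). Rating rows from sessions in
#' which the rater's own affect was abnormal (`rater_affect_valid = FALSE`)
#' are excluded first; pictures missing either dimension are reported and
#' excluded.
#'
#' @param ratings Data frame with columns `rater_id`, `image_id`, `dimension`
#'   (`valence`/`arousal`), `score` (integer 1-9) and optionally `session_id`
#'   and `rater_affect_valid`.
#' @param threshold Identity-ratio screening threshold in `[0, 1]`;
#'   default `0.6`.
#' @param round_id Optional label for the rating round (e.g. `"expert"`).
#' @return A data.frame of class `hdrps_screening`, one row per picture, with
#'   modal labels, identity ratios, mean ratings, rater counts and a
#'   `retained` flag. Attribute `"dropped_incomplete"` lists pictures missing
#'   a dimension.
#' @seealso [identity_ratio()], [merge_rounds()]
#' @export
screen_images <- function(ratings, threshold = 0.6, round_id = NULL) {
  .check_ratings(ratings)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  if (!is.null(ratings$rater_affect_valid)) {
    bad <- !ratings$rater_affect_valid
    if (any(bad)) {
      message("excluding ", sum(bad),
              " rating(s) from sessions with abnormal rater affect")
      ratings <- ratings[!bad, , drop = FALSE]
    }
  }
  ids <- unique(ratings$image_id)
  has_val <- ids %in% ratings$image_id[ratings$dimension == "valence"]
  has_aro <- ids %in% ratings$image_id[ratings$dimension == "arousal"]
  incomplete <- ids[!(has_val & has_aro)]
  if (length(incomplete)) {
    warning(length(incomplete), " picture(s) missing a dimension were ",
            "excluded: ", paste(utils::head(incomplete, 5), collapse = ", "),
            if (length(incomplete) > 5) ", ..." else "", call. = FALSE)
  }
  ids <- setdiff(ids, incomplete)

  one_dim <- function(id, dim) {
    s <- ratings$score[ratings$image_id == id & ratings$dimension == dim]
    c(identity_ratio(s, dim)[c("label", "ratio")], mean = mean(s), n = length(s))
  }
  rows <- lapply(ids, function(id) {
    v <- one_dim(id, "valence")
    a <- one_dim(id, "arousal")
    data.frame(image_id = id,
               valence_label = v$label, valence_ratio = v$ratio,
               arousal_label = a$label, arousal_ratio = a$ratio,
               mean_valence = v$mean, mean_arousal = a$mean,
               n_raters = as.integer(max(v$n, a$n)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(image_id = character(), valence_label = character(),
                      valence_ratio = numeric(), arousal_label = character(),
                      arousal_ratio = numeric(), mean_valence = numeric(),
                      mean_arousal = numeric(), n_raters = integer(),
                      stringsAsFactors = FALSE)
  }
  out$retained <- !is.na(out$valence_label) & !is.na(out$arousal_label) &
    out$valence_ratio >= threshold & out$arousal_ratio >= threshold
  attr(out, "threshold") <- threshold
  attr(out, "round_id") <- round_id
  attr(out, "dropped_incomplete") <- incomplete
  class(out) <- c("hdrps_screening", class(out))
  out
}

#' Merge two screening rounds into the final picture library
#'
#' A picture enters the library iff it was retained in both rounds *and*
#' carries the same valence label and the same arousal label in both
#' (label-consistency rule, e.g. positive-positive and low-low). Pictures
#' present in only one round count as not retained. Final mean valence and
#' arousal default to the second (larger-panel) round's rating means; set
#' `means = "pooled"` for a rater-weighted pool of both rounds. Neutral
#' pictures are additionally split into low/high-neutral subtypes from the
#' final mean valence.
#'
#' @param round1,round2 `hdrps_screening` objects from [screen_images()],
#'   screened at the same threshold.
#' @param means `"round2"` (default) or `"pooled"`.
#' @param categories Optional data.frame (`image_id`, `category`) giving each
#'   picture's content category; by default the category is parsed from the
#'   image id prefix (`<category>-...`).
#' @return A data.frame of class `hdrps_library`: `image_id`, `category`,
#'   `mean_valence`, `mean_arousal`, `valence_label`, `arousal_label`,
#'   `neutral_subtype` (`NA` for non-neutral pictures), `subtype_flagged`,
#'   identity ratios and `n_raters` from round 2.
#' @export
merge_rounds <- function(round1, round2, means = c("round2", "pooled"),
                         categories = NULL) {
  means <- match.arg(means)
  if (!identical(attr(round1, "threshold"), attr(round2, "threshold"))) {
    stop("rounds were screened at different thresholds", call. = FALSE)
  }
  r1 <- round1[round1$retained, , drop = FALSE]
  r2 <- round2[round2$retained, , drop = FALSE]
  m <- merge(r1, r2, by = "image_id", suffixes = c(".1", ".2"))
  keep <- m$valence_label.1 == m$valence_label.2 &
    m$arousal_label.1 == m$arousal_label.2
  m <- m[keep, , drop = FALSE]

  if (means == "round2") {
    mv <- m$mean_valence.2
    ma <- m$mean_arousal.2
  } else {
    w1 <- m$n_raters.1
    w2 <- m$n_raters.2
    mv <- (m$mean_valence.1 * w1 + m$mean_valence.2 * w2) / (w1 + w2)
    ma <- (m$mean_arousal.1 * w1 + m$mean_arousal.2 * w2) / (w1 + w2)
  }

  if (is.null(categories)) {
    category <- parse_image_id(m$image_id)$category
  } else {
    category <- categories$category[match(m$image_id, categories$image_id)]
  }
  if (anyNA(category) && nrow(m) > 0L) {
    stop("could not determine the category of picture(s): ",
         paste(utils::head(m$image_id[is.na(category)], 5), collapse = ", "),
         call. = FALSE)
  }

  lib <- data.frame(image_id = m$image_id, category = category,
                    mean_valence = mv, mean_arousal = ma,
                    valence_label = m$valence_label.2,
                    arousal_label = m$arousal_label.2,
                    neutral_subtype = rep(NA_character_, nrow(m)),
                    subtype_flagged = rep(FALSE, nrow(m)),
                    valence_identity_ratio = m$valence_ratio.2,
                    arousal_identity_ratio = m$arousal_ratio.2,
                    n_raters = m$n_raters.2,
                    stringsAsFactors = FALSE)
  neu <- lib$valence_label == "neutral"
  if (any(neu)) {
    sub <- withCallingHandlers(neutral_subtype(lib$mean_valence[neu]),
                               warning = function(w) invokeRestart("muffleWarning"))
    lib$neutral_subtype[neu] <- sub
    lib$subtype_flagged[neu] <- attr(sub, "flagged")
  }
  rownames(lib) <- NULL
  attr(lib, "threshold") <- attr(round1, "threshold")
  attr(lib, "means") <- means
  class(lib) <- c("hdrps_library", class(lib))
  lib
}

#' @export
print.hdrps_library <- function(x, ...) {
  cat("Affect-labeled picture library:", nrow(x), "pictures\n")
  cat("  identity-ratio threshold:", attr(x, "threshold"),
      "| means from:", attr(x, "means"), "\n")
  tab <- table(factor(x$category, levels = .categories))
  cat("  per category:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Descriptive statistics of a picture library
#'
#' Per-category counts, min/max/mean of valence and arousal, plus the total
#' library size and each category's percentage share (rounded to 2 decimals).
#'
#' @param library An `hdrps_library` (or any data.frame with `category`,
#'   `mean_valence`, `mean_arousal`).
#' @return A data.frame of class `hdrps_library_stats`, one row per category,
#'   with attribute `"total"`.
#' @export
library_stats <- function(library) {
  stopifnot(nrow(library) > 0L)
  cats <- .categories
  rows <- lapply(cats, function(cc) {
    sub <- library[library$category == cc, , drop = FALSE]
    data.frame(category = cc, n = nrow(sub),
               valence_min = if (nrow(sub)) min(sub$mean_valence) else NA_real_,
               valence_max = if (nrow(sub)) max(sub$mean_valence) else NA_real_,
               valence_mean = if (nrow(sub)) mean(sub$mean_valence) else NA_real_,
               arousal_min = if (nrow(sub)) min(sub$mean_arousal) else NA_real_,
               arousal_max = if (nrow(sub)) max(sub$mean_arousal) else NA_real_,
               arousal_mean = if (nrow(sub)) mean(sub$mean_arousal) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- sum(out$n)
  out$share_pct <- round(out$n / total * 100, 2)
  attr(out, "total") <- total
  class(out) <- c("hdrps_library_stats", class(out))
  out
}

#' @export
print.hdrps_library_stats <- function(x, digits = 2, ...) {
  cat("Library descriptive statistics (total", attr(x, "total"), "pictures)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Category shares from per-category counts
#'
#' @param counts Named integer vector or data.frame (`category`, `n`).
#' @return Named numeric vector of percentage shares rounded to 2 decimals.
#' @export
category_shares <- function(counts) {
  if (is.data.frame(counts)) counts <- stats::setNames(counts$n, counts$category)
  round(counts / sum(counts) * 100, 2)
}

# --- manifest I/O ----------------------------------------------------------

#' Read and write library manifests
#'
#' The library manifest is a JSON array of records mirroring the library
#' columns (image id, category, means, labels, subtype, identity ratios,
#' rater counts).
#'
#' @param library An `hdrps_library`.
#' @param path File path.
#' @return `read_manifest()` returns an `hdrps_library`;
#'   `write_manifest()` returns `path` invisibly.
#' @export
write_manifest <- function(library, path) {
  meta <- list(threshold = attr(library, "threshold"),
               means = attr(library, "means"))
  payload <- list(meta = meta, images = as.data.frame(library))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lib <- payload$images
  if (is.null(lib$neutral_subtype)) lib$neutral_subtype <- NA_character_
  attr(lib, "threshold") <- payload$meta$threshold
  attr(lib, "means") <- payload$meta$means
  class(lib) <- c("hdrps_library", class(lib))
  lib
}

#' Read a rating-round CSV
#'
#' Expects a header `rater_id,image_id,dimension,score,session_id,
#' rater_affect_valid`.
#'
#' @param path CSV path.
#' @return Data frame of rating records.
#' @export
read_ratings <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(out$rater_affect_valid)) {
    out$rater_affect_valid <- as.logical(out$rater_affect_valid)
  }
  .check_ratings(out)
}
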