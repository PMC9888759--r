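#' @keywords internal
"_PACKAGE"

# Shared level sets. Valence/arousal labels are ordered from the low to the
# high end of their dimension; categories follow the library taxonomy.
.valence_levels <- c("negative", "neutral", "positive")
.arousal_levels <- c("low", "medium", "high")
.neutral_subtypes <- c("low_neutral", "high_neutral")
.categories <- c("people", "animals", "plants", "objects", "scenes")

#' Picture categories of the material library
#'
#' The five content categories used throughout the toolkit: people, animals,
#' plants, objects and scenes.
#'
#' @return Character vector of the five category names.
#' @export
affect_categories <- function() .categories

#' Affect label level sets
#'
#' @return Character vector of labels, ordered from the low to the high end of
#'   the dimension.
#' @export
valence_levels <- function() .valence_levels

#' @rdname valence_levels
#' @export
arousal_levels <- function() .arousal_levels

.check_scores <- function(score, what = "score") {
  if (length(score) == 0L) stop(what, " must be non-empty", call. = FALSE)
  if (!is.numeric(score) || anyNA(score)) {
    stop(what, " must be numeric with no missing values", call. = FALSE)
  }
  if (any(score != round(score))) {
    stop(what, " must be integer-valued on the 9-point scale (fractional ",
         "ratings are rejected, not rounded)", call. = FALSE)
  }
  if (any(score < 1 | score > 9)) {
    stop(what, " must lie in [1, 9]", call. = FALSE)
  }
  as.integer(score)
}

#' Convert a 9-point valence rating to its affect label
#'
#' Ratings 1-3 are labeled `negative`, 4-6 `neutral` and 7-9 `positive`.
#' The three label preimages partition the integers 1..9; fractional or
#' out-of-range ratings are rejected.
#'
#' @param score Integer vector of 9-point valence ratings.
#' @return Character vector of labels in `valence_levels()`.
#' @examples
#' valence_rating_to_label(c(3, 5, 9))
#' @export
valence_rating_to_label <- function(score) {
  score <- .check_scores(score, "valence rating")
  .valence_levels[(score - 1L) %/% 3L + 1L]
}

#' Convert a 9-point arousal rating to its affect label
#'
#' Ratings 1-3 are labeled `low`, 4-6 `medium` and 7-9 `high`.
#'
#' @inheritParams valence_rating_to_label
#' @return Character vector of labels in `arousal_levels()`.
#' @export
arousal_rating_to_label <- function(score) {
  score <- .check_scores(score, "arousal rating")
  .arousal_levels[(score - 1L) %/% 3L + 1L]
}

.rating_to_label <- function(score, dimension) {
  switch(dimension,
         valence = valence_rating_to_label(score),
         arousal = arousal_rating_to_label(score),
         stop("dimension must be 'valence' or 'arousal'", call. = FALSE))
}

#' Split neutral pictures into low- and high-neutral subtypes
#'
#' Neutral pictures are subdivided by mean valence: `(4, 5]` is low neutral
#' and `(5, 6]` is high neutral. A neutral picture's mean can fall outside
#' `(4, 6]` because its label comes from the modal rater label rather than the
#' mean; such pictures are assigned the nearer subtype and flagged in the
#' `"flagged"` attribute (with a warning).
#'
#' @param mean_valence Numeric vector of mean valence ratings of pictures whose
#'   valence label is neutral.
#' @return Character vector (`"low_neutral"`/`"high_neutral"`) with a logical
#'   attribute `"flagged"` marking means outside `(4, 6]`.
#' @examples
#' neutral_subtype(c(4.57, 5.84))
#' @export
neutral_subtype <- function(mean_valence) {
  if (length(mean_valence) == 0L) stop("mean_valence must be non-empty", call. = FALSE)
  if (!is.numeric(mean_valence) || anyNA(mean_valence)) {
    stop("mean_valence must be numeric with no missing values", call. = FALSE)
  }
  if (any(mean_valence < 1 | mean_valence > 9)) {
    stop("mean_valence must lie in [1, 9]", call. = FALSE)
  }
  out <- ifelse(mean_valence <= 5, "low_neutral", "high_neutral")
  flagged <- mean_valence <= 4 | mean_valence > 6
  if (any(flagged)) {
    warning(sum(flagged), " neutral picture(s) have mean valence outside ",
            "(4, 6]; assigned the nearer subtype and flagged", call. = FALSE)
  }
  attr(out, "flagged") <- flagged
  out
}

#' Rater/participant eligibility gate
#'
#' A candidate passes iff they pass the color-vision test and score below the
#' anxiety and depression cutoffs (SAS < 50, SDS < 53, the Chinese normative
#' standards).
#'
#' @param color_vision_pass Logical vector: passed the color-blindness test.
#' @param sas_score Numeric vector of Zung self-rating anxiety scale scores.
#' @param sds_score Numeric vector of Zung self-rating depression scale scores.
#' @param sas_cutoff,sds_cutoff Exclusive upper cutoffs (defaults 50 and 53).
#' @return Logical vector, `TRUE` where all three conditions hold.
#' @examples
#' eligibility_check(c(TRUE, TRUE, FALSE), c(49.9, 50, 30), c(52.9, 40, 30))
#' @export
eligibility_check <- function(color_vision_pass, sas_score, sds_score,
                              sas_cutoff = 50, sds_cutoff = 53) {
  if (anyNA(color_vision_pass) || anyNA(sas_score) || anyNA(sds_score)) {
    stop("eligibility fields must not be missing", call. = FALSE)
  }
  if (!is.logical(color_vision_pass)) {
    stop("color_vision_pass must be logical", call. = FALSE)
  }
  color_vision_pass & (sas_score < sas_cutoff) & (sds_score < sds_cutoff)
}

# --- image naming convention: <category>-<p|hn|ln|n><NNN> ------------------

.stratum_codes <- c(positive = "p", high_neutral = "hn", low_neutral = "ln",
                    negative = "n", neutral = "n")

#' Parse library image identifiers
#'
#' Library images are named `<category>-<p|hn|ln|n><NNN>`, e.g. `people-hn093`
#' is the 93rd high-neutral picture of the people category.
#'
#' @param image_id Character vector of image identifiers.
#' @return A data.frame with columns `image_id`, `category` and `stratum`
#'   (`positive`, `high_neutral`, `low_neutral` or `negative`; `NA` when the
#'   suffix does not follow the convention).
#' @export
parse_image_id <- function(image_id) {
  category <- sub("-.*$", "", image_id)
  category[!category %in% .categories] <- NA_character_
  suffix <- sub("^[^-]*-", "", image_id)
  code <- sub("[0-9]+$", "", suffix)
  stratum <- names(.stratum_codes)[match(code, .stratum_codes)]
  data.frame(image_id = image_id, category = category, stratum = stratum,
             stringsAsFactors = FALSE)
}

#' @rdname parse_image_id
#' @param category Category name (one of [affect_categories()]).
#' @param stratum `positive`, `high_neutral`, `low_neutral`, `neutral` or
#'   `negative`.
#' @param n Integer index within the category/stratum.
#' @export
format_image_id <- function(category, stratum, n) {
  stopifnot(all(category %in% .categories), all(stratum %in% names(.stratum_codes)))
  sprintf("%s-%s%03d", category, .stratum_codes[stratum], as.integer(n))
}

# Restore-on-exit seeding so generation is reproducible without disturbing
# the caller's RNG stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
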