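.strata_for <- function(version) {
  switch(version,
         v1_3opt = c("positive", "neutral", "negative"),
         v2_4opt = c("positive", "high_neutral", "low_neutral", "negative"),
         stop("version must be 'v1_3opt' or 'v2_4opt'", call. = FALSE))
}

# image ids of a library stratum within one category; v1's single neutral
# stratum is the union of the two neutral subtypes
.stratum_pool <- function(library, category, stratum) {
  sub <- library[library$category == category, , drop = FALSE]
  switch(stratum,
         positive = sub$image_id[sub$valence_label == "positive"],
         negative = sub$image_id[sub$valence_label == "negative"],
         neutral = sub$image_id[sub$valence_label == "neutral"],
         high_neutral = sub$image_id[sub$valence_label == "neutral" &
                                       !is.na(sub$neutral_subtype) &
                                       sub$neutral_subtype == "high_neutral"],
         low_neutral = sub$image_id[sub$valence_label == "neutral" &
                                      !is.na(sub$neutral_subtype) &
                                      sub$neutral_subtype == "low_neutral"])
}

#' Check that a library can supply every trial stratum
#'
#' @param library An `hdrps_library`.
#' @param version Scale version: `"v2_4opt"` (positive / high-neutral /
#'   low-neutral / negative, the formal scale) or `"v1_3opt"` (positive /
#'   neutral / negative, the pre-test scale).
#' @return Invisibly `TRUE`; errors with a diagnostic naming every deficient
#'   (category, stratum) pair otherwise.
#' @export
check_library_coverage <- function(library, version = c("v2_4opt", "v1_3opt")) {
  version <- match.arg(version)
  strata <- .strata_for(version)
  missing <- character()
  for (cc in .categories) {
    for (st in strata) {
      if (length(.stratum_pool(library, cc, st)) == 0L) {
        missing <- c(missing, paste0("(", cc, ", ", st, ")"))
      }
    }
  }
  if (length(missing)) {
    stop("library cannot supply stratum picture(s) for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate dynamic picture-choice trials
#'
#' One trial consists of five rounds, one per picture category, with the
#' category order a seeded random permutation. Each round presents one
#' picture per valence stratum (drawn uniformly at random from the library
#' pictures of that category and stratum, without replacement within the
#' round) in a random presentation order. The same seed on the same library
#' reproduces the same trial sequence exactly.
#'
#' @param library An `hdrps_library` covering every (category, stratum) pair.
#' @param n_trials Number of trials to generate.
#' @param version `"v2_4opt"` (default) or `"v1_3opt"`.
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @return A data.frame of class `hdrps_trials`: `trial`, `round` (1-5),
#'   `category`, `stratum`, `image_id`, `position` (presentation order within
#'   the round), with attributes `version` and `seed`.
#' @export
generate_trials <- function(library, n_trials = 1L,
                            version = c("v2_4opt", "v1_3opt"), seed = NULL) {
  version <- match.arg(version)
  check_library_coverage(library, version)
  strata <- .strata_for(version)
  pools <- list()
  for (cc in .categories) {
    pools[[cc]] <- lapply(stats::setNames(strata, strata), function(st) {
      .stratum_pool(library, cc, st)
    })
  }
  .with_seed(seed, {
    rows <- vector("list", n_trials)
    for (tr in seq_len(n_trials)) {
      cats <- sample(.categories)
      per_round <- lapply(seq_along(cats), function(rd) {
        picks <- vapply(pools[[cats[rd]]],
                        function(p) if (length(p) == 1L) p else sample(p, 1L),
                        character(1L))
        data.frame(trial = tr, round = rd, category = cats[rd],
                   stratum = strata, image_id = unname(picks),
                   position = sample(length(strata)),
                   stringsAsFactors = FALSE)
      })
      rows[[tr]] <- do.call(rbind, per_round)
    }
    out <- do.call(rbind, rows)
    attr(out, "version") <- version
    attr(out, "seed") <- seed
    class(out) <- c("hdrps_trials", class(out))
    out
  })
}

#' @export
print.hdrps_trials <- function(x, ...) {
  cat("Dynamic picture-choice trials:", max(x$trial), "trial(s),",
      attr(x, "version"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more presentation rows\n")
  invisible(x)
}

.modal_valence_label <- function(labels) {
  # neutral subtypes collapse to neutral; ties resolve toward the middle
  labels[labels %in% .neutral_subtypes] <- "neutral"
  counts <- table(factor(labels, levels = .valence_levels))
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) top else "neutral"
}

#' Score one trial's picture selections
#'
#' The trial score is the mean library valence of the five selected pictures
#' (on the 9-point scale); the trial label is the modal valence label of the
#' selections, with neutral subtypes collapsed to neutral and ties resolved
#' toward neutral.
#'
#' @param selected Character vector of the 5 selected image ids.
#' @param library The `hdrps_library` the trial was generated from.
#' @param n_rounds Required number of selections (default 5); trials with
#'   fewer are incomplete and rejected.
#' @return List with `trial_score` (numeric) and `trial_label`.
#' @export
score_trial <- function(selected, library, n_rounds = 5L) {
  if (length(selected) < n_rounds) {
    stop("incomplete trial: ", length(selected), " of ", n_rounds,
         " selections; excluded from analysis", call. = FALSE)
  }
  idx <- match(selected, library$image_id)
  if (anyNA(idx)) {
    stop("selected picture(s) not in library: ",
         paste(selected[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  list(trial_score = mean(library$mean_valence[idx]),
       trial_label = .modal_valence_label(library$valence_label[idx]))
}

#' Score a table of trial responses
#'
#' @param responses Data frame with columns `participant_id`, `trial`,
#'   `round`, `image_id` (the selected picture).
#' @param library The `hdrps_library`.
#' @param n_rounds Selections required per trial; incomplete trials are
#'   dropped with a warning.
#' @return Data frame, one row per (participant, trial): `trial_score`,
#'   `trial_label`.
#' @export
score_responses <- function(responses, library, n_rounds = 5L) {
  key <- interaction(responses$participant_id, responses$trial, drop = TRUE)
  pieces <- split(responses, key)
  complete <- vapply(pieces, nrow, integer(1L)) >= n_rounds
  if (any(!complete)) {
    warning(sum(!complete), " incomplete trial(s) dropped", call. = FALSE)
  }
  rows <- lapply(pieces[complete], function(p) {
    s <- score_trial(p$image_id, library, n_rounds)
    data.frame(participant_id = p$participant_id[1L], trial = p$trial[1L],
               trial_score = s$trial_score, trial_label = s$trial_label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$trial), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Within-participant picture duplication rate
#'
#' Fraction of picture presentations, from the second trial onward of a
#' participant's first `window` trials, that repeat a picture already
#' presented to that participant. With one trial the rate is 0 by definition;
#' on a minimal library every later presentation is a repeat and the rate
#' is 1. Used to monitor how a larger library lowers the repetition a
#' respondent experiences across repeated administrations.
#'
#' @param trials An `hdrps_trials` data frame (one participant's trials), or
#'   any data frame with `trial` and `image_id` presentation rows.
#' @param window Number of leading trials to consider (default: all).
#' @return Numeric in `[0, 1]`.
#' @export
duplication_rate <- function(trials, window = max(trials$trial)) {
  keep <- trials$trial <= window
  tr <- trials$trial[keep]
  ids <- trials$image_id[keep]
  o <- order(tr)
  tr <- tr[o]; ids <- ids[o]
  first <- tr == min(tr)
  later <- which(!first)
  if (length(later) == 0L) return(0)
  seen_before <- vapply(later, function(i) ids[i] %in% ids[tr < tr[i]], logical(1L))
  mean(seen_before)
}
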