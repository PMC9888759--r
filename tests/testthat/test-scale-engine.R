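test_that("a minimal library forces every trial to use all 20 pictures once", {
  lib <- make_full_library(per_stratum = 1)
  tri <- generate_trials(lib, n_trials = 3, seed = 11)
  for (t in 1:3) {
    one <- tri[tri$trial == t, ]
    expect_setequal(one$image_id, lib$image_id)
    expect_setequal(one$category, affect_categories())  # a permutation of the 5
    expect_equal(nrow(one), 20L)
  }
})

test_that("trial generation is deterministic in the seed", {
  lib <- make_full_library(per_stratum = 3)
  expect_identical(generate_trials(lib, 5, seed = 42),
                   generate_trials(lib, 5, seed = 42))
  expect_false(identical(generate_trials(lib, 5, seed = 42),
                         generate_trials(lib, 5, seed = 43)))
  # the caller's RNG stream is left untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_trials(lib, 2, seed = 7)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated items satisfy the trial invariants on fuzzed libraries", {
  set.seed(601)
  for (rep in 1:5) {
    lib <- make_full_library(per_stratum = sample(1:4, 1), jitter = 0.4)
    for (version in c("v2_4opt", "v1_3opt")) {
      tri <- generate_trials(lib, n_trials = 4, version = version)
      n_strata <- if (version == "v2_4opt") 4L else 3L
      for (key in unique(paste(tri$trial, tri$round))) {
        item <- tri[paste(tri$trial, tri$round) == key, ]
        expect_equal(nrow(item), n_strata)        # exactly one per stratum
        expect_equal(anyDuplicated(item$stratum), 0L)
        expect_setequal(item$position, seq_len(n_strata))
        idx <- match(item$image_id, lib$image_id)
        expect_true(all(lib$category[idx] == item$category[1]))
        # presented pictures carry the stratum's library label
        lab <- ifelse(lib$valence_label[idx] == "neutral",
                      lib$neutral_subtype[idx], lib$valence_label[idx])
        if (version == "v2_4opt") {
          expect_true(all(lab == item$stratum))
        } else {
          expect_true(all(ifelse(item$stratum == "neutral",
                                 lab %in% c("low_neutral", "high_neutral"),
                                 lab == item$stratum)))
        }
      }
    }
  }
})

test_that("a library missing a stratum fails generation with a named diagnostic", {
  lib <- make_full_library(per_stratum = 1)
  lib <- lib[!(lib$category == "plants" &
                 lib$neutral_subtype %in% "high_neutral"), ]
  expect_error(generate_trials(lib, 1, seed = 1),
               "\\(plants, high_neutral\\)")
  # the 3-option version draws its neutral from both subtypes, so it still works
  expect_silent(tri <- generate_trials(lib, 1, version = "v1_3opt", seed = 1))
  expect_equal(nrow(tri), 15L)
})

test_that("trial scoring averages selected valences and takes the modal label", {
  ex <- hdrps_reference()$exemplars
  lib <- make_library(data.frame(image_id = ex$image_id, category = ex$category,
                                 mean_valence = ex$valence,
                                 valence_label = ifelse(ex$stratum %in% c("low_neutral", "high_neutral"),
                                                        "neutral", ex$stratum),
                                 stringsAsFactors = FALSE))
  positives <- ex$image_id[ex$stratum == "positive"]
  s <- score_trial(positives, lib)
  expect_equal(s$trial_score, mean(c(6.65, 6.11, 6.70, 6.74, 6.92)))
  expect_equal(s$trial_score, 6.624)
  expect_identical(s$trial_label, "positive")

  negatives <- ex$image_id[ex$stratum == "negative"]
  expect_identical(score_trial(c(negatives, positives[1]), lib, n_rounds = 5)$trial_label,
                   "negative")

  # positive/negative tie resolves toward neutral; subtypes collapse first
  tie <- c(positives[1:2], ex$image_id[ex$stratum == "high_neutral"][1],
           negatives[1:2])
  expect_identical(score_trial(tie, lib)$trial_label, "neutral")

  # permutation invariance in round order
  expect_equal(score_trial(rev(tie), lib), score_trial(tie, lib))

  expect_error(score_trial(positives[1:3], lib), "incomplete")
  expect_error(score_trial(c(positives[1:4], "people-zzz"), lib), "not in library")
})

test_that("response tables are scored per trial and incomplete trials dropped", {
  lib <- make_full_library(per_stratum = 1)
  pos_ids <- lib$image_id[lib$valence_label == "positive"]
  neg_ids <- lib$image_id[lib$valence_label == "negative"]
  responses <- rbind(
    data.frame(participant_id = "P1", trial = 1, round = 1:5, image_id = pos_ids),
    data.frame(participant_id = "P1", trial = 2, round = 1:5, image_id = neg_ids),
    data.frame(participant_id = "P2", trial = 1, round = 1:3, image_id = pos_ids[1:3]))
  expect_warning(sc <- score_responses(responses, lib), "incomplete")
  expect_equal(nrow(sc), 2L)
  expect_identical(sc$trial_label, c("positive", "negative"))
  expect_equal(sc$trial_score, c(7.5, 2.5))
})

test_that("a degenerate always-positive respondent is labeled positive everywhere", {
  lib <- make_full_library(per_stratum = 2, jitter = 0.3)
  tri <- generate_trials(lib, n_trials = 6, seed = 9)
  sel <- tri[tri$stratum == "positive", c("trial", "round", "image_id")]
  sel$participant_id <- "P1"
  sc <- score_responses(sel, lib, n_rounds = 5)
  expect_identical(unique(sc$trial_label), "positive")
})

test_that("duplication rate counts repeated presentations against earlier trials", {
  lib <- make_full_library(per_stratum = 1)
  expect_equal(duplication_rate(generate_trials(lib, 1, seed = 2)), 0)
  # minimal library: the second trial can only repeat pictures
  expect_equal(duplication_rate(generate_trials(lib, 2, seed = 2)), 1)

  # brute-force oracle on arbitrary presentation sequences
  set.seed(602)
  for (rep in 1:6) {
    fake <- data.frame(trial = rep(1:5, each = 4),
                       image_id = sample(sprintf("img%02d", 1:12), 20,
                                         replace = TRUE),
                       stringsAsFactors = FALSE)
    seen <- character(0); hits <- 0L; total <- 0L
    for (t in 1:5) {
      ids <- fake$image_id[fake$trial == t]
      if (t > 1) { hits <- hits + sum(ids %in% seen); total <- total + length(ids) }
      seen <- union(seen, ids)
    }
    expect_equal(duplication_rate(fake), hits / total)
    # a window restricted to the first trial has no repeats
    expect_equal(duplication_rate(fake, window = 1), 0)
  }
})

test_that("within-stratum sampling is uniform across a larger pool", {
  lib <- make_full_library(per_stratum = 3)
  tri <- generate_trials(lib, n_trials = 2000, seed = 603)
  pool <- lib$image_id[lib$category == "people" & lib$valence_label == "positive"]
  picks <- tri$image_id[tri$category == "people" & tri$stratum == "positive"]
  counts <- table(factor(picks, levels = pool))
  expect_equal(sum(counts), 2000)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})
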