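test_that("identity ratio counts modal labels and refuses ties a dominant label", {
  r <- identity_ratio(c(2, 2, 3, 8, 5, 5, 2), "valence")
  expect_identical(r$label, "negative")
  expect_equal(r$ratio, 4 / 7)

  expect_equal(identity_ratio(c(7, 7, 7), "valence")[c("label", "ratio")],
               list(label = "positive", ratio = 1))

  tie <- identity_ratio(c(4, 4, 8, 8), "valence")
  expect_true(is.na(tie$label))
  expect_equal(tie$ratio, 0.5)

  expect_error(identity_ratio(integer(0), "valence"), "non-empty")
})

test_that("screening retains a picture iff both dimensions reach the threshold", {
  scores <- list(
    # valence modal ratio 4/7, arousal 6/7: fails the 0.6 screen on valence
    borderline = list(v = c(2, 2, 3, 8, 5, 5, 2), a = c(2, 2, 1, 2, 3, 2, 7)),
    # unanimous on both dimensions
    clean = list(v = c(8, 8, 7, 9, 7, 8, 9), a = c(2, 3, 1, 2, 2, 1, 3)))
  ratings <- do.call(rbind, lapply(names(scores), function(id) {
    data.frame(rater_id = sprintf("r%d", 1:7), image_id = paste0("people-", id),
               dimension = rep(c("valence", "arousal"), each = 7),
               score = c(scores[[id]]$v, scores[[id]]$a),
               session_id = "s1", rater_affect_valid = TRUE,
               stringsAsFactors = FALSE)
  }))
  scr <- screen_images(ratings, threshold = 0.6)
  expect_identical(scr$retained[match(c("people-borderline", "people-clean"),
                                      scr$image_id)], c(FALSE, TRUE))
  # a vacuous threshold retains every picture of this tie-free table
  expect_true(all(screen_images(ratings, threshold = 0)$retained))

  # abnormal-affect sessions are excluded before counting
  flip <- data.frame(rater_id = sprintf("x%d", 1:6), image_id = "people-borderline",
                     dimension = "valence", score = 9, session_id = "s2",
                     rater_affect_valid = FALSE, stringsAsFactors = FALSE)
  scr2 <- suppressMessages(screen_images(rbind(ratings, flip), threshold = 0.6))
  expect_identical(scr2[order(scr2$image_id), ], scr[order(scr$image_id), ],
                   ignore_attr = TRUE)

  # pictures missing a dimension are reported and excluded
  orphan <- data.frame(rater_id = "r1", image_id = "people-orphan",
                       dimension = "valence", score = 5, session_id = "s1",
                       rater_affect_valid = TRUE, stringsAsFactors = FALSE)
  expect_warning(scr3 <- screen_images(rbind(ratings, orphan)), "missing a dimension")
  expect_false("people-orphan" %in% scr3$image_id)
  expect_identical(attr(scr3, "dropped_incomplete"), "people-orphan")
})

test_that("round merge keeps pictures retained in both rounds with consistent labels", {
  # 10 pictures: 7 valence-consistent, 6 arousal-consistent, 5 consistent on both
  v1 <- c("positive", "positive", "negative", "neutral", "neutral",
          "positive", "negative", "neutral", "positive", "negative")
  v2 <- c("positive", "positive", "negative", "neutral", "neutral",
          "positive", "negative", "negative", "neutral", "positive")
  a1 <- c("low", "medium", "high", "low", "medium",
          "high", "low", "medium", "high", "low")
  a2 <- c("low", "medium", "high", "medium", "medium",
          "low", "low", "high", "low", "low")
  stopifnot(sum(v1 == v2) == 7, sum(a1 == a2) == 6,
            sum(v1 == v2 & a1 == a2) == 5)
  ids <- sprintf("people-%03d", 1:10)
  lib <- merge_rounds(make_screening(ids, v1, a1),
                      make_screening(ids, v2, a2))
  expect_equal(nrow(lib), 5L)
  expect_setequal(lib$image_id, ids[v1 == v2 & a1 == a2])

  # label-consistency examples
  both <- merge_rounds(make_screening("people-001", "positive", "low"),
                       make_screening("people-001", "positive", "low"))
  expect_equal(nrow(both), 1L)
  differ <- merge_rounds(make_screening("people-001", "positive", "low"),
                         make_screening("people-001", "negative", "low"))
  expect_equal(nrow(differ), 0L)

  # present in only one round => not retained
  only1 <- merge_rounds(make_screening(c("people-001", "people-002"),
                                       "positive", "low"),
                        make_screening("people-001", "positive", "low"))
  expect_identical(only1$image_id, "people-001")

  expect_error(merge_rounds(make_screening("people-001", "positive", "low",
                                           threshold = 0.6),
                            make_screening("people-001", "positive", "low",
                                           threshold = 0.5)),
               "different thresholds")
})

test_that("final library means come from round 2 unless pooling is requested", {
  r1 <- make_screening("people-001", "neutral", "medium", mean_valence = 4.0,
                       mean_arousal = 4.0)
  r2 <- make_screening("people-001", "neutral", "medium", mean_valence = 5.0,
                       mean_arousal = 6.0)
  r1$n_raters <- 7L; r2$n_raters <- 35L
  expect_equal(merge_rounds(r1, r2)$mean_valence, 5.0)
  pooled <- merge_rounds(r1, r2, means = "pooled")
  expect_equal(pooled$mean_valence, (4 * 7 + 5 * 35) / 42)
  expect_equal(pooled$mean_arousal, (4 * 7 + 6 * 35) / 42)
  # the neutral picture gets a subtype from its final mean valence
  expect_identical(merge_rounds(r1, r2)$neutral_subtype, "low_neutral")
})

test_that("screening matches a brute-force recount and is monotone in the threshold", {
  set.seed(401)
  for (rep in 1:8) {
    tab <- random_rating_table(n_raters = sample(3:7, 1),
                               n_images = sample(8:20, 1))
    scr <- screen_images(tab, threshold = 0.6)
    for (i in seq_len(nrow(scr))) {
      id <- scr$image_id[i]
      v <- oracle_identity(tab$score[tab$image_id == id & tab$dimension == "valence"],
                           "valence")
      a <- oracle_identity(tab$score[tab$image_id == id & tab$dimension == "arousal"],
                           "arousal")
      expect_identical(scr$valence_label[i], v$label)
      expect_identical(scr$arousal_label[i], a$label)
      expect_equal(scr$valence_ratio[i], v$ratio, tolerance = 1e-10)
      expect_equal(scr$arousal_ratio[i], a$ratio, tolerance = 1e-10)
      expect_identical(scr$retained[i],
                       !is.na(v$label) && !is.na(a$label) &&
                         v$ratio >= 0.6 && a$ratio >= 0.6)
    }
    retained_sets <- lapply(c(0, 0.3, 0.5, 0.6, 0.8, 1), function(th) {
      s <- screen_images(tab, threshold = th)
      s$image_id[s$retained]
    })
    for (j in seq_len(length(retained_sets) - 1L)) {
      expect_true(all(retained_sets[[j + 1L]] %in% retained_sets[[j]]))
    }
  }
})

test_that("true labels are recovered as rater noise vanishes and degrade with noise", {
  build <- function(noise) {
    cfg <- sim_config(n_images_per_category = 12, rater_noise_sd = noise,
                      abnormal_affect_rate = 0)
    s <- simulate_ratings(cfg, seed = 77)
    lib <- merge_rounds(screen_images(s$expert), screen_images(s$professional))
    truth <- s$truth
    idx <- match(lib$image_id, truth$image_id)
    list(n = nrow(lib),
         recovery = mean(lib$valence_label == truth$true_valence_label[idx] &
                           lib$arousal_label == truth$true_arousal_label[idx]))
  }
  noiseless <- build(0)
  expect_equal(noiseless$n, 60L)         # nothing screened out
  expect_equal(noiseless$recovery, 1)    # labels match ground truth exactly
  noisy <- suppressWarnings(lapply(c(1.2, 3), build))
  expect_true(noiseless$n >= noisy[[1]]$n)
  expect_true(noisy[[1]]$n > noisy[[2]]$n)  # retention decays with noise
})

test_that("library statistics aggregate per category and shares sum to one", {
  lib <- make_full_library(per_stratum = 2)
  st <- library_stats(lib)
  expect_equal(attr(st, "total"), 40L)
  expect_equal(st$n, rep(8L, 5))
  expect_equal(sum(st$share_pct), 100)
  expect_equal(st$valence_min, rep(2.5, 5))
  expect_equal(st$valence_max, rep(7.5, 5))

  solo <- make_library(data.frame(image_id = "plants-p001", category = "plants",
                                  mean_valence = 7, valence_label = "positive",
                                  stringsAsFactors = FALSE))
  sst <- library_stats(solo)
  expect_equal(sst$share_pct[sst$category == "plants"], 100)
  expect_equal(sum(sst$share_pct), 100)
})

test_that("manifests and rating tables survive a round trip through disk", {
  lib <- make_full_library(per_stratum = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(lib, path)
  back <- read_manifest(path)
  expect_equal(as.data.frame(back), as.data.frame(lib))

  tab <- random_rating_table(3, 4)
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  expect_equal(read_ratings(csv), tab)
})
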