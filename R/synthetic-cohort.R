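#' Configuration of the synthetic rating/respondent cohort
#'
#' Collects and validates every knob of the synthetic data generator. The
#' defaults emulate the design of the original studies at desk scale: two
#' independent rating rounds (7 experts and 35 professional judges per
#' picture, matching the per-picture panel sizes of the 14-expert and
#' 209-judge studies), five picture categories, respondents measured twice a
#' day for seven days, and the formal study's demographic mix.
#'
#' Per category, true picture valence is an equal-weight mixture over the
#' four presentation strata with component means 2.5 (negative), 4.5
#' (low neutral), 5.5 (high neutral) and 7.5 (positive): adjacent strata sit
#' symmetrically about the scale midpoint, so the nearest-picture decision
#' boundaries (3.5 and 6.5) coincide with the rating-label boundaries. True
#' arousal is normal with the released per-category library means.
#'
#' @param n_images_per_category Pictures simulated per category (default 120,
#'   large enough that after identity-ratio screening at realistic rater
#'   noise every (category, stratum) cell keeps several pictures, as the
#'   real material library does).
#' @param valence_component_means Stratum component means of true valence.
#' @param valence_component_sd Within-stratum true-valence SD (default 0.6).
#' @param arousal_means Named per-category true-arousal means.
#' @param arousal_sd True-arousal SD (default 1.5).
#' @param n_raters_expert,n_raters_professional Raters per picture in the two
#'   rounds (defaults 7 and 35).
#' @param rater_noise_sd SD of a rater's error around the true value
#'   (default 1.2).
#' @param abnormal_affect_rate Fraction of rater sessions flagged as given
#'   under abnormal rater affect (excluded by screening; default 0.02).
#' @param n_participants Respondents in the validation cohort (default 100).
#' @param n_trials Administrations per respondent (default 14 = 7 days x 2).
#' @param start_level Initial latent valence of every respondent on the
#'   9-point scale (default 5, the scale midpoint; trajectories diffuse from
#'   it under each respondent's volatility).
#' @param drift Per-administration drift of the latent walk (default 0).
#' @param volatility Baseline per-administration SD of the bounded latent
#'   random walk (default 0.3).
#' @param beta_age,beta_sas,beta_sds Log-volatility loadings on the z-scored
#'   covariates: instability declines with age and rises with anxiety and
#'   depression scores (defaults -0.3, 0.1, 0.1).
#' @param temperature Choice softmax temperature: selection probability is
#'   proportional to `exp(-|picture valence - latent affect| / temperature)`
#'   (default 0.5).
#' @param sam_noise_sd SD of SAM report noise around latent affect
#'   (default 0.5).
#' @param pa_intercept,pa_slope,na_intercept,na_slope,panas_noise_sd Affine
#'   PANAS model: `PA = pa_intercept + pa_slope * affect + noise` (and
#'   analogously NA), clipped to the 10-50 subscale range. The weak loadings
#'   and large noise emulate PANAS's different (past-week) construct.
#' @param version Scale version administered (default `"v2_4opt"`).
#' @return Validated list of class `hdrps_sim_config`.
#' @export
sim_config <- function(n_images_per_category = 120L,
                       valence_component_means = c(negative = 2.5,
                                                   low_neutral = 4.5,
                                                   high_neutral = 5.5,
                                                   positive = 7.5),
                       valence_component_sd = 0.6,
                       arousal_means = c(people = 5.80, animals = 5.20,
                                         plants = 4.95, objects = 4.63,
                                         scenes = 4.43),
                       arousal_sd = 1.5,
                       n_raters_expert = 7L,
                       n_raters_professional = 35L,
                       rater_noise_sd = 1.2,
                       abnormal_affect_rate = 0.02,
                       n_participants = 100L,
                       n_trials = 14L,
                       start_level = 5,
                       drift = 0, volatility = 0.3,
                       beta_age = -0.3, beta_sas = 0.1, beta_sds = 0.1,
                       temperature = 0.5,
                       sam_noise_sd = 0.5,
                       pa_intercept = 22, pa_slope = 1.5,
                       na_intercept = 25, na_slope = -1.5,
                       panas_noise_sd = 8,
                       version = c("v2_4opt", "v1_3opt")) {
  version <- match.arg(version)
  stopifnot(n_images_per_category >= 1, n_raters_expert >= 2,
            n_raters_professional >= 2, rater_noise_sd >= 0,
            valence_component_sd >= 0, arousal_sd >= 0,
            abnormal_affect_rate >= 0, abnormal_affect_rate < 1,
            n_participants >= 1, n_trials >= 1,
            start_level >= 1, start_level <= 9,
            volatility >= 0, temperature > 0,
            sam_noise_sd >= 0, panas_noise_sd >= 0,
            all(.categories %in% names(arousal_means)))
  cfg <- as.list(environment())
  class(cfg) <- "hdrps_sim_config"
  cfg
}

#' @export
print.hdrps_sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d pictures/category; rater panels %d (expert) + %d (professional), noise SD %.2f\n",
              x$n_images_per_category, x$n_raters_expert,
              x$n_raters_professional, x$rater_noise_sd))
  cat(sprintf("  %d respondents x %d administrations (%s); volatility %.2f, temperature %.2f, SAM noise SD %.2f\n",
              x$n_participants, x$n_trials, x$version, x$volatility,
              x$temperature, x$sam_noise_sd))
  invisible(x)
}

#' Simulate two rounds of picture ratings with known ground truth
#'
#' Draws true valence/arousal per picture from the configured per-category
#' distributions, then simulates an expert and a (larger) professional rating
#' round: every rater's score is `round(clip(true + N(0, noise_sd), 1, 9))`.
#' A configurable fraction of rater sessions is flagged as given under
#' abnormal rater affect (`rater_affect_valid = FALSE`), mirroring the
#' pre-session affect check. The true label of a picture is the label a
#' noiseless rater would produce, i.e. the binned rounded true value.
#'
#' @param config An [sim_config()] object.
#' @param seed Optional integer seed (RNG state restored on exit).
#' @return List: `expert` and `professional` rating data frames (columns
#'   `rater_id`, `image_id`, `dimension`, `score`, `session_id`,
#'   `rater_affect_valid`), and `truth` (per picture: true values and labels).
#' @export
simulate_ratings <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "hdrps_sim_config"))
  .with_seed(seed, {
    n_cat <- config$n_images_per_category
    n_img <- n_cat * length(.categories)
    category <- rep(.categories, each = n_cat)
    image_id <- sprintf("%s-%03d", category, rep(seq_len(n_cat), times = length(.categories)))

    comp <- sample(seq_along(config$valence_component_means), n_img, replace = TRUE)
    true_v <- .clip(stats::rnorm(n_img,
                                 mean = config$valence_component_means[comp],
                                 sd = config$valence_component_sd), 1, 9)
    true_a <- .clip(stats::rnorm(n_img, mean = config$arousal_means[category],
                                 sd = config$arousal_sd), 1, 9)
    truth <- data.frame(image_id = image_id, category = category,
                        true_valence = true_v, true_arousal = true_a,
                        true_valence_label = valence_rating_to_label(round(true_v)),
                        true_arousal_label = arousal_rating_to_label(round(true_a)),
                        stringsAsFactors = FALSE)

    one_round <- function(prefix, n_raters) {
      rater_id <- sprintf("%s%03d", prefix, seq_len(n_raters))
      valid <- stats::runif(n_raters) >= config$abnormal_affect_rate
      grid <- expand.grid(rater = seq_len(n_raters), img = seq_len(n_img),
                          dimension = c("valence", "arousal"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      true_val <- ifelse(grid$dimension == "valence",
                         true_v[grid$img], true_a[grid$img])
      score <- as.integer(round(.clip(
        true_val + stats::rnorm(nrow(grid), 0, config$rater_noise_sd), 1, 9)))
      data.frame(rater_id = rater_id[grid$rater],
                 image_id = image_id[grid$img],
                 dimension = grid$dimension,
                 score = score,
                 session_id = paste0(rater_id[grid$rater], "-s1"),
                 rater_affect_valid = valid[grid$rater],
                 stringsAsFactors = FALSE)
    }
    list(expert = one_round("e", config$n_raters_expert),
         professional = one_round("j", config$n_raters_professional),
         truth = truth)
  })
}

.reflect_into <- function(x, lo = 1, hi = 9) {
  x <- ifelse(x < lo, 2 * lo - x, x)
  x <- ifelse(x > hi, 2 * hi - x, x)
  .clip(x, lo, hi)  # guard against overshooting reflections
}

.zscore <- function(x) if (stats::sd(x) == 0) rep(0, length(x)) else (x - mean(x)) / stats::sd(x)

#' Simulate respondents taking the picture scale with known latent affect
#'
#' Each respondent carries a latent valence trajectory: a bounded random walk
#' on the 9-point scale whose per-respondent volatility loads on age (down)
#' and on anxiety/depression scores (up). Per administration the respondent
#' receives a freshly generated trial, selects in each round the picture `p`
#' with probability proportional to
#' `exp(-|mean_valence_p - affect| / temperature)`, and reports SAM valence
#' before and after the trial (`round(clip(affect + noise))`) plus PANAS
#' positive/negative scores (affine in affect with heavy item noise).
#'
#' @param config An [sim_config()] object.
#' @param library An `hdrps_library` satisfying the coverage precondition of
#'   [generate_trials()] for `config$version`.
#' @param seed Optional integer seed.
#' @return List: `trials` (presented pictures), `responses` (selections),
#'   `calibration` (per administration: `sam_pre`, `sam_post`, `panas_pa`,
#'   `panas_na`), `participants` (covariates and true volatility) and `truth`
#'   (per administration latent affect).
#' @export
simulate_respondents <- function(config = sim_config(), library, seed = NULL) {
  stopifnot(inherits(config, "hdrps_sim_config"))
  check_library_coverage(library, config$version)
  ref <- hdrps_reference()$cohorts$formal
  .with_seed(seed, {
    n <- config$n_participants
    pid <- sprintf("P%04d", seq_len(n))
    age_group <- sample(1:4, n, replace = TRUE, prob = ref$age_group_shares)
    age_lo <- c(18, 31, 41, 51)[age_group]
    age_hi <- c(30, 40, 50, 60)[age_group]
    age <- age_lo + floor(stats::runif(n) * (age_hi - age_lo + 1))
    p_female <- ref$females / (ref$males + ref$females)
    gender <- 1L + stats::rbinom(n, 1L, p_female)  # 1 = male, 2 = female
    management_level <- sample(1:4, n, replace = TRUE, prob = ref$management_shares)
    marital_status <- sample(1:3, n, replace = TRUE, prob = ref$marital_shares)
    education <- sample(1:3, n, replace = TRUE, prob = ref$education_shares)
    seniority <- floor(stats::runif(n) * pmax(age - 18, 1))
    sas <- .clip(stats::rnorm(n, 40, 8), 20, 80)
    sds <- .clip(stats::rnorm(n, 42, 8), 20, 80)
    volatility <- config$volatility * exp(config$beta_age * .zscore(age) +
                                            config$beta_sas * .zscore(sas) +
                                            config$beta_sds * .zscore(sds))
    participants <- data.frame(participant_id = pid, gender = gender,
                               age = age, management_level = management_level,
                               seniority = seniority,
                               marital_status = marital_status,
                               education = education, sas = sas, sds = sds,
                               volatility = volatility,
                               stringsAsFactors = FALSE)

    trial_list <- vector("list", n)
    resp_list <- vector("list", n)
    calib_list <- vector("list", n)
    truth_list <- vector("list", n)
    for (i in seq_len(n)) {
      tri <- generate_trials(library, n_trials = config$n_trials,
                             version = config$version)
      tri_df <- as.data.frame(tri)
      tri_df$participant_id <- pid[i]

      a <- numeric(config$n_trials)
      a[1] <- .clip(config$start_level, 1, 9)
      if (config$n_trials > 1) {
        for (t in 2:config$n_trials) {
          a[t] <- .reflect_into(a[t - 1] + config$drift +
                                  stats::rnorm(1, 0, volatility[i]))
        }
      }

      sel_rows <- vector("list", config$n_trials)
      for (t in seq_len(config$n_trials)) {
        rows <- tri_df[tri_df$trial == t, , drop = FALSE]
        picks <- vapply(split(rows, rows$round), function(rr) {
          v <- library$mean_valence[match(rr$image_id, library$image_id)]
          d <- abs(v - a[t])
          w <- exp(-(d - min(d)) / config$temperature)  # stable softmax
          rr$image_id[sample.int(length(w), 1L, prob = w)]
        }, character(1L))
        sel_rows[[t]] <- data.frame(participant_id = pid[i], trial = t,
                                    round = as.integer(names(picks)),
                                    image_id = unname(picks),
                                    stringsAsFactors = FALSE)
      }
      resp_list[[i]] <- do.call(rbind, sel_rows)

      sam_pre <- as.integer(round(.clip(a + stats::rnorm(config$n_trials, 0, config$sam_noise_sd), 1, 9)))
      sam_post <- as.integer(round(.clip(a + stats::rnorm(config$n_trials, 0, config$sam_noise_sd), 1, 9)))
      panas_pa <- .clip(config$pa_intercept + config$pa_slope * a +
                          stats::rnorm(config$n_trials, 0, config$panas_noise_sd), 10, 50)
      panas_na <- .clip(config$na_intercept + config$na_slope * a +
                          stats::rnorm(config$n_trials, 0, config$panas_noise_sd), 10, 50)
      calib_list[[i]] <- data.frame(participant_id = pid[i],
                                    trial = seq_len(config$n_trials),
                                    sam_pre = sam_pre, sam_post = sam_post,
                                    panas_pa = panas_pa, panas_na = panas_na,
                                    stringsAsFactors = FALSE)
      truth_list[[i]] <- data.frame(participant_id = pid[i],
                                    trial = seq_len(config$n_trials),
                                    latent_affect = a, stringsAsFactors = FALSE)
      trial_list[[i]] <- tri_df
    }
    list(trials = do.call(rbind, trial_list),
         responses = do.call(rbind, resp_list),
         calibration = do.call(rbind, calib_list),
         participants = participants,
         truth = do.call(rbind, truth_list))
  })
}

#' PANAS composite score
#'
#' The single PANAS correlate used in the validity and instability analyses:
#' by default the affect balance `PA - NA`; the PA-only and NA-only variants
#' are available.
#'
#' @param pa,na Positive/negative subscale scores.
#' @param type `"balance"` (default), `"pa"` or `"na"`.
#' @return Numeric vector.
#' @export
panas_composite <- function(pa, na, type = c("balance", "pa", "na")) {
  type <- match.arg(type)
  switch(type, balance = pa - na, pa = pa, na = na)
}
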