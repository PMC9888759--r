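# Independent oracles and fixture builders. The oracles deliberately use
# different computational routes from the package (lookup tables, covariance
# identities, explicit sums) so agreement is a real cross-check.

oracle_valence_label <- function(score) {
  rep(c("negative", "neutral", "positive"), each = 3)[score]
}

oracle_arousal_label <- function(score) {
  rep(c("low", "medium", "high"), each = 3)[score]
}

# brute-force modal label + identity ratio by explicit counting
oracle_identity <- function(scores, dimension) {
  lab <- if (dimension == "valence") oracle_valence_label(scores) else oracle_arousal_label(scores)
  counts <- sapply(unique(lab), function(l) sum(lab == l))
  top <- max(counts)
  modal <- names(counts)[counts == top]
  list(label = if (length(modal) == 1L) modal else NA_character_,
       ratio = top / length(scores))
}

# Cronbach's alpha via the covariance identity k*cbar / (vbar + (k-1)*cbar),
# mathematically equal to the variance-ratio formula but computed from the
# item covariance matrix.
oracle_alpha <- function(cases_by_items) {
  C <- stats::cov(cases_by_items)
  k <- ncol(C)
  vbar <- mean(diag(C))
  cbar <- mean(C[upper.tri(C)])
  k * cbar / (vbar + (k - 1) * cbar)
}

# Pearson r from raw sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# random rating table covering both dimensions for every image
random_rating_table <- function(n_raters, n_images) {
  grid <- expand.grid(rater = seq_len(n_raters), img = seq_len(n_images),
                      dimension = c("valence", "arousal"),
                      stringsAsFactors = FALSE)
  data.frame(rater_id = sprintf("r%02d", grid$rater),
             image_id = sprintf("people-%03d", grid$img),
             dimension = grid$dimension,
             score = sample(1:9, nrow(grid), replace = TRUE),
             session_id = "s1", rater_affect_valid = TRUE,
             stringsAsFactors = FALSE)
}

# construct an hdrps_library directly from per-picture specs
make_library <- function(df, threshold = 0.6) {
  df$neutral_subtype <- ifelse(df$valence_label == "neutral",
                               ifelse(df$mean_valence <= 5, "low_neutral", "high_neutral"),
                               NA_character_)
  if (is.null(df$mean_arousal)) df$mean_arousal <- 5
  if (is.null(df$arousal_label)) df$arousal_label <- "medium"
  attr(df, "threshold") <- threshold
  attr(df, "means") <- "round2"
  class(df) <- c("hdrps_library", class(df))
  df
}

# library with `per_stratum` pictures in every (category, stratum) cell,
# stratum valences centred at 2.5 / 4.5 / 5.5 / 7.5
make_full_library <- function(per_stratum = 1, jitter = 0) {
  centers <- c(negative = 2.5, low_neutral = 4.5, high_neutral = 5.5,
               positive = 7.5)
  labels <- c(negative = "negative", low_neutral = "neutral",
              high_neutral = "neutral", positive = "positive")
  rows <- list()
  for (cc in affect_categories()) {
    for (st in names(centers)) {
      for (i in seq_len(per_stratum)) {
        v <- centers[[st]] + if (jitter > 0) stats::runif(1, -jitter, jitter) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = sprintf("%s-%s%03d", cc,
                             c(negative = "n", low_neutral = "ln",
                               high_neutral = "hn", positive = "p")[[st]], i),
          category = cc, mean_valence = v,
          valence_label = labels[[st]], stringsAsFactors = FALSE)
      }
    }
  }
  make_library(do.call(rbind, rows))
}

# screening-result scaffold for merge_rounds contract tests
make_screening <- function(image_id, valence_label, arousal_label,
                           retained = TRUE, threshold = 0.6,
                           mean_valence = 5, mean_arousal = 5) {
  out <- data.frame(image_id = image_id, valence_label = valence_label,
                    valence_ratio = 1, arousal_label = arousal_label,
                    arousal_ratio = 1, mean_valence = mean_valence,
                    mean_arousal = mean_arousal, n_raters = 7L,
                    retained = retained, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("hdrps_screening", class(out))
  out
}
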