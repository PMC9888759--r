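#' Published reference statistics of the HDRPS material library and cohorts
#'
#' Reference numbers released with the original HDRPS instrument, usable as
#' inputs for bookkeeping checks and as calibration anchors for the synthetic
#' generator: the per-category descriptive statistics of the 3,386-picture
#' material library, the twenty published exemplar pictures with their mean
#' valence (V) and arousal (A) ratings, and the recruitment/exclusion
#' bookkeeping of the rating panels and validation cohorts.
#'
#' @return A list with components:
#' \describe{
#'   \item{library}{data.frame, one row per category: `n`, valence and
#'     arousal min/max/mean of the released material library.}
#'   \item{exemplars}{data.frame of the 20 published exemplar pictures:
#'     `image_id` (category-stratum naming convention), `category`,
#'     `stratum`, `valence`, `arousal`.}
#'   \item{cohorts}{list of recruitment bookkeeping counts: the expert panel
#'     (`expert_panel`), the professional rating round (`professional`:
#'     recruited, low-relevance, color-vision, SAS/SDS exclusions with their
#'     overlap) and the formal validation study (`formal`: recruited, male
#'     and female counts of those passing screening, plus demographic
#'     shares).}
#' }
#' @export
hdrps_reference <- function() {
  library <- data.frame(
    category = c("people", "animals", "plants", "objects", "scenes"),
    n = c(404L, 585L, 529L, 609L, 1259L),
    valence_min = c(1.00, 2.27, 2.88, 1.92, 2.01),
    valence_max = c(8.97, 8.09, 8.02, 8.21, 7.90),
    valence_mean = c(5.04, 5.72, 5.94, 5.33, 5.14),
    arousal_min = c(1.21, 2.32, 2.23, 1.13, 1.01),
    arousal_max = c(8.94, 8.71, 7.42, 9.00, 7.30),
    arousal_mean = c(5.80, 5.20, 4.95, 4.63, 4.43),
    stringsAsFactors = FALSE)

  ex <- function(cat, code, n, v, a) {
    stratum <- c(p = "positive", hn = "high_neutral", ln = "low_neutral",
                 n = "negative")[[code]]
    data.frame(image_id = sprintf("%s-%s%03d", cat, code, n), category = cat,
               stratum = stratum, valence = v, arousal = a,
               stringsAsFactors = FALSE)
  }
  exemplars <- rbind(
    ex("people", "p", 81, 6.65, 7.30), ex("people", "hn", 93, 5.84, 4.96),
    ex("people", "ln", 16, 4.57, 3.94), ex("people", "n", 127, 2.67, 4.17),
    ex("animals", "p", 57, 6.11, 6.14), ex("animals", "hn", 78, 5.76, 4.98),
    ex("animals", "ln", 5, 4.46, 4.03), ex("animals", "n", 2, 3.38, 7.97),
    ex("plants", "p", 264, 6.70, 6.21), ex("plants", "hn", 170, 5.89, 5.03),
    ex("plants", "ln", 3, 4.05, 3.98), ex("plants", "n", 13, 3.47, 3.73),
    ex("objects", "p", 205, 6.74, 5.08), ex("objects", "hn", 167, 5.80, 4.98),
    ex("objects", "ln", 17, 4.45, 5.23), ex("objects", "n", 125, 2.78, 4.88),
    ex("scenes", "p", 306, 6.92, 6.16), ex("scenes", "hn", 44, 5.93, 4.83),
    ex("scenes", "ln", 100, 4.69, 4.02), ex("scenes", "n", 235, 2.98, 4.11))

  cohorts <- list(
    expert_panel = list(recruited = 14L, qualified = 14L, group_size = 7L),
    professional = list(recruited = 244L, low_relevance = 25L,
                        color_vision_fail = 1L, sas_exceed = 9L,
                        sds_exceed = 3L, sas_and_sds_exceed = 3L),
    pretest = list(recruited = 261L, passed_screening = 229L,
                   completed = 209L),
    formal = list(recruited = 636L, males = 154L, females = 368L,
                  age_group_shares = c(`18-30` = 0.356, `31-40` = 0.276,
                                       `41-50` = 0.239, `51-60` = 0.128),
                  marital_shares = c(unmarried = 0.337, married = 0.615,
                                     divorced = 0.048),
                  education_shares = c(college_or_below = 0.287,
                                       undergraduate = 0.421,
                                       master_or_above = 0.291),
                  management_shares = c(government = 0.282, enterprise = 0.324,
                                        service = 0.065, other = 0.329)))

  list(library = library, exemplars = exemplars, cohorts = cohorts)
}
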