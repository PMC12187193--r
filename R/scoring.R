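#' Packaged per-temperature aerobic-scope cutoffs
#'
#' The published classification cutoffs: for each temperature treatment,
#' the 25th/50th/75th percentile of the aerobic-scope range available for
#' the species (per-minute units). The 21 and 24 degC treatments share one
#' row ("high"). Individuals score 1-4 points per temperature against
#' these cutoffs.
#'
#' @return A tibble with columns `temp_bucket` (`"16"`, `"10"`, `"high"`),
#'   `c25`, `c50`, `c75`, `provenance`.
#' @export
#' @examples
#' table1_cutoffs()
table1_cutoffs <- function() {
  tibble::tibble(
    temp_bucket = c("16", "10", "high"),
    c25 = c(1.75, 2.59, 3.35),
    c50 = c(2.60, 3.68, 4.20),
    c75 = c(3.45, 4.77, 5.05),
    provenance = "table1_packaged"
  )
}

#' Cutoff row for a treatment temperature
#'
#' Maps a numeric treatment temperature onto its cutoff bucket: 16 degC
#' and 10 degC have their own rows; anything >= 21 uses the pooled
#' high-temperature ("21-24 degC") row.
#'
#' @param cutoffs A cutoff tibble ([table1_cutoffs()] or derived).
#' @param temp_c Treatment temperature (degC).
#' @return A single cutoff row.
#' @export
cutoffs_for_temp <- function(cutoffs, temp_c) {
  bucket <- if (temp_c >= 21) "high" else as.character(round(temp_c))
  row <- cutoffs[cutoffs$temp_bucket == bucket, ]
  if (nrow(row) != 1) {
    stop("no cutoff row for treatment temperature ", temp_c, " degC",
         call. = FALSE)
  }
  row
}

validate_cutoffs <- function(c25, c50, c75) {
  if (!(c25 < c50 && c50 < c75)) {
    stop("degenerate cutoffs: need c25 < c50 < c75", call. = FALSE)
  }
}

#' Evenly spaced percentile cutoffs from an aerobic-scope range
#'
#' Linear interpolation over `[as_min, as_max]`:
#' `c_p = as_min + p * (as_max - as_min)` for p = 0.25, 0.5, 0.75. This is
#' the reading under which every published cutoff row is exactly evenly
#' spaced, and it reproduces those rows from their implied (min, max).
#'
#' @param as_min,as_max The species' aerobic-scope range at one
#'   temperature; `as_min < as_max`.
#' @param temp_bucket Label for the resulting row.
#' @return A one-row cutoff tibble, `provenance = "range_interpolated"`.
#' @export
#' @examples
#' cutoffs_from_range(0.9, 4.3)  # the 16 degC row: 1.75 / 2.60 / 3.45
cutoffs_from_range <- function(as_min, as_max, temp_bucket = "custom") {
  if (!(as_min < as_max)) {
    stop("`as_min` must be strictly less than `as_max`", call. = FALSE)
  }
  cc <- as_min + c(0.25, 0.5, 0.75) * (as_max - as_min)
  validate_cutoffs(cc[1], cc[2], cc[3])
  tibble::tibble(temp_bucket = temp_bucket, c25 = cc[1], c50 = cc[2],
                 c75 = cc[3], provenance = "range_interpolated")
}

#' Empirical percentile cutoffs from observed aerobic-scope values
#'
#' The alternative reading of the percentile method: the 25th/50th/75th
#' empirical quantiles of pooled aerobic-scope data, with the same order
#' statistic interpolation rule (`h = q * (n - 1)`, R type 7) used for the
#' SMR quantile.
#'
#' @param as_values At least 4 aerobic-scope values.
#' @param probs The three probabilities; default `c(0.25, 0.5, 0.75)`.
#' @param temp_bucket Label for the resulting row.
#' @return A one-row cutoff tibble, `provenance = "empirical"`.
#' @export
cutoffs_empirical <- function(as_values, probs = c(0.25, 0.5, 0.75),
                              temp_bucket = "custom") {
  if (length(as_values) < 4) {
    stop("need at least 4 aerobic-scope values for empirical cutoffs",
         call. = FALSE)
  }
  cc <- unname(stats::quantile(as_values, probs = probs, type = 7))
  validate_cutoffs(cc[1], cc[2], cc[3])
  tibble::tibble(temp_bucket = temp_bucket, c25 = cc[1], c50 = cc[2],
                 c75 = cc[3], provenance = "empirical")
}

#' Rank score of one aerobic-scope value
#'
#' 1 point below the 25th-percentile cutoff, 2 from there to the median,
#' 3 from the median to the 75th, 4 at or above the 75th. Bands are
#' lower-inclusive half-open (a value exactly on a cutoff takes the higher
#' score), which makes the score monotone, total and deterministic.
#' Negative scope scores 1.
#'
#' @param as_value A finite aerobic-scope value (same units as the
#'   cutoffs).
#' @param cutoffs A one-row cutoff tibble.
#' @return Integer score in 1..4.
#' @export
rank_score <- function(as_value, cutoffs) {
  stopifnot(is.finite(as_value), nrow(cutoffs) == 1)
  validate_cutoffs(cutoffs$c25, cutoffs$c50, cutoffs$c75)
  1L + (as_value >= cutoffs$c25) + (as_value >= cutoffs$c50) +
    (as_value >= cutoffs$c75)
}

#' Total performance score over the three temperature treatments
#'
#' The arithmetic sum of exactly three per-temperature rank scores (16,
#' 10, and 21-or-24 degC), hence in 3..12. Missing temperatures are an
#' error: the scheme is defined only on complete triples and nothing is
#' imputed.
#'
#' @param ranks Exactly three integers, each in 1..4.
#' @return Integer total in 3..12.
#' @export
#' @examples
#' total_score(c(3, 1, 1)) # intermediate only at the optimum -> 5, low
total_score <- function(ranks) {
  if (length(ranks) != 3 || anyNA(ranks)) {
    stop("a total score needs exactly one rank per temperature ",
         "treatment (three in all); no imputation", call. = FALSE)
  }
  if (!all(ranks %in% 1:4)) {
    stop("rank scores must be integers in 1..4", call. = FALSE)
  }
  as.integer(sum(ranks))
}

#' Phenotype class from a total score
#'
#' Low performer at total <= 5, intermediate at 6-9, high performer at
#' total >= 10 - the integer bands obtained by rounding the 25th/75th
#' percentiles (5.25 and 9.75) of the achievable 3..12 interval.
#'
#' @param total Integer in 3..12.
#' @return `"low"`, `"intermediate"` or `"high"`.
#' @export
classify <- function(total) {
  if (length(total) != 1 || is.na(total) || total != round(total) ||
      total < 3 || total > 12) {
    stop("`total` must be an integer in 3..12", call. = FALSE)
  }
  if (total <= 5) "low" else if (total <= 9) "intermediate" else "high"
}

#' Percentile thresholds of the achievable score interval
#'
#' The class boundaries derive from linear interpolation over the
#' achievable total-score interval \[3, 12\]: `3 + p * 9` gives 5.25 at
#' p = 0.25 and 9.75 at p = 0.75, rounded to the integer thresholds 5
#' (low, <=) and 10 (high, >=) actually used.
#'
#' @param p Probability; vectorized.
#' @return A tibble: `p`, `threshold` (exact), `rounded` (integer).
#' @export
#' @examples
#' score_band_thresholds(c(0.25, 0.75))
score_band_thresholds <- function(p = c(0.25, 0.75)) {
  stopifnot(all(p >= 0 & p <= 1))
  threshold <- 3 + p * (12 - 3)
  tibble::tibble(p = p, threshold = threshold, rounded = round(threshold))
}

#' Score one individual's aerobic-scope triple
#'
#' @param as_16,as_10,as_high Aerobic scope at the 16 degC, 10 degC and
#'   high (21 or 24 degC) treatments, on the cutoffs' unit scale.
#' @param cutoffs A three-row cutoff tibble ([table1_cutoffs()] or
#'   derived) with buckets `"16"`, `"10"`, `"high"`.
#' @return A one-row scorecard tibble: `score_16`, `score_10`,
#'   `score_high`, `total`, `phenotype`.
#' @export
#' @examples
#' score_individual(3.0, 4.0, 5.5) # 3 + 3 + 4 = 10 -> high
score_individual <- function(as_16, as_10, as_high,
                             cutoffs = table1_cutoffs()) {
  s16 <- rank_score(as_16, cutoffs_for_temp(cutoffs, 16))
  s10 <- rank_score(as_10, cutoffs_for_temp(cutoffs, 10))
  shigh <- rank_score(as_high, cutoffs_for_temp(cutoffs, 21))
  total <- total_score(c(s16, s10, shigh))
  tibble::tibble(score_16 = s16, score_10 = s10, score_high = shigh,
                 total = total, phenotype = classify(total))
}
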