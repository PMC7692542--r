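#' Interpersonal attraction composite
#'
#' The social- and task-attraction items collapse into a single measure:
#' the arithmetic mean of the 8 items (7-point Likert scale).
#'
#' @param items numeric vector of exactly 8 values in 1..7, no missing.
#' @return scalar in \[1, 7\].
#' @export
attraction_score <- function(items) {
  if (length(items) != 8) stop("exactly 8 attraction items expected")
  if (anyNA(items)) stop("missing attraction item")
  if (any(items < 1 | items > 7)) stop("attraction items must lie in 1..7")
  mean(items)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a k-item scale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#'
#' @param items numeric matrix, participants x items.
#' @return scalar alpha (at most 1).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  n <- nrow(items); k <- ncol(items)
  if (n < 2 || k < 2) stop("need at least 2 participants and 2 items")
  total_var <- stats::var(rowSums(items))
  if (total_var <= 0) stop("zero total-score variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
}

#' Profile correlation (impression accuracy)
#'
#' Pearson correlation across the 15 personality items between a target's
#' self-ratings and the partner's ratings of the target.  Items where the
#' observer chose "Cannot make judgment" (`NA`) are dropped pairwise; the
#' result is missing when fewer than `min_items` complete pairs remain or
#' either profile is constant over them.
#'
#' @param self,observer numeric vectors of equal length (15 in the standard
#'   inventory); `observer` may contain `NA`.
#' @param min_items smallest number of complete pairs for a defined
#'   correlation (default 5).
#' @return scalar in \[-1, 1\], or `NA` with a `reason` attribute.
#' @export
profile_correlation <- function(self, observer, min_items = 5) {
  stopifnot(length(self) == length(observer))
  ok <- !is.na(self) & !is.na(observer)
  if (sum(ok) < min_items) {
    return(structure(NA_real_, reason = sprintf(
      "only %d complete item pair(s), need %d", sum(ok), min_items)))
  }
  s <- self[ok]; o <- observer[ok]
  if (stats::sd(s) == 0 || stats::sd(o) == 0) {
    return(structure(NA_real_, reason = "constant profile"))
  }
  stats::cor(s, o)
}

#' Affective valence
#'
#' Percentage of positive emotion words minus percentage of negative
#' emotion words in a free-text description of the interaction.
#'
#' @param pos_pct,neg_pct percentages in \[0, 100\].
#' @return scalar in \[-100, 100\].
#' @export
affective_valence <- function(pos_pct, neg_pct) {
  if (any(c(pos_pct, neg_pct) < 0) || any(c(pos_pct, neg_pct) > 100)) {
    stop("percentages must lie in [0, 100]")
  }
  pos_pct - neg_pct
}

#' Emotion-word rate from a user lexicon
#'
#' Simple stand-in counter for dictionary-based text analysis when raw
#' word percentages are not supplied: the percentage of tokens matching a
#' word set, case-insensitively.
#'
#' @param tokens character vector of words (at least one).
#' @param lexicon character vector of dictionary words.
#' @return percentage in \[0, 100\].
#' @export
lexicon_rate <- function(tokens, lexicon) {
  if (length(tokens) == 0) stop("empty token list")
  100 * mean(tolower(tokens) %in% tolower(lexicon))
}

#' Outcome table from questionnaire records
#'
#' One row per participant: the attraction composite, impression accuracy
#' (profile correlation between the partner's self profile and this
#' participant's observer ratings of the partner -- i.e. how accurately
#' this participant judged their partner), affective valence, and gender.
#'
#' @param records a `questionnaire_records` data frame.
#' @param min_items passed to [profile_correlation()].
#' @return data frame with columns `participant_id`, `dyad_id`,
#'   `attraction`, `impression_accuracy`, `affective_valence`, `gender`.
#' @export
outcome_table <- function(records, min_items = 5) {
  n <- nrow(records)
  partner_of <- function(i) {
    same <- which(records$dyad_id == records$dyad_id[i])
    setdiff(same, i)[1]
  }
  acc <- vapply(seq_len(n), function(i) {
    j <- partner_of(i)
    if (is.na(j)) return(NA_real_)
    as.numeric(profile_correlation(records$bfi_self[[j]],
                                   records$bfi_observer[[i]], min_items))
  }, numeric(1))
  data.frame(
    participant_id = records$participant_id,
    dyad_id = records$dyad_id,
    attraction = vapply(records$attraction_items, attraction_score,
                        numeric(1)),
    impression_accuracy = acc,
    affective_valence = mapply(affective_valence, records$pos_pct,
                               records$neg_pct),
    gender = records$gender,
    stringsAsFactors = FALSE
  )
}
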