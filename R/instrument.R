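#' Sensitivity and specificity of the instrument at its threshold
#'
#' The instrument is modelled as a binormal latent score: condition-negative
#' individuals draw scores from N(mean_neg, sd_neg) and condition-positive
#' individuals from N(mean_pos, sd_pos); a screen is positive when the score
#' strictly exceeds the threshold (ties score negative). Raising the
#' threshold therefore lowers sensitivity and raises specificity — the
#' classic cut-score trade-off.
#'
#' @param inst Instrument parameter list (see [scenario_config()]).
#' @return A list of class `operating_point` with `threshold`, `sensitivity`
#'   = P(score > threshold | positive class) and `specificity`
#'   = P(score <= threshold | negative class), both closed-form Gaussian
#'   tails.
#' @export
operating_point <- function(inst) {
  if (inst$sd_score_negative <= 0 || inst$sd_score_positive <= 0) {
    stop("invalid scenario: field 'instrument.sd_score_*' must be in (0, Inf]",
         call. = FALSE)
  }
  structure(list(
    threshold = inst$threshold,
    sensitivity = stats::pnorm(inst$threshold,
                               mean = inst$mean_score_positive,
                               sd = inst$sd_score_positive,
                               lower.tail = FALSE),
    specificity = stats::pnorm(inst$threshold,
                               mean = inst$mean_score_negative,
                               sd = inst$sd_score_negative)
  ), class = "operating_point")
}

#' Operating points over a grid of thresholds
#'
#' @param inst Instrument parameter list.
#' @param n_points Number of grid points (>= 2).
#' @param span Length-2 numeric range of thresholds to cover.
#' @return A data frame with columns `threshold`, `sensitivity`,
#'   `specificity`, ordered by threshold; sensitivity is non-increasing and
#'   specificity non-decreasing along the grid.
#' @export
threshold_grid <- function(inst, n_points, span) {
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  if (length(span) != 2 || !is.finite(diff(range(span))) || diff(range(span)) == 0) {
    stop("span must be a non-empty numeric range", call. = FALSE)
  }
  thresholds <- seq(min(span), max(span), length.out = n_points)
  rows <- lapply(thresholds, function(th) {
    inst$threshold <- th
    op <- operating_point(inst)
    data.frame(threshold = th, sensitivity = op$sensitivity,
               specificity = op$specificity)
  })
  do.call(rbind, rows)
}
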