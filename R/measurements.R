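#' Ponderal gain
#'
#' Relative body-weight change between two weighings, expressed against the
#' final weight:
#' \deqn{PG(\%) = \frac{final - initial}{final} \times 100}
#' Signed: a loss yields a negative gain. The value is returned at full
#' precision; round only at presentation (2 dp is conventional).
#'
#' @param initial,final Body weights in grams, both > 0. Vectorised.
#' @return Ponderal gain in percent.
#' @examples
#' ponderal_gain(200, 250)  # 20
#' ponderal_gain(250, 200)  # -25
#' @export
ponderal_gain <- function(initial, final) {
  if (any(!is.finite(initial)) || any(!is.finite(final)) ||
      any(initial <= 0) || any(final <= 0))
    stop("body weights must be positive and finite")
  (final - initial) / final * 100
}

#' Weekly ponderal-gain series
#'
#' Per-week ponderal gain over consecutive weighings of one animal, the
#' earlier weight of each pair serving as the initial weight. This is the
#' quantity monitored for the sudden pre-prodrome weight jump.
#'
#' @param weeks Integer vector of observation weeks, strictly increasing.
#' @param weights Body weights in grams, same length, all > 0.
#' @return Data frame with columns `week` (the later week of each pair) and
#'   `pg` (percent). Zero rows when fewer than 2 observations.
#' @examples
#' weekly_ponderal_series(1:3, c(200, 220, 231))$pg  # 9.09..., 4.76...
#' @export
weekly_ponderal_series <- function(weeks, weights) {
  weeks <- as.integer(weeks)
  if (length(weeks) != length(weights))
    stop("'weeks' and 'weights' lengths differ")
  if (is.unsorted(weeks, strictly = TRUE))
    stop("'weeks' must be strictly increasing")
  if (length(weights) < 2L)
    return(data.frame(week = integer(), pg = numeric()))
  n <- length(weights)
  data.frame(week = weeks[-1L],
             pg = ponderal_gain(weights[-n], weights[-1L]))
}

#' Corrected terminal body weight
#'
#' Terminal body weight minus the weight of the full intestine and its
#' content. In this model the cecum of induced animals is frequently
#' distended and impacted, so the raw terminal weight overstates body mass;
#' reported weights are corrected for the intestinal compartment.
#'
#' @param total_bw Total body weight prior to euthanasia (grams).
#' @param intestine_plus_content Weight of the full intestine with content
#'   (grams); must satisfy `0 <= intestine_plus_content < total_bw`.
#' @return Corrected weight in grams. Vectorised.
#' @export
corrected_body_weight <- function(total_bw, intestine_plus_content) {
  if (any(intestine_plus_content < 0) ||
      any(intestine_plus_content >= total_bw))
    stop("need 0 <= intestine_plus_content < total_bw")
  total_bw - intestine_plus_content
}

#' Mean food or water consumption per animal per day
#'
#' Difference between the repository (food hopper or water bottle) weight at
#' the start and end of the period, divided by the number of animals in the
#' cage times the number of days. Refills are modelled as separate records,
#' so the start weight can never be below the end weight.
#'
#' @param start_weight,end_weight Repository weights in grams.
#' @param n_animals Animals in the cage (>= 1).
#' @param n_days Days in the period (>= 1).
#' @return Grams per animal per day.
#' @examples
#' mean_consumption(700, 0, 5, 7)  # 20
#' @export
mean_consumption <- function(start_weight, end_weight, n_animals, n_days) {
  if (any(n_animals < 1) || any(n_days < 1))
    stop("need n_animals >= 1 and n_days >= 1")
  if (any(start_weight < end_weight))
    stop("repository weight increased over the period; ",
         "model refills as separate records")
  (start_weight - end_weight) / (n_animals * n_days)
}

#' Detect the lethal prodrome from weights and clinical signs
#'
#' Animals that die of hemorrhagic enteritis in this model follow a
#' stereotyped sequence: a sudden weekly body-weight gain (about 6-10%),
#' then swollen abdomen, diarrhea, priapism, and death. This detector turns
#' weekly weights and observed signs into per-week alert levels:
#'
#' * `watch` -- weekly ponderal gain at or above `watch_pg` (default 6%), or
#'   any single prodrome sign.
#' * `high` -- weekly gain above `high_pg` (default 10%), or a sudden gain
#'   followed (same or later week) by any of swollen abdomen, diarrhea or
#'   priapism, or two or more distinct signs flagged by that week.
#'
#' Alert levels are cumulative in the sign history, so adding a sign can
#' only raise, never lower, the alert.
#'
#' @param weeks,weights The animal's weighing weeks (strictly increasing)
#'   and weights in grams.
#' @param signs Data frame with columns `week`, `swollen_abdomen`,
#'   `diarrhea`, `priapism` (logical). Missing weeks count as all-FALSE.
#' @param watch_pg,high_pg Thresholds in percent weekly ponderal gain.
#' @return Data frame, one row per observation week: flags `sudden_gain`,
#'   `swollen_abdomen`, `diarrhea`, `priapism`, the weekly `pg`, and
#'   `alert_level` in \{none, watch, high\}.
#' @export
detect_prodrome <- function(weeks, weights, signs = NULL,
                            watch_pg = 6, high_pg = 10) {
  weeks <- as.integer(weeks)
  pg <- weekly_ponderal_series(weeks, weights)
  out <- data.frame(week = weeks,
                    pg = c(NA_real_, pg$pg)[seq_along(weeks)],
                    sudden_gain = FALSE, swollen_abdomen = FALSE,
                    diarrhea = FALSE, priapism = FALSE,
                    alert_level = "none", stringsAsFactors = FALSE)
  if (length(weeks) >= 2L)
    out$pg <- c(NA_real_, pg$pg)
  out$sudden_gain <- !is.na(out$pg) & out$pg >= watch_pg
  if (!is.null(signs) && nrow(signs)) {
    for (col in c("swollen_abdomen", "diarrhea", "priapism")) {
      if (!col %in% names(signs)) next
      hit <- as.integer(signs$week[which(as.logical(signs[[col]]))])
      out[[col]] <- out$week %in% hit
    }
  }
  # cumulative history: a flag raised at week w is active from w on
  seen_gain <- cumsum(out$sudden_gain) > 0
  seen <- cbind(abdomen = cumsum(out$swollen_abdomen) > 0,
                diarrhea = cumsum(out$diarrhea) > 0,
                priapism = cumsum(out$priapism) > 0)
  n_signs <- rowSums(seen) + seen_gain
  any_sign <- rowSums(seen) > 0
  high <- (!is.na(out$pg) & out$pg > high_pg) |
    (seen_gain & any_sign) | n_signs >= 2
  high <- cumsum(high) > 0
  watch <- seen_gain | any_sign
  out$alert_level <- ifelse(high, "high", ifelse(watch, "watch", "none"))
  out
}

#' Plausibility-gate thermography readings
#'
#' Surface temperatures outside a plausible physiological band are treated
#' as sensor artifacts (reflections, mis-aimed spot) and dropped with a
#' warning rather than propagated.
#'
#' @param readings Data frame with at least a `celsius` column.
#' @param lower,upper Band in degrees Celsius (default 20-45).
#' @return The readings inside the band.
#' @export
filter_temperatures <- function(readings, lower = 20, upper = 45) {
  bad <- !is.finite(readings$celsius) |
    readings$celsius < lower | readings$celsius > upper
  if (any(bad))
    warning(sum(bad), " temperature reading(s) outside [", lower, ", ",
            upper, "] degrees C dropped as implausible")
  readings[!bad, , drop = FALSE]
}

#' Per-arm temperature summary
#'
#' Arithmetic mean and sample SD of thermography readings per experimental
#' arm at one measurement site. A single reading yields SD 0 with a warning
#' (rather than NA), so small fixtures summarise cleanly.
#'
#' @param readings Data frame with columns `animal_id`, `week`, `site`
#'   (`"back"` or `"abdomen"`), `celsius`.
#' @param arms Named character vector mapping `animal_id` to arm label, or a
#'   data frame with columns `animal_id`, `arm`.
#' @param site Which site to summarise.
#' @return Data frame with columns `arm`, `site`, `mean`, `sd`, `n`.
#' @export
group_temperature_summary <- function(readings, arms, site = "abdomen") {
  site <- match.arg(site, c("back", "abdomen"))
  if (is.data.frame(arms))
    arms <- setNames(as.character(arms$arm), arms$animal_id)
  r <- readings[readings$site == site, , drop = FALSE]
  r$arm <- arms[as.character(r$animal_id)]
  if (anyNA(r$arm))
    stop("readings from animal(s) with no arm label: ",
         paste(unique(r$animal_id[is.na(r$arm)]), collapse = ", "))
  if (nrow(r) == 0L)
    stop("no '", site, "' readings to summarise")
  res <- do.call(rbind, lapply(split(r$celsius, r$arm), function(v) {
    s <- if (length(v) > 1L) stats::sd(v) else {
      warning("single reading in an arm: SD reported as 0")
      0
    }
    data.frame(mean = mean(v), sd = s, n = length(v))
  }))
  data.frame(arm = rownames(res), site = site, res,
             row.names = NULL, stringsAsFactors = FALSE)
}
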