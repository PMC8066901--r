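# Independent oracles and small generators used across the suite.

# One random complete observation vector on a sheet: a score drawn
# uniformly from each parameter's available levels.
random_complete_scores <- function(sheet) {
  vapply(sheet$parameters, function(p) {
    s <- p$available_scores
    if (length(s) == 1L) s else sample(s, 1L)
  }, integer(1))
}

# Brute-force total: explicit loop over parameters, independent of assess().
brute_force_total <- function(scores) {
  tot <- 0L
  for (nm in names(scores)) tot <- tot + scores[[nm]]
  tot
}

# Product-limit survival by explicit risk-set products. Returns the step
# function as (time, surv) at distinct event times. Censored animals at a
# tied time remain in the risk set for that time (deaths first).
km_oracle <- function(time, event) {
  stopifnot(length(time) == length(event))
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    t <- ts[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

# Textbook two-sample log-rank chi-square by explicit sums over event times.
logrank_oracle <- function(time1, event1, time2, event2) {
  time <- c(time1, time2); event <- c(event1, event2)
  grp <- rep(1:2, c(length(time1), length(time2)))
  ts <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ts) {
    n <- sum(time >= t); n1 <- sum(time >= t & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(0)
  (O1 - E1)^2 / V
}

# A random small survival roster: n animals, random event/censor weeks.
random_roster <- function(n, max_week = 12) {
  data.frame(
    animal_id = sprintf("a%02d", seq_len(n)),
    arm = "X",
    week = sample.int(max_week, n, replace = TRUE),
    outcome = sample(c("spontaneous_death", "scheduled_sacrifice"), n,
                     replace = TRUE),
    stringsAsFactors = FALSE)
}

# Long-format observations for one animal-week, all 14 parameters at the
# given named scores (default all zero), one observer.
obs_frame <- function(sheet, week = 1, animal_id = "r1", scores = NULL,
                      observer = "obs1") {
  s <- setNames(rep(0L, length(sheet$parameters)), names(sheet$parameters))
  if (!is.null(scores)) s[names(scores)] <- scores
  data.frame(animal_id = animal_id, week = week,
             parameter = names(s), score = as.integer(s),
             observer_id = observer, stringsAsFactors = FALSE)
}
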