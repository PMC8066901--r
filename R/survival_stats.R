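#' Survival rate of an experimental arm
#'
#' Percentage of enrolled animals not lost to the counted event types.
#' Scheduled sacrifice is administrative censoring and never counts against
#' survival. By default only spontaneous deaths count as events, matching
#' how survival is reported for this protocol; humane euthanasia can be
#' counted as an event too via `events`.
#'
#' @param records Data frame for one arm with a column `outcome` in
#'   \{`spontaneous_death`, `humane_euthanasia`, `scheduled_sacrifice`\}.
#' @param events Outcomes counted as failures.
#' @return Percent survival (full precision; present at 1 dp).
#' @examples
#' arm <- data.frame(outcome = c(rep("scheduled_sacrifice", 6),
#'                               rep("spontaneous_death", 2)))
#' survival_rate(arm)  # 75
#' @export
survival_rate <- function(records,
                          events = c("spontaneous_death")) {
  if (is.null(records) || nrow(records) == 0L)
    stop("empty arm: no survival records")
  ok <- c("spontaneous_death", "humane_euthanasia", "scheduled_sacrifice")
  bad <- setdiff(unique(records$outcome), ok)
  if (length(bad))
    stop("unknown outcome(s): ", paste(bad, collapse = ", "))
  100 * sum(!records$outcome %in% events) / nrow(records)
}

.surv_object <- function(records, events) {
  stopifnot(all(c("week", "outcome") %in% names(records)))
  if (any(records$week <= 0))
    stop("survival times must be positive")
  survival::Surv(time = as.numeric(records$week),
                 event = as.integer(records$outcome %in% events))
}

#' Kaplan-Meier estimate for one or more arms
#'
#' Product-limit estimator of survival after the first carcinogen
#' administration. Scheduled sacrifices enter as right-censored; at tied
#' times deaths are processed before censorings (the standard convention).
#' Fitting is delegated to [survival::survfit()].
#'
#' @param records Data frame with columns `animal_id`, `week`, `outcome`,
#'   and optionally `arm` (curves stratified by arm when present).
#' @param events Outcomes treated as events; the rest are censored.
#' @return An object of class `he_km` wrapping the `survfit` fit with a
#'   tidy step `table` (time, n.risk, n.event, n.censor, surv, per arm).
#' @export
km_estimate <- function(records, events = c("spontaneous_death")) {
  y <- .surv_object(records, events)
  if ("arm" %in% names(records) && length(unique(records$arm)) > 1L) {
    arm <- factor(records$arm)
    fit <- survival::survfit(y ~ arm)
    strata <- rep(sub("^arm=", "", names(fit$strata)), fit$strata)
  } else {
    fit <- survival::survfit(y ~ 1)
    strata <- rep(if ("arm" %in% names(records))
      as.character(records$arm[1]) else "all", length(fit$time))
  }
  tab <- data.frame(arm = strata, time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv, stringsAsFactors = FALSE)
  structure(list(fit = fit, table = tab, events = events),
            class = "he_km")
}

#' @export
print.he_km <- function(x, ...) {
  cat("<he_km> Kaplan-Meier estimate (events:",
      paste(x$events, collapse = ", "), ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
summary.he_km <- function(object, ...) summary(object$fit, ...)

#' Plot a Kaplan-Meier curve
#' @param x An `he_km`.
#' @param ... Passed to `plot.survfit`.
#' @export
plot.he_km <- function(x, ...) {
  graphics::plot(x$fit, xlab = "Weeks after first administration",
                 ylab = "Survival probability", mark.time = TRUE, ...)
  invisible(x)
}

#' Survival probability at a time point
#'
#' Step-function lookup on an `he_km` curve: S(t) at the given time (the
#' value after the last event at or before `time`).
#'
#' @param km An `he_km`.
#' @param time Time in weeks.
#' @param arm Arm label when the curve is stratified.
#' @return Survival probability in [0, 1].
#' @export
km_surv_at <- function(km, time, arm = NULL) {
  tab <- km$table
  if (!is.null(arm)) tab <- tab[tab$arm == arm, , drop = FALSE]
  tab <- tab[tab$time <= time, , drop = FALSE]
  if (nrow(tab) == 0L) return(1)
  tab$surv[which.max(tab$time)]
}

#' Log-rank comparison of two arms
#'
#' Standard log-rank chi-square test (1 df) that two survival curves are
#' equal, via [survival::survdiff()].
#'
#' @param arm_a,arm_b Data frames with `week` and `outcome` columns.
#' @param events Outcomes treated as events.
#' @return List with `statistic` (chi-square), `df`, and `p`.
#' @export
logrank_test <- function(arm_a, arm_b, events = c("spontaneous_death")) {
  if (!nrow(arm_a) || !nrow(arm_b))
    stop("both arms must be non-empty")
  df <- rbind(
    data.frame(week = arm_a$week, outcome = arm_a$outcome, g = "A"),
    data.frame(week = arm_b$week, outcome = arm_b$outcome, g = "B"))
  y <- .surv_object(df, events)
  if (all(y[, "status"] == 0)) # no events anywhere: curves identical
    return(list(statistic = 0, df = 1L, p = 1))
  sd <- survival::survdiff(y ~ g, data = data.frame(g = df$g))
  list(statistic = unname(sd$chisq), df = 1L,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Group HE-score summary
#'
#' Group mean of per-animal total HE scores -- the sum of the animals'
#' totals divided by the number of animals in the group -- with the sample
#' SD. Only totals from complete assessments should be supplied.
#'
#' @param totals Numeric vector of per-animal total scores (one per animal).
#' @param arm Optional arm label carried into the result.
#' @return Data frame with `arm`, `mean`, `sd`, `n`. Single animals get
#'   SD 0 by convention.
#' @export
group_he_score <- function(totals, arm = NA_character_) {
  if (length(totals) == 0L) stop("no scores supplied")
  if (anyNA(totals)) stop("totals contain NA; drop incomplete assessments")
  data.frame(arm = arm, mean = mean(totals),
             sd = if (length(totals) > 1L) stats::sd(totals) else 0,
             n = length(totals), stringsAsFactors = FALSE)
}

#' Compare a measurement across arms (ANOVA + post hoc)
#'
#' One-way ANOVA across arms, or two-way ANOVA (arm-type x timepoint, with
#' interaction, type-II sums of squares) when a `timepoint` factor is given.
#' Post hoc pairwise comparisons between arms use Tukey's HSD or
#' Bonferroni-adjusted pairwise t tests. Significance is declared at
#' p < `alpha` (default 0.05). If every arm is constant with identical
#' values, the comparison is degenerate: F is reported as 0 and pairwise
#' comparisons are suppressed.
#'
#' @param values Numeric response values.
#' @param arm Arm label per value (>= 2 arms, >= 2 values each).
#' @param timepoint Optional second factor for a two-way layout.
#' @param posthoc `"tukey"` or `"bonferroni"`.
#' @param alpha Significance level.
#' @return List of class `he_anova`: `anova` (data frame of terms, F, p),
#'   `posthoc` (pairwise table or NULL), `method`, `degenerate`.
#' @export
compare_groups <- function(values, arm, timepoint = NULL,
                           posthoc = c("tukey", "bonferroni"),
                           alpha = 0.05) {
  posthoc <- match.arg(posthoc)
  arm <- factor(arm)
  if (nlevels(arm) < 2L) stop("need at least two arms")
  if (any(table(arm) < 2L)) stop("need >= 2 values per arm")
  dat <- data.frame(y = as.numeric(values), arm = arm)
  degenerate <- stats::var(dat$y) == 0
  if (degenerate) {
    tab <- data.frame(term = "arm", F = 0, p = 1)
    return(structure(list(anova = tab, posthoc = NULL, method = posthoc,
                          degenerate = TRUE, alpha = alpha),
                     class = "he_anova"))
  }
  if (is.null(timepoint)) {
    fit <- stats::aov(y ~ arm, data = dat)
    a <- summary(fit)[[1]]
    tab <- data.frame(term = trimws(rownames(a)), F = a[["F value"]],
                      p = a[["Pr(>F)"]])
  } else {
    dat$timepoint <- factor(timepoint)
    fit <- stats::aov(y ~ arm * timepoint, data = dat)
    a <- car::Anova(fit, type = 2)
    tab <- data.frame(term = trimws(rownames(a)), F = a[["F value"]],
                      p = a[["Pr(>F)"]])
  }
  tab <- tab[!is.na(tab$F), , drop = FALSE]
  ph <- if (posthoc == "tukey") {
    tk <- stats::TukeyHSD(fit, which = "arm")$arm
    data.frame(pair = rownames(tk), diff = tk[, "diff"],
               p_adj = tk[, "p adj"],
               significant = tk[, "p adj"] < alpha,
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    pt <- stats::pairwise.t.test(dat$y, dat$arm,
                                 p.adjust.method = "bonferroni")$p.value
    pairs <- which(!is.na(pt), arr.ind = TRUE)
    data.frame(pair = paste(rownames(pt)[pairs[, 1]],
                            colnames(pt)[pairs[, 2]], sep = "-"),
               diff = NA_real_, p_adj = pt[pairs],
               significant = pt[pairs] < alpha,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(anova = tab, posthoc = ph, method = posthoc,
                 degenerate = FALSE, alpha = alpha),
            class = "he_anova")
}

#' @export
print.he_anova <- function(x, ...) {
  cat("<he_anova>", if (x$degenerate) "(degenerate: constant response)",
      "\n")
  print(x$anova, row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat("post hoc (", x$method, "):\n", sep = "")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
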