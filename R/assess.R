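#' Merge independent observer scores for one animal-week
#'
#' Monitoring is performed by several observers scoring the same animal
#' independently. Scores are merged per parameter by taking the maximum
#' across observers: the welfare-conservative rule, so an animal is never
#' under-scored because one observer missed a sign. Parameters nobody scored
#' are left missing (`NA`).
#'
#' The merge is idempotent and order-invariant.
#'
#' @param observations Data frame with columns `parameter`, `score`, and
#'   optionally `observer_id`, all for a single animal-week.
#' @param sheet The active `he_sheet`; observations must name its parameters.
#' @return Named integer vector over all sheet parameters (NA = unobserved).
#' @examples
#' obs <- data.frame(parameter = rep("Stool appearance", 3),
#'                   score = c(1, 0, 1),
#'                   observer_id = c("A", "B", "C"))
#' merge_observers(obs, sheet_table1())[["Stool appearance"]]  # 1
#' @export
merge_observers <- function(observations, sheet) {
  stopifnot(inherits(sheet, "he_sheet"))
  out <- rep(NA_integer_, length(sheet$parameters))
  names(out) <- names(sheet$parameters)
  if (is.null(observations) || nrow(observations) == 0L)
    return(out)
  if (!all(c("parameter", "score") %in% names(observations)))
    stop("observations need 'parameter' and 'score' columns")
  unknown <- setdiff(unique(observations$parameter), names(out))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  mx <- tapply(as.integer(observations$score), observations$parameter, max)
  out[names(mx)] <- as.integer(mx)
  out
}

#' Assess one animal-week against a score sheet
#'
#' Computes the animal's total HE score (when every parameter was scored)
#' and the removal decision. The decision is `"remove_euthanize"` when the
#' total reaches the sheet's critical limit, or when any single parameter
#' sits at one of its euthanasia-trigger levels -- triggers are evaluated
#' even on incomplete records, so a sick animal is never missed because a
#' record is partial. An incomplete record has `total = NA` and is excluded
#' from group means.
#'
#' @param sheet An `he_sheet`.
#' @param scores Named integer vector of per-parameter scores (e.g. from
#'   [merge_observers()]); `NA` = unobserved. Scores must be available
#'   levels of their parameter.
#' @param animal_id,week Identifiers carried into the result.
#' @return An object of class `he_assessment`: list with `animal_id`,
#'   `week`, `scores`, `total` (NA if incomplete), `complete`,
#'   `triggered_parameters`, `decision`.
#' @examples
#' sh <- sheet_table1()
#' s <- setNames(rep(0L, 14), names(sh$parameters))
#' s["Mental status"] <- 3L
#' assess(sh, s, "r1", 5)$decision  # "remove_euthanize" (stupor/coma)
#' @export
assess <- function(sheet, scores, animal_id = NA_character_,
                   week = NA_integer_) {
  stopifnot(inherits(sheet, "he_sheet"))
  full <- rep(NA_integer_, length(sheet$parameters))
  names(full) <- names(sheet$parameters)
  if (length(scores)) {
    if (is.null(names(scores)))
      stop("'scores' must be named by parameter")
    unknown <- setdiff(names(scores), names(full))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    full[names(scores)] <- as.integer(scores)
  }
  triggered <- character()
  for (nm in names(full)) {
    s <- full[[nm]]
    if (is.na(s)) next
    p <- sheet$parameters[[nm]]
    if (!s %in% p$available_scores)
      stop("score ", s, " is not an available level of parameter '",
           nm, "' (available: ",
           paste(p$available_scores, collapse = ","), ")")
    if (s %in% p$euthanasia_scores)
      triggered <- c(triggered, nm)
  }
  complete <- !anyNA(full)
  total <- if (complete) sum(full) else NA_integer_
  decision <- if ((complete && total >= sheet$critical_limit) ||
                  length(triggered))
    "remove_euthanize" else "continue"
  structure(
    list(animal_id = animal_id, week = as.integer(week),
         scores = full, total = total, complete = complete,
         triggered_parameters = triggered, decision = decision),
    class = "he_assessment")
}

#' @export
print.he_assessment <- function(x, ...) {
  cat(sprintf("<he_assessment> animal %s, week %s: total %s (%s), decision %s\n",
              x$animal_id, x$week,
              ifelse(is.na(x$total), "NA", x$total),
              ifelse(x$complete, "complete", "incomplete"),
              x$decision))
  if (length(x$triggered_parameters))
    cat("  triggered:", paste(x$triggered_parameters, collapse = "; "), "\n")
  nz <- x$scores[!is.na(x$scores) & x$scores > 0]
  if (length(nz))
    cat("  non-zero:",
        paste(sprintf("%s=%d", names(nz), nz), collapse = "; "), "\n")
  invisible(x)
}

#' Score an animal's full observation timeline
#'
#' Runs [merge_observers()] and [assess()] week by week over one animal's
#' long-format observations and reports the endpoint week: the first week
#' whose decision is `remove_euthanize` (either by total critical limit or a
#' single-parameter trigger), or `NA` if the animal never reaches it.
#'
#' @param sheet An `he_sheet`.
#' @param observations Long data frame for one animal: columns `animal_id`,
#'   `week`, `parameter`, `score`, optional `observer_id`.
#' @return An object of class `he_timeline`: list of `he_assessment`s in
#'   week order, with attributes `animal_id` and `endpoint_week`.
#' @export
score_timeline <- function(sheet, observations) {
  stopifnot(inherits(sheet, "he_sheet"),
            all(c("animal_id", "week", "parameter", "score") %in%
                names(observations)))
  ids <- unique(observations$animal_id)
  if (length(ids) != 1L)
    stop("score_timeline expects observations for exactly one animal, got ",
         length(ids))
  weeks <- sort(unique(as.integer(observations$week)))
  out <- vector("list", length(weeks))
  for (i in seq_along(weeks)) {
    wk <- observations[observations$week == weeks[i], , drop = FALSE]
    if (anyDuplicated(wk[c("parameter", if ("observer_id" %in% names(wk))
                           "observer_id")]))
      stop("duplicate observation for animal ", ids, " in week ", weeks[i])
    out[[i]] <- assess(sheet, merge_observers(wk, sheet), ids, weeks[i])
  }
  dec <- vapply(out, `[[`, character(1), "decision")
  endpoint <- if (any(dec == "remove_euthanize"))
    weeks[which(dec == "remove_euthanize")[1]] else NA_integer_
  structure(out, class = "he_timeline", animal_id = ids,
            endpoint_week = endpoint)
}

#' @export
print.he_timeline <- function(x, ...) {
  ep <- attr(x, "endpoint_week")
  cat(sprintf("<he_timeline> animal %s: %d weeks, endpoint week %s\n",
              attr(x, "animal_id"), length(x),
              ifelse(is.na(ep), "none", ep)))
  for (a in x)
    cat(sprintf("  week %2d: total %2s  %s\n", a$week,
                ifelse(is.na(a$total), "NA", a$total), a$decision))
  invisible(x)
}

#' Endpoint week of a scored timeline
#' @param timeline An `he_timeline`.
#' @return Integer week or `NA`.
#' @export
endpoint_week <- function(timeline) {
  stopifnot(inherits(timeline, "he_timeline"))
  attr(timeline, "endpoint_week")
}
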