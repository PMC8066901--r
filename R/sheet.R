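#' Define a score-sheet parameter
#'
#' A parameter is one row of a humane-endpoint (HE) score sheet: an ordinal
#' welfare item scored on a subset of \{0, 1, 2, 3\}, with a text descriptor
#' per available level and an optional set of levels that mandate euthanasia
#' on their own, regardless of the animal's total score.
#'
#' Level 0 must always be available: every parameter has a "Normal"/absent
#' state. Levels without a descriptor (the sheet's "---" cells) are simply
#' unavailable, not zero.
#'
#' @param name Parameter name (unique within a sheet).
#' @param category One of `"general_appearance"`, `"behavior"`,
#'   `"clinical_signs"`.
#' @param levels Named character vector of descriptors; names are the
#'   available scores (`"0"`..`"3"`). Must include `"0"`.
#' @param euthanasia_scores Integer vector of levels that trigger mandatory
#'   euthanasia (subset of the available scores). Default none.
#' @return An object of class `he_parameter`.
#' @examples
#' he_parameter("Convulsions", "clinical_signs",
#'              c("0" = "Absence", "3" = "Presence"))
#' @export
he_parameter <- function(name, category, levels, euthanasia_scores = integer()) {
  category <- match.arg(category,
                        c("general_appearance", "behavior", "clinical_signs"))
  if (!is.character(levels) || is.null(names(levels)) || length(levels) == 0)
    stop("'levels' must be a named character vector of descriptors")
  scores <- suppressWarnings(as.integer(names(levels)))
  if (anyNA(scores) || any(scores < 0L | scores > 3L))
    stop("level names must be integer scores in 0..3")
  if (anyDuplicated(scores))
    stop("duplicate score levels for parameter '", name, "'")
  if (!0L %in% scores)
    stop("parameter '", name, "' must have a level 0 (normal/absent)")
  if (any(!nzchar(levels)))
    stop("every available level of '", name, "' needs a non-empty descriptor")
  euthanasia_scores <- as.integer(euthanasia_scores)
  if (!all(euthanasia_scores %in% scores))
    stop("euthanasia scores of '", name,
         "' must be a subset of its available scores")
  ord <- order(scores)
  structure(
    list(name = as.character(name),
         category = category,
         levels = levels[ord],
         available_scores = scores[ord],
         euthanasia_scores = sort(euthanasia_scores)),
    class = "he_parameter")
}

#' Assemble a humane-endpoint score sheet
#'
#' @param sheet_id Identifier stored with the sheet (e.g. `"table1"`).
#' @param parameters List of [he_parameter()] objects; order is kept.
#' @param critical_limit Total HE score at or above which an animal must be
#'   removed from the protocol and euthanised. Must be >= 1.
#' @return An object of class `he_sheet`.
#' @seealso [sheet_table1()], [sheet_refined()], [assess()]
#' @export
he_sheet <- function(sheet_id, parameters, critical_limit) {
  if (!length(parameters) ||
      !all(vapply(parameters, inherits, logical(1), "he_parameter")))
    stop("'parameters' must be a non-empty list of he_parameter objects")
  nms <- vapply(parameters, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate parameter names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  critical_limit <- as.integer(critical_limit)
  if (length(critical_limit) != 1L || is.na(critical_limit) ||
      critical_limit < 1L)
    stop("'critical_limit' must be a single integer >= 1")
  names(parameters) <- nms
  structure(
    list(sheet_id = as.character(sheet_id),
         parameters = parameters,
         critical_limit = critical_limit),
    class = "he_sheet")
}

#' Maximum attainable total score of a sheet
#'
#' Sum over parameters of each parameter's highest available level.
#'
#' @param sheet An `he_sheet`.
#' @return Integer.
#' @export
max_total <- function(sheet) {
  stopifnot(inherits(sheet, "he_sheet"))
  sum(vapply(sheet$parameters,
             function(p) max(p$available_scores), integer(1)))
}

#' @export
print.he_parameter <- function(x, ...) {
  eu <- if (length(x$euthanasia_scores))
    paste0(" [euthanasia at ", paste(x$euthanasia_scores, collapse = ","), "]")
  else ""
  cat(sprintf("<he_parameter> %s (%s)%s\n", x$name, x$category, eu))
  for (i in seq_along(x$available_scores))
    cat(sprintf("  %d: %s\n", x$available_scores[i], x$levels[[i]]))
  invisible(x)
}

#' @export
print.he_sheet <- function(x, ...) {
  cat(sprintf("<he_sheet> '%s': %d parameters, critical limit %d, max total %d\n",
              x$sheet_id, length(x$parameters), x$critical_limit,
              max_total(x)))
  for (p in x$parameters) {
    eu <- if (length(p$euthanasia_scores))
      paste0("  (euthanasia at ",
             paste(p$euthanasia_scores, collapse = ","), ")")
    else ""
    cat(sprintf("  %-45s levels {%s}%s\n", p$name,
                paste(p$available_scores, collapse = ","), eu))
  }
  invisible(x)
}

#' @export
summary.he_sheet <- function(object, ...) {
  data.frame(
    parameter = vapply(object$parameters, `[[`, character(1), "name"),
    category = vapply(object$parameters, `[[`, character(1), "category"),
    max_score = vapply(object$parameters,
                       function(p) max(p$available_scores), integer(1)),
    n_levels = vapply(object$parameters,
                      function(p) length(p$available_scores), integer(1)),
    euthanasia_levels = vapply(object$parameters, function(p)
      paste(p$euthanasia_scores, collapse = ","), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' The 14-parameter score sheet for DMH-induced colorectal carcinogenesis
#'
#' The default monitoring rubric for rats under chemical colorectal-cancer
#' induction, adapted from the CCAC cancer-model guidelines: 14 ordinal
#' parameters in three categories (general appearance / state of
#' consciousness, behaviour, clinical signs). Four levels mandate euthanasia
#' on their own (body-weight loss >20%, stupor/coma, necrosis of induced skin
#' lesions, inflammatory exudate); a total HE score of four mandates removal
#' regardless of which parameters contribute.
#'
#' Body-weight levels are assigned from the ponderal gain since enrolment,
#' computed with [ponderal_gain()].
#'
#' @return An `he_sheet` with 14 parameters, `critical_limit = 4` and a
#'   maximum total of 36.
#' @examples
#' sh <- sheet_table1()
#' max_total(sh)  # 36
#' @export
sheet_table1 <- function() {
  p <- list(
    he_parameter("Body condition", "general_appearance",
      c("0" = "Good", "1" = "Altered body condition", "2" = "Emaciated")),
    he_parameter("Body weight", "general_appearance",
      c("0" = "Normal", "1" = "Loss of <10%", "2" = "Loss of 10-20%",
        "3" = "Loss of >20% (euthanasia)"),
      euthanasia_scores = 3L),
    he_parameter("Posture", "general_appearance",
      c("0" = "Normal posture",
        "1" = "Posture changes (orthopnea posture)")),
    he_parameter("Hair appearance and grooming", "general_appearance",
      c("0" = "Normal", "1" = "Lack of grooming",
        "2" = "Bad-looking hair and chromodachryorrhea",
        "3" = "Chromodachryorrhea and hair with a very bad appearance")),
    he_parameter("Mucous color", "general_appearance",
      c("0" = "Normal", "1" = "Slightly anemic", "2" = "Moderately anemic",
        "3" = "Severe anemia")),
    he_parameter("Eyes, ears, and whiskers", "general_appearance",
      c("0" = "Normal",
        "1" = "Partially closed eyes, droopy ears, and forward whiskers",
        "2" = paste("Completely closed eyes, droopy and curved ears,",
                    "and forward and bunched whiskers"))),
    he_parameter("Mental status", "general_appearance",
      c("0" = "Normal", "1" = "Lethargic",
        "3" = "Stupor/coma (euthanasia)"),
      euthanasia_scores = 3L),
    he_parameter("Response to external stimuli", "behavior",
      c("0" = "Normal", "1" = "Moderate response",
        "2" = "Moderate response with vocalization",
        "3" = "Violent response")),
    he_parameter("Hydration status", "clinical_signs",
      c("0" = "Normal", "1" = "Abnormal skin pinch test (>2 s)")),
    he_parameter("Stool appearance", "clinical_signs",
      c("0" = "Normal", "1" = "Diarrhea", "2" = "Black (digested blood)",
        "3" = "Bloody stool")),
    he_parameter("Convulsions", "clinical_signs",
      c("0" = "Absence", "3" = "Presence")),
    he_parameter("Dimension of damage caused by injections", "clinical_signs",
      c("0" = "Without skin lesion", "1" = "Lesion with diameter <=8 mm",
        "2" = "Lesion with diameters of >=9 and <=14 mm",
        "3" = "Lesion with diameters of >=15 mm")),
    he_parameter("Macroscopic appearance of induced skin lesions",
      "clinical_signs",
      c("0" = "Absence of necrosis",
        "3" = "Presence of necrosis (euthanasia)"),
      euthanasia_scores = 3L),
    he_parameter("Infection of induced skin lesions", "clinical_signs",
      c("0" = "Absence of infection",
        "3" = "Presence of inflammatory exudate (euthanasia)"),
      euthanasia_scores = 3L)
  )
  he_sheet("table1", p, critical_limit = 4L)
}

#' Refined score sheet with thermography, priapism and sudden weight gain
#'
#' Extends [sheet_table1()] with the three parameters identified as early
#' warnings of the lethal enteritis prodrome in this model: elevation of the
#' abdominal surface temperature over concurrent controls, priapism, and a
#' sudden weekly body-weight gain. Level definitions:
#'
#' * Abdominal temperature elevation: 0 = within 1 SD of the concurrent
#'   control mean, 1 = 1-2 SD above, 2 = more than 2 SD above.
#' * Priapism: 0 = absent, 2 = present.
#' * Sudden body-weight gain: 0 = weekly ponderal gain below 6%,
#'   1 = 6-10%, 2 = above 10%.
#'
#' The thresholds (6% and 10% weekly gain; SD bands on temperature) mirror
#' the magnitudes observed in animals that later died, and are configurable
#' through [detect_prodrome()] when used for alerting rather than scoring.
#' The critical limit is kept at 4, matching the base sheet.
#'
#' @return An `he_sheet` with 17 parameters.
#' @export
sheet_refined <- function() {
  base <- sheet_table1()
  extra <- list(
    he_parameter("Abdominal temperature elevation", "clinical_signs",
      c("0" = "Within 1 SD of concurrent control mean",
        "1" = "1-2 SD above concurrent control mean",
        "2" = ">2 SD above concurrent control mean")),
    he_parameter("Priapism", "clinical_signs",
      c("0" = "Absent", "2" = "Present")),
    he_parameter("Sudden body weight gain", "clinical_signs",
      c("0" = "Weekly ponderal gain <6%",
        "1" = "Weekly ponderal gain 6-10%",
        "2" = "Weekly ponderal gain >10%"))
  )
  he_sheet("refined", c(unname(base$parameters), extra),
           critical_limit = base$critical_limit)
}

#' Serialise a score sheet to JSON
#'
#' The JSON layout is declarative and diffable: one object per parameter with
#' its category, available levels (score -> descriptor), and euthanasia
#' levels, plus the sheet id and critical limit. [read_sheet_json()] inverts
#' it exactly.
#'
#' @param sheet An `he_sheet`.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_sheet_json <- function(sheet, path) {
  stopifnot(inherits(sheet, "he_sheet"))
  obj <- list(
    sheet_id = sheet$sheet_id,
    critical_limit = sheet$critical_limit,
    parameters = lapply(unname(sheet$parameters), function(p) list(
      name = p$name,
      category = p$category,
      levels = as.list(p$levels),
      euthanasia_scores = p$euthanasia_scores))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a score sheet from JSON
#'
#' @param path File written by [write_sheet_json()] (or hand-authored in the
#'   same layout).
#' @return An `he_sheet`.
#' @export
read_sheet_json <- function(path) {
  obj <- jsonlite::read_json(path)
  params <- lapply(obj$parameters, function(p)
    he_parameter(p$name, p$category,
                 unlist(p$levels),
                 euthanasia_scores = unlist(p$euthanasia_scores)))
  he_sheet(obj$sheet_id, params, obj$critical_limit)
}
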