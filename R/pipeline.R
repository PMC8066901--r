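#' Pipeline run configuration
#'
#' Exactly one data source: either `simulate = TRUE` (a cohort is generated
#' from `sim` with `seed`) or a named list/vector of CSV `paths` as written
#' by [write_cohort_csv()] (at minimum `events`; optionally `animals`,
#' `weights`, `observations`, `signs`, `temperatures`).
#'
#' @param simulate Generate the cohort instead of reading files.
#' @param paths Named paths to input CSVs (when `simulate = FALSE`).
#' @param sheet `"table1"`, `"refined"`, a path to a sheet JSON, or an
#'   `he_sheet`.
#' @param seed Root seed for simulation.
#' @param sim An [sim_config()] used when simulating.
#' @param watch_pg,high_pg Prodrome detector thresholds (percent weekly
#'   ponderal gain).
#' @param events Outcomes counted as failures in survival summaries.
#' @param out_dir Optional directory; when set, [run_pipeline()] writes
#'   `report.json` and the per-table CSVs there.
#' @return A validated list of class `he_run_config`.
#' @export
run_config <- function(simulate = TRUE, paths = NULL, sheet = "table1",
                       seed = 1L, sim = sim_config(),
                       watch_pg = 6, high_pg = 10,
                       events = "spontaneous_death", out_dir = NULL) {
  if (simulate == !is.null(paths))
    stop("exactly one data source: simulate = TRUE xor 'paths'")
  if (is.character(sheet) && length(sheet) == 1L) {
    sheet <- switch(sheet,
                    table1 = sheet_table1(),
                    refined = sheet_refined(),
                    read_sheet_json(sheet))
  }
  stopifnot(inherits(sheet, "he_sheet"), inherits(sim, "he_sim_config"))
  structure(list(simulate = simulate, paths = paths, sheet = sheet,
                 seed = as.integer(seed), sim = sim, watch_pg = watch_pg,
                 high_pg = high_pg, events = events, out_dir = out_dir),
            class = "he_run_config")
}

#' Read cohort tables from CSV files
#'
#' @param paths Named character vector/list of file paths (names as in
#'   [write_cohort_csv()]), or a directory containing the standard files.
#' @return List of data frames.
#' @export
read_cohort_csv <- function(paths) {
  if (length(paths) == 1L && is.null(names(paths)) && dir.exists(paths)) {
    fls <- list.files(paths, pattern = "\\.csv$", full.names = TRUE)
    paths <- stats::setNames(fls, sub("\\.csv$", "", basename(fls)))
  }
  missing <- !file.exists(unlist(paths))
  if (any(missing))
    stop("input file(s) not found: ",
         paste(unlist(paths)[missing], collapse = ", "))
  lapply(as.list(paths), utils::read.csv, stringsAsFactors = FALSE)
}

#' Validate cohort input tables
#'
#' Schema, week-monotonicity and cross-table referential checks, split into
#' fatal errors (unknown animal ids, score levels unavailable on the active
#' sheet, missing required columns) and warnings (implausible temperature
#' readings, which are dropped downstream).
#'
#' @param tables List of data frames (`events` required; `animals`,
#'   `weights`, `observations`, `temperatures` checked when present).
#' @param sheet The active `he_sheet`.
#' @return List of class `he_validation`: `errors`, `warnings`, `ok`.
#' @export
validate_inputs <- function(tables, sheet = sheet_table1()) {
  errors <- character(); warnings <- character()
  req <- function(tb, cols) {
    miss <- setdiff(cols, names(tables[[tb]]))
    if (length(miss))
      errors <<- c(errors, sprintf("[schema] %s: missing column(s) %s",
                                   tb, paste(miss, collapse = ", ")))
    length(miss) == 0L
  }
  if (is.null(tables$events)) {
    errors <- c(errors, "[schema] 'events' table is required")
  } else if (req("events", c("animal_id", "arm", "week", "outcome"))) {
    bad <- setdiff(unique(tables$events$outcome),
                   c("spontaneous_death", "humane_euthanasia",
                     "scheduled_sacrifice"))
    if (length(bad))
      errors <- c(errors, paste("[events] unknown outcome(s):",
                                paste(bad, collapse = ", ")))
    if (any(tables$events$week <= 0))
      errors <- c(errors, "[events] non-positive event weeks")
  }
  roster <- if (!is.null(tables$animals)) tables$animals$animal_id
            else unique(tables$events$animal_id)
  for (tb in c("weights", "observations", "temperatures", "signs")) {
    if (is.null(tables[[tb]])) next
    if (!req(tb, c("animal_id", "week"))) next
    unknown <- setdiff(unique(tables[[tb]]$animal_id), roster)
    if (length(unknown))
      errors <- c(errors, sprintf("[%s] unknown animal_id(s): %s", tb,
                                  paste(unknown, collapse = ", ")))
  }
  if (!is.null(tables$weights) &&
      all(c("animal_id", "week", "grams") %in% names(tables$weights))) {
    for (id in unique(tables$weights$animal_id)) {
      wk <- tables$weights$week[tables$weights$animal_id == id]
      if (anyDuplicated(wk) || is.unsorted(sort(wk), strictly = TRUE))
        if (anyDuplicated(wk))
          errors <- c(errors,
                      sprintf("[weights] duplicate week for animal %s", id))
    }
    if (any(tables$weights$grams <= 0))
      errors <- c(errors, "[weights] non-positive body weights")
  }
  if (!is.null(tables$observations) &&
      all(c("parameter", "score") %in% names(tables$observations))) {
    ob <- tables$observations
    unknown <- setdiff(unique(ob$parameter), names(sheet$parameters))
    if (length(unknown))
      errors <- c(errors, paste("[observations] unknown parameter(s):",
                                paste(unknown, collapse = ", ")))
    for (p in intersect(unique(ob$parameter), names(sheet$parameters))) {
      avail <- sheet$parameters[[p]]$available_scores
      bad <- setdiff(unique(ob$score[ob$parameter == p]), avail)
      if (length(bad))
        errors <- c(errors,
                    sprintf("[observations] score %s unavailable for '%s'",
                            paste(bad, collapse = ","), p))
    }
  }
  if (!is.null(tables$temperatures) &&
      "celsius" %in% names(tables$temperatures)) {
    n_bad <- sum(tables$temperatures$celsius < 20 |
                 tables$temperatures$celsius > 45)
    if (n_bad)
      warnings <- c(warnings,
                    sprintf("[temperatures] %d implausible reading(s) will be dropped",
                            n_bad))
  }
  structure(list(errors = errors, warnings = warnings,
                 ok = length(errors) == 0L),
            class = "he_validation")
}

#' @export
print.he_validation <- function(x, ...) {
  cat("<he_validation>", if (x$ok) "OK" else "FAILED", "\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Run the full assessment pipeline
#'
#' Stages, in order: simulate or load the cohort; validate inputs; merge
#' observers and assess every animal-week against the active sheet; compute
#' body-metric series and prodrome alerts; survival rates, Kaplan-Meier
#' curves and the log-rank comparison of induced arms; per-arm HE-score and
#' temperature summaries with ANOVA/post hoc comparisons. Any stage failure
#' aborts with a stage-labelled error.
#'
#' @param config An [run_config()].
#' @return An object of class `he_report`: named list of result tables plus
#'   a provenance block (seed, sheet id, package version). When
#'   `config$out_dir` is set, `report.json` (and simulated cohort CSVs) are
#'   written there.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "he_run_config"))
  sheet <- config$sheet
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }

  tables <- stage("load", {
    if (config$simulate) {
      co <- simulate_cohort(config$sim, config$seed)
      unclass(co)[c("animals", "weights", "observations", "signs",
                    "temperatures", "consumption", "events", "truth")]
    } else read_cohort_csv(config$paths)
  })

  val <- stage("validate", validate_inputs(tables, sheet))
  if (!val$ok)
    stop("[validate] input validation failed:\n  ",
         paste(val$errors, collapse = "\n  "), call. = FALSE)

  # per-animal weekly assessments
  assessments <- stage("assess", {
    if (is.null(tables$observations)) NULL else {
      ids <- unique(tables$observations$animal_id)
      tl <- lapply(ids, function(id)
        score_timeline(sheet, tables$observations[
          tables$observations$animal_id == id, , drop = FALSE]))
      names(tl) <- ids
      tl
    }
  })
  score_rows <- if (!is.null(assessments)) do.call(rbind, lapply(
    assessments, function(tl) data.frame(
      animal_id = attr(tl, "animal_id"),
      week = vapply(tl, `[[`, integer(1), "week"),
      total = vapply(tl, `[[`, integer(1), "total"),
      decision = vapply(tl, `[[`, character(1), "decision"),
      stringsAsFactors = FALSE)))

  arm_of <- stats::setNames(as.character(tables$events$arm),
                            tables$events$animal_id)

  # group HE-score summaries: per-animal mean weekly total, then arm mean
  score_summary <- stage("group_scores", {
    if (is.null(score_rows)) NULL else {
      cs <- score_rows[!is.na(score_rows$total), , drop = FALSE]
      per_animal <- tapply(cs$total, cs$animal_id, mean)
      arms <- arm_of[names(per_animal)]
      do.call(rbind, lapply(sort(unique(arms)), function(a)
        group_he_score(per_animal[arms == a & !is.na(arms)], arm = a)))
    }
  })

  # prodrome alerts
  alerts <- stage("prodrome", {
    if (is.null(tables$weights)) NULL else {
      ids <- unique(tables$weights$animal_id)
      do.call(rbind, lapply(ids, function(id) {
        w <- tables$weights[tables$weights$animal_id == id, , drop = FALSE]
        w <- w[order(w$week), , drop = FALSE]
        sg <- if (!is.null(tables$signs))
          tables$signs[tables$signs$animal_id == id, , drop = FALSE]
        fl <- detect_prodrome(w$week, w$grams, sg,
                              watch_pg = config$watch_pg,
                              high_pg = config$high_pg)
        cbind(animal_id = id, fl, stringsAsFactors = FALSE)
      }))
    }
  })

  # survival
  surv <- stage("survival", {
    ev <- tables$events
    rates <- do.call(rbind, lapply(sort(unique(ev$arm)), function(a) {
      e <- ev[ev$arm == a, , drop = FALSE]
      data.frame(arm = a, n = nrow(e),
                 deaths = sum(e$outcome %in% config$events),
                 survival = survival_rate(e, events = config$events),
                 stringsAsFactors = FALSE)
    }))
    km <- km_estimate(ev, events = config$events)
    crc <- grep("^CRC", sort(unique(ev$arm)), value = TRUE)
    lr <- if (length(crc) == 2L)
      logrank_test(ev[ev$arm == crc[1], ], ev[ev$arm == crc[2], ],
                   events = config$events)
    list(rates = rates, km = km, logrank_induced = lr)
  })

  # temperatures
  temp_summary <- stage("temperature", {
    if (is.null(tables$temperatures)) NULL else {
      tmp <- suppressWarnings(filter_temperatures(tables$temperatures))
      out <- list()
      for (s in intersect(c("back", "abdomen"), unique(tmp$site)))
        out[[s]] <- group_temperature_summary(tmp, arm_of, site = s)
      cmp <- NULL
      ab <- tmp[tmp$site == "abdomen", , drop = FALSE]
      if (nrow(ab)) {
        ab$arm <- arm_of[as.character(ab$animal_id)]
        if (length(unique(ab$arm)) >= 2L && all(table(ab$arm) >= 2L))
          cmp <- compare_groups(ab$celsius, ab$arm, posthoc = "bonferroni")
      }
      list(summaries = do.call(rbind, out), abdomen_anova = cmp)
    }
  })

  report <- structure(list(
    validation = val,
    survival = surv$rates,
    km_table = surv$km$table,
    logrank_induced = surv$logrank_induced,
    score_summary = score_summary,
    scores = score_rows,
    prodrome_alerts = alerts,
    temperature = temp_summary,
    provenance = list(seed = config$seed, sheet_id = sheet$sheet_id,
                      critical_limit = sheet$critical_limit,
                      events = config$events,
                      simulated = config$simulate,
                      package_version =
                        as.character(utils::packageVersion("hescore")))),
    class = "he_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_json(report, file.path(config$out_dir, "report.json"))
    if (config$simulate)
      for (tb in names(tables))
        utils::write.csv(tables[[tb]],
                         file.path(config$out_dir, paste0(tb, ".csv")),
                         row.names = FALSE)
  }
  report
}

#' Serialise a report to JSON
#' @param report An `he_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "he_report"))
  out <- list(
    provenance = report$provenance,
    validation = list(ok = report$validation$ok,
                      warnings = report$validation$warnings),
    survival = report$survival,
    km_table = report$km_table,
    logrank_induced = report$logrank_induced,
    score_summary = report$score_summary,
    prodrome_alerts = report$prodrome_alerts,
    temperature_summary = report$temperature$summaries)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = 10, na = "null")
  invisible(path)
}

#' @export
print.he_report <- function(x, ...) {
  cat("<he_report> sheet", x$provenance$sheet_id, "| seed",
      x$provenance$seed, "\n\nSurvival by arm:\n")
  print(x$survival, row.names = FALSE)
  if (!is.null(x$logrank_induced))
    cat(sprintf("\nLog-rank (induced arms): chisq = %.3f, p = %.3f\n",
                x$logrank_induced$statistic, x$logrank_induced$p))
  if (!is.null(x$score_summary)) {
    cat("\nHE-score summary (per-animal mean weekly total):\n")
    print(x$score_summary, row.names = FALSE)
  }
  if (!is.null(x$temperature$summaries)) {
    cat("\nTemperature summary:\n")
    print(x$temperature$summaries, row.names = FALSE)
  }
  if (!is.null(x$prodrome_alerts)) {
    hi <- x$prodrome_alerts[x$prodrome_alerts$alert_level == "high", ]
    cat("\nHigh prodrome alerts:",
        length(unique(hi$animal_id)), "animal(s)\n")
  }
  invisible(x)
}
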