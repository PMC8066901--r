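#' Simulation configuration for a synthetic carcinogenesis cohort
#'
#' Bundles every knob of the cohort generator with defaults that emulate the
#' monitored trial design: four arms (two EDTA-saline control arms of 6, two
#' DMH-induced arms of 8 and 9), seven weekly intraperitoneal
#' administrations, scheduled sacrifices of arms 1 at week 11 and arms 2 at
#' week 17, a lethal enteritis prodrome striking a fraction of induced
#' animals with the ordered sign sequence sudden weight gain -> swollen
#' abdomen -> diarrhea -> priapism -> death, elevated abdominal surface
#' temperature in induced animals, and sporadic grooming lapses in all arms
#' after the first injection.
#'
#' @param arms Named integer vector of arm sizes.
#' @param sacrifice_weeks Named integer vector, scheduled sacrifice week per
#'   arm (weeks after the first administration; week 1 = first injection).
#' @param admin_weeks Weeks of carcinogen/vehicle administration.
#' @param prodrome_incidence Probability an induced animal develops the
#'   lethal prodrome (default 0.28, about 5 deaths in 17 induced animals).
#' @param lag_abdomen Mean and SD (weeks, rounded and clamped to 0..3) from
#'   sudden gain to swollen abdomen.
#' @param lag_diarrhea,lag_priapism,lag_death Integer ranges (weeks),
#'   sampled uniformly: abdomen->diarrhea, diarrhea->priapism,
#'   priapism->death.
#' @param death_window Weeks in which prodrome deaths may fall (clipped to
#'   the arm's sacrifice week).
#' @param bw_initial Range of enrolment body weights (grams).
#' @param growth_pg_control,growth_pg_induced Weekly growth expressed as
#'   ponderal gain (percent): the mean weekly gain decays geometrically
#'   from `init` toward `floor` (`mean_t = floor + (init - floor) *
#'   decay^(t-1)`) with Gaussian noise `sd`, emulating the fast juvenile
#'   growth of young Wistar rats (about 9% in the first administration
#'   week) slowing to about 2% per week by mid-protocol. The induced arms'
#'   lower floor produces the smaller final weights of carcinogen-exposed
#'   animals.
#' @param sudden_gain_pg Range (percent) of the single-week ponderal jump in
#'   prodrome animals.
#' @param temp_back Mean/SD of back surface temperature, all arms (Celsius).
#' @param temp_abdomen_control,temp_abdomen_induced Mean/SD of abdominal
#'   surface temperature for control and induced animals (readings exist
#'   only after the first swollen abdomen in the cohort).
#' @param grooming_lapse_prob Weekly probability of a lack-of-grooming
#'   observation (score 1) after the first injection, any arm.
#' @param mild_sign_prob Weekly probability of an incidental mild (score 1)
#'   finding on body condition, posture or response to stimuli.
#' @param lethargy_prob Probability a prodrome animal shows lethargy in its
#'   final weeks.
#' @param sudden_death_hazard Weekly probability of patternless sudden death
#'   in induced animals (default 0: off, so detector-sensitivity properties
#'   are exact).
#' @param food_gpd,water_gpd Mean/SD of per-animal daily food and water
#'   consumption (grams/day), used to synthesise cage repository weighings.
#' @return A validated list of class `he_sim_config`.
#' @export
sim_config <- function(arms = c(CTRL1 = 6L, CTRL2 = 6L, CRC1 = 8L, CRC2 = 9L),
                       sacrifice_weeks = c(CTRL1 = 11L, CRC1 = 11L,
                                           CTRL2 = 17L, CRC2 = 17L),
                       admin_weeks = 1:7,
                       prodrome_incidence = 0.28,
                       lag_abdomen = c(mean = 1, sd = 1),
                       lag_diarrhea = 0:2,
                       lag_priapism = 2:4,
                       lag_death = 1:3,
                       death_window = 8:17,
                       bw_initial = c(200, 250),
                       growth_pg_control = c(init = 9, floor = 2,
                                             decay = 0.75, sd = 1.5),
                       growth_pg_induced = c(init = 9, floor = 1.2,
                                             decay = 0.75, sd = 1.5),
                       sudden_gain_pg = c(6, 12),
                       temp_back = c(mean = 31.0, sd = 1.5),
                       temp_abdomen_control = c(mean = 31.05, sd = 1.83),
                       temp_abdomen_induced = c(mean = 32.76, sd = 0.69),
                       grooming_lapse_prob = 0.25,
                       mild_sign_prob = 0.02,
                       lethargy_prob = 0.5,
                       sudden_death_hazard = 0,
                       food_gpd = c(mean = 25, sd = 2),
                       water_gpd = c(mean = 35, sd = 3)) {
  cfg <- as.list(environment())
  if (any(cfg$arms < 1L)) stop("arm sizes must be >= 1")
  if (!all(names(cfg$arms) %in% names(cfg$sacrifice_weeks)))
    stop("every arm needs a sacrifice week")
  probs <- c(cfg$prodrome_incidence, cfg$grooming_lapse_prob,
             cfg$mild_sign_prob, cfg$lethargy_prob, cfg$sudden_death_hazard)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(c(cfg$lag_diarrhea, cfg$lag_priapism, cfg$lag_death) < 0))
    stop("lags must be non-negative")
  if (any(cfg$lag_death < 1)) stop("death must follow the last sign by >= 1 week")
  if (cfg$bw_initial[1] <= 0 || diff(cfg$bw_initial) < 0)
    stop("bw_initial must be a positive, non-decreasing range")
  if (cfg$sudden_gain_pg[1] <= 0 || cfg$sudden_gain_pg[2] >= 100)
    stop("sudden_gain_pg must lie in (0, 100)")
  for (gp in list(cfg$growth_pg_control, cfg$growth_pg_induced)) {
    if (!all(c("init", "floor", "decay", "sd") %in% names(gp)))
      stop("growth parameters need init, floor, decay and sd")
    if (gp["decay"] <= 0 || gp["decay"] > 1 || gp["sd"] < 0)
      stop("growth decay must lie in (0, 1] and sd must be >= 0")
  }
  structure(cfg, class = "he_sim_config")
}

#' @export
print.he_sim_config <- function(x, ...) {
  cat("<he_sim_config>\n")
  cat("  arms:", paste(sprintf("%s=%d", names(x$arms), x$arms),
                       collapse = ", "), "\n")
  cat("  sacrifice weeks:",
      paste(sprintf("%s@%d", names(x$sacrifice_weeks), x$sacrifice_weeks),
            collapse = ", "), "\n")
  cat(sprintf("  prodrome incidence %.2f; sudden gain %.0f-%.0f%%\n",
              x$prodrome_incidence, x$sudden_gain_pg[1], x$sudden_gain_pg[2]))
  invisible(x)
}

# Deterministic 31-bit substream seed from the root seed and a string key,
# so each animal draws from its own stream and adding an animal does not
# perturb the others.
.substream_seed <- function(root, key) {
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 131 + c) %% 2147483647
  as.integer((as.numeric(root) %% 2147483647 * 48271 + h) %% 2147483647)
}

.is_induced <- function(arm) grepl("^CRC", arm)

# Draw the prodrome event chain for one animal, working backwards from the
# death week so that every prodrome animal dies on-study.
.draw_prodrome_chain <- function(cfg, sacrifice) {
  window <- cfg$death_window[cfg$death_window <= sacrifice]
  death <- if (length(window) > 1L) sample(window, 1L) else window
  for (i in 1:25) {
    l_abd <- min(max(round(stats::rnorm(1, cfg$lag_abdomen["mean"],
                                        cfg$lag_abdomen["sd"])), 0), 3)
    l_dia <- sample(cfg$lag_diarrhea, 1L)
    l_pri <- sample(cfg$lag_priapism, 1L)
    l_dea <- sample(cfg$lag_death, 1L)
    gain <- death - (l_abd + l_dia + l_pri + l_dea)
    if (gain >= 3L) break
  }
  if (gain < 3L) { # fall back to the minimal admissible lags
    l_abd <- 0L; l_dia <- 0L
    l_pri <- min(cfg$lag_priapism); l_dea <- min(cfg$lag_death)
    gain <- death - (l_abd + l_dia + l_pri + l_dea)
  }
  list(gain = gain, abdomen = gain + l_abd, diarrhea = gain + l_abd + l_dia,
       priapism = gain + l_abd + l_dia + l_pri, death = death)
}

#' Simulate a synthetic monitoring cohort
#'
#' Generates a full longitudinal dataset with the statistical structure the
#' analysis pipeline assumes: per-animal weekly body weights, score-sheet
#' observations, clinical signs, cage consumption records, thermography
#' readings, terminal events, and a ground-truth table for evaluating the
#' prodrome detector. Deterministic given `(config, seed)`; each animal has
#' its own random substream keyed on its id.
#'
#' Prodrome animals follow the ordered sequence sudden gain (a single-week
#' multiplicative jump of 6-12% ponderal gain) -> swollen abdomen ->
#' diarrhea -> priapism -> spontaneous death, with configured lags; the
#' generated score observations are consistent with the signs (diarrhea
#' scores stool appearance 1, swollen abdomen scores body condition 1,
#' optional lethargy). All other animals survive to their arm's scheduled
#' sacrifice.
#'
#' @param config An [sim_config()] object.
#' @param seed Integer root seed.
#' @return An object of class `he_cohort`: list of data frames `animals`,
#'   `weights`, `observations`, `signs`, `temperatures`, `consumption`,
#'   `events`, `truth`, plus the `config` and `seed`.
#' @examples
#' co <- simulate_cohort(sim_config(prodrome_incidence = 0), seed = 1)
#' survival_rate(co$events[co$events$arm == "CRC1", ])  # 100
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "he_sim_config"))
  cfg <- config
  sheet <- sheet_table1()
  par_names <- names(sheet$parameters)

  animals <- do.call(rbind, lapply(names(cfg$arms), function(arm)
    data.frame(animal_id = sprintf("%s_%02d", arm, seq_len(cfg$arms[[arm]])),
               arm = arm, induced = .is_induced(arm),
               sacrifice_week = cfg$sacrifice_weeks[[arm]],
               stringsAsFactors = FALSE)))

  weights <- list(); obs <- list(); signs <- list()
  events <- list(); truth <- list()

  for (i in seq_len(nrow(animals))) {
    a <- animals[i, ]
    set.seed(.substream_seed(seed, a$animal_id))
    init_bw <- stats::runif(1, cfg$bw_initial[1], cfg$bw_initial[2])

    prodrome <- a$induced && stats::runif(1) < cfg$prodrome_incidence
    chain <- if (prodrome) .draw_prodrome_chain(cfg, a$sacrifice_week)
    last_week <- if (prodrome) chain$death else a$sacrifice_week

    # weekly weights from enrolment (week 0) to the last week on study;
    # weekly growth is a decaying ponderal gain, so a weekly PG recomputed
    # from the series equals the drawn value
    gp <- if (a$induced) cfg$growth_pg_induced else cfg$growth_pg_control
    wks <- 0:last_week
    w <- numeric(length(wks)); w[1] <- init_bw
    g_jump <- if (prodrome)
      stats::runif(1, cfg$sudden_gain_pg[1], cfg$sudden_gain_pg[2])
    for (k in 2:length(wks)) {
      if (prodrome && wks[k] == chain$gain) {
        pg <- g_jump                            # the single-week jump
      } else {
        mu <- gp["floor"] + (gp["init"] - gp["floor"]) *
          gp["decay"]^(wks[k] - 1)
        pg <- min(stats::rnorm(1, mu, gp["sd"]), 50)
      }
      w[k] <- w[k - 1] / (1 - pg / 100)
    }
    weights[[i]] <- data.frame(animal_id = a$animal_id, week = wks,
                               grams = round(w, 2),
                               stringsAsFactors = FALSE)

    ow <- 1:last_week
    sg <- data.frame(animal_id = a$animal_id, week = ow,
                     swollen_abdomen = FALSE, diarrhea = FALSE,
                     priapism = FALSE, stringsAsFactors = FALSE)
    if (prodrome) {
      sg$swollen_abdomen <- ow >= chain$abdomen
      sg$diarrhea <- ow >= chain$diarrhea
      sg$priapism <- ow >= chain$priapism
    }
    signs[[i]] <- sg

    # score-sheet observations, one row per parameter-week
    m <- matrix(0L, nrow = length(ow), ncol = length(par_names),
                dimnames = list(NULL, par_names))
    post_inj <- ow > min(cfg$admin_weeks)
    m[post_inj & stats::runif(length(ow)) < cfg$grooming_lapse_prob,
      "Hair appearance and grooming"] <- 1L
    for (p in c("Body condition", "Posture", "Response to external stimuli"))
      m[stats::runif(length(ow)) < cfg$mild_sign_prob, p] <- 1L
    if (prodrome) {
      m[ow >= chain$diarrhea, "Stool appearance"] <- 1L
      m[ow >= chain$abdomen, "Body condition"] <- 1L
      if (stats::runif(1) < cfg$lethargy_prob)
        m[ow >= chain$priapism, "Mental status"] <- 1L
    }
    obs[[i]] <- data.frame(
      animal_id = a$animal_id,
      week = rep(ow, times = length(par_names)),
      parameter = rep(par_names, each = length(ow)),
      score = as.integer(m), observer_id = "sim",
      stringsAsFactors = FALSE)

    events[[i]] <- data.frame(
      animal_id = a$animal_id, arm = a$arm,
      week = last_week,
      outcome = if (prodrome) "spontaneous_death" else "scheduled_sacrifice",
      stringsAsFactors = FALSE)

    truth[[i]] <- data.frame(
      animal_id = a$animal_id, arm = a$arm, prodrome = prodrome,
      gain_week = if (prodrome) chain$gain else NA_integer_,
      abdomen_week = if (prodrome) chain$abdomen else NA_integer_,
      diarrhea_week = if (prodrome) chain$diarrhea else NA_integer_,
      priapism_week = if (prodrome) chain$priapism else NA_integer_,
      death_week = if (prodrome) chain$death else NA_integer_,
      stringsAsFactors = FALSE)
  }

  cohort <- list(config = cfg, seed = as.integer(seed),
                 animals = animals,
                 weights = do.call(rbind, weights),
                 observations = do.call(rbind, obs),
                 signs = do.call(rbind, signs),
                 events = do.call(rbind, events),
                 truth = do.call(rbind, truth))
  cohort$temperatures <- simulate_temperatures(cfg, cohort, seed)
  cohort$consumption <- .simulate_consumption(cfg, cohort, seed)
  structure(cohort, class = "he_cohort")
}

#' Simulate thermography readings for a cohort
#'
#' Weekly Gaussian surface-temperature readings per animal. Back readings
#' run for every on-study week of every animal. Abdominal readings begin
#' only in the week the first swollen abdomen is observed anywhere in the
#' cohort (measurement of the tumour-site region starts when swelling is
#' first noticed); induced and control animals draw from their respective
#' configured distributions. If no animal ever shows a swollen abdomen, no
#' abdominal readings exist.
#'
#' @param config An `he_sim_config`.
#' @param cohort A (partial) cohort with `animals`, `signs` and `events`.
#' @param seed Root seed; the temperature substream is independent of the
#'   weight/sign substreams.
#' @return Data frame `animal_id`, `week`, `site`, `celsius`.
#' @export
simulate_temperatures <- function(config, cohort, seed = 1L) {
  cfg <- config
  sw <- cohort$signs
  gate <- if (any(sw$swollen_abdomen))
    min(sw$week[sw$swollen_abdomen]) else NA_integer_
  out <- list()
  for (i in seq_len(nrow(cohort$animals))) {
    a <- cohort$animals[i, ]
    set.seed(.substream_seed(seed, paste0("temp:", a$animal_id)))
    last_week <- cohort$events$week[cohort$events$animal_id == a$animal_id]
    ow <- 1:last_week
    back <- data.frame(animal_id = a$animal_id, week = ow, site = "back",
                       celsius = round(stats::rnorm(
                         length(ow), cfg$temp_back["mean"],
                         cfg$temp_back["sd"]), 2),
                       stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- back
    if (!is.na(gate) && last_week >= gate) {
      aw <- gate:last_week
      par <- if (a$induced) cfg$temp_abdomen_induced else
        cfg$temp_abdomen_control
      out[[length(out) + 1L]] <- data.frame(
        animal_id = a$animal_id, week = aw, site = "abdomen",
        celsius = round(stats::rnorm(length(aw), par["mean"], par["sd"]), 2),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Cage-level food/water repository weighings (cages of <= 5 within an arm).
.simulate_consumption <- function(cfg, cohort, seed) {
  out <- list()
  for (arm in names(cfg$arms)) {
    ids <- cohort$animals$animal_id[cohort$animals$arm == arm]
    cages <- split(ids, ceiling(seq_along(ids) / 5))
    for (ci in seq_along(cages)) {
      cage_id <- sprintf("%s_cage%d", arm, ci)
      set.seed(.substream_seed(seed, paste0("cons:", cage_id)))
      ends <- cohort$events$week[match(cages[[ci]], cohort$events$animal_id)]
      for (wk in 1:max(ends)) {
        n <- sum(ends >= wk)
        if (n == 0L) break
        for (kind in c("food", "water")) {
          par <- if (kind == "food") cfg$food_gpd else cfg$water_gpd
          gpd <- max(stats::rnorm(1, par["mean"], par["sd"]), 1)
          used <- gpd * n * 7
          start <- ceiling(used / 50) * 50 + 200   # plausible refill size
          out[[length(out) + 1L]] <- data.frame(
            cage_id = cage_id, arm = arm, week = wk, kind = kind,
            start_weight = start, end_weight = round(start - used, 1),
            n_animals = n, n_days = 7L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Ground truth of a simulated cohort
#'
#' Per-animal truth table (prodrome status, sign-onset weeks, death week)
#' for evaluating the prodrome detector's sensitivity and lead time.
#'
#' @param cohort An `he_cohort`.
#' @return Data frame with one row per animal.
#' @export
ground_truth <- function(cohort) {
  stopifnot(inherits(cohort, "he_cohort"))
  cohort$truth
}

#' @export
print.he_cohort <- function(x, ...) {
  tr <- x$truth
  cat(sprintf("<he_cohort> seed %d: %d animals in %d arms, %d prodrome deaths\n",
              x$seed, nrow(x$animals), length(unique(x$animals$arm)),
              sum(tr$prodrome)))
  print(table(arm = x$events$arm, outcome = x$events$outcome))
  invisible(x)
}

#' @export
summary.he_cohort <- function(object, ...) {
  ev <- object$events
  do.call(rbind, lapply(split(ev, ev$arm), function(e)
    data.frame(arm = e$arm[1], n = nrow(e),
               deaths = sum(e$outcome == "spontaneous_death"),
               survival = survival_rate(e), row.names = NULL)))
}

#' Write a cohort to CSV files
#'
#' One CSV per table (`animals`, `weights`, `observations`, `signs`,
#' `temperatures`, `consumption`, `events`, `truth`) plus a JSON run
#' manifest echoing the seed and file paths. Output is byte-stable for a
#' fixed `(config, seed)`.
#'
#' @param cohort An `he_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "he_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("animals", "weights", "observations", "signs",
              "temperatures", "consumption", "events", "truth")
  paths <- character()
  for (tb in tables) {
    p <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(cohort[[tb]], p, row.names = FALSE)
    paths[tb] <- p
  }
  manifest <- list(seed = cohort$seed, files = as.list(paths),
                   arms = as.list(cohort$config$arms))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Read a simulation configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [sim_config()];
#' omitted keys keep their defaults.
#'
#' @param path YAML file.
#' @return An `he_sim_config`.
#' @export
read_sim_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  do.call(sim_config, raw)
}
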