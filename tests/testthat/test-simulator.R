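test_that("simulation is deterministic and byte-stable given (config, seed)", {
  cfg <- sim_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort_csv(simulate_cohort(cfg, seed = 9), d1)
  write_cohort_csv(simulate_cohort(cfg, seed = 9), d2)
  for (f in list.files(d1, pattern = "csv$"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # a different seed gives a different cohort
  co3 <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(co3$weights,
                         simulate_cohort(cfg, seed = 9)$weights))
})

test_that("zero prodrome incidence yields full survival everywhere", {
  co <- simulate_cohort(sim_config(prodrome_incidence = 0), seed = 3)
  expect_true(all(co$events$outcome == "scheduled_sacrifice"))
  for (a in unique(co$events$arm))
    expect_equal(survival_rate(co$events[co$events$arm == a, ]), 100)
  expect_equal(sum(ground_truth(co)$prodrome), 0)
  # and no induced-phase abdomen gate is ever opened without swelling
  expect_false("abdomen" %in% co$temperatures$site)
})

test_that("prodrome events keep the ordered sign sequence and stop records", {
  for (seed in c(2, 7, 13, 29)) {
    co <- simulate_cohort(sim_config(prodrome_incidence = 0.5), seed = seed)
    tr <- ground_truth(co)
    pr <- tr[tr$prodrome, ]
    expect_gt(nrow(pr), 0)
    expect_true(all(pr$gain_week <= pr$abdomen_week))
    expect_true(all(pr$abdomen_week <= pr$diarrhea_week))
    expect_true(all(pr$diarrhea_week <= pr$priapism_week))
    expect_true(all(pr$priapism_week < pr$death_week))
    sac <- co$config$sacrifice_weeks[pr$arm]
    expect_true(all(pr$death_week <= sac))
    # no records after death or sacrifice
    last <- setNames(co$events$week, co$events$animal_id)
    for (tb in c("weights", "observations", "signs", "temperatures"))
      expect_true(all(co[[tb]]$week <= last[co[[tb]]$animal_id]),
                  label = tb)
    # only induced animals die
    expect_true(all(grepl("^CRC", pr$arm)))
  }
})

test_that("generated observations are consistent with the signs", {
  co <- simulate_cohort(sim_config(prodrome_incidence = 1), seed = 5)
  ob <- co$observations
  tr <- ground_truth(co)
  for (i in which(tr$prodrome)) {
    id <- tr$animal_id[i]
    stool <- ob[ob$animal_id == id & ob$parameter == "Stool appearance", ]
    expect_true(all(stool$score[stool$week >= tr$diarrhea_week[i]] >= 1L))
    bc <- ob[ob$animal_id == id & ob$parameter == "Body condition", ]
    expect_true(all(bc$score[bc$week >= tr$abdomen_week[i]] >= 1L))
  }
  # scores are valid levels of the default sheet
  sheet <- sheet_table1()
  for (p in unique(ob$parameter))
    expect_true(all(ob$score[ob$parameter == p] %in%
                    sheet$parameters[[p]]$available_scores))
})

test_that("per-animal substreams are stable when an arm grows", {
  small <- simulate_cohort(sim_config(), seed = 4)
  grown <- simulate_cohort(sim_config(
    arms = c(CTRL1 = 6L, CTRL2 = 6L, CRC1 = 8L, CRC2 = 12L)), seed = 4)
  for (id in c("CTRL1_01", "CRC1_05", "CRC2_03"))
    expect_identical(small$weights[small$weights$animal_id == id, ],
                     grown$weights[grown$weights$animal_id == id, ])
})

test_that("temperature generation recovers its configured parameters", {
  cfg <- sim_config(prodrome_incidence = 0.6)
  # SD 0 collapses readings onto the configured means
  cfg0 <- sim_config(prodrome_incidence = 0.6,
                     temp_back = c(mean = 31, sd = 0),
                     temp_abdomen_control = c(mean = 31.05, sd = 0),
                     temp_abdomen_induced = c(mean = 32.76, sd = 0))
  co0 <- simulate_cohort(cfg0, seed = 8)
  tm <- co0$temperatures
  expect_true(all(tm$celsius[tm$site == "back"] == 31))
  ind <- co0$animals$animal_id[co0$animals$induced]
  ab <- tm[tm$site == "abdomen", ]
  expect_true(all(ab$celsius[ab$animal_id %in% ind] == 32.76))
  expect_true(all(ab$celsius[!ab$animal_id %in% ind] == 31.05))
  # abdomen readings only exist from the first swelling onward
  gate <- min(co0$signs$week[co0$signs$swollen_abdomen])
  expect_true(all(ab$week >= gate))
})

test_that("yaml configs round through sim_config defaults", {
  p <- system.file("extdata", "example_config.yaml", package = "hescore")
  cfg <- read_sim_config_yaml(p)
  expect_s3_class(cfg, "he_sim_config")
  expect_equal(unname(cfg$arms[c("CRC1", "CRC2")]), c(8, 9))
  expect_equal(unname(cfg$temp_abdomen_induced["mean"]), 32.76)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_knob: 1", bad)
  expect_error(read_sim_config_yaml(bad), "unknown config key")
})

test_that("invalid configurations fail before any sampling", {
  expect_error(sim_config(prodrome_incidence = 1.2), "probabilities")
  expect_error(sim_config(arms = c(CTRL1 = 0L)), "arm sizes")
  expect_error(sim_config(lag_death = 0:1), "death")
})
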