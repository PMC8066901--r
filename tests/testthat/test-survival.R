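test_that("survival rate counts spontaneous deaths against enrolment", {
  arm8 <- data.frame(outcome = c(rep("scheduled_sacrifice", 6),
                                 rep("spontaneous_death", 2)))
  expect_equal(survival_rate(arm8), 75)
  arm9 <- data.frame(outcome = c(rep("scheduled_sacrifice", 6),
                                 rep("spontaneous_death", 3)))
  expect_equal(round(survival_rate(arm9), 1), 66.7)
  ctrl <- data.frame(outcome = rep("scheduled_sacrifice", 6))
  expect_equal(survival_rate(ctrl), 100)

  # humane euthanasia is not a spontaneous death by default, but can be
  # counted as a welfare failure
  he <- data.frame(outcome = c(rep("scheduled_sacrifice", 3),
                               "humane_euthanasia"))
  expect_equal(survival_rate(he), 100)
  expect_equal(survival_rate(he, events = c("spontaneous_death",
                                            "humane_euthanasia")), 75)

  expect_error(survival_rate(data.frame()), "empty arm")
  expect_error(survival_rate(data.frame(outcome = "died")), "unknown")
})

test_that("survival rate is invariant to record order and week units", {
  ev <- reconstruction_events()
  crc1 <- ev[ev$arm == "CRC1", ]
  expect_equal(survival_rate(crc1[sample(nrow(crc1)), ]),
               survival_rate(crc1))
  days <- crc1; days$week <- days$week * 7
  expect_equal(survival_rate(days), survival_rate(crc1))
})

test_that("the product-limit estimate matches hand and oracle computations", {
  # no events: flat at 1
  cens <- data.frame(animal_id = letters[1:6], week = 11,
                     outcome = "scheduled_sacrifice")
  km <- km_estimate(cens)
  expect_true(all(km$table$surv == 1))
  expect_equal(km_surv_at(km, 11), 1)

  # deaths at 8 and 10 among 8, rest censored at 11: S(11) = (7/8)(6/7)
  arm <- data.frame(animal_id = letters[1:8],
                    week = c(8, 10, rep(11, 6)),
                    outcome = c("spontaneous_death", "spontaneous_death",
                                rep("scheduled_sacrifice", 6)))
  km <- km_estimate(arm)
  expect_equal(km_surv_at(km, 11), 0.75)
  expect_equal(km_surv_at(km, 9), 7 / 8)

  # oracle equivalence on random small rosters
  set.seed(61)
  for (i in 1:60) {
    r <- random_roster(sample(3:12, 1))
    km <- km_estimate(r)
    orc <- km_oracle(r$week, as.integer(r$outcome == "spontaneous_death"))
    for (j in seq_len(nrow(orc)))
      expect_equal(km_surv_at(km, orc$time[j]), orc$surv[j])
    # monotone, in [0, 1], starts at 1
    expect_true(all(diff(km$table$surv) <= 1e-12))
    expect_true(all(km$table$surv >= 0 & km$table$surv <= 1))
  }
})

test_that("with no censoring before the last event S(t_max) is the survivor fraction", {
  set.seed(62)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    wk <- sample.int(9, n, replace = TRUE)
    r <- data.frame(animal_id = seq_len(n), week = wk,
                    outcome = ifelse(wk < 10, "spontaneous_death",
                                     "scheduled_sacrifice"))
    r$week[1] <- 10; r$outcome[1] <- "scheduled_sacrifice"  # censor last
    km <- km_estimate(r)
    expect_equal(km_surv_at(km, 9.5),
                 sum(r$outcome != "spontaneous_death") / n)
  }
})

test_that("log-rank matches the textbook statistic and its null behaviour", {
  ev <- reconstruction_events()
  a <- ev[ev$arm == "CRC1", ]; b <- ev[ev$arm == "CRC2", ]

  # identical arms: statistic 0, p 1
  same <- logrank_test(a, a)
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_equal(same$p, 1, tolerance = 1e-6)

  # reconstruction comparison is non-significant
  lr <- logrank_test(a, b)
  expect_gt(lr$p, 0.05)

  # textbook-formula oracle on a small fixture
  f1 <- data.frame(week = c(3, 5, 8, 11), outcome = c(
    "spontaneous_death", "spontaneous_death", "scheduled_sacrifice",
    "scheduled_sacrifice"))
  f2 <- data.frame(week = c(4, 9, 11), outcome = c(
    "spontaneous_death", "scheduled_sacrifice", "scheduled_sacrifice"))
  lr2 <- logrank_test(f1, f2)
  orc <- logrank_oracle(f1$week, as.integer(f1$outcome == "spontaneous_death"),
                        f2$week, as.integer(f2$outcome == "spontaneous_death"))
  expect_equal(lr2$statistic, orc, tolerance = 1e-8)

  expect_error(logrank_test(a, a[0, ]), "non-empty")
})

test_that("group score statistics implement the group-mean formula", {
  expect_equal(group_he_score(c(0, 0, 0))$mean, 0)
  expect_equal(group_he_score(c(1, 0, 2, 1))$mean, 1)
  s1 <- group_he_score(3)
  expect_equal(s1$mean, 3); expect_equal(s1$sd, 0)
  expect_error(group_he_score(numeric()), "no scores")
  expect_error(group_he_score(c(1, NA)), "incomplete")

  # pooled mean equals the n-weighted mean of arm means
  a <- c(1, 2, 2); b <- c(0, 1, 3, 2)
  pooled <- group_he_score(c(a, b))$mean
  expect_equal(pooled,
               (3 * group_he_score(a)$mean + 4 * group_he_score(b)$mean) / 7)
})

test_that("group comparisons match hand-computed ANOVA and adjustments", {
  # constant response: degenerate, F 0, no comparisons
  cg <- compare_groups(rep(5, 8), rep(c("a", "b"), each = 4))
  expect_true(cg$degenerate)
  expect_equal(cg$anova$F, 0)
  expect_null(cg$posthoc)

  # two arms {1,2,3} vs {4,5,6}: F = 13.5 by the textbook formula
  cg2 <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(cg2$anova$F[cg2$anova$term == "arm"], 13.5)

  # Bonferroni-adjusted p never below the raw p
  set.seed(71)
  y <- rnorm(24); g <- rep(letters[1:4], each = 6)
  raw <- stats::pairwise.t.test(y, g, p.adjust.method = "none")$p.value
  cgb <- compare_groups(y, g, posthoc = "bonferroni")
  adj <- stats::pairwise.t.test(y, g, p.adjust.method = "bonferroni")$p.value
  expect_true(all(adj >= raw, na.rm = TRUE))
  expect_equal(sort(cgb$posthoc$p_adj), sort(adj[!is.na(adj)]))

  # two-way layout reports arm, timepoint and interaction terms
  y2 <- rnorm(24); tp <- rep(rep(c("w11", "w17"), each = 3), 4)
  cg3 <- compare_groups(y2, g, timepoint = tp)
  expect_setequal(cg3$anova$term, c("arm", "timepoint", "arm:timepoint"))
})

test_that("Tukey and Bonferroni control false positives on null data", {
  set.seed(42)
  n_sim <- 1000
  clean_tk <- 0L; clean_bf <- 0L
  for (i in seq_len(n_sim)) {
    y <- rnorm(24); g <- rep(c("CTRL1", "CTRL2", "CRC1", "CRC2"), each = 6)
    tk <- compare_groups(y, g, posthoc = "tukey")
    bf <- compare_groups(y, g, posthoc = "bonferroni")
    clean_tk <- clean_tk + !any(tk$posthoc$significant)
    clean_bf <- clean_bf + !any(bf$posthoc$significant)
  }
  expect_gt(clean_tk / n_sim, 0.94)
  expect_gt(clean_bf / n_sim, 0.94)
})
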