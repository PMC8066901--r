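test_that("ponderal gain follows the final-weight-denominator formula", {
  expect_equal(ponderal_gain(200, 200), 0)
  expect_equal(ponderal_gain(200, 250), 20)
  expect_equal(ponderal_gain(250, 200), -25)   # signed losses
  expect_error(ponderal_gain(0, 100), "positive")
  expect_error(ponderal_gain(100, -5), "positive")
})

test_that("ponderal gain is bounded above by 100 on a positive-weight grid", {
  g <- expand.grid(a = seq(50, 500, by = 25), b = seq(50, 500, by = 25))
  pg <- ponderal_gain(g$a, g$b)
  expect_true(all(pg < 100))
  # gains and losses between the same two weights are asymmetric in
  # magnitude (the denominator is whichever weight is final)
  expect_false(isTRUE(all.equal(abs(ponderal_gain(200, 250)),
                                abs(ponderal_gain(250, 200)))))
})

test_that("weekly series gives consecutive-pair gains and inverts exactly", {
  flat <- weekly_ponderal_series(1:3, c(200, 200, 200))
  expect_equal(flat$pg, c(0, 0))

  s <- weekly_ponderal_series(1:3, c(200, 220, 231))
  expect_equal(s$week, c(2L, 3L))
  expect_equal(s$pg, c(20 / 220 * 100, 11 / 231 * 100))

  # a multiplicative series w_t = w_{t-1} / (1 - g) has constant gain g
  g <- 7.5
  w <- 200 * (1 / (1 - g / 100))^(0:5)
  expect_equal(weekly_ponderal_series(0:5, w)$pg, rep(g, 5))

  # reconstructing weights from the gains recovers the series
  set.seed(5)
  w <- cumsum(c(250, runif(9, -10, 30)))
  pg <- weekly_ponderal_series(1:10, w)$pg
  rec <- Reduce(function(prev, g) prev / (1 - g / 100), pg,
                accumulate = TRUE, init = w[1])
  expect_equal(rec, w, tolerance = 1e-9)

  expect_equal(nrow(weekly_ponderal_series(1L, 200)), 0)
  expect_error(weekly_ponderal_series(c(1, 1, 2), c(1, 2, 3) * 100),
               "strictly increasing")
})

test_that("corrected body weight subtracts the intestinal compartment", {
  expect_equal(corrected_body_weight(400, 0), 400)
  expect_equal(corrected_body_weight(400, 35), 365)
  expect_error(corrected_body_weight(400, 400))
  expect_error(corrected_body_weight(400, -1))
  expect_true(all(corrected_body_weight(c(300, 400), c(20, 35)) <=
                  c(300, 400)))
})

test_that("mean consumption divides by animal-days and rejects refid gains", {
  expect_equal(mean_consumption(700, 0, 5, 7), 20)
  expect_equal(mean_consumption(500, 500, 4, 7), 0)
  expect_error(mean_consumption(0, 100, 4, 7), "refill")
  expect_error(mean_consumption(700, 0, 0, 7), "n_animals")
})

test_that("the prodrome detector reproduces the observed case patterns", {
  # flat weights, no signs: never an alert
  fl <- detect_prodrome(1:8, rep(300, 8))
  expect_true(all(fl$alert_level == "none"))

  # case 1: 10.49% jump at week 5, swollen abdomen week 6 -> high by week 6
  w <- c(rep(250, 4), 250 / (1 - 0.1049))
  w <- c(w, rep(w[5], 3))
  signs <- data.frame(week = 6, swollen_abdomen = TRUE, diarrhea = FALSE,
                      priapism = FALSE)
  fl <- detect_prodrome(1:8, w, signs)
  expect_true(fl$sudden_gain[fl$week == 5])
  expect_identical(fl$alert_level[fl$week == 6], "high")

  # case 2: a 6.40% jump alone is watch, not high
  w2 <- c(rep(250, 4), 250 / (1 - 0.064), rep(250 / (1 - 0.064), 2))
  fl2 <- detect_prodrome(1:7, w2)
  expect_identical(fl2$alert_level[fl2$week == 5], "watch")
  expect_false(any(fl2$alert_level == "high"))

  # a gain above 10% is high on its own
  w3 <- c(rep(250, 4), 250 / (1 - 0.12))
  fl3 <- detect_prodrome(1:5, w3)
  expect_identical(fl3$alert_level[fl3$week == 5], "high")
})

test_that("adding a sign never lowers the alert level", {
  lvl <- c(none = 0, watch = 1, high = 2)
  set.seed(41)
  for (i in 1:50) {
    n <- 10
    w <- cumsum(c(250, runif(n - 1, -5, 25)))
    signs <- data.frame(week = 1:n,
                        swollen_abdomen = runif(n) < 0.15,
                        diarrhea = runif(n) < 0.15,
                        priapism = runif(n) < 0.1)
    base <- detect_prodrome(1:n, w, signs)
    more <- signs
    j <- sample(n, 1); col <- sample(c("swollen_abdomen", "diarrhea",
                                       "priapism"), 1)
    more[j, col] <- TRUE
    upd <- detect_prodrome(1:n, w, more)
    expect_true(all(lvl[upd$alert_level] >= lvl[base$alert_level]))
    # alerts never de-escalate over time within one animal
    expect_true(all(diff(lvl[base$alert_level]) >= 0))
  }
})

test_that("temperature summaries use sample SD with the single-reading rule", {
  r <- data.frame(animal_id = c("a", "b"), week = 1, site = "abdomen",
                  celsius = c(30, 32))
  arms <- c(a = "CRC2", b = "CRC2")
  s <- group_temperature_summary(r, arms, "abdomen")
  expect_equal(s$mean, 31)
  expect_equal(s$sd, sqrt(2), tolerance = 1e-6)

  one <- data.frame(animal_id = "a", week = 1, site = "abdomen",
                    celsius = 31)
  expect_warning(s1 <- group_temperature_summary(one, arms, "abdomen"),
                 "single reading")
  expect_equal(s1$sd, 0)

  same <- data.frame(animal_id = rep("a", 4), week = 1:4, site = "back",
                     celsius = rep(31.2, 4))
  expect_equal(group_temperature_summary(same, arms, "back")$sd, 0)

  expect_error(group_temperature_summary(one, arms, "back"), "no 'back'")
})

test_that("implausible temperature readings are gated out with a warning", {
  r <- data.frame(animal_id = "a", week = 1:3, site = "back",
                  celsius = c(31, 55, 10))
  expect_warning(kept <- filter_temperatures(r), "implausible")
  expect_equal(kept$celsius, 31)
})
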