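benign_vent <- function(...) {
  v <- tibble::tibble(spo2_min = 99, major_leak = FALSE,
                      flow_over_15_flush_twice = FALSE,
                      no_chest_movement = FALSE, two_handed_needed = FALSE,
                      operator_substitution = FALSE, tidal_volume = 500,
                      ideal_body_weight = 70)
  mod <- list(...)
  for (nm in names(mod)) v[[nm]] <- mod[[nm]]
  v
}

test_that("the DMV predicate implements every ventilation criterion", {
  expect_false(label_dmv(benign_vent()))
  expect_true(label_dmv(benign_vent(spo2_min = 90)))          # desaturation
  expect_true(label_dmv(benign_vent(tidal_volume = 340)))     # < 5 mL/kg IBW
  expect_false(label_dmv(benign_vent(tidal_volume = 351)))
  for (flag in c("major_leak", "flow_over_15_flush_twice",
                 "no_chest_movement", "two_handed_needed",
                 "operator_substitution")) {
    args <- stats::setNames(list(TRUE), flag)
    expect_true(label_dmv(do.call(benign_vent, args)))
  }
  expect_error(label_dmv(benign_vent()[, -1]), "missing fields")
})

test_that("Devine ideal body weight matches the textbook case", {
  expect_equal(ideal_body_weight(177.8, "male"), 73)     # 70 inches
  expect_equal(ideal_body_weight(162.6, "female"),
               45.5 + 2.3 * (162.6 / 2.54 - 60), tolerance = 1e-9)
  expect_equal(ideal_body_weight(100, "female"), 45.5)   # floored at base
})

lowest_risk <- tibble::tibble(
  age = 30, gender = "female", bmi = 22, tmd = 9, mmt = 1,
  snoring = FALSE, neck_radiation = FALSE,
  difficult_intubation_history = FALSE, sleep_apnea = FALSE, beard = FALSE)

highest_risk <- tibble::tibble(
  age = 70, gender = "male", bmi = 35, tmd = 3.5, mmt = 4,
  snoring = TRUE, neck_radiation = TRUE,
  difficult_intubation_history = TRUE, sleep_apnea = TRUE, beard = TRUE)

test_that("DIFFMASK spans 0 to 18 and sums per component", {
  expect_equal(diffmask_score(lowest_risk)$diffmask, 0L)
  expect_equal(diffmask_score(highest_risk)$diffmask, 18L)
  expect_true(diffmask_score(highest_risk)$at_risk)
  expect_false(diffmask_score(lowest_risk)$at_risk)

  # mixed record, hand-summed against the packaged table:
  # age 50 -> 1, male -> 1, bmi 27 -> 1, tmd 5 -> 1, mmt 3 -> 1,
  # snoring -> 2, others FALSE -> 0; total 7
  mixed <- tibble::tibble(
    age = 50, gender = "male", bmi = 27, tmd = 5, mmt = 3,
    snoring = TRUE, neck_radiation = FALSE,
    difficult_intubation_history = FALSE, sleep_apnea = FALSE,
    beard = FALSE)
  expect_equal(diffmask_score(mixed)$diffmask, 7L)
})

test_that("DIFFMASK is monotone in every component", {
  worsen <- list(
    age = function(r) { r$age <- r$age + 20; r },
    gender = function(r) { r$gender <- "male"; r },
    bmi = function(r) { r$bmi <- r$bmi + 6; r },
    tmd = function(r) { r$tmd <- max(3, r$tmd - 3); r },
    mmt = function(r) { r$mmt <- min(4, r$mmt + 1); r },
    snoring = function(r) { r$snoring <- TRUE; r },
    neck_radiation = function(r) { r$neck_radiation <- TRUE; r },
    difficult_intubation_history = function(r) {
      r$difficult_intubation_history <- TRUE; r },
    sleep_apnea = function(r) { r$sleep_apnea <- TRUE; r },
    beard = function(r) { r$beard <- TRUE; r })
  set.seed(50)
  for (i in 1:25) {
    r <- tibble::tibble(
      age = stats::runif(1, 20, 75), gender = sample(c("male", "female"), 1),
      bmi = stats::runif(1, 17, 36), tmd = stats::runif(1, 3.5, 11),
      mmt = sample(1:4, 1), snoring = sample(c(TRUE, FALSE), 1),
      neck_radiation = sample(c(TRUE, FALSE), 1),
      difficult_intubation_history = sample(c(TRUE, FALSE), 1),
      sleep_apnea = sample(c(TRUE, FALSE), 1),
      beard = sample(c(TRUE, FALSE), 1))
    base <- diffmask_score(r)$diffmask
    for (f in worsen)
      expect_gte(diffmask_score(f(r))$diffmask, base)
  }
})

test_that("weight tables are validated and loadable from YAML", {
  w <- diffmask_default_weights()
  expect_equal(attr(w, "max_score"), 18)
  broken <- unclass(w)
  broken$beard$yes <- 5
  expect_error(validate_diffmask_weights(broken), "18")
  broken2 <- unclass(w)
  broken2$age <- NULL
  expect_error(validate_diffmask_weights(broken2), "missing components")

  packaged <- read_diffmask_weights(
    system.file("extdata", "diffmask_weights.yaml", package = "maskshape"))
  expect_equal(diffmask_score(highest_risk, packaged)$diffmask, 18L)
  expect_equal(diffmask_score(lowest_risk, packaged)$diffmask, 0L)
})

test_that("baseline tables reproduce published-style percentages", {
  # 669 subjects: 375 female / 294 male overall; 26 of 35 DMV male
  rec <- tibble::tibble(
    gender = c(rep("male", 26), rep("female", 9),
               rep("male", 268), rep("female", 366)),
    dmv = c(rep(TRUE, 35), rep(FALSE, 634)))
  tab <- baseline_table(rec)
  female <- tab[tab$variable == "gender" & tab$level == "female", ]
  male <- tab[tab$variable == "gender" & tab$level == "male", ]
  expect_equal(female$overall, "375 (56.1)")
  expect_equal(male$group_positive, "26 (74.3)")
  expect_equal(male$overall, "294 (43.9)")
  expect_lt(tab$p_fisher[tab$variable == "gender"][1], 0.001)
})

test_that("baseline tables run both continuous tests and note degeneracies", {
  set.seed(60)
  rec <- tibble::tibble(
    age = c(stats::rnorm(40, 40), stats::rnorm(10, 48)),
    flatline = rep(5, 50),
    snoring = sample(c(TRUE, FALSE), 50, TRUE),
    dmv = rep(c(FALSE, TRUE), c(40, 10)))
  tab <- baseline_table(rec)
  age_row <- tab[tab$variable == "age", ]
  expect_false(is.na(age_row$p_anova))
  expect_false(is.na(age_row$p_mann_whitney))
  expect_match(tab$note[tab$variable == "flatline"], "zero variance")
  expect_false(is.na(tab$p_fisher[tab$variable == "snoring"][1]))

  # identical groups: balanced 2x2 Fisher p-value of 1
  rec2 <- tibble::tibble(snoring = rep(c(TRUE, FALSE), 20),
                         dmv = rep(c(TRUE, FALSE), each = 20))
  t2 <- baseline_table(rec2)
  expect_equal(t2$p_fisher[1], 1)
})

test_that("Riley minimum sample size reproduces the published case", {
  n <- riley_min_n(c_statistic = 0.825, prevalence = 0.0523,
                   n_parameters = 3)
  expect_equal(as.integer(n), 331L)
  # more parameters demand more cases
  n6 <- riley_min_n(0.825, 0.0523, 6)
  expect_gt(n6, n)
})

test_that("each Riley criterion matches a step-by-step hand calculation", {
  n <- riley_min_n(0.7, 0.2, 5, method = "integration")
  r2 <- attr(n, "r2_cox_snell")
  # criterion 1: shrinkage >= 0.9
  n1 <- 5 / ((0.9 - 1) * log(1 - r2 / 0.9))
  # criterion 2: optimism <= 0.05 of max R2
  max_r2 <- 1 - (0.2^0.2 * 0.8^0.8)^2
  s2 <- r2 / (r2 + 0.05 * max_r2)
  n2 <- 5 / ((s2 - 1) * log(1 - r2 / s2))
  # criterion 3: outcome proportion within 0.05
  n3 <- (stats::qnorm(0.975) / 0.05)^2 * 0.2 * 0.8
  crit <- attr(n, "criteria")
  expect_equal(unname(crit), c(n1, n2, n3), tolerance = 1e-10)
  expect_equal(as.integer(n), max(ceiling(n1), ceiling(n2), ceiling(n3)))
})

test_that("Riley n falls as prevalence rises while shrinkage dominates", {
  # the discrimination-driven (shrinkage) criterion always relaxes as the
  # outcome becomes less rare; the overall n follows it while it dominates
  shr <- vapply(c(0.0523, 0.1, 0.2, 0.3),
                function(p) attr(riley_min_n(0.825, p, 3,
                                             method = "integration"),
                                 "criteria")[["shrinkage"]], 0)
  expect_true(all(diff(shr) <= 0))
  ns <- vapply(c(0.0523, 0.08, 0.1),
               function(p) as.integer(riley_min_n(0.825, p, 3,
                                                  method = "integration")), 0L)
  expect_true(all(diff(ns) <= 0))
  # simulation and integration conversions agree closely
  r_sim <- attr(riley_min_n(0.825, 0.0523, 3), "r2_cox_snell")
  r_int <- attr(riley_min_n(0.825, 0.0523, 3, method = "integration"),
                "r2_cox_snell")
  expect_equal(r_sim, r_int, tolerance = 0.02)
})

test_that("riley_min_n rejects out-of-range inputs and leaves the RNG alone", {
  expect_error(riley_min_n(0.4, 0.1, 3), "c_statistic")
  expect_error(riley_min_n(0.8, 1.2, 3), "prevalence")
  set.seed(123)
  before <- stats::rnorm(1)
  set.seed(123)
  invisible(riley_min_n(0.8, 0.1, 3))
  expect_equal(stats::rnorm(1), before)
})
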