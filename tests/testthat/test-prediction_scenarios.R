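test_that("threshold choice maximises specificity subject to the sensitivity floor", {
  ch <- choose_threshold(c(0.9, 0.8, 0.7, 0.3), c(1, 1, 0, 0),
                         target_tpr = 0.8)
  expect_equal(ch$threshold, 0.8)
  expect_equal(ch$achieved_tpr, 1.0)
  expect_equal(ch$achieved_tnr, 1.0)

  # perfectly separated: TNR = 1 at the chosen threshold
  ch2 <- choose_threshold(c(0.9, 0.85, 0.2, 0.1), c(1, 1, 0, 0),
                          target_tpr = 0.5)
  expect_equal(ch2$achieved_tnr, 1.0)

  # target 1.0: threshold cannot exceed the lowest positive score
  set.seed(1)
  s <- runif(100); l <- rbinom(100, 1, 0.3)
  ch3 <- choose_threshold(s, l, target_tpr = 1.0)
  expect_lte(ch3$threshold, min(s[l == 1]))
  expect_equal(ch3$achieved_tpr, 1.0)
  expect_gte(ch3$achieved_tpr, ch3$target_tpr)
  expect_true(ch3$threshold > 0 && ch3$threshold < 1)

  expect_error(choose_threshold(s, l, target_tpr = 0), "target_tpr")
  expect_error(choose_threshold(s, l, target_tpr = 1.2), "target_tpr")
  expect_equal(nrow(choose_threshold(s, l)$alternates), 2L)
})

test_that("scenario application is pure and respects group and island filters", {
  ds <- make_fixture("paper_like", n_islands = 150L, seed = 61)
  before <- ds$islands

  same <- apply_scenario(ds, character())
  expect_identical(same$islands[, invasive_groups()],
                   before[, invasive_groups()])

  all4 <- c("rats", "felids", "pigs", "mustelids_mongooses")
  managed <- apply_scenario(ds, all4)
  hosts <- unique(ds$populations$island_id[ds$populations$extant == 1L])
  sel <- managed$islands$island_id %in% hosts
  expect_true(all(managed$islands[sel, all4] == 0L))
  # untouched elsewhere, and the input dataset is unchanged
  expect_identical(managed$islands[!sel, all4], before[!sel, all4])
  expect_identical(ds$islands, before)

  # explicit filter excluding an island leaves its flags alone
  keep_out <- ds$islands$island_id[1L]
  m2 <- apply_scenario(ds, "rats",
                       island_filter = setdiff(ds$islands$island_id,
                                               keep_out))
  expect_equal(m2$islands$rats[m2$islands$island_id == keep_out],
               before$rats[before$island_id == keep_out])

  expect_error(apply_scenario(ds, "direwolves"), "direwolves")
})

test_that("extant classification respects thresholds and aggregates equal recounts", {
  ds <- make_fixture("paper_like", n_islands = 800L, seed = 62)
  fit <- fit_gee(build_design(ds, final_model_spec()))
  thr <- choose_threshold(fit$fitted, fit$y)
  summ <- predict_extant_summary(fit, ds, thr)
  pp <- summ$per_population
  expect_equal(summ$overall$n_extant, sum(ds$populations$extant))
  expect_equal(summ$overall$n_predicted_extirpated,
               sum(pp$risk >= thr$threshold))
  expect_equal(sum(summ$by_class$n_predicted),
               summ$overall$n_predicted_extirpated)
  expect_equal(sum(summ$by_class$n), summ$overall$n_extant)
  expect_true(all(diff(summ$by_class$fraction) <= 0))  # ranked

  # threshold monotonicity: raising it never predicts more extirpations
  lo <- predict_extant_summary(fit, ds, 0.2)
  hi <- predict_extant_summary(fit, ds, 0.6)
  expect_gte(lo$overall$n_predicted_extirpated,
             hi$overall$n_predicted_extirpated)

  # threshold just below 1: nothing classified extirpated
  none <- predict_extant_summary(fit, ds, 1 - 1e-9)
  expect_equal(none$overall$n_predicted_extirpated, 0L)
})

test_that("the identity scenario prevents nothing and carries zero debt", {
  ds <- make_fixture("paper_like", n_islands = 800L, seed = 63)
  fit <- fit_gee(build_design(ds, final_model_spec()))
  sb <- scenario_benefit(fit, ds, 0.3, character())
  expect_equal(sb$aggregates$n_prevented, 0L)
  expect_true(all(abs(sb$per_population$debt) < 1e-12))
  expect_equal(sb$aggregates$total_debt, 0)
})

test_that("managing a harmful invader yields nonnegative debt and the identity invariants", {
  ds <- make_fixture("strong_rat_effect", n_islands = 900L, seed = 64)
  fit <- fit_gee(build_design(ds, model_spec(c("rats"))))
  expect_gt(fit$beta[["rats"]], 0)
  thr <- choose_threshold(fit$fitted, fit$y)
  sb <- scenario_benefit(fit, ds, thr, "rats")
  pp <- sb$per_population
  expect_true(all(pp$debt >= -1e-12))
  expect_gt(sb$aggregates$n_prevented, 0L)
  expect_gt(sb$aggregates$preventable_fraction, 0)
  # preventable implies baseline-classified extirpated
  expect_true(all(pp$baseline_class[pp$preventable == 1L] == 1L))
  # identity: prevented = baseline positives - still-positive-after
  expect_equal(sb$aggregates$n_prevented,
               sum(pp$baseline_class) -
                 sum(pp$baseline_class == 1L & pp$managed_class == 1L))
  # total debt equals the sum of risk reductions
  expect_equal(sb$aggregates$total_debt,
               sum(pp$baseline_risk) - sum(pp$managed_risk),
               tolerance = 1e-10)
  # aggregates equal recounts of per-population rows
  expect_equal(sum(sb$by_class$n_prevented), sb$aggregates$n_prevented)
})

test_that("a protective invader produces negative debt, reported not clipped", {
  tb <- c("(Intercept)" = -1.2, "mice" = -1.0)
  ds <- simulate_dataset(sim_params(n_islands = 600L, true_beta = tb),
                         seed = 65)
  fit <- fit_gee(build_design(ds, model_spec(c("mice"))))
  expect_lt(fit$beta[["mice"]], 0)
  sb <- scenario_benefit(fit, ds, 0.5, "mice")
  expect_lt(min(sb$per_population$debt), 0)
})

test_that("odds ratios follow the fitted probabilities through the link", {
  ds <- make_fixture("paper_like", n_islands = 800L, seed = 66)
  fit <- fit_gee(build_design(ds, final_model_spec()))
  prof <- make_profile("nonvolant_mammal", ln_area = log(9.7),
                       precipitation = 1326, human_presence = 1,
                       invasives = "rats")
  expect_equal(odds_ratio(fit, prof, prof), 1.0)

  prof0 <- make_profile("nonvolant_mammal", ln_area = log(9.7),
                        precipitation = 1326, human_presence = 1)
  # independent hand computation through the link
  b <- fit$beta
  eta0 <- b[["(Intercept)"]] + b[["class_volancy=nonvolant_mammal"]] +
    b[["ln_area"]] * log(9.7) + b[["precipitation"]] * 1326 +
    b[["human_presence"]] +
    b[["class_volancy=nonvolant_mammal:ln_area"]] * log(9.7) +
    b[["class_volancy=nonvolant_mammal:precipitation"]] * 1326
  eta1 <- eta0 + b[["rats"]] + b[["rats:ln_area"]] * log(9.7)
  p0 <- 1 - exp(-exp(eta0)); p1 <- 1 - exp(-exp(eta1))
  expect_equal(odds_ratio(fit, prof, prof0),
               (p1 / (1 - p1)) / (p0 / (1 - p0)), tolerance = 1e-10)

  # pure odds arithmetic: p_a = 0.5 vs p_b = 0.25 gives 3
  expect_equal((0.5 / 0.5) / (0.25 / 0.75), 3)
})

test_that("risk profiles are flat, shifted, or converging as the coefficients dictate", {
  ds <- make_fixture("paper_like", n_islands = 800L, seed = 66)
  fit <- fit_gee(build_design(ds, final_model_spec()))
  prof <- make_profile("volant_bird", ln_area = 0, precipitation = 1326,
                       human_presence = 0)
  sweep <- seq(-5, 10, length.out = 25)

  rp <- risk_profile(fit, "ln_area", sweep, prof,
                     scenarios = list(none = character(), rats = "rats"))
  expect_equal(nrow(rp), 50L)
  none <- rp$risk[rp$scenario == "none"]
  rats <- rp$risk[rp$scenario == "rats"]
  if (fit$beta[["rats"]] > 0 && fit$beta[["rats:ln_area"]] < 0) {
    # rat effect shrinks with area: curves converge on the link scale
    gap <- log(-log1p(-rats)) - log(-log1p(-none))
    expect_true(all(diff(gap) < 1e-8))
  }

  # a variable with zero coefficient gives a flat curve
  fit2 <- fit_gee(build_design(ds, model_spec(c("rats"))))
  fit2$beta[["rats"]] <- 0
  rp2 <- risk_profile(fit2, "rats", c(0, 0.5, 1),
                      make_profile("reptile", ln_area = 1,
                                   precipitation = 1000))
  expect_equal(length(unique(round(rp2$risk, 12))), 1L)

  expect_error(risk_profile(fit, "class_volancy", 1:3, prof),
               "categorical")
})
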