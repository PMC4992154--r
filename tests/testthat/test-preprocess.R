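test_that("covariate transforms produce zero-mean OLS residuals and exact logs", {
  ds <- toy_dataset()
  isl <- transform_covariates(ds$islands)
  expect_equal(isl$ln_area, log(ds$islands$area))
  expect_equal(isl$ln_seasonality, log(ds$islands$temperature_seasonality))
  expect_lt(abs(mean(isl$elevation_residual)), 1e-10)

  # elevations exactly a power of area -> all residuals 0
  isl2 <- ds$islands
  isl2$elevation <- exp(2 + 0.4 * log(isl2$area)) - 1
  t2 <- transform_covariates(isl2)
  expect_lt(max(abs(t2$elevation_residual)), 1e-10)

  isl3 <- ds$islands
  isl3$area[1] <- 0
  expect_error(transform_covariates(isl3), "i1")
})

test_that("five-island residuals match closed-form simple-regression arithmetic", {
  isl <- data.frame(
    island_id = paste0("h", 1:5),
    area = c(1, 10, 100, 1000, 10000),
    elevation = c(10, 30, 20, 200, 500),
    precipitation = rep(1000, 5), mean_temperature = rep(20, 5),
    temperature_seasonality = rep(3, 5), human_presence = rep(0L, 5),
    stringsAsFactors = FALSE
  )
  t1 <- transform_covariates(isl)
  x <- log(isl$area)
  y <- log(isl$elevation + 1)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  expect_equal(t1$elevation_residual, y - b0 - b1 * x, tolerance = 1e-12)
})

test_that("screening flags collinear pairs, rare groups, and missing-heavy covariates", {
  ds <- make_fixture("paper_like", seed = 31)
  scr <- covariate_screen(ds)
  # the generator couples elevation to area above the 0.7 threshold
  fl <- scr$flagged_pairs
  expect_true(any(fl$var1 == "ln_area" & fl$var2 == "ln_elevation"))
  # the four structurally rare groups are excluded, the others kept
  expect_setequal(scr$excluded_groups,
                  c("primates", "medium_omnivores", "small_omnivores",
                    "medium_herbivores"))
})

test_that("screening edge cases: duplicate column r = 1, threshold boundary, constant column", {
  ds <- toy_dataset()
  isl <- transform_covariates(ds$islands)
  isl$mean_temperature <- isl$precipitation  # duplicate in disguise
  scr <- covariate_screen(islex_dataset(isl, ds$populations))
  dup <- scr$correlations[scr$correlations$var1 == "precipitation" &
                            scr$correlations$var2 == "mean_temperature", ]
  expect_equal(dup$r, 1.0)
  expect_true(any(scr$flagged_pairs$r == 1.0))

  # group on 1 of 4 islands (25%): kept at threshold 0.25, excluded above
  scr2 <- covariate_screen(ds, prevalence_threshold = 0.25)
  expect_false("felids" %in% scr2$excluded_groups)  # 2/4 = 50%
  expect_true("pigs" %in% scr2$excluded_groups)     # 0/4
  scr3 <- covariate_screen(ds, prevalence_threshold = 0.51)
  expect_true("felids" %in% scr3$excluded_groups)

  # constant column: correlation undefined, no crash
  isl4 <- ds$islands
  isl4$mean_temperature <- 20
  scr4 <- covariate_screen(islex_dataset(isl4, ds$populations))
  cc <- scr4$correlations
  expect_true(all(is.na(cc$r[cc$var1 == "mean_temperature" |
                               cc$var2 == "mean_temperature"])))
})

test_that("co-occurrence ordination preserves distances and never increases stress", {
  ds <- make_fixture("paper_like", seed = 31)
  ord <- cooccurrence_ordination(ds$islands)
  expect_equal(nrow(ord$points), 12L)
  expect_true(all(diff(ord$stress_trace) <= 1e-8))

  # 4-group toy matrix: a 2-D embedding can honour the full rank order
  toy <- data.frame(island_id = sprintf("t%02d", 1:12))
  toy$rats <- c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 0, 0)
  toy$felids <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 1, 1)
  toy$pigs <- c(0, 0, 1, 1, 1, 1, 0, 0, 0, 1, 0, 1)
  toy$mice <- c(0, 1, 0, 1, 0, 1, 0, 1, 1, 0, 0, 0)
  ord_toy <- cooccurrence_ordination(toy)
  d_in <- ord_toy$distances[upper.tri(ord_toy$distances)]
  d_out <- as.matrix(stats::dist(ord_toy$points))
  d_out <- d_out[upper.tri(d_out)]
  expect_gte(stats::cor(d_in, d_out, method = "spearman"), 0.9)

  # identical occupancy vectors embed at (near) zero distance
  isl <- ds$islands
  isl$mice <- isl$rats
  ord2 <- cooccurrence_ordination(isl)
  expect_lt(sqrt(sum((ord2$points["mice", ] - ord2$points["rats", ])^2)),
            1e-6)

  expect_error(cooccurrence_ordination(ds$islands[, c("island_id", "rats",
                                                      "felids")]),
               "at least 3")
})

test_that("ordination is competitive with an established non-metric solver", {
  skip_if_not_installed("MASS")
  ds <- make_fixture("paper_like", seed = 31)
  ord <- cooccurrence_ordination(ds$islands)
  D <- stats::as.dist(ord$distances)
  iso <- suppressMessages(MASS::isoMDS(D, k = 2, trace = FALSE))
  d_iso <- as.matrix(stats::dist(iso$points))
  d_ord <- as.matrix(stats::dist(ord$points))
  r_iso <- stats::cor(as.vector(stats::as.dist(d_iso)), as.vector(D),
                      method = "spearman")
  r_ord <- stats::cor(as.vector(stats::as.dist(d_ord)), as.vector(D),
                      method = "spearman")
  # the metric majorization trades some rank agreement for metric fit;
  # it must stay within reach of the rank-optimising reference
  expect_gt(r_ord, r_iso - 0.1)
})

test_that("the final model design has the documented 34 columns", {
  ds <- make_fixture("paper_like", seed = 31)
  dm <- build_design(ds, final_model_spec())
  # 1 intercept + 5 class dummies + 7 mains + 5x4 class interactions + rat:area
  expect_equal(ncol(dm$X), 34L)
  expect_equal(dm$term_map$column, colnames(dm$X))
  expect_equal(colnames(dm$X)[1], "(Intercept)")
  expect_false(anyNA(dm$X))
  # encoding is invertible: term_map reconstructs the spec
  mains <- setdiff(unique(dm$term_map$term[!grepl(":", dm$term_map$term)]),
                   "(Intercept)")
  inters <- unique(dm$term_map$term[grepl(":", dm$term_map$term)])
  expect_setequal(mains, final_model_spec()$main_effects)
  expect_setequal(inters, final_model_spec()$interactions)
})

test_that("intercept-only spec produces a single all-ones column", {
  ds <- toy_dataset()
  dm <- build_design(ds, model_spec(character()))
  expect_equal(ncol(dm$X), 1L)
  expect_true(all(dm$X == 1))
})

test_that("rows are sorted by island then species and clusters are retrievable", {
  ds <- toy_dataset()
  dm <- build_design(ds, model_spec(c("ln_area", "rats")))
  expect_equal(dm$keys$island_id, sort(dm$keys$island_id))
  expect_equal(length(unique(dm$cluster)), 4L)
})

test_that("historical versus current presence toggles eradicated groups", {
  ds <- make_fixture("tiny")  # island A has rats present but eradicated
  spec <- model_spec(c("rats"))
  hist <- build_design(ds, spec, use_historical_presence = TRUE)
  curr <- build_design(ds, spec, use_historical_presence = FALSE)
  a_rows <- hist$keys$island_id == "A"
  expect_true(all(hist$X[a_rows, "rats"] == 1))
  expect_true(all(curr$X[a_rows, "rats"] == 0))
  # islands without eradications are unaffected
  expect_equal(hist$X[!a_rows, "rats"], curr$X[!a_rows, "rats"])
})

test_that("a spec referencing an unavailable covariate errors", {
  ds <- toy_dataset()
  expect_error(build_design(ds, model_spec(c("ln_area", "body_condition"))),
               "body_condition")
  expect_error(model_spec(c("a", "a")), "duplicate")
  expect_error(model_spec("a", "a:b:c"), "pairs")
})
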