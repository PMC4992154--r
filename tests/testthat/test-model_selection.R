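test_that("subset enumeration counts equal binomial coefficients", {
  cands <- paste0("t", 1:15)
  expect_length(all_subsets_terms(cands, 7), choose(15, 7))
  expect_length(all_subsets_terms(cands, 7), 6435L)
  expect_length(all_subsets_terms(cands, 1), 15L)
  expect_length(all_subsets_terms(cands, 15), 1L)
  expect_error(all_subsets_terms(cands, 0))
  expect_error(all_subsets_terms(cands, 16))
})

test_that("a dominant predictor ranks first at order one", {
  wins <- vapply(1:20, function(i) {
    ds <- make_fixture("strong_rat_effect", n_islands = 250L,
                       seed = 500 + i)
    rk <- all_subsets_rank(ds, c("rats", "mean_temperature",
                                 "ln_seasonality"), 1L)
    rk$table$terms[1] == "rats"
  }, logical(1L))
  expect_gte(mean(wins), 0.9)
})

test_that("QICu ties between exchangeable candidates break lexicographically", {
  ds <- make_fixture("paper_like", n_islands = 200L, seed = 41)
  ds$islands$zz_rats_copy <- ds$islands$rats
  rk <- all_subsets_rank(ds, c("zz_rats_copy", "rats"), 1L)
  expect_lt(abs(rk$table$qicu[1] - rk$table$qicu[2]), 1e-6)
  expect_equal(rk$table$terms, c("rats", "zz_rats_copy"))
})

test_that("top-model averaging weights follow the information-criterion formula", {
  mock_rank <- function(deltas, coefs) {
    qicu <- 100 + deltas
    tab <- data.frame(terms = names(coefs), qicu = qicu, mse = NA,
                      converged = TRUE, delta_qicu = deltas,
                      in_top = deltas < 2, stringsAsFactors = FALSE)
    structure(list(table = tab, coefs = coefs, order = 1L),
              class = "islex_rank")
  }
  # singleton top set
  a1 <- average_top_models(mock_rank(c(0, 5),
                                     list(m1 = c("(Intercept)" = -1, x = 2),
                                          m2 = c("(Intercept)" = 0, y = 1))))
  expect_equal(a1$weights, c(m1 = 1))
  expect_equal(a1$coefficients[["x"]], 2)

  # equal QICu -> equal weights
  a2 <- average_top_models(mock_rank(c(0, 0),
                                     list(m1 = c("(Intercept)" = -1, x = 2),
                                          m2 = c("(Intercept)" = -3, y = 1))))
  expect_equal(unname(a2$weights), c(0.5, 0.5))
  expect_equal(a2$coefficients[["(Intercept)"]], -2)
  expect_equal(a2$coefficients[["x"]], 1)   # zero-filled averaging
  expect_equal(a2$coefficients[["y"]], 0.5)

  # delta = (0, 2) -> weights (0.731, 0.269)
  a3 <- average_top_models(mock_rank(c(0, 1.9999999),
                                     list(m1 = c(x = 1), m2 = c(x = 3))))
  expect_equal(unname(a3$weights), c(0.7310586, 0.2689414),
               tolerance = 1e-6)
  expect_equal(a3$coefficients[["x"]],
               0.7310586 * 1 + 0.2689414 * 3, tolerance = 1e-6)
  expect_equal(sum(a3$weights), 1, tolerance = 1e-12)
})

test_that("the MSE-by-order rule stops at diminishing returns", {
  # strong three-term truth: the curve should flatten at order ~3
  tb <- c("(Intercept)" = -2.4, "rats" = 1.6, "human_presence" = 1.2,
          "ln_area" = -0.25)
  ds <- simulate_dataset(sim_params(n_islands = 600L, true_beta = tb),
                         seed = 71)
  cands <- c("rats", "human_presence", "ln_area", "mean_temperature",
             "ln_seasonality")
  oc <- order_curve_and_choice(ds, cands, max_order = 5L)
  expect_true(abs(oc$chosen_order - 3L) <= 1L)
  expect_equal(nrow(oc$curve), 5L)

  # rel_tol = 0 runs to max_order while the curve strictly decreases
  oc0 <- order_curve_and_choice(ds, cands[1:3], max_order = 3L,
                                rel_tol = 0)
  if (all(diff(oc0$curve$mse) < 0)) expect_equal(oc0$chosen_order, 3L)

  # pure-noise candidates stop immediately
  ds0 <- simulate_dataset(
    sim_params(n_islands = 400L,
               true_beta = c("(Intercept)" = cloglog(0.25))), seed = 72)
  oc_null <- order_curve_and_choice(ds0, c("mean_temperature",
                                           "ln_seasonality"),
                                    max_order = 2L)
  expect_equal(oc_null$chosen_order, 1L)
})

test_that("interaction screening applies the conservative QICu-improvement rule", {
  # null interaction: rats matter, rats:ln_area truly zero
  tb_null <- c("(Intercept)" = -2.3, "rats" = 1.2)
  rejections <- vapply(1:10, function(i) {
    ds <- simulate_dataset(sim_params(n_islands = 400L, true_beta = tb_null),
                           seed = 800 + i)
    sf <- suppressWarnings(
      screen_and_force(ds, model_spec(c("rats", "ln_area")),
                       candidate_interactions = "rats:ln_area"))
    !("rats:ln_area" %in% sf$final_spec$interactions)
  }, logical(1L))
  expect_gte(mean(rejections), 0.9)

  # strong interaction is retained
  tb_strong <- c("(Intercept)" = -2.3, "rats" = 1.2, "rats:ln_area" = -0.5)
  retained <- vapply(1:10, function(i) {
    ds <- simulate_dataset(sim_params(n_islands = 400L,
                                      true_beta = tb_strong),
                           seed = 900 + i)
    sf <- suppressWarnings(
      screen_and_force(ds, model_spec(c("rats", "ln_area")),
                       candidate_interactions = "rats:ln_area"))
    "rats:ln_area" %in% sf$final_spec$interactions
  }, logical(1L))
  expect_gte(mean(retained), 0.9)
})

test_that("a forced term set that does not clear its threshold is rejected and logged", {
  ds <- simulate_dataset(
    sim_params(n_islands = 400L,
               true_beta = c("(Intercept)" = -2.3, "human_presence" = 1.0)),
    seed = 95)
  sf <- screen_and_force(ds, model_spec(c("human_presence", "ln_area")),
                         forced = list(c("mice", "mice:ln_area")))
  expect_false("mice" %in% sf$final_spec$main_effects)
  expect_true(any(grepl("forced set mice\\+mice:ln_area: dQICu = .* rejected",
                        sf$audit_log)))
  expect_true("mice+mice:ln_area" %in% names(sf$deltas))
})

test_that("run_selection is deterministic and its audit log replays the final model", {
  ds <- make_fixture("paper_like", n_islands = 350L, seed = 99)
  cands <- c("class_volancy", "ln_area", "human_presence", "rats",
             "felids", "mustelids_mongooses")
  sel1 <- run_selection(ds, candidates = cands, max_order = 4L,
                        candidate_interactions = c("rats:ln_area"),
                        forced = list())
  sel2 <- run_selection(ds, candidates = cands, max_order = 4L,
                        candidate_interactions = c("rats:ln_area"),
                        forced = list())
  expect_identical(sel1$final_model, sel2$final_model)
  expect_identical(sel1$audit_log, sel2$audit_log)
  expect_gt(length(sel1$audit_log), 0L)

  # replay: reconstruct the final model from the audit log alone
  log <- sel1$audit_log
  base_line <- grep("^base model \\[", log, value = TRUE)
  mains <- strsplit(sub("^base model \\[(.*)\\] QICu.*$", "\\1", base_line),
                    "+", fixed = TRUE)[[1L]]
  kept <- sub("^interaction (\\S+): .*retained$", "\\1",
              grep("-> retained$", log, value = TRUE))
  forced_lines <- grep("^forced set .*-> added$", log, value = TRUE)
  forced_terms <- unlist(strsplit(sub("^forced set (\\S+): .*$", "\\1",
                                      forced_lines), "+", fixed = TRUE))
  replay_mains <- unique(c(mains,
                           setdiff(unlist(strsplit(c(kept, forced_terms),
                                                   ":")), NA)))
  replay_mains <- replay_mains[!grepl(":", replay_mains)]
  expect_setequal(replay_mains, sel1$final_model$main_effects)
  replay_inters <- unique(c(kept,
                            forced_terms[grepl(":", forced_terms)]))
  expect_setequal(replay_inters[nzchar(replay_inters)],
                  sel1$final_model$interactions)
})
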