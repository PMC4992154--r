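#' Choose a classification threshold at a target sensitivity
#'
#' Scans the distinct fitted risks as candidate thresholds (rule:
#' `risk >= threshold` predicts extirpation). Among thresholds whose
#' true-positive rate on the observed outcomes reaches `target_tpr`, the
#' one maximising the true-negative rate is returned (ties broken towards
#' the larger threshold). Extirpation predictions guide costly conservation
#' action, so a missed true extirpation (false negative) is treated as more
#' costly than a false alarm -- hence a sensitivity target rather than, say,
#' Youden's J. Alternate targets are evaluated for sensitivity analysis.
#'
#' @param fitted fitted risks in (0, 1).
#' @param labels 0/1 observed outcomes (both classes present).
#' @param target_tpr required sensitivity (default 0.80).
#' @param alternates additional TPR targets to tabulate (default 0.90, 0.95).
#' @return List of class `islex_threshold`: `threshold`, `achieved_tpr`,
#'   `achieved_tnr`, `target_tpr`, `alternates` (data.frame target_tpr,
#'   threshold, tpr, tnr).
#' @export
choose_threshold <- function(fitted, labels, target_tpr = 0.80,
                             alternates = c(0.90, 0.95)) {
  if (target_tpr <= 0 || target_tpr > 1) {
    stop("target_tpr must lie in (0, 1]", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (!all(c(0L, 1L) %in% labels)) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  pick <- function(tgt) {
    cand <- sort(unique(fitted))
    tpr <- vapply(cand, function(t) mean(fitted[labels == 1L] >= t),
                  numeric(1L))
    tnr <- vapply(cand, function(t) mean(fitted[labels == 0L] < t),
                  numeric(1L))
    ok <- tpr >= tgt
    if (!any(ok)) {  # even the smallest threshold misses the target
      i <- 1L
    } else {
      best_tnr <- max(tnr[ok])
      i <- max(which(ok & tnr == best_tnr))  # tie -> larger threshold
    }
    c(threshold = cand[i], tpr = tpr[i], tnr = tnr[i])
  }
  main <- pick(target_tpr)
  alt <- t(vapply(alternates, pick, numeric(3L)))
  structure(list(threshold = main[["threshold"]],
                 achieved_tpr = main[["tpr"]],
                 achieved_tnr = main[["tnr"]],
                 target_tpr = target_tpr,
                 alternates = data.frame(target_tpr = alternates,
                                         threshold = alt[, "threshold"],
                                         tpr = alt[, "tpr"],
                                         tnr = alt[, "tnr"])),
            class = "islex_threshold")
}

#' @export
print.islex_threshold <- function(x, ...) {
  cat(sprintf("threshold %.4f: TPR %.1f%% (target %.0f%%), TNR %.1f%%\n",
              x$threshold, 100 * x$achieved_tpr, 100 * x$target_tpr,
              100 * x$achieved_tnr))
  invisible(x)
}

#' Apply a counterfactual invasive-management scenario
#'
#' Returns a copy of the dataset in which the named invasive groups are set
#' absent (presence and eradication flags zeroed) on the filtered islands.
#' The default filter is the islands hosting at least one extant threatened
#' population -- the islands on which management could still avert an
#' extirpation. The input dataset is untouched.
#'
#' @param ds an [islex_dataset()].
#' @param managed_groups invasive group names to manage (eradicate).
#' @param island_filter character vector of island ids, or `NULL` for the
#'   default extant-population filter.
#' @return A modified [islex_dataset()].
#' @export
apply_scenario <- function(ds, managed_groups, island_filter = NULL) {
  stopifnot(inherits(ds, "islex_dataset"))
  unknown <- setdiff(managed_groups, invasive_groups())
  if (length(unknown) > 0L) {
    stop("unknown invasive group(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(island_filter)) {
    island_filter <- unique(ds$populations$island_id[
      ds$populations$extant == 1L])
  }
  sel <- ds$islands$island_id %in% island_filter
  for (g in managed_groups) {
    ds$islands[[g]][sel] <- 0L
    ds$islands[[paste0("eradicated_", g)]][sel] <- 0L
  }
  ds$provenance <- paste0(ds$provenance, " | scenario: managed ",
                          paste(managed_groups, collapse = ","))
  ds
}

# Design + risks for the extant populations under current presence.
extant_risks <- function(fit, ds) {
  dm <- build_design(ds, fit$spec, use_historical_presence = FALSE)
  keep <- dm$extant == 1L
  list(dm = design_subset(dm, which(keep)),
       risk = predict_probability(fit, design_subset(dm, which(keep))))
}

#' Classify extant populations at a threshold
#'
#' Predicts extirpation risk for every extant population (design built with
#' *current* invasive presence, i.e. eradications applied), classifies at
#' the threshold, and aggregates predicted-extirpation counts and fractions
#' overall, per class/volancy group (ranked), and among single-island
#' endemics.
#'
#' @param fit an [fit_gee()] result.
#' @param ds an [islex_dataset()].
#' @param threshold classification threshold in (0, 1) (or an
#'   `islex_threshold`).
#' @return List of class `islex_extant_summary`: `per_population`
#'   (data.frame species_id, island_id, class_volancy,
#'   single_island_endemic, risk, predicted_extirpated), `overall`
#'   (n_extant, n_predicted_extirpated, fraction), `by_class` (ranked
#'   data.frame), `endemic` (same for single-island endemics).
#' @export
predict_extant_summary <- function(fit, ds, threshold) {
  if (inherits(threshold, "islex_threshold")) threshold <- threshold$threshold
  er <- extant_risks(fit, ds)
  if (nrow(er$dm$X) == 0L) {
    return(structure(list(per_population = NULL,
                          overall = list(n_extant = 0L,
                                         n_predicted_extirpated = 0L,
                                         fraction = NA_real_),
                          by_class = NULL, endemic = NULL),
                     class = "islex_extant_summary"))
  }
  cls <- er$dm$class_volancy
  pp <- data.frame(species_id = er$dm$keys$species_id,
                   island_id = er$dm$keys$island_id,
                   class_volancy = cls,
                   single_island_endemic = er$dm$single_island_endemic,
                   risk = er$risk,
                   predicted_extirpated = as.integer(er$risk >= threshold),
                   stringsAsFactors = FALSE)
  by_class <- do.call(rbind, lapply(split(pp, pp$class_volancy), function(d) {
    data.frame(class_volancy = d$class_volancy[1L], n = nrow(d),
               n_predicted = sum(d$predicted_extirpated),
               fraction = mean(d$predicted_extirpated),
               stringsAsFactors = FALSE)
  }))
  by_class <- by_class[order(-by_class$fraction), , drop = FALSE]
  rownames(by_class) <- NULL
  end <- pp[pp$single_island_endemic == 1L, , drop = FALSE]
  structure(list(
    per_population = pp,
    overall = list(n_extant = nrow(pp),
                   n_predicted_extirpated = sum(pp$predicted_extirpated),
                   fraction = mean(pp$predicted_extirpated)),
    by_class = by_class,
    endemic = list(n = nrow(end),
                   n_predicted = sum(end$predicted_extirpated),
                   fraction = if (nrow(end)) mean(end$predicted_extirpated)
                              else NA_real_)),
    class = "islex_extant_summary")
}

#' @export
print.islex_extant_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf("extant populations: %d; predicted extirpated: %d (%.1f%%)\n",
              o$n_extant, o$n_predicted_extirpated, 100 * o$fraction))
  if (!is.null(x$by_class)) print(x$by_class, row.names = FALSE)
  invisible(x)
}

#' Counterfactual benefit of managing invasive mammals
#'
#' Compares each extant population's extirpation risk and classification
#' under current conditions (baseline) against the scenario in which the
#' managed groups are eradicated from the filtered islands. A predicted
#' extirpation is *preventable* if the baseline classifies it extirpated
#' but the managed scenario does not. The per-population extinction debt is
#' `baseline_risk - managed_risk`: the part of a population's extirpation
#' risk attributable to the managed invaders, i.e. the debt management
#' would cancel. Negative debts (possible when a managed group carries a
#' protective coefficient) are reported, not clipped.
#'
#' @param fit an [fit_gee()] result.
#' @param ds an [islex_dataset()].
#' @param threshold classification threshold (or `islex_threshold`).
#' @param managed_groups invasive groups to eradicate.
#' @param island_filter see [apply_scenario()].
#' @return List of class `islex_scenario`: `per_population` (baseline_risk,
#'   managed_risk, baseline_class, managed_class, preventable, debt),
#'   `aggregates` (n_extant, n_baseline_predicted, n_prevented,
#'   preventable_fraction, total_debt, mean_debt), `by_class`, `scenario`.
#' @export
scenario_benefit <- function(fit, ds, threshold, managed_groups,
                             island_filter = NULL) {
  if (inherits(threshold, "islex_threshold")) threshold <- threshold$threshold
  ds_managed <- apply_scenario(ds, managed_groups, island_filter)
  base <- extant_risks(fit, ds)
  man <- extant_risks(fit, ds_managed)
  stopifnot(identical(base$dm$keys, man$dm$keys))
  pp <- data.frame(species_id = base$dm$keys$species_id,
                   island_id = base$dm$keys$island_id,
                   class_volancy = base$dm$class_volancy,
                   single_island_endemic = base$dm$single_island_endemic,
                   baseline_risk = base$risk, managed_risk = man$risk,
                   baseline_class = as.integer(base$risk >= threshold),
                   managed_class = as.integer(man$risk >= threshold),
                   stringsAsFactors = FALSE)
  pp$preventable <- as.integer(pp$baseline_class == 1L &
                                 pp$managed_class == 0L)
  pp$debt <- pp$baseline_risk - pp$managed_risk
  pp <- pp[order(-pp$debt), , drop = FALSE]
  rownames(pp) <- NULL
  by_class <- do.call(rbind, lapply(split(pp, pp$class_volancy), function(d) {
    data.frame(class_volancy = d$class_volancy[1L], n = nrow(d),
               n_baseline_predicted = sum(d$baseline_class),
               n_prevented = sum(d$preventable),
               total_debt = sum(d$debt), stringsAsFactors = FALSE)
  }))
  by_class <- by_class[order(-by_class$total_debt), , drop = FALSE]
  rownames(by_class) <- NULL
  n_base <- sum(pp$baseline_class)
  structure(list(
    per_population = pp,
    aggregates = list(n_extant = nrow(pp),
                      n_baseline_predicted = n_base,
                      n_prevented = sum(pp$preventable),
                      preventable_fraction = if (n_base > 0L)
                        sum(pp$preventable) / n_base else NA_real_,
                      total_debt = sum(pp$debt),
                      mean_debt = mean(pp$debt)),
    by_class = by_class,
    scenario = managed_groups,
    threshold = threshold),
    class = "islex_scenario")
}

#' @export
print.islex_scenario <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("scenario: eradicate %s\n", paste(x$scenario, collapse = ", ")))
  cat(sprintf("baseline predicted extirpations: %d of %d extant\n",
              a$n_baseline_predicted, a$n_extant))
  cat(sprintf("preventable: %d (%.1f%% of predicted); total debt %.1f expected extirpations\n",
              a$n_prevented, 100 * a$preventable_fraction, a$total_debt))
  invisible(x)
}

#' Construct a covariate profile for odds ratios and risk sweeps
#'
#' A named list describing one hypothetical island population: class/volancy
#' level, covariate values on the data scale, and which invasive groups are
#' present (all others absent).
#'
#' @param class_volancy one of [class_volancy_levels()].
#' @param ln_area log island area (ln km^2).
#' @param precipitation annual precipitation (mm).
#' @param human_presence 0/1.
#' @param invasives character vector of present invasive groups.
#' @param ... further covariates (e.g. `elevation_residual`).
#' @return Named list of class `islex_profile`.
#' @export
make_profile <- function(class_volancy, ln_area, precipitation,
                         human_presence = 0, invasives = character(), ...) {
  stopifnot(class_volancy %in% class_volancy_levels())
  prof <- c(list(class_volancy = class_volancy, ln_area = ln_area,
                 precipitation = precipitation,
                 human_presence = human_presence), list(...))
  for (g in invasive_groups()) prof[[g]] <- as.numeric(g %in% invasives)
  structure(prof, class = "islex_profile")
}

# One design row for a profile, matching the fit's columns.
profile_row <- function(fit, profile) {
  cols <- names(fit$beta)
  resolve1 <- function(nm) {
    if (nm == "(Intercept)") return(1)
    if (startsWith(nm, "class_volancy=")) {
      return(as.numeric(sub("^class_volancy=", "", nm) ==
                          profile$class_volancy))
    }
    if (is.null(profile[[nm]])) {
      stop("profile is missing covariate: ", nm, call. = FALSE)
    }
    as.numeric(profile[[nm]])
  }
  x <- vapply(cols, function(cn) {
    prod(vapply(strsplit(cn, ":", fixed = TRUE)[[1L]], resolve1,
                numeric(1L)))
  }, numeric(1L))
  matrix(x, nrow = 1L, dimnames = list(NULL, cols))
}

#' Odds ratio between two covariate profiles
#'
#' Fitted risks `p_a`, `p_b` for the two profiles through the model, then
#' `[p_a/(1-p_a)] / [p_b/(1-p_b)]`. Because the link is complementary
#' log-log, exponentiated coefficients are *not* odds ratios; comparisons
#' are therefore made between fully specified profiles.
#'
#' @param fit an [fit_gee()] result.
#' @param profile_a,profile_b [make_profile()] objects (complete for the
#'   fitted spec).
#' @return A single positive number.
#' @export
odds_ratio <- function(fit, profile_a, profile_b) {
  p_a <- drop(risk_unclamped(profile_row(fit, profile_a) %*% fit$beta))
  p_b <- drop(risk_unclamped(profile_row(fit, profile_b) %*% fit$beta))
  if (any(c(p_a, p_b) <= 0) || any(c(p_a, p_b) >= 1)) {
    stop("fitted risk at 0 or 1; odds ratio undefined", call. = FALSE)
  }
  (p_a / (1 - p_a)) / (p_b / (1 - p_b))
}

#' Risk profile curves along one covariate
#'
#' Evaluates modelled extirpation risk along a sweep of one continuous
#' covariate, holding all other covariates at a fixed profile, for each of
#' several invasive-mammal scenarios (e.g. none / rats / cats / rats+cats).
#' Suitable for plotting risk-versus-area or risk-versus-precipitation
#' panels.
#'
#' @param fit an [fit_gee()] result.
#' @param sweep_variable covariate name (must be continuous and in the
#'   fitted spec; `class_volancy` is rejected).
#' @param sweep_values numeric vector of values to evaluate.
#' @param fixed_profile an [make_profile()] giving all other covariates.
#' @param scenarios named list; each element is a character vector of
#'   present invasive groups.
#' @return Long data.frame: `scenario`, `value`, `risk`.
#' @export
risk_profile <- function(fit, sweep_variable, sweep_values, fixed_profile,
                         scenarios = list(none = character())) {
  if (sweep_variable == "class_volancy") {
    stop("cannot sweep a categorical variable", call. = FALSE)
  }
  if (any(!is.finite(sweep_values))) {
    stop("sweep_values must be finite", call. = FALSE)
  }
  if (is.null(names(scenarios))) {
    names(scenarios) <- vapply(scenarios, function(s) {
      if (length(s)) paste(s, collapse = "+") else "none"
    }, character(1L))
  }
  out <- lapply(names(scenarios), function(sn) {
    prof <- fixed_profile
    for (g in invasive_groups()) {
      prof[[g]] <- as.numeric(g %in% scenarios[[sn]])
    }
    risk <- vapply(sweep_values, function(v) {
      prof[[sweep_variable]] <- v
      drop(risk_unclamped(profile_row(fit, prof) %*% fit$beta))
    }, numeric(1L))
    data.frame(scenario = sn, value = sweep_values, risk = risk,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
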