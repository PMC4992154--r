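#' Enumerate candidate term subsets of one order
#'
#' @param candidates character vector of candidate term names.
#' @param order subset size.
#' @return List of character vectors, in `combn` order.
#' @export
all_subsets_terms <- function(candidates, order) {
  if (order < 1L || order > length(candidates)) {
    stop("order must lie in [1, length(candidates)]", call. = FALSE)
  }
  m <- utils::combn(candidates, order, simplify = FALSE)
  m
}

fit_spec_gee <- function(ds, mains, interactions = character(),
                         reference_level = "amphibian", ...) {
  spec <- model_spec(mains, interactions, reference_level)
  dm <- build_design(ds, spec)
  fit_gee(dm, ...)
}

#' Rank all models of one order by QICu
#'
#' Fits every `choose(length(candidates), order)` main-effects model of the
#' given order and ranks them by QICu. All models are fit on the
#' complete-case rows of the full candidate design (information criteria
#' are only comparable across models fit to the same data), warm-started
#' from the full-model coefficients. Models failing to converge are
#' recorded with a flag and excluded from the ranking. The "top set"
#' (`in_top`) is the models within 2 QICu of the best. QICu ties are broken
#' lexicographically by the `+`-joined term string.
#'
#' @param ds an [islex_dataset()].
#' @param candidates candidate main-effect names.
#' @param order model order (number of terms).
#' @param reference_level class/volancy dummy reference.
#' @return A list of class `islex_rank`: `table` (data.frame with terms,
#'   qicu, delta_qicu, in_top, converged, mse), `coefs` (named list of
#'   coefficient vectors for converged models), `order`.
#' @export
all_subsets_rank <- function(ds, candidates, order,
                             reference_level = "amphibian") {
  subsets <- all_subsets_terms(candidates, order)
  terms_str <- vapply(subsets, paste, character(1L), collapse = "+")
  qicu_v <- rep(NA_real_, length(subsets))
  mse_v <- rep(NA_real_, length(subsets))
  conv <- logical(length(subsets))
  coefs <- vector("list", length(subsets))
  # one design + fit over all candidates; subsets warm-start from it
  full_dm <- build_design(ds, model_spec(candidates,
                                         reference_level = reference_level))
  full_fit <- tryCatch(fit_gee(full_dm), error = function(e) NULL)
  for (i in seq_along(subsets)) {
    fit <- tryCatch({
      spec_i <- model_spec(subsets[[i]], reference_level = reference_level)
      cols_i <- c("(Intercept)",
                  unlist(lapply(subsets[[i]], function(tm)
                    full_dm$term_map$column[full_dm$term_map$term == tm])))
      dm_i <- full_dm
      dm_i$X <- full_dm$X[, cols_i, drop = FALSE]
      dm_i$term_map <- full_dm$term_map[match(cols_i,
                                              full_dm$term_map$column), ]
      dm_i$spec <- spec_i
      b0 <- if (!is.null(full_fit)) full_fit$beta[cols_i] else NULL
      f <- suppressWarnings(fit_gee(dm_i, beta_init = b0))
      if (!f$converged || f$score_norm > 1e-4) {
        # warm start led astray; refit from the independence-GLM init
        f <- fit_gee(dm_i)
      }
      f
    }, error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      conv[i] <- TRUE
      qicu_v[i] <- fit$qicu
      mse_v[i] <- fit$mse
      coefs[[i]] <- fit$beta
    }
  }
  tab <- data.frame(terms = terms_str, qicu = qicu_v, mse = mse_v,
                    converged = conv, stringsAsFactors = FALSE)
  ord <- order(ifelse(tab$converged, tab$qicu, Inf), tab$terms)
  tab <- tab[ord, , drop = FALSE]
  coefs <- coefs[ord]
  best <- min(tab$qicu[tab$converged], na.rm = TRUE)
  tab$delta_qicu <- tab$qicu - best
  tab$in_top <- tab$converged & tab$delta_qicu < 2
  names(coefs) <- tab$terms
  structure(list(table = tab, coefs = coefs, order = order),
            class = "islex_rank")
}

#' Average coefficients over the top model set
#'
#' Akaike-type weights `w ~ exp(-delta_QICu / 2)` over the models with
#' `delta_QICu < 2`, normalised to sum to 1; coefficients absent from a
#' model contribute zero (full / zero-filled averaging).
#'
#' @param ranked an [all_subsets_rank()] result.
#' @return List: `weights` (named by term string), `coefficients`
#'   (zero-filled weighted average), `terms` (union of member terms).
#' @export
average_top_models <- function(ranked) {
  stopifnot(inherits(ranked, "islex_rank"))
  top <- which(ranked$table$in_top)
  if (length(top) == 0L) stop("no converged models in the top set",
                              call. = FALSE)
  delta <- ranked$table$delta_qicu[top]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  names(w) <- ranked$table$terms[top]
  all_cols <- unique(unlist(lapply(ranked$coefs[top], names)))
  avg <- stats::setNames(rep(0, length(all_cols)), all_cols)
  for (k in seq_along(top)) {
    b <- ranked$coefs[[top[k]]]
    avg[names(b)] <- avg[names(b)] + w[k] * b
  }
  term_union <- unique(unlist(strsplit(names(w), "+", fixed = TRUE)))
  list(weights = w, coefficients = avg, terms = term_union)
}

#' MSE-by-order curve and order choice
#'
#' For each order from 1 to `max_order`, ranks all subsets by QICu, averages
#' the top (`delta < 2`) models, computes the in-sample MSE (Brier score) of
#' the averaged coefficients, and chooses the smallest order `k` at which
#' the relative MSE improvement from `k` to `k+1` falls below `rel_tol`
#' (diminishing-returns rule; with `rel_tol = 0` the rule only stops when
#' MSE stops strictly decreasing).
#'
#' @param ds an [islex_dataset()].
#' @param candidates candidate main-effect names.
#' @param max_order largest order to scan (default all candidates).
#' @param rel_tol relative-improvement stopping tolerance (default 0.005).
#' @param reference_level class/volancy dummy reference.
#' @return List of class `islex_order_curve`: `curve` (data.frame order,
#'   mse, best_terms, n_top), `chosen_order`, `base_terms` (top model at
#'   the chosen order), `ranks` (per-order rank objects).
#' @export
order_curve_and_choice <- function(ds, candidates,
                                   max_order = length(candidates),
                                   rel_tol = 0.005,
                                   reference_level = "amphibian") {
  stopifnot(max_order >= 1L, max_order <= length(candidates))
  # one design over all candidates; averaged coefficients index into it
  full_dm <- build_design(ds, model_spec(candidates,
                                         reference_level = reference_level))
  mse_k <- rep(NA_real_, max_order)
  best_terms <- character(max_order)
  n_top <- integer(max_order)
  ranks <- vector("list", max_order)
  for (k in seq_len(max_order)) {
    rk <- all_subsets_rank(ds, candidates, k,
                           reference_level = reference_level)
    ranks[[k]] <- rk
    avg <- average_top_models(rk)
    mu <- cloglog_parts(drop(full_dm$X[, names(avg$coefficients),
                                       drop = FALSE] %*%
                               avg$coefficients))$mu
    mse_k[k] <- mean((as.numeric(full_dm$y) - mu)^2)
    best_terms[k] <- rk$table$terms[which(rk$table$in_top)[1L]]
    n_top[k] <- sum(rk$table$in_top)
  }
  chosen <- max_order
  if (max_order > 1L) {
    for (k in seq_len(max_order - 1L)) {
      improvement <- (mse_k[k] - mse_k[k + 1L]) / mse_k[k]
      if (improvement < rel_tol) {
        chosen <- k
        break
      }
    }
  } else chosen <- 1L
  if (any(diff(mse_k) > 0)) {
    message("MSE-by-order curve is not monotone decreasing; rule applied as stated")
  }
  structure(list(curve = data.frame(order = seq_len(max_order), mse = mse_k,
                                    best_terms = best_terms, n_top = n_top,
                                    stringsAsFactors = FALSE),
                 chosen_order = chosen,
                 base_terms = strsplit(best_terms[chosen], "+",
                                       fixed = TRUE)[[1L]],
                 ranks = ranks),
            class = "islex_order_curve")
}

#' Interaction screening and forced-term addition
#'
#' Starting from a base main-effects model, tests each candidate interaction
#' sequentially (in the given order), adding any main effects the
#' interaction needs; an interaction is retained iff it decreases QICu by
#' more than `delta_threshold` (default 10, a conservative improvement
#' limit), and retained terms stay in the model for subsequent tests.
#' Forced term sets (e.g. a rat main effect plus rat-by-area interaction)
#' are then added jointly iff their joint addition decreases QICu by more
#' than `forced_threshold` (default 20); otherwise they are rejected with a
#' log entry.
#'
#' @param ds an [islex_dataset()].
#' @param base an [model_spec()] (mains only or with interactions).
#' @param candidate_interactions character vector of `"a:b"` strings.
#' @param forced list of character vectors; each element is a term set added
#'   jointly (interactions recognised by `":"`).
#' @param delta_threshold,forced_threshold QICu improvement thresholds.
#' @return List of class `islex_screenforce`: `final_spec`,
#'   `retained_interactions`, `forced_added`, `audit_log` (character),
#'   `deltas` (named numeric of QICu improvements).
#' @export
screen_and_force <- function(ds, base, candidate_interactions = character(),
                             forced = list(), delta_threshold = 10,
                             forced_threshold = 20) {
  stopifnot(inherits(base, "islex_model_spec"))
  mains <- base$main_effects
  inters <- base$interactions
  log_lines <- character()
  deltas <- numeric()
  current_fit <- fit_spec_gee(ds, mains, inters, base$reference_level)
  current_qicu <- current_fit$qicu
  log_lines <- c(log_lines,
                 sprintf("base model [%s] QICu = %.3f",
                         paste(mains, collapse = "+"), current_qicu))
  for (ia in candidate_interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1L]]
    need <- setdiff(parts, mains)
    trial_mains <- c(mains, need)
    trial_inters <- c(inters, ia)
    trial <- tryCatch(fit_spec_gee(ds, trial_mains, trial_inters,
                                   base$reference_level),
                      error = function(e) NULL)
    if (is.null(trial) || !trial$converged) {
      log_lines <- c(log_lines,
                     sprintf("interaction %s: fit failed/non-convergent -> skipped", ia))
      next
    }
    d <- current_qicu - trial$qicu
    deltas[ia] <- d
    if (d > delta_threshold) {
      mains <- trial_mains
      inters <- trial_inters
      current_qicu <- trial$qicu
      log_lines <- c(log_lines,
                     sprintf("interaction %s: dQICu = %.3f > %g -> retained",
                             ia, d, delta_threshold))
    } else {
      log_lines <- c(log_lines,
                     sprintf("interaction %s: dQICu = %.3f <= %g -> rejected",
                             ia, d, delta_threshold))
    }
  }
  forced_added <- list()
  for (fs in forced) {
    fs_inters <- fs[grepl(":", fs, fixed = TRUE)]
    fs_mains <- setdiff(fs, fs_inters)
    trial_mains <- unique(c(mains, fs_mains,
                            setdiff(unlist(strsplit(fs_inters, ":")), mains)))
    trial_inters <- unique(c(inters, fs_inters))
    trial <- tryCatch(fit_spec_gee(ds, trial_mains, trial_inters,
                                   base$reference_level),
                      error = function(e) NULL)
    lbl <- paste(fs, collapse = "+")
    if (is.null(trial) || !trial$converged) {
      log_lines <- c(log_lines,
                     sprintf("forced set %s: fit failed -> rejected", lbl))
      next
    }
    d <- current_qicu - trial$qicu
    deltas[lbl] <- d
    if (d > forced_threshold) {
      mains <- trial_mains
      inters <- trial_inters
      current_qicu <- trial$qicu
      forced_added <- c(forced_added, list(fs))
      log_lines <- c(log_lines,
                     sprintf("forced set %s: dQICu = %.3f > %g -> added",
                             lbl, d, forced_threshold))
    } else {
      log_lines <- c(log_lines,
                     sprintf("forced set %s: dQICu = %.3f <= %g -> rejected",
                             lbl, d, forced_threshold))
    }
  }
  structure(list(final_spec = model_spec(mains, inters,
                                         base$reference_level),
                 retained_interactions = inters,
                 forced_added = forced_added,
                 audit_log = log_lines, deltas = deltas),
            class = "islex_screenforce")
}

#' Run the full model-selection procedure
#'
#' End-to-end selection: (1) covariate screening drops rare invasive groups
#' (and reports collinear pairs); (2) order-wise all-subsets QICu ranking
#' with top-set averaging gives the MSE-by-order curve and the chosen order;
#' (3) the top model at the chosen order becomes the base; (4) candidate
#' interactions are screened at `dQICu > 10`; (5) forced term sets are
#' tested at `dQICu > 20`. Deterministic given data and configuration.
#'
#' @param ds an [islex_dataset()].
#' @param candidates candidate main-effect names; defaults to class/volancy,
#'   the abiotic covariates and all non-excluded invasive groups.
#' @param candidate_interactions,forced passed to [screen_and_force()].
#' @param max_order,rel_tol passed to [order_curve_and_choice()].
#' @param prevalence_threshold,r_threshold passed to [covariate_screen()].
#' @param reference_level class/volancy dummy reference.
#' @return List of class `islex_selection`: `screen`, `order_curve`,
#'   `chosen_order`, `base_model`, `final_model`, `screenforce`,
#'   `audit_log`.
#' @export
run_selection <- function(ds, candidates = NULL,
                          candidate_interactions = c(
                            "class_volancy:ln_area",
                            "class_volancy:precipitation",
                            "class_volancy:felids",
                            "class_volancy:pigs"),
                          forced = list(c("rats", "rats:ln_area")),
                          max_order = NULL, rel_tol = 0.005,
                          prevalence_threshold = 0.10, r_threshold = 0.7,
                          reference_level = "amphibian") {
  scr <- covariate_screen(ds, r_threshold = r_threshold,
                          prevalence_threshold = prevalence_threshold)
  if (is.null(candidates)) {
    candidates <- c("class_volancy", "ln_area", "elevation_residual",
                    "precipitation", "mean_temperature", "ln_seasonality",
                    "human_presence", invasive_groups())
  }
  audit <- sprintf("screening: excluded rare invasive group(s): %s",
                   if (length(scr$excluded_groups))
                     paste(scr$excluded_groups, collapse = ", ") else "none")
  candidates <- setdiff(candidates, scr$excluded_groups)
  if (is.null(max_order)) max_order <- length(candidates)
  audit <- c(audit, sprintf("candidate mains (%d): %s", length(candidates),
                            paste(candidates, collapse = ", ")))
  oc <- order_curve_and_choice(ds, candidates, max_order = max_order,
                               rel_tol = rel_tol,
                               reference_level = reference_level)
  audit <- c(audit,
             sprintf("order %d: MSE = %.5f (top set size %d, best: %s)",
                     oc$curve$order, oc$curve$mse, oc$curve$n_top,
                     oc$curve$best_terms),
             sprintf("chosen order: %d (relative MSE improvement < %g)",
                     oc$chosen_order, rel_tol))
  base <- model_spec(oc$base_terms, reference_level = reference_level)
  sf <- screen_and_force(ds, base, candidate_interactions, forced)
  audit <- c(audit, sf$audit_log)
  structure(list(screen = scr, order_curve = oc,
                 chosen_order = oc$chosen_order,
                 base_model = base, final_model = sf$final_spec,
                 screenforce = sf, audit_log = audit),
            class = "islex_selection")
}

#' @export
print.islex_selection <- function(x, ...) {
  cat("model selection result\n")
  cat("chosen order:", x$chosen_order, "\n")
  cat("base mains:", paste(x$base_model$main_effects, collapse = " + "), "\n")
  print(x$final_model)
  invisible(x)
}
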