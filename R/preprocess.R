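#' Add derived covariates to the island table
#'
#' Natural-log transforms for the skewed strictly-positive covariates
#' (`ln_area`, `ln_seasonality`) and the area-elevation residual. Island
#' area and maximum elevation are strongly collinear, so elevation enters
#' the analysis as the residual of an ordinary least-squares regression of
#' `log(elevation + 1)` on `ln_area` -- the portion of elevational variation
#' (topographic complexity) independent of island size. The +1 offset keeps
#' zero-elevation atolls in the data. Precipitation is left untransformed.
#'
#' @param islands island data.frame (validated as in [islex_dataset()]).
#' @return The island table with columns `ln_area`, `ln_seasonality`,
#'   `ln_elevation`, `elevation_residual` appended.
#' @export
transform_covariates <- function(islands) {
  bad <- !is.finite(islands$area) | islands$area <= 0
  if (any(bad)) {
    stop("nonpositive area for island(s): ",
         paste(utils::head(islands$island_id[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  if (any(islands$temperature_seasonality <= 0, na.rm = TRUE)) {
    stop("temperature_seasonality must be > 0", call. = FALSE)
  }
  islands$ln_area <- log(islands$area)
  islands$ln_seasonality <- log(islands$temperature_seasonality)
  islands$ln_elevation <- log(pmax(islands$elevation, 0) + 1)
  ok <- is.finite(islands$ln_elevation) & is.finite(islands$ln_area)
  fit <- stats::lm.fit(cbind(1, islands$ln_area[ok]),
                       islands$ln_elevation[ok])
  islands$elevation_residual <- NA_real_
  islands$elevation_residual[ok] <- fit$residuals
  islands
}

#' Screen covariates for collinearity, rarity and missingness
#'
#' Three pre-modelling filters: (1) pairwise Pearson correlations among the
#' continuous island covariates (plus the binary human-presence indicator),
#' flagging pairs with `|r|` above `r_threshold`; (2) invasive mammal groups
#' present on fewer than `prevalence_threshold` of islands, flagged for
#' exclusion (too rare to estimate a stable effect); (3) covariates whose
#' missingness fraction exceeds `max_missing` (body mass is screened from
#' the population table).
#'
#' @param ds an [islex_dataset()].
#' @param r_threshold absolute Pearson correlation above which a pair is
#'   flagged (default 0.7).
#' @param prevalence_threshold minimum fraction of islands on which an
#'   invasive group must occur (default 0.10).
#' @param max_missing maximum tolerated missingness fraction (default 0.10).
#' @return A list of class `islex_screen`: `correlations` (long data.frame
#'   with columns var1, var2, r; `r` is `NA` for constant columns),
#'   `flagged_pairs`, `group_prevalence`, `excluded_groups`,
#'   `high_missingness`.
#' @export
covariate_screen <- function(ds, r_threshold = 0.7,
                             prevalence_threshold = 0.10,
                             max_missing = 0.10) {
  stopifnot(inherits(ds, "islex_dataset"))
  isl <- ds$islands
  if (!"ln_area" %in% names(isl)) isl <- transform_covariates(isl)
  cont <- c("ln_area", "ln_elevation", "precipitation", "mean_temperature",
            "ln_seasonality", "human_presence")
  cont <- intersect(cont, names(isl))
  cm <- isl[, cont, drop = FALSE]
  pairs <- utils::combn(cont, 2L)
  r <- apply(pairs, 2L, function(p) {
    x <- cm[[p[1L]]]; y <- cm[[p[2L]]]
    if (stats::sd(x, na.rm = TRUE) == 0 || stats::sd(y, na.rm = TRUE) == 0) {
      return(NA_real_)  # undefined for constant columns
    }
    stats::cor(x, y, use = "complete.obs")
  })
  correlations <- data.frame(var1 = pairs[1L, ], var2 = pairs[2L, ], r = r,
                             stringsAsFactors = FALSE)
  flagged <- correlations[!is.na(correlations$r) &
                            abs(correlations$r) > r_threshold, , drop = FALSE]
  prev <- vapply(invasive_groups(), function(g) mean(isl[[g]] == 1L),
                 numeric(1L))
  excluded <- names(prev)[prev < prevalence_threshold]
  miss <- c(vapply(cont, function(v) mean(is.na(isl[[v]])), numeric(1L)),
            body_mass = mean(is.na(ds$populations$body_mass)))
  structure(list(correlations = correlations, flagged_pairs = flagged,
                 group_prevalence = prev, excluded_groups = excluded,
                 high_missingness = names(miss)[miss > max_missing],
                 missingness = miss),
            class = "islex_screen")
}

#' @export
print.islex_screen <- function(x, ...) {
  cat("covariate screening\n")
  if (nrow(x$flagged_pairs)) {
    cat("collinear pairs (|r| above threshold):\n")
    print(x$flagged_pairs, row.names = FALSE)
  } else cat("no collinear pairs flagged\n")
  cat("invasive groups excluded for rarity:",
      if (length(x$excluded_groups)) paste(x$excluded_groups, collapse = ", ")
      else "none", "\n")
  cat("high-missingness covariates:",
      if (length(x$high_missingness)) paste(x$high_missingness, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Ordination of invasive-group co-occurrence
#'
#' Diagnostic 2-D embedding of the invasive mammal groups based on the
#' Euclidean distance between their presence/absence profiles across
#' islands (groups are the points, islands the samples). Initialised by
#' classical (metric) multidimensional scaling and refined by iterative
#' stress majorization (SMACOF Guttman transform); raw stress is
#' non-increasing across iterations by construction. Reported stress is
#' Kruskal's stress-1. Used to check for strong co-occurrence clusters of
#' invasive groups before modelling; a diffuse embedding supports keeping
#' all groups.
#'
#' @param islands island data.frame with invasive-group columns filled.
#' @param k embedding dimension (default 2).
#' @param max_iter,tol majorization iteration controls.
#' @return A list of class `islex_ordination`: `points` (groups x k),
#'   `stress` (Kruskal stress-1), `stress_trace` (raw stress per iteration),
#'   `distances` (input distance matrix).
#' @export
cooccurrence_ordination <- function(islands, k = 2L, max_iter = 500L,
                                    tol = 1e-10) {
  groups <- intersect(invasive_groups(), names(islands))
  if (length(groups) < 3L) {
    stop("need at least 3 invasive groups for a ", k, "-D ordination",
         call. = FALSE)
  }
  X <- t(as.matrix(islands[, groups, drop = FALSE]))  # groups x islands
  D <- as.matrix(stats::dist(X))
  n <- nrow(D)
  if (k >= n) stop("embedding dimension must be < number of groups",
                   call. = FALSE)
  Z <- stats::cmdscale(D, k = k)
  if (ncol(Z) < k) {  # degenerate configuration; pad with zeros
    Z <- cbind(Z, matrix(0, n, k - ncol(Z)))
  }
  raw_stress <- function(Z) {
    dz <- as.matrix(stats::dist(Z))
    sum((D[upper.tri(D)] - dz[upper.tri(dz)])^2)
  }
  trace <- raw_stress(Z)
  for (it in seq_len(max_iter)) {
    dz <- as.matrix(stats::dist(Z))
    B <- matrix(0, n, n)
    nz <- dz > 0
    B[nz] <- -D[nz] / dz[nz]
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Z_new <- B %*% Z / n
    s_new <- raw_stress(Z_new)
    trace <- c(trace, s_new)
    if (abs(trace[it] - s_new) < tol * max(trace[1L], 1)) {
      Z <- Z_new
      break
    }
    Z <- Z_new
  }
  dz <- as.matrix(stats::dist(Z))
  denom <- sum(dz[upper.tri(dz)]^2)
  stress1 <- if (denom > 0) {
    sqrt(sum((D[upper.tri(D)] - dz[upper.tri(dz)])^2) / denom)
  } else 0
  rownames(Z) <- groups
  structure(list(points = Z, stress = stress1, stress_trace = trace,
                 distances = D),
            class = "islex_ordination")
}

#' Declare a model: main effects and interactions
#'
#' A declarative term list for the extirpation model. Main effects are named
#' covariates of the joined island-population table (`class_volancy`,
#' `ln_area`, `precipitation`, `human_presence`, `elevation_residual`,
#' `ln_seasonality`, `mean_temperature`, `body_mass`, or any invasive group
#' name). Interactions are `"a:b"` strings over those terms. `class_volancy`
#' is dummy-coded against `reference_level`.
#'
#' @param main_effects character vector of term names (no duplicates).
#' @param interactions character vector of `"a:b"` interaction strings.
#' @param reference_level baseline class/volancy level (default
#'   `"amphibian"`, the alphabetical first, for determinism).
#' @return An object of class `islex_model_spec`.
#' @export
model_spec <- function(main_effects, interactions = character(),
                       reference_level = "amphibian") {
  stopifnot(is.character(main_effects), is.character(interactions))
  if (anyDuplicated(main_effects)) {
    stop("duplicate main effects", call. = FALSE)
  }
  if (anyDuplicated(interactions)) {
    stop("duplicate interactions", call. = FALSE)
  }
  if (!reference_level %in% class_volancy_levels()) {
    stop("unknown reference level: ", reference_level, call. = FALSE)
  }
  parts <- strsplit(interactions, ":", fixed = TRUE)
  for (p in parts) {
    if (length(p) != 2L) {
      stop("interactions must be 'a:b' pairs", call. = FALSE)
    }
  }
  structure(list(main_effects = main_effects, interactions = interactions,
                 reference_level = reference_level),
            class = "islex_model_spec")
}

#' @export
print.islex_model_spec <- function(x, ...) {
  cat("model spec:", length(x$main_effects), "main effect(s),",
      length(x$interactions), "interaction(s)\n")
  cat("  mains:", paste(x$main_effects, collapse = " + "), "\n")
  if (length(x$interactions)) {
    cat("  interactions:", paste(x$interactions, collapse = " + "), "\n")
  }
  cat("  class/volancy reference:", x$reference_level, "\n")
  invisible(x)
}

#' The final extirpation model
#'
#' Convenience constructor for the selected model: eight main effects
#' (class/volancy, ln island area, annual precipitation, human presence,
#' invasive cats, rats, pigs, mustelids/mongooses) and five interactions
#' (class/volancy with area, precipitation, cats and pigs, plus rat-by-area).
#'
#' @param reference_level baseline class/volancy level.
#' @return An `islex_model_spec`.
#' @export
final_model_spec <- function(reference_level = "amphibian") {
  model_spec(
    main_effects = c("class_volancy", "ln_area", "precipitation",
                     "human_presence", "felids", "rats", "pigs",
                     "mustelids_mongooses"),
    interactions = c("class_volancy:ln_area", "class_volancy:precipitation",
                     "class_volancy:felids", "class_volancy:pigs",
                     "rats:ln_area"),
    reference_level = reference_level
  )
}

# Resolve one term name to a named list of numeric columns over the joined
# table. class_volancy expands to indicator columns against the reference.
resolve_term <- function(term, joined, reference_level) {
  if (term == "class_volancy") {
    levs <- setdiff(class_volancy_levels(), reference_level)
    cols <- lapply(levs, function(l) as.numeric(joined$class_volancy == l))
    names(cols) <- paste0("class_volancy=", levs)
    return(cols)
  }
  if (!term %in% names(joined)) {
    stop("model spec references unavailable covariate: ", term,
         call. = FALSE)
  }
  out <- list(as.numeric(joined[[term]]))
  names(out) <- term
  out
}

#' Build the numeric design matrix with cluster index
#'
#' Joins populations to (transformed) islands, orders rows by island then
#' species id, and encodes the model terms: intercept, class/volancy dummies
#' against the reference level, continuous/binary main effects, and
#' interactions as elementwise products of the encoded columns. Invasive
#' presence is taken as *historical* presence (eradicated groups still
#' count as present) when `use_historical_presence = TRUE` -- the fitting
#' convention, since eradicated invaders were present long enough to drive
#' extirpations -- and as *current* presence (presence AND NOT eradicated)
#' otherwise, the prediction convention. Rows with missing values in any
#' required column are dropped with a message.
#'
#' @param ds an [islex_dataset()].
#' @param spec an [model_spec()].
#' @param use_historical_presence logical flag (default `TRUE`).
#' @return An object of class `islex_design`: list with `y` (0/1 response),
#'   `X` (numeric matrix with named columns, intercept first), `cluster`
#'   (island id per row), `term_map` (data.frame column -> term), `keys`
#'   (species_id/island_id per row), `spec`, `n_dropped`.
#' @export
build_design <- function(ds, spec, use_historical_presence = TRUE) {
  stopifnot(inherits(ds, "islex_dataset"), inherits(spec, "islex_model_spec"))
  isl <- ds$islands
  if (!"ln_area" %in% names(isl)) isl <- transform_covariates(isl)
  if (!use_historical_presence) {
    for (g in invasive_groups()) {
      isl[[g]] <- as.integer(isl[[g]] == 1L &
                               isl[[paste0("eradicated_", g)]] == 0L)
    }
  }
  joined <- merge(ds$populations, isl, by = "island_id", sort = FALSE)
  joined <- joined[order(joined$island_id, joined$species_id), , drop = FALSE]

  cols <- list(`(Intercept)` = rep(1, nrow(joined)))
  term_of <- c(`(Intercept)` = "(Intercept)")
  resolved <- list()
  for (term in spec$main_effects) {
    rc <- resolve_term(term, joined, spec$reference_level)
    resolved[[term]] <- rc
    cols <- c(cols, rc)
    term_of <- c(term_of, stats::setNames(rep(term, length(rc)), names(rc)))
  }
  for (ia in spec$interactions) {
    ab <- strsplit(ia, ":", fixed = TRUE)[[1L]]
    ra <- if (!is.null(resolved[[ab[1L]]])) resolved[[ab[1L]]] else
      resolve_term(ab[1L], joined, spec$reference_level)
    rb <- if (!is.null(resolved[[ab[2L]]])) resolved[[ab[2L]]] else
      resolve_term(ab[2L], joined, spec$reference_level)
    for (na in names(ra)) {
      for (nb in names(rb)) {
        nm <- paste(na, nb, sep = ":")
        cols[[nm]] <- ra[[na]] * rb[[nb]]
        term_of <- c(term_of, stats::setNames(ia, nm))
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  y <- joined$outcome
  keep <- stats::complete.cases(X) & !is.na(y)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " row(s) dropped for missing covariate values")
  }
  structure(list(y = as.integer(y[keep]),
                 X = X[keep, , drop = FALSE],
                 cluster = joined$island_id[keep],
                 term_map = data.frame(column = names(cols),
                                       term = unname(term_of[names(cols)]),
                                       stringsAsFactors = FALSE),
                 keys = joined[keep, c("species_id", "island_id"),
                               drop = FALSE],
                 extant = joined$extant[keep],
                 class_volancy = joined$class_volancy[keep],
                 single_island_endemic = joined$single_island_endemic[keep],
                 spec = spec,
                 use_historical_presence = use_historical_presence,
                 n_dropped = n_dropped),
            class = "islex_design")
}

#' @export
print.islex_design <- function(x, ...) {
  cat(sprintf("islex_design: %d rows x %d columns, %d clusters (%d dropped)\n",
              nrow(x$X), ncol(x$X), length(unique(x$cluster)), x$n_dropped))
  invisible(x)
}

# Subset a design by row index, preserving structure.
design_subset <- function(dm, idx) {
  out <- dm
  out$y <- dm$y[idx]
  out$X <- dm$X[idx, , drop = FALSE]
  out$cluster <- dm$cluster[idx]
  out$keys <- dm$keys[idx, , drop = FALSE]
  out$extant <- dm$extant[idx]
  out$class_volancy <- dm$class_volancy[idx]
  out$single_island_endemic <- dm$single_island_endemic[idx]
  out
}
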