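#' Parameters of the synthetic island-extirpation generator
#'
#' Defines the ground-truth generative model used for testing the pipeline:
#' log-normal island areas, human presence increasing in log area,
#' precipitation increasing in log area (truncated at 0), per-group logistic
#' invasive occupancy driven by human presence and log area, a zero-truncated
#' geometric number of threatened populations per island, and binary
#' extirpation outcomes with marginal probability `cloglog_inv(x' true_beta)`
#' and within-island dependence induced by a Gaussian copula with
#' exchangeable latent correlation.
#'
#' Defaults emulate the global threatened-island study conditions: about a
#' thousand islands carrying ~2.6 threatened populations each (~2,600
#' records), ~25% extirpation prevalence, 54% of islands uninhabited with
#' uninhabited islands smaller and drier (median areas ~0.6 vs ~134 km^2 for
#' inhabited, ~9.7 km^2 overall; median precipitation ~907 vs ~1,762 mm),
#' ~73% of islands carrying at least one invasive mammal group, uninhabited
#' islands dominated by rat/cat-only combinations, mustelids/mongooses on
#' ~11% of islands, and four rare groups (primates, medium omnivores, small
#' omnivores, medium herbivores) below 10% occupancy.
#'
#' @param n_islands number of islands.
#' @param true_beta named coefficient vector on the cloglog scale. Names are
#'   `"(Intercept)"`, covariate names (`ln_area`, `precipitation`,
#'   `human_presence`, invasive group names), `"class_volancy=<level>"`
#'   indicators (amphibian is the implicit reference), and `":"`-joined
#'   interactions of these.
#' @param exchangeable_rho target pairwise Pearson correlation of outcomes
#'   within an island, in \[0, 1).
#' @param island_area_log_mean,island_area_log_sd parameters of ln(area/km^2).
#' @param inhabited_intercept,inhabited_slope logistic model for human
#'   presence on ln area.
#' @param precip_intercept,precip_slope,precip_sd precipitation (mm) as a
#'   normal in ln area, truncated at 0.
#' @param occupancy_model numeric matrix, one row per invasive group, columns
#'   `intercept`, `human`, `ln_area`: per-group logistic occupancy model.
#' @param eradication_prob named numeric: probability that a present group
#'   has been eradicated (historical-only presence).
#' @param species_geom_prob success probability of the zero-truncated
#'   geometric count of populations per island (mean = 1/prob).
#' @param p_shared_species probability a population belongs to a widespread
#'   (multi-island) species rather than a new single-island endemic.
#' @param class_mix named 6-vector of class/volancy proportions (sums to 1).
#' @return A list of class `islex_sim_params`.
#' @export
sim_params <- function(n_islands = 1000L,
                       true_beta = default_true_beta(),
                       exchangeable_rho = 0.2,
                       island_area_log_mean = log(9.7),
                       island_area_log_sd = 3.8,
                       inhabited_intercept = -3.214,
                       inhabited_slope = 1.2,
                       precip_intercept = 964,
                       precip_slope = 150,
                       precip_sd = 620,
                       occupancy_model = default_occupancy_model(),
                       eradication_prob = c(felids = 0.04, rats = 0.04),
                       species_geom_prob = 1 / 2.6,
                       p_shared_species = 0.25,
                       class_mix = c(amphibian = 0.10, bat = 0.08,
                                     nonvolant_bird = 0.10,
                                     nonvolant_mammal = 0.15,
                                     reptile = 0.22, volant_bird = 0.35)) {
  if (n_islands <= 0) stop("n_islands must be positive", call. = FALSE)
  if (exchangeable_rho < 0 || exchangeable_rho >= 1) {
    stop("exchangeable_rho must lie in [0, 1)", call. = FALSE)
  }
  if (abs(sum(class_mix) - 1) > 1e-8) {
    stop("class_mix must sum to 1", call. = FALSE)
  }
  if (!setequal(names(class_mix), class_volancy_levels())) {
    stop("class_mix must name the six class/volancy levels", call. = FALSE)
  }
  if (species_geom_prob <= 0 || species_geom_prob > 1) {
    stop("species_geom_prob must lie in (0, 1]", call. = FALSE)
  }
  unknown <- setdiff(rownames(occupancy_model), invasive_groups())
  if (length(unknown) > 0L) {
    stop("unknown invasive group(s) in occupancy_model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(n_islands = as.integer(n_islands), true_beta = true_beta,
                 exchangeable_rho = exchangeable_rho,
                 island_area_log_mean = island_area_log_mean,
                 island_area_log_sd = island_area_log_sd,
                 inhabited_intercept = inhabited_intercept,
                 inhabited_slope = inhabited_slope,
                 precip_intercept = precip_intercept,
                 precip_slope = precip_slope, precip_sd = precip_sd,
                 occupancy_model = occupancy_model,
                 eradication_prob = eradication_prob,
                 species_geom_prob = species_geom_prob,
                 p_shared_species = p_shared_species,
                 class_mix = class_mix),
            class = "islex_sim_params")
}

#' Default ground-truth coefficients (cloglog scale)
#'
#' Moderate, ecologically signed effects: positive contributions from
#' invasive rats, cats, pigs and mustelids/mongooses and from human
#' presence; a negative rat-by-area interaction (rats hit small islands
#' hardest); mild class/volancy contrasts against the amphibian reference;
#' intercept set so overall extirpation prevalence is ~25% under the default
#' island and occupancy models.
#'
#' @return Named numeric vector.
#' @export
default_true_beta <- function() {
  c("(Intercept)" = -1.94,
    "class_volancy=bat" = -0.20,
    "class_volancy=nonvolant_bird" = -0.45,
    "class_volancy=nonvolant_mammal" = 0.15,
    "class_volancy=reptile" = -0.30,
    "class_volancy=volant_bird" = 0.30,
    "ln_area" = -0.06,
    "precipitation" = -1.5e-4,
    "human_presence" = 0.50,
    "rats" = 0.80,
    "felids" = 0.50,
    "pigs" = 0.45,
    "mustelids_mongooses" = 0.90,
    "rats:ln_area" = -0.12)
}

#' Default invasive-group occupancy model
#'
#' Logistic coefficients (intercept, human-presence effect, ln-area effect)
#' per group, calibrated so that ~73% of islands carry at least one group,
#' uninhabited islands are mostly invasive-free or rat/cat-only, and four
#' groups are rare (<10% of islands).
#'
#' @return A 12 x 3 numeric matrix with invasive groups as row names.
#' @export
default_occupancy_model <- function() {
  m <- rbind(
    canids              = c(-4.4, 2.9, 0.10),
    felids              = c(-1.7, 1.9, 0.10),
    mustelids_mongooses = c(-4.7, 3.3, 0.10),
    pigs                = c(-4.1, 3.1, 0.10),
    primates            = c(-5.6, 3.0, 0.10),
    medium_omnivores    = c(-5.4, 3.0, 0.10),
    small_omnivores     = c(-5.2, 3.0, 0.10),
    rats                = c(-0.4, 1.4, 0.10),
    mice                = c(-4.3, 3.0, 0.10),
    large_herbivores    = c(-4.3, 3.1, 0.10),
    medium_herbivores   = c(-5.4, 3.0, 0.10),
    lagomorphs          = c(-4.4, 2.9, 0.10)
  )
  colnames(m) <- c("intercept", "human", "ln_area")
  m
}

#' Generate island abiotic covariates and human presence
#'
#' Areas are log-normal; human presence is Bernoulli with logistic
#' probability increasing in ln area; precipitation is normal in ln area,
#' truncated at 0 (so inhabited islands, being larger, are also wetter);
#' log elevation tracks log area with noise (reproducing the collinearity
#' the screening step is designed to catch); mean temperature and (log)
#' temperature seasonality are independent noise.
#'
#' @param params an [sim_params()] object.
#' @param seed RNG seed.
#' @return An island data.frame (invasive columns all 0, to be filled by
#'   [generate_invasive_occupancy()]).
#' @export
generate_islands <- function(params, seed = 1L) {
  stopifnot(inherits(params, "islex_sim_params"))
  n <- params$n_islands
  with_seed(seed, {
    ln_area <- stats::rnorm(n, params$island_area_log_mean,
                            params$island_area_log_sd)
    human <- stats::rbinom(n, 1L,
                           stats::plogis(params$inhabited_intercept +
                                           params$inhabited_slope * ln_area))
    pm <- params$precip_intercept + params$precip_slope * ln_area
    precip <- stats::qnorm(stats::runif(n, stats::pnorm(0, pm, params$precip_sd), 1),
                           pm, params$precip_sd)
    ln_elev <- 2 + 0.5 * ln_area + stats::rnorm(n, 0, 0.7)
    isl <- data.frame(
      island_id = sprintf("isl%05d", seq_len(n)),
      area = exp(ln_area),
      elevation = pmax(exp(ln_elev) - 1, 0),
      precipitation = precip,
      mean_temperature = stats::rnorm(n, 22, 5),
      temperature_seasonality = exp(stats::rnorm(n, 1.2, 0.6)),
      human_presence = human,
      stringsAsFactors = FALSE
    )
    for (g in invasive_groups()) {
      isl[[g]] <- 0L
      isl[[paste0("eradicated_", g)]] <- 0L
    }
    isl
  })
}

#' Fill invasive-group occupancy on generated islands
#'
#' Independent per-group Bernoulli draws from the logistic occupancy model
#' in human presence and ln area; a small fraction of present groups are
#' additionally flagged as eradicated (historical-only presence). Draws are
#' consumed group-by-group in the canonical group order so downstream stages
#' do not perturb them.
#'
#' @param islands output of [generate_islands()].
#' @param params an [sim_params()] object.
#' @param seed RNG seed.
#' @return The island table with presence and eradication flags filled.
#' @export
generate_invasive_occupancy <- function(islands, params, seed = 2L) {
  stopifnot(inherits(params, "islex_sim_params"))
  om <- params$occupancy_model
  n <- nrow(islands)
  ln_area <- log(islands$area)
  with_seed(seed, {
    for (g in rownames(om)) {
      pr <- stats::plogis(om[g, "intercept"] +
                            om[g, "human"] * islands$human_presence +
                            om[g, "ln_area"] * ln_area)
      islands[[g]] <- stats::rbinom(n, 1L, pr)
    }
    for (g in names(params$eradication_prob)) {
      er <- stats::rbinom(n, 1L, params$eradication_prob[[g]])
      islands[[paste0("eradicated_", g)]] <- as.integer(er & islands[[g]] == 1L)
    }
    islands
  })
}

# Evaluate the ground-truth linear predictor for a joined record table.
# Term names: "(Intercept)", plain covariate names, "class_volancy=<level>"
# indicators, and ":"-joined products of these.
sim_linear_predictor <- function(df, true_beta) {
  resolve1 <- function(nm) {
    if (nm == "(Intercept)") return(rep(1, nrow(df)))
    if (startsWith(nm, "class_volancy=")) {
      lev <- sub("^class_volancy=", "", nm)
      if (!lev %in% class_volancy_levels()) {
        stop("unknown class/volancy level in true_beta: ", lev, call. = FALSE)
      }
      return(as.numeric(df$class_volancy == lev))
    }
    if (!nm %in% names(df)) {
      stop("unknown covariate in true_beta: ", nm, call. = FALSE)
    }
    as.numeric(df[[nm]])
  }
  eta <- rep(0, nrow(df))
  for (nm in names(true_beta)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    col <- Reduce(`*`, lapply(parts, resolve1))
    eta <- eta + true_beta[[nm]] * col
  }
  eta
}

#' Pairwise outcome correlation implied by a Gaussian copula
#'
#' For two binary variables with marginal probabilities `p1`, `p2` generated
#' by thresholding standard normals with latent correlation `rho_latent`,
#' returns their Pearson correlation
#' \eqn{(C - p_1 p_2)/\sqrt{p_1(1-p_1)p_2(1-p_2)}}, where `C` is the
#' bivariate-normal orthant probability at the thresholds.
#'
#' @param rho_latent latent normal correlation in (-1, 1).
#' @param p1,p2 marginal success probabilities in (0, 1).
#' @return A correlation in \[-1, 1\].
#' @export
copula_outcome_correlation <- function(rho_latent, p1, p2 = p1) {
  if (rho_latent == 0) return(0)
  a <- stats::qnorm(p1)
  b <- stats::qnorm(p2)
  C <- mvtnorm::pmvnorm(upper = c(a, b),
                        corr = matrix(c(1, rho_latent, rho_latent, 1), 2L))
  (as.numeric(C) - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

#' Latent correlation achieving a target outcome correlation
#'
#' Inverts the monotone mapping of [copula_outcome_correlation()] by root
#' finding, at a common marginal probability `p` (in practice the mean
#' marginal extirpation risk).
#'
#' @param rho_target desired Pearson correlation of the binary outcomes,
#'   in \[0, 1).
#' @param p common marginal probability.
#' @return Latent normal correlation in \[0, 1).
#' @export
latent_rho_for_outcome <- function(rho_target, p) {
  stopifnot(rho_target >= 0, rho_target < 1, p > 0, p < 1)
  if (rho_target == 0) return(0)
  f <- function(r) copula_outcome_correlation(r, p) - rho_target
  stats::uniroot(f, c(1e-6, 0.9999), tol = 1e-8)$root
}

#' Generate populations with correlated extirpation outcomes
#'
#' Each island receives a zero-truncated-geometric number of threatened
#' populations with class/volancy drawn from the class mix; a fraction of
#' populations belong to widespread multi-island species, the rest are
#' single-island endemics. The marginal extirpation probability of record
#' `ij` is `cloglog_inv(x_ij' true_beta)` (evaluated on *historical*
#' invasive presence); within-island dependence comes from a Gaussian copula
#' with exchangeable latent correlation, root-found so the implied pairwise
#' outcome correlation matches `exchangeable_rho` at the mean marginal risk.
#'
#' @param islands completed island table (occupancy filled).
#' @param params an [sim_params()] object.
#' @param seed RNG seed.
#' @return A population data.frame with attribute `"p_marginal"` (the
#'   true per-record risks) attached.
#' @export
generate_populations <- function(islands, params, seed = 3L) {
  stopifnot(inherits(params, "islex_sim_params"))
  with_seed(seed, {
    n_isl <- nrow(islands)
    counts <- 1L + stats::rgeom(n_isl, params$species_geom_prob)
    idx <- rep(seq_len(n_isl), counts)
    n <- length(idx)
    cls <- sample(names(params$class_mix), n, replace = TRUE,
                  prob = params$class_mix)
    # species identity: widespread species are reused across islands
    species_id <- character(n)
    pool <- list()  # per class: character vector of widespread species ids
    n_new <- 0L
    shared <- stats::runif(n) < params$p_shared_species
    for (i in seq_len(n)) {
      cl_i <- cls[i]
      reuse <- shared[i] && length(pool[[cl_i]]) > 0L &&
        stats::runif(1) < 0.7
      if (reuse) {
        species_id[i] <- sample(pool[[cl_i]], 1L)
      } else {
        n_new <- n_new + 1L
        species_id[i] <- sprintf("sp%05d", n_new)
        if (shared[i]) pool[[cl_i]] <- c(pool[[cl_i]], species_id[i])
      }
    }
    df <- data.frame(species_id = species_id,
                     island_id = islands$island_id[idx],
                     class_volancy = cls,
                     stringsAsFactors = FALSE)
    # collapse accidental duplicate (species, island) pairs
    dup <- duplicated(paste(df$species_id, df$island_id))
    df <- df[!dup, , drop = FALSE]
    idx <- idx[!dup]
    n <- nrow(df)

    joined <- cbind(df, islands[idx, setdiff(names(islands), "island_id"),
                                drop = FALSE])
    joined$ln_area <- log(joined$area)
    eta <- sim_linear_predictor(joined, params$true_beta)
    p <- cloglog_parts(eta)$mu
    clamped <- p <= 1e-10 | p >= 1 - 1e-10
    if (mean(clamped) > 0.01) {
      # isolated tail islands clamp legitimately under heavy-tailed areas
      warning(sum(clamped),
              " marginal probabilities clamped to (0,1); extreme true_beta?",
              call. = FALSE)
    }
    rho_lat <- latent_rho_for_outcome(params$exchangeable_rho, mean(p))
    w <- stats::rnorm(n_isl)              # island-level latent factor
    eps <- stats::rnorm(n)
    z <- sqrt(rho_lat) * w[idx] + sqrt(1 - rho_lat) * eps
    y <- as.integer(stats::pnorm(z) < p)

    df$outcome <- y
    df$extant <- 1L - y
    df$body_mass <- round(exp(stats::rnorm(n, 4.5, 1.5)), 1)
    n_per_species <- table(df$species_id)
    df$single_island_endemic <-
      as.integer(n_per_species[df$species_id] == 1L)
    attr(df, "p_marginal") <- p
    df
  })
}

#' Build a named synthetic fixture dataset
#'
#' Deterministic datasets with documented ground truth:
#' \describe{
#'   \item{tiny}{3 islands, 6 populations with hand-fixed outcomes; smoke
#'     tests and file round-trips.}
#'   \item{null_model}{intercept-only truth (no covariate signal) at ~25%
#'     prevalence; calibration/overfitting checks.}
#'   \item{strong_rat_effect}{rat coefficient +2 on the cloglog scale (all
#'     other invasive effects 0); parameter-recovery and signal-detection
#'     tests.}
#'   \item{paper_like}{the full default generator: ~1,000 islands, ~2,600
#'     populations, ~25% extirpated.}
#' }
#' Ground truth is attached as attributes `true_beta` and `rho`.
#'
#' @param name one of `"tiny"`, `"null_model"`, `"strong_rat_effect"`,
#'   `"paper_like"`.
#' @param n_islands override the fixture's island count.
#' @param seed RNG seed (fixtures are bit-identical for a given seed).
#' @return An [islex_dataset()].
#' @export
make_fixture <- function(name = c("tiny", "null_model", "strong_rat_effect",
                                  "paper_like"),
                         n_islands = NULL, seed = 20201L) {
  name <- match.arg(name)
  if (name == "tiny") {
    islands <- data.frame(
      island_id = c("A", "B", "C"),
      area = c(0.5, 12, 300),
      elevation = c(5, 80, 1200),
      precipitation = c(800, 1300, 2100),
      mean_temperature = c(24, 21, 18),
      temperature_seasonality = c(2.1, 3.5, 5.0),
      human_presence = c(0L, 1L, 1L),
      stringsAsFactors = FALSE
    )
    for (g in invasive_groups()) islands[[g]] <- 0L
    islands$rats <- c(1L, 1L, 1L)
    islands$felids <- c(0L, 1L, 1L)
    islands$pigs <- c(0L, 0L, 1L)
    islands$eradicated_rats <- c(1L, 0L, 0L)
    populations <- data.frame(
      species_id = c("s1", "s2", "s2", "s3", "s4", "s5"),
      island_id = c("A", "A", "B", "B", "C", "C"),
      class_volancy = c("reptile", "volant_bird", "volant_bird",
                        "nonvolant_mammal", "amphibian", "nonvolant_bird"),
      outcome = c(1L, 0L, 0L, 1L, 0L, 0L),
      stringsAsFactors = FALSE
    )
    ds <- islex_dataset(islands, populations,
                        provenance = "synthetic fixture 'tiny'")
    return(ds)
  }
  params <- switch(
    name,
    null_model = sim_params(
      n_islands = if (is.null(n_islands)) 400L else n_islands,
      true_beta = c("(Intercept)" = cloglog(0.25))),
    strong_rat_effect = sim_params(
      n_islands = if (is.null(n_islands)) 2000L else n_islands,
      true_beta = c("(Intercept)" = -2.2, "rats" = 2.0)),
    paper_like = sim_params(
      n_islands = if (is.null(n_islands)) 1000L else n_islands)
  )
  ds <- simulate_dataset(params, seed = seed,
                         provenance = sprintf("synthetic fixture '%s'", name))
  attr(ds, "true_beta") <- params$true_beta
  attr(ds, "rho") <- params$exchangeable_rho
  ds
}

#' Run the full generator
#'
#' Chains [generate_islands()], [generate_invasive_occupancy()] and
#' [generate_populations()] (with per-stage seeds derived from `seed`) and
#' validates the result into an [islex_dataset()].
#'
#' @param params an [sim_params()] object.
#' @param seed base RNG seed.
#' @param provenance metadata string.
#' @return An [islex_dataset()].
#' @export
simulate_dataset <- function(params, seed = 1L, provenance = "synthetic") {
  islands <- generate_islands(params, seed = seed)
  islands <- generate_invasive_occupancy(islands, params, seed = seed + 1L)
  populations <- generate_populations(islands, params, seed = seed + 2L)
  ds <- islex_dataset(islands, populations, provenance = provenance)
  attr(ds, "p_marginal") <- attr(populations, "p_marginal")
  ds
}
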