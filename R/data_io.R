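#' Construct a validated island/population dataset
#'
#' Bundles an island table (the cluster unit: one row per island, with
#' abiotic covariates, human presence, and presence/eradication flags for
#' the twelve invasive mammal groups) and a population table (the analysis
#' unit: one row per native species per island, with class/volancy and the
#' binary extirpation outcome), enforcing referential integrity between the
#' two.
#'
#' @param islands data.frame with columns `island_id`, `area` (km^2, > 0),
#'   `elevation` (m), `precipitation` (mm/yr, >= 0), `mean_temperature`
#'   (deg C), `temperature_seasonality` (> 0), `human_presence` (0/1), one
#'   0/1 column per invasive group (see [invasive_groups()]; missing columns
#'   are filled with 0 = absent), and optional `eradicated_<group>` 0/1
#'   columns (1 only where the group is/was present).
#' @param populations data.frame with columns `species_id`, `island_id`,
#'   `class_volancy` (one of [class_volancy_levels()]), `outcome`
#'   (1 = extirpated after AD 1500, 0 = persists), and optional `body_mass`
#'   (g), `extant` (must equal `1 - outcome`), `single_island_endemic` (0/1).
#' @param provenance free-text metadata string.
#' @return An object of class `islex_dataset`: a list with elements
#'   `islands`, `populations`, `provenance`.
#' @seealso [read_dataset()] to build one from delimited files.
#' @export
islex_dataset <- function(islands, populations, provenance = "") {
  islands <- validate_islands(islands)
  populations <- validate_populations(populations, islands$island_id)
  structure(list(islands = islands, populations = populations,
                 provenance = provenance),
            class = "islex_dataset")
}

island_required_cols <- function() {
  c("island_id", "area", "elevation", "precipitation",
    "mean_temperature", "temperature_seasonality", "human_presence")
}

population_required_cols <- function() {
  c("species_id", "island_id", "class_volancy", "outcome")
}

check_binary <- function(x, what) {
  bad <- !(x %in% c(0L, 1L)) | is.na(x)
  if (any(bad)) {
    stop(sprintf("column '%s' must be 0/1; offending values: %s", what,
                 paste(utils::head(unique(x[bad]), 5L), collapse = ", ")),
         call. = FALSE)
  }
  as.integer(x)
}

validate_islands <- function(islands) {
  stopifnot(is.data.frame(islands))
  missing <- setdiff(island_required_cols(), names(islands))
  if (length(missing) > 0L) {
    stop("island table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  islands$island_id <- as.character(islands$island_id)
  if (anyDuplicated(islands$island_id)) {
    stop("duplicate island_id: ",
         paste(unique(islands$island_id[duplicated(islands$island_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(islands$area) | islands$area <= 0)) {
    bad <- islands$island_id[!is.finite(islands$area) | islands$area <= 0]
    stop("island area must be > 0; offending island(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(is.finite(islands$precipitation) & islands$precipitation < 0)) {
    stop("precipitation must be >= 0", call. = FALSE)
  }
  islands$human_presence <- check_binary(islands$human_presence,
                                         "human_presence")
  for (g in invasive_groups()) {
    if (!g %in% names(islands)) {
      islands[[g]] <- 0L  # no information recorded -> coded absent
    } else {
      x <- islands[[g]]
      x[is.na(x) | x == ""] <- 0L  # blank cell -> absent
      islands[[g]] <- check_binary(as.integer(as.numeric(x)), g)
    }
    ecol <- paste0("eradicated_", g)
    if (!ecol %in% names(islands)) {
      islands[[ecol]] <- 0L
    } else {
      x <- islands[[ecol]]
      x[is.na(x) | x == ""] <- 0L
      islands[[ecol]] <- check_binary(as.integer(as.numeric(x)), ecol)
      viol <- islands[[ecol]] == 1L & islands[[g]] == 0L
      if (any(viol)) {
        stop(sprintf(
          "eradication flag set for '%s' on island(s) without recorded presence: %s",
          g, paste(utils::head(islands$island_id[viol], 5L), collapse = ", ")),
          call. = FALSE)
      }
    }
  }
  islands
}

validate_populations <- function(populations, known_islands) {
  stopifnot(is.data.frame(populations))
  missing <- setdiff(population_required_cols(), names(populations))
  if (length(missing) > 0L) {
    stop("population table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  populations$species_id <- as.character(populations$species_id)
  populations$island_id <- as.character(populations$island_id)
  dangling <- setdiff(populations$island_id, known_islands)
  if (length(dangling) > 0L) {
    stop("population rows reference island_id values absent from the island table: ",
         paste(utils::head(dangling, 10L), collapse = ", "), call. = FALSE)
  }
  key <- paste(populations$species_id, populations$island_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (species_id, island_id) pair(s): ",
         paste(utils::head(sub("\r", " on ", key[duplicated(key)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  bad_cv <- setdiff(unique(populations$class_volancy), class_volancy_levels())
  if (length(bad_cv) > 0L) {
    stop("unknown class_volancy level(s): ", paste(bad_cv, collapse = ", "),
         "; allowed: ", paste(class_volancy_levels(), collapse = ", "),
         call. = FALSE)
  }
  populations$outcome <- check_binary(populations$outcome, "outcome")
  if ("extant" %in% names(populations)) {
    populations$extant <- check_binary(populations$extant, "extant")
    if (any(populations$extant != 1L - populations$outcome)) {
      stop("extant flag inconsistent with outcome (must be 1 - outcome)",
           call. = FALSE)
    }
  } else {
    populations$extant <- 1L - populations$outcome
  }
  if ("single_island_endemic" %in% names(populations)) {
    populations$single_island_endemic <-
      check_binary(populations$single_island_endemic, "single_island_endemic")
  } else {
    n_isl <- table(populations$species_id)
    populations$single_island_endemic <-
      as.integer(n_isl[populations$species_id] == 1L)
  }
  populations$body_mass <- if ("body_mass" %in% names(populations)) {
    as.numeric(populations$body_mass)
  } else NA_real_
  populations
}

read_clean_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                        check.names = FALSE, na.strings = c("NA", ""))
  # machine-clean numbers only: "2,656"-style thousands separators rejected
  for (nm in names(df)) {
    if (is.character(df[[nm]]) && any(grepl("^[0-9]{1,3}(,[0-9]{3})+(\\.[0-9]*)?$",
                                            df[[nm]]))) {
      stop(sprintf("column '%s' in %s contains thousands separators; files must be machine-clean",
                   nm, path), call. = FALSE)
    }
  }
  names(df) <- tolower(names(df))
  df
}

apply_column_map <- function(df, column_map) {
  if (is.null(column_map)) return(df)
  stopifnot(is.character(column_map), !is.null(names(column_map)))
  from <- tolower(names(column_map))
  idx <- match(from, names(df))
  names(df)[idx[!is.na(idx)]] <- tolower(column_map[!is.na(idx)])
  df
}

#' Read and validate the island and population tables
#'
#' Reads two comma-delimited files (decimal point, no thousands separators),
#' applies an optional column mapping, validates both schemas, and joins them
#' into an [islex_dataset()]. Missing invasive-group columns and blank
#' invasive-group cells are coded 0 (absent, i.e. no information about the
#' group on that island); eradicated groups keep presence = 1 (historical
#' presence) with the `eradicated_<group>` flag set.
#'
#' @param island_path path to the island CSV.
#' @param population_path path to the population CSV.
#' @param column_map optional named character vector mapping file column
#'   names to canonical names, e.g. `c("Island.Name" = "island_id")`.
#'   Matching is case-insensitive.
#' @param strict if `TRUE` (default), island columns outside the documented
#'   schema (in particular unknown invasive-group or eradication columns)
#'   are rejected with an error naming them.
#' @return An `islex_dataset`.
#' @export
read_dataset <- function(island_path, population_path, column_map = NULL,
                         strict = TRUE) {
  islands <- apply_column_map(read_clean_csv(island_path), column_map)
  populations <- apply_column_map(read_clean_csv(population_path), column_map)
  if (isTRUE(strict)) {
    allowed <- c(island_required_cols(), invasive_groups(),
                 paste0("eradicated_", invasive_groups()))
    unknown <- setdiff(names(islands), allowed)
    if (length(unknown) > 0L) {
      stop("unknown column(s) in island table (unrecognized invasive group?): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  islex_dataset(islands, populations,
                provenance = sprintf("read from %s + %s", island_path,
                                     population_path))
}

#' @export
print.islex_dataset <- function(x, ...) {
  cat(sprintf("islex_dataset: %d islands, %d populations (%d extirpated, %.1f%%)\n",
              nrow(x$islands), nrow(x$populations),
              sum(x$populations$outcome),
              100 * mean(x$populations$outcome)))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Descriptive summary of a dataset
#'
#' Counts and stratified medians: species, populations, islands, extirpation
#' fraction, fraction of islands carrying at least one invasive mammal
#' group, and median area/precipitation for inhabited versus uninhabited
#' islands.
#'
#' @param ds an [islex_dataset()].
#' @return A list of class `islex_summary`.
#' @export
summarize_dataset <- function(ds) {
  stopifnot(inherits(ds, "islex_dataset"))
  isl <- ds$islands
  pop <- ds$populations
  if (nrow(pop) == 0L || nrow(isl) == 0L) {
    out <- list(n_species = 0L, n_populations = 0L, n_islands = nrow(isl),
                n_extirpated = 0L, extirpation_fraction = NA_real_,
                frac_islands_invaded = if (nrow(isl)) NA_real_ else NA_real_,
                frac_islands_uninhabited = NA_real_,
                median_area = c(all = NA_real_, inhabited = NA_real_,
                                uninhabited = NA_real_),
                median_precipitation = c(all = NA_real_, inhabited = NA_real_,
                                         uninhabited = NA_real_))
    class(out) <- "islex_summary"
    return(out)
  }
  inv <- as.matrix(isl[, invasive_groups(), drop = FALSE])
  inhab <- isl$human_presence == 1L
  med3 <- function(x) c(all = stats::median(x),
                        inhabited = stats::median(x[inhab]),
                        uninhabited = stats::median(x[!inhab]))
  out <- list(
    n_species = length(unique(pop$species_id)),
    n_populations = nrow(pop),
    n_islands = nrow(isl),
    n_extirpated = sum(pop$outcome),
    extirpation_fraction = mean(pop$outcome),
    frac_islands_invaded = mean(rowSums(inv) > 0L),
    frac_islands_uninhabited = mean(!inhab),
    median_area = med3(isl$area),
    median_precipitation = med3(isl$precipitation)
  )
  class(out) <- "islex_summary"
  out
}

#' @export
print.islex_summary <- function(x, ...) {
  cat(sprintf("%d species, %d populations on %d islands\n",
              x$n_species, x$n_populations, x$n_islands))
  cat(sprintf("extirpated: %d (%.1f%%)\n", x$n_extirpated,
              100 * x$extirpation_fraction))
  cat(sprintf("islands with >=1 invasive group: %.1f%%; uninhabited: %.1f%%\n",
              100 * x$frac_islands_invaded, 100 * x$frac_islands_uninhabited))
  cat(sprintf("median area km^2 (all/inhabited/uninhabited): %.1f / %.1f / %.1f\n",
              x$median_area[["all"]], x$median_area[["inhabited"]],
              x$median_area[["uninhabited"]]))
  cat(sprintf("median precipitation mm (all/inhabited/uninhabited): %.0f / %.0f / %.0f\n",
              x$median_precipitation[["all"]],
              x$median_precipitation[["inhabited"]],
              x$median_precipitation[["uninhabited"]]))
  invisible(x)
}

#' Write a tabular result as delimited text
#'
#' Plain UTF-8 CSV with header and deterministic column order; round-trips
#' through `read.csv`. An empty result writes a header-only file.
#'
#' @param rows a data.frame (or object coercible to one).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  if (is.null(rows)) stop("rows must be non-null", call. = FALSE)
  rows <- as.data.frame(rows)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write to ", path, call. = FALSE)
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a dataset's two tables to files
#'
#' @param ds an [islex_dataset()].
#' @param island_path,population_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(ds, island_path, population_path) {
  stopifnot(inherits(ds, "islex_dataset"))
  write_table(ds$islands, island_path)
  write_table(ds$populations, population_path)
  invisible(c(island_path, population_path))
}
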