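# End-to-end orchestration: fixtures -> preprocessing -> Gibbs generation
# -> income/health enrichment -> housing -> allocation -> validation, under
# a single master seed, with delimited-text outputs and a JSON manifest.

#' Default pipeline configuration
#'
#' @param seed Master seed governing every random draw of the run.
#' @param n_households Number of census households to simulate.
#' @param min_count Minimum support per conditional-table cell.
#' @param burn_in Gibbs burn-in sweeps.
#' @param frac_train Training fraction of the household-level split.
#' @param dispersion_sigma Lognormal income dispersion (log scale).
#' @param n_iris,n_commune,n_department Fixture zone-tree widths.
#' @return Named configuration list (YAML-serializable).
#' @export
default_config <- function(seed = 1L, n_households = 10000L,
                           min_count = 10L, burn_in = 20L,
                           frac_train = 0.66, dispersion_sigma = 0.25,
                           n_iris = 8L, n_commune = 4L, n_department = 2L) {
  list(seed = as.integer(seed),
       n_households = as.integer(n_households),
       min_count = as.integer(min_count),
       burn_in = as.integer(burn_in),
       frac_train = frac_train,
       dispersion_sigma = dispersion_sigma,
       n_iris = as.integer(n_iris),
       n_commune = as.integer(n_commune),
       n_department = as.integer(n_department),
       head_min_age_multi = 21L,
       head_min_age_single = 18L,
       mother_child_gap = 15L,
       floor_employed = 12672,
       floor_nonworking = 5520,
       avg_dwelling_size = list(center = 59, inner = 69, outer = 89),
       storey_height = 3)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults; a missing
#' seed is an error (runs must be reproducible).
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown)) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(raw$seed)) {
    stop("config error: seed is required", call. = FALSE)
  }
  base[names(raw)] <- raw
  base$seed <- as.integer(base$seed)
  base
}

config_constraints <- function(config) {
  default_constraints(head_min_age_multi = config$head_min_age_multi,
                      head_min_age_single = config$head_min_age_single,
                      mother_child_gap = config$mother_child_gap,
                      burn_in = config$burn_in)
}

config_housing <- function(config) {
  housing_config(avg_dwelling_size = unlist(config$avg_dwelling_size),
                 storey_height = config$storey_height)
}

#' Run the full pipeline
#'
#' Simulates fixture inputs from a ground-truth model, splits the census
#' at the household level (about 66/33, stratified by commune), estimates
#' the conditional tree from the training set, generates a synthetic
#' population matched to the test set's per-zone individual counts by
#' Gibbs sampling, assigns incomes and overweight status, derives the
#' dwelling stock from fixture buildings (topped up until every IRIS can
#' host its households), allocates households to dwellings by income
#' stratum, and validates the result against the held-out test set.
#'
#' @param config Configuration list, see [default_config()].
#' @param out_dir Optional output directory; when given, all tables are
#'   written as delimited text with a JSON `manifest.json` (config hash,
#'   seed, row counts, stage timings).
#' @return An object of class `popgen_run` with all intermediate and final
#'   artifacts.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tic <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  seed <- config$seed
  schema <- default_schema()
  constraints <- config_constraints(config)

  # Stage 0: fixture inputs (census stand-in, zones, income/health tables)
  zone_table <- fixture_zone_table(n_department = config$n_department,
                                   n_commune = config$n_commune,
                                   n_iris = config$n_iris, seed = seed)
  model <- generate_ground_truth_model(seed, schema, zone_table)
  hierarchy <- build_zone_hierarchy(zone_table)
  census <- simulate_census_sample(model, config$n_households,
                                   seed = hash_seed(seed, "census_stage"),
                                   constraints = constraints)
  tic("fixtures")

  # Stage 1: cleaning, discretization, conditional estimation (train only)
  cleaned <- clean_microdata(census, schema)
  micro <- discretize(cleaned$data, schema)
  split <- split_train_test(micro, config$frac_train,
                            seed = hash_seed(seed, "split_stage"),
                            hierarchy = hierarchy)
  est <- estimate_model(split$train, hierarchy, schema,
                        min_count = config$min_count)
  tic("preprocess")

  # Stage 3: Gibbs co-generation matched to the test set's zone sizes
  targets <- table(factor(split$test$zone, zone_ids(hierarchy, "IRIS")))
  zone_pops <- stats::setNames(as.integer(targets), names(targets))
  zone_pops <- zone_pops[zone_pops > 0]
  population <- generate_population(zone_pops, est$cpts, est$size_dists,
                                    constraints,
                                    master_seed = hash_seed(seed,
                                                            "generate_stage"))
  tic("generate")

  # income + overweight enrichment
  im <- income_model(model$zone_medians, model$spc_income_medians,
                     model$population_median,
                     floor_employed = config$floor_employed,
                     floor_nonworking = config$floor_nonworking)
  population <- assign_income(population, hierarchy, im,
                              dispersion_sigma = config$dispersion_sigma,
                              master_seed = hash_seed(seed, "income_stage"))
  population <- assign_overweight(population, model$overweight,
                                  master_seed = hash_seed(seed, "ow_stage"))
  tic("attributes")

  # Stage 4.1: building stock with enough dwellings per IRIS
  hconf <- config_housing(config)
  demand <- table(factor(population$households$zone,
                         zone_ids(hierarchy, "IRIS")))
  stock <- fixture_housing_stock(zone_table, hierarchy, demand, hconf,
                                 seed = hash_seed(seed, "housing_stage"))
  tic("housing")

  # Stage 4.2: allocation by income stratum
  households <- stratify_household_income(population$households)
  assignment <- allocate_households(households, stock$dwellings,
                                    master_seed = hash_seed(seed,
                                                            "alloc_stage"))
  tic("allocate")

  # validation against the held-out test set
  synthetic <- as_microdata(population)
  combos <- list("age_class", "gender", "spc", "activity", "education",
                 "hh_type", "car", "overweight",
                 c("age_class", "gender", "spc", "activity"),
                 c("age_class", "gender", "spc", "activity", "education",
                   "role", "hh_type", "car", "overweight"))
  report <- validate_population(split$test, synthetic, combos, schema)
  tic("validate")

  run <- structure(list(config = config, model = model,
                        hierarchy = hierarchy, census = census,
                        cleaning_report = cleaned$report, split = split,
                        estimated = est, population = population,
                        synthetic = synthetic, buildings = stock$buildings,
                        dwellings = stock$dwellings,
                        assignment = assignment, report = report,
                        timings = timings),
                   class = "popgen_run")
  if (!is.null(out_dir)) {
    write_run(run, out_dir)
  }
  run
}

# Building stock sized to demand: draws fixture buildings and tops up any
# IRIS whose dwelling capacity falls short of its household demand.
fixture_housing_stock <- function(zone_table, hierarchy, demand, hconf,
                                  seed) {
  iris_tab <- zone_table[zone_table$level == "IRIS", , drop = FALSE]
  n0 <- max(16L, as.integer(ceiling(sum(demand) / 4)))
  buildings <- simulate_buildings(iris_tab, n0, seed = seed)
  for (round in 1:20) {
    stock <- build_housing_stock(buildings, hierarchy, hconf)
    cap <- table(factor(stock$dwellings$zone, names(demand)))
    deficit <- as.integer(demand) - as.integer(cap)
    if (all(deficit <= 0)) {
      return(stock)
    }
    short <- names(demand)[deficit > 0]
    extra_tab <- iris_tab[iris_tab$zone %in% short, , drop = FALSE]
    extra <- simulate_buildings(extra_tab,
                                n_buildings = max(8L, sum(deficit > 0) *
                                                    ceiling(max(deficit) / 4)),
                                seed = hash_seed(seed, "topup", round))
    extra$bid <- paste0(extra$bid, "_t", round)
    buildings <- rbind(buildings, extra)
  }
  stop("capacity error: could not provision enough dwellings",
       call. = FALSE)
}

#' @export
print.popgen_run <- function(x, ...) {
  cat("<popgen_run>\n")
  cat(sprintf("  seed %d, %d census households\n", x$config$seed,
              x$config$n_households))
  cat(sprintf("  generated: %d households / %d individuals in %d zones\n",
              nrow(x$population$households),
              nrow(x$population$individuals),
              length(unique(x$population$households$zone))))
  cat(sprintf("  housing: %d buildings, %d dwellings, %d allocations\n",
              nrow(x$buildings), nrow(x$dwellings), nrow(x$assignment)))
  cat("  stage timings (s):",
      paste(names(x$timings), unlist(x$timings), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a pipeline run to delimited text files plus a manifest
#'
#' @param run A `popgen_run`.
#' @param out_dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
    nrow(df)
  }
  counts <- c(
    census = wr(run$census, "census"),
    train = wr(run$split$train, "train"),
    test = wr(run$split$test, "test"),
    households = wr(run$population$households, "households"),
    individuals = wr(run$synthetic, "individuals"),
    buildings = wr(run$buildings, "buildings"),
    dwellings = wr(run$dwellings, "dwellings"),
    assignment = wr(run$assignment, "assignment"),
    metrics = wr(as.data.frame(run$report), "metrics")
  )
  manifest <- list(seed = run$config$seed,
                   config_hash = hash_seed(0L, paste(deparse(run$config),
                                                     collapse = "")),
                   rows = as.list(counts),
                   timings = as.list(run$timings))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
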