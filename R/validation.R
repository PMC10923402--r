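# Endogenous validation: train/test split at the household level, SRMSE
# over marginal and multi-attribute joint distributions, and R2/RMSE/MAE
# fit metrics at regional and per-IRIS scales.

#' Split microdata into training and evaluation sets
#'
#' The split is drawn at the household level (households never straddle
#' the split), stratified by commune so both sets cover the territory.
#'
#' @param tab Microdata table with `hid` and `zone` columns.
#' @param frac_train Fraction of households assigned to the training set
#'   (strictly between 0 and 1; the canonical protocol uses about 2/3).
#' @param seed Integer seed.
#' @param hierarchy Optional `zone_hierarchy`; when supplied, strata are
#'   communes resolved from the zone column, otherwise the zones
#'   themselves.
#' @return List with `train` and `test` tables (disjoint, exhaustive).
#' @export
split_train_test <- function(tab, frac_train = 0.66, seed = 1L,
                             hierarchy = NULL) {
  if (!is.finite(frac_train) || frac_train <= 0 || frac_train >= 1) {
    stop("input error: frac_train must lie strictly between 0 and 1",
         call. = FALSE)
  }
  strata <- if (!is.null(hierarchy)) commune_of(hierarchy, tab$zone) else
    tab$zone
  hh <- unique(data.frame(hid = tab$hid, stratum = strata,
                          stringsAsFactors = FALSE))
  train_ids <- with_substream(seed, "train_test_split", expr = {
    unlist(lapply(split(hh$hid, hh$stratum), function(ids) {
      ids <- ids[sample.int(length(ids))]
      ids[seq_len(round(frac_train * length(ids)))]
    }), use.names = FALSE)
  })
  sel <- tab$hid %in% train_ids
  list(train = tab[sel, , drop = FALSE], test = tab[!sel, , drop = FALSE])
}

#' Standardized root mean square error between two distributions
#'
#' `SRMSE = sqrt(mean((sim - obs)^2)) / mean(obs)` over the common cell
#' grid; zero means a perfect match. Joint distributions are compared over
#' the full cross-classification with absent combinations as zero cells.
#'
#' @param observed,simulated Probability vectors over the same cells
#'   (aligned by names when both are named).
#' @return Non-negative scalar.
#' @export
#' @examples
#' srmse(c(0.5, 0.5), c(0.6, 0.4))   # 0.2
srmse <- function(observed, simulated) {
  if (!is.null(names(observed)) && !is.null(names(simulated))) {
    if (length(observed) != length(simulated) ||
        !setequal(names(observed), names(simulated))) {
      stop("input error: mismatched cell sets", call. = FALSE)
    }
    simulated <- simulated[names(observed)]
  } else if (length(observed) != length(simulated)) {
    stop("input error: mismatched cell sets", call. = FALSE)
  }
  if (sum(observed) <= 0) {
    stop("undefined error: all-zero observed distribution", call. = FALSE)
  }
  sqrt(mean((simulated - observed)^2)) / mean(observed)
}

#' Fit metrics between paired observed and simulated values
#'
#' R2 is the squared Pearson correlation; RMSE and MAE follow their
#' standard definitions. A zero-variance input leaves R2 undefined
#' (reported as NA with `r2_defined = FALSE`).
#'
#' @param observed,simulated Paired numeric vectors of length at least 2.
#' @return List with `r2`, `rmse`, `mae`, `n` and `r2_defined`.
#' @export
#' @examples
#' fit_metrics(c(0, 1, 2), c(1, 2, 3))   # r2 = 1, rmse = 1, mae = 1
fit_metrics <- function(observed, simulated) {
  if (length(observed) != length(simulated) || length(observed) < 2L) {
    stop("input error: paired vectors of length >= 2 required",
         call. = FALSE)
  }
  err <- simulated - observed
  defined <- stats::sd(observed) > 0 && stats::sd(simulated) > 0
  r2 <- if (defined) stats::cor(observed, simulated)^2 else NA_real_
  list(r2 = r2, rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
       n = length(observed), r2_defined = defined)
}

#' Joint distribution of a population over an attribute combination
#'
#' Normalized cell frequencies over the full Cartesian grid of the
#' attributes' schema categories, zero-filled, one unit per individual
#' (household attributes count once per member).
#'
#' @param tab Individual-level table.
#' @param attrs Character vector of 1 to 9 attribute names.
#' @param schema Attribute schema.
#' @return Named probability vector over the full category grid.
#' @export
joint_distribution <- function(tab, attrs, schema = default_schema()) {
  if (length(attrs) < 1L || length(attrs) > 9L) {
    stop("input error: between 1 and 9 attributes", call. = FALSE)
  }
  facs <- lapply(attrs, function(a) {
    cats <- schema_categories(schema, a)
    if (is.null(cats)) {
      stop("schema error: attribute ", a, " is not categorical",
           call. = FALSE)
    }
    if (!a %in% names(tab)) {
      stop("schema error: attribute ", a, " absent from table",
           call. = FALSE)
    }
    factor(as.character(tab[[a]]), levels = cats)
  })
  counts <- as.vector(do.call(table, facs))
  grid <- do.call(expand.grid,
                  c(lapply(attrs, function(a) schema_categories(schema, a)),
                    stringsAsFactors = FALSE))
  names(counts) <- do.call(paste, c(grid, sep = "|"))
  counts / sum(counts)
}

#' Per-zone occurrence comparison for one attribute
#'
#' For each IRIS and attribute category, the percentage of occurrence in
#' the observed (test) and synthetic datasets, with fit metrics over the
#' paired percentages, pooled and per category. Zones present in only one
#' dataset are excluded and reported. Categories whose observed
#' percentages vary by less than `low_variance_sd` percentage points
#' across zones are flagged low-variance (their R2 is not informative).
#'
#' @param test,synthetic Individual-level tables with a `zone` column.
#' @param attribute Attribute name.
#' @param schema Attribute schema.
#' @param low_variance_sd Flag threshold (percentage points).
#' @return List with `table` (zone x category percentages), `metrics`
#'   (pooled), `per_category`, `low_variance` and `excluded_zones`.
#' @export
per_zone_comparison <- function(test, synthetic, attribute,
                                schema = default_schema(),
                                low_variance_sd = 1) {
  cats <- schema_categories(schema, attribute)
  zones <- intersect(unique(test$zone), unique(synthetic$zone))
  excluded <- setdiff(union(unique(test$zone), unique(synthetic$zone)),
                      zones)
  pct <- function(tab, z) {
    v <- factor(as.character(tab[[attribute]][tab$zone == z]), cats)
    100 * as.vector(table(v)) / max(length(v), 1L)
  }
  rows <- do.call(rbind, lapply(zones, function(z) {
    data.frame(zone = z, category = cats, obs_pct = pct(test, z),
               sim_pct = pct(synthetic, z), stringsAsFactors = FALSE)
  }))
  per_cat <- lapply(cats, function(cc) {
    sel <- rows$category == cc
    if (sum(sel) >= 2) fit_metrics(rows$obs_pct[sel], rows$sim_pct[sel])
    else NULL
  })
  names(per_cat) <- cats
  low_var <- vapply(cats, function(cc) {
    sel <- rows$category == cc
    stats::sd(rows$obs_pct[sel]) < low_variance_sd
  }, logical(1))
  list(table = rows,
       metrics = fit_metrics(rows$obs_pct, rows$sim_pct),
       per_category = per_cat,
       low_variance = names(low_var)[low_var],
       excluded_zones = excluded)
}

#' Validation report over attribute combinations and scales
#'
#' Compares a synthetic population against held-out test microdata:
#' SRMSE, R2, RMSE and MAE over the cell percentages of each attribute
#' combination at regional scale, and per-IRIS occurrence metrics for the
#' single attributes.
#'
#' @param test Held-out individual-level microdata.
#' @param synthetic Individual-level synthetic population table.
#' @param combos List of attribute-name vectors (1 to 9 attributes each).
#' @param schema Attribute schema.
#' @return A `metrics_report` data frame with one row per (combination,
#'   scale).
#' @export
validate_population <- function(test, synthetic,
                                combos = as.list(c("age_class", "gender",
                                                   "spc", "activity")),
                                schema = default_schema()) {
  rows <- list()
  for (at in combos) {
    obs <- joint_distribution(test, at, schema)
    sim <- joint_distribution(synthetic, at, schema)
    fm <- fit_metrics(100 * obs, 100 * sim)
    rows[[length(rows) + 1L]] <- data.frame(
      combination = paste(at, collapse = " x "),
      n_attributes = length(at),
      scale = "region",
      srmse = srmse(obs, sim),
      r2 = fm$r2, rmse = fm$rmse, mae = fm$mae,
      cells = length(obs),
      support = nrow(test),
      stringsAsFactors = FALSE
    )
    if (length(at) == 1L && length(unique(test$zone)) > 1L) {
      pz <- per_zone_comparison(test, synthetic, at, schema)
      rows[[length(rows) + 1L]] <- data.frame(
        combination = at,
        n_attributes = 1L,
        scale = "IRIS",
        srmse = NA_real_,
        r2 = pz$metrics$r2, rmse = pz$metrics$rmse, mae = pz$metrics$mae,
        cells = nrow(pz$table),
        support = nrow(test),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
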