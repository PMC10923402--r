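# Fixtures: synthetic census microdata, zone hierarchies, buildings and
# price/income tables with a known generative structure, so every
# downstream stage can be tested against its own ground truth.
#
# The ground-truth conditional tables are random Dirichlet draws except for
# the structurally determined cells (one-person households are Single,
# under-15s are students with inactive SPC, 65+ are employed or retired,
# students map to SPC 8 and retirees to SPC 7). Category supports are chosen
# so that the structural truncation rules almost never bind during forward
# sampling: heads and spouses of multi-person households are 35+ and
# dependent children fall in the two youngest classes, which keeps the
# mother-child age-gap rule slack and makes conditional-table recovery a
# clean binomial sampling problem.

#' Generate a ground-truth generative model
#'
#' Builds the fixture counterpart of the conditional-probability tree: a
#' full set of conditional tables over the schema's categories, a per-zone
#' household-size distribution, per-SPC and per-commune median incomes, and
#' an overweight/obesity contingency by gender x age class x SPC. All
#' probability vectors are valid distributions; the object is deterministic
#' given the seed.
#'
#' @param seed Integer master seed.
#' @param schema Attribute schema, see [default_schema()].
#' @param zone_table Zone table (region/department/commune/IRIS) with a
#'   `zone_class` column; defaults to [fixture_zone_table()] under the same
#'   seed.
#' @return An object of class `ground_truth_model` with fields `schema`,
#'   `cpts`, `size_dist_by_zone`, `spc_income_medians`, `zone_medians`,
#'   `population_median`, `overweight`, `zone_table` and `seed`.
#' @export
#' @examples
#' m <- generate_ground_truth_model(seed = 1)
#' m$cpts$hh_type
generate_ground_truth_model <- function(seed = 1L,
                                        schema = default_schema(),
                                        zone_table = NULL) {
  assert_schema(schema)
  if (is.null(zone_table)) zone_table <- fixture_zone_table(seed = seed)
  hierarchy <- build_zone_hierarchy(zone_table)
  iris <- zone_ids(hierarchy, "IRIS")
  communes <- zone_ids(hierarchy, "commune")

  # Dirichlet cell draw with every positive cell floored at 2%: keeps all
  # supported conditional cells estimable at the package's default
  # min_count on desk-scale samples (no near-zero generative cells).
  dir_row <- function(levels, alpha) {
    p <- numeric(length(levels))
    names(p) <- levels
    pos <- alpha > 0
    d <- rdirichlet1(alpha[pos])
    d <- pmax(d, 0.02)
    p[pos] <- d / sum(d)
    p
  }

  cpts <- with_substream(seed, "ground_truth_cpts", expr = {
    # P(type | size), restricted to size-compatible types
    prob <- rbind(
      dir_row(HH_TYPES, c(1, 0, 0, 0) * 1),
      dir_row(HH_TYPES, c(0, 2, 6, 0)),
      dir_row(HH_TYPES, c(0, 2, 0, 7)),
      dir_row(HH_TYPES, c(0, 1.5, 0, 8)),
      dir_row(HH_TYPES, c(0, 1, 0, 8)),
      dir_row(HH_TYPES, c(0, 1, 0, 8))
    )
    rownames(prob) <- HH_SIZES
    hh_type <- new_cpt("hh_type", "hh_size", HH_TYPES, prob)

    # P(gender | role, type); spouse rows are the structural complement of
    # the head rows (the spouse always takes the opposite gender)
    head_rows <- t(vapply(HH_TYPES, function(t) {
      if (t == "single parent") dir_row(GENDERS, c(2, 6)) else
        dir_row(GENDERS, c(5, 5))
    }, numeric(2)))
    child_rows <- t(vapply(HH_TYPES, function(t) dir_row(GENDERS, c(5, 5)),
                           numeric(2)))
    spouse_rows <- head_rows[, c("Female", "Male")]
    colnames(spouse_rows) <- GENDERS
    prob <- rbind(head_rows, spouse_rows, child_rows)
    rownames(prob) <- cpt_cell_key(rep(ROLES, each = length(HH_TYPES)),
                                   rep(HH_TYPES, times = length(ROLES)))
    gender <- new_cpt("gender", c("role", "hh_type"), GENDERS, prob)

    # P(age class | type, role): adults of multi-person households 35+,
    # single heads 15+, children in the two youngest classes
    cells <- expand.grid(hh_type = HH_TYPES, role = ROLES,
                         stringsAsFactors = FALSE)
    prob <- t(apply(cells, 1, function(r) {
      if (r[["role"]] == "child") {
        dir_row(AGE_CLASSES, c(7, 3, 0, 0))
      } else if (r[["hh_type"]] == "Single") {
        dir_row(AGE_CLASSES, c(0, 4, 5, 3))
      } else {
        dir_row(AGE_CLASSES, c(0, 0, 7, 3))
      }
    }))
    rownames(prob) <- cpt_cell_key(cells$hh_type, cells$role)
    age_class <- new_cpt("age_class", c("hh_type", "role"), AGE_CLASSES, prob)

    # P(activity | age class)
    prob <- rbind(
      dir_row(ACTIVITIES, c(0, 0, 0, 1, 0)),        # [0-15): students
      dir_row(ACTIVITIES, c(6, 1.5, 0, 4, 1)),
      dir_row(ACTIVITIES, c(8, 1.5, 1, 0.3, 1)),
      dir_row(ACTIVITIES, c(1, 0, 9, 0, 0))         # [65-120]
    )
    rownames(prob) <- AGE_CLASSES
    activity <- new_cpt("activity", "age_class", ACTIVITIES, prob)

    # P(SPC | age class, activity): students -> 8, retirees -> 7,
    # employed over occupations 1..6, other non-working over {1..6, 8}
    cells <- expand.grid(age_class = AGE_CLASSES, activity = ACTIVITIES,
                         stringsAsFactors = FALSE)
    prob <- t(apply(cells, 1, function(r) {
      act <- r[["activity"]]
      if (act == "student") {
        dir_row(SPC_LEVELS, c(rep(0, 7), 1))
      } else if (act == "retired") {
        dir_row(SPC_LEVELS, c(rep(0, 6), 1, 0))
      } else if (act == "Employed") {
        if (r[["age_class"]] == AGE_CLASSES[4]) {
          # late-career workers concentrate in mid/upper categories
          dir_row(SPC_LEVELS, c(0, 0, 3, 4, 5, 5, 0, 0))
        } else {
          dir_row(SPC_LEVELS, c(1, 2, 3, 4, 5, 5, 0, 0))
        }
      } else {
        dir_row(SPC_LEVELS, c(1, 1, 1, 2, 3, 3, 0, 2))
      }
    }))
    rownames(prob) <- cpt_cell_key(cells$age_class, cells$activity)
    spc <- new_cpt("spc", c("age_class", "activity"), SPC_LEVELS, prob)

    # P(education | age class, SPC): under-15s none/primary only
    cells <- expand.grid(age_class = AGE_CLASSES, spc = SPC_LEVELS,
                         stringsAsFactors = FALSE)
    prob <- t(apply(cells, 1, function(r) {
      if (r[["age_class"]] == AGE_CLASSES[1]) {
        dir_row(EDU_LEVELS, c(4, 6, 0, 0))
      } else {
        dir_row(EDU_LEVELS, c(1, 2, 4, 3))
      }
    }))
    rownames(prob) <- cpt_cell_key(cells$age_class, cells$spc)
    education <- new_cpt("education", c("age_class", "spc"), EDU_LEVELS, prob)

    # household income class and car ownership
    prob <- t(vapply(HH_TYPES, function(t) dir_row(INCOME_CLASSES, c(3, 4, 3)),
                     numeric(3)))
    rownames(prob) <- HH_TYPES
    income_class <- new_cpt("income_class", "hh_type", INCOME_CLASSES, prob)

    cells <- expand.grid(hh_type = HH_TYPES, income_class = INCOME_CLASSES,
                         stringsAsFactors = FALSE)
    prob <- t(apply(cells, 1, function(r) dir_row(CAR_LEVELS, c(3, 5))))
    rownames(prob) <- cpt_cell_key(cells$hh_type, cells$income_class)
    car <- new_cpt("car", c("hh_type", "income_class"), CAR_LEVELS, prob)

    list(hh_type = hh_type, gender = gender, age_class = age_class,
         activity = activity, spc = spc, education = education,
         income_class = income_class, car = car)
  })
  for (cp in cpts) assert_cpt_in_schema(cp, schema)

  size_dist <- with_substream(seed, "ground_truth_sizes", expr = {
    m <- t(vapply(iris, function(z) {
      d <- pmax(rdirichlet1(c(6, 6, 4, 3, 1.5, 0.8) * 2), 0.02)
      d / sum(d)
    }, numeric(6)))
    colnames(m) <- HH_SIZES
    m
  })

  overweight <- with_substream(seed, "ground_truth_overweight", expr = {
    cells <- expand.grid(gender = GENDERS, age_class = AGE_CLASSES,
                         spc = SPC_LEVELS, stringsAsFactors = FALSE)
    prob <- t(apply(cells, 1, function(r) rdirichlet1(c(6, 3, 1))))
    colnames(prob) <- OVERWEIGHT_LEVELS
    rownames(prob) <- cpt_cell_key(cells$gender, cells$age_class, cells$spc)
    new_cpt("overweight", c("gender", "age_class", "spc"),
            OVERWEIGHT_LEVELS, prob)
  })

  zone_medians <- with_substream(seed, "ground_truth_income", expr = {
    stats::setNames(round(exp(stats::rnorm(length(communes), log(20000),
                                           0.15))), communes)
  })
  spc_medians <- c("1" = 22000, "2" = 26000, "3" = 40000, "4" = 28000,
                   "5" = 20000, "6" = 18000, "7" = 16000, "8" = 9000)

  structure(list(schema = schema, cpts = cpts, size_dist_by_zone = size_dist,
                 spc_income_medians = spc_medians,
                 zone_medians = zone_medians, population_median = 20000,
                 overweight = overweight, zone_table = zone_table,
                 seed = as.integer(seed)),
            class = "ground_truth_model")
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth_model> seed %d: %d conditional tables, ",
                     "%d IRIS, %d communes\n"),
              x$seed, length(x$cpts), nrow(x$size_dist_by_zone),
              length(x$zone_medians)))
  invisible(x)
}

#' Serialize a ground-truth model to JSON
#'
#' @param model A `ground_truth_model`.
#' @param path Optional file path; when NULL the JSON string is returned.
#' @return The path (invisibly) or the JSON string.
#' @export
model_to_json <- function(model, path = NULL) {
  ser_cpt <- function(cp) {
    list(target = cp$target, given = cp$given, levels = cp$levels,
         cells = rownames(cp$prob),
         prob = unname(apply(cp$prob, 1, as.numeric, simplify = FALSE)))
  }
  obj <- list(seed = model$seed,
              cpts = lapply(model$cpts, ser_cpt),
              overweight = ser_cpt(model$overweight),
              size_dist_by_zone = list(
                zones = rownames(model$size_dist_by_zone),
                prob = unname(apply(model$size_dist_by_zone, 1, as.numeric,
                                    simplify = FALSE))),
              spc_income_medians = as.list(model$spc_income_medians),
              zone_medians = as.list(model$zone_medians),
              population_median = model$population_median)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Simulate census-style microdata from a ground-truth model
#'
#' Draws households by forward sampling through the model's conditional
#' tree under the structural rules, assigns individual incomes from the
#' model's income tables (with dispersion and statutory floors) and
#' overweight status from the contingency table, and returns one row per
#' individual.
#'
#' @param model A `ground_truth_model`.
#' @param n_households Total number of households to draw.
#' @param zones Character vector of IRIS ids (defaults to all IRIS of the
#'   model's zone table); households are spread proportionally to zone
#'   population.
#' @param seed Integer seed (independent of the model's seed).
#' @param constraints See [default_constraints()].
#' @return Data frame of individuals with household id, zone id and all
#'   schema attributes (integer age and age class, household income and
#'   income class, overweight status).
#' @export
simulate_census_sample <- function(model, n_households, zones = NULL,
                                   seed = 1L,
                                   constraints = default_constraints()) {
  if (n_households < 1) {
    stop("input error: n_households must be at least 1", call. = FALSE)
  }
  hierarchy <- build_zone_hierarchy(model$zone_table)
  if (is.null(zones)) zones <- zone_ids(hierarchy, "IRIS")
  if (length(zones) == 0L) {
    stop("input error: empty zone list", call. = FALSE)
  }
  if (!all(zones %in% rownames(model$size_dist_by_zone))) {
    stop("input error: zone(s) missing from the model size distributions",
         call. = FALSE)
  }
  pops <- model$zone_table$population[match(zones, model$zone_table$zone)]
  if (anyNA(pops)) pops <- rep(1, length(zones))
  n_by_zone <- largest_remainder(n_households * pops / sum(pops),
                                 n_households)

  offset <- 0L
  parts <- vector("list", length(zones))
  for (i in seq_along(zones)) {
    z <- zones[i]
    if (n_by_zone[i] == 0L) next
    parts[[i]] <- with_substream(seed, "census", z, expr = {
      sizes <- sample(1:6, n_by_zone[i], replace = TRUE,
                      prob = model$size_dist_by_zone[z, ])
      draw_households(sizes, z, model$cpts, constraints, hid_offset = offset)
    })
    offset <- offset + n_by_zone[i]
  }
  pop <- rbind_populations(Filter(Negate(is.null), parts))

  im <- income_model(model$zone_medians, model$spc_income_medians,
                     model$population_median)
  pop <- assign_income(pop, hierarchy, im, master_seed = seed)
  pop <- assign_overweight(pop, model$overweight, master_seed = seed)
  as_microdata(pop)
}

# integer allocation by largest remainder, total preserved
largest_remainder <- function(x, total) {
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

# Flatten a synth_population (with incomes/overweight) into a one-row-per-
# individual microdata table.
as_microdata <- function(pop) {
  ind <- pop$individuals
  hh <- pop$households
  m <- match(ind$hid, hh$hid)
  ind$car <- hh$car[m]
  ind$income_class <- hh$income_class[m]
  if (!is.null(hh$hh_income)) ind$hh_income <- hh$hh_income[m]
  cols <- c("hid", "zone", "hh_size", "hh_type", "car", "income_class",
            "hh_income", "pos", "role", "gender", "age", "age_class",
            "activity", "spc", "education", "income", "overweight")
  ind[, intersect(cols, names(ind))]
}

#' Simulate a building stock
#'
#' Buildings with log-uniform footprints in [50, 2000] m2, uniform heights
#' in [3, 30] m, a land-use tag (mostly residential), a per-m2 price drawn
#' around a zone-class baseline, and an occasional recorded dwelling count.
#'
#' @param zone_table Data frame with columns `zone` and `zone_class`
#'   (center/inner/outer), e.g. the IRIS rows of [fixture_zone_table()].
#' @param n_buildings Number of buildings to draw.
#' @param seed Integer seed.
#' @return Data frame with columns `bid`, `zone`, `zone_class`, `area_m2`,
#'   `height_m`, `land_use`, `n_dwellings` (NA unless recorded) and
#'   `price_m2`.
#' @export
simulate_buildings <- function(zone_table, n_buildings, seed = 1L) {
  if (n_buildings < 1) {
    stop("input error: n_buildings must be at least 1", call. = FALSE)
  }
  zt <- as.data.frame(zone_table)
  if ("level" %in% names(zt)) zt <- zt[zt$level == "IRIS", , drop = FALSE]
  if (nrow(zt) == 0L) stop("input error: empty zone list", call. = FALSE)
  with_substream(seed, "buildings", expr = {
    zi <- 1L + (seq_len(n_buildings) - 1L) %% nrow(zt)
    base_price <- c(center = 9000, inner = 6000, outer = 4000)
    zone_class <- zt$zone_class[zi]
    out <- data.frame(
      bid = paste0("B", seq_len(n_buildings)),
      zone = zt$zone[zi],
      zone_class = zone_class,
      area_m2 = exp(stats::runif(n_buildings, log(50), log(2000))),
      height_m = stats::runif(n_buildings, 3, 30),
      land_use = sample(c("residential", "commercial", "industrial"),
                        n_buildings, replace = TRUE,
                        prob = c(0.85, 0.10, 0.05)),
      n_dwellings = NA_integer_,
      stringsAsFactors = FALSE
    )
    out$price_m2 <- base_price[zone_class] *
      exp(stats::rnorm(n_buildings, 0, 0.3))
    # a minority of buildings carry a recorded dwelling count
    rec <- stats::runif(n_buildings) < 0.1 & out$land_use == "residential"
    out$n_dwellings[rec] <- pmax(1L, as.integer(round(
      out$area_m2[rec] * pmax(1, floor(out$height_m[rec] / 3)) / 70)))
    rownames(out) <- NULL
    out
  })
}
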