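# Income and overweight/obesity enrichment of generated individuals.
#
# Income follows the SPC-weighting scheme: an individual's income is the
# median income of their commune weighted by alpha = r_SPC / r, the ratio of
# the SPC's national median income to the population median, times an
# optional median-preserving lognormal dispersion factor, then floored at
# the statutory minima: the minimum wage (12,672 EUR/year in 2010) for
# employed persons and the Active Solidarity Income (5,520 EUR/year in
# 2010) for non-working persons aged 25 or over. Minors and students under
# 25 receive no income.

#' Income model
#'
#' @param commune_medians Named numeric vector: median annual income
#'   (EUR/year) per commune.
#' @param spc_medians Named numeric vector ("1".."8"): median annual income
#'   per socio-professional category.
#' @param population_median Median annual income of the whole population
#'   (the denominator of the SPC weights).
#' @param floor_employed Minimum annual income of an employed person
#'   (EUR/year).
#' @param floor_nonworking Minimum annual income of a non-working person
#'   aged 25 or over (EUR/year).
#' @return An object of class `income_model` with the `alpha` weights
#'   `spc_medians / population_median`.
#' @export
#' @examples
#' im <- income_model(c(C1 = 20000), c("1" = 30000, "2" = 20000,
#'   "3" = 20000, "4" = 20000, "5" = 20000, "6" = 20000, "7" = 20000,
#'   "8" = 20000), 20000)
#' im$alpha[["1"]]   # 1.5
income_model <- function(commune_medians, spc_medians, population_median,
                         floor_employed = 12672, floor_nonworking = 5520) {
  if (floor_employed <= 0 || floor_nonworking <= 0) {
    stop("input error: income floors must be positive", call. = FALSE)
  }
  if (!all(SPC_LEVELS %in% names(spc_medians))) {
    stop("model error: spc_medians must cover SPC 1..8", call. = FALSE)
  }
  structure(list(commune_medians = commune_medians,
                 spc_medians = spc_medians,
                 population_median = population_median,
                 alpha = spc_medians / population_median,
                 floor_employed = floor_employed,
                 floor_nonworking = floor_nonworking),
            class = "income_model")
}

#' Assign annual incomes to a generated population
#'
#' Applies the SPC weighting of commune median incomes with a
#' median-preserving lognormal dispersion factor (disable with
#' `dispersion_sigma = 0` for exact-reproduction checks), then the
#' statutory floors; household incomes are the sum of member incomes.
#'
#' @param population A `synth_population`.
#' @param hierarchy A `zone_hierarchy` used to resolve each individual's
#'   commune from their IRIS.
#' @param model An [income_model()].
#' @param dispersion_sigma Standard deviation of the lognormal dispersion
#'   on the log scale (default 0.25).
#' @param master_seed Integer master seed (a dedicated substream is used).
#' @return The population with an `income` column on individuals and an
#'   `hh_income` column on households.
#' @export
assign_income <- function(population, hierarchy, model,
                          dispersion_sigma = 0.25, master_seed = 1L) {
  ind <- population$individuals
  if (nrow(ind) == 0L) return(population)
  if (!all(ind$spc %in% SPC_LEVELS)) {
    stop("model error: unknown SPC in population", call. = FALSE)
  }
  communes <- commune_of(hierarchy, ind$zone)
  med <- model$commune_medians[communes]
  if (anyNA(med)) {
    stop("model error: commune(s) without a median income: ",
         paste(unique(communes[is.na(med)]), collapse = ", "),
         call. = FALSE)
  }
  base <- unname(model$alpha[ind$spc] * med)
  disp <- if (dispersion_sigma > 0) {
    with_substream(master_seed, "income_dispersion", expr = {
      exp(stats::rnorm(nrow(ind), 0, dispersion_sigma))
    })
  } else 1
  val <- base * disp
  income <- numeric(nrow(ind))
  minor <- ind$age < 18
  young_student <- !minor & ind$activity == "student" & ind$age < 25
  employed <- !minor & ind$activity == "Employed"
  nonworking25 <- !minor & !young_student & !employed & ind$age >= 25
  other_adult <- !(minor | young_student | employed | nonworking25)
  income[employed] <- pmax(val[employed], model$floor_employed)
  income[nonworking25] <- pmax(val[nonworking25], model$floor_nonworking)
  income[other_adult] <- val[other_adult]
  ind$income <- income
  population$individuals <- ind
  population$households <- aggregate_household_income(population)
  population
}

#' Aggregate member incomes to the household
#'
#' @param population A `synth_population` whose individuals carry incomes.
#' @return The household table with an `hh_income` column (sum of member
#'   incomes).
#' @export
aggregate_household_income <- function(population) {
  ind <- population$individuals
  hh <- population$households
  if (is.null(ind$income) || anyNA(ind$income)) {
    stop("state error: member incomes are not all set", call. = FALSE)
  }
  sums <- tapply(ind$income, ind$hid, sum)
  hh$hh_income <- as.numeric(sums[as.character(hh$hid)])
  hh
}

#' Assign overweight/obesity status
#'
#' Draws each individual's status (0 = normal, 1 = overweight, 2 = obese)
#' independently from the contingency cell for their (gender, age class,
#' SPC) subgroup, falling back to the (gender, age class) margin and then
#' to the overall margin when the cell is absent from the table.
#'
#' @param population A `synth_population`.
#' @param contingency A `cpt` with target `overweight` given
#'   `gender, age_class, spc` (possibly covering only part of the domain).
#' @param master_seed Integer master seed.
#' @return The population with an `overweight` column on individuals.
#' @export
assign_overweight <- function(population, contingency, master_seed = 1L) {
  ind <- population$individuals
  if (nrow(ind) == 0L) return(population)
  p <- cpt_rows_or_na(contingency, ind[, c("gender", "age_class", "spc")])
  miss <- is.na(p[, 1])
  if (any(miss)) {
    # fall back to the gender x age-class margin, then the overall margin
    margin <- marginalize_rows(contingency, c("gender", "age_class"))
    keys <- cpt_key(ind$gender[miss], ind$age_class[miss])
    idx <- match(keys, rownames(margin))
    fb <- margin[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
    still <- is.na(idx)
    if (any(still)) {
      overall <- colMeans(contingency$prob)
      overall <- overall / sum(overall)
      fb[still, ] <- matrix(overall, sum(still), ncol(fb), byrow = TRUE)
    }
    p[miss, ] <- fb
  }
  ind$overweight <- with_substream(master_seed, "overweight", expr = {
    contingency$levels[rcat_rows(p)]
  })
  population$individuals <- ind
  population
}

# Collapse a contingency cpt onto a subset of its conditioning variables by
# averaging cells (support-weighted when support counts are recorded).
marginalize_rows <- function(cpt, keep) {
  parts <- strsplit(rownames(cpt$prob), KEY_SEP, fixed = TRUE)
  pos <- match(keep, cpt$given)
  keys <- vapply(parts, function(p) paste(p[pos], collapse = KEY_SEP),
                 character(1))
  w <- if (!is.null(cpt$support)) cpt$support else rep(1, nrow(cpt$prob))
  num <- rowsum(cpt$prob * w, keys)
  den <- rowsum(w, keys)
  num / as.numeric(den)
}
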