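# Stage 4.1: building classification, dwelling counts from geometry, and
# the three-level price class per building.

#' Default housing parameters
#'
#' @param avg_dwelling_size Average dwelling floor area (m2) per zone
#'   class: 59 for the city center, 69 for the inner suburbs, 89 for the
#'   outer suburbs.
#' @param storey_height Storey height (m) used to convert building height
#'   to a floor count.
#' @param house_max_floors,house_max_area Thresholds of the house/block
#'   rule: a residential building is a house when it has at most this many
#'   floors and a footprint strictly below this area (m2).
#' @return Named list of parameters.
#' @export
housing_config <- function(avg_dwelling_size = c(center = 59, inner = 69,
                                                 outer = 89),
                           storey_height = 3,
                           house_max_floors = 2L,
                           house_max_area = 250) {
  list(avg_dwelling_size = avg_dwelling_size,
       storey_height = storey_height,
       house_max_floors = as.integer(house_max_floors),
       house_max_area = house_max_area)
}

#' Classify buildings as houses or blocks of flats
#'
#' A residential building is a house when it has at most
#' `house_max_floors` floors (height divided by the storey height, at
#' least 1) and a footprint below `house_max_area` m2; other residential
#' buildings are blocks. Non-residential buildings are excluded from the
#' housing stock (flagged, not an error).
#'
#' @param buildings Data frame with `area_m2`, `height_m` and `land_use`
#'   columns.
#' @param config See [housing_config()].
#' @return The table with `floors`, `kind` (`"house"`/`"block"`, NA when
#'   excluded) and `excluded` columns.
#' @export
#' @examples
#' b <- data.frame(area_m2 = c(100, 400), height_m = c(5, 21),
#'                 land_use = "residential")
#' classify_buildings(b)$kind
classify_buildings <- function(buildings, config = housing_config()) {
  b <- as.data.frame(buildings)
  need <- c("area_m2", "height_m", "land_use")
  if (!all(need %in% names(b))) {
    stop("input error: buildings need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(b$area_m2 <= 0 | b$height_m <= 0, na.rm = TRUE)) {
    stop("input error: nonpositive building area or height", call. = FALSE)
  }
  b$floors <- pmax(1L, as.integer(b$height_m %/% config$storey_height))
  b$excluded <- b$land_use != "residential"
  b$kind <- ifelse(b$excluded, NA_character_,
                   ifelse(b$floors <= config$house_max_floors &
                            b$area_m2 < config$house_max_area,
                          "house", "block"))
  b
}

#' Derive dwelling counts from building geometry
#'
#' For blocks without a recorded dwelling count, the count is the total
#' floor surface (footprint times floor count) divided by the zone class's
#' average dwelling size, rounded half-up with a minimum of one. Houses
#' hold one dwelling; recorded counts pass through unchanged; excluded
#' buildings get none.
#'
#' @param buildings Output of [classify_buildings()], with `zone_class`
#'   and optionally `n_dwellings` (NA where unknown) columns.
#' @param config See [housing_config()].
#' @return The table with the `n_dwellings` column filled.
#' @export
#' @examples
#' b <- data.frame(area_m2 = 200, height_m = 9, land_use = "residential",
#'                 zone_class = "center")
#' count_dwellings(classify_buildings(b))$n_dwellings   # 10
count_dwellings <- function(buildings, config = housing_config()) {
  b <- as.data.frame(buildings)
  if (!all(c("kind", "floors", "zone_class") %in% names(b))) {
    stop("input error: classify buildings first", call. = FALSE)
  }
  if (is.null(b$n_dwellings)) b$n_dwellings <- NA_integer_
  avg <- config$avg_dwelling_size[b$zone_class]
  if (anyNA(avg[!b$excluded])) {
    stop("input error: unknown zone class", call. = FALSE)
  }
  total_surface <- b$area_m2 * b$floors
  computed <- pmax(1L, as.integer(floor(total_surface / avg + 0.5)))
  fill <- is.na(b$n_dwellings) & !b$excluded
  b$n_dwellings[fill] <- ifelse(b$kind[fill] == "house", 1L, computed[fill])
  b$n_dwellings[b$excluded] <- NA_integer_
  b
}

#' Assign low/intermediate/high price classes to buildings
#'
#' Tertiles of the price per m2 are computed within each commune;
#' boundaries go to the lower class and an all-equal commune collapses to
#' the intermediate class. Communes with fewer than three priced
#' residential buildings fall back to their department's tertile cuts.
#'
#' @param buildings Data frame with `price_m2`, `zone` and `excluded`
#'   columns.
#' @param hierarchy A `zone_hierarchy` used to resolve communes and
#'   departments from the building zones.
#' @return The table with a `price_class` column (NA for excluded
#'   buildings).
#' @export
assign_price_class <- function(buildings, hierarchy) {
  b <- as.data.frame(buildings)
  if (!"price_m2" %in% names(b)) {
    stop("input error: buildings need a price_m2 column", call. = FALSE)
  }
  if (is.null(b$excluded)) b$excluded <- FALSE
  b$price_class <- NA_character_
  commune <- commune_of(hierarchy, b$zone)
  department <- department_of(hierarchy, b$zone)
  use <- !b$excluded & !is.na(b$price_m2)
  for (cm in unique(commune[use])) {
    sel <- use & commune == cm
    if (sum(sel) >= 3L) {
      b$price_class[sel] <- tertile_classes(b$price_m2[sel])
    } else {
      dp <- department[which(sel)[1]]
      pool <- use & department == dp
      cuts <- tertile_cuts(b$price_m2[pool])
      b$price_class[sel] <- classify_by_cuts(b$price_m2[sel], cuts)
    }
  }
  b
}

#' Expand buildings into a dwelling table
#'
#' @param buildings Classified, counted and price-classed building table.
#' @return Data frame with one row per dwelling: `did`, `bid`, `zone`,
#'   `price_class` (inherited from the building) and an empty `hid`
#'   occupant column.
#' @export
dwellings_from_buildings <- function(buildings) {
  b <- as.data.frame(buildings)
  b <- b[!b$excluded & !is.na(b$n_dwellings) & b$n_dwellings >= 1L, ]
  if (nrow(b) == 0L) {
    return(data.frame(did = character(0), bid = character(0),
                      zone = character(0), price_class = character(0),
                      hid = integer(0)))
  }
  idx <- rep(seq_len(nrow(b)), b$n_dwellings)
  data.frame(
    did = paste0(b$bid[idx], "_", sequence(b$n_dwellings)),
    bid = b$bid[idx],
    zone = b$zone[idx],
    price_class = b$price_class[idx],
    hid = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Build the full housing stock from raw buildings
#'
#' Classification, dwelling counting, price classes and expansion to
#' dwellings in one call.
#'
#' @param buildings Raw building table (see [simulate_buildings()]).
#' @param hierarchy A `zone_hierarchy`.
#' @param config See [housing_config()].
#' @return List with `buildings` (enriched table) and `dwellings`.
#' @export
build_housing_stock <- function(buildings, hierarchy,
                                config = housing_config()) {
  b <- classify_buildings(buildings, config)
  b <- count_dwellings(b, config)
  b <- assign_price_class(b, hierarchy)
  list(buildings = b, dwellings = dwellings_from_buildings(b))
}
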