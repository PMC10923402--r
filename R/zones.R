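# Zone hierarchy: region -> department -> (canton ->) commune -> IRIS.

ZONE_LEVELS <- c("region", "department", "canton", "commune", "IRIS")

#' Build and validate a zone hierarchy
#'
#' @param zone_table Data frame with columns `zone` (id), `level` (one of
#'   region, department, canton, commune, IRIS), `parent` (id, NA for the
#'   region) and `population` (non-negative count). Extra columns (e.g. a
#'   `zone_class` urbanization tag) are kept.
#' @return An object of class `zone_hierarchy` (the validated table).
#' @export
#' @examples
#' zt <- fixture_zone_table(seed = 1)
#' h <- build_zone_hierarchy(zt)
#' zone_ids(h, "IRIS")
build_zone_hierarchy <- function(zone_table) {
  need <- c("zone", "level", "parent", "population")
  if (!all(need %in% names(zone_table))) {
    stop("input error: zone table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  zt <- as.data.frame(zone_table)
  zt$zone <- as.character(zt$zone)
  zt$parent <- as.character(zt$parent)
  if (anyDuplicated(zt$zone)) {
    stop("input error: duplicate zone id(s): ",
         paste(unique(zt$zone[duplicated(zt$zone)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(zt$level %in% ZONE_LEVELS)) {
    stop("input error: unknown zone level(s)", call. = FALSE)
  }
  if (any(zt$population < 0, na.rm = TRUE)) {
    stop("input error: negative population count", call. = FALSE)
  }
  root <- zt$level == "region"
  if (!any(root)) stop("hierarchy error: no region root", call. = FALSE)
  nonroot <- zt[!root, , drop = FALSE]
  orphan <- !(nonroot$parent %in% zt$zone) | is.na(nonroot$parent)
  if (any(orphan)) {
    stop("hierarchy error: orphan zone(s): ",
         paste(nonroot$zone[orphan], collapse = ", "), call. = FALSE)
  }
  # walk every node to the root; detects cycles and checks IRIS lineage
  parent_of <- stats::setNames(zt$parent, zt$zone)
  level_of <- stats::setNames(zt$level, zt$zone)
  for (z in zt$zone) {
    seen <- character(0)
    cur <- z
    while (!is.na(parent_of[[cur]]) && level_of[[cur]] != "region") {
      if (cur %in% seen) {
        stop("hierarchy error: cycle at zone ", z, call. = FALSE)
      }
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
    if (level_of[[cur]] != "region") {
      stop("hierarchy error: zone ", z, " does not reach the region",
           call. = FALSE)
    }
  }
  iris <- zt$zone[zt$level == "IRIS"]
  if (length(iris)) {
    has_commune <- vapply(iris, function(z) {
      "commune" %in% level_of[ancestor_chain(parent_of, level_of, z)]
    }, logical(1))
    if (!all(has_commune)) {
      stop("hierarchy error: IRIS without commune ancestor: ",
           paste(iris[!has_commune], collapse = ", "), call. = FALSE)
    }
  }
  structure(zt, class = c("zone_hierarchy", "data.frame"))
}

ancestor_chain <- function(parent_of, level_of, zone) {
  chain <- character(0)
  cur <- zone
  while (level_of[[cur]] != "region") {
    cur <- parent_of[[cur]]
    chain <- c(chain, cur)
  }
  chain
}

#' Zone ids at a hierarchy level
#' @param hierarchy A `zone_hierarchy`.
#' @param level One of region, department, canton, commune, IRIS.
#' @export
zone_ids <- function(hierarchy, level = "IRIS") {
  hierarchy$zone[hierarchy$level == level]
}

#' Ancestors of a zone, finest first, ending at the region
#' @param hierarchy A `zone_hierarchy`.
#' @param zone Zone id.
#' @export
zone_ancestors <- function(hierarchy, zone) {
  if (!zone %in% hierarchy$zone) {
    stop("unknown zone: ", zone, call. = FALSE)
  }
  parent_of <- stats::setNames(hierarchy$parent, hierarchy$zone)
  level_of <- stats::setNames(hierarchy$level, hierarchy$zone)
  ancestor_chain(parent_of, level_of, zone)
}

# Commune ancestor (or the zone itself if already a commune) for each of a
# vector of zone ids.
commune_of <- function(hierarchy, zones) {
  lut <- vapply(unique(zones), function(z) {
    if (hierarchy$level[match(z, hierarchy$zone)] == "commune") return(z)
    chain <- zone_ancestors(hierarchy, z)
    lv <- hierarchy$level[match(chain, hierarchy$zone)]
    if (!"commune" %in% lv) return(NA_character_)
    chain[match("commune", lv)]
  }, character(1))
  unname(lut[zones])
}

department_of <- function(hierarchy, zones) {
  lut <- vapply(unique(zones), function(z) {
    if (hierarchy$level[match(z, hierarchy$zone)] == "department") return(z)
    chain <- zone_ancestors(hierarchy, z)
    lv <- hierarchy$level[match(chain, hierarchy$zone)]
    chain[match("department", lv)]
  }, character(1))
  unname(lut[zones])
}

#' Fixture zone table
#'
#' A four-level tree (1 region, 2 departments, 4 communes, 8 IRIS by
#' default) with commune urbanization classes center/inner/outer and
#' randomized IRIS population counts. IRIS inherit their commune's class.
#'
#' @param n_department,n_commune,n_iris Tree widths.
#' @param seed Integer seed for the population counts.
#' @param mean_iris_pop Mean population per IRIS.
#' @return Data frame suitable for [build_zone_hierarchy()], with a
#'   `zone_class` column.
#' @export
fixture_zone_table <- function(n_department = 2, n_commune = 4, n_iris = 8,
                               seed = 1, mean_iris_pop = 1500) {
  deps <- paste0("D", seq_len(n_department))
  coms <- paste0("C", seq_len(n_commune))
  iris <- paste0("I", seq_len(n_iris))
  com_parent <- deps[(seq_len(n_commune) - 1L) %% n_department + 1L]
  iris_parent <- coms[(seq_len(n_iris) - 1L) %% n_commune + 1L]
  com_class <- c("center", "inner",
                 rep("outer", max(0, n_commune - 2)))[seq_len(n_commune)]
  pops <- with_substream(seed, "fixture_zone_pop", expr = {
    pmax(200L, as.integer(round(mean_iris_pop *
                                  stats::runif(n_iris, 0.6, 1.4))))
  })
  tab <- rbind(
    data.frame(zone = "R1", level = "region", parent = NA_character_,
               population = NA_integer_, zone_class = NA_character_),
    data.frame(zone = deps, level = "department", parent = "R1",
               population = NA_integer_, zone_class = NA_character_),
    data.frame(zone = coms, level = "commune", parent = com_parent,
               population = NA_integer_, zone_class = com_class),
    data.frame(zone = iris, level = "IRIS", parent = iris_parent,
               population = pops,
               zone_class = com_class[match(iris_parent, coms)])
  )
  # aggregate populations upward
  tab$population[match(coms, tab$zone)] <- vapply(coms, function(cm) {
    sum(tab$population[tab$parent == cm & tab$level == "IRIS"])
  }, integer(1))
  tab$population[match(deps, tab$zone)] <- vapply(deps, function(d) {
    sum(tab$population[tab$parent == d & tab$level == "commune"])
  }, integer(1))
  tab$population[tab$zone == "R1"] <-
    sum(tab$population[tab$level == "department"])
  rownames(tab) <- NULL
  tab
}
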