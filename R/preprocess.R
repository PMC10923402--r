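# Stage 1: microdata cleaning, discretization, and estimation of the
# conditional probability tables with hierarchical spatial fallback.

#' Clean census-style microdata
#'
#' Removes rows with missing, out-of-schema or out-of-range values in the
#' mandatory fields, and then removes every remaining member of any
#' household that lost a member (a partial household is structurally
#' invalid). The report counts removals by rule.
#'
#' @param raw Data frame with at least `hid` and `zone` columns.
#' @param schema Attribute schema.
#' @return List with `data` (the cleaned table) and `report` (an object of
#'   class `cleaning_report`: per-rule removed-row counts, plus the number
#'   of households dropped whole).
#' @export
clean_microdata <- function(raw, schema = default_schema()) {
  if (!all(c("hid", "zone") %in% names(raw))) {
    stop("input error: microdata needs hid and zone columns", call. = FALSE)
  }
  tab <- as.data.frame(raw)
  n <- nrow(tab)
  bad <- rep(FALSE, n)
  counts <- c(missing = 0L, `out of range` = 0L, `out of schema` = 0L)

  flag <- function(sel, rule) {
    new <- sel & !bad
    counts[[rule]] <<- counts[[rule]] + sum(new)
    bad <<- bad | sel
  }
  flag(is.na(tab$hid) | is.na(tab$zone), "missing")
  if ("age" %in% names(tab)) {
    agev <- suppressWarnings(as.numeric(tab$age))
    flag(is.na(tab$age), "missing")
    flag(is.na(agev) & !is.na(tab$age), "out of range")
    flag(!is.na(agev) & (agev < 0 | agev > 120), "out of range")
  }
  for (v in names(schema)) {
    if (!v %in% names(tab)) next
    cats <- schema[[v]]$categories
    if (is.null(cats)) next
    val <- as.character(tab[[v]])
    flag(is.na(val), "missing")
    flag(!is.na(val) & !val %in% cats, "out of schema")
  }
  bad_households <- unique(tab$hid[bad])
  keep <- !(tab$hid %in% bad_households)
  report <- structure(list(rules = counts,
                           rows_removed = sum(!keep),
                           rows_removed_directly = sum(bad),
                           households_removed = length(bad_households)),
                      class = "cleaning_report")
  list(data = tab[keep, , drop = FALSE], report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  for (r in names(x$rules)) cat(sprintf("  %-14s %d\n", r, x$rules[[r]]))
  cat(sprintf("  rows removed    %d (whole-household rule)\n",
              x$rows_removed))
  cat(sprintf("  households lost %d\n", x$households_removed))
  invisible(x)
}

#' Discretize continuous attributes
#'
#' Maps integer ages to the four age classes (lower bound inclusive, upper
#' exclusive, 120 included in the last class) and, when the table carries a
#' household income but no income class, derives the three income classes
#' as income tertiles (boundaries to the lower class). Categorical columns
#' are verified against the schema.
#'
#' @param tab Microdata table.
#' @param schema Attribute schema.
#' @return The table with `age_class` (and `income_class` if derivable)
#'   columns added.
#' @export
discretize <- function(tab, schema = default_schema()) {
  tab <- as.data.frame(tab)
  if (!"age" %in% names(tab)) {
    stop("input error: numeric age column required", call. = FALSE)
  }
  tab$age_class <- age_to_class(as.numeric(tab$age))
  if (!"income_class" %in% names(tab) && "hh_income" %in% names(tab)) {
    tab$income_class <- tertile_classes(tab$hh_income)
  }
  for (v in names(schema)) {
    if (!v %in% names(tab)) next
    cats <- schema[[v]]$categories
    if (is.null(cats)) next
    val <- as.character(tab[[v]])
    if (any(!is.na(val) & !val %in% cats)) {
      stop("input error: out-of-schema value in ", v, call. = FALSE)
    }
  }
  tab
}

#' Estimate a conditional probability table
#'
#' Empirical estimate of P(target | given) from microdata. When `"zone"` is
#' part of the conditioning tuple, every IRIS gets its own cell estimated
#' at the finest spatial level of its ancestor chain whose support reaches
#' `min_count`, falling back to commune, department and finally region
#' (hierarchical gap-filling for sparse cells). Target categories whose
#' regional relative frequency is below `merge_floor` are merged into the
#' variable's designated "other" category when the schema defines one.
#'
#' @param tab Microdata table carrying the target and conditioning columns
#'   (and `zone` when conditioning on it).
#' @param target Target variable name.
#' @param given Character vector of conditioning variables; may include
#'   `"zone"`.
#' @param hierarchy A `zone_hierarchy` (required when conditioning on
#'   zone).
#' @param min_count Minimum observations per conditioning cell (default
#'   10).
#' @param schema Attribute schema.
#' @param merge_floor Regional relative-frequency floor below which target
#'   categories are merged into the "other" category (default 0.005).
#' @return A `cpt` whose cells record the estimation support and the
#'   spatial level used.
#' @export
estimate_conditional <- function(tab, target, given, hierarchy = NULL,
                                 min_count = 10L,
                                 schema = default_schema(),
                                 merge_floor = 0.005) {
  if (min_count < 1L) {
    stop("input error: min_count must be at least 1", call. = FALSE)
  }
  levels_t <- schema_categories(schema, target)
  if (is.null(levels_t)) {
    stop("schema error: target must be categorical", call. = FALSE)
  }
  plain_given <- setdiff(given, "zone")
  for (v in plain_given) {
    if (is.null(schema_categories(schema, v))) {
      stop("schema error: conditioning variable ", v,
           " is not categorical", call. = FALSE)
    }
  }
  need <- c(target, plain_given, if ("zone" %in% given) "zone")
  if (!all(need %in% names(tab))) {
    stop("input error: table lacks column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }

  y <- as.character(tab[[target]])
  # rare-category merge at regional level
  freq <- table(factor(y, levels_t)) / length(y)
  other <- schema[[target]]$other
  if (!is.na(other)) {
    rare <- names(freq)[freq > 0 & freq < merge_floor]
    rare <- setdiff(rare, other)
    if (length(rare)) y[y %in% rare] <- other
  }
  yf <- factor(y, levels_t)

  gkey <- if (length(plain_given)) cpt_key_df(tab, plain_given) else
    rep("", nrow(tab))
  combos <- sort(unique(gkey))

  count_block <- function(sel) {
    # counts over target categories per conditioning combo, in `combos` order
    t(vapply(combos, function(g) {
      tabulate(yf[sel & gkey == g], nbins = length(levels_t))
    }, numeric(length(levels_t))))
  }

  if (!"zone" %in% given) {
    cnt <- count_block(rep(TRUE, nrow(tab)))
    support <- rowSums(cnt)
    short <- support < min_count
    if (any(short)) {
      stop("estimation error: cell(s) below min_count at region level: ",
           paste(gsub(KEY_SEP, "/", combos[short], fixed = TRUE),
                 collapse = "; "), call. = FALSE)
    }
    prob <- cnt / support
    rownames(prob) <- combos
    return(new_cpt(target, plain_given, levels_t, prob,
                   support = as.integer(support),
                   level = rep("region", length(support))))
  }

  if (is.null(hierarchy)) {
    stop("input error: hierarchy required when conditioning on zone",
         call. = FALSE)
  }
  iris <- zone_ids(hierarchy, "IRIS")
  # counts per (ancestor zone at each level, combo)
  chains <- lapply(iris, function(z) c(z, zone_ancestors(hierarchy, z)))
  names(chains) <- iris
  all_nodes <- unique(unlist(chains))
  node_counts <- lapply(all_nodes, function(nd) {
    lv <- hierarchy$level[match(nd, hierarchy$zone)]
    members <- if (lv == "IRIS") nd else {
      iris[vapply(chains, function(ch) nd %in% ch, logical(1))]
    }
    count_block(tab$zone %in% members)
  })
  names(node_counts) <- all_nodes

  rows <- list()
  supc <- integer(0)
  levc <- character(0)
  keys <- character(0)
  for (z in iris) {
    for (j in seq_along(combos)) {
      found <- FALSE
      for (nd in chains[[z]]) {
        cnt <- node_counts[[nd]][j, ]
        if (sum(cnt) >= min_count) {
          rows[[length(rows) + 1L]] <- cnt / sum(cnt)
          supc <- c(supc, as.integer(sum(cnt)))
          levc <- c(levc, hierarchy$level[match(nd, hierarchy$zone)])
          keys <- c(keys, cpt_key(z, combos[j]))
          found <- TRUE
          break
        }
      }
      if (!found) {
        stop("estimation error: cell below min_count even at region: ",
             z, " / ", gsub(KEY_SEP, "/", combos[j], fixed = TRUE),
             call. = FALSE)
      }
    }
  }
  prob <- do.call(rbind, rows)
  rownames(prob) <- keys
  new_cpt(target, c("zone", plain_given), levels_t, prob,
          support = supc, level = levc)
}

#' Household-size distribution of a zone
#'
#' Empirical distribution of household sizes 1..6 in the zone, estimated at
#' the finest level of the zone's ancestor chain whose household count
#' reaches `min_count` (the same hierarchical fallback as
#' [estimate_conditional()]).
#'
#' @param tab Microdata table (one row per individual) with `hid`, `zone`
#'   and `hh_size` columns.
#' @param zone Zone id.
#' @param hierarchy A `zone_hierarchy`.
#' @param min_count Minimum number of households for a level to be used.
#' @return Probability vector over sizes 1..6 (sums to 1) with attributes
#'   `support` and `level`.
#' @export
household_size_distribution <- function(tab, zone, hierarchy,
                                        min_count = 10L) {
  if (!zone %in% hierarchy$zone) {
    stop("input error: unknown zone ", zone, call. = FALSE)
  }
  hh <- tab[!duplicated(tab$hid), c("hid", "zone", "hh_size")]
  iris <- zone_ids(hierarchy, "IRIS")
  chain <- c(zone, zone_ancestors(hierarchy, zone))
  for (nd in chain) {
    lv <- hierarchy$level[match(nd, hierarchy$zone)]
    members <- if (lv == "IRIS") nd else {
      iris[vapply(iris, function(z) {
        nd %in% c(z, zone_ancestors(hierarchy, z))
      }, logical(1))]
    }
    sel <- hh$zone %in% members
    if (sum(sel) >= min_count) {
      cnt <- tabulate(as.integer(hh$hh_size[sel]), nbins = 6L)
      out <- cnt / sum(cnt)
      names(out) <- HH_SIZES
      attr(out, "support") <- sum(sel)
      attr(out, "level") <- lv
      return(out)
    }
  }
  stop("estimation error: household-size cell below min_count even at ",
       "region for zone ", zone, call. = FALSE)
}

#' Estimate the full conditional-table set from microdata
#'
#' Convenience wrapper estimating the eight conditional tables of the
#' generation tree (household type, gender, age class, activity, SPC,
#' education, income class, car ownership) pooled at regional level, plus
#' the per-IRIS household-size distributions with hierarchical fallback.
#'
#' @param tab Microdata table (one row per individual).
#' @param hierarchy A `zone_hierarchy`.
#' @param schema Attribute schema.
#' @param min_count Minimum observations per conditioning cell.
#' @return List with `cpts` (named list usable by [gibbs_sweep()]) and
#'   `size_dists` (named list of per-IRIS size distributions).
#' @export
estimate_model <- function(tab, hierarchy, schema = default_schema(),
                           min_count = 10L) {
  hh <- tab[!duplicated(tab$hid), , drop = FALSE]
  hh$hh_size <- as.character(hh$hh_size)
  est <- function(data, target, given) {
    estimate_conditional(data, target, given, hierarchy,
                         min_count = min_count, schema = schema)
  }
  cpts <- list(
    hh_type = est(hh, "hh_type", "hh_size"),
    gender = est(tab, "gender", c("role", "hh_type")),
    age_class = est(tab, "age_class", c("hh_type", "role")),
    activity = est(tab, "activity", "age_class"),
    spc = est(tab, "spc", c("age_class", "activity")),
    education = est(tab, "education", c("age_class", "spc")),
    income_class = est(hh, "income_class", "hh_type"),
    car = est(hh, "car", c("hh_type", "income_class"))
  )
  iris <- zone_ids(hierarchy, "IRIS")
  size_dists <- lapply(iris, function(z) {
    household_size_distribution(tab, z, hierarchy, min_count)
  })
  names(size_dists) <- iris
  list(cpts = cpts, size_dists = size_dists)
}
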