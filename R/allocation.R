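# Stage 4.2: allocation of households to dwellings within their IRIS by
# matching income strata to price classes, uniformly at random within a
# class, with nearest-class fallback when a class is saturated.

#' Stratify households by income within their zone
#'
#' Per-IRIS income tertiles define three strata aligned with the three
#' dwelling price classes; boundaries go to the lower stratum and an
#' all-equal zone collapses to the intermediate stratum.
#'
#' @param households Household table with `zone` and `hh_income` columns.
#' @return The table with a `stratum` column
#'   (`"low"`/`"intermediate"`/`"high"`).
#' @export
stratify_household_income <- function(households) {
  hh <- as.data.frame(households)
  if (nrow(hh) == 0L) {
    hh$stratum <- character(0)
    return(hh)
  }
  if (is.null(hh$hh_income) || anyNA(hh$hh_income)) {
    stop("state error: household incomes are not all set", call. = FALSE)
  }
  hh$stratum <- NA_character_
  for (z in unique(hh$zone)) {
    sel <- hh$zone == z
    hh$stratum[sel] <- tertile_classes(hh$hh_income[sel])
  }
  hh
}

# class preference order per stratum (own class first, then nearest)
ALLOC_PREFERENCE <- list(
  high = c("high", "intermediate", "low"),
  intermediate = c("intermediate", "high", "low"),
  low = c("low", "intermediate", "high")
)

#' Allocate households to dwellings
#'
#' Within each IRIS, high-stratum households are placed first, then
#' intermediate, then low. Each household draws uniformly at random among
#' the free dwellings of its matching price class; when that class is
#' exhausted it draws from the nearest class (high to intermediate to low,
#' low to intermediate to high, intermediate to high then low). Every
#' household gets exactly one dwelling and no dwelling is assigned twice.
#'
#' @param households Household table with `hid`, `zone` and either a
#'   `stratum` column or `hh_income` (strata are then derived with
#'   [stratify_household_income()]).
#' @param dwellings Dwelling table from [dwellings_from_buildings()].
#' @param master_seed Integer master seed; each zone uses its own
#'   substream, so results do not depend on zone processing order.
#' @return Assignment data frame: `hid`, `did`, `bid`, `zone`, `stratum`,
#'   `price_class`.
#' @export
allocate_households <- function(households, dwellings, master_seed = 1L) {
  hh <- as.data.frame(households)
  dw <- as.data.frame(dwellings)
  if (is.null(hh$stratum)) hh <- stratify_household_income(hh)
  zones <- unique(hh$zone)
  out <- vector("list", length(zones))
  for (i in seq_along(zones)) {
    z <- zones[i]
    hz <- hh[hh$zone == z, , drop = FALSE]
    dz <- dw[dw$zone == z, , drop = FALSE]
    if (nrow(dz) < nrow(hz)) {
      stop("capacity error: zone ", z, " has ", nrow(dz),
           " dwellings for ", nrow(hz), " households", call. = FALSE)
    }
    out[[i]] <- with_substream(master_seed, "allocation", z, expr = {
      pools <- lapply(INCOME_CLASSES, function(cl) {
        idx <- which(dz$price_class == cl)
        idx[sample.int(length(idx))]
      })
      names(pools) <- INCOME_CLASSES
      taken <- lapply(pools, function(x) 0L)   # consumed per pool
      res <- list()
      for (s in c("high", "intermediate", "low")) {
        rows <- which(hz$stratum == s)
        if (!length(rows)) next
        rows <- rows[sample.int(length(rows))]
        picked <- integer(length(rows))
        for (k in seq_along(rows)) {
          for (cl in ALLOC_PREFERENCE[[s]]) {
            if (taken[[cl]] < length(pools[[cl]])) {
              taken[[cl]] <- taken[[cl]] + 1L
              picked[k] <- pools[[cl]][taken[[cl]]]
              break
            }
          }
        }
        res[[s]] <- data.frame(hid = hz$hid[rows],
                               did = dz$did[picked],
                               bid = dz$bid[picked],
                               zone = z,
                               stratum = s,
                               price_class = dz$price_class[picked],
                               stringsAsFactors = FALSE)
      }
      do.call(rbind, Filter(Negate(is.null), res))
    })
  }
  ans <- do.call(rbind, out)
  rownames(ans) <- NULL
  ans
}
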