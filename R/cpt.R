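# ConditionalTable: P(target | conditioning attributes), the unit of the
# conditional-probability tree. Cells are rows of a row-stochastic matrix
# keyed by the conditioning-value tuple; estimated tables also record per-cell
# support counts and the spatial resolution level at which each cell was
# estimated.

KEY_SEP <- "\x1f"

cpt_key <- function(...) {
  cols <- list(...)
  if (length(cols) == 0L) return("")
  do.call(paste, c(cols, sep = KEY_SEP))
}

cpt_key_df <- function(df, given) {
  if (length(given) == 0L) return(rep("", max(nrow(df), 1L)))
  do.call(paste, c(unname(as.list(df[given])), sep = KEY_SEP))
}

#' Construct a conditional probability table
#'
#' @param target Target variable name.
#' @param given Character vector of conditioning variable names (possibly
#'   empty, possibly including `"zone"`).
#' @param levels Ordered categories of the target.
#' @param prob Numeric matrix, one row per conditioning cell and one column
#'   per target category; rows must sum to 1 within 1e-9. Row names are the
#'   conditioning-value keys (see `cpt_cell_key`).
#' @param support Optional integer vector of per-cell observation counts.
#' @param level Optional character vector naming the spatial resolution at
#'   which each cell was estimated.
#' @return An object of class `cpt`.
#' @export
new_cpt <- function(target, given, levels, prob, support = NULL,
                    level = NULL) {
  prob <- as.matrix(prob)
  colnames(prob) <- levels
  if (is.null(rownames(prob))) {
    if (nrow(prob) != 1L || length(given) != 0L) {
      stop("cpt rows must be keyed by conditioning values", call. = FALSE)
    }
    rownames(prob) <- ""
  }
  bad <- abs(rowSums(prob) - 1) > 1e-9
  if (any(bad)) {
    stop("cpt rows must sum to 1 (violated for ",
         paste(utils::head(rownames(prob)[bad], 3), collapse = "; "), ")",
         call. = FALSE)
  }
  structure(list(target = target, given = given, levels = levels,
                 prob = prob, support = support, level = level),
            class = "cpt")
}

#' Key for a conditioning cell
#'
#' Joins conditioning values in the order of the table's `given` vector.
#' @param ... Conditioning values (vectors are combined elementwise).
#' @return Character vector of cell keys.
#' @export
cpt_cell_key <- function(...) cpt_key(...)

#' @export
print.cpt <- function(x, ...) {
  cat(sprintf("<cpt> P(%s | %s): %d cell(s) x %d categories\n", x$target,
              if (length(x$given)) paste(x$given, collapse = ", ") else "-",
              nrow(x$prob), ncol(x$prob)))
  invisible(x)
}

# Probability rows for the conditioning values found in `df` (a data frame
# holding the `given` columns). Missing cells raise an error naming the cell.
cpt_rows <- function(cpt, df) {
  keys <- cpt_key_df(df, cpt$given)
  idx <- match(keys, rownames(cpt$prob))
  if (anyNA(idx)) {
    miss <- unique(keys[is.na(idx)])
    stop("sampling error: no conditional cell for P(", cpt$target, " | ",
         paste(cpt$given, collapse = ","), ") at cell(s) ",
         paste(gsub(KEY_SEP, "/", utils::head(miss, 3), fixed = TRUE),
               collapse = "; "),
         call. = FALSE)
  }
  cpt$prob[idx, , drop = FALSE]
}

# As cpt_rows but returns NA rows instead of erroring (used by fallbacks).
cpt_rows_or_na <- function(cpt, df) {
  keys <- cpt_key_df(df, cpt$given)
  idx <- match(keys, rownames(cpt$prob))
  out <- matrix(NA_real_, length(keys), ncol(cpt$prob),
                dimnames = list(NULL, colnames(cpt$prob)))
  ok <- !is.na(idx)
  out[ok, ] <- cpt$prob[idx[ok], , drop = FALSE]
  out
}

# Probability of given observed target values under the table (vectorized);
# used when computing Gibbs full conditionals.
cpt_prob_of <- function(cpt, df, value) {
  p <- cpt_rows(cpt, df)
  j <- match(value, cpt$levels)
  if (anyNA(j)) stop("unknown category for ", cpt$target, call. = FALSE)
  p[cbind(seq_len(nrow(p)), j)]
}

# As cpt_prob_of, but a conditioning cell absent from the table contributes
# probability 0. Used when scoring hypothetical values in full
# conditionals: empirically estimated tables only carry observed cells, and
# an unobserved combination has zero probability under the tree.
cpt_prob_of0 <- function(cpt, df, value) {
  p <- cpt_rows_or_na(cpt, df)
  j <- match(value, cpt$levels)
  if (anyNA(j)) stop("unknown category for ", cpt$target, call. = FALSE)
  out <- p[cbind(seq_len(nrow(p)), j)]
  out[is.na(out)] <- 0
  out
}

# As cpt_rows but absent cells yield all-zero rows.
cpt_rows_zero <- function(cpt, df) {
  p <- cpt_rows_or_na(cpt, df)
  p[is.na(p)] <- 0
  p
}

# Check every category appearing in a cpt against a schema.
assert_cpt_in_schema <- function(cpt, schema) {
  cats <- schema_categories(schema, cpt$target)
  if (!all(cpt$levels %in% cats)) {
    stop("cpt levels for ", cpt$target, " are not all schema categories",
         call. = FALSE)
  }
  invisible(cpt)
}

#' Serialize a conditional table to JSON
#'
#' @param cpt A `cpt` object.
#' @param path File path to write.
#' @export
write_cpt_json <- function(cpt, path) {
  obj <- list(target = cpt$target, given = cpt$given, levels = cpt$levels,
              cells = rownames(cpt$prob),
              prob = unname(apply(cpt$prob, 1, as.numeric, simplify = FALSE)),
              support = cpt$support, level = cpt$level)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a conditional table from JSON
#'
#' @param path File path written by [write_cpt_json()].
#' @return A `cpt` object.
#' @export
read_cpt_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  prob <- matrix(unlist(obj$prob), nrow = length(obj$cells), byrow = TRUE)
  rownames(prob) <- obj$cells
  new_cpt(obj$target, as.character(obj$given), as.character(obj$levels),
          prob,
          support = if (!is.null(obj$support)) as.integer(obj$support),
          level = if (!is.null(obj$level)) as.character(obj$level))
}
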