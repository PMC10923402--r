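# Attribute schema: the catalogue of variables and categories that drives
# discretization, sampling and validation.

AGE_CLASSES <- c("[0-15)", "[15-35)", "[35-65)", "[65-120]")
AGE_LO <- c(0L, 15L, 35L, 65L)
AGE_HI <- c(14L, 34L, 64L, 120L)   # inclusive upper integer age per class

HH_TYPES   <- c("Single", "single parent", "couple", "family")
HH_SIZES   <- as.character(1:6)
ROLES      <- c("head", "spouse", "child")
GENDERS    <- c("Male", "Female")
SPC_LEVELS <- as.character(1:8)
SPC_RETIRED  <- "7"
SPC_INACTIVE <- "8"
EDU_LEVELS <- c("none", "primary", "secondary", "university/college")
ACTIVITIES <- c("Employed", "unemployed", "retired", "student",
                "other unemployed")
OVERWEIGHT_LEVELS <- c("0", "1", "2")
CAR_LEVELS <- c("0", "1")
INCOME_CLASSES <- c("low", "intermediate", "high")

#' Default attribute schema
#'
#' Returns the variable/category catalogue used throughout the package:
#' household type, size, income, car ownership and income class at the
#' household level; age (integer and four-class), gender, socio-professional
#' category (SPC, 8 levels), education, role, main activity and
#' overweight/obesity status at the individual level. Age classes are
#' `[0-15)`, `[15-35)`, `[35-65)`, `[65-120]`, lower-inclusive and
#' upper-exclusive except for the final class which includes 120.
#'
#' SPC follows the French occupational convention in which level 7 denotes
#' retirees and level 8 other persons without professional activity.
#'
#' @return An object of class `pop_schema`: a named list of variable
#'   definitions, each with `name`, `level` (`"zonal"`, `"household"` or
#'   `"individual"`), `type` (`"categorical"`, `"integer"` or
#'   `"continuous"`), the ordered `categories` vector (NULL for continuous
#'   variables) and `other`, the designated sink category for rare-category
#'   merging (NA when the variable has none).
#' @export
#' @examples
#' sch <- default_schema()
#' schema_categories(sch, "hh_type")
default_schema <- function() {
  v <- function(name, level, type, categories = NULL, other = NA_character_) {
    list(name = name, level = level, type = type,
         categories = categories, other = other)
  }
  vars <- list(
    v("population",   "zonal",      "integer"),
    v("hh_type",      "household",  "categorical", HH_TYPES),
    v("hh_size",      "household",  "integer",     HH_SIZES),
    v("hh_income",    "household",  "continuous"),
    v("car",          "household",  "integer",     CAR_LEVELS),
    v("income_class", "household",  "categorical", INCOME_CLASSES),
    v("age",          "individual", "integer"),
    v("age_class",    "individual", "categorical", AGE_CLASSES),
    v("gender",       "individual", "categorical", GENDERS),
    v("spc",          "individual", "categorical", SPC_LEVELS,
      other = SPC_INACTIVE),
    v("education",    "individual", "categorical", EDU_LEVELS),
    v("role",         "individual", "categorical", ROLES),
    v("activity",     "individual", "categorical", ACTIVITIES,
      other = "other unemployed"),
    v("income",       "individual", "continuous"),
    v("overweight",   "individual", "integer",     OVERWEIGHT_LEVELS)
  )
  names(vars) <- vapply(vars, `[[`, character(1), "name")
  structure(vars, class = "pop_schema")
}

#' Categories of a schema variable
#'
#' @param schema A `pop_schema`.
#' @param var Variable name.
#' @return Character vector of ordered categories.
#' @export
schema_categories <- function(schema, var) {
  if (!var %in% names(schema)) {
    stop("unknown schema variable: ", var, call. = FALSE)
  }
  schema[[var]]$categories
}

#' @export
print.pop_schema <- function(x, ...) {
  cat("<pop_schema> with", length(x), "variables\n")
  for (v in x) {
    cats <- if (is.null(v$categories)) "(continuous)" else
      paste(v$categories, collapse = ", ")
    cat(sprintf("  %-12s %-10s %-11s %s\n", v$name, v$level, v$type, cats))
  }
  invisible(x)
}

# Validate that a schema carries every variable the generator relies on.
assert_schema <- function(schema) {
  needed <- c("hh_type", "hh_size", "car", "income_class", "age_class",
              "gender", "spc", "education", "role", "activity", "overweight")
  missing <- setdiff(needed, names(schema))
  if (length(missing)) {
    stop("schema error: missing variable(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(schema)
}

#' Map integer ages to the four age classes
#'
#' Lower bound inclusive, upper bound exclusive; the final class includes
#' age 120.
#'
#' @param age Integer vector of ages in `[0, 120]`.
#' @return Character vector of age-class labels.
#' @export
#' @examples
#' age_to_class(c(0, 15, 34, 64, 65, 120))
age_to_class <- function(age) {
  if (any(!is.finite(age)) || any(age < 0) || any(age > 120)) {
    stop("out-of-range error: age must lie in [0, 120]", call. = FALSE)
  }
  AGE_CLASSES[findInterval(age, AGE_LO)]
}

age_class_index <- function(age_class) {
  idx <- match(age_class, AGE_CLASSES)
  if (anyNA(idx)) stop("unknown age class", call. = FALSE)
  idx
}

# Role of the member at 1-based position `pos` within a household of `type`.
# Member 1 is the head; member 2 is the spouse in couples and families and a
# child in single-parent households; members 3+ are always children.
role_for_position <- function(type, pos) {
  ifelse(pos == 1L, "head",
         ifelse(pos == 2L & type %in% c("couple", "family"), "spouse",
                "child"))
}

# Household types compatible with a size: one-person households are Single,
# two-person households are couples or single parents, larger households are
# families or single parents.
types_for_size <- function(size) {
  if (size == 1L) "Single"
  else if (size == 2L) c("single parent", "couple")
  else c("single parent", "family")
}
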