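# Stage 3: household co-generation by Gibbs sampling over the conditional
# probability tree, with integerized household counts per zone.
#
# The joint model per household, given the conditional tables, is
#   size -> type -> (role, gender by structure) -> age class -> activity
#   -> integer age (uniform within the class, truncated by structural rules)
#   -> SPC -> education, plus household-level income class -> car.
# Structural rules: member 1 is the head (minimum age 21 in multi-person
# households, 18 for singles); member 2 is the spouse in couples/families
# with the gender opposite to the head; members 3+ (2+ in single-parent
# households) are children; persons under 18 are students with inactive SPC;
# the mother (female head or spouse) is at least `mother_child_gap` years
# older than every child.

#' Default structural-constraint configuration
#'
#' @param head_min_age_multi Minimum head age in households of size > 1.
#' @param head_min_age_single Absolute minimum head age (one-person
#'   households).
#' @param mother_child_gap Minimum age difference between the mother (female
#'   head or spouse) and every child, in years.
#' @param adult_age Age below which individuals are forced to be students
#'   with inactive SPC.
#' @param retire_age Age from which non-employed individuals default to
#'   retired (SPC 7).
#' @param burn_in Number of Gibbs sweeps before the retained draw.
#' @return A named list of constraint parameters.
#' @export
default_constraints <- function(head_min_age_multi = 21L,
                                head_min_age_single = 18L,
                                mother_child_gap = 15L,
                                adult_age = 18L,
                                retire_age = 65L,
                                burn_in = 20L) {
  list(head_min_age_multi = as.integer(head_min_age_multi),
       head_min_age_single = as.integer(head_min_age_single),
       mother_child_gap = as.integer(mother_child_gap),
       adult_age = as.integer(adult_age),
       retire_age = as.integer(retire_age),
       burn_in = as.integer(burn_in))
}

# The eight conditional tables the generator requires, keyed by target.
REQUIRED_CPTS <- c("hh_type", "gender", "age_class", "activity", "spc",
                   "education", "income_class", "car")

assert_cpt_set <- function(cpts) {
  missing <- setdiff(REQUIRED_CPTS, names(cpts))
  if (length(missing)) {
    stop("cpts must provide conditional tables for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(cpts)
}

#' Integerize household counts for a zone
#'
#' Converts a zone population and a household-size distribution into integer
#' counts of households per size 1..6 whose sizes sum to the population
#' exactly when feasible (otherwise within one individual, preferring
#' undershoot). Among exact solutions the counts minimize the total absolute
#' deviation from the expected counts `N * p_s / sum(s' * p_s')`; ties break
#' to the lexicographically smallest count vector. Only sizes with positive
#' probability are used.
#'
#' @param zone_population Total number of individuals `N` in the zone.
#' @param size_probs Probability vector over household sizes 1..6.
#' @return Integer vector `h[1..6]` of household counts per size.
#' @export
#' @examples
#' integerize_household_counts(10, c(0, 1, 0, 0, 0, 0))
#' integerize_household_counts(9, c(0.5, 0.5, 0, 0, 0, 0))
integerize_household_counts <- function(zone_population, size_probs) {
  N <- zone_population
  if (length(N) != 1L || !is.finite(N) || N < 0) {
    stop("input error: zone population must be a non-negative count",
         call. = FALSE)
  }
  N <- as.integer(round(N))
  if (length(size_probs) != 6L || any(size_probs < 0)) {
    stop("input error: size_probs must be 6 non-negative probabilities",
         call. = FALSE)
  }
  tot <- sum(size_probs)
  if (abs(tot - 1) > 1e-6) {
    stop("input error: size_probs must sum to 1", call. = FALSE)
  }
  p <- size_probs / tot
  if (N == 0L) return(integer(6))
  sizes <- 1:6
  E <- N * p / sum(sizes * p)
  h0 <- pmax(0L, as.integer(floor(E)))
  supp <- which(p > 0)
  # exact total first, then the nearest achievable totals, undershoot
  # preferred at equal distance
  offsets <- c(0L, as.vector(rbind(-(1:12), 1:12)))
  for (target in N + offsets) {
    sol <- integerize_repair(h0, E, supp, target)
    if (!is.null(sol)) return(sol)
  }
  # unreachable for any valid distribution, kept as a hard stop
  stop("integerization failed for population ", N, call. = FALSE)
}

# Bounded dynamic-programming repair around the floored expectation. Finds
# delta (zero outside supp) with sum(s * (h0 + delta)) == target minimizing
# sum(|h0 + delta - E|), tie-broken lexicographically on the count vector.
integerize_repair <- function(h0, E, supp, target) {
  if (target < 0L) return(NULL)
  r <- target - sum((1:6) * h0)
  B <- max(24L, abs(r) + 6L)
  span <- 6L * B
  n_states <- 2L * span + 1L
  idx0 <- span + 1L
  INF <- Inf
  cost <- rep(INF, n_states)
  cost[idx0] <- 0
  vecs <- vector("list", n_states)
  vecs[[idx0]] <- h0
  for (s in supp) {
    lo_d <- -min(h0[s], B)
    deltas <- lo_d:B
    new_cost <- rep(INF, n_states)
    new_vecs <- vector("list", n_states)
    reach <- which(is.finite(cost))
    for (st in reach) {
      base_vec <- vecs[[st]]
      for (d in deltas) {
        nst <- st + s * d
        if (nst < 1L || nst > n_states) next
        cand_vec <- base_vec
        cand_vec[s] <- h0[s] + d
        c_new <- cost[st] + abs(h0[s] + d - E[s]) - abs(h0[s] - E[s])
        if (c_new < new_cost[nst] - 1e-12 ||
            (abs(c_new - new_cost[nst]) <= 1e-12 &&
             lex_less(cand_vec, new_vecs[[nst]]))) {
          new_cost[nst] <- c_new
          new_vecs[[nst]] <- cand_vec
        }
      }
    }
    cost <- new_cost
    vecs <- new_vecs
  }
  goal <- idx0 + r
  if (goal < 1L || goal > length(cost) || !is.finite(cost[goal])) {
    return(NULL)
  }
  as.integer(vecs[[goal]])
}

lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# ---------------------------------------------------------------------------
# Feasible integer-age interval for a member, given class, role, activity and
# the mother/children context. Vectorized over members.
age_bounds <- function(class_idx, role, size, activity, constraints,
                       mother_age = NA_integer_,
                       eldest_child_age = NA_integer_) {
  n <- length(class_idx)
  role <- rep_len(role, n)
  size <- rep_len(size, n)
  activity <- rep_len(activity, n)
  mother_age <- rep_len(mother_age, n)
  eldest_child_age <- rep_len(eldest_child_age, n)
  lo <- AGE_LO[class_idx]
  hi <- AGE_HI[class_idx]
  head_min <- ifelse(size > 1L, constraints$head_min_age_multi,
                     constraints$head_min_age_single)
  is_head <- role == "head"
  lo[is_head] <- pmax(lo[is_head], head_min[is_head])
  nonstudent <- activity != "student"
  lo[nonstudent] <- pmax(lo[nonstudent], constraints$adult_age)
  ch <- role == "child" & !is.na(mother_age)
  hi[ch] <- pmin(hi[ch], mother_age[ch] - constraints$mother_child_gap)
  mo <- role != "child" & !is.na(eldest_child_age)
  lo[mo] <- pmax(lo[mo], eldest_child_age[mo] + constraints$mother_child_gap)
  list(lo = lo, hi = hi)
}

#' Sample an integer age within an age class
#'
#' Draws uniformly over the feasible integer ages of the class after
#' truncation by the structural rules: heads respect the configured minimum
#' age, non-students are at least 18, children are at least
#' `mother_child_gap` years younger than their mother, and a mother is at
#' least that much older than her eldest child.
#'
#' @param age_class One of the four age-class labels.
#' @param role `"head"`, `"spouse"` or `"child"`.
#' @param activity Main activity (non-students are adults).
#' @param household_size Household size (selects the head minimum age).
#' @param mother_age Integer age of the member's mother, or NA.
#' @param eldest_child_age Eldest child age when the member is the mother,
#'   or NA.
#' @param constraints See [default_constraints()].
#' @param n Number of draws.
#' @return Integer vector of ages. Raises a constraint error when the
#'   feasible interval is empty (callers re-draw the age class).
#' @export
#' @examples
#' set.seed(1)
#' range(sample_age_within_class("[0-15)", "child", "student", 3, n = 100))
sample_age_within_class <- function(age_class, role = "head",
                                    activity = "student",
                                    household_size = 1L,
                                    mother_age = NA_integer_,
                                    eldest_child_age = NA_integer_,
                                    constraints = default_constraints(),
                                    n = 1L) {
  ci <- age_class_index(age_class)
  b <- age_bounds(ci, role, household_size, activity, constraints,
                  mother_age, eldest_child_age)
  if (any(b$lo > b$hi)) {
    stop("constraint error: empty feasible age interval for class ",
         age_class, call. = FALSE)
  }
  runif_int(max(n, length(ci)), b$lo, b$hi)
}

# ---------------------------------------------------------------------------
# Forward (ancestral) draw of fully structured households. `sizes` is one
# entry per household; `zone` is recycled. Uses the caller's RNG state.
draw_households <- function(sizes, zone, cpts, constraints,
                            hid_offset = 0L) {
  assert_cpt_set(cpts)
  n_h <- length(sizes)
  if (n_h == 0L) {
    return(empty_population())
  }
  sizes <- as.integer(sizes)
  if (any(sizes < 1L | sizes > 6L)) {
    stop("input error: household sizes must lie in 1..6", call. = FALSE)
  }
  hid <- hid_offset + seq_len(n_h)
  zone <- rep_len(as.character(zone), n_h)

  # household type restricted to size-compatible categories
  p_type <- cpt_rows(cpts$hh_type, data.frame(hh_size = as.character(sizes)))
  mask <- matrix(FALSE, n_h, length(HH_TYPES), dimnames = list(NULL, HH_TYPES))
  for (s in unique(sizes)) {
    mask[sizes == s, types_for_size(s)] <- TRUE
  }
  p_type <- p_type * mask[, colnames(p_type), drop = FALSE]
  if (any(rowSums(p_type) <= 0)) {
    stop("constraint error: empty compatible household type set",
         call. = FALSE)
  }
  type <- colnames(p_type)[rcat_rows(p_type)]

  ind <- data.frame(
    hid = rep(hid, sizes),
    pos = sequence(sizes),
    hh_type = rep(type, sizes),
    hh_size = rep(sizes, sizes),
    zone = rep(zone, sizes),
    stringsAsFactors = FALSE
  )
  ind$role <- role_for_position(ind$hh_type, ind$pos)

  # gender: heads and children from the table, spouse opposite to head
  ind$gender <- NA_character_
  for (r in c("head", "child")) {
    sel <- ind$role == r
    if (any(sel)) {
      p <- cpt_rows(cpts$gender,
                    data.frame(role = r, hh_type = ind$hh_type[sel]))
      ind$gender[sel] <- colnames(p)[rcat_rows(p)]
    }
  }
  sp <- ind$role == "spouse"
  if (any(sp)) {
    head_gender <- ind$gender[ind$pos == 1L]
    ind$gender[sp] <- ifelse(head_gender[match(ind$hid[sp], hid)] == "Male",
                             "Female", "Male")
  }

  # adults (head, spouse) first: age class, activity, integer age
  ind$age_class <- NA_character_
  ind$activity <- NA_character_
  ind$age <- NA_integer_
  adult <- ind$role != "child"
  ind <- draw_member_chain_ancestral(ind, adult, cpts, constraints,
                                     mother_age = NA_integer_)
  # children truncated by the mother's realized age
  mother <- mother_age_by_household(ind, hid)
  child <- ind$role == "child"
  ind <- draw_member_chain_ancestral(ind, child, cpts, constraints,
                                     mother_age = mother[match(ind$hid, hid)])

  # SPC then education
  p <- cpt_rows(cpts$spc, ind[, c("age_class", "activity")])
  ind$spc <- colnames(p)[rcat_rows(p)]
  p <- cpt_rows(cpts$education, ind[, c("age_class", "spc")])
  ind$education <- colnames(p)[rcat_rows(p)]

  # household-level income class and car ownership
  p <- cpt_rows(cpts$income_class, data.frame(hh_type = type))
  income_class <- colnames(p)[rcat_rows(p)]
  p <- cpt_rows(cpts$car,
                data.frame(hh_type = type, income_class = income_class))
  car <- colnames(p)[rcat_rows(p)]

  hh <- data.frame(hid = hid, zone = zone, hh_size = sizes, hh_type = type,
                   income_class = income_class, car = car,
                   stringsAsFactors = FALSE)
  new_population(hh, ind)
}

# Age class (masked by structural feasibility), activity, then integer age
# for the selected members. `mother_age` is the per-member mother age (NA
# when unconstrained).
draw_member_chain_ancestral <- function(ind, sel, cpts, constraints,
                                        mother_age) {
  if (!any(sel)) return(ind)
  sub <- ind[sel, , drop = FALSE]
  m_age <- if (length(mother_age) == 1L) rep(NA_integer_, nrow(sub)) else
    mother_age[sel]
  p <- cpt_rows(cpts$age_class, sub[, c("hh_type", "role")])
  feas <- class_feasible(sub, m_age, constraints)
  p <- p * feas
  if (any(rowSums(p) <= 0)) {
    stop("constraint error: no feasible age class for a ",
         paste(unique(sub$role[rowSums(p) <= 0]), collapse = "/"),
         " member", call. = FALSE)
  }
  cls <- colnames(p)[rcat_rows(p)]
  pa <- cpt_rows(cpts$activity, data.frame(age_class = cls))
  # mask activities whose feasible age interval is empty
  ci <- age_class_index(cls)
  for (j in seq_along(ACTIVITIES)) {
    b <- age_bounds(ci, sub$role, sub$hh_size, ACTIVITIES[j], constraints,
                    mother_age = m_age)
    pa[, j] <- pa[, j] * (b$lo <= b$hi)
  }
  act <- colnames(pa)[rcat_rows(pa)]
  b <- age_bounds(ci, sub$role, sub$hh_size, act, constraints,
                  mother_age = m_age)
  age <- runif_int(nrow(sub), b$lo, b$hi)
  ind$age_class[sel] <- cls
  ind$activity[sel] <- act
  ind$age[sel] <- age
  ind
}

# TRUE where an age class admits at least one feasible integer age for some
# activity (student is the least restrictive under the adult rule).
class_feasible <- function(sub, mother_age, constraints) {
  out <- matrix(TRUE, nrow(sub), 4L, dimnames = list(NULL, AGE_CLASSES))
  for (c in 1:4) {
    b <- age_bounds(rep(c, nrow(sub)), sub$role, sub$hh_size, "student",
                    constraints, mother_age = mother_age,
                    eldest_child_age = sub$eldest_child_age %||% NA_integer_)
    out[, c] <- b$lo <= b$hi
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Integer age of the mother (female head or spouse) per household id, NA
# when the household has none.
mother_age_by_household <- function(ind, hids) {
  cand <- ind[ind$role %in% c("head", "spouse") & ind$gender == "Female", ]
  out <- rep(NA_integer_, length(hids))
  out[match(cand$hid, hids)] <- cand$age
  out
}

eldest_child_age_by_household <- function(ind, hids) {
  ch <- ind[ind$role == "child" & !is.na(ind$age), ]
  if (nrow(ch) == 0L) return(rep(NA_integer_, length(hids)))
  agg <- tapply(ch$age, ch$hid, max)
  out <- rep(NA_integer_, length(hids))
  out[match(names(agg), as.character(hids))] <- as.integer(agg)
  out
}

# ---------------------------------------------------------------------------
# Population container

new_population <- function(households, individuals) {
  structure(list(households = households, individuals = individuals),
            class = "synth_population")
}

empty_population <- function() {
  hh <- data.frame(hid = integer(0), zone = character(0),
                   hh_size = integer(0), hh_type = character(0),
                   income_class = character(0), car = character(0))
  ind <- data.frame(hid = integer(0), pos = integer(0),
                    hh_type = character(0), hh_size = integer(0),
                    zone = character(0), role = character(0),
                    gender = character(0), age_class = character(0),
                    activity = character(0), age = integer(0),
                    spc = character(0), education = character(0))
  new_population(hh, ind)
}

#' @export
print.synth_population <- function(x, ...) {
  cat(sprintf("<synth_population> %d households, %d individuals, %d zone(s)\n",
              nrow(x$households), nrow(x$individuals),
              length(unique(x$households$zone))))
  invisible(x)
}

#' @export
summary.synth_population <- function(object, ...) {
  ind <- object$individuals
  cat(sprintf("Synthetic population: %d households / %d individuals\n",
              nrow(object$households), nrow(ind)))
  cat("Household sizes:\n")
  print(table(object$households$hh_size))
  cat("Age classes:\n")
  print(table(factor(ind$age_class, AGE_CLASSES)))
  cat("Activities:\n")
  print(table(factor(ind$activity, ACTIVITIES)))
  invisible(object)
}

rbind_populations <- function(pops) {
  pops <- Filter(function(p) nrow(p$households) > 0, pops)
  if (length(pops) == 0L) return(empty_population())
  new_population(do.call(rbind, lapply(pops, `[[`, "households")),
                 do.call(rbind, lapply(pops, `[[`, "individuals")))
}

# ---------------------------------------------------------------------------
# Blocked Gibbs sweep

#' One Gibbs sweep over a population's free attributes
#'
#' Performs one systematic scan in the order of the conditional tree: the
#' (age class, integer age) block per member, the (activity, SPC) block, the
#' education level, and the household-level (income class, car ownership)
#' pair. Attributes fixed by the structural rules (roles, genders, household
#' type and size) are never resampled; structurally infeasible categories
#' are masked before each draw. Full conditionals multiply the conditional
#' tables in which the attribute appears as target or as a conditioning
#' variable, so the sweep's stationary distribution is the joint implied by
#' the tree.
#'
#' @param population A `synth_population`.
#' @param cpts Named list of `cpt` objects (targets `hh_type`, `gender`,
#'   `age_class`, `activity`, `spc`, `education`, `income_class`, `car`).
#' @param constraints See [default_constraints()].
#' @return The population after one sweep.
#' @export
gibbs_sweep <- function(population, cpts,
                        constraints = default_constraints()) {
  assert_cpt_set(cpts)
  ind <- population$individuals
  hh <- population$households
  if (nrow(ind) == 0L) return(population)

  # (age class, age) block: heads and spouses, then children
  mother <- mother_age_by_household(ind, hh$hid)
  eldest <- eldest_child_age_by_household(ind, hh$hid)
  adult <- ind$role != "child"
  eld <- eldest[match(ind$hid, hh$hid)]
  eld[!(adult & ind$gender == "Female")] <- NA_integer_   # mothers only
  ind <- gibbs_age_block(ind, adult, cpts, constraints,
                         mother_age = rep(NA_integer_, nrow(ind)),
                         eldest_child_age = eld)
  mother <- mother_age_by_household(ind, hh$hid)
  ind <- gibbs_age_block(ind, !adult, cpts, constraints,
                         mother_age = mother[match(ind$hid, hh$hid)],
                         eldest_child_age = rep(NA_integer_, nrow(ind)))

  # (activity, SPC) block, then education
  ind <- gibbs_activity_spc_block(ind, cpts, constraints,
                                  mother_age = mother[match(ind$hid, hh$hid)])
  p <- cpt_rows(cpts$education, ind[, c("age_class", "spc")])
  ind$education <- colnames(p)[rcat_rows(p)]

  # household-level (income class, car)
  p_ic <- cpt_rows(cpts$income_class, data.frame(hh_type = hh$hh_type))
  for (j in seq_along(INCOME_CLASSES)) {
    p_ic[, j] <- p_ic[, j] *
      cpt_prob_of0(cpts$car,
                  data.frame(hh_type = hh$hh_type,
                             income_class = INCOME_CLASSES[j]), hh$car)
  }
  hh$income_class <- colnames(p_ic)[rcat_rows(p_ic)]
  p <- cpt_rows(cpts$car, hh[, c("hh_type", "income_class")])
  hh$car <- colnames(p)[rcat_rows(p)]

  new_population(hh, ind)
}

# Joint update of (age class, integer age) for the selected members, given
# the current activity/SPC/education. The within-class uniform age density
# cancels when the block is drawn jointly, so class weights are the product
# of the tree's conditionals at the current downstream values, masked by
# interval feasibility.
gibbs_age_block <- function(ind, sel, cpts, constraints, mother_age,
                            eldest_child_age) {
  if (!any(sel)) return(ind)
  sub <- ind[sel, , drop = FALSE]
  m_age <- mother_age[sel]
  e_age <- eldest_child_age[sel]
  n <- nrow(sub)
  w <- cpt_rows(cpts$age_class, sub[, c("hh_type", "role")])
  for (c in 1:4) {
    cls <- AGE_CLASSES[c]
    b <- age_bounds(rep(c, n), sub$role, sub$hh_size, sub$activity,
                    constraints, mother_age = m_age,
                    eldest_child_age = e_age)
    feas <- b$lo <= b$hi
    fa <- cpt_prob_of0(cpts$activity, data.frame(age_class = rep(cls, n)),
                       sub$activity)
    fs <- cpt_prob_of0(cpts$spc,
                       data.frame(age_class = rep(cls, n),
                                  activity = sub$activity), sub$spc)
    fe <- cpt_prob_of0(cpts$education,
                       data.frame(age_class = rep(cls, n), spc = sub$spc),
                       sub$education)
    w[, c] <- w[, c] * feas * fa * fs * fe
  }
  if (any(rowSums(w) <= 0)) {
    stop("sampling error: no feasible age class in Gibbs update",
         call. = FALSE)
  }
  ci <- rcat_rows(w)
  b <- age_bounds(ci, sub$role, sub$hh_size, sub$activity, constraints,
                  mother_age = m_age, eldest_child_age = e_age)
  ind$age_class[sel] <- AGE_CLASSES[ci]
  ind$age[sel] <- runif_int(n, b$lo, b$hi)
  ind
}

# Joint update of (activity, SPC) given class, age and education. The
# observed integer age contributes the truncated-uniform density
# 1/|interval(class, activity)| and an indicator that the age lies in the
# interval -- this is what forces under-18s to remain students.
gibbs_activity_spc_block <- function(ind, cpts, constraints, mother_age) {
  n <- nrow(ind)
  ci <- age_class_index(ind$age_class)
  # education factor per candidate SPC
  E <- matrix(0, n, length(SPC_LEVELS), dimnames = list(NULL, SPC_LEVELS))
  for (s in seq_along(SPC_LEVELS)) {
    E[, s] <- cpt_prob_of0(cpts$education,
                           data.frame(age_class = ind$age_class,
                                      spc = SPC_LEVELS[s]), ind$education)
  }
  w <- matrix(0, n, length(ACTIVITIES), dimnames = list(NULL, ACTIVITIES))
  for (j in seq_along(ACTIVITIES)) {
    a <- ACTIVITIES[j]
    b <- age_bounds(ci, ind$role, ind$hh_size, a, constraints,
                    mother_age = mother_age)
    ok <- b$lo <= b$hi & ind$age >= b$lo & ind$age <= b$hi
    dens <- ifelse(ok, 1 / pmax(b$hi - b$lo + 1L, 1L), 0)
    pa <- cpt_prob_of(cpts$activity,
                      data.frame(age_class = ind$age_class), a)
    S <- cpt_rows_zero(cpts$spc, data.frame(age_class = ind$age_class,
                                            activity = rep(a, n)))
    w[, j] <- pa * dens * rowSums(S * E)
  }
  if (any(rowSums(w) <= 0)) {
    stop("sampling error: no feasible activity in Gibbs update",
         call. = FALSE)
  }
  ind$activity <- ACTIVITIES[rcat_rows(w)]
  S <- cpt_rows(cpts$spc, ind[, c("age_class", "activity")])
  ind$spc <- SPC_LEVELS[rcat_rows(S * E)]
  ind
}

# ---------------------------------------------------------------------------

#' Generate one household
#'
#' Draws a structurally valid household of the requested size: the type from
#' P(type | size) restricted to size-compatible types, member roles by
#' position, genders (spouse opposite to head), then the member attribute
#' chain, followed by `burn_in` Gibbs sweeps.
#'
#' @param zone Zone id the household lives in.
#' @param size Household size (1..6).
#' @param cpts Named list of conditional tables (see [gibbs_sweep()]).
#' @param constraints See [default_constraints()].
#' @param seed Integer seed.
#' @return A list with elements `household` (one-row data frame) and
#'   `members` (data frame of individuals in position order).
#' @export
generate_household <- function(zone, size, cpts,
                               constraints = default_constraints(),
                               seed = 1L) {
  pop <- with_substream(seed, "household", zone, expr = {
    p <- draw_households(as.integer(size), zone, cpts, constraints)
    for (i in seq_len(constraints$burn_in)) {
      p <- gibbs_sweep(p, cpts, constraints)
    }
    p
  })
  list(household = pop$households[1, , drop = FALSE],
       members = pop$individuals)
}

#' Generate the synthetic population of one zone
#'
#' Integerizes the zone population into household counts per size, draws the
#' households through the conditional tree, and applies `burn_in` Gibbs
#' sweeps; the retained state is the final one (one draw per household).
#'
#' @param zone Zone (IRIS) id.
#' @param zone_population Number of individuals to generate.
#' @param cpts Named list of conditional tables.
#' @param size_dist Probability vector over household sizes 1..6 for this
#'   zone.
#' @param constraints See [default_constraints()].
#' @param master_seed Master seed; the zone's substream is derived by
#'   hashing the zone id so results do not depend on zone processing order.
#' @param hid_offset Household-id offset for multi-zone assemblies.
#' @return A `synth_population`.
#' @export
generate_zone_population <- function(zone, zone_population, cpts, size_dist,
                                     constraints = default_constraints(),
                                     master_seed = 1L, hid_offset = 0L) {
  counts <- integerize_household_counts(zone_population, size_dist)
  sizes <- rep(1:6, counts)
  with_substream(master_seed, "zone_population", zone, expr = {
    sizes <- sizes[sample.int(length(sizes))]  # interleave sizes in the zone
    pop <- draw_households(sizes, zone, cpts, constraints, hid_offset)
    for (i in seq_len(constraints$burn_in)) {
      pop <- gibbs_sweep(pop, cpts, constraints)
    }
    pop
  })
}

#' Generate a multi-zone synthetic population
#'
#' @param zone_populations Named integer vector: individuals per zone.
#' @param cpts Named list of conditional tables.
#' @param size_dists Named list (by zone) of size-probability vectors, or a
#'   single vector used for all zones.
#' @param constraints See [default_constraints()].
#' @param master_seed Master seed (per-zone substreams are derived from it).
#' @return A `synth_population` covering all zones.
#' @export
generate_population <- function(zone_populations, cpts, size_dists,
                                constraints = default_constraints(),
                                master_seed = 1L) {
  zones <- names(zone_populations)
  if (is.null(zones)) {
    stop("input error: zone_populations must be named by zone", call. = FALSE)
  }
  zones <- sort(zones)   # output must not depend on zone processing order
  offset <- 0L
  pops <- vector("list", length(zones))
  for (i in seq_along(zones)) {
    z <- zones[i]
    sd <- if (is.list(size_dists)) size_dists[[z]] else size_dists
    pops[[i]] <- generate_zone_population(z, zone_populations[[z]], cpts, sd,
                                          constraints, master_seed,
                                          hid_offset = offset)
    offset <- offset + nrow(pops[[i]]$households)
  }
  rbind_populations(pops)
}
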