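# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

gt_model <- function(seed = 42) {
  cached(paste0("model_", seed), generate_ground_truth_model(seed = seed))
}

gt_hierarchy <- function(seed = 42) {
  cached(paste0("hier_", seed), build_zone_hierarchy(gt_model(seed)$zone_table))
}

small_census <- function(n = 1500, seed = 7) {
  cached(paste0("census_", n, "_", seed),
         simulate_census_sample(gt_model(), n, seed = seed))
}

# A point-mass conditional table: every cell puts all mass on `value`.
point_cpt <- function(target, given, levels, cells, value) {
  prob <- matrix(0, length(cells), length(levels),
                 dimnames = list(cells, levels))
  prob[, value] <- 1
  new_cpt(target, given, levels, prob)
}

# Conditional-table set in which every member attribute is deterministic,
# so only the household-level (income class, car) pair is free. Used to
# check Gibbs convergence against an enumerable two-attribute joint.
fixed_member_cpts <- function(p_ic = c(low = 0.5, intermediate = 0.3,
                                       high = 0.2),
                              p_car_given_ic = rbind(low = c(0.9, 0.1),
                                                     intermediate = c(0.5, 0.5),
                                                     high = c(0.2, 0.8))) {
  sizes <- as.character(1:6)
  types <- c("Single", "single parent", "couple", "family")
  type_cells <- do.call(paste,
                        c(expand.grid(types, c("head", "spouse", "child")),
                          sep = "\x1f"))
  ic_prob <- matrix(rep(p_ic, each = 4), 4, 3,
                    dimnames = list(types, names(p_ic)))
  car_cells <- as.vector(outer(types, names(p_ic), paste, sep = "\x1f"))
  car_prob <- p_car_given_ic[rep(names(p_ic), each = 4), ]
  rownames(car_prob) <- car_cells
  colnames(car_prob) <- c("0", "1")
  spc_cells <- as.vector(outer(
    c("[0-15)", "[15-35)", "[35-65)", "[65-120]"),
    c("Employed", "unemployed", "retired", "student", "other unemployed"),
    paste, sep = "\x1f"))
  edu_cells <- as.vector(outer(
    c("[0-15)", "[15-35)", "[35-65)", "[65-120]"),
    as.character(1:8), paste, sep = "\x1f"))
  list(
    hh_type = point_cpt("hh_type", "hh_size", types, sizes, "Single"),
    gender = point_cpt("gender", c("role", "hh_type"),
                       c("Male", "Female"),
                       do.call(paste,
                               c(expand.grid(c("head", "spouse", "child"),
                                             types), sep = "\x1f")),
                       "Male"),
    age_class = point_cpt("age_class", c("hh_type", "role"),
                          c("[0-15)", "[15-35)", "[35-65)", "[65-120]"),
                          type_cells, "[35-65)"),
    activity = point_cpt("activity", "age_class",
                         c("Employed", "unemployed", "retired", "student",
                           "other unemployed"),
                         c("[0-15)", "[15-35)", "[35-65)", "[65-120]"),
                         "Employed"),
    spc = point_cpt("spc", c("age_class", "activity"),
                    as.character(1:8), spc_cells, "3"),
    education = point_cpt("education", c("age_class", "spc"),
                          c("none", "primary", "secondary",
                            "university/college"),
                          edu_cells, "secondary"),
    income_class = new_cpt("income_class", "hh_type", names(p_ic), ic_prob),
    car = new_cpt("car", c("hh_type", "income_class"), c("0", "1"),
                  car_prob)
  )
}
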