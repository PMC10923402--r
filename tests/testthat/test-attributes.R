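# Minimal single-member population in a given commune setup.
one_person_pop <- function(spc = "3", activity = "Employed", age = 40L,
                           zone = "I1") {
  hh <- data.frame(hid = 1L, zone = zone, hh_size = 1L, hh_type = "Single",
                   income_class = "low", car = "0")
  ind <- data.frame(hid = 1L, pos = 1L, hh_type = "Single", hh_size = 1L,
                    zone = zone, role = "head", gender = "Male",
                    age_class = age_to_class(age), activity = activity,
                    age = age, spc = spc, education = "secondary")
  gibbspop:::new_population(hh, ind)
}

flat_income_model <- function(spc3 = 20000, commune = 20000, pop = 20000) {
  meds <- stats::setNames(rep(pop, 8), as.character(1:8))
  meds[["3"]] <- spc3
  income_model(stats::setNames(rep(commune, 4), c("C1", "C2", "C3", "C4")),
               meds, pop)
}

test_that("income follows the SPC weighting of the commune median", {
  h <- gt_hierarchy()
  # alpha = 1, dispersion off: income equals the commune median
  p <- assign_income(one_person_pop(), h, flat_income_model(),
                     dispersion_sigma = 0)
  expect_equal(p$individuals$income, 20000)
  # r_SPC = 30000, r = 20000 -> alpha = 1.5 -> income 30000
  p <- assign_income(one_person_pop(), h, flat_income_model(spc3 = 30000),
                     dispersion_sigma = 0)
  expect_equal(p$individuals$income, 30000)
})

test_that("statutory floors apply by activity and age", {
  h <- gt_hierarchy()
  # employed with weighted income 8000 is raised to the minimum wage
  p <- assign_income(one_person_pop(), h,
                     flat_income_model(spc3 = 8000, commune = 20000),
                     dispersion_sigma = 0)
  expect_equal(p$individuals$income, 12672)
  # non-working aged 25+ floored at the Active Solidarity Income
  m <- income_model(c(C1 = 20000, C2 = 2, C3 = 2, C4 = 2),
                    stats::setNames(rep(100, 8), as.character(1:8)), 20000)
  p <- assign_income(one_person_pop(spc = "8", activity = "unemployed",
                                    age = 40L), h, m,
                     dispersion_sigma = 0)
  expect_equal(p$individuals$income, 5520)
  # non-working aged 18-24: no floor
  p <- assign_income(one_person_pop(spc = "8", activity = "unemployed",
                                    age = 22L), h, m, dispersion_sigma = 0)
  expect_lt(p$individuals$income, 5520)
  # students under 25 and minors receive nothing
  p <- assign_income(one_person_pop(spc = "8", activity = "student",
                                    age = 20L), h, m, dispersion_sigma = 0)
  expect_equal(p$individuals$income, 0)
})

test_that("household income is the order-invariant sum of member incomes", {
  hh <- data.frame(hid = 1L, zone = "I1", hh_size = 3L, hh_type = "family",
                   income_class = "low", car = "0")
  ind <- data.frame(hid = 1L, pos = 1:3, income = c(20000, 15000, 0))
  pop <- gibbspop:::new_population(hh, ind)
  expect_equal(aggregate_household_income(pop)$hh_income, 35000)
  pop$individuals <- pop$individuals[c(3, 1, 2), ]
  expect_equal(aggregate_household_income(pop)$hh_income, 35000)

  single <- gibbspop:::new_population(
    hh, data.frame(hid = 1L, pos = 1L, income = 5520))
  expect_equal(aggregate_household_income(single)$hh_income, 5520)

  pop$individuals$income[1] <- NA
  expect_error(aggregate_household_income(pop), "state error")
})

test_that("overweight draws follow the contingency cell with fallback", {
  # point mass: every matching agent classified obese
  cells <- cpt_cell_key("Male", "[35-65)", "3")
  point <- new_cpt("overweight", c("gender", "age_class", "spc"),
                   c("0", "1", "2"),
                   matrix(c(0, 0, 1), 1, 3, dimnames = list(cells)))
  pop <- one_person_pop()
  got <- assign_overweight(pop, point, master_seed = 1)
  expect_equal(got$individuals$overweight, "2")

  # fixture cell rates recovered within Monte-Carlo error
  n <- 10000
  hh <- data.frame(hid = 1:n, zone = "I1", hh_size = 1L,
                   hh_type = "Single", income_class = "low", car = "0")
  ind <- data.frame(hid = 1:n, pos = 1L, gender = "Male",
                    age_class = "[35-65)", spc = "3")
  big <- gibbspop:::new_population(hh, ind)
  cell <- new_cpt("overweight", c("gender", "age_class", "spc"),
                  c("0", "1", "2"),
                  matrix(c(0.6, 0.3, 0.1), 1, 3, dimnames = list(cells)))
  got <- assign_overweight(big, cell, master_seed = 2)
  emp <- table(factor(got$individuals$overweight, c("0", "1", "2"))) / n
  for (i in 1:3) {
    p <- c(0.6, 0.3, 0.1)[i]
    expect_lt(abs(emp[i] - p), 3 * sqrt(p * (1 - p) / n))
  }

  # agents without a matching cell use the gender x age margin, then the
  # overall margin
  kid <- one_person_pop(spc = "8", activity = "student", age = 10L)
  got <- assign_overweight(kid, cell, master_seed = 3)
  expect_true(got$individuals$overweight %in% c("0", "1", "2"))
})

test_that("subgroup overweight prevalence matches the model contingency", {
  m <- gt_model()
  s <- small_census()
  grp <- interaction(s$gender, s$age_class, s$spc, drop = TRUE)
  for (g in levels(grp)[table(grp) >= 300]) {
    sub <- s[grp == g, ]
    key <- cpt_cell_key(sub$gender[1], sub$age_class[1], sub$spc[1])
    p <- m$overweight$prob[key, ]
    n <- nrow(sub)
    for (k in c("0", "1", "2")) {
      se <- sqrt(p[k] * (1 - p[k]) / n)
      expect_lt(abs(mean(sub$overweight == k) - p[k]), 3 * se + 0.01,
                label = paste("overweight", k, "in", g))
    }
  }
})
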