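# Brute-force oracle: enumerate all household-count vectors reaching an
# exact total, minimize the deviation from expectation, break ties
# lexicographically. Only tractable for small populations.
brute_integerize <- function(N, p) {
  E <- N * p / sum((1:6) * p)
  supp <- which(p > 0)
  best <- NULL
  best_cost <- Inf
  rec <- function(s_idx, h, remaining) {
    if (s_idx > length(supp)) {
      if (remaining != 0) return()
      cost <- sum(abs(h - E))
      if (cost < best_cost - 1e-12 ||
          (abs(cost - best_cost) <= 1e-12 &&
           gibbspop:::lex_less(h, best))) {
        best <<- h
        best_cost <<- cost
      }
      return()
    }
    s <- supp[s_idx]
    for (k in 0:(remaining %/% s)) {
      h[s] <- k
      rec(s_idx + 1L, h, remaining - k * s)
    }
  }
  rec(1L, integer(6), N)
  best
}

test_that("household-count integerization matches the hand oracles", {
  expect_equal(integerize_household_counts(10, c(0, 1, 0, 0, 0, 0)),
               c(0L, 5L, 0L, 0L, 0L, 0L))
  expect_equal(integerize_household_counts(9, c(0.5, 0.5, 0, 0, 0, 0)),
               c(3L, 3L, 0L, 0L, 0L, 0L))
  expect_equal(integerize_household_counts(0, rep(1 / 6, 6)), integer(6))
  expect_error(integerize_household_counts(-1, rep(1 / 6, 6)),
               "non-negative")
})

test_that("integerization is exactly optimal against brute force", {
  set.seed(101)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    supp <- sort(sample(1:6, k))
    p <- numeric(6)
    p[supp] <- gibbspop:::rdirichlet1(rep(2, k))
    N <- sample(5:40, 1)
    got <- integerize_household_counts(N, p)
    want <- brute_integerize(N, p)
    if (is.null(want)) {
      # no exact solution: nearest achievable total, undershoot preferred
      for (t in N + c(0L, as.vector(rbind(-(1:12), 1:12)))) {
        want <- brute_integerize(t, p)
        if (!is.null(want)) break
      }
      expect_equal(sum((1:6) * got), sum((1:6) * want))
      expect_equal(got, want)
    } else {
      expect_equal(got, want, label = paste("N =", N))
    }
  }
})

test_that("infeasible totals undershoot by one individual", {
  got <- integerize_household_counts(9, c(0, 1, 0, 0, 0, 0))
  expect_equal(sum((1:6) * got), 8)
})

test_that("generated households are structurally valid", {
  cpts <- gt_model()$cpts
  h1 <- generate_household("I1", 1, cpts, seed = 3)
  expect_equal(h1$household$hh_type, "Single")
  expect_equal(h1$members$role, "head")

  # force family at size 4 to pin the role sequence
  cpts_f <- cpts
  prob <- cpts_f$hh_type$prob
  prob["4", ] <- c(0, 0, 0, 1)
  cpts_f$hh_type <- new_cpt("hh_type", "hh_size", cpts_f$hh_type$levels,
                            prob)
  h4 <- generate_household("I1", 4, cpts_f, seed = 3)
  expect_equal(h4$household$hh_type, "family")
  expect_equal(h4$members$role, c("head", "spouse", "child", "child"))

  for (seed in 1:20) {
    h <- generate_household("I2", 2, cpts, seed = seed)
    if (h$household$hh_type == "couple") {
      g <- h$members$gender
      expect_equal(sort(g), c("Female", "Male"))
    }
  }
})

test_that("a sweep leaves point-mass states unchanged", {
  cpts <- fixed_member_cpts(
    p_ic = c(low = 1, intermediate = 0, high = 0),
    p_car_given_ic = rbind(low = c(1, 0), intermediate = c(1, 0),
                           high = c(1, 0)))
  pop <- gibbspop:::with_substream(1, "fp", expr = {
    gibbspop:::draw_households(rep(1L, 50), "I1", cpts,
                               default_constraints())
  })
  cols <- c("age_class", "activity", "spc", "education", "gender")
  set.seed(9)
  swept <- gibbs_sweep(pop, cpts)
  expect_identical(swept$individuals[cols], pop$individuals[cols])
  expect_identical(swept$households[c("hh_type", "income_class", "car")],
                   pop$households[c("hh_type", "income_class", "car")])
})

test_that("Gibbs sweeps converge to an enumerable two-attribute joint", {
  p_ic <- c(low = 0.5, intermediate = 0.3, high = 0.2)
  p_car <- rbind(low = c(0.9, 0.1), intermediate = c(0.5, 0.5),
                 high = c(0.2, 0.8))
  cpts <- fixed_member_cpts(p_ic, p_car)
  n <- 4000
  pop <- gibbspop:::with_substream(2, "joint", expr = {
    gibbspop:::draw_households(rep(1L, n), "I1", cpts,
                               default_constraints())
  })
  # deliberately bad start far from the joint
  pop$households$income_class <- "high"
  pop$households$car <- "0"
  set.seed(33)
  for (i in 1:15) pop <- gibbs_sweep(pop, cpts)
  exact <- as.vector(outer(p_ic, c(1, 1)) * p_car)   # 3 x 2 joint
  names(exact) <- as.vector(outer(names(p_ic), c("0", "1"), paste))
  emp <- table(factor(paste(pop$households$income_class,
                            pop$households$car), names(exact))) / n
  for (cell in names(exact)) {
    se <- sqrt(exact[cell] * (1 - exact[cell]) / n)
    expect_lt(abs(emp[cell] - exact[cell]), 3 * se,
              label = paste("joint cell", cell))
  }
})

test_that("identical seeds give identical trajectories", {
  est <- gt_model()$cpts
  sd1 <- gt_model()$size_dist_by_zone["I1", ]
  p1 <- generate_zone_population("I1", 300, est, sd1, master_seed = 5)
  p2 <- generate_zone_population("I1", 300, est, sd1, master_seed = 5)
  expect_identical(p1, p2)
  p3 <- generate_zone_population("I1", 300, est, sd1, master_seed = 6)
  expect_false(identical(p1$individuals$age, p3$individuals$age))
})

test_that("zone populations conserve size and satisfy every invariant", {
  m <- gt_model()
  pop <- generate_zone_population("I3", 100, m$cpts,
                                  m$size_dist_by_zone["I3", ],
                                  master_seed = 8)
  expect_equal(sum(pop$households$hh_size), 100)
  expect_equal(nrow(pop$individuals), 100)
  expect_equal(nrow(check_population(pop)), 0)
})

test_that("multi-zone generation does not depend on zone order", {
  m <- gt_model()
  zp <- c(I1 = 120, I2 = 80, I3 = 60)
  sds <- lapply(c("I1", "I2", "I3"),
                function(z) m$size_dist_by_zone[z, ])
  names(sds) <- c("I1", "I2", "I3")
  a <- generate_population(zp, m$cpts, sds, master_seed = 4)
  b <- generate_population(rev(zp), m$cpts, sds, master_seed = 4)
  expect_identical(a, b)
})

test_that("ages are uniform within their feasible interval", {
  set.seed(12)
  a <- sample_age_within_class("[0-15)", "child", "student", 3, n = 500)
  expect_true(all(a %in% 0:14))

  h <- sample_age_within_class("[15-35)", "head", "Employed", 2, n = 10000)
  expect_true(all(h %in% 21:34))
  chi <- stats::chisq.test(table(factor(h, 21:34)))
  expect_gt(chi$p.value, 0.01)

  expect_error(sample_age_within_class("[0-15)", "head", "student", 2),
               "constraint error")
  # child age capped by the mother-child gap
  cc <- sample_age_within_class("[15-35)", "child", "student", 2,
                                mother_age = 36L, n = 200)
  expect_true(all(cc %in% 15:21))
})

test_that("generated activity-by-age frequencies track the tables", {
  m <- gt_model()
  pop <- cached("pop_I1_6000", generate_zone_population(
    "I1", 6000, m$cpts, m$size_dist_by_zone["I1", ], master_seed = 21))
  ind <- pop$individuals
  truth <- m$cpts$activity$prob
  for (cls in rownames(truth)) {
    sub <- ind$activity[ind$age_class == cls]
    n <- length(sub)
    for (act in colnames(truth)) {
      p <- truth[cls, act]
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(mean(sub == act) - p), 3 * se + 0.005,
                label = paste("P(", act, "|", cls, ")"))
    }
  }
})
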