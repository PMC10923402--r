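test_that("the train/test split is household-exact and reproducible", {
  s <- small_census()
  sp <- split_train_test(s, 0.66, seed = 5, hierarchy = gt_hierarchy())
  n_train <- length(unique(sp$train$hid))
  n_total <- length(unique(s$hid))
  # within the per-commune rounding remainder of 66%
  expect_lt(abs(n_train - 0.66 * n_total), 4)
  expect_equal(sort(c(unique(sp$train$hid), unique(sp$test$hid))),
               sort(unique(s$hid)))
  expect_length(intersect(sp$train$hid, sp$test$hid), 0)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(s))

  sp2 <- split_train_test(s, 0.66, seed = 5, hierarchy = gt_hierarchy())
  expect_identical(sp, sp2)
  expect_error(split_train_test(s, 1.2), "strictly between")
})

test_that("SRMSE matches its hand oracle and is zero only at identity", {
  expect_equal(srmse(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(srmse(c(0.5, 0.5), c(0.6, 0.4)), 0.2)
  set.seed(3)
  for (i in 1:10) {
    p <- gibbspop:::rdirichlet1(rep(1, 8))
    expect_equal(srmse(p, p), 0)
    perm <- sample(8)
    q <- gibbspop:::rdirichlet1(rep(1, 8))
    expect_equal(srmse(p, q), srmse(p[perm], q[perm]))
    expect_gt(srmse(p, q), 0)
  }
  expect_error(srmse(c(a = 0.5, b = 0.5), c(a = 0.4, c = 0.6)),
               "mismatched")
  expect_error(srmse(c(0, 0), c(0.5, 0.5)), "undefined")
})

test_that("fit metrics follow their standard definitions", {
  fm <- fit_metrics(c(0, 1, 2), c(0, 1, 2))
  expect_equal(c(fm$r2, fm$rmse, fm$mae), c(1, 0, 0))
  fm <- fit_metrics(c(0, 1, 2), c(1, 2, 3))
  expect_equal(c(fm$r2, fm$rmse, fm$mae), c(1, 1, 1))

  set.seed(4)
  for (i in 1:10) {
    a <- stats::rnorm(20)
    b <- stats::rnorm(20)
    fm <- fit_metrics(a, b)
    expect_lte(fm$mae, fm$rmse)
  }
  fm <- fit_metrics(rep(1, 5), 1:5)
  expect_true(is.na(fm$r2))
  expect_false(fm$r2_defined)
})

test_that("joint distributions cover the full category grid", {
  s <- small_census()
  g1 <- joint_distribution(s, "gender")
  expect_equal(unname(g1["Male"]), mean(s$gender == "Male"))
  g2 <- joint_distribution(s, c("gender", "age_class"))
  expect_length(g2, 8)
  expect_equal(sum(g2), 1)
  g9 <- joint_distribution(s, c("age_class", "gender", "spc", "activity",
                                "education", "role", "hh_type", "car",
                                "overweight"))
  expect_length(g9, 4 * 2 * 8 * 5 * 4 * 3 * 4 * 2 * 3)
  expect_equal(sum(g9), 1)
  expect_error(joint_distribution(s, "no_such"), "unknown schema variable")
})

test_that("per-zone comparison is exact on identical data and flags
           low-variance categories", {
  s <- small_census()
  pz <- per_zone_comparison(s, s, "age_class")
  expect_equal(pz$metrics$r2, 1)
  expect_equal(pz$metrics$rmse, 0)
  expect_true(all(pz$table$obs_pct == pz$table$sim_pct))

  flat <- data.frame(zone = rep(c("I1", "I2", "I3"), each = 100),
                     gender = rep(c("Male", "Female"), 150))
  pz2 <- per_zone_comparison(flat, flat, "gender")
  expect_setequal(pz2$low_variance, c("Male", "Female"))

  extra <- rbind(flat, data.frame(zone = "I9", gender = "Male"))
  pz3 <- per_zone_comparison(extra, flat, "gender")
  expect_equal(pz3$excluded_zones, "I9")
})

test_that("validation reports cover combinations at both scales", {
  s <- small_census()
  rep <- validate_population(s, s, combos = list("gender",
                                                 c("gender", "age_class")))
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$srmse[rep$scale == "region"], c(0, 0))
  expect_true("IRIS" %in% rep$scale)
})
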