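test_that("zone hierarchy is validated and round-trips through text", {
  zt <- fixture_zone_table(seed = 1)
  h <- build_zone_hierarchy(zt)
  expect_s3_class(h, "zone_hierarchy")
  expect_length(zone_ids(h, "IRIS"), 8)
  expect_equal(zone_ancestors(h, "I1"), c("C1", "D1", "R1"))

  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(h), path, row.names = FALSE)
  back <- build_zone_hierarchy(utils::read.csv(path))
  expect_equal(as.data.frame(back), as.data.frame(h))

  orphan <- zt
  orphan$parent[orphan$zone == "I3"] <- "C99"
  expect_error(build_zone_hierarchy(orphan), "orphan")
  dup <- rbind(zt, zt[zt$zone == "I1", ])
  expect_error(build_zone_hierarchy(dup), "duplicate")
})

test_that("cleaning removes invalid rows and whole partial households", {
  s <- small_census()[, c("hid", "zone", "hh_size", "hh_type", "role",
                          "gender", "age", "activity", "spc")]
  clean <- clean_microdata(s)
  expect_equal(nrow(clean$data), nrow(s))
  expect_true(all(clean$report$rules == 0))

  bad <- s
  victim <- bad$hid[bad$hh_size == 3][1]
  bad$age[bad$hid == victim][1] <- -3
  clean <- clean_microdata(bad)
  expect_equal(clean$report$rules[["out of range"]], 1)
  expect_equal(nrow(clean$data), nrow(bad) - 3)   # whole household dropped
  expect_false(victim %in% clean$data$hid)

  bad2 <- s
  bad2$gender[5] <- "unknown"
  clean2 <- clean_microdata(bad2)
  expect_equal(clean2$report$rules[["out of schema"]], 1)
  expect_false(s$hid[5] %in% clean2$data$hid)

  expect_error(clean_microdata(data.frame(zone = "I1")), "hid")
})

test_that("age discretization follows the bin boundary conventions", {
  tab <- data.frame(hid = 1:6, zone = "I1",
                    age = c(0, 14, 15, 34, 64, 120))
  out <- discretize(tab)
  expect_equal(out$age_class,
               c("[0-15)", "[0-15)", "[15-35)", "[15-35)", "[35-65)",
                 "[65-120]"))
  expect_error(discretize(data.frame(hid = 1, zone = "I1", age = 121)),
               "out-of-range")
  # income classes derived from household income when absent
  tab2 <- data.frame(hid = 1:9, zone = "I1", age = 30,
                     hh_income = (1:9) * 1000)
  out2 <- discretize(tab2)
  expect_equal(unname(table(out2$income_class)[c("low", "intermediate",
                                                 "high")]),
               c(3L, 3L, 3L), ignore_attr = TRUE)
})

test_that("conditional estimation falls back across spatial levels", {
  h <- gt_hierarchy()
  # I1 has plenty of data, I2 only 3 rows; commune C2 (parent of I2) has 200
  mk <- function(zone, n, p_female) {
    data.frame(zone = zone, hh_type = "couple",
               gender = c(rep("Female", round(n * p_female)),
                          rep("Male", n - round(n * p_female))))
  }
  tab <- rbind(mk("I1", 500, 0.5), mk("I2", 3, 1), mk("I6", 200, 0.2))
  cp <- estimate_conditional(tab, "gender", c("zone", "hh_type"), h,
                             min_count = 10)
  k1 <- cpt_cell_key("I1", "couple")
  k2 <- cpt_cell_key("I2", "couple")
  expect_equal(cp$level[match(k1, rownames(cp$prob))], "IRIS")
  expect_equal(cp$prob[k1, "Female"], 0.5)
  # I2 falls back to commune C2, whose data lives in sibling IRIS I6
  expect_equal(cp$level[match(k2, rownames(cp$prob))], "commune")
  expect_equal(cp$prob[k2, "Female"], (3 + 40) / 203)

  expect_error(estimate_conditional(tab[1:5, ], "gender",
                                    c("zone", "hh_type"), h,
                                    min_count = 10),
               "estimation error")
})

test_that("fallback resolution never coarsens when min_count decreases", {
  h <- gt_hierarchy()
  s <- small_census()
  lv <- c(IRIS = 1, commune = 2, canton = 3, department = 4, region = 5)
  prev <- NULL
  for (mc in c(200, 50, 10)) {
    cp <- estimate_conditional(s, "gender", c("zone", "role"), h,
                               min_count = mc)
    cur <- lv[cp$level]
    names(cur) <- rownames(cp$prob)
    if (!is.null(prev)) {
      shared <- intersect(names(cur), names(prev))
      expect_true(all(cur[shared] <= prev[shared]))
    }
    prev <- cur
  }
})

test_that("rare target categories merge into the designated other", {
  h <- gt_hierarchy()
  tab <- data.frame(zone = "I1", age_class = "[35-65)",
                    activity = c(rep("Employed", 600),
                                 rep("unemployed", 2),
                                 rep("other unemployed", 398)))
  cp <- estimate_conditional(tab, "activity", "age_class", h,
                             min_count = 10)
  expect_equal(cp$prob["[35-65)", "unemployed"], 0)
  expect_equal(cp$prob["[35-65)", "other unemployed"], 0.4)
})

test_that("estimation is deterministic and probability-valid", {
  s <- small_census()
  h <- gt_hierarchy()
  e1 <- estimate_model(s, h)
  e2 <- estimate_model(s, h)
  expect_identical(e1, e2)
  for (cp in e1$cpts) {
    expect_true(all(abs(rowSums(cp$prob) - 1) < 1e-9))
    expect_true(all(cp$support >= 10))
  }
})

test_that("household size distributions honor zone fallback", {
  h <- gt_hierarchy()
  couples <- data.frame(hid = rep(1:50, each = 2), zone = "I1", hh_size = 2)
  d <- household_size_distribution(couples, "I1", h, min_count = 10)
  expect_equal(as.numeric(d), c(0, 1, 0, 0, 0, 0))
  # empty IRIS falls back to its commune (I5 shares commune C1 with I1)
  d5 <- household_size_distribution(couples, "I5", h, min_count = 10)
  expect_equal(as.numeric(d5), c(0, 1, 0, 0, 0, 0))
  expect_equal(attr(d5, "level"), "commune")

  s <- small_census()
  for (z in zone_ids(h, "IRIS")) {
    dz <- household_size_distribution(s, z, h)
    expect_lt(abs(sum(dz) - 1), 1e-9)
  }
})
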