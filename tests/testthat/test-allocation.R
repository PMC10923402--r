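make_dwellings <- function(n_high, n_int, n_low, zone = "I1") {
  n <- n_high + n_int + n_low
  data.frame(did = paste0("D", seq_len(n)),
             bid = paste0("B", seq_len(n)),
             zone = zone,
             price_class = rep(c("high", "intermediate", "low"),
                               c(n_high, n_int, n_low)),
             hid = NA_integer_, stringsAsFactors = FALSE)
}

make_households <- function(n_high, n_int, n_low, zone = "I1") {
  n <- n_high + n_int + n_low
  data.frame(hid = seq_len(n), zone = zone,
             stratum = rep(c("high", "intermediate", "low"),
                           c(n_high, n_int, n_low)),
             stringsAsFactors = FALSE)
}

test_that("income strata are per-zone tertiles", {
  hh <- data.frame(hid = 1:9, zone = "I1", hh_income = (1:9) * 1000)
  got <- stratify_household_income(hh)
  expect_equal(got$stratum,
               rep(c("low", "intermediate", "high"), each = 3))
  eq <- data.frame(hid = 1:4, zone = "I1", hh_income = 20000)
  expect_equal(stratify_household_income(eq)$stratum,
               rep("intermediate", 4))
  expect_equal(nrow(stratify_household_income(
    data.frame(hid = integer(0), zone = character(0),
               hh_income = numeric(0)))), 0)
})

test_that("raising a household's income never lowers its stratum", {
  set.seed(17)
  lv <- c(low = 1, intermediate = 2, high = 3)
  for (i in 1:20) {
    inc <- stats::rlnorm(30, 10, 0.5)
    hh <- data.frame(hid = 1:30, zone = "I1", hh_income = inc)
    s0 <- stratify_household_income(hh)$stratum
    j <- sample(30, 1)
    hh$hh_income[j] <- hh$hh_income[j] * 2
    s1 <- stratify_household_income(hh)$stratum
    expect_gte(lv[s1[j]], lv[s0[j]])
  }
})

test_that("balanced demand achieves complete own-class matching", {
  dw <- make_dwellings(15, 12, 13)
  hh <- make_households(15, 12, 13)
  for (seed in c(1, 2, 99)) {
    got <- allocate_households(hh, dw, master_seed = seed)
    expect_equal(nrow(got), 40)
    expect_true(all(got$stratum == got$price_class))
    expect_false(anyDuplicated(got$did) > 0)
  }
})

test_that("saturated classes spill to the nearest class", {
  dw <- make_dwellings(15, 30, 0)
  hh <- make_households(20, 0, 0)
  got <- allocate_households(hh, dw, master_seed = 3)
  expect_equal(sum(got$price_class == "high"), 15)
  expect_equal(sum(got$price_class == "intermediate"), 5)

  # low-stratum spill goes upward through intermediate first
  dw2 <- make_dwellings(10, 4, 6)
  hh2 <- make_households(0, 0, 12)
  got2 <- allocate_households(hh2, dw2, master_seed = 3)
  expect_equal(sum(got2$price_class == "low"), 6)
  expect_equal(sum(got2$price_class == "intermediate"), 4)
  expect_equal(sum(got2$price_class == "high"), 2)
})

test_that("assignments are a bijection and zones are capacity-checked", {
  dw <- make_dwellings(5, 5, 5)
  hh <- make_households(4, 6, 2)
  got <- allocate_households(hh, dw, master_seed = 8)
  expect_setequal(got$hid, hh$hid)
  expect_false(anyDuplicated(got$did) > 0)
  expect_true(all(got$did %in% dw$did))

  too_many <- make_households(10, 10, 10)
  expect_error(allocate_households(too_many, dw, master_seed = 1),
               "capacity error.*I1")
})

test_that("the stratum-by-class contingency is seed-invariant when balanced", {
  dw <- make_dwellings(7, 6, 7)
  hh <- make_households(7, 6, 7)
  tabs <- lapply(c(4, 5), function(seed) {
    got <- allocate_households(hh, dw, master_seed = seed)
    table(got$stratum, got$price_class)
  })
  expect_equal(tabs[[1]], tabs[[2]])
})
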