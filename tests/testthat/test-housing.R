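test_that("house/block classification follows the geometric rule", {
  b <- data.frame(
    area_m2 = c(100, 400, 100, 300),
    height_m = c(5, 21, 5, 4),
    land_use = c("residential", "residential", "commercial", "residential"))
  got <- classify_buildings(b)
  expect_equal(got$kind, c("house", "block", NA, "block"))
  expect_equal(got$excluded, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(got$floors, c(1L, 7L, 1L, 1L))

  expect_error(classify_buildings(data.frame(area_m2 = -1, height_m = 3,
                                             land_use = "residential")),
               "nonpositive")
})

test_that("dwelling counts follow the surface-over-average-size rule", {
  b <- data.frame(area_m2 = 200, height_m = 9, land_use = "residential",
                  zone_class = "center")
  got <- count_dwellings(classify_buildings(b))
  expect_equal(got$floors, 3L)
  expect_equal(got$n_dwellings, 10L)   # 600 m2 / 59 m2, rounded half-up

  house <- data.frame(area_m2 = 120, height_m = 5,
                      land_use = "residential", zone_class = "outer")
  expect_equal(count_dwellings(classify_buildings(house))$n_dwellings, 1L)

  rec <- data.frame(area_m2 = 500, height_m = 20,
                    land_use = "residential", zone_class = "inner",
                    n_dwellings = 24L)
  expect_equal(count_dwellings(classify_buildings(rec))$n_dwellings, 24L)
})

test_that("total dwellings equal the analytic value for a fixture stock", {
  zt <- gt_model()$zone_table
  b <- simulate_buildings(zt, 400, seed = 9)
  stock <- build_housing_stock(b, gt_hierarchy())
  eb <- stock$buildings
  avg <- c(center = 59, inner = 69, outer = 89)
  expected <- integer(nrow(eb))
  for (i in seq_len(nrow(eb))) {
    if (eb$excluded[i]) next
    if (!is.na(b$n_dwellings[i])) {
      expected[i] <- b$n_dwellings[i]
    } else {
      fl <- max(1, floor(eb$height_m[i] / 3))
      if (fl <= 2 && eb$area_m2[i] < 250) {
        expected[i] <- 1L
      } else {
        expected[i] <- max(1, floor(eb$area_m2[i] * fl /
                                      avg[[eb$zone_class[i]]] + 0.5))
      }
    }
  }
  expect_equal(sum(eb$n_dwellings, na.rm = TRUE), sum(expected))
  expect_equal(nrow(stock$dwellings), sum(expected))
})

test_that("price classes are commune tertiles with deterministic ties", {
  h <- gt_hierarchy()
  b <- data.frame(bid = paste0("B", 1:9), zone = "I1",
                  price_m2 = (1:9) * 1000, excluded = FALSE)
  got <- assign_price_class(b, h)
  expect_equal(unname(table(got$price_class)[c("low", "intermediate",
                                               "high")]),
               c(3L, 3L, 3L), ignore_attr = TRUE)
  expect_equal(got$price_class[1:3], rep("low", 3))
  expect_equal(got$price_class[7:9], rep("high", 3))

  eq <- data.frame(bid = paste0("E", 1:5), zone = "I2", price_m2 = 4000,
                   excluded = FALSE)
  expect_equal(assign_price_class(eq, h)$price_class,
               rep("intermediate", 5))

  # a commune with too few priced buildings uses department tertiles:
  # I5 shares department D1 with I1 (via communes C1, C3)
  small <- rbind(b, data.frame(bid = "S1", zone = "I3", price_m2 = 9000,
                               excluded = FALSE))
  got2 <- assign_price_class(small, h)
  expect_equal(got2$price_class[got2$bid == "S1"], "high")

  # classification is a partition of the residential stock
  expect_false(anyNA(got$price_class))
})
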