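test_that("waste inputs scale dose by content with micro-unit conversion", {
  dry <- waste_amendment("dry")
  inp9 <- waste_input(9, dry)
  expect_equal(unname(inp9["N"]), 109.8)
  expect_gte(inp9[["N"]], 101); expect_lte(inp9[["N"]], 118)
  # micro elements: mg kg^-1 -> kg ha^-1 via dose * content / 1000
  expect_equal(unname(inp9["B"]), 9 * 10.8 / 1000)

  fresh <- waste_amendment("fresh")
  inp18 <- waste_input(18, fresh)
  expect_equal(unname(inp18["N"]), 297)
  expect_gte(inp18[["N"]], 289); expect_lte(inp18[["N"]], 310)

  expect_true(all(waste_input(0, dry) == 0))
  expect_error(waste_input(-1, dry), ">= 0")
  # linearity in dose
  expect_equal(waste_input(27, dry), 3 * inp9)
})

test_that("mineral input fills unlisted elements with zero", {
  std <- mineral_input()
  expect_equal(unname(std[c("N", "P", "K", "Ca", "S")]),
               c(229, 12.5, 71.4, 31.5, 19))
  expect_equal(unname(std["Mg"]), 0)
  expect_true(all(std[c("B", "Cu", "Fe", "Mn", "Zn")] == 0))
  expect_true(all(mineral_input(c(N = 0)) == 0))
  usr <- mineral_input(c(K = 50))
  expect_equal(unname(usr["K"]), 50)
  expect_true(all(usr[setdiff(names(usr), "K")] == 0))
  expect_error(mineral_input(c(N = -3)), ">= 0")
})

test_that("fruit removal is yield x dry matter x concentration", {
  expect_equal(unname(fruit_removal(60, c(K = 10))["K"]), 66)
  expect_true(all(fruit_removal(0, c(K = 10, N = 12)) == 0))
  expect_equal(fruit_removal(80, c(K = 10)), 2 * fruit_removal(40, c(K = 10)))
  expect_error(fruit_removal(60, c(K = 10), dm_fraction = 1.2), "dm_fraction")
  expect_error(fruit_removal(-1, c(K = 10)))
})

test_that("cumulated budgets match a spreadsheet oracle and sign convention", {
  one <- list(list(inputs = c(N = 100), removals = c(N = 40)))
  expect_equal(cumulate_budget(one)$budget, 60)

  # 3-cycle toy case cumulated by hand, element by element
  cyc <- list(
    list(inputs = c(N = 110, K = 22, P = 20), removals = c(N = 40, K = 65, P = 5)),
    list(inputs = c(N = 95, K = 20, P = 18), removals = c(N = 38, K = 60, P = 4)),
    list(inputs = c(N = 120, K = 25, P = 21), removals = c(N = 45, K = 70, P = 6)))
  bs <- cumulate_budget(cyc, treatment = "D9")
  expect_s3_class(bs, "balance_sheet")
  oracle <- data.frame(element = c("K", "N", "P"),
                       input = c(67, 325, 59), removal = c(195, 123, 15),
                       budget = c(-128, 202, 44))
  expect_equal(as.data.frame(bs)[names(oracle)], oracle)
  expect_equal(bs$budget, bs$input - bs$removal)

  # zero inputs with positive removals: strictly negative (the K pattern)
  ctrl <- cumulate_budget(list(list(inputs = c(K = 0), removals = c(K = 30)),
                               list(inputs = c(K = 0), removals = c(K = 25))))
  expect_lt(ctrl$budget, 0)
  # order of cycles is immaterial
  expect_equal(as.data.frame(cumulate_budget(rev(cyc), treatment = "D9")),
               as.data.frame(bs))
  expect_error(cumulate_budget(list(list(inputs = c(N = 1), removals = c(K = 1)))),
               "mismatched")
})

test_that("budget linearity in dose holds for fixed composition", {
  dry <- waste_amendment("dry")
  fruit <- c(N = 12, P = 1.3, K = 14, Ca = 1, Mg = 1, S = 1.1)
  elems <- names(fruit)
  sheet_for <- function(dose) {
    cyc <- list(list(inputs = waste_input(dose, dry)[elems],
                     removals = fruit_removal(0, fruit)))
    cumulate_budget(cyc)
  }
  s9 <- sheet_for(9); s36 <- sheet_for(36)
  expect_equal(s36$input, 4 * s9$input, tolerance = 1e-12)
})

test_that("kg/ha to mmolc/dm3 conversion and its inverse", {
  expect_equal(round(kg_ha_to_mmolc(152, 39.098), 2), 3.89)
  expect_equal(kg_ha_to_mmolc(0, 39.098), 0)
  expect_equal(kg_ha_to_mmolc(39.098, 39.098), 1, tolerance = 1e-12)
  # divalent cation carries twice the charge
  expect_equal(kg_ha_to_mmolc(40.078, 40.078, charge = 2), 2, tolerance = 1e-12)
  for (mass in c(0.3, 45, 152)) {
    conc <- kg_ha_to_mmolc(mass, 24.305, charge = 2)
    expect_equal(mmolc_to_kg_ha(conc, 24.305, charge = 2), mass, tolerance = 1e-10)
  }
  expect_error(kg_ha_to_mmolc(10, -1), "molar_mass")
  expect_error(kg_ha_to_mmolc(10, 39, soil_volume = 0), "soil_volume")
})

test_that("base saturation arithmetic", {
  bs <- base_saturation(2, 15, 6, 20)
  expect_equal(as.numeric(bs), 100 * 23 / 43, tolerance = 1e-12)
  expect_equal(attr(bs, "cec"), 43)
  expect_equal(as.numeric(base_saturation(2, 15, 6, 0)), 100)
  # initial-soil means reproduce the reported plot-level mean within rounding
  init <- base_saturation(2.3, 15.3, 6.4, 43.8 - 24)
  expect_equal(as.numeric(init), 54.5, tolerance = 0.02)
  expect_error(base_saturation(0, 0, 0, 0), "CEC")
})
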