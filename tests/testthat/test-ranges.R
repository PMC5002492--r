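basis2 <- ilr_basis(sbp_table(rbind(c(1, -1)), parts = c("A", "B")))

test_that("balance confidence intervals are Student-t", {
  # hand case: n = 4, values 1..4
  m <- matrix(1:4, ncol = 1, dimnames = list(NULL, "[B | A]"))
  ci <- balance_ci(m)
  expect_equal(ci$mean, 2.5)
  expect_equal(ci$lower, 2.5 - qt(0.975, 3) * sd(1:4) / 2, tolerance = 1e-12)
  expect_equal(round(c(ci$lower, ci$upper), 4), c(0.4457, 4.5543))
  # identical values give a zero-width interval
  cz <- balance_ci(matrix(rep(1.3, 5), ncol = 1))
  expect_equal(c(cz$lower, cz$mean, cz$upper), rep(1.3, 3))
  # alpha -> 1 collapses to the mean
  ca <- balance_ci(m, alpha = 1 - 1e-12)
  expect_lt(ca$upper - ca$lower, 1e-10)
  expect_error(balance_ci(m[1, , drop = FALSE]), "at least 2")
})

test_that("Monte-Carlo ranges approach the closed-form box image", {
  ci <- data.frame(balance = "[B | A]", mean = 0, lower = -0.1, upper = 0.1, n = 10)
  rg <- mc_conc_ranges(ci, basis2, n_draws = 1e5, seed = 4)
  part1 <- function(b) 1000 * exp(b / sqrt(2)) / (exp(b / sqrt(2)) + exp(-b / sqrt(2)))
  expect_equal(rg$min[1], part1(-0.1), tolerance = 0.5 / part1(-0.1))
  expect_equal(rg$max[1], part1(0.1), tolerance = 0.5 / part1(0.1))
  expect_equal(rg$mean[1], 500)
  expect_true(all(rg$min <= rg$mean & rg$mean <= rg$max))

  # zero-width box collapses onto the back-transformed centroid
  b0 <- sqrt(1 / 2) * log(12.2 / 2.2)
  cz <- data.frame(balance = "[B | A]", mean = b0, lower = b0, upper = b0, n = 10)
  rz <- mc_conc_ranges(cz, basis2, n_draws = 100, seed = 1)
  expect_equal(rz$min, rz$mean)
  expect_equal(rz$max, rz$mean)
  expect_equal(rz$mean[1] / rz$mean[2], 12.2 / 2.2, tolerance = 1e-6)

  expect_error(mc_conc_ranges(transform(ci, lower = 0.2), basis2), "lower bound")
  expect_error(mc_conc_ranges(ci, ilr_basis(sbp_guava(complete = FALSE))))
})

test_that("identical seeds give identical ranges; draws depend on the seed", {
  basis <- ilr_basis(sbp_guava())
  ci <- data.frame(balance = basis$labels, mean = 0,
                   lower = seq(-0.2, -0.08, length.out = 7),
                   upper = seq(0.1, 0.22, length.out = 7), n = 12)
  r1 <- mc_conc_ranges(ci, basis, n_draws = 2000, seed = 99)
  r2 <- mc_conc_ranges(ci, basis, n_draws = 2000, seed = 99)
  expect_identical(r1, r2)
  r3 <- mc_conc_ranges(ci, basis, n_draws = 2000, seed = 100)
  expect_false(identical(r1$min, r3$min))
  # quantile option narrows the reported range
  rq <- mc_conc_ranges(ci, basis, n_draws = 2000, seed = 99,
                       quantiles = c(0.05, 0.95))
  expect_true(all(rq$min >= r1$min & rq$max <= r1$max))
})

test_that("widening the interval box never narrows nutrient ranges", {
  basis <- ilr_basis(sbp_guava())
  set.seed(17)
  for (rep in 1:50) {
    mid <- rnorm(7, sd = 0.3)
    half <- runif(7, 0.02, 0.1)
    grow <- 1 + runif(7, 0.5, 1.5)
    ci1 <- data.frame(balance = basis$labels, mean = mid,
                      lower = mid - half, upper = mid + half, n = 10)
    ci2 <- transform(ci1, lower = mid - half * grow, upper = mid + half * grow)
    r1 <- mc_conc_ranges(ci1, basis, n_draws = 3000, seed = rep)
    r2 <- mc_conc_ranges(ci2, basis, n_draws = 3000, seed = rep)
    expect_true(all(r2$min <= r1$min + 1e-12))
    expect_true(all(r2$max >= r1$max - 1e-12))
  }
})

test_that("critical values appear only for disjoint ranges, at the gap midpoint", {
  mk <- function(min, max, part = "P") {
    structure(data.frame(part = part, min = min, mean = (min + max) / 2, max = max),
              class = c("conc_range", "data.frame"))
  }
  cv <- critical_values(mk(2, 3), mk(1.0, 1.5))
  expect_equal(cv$critical, 1.75)
  expect_true(is.na(critical_values(mk(2, 3), mk(2.5, 4))$critical))
  expect_true(is.na(critical_values(mk(2, 3), mk(2, 3))$critical))
  # TP above TN, facing-bound variant
  up <- critical_values(mk(1, 2), mk(3, 4))
  expect_equal(up$critical, 2.5)
  expect_equal(critical_values(mk(1, 2), mk(3, 4), method = "facing")$critical, 2)
  expect_error(critical_values(mk(1, 2), mk(3, 4, part = "S")), "different parts")
})

test_that("N/P ratio range is scale invariant", {
  expect_equal(unname(np_ratio_range(c(N = 22, P = 2))), c(11, 11))
  m <- rbind(c(N = 20, P = 1.7, K = 5), c(N = 23, P = 1.9, K = 5))
  r <- np_ratio_range(m)
  expect_equal(unname(r), c(20 / 1.7, 23 / 1.9), tolerance = 1e-12)
  expect_equal(np_ratio_range(m * 2), r)
  same <- rbind(c(N = 20, P = 1.7), c(N = 20, P = 1.7))
  expect_equal(diff(np_ratio_range(same)), c(max = 0))
  expect_error(np_ratio_range(c(N = 1, K = 2)), "'N' and 'P'")
})
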