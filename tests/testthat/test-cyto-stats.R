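# Severing rates, crossover densities, group comparisons.

test_that("severing rate arithmetic and window-splitting invariance", {
  r0 <- severing_rate(list(events = data.frame(cell = integer(0)),
                           cell_areas = c(100, 200), duration = c(10, 10)))
  expect_true(all(r0$per_cell == 0))
  r1 <- severing_rate(list(events = data.frame(cell = rep(1L, 10)),
                           cell_areas = 100, duration = 10))
  expect_equal(r1$per_cell, 0.01)
  # splitting one observation window into two sub-windows with the events
  # apportioned by area leaves the per-window rates (hence the mean) intact
  whole <- severing_rate(list(events = data.frame(cell = rep(1L, 10)),
                              cell_areas = 100, duration = 10))
  split2 <- severing_rate(list(events = data.frame(cell = rep(c(1L, 2L),
                                                              c(6, 4))),
                               cell_areas = c(60, 40), duration = c(10, 10)))
  expect_equal(split2$mean, whole$mean)
  expect_error(severing_rate(list(events = data.frame(cell = 1L),
                                  cell_areas = 0, duration = 10)), "positive")
  # SD is across cells, not pooled
  rr <- severing_rate(list(events = data.frame(cell = c(1L, 1L, 2L)),
                           cell_areas = c(10, 10), duration = c(1, 1)))
  expect_equal(rr$sd, stats::sd(c(0.2, 0.1)))
})

test_that("rate estimator is unbiased under the Poisson generator", {
  means <- vapply(1:200, function(s) {
    rec <- make_severing_series(severing_sim_spec(1e-3, rep(625, 16), 10,
                                                  seed = s))
    severing_rate(rec)$mean
  }, 0)
  expect_lt(abs(mean(means) / 1e-3 - 1), 0.02)
  # single-replicate group mean within 3 sigma of the truth
  se <- sqrt(1e-3 / (625 * 10) / 16) # Poisson rate variance across 16 cells
  expect_lt(abs(mean(means) - 1e-3), 3 * se / sqrt(200))
})

test_that("crossover density arithmetic matches the printed convention", {
  cd <- crossover_density(rep(11, 6), rep(12, 6), 10)
  expect_equal(cd$mean_t1, 11)
  expect_equal(cd$percent_change, 9) # 11.0 -> 12 per 10 um^2
  expect_equal(crossover_density(rep(15, 6), rep(5, 6), 10)$percent_change,
               -67) # printed means 15 -> 5
  expect_equal(crossover_density(rep(7, 4), rep(7, 4), 10)$percent_change, 0)
  z <- crossover_density(rep(0, 4), rep(7, 4), 10)
  expect_true(z$undefined_baseline)
  expect_true(is.na(z$percent_change))
  # density normalization: counts in a 20 um^2 window halve per 10 um^2
  expect_equal(crossover_density(rep(10, 3), rep(10, 3), 20)$mean_t1, 5)
})

test_that("Mann-Whitney exact p matches exhaustive enumeration", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- compare_groups(a, b, "mann_whitney")
  expect_equal(unname(res$statistic), 0)
  # oracle: all 20 assignments of ranks 1..6 to group a
  vals <- c(a, b)
  combs <- utils::combn(6, 3)
  Us <- apply(combs, 2L, function(idx) {
    ga <- vals[idx]; gb <- vals[-idx]
    sum(outer(ga, gb, ">")) + 0.5 * sum(outer(ga, gb, "=="))
  })
  obsU <- sum(outer(a, b, ">"))
  p_exact <- mean(Us <= obsU | Us >= (9 - obsU)) # two-sided, U_max = 9
  expect_equal(p_exact, 0.1)
  expect_equal(res$p_value, p_exact)
  # identical samples: p = 1
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # symmetry of the two-sided p-value
  set.seed(2)
  x <- rnorm(12); y <- rnorm(15, 1)
  expect_equal(compare_groups(x, y)$p_value, compare_groups(y, x)$p_value)
  expect_equal(compare_groups(x, y, "t_test")$p_value,
               compare_groups(y, x, "t_test")$p_value)
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
  expect_error(compare_groups(1, 2, "t_test"), "at least 2")
})

test_that("both tests detect a 2-SD shift at n = 50 essentially always", {
  hits <- vapply(1:300, function(s) {
    set.seed(s)
    a <- rnorm(50); b <- rnorm(50, 2)
    compare_groups(a, b, "mann_whitney")$p_value < 0.001
  }, TRUE)
  expect_gte(mean(hits), 0.99)
})
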