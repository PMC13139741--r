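test_that("profiles normalise and the purity shorthand spreads mass correctly", {
  p <- kano_profile("A", purity = 0.8)
  expect_s3_class(p, "kano_profile")
  expect_equal(sum(p), 1.0)
  dist <- profile_category_distribution(p)
  expect_equal(unname(dist[["A"]]), 0.8)
  # remainder uniform over the other 22 cells: I holds 9 of them
  expect_equal(unname(dist[["I"]]), 0.2 * 9 / 22)

  pure <- kano_profile("M")
  tab <- kano_evaluation_table()
  expect_true(all(pure[tab == "M"] == 1 / 3))
  expect_true(all(pure[tab != "M"] == 0))

  w <- matrix(runif(25), 5, 5)
  expect_equal(sum(kano_profile(cell_weights = w)), 1.0)
  expect_error(kano_profile(cell_weights = matrix(-1, 5, 5)))
  expect_error(kano_profile("Z"))
})

test_that("profile_from_frequencies matches observed category proportions", {
  counts <- c(M = 282, O = 235, A = 725, I = 322, R = 2, Q = 5)
  p <- profile_from_frequencies(counts)
  expect_equal(profile_category_distribution(p),
               counts / sum(counts), tolerance = 1e-12)

  all_m <- profile_from_frequencies(c(M = 50))
  tab <- kano_evaluation_table()
  expect_true(all(all_m[tab == "M"] == 1 / 3))
  expect_equal(sum(all_m), 1.0)
})

test_that("degenerate generator yields the forced classification", {
  w <- matrix(0, 5, 5); w[3, 5] <- 1  # (neutral, dislike) -> M
  d <- simulate_kano_survey(list(x = kano_profile(cell_weights = w)),
                            n = 500, seed = 5)
  counts <- tabulate_item(d$x_func, d$x_dys)
  expect_identical(unname(counts[["M"]]), 500L)
  expect_identical(modal_category(counts)$category, "M")
})

test_that("empirical cell frequencies converge to the profile weights", {
  w <- matrix(0, 5, 5); w[1, 3] <- 0.5; w[1, 5] <- 0.5  # A and O half-half
  d <- simulate_kano_survey(list(x = kano_profile(cell_weights = w)),
                            n = 100000, seed = 6)
  counts <- tabulate_item(d$x_func, d$x_dys)
  expect_lt(abs(counts[["A"]] / 100000 - 0.5), 0.01)
  expect_lt(abs(counts[["O"]] / 100000 - 0.5), 0.01)
})

test_that("logic-error flags follow their Bernoulli rate", {
  d <- simulate_kano_survey(list(x = kano_profile("I")), n = 10000, seed = 8,
                            logic_error_rate = 0.1)
  scr <- screen_respondents(d, time_column = NULL)
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.1)
  expect_gte(scr$report$n_logic_excluded, bounds[[1]])
  expect_lte(scr$report$n_logic_excluded, bounds[[2]])
})

test_that("identical spec and seed give byte-identical datasets", {
  profiles <- list(a = kano_profile("O", 0.6), b = kano_profile("A", 0.6))
  d1 <- simulate_kano_survey(profiles, n = 200, seed = 123,
                             logic_error_rate = 0.05)
  d2 <- simulate_kano_survey(profiles, n = 200, seed = 123,
                             logic_error_rate = 0.05)
  expect_identical(d1, d2)

  # and the ambient RNG state is untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(simulate_kano_survey(profiles, n = 10, seed = 1))
  expect_identical(runif(3), before)
})

test_that("round trip: generated data recovers source category proportions", {
  counts <- c(M = 654, O = 209, A = 471, I = 220, R = 10, Q = 7)
  p <- profile_from_frequencies(counts)
  d <- simulate_kano_survey(list(x = p), n = 20000, seed = 9)
  got <- tabulate_item(d$x_func, d$x_dys)
  expect_true(all(abs(got / 20000 - counts / sum(counts)) < 0.02))
})
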