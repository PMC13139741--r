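fit_nurse <- kano(nurse_demand_frequencies())

test_that("the fitted object reproduces the published nurse-demand analysis", {
  it <- fit_nurse$items
  pub <- nurse_demand_frequencies()
  expect_identical(it$category, pub$published_attribute)
  expect_identical(unname(fit_nurse$attribute_tally[c("M", "O", "A", "I")]),
                   c(8L, 8L, 7L, 3L))
  expect_false(any(it$is_tie))
  expect_equal(round_half_up(it$si), pub$published_SI)
  expect_equal(round_half_up(it$dsi), pub$published_DSI)
  expect_identical(fit_nurse$quadrants$I,
                   as.character(c(2, 3, 4, 11, 15, 16, 19, 20)))
  expect_identical(fit_nurse$quadrants$II,
                   as.character(c(1, 9, 12, 13, 14, 24, 26)))
  expect_identical(fit_nurse$quadrants$III, as.character(c(17, 22, 23)))
  expect_identical(fit_nurse$quadrants$IV,
                   as.character(c(5, 6, 7, 8, 10, 18, 21, 25)))
})

test_that("quadrant memberships also reproduce from 2-dp display values", {
  pub <- nurse_demand_frequencies()
  si2 <- round_half_up(fit_nurse$items$si)
  dsi2 <- round_half_up(fit_nurse$items$dsi)
  origin2 <- kano_origin(si2, dsi2)
  q2 <- assign_quadrant(si2, dsi2, origin2)
  expect_identical(as.character(q2), as.character(fit_nurse$items$quadrant))
})

test_that("respondent-level and aggregated paths agree on simulated data", {
  pub <- nurse_demand_frequencies()
  profiles <- lapply(seq_len(4), function(i) {
    profile_from_frequencies(unlist(pub[i, c("M", "O", "A", "I", "R", "Q")]))
  })
  names(profiles) <- pub$item[1:4]
  d <- simulate_kano_survey(profiles, n = 400, seed = 51)
  fit_resp <- kano(d, screen = FALSE)

  agg <- cbind(
    data.frame(item = fit_resp$items$item_id, label = fit_resp$items$label),
    fit_resp$items[, c("M", "O", "A", "I", "R", "Q")]
  )
  fit_agg <- kano(agg)
  expect_identical(fit_agg$items$category, fit_resp$items$category)
  expect_equal(fit_agg$items$si, fit_resp$items$si)
  expect_equal(fit_agg$origin, fit_resp$origin)
})

test_that("screening integrates into the respondent-level fit", {
  d <- simulate_kano_survey(list(x = kano_profile("O", 0.8)), n = 400,
                            seed = 52, logic_error_rate = 0.1)
  fit <- kano(d)
  expect_false(is.null(fit$screening))
  r <- fit$screening$report
  expect_identical(r$n_received, 400L)
  expect_identical(r$n_valid, r$n_received - r$n_logic_excluded - r$n_time_excluded)
  expect_identical(sum(fit$items$n_total), r$n_valid)
  expect_identical(fit$items$category, "O")

  # explicit opt-out keeps everyone
  fit_all <- kano(d, screen = FALSE)
  expect_identical(unname(fit_all$items$n_total[[1]]), 400L)
})

test_that("fit errors name their cause", {
  expect_error(kano(data.frame(x = 1)), "codebook")
  d <- data.frame(a_func = NA_integer_, a_dys = 3L)
  expect_error(kano(d, kano_codebook("a")), "item 'a' has no complete")
})

test_that("print, summary, coef and plot methods run and show key results", {
  expect_output(print(fit_nurse), "26 items")
  expect_output(print(fit_nurse), "M:8 +O:8 +A:7 +I:3")
  s <- summary(fit_nurse)
  expect_output(print(s), "predominance.*2, 3, 4, 11, 15, 16, 19, 20")
  expect_identical(s$table$attribute, nurse_demand_frequencies()$published_attribute)

  cf <- coef(fit_nurse)
  expect_identical(dim(cf), c(26L, 2L))
  expect_equal(unname(cf["1", "si"]), 960 / 1564)

  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit_nurse))
})

test_that("simulate() draws parametric-bootstrap datasets from the fit", {
  sims <- simulate(fit_nurse, nsim = 2, seed = 53, n = 100)
  expect_length(sims, 2L)
  expect_identical(nrow(sims[[1]]), 100L)
  expect_identical(ncol(sims[[1]]), 3L + 2L * 26L)
  expect_false(identical(sims[[1]], sims[[2]]))
  # reproducible
  again <- simulate(fit_nurse, nsim = 2, seed = 53, n = 100)
  expect_identical(sims, again)
})

test_that("tie-break precedence is honoured and surfaced in the fit", {
  agg <- data.frame(item = "t", label = "tied", M = 5, O = 5, A = 1,
                    I = 0, R = 0, Q = 0)
  fit <- kano(agg)
  expect_identical(fit$items$category, "M")
  expect_true(fit$items$is_tie)
  fit_alt <- kano(agg, tie_precedence = c("O", "M", "A", "I", "R", "Q"))
  expect_identical(fit_alt$items$category, "O")
})
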