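test_that("SI and DSI reproduce worked frequency-row examples", {
  expect_equal(satisfaction_index(c(M = 282, O = 235, A = 725, I = 322)),
               960 / 1564)
  expect_equal(round_half_up(satisfaction_index(c(M = 282, O = 235, A = 725, I = 322))),
               0.61)
  expect_equal(round_half_up(satisfaction_index(c(M = 148, O = 534, A = 433, I = 454))),
               0.62)
  expect_equal(satisfaction_index(c(A = 10, O = 0, M = 0, I = 0)), 1.0)

  expect_equal(importance_index(c(M = 699, O = 272, A = 291, I = 301)),
               -971 / 1563)
  expect_equal(round_half_up(importance_index(c(M = 699, O = 272, A = 291, I = 301))),
               -0.62)
  expect_equal(round_half_up(importance_index(c(M = 131, O = 102, A = 714, I = 608))),
               -0.15)
  expect_equal(importance_index(c(A = 5, I = 5, O = 0, M = 0)), 0.0)

  # R and Q never enter the denominators
  base <- c(M = 3, O = 4, A = 5, I = 6)
  expect_equal(satisfaction_index(c(base, R = 100, Q = 100)),
               satisfaction_index(base))
  expect_error(satisfaction_index(c(M = 0, O = 0, A = 0, I = 0, R = 9)),
               "undefined")
})

test_that("indices stay in range on random frequency rows", {
  set.seed(11)
  for (rep in 1:200) {
    x <- random_freq_row()
    si <- satisfaction_index(x)
    dsi <- importance_index(x)
    expect_gte(si, 0); expect_lte(si, 1)
    expect_gte(dsi, -1); expect_lte(dsi, 0)
  }
})

test_that("adding a one-dimensional response never lowers SI nor raises DSI", {
  set.seed(12)
  for (rep in 1:100) {
    x <- random_freq_row()
    y <- x; y[["O"]] <- y[["O"]] + 1
    expect_gte(satisfaction_index(y), satisfaction_index(x))
    expect_lte(importance_index(y), importance_index(x))
  }
})

test_that("origin is the per-axis mean and handles degenerate inputs", {
  expect_equal(kano_origin(0.5, -0.5), c(x0 = 0.5, y0 = 0.5))
  expect_equal(kano_origin(rep(0.3, 4), rep(-0.7, 4)), c(x0 = 0.7, y0 = 0.3))
  expect_equal(kano_origin(c(0.2, 0.6), c(-0.1, -0.5)), c(x0 = 0.3, y0 = 0.4))
  expect_error(kano_origin(numeric(0), numeric(0)), "at least one")
})

test_that("quadrant assignment partitions the plane with ties going high", {
  origin <- c(x0 = 0.4, y0 = 0.5)
  expect_identical(as.character(assign_quadrant(0.6, -0.5, origin)), "I")
  expect_identical(as.character(assign_quadrant(0.6, -0.2, origin)), "II")
  expect_identical(as.character(assign_quadrant(0.3, -0.2, origin)), "III")
  expect_identical(as.character(assign_quadrant(0.3, -0.5, origin)), "IV")
  # exactly at the origin -> predominance
  expect_identical(as.character(assign_quadrant(0.5, -0.4, origin)), "I")

  set.seed(13)
  si <- runif(500); dsi <- -runif(500)
  q <- assign_quadrant(si, dsi, origin)
  expect_false(anyNA(q))
  expect_identical(levels(q), c("I", "II", "III", "IV"))
})

test_that("quadrant strategy names form the fixed bijection", {
  s <- quadrant_strategies()
  expect_identical(names(s), c("I", "II", "III", "IV"))
  expect_identical(unname(s), c("predominance", "improving",
                                "secondary improving", "reserving"))
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(c(0.615, -0.615, 0.125, -0.125)),
               c(0.62, -0.62, 0.13, -0.13))
  expect_equal(round_half_up(0.61499), 0.61)
})
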