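test_that("desirability trajectories have the documented shapes", {
  mono <- make_desirability_weights("monotone-increasing", K = 6)
  expect_equal(mono, 0:6)

  mid <- make_desirability_weights("peak-at-midpoint", K = 6)
  expect_equal(which.max(mid) - 1, 3)
  expect_equal(mid[1], 0)
  expect_equal(mid, rev(mid))          # symmetric decay

  interior <- make_desirability_weights("peak-interior", K = 6,
                                        peak_category = 4)
  expect_equal(which.max(interior) - 1, 4)
  expect_lt(interior[7], 6)            # extreme category not maximal

  for (shape in c("monotone-increasing", "peak-interior",
                  "peak-at-midpoint")) {
    for (K in c(3, 4, 6)) {
      w <- make_desirability_weights(shape, K = K)
      expect_length(w, K + 1)
      expect_gte(min(w), 0)
      expect_lte(max(w), 6)
      expect_equal(max(w), 6)          # rescaled to the full 0-6 metric
    }
  }
  expect_error(make_desirability_weights("peak-interior", K = 4,
                                         peak_category = 7), "0..K")
})

test_that("raw desirability ratings map affinely onto the 0-6 metric", {
  expect_equal(rescale_desirability(1, 1, 7), 0)
  expect_equal(rescale_desirability(7, 1, 7), 6)
  expect_equal(rescale_desirability(4, 1, 7), 3)
  # order and relative spacing preserved
  r <- c(2, 3.5, 6.5)
  w <- rescale_desirability(r, 1, 7)
  expect_equal(diff(w) / diff(r), rep(1, 2))
  expect_equal(rescale_desirability(c(3, 3, 3), 1, 5),
               rep(3, 3))
  expect_error(rescale_desirability(3, 2, 2), "Degenerate")
  expect_error(rescale_desirability(9, 1, 7), "outside")
})

test_that("scoring weights validate structure and round-trip via tables", {
  w <- scoring_weights(3, 2, 7, faking_weights = 0:6)
  expect_equal(w$trait[2, ], 0:6)
  expect_equal(w$trait[1, ], rep(0, 7))
  expect_error(scoring_weights(3, 2, 7, faking_weights = 0:5), "category")
  expect_error(scoring_weights(3, 2, 7, faking_weights = c(0:5, 9)),
               "\\[0, 6\\]")

  ws <- list(scoring_weights(2, 1, 4, c(0, 2, 4, 6)),
             scoring_weights(2, 2, 4, c(6, 4, 2, 0)))
  tab <- weights_to_table(ws)
  expect_s3_class(tab, "tbl_df")
  expect_equal(nrow(tab), 2 * 4 * 3)   # items x categories x (traits+faking)
  back <- table_to_weights(tab)
  expect_equal(back[[1]]$trait, ws[[1]]$trait)
  expect_equal(back[[2]]$faking, ws[[2]]$faking)
})
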