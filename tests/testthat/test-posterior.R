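test_that("modal assignment uses the argmax with ties toward lower class", {
  tab <- tibble::tibble(
    person_id = rep("p1", 9), item_id = rep(c("i1", "i2", "i3"), each = 3),
    class = rep(0:2, 3),
    probability = c(0.6, 0.3, 0.1,   # clear mode
                    0.5, 0.5, 0.0,   # tie -> class 0
                    0.1, 0.2, 0.7))
  a <- modal_assignment(tab)
  expect_equal(a$class[match(c("i1", "i2", "i3"), a$item_id)], c(0, 0, 2))
})

test_that("strategy consistency counts class-use patterns", {
  assignments <- tibble::tibble(
    person_id = rep(c("a", "b", "c", "d"), each = 3),
    item_id = rep(c("i1", "i2", "i3"), 4),
    class = c(0, 0, 0,   # one class
              0, 2, 0,   # two classes S-only/F-only
              1, 2, 1,   # two classes S&F/F-only
              0, 1, 2))  # all three
  sc <- strategy_consistency(assignments)
  expect_equal(sc$per_person$n_classes[match(c("a", "b", "c", "d"),
                                             sc$per_person$person_id)],
               c(1, 2, 2, 3))
  expect_equal(sum(sc$summary$n_persons), 4)
  expect_equal(sc$summary$n_persons[sc$summary$pattern == "S-only"], 1)
  expect_equal(sc$summary$n_persons[sc$summary$pattern == "S&F/F-only"], 1)
})

test_that("hit rate pools correct assignments over all cells", {
  truth <- tidyr::expand_grid(person_id = c("p1", "p2"),
                              item_id = c("i1", "i2", "i3"))
  truth$true_class <- c(0, 1, 2, 0, 1, 2)
  assign <- truth |> dplyr::rename(class = true_class)
  expect_equal(hit_rate(assign, truth), 100)
  assign2 <- assign
  assign2$class[c(2, 5)] <- c(2, 0)   # 4 of 6 correct
  expect_equal(hit_rate(assign2, truth), 100 * 4 / 6)
  expect_error(hit_rate(assign, dplyr::select(truth, -true_class)),
               "Ground-truth")
})

test_that("recovery metrics have their closed-form values", {
  df <- tibble::tibble(family = "a", truth = rnorm(50))
  df$estimate <- df$truth
  m <- recovery_metrics(df)
  expect_equal(m$bias, 0)
  expect_equal(m$rmse, 0)
  expect_equal(m$correlation, 1, tolerance = 1e-6)

  df2 <- tibble::tibble(family = "b", truth = rnorm(50))
  df2$estimate <- df2$truth + 0.5
  m2 <- recovery_metrics(df2)
  expect_equal(m2$bias, 0.5)
  expect_equal(m2$rmse, 0.5)

  set.seed(1)
  sigma <- 0.3
  df3 <- tibble::tibble(family = "c", truth = rnorm(20000))
  df3$estimate <- df3$truth + rnorm(20000, 0, sigma)
  m3 <- recovery_metrics(df3)
  expect_equal(m3$bias, 0, tolerance = 0.01)
  expect_equal(m3$rmse, sigma, tolerance = 0.01)
  expect_error(recovery_metrics(df3[0, ]), "Empty")
})

test_that("class probability tables match the kernel on fitted models", {
  tf <- cached_tiny_fit()
  fit <- tf$fit
  tab_c <- class_probability_table(fit, "conditional", n_draws = 50)
  tab_s <- class_probability_table(fit, "structural", n_draws = 50)
  for (tab in list(tab_c, tab_s)) {
    sums <- tab |>
      dplyr::group_by(person_id, item_id) |>
      dplyr::summarise(s = sum(probability), .groups = "drop")
    expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-9)
  }

  # single draw, single cell: structural table equals the kernel Eq.-7
  # probabilities and the conditional table equals the responsibilities
  u <- fakemix:::unpack_draw(fit, 1)
  D <- fit$wa$D
  item1 <- item_parameters(
    trait_slopes = u$aS[1, ], faking_slope = u$aF[1],
    gamma_s = u$gS[1, ], gamma_sf = u$gSF[1, ], gamma_f = u$gF[1, ],
    beta = u$beta[1, ], delta_s = u$dS[1], delta_f = u$dF[1])
  per1 <- person_parameters(theta = u$persons[1, seq_len(D)],
                            eta = u$persons[1, D + 1],
                            phi = u$persons[1, D + 2],
                            psi = u$persons[1, D + 3])
  pop1 <- population_parameters(diag(D + 3), nu_phi = u$globals[1],
                                nu_psi = u$globals[2],
                                lambda = u$globals[3],
                                sigma_s = u$globals[4],
                                sigma_sf = u$globals[5],
                                sigma_f = u$globals[6])
  terms <- fakemix:::draw_cell_terms(fit, 1)
  lp <- terms$cls[1, 1, ]
  expect_equal(exp(lp), class_probabilities(per1, item1, pop1),
               tolerance = 1e-10)
  resp <- terms$cls[1, 1, ] + terms$resp[1, 1, ] + terms$rt[1, 1, ]
  y11 <- fit$y[1, 1]; t11 <- exp(fit$logt[1, 1])
  expect_equal(exp(resp - max(resp)) / sum(exp(resp - max(resp))),
               responsibilities(y11, t11, per1, item1,
                                tf$design$weights[[1]], pop1),
               tolerance = 1e-8)
})

test_that("structural and conditional tables coincide for uninformative
          data-generating parameters", {
  # a fit is not needed: with identical response and RT models across
  # classes the responsibilities equal the structural probabilities
  w <- scoring_weights(1, 1, 3, faking_weights = rep(0, 3))
  w$trait[1, ] <- 0    # no trait term either: all classes share one model
  it <- item_parameters(0.8, faking_slope = 0, gamma_s = c(0, 1, -1),
                        gamma_sf = c(0, 1, -1), gamma_f = c(0, 1, -1),
                        beta = c(0, 0.3, -0.2), delta_s = 1.6,
                        delta_f = 1.6)
  pop <- population_parameters(diag(4), nu_psi = 1.2, lambda = 1e-9,
                               sigma_s = .5, sigma_sf = .5, sigma_f = .5)
  pr <- person_parameters(0.7, eta = -0.3, phi = 0.2, psi = 0.9)
  struct <- class_probabilities(pr, it, pop)
  cond <- responsibilities(1, 4.2, pr, it, w, pop)
  expect_equal(cond, struct, tolerance = 1e-6)
})

test_that("overall class proportions are the item-average of item-level
          proportions", {
  tf <- cached_tiny_fit()
  overall <- class_proportions(tf$fit, "structural", "overall",
                               n_draws = 40)
  per_item <- class_proportions(tf$fit, "structural", "item", n_draws = 40)
  agg <- per_item |>
    dplyr::group_by(class) |>
    dplyr::summarise(estimate = mean(estimate))
  expect_equal(overall$estimate, agg$estimate, tolerance = 1e-9)
  expect_equal(sum(overall$estimate), 1, tolerance = 1e-9)
  expect_true(all(overall$conf.low <= overall$estimate + 1e-12))
  expect_true(all(overall$conf.high >= overall$estimate - 1e-12))
})
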