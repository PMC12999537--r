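test_that("seeded simulation is bit-reproducible and well-formed", {
  d <- tiny_design()
  a <- simulate_assessment(d, seed = 1)
  b <- simulate_assessment(d, seed = 1)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$rt_seconds > 0))
  expect_true(all(a$response %in% 0:(d$n_categories - 1)))
  expect_equal(nrow(a), d$n_persons * length(d$items))
  c <- simulate_assessment(d, seed = 2)
  expect_false(identical(a$response, c$response))
})

test_that("person draws have the requested correlation structure", {
  S <- default_latent_correlations(3)
  expect_true(isSymmetric(S))
  expect_equal(S[4, 6], .32)  # faking x strategy inclination
  expect_gt(min(eigen(S, only.values = TRUE)$values), 0)

  p <- draw_persons(10000, diag(5), seed = 99)
  X <- as.matrix(p[-1])
  cors <- cor(X)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.05)
  expect_lt(max(abs(colMeans(X))), 4 / sqrt(10000))

  p2 <- draw_persons(10000, S, seed = 100)
  expect_equal(cor(p2$eta, p2$psi), .32, tolerance = 0.05)
  bad <- diag(4); bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(draw_persons(10, bad), "positive definite")
})

test_that("a degenerate latent response model yields a faking-free test", {
  d <- tiny_design(n_persons = 60)
  d$items <- lapply(d$items, function(it) { it$beta <- c(0, -30, -60); it })
  dat <- simulate_assessment(d, seed = 5)
  expect_true(all(dat$true_class == 0))
})

test_that("responses and times follow the class-specific models", {
  # single item, fixed person: category frequencies given the trait-only
  # class match the model probabilities within binomial error
  d <- tiny_design(n_persons = 2000, items_per_trait = 1, n_traits = 1,
                   n_categories = 4)
  dat <- simulate_assessment(d, seed = 21)
  truth <- sim_truth(dat)
  plist <- fakemix:::persons_to_list(truth)
  s_cells <- which(dat$true_class == 0)
  ok <- 0
  probs <- t(vapply(seq_len(nrow(truth)), function(n) {
    category_probabilities(0, plist[[n]], d$items[[1]], d$weights[[1]])
  }, numeric(4)))
  expected <- colMeans(probs[dat$true_class == 0, ])
  observed <- as.vector(prop.table(table(factor(dat$response[s_cells],
                                                levels = 0:3))))
  expect_equal(observed, expected, tolerance = 4 / sqrt(length(s_cells)))

  # mean log-time in the dual-process class matches its implied mean
  sf <- which(dat$true_class == 1)
  implied <- d$items[[1]]$delta_s + d$pop$lambda * d$items[[1]]$delta_f -
    d$pop$nu_phi * truth$phi[sf]
  expect_equal(mean(log(dat$rt_seconds[sf])), mean(implied),
               tolerance = 4 * d$pop$sigma_sf / sqrt(length(sf)))
})

test_that("class frequencies converge to the average model probabilities", {
  d <- tiny_design(n_persons = 2000, items_per_trait = 2, n_traits = 1)
  dat <- simulate_assessment(d, seed = 31)
  truth <- sim_truth(dat)
  plist <- fakemix:::persons_to_list(truth)
  avg <- Reduce(`+`, lapply(seq_along(plist), function(n) {
    rowMeans(vapply(d$items, function(it) {
      class_probabilities(plist[[n]], it, d$pop)
    }, numeric(3)))
  })) / length(plist)
  freq <- as.vector(prop.table(table(factor(dat$true_class, levels = 0:2))))
  n_cells <- nrow(dat)
  se <- sqrt(avg * (1 - avg) / n_cells)
  expect_true(all(abs(freq - avg) < 3 * se + 0.01))
})

test_that("default scenario reproduces the qualitative median RT ordering", {
  d <- sim_design(n_persons = 400)
  dat <- simulate_assessment(d, seed = 41)
  med <- tapply(dat$rt_seconds, dat$true_class, median)
  # dual-process slowest, faking-only fastest
  expect_gt(med["1"], med["0"])
  expect_gt(med["0"], med["2"])
})
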