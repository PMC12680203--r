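test_that("fitting the worked example stores the documented class moments", {
  fit <- mdem(worked_example(), order = 3)
  st <- fit$states[["c2"]]
  expect_equal(st$count, 5L)
  expect_equal(st$mean, 11.6)
  expect_equal(st$central_moment, 58.752)
  expect_equal(glance(fit)$n_absorbed, 5L)
})

test_that("fit validates its inputs", {
  d <- tibble::tibble(x = c(1, 2), class = c("a", "b"))
  expect_error(mdem(d, class = "label"), "not found")
  expect_error(mdem(dplyr::mutate(d, x = c("1", "2"))), "numeric")
  expect_error(mdem(dplyr::mutate(d, x = c(1, NA))), "finite")
  # declared-but-empty class (factor level with no rows)
  d2 <- tibble::tibble(x = 1:3, class = factor(c("a", "a", "b"), levels = c("a", "b", "c")))
  expect_error(mdem(d2), "no training rows.*c")
})

test_that("singleton classes fit and score degenerately but gracefully", {
  d <- tibble::tibble(x = c(0.25, 0.75), class = c("a", "b"))
  fit <- mdem(d, order = 2)
  expect_equal(fit$states$a$central_moment, 0)
  sc <- mdem_displacement(fit, 0.5)  # exact symmetric tie in binary floating point
  # both classes singleton and equidistant: tie broken by class position
  expect_equal(sc$weighted[1], sc$weighted[2], tolerance = 1e-12)
  expect_true(sc$chosen[1])
})

test_that("displacement scores match hand enumeration on the A/B example", {
  d <- tibble::tibble(x = c(0.0, 0.2, 0.9), class = c("A", "A", "B"))
  fit <- mdem(d, order = 1)
  sc <- mdem_displacement(fit, 0.5)
  expect_equal(sc$raw, c(0.4 / 3, 0.2), tolerance = 1e-12)
  expect_equal(sc$weighted, c(0.8 / 3, 0.2), tolerance = 1e-12)
  expect_equal(sc$class[sc$chosen], "B")
  expect_equal(sc$weighted, sc$raw * sc$count)
  expect_true(all(sc$weighted >= 0))
  expect_equal(mdem_margin(fit, 0.5), 0.8 / 3 - 0.2, tolerance = 1e-12)
  # a point at a class mean has zero raw displacement for that class
  sc0 <- mdem_displacement(fit, 0.1)
  expect_equal(sc0$raw[1], 0)
  expect_equal(sc0$class[sc0$chosen], "A")
})

test_that("a small class can win against a big class on weighted displacement", {
  # dense cluster of 46 points vs a sparse pair; the probe sits near the pair
  set.seed(5)
  big <- matrix(rnorm(92, mean = 0.3, sd = 0.03), ncol = 2)
  small <- rbind(c(0.8, 0.8), c(0.9, 0.9))
  d <- dplyr::bind_rows(
    tibble::tibble(x1 = big[, 1], x2 = big[, 2], class = "big"),
    tibble::tibble(x1 = small[, 1], x2 = small[, 2], class = "small")
  )
  fit <- mdem(d, order = 1)
  sc <- mdem_displacement(fit, c(0.6, 0.6))
  expect_gt(sc$raw[sc$class == "small"], sc$raw[sc$class == "big"])
  expect_equal(sc$class[sc$chosen], "small")
})

test_that("evolution commits the point to the winning class only", {
  d <- tibble::tibble(x = c(0.0, 0.2, 0.9), class = c("A", "A", "B"))
  fit <- mdem(d, order = 1)
  ev <- mdem_evolve(fit, tibble::tibble(x = 0.5))
  expect_equal(ev$class, "B")
  expect_equal(ev$model$states$B$count, 2L)
  expect_equal(ev$model$states$B$mean, 0.7)
  expect_equal(ev$model$states$A$count, 2L) # untouched
  # frozen predictions leave the model alone and are permutation-invariant
  frozen <- mdem(d, order = 1, evolve = FALSE)
  batch <- tibble::tibble(x = c(0.5, 0.05, 0.85, 0.4))
  p1 <- predict(frozen, batch)
  p2 <- predict(frozen, batch[c(3, 1, 4, 2), , drop = FALSE])
  expect_equal(p2, p1[c(3, 1, 4, 2)])
  expect_equal(predict(frozen, batch), p1) # repeated calls identical
})

test_that("batch prediction is sequential and order-sensitive only when evolving", {
  expect_equal(predict(mdem(worked_example()), worked_example()[0, ]), character(0))
  # all-at-the-mean batch grows the winning class by the batch size
  d <- tibble::tibble(x = c(0.1, 0.12, 0.9, 0.92), class = c("a", "a", "b", "b"))
  fit <- mdem(d, order = 1)
  ev <- mdem_evolve(fit, tibble::tibble(x = rep(0.11, 5)))
  expect_equal(ev$class, rep("a", 5))
  expect_equal(ev$model$states$a$count, 7L)
  # an evolving model tracks drift that a frozen one misses
  # a slow march away from class a: the evolving model's class-a mean keeps
  # up with the drift, the frozen model flips to b past the midpoint
  drift <- tibble::tibble(x = seq(0.15, 0.6, length.out = 20))
  p_evolve <- predict(mdem(d, order = 1), drift, evolve = TRUE)
  p_frozen <- predict(mdem(d, order = 1), drift, evolve = FALSE)
  expect_false(identical(p_evolve, p_frozen))
})

test_that("single-class models always predict that class; margin needs two", {
  fit <- mdem(worked_example())
  expect_equal(predict(fit, tibble::tibble(x = c(-5, 100))), c("c2", "c2"))
  expect_error(mdem_margin(fit, 3), "single-class")
})

test_that("incremental scoring matches the brute-force oracle on random instances", {
  insts <- random_instances(220, seed = 77)
  for (inst in insts) {
    df <- instance_to_df(inst)
    fit <- mdem(df, order = inst$order)
    got <- mdem_displacement(fit, inst$x)
    want <- oracle_displacements(inst$sets, inst$x, order = inst$order)
    expect_equal(got$raw, want$raw, tolerance = 1e-9)
    expect_equal(got$weighted, want$weighted, tolerance = 1e-9)
    expect_equal(got$class[got$chosen], want$class[want$chosen])
  }
})

test_that("predictions are invariant to a common positive rescaling", {
  set.seed(31)
  for (order in 1:4) {
    d <- two_gaussians(n = 40, sep = 3, seed = order)
    test <- dplyr::select(two_gaussians(n = 10, sep = 3, seed = order + 50), -class)
    c0 <- 3.7
    d_scaled <- dplyr::mutate(d, x1 = x1 * c0)
    test_scaled <- dplyr::mutate(test, x1 = x1 * c0)
    p1 <- predict(mdem(d, order = order, evolve = FALSE), test)
    p2 <- predict(mdem(d_scaled, order = order, evolve = FALSE), test_scaled)
    expect_equal(p1, p2)
  }
})

test_that("permuting class declaration order permutes nothing but labels", {
  d <- tibble::tibble(x = c(0.0, 0.2, 0.9), class = c("A", "A", "B"))
  d_rev <- d[c(3, 1, 2), ]
  batch <- tibble::tibble(x = c(0.5, 0.1, 0.7))
  expect_equal(predict(mdem(d, evolve = FALSE), batch),
               predict(mdem(d_rev, evolve = FALSE), batch))
  expect_equal(mdem_margin(mdem(d), 0.5), mdem_margin(mdem(d_rev), 0.5))
})

test_that("two identical classes give zero margin", {
  d <- tibble::tibble(x = rep(c(0.1, 0.5, 0.9), 2),
                      class = rep(c("a", "b"), each = 3))
  fit <- mdem(d, order = 2)
  expect_equal(mdem_margin(fit, 0.42), 0)
})

test_that("well-separated Gaussian classes are classified near-perfectly", {
  accs <- sapply(1:5, function(s) {
    train <- two_gaussians(n = 100, sep = 6, sd = 0.05, seed = s)
    test <- two_gaussians(n = 50, sep = 6, sd = 0.05, seed = s + 100)
    mean(predict(mdem(train, order = 1), test) == test$class)
  })
  expect_true(all(accs >= 0.99))
})

test_that("fitted class means recover generator means within 3 SE", {
  n <- 400; sd0 <- 0.05
  d <- two_gaussians(n = n, sep = 6, sd = sd0, seed = 9)
  fit <- mdem(d, order = 1)
  se <- sd0 / sqrt(n)
  expect_lt(abs(fit$states$a$mean - (0.5 - 3 * sd0)), 3 * se)
  expect_lt(abs(fit$states$b$mean - (0.5 + 3 * sd0)), 3 * se)
})

test_that("count-plus-one weighting is available and changes ties predictably", {
  d <- tibble::tibble(x = c(0.0, 0.2, 0.9), class = c("A", "A", "B"))
  sc <- mdem_displacement(mdem(d, weight = "count_plus_1"), 0.5)
  expect_equal(sc$weighted, sc$raw * (sc$count + 1))
})
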