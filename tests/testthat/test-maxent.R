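# MaxEnt estimator: feature construction, the penalized convex fit against
# independent oracles, prediction transforms, and cross-validation mechanics.

test_that("background sampling is uniform, distinct and reproducible", {
  st <- bare_stack(list(Elevation = matrix(1, 100, 200)))  # 20,000 cells
  b1 <- sample_background(st, 1000, seed = 5)
  expect_identical(sample_background(st, 1000, seed = 5), b1)
  expect_equal(nrow(unique(b1[, c("row", "col")])), 1000)
  # n >= #unmasked: every cell once
  small <- bare_stack(list(Elevation = matrix(1, 5, 6)))
  expect_message(all_bg <- sample_background(small, 100, seed = 1), "taking all")
  expect_equal(nrow(all_bg), 30)
  # empirical per-cell selection rate over repeated draws ~ n / N = 0.05
  hits <- 0
  for (s in 1:200) {
    b <- sample_background(st, 1000, seed = s)
    hits <- hits + sum(b$row <= 10 & b$col <= 10)  # watch 100 fixed cells
  }
  expect_lt(abs(hits / (200 * 100) - 0.05), 0.01)
})

test_that("features are scaled to [0,1] with documented arithmetic", {
  bg <- data.frame(x = c(0, 2, 4, 6, 8, 10))
  defs <- make_feature_defs(bg, kinds = c(x = "continuous"), fc = c("L"))
  expect_equal(as.numeric(feature_matrix(defs, data.frame(x = 5))), 0.5)

  defs_lq <- make_feature_defs(bg, kinds = c(x = "continuous"),
                               fc = c("L", "Q"))
  got <- as.numeric(feature_matrix(defs_lq, data.frame(x = 3)))
  expect_equal(got, c(0.3, 0.09))

  # hinge knots strictly inside the range; all hinge features in [0,1]
  defs_h <- make_feature_defs(bg, kinds = c(x = "continuous"), fc = "H",
                              n_hinge_knots = 7)
  knots <- vapply(defs_h, function(d) d$knot, 0)
  expect_true(all(knots > 0 & knots < 10))
  fm <- feature_matrix(defs_h, bg)
  expect_true(all(fm >= 0 & fm <= 1))

  # constant layer is skipped with a warning
  bg2 <- cbind(bg, k = 1)
  expect_warning(defs2 <- make_feature_defs(bg2,
    kinds = c(x = "continuous", k = "continuous"), fc = "L"), "constant")
  expect_equal(length(defs2), 1L)

  # categorical layers get one indicator per observed level regardless of fc
  bg3 <- data.frame(Drainage = c(1, 1, 2, 3))
  defs3 <- make_feature_defs(bg3, fc = "L")
  expect_equal(vapply(defs3, function(d) d$kind, ""), rep("indicator", 3))
  expect_equal(as.numeric(feature_matrix(defs3, data.frame(Drainage = 2))),
               c(0, 1, 0))

  # projection clamping keeps out-of-range values at the range edge
  defs_l <- make_feature_defs(bg, kinds = c(x = "continuous"), fc = "L")
  expect_equal(as.numeric(feature_matrix(defs_l, data.frame(x = 99))), 1)
  expect_equal(as.numeric(feature_matrix(defs_l, data.frame(x = 99),
                                         clamp = FALSE)), 9.9)
})

test_that("total shrinkage yields the uniform distribution over background", {
  set.seed(31)
  bg <- data.frame(x = runif(200, 0, 10))
  pres <- data.frame(x = runif(20, 4, 9))
  m <- maxent(pres, bg, maxent_config(rm = 1e8, fc = "L"))
  expect_true(all(m$lambda == 0))
  raw <- predict(m, bg, type = "raw")
  expect_equal(raw, rep(1 / 200, 200))
  # uniform model closed form: H = log nb, cloglog = 1 - exp(-1)
  expect_equal(m$entropy, log(200))
  expect_equal(predict(m, pres[1, , drop = FALSE], type = "cloglog"),
               1 - exp(-1))
})

test_that("one-feature fit matches a brute-force grid/optimize oracle", {
  bg <- data.frame(x = c(0, 5, 10))
  pres <- data.frame(x = c(6, 8))
  cfg <- maxent_config(rm = 1, fc = "L", convergence = 1e-12, max_iter = 5000)
  m <- maxent(pres, bg, cfg)
  # independent objective written from scratch
  fb <- bg$x / 10; fp <- pres$x / 10
  beta <- 1 * sqrt(max(stats::var(fp), 1e-4) / 2)
  obj <- function(l) -mean(l * fp) + log(sum(exp(l * fb))) + beta * abs(l)
  l_grid <- seq(-20, 20, by = 1e-3)
  l0 <- l_grid[which.min(vapply(l_grid, obj, 0))]
  l_star <- stats::optimize(obj, c(l0 - 1e-2, l0 + 1e-2), tol = 1e-9)$minimum
  expect_lt(abs(unname(m$lambda) - l_star), 1e-4)
  expect_lt(abs(m$objective - obj(l_star)), 1e-8)
})

test_that("raw scores are a probability distribution over training background", {
  set.seed(33)
  bg <- data.frame(a = runif(500), b = runif(500))
  pres <- data.frame(a = runif(40, 0.3, 1), b = runif(40, 0, 0.6))
  m <- maxent(pres, bg, maxent_config(rm = 1, fc = c("L", "Q"),
                                      n_hinge_knots = 5))
  expect_lt(abs(sum(predict(m, bg, type = "raw")) - 1), 1e-9)
  # scaling lambda: log-raw responds by lambda.f minus the new logZ (oracle)
  m2 <- m
  m2$lambda <- 2 * m$lambda
  Fb <- feature_matrix(m$defs, bg, clamp = FALSE)
  s2 <- as.numeric(Fb %*% m2$lambda)
  m2$logZ <- max(s2) + log(sum(exp(s2 - max(s2))))
  expect_lt(abs(sum(predict(m2, bg, type = "raw")) - 1), 1e-9)
})

test_that("cloglog is a monotone transform of raw with the entropy constant", {
  set.seed(35)
  bg <- data.frame(a = runif(300))
  pres <- data.frame(a = runif(25, 0.5, 1))
  m <- maxent(pres, bg, maxent_config(rm = 0.5, fc = c("L", "Q")))
  raw <- predict(m, bg, type = "raw")
  cll <- predict(m, bg, type = "cloglog")
  expect_true(all(cll >= 0 & cll <= 1))
  expect_equal(order(raw), order(cll))
  expect_equal(cll, 1 - exp(-exp(m$entropy) * raw))
})

test_that("the penalized objective is convex: restarts agree", {
  set.seed(37)
  bg <- data.frame(a = runif(300), b = runif(300))
  pres <- data.frame(a = runif(30, 0.4, 1), b = runif(30, 0, 0.7))
  cfg <- maxent_config(rm = 1, fc = c("L", "Q"), convergence = 1e-9,
                       max_iter = 4000)
  m0 <- maxent(pres, bg, cfg)
  set.seed(1)
  m1 <- maxent(pres, bg, cfg, start = runif(length(m0$lambda), -2, 2))
  expect_lt(abs(m0$objective - m1$objective), 1e-6)
})

test_that("regularization shrinks: nonzero count non-increasing in rm", {
  set.seed(39)
  bg <- data.frame(a = runif(400), b = runif(400), c = runif(400))
  pres <- data.frame(a = runif(50, 0.4, 1), b = runif(50, 0, 0.7),
                     c = runif(50, 0.2, 0.9))
  ks <- vapply(c(0.25, 1, 4, 16, 64), function(rm) {
    m <- maxent(pres, bg, maxent_config(rm = rm, fc = c("L", "Q"),
                                        n_hinge_knots = 4))
    sum(m$lambda != 0)
  }, 0)
  expect_true(all(diff(ks) <= 0))
})

test_that("a known generating coefficient is recovered", {
  set.seed(41)
  nb <- 2000
  bg <- data.frame(x = runif(nb, 0, 10))
  z <- (bg$x - min(bg$x)) / (max(bg$x) - min(bg$x))
  lambda_true <- 1.5
  p <- exp(lambda_true * z); p <- p / sum(p)
  pres <- bg[sample.int(nb, 500, replace = TRUE, prob = p), , drop = FALSE]
  m <- maxent(pres, bg, maxent_config(rm = 0.5, fc = "L",
                                      convergence = 1e-9, max_iter = 3000))
  expect_lt(abs(unname(m$lambda) - lambda_true), 0.2)
})

test_that("model JSON serialization round-trips predictions", {
  set.seed(43)
  bg <- data.frame(a = runif(200), Drainage = sample(1:3, 200, TRUE))
  pres <- data.frame(a = runif(20, 0.4, 1), Drainage = sample(1:3, 20, TRUE))
  m <- maxent(pres, bg, maxent_config(rm = 1, fc = c("L", "Q", "H"),
                                      n_hinge_knots = 3))
  p <- withr::local_tempfile(fileext = ".json")
  write_maxent(m, p)
  m2 <- read_maxent(p)
  expect_equal(predict(m2, bg), predict(m, bg), tolerance = 1e-12)
  expect_equal(m2$entropy, m$entropy)
})

test_that("cross-validation partitions evenly and handles leave-one-out", {
  set.seed(45)
  bg <- data.frame(x = runif(150, 0, 10))
  pres <- data.frame(x = runif(12, 6, 10))
  cv <- cross_validate(pres, bg, maxent_config(rm = 1, fc = "L"), k = 5,
                       seed = 2)
  expect_equal(sum(cv$folds$n_test), 12)
  expect_true(max(cv$folds$n_test) - min(cv$folds$n_test) <= 1)
  loo <- cross_validate(pres, bg, maxent_config(rm = 1, fc = "L"), k = 12,
                        seed = 2)
  expect_true(all(loo$folds$n_test == 1))
  expect_error(cross_validate(pres, bg, k = 13), "exceeds")
})
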