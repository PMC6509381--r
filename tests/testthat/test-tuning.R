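# Screening, AICc tuning, AUC/TSS and threshold rules.

test_that("spearman screen drops one member of a perfectly correlated pair", {
  set.seed(51)
  x <- rnorm(100)
  tab <- data.frame(a = x, b = x, c = rnorm(100))
  rep1 <- spearman_screen(tab)
  expect_true("c" %in% rep1$retained)
  expect_equal(length(intersect(rep1$retained, c("a", "b"))), 1)
  expect_equal(nrow(rep1$dropped), 1)
  expect_true(rep1$dropped$variable %in% c("a", "b"))

  # rank invariance: x and exp(x) have rho = 1
  tab2 <- data.frame(a = x, b = exp(x), c = rnorm(100))
  rep2 <- spearman_screen(tab2)
  expect_equal(nrow(rep2$dropped), 1)

  # independent noise at n = 200: nothing dropped
  set.seed(52)
  tab3 <- as.data.frame(matrix(rnorm(200 * 5), 200))
  rep3 <- spearman_screen(tab3)
  expect_equal(length(rep3$retained), 5)

  # constant column flagged, not tested
  tab4 <- data.frame(a = x, k = 1)
  rep4 <- spearman_screen(tab4)
  expect_true("k" %in% rep4$dropped$variable)
  expect_match(rep4$dropped$reason[rep4$dropped$variable == "k"], "constant")

  expect_error(spearman_screen(tab[1:2, ]), "3 rows")
})

test_that("shadow screen confirms a real signal and rejects pure noise", {
  set.seed(53)
  n <- 400
  tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  labels <- as.integer(tab$x1 > stats::median(tab$x1))
  keep <- shadow_screen(tab, labels, seed = 3, n_rounds = 12,
                        num_trees = 100)
  expect_true("x1" %in% keep)
  expect_false("x2" %in% keep)
  expect_false("x3" %in% keep)
  hits <- attr(keep, "hits")
  expect_equal(unname(hits["x1"]), 12)
  # determinism
  keep2 <- shadow_screen(tab, labels, seed = 3, n_rounds = 12,
                         num_trees = 100)
  expect_identical(as.character(keep), as.character(keep2))
  expect_error(shadow_screen(tab, rep(1, n)), "two classes")
})

test_that("AICc follows its definition and an independent recompute", {
  set.seed(55)
  bg <- data.frame(x = runif(300, 0, 10))
  pres <- data.frame(x = runif(25, 5, 10))
  m <- maxent(pres, bg, maxent_config(rm = 0.5, fc = c("L", "Q")))
  a <- aicc(m, pres)
  k <- attr(a, "k"); lnL <- attr(a, "lnL"); n <- nrow(pres)
  expect_equal(as.numeric(a), 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1))
  # independent lnL from the serialized model
  p <- withr::local_tempfile(fileext = ".json")
  write_maxent(m, p)
  mm <- jsonlite::read_json(p, simplifyVector = TRUE)
  z <- (pmin(pmax(pres$x, mm$features$lo[1]), mm$features$hi[1]) -
          mm$features$lo[1]) / (mm$features$hi[1] - mm$features$lo[1])
  feats <- cbind(z, z^2)
  lnL_oracle <- sum(feats %*% mm$lambda - mm$logZ)
  expect_lt(abs(lnL - lnL_oracle), 1e-9)

  # k = 0: AICc reduces to -2 lnL exactly
  m0 <- maxent(pres, bg, maxent_config(rm = 1e8, fc = "L"))
  a0 <- aicc(m0, pres)
  expect_equal(attr(a0, "k"), 0)
  expect_equal(as.numeric(a0), -2 * attr(a0, "lnL"))

  # n - k - 1 <= 0: undefined
  m$lambda[] <- 1
  expect_equal(as.numeric(aicc(m, pres[1:2, , drop = FALSE])), Inf)
})

test_that("AICc grows when a useless feature enters at (almost) fixed fit", {
  set.seed(57)
  bg <- data.frame(x = runif(300, 0, 10))
  pres <- data.frame(x = runif(25, 5, 10))
  m <- maxent(pres, bg, maxent_config(rm = 0.5, fc = "L"))
  a1 <- aicc(m, pres)
  m2 <- m
  m2$defs <- structure(c(m$defs, m$defs[1]), class = "feature_defs")
  m2$lambda <- c(m$lambda, dup = 1e-12)  # duplicate feature, negligible weight
  a2 <- aicc(m2, pres)
  expect_equal(attr(a2, "k"), attr(a1, "k") + 1)
  expect_gt(as.numeric(a2), as.numeric(a1))
})

test_that("tuning returns the AICc argmin with deterministic tie-breaks", {
  set.seed(59)
  bg <- data.frame(x = runif(300, 0, 10))
  pres <- data.frame(x = runif(30, 5, 10))
  single <- tune_maxent(pres, bg, rm_list = 2, fc_list = "L")
  expect_equal(nrow(single$table), 1)
  expect_equal(single$best, 1)
  expect_error(tune_maxent(pres, bg, rm_list = numeric(0)), "empty")

  # data generated from a linear-only Gibbs model: L wins or ties within 2
  cfg <- maxent_config(n_hinge_knots = 4)
  for (s in 1:5) {
    set.seed(s)
    nb <- 600
    bgl <- data.frame(x = runif(nb, 0, 10))
    z <- (bgl$x - min(bgl$x)) / (max(bgl$x) - min(bgl$x))
    p <- exp(2 * z); p <- p / sum(p)
    presl <- bgl[sample.int(nb, 300, replace = TRUE, prob = p), , drop = FALSE]
    tr <- tune_maxent(presl, bgl, rm_list = 1, fc_list = c("L", "LQH"),
                      config = cfg)
    aic_l <- tr$table$aicc[tr$table$fc == "L"]
    expect_lt(aic_l - min(tr$table$aicc), 2 + 1e-9,
              label = sprintf("seed %d: AICc(L) - min", s))
  }
})

test_that("AUC is the rank statistic with half-weight ties", {
  expect_equal(auc_score(c(5, 6), c(1, 2)), 1.0)
  expect_equal(auc_score(c(1, 2, 3), c(1, 2, 3)), 0.5)
  # 4-pair enumeration: wins 3, losses 1 -> 0.75
  expect_equal(auc_score(c(0.9, 0.8), c(0.7, 0.85)), 0.75)
  # invariance under strictly monotone transforms
  set.seed(61)
  sp <- runif(30); sb <- runif(50)
  a0 <- auc_score(sp, sb)
  expect_equal(auc_score(exp(3 * sp), exp(3 * sb)), a0)
  expect_equal(auc_score(qlogis(sp), qlogis(sb)), a0)
})

test_that("confusion metrics follow the TSS identity at the edges", {
  sp <- c(0.2, 0.6, 0.7, 0.9, 0.9, 0.95, 0.4, 0.8, 0.85, 0.99)
  sb <- c(0.1, 0.15, 0.3, 0.35, 0.5, 0.45, 0.55, 0.25, 0.65, 0.05)
  cm <- confusion_at(0.5, sp, sb)
  expect_equal(cm$tss, cm$sensitivity + cm$specificity - 1)
  expect_equal(cm$sensitivity, mean(sp >= 0.5))
  expect_equal(cm$specificity, mean(sb < 0.5))
  cm0 <- confusion_at(0, sp, sb)
  expect_equal(c(cm0$sensitivity, cm0$specificity, cm0$tss), c(1, 0, 0))
  cm1 <- confusion_at(1 + 1e-9, sp, sb)
  expect_equal(c(cm1$sensitivity, cm1$specificity, cm1$tss), c(0, 1, 0))
})

test_that("weighted threshold arithmetic is exact", {
  # equal TSS: plain mean
  expect_equal(as.numeric(weighted_threshold(c(0.2, 0.3, 0.4),
                                             c(0.4, 0.4, 0.4))), 0.3)
  # TSS (0.5, 0.25, 0.25) with thresholds (0.2, 0.3, 0.4) -> 0.275
  expect_equal(as.numeric(weighted_threshold(c(0.2, 0.3, 0.4),
                                             c(0.5, 0.25, 0.25))), 0.275)
  # all TSS <= 0: unweighted fallback, flagged
  w <- weighted_threshold(c(0.2, 0.4), c(-0.1, 0))
  expect_equal(as.numeric(w), 0.3)
  expect_true(attr(w, "fallback"))
})

test_that("threshold rules behave on separated scores and obey invariants", {
  sp <- c(0.7, 0.8, 0.9); sb <- c(0.1, 0.2, 0.3)
  th <- habitat_thresholds(sp, sb)
  expect_gte(th$mtss, max(sb))
  expect_lte(th$mtss, min(sp))
  expect_equal(unname(th$tss["mtss"]), 1)

  set.seed(63)
  for (i in 1:20) {
    sp <- runif(25, 0.3, 1); sb <- runif(40, 0, 0.8)
    th <- habitat_thresholds(sp, sb)
    expect_gte(th$tss["mtss"] + 1e-12, th$tss["etss"])
    expect_gte(th$tss["mtss"] + 1e-12, th$tss["ptss"])
    expect_gte(th$weighted, min(th$mtss, th$ptss, th$etss))
    expect_lte(th$weighted, max(th$mtss, th$ptss, th$etss))
  }
  # PTSS is the interpolated 10th percentile of presence scores
  sp2 <- seq(0.1, 1, by = 0.1)
  th2 <- habitat_thresholds(sp2, runif(30, 0, 0.5))
  expect_equal(th2$ptss, unname(stats::quantile(sp2, 0.1)))
})
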