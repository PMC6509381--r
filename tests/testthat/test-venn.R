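# Venn four-set attribution: set identities, exhaustive truth-table oracle,
# the loss-convention permutation, area accounting, and map export.

test_that("binarization thresholds and propagates nodata", {
  s <- matrix(c(0.2, 0.5, 0.7, NA), 2, 2)
  expect_equal(as.vector(binarize(s, 0.5)), c(0L, 1L, 1L, NA))
  expect_equal(as.vector(binarize(s, 0))[1:3], c(1L, 1L, 1L))
  expect_equal(as.vector(binarize(s, 1))[1:3], c(0L, 0L, 0L))
  m <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)
  expect_true(is.na(binarize(s, 0.5, mask = m)[2, 1]))
})

test_that("changed sets obey the union/intersection identities", {
  set.seed(71)
  for (i in 1:10) {
    sh <- make_sh(random_habitat(), random_habitat(),
                  random_habitat(), random_habitat())
    cs <- changed_sets(sh)
    cur <- sh$HCUR == 1; ccs <- sh$HCCS == 1
    # brute-force per-cell verification
    expect_identical(cs$unchanged, cur & ccs)
    expect_identical(cs$gain, ccs & !cur)
    expect_identical(cs$loss, cur & !ccs)
    expect_false(any(cs$unchanged & cs$gain))
    expect_false(any(cs$unchanged & cs$loss))
    expect_false(any(cs$gain & cs$loss))
    expect_identical(cs$unchanged | cs$gain | cs$loss, cur | ccs)
  }
  # degenerate cases
  h <- random_habitat()
  cs2 <- changed_sets(make_sh(h, h, h, h))
  expect_false(any(cs2$gain) || any(cs2$loss))
  expect_identical(cs2$unchanged, h == 1)
  z <- matrix(0L, 8, 8)
  cs3 <- changed_sets(make_sh(z, h, h, h))
  expect_identical(cs3$gain, h == 1)
  expect_false(any(cs3$loss))
  expect_error(changed_sets(make_sh(z, h, h, matrix(0L, 4, 4))), "shape")
})

test_that("all 16 membership combinations match the hand oracle", {
  combos <- expand.grid(cur = 0:1, clc = 0:1, slr = 0:1, ccs = 0:1)
  sh <- make_sh(matrix(combos$cur, 4, 4), matrix(combos$clc, 4, 4),
                matrix(combos$slr, 4, 4), matrix(combos$ccs, 4, 4))
  for (conv in c("as_printed", "symmetric")) {
    got <- decomp_labels(decompose_change(sh, conv))
    expect_identical(as.vector(got), as.vector(venn_oracle_map(sh, conv)),
                     label = conv)
  }
  # spot checks straight from the definitions
  # gain cell present in both single-scenario gains -> shared
  i <- which(combos$cur == 0 & combos$clc == 1 & combos$slr == 1 &
               combos$ccs == 1)
  lab <- decomp_labels(decompose_change(sh))
  expect_equal(as.vector(lab)[i], "gain_s_ics")
  # loss cell retained under both single scenarios -> shared (as printed)
  j <- which(combos$cur == 1 & combos$clc == 1 & combos$slr == 1 &
               combos$ccs == 0)
  expect_equal(as.vector(lab)[j], "loss_s_ics")
})

test_that("degenerate single-driver habitats push change into coupling", {
  h <- matrix(1L, 4, 4); z <- matrix(0L, 4, 4)
  # no change under either single scenario, but gain under combined
  g <- decomp_labels(decompose_change(make_sh(z, z, z, h)))
  expect_true(all(g == "gain_c_ics"))
  # everything lost under combined; single scenarios keep nothing
  l_print <- decomp_labels(decompose_change(make_sh(h, z, z, z),
                                            "as_printed"))
  expect_true(all(l_print == "loss_c_ics"))
  l_sym <- decomp_labels(decompose_change(make_sh(h, z, z, z), "symmetric"))
  expect_true(all(l_sym == "loss_s_ics"))
})

test_that("loss conventions are an exact label permutation of each other", {
  perm <- c(loss_s_ics = "loss_c_ics", loss_c_ics = "loss_s_ics",
            loss_p_clc = "loss_p_slr", loss_p_slr = "loss_p_clc")
  set.seed(73)
  for (i in 1:10) {
    sh <- make_sh(random_habitat(), random_habitat(),
                  random_habitat(), random_habitat())
    ap <- decomp_labels(decompose_change(sh, "as_printed"))
    sy <- decomp_labels(decompose_change(sh, "symmetric"))
    is_loss <- ap %in% names(perm)
    expect_identical(unname(perm[ap[is_loss]]), sy[is_loss])
    # gains and non-loss labels are convention-invariant
    expect_identical(ap[!is_loss], sy[!is_loss])
  }
})

test_that("decomposition labels partition the grid and conserve counts", {
  set.seed(75)
  sh <- make_sh(random_habitat(10, 10), random_habitat(10, 10),
                random_habitat(10, 10), random_habitat(10, 10))
  sh$HCUR[1, 1:3] <- NA; sh$HCLC[1, 1:3] <- NA
  sh$HSLR[1, 1:3] <- NA; sh$HCCS[1, 1:3] <- NA
  d <- decompose_change(sh)
  expect_equal(sum(!is.na(d$codes)), 97)
  cs <- changed_sets(sh)
  lab <- decomp_labels(d)
  expect_equal(sum(lab %in% c("gain_p_clc", "gain_p_slr", "gain_s_ics",
                              "gain_c_ics"), na.rm = TRUE), sum(cs$gain))
  expect_equal(sum(lab %in% c("loss_p_clc", "loss_p_slr", "loss_s_ics",
                              "loss_c_ics"), na.rm = TRUE), sum(cs$loss))
  expect_equal(sum(lab == "unchanged", na.rm = TRUE), sum(cs$unchanged))
})

test_that("a 4x4 worked example reproduces the hand-built label grid", {
  cur <- matrix(c(1, 1, 0, 0,
                  1, 1, 0, 0,
                  0, 0, 0, 0,
                  1, 0, 0, 0), 4, 4, byrow = TRUE)
  clc <- matrix(c(1, 0, 1, 0,
                  1, 1, 0, 0,
                  1, 0, 0, 0,
                  0, 0, 0, 0), 4, 4, byrow = TRUE)
  slr <- matrix(c(1, 1, 1, 0,
                  0, 1, 0, 0,
                  0, 1, 0, 0,
                  0, 0, 0, 0), 4, 4, byrow = TRUE)
  ccs <- matrix(c(1, 0, 1, 1,
                  0, 1, 0, 0,
                  1, 1, 0, 0,
                  0, 0, 0, 0), 4, 4, byrow = TRUE)
  # hand enumeration, cell by cell (as_printed):
  # (1,1) cur&ccs unchanged | (1,2) loss, kept slr only -> p_slr
  # (1,3) gain in clc&slr -> s_ics | (1,4) gain in neither -> c_ics
  # (2,1) loss, kept clc only -> p_clc | (2,2) unchanged
  # (3,1) gain, clc only -> p_clc | (3,2) gain, slr only -> p_slr
  # (4,1) loss, kept neither -> c_ics | rest absent
  want <- matrix(c("unchanged", "loss_p_slr", "gain_s_ics", "gain_c_ics",
                   "loss_p_clc", "unchanged", "absent", "absent",
                   "gain_p_clc", "gain_p_slr", "absent", "absent",
                   "loss_c_ics", "absent", "absent", "absent"),
                 4, 4, byrow = TRUE)
  got <- decomp_labels(decompose_change(make_sh(cur, clc, slr, ccs)))
  expect_identical(got, want)
})

test_that("area table sums components exactly and rounds half-up", {
  # printed-table arithmetic (northern increase/decrease, southern rows)
  ap <- area_percentages(c(27038, 164, 1073, 2659))
  expect_equal(ap$total, 30934)
  expect_equal(ap$pct, c(87.41, 0.53, 3.47, 8.60))
  ap2 <- area_percentages(c(1758, 2618, 204, 0))
  expect_equal(ap2$total, 4580)
  expect_equal(ap2$pct, c(38.38, 57.16, 4.45, 0.00))
  # one class holding all change
  ap3 <- area_percentages(c(0, 0, 12, 0))
  expect_equal(ap3$pct, c(0, 0, 100, 0))
  # zero change: flagged zeros
  ap0 <- area_percentages(c(0, 0, 0, 0))
  expect_true(ap0$flagged)
  expect_equal(ap0$pct, rep(0, 4))

  # end-to-end area table from a decomposition, with cell size applied
  set.seed(77)
  sh <- make_sh(random_habitat(), random_habitat(),
                random_habitat(), random_habitat())
  d <- decompose_change(sh)
  at <- area_table(d, cell_size = 2)   # 4 km^2 cells
  comp <- as.numeric(at[1, c("H_p_clc", "H_p_slr", "H_s_ics", "H_c_ics")])
  expect_equal(sum(comp), at$H_changed[1])
  expect_equal(at$H_changed[1], sum(changed_sets(sh)$gain) * 4)
  pct <- as.numeric(at[1, c("pct_p_clc", "pct_p_slr", "pct_s_ics",
                            "pct_c_ics")])
  expect_lt(abs(sum(pct) - 100), 0.011)
})

test_that("coded map export round-trips with legend and nodata", {
  set.seed(79)
  sh <- make_sh(random_habitat(6, 7), random_habitat(6, 7),
                random_habitat(6, 7), random_habitat(6, 7))
  for (nm in names(sh)) sh[[nm]][6, 7] <- NA
  d <- decompose_change(sh)
  d$grid <- grid_spec(6, 7, 1)
  asc <- withr::local_tempfile(fileext = ".asc")
  leg <- withr::local_tempfile(fileext = ".csv")
  export_map(d, asc, leg)
  back <- read_decomposition(asc, leg)
  expect_identical(back$codes, d$codes)
  expect_true(is.na(back$codes[6, 7]))
  legend <- utils::read.csv(leg)
  expect_equal(nrow(legend),
               length(unique(d$codes[!is.na(d$codes)])))
})
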