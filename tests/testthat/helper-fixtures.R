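# Shared fixtures and independent oracles, all built in code.

tiny_stack <- function(nrows = 12, ncols = 20, seed = 101, ...) {
  synth_landscape(grid_spec(nrows, ncols, 1), seed = seed, ...)
}

# A bare stack with explicitly chosen layers (no synthesis), handy when a test
# needs full control of the values.
bare_stack <- function(layers, mask = NULL, cell_size = 1) {
  nr <- nrow(layers[[1]]); nc <- ncol(layers[[1]])
  env_stack(grid_spec(nr, nc, cell_size), layers, mask)
}

const_layer <- function(value, nr, nc) matrix(value, nr, nc)

# Wrap four 0/1 matrices as a scenario-habitat list.
make_sh <- function(cur, clc, slr, ccs) {
  list(HCUR = cur, HCLC = clc, HSLR = slr, HCCS = ccs)
}

random_habitat <- function(nr = 8, nc = 8, p = 0.5) {
  matrix(stats::rbinom(nr * nc, 1, p), nr, nc)
}

# Independent hand-enumerated attribution oracle. For a single cell with
# membership flags (cur, clc, slr, ccs) it returns the expected label,
# written as direct case analysis (not reusing package set algebra).
venn_oracle_cell <- function(cur, clc, slr, ccs, convention = "as_printed") {
  if (!cur && !ccs) return("absent")
  if (cur && ccs) return("unchanged")
  if (!cur && ccs) {                      # gain
    in_clc <- clc == 1; in_slr <- slr == 1
    if (in_clc && in_slr) return("gain_s_ics")
    if (in_clc) return("gain_p_clc")
    if (in_slr) return("gain_p_slr")
    return("gain_c_ics")
  }
  # loss: cur & !ccs
  if (convention == "as_printed") {
    kept_clc <- clc == 1; kept_slr <- slr == 1
    if (kept_clc && kept_slr) return("loss_s_ics")
    if (kept_clc) return("loss_p_clc")
    if (kept_slr) return("loss_p_slr")
    return("loss_c_ics")
  }
  lost_clc <- clc == 0; lost_slr <- slr == 0
  if (lost_clc && lost_slr) return("loss_s_ics")
  if (lost_clc) return("loss_p_clc")
  if (lost_slr) return("loss_p_slr")
  "loss_c_ics"
}

venn_oracle_map <- function(sh, convention = "as_printed") {
  out <- matrix(NA_character_, nrow(sh$HCUR), ncol(sh$HCUR))
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out)))
    out[i, j] <- venn_oracle_cell(sh$HCUR[i, j], sh$HCLC[i, j],
                                  sh$HSLR[i, j], sh$HCCS[i, j], convention)
  out
}

decomp_labels <- function(decomp) {
  lg <- decomp$legend
  matrix(lg$label[match(decomp$codes, lg$code)],
         nrow(decomp$codes), ncol(decomp$codes))
}

# Brute-force Monte Carlo pick-freeze Sobol estimator (Saltelli/Jansen):
# the independent variance-based oracle for the eFAST estimates.
sobol_pickfreeze <- function(f, dists, n = 1e5, seed = 1) {
  set.seed(seed)
  m <- length(dists)
  nms <- vapply(dists, function(d) d$variable, "")
  draw <- function() {
    X <- as.data.frame(lapply(dists, function(d) {
      inv <- coastniche:::dist_invcdf(d)
      inv(stats::runif(n))
    }))
    names(X) <- nms
    X
  }
  A <- draw(); B <- draw()
  yA <- f(A); yB <- f(B)
  V <- stats::var(c(yA, yB))
  SF <- ST <- numeric(m)
  for (i in seq_len(m)) {
    ABi <- A; ABi[[i]] <- B[[i]]
    yABi <- f(ABi)
    SF[i] <- mean(yB * (yABi - yA)) / V       # Saltelli 2010 first-order
    ST[i] <- mean((yA - yABi)^2) / (2 * V)    # Jansen total
  }
  list(S_F = SF, S_T = ST)
}

# Ishigami test function and its closed-form Sobol indices.
ishigami_f <- function(a = 7, b = 0.1) {
  function(X) sin(X$x1) + a * sin(X$x2)^2 + b * X$x3^4 * sin(X$x1)
}

ishigami_dists <- function() {
  lapply(c("x1", "x2", "x3"), function(nm)
    list(variable = nm, family = "uniform",
         params = list(min = -pi, max = pi)))
}

ishigami_true <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  V <- V1 + V2 + V13
  list(S_F = c(V1, V2, 0) / V, S_T = c(V1 + V13, V2, V13) / V, V = V)
}
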