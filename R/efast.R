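# Extended FAST (Fourier Amplitude Sensitivity Test): drive all inputs along
# sinusoidal search curves, one block per factor with that factor at the high
# frequency omega_max and all others at low distinct frequencies, then read
# variance shares off the Fourier spectrum of the model output.
#   S_F = main-effect share   (harmonics p*omega_max, p = 1..M)
#   S_T = 1 - complementary share (all frequencies up to omega_max/2)

#' eFAST sample-size formula
#'
#' Total number of model evaluations `N = (2*M*omega_max + 1) * m` for the
#' per-factor resampled design: `Ns = 2*M*omega_max + 1` runs per factor
#' block, one block per input factor.
#'
#' @param M Interference factor (number of harmonics).
#' @param omega_max Highest search-curve frequency.
#' @param m Number of input factors.
#' @return Integer count of model evaluations.
#' @export
efast_sample_size <- function(M, omega_max, m) {
  stopifnot(M >= 1, omega_max >= 1, m >= 1)
  (2 * M * omega_max + 1) * m
}

# ---- input marginal distributions -----------------------------------------

dist_invcdf <- function(spec) {
  p <- spec$params
  switch(spec$family,
    uniform = function(u) stats::qunif(u, p$min, p$max),
    normal = function(u) stats::qnorm(u, p$mean, p$sd),
    lognormal = function(u) stats::qlnorm(u, p$meanlog, p$sdlog),
    empirical = {
      q <- p$quantiles
      function(u) stats::approx(seq(0, 1, length.out = length(q)), q, u,
                                rule = 2)$y
    },
    categorical = function(u) {
      cum <- cumsum(p$probs)
      p$levels[pmin(findInterval(u, c(0, cum), left.open = TRUE,
                                 rightmost.closed = TRUE),
                    length(p$levels))]
    },
    degenerate = function(u) rep(p$value, length(u)),
    stop("unknown family ", spec$family))
}

chisq_gof <- function(x, qfun, n_par, nbins = 20) {
  n <- length(x)
  edges <- qfun(seq(0, 1, length.out = nbins + 1))
  edges[1] <- -Inf; edges[nbins + 1] <- Inf
  obs <- as.numeric(table(cut(x, unique(edges), labels = FALSE)))
  k <- length(unique(edges)) - 1L
  expd <- n / k
  stat <- sum((obs - expd)^2 / expd)
  df <- max(1L, k - 1L - n_par)
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Fit marginal input distributions for the sensitivity design
#'
#' For each layer, candidate parametric families (uniform, normal, and —
#' where all values are positive — lognormal) are fitted by closed-form
#' maximum likelihood and checked with a chi-square goodness-of-fit test on
#' equiprobable bins; the family with the best (largest) p-value is kept if it
#' passes at `alpha`, otherwise the empirical quantile distribution is used.
#' Categorical layers use their observed level frequencies; constant layers
#' are flagged degenerate (and get zero sensitivity downstream).
#'
#' @param stack An [env_stack()].
#' @param region_mask Optional logical matrix; TRUE cells are excluded in
#'   addition to the stack's own mask.
#' @param alpha Chi-square acceptance level.
#' @param nbins Equiprobable bins for the test.
#' @return List of class `dist_specs`, one spec per layer with elements
#'   `variable`, `family`, `params`, `gof`.
#' @export
fit_distributions <- function(stack, region_mask = NULL, alpha = 0.01,
                              nbins = 20) {
  mask <- stack$mask
  if (!is.null(region_mask)) mask <- mask | region_mask
  if (sum(!mask) < 30) stop("need at least 30 unmasked cells")
  specs <- list()
  for (nm in names(stack$layers)) {
    x <- stack$layers[[nm]][!mask]
    if (stack$kinds[[nm]] == "categorical") {
      tb <- table(x)
      specs[[nm]] <- list(variable = nm, family = "categorical",
                          params = list(levels = as.numeric(names(tb)),
                                        probs = as.numeric(tb) / length(x)),
                          gof = list(stat = 0, df = NA, p = 1))
      next
    }
    if (stats::sd(x) == 0) {
      specs[[nm]] <- list(variable = nm, family = "degenerate",
                          params = list(value = x[1]),
                          gof = list(stat = NA, df = NA, p = NA))
      next
    }
    cands <- list(uniform = list(params = list(min = min(x), max = max(x)),
                                 n_par = 2))
    cands$normal <- list(params = list(mean = mean(x),
                                       sd = stats::sd(x)), n_par = 2)
    if (all(x > 0))
      cands$lognormal <- list(params = list(meanlog = mean(log(x)),
                                            sdlog = stats::sd(log(x))),
                              n_par = 2)
    best <- NULL
    for (fam in names(cands)) {
      spec <- list(variable = nm, family = fam, params = cands[[fam]]$params)
      g <- chisq_gof(x, dist_invcdf(spec), cands[[fam]]$n_par, nbins)
      spec$gof <- g
      if (is.null(best) || g$p > best$gof$p) best <- spec
    }
    if (best$gof$p <= alpha) {
      # no parametric family fits: empirical quantiles
      qs <- stats::quantile(x, seq(0, 1, length.out = 201), names = FALSE)
      best <- list(variable = nm, family = "empirical",
                   params = list(quantiles = qs),
                   gof = list(stat = NA, df = NA, p = NA))
    }
    specs[[nm]] <- best
  }
  structure(specs, class = "dist_specs")
}

#' @export
print.dist_specs <- function(x, ...) {
  for (s in x)
    cat(sprintf("  %-10s %-11s (GOF p = %s)\n", s$variable, s$family,
                if (is.na(s$gof$p)) "-" else sprintf("%.3f", s$gof$p)))
  invisible(x)
}

# ---- design ---------------------------------------------------------------

efast_frequencies <- function(m, M, omega_max, allow_cycling = FALSE) {
  band <- floor(omega_max / (2 * M))
  if (band < 1)
    stop("omega_max too small: omega_max/(2M) < 1")
  if (m - 1 > band) {
    if (!allow_cycling)
      stop(sprintf(paste0("cannot assign %d distinct complementary ",
                          "frequencies <= %d; need omega_max >= %d ",
                          "(or allow_cycling = TRUE)"),
                   m - 1, band, 2 * M * (m - 1)))
    warning("complementary frequencies cycle within 1..", band,
            "; total-index estimates may be biased")
  }
  # spread over the whole band: clustered tiny frequencies (1, 2, ...) trace
  # closed low-order Lissajous curves whose cross moments bias the variance
  # estimate, while frequencies above the band leak harmonics past the
  # omega_max/2 cutoff
  n_comp <- max(m - 1, 1)
  comp <- if (n_comp <= band) {
    v <- floor(seq(1, band, length.out = n_comp))
    while (anyDuplicated(v)) v[duplicated(v)] <- v[duplicated(v)] + 1L
    v
  } else rep_len(seq_len(band), n_comp)
  lapply(seq_len(m), function(i) {
    w <- numeric(m)
    w[i] <- omega_max
    w[-i] <- comp[seq_len(m - 1)]
    w
  })
}

#' Build the extended-FAST search-curve design
#'
#' One block per factor: the factor of interest runs at `omega_max`, the
#' complementary factors at distinct low frequencies `<= omega_max/(2M)`. The
#' curve parameter sweeps `Ns = 2*M*omega_max + 1` equispaced points of
#' `(-pi, pi]`, and factor values are
#' `InvCDF_j(1/2 + arcsin(sin(omega_j s + phi_j))/pi)` with random phases
#' `phi` drawn once per block from the given seed.
#'
#' @param dists A [fit_distributions()] result (or any list of dist specs).
#' @param M Interference factor.
#' @param omega_max Peak frequency.
#' @param seed Phase seed.
#' @param allow_cycling Permit complementary-frequency reuse (with a warning)
#'   when the band is too narrow for `m - 1` distinct values.
#' @return List of class `efast_design`: `blocks` (list of data.frames,
#'   `Ns` rows x `m` factor columns), `s`, `freqs`, `M`, `omega_max`.
#' @export
efast_design <- function(dists, M = 4, omega_max = 416, seed = 1,
                         allow_cycling = FALSE) {
  m <- length(dists)
  nms <- vapply(dists, function(d) d$variable, "")
  freqs <- efast_frequencies(m, M, omega_max, allow_cycling)
  Ns <- 2 * M * omega_max + 1
  s <- 2 * pi * seq_len(Ns) / Ns - pi
  set.seed(seed)
  inv <- lapply(dists, dist_invcdf)
  blocks <- vector("list", m)
  for (i in seq_len(m)) {
    phi <- stats::runif(m, 0, 2 * pi)
    X <- matrix(0, Ns, m)
    for (j in seq_len(m)) {
      u <- 0.5 + asin(sin(freqs[[i]][j] * s + phi[j])) / pi
      u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
      X[, j] <- inv[[j]](u)
    }
    colnames(X) <- nms
    blocks[[i]] <- as.data.frame(X)
  }
  structure(list(blocks = blocks, s = s, freqs = freqs, M = M,
                 omega_max = omega_max, variables = nms),
            class = "efast_design")
}

# one-sided power spectrum Lambda_p = A_p^2 + B_p^2, p = 1..(Ns-1)/2
efast_spectrum <- function(y) {
  Ns <- length(y)
  co <- stats::fft(y) / Ns
  Mod(co[2:((Ns - 1) / 2 + 1)])^2
}

#' First-order (main-effect) eFAST index from one output block
#'
#' Variance at the harmonics `p * omega_high`, `p = 1..M`, as a share of the
#' total variance (all frequencies). Constant output yields 0 with attribute
#' `flagged`.
#'
#' @param y Model output along one factor's search curve; odd length
#'   `>= 2*M*omega_high + 1`.
#' @param omega_high The factor's frequency.
#' @param M Interference factor.
#' @return `S_F` in \[0, 1\].
#' @export
efast_first_order <- function(y, omega_high, M = 4) {
  Ns <- length(y)
  if (Ns %% 2 == 0 || Ns < 2 * M * omega_high + 1)
    stop("y must have odd length >= 2*M*omega_high + 1")
  if (stats::var(y) == 0) {
    out <- 0; attr(out, "flagged") <- "constant output"
    return(out)
  }
  lam <- efast_spectrum(y)
  V <- 2 * sum(lam)
  2 * sum(lam[seq_len(M) * omega_high]) / V
}

#' Total eFAST index from one output block
#'
#' One minus the complementary share: the variance explained by all
#' frequencies up to `omega_high/2` (the band containing every harmonic of
#' every complementary factor) divided by the total variance.
#'
#' @inheritParams efast_first_order
#' @return `S_T` in \[0, 1\].
#' @export
efast_total <- function(y, omega_high, M = 4) {
  Ns <- length(y)
  if (Ns %% 2 == 0 || Ns < 2 * M * omega_high + 1)
    stop("y must have odd length >= 2*M*omega_high + 1")
  if (stats::var(y) == 0) {
    out <- 0; attr(out, "flagged") <- "constant output"
    return(out)
  }
  lam <- efast_spectrum(y)
  V <- 2 * sum(lam)
  cutoff <- floor(omega_high / 2)
  1 - 2 * sum(lam[seq_len(cutoff)]) / V
}

rank_desc <- function(v, ties = "min") as.integer(rank(-v, ties.method = ties))

#' Run eFAST on an arbitrary model function
#'
#' Evaluates `f` on every design row of every factor block, for `n_repeats`
#' independent phase draws, and aggregates first-order and total indices.
#'
#' @param f Function mapping a data.frame of factor values to a numeric
#'   vector of outputs.
#' @param dists List of input distribution specs ([fit_distributions()]).
#' @param M,omega_max,allow_cycling Design parameters ([efast_design()]).
#' @param seed Base phase seed; repeat `r` uses `seed + r - 1`.
#' @param n_repeats Independent repeats whose spread is reported.
#' @return Object of class `efast_result`: data.frame `table` with columns
#'   `variable`, `S_F`, `S_F_sd`, `rank_SF`, `S_T`, `S_T_sd`, `rank_ST`,
#'   `diff`, `rank_diff`; plus `sums` and the call parameters.
#' @export
efast_run <- function(f, dists, M = 4, omega_max = 416, seed = 1,
                      n_repeats = 1, allow_cycling = FALSE) {
  m <- length(dists)
  nms <- vapply(dists, function(d) d$variable, "")
  degen <- vapply(dists, function(d) d$family == "degenerate", TRUE)
  SF <- matrix(0, n_repeats, m); ST <- matrix(0, n_repeats, m)
  for (r in seq_len(n_repeats)) {
    des <- efast_design(dists, M, omega_max, seed = seed + r - 1,
                        allow_cycling = allow_cycling)
    for (i in seq_len(m)) {
      if (degen[i]) next  # constant input cannot drive the output
      y <- f(des$blocks[[i]])
      SF[r, i] <- efast_first_order(y, omega_max, M)
      ST[r, i] <- efast_total(y, omega_max, M)
    }
  }
  sf <- colMeans(SF); st <- colMeans(ST)
  sf_sd <- apply(SF, 2, stats::sd); st_sd <- apply(ST, 2, stats::sd)
  dif <- st - sf
  tab <- data.frame(variable = nms, S_F = sf, S_F_sd = sf_sd,
                    rank_SF = rank_desc(sf), S_T = st, S_T_sd = st_sd,
                    rank_ST = rank_desc(st), diff = dif,
                    rank_diff = rank_desc(dif, ties = "first"))
  structure(list(table = tab,
                 sums = c(S_F = sum(sf), S_T = sum(st), diff = sum(dif)),
                 M = M, omega_max = omega_max, n_repeats = n_repeats,
                 Ns = 2 * M * omega_max + 1),
            class = "efast_result")
}

#' Global sensitivity analysis of a fitted suitability model
#'
#' The whole-model workflow: fit marginal distributions from the stack (or
#' take them as given), sample every factor independently along the eFAST
#' search curves, evaluate the model's cloglog suitability on each design row,
#' and estimate per-variable first-order and total indices with their
#' interaction difference `S_T - S_F`. Repeats with different phase seeds give
#' the spread columns.
#'
#' @param model A fitted [maxent()] (or any object with a compatible
#'   `predict` method).
#' @param stack An [env_stack()] supplying the input distributions.
#' @param region_mask Optional extra mask for [fit_distributions()].
#' @param dists Optional precomputed distribution specs.
#' @param M,omega_max,allow_cycling,seed,n_repeats As in [efast_run()].
#' @return An `efast_result`.
#' @export
efast_gsa <- function(model, stack, region_mask = NULL, dists = NULL,
                      M = 4, omega_max = 416, seed = 1, n_repeats = 5,
                      allow_cycling = FALSE) {
  if (is.null(dists))
    dists <- fit_distributions(stack, region_mask)
  efast_run(function(X) predict(model, X, type = "cloglog"),
            dists, M = M, omega_max = omega_max, seed = seed,
            n_repeats = n_repeats, allow_cycling = allow_cycling)
}

#' Interaction effect per variable
#'
#' The elementwise difference `S_T - S_F`, the variance share a variable
#' contributes only through interactions, with descending ranks (ties broken
#' by variable order).
#'
#' @param result An `efast_result`, or a data.frame with columns `variable`,
#'   `S_F`, `S_T` (e.g. a published sensitivity table).
#' @return data.frame with `variable`, `diff`, `rank`.
#' @export
interaction_effect <- function(result) {
  tab <- if (inherits(result, "efast_result")) result$table else result
  dif <- tab$S_T - tab$S_F
  data.frame(variable = tab$variable, diff = dif,
             rank = rank_desc(dif, ties = "first"))
}

#' @export
print.efast_result <- function(x, ...) {
  tab <- x$table
  cat(sprintf("eFAST sensitivity (M = %d, omega_max = %d, Ns = %d, %d repeat%s)\n",
              x$M, x$omega_max, x$Ns, x$n_repeats,
              if (x$n_repeats > 1) "s" else ""))
  show <- data.frame(variable = tab$variable,
                     S_F = sprintf("%.4f (%.4f)", tab$S_F, tab$S_F_sd),
                     rank = tab$rank_SF,
                     S_T = sprintf("%.4f (%.4f)", tab$S_T, tab$S_T_sd),
                     rank = tab$rank_ST,
                     diff = sprintf("%.4f", tab$diff),
                     rank = tab$rank_diff, check.names = FALSE)
  print(show, row.names = FALSE)
  cat(sprintf("Sum: S_F %.4f, S_T %.4f, diff %.4f\n",
              x$sums["S_F"], x$sums["S_T"], x$sums["diff"]))
  invisible(x)
}

#' @export
as.data.frame.efast_result <- function(x, ...) x$table
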