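# Presence-only maximum-entropy niche model: a Gibbs distribution over
# background cells, exp(lambda . f(x) - logZ), fitted by minimizing the
# L1-penalized log loss
#   -(1/np) sum_presence lambda . f(x_i) + log Z_bg(lambda) + sum_j beta_j |lambda_j|
# (convex), with linear / quadratic / hinge features on continuous layers and
# level indicators on categorical layers, all scaled to [0,1] on the training
# background.

#' MaxEnt run configuration
#'
#' @param rm Regularization multiplier (> 0); scales all feature penalties.
#' @param fc Feature classes, a subset of `c("L","Q","H")` (categorical layers
#'   always get indicators).
#' @param n_background Background sample size.
#' @param max_iter Maximum optimizer iterations.
#' @param convergence Stop when the objective decrease falls below this.
#' @param tau Prevalence used by the optional logistic output.
#' @param n_hinge_knots Hinge knots per direction per continuous layer.
#' @param seed Seed for background sampling in high-level wrappers.
#' @return List of class `maxent_config`.
#' @export
maxent_config <- function(rm = 1, fc = c("L", "Q", "H"),
                          n_background = 10000, max_iter = 1000,
                          convergence = 1e-5, tau = 0.5,
                          n_hinge_knots = 50, seed = 1) {
  stopifnot(rm > 0, all(fc %in% c("L", "Q", "H")),
            n_background >= 1, max_iter >= 1, convergence > 0,
            tau > 0, tau < 1, n_hinge_knots >= 1)
  structure(list(rm = rm, fc = fc, n_background = n_background,
                 max_iter = max_iter, convergence = convergence, tau = tau,
                 n_hinge_knots = n_hinge_knots, seed = seed),
            class = "maxent_config")
}

#' Sample background (pseudo-absence) cells from a stack
#'
#' Draws `n` distinct unmasked cells uniformly without replacement; if fewer
#' than `n` unmasked cells exist, all are taken (with a message).
#'
#' @param stack An [env_stack()].
#' @param n Number of background cells.
#' @param seed Integer seed.
#' @return data.frame with `row`, `col` and one column per layer.
#' @export
sample_background <- function(stack, n, seed = 1) {
  idx <- which(!stack$mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no unmasked cells to sample background from")
  set.seed(seed)
  if (n >= nrow(idx)) {
    if (n > nrow(idx))
      message("requested ", n, " background points but only ", nrow(idx),
              " unmasked cells; taking all")
    pick <- seq_len(nrow(idx))
  } else {
    pick <- sample.int(nrow(idx), n)
  }
  stack_table(stack, data.frame(row = idx[pick, 1], col = idx[pick, 2]))
}

drop_cell_cols <- function(d) d[, setdiff(names(d), c("row", "col")), drop = FALSE]

#' Build feature definitions from a training background table
#'
#' Scaling constants (per-layer min/max) come from the background; all feature
#' values lie in \[0,1\] on training data. Constant layers are skipped with a
#' warning; hinge knots are placed strictly inside the training range.
#'
#' @param background data.frame of layer values (training background).
#' @param kinds Named character vector `"continuous"`/`"categorical"` per
#'   layer; defaults to categorical for `Drainage`/`Tclass`.
#' @param fc Feature classes (subset of L, Q, H).
#' @param n_hinge_knots Knots per direction per continuous layer.
#' @return List of class `feature_defs`.
#' @export
make_feature_defs <- function(background, kinds = NULL,
                              fc = c("L", "Q", "H"), n_hinge_knots = 50) {
  background <- drop_cell_cols(background)
  nms <- names(background)
  if (is.null(kinds)) {
    kinds <- ifelse(nms %in% CATEGORICAL_LAYERS, "categorical", "continuous")
    names(kinds) <- nms
  }
  defs <- list()
  for (nm in nms) {
    x <- background[[nm]]
    if (kinds[[nm]] == "categorical") {
      for (lev in sort(unique(x)))
        defs[[length(defs) + 1L]] <- list(kind = "indicator", layer = nm,
                                          level = lev)
      next
    }
    lo <- min(x); hi <- max(x)
    if (hi <= lo) {
      warning("layer ", nm, " is constant on the background; skipped")
      next
    }
    if ("L" %in% fc)
      defs[[length(defs) + 1L]] <- list(kind = "linear", layer = nm,
                                        lo = lo, hi = hi)
    if ("Q" %in% fc)
      defs[[length(defs) + 1L]] <- list(kind = "quadratic", layer = nm,
                                        lo = lo, hi = hi)
    if ("H" %in% fc) {
      knots <- seq(lo, hi, length.out = n_hinge_knots + 2L)
      knots <- knots[-c(1L, n_hinge_knots + 2L)]
      knots <- knots[knots > lo & knots < hi]  # degenerate-range guard
      for (k in knots) {
        defs[[length(defs) + 1L]] <- list(kind = "forward_hinge", layer = nm,
                                          knot = k, lo = lo, hi = hi)
        defs[[length(defs) + 1L]] <- list(kind = "reverse_hinge", layer = nm,
                                          knot = k, lo = lo, hi = hi)
      }
    }
  }
  structure(defs, class = "feature_defs")
}

feature_names <- function(defs) {
  vapply(defs, function(d) switch(d$kind,
    linear = d$layer,
    quadratic = paste0(d$layer, "^2"),
    forward_hinge = sprintf("h(%s>%.6g)", d$layer, d$knot),
    reverse_hinge = sprintf("h(%s<%.6g)", d$layer, d$knot),
    indicator = sprintf("%s==%g", d$layer, d$level)), "")
}

#' Evaluate a feature matrix for a table of layer values
#'
#' Continuous layers are clamped to the training range before feature
#' evaluation (standard MaxEnt projection behaviour), so all features stay in
#' \[0,1\].
#'
#' @param defs A [make_feature_defs()] result.
#' @param table data.frame of layer values.
#' @param clamp Clamp values to the training range (default TRUE).
#' @return Numeric matrix, one column per feature.
#' @export
feature_matrix <- function(defs, table, clamp = TRUE) {
  table <- drop_cell_cols(table)
  n <- nrow(table)
  out <- matrix(0, n, length(defs))
  for (j in seq_along(defs)) {
    d <- defs[[j]]
    x <- table[[d$layer]]
    if (is.null(x)) stop("table lacks layer ", d$layer)
    if (d$kind == "indicator") {
      out[, j] <- as.numeric(x == d$level)
      next
    }
    if (clamp) x <- pmin(pmax(x, d$lo), d$hi)
    out[, j] <- switch(d$kind,
      linear = (x - d$lo) / (d$hi - d$lo),
      quadratic = ((x - d$lo) / (d$hi - d$lo))^2,
      forward_hinge = pmax(0, (x - d$knot) / (d$hi - d$knot)),
      reverse_hinge = pmax(0, (d$knot - x) / (d$knot - d$lo)))
  }
  colnames(out) <- feature_names(defs)
  out
}

logsumexp <- function(s) {
  m <- max(s)
  m + log(sum(exp(s - m)))
}

# Penalized objective and pieces; Fp/Fb are presence/background feature
# matrices.
maxent_objective <- function(lambda, Fp, Fb, beta) {
  -mean(Fp %*% lambda) + logsumexp(Fb %*% lambda) + sum(beta * abs(lambda))
}

soft_threshold <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

#' Fit a maximum-entropy presence-only model
#'
#' The fitting function of the package. Takes presence and background tables
#' of raw layer values, builds the [0,1]-scaled feature space from the
#' background, and minimizes the L1-penalized MaxEnt log loss with an
#' accelerated proximal-gradient (FISTA) scheme with backtracking line search
#' and momentum restarts. Per-feature penalties default to
#' `beta_j = rm * sqrt(var_j / np)` with `var_j` the feature variance over the
#' presences and `np` the presence count.
#'
#' @param presence data.frame of layer values at presence records (at least 2).
#' @param background data.frame of layer values at background cells.
#' @param config A [maxent_config()].
#' @param kinds Layer kinds as in [make_feature_defs()].
#' @param defs Optional precomputed [make_feature_defs()]; built from the
#'   background otherwise.
#' @param start Optional starting coefficient vector.
#' @return Object of class `maxent` with elements `defs`, `lambda`, `beta`,
#'   `logZ`, `entropy`, `objective`, `converged`, `iterations`, `config`.
#' @seealso [predict.maxent()], [cross_validate()], [tune_maxent()]
#' @export
maxent <- function(presence, background, config = maxent_config(),
                   kinds = NULL, defs = NULL, start = NULL) {
  presence <- drop_cell_cols(presence)
  background <- drop_cell_cols(background)
  if (nrow(presence) < 2) stop("need at least 2 presence records")
  if (is.null(defs))
    defs <- make_feature_defs(background, kinds = kinds, fc = config$fc,
                              n_hinge_knots = config$n_hinge_knots)
  Fp <- feature_matrix(defs, presence)
  Fb <- feature_matrix(defs, background, clamp = FALSE)
  if (any(!is.finite(Fp)) || any(!is.finite(Fb)))
    stop("non-finite feature values")
  np <- nrow(Fp)
  v <- apply(Fp, 2, stats::var)
  beta <- config$rm * sqrt(pmax(v, 1e-4) / np)

  J <- ncol(Fp)
  lambda <- if (is.null(start)) rep(0, J) else as.numeric(start)
  fp_mean <- colMeans(Fp)
  smooth <- function(l) -sum(fp_mean * l) + logsumexp(Fb %*% l)
  grad <- function(l) {
    s <- as.numeric(Fb %*% l)
    q <- exp(s - logsumexp(s))
    as.numeric(crossprod(Fb, q)) - fp_mean
  }

  obj_old <- smooth(lambda) + sum(beta * abs(lambda))
  y <- lambda; t_mom <- 1; step <- 1
  converged <- FALSE; it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    gy <- grad(y); fy <- smooth(y)
    repeat {  # backtracking on the smooth majorizer
      cand <- soft_threshold(y - step * gy, step * beta)
      dlt <- cand - y
      if (smooth(cand) <= fy + sum(gy * dlt) + sum(dlt^2) / (2 * step) + 1e-12)
        break
      step <- step / 2
      if (step < 1e-12) break
    }
    obj_new <- smooth(cand) + sum(beta * abs(cand))
    if (obj_new > obj_old) {  # momentum restart keeps the sequence monotone
      y <- lambda; t_mom <- 1
      cand <- soft_threshold(y - step * grad(y), step * beta)
      obj_new <- smooth(cand) + sum(beta * abs(cand))
      if (obj_new > obj_old) { converged <- TRUE; break }
    }
    t_new <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
    y <- cand + ((t_mom - 1) / t_new) * (cand - lambda)
    lambda <- cand; t_mom <- t_new
    if (obj_old - obj_new < config$convergence &&
        obj_old - obj_new >= 0) { converged <- TRUE; obj_old <- obj_new; break }
    obj_old <- obj_new
    step <- step * 2  # let the step grow back
  }

  sb <- as.numeric(Fb %*% lambda)
  logZ <- logsumexp(sb)
  q <- exp(sb - logZ)
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  names(lambda) <- colnames(Fp)
  structure(list(defs = defs, lambda = lambda, beta = beta, logZ = logZ,
                 entropy = H, objective = obj_old, converged = converged,
                 iterations = it, np = np, nb = nrow(Fb), config = config),
            class = "maxent")
}

#' @export
print.maxent <- function(x, ...) {
  cat(sprintf("maxent model: %d features (%d nonzero), rm = %g, fc = %s\n",
              length(x$lambda), sum(x$lambda != 0), x$config$rm,
              paste(x$config$fc, collapse = "")))
  cat(sprintf("  presences %d, background %d; entropy %.4f nats; %s in %d iter\n",
              x$np, x$nb, x$entropy,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' @export
summary.maxent <- function(object, ...) {
  nz <- object$lambda[object$lambda != 0]
  out <- list(model = object,
              nonzero = nz[order(-abs(nz))],
              aic_k = sum(object$lambda != 0))
  class(out) <- "summary.maxent"
  out
}

#' @export
print.summary.maxent <- function(x, ...) {
  print(x$model)
  cat("nonzero coefficients:\n")
  print(round(x$nonzero, 4))
  invisible(x)
}

#' @export
coef.maxent <- function(object, ...) object$lambda

#' Predict suitability from a fitted maxent model
#'
#' `raw` is the Gibbs probability `exp(lambda . f(x) - logZ)` (sums to 1 over
#' the training background); `cloglog` is `1 - exp(-exp(H) * raw)` with `H`
#' the entropy of the raw training distribution; `logistic` is the
#' prevalence-tau logistic transform `c*raw/(1+c*raw)`,
#' `c = exp(H)*tau/(1-tau)`.
#'
#' @param object A fitted [maxent()] model.
#' @param newdata data.frame of layer values.
#' @param type One of `"cloglog"`, `"raw"`, `"logistic"`, `"link"`.
#' @param clamp Clamp features to the training range (default TRUE).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.maxent <- function(object, newdata,
                           type = c("cloglog", "raw", "logistic", "link"),
                           clamp = TRUE, ...) {
  type <- match.arg(type)
  FX <- feature_matrix(object$defs, newdata, clamp = clamp)
  link <- as.numeric(FX %*% object$lambda) - object$logZ
  if (type == "link") return(link)
  raw <- exp(link)
  switch(type,
         raw = raw,
         cloglog = 1 - exp(-exp(object$entropy) * raw),
         logistic = {
           cc <- exp(object$entropy) * object$config$tau / (1 - object$config$tau)
           cc * raw / (1 + cc * raw)
         })
}

#' Predict a suitability map over a stack
#'
#' @param model A fitted [maxent()].
#' @param stack An [env_stack()].
#' @param type Passed to [predict.maxent()].
#' @return Matrix of predictions; NA on masked cells.
#' @export
predict_stack <- function(model, stack, type = "cloglog") {
  tab <- stack_table(stack)
  p <- predict(model, tab, type = type)
  out <- matrix(NA_real_, stack$grid$nrows, stack$grid$ncols)
  out[cbind(tab$row, tab$col)] <- p
  out
}

#' Suitability map as a plot
#' @param x A fitted [maxent()].
#' @param stack An [env_stack()] to predict over.
#' @param ... Passed to [graphics::image()].
#' @export
plot.maxent <- function(x, stack, ...) {
  m <- predict_stack(x, stack)
  graphics::image(t(m), useRaster = TRUE,
                  main = "predicted suitability (cloglog)", ...)
  invisible(x)
}

#' Serialize / load a fitted model as JSON
#'
#' A readable analogue of MaxEnt's lambdas file: feature definitions,
#' coefficients, penalties, normalizer and entropy.
#'
#' @param model A fitted [maxent()].
#' @param path Output JSON path.
#' @return `read_maxent` returns the restored `maxent` object.
#' @export
write_maxent <- function(model, path) {
  payload <- list(
    features = lapply(model$defs, function(d) d[!vapply(d, is.null, TRUE)]),
    lambda = unname(model$lambda), beta = unname(model$beta),
    logZ = model$logZ, entropy = model$entropy,
    objective = model$objective, converged = model$converged,
    iterations = model$iterations, np = model$np, nb = model$nb,
    config = unclass(model$config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maxent
#' @export
read_maxent <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  defs <- structure(lapply(p$features, function(d) d), class = "feature_defs")
  cfg <- p$config
  cfg$fc <- unlist(cfg$fc)
  config <- do.call(maxent_config, cfg)
  lambda <- unlist(p$lambda)
  names(lambda) <- feature_names(defs)
  structure(list(defs = defs, lambda = lambda, beta = unlist(p$beta),
                 logZ = p$logZ, entropy = p$entropy, objective = p$objective,
                 converged = p$converged, iterations = p$iterations,
                 np = p$np, nb = p$nb, config = config),
            class = "maxent")
}

#' k-fold cross-validation of a maxent model
#'
#' Partitions presences into `k` folds by a seeded shuffle (fold sizes differ
#' by at most one), trains on the remaining presences against the shared
#' background, and evaluates each held-out fold: test AUC (cloglog scores vs
#' background) and TSS at the training MTSS threshold.
#'
#' @param presence data.frame of presence layer values.
#' @param background data.frame of background layer values (shared across
#'   folds).
#' @param config A [maxent_config()].
#' @param k Number of folds (<= number of presences).
#' @param seed Shuffle seed.
#' @return List of class `maxent_cv`: per-fold metrics data.frame `folds`,
#'   `mean_auc`, `sd_auc`, `mean_tss`.
#' @export
cross_validate <- function(presence, background, config = maxent_config(),
                           k = 10, seed = 1) {
  presence <- drop_cell_cols(presence)
  background <- drop_cell_cols(background)
  n <- nrow(presence)
  if (k > n) stop("k exceeds the number of presences")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  res <- data.frame(fold = seq_len(k), n_test = NA_real_,
                    auc = NA_real_, tss = NA_real_)
  for (f in seq_len(k)) {
    tr <- presence[fold != f, , drop = FALSE]
    te <- presence[fold == f, , drop = FALSE]
    m <- maxent(tr, background, config)
    s_tr <- predict(m, tr); s_bg <- predict(m, background)
    s_te <- predict(m, te)
    thr <- habitat_thresholds(s_tr, s_bg)
    cm <- confusion_at(thr$mtss, s_te, s_bg)
    res$n_test[f] <- nrow(te)
    res$auc[f] <- auc_score(s_te, s_bg)
    res$tss[f] <- cm$tss
  }
  structure(list(folds = res, mean_auc = mean(res$auc),
                 sd_auc = stats::sd(res$auc), mean_tss = mean(res$tss),
                 k = k),
            class = "maxent_cv")
}

#' @export
print.maxent_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: mean test AUC %.3f (sd %.3f), mean TSS %.3f\n",
              x$k, x$mean_auc, x$sd_auc, x$mean_tss))
  invisible(x)
}
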