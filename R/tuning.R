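# Predictor screening, AICc tuning over the RM x FC grid, and
# threshold-dependent / independent evaluation (AUC, TSS, threshold rules).

#' Spearman collinearity screen
#'
#' Iteratively removes variables from highly correlated pairs: among retained
#' variables, find the pair with the largest |rho| that exceeds both the
#' correlation and significance thresholds, drop the member with the larger
#' mean |rho| against all other retained variables, and repeat until no
#' offending pair remains. Constant columns cannot be tested and are flagged.
#'
#' @param table data.frame of numeric variables (>= 3 rows).
#' @param r_thresh Absolute Spearman rho threshold.
#' @param p_thresh Significance threshold.
#' @return List of class `screening_report`: `retained`, `dropped`
#'   (data.frame with reasons), `rho` and `p` matrices on the input variables.
#' @export
spearman_screen <- function(table, r_thresh = 0.8, p_thresh = 0.001) {
  table <- drop_cell_cols(table)
  if (nrow(table) < 3) stop("need at least 3 rows")
  nms <- names(table)
  const <- vapply(table, function(x) stats::sd(x) == 0, TRUE)
  dropped <- data.frame(variable = character(), reason = character())
  if (any(const))
    dropped <- rbind(dropped,
                     data.frame(variable = nms[const],
                                reason = "constant column: rho undefined"))
  vars <- nms[!const]
  p0 <- length(vars)
  rho <- matrix(NA_real_, p0, p0, dimnames = list(vars, vars))
  pv <- rho
  for (i in seq_len(p0)) for (j in seq_len(p0)) {
    if (i >= j) next
    ct <- suppressWarnings(
      stats::cor.test(table[[vars[i]]], table[[vars[j]]],
                      method = "spearman", exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  diag(rho) <- 1; diag(pv) <- 0
  retained <- vars
  repeat {
    if (length(retained) < 2) break
    r <- abs(rho[retained, retained, drop = FALSE])
    p <- pv[retained, retained, drop = FALSE]
    offend <- r > r_thresh & p < p_thresh
    diag(offend) <- FALSE
    if (!any(offend)) break
    r_off <- r; r_off[!offend] <- -Inf
    ij <- which(r_off == max(r_off), arr.ind = TRUE)[1, ]
    pair <- retained[ij]
    # drop the member more correlated, on average, with everything else
    mean_abs <- function(v) mean(r[v, setdiff(retained, v)])
    drop_var <- if (mean_abs(pair[1]) >= mean_abs(pair[2])) pair[1] else pair[2]
    other <- setdiff(pair, drop_var)
    dropped <- rbind(dropped, data.frame(
      variable = drop_var,
      reason = sprintf("|rho|=%.3f with %s (p=%.2g)",
                       r[pair[1], pair[2]], other, p[pair[1], pair[2]])))
    retained <- setdiff(retained, drop_var)
  }
  structure(list(retained = retained, dropped = dropped, rho = rho, p = pv),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("spearman screen:", length(x$retained), "retained,",
      nrow(x$dropped), "dropped\n")
  if (nrow(x$dropped)) print(x$dropped, row.names = FALSE)
  invisible(x)
}

#' Shadow-feature importance screen
#'
#' A simplified shadow-feature (Boruta-style) procedure: in each round, a
#' permuted copy of every column is appended, a random-forest classifier
#' (presence vs background) is fitted, and a real column scores a hit when its
#' importance exceeds the maximum shadow importance. A variable is confirmed
#' when its hit count is significantly above the fair-coin null (one-sided
#' binomial test at `alpha`).
#'
#' @param table data.frame of predictors.
#' @param labels Binary labels (presence = 1 / background = 0), both classes
#'   present.
#' @param seed Integer seed (whole procedure is deterministic given it).
#' @param n_rounds Number of permutation rounds.
#' @param alpha Confirmation significance level.
#' @param num_trees Trees per forest.
#' @return Character vector of confirmed (retained) variables, with the
#'   per-variable hit counts as attribute `hits`.
#' @export
shadow_screen <- function(table, labels, seed = 1, n_rounds = 20,
                          alpha = 0.01, num_trees = 200) {
  table <- drop_cell_cols(table)
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must contain exactly two classes")
  nms <- names(table)
  set.seed(seed)
  hits <- setNames(integer(length(nms)), nms)
  for (r in seq_len(n_rounds)) {
    shadow <- as.data.frame(lapply(table, sample))
    names(shadow) <- paste0("shadow_", nms)
    d <- cbind(table, shadow, .y = y)
    fit <- ranger::ranger(dependent.variable.name = ".y", data = d,
                          num.trees = num_trees, importance = "impurity",
                          seed = seed * 1000 + r, num.threads = 1,
                          verbose = FALSE)
    imp <- fit$variable.importance
    max_shadow <- max(imp[paste0("shadow_", nms)])
    hits <- hits + as.integer(imp[nms] > max_shadow)
  }
  pvals <- vapply(hits, function(h)
    stats::binom.test(h, n_rounds, p = 0.5,
                      alternative = "greater")$p.value, 0)
  retained <- nms[pvals < alpha]
  attr(retained, "hits") <- hits
  retained
}

#' Corrected Akaike information criterion of a maxent fit
#'
#' `lnL` is the sum over presences of the log raw (background-normalized)
#' score; `k` is the number of nonzero coefficients.
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)`, undefined (`Inf`) when
#' `n - k - 1 <= 0`.
#'
#' @param model A fitted [maxent()].
#' @param presence data.frame of presence layer values.
#' @return Numeric AICc with attributes `k` and `lnL`.
#' @export
aicc <- function(model, presence) {
  k <- sum(model$lambda != 0)
  n <- nrow(presence)
  lnL <- sum(predict(model, presence, type = "link"))
  val <- if (n - k - 1 <= 0) Inf else 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
  attr(val, "k") <- k
  attr(val, "lnL") <- lnL
  val
}

#' AICc tuning over a regularization-multiplier x feature-class grid
#'
#' Fits every `(rm, fc)` combination on the full data and returns the AICc
#' table and the argmin model. Ties break toward fewer nonzero coefficients,
#' then smaller rm, then the order of `fc_list`.
#'
#' @param presence,background data.frames of layer values.
#' @param rm_list Numeric vector of regularization multipliers.
#' @param fc_list Character vector of feature-class combinations, e.g.
#'   `c("L","LQ","LQH")`.
#' @param config Base [maxent_config()] supplying the remaining settings.
#' @return List of class `tuning_result`: `table` (rm, fc, k, lnL, aicc),
#'   `best` (row index), `best_model`.
#' @export
tune_maxent <- function(presence, background, rm_list = 1:4,
                        fc_list = c("L", "LQ", "LQH"),
                        config = maxent_config()) {
  if (!length(rm_list) || !length(fc_list))
    stop("tuning grid is empty (rm_list / fc_list)")
  rows <- expand.grid(fc = fc_list, rm = rm_list,
                      stringsAsFactors = FALSE)[, c("rm", "fc")]
  rows <- rows[order(match(rows$rm, rm_list), match(rows$fc, fc_list)), ]
  tab <- data.frame(rm = rows$rm, fc = rows$fc, k = NA_real_,
                    lnL = NA_real_, aicc = NA_real_)
  models <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cfg <- config
    cfg$rm <- tab$rm[i]
    cfg$fc <- strsplit(tab$fc[i], "")[[1]]
    m <- maxent(presence, background, cfg)
    a <- aicc(m, presence)
    tab$k[i] <- attr(a, "k"); tab$lnL[i] <- attr(a, "lnL")
    tab$aicc[i] <- as.numeric(a)
    models[[i]] <- m
  }
  if (all(!is.finite(tab$aicc)))
    stop("AICc undefined for every combination (n - k - 1 <= 0 throughout)")
  ord <- order(tab$aicc, tab$k, match(tab$rm, rm_list),
               match(tab$fc, fc_list))
  best <- ord[1]
  structure(list(table = tab, best = best, best_model = models[[best]]),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  tab <- x$table
  tab$aicc <- round(tab$aicc, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("best: rm = %g, fc = %s (AICc %.2f)\n",
              tab$rm[x$best], tab$fc[x$best], tab$aicc[x$best]))
  invisible(x)
}

#' Rank-based AUC
#'
#' Probability that a random presence score exceeds a random background score,
#' ties counting one half (equivalent to the Mann-Whitney statistic).
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (!np || !nb) stop("both score vectors must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Confusion metrics at a threshold
#'
#' Sensitivity = fraction of presence scores >= threshold; specificity =
#' fraction of background scores < threshold; TSS = sensitivity +
#' specificity - 1.
#'
#' @param threshold Score threshold.
#' @param presence_scores,background_scores Numeric score vectors.
#' @return List with `sensitivity`, `specificity`, `tss`.
#' @export
confusion_at <- function(threshold, presence_scores, background_scores) {
  sens <- mean(presence_scores >= threshold)
  spec <- mean(background_scores < threshold)
  list(sensitivity = sens, specificity = spec, tss = sens + spec - 1)
}

#' Threshold rules and the TSS-weighted average threshold
#'
#' Three standard binarization rules on cloglog scores:
#' * MTSS — maximum training sensitivity plus specificity: the candidate
#'   threshold (an observed score) maximizing sens + spec, smallest on ties;
#' * PTSS — 10% training presence: the 10th percentile of presence scores
#'   (linear interpolation);
#' * ETSS — equal training sensitivity and specificity: candidate minimizing
#'   |sens - spec|, smallest on ties.
#'
#' The combined threshold is the TSS-weighted average
#' `sum(t_r * TSS_r) / sum(TSS_r)`; when every rule's TSS is <= 0 it falls
#' back to the unweighted mean (flagged).
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @param ptss_quantile Presence-score quantile for the PTSS rule.
#' @param weighting `"tss"` (default) or `"mean"`.
#' @return List of class `threshold_set`: `mtss`, `ptss`, `etss`, their
#'   `tss` values, `weighted`, and `fallback` flag.
#' @export
habitat_thresholds <- function(presence_scores, background_scores,
                               ptss_quantile = 0.1, weighting = "tss") {
  if (!length(presence_scores) || !length(background_scores))
    stop("scores must be non-empty")
  cand <- sort(unique(c(presence_scores, background_scores)))
  sens <- vapply(cand, function(t) mean(presence_scores >= t), 0)
  spec <- vapply(cand, function(t) mean(background_scores < t), 0)
  tss <- sens + spec - 1
  mtss <- cand[which.max(tss)]  # which.max takes the first (smallest) maximizer
  etss <- cand[which.min(abs(sens - spec))]
  ptss <- unname(stats::quantile(presence_scores, ptss_quantile, type = 7))
  t3 <- c(mtss = mtss, ptss = ptss, etss = etss)
  tss3 <- vapply(t3, function(t)
    confusion_at(t, presence_scores, background_scores)$tss, 0)
  w <- weighted_threshold(t3, tss3, weighting)
  structure(list(mtss = unname(t3["mtss"]), ptss = unname(t3["ptss"]),
                 etss = unname(t3["etss"]), tss = tss3,
                 weighted = w, fallback = attr(w, "fallback")),
            class = "threshold_set")
}

#' TSS-weighted combination of rule thresholds
#'
#' `sum(t_r * TSS_r) / sum(TSS_r)`; when the TSS sum is not positive the
#' unweighted mean is returned with attribute `fallback = TRUE`.
#'
#' @param thresholds Numeric vector of rule thresholds.
#' @param tss Their TSS values.
#' @param weighting `"tss"` or `"mean"`.
#' @return The combined threshold (always within `[min, max]` of the inputs).
#' @export
weighted_threshold <- function(thresholds, tss, weighting = "tss") {
  stopifnot(length(thresholds) == length(tss))
  fallback <- FALSE
  if (weighting == "tss" && sum(tss) > 0) {
    w <- sum(thresholds * tss) / sum(tss)
  } else {
    if (weighting == "tss") fallback <- TRUE
    w <- mean(thresholds)
  }
  attr(w, "fallback") <- fallback
  w
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("thresholds: MTSS %.4f (TSS %.3f), PTSS %.4f (TSS %.3f), ETSS %.4f (TSS %.3f)\n",
              x$mtss, x$tss["mtss"], x$ptss, x$tss["ptss"],
              x$etss, x$tss["etss"]))
  cat(sprintf("  weighted average threshold: %.4f%s\n", x$weighted,
              if (x$fallback) " (unweighted fallback: all TSS <= 0)" else ""))
  invisible(x)
}
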