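# Synthetic coastal landscape: autocorrelated environmental fields on a grid
# with a sea edge at the western (col 1) side, an elevation ramp rising
# landward, and future scenarios built by climate offsets and/or a uniform
# sea-level rise that inundates (masks) cells dropping below 0 m.

# Gaussian-kernel smoothing with reflecting edges; length = kernel sd in cells.
smooth_field <- function(m, length) {
  if (length <= 0) return(m)
  half <- max(1L, ceiling(3 * length))
  k <- stats::dnorm(seq(-half, half), sd = length)
  k <- k / sum(k)
  reflect_idx <- function(j, n) {
    # fold any integer into 1..n by reflection at both edges
    j <- (j - 1L) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  conv1 <- function(v) {
    n <- length(v)
    vp <- v[reflect_idx(seq(1L - half, n + half), n)]
    stats::filter(vp, k, sides = 2)[(half + 1L):(half + n)]
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

rescale_range <- function(m, lo, hi) {
  rng <- range(m)
  if (diff(rng) == 0) return(matrix(lo, nrow(m), ncol(m)))
  lo + (m - rng[1]) / diff(rng) * (hi - lo)
}

# Realistic default ranges for the 7 bioclimatic + 5 continuous soil layers.
default_layer_ranges <- function() {
  list(Bio02 = c(4, 14),      # mean diurnal range, degC
       Bio03 = c(20, 40),     # isothermality, %
       Bio05 = c(22, 36),     # max temp warmest month, degC
       Bio08 = c(2, 28),      # mean temp wettest quarter, degC
       Bio14 = c(0, 60),      # precip driest month, mm
       Bio15 = c(30, 110),    # precip seasonality, CV
       Bio19 = c(10, 400),    # precip coldest quarter, mm
       Tece = c(0, 8),        # electrical conductivity, dS/m
       Tgravel = c(0, 30),    # volume % gravel
       Toc = c(0.2, 4),       # % organic carbon
       Tph = c(4.5, 9),       # pH
       Tsand = c(20, 90))     # % sand
}

#' Generate a synthetic coastal environmental stack
#'
#' Builds 15 co-registered layers — 7 continuous bioclimatic, 6 soil (of which
#' `Drainage` and `Tclass` are categorical) and `Elevation` — on the given
#' grid. Continuous layers are spatially autocorrelated fields (Gaussian-kernel
#' smoothed white noise) rescaled to realistic ranges; categorical layers are
#' smoothed fields cut into `n_categories` levels; elevation is a linear ramp
#' from `elev_range[1]` at the western (sea-side, column 1) edge to
#' `elev_range[2]` at the landward edge plus smoothed noise. Cells with
#' elevation below 0 are masked as sea.
#'
#' @param grid A [grid_spec()] (default 100 x 200 cells of 1 km).
#' @param autocorr Autocorrelation length in cells (Gaussian kernel sd);
#'   0 gives i.i.d. noise.
#' @param ranges Named list of `c(min, max)` per continuous non-elevation
#'   layer; defaults cover all 12.
#' @param elev_range Elevation ramp endpoints in metres, sea edge to landward
#'   edge.
#' @param elev_noise_sd Sd (m) of the smoothed noise added to the ramp.
#' @param n_categories Number of levels for each categorical soil layer.
#' @param seed Integer seed; identical seeds give bit-identical stacks.
#' @return An [env_stack()] of 15 layers.
#' @export
synth_landscape <- function(grid = grid_spec(100, 200, 1),
                            autocorr = 6,
                            ranges = default_layer_ranges(),
                            elev_range = c(-2, 20),
                            elev_noise_sd = 1,
                            n_categories = 4,
                            seed = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  set.seed(seed)
  nr <- grid$nrows; nc <- grid$ncols
  field <- function() {
    f <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), autocorr)
    matrix(f, nr, nc)
  }
  layers <- list()
  for (nm in setdiff(STACK_LAYERS, c(CATEGORICAL_LAYERS, "Elevation"))) {
    r <- ranges[[nm]]
    if (is.null(r)) r <- c(0, 1)
    layers[[nm]] <- rescale_range(field(), r[1], r[2])
  }
  for (nm in CATEGORICAL_LAYERS) {
    f <- field()
    br <- stats::quantile(f, probs = seq(0, 1, length.out = n_categories + 1))
    br[1] <- -Inf; br[n_categories + 1] <- Inf
    layers[[nm]] <- matrix(as.numeric(cut(f, br, labels = FALSE)), nr, nc)
  }
  ramp <- matrix(rep(seq(elev_range[1], elev_range[2], length.out = nc),
                     each = nr), nr, nc)
  noise <- if (elev_noise_sd > 0) {
    f <- field()
    f <- f - mean(f)
    s <- stats::sd(f)
    if (s > 0) f / s * elev_noise_sd else f
  } else matrix(0, nr, nc)
  layers$Elevation <- ramp + noise
  layers <- layers[STACK_LAYERS]
  mask <- layers$Elevation < 0
  env_stack(grid, layers, mask)
}

climate_layer_names <- function(stack)
  grep("^Bio", names(stack$layers), value = TRUE)

#' Apply climate-change offsets/scales to a stack
#'
#' Returns a stack identical to the input except in the named bioclimatic
#' layers, each transformed cellwise as `scale * value + offset`. Deltas on
#' non-climate layers are rejected.
#'
#' @param stack An [env_stack()].
#' @param deltas Named list: each element either a single number (offset) or a
#'   list with elements `offset` and/or `scale`. Names must be climate layers.
#' @return The modified [env_stack()].
#' @export
apply_climate_change <- function(stack, deltas) {
  clim <- climate_layer_names(stack)
  bad <- setdiff(names(deltas), clim)
  if (length(bad))
    stop("climate deltas reference non-climate layers: ",
         paste(bad, collapse = ", "))
  out <- stack
  for (nm in names(deltas)) {
    d <- deltas[[nm]]
    if (is.numeric(d)) d <- list(offset = d)
    off <- if (is.null(d$offset)) 0 else d$offset
    sc <- if (is.null(d$scale)) 1 else d$scale
    out$layers[[nm]] <- sc * out$layers[[nm]] + off
  }
  out
}

#' Apply a uniform sea-level rise to a stack
#'
#' Lowers `Elevation` by `rise` metres everywhere; cells whose new elevation
#' falls below 0 are inundated and added to the nodata mask. No other layer
#' changes.
#'
#' @param stack An [env_stack()].
#' @param rise Sea-level rise in metres, non-negative.
#' @return The modified [env_stack()] with a (possibly) grown mask.
#' @export
apply_sea_level_rise <- function(stack, rise) {
  if (!is.numeric(rise) || length(rise) != 1L || rise < 0)
    stop("rise must be a single non-negative number")
  out <- stack
  out$layers$Elevation <- out$layers$Elevation - rise
  out$mask <- out$mask | (out$layers$Elevation < 0)
  out
}

#' Build the four-scenario set (CUR, CLC, SLR, CCS)
#'
#' @param stack Current-conditions [env_stack()].
#' @param deltas Climate deltas as in [apply_climate_change()].
#' @param rise Sea-level rise in metres as in [apply_sea_level_rise()].
#' @return A list of class `scenario_set` with elements `CUR` (input), `CLC`
#'   (climate change only), `SLR` (sea-level rise only), `CCS` (both).
#' @export
make_scenarios <- function(stack, deltas, rise) {
  out <- list(CUR = stack,
              CLC = apply_climate_change(stack, deltas),
              SLR = apply_sea_level_rise(stack, rise),
              CCS = apply_sea_level_rise(apply_climate_change(stack, deltas),
                                         rise))
  class(out) <- "scenario_set"
  out
}

#' @export
print.scenario_set <- function(x, ...) {
  cat("scenario_set: CUR / CLC / SLR / CCS on a",
      x$CUR$grid$nrows, "x", x$CUR$grid$ncols, "grid\n")
  cat(sprintf("  unmasked cells: CUR %d, SLR %d, CCS %d\n",
              sum(!x$CUR$mask), sum(!x$SLR$mask), sum(!x$CCS$mask)))
  invisible(x)
}

#' Known generating suitability model for recovery tests
#'
#' A ground-truth suitability surface: a linear predictor on standardized
#' named layers pushed through the cloglog link
#' `1 - exp(-exp(eta))`, giving values in (0, 1). Standardization constants
#' are frozen at construction from the reference stack so the same model can
#' be evaluated on scenario stacks.
#'
#' @param stack Reference [env_stack()] providing standardization constants.
#' @param coefficients Named numeric vector of coefficients on layers.
#' @param intercept Intercept of the linear predictor.
#' @return Object of class `true_model`.
#' @export
true_model <- function(stack,
                       coefficients = c(Bio02 = -4, Elevation = -8),
                       intercept = -11) {
  nms <- names(coefficients)
  stopifnot(all(nms %in% names(stack$layers)))
  ctr <- vapply(nms, function(nm) mean(stack$layers[[nm]][!stack$mask]), 0)
  scl <- vapply(nms, function(nm) stats::sd(stack$layers[[nm]][!stack$mask]), 0)
  scl[scl == 0] <- 1
  structure(list(coefficients = coefficients, intercept = intercept,
                 center = ctr, scale = scl),
            class = "true_model")
}

#' Evaluate a true model's suitability over a stack
#' @param model A [true_model()].
#' @param stack An [env_stack()].
#' @return Matrix of suitabilities in \[0, 1\]; NA on masked cells.
#' @export
true_suitability <- function(model, stack) {
  eta <- matrix(model$intercept, stack$grid$nrows, stack$grid$ncols)
  for (nm in names(model$coefficients)) {
    z <- (stack$layers[[nm]] - model$center[nm]) / model$scale[nm]
    eta <- eta + model$coefficients[nm] * z
  }
  s <- 1 - exp(-exp(eta))
  s[stack$mask] <- NA_real_
  s
}

#' Sample presence records from a suitability surface
#'
#' Draws `n` presence cells (with replacement) among unmasked cells with
#' probability proportional to suitability, and returns records at the cell
#' centers.
#'
#' @param stack An [env_stack()].
#' @param suitability Matrix of non-negative weights (e.g.
#'   [true_suitability()] output); NA treated as 0.
#' @param n Number of records.
#' @param seed Integer seed.
#' @param species Species label written to the records.
#' @return data.frame of class `occurrence_set` with columns
#'   `species`, `x`, `y`.
#' @export
sample_occurrences <- function(stack, suitability, n, seed = 1,
                               species = "synthetic") {
  stopifnot(n >= 1)
  w <- suitability
  w[stack$mask] <- 0
  w[is.na(w)] <- 0
  if (any(w < 0)) stop("suitability weights must be non-negative")
  if (sum(w) == 0) stop("all-zero suitability: nothing to sample from")
  set.seed(seed)
  idx <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
  rc <- arrayInd(idx, dim(w))
  ctr <- cell_center(rc[, 1], rc[, 2], stack$grid)
  out <- data.frame(species = species, x = ctr$x, y = ctr$y)
  class(out) <- c("occurrence_set", "data.frame")
  out
}
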