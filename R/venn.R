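# Venn four-set decomposition of habitat change. With binary habitat maps
# under current conditions (HCUR) and the three futures (HCLC climate-only,
# HSLR sea-level-rise-only, HCCS combined), the change between HCUR and HCCS
# is split into pure climate, pure sea-level-rise, shared, and coupling
# effects, separately for gains and losses.

VENN_CODES <- data.frame(
  code = 0:9,
  label = c("absent", "unchanged",
            "gain_p_clc", "gain_p_slr", "gain_s_ics", "gain_c_ics",
            "loss_p_clc", "loss_p_slr", "loss_s_ics", "loss_c_ics"),
  stringsAsFactors = FALSE)

#' Binarize a suitability map at a threshold
#'
#' @param suitability Numeric matrix of cloglog suitabilities; NA = nodata.
#' @param threshold Threshold in \[0, 1\]; suitable where value >= threshold.
#' @param mask Optional logical matrix of additional nodata cells.
#' @return Integer matrix of 0/1 with NA preserved.
#' @export
binarize <- function(suitability, threshold, mask = NULL) {
  stopifnot(threshold >= 0, threshold <= 1)
  out <- ifelse(suitability >= threshold, 1L, 0L)
  if (!is.null(mask)) out[mask] <- NA_integer_
  out
}

#' Binary habitat maps for all four scenarios
#'
#' Predicts the model over each scenario stack, binarizes at the threshold,
#' and applies the inundation convention: a cell masked under some but not
#' all scenarios (e.g. inundated under SLR/CCS) counts as unsuitable (0)
#' there — inundation is habitat loss, not missing data. Only cells masked
#' under every scenario are nodata.
#'
#' @param model A fitted [maxent()].
#' @param scenarios A [make_scenarios()] result.
#' @param threshold Binarization threshold (e.g. the weighted threshold from
#'   [habitat_thresholds()]).
#' @return List of class `scenario_habitats` with elements `HCUR`, `HCLC`,
#'   `HSLR`, `HCCS` (0/1/NA matrices on a common nodata pattern) and `grid`.
#' @export
scenario_habitats <- function(model, scenarios, threshold) {
  stopifnot(inherits(scenarios, "scenario_set"))
  common_mask <- scenarios$CUR$mask & scenarios$CLC$mask &
    scenarios$SLR$mask & scenarios$CCS$mask
  hab <- function(stack) {
    s <- predict_stack(model, stack)
    b <- binarize(s, threshold)
    b[is.na(b)] <- 0L          # masked-under-this-scenario = unsuitable
    b[common_mask] <- NA_integer_
    b
  }
  structure(list(HCUR = hab(scenarios$CUR), HCLC = hab(scenarios$CLC),
                 HSLR = hab(scenarios$SLR), HCCS = hab(scenarios$CCS),
                 grid = scenarios$CUR$grid),
            class = "scenario_habitats")
}

check_habitats <- function(sh) {
  need <- c("HCUR", "HCLC", "HSLR", "HCCS")
  if (!all(need %in% names(sh))) stop("need maps HCUR, HCLC, HSLR, HCCS")
  d <- dim(sh$HCUR)
  for (nm in need) {
    if (!identical(dim(sh[[nm]]), d)) stop("habitat maps differ in shape")
    if (!identical(is.na(sh[[nm]]), is.na(sh$HCUR)))
      stop("habitat maps differ in nodata pattern")
  }
  invisible(sh)
}

as01 <- function(m) { m[is.na(m)] <- 0L; m == 1L }

#' Unchanged, gained and lost habitat between current and combined scenarios
#'
#' `unchanged = HCCS & HCUR`; `gain = HCCS & !HCUR`; `loss = HCUR & !HCCS`.
#' The three sets are pairwise disjoint and cover `HCUR | HCCS`.
#'
#' @param sh A `scenario_habitats` (or plain list of the four 0/1/NA maps).
#' @return List of logical matrices `unchanged`, `gain`, `loss`.
#' @export
changed_sets <- function(sh) {
  check_habitats(sh)
  cur <- as01(sh$HCUR); ccs <- as01(sh$HCCS)
  list(unchanged = ccs & cur, gain = ccs & !cur, loss = cur & !ccs)
}

#' Attribute habitat gain to pure, shared and coupling effects
#'
#' Within the gained cells (`HCCS` minus `HCUR`): cells also gained under
#' both single-driver scenarios are `s_ics` (shared); gained under the
#' climate-only scenario alone, `p_clc`; under the sea-level-rise-only
#' scenario alone, `p_slr`; under neither, `c_ics` (coupling). The four
#' labels partition the gain.
#'
#' @param sh A `scenario_habitats`.
#' @return Character matrix with labels on gain cells, NA elsewhere.
#' @export
attribute_gain <- function(sh) {
  check_habitats(sh)
  cur <- as01(sh$HCUR)
  gain <- changed_sets(sh)$gain
  gclc <- as01(sh$HCLC) & !cur
  gslr <- as01(sh$HSLR) & !cur
  out <- matrix(NA_character_, nrow(gain), ncol(gain))
  out[gain & gclc & gslr] <- "s_ics"
  out[gain & gclc & !gslr] <- "p_clc"
  out[gain & !gclc & gslr] <- "p_slr"
  out[gain & !gclc & !gslr] <- "c_ics"
  out
}

#' Attribute habitat loss to pure, shared and coupling effects
#'
#' Two conventions are offered because the two natural readings of the loss
#' partition differ (and are an exact label permutation of each other):
#'
#' * `as_printed` (default): loss cells are classified by membership in the
#'   single-scenario habitat sets — retained under both `HCLC` and `HSLR`
#'   is shared (`s_ics`), retained under `HCLC` only is `p_clc`, under
#'   `HSLR` only is `p_slr`, under neither is coupling (`c_ics`).
#' * `symmetric`: the mirror of [attribute_gain()] — lost under both
#'   single scenarios is shared, lost under exactly one is that driver's
#'   pure effect, lost under neither is coupling.
#'
#' Cellwise, `as_printed` shared == `symmetric` coupling, and `as_printed`
#' `p_clc` == `symmetric` `p_slr` (and vice versa).
#'
#' @param sh A `scenario_habitats`.
#' @param convention `"as_printed"` or `"symmetric"`.
#' @return Character matrix with labels on loss cells, NA elsewhere.
#' @export
attribute_loss <- function(sh, convention = c("as_printed", "symmetric")) {
  convention <- match.arg(convention)
  check_habitats(sh)
  cur <- as01(sh$HCUR)
  loss <- changed_sets(sh)$loss
  out <- matrix(NA_character_, nrow(loss), ncol(loss))
  if (convention == "as_printed") {
    rclc <- as01(sh$HCLC) & cur   # retained under climate-only
    rslr <- as01(sh$HSLR) & cur   # retained under slr-only
    out[loss & rclc & rslr] <- "s_ics"
    out[loss & rclc & !rslr] <- "p_clc"
    out[loss & !rclc & rslr] <- "p_slr"
    out[loss & !rclc & !rslr] <- "c_ics"
  } else {
    lclc <- cur & !as01(sh$HCLC)  # lost under climate-only
    lslr <- cur & !as01(sh$HSLR)  # lost under slr-only
    out[loss & lclc & lslr] <- "s_ics"
    out[loss & lclc & !lslr] <- "p_clc"
    out[loss & !lclc & lslr] <- "p_slr"
    out[loss & !lclc & !lslr] <- "c_ics"
  }
  out
}

#' Full per-cell decomposition of habitat change
#'
#' Merges the unchanged/gain/loss classifications into one coded map: every
#' non-nodata cell gets exactly one label from absent, unchanged, four gain
#' classes and four loss classes.
#'
#' @param sh A `scenario_habitats`.
#' @param convention Loss convention, see [attribute_loss()].
#' @return Object of class `decomposition_map`: integer `codes` matrix,
#'   `legend` (code/label table), `convention`, and `grid` if `sh` has one.
#' @export
decompose_change <- function(sh, convention = c("as_printed", "symmetric")) {
  convention <- match.arg(convention)
  check_habitats(sh)
  cs <- changed_sets(sh)
  g <- attribute_gain(sh)
  l <- attribute_loss(sh, convention)
  codes <- matrix(0L, nrow(sh$HCUR), ncol(sh$HCUR))
  codes[cs$unchanged] <- 1L
  for (cl in c("p_clc", "p_slr", "s_ics", "c_ics")) {
    codes[!is.na(g) & g == cl] <-
      VENN_CODES$code[VENN_CODES$label == paste0("gain_", cl)]
    codes[!is.na(l) & l == cl] <-
      VENN_CODES$code[VENN_CODES$label == paste0("loss_", cl)]
  }
  codes[is.na(sh$HCUR)] <- NA_integer_
  structure(list(codes = codes, legend = VENN_CODES,
                 convention = convention, grid = sh$grid),
            class = "decomposition_map")
}

#' @export
print.decomposition_map <- function(x, ...) {
  cat("decomposition_map (", x$convention, " loss convention)\n", sep = "")
  tb <- table(factor(x$codes[!is.na(x$codes)], levels = VENN_CODES$code,
                     labels = VENN_CODES$label))
  print(tb)
  invisible(x)
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Percentages of changed habitat per effect class
#'
#' Given the four component areas of one change direction, returns each
#' component as a percentage of their total, rounded half-up to 2 decimals.
#'
#' @param areas Numeric vector of component areas (named or not).
#' @return List with `total` and `pct`; `flagged` TRUE when the total is 0
#'   (percentages then reported as 0).
#' @export
area_percentages <- function(areas) {
  total <- sum(areas)
  if (total == 0)
    return(list(total = 0, pct = rep(0, length(areas)), flagged = TRUE))
  list(total = total, pct = round_half_up(100 * areas / total, 2),
       flagged = FALSE)
}

#' Area accounting of a change decomposition
#'
#' One row per change direction (increase/decrease) with the area (km^2,
#' cell count x cell_size^2) of each effect class, its percentage of that
#' direction's changed total, and the total itself.
#'
#' @param decomp A [decompose_change()] result.
#' @param cell_size Cell edge in km; defaults to the decomposition's grid.
#' @return data.frame of class `area_table` with columns `direction`,
#'   `H_p_clc`, `pct_p_clc`, ..., `H_changed`, `pct_changed`.
#' @export
area_table <- function(decomp, cell_size = NULL) {
  if (is.null(cell_size))
    cell_size <- if (!is.null(decomp$grid)) decomp$grid$cell_size else 1
  a <- cell_size^2
  codes <- decomp$codes
  cnt <- function(lbl) sum(codes == VENN_CODES$code[VENN_CODES$label == lbl],
                           na.rm = TRUE)
  classes <- c("p_clc", "p_slr", "s_ics", "c_ics")
  out <- NULL
  for (dir in c("gain", "loss")) {
    areas <- vapply(classes, function(cl) cnt(paste0(dir, "_", cl)) * a, 0)
    ap <- area_percentages(areas)
    row <- data.frame(direction = if (dir == "gain") "increased" else "decreased",
                      H_p_clc = areas[1], pct_p_clc = ap$pct[1],
                      H_p_slr = areas[2], pct_p_slr = ap$pct[2],
                      H_s_ics = areas[3], pct_s_ics = ap$pct[3],
                      H_c_ics = areas[4], pct_c_ics = ap$pct[4],
                      H_changed = ap$total,
                      pct_changed = if (ap$flagged) 0 else 100)
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  class(out) <- c("area_table", "data.frame")
  out
}

#' Export / import a decomposition map as coded raster plus legend
#'
#' Writes the integer code grid as an ESRI ASCII grid and the legend (code,
#' label, display color) as CSV.
#'
#' @param decomp A [decompose_change()] result (with a grid).
#' @param path_asc Output `.asc` path.
#' @param path_legend Output legend CSV path.
#' @return `read_decomposition` returns the restored `decomposition_map`.
#' @export
export_map <- function(decomp, path_asc, path_legend) {
  if (is.null(decomp$grid)) stop("decomposition has no grid geometry")
  present <- sort(unique(decomp$codes[!is.na(decomp$codes)]))
  legend <- VENN_CODES[VENN_CODES$code %in% present, ]
  palette <- c("grey90", "grey60", "darkgreen", "seagreen3", "olivedrab2",
               "yellowgreen", "firebrick", "orange", "gold", "salmon")
  legend$color <- palette[legend$code + 1L]
  write_ascii_grid(path_asc, decomp$codes, decomp$grid,
                   mask = is.na(decomp$codes))
  utils::write.csv(legend, path_legend, row.names = FALSE, quote = FALSE)
  invisible(path_asc)
}

#' @rdname export_map
#' @export
read_decomposition <- function(path_asc, path_legend) {
  g <- read_ascii_grid(path_asc)
  codes <- g$values
  codes[g$mask] <- NA_real_
  structure(list(codes = matrix(as.integer(codes), nrow(codes), ncol(codes)),
                 legend = utils::read.csv(path_legend),
                 convention = NA_character_, grid = g$grid),
            class = "decomposition_map")
}
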