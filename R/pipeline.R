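# End-to-end runner: synthesize (or load) -> thin/split -> screen -> tune ->
# fit -> evaluate + thresholds -> global sensitivity -> scenario projection ->
# binarize -> decompose -> report. One master seed fans out to per-stage
# seeds so any stage can be re-run in isolation.

#' Default pipeline configuration
#'
#' A fully populated, YAML-serializable configuration for [run_pipeline()].
#' Every block can be overridden; `load_config()` reads a YAML file over
#' these defaults.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param output_dir Where stage outputs and the run manifest are written.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(seed = 1, output_dir = tempfile("coastniche_run_")) {
  structure(list(
    seed = seed,
    output_dir = output_dir,
    synthetic = list(
      nrows = 100, ncols = 200, cell_size = 1, autocorr = 6,
      elev_range = c(-2, 20), elev_noise_sd = 1, n_categories = 4,
      true_coefficients = c(Bio02 = -4, Elevation = -8),
      true_intercept = -11, n_presence = 300),
    stack_dir = NULL,          # read a stack instead of synthesizing
    occurrences_csv = NULL,    # read occurrences instead of sampling
    thinning = list(cell_size = 1),   # default: one raster cell
    region_y_threshold = NULL, # split north/south at this y, NULL = one region
    screening = list(spearman = TRUE, r_thresh = 0.8, p_thresh = 0.001,
                     shadow = TRUE, n_rounds = 20, alpha = 0.01,
                     num_trees = 200),
    maxent = list(n_background = 10000, max_iter = 1000, convergence = 1e-5,
                  tau = 0.5, n_hinge_knots = 10),
    tuning = list(rm_list = 1:4, fc_list = c("L", "LQ", "LQH")),
    cv = list(k = 10),
    gsa = list(M = 4, omega_max = 32, n_repeats = 5, allow_cycling = TRUE),
    scenario = list(deltas = list(Bio02 = 1.0, Bio05 = 1.5, Bio08 = 1.5,
                                  Bio19 = 20),
                    rise = 1),
    attribution = list(convention = "as_printed")),
    class = "run_config")
}

#' @rdname default_config
#' @param path YAML file whose entries override the defaults.
#' @export
load_config <- function(path, seed = 1) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(seed = seed)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_rec(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  structure(merge_rec(unclass(cfg), user), class = "run_config")
}

stage_seeds <- function(master) {
  set.seed(master)
  s <- sample.int(.Machine$integer.max - 1L, 10)
  names(s) <- c("synthesize", "occurrences", "background", "screen", "tune",
                "fit", "evaluate", "gsa", "project", "report")
  s
}

restrict_stack <- function(stack, region_rows) {
  # region = logical matrix of cells belonging to the region
  out <- stack
  out$mask <- out$mask | !region_rows
  out
}

#' Run the full analysis pipeline
#'
#' Executes the workflow end to end per the configuration, writing stage
#' outputs (stack, occurrences, tuning table, sensitivity table, area table,
#' coded change map) and a YAML run manifest under `config$output_dir`. The
#' run is deterministic given `config$seed`. A failing stage stops the run
#' with its name; the manifest records the failure point.
#'
#' @param config A [default_config()]-shaped list.
#' @return List of class `coastniche_run`: `config`, per-region `regions`
#'   (each with the fitted model, tuning, cross-validation, thresholds,
#'   sensitivity result, decomposition and area table), `manifest`.
#' @export
run_pipeline <- function(config = default_config()) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- stage_seeds(config$seed)
  manifest <- list(config = serializable(config),
                   package_version = as.character(utils::packageVersion("coastniche")),
                   r_version = R.version.string,
                   stages = list(), status = "running")
  t_all <- Sys.time()
  current <- "init"
  stamp <- function(name, t0, files = character()) {
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3),
      checksums = as.list(tools::md5sum(files[file.exists(files)])))
  }
  finish_manifest <- function(status, failed_stage = NULL) {
    manifest$status <<- status
    if (!is.null(failed_stage)) manifest$failed_stage <<- failed_stage
    yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  }

  res <- tryCatch({
    # -- synthesize / ingest -------------------------------------------------
    current <- "synthesize"; t0 <- Sys.time()
    if (!is.null(config$stack_dir)) {
      stack <- read_stack(config$stack_dir)
      truth <- NULL
    } else {
      sy <- config$synthetic
      stack <- synth_landscape(
        grid = grid_spec(sy$nrows, sy$ncols, sy$cell_size),
        autocorr = sy$autocorr, elev_range = sy$elev_range,
        elev_noise_sd = sy$elev_noise_sd, n_categories = sy$n_categories,
        seed = seeds["synthesize"])
      truth <- true_model(stack, coefficients = unlist(sy$true_coefficients),
                          intercept = sy$true_intercept)
    }
    stack_out <- file.path(config$output_dir, "stack")
    write_stack(stack, stack_out)
    stamp("synthesize", t0, file.path(stack_out, "manifest.yaml"))

    # -- occurrences ---------------------------------------------------------
    current <- "occurrences"; t0 <- Sys.time()
    if (!is.null(config$occurrences_csv)) {
      occ <- read_occurrences(config$occurrences_csv)
    } else {
      if (is.null(truth)) stop("no occurrences_csv and no synthetic truth")
      occ <- sample_occurrences(stack, true_suitability(truth, stack),
                                n = config$synthetic$n_presence,
                                seed = seeds["occurrences"])
    }
    occ <- thin_occurrences(occ, config$thinning$cell_size,
                            origin = stack$grid$origin)
    occ_path <- file.path(config$output_dir, "occurrences.csv")
    write_occurrences(occ, occ_path)
    stamp("occurrences", t0, occ_path)

    # -- regions -------------------------------------------------------------
    regions <- list()
    if (is.null(config$region_y_threshold)) {
      regions$all <- list(occ = occ, stack = stack)
    } else {
      sp <- split_regions(occ, config$region_y_threshold)
      ymid <- stack$grid$origin[2] +
        (seq_len(stack$grid$nrows) - 0.5) * stack$grid$cell_size
      north_rows <- matrix(ymid >= config$region_y_threshold,
                           stack$grid$nrows, stack$grid$ncols)
      regions$north <- list(occ = sp$north,
                            stack = restrict_stack(stack, north_rows))
      regions$south <- list(occ = sp$south,
                            stack = restrict_stack(stack, !north_rows))
    }

    out_regions <- list()
    for (rg in names(regions)) {
      occ_r <- regions[[rg]]$occ
      stack_r <- regions[[rg]]$stack
      tag <- function(base) file.path(config$output_dir,
                                      sprintf("%s_%s", rg, base))

      # -- background + tables ----------------------------------------------
      current <- paste0(rg, ":background"); t0 <- Sys.time()
      bg <- sample_background(stack_r, config$maxent$n_background,
                              seed = seeds["background"])
      pres <- extract_predictors(occ_r, stack_r)
      stamp(current, t0)

      # -- screening ---------------------------------------------------------
      current <- paste0(rg, ":screen"); t0 <- Sys.time()
      keep <- setdiff(names(stack_r$layers), c("row", "col"))
      scr <- config$screening
      spearman_rep <- NULL
      if (isTRUE(scr$spearman)) {
        clim <- intersect(climate_layer_names(stack_r), keep)
        spearman_rep <- spearman_screen(drop_cell_cols(bg)[clim],
                                        r_thresh = scr$r_thresh,
                                        p_thresh = scr$p_thresh)
        keep <- setdiff(keep, setdiff(clim, spearman_rep$retained))
      }
      if (isTRUE(scr$shadow)) {
        tab <- rbind(drop_cell_cols(pres)[keep], drop_cell_cols(bg)[keep])
        labels <- c(rep(1, nrow(pres)), rep(0, nrow(bg)))
        confirmed <- shadow_screen(tab, labels, seed = seeds["screen"],
                                   n_rounds = scr$n_rounds,
                                   alpha = scr$alpha,
                                   num_trees = scr$num_trees)
        if (length(confirmed) >= 2) keep <- intersect(keep, confirmed)
        else warning("shadow screen confirmed < 2 variables; keeping all")
      }
      pres_k <- drop_cell_cols(pres)[keep]
      bg_k <- drop_cell_cols(bg)[keep]
      kinds_k <- stack_r$kinds[keep]
      stamp(current, t0)

      # -- tuning ------------------------------------------------------------
      current <- paste0(rg, ":tune"); t0 <- Sys.time()
      base_cfg <- maxent_config(
        n_background = config$maxent$n_background,
        max_iter = config$maxent$max_iter,
        convergence = config$maxent$convergence,
        tau = config$maxent$tau,
        n_hinge_knots = config$maxent$n_hinge_knots,
        seed = seeds["tune"])
      tune_res <- tune_maxent(pres_k, bg_k,
                              rm_list = config$tuning$rm_list,
                              fc_list = config$tuning$fc_list,
                              config = base_cfg)
      tune_path <- tag("tuning.csv")
      utils::write.csv(tune_res$table, tune_path, row.names = FALSE)
      stamp(current, t0, tune_path)

      # -- final fit + evaluation -------------------------------------------
      current <- paste0(rg, ":fit"); t0 <- Sys.time()
      best <- tune_res$table[tune_res$best, ]
      fit_cfg <- base_cfg
      fit_cfg$rm <- best$rm
      fit_cfg$fc <- strsplit(best$fc, "")[[1]]
      model <- tune_res$best_model
      model_path <- tag("model.json")
      write_maxent(model, model_path)
      stamp(current, t0, model_path)

      current <- paste0(rg, ":evaluate"); t0 <- Sys.time()
      cv <- cross_validate(pres_k, bg_k, fit_cfg,
                           k = min(config$cv$k, nrow(pres_k)),
                           seed = seeds["evaluate"])
      s_pres <- predict(model, pres_k)
      s_bg <- predict(model, bg_k)
      thr <- habitat_thresholds(s_pres, s_bg)
      train_auc <- auc_score(s_pres, s_bg)
      stamp(current, t0)

      # -- global sensitivity -----------------------------------------------
      current <- paste0(rg, ":gsa"); t0 <- Sys.time()
      stack_keep <- stack_r
      stack_keep$layers <- stack_keep$layers[keep]
      stack_keep$kinds <- stack_keep$kinds[keep]
      sens <- efast_gsa(model, stack_keep,
                        M = config$gsa$M, omega_max = config$gsa$omega_max,
                        seed = seeds["gsa"], n_repeats = config$gsa$n_repeats,
                        allow_cycling = isTRUE(config$gsa$allow_cycling))
      sens_path <- tag("sensitivity.csv")
      write_sensitivity_csv(sens, sens_path)
      stamp(current, t0, sens_path)

      # -- scenarios + decomposition ----------------------------------------
      current <- paste0(rg, ":project"); t0 <- Sys.time()
      scen <- make_scenarios(stack_r, config$scenario$deltas,
                             config$scenario$rise)
      sh <- scenario_habitats(model, scen, thr$weighted)
      decomp <- decompose_change(sh, config$attribution$convention)
      at <- area_table(decomp)
      area_path <- tag("area.csv")
      utils::write.csv(at, area_path, row.names = FALSE)
      map_path <- tag("change_map.asc")
      legend_path <- tag("change_legend.csv")
      export_map(decomp, map_path, legend_path)
      stamp(current, t0, c(area_path, map_path, legend_path))

      out_regions[[rg]] <- list(
        occ = occ_r, retained = keep, spearman = spearman_rep,
        tuning = tune_res, model = model, cv = cv, thresholds = thr,
        train_auc = train_auc, sensitivity = sens, decomposition = decomp,
        area = at)
    }

    # -- report --------------------------------------------------------------
    current <- "report"; t0 <- Sys.time()
    summary_path <- file.path(config$output_dir, "summary.txt")
    write_run_summary(out_regions, summary_path)
    manifest$thresholds <- lapply(out_regions, function(r)
      list(mtss = r$thresholds$mtss, ptss = r$thresholds$ptss,
           etss = r$thresholds$etss, weighted = r$thresholds$weighted))
    stamp("report", t0, summary_path)
    out_regions
  }, error = function(e) {
    finish_manifest("failed", current)
    stop("pipeline stage [", current, "] failed: ", conditionMessage(e),
         call. = FALSE)
  })

  manifest$total_seconds <-
    round(as.numeric(difftime(Sys.time(), t_all, units = "secs")), 3)
  finish_manifest("ok")
  structure(list(config = config, regions = res, manifest = manifest),
            class = "coastniche_run")
}

serializable <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), serializable))
  if (is.null(x) || length(x) == 0) return(x)
  if (!is.null(names(x)) && is.numeric(x)) return(as.list(x))
  x
}

#' Write a sensitivity table in the standard report shape
#'
#' One row per variable (`S_F`, spread, rank, `S_T`, spread, rank, difference,
#' rank) plus a final `Sum` row.
#'
#' @param sens An `efast_result`.
#' @param path CSV output path.
#' @export
write_sensitivity_csv <- function(sens, path) {
  tab <- sens$table
  out <- data.frame(variable = tab$variable,
                    S_F = tab$S_F, S_F_sd = tab$S_F_sd, rank_SF = tab$rank_SF,
                    S_T = tab$S_T, S_T_sd = tab$S_T_sd, rank_ST = tab$rank_ST,
                    diff = tab$diff, rank_diff = tab$rank_diff)
  sum_row <- data.frame(variable = "Sum",
                        S_F = sum(tab$S_F), S_F_sd = NA, rank_SF = NA,
                        S_T = sum(tab$S_T), S_T_sd = NA, rank_ST = NA,
                        diff = sum(tab$diff), rank_diff = NA)
  utils::write.csv(rbind(out, sum_row), path, row.names = FALSE)
  invisible(path)
}

write_run_summary <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rg in names(regions)) {
    r <- regions[[rg]]
    best <- r$tuning$table[r$tuning$best, ]
    writeLines(sprintf("== region %s ==", rg), con)
    writeLines(sprintf("presences: %d, retained variables: %s",
                       nrow(r$occ), paste(r$retained, collapse = ", ")), con)
    writeLines(sprintf("best model: rm = %g, fc = %s (AICc %.2f, k = %d)",
                       best$rm, best$fc, best$aicc, best$k), con)
    writeLines(sprintf("training AUC %.3f; CV mean AUC %.3f (sd %.3f); CV mean TSS %.3f",
                       r$train_auc, r$cv$mean_auc, r$cv$sd_auc,
                       r$cv$mean_tss), con)
    writeLines(sprintf("thresholds: MTSS %.4f PTSS %.4f ETSS %.4f -> weighted %.4f",
                       r$thresholds$mtss, r$thresholds$ptss,
                       r$thresholds$etss, r$thresholds$weighted), con)
    s <- r$sensitivity$table
    top <- s$variable[order(s$rank_ST)][seq_len(min(3, nrow(s)))]
    writeLines(sprintf("top total-effect variables: %s",
                       paste(top, collapse = ", ")), con)
    a <- r$area
    writeLines(sprintf("increased habitat: %g km^2; decreased: %g km^2",
                       a$H_changed[1], a$H_changed[2]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @export
print.coastniche_run <- function(x, ...) {
  cat("coastniche pipeline run (seed", x$config$seed, ")\n")
  for (rg in names(x$regions)) {
    r <- x$regions[[rg]]
    best <- r$tuning$table[r$tuning$best, ]
    cat(sprintf("  %s: rm %g fc %s | CV AUC %.3f | gain %g km^2, loss %g km^2\n",
                rg, best$rm, best$fc, r$cv$mean_auc,
                r$area$H_changed[1], r$area$H_changed[2]))
  }
  invisible(x)
}
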