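# Conflict-record summaries and the end-to-end pipeline driver.

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Tally conflict records by complaint type and severity
#'
#' Cross-tabulates complaint types against severity classes 1-4 (1 the
#' most severe), with whole-percent shares of the grand total
#' (half-away-from-zero rounding) and the severity-group shares commonly
#' reported: class 1 (high), classes 2-3 (mild), class 4 (low).
#'
#' @param records data.frame with columns \code{complaint_type} and
#'   \code{severity}.
#' @return a \code{conflict_summary}: \code{by_type} (count, percent),
#'   \code{type_by_severity} (contingency table), \code{severity_share},
#'   \code{n}.
#' @export
summarize_conflicts <- function(records) {
  if (!nrow(records)) stop("no conflict records")
  if (!all(c("complaint_type", "severity") %in% names(records)))
    stop("records need columns complaint_type and severity")
  if (!all(records$severity %in% 1:4))
    stop("severity must be in 1..4")
  n <- nrow(records)
  counts <- sort(table(records$complaint_type), decreasing = TRUE)
  by_type <- data.frame(
    complaint_type = names(counts),
    count = as.integer(counts),
    percent = round_half_up(100 * as.integer(counts) / n),
    stringsAsFactors = FALSE)
  tab <- table(records$complaint_type, factor(records$severity, levels = 1:4))
  sev <- table(factor(records$severity, levels = 1:4))
  share <- c(high = round_half_up(100 * sev[["1"]] / n),
             mild = round_half_up(100 * (sev[["2"]] + sev[["3"]]) / n),
             low = round_half_up(100 * sev[["4"]] / n))
  structure(list(by_type = by_type, type_by_severity = tab,
                 severity_share = share, n = n),
            class = "conflict_summary")
}

#' @export
print.conflict_summary <- function(x, ...) {
  cat(sprintf("<conflict_summary> %d records\n", x$n))
  print(x$by_type)
  cat(sprintf("severity shares: high %g%%, mild %g%%, low %g%%\n",
              x$severity_share["high"], x$severity_share["mild"],
              x$severity_share["low"]))
  invisible(x)
}

#' Default pipeline configuration
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @return a nested config list accepted by \code{\link{run_pipeline}}.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    landscape = list(n_rows = 40, n_cols = 40, cell_size = 50,
                     n_cover_classes = 8, cover_range = 5,
                     focal_fraction = 0.25),
    truth = list(beta0 = -4,
                 betas = list(elevation = 2.5e-3, pop_density = 0.8,
                              dist_urban = 5e-5)),
    conflicts = list(n_used = 120),
    thinning = list(min_distance = 100, n_repetitions = 20),
    background = list(buffer_radius = 100, ratio = 5),
    screening = list(vif_threshold = 10, r2_threshold = 0.7),
    selection = list(delta_threshold = 2.0),
    fit = list(B = 1000, m = 0),
    validation = list(k = 5, gates = c(auc = 0.7, omission = 0.3)),
    mapping = list(breaks = c(0.25, 0.5, 0.75))
  )
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Chains every stage — landscape simulation, conflict draws, spatial
#' thinning, background generation, covariate extraction, collinearity
#' screening, exhaustive AIC selection, the final bootstrap fit,
#' spatial-hold-out and k-fold validation, and risk-map projection — and
#' returns all stage outputs plus a run manifest (config snapshot, seeds,
#' and md5 checksums of any files written).
#'
#' @param config nested list as from \code{\link{default_config}}, or a
#'   path to a YAML file with the same structure.
#' @param out_dir optional directory; when given, writes the coefficient
#'   table (CSV), fit metadata (JSON), model ranking (CSV), validation
#'   report (CSV + JSON), used/background points (CSV) and the risk and
#'   hotspot rasters (ASCII grid).
#' @return a \code{pipeline_result} list; element \code{manifest} records
#'   config, seeds, stage summaries and output checksums.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  stage <- "landscape"
  result <- tryCatch({
    ls_cfg <- cfg$landscape
    spec <- landscape_spec(n_rows = ls_cfg$n_rows, n_cols = ls_cfg$n_cols,
                           cell_size = ls_cfg$cell_size,
                           n_cover_classes = ls_cfg$n_cover_classes,
                           cover_range = ls_cfg$cover_range,
                           seed = cfg$seed)
    truth <- true_model(cfg$truth$beta0, unlist(cfg$truth$betas))
    study <- simulate_landscape(spec, truth,
                                focal_fraction = ls_cfg$focal_fraction)

    stage <- "conflicts"
    used_raw <- simulate_conflicts(study, cfg$conflicts$n_used,
                                   seed = cfg$seed + 101)

    stage <- "thin"
    used_raw <- filter_by_mask(used_raw, study$region_mask)
    thin <- spatial_thin(used_raw, cfg$thinning$min_distance,
                         cfg$thinning$n_repetitions, seed = cfg$seed + 202)
    used <- thin$retained

    stage <- "background"
    bg <- generate_background(study$region_mask, used,
                              buffer_radius = cfg$background$buffer_radius,
                              ratio = cfg$background$ratio,
                              seed = cfg$seed + 303)

    stage <- "extract"
    pts <- rbind(as.data.frame(used[, c("id", "x", "y", "label")]),
                 as.data.frame(bg[, c("id", "x", "y", "label")]))
    pts$id <- seq_len(nrow(pts))
    class(pts) <- c("point_set", "data.frame")
    pts <- extract_values(study$stack, pts)
    cont <- spec$covariates$name
    data <- rspf_design(pts, continuous = cont, categorical = "cover")

    stage <- "screen"
    scr <- screen_covariates(data$x[, cont, drop = FALSE],
                             vif_threshold = cfg$screening$vif_threshold,
                             r2_threshold = cfg$screening$r2_threshold,
                             priority = cont)
    kept_terms <- c(scr$retained, "cover")
    data_kept <- rspf_design(pts, continuous = scr$retained,
                             categorical = "cover")

    stage <- "select"
    ranking <- rank_and_select(data_kept,
                               delta_threshold = cfg$selection$delta_threshold)

    stage <- "fit"
    sel_terms <- ranking$selected_terms
    d <- design_subset(data_kept, sel_terms)
    fit <- fit_rspf(list(x = d$x, y = d$y, terms = sel_terms,
                         reference_class = data_kept$reference_class),
                    B = cfg$fit$B, m = cfg$fit$m, seed = cfg$seed + 404)

    stage <- "validate"
    holdout <- spatial_holdout(pts, study$focal_mask)
    idx_train <- which(pts$id %in% holdout$train$id)
    idx_test <- which(pts$id %in% holdout$test$id)
    val_spatial <- validate_split(data_kept, idx_train, idx_test,
                                  terms = sel_terms,
                                  gates = cfg$validation$gates)
    val_kfold <- kfold_cv(data_kept, terms = sel_terms,
                          k = cfg$validation$k, seed = cfg$seed + 505,
                          gates = cfg$validation$gates)

    stage <- "map"
    risk <- project_model(fit, study$stack)
    risk_focal <- crop_to_focus(risk, study$focal_mask)
    hotspots <- classify_hotspots(risk, cfg$mapping$breaks)

    list(study = study, thinning = thin, used = used, background = bg,
         points = pts, screening = scr, ranking = ranking, fit = fit,
         validation = list(spatial = val_spatial, kfold = val_kfold),
         risk = risk, risk_focal = risk_focal, hotspots = hotspots)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    coefs <- data.frame(covariate = names(result$fit$beta),
                        estimate = unname(result$fit$beta),
                        se = unname(result$fit$se),
                        p_value = unname(result$fit$p))
    utils::write.csv(coefs, p("coefficients.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(loglik = result$fit$loglik, aic = result$fit$aic,
           k = result$fit$k, B = result$fit$B, m = result$fit$m,
           seed = config$seed,
           reference_class = result$fit$reference_class),
      p("fit_metadata.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(result$ranking$rows, p("model_ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(result$validation$kfold$per_fold, p("kfold.csv"),
                     row.names = FALSE)
    jsonlite::write_json(result$validation$spatial, p("spatial_holdout.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    write_points_csv(result$used, p("used_points.csv"))
    write_points_csv(result$background, p("background_points.csv"))
    write_ascii_grid(result$risk, p("risk.asc"))
    write_ascii_grid(result$hotspots, p("hotspots.asc"))
    files <- list.files(out_dir, full.names = TRUE)
  }
  manifest <- list(
    config = config,
    seeds = list(master = config$seed, conflicts = config$seed + 101,
                 thin = config$seed + 202, background = config$seed + 303,
                 fit = config$seed + 404, kfold = config$seed + 505),
    stages = list(n_used_raw = config$conflicts$n_used,
                  n_used = nrow(result$used),
                  n_background = nrow(result$background),
                  selected_model = result$ranking$rows$model[
                    result$ranking$selected],
                  aic = result$fit$aic),
    outputs = if (length(files))
      data.frame(path = files, md5 = unname(tools::md5sum(files)),
                 stringsAsFactors = FALSE)
    else NULL)
  result$manifest <- manifest
  class(result) <- "pipeline_result"
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest$stages
  cat("<pipeline_result>\n")
  cat(sprintf("  used: %d (thinned from %d), background: %d\n",
              m$n_used, m$n_used_raw, m$n_background))
  cat(sprintf("  selected model: %s (AIC %.2f)\n", m$selected_model, m$aic))
  cat(sprintf("  spatial holdout AUC: %.3f; k-fold mean AUC: %.3f\n",
              x$validation$spatial$auc, x$validation$kfold$mean["auc"]))
  invisible(x)
}
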