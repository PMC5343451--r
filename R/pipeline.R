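#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. With the defaults the
#' pipeline runs on a synthetic world: a 3000 x 3000 km landscape at 30 km
#' resolution whose seven covariate surfaces, arid belt and true log-linear
#' density model mirror the global wild pig analysis, 118 mainland + 11
#' island density records, and a 100-1000 km background buffer ring around
#' the native range. Supply `records` and `grids` to run on real data
#' instead.
#'
#' @param seed master integer seed; every stochastic stage derives its seed
#'   from it.
#' @param out_dir output directory for the report bundle.
#' @param landscape a [landscape_config()] (synthetic mode).
#' @param true_model a [true_model()] (synthetic mode).
#' @param records optional data frame (or path) of density records; disables
#'   synthesis.
#' @param grids optional named list of [raster_grid()] (or .asc paths), one
#'   per covariate; required when `records` is given.
#' @param covariates named list of [covariate_spec()].
#' @param n_mainland,n_island record counts for the synthetic sampler.
#' @param log_offset offset added to density before the natural log
#'   (default 1: background zeros map to response 0).
#' @param cor_threshold Pearson `|r|` above which covariates are pruned.
#' @param buffer_inner_km,buffer_outer_km background buffer ring bounds.
#' @param k folds for cross-validation, or `"huberty"`.
#' @param se_variant unconditional SE estimator, see [model_average()].
#' @param class_breaks density-class anchors, see [classify_density()].
#' @param smearing log-normal back-transform correction for the map.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = tempfile("densmmi_run"),
                            landscape = NULL,
                            true_model = default_true_model(),
                            records = NULL, grids = NULL,
                            covariates = default_covariate_specs(),
                            n_mainland = 118, n_island = 11,
                            log_offset = 1,
                            cor_threshold = 0.70,
                            buffer_inner_km = 100,
                            buffer_outer_km = 1000,
                            k = "huberty",
                            se_variant = "sum_of_roots",
                            class_breaks = c(1, 6, 11),
                            smearing = FALSE) {
  if (is.null(landscape)) {
    landscape <- landscape_config(seed = seed, covariates = covariates)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

stage_log <- function(quiet, ...) {
  if (!quiet) message(sprintf(...))
}

# Subset a design table to a set of columns (keeps scaling metadata).
design_subset <- function(design, cols) {
  design$columns <- design$columns[, cols, drop = FALSE]
  design$scaling <- design$scaling[design$scaling$column %in% cols, ,
                                   drop = FALSE]
  if (!is.null(design$chosen_radius)) {
    design$chosen_radius <- design$chosen_radius[cols]
  }
  design
}

#' Run the full density-distribution analysis
#'
#' Executes, in order: (1) data synthesis or loading; (2) aggregation of
#' repeated estimates and the island/mainland Welch comparison; (3)
#' zero-density background sampling in the buffer ring (clipped to the grid
#' extent); (4) moving-window covariate extraction, AICc scale/form
#' selection, standardisation and correlation pruning; (5) all-subsets AICc
#' enumeration, model averaging and variable importance; (6) the
#' model-averaged prediction map and its density classification; (7) k-fold
#' cross-validation. Writes a report bundle (model-selection table, averaged
#' coefficients, pruning log, CV report, maps as ESRI ASCII, run manifest)
#' to `config$out_dir` and returns the pieces invisibly.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return Invisibly, a list with `records`, `welch_log`, `welch_raw`,
#'   `background`, `design`, `pruning`, `fit`, `map`, `classes`, `cv`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  specs <- config$covariates
  native <- NULL

  # -- stage 1: data ---------------------------------------------------
  if (is.null(config$records)) {
    land <- generate_landscape(config$landscape)
    native <- config$landscape$native_polygon
    # the true model acts on the buffer-mean covariates at each covariate's
    # native scale (its first candidate radius), mirroring how the
    # landscape variables are defined in the analysis
    true_grids <- land$grids
    for (nm in names(true_grids)) {
      if (!is.null(specs[[nm]])) {
        true_grids[[nm]] <- focal_mean(true_grids[[nm]],
                                       specs[[nm]]$candidate_radii_km[1])
      }
    }
    dens <- generate_true_density(true_grids, config$true_model,
                                  seed = seed + 1L, island = land$island)
    records <- sample_study_sites(dens, land$island,
                                  n_mainland = config$n_mainland,
                                  n_island = config$n_island,
                                  seed = seed + 2L,
                                  native_polygon = native)
    grids <- land$grids
  } else {
    records <- if (is.character(config$records)) {
      read_records(config$records)
    } else config$records
    grids <- lapply(config$grids, function(g) {
      if (is.character(g)) read_asc(g) else g
    })
    native <- config$landscape$native_polygon
  }
  stage_log(quiet, "stage 1 (data): %d records, %d covariate grids",
            nrow(records), length(grids))

  # -- stage 2: aggregation + island/mainland comparison --------------
  records <- aggregate_records(records)
  welch_log <- compare_island_mainland(records, log_scale = TRUE)
  welch_raw <- compare_island_mainland(records, log_scale = FALSE)
  stage_log(quiet,
            "stage 2 (design): %d sites after averaging; island vs mainland t = %.2f (log scale)",
            nrow(records), welch_log$t)

  # -- stage 3: background sampling -----------------------------------
  ref <- grids[[1]]
  bbox <- c(ref$xll, ref$xll + ncol(ref$values) * ref$cellsize,
            ref$yll, ref$yll + nrow(ref$values) * ref$cellsize)
  n_native <- sum(records$region == "native" & !records$is_island)
  background <- sample_background(native, config$buffer_inner_km,
                                  config$buffer_outer_km,
                                  n_native_estimates = n_native,
                                  seed = seed + 3L, bbox = bbox)
  stage_log(quiet, "stage 3 (background): %d zero-density points from %d native estimates",
            nrow(background), n_native)

  # -- stage 4: covariate engineering ---------------------------------
  mainland <- records[!records$is_island, , drop = FALSE]
  model_records <- rbind(mainland, background)
  stack <- build_focal_stack(grids, specs)
  raw_all <- extract_covariates(model_records, stack)
  response0 <- log(model_records$density + config$log_offset)
  chosen <- list()
  quad <- character(0)
  raw <- list()
  for (nm in names(grids)) {
    cand <- raw_all[, grep(paste0("^", nm, "_r"), names(raw_all)),
                    drop = FALSE]
    names(cand) <- sub(paste0("^", nm, "_r"), "", names(cand))
    sel <- select_scale(response0, as.list(cand), spec = specs[[nm]])
    chosen[[nm]] <- sel$radius_km
    if (sel$form == "quadratic") quad <- c(quad, nm)
    raw[[nm]] <- cand[[as.character(sel$radius_km)]]
  }
  chosen <- unlist(chosen)
  design <- standardize_design(as.data.frame(raw), model_records$density,
                               log_offset = config$log_offset,
                               chosen_radius = chosen)
  pruning <- prune_correlated(design, threshold = config$cor_threshold)
  design <- design_subset(design, pruning$retained)
  quad <- intersect(quad, pruning$retained)
  stage_log(quiet,
            "stage 4 (covariates): %d retained (%d pruned at |r| > %.2f); quadratic: %s",
            length(pruning$retained), length(pruning$dropped),
            config$cor_threshold,
            if (length(quad)) paste(quad, collapse = ", ") else "none")

  # -- stage 5: enumeration + averaging -------------------------------
  fit <- mmi_fit(design, quadratic = quad, se_variant = config$se_variant)
  stage_log(quiet, "stage 5 (fit): %d models; top AICc %.2f (weight %.2f, adj R^2 %.2f)",
            nrow(fit$model_set$models), fit$model_set$models$AICc[1],
            fit$model_set$models$weight[1], fit$model_set$models$adj_r2[1])

  # -- stage 6: prediction map ----------------------------------------
  map <- predict_map(fit, grids[pruning$retained],
                     smearing = config$smearing)
  classes <- classify_density(map, breaks = config$class_breaks)
  stage_log(quiet, "stage 6 (map): predicted density %.2f-%.2f animals/km^2",
            min(map$values), max(map$values))

  # -- stage 7: cross-validation --------------------------------------
  cv <- cross_validate(fit, k = config$k, seed = seed + 4L)
  stage_log(quiet, "stage 7 (validation): k = %d, MSPE %.3f, r %.3f",
            cv$k, cv$mspe, cv$pearson_r)

  # -- report bundle ---------------------------------------------------
  od <- config$out_dir
  write_records(records, file.path(od, "records.tsv"))
  write_records(background, file.path(od, "background.tsv"))
  write_modsel_table(fit$model_set, file.path(od, "model_selection.tsv"))
  write_averaged_table(fit$averaged, file.path(od, "averaged_model.tsv"))
  utils::write.table(pruning$log, file.path(od, "pruning.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(id = model_records$id, response = design$response,
               design$columns, check.names = FALSE),
    file.path(od, "design_table.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  write_cv_report(cv, file.path(od, "cv_report.tsv"))
  write_asc(map, file.path(od, "density_map.asc"))
  write_asc(classes, file.path(od, "class_map.asc"))
  welch_tab <- data.frame(
    scale = c("log", "raw"),
    t = c(welch_log$t, welch_raw$t),
    df = c(welch_log$df, welch_raw$df),
    p = c(welch_log$p, welch_raw$p))
  utils::write.table(welch_tab, file.path(od, "island_mainland.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    seed = seed,
    n_records = nrow(records), n_background = nrow(background),
    n_model = length(design$response),
    retained = pruning$retained, quadratic = quad,
    chosen_radius_km = as.list(design$chosen_radius),
    log_offset = config$log_offset,
    cor_threshold = config$cor_threshold,
    buffer_km = c(config$buffer_inner_km, config$buffer_outer_km),
    k = cv$k, se_variant = config$se_variant,
    class_breaks = config$class_breaks,
    package_version = as.character(utils::packageVersion("densmmi")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(records = records, welch_log = welch_log,
                 welch_raw = welch_raw, background = background,
                 design = design, pruning = pruning, fit = fit, map = map,
                 classes = classes, cv = cv, manifest = manifest))
}

#' Write a model-selection table
#'
#' Tab-delimited table mirroring the standard presentation: one 0/1
#' membership column per term block, then K, AICc, delta, weight and logL,
#' models in AICc order.
#'
#' @param model_set a [enumerate_models()] result.
#' @param path output file.
#' @param top write only the first `top` models (default all).
#' @return `path`, invisibly.
#' @export
write_modsel_table <- function(model_set, path, top = Inf) {
  m <- model_set$models
  keep <- seq_len(min(nrow(m), top))
  tab <- cbind(as.data.frame(model_set$membership * 1L)[keep, , drop = FALSE],
               m[keep, c("K", "AICc", "delta", "weight", "logL")])
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the averaged-model report
#'
#' Tab-delimited: per block, the importance value, the averaged main and
#' quadratic estimates and their unconditional SEs.
#'
#' @param averaged a [model_average()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_averaged_table <- function(averaged, path) {
  blocks <- names(averaged$importance)
  tab <- data.frame(
    variable = c("(Intercept)", blocks),
    importance = c(NA, averaged$importance[blocks]),
    estimate = averaged$coefficients[c("(Intercept)", blocks)],
    se = averaged$se[c("(Intercept)", blocks)],
    estimate_q = NA_real_, se_q = NA_real_)
  for (b in blocks) {
    qn <- paste0(b, ".q")
    if (qn %in% names(averaged$coefficients)) {
      tab$estimate_q[tab$variable == b] <- averaged$coefficients[qn]
      tab$se_q[tab$variable == b] <- averaged$se[qn]
    }
  }
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NODATA")
  invisible(path)
}

#' Published model-selection table of the global wild pig analysis
#'
#' Loads the ten top-ranked models of the published seven-variable global
#' wild pig density analysis (n = 183 = 118 mainland + 65 background
#' records): per-variable membership flags, the parameter count K and the
#' Gaussian log-likelihood. Shipped with the package so the AICc, Akaike
#' weight, evidence-ratio and importance arithmetic can be exercised
#' without the original data.
#'
#' @param path file path; defaults to the copy installed with the package.
#' @return Data frame with seven 0/1 membership columns plus `K` and `logL`.
#' @export
read_modsel_table <- function(path = system.file("extdata",
                                                 "wildpig_modsel.tsv",
                                                 package = "densmmi")) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Recompute model-selection quantities from log-likelihoods
#'
#' Given a table of candidate models (0/1 membership flags per variable,
#' parameter count `K`, log-likelihood `logL`), recomputes AICc, Akaike
#' differences and weights at sample size `n`, and the per-variable
#' importance values (sum of weights over models containing the variable).
#' Applied to the shipped published table this regenerates its AICc, delta,
#' weight and importance columns from first principles.
#'
#' @param tab data frame with membership flag columns plus `K` and `logL`.
#' @param n sample size (default 183, the published analysis).
#' @return List: `models` (the table with `AICc`, `delta`, `weight` added)
#'   and `importance` (named vector over the flag columns).
#' @export
modsel_from_logl <- function(tab, n = 183) {
  stopifnot(all(c("K", "logL") %in% names(tab)))
  flags <- setdiff(names(tab), c("K", "logL"))
  tab$AICc <- compute_aicc(tab$logL, tab$K, n)
  aw <- akaike_weights(tab$AICc)
  tab$delta <- aw$delta
  tab$weight <- aw$weight
  imp <- vapply(flags, function(f) sum(tab$weight[tab[[f]] == 1]), 0)
  list(models = tab[order(tab$AICc), ], importance = imp)
}
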