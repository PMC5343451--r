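#' Build focal-mean surfaces at candidate radii
#'
#' For every covariate, computes the moving-window mean surface at each of
#' its candidate radii (a radius smaller than the cell size reads the raw
#' surface).
#'
#' @param grids named list of [raster_grid()], one per covariate.
#' @param specs named list of [covariate_spec()] giving the candidate radii;
#'   covariates without a spec default to the raw surface (radius 0).
#' @return Nested named list: `stack[[covariate]][[as.character(radius)]]`.
#' @export
build_focal_stack <- function(grids, specs = NULL) {
  out <- list()
  for (nm in names(grids)) {
    radii <- if (!is.null(specs) && nm %in% names(specs)) {
      specs[[nm]]$candidate_radii_km
    } else 0
    out[[nm]] <- stats::setNames(
      lapply(radii, function(r) focal_mean(grids[[nm]], r)),
      as.character(radii)
    )
  }
  out
}

#' Extract covariate values at record locations
#'
#' One row per record, one column per (covariate, radius) pair, reading the
#' focal-mean surface at the record's cell. Columns are named
#' `<covariate>_r<radius>`.
#'
#' @param records data frame of density records (columns `x`, `y`).
#' @param grids_by_radius nested list as returned by [build_focal_stack()].
#' @return Data frame of raw covariate values.
#' @export
extract_covariates <- function(records, grids_by_radius) {
  cols <- list()
  for (nm in names(grids_by_radius)) {
    for (r in names(grids_by_radius[[nm]])) {
      cols[[paste0(nm, "_r", r)]] <-
        grid_value_at(grids_by_radius[[nm]][[r]], records$x, records$y)
    }
  }
  as.data.frame(cols)
}

#' Select the best scale and form for one covariate
#'
#' Fits a univariate regression of the response on the covariate at each
#' candidate radius — linear, and additionally quadratic where the spec
#' allows a curvilinear relationship — and picks the radius with the lowest
#' AICc. The quadratic form is selected iff its AICc beats the linear form
#' at that radius. AICc ties break toward the smallest radius.
#'
#' @param response numeric response (log density).
#' @param candidates named list, radius (as character or number) -> raw
#'   covariate column.
#' @param spec the covariate's [covariate_spec()] (only `allow_quadratic`
#'   is used); alternatively pass `allow_quadratic` directly.
#' @param allow_quadratic overrides `spec$allow_quadratic` if given.
#' @return List: `radius_km`, `form` (`"linear"` or `"quadratic"`), and the
#'   per-candidate AICc table.
#' @export
select_scale <- function(response, candidates, spec = NULL,
                         allow_quadratic = NULL) {
  if (is.null(allow_quadratic)) {
    allow_quadratic <- !is.null(spec) && isTRUE(spec$allow_quadratic)
  }
  stopifnot(length(candidates) >= 1)
  radii <- as.numeric(names(candidates))
  rows <- list()
  for (i in seq_along(candidates)) {
    v <- as.numeric(candidates[[i]])
    if (stats::sd(v) == 0) {
      stop("degenerate-fit error: candidate column at radius ", radii[i],
           " km is constant", call. = FALSE)
    }
    z <- std01(v)
    flin <- fit_ols(response, matrix(z, ncol = 1))
    a_lin <- compute_aicc(flin$logL, length(flin$coefficients) + 1L, flin$n)
    a_quad <- NA_real_
    if (allow_quadratic) {
      blk <- term_block("v", z, quadratic = TRUE)
      fq <- fit_ols(response, blk$columns)
      a_quad <- compute_aicc(fq$logL, length(fq$coefficients) + 1L, fq$n)
    }
    rows[[i]] <- data.frame(radius_km = radii[i], aicc_linear = a_lin,
                            aicc_quadratic = a_quad)
  }
  tab <- do.call(rbind, rows)
  best <- pmin(tab$aicc_linear, tab$aicc_quadratic, na.rm = TRUE)
  ord <- order(best, tab$radius_km)   # ties -> smallest radius
  pick <- ord[1]
  form <- if (allow_quadratic && !is.na(tab$aicc_quadratic[pick]) &&
              tab$aicc_quadratic[pick] < tab$aicc_linear[pick]) {
    "quadratic"
  } else "linear"
  list(radius_km = tab$radius_km[pick], form = form, aicc = tab)
}

#' Standardise the analysis table
#'
#' Builds the design table the regression machinery consumes: the response
#' is `log(density + log_offset)` and every covariate column is centred and
#' scaled by its own mean and standard deviation. The scaling parameters are
#' retained so fitted models can be applied to new locations and maps.
#'
#' @param raw data frame of raw covariate columns (one per retained
#'   covariate, already at its chosen scale).
#' @param density response densities (animals/km^2, >= 0).
#' @param log_offset added before the log; must be > 0 if any density is 0.
#'   The default 1 maps zero-density background records to response 0.
#' @param chosen_radius optional named vector, covariate -> radius km (kept
#'   as metadata for prediction).
#' @return Object of class `design_table`: `response`, `columns` (matrix),
#'   `scaling` (data frame of per-column centre/scale), `chosen_radius`,
#'   `log_offset`.
#' @export
standardize_design <- function(raw, density, log_offset = 1,
                               chosen_radius = NULL) {
  density <- as.numeric(density)
  if (any(density < 0)) {
    stop("domain error: negative density", call. = FALSE)
  }
  if (any(density == 0) && log_offset <= 0) {
    stop("domain error: zero density requires log_offset > 0", call. = FALSE)
  }
  raw <- as.data.frame(raw)
  ctr <- vapply(raw, mean, 0)
  scl <- vapply(raw, stats::sd, 0)
  if (any(!is.finite(scl)) || any(scl == 0)) {
    stop("degenerate-fit error: constant covariate column", call. = FALSE)
  }
  cols <- scale(as.matrix(raw), center = ctr, scale = scl)
  attr(cols, "scaled:center") <- NULL
  attr(cols, "scaled:scale") <- NULL
  structure(list(
    response = log(density + log_offset),
    columns = cols,
    scaling = data.frame(column = names(raw), center = unname(ctr),
                         scale = unname(scl), stringsAsFactors = FALSE),
    chosen_radius = chosen_radius,
    log_offset = log_offset
  ), class = "design_table")
}

#' Invert the standardisation of a design column
#'
#' @param design a [standardize_design()] result.
#' @param column column name.
#' @return The raw (unstandardised) values of that column.
#' @export
unstandardize <- function(design, column) {
  i <- match(column, design$scaling$column)
  if (is.na(i)) stop("unknown column '", column, "'", call. = FALSE)
  design$columns[, column] * design$scaling$scale[i] + design$scaling$center[i]
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("design_table: %d records x %d covariates (log offset %g)\n",
              length(x$response), ncol(x$columns), x$log_offset))
  cat("  columns:", paste(colnames(x$columns), collapse = ", "), "\n")
  invisible(x)
}

#' Prune highly correlated covariates
#'
#' Greedy exclusion: while any pair of retained columns has
#' `|Pearson r| > threshold`, the most-correlated offending pair is found
#' and its lower-priority member dropped. Priority defaults to the absolute
#' univariate t-statistic of each column against the response (a
#' deterministic stand-in for expert judgement); an explicit priority
#' ordering can be supplied instead.
#'
#' @param design a [standardize_design()] result (or a plain matrix plus
#'   `response`).
#' @param threshold correlation threshold (default 0.70).
#' @param priority optional character vector, highest priority first; names
#'   not listed rank below listed ones.
#' @param response response vector, required if `design` is a bare matrix.
#' @return List: `retained` (column names), `dropped`, and `log` — a data
#'   frame of (dropped, kept, r) decisions.
#' @export
prune_correlated <- function(design, threshold = 0.70, priority = NULL,
                             response = NULL) {
  if (inherits(design, "design_table")) {
    X <- design$columns
    if (is.null(response)) response <- design$response
  } else {
    X <- as.matrix(design)
  }
  stopifnot(ncol(X) >= 1)
  nms <- colnames(X)
  rank_of <- if (!is.null(priority)) {
    r <- match(nms, priority)
    r[is.na(r)] <- length(priority) + seq_len(sum(is.na(r)))
    stats::setNames(r, nms)
  } else {
    if (is.null(response)) {
      stop("argument error: need a response (or explicit priority) to rank ",
           "columns", call. = FALSE)
    }
    tstat <- vapply(nms, function(nm) {
      f <- fit_ols(response, X[, nm, drop = FALSE])
      abs(f$coefficients[2] / f$se[2])
    }, 0)
    stats::setNames(rank(-tstat, ties.method = "first"), nms)
  }
  retained <- nms
  log_rows <- list()
  repeat {
    if (length(retained) < 2) break
    cm <- stats::cor(X[, retained, drop = FALSE])
    diag(cm) <- 0
    if (max(abs(cm)) <= threshold) break
    idx <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    a <- retained[idx[1]]; b <- retained[idx[2]]
    drop_nm <- if (rank_of[a] > rank_of[b]) a else b
    keep_nm <- if (drop_nm == a) b else a
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      dropped = drop_nm, kept = keep_nm, r = cm[idx[1], idx[2]],
      stringsAsFactors = FALSE)
    retained <- setdiff(retained, drop_nm)
  }
  list(retained = retained, dropped = setdiff(nms, retained),
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(dropped = character(0), kept = character(0),
                    r = numeric(0)))
}
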