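#' Fit the multimodel-inference density model
#'
#' The package's central fitting function. Takes a standardised design table
#' (log-density response plus centred/scaled covariate columns), builds one
#' term block per covariate — pairing a re-standardised quadratic column
#' with the main effect where a curvilinear response is hypothesised — fits
#' every subset of the blocks by ordinary least squares, ranks the candidate
#' models by AICc, and computes Akaike weights, full (zero-substitution)
#' model-averaged coefficients with unconditional standard errors, and
#' variable importance values.
#'
#' @param design a [standardize_design()] result.
#' @param quadratic character vector of covariate names that get a linked
#'   quadratic term.
#' @param se_variant unconditional SE estimator, see [model_average()].
#' @param max_blocks enumeration guard, see [enumerate_models()].
#' @return Object of class `density_mmi` with components `model_set`,
#'   `averaged`, `design`, `quadratic`, `call`. Supported methods:
#'   `print`, `summary`, `coef`, `fitted`, `residuals`, `predict`, `plot`,
#'   `simulate`, and [importance()].
#' @seealso [predict_map()] to apply the fit to covariate rasters,
#'   [cross_validate()] for k-fold validation.
#' @export
mmi_fit <- function(design, quadratic = character(0),
                    se_variant = c("sum_of_roots", "sqrt_sum"),
                    max_blocks = 20) {
  stopifnot(inherits(design, "design_table"))
  se_variant <- match.arg(se_variant)
  nms <- colnames(design$columns)
  bad <- setdiff(quadratic, nms)
  if (length(bad)) {
    stop("argument error: quadratic term(s) for unknown covariate(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  blocks <- lapply(nms, function(nm) {
    term_block(nm, design$columns[, nm], quadratic = nm %in% quadratic)
  })
  ms <- enumerate_models(design$response, blocks, max_blocks = max_blocks)
  avg <- model_average(ms, se_variant = se_variant)
  structure(list(model_set = ms, averaged = avg, design = design,
                 quadratic = quadratic, call = match.call()),
            class = "density_mmi")
}

# Full design matrix (all blocks, no intercept) of a fitted object.
full_block_matrix <- function(object) {
  do.call(cbind, lapply(object$model_set$blocks, `[[`, "columns"))
}

#' @export
print.density_mmi <- function(x, ...) {
  ms <- x$model_set$models
  cat(sprintf(
    "All-subsets AICc density model: %d models over %d blocks (n = %d)\n",
    nrow(ms), length(x$model_set$blocks), x$model_set$n))
  cat(sprintf("Top model: %s (AICc %.2f, weight %.2f, adj R^2 %.2f)\n",
              ms$terms[1], ms$AICc[1], ms$weight[1], ms$adj_r2[1]))
  cat("\nModel-averaged coefficients (unconditional SE):\n")
  print(data.frame(estimate = round(x$averaged$coefficients, 3),
                   se = round(x$averaged$se, 3)))
  invisible(x)
}

#' @export
summary.density_mmi <- function(object, n_models = 10, ...) {
  structure(list(
    selection = utils::head(object$model_set$models, n_models),
    averaged = data.frame(
      estimate = object$averaged$coefficients,
      se = object$averaged$se),
    importance = sort(object$averaged$importance, decreasing = TRUE),
    residual_sd = object$averaged$residual_sd,
    n = object$model_set$n
  ), class = "summary.density_mmi")
}

#' @export
print.summary.density_mmi <- function(x, ...) {
  cat("Model selection (top models by AICc):\n")
  print(transform(x$selection, AICc = round(AICc, 2),
                  delta = round(delta, 2), weight = round(weight, 2),
                  logL = round(logL, 2), adj_r2 = round(adj_r2, 2)),
        row.names = FALSE)
  cat("\nVariable importance values:\n")
  print(round(x$importance, 2))
  cat("\nModel-averaged coefficients:\n")
  print(round(x$averaged, 3))
  cat(sprintf("\nn = %d, weighted residual SD (log scale) = %.3f\n",
              x$n, x$residual_sd))
  invisible(x)
}

#' @export
coef.density_mmi <- function(object, ...) object$averaged$coefficients

#' @export
fitted.density_mmi <- function(object, ...) {
  X <- full_block_matrix(object)
  b <- object$averaged$coefficients
  drop(b["(Intercept)"] + X[, setdiff(names(b), "(Intercept)"),
                            drop = FALSE] %*%
         b[setdiff(names(b), "(Intercept)")])
}

#' @export
residuals.density_mmi <- function(object, ...) {
  object$design$response - fitted(object)
}

#' Variable importance of a fitted density model
#'
#' @param object a [mmi_fit()] result (or a `model_set`).
#' @return Named vector of importance values in \[0, 1\].
#' @export
importance <- function(object) {
  if (inherits(object, "density_mmi")) return(object$averaged$importance)
  variable_importance(object)
}

#' @export
#' @importFrom stats simulate
simulate.density_mmi <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- as.data.frame(replicate(
    nsim, mu + stats::rnorm(length(mu), sd = object$averaged$residual_sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Predict from a fitted density model
#'
#' With `newdata` a data frame of raw covariate values (one column per
#' covariate, at the covariate's chosen scale), values are standardised with
#' the training centring/scale, block terms (including quadratics) formed,
#' and the model-averaged coefficients applied. `type = "log"` returns the
#' linear predictor on the log scale; `type = "density"` back-transforms
#' with `exp`, subtracts the log offset, and floors at zero.
#'
#' @param object a [mmi_fit()] result.
#' @param newdata data frame of raw covariate values; omitted = training
#'   data.
#' @param type `"log"` or `"density"`.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.density_mmi <- function(object, newdata = NULL,
                                type = c("log", "density"), ...) {
  type <- match.arg(type)
  eta <- if (is.null(newdata)) {
    fitted(object)
  } else {
    b <- object$averaged$coefficients
    pred <- rep(b[["(Intercept)"]], nrow(newdata))
    sc <- object$design$scaling
    for (blk in object$model_set$blocks) {
      nm <- blk$name
      if (!nm %in% names(newdata)) {
        stop("configuration error: newdata lacks covariate '", nm, "'",
             call. = FALSE)
      }
      i <- match(nm, sc$column)
      z <- (newdata[[nm]] - sc$center[i]) / sc$scale[i]
      pred <- pred + b[[nm]] * z
      if (blk$quadratic) {
        pred <- pred + b[[paste0(nm, ".q")]] * (z^2 - blk$q_center) /
          blk$q_scale
      }
    }
    pred
  }
  if (type == "log") return(eta)
  pmax(exp(eta) - object$design$log_offset, 0)
}

#' Response curves of a fitted density model
#'
#' Plots the model-averaged predicted log density against each covariate
#' over the range observed in training, holding all other covariates at
#' their mean (standardised 0).
#'
#' @param x a [mmi_fit()] result.
#' @param covariates which covariates to plot (default all blocks).
#' @param npts curve resolution.
#' @param ... passed to [graphics::plot()].
#' @export
plot.density_mmi <- function(x, covariates = NULL, npts = 100, ...) {
  blocks <- x$model_set$blocks
  if (is.null(covariates)) covariates <- vapply(blocks, `[[`, "", "name")
  b <- x$averaged$coefficients
  nb <- length(covariates)
  mfrow_old <- graphics::par(mfrow = c(ceiling(nb / 3), min(nb, 3)))
  on.exit(graphics::par(mfrow_old))
  sc <- x$design$scaling
  for (nm in covariates) {
    blk <- blocks[[nm]]
    i <- match(nm, sc$column)
    zr <- range(blk$columns[, nm])
    z <- seq(zr[1], zr[2], length.out = npts)
    eta <- b[["(Intercept)"]] + b[[nm]] * z
    if (blk$quadratic) {
      eta <- eta + b[[paste0(nm, ".q")]] * (z^2 - blk$q_center) / blk$q_scale
    }
    raw <- z * sc$scale[i] + sc$center[i]
    graphics::plot(raw, eta, type = "l", xlab = nm,
                   ylab = "log density", ...)
  }
  invisible(x)
}
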