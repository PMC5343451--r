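#' Huberty's rule of thumb for the number of CV folds
#'
#' The heuristic held-out fraction for validating a model with `p`
#' predictors is `h = 1 / (1 + sqrt(p - 1))`; the corresponding number of
#' folds is `k = ceiling(1 / h) = ceiling(1 + sqrt(p - 1))`. With the seven
#' retained predictors of the motivating analysis this gives k = 4.
#'
#' @param p number of predictor variables (>= 2).
#' @return Integer number of folds.
#' @export
huberty_k <- function(p) {
  if (p < 2) stop("domain error: Huberty's rule needs p >= 2", call. = FALSE)
  as.integer(ceiling(1 + sqrt(p - 1)))
}

#' Random balanced k-fold partition
#'
#' @param n number of records.
#' @param k number of folds, `2 <= k <= n`.
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..k`; fold sizes differ by at
#'   most one.
#' @export
kfold_split <- function(n, k, seed = 1L) {
  if (k > n) stop("argument error: k must not exceed n", call. = FALSE)
  if (k < 2) stop("argument error: k must be >= 2", call. = FALSE)
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' k-fold cross-validation of the averaged density model
#'
#' Splits the records into k balanced folds; for each fold the candidate
#' models are refit on the training part only and their averaged prediction
#' is evaluated on the held-out part, on the model (log-density) scale.
#' With `refit_selection = TRUE` the all-subsets enumeration and Akaike
#' weighting are rerun within each training fold; by default the model set
#' and weights of the full-data fit are held fixed and only the candidate
#' models' coefficients are refit per fold. Reports the pooled mean squared
#' prediction error (MSPE) and the Pearson correlation between observed and
#' predicted held-out values with its t-statistic
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`.
#'
#' @param object a [mmi_fit()] result.
#' @param k number of folds, or `"huberty"` to apply [huberty_k()] to the
#'   number of blocks.
#' @param seed integer seed for the fold assignment.
#' @param refit_selection rerun enumeration + weighting per fold.
#' @return Object of class `cv_result`: `k`, `folds`, `mspe` (pooled, log
#'   scale), `per_fold_mspe`, `pearson_r`, `t`, `df`, `observed`,
#'   `predicted`, `seed`.
#' @export
cross_validate <- function(object, k = "huberty", seed = 1L,
                           refit_selection = FALSE) {
  stopifnot(inherits(object, "density_mmi"))
  y <- object$design$response
  n <- length(y)
  blocks <- object$model_set$blocks
  if (identical(k, "huberty")) k <- huberty_k(length(blocks))
  k <- as.integer(k)
  folds <- kfold_split(n, k, seed = seed)
  X <- full_block_matrix(object)
  w_full <- object$model_set$models$weight
  membership <- object$model_set$membership
  pred <- numeric(n)
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    ytr <- y[!test]
    if (sum(!test) <= ncol(X) + 1) {
      stop("fold error: fold ", f, " leaves too few training records (",
           sum(!test), ") to fit ", ncol(X), " coefficients", call. = FALSE)
    }
    blocks_tr <- lapply(blocks, function(bl) {
      bl$columns <- bl$columns[!test, , drop = FALSE]
      bl
    })
    if (refit_selection) {
      ms_tr <- enumerate_models(ytr, blocks_tr)
      avg_tr <- model_average(ms_tr)
      b <- avg_tr$coefficients
    } else {
      # fixed structure: same model list and weights, coefficients refit
      coefs <- matrix(0, length(w_full),
                      1L + ncol(X),
                      dimnames = list(NULL, c("(Intercept)", colnames(X))))
      for (i in seq_along(w_full)) {
        inc <- membership[i, ]
        Xi <- if (any(inc)) {
          do.call(cbind, lapply(blocks_tr[inc], `[[`, "columns"))
        } else NULL
        fit <- fit_ols(ytr, Xi)
        coefs[i, names(fit$coefficients)] <- fit$coefficients
      }
      b <- colSums(w_full * coefs)
    }
    eta <- b[["(Intercept)"]] +
      drop(X[test, , drop = FALSE] %*% b[colnames(X)])
    pred[test] <- eta
    per_fold[f] <- mean((y[test] - eta)^2)
  }
  r <- stats::cor(y, pred)
  structure(list(
    k = k, folds = folds,
    mspe = mean((y - pred)^2),
    per_fold_mspe = per_fold,
    pearson_r = r,
    t = r * sqrt(n - 2) / sqrt(1 - r^2),
    df = n - 2L,
    observed = y, predicted = pred, seed = seed,
    refit_selection = refit_selection
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d%s)\n", x$k, x$seed,
              if (x$refit_selection) ", selection refit per fold" else ""))
  cat(sprintf("  MSPE (log scale): %.3f\n", x$mspe))
  cat(sprintf("  Pearson r (obs vs pred): %.3f (t = %.3f, df = %d)\n",
              x$pearson_r, x$t, x$df))
  invisible(x)
}

#' Write a cross-validation report
#'
#' Tab-delimited: one row per fold plus a pooled row with r, t and df.
#'
#' @param cv a [cross_validate()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  tab <- data.frame(
    fold = c(seq_len(cv$k), NA),
    mspe = c(cv$per_fold_mspe, cv$mspe),
    pearson_r = c(rep(NA, cv$k), cv$pearson_r),
    t = c(rep(NA, cv$k), cv$t),
    df = c(rep(NA, cv$k), cv$df),
    k = cv$k, seed = cv$seed
  )
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NODATA")
  invisible(path)
}
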