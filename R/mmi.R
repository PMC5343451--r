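#' Ordinary least squares fit with Gaussian log-likelihood
#'
#' Fits `response ~ intercept + columns` by QR least squares and returns the
#' quantities the information-theoretic machinery needs: coefficients and
#' standard errors, residual sum of squares, the Gaussian maximum-likelihood
#' log-likelihood `logL = -(n/2) * (log(2*pi) + log(RSS/n) + 1)`, R^2 and
#' adjusted R^2.
#'
#' @param response numeric response vector.
#' @param columns numeric matrix (or NULL for the intercept-only model); the
#'   intercept is added internally.
#' @return Object of class `ols_fit`: `coefficients`, `se`, `rss`, `logL`,
#'   `r2`, `adj_r2`, `n`, `p` (number of non-intercept coefficients),
#'   `fitted`, `residuals`.
#' @export
fit_ols <- function(response, columns = NULL) {
  y <- as.numeric(response)
  n <- length(y)
  X <- if (is.null(columns) || NCOL(columns) == 0) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    columns <- as.matrix(columns)
    if (is.null(colnames(columns))) {
      colnames(columns) <- paste0("x", seq_len(ncol(columns)))
    }
    cbind("(Intercept)" = 1, columns)
  }
  p_all <- ncol(X)
  if (n <= p_all) {
    stop("degenerate-fit error: need more observations than coefficients",
         call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < p_all) {
    stop("degenerate-fit error: rank-deficient design", call. = FALSE)
  }
  coefs <- qr.coef(qx, y)
  fitted <- drop(X %*% coefs)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) {
    # constant response: the trivial fit, with R^2 = 0 and no likelihood
    return(structure(list(
      coefficients = coefs, se = rep(NA_real_, p_all), rss = 0,
      logL = NA_real_, r2 = 0, adj_r2 = 0, n = n, p = p_all - 1L,
      fitted = fitted, residuals = resid
    ), class = "ols_fit"))
  }
  if (rss <= 1e-12 * tss) {
    stop("perfect-fit error: residual sum of squares is zero, ",
         "log-likelihood undefined", call. = FALSE)
  }
  sigma2 <- rss / (n - p_all)
  rinv <- backsolve(qr.R(qx), diag(p_all))
  se <- sqrt(rowSums(rinv^2) * sigma2)
  names(se) <- colnames(X)[qx$pivot]
  se <- se[colnames(X)]
  r2 <- 1 - rss / tss
  structure(list(
    coefficients = coefs, se = se, rss = rss,
    logL = -(n / 2) * (log(2 * pi) + log(rss / n) + 1),
    r2 = r2,
    adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p_all),
    n = n, p = p_all - 1L, fitted = fitted, residuals = resid
  ), class = "ols_fit")
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2*logL + 2K + 2K(K+1)/(n - K - 1)`.
#'
#' @param logL Gaussian maximum-likelihood log-likelihood.
#' @param K number of estimated parameters, counting the intercept, every
#'   slope coefficient and the residual variance.
#' @param n sample size; must exceed `K + 1`.
#' @return The criterion value (lower is better).
#' @export
compute_aicc <- function(logL, K, n) {
  if (any(n <= K + 1)) {
    stop("domain error: AICc requires n > K + 1", call. = FALSE)
  }
  -2 * logL + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike differences and weights
#'
#' `delta_i = AICc_i - min(AICc)`; weights are the softmax of `-delta/2`,
#' computed with a max shift so that very large differences (the abiotic-only
#' family sits ~73 AICc units above the top model in the motivating
#' analysis) cannot underflow the normaliser.
#'
#' @param aicc numeric vector of AICc values (finite).
#' @return List with `delta` and `weight` (weights sum to 1).
#' @export
akaike_weights <- function(aicc) {
  if (!length(aicc) || !all(is.finite(aicc))) {
    stop("argument error: need >= 1 finite AICc value", call. = FALSE)
  }
  delta <- aicc - min(aicc)
  ew <- exp(-delta / 2)   # max shift: min delta is 0 by construction
  list(delta = delta, weight = ew / sum(ew))
}

#' Evidence ratio between two models
#'
#' @param weight_a,weight_b Akaike weights; `weight_b` must be positive.
#' @return `weight_a / weight_b`, the relative support for model a.
#' @export
evidence_ratio <- function(weight_a, weight_b) {
  if (any(weight_b <= 0)) {
    stop("division error: reference weight must be > 0", call. = FALSE)
  }
  weight_a / weight_b
}

#' Term block: a covariate's linked design columns
#'
#' A covariate enters candidate models as a block: its standardised main
#' column and, where the hypothesised relationship is curvilinear, a
#' quadratic column built as the square of the main column re-standardised
#' to mean 0 / sd 1. The two columns enter and leave models together
#' (hierarchy preserved). The quadratic centring and scale are stored so a
#' fitted model can be applied to new data.
#'
#' @param name block (covariate) name.
#' @param main standardised main-effect column.
#' @param quadratic add the re-standardised squared column.
#' @return Object of class `term_block`: `name`, `columns` (matrix with 1 or
#'   2 named columns), `quadratic`, `q_center`, `q_scale`.
#' @export
term_block <- function(name, main, quadratic = FALSE) {
  main <- as.numeric(main)
  cols <- matrix(main, ncol = 1, dimnames = list(NULL, name))
  q_center <- q_scale <- NA_real_
  if (quadratic) {
    sq <- main^2
    q_center <- mean(sq)
    q_scale <- stats::sd(sq)
    if (!is.finite(q_scale) || q_scale == 0) {
      stop("degenerate-fit error: quadratic column is constant", call. = FALSE)
    }
    cols <- cbind(cols, (sq - q_center) / q_scale)
    colnames(cols) <- c(name, paste0(name, ".q"))
  }
  structure(list(name = name, columns = cols, quadratic = quadratic,
                 q_center = q_center, q_scale = q_scale),
            class = "term_block")
}

#' All-subsets model enumeration ranked by AICc
#'
#' Fits every subset of the term blocks (including the intercept-only
#' model), computes each model's AICc with `K = #coefficients + 1` (the
#' residual variance counts as a parameter), and ranks the models. Akaike
#' differences and weights are filled over the full enumeration.
#' Rank-deficient subsets are excluded and logged.
#'
#' @param response numeric response (log density).
#' @param blocks list of [term_block()] objects.
#' @param max_blocks guard on enumeration size (`2^max_blocks` models).
#' @return Object of class `model_set`: `models` (data frame with columns
#'   `model`, `terms`, `K`, `logL`, `AICc`, `delta`, `weight`, `adj_r2`,
#'   sorted by AICc), `fits` (per-model named coefficient and SE vectors),
#'   `blocks`, `membership` (logical matrix model x block), `n`,
#'   `excluded` (log of skipped subsets).
#' @export
enumerate_models <- function(response, blocks, max_blocks = 20) {
  stopifnot(length(blocks) >= 1)
  if (length(blocks) > max_blocks) {
    stop("argument error: enumeration of 2^", length(blocks),
         " models refused (guard at 2^", max_blocks, ")", call. = FALSE)
  }
  names(blocks) <- vapply(blocks, `[[`, "", "name")
  B <- length(blocks)
  n_models <- 2L^B
  rows <- vector("list", n_models)
  fits <- vector("list", n_models)
  membership <- matrix(FALSE, n_models, B,
                       dimnames = list(NULL, names(blocks)))
  excluded <- character(0)
  for (m in seq_len(n_models) - 1L) {
    inc <- as.logical(bitwAnd(m, 2L^(seq_len(B) - 1L)) > 0L)
    X <- if (any(inc)) {
      do.call(cbind, lapply(blocks[inc], `[[`, "columns"))
    } else NULL
    fit <- tryCatch(fit_ols(response, X), error = function(e) e)
    lbl <- if (any(inc)) paste(names(blocks)[inc], collapse = "+") else "1"
    if (inherits(fit, "error")) {
      excluded <- c(excluded, paste0(lbl, ": ", conditionMessage(fit)))
      next
    }
    K <- length(fit$coefficients) + 1L
    rows[[m + 1L]] <- data.frame(
      model = m + 1L, terms = lbl, K = K, logL = fit$logL,
      AICc = compute_aicc(fit$logL, K, fit$n), adj_r2 = fit$adj_r2,
      stringsAsFactors = FALSE
    )
    fits[[m + 1L]] <- list(coefficients = fit$coefficients, se = fit$se)
    membership[m + 1L, ] <- inc
  }
  keep <- !vapply(rows, is.null, TRUE)
  tab <- do.call(rbind, rows[keep])
  fits <- fits[keep]
  membership <- membership[keep, , drop = FALSE]
  ord <- order(tab$AICc)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  membership <- membership[ord, , drop = FALSE]
  aw <- akaike_weights(tab$AICc)
  tab$delta <- aw$delta
  tab$weight <- aw$weight
  tab <- tab[, c("model", "terms", "K", "logL", "AICc", "delta", "weight",
                 "adj_r2")]
  rownames(tab) <- NULL
  structure(list(models = tab, fits = fits, blocks = blocks,
                 membership = membership, n = length(response),
                 excluded = excluded),
            class = "model_set")
}

#' @export
print.model_set <- function(x, n = 10, ...) {
  cat(sprintf("model_set: %d candidate models over %d term blocks (n = %d)\n",
              nrow(x$models), length(x$blocks), x$n))
  print(utils::head(
    transform(x$models, AICc = round(AICc, 2), delta = round(delta, 2),
              weight = round(weight, 3), logL = round(logL, 2),
              adj_r2 = round(adj_r2, 3)), n),
    row.names = FALSE)
  if (length(x$excluded)) {
    cat(length(x$excluded), "subset(s) excluded as rank-deficient\n")
  }
  invisible(x)
}

#' Variable importance values
#'
#' The importance of a term block is the sum of Akaike weights of all
#' candidate models that contain it; it lies in \[0, 1\].
#'
#' @param model_set a [enumerate_models()] result.
#' @return Named numeric vector, one value per block.
#' @export
variable_importance <- function(model_set) {
  w <- model_set$models$weight
  colSums(model_set$membership * w)
}

#' Full (unconditional) model averaging
#'
#' Averages each coefficient over the entire model set with Akaike weights,
#' substituting 0 in models where the term is absent ("full" averaging), and
#' reports unconditional standard errors that combine within-model sampling
#' variance and between-model spread. The default SE estimator is the
#' weighted sum of roots, `SE = sum_i w_i * sqrt(var_i + (b_i - bbar)^2)`
#' (with `var_i = 0` where the term is absent); the square-root of the
#' weighted sum, `sqrt(sum_i w_i * (var_i + (b_i - bbar)^2))`, is available
#' as the `"sqrt_sum"` variant.
#'
#' @param model_set a [enumerate_models()] result.
#' @param se_variant `"sum_of_roots"` (default) or `"sqrt_sum"`.
#' @return Object of class `averaged_model`: `coefficients`, `se` (named,
#'   intercept first), `importance` per block, `blocks`, `residual_sd`
#'   (weighted residual SD of the member models), `n`, `se_variant`.
#' @export
model_average <- function(model_set, se_variant = c("sum_of_roots",
                                                    "sqrt_sum")) {
  se_variant <- match.arg(se_variant)
  if (!inherits(model_set, "model_set") || !nrow(model_set$models)) {
    stop("argument error: empty model set", call. = FALSE)
  }
  w <- model_set$models$weight
  coef_names <- unique(unlist(lapply(model_set$fits,
                                     function(f) names(f$coefficients))))
  coef_names <- c("(Intercept)", setdiff(coef_names, "(Intercept)"))
  nm <- length(coef_names); M <- length(w)
  B <- matrix(0, M, nm, dimnames = list(NULL, coef_names))
  V <- matrix(0, M, nm, dimnames = list(NULL, coef_names))
  for (i in seq_len(M)) {
    f <- model_set$fits[[i]]
    B[i, names(f$coefficients)] <- f$coefficients
    V[i, names(f$se)] <- f$se^2
  }
  bbar <- colSums(w * B)
  dev2 <- sweep(B, 2, bbar)^2
  se <- if (se_variant == "sum_of_roots") {
    colSums(w * sqrt(V + dev2))
  } else {
    sqrt(colSums(w * (V + dev2)))
  }
  # weighted residual SD (ML scale) of member models, used by the optional
  # log-normal back-transform correction
  n <- model_set$n
  rss <- exp((-2 * model_set$models$logL / n) - log(2 * pi) - 1) * n
  resid_sd <- sqrt(sum(w * rss / n))
  structure(list(coefficients = bbar, se = se,
                 importance = variable_importance(model_set),
                 blocks = model_set$blocks, residual_sd = resid_sd,
                 n = n, se_variant = se_variant),
            class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat("Full model-averaged coefficients (unconditional SE):\n")
  tab <- data.frame(estimate = round(x$coefficients, 3),
                    se = round(x$se, 3))
  print(tab)
  cat("\nVariable importance values:\n")
  print(round(sort(x$importance, decreasing = TRUE), 2))
  invisible(x)
}
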