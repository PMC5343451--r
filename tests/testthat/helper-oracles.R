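# Independent oracles and fixture builders used across the suite.

# Brute-force focal mean: per-cell loop over every other cell, distance by
# cell centres, inclusive radius, NA cells excluded.
brute_focal <- function(grid, radius) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v); cs <- grid$cellsize
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0; cnt <- 0
    for (ii in seq_len(nr)) for (jj in seq_len(nc)) {
      d2 <- ((ii - i)^2 + (jj - j)^2) * cs^2
      if (d2 <= radius^2 + 1e-9 && !is.na(v[ii, jj])) {
        acc <- acc + v[ii, jj]; cnt <- cnt + 1
      }
    }
    if (cnt > 0) out[i, j] <- acc / cnt
  }
  out
}

# Normal-equations OLS oracle.
brute_ols_coef <- function(y, X) {
  Xf <- cbind(1, X)
  solve(t(Xf) %*% Xf, t(Xf) %*% y)[, 1]
}

# Independent all-subsets oracle: refits every subset from scratch with
# stats::lm / stats::logLik and recomputes AICc from the closed form.
brute_enumerate <- function(y, block_cols) {
  B <- length(block_cols)
  n <- length(y)
  out <- list()
  for (m in 0:(2^B - 1)) {
    inc <- as.logical(bitwAnd(m, 2^(seq_len(B) - 1)) > 0)
    dat <- if (any(inc)) {
      as.data.frame(do.call(cbind, block_cols[inc]))
    } else data.frame(row.names = seq_len(n))
    dat$y <- y
    fit <- stats::lm(y ~ ., data = dat)
    ll <- as.numeric(stats::logLik(fit))
    K <- length(stats::coef(fit)) + 1
    aicc <- -2 * ll + 2 * K + 2 * K * (K + 1) / (n - K - 1)
    out[[m + 1]] <- data.frame(mask = m, K = K, logL = ll, AICc = aicc)
  }
  do.call(rbind, out)
}

# Empirical semivariogram at integer cell lags along rows/columns.
sample_semivariance <- function(m, lag) {
  dx <- (m[, seq_len(ncol(m) - lag)] - m[, seq_len(ncol(m) - lag) + lag])^2
  dy <- (m[seq_len(nrow(m) - lag), ] - m[seq_len(nrow(m) - lag) + lag, ])^2
  mean(c(dx, dy)) / 2
}

# Small standardised design table built from a given matrix of raw columns.
make_design <- function(raw, density, log_offset = 0) {
  standardize_design(as.data.frame(raw), density, log_offset = log_offset)
}

# Synthetic regression problem with a known block structure: n records,
# standard-normal covariates, response from given main/quad coefficients.
make_block_problem <- function(n, coefs, quadratic = character(0),
                               noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  raw <- as.data.frame(lapply(coefs, function(.) stats::rnorm(n)))
  names(raw) <- names(coefs)
  eta <- 0
  for (nm in names(coefs)) {
    z <- scale(raw[[nm]])[, 1]
    b <- coefs[[nm]]
    eta <- eta + b[["m"]] * z
    if ("q" %in% names(b)) eta <- eta + b[["q"]] * scale(z^2)[, 1]
  }
  y <- eta + stats::rnorm(n, sd = noise_sd)
  # density = exp(y), so the log response (offset 0) recovers y exactly
  list(raw = raw, response = y, density = exp(y))
}
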