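test_that("fit_ols reproduces the hand-solved three-point problem", {
  f <- fit_ols(c(1, 2, 4), matrix(c(0, 1, 2), ncol = 1))
  expect_equal(unname(f$coefficients), c(5 / 6, 1.5), tolerance = 1e-12)
  expect_equal(f$rss, 1 / 6, tolerance = 1e-12)
})

test_that("fit_ols matches the normal-equations oracle on random problems", {
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(150), 50, 3)
    y <- drop(X %*% c(1, -2, 0.5)) + rnorm(50)
    f <- fit_ols(y, X)
    expect_equal(unname(f$coefficients), unname(brute_ols_coef(y, X)),
                 tolerance = 1e-8)
    # likelihood closed form
    expect_equal(f$logL,
                 -(50 / 2) * (log(2 * pi) + log(f$rss / 50) + 1),
                 tolerance = 1e-12)
    # se and adj R2 agree with stats::lm
    lmf <- summary(stats::lm(y ~ X))
    expect_equal(unname(f$se), unname(lmf$coefficients[, 2]),
                 tolerance = 1e-10)
    expect_equal(f$adj_r2, lmf$adj.r.squared, tolerance = 1e-10)
  }
})

test_that("fit_ols degenerate cases behave as specified", {
  # constant zero response: zero coefficients and R2 = 0
  f0 <- fit_ols(rep(0, 10), matrix(rnorm(10), ncol = 1))
  expect_equal(unname(f0$coefficients), c(0, 0), tolerance = 1e-12)
  expect_equal(f0$r2, 0)
  # rank deficiency
  x <- rnorm(20)
  expect_error(fit_ols(rnorm(20), cbind(x, 2 * x)), "degenerate-fit")
  # exact linear response: perfect fit has no likelihood
  expect_error(fit_ols(2 * x + 1, cbind(x)), "perfect-fit")
})

test_that("compute_aicc applies the small-sample correction", {
  expect_equal(compute_aicc(0, 1, 100), 2 + 4 / 98, tolerance = 1e-12)
  expect_error(compute_aicc(-10, 10, 11), "domain error")
  expect_error(compute_aicc(-10, 10, 10), "domain error")
})

test_that("Akaike weights are a shifted softmax summing to one", {
  expect_equal(akaike_weights(123.4)$weight, 1)
  expect_equal(akaike_weights(c(10, 10))$weight, c(0.5, 0.5))
  set.seed(2)
  a <- runif(20, 100, 400)
  w <- akaike_weights(a)
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  # invariant under adding a constant to every AICc
  w2 <- akaike_weights(a + 57.3)
  expect_equal(w$weight, w2$weight, tolerance = 1e-12)
  # huge spreads do not underflow the normaliser
  w3 <- akaike_weights(c(237.94, 311.30, 1200))
  expect_true(all(is.finite(w3$weight)))
  expect_equal(sum(w3$weight), 1, tolerance = 1e-12)
})

test_that("evidence ratios behave algebraically", {
  expect_equal(evidence_ratio(0.4, 0.4), 1)
  w <- akaike_weights(c(100, 104))$weight
  expect_equal(evidence_ratio(w[1], w[2]), exp(2), tolerance = 1e-12)
  expect_error(evidence_ratio(0.5, 0), "division")
})

test_that("enumeration covers all subsets with the published K convention", {
  prob <- make_block_problem(
    n = 80,
    coefs = list(pet = c(m = 0.4, q = -0.2),
                 carnivore_richness = c(m = -0.25),
                 precip_wet = c(m = 0.2), unvegetated = c(m = -0.2),
                 agriculture = c(m = 0.2, q = -0.1),
                 precip_dry = c(m = 0.1), forest = c(m = 0)),
    quadratic = c("pet", "agriculture"), seed = 3)
  d <- make_design(prob$raw, prob$density)
  fit <- mmi_fit(d, quadratic = c("pet", "agriculture"))
  ms <- fit$model_set
  expect_equal(nrow(ms$models), 128)   # 2^7
  # full model: 7 blocks, 2 quadratics -> 9 slopes + intercept + variance
  full <- ms$models[ms$models$terms ==
                      paste(names(prob$raw), collapse = "+"), ]
  expect_equal(full$K, 11)
  # six-block model without forest: K = 10
  six <- ms$models[ms$models$terms ==
                     paste(setdiff(names(prob$raw), "forest"),
                           collapse = "+"), ]
  expect_equal(six$K, 10)
  # sorted by AICc with weights summing to 1
  expect_false(is.unsorted(ms$models$AICc))
  expect_equal(sum(ms$models$weight), 1, tolerance = 1e-12)

  # nested property: adding a block never decreases logL
  for (i in seq_len(nrow(ms$models))) {
    sub <- ms$membership[i, ]
    sups <- which(apply(ms$membership, 1, function(m) all(m[sub])))
    expect_true(all(ms$models$logL[sups] >= ms$models$logL[i] - 1e-8))
  }
})

test_that("enumeration matches an independent refit-from-scratch oracle for 4 blocks", {
  set.seed(10)
  n <- 60
  cols <- list(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  y <- 0.8 * cols$a - 0.5 * cols$b + rnorm(n, sd = 0.6)
  blocks <- lapply(names(cols), function(nm) term_block(nm, scale(cols[[nm]])[, 1]))
  ms <- enumerate_models(y, blocks)
  oracle <- brute_enumerate(y, lapply(cols, function(v) scale(v)[, 1]))
  expect_equal(nrow(ms$models), 16)
  # match per subset on K, logL and AICc
  oracle$terms <- vapply(oracle$mask, function(m) {
    inc <- as.logical(bitwAnd(m, 2^(0:3)) > 0)
    if (any(inc)) paste(names(cols)[inc], collapse = "+") else "1"
  }, "")
  merged <- merge(ms$models, oracle, by = "terms",
                  suffixes = c("", ".oracle"))
  expect_equal(nrow(merged), 16)
  expect_equal(merged$K, merged$K.oracle)
  expect_equal(merged$logL, merged$logL.oracle, tolerance = 1e-8)
  expect_equal(merged$AICc, merged$AICc.oracle, tolerance = 1e-8)
})

test_that("AICc ordering is invariant to affine rescaling of covariates", {
  set.seed(21)
  n <- 70
  raw <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 0.6 * raw$a - 0.4 * raw$c + rnorm(n, sd = 0.5)
  blocks1 <- lapply(names(raw), function(nm) term_block(nm, raw[[nm]]))
  raw2 <- data.frame(a = 5 * raw$a - 3, b = -0.2 * raw$b, c = raw$c + 100)
  blocks2 <- lapply(names(raw2), function(nm) term_block(nm, raw2[[nm]]))
  m1 <- enumerate_models(y, blocks1)
  m2 <- enumerate_models(y, blocks2)
  expect_equal(m1$models$terms, m2$models$terms)
  expect_equal(m1$models$AICc, m2$models$AICc, tolerance = 1e-8)
})

# minimal hand-built model_set for averaging arithmetic
toy_model_set <- function(weights, fits, membership, n = 50) {
  structure(list(
    models = data.frame(model = seq_along(weights), terms = "x",
                        K = 3, logL = -10, AICc = 20,
                        delta = 0, weight = weights, adj_r2 = 0.5),
    fits = fits,
    blocks = list(x = term_block("x", rnorm(n))),
    membership = membership, n = n, excluded = character(0)
  ), class = "model_set")
}

test_that("full model averaging uses zero substitution and weight algebra", {
  # two models, weights 0.75/0.25, term only in the first with beta = 2
  ms <- toy_model_set(
    weights = c(0.75, 0.25),
    fits = list(
      list(coefficients = c("(Intercept)" = 1, x = 2),
           se = c("(Intercept)" = 0.1, x = 0.4)),
      list(coefficients = c("(Intercept)" = 1.2),
           se = c("(Intercept)" = 0.1))),
    membership = matrix(c(TRUE, FALSE), 2, 1,
                        dimnames = list(NULL, "x")))
  avg <- model_average(ms)
  expect_equal(unname(avg$coefficients["x"]), 1.5)
  # SE: 0.75*sqrt(0.4^2 + 0.25) + 0.25*sqrt(0 + 2.25)
  expect_equal(unname(avg$se["x"]),
               0.75 * sqrt(0.16 + 0.25) + 0.25 * 1.5, tolerance = 1e-12)
  expect_equal(unname(avg$importance["x"]), 0.75)
  # sqrt-of-weighted-sum variant
  avg2 <- model_average(ms, se_variant = "sqrt_sum")
  expect_equal(unname(avg2$se["x"]),
               sqrt(0.75 * (0.16 + 0.25) + 0.25 * 2.25), tolerance = 1e-12)

  # single model with weight 1: averaging returns that model
  ms1 <- toy_model_set(
    weights = 1,
    fits = list(list(coefficients = c("(Intercept)" = 0.3, x = -1.1),
                     se = c("(Intercept)" = 0.05, x = 0.2))),
    membership = matrix(TRUE, 1, 1, dimnames = list(NULL, "x")))
  avg1 <- model_average(ms1)
  expect_equal(unname(avg1$coefficients), c(0.3, -1.1))
  expect_equal(unname(avg1$se), c(0.05, 0.2))
})

test_that("averaged coefficients stay inside the convex hull of per-model estimates", {
  prob <- make_block_problem(
    n = 90, coefs = list(a = c(m = 0.5), b = c(m = -0.3), c = c(m = 0)),
    seed = 17)
  d <- make_design(prob$raw, prob$density)
  fit <- mmi_fit(d)
  for (nm in colnames(d$columns)) {
    ests <- vapply(fit$model_set$fits, function(f) {
      if (nm %in% names(f$coefficients)) f$coefficients[[nm]] else 0
    }, 0)
    b <- fit$averaged$coefficients[[nm]]
    expect_gte(b, min(ests) - 1e-12)
    expect_lte(b, max(ests) + 1e-12)
  }
  # importance equals the weight mass of models containing each block
  imp <- variable_importance(fit$model_set)
  man <- colSums(fit$model_set$membership * fit$model_set$models$weight)
  expect_equal(imp, man)
  expect_true(all(imp >= 0 & imp <= 1))
})

test_that("the fitted model object supports the standard S3 interface", {
  prob <- make_block_problem(
    n = 100, coefs = list(a = c(m = 0.6, q = -0.3), b = c(m = -0.4)),
    quadratic = "a", seed = 5)
  d <- make_design(prob$raw, prob$density)
  fit <- mmi_fit(d, quadratic = "a")
  expect_s3_class(fit, "density_mmi")
  expect_named(coef(fit),
               c("(Intercept)", "a", "a.q", "b"))
  expect_equal(length(fitted(fit)), 100)
  expect_equal(residuals(fit), d$response - fitted(fit))
  expect_output(print(fit), "Model-averaged coefficients")
  expect_output(print(summary(fit)), "Variable importance")
  # training-data predict equals fitted; density scale back-transforms
  expect_equal(predict(fit), fitted(fit))
  pd <- predict(fit, newdata = prob$raw, type = "density")
  expect_true(all(pd >= 0))
  expect_equal(predict(fit, newdata = prob$raw, type = "log"),
               fitted(fit), tolerance = 1e-10)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(100, 3))
})
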