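tpl <- bundled_template("original")

test_that("lag-one excess matches brute-force enumeration on a toy matrix", {
  m <- rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0))
  r <- lag_one_excess(m, n_boot = 0)
  # both column rates 0.5; observed joint 0.5; expected 0.25; excess 25%
  expect_equal(r$per_pair$observed, 0.5)
  expect_equal(r$per_pair$expected, 0.25)
  expect_equal(r$excess_pct, 25)
  expect_error(lag_one_excess(m[1, , drop = FALSE]), "at least 2")
})

test_that("independent Bernoulli columns have no lag-one excess", {
  set.seed(23)
  m <- matrix(rbinom(4000 * 30, 1, 0.02), 4000, 30)
  r <- lag_one_excess(m, n_boot = 200, seed = 5)
  expect_lt(abs(r$excess_pct), 3 * r$se_pct)
})

test_that("position-heterogeneous templates are corrected by the product rule", {
  # strongly uneven column rates induce no spurious excess because the
  # expectation uses each pair's own rates
  set.seed(29)
  rates <- rep(c(0.001, 0.08), 15)
  m <- vapply(rates, function(p) rbinom(5000, 1, p), numeric(5000))
  r <- lag_one_excess(m, n_boot = 200, seed = 6)
  expect_lt(abs(r$excess_pct), 3 * r$se_pct)
})

test_that("the dispersion test distinguishes Poisson from Gamma-mixed totals", {
  set.seed(31)
  pois <- rpois(2000, 1.5)
  dp <- dispersion_test(pois)
  expect_gt(dp$p_value, 0.05)
  expect_equal(dp$dispersion_index, 1, tolerance = 0.1)
  mixed <- rpois(2000, 1.5 * rgamma(2000, shape = 1, rate = 1))
  dm <- dispersion_test(mixed)
  expect_gt(dm$variance, dm$mean)
  expect_lt(dm$p_value, 0.05)
  # degenerate inputs
  expect_lt(dispersion_test(rep(2L, 500))$dispersion_index, 1)
  expect_true(is.na(dispersion_test(rep(0L, 500))$p_value))
  expect_error(dispersion_test(rpois(10, 1)), "at least 30")
})

test_that("the GLM design encodes bases, position and the structure window", {
  prof <- toy_structure_profile(tpl)
  X <- build_design(tpl, prof)
  pos <- attr(X, "positions")
  expect_identical(pos, 4:67)
  expect_equal(nrow(X), 64)
  expect_equal(ncol(X), 11)       # 3 base indicators + position + 7 structure
  tb <- tpl$template_ext_order[pos]
  expect_identical(X$base_T, as.integer(tb == "T"))
  expect_identical(X$base_C + X$base_G + X$base_T, as.integer(tb != "A"))
  # structure features at offset k are the profile shifted by k
  for (k in c(-3, 0, 3)) {
    nm <- if (k < 0) paste0("s_m", -k) else if (k == 0) "s_0" else paste0("s_p", k)
    expect_equal(X[[nm]], prof$s[pos + k])
  }
  # template A absorbed in the bias: a homopolymer-A design has all-zero
  # base indicators
  polyA <- template_spec("pA", strrep("A", 80), 4)
  Xa <- build_design(polyA, toy_structure_profile(polyA))
  expect_true(all(Xa$base_C == 0 & Xa$base_G == 0 & Xa$base_T == 0))
  expect_error(build_design(tpl, prof[1:40, ]), "cover")
})

test_that("the binomial GLM recovers known weights from simulated outcomes", {
  prof <- toy_structure_profile(tpl)
  X <- build_design(tpl, prof)
  # drop collinear structure columns for a clean recovery target
  X_small <- X[, c("base_C", "base_G", "base_T", "position", "s_0")]
  attr(X_small, "positions") <- attr(X, "positions")
  beta <- c(-4.5, 0.3, -0.2, 1.6, 0.01, 0.8)
  eta <- as.vector(cbind(1, as.matrix(X_small)) %*% beta)
  set.seed(37)
  n_per <- 40000
  errs <- rbinom(nrow(X_small), n_per, plogis(eta))
  fit <- fit_glm(X_small, errs, rep(n_per, nrow(X_small)))
  est <- fit$coefficients
  z <- abs(est$estimate - beta) / est$se
  expect_true(all(z < 3))
  expect_lt(mean(z), 1.5)
  # self-prediction is essentially perfect at this depth
  r2 <- glm_predict_r2(fit, X_small, errs, rep(n_per, nrow(X_small)))
  expect_gt(r2$r_squared, 0.95)
})

test_that("outcomes independent of all features give R-squared near zero", {
  prof <- toy_structure_profile(tpl)
  X <- build_design(tpl, prof)
  set.seed(43)
  errs <- rbinom(nrow(X), 5000, 0.01)      # flat true rate
  fit <- fit_glm(X, errs, rep(5000, nrow(X)))
  r2 <- glm_predict_r2(fit, X, errs, rep(5000, nrow(X)))
  # in-sample R2 on pure noise stays small (11 features, 64 positions)
  expect_lt(r2$r_squared, 0.4)
})

test_that("template-T-driven errors yield a positive T weight and transfer across templates", {
  swp <- bundled_template("swapped")
  dp <- load_preset("dpo4_paper")
  cond <- cation_condition(mn_uM = 800)
  fits <- list()
  data <- list()
  for (t in list(tpl, swp)) {
    sim <- simulate_extension(t, dp, cond, n = 4000, seed = 47,
                              noise_sub_prob = 1e-3)
    q <- quantify_well(sim$insert, t, keep_error_matrix = TRUE)
    X <- build_design(t, toy_structure_profile(t))
    pos <- attr(X, "positions")
    errs <- colSums(q$error_matrix)[pos]
    tots <- rep(nrow(q$error_matrix), length(pos))
    fits[[t$name]] <- fit_glm(X, errs, tots)
    data[[t$name]] <- list(X = X, errs = errs, tots = tots)
  }
  for (nm in names(fits)) {
    co <- fits[[nm]]$coefficients
    wT <- co[co$term == "base_T", ]
    expect_gt(wT$estimate, 0)
    expect_gt(wT$estimate / wT$se, 3)     # clearly resolved, not marginal
  }
  # weights fitted on one template predict the other's spatial profile
  cross <- glm_predict_r2(fits$original, data$swapped$X,
                          data$swapped$errs, data$swapped$tots)
  expect_gt(cross$r_squared, 0.5)
})

test_that("GLM fits reproduce their own generating R-squared", {
  prof <- toy_structure_profile(tpl)
  X <- build_design(tpl, prof)
  set.seed(53)
  beta <- c(-5.2, 0.2, 0.1, 2.0, 0.005, rep(0.2, 7))
  eta <- as.vector(cbind(1, as.matrix(X)) %*% beta)
  n_per <- 3000
  errs1 <- rbinom(nrow(X), n_per, plogis(eta))
  fit1 <- fit_glm(X, errs1, rep(n_per, nrow(X)))
  r2_1 <- glm_predict_r2(fit1, X, errs1, rep(n_per, nrow(X)))$r_squared
  # regenerate from the *fitted* model and refit
  errs2 <- rbinom(nrow(X), n_per, fit1$fitted_rates)
  fit2 <- fit_glm(X, errs2, rep(n_per, nrow(X)))
  r2_2 <- glm_predict_r2(fit2, X, errs2, rep(n_per, nrow(X)))$r_squared
  expect_lt(abs(r2_1 - r2_2), 0.05)
})
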