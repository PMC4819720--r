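test_that("shared connectivity equals column inner products", {
  W <- matrix(c(0, .5, .2, .5, 0, .1, .2, .1, 0), 3)
  prod <- shared_connectivity(W, W)
  expect_equal(prod, triple_loop_product(W, W))
  # diagonal entries are squared column norms
  expect_equal(diag(prod), colSums(W^2))
  expect_equal(shared_connectivity(matrix(0, 3, 3), W), matrix(0, 3, 3))
  expect_error(shared_connectivity(W, matrix(0, 4, 4)), "mismatch")

  taylorconn:::with_seed(8, {
    for (i in 1:20) {
      A <- matrix(rnorm(25), 5); A <- (A + t(A)) / 2; diag(A) <- 0
      B <- matrix(rnorm(25), 5); B <- (B + t(B)) / 2; diag(B) <- 0
      expect_lt(max(abs(shared_connectivity(A, B) -
                          triple_loop_product(A, B))), 1e-12)
    }
  })
})

test_that("term construction counts regressors per model variant", {
  stk <- small_stack(P = 12, D = 5)
  K <- function(v) ncol(build_terms(stk, model_spec(v))$design)
  expect_equal(K("linear"), 6)           # 5 matrices + offset
  expect_equal(K("nonlinear"), 11)       # + 5 squares
  expect_equal(K("nonlinear_cross"), 21) # + 10 unordered cross pairs
  tl <- build_terms(stk, model_spec("nonlinear_cross"))
  # every quadratic regressor is symmetric by construction
  for (r in tl$regressors) expect_lt(max(abs(r - t(r))), 1e-12)
  expect_error(
    build_terms(stk, model_spec("single_frequency", matrices = "nope")),
    "matches no matrix")
})

test_that("coefficient counting follows both conventions", {
  expect_equal(count_coefficients(10, "hessian")$total, 110)
  expect_equal(count_coefficients(1, "hessian")$total, 2)
  expect_equal(count_coefficients(5, "hessian")$total, 30)
  expect_equal(count_coefficients(5, "distinct")$total, 20)
  expect_equal(count_coefficients(5, "hessian",
                                  include_cross_terms = FALSE)$total, 10)
  expect_equal(count_coefficients(5, "hessian",
                                  include_quadratic = FALSE)$total, 5)
})

test_that("an exact linear relation is fitted exactly", {
  stk <- small_stack(P = 10, D = 1, seed = 3)
  V <- connectivity_matrix(2 * unclass(stk$matrices[[1]]),
                           region_labels = stk$region_labels)
  fit <- fit_taylor(V, stk, model_spec("single_frequency",
                                       matrices = "W1"))
  expect_equal(unname(fit$a), 2, tolerance = 1e-10)
  expect_equal(fit$c, 0, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("noiseless planted coefficients are recovered exactly", {
  sp <- synthetic_spec(P = 20, D = 3, planted_c = 0.07, seed = 91)
  stk <- gen_stack(sp)
  V <- plant_target(stk, sp)
  pl <- attr(V, "planted")
  fit <- fit_taylor(V, stk, model_spec("nonlinear_cross"))
  rel <- function(est, truth) max(abs(est - truth) / pmax(abs(truth), 1e-8))
  expect_lt(rel(unname(fit$a), pl$a), 1e-6)
  expect_lt(rel(fit$b[upper.tri(fit$b, diag = TRUE)],
                pl$b[upper.tri(pl$b, diag = TRUE)]), 1e-6)
  expect_lt(abs(fit$c - 0.07), 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)

  # iterative estimator converges to the same optimum
  it <- fit_taylor(V, stk, model_spec("nonlinear_cross"),
                   method = "iterative")
  expect_equal(it$coefficients, fit$coefficients, tolerance = 1e-5)
})

test_that("pure-noise targets yield chance-level R^2", {
  # with K regressors independent of the target, E[R^2] ~ (K-1)/(E-1)
  taylorconn:::with_seed(17, {
    P <- 30; E <- P * (P - 1) / 2
    r2s <- vapply(1:30, function(i) {
      sp <- synthetic_spec(P, 5, seed = 300 + i)
      stk <- gen_stack(sp)
      V <- random_cm(P, seed = 700 + i)
      fit_taylor(V, stk, model_spec("nonlinear_cross"))$r2
    }, numeric(1))
    K <- 21
    expect_lt(abs(mean(r2s) - (K - 1) / (E - 1)), 0.02)
  })
})

test_that("prediction reproduces the training fit and offset geometry", {
  stk <- small_stack(P = 10, D = 2, seed = 5)
  sp <- synthetic_spec(10, 2, planted_c = 0.1, seed = 5)
  V <- plant_target(stk, sp)
  fit <- fit_taylor(V, stk, model_spec("nonlinear_cross"))
  Vhat <- predict(fit, stk)
  expect_lt(max(abs(Vhat - V)), 1e-8)

  # zeroed coefficients predict the zero matrix
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_equal(max(abs(predict(fit0, stk))), 0)

  # offset-only coefficients give a constant off-diagonal matrix
  fitc <- fit
  fitc$coefficients[] <- 0
  fitc$coefficients["offset"] <- 0.1
  pc <- predict(fitc, stk)
  expect_true(all(abs(upper_tri_vec(pc) - 0.1) < 1e-12))
  expect_true(all(diag(pc) == 0))
})

test_that("refitting the fitted matrix returns the same coefficients", {
  stk <- small_stack(P = 12, D = 3, seed = 31)
  V <- random_cm(12, seed = 32)
  fit <- fit_taylor(V, stk, model_spec("nonlinear_cross"))
  Vhat <- connectivity_matrix(fit$fitted, region_labels = stk$region_labels,
                              symmetrize_tol = 1e-9)
  refit <- fit_taylor(Vhat, stk, model_spec("nonlinear_cross"))
  expect_equal(refit$coefficients, fit$coefficients, tolerance = 1e-8)
  expect_equal(refit$r2, 1, tolerance = 1e-10)
})

test_that("R^2 matches hand arithmetic and flags degenerate targets", {
  lab <- c("a", "b", "c")
  V <- connectivity_matrix(sym_from_upper(c(.2, .4, .6), 3, lab))
  expect_equal(r_squared(V, V), 1)
  Vm <- connectivity_matrix(sym_from_upper(rep(mean(c(.2, .4, .6)), 3),
                                           3, lab))
  expect_equal(r_squared(V, Vm), 0)
  Vh <- connectivity_matrix(sym_from_upper(c(.2, .5, .5), 3, lab))
  expect_equal(r_squared(V, Vh), 0.75)
  expect_error(r_squared(Vm, V), "constant target")
})

test_that("spectral diagnostics: zero trace, real spectrum, 2x2 closed form", {
  base <- small_stack(P = 8, D = 2, seed = 9)
  # shrink weights so the spectral radius sits inside the unit disc
  stk <- matrix_stack(lapply(base$matrices, function(w) {
    connectivity_matrix(unclass(w) * 0.2,
                        region_labels = base$region_labels)
  }))
  expect_silent(d <- spectral_check(stk))
  expect_equal(d$trace, c(0, 0))
  for (ev in d$eigenvalues) {
    expect_true(is.numeric(ev))          # symmetric input: real spectrum
    expect_lt(abs(sum(ev)), 1e-10)       # sum of eigenvalues = trace = 0
  }
  two <- connectivity_matrix(matrix(c(0, .4, .4, 0), 2))
  d2 <- spectral_check(matrix_stack(list(A = two)))
  expect_equal(sort(d2$eigenvalues[[1]]), c(-.4, .4))
  big <- connectivity_matrix(matrix(c(0, 1.5, 1.5, 0), 2) / 1.0,
                             metric = "generic")
  expect_warning(spectral_check(matrix_stack(list(B = big))),
                 "spectral radius")
})

test_that("nested model sequences have non-decreasing R^2", {
  stk <- small_stack(P = 14, D = 3, seed = 71)
  V <- random_cm(14, seed = 72)
  variants <- nested_variants(V, stk)
  fits <- fit_model_sequence(V, stk, variants)
  r2s <- vapply(fits, `[[`, numeric(1), "r2")
  expect_length(fits, 4)
  expect_true(all(diff(r2s) >= -1e-12))

  # a target equal to one input matrix is explained from the first model on
  V1 <- connectivity_matrix(unclass(stk$matrices[[2]]) * 1,
                            region_labels = stk$region_labels)
  v1 <- nested_variants(V1, stk)
  expect_identical(attr(v1, "best_single"), "W2")
  f1 <- fit_model_sequence(V1, stk, v1)
  expect_true(all(abs(vapply(f1, `[[`, numeric(1), "r2") - 1) < 1e-10))

  # noiseless planted cross-term target ends the sequence at R^2 = 1
  sp <- synthetic_spec(14, 3, seed = 73)
  Vp <- plant_target(stk, sp)
  fp <- fit_model_sequence(Vp, stk, nested_variants(Vp, stk))
  expect_equal(fp$nonlinear_cross$r2, 1, tolerance = 1e-10)
})

test_that("collinear stacks are flagged and solved by minimum norm", {
  stk <- small_stack(P = 10, D = 2, seed = 55)
  dup <- matrix_stack(list(W1 = stk$matrices[[1]],
                           W2 = stk$matrices[[1]],
                           W3 = stk$matrices[[2]]))
  V <- random_cm(10, seed = 56)
  expect_warning(fit <- fit_taylor(V, dup, model_spec("linear")),
                 "rank-deficient")
  expect_true(fit$rank_deficient)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("confidence intervals cover planted coefficients at noise", {
  # classical linear-model CIs: with noise present, planted values should
  # mostly fall inside the 95% intervals
  hits <- 0; total <- 0
  for (s in 1:10) {
    sp <- synthetic_spec(16, 2, planted_c = 0.05, noise_sd = 0.05,
                         seed = 800 + s)
    stk <- gen_stack(sp)
    V <- plant_target(stk, sp)
    pl <- attr(V, "planted")
    fit <- fit_taylor(V, stk, model_spec("nonlinear_cross"))
    # check linear coefficients and offset, by position/name
    for (k in seq_along(fit$a)) {
      total <- total + 1
      if (pl$a[k] >= fit$ci[k, 1] && pl$a[k] <= fit$ci[k, 2]) hits <- hits + 1
    }
    total <- total + 1
    if (pl$c >= fit$ci["offset", 1] && pl$c <= fit$ci["offset", 2]) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.8)
})
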