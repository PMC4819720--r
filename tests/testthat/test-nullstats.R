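test_that("pseudo-matrices preserve the spectrum and randomize structure", {
  W <- random_cm(12, seed = 1)
  raw <- pseudo_matrix(W, seed = 2, zero_diagonal = FALSE)
  ev_in <- eigen(unclass(W) * 1, symmetric = TRUE, only.values = TRUE)$values
  ev_out <- eigen(raw, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(abs(sort(ev_in) - sort(ev_out))), 1e-8)

  ps <- pseudo_matrix(W, seed = 2)
  expect_s3_class(ps, "connectivity_matrix")
  expect_true(all(diag(ps) == 0))
  expect_lt(max(abs(ps - t(ps))), 1e-12)

  # surrogate differs from the input, and across seeds, for many seeds
  dists <- vapply(1:100, function(s) {
    norm(unclass(pseudo_matrix(W, seed = s)) - unclass(W) * 1, "F")
  }, numeric(1))
  expect_true(all(dists > 0))
  p1 <- pseudo_matrix(W, seed = 10)
  p2 <- pseudo_matrix(W, seed = 11)
  expect_gt(norm(unclass(p1) - unclass(p2) * 1, "F"), 0)
  # reproducible given the seed
  expect_equal(unclass(pseudo_matrix(W, seed = 10)) * 1, unclass(p1) * 1)

  asym <- matrix(runif(9), 3)
  expect_error(pseudo_matrix(asym), "symmetric")
})

test_that("variance-explained test: planted signal attains the minimum p", {
  sp <- synthetic_spec(14, 3, seed = 21)
  stk <- gen_stack(sp)
  V <- plant_target(stk, sp)
  res <- test_variance_explained(V, stk, model_spec("nonlinear_cross"),
                                 n_perm = 200, seed = 4)
  expect_equal(res$observed, 1, tolerance = 1e-10)
  expect_equal(res$p_value, 1 / 201)
  expect_equal(res$bonferroni_alpha, 0.01)
  expect_true(res$significant)
  # add-one rule: p can never be zero and is bounded by the design
  expect_gte(res$p_value, 1 / (res$n_perm + 1))
  expect_error(test_variance_explained(V, stk, model_spec("linear"),
                                       n_perm = 0), "n_perm")
})

test_that("permutation p-values are reproducible given the seed", {
  sp <- synthetic_spec(10, 2, seed = 33)
  stk <- gen_stack(sp)
  V <- random_cm(10, seed = 34)
  r1 <- test_variance_explained(V, stk, model_spec("linear"),
                                n_perm = 50, seed = 9)
  r2 <- test_variance_explained(V, stk, model_spec("linear"),
                                n_perm = 50, seed = 9)
  expect_identical(r1$null_values, r2$null_values)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("gradient statistic is the least-squares slope of R^2", {
  expect_equal(taylorconn:::r2_slope(c(0.1, 0.2, 0.3, 0.4)), 0.1)
  expect_equal(taylorconn:::r2_slope(rep(0.3, 4)), 0)

  # planted full structure: the real gradient beats the surrogate nulls
  sp <- synthetic_spec(14, 3, seed = 41)
  stk <- gen_stack(sp)
  V <- plant_target(stk, sp)
  variants <- nested_variants(V, stk)
  g <- test_gradient(V, stk, variants, n_perm = 100, seed = 5)
  expect_gt(g$observed, stats::quantile(g$null_values, 0.95))
  expect_lt(g$p_value, 0.05)
  expect_length(g$observed_r2, 4)
  expect_error(test_gradient(V, stk, variants[1], n_perm = 10), "2 ordered")
})

test_that("increment tests isolate where planted structure lives", {
  # purely linear planted structure: the linear step is the significant one
  b0 <- matrix(0, 3, 3)
  sp_lin <- synthetic_spec(16, 3, planted_a = c(0.6, -0.5, 0.4),
                           planted_b = b0, noise_sd = 0.02, seed = 51)
  stk <- gen_stack(sp_lin)
  V <- plant_target(stk, sp_lin)
  variants <- nested_variants(V, stk)
  inc <- test_increments(V, stk, variants, n_perm = 200, seed = 6)
  expect_length(inc, 3)
  expect_equal(inc[[1]]$bonferroni_alpha, 0.05 / 3)
  expect_lt(inc[[1]]$p_value, 0.05 / 3)      # single freq -> linear
  expect_gt(inc[[2]]$p_value, 0.05 / 3)      # no quadratic structure
  # observed increments along a nested sequence are never negative
  for (r in inc) expect_gte(r$observed, -1e-12)

  # cross-term-only structure: only the final increment carries signal
  b12 <- matrix(0, 3, 3); b12[1, 2] <- b12[2, 1] <- 0.8
  sp_x <- synthetic_spec(16, 3, planted_a = rep(0, 3), planted_b = b12,
                         noise_sd = 0.02, seed = 52)
  stk_x <- gen_stack(sp_x)
  Vx <- plant_target(stk_x, sp_x)
  vx <- nested_variants(Vx, stk_x)
  incx <- test_increments(Vx, stk_x, vx, n_perm = 200, seed = 7)
  expect_lt(incx[[3]]$p_value, 0.05 / 3)

  # identical successive models: zero increment, p near 1
  same <- list(model_spec("linear"), model_spec("linear"))
  inc0 <- test_increments(V, stk, same, n_perm = 50, seed = 8)
  expect_equal(inc0[[1]]$observed, 0)
  expect_gt(inc0[[1]]$p_value, 0.5)
})

test_that("subject-swap test detects subject-specific mappings only", {
  P <- 12; D <- 2
  shared <- gen_stack(synthetic_spec(P, D, seed = 61))
  # subjects 1-3 share one stack and target: exchangeable, no significance
  spec <- model_spec("linear")
  Vs <- replicate(3, {
    sp <- synthetic_spec(P, D, noise_sd = 0.1, seed = 62)
    plant_target(shared, sp)
  }, simplify = FALSE)
  stacks <- list(shared, shared, shared)
  res <- subject_swap_test(Vs, stacks, spec, n_perm = 100, seed = 10)
  expect_false(any(vapply(res, `[[`, logical(1), "significant")))

  # one subject with its own strong stack-target mapping stands out
  own <- gen_stack(synthetic_spec(P, D, seed = 63))
  sp_own <- synthetic_spec(P, D, noise_sd = 0.01, seed = 64)
  V_own <- plant_target(own, sp_own)
  res2 <- subject_swap_test(c(Vs[1:2], list(V_own)),
                            list(shared, shared, own),
                            spec, n_perm = 100, seed = 11)
  expect_true(res2[[3]]$significant)

  expect_error(subject_swap_test(Vs[1:2], stacks[1:2], spec), "3 subjects")
  expect_error(subject_swap_test(Vs, stacks, spec, n_perm = 0), "n_perm")
})

test_that("Mann-Whitney U agrees with enumeration and wilcox.test", {
  # symmetry: identical samples give Z = 0, p = 1
  r <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$Z, 0)
  expect_equal(r$p, 1)

  # complete separation
  r2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$U, 0)
  en <- mw_enumerate(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6), exact = TRUE)$p, en$p)

  # all sample-size pairs with n_a + n_b <= 8, random tie-free data
  taylorconn:::with_seed(77, {
    for (na in 1:7) {
      for (nb in 1:(8 - na)) {
        a <- rnorm(na); b <- rnorm(nb)
        imp <- mann_whitney_u(a, b, exact = TRUE)
        oracle <- mw_enumerate(a, b)
        expect_equal(imp$U, oracle$U)
        expect_equal(imp$p, oracle$p)
      }
    }
  })

  # normal approximation cross-checked against stats::wilcox.test
  taylorconn:::with_seed(78, {
    a <- rnorm(40, 1); b <- rnorm(35)
    imp <- mann_whitney_u(a, b)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    expect_equal(imp$U, unname(ref$statistic))
    expect_equal(imp$p, ref$p.value, tolerance = 1e-10)
    expect_gt(imp$Z, 0)
    expect_lt(imp$p, 0.05)
  })

  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("regional contribution retains round(R^2 * E) top edges", {
  # target equal to one stack matrix: R^2 = 1, all edges retained,
  # node strength maximal where fitted connectivity concentrates
  P <- 9
  star <- matrix(0, P, P)
  star[1, 2:P] <- star[2:P, 1] <- 0.5
  stk <- matrix_stack(list(
    W1 = connectivity_matrix(star, region_labels = paste0("R", 1:P))))
  V <- connectivity_matrix(star, region_labels = paste0("R", 1:P))
  rc <- regional_contribution(V, stk, matrix_name = "W1")
  expect_equal(rc$r2, 1, tolerance = 1e-10)
  expect_equal(rc$n_retained, P * (P - 1) / 2)
  expect_equal(names(which.max(rc$node_strength)), "R1")

  # partial fit: retained count tracks round(r2 * E)
  sp <- synthetic_spec(12, 2, noise_sd = 0.15, seed = 81)
  stk2 <- gen_stack(sp)
  V2 <- plant_target(stk2, sp)
  rc2 <- regional_contribution(V2, stk2, matrix_name = "W1")
  E <- 12 * 11 / 2
  expect_equal(rc2$n_retained, round(rc2$r2 * E))
  expect_equal(nrow(rc2$retained_edges), rc2$n_retained)
  # retained edges are the largest by absolute fitted weight
  expect_gte(min(abs(rc2$retained_edges$weight)),
             sort(abs(rc2$fit$fitted[upper.tri(rc2$fit$fitted)]),
                  decreasing = TRUE)[rc2$n_retained])

  # a target exactly orthogonal to the regressor fits with R^2 = 0:
  # nothing is retained, with a warning
  taylorconn:::with_seed(82, {
    u <- upper_tri_vec(stk2$matrices[[1]])
    v <- rnorm(E)
    v <- residuals(lm(v ~ u))          # orthogonal to regressor + offset
    Vbad <- connectivity_matrix(sym_from_upper(v, 12, paste0("R", 1:12)))
  })
  expect_warning(
    rc3 <- regional_contribution(Vbad, stk2, matrix_name = "W1"),
    "empty result")
  expect_equal(rc3$n_retained, 0L)
})
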