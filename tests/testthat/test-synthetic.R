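test_that("an empty edge pattern yields the identity precision matrix", {
  th <- make_precision_matrix(c(a = 3, b = 2), within_pc = 0)
  expect_equal(unclass(th)[1:5, 1:5], diag(5), ignore_attr = TRUE)
  expect_equal(max(abs(attr(th, "w_true"))), 0)
})

test_that("a single requested partial correlation lands in the precision matrix", {
  th <- make_precision_matrix(c(a = 2), within_pc = 0.3)
  expect_equal(th[1, 2] / sqrt(th[1, 1] * th[2, 2]), -0.3, tolerance = 1e-12)
  expect_equal(attr(th, "w_true")[1, 2], 0.3, tolerance = 1e-12)
})

test_that("the default 19-node spec reproduces the requested pattern exactly", {
  spec <- synthetic_spec()
  for (g in c("young", "old")) {
    th <- spec$theta_by_group[[g]]
    expect_equal(attr(th, "delta"), 0)  # SPD without inflation
    W <- partial_corr_from_precision(unclass(th))
    expect_lt(max(abs(W - attr(th, "requested"))), 1e-6)
    expect_gt(min(eigen(unclass(th), symmetric = TRUE)$values), 1e-8)
    expect_lte(max(abs(W)), 0.6)
  }
})

test_that("diagonal inflation attenuates and re-stores the ground truth", {
  # all-pairs block at 0.25 is not SPD raw; inflation must kick in
  edges <- do.call(rbind, lapply(combn(6, 2, simplify = FALSE), function(ij)
    data.frame(from = ij[1], to = ij[2], pc = 0.25)))
  th <- make_precision_matrix(c(a = 6), within_pc = 0, extra_edges = edges)
  delta <- attr(th, "delta")
  expect_gt(delta, 0)
  expect_equal(attr(th, "w_true")[1, 2], 0.25 / (1 + delta), tolerance = 1e-10)
  expect_equal(attr(th, "w_true"), partial_corr_from_precision(unclass(th)),
               tolerance = 1e-12)
})

test_that("an unreachable SPD pattern raises an infeasible-spec error", {
  edges <- do.call(rbind, lapply(combn(6, 2, simplify = FALSE), function(ij)
    data.frame(from = ij[1], to = ij[2], pc = 0.59)))
  expect_error(make_precision_matrix(c(a = 6), within_pc = 0, extra_edges = edges),
               class = "bridgenet_infeasible_spec")
  expect_error(make_precision_matrix(c(a = 2), within_pc = 0.7),
               class = "bridgenet_input")
})

test_that("partial correlations follow the precision-matrix identity", {
  expect_equal(partial_corr_from_precision(diag(4)), matrix(0, 4, 4))
  th <- matrix(c(2, -0.5, -0.5, 2), 2)
  expect_equal(partial_corr_from_precision(th)[1, 2], 0.25)
  expect_error(partial_corr_from_precision(matrix(c(1, 2, 2, 1), 2)),
               class = "bridgenet_linalg")
})

test_that("partial correlations agree with the conditioning-based oracle", {
  set.seed(20)
  for (r in 1:5) {
    A <- matrix(rnorm(36), 6)
    Sigma <- crossprod(A) + diag(6)
    W <- partial_corr_from_precision(solve(Sigma))
    expect_equal(W, pcor_by_conditioning(Sigma), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("item simulation is byte-identical under a fixed seed", {
  spec <- synthetic_spec(n_per_group = c(young = 40, old = 40))
  d1 <- simulate_items(spec, "young", seed = 7)
  d2 <- simulate_items(spec, "young", seed = 7)
  expect_identical(d1, d2)
  # and does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_items(spec, "young", seed = 7))
  expect_identical(rnorm(1), before)
})

test_that("extreme thresholds produce constant items that trip the degenerate path", {
  spec <- synthetic_spec(n_per_group = c(young = 60, old = 60),
                         ordinal_thresholds = c(10, 11, 12))
  ds <- simulate_items(spec, "young")
  expect_true(all(as.matrix(ds[paste0("hd", 1:7)]) == 0))
  expect_error(preprocess(ds), class = "bridgenet_degenerate_input")
})

test_that("threshold validation enforces zero-inflating increasing cutpoints", {
  expect_error(synthetic_spec(ordinal_thresholds = c(-0.5, 1, 2)),
               class = "bridgenet_input")
  expect_error(synthetic_spec(ordinal_thresholds = c(1, 1, 2)),
               class = "bridgenet_input")
})

test_that("items are zero-inflated at the rate the thresholds imply", {
  spec <- synthetic_spec(n_per_group = c(old = 4000))
  ds <- simulate_items(spec, "old")
  zero_rates <- colMeans(as.matrix(ds[paste0("ha", 1:7)]) == 0)
  # expected rate pnorm(0.8 / sd) with each item's latent SD from Theta^-1
  sds <- sqrt(diag(solve(unclass(spec$theta_by_group$old))))[paste0("ha", 1:7)]
  expect_true(all(abs(zero_rates - pnorm(0.8 / sds)) < 0.04))
  expect_true(all(zero_rates > 0.6))  # strong zero inflation throughout
  cog <- as.matrix(ds[item_columns[1:5]])
  expect_true(all(cog > 0 & cog < 1))
  expect_equal(attr(ds, "n_dropped"), 0L)
})

test_that("empirical latent covariance converges to the model covariance", {
  spec <- synthetic_spec(n_per_group = c(old = 20000))
  ds <- simulate_items(spec, "old")
  L <- attr(ds, "latent")
  Sig <- solve(unclass(spec$theta_by_group$old))
  expect_lt(norm(cov(L) - Sig, "F") / norm(Sig, "F"), 0.1)
})

test_that("observed item correlations keep the sign of the latent truth", {
  spec <- synthetic_spec(n_per_group = c(old = 4000))
  Sig <- solve(unclass(spec$theta_by_group$old))
  truth_sign <- sign(Sig["hd6", "hd7"])
  hits <- vapply(1:200, function(s) {
    ds <- simulate_items(spec, "old", seed = s)
    sign(cor(ds$hd6, ds$hd7)) == truth_sign
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("the planted bridge has the maximal |BEI| among affective nodes", {
  spec <- synthetic_spec()
  for (g in c("young", "old")) {
    bei <- bridge_expected_influence(spec$w_true_by_group[[g]], spec$domains)
    aff <- names(spec$domains)[spec$domains != "cognitive"]
    expect_equal(names(which.max(abs(bei[aff]))),
                 unname(spec$bridge_node_by_group[g]))
  }
})

test_that("null mediation paths give vanishing association at large n", {
  d <- simulate_mediation_data(list(a = 0, a_int = 0), n = 10000, seed = 2)
  expect_lt(abs(cor(d$gmv, d$cognition)), 0.05)
})

test_that("mediation generator recovers its path coefficients by OLS", {
  d <- simulate_mediation_data(list(), n = 10000, seed = 3)
  zs <- function(x) as.numeric(scale(x))
  cm <- coef(lm(zs(cognition) ~ zs(gmv) * zs(age) + sex + zs(education), d))
  cy <- coef(lm(zs(hd7) ~ zs(cognition) + zs(gmv) + zs(age) + sex + zs(education), d))
  expect_lt(abs(cm[["zs(gmv)"]] - 0.142), 0.05)
  expect_lt(abs(cm[["zs(gmv):zs(age)"]] - 0.186), 0.05)
  expect_lt(abs(cy[["zs(cognition)"]] - (-0.147)), 0.05)
  expect_lt(abs(cy[["zs(gmv)"]] - 0.013), 0.05)
  # indirect effect at +1 SD of age equals (a + a_int) * b analytically
  ind1 <- (cm[["zs(gmv)"]] + cm[["zs(gmv):zs(age)"]]) * cy[["zs(cognition)"]]
  expect_lt(abs(ind1 - (0.142 + 0.186) * (-0.147)), 0.02)
})

test_that("mediation generator is deterministic and validates error SDs", {
  expect_identical(simulate_mediation_data(list(), n = 50, seed = 9),
                   simulate_mediation_data(list(), n = 50, seed = 9))
  expect_error(simulate_mediation_data(list(error_sd = c(0, 1, 1)), n = 50),
               class = "bridgenet_input")
  expect_error(simulate_mediation_data(list(a = 0.9, a_int = 0.9), n = 50),
               class = "bridgenet_infeasible_spec")
})
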