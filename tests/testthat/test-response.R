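test_that("the 8-point grid reproduces the Casimir-Polder identity", {
  g <- make_frequency_grid(8)
  expect_equal(casimir_polder_check(g, 1, 1), 0.5, tolerance = 1e-6)
  # off-anchor scales are held to the rule's interpolation accuracy
  expect_equal(casimir_polder_check(g, 2, 3), 1 / 5, tolerance = 1e-3)
  expect_true(all(diff(g$nodes) > 0) && all(g$nodes > 0))
})

test_that("grid refinement does not degrade the quadrature", {
  g8 <- make_frequency_grid(8)
  g16 <- make_frequency_grid(16)
  av <- exp(seq(log(0.25), log(4), length.out = 12))
  err <- function(g) max(outer(av, av, Vectorize(function(a, b)
    abs(casimir_polder_check(g, a, b) * (a + b) - 1))))
  expect_lte(err(g16), err(g8))
})

test_that("the classical Legendre map is available and consistent", {
  g <- make_frequency_grid(8, type = "legendre")
  expect_equal(casimir_polder_check(g, 1, 1), 0.5, tolerance = 1e-2)
  expect_identical(g$type, "legendre")
})

test_that("direct response matches the spectral assembly", {
  sys <- fixture_system("h2_h2")
  h <- sys$hessians$A
  sol <- solve_erpa(h)
  for (w in c(0.3, 1.1)) {
    C <- response_direct(h, w)
    Cs <- matrix(0, nrow(C), ncol(C))
    for (k in seq_along(sol$omegas))
      Cs <- Cs + sol$signs[k] * sol$omegas[k] /
        (sol$omegas[k]^2 + w^2) * tcrossprod(sol$Y[, k])
    expect_lt(max(abs(C - Cs)), 1e-9)
  }
})

test_that("the response decays at high frequency", {
  h <- fixture_system("he_he")$hessians$A
  expect_lt(norm(response_direct(h, 1e6), "F"), 1e-6)
})

test_that("response projection matches a triple-loop contraction", {
  set.seed(4)
  C <- matrix(rnorm(36), 6); C <- (C + t(C)) / 2
  D <- matrix(rnorm(18), 6, 3)
  ref <- matrix(0, 6, 3)
  for (p in 1:6) for (L in 1:3) for (q in 1:6)
    ref[p, L] <- ref[p, L] + C[p, q] * D[q, L]
  expect_equal(project_response(C, D), ref, tolerance = 1e-14)
  expect_equal(project_response(C, D[, 1, drop = FALSE]),
               C %*% D[, 1, drop = FALSE])
  expect_true(all(project_response(C, 0 * D) == 0))
  expect_error(project_response(C, matrix(0, 5, 2)), "dimension")
})

test_that("zero coupling terminates the expansion exactly at order zero", {
  syn <- generate_synthetic_instance(21, 15, 4, coupling_strength = 0)
  pr <- recursive_projected_response(syn, syn$D, 0.7, 10)
  expect_length(pr$orders, 1)
  expect_lt(max(abs(pr$total - response_direct(syn, 0.7) %*% syn$D)), 1e-12)
})

test_that("order zero is the uncoupled (block-diagonal) response", {
  sys <- fixture_system("h2_h2")
  h <- sys$hessians$A
  D <- matrix(rnorm(sys$pairs$A$n * 3), ncol = 3)
  pr <- recursive_projected_response(h, D, 0.5, 0)
  h0 <- h
  h0$A_plus <- h$A0_plus; h0$A_minus <- h$A0_minus
  ref <- response_direct(h0, 0.5) %*% D
  expect_lt(max(abs(pr$orders[[1]] - ref)), 1e-10)
})

test_that("the expansion converges to the direct solve on fixtures", {
  for (name in c("h2_h2", "h2o_h2o")) {
    sys <- fixture_system(name)
    h <- sys$hessians$A
    D <- transform_and_scale(
      pivoted_cholesky(coulomb_accessor_dense(sys$ints$a$eri), 1e-8),
      sys$states$A, sys$pairs$A)
    ref <- response_direct(h, 0.4) %*% D
    pr <- recursive_projected_response(h, D, 0.4, 30)
    expect_lt(max(abs(pr$total - ref)) / max(abs(ref)), 1e-8)
    # truncation error decreases with order
    err <- vapply(seq_along(pr$orders), function(k)
      max(abs(Reduce(`+`, pr$orders[1:k]) - ref)), 0)
    expect_lt(err[11], err[3])
    expect_false(pr$diverging)
  }
})

test_that("weak coupling gives geometric decay of the increments", {
  syn <- generate_synthetic_instance(31, 20, 5, coupling_strength = 0.05)
  pr <- recursive_projected_response(syn, syn$D, 0.3, 12)
  nr <- pr$increment_norms
  expect_true(all(diff(log(nr[2:10])) < 0))
})

test_that("per-node diagnostics sum to the dispersion energy", {
  calc <- fixture_calc("h2_h2", order = 6, keep = TRUE)
  f <- tempfile(fileext = ".csv")
  d <- write_response_diagnostics(calc, f)
  expect_true(file.exists(f))
  last <- d[d$order == 6, ]
  expect_equal(sum(last$partial_energy), calc$e_coupled, tolerance = 1e-10)
  expect_equal(nrow(d), 8 * 7)
})

test_that("the resolvent is applied blockwise, never as a full inverse", {
  syn <- generate_synthetic_instance(41, 18, 4, coupling_strength = 0.1)
  # corrupt the off-block entries of A0: a blockwise solver must not see them
  syn2 <- syn
  mask <- matrix(TRUE, 18, 18)
  for (b in syn$block_layout) mask[b, b] <- FALSE
  syn2$A0_plus[mask] <- 37; syn2$A0_minus[mask] <- -37
  X <- matrix(rnorm(18 * 4), 18, 4)
  s1 <- mrdisp:::.lambda_solver(syn, 0.5)(X)
  s2 <- mrdisp:::.lambda_solver(syn2, 0.5)(X)
  expect_equal(s1, s2, tolerance = 1e-12)
  # and the blockwise solve agrees with the dense reference inverse
  Lam <- syn$A0_minus %*% syn$A0_plus + diag(0.5^2, 18)
  expect_lt(max(abs(s1 - solve(Lam, X))), 1e-10)
})
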