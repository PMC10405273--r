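test_that("RDM-contraction Hessians equal brute-force operator algebra", {
  # two-electron monomers keep the determinant space tiny
  for (name in c("h2_h2", "he_he")) {
    sys <- fixture_system(name)
    st <- sys$states$A
    h <- sys$hessians$A
    bf <- erpa_eom_bruteforce(st, sys$nos$A, sys$pairs$A)
    expect_lt(max(abs(h$eom_A - bf$A)), 1e-10)
    expect_lt(max(abs(h$eom_B - bf$B)), 1e-10)
  }
})

test_that("Hessians are symmetric and reduce to textbook RPA at mean field", {
  sys <- fixture_system("he_he")
  h <- sys$hessians$A
  expect_lt(max(abs(h$A_plus - t(h$A_plus))), 1e-10)
  expect_lt(max(abs(h$A_minus - t(h$A_minus))), 1e-10)
  # independent dense RPA construction from orbital energies and integrals
  ints <- sys$ints$a
  scf <- rhf(ints, 2)
  eri <- sys$nos$A$eri_no
  pr <- sys$pairs$A$pairs
  np <- nrow(pr)
  A <- matrix(0, np, np); B <- matrix(0, np, np)
  for (i in seq_len(np)) for (j in seq_len(np)) {
    a <- pr$p[i]; ii <- pr$q[i]; b <- pr$p[j]; jj <- pr$q[j]
    A[i, j] <- (if (i == j) scf$eps[a] - scf$eps[ii] else 0) +
      2 * eri[ii, a, jj, b] - eri[ii, jj, a, b]
    B[i, j] <- 2 * eri[ii, a, b, jj] - eri[ii, b, a, jj]
  }
  expect_lt(max(abs(h$A_plus - (A + B))), 1e-8)
  expect_lt(max(abs(h$A_minus - (A - B))), 1e-8)
  # excitation energies against an independent symmetric-eigenvalue route
  sol <- solve_erpa(h)
  S <- with(eigen(A - B, symmetric = TRUE), vectors %*% (sqrt(values) * t(vectors)))
  om_ref <- sqrt(sort(eigen(S %*% (A + B) %*% S, symmetric = TRUE,
                            only.values = TRUE)$values))
  expect_equal(sol$omegas, om_ref, tolerance = 1e-8)
})

test_that("a single-pair system reproduces the closed-form RPA root", {
  syn <- generate_synthetic_instance(11, pair_dim = 1, n_chol = 1, coupling_strength = 0)
  sol <- solve_erpa(syn)
  expect_equal(sol$omegas, sqrt(syn$A_plus[1, 1] * syn$A_minus[1, 1]),
               tolerance = 1e-12)
  expect_equal(sol$n_discarded_negative, 0)
})

test_that("retained roots are positive and bounded by the pair dimension", {
  for (name in c("h2_h2", "h2o_h2o", "h2_h2_es")) {
    sol <- solve_erpa(fixture_system(name)$hessians$A)
    expect_true(all(sol$omegas > 0))
    expect_lte(length(sol$omegas), fixture_system(name)$pairs$A$n)
  }
})

test_that("no roots are discarded when the Hessian product is positive definite", {
  sys <- fixture_system("h2_h2")
  h <- sys$hessians$A
  expect_gt(min(eigen(h$A_minus, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_gt(min(eigen(h$A_plus, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(solve_erpa(h)$n_discarded_negative, 0)
})

test_that("the alpha split is exact and block-structured", {
  h <- fixture_system("h2o_h2o")$hessians$A
  expect_equal(h$A0_plus + h$A1_plus, h$A_plus, tolerance = 1e-14)
  expect_equal(h$A0_minus + h$A1_minus, h$A_minus, tolerance = 1e-14)
  mask <- matrix(TRUE, nrow(h$A_plus), nrow(h$A_plus))
  for (b in h$block_layout) mask[b, b] <- FALSE
  expect_true(all(h$A0_plus[mask] == 0))
  expect_true(all(h$A0_minus[mask] == 0))
  # an already block-diagonal instance has zero coupling part
  syn <- generate_synthetic_instance(5, 12, 3, coupling_strength = 0)
  expect_true(all(syn$A1_plus == 0))
})

test_that("RDM inconsistency is rejected", {
  sys <- fixture_system("h2_h2")
  st <- sys$states$A
  st$n_electrons <- 4
  expect_error(build_hessians(st, sys$nos$A, sys$pairs$A), "trace")
})
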