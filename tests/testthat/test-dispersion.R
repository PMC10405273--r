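test_that("two single-mode monomers give the analytic Casimir-Polder value", {
  # one pair per monomer: E = -4 (dA dB)^2 / (wA + wB)
  mk <- function(seed) generate_synthetic_instance(seed, 1, 1, 0)
  a <- mk(1); b <- mk(2)
  wa <- sqrt(a$A_plus[1, 1] * a$A_minus[1, 1])
  wb <- sqrt(b$A_plus[1, 1] * b$A_minus[1, 1])
  grid <- make_frequency_grid(8)
  pra <- lapply(grid$nodes, function(w) recursive_projected_response(a, a$D, w, 0))
  prb <- lapply(grid$nodes, function(w) recursive_projected_response(b, b$D, w, 0))
  de <- dispersion_energy(pra, prb, a$D, b$D, grid)
  # transition moments carry the (A-)^(1/2)/sqrt(omega) normalization
  exact <- -4 * (a$D[1, 1] * b$D[1, 1])^2 *
    a$A_minus[1, 1] * b$A_minus[1, 1] / (wa * wb * (wa + wb))
  expect_lt(abs(de$energy - exact) / abs(exact), 2e-3)
  expect_lt(de$energy, 0)
  # with both mode frequencies on a quadrature anchor scale (omega = 1) the
  # one-term value is reproduced to better than 1e-6 relative
  for (nm in c("a", "b")) {
    m <- get(nm)
    m$A_plus <- m$A0_plus <- matrix(1.3)
    m$A_minus <- m$A0_minus <- matrix(1 / 1.3)
    m$A1_plus <- m$A1_minus <- matrix(0)
    assign(nm, m)
  }
  pra <- lapply(grid$nodes, function(w) recursive_projected_response(a, a$D, w, 0))
  prb <- lapply(grid$nodes, function(w) recursive_projected_response(b, b$D, w, 0))
  de1 <- dispersion_energy(pra, prb, a$D, b$D, grid)
  exact1 <- -4 * (a$D[1, 1] * b$D[1, 1])^2 * (1 / 1.3)^2 / (1 * 1 * 2)
  expect_lt(abs(de1$energy - exact1) / abs(exact1), 1e-6)
})

test_that("the reduced-scaling path matches the sum-over-states oracle", {
  for (name in c("h2_h2", "he_he")) {
    calc <- fixture_calc(name)
    sos <- fixture_sos(name)
    expect_lt(abs(calc$e_coupled - sos$energy), 1e-6)
  }
})

test_that("swapping monomer labels leaves the dispersion energy unchanged", {
  fx <- fixture_suite()$h2_h2
  sys <- fixture_system("h2_h2")
  sys_sw <- prepare_interaction(fx$geom_b, fx$geom_a, fx$basis,
                               fx$active_b, fx$active_a)
  c1 <- dispersion_calculation(system = sys, threshold = 1e-8, order = 12,
                               keep = FALSE)
  c2 <- dispersion_calculation(system = sys_sw, threshold = 1e-8, order = 12,
                               keep = FALSE)
  # independent re-preparation (different AO ordering, pivots, orbitals)
  expect_equal(c1$e_coupled, c2$e_coupled, tolerance = 1e-7)
  # exact trace symmetry of the kernel contraction itself
  calc <- fixture_calc("h2_h2", order = 12, keep = TRUE)
  grid <- calc$full_grid
  e_ab <- dispersion_energy(calc$responses$A, calc$responses$B,
                            calc$D$A, calc$D$B, grid)$energy
  e_ba <- dispersion_energy(calc$responses$B, calc$responses$A,
                            calc$D$B, calc$D$A, grid)$energy
  expect_equal(e_ab, e_ba, tolerance = 1e-13)
})

test_that("doubling the coupling integrals quadruples the energy", {
  sys <- fixture_system("he_he")
  sol_a <- solve_erpa(sys$hessians$A)
  sol_b <- solve_erpa(sys$hessians$B)
  g <- g_cross_dense(sys$states$A, sys$states$B, sys$ints$a$eri,
                     sys$pairs$A, sys$pairs$B)
  e1 <- dispersion_sum_over_states(sol_a, sol_b, g)
  e2 <- dispersion_sum_over_states(sol_a, sol_b, 2 * g)
  expect_equal(e2, 4 * e1, tolerance = 1e-12)
})

test_that("ground-state fixtures have negative dispersion and induction", {
  for (name in c("h2_h2", "he_he", "h2o_h2o", "h2o_h2o_hf")) {
    expect_lt(fixture_calc(name)$e_coupled, 0)
  }
  ind <- induction_energy(system = fixture_system("h2o_h2o"))
  expect_lt(ind$a_from_b, 0)
  expect_lt(ind$b_from_a, 0)
})

test_that("grid refinement changes fixture energies at sub-microhartree level", {
  for (name in c("h2_h2", "he_he")) {
    sys <- fixture_system(name)
    e8 <- dispersion_calculation(system = sys, threshold = 1e-8, order = 15,
                                 grid = make_frequency_grid(8), keep = FALSE)$e_coupled
    e16 <- dispersion_calculation(system = sys, threshold = 1e-8, order = 15,
                                  grid = make_frequency_grid(16), keep = FALSE)$e_coupled
    expect_lt(abs(e8 - e16), 1e-8)
  }
})

test_that("per-order energies converge monotonically at high order", {
  calc <- fixture_calc("h2_h2")
  err <- abs(calc$per_order - calc$e_direct)
  expect_lt(err[11], err[3])     # order 10 vs order 2
  expect_equal(calc$per_order[length(calc$per_order)], calc$e_coupled,
               tolerance = 1e-14)
})

test_that("static-response induction matches the spectral route", {
  ind <- induction_energy(system = fixture_system("h2_h2"))
  sol <- solve_erpa(ind$hessians$A)
  v <- ind$potentials$A
  e_sos <- -2 * sum((t(sol$Y) %*% v)^2 / sol$omegas)
  expect_equal(ind$a_from_b, e_sos, tolerance = 1e-8)
  # zero potential, zero induction
  expect_equal(induction_static(0 * v, response_direct(ind$hessians$A, 0)), 0)
  # single-mode closed form
  syn <- generate_synthetic_instance(9, 1, 1, 0)
  w <- sqrt(syn$A_plus[1, 1] * syn$A_minus[1, 1])
  vv <- 0.37
  e1 <- induction_static(vv, response_direct(syn, 0))
  expect_equal(e1, -2 * vv^2 * syn$A_minus[1, 1] / w^2, tolerance = 1e-10)
})

test_that("the convergence scan reports microhartree-accurate orders", {
  sc <- convergence_scan(system = fixture_system("h2_h2"), n_max = 10)
  expect_false(sc$diverging)
  expect_true(is.finite(sc$order_converged))
  expect_lte(sc$order_converged, 8)
  expect_lt(sc$percent_errors[9], 0.1)
})
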