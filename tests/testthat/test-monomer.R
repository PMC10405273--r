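test_that("occupation sum rule 2*sum(n) = N holds for every produced state", {
  st <- fixture_system("h2_h2")$states$A
  expect_equal(2 * sum(st$occupations), st$n_electrons, tolerance = 1e-10)
  st2 <- fixture_system("h2o_h2o")$states$B
  expect_equal(2 * sum(st2$occupations), st2$n_electrons, tolerance = 1e-10)
  expect_true(all(st2$occupations[st2$partition$s1] == 1))
  expect_true(all(st2$occupations[st2$partition$s3] == 0))
  expect_true(all(st2$occupations[st2$partition$s2] > 0 &
                    st2$occupations[st2$partition$s2] < 1))
})

test_that("mean-field limit is a single determinant with 0/1 occupations", {
  st <- prepare_monomer_state(water_geom(), "sto-3g", active_space(0, 0))
  expect_true(all(st$occupations %in% c(0, 1)))
  expect_length(st$partition$s2, 0)
  expect_equal(sum(st$occupations), 5)
  # closed-shell two-matrix trace N(N-1)
  d2 <- st$rdm2_occ
  tr <- 0
  for (p in 1:5) for (q in 1:5) tr <- tr + d2[p, q, p, q]
  expect_equal(tr, 10 * 9, tolerance = 1e-10)
})

test_that("a six-in-six active specification yields |s2| = 6", {
  # partition arithmetic for a 42-electron monomer with CAS(6,6)
  act <- active_space(6, 6, n_states = 2, target_state = 1)
  n_inact <- (42 - act$n_electrons) / 2
  part <- list(s1 = seq_len(n_inact),
               s2 = n_inact + seq_len(act$n_orbitals),
               s3 = (n_inact + 7):60)
  expect_length(part$s2, 6)
  expect_identical(act$weights, c(0.5, 0.5))
  expect_error(active_space(6, 2), "n_electrons")
  expect_error(active_space(2, 2, n_states = 1, target_state = 2), "target_state")
})

test_that("two-matrix trace identity holds for CAS states", {
  st <- fixture_system("h2o_h2o")$states$A
  d2 <- st$rdm2_occ
  n <- dim(d2)[1]
  tr <- 0
  for (p in seq_len(n)) for (q in seq_len(n)) tr <- tr + d2[p, q, p, q]
  expect_equal(tr, 10 * 9, tolerance = 1e-8)
})

test_that("counterpoise interaction energy vanishes at large separation", {
  far <- translate_geometry(h2_geom(), c(600, 0, 0))
  sup <- supermolecular_energy(h2_geom(), far, "sto-3g", method = "hf")
  expect_lt(abs(sup$e_int), 1e-8)
})

test_that("counterpoise energy equals the three-energy bookkeeping", {
  a <- h2_geom(); b <- translate_geometry(h2_geom(), c(2.5, 0, 0))
  sup <- supermolecular_energy(a, b, "sto-3g", method = "hf")
  e_ab <- rhf(ao_integrals(dimer_geometry(a, b), "sto-3g"), 4)$energy
  e_a <- rhf(ao_integrals(ghosted_geometry(a, b), "sto-3g"), 2)$energy
  e_b <- rhf(ao_integrals(ghosted_geometry(b, a), "sto-3g"), 2)$energy
  expect_equal(sup$e_int, e_ab - e_a - e_b, tolerance = 1e-10)
})

test_that("excited-state preparation tags and orders states correctly", {
  st <- fixture_system("h2_h2_es")$states$A
  expect_identical(st$electronic_state, "ES")
  gs <- fixture_system("h2_h2")$states$A
  expect_gt(st$energy, gs$energy)
})
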