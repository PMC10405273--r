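test_that("orbital optimization lowers the energy and kills the gradient", {
  gA <- h2_geom()
  gB <- translate_geometry(gA, c(3.5, 0, 0))
  ints <- mrdisp:::.dimer_pair_integrals(gA, gB, "6-31g")$a
  scf <- rhf(ints, 2)
  act <- active_space(2, 2)
  C0 <- select_active_orbitals(ints, scf, 2, act, ints$geom)
  mos <- list(C = C0); attr(mos, "nelec") <- 2
  e_casci <- mrdisp:::casci(ints, mos, act)$energies[1]
  opt <- casscf_optimize(ints, C0, 2, act)
  expect_true(opt$converged)
  expect_lt(opt$grad_norm, 1e-6)
  expect_lt(opt$energies[1], e_casci + 1e-12)
})

test_that("analytic orbital gradient matches finite differences", {
  ints <- ao_integrals(water_geom(), "sto-3g")
  scf <- rhf(ints, 10)
  act <- active_space(4, 4)
  C0 <- select_active_orbitals(ints, scf, 10, act, water_geom())
  # water/sto-3g with CAS(4,4): 3 inactive + 4 active fill all 7 orbitals,
  # so the free rotations are active <-> inactive
  rot <- as.matrix(expand.grid(p = 4:7, q = 1:3))
  ctx <- list(act = 4:7, n_inact = 3, active = act, rot_pairs = rot,
              tab = mrdisp:::.det_operator_tables(
                mrdisp:::enumerate_dets(4, 2, 2), 4))
  base <- mrdisp:::.cas_eval(ints, C0, ctx)
  set.seed(2)
  for (k in sample(nrow(rot), 4)) {
    h <- 1e-6
    K <- matrix(0, 7, 7); K[rot[k, 1], rot[k, 2]] <- h; K <- K - t(K)
    ep <- mrdisp:::.cas_eval(ints, C0 %*% mrdisp:::.skew_expm(K), ctx)$energy
    K[] <- 0; K[rot[k, 1], rot[k, 2]] <- -h; K <- K - t(K)
    em <- mrdisp:::.cas_eval(ints, C0 %*% mrdisp:::.skew_expm(K), ctx)$energy
    expect_equal(base$grad[k], (ep - em) / (2 * h), tolerance = 1e-5)
  }
})

test_that("state-averaged optimization keeps both roots ordered", {
  es <- active_space(2, 2, n_states = 2, target_state = 2)
  st <- fixture_system("h2_h2_es")$states$A
  expect_equal(st$electronic_state, "ES")
  # open-shell singlet: both active naturals half-filled
  expect_equal(sort(st$occupations[st$partition$s2]), c(0.5, 0.5),
               tolerance = 1e-8)
})
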