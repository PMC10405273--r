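test_that("delta(HF) is the residual of the mean-field component sum", {
  comp <- sapt_components(-2, 5, -1.5, 1.2, 0, 0, 0)
  expect_equal(delta_hf(-2 + 5 - 1.5 + 1.2, comp), 0)
  # invariant under shifting the supermolecular energy and the component sum
  comp2 <- sapt_components(-2 + 1, 5, -1.5, 1.2, 0, 0, 0)
  expect_equal(delta_hf(3.7, comp), delta_hf(3.7 + 1, comp2))
})

test_that("delta(CAS) scales by the induction ratio and matches printed values", {
  expect_equal(delta_cas(-0.48, -1.45, -1.45), -0.48)
  expect_equal(round_half_away(delta_cas(-0.48, -1.45, -1.42), 2), -0.47)
  expect_equal(round_half_away(delta_cas(-0.43, -1.57, -1.54), 2), -0.42)
  expect_error(delta_cas(-0.4, 0, -1), "zero")
})

test_that("exchange scaling follows the polarization ratio", {
  expect_equal(scale_exchange(1.0, -4.0, -5.0), 1.25)
  expect_equal(scale_exchange(0.87, -3.3, -3.3), 0.87)   # identical bases
  expect_gt(scale_exchange(0.5, -2, -3), 0)              # sign preserved
  expect_error(scale_exchange(1, 0, 1), "zero")
})

test_that("component totals reproduce the printed tables within rounding", {
  t1 <- load_component_table("table1")
  bc <- t1[t1$complex == "benzene-cyclopentane" & t1$state == "GS", ]
  comp <- sapt_components(bc$e_elst, bc$e_exch, bc$e_ind, bc$e_exch_ind,
                          bc$e_disp, bc$e_exch_disp, bc$delta,
                          state = "GS", complex_id = bc$complex)
  expect_equal(total_sapt(comp), -3.63, tolerance = 1e-12)
  expect_equal(total_sapt(sapt_components(0, 0, 0, 0, 0, 0, 0)), 0)
  v <- verify_table_totals()
  expect_true(all(v$consistent))
  expect_true(all(abs(v$deviation) <= 0.015))
})

test_that("supermolecular-plus-dispersion totals match the printed columns", {
  expect_equal(cas_plus_disp(2.75, -7.13, 0.87), -3.51, tolerance = 1e-12)
  expect_equal(cas_plus_disp(2.95, -8.03, 0.85), -4.23, tolerance = 1e-12)
  expect_equal(cas_plus_disp(1.7, 0, 0), 1.7)
})

test_that("the inconsistent printed row is reported, not silently fixed", {
  kd <- known_table_discrepancies()
  expect_equal(nrow(kd), 1)
  expect_equal(kd$complex, "acoh-pentane")
  expect_equal(kd$deviation, 0.06, tolerance = 1e-10)
})

test_that("error metrics reproduce the printed MAE values", {
  t2 <- load_component_table("table2")
  expect_equal(round_half_away(error_metrics(t2$cas_disp, t2$reference)$mae, 2), 0.03)
  t3 <- load_component_table("table3")
  expect_equal(round_half_away(error_metrics(t3$sapt, t3$reference)$mae, 2), 0.10)
  m0 <- error_metrics(c(1, 2), c(1, 2))
  expect_equal(m0$mae, 0)
  expect_equal(m0$mape, 0)
  expect_error(error_metrics(1, 0), "zero")
  expect_error(error_metrics(1:3, 1:2), "equal-length")
})

test_that("excited-minus-ground component differences are antisymmetric", {
  t1 <- load_component_table("table1")
  gs <- t1[t1$state == "GS", ]; es <- t1[t1$state == "ES", ]
  d_es_gs <- es$e_disp - gs$e_disp
  d_gs_es <- gs$e_disp - es$e_disp
  expect_equal(d_es_gs, -d_gs_es)
})
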