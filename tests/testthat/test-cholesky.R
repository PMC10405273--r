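test_that("a 2x2 positive matrix reproduces the closed-form factorization", {
  # accessor for an explicit 2x2 PSD Coulomb-like matrix over one AO pair set
  M <- matrix(c(2.0, 0.6, 0.6, 1.0), 2)
  acc <- list(nao = 2, npairs = 2, pairs = cbind(p = c(1, 2), q = c(1, 2)),
              diag = function() diag(M),
              column = function(p, q) M[, if (p == 1) 1 else 2])
  ch <- pivoted_cholesky(acc, threshold = 1e-14)
  R <- ch$R
  expect_equal(R %*% t(R), M, tolerance = 1e-12)
  # first pivot is the largest diagonal
  expect_equal(abs(R[1, 1]), sqrt(2.0), tolerance = 1e-12)
})

test_that("the residual-sum criterion is honored on a water monomer", {
  acc <- coulomb_accessor_dense(ao_integrals(water_geom(), "sto-3g")$eri)
  ch <- pivoted_cholesky(acc, threshold = 1e-2)
  expect_lt(ch$residual_sum, 1e-2)
  # reconstruction error bounded by the residual criterion
  G <- ch$R %*% t(ch$R)
  exact <- outer(seq_len(acc$npairs), seq_len(acc$npairs),
                 Vectorize(function(i, j) {
                   p <- acc$pairs[i, 1]; q <- acc$pairs[i, 2]
                   acc$column(acc$pairs[j, 1], acc$pairs[j, 2])[i]
                 }))
  expect_lt(max(abs(G - exact)), 1e-2)
})

test_that("vector count is monotone non-increasing in the threshold", {
  acc <- coulomb_accessor_dense(ao_integrals(h2_geom(), "6-31g")$eri)
  n <- vapply(c(1e-8, 1e-4, 1e-2, 1), function(t)
    pivoted_cholesky(acc, t)$n_chol, 0)
  expect_true(all(diff(n) <= 0))
})

test_that("scaled NO factors reconstruct the occupation-scaled integrals", {
  sys <- fixture_system("h2_h2")
  ch <- pivoted_cholesky(coulomb_accessor_dense(sys$ints$a$eri), 1e-10)
  Da <- transform_and_scale(ch, sys$states$A, sys$pairs$A)
  g_rec <- Da %*% t(Da)
  g_ref <- oracle_g_tensor(sys$states$A, sys$nos$A, sys$pairs$A)
  expect_lt(max(abs(g_rec - g_ref)), 1e-8)
  # symmetry of the reconstructed tensor
  expect_equal(g_rec, t(g_rec), tolerance = 1e-12)
})

test_that("mean-field occupied-virtual pairs keep plain Coulomb integrals", {
  sys <- fixture_system("he_he")
  ch <- pivoted_cholesky(coulomb_accessor_dense(sys$ints$a$eri), 1e-10)
  Da <- transform_and_scale(ch, sys$states$A, sys$pairs$A)
  g_rec <- Da %*% t(Da)
  pr <- sys$pairs$A$pairs
  eri_no <- sys$nos$A$eri_no
  for (i in seq_len(nrow(pr)))
    expect_lt(abs(g_rec[i, i] - eri_no[pr$p[i], pr$q[i], pr$p[i], pr$q[i]]),
              1e-8)
})

test_that("non-PSD input is rejected", {
  acc <- list(nao = 1, npairs = 1, pairs = cbind(p = 1, q = 1),
              diag = function() -1, column = function(p, q) -1)
  expect_error(pivoted_cholesky(acc), "not PSD")
})
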