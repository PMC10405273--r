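# The s-type closed forms used here are textbook Gaussian-product results,
# independent of the Hermite-recursion engine under test.

s_eri_closed <- function(a, b, c, d, A, B, C, D) {
  p <- a + b; q <- c + d
  P <- (a * A + b * B) / p; Q <- (c * C + d * D) / q
  K1 <- exp(-a * b / p * sum((A - B)^2)); K2 <- exp(-c * d / q * sum((C - D)^2))
  T <- p * q / (p + q) * sum((P - Q)^2)
  F0 <- if (T < 1e-12) 1 - T / 3 else 0.5 * sqrt(pi / T) * pracma::erf(sqrt(T))
  N <- function(x) (2 * x / pi)^0.75
  2 * pi^2.5 / (p * q * sqrt(p + q)) * K1 * K2 * F0 * N(a) * N(b) * N(c) * N(d)
}

test_that("two-electron integrals over s functions match the closed form", {
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0.3, -0.2, 1.0)))
  bs <- basis_shells(g, "dz.s")
  ints <- ao_integrals(g, "dz.s")
  pos <- lapply(bs$atom, function(i) g$coords[i, ] * mrdisp:::BOHR_PER_ANGSTROM)
  set.seed(1)
  for (rep in 1:40) {
    idx <- sample(8, 4, replace = TRUE)
    ref <- s_eri_closed(bs$exps[idx[1]], bs$exps[idx[2]], bs$exps[idx[3]],
                        bs$exps[idx[4]], pos[[idx[1]]], pos[[idx[2]]],
                        pos[[idx[3]]], pos[[idx[4]]])
    expect_equal(ints$eri[idx[1], idx[2], idx[3], idx[4]], ref, tolerance = 1e-12)
  }
})

test_that("contracted AOs are normalized and the Coulomb diagonal is nonnegative", {
  ints <- ao_integrals(water_geom(), "sto-3g")
  expect_equal(diag(ints$S), rep(1, ints$nao), tolerance = 1e-10)
  acc <- coulomb_accessor_dense(ints$eri)
  expect_true(all(acc$diag() >= 0))
})

test_that("p-function integrals are rotationally invariant", {
  rot <- function(th) rbind(c(cos(th), -sin(th), 0),
                            c(sin(th), cos(th), 0), c(0, 0, 1))
  gw <- water_geom()
  gw2 <- geometry(gw$elements, gw$coords %*% t(rot(0.7)))
  e1 <- rhf(ao_integrals(gw, "sto-3g"), 10)$energy
  e2 <- rhf(ao_integrals(gw2, "sto-3g"), 10)$energy
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("RHF reproduces standard minimal-basis total energies", {
  # well-known STO-3G values at standard geometries
  expect_equal(rhf(ao_integrals(h2_geom(), "sto-3g"), 2)$energy,
               -1.1167, tolerance = 2e-4)
  expect_equal(rhf(ao_integrals(he_geom(), "sto-3g"), 2)$energy,
               -2.8078, tolerance = 2e-4)
  expect_equal(rhf(ao_integrals(water_geom(), "sto-3g"), 10)$energy,
               -74.963, tolerance = 5e-3)
})

test_that("on-demand Coulomb accessor agrees with the dense tensor", {
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.9)))
  acc <- coulomb_accessor(g, "6-31g")
  ints <- ao_integrals(g, "6-31g")
  dense <- coulomb_accessor_dense(ints$eri)
  expect_equal(acc$diag(), dense$diag(), tolerance = 1e-12)
  expect_equal(acc$column(3, 2), dense$column(3, 2), tolerance = 1e-12)
  # far-separated functions barely couple
  gfar <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 40)))
  ifar <- ao_integrals(gfar, "dz.s")
  expect_lt(abs(ifar$eri[1, 5, 1, 5]), 1e-8)
})
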