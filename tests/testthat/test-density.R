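test_that("the dispersion density integrates to the dispersion energy", {
  calc <- fixture_calc("h2_h2", order = 10, keep = TRUE)
  den <- dispersion_density(calc, spacing = 0.25, margin = 4)
  e_int <- sum(den$QAB) * den$voxel_bohr3
  expect_equal(e_int, calc$e_coupled, tolerance = 1e-12)
  # raw (pre-rescale) normalization within 1% on this grid
  expect_lt(abs(den$raw_integral - calc$e_coupled) / abs(calc$e_coupled), 0.01)
  # per-monomer fields carry the same normalization
  expect_equal(sum(den$QA) * den$voxel_bohr3, calc$e_coupled, tolerance = 1e-12)
})

test_that("grid refinement improves the raw normalization", {
  calc <- fixture_calc("h2_h2", order = 10, keep = TRUE)
  coarse <- dispersion_density(calc, spacing = 0.55, margin = 3)
  fine <- dispersion_density(calc, spacing = 0.25, margin = 4)
  err <- function(d) abs(d$raw_integral - d$energy) / abs(d$energy)
  expect_lt(err(fine), err(coarse))
})

test_that("iso-values follow the enclosed-fraction contract", {
  calc <- fixture_calc("h2_h2", order = 10, keep = TRUE)
  den <- dispersion_density(calc, spacing = 0.3)
  iso <- isosurface_fractions(den, c(100, 50, 10, 1))
  expect_equal(unname(iso["100%"]), 0)
  expect_true(all(diff(unname(iso)) >= 0))   # smaller fraction, higher iso
  expect_error(isosurface_fractions(den, c(0.5, 150)))
})

test_that("a synthetic Gaussian blob reproduces the analytic half-mass iso-value", {
  sp <- 0.12; sigma <- 0.8
  ax <- seq(-4, 4, by = sp)
  pts <- expand.grid(x = ax, y = ax, z = ax)
  vals <- exp(-(pts$x^2 + pts$y^2 + pts$z^2) / (2 * sigma^2))
  grid <- structure(list(QAB = array(vals, rep(length(ax), 3)),
                         origin = rep(-4, 3), spacing = sp,
                         dims = rep(length(ax), 3),
                         voxel_bohr3 = sp^3), class = "density_grid")
  iso <- isosurface_fractions(grid, 50)
  # enclosed mass above iso v: radius r(v) = sigma sqrt(-2 log v);
  # fraction = P(chi^2_3 <= r^2/sigma^2); invert for fraction = 1/2
  r2_half <- 2 * sigma^2 * qgamma(0.5, 3 / 2)
  iso_exact <- exp(-r2_half / (2 * sigma^2))
  expect_equal(unname(iso), iso_exact, tolerance = 0.02)
})

test_that("difference densities integrate to the dispersion-energy difference", {
  calc_gs <- fixture_calc("h2_h2", order = 10, keep = TRUE)
  sys_es <- fixture_system("h2_h2_es")
  calc_es_raw <- dispersion_calculation(system = sys_es, threshold = 1e-8,
                                        order = 10, keep = TRUE)
  # same box for both (the ES fixture has a different separation, so rebuild
  # the GS density on the wider box via margin choice is not needed here:
  # compare integrals only)
  den_gs <- dispersion_density(calc_gs, spacing = 0.3)
  den_es <- dispersion_density(calc_es_raw, spacing = 0.3)
  expect_equal(sum(den_es$QAB) * den_es$voxel_bohr3 -
                 sum(den_gs$QAB) * den_gs$voxel_bohr3,
               calc_es_raw$e_coupled - calc_gs$e_coupled, tolerance = 1e-12)
})

test_that("cube export writes a well-formed grid", {
  calc <- fixture_calc("h2_h2", order = 10, keep = TRUE)
  den <- dispersion_density(calc, spacing = 0.45)
  f <- tempfile(fileext = ".cube")
  write_cube(den, f, "QAB", units = "kcal_A3")
  lines <- readLines(f)
  hdr <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  natoms <- as.integer(hdr[1])
  expect_equal(natoms, 4)                 # the full dimer, four real atoms
  nvals <- sum(vapply(lines[-seq_len(6 + natoms)], function(l)
    length(strsplit(trimws(l), "\\s+")[[1]]), 0L))
  expect_equal(nvals, prod(den$dims))
})
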