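# Shared fixture systems, prepared once per test run. All fixtures are
# generated in code; nothing is read from disk except the shipped CSV tables.

.fx_cache <- new.env(parent = emptyenv())

fixture_system <- function(name) {
  if (is.null(.fx_cache[[name]]))
    .fx_cache[[name]] <- prepare_fixture(name)
  .fx_cache[[name]]
}

# tight-threshold high-order dispersion with the direct reference attached
fixture_calc <- function(name, order = 30L, threshold = 1e-8, keep = FALSE) {
  key <- sprintf("calc_%s_%d_%g_%d", name, order, threshold, keep)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- dispersion_calculation(system = fixture_system(name),
                                               threshold = threshold,
                                               order = order, direct = TRUE,
                                               keep = keep)
  .fx_cache[[key]]
}

fixture_sos <- function(name) {
  key <- paste0("sos_", name)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- dispersion_sos_reference(system = fixture_system(name))
  .fx_cache[[key]]
}

# small helper geometries
h2_geom <- function() geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.7414)))
he_geom <- function() geometry("He", matrix(0, 1, 3))
water_geom <- function()
  geometry(c("O", "H", "H"), rbind(c(0, 0, 0.1173),
                                   c(0, 0.7572, -0.4692),
                                   c(0, -0.7572, -0.4692)))
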