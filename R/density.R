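# Spatial dispersion-density maps. Each monomer's share of the dispersion
# energy is attributed per orbital pair to the generalized-occupied member
# and spread over that natural orbital's density, giving fields Q^A, Q^B and
# Q^AB that integrate to E_disp (enforced exactly on the evaluation grid).

# values of all contracted AOs at the given points (bohr): npoints x nao
.ao_values <- function(bs, coords_bohr, points) {
  tab <- .ao_table(bs)
  npt <- nrow(points)
  out <- matrix(0, npt, nrow(tab))
  for (k in seq_len(nrow(tab))) {
    sh <- bs$shells[[tab$shell[k]]]
    at <- sh$atom
    dx <- points[, 1] - coords_bohr[at, 1]
    dy <- points[, 2] - coords_bohr[at, 2]
    dz <- points[, 3] - coords_bohr[at, 3]
    r2 <- dx^2 + dy^2 + dz^2
    rad <- numeric(npt)
    for (i in seq_along(sh$exps))
      rad <- rad + sh$coefs[i] * exp(-sh$exps[i] * r2)
    ang <- rep(1, npt)
    if (tab$px[k] > 0) ang <- ang * dx^tab$px[k]
    if (tab$py[k] > 0) ang <- ang * dy^tab$py[k]
    if (tab$pz[k] > 0) ang <- ang * dz^tab$pz[k]
    out[, k] <- rad * ang
  }
  out
}

# per-pair dispersion-energy contributions for both monomers (hartree)
.pair_contributions <- function(calc) {
  if (is.null(calc$responses))
    stop("pair contributions need a dispersion_calculation(..., keep = TRUE) result")
  grid <- calc$full_grid
  Da <- calc$D$A; Db <- calc$D$B
  ca <- numeric(nrow(Da)); cb <- numeric(nrow(Db))
  for (j in seq_len(grid$n_points)) {
    Ca <- calc$responses$A[[j]]$total
    Cb <- calc$responses$B[[j]]$total
    Wa <- crossprod(Da, Ca)
    Wb <- crossprod(Db, Cb)
    ca <- ca - (8 / pi) * grid$weights[j] * rowSums(Da * (Ca %*% Wb))
    cb <- cb - (8 / pi) * grid$weights[j] * rowSums(Db * (Cb %*% Wa))
  }
  list(A = ca, B = cb)
}

#' Spatial dispersion-density map of a dimer
#'
#' Builds Q^A, Q^B and Q^AB = (Q^A + Q^B)/2 on a regular Cartesian grid.
#' Per-pair contributions of the reduced-scaling dispersion trace are
#' attributed to the occupied natural orbital of each pair and spread over
#' its orbital density; Q^AB is rescaled so its Riemann integral over the
#' grid reproduces the dispersion energy exactly. A warning is issued when
#' the raw (pre-rescaling) normalization is off by more than 5% (grid too
#' coarse).
#'
#' @param calc a `dispersion_result` from [dispersion_calculation()] with
#'   `keep = TRUE`
#' @param spacing grid spacing in angstrom
#' @param margin box margin around the atoms in angstrom
#' @return object of class `density_grid`: `origin` (angstrom), `spacing`,
#'   `dims`, fields `QA`, `QB`, `QAB` (hartree / bohr^3, 3-d arrays),
#'   `energy`, `raw_integral`
#' @export
dispersion_density <- function(calc, spacing = 0.3, margin = 4.0) {
  contrib <- .pair_contributions(calc)
  ints <- calc$ints$a
  geom <- ints$geom
  coords_bohr <- geom$coords * BOHR_PER_ANGSTROM
  lo <- apply(geom$coords, 2, min) - margin
  hi <- apply(geom$coords, 2, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  ax <- lapply(1:3, function(k) lo[k] + spacing * (seq_len(dims[k]) - 1))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  pts_bohr <- pts * BOHR_PER_ANGSTROM
  ao <- .ao_values(ints$basis, coords_bohr, pts_bohr)
  voxel_bohr3 <- (spacing * BOHR_PER_ANGSTROM)^3
  qfield <- function(state, pairs, cpair) {
    w_orb <- tapply(cpair, pairs$pairs$q, sum)
    q <- numeric(nrow(pts))
    mo <- ao %*% state$no_coefficients[, as.integer(names(w_orb)), drop = FALSE]
    for (k in seq_along(w_orb)) q <- q + w_orb[[k]] * mo[, k]^2
    q
  }
  qa <- qfield(calc$states$A, calc$pairs$A, contrib$A)
  qb <- qfield(calc$states$B, calc$pairs$B, contrib$B)
  qab <- (qa + qb) / 2
  raw <- sum(qab) * voxel_bohr3
  e <- calc$e_coupled
  if (abs(raw - e) > 0.05 * abs(e))
    warning(sprintf(paste0("dispersion_density: grid integral %.3e vs energy %.3e ",
                           "(off by %.1f%%); refine spacing/margin"),
                    raw, e, 100 * abs(raw - e) / abs(e)))
  sc <- e / raw
  shape <- function(v) array(v, dims)
  # the map belongs to the physical dimer: both monomers are real atoms
  dimer_geom <- geometry(geom$elements, geom$coords,
                         rep(FALSE, length(geom$elements)))
  structure(list(origin = lo, spacing = spacing, dims = dims,
                 QA = shape(qa * (e / (sum(qa) * voxel_bohr3))),
                 QB = shape(qb * (e / (sum(qb) * voxel_bohr3))),
                 QAB = shape(qab * sc),
                 energy = e, raw_integral = raw,
                 voxel_bohr3 = voxel_bohr3, geom = dimer_geom),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid: %d x %d x %d, spacing %.2f A, integral %.6e Eh (energy %.6e)>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              sum(x$QAB) * x$voxel_bohr3, x$energy))
  invisible(x)
}

#' Difference of two dispersion-density grids (e.g. excited minus ground)
#'
#' Positive regions mark where the (negative) dispersion energy density is
#' depleted in the first grid relative to the second.
#' @param a,b `density_grid` objects on identical grids
#' @export
density_difference <- function(a, b) {
  if (!all(a$dims == b$dims) || any(abs(a$origin - b$origin) > 1e-10))
    stop("density_difference: grids do not match")
  out <- a
  out$QA <- a$QA - b$QA; out$QB <- a$QB - b$QB; out$QAB <- a$QAB - b$QAB
  out$energy <- a$energy - b$energy
  out$raw_integral <- a$raw_integral - b$raw_integral
  out
}

#' Iso-values enclosing given fractions of the integrated density
#'
#' For each fraction f (percent), returns the iso-value v such that the
#' region with `|density| > v` contains f% of the integrated absolute
#' density. A fraction of 100 gives 0.
#'
#' @param grid a `density_grid`
#' @param fractions percentages in (0, 100\]
#' @param field which field to analyze (default `"QAB"`)
#' @export
isosurface_fractions <- function(grid, fractions = c(50, 40, 30, 20, 10, 1),
                                 field = "QAB") {
  v <- abs(as.vector(grid[[field]]))
  if (!length(v) || all(v == 0)) stop("isosurface_fractions: empty grid")
  stopifnot(all(fractions > 0), all(fractions <= 100))
  ord <- order(v, decreasing = TRUE)
  cf <- cumsum(v[ord]) / sum(v)
  out <- vapply(fractions, function(f) {
    if (f >= 100) return(0)
    k <- which(cf >= f / 100)[1]
    v[ord][k]
  }, 0)
  names(out) <- paste0(fractions, "%")
  out
}

#' Write a density field as a Gaussian cube file
#'
#' Standard cube layout (header in bohr, z-fastest value ordering). Ghost
#' centers are omitted from the atom list. Values can be exported in
#' hartree/bohr^3 (default) or kcal/mol/A^3.
#'
#' @param grid a `density_grid`
#' @param path output file
#' @param field `"QAB"`, `"QA"` or `"QB"`
#' @param units `"au"` or `"kcal_A3"`
#' @export
write_cube <- function(grid, path, field = "QAB", units = c("au", "kcal_A3")) {
  units <- match.arg(units)
  vals <- grid[[field]]
  conv <- if (units == "au") 1 else HARTREE_TO_KCAL * BOHR_PER_ANGSTROM^3
  vals <- vals * conv
  geom <- grid$geom
  real <- which(!geom$ghost)
  b <- BOHR_PER_ANGSTROM
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("dispersion density %s (%s)", field, units),
               "generated by mrdisp"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", length(real),
                     grid$origin[1] * b, grid$origin[2] * b, grid$origin[3] * b), con)
  for (k in 1:3) {
    step <- c(0, 0, 0); step[k] <- grid$spacing * b
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[k],
                       step[1], step[2], step[3]), con)
  }
  for (i in real)
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f",
                       .element_charges[geom$elements[i]],
                       .element_charges[geom$elements[i]],
                       geom$coords[i, 1] * b, geom$coords[i, 2] * b,
                       geom$coords[i, 3] * b), con)
  for (ix in seq_len(grid$dims[1]))
    for (iy in seq_len(grid$dims[2])) {
      row <- vals[ix, iy, ]
      for (start in seq(1, length(row), by = 6))
        writeLines(paste(sprintf("%13.5e", row[start:min(start + 5, length(row))]),
                         collapse = " "), con)
    }
  invisible(path)
}
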