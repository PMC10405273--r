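#' @useDynLib mrdisp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim setNames
#' @importFrom utils head read.csv tail
NULL

BOHR_PER_ANGSTROM <- 1 / 0.52917721067
#' Conversion factor from hartree to kcal/mol
#' @export
HARTREE_TO_KCAL <- 627.5095

.element_charges <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
                      F = 9, Ne = 10)

#' Molecular geometry with optional ghost centers
#'
#' A geometry is a set of atomic centers in angstrom. Ghost centers carry basis
#' functions but no nucleus and no electrons; they implement the dimer-centered
#' basis used for counterpoise-consistent monomer calculations.
#'
#' @param elements character vector of element symbols
#' @param coords numeric matrix (n x 3) of Cartesian coordinates in angstrom
#' @param ghost logical vector marking ghost centers (default none)
#' @return an object of class `geometry`
#' @export
geometry <- function(elements, coords, ghost = rep(FALSE, length(elements))) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(length(elements) == nrow(coords), length(ghost) == length(elements))
  if (!all(is.finite(coords))) stop("geometry: coordinates must be finite")
  if (all(ghost)) stop("geometry: at least one non-ghost atom is required")
  if (!all(elements %in% names(.element_charges)))
    stop("geometry: unknown element(s): ",
         paste(setdiff(elements, names(.element_charges)), collapse = ", "))
  structure(list(elements = elements, coords = coords, ghost = as.logical(ghost)),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry: %d centers (%d ghost)>\n", length(x$elements), sum(x$ghost)))
  for (i in seq_along(x$elements))
    cat(sprintf("  %s%-3s %10.5f %10.5f %10.5f\n",
                if (x$ghost[i]) "X-" else "", x$elements[i],
                x$coords[i, 1], x$coords[i, 2], x$coords[i, 3]))
  invisible(x)
}

#' Number of electrons carried by the non-ghost atoms
#' @param geom a [geometry()]
#' @param charge net charge (default 0)
#' @export
n_electrons <- function(geom, charge = 0) {
  sum(.element_charges[geom$elements[!geom$ghost]]) - charge
}

#' Read a geometry from an XYZ file
#'
#' Standard XYZ layout (count line, comment line, element x y z). Ghost centers
#' are marked by a prefix on the element symbol, by default `"X-"`.
#'
#' @param path file path
#' @param ghost_prefix prefix marking ghost atoms
#' @return a [geometry()]
#' @export
read_xyz <- function(path, ghost_prefix = "X-") {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  el <- vapply(rows, `[[`, "", 1)
  ghost <- startsWith(el, ghost_prefix)
  el[ghost] <- substring(el[ghost], nchar(ghost_prefix) + 1)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  geometry(el, xyz, ghost)
}

#' Write a geometry to an XYZ file
#' @param geom a [geometry()]
#' @param path file path
#' @param comment comment line
#' @param ghost_prefix prefix marking ghost atoms
#' @export
write_xyz <- function(geom, path, comment = "", ghost_prefix = "X-") {
  el <- ifelse(geom$ghost, paste0(ghost_prefix, geom$elements), geom$elements)
  lines <- c(length(el), comment,
             sprintf("%-5s %14.8f %14.8f %14.8f", el,
                     geom$coords[, 1], geom$coords[, 2], geom$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Combine two geometries into a dimer
#' @param a,b [geometry()] objects
#' @export
dimer_geometry <- function(a, b) {
  geometry(c(a$elements, b$elements), rbind(a$coords, b$coords),
           c(a$ghost, b$ghost))
}

#' Monomer geometry in the dimer-centered basis
#'
#' Returns `real` with the partner's atoms turned into ghost centers, so the
#' monomer is computed in the full dimer basis (counterpoise-consistent).
#' @param real,partner [geometry()] objects
#' @export
ghosted_geometry <- function(real, partner) {
  geometry(c(real$elements, partner$elements),
           rbind(real$coords, partner$coords),
           c(real$ghost, rep(TRUE, length(partner$elements))))
}

#' Translate a geometry
#' @param geom a [geometry()]
#' @param shift length-3 displacement in angstrom
#' @export
translate_geometry <- function(geom, shift) {
  geometry(geom$elements, sweep(geom$coords, 2, shift, "+"), geom$ghost)
}

nuclear_repulsion <- function(geom) {
  idx <- which(!geom$ghost)
  z <- .element_charges[geom$elements[idx]]
  xyz <- geom$coords[idx, , drop = FALSE] * BOHR_PER_ANGSTROM
  e <- 0
  if (length(idx) > 1)
    for (i in 2:length(idx))
      for (j in 1:(i - 1))
        e <- e + z[i] * z[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  unname(e)
}
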