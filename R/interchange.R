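#' Interchange container for monomer states and Cholesky factors
#'
#' A single hierarchical JSON container with fixed dataset names
#' (`no_coeff`, `occupations`, `partition`, `rdm1`, `rdm2_occ`,
#' `rdm2_active`, `nuclei`, optionally `cholesky/R` and `cholesky/D_A`,
#' `cholesky/D_B`). It lets the whole response machinery run from stored
#' wave-function data without any electronic-structure backend: a state read
#' back from the container is accepted by [build_hessians()],
#' [transform_and_scale()] and everything downstream. Text-based (JSON) so
#' containers are diffable and portable.
#'
#' @param state a `monomer_state`
#' @param path output file
#' @param cholesky optional `cholesky_factor` to embed
#' @param D optional named list of scaled factors to embed (e.g.
#'   `list(A = Da, B = Db)`)
#' @export
write_monomer_state <- function(state, path, cholesky = NULL, D = NULL) {
  obj <- list(
    format = "mrdisp-interchange-1",
    label = state$label,
    electronic_state = state$electronic_state,
    n_electrons = state$n_electrons,
    nao = state$nao,
    no_coeff = state$no_coefficients,
    occupations = state$occupations,
    partition = lapply(state$partition, as.integer),
    rdm1 = state$rdm1,
    rdm2_occ = list(dim = dim(state$rdm2_occ),
                    values = as.vector(state$rdm2_occ)),
    rdm2_active = {
      s2 <- state$partition$s2
      if (length(s2)) list(dim = rep(length(s2), 4),
                           values = as.vector(state$rdm2_occ[s2, s2, s2, s2]))
      else NULL
    },
    nuclei = list(elements = state$geom$elements,
                  coords = state$geom$coords,
                  ghost = state$geom$ghost),
    active = unclass(state$active),
    basis_label = state$basis_label,
    energy = state$energy)
  if (!is.null(cholesky))
    obj$cholesky <- list(R = list(dim = dim(cholesky$R),
                                  values = as.vector(cholesky$R)),
                         pairs = cholesky$pairs,
                         threshold = cholesky$threshold, nao = cholesky$nao,
                         residual_sum = cholesky$residual_sum)
  if (!is.null(D))
    obj$cholesky_D <- lapply(D, function(x)
      list(dim = dim(x), values = as.vector(x)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_monomer_state
#' @param path file written by [write_monomer_state()]
#' @return a `monomer_state` (plus `cholesky`/`cholesky_D` attributes when
#'   embedded)
#' @export
read_monomer_state <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mrdisp-interchange-1"))
    stop("read_monomer_state: not an mrdisp interchange container")
  m <- obj$nao
  part <- lapply(obj$partition, as.integer)
  st <- structure(list(
    label = obj$label,
    no_coefficients = as.matrix(obj$no_coeff),
    occupations = obj$occupations,
    partition = part,
    rdm1 = as.matrix(obj$rdm1),
    rdm2_occ = array(obj$rdm2_occ$values, obj$rdm2_occ$dim),
    n_electrons = obj$n_electrons,
    electronic_state = obj$electronic_state,
    energy = obj$energy,
    active = do.call(active_space, obj$active[c("n_electrons", "n_orbitals",
                                                "n_states", "target_state",
                                                "weights")]),
    basis_label = obj$basis_label,
    geom = geometry(obj$nuclei$elements, obj$nuclei$coords, obj$nuclei$ghost),
    nao = m), class = "monomer_state")
  if (!is.null(obj$cholesky)) {
    R <- array(obj$cholesky$R$values, obj$cholesky$R$dim)
    attr(st, "cholesky") <- structure(
      list(R = R, pairs = as.matrix(obj$cholesky$pairs), n_chol = ncol(R),
           threshold = obj$cholesky$threshold,
           residual_sum = obj$cholesky$residual_sum,
           nao = obj$cholesky$nao),
      class = "cholesky_factor")
  }
  if (!is.null(obj$cholesky_D))
    attr(st, "cholesky_D") <- lapply(obj$cholesky_D, function(x)
      array(x$values, x$dim))
  st
}
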