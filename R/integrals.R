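#' Atomic-orbital integrals for a geometry and basis
#'
#' Computes overlap, kinetic, nuclear-attraction and two-electron Coulomb
#' integrals over contracted Cartesian Gaussians. The electron-repulsion
#' tensor is returned in chemist convention: `eri[p,q,r,s]` is `(pq|rs)`,
#' the Coulomb interaction of densities `pq` and `rs`. Ghost centers
#' contribute basis functions but no nuclear potential.
#'
#' @param geom a [geometry()]
#' @param basis_label basis-set label, see [basis_shells()]
#' @return list with `S`, `T`, `V`, `hcore`, `eri` (4-d array), `nao`,
#'   `enuc`, the basis structure and the geometry
#' @export
ao_integrals <- function(geom, basis_label) {
  bs <- basis_shells(geom, basis_label)
  coords <- geom$coords * BOHR_PER_ANGSTROM
  charges <- ifelse(geom$ghost, 0, .element_charges[geom$elements])
  one <- cpp_one_electron(coords, charges, as.integer(bs$atom), as.integer(bs$l),
                          as.integer(bs$nprim), bs$exps, bs$coefs)
  eri <- cpp_eri(coords, as.integer(bs$atom), as.integer(bs$l),
                 as.integer(bs$nprim), bs$exps, bs$coefs)
  dim(eri) <- rep(bs$nao, 4)
  list(S = one$S, T = one$T, V = one$V, hcore = one$T + one$V, eri = eri,
       nao = bs$nao, enuc = nuclear_repulsion(geom), basis = bs, geom = geom,
       basis_label = basis_label)
}

#' Coulomb-matrix accessor for pivoted Cholesky decomposition
#'
#' Exposes the diagonal `(pq|pq)` and on-demand columns `(rs|pq)` of the AO
#' Coulomb matrix over triangle pairs `p >= q` without keeping the fourth-order
#' tensor in memory; each request re-evaluates the needed shell quartets.
#'
#' @param geom a [geometry()]
#' @param basis_label basis-set label
#' @return list with `nao`, `npairs`, `diag()` and `column(p, q)` closures and
#'   the pair table (`p`, `q`, both 1-based, p >= q)
#' @export
coulomb_accessor <- function(geom, basis_label) {
  bs <- basis_shells(geom, basis_label)
  coords <- geom$coords * BOHR_PER_ANGSTROM
  nao <- bs$nao
  pr <- do.call(rbind, lapply(seq_len(nao), function(p)
    cbind(p = p, q = seq_len(p))))
  list(
    nao = nao,
    npairs = nrow(pr),
    pairs = pr,
    diag = function() {
      d <- cpp_coulomb_diag(coords, as.integer(bs$atom), as.integer(bs$l),
                            as.integer(bs$nprim), bs$exps, bs$coefs)
      if (any(d < -1e-10)) stop("Coulomb diagonal has negative entries")
      d
    },
    column = function(p, q) {
      cpp_coulomb_column(coords, as.integer(bs$atom), as.integer(bs$l),
                         as.integer(bs$nprim), bs$exps, bs$coefs,
                         as.integer(p), as.integer(q))
    })
}

#' Dense in-memory Coulomb accessor built from a precomputed ERI tensor
#'
#' Same contract as [coulomb_accessor()], backed by an existing `eri` array;
#' used when the tensor is already available (e.g. inside a full calculation).
#' @param eri 4-d ERI array in chemist convention
#' @export
coulomb_accessor_dense <- function(eri) {
  nao <- dim(eri)[1]
  pr <- do.call(rbind, lapply(seq_len(nao), function(p)
    cbind(p = p, q = seq_len(p))))
  pick <- function(p, q) eri[cbind(pr[, 1], pr[, 2], p, q)]
  list(nao = nao, npairs = nrow(pr), pairs = pr,
       diag = function() eri[cbind(pr[, 1], pr[, 2], pr[, 1], pr[, 2])],
       column = pick)
}

# 4-index transformation of the ERI tensor to a new orbital basis
transform_eri <- function(eri, C) {
  m <- dim(eri)[1]
  k <- ncol(C)
  x <- matrix(eri, m, m^3)                 # p | qrs
  x <- crossprod(C, x)                     # p' | qrs
  x <- array(x, c(k, m, m, m))
  x <- aperm(x, c(2, 3, 4, 1))             # q r s p'
  x <- matrix(x, m, m^2 * k)
  x <- crossprod(C, x)                     # q' | rsp'
  x <- array(x, c(k, m, m, k))
  x <- aperm(x, c(2, 3, 4, 1))             # r s p' q'
  x <- matrix(x, m, m * k^2)
  x <- crossprod(C, x)                     # r' | sp'q'
  x <- array(x, c(k, m, k, k))
  x <- aperm(x, c(2, 3, 4, 1))             # s p' q' r'
  x <- matrix(x, m, k^3)
  x <- crossprod(C, x)                     # s' | p'q'r'
  aperm(array(x, c(k, k, k, k)), c(2, 3, 4, 1))
}
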