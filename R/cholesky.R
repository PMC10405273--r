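#' Pivoted Cholesky decomposition of the AO Coulomb matrix
#'
#' Incomplete Cholesky factorization of the positive-semidefinite matrix
#' `(pq|rs)` over triangle AO pairs `p >= q`, with full pivoting on the
#' largest remaining diagonal (ties broken by lowest pair index). The
#' factorization stops once the summed residual diagonal
#' `sum_{p>=q} ((pq|pq) - sum_L R_pq,L^2)` drops below `threshold` -- a sum
#' criterion, not a max criterion. The production default is 1e-2; a tight
#' threshold (1e-8) reproduces the integrals to oracle accuracy.
#'
#' @param accessor a Coulomb accessor ([coulomb_accessor()] or
#'   [coulomb_accessor_dense()])
#' @param threshold residual-sum stopping criterion
#' @param max_vectors optional cap on the number of Cholesky vectors
#' @return object of class `cholesky_factor`: `R` (n_pairs x n_chol),
#'   `pairs`, `n_chol`, `threshold`, `residual_sum`
#' @export
pivoted_cholesky <- function(accessor, threshold = 1e-2, max_vectors = Inf) {
  d <- accessor$diag()
  if (any(d < -1e-10)) stop("pivoted_cholesky: negative diagonal, input not PSD")
  d <- pmax(d, 0)
  npair <- accessor$npairs
  Rv <- list()
  repeat {
    if (sum(d) < threshold || length(Rv) >= max_vectors || length(Rv) >= npair)
      break
    k <- which.max(d)      # ties: which.max returns the lowest index
    piv <- d[k]
    if (piv <= 0) break
    col <- accessor$column(accessor$pairs[k, 1], accessor$pairs[k, 2])
    if (length(Rv)) {
      Rmat <- do.call(cbind, Rv)
      col <- col - Rmat %*% Rmat[k, ]
    }
    vec <- as.numeric(col) / sqrt(piv)
    Rv[[length(Rv) + 1]] <- vec
    d <- d - vec^2
    if (min(d) < -1e-8 * max(abs(d), 1))
      stop("pivoted_cholesky: negative residual pivot beyond numerical noise")
    d <- pmax(d, 0)
  }
  R <- if (length(Rv)) do.call(cbind, Rv) else matrix(0, npair, 0)
  structure(list(R = R, pairs = accessor$pairs, n_chol = ncol(R),
                 threshold = threshold, residual_sum = sum(d), nao = accessor$nao),
            class = "cholesky_factor")
}

#' @export
print.cholesky_factor <- function(x, ...) {
  cat(sprintf("<cholesky_factor: %d vectors over %d AO pairs, residual %.3e (threshold %.1e)>\n",
              x$n_chol, nrow(x$R), x$residual_sum, x$threshold))
  invisible(x)
}

#' Occupation-scaled natural-orbital Cholesky factors
#'
#' Transforms the AO Cholesky vectors to the monomer's natural-orbital basis
#' and applies the occupation scaling, D_(pq),L = (sqrt(n_p) + sqrt(n_q))
#' R~_(pq),L, so that sum_L D D^T reconstructs the modified integral tensor g.
#' One AO decomposition (dimer-centered basis) serves both monomers.
#'
#' @param chol a `cholesky_factor`
#' @param state a `monomer_state`
#' @param pairs the monomer's `pair_index`
#' @return matrix (n_pairs x n_chol)
#' @export
transform_and_scale <- function(chol, state, pairs) {
  m <- chol$nao
  if (nrow(state$no_coefficients) != m)
    stop("transform_and_scale: AO dimension mismatch between factor and state")
  C <- state$no_coefficients
  fac <- sqrt(state$occupations)
  pr <- pairs$pairs
  D <- matrix(0, pairs$n, chol$n_chol)
  if (chol$n_chol == 0) return(D)
  Cp <- C[, pr$p, drop = FALSE]
  Cq <- C[, pr$q, drop = FALSE]
  for (L in seq_len(chol$n_chol)) {
    Msym <- matrix(0, m, m)
    Msym[chol$pairs] <- chol$R[, L]
    Msym[chol$pairs[, c(2, 1)]] <- chol$R[, L]
    # R~_pq = c_p^T M c_q for each listed pair
    D[, L] <- (fac[pr$p] + fac[pr$q]) * colSums(Cp * (Msym %*% Cq))
  }
  D
}
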