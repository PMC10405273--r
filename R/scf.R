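#' Restricted Hartree-Fock
#'
#' Plain closed-shell SCF with DIIS acceleration, suitable for the desk-scale
#' systems this package targets. Orbitals are returned in increasing orbital
#' energy with a deterministic sign convention (largest-magnitude coefficient
#' positive).
#'
#' @param ints output of [ao_integrals()]
#' @param nelec number of electrons (even)
#' @param max_iter,conv iteration cap and density convergence threshold
#' @return list with `C` (AO x MO coefficients), `eps` (orbital energies),
#'   `energy` (total electronic + nuclear), `nocc`, `converged`
#' @export
rhf <- function(ints, nelec, max_iter = 200L, conv = 1e-10) {
  if (nelec %% 2 != 0) stop("rhf: only closed-shell (even) electron counts")
  nocc <- nelec / 2
  m <- ints$nao
  if (nocc > m) stop("rhf: more occupied orbitals than basis functions")
  S <- ints$S
  se <- eigen(S, symmetric = TRUE)
  if (min(se$values) < 1e-9) stop("rhf: near-singular overlap matrix")
  X <- se$vectors %*% diag(1 / sqrt(se$values), m) %*% t(se$vectors)
  h <- ints$hcore
  eri_mat <- matrix(ints$eri, m * m, m * m)       # (pq | rs)
  eriK <- matrix(aperm(ints$eri, c(1, 3, 2, 4)), m * m, m * m)  # (pr | qs)

  mo_from_fock <- function(F) {
    Ft <- t(X) %*% F %*% X
    ev <- eigen((Ft + t(Ft)) / 2, symmetric = TRUE)
    ord <- order(ev$values)            # ascending orbital energies
    ev$values <- ev$values[ord]
    ev$vectors <- ev$vectors[, ord, drop = FALSE]
    C <- X %*% ev$vectors
    # deterministic phases
    for (k in seq_len(m)) {
      j <- which.max(abs(C[, k]))
      if (C[j, k] < 0) C[, k] <- -C[, k]
    }
    list(C = C, eps = ev$values)
  }

  mo <- mo_from_fock(h)
  D <- 2 * tcrossprod(mo$C[, seq_len(nocc), drop = FALSE])
  fock <- function(D) {
    J <- matrix(eri_mat %*% as.vector(D), m, m)
    K <- matrix(eriK %*% as.vector(D), m, m)
    h + J - 0.5 * K
  }
  errs <- list(); focks <- list()
  converged <- FALSE
  energy <- NA_real_
  for (it in seq_len(max_iter)) {
    F <- fock(D)
    energy <- 0.5 * sum(D * (h + F)) + ints$enuc
    # DIIS on the orbital-gradient residual FDS - SDF
    r <- F %*% D %*% S - S %*% D %*% F
    errs[[length(errs) + 1]] <- as.vector(r)
    focks[[length(focks) + 1]] <- F
    if (length(errs) > 8) { errs <- errs[-1]; focks <- focks[-1] }
    nd <- length(errs)
    if (nd > 1) {
      B <- matrix(0, nd + 1, nd + 1)
      for (i in seq_len(nd)) for (j in seq_len(nd))
        B[i, j] <- sum(errs[[i]] * errs[[j]])
      B[nd + 1, seq_len(nd)] <- B[seq_len(nd), nd + 1] <- -1
      rhs <- c(rep(0, nd), -1)
      cf <- tryCatch(solve(B, rhs)[seq_len(nd)], error = function(e) NULL)
      if (!is.null(cf)) {
        F <- Reduce(`+`, Map(`*`, focks, cf))
      }
    }
    mo <- mo_from_fock(F)
    Dn <- 2 * tcrossprod(mo$C[, seq_len(nocc), drop = FALSE])
    if (max(abs(Dn - D)) < conv) { D <- Dn; converged <- TRUE; break }
    D <- Dn
  }
  if (!converged)
    stop(sprintf("rhf: SCF not converged in %d iterations (last dmax change at %g)",
                 max_iter, max(abs(Dn - D))))
  F <- fock(D)
  energy <- 0.5 * sum(D * (h + F)) + ints$enuc
  mo <- mo_from_fock(F)
  list(C = mo$C, eps = mo$eps, energy = energy, nocc = nocc, converged = converged)
}
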