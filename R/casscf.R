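# Orbital-optimized (state-averaged) CASSCF. The orbital gradient uses the
# generalized Fock matrix built from the state-averaged active RDMs; the
# rotation is parametrized by the independent inter-space generators and
# optimized quasi-Newton. Desk-scale systems only: every iteration performs
# a full integral transformation.
#
# The CI problem is solved through precomputed operator tables over the fixed
# active determinant basis: columns of E1tab / O2tab hold the matrix
# representations of E_tu and e_(pq),(rs) = E_pr E_qs - delta_qr E_ps, so the
# Hamiltonian assembly and the RDMs reduce to single matrix products.

.skew_expm <- function(K) {
  nrm <- max(abs(K))
  if (nrm == 0) return(diag(nrow(K)))
  s <- max(0L, ceiling(log2(nrm / 0.25)))
  A <- K / 2^s
  U <- diag(nrow(K)); term <- diag(nrow(K))
  for (k in 1:16) {
    term <- term %*% A / k
    U <- U + term
    if (max(abs(term)) < 1e-16) break
  }
  for (i in seq_len(s)) U <- U %*% U
  sv <- svd(U)
  sv$u %*% t(sv$v)
}

# operator tables over an active determinant basis
.det_operator_tables <- function(dets, M) {
  nd <- length(dets)
  keys <- vapply(dets, det_key, "")
  Emat <- function(a, b) {
    out <- matrix(0, nd, nd)
    for (j in seq_len(nd)) {
      r <- apply_E(wf_new(dets[j], 1), a, b)
      if (length(r$coef))
        out[match(vapply(r$dets, det_key, ""), keys), j] <- r$coef
    }
    out
  }
  E1 <- matrix(0, nd * nd, M * M)
  Ms <- vector("list", M * M)
  for (u in seq_len(M)) for (t in seq_len(M)) {
    Ms[[t + (u - 1) * M]] <- Emat(t, u)
    E1[, t + (u - 1) * M] <- as.vector(Ms[[t + (u - 1) * M]])
  }
  O2 <- matrix(0, nd * nd, M^4)
  for (s in seq_len(M)) for (r in seq_len(M)) for (q in seq_len(M)) for (p in seq_len(M)) {
    Mop <- Ms[[p + (r - 1) * M]] %*% Ms[[q + (s - 1) * M]]
    if (q == r) Mop <- Mop - Ms[[p + (s - 1) * M]]
    O2[, p + (q - 1) * M + (r - 1) * M^2 + (s - 1) * M^3] <- as.vector(Mop)
  }
  list(E1 = E1, O2 = O2, n_det = nd)
}

# energy, gradient and CI data at given MO coefficients, using tables
.cas_eval <- function(ints, C, ctx) {
  m <- ints$nao
  act <- ctx$act
  M <- length(act)
  iidx <- seq_len(ctx$n_inact)
  v <- transform_eri(ints$eri, C)
  hmo <- t(C) %*% ints$hcore %*% C
  F_in <- hmo
  for (i in iidx) F_in <- F_in + 2 * v[, , i, i] - v[, i, i, ]
  e_core <- ints$enuc
  if (ctx$n_inact > 0) e_core <- e_core + sum(diag((hmo + F_in)[iidx, iidx, drop = FALSE]))
  heff <- F_in[act, act, drop = FALSE]
  v_act <- v[act, act, act, act, drop = FALSE]
  vphys <- aperm(array(v_act, rep(M, 4)), c(1, 3, 2, 4))   # <pq|rs>
  nd <- ctx$tab$n_det
  H <- matrix(ctx$tab$E1 %*% as.vector(heff) +
                0.5 * ctx$tab$O2 %*% as.vector(vphys), nd, nd)
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(ev$values)
  energies <- e_core + ev$values[ord]
  vecs <- ev$vectors[, ord, drop = FALSE]
  ns <- ctx$active$n_states
  e_sa <- sum(ctx$active$weights * energies[seq_len(ns)])
  # state-averaged RDMs through the same tables
  P <- matrix(0, nd, nd)
  for (k in seq_len(ns))
    P <- P + ctx$active$weights[k] * tcrossprod(vecs[, k])
  g1 <- matrix(crossprod(ctx$tab$E1, as.vector(P)), M, M)
  g2 <- array(crossprod(ctx$tab$O2, as.vector(P)), rep(M, 4))
  G2c <- aperm(g2, c(1, 3, 2, 4))                          # chemist pairing
  F_act <- matrix(0, m, m)
  for (t in seq_len(M)) for (u in seq_len(M)) {
    if (abs(g1[t, u]) < 1e-14) next
    F_act <- F_act + g1[t, u] * (v[, , act[t], act[u]] - 0.5 * v[, act[t], act[u], ])
  }
  Fg <- matrix(0, m, m)
  if (ctx$n_inact > 0) Fg[iidx, ] <- 2 * t((F_in + F_act)[, iidx, drop = FALSE])
  if (M > 0) {
    Fg[act, ] <- g1 %*% t(F_in[, act, drop = FALSE])
    vq <- array(v[, act, act, act], c(m, M, M, M))
    for (t in seq_len(M))
      Fg[act[t], ] <- Fg[act[t], ] +
        as.vector(matrix(vq, m, M^3) %*% as.vector(G2c[t, , , ]))
  }
  grad_full <- 2 * (t(Fg) - Fg)   # dE/dK_pq for the C -> C exp(K) convention
  list(energy = e_sa, grad = grad_full[ctx$rot_pairs],
       energies = energies, vecs = vecs)
}

#' State-averaged CASSCF orbital optimization
#'
#' Minimizes the (state-averaged) CASCI energy with respect to orbital
#' rotations between the inactive, active and virtual spaces, using analytic
#' generalized-Fock gradients and quasi-Newton steps on the exponential
#' parametrization. Starting orbitals come from [rhf()] with the
#' population-based active selection of [select_active_orbitals()].
#'
#' @param ints [ao_integrals()] for the geometry
#' @param C0 starting MO coefficients (AO x MO, S-orthonormal)
#' @param nelec total electron count
#' @param active an [active_space()]
#' @param max_iter,grad_tol outer iteration cap and gradient convergence
#' @return list with optimized `C`, `energies` (per state), `iterations`,
#'   `grad_norm`, `converged`
#' @export
casscf_optimize <- function(ints, C0, nelec, active, max_iter = 400L,
                            grad_tol = 1e-7) {
  m <- ints$nao
  n_inact <- (nelec - active$n_electrons) / 2
  act <- n_inact + seq_len(active$n_orbitals)
  virt <- setdiff(seq_len(m), c(seq_len(n_inact), act))
  pairs <- rbind(
    if (n_inact > 0 && length(act)) expand.grid(p = act, q = seq_len(n_inact)),
    if (n_inact > 0 && length(virt)) expand.grid(p = virt, q = seq_len(n_inact)),
    if (length(act) && length(virt)) expand.grid(p = virt, q = act))
  rot_pairs <- as.matrix(pairs)
  npar <- if (is.null(rot_pairs)) 0L else nrow(rot_pairs)
  na <- active$n_electrons / 2
  dets <- enumerate_dets(active$n_orbitals, na, na)
  ctx <- list(act = act, n_inact = n_inact, active = active,
              rot_pairs = rot_pairs,
              tab = .det_operator_tables(dets, active$n_orbitals))
  C <- C0
  last <- .cas_eval(ints, C, ctx)
  if (npar == 0)
    return(list(C = C, energies = last$energies[seq_len(active$n_states)],
                iterations = 0L, grad_norm = 0, converged = TRUE))
  Hinv <- diag(npar)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    g <- last$grad
    if (max(abs(g)) < grad_tol) { converged <- TRUE; break }
    d <- -as.vector(Hinv %*% g)
    step <- min(1, 0.35 / max(abs(d)))
    improved <- FALSE
    for (ls in 1:25) {
      K <- matrix(0, m, m)
      K[rot_pairs] <- step * d
      K <- K - t(K)
      Cn <- C %*% .skew_expm(K)
      trial <- .cas_eval(ints, Cn, ctx)
      if (trial$energy < last$energy + 1e-13) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) break
    s <- step * d
    y <- trial$grad - g
    sy <- sum(s * y)
    if (sy > 1e-12) {
      rho <- 1 / sy
      I <- diag(npar)
      Hinv <- (I - rho * outer(s, y)) %*% Hinv %*% (I - rho * outer(y, s)) +
        rho * outer(s, s)
    } else {
      Hinv <- diag(npar)
    }
    C <- Cn
    last <- trial
  }
  if (!converged && max(abs(last$grad)) >= grad_tol * 100)
    warning(sprintf("casscf_optimize: gradient %.2e after %d iterations",
                    max(abs(last$grad)), it))
  list(C = C, energies = last$energies[seq_len(active$n_states)],
       iterations = it, grad_norm = max(abs(last$grad)),
       converged = converged)
}
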