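# Independent brute-force oracles. These deliberately share no kernels with
# the production paths: Hessians come from explicit operator matrices over a
# full determinant space, and the g tensor from a dense integral transform.

#' Brute-force ERPA matrices from determinant-space operator algebra
#'
#' Evaluates the equation-of-motion double commutators
#' `<0|[E_qp, [H, E_rs]]|0>` literally, by building the Hamiltonian and the
#' spin-summed excitation operators as matrices over the full determinant
#' space in the state's natural-orbital basis. Exponential cost: intended for
#' two-electron monomers in tiny bases as an independent check of the
#' RDM-contraction Hessian build.
#'
#' @param state a `monomer_state`
#' @param integrals natural-orbital integrals from [no_integrals()]
#' @param pairs a `pair_index`
#' @return list with raw EOM matrices `A` and `B` over the pair index
#' @export
erpa_eom_bruteforce <- function(state, integrals, pairs) {
  m <- state$nao
  nel <- state$n_electrons
  if (choose(2 * m, nel) > 50000) stop("erpa_eom_bruteforce: system too large")
  na <- nel / 2
  dets <- enumerate_dets(m, na, na)
  keys <- vapply(dets, det_key, "")
  H <- slater_condon_H(dets, integrals$h_no, integrals$eri_no)
  # the reference state: re-solve the CAS problem in the NO active orbitals
  act <- state$partition$s2
  n_inact <- length(state$partition$s1)
  if (length(act) > 0) {
    heff <- integrals$h_no[act, act, drop = FALSE]
    if (n_inact > 0) {
      iidx <- state$partition$s1
      for (t in seq_along(act)) for (u in seq_along(act)) {
        v <- 0
        for (i in iidx)
          v <- v + 2 * integrals$eri_no[i, i, act[t], act[u]] -
            integrals$eri_no[i, act[t], i, act[u]]
        heff[t, u] <- heff[t, u] + v
      }
    }
    v_act <- integrals$eri_no[act, act, act, act, drop = FALSE]
    adets <- enumerate_dets(length(act), state$active$n_electrons / 2,
                            state$active$n_electrons / 2)
    Ha <- slater_condon_H(adets, heff, array(v_act, rep(length(act), 4)))
    ev <- eigen((Ha + t(Ha)) / 2, symmetric = TRUE)
    ord <- order(ev$values)
    civec <- ev$vectors[, ord[state$active$target_state]]
    core_so <- if (n_inact > 0)
      sort(c(so_index(seq_len(n_inact), 1L), so_index(seq_len(n_inact), 2L)))
    else integer(0)
    psi <- numeric(length(dets))
    for (i in seq_along(adets)) {
      sp <- so_spatial(adets[[i]]) + n_inact
      full <- sort(c(core_so, so_index(sp, so_spin(adets[[i]]))))
      psi[match(det_key(full), keys)] <- civec[i]
    }
  } else {
    occ_so <- sort(c(so_index(seq_len(na), 1L), so_index(seq_len(na), 2L)))
    psi <- as.numeric(keys == det_key(occ_so))
  }
  # spin-summed excitation operator matrices
  Emat <- function(a, b) {
    M <- matrix(0, length(dets), length(dets))
    for (j in seq_along(dets)) {
      out <- apply_E(wf_new(dets[j], 1), a, b)
      if (length(out$coef))
        M[match(vapply(out$dets, det_key, ""), keys), j] <- out$coef
    }
    M
  }
  np <- pairs$n
  A <- matrix(0, np, np); B <- matrix(0, np, np)
  Ecache <- list()
  getE <- function(a, b) {
    k <- paste(a, b)
    if (is.null(Ecache[[k]])) Ecache[[k]] <<- Emat(a, b)
    Ecache[[k]]
  }
  dc <- function(Eqp, Ers) {
    # <psi| [E_qp, [H, E_rs]] |psi>
    inner <- H %*% Ers - Ers %*% H
    comm <- Eqp %*% inner - inner %*% Eqp
    as.numeric(t(psi) %*% comm %*% psi)
  }
  for (i in seq_len(np)) {
    p <- pairs$pairs$p[i]; q <- pairs$pairs$q[i]
    Eqp <- getE(q, p)
    for (j in seq_len(np)) {
      r <- pairs$pairs$p[j]; s <- pairs$pairs$q[j]
      A[i, j] <- dc(Eqp, getE(r, s))
      B[i, j] <- dc(Eqp, getE(s, r))
    }
  }
  list(A = A, B = B, psi = psi)
}

#' Dense occupation-scaled integral tensor (direct assembly)
#'
#' Builds g over monomer pairs directly from the NO-basis Coulomb integrals,
#' g_(pq),(rs) = (sqrt(n_p) + sqrt(n_q)) (sqrt(n_r) + sqrt(n_s)) (pq|rs),
#' as an element-wise reference for the Cholesky-factorized representation.
#'
#' @param state a `monomer_state`
#' @param integrals natural-orbital integrals
#' @param pairs a `pair_index` over the state's partition
#' @return matrix (n_pairs x n_pairs)
#' @export
oracle_g_tensor <- function(state, integrals, pairs) {
  if (state$nao > 40) stop("oracle_g_tensor: size guard exceeded")
  fac <- sqrt(state$occupations)
  pr <- pairs$pairs
  n <- pairs$n
  g <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    g[i, j] <- (fac[pr$p[i]] + fac[pr$q[i]]) * (fac[pr$p[j]] + fac[pr$q[j]]) *
      integrals$eri_no[pr$p[i], pr$q[i], pr$p[j], pr$q[j]]
  }
  g
}

#' Cross-monomer occupation-scaled coupling matrix (dense assembly)
#'
#' Same as [oracle_g_tensor()] but coupling the pair space of monomer A to
#' that of monomer B through the shared (dimer-centered) AO basis.
#'
#' @param state_a,state_b `monomer_state` objects sharing one AO basis
#' @param eri_ao shared AO ERI tensor (chemist convention)
#' @param pairs_a,pairs_b pair indices of the two monomers
#' @return matrix (n_pairs_A x n_pairs_B)
#' @export
g_cross_dense <- function(state_a, state_b, eri_ao, pairs_a, pairs_b) {
  Ca <- state_a$no_coefficients
  Cb <- state_b$no_coefficients
  m <- dim(eri_ao)[1]
  # (p_A q_A | r_B s_B): transform first two indices by Ca, last two by Cb
  x <- matrix(eri_ao, m, m^3)
  x <- array(crossprod(Ca, x), c(m, m, m, m)); x <- aperm(x, c(2, 3, 4, 1))
  x <- matrix(x, m, m^3)
  x <- array(crossprod(Ca, x), c(m, m, m, m)); x <- aperm(x, c(2, 3, 4, 1))
  x <- matrix(x, m, m^3)
  x <- array(crossprod(Cb, x), c(m, m, m, m)); x <- aperm(x, c(2, 3, 4, 1))
  x <- matrix(x, m, m^3)
  x <- array(crossprod(Cb, x), c(m, m, m, m)); x <- aperm(x, c(2, 3, 4, 1))
  fa <- sqrt(state_a$occupations); fb <- sqrt(state_b$occupations)
  pa <- pairs_a$pairs; pb <- pairs_b$pairs
  g <- matrix(0, pairs_a$n, pairs_b$n)
  for (i in seq_len(pairs_a$n)) for (j in seq_len(pairs_b$n)) {
    g[i, j] <- (fa[pa$p[i]] + fa[pa$q[i]]) * (fb[pb$p[j]] + fb[pb$q[j]]) *
      x[pa$p[i], pa$q[i], pb$p[j], pb$q[j]]
  }
  g
}
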