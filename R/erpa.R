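#' ERPA Hessian matrices of a monomer
#'
#' Builds the symmetric pair-index Hessians A+ and A- from the equation-of-
#' motion double commutators evaluated with the state's spin-free one- and
#' two-electron reduced density matrices (natural-orbital basis), absorbs the
#' diagonal response metric 2(n_q - n_p), and records the block layout used
#' by the coupling-constant expansion. In the single-determinant limit the
#' matrices reduce to the standard singlet RPA combinations A+B and A-B.
#'
#' @param state a `monomer_state` (see [prepare_monomer_state()])
#' @param integrals natural-orbital integrals from [no_integrals()]
#' @param pairs a `pair_index` built from the state's partition and
#'   occupations
#' @return object of class `erpa_hessians` with `A_plus`, `A_minus` (metric-
#'   absorbed), `metric`, `pairs`, and the raw EOM matrices
#' @export
build_hessians <- function(state, integrals, pairs) {
  m <- state$nao
  occ <- state$occupations
  if (abs(2 * sum(occ) - state$n_electrons) > 1e-8)
    stop("build_hessians: one-matrix trace inconsistent with electron count")
  d1 <- 2 * occ
  n_go <- dim(state$rdm2_occ)[1]
  d2 <- array(0, rep(m, 4))
  d2[seq_len(n_go), seq_len(n_go), seq_len(n_go), seq_len(n_go)] <- state$rdm2_occ
  pr <- as.matrix(pairs$pairs[, c("p", "q")])
  res <- cpp_erpa_hessians(m, integrals$h_no, as.vector(integrals$eri_no),
                           d1, as.vector(d2), pr)
  # EOM convention: the de-excitation coupling block enters with a minus sign,
  # so A+B (textbook) = A_eom - B_eom and A-B = A_eom + B_eom
  Ap <- res$A - res$B
  Am <- res$A + res$B
  Ap <- (Ap + t(Ap)) / 2
  Am <- (Am + t(Am)) / 2
  metric <- d1[pr[, 2]] - d1[pr[, 1]]      # 2 (n_q - n_p) > 0 by construction
  if (any(metric <= 0))
    stop("build_hessians: nonpositive metric; rebuild pairs with occupations")
  s <- 1 / sqrt(metric)
  Ap <- Ap * tcrossprod(s)
  Am <- Am * tcrossprod(s)
  structure(list(A_plus = Ap, A_minus = Am, metric = metric, pairs = pairs,
                 eom_A = res$A, eom_B = res$B,
                 normalization = "Y = omega^(-1/2) (A-)^(1/2) u, u orthonormal"),
            class = "erpa_hessians")
}

#' Split the Hessians into block-diagonal (alpha = 0) and coupling parts
#'
#' The zeroth-order Hamiltonian of the coupling-constant expansion is chosen
#' so that its Hessian is the block-diagonal restriction of the full one to
#' the layout declared by the pair index (active-active block; per-inactive
#' and per-virtual active subblocks; diagonal inactive->virtual entries).
#' A0 + A1 reproduces the input exactly.
#'
#' @param h an `erpa_hessians`
#' @return the same object with `A0_plus`, `A0_minus`, `A1_plus`, `A1_minus`
#'   and `block_layout` attached
#' @export
split_alpha <- function(h) {
  n <- nrow(h$A_plus)
  mask <- matrix(FALSE, n, n)
  for (b in h$pairs$blocks) mask[b, b] <- TRUE
  h$A0_plus <- ifelse(mask, h$A_plus, 0)
  h$A0_minus <- ifelse(mask, h$A_minus, 0)
  h$A1_plus <- h$A_plus - h$A0_plus
  h$A1_minus <- h$A_minus - h$A0_minus
  h$block_layout <- h$pairs$blocks
  h
}

#' Solve the ERPA eigenproblem
#'
#' Works in the metric-absorbed representation: with S = (A-)^(1/2), the
#' symmetric product S A+ S is diagonalized, omega_nu = sqrt(lambda_nu), and
#' transition vectors Y_nu = omega_nu^(-1/2) S u_nu, which makes the spectral
#' response sum_nu omega_nu Y Y^T / (omega^2 + omega_nu^2) equal to the
#' resolvent (A+ + omega^2 (A-)^(-1))^(-1). Roots with nonpositive
#' lambda are spurious and discarded (counted). If A- is indefinite (possible
#' for excited-state references), the nonsymmetric product A- A+ is used and
#' each root carries a sign: negative-signed roots are the negative
#' transitions excluded from the Casimir-Polder sum.
#'
#' @param h an `erpa_hessians`
#' @param pos_tol positivity threshold for retained roots
#' @return object of class `erpa_solution`: `omegas`, `Y` (pair dim x roots),
#'   `signs`, `n_discarded_negative`, `normalization`
#' @export
solve_erpa <- function(h, pos_tol = 1e-10) {
  Am <- h$A_minus; Ap <- h$A_plus
  n <- nrow(Am)
  evm <- eigen(Am, symmetric = TRUE)
  if (min(evm$values) > -pos_tol) {
    # stable (positive-semidefinite A-) path
    lam <- pmax(evm$values, 0)
    S <- evm$vectors %*% (sqrt(lam) * t(evm$vectors))
    W <- S %*% Ap %*% S
    ev <- eigen((W + t(W)) / 2, symmetric = TRUE)
    keep <- ev$values > pos_tol
    omega <- sqrt(ev$values[keep])
    ord <- order(omega)
    omega <- omega[ord]
    U <- ev$vectors[, keep, drop = FALSE][, ord, drop = FALSE]
    Y <- S %*% sweep(U, 2, sqrt(omega), "/")
    sol <- list(omegas = omega, Y = Y, signs = rep(1, length(omega)),
                n_discarded_negative = sum(!keep))
  } else {
    M <- Am %*% Ap
    ev <- eigen(M)
    lam <- ev$values
    keep <- abs(Im(lam)) < 1e-8 & Re(lam) > pos_tol
    omega <- sqrt(Re(lam[keep]))
    F <- Re(ev$vectors[, keep, drop = FALSE])
    # normalize f^T A+ f = sign * omega
    signs <- numeric(length(omega)); Y <- matrix(0, n, length(omega))
    for (k in seq_along(omega)) {
      f <- F[, k]
      val <- as.numeric(t(f) %*% Ap %*% f)
      signs[k] <- sign(val)
      Y[, k] <- f / sqrt(abs(val) / omega[k])
    }
    ord <- order(omega)
    sol <- list(omegas = omega[ord], Y = Y[, ord, drop = FALSE],
                signs = signs[ord],
                n_discarded_negative = sum(!keep) + sum(signs < 0))
  }
  sol$normalization <- h$normalization
  structure(sol, class = "erpa_solution")
}

#' Frequency-dependent density response by direct linear solve
#'
#' C(omega) = (A- A+ + omega^2 I)^(-1) A-, the real part of the pair-space
#' linear response at imaginary frequency; equals the spectral assembly from
#' [solve_erpa()] including any negative-signed roots.
#'
#' @param h an `erpa_hessians`
#' @param omega imaginary-frequency value (hartree), `omega >= 0`
#' @return symmetric pair-index response matrix
#' @export
response_direct <- function(h, omega) {
  stopifnot(omega >= 0)
  n <- nrow(h$A_plus)
  M <- h$A_minus %*% h$A_plus + diag(omega^2, n)
  kappa <- rcond(M)
  if (!is.finite(kappa) || kappa < 1e-14)
    stop(sprintf("response_direct: near-singular response system (rcond %.2e)", kappa))
  C <- solve(M, h$A_minus)
  (C + t(C)) / 2
}

#' Sum-over-states second-order dispersion energy (sixth-power oracle)
#'
#' E_disp = -4 sum_{nu mu} (Y_nu^A g Y_mu^B)^2 / (omega_nu + omega_mu) over
#' the retained (positive) ERPA roots of both monomers; `g_cross` couples
#' A-pairs to B-pairs through the occupation-scaled two-electron integrals.
#'
#' @param sol_a,sol_b `erpa_solution` objects for monomers A and B
#' @param g_cross matrix (A-pair dim x B-pair dim)
#' @return dispersion energy in hartree (negative for ground states)
#' @export
dispersion_sum_over_states <- function(sol_a, sol_b, g_cross) {
  if (length(sol_a$omegas) == 0 || length(sol_b$omegas) == 0)
    stop("dispersion_sum_over_states: empty excitation spectrum")
  ka <- sol_a$signs > 0; kb <- sol_b$signs > 0
  Ta <- t(sol_a$Y[, ka, drop = FALSE]) %*% g_cross %*% sol_b$Y[, kb, drop = FALSE]
  denom <- outer(sol_a$omegas[ka], sol_b$omegas[kb], "+")
  -4 * sum(Ta^2 / denom)
}
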