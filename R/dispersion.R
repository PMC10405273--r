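#' Second-order dispersion energy from projected responses on a grid
#'
#' Accumulates `E = -(8/pi) sum_j w_j Tr[W^A(w_j) W^B(w_j)]` with the
#' reduced-dimension kernels `W^X = D^X^T C~^X(w_j)` (N_chol x N_chol). When
#' the projected responses carry per-order increments, the energy is also
#' resolved by truncation order (both monomers truncated consistently).
#'
#' @param pra,prb lists of `projected_response` objects, one per grid node
#' @param Da,Db occupation-scaled Cholesky factors of the monomers
#' @param grid the `frequency_grid` the responses were evaluated on
#' @return list with `energy` (hartree) and `per_order` (energies at
#'   truncation orders 0..n)
#' @export
dispersion_energy <- function(pra, prb, Da, Db, grid) {
  if (length(pra) != grid$n_points || length(prb) != grid$n_points)
    stop("dispersion_energy: responses and grid have different node counts")
  nord <- min(length(pra[[1]]$orders), length(prb[[1]]$orders))
  per_order <- numeric(nord)
  energy <- 0
  for (j in seq_len(grid$n_points)) {
    Wa_cum <- matrix(0, ncol(Da), ncol(Da))
    Wb_cum <- matrix(0, ncol(Db), ncol(Db))
    # cumulative kernels by order (a monomer whose series terminated early
    # contributes its full response at every higher order)
    Wa_k <- lapply(pra[[j]]$orders, function(Ck) crossprod(Da, Ck))
    Wb_k <- lapply(prb[[j]]$orders, function(Ck) crossprod(Db, Ck))
    for (k in seq_len(nord)) {
      if (k <= length(Wa_k)) Wa_cum <- Wa_cum + Wa_k[[k]]
      if (k <= length(Wb_k)) Wb_cum <- Wb_cum + Wb_k[[k]]
      per_order[k] <- per_order[k] -
        (8 / pi) * grid$weights[j] * sum(Wa_cum * t(Wb_cum))
    }
    Wa_full <- crossprod(Da, pra[[j]]$total)
    Wb_full <- crossprod(Db, prb[[j]]$total)
    energy <- energy - (8 / pi) * grid$weights[j] * sum(Wa_full * t(Wb_full))
  }
  list(energy = energy, per_order = per_order)
}

# dimer-centered integrals for both monomers with one shared ERI evaluation
.dimer_pair_integrals <- function(geom_a, geom_b, basis_label) {
  els <- c(geom_a$elements, geom_b$elements)
  xyz <- rbind(geom_a$coords, geom_b$coords)
  na <- length(geom_a$elements)
  nb <- length(geom_b$elements)
  ga <- geometry(els, xyz, c(rep(FALSE, na), rep(TRUE, nb)))
  gb <- geometry(els, xyz, c(rep(TRUE, na), rep(FALSE, nb)))
  ints_a <- ao_integrals(ga, basis_label)
  bs <- ints_a$basis
  one_b <- cpp_one_electron(xyz * BOHR_PER_ANGSTROM,
                            ifelse(gb$ghost, 0, .element_charges[gb$elements]),
                            as.integer(bs$atom), as.integer(bs$l),
                            as.integer(bs$nprim), bs$exps, bs$coefs)
  ints_b <- ints_a
  ints_b$V <- one_b$V
  ints_b$hcore <- ints_a$T + one_b$V
  ints_b$enuc <- nuclear_repulsion(gb)
  ints_b$geom <- gb
  list(a = ints_a, b = ints_b, geom_a = ga, geom_b = gb)
}

#' Prepare both monomers of a dimer for response calculations
#'
#' Runs the dimer-centered electronic-structure preparation once: shared AO
#' integrals, RHF + (state-averaged) CASSCF + CASCI per monomer, natural
#' orbitals and RDMs, pair indices, and the alpha-split ERPA Hessians. The
#' returned system is the common input of the dispersion, induction and
#' density routines.
#'
#' @inheritParams dispersion_calculation
#' @param optimize_orbitals orbital-optimize the active space (default TRUE)
#' @return object of class `dimer_system`
#' @export
prepare_interaction <- function(geom_a, geom_b, basis_label,
                                active_a = active_space(0, 0),
                                active_b = active_space(0, 0),
                                optimize_orbitals = TRUE) {
  ints <- .dimer_pair_integrals(geom_a, geom_b, basis_label)
  st_a <- prepare_monomer_state(ints$geom_a, basis_label, active_a, "A", ints$a,
                                optimize_orbitals = optimize_orbitals)
  st_b <- prepare_monomer_state(ints$geom_b, basis_label, active_b, "B", ints$b,
                                optimize_orbitals = optimize_orbitals)
  nos_a <- no_integrals(st_a, ints$a)
  nos_b <- no_integrals(st_b, ints$b)
  pr_a <- build_pair_index(st_a$partition, st_a$occupations)
  pr_b <- build_pair_index(st_b$partition, st_b$occupations)
  h_a <- split_alpha(build_hessians(st_a, nos_a, pr_a))
  h_b <- split_alpha(build_hessians(st_b, nos_b, pr_b))
  structure(list(ints = ints,
                 states = list(A = st_a, B = st_b),
                 nos = list(A = nos_a, B = nos_b),
                 pairs = list(A = pr_a, B = pr_b),
                 hessians = list(A = h_a, B = h_b),
                 geom_a = geom_a, geom_b = geom_b,
                 basis_label = basis_label,
                 actives = list(A = active_a, B = active_b)),
            class = "dimer_system")
}

#' @export
print.dimer_system <- function(x, ...) {
  cat(sprintf("<dimer_system: %s | A: %d e-, CAS(%d,%d), %s | B: %d e-, CAS(%d,%d), %s | %d AOs>\n",
              x$basis_label,
              x$states$A$n_electrons, x$actives$A$n_electrons,
              x$actives$A$n_orbitals, x$states$A$electronic_state,
              x$states$B$n_electrons, x$actives$B$n_electrons,
              x$actives$B$n_orbitals, x$states$B$electronic_state,
              x$ints$a$nao))
  invisible(x)
}

#' Full coupled dispersion calculation for a dimer
#'
#' End-to-end fifth-power-scaling pipeline: dimer-centered monomer states
#' (RHF + determinant CASCI), ERPA Hessians split at the group-product-
#' function zeroth order, one pivoted Cholesky decomposition of the AO
#' Coulomb matrix serving both monomers, and the recursive coupling-constant
#' expansion of the projected response on an imaginary-frequency grid.
#'
#' @param geom_a,geom_b monomer geometries (no ghosts; the dimer-centered
#'   basis is constructed internally)
#' @param basis_label basis-set label
#' @param active_a,active_b [active_space()] specs
#' @param threshold Cholesky residual-sum threshold (production default 1e-2)
#' @param grid a `frequency_grid` (default 8-point optimized rule)
#' @param order truncation order of the coupling-constant expansion
#' @param direct also evaluate the reference coupled response by direct
#'   linear solves at every node
#' @param keep keep heavy intermediates (states, Hessians, factors, per-node
#'   responses) in the result, needed by the dispersion-density map
#' @param system optional prepared [prepare_interaction()] system; when given
#'   the geometry/basis/active arguments are ignored
#' @return object of class `dispersion_result`
#' @export
dispersion_calculation <- function(geom_a, geom_b, basis_label,
                                   active_a = active_space(0, 0),
                                   active_b = active_space(0, 0),
                                   threshold = 1e-2,
                                   grid = make_frequency_grid(),
                                   order = 8L,
                                   direct = FALSE,
                                   keep = TRUE,
                                   system = NULL) {
  if (is.null(system))
    system <- prepare_interaction(geom_a, geom_b, basis_label, active_a, active_b)
  ints <- system$ints
  st_a <- system$states$A; st_b <- system$states$B
  pr_a <- system$pairs$A; pr_b <- system$pairs$B
  h_a <- system$hessians$A; h_b <- system$hessians$B
  chol <- pivoted_cholesky(coulomb_accessor_dense(ints$a$eri), threshold)
  Da <- transform_and_scale(chol, st_a, pr_a)
  Db <- transform_and_scale(chol, st_b, pr_b)
  pra <- lapply(grid$nodes, function(w) recursive_projected_response(h_a, Da, w, order))
  prb <- lapply(grid$nodes, function(w) recursive_projected_response(h_b, Db, w, order))
  de <- dispersion_energy(pra, prb, Da, Db, grid)
  e_direct <- NA_real_
  if (direct) {
    e_direct <- 0
    for (j in seq_len(grid$n_points)) {
      Wa <- crossprod(Da, project_response(response_direct(h_a, grid$nodes[j]), Da))
      Wb <- crossprod(Db, project_response(response_direct(h_b, grid$nodes[j]), Db))
      e_direct <- e_direct - (8 / pi) * grid$weights[j] * sum(Wa * t(Wb))
    }
  }
  res <- list(e_coupled = de$energy,
              e_uncoupled = de$per_order[1],
              per_order = de$per_order,
              e_direct = e_direct,
              n_chol = chol$n_chol,
              grid = grid[c("n_points", "omega0", "type")],
              order = order,
              diverging = any(vapply(c(pra, prb), `[[`, TRUE, "diverging")),
              basis_label = system$basis_label)
  if (keep) {
    res$states <- list(A = st_a, B = st_b)
    res$pairs <- list(A = pr_a, B = pr_b)
    res$hessians <- list(A = h_a, B = h_b)
    res$D <- list(A = Da, B = Db)
    res$responses <- list(A = pra, B = prb)
    res$cholesky <- chol
    res$ints <- ints
    res$full_grid <- grid
  }
  structure(res, class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("<dispersion_result: E_disp = %.8f Eh (%.4f kcal/mol), order %d, N_chol = %d>\n",
              x$e_coupled, x$e_coupled * HARTREE_TO_KCAL, x$order, x$n_chol))
  cat(sprintf("  uncoupled: %.8f Eh; grid: %d-point %s\n",
              x$e_uncoupled, x$grid$n_points, x$grid$type))
  invisible(x)
}

#' Sixth-power sum-over-states dispersion for a dimer (reference path)
#'
#' Runs the same monomer preparation as [dispersion_calculation()] but
#' evaluates the dispersion energy from the full ERPA spectra and the dense
#' occupation-scaled coupling integrals -- the quadrature-free reference the
#' reduced-scaling pipeline must reproduce.
#'
#' @inheritParams dispersion_calculation
#' @return list with `energy` (hartree) and the per-monomer root filters
#' @export
dispersion_sos_reference <- function(geom_a, geom_b, basis_label,
                                     active_a = active_space(0, 0),
                                     active_b = active_space(0, 0),
                                     system = NULL) {
  if (is.null(system))
    system <- prepare_interaction(geom_a, geom_b, basis_label, active_a, active_b)
  st_a <- system$states$A; st_b <- system$states$B
  pr_a <- system$pairs$A; pr_b <- system$pairs$B
  sol_a <- solve_erpa(system$hessians$A)
  sol_b <- solve_erpa(system$hessians$B)
  g <- g_cross_dense(st_a, st_b, system$ints$a$eri, pr_a, pr_b)
  list(energy = dispersion_sum_over_states(sol_a, sol_b, g),
       n_discarded = c(A = sol_a$n_discarded_negative,
                       B = sol_b$n_discarded_negative),
       omegas = list(A = sol_a$omegas, B = sol_b$omegas))
}

#' Convergence scan of the coupling-constant expansion
#'
#' Evaluates the dispersion energy at every truncation order up to `n_max`
#' against the direct (fully coupled) reference on the same grid, reporting
#' signed errors and the first order reaching microhartree agreement.
#'
#' @inheritParams dispersion_calculation
#' @param n_max largest truncation order
#' @param tol_uEh convergence target in hartree (default 1e-6)
#' @return list with `per_order`, `e_direct`, `errors`, `order_converged`,
#'   `percent_errors`
#' @export
convergence_scan <- function(geom_a, geom_b, basis_label,
                             active_a = active_space(0, 0),
                             active_b = active_space(0, 0),
                             threshold = 1e-8,
                             grid = make_frequency_grid(),
                             n_max = 10L, tol_uEh = 1e-6, system = NULL) {
  calc <- dispersion_calculation(geom_a, geom_b, basis_label, active_a, active_b,
                                 threshold = threshold, grid = grid,
                                 order = n_max, direct = TRUE, keep = FALSE,
                                 system = system)
  errs <- calc$per_order - calc$e_direct
  conv <- which(abs(errs) < tol_uEh)
  list(per_order = calc$per_order,
       e_direct = calc$e_direct,
       errors = errs,
       percent_errors = 100 * abs(errs) / abs(calc$e_direct),
       order_converged = if (length(conv)) conv[1] - 1L else NA_integer_,
       diverging = calc$diverging)
}

#' Static-response second-order induction energy
#'
#' Low-level contraction: `E = -2 v^T C(0) v` for one direction, with `v` the
#' occupation-scaled electrostatic-potential vector of the partner over the
#' monomer's pair index and `C(0)` the static pair-space response.
#'
#' @param v potential vector over the monomer's pairs
#' @param C0 static response matrix from [response_direct()] at `omega = 0`
#' @return induction energy for this direction (hartree)
#' @export
induction_static <- function(v, C0) {
  ev <- eigen(C0, symmetric = TRUE, only.values = TRUE)$values
  if (min(abs(ev)) < 1e-12)
    stop(sprintf("induction_static: near-singular static response (min |eig| %.2e)",
                 min(abs(ev))))
  -2 * as.numeric(t(v) %*% C0 %*% v)
}

#' Second-order induction energy of a dimer from static monomer responses
#'
#' Contracts each monomer's static coupled response with the electrostatic
#' potential (nuclei plus frozen electron density) of its partner and sums
#' both directions: the fourth-power route to E_ind^(2).
#'
#' @inheritParams dispersion_calculation
#' @return list with `e_ind` (total, hartree), `a_from_b`, `b_from_a`
#' @export
induction_energy <- function(geom_a, geom_b, basis_label,
                             active_a = active_space(0, 0),
                             active_b = active_space(0, 0),
                             system = NULL) {
  if (is.null(system))
    system <- prepare_interaction(geom_a, geom_b, basis_label, active_a, active_b)
  ints <- system$ints
  st_a <- system$states$A; st_b <- system$states$B
  v_ao <- function(src_ints, src_state) {
    # nuclear attraction of the partner's nuclei + Coulomb of its density
    m <- src_ints$nao
    D_ao <- src_state$no_coefficients %*%
      (2 * src_state$occupations * t(src_state$no_coefficients))
    J <- matrix(matrix(src_ints$eri, m^2, m^2) %*% as.vector(D_ao), m, m)
    src_ints$V + J
  }
  pot_vec <- function(state, pairs, vmat_ao) {
    vno <- t(state$no_coefficients) %*% vmat_ao %*% state$no_coefficients
    fac <- sqrt(state$occupations)
    (fac[pairs$pairs$p] + fac[pairs$pairs$q]) * vno[cbind(pairs$pairs$p, pairs$pairs$q)]
  }
  pr_a <- system$pairs$A
  pr_b <- system$pairs$B
  h_a <- system$hessians$A
  h_b <- system$hessians$B
  v_on_a <- pot_vec(st_a, pr_a, v_ao(ints$b, st_b))
  v_on_b <- pot_vec(st_b, pr_b, v_ao(ints$a, st_a))
  e_ab <- induction_static(v_on_a, response_direct(h_a, 0))
  e_ba <- induction_static(v_on_b, response_direct(h_b, 0))
  list(e_ind = e_ab + e_ba, a_from_b = e_ab, b_from_a = e_ba,
       states = list(A = st_a, B = st_b),
       hessians = list(A = h_a, B = h_b),
       pairs = list(A = pr_a, B = pr_b),
       potentials = list(A = v_on_a, B = v_on_b))
}
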