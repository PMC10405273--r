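#' Monomer electronic state in its natural-orbital representation
#'
#' Runs RHF and (for a non-empty active space) a determinant CASCI in the
#' given basis, then transforms to state-specific natural orbitals. The
#' returned object carries everything the response machinery needs: NO
#' coefficients, occupation numbers in \[0, 1\] (2 sum(n) = N), the
#' inactive/active/virtual partition, and the spin-free one- and two-electron
#' reduced density matrices over the generalized-occupied orbitals.
#'
#' Ghost centers in `geom` put the monomer in a dimer-centered basis. With
#' `active$n_orbitals == 0` the state is the single-determinant (mean-field)
#' reference with occupations exactly 0/1.
#'
#' @param geom a [geometry()] (may contain ghost centers)
#' @param basis_label basis-set label
#' @param active an [active_space()]; use `active_space(0, 0)` for mean field
#' @param label monomer tag, conventionally `"A"` or `"B"`
#' @param ints optional precomputed [ao_integrals()] for `geom`
#' @return an object of class `monomer_state`
#' @export
prepare_monomer_state <- function(geom, basis_label, active = active_space(0, 0),
                                  label = "A", ints = NULL,
                                  optimize_orbitals = TRUE) {
  if (is.null(ints)) ints <- ao_integrals(geom, basis_label)
  m <- ints$nao
  nelec <- n_electrons(geom)
  scf <- rhf(ints, nelec)
  mos <- scf
  if (active$n_orbitals > 0L)
    mos$C <- select_active_orbitals(ints, scf, nelec, active, geom)
  attr(mos, "nelec") <- nelec
  if (active$n_orbitals > 0L && optimize_orbitals) {
    opt <- casscf_optimize(ints, mos$C, nelec, active)
    mos$C <- opt$C
  }

  if (active$n_orbitals == 0L) {
    nocc <- nelec / 2
    occ <- c(rep(1, nocc), rep(0, m - nocc))
    C_no <- scf$C
    part <- list(s1 = seq_len(nocc), s2 = integer(0),
                 s3 = if (nocc < m) (nocc + 1):m else integer(0))
    n_go <- nocc
    # closed-shell determinant two-matrix over the occupied orbitals
    wf <- wf_new(list(sort(c(so_index(seq_len(nocc), 1L), so_index(seq_len(nocc), 2L)))), 1)
    rd <- rdm2_from_wf(wf, nocc)
    d2_occ <- rd$d2
    state_energy <- scf$energy
    es_tag <- "GS"
    ci <- NULL
  } else {
    ci <- casci(ints, mos, active)
    n_inact <- ci$n_inact
    n_go <- n_inact + active$n_orbitals
    # embed the target CI vector with the inactive core made explicit
    core_so <- if (n_inact > 0)
      sort(c(so_index(seq_len(n_inact), 1L), so_index(seq_len(n_inact), 2L)))
    else integer(0)
    dets_full <- lapply(ci$dets, function(d) {
      sp <- so_spatial(d) + n_inact
      sort(c(core_so, so_index(sp, so_spin(d))))
    })
    keep <- abs(ci$civec) > 1e-14
    wf <- wf_new(dets_full[keep], ci$civec[keep])
    rd <- rdm2_from_wf(wf, n_go)
    # natural orbitals of the target state: rotate the active block only
    gamma_act <- rd$d1[n_inact + seq_len(active$n_orbitals),
                       n_inact + seq_len(active$n_orbitals), drop = FALSE]
    evg <- eigen((gamma_act + t(gamma_act)) / 2, symmetric = TRUE)
    U <- evg$vectors   # descending eigenvalues
    for (k in seq_len(ncol(U))) {
      j <- which.max(abs(U[, k]))
      if (U[j, k] < 0) U[, k] <- -U[, k]
    }
    occ_act <- pmin(pmax(evg$values / 2, 0), 1)
    W <- diag(n_go)
    W[n_inact + seq_len(active$n_orbitals), n_inact + seq_len(active$n_orbitals)] <- U
    # contravariant 4-index rotation of the two-matrix
    d2_occ <- rd$d2
    for (k in 1:4) {
      d2_occ <- array(crossprod(W, matrix(d2_occ, n_go, n_go^3)), rep(n_go, 4))
      d2_occ <- aperm(d2_occ, c(2, 3, 4, 1))
    }
    C_no <- mos$C
    C_no[, ci$act] <- C_no[, ci$act, drop = FALSE] %*% U
    occ <- c(rep(1, n_inact), occ_act, rep(0, m - n_go))
    part <- list(s1 = seq_len(n_inact),
                 s2 = n_inact + seq_len(active$n_orbitals),
                 s3 = if (n_go < m) (n_go + 1):m else integer(0))
    state_energy <- ci$energies[active$target_state]
    es_tag <- if (active$target_state > 1L) "ES" else "GS"
  }

  if (abs(2 * sum(occ) - nelec) > 1e-10)
    stop("prepare_monomer_state: occupation sum rule violated")

  st <- structure(list(
    label = label,
    no_coefficients = C_no,
    occupations = occ,
    partition = part,
    rdm1 = diag(2 * occ, m),
    rdm2_occ = d2_occ,       # gen-occ spin-free two-matrix, NO basis
    n_electrons = nelec,
    electronic_state = es_tag,
    energy = state_energy,
    scf_energy = scf$energy,
    active = active,
    basis_label = basis_label,
    geom = geom,
    nao = m), class = "monomer_state")
  st
}

#' @export
print.monomer_state <- function(x, ...) {
  cat(sprintf("<monomer_state %s: %d electrons, %d AOs, %s, CAS(%d,%d)>\n",
              x$label, x$n_electrons, x$nao, x$electronic_state,
              x$active$n_electrons, x$active$n_orbitals))
  cat("  occupations:", paste(sprintf("%.4f", x$occupations), collapse = " "), "\n")
  invisible(x)
}

#' Starting-orbital selection for an active-space calculation
#'
#' Reorders the canonical RHF orbitals so the active window sits around the
#' Fermi level. In a dimer-centered (ghost-augmented) basis the lowest
#' canonical virtuals can be ghost-localized; active virtuals are therefore
#' taken, in energy order, from those with a dominant Mulliken population on
#' the real atoms (falling back to the largest populations available).
#'
#' @param ints [ao_integrals()] of the geometry
#' @param scf an [rhf()] result
#' @param nelec electron count
#' @param active an [active_space()]
#' @param geom the [geometry()] (for ghost flags)
#' @return reordered MO coefficient matrix
#' @export
select_active_orbitals <- function(ints, scf, nelec, active, geom) {
  m <- ints$nao
  nocc <- nelec / 2
  n_occ_act <- active$n_electrons / 2
  n_virt_act <- active$n_orbitals - n_occ_act
  if (n_occ_act > nocc || n_virt_act < 0)
    stop("select_active_orbitals: active space inconsistent with electron count")
  C <- scf$C
  if (n_virt_act > 0) {
    ao_atom <- rep(ints$basis$atom,
                   times = (ints$basis$l + 1) * (ints$basis$l + 2) / 2)
    real_ao <- ao_atom %in% which(!geom$ghost)
    SC <- ints$S %*% C
    qreal <- colSums(C[real_ao, , drop = FALSE] * SC[real_ao, , drop = FALSE])
    virts <- if (nocc < m) (nocc + 1):m else integer(0)
    good <- virts[qreal[virts] >= 0.4]
    rest <- setdiff(virts, good)
    ranked <- c(good, rest[order(-qreal[rest])])
    sel <- sort(ranked[seq_len(n_virt_act)])
    perm <- c(seq_len(nocc), sel, setdiff(virts, sel))
    C <- C[, perm, drop = FALSE]
  }
  C
}

#' One- and two-electron integrals in the natural-orbital basis of a state
#' @param state a `monomer_state`
#' @param ints the [ao_integrals()] of the same geometry/basis
#' @return list with `h_no` and `eri_no` (chemist convention)
#' @export
no_integrals <- function(state, ints) {
  C <- state$no_coefficients
  list(h_no = t(C) %*% ints$hcore %*% C,
       eri_no = transform_eri(ints$eri, C))
}

#' Counterpoise-corrected supermolecular interaction energy
#'
#' E_int = E(dimer) - E(A in dimer basis) - E(B in dimer basis), all three
#' calculations in the same dimer-centered basis (Boys-Bernardi counterpoise).
#'
#' @param mon_a,mon_b monomer [geometry()] objects
#' @param basis_label basis-set label
#' @param method `"hf"` or `"casci"`
#' @param active_dimer,active_a,active_b [active_space()] specs for the CASCI
#'   path (ignored for HF)
#' @return list with `e_int` (hartree) and the three total energies
#' @export
supermolecular_energy <- function(mon_a, mon_b, basis_label,
                                  method = c("hf", "casci"),
                                  active_dimer = NULL, active_a = NULL,
                                  active_b = NULL) {
  method <- match.arg(method)
  if (any(mon_a$ghost) || any(mon_b$ghost))
    stop("supermolecular_energy: fragment geometries must not contain ghosts")
  run <- function(geom, active) {
    ints <- ao_integrals(geom, basis_label)
    scf <- rhf(ints, n_electrons(geom))
    if (method == "hf" || is.null(active) || active$n_orbitals == 0)
      return(scf$energy)
    mos <- scf; attr(mos, "nelec") <- n_electrons(geom)
    ci <- casci(ints, mos, active)
    ci$energies[active$target_state]
  }
  e_ab <- run(dimer_geometry(mon_a, mon_b), active_dimer)
  e_a <- run(ghosted_geometry(mon_a, mon_b), active_a)
  e_b <- run(ghosted_geometry(mon_b, mon_a), active_b)
  list(e_int = e_ab - e_a - e_b, e_dimer = e_ab, e_a = e_a, e_b = e_b)
}
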