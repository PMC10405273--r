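# Determinant algebra over spin orbitals, used for CASCI wave functions,
# reduced density matrices and the brute-force test oracles. Determinants are
# sorted integer vectors of occupied spin orbitals; spin orbital 2*(s-1)+sigma
# belongs to spatial orbital s with sigma = 1 (alpha) or 2 (beta).

so_index <- function(spatial, spin) 2L * (spatial - 1L) + spin
so_spatial <- function(so) (so + 1L) %/% 2L
so_spin <- function(so) ((so - 1L) %% 2L) + 1L

det_key <- function(det) paste(det, collapse = ",")

# a_so |det>: returns list(det, phase) or NULL
ann_so <- function(det, so) {
  pos <- match(so, det)
  if (is.na(pos)) return(NULL)
  list(det = det[-pos], phase = if (pos %% 2 == 1) 1 else -1)
}

# a^+_so |det>
cre_so <- function(det, so) {
  if (so %in% det) return(NULL)
  nbefore <- sum(det < so)
  newdet <- sort(c(det, so))
  list(det = newdet, phase = if (nbefore %% 2 == 0) 1 else -1)
}

# wavefunction: list(dets = list of sorted int vectors, coef = numeric)
wf_new <- function(dets, coef) list(dets = dets, coef = coef)

wf_canonical <- function(wf) {
  if (length(wf$coef) == 0) return(wf)
  keys <- vapply(wf$dets, det_key, "")
  agg <- tapply(wf$coef, keys, sum)
  keep <- abs(agg) > 1e-14
  agg <- agg[keep]
  first <- wf$dets[!duplicated(keys)]
  names(first) <- keys[!duplicated(keys)]
  wf_new(unname(first[names(agg)]), as.numeric(agg))
}

wf_dot <- function(a, b) {
  ka <- vapply(a$dets, det_key, "")
  kb <- vapply(b$dets, det_key, "")
  i <- match(ka, kb)
  sum(a$coef[!is.na(i)] * b$coef[i[!is.na(i)]])
}

# spin-summed singlet excitation E_ab = sum_sigma a^+_{a sigma} a_{b sigma}
apply_E <- function(wf, a, b) {
  dets <- list(); coef <- numeric(0)
  for (i in seq_along(wf$coef)) {
    for (sp in 1:2) {
      r1 <- ann_so(wf$dets[[i]], so_index(b, sp))
      if (is.null(r1)) next
      r2 <- cre_so(r1$det, so_index(a, sp))
      if (is.null(r2)) next
      dets[[length(dets) + 1]] <- r2$det
      coef <- c(coef, wf$coef[i] * r1$phase * r2$phase)
    }
  }
  wf_canonical(wf_new(dets, coef))
}

# ---- Slater-Condon Hamiltonian over a determinant basis -------------------
# h: spatial one-electron matrix; eri: spatial chemist (pq|rs) array
# spin-orbital <pq|rs> = (p r | q s) * delta(spin p, r) * delta(spin q, s)

.so_coulomb <- function(eri, p, q, r, s) {
  v <- 0
  if (so_spin(p) == so_spin(r) && so_spin(q) == so_spin(s))
    v <- eri[so_spatial(p), so_spatial(r), so_spatial(q), so_spatial(s)]
  v
}

# phase of aligning det with orbital o annihilated
.ann_phase <- function(det, o) {
  pos <- match(o, det)
  if (pos %% 2 == 1) 1 else -1
}

slater_condon_H <- function(dets, h, eri) {
  nd <- length(dets)
  H <- matrix(0, nd, nd)
  for (I in seq_len(nd)) {
    di <- dets[[I]]
    for (J in I:nd) {
      dj <- dets[[J]]
      only_i <- setdiff(di, dj)
      only_j <- setdiff(dj, di)
      nex <- length(only_i)
      val <- 0
      if (nex == 0) {
        for (p in di) val <- val + h[so_spatial(p), so_spatial(p)]
        np <- length(di)
        if (np > 1)
          for (a in 1:(np - 1)) for (b in (a + 1):np) {
            p <- di[a]; q <- di[b]
            val <- val + .so_coulomb(eri, p, q, p, q) - .so_coulomb(eri, p, q, q, p)
          }
      } else if (nex == 1) {
        m <- only_i; p <- only_j
        g <- .ann_phase(di, m) * .ann_phase(dj, p)
        if (so_spin(m) == so_spin(p)) {
          v <- h[so_spatial(m), so_spatial(p)]
          for (n in intersect(di, dj))
            v <- v + .so_coulomb(eri, m, n, p, n) - .so_coulomb(eri, m, n, n, p)
          val <- g * v
        }
      } else if (nex == 2) {
        m <- only_i[1]; n <- only_i[2]
        p <- only_j[1]; q <- only_j[2]
        r1 <- ann_so(di, m); r2 <- ann_so(r1$det, n)
        s1 <- ann_so(dj, p); s2 <- ann_so(s1$det, q)
        g <- r1$phase * r2$phase * s1$phase * s2$phase
        val <- g * (.so_coulomb(eri, m, n, p, q) - .so_coulomb(eri, m, n, q, p))
      }
      H[I, J] <- H[J, I] <- val
    }
  }
  H
}

# all determinants with na alpha and nb beta electrons in norb spatial orbitals
enumerate_dets <- function(norb, na, nb) {
  combs_a <- if (na == 0) list(integer(0)) else
    asplit(utils::combn(seq_len(norb), na), 2)
  combs_b <- if (nb == 0) list(integer(0)) else
    asplit(utils::combn(seq_len(norb), nb), 2)
  dets <- list()
  for (ca in combs_a) for (cb in combs_b)
    dets[[length(dets) + 1]] <- sort(c(so_index(as.integer(ca), 1L),
                                       so_index(as.integer(cb), 2L)))
  dets
}

# ---- CASCI ----------------------------------------------------------------

#' Active-space specification
#'
#' @param n_electrons,n_orbitals active electrons and orbitals
#' @param n_states number of CI roots to resolve
#' @param target_state 1-based index of the state of interest
#' @param weights state-averaging weights (default equal)
#' @export
active_space <- function(n_electrons, n_orbitals, n_states = 1L,
                         target_state = 1L, weights = NULL) {
  if (n_electrons < 0 || n_electrons > 2 * n_orbitals)
    stop("active_space: need 0 <= n_electrons <= 2 * n_orbitals")
  if (target_state > n_states) stop("active_space: target_state exceeds n_states")
  if (is.null(weights)) weights <- rep(1 / n_states, n_states)
  if (length(weights) != n_states || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-10)
    stop("active_space: weights must be nonnegative and sum to 1")
  structure(list(n_electrons = as.integer(n_electrons),
                 n_orbitals = as.integer(n_orbitals),
                 n_states = as.integer(n_states),
                 target_state = as.integer(target_state),
                 weights = weights),
            class = "active_space")
}

# CASCI in a fixed molecular-orbital basis. Returns state energies, the CI
# vector of the target state and index bookkeeping.
casci <- function(ints, mos, active) {
  m <- ints$nao
  nelec_tot <- attr(mos, "nelec")
  n_inact <- (nelec_tot - active$n_electrons) / 2
  if (n_inact < 0 || n_inact != round(n_inact))
    stop("casci: inconsistent electron count for the active space")
  n_inact <- as.integer(n_inact)
  if (n_inact + active$n_orbitals > m)
    stop("casci: active space does not fit in the orbital space")
  act <- n_inact + seq_len(active$n_orbitals)
  C <- mos$C
  hmo <- t(C) %*% ints$hcore %*% C
  # core energy and effective one-electron integrals need only a few blocks
  Cact <- C[, act, drop = FALSE]
  Cin <- C[, seq_len(n_inact), drop = FALSE]
  e_core <- ints$enuc
  heff <- hmo[act, act, drop = FALSE]
  if (n_inact > 0) {
    Din <- 2 * tcrossprod(Cin)
    Jm <- matrix(matrix(ints$eri, m^2, m^2) %*% as.vector(Din), m, m)
    Km <- matrix(matrix(aperm(ints$eri, c(1, 3, 2, 4)), m^2, m^2) %*% as.vector(Din), m, m)
    Fin <- ints$hcore + Jm - 0.5 * Km
    e_core <- e_core + 0.5 * sum(Din * (ints$hcore + Fin))
    heff <- t(Cact) %*% Fin %*% Cact
  }
  v_act <- transform_eri(ints$eri, Cact)
  if (active$n_electrons %% 2 != 0)
    stop("casci: only even active electron counts are supported")
  na <- active$n_electrons / 2
  dets <- enumerate_dets(active$n_orbitals, na, na)
  H <- slater_condon_H(dets, heff, v_act)
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(ev$values)              # ascending state energies
  nstates <- min(active$n_states, length(ev$values))
  energies <- e_core + ev$values[ord]
  civecs <- ev$vectors[, ord, drop = FALSE]
  # deterministic CI phase
  for (k in seq_len(ncol(civecs))) {
    j <- which.max(abs(civecs[, k]))
    if (civecs[j, k] < 0) civecs[, k] <- -civecs[, k]
  }
  list(energies = energies[seq_len(nstates)],
       all_energies = energies,
       civec = civecs[, active$target_state],
       civecs = civecs[, seq_len(nstates), drop = FALSE],
       dets = dets, act = act, n_inact = n_inact, e_core = e_core)
}

# spin-summed 1-RDM <E_pq> over a set of spatial orbitals, from a determinant
# expansion `wf` whose spin orbitals index into that set
rdm1_from_wf <- function(wf, norb) {
  g <- matrix(0, norb, norb)
  for (p in seq_len(norb)) for (q in seq_len(norb)) {
    g[p, q] <- wf_dot(wf, apply_E(wf, p, q))
  }
  (g + t(g)) / 2
}

# spin-free two-matrix d2[p,q,r,s] = <sum_{st} a+_{p s} a+_{q t} a_{s t} a_{r s}>
# (index pairing (p,r),(q,s)) over `norb` spatial orbitals
rdm2_from_wf <- function(wf, norb) {
  # cache E_ab |wf> for all a,b
  Ew <- vector("list", norb * norb)
  idx <- function(a, b) (a - 1L) * norb + b
  for (a in seq_len(norb)) for (b in seq_len(norb))
    Ew[[idx(a, b)]] <- apply_E(wf, a, b)
  d1 <- matrix(0, norb, norb)
  for (p in seq_len(norb)) for (q in seq_len(norb))
    d1[p, q] <- wf_dot(wf, Ew[[idx(p, q)]])
  d2 <- array(0, rep(norb, 4))
  for (p in seq_len(norb)) for (r in seq_len(norb)) {
    Erp <- Ew[[idx(r, p)]]
    for (q in seq_len(norb)) for (s in seq_len(norb)) {
      ee <- wf_dot(Erp, Ew[[idx(q, s)]])  # <E_pr E_qs>
      d2[p, q, r, s] <- ee - (if (q == r) d1[p, s] else 0)
    }
  }
  list(d1 = d1, d2 = d2)
}
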