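# Self-contained fixture dimers and seeded synthetic ERPA instances. The
# fixtures stand in for the large benchmark dimers of production studies:
# small enough that the sixth-power sum-over-states reference runs in
# seconds, yet covering mean-field, multiconfigurational ground-state and
# excited-state monomers.

#' Built-in fixture dimers
#'
#' Returns the descriptor list for the test-suite dimers: H2-H2 with
#' CAS(2,2) monomers, He-He at mean field, the water dimer with CAS(4,4) and
#' a mean-field variant, and an excited-state H2-H2 fixture whose A monomer
#' is the S1 state of a two-state-averaged CAS(2,2).
#'
#' @return named list of fixtures, each with `geom_a`, `geom_b`, `basis`,
#'   `active_a`, `active_b`, `tags`
#' @export
fixture_suite <- function() {
  h2 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.7414)))
  he <- geometry("He", matrix(0, 1, 3))
  w1 <- geometry(c("O", "H", "H"),
                 rbind(c(-1.551007, -0.114520, 0),
                       c(-1.934259, 0.762503, 0),
                       c(-0.599677, 0.040712, 0)))
  w2 <- geometry(c("O", "H", "H"),
                 rbind(c(1.350625, 0.111469, 0),
                       c(1.680398, -0.373741, -0.758561),
                       c(1.680398, -0.373741, 0.758561)))
  list(
    h2_h2 = list(geom_a = h2, geom_b = translate_geometry(h2, c(3.5, 0, 0)),
                 basis = "6-31g",
                 active_a = active_space(2, 2), active_b = active_space(2, 2),
                 tags = c(state = "GS", sign = "negative")),
    he_he = list(geom_a = he, geom_b = translate_geometry(he, c(3.0, 0, 0)),
                 basis = "dz.s",
                 active_a = active_space(0, 0), active_b = active_space(0, 0),
                 tags = c(state = "GS", sign = "negative")),
    h2o_h2o = list(geom_a = w1, geom_b = w2, basis = "sto-3g",
                   active_a = active_space(4, 4), active_b = active_space(4, 4),
                   tags = c(state = "GS", sign = "negative")),
    h2o_h2o_hf = list(geom_a = w1, geom_b = w2, basis = "sto-3g",
                      active_a = active_space(0, 0), active_b = active_space(0, 0),
                      tags = c(state = "GS", sign = "negative")),
    h2_h2_es = list(geom_a = h2, geom_b = translate_geometry(h2, c(4.0, 0, 0)),
                    basis = "6-31g",
                    active_a = active_space(2, 2, n_states = 2, target_state = 2),
                    active_b = active_space(2, 2),
                    tags = c(state = "ES", sign = "unconstrained"))
  )
}

#' Prepare a fixture dimer by name
#' @param name a name from [fixture_suite()]
#' @param optimize_orbitals passed to [prepare_interaction()]
#' @return a `dimer_system`
#' @export
prepare_fixture <- function(name, optimize_orbitals = TRUE) {
  fx <- fixture_suite()[[name]]
  if (is.null(fx)) stop("unknown fixture: ", name)
  prepare_interaction(fx$geom_a, fx$geom_b, fx$basis, fx$active_a, fx$active_b,
                      optimize_orbitals = optimize_orbitals)
}

#' Seeded synthetic ERPA instance
#'
#' Generates a reproducible pair-space problem with a declared block layout:
#' symmetric positive-definite zeroth-order Hessians `A0+/-` (block
#' diagonal), a coupling part `A1+/-` confined to the off-block complement
#' with Frobenius norm controlled by `coupling_strength` (0 gives an exactly
#' block-diagonal problem), and a synthetic projection panel `D`. Positive
#' definiteness of `A+/-(alpha)` over alpha in \[0, 1\] is enforced by
#' construction (diagonal dominance of the block part over the coupling).
#'
#' @param seed integer seed
#' @param pair_dim pair-space dimension
#' @param n_chol number of synthetic Cholesky columns
#' @param coupling_strength relative size of the off-block coupling
#' @param n_blocks number of diagonal blocks (default ~4)
#' @return an object usable by [split_alpha()]-consumers: class
#'   `erpa_hessians` with the split already attached
#' @export
generate_synthetic_instance <- function(seed, pair_dim, n_chol,
                                        coupling_strength = 0.1,
                                        n_blocks = min(4L, pair_dim)) {
  stopifnot(pair_dim >= 1, n_chol >= 1)
  set.seed(seed)
  sizes <- diff(round(seq(0, pair_dim, length.out = n_blocks + 1)))
  sizes <- sizes[sizes > 0]
  blocks <- split(seq_len(pair_dim), rep(seq_along(sizes), sizes))
  blocks <- unname(blocks)
  spd_block <- function(k) {
    Q <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
    Q %*% (stats::runif(k, 0.5, 2.5) * t(Q))
  }
  A0p <- matrix(0, pair_dim, pair_dim)
  A0m <- matrix(0, pair_dim, pair_dim)
  for (b in blocks) {
    A0p[b, b] <- spd_block(length(b))
    A0m[b, b] <- spd_block(length(b))
  }
  offmask <- matrix(TRUE, pair_dim, pair_dim)
  for (b in blocks) offmask[b, b] <- FALSE
  rand_sym <- function() {
    Mx <- matrix(stats::rnorm(pair_dim^2), pair_dim)
    Mx <- (Mx + t(Mx)) / 2
    Mx[!offmask] <- 0
    Mx
  }
  A1p <- rand_sym(); A1m <- rand_sym()
  if (coupling_strength == 0) {
    A1p[] <- 0; A1m[] <- 0
  } else {
    # keep A(alpha) comfortably positive definite across alpha in [0, 1]
    lim <- 0.45 * min(eigen(A0p, symmetric = TRUE, only.values = TRUE)$values,
                      eigen(A0m, symmetric = TRUE, only.values = TRUE)$values)
    sc <- coupling_strength * lim
    nrm_p <- max(abs(eigen(A1p, symmetric = TRUE, only.values = TRUE)$values), 1e-12)
    nrm_m <- max(abs(eigen(A1m, symmetric = TRUE, only.values = TRUE)$values), 1e-12)
    A1p <- A1p * sc / nrm_p
    A1m <- A1m * sc / nrm_m
  }
  D <- matrix(stats::rnorm(pair_dim * n_chol), pair_dim, n_chol)
  pairs <- structure(list(pairs = data.frame(p = seq_len(pair_dim) + 1L,
                                             q = rep(1L, pair_dim), group = 4L),
                          blocks = blocks, n = pair_dim, n_dropped = 0L),
                     class = "pair_index")
  structure(list(A_plus = A0p + A1p, A_minus = A0m + A1m,
                 A0_plus = A0p, A0_minus = A0m,
                 A1_plus = A1p, A1_minus = A1m,
                 block_layout = blocks,
                 metric = rep(1, pair_dim), pairs = pairs,
                 D = D, seed = seed,
                 coupling_strength = coupling_strength,
                 normalization = "synthetic"),
            class = "erpa_hessians")
}
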