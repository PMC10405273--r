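# Imaginary-frequency quadrature and the recursive coupling-constant
# expansion of the projected density response.

.grid_cache <- new.env(parent = emptyenv())

# Solve for an n-point rule reproducing the Casimir-Polder Lorentzian family
# 1/(c + omega^2): value and slope enforced strongly at three anchor scales
# omega0*(0.4, 2, 10), least-squares value/slope conditions over a dense
# logarithmic scale range that widens with n (so refinement extends both the
# accuracy and the covered spectral range). Deterministic Levenberg-Marquardt
# with restarts.
.cp_rule <- function(n, omega0) {
  if (n < 4) stop("optimized Casimir-Polder rule needs n >= 4")
  anchors <- (omega0 * c(0.4, 2, 10))^2
  rf <- n / 8
  dense <- exp(seq(log(omega0 * 0.4 / rf), log(omega0 * 10 * rf),
                   length.out = 5 * n))^2
  wA <- 1e4
  Fres <- function(par) {
    om2 <- exp(par[1:n])^2
    wt <- exp(par[(n + 1):(2 * n)])
    c(wA * vapply(anchors, function(c)
        (sum(wt / (c + om2)) - pi / (2 * sqrt(c))) * sqrt(c), 0),
      wA * vapply(anchors, function(c)
        (sum(wt / (c + om2)^2) - pi / (4 * c^1.5)) * c^1.5, 0),
      vapply(dense, function(c)
        (sum(wt / (c + om2)) - pi / (2 * sqrt(c))) * sqrt(c), 0),
      vapply(dense, function(c)
        (sum(wt / (c + om2)^2) - pi / (4 * c^1.5)) * c^1.5, 0))
  }
  gl <- pracma::gaussLegendre(n, -1, 1)
  par <- c(log(omega0 * (1 + gl$x) / (1 - gl$x)),
           log(gl$w * 2 * omega0 / (1 - gl$x)^2))
  for (rep in 1:6) {
    fit <- minpack.lm::nls.lm(par, fn = Fres,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 1024, ftol = 1e-15, ptol = 1e-15))
    par <- fit$par
  }
  om <- exp(par[1:n]); wt <- exp(par[(n + 1):(2 * n)])
  ord <- order(om)
  r <- Fres(par)
  list(nodes = om[ord], weights = wt[ord],
       anchor_residual = max(abs(r[1:6])) / wA,
       dense_residual = max(abs(r[-(1:6)])))
}

#' Imaginary-frequency quadrature grid for Casimir-Polder integration
#'
#' Default (`type = "cp"`): an n-point rule constructed at run time to
#' integrate the Lorentzian family `1/(c + omega^2)` exactly in value and
#' slope at three anchor scales (`omega0 * 0.4, 2, 10` hartree) with
#' interpolatory conditions between -- the optimized imaginary-frequency
#' grids customary in response-function codes. `type = "legendre"` is the
#' classical Gauss-Legendre rule under the rational map
#' `omega = omega0 (1+t)/(1-t)`.
#'
#' @param n_points number of nodes (default 8)
#' @param omega0 map/scale parameter in hartree (default 0.5)
#' @param type `"cp"` (optimized, default) or `"legendre"`
#' @return object of class `frequency_grid` with `nodes`, `weights`
#' @export
make_frequency_grid <- function(n_points = 8L, omega0 = 0.5,
                                type = c("cp", "legendre")) {
  type <- match.arg(type)
  stopifnot(n_points >= 1, omega0 > 0)
  if (type == "legendre" || n_points < 4) {
    gl <- pracma::gaussLegendre(n_points, -1, 1)
    nodes <- omega0 * (1 + gl$x) / (1 - gl$x)
    weights <- gl$w * 2 * omega0 / (1 - gl$x)^2
    ord <- order(nodes)
    grid <- list(nodes = nodes[ord], weights = weights[ord])
    type <- "legendre"
  } else {
    key <- sprintf("cp_%d_%.12g", n_points, omega0)
    if (is.null(.grid_cache[[key]]))
      .grid_cache[[key]] <- .cp_rule(n_points, omega0)
    grid <- .grid_cache[[key]]
  }
  structure(list(nodes = grid$nodes, weights = grid$weights,
                 n_points = as.integer(n_points), omega0 = omega0, type = type),
            class = "frequency_grid")
}

#' Evaluate the Casimir-Polder identity on a grid
#'
#' Computes `(2/pi) sum_j w_j a b / ((a^2 + w_j^2)(b^2 + w_j^2))`, whose
#' exact value is `1/(a+b)`; used to validate quadrature accuracy.
#' @param grid a `frequency_grid`
#' @param a,b positive scales (hartree)
#' @export
casimir_polder_check <- function(grid, a, b) {
  (2 / pi) * sum(grid$weights * a * b /
                   ((a^2 + grid$nodes^2) * (b^2 + grid$nodes^2)))
}

#' Project a pair-space response matrix onto the Cholesky basis
#' @param C pair-index response matrix
#' @param D occupation-scaled Cholesky factor of the same monomer
#' @return `C %*% D` (n_pairs x n_chol)
#' @export
project_response <- function(C, D) {
  if (ncol(C) != nrow(D)) stop("project_response: dimension mismatch")
  C %*% D
}

# block-diagonal resolvent Lambda(omega) = A0- A0+ + omega^2, with per-block
# LU solves only (the full-dimension inverse is never formed)
.lambda_solver <- function(h, omega) {
  blocks <- h$block_layout
  facs <- lapply(blocks, function(b) {
    Lb <- h$A0_minus[b, b, drop = FALSE] %*% h$A0_plus[b, b, drop = FALSE] +
      diag(omega^2, length(b))
    lu <- tryCatch(solve(Lb), error = function(e)
      stop("recursive response: singular Lambda block (omega too small?)"))
    lu
  })
  function(X) {
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      X[b, ] <- facs[[i]] %*% X[b, , drop = FALSE]
    }
    X
  }
}

#' Projected density response by the recursive coupling-constant expansion
#'
#' Expands the projected response `C(alpha, omega) D` in powers of the
#' coupling constant around the block-diagonal zeroth-order Hessians and
#' evaluates the series at alpha = 1, truncated at order `n`. Order 0 is the
#' uncoupled approximation; for `A1 = 0` the series terminates exactly at
#' order 0. Each step costs one multiplication of a pair x N_chol panel by
#' the coupling Hessians (the fifth-power bottleneck) plus block resolvent
#' applications.
#'
#' @param h an `erpa_hessians` after [split_alpha()]
#' @param D occupation-scaled Cholesky factor (n_pairs x N_chol)
#' @param omega imaginary frequency (hartree)
#' @param n truncation order (>= 0)
#' @return object of class `projected_response`: `orders` (list of per-order
#'   increments), `total`, `diverging` flag, `increment_norms`
#' @export
recursive_projected_response <- function(h, D, omega, n) {
  if (is.null(h$A0_plus)) stop("recursive_projected_response: call split_alpha() first")
  lam <- .lambda_solver(h, omega)
  V0 <- h$A0_minus %*% D
  V1 <- h$A1_minus %*% D
  a1_zero <- max(abs(h$A1_plus)) == 0 && max(abs(h$A1_minus)) == 0
  M1 <- function(U) h$A0_minus %*% (h$A1_plus %*% U) + h$A1_minus %*% (h$A0_plus %*% U)
  M2 <- function(U) h$A1_minus %*% (h$A1_plus %*% U)
  # P_k V recursion for V in {V0, V1}: P_0 = Lambda^-1, P_k = -Lambda^-1 (M1 P_{k-1} + M2 P_{k-2})
  S_prev2 <- NULL; S_prev1 <- lam(V0)
  W_prev2 <- NULL; W_prev1 <- lam(V1)
  orders <- list(S_prev1)                       # C~^(0) = P_0 V0
  norms <- norm(S_prev1, "F")
  kmax <- if (a1_zero) 0L else n
  if (kmax >= 1) {
    for (k in seq_len(kmax)) {
      S_new <- -lam(M1(S_prev1) + if (k >= 2) M2(S_prev2) else 0)
      W_new <- -lam(M1(W_prev1) + if (k >= 2) M2(W_prev2) else 0)
      orders[[k + 1]] <- S_new + W_prev1        # C~^(k) = P_k V0 + P_{k-1} V1
      norms <- c(norms, norm(orders[[k + 1]], "F"))
      S_prev2 <- S_prev1; S_prev1 <- S_new
      W_prev2 <- W_prev1; W_prev1 <- W_new
    }
  }
  diverging <- FALSE
  if (length(norms) >= 6) {
    tail_incr <- diff(tail(norms, 4))
    diverging <- all(tail_incr > 0)
  }
  if (diverging)
    warning("recursive_projected_response: increment norms growing; ",
            "series may diverge for this monomer")
  structure(list(orders = orders, total = Reduce(`+`, orders),
                 increment_norms = norms, truncation = n,
                 diverging = diverging, omega = omega),
            class = "projected_response")
}

#' Per-node, per-order convergence diagnostics as CSV
#'
#' Writes one row per frequency node and truncation order with the increment
#' norm and the partial dispersion energy accumulated up to that order, for
#' both monomers truncated consistently.
#'
#' @param calc a `dispersion_result` from
#'   [dispersion_calculation()] with `keep = TRUE`
#' @param path output CSV file
#' @export
write_response_diagnostics <- function(calc, path) {
  if (is.null(calc$responses))
    stop("write_response_diagnostics: need a keep = TRUE dispersion result")
  grid <- calc$full_grid
  rows <- list()
  for (j in seq_len(grid$n_points)) {
    pa <- calc$responses$A[[j]]; pb <- calc$responses$B[[j]]
    nord <- max(length(pa$orders), length(pb$orders))
    Wa <- matrix(0, ncol(calc$D$A), ncol(calc$D$A))
    Wb <- matrix(0, ncol(calc$D$B), ncol(calc$D$B))
    for (k in seq_len(nord)) {
      if (k <= length(pa$orders)) Wa <- Wa + crossprod(calc$D$A, pa$orders[[k]])
      if (k <= length(pb$orders)) Wb <- Wb + crossprod(calc$D$B, pb$orders[[k]])
      rows[[length(rows) + 1]] <- data.frame(
        node = j, omega = grid$nodes[j], order = k - 1L,
        norm_A = if (k <= length(pa$increment_norms)) pa$increment_norms[k] else 0,
        norm_B = if (k <= length(pb$increment_norms)) pb$increment_norms[k] else 0,
        partial_energy = -(8 / pi) * grid$weights[j] * sum(Wa * t(Wb)))
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
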