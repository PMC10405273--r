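#' Orbital-pair index for ERPA excitation operators
#'
#' Enumerates pairs (p, q), p > q, over the inactive (s1), active (s2) and
#' virtual (s3) orbital subsets in the four physically coupled subranges
#' s2 x s1, s3 x s1, s2 x s2, s3 x s2 (no inactive-inactive and no
#' virtual-virtual pairs: their one-matrix metric vanishes). The ordering is
#' deterministic; group offsets and the block layout of the zeroth-order
#' (group-product-function) Hessian are exposed for the recursion.
#'
#' Pairs whose occupation difference `n_q - n_p` falls below `degeneracy_tol`
#' carry a singular response metric and are dropped (counted in the result)
#' when `occupations` are supplied.
#'
#' @param partition list with integer index vectors `s1`, `s2`, `s3`
#' @param occupations optional occupation numbers used to filter degenerate
#'   active pairs
#' @param degeneracy_tol metric threshold for dropping a pair
#' @return object of class `pair_index`: data frame `pairs` (p, q, group),
#'   `group_offsets`, `blocks` (list of row-index vectors), `n_dropped`
#' @export
build_pair_index <- function(partition, occupations = NULL,
                             degeneracy_tol = 1e-6) {
  s1 <- partition$s1; s2 <- partition$s2; s3 <- partition$s3
  if (length(c(s1, s2)) == 0) stop("build_pair_index: no occupied orbitals")
  if (length(c(s2, s3)) == 0) stop("build_pair_index: no secondary orbitals")
  rows <- list()
  add <- function(p, q, group) rows[[length(rows) + 1]] <<- c(p, q, group)
  for (q in s1) for (p in s2) add(p, q, 1L)               # s2 x s1
  for (q in s1) for (p in s3) add(p, q, 2L)               # s3 x s1
  if (length(s2) > 1)
    for (qi in seq_along(s2)[-length(s2)])
      for (pi in (qi + 1):length(s2)) add(s2[pi], s2[qi], 3L)  # s2 x s2, p > q
  for (q in s2) for (p in s3) add(p, q, 4L)               # s3 x s2
  pr <- do.call(rbind, rows)
  pr <- data.frame(p = pr[, 1], q = pr[, 2], group = pr[, 3])
  n_dropped <- 0L
  if (!is.null(occupations)) {
    metric <- occupations[pr$q] - occupations[pr$p]
    keep <- metric > degeneracy_tol
    n_dropped <- sum(!keep)
    pr <- pr[keep, , drop = FALSE]
    rownames(pr) <- NULL
  }
  if (nrow(pr) == 0) stop("build_pair_index: empty pair space")
  group_offsets <- c(0, cumsum(tabulate(pr$group, nbins = 4)))
  # block layout of the alpha = 0 Hessian
  blocks <- list()
  idx <- seq_len(nrow(pr))
  g3 <- idx[pr$group == 3L]
  if (length(g3)) blocks[[length(blocks) + 1]] <- g3     # active-active block
  for (i in s1) {
    b <- idx[pr$group == 1L & pr$q == i]                 # inactive -> active
    if (length(b)) blocks[[length(blocks) + 1]] <- b
  }
  for (k in idx[pr$group == 2L])                          # inactive -> virtual
    blocks[[length(blocks) + 1]] <- k
  for (a in s3) {
    b <- idx[pr$group == 4L & pr$p == a]                 # active -> virtual
    if (length(b)) blocks[[length(blocks) + 1]] <- b
  }
  structure(list(pairs = pr, group_offsets = group_offsets, blocks = blocks,
                 n_dropped = n_dropped, n = nrow(pr)),
            class = "pair_index")
}

#' @export
print.pair_index <- function(x, ...) {
  cat(sprintf("<pair_index: %d pairs (%d dropped), groups %s, %d blocks>\n",
              x$n, x$n_dropped,
              paste(diff(x$group_offsets), collapse = "/"), length(x$blocks)))
  invisible(x)
}
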