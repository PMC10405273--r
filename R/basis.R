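# Built-in Gaussian basis sets. STO-3G parameters are the standard published
# values; "dz.s" is a package-defined even-tempered s-only double-zeta-quality
# set used for compact two-electron test atoms.

.basis_library <- list(
  "sto-3g" = list(
    H = list(list(l = 0,
                  exps = c(3.42525091, 0.62391373, 0.16885540),
                  coefs = c(0.15432897, 0.53532814, 0.44463454))),
    He = list(list(l = 0,
                   exps = c(6.36242139, 1.15892300, 0.31364979),
                   coefs = c(0.15432897, 0.53532814, 0.44463454))),
    O = list(list(l = 0,
                  exps = c(130.7093200, 23.8088610, 6.4436083),
                  coefs = c(0.15432897, 0.53532814, 0.44463454)),
             list(l = 0,
                  exps = c(5.0331513, 1.1695961, 0.3803890),
                  coefs = c(-0.09996723, 0.39951283, 0.70011547)),
             list(l = 1,
                  exps = c(5.0331513, 1.1695961, 0.3803890),
                  coefs = c(0.15591627, 0.60768372, 0.39195739)))
  ),
  "6-31g" = list(
    H = list(list(l = 0,
                  exps = c(18.7311370, 2.8253937, 0.6401217),
                  coefs = c(0.03349460, 0.23472695, 0.81375733)),
             list(l = 0, exps = 0.1612778, coefs = 1.0))
  ),
  # even-tempered 4s sets (ratio 4), package-defined
  "dz.s" = list(
    H = list(list(l = 0, exps = 8.0, coefs = 1.0),
             list(l = 0, exps = 2.0, coefs = 1.0),
             list(l = 0, exps = 0.5, coefs = 1.0),
             list(l = 0, exps = 0.125, coefs = 1.0)),
    He = list(list(l = 0, exps = 19.2, coefs = 1.0),
              list(l = 0, exps = 4.8, coefs = 1.0),
              list(l = 0, exps = 1.2, coefs = 1.0),
              list(l = 0, exps = 0.3, coefs = 1.0))
  )
)

.double_factorial <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))

# normalize contracted shell: primitive norms folded in, then unit self-overlap
.normalize_shell <- function(shell) {
  l <- shell$l
  a <- shell$exps
  prim_norm <- (2 * a / pi)^0.75 * (4 * a)^(l / 2) / sqrt(.double_factorial(2 * l - 1))
  c0 <- shell$coefs * prim_norm
  p <- outer(a, a, "+")
  s_self <- sum(outer(c0, c0) * (pi / p)^1.5 *
                  .double_factorial(2 * l - 1) / (2 * p)^l)
  shell$coefs <- c0 / sqrt(s_self)
  shell
}

#' Build the shell list for a geometry
#'
#' @param geom a [geometry()]
#' @param basis_label one of `"sto-3g"`, `"6-31g"`, `"dz.s"`
#' @return list with per-shell arrays used by the integral kernels and AO count
#' @export
basis_shells <- function(geom, basis_label) {
  lib <- .basis_library[[tolower(basis_label)]]
  if (is.null(lib)) stop("unknown basis set: ", basis_label)
  shells <- list()
  for (i in seq_along(geom$elements)) {
    el <- geom$elements[i]
    if (is.null(lib[[el]]))
      stop("basis ", basis_label, " has no parameters for element ", el)
    for (sh in lib[[el]]) {
      sh <- .normalize_shell(sh)
      sh$atom <- i
      shells[[length(shells) + 1]] <- sh
    }
  }
  nao <- sum(vapply(shells, function(s) (s$l + 1) * (s$l + 2) / 2, 0))
  list(shells = shells,
       atom = vapply(shells, `[[`, 0, "atom"),
       l = vapply(shells, `[[`, 0, "l"),
       nprim = vapply(shells, function(s) length(s$exps), 0),
       exps = unlist(lapply(shells, `[[`, "exps")),
       coefs = unlist(lapply(shells, `[[`, "coefs")),
       nao = nao)
}

# per-AO metadata: owning atom, shell, Cartesian powers
.ao_table <- function(bs) {
  rows <- list()
  for (s in seq_along(bs$shells)) {
    l <- bs$l[s]
    # match the C++ ordering: i from l down to 0, j from l-i down to 0
    comps <- list()
    for (i in l:0) for (j in (l - i):0) comps[[length(comps) + 1]] <- c(i, j, l - i - j)
    for (cc in comps)
      rows[[length(rows) + 1]] <- data.frame(atom = bs$atom[s], shell = s,
                                             px = cc[1], py = cc[2], pz = cc[3])
  }
  do.call(rbind, rows)
}
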