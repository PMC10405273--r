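// McMurchie-Davidson evaluation of one- and two-electron Gaussian integrals.
// Contracted Cartesian shells up to l = 2; coefficients arrive fully normalized
// from the R side, so no scaling happens here.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// Boys function F_m(T) for m = 0..mmax, downward recursion from a series tail.
static void boys(double T, int mmax, std::vector<double> &F) {
  F.assign(mmax + 1, 0.0);
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (T > 35.0) {
    F[0] = 0.5 * std::sqrt(PI / T);
    double expT = std::exp(-T);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - expT) / (2.0 * T);
    return;
  }
  // series for F_mmax, then downward recursion
  double expT = std::exp(-T);
  double term = 1.0 / (2.0 * mmax + 1.0);
  double sum = term;
  for (int k = 1; k < 200; ++k) {
    term *= 2.0 * T / (2.0 * mmax + 2.0 * k + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[mmax] = expT * sum;
  for (int m = mmax; m > 0; --m)
    F[m - 1] = (2.0 * T * F[m] + expT) / (2.0 * m - 1.0);
}

// Hermite expansion coefficients E_t^{ij} for one Cartesian direction.
// Returns E[t] for t = 0..i+j, includes exp(-mu*AB^2) prefactor.
struct Etab {
  // E[i][j][t]
  std::vector<double> v;
  int imax, jmax;
  double &at(int i, int j, int t) { return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t]; }
};

static void hermite_E(int imax, int jmax, double a, double b, double AB, Etab &E) {
  double p = a + b, mu = a * b / p;
  E.imax = imax; E.jmax = jmax;
  E.v.assign((imax + 1) * (jmax + 1) * (imax + jmax + 1), 0.0);
  E.at(0, 0, 0) = std::exp(-mu * AB * AB);
  double PA = -b * AB / p;  // P - A with AB = A - B
  double PB = a * AB / p;   // P - B
  for (int i = 0; i <= imax; ++i) {
    for (int j = 0; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double val = 0.0;
        if (i > 0) {
          if (t > 0) val += E.at(i - 1, j, t - 1) / (2.0 * p);
          if (t <= i - 1 + j) val += PA * E.at(i - 1, j, t);
          if (t + 1 <= i - 1 + j) val += (t + 1.0) * E.at(i - 1, j, t + 1);
        } else {
          if (t > 0) val += E.at(i, j - 1, t - 1) / (2.0 * p);
          if (t <= i + j - 1) val += PB * E.at(i, j - 1, t);
          if (t + 1 <= i + j - 1) val += (t + 1.0) * E.at(i, j - 1, t + 1);
        }
        E.at(i, j, t) = val;
      }
    }
  }
}

// Hermite Coulomb integrals R_{tuv} = R^0_{tuv}(p, PQ).
static void hermite_R(int tmax, int umax, int vmax, double p,
                      double X, double Y, double Z, std::vector<double> &R0) {
  int L = tmax + umax + vmax;
  double T = p * (X * X + Y * Y + Z * Z);
  std::vector<double> F;
  boys(T, L, F);
  // R^n_{tuv} stored as R[n][t][u][v]; build by recursion on total order
  int dt = tmax + 1, du = umax + 1, dv = vmax + 1;
  std::vector<double> R((L + 1) * dt * du * dv, 0.0);
  auto idx = [&](int n, int t, int u, int v) {
    return ((n * dt + t) * du + u) * dv + v;
  };
  for (int n = 0; n <= L; ++n) {
    double f = 1.0;
    for (int k = 0; k < n; ++k) f *= -2.0 * p;
    R[idx(n, 0, 0, 0)] = f * F[n];
  }
  for (int tot = 1; tot <= L; ++tot) {
    for (int t = 0; t <= std::min(tot, tmax); ++t)
      for (int u = 0; u <= std::min(tot - t, umax); ++u) {
        int v = tot - t - u;
        if (v < 0 || v > vmax) continue;
        for (int n = 0; n <= L - tot; ++n) {
          double val = 0.0;
          if (t > 0) {
            if (t > 1) val += (t - 1.0) * R[idx(n + 1, t - 2, u, v)];
            val += X * R[idx(n + 1, t - 1, u, v)];
          } else if (u > 0) {
            if (u > 1) val += (u - 1.0) * R[idx(n + 1, t, u - 2, v)];
            val += Y * R[idx(n + 1, t, u - 1, v)];
          } else {
            if (v > 1) val += (v - 1.0) * R[idx(n + 1, t, u, v - 2)];
            val += Z * R[idx(n + 1, t, u, v - 1)];
          }
          R[idx(n, t, u, v)] = val;
        }
      }
  }
  R0.assign(dt * du * dv, 0.0);
  for (int t = 0; t <= tmax; ++t)
    for (int u = 0; u <= umax; ++u)
      for (int v = 0; v <= vmax; ++v)
        R0[(t * du + u) * dv + v] = R[idx(0, t, u, v)];
}

struct Shell {
  int atom;            // 0-based
  int l;
  std::vector<double> exps, coefs;
  double x, y, z;
  int ao_off;          // first AO index (0-based)
  int nao() const { return (l + 1) * (l + 2) / 2; }
};

// Cartesian component exponents for a shell of angular momentum l, in a fixed order.
static void cart_comps(int l, std::vector<std::array<int, 3>> &c) {
  c.clear();
  for (int i = l; i >= 0; --i)
    for (int j = l - i; j >= 0; --j)
      c.push_back({i, j, l - i - j});
}

static std::vector<Shell> build_shells(NumericMatrix coords, IntegerVector shell_atom,
                                       IntegerVector shell_l, IntegerVector shell_nprim,
                                       NumericVector exps, NumericVector coefs) {
  std::vector<Shell> sh(shell_atom.size());
  int k = 0, ao = 0;
  for (int s = 0; s < shell_atom.size(); ++s) {
    sh[s].atom = shell_atom[s] - 1;
    sh[s].l = shell_l[s];
    sh[s].x = coords(sh[s].atom, 0);
    sh[s].y = coords(sh[s].atom, 1);
    sh[s].z = coords(sh[s].atom, 2);
    for (int p = 0; p < shell_nprim[s]; ++p) {
      sh[s].exps.push_back(exps[k]);
      sh[s].coefs.push_back(coefs[k]);
      ++k;
    }
    sh[s].ao_off = ao;
    ao += sh[s].nao();
  }
  return sh;
}

static int count_ao(const std::vector<Shell> &sh) {
  int n = 0;
  for (auto &s : sh) n += s.nao();
  return n;
}

// one-electron integrals: overlap, kinetic, nuclear attraction
// [[Rcpp::export]]
List cpp_one_electron(NumericMatrix coords, NumericVector charges,
                      IntegerVector shell_atom, IntegerVector shell_l,
                      IntegerVector shell_nprim, NumericVector exps, NumericVector coefs) {
  std::vector<Shell> sh = build_shells(coords, shell_atom, shell_l, shell_nprim, exps, coefs);
  int nao = count_ao(sh);
  NumericMatrix S(nao, nao), T(nao, nao), V(nao, nao);
  std::vector<std::array<int, 3>> ca, cb;

  for (size_t A = 0; A < sh.size(); ++A) {
    for (size_t B = 0; B <= A; ++B) {
      const Shell &sa = sh[A], &sb = sh[B];
      cart_comps(sa.l, ca);
      cart_comps(sb.l, cb);
      double ABx = sa.x - sb.x, ABy = sa.y - sb.y, ABz = sa.z - sb.z;
      int na = sa.nao(), nb = sb.nao();
      std::vector<double> Sblk(na * nb, 0.0), Tblk(na * nb, 0.0), Vblk(na * nb, 0.0);
      for (size_t ia = 0; ia < sa.exps.size(); ++ia) {
        for (size_t ib = 0; ib < sb.exps.size(); ++ib) {
          double a = sa.exps[ia], b = sb.exps[ib], cc = sa.coefs[ia] * sb.coefs[ib];
          double p = a + b;
          double Px = (a * sa.x + b * sb.x) / p, Py = (a * sa.y + b * sb.y) / p,
                 Pz = (a * sa.z + b * sb.z) / p;
          // E tables with margin +2 in the second index for the kinetic part
          Etab Ex, Ey, Ez;
          hermite_E(sa.l, sb.l + 2, a, b, ABx, Ex);
          hermite_E(sa.l, sb.l + 2, a, b, ABy, Ey);
          hermite_E(sa.l, sb.l + 2, a, b, ABz, Ez);
          double pref = std::pow(PI / p, 1.5);
          for (int q = 0; q < na; ++q) {
            for (int r = 0; r < nb; ++r) {
              int i1 = ca[q][0], j1 = ca[q][1], k1 = ca[q][2];
              int i2 = cb[r][0], j2 = cb[r][1], k2 = cb[r][2];
              double sx = Ex.at(i1, i2, 0), sy = Ey.at(j1, j2, 0), sz = Ez.at(k1, k2, 0);
              double sval = pref * sx * sy * sz;
              Sblk[q * nb + r] += cc * sval;
              // kinetic via 1D relations
              auto kin1d = [&](Etab &E, int i, int j) {
                double t = b * (2.0 * j + 1.0) * E.at(i, j, 0) -
                           2.0 * b * b * E.at(i, j + 2, 0);
                if (j >= 2) t -= 0.5 * j * (j - 1.0) * E.at(i, j - 2, 0);
                return t;
              };
              double tx = kin1d(Ex, i1, i2), ty = kin1d(Ey, j1, j2), tz = kin1d(Ez, k1, k2);
              double tval = pref * (tx * sy * sz + sx * ty * sz + sx * sy * tz);
              Tblk[q * nb + r] += cc * tval;
            }
          }
          // nuclear attraction
          int lsum = sa.l + sb.l;
          for (int at = 0; at < coords.nrow(); ++at) {
            double Z = charges[at];
            if (Z == 0.0) continue;
            std::vector<double> R0;
            hermite_R(lsum, lsum, lsum, p, Px - coords(at, 0), Py - coords(at, 1),
                      Pz - coords(at, 2), R0);
            int du = lsum + 1, dv = lsum + 1;
            for (int q = 0; q < na; ++q) {
              for (int r = 0; r < nb; ++r) {
                int i1 = ca[q][0], j1 = ca[q][1], k1 = ca[q][2];
                int i2 = cb[r][0], j2 = cb[r][1], k2 = cb[r][2];
                double acc = 0.0;
                for (int t = 0; t <= i1 + i2; ++t)
                  for (int u = 0; u <= j1 + j2; ++u)
                    for (int v = 0; v <= k1 + k2; ++v)
                      acc += Ex.at(i1, i2, t) * Ey.at(j1, j2, u) * Ez.at(k1, k2, v) *
                             R0[(t * du + u) * dv + v];
                Vblk[q * nb + r] += -Z * cc * (2.0 * PI / p) * acc;
              }
            }
          }
        }
      }
      for (int q = 0; q < na; ++q) {
        for (int r = 0; r < nb; ++r) {
          int I = sa.ao_off + q, J = sb.ao_off + r;
          S(I, J) = Sblk[q * nb + r]; S(J, I) = S(I, J);
          T(I, J) = Tblk[q * nb + r]; T(J, I) = T(I, J);
          V(I, J) = Vblk[q * nb + r]; V(J, I) = V(I, J);
        }
      }
    }
  }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V);
}

// ERI over a shell quartet, chemist convention (ab|cd), accumulated into `out`
static void eri_quartet(const Shell &sa, const Shell &sb, const Shell &sc, const Shell &sd,
                        std::vector<double> &out) {
  std::vector<std::array<int, 3>> ca, cb, cc2, cd;
  cart_comps(sa.l, ca); cart_comps(sb.l, cb);
  cart_comps(sc.l, cc2); cart_comps(sd.l, cd);
  int na = sa.nao(), nb = sb.nao(), nc = sc.nao(), nd = sd.nao();
  out.assign(na * nb * nc * nd, 0.0);
  double ABx = sa.x - sb.x, ABy = sa.y - sb.y, ABz = sa.z - sb.z;
  double CDx = sc.x - sd.x, CDy = sc.y - sd.y, CDz = sc.z - sd.z;
  int l12 = sa.l + sb.l, l34 = sc.l + sd.l;
  for (size_t ia = 0; ia < sa.exps.size(); ++ia)
    for (size_t ib = 0; ib < sb.exps.size(); ++ib) {
      double a = sa.exps[ia], b = sb.exps[ib], p = a + b;
      double c12 = sa.coefs[ia] * sb.coefs[ib];
      double Px = (a * sa.x + b * sb.x) / p, Py = (a * sa.y + b * sb.y) / p,
             Pz = (a * sa.z + b * sb.z) / p;
      Etab E1x, E1y, E1z;
      hermite_E(sa.l, sb.l, a, b, ABx, E1x);
      hermite_E(sa.l, sb.l, a, b, ABy, E1y);
      hermite_E(sa.l, sb.l, a, b, ABz, E1z);
      for (size_t ic = 0; ic < sc.exps.size(); ++ic)
        for (size_t id = 0; id < sd.exps.size(); ++id) {
          double c = sc.exps[ic], d = sd.exps[id], q = c + d;
          double c34 = sc.coefs[ic] * sd.coefs[id];
          double Qx = (c * sc.x + d * sd.x) / q, Qy = (c * sc.y + d * sd.y) / q,
                 Qz = (c * sc.z + d * sd.z) / q;
          Etab E2x, E2y, E2z;
          hermite_E(sc.l, sd.l, c, d, CDx, E2x);
          hermite_E(sc.l, sd.l, c, d, CDy, E2y);
          hermite_E(sc.l, sd.l, c, d, CDz, E2z);
          double alpha = p * q / (p + q);
          std::vector<double> R0;
          hermite_R(l12 + l34, l12 + l34, l12 + l34, alpha, Px - Qx, Py - Qy, Pz - Qz, R0);
          int du = l12 + l34 + 1, dv = l12 + l34 + 1;
          double pref = 2.0 * std::pow(PI, 2.5) / (p * q * std::sqrt(p + q)) * c12 * c34;
          for (int w = 0; w < na; ++w)
            for (int x = 0; x < nb; ++x) {
              int i1 = ca[w][0] + cb[x][0], j1 = ca[w][1] + cb[x][1], k1 = ca[w][2] + cb[x][2];
              for (int y = 0; y < nc; ++y)
                for (int z = 0; z < nd; ++z) {
                  int i2 = cc2[y][0] + cd[z][0], j2 = cc2[y][1] + cd[z][1],
                      k2 = cc2[y][2] + cd[z][2];
                  double acc = 0.0;
                  for (int t = 0; t <= i1; ++t)
                    for (int u = 0; u <= j1; ++u)
                      for (int v = 0; v <= k1; ++v) {
                        double e1 = E1x.at(ca[w][0], cb[x][0], t) *
                                    E1y.at(ca[w][1], cb[x][1], u) *
                                    E1z.at(ca[w][2], cb[x][2], v);
                        if (e1 == 0.0) continue;
                        double inner = 0.0;
                        for (int tt = 0; tt <= i2; ++tt)
                          for (int uu = 0; uu <= j2; ++uu)
                            for (int vv = 0; vv <= k2; ++vv) {
                              double e2 = E2x.at(cc2[y][0], cd[z][0], tt) *
                                          E2y.at(cc2[y][1], cd[z][1], uu) *
                                          E2z.at(cc2[y][2], cd[z][2], vv);
                              if (e2 == 0.0) continue;
                              double sgn = ((tt + uu + vv) % 2 == 0) ? 1.0 : -1.0;
                              inner += sgn * e2 *
                                       R0[((t + tt) * du + (u + uu)) * dv + (v + vv)];
                            }
                        acc += e1 * inner;
                      }
                  out[((w * nb + x) * nc + y) * nd + z] += pref * acc;
                }
            }
        }
    }
}

// full ERI tensor (ab|cd), chemist convention, as an nao^4 array
// [[Rcpp::export]]
NumericVector cpp_eri(NumericMatrix coords, IntegerVector shell_atom, IntegerVector shell_l,
                      IntegerVector shell_nprim, NumericVector exps, NumericVector coefs) {
  std::vector<Shell> sh = build_shells(coords, shell_atom, shell_l, shell_nprim, exps, coefs);
  int nao = count_ao(sh);
  NumericVector eri((R_xlen_t)nao * nao * nao * nao);
  std::vector<double> blk;
  long n = nao;
  for (size_t A = 0; A < sh.size(); ++A)
    for (size_t B = 0; B <= A; ++B)
      for (size_t C = 0; C <= A; ++C)
        for (size_t D = 0; D <= (C == A ? B : C); ++D) {
          eri_quartet(sh[A], sh[B], sh[C], sh[D], blk);
          int na = sh[A].nao(), nb = sh[B].nao(), nc = sh[C].nao(), nd = sh[D].nao();
          for (int w = 0; w < na; ++w)
            for (int x = 0; x < nb; ++x)
              for (int y = 0; y < nc; ++y)
                for (int z = 0; z < nd; ++z) {
                  double val = blk[((w * nb + x) * nc + y) * nd + z];
                  long i = sh[A].ao_off + w, j = sh[B].ao_off + x,
                       k = sh[C].ao_off + y, l = sh[D].ao_off + z;
                  // 8-fold symmetry
                  eri[i + n * (j + n * (k + n * l))] = val;
                  eri[j + n * (i + n * (k + n * l))] = val;
                  eri[i + n * (j + n * (l + n * k))] = val;
                  eri[j + n * (i + n * (l + n * k))] = val;
                  eri[k + n * (l + n * (i + n * j))] = val;
                  eri[l + n * (k + n * (i + n * j))] = val;
                  eri[k + n * (l + n * (j + n * i))] = val;
                  eri[l + n * (k + n * (j + n * i))] = val;
                }
        }
  return eri;
}

// diagonal (pq|pq) of the AO Coulomb matrix over triangle pairs p >= q
// (column-major pair enumeration: (1,1),(2,1),(2,2),(3,1),...)
// [[Rcpp::export]]
NumericVector cpp_coulomb_diag(NumericMatrix coords, IntegerVector shell_atom,
                               IntegerVector shell_l, IntegerVector shell_nprim,
                               NumericVector exps, NumericVector coefs) {
  std::vector<Shell> sh = build_shells(coords, shell_atom, shell_l, shell_nprim, exps, coefs);
  int nao = count_ao(sh);
  NumericVector out(nao * (nao + 1) / 2);
  std::vector<double> blk;
  // map AO -> shell
  std::vector<int> aosh(nao), aoloc(nao);
  for (size_t s = 0; s < sh.size(); ++s)
    for (int k = 0; k < sh[s].nao(); ++k) {
      aosh[sh[s].ao_off + k] = (int)s;
      aoloc[sh[s].ao_off + k] = k;
    }
  int idx = 0;
  for (int p = 0; p < nao; ++p)
    for (int q = 0; q <= p; ++q) {
      const Shell &sa = sh[aosh[p]], &sb = sh[aosh[q]];
      eri_quartet(sa, sb, sa, sb, blk);
      int nb = sb.nao(), nc = sa.nao(), nd = sb.nao();
      int w = aoloc[p], x = aoloc[q];
      out[idx++] = blk[((w * nb + x) * nc + w) * nd + x];
    }
  return out;
}

// one column (rs|pq) of the AO Coulomb matrix for fixed (p,q), over pairs r >= s
// [[Rcpp::export]]
NumericVector cpp_coulomb_column(NumericMatrix coords, IntegerVector shell_atom,
                                 IntegerVector shell_l, IntegerVector shell_nprim,
                                 NumericVector exps, NumericVector coefs,
                                 int p1, int q1) {
  std::vector<Shell> sh = build_shells(coords, shell_atom, shell_l, shell_nprim, exps, coefs);
  int nao = count_ao(sh);
  int p = p1 - 1, q = q1 - 1;
  std::vector<int> aosh(nao), aoloc(nao);
  for (size_t s = 0; s < sh.size(); ++s)
    for (int k = 0; k < sh[s].nao(); ++k) {
      aosh[sh[s].ao_off + k] = (int)s;
      aoloc[sh[s].ao_off + k] = k;
    }
  NumericVector out(nao * (nao + 1) / 2);
  std::vector<double> blk;
  int idx = 0;
  for (int r = 0; r < nao; ++r)
    for (int s = 0; s <= r; ++s) {
      const Shell &sa = sh[aosh[r]], &sb = sh[aosh[s]], &sc = sh[aosh[p]], &sd = sh[aosh[q]];
      eri_quartet(sa, sb, sc, sd, blk);
      int nb = sb.nao(), nc = sc.nao(), nd = sd.nao();
      out[idx++] = blk[((aoloc[r] * nb + aoloc[s]) * nc + aoloc[p]) * nd + aoloc[q]];
    }
  return out;
}
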