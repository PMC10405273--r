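// ERPA Hessian matrices over orbital-pair excitations, from spin-free 1-/2-RDMs.
//
// Computes M[(p,q),(a,b)] = <0| [E_qp, [H, E_ab]] |0> with spin-summed E_ab,
// H = sum h_tu E_tu + 1/2 sum <tu|vw> (E_tv E_uw - delta_uv E_tw).
// The double commutator is a two-body operator, so the expectation closes over
// the one-matrix (diagonal in the natural-orbital basis) and the two-matrix
//   d2[p,q,r,s] = <0| sum_{st} a+_ps a+_qt a_st a_rt' ... |0>  (spin-free,
//   index pairing (p<->r),(q<->s); zero whenever an index is unoccupied).
// The expansion below follows from [E_tv E_uw, E_rs] and [E_qp, E_ab E_cd]
// worked out term by term; <E_ab E_cd> = d2_{ac,bd} + delta_bc D1_ad.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct Work {
  int m;
  const double *h;    // m x m
  const double *eri;  // m^4 chemist (pq|rs)
  const double *d1;   // diagonal of spin-summed 1-RDM (2 * occupation)
  const double *d2;   // m^4
  std::vector<double> Z3, Z4, Z5, Z6, K;  // m x m precomputes

  inline double v(int t, int u, int vv, int w) const {  // <tu|vw> = (tv|uw)
    return eri[t + m * (vv + m * (u + (long)m * w))];
  }
  inline double D2(int p, int q, int r, int s) const {
    return d2[p + m * (q + m * (r + (long)m * s))];
  }
  inline double G(int a, int b, int c, int d) const {  // <E_ab E_cd>
    double g = D2(a, c, b, d);
    if (b == c && a == d) g += d1[a];
    return g;
  }
};

static void precompute(Work &W) {
  int m = W.m;
  W.Z3.assign(m * m, 0.0);
  W.Z4.assign(m * m, 0.0);
  W.Z5.assign(m * m, 0.0);
  W.Z6.assign(m * m, 0.0);
  W.K.assign(m * m, 0.0);
  for (int a = 0; a < m; ++a)
    for (int b = 0; b < m; ++b) {
      double z3 = 0, z5 = 0;
      for (int t = 0; t < m; ++t)
        for (int u = 0; u < m; ++u)
          for (int w = 0; w < m; ++w) {
            // Z3[p=a][r=b] = sum_{tuv} <tu|vb> G_{tv,ua}; (t,u,w)->(t,u,v)
            z3 += W.v(t, u, w, b) * W.G(t, w, u, a);
            // Z5[p=a][r=b] = sum_{tuw} <tu|bw> G_{ta,uw}
            z5 += W.v(t, u, b, w) * W.G(t, a, u, w);
          }
      W.Z3[a + m * b] = z3;
      W.Z5[a + m * b] = z5;
    }
  // Z4[q][s] = sum_{tvw} <ts|vw> G_{tv,qw};  Z6[q][s] = sum_{uvw} <su|vw> G_{qv,uw}
  for (int a = 0; a < m; ++a)
    for (int b = 0; b < m; ++b) {
      double z4 = 0, z6 = 0, k = 0;
      for (int t = 0; t < m; ++t) {
        k += W.v(a, t, t, b);  // K[a][b] = sum_u <au|ub>
        for (int vv = 0; vv < m; ++vv)
          for (int w = 0; w < m; ++w) {
            z4 += W.v(t, b, vv, w) * W.G(t, vv, a, w);
            z6 += W.v(b, t, vv, w) * W.G(a, vv, t, w);
          }
      }
      W.Z4[a + m * b] = z4;
      W.Z6[a + m * b] = z6;
      W.K[a + m * b] = k;
    }
}

// M_{(pq),(rs)} = <[E_qp, [H, E_rs]]>
static double Melem(const Work &W, int p, int q, int r, int s) {
  int m = W.m;
  double acc = 0.0;
  // one-body pieces (D1 diagonal)
  if (q == s) acc += (W.d1[q] - W.d1[p]) * W.h[p + m * r];
  if (p == r) acc += (W.d1[p] - W.d1[q]) * W.h[s + m * q];
  // effective one-body from delta_uv contraction of the two-body operator
  if (q == s) acc += 0.5 * (W.d1[p] - W.d1[q]) * W.K[p + m * r];
  if (p == r) acc += 0.5 * (W.d1[q] - W.d1[p]) * W.K[s + m * q];
  // delta-contracted two-body precomputes
  if (q == s) acc += -0.5 * (W.Z3[p + m * r] + W.Z5[p + m * r]);
  if (p == r) acc += -0.5 * (W.Z4[q + m * s] + W.Z6[q + m * s]);
  // explicit double sums
  double t3a = 0, t3b = 0, t3c = 0, t4a = 0, t4b = 0, t4d = 0;
  double t5a = 0, t5c = 0, t5d = 0, t6b = 0, t6c = 0, t6d = 0;
  for (int t = 0; t < m; ++t)
    for (int u = 0; u < m; ++u) {
      t3a += W.v(p, u, t, r) * W.G(q, t, u, s);   // (u,v)->(u,t)
      t3b += W.v(t, u, q, r) * W.G(t, p, u, s);
      t3c += W.v(t, p, u, r) * W.G(t, u, q, s);   // (t,v)->(t,u)
      t4a += W.v(p, s, t, u) * W.G(q, t, r, u);   // (v,w)->(t,u)
      t4b += W.v(t, s, q, u) * W.G(t, p, r, u);   // (t,w)->(t,u)
      t4d += W.v(t, s, u, q) * W.G(t, u, r, p);   // (t,v)->(t,u)
      t5a += W.v(p, u, r, t) * W.G(q, s, u, t);   // (u,w)->(u,t)
      t5c += W.v(t, p, r, u) * W.G(t, s, q, u);   // (t,w)->(t,u)
      t5d += W.v(t, u, r, q) * W.G(t, s, u, p);
      t6b += W.v(s, u, q, t) * W.G(r, p, u, t);   // (u,w)->(u,t)
      t6c += W.v(s, p, t, u) * W.G(r, t, q, u);   // (v,w)->(t,u)
      t6d += W.v(s, u, t, q) * W.G(r, t, u, p);   // (u,v)->(u,t)
    }
  acc += 0.5 * (t3a - t3b + t3c - t4a + t4b + t4d + t5a + t5c - t5d + t6b - t6c + t6d);
  return acc;
}

// [[Rcpp::export]]
List cpp_erpa_hessians(int m, NumericMatrix h, NumericVector eri, NumericVector d1,
                       NumericVector d2, IntegerMatrix pairs) {
  Work W;
  W.m = m;
  W.h = h.begin();
  W.eri = eri.begin();
  W.d1 = d1.begin();
  W.d2 = d2.begin();
  precompute(W);
  int np = pairs.nrow();
  NumericMatrix A(np, np), B(np, np);
  for (int a = 0; a < np; ++a) {
    int p = pairs(a, 0) - 1, q = pairs(a, 1) - 1;
    for (int b = 0; b < np; ++b) {
      int r = pairs(b, 0) - 1, s = pairs(b, 1) - 1;
      A(a, b) = Melem(W, p, q, r, s);
      B(a, b) = Melem(W, p, q, s, r);
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}
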