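// Smooth energy terms and their analytic gradients.
//
// Terms: molecular-mechanics bonded (bonds, angles, periodic torsions),
// Lennard-Jones with scalable radii, distance-dependent-dielectric Coulomb,
// implicit-solvation surrogates (polar burial penalty + surface-area term
// driven by a smooth pairwise burial count), geometric hydrogen bonds, and
// harmonic distance/position restraints. Statistical lookup terms are
// evaluated on the R side (they carry no gradient).

#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// [[Rcpp::export]]
List energy_core(NumericMatrix coords,
                 IntegerMatrix bonds, NumericVector bonds_b0, double kb,
                 IntegerMatrix angles, NumericVector angles_th0, double ka,
                 NumericMatrix torsions,
                 NumericVector charge, NumericVector radius,
                 NumericVector eps, NumericVector excl_keys,
                 NumericVector p14_keys, double cutoff, double coul_const,
                 double scale14,
                 IntegerVector hb_donors, IntegerMatrix hb_acceptors,
                 double hb_strength, double hb_r0, double hb_sigma,
                 IntegerVector res_of_atom,
                 double solv_kpol, double solv_gamma, double solv_sigma,
                 double solv_b0, NumericVector sasa_ref,
                 NumericMatrix rest_dist, NumericMatrix rest_pos,
                 double vdw_scale, NumericVector weights, bool want_grad) {
  const int n = coords.nrow();
  const double* X = REAL(coords);          // column-major: X[i], X[i+n], X[i+2n]
  NumericMatrix grad(want_grad ? n : 1, 3);
  double* G = REAL(grad);
  const int gn = want_grad ? n : 1;

  const double w_bonded = weights[0], w_vdw = weights[1], w_coul = weights[2],
               w_pol = weights[3], w_np = weights[4], w_hb = weights[5],
               w_rd = weights[6], w_rp = weights[7];

  double E_bonded = 0, E_vdw = 0, E_coul = 0, E_pol = 0, E_np = 0,
         E_hb = 0, E_rd = 0, E_rp = 0;

  auto getv = [&](int i, double* v) {
    v[0] = X[i]; v[1] = X[i + n]; v[2] = X[i + 2 * n];
  };
  auto addg = [&](int i, double w, const double* f) {
    if (!want_grad) return;
    G[i] += w * f[0]; G[i + gn] += w * f[1]; G[i + 2 * gn] += w * f[2];
  };

  // ---- bonds ----
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double d[3] = {X[i] - X[j], X[i + n] - X[j + n], X[i + 2 * n] - X[j + 2 * n]};
    double r = std::sqrt(dot3(d, d));
    double dev = r - bonds_b0[b];
    E_bonded += kb * dev * dev;
    if (want_grad && r > 1e-12) {
      double c = 2.0 * kb * dev / r;
      double f[3] = {c * d[0], c * d[1], c * d[2]};
      addg(i, w_bonded, f);
      double fm[3] = {-f[0], -f[1], -f[2]};
      addg(j, w_bonded, fm);
    }
  }

  // ---- angles ----
  for (int a = 0; a < angles.nrow(); ++a) {
    int i = angles(a, 0) - 1, j = angles(a, 1) - 1, k = angles(a, 2) - 1;
    double u[3] = {X[i] - X[j], X[i + n] - X[j + n], X[i + 2 * n] - X[j + 2 * n]};
    double v[3] = {X[k] - X[j], X[k + n] - X[j + n], X[k + 2 * n] - X[j + 2 * n]};
    double nu = std::sqrt(dot3(u, u)), nv = std::sqrt(dot3(v, v));
    if (nu < 1e-12 || nv < 1e-12) continue;
    double c = dot3(u, v) / (nu * nv);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    double dev = th - angles_th0[a];
    E_bonded += ka * dev * dev;
    if (want_grad) {
      double s = std::sqrt(1.0 - c * c);
      if (s < 1e-8) s = 1e-8;
      double coef = 2.0 * ka * dev;
      double di[3], dk[3], dj[3];
      for (int t = 0; t < 3; ++t) {
        di[t] = (c * u[t] / nu - v[t] / nv) / (nu * s);
        dk[t] = (c * v[t] / nv - u[t] / nu) / (nv * s);
        dj[t] = -di[t] - dk[t];
      }
      double fi[3] = {coef * di[0], coef * di[1], coef * di[2]};
      double fj[3] = {coef * dj[0], coef * dj[1], coef * dj[2]};
      double fk[3] = {coef * dk[0], coef * dk[1], coef * dk[2]};
      addg(i, w_bonded, fi); addg(j, w_bonded, fj); addg(k, w_bonded, fk);
    }
  }

  // ---- periodic torsions (proper + planarity impropers) ----
  for (int t = 0; t < torsions.nrow(); ++t) {
    int i = (int)torsions(t, 0) - 1, j = (int)torsions(t, 1) - 1,
        k = (int)torsions(t, 2) - 1, l = (int)torsions(t, 3) - 1;
    double kt = torsions(t, 4);
    double per = torsions(t, 5);
    double delta = torsions(t, 6) * M_PI / 180.0;
    double p1[3], p2[3], p3[3], p4[3];
    getv(i, p1); getv(j, p2); getv(k, p3); getv(l, p4);
    double b1[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
    double b2[3] = {p3[0] - p2[0], p3[1] - p2[1], p3[2] - p2[2]};
    double b3[3] = {p4[0] - p3[0], p4[1] - p3[1], p4[2] - p3[2]};
    double n1[3], n2[3];
    cross3(b1, b2, n1); cross3(b2, b3, n2);
    double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
    double nb2 = std::sqrt(dot3(b2, b2));
    if (n1sq < 1e-12 || n2sq < 1e-12 || nb2 < 1e-12) continue;
    double mn[3];
    cross3(n1, n2, mn);
    double x = dot3(n1, n2) * nb2;
    double y = dot3(mn, b2);
    double phi = std::atan2(y, x);
    E_bonded += kt * (1.0 + std::cos(per * phi - delta));
    if (want_grad) {
      double dEdphi = -kt * per * std::sin(per * phi - delta);
      double dpi[3], dpl[3], dpj[3], dpk[3];
      double c12 = dot3(b1, b2) / (nb2 * nb2);
      double c32 = dot3(b3, b2) / (nb2 * nb2);
      for (int q = 0; q < 3; ++q) {
        dpi[q] = -nb2 / n1sq * n1[q];
        dpl[q] = nb2 / n2sq * n2[q];
        dpj[q] = -(1.0 + c12) * dpi[q] + c32 * dpl[q];
        dpk[q] = c12 * dpi[q] - (1.0 + c32) * dpl[q];
      }
      double fi[3], fj[3], fk[3], fl[3];
      for (int q = 0; q < 3; ++q) {
        fi[q] = dEdphi * dpi[q]; fj[q] = dEdphi * dpj[q];
        fk[q] = dEdphi * dpk[q]; fl[q] = dEdphi * dpl[q];
      }
      addg(i, w_bonded, fi); addg(j, w_bonded, fj);
      addg(k, w_bonded, fk); addg(l, w_bonded, fl);
    }
  }

  // ---- nonbonded: LJ + screened Coulomb + burial for solvation ----
  std::unordered_set<long long> excl, p14;
  for (int q = 0; q < excl_keys.size(); ++q)
    excl.insert((long long)excl_keys[q]);
  for (int q = 0; q < p14_keys.size(); ++q)
    p14.insert((long long)p14_keys[q]);
  auto pkey = [&](int i, int j) -> long long {
    int lo = i < j ? i : j, hi = i < j ? j : i;
    return (long long)lo * n + hi;
  };

  std::vector<double> burial(n, 0.0);
  const double cut2 = cutoff * cutoff;
  const double ssig2 = solv_sigma * solv_sigma;

  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d[3] = {X[i] - X[j], X[i + n] - X[j + n],
                     X[i + 2 * n] - X[j + 2 * n]};
      double r2 = dot3(d, d);
      if (r2 >= cut2) continue;
      double r = std::sqrt(r2);
      // burial counts every neighbor, bonded or not
      double bexp = std::exp(-r2 / (2.0 * ssig2));
      burial[i] += bexp; burial[j] += bexp;
      long long key = pkey(i, j);
      if (excl.count(key)) continue;
      double scale = p14.count(key) ? scale14 : 1.0;
      // Lennard-Jones, sigma convention: minimum -eps at sigma*2^(1/6)
      double sig = (radius[i] + radius[j]) * vdw_scale;
      double e = std::sqrt(eps[i] * eps[j]);
      double sr2 = sig * sig / r2;
      double sr6 = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      E_vdw += scale * 4.0 * e * (sr12 - sr6);
      // Coulomb with distance-dependent dielectric eps(r) = 4r
      double ec = scale * coul_const * charge[i] * charge[j] / (4.0 * r2);
      E_coul += ec;
      if (want_grad) {
        double flj = scale * 24.0 * e * (-2.0 * sr12 + sr6) / r2;
        double fc = -2.0 * ec / r2;
        double cc = w_vdw * flj + w_coul * fc;
        for (int q = 0; q < 3; ++q) {
          double g = cc * d[q];
          G[i + q * gn] += g;
          G[j + q * gn] -= g;
        }
      }
    }
  }

  // ---- solvation from burial ----
  std::vector<double> dEdB(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double qp = charge[i] * charge[i];
    E_pol += solv_kpol * qp * burial[i];
    double ex = std::exp(-burial[i] / solv_b0);
    E_np += solv_gamma * sasa_ref[i] * ex;
    dEdB[i] = w_pol * solv_kpol * qp -
              w_np * solv_gamma * sasa_ref[i] * ex / solv_b0;
  }
  if (want_grad) {
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double d[3] = {X[i] - X[j], X[i + n] - X[j + n],
                       X[i + 2 * n] - X[j + 2 * n]};
        double r2 = dot3(d, d);
        if (r2 >= cut2) continue;
        double bexp = std::exp(-r2 / (2.0 * ssig2));
        double c = -(dEdB[i] + dEdB[j]) * bexp / ssig2;
        for (int q = 0; q < 3; ++q) {
          double g = c * d[q];
          G[i + q * gn] += g;
          G[j + q * gn] -= g;
        }
      }
    }
  }

  // ---- geometric hydrogen bonds: N (donor) ... O=C (acceptor) ----
  for (int a = 0; a < hb_donors.size(); ++a) {
    int iN = hb_donors[a] - 1;
    for (int b = 0; b < hb_acceptors.nrow(); ++b) {
      int iO = hb_acceptors(b, 0) - 1, iC = hb_acceptors(b, 1) - 1;
      if (res_of_atom[iN] == res_of_atom[iO]) continue;
      if (excl.count(pkey(iN, iO))) continue;
      double d[3] = {X[iN] - X[iO], X[iN + n] - X[iO + n],
                     X[iN + 2 * n] - X[iO + 2 * n]};
      double r2 = dot3(d, d);
      if (r2 > 4.2 * 4.2 || r2 < 1e-6) continue;
      double r = std::sqrt(r2);
      double z = (r - hb_r0) / hb_sigma;
      double fd = std::exp(-z * z);
      // angle C-O-N at the acceptor
      double u[3] = {X[iC] - X[iO], X[iC + n] - X[iO + n],
                     X[iC + 2 * n] - X[iO + 2 * n]};
      double nu = std::sqrt(dot3(u, u));
      if (nu < 1e-12) continue;
      double c = dot3(u, d) / (nu * r);
      c = std::max(-1.0, std::min(1.0, c));
      double th = std::acos(c);
      double fa = 0.5 * (1.0 - c);     // 1 at linear C-O...N, 0 at 0 deg
      E_hb += -hb_strength * fd * fa;
      if (want_grad) {
        // distance part
        double dfd_dr = fd * (-2.0 * z / hb_sigma);
        double cdist = -hb_strength * fa * dfd_dr / r;
        // angle part: dfa/dc = -1/2, c = cos(th)
        double dE_dc = -hb_strength * fd * (-0.5);
        // d c / d r_N etc. for c = u.d/(|u||d|), u = C-O, d = N-O
        double invr = 1.0 / r, invu = 1.0 / nu;
        double fN[3], fC[3], fO[3];
        for (int q = 0; q < 3; ++q) {
          double dc_dN = (u[q] * invu - c * d[q] * invr) * invr;
          double dc_dC = (d[q] * invr - c * u[q] * invu) * invu;
          fN[q] = cdist * d[q] + dE_dc * dc_dN;
          fC[q] = dE_dc * dc_dC;
          fO[q] = -cdist * d[q] - dE_dc * (dc_dN + dc_dC);
        }
        addg(iN, w_hb, fN); addg(iC, w_hb, fC); addg(iO, w_hb, fO);
      }
    }
  }

  // ---- harmonic restraints ----
  for (int q = 0; q < rest_dist.nrow(); ++q) {
    int i = (int)rest_dist(q, 0) - 1, j = (int)rest_dist(q, 1) - 1;
    double d0 = rest_dist(q, 2), w = rest_dist(q, 3);
    double d[3] = {X[i] - X[j], X[i + n] - X[j + n],
                   X[i + 2 * n] - X[j + 2 * n]};
    double r = std::sqrt(dot3(d, d));
    double dev = r - d0;
    E_rd += w * dev * dev;
    if (want_grad && r > 1e-12) {
      double c = 2.0 * w * dev / r;
      double f[3] = {c * d[0], c * d[1], c * d[2]};
      addg(i, w_rd, f);
      double fm[3] = {-f[0], -f[1], -f[2]};
      addg(j, w_rd, fm);
    }
  }
  for (int q = 0; q < rest_pos.nrow(); ++q) {
    int i = (int)rest_pos(q, 0) - 1;
    double w = rest_pos(q, 4);
    double d[3] = {X[i] - rest_pos(q, 1), X[i + n] - rest_pos(q, 2),
                   X[i + 2 * n] - rest_pos(q, 3)};
    E_rp += w * dot3(d, d);
    if (want_grad) {
      double f[3] = {2.0 * w * d[0], 2.0 * w * d[1], 2.0 * w * d[2]};
      addg(i, w_rp, f);
    }
  }

  NumericVector terms = NumericVector::create(
      _["bonded"] = E_bonded, _["vdw"] = E_vdw, _["coulomb"] = E_coul,
      _["solv_polar"] = E_pol, _["solv_nonpolar"] = E_np, _["hbond"] = E_hb,
      _["restraint_distance"] = E_rd, _["restraint_position"] = E_rp);
  if (want_grad) return List::create(_["terms"] = terms, _["grad"] = grad);
  return List::create(_["terms"] = terms);
}
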