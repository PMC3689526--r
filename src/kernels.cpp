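#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Masked median filter with truncated (shrinking) boxes at the frame edges.
// Masked pixels never enter a median; a box with no usable pixel yields NA.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, LogicalMatrix mask, int box) {
  const int nr = img.nrow(), nc = img.ncol(), h = box / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(box * box);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      const int i0 = std::max(0, i - h), i1 = std::min(nr - 1, i + h);
      const int j0 = std::max(0, j - h), j1 = std::min(nc - 1, j + h);
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii)
          if (!mask(ii, jj)) buf.push_back(img(ii, jj));
      const int n = buf.size();
      if (n == 0) { out(i, j) = NA_REAL; continue; }
      const int m = n / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      double med = buf[m];
      if (n % 2 == 0) {
        // even count: mean of the two central order statistics (stats::median)
        double lo = *std::max_element(buf.begin(), buf.begin() + m);
        med = 0.5 * (lo + med);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 8-connected component labelling of above-threshold unmasked pixels, with
// per-component pixel count, summed intensity and intensity-weighted centroid.
// Coordinates are 0-based (fast = row index, slow = column index).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List label_peaks_cpp(NumericMatrix img, LogicalMatrix mask, double threshold) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> npix;
  std::vector<double> tot, cf, cs, vmax;
  std::vector<int> stack;
  int nlab = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (lab(i, j) != 0 || mask(i, j) || !(img(i, j) > threshold)) continue;
      ++nlab;
      double s = 0, sf = 0, ss = 0, mx = R_NegInf;
      int n = 0;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = nlab;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        const double v = img(pi, pj);
        s += v; sf += v * pi; ss += v * pj; ++n;
        if (v > mx) mx = v;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (lab(qi, qj) != 0 || mask(qi, qj) || !(img(qi, qj) > threshold)) continue;
            lab(qi, qj) = nlab;
            stack.push_back(qi + qj * nr);
          }
        }
      }
      npix.push_back(n); tot.push_back(s);
      // intensity-weighted centroid (components are strictly above threshold,
      // so s > 0 whenever the threshold is non-negative)
      cf.push_back(s != 0 ? sf / s : NA_REAL);
      cs.push_back(s != 0 ? ss / s : NA_REAL);
      vmax.push_back(mx);
    }
  }
  return List::create(_["labels"] = lab,
                      _["n_pixels"] = wrap(npix),
                      _["intensity"] = wrap(tot),
                      _["fast"] = wrap(cf),
                      _["slow"] = wrap(cs),
                      _["max_value"] = wrap(vmax));
}

// ---------------------------------------------------------------------------
// Direction search for the known-cell autoindexer: for each sampled direction
// the peak positions are projected onto the direction and the magnitude
// spectrum of the projected density is evaluated at real-space periodicities
// inside windows around the reference axis lengths.  Frequencies are swept
// with a per-point phase recurrence, which evaluates exactly the same
// quantity as an FFT of the binned projection at those bins.
// Returns, per (direction, window), the best length and its spectral
// magnitude (figure of merit).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List dft_search_cpp(NumericMatrix pts, NumericMatrix dirs,
                    NumericMatrix windows, double step) {
  const int np = pts.nrow(), nd = dirs.nrow(), nw = windows.nrow();
  NumericMatrix fom(nd, nw), bestL(nd, nw);
  std::vector<double> t(np);
  int nfmax = 0;
  std::vector<int> nf(nw);
  for (int w = 0; w < nw; ++w) {
    nf[w] = (int)std::floor((windows(w, 1) - windows(w, 0)) / step) + 1;
    nfmax = std::max(nfmax, nf[w]);
  }
  std::vector<double> re(nfmax), im(nfmax);
  for (int d = 0; d < nd; ++d) {
    const double dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    double tmin = R_PosInf, tmax = R_NegInf;
    for (int p = 0; p < np; ++p) {
      t[p] = pts(p, 0) * dx + pts(p, 1) * dy + pts(p, 2) * dz;
      tmin = std::min(tmin, t[p]);
      tmax = std::max(tmax, t[p]);
    }
    for (int w = 0; w < nw; ++w) {
      const double L0 = windows(w, 0);
      const int n = nf[w];
      // projections must span a few lattice periods along this direction,
      // otherwise every frequency sums coherently (DC leakage) and the
      // spectral magnitude is meaningless
      if ((tmax - tmin) * windows(w, 1) < 3.0) {
        fom(d, w) = 0.0;
        bestL(d, w) = L0;
        continue;
      }
      std::fill(re.begin(), re.begin() + n, 0.0);
      std::fill(im.begin(), im.begin() + n, 0.0);
      for (int p = 0; p < np; ++p) {
        const double a0 = 2.0 * M_PI * L0 * t[p];
        const double da = 2.0 * M_PI * step * t[p];
        double cr = std::cos(a0), ci = std::sin(a0);
        const double sr = std::cos(da), si = std::sin(da);
        for (int f = 0; f < n; ++f) {
          re[f] += cr; im[f] += ci;
          const double nr_ = cr * sr - ci * si;
          ci = cr * si + ci * sr;
          cr = nr_;
        }
      }
      double best = -1.0; int bi = 0;
      for (int f = 0; f < n; ++f) {
        const double m = re[f] * re[f] + im[f] * im[f];
        if (m > best) { best = m; bi = f; }
      }
      fom(d, w) = std::sqrt(best);
      bestL(d, w) = L0 + bi * step;
    }
  }
  return List::create(_["fom"] = fom, _["length"] = bestL);
}

// ---------------------------------------------------------------------------
// Still-diffraction excitation geometry.  Beam along +z; the Ewald sphere for
// wavenumber k is centred at -k z.  For a convergent beam the centre is
// rotated about the reciprocal-space origin by half the convergence angle in
// the plane containing z and the point's azimuth: towards the point for the
// short-wavelength limit (r_low), away for the long-wavelength limit
// (r_high).  r = k - |q - centre|, positive inside the sphere.
// ---------------------------------------------------------------------------

static inline void excitation_pair(double qx, double qy, double qz,
                                   double kmax, double kmin,
                                   double sind, double cosd,
                                   double &rlow, double &rhigh) {
  const double qr = std::sqrt(qx * qx + qy * qy);
  double du = qr - kmax * sind, dz = qz + kmax * cosd;
  rlow = kmax - std::sqrt(du * du + dz * dz);
  du = qr + kmin * sind; dz = qz + kmin * cosd;
  rhigh = kmin - std::sqrt(du * du + dz * dz);
}

static inline double sphere_cut(double q) {
  if (q <= 0) return 0.0;
  if (q >= 1) return 1.0;
  return q * q * (3.0 - 2.0 * q);
}

// Per-point excitation errors for one orientation (vectorised over points).
// [[Rcpp::export]]
NumericMatrix excitation_cpp(NumericMatrix q, double lambda,
                             double bandwidth, double convergence) {
  const int n = q.nrow();
  const double k0 = 1.0 / lambda;
  const double kmax = 1.0 / (lambda * (1.0 - 0.5 * bandwidth));
  const double kmin = 1.0 / (lambda * (1.0 + 0.5 * bandwidth));
  const double sind = std::sin(0.5 * convergence), cosd = std::cos(0.5 * convergence);
  (void)k0;
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double rl, rh;
    excitation_pair(q(i, 0), q(i, 1), q(i, 2), kmax, kmin, sind, cosd, rl, rh);
    out(i, 0) = rl; out(i, 1) = rh;
  }
  return out;
}

// ---------------------------------------------------------------------------
// One simulated still pattern: partiality, Lorentz factor and detector
// position for every lattice point with p > 0.  Columns of the result:
// index (1-based into q0), r_low, r_high, p, lorentz, x_mm, y_mm, on_det.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix pattern_obs_cpp(NumericMatrix q0, NumericMatrix rot,
                              double lambda, double bandwidth, double convergence,
                              double profile_r, double clen, double half_side) {
  const int n = q0.nrow();
  const double k0 = 1.0 / lambda;
  const double kmax = 1.0 / (lambda * (1.0 - 0.5 * bandwidth));
  const double kmin = 1.0 / (lambda * (1.0 + 0.5 * bandwidth));
  const double sind = std::sin(0.5 * convergence), cosd = std::cos(0.5 * convergence);
  const double m = profile_r + (kmax - kmin) + k0 * convergence + 1e-9;
  const double lo2 = (k0 - m) * (k0 - m), hi2 = (k0 + m) * (k0 + m);
  const double r00 = rot(0,0), r01 = rot(0,1), r02 = rot(0,2);
  const double r10 = rot(1,0), r11 = rot(1,1), r12 = rot(1,2);
  const double r20 = rot(2,0), r21 = rot(2,1), r22 = rot(2,2);
  std::vector<double> rows;
  for (int i = 0; i < n; ++i) {
    const double ax = q0(i, 0), ay = q0(i, 1), az = q0(i, 2);
    const double qx = r00 * ax + r01 * ay + r02 * az;
    const double qy = r10 * ax + r11 * ay + r12 * az;
    const double qz = r20 * ax + r21 * ay + r22 * az;
    const double zz = qz + k0;
    const double t = qx * qx + qy * qy + zz * zz;
    if (t < lo2 || t > hi2) continue;
    double rl, rh;
    excitation_pair(qx, qy, qz, kmax, kmin, sind, cosd, rl, rh);
    const double p = sphere_cut((rl + profile_r) / (2.0 * profile_r)) -
                     sphere_cut((rh + profile_r) / (2.0 * profile_r));
    if (!(p > 0.0)) continue;
    const double L = (rl - rh) / (2.0 * profile_r);
    const double w = p * 2.0 * profile_r / std::max(rl - rh, 1e-15);
    double x = NA_REAL, y = NA_REAL, on = 0.0;
    if (zz > 1e-12) {
      x = qx * clen / zz;
      y = qy * clen / zz;
      if (std::fabs(x) <= half_side && std::fabs(y) <= half_side) on = 1.0;
    }
    rows.push_back(i + 1.0); rows.push_back(rl); rows.push_back(rh);
    rows.push_back(p); rows.push_back(L); rows.push_back(w);
    rows.push_back(x); rows.push_back(y); rows.push_back(on);
  }
  const int nobs = rows.size() / 9;
  NumericMatrix out(nobs, 9);
  for (int r = 0; r < nobs; ++r)
    for (int c = 0; c < 9; ++c) out(r, c) = rows[r * 9 + c];
  colnames(out) = CharacterVector::create("index", "r_low", "r_high", "p",
                                          "lorentz", "weight", "x_mm", "y_mm",
                                          "on_detector");
  return out;
}

// ---------------------------------------------------------------------------
// Monte-Carlo convergence engine: simulates n_patterns random orientations,
// accumulates odd/even half-data-set sums per unique reflection, and reports
// R_split at each requested pattern-count checkpoint.  Uses R's RNG so a
// set.seed() call in R makes the whole run reproducible.
// rot_override (3*n x 3, optional) fixes the orientations for testing.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List rsplit_engine_cpp(NumericMatrix q0, IntegerVector asu, NumericVector Ifull,
                       double lambda, double bandwidth, double convergence,
                       double profile_r, double clen, double half_side,
                       double scale_sd, double noise_sd,
                       int n_patterns, IntegerVector checkpoints,
                       Nullable<NumericMatrix> rot_override = R_NilValue) {
  const int n = q0.nrow();
  int nuniq = 0;
  for (int i = 0; i < n; ++i) nuniq = std::max(nuniq, asu[i]);
  const double k0 = 1.0 / lambda;
  const double kmax = 1.0 / (lambda * (1.0 - 0.5 * bandwidth));
  const double kmin = 1.0 / (lambda * (1.0 + 0.5 * bandwidth));
  const double sind = std::sin(0.5 * convergence), cosd = std::cos(0.5 * convergence);
  const double m = profile_r + (kmax - kmin) + k0 * convergence + 1e-9;
  const double lo2 = (k0 - m) * (k0 - m), hi2 = (k0 + m) * (k0 + m);

  std::vector<double> sum_odd(nuniq, 0.0), sum_even(nuniq, 0.0);
  std::vector<int> cnt_odd(nuniq, 0), cnt_even(nuniq, 0);
  const int ncp = checkpoints.size();
  NumericVector cp_rs(ncp, NA_REAL);
  IntegerVector cp_nc(ncp, NA_INTEGER);
  NumericVector cp_obs(ncp, NA_REAL);
  int next_cp = 0;
  long long total_obs = 0;

  NumericMatrix rots;
  bool have_rots = false;
  if (rot_override.isNotNull()) { rots = rot_override.get(); have_rots = true; }

  for (int pat = 1; pat <= n_patterns; ++pat) {
    if (pat % 512 == 0) Rcpp::checkUserInterrupt();
    double R00,R01,R02,R10,R11,R12,R20,R21,R22;
    if (have_rots) {
      const int o = 3 * (pat - 1);
      R00=rots(o,0);   R01=rots(o,1);   R02=rots(o,2);
      R10=rots(o+1,0); R11=rots(o+1,1); R12=rots(o+1,2);
      R20=rots(o+2,0); R21=rots(o+2,1); R22=rots(o+2,2);
    } else {
      // uniform rotation from a normalised Gaussian quaternion (Haar measure)
      double qw = norm_rand(), qx = norm_rand(), qy = norm_rand(), qz = norm_rand();
      const double qn = std::sqrt(qw*qw + qx*qx + qy*qy + qz*qz);
      qw /= qn; qx /= qn; qy /= qn; qz /= qn;
      R00 = 1 - 2*(qy*qy + qz*qz); R01 = 2*(qx*qy - qz*qw); R02 = 2*(qx*qz + qy*qw);
      R10 = 2*(qx*qy + qz*qw); R11 = 1 - 2*(qx*qx + qz*qz); R12 = 2*(qy*qz - qx*qw);
      R20 = 2*(qx*qz - qy*qw); R21 = 2*(qy*qz + qx*qw); R22 = 1 - 2*(qx*qx + qy*qy);
    }
    const double scale = 1.0 + scale_sd * norm_rand();
    const bool odd = (pat % 2 == 1);
    for (int i = 0; i < n; ++i) {
      const double ax = q0(i, 0), ay = q0(i, 1), az = q0(i, 2);
      const double qx = R00 * ax + R01 * ay + R02 * az;
      const double qy = R10 * ax + R11 * ay + R12 * az;
      const double qz = R20 * ax + R21 * ay + R22 * az;
      const double zz = qz + k0;
      const double t = qx * qx + qy * qy + zz * zz;
      if (t < lo2 || t > hi2) continue;
      double rl, rh;
      excitation_pair(qx, qy, qz, kmax, kmin, sind, cosd, rl, rh);
      const double p = sphere_cut((rl + profile_r) / (2.0 * profile_r)) -
                       sphere_cut((rh + profile_r) / (2.0 * profile_r));
      if (!(p > 0.0)) continue;
      if (zz <= 1e-12) continue;
      const double x = qx * clen / zz, y = qy * clen / zz;
      if (std::fabs(x) > half_side || std::fabs(y) > half_side) continue;
      // flux-conserving weight: a flat-top spectrum spreads the pulse energy
      // over the excited slab, so the recorded partial intensity carries
      // p / Lambda with Lambda = (r_low - r_high) / (2R) the slab-to-profile
      // thickness ratio (the Lorentz factor of a still exposure)
      const double w = p * 2.0 * profile_r / std::max(rl - rh, 1e-15);
      double I = scale * w * Ifull[i];
      if (noise_sd > 0) I += noise_sd * norm_rand();
      const int u = asu[i] - 1;
      if (odd) { sum_odd[u] += I; ++cnt_odd[u]; }
      else     { sum_even[u] += I; ++cnt_even[u]; }
      ++total_obs;
    }
    while (next_cp < ncp && checkpoints[next_cp] == pat) {
      double num = 0.0, den = 0.0;
      int ncom = 0;
      for (int u = 0; u < nuniq; ++u) {
        if (cnt_odd[u] > 0 && cnt_even[u] > 0) {
          const double io = sum_odd[u] / cnt_odd[u];
          const double ie = sum_even[u] / cnt_even[u];
          num += std::fabs(ie - io);
          den += 0.5 * (ie + io);
          ++ncom;
        }
      }
      cp_rs[next_cp] = (den != 0.0) ? num / (std::sqrt(2.0) * den) : NA_REAL;
      cp_nc[next_cp] = ncom;
      cp_obs[next_cp] = (double)total_obs / pat;
      ++next_cp;
    }
  }
  return List::create(_["n_patterns"] = checkpoints,
                      _["r_split"] = cp_rs,
                      _["n_common"] = cp_nc,
                      _["mean_obs_per_pattern"] = cp_obs);
}
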