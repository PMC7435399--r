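#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// minimum-image displacement component, result in (-L/2, L/2]
static inline double mi(double d, double L) {
  return d - L * std::ceil(d / L - 0.5);
}

// Histogram of minimum-image ref->obs distances over all frames.
// coords: n_atoms x 3 x n_frames (column-major as R array), distances pm.
// ref/obs: 0-based atom indices. mol: molecule id per atom (for the
// intramolecular exclusion). Bins are half-open [r, r+dr); d == r_max falls
// outside the last bin.
// [[Rcpp::export]]
List rdf_count_kernel(NumericVector coords, IntegerVector dims,
                      IntegerVector ref, IntegerVector obs,
                      IntegerVector mol, NumericMatrix box,
                      double r_max, int n_bins, bool excl_intra) {
  const int na = dims[0], nf = dims[2];
  const double dr = r_max / n_bins;
  const double r2max = r_max * r_max;
  std::vector<double> counts(n_bins, 0.0);
  double enumerated = 0.0;  // pairs within r_max, frame-summed
  const double* c = coords.begin();
  const R_xlen_t fstride = (R_xlen_t)na * 3;
  for (int f = 0; f < nf; ++f) {
    const double Lx = box(f, 0), Ly = box(f, 1), Lz = box(f, 2);
    const double* cf = c + (R_xlen_t)f * fstride;
    for (int i = 0; i < ref.size(); ++i) {
      const int a = ref[i];
      const double ax = cf[a], ay = cf[a + na], az = cf[a + 2 * na];
      for (int j = 0; j < obs.size(); ++j) {
        const int b = obs[j];
        if (b == a) continue;
        if (excl_intra && mol[a] == mol[b]) continue;
        const double dx = mi(cf[b] - ax, Lx);
        const double dy = mi(cf[b + na] - ay, Ly);
        const double dz = mi(cf[b + 2 * na] - az, Lz);
        const double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < r2max) {
          const int bin = (int)(std::sqrt(r2) / dr);
          if (bin < n_bins) { counts[bin] += 1.0; enumerated += 1.0; }
        }
      }
    }
  }
  return List::create(_["counts"] = NumericVector(counts.begin(), counts.end()),
                      _["enumerated"] = enumerated);
}

// Hydrogen-bond occupancy scan. For every (donor-H, acceptor) candidate
// pair, test minimum-image distance <= r_cut per frame (closed ball: a pair
// exactly at the cutoff is bonded). Only pairs bonded in at least one frame
// are materialised; never-bonded candidates are counted but dropped.
// [[Rcpp::export]]
List occupancy_kernel(NumericVector coords, IntegerVector dims,
                      IntegerVector don, IntegerVector acc,
                      NumericMatrix box, double r_cut) {
  const int na = dims[0], nf = dims[2];
  const double r2cut = r_cut * r_cut;
  const double* c = coords.begin();
  const R_xlen_t fstride = (R_xlen_t)na * 3;
  std::vector<int> keep_d, keep_a;
  std::vector<std::vector<char> > rows;
  std::vector<char> h((size_t)nf);
  long long n_candidates = 0;
  for (int i = 0; i < don.size(); ++i) {
    const int d = don[i];
    for (int j = 0; j < acc.size(); ++j) {
      const int a = acc[j];
      if (a == d) continue;
      ++n_candidates;
      bool ever = false;
      for (int f = 0; f < nf; ++f) {
        const double* cf = c + (R_xlen_t)f * fstride;
        const double dx = mi(cf[a] - cf[d], box(f, 0));
        const double dy = mi(cf[a + na] - cf[d + na], box(f, 1));
        const double dz = mi(cf[a + 2 * na] - cf[d + 2 * na], box(f, 2));
        const char b = (dx * dx + dy * dy + dz * dz) <= r2cut;
        h[(size_t)f] = b;
        if (b) ever = true;
      }
      if (ever) {
        keep_d.push_back(d + 1);  // back to 1-based
        keep_a.push_back(a + 1);
        rows.push_back(h);
      }
    }
  }
  const int np = (int)rows.size();
  LogicalMatrix m(np, nf);
  for (int p = 0; p < np; ++p)
    for (int f = 0; f < nf; ++f) m(p, f) = (bool)rows[(size_t)p][(size_t)f];
  return List::create(_["donor"] = IntegerVector(keep_d.begin(), keep_d.end()),
                      _["acceptor"] = IntegerVector(keep_a.begin(), keep_a.end()),
                      _["h"] = m, _["n_candidates"] = (double)n_candidates);
}

// Mean squared displacement with sliding time origins (spacing one frame).
// pos: n_mol x 3 x n_frames unwrapped centre-of-mass positions.
// Returns sum of squared displacements and sample counts per lag 0..max_lag.
// [[Rcpp::export]]
List msd_kernel(NumericVector pos, IntegerVector dims, int max_lag) {
  const int nm = dims[0], nf = dims[2];
  std::vector<double> ssd((size_t)max_lag + 1, 0.0);
  std::vector<double> nsm((size_t)max_lag + 1, 0.0);
  const double* p = pos.begin();
  const R_xlen_t fstride = (R_xlen_t)nm * 3;
  for (int lag = 0; lag <= max_lag; ++lag) {
    double acc = 0.0;
    const int norig = nf - lag;
    for (int t0 = 0; t0 < norig; ++t0) {
      const double* a = p + (R_xlen_t)t0 * fstride;
      const double* b = p + (R_xlen_t)(t0 + lag) * fstride;
      for (int m = 0; m < nm; ++m) {
        const double dx = b[m] - a[m];
        const double dy = b[m + nm] - a[m + nm];
        const double dz = b[m + 2 * nm] - a[m + 2 * nm];
        acc += dx * dx + dy * dy + dz * dz;
      }
    }
    ssd[(size_t)lag] = acc;
    nsm[(size_t)lag] = (double)norig * nm;
  }
  return List::create(_["ssd"] = NumericVector(ssd.begin(), ssd.end()),
                      _["n"] = NumericVector(nsm.begin(), nsm.end()));
}
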