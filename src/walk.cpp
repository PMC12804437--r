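#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// splitmix64: decorrelated per-replicate seeds from one master seed
static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Uniform-grid spatial index over capture sites.  Cell size equals the
// largest interaction radius, so any site within range of a walker lies in
// the walker's cell or one of its 8 neighbours.
struct SiteIndex {
  double x0, y0, cell;
  int nx, ny;
  std::vector<std::vector<int>> bins;
  bool empty;

  SiteIndex(const NumericVector &sx, const NumericVector &sy,
            const std::vector<double> &rad,
            double xmin, double ymin, double xmax, double ymax) {
    empty = sx.size() == 0;
    if (empty) return;
    double rmax = 0.0;
    for (double r : rad) rmax = std::max(rmax, r);
    cell = std::max(rmax, 1e-6);
    x0 = xmin; y0 = ymin;
    nx = std::max(1, (int)std::ceil((xmax - xmin) / cell));
    ny = std::max(1, (int)std::ceil((ymax - ymin) / cell));
    bins.assign((size_t)nx * ny, {});
    for (int i = 0; i < sx.size(); ++i) {
      int ix = std::min(nx - 1, std::max(0, (int)std::floor((sx[i] - x0) / cell)));
      int iy = std::min(ny - 1, std::max(0, (int)std::floor((sy[i] - y0) / cell)));
      bins[ix + (size_t)nx * iy].push_back(i);
    }
  }

  // nearest site whose centre is within rad[i] of (x, y); ties -> lowest index
  int nearest(double x, double y, const NumericVector &sx, const NumericVector &sy,
              const std::vector<double> &rad, double &dist) const {
    if (empty) return -1;
    int ix = (int)std::floor((x - x0) / cell);
    int iy = (int)std::floor((y - y0) / cell);
    int best = -1;
    double bestd = R_PosInf;
    for (int dy = -1; dy <= 1; ++dy) {
      int jy = iy + dy;
      if (jy < 0 || jy >= ny) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int jx = ix + dx;
        if (jx < 0 || jx >= nx) continue;
        for (int i : bins[jx + (size_t)nx * jy]) {
          double ddx = sx[i] - x, ddy = sy[i] - y;
          double d = std::sqrt(ddx * ddx + ddy * ddy);
          if (d <= rad[i] && (d < bestd || (d == bestd && i < best))) {
            bestd = d; best = i;
          }
        }
      }
    }
    dist = bestd;
    return best;
  }
};

// [[Rcpp::export]]
List cpp_simulate(double rx, double ry, NumericVector region,
                  NumericVector sx, NumericVector sy, IntegerVector szone,
                  NumericVector sq, NumericVector sp, NumericVector sse,
                  int n_zones, double step_len, int S, int n_days,
                  int N, int reps, double seed,
                  bool hourly, bool return_positions, bool track_msd) {
  const double xmin = region[0], ymin = region[1], xmax = region[2], ymax = region[3];
  const int n_sites = sx.size();
  const int total_steps = S * n_days;
  const int nb = hourly ? total_steps : n_days;

  std::vector<double> rad(n_sites), qrad(n_sites);
  for (int i = 0; i < n_sites; ++i) {
    qrad[i] = sq[i];
    rad[i] = sq[i] + sp[i];
  }
  SiteIndex idx(sx, sy, rad, xmin, ymin, xmax, ymax);

  IntegerVector captures(nb * n_zones * reps);
  captures.attr("dim") = IntegerVector::create(nb, n_zones, reps);
  IntegerVector captured(reps), exited(reps), freew(reps);
  NumericMatrix msd(track_msd ? total_steps : 0, track_msd ? reps : 0);
  std::vector<double> pos_out; // rep, x, y triples

  uint64_t state = (uint64_t)seed;
  std::vector<double> wx(N), wy(N);
  std::vector<char> active(N);

  for (int rep = 0; rep < reps; ++rep) {
    std::mt19937_64 rng(splitmix64(state));
    std::uniform_real_distribution<double> U(0.0, 1.0);
    std::fill(wx.begin(), wx.end(), rx);
    std::fill(wy.begin(), wy.end(), ry);
    std::fill(active.begin(), active.end(), 1);
    int ncap = 0, nexit = 0;

    for (int step = 1; step <= total_steps; ++step) {
      const int bin = hourly ? (step - 1) : (step - 1) / S;
      double ssum = 0.0;
      int scount = 0;
      for (int w = 0; w < N; ++w) {
        if (!active[w]) continue;
        double x = wx[w], y = wy[w];
        bool attracted = false;
        double tx = 0.0, ty = 0.0, tdist = 0.0;
        if (n_sites > 0) {
          double d;
          int s = idx.nearest(x, y, sx, sy, rad, d);
          if (s >= 0) {
            if (U(rng) < sse[s]) {          // walker feels the site
              if (d <= qrad[s]) {           // inside the collection disk
                captures[bin + (size_t)nb * (szone[s] - 1) + (size_t)nb * n_zones * rep]++;
                active[w] = 0;
                ncap++;
                continue;
              }
              attracted = true;             // inside the attracting annulus
              tx = sx[s]; ty = sy[s]; tdist = d;
            }
          }
        }
        if (attracted) {
          if (tdist <= step_len) { x = tx; y = ty; }
          else {
            x += step_len * (tx - x) / tdist;
            y += step_len * (ty - y) / tdist;
          }
        } else {
          double th = 2.0 * M_PI * U(rng);
          x += step_len * std::cos(th);
          y += step_len * std::sin(th);
        }
        if (x < xmin || x > xmax || y < ymin || y > ymax) {
          active[w] = 0;
          nexit++;
          continue;
        }
        wx[w] = x; wy[w] = y;
        if (track_msd) {
          double dx = x - rx, dy = y - ry;
          ssum += dx * dx + dy * dy;
          scount++;
        }
      }
      if (track_msd) msd(step - 1, rep) = scount > 0 ? ssum / scount : NA_REAL;
    }
    captured[rep] = ncap;
    exited[rep] = nexit;
    freew[rep] = N - ncap - nexit;
    if (return_positions) {
      for (int w = 0; w < N; ++w) if (active[w]) {
        pos_out.push_back(rep + 1.0);
        pos_out.push_back(wx[w]);
        pos_out.push_back(wy[w]);
      }
    }
  }

  NumericMatrix positions(return_positions ? (int)(pos_out.size() / 3) : 0, 3);
  if (return_positions && !pos_out.empty()) {
    for (size_t i = 0; i < pos_out.size() / 3; ++i) {
      positions(i, 0) = pos_out[3 * i];
      positions(i, 1) = pos_out[3 * i + 1];
      positions(i, 2) = pos_out[3 * i + 2];
    }
    colnames(positions) = CharacterVector::create("rep", "x", "y");
  }

  return List::create(_["captures"] = captures,
                      _["captured"] = captured,
                      _["exited"] = exited,
                      _["free"] = freew,
                      _["msd"] = msd,
                      _["positions"] = positions);
}
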