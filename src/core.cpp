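#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Max-min path propagation for fuzzy connectedness.
//
// Affinity between 4/8-adjacent pixels c, d:
//   kappa = w1 * exp(-((I_c+I_d)/2 - mu_o)^2 / (2 sd_o^2))
//         + w2 * exp(-(I_c-I_d)^2 / (2 sd_g^2))
// Connectivity of x = max over paths seed->x of the minimum affinity along
// the path; conn(seed) = 1 (empty-path convention). Best-first (Dijkstra
// with a max-heap): pop the strongest pending pixel, relax its neighbours
// with min(conn(c), kappa(c, d)).
// [[Rcpp::export]]
NumericMatrix fc_connectivity_cpp(NumericMatrix img, int seed_r, int seed_c,
                                  int adjacency, double w1, double w2,
                                  double mu_o, double sd_o, double sd_g) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  if (seed_r < 1 || seed_r > nr || seed_c < 1 || seed_c > nc)
    stop("seed out of bounds");
  std::vector<double> conn(n, -1.0);
  std::vector<char> done(n, 0);
  const int ndir = (adjacency == 4) ? 4 : 8;
  const int drs[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dcs[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const double inv2so = 1.0 / (2.0 * sd_o * sd_o);
  const double inv2sg = 1.0 / (2.0 * sd_g * sd_g);

  typedef std::pair<double, int> node;
  std::priority_queue<node> pq;
  const int s0 = (seed_r - 1) + (seed_c - 1) * nr;
  conn[s0] = 1.0;
  pq.push(node(1.0, s0));
  while (!pq.empty()) {
    node top = pq.top(); pq.pop();
    int idx = top.second;
    if (done[idx]) continue;
    done[idx] = 1;
    const int r = idx % nr, c = idx / nr;
    const double ic = img(r, c), base = top.first;
    for (int k = 0; k < ndir; ++k) {
      const int rr = r + drs[k], cc = c + dcs[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int j = rr + cc * nr;
      if (done[j]) continue;
      const double id = img(rr, cc);
      const double m = 0.5 * (ic + id) - mu_o;
      const double g = ic - id;
      double kap = w1 * std::exp(-m * m * inv2so) +
                   w2 * std::exp(-g * g * inv2sg);
      double cand = std::min(base, kap);
      if (cand > conn[j]) {
        conn[j] = cand;
        pq.push(node(cand, j));
      }
    }
  }
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = std::max(conn[r + c * nr], 0.0);
  return out;
}

// 8-connected component of {values >= tau} containing the seed.
// [[Rcpp::export]]
IntegerMatrix seed_component_cpp(NumericMatrix values, double tau,
                                 IntegerVector seed_r, IntegerVector seed_c) {
  const int nr = values.nrow(), nc = values.ncol();
  IntegerMatrix mask(nr, nc);
  const int drs[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dcs[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  std::vector<int> stack;
  for (int s = 0; s < seed_r.size(); ++s) {
    const int r0 = seed_r[s] - 1, c0 = seed_c[s] - 1;
    if (r0 < 0 || r0 >= nr || c0 < 0 || c0 >= nc) stop("seed out of bounds");
    if (values(r0, c0) < tau || mask(r0, c0)) continue;
    mask(r0, c0) = 1;
    stack.push_back(r0 + c0 * nr);
    while (!stack.empty()) {
      const int idx = stack.back(); stack.pop_back();
      const int r = idx % nr, c = idx / nr;
      for (int k = 0; k < 8; ++k) {
        const int rr = r + drs[k], cc = c + dcs[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (mask(rr, cc) || values(rr, cc) < tau) continue;
        mask(rr, cc) = 1;
        stack.push_back(rr + cc * nr);
      }
    }
  }
  return mask;
}

// Zhang-Suen thinning: iterative boundary peeling that preserves
// connectivity, yielding a 1-pixel-wide medial-axis approximation.
// [[Rcpp::export]]
IntegerMatrix thin_cpp(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix m(clone(mask));
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return m(r, c) ? 1 : 0;
  };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      std::vector<int> del;
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!m(r, c)) continue;
          // neighbours P2..P9 clockwise from north
          int p[8] = {at(r - 1, c), at(r - 1, c + 1), at(r, c + 1),
                      at(r + 1, c + 1), at(r + 1, c), at(r + 1, c - 1),
                      at(r, c - 1), at(r - 1, c - 1)};
          int b = p[0] + p[1] + p[2] + p[3] + p[4] + p[5] + p[6] + p[7];
          if (b < 2 || b > 6) continue;
          int a = 0;
          for (int k = 0; k < 8; ++k) if (!p[k] && p[(k + 1) % 8]) ++a;
          if (a != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          del.push_back(r + c * nr);
        }
      }
      if (!del.empty()) changed = true;
      for (size_t i = 0; i < del.size(); ++i)
        m(del[i] % nr, del[i] / nr) = 0;
    }
  }
  return m;
}
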