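// Coalescent simulation of a two-population split/decline history with
// microsatellite (generalized stepwise mutation) and mitochondrial
// (HKY + invariant sites / gamma rates) markers, plus a fast summary-
// statistic kernel used when building large ABC reference tables.
//
// Conventions:
//  * times in generations, sizes in diploid effective individuals;
//  * autosomal loci: 2 lineages per diploid, coalescence rate
//    k(k-1)/2 / (2N); mitochondrial: 1 lineage per individual and
//    effective size N/4 (scale = 0.25);
//  * backward in time: sampled pops S and N with sizes (N_S, N_N) on
//    [0, t_dec), (N_S0, N_N0) on [t_dec, t_split), merging into a single
//    ancestor of size N_A at t_split. "No size change" is encoded by
//    passing N_S0 = N_S etc.
//
// A dedicated 64-bit RNG (splitmix/xorshift-free std::mt19937_64) is
// seeded per dataset so reference tables are reproducible row by row and
// chunk-parallelizable.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<double> time;
  std::vector<int> parent, left, right;
  int root;
  double total_length() const {
    double L = 0.0;
    for (size_t i = 0; i < parent.size(); ++i)
      if (parent[i] >= 0) L += time[parent[i]] - time[i];
    return L;
  }
};

// backward-in-time tree under the two-population piecewise history
Tree sim_tree(int k_s, int k_n, double nS, double nN, double nS0, double nN0,
              double nA, double t_dec, double t_split, double scale,
              std::mt19937_64 &rng) {
  const int total = k_s + k_n;
  const int nnodes = 2 * total - 1;
  Tree tr;
  tr.time.assign(nnodes, 0.0);
  tr.parent.assign(nnodes, -1);
  tr.left.assign(nnodes, -1);
  tr.right.assign(nnodes, -1);
  std::vector<int> S, N;
  S.reserve(total); N.reserve(k_n);
  for (int i = 0; i < k_s; ++i) S.push_back(i);
  for (int i = 0; i < k_n; ++i) N.push_back(k_s + i);
  int next = total;
  double t = 0.0;
  bool merged = (k_n == 0 && t_split <= 0.0);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  while ((int)(S.size() + N.size()) > 1) {
    if (!merged && t >= t_split) {
      for (int id : N) S.push_back(id);
      N.clear();
      merged = true;
    }
    double boundary;
    double curNS, curNN = 1.0;
    if (merged) {
      boundary = std::numeric_limits<double>::infinity();
      curNS = nA;
    } else if (t < t_dec) {
      boundary = t_dec;
      curNS = nS; curNN = nN;
    } else {
      boundary = t_split;
      curNS = nS0; curNN = nN0;
    }
    double rs = 0.0, rn = 0.0;
    const size_t ks = S.size(), kn = N.size();
    if (ks >= 2) rs = ks * (ks - 1) / 2.0 / (2.0 * curNS * scale);
    if (!merged && kn >= 2) rn = kn * (kn - 1) / 2.0 / (2.0 * curNN * scale);
    const double rtot = rs + rn;
    if (rtot <= 0.0) { t = boundary; continue; }
    const double w = -std::log(1.0 - U(rng)) / rtot;
    if (t + w >= boundary) { t = boundary; continue; }
    t += w;
    std::vector<int> &pool = (U(rng) * rtot < rs) ? S : N;
    const size_t k = pool.size();
    size_t i = (size_t)(U(rng) * k);
    size_t j = (size_t)(U(rng) * (k - 1));
    if (j >= i) ++j;
    if (i >= k) i = k - 1;
    if (j >= k) j = k - 1;
    const int a = pool[i], b = pool[j];
    tr.time[next] = t;
    tr.left[next] = a; tr.right[next] = b;
    tr.parent[a] = next; tr.parent[b] = next;
    // replace a with the new node, remove b
    pool[i] = next;
    pool.erase(pool.begin() + j);
    ++next;
  }
  tr.root = next - 1;
  return tr;
}

// preorder node list (root first)
std::vector<int> preorder(const Tree &tr) {
  std::vector<int> out, stack;
  stack.push_back(tr.root);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    out.push_back(v);
    if (tr.left[v] >= 0) { stack.push_back(tr.left[v]); stack.push_back(tr.right[v]); }
  }
  return out;
}

// GSM microsatellite evolution down the tree; returns tip allele sizes
std::vector<int> evolve_gsm(const Tree &tr, int ntips, double mu, double gsm_p,
                            int root_size, int size_min, int size_max,
                            std::mt19937_64 &rng, int &overflow) {
  std::vector<int> state(tr.time.size(), root_size);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  std::vector<int> order = preorder(tr);
  for (int v : order) {
    if (tr.parent[v] < 0) continue;
    const double len = tr.time[tr.parent[v]] - tr.time[v];
    int s = state[tr.parent[v]];
    std::poisson_distribution<int> P(mu * len);
    const int nmut = P(rng);
    for (int m = 0; m < nmut; ++m) {
      int step = 1;
      if (gsm_p > 0.0) {
        // geometric number of repeat units, P(k) = (1-p) p^(k-1)
        while (U(rng) < gsm_p) ++step;
      }
      if (U(rng) < 0.5) step = -step;
      s += step;
      while (s < size_min || s > size_max) {
        ++overflow;
        if (s > size_max) s = 2 * size_max - s;
        if (s < size_min) s = 2 * size_min - s;
      }
    }
    state[v] = s;
  }
  std::vector<int> tips(ntips);
  for (int i = 0; i < ntips; ++i) tips[i] = state[i];
  return tips;
}

// HKY rate structure: bases 0=A,1=C,2=G,3=T; transitions A<->G, C<->T
struct HKY {
  double q[4][4];     // normalized so sum_i pi_i sum_j q_ij = 1
  double out[4];
  double pi[4];
  HKY(const double *pi_in, double kappa) {
    for (int i = 0; i < 4; ++i) pi[i] = pi_in[i];
    double scale = 0.0;
    for (int i = 0; i < 4; ++i) {
      for (int j = 0; j < 4; ++j) {
        if (i == j) { q[i][j] = 0.0; continue; }
        const bool transition = (i + j == 2) || (i + j == 4 && i != 2 && j != 2);
        // A(0)<->G(2): i+j==2; C(1)<->T(3): i+j==4 excluding G,G
        q[i][j] = (transition ? kappa : 1.0) * pi[j];
      }
    }
    for (int i = 0; i < 4; ++i) {
      out[i] = 0.0;
      for (int j = 0; j < 4; ++j) out[i] += q[i][j];
      scale += pi[i] * out[i];
    }
    for (int i = 0; i < 4; ++i) {
      out[i] /= scale;
      for (int j = 0; j < 4; ++j) q[i][j] /= scale;
    }
  }
  int sample_base(std::mt19937_64 &rng) const {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    double u = U(rng), c = 0.0;
    for (int i = 0; i < 3; ++i) { c += pi[i]; if (u < c) return i; }
    return 3;
  }
};

// evolve one site down the tree under HKY at the given per-generation rate
void evolve_site(const Tree &tr, const std::vector<int> &order, const HKY &hky,
                 double rate, std::vector<int> &state, std::mt19937_64 &rng) {
  std::uniform_real_distribution<double> U(0.0, 1.0);
  state[tr.root] = hky.sample_base(rng);
  for (int v : order) {
    if (tr.parent[v] < 0) continue;
    double len = tr.time[tr.parent[v]] - tr.time[v];
    int b = state[tr.parent[v]];
    for (;;) {
      const double r = rate * hky.out[b];
      if (r <= 0.0) break;
      const double dt = -std::log(1.0 - U(rng)) / r;
      if (dt >= len) break;
      len -= dt;
      // choose target base proportional to q[b][j]
      double u = U(rng) * hky.out[b], c = 0.0;
      int j = 3;
      for (int jj = 0; jj < 4; ++jj) {
        if (jj == b) continue;
        c += hky.q[b][jj];
        if (u < c) { j = jj; break; }
      }
      b = j;
    }
    state[v] = b;
  }
}

}  // namespace

// [[Rcpp::export(name = ".sim_dataset_cpp")]]
List sim_dataset_cpp(int n_s, int n_n,
                     double nS, double nN, double nS0, double nN0, double nA,
                     double t_dec, double t_split,
                     int n_loci, double mu_ms, double gsm_p,
                     int size_root, int size_min, int size_max,
                     double mu_mt, double kappa, NumericVector base_freq,
                     double prop_inv, double gamma_shape,
                     int len_cytb, int len_hv1,
                     double mt_scale, int seed) {
  std::mt19937_64 rng((uint64_t)seed * 2862933555777941757ULL + 3037000493ULL);
  const int n_ind = n_s + n_n;
  int overflow = 0;

  // --- microsatellites: 2 lineages per diploid individual -----------------
  IntegerMatrix ms(n_ind, 2 * n_loci);
  NumericVector tmrca(n_loci + 1);
  for (int l = 0; l < n_loci; ++l) {
    Tree tr = sim_tree(2 * n_s, 2 * n_n, nS, nN, nS0, nN0, nA,
                       t_dec, t_split, 1.0, rng);
    tmrca[l] = tr.time[tr.root];
    std::vector<int> tips = evolve_gsm(tr, 2 * n_ind, mu_ms, gsm_p,
                                       size_root, size_min, size_max,
                                       rng, overflow);
    for (int i = 0; i < n_ind; ++i) {
      ms(i, 2 * l) = tips[2 * i];
      ms(i, 2 * l + 1) = tips[2 * i + 1];
    }
  }

  // --- mtDNA: one linked tree, partition-specific rate heterogeneity ------
  const int L = len_cytb + len_hv1;
  IntegerMatrix mt(n_ind, L);
  if (L > 0 && n_ind >= 2) {
    Tree tr = sim_tree(n_s, n_n, nS, nN, nS0, nN0, nA,
                       t_dec, t_split, mt_scale, rng);
    tmrca[n_loci] = tr.time[tr.root];
    double pi4[4] = {base_freq[0], base_freq[1], base_freq[2], base_freq[3]};
    HKY hky(pi4, kappa);
    std::vector<int> order = preorder(tr);
    std::vector<int> state(tr.time.size());
    std::uniform_real_distribution<double> U(0.0, 1.0);
    const double shp = gamma_shape > 0.0 ? gamma_shape : 1.0;
    std::gamma_distribution<double> G(shp, 1.0 / shp);
    for (int s = 0; s < L; ++s) {
      double rate;
      if (s < len_cytb) {
        // invariant-sites model: fraction prop_inv has rate 0, the rest is
        // scaled so the partition mean rate equals mu_mt
        rate = (U(rng) < prop_inv) ? 0.0 : mu_mt / (1.0 - prop_inv);
      } else {
        // gamma rate heterogeneity with mean 1
        rate = (gamma_shape > 0.0) ? mu_mt * G(rng) : mu_mt;
      }
      if (rate <= 0.0) {
        const int b = hky.sample_base(rng);
        for (int i = 0; i < n_ind; ++i) mt(i, s) = b;
        continue;
      }
      evolve_site(tr, order, hky, rate, state, rng);
      for (int i = 0; i < n_ind; ++i) mt(i, s) = state[i];
    }
  }
  return List::create(_["ms"] = ms, _["mt"] = mt, _["tmrca"] = tmrca,
                      _["overflow"] = overflow);
}

namespace {

// Weir & Cockerham (1984) multilocus theta for two populations on a
// complete (no missing data) allele-size matrix
double wc_theta2(const IntegerMatrix &ms, int n_s, int n_n, int n_loci) {
  double A = 0.0, B = 0.0, C = 0.0;
  const double r = 2.0;
  const int n_ind = n_s + n_n;
  for (int l = 0; l < n_loci; ++l) {
    // collect alleles
    std::vector<int> alleles;
    for (int i = 0; i < n_ind; ++i) {
      alleles.push_back(ms(i, 2 * l));
      alleles.push_back(ms(i, 2 * l + 1));
    }
    std::sort(alleles.begin(), alleles.end());
    alleles.erase(std::unique(alleles.begin(), alleles.end()), alleles.end());
    const double n1 = n_s, n2 = n_n;
    const double nbar = (n1 + n2) / 2.0;
    if (nbar <= 1.0) continue;
    const double nc = (r * nbar - (n1 * n1 + n2 * n2) / (r * nbar)) / (r - 1.0);
    for (int al : alleles) {
      double cnt1 = 0, cnt2 = 0, het1 = 0, het2 = 0;
      for (int i = 0; i < n_ind; ++i) {
        const int a = ms(i, 2 * l), b = ms(i, 2 * l + 1);
        const int c = (a == al) + (b == al);
        const bool h = (a != b) && c > 0;
        if (i < n_s) { cnt1 += c; het1 += h; } else { cnt2 += c; het2 += h; }
      }
      const double p1 = cnt1 / (2.0 * n1), p2 = cnt2 / (2.0 * n2);
      const double pbar = (n1 * p1 + n2 * p2) / (r * nbar);
      const double s2 = (n1 * (p1 - pbar) * (p1 - pbar) +
                         n2 * (p2 - pbar) * (p2 - pbar)) / ((r - 1.0) * nbar);
      const double hbar = (het1 + het2) / (r * nbar);
      A += nbar / nc * (s2 - 1.0 / (nbar - 1.0) *
             (pbar * (1.0 - pbar) - (r - 1.0) / r * s2 - hbar / 4.0));
      B += nbar / (nbar - 1.0) * (pbar * (1.0 - pbar) - (r - 1.0) / r * s2 -
             (2.0 * nbar - 1.0) / (4.0 * nbar) * hbar);
      C += hbar / 2.0;
    }
  }
  const double denom = A + B + C;
  return denom == 0.0 ? 0.0 : A / denom;
}

double tajima_d(double S, double pi_count, int n) {
  if (S <= 0.0 || n < 4) return 0.0;
  double a1 = 0.0, a2 = 0.0;
  for (int i = 1; i < n; ++i) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
  const double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  const double b2 = 2.0 * (n * n + n + 3.0) / (9.0 * n * (n - 1.0));
  const double c1 = b1 - 1.0 / a1;
  const double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  const double e1 = c1 / a1;
  const double e2 = c2 / (a1 * a1 + a2);
  const double V = e1 * S + e2 * S * (S - 1.0);
  if (V <= 0.0) return 0.0;
  return (pi_count - S / a1) / std::sqrt(V);
}

}  // namespace

// The 18 ABC summary statistics, fixed order (see R documentation):
//  1 nal_S   2 nal_N   3 he_S    4 he_N    5 sizevar_S  6 sizevar_N
//  7 fst_ms  8 allele_share  9 dmu2
// 10 mratio_S 11 mratio_N 12 hap_S 13 hap_N 14 pi_S 15 pi_N
// 16 tajd_S 17 tajd_N 18 dxy_mt
// [[Rcpp::export(name = ".summary_stats_cpp")]]
NumericVector summary_stats_cpp(IntegerMatrix ms, IntegerMatrix mt, int n_s) {
  const int n_ind = ms.nrow();
  const int n_n = n_ind - n_s;
  const int n_loci = ms.ncol() / 2;
  const int L = mt.ncol();
  NumericVector out(18);

  // microsatellite per-population statistics
  for (int pop = 0; pop < 2; ++pop) {
    const int from = pop == 0 ? 0 : n_s;
    const int to = pop == 0 ? n_s : n_ind;
    const int nind = to - from;
    if (nind == 0) continue;
    const double genes = 2.0 * nind;
    double nal = 0.0, he = 0.0, var = 0.0, mratio = 0.0;
    for (int l = 0; l < n_loci; ++l) {
      std::vector<int> x;
      x.reserve(2 * nind);
      for (int i = from; i < to; ++i) {
        x.push_back(ms(i, 2 * l));
        x.push_back(ms(i, 2 * l + 1));
      }
      std::vector<int> u(x);
      std::sort(u.begin(), u.end());
      u.erase(std::unique(u.begin(), u.end()), u.end());
      nal += u.size();
      double sp2 = 0.0;
      for (int al : u) {
        double c = 0;
        for (int v : x) c += (v == al);
        const double p = c / genes;
        sp2 += p * p;
      }
      if (genes > 1) he += genes / (genes - 1.0) * (1.0 - sp2);
      double m = 0.0;
      for (int v : x) m += v;
      m /= x.size();
      double vv = 0.0;
      for (int v : x) vv += (v - m) * (v - m);
      var += vv / (x.size() - 1.0);
      // Garza-Williamson M: allele count over allele-size range + 1
      mratio += (double)u.size() / (u.back() - u.front() + 1.0);
    }
    out[0 + pop] = nal / n_loci;
    out[2 + pop] = he / n_loci;
    out[4 + pop] = var / n_loci;
    out[9 + pop] = mratio / n_loci;
  }
  out[6] = wc_theta2(ms, n_s, n_n, n_loci);

  // shared-allele classification index (mean Jaccard overlap of allele
  // sets) and Goldstein's (delta mu)^2
  double share = 0.0, dmu2 = 0.0;
  for (int l = 0; l < n_loci; ++l) {
    std::vector<int> aS, aN;
    double mS = 0.0, mN = 0.0;
    for (int i = 0; i < n_ind; ++i) {
      for (int k = 0; k < 2; ++k) {
        const int v = ms(i, 2 * l + k);
        if (i < n_s) { aS.push_back(v); mS += v; } else { aN.push_back(v); mN += v; }
      }
    }
    mS /= aS.size(); mN /= aN.size();
    dmu2 += (mS - mN) * (mS - mN);
    std::sort(aS.begin(), aS.end());
    aS.erase(std::unique(aS.begin(), aS.end()), aS.end());
    std::sort(aN.begin(), aN.end());
    aN.erase(std::unique(aN.begin(), aN.end()), aN.end());
    std::vector<int> inter, uni;
    std::set_intersection(aS.begin(), aS.end(), aN.begin(), aN.end(),
                          std::back_inserter(inter));
    std::set_union(aS.begin(), aS.end(), aN.begin(), aN.end(),
                   std::back_inserter(uni));
    share += (double)inter.size() / uni.size();
  }
  out[7] = share / n_loci;
  out[8] = dmu2 / n_loci;

  // mtDNA statistics: copy sequences into contiguous rows, then derive
  // everything from one pairwise-difference matrix
  if (L > 0) {
    std::vector<signed char> seq((size_t)n_ind * L);
    const int *mp = mt.begin();  // column-major
    for (int s = 0; s < L; ++s)
      for (int i = 0; i < n_ind; ++i)
        seq[(size_t)i * L + s] = (signed char)mp[i + (size_t)n_ind * s];
    std::vector<int> dmat((size_t)n_ind * n_ind, 0);
    for (int i = 0; i < n_ind; ++i) {
      const signed char *ri = &seq[(size_t)i * L];
      for (int j = i + 1; j < n_ind; ++j) {
        const signed char *rj = &seq[(size_t)j * L];
        int d = 0;
        for (int s = 0; s < L; ++s) d += (ri[s] != rj[s]);
        dmat[(size_t)i * n_ind + j] = dmat[(size_t)j * n_ind + i] = d;
      }
    }
    for (int pop = 0; pop < 2; ++pop) {
      const int from = pop == 0 ? 0 : n_s;
      const int to = pop == 0 ? n_s : n_ind;
      const int nind = to - from;
      if (nind == 0) continue;
      // haplotypes: individuals at zero distance share one
      int nh = 0;
      for (int i = from; i < to; ++i) {
        bool seen = false;
        for (int j = from; j < i; ++j)
          if (dmat[(size_t)i * n_ind + j] == 0) { seen = true; break; }
        if (!seen) ++nh;
      }
      out[11 + pop] = nh;
      int seg = 0;
      for (int s = 0; s < L; ++s) {
        const signed char b0 = seq[(size_t)from * L + s];
        for (int i = from + 1; i < to; ++i)
          if (seq[(size_t)i * L + s] != b0) { ++seg; break; }
      }
      double pi_count = 0.0;
      int npairs = 0;
      for (int i = from; i < to; ++i)
        for (int j = i + 1; j < to; ++j) {
          pi_count += dmat[(size_t)i * n_ind + j];
          ++npairs;
        }
      if (npairs > 0) pi_count /= npairs;
      out[13 + pop] = pi_count / L;        // per-site nucleotide diversity
      out[15 + pop] = tajima_d(seg, pi_count, nind);
    }
    // between-population mean pairwise differences per site (Dxy)
    double dxy = 0.0;
    int np = 0;
    for (int i = 0; i < n_s; ++i)
      for (int j = n_s; j < n_ind; ++j) {
        dxy += dmat[(size_t)i * n_ind + j];
        ++np;
      }
    out[17] = np > 0 ? dxy / np / L : 0.0;
  }
  for (int i = 0; i < 18; ++i) if (!R_finite(out[i])) out[i] = 0.0;
  return out;
}
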