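// Forward-in-time Wright-Fisher expansion on a deme lattice.
//
// State is one haplotype store per occupied deme, diploid-major (rows
// 2i, 2i+1 belong to individual i).  Each generation applies, in order:
// stochastic logistic growth + WF resampling with Poisson recombination
// on the cM map, symmetric haplotype exchange with occupied 4-neighbours,
// and colonization of empty habitable neighbours by F founder haplotypes
// once the source census exceeds threshold*K.  All randomness comes from
// R's RNG so set.seed() in R gives bitwise reproducibility.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<unsigned char> Hap;
typedef std::vector<Hap> Deme;

struct ChromSpan {
  int from, to;       // inclusive SNP index range
  double cm0, cm1;    // cM bounds
  double morgans;     // map length
};

static inline int runif_int(int n) {
  // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// Meiosis: recombine haplotypes a and b into out, independent start
// parent and Poisson(number of Morgans) crossovers per chromosome.
static void gamete(const Hap &a, const Hap &b,
                   const std::vector<ChromSpan> &chr,
                   const double *cm, Hap &out) {
  for (size_t ci = 0; ci < chr.size(); ci++) {
    const ChromSpan &c = chr[ci];
    const Hap *cur = (unif_rand() < 0.5) ? &a : &b;
    int k = (int)R::rpois(c.morgans);
    if (k == 0) {
      std::copy(cur->begin() + c.from, cur->begin() + c.to + 1,
                out.begin() + c.from);
      continue;
    }
    std::vector<double> cx(k);
    for (int i = 0; i < k; i++)
      cx[i] = c.cm0 + unif_rand() * (c.cm1 - c.cm0);
    std::sort(cx.begin(), cx.end());
    int seg = c.from;
    for (int i = 0; i < k; i++) {
      const double *hit = std::upper_bound(cm + c.from, cm + c.to + 1, cx[i]);
      int brk = (int)(hit - cm);
      if (brk > seg)
        std::copy(cur->begin() + seg, cur->begin() + brk, out.begin() + seg);
      seg = brk;
      cur = (cur == &a) ? &b : &a;
    }
    if (c.to + 1 > seg)
      std::copy(cur->begin() + seg, cur->begin() + c.to + 1,
                out.begin() + seg);
  }
}

// [[Rcpp::export]]
List sim_expansion_cpp(LogicalVector habitable, IntegerVector K,
                       int width, int height, int origin,
                       double r, double m, int F, double thresh,
                       NumericVector pos_cM, IntegerVector chrom_id,
                       NumericVector init_freqs, int generations,
                       bool full_occupancy) {
  RNGScope scope;
  const int ncell = width * height;
  const int L = pos_cM.size();
  const double *cm = REAL(pos_cM);

  std::vector<ChromSpan> chr;
  for (int i = 0; i < L;) {
    int j = i;
    while (j + 1 < L && chrom_id[j + 1] == chrom_id[i]) j++;
    ChromSpan c;
    c.from = i; c.to = j; c.cm0 = pos_cM[i]; c.cm1 = pos_cM[j];
    c.morgans = (c.cm1 - c.cm0) / 100.0;
    chr.push_back(c);
    i = j + 1;
  }

  std::vector<Deme> pop(ncell);
  std::vector<int> census(ncell, 0);
  std::vector<int> arrival(ncell, -1);
  std::vector<int> e_par, e_chi, e_gen;

  for (int c = 0; c < ncell; c++) {
    bool seed_cell = full_occupancy ? (habitable[c] && K[c] > 0)
                                    : (c == origin - 1);
    if (!seed_cell) continue;
    int n = K[c];
    pop[c].assign(2 * n, Hap(L));
    for (int h = 0; h < 2 * n; h++)
      for (int l = 0; l < L; l++)
        pop[c][h][l] = (unif_rand() < init_freqs[l]) ? 1 : 0;
    census[c] = n;
    arrival[c] = 0;
  }

  for (int g = 1; g <= generations; g++) {
    // growth + WF resampling with recombination
    for (int c = 0; c < ncell; c++) {
      int N = census[c];
      if (N == 0) continue;
      int Kc = K[c];
      double mu = N + r * N * (1.0 - (double)N / Kc);
      double p = mu / Kc;
      if (p > 1.0) p = 1.0;
      int Nn = (int)R::rbinom((double)Kc, p);
      if (Nn < 1) Nn = 1;
      Deme next(2 * Nn, Hap(L));
      for (int i = 0; i < Nn; i++) {
        int p1 = runif_int(N), p2 = runif_int(N);
        gamete(pop[c][2 * p1], pop[c][2 * p1 + 1], chr, cm, next[2 * i]);
        gamete(pop[c][2 * p2], pop[c][2 * p2 + 1], chr, cm, next[2 * i + 1]);
      }
      pop[c].swap(next);
      census[c] = Nn;
    }

    // symmetric migration: each unordered neighbour pair handled once
    if (m > 0) {
      for (int row = 1; row <= height; row++) {
        for (int col = 1; col <= width; col++) {
          int c = (row - 1) * width + col - 1;
          if (census[c] == 0) continue;
          int nb[2];
          nb[0] = (col < width) ? c + 1 : -1;
          nb[1] = (row < height) ? c + width : -1;
          for (int q = 0; q < 2; q++) {
            int d = nb[q];
            if (d < 0 || census[d] == 0) continue;
            int cap = std::min(2 * census[c], 2 * census[d]);
            int nm = (int)R::rbinom((double)cap, m);
            for (int t = 0; t < nm; t++) {
              int hi = runif_int(2 * census[c]);
              int hj = runif_int(2 * census[d]);
              pop[c][hi].swap(pop[d][hj]);
            }
          }
        }
      }
    }

    // colonization by budding founders
    std::vector<int> occ;
    for (int c = 0; c < ncell; c++)
      if (census[c] > 0) occ.push_back(c);
    for (size_t oi = 0; oi < occ.size(); oi++) {
      int c = occ[oi];
      if ((double)census[c] <= thresh * K[c]) continue;
      int row = c / width + 1, col = c % width + 1;
      int nbs[4];
      nbs[0] = (row > 1) ? c - width : -1;
      nbs[1] = (row < height) ? c + width : -1;
      nbs[2] = (col > 1) ? c - 1 : -1;
      nbs[3] = (col < width) ? c + 1 : -1;
      for (int q = 0; q < 4; q++) {
        int d = nbs[q];
        if (d < 0 || !habitable[d] || census[d] > 0 || K[d] < 1) continue;
        int S = 2 * census[c];
        int Fd = std::min(F, S);
        if (Fd % 2) Fd--;
        if (Fd < 2) continue;
        std::vector<int> idx(S);
        for (int i = 0; i < S; i++) idx[i] = i;
        for (int i = 0; i < Fd; i++) {
          int j = i + runif_int(S - i);
          std::swap(idx[i], idx[j]);
        }
        Deme founders(Fd);
        for (int i = 0; i < Fd; i++) founders[i] = pop[c][idx[i]];
        pop[d].swap(founders);
        census[d] = Fd / 2;
        arrival[d] = g;
        e_par.push_back(c + 1);
        e_chi.push_back(d + 1);
        e_gen.push_back(g);
      }
    }
  }

  int tot = 0;
  std::vector<int> occf;
  for (int c = 0; c < ncell; c++)
    if (census[c] > 0) { occf.push_back(c); tot += 2 * census[c]; }
  IntegerMatrix H(tot, L);
  IntegerVector deme_of(tot);
  int rrow = 0;
  for (size_t oi = 0; oi < occf.size(); oi++) {
    int c = occf[oi];
    for (size_t h = 0; h < pop[c].size(); h++) {
      for (int l = 0; l < L; l++) H(rrow, l) = pop[c][h][l];
      deme_of[rrow] = c + 1;
      rrow++;
    }
  }

  IntegerVector arr(ncell), cen(ncell);
  for (int c = 0; c < ncell; c++) { arr[c] = arrival[c]; cen[c] = census[c]; }

  return List::create(
      _["arrival"] = arr, _["census"] = cen,
      _["edge_parent"] = wrap(e_par), _["edge_child"] = wrap(e_chi),
      _["edge_generation"] = wrap(e_gen),
      _["haplotypes"] = H, _["deme_of"] = deme_of);
}
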