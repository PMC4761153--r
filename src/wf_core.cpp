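#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>

using namespace Rcpp;

// Forward Wright-Fisher core for one replicate locus.
//
// Haplotypes are grouped into classes sharing an identical mutation set;
// reproduction is a multinomial draw over classes with weights
// count * fitness, i.e. genic (semidominant, h = 1/2) selection in which a
// haplotype carrying mutations {j} has fitness prod_j (1 - s_j / 2) and
// diploid fitness is the product over the two haplotypes. Sites are
// infinite-sites on a finite grid of L positions: a new mutation redraws its
// position while it collides with a currently segregating one. No
// recombination within the locus.

namespace {

struct HapClass {
  int count;
  double w;
  std::vector<int> muts;  // sorted mutation ids
};

struct MutInfo {
  int site;
  double s;       // selection coefficient (rescaled), 0 for neutral
  bool neutral;
  bool dead;      // lost or fixed and removed
};

double class_fitness(const std::vector<int>& muts,
                     const std::vector<MutInfo>& reg) {
  double w = 1.0;
  for (int id : muts) w *= 1.0 - 0.5 * reg[id].s;
  return w;
}

// remove lost and fixed mutations; drop empty classes
void cleanup(std::vector<HapClass>& pop, std::vector<MutInfo>& reg,
             std::vector<char>& occupied, long& fixed_neutral,
             long& fixed_selected) {
  long P = 0;
  std::unordered_map<int, long> tot;
  for (const HapClass& h : pop) {
    if (h.count == 0) continue;
    P += h.count;
    for (int id : h.muts) tot[id] += h.count;
  }
  std::vector<char> fixed(reg.size(), 0);
  bool any_fixed = false;
  for (auto& kv : tot) {
    if (kv.second == P) {
      fixed[kv.first] = 1;
      any_fixed = true;
      if (reg[kv.first].neutral) ++fixed_neutral; else ++fixed_selected;
      occupied[reg[kv.first].site] = 0;
      reg[kv.first].dead = true;
    }
  }
  // mutations absent from tot were lost
  for (size_t id = 0; id < reg.size(); ++id) {
    if (!reg[id].dead && tot.find((int)id) == tot.end()) {
      occupied[reg[id].site] = 0;
      reg[id].dead = true;
    }
  }
  std::vector<HapClass> keep;
  keep.reserve(pop.size());
  for (HapClass& h : pop) {
    if (h.count == 0) continue;
    if (any_fixed) {
      std::vector<int> m2;
      m2.reserve(h.muts.size());
      for (int id : h.muts) if (!fixed[id]) m2.push_back(id);
      h.muts.swap(m2);
      h.w = class_fitness(h.muts, reg);
    }
    keep.push_back(std::move(h));
  }
  pop.swap(keep);
}

} // namespace

// [[Rcpp::export(name = ".wf_simulate_locus")]]
List wf_simulate_locus(int L, double mu,
                       IntegerVector phase_gens,
                       NumericVector phase_startN,
                       NumericVector phase_endN,
                       IntegerVector phase_expo,   // 1 = exponential
                       double dfe_shape, double mean_s,
                       double neutral_fraction,
                       IntegerVector sample_sizes) {
  const int nphase = phase_gens.size();
  const int nsz = sample_sizes.size();
  const int nmax = max(sample_sizes);

  std::vector<HapClass> pop(1);
  std::vector<MutInfo> reg;
  std::vector<char> occupied(L, 0);
  long fixed_neutral = 0, fixed_selected = 0, n_capped = 0, n_mut = 0;

  int N0 = (int)std::max(1.0, std::floor(phase_startN[0] + 0.5));
  pop[0].count = 2 * N0;
  pop[0].w = 1.0;

  std::vector<double> prob;
  std::vector<int> draw;
  int gen_since_cleanup = 0;

  for (int ph = 0; ph < nphase; ++ph) {
    const int G = phase_gens[ph];
    const double Ns = phase_startN[ph], Ne = phase_endN[ph];
    const double r = phase_expo[ph] ? std::log(Ne / Ns) / G : 0.0;
    for (int g = 1; g <= G; ++g) {
      double Nt = phase_expo[ph] ? Ns * std::exp(r * g) : Ne;
      int N2 = 2 * (int)std::max(1.0, std::floor(Nt + 0.5));

      // multinomial reproduction over classes
      const int K = pop.size();
      prob.resize(K);
      draw.resize(K);
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        prob[k] = (double)pop[k].count * pop[k].w;
        tot += prob[k];
      }
      for (int k = 0; k < K; ++k) prob[k] /= tot;
      rmultinom(N2, prob.data(), K, draw.data());
      for (int k = 0; k < K; ++k) pop[k].count = draw[k];

      // new mutations
      int M = (int)R::rpois((double)N2 * mu * (double)L);
      for (int m = 0; m < M; ++m) {
        // pick a carrier haplotype uniformly
        double u = unif_rand() * N2;
        int k = 0;
        double acc = pop[0].count;
        while (acc < u && k + 1 < (int)pop.size()) acc += pop[++k].count;
        if (pop[k].count == 0) continue;  // numerical edge
        // free site (redraw on collision with a segregating site)
        int site = -1;
        for (int tries = 0; tries < 20 * L; ++tries) {
          int cand = (int)(unif_rand() * L);
          if (cand >= L) cand = L - 1;
          if (!occupied[cand]) { site = cand; break; }
        }
        if (site < 0) continue;  // locus saturated; drop mutation
        MutInfo mi;
        mi.site = site;
        mi.neutral = (neutral_fraction >= 1.0) ||
          (neutral_fraction > 0.0 && unif_rand() < neutral_fraction);
        if (mi.neutral) {
          mi.s = 0.0;
        } else {
          double s = R::rgamma(dfe_shape, mean_s / dfe_shape);
          if (s > 1.0) { s = 1.0; ++n_capped; }
          mi.s = s;
        }
        mi.dead = false;
        occupied[site] = 1;
        int id = reg.size();
        reg.push_back(mi);
        ++n_mut;
        HapClass nh;
        nh.count = 1;
        nh.muts = pop[k].muts;
        nh.muts.push_back(id);
        nh.w = pop[k].w * (1.0 - 0.5 * mi.s);
        pop[k].count -= 1;
        pop.push_back(std::move(nh));
      }

      if (++gen_since_cleanup >= 32) {
        cleanup(pop, reg, occupied, fixed_neutral, fixed_selected);
        gen_since_cleanup = 0;
      }
    }
  }
  cleanup(pop, reg, occupied, fixed_neutral, fixed_selected);

  // ---- sample nmax haplotypes without replacement; nested subsamples are
  // prefixes of the shuffled draw
  long P = 0;
  for (const HapClass& h : pop) P += h.count;
  std::vector<int> expand;
  expand.reserve(P);
  for (size_t k = 0; k < pop.size(); ++k)
    for (int c = 0; c < pop[k].count; ++c) expand.push_back((int)k);
  if (nmax > (int)P) stop("sample size exceeds population");
  for (int i = 0; i < nmax; ++i) {  // partial Fisher-Yates
    int j = i + (int)(unif_rand() * (P - i));
    if (j >= (int)P) j = P - 1;
    std::swap(expand[i], expand[j]);
  }

  // per segregating mutation, allele count within each nested subsample
  std::vector<int> sorted_idx(nsz);
  IntegerVector szs = clone(sample_sizes);
  std::sort(szs.begin(), szs.end());
  std::unordered_map<int, std::vector<int>> cnt;
  for (int i = 0; i < nmax; ++i) {
    const HapClass& h = pop[expand[i]];
    for (int id : h.muts) {
      auto& v = cnt[id];
      if (v.empty()) v.assign(nsz, 0);
      // smallest sample size that includes haplotype index i
      for (int j = 0; j < nsz; ++j) if (szs[j] > i) { v[j] += 1; break; }
    }
  }

  // fold into SFS per sample size and site class (0 neutral, 1 selected)
  List out(nsz);
  for (int j = 0; j < nsz; ++j) {
    int n = szs[j];
    IntegerVector sfsN(n / 2), sfsS(n / 2);
    out[j] = List::create(Named("n") = n, Named("neutral") = sfsN,
                          Named("selected") = sfsS);
  }
  for (auto& kv : cnt) {
    int ac = 0;
    for (int j = 0; j < nsz; ++j) {
      ac += kv.second[j];  // prefix sums: count within szs[j]
      int n = szs[j];
      if (ac <= 0 || ac >= n) continue;
      int m = ac < n - ac ? ac : n - ac;
      List rec = out[j];
      if (reg[kv.first].neutral) {
        IntegerVector v = rec["neutral"];
        v[m - 1] += 1;
      } else {
        IntegerVector v = rec["selected"];
        v[m - 1] += 1;
      }
    }
  }

  return List::create(Named("sfs") = out,
                      Named("n_mutations") = (double)n_mut,
                      Named("n_capped") = (double)n_capped,
                      Named("fixed_neutral") = (double)fixed_neutral,
                      Named("fixed_selected") = (double)fixed_selected);
}
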