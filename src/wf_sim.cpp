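#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Forward Wright-Fisher simulator on a finite chromosome.
//
// Each haplotype is a sorted vector of integer positions (1-based bp)
// carrying the derived allele. Mutation is infinite-sites on the integer
// grid (collisions with any previously used position are redrawn);
// recombination places Poisson(rec*L) crossovers per meiosis, uniform on
// the chromosome. Selection is additive at a single sweep site: diploid
// fitness 1, 1+s, 1+2s for 0/1/2 copies of the beneficial allele.
//
// Uses R's RNG throughout so set.seed() in R fixes the full trajectory.

typedef std::vector<int> Hap;

static inline int runif_pos(double L) {
  int pos = 1 + (int)(unif_rand() * L);
  if (pos > (int)L) pos = (int)L;
  return pos;
}

static inline bool carries(const Hap &h, int pos) {
  return std::binary_search(h.begin(), h.end(), pos);
}

// recombinant gamete from the two haplotypes of one diploid parent
static Hap make_gamete(const Hap &h1, const Hap &h2, double rec, double L) {
  int nx = (int)R::rpois(rec * L);
  bool first = unif_rand() < 0.5;
  if (nx == 0) return first ? h1 : h2;
  std::vector<double> bps(nx);
  for (int i = 0; i < nx; ++i) bps[i] = unif_rand() * L;
  std::sort(bps.begin(), bps.end());
  bps.push_back(L + 1.0);  // terminal segment

  Hap out;
  out.reserve(std::max(h1.size(), h2.size()));
  double prev = 0.0;
  bool cur = first;
  for (size_t i = 0; i < bps.size(); ++i) {
    const Hap &src = cur ? h1 : h2;
    Hap::const_iterator lo =
        std::lower_bound(src.begin(), src.end(), (int)std::ceil(prev));
    // positions p with prev <= p < bps[i]  (positions are integers >= 1)
    for (Hap::const_iterator it = lo; it != src.end() && *it < bps[i]; ++it)
      out.push_back(*it);
    prev = bps[i];
    cur = !cur;
  }
  return out;
}

static void add_mutations(Hap &h, double mu, double L,
                          std::unordered_set<int> &used) {
  int nm = (int)R::rpois(mu * L);
  for (int i = 0; i < nm; ++i) {
    int pos = runif_pos(L);
    int tries = 0;
    while (used.count(pos) && tries < 1000) { pos = runif_pos(L); ++tries; }
    if (used.count(pos)) continue;  // grid effectively saturated
    used.insert(pos);
    h.insert(std::lower_bound(h.begin(), h.end(), pos), pos);
  }
}

// drop positions fixed in the whole population (they are no longer
// segregating and only bloat the per-haplotype vectors)
static void drop_fixed(std::vector<Hap> &pop) {
  size_t n = pop.size();
  std::unordered_map<int, size_t> cnt;
  for (size_t i = 0; i < n; ++i)
    for (size_t j = 0; j < pop[i].size(); ++j) cnt[pop[i][j]]++;
  std::unordered_set<int> fixed;
  for (std::unordered_map<int, size_t>::iterator it = cnt.begin();
       it != cnt.end(); ++it)
    if (it->second == n) fixed.insert(it->first);
  if (fixed.empty()) return;
  for (size_t i = 0; i < n; ++i) {
    Hap keep;
    keep.reserve(pop[i].size());
    for (size_t j = 0; j < pop[i].size(); ++j)
      if (!fixed.count(pop[i][j])) keep.push_back(pop[i][j]);
    pop[i].swap(keep);
  }
}

// one generation; fitness weights w over diploids (empty => neutral)
static void next_generation(std::vector<Hap> &pop, double mu, double rec,
                            double L, const std::vector<double> &w,
                            std::unordered_set<int> &used) {
  size_t nhap = pop.size();
  size_t ndip = nhap / 2;
  std::vector<double> cw;
  double tot = 0.0;
  if (!w.empty()) {
    cw.resize(ndip);
    for (size_t d = 0; d < ndip; ++d) { tot += w[d]; cw[d] = tot; }
  }
  std::vector<Hap> next(nhap);
  for (size_t i = 0; i < nhap; ++i) {
    size_t d;
    if (w.empty()) {
      d = (size_t)(unif_rand() * ndip);
      if (d >= ndip) d = ndip - 1;
    } else {
      double u = unif_rand() * tot;
      d = std::lower_bound(cw.begin(), cw.end(), u) - cw.begin();
      if (d >= ndip) d = ndip - 1;
    }
    next[i] = make_gamete(pop[2 * d], pop[2 * d + 1], rec, L);
    add_mutations(next[i], mu, L, used);
  }
  pop.swap(next);
}

static int count_allele(const std::vector<Hap> &pop, int pos) {
  int c = 0;
  for (size_t i = 0; i < pop.size(); ++i)
    if (carries(pop[i], pos)) ++c;
  return c;
}

// [[Rcpp::export]]
List wf_simulate_cpp(int n_diploid, double chrom_length, double mu, double rec,
                     double s, int sweep_pos, int burnin_gen, int max_sweep_gen,
                     int retry_cap, int sample_diploids) {
  double L = chrom_length;
  int nhap = 2 * n_diploid;
  std::vector<Hap> pop(nhap);
  std::unordered_set<int> used;
  used.insert(sweep_pos);  // reserve the sweep site for the beneficial allele

  std::vector<double> neutral;  // empty => uniform parent choice

  for (int g = 0; g < burnin_gen; ++g) {
    next_generation(pop, mu, rec, L, neutral, used);
    if (g % 25 == 24) drop_fixed(pop);
  }
  drop_fixed(pop);

  int retries = 0, sweep_generations = 0;
  bool fixed_ok = true;
  if (s > 0.0) {
    fixed_ok = false;
    std::vector<Hap> saved = pop;  // state at allele introduction
    for (int attempt = 0; attempt <= retry_cap && !fixed_ok; ++attempt) {
      if (attempt > 0) { pop = saved; ++retries; }
      // introduce the beneficial allele on one random haplotype
      int h0 = (int)(unif_rand() * nhap);
      if (h0 >= nhap) h0 = nhap - 1;
      pop[h0].insert(
          std::lower_bound(pop[h0].begin(), pop[h0].end(), sweep_pos),
          sweep_pos);
      int g = 0;
      while (g < max_sweep_gen) {
        std::vector<double> w((size_t)n_diploid);
        for (int d = 0; d < n_diploid; ++d) {
          int cnt = (carries(pop[2 * d], sweep_pos) ? 1 : 0) +
                    (carries(pop[2 * d + 1], sweep_pos) ? 1 : 0);
          w[d] = 1.0 + s * cnt;
        }
        next_generation(pop, mu, rec, L, w, used);
        ++g;
        int c = count_allele(pop, sweep_pos);
        if (c == 0) break;               // lost: retry
        if (c == nhap) { fixed_ok = true; break; }
        if (g % 25 == 24) drop_fixed(pop);
      }
      sweep_generations = g;
    }
    if (!fixed_ok)
      stop("beneficial allele was lost in every attempt (retry cap %d)",
           retry_cap);
  }

  // sample diploids without replacement
  if (sample_diploids > n_diploid) sample_diploids = n_diploid;
  std::vector<int> idx(n_diploid);
  for (int i = 0; i < n_diploid; ++i) idx[i] = i;
  for (int i = 0; i < sample_diploids; ++i) {
    int j = i + (int)(unif_rand() * (n_diploid - i));
    if (j >= n_diploid) j = n_diploid - 1;
    std::swap(idx[i], idx[j]);
  }

  int ns = 2 * sample_diploids;
  std::vector<const Hap *> smp(ns);
  for (int i = 0; i < sample_diploids; ++i) {
    smp[2 * i] = &pop[2 * idx[i]];
    smp[2 * i + 1] = &pop[2 * idx[i] + 1];
  }

  // segregating positions within the sample
  std::unordered_map<int, int> cnt;
  for (int i = 0; i < ns; ++i)
    for (size_t j = 0; j < smp[i]->size(); ++j) cnt[(*smp[i])[j]]++;
  std::vector<int> segpos;
  for (std::unordered_map<int, int>::iterator it = cnt.begin();
       it != cnt.end(); ++it)
    if (it->second > 0 && it->second < ns) segpos.push_back(it->first);
  std::sort(segpos.begin(), segpos.end());

  IntegerMatrix alleles(ns, (int)segpos.size());
  for (int i = 0; i < ns; ++i)
    for (size_t j = 0; j < segpos.size(); ++j)
      alleles(i, (int)j) = carries(*smp[i], segpos[j]) ? 1 : 0;

  return List::create(_["positions"] = wrap(segpos),
                      _["alleles"] = alleles,
                      _["retries"] = retries,
                      _["sweep_generations"] = sweep_generations);
}
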