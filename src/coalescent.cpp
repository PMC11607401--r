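// Structured-coalescent engine with instantaneous introgression pulses.
//
// Time runs backward from the present in generations. Between demographic
// events the process is a continuous-time coalescent: within a population of
// (already ploidy-scaled) size Ne each lineage pair coalesces at rate
// 1/(2 Ne) per generation. Events (sorted by time):
//   type 0  pulse(source a, dest b, phi x): each lineage in b moves to a
//           independently with probability x
//   type 1  split(derived a, ancestral b): all lineages in a move to b
//   type 2  ne-change(pop a, new size x)
// Uses R's RNG (unif_rand/exp_rand/rpois) so set.seed() governs everything.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> parent;     // length 2n-1, root -> -1
  std::vector<double> time;    // node times (leaves at 0)
};

// one genealogy; lin_pop0 are 0-based population indices per lineage
Tree sim_one_tree(const std::vector<int>& lin_pop0,
                  const std::vector<double>& ne_init,
                  const NumericMatrix& events) {
  const int n = lin_pop0.size();
  const int n_pops = ne_init.size();
  const int n_ev = events.nrow();
  std::vector<double> ne(ne_init);
  std::vector<int> active(n);       // node ids of live lineages
  std::vector<int> pop(2 * n - 1);  // population of each live node
  Tree tr;
  tr.parent.assign(2 * n - 1, -1);
  tr.time.assign(2 * n - 1, 0.0);
  for (int i = 0; i < n; ++i) { active[i] = i; pop[i] = lin_pop0[i]; }
  int n_active = n, next_node = n, ev = 0;
  double t = 0.0;
  std::vector<int> count(n_pops);
  std::vector<double> rate(n_pops);

  while (n_active > 1) {
    std::fill(count.begin(), count.end(), 0);
    for (int i = 0; i < n_active; ++i) ++count[pop[active[i]]];
    double total = 0.0;
    for (int p = 0; p < n_pops; ++p) {
      rate[p] = count[p] >= 2
        ? 0.5 * count[p] * (count[p] - 1) / (2.0 * ne[p]) : 0.0;
      total += rate[p];
    }
    double t_ev = ev < n_ev ? events(ev, 0) : R_PosInf;
    double wait = total > 0 ? exp_rand() / total : R_PosInf;
    if (t + wait < t_ev) {
      t += wait;
      // choose population proportional to rate, then a uniform pair
      double u = unif_rand() * total;
      int p = -1;
      for (int q = 0; q < n_pops; ++q) {
        if (rate[q] <= 0.0) continue;
        p = q;                       // falls through to the last positive
        if (u < rate[q]) break;      // rate on fp underflow of u
        u -= rate[q];
      }
      int k = count[p];
      int i1 = (int)(unif_rand() * k); if (i1 >= k) i1 = k - 1;
      int i2 = (int)(unif_rand() * (k - 1)); if (i2 >= k - 1) i2 = k - 2;
      if (i2 >= i1) ++i2;
      // map within-pop indices to positions in `active`
      int a1 = -1, a2 = -1, seen = 0;
      for (int i = 0; i < n_active; ++i) {
        if (pop[active[i]] == p) {
          if (seen == i1) a1 = i;
          if (seen == i2) a2 = i;
          ++seen;
        }
      }
      int node = next_node++;
      tr.time[node] = t;
      tr.parent[active[a1]] = node;
      tr.parent[active[a2]] = node;
      pop[node] = p;
      // replace a1 with the new node, drop a2
      active[a1] = node;
      active[a2] = active[n_active - 1];
      --n_active;
    } else {
      if (!R_FINITE(t_ev))
        stop("no common ancestor reachable: model leaves disconnected populations");
      t = t_ev;
      int type = (int)events(ev, 1);
      int a = (int)events(ev, 2), b = (int)events(ev, 3);
      double x = events(ev, 4);
      if (type == 0) {
        for (int i = 0; i < n_active; ++i)
          if (pop[active[i]] == b && unif_rand() < x) pop[active[i]] = a;
      } else if (type == 1) {
        for (int i = 0; i < n_active; ++i)
          if (pop[active[i]] == a) pop[active[i]] = b;
      } else {
        ne[a] = x;
      }
      ++ev;
    }
  }
  return tr;
}

// leaf lists under every node (leaves are 0..n-1)
void leaf_sets(const Tree& tr, int n, std::vector<std::vector<int> >& out) {
  int m = 2 * n - 1;
  out.assign(m, std::vector<int>());
  // nodes are created in increasing time order, so children precede parents
  for (int i = 0; i < n; ++i) out[i].push_back(i);
  for (int i = 0; i < m; ++i) {
    int p = tr.parent[i];
    if (p >= 0)
      out[p].insert(out[p].end(), out[i].begin(), out[i].end());
  }
}

} // namespace

// [[Rcpp::export(name = ".simTreesCpp")]]
List sim_trees_cpp(int n_sims, IntegerVector lin_pop0, NumericVector ne0,
                   NumericMatrix events) {
  const int n = lin_pop0.size();
  if (n < 2) stop("need at least two lineages");
  std::vector<int> lp(lin_pop0.begin(), lin_pop0.end());
  std::vector<double> ne(ne0.begin(), ne0.end());
  IntegerMatrix parent(2 * n - 1, n_sims);
  NumericMatrix time(2 * n - 1, n_sims);
  RNGScope scope;
  for (int s = 0; s < n_sims; ++s) {
    Tree tr = sim_one_tree(lp, ne, events);
    for (int i = 0; i < 2 * n - 1; ++i) {
      parent(i, s) = tr.parent[i];
      time(i, s) = tr.time[i];
    }
  }
  return List::create(_["parent"] = parent, _["time"] = time);
}

// Simulate n_loci genealogies and accumulate frequency-weighted ABBA/BABA
// sums per locus without materializing site patterns. test_pop maps each
// lineage to -1 (unused) or 0..3 for (P1, P2, P3, outgroup); derived-allele
// frequencies are lineage means. Sites where the outgroup is polymorphic
// are skipped; outgroup-derived sites are polarized by flipping. Draw order
// matches sim_patterns_cpp exactly, so the two paths agree site-for-site
// under the same seed.
// [[Rcpp::export(name = ".abbaLociCpp")]]
List abba_loci_cpp(int n_loci, IntegerVector lin_pop0, NumericVector ne0,
                   NumericMatrix events, double mu_len,
                   IntegerVector test_pop) {
  const int n = lin_pop0.size();
  if (n < 2) stop("need at least two lineages");
  std::vector<int> lp(lin_pop0.begin(), lin_pop0.end());
  std::vector<double> ne(ne0.begin(), ne0.end());
  double cnt[4] = {0, 0, 0, 0};
  for (int i = 0; i < n; ++i)
    if (test_pop[i] >= 0) cnt[test_pop[i]] += 1.0;
  for (int g = 0; g < 4; ++g)
    if (cnt[g] == 0) stop("every test population needs sampled lineages");
  NumericVector abba(n_loci), baba(n_loci);
  IntegerVector used(n_loci), skipped(n_loci);
  const int m = 2 * n - 1;
  std::vector<int> der4(4 * m);
  RNGScope scope;
  for (int l = 0; l < n_loci; ++l) {
    Tree tr = sim_one_tree(lp, ne, events);
    // per-node derived counts in the four test populations: internal node
    // ids strictly exceed their children's, so one linear roll-up suffices
    std::fill(der4.begin(), der4.end(), 0);
    for (int i = 0; i < n; ++i)
      if (test_pop[i] >= 0) der4[4 * i + test_pop[i]] = 1;
    for (int i = 0; i < m - 1; ++i) {
      int p = tr.parent[i];
      for (int g = 0; g < 4; ++g) der4[4 * p + g] += der4[4 * i + g];
    }
    for (int node = 0; node < 2 * n - 2; ++node) {
      double len = tr.time[tr.parent[node]] - tr.time[node];
      int k = (int)R::rpois(len * mu_len);
      if (k == 0) continue;
      const int* der = &der4[4 * node];
      double p1 = der[0] / cnt[0], p2 = der[1] / cnt[1],
             p3 = der[2] / cnt[2], pO = der[3] / cnt[3];
      if (pO > 0.0 && pO < 1.0) { skipped[l] += k; continue; }
      if (pO == 1.0) { p1 = 1 - p1; p2 = 1 - p2; p3 = 1 - p3; }
      abba[l] += k * (1 - p1) * p2 * p3;
      baba[l] += k * p1 * (1 - p2) * p3;
      used[l] += k;
    }
  }
  return List::create(_["abba"] = abba, _["baba"] = baba,
                      _["nUsed"] = used, _["nSkipped"] = skipped);
}

// Simulate n_loci independent genealogies and overlay infinite-sites
// mutations: Poisson(branch_length * mu_len) per branch, every mutation a new
// biallelic site whose derived allele is carried by the branch's descendants.
// Returns the 0/1 haploid pattern matrix (sites x lineages) and the
// 1-based locus of origin per site.
// [[Rcpp::export(name = ".simPatternsCpp")]]
List sim_patterns_cpp(int n_loci, IntegerVector lin_pop0, NumericVector ne0,
                      NumericMatrix events, double mu_len) {
  const int n = lin_pop0.size();
  if (n < 2) stop("need at least two lineages");
  std::vector<int> lp(lin_pop0.begin(), lin_pop0.end());
  std::vector<double> ne(ne0.begin(), ne0.end());
  std::vector<char> patterns;           // flattened, stride n
  std::vector<int> locus;
  std::vector<std::vector<int> > ls;
  RNGScope scope;
  for (int l = 0; l < n_loci; ++l) {
    Tree tr = sim_one_tree(lp, ne, events);
    leaf_sets(tr, n, ls);
    for (int node = 0; node < 2 * n - 2; ++node) {  // root excluded
      double len = tr.time[tr.parent[node]] - tr.time[node];
      int k = (int)R::rpois(len * mu_len);
      for (int m = 0; m < k; ++m) {
        size_t off = patterns.size();
        patterns.resize(off + n, 0);
        for (size_t j = 0; j < ls[node].size(); ++j)
          patterns[off + ls[node][j]] = 1;
        locus.push_back(l + 1);
      }
    }
  }
  const int n_sites = locus.size();
  IntegerMatrix pat(n_sites, n);
  for (int s = 0; s < n_sites; ++s)
    for (int j = 0; j < n; ++j)
      pat(s, j) = patterns[(size_t)s * n + j];
  return List::create(_["patterns"] = pat,
                      _["locus"] = IntegerVector(locus.begin(), locus.end()));
}
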