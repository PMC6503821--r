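// Multi-deme backward-in-time coalescent with founding bottlenecks and
// continuous migration, plus SNP-mode mutation placement (one mutation per
// genealogy, uniform on total branch length, so every site is polymorphic in
// the pooled sample).  All randomness goes through R's RNG so that set.seed()
// on the R side gives bitwise-reproducible output.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Scheduled {
  double time;
  int type;     // 0 = bottleneck start (resize), 1 = merge derived -> source
  int deme;     // deme affected (derived deme)
  int source;   // merge target (type 1 only)
  double size;  // new size (type 0 only)
};

struct MigEdge {
  int from, to;
  double rate, t0, t1;
};

struct Genealogy {
  std::vector<int> parent;    // length 2n-1, root has -1
  std::vector<double> time;   // node times (generations before sampling)
  int n_tips;
};

// Simulate one genealogy.  sample_sizes are gene-copy counts per deme
// (2 x diploids); tips are deme-major, 0..n-1.
Genealogy sim_genealogy(const std::vector<int>& copies,
                        const std::vector<double>& ne,
                        std::vector<Scheduled> sched,
                        const std::vector<MigEdge>& mig) {
  const int D = (int)copies.size();
  int n = 0;
  for (int d = 0; d < D; ++d) n += copies[d];
  if (n < 2) stop("need at least 2 gene copies in total");

  Genealogy g;
  g.n_tips = n;
  g.parent.assign(2 * n - 1, -1);
  g.time.assign(2 * n - 1, 0.0);

  std::vector<double> size(ne);            // current (backward-time) deme sizes
  std::vector<bool> active(D, true);
  std::vector< std::vector<int> > members(D);
  int tip = 0;
  for (int d = 0; d < D; ++d)
    for (int i = 0; i < copies[d]; ++i) members[d].push_back(tip++);

  double t = 0.0;
  int next_node = n;
  int remaining = n;
  size_t si = 0;

  while (remaining > 1) {
    // per-deme coalescence rates and migration rates
    double total = 0.0;
    for (int d = 0; d < D; ++d) {
      const double k = (double)members[d].size();
      if (active[d] && k > 1.0) total += k * (k - 1.0) / (4.0 * size[d]);
    }
    for (size_t e = 0; e < mig.size(); ++e) {
      const MigEdge& m = mig[e];
      if (active[m.from] && active[m.to] && t >= m.t0 && t < m.t1)
        total += m.rate * (double)members[m.from].size();
    }

    double t_next = (si < sched.size()) ? sched[si].time : R_PosInf;
    // migration edges can switch on at t0 later than now; account for the
    // earliest activation so a zero-rate epoch does not deadlock
    for (size_t e = 0; e < mig.size(); ++e)
      if (mig[e].t0 > t && mig[e].t0 < t_next &&
          active[mig[e].from] && active[mig[e].to])
        t_next = mig[e].t0;

    if (total <= 0.0) {
      if (!R_finite(t_next))
        stop("lineages stranded in isolated demes: scenario invariant violated");
      t = t_next;
      while (si < sched.size() && sched[si].time <= t) {
        const Scheduled& s = sched[si];
        if (s.type == 0) {
          size[s.deme] = s.size;
        } else {
          for (size_t i = 0; i < members[s.deme].size(); ++i)
            members[s.source].push_back(members[s.deme][i]);
          members[s.deme].clear();
          active[s.deme] = false;
        }
        ++si;
      }
      continue;
    }

    const double dt = R::exp_rand() / total;
    if (t + dt >= t_next) {
      t = t_next;
      while (si < sched.size() && sched[si].time <= t) {
        const Scheduled& s = sched[si];
        if (s.type == 0) {
          size[s.deme] = s.size;
        } else {
          for (size_t i = 0; i < members[s.deme].size(); ++i)
            members[s.source].push_back(members[s.deme][i]);
          members[s.deme].clear();
          active[s.deme] = false;
        }
        ++si;
      }
      continue;
    }
    t += dt;

    // choose which event fired
    double u = unif_rand() * total;
    int ev_deme = -1, ev_edge = -1;
    for (int d = 0; d < D; ++d) {
      const double k = (double)members[d].size();
      if (!(active[d] && k > 1.0)) continue;
      const double r = k * (k - 1.0) / (4.0 * size[d]);
      if (u < r) { ev_deme = d; break; }
      u -= r;
    }
    if (ev_deme < 0) {
      for (size_t e = 0; e < mig.size(); ++e) {
        const MigEdge& m = mig[e];
        if (!(active[m.from] && active[m.to] && t >= m.t0 && t < m.t1)) continue;
        const double r = m.rate * (double)members[m.from].size();
        if (u < r) { ev_edge = (int)e; break; }
        u -= r;
      }
    }

    if (ev_deme >= 0) {
      std::vector<int>& mem = members[ev_deme];
      const int k = (int)mem.size();
      int i1 = (int)std::floor(unif_rand() * k);
      if (i1 >= k) i1 = k - 1;
      int i2 = (int)std::floor(unif_rand() * (k - 1));
      if (i2 >= k - 1) i2 = k - 2;
      if (i2 >= i1) ++i2;
      const int a = mem[i1], b = mem[i2];
      const int node = next_node++;
      g.parent[a] = node;
      g.parent[b] = node;
      g.time[node] = t;
      mem[i1] = node;
      mem[i2] = mem.back();
      mem.pop_back();
      --remaining;
    } else if (ev_edge >= 0) {
      const MigEdge& m = mig[ev_edge];
      std::vector<int>& mem = members[m.from];
      const int k = (int)mem.size();
      int i1 = (int)std::floor(unif_rand() * k);
      if (i1 >= k) i1 = k - 1;
      members[m.to].push_back(mem[i1]);
      mem[i1] = mem.back();
      mem.pop_back();
    }
    // (numerical slop: if neither chosen, loop again)
  }
  return g;
}

// Place one mutation uniformly on the total branch length; returns 0/1 per tip.
void place_mutation(const Genealogy& g, std::vector<int>& der) {
  const int n = g.n_tips;
  const int nn = 2 * n - 1;
  double total = 0.0;
  for (int v = 0; v < nn; ++v)
    if (g.parent[v] >= 0) total += g.time[g.parent[v]] - g.time[v];
  double u = unif_rand() * total;
  int chosen = -1;
  for (int v = 0; v < nn; ++v) {
    if (g.parent[v] < 0) continue;
    const double L = g.time[g.parent[v]] - g.time[v];
    if (u < L) { chosen = v; break; }
    u -= L;
  }
  if (chosen < 0) chosen = nn - 2;  // guard against fp round-off

  // children lists, then DFS from chosen collecting tips
  std::vector<int> child1(nn, -1), child2(nn, -1);
  for (int v = 0; v < nn - 1; ++v) {
    const int p = g.parent[v];
    if (p < 0) continue;
    if (child1[p] < 0) child1[p] = v; else child2[p] = v;
  }
  der.assign(n, 0);
  std::vector<int> stack;
  stack.push_back(chosen);
  while (!stack.empty()) {
    const int v = stack.back();
    stack.pop_back();
    if (v < n) { der[v] = 1; continue; }
    if (child1[v] >= 0) stack.push_back(child1[v]);
    if (child2[v] >= 0) stack.push_back(child2[v]);
  }
}

void parse_config(const IntegerVector& copies_r, const NumericVector& ne_r,
                  const NumericMatrix& events, const NumericMatrix& migration,
                  std::vector<int>& copies, std::vector<double>& ne,
                  std::vector<Scheduled>& sched, std::vector<MigEdge>& mig) {
  const int D = copies_r.size();
  copies.assign(copies_r.begin(), copies_r.end());
  ne.assign(ne_r.begin(), ne_r.end());
  if ((int)ne.size() != D) stop("ne and sample_sizes lengths differ");
  for (int d = 0; d < D; ++d)
    if (ne[d] <= 0) stop("effective sizes must be positive");

  // events: time, derived, source, severity, duration (R passes 0-based demes)
  for (int i = 0; i < events.nrow(); ++i) {
    const double t0 = events(i, 0);
    const int der = (int)events(i, 1);
    const int src = (int)events(i, 2);
    const double sev = events(i, 3);
    const double dur = events(i, 4);
    if (der < 0 || der >= D || src < 0 || src >= D) stop("event deme out of range");
    if (sev <= 0 || sev > 1) stop("severity must be in (0,1]");
    Scheduled a; a.time = t0; a.type = 0; a.deme = der; a.source = -1;
    a.size = std::max(sev * ne[der], 1e-12);
    Scheduled b; b.time = t0 + dur; b.type = 1; b.deme = der; b.source = src;
    b.size = 0.0;
    sched.push_back(a);
    sched.push_back(b);
  }
  std::sort(sched.begin(), sched.end(),
            [](const Scheduled& x, const Scheduled& y) {
              if (x.time != y.time) return x.time < y.time;
              return x.type < y.type;
            });

  for (int i = 0; i < migration.nrow(); ++i) {
    MigEdge m;
    m.from = (int)migration(i, 0);
    m.to = (int)migration(i, 1);
    m.rate = migration(i, 2);
    m.t0 = migration(i, 3);
    m.t1 = migration(i, 4);
    if (m.from < 0 || m.from >= D || m.to < 0 || m.to >= D)
      stop("migration deme out of range");
    if (m.rate < 0) stop("migration rate must be non-negative");
    if (m.rate > 0) mig.push_back(m);
  }
}

}  // namespace

// [[Rcpp::export(name = ".sim_genealogy_cpp")]]
List sim_genealogy_cpp(IntegerVector sample_copies, NumericVector ne,
                       NumericMatrix events, NumericMatrix migration) {
  std::vector<int> copies;
  std::vector<double> sizes;
  std::vector<Scheduled> sched;
  std::vector<MigEdge> mig;
  parse_config(sample_copies, ne, events, migration, copies, sizes, sched, mig);
  Genealogy g = sim_genealogy(copies, sizes, sched, mig);
  return List::create(_["parent"] = IntegerVector(g.parent.begin(), g.parent.end()),
                      _["time"] = NumericVector(g.time.begin(), g.time.end()),
                      _["n_tips"] = g.n_tips);
}

// [[Rcpp::export(name = ".place_mutation_cpp")]]
IntegerVector place_mutation_cpp(IntegerVector parent, NumericVector time,
                                 int n_tips) {
  Genealogy g;
  g.parent.assign(parent.begin(), parent.end());
  g.time.assign(time.begin(), time.end());
  g.n_tips = n_tips;
  std::vector<int> der;
  place_mutation(g, der);
  return IntegerVector(der.begin(), der.end());
}

// Full dataset: a batch of n_loci independent genealogies over which the
// n_loci segregating sites are allocated multinomially, proportional to each
// genealogy's total branch length.  This reproduces the infinite-sites
// Poisson mutation process conditional on the total number of segregating
// sites (so the pooled conditional SFS is proportional to 1/i), which a
// one-uniform-mutation-per-tree scheme would not: the latter yields the
// fixed-S law, which over-weights short genealogies.  Gene copies are
// paired (2j, 2j+1) into diploid genotypes counting derived alleles.
// [[Rcpp::export(name = ".sim_dataset_cpp")]]
IntegerMatrix sim_dataset_cpp(int n_loci, IntegerVector sample_copies,
                              NumericVector ne, NumericMatrix events,
                              NumericMatrix migration) {
  if (n_loci < 1) stop("n_loci must be >= 1");
  std::vector<int> copies;
  std::vector<double> sizes;
  std::vector<Scheduled> sched;
  std::vector<MigEdge> mig;
  parse_config(sample_copies, ne, events, migration, copies, sizes, sched, mig);
  int n = 0;
  for (size_t d = 0; d < copies.size(); ++d) {
    if (copies[d] % 2 != 0) stop("gene-copy counts must be even (diploids)");
    n += copies[d];
  }
  const int n_dip = n / 2;

  std::vector<Genealogy> trees;
  trees.reserve(n_loci);
  std::vector<double> len(n_loci);
  double len_total = 0.0;
  for (int j = 0; j < n_loci; ++j) {
    trees.push_back(sim_genealogy(copies, sizes, sched, mig));
    const Genealogy& g = trees.back();
    double L = 0.0;
    for (int v = 0; v < 2 * n - 1; ++v)
      if (g.parent[v] >= 0) L += g.time[g.parent[v]] - g.time[v];
    len[j] = L;
    len_total += L;
  }

  // multinomial allocation via sequential conditional binomials
  std::vector<int> sites(n_loci, 0);
  int left = n_loci;
  double mass = len_total;
  for (int j = 0; j < n_loci && left > 0; ++j) {
    double p = (mass > 0.0) ? len[j] / mass : 1.0;
    if (p > 1.0) p = 1.0;
    const int c = (j == n_loci - 1) ? left
                                    : (int)R::rbinom((double)left, p);
    sites[j] = c;
    left -= c;
    mass -= len[j];
  }

  IntegerMatrix out(n_loci, n_dip);
  std::vector<int> der;
  int row = 0;
  for (int j = 0; j < n_loci; ++j) {
    for (int s = 0; s < sites[j]; ++s) {
      place_mutation(trees[j], der);
      for (int c = 0; c < n_dip; ++c) out(row, c) = der[2 * c] + der[2 * c + 1];
      ++row;
    }
  }
  return out;
}
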