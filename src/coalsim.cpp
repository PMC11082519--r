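// Structured-coalescent simulator for island-colonization demographies.
//
// Backward-time conventions: time 0 = present, measured in generations.
// Deme d has diploid size N_d(t) = N_d * exp(-r_d * t) while it exists
// (t <= t_split_d); at t_split_d all its lineages move to parent_d.
// Pairwise coalescence rate within d: C(k,2) / (2 N_d(t)).
// A migration epoch (dest, source, M, on, off) moves single lineages from
// dest to source at per-lineage rate M / N_dest(t) while on <= t < off
// (forward-time migrants arriving in dest trace back to source).
// Every SNP is an independent genealogy carrying exactly one mutation
// placed uniformly by branch length (fixed-S convention), so each row of
// the output is segregating by construction.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Demography {
  std::vector<double> N, r, t_split; // t_split = +inf for root
  std::vector<int> parent;           // -1 for root
  std::vector<int> samples;          // haploid sample size per deme
  std::vector<int> m_dest, m_src;
  std::vector<double> m_M, m_on, m_off;
  int n_demes() const { return (int)N.size(); }
};

// waiting time to an inhomogeneous event with rate a*exp(b*t), from t0
double next_time(double a, double b, double t0, double E) {
  if (a <= 0.0) return R_PosInf;
  if (b == 0.0) return t0 + E / a;
  double arg = std::exp(b * t0) + b * E / a;
  if (arg <= 0.0) return R_PosInf;
  return std::log(arg) / b;
}

struct Tree {
  std::vector<int> parent;     // node -> parent (-1 root)
  std::vector<double> time;    // node times (generations)
  std::vector<int> leaf_deme;  // deme of each leaf
  int n_leaves;
};

struct Workspace {
  std::vector<std::vector<int>> lin;
  std::vector<double> cand_coal, cand_mig;
  std::vector<std::pair<double, int>> bounds;
  // flat children arrays for mutation placement
  std::vector<int> child_off, child_buf;
};

void simulate_tree(const Demography& dem, double ceiling, Tree& tr,
                   Workspace& ws) {
  int P = dem.n_demes();
  int n = 0;
  for (int d = 0; d < P; ++d) n += dem.samples[d];
  if (n < 2) stop("need at least two sampled haplotypes");

  tr.n_leaves = n;
  tr.parent.assign(2 * n - 1, -1);
  tr.time.assign(2 * n - 1, 0.0);
  tr.leaf_deme.clear();
  tr.leaf_deme.reserve(n);

  ws.lin.resize(P);
  std::vector<std::vector<int>>& lin = ws.lin;
  for (int d = 0; d < P; ++d) lin[d].clear();
  {
    int id = 0;
    for (int d = 0; d < P; ++d)
      for (int i = 0; i < dem.samples[d]; ++i) {
        lin[d].push_back(id++);
        tr.leaf_deme.push_back(d);
      }
  }
  int next_node = n, n_active = n;
  int E = (int)dem.m_M.size();

  // scheduled boundaries: splits and migration-window edges
  std::vector<std::pair<double, int>>& bounds = ws.bounds;
  bounds.clear();
  for (int d = 0; d < P; ++d)
    if (dem.parent[d] >= 0) bounds.push_back({dem.t_split[d], d});
  for (int e = 0; e < E; ++e) {
    bounds.push_back({dem.m_on[e], -1});
    bounds.push_back({dem.m_off[e], -1});
  }
  std::sort(bounds.begin(), bounds.end());
  size_t bi = 0;
  double t = 0.0;

  // cached next-event candidates; valid until the lineage configuration
  // of the deme changes (independent Poisson processes are memoryless)
  ws.cand_coal.assign(P, R_PosInf);
  ws.cand_mig.assign(E, R_PosInf);
  std::vector<double>& cand_coal = ws.cand_coal;
  std::vector<double>& cand_mig = ws.cand_mig;
  auto redraw_coal = [&](int d) {
    int k = (int)lin[d].size();
    if (k >= 2 && t < dem.t_split[d]) {
      double a = 0.5 * k * (k - 1) / (2.0 * dem.N[d]);
      cand_coal[d] = next_time(a, dem.r[d], t, exp_rand());
    } else cand_coal[d] = R_PosInf;
  };
  auto redraw_mig = [&](int e) {
    int d = dem.m_dest[e];
    int k = (int)lin[d].size();
    if (k >= 1 && t >= dem.m_on[e] && t < dem.m_off[e]) {
      double a = k * dem.m_M[e] / dem.N[d];
      double cand = next_time(a, dem.r[d], t, exp_rand());
      cand_mig[e] = (cand < dem.m_off[e]) ? cand : R_PosInf;
    } else cand_mig[e] = R_PosInf;
  };
  auto touch_deme = [&](int d) {
    redraw_coal(d);
    for (int e = 0; e < E; ++e)
      if (dem.m_dest[e] == d) redraw_mig(e);
  };
  for (int d = 0; d < P; ++d) touch_deme(d);

  while (n_active > 1) {
    double t_next = (bi < bounds.size()) ? bounds[bi].first : R_PosInf;

    double best = R_PosInf;
    int best_kind = -1, best_deme = -1, best_epoch = -1;
    for (int d = 0; d < P; ++d)
      if (cand_coal[d] < best) {
        best = cand_coal[d]; best_kind = 0; best_deme = d;
      }
    for (int e = 0; e < E; ++e)
      if (cand_mig[e] < best) {
        best = cand_mig[e]; best_kind = 1;
        best_deme = dem.m_dest[e]; best_epoch = e;
      }

    if (best >= t_next) {
      if (!std::isfinite(t_next)) {
        // no boundary and no possible event left: demes are disconnected
        stop("demography never coalesces: %d lineages stranded", n_active);
      }
      t = t_next;
      int code = bounds[bi].second;
      ++bi;
      if (code >= 0) { // split: child deme merges into its parent
        int par = dem.parent[code];
        for (int id : lin[code]) lin[par].push_back(id);
        lin[code].clear();
        touch_deme(code);
        touch_deme(par);
      } else { // migration window edge: epoch activity changed
        for (int e = 0; e < E; ++e) redraw_mig(e);
      }
      continue;
    }

    t = best;
    if (t > ceiling)
      stop("coalescent time ceiling exceeded (%g generations)", ceiling);
    if (best_kind == 0) { // coalescence in best_deme
      std::vector<int>& v = lin[best_deme];
      int k = (int)v.size();
      int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      int a_id = v[i], b_id = v[j];
      int node = next_node++;
      tr.parent[a_id] = node;
      tr.parent[b_id] = node;
      tr.time[node] = t;
      if (i > j) std::swap(i, j);
      v.erase(v.begin() + j);
      v.erase(v.begin() + i);
      v.push_back(node);
      --n_active;
      touch_deme(best_deme);
    } else { // migration: one lineage in dest traces back to source
      std::vector<int>& v = lin[best_deme];
      int k = (int)v.size();
      int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
      int id = v[i];
      v.erase(v.begin() + i);
      lin[dem.m_src[best_epoch]].push_back(id);
      touch_deme(best_deme);
      touch_deme(dem.m_src[best_epoch]);
    }
  }
}

Demography build_dem(NumericVector N, NumericVector r, NumericVector t_split,
                     IntegerVector parent, IntegerVector samples,
                     IntegerVector m_dest, IntegerVector m_src,
                     NumericVector m_M, NumericVector m_on,
                     NumericVector m_off) {
  Demography dem;
  int P = N.size();
  dem.N.assign(N.begin(), N.end());
  dem.r.assign(r.begin(), r.end());
  dem.t_split.resize(P);
  dem.parent.assign(parent.begin(), parent.end());
  dem.samples.assign(samples.begin(), samples.end());
  for (int d = 0; d < P; ++d) {
    dem.t_split[d] = NumericVector::is_na(t_split[d]) ? R_PosInf : t_split[d];
    if (dem.N[d] <= 0) stop("non-positive deme size");
  }
  dem.m_dest.assign(m_dest.begin(), m_dest.end());
  dem.m_src.assign(m_src.begin(), m_src.end());
  dem.m_M.assign(m_M.begin(), m_M.end());
  dem.m_on.assign(m_on.begin(), m_on.end());
  dem.m_off.assign(m_off.begin(), m_off.end());
  return dem;
}

// place one mutation uniformly by branch length; return derived-leaf set
void drop_mutation_on(const Tree& tr, std::vector<int>& alleles,
                      Workspace& ws) {
  int n_nodes = (int)tr.parent.size();
  double total = 0.0;
  for (int v = 0; v < n_nodes; ++v)
    if (tr.parent[v] >= 0) total += tr.time[tr.parent[v]] - tr.time[v];
  if (total <= 0.0) stop("degenerate genealogy: zero total branch length");
  double u = unif_rand() * total, acc = 0.0;
  int hit = -1;
  for (int v = 0; v < n_nodes; ++v) {
    if (tr.parent[v] < 0) continue;
    acc += tr.time[tr.parent[v]] - tr.time[v];
    if (u <= acc) { hit = v; break; }
  }
  if (hit < 0) hit = n_nodes - 2;
  // flat children arrays (counting sort by parent)
  ws.child_off.assign(n_nodes + 1, 0);
  ws.child_buf.resize(n_nodes);
  for (int v = 0; v < n_nodes; ++v)
    if (tr.parent[v] >= 0) ++ws.child_off[tr.parent[v] + 1];
  for (int v = 0; v < n_nodes; ++v) ws.child_off[v + 1] += ws.child_off[v];
  {
    std::vector<int> cur(ws.child_off.begin(), ws.child_off.end() - 1);
    for (int v = 0; v < n_nodes; ++v)
      if (tr.parent[v] >= 0) ws.child_buf[cur[tr.parent[v]]++] = v;
  }
  std::fill(alleles.begin(), alleles.end(), 0);
  std::vector<int> stack = {hit};
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    if (v < tr.n_leaves) alleles[v] = 1;
    for (int c = ws.child_off[v]; c < ws.child_off[v + 1]; ++c)
      stack.push_back(ws.child_buf[c]);
  }
}

} // namespace

// [[Rcpp::export]]
List sim_genealogies_cpp(NumericVector N, NumericVector r,
                         NumericVector t_split, IntegerVector parent,
                         IntegerVector samples, IntegerVector m_dest,
                         IntegerVector m_src, NumericVector m_M,
                         NumericVector m_on, NumericVector m_off,
                         int n_trees, double ceiling) {
  Demography dem = build_dem(N, r, t_split, parent, samples, m_dest, m_src,
                             m_M, m_on, m_off);
  List out(n_trees);
  Tree tr;
  Workspace ws;
  for (int i = 0; i < n_trees; ++i) {
    simulate_tree(dem, ceiling, tr, ws);
    out[i] = List::create(
      _["parent"] = IntegerVector(tr.parent.begin(), tr.parent.end()),
      _["time"] = NumericVector(tr.time.begin(), tr.time.end()),
      _["leaf_deme"] = IntegerVector(tr.leaf_deme.begin(),
                                     tr.leaf_deme.end()),
      _["n_leaves"] = tr.n_leaves);
  }
  return out;
}

// mutation_model: 0 = length-weighted (a site is a SNP with probability
// proportional to its genealogy's total branch length, the small-mutation
// -rate limit of infinite-sites conditioning on segregation; reproduces
// the neutral SFS ~ 1/i), 1 = strict one-tree-one-mutation (ms -s 1)
// [[Rcpp::export]]
IntegerMatrix sim_snp_matrix_cpp(NumericVector N, NumericVector r,
                                 NumericVector t_split, IntegerVector parent,
                                 IntegerVector samples, IntegerVector m_dest,
                                 IntegerVector m_src, NumericVector m_M,
                                 NumericVector m_on, NumericVector m_off,
                                 int n_snps, double ceiling,
                                 int mutation_model) {
  Demography dem = build_dem(N, r, t_split, parent, samples, m_dest, m_src,
                             m_M, m_on, m_off);
  int n = 0;
  for (size_t d = 0; d < dem.samples.size(); ++d) n += dem.samples[d];
  IntegerMatrix out(n_snps, n);
  std::vector<int> alleles(n);
  Workspace ws;

  if (mutation_model == 1) { // fixed-S: one mutation on every tree
    Tree tr;
    for (int s = 0; s < n_snps; ++s) {
      simulate_tree(dem, ceiling, tr, ws);
      drop_mutation_on(tr, alleles, ws);
      for (int j = 0; j < n; ++j) out(s, j) = alleles[j];
    }
    return out;
  }

  // length-weighted: draw a batch of genealogies, give tree j a SNP count
  // proportional to its total branch length (systematic resampling, which
  // adds less noise than multinomial), then place independent mutations
  std::vector<Tree> trees(n_snps);
  std::vector<double> w(n_snps);
  double wsum = 0.0;
  for (int j = 0; j < n_snps; ++j) {
    simulate_tree(dem, ceiling, trees[j], ws);
    double L = 0.0;
    const Tree& tr = trees[j];
    for (size_t v = 0; v < tr.parent.size(); ++v)
      if (tr.parent[v] >= 0) L += tr.time[tr.parent[v]] - tr.time[v];
    w[j] = L;
    wsum += L;
  }
  std::vector<int> cnt(n_snps, 0);
  {
    double u = unif_rand(), cum = 0.0;
    int k = 0;
    for (int j = 0; j < n_snps && k < n_snps; ++j) {
      cum += w[j] / wsum * n_snps;
      while (k + u <= cum && k < n_snps) { ++cnt[j]; ++k; }
    }
    while (k < n_snps) { ++cnt[n_snps - 1]; ++k; } // guard rounding
  }
  int s = 0;
  for (int j = 0; j < n_snps; ++j)
    for (int c = 0; c < cnt[j]; ++c) {
      drop_mutation_on(trees[j], alleles, ws);
      for (int jj = 0; jj < n; ++jj) out(s, jj) = alleles[jj];
      ++s;
    }
  // shuffle rows so repeated-tree SNPs are not adjacent
  for (int i = n_snps - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1)); if (j > i) j = i;
    if (j != i)
      for (int jj = 0; jj < n; ++jj) std::swap(out(i, jj), out(j, jj));
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector drop_mutation_cpp(IntegerVector parent, NumericVector time,
                                int n_leaves) {
  Tree tr;
  tr.parent.assign(parent.begin(), parent.end());
  tr.time.assign(time.begin(), time.end());
  tr.n_leaves = n_leaves;
  std::vector<int> alleles(n_leaves);
  Workspace ws;
  drop_mutation_on(tr, alleles, ws);
  return IntegerVector(alleles.begin(), alleles.end());
}
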