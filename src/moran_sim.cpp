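// Forward-time diploid Moran simulator over recombining linkage blocks.
//
// Each individual carries 2 haplotypes x (n_chr * L) blocks; a block stores
// only the product of (1 + s) over the mutations it has ever received, so the
// number of segregating mutations never enters the per-event cost. One
// generation is defined as N birth-death events. All randomness flows through
// R's RNG so that set.seed() on the R side gives full reproducibility.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstring>

using namespace Rcpp;

namespace {

struct MutRec {
  double s;
  int type;          // 0 = deleterious, 1 = beneficial, 2 = neutral marker
  double origin_gen;
  int block;         // block index within a haplotype, 0..B-1
  int count;         // carrier copies among the 2N haplotypes
  bool resolved;     // fixed or lost; no longer in any block list
};

struct FixedRec {
  int id;
  double s;
  int type;
  double origin_gen;
  double fix_gen;
};

inline int runif_int(int n) {
  // uniform on 0..n-1; unif_rand() < 1 strictly
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// choose k distinct hotspot positions in 1..L-1 (ascending)
inline void draw_crossovers(int k, int L, std::vector<int>& pos) {
  pos.clear();
  while ((int)pos.size() < k) {
    int p = 1 + runif_int(L - 1);
    bool dup = false;
    for (int q : pos) if (q == p) { dup = true; break; }
    if (!dup) pos.push_back(p);
  }
  std::sort(pos.begin(), pos.end());
}

// copy one recombined haploid genome from parent haplotypes h0/h1 into gam;
// src[b] records the source haplotype of each block (may be null).
// Segments between crossover positions are block-copied.
void gamete_from(const double* h0, const double* h1,
                 int n_chr, int L, int n_cross,
                 double* gam, int* src, std::vector<int>& scratch) {
  for (int c = 0; c < n_chr; ++c) {
    int off = c * L;
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    if (n_cross > 0) draw_crossovers(n_cross, L, scratch); else scratch.clear();
    int b0 = 0;
    std::size_t xi = 0;
    while (b0 < L) {
      int b1 = (xi < scratch.size()) ? scratch[xi] : L;
      const double* hs = (cur == 0) ? h0 : h1;
      std::memcpy(gam + off + b0, hs + off + b0,
                  (std::size_t)(b1 - b0) * sizeof(double));
      if (src) std::fill(src + off + b0, src + off + b1, cur);
      cur ^= 1;
      ++xi;
      b0 = b1;
    }
  }
}

// product of n doubles with independent accumulators (breaks the fp
// latency chain; fitness products are order-insensitive here)
inline double prod_range(const double* a, int n) {
  double p0 = 1.0, p1 = 1.0, p2 = 1.0, p3 = 1.0;
  int i = 0;
  for (; i + 4 <= n; i += 4) {
    p0 *= a[i]; p1 *= a[i + 1]; p2 *= a[i + 2]; p3 *= a[i + 3];
  }
  for (; i < n; ++i) p0 *= a[i];
  return (p0 * p1) * (p2 * p3);
}

class MoranSim {
public:
  // architecture and rates
  int N, n_chr, L, n_cross, B;
  double Ud, Ub, g_shape, g_scale, b_mean;
  bool ledger_on, tracer_on;
  int tracer_block;

  long long events;
  std::vector<double> loads;  // (ind*2 + hap)*B + b
  std::vector<double> w;
  double wmax;
  std::vector<double> mean_traj, var_traj;

  // fixation ledger: records indexed by id - 1; active_list holds the
  // currently segregating ids (hot loops index the vector directly)
  std::vector<MutRec> recs;
  std::vector<int> active_list;
  std::vector<FixedRec> fixed;
  std::vector<std::vector<int>> ids;  // per block copy, active mutation ids
  int next_id;
  bool extinct;

  // neutral-tracer genealogy at one focal block
  std::vector<int> cur_node;          // 2N leaf pointers
  std::vector<int> node_parent;
  std::vector<double> node_time;

  // scratch buffers
  std::vector<double> g1, g2;
  std::vector<int> src1, src2;
  std::vector<std::vector<int>> gid1, gid2;
  std::vector<int> xscratch;

  MoranSim(int N_, int n_chr_, int L_, int n_cross_,
           double Ud_, double Ub_, double g_shape_, double g_scale_,
           double b_mean_, bool ledger, bool tracer, int tracer_block_)
      : N(N_), n_chr(n_chr_), L(L_), n_cross(n_cross_), B(n_chr_ * L_),
        Ud(Ud_), Ub(Ub_), g_shape(g_shape_), g_scale(g_scale_),
        b_mean(b_mean_), ledger_on(ledger), tracer_on(tracer),
        tracer_block(tracer_block_), events(0), next_id(1), extinct(false) {
    loads.assign((std::size_t)N * 2 * B, 1.0);
    w.assign(N, 1.0);
    wmax = 1.0;
    if (ledger_on) ids.assign((std::size_t)N * 2 * B, {});
    if (tracer_on) {
      cur_node.resize(2 * N);
      node_parent.reserve(4 * N);
      node_time.reserve(4 * N);
      for (int i = 0; i < 2 * N; ++i) {
        cur_node[i] = i;
        node_parent.push_back(-1);
        node_time.push_back(0.0);
      }
    }
    g1.resize(B); g2.resize(B);
    src1.resize(B); src2.resize(B);
    if (ledger_on) { gid1.assign(B, {}); gid2.assign(B, {}); }
  }

  double gen() const { return (double)events / N; }

  std::size_t cix(int ind, int hap) const {
    return ((std::size_t)ind * 2 + hap) * B;
  }

  int sample_parent() {
    for (int tries = 0; ; ++tries) {
      int i = runif_int(N);
      double wi = w[i];
      if (wi >= wmax || unif_rand() * wmax < wi) return i;
      if (tries > 0 && tries % 4096 == 0) {
        refresh_wmax();
        if (wmax <= 0.0) { extinct = true; return -1; }
      }
    }
  }

  void refresh_wmax() { wmax = *std::max_element(w.begin(), w.end()); }

  void mutate_buffer(std::vector<double>& g1_, std::vector<double>& g2_) {
    int nd = (int)R::rpois(Ud);
    int nb = (int)R::rpois(Ub);
    for (int m = 0; m < nd + nb; ++m) {
      bool del = m < nd;
      double s = del ? -R::rgamma(g_shape, g_scale) : R::rexp(b_mean);
      int copy = runif_int(2 * B);
      int hap = copy / B, b = copy % B;
      std::vector<double>& tgt = (hap == 0) ? g1_ : g2_;
      double f = 1.0 + s;
      tgt[b] = (f <= 0.0) ? 0.0 : tgt[b] * f;
      if (ledger_on) {
        int id = next_id++;
        recs.push_back(MutRec{s, del ? 0 : 1, gen(), b, 0, false});
        active_list.push_back(id);
        ((hap == 0) ? gid1 : gid2)[b].push_back(id);
      }
    }
  }

  void moran_event() {
    int dier = runif_int(N);
    int p1 = sample_parent();
    int p2 = extinct ? -1 : sample_parent();
    if (extinct) stop("population extinct: all fitnesses are zero");

    const double* h1a = &loads[cix(p1, 0)];
    const double* h1b = &loads[cix(p1, 1)];
    const double* h2a = &loads[cix(p2, 0)];
    const double* h2b = &loads[cix(p2, 1)];
    gamete_from(h1a, h1b, n_chr, L, n_cross, g1.data(),
                (tracer_on || ledger_on) ? src1.data() : nullptr, xscratch);
    gamete_from(h2a, h2b, n_chr, L, n_cross, g2.data(),
                (tracer_on || ledger_on) ? src2.data() : nullptr, xscratch);

    if (ledger_on) {
      // inherited ids follow the same block sources as the loads
      assign_gamete_ids(p1, src1, gid1);
      assign_gamete_ids(p2, src2, gid2);
    }

    mutate_buffer(g1, g2);

    if (ledger_on) {
      for (int hap = 0; hap < 2; ++hap) {
        std::size_t base = cix(dier, hap);
        for (int b = 0; b < B; ++b)
          for (int id : ids[base + b]) recs[id - 1].count--;
      }
    }

    double old_w = w[dier];
    std::memcpy(&loads[cix(dier, 0)], g1.data(), B * sizeof(double));
    std::memcpy(&loads[cix(dier, 1)], g2.data(), B * sizeof(double));
    double nw = prod_range(g1.data(), B) * prod_range(g2.data(), B);
    w[dier] = nw;
    if (nw > wmax) wmax = nw;
    else if (old_w >= wmax && nw < old_w) refresh_wmax();

    if (ledger_on) {
      for (int b = 0; b < B; ++b) {
        ids[cix(dier, 0) + b].swap(gid1[b]);
        ids[cix(dier, 1) + b].swap(gid2[b]);
      }
      for (int hap = 0; hap < 2; ++hap) {
        std::size_t base = cix(dier, hap);
        for (int b = 0; b < B; ++b)
          for (int id : ids[base + b]) recs[id - 1].count++;
      }
    }

    if (tracer_on) {
      double t = gen();
      int par1 = cur_node[p1 * 2 + src1[tracer_block]];
      int par2 = cur_node[p2 * 2 + src2[tracer_block]];
      node_parent.push_back(par1); node_time.push_back(t);
      cur_node[dier * 2 + 0] = (int)node_parent.size() - 1;
      node_parent.push_back(par2); node_time.push_back(t);
      cur_node[dier * 2 + 1] = (int)node_parent.size() - 1;
    }

    ++events;
    if (events % N == 0) end_generation();
  }

  void assign_gamete_ids(int p, const std::vector<int>& src,
                         std::vector<std::vector<int>>& gid) {
    for (int b = 0; b < B; ++b) gid[b] = ids[cix(p, src[b]) + b];
  }

  void end_generation() {
    double m = 0.0;
    for (double x : w) m += x;
    m /= N;
    double v = 0.0;
    for (double x : w) v += (x - m) * (x - m);
    v = (N > 1) ? v / (N - 1) : 0.0;
    mean_traj.push_back(m);
    var_traj.push_back(v);
    if (ledger_on) ledger_check();
  }

  void ledger_check() {
    double t = gen();
    for (std::size_t k = 0; k < active_list.size(); ) {
      int id = active_list[k];
      MutRec& r = recs[id - 1];
      if (r.count <= 0) {
        r.resolved = true;  // lost; no block list still holds the id
        active_list[k] = active_list.back();
        active_list.pop_back();
        continue;
      }
      if (r.count >= 2 * N) {
        fixed.push_back(FixedRec{id, r.s, r.type, r.origin_gen, t});
        // strip the fixed id from every copy of its block; the load keeps
        // its (1+s) factor
        for (int ind = 0; ind < N; ++ind)
          for (int hap = 0; hap < 2; ++hap) {
            std::vector<int>& v = ids[cix(ind, hap) + r.block];
            auto it = std::find(v.begin(), v.end(), id);
            if (it != v.end()) { *it = v.back(); v.pop_back(); }
          }
        r.resolved = true;
        active_list[k] = active_list.back();
        active_list.pop_back();
        continue;
      }
      ++k;
    }
  }

  void run_generations(double n_gen) {
    long long n_ev = (long long)std::llround(n_gen * N);
    for (long long e = 0; e < n_ev; ++e) {
      moran_event();
      if ((e & 0xFFFF) == 0xFFFF) checkUserInterrupt();
    }
  }
};

}  // namespace

// [[Rcpp::export]]
SEXP cpp_sim_new(int N, int n_chr, int L, int n_cross,
                 double Ud, double Ub, double g_shape, double g_scale,
                 double b_mean, bool ledger, bool tracer, int tracer_block) {
  if (N < 2) stop("N must be at least 2");
  if (L < 2) stop("blocks_per_chromosome must be at least 2");
  if (n_cross > L - 1) stop("crossovers_per_chromosome must be <= L - 1");
  XPtr<MoranSim> p(new MoranSim(N, n_chr, L, n_cross, Ud, Ub, g_shape,
                                g_scale, b_mean, ledger, tracer, tracer_block),
                   true);
  return p;
}

// [[Rcpp::export]]
void cpp_sim_run(SEXP ptr, double n_gen) {
  XPtr<MoranSim> p(ptr);
  p->run_generations(n_gen);
}

// [[Rcpp::export]]
List cpp_sim_trajectory(SEXP ptr) {
  XPtr<MoranSim> p(ptr);
  return List::create(_["mean_fitness"] = wrap(p->mean_traj),
                      _["var_fitness"] = wrap(p->var_traj));
}

// [[Rcpp::export]]
List cpp_sim_state(SEXP ptr) {
  XPtr<MoranSim> p(ptr);
  NumericMatrix m(2 * p->B, p->N);
  for (int i = 0; i < p->N; ++i)
    for (int k = 0; k < 2 * p->B; ++k)
      m(k, i) = p->loads[(std::size_t)i * 2 * p->B + k];
  return List::create(_["loads"] = m, _["fitness"] = wrap(p->w),
                      _["generation"] = p->gen(), _["N"] = p->N,
                      _["n_chr"] = p->n_chr, _["L"] = p->L);
}

// [[Rcpp::export]]
int cpp_sim_inject(SEXP ptr, double s, int type, int ind, int hap, int block) {
  // ind/hap/block < 0 mean "draw uniformly"; requires the ledger
  XPtr<MoranSim> p(ptr);
  if (!p->ledger_on) stop("mutation injection requires ledger = TRUE");
  if (ind < 0) ind = runif_int(p->N);
  if (hap < 0) hap = runif_int(2);
  if (block < 0) block = runif_int(p->B);
  double f = 1.0 + s;
  std::size_t at = p->cix(ind, hap) + block;
  p->loads[at] = (f <= 0.0) ? 0.0 : p->loads[at] * f;
  int id = p->next_id++;
  p->recs.push_back(MutRec{s, type, p->gen(), block, 1, false});
  p->active_list.push_back(id);
  p->ids[at].push_back(id);
  // refresh this individual's fitness
  double nw = 1.0;
  for (int b = 0; b < 2 * p->B; ++b) nw *= p->loads[p->cix(ind, 0) + b];
  p->w[ind] = nw;
  if (nw > p->wmax) p->wmax = nw;
  return id;
}

// [[Rcpp::export]]
int cpp_sim_marker_status(SEXP ptr, int id) {
  // 0 = still segregating, 1 = fixed, -1 = lost
  XPtr<MoranSim> p(ptr);
  if (id < 1 || id > (int)p->recs.size()) stop("unknown mutation id");
  if (!p->recs[id - 1].resolved) return 0;
  for (const FixedRec& f : p->fixed) if (f.id == id) return 1;
  return -1;
}

// [[Rcpp::export]]
int cpp_sim_run_until_resolved(SEXP ptr, int id, double max_gen) {
  XPtr<MoranSim> p(ptr);
  double g0 = p->gen();
  if (id < 1 || id > (int)p->recs.size()) stop("unknown mutation id");
  while (p->gen() - g0 < max_gen) {
    p->run_generations(1.0);
    if (p->recs[id - 1].resolved) {
      for (const FixedRec& f : p->fixed) if (f.id == id) return 1;
      return -1;
    }
  }
  return 0;
}

// [[Rcpp::export]]
DataFrame cpp_sim_fixations(SEXP ptr) {
  XPtr<MoranSim> p(ptr);
  int n = (int)p->fixed.size();
  IntegerVector id(n), type(n);
  NumericVector s(n), og(n), fg(n);
  for (int i = 0; i < n; ++i) {
    id[i] = p->fixed[i].id; s[i] = p->fixed[i].s; type[i] = p->fixed[i].type;
    og[i] = p->fixed[i].origin_gen; fg[i] = p->fixed[i].fix_gen;
  }
  return DataFrame::create(_["id"] = id, _["s"] = s, _["type"] = type,
                           _["origin_gen"] = og, _["fixation_gen"] = fg);
}

// [[Rcpp::export]]
DataFrame cpp_sim_segregating(SEXP ptr) {
  XPtr<MoranSim> p(ptr);
  int n = (int)p->active_list.size();
  IntegerVector id(n), type(n), count(n), block(n);
  NumericVector s(n), og(n);
  for (int i = 0; i < n; ++i) {
    int k = p->active_list[i];
    const MutRec& r = p->recs[k - 1];
    id[i] = k; s[i] = r.s; type[i] = r.type;
    og[i] = r.origin_gen; count[i] = r.count; block[i] = r.block;
  }
  return DataFrame::create(_["id"] = id, _["s"] = s, _["type"] = type,
                           _["origin_gen"] = og, _["count"] = count,
                           _["block"] = block);
}

// [[Rcpp::export]]
NumericVector cpp_sim_tracer_pairs(SEXP ptr, int n_pairs) {
  // pairwise coalescence times (generations before now) of random copy pairs
  XPtr<MoranSim> p(ptr);
  if (!p->tracer_on) stop("tracer genealogy was not enabled");
  NumericVector out(n_pairs);
  double now = p->gen();
  for (int k = 0; k < n_pairs; ++k) {
    int i = runif_int(2 * p->N), j = runif_int(2 * p->N);
    while (j == i) j = runif_int(2 * p->N);
    std::unordered_set<int> anc;
    for (int u = p->cur_node[i]; u >= 0; u = p->node_parent[u]) anc.insert(u);
    double t2 = NA_REAL;
    for (int u = p->cur_node[j]; u >= 0; u = p->node_parent[u])
      if (anc.count(u)) { t2 = now - p->node_time[u]; break; }
    out[k] = t2;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_make_gamete(NumericMatrix parent, int n_chr, int L, int n_cross) {
  // parent: B x 2 matrix of block loads (columns = haplotypes)
  int B = n_chr * L;
  if (parent.nrow() != B || parent.ncol() != 2)
    stop("parent must be a (n_chr*L) x 2 matrix");
  std::vector<double> h0(B), h1(B);
  for (int b = 0; b < B; ++b) { h0[b] = parent(b, 0); h1[b] = parent(b, 1); }
  NumericVector gam(B);
  IntegerVector src(B);
  std::vector<double> g(B);
  std::vector<int> s(B);
  std::vector<int> scratch;
  gamete_from(h0.data(), h1.data(), n_chr, L, n_cross, g.data(), s.data(),
              scratch);
  for (int b = 0; b < B; ++b) { gam[b] = g[b]; src[b] = s[b]; }
  return List::create(_["loads"] = gam, _["source"] = src);
}

// [[Rcpp::export]]
List cpp_mutate_genome(NumericMatrix genome, double Ud, double Ub,
                       double g_shape, double g_scale, double b_mean) {
  // genome: B x 2 block loads; returns mutated copy plus the drawn mutations
  int B = genome.nrow();
  NumericMatrix out = clone(genome);
  int nd = (int)R::rpois(Ud);
  int nb = (int)R::rpois(Ub);
  int n = nd + nb;
  NumericVector s(n);
  IntegerVector hap(n), block(n), type(n);
  for (int m = 0; m < n; ++m) {
    bool del = m < nd;
    double sv = del ? -R::rgamma(g_shape, g_scale) : R::rexp(b_mean);
    int copy = runif_int(2 * B);
    int h = copy / B, b = copy % B;
    double f = 1.0 + sv;
    out(b, h) = (f <= 0.0) ? 0.0 : out(b, h) * f;
    s[m] = sv; hap[m] = h; block[m] = b; type[m] = del ? 0 : 1;
  }
  return List::create(_["loads"] = out,
                      _["mutations"] = DataFrame::create(
                          _["hap"] = hap, _["block"] = block, _["s"] = s,
                          _["type"] = type));
}
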