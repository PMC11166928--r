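#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structured-coalescent simulator for unlinked biallelic SNPs.
//
// Demography: n demes exchanging migrants under an epoch-wise schedule of
// symmetric backward migration matrices (per-generation lineage-movement
// probabilities), all demes merging into a single panmictic ancestral
// population of size anc_ne at split_time generations before present.
// Sizes are haploid; time is continuous in generations (the usual
// continuous-time approximation of the discrete-generation island model).
//
// Each site is an independent genealogy onto which exactly one mutation is
// placed uniformly along the total branch length (fixed-S SNP scheme), so
// every site is polymorphic among the sampled sequences by construction;
// the retention loop below still guards the contract.

namespace {

struct Tree {
  std::vector<int> child1, child2, parent;
  std::vector<double> time;
  int n_leaves;
  int next_node;
  Tree(int S)
      : child1(2 * S - 1, -1), child2(2 * S - 1, -1),
        parent(2 * S - 1, -1), time(2 * S - 1, 0.0), n_leaves(S),
        next_node(S) {}
  int merge(int a, int b, double t) {
    int p = next_node++;
    child1[p] = a;
    child2[p] = b;
    parent[a] = p;
    parent[b] = p;
    time[p] = t;
    return p;
  }
};

// Draw one genealogy and return the derived-allele indicator per leaf.
void simulate_site(const IntegerVector &sample_counts,
                   const NumericVector &deme_sizes, double anc_ne,
                   const NumericVector &epoch_ends,
                   const std::vector<NumericMatrix> &mig,
                   const std::vector<std::vector<double> > &rowsum,
                   double split_time, std::vector<int> &out) {
  const int D = sample_counts.size();
  int S = 0;
  for (int d = 0; d < D; ++d) S += sample_counts[d];

  Tree tree(S);
  std::vector<std::vector<int> > members(D);
  {
    int leaf = 0;
    for (int d = 0; d < D; ++d)
      for (int i = 0; i < sample_counts[d]; ++i) members[d].push_back(leaf++);
  }

  int n_act = S;
  double t = 0.0;
  int epoch = 0;
  const int n_epochs = epoch_ends.size();

  // Per-deme event rates with scalar totals, maintained incrementally:
  // recomputed in full at epoch switches and periodically (to bound float
  // drift), otherwise updated only for the demes an event touches.
  std::vector<double> coal_rate(D), mig_rate(D);
  double coal_tot = 0.0, mig_tot = 0.0;
  long since_refresh = 0;

  #define REFRESH_RATES                                                     \
    do {                                                                    \
      coal_tot = 0.0;                                                       \
      mig_tot = 0.0;                                                        \
      for (int d = 0; d < D; ++d) {                                         \
        double k = static_cast<double>(members[d].size());                  \
        coal_rate[d] = k * (k - 1.0) / 2.0 / deme_sizes[d];                 \
        mig_rate[d] = (epoch < n_epochs) ? k * rowsum[epoch][d] : 0.0;      \
        coal_tot += coal_rate[d];                                           \
        mig_tot += mig_rate[d];                                             \
      }                                                                     \
      since_refresh = 0;                                                    \
    } while (0)

  #define TOUCH_DEME(d)                                                     \
    do {                                                                    \
      double k = static_cast<double>(members[d].size());                    \
      double nc = k * (k - 1.0) / 2.0 / deme_sizes[d];                      \
      double nm = (epoch < n_epochs) ? k * rowsum[epoch][d] : 0.0;          \
      coal_tot += nc - coal_rate[d];                                        \
      mig_tot += nm - mig_rate[d];                                          \
      coal_rate[d] = nc;                                                    \
      mig_rate[d] = nm;                                                     \
    } while (0)

  REFRESH_RATES;

  // Island phase: migration + within-deme coalescence until split_time.
  while (n_act > 1 && t < split_time) {
    double t_next = split_time;
    if (epoch < n_epochs && epoch_ends[epoch] < t_next)
      t_next = epoch_ends[epoch];

    if (++since_refresh >= 8192) REFRESH_RATES;
    double R = coal_tot + mig_tot;
    if (R <= 1e-300) {
      t = t_next;
      if (epoch < n_epochs && t >= epoch_ends[epoch]) ++epoch;
      REFRESH_RATES;
      continue;
    }
    double dt = exp_rand() / R;
    if (t + dt >= t_next) {
      t = t_next;
      if (epoch < n_epochs && t >= epoch_ends[epoch]) ++epoch;
      REFRESH_RATES;
      continue;
    }
    t += dt;
    double u = unif_rand() * R;
    if (u < coal_tot) {
      int d = 0;
      while (d < D - 1 && u >= coal_rate[d]) u -= coal_rate[d], ++d;
      std::vector<int> &mem = members[d];
      int k = static_cast<int>(mem.size());
      if (k < 2) { REFRESH_RATES; continue; } // drift guard
      int a = static_cast<int>(unif_rand() * k);
      if (a >= k) a = k - 1;
      int b = static_cast<int>(unif_rand() * (k - 1));
      if (b >= k - 1) b = k - 2;
      if (b >= a) ++b;
      int p = tree.merge(mem[a], mem[b], t);
      // swap-remove the two children, insert the parent
      int hi = (a > b) ? a : b, lo = (a > b) ? b : a;
      mem[hi] = mem.back();
      mem.pop_back();
      mem[lo] = mem.back();
      mem.pop_back();
      mem.push_back(p);
      --n_act;
      TOUCH_DEME(d);
    } else {
      u -= coal_tot;
      int d = 0;
      while (d < D - 1 && u >= mig_rate[d]) u -= mig_rate[d], ++d;
      std::vector<int> &mem = members[d];
      int k = static_cast<int>(mem.size());
      if (k < 1) { REFRESH_RATES; continue; } // drift guard
      int a = static_cast<int>(unif_rand() * k);
      if (a >= k) a = k - 1;
      const NumericMatrix &M = mig[epoch];
      double v = unif_rand() * rowsum[epoch][d];
      int dest = -1;
      for (int j = 0; j < D; ++j) {
        if (j == d) continue;
        v -= M(d, j);
        if (v <= 0.0) {
          dest = j;
          break;
        }
      }
      if (dest < 0) { // numerical slack: last positive entry
        for (int j = D - 1; j >= 0; --j)
          if (j != d && M(d, j) > 0.0) {
            dest = j;
            break;
          }
      }
      if (dest >= 0) {
        members[dest].push_back(mem[a]);
        mem[a] = mem.back();
        mem.pop_back();
        TOUCH_DEME(d);
        TOUCH_DEME(dest);
      }
    }
  }
  #undef REFRESH_RATES
  #undef TOUCH_DEME

  // Ancestral panmictic phase.
  if (n_act > 1) {
    std::vector<int> pool;
    for (int d = 0; d < D; ++d)
      for (size_t i = 0; i < members[d].size(); ++i)
        pool.push_back(members[d][i]);
    if (t < split_time) t = split_time;
    while (pool.size() > 1) {
      double k = static_cast<double>(pool.size());
      double rate = k * (k - 1.0) / 2.0 / anc_ne;
      t += exp_rand() / rate;
      int n = static_cast<int>(pool.size());
      int a = static_cast<int>(unif_rand() * n);
      if (a >= n) a = n - 1;
      int b = static_cast<int>(unif_rand() * (n - 1));
      if (b >= n - 1) b = n - 2;
      if (b >= a) ++b;
      int p = tree.merge(pool[a], pool[b], t);
      int hi = (a > b) ? a : b, lo = (a > b) ? b : a;
      pool[hi] = pool.back();
      pool.pop_back();
      pool[lo] = pool.back();
      pool.pop_back();
      pool.push_back(p);
    }
  }

  // One mutation uniform on total branch length; derived = leaves below it.
  int root = 2 * S - 2;
  double total_len = 0.0;
  for (int v = 0; v < root; ++v) total_len += tree.time[tree.parent[v]] - tree.time[v];
  double u = unif_rand() * total_len;
  int hit = root - 1;
  for (int v = 0; v < root; ++v) {
    u -= tree.time[tree.parent[v]] - tree.time[v];
    if (u <= 0.0) {
      hit = v;
      break;
    }
  }
  std::fill(out.begin(), out.end(), 0);
  std::vector<int> stack;
  stack.push_back(hit);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    if (tree.child1[v] < 0) {
      out[v] = 1;
    } else {
      stack.push_back(tree.child1[v]);
      stack.push_back(tree.child2[v]);
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".sim_snp_sites")]]
IntegerMatrix sim_snp_sites(IntegerVector sample_counts,
                            NumericVector deme_sizes, double anc_ne,
                            NumericVector epoch_ends, List mig_matrices,
                            double split_time, int n_snps,
                            int max_tries_factor = 10) {
  const int D = sample_counts.size();
  if (deme_sizes.size() != D) stop("deme_sizes and sample_counts disagree");
  int S = 0;
  for (int d = 0; d < D; ++d) {
    if (sample_counts[d] < 0) stop("negative sample count");
    if (deme_sizes[d] <= 0) stop("deme sizes must be positive");
    S += sample_counts[d];
  }
  if (S < 2) stop("need at least 2 sampled sequences");
  if (anc_ne <= 0) stop("ancestral size must be positive");

  const int n_epochs = epoch_ends.size();
  if (mig_matrices.size() != n_epochs)
    stop("one migration matrix per epoch required");
  std::vector<NumericMatrix> mig;
  std::vector<std::vector<double> > rowsum;
  for (int e = 0; e < n_epochs; ++e) {
    NumericMatrix M = mig_matrices[e];
    if (M.nrow() != D || M.ncol() != D) stop("migration matrix dimension mismatch");
    std::vector<double> rs(D, 0.0);
    for (int i = 0; i < D; ++i)
      for (int j = 0; j < D; ++j)
        if (j != i) {
          if (M(i, j) < 0) stop("negative migration rate");
          rs[i] += M(i, j);
        }
    mig.push_back(M);
    rowsum.push_back(rs);
  }

  IntegerMatrix geno(S, n_snps);
  std::vector<int> site(S);
  long max_tries = static_cast<long>(max_tries_factor) * n_snps + 100;
  long tries = 0;
  int filled = 0;
  while (filled < n_snps) {
    if (++tries > max_tries)
      stop("simulation yield failure: %d polymorphic sites after %ld attempts",
           filled, tries - 1);
    simulate_site(sample_counts, deme_sizes, anc_ne, epoch_ends, mig, rowsum,
                  split_time, site);
    int c1 = 0;
    for (int i = 0; i < S; ++i) c1 += site[i];
    if (c1 == 0 || c1 == S) continue; // monomorphic: discard, top up
    bool flip = 2 * c1 > S;           // code the minor allele as 1
    for (int i = 0; i < S; ++i) geno(i, filled) = flip ? 1 - site[i] : site[i];
    ++filled;
    if (filled % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return geno;
}
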