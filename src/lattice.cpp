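// Hexagonal-lattice simulator of stem-cell clonal dynamics.
//
// Site kinds: 0 = empty, 1 = wild-type stem (A), 2 = advantaged mutant stem (B),
// 3 = transit-amplifying (C). Grids are R matrices with nrow = height (rows) and
// ncol = width (columns), column-major; internal index idx = col * H + row.
//
// Hex adjacency uses odd-row ("odd-r") offset coordinates. Toroidal wrap
// requires an even number of rows (validated on the R side) so that row parity
// is consistent across the seam.
//
// Within-day phase order (documented in the package vignette):
//   1. stem losses, sampled simultaneously (Bernoulli per cell);
//   2. vacancies filled in uniformly random order, donor uniform among
//      occupied stem neighbours;
//   3. neutral then non-neutral mutations (fresh clone labels);
//   4. heterogeneous compartment: differentiation, TA division into remaining
//      vacancies, TA loss;
//   5. migration (plain swaps, or energy-gated in heterogeneous mode).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

enum Kind { K_EMPTY = 0, K_A = 1, K_B = 2, K_C = 3 };

// Offsets for odd-r hex layout: {even-row set, odd-row set}, each 6 x (dr, dc).
static const int HEX_DR[6] = {0, 0, -1, -1, 1, 1};
static const int HEX_DC_EVEN[6] = {-1, 1, -1, 0, -1, 0};
static const int HEX_DC_ODD[6] = {-1, 1, 0, 1, 0, 1};

// Fill out[] with up to 6 neighbour indices; returns count.
static inline int hex_nbrs(int site, int H, int W, bool torus, int *out) {
  int r = site % H, c = site / H;
  const int *dc = (r % 2 == 0) ? HEX_DC_EVEN : HEX_DC_ODD;
  int k = 0;
  for (int d = 0; d < 6; ++d) {
    int rr = r + HEX_DR[d], cc = c + dc[d];
    if (torus) {
      rr = (rr + H) % H;
      cc = (cc + W) % W;
    } else if (rr < 0 || rr >= H || cc < 0 || cc >= W) {
      continue;
    }
    out[k++] = cc * H + rr;
  }
  return k;
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbors(int row, int col, int height, int width, bool torus) {
  // row, col are 0-based here; the R wrapper handles 1-based conversion.
  int out[6];
  int site = col * height + row;
  int k = hex_nbrs(site, height, width, torus, out);
  IntegerMatrix res(k, 2);
  for (int i = 0; i < k; ++i) {
    res(i, 0) = out[i] % height;
    res(i, 1) = out[i] / height;
  }
  return res;
}

struct Tree {
  std::vector<int> parent, birth, cls;   // cls: 0 root, 1 neutral, 2 non-neutral
  std::vector<double> live;
  std::vector<char> active;
  int new_label(int par, int day, int cl) {
    parent.push_back(par);
    birth.push_back(day);
    cls.push_back(cl);
    live.push_back(0.0);
    active.push_back(1);
    return (int)parent.size() - 1;
  }
};

// Lattice-energy of one site given current occupancy (empty sites: 0).
static double site_energy(const std::vector<int> &kind, const int *diff,
                          double penalty, int site, int H, int W, bool torus) {
  int k = kind[site];
  if (k == K_EMPTY) return 0.0;
  int nb[6];
  int n = hex_nbrs(site, H, W, torus, nb);
  int n_stem = 0, n_ta = 0, n_empty = 0;
  for (int i = 0; i < n; ++i) {
    int kk = kind[nb[i]];
    if (kk == K_A || kk == K_B) ++n_stem;
    else if (kk == K_C) ++n_ta;
    else ++n_empty;
  }
  double d = diff ? (double)diff[site] : 0.0;
  if (k == K_A || k == K_B) return (double)n_ta + d * penalty;
  return (double)n_stem - (double)n_empty + (1.0 - d) * penalty;
}

// [[Rcpp::export]]
double cpp_total_energy(IntegerMatrix kind, Nullable<IntegerMatrix> diff_map,
                        double penalty, bool torus) {
  int H = kind.nrow(), W = kind.ncol(), N = H * W;
  std::vector<int> kv(kind.begin(), kind.end());
  const int *diff = NULL;
  IntegerMatrix dm;
  if (diff_map.isNotNull()) {
    dm = diff_map.get();
    diff = INTEGER(dm);
  }
  double e = 0.0;
  for (int i = 0; i < N; ++i) e += site_energy(kv, diff, penalty, i, H, W, torus);
  return e;
}

static inline int runif_int(int n) {  // uniform on 0..n-1
  int k;
  do { k = (int)(unif_rand() * n); } while (k >= n);
  return k;
}

// One migration sweep over all adjacent pairs (each pair visited once via the
// three "forward" directions). Energy-gated when `gated` is true: a proposed
// swap is applied only if it strictly lowers the total lattice energy.
static void migrate_sweep(std::vector<int> &kind, std::vector<int> &label,
                          std::vector<int> &qv, double p_swap, bool gated,
                          const int *diff, double penalty, int H, int W, bool torus) {
  if (p_swap <= 0) return;
  int N = H * W;
  int nb[6], nbi[6], nbj[6];
  for (int i = 0; i < N; ++i) {
    int n = hex_nbrs(i, H, W, torus, nb);
    int r = i % H;
    const int *dc = (r % 2 == 0) ? HEX_DC_EVEN : HEX_DC_ODD;
    for (int d = 0; d < 6; ++d) {
      // forward directions only: (0,+1) and the two dr=+1 offsets
      if (!(HEX_DR[d] == 1 || (HEX_DR[d] == 0 && dc[d] == 1))) continue;
      // recover the neighbour for this offset (may be clipped)
      int rr = r + HEX_DR[d], cc = i / H + dc[d];
      if (torus) { rr = (rr + H) % H; cc = (cc + W) % W; }
      else if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      int j = cc * H + rr;
      if (j == i) continue;
      if (kind[i] == K_EMPTY && kind[j] == K_EMPTY) continue;
      if (unif_rand() >= p_swap) continue;
      if (gated) {
        // total energy restricted to the sites whose terms can change
        int ni = hex_nbrs(i, H, W, torus, nbi);
        int nj = hex_nbrs(j, H, W, torus, nbj);
        double before = site_energy(kind, diff, penalty, i, H, W, torus) +
                        site_energy(kind, diff, penalty, j, H, W, torus);
        for (int t = 0; t < ni; ++t) if (nbi[t] != j) before += site_energy(kind, diff, penalty, nbi[t], H, W, torus);
        for (int t = 0; t < nj; ++t) if (nbj[t] != i && nbj[t] != i) before += site_energy(kind, diff, penalty, nbj[t], H, W, torus);
        std::swap(kind[i], kind[j]); std::swap(label[i], label[j]); std::swap(qv[i], qv[j]);
        double after = site_energy(kind, diff, penalty, i, H, W, torus) +
                       site_energy(kind, diff, penalty, j, H, W, torus);
        for (int t = 0; t < ni; ++t) if (nbi[t] != j) after += site_energy(kind, diff, penalty, nbi[t], H, W, torus);
        for (int t = 0; t < nj; ++t) if (nbj[t] != i) after += site_energy(kind, diff, penalty, nbj[t], H, W, torus);
        if (!(after < before)) {  // reject: revert
          std::swap(kind[i], kind[j]); std::swap(label[i], label[j]); std::swap(qv[i], qv[j]);
        }
      } else {
        std::swap(kind[i], kind[j]); std::swap(label[i], label[j]); std::swap(qv[i], qv[j]);
      }
    }
  }
  (void)nb;
}

// [[Rcpp::export]]
List cpp_migrate(IntegerMatrix kind, IntegerMatrix label, IntegerMatrix qmat,
                 double p_swap, bool gated, Nullable<IntegerMatrix> diff_map,
                 double penalty, bool torus) {
  int H = kind.nrow(), W = kind.ncol();
  std::vector<int> kv(kind.begin(), kind.end());
  std::vector<int> lv(label.begin(), label.end());
  std::vector<int> qv(qmat.begin(), qmat.end());
  const int *diff = NULL;
  IntegerMatrix dm;
  if (diff_map.isNotNull()) { dm = diff_map.get(); diff = INTEGER(dm); }
  migrate_sweep(kv, lv, qv, p_swap, gated, diff, penalty, H, W, torus);
  IntegerMatrix ko(H, W), lo(H, W), qo(H, W);
  std::copy(kv.begin(), kv.end(), ko.begin());
  std::copy(lv.begin(), lv.end(), lo.begin());
  std::copy(qv.begin(), qv.end(), qo.begin());
  return List::create(_["kind"] = ko, _["label"] = lo, _["q"] = qo);
}

// Recursive clone sizes: labels are assigned in increasing order so every
// parent label is smaller than its children; one reverse pass accumulates
// sum(n) = live(n) + sum over children.
static void recursive_sizes(const Tree &tr, std::vector<double> &rec) {
  int n = (int)tr.parent.size();
  rec.assign(tr.live.begin(), tr.live.end());
  for (int i = n - 1; i >= 1; --i) {
    if (rec[i] != 0.0) rec[tr.parent[i]] += rec[i];
  }
}

// [[Rcpp::export]]
List cpp_sim_run(IntegerMatrix kind, IntegerMatrix label, IntegerMatrix qmat,
                 IntegerVector tree_parent, IntegerVector tree_birth,
                 IntegerVector tree_class, NumericVector tree_live,
                 LogicalVector tree_active, List par, bool heterogeneous,
                 Nullable<IntegerMatrix> diff_map, int start_day, int n_days,
                 IntegerVector checkpoint_days, int purge_every) {
  int H = kind.nrow(), W = kind.ncol(), N = H * W;
  bool torus = as<bool>(par["torus"]);
  double p_loss_a = as<double>(par["p_loss_a"]);
  double p_loss_b = as<double>(par["p_loss_b"]);
  double p_mut = as<double>(par["p_mut"]);
  double p_nn = as<double>(par["p_nn"]);
  double p_swap = as<double>(par["p_swap"]);
  double p_diff = as<double>(par["p_diff"]);
  double p_tadiv = as<double>(par["p_tadiv"]);
  double p_taloss = as<double>(par["p_taloss"]);
  int q_max = as<int>(par["q_max"]);
  double penalty = as<double>(par["penalty"]);

  std::vector<int> kv(kind.begin(), kind.end());
  std::vector<int> lv(label.begin(), label.end());
  std::vector<int> qv(qmat.begin(), qmat.end());
  const int *diff = NULL;
  IntegerMatrix dm;
  if (diff_map.isNotNull()) { dm = diff_map.get(); diff = INTEGER(dm); }

  Tree tr;
  int n0 = tree_parent.size();
  tr.parent.assign(tree_parent.begin(), tree_parent.end());
  tr.birth.assign(tree_birth.begin(), tree_birth.end());
  tr.cls.assign(tree_class.begin(), tree_class.end());
  tr.live.assign(tree_live.begin(), tree_live.end());
  tr.active.resize(n0);
  for (int i = 0; i < n0; ++i) tr.active[i] = tree_active[i] ? 1 : 0;

  std::vector<int> empties;
  empties.reserve(N / 8 + 16);
  std::vector<int> keep;
  keep.reserve(N / 8 + 16);
  int nb[6], donors[6];

  // checkpoint bookkeeping
  std::vector<int> cps(checkpoint_days.begin(), checkpoint_days.end());
  std::sort(cps.begin(), cps.end());
  size_t cp_i = 0;
  while (cp_i < cps.size() && cps[cp_i] <= start_day) ++cp_i;
  std::vector<int> out_day, out_label, out_parent, out_class, out_birth;
  std::vector<double> out_cells;
  std::vector<double> rec;

  RNGScope scope;

  // persistent bookkeeping: vacancy list and stem-cell counts
  int n_a = 0, n_b = 0;
  for (int i = 0; i < N; ++i) {
    if (kv[i] == K_EMPTY) empties.push_back(i);
    else if (kv[i] == K_A) ++n_a;
    else if (kv[i] == K_B) ++n_b;
  }

  for (int d = 1; d <= n_days; ++d) {
    int day = start_day + d;

    // Phase 1: simultaneous stem losses. A binomial count of losses with
    // uniform distinct site selection is equivalent to an independent
    // Bernoulli draw per cell.
    if (p_loss_a > 0 && n_a > 0) {
      int k = (int)R::rbinom((double)n_a, p_loss_a);
      for (int t = 0; t < k; ++t) {
        int site;
        do { site = runif_int(N); } while (kv[site] != K_A);
        tr.live[lv[site]] -= 1; kv[site] = K_EMPTY; lv[site] = -1;
        empties.push_back(site); --n_a;
      }
    }
    if (p_loss_b > 0 && n_b > 0) {
      int k = (int)R::rbinom((double)n_b, p_loss_b);
      for (int t = 0; t < k; ++t) {
        int site;
        do { site = runif_int(N); } while (kv[site] != K_B);
        tr.live[lv[site]] -= 1; kv[site] = K_EMPTY; lv[site] = -1;
        empties.push_back(site); --n_b;
      }
    }

    // Phase 2: fill vacancies in random order; donor uniform among occupied
    // stem (A/B) neighbours; a vacancy with no stem neighbour stays empty.
    if (!empties.empty()) {
      for (int i = (int)empties.size() - 1; i > 0; --i)
        std::swap(empties[i], empties[runif_int(i + 1)]);
      keep.clear();
      for (size_t e = 0; e < empties.size(); ++e) {
        int site = empties[e];
        int n = hex_nbrs(site, H, W, torus, nb);
        int nd = 0;
        for (int t = 0; t < n; ++t)
          if (kv[nb[t]] == K_A || kv[nb[t]] == K_B) donors[nd++] = nb[t];
        if (nd == 0) { keep.push_back(site); continue; }
        int don = donors[nd == 1 ? 0 : runif_int(nd)];
        kv[site] = kv[don]; lv[site] = lv[don]; qv[site] = 0;
        tr.live[lv[site]] += 1;
        if (kv[site] == K_A) ++n_a; else ++n_b;
      }
      empties.swap(keep);
    }

    // Phase 3: mutations. Event counts are binomial over the eligible pool;
    // event sites drawn uniformly by rejection (the lattice is mostly full).
    int n_occ = N - (int)empties.size();
    if (p_mut > 0 && n_occ > 0) {
      int n_mut = (int)R::rbinom((double)n_occ, p_mut);
      for (int m = 0; m < n_mut; ++m) {
        int site;
        do { site = runif_int(N); } while (kv[site] == K_EMPTY);
        int old = lv[site];
        int lab = tr.new_label(old, day, 1);
        tr.live[old] -= 1; tr.live[lab] += 1; lv[site] = lab;
      }
    }
    if (p_nn > 0 && n_a > 0) {
      int n_nn = (int)R::rbinom((double)n_a, p_nn);
      for (int m = 0; m < n_nn && n_a > 0; ++m) {
        int site, guard = 0;
        do { site = runif_int(N); } while (kv[site] != K_A && ++guard < 100 * N);
        if (kv[site] != K_A) break;
        int old = lv[site];
        int lab = tr.new_label(old, day, 2);
        tr.live[old] -= 1; tr.live[lab] += 1; lv[site] = lab;
        kv[site] = K_B; --n_a; ++n_b;
      }
    }

    // Phase 4: heterogeneous compartment.
    if (heterogeneous) {
      // 4a. differentiation A -> C (q = 0) where diff(i) = 1
      if (p_diff > 0 && diff) {
        for (int i = 0; i < N; ++i)
          if (kv[i] == K_A && diff[i] == 1 && unif_rand() < p_diff) {
            kv[i] = K_C; qv[i] = 0; --n_a;
          }
      }
      // 4b. TA division into remaining vacancies; both daughters carry q + 1
      if (p_tadiv > 0 && !empties.empty()) {
        for (int i = (int)empties.size() - 1; i > 0; --i)
          std::swap(empties[i], empties[runif_int(i + 1)]);
        keep.clear();
        for (size_t e = 0; e < empties.size(); ++e) {
          int site = empties[e];
          int n = hex_nbrs(site, H, W, torus, nb);
          int nd = 0;
          for (int t = 0; t < n; ++t)
            if (kv[nb[t]] == K_C && qv[nb[t]] < q_max) donors[nd++] = nb[t];
          if (nd == 0 || unif_rand() >= p_tadiv) { keep.push_back(site); continue; }
          int don = donors[nd == 1 ? 0 : runif_int(nd)];
          kv[site] = K_C; lv[site] = lv[don]; qv[site] = qv[don] + 1;
          qv[don] = qv[don] + 1;
          tr.live[lv[site]] += 1;
        }
        empties.swap(keep);
      }
      // 4c. TA loss
      if (p_taloss > 0) {
        for (int i = 0; i < N; ++i)
          if (kv[i] == K_C && unif_rand() < p_taloss) {
            tr.live[lv[i]] -= 1; kv[i] = K_EMPTY; lv[i] = -1; qv[i] = 0;
            empties.push_back(i);
          }
      }
    }

    // Phase 5: migration
    migrate_sweep(kv, lv, qv, p_swap, heterogeneous, diff, penalty, H, W, torus);

    // Purge: tombstone clone records with no surviving members or descendants.
    if (purge_every > 0 && day % purge_every == 0) {
      recursive_sizes(tr, rec);
      for (size_t i = 1; i < tr.parent.size(); ++i)
        if (tr.active[i] && rec[i] == 0.0) tr.active[i] = 0;
    }

    // Checkpoint: recursive clone sizes of live clones.
    while (cp_i < cps.size() && cps[cp_i] == day) {
      recursive_sizes(tr, rec);
      for (size_t i = 0; i < tr.parent.size(); ++i) {
        if (!tr.active[i] || rec[i] == 0.0) continue;
        out_day.push_back(day);
        out_label.push_back((int)i);
        out_parent.push_back(tr.parent[i]);
        out_class.push_back(tr.cls[i]);
        out_birth.push_back(tr.birth[i]);
        out_cells.push_back(rec[i]);
      }
      ++cp_i;
    }
  }

  IntegerMatrix ko(H, W), lo(H, W), qo(H, W);
  std::copy(kv.begin(), kv.end(), ko.begin());
  std::copy(lv.begin(), lv.end(), lo.begin());
  std::copy(qv.begin(), qv.end(), qo.begin());

  int nt = (int)tr.parent.size();
  IntegerVector tp(nt), tb(nt), tc(nt);
  NumericVector tl(nt);
  LogicalVector ta(nt);
  for (int i = 0; i < nt; ++i) {
    tp[i] = tr.parent[i]; tb[i] = tr.birth[i]; tc[i] = tr.cls[i];
    tl[i] = tr.live[i]; ta[i] = tr.active[i] != 0;
  }

  return List::create(
    _["kind"] = ko, _["label"] = lo, _["q"] = qo,
    _["tree_parent"] = tp, _["tree_birth"] = tb, _["tree_class"] = tc,
    _["tree_live"] = tl, _["tree_active"] = ta,
    _["cp_day"] = wrap(out_day), _["cp_label"] = wrap(out_label),
    _["cp_parent"] = wrap(out_parent), _["cp_class"] = wrap(out_class),
    _["cp_birth"] = wrap(out_birth), _["cp_cells"] = wrap(out_cells),
    _["end_day"] = start_day + n_days);
}

// [[Rcpp::export]]
NumericVector cpp_recursive_sizes(IntegerVector parent, NumericVector live) {
  int n = parent.size();
  NumericVector rec = clone(live);
  for (int i = n - 1; i >= 1; --i)
    if (rec[i] != 0.0) rec[parent[i]] += rec[i];
  return rec;
}
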