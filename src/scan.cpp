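#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sequences are encoded as integers: 1=A, 2=C, 3=G, 4=T, 0=masked/ambiguous.
// A masked base contributes frequency 0 to every score it participates in.

// Flattened matrix payload for fast scanning: w5[i*5 + b] = Ci * f(i, b)
// for b in 1..4, and 0 for the masked symbol b = 0.
struct FlatPwm {
  std::vector<double> w5;        // L x 5
  std::vector<double> core_w5;   // nc x 5 (core columns only)
  std::vector<int> core_off;     // 0-based core position offsets
  double den_all, den_core;
  int L, nc;
};

static FlatPwm flatten(const NumericMatrix& w, const NumericVector& colmax,
                       const IntegerVector& core) {
  FlatPwm f;
  f.L = w.ncol();
  f.nc = core.size();
  f.w5.assign(5 * f.L, 0.0);
  for (int i = 0; i < f.L; ++i)
    for (int b = 0; b < 4; ++b) f.w5[i * 5 + b + 1] = w(b, i);
  f.den_all = 0.0; f.den_core = 0.0;
  for (int i = 0; i < f.L; ++i) f.den_all += colmax[i];
  f.core_w5.assign(5 * f.nc, 0.0);
  f.core_off.resize(f.nc);
  for (int j = 0; j < f.nc; ++j) {
    int c = core[j] - 1;
    f.core_off[j] = c;
    f.den_core += colmax[c];
    for (int b = 0; b < 5; ++b) f.core_w5[j * 5 + b] = f.w5[c * 5 + b];
  }
  return f;
}

// Scan one encoded sequence with a flattened matrix; a window is a hit when
// core similarity >= core_threshold AND full similarity >= threshold.
static void scan_flat(const int* s, int n, const FlatPwm& f,
                      double threshold, double core_threshold,
                      std::vector<std::pair<int,double> >& out) {
  if (n < f.L || f.L == 0) return;
  const double core_cut = core_threshold * f.den_core - 1e-9;
  const double full_cut = threshold * f.den_all - 1e-9;
  const double* w5 = f.w5.data();
  const double* cw5 = f.core_w5.data();
  const int* coff = f.core_off.data();
  const int L = f.L, nc = f.nc;
  for (int p = 0; p + L <= n; ++p) {
    const int* sp = s + p;
    double cnum = 0.0;
    for (int j = 0; j < nc; ++j) cnum += cw5[j * 5 + sp[coff[j]]];
    if (cnum < core_cut) continue;
    double num = 0.0;
    for (int i = 0; i < L; ++i) num += w5[i * 5 + sp[i]];
    if (num >= full_cut)
      out.push_back(std::make_pair(p, f.den_all > 0 ? num / f.den_all : 0.0));
  }
}

// [[Rcpp::export]]
List mss_scan_cpp(IntegerVector seq, NumericMatrix w, NumericVector colmax,
                  IntegerVector core, double threshold, double core_threshold) {
  FlatPwm f = flatten(w, colmax, core);
  std::vector<std::pair<int,double> > hits;
  scan_flat(INTEGER(seq), seq.size(), f, threshold, core_threshold, hits);
  IntegerVector starts(hits.size());
  NumericVector scores(hits.size());
  for (size_t k = 0; k < hits.size(); ++k) {
    starts[k] = hits[k].first + 1;             // 1-based window start
    scores[k] = hits[k].second;
  }
  return List::create(_["start"] = starts, _["score"] = scores);
}

// ---- Altschul-Erickson dinucleotide-preserving shuffle -------------------

// Shuffle one run of unmasked bases in place. Preserves the exact
// dinucleotide multiset and the first and last characters of the run.
static void ae_shuffle_run(std::vector<int>& s, int from, int to) {
  const int m = to - from;             // run length
  if (m <= 3) return;                  // nothing can move
  const int A = 5;                     // symbols 1..4 (index 0 unused)
  std::vector<std::vector<int> > adj(A);
  for (int i = from; i + 1 < to; ++i) adj[s[i]].push_back(s[i + 1]);
  const int first = s[from], last = s[to - 1];
  bool trivial = true;
  for (int i = from + 1; i < to; ++i) if (s[i] != first) { trivial = false; break; }
  if (trivial) return;                 // single-letter run

  std::vector<int> last_edge(A, -1);
  // choose a random "last edge" per vertex until they form a tree into `last`
  for (int tries = 0; tries < 100000; ++tries) {
    for (int v = 1; v < A; ++v) {
      last_edge[v] = -1;
      if (v != last && !adj[v].empty())
        last_edge[v] = adj[v][(int)(unif_rand() * adj[v].size())];
    }
    bool ok = true;
    for (int v = 1; v < A && ok; ++v) {
      if (v == last || adj[v].empty()) continue;
      int cur = v;
      for (int step = 0; step < A; ++step) {
        if (cur == last) break;
        cur = last_edge[cur];
        if (cur < 0) break;
      }
      if (cur != last) ok = false;
    }
    if (ok) break;
    if (tries == 99999) return;        // give up, leave run unchanged
  }
  // permute remaining edges, append the reserved last edge
  for (int v = 1; v < A; ++v) {
    std::vector<int>& e = adj[v];
    if (e.empty()) continue;
    if (last_edge[v] >= 0) {
      for (size_t k = 0; k < e.size(); ++k)
        if (e[k] == last_edge[v]) { e.erase(e.begin() + k); break; }
    }
    for (int k = (int)e.size() - 1; k > 0; --k) {
      int j = (int)(unif_rand() * (k + 1));
      std::swap(e[k], e[j]);
    }
    if (last_edge[v] >= 0) e.push_back(last_edge[v]);
  }
  // Eulerian walk
  std::vector<int> ptr(A, 0);
  int cur = first;
  for (int i = from + 1; i < to; ++i) {
    int nxt = adj[cur][ptr[cur]++];
    s[i] = nxt;
    cur = nxt;
  }
}

// [[Rcpp::export]]
IntegerVector dinuc_shuffle_cpp(IntegerVector seq) {
  const int n = seq.size();
  std::vector<int> s(seq.begin(), seq.end());
  int i = 0;
  while (i < n) {
    if (s[i] == 0) { ++i; continue; }
    int j = i;
    while (j < n && s[j] != 0) ++j;    // [i, j) unmasked run
    ae_shuffle_run(s, i, j);
    i = j;
  }
  return wrap(s);
}

// ---- batched shuffle-null counting ---------------------------------------

// seqs: list of integer vectors; masks: list of integer vectors of 1-based
// positions to zero out AFTER shuffling (the mask-after-shuffle order, so
// every replicate analyses the same amount of sequence as the real set);
// B replicates. For each replicate, each promoter is shuffled, masked and
// scanned with every matrix on both strands; per family, transitively
// overlapping hits collapse to one (the same pruning as on real data).
// Returns an nfam x B matrix of pooled pruned counts.
// [[Rcpp::export]]
NumericMatrix shuffle_family_counts_cpp(List seqs, List w_list, List wrc_list,
                                        List colmax_list, List colmaxrc_list,
                                        List core_list, List corerc_list,
                                        NumericVector thresholds,
                                        IntegerVector fam_index, int nfam,
                                        List masks, int B,
                                        double core_threshold) {
  const int npwm = w_list.size(), nseq = seqs.size();
  std::vector<FlatPwm> F(npwm), Frc(npwm);
  for (int k = 0; k < npwm; ++k) {
    F[k] = flatten(as<NumericMatrix>(w_list[k]),
                   as<NumericVector>(colmax_list[k]),
                   as<IntegerVector>(core_list[k]));
    Frc[k] = flatten(as<NumericMatrix>(wrc_list[k]),
                     as<NumericVector>(colmaxrc_list[k]),
                     as<IntegerVector>(corerc_list[k]));
  }
  NumericMatrix counts(nfam, B);
  std::vector<std::vector<std::pair<int,int> > > fam_iv(nfam);
  std::vector<std::pair<int,double> > tmp;
  for (int b = 0; b < B; ++b) {
    for (int si = 0; si < nseq; ++si) {
      IntegerVector sv = seqs[si];
      std::vector<int> s(sv.begin(), sv.end());
      int i = 0, n = (int)s.size();
      while (i < n) {
        if (s[i] == 0) { ++i; continue; }
        int j = i;
        while (j < n && s[j] != 0) ++j;
        ae_shuffle_run(s, i, j);
        i = j;
      }
      IntegerVector mk = masks[si];
      for (int m = 0; m < mk.size(); ++m) s[mk[m] - 1] = 0;
      for (int f = 0; f < nfam; ++f) fam_iv[f].clear();
      for (int k = 0; k < npwm; ++k) {
        std::vector<std::pair<int,int> >& iv = fam_iv[fam_index[k] - 1];
        tmp.clear();
        scan_flat(s.data(), n, F[k], thresholds[k], core_threshold, tmp);
        scan_flat(s.data(), n, Frc[k], thresholds[k], core_threshold, tmp);
        for (size_t q = 0; q < tmp.size(); ++q)
          iv.push_back(std::make_pair(tmp[q].first, tmp[q].first + F[k].L));
      }
      for (int f = 0; f < nfam; ++f) {
        std::vector<std::pair<int,int> >& h = fam_iv[f];
        if (h.empty()) continue;
        std::sort(h.begin(), h.end());
        int groups = 1, maxend = h[0].second;
        for (size_t q = 1; q < h.size(); ++q) {
          if (h[q].first >= maxend) { ++groups; maxend = h[q].second; }
          else if (h[q].second > maxend) maxend = h[q].second;
        }
        counts(f, b) += groups;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return counts;
}
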