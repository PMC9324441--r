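#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Exact quartet bookkeeping for leaf-labeled trees given as split sets.
// A tree (species tree or input locus) is represented by the list of one
// side of each of its nontrivial splits, as integer taxon ids.  For every
// 4-subset of a locus's leaves the induced quartet topology is recorded
// once (an edge splits a 4-subset 2v2 only if it lies on the quartet's
// central path, so repeated assignments are consistent), together with the
// minimum edge weight along that path (the weight of the induced quartet).

namespace {

// rank of sorted 0-based quartet a<b<c<d among C(m,4) combinations
struct ChooseTab {
  std::vector<double> c2, c3, c4;
  explicit ChooseTab(int m) : c2(m, 0.0), c3(m, 0.0), c4(m, 0.0) {
    for (int i = 0; i < m; ++i) {
      c2[i] = (double)i * (i - 1) / 2.0;
      c3[i] = c2[i] * (i - 2) / 3.0;
      c4[i] = c3[i] * (i - 3) / 4.0;
    }
  }
  inline size_t rank(int a, int b, int c, int d) const {
    return (size_t)(c4[d] + c3[c] + c2[b] + a);
  }
  inline size_t n4(int m) const {
    return m < 4 ? 0 : (size_t)((double)m * (m - 1) * (m - 2) * (m - 3) / 24.0);
  }
};

// pairing code of quartet {i,j,k,l} (sorted internally) where {p1,p2} is
// one cherry: 1 = lo12|hi34, 2 = 13|24, 3 = 14|23
inline int pairing_code(int p1, int p2, const int four[4]) {
  const int lo = std::min(p1, p2), hi = std::max(p1, p2);
  if (lo == four[0]) {
    if (hi == four[1]) return 1;
    if (hi == four[2]) return 2;
    return 3;
  }
  // cherry excludes the smallest element: complement pairing
  if (lo == four[2]) return 1;          // {c,d} -> ab|cd
  if (hi == four[3]) return 2;          // {b,d} -> ac|bd
  return 3;                             // {b,c} -> ad|bc
}

// fill topo (and optionally wmin) tables for a tree on m local leaves
void fill_tables(const std::vector<std::vector<int> > &sides_local, int m,
                 const std::vector<double> *weights, const ChooseTab &ct,
                 std::vector<signed char> &topo, std::vector<double> *wmin) {
  std::vector<char> inA(m);
  for (size_t s = 0; s < sides_local.size(); ++s) {
    const std::vector<int> &A = sides_local[s];
    if ((int)A.size() < 2 || m - (int)A.size() < 2) continue;
    std::fill(inA.begin(), inA.end(), 0);
    for (size_t i = 0; i < A.size(); ++i) inA[A[i]] = 1;
    std::vector<int> B;
    B.reserve(m - A.size());
    for (int i = 0; i < m; ++i)
      if (!inA[i]) B.push_back(i);
    const double w = weights ? (*weights)[s] : 1.0;
    int four[4];
    for (size_t i = 0; i + 1 < A.size(); ++i)
      for (size_t j = i + 1; j < A.size(); ++j)
        for (size_t k = 0; k + 1 < B.size(); ++k)
          for (size_t l = k + 1; l < B.size(); ++l) {
            four[0] = A[i]; four[1] = A[j]; four[2] = B[k]; four[3] = B[l];
            std::sort(four, four + 4);
            const size_t idx = ct.rank(four[0], four[1], four[2], four[3]);
            topo[idx] = (signed char)pairing_code(A[i], A[j], four);
            if (wmin && w < (*wmin)[idx]) (*wmin)[idx] = w;
          }
  }
}

// convert a list of global-id sides into local 0-based indices, dropping
// taxa outside the locus leaf set
std::vector<std::vector<int> > localize(const List &sides,
                                        const std::vector<int> &pos) {
  std::vector<std::vector<int> > out(sides.size());
  for (R_xlen_t s = 0; s < sides.size(); ++s) {
    IntegerVector side = sides[s];
    std::vector<int> loc;
    loc.reserve(side.size());
    for (R_xlen_t i = 0; i < side.size(); ++i) {
      int g = side[i];
      if (g >= 1 && g < (int)pos.size() && pos[g] >= 0) loc.push_back(pos[g]);
    }
    out[s] = loc;
  }
  return out;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_locus_scores(List st_sides, List loci, int n_global,
                               bool weighted) {
  const R_xlen_t L = loci.size();
  NumericVector out(L);
  std::vector<int> pos(n_global + 1, -1);
  for (R_xlen_t li = 0; li < L; ++li) {
    List locus = loci[li];
    IntegerVector leaves = locus["leaves"];
    const int m = leaves.size();
    if (m < 4) { out[li] = 0.0; continue; }
    for (int i = 0; i < m; ++i) {
      int g = leaves[i];
      if (g < 1 || g > n_global) stop("locus leaf id out of range");
      pos[g] = i;
    }
    ChooseTab ct(m + 1);
    const size_t nq = ct.n4(m);
    std::vector<signed char> topoL(nq, 0), topoS(nq, 0);
    std::vector<double> wmin(nq, std::numeric_limits<double>::infinity());
    List lsides = locus["sides"];
    NumericVector wts = locus["weights"];
    std::vector<double> wv(wts.begin(), wts.end());
    fill_tables(localize(lsides, pos), m, weighted ? &wv : (std::vector<double> *)0,
                ct, topoL, &wmin);
    fill_tables(localize(st_sides, pos), m, (std::vector<double> *)0, ct,
                topoS, (std::vector<double> *)0);
    double sc = 0.0;
    for (size_t q = 0; q < nq; ++q)
      if (topoL[q] != 0 && topoL[q] == topoS[q])
        sc += weighted ? wmin[q] : 1.0;
    out[li] = sc;
    for (int i = 0; i < m; ++i) pos[leaves[i]] = -1;
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_branch_tally(List clusters, List loci, int n_global,
                               bool weighted) {
  if (clusters.size() != 4) stop("need exactly 4 clusters");
  const R_xlen_t L = loci.size();
  NumericMatrix out(L, 3);
  std::vector<int> pos(n_global + 1, -1);
  // cluster membership by global id: 0..3, -1 elsewhere
  std::vector<int> clus(n_global + 1, -1);
  for (int c = 0; c < 4; ++c) {
    IntegerVector cl = clusters[c];
    for (R_xlen_t i = 0; i < cl.size(); ++i) {
      int g = cl[i];
      if (g < 1 || g > n_global) stop("cluster taxon id out of range");
      if (clus[g] != -1) stop("clusters must be disjoint");
      clus[g] = c;
    }
  }
  for (R_xlen_t li = 0; li < L; ++li) {
    List locus = loci[li];
    IntegerVector leaves = locus["leaves"];
    const int m = leaves.size();
    if (m < 4) continue;
    for (int i = 0; i < m; ++i) pos[leaves[i]] = i;
    ChooseTab ct(m + 1);
    const size_t nq = ct.n4(m);
    std::vector<signed char> topoL(nq, 0);
    std::vector<double> wmin(nq, std::numeric_limits<double>::infinity());
    List lsides = locus["sides"];
    NumericVector wts = locus["weights"];
    std::vector<double> wv(wts.begin(), wts.end());
    fill_tables(localize(lsides, pos), m, weighted ? &wv : (std::vector<double> *)0,
                ct, topoL, &wmin);
    // local members of each cluster
    std::vector<int> A[4];
    for (int i = 0; i < m; ++i) {
      int c = clus[leaves[i]];
      if (c >= 0) A[c].push_back(i);
    }
    int four[4];
    for (size_t ia = 0; ia < A[0].size(); ++ia)
      for (size_t ib = 0; ib < A[1].size(); ++ib)
        for (size_t ic = 0; ic < A[2].size(); ++ic)
          for (size_t id = 0; id < A[3].size(); ++id) {
            const int a = A[0][ia], b = A[1][ib], c = A[2][ic], d = A[3][id];
            four[0] = a; four[1] = b; four[2] = c; four[3] = d;
            std::sort(four, four + 4);
            const size_t idx = ct.rank(four[0], four[1], four[2], four[3]);
            const int code = topoL[idx];
            if (code == 0) continue;
            // which cluster member is paired with a under this code?
            int partner;
            if (a == four[0]) partner = (code == 1) ? four[1] : (code == 2) ? four[2] : four[3];
            else if (a == four[1]) partner = (code == 1) ? four[0] : (code == 2) ? four[3] : four[2];
            else if (a == four[2]) partner = (code == 1) ? four[3] : (code == 2) ? four[0] : four[1];
            else partner = (code == 1) ? four[2] : (code == 2) ? four[1] : four[0];
            const int col = (partner == b) ? 0 : (partner == c) ? 1 : 2;
            out(li, col) += weighted ? wmin[idx] : 1.0;
          }
    for (int i = 0; i < m; ++i) pos[leaves[i]] = -1;
  }
  return out;
}
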