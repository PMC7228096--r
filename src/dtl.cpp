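// Parsimonious duplication-transfer-loss (DTL) reconciliation against an
// undated species tree, and its application to rooting an unrooted gene tree
// on every edge. Dynamic program over (gene node, species node) states:
//   c[g][s]   cheapest reconciliation of the gene subtree at g with g mapped
//             to species node s
//   in[g][s]  min over s' in subtree(s) of c[g][s'] + lossCost * dist(s, s')
//   best[g][s] min over s' in subtree(s) of c[g][s'] (no loss charge; a
//             transferred lineage arrives exactly where it lands)
//   out[g][s] min of best[g][s''] over species nodes s'' incomparable to s
//             (the permitted recipients of an undated transfer from s)
// Events at an internal gene node g with children g1, g2 mapped at s:
//   speciation  min(in[g1][sl] + in[g2][sr], in[g1][sr] + in[g2][sl])
//   duplication D + in[g1][s] + in[g2][s]
//   transfer    T + min(in[g1][s] + out[g2][s], in[g2][s] + out[g1][s])
// Total cost of a rooting is min over s of c[root][s]. Each rooting is an
// independent recomputation (no reuse across edges), which keeps the
// per-edge costs exactly equal to single-rooting recomputations.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const double BIG = 1e15;

namespace {

struct Species {
  int S, root;
  std::vector<int> left, right;      // -1 for leaves
  std::vector<int> post, pre;

  Species(const IntegerVector& l, const IntegerVector& r, int root_)
      : S(l.size()), root(root_), left(l.begin(), l.end()),
        right(r.begin(), r.end()) {
    post.reserve(S); pre.reserve(S);
    std::vector<int> stack{root};
    while (!stack.empty()) {           // preorder
      int s = stack.back(); stack.pop_back();
      pre.push_back(s);
      if (left[s] >= 0) { stack.push_back(left[s]); stack.push_back(right[s]); }
    }
    post.assign(pre.rbegin(), pre.rend());  // reverse preorder is a postorder
  }
};

// DP for one rooted gene tree given as child arrays (-1 for leaves) in
// postorder; gmap holds the species node of each gene leaf.
double dtl_cost(const Species& sp,
                const std::vector<int>& gleft, const std::vector<int>& gright,
                const std::vector<int>& gpost, const std::vector<int>& gmap,
                double cL, double cD, double cT) {
  const int S = sp.S;
  const int G = gleft.size();
  std::vector<std::vector<double>> IN(G), OUT(G);
  std::vector<double> c(S), bestc(S);
  int groot = gpost.back();
  for (int gi = 0; gi < (int)gpost.size(); ++gi) {
    int g = gpost[gi];
    if (gleft[g] < 0) {
      for (int s = 0; s < S; ++s) c[s] = (s == gmap[g]) ? 0.0 : BIG;
    } else {
      const std::vector<double>& in1 = IN[gleft[g]];
      const std::vector<double>& in2 = IN[gright[g]];
      const std::vector<double>& out1 = OUT[gleft[g]];
      const std::vector<double>& out2 = OUT[gright[g]];
      for (int s = 0; s < S; ++s) {
        double best = cD + in1[s] + in2[s];                  // duplication
        if (sp.left[s] >= 0) {                               // speciation
          int sl = sp.left[s], sr = sp.right[s];
          double spec = std::min(in1[sl] + in2[sr], in1[sr] + in2[sl]);
          if (spec < best) best = spec;
        }
        double tr = cT + std::min(in1[s] + out2[s], in2[s] + out1[s]);
        if (tr < best) best = tr;
        c[s] = std::min(best, BIG);
      }
    }
    // in[g] and best[g]: species postorder
    IN[g].assign(S, BIG);
    for (int si = 0; si < S; ++si) {
      int s = sp.post[si];
      double v = c[s], b = c[s];
      if (sp.left[s] >= 0) {
        v = std::min(v, IN[g][sp.left[s]] + cL);
        v = std::min(v, IN[g][sp.right[s]] + cL);
        b = std::min(b, std::min(bestc[sp.left[s]], bestc[sp.right[s]]));
      }
      IN[g][s] = std::min(v, BIG);
      bestc[s] = std::min(b, BIG);
    }
    // out[g]: species preorder
    OUT[g].assign(S, BIG);
    for (int si = 0; si < S; ++si) {
      int s = sp.pre[si];
      if (sp.left[s] < 0) continue;
      int sl = sp.left[s], sr = sp.right[s];
      OUT[g][sl] = std::min(OUT[g][s], bestc[sr]);
      OUT[g][sr] = std::min(OUT[g][s], bestc[sl]);
    }
  }
  // answer uses c of the gene root (still in the buffer)
  double ans = BIG;
  for (int s = 0; s < S; ++s) ans = std::min(ans, c[s]);
  return ans;
}

} // namespace

// [[Rcpp::export]]
double cpp_dtl_cost(IntegerVector gLeft, IntegerVector gRight,
                    IntegerVector gPost, IntegerVector gMap,
                    IntegerVector sLeft, IntegerVector sRight, int sRoot,
                    double lossCost, double dupCost, double transferCost) {
  Species sp(sLeft, sRight, sRoot);
  std::vector<int> gl(gLeft.begin(), gLeft.end());
  std::vector<int> gr(gRight.begin(), gRight.end());
  std::vector<int> gp(gPost.begin(), gPost.end());
  std::vector<int> gm(gMap.begin(), gMap.end());
  double v = dtl_cost(sp, gl, gr, gp, gm, lossCost, dupCost, transferCost);
  return (v >= BIG) ? R_PosInf : v;
}

// Root the unrooted gene tree (edge matrix, 0-based; tips 0..nTips-1) on
// every edge in turn and return the reconciliation cost of each rooting.
// [[Rcpp::export]]
NumericVector cpp_dtl_all_rootings(IntegerMatrix edges, int nTips,
                                   IntegerVector leafMap,
                                   IntegerVector sLeft, IntegerVector sRight,
                                   int sRoot, double lossCost, double dupCost,
                                   double transferCost) {
  Species sp(sLeft, sRight, sRoot);
  const int E = edges.nrow();
  const int M = nTips * 2 - 2;        // nodes of the unrooted tree
  const int G = M + 1;                // plus the virtual root
  // adjacency (degree <= 3)
  std::vector<std::vector<int>> adj(M);
  for (int i = 0; i < E; ++i) {
    adj[edges(i, 0)].push_back(edges(i, 1));
    adj[edges(i, 1)].push_back(edges(i, 0));
  }
  std::vector<int> gleft(G), gright(G), gmap(G, -1), gpost;
  for (int t = 0; t < nTips; ++t) gmap[t] = leafMap[t];
  NumericVector out(E);
  std::vector<std::pair<int, int>> stack;  // (node, parent)
  for (int i = 0; i < E; ++i) {
    int a = edges(i, 0), b = edges(i, 1);
    std::fill(gleft.begin(), gleft.end(), -1);
    std::fill(gright.begin(), gright.end(), -1);
    int root = M;
    gleft[root] = a; gright[root] = b;
    gpost.clear();
    // iterative preorder from the virtual root, then reverse
    std::vector<int> pre;
    pre.push_back(root);
    stack.clear();
    stack.push_back({a, b}); stack.push_back({b, a});
    while (!stack.empty()) {
      auto [v, par] = stack.back(); stack.pop_back();
      pre.push_back(v);
      int ch[2], k = 0;
      for (int nb : adj[v]) if (nb != par) ch[k++] = nb;
      if (v >= nTips) {
        gleft[v] = ch[0]; gright[v] = ch[1];
        stack.push_back({ch[0], v}); stack.push_back({ch[1], v});
      }
    }
    gpost.assign(pre.rbegin(), pre.rend());
    double v = dtl_cost(sp, gleft, gright, gpost, gmap,
                        lossCost, dupCost, transferCost);
    out[i] = (v >= BIG) ? R_PosInf : v;
  }
  return out;
}
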