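// Core parsimony kernels: Fitch scoring with the multifurcation (state-count)
// generalisation, per-edge Fitch root sets, leaf placement costs for stepwise
// addition, and full TBR move enumeration with O(1)-per-reconnection scoring.
//
// Conventions shared with the R side:
//  - trees arrive as ape edge matrices; tips are nodes 1..ntip,
//    internal nodes ntip+1.. (ids need not be contiguous after surgery);
//  - `masks` is an ntip x nchar integer matrix, row i = tip i, each cell a
//    bitmask over states 0..9 (bit s = 1<<s); missing/inapplicable cells are
//    the full state set;
//  - edge indices in TBR moves are 1-based rows of the input edge matrix;
//    reconnection anchor 0 denotes the "stub" (the merged edge left after
//    suppressing the bisected endpoint, or the detached tip itself).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const int NSTATES = 10;

// Fitch combine: intersection if non-empty, else union (an event).
static inline int fcomb(int a, int b, int& events) {
  int x = a & b;
  if (x) return x;
  ++events;
  return a | b;
}

struct Adj {
  // adjacency lists: for each node, (neighbour, 1-based edge index)
  std::vector<std::vector<std::pair<int, int> > > nb;
  int nnode;
  int any_tip() const {
    for (int v = 1; v <= nnode; ++v)
      if (nb[v].size() == 1) return v;
    return 1;
  }
  Adj(const IntegerMatrix& edge) {
    int mx = 0;
    for (int i = 0; i < edge.nrow(); ++i)
      mx = std::max(mx, std::max(edge(i, 0), edge(i, 1)));
    nnode = mx;
    nb.resize(mx + 1);
    for (int i = 0; i < edge.nrow(); ++i) {
      int a = edge(i, 0), b = edge(i, 1);
      nb[a].push_back(std::make_pair(b, i + 1));
      nb[b].push_back(std::make_pair(a, i + 1));
    }
  }
};

// ---------------------------------------------------------------------------
// General Fitch length (handles polytomies and degree-2/degree-1 roots).
// For a node with k children the state-count rule is used: with c(s) = number
// of child sets containing state s and K = max_s c(s), the node set is
// {s : c(s) = K} and the node adds (k - K) steps.  For k = 2 this is exactly
// the classic intersection/union rule.
// [[Rcpp::export]]
List c_fitch(IntegerMatrix edge, int ntip, IntegerMatrix masks,
             NumericVector weights) {
  int E = edge.nrow();
  int nchar = masks.ncol();
  int mx = 0;
  for (int i = 0; i < E; ++i)
    mx = std::max(mx, std::max(edge(i, 0), edge(i, 1)));

  std::vector<std::vector<int> > kids(mx + 1);
  std::vector<int> indeg(mx + 1, 0);
  std::vector<bool> seen(mx + 1, false);
  for (int i = 0; i < E; ++i) {
    kids[edge(i, 0)].push_back(edge(i, 1));
    indeg[edge(i, 1)]++;
    seen[edge(i, 0)] = seen[edge(i, 1)] = true;
  }
  int root = -1;
  for (int v = 1; v <= mx; ++v)
    if (seen[v] && indeg[v] == 0) { root = v; break; }
  if (root < 0) stop("edge matrix has no root (cycle?)");

  // postorder over internal nodes
  std::vector<int> post;
  post.reserve(mx);
  std::vector<int> stack;
  stack.push_back(root);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    post.push_back(v);
    for (size_t j = 0; j < kids[v].size(); ++j) stack.push_back(kids[v][j]);
  }
  std::reverse(post.begin(), post.end());

  IntegerVector steps(nchar);
  std::vector<int> set(mx + 1);
  double total = 0.0;
  for (int c = 0; c < nchar; ++c) {
    int ev = 0;
    for (size_t i = 0; i < post.size(); ++i) {
      int v = post[i];
      const std::vector<int>& kv = kids[v];
      if (kv.empty()) {
        set[v] = masks(v - 1, c);
      } else if (kv.size() == 1) {
        // a tip used as root keeps its own observation; a degree-2 internal
        // root just passes the child set through
        set[v] = (v <= ntip) ? fcomb(masks(v - 1, c), set[kv[0]], ev)
                             : set[kv[0]];
      } else if (kv.size() == 2) {
        set[v] = fcomb(set[kv[0]], set[kv[1]], ev);
      } else {
        int cnt[NSTATES] = {0};
        for (size_t j = 0; j < kv.size(); ++j) {
          int m = set[kv[j]];
          for (int s = 0; s < NSTATES; ++s)
            if (m & (1 << s)) cnt[s]++;
        }
        int K = 0;
        for (int s = 0; s < NSTATES; ++s) K = std::max(K, cnt[s]);
        int m = 0;
        for (int s = 0; s < NSTATES; ++s)
          if (cnt[s] == K) m |= (1 << s);
        set[v] = m;
        ev += (int)kv.size() - K;
      }
    }
    steps[c] = ev;
    total += weights[c] * ev;
  }
  return List::create(_["total"] = total, _["steps"] = steps);
}

// ---------------------------------------------------------------------------
// Fragment F-sets.  The fragment is the connected component of `u` after
// removing edge `ban` (ban = 0: no edge removed).  The fragment is rooted at
// u and must be binary away from u.  Outputs, per reconnection edge and
// character, the Fitch state set of a virtual root placed on that edge, plus
// the (weighted) Fitch length of the fragment.  Reconnection edge ids are
// original 1-based edge indices, with 0 denoting the stub at u.
struct FragSets {
  double steps;                 // weighted Fitch length of the fragment
  std::vector<int> rec;         // reconnection edge ids (0 = stub)
  std::vector<int> F;           // rec.size() x nchar, row-major by rec
  std::vector<int> nodes;       // nodes in the fragment
};

static void frag_fsets(const Adj& adj, int u, int ban, int ntip,
                       const IntegerMatrix& masks, const NumericVector& w,
                       FragSets& out) {
  int nchar = masks.ncol();
  out.steps = 0.0;
  out.rec.clear();
  out.F.clear();
  out.nodes.clear();

  std::vector<std::pair<int, int> > rootkids;  // (child, edge id)
  for (size_t j = 0; j < adj.nb[u].size(); ++j)
    if (adj.nb[u][j].second != ban) rootkids.push_back(adj.nb[u][j]);

  if (rootkids.empty()) {  // detached tip
    out.rec.push_back(0);
    out.F.resize(nchar);
    for (int c = 0; c < nchar; ++c) out.F[c] = masks(u - 1, c);
    out.nodes.push_back(u);
    return;
  }

  // preorder DFS from u; record parent, parent edge id, sibling
  std::vector<int> order, parent(adj.nnode + 1, 0), pedge(adj.nnode + 1, 0),
      sib(adj.nnode + 1, 0);
  std::vector<std::pair<int, int> > st;  // (node, parent)
  for (size_t j = 0; j < rootkids.size(); ++j)
    st.push_back(std::make_pair(rootkids[j].first, u));
  // record parent edges for root kids
  for (size_t j = 0; j < rootkids.size(); ++j)
    pedge[rootkids[j].first] = rootkids[j].second;
  std::vector<std::vector<int> > kidsv(adj.nnode + 1);
  while (!st.empty()) {
    int v = st.back().first, p = st.back().second;
    st.pop_back();
    order.push_back(v);
    parent[v] = p;
    for (size_t j = 0; j < adj.nb[v].size(); ++j) {
      int nbr = adj.nb[v][j].first, eid = adj.nb[v][j].second;
      if (eid == ban || nbr == p) continue;
      st.push_back(std::make_pair(nbr, v));
      pedge[nbr] = eid;
      kidsv[v].push_back(nbr);
    }
  }
  // siblings (all non-root internal fragment nodes have exactly 2 children)
  for (size_t i = 0; i < order.size(); ++i) {
    int v = order[i];
    if (kidsv[v].size() == 2) {
      sib[kidsv[v][0]] = kidsv[v][1];
      sib[kidsv[v][1]] = kidsv[v][0];
    }
  }
  bool whole_tree = (rootkids.size() == 1);  // u is a tip used as root
  int c0 = rootkids[0].first;
  int c1 = (rootkids.size() == 2) ? rootkids[1].first : 0;
  if (rootkids.size() == 2) { sib[c0] = c1; sib[c1] = c0; }

  // reconnection edges: stub (if cut vertex) then every non-root-incident
  // edge; for the whole-tree case every edge including (c0, u).
  if (!whole_tree) out.rec.push_back(0);
  std::vector<int> recnode;  // node whose parent edge is the rec edge
  recnode.push_back(0);      // placeholder for stub / (c0,u)
  if (whole_tree) out.rec.push_back(pedge[c0]);
  for (size_t i = 0; i < order.size(); ++i) {
    int v = order[i];
    if (v == c0 && whole_tree) continue;  // already added
    if (parent[v] == u && !whole_tree) continue;  // merged into stub
    if (!(v == c0 && whole_tree)) {
      out.rec.push_back(pedge[v]);
      recnode.push_back(v);
    }
  }
  size_t nrec = out.rec.size();
  out.F.assign(nrec * nchar, 0);
  out.nodes = order;
  out.nodes.push_back(u);

  std::vector<int> D(adj.nnode + 1), U(adj.nnode + 1);
  for (int c = 0; c < nchar; ++c) {
    int ev = 0;
    // downpass (reverse preorder)
    for (size_t i = order.size(); i-- > 0;) {
      int v = order[i];
      if (kidsv[v].empty())
        D[v] = masks(v - 1, c);
      else
        D[v] = fcomb(D[kidsv[v][0]], D[kidsv[v][1]], ev);
    }
    int rootset, dummy = 0;
    if (whole_tree) {
      rootset = fcomb(D[c0], masks(u - 1, c), ev);
    } else {
      rootset = fcomb(D[c0], D[c1], ev);
    }
    out.steps += w[c] * ev;
    // uppass
    for (size_t i = 0; i < order.size(); ++i) {
      int v = order[i];
      int p = parent[v];
      if (p == u) {
        U[v] = whole_tree ? masks(u - 1, c) : D[sib[v]];
      } else {
        U[v] = fcomb(U[p], D[sib[v]], dummy);
      }
    }
    // F per reconnection edge
    size_t r = 0;
    if (!whole_tree) {
      out.F[r * nchar + c] = rootset;  // stub
      ++r;
    } else {
      out.F[r * nchar + c] = rootset;  // edge (c0, u)
      ++r;
    }
    for (; r < nrec; ++r) {
      int v = recnode[r];
      out.F[r * nchar + c] = fcomb(D[v], U[v], dummy);
    }
  }
}

// ---------------------------------------------------------------------------
// Cost of attaching a new leaf (bitmask vector `newmask`) on every edge of a
// binary unrooted tree.  Returns a vector aligned with edge matrix rows:
// new tree length = base length + cost[e].
// [[Rcpp::export]]
NumericVector c_placement_costs(IntegerMatrix edge, int ntip,
                                IntegerMatrix masks, NumericVector weights,
                                IntegerVector newmask) {
  Adj adj(edge);
  int nchar = masks.ncol();
  FragSets fs;
  frag_fsets(adj, adj.any_tip(), 0, ntip, masks, weights, fs);
  NumericVector cost(edge.nrow(), NA_REAL);
  for (size_t r = 0; r < fs.rec.size(); ++r) {
    double cc = 0.0;
    for (int c = 0; c < nchar; ++c)
      if ((fs.F[r * nchar + c] & newmask[c]) == 0) cc += weights[c];
    cost[fs.rec[r] - 1] = cc;
  }
  return cost;
}

// Weighted Fitch length of a binary unrooted tree (fast path).
// [[Rcpp::export]]
double c_tree_length(IntegerMatrix edge, int ntip, IntegerMatrix masks,
                     NumericVector weights) {
  Adj adj(edge);
  FragSets fs;
  frag_fsets(adj, adj.any_tip(), 0, ntip, masks, weights, fs);
  return fs.steps;
}

// ---------------------------------------------------------------------------
// Enumerate all TBR moves.  For every bisection (edge e) and every pair of
// reconnection edges (a in fragment A, b in fragment B, anchor 0 = stub), the
// length of the reconnected tree is  len(A) + len(B) + join(F_A(a), F_B(b)).
// The pair (0, 0) re-creates the original tree and is skipped.  Returns the
// minimum length over the neighbourhood, all moves with length <= cutoff and
// all moves attaining the minimum.
// [[Rcpp::export]]
List c_tbr_moves(IntegerMatrix edge, int ntip, IntegerMatrix masks,
                 NumericVector weights, double cutoff) {
  Adj adj(edge);
  int E = edge.nrow();
  int nchar = masks.ncol();
  double best = R_PosInf;
  std::vector<int> m_e, m_a, m_b;        // moves <= cutoff
  std::vector<double> m_len;
  std::vector<int> bm_e, bm_a, bm_b;     // moves == best
  FragSets A, B;

  for (int e = 1; e <= E; ++e) {
    int u = edge(e - 1, 0), v = edge(e - 1, 1);
    frag_fsets(adj, u, e, ntip, masks, weights, A);
    frag_fsets(adj, v, e, ntip, masks, weights, B);
    double base = A.steps + B.steps;
    size_t na = A.rec.size(), nb = B.rec.size();
    for (size_t ia = 0; ia < na; ++ia) {
      const int* FA = &A.F[ia * nchar];
      for (size_t ib = 0; ib < nb; ++ib) {
        if (A.rec[ia] == 0 && B.rec[ib] == 0) continue;  // original tree
        const int* FB = &B.F[ib * nchar];
        double len = base;
        double lim = std::max(cutoff, best);
        bool over = false;
        for (int c = 0; c < nchar; ++c) {
          if ((FA[c] & FB[c]) == 0) {
            len += weights[c];
            if (len > lim) { over = true; break; }
          }
        }
        if (over) continue;
        if (len < best) {
          best = len;
          bm_e.clear(); bm_a.clear(); bm_b.clear();
        }
        if (len == best) {
          bm_e.push_back(e); bm_a.push_back(A.rec[ia]); bm_b.push_back(B.rec[ib]);
        }
        if (len <= cutoff) {
          m_e.push_back(e); m_a.push_back(A.rec[ia]); m_b.push_back(B.rec[ib]);
          m_len.push_back(len);
        }
      }
    }
  }
  return List::create(
      _["min"] = best,
      _["moves"] = DataFrame::create(_["e"] = wrap(m_e), _["a"] = wrap(m_a),
                                     _["b"] = wrap(m_b), _["len"] = wrap(m_len)),
      _["min_moves"] = DataFrame::create(_["e"] = wrap(bm_e), _["a"] = wrap(bm_a),
                                         _["b"] = wrap(bm_b)));
}
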