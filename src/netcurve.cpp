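#include <Rcpp.h>
#include <vector>
#include <set>
using namespace Rcpp;

// uniform integer in [0, n)
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

//' @noRd
// [[Rcpp::export]]
List cpp_bfs_map(IntegerVector offsets, IntegerVector targets, int root0,
                 bool shuffle) {
  // CSR adjacency, 0-based; a self-loop occurs twice in its vertex's list.
  int n = offsets.size() - 1;
  std::vector<int> qT;            // explored/touched vertices in queue order
  qT.reserve(n);
  std::vector<int> tpos(n, 0);    // 1-based QueueT position, 0 = untouched
  std::vector<int> refpos(n, 0);  // QueueG position of the reference copy
  std::vector<int> treey;         // parent's QueueT position per queued vertex
  std::vector<int> copyy;         // parent's reference-copy position per copy
  std::vector<int> vdeg, vchild;  // per queued vertex: graph degree, children

  qT.push_back(root0);
  tpos[root0] = 1;
  refpos[root0] = 1;  // the root's own initial copy heads QueueG
  treey.push_back(0);
  long long gpos = 1;  // copies pushed so far (root copy included)

  std::vector<int> nb;
  size_t i = 0;
  while (i < qT.size()) {
    int v = qT[i];
    int beg = offsets[v], end = offsets[v + 1];
    nb.assign(targets.begin() + beg, targets.begin() + end);
    if (shuffle) {
      for (int j = (int)nb.size() - 1; j > 0; --j) {
        int k = runif_int(j + 1);
        std::swap(nb[j], nb[k]);
      }
    }
    int myref = refpos[v];
    int children = 0;
    for (size_t j = 0; j < nb.size(); ++j) {
      int w = nb[j];
      ++gpos;
      copyy.push_back(myref);
      if (tpos[w] == 0) {
        qT.push_back(w);
        tpos[w] = (int)qT.size();
        refpos[w] = (int)gpos;
        treey.push_back(tpos[v]);
        ++children;
      }
    }
    vdeg.push_back(end - beg);
    vchild.push_back(children);
    ++i;
  }
  return List::create(
      _["order"] = wrap(qT), _["tree_parent_pos"] = wrap(treey),
      _["copy_parent_ref"] = wrap(copyy), _["ref_pos_gc"] = wrap(refpos),
      _["vdeg"] = wrap(vdeg), _["vchild"] = wrap(vchild));
}

static IntegerMatrix adj_to_edges(const std::vector<std::set<int> > &adj) {
  long long m = 0;
  for (size_t v = 0; v < adj.size(); ++v)
    for (std::set<int>::const_iterator it = adj[v].begin();
         it != adj[v].end(); ++it)
      if (*it >= (int)v) ++m;
  IntegerMatrix e((int)m, 2);
  long long row = 0;
  for (size_t v = 0; v < adj.size(); ++v)
    for (std::set<int>::const_iterator it = adj[v].begin();
         it != adj[v].end(); ++it)
      if (*it >= (int)v) {
        e(row, 0) = (int)v + 1;
        e(row, 1) = *it + 1;
        ++row;
      }
  return e;
}

//' @noRd
// [[Rcpp::export]]
SEXP cpp_dmc(int n, double q_del, double q_con, double m_cap) {
  // duplication-mutation-complementation growth from a single-edge seed
  std::vector<std::set<int> > adj(n);
  adj[0].insert(1);
  adj[1].insert(0);
  double M = 1;
  for (int v = 2; v < n; ++v) {
    int a = runif_int(v);
    std::vector<int> nbrs(adj[a].begin(), adj[a].end());
    for (size_t j = 0; j < nbrs.size(); ++j) {
      int w = nbrs[j];
      adj[v].insert(w);
      adj[w].insert(v);
    }
    M += (double)nbrs.size();
    for (size_t j = 0; j < nbrs.size(); ++j) {
      int w = nbrs[j];
      if (unif_rand() < q_del) {
        M -= 1;
        if (unif_rand() < 0.5) {
          adj[v].erase(w);
          adj[w].erase(v);
        } else {
          adj[a].erase(w);
          adj[w].erase(a);
        }
      }
    }
    if (unif_rand() < q_con) {
      adj[v].insert(a);
      adj[a].insert(v);
      M += 1;
    }
    if (M > m_cap) return R_NilValue;
  }
  return adj_to_edges(adj);
}

//' @noRd
// [[Rcpp::export]]
SEXP cpp_dmr(int n, double q_del, double q_new, double m_cap) {
  // duplication-mutation-random growth from a single-edge seed
  std::vector<std::set<int> > adj(n);
  adj[0].insert(1);
  adj[1].insert(0);
  double M = 1;
  std::vector<int> pool;
  for (int v = 2; v < n; ++v) {
    int a = runif_int(v);
    std::vector<int> nbrs(adj[a].begin(), adj[a].end());
    for (size_t j = 0; j < nbrs.size(); ++j) {
      if (unif_rand() >= q_del) {
        int w = nbrs[j];
        adj[v].insert(w);
        adj[w].insert(v);
        M += 1;
      }
    }
    // random new links: Binomial(v, q_new / v) uniform distinct targets
    int nnew = (int)R::rbinom((double)v, q_new / (double)v);
    if (nnew > 0) {
      pool.resize(v);
      for (int j = 0; j < v; ++j) pool[j] = j;
      for (int j = 0; j < nnew; ++j) {
        int k = j + runif_int(v - j);
        std::swap(pool[j], pool[k]);
        int w = pool[j];
        if (adj[v].insert(w).second) {
          adj[w].insert(v);
          M += 1;
        }
      }
    }
    if (M > m_cap) return R_NilValue;
  }
  return adj_to_edges(adj);
}

//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_lpa(int n, int m) {
  // linear preferential attachment from a single-edge seed; m distinct
  // degree-proportional targets per new vertex
  std::vector<int> e1, e2, stubs;
  e1.push_back(1);
  e2.push_back(2);
  stubs.push_back(0);
  stubs.push_back(1);
  std::vector<int> chosen;
  for (int v = 2; v < n; ++v) {
    chosen.clear();
    int mm = m < v ? m : v;
    while ((int)chosen.size() < mm) {
      int w = stubs[runif_int((int)stubs.size())];
      bool dup = false;
      for (size_t j = 0; j < chosen.size(); ++j)
        if (chosen[j] == w) { dup = true; break; }
      if (!dup) chosen.push_back(w);
    }
    for (size_t j = 0; j < chosen.size(); ++j) {
      e1.push_back(v + 1);
      e2.push_back(chosen[j] + 1);
      stubs.push_back(v);
      stubs.push_back(chosen[j]);
    }
  }
  IntegerMatrix e((int)e1.size(), 2);
  for (size_t j = 0; j < e1.size(); ++j) {
    e(j, 0) = e1[j];
    e(j, 1) = e2[j];
  }
  return e;
}
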