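// Parsimony kernel: Fitch set operations on unrooted binary trees,
// fragment root-set computation for fast TBR/stepwise-addition rescoring,
// and the TBR hill climb itself.
//
// Node ids are 0-based internally: tips 0..ntip-1, internal nodes >= ntip.
// Character data arrive as bitmasks (bit s set <=> state s in the cell's
// ambiguity set); missing / inapplicable cells carry the full mask of the
// character's defined states.  Trees cross the R boundary as ape edge
// matrices (inbound) and newick strings over 1-based tip indices (outbound).

#include <Rcpp.h>
#include <cstring>
#include <set>
#include <string>
#include <vector>
using namespace Rcpp;
typedef unsigned char u8;

static const double EPS = 1e-9;

// ---------------------------------------------------------------- adjacency

static std::vector<std::vector<int> > buildAdj(const IntegerMatrix& edge,
                                               int& nnode) {
  int mx = 0;
  for (int i = 0; i < edge.nrow(); i++) {
    mx = std::max(mx, std::max(edge(i, 0), edge(i, 1)));
  }
  nnode = mx;  // 1-based max id == node count upper bound
  std::vector<std::vector<int> > adj(nnode);
  for (int i = 0; i < edge.nrow(); i++) {
    int a = edge(i, 0) - 1, b = edge(i, 1) - 1;
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  for (size_t i = 0; i < adj.size(); i++)
    std::sort(adj[i].begin(), adj[i].end());
  return adj;
}

static void sortAdj(std::vector<std::vector<int> >& adj) {
  for (size_t i = 0; i < adj.size(); i++)
    std::sort(adj[i].begin(), adj[i].end());
}

// ------------------------------------------------------------------ newick

static void newickRec(const std::vector<std::vector<int> >& adj, int ntip,
                      int v, int parent, std::string& out) {
  if (v < ntip) {
    out += std::to_string(v + 1);
    return;
  }
  out += '(';
  bool first = true;
  for (size_t i = 0; i < adj[v].size(); i++) {
    int w = adj[v][i];
    if (w == parent) continue;
    if (!first) out += ',';
    first = false;
    newickRec(adj, ntip, w, v, out);
  }
  out += ')';
}

static std::string toNewick(const std::vector<std::vector<int> >& adj,
                            int ntip) {
  // root the written tree at the internal neighbour of the smallest tip
  int t0 = -1;
  for (int i = 0; i < ntip; i++)
    if (!adj[i].empty()) { t0 = i; break; }
  int r = adj[t0][0];
  std::string s;
  if (adj[r].size() < 2) {  // two-tip tree
    s = "(" + std::to_string(t0 + 1) + "," + std::to_string(r + 1) + ");";
    return s;
  }
  newickRec(adj, ntip, r, -1, s);
  s += ';';
  return s;
}

// canonical topology key: sorted bipartition bitsets (side without tip t0)
static std::string topoKeyAdj(const std::vector<std::vector<int> >& adj,
                              int ntip) {
  int nb = (ntip + 7) / 8;
  std::vector<std::string> parts;
  // DFS from smallest present tip, gathering tip sets below each edge
  int t0 = -1;
  for (int i = 0; i < ntip; i++)
    if (!adj[i].empty()) { t0 = i; break; }
  std::vector<int> stack, par((size_t)adj.size(), -2), order;
  stack.push_back(adj[t0][0]);
  par[adj[t0][0]] = t0;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    for (size_t i = 0; i < adj[v].size(); i++) {
      int w = adj[v][i];
      if (w != par[v]) { par[w] = v; stack.push_back(w); }
    }
  }
  std::vector<std::string> below((size_t)adj.size(), std::string());
  for (int i = (int)order.size() - 1; i >= 0; i--) {
    int v = order[i];
    std::string bs(nb, '\0');
    if (v < ntip) {
      bs[v / 8] |= (char)(1 << (v % 8));
    } else {
      for (size_t j = 0; j < adj[v].size(); j++) {
        int w = adj[v][j];
        if (w == par[v]) continue;
        for (int b = 0; b < nb; b++) bs[b] |= below[w][b];
      }
    }
    below[v] = bs;
    if (v >= ntip && par[v] >= 0 && par[v] != t0) parts.push_back(bs);
  }
  std::sort(parts.begin(), parts.end());
  std::string key;
  for (size_t i = 0; i < parts.size(); i++) key += parts[i];
  return key;
}

// ------------------------------------------------------- full-tree scoring

// Per-character Fitch step counts; works for any rooting / degree pattern
// (children are combined sequentially, exact on binary trees).
static void fitchCountsAdj(const std::vector<std::vector<int> >& adj, int ntip,
                           const u8* tips, int nchar,
                           std::vector<double>& counts) {
  counts.assign(nchar, 0.0);
  int nnode = (int)adj.size();
  int root = -1;
  for (int v = ntip; v < nnode; v++)
    if (!adj[v].empty()) { root = v; break; }
  if (root < 0) {  // at most one edge between two tips
    int a = -1, b = -1;
    for (int i = 0; i < ntip; i++)
      if (!adj[i].empty()) { if (a < 0) a = i; else b = i; }
    if (a >= 0 && b >= 0)
      for (int c = 0; c < nchar; c++)
        if (!(tips[a * nchar + c] & tips[b * nchar + c])) counts[c] += 1;
    return;
  }
  std::vector<int> stack, par(nnode, -2), order;
  stack.push_back(root);
  par[root] = -1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    for (size_t i = 0; i < adj[v].size(); i++)
      if (adj[v][i] != par[v]) { par[adj[v][i]] = v; stack.push_back(adj[v][i]); }
  }
  std::vector<u8> S((size_t)nnode * nchar, 0);
  for (int i = (int)order.size() - 1; i >= 0; i--) {
    int v = order[i];
    if (v < ntip) {
      std::memcpy(&S[(size_t)v * nchar], tips + (size_t)v * nchar, nchar);
      continue;
    }
    bool first = true;
    u8* sv = &S[(size_t)v * nchar];
    for (size_t j = 0; j < adj[v].size(); j++) {
      int w = adj[v][j];
      if (w == par[v]) continue;
      const u8* sw = &S[(size_t)w * nchar];
      if (first) {
        std::memcpy(sv, sw, nchar);
        first = false;
      } else {
        for (int c = 0; c < nchar; c++) {
          u8 in = sv[c] & sw[c];
          if (in) sv[c] = in;
          else { sv[c] |= sw[c]; counts[c] += 1; }
        }
      }
    }
  }
}

static double scoreFromCounts(const std::vector<double>& counts,
                              const double* minsteps, double k,
                              int objective) {
  double s = 0.0;
  for (size_t c = 0; c < counts.size(); c++) {
    if (objective == 1) {
      double es = counts[c] - minsteps[c];
      if (es < 0) es = 0;
      s += k / (k + es);
    } else {
      s -= counts[c];
    }
  }
  return s;
}

// ---------------------------------------------------------------- fragments

struct Frag {
  bool single;
  int singleLeaf;
  int supNode, supA, supB;                  // suppressed node and neighbours
  std::vector<std::pair<int, int> > edges;  // (parent, child), global ids
  std::vector<double> len;                  // per character
  std::vector<u8> rootset;                  // edges.size() x nchar
};

// Core: per-edge Fitch root sets and the fragment's unrooted length, for the
// tree in `ladj` restricted to the component containing `rootleaf` (a tip).
static void fragCore(const std::vector<std::vector<int> >& ladj, int ntip,
                     const u8* tips, int nchar, int rootleaf, Frag& F) {
  F.single = false;
  F.edges.clear();
  F.len.assign(nchar, 0.0);
  int nnode = (int)ladj.size();
  int c0 = ladj[rootleaf][0];
  std::vector<int> stack, par(nnode, -2), order;
  stack.push_back(c0);
  par[c0] = rootleaf;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    for (size_t i = 0; i < ladj[v].size(); i++)
      if (ladj[v][i] != par[v]) { par[ladj[v][i]] = v; stack.push_back(ladj[v][i]); }
  }
  std::vector<u8> D((size_t)nnode * nchar, 0), A((size_t)nnode * nchar, 0);
  // down pass (children before parents)
  for (int i = (int)order.size() - 1; i >= 0; i--) {
    int v = order[i];
    u8* dv = &D[(size_t)v * nchar];
    if (v < ntip) {
      std::memcpy(dv, tips + (size_t)v * nchar, nchar);
      continue;
    }
    bool first = true;
    for (size_t j = 0; j < ladj[v].size(); j++) {
      int w = ladj[v][j];
      if (w == par[v]) continue;
      const u8* dw = &D[(size_t)w * nchar];
      if (first) { std::memcpy(dv, dw, nchar); first = false; }
      else {
        for (int c = 0; c < nchar; c++) {
          u8 in = dv[c] & dw[c];
          if (in) dv[c] = in;
          else { dv[c] |= dw[c]; F.len[c] += 1; }
        }
      }
    }
  }
  // root-leaf join completes the unrooted fragment length
  {
    const u8* dc = &D[(size_t)c0 * nchar];
    const u8* tl = tips + (size_t)rootleaf * nchar;
    for (int c = 0; c < nchar; c++)
      if (!(dc[c] & tl[c])) F.len[c] += 1;
  }
  // up pass: A[v] = Fitch set of everything on the parent side of v
  std::memcpy(&A[(size_t)c0 * nchar], tips + (size_t)rootleaf * nchar, nchar);
  for (size_t i = 0; i < order.size(); i++) {
    int v = order[i];
    if (v < ntip) continue;
    // children of v
    int ch[3], nc = 0;
    for (size_t j = 0; j < ladj[v].size(); j++)
      if (ladj[v][j] != par[v]) ch[nc++] = ladj[v][j];
    const u8* av = &A[(size_t)v * nchar];
    for (int x = 0; x < nc; x++) {
      u8* ax = &A[(size_t)ch[x] * nchar];
      std::memcpy(ax, av, nchar);
      for (int y = 0; y < nc; y++) {
        if (y == x) continue;
        const u8* dy = &D[(size_t)ch[y] * nchar];
        for (int c = 0; c < nchar; c++) {
          u8 in = ax[c] & dy[c];
          ax[c] = in ? in : (u8)(ax[c] | dy[c]);
        }
      }
    }
  }
  // edges in deterministic (preorder) sequence; root set on edge (par,v)
  F.rootset.assign(order.size() * (size_t)nchar, 0);
  for (size_t i = 0; i < order.size(); i++) {
    int v = order[i];
    F.edges.push_back(std::make_pair(par[v], v));
    u8* rs = &F.rootset[i * (size_t)nchar];
    const u8* dv = &D[(size_t)v * nchar];
    const u8* av = &A[(size_t)v * nchar];
    for (int c = 0; c < nchar; c++) {
      u8 in = dv[c] & av[c];
      rs[c] = in ? in : (u8)(dv[c] | av[c]);
    }
  }
}

// Build the fragment on `start`'s side of the bisected edge (start, avoid),
// suppressing `start` if it becomes degree-2.
static void buildFrag(const std::vector<std::vector<int> >& adj, int ntip,
                      const u8* tips, int nchar, int start, int avoid,
                      Frag& F) {
  F.supNode = -1;
  if (start < ntip) {
    F.single = true;
    F.singleLeaf = start;
    F.edges.clear();
    F.len.assign(nchar, 0.0);
    F.rootset.assign(nchar, 0);
    std::memcpy(&F.rootset[0], tips + (size_t)start * nchar, nchar);
    return;
  }
  int nnode = (int)adj.size();
  std::vector<std::vector<int> > ladj(nnode);
  std::vector<char> in(nnode, 0);
  std::vector<int> stack;
  stack.push_back(start);
  in[start] = 1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    for (size_t i = 0; i < adj[v].size(); i++) {
      int w = adj[v][i];
      if (v == start && w == avoid) continue;
      if (!in[w]) { in[w] = 1; stack.push_back(w); }
    }
  }
  for (int v = 0; v < nnode; v++) {
    if (!in[v] || v == start) continue;
    for (size_t i = 0; i < adj[v].size(); i++) {
      int w = adj[v][i];
      if (in[w] && w != start) ladj[v].push_back(w);
    }
  }
  // suppress start (degree 2 inside the fragment)
  int nb[2], nn = 0;
  for (size_t i = 0; i < adj[start].size(); i++)
    if (adj[start][i] != avoid) nb[nn++] = adj[start][i];
  F.supNode = start;
  F.supA = nb[0];
  F.supB = nb[1];
  ladj[nb[0]].push_back(nb[1]);
  ladj[nb[1]].push_back(nb[0]);
  for (int v = 0; v < nnode; v++)
    std::sort(ladj[v].begin(), ladj[v].end());
  int rootleaf = -1;
  for (int t = 0; t < ntip; t++)
    if (in[t]) { rootleaf = t; break; }
  fragCore(ladj, ntip, tips, nchar, rootleaf, F);
}

// Apply a TBR reconnection.  eU/eV index into F.edges (or -1 for a
// single-leaf fragment).  Junction nodes reuse the bisected edge's endpoints.
static void applyMove(std::vector<std::vector<int> >& adj, int u, int v,
                      const Frag& FU, const Frag& FV, int eU, int eV) {
  // detach
  adj[u].erase(std::find(adj[u].begin(), adj[u].end(), v));
  adj[v].erase(std::find(adj[v].begin(), adj[v].end(), u));
  int ju, jv;
  if (FU.single) {
    ju = FU.singleLeaf;
  } else {
    int a = FU.supA, b = FU.supB;
    adj[u].clear();
    adj[a].erase(std::find(adj[a].begin(), adj[a].end(), u));
    adj[b].erase(std::find(adj[b].begin(), adj[b].end(), u));
    adj[a].push_back(b);
    adj[b].push_back(a);
    int p = FU.edges[eU].first, q = FU.edges[eU].second;
    adj[p].erase(std::find(adj[p].begin(), adj[p].end(), q));
    adj[q].erase(std::find(adj[q].begin(), adj[q].end(), p));
    adj[p].push_back(u);
    adj[q].push_back(u);
    adj[u].push_back(p);
    adj[u].push_back(q);
    ju = u;
  }
  if (FV.single) {
    jv = FV.singleLeaf;
  } else {
    int a = FV.supA, b = FV.supB;
    adj[v].clear();
    adj[a].erase(std::find(adj[a].begin(), adj[a].end(), v));
    adj[b].erase(std::find(adj[b].begin(), adj[b].end(), v));
    adj[a].push_back(b);
    adj[b].push_back(a);
    int p = FV.edges[eV].first, q = FV.edges[eV].second;
    adj[p].erase(std::find(adj[p].begin(), adj[p].end(), q));
    adj[q].erase(std::find(adj[q].begin(), adj[q].end(), p));
    adj[p].push_back(v);
    adj[q].push_back(v);
    adj[v].push_back(p);
    adj[v].push_back(q);
    jv = v;
  }
  adj[ju].push_back(jv);
  adj[jv].push_back(ju);
  sortAdj(adj);
}

// ------------------------------------------------------------- R interface

// [[Rcpp::export]]
NumericVector cpp_fitch_counts(IntegerMatrix edge, int ntip,
                               IntegerMatrix tipmask) {
  int nchar = tipmask.ncol(), nnode;
  std::vector<std::vector<int> > adj = buildAdj(edge, nnode);
  std::vector<u8> tips((size_t)ntip * nchar);
  for (int t = 0; t < ntip; t++)
    for (int c = 0; c < nchar; c++) tips[(size_t)t * nchar + c] = (u8)tipmask(t, c);
  std::vector<double> counts;
  fitchCountsAdj(adj, ntip, &tips[0], nchar, counts);
  return wrap(counts);
}

// [[Rcpp::export]]
String cpp_topo_key(IntegerMatrix edge, int ntip) {
  int nnode;
  std::vector<std::vector<int> > adj = buildAdj(edge, nnode);
  std::string key = topoKeyAdj(adj, ntip);
  // hex-encode so the key survives as an R string
  static const char* hx = "0123456789abcdef";
  std::string out;
  for (size_t i = 0; i < key.size(); i++) {
    out += hx[(key[i] >> 4) & 15];
    out += hx[key[i] & 15];
  }
  return String(out);
}

// [[Rcpp::export]]
String cpp_addition_tree(IntegerVector order, IntegerMatrix tipmask,
                         NumericVector minsteps, double k, int objective) {
  int ntip = tipmask.nrow(), nchar = tipmask.ncol();
  std::vector<u8> tips((size_t)ntip * nchar);
  for (int t = 0; t < ntip; t++)
    for (int c = 0; c < nchar; c++) tips[(size_t)t * nchar + c] = (u8)tipmask(t, c);
  int nnode = 2 * ntip - 2;
  std::vector<std::vector<int> > adj(nnode);
  int t0 = order[0] - 1, t1 = order[1] - 1, t2 = order[2] - 1;
  int inode = ntip;
  adj[inode].push_back(t0); adj[inode].push_back(t1); adj[inode].push_back(t2);
  adj[t0].push_back(inode); adj[t1].push_back(inode); adj[t2].push_back(inode);
  sortAdj(adj);
  Frag F;
  std::vector<char> present(ntip, 0);
  present[t0] = present[t1] = present[t2] = 1;
  for (int m = 3; m < order.size(); m++) {
    int t = order[m] - 1;
    int rootleaf = -1;
    for (int i = 0; i < ntip; i++)
      if (present[i]) { rootleaf = i; break; }
    fragCore(adj, ntip, &tips[0], nchar, rootleaf, F);
    const u8* tm = &tips[(size_t)t * nchar];
    double best = -1e300;
    int bestE = -1;
    for (size_t e = 0; e < F.edges.size(); e++) {
      const u8* rs = &F.rootset[e * (size_t)nchar];
      double sc = 0.0;
      for (int c = 0; c < nchar; c++) {
        double len = F.len[c] + ((rs[c] & tm[c]) ? 0.0 : 1.0);
        if (objective == 1) {
          double es = len - minsteps[c];
          if (es < 0) es = 0;
          sc += k / (k + es);
        } else {
          sc -= len;
        }
      }
      if (sc > best + EPS) { best = sc; bestE = (int)e; }
    }
    int p = F.edges[bestE].first, q = F.edges[bestE].second;
    int nv = ntip + m - 2;
    adj[p].erase(std::find(adj[p].begin(), adj[p].end(), q));
    adj[q].erase(std::find(adj[q].begin(), adj[q].end(), p));
    adj[p].push_back(nv); adj[q].push_back(nv);
    adj[nv].push_back(p); adj[nv].push_back(q);
    adj[nv].push_back(t); adj[t].push_back(nv);
    present[t] = 1;
    sortAdj(adj);
  }
  return String(toNewick(adj, ntip));
}

// [[Rcpp::export]]
List cpp_tbr(IntegerMatrix edge, int ntip, IntegerMatrix tipmask,
             NumericVector minsteps, double k, int objective, int bufferCap,
             double maxMoves) {
  int nchar = tipmask.ncol(), nnode;
  std::vector<std::vector<int> > adj = buildAdj(edge, nnode);
  std::vector<u8> tips((size_t)ntip * nchar);
  for (int t = 0; t < ntip; t++)
    for (int c = 0; c < nchar; c++) tips[(size_t)t * nchar + c] = (u8)tipmask(t, c);
  std::vector<double> counts;
  fitchCountsAdj(adj, ntip, &tips[0], nchar, counts);
  double cur = scoreFromCounts(counts, REAL(minsteps), k, objective);
  double moves = 0, examined = 0;
  bool truncated = false;
  std::vector<double> f0(nchar), f1(nchar);
  Frag FU, FV;
  std::vector<double> M;
  std::vector<std::string> equalTrees;
  std::set<std::string> seen;

  for (int phase = 0; phase < 2; phase++) {
    // phase 0: hill climb (accept first improvement, restart sweep)
    // phase 1: one collection sweep for equal-score distinct neighbours
    bool improvedAny = true;
    if (phase == 1) {
      improvedAny = false;
      seen.insert(topoKeyAdj(adj, ntip));
    }
    bool sweeping = true;
    while (sweeping) {
      sweeping = false;
      // canonical bisection order
      std::vector<std::pair<int, int> > edges;
      for (int a = 0; a < nnode; a++)
        for (size_t i = 0; i < adj[a].size(); i++)
          if (adj[a][i] > a) edges.push_back(std::make_pair(a, adj[a][i]));
      bool accepted = false;
      for (size_t be = 0; be < edges.size() && !accepted; be++) {
        int u = edges[be].first, v = edges[be].second;
        if (ntip < 4) break;
        buildFrag(adj, ntip, &tips[0], nchar, u, v, FU);
        buildFrag(adj, ntip, &tips[0], nchar, v, u, FV);
        double C0 = 0.0;
        for (int c = 0; c < nchar; c++) {
          double base = FU.len[c] + FV.len[c];
          if (objective == 1) {
            double e0 = base - minsteps[c];
            if (e0 < 0) e0 = 0;
            double e1 = base + 1 - minsteps[c];
            if (e1 < 0) e1 = 0;
            f0[c] = k / (k + e0);
            f1[c] = k / (k + e1);
          } else {
            f0[c] = -base;
            f1[c] = -(base + 1);
          }
          C0 += f0[c];
        }
        if (phase == 0 && C0 <= cur + EPS) continue;  // no pair can improve
        int eU = FU.single ? 1 : (int)FU.edges.size();
        int eV = FV.single ? 1 : (int)FV.edges.size();
        M.assign((size_t)eU * eV, C0);
        const u8* RU = FU.single ? &FU.rootset[0] : &FU.rootset[0];
        for (int c = 0; c < nchar; c++) {
          double d = f1[c] - f0[c];
          if (d == 0.0) continue;
          for (int i = 0; i < eU; i++) {
            u8 rc = RU[(size_t)i * nchar + c];
            const u8* RV = &FV.rootset[0];
            double* Mi = &M[(size_t)i * eV];
            for (int j = 0; j < eV; j++)
              if (!(rc & RV[(size_t)j * nchar + c])) Mi[j] += d;
          }
        }
        examined += (double)eU * eV;
        for (int i = 0; i < eU && !accepted; i++) {
          for (int j = 0; j < eV; j++) {
            double sc = M[(size_t)i * eV + j];
            if (phase == 0 && sc > cur + EPS) {
              applyMove(adj, u, v, FU, FV, FU.single ? -1 : i,
                        FV.single ? -1 : j);
              fitchCountsAdj(adj, ntip, &tips[0], nchar, counts);
              cur = scoreFromCounts(counts, REAL(minsteps), k, objective);
              moves += 1;
              accepted = true;
              break;
            }
            if (phase == 1 && std::fabs(sc - cur) <= EPS) {
              if ((int)equalTrees.size() >= bufferCap) { truncated = true; continue; }
              std::vector<std::vector<int> > cand = adj;
              applyMove(cand, u, v, FU, FV, FU.single ? -1 : i,
                        FV.single ? -1 : j);
              std::string key = topoKeyAdj(cand, ntip);
              if (seen.insert(key).second)
                equalTrees.push_back(toNewick(cand, ntip));
            }
          }
        }
      }
      if (phase == 0 && accepted && moves < maxMoves) sweeping = true;
      if (accepted && moves >= maxMoves) truncated = true;
    }
    if (phase == 0 && bufferCap <= 1) break;
  }
  return List::create(_["newick"] = String(toNewick(adj, ntip)),
                      _["score"] = cur, _["moves"] = moves,
                      _["examined"] = examined,
                      _["equal"] = wrap(equalTrees),
                      _["truncated"] = truncated);
}

// [[Rcpp::export]]
CharacterVector cpp_tbr_neighbors(IntegerMatrix edge, int ntip) {
  int nnode;
  std::vector<std::vector<int> > adj = buildAdj(edge, nnode);
  std::set<std::string> seen;
  seen.insert(topoKeyAdj(adj, ntip));
  std::vector<std::string> out;
  if (ntip < 4) return wrap(out);
  // dummy single-character data: fragments only need structure here
  std::vector<u8> tips((size_t)ntip, 1);
  Frag FU, FV;
  std::vector<std::pair<int, int> > edges;
  for (int a = 0; a < nnode; a++)
    for (size_t i = 0; i < adj[a].size(); i++)
      if (adj[a][i] > a) edges.push_back(std::make_pair(a, adj[a][i]));
  for (size_t be = 0; be < edges.size(); be++) {
    int u = edges[be].first, v = edges[be].second;
    buildFrag(adj, ntip, &tips[0], 1, u, v, FU);
    buildFrag(adj, ntip, &tips[0], 1, v, u, FV);
    int eU = FU.single ? 1 : (int)FU.edges.size();
    int eV = FV.single ? 1 : (int)FV.edges.size();
    for (int i = 0; i < eU; i++) {
      for (int j = 0; j < eV; j++) {
        std::vector<std::vector<int> > cand = adj;
        applyMove(cand, u, v, FU, FV, FU.single ? -1 : i, FV.single ? -1 : j);
        std::string key = topoKeyAdj(cand, ntip);
        if (seen.insert(key).second) out.push_back(toNewick(cand, ntip));
      }
    }
  }
  return wrap(out);
}
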