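#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Stochastic network growth engine.
//
// One iteration = up to three sequential sub-events, fired independently:
//   node event (prob pn): add a node (prob p) or delete a uniform random node,
//   edge event (prob pe): attempt addition (prob q) or attempt removal,
//   duplication event (prob pd): duplicate a node (prob r) or fuse two nodes.
// Node slots are never reused; the returned ids make duplication lineages
// traceable and runs replayable. All randomness goes through R's RNG so a
// set.seed() call on the R side gives bit-identical runs.

namespace {

struct Engine {
  std::vector< std::vector<int> > adj; // adjacency lists by internal slot
  std::vector<int> color;
  std::vector<int> id;
  std::vector<char> alive;
  std::vector<int> alive_slots;        // slots of living nodes
  std::vector<int> pos_in_alive;       // slot -> index in alive_slots (-1 if dead)
  long long m = 0;
  int next_id = 0;

  int n_alive() const { return (int)alive_slots.size(); }

  int add_node(int col) {
    int s = (int)adj.size();
    adj.push_back(std::vector<int>());
    color.push_back(col);
    id.push_back(next_id++);
    alive.push_back(1);
    pos_in_alive.push_back((int)alive_slots.size());
    alive_slots.push_back(s);
    return s;
  }

  int random_alive() const {
    int k = (int)(unif_rand() * n_alive());
    if (k >= n_alive()) k = n_alive() - 1;
    return alive_slots[k];
  }

  // two distinct living slots
  void random_pair(int &a, int &b) const {
    a = random_alive();
    do { b = random_alive(); } while (b == a);
  }

  bool connected(int a, int b) const {
    const std::vector<int> &sm = adj[a].size() <= adj[b].size() ? adj[a] : adj[b];
    int other = adj[a].size() <= adj[b].size() ? b : a;
    return std::find(sm.begin(), sm.end(), other) != sm.end();
  }

  void add_edge(int a, int b) {
    adj[a].push_back(b);
    adj[b].push_back(a);
    ++m;
  }

  static void erase_one(std::vector<int> &v, int x) {
    std::vector<int>::iterator it = std::find(v.begin(), v.end(), x);
    if (it != v.end()) { *it = v.back(); v.pop_back(); }
  }

  void remove_edge(int a, int b) {
    erase_one(adj[a], b);
    erase_one(adj[b], a);
    --m;
  }

  void remove_node(int s) {
    for (size_t i = 0; i < adj[s].size(); ++i) erase_one(adj[adj[s][i]], s);
    m -= (long long)adj[s].size();
    adj[s].clear();
    alive[s] = 0;
    int k = pos_in_alive[s];
    int last = alive_slots.back();
    alive_slots[k] = last;
    pos_in_alive[last] = k;
    alive_slots.pop_back();
    pos_in_alive[s] = -1;
  }

  // new node gets ancestor's color and edges to the ancestor's neighbours
  // (no ancestor<->duplicate edge)
  int duplicate_node(int anc) {
    std::vector<int> nbrs = adj[anc]; // copy before reallocation
    int s = add_node(color[anc]);
    for (size_t i = 0; i < nbrs.size(); ++i) add_edge(s, nbrs[i]);
    return s;
  }

  // a keeps its id and color, inherits b's edges (self-loops and duplicate
  // edges discarded), b is deleted
  void fuse_nodes(int a, int b) {
    std::vector<int> nbrs = adj[b];
    remove_node(b);
    for (size_t i = 0; i < nbrs.size(); ++i) {
      int nb = nbrs[i];
      if (nb != a && !connected(a, nb)) add_edge(a, nb);
    }
  }
};

// trace event codes (see R side for labels)
enum EvCode { EV_NODE_ADD = 1, EV_NODE_REMOVE = 2, EV_EDGE_ADD = 3,
              EV_EDGE_REMOVE = 4, EV_DUPLICATE = 5, EV_FUSE = 6 };

struct Trace {
  bool on;
  std::vector<double> iter;
  std::vector<int> code;
  std::vector<int> ok;
  std::vector<int> node_a, node_b;
  void rec(double it, int cd, bool success, int a, int b) {
    if (!on) return;
    iter.push_back(it); code.push_back(cd); ok.push_back(success ? 1 : 0);
    node_a.push_back(a); node_b.push_back(b);
  }
};

int draw_color(const NumericVector &color_cum) {
  double u = unif_rand();
  int nc = color_cum.size();
  for (int k = 0; k < nc; ++k) if (u < color_cum[k]) return k;
  return nc - 1;
}

} // namespace

// [[Rcpp::export(name = ".grow_engine")]]
List grow_engine(double pn, double pe, double pd,
                 double p, double q, double r,
                 NumericVector color_cum,
                 Nullable<NumericMatrix> ematrix_,
                 int edge_retries,
                 IntegerVector init_colors,
                 IntegerMatrix init_edges,
                 double max_nodes, double max_edges, double max_iterations,
                 double iteration_cap,
                 bool trace_on) {
  Engine g;
  Trace tr; tr.on = trace_on;
  bool use_e = ematrix_.isNotNull();
  NumericMatrix emat;
  if (use_e) emat = NumericMatrix(ematrix_);

  for (int i = 0; i < init_colors.size(); ++i) g.add_node(init_colors[i]);
  for (int e = 0; e < init_edges.nrow(); ++e) {
    int a = init_edges(e, 0), b = init_edges(e, 1);
    if (a != b && !g.connected(a, b)) g.add_edge(a, b);
  }

  bool capped = false;
  double iter = 0;
  bool stop_nodes = max_nodes > 0, stop_edges = max_edges > 0,
       stop_iter = max_iterations >= 0; // 0 is a legal iteration budget

#define DONE() ((stop_nodes && g.n_alive() >= max_nodes) || \
                (stop_edges && g.m >= max_edges))

  while (true) {
    if (stop_iter && iter >= max_iterations) break;
    if (DONE()) break;
    if (!stop_iter && iter >= iteration_cap) { capped = true; break; }
    iter += 1;

    // ---- node event ----
    if (unif_rand() < pn) {
      if (unif_rand() < p) {
        int s = g.add_node(draw_color(color_cum));
        tr.rec(iter, EV_NODE_ADD, true, g.id[s], -1);
      } else if (g.n_alive() >= 1) {
        int s = g.random_alive();
        tr.rec(iter, EV_NODE_REMOVE, true, g.id[s], -1);
        g.remove_node(s);
      } else {
        tr.rec(iter, EV_NODE_REMOVE, false, -1, -1);
      }
      if (DONE()) break;
    }

    // ---- edge event ----
    if (unif_rand() < pe) {
      if (unif_rand() < q) { // attempt addition
        bool ok = false; int a = -1, b = -1;
        if (g.n_alive() >= 2) {
          if (use_e) {
            for (int t = 0; t < edge_retries; ++t) {
              g.random_pair(a, b);
              if (unif_rand() < emat(g.color[a], g.color[b]) &&
                  !g.connected(a, b)) {
                g.add_edge(a, b); ok = true; break;
              }
            }
          } else {
            g.random_pair(a, b);
            if (!g.connected(a, b)) { g.add_edge(a, b); ok = true; }
          }
        }
        tr.rec(iter, EV_EDGE_ADD, ok, ok ? g.id[a] : -1, ok ? g.id[b] : -1);
      } else { // attempt removal
        bool ok = false; int a = -1, b = -1;
        if (g.n_alive() >= 2) {
          g.random_pair(a, b);
          if (g.connected(a, b)) { g.remove_edge(a, b); ok = true; }
        }
        tr.rec(iter, EV_EDGE_REMOVE, ok, ok ? g.id[a] : -1, ok ? g.id[b] : -1);
      }
      if (DONE()) break;
    }

    // ---- duplication / fusion event ----
    if (unif_rand() < pd) {
      if (unif_rand() < r) {
        if (g.n_alive() >= 1) {
          int anc = g.random_alive();
          int s = g.duplicate_node(anc);
          tr.rec(iter, EV_DUPLICATE, true, g.id[anc], g.id[s]);
        } else tr.rec(iter, EV_DUPLICATE, false, -1, -1);
      } else {
        if (g.n_alive() >= 2) {
          int a, b; g.random_pair(a, b);
          tr.rec(iter, EV_FUSE, true, g.id[a], g.id[b]);
          g.fuse_nodes(a, b);
        } else tr.rec(iter, EV_FUSE, false, -1, -1);
      }
      if (DONE()) break;
    }
  }
#undef DONE

  // compact living nodes, edges as 1-based indices into the output order
  int n_out = g.n_alive();
  std::vector<int> slot_to_out(g.adj.size(), -1);
  IntegerVector out_ids(n_out), out_colors(n_out);
  {
    int j = 0;
    for (size_t s = 0; s < g.adj.size(); ++s) {
      if (!g.alive[s]) continue;
      slot_to_out[s] = j;
      out_ids[j] = g.id[s];
      out_colors[j] = g.color[s];
      ++j;
    }
  }
  IntegerMatrix out_edges((int)g.m, 2);
  {
    int e = 0;
    for (size_t s = 0; s < g.adj.size(); ++s) {
      if (!g.alive[s]) continue;
      for (size_t i = 0; i < g.adj[s].size(); ++i) {
        size_t t = (size_t)g.adj[s][i];
        if (t > s) {
          out_edges(e, 0) = slot_to_out[s] + 1;
          out_edges(e, 1) = slot_to_out[t] + 1;
          ++e;
        }
      }
    }
  }

  List out = List::create(
    _["ids"] = out_ids,
    _["colors"] = out_colors,
    _["edges"] = out_edges,
    _["iterations"] = iter,
    _["capped"] = capped);
  if (trace_on) {
    out["trace"] = DataFrame::create(
      _["iteration"] = wrap(tr.iter),
      _["event"] = wrap(tr.code),
      _["success"] = wrap(tr.ok),
      _["node_a"] = wrap(tr.node_a),
      _["node_b"] = wrap(tr.node_b));
  }
  return out;
}
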