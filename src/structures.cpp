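// Mutable containers for the discrete-event core, held behind external
// pointers so the hot paths (event queue, spike log, transition trace,
// trajectory recorder) run without copy-on-write of large R vectors.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// binary min-heap of (key, id); key packs (due_time, seq) so ties are FIFO

struct EvHeap {
  std::vector<double> key;
  std::vector<int> id;
};

// [[Rcpp::export]]
SEXP heap_new_cpp() {
  XPtr<EvHeap> p(new EvHeap(), true);
  return p;
}

// [[Rcpp::export]]
void heap_push_cpp(SEXP hp, double key, int id) {
  XPtr<EvHeap> h(hp);
  h->key.push_back(key);
  h->id.push_back(id);
  size_t i = h->key.size() - 1;
  while (i > 0) {
    size_t par = (i - 1) / 2;
    if (h->key[par] <= h->key[i]) break;
    std::swap(h->key[par], h->key[i]);
    std::swap(h->id[par], h->id[i]);
    i = par;
  }
}

// [[Rcpp::export]]
int heap_pop_cpp(SEXP hp) {
  XPtr<EvHeap> h(hp);
  size_t n = h->key.size();
  if (n == 0) return NA_INTEGER;
  int top = h->id[0];
  h->key[0] = h->key[n - 1];
  h->id[0] = h->id[n - 1];
  h->key.pop_back();
  h->id.pop_back();
  n--;
  size_t i = 0;
  while (true) {
    size_t l = 2 * i + 1, r = 2 * i + 2, s = i;
    if (l < n && h->key[l] < h->key[s]) s = l;
    if (r < n && h->key[r] < h->key[s]) s = r;
    if (s == i) break;
    std::swap(h->key[s], h->key[i]);
    std::swap(h->id[s], h->id[i]);
    i = s;
  }
  return top;
}

// [[Rcpp::export]]
double heap_min_key_cpp(SEXP hp) {
  XPtr<EvHeap> h(hp);
  if (h->key.empty()) return NA_REAL;
  return h->key[0];
}

// [[Rcpp::export]]
int heap_size_cpp(SEXP hp) {
  XPtr<EvHeap> h(hp);
  return (int)h->key.size();
}

// ---------------------------------------------------------------------------
// spike log: (t_us, pool code, cell) with vectorised append

struct SpikeLog {
  std::vector<double> t;
  std::vector<int> code;
  std::vector<int> cell;
};

// [[Rcpp::export]]
SEXP spikelog_new_cpp() {
  XPtr<SpikeLog> p(new SpikeLog(), true);
  return p;
}

// [[Rcpp::export]]
void spikelog_add_cpp(SEXP lp, double t_us, int code, IntegerVector cells) {
  XPtr<SpikeLog> l(lp);
  for (int i = 0; i < cells.size(); i++) {
    l->t.push_back(t_us);
    l->code.push_back(code);
    l->cell.push_back(cells[i]);
  }
}

// [[Rcpp::export]]
int spikelog_size_cpp(SEXP lp) {
  XPtr<SpikeLog> l(lp);
  return (int)l->t.size();
}

// [[Rcpp::export]]
List spikelog_collect_cpp(SEXP lp) {
  XPtr<SpikeLog> l(lp);
  return List::create(_["t_us"] = wrap(l->t), _["code"] = wrap(l->code),
                      _["cell"] = wrap(l->cell));
}

// ---------------------------------------------------------------------------
// transition trace: one row per dispatch

struct TraceLog {
  std::vector<double> t;
  std::vector<std::string> comp, ev, from, to;
};

// [[Rcpp::export]]
SEXP trace_new_cpp() {
  XPtr<TraceLog> p(new TraceLog(), true);
  return p;
}

// [[Rcpp::export]]
void trace_add_cpp(SEXP tp, double t_us, std::string comp, std::string ev,
                   std::string from, std::string to) {
  XPtr<TraceLog> t(tp);
  t->t.push_back(t_us);
  t->comp.push_back(comp);
  t->ev.push_back(ev);
  t->from.push_back(from);
  t->to.push_back(to);
}

// [[Rcpp::export]]
List trace_collect_cpp(SEXP tp) {
  XPtr<TraceLog> t(tp);
  return List::create(_["t_us"] = wrap(t->t), _["component"] = wrap(t->comp),
                      _["event"] = wrap(t->ev), _["from_state"] = wrap(t->from),
                      _["to_state"] = wrap(t->to));
}

// ---------------------------------------------------------------------------
// trajectory recorder: fixed-width rows of (theta, omega) plus contact flag

struct TrajRec {
  int nw;
  std::vector<double> theta;
  std::vector<double> omega;
  std::vector<int> contact;
};

// [[Rcpp::export]]
SEXP traj_new_cpp(int nw) {
  XPtr<TrajRec> p(new TrajRec(), true);
  p->nw = nw;
  return p;
}

// [[Rcpp::export]]
void traj_add_cpp(SEXP tp, NumericVector theta, NumericVector omega,
                  int contact) {
  XPtr<TrajRec> t(tp);
  t->theta.insert(t->theta.end(), theta.begin(), theta.end());
  t->omega.insert(t->omega.end(), omega.begin(), omega.end());
  t->contact.push_back(contact);
}

// [[Rcpp::export]]
List traj_collect_cpp(SEXP tp) {
  XPtr<TrajRec> t(tp);
  int nrow = t->nw > 0 ? (int)t->theta.size() / t->nw : 0;
  NumericMatrix th(t->nw, nrow), om(t->nw, nrow);
  std::copy(t->theta.begin(), t->theta.end(), th.begin());
  std::copy(t->omega.begin(), t->omega.end(), om.begin());
  return List::create(_["theta"] = th, _["omega"] = om,
                      _["contact"] = wrap(t->contact), _["n"] = nrow);
}
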