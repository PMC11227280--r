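// Fixed-structure nearest-neighbor evaluation core.  The parameter tables
// live on the R side (R/energy.R) and are passed in as a list; this file
// only evaluates.  Pair-type order everywhere: CG, GC, GU, UG, AU, UA.

#include <Rcpp.h>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

const double E_INF = 1e9;

struct ETables {
  double stack[6][6];
  std::vector<double> hairpin, bulge, internal;
  double mmh[6][4][4], mmi[6][4][4], mmi23[6][4][4];
  double mm1n[6];
  double terminal_au, ninio_slope, ninio_max, ml_closing, ml_intern;
  std::unordered_map<std::string, double> tetra, hexa, tri;
};

int base_idx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': case 'T': return 3;
  }
  return -1;
}

// pair-type index in CG,GC,GU,UG,AU,UA order; -1 if not pairable
int pt_idx(int a, int b) {
  if (a == 1 && b == 2) return 0;
  if (a == 2 && b == 1) return 1;
  if (a == 2 && b == 3) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 0 && b == 3) return 4;
  if (a == 3 && b == 0) return 5;
  return -1;
}

int pt_rev(int pt) {
  static const int rev[6] = {1, 0, 3, 2, 5, 4};
  return rev[pt];
}

bool au_end(int pt) { return pt >= 2; }

void read_mm(const NumericMatrix& m, double out[6][4][4]) {
  // R side flattens to 6 x 16 (pair x (4*x + y))
  for (int p = 0; p < 6; ++p)
    for (int x = 0; x < 4; ++x)
      for (int y = 0; y < 4; ++y) out[p][x][y] = m(p, 4 * x + y);
}

std::unordered_map<std::string, double> read_named(const NumericVector& v) {
  std::unordered_map<std::string, double> out;
  CharacterVector nm = v.names();
  for (int k = 0; k < v.size(); ++k) out[as<std::string>(nm[k])] = v[k];
  return out;
}

ETables read_tables(const List& tb) {
  ETables t;
  NumericMatrix st = tb["stack"];
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) t.stack[a][b] = st(a, b);
  t.hairpin = as<std::vector<double>>(tb["hairpin"]);
  t.bulge = as<std::vector<double>>(tb["bulge"]);
  t.internal = as<std::vector<double>>(tb["internal"]);
  read_mm(tb["mmh"], t.mmh);
  read_mm(tb["mmi"], t.mmi);
  read_mm(tb["mmi23"], t.mmi23);
  NumericVector m1 = tb["mm1n"];
  for (int p = 0; p < 6; ++p) t.mm1n[p] = m1[p];
  t.terminal_au = as<double>(tb["terminal_au"]);
  t.ninio_slope = as<double>(tb["ninio_slope"]);
  t.ninio_max = as<double>(tb["ninio_max"]);
  t.ml_closing = as<double>(tb["ml_closing"]);
  t.ml_intern = as<double>(tb["ml_intern"]);
  t.tetra = read_named(tb["tetraloops"]);
  t.hexa = read_named(tb["hexaloops"]);
  t.tri = read_named(tb["triloops"]);
  return t;
}

double loop_init(const std::vector<double>& tab, int size) {
  if (size <= (int)tab.size()) return tab[size - 1];
  return tab[29] + 1.079 * std::log((double)size / 30.0);
}

double hairpin_e(const ETables& t, const std::string& s, const std::vector<int>& b,
                 int i, int j, int pt) {
  int size = j - i - 1;
  if (size < 3) return E_INF;
  if (size == 4 || size == 6 || size == 3) {
    std::string key = s.substr(i, size + 2);
    const std::unordered_map<std::string, double>* m =
      size == 4 ? &t.tetra : (size == 6 ? &t.hexa : &t.tri);
    auto it = m->find(key);
    if (it != m->end()) {
      if (size == 3) return it->second + (au_end(pt) ? t.terminal_au : 0.0);
      return it->second;
    }
  }
  if (size == 3) return loop_init(t.hairpin, size) + (au_end(pt) ? t.terminal_au : 0.0);
  return loop_init(t.hairpin, size) + t.mmh[pt][b[i + 1]][b[j - 1]];
}

double two_loop_e(const ETables& t, const std::vector<int>& b,
                  int i, int j, int k, int l, int pto, int pti) {
  int n1 = k - i - 1, n2 = j - l - 1;
  int ptir = pt_rev(pti);
  if (n1 == 0 && n2 == 0) return t.stack[pto][ptir];
  if (n1 == 0 || n2 == 0) {
    int size = n1 + n2;
    double e = loop_init(t.bulge, size);
    if (size == 1) {
      e += t.stack[pto][ptir];
    } else {
      e += (au_end(pto) ? t.terminal_au : 0.0) + (au_end(pti) ? t.terminal_au : 0.0);
    }
    return e;
  }
  int ns = std::min(n1, n2), nl = std::max(n1, n2);
  double base = loop_init(t.internal, n1 + n2) +
    std::min(t.ninio_max, t.ninio_slope * (nl - ns));
  if (ns == 1 && nl > 2) return base + t.mm1n[pto] + t.mm1n[ptir];
  const double(*mm)[4][4] = (ns == 2 && nl == 3) ? t.mmi23 : t.mmi;
  return base + mm[pto][b[i + 1]][b[j - 1]] + mm[ptir][b[l + 1]][b[k - 1]];
}

// evaluate one structure; pairs as parallel (i, j) vectors, 0-based, i < j,
// sorted by i, assumed nested and canonical (validated on the R side)
double eval_structure(const ETables& t, const std::string& s, const std::vector<int>& b,
                      const std::vector<int>& pi, const std::vector<int>& pj) {
  int np = pi.size();
  if (np == 0) return 0.0;
  std::vector<int> pt(np), parent(np, -1);
  for (int k = 0; k < np; ++k) {
    pt[k] = pt_idx(b[pi[k]], b[pj[k]]);
    if (pt[k] < 0) return NA_REAL;
  }
  std::vector<int> stack;
  std::vector<std::vector<int>> children(np);
  for (int k = 0; k < np; ++k) {
    while (!stack.empty() && pi[k] > pj[stack.back()]) stack.pop_back();
    if (!stack.empty()) {
      parent[k] = stack.back();
      children[stack.back()].push_back(k);
    }
    stack.push_back(k);
  }
  double e = 0.0;
  bool impossible = false;
  for (int k = 0; k < np; ++k) {
    if (children[k].empty()) {
      double h = hairpin_e(t, s, b, pi[k], pj[k], pt[k]);
      if (h >= E_INF) impossible = true;
      e += h;
    } else if (children[k].size() == 1) {
      int c = children[k][0];
      e += two_loop_e(t, b, pi[k], pj[k], pi[c], pj[c], pt[k], pt[c]);
    } else {
      e += t.ml_closing + t.ml_intern * (1 + (int)children[k].size());
      if (au_end(pt[k])) e += t.terminal_au;
      for (int c : children[k])
        if (au_end(pt[c])) e += t.terminal_au;
    }
    if (parent[k] < 0 && au_end(pt[k])) e += t.terminal_au;
  }
  if (impossible) return R_PosInf;
  return std::round(e * 100.0) / 100.0;
}

std::vector<int> base_codes(const std::string& s) {
  std::vector<int> b(s.size());
  for (size_t k = 0; k < s.size(); ++k) b[k] = base_idx(s[k]);
  return b;
}

}  // namespace

// [[Rcpp::export(name = ".energy_eval")]]
double energy_eval(std::string seq, IntegerMatrix pairs, List tables) {
  ETables t = read_tables(tables);
  std::vector<int> b = base_codes(seq);
  int np = pairs.nrow();
  std::vector<int> pi(np), pj(np);
  for (int k = 0; k < np; ++k) {
    pi[k] = pairs(k, 0);
    pj[k] = pairs(k, 1);
  }
  return eval_structure(t, seq, b, pi, pj);
}

// Batch evaluation: `flat` rows are (structure index 1..n, i, j), grouped by
// structure index with i ascending within each structure.
// [[Rcpp::export(name = ".energy_batch")]]
NumericVector energy_batch(std::string seq, IntegerMatrix flat, int n, List tables) {
  ETables t = read_tables(tables);
  std::vector<int> b = base_codes(seq);
  NumericVector out(n);
  int r = 0, m = flat.nrow();
  for (int s = 1; s <= n; ++s) {
    std::vector<int> pi, pj;
    while (r < m && flat(r, 0) == s) {
      pi.push_back(flat(r, 1));
      pj.push_back(flat(r, 2));
      ++r;
    }
    out[s - 1] = eval_structure(t, seq, b, pi, pj);
  }
  return out;
}
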