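// Structured-motif matcher (PatScan dialect subset) and an independent
// exhaustive reference enumerator.
//
// Element encoding received from R (compile_pattern_spec()):
//   literal: type=0, chars = string over A,C,G,U,N,R,Y,S,W
//   segment: type=1, seg id (1-based), min, max
//   backref: type=2, seg id it pairs with, 4x4 logical rule matrix
//            (rows = segment base, cols = partner base, order A,C,G,U),
//            budgets m (mismatches), d (deletions), i (insertions)
//   alternation: type=3, branches = character vector of literals
//
// A back-reference with budgets [m,d,i] matches a substring q when q can be
// aligned against the reverse of the bound segment p with <= d segment
// positions deleted, <= i partner positions inserted, and <= m aligned
// columns whose (p base, q base) is outside the pairing rule.  Sequence N
// never satisfies a pairing rule.

#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <set>
#include <tuple>
#include <vector>

using namespace Rcpp;

namespace {

const int BASE_N = 4;  // code for N

struct Elem {
  int type = 0;
  std::vector<uint8_t> lit;                 // literal masks
  int segid = 0, minl = 0, maxl = 0;        // segment
  int m = 0, d = 0, ins = 0;                // backref budgets
  bool rule[5][5] = {{false}};              // backref pairing rule
  std::vector<std::vector<uint8_t>> branches;  // alternation literal masks
};

int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': return 3;
    case 'T': return 3;
    case 'N': return 4;
  }
  stop("sequence contains a character outside {A,C,G,U,T,N}");
  return -1;
}

// pattern character -> mask over base codes (bit 4 = matches sequence N)
uint8_t pat_mask(char c) {
  switch (c) {
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 4;
    case 'U': case 'T': return 8;
    case 'R': return 1 | 4;
    case 'Y': return 2 | 8;
    case 'S': return 2 | 4;
    case 'W': return 1 | 8;
    case 'N': return 1 | 2 | 4 | 8 | 16;
  }
  stop("pattern literal contains unsupported character");
  return 0;
}

std::vector<uint8_t> lit_masks(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t k = 0; k < s.size(); ++k) v[k] = pat_mask(s[k]);
  return v;
}

std::vector<Elem> decode_elems(const List& elems) {
  std::vector<Elem> out;
  for (int k = 0; k < elems.size(); ++k) {
    List e = elems[k];
    Elem el;
    el.type = as<int>(e["type"]);
    if (el.type == 0) {
      el.lit = lit_masks(as<std::string>(e["chars"]));
    } else if (el.type == 1) {
      el.segid = as<int>(e["seg"]);
      el.minl = as<int>(e["min"]);
      el.maxl = as<int>(e["max"]);
    } else if (el.type == 2) {
      el.segid = as<int>(e["seg"]);
      el.m = as<int>(e["m"]);
      el.d = as<int>(e["d"]);
      el.ins = as<int>(e["i"]);
      LogicalMatrix rm = e["rule"];
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b) el.rule[a][b] = rm(a, b);
      // N never pairs
      for (int a = 0; a < 5; ++a) { el.rule[a][4] = false; el.rule[4][a] = false; }
    } else if (el.type == 3) {
      CharacterVector br = e["branches"];
      for (int b = 0; b < br.size(); ++b)
        el.branches.push_back(lit_masks(as<std::string>(br[b])));
    } else {
      stop("unknown element type");
    }
    out.push_back(el);
  }
  return out;
}

std::vector<int> encode_seq(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t k = 0; k < s.size(); ++k) v[k] = base_code(s[k]);
  return v;
}

bool lit_ok(const std::vector<uint8_t>& lit, const std::vector<int>& seq, int pos) {
  if (pos + (int)lit.size() > (int)seq.size()) return false;
  for (size_t k = 0; k < lit.size(); ++k)
    if (!(lit[k] & (1 << seq[pos + k]))) return false;
  return true;
}

struct BrefAln {
  bool feasible = false;
  int mism = 0, del = 0, ins = 0;
  std::vector<std::pair<int, int>> pairs;  // absolute (segment pos, partner pos)
};

// Banded DP: align reverse(p) against q, minimising mismatches for each
// (deletions, insertions) budget split; canonical traceback prefers aligned
// columns, then deletions, then insertions.
BrefAln backref_align(const std::vector<int>& seq, const Elem& el,
                      int p_start, int p_len, int q_start, int q_len) {
  const int D = el.d, I = el.ins;
  const int INFTY = 1 << 20;
  BrefAln res;
  if (q_len < p_len - D || q_len > p_len + I) return res;
  // dp[a][b][du][iu]
  auto idx = [&](int a, int b, int du, int iu) {
    return ((a * (q_len + 1) + b) * (D + 1) + du) * (I + 1) + iu;
  };
  std::vector<int> dp((p_len + 1) * (q_len + 1) * (D + 1) * (I + 1), INFTY);
  dp[idx(0, 0, 0, 0)] = 0;
  auto pbase = [&](int a) { return seq[p_start + p_len - 1 - a]; };  // reverse of p
  auto qbase = [&](int b) { return seq[q_start + b]; };
  for (int a = 0; a <= p_len; ++a)
    for (int b = 0; b <= q_len; ++b)
      for (int du = 0; du <= D; ++du)
        for (int iu = 0; iu <= I; ++iu) {
          int cur = dp[idx(a, b, du, iu)];
          if (cur >= INFTY) continue;
          if (a < p_len && b < q_len) {
            int cost = el.rule[pbase(a)][qbase(b)] ? 0 : 1;
            int& t = dp[idx(a + 1, b + 1, du, iu)];
            if (cur + cost < t) t = cur + cost;
          }
          if (a < p_len && du < D) {
            int& t = dp[idx(a + 1, b, du + 1, iu)];
            if (cur < t) t = cur;
          }
          if (b < q_len && iu < I) {
            int& t = dp[idx(a, b + 1, du, iu + 1)];
            if (cur < t) t = cur;
          }
        }
  int best = INFTY, bdu = 0, biu = 0;
  for (int du = 0; du <= D; ++du)
    for (int iu = 0; iu <= I; ++iu) {
      int v = dp[idx(p_len, q_len, du, iu)];
      if (v < best || (v == best && du + iu < bdu + biu)) {
        best = v; bdu = du; biu = iu;
      }
    }
  if (best > el.m) return res;
  res.feasible = true;
  res.mism = best; res.del = bdu; res.ins = biu;
  // traceback
  int a = p_len, b = q_len, du = bdu, iu = biu;
  while (a > 0 || b > 0) {
    int cur = dp[idx(a, b, du, iu)];
    if (a > 0 && b > 0) {
      int cost = el.rule[pbase(a - 1)][qbase(b - 1)] ? 0 : 1;
      if (dp[idx(a - 1, b - 1, du, iu)] + cost == cur) {
        if (cost == 0)
          res.pairs.push_back({p_start + p_len - 1 - (a - 1), q_start + (b - 1)});
        --a; --b;
        continue;
      }
    }
    if (a > 0 && du > 0 && dp[idx(a - 1, b, du - 1, iu)] == cur) {
      --a; --du;
      continue;
    }
    --b; --iu;
  }
  std::reverse(res.pairs.begin(), res.pairs.end());
  return res;
}

struct MatchRec {
  int start = 0, end = 0;
  std::vector<int> iv;           // 2 per element: start, end
  std::vector<int> branch;       // per element, -1 or branch index
  std::vector<BrefAln> alns;     // per element (feasible only for backrefs)
};

struct Ctx {
  const std::vector<Elem>* elems;
  const std::vector<int>* seq;
  std::vector<int> seg_start, seg_len;      // by segment id
  std::vector<int> min_rest;                // min span of elements k..end
  std::unordered_map<uint64_t, BrefAln> memo;
  std::vector<MatchRec> out;
};

// pack a (elem, p_start, p_len, q_start, q_len) memo key into disjoint bit
// fields: elem < 16, positions < 2^20, lengths < 128
uint64_t memo_key(int k, int ps, int pl, int qs, int ql) {
  return (((uint64_t)k) << 60) | (((uint64_t)ps) << 40) | (((uint64_t)pl) << 33) |
         (((uint64_t)qs) << 13) | (uint64_t)ql;
}

void engine_rec(Ctx& ctx, int k, int pos, MatchRec& cur) {
  const std::vector<Elem>& elems = *ctx.elems;
  const std::vector<int>& seq = *ctx.seq;
  int n = seq.size();
  if (k == (int)elems.size()) {
    // each recursion path carries a distinct interval vector (alternation
    // branches are deduplicated by length at the branch point), so no
    // further dedup is needed
    cur.end = pos;
    ctx.out.push_back(cur);
    return;
  }
  if (pos + ctx.min_rest[k] > n) return;
  const Elem& el = elems[k];
  if (el.type == 0) {
    if (!lit_ok(el.lit, seq, pos)) return;
    cur.iv[2 * k] = pos; cur.iv[2 * k + 1] = pos + el.lit.size();
    engine_rec(ctx, k + 1, pos + el.lit.size(), cur);
  } else if (el.type == 1) {
    for (int L = el.minl; L <= el.maxl; ++L) {
      if (pos + L > n) break;
      ctx.seg_start[el.segid] = pos; ctx.seg_len[el.segid] = L;
      cur.iv[2 * k] = pos; cur.iv[2 * k + 1] = pos + L;
      engine_rec(ctx, k + 1, pos + L, cur);
    }
  } else if (el.type == 2) {
    int ps = ctx.seg_start[el.segid], pl = ctx.seg_len[el.segid];
    int lo = std::max(0, pl - el.d), hi = pl + el.ins;
    for (int L = lo; L <= hi; ++L) {
      if (pos + L > n) break;
      uint64_t key = memo_key(k, ps, pl, pos, L);
      auto it = ctx.memo.find(key);
      if (it == ctx.memo.end())
        it = ctx.memo.emplace(key, backref_align(seq, el, ps, pl, pos, L)).first;
      if (!it->second.feasible) continue;
      cur.iv[2 * k] = pos; cur.iv[2 * k + 1] = pos + L;
      cur.alns[k] = it->second;
      engine_rec(ctx, k + 1, pos + L, cur);
    }
  } else {  // alternation: one match per distinct branch length
    std::set<int> done_len;
    for (size_t b = 0; b < el.branches.size(); ++b) {
      int L = el.branches[b].size();
      if (done_len.count(L)) continue;
      if (lit_ok(el.branches[b], seq, pos)) {
        done_len.insert(L);
        cur.iv[2 * k] = pos; cur.iv[2 * k + 1] = pos + L;
        cur.branch[k] = b;
        engine_rec(ctx, k + 1, pos + L, cur);
      }
    }
  }
}

int elem_min_span(const Elem& el) {
  switch (el.type) {
    case 0: return el.lit.size();
    case 1: return el.minl;
    case 2: return 0;  // depends on bound segment; 0 is a safe lower bound
    default: {
      int mn = INT_MAX;
      for (auto& b : el.branches) mn = std::min(mn, (int)b.size());
      return mn == INT_MAX ? 0 : mn;
    }
  }
}

List pack_matches(std::vector<MatchRec>& recs, int nelem) {
  std::sort(recs.begin(), recs.end(), [](const MatchRec& a, const MatchRec& b) {
    if (a.start != b.start) return a.start < b.start;
    if (a.iv != b.iv) return a.iv < b.iv;
    return a.end < b.end;
  });
  List out(recs.size());
  for (size_t r = 0; r < recs.size(); ++r) {
    const MatchRec& m = recs[r];
    IntegerMatrix iv(nelem, 2);
    for (int k = 0; k < nelem; ++k) { iv(k, 0) = m.iv[2 * k]; iv(k, 1) = m.iv[2 * k + 1]; }
    List brefs(nelem);
    for (int k = 0; k < nelem; ++k) {
      if (!m.alns.empty() && m.alns[k].feasible) {
        const BrefAln& a = m.alns[k];
        IntegerMatrix pr(a.pairs.size(), 2);
        for (size_t p = 0; p < a.pairs.size(); ++p) {
          pr(p, 0) = a.pairs[p].first; pr(p, 1) = a.pairs[p].second;
        }
        brefs[k] = List::create(_["mismatches"] = a.mism, _["deletions"] = a.del,
                                _["insertions"] = a.ins, _["pairs"] = pr);
      }
    }
    IntegerVector branch(nelem);
    for (int k = 0; k < nelem; ++k)
      branch[k] = m.branch.empty() ? -1 : m.branch[k];
    out[r] = List::create(_["start"] = m.start, _["end"] = m.end,
                          _["intervals"] = iv, _["backrefs"] = brefs,
                          _["branch"] = branch);
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".engine_match")]]
List engine_match(List elems, std::string seq) {
  std::vector<Elem> ev = decode_elems(elems);
  std::vector<int> sv = encode_seq(seq);
  int nelem = ev.size();
  int nseg = 0;
  for (auto& e : ev) nseg = std::max(nseg, e.segid);
  Ctx ctx;
  ctx.elems = &ev; ctx.seq = &sv;
  ctx.seg_start.assign(nseg + 1, 0);
  ctx.seg_len.assign(nseg + 1, 0);
  ctx.min_rest.assign(nelem + 1, 0);
  for (int k = nelem - 1; k >= 0; --k)
    ctx.min_rest[k] = ctx.min_rest[k + 1] + elem_min_span(ev[k]);
  for (int start = 0; start <= (int)sv.size(); ++start) {
    MatchRec cur;
    cur.start = start;
    cur.iv.assign(2 * nelem, 0);
    cur.branch.assign(nelem, -1);
    cur.alns.assign(nelem, BrefAln());
    engine_rec(ctx, 0, start, cur);
  }
  return pack_matches(ctx.out, nelem);
}

// ---------------------------------------------------------------------------
// Independent reference enumerator: tries every start and every element
// length assignment, then verifies each assignment linearly; back-references
// are verified by explicit enumeration of every placement of deletions and
// insertions (no dynamic programming, no pruning).
// ---------------------------------------------------------------------------

namespace {

// does any alignment of reverse(p) vs q with exactly du deletions (a subset
// of reversed-p positions) and iu insertions (a subset of q positions) leave
// <= m mismatches?  enumerate subsets recursively.
bool naive_bref_subsets(const std::vector<int>& rp, const std::vector<int>& q,
                        const Elem& el, size_t ai, size_t bi, int du, int iu,
                        int mism) {
  if (mism > el.m) return false;
  if (ai == rp.size() && bi == q.size()) return du == 0 && iu == 0;
  // option 1: delete current p position
  if (ai < rp.size() && du > 0 &&
      naive_bref_subsets(rp, q, el, ai + 1, bi, du - 1, iu, mism))
    return true;
  // option 2: insert current q position
  if (bi < q.size() && iu > 0 &&
      naive_bref_subsets(rp, q, el, ai, bi + 1, du, iu - 1, mism))
    return true;
  // option 3: align
  if (ai < rp.size() && bi < q.size()) {
    int add = el.rule[rp[ai]][q[bi]] ? 0 : 1;
    if (naive_bref_subsets(rp, q, el, ai + 1, bi + 1, du, iu, mism + add))
      return true;
  }
  return false;
}

bool naive_bref_ok(const std::vector<int>& seq, const Elem& el,
                   int p_start, int p_len, int q_start, int q_len) {
  std::vector<int> rp(p_len), q(q_len);
  for (int a = 0; a < p_len; ++a) rp[a] = seq[p_start + p_len - 1 - a];
  for (int b = 0; b < q_len; ++b) q[b] = seq[q_start + b];
  for (int du = 0; du <= el.d; ++du)
    for (int iu = 0; iu <= el.ins; ++iu) {
      if (p_len - du + iu != q_len) continue;
      if (naive_bref_subsets(rp, q, el, 0, 0, du, iu, 0)) return true;
    }
  return false;
}

struct NaiveCtx {
  const std::vector<Elem>* elems;
  const std::vector<int>* seq;
  std::set<std::vector<int>> seen;
  std::vector<MatchRec> out;
};

// enumerate a full length assignment (lens[k] for every element, and a
// branch choice for alternations), then verify it from scratch
void naive_assign(NaiveCtx& ctx, int start, size_t k, std::vector<int>& lens,
                  std::vector<int>& branch) {
  const std::vector<Elem>& elems = *ctx.elems;
  const std::vector<int>& seq = *ctx.seq;
  if (k == elems.size()) {
    // verify linearly
    int pos = start;
    std::vector<int> seg_start(16, 0), seg_len(16, 0);
    std::vector<int> iv(2 * elems.size());
    for (size_t j = 0; j < elems.size(); ++j) {
      const Elem& el = elems[j];
      int L = lens[j];
      if (pos + L > (int)seq.size()) return;
      if (el.type == 0) {
        if (!lit_ok(el.lit, seq, pos)) return;
      } else if (el.type == 1) {
        if ((int)seg_start.size() <= el.segid) { seg_start.resize(el.segid + 1); seg_len.resize(el.segid + 1); }
        seg_start[el.segid] = pos; seg_len[el.segid] = L;
      } else if (el.type == 2) {
        if (!naive_bref_ok(seq, el, seg_start[el.segid], seg_len[el.segid], pos, L))
          return;
      } else {
        if (!lit_ok(el.branches[branch[j]], seq, pos)) return;
      }
      iv[2 * j] = pos; iv[2 * j + 1] = pos + L;
      pos += L;
    }
    std::vector<int> key = iv;
    key.push_back(start);
    if (ctx.seen.insert(key).second) {
      MatchRec m;
      m.start = start; m.end = pos; m.iv = iv;
      m.branch.assign(elems.size(), -1);
      for (size_t j = 0; j < elems.size(); ++j)
        if (elems[j].type == 3) m.branch[j] = branch[j];
      ctx.out.push_back(m);
    }
    return;
  }
  const Elem& el = elems[k];
  if (el.type == 0) {
    lens[k] = el.lit.size();
    naive_assign(ctx, start, k + 1, lens, branch);
  } else if (el.type == 1) {
    for (int L = el.minl; L <= el.maxl; ++L) {
      lens[k] = L;
      naive_assign(ctx, start, k + 1, lens, branch);
    }
  } else if (el.type == 2) {
    // partner length depends on the segment's length choice earlier in lens
    int pl = -1;
    for (size_t j = 0; j < k; ++j)
      if (elems[j].type == 1 && elems[j].segid == el.segid) pl = lens[j];
    for (int L = std::max(0, pl - el.d); L <= pl + el.ins; ++L) {
      lens[k] = L;
      naive_assign(ctx, start, k + 1, lens, branch);
    }
  } else {
    for (size_t b = 0; b < el.branches.size(); ++b) {
      lens[k] = el.branches[b].size();
      branch[k] = b;
      naive_assign(ctx, start, k + 1, lens, branch);
    }
  }
}

}  // namespace

// Columnar variant of the engine for high-volume scans: one call returns
// all matches as flat matrices instead of per-match R lists.
// [[Rcpp::export(name = ".engine_scan")]]
List engine_scan(List elems, std::string seq) {
  std::vector<Elem> ev = decode_elems(elems);
  std::vector<int> sv = encode_seq(seq);
  int nelem = ev.size();
  int nseg = 0;
  for (auto& e : ev) nseg = std::max(nseg, e.segid);
  Ctx ctx;
  ctx.elems = &ev; ctx.seq = &sv;
  ctx.seg_start.assign(nseg + 1, 0);
  ctx.seg_len.assign(nseg + 1, 0);
  ctx.min_rest.assign(nelem + 1, 0);
  for (int k = nelem - 1; k >= 0; --k)
    ctx.min_rest[k] = ctx.min_rest[k + 1] + elem_min_span(ev[k]);
  for (int start = 0; start <= (int)sv.size(); ++start) {
    MatchRec cur;
    cur.start = start;
    cur.iv.assign(2 * nelem, 0);
    cur.branch.assign(nelem, -1);
    cur.alns.assign(nelem, BrefAln());
    engine_rec(ctx, 0, start, cur);
  }
  std::vector<MatchRec>& recs = ctx.out;
  std::sort(recs.begin(), recs.end(), [](const MatchRec& a, const MatchRec& b) {
    if (a.start != b.start) return a.start < b.start;
    if (a.iv != b.iv) return a.iv < b.iv;
    return a.end < b.end;
  });
  int n = recs.size();
  IntegerVector start(n), end(n);
  IntegerMatrix iv(n, 2 * nelem), branch(n, nelem);
  // per-backref realised budgets, one 3-column matrix per backref element
  std::vector<int> bref_elems;
  for (int k = 0; k < nelem; ++k)
    if (ev[k].type == 2) bref_elems.push_back(k);
  List bref_stats(bref_elems.size());
  std::vector<IntegerMatrix> stats;
  for (size_t z = 0; z < bref_elems.size(); ++z) stats.push_back(IntegerMatrix(n, 3));
  size_t total_pairs = 0;
  for (auto& m : recs)
    for (auto& a : m.alns) total_pairs += a.pairs.size();
  IntegerMatrix flat(total_pairs, 3);
  size_t fr = 0;
  for (int r = 0; r < n; ++r) {
    const MatchRec& m = recs[r];
    start[r] = m.start; end[r] = m.end;
    for (int k = 0; k < nelem; ++k) {
      iv(r, 2 * k) = m.iv[2 * k];
      iv(r, 2 * k + 1) = m.iv[2 * k + 1];
      branch(r, k) = m.branch[k];
    }
    std::vector<std::pair<int, int>> mp;
    for (size_t z = 0; z < bref_elems.size(); ++z) {
      const BrefAln& a = m.alns[bref_elems[z]];
      stats[z](r, 0) = a.mism; stats[z](r, 1) = a.del; stats[z](r, 2) = a.ins;
      mp.insert(mp.end(), a.pairs.begin(), a.pairs.end());
    }
    std::sort(mp.begin(), mp.end());  // nested-structure evaluation wants i ascending
    for (auto& pr : mp) {
      flat(fr, 0) = r + 1; flat(fr, 1) = pr.first; flat(fr, 2) = pr.second;
      ++fr;
    }
  }
  for (size_t z = 0; z < bref_elems.size(); ++z) bref_stats[z] = stats[z];
  IntegerVector bref_at(bref_elems.size());
  for (size_t z = 0; z < bref_elems.size(); ++z) bref_at[z] = bref_elems[z] + 1;
  return List::create(
    _["n"] = n, _["start"] = start, _["end"] = end, _["intervals"] = iv,
    _["branch"] = branch, _["backref_elems"] = bref_at,
    _["backref_stats"] = bref_stats, _["pairs"] = flat
  );
}

// [[Rcpp::export(name = ".naive_match")]]
List naive_match(List elems, std::string seq) {
  std::vector<Elem> ev = decode_elems(elems);
  std::vector<int> sv = encode_seq(seq);
  NaiveCtx ctx;
  ctx.elems = &ev; ctx.seq = &sv;
  std::vector<int> lens(ev.size(), 0), branch(ev.size(), -1);
  for (int start = 0; start <= (int)sv.size(); ++start)
    naive_assign(ctx, start, 0, lens, branch);
  return pack_matches(ctx.out, ev.size());
}
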