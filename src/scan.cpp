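#include <Rcpp.h>
#include <map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Phased allele matrices are 0/1/NA_INTEGER with rows = chromosomes and
// columns = SNPs. A missing genotype matches either allele during carrier
// counting (optimistic matching).

static inline bool cellMatch(int v, int t) {
  return v == NA_INTEGER || v == t;
}

struct Window {
  int start;    // 0-based column
  int end;      // 0-based column, inclusive
  int carriers; // matching chromosomes, missing counted as matching
  int tmpl;     // row index of the template chromosome
};

// Collect, for one template chromosome over one NA-free run [a, b], the
// right-maximal windows with carrier count >= need (two-pointer sweep:
// L(j) = smallest i so that [i, j] still has >= need carriers; L is
// non-decreasing in j, so windows (L(j), j) with L(j+1) > L(j) are exactly
// the windows that cannot be extended with this template's alleles).
static void paretoWindows(const IntegerMatrix &H, const std::vector<int> &tv,
                          int lo, int a, int b, int tmplRow, int need,
                          std::vector<Window> &out) {
  const int n = H.nrow();
  std::vector<int> mism(n, 0);
  int cnt = n, i = a;
  std::vector<int> L(b - a + 1, -1), C(b - a + 1, 0);
  for (int j = a; j <= b; ++j) {
    const int tj = tv[j - lo];
    for (int h = 0; h < n; ++h) {
      if (!cellMatch(H(h, j), tj)) {
        if (mism[h]++ == 0) --cnt;
      }
    }
    while (cnt < need && i <= j) {
      const int ti = tv[i - lo];
      for (int h = 0; h < n; ++h) {
        if (!cellMatch(H(h, i), ti)) {
          if (--mism[h] == 0) ++cnt;
        }
      }
      ++i;
    }
    if (i <= j) {
      L[j - a] = i;
      C[j - a] = cnt;
    }
  }
  for (int j = a; j <= b; ++j) {
    if (L[j - a] < 0) continue;
    bool corner = (j == b) || (L[j - a + 1] > L[j - a]) || (L[j - a + 1] < 0);
    if (corner) out.push_back({L[j - a], j, C[j - a], tmplRow});
  }
}

// Deduplicate rows over [lo, hi]; returns representative row indices.
static std::vector<int> uniqueTemplates(const IntegerMatrix &H, int lo, int hi) {
  std::map<std::vector<int>, int> seen;
  std::vector<int> reps;
  for (int h = 0; h < H.nrow(); ++h) {
    std::vector<int> key(hi - lo + 1);
    for (int c = lo; c <= hi; ++c) key[c - lo] = H(h, c);
    if (seen.insert({key, h}).second) reps.push_back(h);
  }
  return reps;
}

static bool stringsAgree(const IntegerMatrix &H, int rowA, int rowB,
                         int from, int to) {
  for (int c = from; c <= to; ++c)
    if (H(rowA, c) != H(rowB, c)) return false;
  return true;
}

// Enumerate every maximal allele-specified contiguous window within columns
// [lo, hi] whose carrier count is >= need. Maximal: not extendable in either
// direction and not a sub-window (with agreeing alleles) of another window.
// [[Rcpp::export]]
List cpp_scan_segment(IntegerMatrix H, int lo, int hi, int need) {
  std::vector<Window> cand;
  const std::vector<int> reps = uniqueTemplates(H, lo, hi);
  for (int t : reps) {
    std::vector<int> tv(hi - lo + 1);
    for (int c = lo; c <= hi; ++c) tv[c - lo] = H(t, c);
    int a = -1;
    for (int c = lo; c <= hi + 1; ++c) {
      const bool ok = (c <= hi) && tv[c - lo] != NA_INTEGER;
      if (ok && a < 0) a = c;
      if (!ok && a >= 0) {
        paretoWindows(H, tv, lo, a, c - 1, t, need, cand);
        a = -1;
      }
    }
  }
  // drop duplicates (same window, same allele string)
  std::map<std::pair<int, int>, std::vector<int>> byWin;
  for (size_t k = 0; k < cand.size(); ++k)
    byWin[{cand[k].start, cand[k].end}].push_back((int)k);
  std::vector<Window> uniq;
  for (auto &kv : byWin) {
    std::vector<int> keepIdx;
    for (int k : kv.second) {
      bool dup = false;
      for (int q : keepIdx) {
        if (stringsAgree(H, cand[k].tmpl, cand[q].tmpl, cand[k].start,
                         cand[k].end)) {
          dup = true;
          break;
        }
      }
      if (!dup) keepIdx.push_back(k);
    }
    for (int k : keepIdx) uniq.push_back(cand[k]);
  }
  // subset filter: drop any window contained (with agreeing alleles) in a
  // longer one
  std::vector<int> ord(uniq.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = (int)k;
  std::sort(ord.begin(), ord.end(), [&](int x, int y) {
    const int lx = uniq[x].end - uniq[x].start, ly = uniq[y].end - uniq[y].start;
    if (lx != ly) return lx > ly;
    if (uniq[x].start != uniq[y].start) return uniq[x].start < uniq[y].start;
    return x < y;
  });
  std::vector<int> kept;
  std::vector<bool> keep(uniq.size(), false);
  for (int k : ord) {
    bool contained = false;
    for (int q : kept) {
      if (uniq[q].start <= uniq[k].start && uniq[q].end >= uniq[k].end &&
          !(uniq[q].start == uniq[k].start && uniq[q].end == uniq[k].end) &&
          stringsAgree(H, uniq[q].tmpl, uniq[k].tmpl, uniq[k].start,
                       uniq[k].end)) {
        contained = true;
        break;
      }
    }
    if (!contained) {
      keep[k] = true;
      kept.push_back(k);
    }
  }
  int m = 0;
  for (size_t k = 0; k < uniq.size(); ++k)
    if (keep[k]) ++m;
  IntegerVector starts(m), ends(m), carriers(m);
  List alleles(m);
  int w = 0;
  for (size_t k = 0; k < uniq.size(); ++k) {
    if (!keep[k]) continue;
    starts[w] = uniq[k].start;
    ends[w] = uniq[k].end;
    carriers[w] = uniq[k].carriers;
    IntegerVector al(uniq[k].end - uniq[k].start + 1);
    for (int c = uniq[k].start; c <= uniq[k].end; ++c)
      al[c - uniq[k].start] = H(uniq[k].tmpl, c);
    alleles[w] = al;
    ++w;
  }
  return List::create(_["start"] = starts, _["end"] = ends,
                      _["carriers"] = carriers, _["alleles"] = alleles);
}

// Longest maximal window containing the site (seed, allele); exact search
// over template chromosomes carrying that allele. Ties: SNP count, then
// genetic length (cm), then leftmost start.
// [[Rcpp::export]]
List cpp_grow_exact(IntegerMatrix H, int lo, int hi, int seed, int allele,
                    int need, NumericVector cm) {
  const int n = H.nrow();
  std::map<std::vector<int>, bool> seen;
  bool found = false;
  Window best{0, -1, 0, 0};
  double bestCm = -1.0;
  for (int t = 0; t < n; ++t) {
    if (H(t, seed) != allele) continue;
    std::vector<int> key(hi - lo + 1);
    for (int c = lo; c <= hi; ++c) key[c - lo] = H(t, c);
    if (!seen.insert({key, true}).second) continue;
    // NA-free run of this template containing the seed
    int a = seed, b = seed;
    while (a - 1 >= lo && H(t, a - 1) != NA_INTEGER) --a;
    while (b + 1 <= hi && H(t, b + 1) != NA_INTEGER) ++b;
    std::vector<int> tv(hi - lo + 1);
    for (int c = lo; c <= hi; ++c) tv[c - lo] = H(t, c);
    std::vector<Window> wins;
    paretoWindows(H, tv, lo, a, b, t, need, wins);
    for (const Window &w : wins) {
      if (w.start > seed || w.end < seed) continue;
      const int len = w.end - w.start + 1;
      const double clen = cm[w.end] - cm[w.start];
      const int blen = best.end - best.start + 1;
      bool better = false;
      if (!found || len > blen)
        better = true;
      else if (len == blen && clen > bestCm)
        better = true;
      else if (len == blen && clen == bestCm && w.start < best.start)
        better = true;
      else if (len == blen && clen == bestCm && w.start == best.start) {
        // same window, different allele string: smallest string wins
        for (int c = w.start; c <= w.end; ++c) {
          const int va = H(w.tmpl, c), vb = H(best.tmpl, c);
          if (va != vb) {
            better = va < vb;
            break;
          }
        }
      }
      if (better) {
        best = w;
        bestCm = clen;
        found = true;
      }
    }
  }
  if (!found) return List::create();
  IntegerVector al(best.end - best.start + 1);
  for (int c = best.start; c <= best.end; ++c)
    al[c - best.start] = H(best.tmpl, c);
  return List::create(_["start"] = best.start, _["end"] = best.end,
                      _["carriers"] = best.carriers, _["alleles"] = al);
}

// Greedy bidirectional growth with a per-side skip allowance. At each step
// the adjacent SNP is tentatively appended with the allele that keeps the
// most carriers; acceptance requires the joint carrier count to stay >=
// need, otherwise the SNP may be skipped (up to `skip` per side).
// [[Rcpp::export]]
List cpp_grow_greedy(IntegerMatrix H, int lo, int hi, int seed, int allele,
                     int need, int skip) {
  const int n = H.nrow();
  std::vector<char> carrier(n);
  int cnt = 0;
  for (int h = 0; h < n; ++h) {
    carrier[h] = cellMatch(H(h, seed), allele);
    if (carrier[h]) ++cnt;
  }
  std::vector<int> sites{seed}, alleles{allele};
  int lnext = seed - 1, rnext = seed + 1, lskip = 0, rskip = 0;
  bool lopen = lnext >= lo, ropen = rnext <= hi;
  auto step = [&](int &j, int dir, int &skipsUsed, bool &open) {
    int c0 = 0, c1 = 0;
    for (int h = 0; h < n; ++h) {
      if (!carrier[h]) continue;
      const int v = H(h, j);
      if (cellMatch(v, 0)) ++c0;
      if (cellMatch(v, 1)) ++c1;
    }
    const int a = (c1 > c0) ? 1 : 0;
    const int c = (c1 > c0) ? c1 : c0;
    if (c >= need) {
      for (int h = 0; h < n; ++h)
        if (carrier[h] && !cellMatch(H(h, j), a)) carrier[h] = 0;
      cnt = c;
      sites.push_back(j);
      alleles.push_back(a);
      j += dir;
    } else if (skipsUsed < skip) {
      ++skipsUsed;
      j += dir;
    } else {
      open = false;
      return;
    }
    if (j < lo || j > hi) open = false;
  };
  while (lopen || ropen) {
    if (lopen) step(lnext, -1, lskip, lopen);
    if (ropen) step(rnext, +1, rskip, ropen);
  }
  std::vector<int> ord(sites.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = (int)k;
  std::sort(ord.begin(), ord.end(),
            [&](int x, int y) { return sites[x] < sites[y]; });
  IntegerVector s(sites.size()), al(sites.size());
  for (size_t k = 0; k < ord.size(); ++k) {
    s[k] = sites[ord[k]];
    al[k] = alleles[ord[k]];
  }
  return List::create(_["sites"] = s, _["alleles"] = al, _["carriers"] = cnt);
}
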