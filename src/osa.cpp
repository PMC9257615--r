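#include <Rcpp.h>
using namespace Rcpp;

// Optimal string alignment (restricted Damerau-Levenshtein) distance:
// unit-cost substitutions, insertions, deletions and transpositions of
// adjacent characters. Computed with a per-pair cutoff; returns maxd + 1
// as soon as the distance provably exceeds maxd (early abandoning), so
// callers can treat values > maxd as "no match".
// [[Rcpp::export]]
IntegerVector osa_distance_cpp(CharacterVector a, CharacterVector b,
                               IntegerVector maxd) {
  R_xlen_t n = a.size();
  IntegerVector out(n);
  std::vector<int> prev2, prev, cur;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(a[i]);
    std::string t = as<std::string>(b[i]);
    int cap = maxd[i];
    if (cap < 0) cap = 0;
    int ls = (int)s.size(), lt = (int)t.size();
    if (std::abs(ls - lt) > cap) { out[i] = cap + 1; continue; }
    prev.resize(lt + 1);
    for (int j = 0; j <= lt; ++j) prev[j] = j;
    prev2.assign(lt + 1, 0);
    cur.assign(lt + 1, 0);
    bool bailed = false;
    for (int r = 1; r <= ls; ++r) {
      cur[0] = r;
      int rowmin = cur[0];
      for (int c = 1; c <= lt; ++c) {
        int cost = (s[r - 1] == t[c - 1]) ? 0 : 1;
        int v = std::min(std::min(prev[c] + 1, cur[c - 1] + 1),
                         prev[c - 1] + cost);
        if (r > 1 && c > 1 && s[r - 1] == t[c - 2] && s[r - 2] == t[c - 1])
          v = std::min(v, prev2[c - 2] + 1);
        cur[c] = v;
        if (v < rowmin) rowmin = v;
      }
      if (rowmin > cap) { bailed = true; break; }
      // rotate: prev2 <- prev, prev <- cur, cur <- scratch
      std::swap(prev2, prev);
      std::swap(prev, cur);
    }
    out[i] = bailed ? cap + 1 : std::min(prev[lt], cap + 1);
  }
  return out;
}
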