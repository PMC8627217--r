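#include <Rcpp.h>
#include <vector>
#include <array>
#include <string>

// Matching statistics via a suffix automaton built over the (reversed) target
// text. For each start position i of the query, the profile holds the length
// of the longest substring query[i..] occurring anywhere in the text. The
// alphabet is {A,C,G,T,N,other}; 'N' and any other byte are literal letters,
// so a separator byte absent from queries cannot be matched across.

namespace {

const int ALPHA = 6;

inline int base_idx(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  case 'N': case 'n': return 4;
  default: return 5;
  }
}

struct SuffixAutomaton {
  std::vector<std::array<int, ALPHA> > nxt;
  std::vector<int> link, len;
  int last;

  explicit SuffixAutomaton(size_t cap) {
    nxt.reserve(2 * cap + 4);
    link.reserve(2 * cap + 4);
    len.reserve(2 * cap + 4);
    std::array<int, ALPHA> none;
    none.fill(-1);
    nxt.push_back(none);
    link.push_back(-1);
    len.push_back(0);
    last = 0;
  }

  void extend(int c) {
    std::array<int, ALPHA> none;
    none.fill(-1);
    int cur = (int)nxt.size();
    nxt.push_back(none);
    link.push_back(-1);
    len.push_back(len[last] + 1);
    int p = last;
    while (p != -1 && nxt[p][c] == -1) {
      nxt[p][c] = cur;
      p = link[p];
    }
    if (p == -1) {
      link[cur] = 0;
    } else {
      int q = nxt[p][c];
      if (len[p] + 1 == len[q]) {
        link[cur] = q;
      } else {
        int clone = (int)nxt.size();
        nxt.push_back(nxt[q]);
        link.push_back(link[q]);
        len.push_back(len[p] + 1);
        while (p != -1 && nxt[p][c] == q) {
          nxt[p][c] = clone;
          p = link[p];
        }
        link[q] = clone;
        link[cur] = clone;
      }
    }
    last = cur;
  }
};

} // namespace

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_match_profile(std::string query, std::string text) {
  size_t n = query.size(), m = text.size();
  Rcpp::IntegerVector profile(n);
  if (n == 0 || m == 0) return profile;

  // automaton over reversed text; stream reversed query: the longest suffix
  // of the reversed prefix is the longest forward match starting at n-1-j
  SuffixAutomaton sam(m);
  for (size_t j = m; j > 0; --j) sam.extend(base_idx(text[j - 1]));

  int v = 0, l = 0;
  for (size_t j = n; j > 0; --j) {
    int c = base_idx(query[j - 1]);
    while (v != 0 && sam.nxt[v][c] == -1) {
      v = sam.link[v];
      l = sam.len[v];
    }
    if (sam.nxt[v][c] != -1) {
      v = sam.nxt[v][c];
      ++l;
    } else {
      v = 0;
      l = 0;
    }
    profile[j - 1] = l;
  }
  return profile;
}
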