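#include <Rcpp.h>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

// Suffix automaton over the concatenated target text (every contig and its
// reverse complement, each terminated by a non-nucleotide separator byte).
// States are linear in the text length; transitions use std::map because the
// effective alphabet (A,C,G,T,N + separators) is tiny.
namespace {

struct SuffixAutomaton {
  std::vector<int> link;
  std::vector<int> len;
  std::vector<std::map<unsigned char, int> > nxt;
  int last;

  SuffixAutomaton() : last(0) {
    link.push_back(-1);
    len.push_back(0);
    nxt.push_back(std::map<unsigned char, int>());
  }

  void reserve(size_t n) {
    link.reserve(2 * n + 4);
    len.reserve(2 * n + 4);
    nxt.reserve(2 * n + 4);
  }

  int new_state(int l) {
    link.push_back(-1);
    len.push_back(l);
    nxt.push_back(std::map<unsigned char, int>());
    return static_cast<int>(len.size()) - 1;
  }

  void extend(unsigned char c) {
    int cur = new_state(len[last] + 1);
    int p = last;
    while (p != -1 && nxt[p].find(c) == nxt[p].end()) {
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
        int clone = new_state(len[p] + 1);
        nxt[clone] = nxt[q];
        link[clone] = link[q];
        while (p != -1) {
          std::map<unsigned char, int>::iterator it = nxt[p].find(c);
          if (it == nxt[p].end() || it->second != q) break;
          it->second = clone;
          p = link[p];
        }
        link[q] = clone;
        link[cur] = clone;
      }
    }
    last = cur;
  }
};

// Separator bytes never collide with uppercase nucleotides, so a match can
// never include one; boundaries between contigs/strands are therefore
// unbridgeable even when separator byte values recycle.
inline unsigned char separator_byte(size_t i) {
  static const std::string pool =
      "!\"#$%&'()*+,-./0123456789:;<=>?@[\\]^_`{|}~";
  return static_cast<unsigned char>(pool[i % pool.size()]);
}

}  // namespace

//' @useDynLib panmem, .registration = TRUE
// [[Rcpp::export(name = ".ms_stream_cpp")]]
IntegerVector ms_stream_cpp(std::string pivot, std::vector<std::string> targets) {
  if (pivot.empty()) stop("pivot sequence is empty");
  size_t total = 0;
  for (size_t i = 0; i < targets.size(); ++i) total += targets[i].size() + 1;
  if (total <= targets.size()) stop("target text is empty");

  SuffixAutomaton sam;
  sam.reserve(total);
  for (size_t i = 0; i < targets.size(); ++i) {
    const std::string& s = targets[i];
    for (size_t j = 0; j < s.size(); ++j) {
      sam.extend(static_cast<unsigned char>(s[j]));
    }
    sam.extend(separator_byte(i));
  }

  const size_t m = pivot.size();
  IntegerVector ms(m);
  int v = 0;
  int l = 0;
  for (size_t j = 0; j < m; ++j) {
    unsigned char c = static_cast<unsigned char>(pivot[j]);
    while (v != 0 && sam.nxt[v].find(c) == sam.nxt[v].end()) {
      v = sam.link[v];
      l = sam.len[v];
    }
    std::map<unsigned char, int>::iterator it = sam.nxt[v].find(c);
    if (it != sam.nxt[v].end()) {
      v = it->second;
      ++l;
    } else {
      v = 0;
      l = 0;
    }
    ms[j] = l;
  }
  return ms;
}
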