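#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Watson-Crick (A-U, G-C) plus G-U wobble
static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'U';
  case 'U': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'U';
  case 'C': return b == 'G';
  default:  return false;
  }
}

static inline int encode(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'U': return 3;
  default:  return -1;
  }
}

// pair table over encoded bases (A,C,G,U): AU, GC, GU and reverses
static const bool PAIR_TAB[4][4] = {
  // A      C      G      U
  {false, false, false, true },  // A
  {false, false, true,  false}, // C
  {false, true,  false, true },  // G
  {true,  false, true,  false}  // U
};

// Fill Nussinov DP for encoded sequence; M is row-major (M[i][j], i<=j),
// MT its transpose kept in step so column reads of M become row reads.
// M[i][j] = max pairs in s[i..j]; pair (i,k) requires k - i > min_loop.
static void fill_dp(const std::vector<int>& code, int min_loop,
                    std::vector<short>& M, std::vector<short>& MT) {
  const int n = (int) code.size();
  std::fill(M.begin(), M.end(), 0);
  std::fill(MT.begin(), MT.end(), 0);
  for (int j = min_loop + 1; j < n; ++j) {
    const short* colj = &MT[(size_t) j * n]; // colj[i] = M[i][j]
    for (int i = j - min_loop - 1; i >= 0; --i) {
      const short* rowi1 = &M[(size_t) (i + 1) * n]; // M[i+1][.]
      const bool* pr = PAIR_TAB[code[i]];
      short best = rowi1[j]; // i unpaired
      // peel k == j (no right segment)
      if (pr[code[j]]) {
        short v = (short) (1 + rowi1[j - 1]);
        if (v > best) best = v;
      }
      for (int k = i + min_loop + 1; k < j; ++k) {
        if (!pr[code[k]]) continue;
        // 1 + M[i+1][k-1] + M[k+1][j]; colj[k+1] = M[k+1][j]
        short v = (short) (1 + rowi1[k - 1] + colj[k + 1]);
        if (v > best) best = v;
      }
      M[(size_t) i * n + j] = best;
      MT[(size_t) j * n + i] = best;
    }
  }
}

// Deterministic traceback: prefer pairing the smallest i, and among optimal
// partners of i choose the largest k.
static void traceback(const std::vector<int>& code, int min_loop,
                      const std::vector<short>& M, std::string& db) {
  const int n = (int) code.size();
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || M[(size_t) i * n + j] == 0) continue;
    const short target = M[(size_t) i * n + j];
    int chosen = -1;
    for (int k = j; k >= i + min_loop + 1; --k) { // largest k first
      if (!PAIR_TAB[code[i]][code[k]]) continue;
      short v = 1;
      if (k - 1 >= i + 1) v = (short) (v + M[(size_t) (i + 1) * n + (k - 1)]);
      if (k + 1 <= j)     v = (short) (v + M[(size_t) (k + 1) * n + j]);
      if (v == target) { chosen = k; break; }
    }
    if (chosen >= 0) {
      db[i] = '(';
      db[chosen] = ')';
      if (chosen + 1 <= j) stack.push_back(std::make_pair(chosen + 1, j));
      if (i + 1 <= chosen - 1) stack.push_back(std::make_pair(i + 1, chosen - 1));
    } else {
      stack.push_back(std::make_pair(i + 1, j));
    }
  }
}

static std::vector<int> encode_seq(const std::string& s) {
  std::vector<int> code(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = encode(s[i]);
    if (c < 0) stop("invalid RNA character '%c'", s[i]);
    code[i] = c;
  }
  return code;
}

// [[Rcpp::export]]
List nussinov_fold_cpp(std::string seq, int min_loop) {
  const int n = (int) seq.size();
  if (n == 0) stop("empty sequence");
  std::vector<int> code = encode_seq(seq);
  std::vector<short> M((size_t) n * n, 0), MT((size_t) n * n, 0);
  fill_dp(code, min_loop, M, MT);
  std::string db(n, '.');
  traceback(code, min_loop, M, db);
  return List::create(_["pair_score"] = (int) M[n - 1],
                      _["structure"] = db);
}

// Scores only (no traceback); used for permutation nulls.
// [[Rcpp::export]]
IntegerVector nussinov_score_batch_cpp(CharacterVector seqs, int min_loop) {
  const int m = seqs.size();
  IntegerVector out(m);
  std::vector<short> M, MT;
  for (int q = 0; q < m; ++q) {
    std::string s = as<std::string>(seqs[q]);
    const int n = (int) s.size();
    if (n == 0) { out[q] = 0; continue; }
    std::vector<int> code = encode_seq(s);
    M.assign((size_t) n * n, 0);
    MT.assign((size_t) n * n, 0);
    fill_dp(code, min_loop, M, MT);
    out[q] = (int) M[n - 1];
  }
  return out;
}

// 0-based start positions i with s[i]==s[i+1]==s[i+2] and s[i+3]==s[i+4]==s[i+5]
// (slippery heptamer X XXY YYZ; N7 unconstrained).
// [[Rcpp::export]]
IntegerVector find_slippery_starts_cpp(std::string seq) {
  const int n = (int) seq.size();
  std::vector<int> hits;
  for (int i = 0; i + 7 <= n; ++i) {
    if (seq[i] == seq[i + 1] && seq[i] == seq[i + 2] &&
        seq[i + 3] == seq[i + 4] && seq[i + 3] == seq[i + 5])
      hits.push_back(i);
  }
  return wrap(hits);
}
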