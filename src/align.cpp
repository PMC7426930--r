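#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <string>
using namespace Rcpp;

// Pairwise alignment and p-distance kernels.
//
// align_overlap_cpp: affine-gap (Gotoh) semi-global alignment with free end
// gaps in both sequences, suited to mapping a locus fragment onto a longer
// reference (or vice versa). A gap run of length k costs
// gap_open + k * gap_ext; terminal gaps are free. IUPAC ambiguity characters
// (anything outside A/C/G/T) are scored 0 against any character.

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static const int NEG = -1000000000;

// traceback states
enum { ST_M = 0, ST_E = 1, ST_F = 2, ST_START = 3 };

// In overlap mode the aligned block must start at the beginning of one of
// the two sequences (classic free-end-gap semantics). In local mode the
// block may start and end anywhere in both sequences (Smith-Waterman
// ends), which is what read mapping needs: a vector-padded query mapping
// to an interior reference interval skips both prefixes.

// [[Rcpp::export]]
List align_overlap_cpp(std::string a, std::string b,
                       int match = 1, int mismatch = -1,
                       int gap_open = -4, int gap_ext = -1,
                       bool local = false) {
  const int n = (int)a.size();  // query rows
  const int m = (int)b.size();  // reference columns
  if (n == 0 || m == 0)
    stop("align_overlap_cpp: empty sequence");

  // rolling score rows; full byte traceback
  std::vector<int> prevH(m + 1), curH(m + 1);
  std::vector<int> prevF(m + 1), curF(m + 1);
  std::vector<int> curE(m + 1);
  // tbH: state achieving H at (i,j); tbE/tbF: 0 = opened, 1 = extended
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), ST_START);
  std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);
  // fresh-start marker for M cells (local mode only)
  std::vector<unsigned char> tbS(local ? (size_t)(n + 1) * (m + 1) : 1, 0);
  const size_t W = (size_t)m + 1;
  std::vector<int> colM(n + 1, 0);  // H values of the last column

  for (int j = 0; j <= m; ++j) { prevH[j] = 0; prevF[j] = NEG; }

  int bestAll = 0, bai = 0, baj = 0;  // local-mode optimum
  const int go = gap_open + gap_ext;  // cost of first gap character

  for (int i = 1; i <= n; ++i) {
    curH[0] = 0; curE[0] = NEG; curF[0] = NEG;
    const char ai = a[i - 1];
    const bool ai_base = is_base(ai);
    for (int j = 1; j <= m; ++j) {
      const char bj = b[j - 1];
      int s;
      if (!ai_base || !is_base(bj)) s = 0;
      else s = (ai == bj) ? match : mismatch;

      int M;
      if (local && prevH[j - 1] < 0) {
        M = s;
        tbS[(size_t)i * W + j] = 1;
      } else {
        M = prevH[j - 1] + s;
      }

      int e_open = curH[j - 1] + go;
      int e_ext  = (curE[j - 1] == NEG) ? NEG : curE[j - 1] + gap_ext;
      int E; unsigned char te;
      if (e_ext > e_open) { E = e_ext; te = 1; } else { E = e_open; te = 0; }

      int f_open = prevH[j] + go;
      int f_ext  = (prevF[j] == NEG) ? NEG : prevF[j] + gap_ext;
      int F; unsigned char tf;
      if (f_ext > f_open) { F = f_ext; tf = 1; } else { F = f_open; tf = 0; }

      int H = M; unsigned char th = ST_M;
      if (E > H) { H = E; th = ST_E; }
      if (F > H) { H = F; th = ST_F; }

      curH[j] = H; curE[j] = E; curF[j] = F;
      tbH[(size_t)i * W + j] = th;
      tbE[(size_t)i * W + j] = te;
      tbF[(size_t)i * W + j] = tf;
      if (local && H > bestAll) { bestAll = H; bai = i; baj = j; }
    }
    colM[i] = curH[m];
    if (i < n) { std::swap(prevH, curH); std::swap(prevF, curF); }
  }

  // best end cell: scan row n (query exhausted, trailing reference free),
  // then column m (reference exhausted); ties keep the first encountered.
  int best, bi, bj;
  if (local) {
    best = bestAll; bi = bai; bj = baj;
  } else {
    best = NEG; bi = n; bj = 0;
    for (int j = 0; j <= m; ++j)
      if (curH[j] > best) { best = curH[j]; bi = n; bj = j; }
    for (int i = 0; i <= n; ++i)
      if (colM[i] > best) { best = colM[i]; bi = i; bj = m; }
  }

  // The traceback matrices were only filled during the first pass, which
  // kept all rows of tbH/tbE/tbF (byte matrices) — those are complete.
  int i = bi, j = bj;
  std::string aln_a, aln_b;
  aln_a.reserve(n + m); aln_b.reserve(n + m);
  unsigned char state = (i == 0 || j == 0) ? ST_START : tbH[(size_t)i * W + j];
  while (state != ST_START) {
    if (state == ST_M) {
      aln_a.push_back(a[i - 1]); aln_b.push_back(b[j - 1]);
      bool started = local && tbS[(size_t)i * W + j];
      --i; --j;
      state = (started || i == 0 || j == 0) ? ST_START
                                            : tbH[(size_t)i * W + j];
    } else if (state == ST_E) {
      unsigned char te = tbE[(size_t)i * W + j];
      aln_a.push_back('-'); aln_b.push_back(b[j - 1]);
      --j;
      if (te == 0) state = (i == 0 || j == 0) ? ST_START : tbH[(size_t)i * W + j];
    } else { // ST_F
      unsigned char tf = tbF[(size_t)i * W + j];
      aln_a.push_back(a[i - 1]); aln_b.push_back('-');
      --i;
      if (tf == 0) state = (i == 0 || j == 0) ? ST_START : tbH[(size_t)i * W + j];
    }
  }
  std::reverse(aln_a.begin(), aln_a.end());
  std::reverse(aln_b.begin(), aln_b.end());

  const int q_start = i, ref_start = j;      // 0-based starts
  const int q_end = bi, ref_end = bj;        // half-open ends

  // projection of the query onto reference coordinates, and identity over
  // comparable (both A/C/G/T) aligned sites
  std::string ref_aligned;
  ref_aligned.reserve(ref_end - ref_start);
  int n_ident = 0, n_comp = 0;
  for (size_t k = 0; k < aln_a.size(); ++k) {
    char ca = aln_a[k], cb = aln_b[k];
    if (cb != '-') ref_aligned.push_back(ca);
    if (ca != '-' && cb != '-' && is_base(ca) && is_base(cb)) {
      ++n_comp;
      if (ca == cb) ++n_ident;
    }
  }

  return List::create(
    _["score"] = best,
    _["q_start"] = q_start, _["q_end"] = q_end,
    _["ref_start"] = ref_start, _["ref_end"] = ref_end,
    _["aln_query"] = aln_a, _["aln_ref"] = aln_b,
    _["ref_aligned"] = ref_aligned,
    _["n_ident"] = n_ident, _["n_comp"] = n_comp);
}

// uncorrected p-distance with pairwise deletion: sites where both characters
// are A/C/G/T are comparable; everything else (gaps, N, ambiguity codes) is
// excluded from the pair.

// [[Rcpp::export]]
IntegerVector pdist_pair_cpp(std::string a, std::string b) {
  if (a.size() != b.size())
    stop("pdist_pair_cpp: sequences must have equal length (same alignment)");
  int mism = 0, comp = 0;
  for (size_t k = 0; k < a.size(); ++k) {
    char ca = a[k], cb = b[k];
    if (is_base(ca) && is_base(cb)) {
      ++comp;
      if (ca != cb) ++mism;
    }
  }
  return IntegerVector::create(mism, comp);
}

// all-pairs mismatch and comparable-site counts over equal-length rows

// [[Rcpp::export]]
List pdist_all_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  size_t len = 0;
  for (int i = 0; i < n; ++i) {
    s[i] = as<std::string>(seqs[i]);
    if (i == 0) len = s[i].size();
    else if (s[i].size() != len)
      stop("pdist_all_cpp: rows must have equal length");
  }
  IntegerMatrix mism(n, n), comp(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int mm = 0, cc = 0;
      const char* p = s[i].data();
      const char* q = s[j].data();
      for (size_t k = 0; k < len; ++k) {
        if (is_base(p[k]) && is_base(q[k])) {
          ++cc;
          if (p[k] != q[k]) ++mm;
        }
      }
      mism(i, j) = mm; mism(j, i) = mm;
      comp(i, j) = cc; comp(j, i) = cc;
    }
  }
  return List::create(_["mismatches"] = mism, _["comparable"] = comp);
}
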