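#include <Rcpp.h>
using namespace Rcpp;

// Simplified RNA secondary-structure model: additive per-pair energies
// (GC -3, AU -2, GU -1 kcal/mol), nested structures only, hairpin loops
// of at least `minloop` unpaired nucleotides. Minimisation by a
// Nussinov-style O(n^3) dynamic program with a deterministic traceback.

static inline double pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return 1.0; // disallowed (positive sentinel, never chosen)
}

// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(std::string seq, int minloop) {
  int n = seq.size();
  // E[i][j]: minimal energy of subsequence [i, j], 0-based inclusive.
  std::vector<std::vector<double> > E(n, std::vector<double>(n, 0.0));
  for (int len = minloop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = E[i + 1][j]; // i unpaired
      for (int k = i + minloop + 1; k <= j; ++k) {
        double e = pair_energy(seq[i], seq[k]);
        if (e > 0) continue;
        double cand = e + E[i + 1][k - 1] + (k + 1 <= j ? E[k + 1][j] : 0.0);
        if (cand < best) best = cand;
      }
      E[i][j] = best;
    }
  }

  // Traceback: prefer pairing i, with the smallest partner, on ties.
  IntegerVector partner(n, NA_INTEGER);
  std::vector<std::pair<int, int> > stack;
  if (n > 0) stack.push_back(std::make_pair(0, n - 1));
  const double eps = 1e-9;
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < minloop + 1) continue;
    bool paired = false;
    for (int k = i + minloop + 1; k <= j; ++k) {
      double e = pair_energy(seq[i], seq[k]);
      if (e > 0) continue;
      double cand = e + E[i + 1][k - 1] + (k + 1 <= j ? E[k + 1][j] : 0.0);
      if (cand <= E[i][j] + eps) {
        partner[i] = k + 1; // 1-based for R
        partner[k] = i + 1;
        if (k - 1 > i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k + 1 < j) stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }

  std::string db(n, '.');
  for (int i = 0; i < n; ++i) {
    if (partner[i] != NA_INTEGER) db[i] = (partner[i] - 1 > i) ? '(' : ')';
  }
  return List::create(_["energy"] = n > 0 ? E[0][n - 1] : 0.0,
                      _["dotbracket"] = db,
                      _["pair_table"] = partner);
}

static inline bool complementary(char m, char t, bool allow_gu) {
  // m, t both RNA-normalised (T -> U) uppercase
  if ((m == 'A' && t == 'U') || (m == 'U' && t == 'A') ||
      (m == 'G' && t == 'C') || (m == 'C' && t == 'G')) return true;
  if (allow_gu && ((m == 'G' && t == 'U') || (m == 'U' && t == 'G'))) return true;
  return false;
}

// Best antisense complementarity of `tag` anywhere in `window`: for each
// alignment, count positions where tag base pairs (WC or G:U) the window
// base it would face in an antiparallel duplex. Used as a cheap prescan
// for duplex evidence before the O(n^3) fold.
// [[Rcpp::export(name = ".best_duplex_match")]]
IntegerVector best_duplex_match(std::string tag, std::string window,
                                int exclude_start, int exclude_end) {
  int L = tag.size(), n = window.size();
  int best = -1, best_pos = -1;
  for (int s = 0; s + L <= n; ++s) {
    if (s + L - 1 >= exclude_start && s <= exclude_end) continue;
    int cnt = 0;
    for (int i = 0; i < L; ++i) {
      // tag position i (0-based from 5') faces window position s + L - 1 - i
      if (complementary(tag[i], window[s + L - 1 - i], true)) ++cnt;
    }
    if (cnt > best) { best = cnt; best_pos = s; }
  }
  return IntegerVector::create(best, best_pos + 1);
}

// Plant miRNA target scoring: antiparallel ungapped alignment of the miRNA
// against every transcript window; per position match 0, G:U 0.5,
// mismatch 1.0; penalties at miRNA positions 2-13 (1-based from the 5'
// end) doubled. Returns all windows with score <= threshold.
// [[Rcpp::export(name = ".scan_target_sites")]]
DataFrame scan_target_sites(std::string mirna, std::string transcript,
                            double threshold) {
  int L = mirna.size(), n = transcript.size();
  std::vector<int> pos;
  std::vector<double> score;
  for (int s = 0; s + L <= n; ++s) {
    double sc = 0.0;
    for (int i = 0; i < L && sc <= threshold; ++i) {
      char m = mirna[i];
      char t = transcript[s + L - 1 - i];
      double pen;
      if (complementary(m, t, false)) pen = 0.0;
      else if (complementary(m, t, true)) pen = 0.5;
      else pen = 1.0;
      if (i + 1 >= 2 && i + 1 <= 13) pen *= 2.0;
      sc += pen;
    }
    if (sc <= threshold) { pos.push_back(s + 1); score.push_back(sc); }
  }
  return DataFrame::create(_["start"] = pos, _["score"] = score);
}
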