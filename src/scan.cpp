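#include <Rcpp.h>
using namespace Rcpp;

// PWM scan over a set of equal-length sequences, both strands.
//
// `score` is a 4 x m log-odds matrix with rows A, C, G, T. N (or any
// unrecognised base) contributes 0 at its position. For each sequence the
// maximal-scoring (start, strand) pairs are collected; ties within `tie_eps`
// of the maximum are all kept so the caller can weight them. The reported
// single best site breaks ties by smallest |offset| from the central (TSS)
// position, then '+' strand, then leftmost start.
//
// Offsets are motif centres in bp relative to the sequence centre:
// offset = start + (m - 1)/2 - (L - 1)/2 (half-integer for even m).
// [[Rcpp::export]]
List scan_pwm_cpp(CharacterVector seqs, NumericMatrix score,
                  double tie_eps = 1e-9) {
  const int n = seqs.size();
  const int m = score.ncol();
  NumericVector best_offset(n), best_score(n);
  CharacterVector best_strand(n);
  List tie_offsets(n);
  IntegerVector n_ties(n);

  for (int s = 0; s < n; ++s) {
    const char *str = CHAR(STRING_ELT(seqs, s));
    const int L = LENGTH(STRING_ELT(seqs, s));
    if (L < m) stop("sequence shorter than motif");
    std::vector<int> code(L);
    bool all_n = true;
    for (int i = 0; i < L; ++i) {
      switch (str[i]) {
        case 'A': case 'a': code[i] = 0; all_n = false; break;
        case 'C': case 'c': code[i] = 1; all_n = false; break;
        case 'G': case 'g': code[i] = 2; all_n = false; break;
        case 'T': case 't': code[i] = 3; all_n = false; break;
        default: code[i] = -1;
      }
    }
    if (all_n) {
      best_offset[s] = NA_REAL;
      best_strand[s] = NA_STRING;
      best_score[s] = R_NegInf;
      tie_offsets[s] = NumericVector(0);
      n_ties[s] = 0;
      continue;
    }
    const double centre = (L - 1) / 2.0;
    const double half_m = (m - 1) / 2.0;
    double max_sc = R_NegInf;
    std::vector<int> tie_start;
    std::vector<int> tie_fwd;  // 1 = '+', 0 = '-'
    for (int start = 0; start <= L - m; ++start) {
      double fs = 0.0, rs = 0.0;
      for (int i = 0; i < m; ++i) {
        const int b = code[start + i];
        if (b >= 0) {
          fs += score(b, i);
          // reverse strand: complement base, reversed position
          rs += score(3 - b, m - 1 - i);
        }
      }
      for (int strand = 0; strand < 2; ++strand) {
        const double sc = strand == 0 ? fs : rs;
        if (sc > max_sc + tie_eps) {
          max_sc = sc;
          tie_start.clear();
          tie_fwd.clear();
          tie_start.push_back(start);
          tie_fwd.push_back(strand == 0 ? 1 : 0);
        } else if (sc >= max_sc - tie_eps) {
          tie_start.push_back(start);
          tie_fwd.push_back(strand == 0 ? 1 : 0);
        }
      }
    }
    // pick the reported site: min |offset|, then '+', then leftmost
    int pick = 0;
    double pick_abs = R_PosInf;
    NumericVector offs(tie_start.size());
    for (size_t j = 0; j < tie_start.size(); ++j) {
      const double off = tie_start[j] + half_m - centre;
      offs[j] = off;
      const double a = std::fabs(off);
      const bool better =
        (a < pick_abs - 1e-12) ||
        (std::fabs(a - pick_abs) <= 1e-12 &&
         (tie_fwd[j] > tie_fwd[pick] ||
          (tie_fwd[j] == tie_fwd[pick] && tie_start[j] < tie_start[pick])));
      if (j == 0 || better) {
        pick = (int)j;
        pick_abs = a;
      }
    }
    best_offset[s] = offs[pick];
    best_strand[s] = tie_fwd[pick] ? "+" : "-";
    best_score[s] = max_sc;
    tie_offsets[s] = offs;
    n_ties[s] = (int)tie_start.size();
  }
  return List::create(_["offset"] = best_offset,
                      _["strand"] = best_strand,
                      _["score"] = best_score,
                      _["tie_offsets"] = tie_offsets,
                      _["n_ties"] = n_ties);
}
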