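#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Needleman-Wunsch global alignment of bisulfite-converted reads against an
// in-silico converted reference. At CpG reference positions (where the
// reference keeps a C under the fully-methylated assumption) a read C or T
// both count as a match, so methylated and unmethylated epialleles align
// equally well. Linear gap penalty; traceback ties resolved deterministically
// (diagonal, then deletion, then insertion).

// [[Rcpp::export]]
List cpp_align_reads(CharacterVector reads, std::string ref,
                     IntegerVector cpg0, double match, double mismatch,
                     double gap) {
  const int L = (int) ref.size();
  std::vector<bool> iscpg(L, false);
  for (int k = 0; k < cpg0.size(); ++k) {
    int p = cpg0[k];
    if (p >= 0 && p < L) iscpg[p] = true;
  }
  const int n = reads.size();
  NumericVector scores(n);
  CharacterVector aligned(n);

  std::vector<double> prev, cur;
  for (int r = 0; r < n; ++r) {
    std::string read = as<std::string>(reads[r]);
    const int m = (int) read.size();
    // S has (L+1) x (m+1) cells; keep full matrix for traceback
    std::vector<double> S((size_t)(L + 1) * (m + 1));
    for (int j = 0; j <= m; ++j) S[j] = gap * j;
    for (int i = 1; i <= L; ++i) {
      double *row = &S[(size_t)i * (m + 1)];
      const double *up = &S[(size_t)(i - 1) * (m + 1)];
      row[0] = gap * i;
      const char rc = ref[i - 1];
      const bool cpg = iscpg[i - 1];
      for (int j = 1; j <= m; ++j) {
        const char qc = read[j - 1];
        bool ok = (qc == rc) || (cpg && rc == 'C' && qc == 'T');
        double diag = up[j - 1] + (ok ? match : mismatch);
        double del = up[j] + gap;      // reference base unmatched
        double ins = row[j - 1] + gap; // read base unmatched
        double best = diag;
        if (del > best) best = del;
        if (ins > best) best = ins;
        row[j] = best;
      }
    }
    scores[r] = S[(size_t)L * (m + 1) + m];

    // traceback: per reference position, the read base aligned to it or '-'
    std::string out(L, '-');
    int i = L, j = m;
    while (i > 0 || j > 0) {
      const double here = S[(size_t)i * (m + 1) + j];
      if (i > 0 && j > 0) {
        const char rc = ref[i - 1];
        const char qc = read[j - 1];
        bool ok = (qc == rc) || (iscpg[i - 1] && rc == 'C' && qc == 'T');
        double sub = ok ? match : mismatch;
        if (here == S[(size_t)(i - 1) * (m + 1) + (j - 1)] + sub) {
          out[i - 1] = qc;
          --i; --j;
          continue;
        }
      }
      if (i > 0 && here == S[(size_t)(i - 1) * (m + 1) + j] + gap) {
        out[i - 1] = '-';
        --i;
        continue;
      }
      // insertion: read base consumed, no reference position
      --j;
    }
    aligned[r] = out;
  }
  return List::create(_["score"] = scores, _["aligned"] = aligned);
}
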