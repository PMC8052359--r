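#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty and
// deterministic traceback: on equal score prefer match/mismatch, then
// deletion (gap in the read, consuming reference), then insertion
// (extra read base).
//
// For each read we also emit:
//  * a CIGAR-style operation string over {M, I, D},
//  * ref_row: one character per reference position -- the aligned read base
//    at M columns, '-' at deletions (insertions are not representable in
//    reference coordinates and are reported via the CIGAR / indel flag),
//  * a flag for whether any inserted or deleted base falls inside the
//    1-based reference interval [ps_start, ps_end] (0,0 disables the test).
//    A deletion counts when the deleted reference position lies inside the
//    interval; an insertion counts when its anchor (the reference position
//    it follows) lies strictly inside, i.e. ps_start <= anchor < ps_end.

struct AlignResult {
  double score;
  std::string cigar;
  std::string ref_row;
  bool indel_in_interval;
};

static AlignResult nw_one(const std::string& read, const std::string& ref,
                          double match, double mismatch, double gap,
                          int ps_start, int ps_end) {
  const int m = read.size(), n = ref.size();
  std::vector<double> prev(n + 1), cur(n + 1);
  // dp rows kept, but traceback needs the full matrix; store it
  std::vector<std::vector<double>> dp(m + 1, std::vector<double>(n + 1));
  for (int j = 0; j <= n; ++j) dp[0][j] = gap * j;
  for (int i = 1; i <= m; ++i) {
    dp[i][0] = gap * i;
    for (int j = 1; j <= n; ++j) {
      double s = dp[i - 1][j - 1] +
                 (read[i - 1] == ref[j - 1] ? match : mismatch);
      double del = dp[i][j - 1] + gap;   // gap in read
      double ins = dp[i - 1][j] + gap;   // gap in ref
      double best = s;
      if (del > best) best = del;
      if (ins > best) best = ins;
      dp[i][j] = best;
    }
  }

  // traceback with stated preference order
  std::string ops;           // reversed
  std::string row(n, '-');
  bool hit = false;
  int i = m, j = n;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        std::abs(dp[i][j] - (dp[i - 1][j - 1] +
            (read[i - 1] == ref[j - 1] ? match : mismatch))) < eps) {
      ops.push_back('M');
      row[j - 1] = read[i - 1];
      --i; --j;
    } else if (j > 0 && std::abs(dp[i][j] - (dp[i][j - 1] + gap)) < eps) {
      ops.push_back('D');
      if (ps_start > 0 && j >= ps_start && j <= ps_end) hit = true;
      --j;
    } else {
      ops.push_back('I');
      // anchor: reference position the inserted base follows (= j here)
      if (ps_start > 0 && j >= ps_start && j < ps_end) hit = true;
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());

  // run-length encode the operation string
  std::string cigar;
  for (size_t k = 0; k < ops.size();) {
    size_t r = k;
    while (r < ops.size() && ops[r] == ops[k]) ++r;
    cigar += std::to_string(r - k);
    cigar.push_back(ops[k]);
    k = r;
  }

  AlignResult res;
  res.score = dp[m][n];
  res.cigar = cigar;
  res.ref_row = row;
  res.indel_in_interval = hit;
  return res;
}

// [[Rcpp::export]]
List nw_batch_cpp(CharacterVector reads, std::string ref,
                  double match, double mismatch, double gap,
                  int ps_start = 0, int ps_end = 0) {
  const int n = reads.size();
  NumericVector score(n);
  CharacterVector cigar(n), ref_row(n);
  LogicalVector indel(n);
  for (int k = 0; k < n; ++k) {
    std::string rd = as<std::string>(reads[k]);
    AlignResult r = nw_one(rd, ref, match, mismatch, gap, ps_start, ps_end);
    score[k] = r.score;
    cigar[k] = r.cigar;
    ref_row[k] = r.ref_row;
    indel[k] = r.indel_in_interval;
  }
  return List::create(_["score"] = score, _["cigar"] = cigar,
                      _["ref_row"] = ref_row, _["indel"] = indel);
}
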