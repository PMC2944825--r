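#include <Rcpp.h>
using namespace Rcpp;

// Best local alignment of a position-specific score matrix against a
// sequence. The alignment is local on both sides: flanking sequence
// residues and flanking profile positions are free, internal gaps are
// penalised affinely (gap_open for the first skipped residue/position,
// gap_extend for each further one), and at least one profile position must
// be matched to a residue. No zero floor is applied, so the best score can
// be negative when every match score is. Ties are broken towards the
// smallest sequence start, then the smallest end.
//
// scores: L x 20 matrix, rows = profile positions, columns = alphabet.
// seq_idx: 1-based column index of each sequence residue.
// [[Rcpp::export]]
List profile_dp(NumericMatrix scores, IntegerVector seq_idx,
                double gap_open, double gap_extend) {
  const int L = scores.nrow();
  const int n = seq_idx.size();
  const double NEG = -std::numeric_limits<double>::infinity();

  // One row at a time; start[...] records the sequence start of the
  // alignment each cell extends (for span reporting and tie-breaking).
  std::vector<double> M_prev(n + 1, NEG), D_prev(n + 1, NEG), I_prev(n + 1, NEG);
  std::vector<double> M_cur(n + 1, NEG), D_cur(n + 1, NEG), I_cur(n + 1, NEG);
  std::vector<int> Ms_prev(n + 1, 0), Ds_prev(n + 1, 0), Is_prev(n + 1, 0);
  std::vector<int> Ms_cur(n + 1, 0), Ds_cur(n + 1, 0), Is_cur(n + 1, 0);

  double best = NEG;
  int best_start = 0, best_end = 0;

  for (int i = 1; i <= L; ++i) {
    M_cur[0] = D_cur[0] = I_cur[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      // Match profile position i to residue j.
      double sc = scores(i - 1, seq_idx[j - 1] - 1);
      double val = 0.0;          // fresh local start at residue j
      int st = j;
      if (M_prev[j - 1] > val || (M_prev[j - 1] == val && Ms_prev[j - 1] < st)) {
        val = M_prev[j - 1]; st = Ms_prev[j - 1];
      }
      if (D_prev[j - 1] > val || (D_prev[j - 1] == val && Ds_prev[j - 1] < st)) {
        val = D_prev[j - 1]; st = Ds_prev[j - 1];
      }
      if (I_prev[j - 1] > val || (I_prev[j - 1] == val && Is_prev[j - 1] < st)) {
        val = I_prev[j - 1]; st = Is_prev[j - 1];
      }
      M_cur[j] = sc + val;
      Ms_cur[j] = st;

      // Delete profile position i (internal only: must extend an alignment).
      // A deletion run may directly follow an insertion run (each opens its
      // own affine gap), so I also feeds D.
      double dval = NEG; int dst = 0;
      if (M_prev[j] > NEG) { dval = M_prev[j] + gap_open; dst = Ms_prev[j]; }
      double dext = (D_prev[j] > NEG) ? D_prev[j] + gap_extend : NEG;
      if (dext > dval || (dext == dval && dval > NEG && Ds_prev[j] < dst)) {
        dval = dext; dst = Ds_prev[j];
      }
      double dswitch = (I_prev[j] > NEG) ? I_prev[j] + gap_open : NEG;
      if (dswitch > dval || (dswitch == dval && dval > NEG && Is_prev[j] < dst)) {
        dval = dswitch; dst = Is_prev[j];
      }
      D_cur[j] = dval;
      Ds_cur[j] = dst;

      // Insert residue j (internal only); D feeds I symmetrically.
      double ival = NEG; int ist = 0;
      if (M_cur[j - 1] > NEG) { ival = M_cur[j - 1] + gap_open; ist = Ms_cur[j - 1]; }
      double iext = (I_cur[j - 1] > NEG) ? I_cur[j - 1] + gap_extend : NEG;
      if (iext > ival || (iext == ival && ival > NEG && Is_cur[j - 1] < ist)) {
        ival = iext; ist = Is_cur[j - 1];
      }
      double iswitch = (D_cur[j - 1] > NEG) ? D_cur[j - 1] + gap_open : NEG;
      if (iswitch > ival || (iswitch == ival && ival > NEG && Ds_cur[j - 1] < ist)) {
        ival = iswitch; ist = Ds_cur[j - 1];
      }
      I_cur[j] = ival;
      Is_cur[j] = ist;

      // Free trailing gaps mean every alignment can be taken to end in a
      // match, so only M cells compete for the optimum.
      if (M_cur[j] > best ||
          (M_cur[j] == best &&
           (Ms_cur[j] < best_start || (Ms_cur[j] == best_start && j < best_end)))) {
        best = M_cur[j];
        best_start = Ms_cur[j];
        best_end = j;
      }
    }
    std::swap(M_prev, M_cur); std::swap(D_prev, D_cur); std::swap(I_prev, I_cur);
    std::swap(Ms_prev, Ms_cur); std::swap(Ds_prev, Ds_cur); std::swap(Is_prev, Is_cur);
  }

  return List::create(_["score"] = best,
                      _["start"] = best_start,
                      _["end"] = best_end);
}
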