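#include <Rcpp.h>
using namespace Rcpp;

// Length-sensing remodeling sweeps. Nucleosomes are visited 5' to 3' within
// each sweep; flanks are measured from current positions to the neighbor
// footprints or to the template ends [0, template_length). Direction is a
// fair coin flip (R RNG) when both flanks reach flank_cutoff. With
// flank_cutoff >= step no move can create an overlap.
// [[Rcpp::export]]
IntegerVector ls_sweeps_cpp(IntegerVector entries, int template_length,
                            int nuc_length, int flank_cutoff, int step,
                            int n_sweeps, bool until_blocked) {
  IntegerVector e = clone(entries);
  int n = e.size();
  if (n == 0) return e;
  for (int s = 0; s < n_sweeps; ++s) {
    for (int i = 0; i < n; ++i) {
      int left_bound = (i == 0) ? 0 : e[i - 1] + nuc_length;
      int right_bound = (i == n - 1) ? template_length : e[i + 1];
      int flank5 = e[i] - left_bound;
      int flank3 = right_bound - (e[i] + nuc_length);
      bool ok5 = flank5 >= flank_cutoff;
      bool ok3 = flank3 >= flank_cutoff;
      int dir;
      if (ok5 && ok3) dir = (unif_rand() < 0.5) ? -1 : 1;
      else if (ok5) dir = -1;
      else if (ok3) dir = 1;
      else continue;
      if (until_blocked) {
        int flank = (dir < 0) ? flank5 : flank3;
        while (flank >= flank_cutoff) {
          e[i] += dir * step;
          flank -= step;
        }
      } else {
        e[i] += dir * step;
      }
    }
  }
  return e;
}
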