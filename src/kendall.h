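#pragma once

// Kendall tau-b discriminative power, full-sample and per-LOOCV-fold.
// X: n x p, column-major (as stored by R). y: n binary labels in {0,1}.
// powers_out: length p.  fold_out (may be null): p x n column-major, column m =
// powers with subject m removed.
void kendall_powers_core(const double *X, const int *y, int n, int p,
                         double *powers_out, double *fold_out);
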