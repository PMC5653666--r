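#include <Rcpp.h>
#include <string>
#include <vector>
#include <climits>

using namespace Rcpp;

// Global affine-gap alignment (Gotoh) of a read segment against a
// reference segment. The gap model charges `gap_open` for the first base
// of a gap and `gap_ext` for each additional base, so a length-L gap
// costs gap_open + (L-1)*gap_ext. `N` against anything scores as a
// mismatch. Tie-breaking in the traceback prefers diagonal moves, then
// deletions, then insertions, and prefers extending an open gap over
// opening a new one (fewer gap openings); indel events are additionally
// left-normalised downstream, so the traceback choice only needs to be
// deterministic.

static inline int subst_score(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string read, std::string ref,
                 int match, int mismatch, int gap_open, int gap_ext) {
  const int m = (int) read.size();
  const int n = (int) ref.size();
  const int NEG = INT_MIN / 4;
  const int W = n + 1;

  std::vector<int> H((m + 1) * W), E((m + 1) * W), F((m + 1) * W);
  // E: gap in the read (deletion, consumes ref); F: gap in the ref
  // (insertion, consumes read)
  H[0] = 0; E[0] = NEG; F[0] = NEG;
  for (int j = 1; j <= n; ++j) {
    E[j] = gap_open + (j - 1) * gap_ext;
    H[j] = E[j];
    F[j] = NEG;
  }
  for (int i = 1; i <= m; ++i) {
    F[i * W] = gap_open + (i - 1) * gap_ext;
    H[i * W] = F[i * W];
    E[i * W] = NEG;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int idx = i * W + j;
      int e_open = H[idx - 1] + gap_open;
      int e_ext  = E[idx - 1] + gap_ext;
      E[idx] = (e_ext >= e_open) ? e_ext : e_open;
      int f_open = H[idx - W] + gap_open;
      int f_ext  = F[idx - W] + gap_ext;
      F[idx] = (f_ext >= f_open) ? f_ext : f_open;
      int diag = H[idx - W - 1] +
        subst_score(read[i - 1], ref[j - 1], match, mismatch);
      int best = diag;
      if (E[idx] > best) best = E[idx];
      if (F[idx] > best) best = F[idx];
      H[idx] = best;
    }
  }

  // traceback with run-length-encoded ops, built back-to-front
  std::vector<char> ops;
  std::vector<int> lens;
  int n_mismatch = 0;
  int i = m, j = n;
  // state 0 = H, 1 = E (in-gap deletion), 2 = F (in-gap insertion)
  int state = 0;
  auto push = [&](char op) {
    if (!ops.empty() && ops.back() == op) lens.back()++;
    else { ops.push_back(op); lens.push_back(1); }
  };
  while (i > 0 || j > 0) {
    const int idx = i * W + j;
    if (state == 0) {
      if (i == 0) { state = 1; continue; }
      if (j == 0) { state = 2; continue; }
      int diag = H[idx - W - 1] +
        subst_score(read[i - 1], ref[j - 1], match, mismatch);
      if (H[idx] == diag) {
        if (subst_score(read[i - 1], ref[j - 1], match, mismatch) == mismatch)
          n_mismatch++;
        push('M'); --i; --j;
      } else if (H[idx] == E[idx]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      push('D'); // consumes ref
      int e_ext = (j >= 2) ? E[idx - 1] + gap_ext : NEG;
      if (E[idx] == e_ext) { --j; /* stay in E */ }
      else { --j; state = 0; }
    } else {
      push('I'); // consumes read
      int f_ext = (i >= 2) ? F[idx - W] + gap_ext : NEG;
      if (F[idx] == f_ext) { --i; }
      else { --i; state = 0; }
    }
  }
  std::reverse(ops.begin(), ops.end());
  std::reverse(lens.begin(), lens.end());
  CharacterVector op_out(ops.size());
  IntegerVector len_out(lens.size());
  for (size_t k = 0; k < ops.size(); ++k) {
    op_out[k] = std::string(1, ops[k]);
    len_out[k] = lens[k];
  }
  return List::create(_["score"] = H[m * W + n],
                      _["op"] = op_out,
                      _["len"] = len_out,
                      _["n_mismatch"] = n_mismatch);
}
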