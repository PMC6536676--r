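#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Affine-gap (Gotoh) Smith-Waterman with full traceback.
//
// Sequences arrive as 0-based integer codes indexing the substitution
// matrix. Gap costs are positive; a gap of length L costs open + L * extend
// (NCBI convention: the first gap residue costs open + extend).
//
// Tie-breaking among co-optimal local alignments is total and documented:
// smallest query start, then smallest subject start, then smallest query
// end, then smallest subject end. Traceback prefers diagonal > gap-in-query
// > gap-in-subject so the reported alignment is deterministic.

namespace {

struct Trace {
  // per-cell traceback pointers, 2 bits each would do; bytes are simple
  std::vector<uint8_t> h, e, f;
  size_t ncol;
  Trace(size_t m, size_t n) : h((m + 1) * (n + 1)), e((m + 1) * (n + 1)),
                              f((m + 1) * (n + 1)), ncol(n + 1) {}
  inline size_t at(size_t i, size_t j) const { return i * ncol + j; }
};

} // namespace

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector q, IntegerVector s, NumericMatrix mat,
              double gap_open, double gap_extend) {
  const int m = q.size(), n = s.size();
  if (m == 0 || n == 0) stop("empty sequence");
  const double NEG = -1e30;

  Trace tr(m, n);
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev; // E only needs current row
  std::vector<double> Erow(n + 1, NEG), Fcol(n + 1, NEG);

  double best = 0.0;
  std::vector<std::pair<int, int> > best_ends;

  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0;
    double E = NEG; // gap in query, along the row
    for (int j = 1; j <= n; ++j) {
      // E: consume subject char j (gap in query)
      double e_open = Hcur[j - 1] - gap_open - gap_extend;
      double e_ext = E - gap_extend;
      uint8_t eptr = (e_open >= e_ext) ? 0 : 1; // 0 = from H, 1 = extend
      E = (e_open >= e_ext) ? e_open : e_ext;
      tr.e[tr.at(i, j)] = eptr;

      // F: consume query char i (gap in subject), per column
      double f_open = Hprev[j] - gap_open - gap_extend;
      double f_ext = Fcol[j] - gap_extend;
      uint8_t fptr = (f_open >= f_ext) ? 0 : 1;
      Fcol[j] = (f_open >= f_ext) ? f_open : f_ext;
      tr.f[tr.at(i, j)] = fptr;

      double diag = Hprev[j - 1] + mat(q[i - 1], s[j - 1]);

      double h = 0.0;
      uint8_t hptr = 0; // 0 = stop (score 0)
      if (diag >= h) { h = diag; hptr = 1; }
      if (E > h) { h = E; hptr = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; hptr = 3; }
      // preference order on ties: diag > E > F (diag checked first with >=)
      Hcur[j] = h;
      tr.h[tr.at(i, j)] = hptr;

      if (h > best + 1e-9) {
        best = h;
        best_ends.clear();
        best_ends.push_back(std::make_pair(i, j));
      } else if (h > 0 && h > best - 1e-9) {
        best_ends.push_back(std::make_pair(i, j));
      }
    }
    std::swap(Hprev, Hcur);
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["hit"] = false);
  }

  // trace each co-optimal end, keep the one with the documented tie-break
  int bqs = -1, bss = -1, bqe = -1, bse = -1, blen = 0, bmatch = 0;
  for (size_t k = 0; k < best_ends.size(); ++k) {
    int i = best_ends[k].first, j = best_ends[k].second;
    int qe = i, se = j, len = 0, match = 0;
    int state = 0; // 0 = H, 1 = E, 2 = F
    while (true) {
      if (state == 0) {
        uint8_t p = tr.h[tr.at(i, j)];
        if (p == 0) break;
        if (p == 1) {
          if (q[i - 1] == s[j - 1]) ++match;
          --i; --j; ++len;
        } else if (p == 2) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) {
        uint8_t p = tr.e[tr.at(i, j)];
        --j; ++len;
        state = (p == 0) ? 0 : 1;
      } else {
        uint8_t p = tr.f[tr.at(i, j)];
        --i; ++len;
        state = (p == 0) ? 0 : 2;
      }
    }
    int qs = i + 1, ss = j + 1;
    bool take = (bqs < 0);
    if (!take) {
      if (qs != bqs) take = qs < bqs;
      else if (ss != bss) take = ss < bss;
      else if (qe != bqe) take = qe < bqe;
      else take = se < bse;
    }
    if (take) {
      bqs = qs; bss = ss; bqe = qe; bse = se; blen = len; bmatch = match;
    }
  }

  return List::create(
    _["score"] = best, _["hit"] = true,
    _["query_start"] = bqs, _["query_end"] = bqe,
    _["subject_start"] = bss, _["subject_end"] = bse,
    _["alignment_length"] = blen, _["identities"] = bmatch);
}
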