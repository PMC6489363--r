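#include <Rcpp.h>
using namespace Rcpp;

// Hamming-distance assignment of read prefixes to a barcode panel.
// Status codes: 1 = assigned, 2 = unassigned_distance, 3 = unassigned_ambiguous.
// Any character differing from the (validated ACGT) barcode base counts as a
// mismatch, so N and other ambiguity codes are mismatches by construction.
// [[Rcpp::export]]
List hamming_assign_cpp(CharacterVector prefixes, CharacterVector barcodes,
                        int max_mismatches) {
  const int n = prefixes.size();
  const int k = barcodes.size();
  std::vector<std::string> bc(k);
  for (int j = 0; j < k; ++j) bc[j] = as<std::string>(barcodes[j]);
  const int L = k > 0 ? (int) bc[0].size() : 0;

  IntegerVector status(n), index(n), dist(n);
  for (int i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(prefixes, i));
    int best = L + 1, best_j = -1, n_best = 0;
    for (int j = 0; j < k; ++j) {
      const std::string &b = bc[j];
      int d = 0;
      for (int p = 0; p < L; ++p) {
        if (r[p] != b[p] && ++d > best) break;  // cannot beat or tie: bail
      }
      if (d < best) {
        best = d; best_j = j; n_best = 1;
      } else if (d == best) {
        ++n_best;
      }
    }
    if (best <= max_mismatches) {
      if (n_best == 1) {
        status[i] = 1; index[i] = best_j + 1; dist[i] = best;
      } else {
        status[i] = 3; index[i] = NA_INTEGER; dist[i] = best;
      }
    } else {
      status[i] = 2; index[i] = NA_INTEGER; dist[i] = NA_INTEGER;
    }
  }
  return List::create(_["status"] = status, _["index"] = index,
                      _["distance"] = dist);
}

// All-pairs Hamming distance matrix for equal-length sequences.
// [[Rcpp::export]]
IntegerMatrix hamming_matrix_cpp(CharacterVector seqs) {
  const int k = seqs.size();
  std::vector<std::string> s(k);
  for (int j = 0; j < k; ++j) s[j] = as<std::string>(seqs[j]);
  const int L = k > 0 ? (int) s[0].size() : 0;
  IntegerMatrix m(k, k);
  for (int i = 0; i < k; ++i) {
    for (int j = i + 1; j < k; ++j) {
      int d = 0;
      for (int p = 0; p < L; ++p) if (s[i][p] != s[j][p]) ++d;
      m(i, j) = d;
      m(j, i) = d;
    }
  }
  return m;
}
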