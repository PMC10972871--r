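#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Exact k-mer seeding of translated read frames against a protein set,
// followed by an ungapped pre-extension: for every seeded (peptide, protein)
// diagonal, the best-scoring ungapped segment on that diagonal (Kadane scan)
// is computed and the pair is reported when it reaches min_ungapped. Gapped
// extension happens R-side; the gate must stay below any raw score that can
// survive the e-value cutoff (each gap costs >= gap_open + gap_extend, so a
// passing gapped alignment always contains a high-scoring ungapped run).
//
// submat: integer substitution matrix with single-letter dimnames.
// Returns 1-based (peptide index, protein index, best ungapped score).

// [[Rcpp::export]]
List seed_scan_cpp(CharacterVector peptides, CharacterVector proteins,
                   int k, IntegerMatrix submat, double min_ungapped) {
  List dn = submat.attr("dimnames");
  CharacterVector alpha = dn[0];
  const int na = alpha.size();
  int code[256];
  std::fill(code, code + 256, -1);
  int xcode = -1;
  for (int i = 0; i < na; ++i) {
    const char c = CHAR(STRING_ELT(alpha, i))[0];
    code[(unsigned char)c] = i;
    if (c == 'X') xcode = i;
  }
  if (xcode < 0) stop("substitution matrix lacks an 'X' row");

  // flat copy of the matrix for speed
  std::vector<int> M(na * na);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < na; ++j) M[i * na + j] = submat(i, j);

  // encode proteins and build the k-mer index
  const int np = proteins.size();
  std::vector<std::vector<int8_t>> prot(np);
  std::unordered_map<uint64_t, std::vector<uint32_t>> index;
  for (int p = 0; p < np; ++p) {
    const char* s = CHAR(STRING_ELT(proteins, p));
    const int n = LENGTH(STRING_ELT(proteins, p));
    prot[p].resize(n);
    for (int i = 0; i < n; ++i) {
      int c = code[(unsigned char)s[i]];
      prot[p][i] = (int8_t)(c < 0 ? xcode : c);
    }
    if (n < k) continue;
    uint64_t key = 0;
    const uint64_t mask = (k >= 12) ? ~UINT64_C(0) : ((UINT64_C(1) << (5 * k)) - 1);
    for (int i = 0; i < n; ++i) {
      key = ((key << 5) | (uint64_t)prot[p][i]) & mask;
      if (i >= k - 1)
        index[key].push_back(((uint32_t)p << 16) | (uint32_t)(i - k + 1));
    }
  }

  std::vector<int> out_pep, out_prot;
  std::vector<double> out_score;
  std::vector<int8_t> pep;
  std::unordered_set<uint64_t> seen_diag;   // (prot, diag) per peptide
  std::unordered_set<uint64_t> emitted;     // (pep, prot) already reported

  const int nq = peptides.size();
  for (int q = 0; q < nq; ++q) {
    const char* s = CHAR(STRING_ELT(peptides, q));
    const int n = LENGTH(STRING_ELT(peptides, q));
    if (n < k) continue;
    pep.resize(n);
    for (int i = 0; i < n; ++i) {
      int c = code[(unsigned char)s[i]];
      pep[i] = (int8_t)(c < 0 ? xcode : c);
    }
    seen_diag.clear();
    uint64_t key = 0;
    const uint64_t mask = (k >= 12) ? ~UINT64_C(0) : ((UINT64_C(1) << (5 * k)) - 1);
    for (int i = 0; i < n; ++i) {
      key = ((key << 5) | (uint64_t)pep[i]) & mask;
      if (i < k - 1) continue;
      auto it = index.find(key);
      if (it == index.end()) continue;
      const int qpos = i - k + 1;
      for (uint32_t packed : it->second) {
        const int p = (int)(packed >> 16);
        const int ppos = (int)(packed & 0xffff);
        const int diag = ppos - qpos;                     // prot - pep offset
        const uint64_t dkey =
            ((uint64_t)p << 32) | (uint32_t)(diag + 0x10000);
        if (!seen_diag.insert(dkey).second) continue;
        // Kadane over the whole diagonal
        const int pn = (int)prot[p].size();
        int qs = diag < 0 ? -diag : 0;   // first pep position on diagonal
        double best = -1e18, cur = 0;
        for (int a = qs; a < n && a + diag < pn; ++a) {
          cur += M[pep[a] * na + prot[p][a + diag]];
          if (cur > best) best = cur;
          if (cur < 0) cur = 0;
        }
        if (best >= min_ungapped) {
          const uint64_t ekey = ((uint64_t)q << 24) | (uint64_t)p;
          auto em = emitted.insert(ekey);
          if (em.second) {
            out_pep.push_back(q + 1);
            out_prot.push_back(p + 1);
            out_score.push_back(best);
          } else {
            // keep the best ungapped score for an already-listed pair
            for (size_t j = out_pep.size(); j-- > 0;) {
              if (out_pep[j] == q + 1 && out_prot[j] == p + 1) {
                if (best > out_score[j]) out_score[j] = best;
                break;
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["pep"] = wrap(out_pep), _["prot"] = wrap(out_prot),
                      _["ungapped"] = wrap(out_score));
}
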