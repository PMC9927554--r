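#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cctype>
using namespace Rcpp;

// Frameshift-aware local alignment of DNA against a protein.
//
// States per cell (i = nucleotides of DNA consumed, j = residues consumed):
//   M: codon column, consumes 3 nt / 1 aa; frameshift variants consume
//      2 nt (fs-) or 4 nt (fs+), charged fs penalty.  The codon scored is
//      always the last 3 nt ending at i, so a fs- column re-reads one
//      nucleotide of the previous column and a fs+ column skips one.
//   D: unaligned protein letter (affine), consumes 0 nt / 1 aa.
//   I: unaligned codon (affine), consumes 3 nt / 0 aa.
// Local semantics: a new alignment may start (score floor 0) only on a
// regular codon column.  Soft-masked (lowercase) codon positions have their
// substitution score capped at 0; codons containing non-ACGT letters score 0.

static const int NEG = -100000000;

static inline int nt_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// [[Rcpp::export]]
List fs_align_cpp(std::string dna, IntegerVector prot, IntegerMatrix subst,
                  int go_del, int ge_del, int go_ins, int ge_ins, int fs,
                  int min_score, bool score_only) {
  const int n = (int) dna.size();
  const int m = (int) prot.size();
  const int W = m + 1;

  // codon index ending at i (1-based in consumed nt), -1 if any non-ACGT
  std::vector<int> ci(n + 1, -1);
  std::vector<char> masked(n + 1, 0);
  for (int i = 3; i <= n; ++i) {
    int a = nt_code(dna[i - 3]), b = nt_code(dna[i - 2]), c = nt_code(dna[i - 1]);
    ci[i] = (a < 0 || b < 0 || c < 0) ? -1 : 16 * a + 4 * b + c;
    masked[i] = (std::islower((unsigned char) dna[i - 3]) ||
                 std::islower((unsigned char) dna[i - 2]) ||
                 std::islower((unsigned char) dna[i - 1])) ? 1 : 0;
  }

  std::vector<int> M((size_t)(n + 1) * W, NEG);
  std::vector<int> D((size_t)(n + 1) * W, NEG);
  std::vector<int> I((size_t)(n + 1) * W, NEG);
  std::vector<int> H((size_t)(n + 1) * W, 0);

  // flat copies for fast unchecked access
  std::vector<int> S(64 * 21);
  for (int c = 0; c < 64; ++c)
    for (int a = 0; a < 21; ++a) S[c * 21 + a] = subst(c, a);
  std::vector<int> pj(m);
  for (int j = 0; j < m; ++j) pj[j] = prot[j];

  // substitution score for codon ending at i vs protein letter index a
  #define SC(i, a) (ci[(i)] < 0 || (a) < 0 ? 0 : \
    (masked[(i)] ? std::min(S[ci[(i)] * 21 + (a)], 0) : S[ci[(i)] * 21 + (a)]))

  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int* Hr = &H[(size_t) i * W];
    int* Dr = &D[(size_t) i * W];
    int* Mr = &M[(size_t) i * W];
    int* Ir = &I[(size_t) i * W];
    const int* H2 = i >= 2 ? &H[(size_t)(i - 2) * W] : NULL;
    const int* H3 = i >= 3 ? &H[(size_t)(i - 3) * W] : NULL;
    const int* H4 = i >= 4 ? &H[(size_t)(i - 4) * W] : NULL;
    const int* I3 = i >= 3 ? &I[(size_t)(i - 3) * W] : NULL;
    const int cii = ci[i];
    const int* Sc = cii >= 0 ? &S[cii * 21] : NULL;
    const bool mk = masked[i] != 0;
    for (int j = 1; j <= m; ++j) {
      int m_val = NEG, d_val, i_val = NEG;
      if (i >= 3) {
        const int a = pj[j - 1];
        int s = (Sc == NULL || a < 0) ? 0 : (mk ? std::min(Sc[a], 0) : Sc[a]);
        int src = H3[j - 1] > 0 ? H3[j - 1] : 0;
        if (H2[j - 1] - fs > src) src = H2[j - 1] - fs;
        if (H4 != NULL && H4[j - 1] - fs > src) src = H4[j - 1] - fs;
        m_val = s + src;
        i_val = std::max(H3[j] - go_ins, I3[j] - ge_ins);
      }
      d_val = std::max(Hr[j - 1] - go_del, Dr[j - 1] - ge_del);
      Mr[j] = m_val;
      Dr[j] = d_val;
      Ir[j] = i_val;
      Hr[j] = std::max(m_val, std::max(d_val, i_val));
      if (m_val > best) best = m_val;
    }
  }

  if (score_only) {
    return List::create(Named("best") = best);
  }

  // candidate end cells (alignments end on a codon column)
  struct Cand { int score, i, j; };
  std::vector<Cand> cand;
  for (int i = 3; i <= n; ++i)
    for (int j = 1; j <= m; ++j)
      if (M[(size_t) i * W + j] >= min_score)
        cand.push_back({M[(size_t) i * W + j], i, j});
  std::sort(cand.begin(), cand.end(), [](const Cand& a, const Cand& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });

  std::vector<char> used(n + 1, 0);
  List out;
  for (const Cand& cd : cand) {
    if (used[cd.i - 1]) continue;  // shoulder of an already reported peak
    int i = cd.i, j = cd.j, state = 0;  // 0=M, 1=D, 2=I
    std::vector<int> ops;  // 1=M3 2=FS2 3=FS4 4=DEL 5=INS (reversed)
    bool done = false;
    while (!done) {
      size_t r = (size_t) i * W;
      if (state == 0) {
        int v = M[r + j], s = SC(i, prot[j - 1]);
        int h3 = i >= 3 ? H[(size_t)(i - 3) * W + j - 1] : NEG;
        int h2 = i >= 3 ? H[(size_t)(i - 2) * W + j - 1] : NEG;
        int h4 = i >= 4 ? H[(size_t)(i - 4) * W + j - 1] : NEG;
        if (h3 > 0 && v == s + h3) {
          ops.push_back(1); i -= 3; --j;
        } else if (h2 > 0 && v == s - fs + h2) {
          ops.push_back(2); i -= 2; --j;
        } else if (h4 > 0 && v == s - fs + h4) {
          ops.push_back(3); i -= 4; --j;
        } else {  // fresh start on a regular codon column
          ops.push_back(1); i -= 3; --j;
          done = true;
          break;
        }
      } else if (state == 1) {
        int v = D[r + j];
        ops.push_back(4);
        if (v == H[r + j - 1] - go_del) { --j; }
        else { --j; state = 1; continue; }
      } else {
        int v = I[r + j];
        ops.push_back(5);
        if (v == H[(size_t)(i - 3) * W + j] - go_ins) { i -= 3; }
        else { i -= 3; state = 2; continue; }
      }
      // resolve state of H at new cell (tie order M > D > I)
      size_t r2 = (size_t) i * W;
      int h = H[r2 + j];
      if (h == M[r2 + j]) state = 0;
      else if (h == D[r2 + j]) state = 1;
      else state = 2;
    }
    std::reverse(ops.begin(), ops.end());
    bool clash = false;           // shoulder alignments share DNA with a peak
    for (int p = i; p < cd.i; ++p) if (used[p]) { clash = true; break; }
    if (clash) continue;
    for (int p = i; p < cd.i; ++p) used[p] = 1;
    out.push_back(List::create(
      Named("score") = cd.score,
      Named("dna_start") = i, Named("dna_end") = cd.i,
      Named("prot_start") = j, Named("prot_end") = cd.j,
      Named("ops") = IntegerVector(ops.begin(), ops.end())));
  }
  #undef SC
  return out;
}
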