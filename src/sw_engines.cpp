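// Smith-Waterman affine-gap scoring engines.
//
// Two independent routes to the same score:
//  * c_sw_reference — naive full-matrix Gotoh DP with rolling rows; the
//    oracle and the fallback path for queries that exceed the shared-memory
//    budget.
//  * c_sw_tiled — the tiled engine: the DP matrix is processed in K x P
//    tiles in column-major order (a tile column = K consecutive subject
//    residues, all query rows top to bottom).  Row-boundary values of H and
//    F flow through a K-register carry model; column-boundary values of H
//    and E cross tile columns only through an explicit column buffer that
//    models per-thread shared memory (2 bytes per cell, 2 matrices, hence
//    4 bytes per buffered query position).
//
// Recurrences (standard Gotoh; 1-based i over query, j over subject):
//   E(i,j) = max(E(i,j-1) - sigma, H(i,j-1) - rho - sigma)
//   F(i,j) = max(F(i-1,j) - sigma, H(i-1,j) - rho - sigma)
//   H(i,j) = max(0, E(i,j), F(i,j), H(i-1,j-1) + sbt(S1[i], S2[j]))
// Borders: H(.,0) = H(0,.) = 0, E(i,0) = F(0,j) = -inf (large negative
// sentinel that cannot wrap 32-bit arithmetic after one subtraction).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const int NEG_INF = -(1 << 28);
static const int I16_MAX = 32767;
static const int I16_MIN = -32768;

// q, s: 1-based residue indices into sbt (R passes its own 1-based indices).
// [[Rcpp::export]]
int c_sw_reference(IntegerVector q, IntegerVector s, IntegerMatrix sbt,
                   int rho, int sigma) {
  const int L1 = q.size(), L2 = s.size();
  if (L2 == 0 || L1 == 0) return 0;
  std::vector<int> Hprev(L2 + 1, 0), Hcur(L2 + 1, 0), Frow(L2 + 1, NEG_INF);
  int best = 0;
  for (int i = 1; i <= L1; ++i) {
    int E = NEG_INF;        // E(i, 0)
    Hcur[0] = 0;
    const int qi = q[i - 1] - 1;
    for (int j = 1; j <= L2; ++j) {
      E = std::max(E - sigma, Hcur[j - 1] - rho - sigma);
      const int F = std::max(Frow[j] - sigma, Hprev[j] - rho - sigma);
      int H = Hprev[j - 1] + sbt(qi, s[j - 1] - 1);
      H = std::max(std::max(0, H), std::max(E, F));
      Frow[j] = F;
      Hcur[j] = H;
      if (H > best) best = H;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

// Tiled engine for one lane of an interleaved layout.
//
// prof: padded_query_length x (n_letters + 1) profile; row i-1 holds
//       sbt(query[i], a) for every letter a, with the pad column last and
//       padded query rows holding the pad score.
// flat: residue indices (1-based, pad index = n_letters + 1) of the whole
//       interleaved group; residue j (0-based) of `lane` (0-based) lives at
//       flat[group_size * j + lane].  padded_len columns per lane.
// Returns the score plus instrumentation of the memory model.
// [[Rcpp::export]]
List c_sw_tiled(IntegerMatrix prof, IntegerVector flat, int lane,
                int group_size, int padded_len, int K, int P,
                int rho, int sigma) {
  const int Qpad = prof.nrow();
  if (K < 1) stop("K must be >= 1");
  if (P < 4 || P % 4 != 0) stop("P must be a positive multiple of 4");
  if (Qpad % P != 0) stop("profile length is not a multiple of P");
  if (padded_len % K != 0) stop("padded subject length is not a multiple of K");

  const int n_tile_cols = padded_len / K;
  long long buffer_reads = 0, buffer_writes = 0, cells = 0;
  bool overflow = false;
  int best = 0;

  // Column buffers: col_H[r], col_E[r] hold H and E of row r+1 at the last
  // column of the previous tile column (the shared-memory model).
  std::vector<int> col_H(Qpad, 0), col_E(Qpad, NEG_INF);
  std::vector<int> hReg(K), fReg(K);

  for (int tc = 0; tc < n_tile_cols; ++tc) {
    const int j0 = tc * K;
    // top border of this tile column: H(0, j) = 0, F(0, j) = -inf
    std::fill(hReg.begin(), hReg.end(), 0);
    std::fill(fReg.begin(), fReg.end(), NEG_INF);
    int diag0 = 0;  // H(i-1, j0-1); starts at H(0, j0-1) = 0
    for (int i = 1; i <= Qpad; ++i) {
      const int hl0 = col_H[i - 1];  // H(i, j0-1), read before overwrite
      int hLeft = hl0;
      int eLeft = col_E[i - 1];      // E(i, j0-1)
      buffer_reads += 2;
      int diag = diag0;
      for (int t = 0; t < K; ++t) {
        const int sidx = flat[(long long)group_size * (j0 + t) + lane] - 1;
        const int E = std::max(eLeft - sigma, hLeft - rho - sigma);
        const int F = std::max(fReg[t] - sigma, hReg[t] - rho - sigma);
        int H = diag + prof(i - 1, sidx);
        H = std::max(std::max(0, H), std::max(E, F));
        diag = hReg[t];   // old H(i-1, j0+t) feeds the next cell's diagonal
        hReg[t] = H;
        fReg[t] = F;
        eLeft = E;
        hLeft = H;
        if (H > best) best = H;
      }
      cells += K;
      // spill the tile column's Kth-column H and E to the shared buffer
      if (hReg[K - 1] > I16_MAX || hReg[K - 1] < I16_MIN) overflow = true;
      if (eLeft > I16_MAX || eLeft < I16_MIN) overflow = true;
      col_H[i - 1] = hReg[K - 1];
      col_E[i - 1] = eLeft;
      buffer_writes += 2;
      diag0 = hl0;
    }
  }

  return List::create(
    _["score"] = best,
    _["buffer_reads"] = (double)buffer_reads,
    _["buffer_writes"] = (double)buffer_writes,
    _["peak_buffer_bytes"] = 4.0 * Qpad,  // 2 matrices x 2 bytes per cell
    _["cells"] = (double)cells,
    _["tile_cols"] = n_tile_cols,
    _["overflow"] = overflow);
}
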