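#include <Rcpp.h>
using namespace Rcpp;

// Raw-pointer column access throughout: these three kernels carry nearly
// all the arithmetic of the soft simulator, and element accessors cost
// several times the loop body itself on this code path.

// Parity (haplotype-source) indicators for independent gamete lineages.
// Each row is one gamete; entry (i, j) is the running crossover count mod 2
// after marker j, i.e. 0 = read the first homologue, 1 = the second.
// Chromosome starts re-randomize at rate 0.5 (the virtual r01); within a
// chromosome the parity flips with probability r_adj[j].
// [[Rcpp::export]]
IntegerMatrix cpp_sample_parity(int n_rows, NumericVector r_adj,
                                LogicalVector chrom_first) {
  int m = r_adj.size();
  IntegerMatrix out(n_rows, m);
  int *po = INTEGER(out);
  for (int j = 0; j < m; ++j) {
    int *col = po + (size_t)n_rows * j;
    if (chrom_first[j]) {
      for (int i = 0; i < n_rows; ++i)
        col[i] = unif_rand() < 0.5 ? 1 : 0;
    } else {
      double r = r_adj[j];
      const int *prev = col - n_rows;
      for (int i = 0; i < n_rows; ++i) {
        int flip = unif_rand() < r ? 1 : 0;
        col[i] = prev[i] ^ flip;
      }
    }
  }
  return out;
}

// Forward pass of the soft-progeny construction: every progeny slot i gets
// one candidate offspring from every mating pair k (gametes fixed by the
// parity draws Hm/Hp), and the slot's soft allele scores are the
// Gumbel-Softmax-weighted convex combination over pairs.
//   W : n x 2m selected-parent allele scores (may be soft)
//   y : N x P Gumbel-Softmax weights (rows sum to 1)
//   Hm, Hp : (N*P) x m parity indicators, row index i + N*k
//   kM, kP : 0-based parent indices per pair
// Returns wsoft (N x 2m) plus the per-pair gametes kept for the backward
// pass.
// [[Rcpp::export]]
List cpp_soft_progeny_forward(NumericMatrix W, NumericMatrix y,
                              IntegerMatrix Hm, IntegerMatrix Hp,
                              IntegerVector kM, IntegerVector kP) {
  int N = y.nrow(), P = y.ncol();
  int m = Hm.ncol();
  int n = W.nrow();
  size_t NP = (size_t)N * P;
  NumericMatrix wsoft(N, 2 * m);
  NumericMatrix gamM(N * P, m), gamP(N * P, m);
  double *pw = REAL(wsoft), *pgm = REAL(gamM), *pgp = REAL(gamP);
  const double *pW = REAL(W), *py = REAL(y);
  const int *phm = INTEGER(Hm), *php = INTEGER(Hp);
  for (int k = 0; k < P; ++k) {
    int pM = kM[k], pP = kP[k];
    const double *yk = py + (size_t)N * k;
    for (int j = 0; j < m; ++j) {
      double wM0 = pW[pM + (size_t)n * j], wM1 = pW[pM + (size_t)n * (j + m)];
      double wP0 = pW[pP + (size_t)n * j], wP1 = pW[pP + (size_t)n * (j + m)];
      double *gm = pgm + NP * j + (size_t)N * k;
      double *gp = pgp + NP * j + (size_t)N * k;
      const int *hm = phm + NP * j + (size_t)N * k;
      const int *hp = php + NP * j + (size_t)N * k;
      double *ws1 = pw + (size_t)N * j;
      double *ws2 = pw + (size_t)N * (j + m);
      for (int i = 0; i < N; ++i) {
        double g1 = hm[i] ? wM1 : wM0;
        double g2 = hp[i] ? wP1 : wP0;
        gm[i] = g1;
        gp[i] = g2;
        ws1[i] += yk[i] * g1;
        ws2[i] += yk[i] * g2;
      }
    }
  }
  return List::create(_["wsoft"] = wsoft, _["gamM"] = gamM, _["gamP"] = gamP);
}

// Reverse pass of cpp_soft_progeny_forward: given the gradient G with
// respect to wsoft, accumulate gradients for the parent matrix W and the
// weights y.  The parity draws are constants of the graph.
// [[Rcpp::export]]
List cpp_soft_progeny_backward(NumericMatrix G, NumericMatrix W,
                               NumericMatrix y,
                               IntegerMatrix Hm, IntegerMatrix Hp,
                               NumericMatrix gamM, NumericMatrix gamP,
                               IntegerVector kM, IntegerVector kP) {
  int N = y.nrow(), P = y.ncol();
  int m = Hm.ncol();
  int n = W.nrow();
  size_t NP = (size_t)N * P;
  NumericMatrix dW(n, 2 * m);
  NumericMatrix dy(N, P);
  double *pdW = REAL(dW), *pdy = REAL(dy);
  const double *pG = REAL(G), *py = REAL(y);
  const double *pgm = REAL(gamM), *pgp = REAL(gamP);
  const int *phm = INTEGER(Hm), *php = INTEGER(Hp);
  for (int k = 0; k < P; ++k) {
    int pM = kM[k], pP = kP[k];
    const double *yk = py + (size_t)N * k;
    double *dyk = pdy + (size_t)N * k;
    for (int j = 0; j < m; ++j) {
      const double *g1c = pG + (size_t)N * j;
      const double *g2c = pG + (size_t)N * (j + m);
      const double *gm = pgm + NP * j + (size_t)N * k;
      const double *gp = pgp + NP * j + (size_t)N * k;
      const int *hm = phm + NP * j + (size_t)N * k;
      const int *hp = php + NP * j + (size_t)N * k;
      double dWM0 = 0, dWM1 = 0, dWP0 = 0, dWP1 = 0;
      for (int i = 0; i < N; ++i) {
        double g1 = g1c[i], g2 = g2c[i];
        double yy = yk[i];
        dyk[i] += g1 * gm[i] + g2 * gp[i];
        if (hm[i]) dWM1 += g1 * yy; else dWM0 += g1 * yy;
        if (hp[i]) dWP1 += g2 * yy; else dWP0 += g2 * yy;
      }
      pdW[pM + (size_t)n * j] += dWM0;
      pdW[pM + (size_t)n * (j + m)] += dWM1;
      pdW[pP + (size_t)n * j] += dWP0;
      pdW[pP + (size_t)n * (j + m)] += dWP1;
    }
  }
  return List::create(_["dW"] = dW, _["dy"] = dy);
}
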