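#include <Rcpp.h>
using namespace Rcpp;

// Moment-matched beta draw; falls back to the mean when the SD is
// degenerate or infeasible for a beta distribution.
static double rbeta_moment(double mean, double sd) {
  if (mean <= 0.0 || mean >= 1.0 || sd <= 0.0) return mean;
  double v = sd * sd;
  double f = mean * (1.0 - mean) / v - 1.0;
  if (f <= 0.0) return mean;
  return R::rbeta(mean * f, (1.0 - mean) * f);
}

// Floor + Bernoulli on the fractional part (expectation-preserving).
static double stoch_round(double x) {
  double f = std::floor(x);
  return f + ((R::unif_rand() < (x - f)) ? 1.0 : 0.0);
}

// Neighbour order: NW, N, NE, W, E, SW, S, SE (row 1 = northernmost band,
// so "north" is row - 1).
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// [[Rcpp::export]]
NumericMatrix cppNeighbourExchange(NumericMatrix N, NumericMatrix K,
                                   NumericMatrix rugFactor,
                                   double pMig, double cvMig,
                                   double fissionLo, double fissionHi,
                                   double emigCoef) {
  int nr = N.nrow(), nc = N.ncol();
  NumericMatrix out = clone(N);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double n = out(i, j);
      if (n <= 0.0) continue;
      double kf = K(i, j);
      // fission ("budding-off") trigger: one draw per focal cell
      double thr = R::runif(fissionLo, fissionHi);
      double ratio = (kf > 0.0) ? n / kf : R_PosInf;
      if (ratio <= thr) continue;
      for (int d = 0; d < 8; ++d) {
        int ti = i + DR[d], tj = j + DC[d];
        if (ti < 0 || ti >= nr || tj < 0 || tj >= nc) continue;
        double kn = K(ti, tj);
        if (kn <= 0.0) continue; // sea or zero-capacity neighbour
        double krel = (kf > 0.0) ? kf / kn : 0.0;
        if (krel >= 1.0) continue;
        if (R::unif_rand() >= std::exp(-emigCoef * krel)) continue;
        double nrem = out(i, j);
        if (nrem < 1.0) break;
        double prop = rbeta_moment(pMig, cvMig * pMig);
        double mig = stoch_round(prop * nrem * rugFactor(i, j));
        if (mig <= 0.0) continue;
        if (mig > nrem) mig = std::floor(nrem);
        out(i, j) -= mig;
        out(ti, tj) += mig;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cppLongDistanceDispersal(NumericMatrix N, NumericMatrix K,
                                       NumericMatrix landMask,
                                       NumericMatrix distWater,
                                       NumericMatrix nppRel,
                                       NumericMatrix rugFactor,
                                       double pMig, double cvMig,
                                       double fissionLo, double fissionHi,
                                       double dMaxKm, double cellWidthKm,
                                       double dCellMax, double prodScale,
                                       double omega, bool waterLiteral) {
  int nr = N.nrow(), nc = N.ncol();
  NumericMatrix out = clone(N);
  double capKm = dCellMax * cellWidthKm;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double n = out(i, j);
      if (n < 1.0) continue;
      double kf = K(i, j);
      double thr = R::runif(fissionLo, fissionHi);
      double ratio = (kf > 0.0) ? n / kf : R_PosInf;
      if (ratio <= thr) continue;
      // productivity-inflated exponential dispersal scale, capped last
      double rel = nppRel(i, j);
      if (rel <= 0.0) rel = 1e-3;
      if (rel > 1.0) rel = 1.0;
      double scale = dMaxKm * std::pow(prodScale, -std::log10(rel));
      if (scale > capKm) scale = capKm;
      double dKm = R::exp_rand() * scale;
      double dCells = dKm / cellWidthKm;
      int dx = (int) R::rpois(dCells);
      int dy = (int) R::rpois(dCells);
      if (dx == 0 && dy == 0) continue;
      if (R::unif_rand() < 0.5) dx = -dx;
      if (R::unif_rand() < 0.5) dy = -dy;
      int ti = i + dy, tj = j + dx;
      if (ti < 0 || ti >= nr || tj < 0 || tj >= nc) continue;
      if (landMask(ti, tj) <= 0.0) continue;
      double dl = std::sqrt((double) dx * dx + (double) dy * dy);
      double dh2o = distWater(ti, tj);
      double pl;
      if (waterLiteral) {
        pl = (dh2o > 0.0) ? 1.0 - std::pow(dl / dh2o, omega) : 0.0;
      } else {
        pl = 1.0 - std::pow(dh2o / dl, omega);
      }
      if (pl < 0.0) pl = 0.0;
      if (pl > 1.0) pl = 1.0;
      if (R::unif_rand() >= pl) continue;
      double nrem = out(i, j);
      double prop = rbeta_moment(pMig, cvMig * pMig);
      double mig = stoch_round(prop * nrem * rugFactor(i, j));
      if (mig <= 0.0) continue;
      if (mig > nrem) mig = std::floor(nrem);
      out(i, j) -= mig;
      out(ti, tj) += mig;
    }
  }
  return out;
}

// Euclidean distance (cell units) from every cell to the nearest wet cell.
// Grids are small (order 10^4 cells), so the direct scan over wet cells is
// adequate.
// [[Rcpp::export]]
NumericMatrix cppDistanceToWater(int nr, int nc,
                                 IntegerVector wetRow, IntegerVector wetCol) {
  NumericMatrix out(nr, nc);
  int nw = wetRow.size();
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double best = R_PosInf;
      for (int w = 0; w < nw; ++w) {
        double dr = (double) (wetRow[w] - 1 - i);
        double dc = (double) (wetCol[w] - 1 - j);
        double d2 = dr * dr + dc * dc;
        if (d2 < best) best = d2;
      }
      out(i, j) = std::sqrt(best);
    }
  }
  return out;
}
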