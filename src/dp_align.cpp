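#include <Rcpp.h>
using namespace Rcpp;

// Local DP over label indices with an in-recurrence X-drop.
//   S(i,j) = max(0, max_{1<=a,b<=lookback} S(i-a,j-b) + match_bonus
//                   - sizing_penalty - (b-1)*miss_penalty - (a-1)*false_penalty)
// subject to: extending a chain is forbidden when the chain's running
// maximum would exceed the new score by more than max_drop. M(i,j) tracks
// the running maximum along the chosen chain, so every S value is the score
// of one contiguous local alignment segment — a chain cannot sag through an
// extended discordant region and resume on the other side.
//
// gcum[j] is the cumulative declared HIC gap length up to reference label j;
// a reference interval containing declared gap bases gets sizing slack: the
// gap is treated as a free non-negative length, so only a deficit of query
// length relative to the non-gap part of the interval is penalised.
// [[Rcpp::export]]
List dp_fill_cpp(NumericVector q, NumericVector r, NumericVector gcum,
                 double sigma, double match_bonus, double miss_penalty,
                 double false_penalty, int lookback, double max_drop,
                 double penalty_weight, double gap_prior) {
  int nq = q.size(), nr = r.size();
  NumericMatrix S(nq, nr), M(nq, nr);
  IntegerMatrix Pa(nq, nr), Pb(nq, nr);  // traceback step sizes; 0 = chain start
  for (int i = 0; i < nq; i++) {
    for (int j = 0; j < nr; j++) {
      double best = 0, bestM = 0; int ba = 0, bb = 0;
      for (int a = 1; a <= lookback && i - a >= 0; a++) {
        double qlen = q[i] - q[i - a];
        for (int b = 1; b <= lookback && j - b >= 0; b++) {
          double rlen = r[j] - r[j - b];
          double slack = gcum[j] - gcum[j - b];
          double pen;
          if (slack > 0 && qlen >= rlen - slack) {
            // the declared gap is a free non-negative length, but a mild
            // linear prior (per kb of implied gap) makes the DP prefer the
            // smallest crossing consistent with the labels
            pen = gap_prior * (qlen - (rlen - slack)) / 1000.0;
          } else {
            double rr = (slack > 0) ? (rlen - slack) : rlen;
            double diff = qlen - rr;
            if (sigma <= 0) {
              pen = (diff == 0) ? 0.0 : R_PosInf;
            } else {
              double denom = sigma * sigma * std::max(rr, 1000.0) / 1000.0;
              pen = penalty_weight * diff * diff / denom;
            }
          }
          double cand = S(i - a, j - b) + match_bonus - pen
            - (b - 1) * miss_penalty - (a - 1) * false_penalty;
          if (cand > best && M(i - a, j - b) - cand <= max_drop) {
            best = cand;
            bestM = std::max(M(i - a, j - b), cand);
            ba = a; bb = b;
          }
        }
      }
      S(i, j) = best; M(i, j) = bestM; Pa(i, j) = ba; Pb(i, j) = bb;
    }
  }
  return List::create(_["S"] = S, _["Pa"] = Pa, _["Pb"] = Pb);
}
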