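#include <Rcpp.h>
using namespace Rcpp;

// Sequential Elo replay. winner/loser are 0-based indices into entry.
// Returns per-event post-update scores of both contestants, the winner's
// expected-win probability, and the accumulated negative log-likelihood.
// [[Rcpp::export]]
List elo_replay_cpp(IntegerVector winner, IntegerVector loser,
                    NumericVector entry, double k, double scale) {
  int n = winner.size();
  NumericVector scores = clone(entry);
  NumericVector w_post(n), l_post(n), e_win(n);
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    int w = winner[t], l = loser[t];
    double e = 1.0 / (1.0 + std::pow(10.0, (scores[l] - scores[w]) / scale));
    double delta = k * (1.0 - e);
    scores[w] += delta;
    scores[l] -= delta;
    w_post[t] = scores[w];
    l_post[t] = scores[l];
    e_win[t] = e;
    nll -= std::log(e);
  }
  return List::create(_["winner_post"] = w_post, _["loser_post"] = l_post,
                      _["e_winner"] = e_win, _["final_scores"] = scores,
                      _["nll"] = nll);
}

// Likelihood only (hot path for ML fitting).
// [[Rcpp::export]]
double elo_nll_cpp(IntegerVector winner, IntegerVector loser,
                   NumericVector entry, double k, double scale) {
  int n = winner.size();
  std::vector<double> scores(entry.begin(), entry.end());
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    int w = winner[t], l = loser[t];
    double e = 1.0 / (1.0 + std::pow(10.0, (scores[l] - scores[w]) / scale));
    double delta = k * (1.0 - e);
    scores[w] += delta;
    scores[l] -= delta;
    nll -= std::log(e);
  }
  return nll;
}

// Generate a pant-grunt stream from an Elo process: at each event a random
// pair meets and the outcome is drawn from the current-score expectation.
// Used by the synthetic-data module; uses R's RNG so seeds propagate.
// [[Rcpp::export]]
List elo_stream_cpp(int n_events, NumericVector entry, double k, double scale) {
  int m = entry.size();
  NumericVector scores = clone(entry);
  IntegerVector winner(n_events), loser(n_events);
  for (int t = 0; t < n_events; ++t) {
    int i = (int)std::floor(R::runif(0.0, 1.0) * m);
    int j = (int)std::floor(R::runif(0.0, 1.0) * (m - 1));
    if (j >= i) j += 1;
    double e_i = 1.0 / (1.0 + std::pow(10.0, (scores[j] - scores[i]) / scale));
    int w, l;
    if (R::runif(0.0, 1.0) < e_i) { w = i; l = j; } else { w = j; l = i; }
    double e_w = 1.0 / (1.0 + std::pow(10.0, (scores[l] - scores[w]) / scale));
    double delta = k * (1.0 - e_w);
    scores[w] += delta;
    scores[l] -= delta;
    winner[t] = w + 1;
    loser[t] = l + 1;
  }
  return List::create(_["winner"] = winner, _["loser"] = loser,
                      _["final_scores"] = scores);
}
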