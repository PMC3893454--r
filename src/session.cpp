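#include <Rcpp.h>
using namespace Rcpp;

// Trial loop of the two-step task: hybrid agent (SARSA(lambda) model-free
// values + one-step Bellman model-based values over the true transition
// matrix, softmax-mixed by w, with a perseveration bonus) interacting with
// a reward-probability walk. Draws four uniforms per trial (stage-1 choice,
// transition, stage-2 choice, reward) from R's RNG stream, in that order,
// so results are reproducible via set.seed() and replayable from R.

// [[Rcpp::export(name = ".sim_session_cpp")]]
List sim_session_cpp(NumericMatrix walk, int n_trials, double p_common,
                     double alpha1, double alpha2, double lam,
                     double beta1, double beta2, double w, double rho) {
  IntegerVector choice1(n_trials), common(n_trials), state2(n_trials),
      choice2(n_trials), reward(n_trials);
  double q1[2] = {0.0, 0.0};
  double q2[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
  int prev_choice = -1;

  for (int t = 0; t < n_trials; t++) {
    double m0 = q2[0][0] > q2[0][1] ? q2[0][0] : q2[0][1];
    double m1 = q2[1][0] > q2[1][1] ? q2[1][0] : q2[1][1];
    double qmb0 = p_common * m0 + (1.0 - p_common) * m1;
    double qmb1 = p_common * m1 + (1.0 - p_common) * m0;
    double qn0 = w * qmb0 + (1.0 - w) * q1[0];
    double qn1 = w * qmb1 + (1.0 - w) * q1[1];
    if (prev_choice == 0) qn0 += rho;
    if (prev_choice == 1) qn1 += rho;
    double p1 = 1.0 / (1.0 + exp(beta1 * (qn1 - qn0)));
    int c1 = R::runif(0.0, 1.0) < p1 ? 0 : 1;

    int com = R::runif(0.0, 1.0) < p_common ? 1 : 0;
    int s2 = com ? c1 : 1 - c1;

    double p2 = 1.0 / (1.0 + exp(beta2 * (q2[s2][1] - q2[s2][0])));
    int c2 = R::runif(0.0, 1.0) < p2 ? 0 : 1;

    int r = R::runif(0.0, 1.0) < walk(t, 2 * s2 + c2) ? 1 : 0;

    double d1 = q2[s2][c2] - q1[c1];
    q1[c1] += alpha1 * d1;
    double d2 = r - q2[s2][c2];
    q2[s2][c2] += alpha2 * d2;
    q1[c1] += alpha1 * lam * d2;

    prev_choice = c1;
    choice1[t] = c1;
    common[t] = com;
    state2[t] = s2;
    choice2[t] = c2;
    reward[t] = r;
  }
  return List::create(_["choice1"] = choice1, _["common"] = common,
                      _["state2"] = state2, _["choice2"] = choice2,
                      _["reward"] = reward);
}
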