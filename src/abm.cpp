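#include <Rcpp.h>
using namespace Rcpp;

// Proportional-imitation chain for the two-population game.
//
// State: k1 of N1 population-1 agents show behavior 1, k2 of N2 population-2
// agents show behavior 2. One elementary step: choose a population with
// probability proportional to its size, draw a focal and a model agent
// uniformly without replacement, and let the focal adopt the model's behavior
// with probability max(0, dE) / dmax, where dE is the model-minus-focal
// expected-payoff difference at the current state (equal to +/- the growth
// bracket of that population) and dmax is the maximal payoff difference over
// the parameter set. Only same-population imitation occurs. One generation =
// N1 + N2 elementary steps. Uses R's RNG, so runs are reproducible under
// set.seed().
//
// coef: a1, u1, v1, a2, u2, v2 of the affine brackets G = a + u p + v q.
// [[Rcpp::export]]
NumericMatrix abm_run_cpp(int N1, int N2, int k1, int k2,
                          NumericVector coef, double dmax,
                          int n_generations, int record_every,
                          double mutation) {
  const double a1 = coef[0], u1 = coef[1], v1 = coef[2];
  const double a2 = coef[3], u2 = coef[4], v2 = coef[5];
  const int steps_per_gen = N1 + N2;
  const double prob1 = (double)N1 / (N1 + N2);
  const int n_rec = n_generations / record_every + 1;
  NumericMatrix out(n_rec, 3);
  int rec = 0;
  out(rec, 0) = 0.0;
  out(rec, 1) = (double)k1 / N1;
  out(rec, 2) = (double)k2 / N2;
  rec++;

  for (int gen = 1; gen <= n_generations; gen++) {
    for (int s = 0; s < steps_per_gen; s++) {
      const double p = (double)k1 / N1;
      const double q = (double)k2 / N2;
      const bool pop1 = unif_rand() < prob1;
      const int N = pop1 ? N1 : N2;
      const int k = pop1 ? k1 : k2;
      // focal behavior: cooperative (preferred) with prob k/N
      const bool focal_coop = unif_rand() < (double)k / N;
      if (mutation > 0.0 && unif_rand() < mutation) {
        const bool new_coop = unif_rand() < 0.5;
        if (new_coop != focal_coop) {
          const int d = new_coop ? 1 : -1;
          if (pop1) k1 += d; else k2 += d;
        }
        continue;
      }
      // model drawn without replacement from the same population
      const int k_rest = k - (focal_coop ? 1 : 0);
      const bool model_coop = unif_rand() < (double)k_rest / (N - 1);
      if (model_coop == focal_coop) continue;
      if (dmax <= 0.0) continue;  // degenerate game: no imitation pressure
      const double G = pop1 ? (a1 + u1 * p + v1 * q)
                            : (a2 + u2 * p + v2 * q);
      const double dE = model_coop ? G : -G;
      if (dE <= 0.0) continue;
      if (unif_rand() < dE / dmax) {
        const int d = model_coop ? 1 : -1;
        if (pop1) k1 += d; else k2 += d;
      }
    }
    if (gen % record_every == 0) {
      out(rec, 0) = gen;
      out(rec, 1) = (double)k1 / N1;
      out(rec, 2) = (double)k2 / N2;
      rec++;
    }
  }
  return out;
}
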