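// Exact Gillespie simulation of the effector/tumor reaction systems.
//
// Species order: E, T, C, Ed (exhausted effectors), Td (lysed tumor cells).
// Ed/Td are cumulative counters; they never enter a propensity.
//
// model = 1 (conjugate), rates = (s, r, d, gamma, alpha1, alpha2):
//   0: E -> 0          d*E
//   1: T -> T + E      s*T
//   2: T -> 2T         r*T
//   3: E + T -> C      gamma*E*T/v
//   4: C -> Td + E     alpha1*C   (tumor lysed, effector returned)
//   5: C -> T + Ed     alpha2*C   (tumor survives, effector exhausted)
//   6: mutation        mu*T       (terminates the run: escape;
//                                  mutation_mode = 0 only)
// model = 2 (reduced), rates = (s, r, d, beta1, beta2):
//   0: E -> 0          d*E
//   1: T -> T + E      s*T
//   2: T -> 2T         r*T
//   3: E + T -> Td + E beta1*E*T/v
//   4: E + T -> T + Ed beta2*E*T/v
//   5: mutation        mu*T
//
// mutation_mode: 0 = escape propensity mu*T (a per-cell-per-day channel);
//                1 = each tumor division yields an escaping mutant with
//                    probability mu (mutations arise at DNA replication).
// Uses R's RNG (unif_rand) so set.seed() in R controls every draw.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// outcome codes
static const int EXTINCT = 0, ESCAPED = 1, CENSORED = 2;

// record modes
static const int REC_NONE = 0, REC_FULL = 1, REC_THIN = 2;

// [[Rcpp::export(name = ".ssa_run")]]
List ssa_run(int model, NumericVector rates, NumericVector init,
             double t_max, double mu, double v, int mutation_mode,
             int record_mode, double record_dt, double max_events) {
  double E = init[0], T = init[1], C = (init.size() > 2) ? init[2] : 0.0;
  double Ed = 0.0, Td = 0.0;
  const bool conj = (model == 1);
  const double s = rates[0], r = rates[1], d = rates[2];
  double gamma = 0, a1 = 0, a2 = 0, b1 = 0, b2 = 0;
  if (conj) { gamma = rates[3]; a1 = rates[4]; a2 = rates[5]; }
  else      { b1 = rates[3]; b2 = rates[4]; }

  std::vector<double> log_rows;   // time, reaction, E, T, C, Ed, Td
  double next_rec = 0.0;
  auto record = [&](double t, int rxn) {
    log_rows.push_back(t);
    log_rows.push_back((double)rxn);
    log_rows.push_back(E); log_rows.push_back(T); log_rows.push_back(C);
    log_rows.push_back(Ed); log_rows.push_back(Td);
  };
  if (record_mode != REC_NONE) record(0.0, -1);
  if (record_mode == REC_THIN) next_rec = record_dt;

  double t = 0.0;
  double n_events = 0.0;
  unsigned long ticker = 0;
  int outcome = CENSORED;
  double end_time = t_max;

  bool extinct_now = (T == 0.0) && (!conj || C == 0.0);
  if (extinct_now) {
    outcome = EXTINCT;
    end_time = 0.0;
  } else {
    double prop[7];
    int n_rxn = conj ? 7 : 6;
    while (true) {
      prop[0] = d * E;
      prop[1] = s * T;
      prop[2] = r * T;
      double mu_prop = (mutation_mode == 0) ? mu * T : 0.0;
      if (conj) {
        prop[3] = gamma * E * T / v;
        prop[4] = a1 * C;
        prop[5] = a2 * C;
        prop[6] = mu_prop;
      } else {
        prop[3] = b1 * E * T / v;
        prop[4] = b2 * E * T / v;
        prop[5] = mu_prop;
      }
      double a0 = 0.0;
      for (int i = 0; i < n_rxn; ++i) a0 += prop[i];
      if (a0 <= 0.0) {
        // nothing can happen again; classify by the tumor state now
        bool gone = (T == 0.0) && (!conj || C == 0.0);
        outcome = gone ? EXTINCT : CENSORED;
        end_time = gone ? t : t_max;
        break;
      }
      double tau = -std::log(unif_rand()) / a0;
      if (record_mode == REC_THIN) {
        // grid points before the next event carry the pre-event state
        while (next_rec < t + tau && next_rec <= t_max) {
          record(next_rec, -1);
          next_rec += record_dt;
        }
      }
      if (t + tau > t_max) { outcome = CENSORED; end_time = t_max; break; }
      t += tau;
      double u = unif_rand() * a0;
      int rxn = 0;
      double acc = prop[0];
      while (u > acc && rxn < n_rxn - 1) { ++rxn; acc += prop[rxn]; }
      n_events += 1.0;

      // per-division escape: thin the division channel by the mutation
      // probability; the mutant subclone's own growth is out of scope, so
      // the run ends at the mutation event
      if (mutation_mode == 1 && rxn == 2 && mu > 0.0 && unif_rand() < mu) {
        outcome = ESCAPED; end_time = t;
        if (record_mode == REC_FULL) record(t, n_rxn - 1);
        break;
      }

      if (conj) {
        switch (rxn) {
          case 0: E -= 1; break;
          case 1: E += 1; break;
          case 2: T += 1; break;
          case 3: E -= 1; T -= 1; C += 1; break;
          case 4: C -= 1; E += 1; Td += 1; break;  // lysis
          case 5: C -= 1; T += 1; Ed += 1; break;  // exhaustion
          case 6: outcome = ESCAPED; end_time = t; break;
        }
        if (rxn == 6) { if (record_mode == REC_FULL) record(t, rxn); break; }
      } else {
        switch (rxn) {
          case 0: E -= 1; break;
          case 1: E += 1; break;
          case 2: T += 1; break;
          case 3: T -= 1; Td += 1; break;          // killing
          case 4: E -= 1; Ed += 1; break;          // exhaustion
          case 5: outcome = ESCAPED; end_time = t; break;
        }
        if (rxn == 5) { if (record_mode == REC_FULL) record(t, rxn); break; }
      }

      if (record_mode == REC_FULL) record(t, rxn);

      if (T == 0.0 && (!conj || C == 0.0)) {
        outcome = EXTINCT; end_time = t; break;
      }
      if (n_events >= max_events) { outcome = CENSORED; end_time = t; break; }
      if ((++ticker & 0xFFFFFUL) == 0) checkUserInterrupt();
    }
  }

  NumericMatrix log_mat(0, 7);
  if (!log_rows.empty()) {
    int nrow = (int)(log_rows.size() / 7);
    log_mat = NumericMatrix(nrow, 7);
    for (int i = 0; i < nrow; ++i)
      for (int j = 0; j < 7; ++j)
        log_mat(i, j) = log_rows[(size_t)i * 7 + j];
  }
  colnames(log_mat) = CharacterVector::create("time", "reaction", "E", "T",
                                              "C", "Ed", "Td");

  return List::create(
    _["outcome"] = outcome,
    _["end_time"] = end_time,
    _["final_state"] = NumericVector::create(_["E"] = E, _["T"] = T,
                                             _["C"] = C, _["Ed"] = Ed,
                                             _["Td"] = Td),
    _["n_events"] = n_events,
    _["log"] = log_mat);
}
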