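#include <Rcpp.h>
using namespace Rcpp;

// 1D lattice loop-extrusion engine.
//
// The engine draws all randomness from R's RNG stream (unif_rand), so runs are
// reproducible under set.seed() and can be replayed draw-for-draw by the plain
// R reference interpreter used in the test suite. The draw protocol per 1D
// step is fixed and must not be reordered:
//
//   1. Fisher-Yates shuffle of LE update order: for i = n_les-1 .. 1,
//      j = floor(u * (i+1)), swap(perm[i], perm[j]).   (n_les - 1 draws)
//   2. For each LE in shuffled order:
//      a. left leg moves to left-1 if that site is on-lattice, unoccupied and
//         (in blocking/anchoring modes) not centromeric; else it stays;
//      b. right leg likewise to right+1;
//      c. unless the LE is anchored (anchoring mode with a leg arrested at a
//         centromeric site), draw u; if u < 1/lifetime the LE unbinds and
//         rebinds at a random free adjacent pair: up to max_tries draws of
//         i = floor(u * (n-1)), accepting the first free pair (i, i+1).
//         If no free pair is found the LE re-occupies its previous pair
//         (it waits one step).
//
// Both legs of one LE attempt their move in the same sub-step; a leg blocked
// this step may move the next. Chromosome ends are permanent barriers.

static inline int floor_unif(int k) {
  // uniform integer in [0, k): floor(u * k), clamped against u == 1.0
  int v = (int)(unif_rand() * k);
  if (v >= k) v = k - 1;
  return v;
}

// [[Rcpp::export]]
List cpp_run_extrusion(int n, IntegerVector centromeres, int n_les,
                       double lifetime, int mode, int n_steps,
                       int sample_every, int max_tries) {
  // mode: 0 = none, 1 = blocking, 2 = anchoring
  if (n < 2) stop("chromosome must have at least 2 sites");
  if (n_les < 1) stop("need at least one loop extruder");
  if (2 * n_les > n) stop("2 * n_les must not exceed n_nucleosomes");

  std::vector<bool> centro(n, false);
  for (int i = 0; i < centromeres.size(); ++i) {
    int c = centromeres[i];
    if (c < 0 || c >= n) stop("centromere position out of range");
    centro[c] = true;
  }
  const bool barrier = (mode >= 1);
  const bool anchoring = (mode == 2);
  const double p_unbind = 1.0 / lifetime;

  std::vector<bool> occ(n, false);
  std::vector<int> L(n_les), R(n_les);

  auto pair_free = [&](int i) {
    return !occ[i] && !occ[i + 1] &&
           !(barrier && (centro[i] || centro[i + 1]));
  };

  // initial placement: LEs bind random disjoint adjacent pairs
  for (int k = 0; k < n_les; ++k) {
    bool placed = false;
    for (int t = 0; t < max_tries * 10; ++t) {
      int i = floor_unif(n - 1);
      if (pair_free(i)) {
        L[k] = i; R[k] = i + 1;
        occ[i] = occ[i + 1] = true;
        placed = true;
        break;
      }
    }
    if (!placed) stop("could not place LE %d on a free adjacent pair", k + 1);
  }

  const int n_samples = n_steps / sample_every + 1 +
                        ((n_steps % sample_every) ? 1 : 0);
  IntegerMatrix sampL(n_samples, n_les), sampR(n_samples, n_les);
  IntegerVector samp_step(n_samples);
  int s_i = 0;
  auto record = [&](int step) {
    for (int k = 0; k < n_les; ++k) {
      sampL(s_i, k) = L[k];
      sampR(s_i, k) = R[k];
    }
    samp_step[s_i] = step;
    ++s_i;
  };
  record(0);

  std::vector<int> perm(n_les);
  long n_unbind = 0, n_rebind_fail = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // Fisher-Yates shuffle of the update order
    for (int k = 0; k < n_les; ++k) perm[k] = k;
    for (int i = n_les - 1; i >= 1; --i) {
      int j = floor_unif(i + 1);
      std::swap(perm[i], perm[j]);
    }

    for (int kk = 0; kk < n_les; ++kk) {
      int k = perm[kk];
      // left leg
      int d = L[k] - 1;
      if (d >= 0 && !occ[d] && !(barrier && centro[d])) {
        occ[L[k]] = false; occ[d] = true; L[k] = d;
      }
      // right leg
      d = R[k] + 1;
      if (d < n && !occ[d] && !(barrier && centro[d])) {
        occ[R[k]] = false; occ[d] = true; R[k] = d;
      }
      // unbinding / rebinding
      bool anchored = anchoring &&
        ((L[k] > 0 && centro[L[k] - 1]) ||
         (R[k] < n - 1 && centro[R[k] + 1]));
      if (!anchored && unif_rand() < p_unbind) {
        int oldL = L[k], oldR = R[k];
        occ[oldL] = occ[oldR] = false;
        bool placed = false;
        for (int t = 0; t < max_tries; ++t) {
          int i = floor_unif(n - 1);
          if (pair_free(i)) {
            L[k] = i; R[k] = i + 1;
            occ[i] = occ[i + 1] = true;
            placed = true;
            break;
          }
        }
        if (!placed) { // wait one step at the old pair
          L[k] = oldL; R[k] = oldR;
          occ[oldL] = occ[oldR] = true;
          ++n_rebind_fail;
        } else {
          ++n_unbind;
        }
      }
    }

    if (step % sample_every == 0 || step == n_steps) record(step);
  }

  // trim sample matrices if over-allocated (n_steps a multiple of sample_every)
  if (s_i < n_samples) {
    sampL = sampL(Range(0, s_i - 1), _);
    sampR = sampR(Range(0, s_i - 1), _);
    samp_step = samp_step[Range(0, s_i - 1)];
  }

  LogicalVector anchL(n_les), anchR(n_les);
  for (int k = 0; k < n_les; ++k) {
    anchL[k] = anchoring && L[k] > 0 && centro[L[k] - 1];
    anchR[k] = anchoring && R[k] < n - 1 && centro[R[k] + 1];
  }

  return List::create(
    _["steps"] = samp_step,
    _["left"] = sampL,
    _["right"] = sampR,
    _["final_left"] = IntegerVector(L.begin(), L.end()),
    _["final_right"] = IntegerVector(R.begin(), R.end()),
    _["anchored_left"] = anchL,
    _["anchored_right"] = anchR,
    _["n_unbind"] = (double)n_unbind,
    _["n_rebind_fail"] = (double)n_rebind_fail);
}
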