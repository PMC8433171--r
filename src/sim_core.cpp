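// Compiled inner loop of the water-strider swarm model.
//
// One step executes the fixed phase schedule
//   (1) force evaluation  (2) semi-implicit Euler integration
//   (3) consumption & mass update  (4) cull at critical masses
//   (5) recruitment  (6) food deposition  (7) recording
// and draws all random numbers from R's single RNG stream in a fixed order
// (birth test -> x -> y -> mass, then food test -> x -> y), so a trajectory
// is fully reproducible from (params, seed) despite the variable-length
// arrays. The R-level phase functions implement the same arithmetic and are
// used in the tests to cross-check this engine.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Par {
  double Lx, Ly, dt;
  double Brep0, Rrep0, Batt0, Ratt0;
  double Bbound, Rbound;
  double Bfood0, Rfood, Rthres;
  double alpha, beta, eta0;
  double mu, lam;
  double ms, msSpread, mmin, mmax;
  double pBirth, pFood, qFood;
  double Bwave, Rwave, wavePeriod, waveDuration;
  double mc12, mc23;
  bool waveOn;
};

Par readPar(const List& p) {
  Par q;
  q.Lx = p["Lx"]; q.Ly = p["Ly"]; q.dt = p["dt"];
  q.Brep0 = p["B_repuls0"]; q.Rrep0 = p["R_repuls0"];
  q.Batt0 = p["B_attract0"]; q.Ratt0 = p["R_attract0"];
  q.Bbound = p["B_bound"]; q.Rbound = p["R_bound"];
  q.Bfood0 = p["B_food0"]; q.Rfood = p["R_food"]; q.Rthres = p["R_food_thres"];
  q.alpha = p["alpha_exp"]; q.beta = p["beta_exp"]; q.eta0 = p["eta0"];
  q.mu = p["mu"]; q.lam = p["lam"];
  q.ms = p["m_s"]; q.msSpread = p["m_s_spread"];
  q.mmin = p["m_min"]; q.mmax = p["m_max"];
  q.pBirth = p["p_birth"]; q.pFood = p["p_food"]; q.qFood = p["q_food"];
  q.Bwave = p["B_wave"]; q.Rwave = p["R_wave"];
  q.wavePeriod = p["wave_period"]; q.waveDuration = p["wave_duration"];
  q.mc12 = p["m_class12"]; q.mc23 = p["m_class23"];
  q.waveOn = q.Bwave > 0 && q.wavePeriod > 0 && q.waveDuration > 0;
  return q;
}

struct Animals {
  std::vector<double> id, x, y, vx, vy, m, tb;
  size_t size() const { return id.size(); }
  void erase(size_t j) {
    id.erase(id.begin() + j); x.erase(x.begin() + j); y.erase(y.begin() + j);
    vx.erase(vx.begin() + j); vy.erase(vy.begin() + j);
    m.erase(m.begin() + j); tb.erase(tb.begin() + j);
  }
};

struct Food {
  std::vector<double> id, x, y, rem;
  size_t size() const { return id.size(); }
  void erase(size_t n) {
    id.erase(id.begin() + n); x.erase(x.begin() + n);
    y.erase(y.begin() + n); rem.erase(rem.begin() + n);
  }
};

}  // namespace

// [[Rcpp::export(name = ".simCore")]]
List simCore(List parList, NumericMatrix animals0, NumericMatrix food0,
             double t0, double born0, double diedMin0, double diedMax0,
             double nextAid0, double nextFid0,
             double deposited0, double intake0,
             int nSteps, int recordEvery, bool recordInitial) {
  const Par P = readPar(parList);
  const double dt = P.dt;

  Animals A;
  for (int i = 0; i < animals0.nrow(); ++i) {
    A.id.push_back(animals0(i, 0)); A.x.push_back(animals0(i, 1));
    A.y.push_back(animals0(i, 2)); A.vx.push_back(animals0(i, 3));
    A.vy.push_back(animals0(i, 4)); A.m.push_back(animals0(i, 5));
    A.tb.push_back(animals0(i, 6));
  }
  Food F;
  for (int i = 0; i < food0.nrow(); ++i) {
    F.id.push_back(food0(i, 0)); F.x.push_back(food0(i, 1));
    F.y.push_back(food0(i, 2)); F.rem.push_back(food0(i, 3));
  }

  double t = t0, born = born0, diedMin = diedMin0, diedMax = diedMax0;
  double nextAid = nextAid0, nextFid = nextFid0;
  double deposited = deposited0, intake = intake0;

  // recording buffers
  std::vector<double> sStep, sT, sId, sX, sY, sVx, sVy, sM, sTb;
  std::vector<double> fStep, fT, fId, fX, fY, fRem;
  std::vector<double> cStep, cT, cN, cN1, cN2, cN3, cBorn, cDmin, cDmax,
      cNfood, cFmass;
  std::vector<double> eT, eId, eX, eY;
  std::vector<int> eKind;  // 0 deposit, 1 exhaust

  auto record = [&](int stepIdx) {
    const size_t N = A.size();
    double n1 = 0, n2 = 0, n3 = 0;
    for (size_t j = 0; j < N; ++j) {
      sStep.push_back(stepIdx); sT.push_back(t);
      sId.push_back(A.id[j]); sX.push_back(A.x[j]); sY.push_back(A.y[j]);
      sVx.push_back(A.vx[j]); sVy.push_back(A.vy[j]);
      sM.push_back(A.m[j]); sTb.push_back(A.tb[j]);
      if (A.m[j] < P.mc12) ++n1;
      else if (A.m[j] < P.mc23) ++n2;
      else ++n3;
    }
    double fmass = 0;
    for (size_t n = 0; n < F.size(); ++n) {
      fStep.push_back(stepIdx); fT.push_back(t);
      fId.push_back(F.id[n]); fX.push_back(F.x[n]); fY.push_back(F.y[n]);
      fRem.push_back(F.rem[n]);
      if (std::isfinite(F.rem[n])) fmass += F.rem[n];
    }
    cStep.push_back(stepIdx); cT.push_back(t);
    cN.push_back((double)N); cN1.push_back(n1); cN2.push_back(n2);
    cN3.push_back(n3); cBorn.push_back(born); cDmin.push_back(diedMin);
    cDmax.push_back(diedMax); cNfood.push_back((double)F.size());
    cFmass.push_back(fmass);
  };

  if (recordInitial) record(0);

  std::vector<double> fx, fy, m13, m23, demand;
  std::vector<int> target;

  for (int s = 1; s <= nSteps; ++s) {
    const size_t N = A.size();

    // (1) forces
    fx.assign(N, 0.0); fy.assign(N, 0.0);
    m13.resize(N); m23.resize(N);
    for (size_t j = 0; j < N; ++j) {
      m13[j] = std::cbrt(A.m[j]);
      m23[j] = m13[j] * m13[j];
    }
    // Pair forces: shared Gaussian kernels with pair-symmetric radii
    // (mean m^(1/3) scales); the amplitude of the force ON an animal uses
    // that animal's own strength m^(2/3) -- each animal responds with its
    // own force, so bigger animals react more strongly to the same signal.
    for (size_t j = 0; j + 1 < N; ++j) {
      for (size_t k = j + 1; k < N; ++k) {
        const double dx = A.x[j] - A.x[k], dy = A.y[j] - A.y[k];
        const double d2 = dx * dx + dy * dy;
        const double s13 = 0.5 * (m13[j] + m13[k]);
        const double Ra = P.Ratt0 * s13;
        if (d2 > 36.0 * Ra * Ra) continue;  // both kernels < 1e-15 of peak
        const double Rr = P.Rrep0 * s13;
        const double ga = std::exp(-d2 / (Ra * Ra));
        double kern = -P.Batt0 * ga;
        if (d2 <= 36.0 * Rr * Rr)
          kern += P.Brep0 * std::exp(-d2 / (Rr * Rr));
        fx[j] += m23[j] * kern * dx; fy[j] += m23[j] * kern * dy;
        fx[k] -= m23[k] * kern * dx; fy[k] -= m23[k] * kern * dy;
      }
    }
    // phase of the periodic wave schedule (t mod period, t >= 0)
    const double phase =
        P.waveOn ? t - std::floor(t / P.wavePeriod) * P.wavePeriod : 0.0;
    const bool waveActive = P.waveOn && phase < P.waveDuration;
    for (size_t j = 0; j < N; ++j) {
      fx[j] += P.Bbound * std::exp(-A.x[j] / P.Rbound) -
               P.Bbound * std::exp(-(P.Lx - A.x[j]) / P.Rbound);
      fy[j] += P.Bbound * std::exp(-A.y[j] / P.Rbound) -
               P.Bbound * std::exp(-(P.Ly - A.y[j]) / P.Rbound);
      const double Bf = P.Bfood0 * std::pow(A.m[j], P.alpha);
      for (size_t n = 0; n < F.size(); ++n) {
        const double dx = A.x[j] - F.x[n], dy = A.y[j] - F.y[n];
        const double d2 = dx * dx + dy * dy;
        if (d2 > 36.0 * P.Rfood * P.Rfood) continue;
        const double g = std::exp(-d2 / (P.Rfood * P.Rfood));
        fx[j] -= Bf * dx * g; fy[j] -= Bf * dy * g;
      }
      if (waveActive)
        fx[j] += P.Bwave * std::pow(A.m[j], P.alpha) *
                 std::exp(-A.x[j] / P.Rwave);
    }

    // (2) semi-implicit Euler: v <- (v + dt F/m) / (1 + dt eta/m), r <- r + dt v
    for (size_t j = 0; j < N; ++j) {
      const double eta = P.eta0 * std::pow(A.m[j], P.beta);
      const double den = 1.0 + dt * eta / A.m[j];
      A.vx[j] = (A.vx[j] + dt * fx[j] / A.m[j]) / den;
      A.vy[j] = (A.vy[j] + dt * fy[j] / A.m[j]) / den;
      A.x[j] += dt * A.vx[j];
      A.y[j] += dt * A.vy[j];
      if (!std::isfinite(A.x[j]) || !std::isfinite(A.y[j]) ||
          !std::isfinite(A.vx[j]) || !std::isfinite(A.vy[j]))
        stop("non-finite position/velocity for animal id %d at t = %g "
             "(integration phase)", (int)A.id[j], t);
    }

    // (3) consumption & mass update
    if (N > 0) {
      target.assign(N, -1);
      demand.assign(N, 0.0);
      const double gate2 = P.Rthres * P.Rthres;
      std::vector<double> totDem(F.size(), 0.0);
      for (size_t j = 0; j < N; ++j) {
        double best = gate2;
        for (size_t n = 0; n < F.size(); ++n) {
          const double dx = A.x[j] - F.x[n], dy = A.y[j] - F.y[n];
          const double d2 = dx * dx + dy * dy;
          if (d2 < best) { best = d2; target[j] = (int)n; }
          // ties keep the earlier (lowest-id) portion: strict <
        }
        if (target[j] >= 0) {
          demand[j] = P.mu * A.m[j] * dt;
          totDem[target[j]] += demand[j];
        }
      }
      std::vector<double> factor(F.size(), 1.0);
      for (size_t n = 0; n < F.size(); ++n) {
        if (totDem[n] <= 0) continue;
        if (totDem[n] <= F.rem[n]) {
          F.rem[n] -= totDem[n];
        } else {
          factor[n] = F.rem[n] / totDem[n];
          F.rem[n] = 0.0;
        }
      }
      for (size_t j = 0; j < N; ++j) {
        if (target[j] >= 0) {
          const double got = demand[j] * factor[target[j]];
          A.m[j] += got;
          intake += got;
        }
        A.m[j] *= (1.0 - P.lam * dt);
      }
      for (size_t n = F.size(); n-- > 0;) {
        if (F.rem[n] <= 0.0) {
          eT.push_back(t); eKind.push_back(1);
          eId.push_back(F.id[n]); eX.push_back(F.x[n]); eY.push_back(F.y[n]);
          F.erase(n);
        }
      }
    }

    // (4) cull at critical masses (inclusive comparisons)
    for (size_t j = A.size(); j-- > 0;) {
      if (A.m[j] >= P.mmax) { ++diedMax; A.erase(j); }
      else if (A.m[j] <= P.mmin) { ++diedMin; A.erase(j); }
    }

    // (5) recruitment: one Bernoulli trial per step
    if (unif_rand() < P.pBirth) {
      A.id.push_back(nextAid); nextAid += 1;
      A.x.push_back(unif_rand() * P.Lx);
      A.y.push_back(unif_rand() * P.Ly);
      A.vx.push_back(0.0); A.vy.push_back(0.0);
      A.m.push_back(P.ms + (2.0 * unif_rand() - 1.0) * P.msSpread);
      A.tb.push_back(t);
      born += 1;
    }

    // (6) food deposition: one Bernoulli trial per step
    if (unif_rand() < P.pFood) {
      F.id.push_back(nextFid); nextFid += 1;
      const double px = unif_rand() * P.Lx, py = unif_rand() * P.Ly;
      F.x.push_back(px); F.y.push_back(py);
      F.rem.push_back(P.qFood);
      if (std::isfinite(P.qFood)) deposited += P.qFood;
      eT.push_back(t + dt); eKind.push_back(0);
      eId.push_back(nextFid - 1); eX.push_back(px); eY.push_back(py);
    }

    // (7) advance time, record (accumulated so that composing single steps
    // reproduces a long run bit-for-bit)
    t += dt;
    if (recordEvery > 0 && s % recordEvery == 0) record(s);
  }

  const size_t N = A.size();
  NumericMatrix animalsOut(N, 7);
  for (size_t j = 0; j < N; ++j) {
    animalsOut(j, 0) = A.id[j]; animalsOut(j, 1) = A.x[j];
    animalsOut(j, 2) = A.y[j]; animalsOut(j, 3) = A.vx[j];
    animalsOut(j, 4) = A.vy[j]; animalsOut(j, 5) = A.m[j];
    animalsOut(j, 6) = A.tb[j];
  }
  NumericMatrix foodOut(F.size(), 4);
  for (size_t n = 0; n < F.size(); ++n) {
    foodOut(n, 0) = F.id[n]; foodOut(n, 1) = F.x[n];
    foodOut(n, 2) = F.y[n]; foodOut(n, 3) = F.rem[n];
  }

  CharacterVector kinds(eKind.size());
  for (size_t i = 0; i < eKind.size(); ++i)
    kinds[i] = eKind[i] == 0 ? "deposit" : "exhaust";

  return List::create(
      _["animals"] = animalsOut, _["food"] = foodOut, _["t"] = t,
      _["nBorn"] = born, _["nDiedMin"] = diedMin, _["nDiedMax"] = diedMax,
      _["nextAnimalId"] = nextAid, _["nextFoodId"] = nextFid,
      _["totalDeposited"] = deposited, _["totalIntake"] = intake,
      _["snapshots"] = DataFrame::create(
          _["step"] = sStep, _["t"] = sT, _["id"] = sId, _["x"] = sX,
          _["y"] = sY, _["vx"] = sVx, _["vy"] = sVy, _["m"] = sM,
          _["t_birth"] = sTb),
      _["foodSnapshots"] = DataFrame::create(
          _["step"] = fStep, _["t"] = fT, _["id"] = fId, _["x"] = fX,
          _["y"] = fY, _["remaining"] = fRem),
      _["counters"] = DataFrame::create(
          _["step"] = cStep, _["t"] = cT, _["N"] = cN, _["N_c1"] = cN1,
          _["N_c2"] = cN2, _["N_c3"] = cN3, _["n_born"] = cBorn,
          _["n_died_min"] = cDmin, _["n_died_max"] = cDmax,
          _["n_food"] = cNfood, _["food_mass"] = cFmass),
      _["foodEvents"] = DataFrame::create(
          _["t"] = eT, _["event"] = kinds, _["id"] = eId, _["x"] = eX,
          _["y"] = eY));
}
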