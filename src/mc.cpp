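// Monte Carlo photon-packet transport in a homogeneous slab.
//
// MCML-style implicit capture: step length sampled from exp(mu_t), a fraction
// mu_a/mu_t of the packet weight deposited at every interaction site,
// Henyey-Greenstein scattering, Fresnel reflection/refraction at the top and
// bottom boundaries, Russian roulette below a weight threshold. Escaping
// weight through the top surface is accumulated into the diffuse reflectance
// and binned by the number of interactions the packet has undergone.
//
// Uses R's RNG (unif_rand) so a set.seed() in the calling R code makes runs
// exactly reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double fresnel_unpolarized(double n1, double n2, double cos_i) {
  // cos_i > 0 is the cosine of the angle of incidence
  if (n1 == n2) return 0.0;
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = n1 / n2 * sin_i;
  if (sin_t >= 1.0) return 1.0; // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export(name = ".mc_run")]]
List mc_run(double mua, double mus, double g,
            double n_inside, double n_outside,
            double thickness_cm, int n_photons,
            double roulette_threshold, int roulette_survival,
            int hist_cap, double max_steps) {
  if (!std::isfinite(mua) || !(std::isfinite(mus)) || mua < 0.0 || mus < 0.0)
    stop("non-finite or negative optical coefficients");
  if (mua + mus <= 0.0) stop("mua + mus must be > 0");
  if (g <= -1.0 || g >= 1.0) stop("g must be in (-1, 1)");

  const double mut = mua + mus;
  const double albedo = mus / mut;
  const bool semi_infinite = !std::isfinite(thickness_cm);
  const double d = thickness_cm;

  // specular reflection of the normally incident beam at the top surface
  double rsp = 0.0;
  if (n_inside != n_outside) {
    double t = (n_outside - n_inside) / (n_outside + n_inside);
    rsp = t * t;
  }

  NumericVector hist(hist_cap + 1); // 1..hist_cap, last entry = overflow
  double w_reflect = 0.0, w_transmit = 0.0, w_absorb = 0.0;
  double roulette_net = 0.0; // killed weight minus injected survivor weight
  double lost = 0.0;         // packets abandoned at the step cap (mua > 0)
  double sum_j = 0.0;        // for mean interactions of escaping-top packets
  double sum_jw = 0.0;

  RNGScope scope;

  for (int ip = 0; ip < n_photons; ++ip) {
    double w = 1.0 - rsp;
    double z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    long j = 0;
    double steps = 0.0;
    bool alive = true;

    while (alive) {
      double s = -std::log(unif_rand()) / mut; // cm
      // propagate, handling (possibly repeated) boundary hits within the step
      while (true) {
        double db = R_PosInf;
        bool top = false;
        if (uz < 0.0) { db = z / (-uz); top = true; }
        else if (uz > 0.0 && !semi_infinite) { db = (d - z) / uz; }
        if (s < db) { z += s * uz; break; }
        // move to the boundary
        z = top ? 0.0 : (semi_infinite ? z + s * uz : d);
        s -= db;
        double cos_i = std::fabs(uz);
        double refl = fresnel_unpolarized(n_inside, n_outside, cos_i);
        if (unif_rand() < refl) {
          uz = -uz; // internal reflection, continue with the remaining step
        } else {
          if (top) {
            w_reflect += w;
            long bin = (j >= 1 && j <= hist_cap) ? (j - 1) : hist_cap;
            if (j >= 1) hist[bin] += w;
            sum_jw += w * (double)j;
            sum_j += w;
          } else {
            w_transmit += w;
          }
          alive = false;
          break;
        }
      }
      if (!alive) break;

      // interaction site
      j += 1;
      steps += 1.0;
      w_absorb += w * (mua / mut);
      w *= albedo;
      if (w <= 0.0) { alive = false; break; }

      // Russian roulette
      if (w < roulette_threshold) {
        if (unif_rand() * roulette_survival < 1.0) {
          roulette_net -= w * (roulette_survival - 1);
          w *= roulette_survival;
        } else {
          roulette_net += w;
          alive = false;
          break;
        }
      }

      // Henyey-Greenstein scatter
      double ct;
      if (g == 0.0) {
        ct = 2.0 * unif_rand() - 1.0;
      } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
        if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
      }
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * unif_rand();
      double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp;
        uy = st * sp;
        uz = (uz >= 0.0) ? ct : -ct;
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nuz = -st * cp * den + uz * ct;
        double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
        ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
      }

      if (steps >= max_steps) {
        // In a conservative (mua == 0) semi-infinite medium every packet
        // escapes through the top with probability 1, so closing the walk
        // analytically is unbiased; the weight goes into the overflow bin.
        if (mua == 0.0 && semi_infinite) {
          w_reflect += w;
          hist[hist_cap] += w;
          sum_jw += w * (double)j;
          sum_j += w;
        } else {
          lost += w;
        }
        alive = false;
      }
    }
  }

  double np = (double)n_photons;
  hist = hist / np;
  double r_total = w_reflect / np;
  return List::create(
    _["r_total"] = r_total,
    _["t_total"] = w_transmit / np,
    _["absorbed"] = w_absorb / np,
    _["specular"] = rsp,
    _["roulette_net"] = roulette_net / np,
    _["lost"] = lost / np,
    _["n_reflect"] = hist,
    _["overflow"] = hist[hist_cap],
    _["mean_interactions"] = sum_j > 0 ? sum_jw / sum_j : NA_REAL,
    _["n_photons"] = n_photons);
}
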