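// Multi-type continuous-time birth-death simulation of clonal tumor
// evolution on a fitness landscape, run until a local-maximum genotype
// reaches fixation. Death rate is common to all clones and density
// dependent, D(N) = log(1 + N/Kc) with Kc = N0/(e - 1), so a wild-type
// population of size N0 starts at its demographic equilibrium.
//
// Two integrators behind one interface: an exact Gillespie algorithm and a
// binomial/Poisson tau-leap (births Poisson, deaths binomial with
// p = 1 - exp(-D tau), at most one new mutation per birth). Genotypes with
// birth rate 0 are never added to the population.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pop {
  // clone state indexed by genotype bitmask (dense; K <= 14)
  std::vector<double> n;
  std::vector<int> alive;        // list of genotypes with n > 0
  std::vector<int> pos;          // position of genotype in `alive`, -1 if dead
  std::vector<int> parent;       // spawning genotype, -1 if never created
  double N;

  explicit Pop(int nG, double N0) :
    n(1 << nG, 0.0), alive(), pos(1 << nG, -1), parent(1 << nG, -1), N(N0) {
    n[0] = N0;
    alive.push_back(0);
    pos[0] = 0;
    parent[0] = 0;
  }

  void add(int g, double k, int par) {
    if (n[g] <= 0.0) {
      parent[g] = par;  // (re-)created: record the living lineage's ancestor
      if (pos[g] < 0) { pos[g] = alive.size(); alive.push_back(g); }
    }
    n[g] += k;
    N += k;
  }

  void remove(int g, double k) {
    n[g] -= k;
    N -= k;
    if (n[g] <= 0.0) {
      n[g] = 0.0;
      int p = pos[g];
      int last = alive.back();
      alive[p] = last; pos[last] = p;
      alive.pop_back();
      pos[g] = -1;
    }
  }

  int top_clone() const {
    int best = alive.empty() ? 0 : alive[0];
    for (int g : alive) if (n[g] > n[best]) best = g;
    return best;
  }
};

struct Snapshots {
  std::vector<double> time, size, top_n;
  std::vector<int> top_geno;
  double last_N = -1.0, last_t = -1e300;

  void maybe_record(double t, const Pop& pop, double dt_max) {
    // >= 1% population change or dt_max elapsed, with a minimum spacing of
    // dt_max/25 so that demographic noise does not flood the record
    if (last_N > 0) {
      if (t - last_t < dt_max / 25.0) return;
      if (std::fabs(pop.N - last_N) < 0.01 * last_N && t - last_t < dt_max)
        return;
    }
    int tg = pop.top_clone();
    time.push_back(t); size.push_back(pop.N);
    top_geno.push_back(tg); top_n.push_back(pop.n[tg]);
    last_N = pop.N; last_t = t;
  }
};

// total mutation rate over genes not yet mutated in g
inline double mu_total(int g, int nG, const double* mu) {
  double s = 0.0;
  for (int j = 0; j < nG; ++j)
    if (!((g >> j) & 1)) s += mu[j];
  return s;
}

inline int draw_gene(int g, int nG, const double* mu, double mtot) {
  double u = unif_rand() * mtot, acc = 0.0;
  for (int j = 0; j < nG; ++j) {
    if ((g >> j) & 1) continue;
    acc += mu[j];
    if (u <= acc) return j;
  }
  for (int j = nG - 1; j >= 0; --j) if (!((g >> j) & 1)) return j;
  return -1;
}

} // namespace

// [[Rcpp::export(name = ".sim_fixation_cpp")]]
List sim_fixation_cpp(int n_genes,
                      NumericVector birth_rate,
                      LogicalVector is_local_max,
                      double N0,
                      double theta,
                      double max_time,
                      NumericVector mu,
                      int method,       // 0 = gillespie, 1 = tau-leap
                      double leap_frac, // per-capita event prob per step
                      double snap_dt) {
  const int nG = n_genes;
  const double Kc = N0 / (std::exp(1.0) - 1.0);
  Pop pop(nG, N0);
  Snapshots snaps;
  double t = 0.0;
  int fixated = -1;
  int check = 0;

  snaps.maybe_record(t, pop, snap_dt);

  while (t < max_time) {
    const double D = std::log1p(pop.N / Kc);

    if (method == 0) {
      // exact Gillespie: one event at a time
      double Rb = 0.0;
      for (int g : pop.alive) Rb += pop.n[g] * birth_rate[g];
      const double Rd = D * pop.N;
      const double R = Rb + Rd;
      if (R <= 0.0) break;  // extinct
      t += R::rexp(1.0) / R;
      double u = unif_rand() * R;
      if (u < Rb) {
        // birth: pick clone proportional to n * b
        double acc = 0.0; int gsel = pop.alive[0];
        for (int g : pop.alive) {
          acc += pop.n[g] * birth_rate[g];
          if (u <= acc) { gsel = g; break; }
        }
        double mtot = mu_total(gsel, nG, &mu[0]);
        if (unif_rand() < mtot) {
          int j = draw_gene(gsel, nG, &mu[0], mtot);
          int child = gsel | (1 << j);
          if (birth_rate[child] > 0.0) pop.add(child, 1.0, gsel);
          // inviable offspring (birth rate 0) are never added
        } else {
          pop.add(gsel, 1.0, gsel);
        }
      } else {
        // death: pick clone proportional to n
        double v = (u - Rb) / D, acc = 0.0; int gsel = pop.alive[0];
        for (int g : pop.alive) {
          acc += pop.n[g];
          if (v <= acc) { gsel = g; break; }
        }
        pop.remove(gsel, 1.0);
      }
      ++check;
      if ((check & 0x3F) == 0) snaps.maybe_record(t, pop, snap_dt);
    } else {
      // tau-leap
      double bmax = 0.0;
      for (int g : pop.alive) if (birth_rate[g] > bmax) bmax = birth_rate[g];
      double tau = leap_frac / (bmax + D);
      const double pdie = -std::expm1(-D * tau);
      // snapshot of the alive list: additions during the loop apply next step
      std::vector<int> cur(pop.alive);
      for (int g : cur) {
        double ng = pop.n[g];
        if (ng <= 0.0) continue;
        double births = R::rpois(ng * birth_rate[g] * tau);
        double deaths = R::rbinom(ng, pdie);
        double mtot = mu_total(g, nG, &mu[0]);
        double mut = (births > 0 && mtot > 0) ? R::rbinom(births, mtot) : 0.0;
        for (int m = 0; m < (int)mut; ++m) {
          int j = draw_gene(g, nG, &mu[0], mtot);
          int child = g | (1 << j);
          if (birth_rate[child] > 0.0) pop.add(child, 1.0, g);
        }
        pop.add(g, births - mut, g);
        pop.remove(g, std::min(deaths, pop.n[g]));
      }
      t += tau;
      if (pop.N <= 0.0) break;  // extinct
      snaps.maybe_record(t, pop, snap_dt);
    }

    // fixation: a local-maximum genotype holds >= theta of the population
    if (method == 1 || (check & 0xFF) == 0) {
      int tg = pop.top_clone();
      if (is_local_max[tg] && pop.n[tg] >= theta * pop.N) {
        fixated = tg;
        break;
      }
    }
  }

  snaps.last_N = -1.0;  // force a final snapshot
  snaps.maybe_record(t, pop, snap_dt);

  std::string status = fixated >= 0 ? "fixated" :
                       (pop.N <= 0.0 ? "extinct" : "timeout");

  return List::create(
    _["status"] = status,
    _["fixated"] = fixated,
    _["final_time"] = t,
    _["parent"] = IntegerVector(pop.parent.begin(), pop.parent.end()),
    _["snap_time"] = NumericVector(snaps.time.begin(), snaps.time.end()),
    _["snap_size"] = NumericVector(snaps.size.begin(), snaps.size.end()),
    _["snap_top"] = IntegerVector(snaps.top_geno.begin(), snaps.top_geno.end()),
    _["snap_top_n"] = NumericVector(snaps.top_n.begin(), snaps.top_n.end()));
}
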