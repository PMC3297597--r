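#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Compiled replicate engine.  The draw protocol (one uniform per initial
// age; per attack: selection, capture, victim; one binomial per season with
// deaths) is identical to the R-level reference path, so a replicate run
// from the same seed is bit-identical in either engine.

namespace {

struct Pars {
  int n_total, max_age, n_attacks, max_seasons;
  double beta, p_capture_f, p_capture_b;
  double fx_f, fx_b;          // reproductive success f(x) per phenotype
  bool freq_dependent, empty_group_renormalize, has_competition, ages_uniform;
  double r_f, r_b, a_ff, a_fb, a_bf, a_bb;
  double init_freq_f;
};

Pars unpack(const List& P) {
  Pars p;
  p.n_total = as<int>(P["n_total"]);
  p.max_age = as<int>(P["max_age"]);
  p.n_attacks = as<int>(P["n_attacks"]);
  p.max_seasons = as<int>(P["max_seasons"]);
  p.beta = as<double>(P["beta"]);
  p.p_capture_f = as<double>(P["p_capture_f"]);
  p.p_capture_b = as<double>(P["p_capture_b"]);
  double sc = as<double>(P["repro_scale"]), ex = as<double>(P["repro_exponent"]);
  p.fx_f = sc * std::pow(as<double>(P["x_f"]), ex);
  p.fx_b = sc * std::pow(as<double>(P["x_b"]), ex);
  p.freq_dependent = as<bool>(P["freq_dependent"]);
  p.empty_group_renormalize = as<bool>(P["empty_group_renormalize"]);
  p.has_competition = as<bool>(P["has_competition"]);
  p.ages_uniform = as<bool>(P["ages_uniform"]);
  p.r_f = as<double>(P["r_f"]);  p.r_b = as<double>(P["r_b"]);
  p.a_ff = as<double>(P["a_ff"]); p.a_fb = as<double>(P["a_fb"]);
  p.a_bf = as<double>(P["a_bf"]); p.a_bb = as<double>(P["a_bb"]);
  p.init_freq_f = as<double>(P["init_freq_f"]);
  return p;
}

struct Pop {
  std::vector<int> cf, cb;
  int nf, nb, kills;
};

void init_pop(const Pars& p, Pop& s) {
  s.cf.assign(p.max_age, 0);
  s.cb.assign(p.max_age, 0);
  s.nf = (int)std::floor(p.init_freq_f * p.n_total + 0.5);
  s.nb = p.n_total - s.nf;
  s.kills = 0;
  if (p.ages_uniform) {
    for (int k = 0; k < s.nf; ++k)
      s.cf[(int)(unif_rand() * p.max_age)]++;
    for (int k = 0; k < s.nb; ++k)
      s.cb[(int)(unif_rand() * p.max_age)]++;
  } else {
    s.cf[0] = s.nf;
    s.cb[0] = s.nb;
  }
}

// Run the attack sequence; returns false if the population emptied.
bool run_attacks(const Pars& p, Pop& s) {
  for (int k = 0; k < p.n_attacks; ++k) {
    if (s.nf + s.nb == 0) return false;
    double psel;
    if (p.freq_dependent) {
      double d = p.beta * s.nf + s.nb;
      psel = (d == 0.0) ? 0.0 : p.beta * s.nf / d;
    } else {
      psel = p.beta / (1.0 + p.beta);
      if (p.empty_group_renormalize) {
        if (s.nf == 0) psel = 0.0;
        if (s.nb == 0) psel = 1.0;
      }
    }
    double u_sel = unif_rand();
    bool isF = u_sel < psel;
    int nsel = isF ? s.nf : s.nb;
    if (nsel == 0) continue;                    // empty group: attack fails
    double pcap = isF ? p.p_capture_f : p.p_capture_b;
    double u_cap = unif_rand();
    if (u_cap >= pcap) continue;                // escape
    int v = (int)(unif_rand() * nsel) + 1;      // victim index, age-blind
    std::vector<int>& c = isF ? s.cf : s.cb;
    int cum = 0;
    for (int idx = 0; idx < p.max_age; ++idx) {
      cum += c[idx];
      if (v <= cum) { c[idx]--; break; }
    }
    if (isF) s.nf--; else s.nb--;
    s.kills++;
  }
  return s.nf + s.nb > 0;
}

// Reproduction, senescence, ageing; returns false on extinction.
bool advance(const Pars& p, Pop& s) {
  int A = p.max_age;
  if (s.nf + s.nb == 0) return false;
  int seniors = s.cf[A - 1] + s.cb[A - 1];
  int D = s.kills + seniors;
  int kf = 0;
  if (D > 0) {
    double phiF = 1.0, phiB = 1.0;
    if (p.has_competition) {
      phiF = std::max(0.0, p.r_f - p.a_ff * s.nf - p.a_fb * s.nb);
      phiB = std::max(0.0, p.r_b - p.a_bf * s.nf - p.a_bb * s.nb);
    }
    double outF = s.nf * p.fx_f * phiF;
    double outB = s.nb * p.fx_b * phiB;
    double den = outF + outB;
    double share = den > 0.0 ? outF / den : (double)s.nf / (s.nf + s.nb);
    double wF = D * share;
    kf = (int)R::rbinom((double)D, wF / D);
  }
  for (int idx = A - 1; idx >= 1; --idx) {
    s.cf[idx] = s.cf[idx - 1];
    s.cb[idx] = s.cb[idx - 1];
  }
  s.cf[0] = kf;
  s.cb[0] = D - kf;
  s.nf = 0; s.nb = 0;
  for (int idx = 0; idx < A; ++idx) { s.nf += s.cf[idx]; s.nb += s.cb[idx]; }
  s.kills = 0;
  return true;
}

}  // namespace

// Outcome codes: 0 F_fixed, 1 B_fixed, 2 timeout, 3 extinct.
// [[Rcpp::export]]
List cpp_run_replicate(List P) {
  Pars p = unpack(P);
  Pop s;
  init_pop(p, s);
  int season = 0, outcome;
  for (;;) {
    if (s.nf + s.nb == 0) { outcome = 3; break; }
    if (s.nb == 0) { outcome = 0; break; }
    if (s.nf == 0) { outcome = 1; break; }
    if (season >= p.max_seasons) { outcome = 2; break; }
    if (!run_attacks(p, s)) { outcome = 3; break; }
    if (!advance(p, s)) { outcome = 3; break; }
    season++;
  }
  return List::create(_["outcome"] = outcome, _["seasons"] = season,
                      _["n_f_final"] = s.nf);
}

// Fixed-length trajectory (no fixation stop); truncates on extinction.
// [[Rcpp::export]]
List cpp_run_trajectory(List P, int n_seasons) {
  Pars p = unpack(P);
  Pop s;
  init_pop(p, s);
  std::vector<int> nf_rec, nb_rec;
  nf_rec.reserve(n_seasons);
  nb_rec.reserve(n_seasons);
  for (int t = 0; t < n_seasons; ++t) {
    if (!run_attacks(p, s)) break;
    if (!advance(p, s)) break;
    nf_rec.push_back(s.nf);
    nb_rec.push_back(s.nb);
  }
  return List::create(_["n_f"] = wrap(nf_rec), _["n_b"] = wrap(nb_rec));
}
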