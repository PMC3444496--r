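// Discrete-event engine: simulates one individual per inner loop from ART
// initiation to death, sampling competing covariate-conditional Weibull
// event times (Barton-style conditional re-sampling at every decision
// point) and accruing discounted costs, life-years and QALYs.
//
// Each individual runs on an independent counter-based RNG substream
// derived from (seed, index), so cohorts are order-independent and arms can
// share random numbers (CRN) by sharing the seed.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {
    // warm-up so nearby seeds decorrelate
    next_u64(); next_u64();
  }
  uint64_t next_u64() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() {
    double u = (next_u64() >> 11) * (1.0 / 9007199254740992.0);
    if (u <= 0.0) u = 1e-300;
    if (u >= 1.0) u = 1.0 - 1e-16;
    return u;
  }
  double unif(double lo, double hi) { return lo + (hi - lo) * unif(); }
  double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  int categ(const std::vector<double>& probs) {
    double u = unif(), c = 0.0;
    for (size_t i = 0; i < probs.size(); ++i) {
      c += probs[i];
      if (u <= c) return (int)i;
    }
    return (int)probs.size() - 1;
  }
  double triangular(double a, double b, double m) {
    double u = unif(), f = (m - a) / (b - a);
    return (u < f) ? a + std::sqrt(u * (b - a) * (m - a))
                   : b - std::sqrt((1.0 - u) * (b - a) * (b - m));
  }
};

const int NCOV = 26;
// covariate indices (keep in sync with art_covariates() on the R side)
enum Cov { FEMALE = 0, AGE, LOG10VL, CD4, HCV, ADH, YEAR, NPIS, RESLEV,
           REGNUM, LINE2, LINE3, PF1, PF2, RC2, RC3, RC4, IDU, HOMO, OTHTR,
           AIDSC, DOSES1, DOSES3, PILLS, ARTYRS, ARTCOST };

struct Spec {
  double shape;
  double med[4];
  double beta[NCOV];
  double floor;
  bool any_beta;
};

struct Table { std::vector<double> vals, probs; };

struct Pars {
  double ref[NCOV];
  Spec supp12, supp3, vf12, vf3, rswitch, firstres, classsw, hosp;
  double death_shape[2], death_med[2];
  double aids_shape, aids_med[3], aids_breaks[2], aids_mult[4];
  double adh_beta[NCOV];
  double art_loganchor[3], art_beta[NCOV];
  double nonart_loganchor[4], nonart_beta[NCOV];
  double ns_meanlog, ns_sdlog;
  double ubreaks[2], w_unsupp[3], w_supp[3];
  double cd4_a[3], cd4_b[3], ns_decline;
  double rate, c_line, c_reg, c_ae, c_aids, c_hosp;
  double tox_p, deadline, l3window, reb_lo, reb_hi, vfloor, medfloor;
  double cd4cap, age_cap;
  double res_lo[4], res_hi[4], tri[3];
  Table reg_npis[3], reg_doses[3], reg_pills[3];
};

void fill_vec(const NumericVector& v, double* out, int n) {
  for (int i = 0; i < n; ++i) out[i] = (i < v.size()) ? v[i] : v[v.size() - 1];
}

Spec read_spec(const List& l) {
  Spec s;
  s.shape = as<double>(l["shape"]);
  s.floor = as<double>(l["floor"]);
  fill_vec(as<NumericVector>(l["med"]), s.med, 4);
  NumericVector b = as<NumericVector>(l["beta"]);
  s.any_beta = false;
  for (int i = 0; i < NCOV; ++i) {
    s.beta[i] = b[i];
    if (b[i] != 0.0) s.any_beta = true;
  }
  return s;
}

Table read_table(const List& l) {
  Table t;
  t.vals = as<std::vector<double> >(l["values"]);
  t.probs = as<std::vector<double> >(l["probs"]);
  return t;
}

Pars read_pars(const List& par) {
  Pars p;
  fill_vec(as<NumericVector>(par["ref"]), p.ref, NCOV);
  p.supp12 = read_spec(par["supp12"]);
  p.supp3 = read_spec(par["supp3"]);
  p.vf12 = read_spec(par["vf12"]);
  p.vf3 = read_spec(par["vf3"]);
  p.rswitch = read_spec(par["rswitch"]);
  p.firstres = read_spec(par["firstres"]);
  p.classsw = read_spec(par["classsw"]);
  p.hosp = read_spec(par["hosp"]);
  fill_vec(as<NumericVector>(par["death_shape"]), p.death_shape, 2);
  fill_vec(as<NumericVector>(par["death_med"]), p.death_med, 2);
  p.aids_shape = as<double>(par["aids_shape"]);
  fill_vec(as<NumericVector>(par["aids_med"]), p.aids_med, 3);
  fill_vec(as<NumericVector>(par["aids_breaks"]), p.aids_breaks, 2);
  fill_vec(as<NumericVector>(par["aids_mult"]), p.aids_mult, 4);
  fill_vec(as<NumericVector>(par["adh_beta"]), p.adh_beta, NCOV);
  fill_vec(as<NumericVector>(par["art_loganchor"]), p.art_loganchor, 3);
  fill_vec(as<NumericVector>(par["art_beta"]), p.art_beta, NCOV);
  fill_vec(as<NumericVector>(par["nonart_loganchor"]), p.nonart_loganchor, 4);
  fill_vec(as<NumericVector>(par["nonart_beta"]), p.nonart_beta, NCOV);
  p.ns_meanlog = as<double>(par["ns_meanlog"]);
  p.ns_sdlog = as<double>(par["ns_sdlog"]);
  fill_vec(as<NumericVector>(par["util_breaks"]), p.ubreaks, 2);
  fill_vec(as<NumericVector>(par["util_unsupp"]), p.w_unsupp, 3);
  fill_vec(as<NumericVector>(par["util_supp"]), p.w_supp, 3);
  fill_vec(as<NumericVector>(par["cd4_a"]), p.cd4_a, 3);
  fill_vec(as<NumericVector>(par["cd4_b"]), p.cd4_b, 3);
  p.ns_decline = as<double>(par["ns_decline"]);
  p.rate = as<double>(par["rate"]);
  p.c_line = as<double>(par["c_line"]);
  p.c_reg = as<double>(par["c_reg"]);
  p.c_ae = as<double>(par["c_ae"]);
  p.c_aids = as<double>(par["c_aids"]);
  p.c_hosp = as<double>(par["c_hosp"]);
  p.tox_p = as<double>(par["tox_p"]);
  p.deadline = as<double>(par["deadline"]);
  p.l3window = as<double>(par["l3window"]);
  p.reb_lo = as<double>(par["reb_lo"]);
  p.reb_hi = as<double>(par["reb_hi"]);
  p.vfloor = as<double>(par["vfloor"]);
  p.medfloor = as<double>(par["medfloor"]);
  p.cd4cap = as<double>(par["cd4cap"]);
  p.age_cap = as<double>(par["age_cap"]);
  NumericVector rb = as<NumericVector>(par["res_bounds"]); // c(1,5,10,25)
  double lo[4] = {0.0, rb[0], rb[1], rb[2]};
  double hi[4] = {rb[0], rb[1], rb[2], rb[3]};
  for (int i = 0; i < 4; ++i) { p.res_lo[i] = lo[i]; p.res_hi[i] = hi[i]; }
  fill_vec(as<NumericVector>(par["tri"]), p.tri, 3);
  List rt = par["regimen_tables"];
  for (int l = 0; l < 3; ++l) {
    List tab = rt[l];
    p.reg_npis[l] = read_table(tab["n_pis"]);
    p.reg_doses[l] = read_table(tab["doses"]);
    p.reg_pills[l] = read_table(tab["pills"]);
  }
  return p;
}

inline double dot_dev(const double* beta, const double* dev) {
  double s = 0.0;
  for (int i = 0; i < NCOV; ++i) s += beta[i] * dev[i];
  return s;
}

inline double cond_time(double shape, double med, double elapsed, double u,
                        double medfloor) {
  if (med < medfloor) med = medfloor;
  double scale = med / std::pow(M_LN2, 1.0 / shape);
  double a = std::pow(elapsed / scale, shape) - std::log(u);
  return scale * std::pow(a, 1.0 / shape);
}

inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Ind {   // evolving state of one individual
  double female, age0, hcv, cd4, vl, vl0, adh0, reslev, year, npis, doses,
      pills;
  int trans, aidsf, resclass, line, regnum, nfail_after, nfail_no;
  bool suppressed;
  double nonhiv_t;
};

const int NOUT = 32;

struct TraceBuf {
  std::vector<double> id, t0, t1, line, cd4, vl, supp, adh, art, nonart, w,
      ev, cost;
  void push(int i, double a, double b, int l, double c, double v, bool s,
            double ad, double am, double nm, double u, int e, double co) {
    id.push_back(i + 1); t0.push_back(a); t1.push_back(b);
    line.push_back(l); cd4.push_back(c); vl.push_back(v);
    supp.push_back(s ? 1 : 0); adh.push_back(ad); art.push_back(am);
    nonart.push_back(nm); w.push_back(u); ev.push_back(e); cost.push_back(co);
  }
};

// event codes
enum Ev { E_NONHIV = 0, E_HIVDEATH, E_AIDS, E_DEADLINE, E_FAIL, E_RES,
          E_RSWITCH, E_HOSP, E_SUPP };
// tie-break rank (lower preempts): death > AIDS > line-failure events >
// resistance > regimen switch > hospitalization > suppression
const int PRIO[9] = {0, 1, 2, 3, 4, 5, 6, 7, 8};

void simulate_one(const Pars& P, Ind st, Rng& rng, int idx, double* out,
                  TraceBuf* tb) {
  double t = 0.0;
  int line = 1;
  double line_start = 0.0, reg_start = 0.0, supp_time = 0.0;
  double res_clock = 0.0, hosp_clock = 0.0, aids_clock = 0.0;
  double cd4_anchor = 0.0;
  bool l3_blocked = false, l3_supp_seen = false;
  double ns_daily = 0.0;
  double months_line[4] = {0, 0, 0, 0};
  double supp_line[3] = {0, 0, 0};
  double reach[3] = {0, 0, 0};   // lines 2, 3, nonsupp
  int n_rswitch = 0, n_lswitch = 0, n_hosp = 0, n_aids = 0, n_tox = 0;
  double ly_d = 0, qaly_d = 0, qaly_u = 0, art_d = 0, art_u = 0,
      nonart_d = 0, nonart_u = 0, ev_d = 0, ev_u = 0;
  int death_hiv = 0;
  double cap_t = (P.age_cap - st.age0) * 12.0;
  if (cap_t < 0) cap_t = 0;
  double r = P.rate;

  // baseline adherence offset: anchor the logit model at the individual's
  // sampled baseline adherence under baseline covariates
  double dev[NCOV];
  auto fill_dev = [&](double tt, double art_m) {
    dev[FEMALE] = st.female - P.ref[FEMALE];
    dev[AGE] = (st.age0 + tt / 12.0) - P.ref[AGE];
    dev[LOG10VL] = st.vl - P.ref[LOG10VL];
    dev[CD4] = st.cd4 - P.ref[CD4];
    dev[HCV] = st.hcv - P.ref[HCV];
    dev[ADH] = 0.0;  // set after the adherence update
    dev[YEAR] = st.year - P.ref[YEAR];
    dev[NPIS] = st.npis - P.ref[NPIS];
    dev[RESLEV] = st.reslev - P.ref[RESLEV];
    dev[REGNUM] = st.regnum - P.ref[REGNUM];
    dev[LINE2] = (line == 2 ? 1 : 0) - P.ref[LINE2];
    dev[LINE3] = (line >= 3 ? 1 : 0) - P.ref[LINE3];
    int nf = st.nfail_after + st.nfail_no;
    dev[PF1] = (nf == 1 ? 1 : 0) - P.ref[PF1];
    dev[PF2] = (nf > 1 ? 1 : 0) - P.ref[PF2];
    dev[RC2] = (st.resclass == 2 ? 1 : 0) - P.ref[RC2];
    dev[RC3] = (st.resclass == 3 ? 1 : 0) - P.ref[RC3];
    dev[RC4] = (st.resclass == 4 ? 1 : 0) - P.ref[RC4];
    dev[IDU] = (st.trans == 1 ? 1 : 0) - P.ref[IDU];
    dev[HOMO] = (st.trans == 2 ? 1 : 0) - P.ref[HOMO];
    dev[OTHTR] = (st.trans == 3 ? 1 : 0) - P.ref[OTHTR];
    dev[AIDSC] = st.aidsf - P.ref[AIDSC];
    dev[DOSES1] = (st.doses == 1 ? 1 : 0) - P.ref[DOSES1];
    dev[DOSES3] = (st.doses >= 3 ? 1 : 0) - P.ref[DOSES3];
    dev[PILLS] = st.pills - P.ref[PILLS];
    dev[ARTYRS] = tt / 12.0 - P.ref[ARTYRS];
    dev[ARTCOST] = art_m - P.ref[ARTCOST];
  };

  double art_m0;
  fill_dev(0.0, P.ref[ARTCOST]);
  art_m0 = std::exp(P.art_loganchor[0] + dot_dev(P.art_beta, dev));
  fill_dev(0.0, art_m0);
  double p0 = st.adh0;
  if (p0 < 0.01) p0 = 0.01;
  if (p0 > 0.99) p0 = 0.99;
  double adh_offset = std::log(p0 / (1 - p0)) - dot_dev(P.adh_beta, dev);

  auto redraw_regimen = [&](int l) {
    int li = (l > 3 ? 3 : l) - 1;
    st.npis = P.reg_npis[li].vals[rng.categ(P.reg_npis[li].probs)];
    st.doses = P.reg_doses[li].vals[rng.categ(P.reg_doses[li].probs)];
    st.pills = P.reg_pills[li].vals[rng.categ(P.reg_pills[li].probs)];
  };

  int iter = 0;
  while (true) {
    if (++iter > 200000) { death_hiv = 0; break; }  // non-termination guard
    // current models
    double art_m;
    fill_dev(t, P.ref[ARTCOST]);
    if (line == 4) {
      art_m = ns_daily * 30.4375;
    } else {
      art_m = std::exp(P.art_loganchor[line - 1] + dot_dev(P.art_beta, dev));
    }
    dev[ARTCOST] = art_m - P.ref[ARTCOST];
    double adh_pct = 100.0 * invlogit(adh_offset + dot_dev(P.adh_beta, dev));
    dev[ADH] = adh_pct - P.ref[ADH];
    int nline = (line == 4 ? 4 : line) - 1;
    double nonart_m =
        std::exp(P.nonart_loganchor[nline] + dot_dev(P.nonart_beta, dev));
    int stratum = (st.cd4 < P.ubreaks[0]) ? 0 : (st.cd4 < P.ubreaks[1] ? 1 : 2);
    double w = st.suppressed ? P.w_supp[stratum] : P.w_unsupp[stratum];

    // candidate events (absolute times, months from ART initiation)
    double best_t = st.nonhiv_t < cap_t ? st.nonhiv_t : cap_t;
    int best_e = E_NONHIV;
    auto offer = [&](double tt, int e) {
      if (tt < best_t - 1e-12 ||
          (std::fabs(tt - best_t) <= 1e-12 && PRIO[e] < PRIO[best_e])) {
        best_t = tt; best_e = e;
      }
    };
    {  // HIV death, stratified by AIDS status, clock from ART initiation
      int sidx = st.aidsf ? 1 : 0;
      offer(cond_time(P.death_shape[sidx], P.death_med[sidx], t, rng.unif(),
                      P.medfloor), E_HIVDEATH);
    }
    {  // AIDS-defining event: renewal clock, CD4/transmission strata
      int cs = (st.cd4 < P.aids_breaks[0]) ? 0
               : (st.cd4 < P.aids_breaks[1] ? 1 : 2);
      double med = P.aids_med[cs] * P.aids_mult[st.trans];
      offer(aids_clock + cond_time(P.aids_shape, med, t - aids_clock,
                                   rng.unif(), P.medfloor), E_AIDS);
    }
    {  // resistance: first development from ART start, later class switches
       // on a renewal clock
      if (st.resclass == 1) {
        double med = P.firstres.med[0] +
            (P.firstres.any_beta ? dot_dev(P.firstres.beta, dev) : 0.0);
        offer(cond_time(P.firstres.shape, med, t, rng.unif(),
                        P.firstres.floor), E_RES);
      } else {
        double med = P.classsw.med[0] +
            (P.classsw.any_beta ? dot_dev(P.classsw.beta, dev) : 0.0);
        offer(res_clock + cond_time(P.classsw.shape, med, t - res_clock,
                                    rng.unif(), P.classsw.floor), E_RES);
      }
    }
    if (line <= 3) {  // regimen switch without virological failure
      double med = P.rswitch.med[line - 1] +
          (P.rswitch.any_beta ? dot_dev(P.rswitch.beta, dev) : 0.0);
      offer(reg_start + cond_time(P.rswitch.shape, med, t - reg_start,
                                  rng.unif(), P.rswitch.floor), E_RSWITCH);
    }
    if (line <= 3) {
      if (!st.suppressed) {
        if (line <= 2) {
          double med = P.supp12.med[line - 1] +
              (P.supp12.any_beta ? dot_dev(P.supp12.beta, dev) : 0.0);
          offer(reg_start + cond_time(P.supp12.shape, med, t - reg_start,
                                      rng.unif(), P.supp12.floor), E_SUPP);
          offer(line_start + P.deadline, E_DEADLINE);
        } else if (!l3_blocked) {
          offer(reg_start + cond_time(P.supp3.shape, P.supp3.med[0],
                                      t - reg_start, rng.unif(),
                                      P.supp3.floor), E_SUPP);
          if (!l3_supp_seen) offer(line_start + P.l3window, E_DEADLINE);
        }
      } else {
        const Spec& vf = (line <= 2) ? P.vf12 : P.vf3;
        double med = vf.med[(line <= 2) ? line - 1 : 0] +
            (vf.any_beta ? dot_dev(vf.beta, dev) : 0.0);
        offer(supp_time + cond_time(vf.shape, med, t - supp_time, rng.unif(),
                                    vf.floor), E_FAIL);
      }
    }
    {  // hospitalization: renewal clock
      double med = P.hosp.med[nline] +
          (P.hosp.any_beta ? dot_dev(P.hosp.beta, dev) : 0.0);
      offer(hosp_clock + cond_time(P.hosp.shape, med, t - hosp_clock,
                                   rng.unif(), P.hosp.floor), E_HOSP);
    }

    // accrue the interval [t, best_t)
    double tn = best_t;
    double dt = tn - t;
    if (dt < 0) dt = 0;
    double midf = std::pow(1.0 + r, -((t + tn) / 2.0) / 12.0);
    double endf = std::pow(1.0 + r, -tn / 12.0);
    art_u += art_m * dt;      art_d += art_m * dt * midf;
    nonart_u += nonart_m * dt; nonart_d += nonart_m * dt * midf;
    ly_d += dt / 12.0 * midf;
    qaly_u += dt / 12.0 * w;  qaly_d += dt / 12.0 * w * midf;
    months_line[line - 1] += dt;

    double cd4_at_t = st.cd4, vl_at_t = st.vl;
    bool supp_at_t = st.suppressed;
    double adh_at_t = adh_pct / 100.0;
    int line_at_t = line;

    // markers evolve over the interval
    if (line == 4) {
      st.cd4 -= P.ns_decline / 12.0 * dt;
    } else {
      int li = line - 1;
      st.cd4 += P.cd4_a[li] *
          (std::log(1.0 + P.cd4_b[li] * (tn - cd4_anchor)) -
           std::log(1.0 + P.cd4_b[li] * (t - cd4_anchor)));
    }
    if (st.cd4 < 0) st.cd4 = 0;
    if (st.cd4 > P.cd4cap) st.cd4 = P.cd4cap;
    if (st.cd4 < 200) st.aidsf = 1;  // permanent classification
    t = tn;

    // handle the event
    double cost = 0.0;
    bool done = false;
    auto enter_nonsupp = [&]() {
      line = 4;
      reach[2] = 1;
      line_start = reg_start = t;
      cd4_anchor = t;
      st.suppressed = false;
      ns_daily = std::exp(P.ns_meanlog + P.ns_sdlog * rng.norm());
    };
    auto line_switch = [&]() {
      n_lswitch++;
      line++;
      if (line == 2) reach[0] = 1;
      if (line == 3) { reach[1] = 1; l3_blocked = false; l3_supp_seen = false; }
      line_start = reg_start = t;
      cd4_anchor = t;
      st.suppressed = false;
      st.regnum++;
      if (line == 3 && st.resclass >= 4) { enter_nonsupp(); return; }
      redraw_regimen(line);
    };
    switch (best_e) {
      case E_NONHIV: death_hiv = 0; done = true; break;
      case E_HIVDEATH: death_hiv = 1; done = true; break;
      case E_AIDS:
        cost = P.c_aids; n_aids++; st.aidsf = 1; aids_clock = t; break;
      case E_DEADLINE:
        st.nfail_no++;
        cost = P.c_line;
        if (line <= 2) {
          line_switch();
        } else {  // line-3 window breach: reshuffle, no further attempts
          l3_blocked = true;
          st.regnum++;
          redraw_regimen(3);
          reg_start = t;
        }
        break;
      case E_FAIL:
        st.nfail_after++;
        st.suppressed = false;
        st.vl = rng.unif(P.reb_lo, P.reb_hi);
        cost = P.c_line;
        if (line <= 2) {
          line_switch();
        } else if (st.resclass >= 4) {
          enter_nonsupp();
        } else {  // stay on line 3, reshuffle the regimen
          st.regnum++;
          redraw_regimen(3);
          reg_start = t;
        }
        break;
      case E_RES: {
        res_clock = t;
        if (st.resclass >= 4) {
          double d = rng.triangular(P.tri[0], P.tri[1], P.tri[2]);
          if (d > st.reslev) st.reslev = d;
        } else {
          st.resclass++;
          st.reslev = rng.unif(P.res_lo[st.resclass - 1],
                               P.res_hi[st.resclass - 1]);
          if (line == 3 && st.resclass >= 4) {
            cost = P.c_line;
            if (st.suppressed) { st.suppressed = false;
              st.vl = rng.unif(P.reb_lo, P.reb_hi); }
            enter_nonsupp();
          }
        }
        break;
      }
      case E_RSWITCH: {
        n_rswitch++;
        bool tox = rng.unif() < P.tox_p;
        if (tox) n_tox++;
        cost = P.c_reg + (tox ? P.c_ae : 0.0);
        st.regnum++;
        redraw_regimen(line);
        reg_start = t;
        break;
      }
      case E_HOSP: cost = P.c_hosp; n_hosp++; hosp_clock = t; break;
      case E_SUPP:
        st.suppressed = true;
        st.vl = P.vfloor;
        supp_time = t;
        if (line <= 3) supp_line[line - 1] = 1;
        if (line == 3) l3_supp_seen = true;
        break;
    }
    ev_u += cost;
    ev_d += cost * endf;
    if (tb) {
      tb->push(idx, tn - dt, tn, line_at_t, cd4_at_t, vl_at_t, supp_at_t,
               adh_at_t, art_m, nonart_m, w, best_e, cost);
    }
    if (done) break;
  }

  out[0] = t;
  out[1] = ly_d;
  out[2] = t / 12.0;
  out[3] = qaly_d;
  out[4] = qaly_u;
  out[5] = art_d;
  out[6] = art_u;
  out[7] = nonart_d;
  out[8] = nonart_u;
  out[9] = ev_d;
  out[10] = ev_u;
  out[11] = n_rswitch;
  out[12] = n_lswitch;
  out[13] = n_hosp;
  out[14] = n_aids;
  out[15] = st.nfail_after;
  out[16] = st.nfail_no;
  out[17] = months_line[0];
  out[18] = months_line[1];
  out[19] = months_line[2];
  out[20] = months_line[3];
  out[21] = supp_line[0];
  out[22] = supp_line[1];
  out[23] = supp_line[2];
  out[24] = reach[0];
  out[25] = reach[1];
  out[26] = reach[2];
  out[27] = death_hiv;
  out[28] = st.resclass;
  out[29] = st.cd4;
  out[30] = st.regnum;
  out[31] = n_tox;
}

}  // namespace

// [[Rcpp::export(name = ".sim_cohort_cpp")]]
List sim_cohort_cpp(List par, NumericMatrix baseline, int seed,
                    bool trace = false) {
  Pars P = read_pars(par);
  int n = baseline.nrow();
  NumericMatrix out(n, NOUT);
  TraceBuf tb;
  for (int i = 0; i < n; ++i) {
    Ind st;
    st.female = baseline(i, 0);
    st.age0 = baseline(i, 1);
    st.hcv = baseline(i, 2);
    st.trans = (int)baseline(i, 3);
    st.aidsf = (int)baseline(i, 4);
    st.cd4 = baseline(i, 5);
    st.vl = baseline(i, 6);
    st.vl0 = baseline(i, 6);
    st.adh0 = baseline(i, 7);
    st.reslev = baseline(i, 8);
    st.resclass = (int)baseline(i, 9);
    st.year = baseline(i, 10);
    st.npis = baseline(i, 11);
    st.doses = baseline(i, 12);
    st.pills = baseline(i, 13);
    st.nonhiv_t = baseline(i, 14);
    st.line = 1;
    st.regnum = 1;
    st.nfail_after = 0;
    st.nfail_no = 0;
    st.suppressed = false;
    uint64_t sub = (uint64_t)(uint32_t)seed;
    sub = sub * 0x9E3779B97F4A7C15ULL + (uint64_t)(i + 1) * 0xD1B54A32D192ED03ULL;
    Rng rng(sub);
    double tmp[NOUT];
    simulate_one(P, st, rng, i, tmp, trace ? &tb : (TraceBuf*)0);
    for (int j = 0; j < NOUT; ++j) out(i, j) = tmp[j];
  }
  List res = List::create(_["outcomes"] = out);
  if (trace) {
    res["trace"] = DataFrame::create(
        _["id"] = tb.id, _["t0"] = tb.t0, _["t1"] = tb.t1,
        _["line"] = tb.line, _["cd4"] = tb.cd4, _["log10vl"] = tb.vl,
        _["suppressed"] = tb.supp, _["adherence"] = tb.adh,
        _["art_monthly"] = tb.art, _["nonart_monthly"] = tb.nonart,
        _["utility"] = tb.w, _["event"] = tb.ev, _["event_cost"] = tb.cost);
  }
  return res;
}
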