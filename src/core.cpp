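// Numeric core of the reputation game: beta-belief calculus, message
// evaluation, the per-conversation update step, and the run loop.
// All randomness comes from R's RNG so that set.seed() at the R level
// makes every run fully reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// strategy codes (kept in sync with rg_strategies() on the R side)
enum Strategy { ORDINARY = 0, DECEPTIVE = 1, MANIPULATIVE = 2,
                DOMINANT = 3, DESTRUCTIVE = 4 };

// ---------------------------------------------------------------------------
// beta-belief primitives. A belief (mu, la) encodes Beta(f | mu + 1, la + 1):
// mu counts confirming events, la disconfirming ones.
// ---------------------------------------------------------------------------

static inline double bmean(double mu, double la) {
  return (mu + 1.0) / (mu + la + 2.0);
}

static inline double bvar(double mu, double la) {
  double s = mu + la + 2.0;
  return (mu + 1.0) * (la + 1.0) / ((s + 1.0) * s * s);
}

static inline double blogpdf(double mu, double la, double f) {
  return mu * std::log(f) + la * std::log1p(-f) - R::lbeta(mu + 1.0, la + 1.0);
}

// per-observation (predictive) surprise: KL divergence between the
// Bernoulli next-event distributions implied by the posterior means of the
// claim and of the receiver's prior. Bounded for means inside (0,1) and
// independent of how sharp the two beliefs are, so skepticism is driven by
// how far the claimed frequency sits from the receiver's estimate, not by
// how much evidence either side has piled up.
static double pred_surprise_core(double cmu, double cla, double pmu, double pla) {
  double mc = bmean(cmu, cla), mp = bmean(pmu, pla);
  return mc * std::log(mc / mp) + (1.0 - mc) * std::log((1.0 - mc) / (1.0 - mp));
}

static double kl_beta_core(double pmu, double pla, double qmu, double qla) {
  double a1 = pmu + 1.0, b1 = pla + 1.0, a2 = qmu + 1.0, b2 = qla + 1.0;
  return R::lbeta(a2, b2) - R::lbeta(a1, b1)
       + (a1 - a2) * R::digamma(a1)
       + (b1 - b2) * R::digamma(b1)
       + (a2 - a1 + b2 - b1) * R::digamma(a1 + b1);
}

// Compress a beta mixture to the single beta minimizing KL(mixture || beta).
// The optimum matches the mixture's sufficient statistics E[ln f] and
// E[ln(1-f)]; the digamma moment equations are solved by damped Newton
// iteration started from mean/variance moment matching. Pseudo-counts are
// kept nonnegative: when the unconstrained optimum would need mu < 0 (or
// la < 0) the count is pinned at zero and the remaining equation re-solved.
// Returns true when Newton converged; on non-convergence the moment-matched
// fallback is returned.
static bool compress_core(int k, const double* w, const double* mus,
                          const double* las, double& out_mu, double& out_la) {
  // fast paths: single effective component
  int heavy = -1;
  for (int i = 0; i < k; i++) if (w[i] >= 1.0 - 1e-12) heavy = i;
  if (k == 1) heavy = 0;
  if (heavy >= 0) { out_mu = mus[heavy]; out_la = las[heavy]; return true; }

  double T1 = 0.0, T2 = 0.0, m = 0.0, m2 = 0.0;
  bool allsame = true;
  for (int i = 0; i < k; i++) {
    if (mus[i] != mus[0] || las[i] != las[0]) allsame = false;
    double a = mus[i] + 1.0, b = las[i] + 1.0;
    double dg = R::digamma(a + b);
    T1 += w[i] * (R::digamma(a) - dg);
    T2 += w[i] * (R::digamma(b) - dg);
    double mi = a / (a + b);
    double vi = a * b / ((a + b) * (a + b) * (a + b + 1.0));
    m  += w[i] * mi;
    m2 += w[i] * (vi + mi * mi);
  }
  if (allsame) { out_mu = mus[0]; out_la = las[0]; return true; }
  double v = m2 - m * m;
  if (v < 1e-14) v = 1e-14;

  double s0 = m * (1.0 - m) / v - 1.0;
  if (s0 < 1e-8) s0 = 1e-8;
  double a = m * s0, b = (1.0 - m) * s0;
  if (a < 1e-8) a = 1e-8;
  if (b < 1e-8) b = 1e-8;

  bool conv = false;
  for (int it = 0; it < 100; it++) {
    double dg = R::digamma(a + b), tg = R::trigamma(a + b);
    double r1 = R::digamma(a) - dg - T1;
    double r2 = R::digamma(b) - dg - T2;
    if (std::fabs(r1) < 1e-10 && std::fabs(r2) < 1e-10) { conv = true; break; }
    double J11 = R::trigamma(a) - tg, J22 = R::trigamma(b) - tg, J12 = -tg;
    double det = J11 * J22 - J12 * J12;
    if (!(det > 0.0) || !std::isfinite(det)) break;
    double da = -(J22 * r1 - J12 * r2) / det;
    double db = -(-J12 * r1 + J11 * r2) / det;
    double step = 1.0;
    while ((a + step * da <= 1e-10 || b + step * db <= 1e-10) && step > 1e-9)
      step *= 0.5;
    double an = a + step * da, bn = b + step * db;
    double base = r1 * r1 + r2 * r2;
    for (int h = 0; h < 30; h++) {
      double dgn = R::digamma(an + bn);
      double n1 = R::digamma(an) - dgn - T1;
      double n2 = R::digamma(bn) - dgn - T2;
      if (n1 * n1 + n2 * n2 <= base || step < 1e-9) break;
      step *= 0.5;
      an = a + step * da; bn = b + step * db;
      if (an <= 1e-10) an = 1e-10;
      if (bn <= 1e-10) bn = 1e-10;
    }
    a = an; b = bn;
  }

  if (!conv) {
    double s2 = m * (1.0 - m) / v - 1.0;
    if (s2 < 1e-8) s2 = 1e-8;
    a = m * s2; b = (1.0 - m) * s2;
  } else {
    // nonnegative pseudo-counts: pin at the boundary and re-solve the other
    if (a < 1.0) {
      a = 1.0;
      for (int it = 0; it < 100; it++) {
        double r = R::digamma(b) - R::digamma(a + b) - T2;
        if (std::fabs(r) < 1e-10) break;
        double d = R::trigamma(b) - R::trigamma(a + b);
        double bn = b - r / d;
        if (bn < 1.0) { b = 1.0; break; }
        if (std::fabs(bn - b) < 1e-14) { b = bn; break; }
        b = bn;
      }
    } else if (b < 1.0) {
      b = 1.0;
      for (int it = 0; it < 100; it++) {
        double r = R::digamma(a) - R::digamma(a + b) - T1;
        if (std::fabs(r) < 1e-10) break;
        double d = R::trigamma(a) - R::trigamma(a + b);
        double an = a - r / d;
        if (an < 1.0) { a = 1.0; break; }
        if (std::fabs(an - a) < 1e-14) { a = an; break; }
        a = an;
      }
    }
  }
  out_mu = a - 1.0; if (out_mu < 0.0) out_mu = 0.0;
  out_la = b - 1.0; if (out_la < 0.0) out_la = 0.0;
  return conv;
}

// ---------------------------------------------------------------------------
// world state
// ---------------------------------------------------------------------------

struct Cfg {
  double blush_prob, alpha, gamma, up_margin, lo_margin, max_exp, evidence_cap,
         self_weight;
  bool known_freq;
  bool round_robin;
};

struct World {
  int n;
  std::vector<double> honesty;
  std::vector<int> strat;
  std::vector<double> hb_mu, hb_la;    // n x n, column-major: [a + n*b] = a's belief about b
  std::vector<double> bb;              // n x 4: lie_mu, lie_la, tr_mu, tr_la (column-major)
  std::vector<double> tom_mu, tom_la;  // n x n x n: [a + n*c + n*n*t] = a's estimate of c's belief about t
  std::vector<double> fr_cnt, fr_sum;  // n x n: [a + n*c] = a's ledger for counterpart c

  inline int hi(int a, int b) const { return a + n * b; }
  inline int ti(int a, int c, int t) const { return a + n * (c + n * t); }
  inline double bbv(int a, int col) const { return bb[a + n * col]; }
  inline double& bbr(int a, int col) { return bb[a + n * col]; }
};

static Cfg cfg_from(const List& cfg) {
  Cfg C;
  C.blush_prob = as<double>(cfg["blush_prob"]);
  C.alpha = as<double>(cfg["alpha"]);
  C.gamma = as<double>(cfg["gamma"]);
  NumericVector marg = cfg["lics_margins"];
  C.up_margin = marg[0];
  C.lo_margin = marg[1];
  C.max_exp = as<double>(cfg["max_exponent"]);
  C.known_freq = as<bool>(cfg["known_frequencies"]);
  C.evidence_cap = as<double>(cfg["evidence_cap"]);
  C.self_weight = as<double>(cfg["self_weight"]);
  std::string init = as<std::string>(cfg["initiator"]);
  C.round_robin = (init == "round_robin");
  return C;
}

static World world_from(const List& w) {
  World W;
  W.n = as<int>(w["n"]);
  W.honesty = as<std::vector<double> >(w["honesty"]);
  W.strat = as<std::vector<int> >(w["strategy_code"]);
  W.hb_mu = as<std::vector<double> >(w["hb_mu"]);
  W.hb_la = as<std::vector<double> >(w["hb_la"]);
  W.bb = as<std::vector<double> >(w["bb"]);
  W.tom_mu = as<std::vector<double> >(w["tom_mu"]);
  W.tom_la = as<std::vector<double> >(w["tom_la"]);
  W.fr_cnt = as<std::vector<double> >(w["fr_cnt"]);
  W.fr_sum = as<std::vector<double> >(w["fr_sum"]);
  return W;
}

static List world_to(const World& W) {
  int n = W.n;
  NumericMatrix hb_mu(n, n), hb_la(n, n), bb(n, 4), fr_cnt(n, n), fr_sum(n, n);
  std::copy(W.hb_mu.begin(), W.hb_mu.end(), hb_mu.begin());
  std::copy(W.hb_la.begin(), W.hb_la.end(), hb_la.begin());
  std::copy(W.bb.begin(), W.bb.end(), bb.begin());
  std::copy(W.fr_cnt.begin(), W.fr_cnt.end(), fr_cnt.begin());
  std::copy(W.fr_sum.begin(), W.fr_sum.end(), fr_sum.begin());
  NumericVector tom_mu(n * n * n), tom_la(n * n * n);
  std::copy(W.tom_mu.begin(), W.tom_mu.end(), tom_mu.begin());
  std::copy(W.tom_la.begin(), W.tom_la.end(), tom_la.begin());
  tom_mu.attr("dim") = IntegerVector::create(n, n, n);
  tom_la.attr("dim") = IntegerVector::create(n, n, n);
  return List::create(
    _["n"] = n,
    _["honesty"] = W.honesty,
    _["strategy_code"] = W.strat,
    _["hb_mu"] = hb_mu, _["hb_la"] = hb_la,
    _["bb"] = bb,
    _["tom_mu"] = tom_mu, _["tom_la"] = tom_la,
    _["fr_cnt"] = fr_cnt, _["fr_sum"] = fr_sum);
}

// ---------------------------------------------------------------------------
// friendship, strategies, message construction
// ---------------------------------------------------------------------------

// -1 enemy, 0 neutral, +1 friend: counterpart's running mean of communicated
// opinions about oneself compared with the grand mean pooled over all
// received opinions about oneself. Ties and empty ledgers are neutral.
static int fstatus(const World& W, int a, int c) {
  double cnt = W.fr_cnt[W.hi(a, c)];
  if (cnt <= 0.0) return 0;
  double tot = 0.0, totc = 0.0;
  for (int k = 0; k < W.n; k++) {
    tot += W.fr_sum[W.hi(a, k)];
    totc += W.fr_cnt[W.hi(a, k)];
  }
  double mine = W.fr_sum[W.hi(a, c)] / cnt;
  double grand = tot / totc;
  if (mine > grand) return 1;
  if (mine < grand) return -1;
  return 0;
}

static int sample_weighted(int k, const double* w) {
  double tot = 0.0;
  for (int i = 0; i < k; i++) tot += w[i];
  double u = unif_rand() * tot, acc = 0.0;
  for (int i = 0; i < k; i++) {
    acc += w[i];
    if (u < acc) return i;
  }
  return k - 1;
}

static inline int sample_uniform(int k) {
  int i = (int)(unif_rand() * k);
  return i >= k ? k - 1 : i;
}

static int select_partner_core(const World& W, int i) {
  std::vector<double> w;
  std::vector<int> idx;
  for (int c = 0; c < W.n; c++) {
    if (c == i) continue;
    double m = bmean(W.hb_mu[W.hi(i, c)], W.hb_la[W.hi(i, c)]);
    double wt = 1.0;
    if (W.strat[i] == MANIPULATIVE) wt = 1.0 - m;
    else if (W.strat[i] == DOMINANT || W.strat[i] == DESTRUCTIVE) wt = m;
    w.push_back(wt);
    idx.push_back(c);
  }
  return idx[sample_weighted((int)w.size(), w.data())];
}

static int select_topic_core(const World& W, int i, int j) {
  switch (W.strat[i]) {
  case MANIPULATIVE:
    return j;
  case DOMINANT:
    if (unif_rand() < 0.5) return i;
    return sample_uniform(W.n);
  case DESTRUCTIVE: {
    std::vector<int> enemies;
    for (int c = 0; c < W.n; c++)
      if (c != i && fstatus(W, i, c) < 0) enemies.push_back(c);
    if (!enemies.empty()) return enemies[sample_uniform((int)enemies.size())];
    // no enemies yet: uniform over the others, never self
    int pick = sample_uniform(W.n - 1);
    return pick >= i ? pick + 1 : pick;
  }
  default:
    return sample_uniform(W.n);
  }
}

// +1 positive, -1 negative
static int lie_direction_core(const World& W, int speaker, int receiver, int topic) {
  if (topic == speaker) return 1;
  if (W.strat[speaker] == MANIPULATIVE && topic == receiver) return 1;  // flattery
  return fstatus(W, speaker, topic) < 0 ? -1 : 1;  // neutral defaults to positive
}

struct Msg {
  int speaker, receiver, topic;
  double cmu, cla;
  bool honest, blush;
};

static Msg compose_core(const World& W, const Cfg& C, int s, int r, int t) {
  Msg m;
  m.speaker = s; m.receiver = r; m.topic = t;
  m.honest = unif_rand() < W.honesty[s];
  if (m.honest) {
    m.cmu = W.hb_mu[W.hi(s, t)];
    m.cla = W.hb_la[W.hi(s, t)];
    m.blush = false;
  } else {
    // a lie is anchored at the speaker's theory of mind of the receiver's
    // belief on the topic, shifted by alpha in the chosen direction
    double tmu = W.tom_mu[W.ti(s, r, t)], tla = W.tom_la[W.ti(s, r, t)];
    if (lie_direction_core(W, s, r, t) > 0) { m.cmu = tmu + C.alpha; m.cla = tla; }
    else { m.cmu = tmu; m.cla = tla + C.alpha; }
    bool suppress = (W.strat[s] == DESTRUCTIVE);
    m.blush = !suppress && (unif_rand() < C.blush_prob);
  }
  return m;
}

// ---------------------------------------------------------------------------
// receiver-side learning step
// ---------------------------------------------------------------------------

struct Trace {
  double yh, surprise, rblush;
  bool confession;
};

// compress the posterior mixture {w1: belief + one confirming count,
// 1-w1: belief + one disconfirming count} back into (mu, la)
static void soft_count_update(double& mu, double& la, double w1) {
  double w[2] = { w1, 1.0 - w1 };
  double mus[2] = { mu + 1.0, mu };
  double las[2] = { la, la + 1.0 };
  double omu, ola;
  compress_core(2, w, mus, las, omu, ola);
  mu = omu; la = ola;
}

// compress the posterior mixture {w1: belief + one trial with the given
// outcome; 1-w1: belief unchanged (the trial did not happen)}
static void soft_trial_update(double& mu, double& la, double w1, bool success) {
  double w[2] = { w1, 1.0 - w1 };
  double mus[2] = { success ? mu + 1.0 : mu, mu };
  double las[2] = { success ? la : la + 1.0, la };
  double omu, ola;
  compress_core(2, w, mus, las, omu, ola);
  mu = omu; la = ola;
}

static void do_receive(World& W, const Cfg& C, const Msg& m, Trace& tr) {
  int r = m.receiver, s = m.speaker, t = m.topic;
  int n = W.n;

  double xbar = bmean(W.hb_mu[W.hi(r, s)], W.hb_la[W.hi(r, s)]);
  bool conf = (t == s) && (bmean(m.cmu, m.cla) < xbar);
  double surp = pred_surprise_core(m.cmu, m.cla,
                                   W.hb_mu[W.hi(r, t)], W.hb_la[W.hi(r, t)]);

  double rb, yh;
  if (C.known_freq) {
    // oracle mode: blush frequencies clamped at the true values
    // (blush_prob for lies, 0 for truths): a blush certifies a lie
    if (m.blush) {
      rb = R_PosInf;
      yh = 0.0;
    } else {
      rb = 1.0 - C.blush_prob;
      if (conf) yh = 1.0;
      else {
        double e = C.gamma * surp;
        if (e > C.max_exp) e = C.max_exp;
        double total = rb * std::exp(e);
        yh = xbar / (xbar + (1.0 - xbar) * total);
      }
    }
  } else {
    double fl = bmean(W.bbv(r, 0), W.bbv(r, 1));
    double ft = bmean(W.bbv(r, 2), W.bbv(r, 3));
    rb = m.blush ? fl / ft : (1.0 - fl) / (1.0 - ft);
    if (conf) yh = 1.0;
    else {
      double e = C.gamma * surp;
      if (e > C.max_exp) e = C.max_exp;
      double total = rb * std::exp(e);
      yh = xbar / (xbar + (1.0 - xbar) * total);
    }
  }

  // 1. speaker-honesty belief: the exact per-message posterior is the
  // mixture {yh: one honest observation; 1-yh: one dishonest observation};
  // it is compressed back into a single beta. When yh equals the prior
  // predictive mean the mixture reproduces the prior exactly, so
  // uninformative messages move the belief (almost) nothing, while
  // decisive classifications (blushes, confessions) add a full count.
  soft_count_update(W.hb_mu[W.hi(r, s)], W.hb_la[W.hi(r, s)], yh);

  // 2. topic belief. Only the novel part of the claim relative to the
  // receiver's theory of mind of the speaker is used: what the speaker was
  // already believed to believe has been counted before, and adding it
  // again on every exchange would compound pseudo-counts exponentially.
  // Under the honest hypothesis the novel evidence is fused as reported;
  // under the lie hypothesis the content is discarded and the prior kept.
  {
    double nmu = m.cmu - W.tom_mu[W.ti(r, s, t)];
    double nla = m.cla - W.tom_la[W.ti(r, s, t)];
    if (nmu < 0.0) nmu = 0.0;
    if (nla < 0.0) nla = 0.0;
    // one message carries at most evidence_cap observations' worth of
    // evidence. Without a fixed cap the acknowledged double-counting of
    // shared sources (the same content returning over several
    // conversational paths) compounds pseudo-counts exponentially in a
    // small, highly-connected group; any fixed cap keeps growth linear.
    // Confessions are exempt: they are believed outright, anchored in the
    // speaker's own self-observations (no echo path), and adopting them in
    // full is what lets a partly-honest self-deprecating agent undo its
    // own accumulated flattery.
    double ntot = nmu + nla;
    if (!conf && ntot > C.evidence_cap) {
      nmu *= C.evidence_cap / ntot;
      nla *= C.evidence_cap / ntot;
    }
    double pmu = W.hb_mu[W.hi(r, t)], pla = W.hb_la[W.hi(r, t)];
    double w[2] = { yh, 1.0 - yh };
    double mus[2] = { pmu + nmu, pmu };
    double las[2] = { pla + nla, pla };
    double omu, ola;
    compress_core(2, w, mus, las, omu, ola);
    W.hb_mu[W.hi(r, t)] = omu;
    W.hb_la[W.hi(r, t)] = ola;
  }

  // 3. blush-frequency beliefs (disabled in oracle mode). Under the lie
  // hypothesis (weight 1-yh) the message is a trial for the lie channel
  // and the truth channel is untouched; under the honest hypothesis
  // (weight yh) vice versa. Each channel's posterior mixture is compressed.
  if (!C.known_freq) {
    if (m.blush) {
      soft_trial_update(W.bbr(r, 0), W.bbr(r, 1), 1.0 - yh, true);   // lie channel
      soft_trial_update(W.bbr(r, 2), W.bbr(r, 3), yh, true);         // truth channel
    } else {
      soft_trial_update(W.bbr(r, 0), W.bbr(r, 1), 1.0 - yh, false);
      soft_trial_update(W.bbr(r, 2), W.bbr(r, 3), yh, false);
    }
  }

  // 4. theory of mind about (speaker, topic): ratchet up to the largest
  // pseudo-counts the speaker has ever professed. A plain adoption of the
  // last claim would let the tracker drop whenever a small (theory-of-mind
  // anchored) lie follows a sharp honest claim, making old content look
  // novel again on every alternation; the componentwise maximum is what
  // lets the novelty subtraction in step 2 suppress repeated content.
  if (m.cmu > W.tom_mu[W.ti(r, s, t)]) W.tom_mu[W.ti(r, s, t)] = m.cmu;
  if (m.cla > W.tom_la[W.ti(r, s, t)]) W.tom_la[W.ti(r, s, t)] = m.cla;

  // 5. friendship ledger: only messages about oneself count
  if (t == r) {
    W.fr_cnt[W.hi(r, s)] += 1.0;
    W.fr_sum[W.hi(r, s)] += bmean(m.cmu, m.cla);
  }

  (void)n;
  tr.yh = yh; tr.surprise = surp; tr.rblush = rb; tr.confession = conf;
}

// speaker-side self-perception: exact counts of own behavior. The speaker
// knows whether it just lied, so its belief about its own honesty gets one
// exact count per message; this is what gives partly-honest agents accurate
// low self-images, and therefore real confessions, while fully deceptive
// agents (who never speak honestly about themselves) escape that
// counterweight. Blush-frequency self-counts are the second channel of
// reliable self-perception (disabled in oracle mode, where frequencies
// are clamped and not learned).
static void do_self_observe(World& W, const Cfg& C, int s, bool honest, bool blush) {
  if (honest) W.hb_mu[W.hi(s, s)] += C.self_weight;
  else W.hb_la[W.hi(s, s)] += C.self_weight;
  if (C.known_freq) return;
  if (honest) W.bbr(s, 3) += 1.0;        // truth, never blushes
  else if (blush) W.bbr(s, 0) += 1.0;    // lie with blush
  else W.bbr(s, 1) += 1.0;               // lie without blush
}

// speaker-side theory-of-mind nudge after sending: the speaker assumes the
// receiver partially adopts what was new in the claim, weighted by the
// speaker's estimate of its own credibility in the receiver's eyes. The
// adoption target is the componentwise maximum of the previous estimate and
// the claim (the receiver never un-learns counts it already holds).
static void tom_nudge(World& W, int s, int r, int t, double cmu, double cla) {
  double wt = bmean(W.tom_mu[W.ti(s, r, s)], W.tom_la[W.ti(s, r, s)]);
  double pmu = W.tom_mu[W.ti(s, r, t)], pla = W.tom_la[W.ti(s, r, t)];
  double tmu = pmu > cmu ? pmu : cmu;
  double tla = pla > cla ? pla : cla;
  double w[2] = { wt, 1.0 - wt };
  double mus[2] = { tmu, pmu };
  double las[2] = { tla, pla };
  double omu, ola;
  compress_core(2, w, mus, las, omu, ola);
  W.tom_mu[W.ti(s, r, t)] = omu;
  W.tom_la[W.ti(s, r, t)] = ola;
}

static inline bool lics_core(const World& W, const Cfg& C, int a) {
  double fl, ft;
  if (C.known_freq) { fl = C.blush_prob; ft = 0.0; }
  else {
    fl = bmean(W.bbv(a, 0), W.bbv(a, 1));
    ft = bmean(W.bbv(a, 2), W.bbv(a, 3));
  }
  return C.up_margin * ft > C.lo_margin * fl;
}

static double informedness_core(const World& W, int a,
                                const std::vector<double>& truths,
                                bool ordinary_only) {
  double acc = 0.0;
  int cnt = 0;
  for (int c = 0; c < W.n; c++) {
    if (ordinary_only && W.strat[c] != ORDINARY) continue;
    double f = truths[c];
    if (f < 1e-6) f = 1e-6;
    if (f > 1.0 - 1e-6) f = 1.0 - 1e-6;
    acc += blogpdf(W.hb_mu[W.hi(a, c)], W.hb_la[W.hi(a, c)], f);
    cnt++;
  }
  return cnt > 0 ? acc / cnt : 0.0;
}

// ---------------------------------------------------------------------------
// exported single-shot operations (shared kernels for the R-level API)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_kl_beta(double pmu, double pla, double qmu, double qla) {
  return kl_beta_core(pmu, pla, qmu, qla);
}

// [[Rcpp::export]]
double cpp_pred_surprise(double cmu, double cla, double pmu, double pla) {
  return pred_surprise_core(cmu, cla, pmu, pla);
}

// [[Rcpp::export]]
NumericVector cpp_compress(NumericVector w, NumericVector mu, NumericVector la) {
  double omu, ola;
  bool conv = compress_core((int)w.size(), REAL(w), REAL(mu), REAL(la), omu, ola);
  return NumericVector::create(_["mu"] = omu, _["la"] = ola,
                               _["converged"] = conv ? 1.0 : 0.0);
}

// [[Rcpp::export]]
List cpp_receive(List world, List cfg, int receiver, int speaker, int topic,
                 double claim_mu, double claim_la, bool blush) {
  World W = world_from(world);
  Cfg C = cfg_from(cfg);
  Msg m;
  m.speaker = speaker; m.receiver = receiver; m.topic = topic;
  m.cmu = claim_mu; m.cla = claim_la; m.blush = blush; m.honest = false;
  Trace tr;
  do_receive(W, C, m, tr);
  return List::create(
    _["world"] = world_to(W),
    _["trace"] = List::create(
      _["y_h"] = tr.yh, _["surprise"] = tr.surprise,
      _["ratio_blush"] = tr.rblush, _["confession"] = tr.confession));
}

// [[Rcpp::export]]
List cpp_self_observe(List world, List cfg, int speaker, bool honest, bool blush) {
  World W = world_from(world);
  Cfg C = cfg_from(cfg);
  do_self_observe(W, C, speaker, honest, blush);
  return world_to(W);
}

// ---------------------------------------------------------------------------
// run loop
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run(List world, List cfg, int n_steps, int t_offset,
             int record_every, bool record_messages) {
  World W = world_from(world);
  Cfg C = cfg_from(cfg);
  int n = W.n;

  const std::vector<double>& truths = W.honesty;

  int n_rec = record_every > 0 ? n_steps / record_every : 0;
  int ncol = 1 + n * (n - 1) + 5 * n + 2;
  NumericMatrix traj(n_rec, ncol);
  NumericMatrix msgs(record_messages ? 2 * n_steps : 0, 10);

  // per-agent counters: messages sent, honest sent, lies sent, blushes sent
  std::vector<double> sent(n, 0.0), sent_honest(n, 0.0),
                      sent_lie(n, 0.0), sent_blush(n, 0.0);
  double msgs_cum = 0.0, honest_cum = 0.0;

  // LICS episode tracking (every step, independent of recording cadence)
  std::vector<int> ep_start(n, -1);
  std::vector<double> ep_agent, ep_s, ep_e, ep_open;
  std::vector<bool> in_lics(n);
  for (int a = 0; a < n; a++) in_lics[a] = lics_core(W, C, a);
  for (int a = 0; a < n; a++) if (in_lics[a]) ep_start[a] = t_offset;

  int rec_row = 0, msg_row = 0;

  for (int step = 1; step <= n_steps; step++) {
    int t_now = t_offset + step;

    int i = C.round_robin ? (t_now - 1) % n : sample_uniform(n);
    int j = select_partner_core(W, i);
    int topic = select_topic_core(W, i, j);

    // initiator speaks, partner listens; then the partner answers on the
    // same topic, after having updated on the initiator's message
    int sp = i, rc = j;
    for (int half = 0; half < 2; half++) {
      Msg m = compose_core(W, C, sp, rc, topic);
      do_self_observe(W, C, sp, m.honest, m.blush);
      Trace tr;
      do_receive(W, C, m, tr);
      tom_nudge(W, sp, rc, topic, m.cmu, m.cla);

      sent[sp] += 1.0;
      msgs_cum += 1.0;
      if (m.honest) { sent_honest[sp] += 1.0; honest_cum += 1.0; }
      else {
        sent_lie[sp] += 1.0;
        if (m.blush) sent_blush[sp] += 1.0;
      }
      if (record_messages) {
        msgs(msg_row, 0) = t_now;
        msgs(msg_row, 1) = sp + 1;
        msgs(msg_row, 2) = rc + 1;
        msgs(msg_row, 3) = topic + 1;
        msgs(msg_row, 4) = m.honest ? 1.0 : 0.0;
        msgs(msg_row, 5) = m.blush ? 1.0 : 0.0;
        msgs(msg_row, 6) = tr.yh;
        msgs(msg_row, 7) = tr.surprise;
        msgs(msg_row, 8) = tr.rblush;
        msgs(msg_row, 9) = tr.confession ? 1.0 : 0.0;
        msg_row++;
      }
      sp = j; rc = i;
    }

    // LICS episode bookkeeping at every step
    for (int a = 0; a < n; a++) {
      bool now = lics_core(W, C, a);
      if (now && !in_lics[a]) ep_start[a] = t_now;
      if (!now && in_lics[a]) {
        ep_agent.push_back(a + 1);
        ep_s.push_back(ep_start[a]);
        ep_e.push_back(t_now - 1);
        ep_open.push_back(0.0);
      }
      in_lics[a] = now;
    }

    if (record_every > 0 && step % record_every == 0 && rec_row < n_rec) {
      int col = 0;
      traj(rec_row, col++) = t_now;
      for (int a = 0; a < n; a++)
        for (int b = 0; b < n; b++) {
          if (a == b) continue;
          traj(rec_row, col++) = bmean(W.hb_mu[W.hi(a, b)], W.hb_la[W.hi(a, b)]);
        }
      for (int a = 0; a < n; a++) {
        double fl, ft;
        if (C.known_freq) { fl = C.blush_prob; ft = 0.0; }
        else {
          fl = bmean(W.bbv(a, 0), W.bbv(a, 1));
          ft = bmean(W.bbv(a, 2), W.bbv(a, 3));
        }
        traj(rec_row, col++) = fl;
        traj(rec_row, col++) = ft;
        traj(rec_row, col++) = in_lics[a] ? 1.0 : 0.0;
        traj(rec_row, col++) = informedness_core(W, a, truths, false);
        traj(rec_row, col++) = informedness_core(W, a, truths, true);
      }
      traj(rec_row, col++) = msgs_cum;
      traj(rec_row, col++) = honest_cum;
      rec_row++;
    }
  }

  // close open episodes
  for (int a = 0; a < n; a++) {
    if (in_lics[a]) {
      ep_agent.push_back(a + 1);
      ep_s.push_back(ep_start[a]);
      ep_e.push_back(t_offset + n_steps);
      ep_open.push_back(1.0);
    }
  }
  int nep = (int)ep_agent.size();
  NumericMatrix episodes(nep, 4);
  for (int e = 0; e < nep; e++) {
    episodes(e, 0) = ep_agent[e];
    episodes(e, 1) = ep_s[e];
    episodes(e, 2) = ep_e[e];
    episodes(e, 3) = ep_open[e];
  }

  NumericMatrix counts(n, 4);
  for (int a = 0; a < n; a++) {
    counts(a, 0) = sent[a];
    counts(a, 1) = sent_honest[a];
    counts(a, 2) = sent_lie[a];
    counts(a, 3) = sent_blush[a];
  }

  return List::create(
    _["world"] = world_to(W),
    _["trajectory"] = traj,
    _["episodes"] = episodes,
    _["counts"] = counts,
    _["messages"] = msgs,
    _["t_end"] = t_offset + n_steps);
}

// exported helpers used by the R-level strategy functions so that the engine
// and the user-facing API share one implementation

// [[Rcpp::export]]
int cpp_fstatus(List world, int agent, int counterpart) {
  World W = world_from(world);
  return fstatus(W, agent, counterpart);
}

// [[Rcpp::export]]
List cpp_compose(List world, List cfg, int speaker, int receiver, int topic) {
  World W = world_from(world);
  Cfg C = cfg_from(cfg);
  Msg m = compose_core(W, C, speaker, receiver, topic);
  return List::create(
    _["claim_mu"] = m.cmu, _["claim_la"] = m.cla,
    _["honest"] = m.honest, _["blush"] = m.blush);
}

// [[Rcpp::export]]
double cpp_informedness(List world, int agent, NumericVector truths,
                        bool ordinary_only) {
  World W = world_from(world);
  std::vector<double> tr = as<std::vector<double> >(truths);
  return informedness_core(W, agent, tr, ordinary_only);
}
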