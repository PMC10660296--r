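// Core simulators for delayed stochastic reaction networks.
//
// Conventions shared with the R level:
//  * time grid is 0..T with unit step; interval i is (i-1, i];
//  * reaction k initiates at rate h_k(z) (exponential waiting time) and
//    completes after a random delay (sum of independent Gammas);
//  * delayed reactions consume reactants at initiation and deliver
//    products at completion; undelayed reactions apply their full net
//    change instantly;
//  * all randomness is drawn from R's RNG stream, so set.seed() on the
//    R side makes every simulation reproducible.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double propensity(int type, double rate, double K, int subs,
                                const std::vector<double>& z) {
    if (type == 0) return rate;                    // constant
    double s = z[subs];
    if (type == 1) return rate * s;                // linear mass action
    return rate * s / (K + s);                     // Michaelis-Menten
}

struct Pending {
    double t_complete;
    double t_init;
    int k;
    long seq;
};
struct PendCmp {
    bool operator()(const Pending& a, const Pending& b) const {
        if (a.t_complete != b.t_complete) return a.t_complete > b.t_complete;
        return a.seq > b.seq;  // ties processed in initiation order
    }
};

// Exact delayed SSA. Returns the trajectory sampled at integer times,
// the completion event log, per-interval completion counts, and any
// reactions still pending (initiated but not completed) at time T.
// [[Rcpp::export]]
List cpp_ssa(IntegerMatrix reactant, IntegerMatrix netchange,
             IntegerVector propType, NumericVector rate, NumericVector K,
             IntegerVector subs, List delayShapes, List delayRates,
             IntegerVector z0, int T) {
    const int v = reactant.nrow(), u = reactant.ncol();
    std::vector<double> z(u);
    for (int j = 0; j < u; ++j) z[j] = z0[j];

    IntegerMatrix traj(u, T + 1);
    IntegerMatrix counts(v, T);
    std::vector<double> evInit, evComp;
    std::vector<int> evType;
    std::priority_queue<Pending, std::vector<Pending>, PendCmp> q;

    double t = 0.0;
    int gridNext = 0;
    long seq = 0;
    std::vector<double> h(v);

    auto recordUpTo = [&](double tev) {
        while (gridNext <= T && static_cast<double>(gridNext) < tev) {
            for (int j = 0; j < u; ++j)
                traj(j, gridNext) = static_cast<int>(z[j]);
            ++gridNext;
        }
    };

    for (;;) {
        double h0 = 0.0;
        for (int k = 0; k < v; ++k) {
            h[k] = propensity(propType[k], rate[k], K[k], subs[k], z);
            if (h[k] < 0) stop("negative propensity encountered");
            h0 += h[k];
        }
        double tInit = (h0 > 0) ? t + exp_rand() / h0 : R_PosInf;
        double tComp = q.empty() ? R_PosInf : q.top().t_complete;
        double tev = std::min(tInit, tComp);
        if (!R_FINITE(tev) || tev > T) break;
        recordUpTo(tev);
        if (tComp <= tInit) {                       // completion
            Pending p = q.top();
            q.pop();
            t = p.t_complete;
            for (int j = 0; j < u; ++j)             // deliver products
                z[j] += netchange(p.k, j) + reactant(p.k, j);
            evInit.push_back(p.t_init);
            evComp.push_back(t);
            evType.push_back(p.k + 1);
            int bin = static_cast<int>(std::ceil(t));
            if (bin < 1) bin = 1;
            if (bin > T) bin = T;
            counts(p.k, bin - 1) += 1;
        } else {                                    // initiation
            t = tInit;
            double uu = unif_rand() * h0;
            int k = 0;
            double acc = h[0];
            while (uu > acc && k < v - 1) acc += h[++k];
            NumericVector sh = delayShapes[k], rt = delayRates[k];
            if (sh.size() == 0) {                   // undelayed: instant
                for (int j = 0; j < u; ++j) z[j] += netchange(k, j);
                evInit.push_back(t);
                evComp.push_back(t);
                evType.push_back(k + 1);
                int bin = static_cast<int>(std::ceil(t));
                if (bin < 1) bin = 1;
                if (bin > T) bin = T;
                counts(k, bin - 1) += 1;
            } else {
                for (int j = 0; j < u; ++j) z[j] -= reactant(k, j);
                double delta = 0.0;
                for (int c = 0; c < sh.size(); ++c)
                    delta += R::rgamma(sh[c], 1.0 / rt[c]);
                q.push({t + delta, t, k, seq++});
            }
        }
    }
    recordUpTo(static_cast<double>(T) + 0.5);

    int nPend = q.size();
    NumericVector pInit(nPend), pComp(nPend);
    IntegerVector pType(nPend);
    for (int i = 0; i < nPend; ++i) {
        Pending p = q.top();
        q.pop();
        pInit[i] = p.t_init;
        pComp[i] = p.t_complete;
        pType[i] = p.k + 1;
    }
    return List::create(
        _["traj"] = traj, _["counts"] = counts,
        _["event_init"] = wrap(evInit), _["event_complete"] = wrap(evComp),
        _["event_type"] = wrap(evType),
        _["pending_init"] = pInit, _["pending_complete"] = pComp,
        _["pending_type"] = pType);
}

// Delayed tau-leaping on the unit measurement grid.  Per interval i and
// reaction k the completion count is Poisson with mean equal to the
// interpolated completion propensity; the lag-0 term (which would need
// the yet-unknown state z(i)) is evaluated at z(i-1).  Counts of
// reactant-consuming reactions are truncated to the feasible range so
// the state never goes negative.
// [[Rcpp::export]]
List cpp_tau_leap(IntegerMatrix reactant, IntegerMatrix netchange,
                  IntegerVector propType, NumericVector rate,
                  NumericVector K, IntegerVector subs, List weights,
                  IntegerVector z0, int T, int startFrom = 0,
                  Nullable<IntegerMatrix> prevTraj = R_NilValue,
                  Nullable<IntegerMatrix> prevCounts = R_NilValue) {
    const int v = reactant.nrow(), u = reactant.ncol();
    std::vector<double> z(u);
    for (int j = 0; j < u; ++j) z[j] = z0[j];

    std::vector<bool> consuming(v, false);
    for (int k = 0; k < v; ++k)
        for (int j = 0; j < u; ++j)
            if (reactant(k, j) > 0) consuming[k] = true;

    NumericMatrix H(v, T + 1);
    for (int k = 0; k < v; ++k)
        H(k, 0) = propensity(propType[k], rate[k], K[k], subs[k], z);

    IntegerMatrix traj(u, T + 1);
    for (int j = 0; j < u; ++j) traj(j, 0) = z0[j];
    IntegerMatrix counts(v, T);

    // Partial re-simulation: keep the incumbent's history up to time
    // startFrom and continue the leaping from there.  The retained
    // prefix fixes the states entering the delay convolution, so the
    // proposal is the model's conditional law of the remaining counts.
    if (startFrom > 0) {
        IntegerMatrix pT(prevTraj), pC(prevCounts);
        std::vector<double> zz(u);
        for (int i = 0; i <= startFrom; ++i) {
            for (int j = 0; j < u; ++j) {
                traj(j, i) = pT(j, i);
                zz[j] = pT(j, i);
            }
            for (int k = 0; k < v; ++k)
                H(k, i) = propensity(propType[k], rate[k], K[k], subs[k],
                                     zz);
            if (i > 0)
                for (int k = 0; k < v; ++k) counts(k, i - 1) = pC(k, i - 1);
        }
        for (int j = 0; j < u; ++j) z[j] = pT(j, startFrom);
    }

    for (int i = startFrom + 1; i <= T; ++i) {
        // Lagged part of the completion propensity (lags >= 1).
        std::vector<double> flag(v, 0.0), fhat(v, 0.0), w0(v, 0.0);
        for (int k = 0; k < v; ++k) {
            NumericVector w = weights[k];
            const int L = w.size();
            w0[k] = w[0];
            double f = 0.0;
            for (int j = 1; j < L && j <= i; ++j) f += w[j] * H(k, i - j);
            flag[k] = f;
        }
        // Predictor: the lag-0 term needs h at the yet-unknown z(i);
        // evaluate it at the expected end-of-interval state.
        for (int k = 0; k < v; ++k) fhat[k] = flag[k] + w0[k] * H(k, i - 1);
        std::vector<double> zhat(z);
        for (int k = 0; k < v; ++k)
            for (int j = 0; j < u; ++j) zhat[j] += netchange(k, j) * fhat[k];
        for (int j = 0; j < u; ++j) if (zhat[j] < 0) zhat[j] = 0;
        for (int k = 0; k < v; ++k)
            fhat[k] = flag[k] + w0[k] *
                propensity(propType[k], rate[k], K[k], subs[k], zhat);
        // production reactions first, then consumers against the updated
        // tentative state (keeps the reconstruction indicator chi = 1).
        for (int pass = 0; pass < 2; ++pass) {
            for (int k = 0; k < v; ++k) {
                if (consuming[k] != (pass == 1)) continue;
                int r = 0;
                if (!consuming[k]) {
                    r = (fhat[k] > 0) ? static_cast<int>(R::rpois(fhat[k]))
                                      : 0;
                } else {
                    double cap = R_PosInf;
                    for (int j = 0; j < u; ++j)
                        if (reactant(k, j) > 0)
                            cap = std::min(cap,
                                           std::floor(z[j] / reactant(k, j)));
                    if (fhat[k] <= 0) {
                        r = 0;
                    } else if (!R_FINITE(cap)) {
                        r = static_cast<int>(R::rpois(fhat[k]));
                    } else {
                        double pc = R::ppois(cap, fhat[k], 1, 0);
                        if (pc <= 0) {
                            r = static_cast<int>(cap);
                        } else {
                            double uu = unif_rand() * pc;
                            r = static_cast<int>(
                                R::qpois(uu, fhat[k], 1, 0));
                            if (r > cap) r = static_cast<int>(cap);
                        }
                    }
                }
                counts(k, i - 1) = r;
                for (int j = 0; j < u; ++j) z[j] += netchange(k, j) * r;
            }
        }
        for (int j = 0; j < u; ++j) traj(j, i) = static_cast<int>(z[j]);
        for (int k = 0; k < v; ++k)
            H(k, i) = propensity(propType[k], rate[k], K[k], subs[k], z);
    }
    return List::create(_["traj"] = traj, _["counts"] = counts);
}

// Interpolated completion propensity f-hat for every reaction and
// interval, given the initiation propensities H (reactions x 0..T) and
// per-reaction lag weights.  The delay distribution is restricted to
// [0, i] for early intervals (initiations cannot predate time 0).
// [[Rcpp::export]]
NumericMatrix cpp_fhat(NumericMatrix H, List weights) {
    const int v = H.nrow();
    const int T = H.ncol() - 1;
    NumericMatrix out(v, T);
    for (int k = 0; k < v; ++k) {
        NumericVector w = weights[k];
        const int L = w.size();
        for (int i = 1; i <= T; ++i) {
            double f = 0.0;
            for (int j = 0; j < L && j <= i; ++j) f += w[j] * H(k, i - j);
            out(k, i - 1) = f;
        }
    }
    return out;
}

// Local level-shift Metropolis moves on the latent counts of one cell:
// propose +-1 on a single per-interval completion count, which shifts
// the reconstructed trajectory suffix by the reaction's net change.
// The acceptance ratio is the exact change of the joint target
// (Poisson count likelihood x Gaussian observation likelihood); the
// +-1 proposal is symmetric.  These moves keep the incumbent's
// data-matched path shape while letting its level drift, which is the
// slow direction of the simulation-based proposals.
//
// HU (reactions x 0..T) and FU (reactions x 1..T) are the rate-free
// initiation and completion propensities; they, together with traj and
// counts, are updated in place on acceptance.
// [[Rcpp::export]]
List cpp_level_moves(IntegerMatrix reactant, IntegerMatrix netchange,
                     IntegerVector propType, NumericVector rate,
                     NumericVector K, IntegerVector subs, List weights,
                     IntegerMatrix traj, IntegerMatrix counts,
                     NumericMatrix HU, NumericMatrix FU,
                     IntegerVector obsIdx, NumericMatrix yobs,
                     double sigmaE, int nMoves) {
    const int v = reactant.nrow(), u = reactant.ncol();
    const int T = counts.ncol();
    int accepted = 0;

    std::vector<double> hu1(v), fu1(v);
    NumericMatrix HUp(v, T + 1), FUp(v, T);

    for (int mv = 0; mv < nMoves; ++mv) {
        int k = static_cast<int>(unif_rand() * v);
        if (k >= v) k = v - 1;
        int i = 1 + static_cast<int>(unif_rand() * T);
        if (i > T) i = T;
        int mag = 1 + static_cast<int>(unif_rand() * 4);
        if (mag > 4) mag = 4;
        int delta = (unif_rand() < 0.5) ? mag : -mag;
        int r0 = counts(k, i - 1);
        if (r0 + delta < 0) continue;

        // feasibility of the shifted suffix
        bool feasible = true;
        for (int j = 0; j < u && feasible; ++j) {
            int nc = netchange(k, j);
            if (nc == 0) continue;
            if (delta * nc < 0) {
                for (int t = i; t <= T; ++t)
                    if (traj(j, t) + delta * nc < 0) { feasible = false;
                        break; }
            }
        }
        if (!feasible) continue;

        // which reactions' initiation propensities the shift touches
        std::vector<bool> affected(v, false);
        for (int kk = 0; kk < v; ++kk)
            if (propType[kk] != 0 && netchange(k, subs[kk]) != 0)
                affected[kk] = true;

        // shifted rate-free initiation propensities on the suffix
        for (int t = i; t <= T; ++t) {
            for (int kk = 0; kk < v; ++kk) {
                if (!affected[kk]) continue;
                double s = traj(subs[kk], t) +
                    delta * netchange(k, subs[kk]);
                HUp(kk, t) = (propType[kk] == 1) ? s : s / (K[kk] + s);
            }
        }

        // change of the Poisson count log-likelihood over the suffix
        // (only affected reactions change f-hat; the moved count's own
        // Poisson term changes even if its propensity does not)
        double dll = 0.0;
        bool ok = true;
        {
            double fOwn = rate[k] * FU(k, i - 1);
            if (r0 + delta > 0 && fOwn <= 0) ok = false;
            else dll += delta * ((fOwn > 0) ? log(fOwn) : 0.0) -
                (R::lgammafn(r0 + delta + 1.0) - R::lgammafn(r0 + 1.0));
        }
        for (int ip = i; ip <= T && ok; ++ip) {
            for (int kk = 0; kk < v; ++kk) {
                if (!affected[kk]) continue;
                NumericVector w = weights[kk];
                const int L = w.size();
                double f = 0.0;
                for (int j = 0; j < L && j <= ip; ++j) {
                    int t = ip - j;
                    f += w[j] * ((t >= i) ? HUp(kk, t) : HU(kk, t));
                }
                FUp(kk, ip - 1) = f;
                double fNew = rate[kk] * f;
                double fOld = rate[kk] * FU(kk, ip - 1);
                int r = counts(kk, ip - 1);
                if (kk == k && ip == i) r = r0 + delta;
                if (r > 0 && fNew <= 0) { ok = false; break; }
                if (r > 0) dll += r * (log(fNew) - log(fOld));
                dll -= fNew - fOld;
            }
        }
        if (!ok) continue;

        // change of the observation log-likelihood
        for (int o = 0; o < obsIdx.size(); ++o) {
            int j = obsIdx[o];
            int nc = netchange(k, j);
            if (nc == 0) continue;
            for (int t = i; t <= T; ++t) {
                double y0 = traj(j, t);
                double y1 = y0 + delta * nc;
                double v0 = y0 + sigmaE, v1 = y1 + sigmaE;
                if (v1 <= 0) { ok = false; break; }
                double res0 = yobs(o, t) - y0, res1 = yobs(o, t) - y1;
                dll += -0.5 * (log(v1) + res1 * res1 / v1) +
                        0.5 * (log(v0) + res0 * res0 / v0);
            }
            if (!ok) break;
        }
        if (!ok) continue;

        if (dll >= 0 || log(unif_rand()) < dll) {
            counts(k, i - 1) = r0 + delta;
            for (int t = i; t <= T; ++t) {
                for (int j = 0; j < u; ++j)
                    traj(j, t) += delta * netchange(k, j);
                for (int kk = 0; kk < v; ++kk) {
                    if (!affected[kk]) continue;
                    HU(kk, t) = HUp(kk, t);
                    FU(kk, t - 1) = FUp(kk, t - 1);
                }
            }
            ++accepted;
        }
    }
    return List::create(_["accepted"] = accepted);
}
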