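// Diploid Li-Stephens HMM on a segmented genotype graph.
//
// State at segment s: (c, k1, k2) = local haplotype configuration plus the
// conditioning haplotype copied by each of the two target haplotypes.
// Transitions between segments factorize over the two haploid chains with
// the stay/switch kernel T = (stay - sw) I + sw 11'; emissions accumulate
// per site within a segment against the copied haplotypes (the homozygous
// part in log space with a per-segment shift so long runs never underflow);
// phase-set factors enter as local weights on configurations (within a
// segment) or configuration pairs (across one boundary).
//
// Factorized representation: the joint forward quantity at segment s is
//   alpha_s(c, k1, k2) = S_s[c](k1, k2) * E1_s(c, k1) * E2_s(c, k2)
// where S_s is the transition-propagated mass entering the segment. At a
// boundary without phase-set weights S is shared by all configurations, so
// one K x K matrix per segment replaces the nconf K x K slices of a dense
// implementation; configuration-pair weights make S configuration-specific
// ("split") only where reads actually constrain a boundary. T (x) T is
// applied through rank-one updates (row/column marginals), the stochastic
// traceback samples the exact transition kernel through its four-component
// mixture decomposition (diagonal^2 / diagonal x uniform / uniform^2), and
// boundary posteriors over configuration pairs come from an analogous
// backward recursion. Workspaces are static and reused across calls (R is
// single-threaded) to avoid reallocating large buffers per individual.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Seg {
  std::vector<int> sites;   // global site indices (columns of H)
  std::vector<int> fixed;   // per site: -1 ambiguous, else 0/1
  std::vector<int> amb;     // offsets into sites that are ambiguous
  IntegerMatrix conf1, conf2;  // nconf x namb
  std::vector<double> wt;   // nconf multiplicative weights (phase sets)
  int nconf;
};

static double theta_watterson(int K) {
  if (K < 2) return 1.0;
  double h = 0.0;
  for (int k = 1; k <= K - 1; ++k) h += 1.0 / k;
  return 1.0 / h;
}

// stay/switch kernel for one haploid chain across g centimorgans
static void stay_switch(double g_cm, int K, double Ne, int Nhap,
                        double* stay, double* sw) {
  if (g_cm < 1e-7) g_cm = 1e-7;
  const double rho = 4.0 * Ne * (g_cm / 100.0) / (double)Nhap;
  const double e = std::exp(-rho / (double)K);
  *sw = (1.0 - e) / (double)K;
  *stay = e + *sw;
}

// g = (T (x) T) a for one K x K slice, via row/column marginals
static void apply_T2(const double* a, double* g, double* um, double* vm,
                     int K, double stay, double sw) {
  double t = 0.0;
  for (int k = 0; k < K; ++k) { um[k] = 0.0; vm[k] = 0.0; }
  for (int k1 = 0; k1 < K; ++k1) {
    const double* row = a + (size_t)k1 * K;
    double rs = 0.0;
    for (int k2 = 0; k2 < K; ++k2) { rs += row[k2]; vm[k2] += row[k2]; }
    um[k1] = rs; t += rs;
  }
  const double e = stay - sw;  // diagonal coefficient of T
  const double ss = e * e, sx = e * sw, xx = sw * sw * t;
  for (int k1 = 0; k1 < K; ++k1) {
    const double* row = a + (size_t)k1 * K;
    const double uterm = sx * um[k1] + xx;
    double* grow = g + (size_t)k1 * K;
    for (int k2 = 0; k2 < K; ++k2)
      grow[k2] = ss * row[k2] + sx * vm[k2] + uterm;
  }
}

// [[Rcpp::export]]
List cpp_hmm_run(const List& seg_sites, const List& seg_fixed,
                 const List& seg_amb, const List& seg_conf1,
                 const List& seg_conf2, const List& seg_wt,
                 const List& bound_wt, const NumericVector& bound_gcm,
                 const IntegerVector& cond, IntegerMatrix H,
                 double Ne, int Nhap, int n_sample, bool want_post,
                 int write1, int write2) {
  const int nseg = seg_sites.size();
  const int K = cond.size();
  if (K < 1) stop("empty conditioning set");
  const size_t KK = (size_t)K * K;

  const double theta = theta_watterson(K);
  const double pm = ((double)K + 0.5 * theta) / ((double)K + theta);
  const double px = (0.5 * theta) / ((double)K + theta);
  const double lpm = std::log(pm), lpx = std::log(px);

  // unpack segments
  std::vector<Seg> segs(nseg);
  int max_conf = 1;
  for (int s = 0; s < nseg; ++s) {
    Seg& sg = segs[s];
    sg.sites = as<std::vector<int>>(seg_sites[s]);
    sg.fixed = as<std::vector<int>>(seg_fixed[s]);
    sg.amb = as<std::vector<int>>(seg_amb[s]);
    sg.conf1 = as<IntegerMatrix>(seg_conf1[s]);
    sg.conf2 = as<IntegerMatrix>(seg_conf2[s]);
    sg.nconf = sg.conf1.nrow();
    if (sg.nconf < 1) stop("segment with zero configurations");
    RObject w = seg_wt[s];
    if (w.isNULL()) sg.wt.assign(sg.nconf, 1.0);
    else sg.wt = as<std::vector<double>>(w);
    max_conf = std::max(max_conf, sg.nconf);
  }
  std::vector<bool> haveW(std::max(nseg - 1, 0));
  std::vector<NumericMatrix> Wm(std::max(nseg - 1, 0));
  for (int s = 0; s + 1 < nseg; ++s) {
    RObject wob = bound_wt[s];
    haveW[s] = !wob.isNULL();
    if (haveW[s]) Wm[s] = as<NumericMatrix>(wob);
  }

  // emission tables (per segment, nconf x K); phase-set configuration
  // weight and the hom-emission log shift folded into E1
  std::vector<size_t> eoff(nseg + 1, 0);
  for (int s = 0; s < nseg; ++s)
    eoff[s + 1] = eoff[s] + (size_t)segs[s].nconf * K;
  static std::vector<double> E1, E2, lhom;
  E1.assign(eoff[nseg], 0.0);
  E2.assign(eoff[nseg], 0.0);
  lhom.resize(K);
  double logoff = 0.0;
  for (int s = 0; s < nseg; ++s) {
    Seg& sg = segs[s];
    const int ns = (int)sg.sites.size(), namb = (int)sg.amb.size();
    int nhom = 0;
    for (int k = 0; k < K; ++k) lhom[k] = 0.0;
    for (int t = 0; t < ns; ++t) {
      const int fx = sg.fixed[t];
      if (fx < 0) continue;
      ++nhom;
      const int* col = &H(0, sg.sites[t]);
      for (int k = 0; k < K; ++k) lhom[k] += (col[cond[k]] == fx) ? lpm : lpx;
    }
    double shift = lhom[0];
    for (int k = 1; k < K; ++k) shift = std::max(shift, lhom[k]);
    if (nhom == 0) shift = 0.0;
    logoff += 2.0 * shift;  // both chains share the hom emission table
    double* e1 = &E1[eoff[s]];
    double* e2 = &E2[eoff[s]];
    for (int k = 0; k < K; ++k) lhom[k] = std::exp(lhom[k] - shift);
    for (int c = 0; c < sg.nconf; ++c) {
      for (int k = 0; k < K; ++k) {
        const double eh = lhom[k];
        double v1 = eh, v2 = eh;
        for (int a = 0; a < namb; ++a) {
          const int site = sg.sites[sg.amb[a]];
          const int obs = H(cond[k], site);
          v1 *= (sg.conf1(c, a) == obs) ? pm : px;
          v2 *= (sg.conf2(c, a) == obs) ? pm : px;
        }
        e1[c * K + k] = v1 * sg.wt[c];
        e2[c * K + k] = v2;
      }
    }
  }

  // transition parameters per boundary
  std::vector<double> stayv(std::max(nseg - 1, 0)), swv(std::max(nseg - 1, 0));
  for (int s = 0; s + 1 < nseg; ++s)
    stay_switch(bound_gcm[s], K, Ne, Nhap, &stayv[s], &swv[s]);

  // S storage: shared (KK) or split (nconf*KK) per segment
  std::vector<bool> split(nseg, false);
  split[0] = false;
  for (int s = 1; s < nseg; ++s) split[s] = haveW[s - 1];
  std::vector<size_t> soff(nseg + 1, 0);
  for (int s = 0; s < nseg; ++s)
    soff[s + 1] = soff[s] + (split[s] ? (size_t)segs[s].nconf * KK : KK);
  static std::vector<double> S, Abuf, Gsplit, um, vm;
  S.assign(soff[nseg], 0.0);
  Abuf.resize(KK);
  um.resize(K); vm.resize(K);
  std::vector<double> logz(nseg, 0.0);
  std::vector<std::vector<double>> cSum(nseg);  // per-config mass, sampler

  // S slice for (segment, config)
  auto Sat = [&](int s, int c) -> const double* {
    return &S[soff[s] + (split[s] ? (size_t)c * KK : 0)];
  };

  // forward
  {
    double* s0 = &S[0];
    const double v = 1.0 / (double)KK;
    for (size_t t = 0; t < KK; ++t) s0[t] = v;
  }
  double zlast = 0.0;
  for (int s = 0; s < nseg; ++s) {
    const int nc = segs[s].nconf;
    const double* e1 = &E1[eoff[s]];
    const double* e2 = &E2[eoff[s]];
    // per-config mass and the config-summed joint A = sum_c alpha_s(c),
    // in one pass over S (shared case) with the config loop innermost on
    // transposed emission tables so it vectorizes
    cSum[s].assign(nc, 0.0);
    if (!split[s]) {
      static std::vector<double> e2t, f1buf, csacc;
      e2t.assign((size_t)K * nc, 0.0);
      for (int c = 0; c < nc; ++c)
        for (int k = 0; k < K; ++k) e2t[(size_t)k * nc + c] = e2[c * K + k];
      f1buf.resize(nc);
      csacc.assign(nc, 0.0);
      const double* sl = Sat(s, 0);
      for (int k1 = 0; k1 < K; ++k1) {
        for (int c = 0; c < nc; ++c) f1buf[c] = e1[c * K + k1];
        const double* srow = sl + (size_t)k1 * K;
        double* arow = &Abuf[(size_t)k1 * K];
        for (int k2 = 0; k2 < K; ++k2) {
          const double sval = srow[k2];
          const double* e2row = &e2t[(size_t)k2 * nc];
          double asum = 0.0;
          for (int c = 0; c < nc; ++c) {
            const double v = f1buf[c] * e2row[c];
            asum += v;
            csacc[c] += sval * v;
          }
          arow[k2] = sval * asum;
        }
      }
      for (int c = 0; c < nc; ++c) cSum[s][c] = csacc[c];
    } else {
      std::fill(Abuf.begin(), Abuf.end(), 0.0);
      for (int c = 0; c < nc; ++c) {
        const double* sl = Sat(s, c);
        double tot = 0.0;
        for (int k1 = 0; k1 < K; ++k1) {
          const double f1 = e1[c * K + k1];
          const double* srow = sl + (size_t)k1 * K;
          double* arow = &Abuf[(size_t)k1 * K];
          double rtot = 0.0;
          for (int k2 = 0; k2 < K; ++k2) {
            const double v = srow[k2] * e2[c * K + k2];
            arow[k2] += f1 * v;
            rtot += v;
          }
          tot += f1 * rtot;
        }
        cSum[s][c] = tot;
      }
    }
    double z = 0.0;
    for (int c = 0; c < nc; ++c) z += cSum[s][c];
    if (!(z > 0.0))
      stop("HMM underflow or inconsistent constraints at segment %d", s + 1);
    logz[s] = std::log(z);
    if (s == nseg - 1) { zlast = z; break; }
    const double inv = 1.0 / z;
    // propagate: S_{s+1} = T2(A / z), mixed over boundary weights if any
    if (!haveW[s]) {
      for (size_t t = 0; t < KK; ++t) Abuf[t] *= inv;
      apply_T2(&Abuf[0], &S[soff[s + 1]], &um[0], &vm[0], K, stayv[s], swv[s]);
    } else {
      const int ncn = segs[s + 1].nconf;
      Gsplit.assign((size_t)nc * KK, 0.0);
      static std::vector<double> slice;
      slice.resize(KK);
      for (int c = 0; c < nc; ++c) {
        const double* sl = Sat(s, c);
        for (int k1 = 0; k1 < K; ++k1) {
          const double f1 = e1[c * K + k1] * inv;
          const double* srow = sl + (size_t)k1 * K;
          double* drow = &slice[(size_t)k1 * K];
          for (int k2 = 0; k2 < K; ++k2)
            drow[k2] = f1 * srow[k2] * e2[c * K + k2];
        }
        apply_T2(&slice[0], &Gsplit[(size_t)c * KK], &um[0], &vm[0], K,
                 stayv[s], swv[s]);
      }
      double* snext = &S[soff[s + 1]];
      for (int cn = 0; cn < ncn; ++cn) {
        double* dst = snext + (size_t)cn * KK;
        std::fill(dst, dst + KK, 0.0);
        for (int c = 0; c < nc; ++c) {
          const double w = Wm[s](c, cn);
          if (w == 0.0) continue;
          const double* g = &Gsplit[(size_t)c * KK];
          for (size_t t = 0; t < KK; ++t) dst[t] += w * g[t];
        }
      }
    }
  }
  double loglik = logoff + std::log(zlast);
  for (int s = 0; s + 1 < nseg; ++s) loglik += logz[s];

  // backward pass for boundary posteriors and per-segment marginals
  List post(std::max(nseg - 1, 0)), marg(nseg);
  if (want_post) {
    // beta: shared KK slice, or per-config when the boundary below is
    // weighted; marginals use alpha o beta summed per configuration
    static std::vector<double> beta, betaprev, Ybuf, Hbuf;
    Ybuf.resize(KK); Hbuf.resize(KK);
    bool bsplit = false;
    beta.assign(KK, 1.0);
    {
      NumericVector m(segs[nseg - 1].nconf);
      for (int c = 0; c < m.size(); ++c) m[c] = cSum[nseg - 1][c] / zlast;
      marg[nseg - 1] = m;
    }
    for (int s = nseg - 2; s >= 0; --s) {
      const int ncp = segs[s].nconf, ncn = segs[s + 1].nconf;
      const double* e1n = &E1[eoff[s + 1]];
      const double* e2n = &E2[eoff[s + 1]];
      NumericMatrix P(ncp, ncn);
      const bool wsplit = haveW[s];
      betaprev.assign(wsplit ? (size_t)ncp * KK : KK, 0.0);
      for (int cn = 0; cn < ncn; ++cn) {
        const double* b = bsplit ? &beta[(size_t)cn * KK] : &beta[0];
        for (int k1 = 0; k1 < K; ++k1) {
          const double f1 = e1n[cn * K + k1];
          const double* brow = b + (size_t)k1 * K;
          double* yrow = &Ybuf[(size_t)k1 * K];
          for (int k2 = 0; k2 < K; ++k2)
            yrow[k2] = f1 * e2n[cn * K + k2] * brow[k2];
        }
        apply_T2(&Ybuf[0], &Hbuf[0], &um[0], &vm[0], K, stayv[s], swv[s]);
        // posterior entries and beta accumulation
        for (int cp = 0; cp < ncp; ++cp) {
          const double w = wsplit ? Wm[s](cp, cn) : 1.0;
          if (w == 0.0) { P(cp, cn) = 0.0; continue; }
          const double* sl = Sat(s, cp);
          const double* e1p = &E1[eoff[s] + (size_t)cp * K];
          const double* e2p = &E2[eoff[s] + (size_t)cp * K];
          double dot = 0.0;
          for (int k1 = 0; k1 < K; ++k1) {
            const double f1 = e1p[k1];
            const double* srow = sl + (size_t)k1 * K;
            const double* hrow = &Hbuf[(size_t)k1 * K];
            double rdot = 0.0;
            for (int k2 = 0; k2 < K; ++k2)
              rdot += srow[k2] * e2p[k2] * hrow[k2];
            dot += f1 * rdot;
          }
          P(cp, cn) = w * dot;
          if (wsplit) {
            double* bp = &betaprev[(size_t)cp * KK];
            for (size_t t = 0; t < KK; ++t) bp[t] += w * Hbuf[t];
          }
        }
        if (!wsplit)
          for (size_t t = 0; t < KK; ++t) betaprev[t] += Hbuf[t];
      }
      double ptot = 0.0;
      for (int cp = 0; cp < ncp; ++cp)
        for (int cn = 0; cn < ncn; ++cn) ptot += P(cp, cn);
      if (!(ptot > 0.0)) stop("degenerate boundary posterior at boundary %d", s + 1);
      for (int cp = 0; cp < ncp; ++cp)
        for (int cn = 0; cn < ncn; ++cn) P(cp, cn) /= ptot;
      post[s] = P;
      // marginal over configurations at segment s, and beta rescale
      NumericVector m(ncp);
      double mtot = 0.0, bmax = 0.0;
      for (double x : betaprev) bmax = std::max(bmax, x);
      const double binv = bmax > 0 ? 1.0 / bmax : 1.0;
      for (double& x : betaprev) x *= binv;
      for (int cp = 0; cp < ncp; ++cp) {
        const double* bl = wsplit ? &betaprev[(size_t)cp * KK] : &betaprev[0];
        const double* sl = Sat(s, cp);
        const double* e1p = &E1[eoff[s] + (size_t)cp * K];
        const double* e2p = &E2[eoff[s] + (size_t)cp * K];
        double x = 0.0;
        for (int k1 = 0; k1 < K; ++k1) {
          const double f1 = e1p[k1];
          const double* srow = sl + (size_t)k1 * K;
          const double* brow = bl + (size_t)k1 * K;
          double r = 0.0;
          for (int k2 = 0; k2 < K; ++k2) r += srow[k2] * e2p[k2] * brow[k2];
          x += f1 * r;
        }
        m[cp] = x; mtot += x;
      }
      for (int cp = 0; cp < ncp; ++cp) m[cp] /= mtot;
      marg[s] = m;
      beta.swap(betaprev);
      bsplit = wsplit;
    }
  }

  // stochastic traceback via the mixture decomposition of T (x) T
  IntegerMatrix samples(nseg, std::max(n_sample, 0));
  for (int dr = 0; dr < n_sample; ++dr) {
    int cs = 0, k1s = 0, k2s = 0;
    {
      // last segment: config from cSum, then k1 | c, then k2 | c, k1
      const int nc = segs[nseg - 1].nconf;
      const double* e1 = &E1[eoff[nseg - 1]];
      const double* e2 = &E2[eoff[nseg - 1]];
      double u = unif_rand() * zlast, acc = 0.0;
      cs = nc - 1;
      for (int c = 0; c < nc; ++c) {
        acc += cSum[nseg - 1][c];
        if (acc >= u) { cs = c; break; }
      }
      const double* sl = Sat(nseg - 1, cs);
      double rtot = 0.0;
      for (int k1 = 0; k1 < K; ++k1) {
        const double* srow = sl + (size_t)k1 * K;
        double r = 0.0;
        for (int k2 = 0; k2 < K; ++k2) r += srow[k2] * e2[cs * K + k2];
        um[k1] = e1[cs * K + k1] * r;
        rtot += um[k1];
      }
      u = unif_rand() * rtot; acc = 0.0; k1s = K - 1;
      for (int k1 = 0; k1 < K; ++k1) {
        acc += um[k1];
        if (acc >= u) { k1s = k1; break; }
      }
      const double* srow = sl + (size_t)k1s * K;
      double ctot = 0.0;
      for (int k2 = 0; k2 < K; ++k2) {
        vm[k2] = srow[k2] * e2[cs * K + k2];
        ctot += vm[k2];
      }
      u = unif_rand() * ctot; acc = 0.0; k2s = K - 1;
      for (int k2 = 0; k2 < K; ++k2) {
        acc += vm[k2];
        if (acc >= u) { k2s = k2; break; }
      }
    }
    samples(nseg - 1, dr) = cs;
    for (int s = nseg - 2; s >= 0; --s) {
      const int ncp = segs[s].nconf;
      const double stay = stayv[s], sw = swv[s];
      const double ed = stay - sw;
      const double ss = ed * ed, sx = ed * sw, xx = sw * sw;
      const bool wsplit = haveW[s];
      const double* e1 = &E1[eoff[s]];
      const double* e2 = &E2[eoff[s]];
      // per-config pieces at the fixed target pair (k1s, k2s):
      //   aY[c]  = alpha_s(c, k1s, k2s)
      //   uY[c]  = sum_k2 alpha_s(c, k1s, k2)   (row slice)
      //   vY[c]  = sum_k1 alpha_s(c, k1, k2s)   (column slice)
      //   tY[c]  = cSum[s][c]
      // each weighted by w(c, cs) when the boundary carries weights
      double Wss = 0.0, Wsu = 0.0, Wus = 0.0, Wuu = 0.0;
      static std::vector<double> aY, uY, vY, tY;
      aY.assign(ncp, 0.0); uY.assign(ncp, 0.0);
      vY.assign(ncp, 0.0); tY.assign(ncp, 0.0);
      for (int c = 0; c < ncp; ++c) {
        const double w = wsplit ? Wm[s](c, cs) : 1.0;
        if (w == 0.0) continue;
        const double* sl = Sat(s, c);
        const double f1s = e1[c * K + k1s];
        const double f2s = e2[c * K + k2s];
        const double* srow = sl + (size_t)k1s * K;
        double rsum = 0.0, csum = 0.0;
        for (int k2 = 0; k2 < K; ++k2) rsum += srow[k2] * e2[c * K + k2];
        for (int k1 = 0; k1 < K; ++k1)
          csum += sl[(size_t)k1 * K + k2s] * e1[c * K + k1];
        aY[c] = w * f1s * f2s * srow[k2s];
        uY[c] = w * f1s * rsum;
        vY[c] = w * f2s * csum;
        tY[c] = w * cSum[s][c];
        Wss += aY[c]; Wsu += uY[c]; Wus += vY[c]; Wuu += tY[c];
      }
      const double w1 = ss * Wss, w2 = sx * Wsu, w3 = sx * Wus, w4 = xx * Wuu;
      const double wt = w1 + w2 + w3 + w4;
      if (!(wt > 0.0)) stop("traceback dead end at boundary %d", s + 1);
      double u = unif_rand() * wt;
      int comp = 3;
      if (u < w1) comp = 0;
      else if (u < w1 + w2) comp = 1;
      else if (u < w1 + w2 + w3) comp = 2;
      int cp = 0, k1n = k1s, k2n = k2s;
      auto pick_c = [&](const std::vector<double>& wv, double tot) {
        double uu = unif_rand() * tot, a = 0.0;
        int out = ncp - 1;
        for (int c = 0; c < ncp; ++c) { a += wv[c]; if (a >= uu) { out = c; break; } }
        return out;
      };
      if (comp == 0) {               // both chains stay on the diagonal
        cp = pick_c(aY, Wss);
      } else if (comp == 1) {        // k1 stays, k2 from the uniform part
        cp = pick_c(uY, Wsu);
        const double* sl = Sat(s, cp);
        const double* srow = sl + (size_t)k1s * K;
        double tot = 0.0;
        for (int k2 = 0; k2 < K; ++k2) {
          vm[k2] = srow[k2] * e2[cp * K + k2];
          tot += vm[k2];
        }
        double uu = unif_rand() * tot, a = 0.0; k2n = K - 1;
        for (int k2 = 0; k2 < K; ++k2) { a += vm[k2]; if (a >= uu) { k2n = k2; break; } }
      } else if (comp == 2) {        // k2 stays, k1 from the uniform part
        cp = pick_c(vY, Wus);
        const double* sl = Sat(s, cp);
        double tot = 0.0;
        for (int k1 = 0; k1 < K; ++k1) {
          um[k1] = sl[(size_t)k1 * K + k2s] * e1[cp * K + k1];
          tot += um[k1];
        }
        double uu = unif_rand() * tot, a = 0.0; k1n = K - 1;
        for (int k1 = 0; k1 < K; ++k1) { a += um[k1]; if (a >= uu) { k1n = k1; break; } }
      } else {                       // both chains from the uniform part
        cp = pick_c(tY, Wuu);
        const double* sl = Sat(s, cp);
        double tot = 0.0;
        for (int k1 = 0; k1 < K; ++k1) {
          const double* srow = sl + (size_t)k1 * K;
          double r = 0.0;
          for (int k2 = 0; k2 < K; ++k2) r += srow[k2] * e2[cp * K + k2];
          um[k1] = e1[cp * K + k1] * r;
          tot += um[k1];
        }
        double uu = unif_rand() * tot, a = 0.0; k1n = K - 1;
        for (int k1 = 0; k1 < K; ++k1) { a += um[k1]; if (a >= uu) { k1n = k1; break; } }
        const double* srow = sl + (size_t)k1n * K;
        double ctot = 0.0;
        for (int k2 = 0; k2 < K; ++k2) {
          vm[k2] = srow[k2] * e2[cp * K + k2];
          ctot += vm[k2];
        }
        uu = unif_rand() * ctot; a = 0.0; k2n = K - 1;
        for (int k2 = 0; k2 < K; ++k2) { a += vm[k2]; if (a >= uu) { k2n = k2; break; } }
      }
      cs = cp; k1s = k1n; k2s = k2n;
      samples(s, dr) = cs;
    }
  }

  // write first sample into H (engine path)
  if (write1 >= 0 && n_sample > 0) {
    for (int s = 0; s < nseg; ++s) {
      const Seg& sg = segs[s];
      const int c = samples(s, 0);
      int ai = 0;
      for (int t = 0; t < (int)sg.sites.size(); ++t) {
        const int site = sg.sites[t];
        if (sg.fixed[t] >= 0) {
          H(write1, site) = sg.fixed[t];
          H(write2, site) = sg.fixed[t];
        } else {
          H(write1, site) = sg.conf1(c, ai);
          H(write2, site) = sg.conf2(c, ai);
          ++ai;
        }
      }
    }
  }

  return List::create(_["samples"] = samples, _["post"] = post,
                      _["marg"] = marg, _["loglik"] = loglik,
                      _["K"] = K);
}
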