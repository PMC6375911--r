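#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Hierarchical AMOVA on squared inter-individual distances, with the three
// Excoffier-style permutation schemes. Components follow the classical
// expected-mean-square coefficients for unbalanced designs:
//   E(MS within pops)            = s2c
//   E(MS among pops in groups)   = s2c + n1 * s2b
//   E(MS among groups)           = s2c + n2 * s2b + n3 * s2a

struct Amova3 {
  double ssd_ag, ssd_apwg, ssd_wp;
  double df_ag, df_ap, df_wp;
  double s2a, s2b, s2c;
  double phi_st, phi_sc, phi_ct;
};

static Amova3 amova3_core(const NumericMatrix &d2, const std::vector<int> &pop,
                          const std::vector<int> &grp_of_pop, int P, int G) {
  int N = d2.nrow();
  std::vector<double> ss_pop(P, 0.0), ss_grp(G, 0.0);
  std::vector<double> np(P, 0.0), ng(G, 0.0);
  double ss_tot = 0.0;
  for (int i = 0; i < N; ++i) {
    np[pop[i]] += 1.0;
    ng[grp_of_pop[pop[i]]] += 1.0;
  }
  for (int i = 0; i < N; ++i) {
    int pi = pop[i], gi = grp_of_pop[pi];
    for (int j = i + 1; j < N; ++j) {
      double v = d2(i, j);
      ss_tot += v;
      int pj = pop[j];
      if (pi == pj) ss_pop[pi] += v;
      if (gi == grp_of_pop[pj]) ss_grp[gi] += v;
    }
  }
  double sum_ss_pop = 0.0, sum_ss_grp = 0.0;
  for (int p = 0; p < P; ++p)
    if (np[p] > 0) sum_ss_pop += ss_pop[p] / np[p];
  for (int g = 0; g < G; ++g)
    if (ng[g] > 0) sum_ss_grp += ss_grp[g] / ng[g];
  ss_tot /= (double)N;

  Amova3 r;
  r.ssd_wp = sum_ss_pop;
  r.ssd_apwg = sum_ss_grp - sum_ss_pop;
  r.ssd_ag = ss_tot - sum_ss_grp;
  r.df_wp = N - P;
  r.df_ap = P - G;
  r.df_ag = G - 1;

  double A = 0.0, B = 0.0, C = 0.0; // unbalanced-design sums
  std::vector<double> sum_np2_g(G, 0.0);
  for (int p = 0; p < P; ++p) {
    B += np[p] * np[p];
    sum_np2_g[grp_of_pop[p]] += np[p] * np[p];
  }
  B /= (double)N;
  for (int g = 0; g < G; ++g) {
    if (ng[g] > 0) A += sum_np2_g[g] / ng[g];
    C += ng[g] * ng[g];
  }
  C /= (double)N;
  double n1 = (N - A) / r.df_ap;
  double n2 = (A - B) / r.df_ag;
  double n3 = (N - C) / r.df_ag;

  double ms_wp = r.ssd_wp / r.df_wp;
  double ms_ap = r.ssd_apwg / r.df_ap;
  double ms_ag = r.ssd_ag / r.df_ag;
  r.s2c = ms_wp;
  r.s2b = (ms_ap - r.s2c) / n1;
  r.s2a = (ms_ag - r.s2c - n2 * r.s2b) / n3;
  double tot = r.s2a + r.s2b + r.s2c;
  r.phi_st = (r.s2a + r.s2b) / tot;
  r.phi_sc = r.s2b / (r.s2b + r.s2c);
  r.phi_ct = r.s2a / tot;
  return r;
}

static void shuffle(std::vector<int> &v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)(R::unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// [[Rcpp::export]]
List cpp_amova3(NumericMatrix d2, IntegerVector pop, IntegerVector grp_of_pop,
                int n_perm) {
  int N = d2.nrow(), P = grp_of_pop.size();
  int G = 0;
  for (int p = 0; p < P; ++p) G = std::max(G, grp_of_pop[p] + 1);
  std::vector<int> pp(pop.begin(), pop.end());
  std::vector<int> gg(grp_of_pop.begin(), grp_of_pop.end());
  Amova3 obs = amova3_core(d2, pp, gg, P, G);

  int ge_st = 0, ge_sc = 0, ge_ct = 0;
  if (n_perm > 0) {
    // scheme ST: individuals permuted among all populations
    std::vector<int> perm = pp;
    for (int b = 0; b < n_perm; ++b) {
      shuffle(perm);
      Amova3 r = amova3_core(d2, perm, gg, P, G);
      if (!ISNAN(r.phi_st) && r.phi_st >= obs.phi_st) ++ge_st;
    }
    // scheme SC: individuals permuted among populations within their group
    std::vector<std::vector<int> > idx_of_grp(G);
    for (int i = 0; i < N; ++i) idx_of_grp[gg[pp[i]]].push_back(i);
    perm = pp;
    std::vector<int> labs;
    for (int b = 0; b < n_perm; ++b) {
      for (int g = 0; g < G; ++g) {
        labs.clear();
        for (size_t k = 0; k < idx_of_grp[g].size(); ++k)
          labs.push_back(perm[idx_of_grp[g][k]]);
        shuffle(labs);
        for (size_t k = 0; k < idx_of_grp[g].size(); ++k)
          perm[idx_of_grp[g][k]] = labs[k];
      }
      Amova3 r = amova3_core(d2, perm, gg, P, G);
      if (!ISNAN(r.phi_sc) && r.phi_sc >= obs.phi_sc) ++ge_sc;
    }
    // scheme CT: whole populations permuted among groups
    std::vector<int> gperm = gg;
    for (int b = 0; b < n_perm; ++b) {
      shuffle(gperm);
      Amova3 r = amova3_core(d2, pp, gperm, P, G);
      if (!ISNAN(r.phi_ct) && r.phi_ct >= obs.phi_ct) ++ge_ct;
    }
  }
  double B1 = (double)n_perm + 1.0;
  double p_st = ISNAN(obs.phi_st) ? NA_REAL : (ge_st + 1.0) / B1;
  double p_sc = ISNAN(obs.phi_sc) ? NA_REAL : (ge_sc + 1.0) / B1;
  double p_ct = ISNAN(obs.phi_ct) ? NA_REAL : (ge_ct + 1.0) / B1;
  return List::create(
      _["ssd"] = NumericVector::create(obs.ssd_ag, obs.ssd_apwg, obs.ssd_wp),
      _["df"] = NumericVector::create(obs.df_ag, obs.df_ap, obs.df_wp),
      _["sigma2"] = NumericVector::create(obs.s2a, obs.s2b, obs.s2c),
      _["phi"] = NumericVector::create(obs.phi_st, obs.phi_sc, obs.phi_ct),
      _["p"] = NumericVector::create(p_st, p_sc, p_ct));
}

// Two-level AMOVA (individuals in populations) with permutation test on
// Phi_ST; used for pairwise population comparisons.
static void amova2_core(const NumericMatrix &d2, const std::vector<int> &pop,
                        int P, double *s2a, double *s2w, double *phi) {
  int N = d2.nrow();
  std::vector<double> ss_pop(P, 0.0), np(P, 0.0);
  double ss_tot = 0.0;
  for (int i = 0; i < N; ++i) np[pop[i]] += 1.0;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double v = d2(i, j);
      ss_tot += v;
      if (pop[i] == pop[j]) ss_pop[pop[i]] += v;
    }
  ss_tot /= (double)N;
  double ssd_wp = 0.0, B = 0.0;
  for (int p = 0; p < P; ++p) {
    if (np[p] > 0) ssd_wp += ss_pop[p] / np[p];
    B += np[p] * np[p];
  }
  double ssd_ap = ss_tot - ssd_wp;
  double nc = (N - B / (double)N) / (P - 1.0);
  double ms_wp = ssd_wp / (double)(N - P);
  double ms_ap = ssd_ap / (double)(P - 1);
  *s2w = ms_wp;
  *s2a = (ms_ap - ms_wp) / nc;
  *phi = *s2a / (*s2a + *s2w);
}

// [[Rcpp::export]]
List cpp_amova2(NumericMatrix d2, IntegerVector pop, int n_perm) {
  int P = 0;
  for (int i = 0; i < pop.size(); ++i) P = std::max(P, pop[i] + 1);
  std::vector<int> pp(pop.begin(), pop.end());
  double s2a, s2w, phi;
  amova2_core(d2, pp, P, &s2a, &s2w, &phi);
  int ge = 0;
  std::vector<int> perm = pp;
  for (int b = 0; b < n_perm; ++b) {
    shuffle(perm);
    double a, w, f;
    amova2_core(d2, perm, P, &a, &w, &f);
    if (!ISNAN(f) && f >= phi) ++ge;
  }
  double pval = ISNAN(phi) ? NA_REAL : (ge + 1.0) / (n_perm + 1.0);
  return List::create(_["sigma2"] = NumericVector::create(s2a, s2w),
                      _["phi_st"] = phi, _["p"] = pval);
}

// Locus-by-locus hierarchical AMOVA for biallelic genotype codes 0/1/2
// (missing = -1): per-locus components on complete cases, using the
// within-set sum-of-squares identity SS = sum(g^2) - sum(g)^2 / n for the
// squared allele-count difference distance, summed over loci; Phi statistics
// from the summed components.
struct LociComp { double s2a, s2b, s2c; int used; };

static LociComp amova_loci_core(const IntegerMatrix &geno,
                                const std::vector<int> &pop,
                                const std::vector<int> &grp_of_pop, int P,
                                int G) {
  int N = geno.nrow(), L = geno.ncol();
  LociComp out = {0.0, 0.0, 0.0, 0};
  std::vector<double> n_p(P), s_p(P), q_p(P);
  std::vector<double> n_g(G), s_g(G), q_g(G), np2_g(G);
  for (int l = 0; l < L; ++l) {
    std::fill(n_p.begin(), n_p.end(), 0.0);
    std::fill(s_p.begin(), s_p.end(), 0.0);
    std::fill(q_p.begin(), q_p.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      int g = geno(i, l);
      if (g < 0) continue;
      int p = pop[i];
      n_p[p] += 1.0;
      s_p[p] += g;
      q_p[p] += (double)g * g;
    }
    std::fill(n_g.begin(), n_g.end(), 0.0);
    std::fill(s_g.begin(), s_g.end(), 0.0);
    std::fill(q_g.begin(), q_g.end(), 0.0);
    std::fill(np2_g.begin(), np2_g.end(), 0.0);
    double Nl = 0.0, St = 0.0, Qt = 0.0;
    int Pl = 0;
    for (int p = 0; p < P; ++p) {
      if (n_p[p] <= 0) continue;
      ++Pl;
      int g = grp_of_pop[p];
      n_g[g] += n_p[p];
      s_g[g] += s_p[p];
      q_g[g] += q_p[p];
      np2_g[g] += n_p[p] * n_p[p];
      Nl += n_p[p];
      St += s_p[p];
      Qt += q_p[p];
    }
    int Gl = 0;
    for (int g = 0; g < G; ++g)
      if (n_g[g] > 0) ++Gl;
    double df_wp = Nl - Pl, df_ap = Pl - Gl, df_ag = Gl - 1;
    if (df_wp < 1 || df_ap < 1 || df_ag < 1) continue;
    double ssd_wp = 0.0, sum_ss_grp = 0.0, A = 0.0, B = 0.0, C = 0.0;
    for (int p = 0; p < P; ++p) {
      if (n_p[p] <= 0) continue;
      ssd_wp += q_p[p] - s_p[p] * s_p[p] / n_p[p];
      B += n_p[p] * n_p[p];
    }
    for (int g = 0; g < G; ++g) {
      if (n_g[g] <= 0) continue;
      sum_ss_grp += q_g[g] - s_g[g] * s_g[g] / n_g[g];
      A += np2_g[g] / n_g[g];
      C += n_g[g] * n_g[g];
    }
    B /= Nl;
    C /= Nl;
    double ss_tot = Qt - St * St / Nl;
    double ssd_apwg = sum_ss_grp - ssd_wp;
    double ssd_ag = ss_tot - sum_ss_grp;
    double n1 = (Nl - A) / df_ap;
    double n2 = (A - B) / df_ag;
    double n3 = (Nl - C) / df_ag;
    double ms_wp = ssd_wp / df_wp;
    double ms_ap = ssd_apwg / df_ap;
    double ms_ag = ssd_ag / df_ag;
    double s2c = ms_wp;
    double s2b = (ms_ap - s2c) / n1;
    double s2a = (ms_ag - s2c - n2 * s2b) / n3;
    out.s2a += s2a;
    out.s2b += s2b;
    out.s2c += s2c;
    out.used += 1;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_amova_loci(IntegerMatrix geno, IntegerVector pop,
                    IntegerVector grp_of_pop, int n_perm) {
  int N = geno.nrow(), P = grp_of_pop.size();
  int G = 0;
  for (int p = 0; p < P; ++p) G = std::max(G, grp_of_pop[p] + 1);
  std::vector<int> pp(pop.begin(), pop.end());
  std::vector<int> gg(grp_of_pop.begin(), grp_of_pop.end());
  LociComp obs = amova_loci_core(geno, pp, gg, P, G);
  double tot = obs.s2a + obs.s2b + obs.s2c;
  double phi_st = (obs.s2a + obs.s2b) / tot;
  double phi_sc = obs.s2b / (obs.s2b + obs.s2c);
  double phi_ct = obs.s2a / tot;

  int ge_st = 0, ge_sc = 0, ge_ct = 0;
  if (n_perm > 0) {
    std::vector<int> perm = pp;
    for (int b = 0; b < n_perm; ++b) {
      shuffle(perm);
      LociComp r = amova_loci_core(geno, perm, gg, P, G);
      double f = (r.s2a + r.s2b) / (r.s2a + r.s2b + r.s2c);
      if (!ISNAN(f) && f >= phi_st) ++ge_st;
    }
    std::vector<std::vector<int> > idx_of_grp(G);
    for (int i = 0; i < N; ++i) idx_of_grp[gg[pp[i]]].push_back(i);
    perm = pp;
    std::vector<int> labs;
    for (int b = 0; b < n_perm; ++b) {
      for (int g = 0; g < G; ++g) {
        labs.clear();
        for (size_t k = 0; k < idx_of_grp[g].size(); ++k)
          labs.push_back(perm[idx_of_grp[g][k]]);
        shuffle(labs);
        for (size_t k = 0; k < idx_of_grp[g].size(); ++k)
          perm[idx_of_grp[g][k]] = labs[k];
      }
      LociComp r = amova_loci_core(geno, perm, gg, P, G);
      double f = r.s2b / (r.s2b + r.s2c);
      if (!ISNAN(f) && f >= phi_sc) ++ge_sc;
    }
    std::vector<int> gperm = gg;
    for (int b = 0; b < n_perm; ++b) {
      shuffle(gperm);
      LociComp r = amova_loci_core(geno, pp, gperm, P, G);
      double f = r.s2a / (r.s2a + r.s2b + r.s2c);
      if (!ISNAN(f) && f >= phi_ct) ++ge_ct;
    }
  }
  double B1 = (double)n_perm + 1.0;
  return List::create(
      _["sigma2"] = NumericVector::create(obs.s2a, obs.s2b, obs.s2c),
      _["phi"] = NumericVector::create(phi_st, phi_sc, phi_ct),
      _["p"] = NumericVector::create((ge_st + 1.0) / B1, (ge_sc + 1.0) / B1,
                                     (ge_ct + 1.0) / B1),
      _["loci_used"] = obs.used);
}
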