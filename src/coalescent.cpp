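#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Structured-coalescent engine shared by the SFS accumulator, the SNP-panel
// simulator, the finite-sites mtDNA simulator and the single-genealogy export.
//
// Conventions:
//  * time runs backward from 0 (sampling) in generations;
//  * sizes are HAPLOID effective sizes (pairwise coalescence rate k(k-1)/2/size);
//  * migration rates are backward per-lineage per-generation probabilities:
//    mig(i, j) is the rate at which a lineage currently in deme i jumps to j;
//  * epochs are half-open [etimes[e], etimes[e+1]); merges move all lineages
//    of deme `from` into deme `to` at the stated time.

struct MigEvent {
  double time;
  int node, from, to;
};

static void simulate_tree(const IntegerVector &samples,
                          const NumericVector &etimes,
                          const NumericMatrix &sizes,
                          const std::vector<NumericMatrix> &migs,
                          const NumericMatrix &merges,
                          std::vector<int> &parent,
                          std::vector<double> &ntime,
                          std::vector<int> &ndeme,
                          std::vector<MigEvent> *miglog) {
  const int D = samples.size();
  const int E = etimes.size();
  const int M = merges.nrow();
  int ntip = 0;
  for (int d = 0; d < D; ++d) ntip += samples[d];
  if (ntip < 2) stop("need at least two sampled lineages");
  const int nnode = 2 * ntip - 1;
  parent.assign(nnode, -1);
  ntime.assign(nnode, 0.0);
  ndeme.assign(nnode, -1);

  std::vector<std::vector<int> > act(D);
  int tip = 0;
  for (int d = 0; d < D; ++d)
    for (int i = 0; i < samples[d]; ++i) {
      act[d].push_back(tip);
      ndeme[tip] = d;
      ++tip;
    }

  int nextnode = ntip, nact = ntip;
  double t = 0.0;
  int eidx = 0, midx = 0;
  std::vector<double> crate(D), mrate(D);

  while (nact > 1) {
    while (eidx + 1 < E && etimes[eidx + 1] <= t) ++eidx;
    double bp = R_PosInf;
    if (eidx + 1 < E) bp = etimes[eidx + 1];
    if (midx < M && merges(midx, 0) < bp) bp = merges(midx, 0);

    const NumericMatrix &mig = migs[eidx];
    double Rtot = 0.0;
    for (int d = 0; d < D; ++d) {
      double k = (double)act[d].size();
      double sz = sizes(eidx, d);
      crate[d] = (k >= 2.0) ? k * (k - 1.0) / 2.0 / sz : 0.0;
      double mr = 0.0;
      for (int e = 0; e < D; ++e)
        if (e != d) mr += mig(d, e);
      mrate[d] = k * mr;
      Rtot += crate[d] + mrate[d];
    }

    if (Rtot <= 0.0) {
      if (!R_finite(bp))
        stop("genealogy cannot coalesce: zero total rate and no further epoch or merge");
      t = bp;
    } else {
      double dt = R::rexp(1.0 / Rtot);
      if (t + dt >= bp) {
        t = bp;
      } else {
        t += dt;
        double u = R::runif(0.0, Rtot);
        int d = 0;
        bool done = false;
        for (d = 0; d < D && !done; ++d) {
          if (u < crate[d]) {
            // coalescence in deme d
            int k = act[d].size();
            int i = (int)(R::unif_rand() * k);
            if (i >= k) i = k - 1;
            int j = (int)(R::unif_rand() * (k - 1));
            if (j >= k - 1) j = k - 2;
            if (j >= i) ++j;
            int a = act[d][i], b = act[d][j];
            int id = nextnode++;
            parent[a] = id;
            parent[b] = id;
            ntime[id] = t;
            ndeme[id] = d;
            // remove the two children, append the parent
            if (i < j) std::swap(i, j); // remove larger index first
            act[d][i] = act[d].back(); act[d].pop_back();
            act[d][j] = act[d].back(); act[d].pop_back();
            act[d].push_back(id);
            --nact;
            done = true;
            break;
          }
          u -= crate[d];
          if (u < mrate[d]) {
            // migration of one lineage out of deme d
            int k = act[d].size();
            double mr = 0.0;
            int e = -1;
            for (int f = 0; f < D; ++f)
              if (f != d) mr += mig(d, f);
            double v = R::runif(0.0, mr);
            for (int f = 0; f < D; ++f) {
              if (f == d) continue;
              if (v < mig(d, f)) { e = f; break; }
              v -= mig(d, f);
            }
            if (e < 0) e = (d + 1) % D;
            int i = (int)(R::unif_rand() * k);
            if (i >= k) i = k - 1;
            int id = act[d][i];
            act[d][i] = act[d].back(); act[d].pop_back();
            act[e].push_back(id);
            if (miglog) miglog->push_back(MigEvent{t, id, d, e});
            done = true;
            break;
          }
          u -= mrate[d];
        }
        if (!done) {
          // numerical edge of the rate walk: retry
          continue;
        }
        continue;
      }
    }

    // arrived exactly at a breakpoint: apply due merges
    while (midx < M && merges(midx, 0) <= t) {
      int from = (int)merges(midx, 1), to = (int)merges(midx, 2);
      for (size_t i = 0; i < act[from].size(); ++i)
        act[to].push_back(act[from][i]);
      act[from].clear();
      ++midx;
    }
  }
}

static std::vector<NumericMatrix> mig_list(const List &migs) {
  std::vector<NumericMatrix> out;
  for (int i = 0; i < migs.size(); ++i)
    out.push_back(as<NumericMatrix>(migs[i]));
  return out;
}

// Accumulate branch lengths of two-deme genealogies into the joint
// (unfolded, descendant-count indexed) spectrum. Cell (i, j) receives the
// total length of branches subtending i sampled lineages of deme 1 and j of
// deme 2, summed over n_genealogies independent genealogies.
// [[Rcpp::export]]
List cpp_sfs_branch(IntegerVector samples, NumericVector etimes,
                    NumericMatrix sizes, List migs, NumericMatrix merges,
                    int n_genealogies) {
  if (samples.size() != 2) stop("joint-SFS accumulation needs exactly two demes");
  int n1 = samples[0], n2 = samples[1];
  std::vector<NumericMatrix> mg = mig_list(migs);
  NumericMatrix acc(n1 + 1, n2 + 1);
  double total = 0.0;
  std::vector<int> parent, ndeme;
  std::vector<double> ntime;
  int ntip = n1 + n2, nnode = 2 * ntip - 1;
  std::vector<int> ci(nnode), cj(nnode);
  for (int g = 0; g < n_genealogies; ++g) {
    simulate_tree(samples, etimes, sizes, mg, merges, parent, ntime, ndeme, NULL);
    std::fill(ci.begin(), ci.end(), 0);
    std::fill(cj.begin(), cj.end(), 0);
    for (int i = 0; i < ntip; ++i) {
      if (i < n1) ci[i] = 1; else cj[i] = 1;
    }
    for (int idx = 0; idx < nnode - 1; ++idx) {
      int p = parent[idx];
      double bl = ntime[p] - ntime[idx];
      acc(ci[idx], cj[idx]) += bl;
      total += bl;
      ci[p] += ci[idx];
      cj[p] += cj[idx];
    }
  }
  return List::create(_["spectrum"] = acc, _["total_length"] = total);
}

// Simulate unlinked loci under the infinite-sites model: per locus one
// genealogy, Poisson(mu_locus * total length) mutations, each mutation a SNP
// whose derived carriers are the sampled lineages below its branch.
// Returns flat carrier lists (0-based haploid indices, deme-1 tips first).
// [[Rcpp::export]]
List cpp_simulate_panel(IntegerVector samples, NumericVector etimes,
                        NumericMatrix sizes, List migs, NumericMatrix merges,
                        double mu_locus, int n_loci) {
  int ntip = 0;
  for (int d = 0; d < samples.size(); ++d) ntip += samples[d];
  if (ntip > 64) stop("panel simulator supports at most 64 haploid samples");
  std::vector<NumericMatrix> mg = mig_list(migs);
  std::vector<int> parent, ndeme;
  std::vector<double> ntime;
  int nnode = 2 * ntip - 1;
  std::vector<uint64_t> mask(nnode);
  std::vector<double> cum(nnode - 1);
  std::vector<int> snp_locus, offsets, carriers;
  offsets.push_back(0);
  for (int loc = 0; loc < n_loci; ++loc) {
    simulate_tree(samples, etimes, sizes, mg, merges, parent, ntime, ndeme, NULL);
    std::fill(mask.begin(), mask.end(), 0ULL);
    for (int i = 0; i < ntip; ++i) mask[i] = 1ULL << i;
    double total = 0.0;
    for (int idx = 0; idx < nnode - 1; ++idx) {
      int p = parent[idx];
      total += ntime[p] - ntime[idx];
      cum[idx] = total;
      mask[p] |= mask[idx];
    }
    int nm = (int)R::rpois(mu_locus * total);
    for (int m = 0; m < nm; ++m) {
      double u = R::runif(0.0, total);
      int idx = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (idx >= nnode - 1) idx = nnode - 2;
      snp_locus.push_back(loc + 1);
      uint64_t mk = mask[idx];
      for (int i = 0; i < ntip; ++i)
        if (mk & (1ULL << i)) carriers.push_back(i);
      offsets.push_back((int)carriers.size());
    }
  }
  return List::create(_["locus"] = wrap(snp_locus),
                      _["offsets"] = wrap(offsets),
                      _["carriers"] = wrap(carriers));
}

// Finite-sites (Jukes-Cantor) sequence simulation on a single genealogy
// shared by all samples (a non-recombining mtDNA fragment). Bases are coded
// 0..3; recurrent mutation is possible.
// [[Rcpp::export]]
IntegerMatrix cpp_simulate_seqs(IntegerVector samples, NumericVector etimes,
                                NumericMatrix sizes, List migs,
                                NumericMatrix merges, double mu_site,
                                int seq_length) {
  std::vector<NumericMatrix> mg = mig_list(migs);
  std::vector<int> parent, ndeme;
  std::vector<double> ntime;
  simulate_tree(samples, etimes, sizes, mg, merges, parent, ntime, ndeme, NULL);
  int ntip = 0;
  for (int d = 0; d < samples.size(); ++d) ntip += samples[d];
  int nnode = 2 * ntip - 1;
  std::vector<double> cum(nnode - 1);
  double total = 0.0;
  for (int idx = 0; idx < nnode - 1; ++idx) {
    total += ntime[parent[idx]] - ntime[idx];
    cum[idx] = total;
  }
  int nm = (int)R::rpois(mu_site * (double)seq_length * total);
  // per-branch mutations, applied parent-to-child (decreasing time)
  std::vector<std::vector<std::pair<double, int> > > muts(nnode);
  for (int m = 0; m < nm; ++m) {
    double u = R::runif(0.0, total);
    int idx = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (idx >= nnode - 1) idx = nnode - 2;
    double below = (idx == 0) ? 0.0 : cum[idx - 1];
    double tm = ntime[idx] + (u - below);
    int site = (int)(R::unif_rand() * seq_length);
    if (site >= seq_length) site = seq_length - 1;
    muts[idx].push_back(std::make_pair(tm, site));
  }
  for (int idx = 0; idx < nnode; ++idx)
    std::sort(muts[idx].begin(), muts[idx].end(),
              [](const std::pair<double, int> &a, const std::pair<double, int> &b) {
                return a.first > b.first;
              });
  std::vector<std::vector<int> > children(nnode);
  for (int idx = 0; idx < nnode - 1; ++idx)
    children[parent[idx]].push_back(idx);
  IntegerMatrix out(ntip, seq_length);
  std::vector<int> rootseq(seq_length);
  for (int s = 0; s < seq_length; ++s) {
    int b = (int)(R::unif_rand() * 4.0);
    rootseq[s] = (b > 3) ? 3 : b;
  }
  // iterative DFS carrying the sequence
  std::vector<std::pair<int, std::vector<int> > > stack;
  stack.push_back(std::make_pair(nnode - 1, rootseq));
  while (!stack.empty()) {
    int node = stack.back().first;
    std::vector<int> seq = stack.back().second;
    stack.pop_back();
    for (size_t k = 0; k < muts[node].size(); ++k) {
      int s = muts[node][k].second;
      int shift = 1 + (int)(R::unif_rand() * 3.0);
      if (shift > 3) shift = 3;
      seq[s] = (seq[s] + shift) % 4;
    }
    if (node < ntip) {
      for (int s = 0; s < seq_length; ++s) out(node, s) = seq[s];
    } else {
      for (size_t c = 0; c < children[node].size(); ++c)
        stack.push_back(std::make_pair(children[node][c], seq));
    }
  }
  return out;
}

// Single-genealogy export: node times, parents (0 for root), demes at node
// creation, and the migration-event log of each lineage.
// [[Rcpp::export]]
List cpp_simulate_genealogy(IntegerVector samples, NumericVector etimes,
                            NumericMatrix sizes, List migs,
                            NumericMatrix merges) {
  std::vector<NumericMatrix> mg = mig_list(migs);
  std::vector<int> parent, ndeme;
  std::vector<double> ntime;
  std::vector<MigEvent> migl;
  simulate_tree(samples, etimes, sizes, mg, merges, parent, ntime, ndeme, &migl);
  int nnode = (int)parent.size();
  IntegerVector par(nnode);
  for (int i = 0; i < nnode; ++i) par[i] = parent[i] + 1; // root -> 0
  NumericVector tm(nnode);
  IntegerVector dm(nnode);
  for (int i = 0; i < nnode; ++i) {
    tm[i] = ntime[i];
    dm[i] = ndeme[i] + 1;
  }
  int nm = (int)migl.size();
  NumericVector mt(nm);
  IntegerVector mn(nm), mf(nm), mo(nm);
  for (int i = 0; i < nm; ++i) {
    mt[i] = migl[i].time;
    mn[i] = migl[i].node + 1;
    mf[i] = migl[i].from + 1;
    mo[i] = migl[i].to + 1;
  }
  return List::create(
      _["parent"] = par, _["time"] = tm, _["deme"] = dm,
      _["migrations"] = DataFrame::create(_["time"] = mt, _["lineage"] = mn,
                                          _["from"] = mf, _["to"] = mo));
}
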