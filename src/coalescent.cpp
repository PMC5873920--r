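// Hudson-style backwards coalescent with recombination under a piecewise
// demographic model (multiple populations, exponential size change, merges,
// optional migration). Ancestral material is tracked per lineage as a list of
// segments, each carrying a bitset of descendant sample haplotypes; a segment
// reaching the full sample size has found its MRCA and is dropped. Mutations
// are dropped on branches under the infinite-sites model at rate mu per bp
// per generation while the simulation runs.
//
// Uses R's RNG (unif_rand / rpois), so results are reproducible via set.seed.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Seg {
  double l, r;                    // [l, r) on [0, L)
  std::vector<uint64_t> bits;     // descendant haplotypes
  int count;                      // popcount of bits
};

struct Lin {
  std::vector<Seg> segs;          // sorted, non-overlapping
  int pop;
};

struct Mut {
  double pos;
  std::vector<int> carriers;      // 0-based haplotype indices
};

inline double rexp1() { return -std::log(unif_rand()); }

inline int popcount_vec(const std::vector<uint64_t>& b) {
  int c = 0;
  for (uint64_t w : b) {
#if defined(__GNUC__) || defined(__clang__)
    c += __builtin_popcountll(w);
#else
    while (w) { c += (int)(w & 1); w >>= 1; }
#endif
  }
  return c;
}

inline double span_of(const Lin& ln) {
  if (ln.segs.empty()) return 0.0;
  return ln.segs.back().r - ln.segs.front().l;
}

inline double anc_len_of(const Lin& ln) {
  double s = 0.0;
  for (const Seg& g : ln.segs) s += g.r - g.l;
  return s;
}

// union of two segment lists with bitset OR on overlaps; fully coalesced
// material (count == n_total) is dropped.
std::vector<Seg> merge_segs(std::vector<Seg> A, std::vector<Seg> B,
                            int n_total) {
  std::vector<Seg> out;
  size_t i = 0, j = 0;
  while (i < A.size() && j < B.size()) {
    Seg& a = A[i];
    Seg& b = B[j];
    if (a.r <= b.l) { out.push_back(a); ++i; continue; }
    if (b.r <= a.l) { out.push_back(b); ++j; continue; }
    double ol = std::max(a.l, b.l);
    double orr = std::min(a.r, b.r);
    if (a.l < ol) { Seg lead = a; lead.r = ol; out.push_back(lead); a.l = ol; }
    else if (b.l < ol) { Seg lead = b; lead.r = ol; out.push_back(lead); b.l = ol; }
    // overlapped piece [ol, orr)
    Seg m;
    m.l = ol; m.r = orr;
    m.bits.resize(a.bits.size());
    for (size_t w = 0; w < m.bits.size(); ++w) m.bits[w] = a.bits[w] | b.bits[w];
    m.count = popcount_vec(m.bits);
    if (m.count < n_total && m.r > m.l) out.push_back(m);
    a.l = orr; b.l = orr;
    if (a.l >= a.r) ++i;
    if (b.l >= b.r) ++j;
  }
  while (i < A.size()) out.push_back(A[i++]);
  while (j < B.size()) out.push_back(B[j++]);
  return out;
}

} // namespace

// [[Rcpp::export]]
List coalescent_sim_cpp(IntegerVector sample_sizes, double L,
                        double mu, double rec,
                        NumericVector N0, NumericVector growth,
                        NumericMatrix events,   // cols: time,type,pop,arg,growth
                        NumericMatrix migration) {
  const int npop = sample_sizes.size();
  int n_total = 0;
  for (int i = 0; i < npop; ++i) n_total += sample_sizes[i];
  if (n_total < 2) stop("need at least 2 sampled haplotypes");
  const int W = (n_total + 63) / 64;

  std::vector<Lin> lins;
  lins.reserve(2 * n_total);
  {
    int h = 0;
    for (int p = 0; p < npop; ++p)
      for (int s = 0; s < sample_sizes[p]; ++s, ++h) {
        Lin ln;
        ln.pop = p;
        Seg g;
        g.l = 0.0; g.r = L;
        g.bits.assign(W, 0);
        g.bits[h / 64] |= (uint64_t(1) << (h % 64));
        g.count = 1;
        ln.segs.push_back(g);
        lins.push_back(ln);
      }
  }

  std::vector<double> curN(N0.begin(), N0.end());
  std::vector<double> g(growth.begin(), growth.end());
  std::vector<double> mout(npop, 0.0);
  bool any_mig = false;
  for (int i = 0; i < npop; ++i)
    for (int j = 0; j < npop; ++j)
      if (i != j && migration(i, j) > 0) { mout[i] += migration(i, j); any_mig = true; }

  std::vector<Mut> muts;
  double t = 0.0;
  int ev = 0;
  const int n_events = events.nrow();
  long iter = 0;

  while (!lins.empty()) {
    if (++iter > 100000000L) stop("coalescent event limit exceeded");

    // population counts, spans
    std::vector<int> k(npop, 0);
    double tot_span = 0.0, tot_anc = 0.0;
    for (const Lin& ln : lins) {
      k[ln.pop]++;
      tot_span += span_of(ln);
      tot_anc += anc_len_of(ln);
    }

    // candidate waiting times from t
    double dt_rec = R_PosInf;
    if (rec > 0 && tot_span > 0) dt_rec = rexp1() / (rec * tot_span);
    double dt_mig = R_PosInf;
    double mig_rate = 0.0;
    if (any_mig) {
      for (int i = 0; i < npop; ++i) mig_rate += k[i] * mout[i];
      if (mig_rate > 0) dt_mig = rexp1() / mig_rate;
    }
    int coal_pop = -1;
    double dt_coal = R_PosInf;
    for (int i = 0; i < npop; ++i) {
      if (k[i] < 2) continue;
      double lam0 = k[i] * (k[i] - 1) / 2.0 / (2.0 * curN[i]);
      double E = rexp1();
      double dt;
      if (g[i] == 0.0) dt = E / lam0;
      else dt = std::log1p(g[i] * E / lam0) / g[i];
      if (dt < dt_coal) { dt_coal = dt; coal_pop = i; }
    }

    double dt_next = std::min(dt_rec, std::min(dt_mig, dt_coal));
    double t_event = (ev < n_events) ? events(ev, 0) : R_PosInf;

    double dt_adv = std::min(dt_next, t_event - t);
    if (!R_finite(dt_adv))
      stop("no possible event: simulation cannot proceed (check model)");

    // mutations over (t, t + dt_adv)
    if (mu > 0 && tot_anc > 0 && dt_adv > 0) {
      int nm = (int) R::rpois(mu * tot_anc * dt_adv);
      for (int m = 0; m < nm; ++m) {
        double u = unif_rand() * tot_anc;
        double acc = 0.0;
        for (const Lin& ln : lins) {
          double a = anc_len_of(ln);
          if (u < acc + a) {
            double v = u - acc;
            for (const Seg& sg : ln.segs) {
              double len = sg.r - sg.l;
              if (v < len) {
                Mut mm;
                mm.pos = sg.l + v;
                for (int hh = 0; hh < n_total; ++hh)
                  if (sg.bits[hh / 64] & (uint64_t(1) << (hh % 64)))
                    mm.carriers.push_back(hh);
                muts.push_back(std::move(mm));
                break;
              }
              v -= len;
            }
            break;
          }
          acc += a;
        }
      }
    }

    // decay population sizes over the advance
    for (int i = 0; i < npop; ++i)
      if (g[i] != 0.0) curN[i] *= std::exp(-g[i] * dt_adv);
    t += dt_adv;

    if (t_event - (t - dt_adv) <= dt_next) {
      // demographic event fires
      int type = (int) events(ev, 1);
      int p = (int) events(ev, 2);
      if (type == 0) {           // merge: pop p into pop dest
        int dest = (int) events(ev, 3);
        for (Lin& ln : lins) if (ln.pop == p) ln.pop = dest;
      } else {                   // size change (+ new growth rate)
        curN[p] = events(ev, 3);
        g[p] = events(ev, 4);
      }
      ++ev;
      continue;
    }

    if (dt_next == dt_coal) {
      // pick two distinct lineages in coal_pop
      std::vector<int> idx;
      for (size_t i = 0; i < lins.size(); ++i)
        if (lins[i].pop == coal_pop) idx.push_back((int) i);
      int a = (int)(unif_rand() * idx.size());
      if (a >= (int) idx.size()) a = idx.size() - 1;
      int b = a;
      while (b == a) {
        b = (int)(unif_rand() * idx.size());
        if (b >= (int) idx.size()) b = idx.size() - 1;
      }
      int ia = idx[a], ib = idx[b];
      Lin merged;
      merged.pop = coal_pop;
      merged.segs = merge_segs(std::move(lins[ia].segs),
                               std::move(lins[ib].segs), n_total);
      // remove ia, ib (larger index first)
      int hi = std::max(ia, ib), lo = std::min(ia, ib);
      lins[hi] = std::move(lins.back()); lins.pop_back();
      if (lo != (int) lins.size()) {
        lins[lo] = std::move(lins.back()); lins.pop_back();
      } else lins.pop_back();
      if (!merged.segs.empty()) lins.push_back(std::move(merged));
    } else if (dt_next == dt_rec) {
      double u = unif_rand() * tot_span;
      double acc = 0.0;
      for (size_t i = 0; i < lins.size(); ++i) {
        double sp = span_of(lins[i]);
        if (u < acc + sp) {
          double x = lins[i].segs.front().l + (u - acc);
          Lin right;
          right.pop = lins[i].pop;
          std::vector<Seg> left;
          for (Seg& sg : lins[i].segs) {
            if (sg.r <= x) left.push_back(std::move(sg));
            else if (sg.l >= x) right.segs.push_back(std::move(sg));
            else {
              Seg sl = sg, sr = sg;
              sl.r = x; sr.l = x;
              left.push_back(std::move(sl));
              right.segs.push_back(std::move(sr));
            }
          }
          lins[i].segs = std::move(left);
          if (lins[i].segs.empty()) {       // breakpoint in leading gap: no-op split
            lins[i] = std::move(right);
          } else if (!right.segs.empty()) {
            lins.push_back(std::move(right));
          }
          break;
        }
        acc += sp;
      }
    } else if (dt_next == dt_mig) {
      double u = unif_rand() * mig_rate;
      double acc = 0.0;
      for (Lin& ln : lins) {
        double w = mout[ln.pop];
        if (u < acc + w) {
          double v = u - acc;
          for (int j = 0; j < npop; ++j) {
            if (j == ln.pop) continue;
            double mij = migration(ln.pop, j);
            if (v < mij) { ln.pop = j; break; }
            v -= mij;
          }
          break;
        }
        acc += w;
      }
    }
  }

  // assemble output
  std::sort(muts.begin(), muts.end(),
            [](const Mut& a, const Mut& b) { return a.pos < b.pos; });
  const int S = (int) muts.size();
  NumericVector pos(S);
  IntegerMatrix gt(n_total, S);
  for (int s = 0; s < S; ++s) {
    pos[s] = muts[s].pos;
    for (int c : muts[s].carriers) gt(c, s) = 1;
  }
  return List::create(_["positions"] = pos, _["states"] = gt,
                      _["tmrca"] = t);
}
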