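#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Forward-in-time simulation of ancestry tract mosaics under multi-pulse
// admixture. A haplotype is, per chromosome, a run-length encoding of
// ancestry labels: tract end positions (cM, last == chromosome length) and
// integer labels. Recombination is Poisson on the genetic map (no
// interference); migrants enter as unadmixed haplotype pairs. All random
// draws go through R's RNG so set.seed() on the R side fixes the output.

typedef std::vector<double> dvec;
typedef std::vector<int> ivec;

struct Chrom {
  dvec ends;
  ivec labs;
};
typedef std::vector<Chrom> Hap;

static void pure_hap(Hap &h, const dvec &len, int lab) {
  size_t C = len.size();
  h.resize(C);
  for (size_t c = 0; c < C; ++c) {
    h[c].ends.assign(1, len[c]);
    h[c].labs.assign(1, lab);
  }
}

// One meiosis for one chromosome: alternate copying between the two parental
// haplotypes at Poisson(len/100) crossover points, merging same-label runs.
static void meiose_chrom(const Chrom &a, const Chrom &b, double len,
                         Chrom &out) {
  int k = (int)R::rpois(len / 100.0);
  out.ends.clear();
  out.labs.clear();
  dvec cuts;
  cuts.reserve(k + 1);
  for (int i = 0; i < k; ++i) cuts.push_back(unif_rand() * len);
  std::sort(cuts.begin(), cuts.end());
  cuts.push_back(len);
  const Chrom *src[2] = {&a, &b};
  int s = (unif_rand() < 0.5) ? 0 : 1;
  double pos = 0.0;
  for (size_t ci = 0; ci < cuts.size(); ++ci) {
    double cut = cuts[ci];
    if (cut > pos) {
      const Chrom &p = *src[s];
      size_t i =
          std::upper_bound(p.ends.begin(), p.ends.end(), pos) - p.ends.begin();
      while (i < p.ends.size() && pos < cut) {
        double e = std::min(p.ends[i], cut);
        int lab = p.labs[i];
        if (!out.labs.empty() && out.labs.back() == lab)
          out.ends.back() = e;
        else {
          out.ends.push_back(e);
          out.labs.push_back(lab);
        }
        pos = e;
        ++i;
      }
      pos = cut;
    }
    s = 1 - s;
  }
  if (out.ends.empty()) {  // len == 0 guard; never expected
    out.ends.push_back(len);
    out.labs.push_back(a.labs.empty() ? 0 : a.labs[0]);
  } else {
    out.ends.back() = len;  // clamp fp drift at the terminus
  }
}

// [[Rcpp::export(name = ".sim_tracts_cpp")]]
List sim_tracts_cpp(NumericVector chrom_len, int N, int g0, double m_founder,
                    int lab_a, int lab_b, IntegerVector ev_gen,
                    IntegerVector ev_lab, NumericVector ev_m,
                    int n_sample_ind) {
  RNGScope scope;
  dvec len(chrom_len.begin(), chrom_len.end());
  size_t C = len.size();
  if (N < 1) stop("population size must be >= 1");
  if (n_sample_ind > N) stop("cannot sample more individuals than N");

  std::vector<Hap> pop(2 * N), nxt(2 * N);
  for (int i = 0; i < N; ++i) {
    int lab = (unif_rand() < m_founder) ? lab_a : lab_b;
    pure_hap(pop[2 * i], len, lab);
    pure_hap(pop[2 * i + 1], len, lab);
  }

  int n_ev = ev_gen.size();
  for (int t = g0 - 1; t >= 0; --t) {
    // events whose generation == t inject migrants into the generation
    // being formed; those genomes then undergo t further meioses
    std::vector<std::pair<double, int> > mig;
    for (int e = 0; e < n_ev; ++e)
      if (ev_gen[e] == t) mig.push_back(std::make_pair(ev_m[e], ev_lab[e]));
    for (int i = 0; i < N; ++i) {
      int mlab = -1;
      if (!mig.empty()) {
        double u = unif_rand(), acc = 0.0;
        for (size_t e = 0; e < mig.size(); ++e) {
          acc += mig[e].first;
          if (u < acc) {
            mlab = mig[e].second;
            break;
          }
        }
      }
      if (mlab >= 0) {
        pure_hap(nxt[2 * i], len, mlab);
        pure_hap(nxt[2 * i + 1], len, mlab);
      } else {
        int mom = (int)(unif_rand() * N);
        if (mom >= N) mom = N - 1;
        int dad = (int)(unif_rand() * N);
        if (dad >= N) dad = N - 1;
        nxt[2 * i].resize(C);
        nxt[2 * i + 1].resize(C);
        for (size_t c = 0; c < C; ++c) {
          meiose_chrom(pop[2 * mom][c], pop[2 * mom + 1][c], len[c],
                       nxt[2 * i][c]);
          meiose_chrom(pop[2 * dad][c], pop[2 * dad + 1][c], len[c],
                       nxt[2 * i + 1][c]);
        }
      }
    }
    std::swap(pop, nxt);
  }

  // sample individuals without replacement (partial Fisher-Yates)
  ivec idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int i = 0; i < n_sample_ind; ++i) {
    int j = i + (int)(unif_rand() * (N - i));
    if (j >= N) j = N - 1;
    std::swap(idx[i], idx[j]);
  }

  // flatten sampled haplotypes into a tract table
  size_t total = 0;
  for (int i = 0; i < n_sample_ind; ++i)
    for (int h = 0; h < 2; ++h)
      for (size_t c = 0; c < C; ++c) total += pop[2 * idx[i] + h][c].ends.size();

  IntegerVector o_hap(total), o_chr(total), o_lab(total);
  NumericVector o_start(total), o_end(total);
  size_t r = 0;
  for (int i = 0; i < n_sample_ind; ++i) {
    for (int h = 0; h < 2; ++h) {
      const Hap &hp = pop[2 * idx[i] + h];
      int hap_id = 2 * i + h + 1;
      for (size_t c = 0; c < C; ++c) {
        double pos = 0.0;
        for (size_t k = 0; k < hp[c].ends.size(); ++k) {
          o_hap[r] = hap_id;
          o_chr[r] = (int)c + 1;
          o_start[r] = pos;
          o_end[r] = hp[c].ends[k];
          o_lab[r] = hp[c].labs[k];
          pos = hp[c].ends[k];
          ++r;
        }
      }
    }
  }
  return List::create(_["hap"] = o_hap, _["chrom"] = o_chr,
                      _["start_cM"] = o_start, _["end_cM"] = o_end,
                      _["label"] = o_lab);
}
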