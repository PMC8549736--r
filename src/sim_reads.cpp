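// Per-sample shotgun read simulation. Uses R's RNG stream (RNGScope) so a
// set.seed() on the R side makes the whole draw reproducible.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>

using namespace Rcpp;

namespace {

inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  default: return 'N';
  }
}

inline int sample_cum(const std::vector<double>& cum) {
  // cum is a cumulative weight vector; returns index in [0, size)
  double u = unif_rand() * cum.back();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] > u) hi = mid; else lo = mid + 1;
  }
  return lo;
}

const char BASES[4] = {'A', 'C', 'G', 'T'};

} // namespace

// genome_orfs: per genome, 1-based indices into orf_seqs (eligible ORFs only,
// i.e. length >= read_len and weight > 0). orf_weights parallel to orf_seqs.
// Returns reads plus per-ORF true counts and the number of background reads.
// [[Rcpp::export(name = ".cpp_sim_reads")]]
List cpp_sim_reads(CharacterVector orf_seqs, NumericVector orf_weights,
                   List genome_orfs, NumericVector genome_probs,
                   CharacterVector bg_seqs, int n_reads, int read_len,
                   double err_rate, double bg_frac) {
  RNGScope rng;
  int n_genomes = genome_probs.size();
  int n_orfs = orf_seqs.size();

  // cumulative genome probabilities
  std::vector<double> gcum(n_genomes);
  double acc = 0.0;
  for (int g = 0; g < n_genomes; ++g) { acc += genome_probs[g]; gcum[g] = acc; }

  // per-genome cumulative ORF weights
  std::vector<std::vector<int>> gorf(n_genomes);
  std::vector<std::vector<double>> gwcum(n_genomes);
  for (int g = 0; g < n_genomes; ++g) {
    IntegerVector idx = genome_orfs[g];
    gorf[g].reserve(idx.size());
    gwcum[g].reserve(idx.size());
    double w = 0.0;
    for (int j = 0; j < idx.size(); ++j) {
      int o = idx[j] - 1;
      gorf[g].push_back(o);
      w += orf_weights[o];
      gwcum[g].push_back(w);
    }
  }

  CharacterVector reads(n_reads);
  IntegerVector orf_counts(n_orfs);
  int n_background = 0;
  std::string buf(read_len, 'N');

  for (int r = 0; r < n_reads; ++r) {
    int g = sample_cum(gcum);
    bool background = (unif_rand() < bg_frac) || gorf[g].empty();
    const char* src;
    int src_len;
    if (background) {
      src = CHAR(STRING_ELT(bg_seqs, g));
      src_len = (int)strlen(src);
      ++n_background;
    } else {
      int o = gorf[g][sample_cum(gwcum[g])];
      src = CHAR(STRING_ELT(orf_seqs, o));
      src_len = (int)strlen(src);
      orf_counts[o] += 1;
    }
    int start = (int)(unif_rand() * (src_len - read_len + 1));
    if (start > src_len - read_len) start = src_len - read_len;
    bool fwd = unif_rand() < 0.5;
    if (fwd) {
      for (int i = 0; i < read_len; ++i) buf[i] = src[start + i];
    } else {
      for (int i = 0; i < read_len; ++i) buf[i] = comp(src[start + read_len - 1 - i]);
    }
    if (err_rate > 0.0) {
      for (int i = 0; i < read_len; ++i) {
        if (unif_rand() < err_rate) {
          char cur = buf[i];
          char nb;
          do { nb = BASES[(int)(unif_rand() * 4) & 3]; } while (nb == cur);
          buf[i] = nb;
        }
      }
    }
    reads[r] = buf;
  }

  return List::create(_["reads"] = reads,
                      _["orf_counts"] = orf_counts,
                      _["n_background"] = n_background);
}

// Random ACGT string generation with R's RNG (used for ORF/background DNA).
// [[Rcpp::export(name = ".cpp_random_dna")]]
CharacterVector cpp_random_dna(IntegerVector lengths) {
  RNGScope rng;
  CharacterVector out(lengths.size());
  for (int i = 0; i < lengths.size(); ++i) {
    std::string s(lengths[i], 'A');
    for (int j = 0; j < lengths[i]; ++j) s[j] = BASES[(int)(unif_rand() * 4) & 3];
    out[i] = s;
  }
  return out;
}
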