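// k-mer pseudoalignment core: canonical 2-bit encoded k-mers (k <= 31),
// equivalence classes of targets, and read -> class-intersection lookup.
#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

namespace {

inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct KmerIndex {
  int k;
  int n_targets;
  std::vector<int> effective_length;
  std::unordered_map<uint64_t, int32_t> kmap;      // canonical code -> class id
  std::vector<std::vector<int>> classes;            // class id -> sorted 0-based targets
};

// Enumerate canonical k-mer codes of a sequence; positions containing
// non-ACGT characters are skipped.
template <typename F>
void for_each_canonical(const char* s, int len, int k, F fun) {
  if (len < k) return;
  uint64_t fwd = 0, rev = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int i = 0; i < len; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid >= k) fun(fwd < rev ? fwd : rev);
  }
}

} // namespace

typedef XPtr<KmerIndex> IndexPtr;

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->n_targets = seqs.size();
  idx->effective_length.resize(seqs.size());

  std::unordered_map<uint64_t, std::vector<int>> ktargets;
  for (int t = 0; t < seqs.size(); ++t) {
    const char* s = CHAR(STRING_ELT(seqs, t));
    int len = (int)strlen(s);
    idx->effective_length[t] = len - k + 1;
    for_each_canonical(s, len, k, [&](uint64_t code) {
      std::vector<int>& v = ktargets[code];
      if (v.empty() || v.back() != t) v.push_back(t);
    });
  }

  std::map<std::vector<int>, int32_t> class_of;
  idx->kmap.reserve(ktargets.size() * 2);
  for (auto& kv : ktargets) {
    auto it = class_of.find(kv.second);
    int32_t cid;
    if (it == class_of.end()) {
      cid = (int32_t)idx->classes.size();
      class_of.emplace(kv.second, cid);
      idx->classes.push_back(kv.second);
    } else {
      cid = it->second;
    }
    idx->kmap.emplace(kv.first, cid);
  }
  return IndexPtr(idx, true);
}

// [[Rcpp::export(name = ".cpp_index_stats")]]
List cpp_index_stats(SEXP ptr) {
  IndexPtr idx(ptr);
  return List::create(_["k"] = idx->k,
                      _["n_targets"] = idx->n_targets,
                      _["n_kmers"] = (double)idx->kmap.size(),
                      _["n_classes"] = (double)idx->classes.size(),
                      _["effective_length"] = wrap(idx->effective_length));
}

// [[Rcpp::export(name = ".cpp_index_classes")]]
List cpp_index_classes(SEXP ptr) {
  IndexPtr idx(ptr);
  List out(idx->classes.size());
  for (size_t i = 0; i < idx->classes.size(); ++i) {
    IntegerVector v(idx->classes[i].begin(), idx->classes[i].end());
    out[i] = v + 1; // 1-based for R
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_index_dump")]]
List cpp_index_dump(SEXP ptr) {
  IndexPtr idx(ptr);
  size_t n = idx->kmap.size();
  CharacterVector codes(n);
  IntegerVector cids(n);
  size_t i = 0;
  for (auto& kv : idx->kmap) {
    codes[i] = std::to_string(kv.first);
    cids[i] = kv.second + 1;
    ++i;
  }
  return List::create(_["kmer_code"] = codes, _["class_id"] = cids);
}

// [[Rcpp::export(name = ".cpp_index_restore")]]
SEXP cpp_index_restore(int k, int n_targets, IntegerVector effective_length,
                       CharacterVector codes, IntegerVector class_ids,
                       List classes) {
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->n_targets = n_targets;
  idx->effective_length.assign(effective_length.begin(), effective_length.end());
  idx->classes.resize(classes.size());
  for (int i = 0; i < classes.size(); ++i) {
    IntegerVector v = classes[i];
    std::vector<int> t(v.begin(), v.end());
    for (auto& x : t) x -= 1;
    idx->classes[i] = t;
  }
  idx->kmap.reserve(codes.size() * 2);
  for (int i = 0; i < codes.size(); ++i) {
    const char* s = CHAR(STRING_ELT(codes, i));
    uint64_t code = 0;
    for (; *s >= '0' && *s <= '9'; ++s) code = code * 10 + (uint64_t)(*s - '0');
    idx->kmap.emplace(code, class_ids[i] - 1);
  }
  return IndexPtr(idx, true);
}

// Pseudoalign reads: per read, intersect the classes of its canonical
// k-mers, ignoring k-mers absent from the index. Returns per-read
// equivalence-class ids (0 = unassigned) plus the deduplicated class
// target sets and counts.
// [[Rcpp::export(name = ".cpp_pseudoalign")]]
List cpp_pseudoalign(SEXP ptr, CharacterVector reads) {
  IndexPtr idx(ptr);
  const int k = idx->k;
  int n = reads.size();
  IntegerVector read_ec(n);
  std::map<std::vector<int>, int> ec_of;
  std::vector<std::vector<int>> ec_targets;
  std::vector<double> ec_counts;
  int n_unassigned = 0, n_short = 0;

  std::vector<int> cur, tmp;
  for (int r = 0; r < n; ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = (int)strlen(s);
    if (len < k) { read_ec[r] = 0; ++n_unassigned; ++n_short; continue; }
    cur.clear();
    bool any_hit = false, dead = false;
    for_each_canonical(s, len, k, [&](uint64_t code) {
      if (dead) return;
      auto it = idx->kmap.find(code);
      if (it == idx->kmap.end()) return; // absent k-mers ignored
      const std::vector<int>& cls = idx->classes[it->second];
      if (!any_hit) {
        cur = cls;
        any_hit = true;
      } else {
        tmp.clear();
        std::set_intersection(cur.begin(), cur.end(), cls.begin(), cls.end(),
                              std::back_inserter(tmp));
        cur.swap(tmp);
        if (cur.empty()) dead = true;
      }
    });
    if (!any_hit || cur.empty()) { read_ec[r] = 0; ++n_unassigned; continue; }
    auto it = ec_of.find(cur);
    int id;
    if (it == ec_of.end()) {
      id = (int)ec_targets.size();
      ec_of.emplace(cur, id);
      ec_targets.push_back(cur);
      ec_counts.push_back(0.0);
    } else id = it->second;
    ec_counts[id] += 1.0;
    read_ec[r] = id + 1;
  }

  List tl(ec_targets.size());
  for (size_t i = 0; i < ec_targets.size(); ++i) {
    IntegerVector v(ec_targets[i].begin(), ec_targets[i].end());
    tl[i] = v + 1;
  }
  return List::create(_["read_ec"] = read_ec,
                      _["ec_targets"] = tl,
                      _["ec_counts"] = wrap(ec_counts),
                      _["n_unassigned"] = n_unassigned,
                      _["n_too_short"] = n_short);
}
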