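#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Hash-based IBD segment detection on phased haplotypes.
//
// Per chromosome, SNPs are cut into consecutive non-overlapping slices of
// `bits` SNPs. Two haplotypes match in a slice when they carry the
// identical allele word; maximal runs of consecutive matching slices form
// one candidate segment per haplotype pair, and a single non-matching
// slice between two matching slices is bridged when the two individuals'
// genotypes conflict at no more than `err_hom` homozygous-opposite sites
// in that slice (err-tolerant slices join runs but can neither start nor
// end one, which keeps chance word collisions from seeding spurious
// segments). Haplotype-level segments of an individual pair are unioned
// per chromosome; segments shorter than `min_len` bp are dropped. Pairs
// (i,i) compare the individual's own two haplotypes and feed the diagonal
// (genomic inbreeding) of the IBD matrix.
//
// Scalability: candidate haplotype pairs are seeded by exact hashing over
// aligned blocks of `B` consecutive slices (B chosen from the minimum
// slice count a reportable segment must span, capped at 3) and then
// verified by a full per-slice scan, so only pairs that can carry a
// reportable segment are ever enumerated. With B > 1, a segment would be
// missed only if every clean (error-free) stretch inside it were shorter
// than 2B-1 <= 5 slices, which requires genotyping-error rates far above
// what the err_hom tolerance targets.

namespace {

struct Run {
  uint64_t key;   // individual pair i * n + j, i <= j
  int start_bp;
  int end_bp;
};

inline int hom_conflicts(const Rbyte* haps, int m, int i, int j,
                         int r0, int bits) {
  const Rbyte* i1 = haps + (size_t)(2 * i) * m;
  const Rbyte* i2 = haps + (size_t)(2 * i + 1) * m;
  const Rbyte* j1 = haps + (size_t)(2 * j) * m;
  const Rbyte* j2 = haps + (size_t)(2 * j + 1) * m;
  int c = 0;
  for (int r = r0; r < r0 + bits; ++r) {
    int di = (int)i1[r] + (int)i2[r], dj = (int)j1[r] + (int)j2[r];
    if ((di == 0 && dj == 2) || (di == 2 && dj == 0)) ++c;
  }
  return c;
}

inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Minimal open-addressing set for uint64 keys (key 0 reserved: offset all
// keys by 1 before insertion).
class FlatSet {
public:
  explicit FlatSet(size_t expect) {
    size_t cap = 64;
    while (cap < expect * 2) cap <<= 1;
    tab_.assign(cap, 0ULL);
    mask_ = cap - 1;
    count_ = 0;
  }
  bool insert(uint64_t key) {               // returns true if newly added
    ++key;
    if (count_ * 2 >= tab_.size()) grow();
    size_t idx = mix64(key) & mask_;
    while (tab_[idx] != 0) {
      if (tab_[idx] == key) return false;
      idx = (idx + 1) & mask_;
    }
    tab_[idx] = key;
    ++count_;
    return true;
  }
  template <class F> void for_each(F f) const {
    for (uint64_t v : tab_) if (v != 0) f(v - 1);
  }
  size_t size() const { return count_; }
private:
  void grow() {
    std::vector<uint64_t> old;
    old.swap(tab_);
    tab_.assign(old.size() * 2, 0ULL);
    mask_ = tab_.size() - 1;
    for (uint64_t v : old) {
      if (v == 0) continue;
      size_t idx = mix64(v) & mask_;
      while (tab_[idx] != 0) idx = (idx + 1) & mask_;
      tab_[idx] = v;
    }
  }
  std::vector<uint64_t> tab_;
  size_t mask_;
  size_t count_;
};

} // namespace

// [[Rcpp::export(name = ".ibd_detect_cpp")]]
List ibd_detect_cpp(RawMatrix haps, IntegerVector chrom, IntegerVector pos,
                    int bits, int err_hom, double min_len, bool as_segments) {
  const int m = haps.nrow();
  const int H = haps.ncol();
  const int n = H / 2;
  if (H % 2 != 0) stop("haplotype matrix needs two columns per individual");
  if (bits < 2 || bits > 30) stop("bits must be in [2, 30]");
  if ((int)chrom.size() != m || (int)pos.size() != m)
    stop("map length must match haplotype rows");
  const Rbyte* hp = haps.begin();

  // chromosome row ranges (map assumed sorted by chrom, pos)
  std::vector<int> c_first, c_last, c_id;
  for (int r = 0; r < m; ++r) {
    if (r == 0 || chrom[r] != chrom[r - 1]) {
      c_first.push_back(r);
      c_id.push_back(chrom[r]);
      if (r > 0) c_last.push_back(r - 1);
    }
    if (r > 0 && pos[r] <= pos[r - 1] && chrom[r] == chrom[r - 1])
      stop("positions must be strictly increasing within a chromosome");
  }
  c_last.push_back(m - 1);

  NumericMatrix G;
  if (!as_segments) G = NumericMatrix(n, n);
  std::vector<int> seg_i, seg_j, seg_chr, seg_s, seg_e;
  std::vector<Run> runs;

  for (size_t ci = 0; ci < c_first.size(); ++ci) {
    const int r0 = c_first[ci];
    const int mc = c_last[ci] - c_first[ci] + 1;
    const int n_slices = mc / bits;
    if (n_slices < 1) continue;

    // smallest slice count a reportable run must have: a run of j slices
    // spans at most max_t (pos[t + j*bits - 1] - pos[t*bits] + 1) bp
    int j_star = n_slices + 1;
    for (int j = 1; j <= n_slices; ++j) {
      double span_max = 0;
      for (int t = 0; t + j <= n_slices; ++t) {
        double sp = (double)pos[r0 + (t + j) * bits - 1] -
                    pos[r0 + t * bits] + 1;
        if (sp > span_max) span_max = sp;
      }
      if (span_max >= min_len) { j_star = j; break; }
    }
    if (j_star > n_slices) continue;        // no segment can reach min_len
    const int B = std::max(1, std::min(3, (j_star + 1) / 2));
    const int n_blocks = n_slices / B;

    // per-haplotype slice words, haplotype-major
    std::vector<uint32_t> W((size_t)H * n_slices);
    for (int h = 0; h < H; ++h) {
      const Rbyte* col = hp + (size_t)h * m + r0;
      uint32_t* wrow = &W[(size_t)h * n_slices];
      for (int t = 0; t < n_slices; ++t) {
        uint32_t w = 0;
        const Rbyte* p = col + t * bits;
        for (int b = 0; b < bits; ++b) w = (w << 1) | (uint32_t)p[b];
        wrow[t] = w;
      }
    }

    // seed candidate pairs from aligned B-slice blocks
    FlatSet cand(4096);
    std::vector<uint64_t> kh(H);
    for (int b = 0; b < n_blocks; ++b) {
      for (int h = 0; h < H; ++h) {
        uint64_t key = 0x12345678ULL;
        const uint32_t* wrow = &W[(size_t)h * n_slices + (size_t)b * B];
        for (int x = 0; x < B; ++x) key = mix64(key ^ wrow[x]);
        // top 40 bits: block hash; low 24 bits: haplotype index (H < 2^24).
        // Hash collisions merely add candidates that verification discards.
        kh[h] = (key << 24) | (uint64_t)h;
      }
      std::sort(kh.begin(), kh.end());
      int g0 = 0;
      for (int h = 1; h <= H; ++h) {
        if (h == H || (kh[h] >> 24) != (kh[g0] >> 24)) {
          if (h - g0 > 1) {
            for (int x = g0; x < h; ++x) {
              uint64_t ha = kh[x] & 0xFFFFFF;
              for (int y = x + 1; y < h; ++y) {
                uint64_t hb = kh[y] & 0xFFFFFF;
                cand.insert(ha < hb ? ha * H + hb : hb * H + ha);
              }
            }
          }
          g0 = h;
        }
      }
    }
    std::vector<uint64_t> pairs;
    pairs.reserve(cand.size());
    cand.for_each([&](uint64_t k) { pairs.push_back(k); });
    std::sort(pairs.begin(), pairs.end());

    // verify every candidate pair by a full per-slice scan
    runs.clear();
    auto finalize = [&](int a, int b, int s_first, int s_last) {
      const int sbp = pos[r0 + s_first * bits];
      const int ebp = pos[r0 + (s_last + 1) * bits - 1];
      if ((double)(ebp - sbp + 1) < min_len) return;
      const int i = a / 2, j = b / 2;
      runs.push_back({(uint64_t)i * n + j, sbp, ebp});
    };
    for (uint64_t pk : pairs) {
      const int a = (int)(pk / H), b = (int)(pk % H);
      const uint32_t* wa = &W[(size_t)a * n_slices];
      const uint32_t* wb = &W[(size_t)b * n_slices];
      int run_start = -1, last_match = -1;
      for (int t = 0; t < n_slices; ++t) {
        if (wa[t] != wb[t]) continue;
        if (run_start < 0) {
          run_start = t;
        } else if (t == last_match + 1) {
          // contiguous
        } else if (t == last_match + 2 &&
                   hom_conflicts(hp, m, a / 2, b / 2,
                                 r0 + (last_match + 1) * bits,
                                 bits) <= err_hom) {
          // single-slice gap bridged
        } else {
          finalize(a, b, run_start, last_match);
          run_start = t;
        }
        last_match = t;
      }
      if (run_start >= 0) finalize(a, b, run_start, last_match);
    }

    // union haplotype-level runs per individual pair
    std::sort(runs.begin(), runs.end(), [](const Run& x, const Run& y) {
      return x.key < y.key || (x.key == y.key && x.start_bp < y.start_bp);
    });
    size_t x = 0;
    while (x < runs.size()) {
      const uint64_t ikey = runs[x].key;
      int s = runs[x].start_bp, e = runs[x].end_bp;
      const int i = (int)(ikey / n), j = (int)(ikey % n);
      auto emit = [&](int s_, int e_) {
        if (as_segments) {
          seg_i.push_back(i + 1); seg_j.push_back(j + 1);
          seg_chr.push_back(c_id[ci]); seg_s.push_back(s_); seg_e.push_back(e_);
        } else {
          const double len = (double)e_ - s_ + 1;
          G(i, j) += len;
          if (i != j) G(j, i) += len;
        }
      };
      size_t y = x + 1;
      for (; y < runs.size() && runs[y].key == ikey; ++y) {
        if (runs[y].start_bp <= e + 1) {
          if (runs[y].end_bp > e) e = runs[y].end_bp;
        } else {
          emit(s, e);
          s = runs[y].start_bp; e = runs[y].end_bp;
        }
      }
      emit(s, e);
      x = y;
    }
    Rcpp::checkUserInterrupt();
  }

  if (as_segments) {
    return List::create(_["i"] = seg_i, _["j"] = seg_j, _["chrom"] = seg_chr,
                        _["start"] = seg_s, _["end"] = seg_e);
  }
  return List::create(_["shared_bp"] = G);
}
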