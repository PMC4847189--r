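#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Base encoding: A=0 C=1 G=2 T=3, anything else (N) = 4. N never matches.
static inline unsigned char enc_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static inline unsigned char comp_base(unsigned char b) { return b < 4 ? 3 - b : 4; }

static std::vector<unsigned char> encode(const std::string &s) {
  std::vector<unsigned char> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc_base(s[i]);
  return v;
}

static std::vector<unsigned char> revcomp(const std::vector<unsigned char> &v) {
  std::vector<unsigned char> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) r[v.size() - 1 - i] = comp_base(v[i]);
  return r;
}

// Bit-plane packing: per sequence three bit vectors over positions — the low
// and high bit of the 2-bit base code, and an N mask. Mismatch at a position
// is then ((lo1^lo2)|(hi1^hi2)|n1|n2), so the mismatch count over a whole
// 64-position block is one popcount. This keeps the all-offset scan exact
// while touching 64 bases per instruction instead of one.
struct Packed {
  std::vector<uint64_t> lo, hi, nn;
  int len;
  int words;
};

static Packed pack(const std::vector<unsigned char> &v, int pad_words) {
  Packed p;
  p.len = (int) v.size();
  p.words = (p.len + 63) / 64;
  int total = p.words + pad_words;
  p.lo.assign(total, 0); p.hi.assign(total, 0); p.nn.assign(total, 0);
  for (int i = 0; i < p.len; ++i) {
    int w = i >> 6, b = i & 63;
    unsigned char c = v[i];
    if (c == 4) {
      p.nn[w] |= (uint64_t) 1 << b;
    } else {
      if (c & 1) p.lo[w] |= (uint64_t) 1 << b;
      if (c & 2) p.hi[w] |= (uint64_t) 1 << b;
    }
  }
  return p;
}

static inline uint64_t fetch(const std::vector<uint64_t> &w, int k, int r) {
  // 64 bits of the sequence starting at position k*64 + r (r in [0,63])
  return r == 0 ? w[k] : (w[k] >> r) | (w[k + 1] << (64 - r));
}

// Mismatches of the packed read against the packed target at offset `off`,
// abandoning once the count exceeds `limit`.
static inline int mm_at(const Packed &read, const Packed &tgt, int off, int limit) {
  const int k = off >> 6, r = off & 63;
  int mm = 0;
  for (int w = 0; w < read.words; ++w) {
    uint64_t tlo = fetch(tgt.lo, k + w, r);
    uint64_t thi = fetch(tgt.hi, k + w, r);
    uint64_t tnn = fetch(tgt.nn, k + w, r);
    uint64_t diff = (tlo ^ read.lo[w]) | (thi ^ read.hi[w]) | tnn | read.nn[w];
    int tail = read.len - (w << 6);
    if (tail < 64) diff &= ((uint64_t) 1 << tail) - 1;
    mm += __builtin_popcountll(diff);
    if (mm > limit) return mm;
  }
  return mm;
}

// Semi-global edit distance: read aligned globally, target gaps free at both
// ends. Returns min distance and (via end_col) the smallest end column
// achieving it.
static int edit_infix(const std::vector<unsigned char> &read,
                      const std::vector<unsigned char> &tgt, int *end_col) {
  const int Lr = (int) read.size(), Lt = (int) tgt.size();
  std::vector<int> prev(Lt + 1, 0), cur(Lt + 1, 0);
  for (int i = 1; i <= Lr; ++i) {
    cur[0] = i;
    int ri = read[i - 1];
    for (int j = 1; j <= Lt; ++j) {
      int sub = prev[j - 1] + ((ri == tgt[j - 1] && ri != 4) ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      int m = sub < del ? sub : del;
      cur[j] = m < ins ? m : ins;
    }
    std::swap(prev, cur);
  }
  int best = prev[0], bj = 0;
  for (int j = 1; j <= Lt; ++j) if (prev[j] < best) { best = prev[j]; bj = j; }
  *end_col = bj;
  return best;
}

// Map each read against a panel of targets. Targets of tandem entries are the
// monomer dimer; offsets scanned on tandem targets are restricted to
// [0, monomer_length) (every placement further right is a duplicate), so the
// reported offset is already canonical. Scan order is: entry (panel order),
// then offset ascending, then strand (+ before -); ties keep the first hit
// found and, when the tie crosses entries, set the ambiguous flag.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector targets,
                        LogicalVector is_tandem, IntegerVector monomer_len,
                        double min_identity, bool allow_indels) {
  const int nR = reads.size(), nT = targets.size();
  std::vector< std::vector<unsigned char> > tgt(nT);
  std::vector<Packed> tpk(nT);
  int max_read_words = 4;
  for (int r = 0; r < nR; ++r) {
    int w = ((int) LENGTH(STRING_ELT(reads, r)) + 63) / 64;
    if (w > max_read_words) max_read_words = w;
  }
  for (int t = 0; t < nT; ++t) {
    tgt[t] = encode(as<std::string>(targets[t]));
    tpk[t] = pack(tgt[t], max_read_words + 2);
  }

  IntegerVector out_entry(nR), out_offset(nR);
  CharacterVector out_strand(nR);
  NumericVector out_identity(nR);
  LogicalVector out_ambig(nR);

  for (int r = 0; r < nR; ++r) {
    std::string rs = as<std::string>(reads[r]);
    std::vector<unsigned char> fwd = encode(rs);
    std::vector<unsigned char> rev = revcomp(fwd);
    Packed fpk = pack(fwd, 0), rpk = pack(rev, 0);
    const int Lr = (int) fwd.size();
    // max mismatches compatible with identity >= min_identity
    int max_mm = (int) std::floor((1.0 - min_identity) * Lr + 1e-9);

    int best_mm = max_mm + 1, best_entry = -1, best_off = -1, best_strand = 0;
    bool ambig = false;

    for (int t = 0; t < nT; ++t) {
      const int Lt = (int) tgt[t].size();
      if (Lr > Lt) continue;
      int max_off = Lt - Lr;                    // inclusive
      if (is_tandem[t]) {
        int lm = monomer_len[t];
        if (lm - 1 < max_off) max_off = lm - 1; // canonical range
      }
      if (!allow_indels) {
        for (int o = 0; o <= max_off; ++o) {
          for (int s = 0; s < 2; ++s) {
            const Packed &R = s == 0 ? fpk : rpk;
            int limit = best_mm < max_mm ? best_mm : max_mm;
            int mm = mm_at(R, tpk[t], o, limit);
            if (mm < best_mm) {
              best_mm = mm; best_entry = t; best_off = o; best_strand = s;
              ambig = false;
            } else if (mm == best_mm && best_mm <= max_mm && t != best_entry) {
              ambig = true;
            }
          }
        }
      } else {
        for (int s = 0; s < 2; ++s) {
          const std::vector<unsigned char> &R = s == 0 ? fwd : rev;
          int end_col = 0;
          int d = edit_infix(R, tgt[t], &end_col);
          int o = end_col - Lr; if (o < 0) o = 0;
          if (is_tandem[t]) o = o % monomer_len[t];
          if (d < best_mm) {
            best_mm = d; best_entry = t; best_off = o; best_strand = s;
            ambig = false;
          } else if (d == best_mm && best_mm <= max_mm && t != best_entry) {
            ambig = true;
          }
        }
      }
    }

    if (best_mm <= max_mm) {
      out_entry[r] = best_entry + 1;
      out_offset[r] = best_off;
      out_strand[r] = best_strand == 0 ? "+" : "-";
      out_identity[r] = 1.0 - (double) best_mm / (double) Lr;
      out_ambig[r] = ambig;
    } else {
      out_entry[r] = NA_INTEGER;
      out_offset[r] = NA_INTEGER;
      out_strand[r] = NA_STRING;
      out_identity[r] = NA_REAL;
      out_ambig[r] = NA_LOGICAL;
    }
  }

  return DataFrame::create(_["entry"] = out_entry, _["offset"] = out_offset,
                           _["strand"] = out_strand, _["identity"] = out_identity,
                           _["ambiguous"] = out_ambig,
                           _["stringsAsFactors"] = false);
}

// Per-offset identity of `pattern` slid along `seq`, both orientations.
// Column 1: pattern as given; column 2: reverse complement of pattern.
// [[Rcpp::export]]
NumericMatrix cpp_identity_profile(std::string seq, std::string pattern) {
  std::vector<unsigned char> S = encode(seq), P = encode(pattern), Q = revcomp(P);
  const int Ls = (int) S.size(), Lp = (int) P.size();
  const int nOff = Ls - Lp + 1;
  if (nOff <= 0) return NumericMatrix(0, 2);
  Packed spk = pack(S, (Lp + 63) / 64 + 2);
  Packed ppk = pack(P, 0), qpk = pack(Q, 0);
  NumericMatrix out(nOff, 2);
  for (int o = 0; o < nOff; ++o) {
    out(o, 0) = (double) (Lp - mm_at(ppk, spk, o, Lp)) / Lp;
    out(o, 1) = (double) (Lp - mm_at(qpk, spk, o, Lp)) / Lp;
  }
  return out;
}

// Accumulate per-monomer-position base counts from reads already oriented to
// the plus strand of the dimer; read base i goes to (offset + i) mod lm.
// [[Rcpp::export]]
IntegerMatrix cpp_base_counts(CharacterVector reads, IntegerVector offsets, int lm) {
  IntegerMatrix counts(4, lm);
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    int off = offsets[r];
    for (size_t i = 0; i < s.size(); ++i) {
      int b = enc_base(s[i]);
      if (b < 4) counts(b, (off + (int) i) % lm)++;
    }
  }
  return counts;
}
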