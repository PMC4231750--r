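#include <Rcpp.h>
#include <unordered_map>
#include <cstring>
using namespace Rcpp;

// 2-bit encode; -1 for anything outside ACGT (N never matches exactly)
static inline int enc(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
  }
  return 'N';
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp(c);
  return r;
}

// k-mer code at s[pos..pos+k), or -1 if non-ACGT present
static long long kmer_code(const std::string &s, size_t pos, int k) {
  long long code = 0;
  for (int j = 0; j < k; ++j) {
    int e = enc(s[pos + j]);
    if (e < 0) return -1;
    code = (code << 2) | e;
  }
  return code;
}

struct RefIndex {
  std::unordered_map<long long, std::vector<int> > pos;
};

// All exact occurrences of each read on both strands of each reference,
// seeded on the read's first k-mer and verified by full comparison.
// Returns hits ordered by (read, ref, offset, strand '+' before '-').
// [[Rcpp::export]]
DataFrame cpp_exact_all(CharacterVector reads, CharacterVector refs, int k) {
  int nref = refs.size();
  std::vector<std::string> R(nref);
  std::vector<RefIndex> idx(nref);
  for (int i = 0; i < nref; ++i) {
    R[i] = as<std::string>(refs[i]);
    if ((int)R[i].size() >= k) {
      for (size_t p = 0; p + k <= R[i].size(); ++p) {
        long long code = kmer_code(R[i], p, k);
        if (code >= 0) idx[i].pos[code].push_back((int)p);
      }
    }
  }
  std::vector<int> out_read, out_ref, out_off;
  std::vector<std::string> out_strand;
  for (int r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    int len = (int)rd.size();
    if (len < k) continue;
    long long cf = kmer_code(rd, 0, k);
    if (cf < 0) continue;  // read contains N: matches nothing exactly
    std::string rc = revcomp(rd);
    long long cr = kmer_code(rc, 0, k);
    for (int i = 0; i < nref; ++i) {
      const std::string &ref = R[i];
      // collect (offset, strand) then emit in offset order, '+' first on ties
      std::vector<std::pair<int, int> > hits;  // (offset, 0='+' 1='-')
      auto it = idx[i].pos.find(cf);
      if (it != idx[i].pos.end()) {
        for (int p : it->second)
          if (p + len <= (int)ref.size() &&
              std::memcmp(ref.data() + p, rd.data(), len) == 0)
            hits.push_back(std::make_pair(p, 0));
      }
      it = idx[i].pos.find(cr);
      if (cr >= 0 && it != idx[i].pos.end()) {
        for (int p : it->second)
          if (p + len <= (int)ref.size() &&
              std::memcmp(ref.data() + p, rc.data(), len) == 0)
            hits.push_back(std::make_pair(p, 1));
      }
      std::sort(hits.begin(), hits.end());
      for (auto &h : hits) {
        out_read.push_back(r + 1);
        out_ref.push_back(i + 1);
        out_off.push_back(h.first);
        out_strand.push_back(h.second == 0 ? "+" : "-");
      }
    }
  }
  return DataFrame::create(_["read"] = out_read, _["ref"] = out_ref,
                           _["offset"] = out_off, _["strand"] = out_strand,
                           _["stringsAsFactors"] = false);
}

static inline int hamming_capped(const char *a, const char *b, int len,
                                 int cap) {
  int mm = 0;
  for (int j = 0; j < len; ++j) {
    if (a[j] != b[j] && ++mm > cap) return mm;
  }
  return mm;
}

// Best gapless (substitution-only) hit of each read against a set of
// consensus sequences, both strands, at most max_mm mismatches.
// Ties resolve to (reference input order, smaller offset, '+' before '-').
// N compares unequal to every base, i.e. a mismatch.
//
// Reads long enough for the pigeonhole bound (length >= 8*(max_mm+1))
// take a seed-and-verify path: the read splits into max_mm+1 disjoint
// segments, at least one of which must align mismatch-free, so the 8-mer
// opening that segment indexes every candidate offset. Shorter reads fall
// back to the full scan. Both paths visit surviving candidates in
// tie-break order and keep the first strictly best hit, which is exactly
// the full scan's answer.
// [[Rcpp::export]]
DataFrame cpp_hamming_best(CharacterVector reads, CharacterVector refs,
                           int max_mm) {
  const int q = 8;  // seed length
  int nref = refs.size();
  std::vector<std::string> R(nref);
  std::vector<std::unordered_map<long long, std::vector<int> > > idx(nref);
  for (int i = 0; i < nref; ++i) {
    R[i] = as<std::string>(refs[i]);
    if ((int)R[i].size() >= q)
      for (size_t p = 0; p + q <= R[i].size(); ++p) {
        long long code = kmer_code(R[i], p, q);
        if (code >= 0) idx[i][code].push_back((int)p);
      }
  }
  int n = reads.size();
  IntegerVector ref_out(n, NA_INTEGER), off_out(n, NA_INTEGER),
      mm_out(n, NA_INTEGER);
  CharacterVector strand_out(n, NA_STRING);
  int nseg = max_mm + 1;
  for (int r = 0; r < n; ++r) {
    std::string rd = as<std::string>(reads[r]);
    std::string rc = revcomp(rd);
    int len = (int)rd.size();
    int best_mm = max_mm + 1, best_ref = -1, best_off = -1, best_str = -1;
    bool seeded = len >= q * nseg;
    if (seeded) {
      // candidate (offset, strand) pairs per reference, via segment seeds
      for (int i = 0; i < nref && best_mm > 0; ++i) {
        const std::string &ref = R[i];
        int L = (int)ref.size();
        std::vector<std::pair<int, int> > cand;  // (offset, strand 0/1)
        for (int str = 0; str < 2; ++str) {
          const std::string &query = str == 0 ? rd : rc;
          for (int s = 0; s < nseg; ++s) {
            int o = (int)((long long)s * len / nseg);
            long long code = kmer_code(query, o, q);
            if (code < 0) continue;
            auto it = idx[i].find(code);
            if (it == idx[i].end()) continue;
            for (int p : it->second) {
              int off = p - o;
              if (off >= 0 && off + len <= L)
                cand.push_back(std::make_pair(off, str));
            }
          }
        }
        std::sort(cand.begin(), cand.end());
        cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
        for (auto &c : cand) {
          int cap = best_mm - 1;
          const std::string &query = c.second == 0 ? rd : rc;
          int mm = hamming_capped(ref.data() + c.first, query.data(), len,
                                  cap);
          if (mm < best_mm) {
            best_mm = mm; best_ref = i; best_off = c.first;
            best_str = c.second;
            if (best_mm == 0) break;
          }
        }
      }
    } else {
      for (int i = 0; i < nref && best_mm > 0; ++i) {
        const std::string &ref = R[i];
        int L = (int)ref.size();
        for (int p = 0; p + len <= L && best_mm > 0; ++p) {
          int cap = best_mm - 1;  // only strictly better survives
          int mm = hamming_capped(ref.data() + p, rd.data(), len, cap);
          if (mm < best_mm) {
            best_mm = mm; best_ref = i; best_off = p; best_str = 0;
            if (best_mm == 0) break;
          }
          cap = best_mm - 1;
          mm = hamming_capped(ref.data() + p, rc.data(), len, cap);
          if (mm < best_mm) {
            best_mm = mm; best_ref = i; best_off = p; best_str = 1;
          }
        }
      }
    }
    if (best_ref >= 0) {
      ref_out[r] = best_ref + 1;
      off_out[r] = best_off;
      mm_out[r] = best_mm;
      strand_out[r] = best_str == 0 ? "+" : "-";
    }
  }
  return DataFrame::create(_["ref"] = ref_out, _["offset"] = off_out,
                           _["strand"] = strand_out, _["mismatches"] = mm_out,
                           _["stringsAsFactors"] = false);
}

// Leftmost 3' adapter match. Returns the insert length (0-based clip
// position) per read, or -1 when no position matches. A suffix of length
// >= min_overlap must equal the adapter prefix of the same length (reads
// running past a full adapter accept the full-adapter comparison); a
// terminal suffix shorter than min_overlap may still match an adapter
// prefix (partial adapter at the very end of the read).
// [[Rcpp::export]]
IntegerVector cpp_clip_adapter(CharacterVector reads, std::string adapter,
                               int min_overlap) {
  int alen = (int)adapter.size();
  int n = reads.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    std::string rd = as<std::string>(reads[r]);
    int len = (int)rd.size();
    int found = -1;
    for (int i = 0; i < len; ++i) {
      int tlen = len - i;
      int cmp = tlen < alen ? tlen : alen;
      if (std::memcmp(rd.data() + i, adapter.data(), cmp) == 0) {
        found = i;
        break;
      }
    }
    out[r] = found;
  }
  return out;
}
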