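// 2-bit packed canonical k-mer counting, hap-mer set algebra and read
// scoring.  Codes are uint64 (k <= 31) shuttled to R as raw vectors of
// 8 bytes per k-mer so that k > 26 stays exact (doubles lose integers
// beyond 2^53).

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cstring>
#include <string>

using namespace Rcpp;

// Open-addressing hash table (linear probing, power-of-2 capacity) for
// packed k-mer codes: node-based std::unordered_map is several times
// slower at the hundreds of millions of inserts a 45x short-read set
// produces.  Codes occupy at most 62 bits, so ~0ULL is a safe empty
// sentinel.
static inline uint64_t mix64(uint64_t x) {
    x += 0x9e3779b97f4a7c15ULL;
    x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
    x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
    return x ^ (x >> 31);
}

struct KTable {
    static constexpr uint64_t EMPTY = ~0ULL;
    std::vector<uint64_t> keys;
    std::vector<uint32_t> vals;
    size_t mask, n;
    explicit KTable(size_t cap_hint = 1 << 16) : n(0) {
        size_t cap = 1;
        while (cap < cap_hint * 2) cap <<= 1;
        keys.assign(cap, EMPTY);
        vals.assign(cap, 0);
        mask = cap - 1;
    }
    void grow() {
        std::vector<uint64_t> ok;
        std::vector<uint32_t> ov;
        ok.swap(keys);
        ov.swap(vals);
        size_t cap = (mask + 1) << 1;
        keys.assign(cap, EMPTY);
        vals.assign(cap, 0);
        mask = cap - 1;
        for (size_t i = 0; i < ok.size(); ++i) {
            if (ok[i] == EMPTY) continue;
            size_t j = mix64(ok[i]) & mask;
            while (keys[j] != EMPTY) j = (j + 1) & mask;
            keys[j] = ok[i];
            vals[j] = ov[i];
        }
    }
    inline void inc(uint64_t key) {
        size_t j = mix64(key) & mask;
        while (true) {
            if (keys[j] == key) { ++vals[j]; return; }
            if (keys[j] == EMPTY) {
                keys[j] = key;
                vals[j] = 1;
                if (++n * 10 > (mask + 1) * 7) grow();
                return;
            }
            j = (j + 1) & mask;
        }
    }
    inline bool contains(uint64_t key) const {
        size_t j = mix64(key) & mask;
        while (true) {
            if (keys[j] == key) return true;
            if (keys[j] == EMPTY) return false;
            j = (j + 1) & mask;
        }
    }
    inline int get(uint64_t key) const {
        size_t j = mix64(key) & mask;
        while (true) {
            if (keys[j] == key) return (int)vals[j];
            if (keys[j] == EMPTY) return -1;
            j = (j + 1) & mask;
        }
    }
};

typedef KTable kcount_map;

static inline int base2bits(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // any IUPAC ambiguity code breaks the window
    }
}

static inline uint64_t kmask(int k) {
    return (2 * k == 64) ? ~0ULL : ((1ULL << (2 * k)) - 1);
}

static void count_one(const char *s, R_xlen_t n, int k, kcount_map &m) {
    const uint64_t mask = kmask(k);
    const int shift = 2 * (k - 1);
    uint64_t f = 0, r = 0;
    int valid = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        int b = base2bits(s[i]);
        if (b < 0) { valid = 0; f = 0; r = 0; continue; }
        f = ((f << 2) | (uint64_t)b) & mask;
        r = (r >> 2) | ((uint64_t)(3 - b) << shift);
        if (valid < k) ++valid;
        if (valid >= k) {
            uint64_t c = f < r ? f : r;
            m.inc(c);
        }
    }
}

static RawVector codes_to_raw(const std::vector<uint64_t> &v) {
    RawVector out(v.size() * 8);
    if (!v.empty()) std::memcpy(RAW(out), v.data(), v.size() * 8);
    return out;
}

static std::vector<uint64_t> raw_to_codes(const RawVector &r) {
    if (r.size() % 8 != 0) stop("raw k-mer code vector length not a multiple of 8");
    std::vector<uint64_t> v(r.size() / 8);
    if (!v.empty()) std::memcpy(v.data(), RAW(r), r.size());
    return v;
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector reads, int k, int min_count_keep) {
    if (k < 3 || k > 31 || k % 2 == 0)
        stop("k must be odd and in [3, 31]");
    kcount_map m;
    for (R_xlen_t i = 0; i < reads.size(); ++i) {
        if (reads[i] == NA_STRING) continue;
        const char *s = CHAR(reads[i]);
        count_one(s, (R_xlen_t)LENGTH(reads[i]), k, m);
        if (i % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    std::vector<uint64_t> codes;
    codes.reserve(m.n);
    for (size_t j = 0; j < m.keys.size(); ++j)
        if (m.keys[j] != KTable::EMPTY && (int)m.vals[j] >= min_count_keep)
            codes.push_back(m.keys[j]);
    std::sort(codes.begin(), codes.end());
    IntegerVector counts(codes.size());
    for (size_t i = 0; i < codes.size(); ++i)
        counts[i] = m.get(codes[i]);
    return List::create(_["codes"] = codes_to_raw(codes), _["counts"] = counts);
}

// [[Rcpp::export]]
List cpp_extract_hapmers(RawVector codes_a, IntegerVector counts_a,
                         RawVector codes_b, IntegerVector counts_b,
                         int min_count, int max_count) {
    std::vector<uint64_t> ca = raw_to_codes(codes_a);
    std::vector<uint64_t> cb = raw_to_codes(codes_b);
    if ((R_xlen_t)ca.size() != counts_a.size() || (R_xlen_t)cb.size() != counts_b.size())
        stop("codes/counts length mismatch");
    KTable ma(ca.size() + 1), mb(cb.size() + 1);
    for (size_t i = 0; i < ca.size(); ++i) { ma.inc(ca[i]); }
    for (size_t i = 0; i < cb.size(); ++i) { mb.inc(cb[i]); }
    // overwrite the placeholder counts with the real ones
    for (size_t i = 0; i < ca.size(); ++i) {
        size_t j = mix64(ca[i]) & ma.mask;
        while (ma.keys[j] != ca[i]) j = (j + 1) & ma.mask;
        ma.vals[j] = (uint32_t)counts_a[i];
    }
    for (size_t i = 0; i < cb.size(); ++i) {
        size_t j = mix64(cb[i]) & mb.mask;
        while (mb.keys[j] != cb[i]) j = (j + 1) & mb.mask;
        mb.vals[j] = (uint32_t)counts_b[i];
    }
    std::vector<uint64_t> sa, sb;
    for (size_t i = 0; i < ca.size(); ++i) {
        int n = counts_a[i];
        if (n < min_count || (max_count > 0 && n > max_count)) continue;
        int nb = mb.get(ca[i]);
        if (nb < min_count) sa.push_back(ca[i]);
    }
    for (size_t i = 0; i < cb.size(); ++i) {
        int n = counts_b[i];
        if (n < min_count || (max_count > 0 && n > max_count)) continue;
        int na = ma.get(cb[i]);
        if (na < min_count) sb.push_back(cb[i]);
    }
    std::sort(sa.begin(), sa.end());
    std::sort(sb.begin(), sb.end());
    return List::create(_["specific_a"] = codes_to_raw(sa),
                        _["specific_b"] = codes_to_raw(sb));
}

// Score each read by occurrences of set-A and set-B canonical k-mers.
// [[Rcpp::export]]
List cpp_score_reads(CharacterVector reads, int k,
                     RawVector set_a, RawVector set_b) {
    std::vector<uint64_t> va = raw_to_codes(set_a), vb = raw_to_codes(set_b);
    KTable sa(va.size() + 1), sb(vb.size() + 1);
    for (size_t i = 0; i < va.size(); ++i) sa.inc(va[i]);
    for (size_t i = 0; i < vb.size(); ++i) sb.inc(vb[i]);
    bool ea = va.empty(), eb = vb.empty();
    const uint64_t mask = kmask(k);
    const int shift = 2 * (k - 1);
    IntegerVector score_a(reads.size()), score_b(reads.size());
    for (R_xlen_t i = 0; i < reads.size(); ++i) {
        int na = 0, nb = 0;
        if (reads[i] != NA_STRING) {
            const char *s = CHAR(reads[i]);
            R_xlen_t n = (R_xlen_t)LENGTH(reads[i]);
            uint64_t f = 0, r = 0;
            int valid = 0;
            for (R_xlen_t j = 0; j < n; ++j) {
                int b = base2bits(s[j]);
                if (b < 0) { valid = 0; f = 0; r = 0; continue; }
                f = ((f << 2) | (uint64_t)b) & mask;
                r = (r >> 2) | ((uint64_t)(3 - b) << shift);
                if (valid < k) ++valid;
                if (valid >= k) {
                    uint64_t c = f < r ? f : r;
                    if (!ea && sa.contains(c)) ++na;
                    if (!eb && sb.contains(c)) ++nb;
                }
            }
        }
        score_a[i] = na;
        score_b[i] = nb;
        if (i % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    return List::create(_["score_a"] = score_a, _["score_b"] = score_b);
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmers(RawVector codes, int k) {
    std::vector<uint64_t> v = raw_to_codes(codes);
    static const char bases[5] = "ACGT";
    CharacterVector out(v.size());
    std::string buf(k, 'A');
    for (size_t i = 0; i < v.size(); ++i) {
        for (int j = 0; j < k; ++j)
            buf[j] = bases[(v[i] >> (2 * (k - 1 - j))) & 3ULL];
        out[i] = buf;
    }
    return out;
}

// Canonical (min of forward / reverse complement) codes of k-length strings.
// [[Rcpp::export]]
RawVector cpp_encode_canonical(CharacterVector kmers, int k) {
    std::vector<uint64_t> v;
    v.reserve(kmers.size());
    const int shift = 2 * (k - 1);
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        const char *s = CHAR(kmers[i]);
        if ((int)LENGTH(kmers[i]) != k) stop("k-mer %d has wrong length", (int)i + 1);
        uint64_t f = 0, r = 0;
        for (int j = 0; j < k; ++j) {
            int b = base2bits(s[j]);
            if (b < 0) stop("non-ACGT base in k-mer %d", (int)i + 1);
            f = (f << 2) | (uint64_t)b;
            r = (r >> 2) | ((uint64_t)(3 - b) << shift);
        }
        v.push_back(f < r ? f : r);
    }
    return codes_to_raw(v);
}

// Random DNA of length n with the given GC fraction, driven by R's RNG.
// [[Rcpp::export]]
CharacterVector cpp_random_dna(int n, double gc) {
    std::string s((size_t)n, 'A');
    double half_gc = gc / 2.0, half_at = (1.0 - gc) / 2.0;
    for (int i = 0; i < n; ++i) {
        double u = unif_rand();
        if (u < half_at) s[i] = 'A';
        else if (u < 2 * half_at) s[i] = 'T';
        else if (u < 2 * half_at + half_gc) s[i] = 'C';
        else s[i] = 'G';
    }
    return CharacterVector::create(s);
}

// Substitution errors at a per-base rate; the replacement base is drawn
// uniformly from the three alternatives.  Uses R's RNG.
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector seqs, double rate) {
    if (rate <= 0) return seqs;
    static const char bases[5] = "ACGT";
    CharacterVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        std::string s(CHAR(seqs[i]), (size_t)LENGTH(seqs[i]));
        for (size_t j = 0; j < s.size(); ++j) {
            if (unif_rand() < rate) {
                char c = s[j];
                char nc;
                do { nc = bases[(int)(unif_rand() * 4.0) & 3]; } while (nc == c);
                s[j] = nc;
            }
        }
        out[i] = s;
        if (i % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    out.attr("names") = seqs.attr("names");
    return out;
}

static std::string revcomp_str(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) {
        switch (r[i]) {
        case 'A': r[i] = 'T'; break; case 'T': r[i] = 'A'; break;
        case 'C': r[i] = 'G'; break; case 'G': r[i] = 'C'; break;
        case 'a': r[i] = 't'; break; case 't': r[i] = 'a'; break;
        case 'c': r[i] = 'g'; break; case 'g': r[i] = 'c'; break;
        default: break;
        }
    }
    return r;
}

// smallest period of u; u is primitive iff smallest period == |u|
static size_t smallest_period(const std::string &u) {
    size_t L = u.size();
    for (size_t p = 1; p < L; ++p) {
        if (L % p != 0) continue;
        bool ok = true;
        for (size_t i = p; i < L && ok; ++i)
            if (u[i] != u[i - p]) ok = false;
        if (ok) return p;
    }
    return L;
}

static std::string canonical_rotation_cpp(const std::string &u) {
    std::string best;
    std::string rc = revcomp_str(u);
    for (int strand = 0; strand < 2; ++strand) {
        const std::string &s = strand == 0 ? u : rc;
        std::string d = s + s;
        for (size_t i = 0; i < s.size(); ++i) {
            std::string rot = d.substr(i, s.size());
            if (best.empty() || rot < best) best = rot;
        }
    }
    return best;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical_rotation(CharacterVector units) {
    CharacterVector out(units.size());
    for (R_xlen_t i = 0; i < units.size(); ++i)
        out[i] = canonical_rotation_cpp(std::string(CHAR(units[i])));
    return out;
}

// Count tandem-repeated candidate units (>= 2 consecutive copies) of each
// length in [min_len, max_len] within the supplied sequences.  Every
// position i with an exact period-L match s[i, i+L) == s[i+L, i+2L)
// contributes one occurrence of the (primitive) unit starting at i; units
// are pooled over rotations and strand via canonical rotation.
// [[Rcpp::export]]
DataFrame cpp_tandem_explore(CharacterVector seqs, int min_len, int max_len) {
    std::unordered_map<std::string, double> tot;
    for (R_xlen_t si = 0; si < seqs.size(); ++si) {
        const char *s = CHAR(seqs[si]);
        R_xlen_t n = (R_xlen_t)LENGTH(seqs[si]);
        for (int L = min_len; L <= max_len; ++L) {
            for (R_xlen_t i = 0; i + 2 * L <= n; ++i) {
                if (std::memcmp(s + i, s + i + L, (size_t)L) != 0) continue;
                std::string u(s + i, s + i + L);
                bool clean = true;
                for (int j = 0; j < L && clean; ++j)
                    if (base2bits(u[j]) < 0) clean = false;
                if (!clean) continue;
                if (smallest_period(u) != (size_t)L) continue;  // skip non-primitive
                tot[canonical_rotation_cpp(u)] += 1.0;
            }
        }
        Rcpp::checkUserInterrupt();
    }
    std::vector<std::pair<std::string, double> > v(tot.begin(), tot.end());
    std::sort(v.begin(), v.end(),
              [](const std::pair<std::string, double> &a,
                 const std::pair<std::string, double> &b) {
                  if (a.second != b.second) return a.second > b.second;
                  return a.first < b.first;
              });
    CharacterVector unit(v.size());
    IntegerVector len(v.size());
    NumericVector count(v.size());
    for (size_t i = 0; i < v.size(); ++i) {
        unit[i] = v[i].first;
        len[i] = (int)v[i].first.size();
        count[i] = v[i].second;
    }
    return DataFrame::create(_["unit"] = unit, _["unit_length"] = len,
                             _["count"] = count,
                             _["stringsAsFactors"] = false);
}
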