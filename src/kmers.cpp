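#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// 2-bit packed k-mers, k <= 63, in a 128-bit word.  Forward and
// reverse-complement words are maintained by rolling updates so
// canonicalization is O(1) per base while streaming.
typedef unsigned __int128 kmer_t;

struct KmerHash {
    size_t operator()(const kmer_t& x) const {
        uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
        uint64_t h = lo * 0x9E3779B97F4A7C15ULL ^ (hi + 0x9E3779B97F4A7C15ULL + (lo << 6));
        return (size_t)h;
    }
};

typedef std::unordered_map<kmer_t, uint32_t, KmerHash> KmerMap;

static inline int base2bits(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline kmer_t revcomp_kmer(kmer_t kmer, int k) {
    kmer_t rc = 0;
    for (int i = 0; i < k; ++i) {
        rc = (rc << 2) | (kmer_t)(3 - (int)(kmer & 3));
        kmer >>= 2;
    }
    return rc;
}

// Stream sequences into a canonical k-mer count table.
static void count_into(const CharacterVector& seqs, int k, KmerMap& tab) {
    const kmer_t mask = (((kmer_t)1) << (2 * k)) - 1;
    const int rcshift = 2 * (k - 1);
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
        const char* str = CHAR(STRING_ELT(seqs, s));
        kmer_t fwd = 0, rev = 0;
        int run = 0;
        for (const char* p = str; *p; ++p) {
            int b = base2bits(*p);
            if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
            fwd = ((fwd << 2) | (kmer_t)b) & mask;
            rev = (rev >> 2) | (((kmer_t)(3 - b)) << rcshift);
            if (++run >= k) ++tab[fwd < rev ? fwd : rev];
        }
    }
}

static void check_k(int k) {
    if (k < 1 || k > 63) stop("k must be in 1..63");
}

// [[Rcpp::export(name = ".cpp_kmer_histogram")]]
DataFrame cpp_kmer_histogram(CharacterVector seqs, int k) {
    check_k(k);
    KmerMap tab;
    tab.reserve(1 << 20);
    count_into(seqs, k, tab);
    std::unordered_map<uint32_t, double> hist;
    for (KmerMap::const_iterator it = tab.begin(); it != tab.end(); ++it)
        hist[it->second] += 1.0;
    std::vector<uint32_t> mult;
    mult.reserve(hist.size());
    for (std::unordered_map<uint32_t, double>::const_iterator it = hist.begin();
         it != hist.end(); ++it)
        mult.push_back(it->first);
    std::sort(mult.begin(), mult.end());
    IntegerVector m(mult.size());
    NumericVector n(mult.size());
    for (size_t i = 0; i < mult.size(); ++i) {
        m[i] = (int)mult[i];
        n[i] = hist[mult[i]];
    }
    return DataFrame::create(_["multiplicity"] = m, _["count"] = n);
}

// Intersection of distinct above-error canonical k-mers of two read sets.
// [[Rcpp::export(name = ".cpp_kmer_intersect")]]
NumericVector cpp_kmer_intersect(CharacterVector a, CharacterVector b, int k,
                                 int min_count_a, int min_count_b) {
    check_k(k);
    KmerMap ta, tb;
    ta.reserve(1 << 20); tb.reserve(1 << 20);
    count_into(a, k, ta);
    count_into(b, k, tb);
    double na = 0, nb = 0, ninter = 0;
    for (KmerMap::const_iterator it = ta.begin(); it != ta.end(); ++it) {
        if ((int)it->second < min_count_a) continue;
        ++na;
        KmerMap::const_iterator jt = tb.find(it->first);
        if (jt != tb.end() && (int)jt->second >= min_count_b) ++ninter;
    }
    for (KmerMap::const_iterator it = tb.begin(); it != tb.end(); ++it)
        if ((int)it->second >= min_count_b) ++nb;
    return NumericVector::create(_["intersection"] = ninter,
                                 _["union"] = na + nb - ninter,
                                 _["n_a"] = na, _["n_b"] = nb);
}

// de Bruijn branch classification over the read k-mer table.  Every stored
// above-error k-mer is probed on both outgoing sides (as oriented and as
// reverse complement) for >= 2 extensions above the error cutoff.  A 2-way
// side with both extension multiplicities <= var_mult * het_peak is a
// variant branch; a side with >= 3 extensions, or any extension above
// rep_mult * hom_peak, is a repeat branch.
// [[Rcpp::export(name = ".cpp_branch_stats")]]
List cpp_branch_stats(CharacterVector seqs, int k, double error_cutoff,
                      double het_peak, double hom_peak,
                      double var_mult, double rep_mult,
                      double max_sample) {
    check_k(k);
    KmerMap tab;
    tab.reserve(1 << 20);
    count_into(seqs, k, tab);
    const kmer_t mask = (((kmer_t)1) << (2 * k)) - 1;
    double n_above = 0;
    for (KmerMap::const_iterator it = tab.begin(); it != tab.end(); ++it)
        if (it->second > error_cutoff) ++n_above;
    uint64_t step = 1;
    if (max_sample > 0 && n_above > max_sample)
        step = (uint64_t)std::ceil(n_above / max_sample);
    double sampled = 0, var_branches = 0, rep_branches = 0;
    uint64_t idx = 0;
    const double var_thr = var_mult * het_peak;
    const double rep_thr = rep_mult * hom_peak;
    for (KmerMap::const_iterator it = tab.begin(); it != tab.end(); ++it) {
        if (it->second <= error_cutoff) continue;
        if ((idx++ % step) != 0) continue;
        ++sampled;
        kmer_t orient[2];
        orient[0] = it->first;
        orient[1] = revcomp_kmer(it->first, k);
        for (int o = 0; o < 2; ++o) {
            int n_ext = 0;
            double ext_max = 0;
            bool all_le_var = true;
            for (int b = 0; b < 4; ++b) {
                kmer_t nxt = ((orient[o] << 2) | (kmer_t)b) & mask;
                kmer_t rc = revcomp_kmer(nxt, k);
                KmerMap::const_iterator jt = tab.find(nxt < rc ? nxt : rc);
                if (jt == tab.end()) continue;
                double c = (double)jt->second;
                if (c <= error_cutoff) continue;
                ++n_ext;
                if (c > ext_max) ext_max = c;
                if (c > var_thr) all_le_var = false;
            }
            if (n_ext < 2) continue;
            if (n_ext >= 3 || ext_max > rep_thr) ++rep_branches;
            else if (all_le_var && het_peak > 0) ++var_branches;
        }
    }
    return List::create(
        _["sampled_kmers"] = sampled,
        _["variant_branches"] = var_branches,
        _["repeat_branches"] = rep_branches,
        _["variant_branch_rate"] = sampled > 0 ? var_branches / sampled : NA_REAL,
        _["repeat_branch_rate"] = sampled > 0 ? rep_branches / sampled : NA_REAL);
}

// Count distinct canonical k-mers shared between every pair of sequences.
// K-mers occurring in more than max_occ sequences are skipped so that
// high-copy repeat families do not link every contig to every other.
// [[Rcpp::export(name = ".cpp_shared_kmer_pairs")]]
DataFrame cpp_shared_kmer_pairs(CharacterVector seqs, int k, int min_shared,
                                int max_occ) {
    check_k(k);
    const kmer_t mask = (((kmer_t)1) << (2 * k)) - 1;
    const int rcshift = 2 * (k - 1);
    std::unordered_map<kmer_t, std::vector<int>, KmerHash> occ;
    occ.reserve(1 << 20);
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
        const char* str = CHAR(STRING_ELT(seqs, s));
        kmer_t fwd = 0, rev = 0;
        int run = 0;
        for (const char* p = str; *p; ++p) {
            int b = base2bits(*p);
            if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
            fwd = ((fwd << 2) | (kmer_t)b) & mask;
            rev = (rev >> 2) | (((kmer_t)(3 - b)) << rcshift);
            if (++run >= k) {
                std::vector<int>& v = occ[fwd < rev ? fwd : rev];
                if ((v.empty() || v.back() != (int)s) && (int)v.size() <= max_occ)
                    v.push_back((int)s);
            }
        }
    }
    std::unordered_map<uint64_t, uint32_t> paircnt;
    for (std::unordered_map<kmer_t, std::vector<int>, KmerHash>::const_iterator
             it = occ.begin(); it != occ.end(); ++it) {
        const std::vector<int>& v = it->second;
        if ((int)v.size() < 2 || (int)v.size() > max_occ) continue;
        for (size_t i = 0; i < v.size(); ++i)
            for (size_t j = i + 1; j < v.size(); ++j)
                ++paircnt[((uint64_t)v[i] << 32) | (uint64_t)v[j]];
    }
    std::vector<int> ii, jj, nn;
    for (std::unordered_map<uint64_t, uint32_t>::const_iterator it =
             paircnt.begin(); it != paircnt.end(); ++it) {
        if ((int)it->second < min_shared) continue;
        ii.push_back((int)(it->first >> 32) + 1);
        jj.push_back((int)(it->first & 0xffffffffULL) + 1);
        nn.push_back((int)it->second);
    }
    return DataFrame::create(_["i"] = wrap(ii), _["j"] = wrap(jj),
                             _["shared"] = wrap(nn));
}

// Substitution injection for simulated sequencing errors; pos is 1-based
// within each read; returns modified copies.
// [[Rcpp::export(name = ".cpp_substitute_bases")]]
CharacterVector cpp_substitute_bases(CharacterVector reads, IntegerVector read_idx,
                                     IntegerVector pos, CharacterVector newbase) {
    std::vector<std::string> out(reads.size());
    for (R_xlen_t i = 0; i < reads.size(); ++i)
        out[i] = as<std::string>(reads[i]);
    for (R_xlen_t i = 0; i < read_idx.size(); ++i) {
        int r = read_idx[i] - 1;
        int p = pos[i] - 1;
        if (r >= 0 && r < (int)out.size() && p >= 0 && p < (int)out[r].size())
            out[r][p] = CHAR(STRING_ELT(newbase, i))[0];
    }
    return wrap(out);
}
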