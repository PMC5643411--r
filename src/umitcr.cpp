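#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
using namespace Rcpp;

// Multi-pattern tag scan with bounded Hamming mismatch.
// For every read, reports every position where any tag matches with at most
// max_mm substitutions (no indels; amplicon orientation is fixed upstream).
// Positions are 0-based. Equivalent to an exact-match automaton over the tag
// set expanded to all Hamming-(<=max_mm) variants, which the reference loader
// guarantees to be collision-free.
// [[Rcpp::export]]
DataFrame tag_scan_cpp(CharacterVector reads, CharacterVector tags, int max_mm) {
    int n_tags = tags.size();
    std::vector<std::string> tag_s(n_tags);
    for (int t = 0; t < n_tags; ++t) tag_s[t] = as<std::string>(tags[t]);

    std::vector<int> out_read, out_tag, out_pos, out_mm;
    for (int i = 0; i < reads.size(); ++i) {
        const char *r = CHAR(STRING_ELT(reads, i));
        int rlen = (int) LENGTH(STRING_ELT(reads, i));
        for (int t = 0; t < n_tags; ++t) {
            const std::string &tg = tag_s[t];
            int tlen = (int) tg.size();
            for (int p = 0; p + tlen <= rlen; ++p) {
                int mm = 0;
                for (int k = 0; k < tlen; ++k) {
                    if (r[p + k] != tg[k] && ++mm > max_mm) break;
                }
                if (mm <= max_mm) {
                    out_read.push_back(i + 1);
                    out_tag.push_back(t + 1);
                    out_pos.push_back(p);
                    out_mm.push_back(mm);
                }
            }
        }
    }
    return DataFrame::create(_["read"] = out_read, _["tag"] = out_tag,
                             _["pos"] = out_pos, _["mm"] = out_mm);
}

// Elementwise longest common prefix of two character vectors (recycled if
// one has length 1).
// [[Rcpp::export]]
IntegerVector lcp_cpp(CharacterVector a, CharacterVector b) {
    int n = std::max(a.size(), b.size());
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        SEXP sa = STRING_ELT(a, a.size() == 1 ? 0 : i);
        SEXP sb = STRING_ELT(b, b.size() == 1 ? 0 : i);
        const char *pa = CHAR(sa), *pb = CHAR(sb);
        int la = LENGTH(sa), lb = LENGTH(sb), m = std::min(la, lb), k = 0;
        while (k < m && pa[k] == pb[k]) ++k;
        out[i] = k;
    }
    return out;
}

// Elementwise longest common suffix.
// [[Rcpp::export]]
IntegerVector lcs_cpp(CharacterVector a, CharacterVector b) {
    int n = std::max(a.size(), b.size());
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        SEXP sa = STRING_ELT(a, a.size() == 1 ? 0 : i);
        SEXP sb = STRING_ELT(b, b.size() == 1 ? 0 : i);
        const char *pa = CHAR(sa), *pb = CHAR(sb);
        int la = LENGTH(sa), lb = LENGTH(sb), m = std::min(la, lb), k = 0;
        while (k < m && pa[la - 1 - k] == pb[lb - 1 - k]) ++k;
        out[i] = k;
    }
    return out;
}

// Elementwise Hamming distance over equal-length strings (recycled scalar
// allowed). Unequal lengths are an error.
// [[Rcpp::export]]
IntegerVector hamming_cpp(CharacterVector a, CharacterVector b) {
    int n = std::max(a.size(), b.size());
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        SEXP sa = STRING_ELT(a, a.size() == 1 ? 0 : i);
        SEXP sb = STRING_ELT(b, b.size() == 1 ? 0 : i);
        if (LENGTH(sa) != LENGTH(sb))
            stop("hamming_cpp: strings must have equal length");
        const char *pa = CHAR(sa), *pb = CHAR(sb);
        int d = 0;
        for (int k = 0; k < LENGTH(sa); ++k) if (pa[k] != pb[k]) ++d;
        out[i] = d;
    }
    return out;
}

static inline int mm_with_len_penalty(const char *pa, int la, const char *pb, int lb) {
    int m = std::min(la, lb), d = std::abs(la - lb);
    for (int k = 0; k < m; ++k) if (pa[k] != pb[k]) ++d;
    return d;
}

// Mismatch count between possibly unequal-length sequences: Hamming over the
// shared prefix plus one mismatch per missing base.
// [[Rcpp::export]]
IntegerVector seq_mismatches_cpp(CharacterVector a, CharacterVector b) {
    int n = std::max(a.size(), b.size());
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        SEXP sa = STRING_ELT(a, a.size() == 1 ? 0 : i);
        SEXP sb = STRING_ELT(b, b.size() == 1 ? 0 : i);
        out[i] = mm_with_len_penalty(CHAR(sa), LENGTH(sa), CHAR(sb), LENGTH(sb));
    }
    return out;
}

// Per-base divergence: mismatches (with length penalty) over the longer length.
// [[Rcpp::export]]
NumericVector seq_divergence_cpp(CharacterVector a, CharacterVector b) {
    int n = std::max(a.size(), b.size());
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        SEXP sa = STRING_ELT(a, a.size() == 1 ? 0 : i);
        SEXP sb = STRING_ELT(b, b.size() == 1 ? 0 : i);
        int la = LENGTH(sa), lb = LENGTH(sb);
        int longer = std::max(la, lb);
        if (longer == 0) { out[i] = 0.0; continue; }
        out[i] = (double) mm_with_len_penalty(CHAR(sa), la, CHAR(sb), lb) / longer;
    }
    return out;
}

// All unordered pairs (i < j, 1-based) of equal-length strings at Hamming
// distance <= max_mm. Pigeonhole blocking: the string is cut into max_mm + 1
// chunks; any pair within distance max_mm agrees exactly on at least one
// chunk, so candidates are enumerated per chunk-value bucket.
// [[Rcpp::export]]
DataFrame near_pairs_cpp(CharacterVector x, int max_mm) {
    int n = x.size();
    std::vector<std::string> s(n);
    for (int i = 0; i < n; ++i) s[i] = as<std::string>(x[i]);
    int len = n ? (int) s[0].size() : 0;
    for (int i = 0; i < n; ++i)
        if ((int) s[i].size() != len) stop("near_pairs_cpp: unequal lengths");

    int n_chunks = max_mm + 1;
    if (len > 0 && n_chunks > len) n_chunks = len;
    std::vector<int> pi, pj, pd;
    std::unordered_set<long long> seen;
    for (int c = 0; c < n_chunks; ++c) {
        int from = (int) ((long long) c * len / n_chunks);
        int to   = (int) ((long long) (c + 1) * len / n_chunks);
        std::unordered_map<std::string, std::vector<int>> buckets;
        for (int i = 0; i < n; ++i)
            buckets[s[i].substr(from, to - from)].push_back(i);
        for (auto &kv : buckets) {
            std::vector<int> &b = kv.second;
            for (size_t u = 0; u < b.size(); ++u) {
                for (size_t v = u + 1; v < b.size(); ++v) {
                    int i = b[u], j = b[v];
                    long long key = (long long) i * n + j;
                    if (seen.count(key)) continue;
                    int d = 0; bool ok = true;
                    for (int k = 0; k < len; ++k) {
                        if (s[i][k] != s[j][k] && ++d > max_mm) { ok = false; break; }
                    }
                    if (ok) {
                        seen.insert(key);
                        pi.push_back(i + 1); pj.push_back(j + 1); pd.push_back(d);
                    }
                }
            }
        }
    }
    return DataFrame::create(_["i"] = pi, _["j"] = pj, _["dist"] = pd);
}

// Apply uniform per-base substitution errors (each hit base becomes one of
// the three other nucleotides with equal probability). Uses the R RNG so
// results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, double rate) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    if (rate <= 0) return clone(seqs);
    int n = seqs.size();
    CharacterVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        for (size_t k = 0; k < s.size(); ++k) {
            if (unif_rand() < rate) {
                char cur = s[k], sub;
                do {
                    sub = bases[(int) std::floor(unif_rand() * 4.0) % 4];
                } while (sub == cur);
                s[k] = sub;
            }
        }
        out[i] = s;
    }
    return out;
}
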