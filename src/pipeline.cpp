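#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstring>

using namespace Rcpp;

static inline char complement_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'a': return 't';
    case 'c': return 'g';
    case 'g': return 'c';
    case 't': return 'a';
    default:  return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string out(s.rbegin(), s.rend());
    for (auto& c : out) c = complement_base(c);
    return out;
}

// Merge one read pair: reverse-complement read2, scan overlaps from longest to
// min_overlap, accept the longest overlap whose mismatch fraction is within
// max_mismatch_fraction.  At overlap mismatches the base with the higher quality
// wins; ties (or missing qualities) fall to read1.
static bool merge_one(const std::string& r1, const std::string& r2,
                      const std::string& q1, const std::string& q2,
                      int min_overlap, double max_mm_frac,
                      std::string& merged) {
    const int l1 = (int) r1.size(), l2 = (int) r2.size();
    if (l1 == 0 || l2 == 0) return false;
    const std::string s2 = revcomp(r2);
    // q2 reversed so it indexes s2
    std::string qr2;
    const bool have_q = (q1.size() == r1.size()) && (q2.size() == r2.size());
    if (have_q) qr2.assign(q2.rbegin(), q2.rend());

    const int max_ov = std::min(l1, l2);
    for (int ov = max_ov; ov >= min_overlap; --ov) {
        const int allowed = (int) std::floor(max_mm_frac * ov);
        int mism = 0;
        const int off = l1 - ov; // start of overlap in r1
        bool ok = true;
        for (int j = 0; j < ov; ++j) {
            if (r1[off + j] != s2[j]) {
                if (++mism > allowed) { ok = false; break; }
            }
        }
        if (!ok) continue;
        merged.clear();
        merged.reserve(l1 + l2 - ov);
        merged.append(r1, 0, off);
        for (int j = 0; j < ov; ++j) {
            char b1 = r1[off + j], b2 = s2[j];
            if (b1 == b2) { merged.push_back(b1); continue; }
            if (have_q && qr2[j] > q1[off + j]) merged.push_back(b2);
            else merged.push_back(b1);
        }
        merged.append(s2, ov, (size_t) (l2 - ov));
        return true;
    }
    return false;
}

// [[Rcpp::export]]
CharacterVector merge_pairs_cpp(CharacterVector read1, CharacterVector read2,
                                CharacterVector qual1, CharacterVector qual2,
                                int min_overlap, double max_mismatch_fraction) {
    const R_xlen_t n = read1.size();
    if (read2.size() != n) stop("read1 and read2 must have equal length");
    const bool have_q = qual1.size() == n && qual2.size() == n;
    CharacterVector out(n);
    std::string merged;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (read1[i] == NA_STRING || read2[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        std::string r1 = as<std::string>(read1[i]);
        std::string r2 = as<std::string>(read2[i]);
        std::string q1 = have_q && qual1[i] != NA_STRING ? as<std::string>(qual1[i]) : std::string();
        std::string q2 = have_q && qual2[i] != NA_STRING ? as<std::string>(qual2[i]) : std::string();
        if (merge_one(r1, r2, q1, q2, min_overlap, max_mismatch_fraction, merged))
            out[i] = merged;
        else
            out[i] = NA_STRING;
    }
    return out;
}

// Best ungapped (Hamming) match of pattern in text at offsets [from, to];
// returns offset or -1; ties go to the leftmost offset.
static int best_hamming_hit(const std::string& text, const std::string& pat,
                            int from, int to, int max_mm, int& best_mm) {
    const int lp = (int) pat.size();
    int best = -1;
    best_mm = max_mm + 1;
    for (int off = from; off <= to; ++off) {
        int mism = 0;
        for (int j = 0; j < lp; ++j) {
            if (text[off + j] != pat[j]) {
                if (++mism >= best_mm) break;
            }
        }
        if (mism < best_mm) { best_mm = mism; best = off; if (mism == 0) break; }
    }
    return (best_mm <= max_mm) ? best : -1;
}

// [[Rcpp::export]]
CharacterVector extract_inserts_cpp(CharacterVector reads, std::string flank5,
                                    std::string flank3, int max_mismatches) {
    const R_xlen_t n = reads.size();
    const int l5 = (int) flank5.size(), l3 = (int) flank3.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (reads[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        std::string s = as<std::string>(reads[i]);
        const int ls = (int) s.size();
        int mm5, mm3;
        if (ls < l5 + l3) { out[i] = NA_STRING; continue; }
        int o5 = best_hamming_hit(s, flank5, 0, ls - l5 - l3, max_mismatches, mm5);
        if (o5 < 0) { out[i] = NA_STRING; continue; }
        int o3 = best_hamming_hit(s, flank3, o5 + l5, ls - l3, max_mismatches, mm3);
        if (o3 < 0) { out[i] = NA_STRING; continue; }
        out[i] = s.substr((size_t) (o5 + l5), (size_t) (o3 - o5 - l5));
    }
    return out;
}

// ---- Needleman-Wunsch global alignment identity ------------------------------
// Linear gap penalty; identity = matches / alignment columns of the optimal-score
// alignment with deterministic traceback preference diagonal > up > left.

struct NWResult { double identity; int matches; int columns; int score; };

static NWResult nw_identity(const std::string& a, const std::string& b,
                            int match, int mismatch, int gap,
                            std::vector<int>& score_buf,
                            std::vector<unsigned char>& dir_buf) {
    const int n = (int) a.size(), m = (int) b.size();
    const int w = m + 1;
    score_buf.assign((size_t) (n + 1) * w, 0);
    dir_buf.assign((size_t) (n + 1) * w, 0); // 0 diag, 1 up (gap in b), 2 left (gap in a)
    for (int j = 1; j <= m; ++j) { score_buf[j] = j * gap; dir_buf[j] = 2; }
    for (int i = 1; i <= n; ++i) {
        score_buf[(size_t) i * w] = i * gap;
        dir_buf[(size_t) i * w] = 1;
        const char ai = a[i - 1];
        for (int j = 1; j <= m; ++j) {
            const size_t at = (size_t) i * w + j;
            int sdiag = score_buf[at - w - 1] + (ai == b[j - 1] ? match : mismatch);
            int sup = score_buf[at - w] + gap;
            int sleft = score_buf[at - 1] + gap;
            int best = sdiag; unsigned char d = 0;
            if (sup > best) { best = sup; d = 1; }
            if (sleft > best) { best = sleft; d = 2; }
            score_buf[at] = best;
            dir_buf[at] = d;
        }
    }
    int i = n, j = m, matches = 0, columns = 0;
    while (i > 0 || j > 0) {
        unsigned char d = dir_buf[(size_t) i * w + j];
        if (i > 0 && j > 0 && d == 0) {
            if (a[i - 1] == b[j - 1]) ++matches;
            --i; --j;
        } else if (i > 0 && (d == 1 || j == 0)) {
            --i;
        } else {
            --j;
        }
        ++columns;
    }
    NWResult r;
    r.matches = matches;
    r.columns = columns;
    r.score = score_buf[(size_t) n * w + m];
    r.identity = columns > 0 ? (double) matches / columns : 1.0;
    return r;
}

// [[Rcpp::export]]
NumericVector nw_identity_cpp(std::string a, std::string b,
                              int match, int mismatch, int gap) {
    std::vector<int> sb;
    std::vector<unsigned char> db;
    NWResult r = nw_identity(a, b, match, mismatch, gap, sb, db);
    return NumericVector::create(_["identity"] = r.identity,
                                 _["matches"] = (double) r.matches,
                                 _["columns"] = (double) r.columns,
                                 _["score"] = (double) r.score);
}

// ---- Greedy centroid clustering ---------------------------------------------
// Sequences must arrive in decreasing-count (ties: lexicographic) order.  Each
// sequence joins the earliest-founded centroid with identity >= threshold, else
// founds a new cluster.  An exact k-mer count bound prunes centroids that cannot
// reach the threshold: an alignment with D non-match columns destroys at most
// k*D of the query's (L-k+1) k-mer tokens, and D <= (1-t) * columns
// <= (1-t) * (Lq + Lc).

static const int KMER_K = 8;

static bool encode_kmers(const std::string& s, std::vector<int>& codes) {
    const int L = (int) s.size();
    codes.clear();
    if (L < KMER_K) return false;
    int code = 0, valid = 0;
    const int mask = (1 << (2 * KMER_K)) - 1;
    for (int i = 0; i < L; ++i) {
        int b;
        switch (s[i]) {
        case 'A': b = 0; break;
        case 'C': b = 1; break;
        case 'G': b = 2; break;
        case 'T': b = 3; break;
        default: return false;
        }
        code = ((code << 2) | b) & mask;
        if (++valid >= KMER_K) codes.push_back(code);
    }
    return true;
}

// [[Rcpp::export]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, double threshold,
                                 int match, int mismatch, int gap) {
    const R_xlen_t n = seqs.size();
    IntegerVector assignment(n);
    std::vector<std::string> sv(n);
    for (R_xlen_t i = 0; i < n; ++i) sv[i] = as<std::string>(seqs[i]);

    std::vector<int> centroid_seq_idx;             // input index of each centroid
    std::vector<std::vector<int> > kmer_index(1 << (2 * KMER_K));
    std::vector<int> shared;                        // shared-token count per centroid
    std::vector<int> touched;
    int max_cent_len = 0;

    std::vector<int> codes, sb;
    std::vector<unsigned char> db;
    std::vector<int> cand;
    std::vector<int> uniq_codes;
    const double eps = 1e-12;

    for (R_xlen_t i = 0; i < n; ++i) {
        const std::string& q = sv[i];
        const int Lq = (int) q.size();
        int joined = -1;
        const bool kmers_ok = encode_kmers(q, codes);
        int min_shared = 0;
        if (kmers_ok && max_cent_len > 0) {
            int Dmax = (int) std::floor((1.0 - threshold) * (Lq + max_cent_len));
            min_shared = (Lq - KMER_K + 1) - Dmax * KMER_K;
        }
        if (kmers_ok && min_shared >= 1) {
            // exact prefilter
            shared.resize(centroid_seq_idx.size(), 0);
            touched.clear();
            for (int c : codes) {
                const std::vector<int>& lst = kmer_index[c];
                for (int cid : lst) {
                    if (shared[cid] == 0) touched.push_back(cid);
                    ++shared[cid];
                }
            }
            cand.clear();
            for (int cid : touched)
                if (shared[cid] >= min_shared) cand.push_back(cid);
            std::sort(cand.begin(), cand.end());
            for (int cid : cand) {
                NWResult r = nw_identity(q, sv[centroid_seq_idx[cid]],
                                         match, mismatch, gap, sb, db);
                if (r.identity >= threshold - eps) { joined = cid; break; }
            }
            for (int cid : touched) shared[cid] = 0;
        } else {
            // bound vacuous: scan every centroid in founding order
            for (size_t cid = 0; cid < centroid_seq_idx.size(); ++cid) {
                NWResult r = nw_identity(q, sv[centroid_seq_idx[cid]],
                                         match, mismatch, gap, sb, db);
                if (r.identity >= threshold - eps) { joined = (int) cid; break; }
            }
        }
        if (joined < 0) {
            joined = (int) centroid_seq_idx.size();
            centroid_seq_idx.push_back((int) i);
            shared.push_back(0);
            if (Lq > max_cent_len) max_cent_len = Lq;
            if (kmers_ok) {
                uniq_codes = codes;
                std::sort(uniq_codes.begin(), uniq_codes.end());
                uniq_codes.erase(std::unique(uniq_codes.begin(), uniq_codes.end()),
                                 uniq_codes.end());
                for (int c : uniq_codes) kmer_index[c].push_back(joined);
            }
        }
        assignment[i] = joined + 1; // 1-based cluster id in founding order
        if ((i & 0x3FF) == 0) Rcpp::checkUserInterrupt();
    }
    return assignment;
}

// Substitute a random different base at (read idx, position); uses R's RNG so
// results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector substitute_bases_cpp(CharacterVector reads, IntegerVector idx,
                                     IntegerVector pos) {
    const R_xlen_t n = reads.size();
    std::vector<std::string> sv(n);
    for (R_xlen_t i = 0; i < n; ++i) sv[i] = as<std::string>(reads[i]);
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    for (R_xlen_t j = 0; j < idx.size(); ++j) {
        const int i = idx[j] - 1;
        const int p = pos[j] - 1;
        if (i < 0 || i >= (int) n) stop("read index out of range");
        if (p < 0 || p >= (int) sv[i].size()) continue;
        char orig = sv[i][p];
        char alt[3];
        int na = 0;
        for (int b = 0; b < 4; ++b) if (bases[b] != orig) alt[na++] = bases[b];
        int pick = (int) std::floor(unif_rand() * na);
        if (pick >= na) pick = na - 1;
        sv[i][p] = alt[pick];
    }
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = sv[i];
    return out;
}
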