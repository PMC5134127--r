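// Seed-and-extend nucleotide local alignment engine.
//
// Targets are indexed by exact words of `word_size` bases; every query word
// hit nominates a (target, diagonal) pair, and the best-scoring ungapped
// segment on each nominated diagonal is found exactly by a max-subarray scan
// (match +1, mismatch -2). Alignments live on single diagonals because the
// dynamics the engine is built for are substitution-only; significance is
// decided downstream from the Karlin-Altschul E-value of the segment score.

#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    }
    return -1;
}

struct SeqIndex {
    std::vector<std::string> seqs;
    std::vector<std::string> names;
    int word;
    double total_len;
    // word -> (seq index, position)
    std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > table;
};

static void collect_words(const std::string& s, int w,
                          std::vector<std::pair<uint64_t, int> >& out) {
    out.clear();
    const int n = (int)s.size();
    if (n < w) return;
    const uint64_t mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1ULL);
    uint64_t key = 0;
    int run = 0; // valid bases accumulated
    for (int i = 0; i < n; ++i) {
        int c = base_code(s[i]);
        if (c < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++run >= w) out.push_back(std::make_pair(key, i - w + 1));
    }
}

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int word_size) {
    if (word_size < 4 || word_size > 31) stop("word_size must be in [4, 31]");
    SeqIndex* idx = new SeqIndex();
    idx->word = word_size;
    idx->total_len = 0;
    std::vector<std::pair<uint64_t, int> > words;
    for (int i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        idx->total_len += (double)s.size();
        collect_words(s, word_size, words);
        for (size_t k = 0; k < words.size(); ++k)
            idx->table[words[k].first].push_back(std::make_pair(i, words[k].second));
        idx->seqs.push_back(s);
        idx->names.push_back(as<std::string>(names[i]));
    }
    XPtr<SeqIndex> p(idx, true);
    return p;
}

// [[Rcpp::export(name = ".cpp_index_info")]]
List cpp_index_info(SEXP xp) {
    XPtr<SeqIndex> idx(xp);
    return List::create(_["n_seqs"] = (int)idx->seqs.size(),
                        _["total_length"] = idx->total_len,
                        _["word_size"] = idx->word,
                        _["names"] = wrap(idx->names));
}

struct Aln {
    int score, len, matches, qstart, tstart;
    Aln() : score(0), len(0), matches(0), qstart(-1), tstart(-1) {}
};

// Exact best-scoring ungapped segment on one diagonal (Kadane scan).
static Aln diag_best(const std::string& q, const std::string& t, int diag) {
    Aln best;
    const int qlen = (int)q.size(), tlen = (int)t.size();
    const int qs = diag > 0 ? diag : 0;
    const int ts = qs - diag;
    const int L = std::min(qlen - qs, tlen - ts);
    int cur = 0, curmatch = 0, curstart = 0;
    for (int i = 0; i < L; ++i) {
        const bool m = (q[qs + i] == t[ts + i]);
        const int sc = m ? 1 : -2;
        if (cur == 0 && sc < 0) { curstart = i + 1; continue; }
        cur += sc;
        if (m) ++curmatch;
        if (cur > best.score) {
            best.score = cur;
            best.len = i - curstart + 1;
            best.matches = curmatch;
            best.qstart = qs + curstart;
            best.tstart = ts + curstart;
        }
        if (cur <= 0) { cur = 0; curmatch = 0; curstart = i + 1; }
    }
    return best;
}

// Best ungapped alignment per (query, target) contig pair over all seeded
// diagonals. Returns one row per pair with >= 1 shared word.
// [[Rcpp::export(name = ".cpp_query_index")]]
DataFrame cpp_query_index(CharacterVector qseqs, SEXP xp) {
    XPtr<SeqIndex> idx(xp);
    const int w = idx->word;
    std::vector<int> out_q, out_t, out_score, out_len, out_match, out_qs, out_ts;
    std::vector<std::pair<uint64_t, int> > words;
    std::vector<uint64_t> cand;
    for (int qi = 0; qi < qseqs.size(); ++qi) {
        std::string q = as<std::string>(qseqs[qi]);
        const int qlen = (int)q.size();
        collect_words(q, w, words);
        cand.clear();
        for (size_t k = 0; k < words.size(); ++k) {
            std::unordered_map<uint64_t, std::vector<std::pair<int, int> > >::const_iterator
                it = idx->table.find(words[k].first);
            if (it == idx->table.end()) continue;
            const std::vector<std::pair<int, int> >& hits = it->second;
            for (size_t h = 0; h < hits.size(); ++h) {
                // key packs (target, diagonal); diagonal offset keeps it positive
                const uint64_t key = ((uint64_t)hits[h].first << 32) |
                    (uint64_t)(uint32_t)(words[k].second - hits[h].second + qlen);
                cand.push_back(key);
            }
        }
        std::sort(cand.begin(), cand.end());
        cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
        int cur_t = -1;
        Aln best;
        for (size_t k = 0; k <= cand.size(); ++k) {
            int ti = (k < cand.size()) ? (int)(cand[k] >> 32) : -2;
            if (ti != cur_t) {
                if (cur_t >= 0 && best.score > 0) {
                    out_q.push_back(qi + 1);
                    out_t.push_back(cur_t + 1);
                    out_score.push_back(best.score);
                    out_len.push_back(best.len);
                    out_match.push_back(best.matches);
                    out_qs.push_back(best.qstart + 1);
                    out_ts.push_back(best.tstart + 1);
                }
                cur_t = ti;
                best = Aln();
            }
            if (k == cand.size()) break;
            const int diag = (int)(uint32_t)(cand[k] & 0xffffffffULL) - qlen;
            Aln a = diag_best(q, idx->seqs[ti], diag);
            if (a.score > best.score) best = a;
        }
    }
    return DataFrame::create(_["query"] = out_q, _["target"] = out_t,
                             _["score"] = out_score, _["length"] = out_len,
                             _["matches"] = out_match, _["qstart"] = out_qs,
                             _["tstart"] = out_ts);
}
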