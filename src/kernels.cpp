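#include <Rcpp.h>
#include <unordered_map>
#include <set>
using namespace Rcpp;

// Longest common substring of a and b.
// Ties: maximal length, then smallest a offset, then smallest b offset.
// Returns c(len, a_off, b_off), offsets 0-based (a_off/b_off = -1 if len 0).
// [[Rcpp::export]]
IntegerVector cpp_lcs_substring(std::string a, std::string b) {
    const int n = a.size(), m = b.size();
    int best = 0, ba = -1, bb = -1;
    std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            if (a[i - 1] == b[j - 1]) {
                cur[j] = prev[j - 1] + 1;
                if (cur[j] > best) {           // strict: keeps smallest end in a
                    best = cur[j];
                    ba = i - cur[j];
                    bb = j - cur[j];
                }
            } else cur[j] = 0;
        }
        std::swap(prev, cur);
        std::fill(cur.begin(), cur.end(), 0);
    }
    return IntegerVector::create(best, ba, bb);
}

static inline bool can_pair(char x, char y, bool wobble) {
    if ((x == 'A' && y == 'T') || (x == 'T' && y == 'A')) return true;
    if ((x == 'C' && y == 'G') || (x == 'G' && y == 'C')) return true;
    if (wobble && ((x == 'G' && y == 'T') || (x == 'T' && y == 'G'))) return true;
    return false;
}

// Nussinov base-pair maximization with deterministic traceback.
// seq: cDNA-alphabet string (T for U); min_loop: minimum unpaired loop span.
// Traceback prefers pairing the leftmost base i, and among partners the
// smallest j. Returns a 2-column matrix of 0-based pair indices (i < j).
// [[Rcpp::export]]
IntegerMatrix cpp_nussinov(std::string seq, int min_loop, bool wobble) {
    const int n = seq.size();
    if (n == 0) return IntegerMatrix(0, 2);
    // N[i][j] stored in flat vector, i <= j
    std::vector<int> N((size_t)n * n, 0);
    auto idx = [n](int i, int j) { return (size_t)i * n + j; };
    for (int span = min_loop + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            int best = N[idx(i + 1, j)];  // i unpaired
            for (int k = i + min_loop + 1; k <= j; ++k) {
                if (!can_pair(seq[i], seq[k], wobble)) continue;
                int inner = (k - i - 1 > min_loop) ? N[idx(i + 1, k - 1)] : 0;
                int right = (k < j) ? N[idx(k + 1, j)] : 0;
                int cand = 1 + inner + right;
                if (cand > best) best = cand;
            }
            N[idx(i, j)] = best;
        }
    }
    std::vector<std::pair<int, int>> pairs;
    std::vector<std::pair<int, int>> stack;
    stack.push_back({0, n - 1});
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (j - i < min_loop + 1) continue;
        int target = N[idx(i, j)];
        if (target == 0) continue;
        bool paired = false;
        for (int k = i + min_loop + 1; k <= j; ++k) {
            if (!can_pair(seq[i], seq[k], wobble)) continue;
            int inner = (k - i - 1 > min_loop) ? N[idx(i + 1, k - 1)] : 0;
            int right = (k < j) ? N[idx(k + 1, j)] : 0;
            if (1 + inner + right == target) {
                pairs.push_back({i, k});
                if (k - i - 1 > min_loop) stack.push_back({i + 1, k - 1});
                if (k < j) stack.push_back({k + 1, j});
                paired = true;
                break;  // smallest j partner
            }
        }
        if (!paired) stack.push_back({i + 1, j});
    }
    std::sort(pairs.begin(), pairs.end());
    IntegerMatrix out(pairs.size(), 2);
    for (size_t r = 0; r < pairs.size(); ++r) {
        out(r, 0) = pairs[r].first;
        out(r, 1) = pairs[r].second;
    }
    return out;
}

// All maximal exact matches >= k between query and target, found by k-mer
// seeding and greedy extension. Returns 3 columns: qstart, tstart, len
// (0-based starts). Deduplicated per diagonal.
// [[Rcpp::export]]
IntegerMatrix cpp_exact_matches(std::string query, std::string target, int k) {
    const int nq = query.size(), nt = target.size();
    IntegerMatrix empty(0, 3);
    if (nq < k || nt < k) return empty;
    std::unordered_map<std::string, std::vector<int>> index;
    for (int t = 0; t + k <= nt; ++t) index[target.substr(t, k)].push_back(t);
    std::set<std::pair<int, int>> seen;  // (diagonal, qstart of maximal run)
    std::vector<std::array<int, 3>> hits;
    for (int q = 0; q + k <= nq; ++q) {
        auto it = index.find(query.substr(q, k));
        if (it == index.end()) continue;
        for (int t : it->second) {
            int q0 = q, t0 = t;
            while (q0 > 0 && t0 > 0 && query[q0 - 1] == target[t0 - 1]) { --q0; --t0; }
            if (seen.count({t - q, q0})) continue;
            seen.insert({t - q, q0});
            int q1 = q + k, t1 = t + k;
            while (q1 < nq && t1 < nt && query[q1] == target[t1]) { ++q1; ++t1; }
            hits.push_back({q0, t0, q1 - q0});
        }
    }
    IntegerMatrix out(hits.size(), 3);
    for (size_t r = 0; r < hits.size(); ++r) {
        out(r, 0) = hits[r][0];
        out(r, 1) = hits[r][1];
        out(r, 2) = hits[r][2];
    }
    return out;
}
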