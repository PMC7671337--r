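#include <Rcpp.h>
#include <vector>
#include <string>

// Semi-global alignment of a read against a longer context: the whole read
// must be aligned (global in the pattern), but it may start and end
// anywhere in the context (local in the subject). Unit costs: mismatch 1,
// gap base 1. Returns the minimum edit count together with the 1-based
// context span [start, end] covered by the best alignment (ties resolved
// toward the leftmost end and, for the start, the leftmost traceback via
// deterministic preference: diagonal, then up, then left).

// [[Rcpp::export]]
Rcpp::IntegerVector semi_global_edits(std::string read, std::string context) {
    const int m = read.size();
    const int n = context.size();
    if (m == 0 || n == 0)
        return Rcpp::IntegerVector::create(m > 0 ? m : 0, 0, 0);

    // dp[j]: edits of best alignment of read[0..i) ending at context pos j
    // st[j]: context start (0-based, exclusive-left) of that alignment
    std::vector<int> dp(n + 1), dp_prev(n + 1);
    std::vector<int> st(n + 1), st_prev(n + 1);
    for (int j = 0; j <= n; ++j) { dp_prev[j] = 0; st_prev[j] = j; }

    for (int i = 1; i <= m; ++i) {
        dp[0] = i;            // read prefix unmatched -> gaps
        st[0] = 0;
        char rc = std::tolower(read[i - 1]);
        for (int j = 1; j <= n; ++j) {
            char cc = std::tolower(context[j - 1]);
            int sub = dp_prev[j - 1] + (rc == cc ? 0 : 1);
            int del = dp_prev[j] + 1;      // gap in context (read char unmatched)
            int ins = dp[j - 1] + 1;       // gap in read (context char consumed)
            int best = sub, src = 0;
            if (del < best) { best = del; src = 1; }
            if (ins < best) { best = ins; src = 2; }
            dp[j] = best;
            st[j] = (src == 0) ? st_prev[j - 1] : (src == 1 ? st_prev[j] : st[j - 1]);
        }
        std::swap(dp, dp_prev);
        std::swap(st, st_prev);
    }

    int best = dp_prev[0], bj = 0;
    for (int j = 1; j <= n; ++j)
        if (dp_prev[j] < best) { best = dp_prev[j]; bj = j; }
    // span in 1-based coordinates; empty span if read aligned off the edge
    int start = st_prev[bj] + 1;
    return Rcpp::IntegerVector::create(best, start, bj);
}
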