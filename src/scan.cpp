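#include <Rcpp.h>
using namespace Rcpp;

// Ungapped scan of many reads against a small set of gene regions.
// For each (read, region) pair, returns the minimum mismatch count over all
// valid start offsets (capped at max_mismatch), the smallest offset achieving
// it (1-based), and how many offsets achieve it.  Placements are abandoned as
// soon as their mismatch count exceeds min(max_mismatch, current best), which
// cannot affect the minimum or the tie count.
// [[Rcpp::export]]
List scan_regions_cpp(CharacterVector reads, CharacterVector regions,
                      int max_mismatch) {
    const int nr = reads.size(), ng = regions.size();
    std::vector<std::string> reg(ng);
    for (int g = 0; g < ng; ++g) reg[g] = as<std::string>(regions[g]);

    IntegerMatrix best_mm(nr, ng), best_off(nr, ng), best_cnt(nr, ng);
    std::fill(best_mm.begin(),  best_mm.end(),  NA_INTEGER);
    std::fill(best_off.begin(), best_off.end(), NA_INTEGER);
    std::fill(best_cnt.begin(), best_cnt.end(), 0);

    for (int r = 0; r < nr; ++r) {
        const char *rd = CHAR(STRING_ELT(reads, r));
        const int R = (int) LENGTH(STRING_ELT(reads, r));
        for (int g = 0; g < ng; ++g) {
            const std::string &sq = reg[g];
            const int L = (int) sq.size();
            if (R > L) continue;  // region shorter than read: skipped
            int best = max_mismatch + 1, cnt = 0, off = NA_INTEGER;
            const char *sqc = sq.data();
            for (int o = 0; o <= L - R; ++o) {
                const int lim = std::min(max_mismatch, best);
                const char *b = sqc + o;
                int mm = 0, k = 0;
                // block-wise compare: branch once per 16 bases so the
                // inner loop vectorises; abandoning at mm > lim cannot
                // change the minimum or the tie count
                while (k < R) {
                    const int kend = (k + 16 <= R) ? k + 16 : R;
                    for (; k < kend; ++k) mm += (rd[k] != b[k]);
                    if (mm > lim) break;
                }
                if (mm > lim) continue;
                if (mm < best) { best = mm; cnt = 1; off = o + 1; }
                else if (mm == best) ++cnt;
            }
            if (best <= max_mismatch) {
                best_mm(r, g) = best;
                best_off(r, g) = off;
                best_cnt(r, g) = cnt;
            }
        }
    }
    return List::create(_["mismatches"] = best_mm, _["offset"] = best_off,
                        _["n_best"] = best_cnt);
}

// All placements of one read in one region with mismatches <= max_mismatch.
// [[Rcpp::export]]
List enumerate_placements_cpp(std::string read, std::string region,
                              int max_mismatch) {
    const int R = (int) read.size(), L = (int) region.size();
    std::vector<int> offs, mms;
    for (int o = 0; o + R <= L; ++o) {
        int mm = 0;
        for (int k = 0; k < R; ++k) {
            mm += (read[k] != region[o + k]);
            if (mm > max_mismatch) break;
        }
        if (mm <= max_mismatch) { offs.push_back(o + 1); mms.push_back(mm); }
    }
    return List::create(_["offset"] = wrap(offs), _["mismatches"] = wrap(mms));
}

// Global (Needleman-Wunsch style) alignment minimising cost with
// match 0, mismatch 1, gap 1.  Traceback prefers diagonal, then up
// (gap in b), then left (gap in a).  Gaps are written as '-'.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b) {
    const int n = (int) a.size(), m = (int) b.size();
    IntegerMatrix M(n + 1, m + 1);
    for (int i = 0; i <= n; ++i) M(i, 0) = i;
    for (int j = 0; j <= m; ++j) M(0, j) = j;
    for (int i = 1; i <= n; ++i)
        for (int j = 1; j <= m; ++j) {
            int d = M(i - 1, j - 1) + (a[i - 1] != b[j - 1]);
            int u = M(i - 1, j) + 1;
            int l = M(i, j - 1) + 1;
            M(i, j) = std::min(d, std::min(u, l));
        }
    std::string ga, gb;
    int i = n, j = m;
    while (i > 0 || j > 0) {
        if (i > 0 && j > 0 &&
            M(i, j) == M(i - 1, j - 1) + (a[i - 1] != b[j - 1])) {
            ga.push_back(a[i - 1]); gb.push_back(b[j - 1]); --i; --j;
        } else if (i > 0 && M(i, j) == M(i - 1, j) + 1) {
            ga.push_back(a[i - 1]); gb.push_back('-'); --i;
        } else {
            ga.push_back('-'); gb.push_back(b[j - 1]); --j;
        }
    }
    std::reverse(ga.begin(), ga.end());
    std::reverse(gb.begin(), gb.end());
    return List::create(_["cost"] = M(n, m), _["aligned_a"] = ga,
                        _["aligned_b"] = gb);
}
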