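#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Core character-scanning loops. Every character-pair equality test that
// belongs to the search itself goes through one counted comparison, so the
// returned `char_comparisons` is an exact, hardware-independent cost proxy.
// Inputs arrive validated and upper-cased from the R layer.

// Failure table: values[i] = length of the longest proper prefix of
// pat[0..i] that is also a suffix of pat[0..i]. Single left-to-right pass;
// each loop iteration performs exactly one comparison and either advances i
// or strictly decreases the candidate length l, so comparisons <= 2*l_p.
// [[Rcpp::export]]
List sbarc_cpp(const std::string& pat) {
    const int lp = (int) pat.size();
    IntegerVector values(lp);
    long long comparisons = 0;
    int l = 0, i = 1;
    values[0] = 0;
    while (i < lp) {
        ++comparisons;
        if (pat[i] == pat[l]) {
            ++l;
            values[i] = l;
            ++i;
        } else if (l > 0) {
            l = values[l - 1];
        } else {
            values[i] = 0;
            ++i;
        }
    }
    return List::create(_["values"] = values,
                        _["comparisons"] = (double) comparisons);
}

// KMP-style exact scan. The sequence index i never moves backward; on a
// mismatch only the pattern index falls back through the failure table.
// After a full match the pattern index continues from sv[lp-1] so
// overlapping occurrences are reported. Window shifts are counted each time
// the implied alignment start (i - j) increases.
// [[Rcpp::export]]
List epm_cpp(const std::string& seq, const std::string& pat,
             const IntegerVector& sv) {
    const long long ls = (long long) seq.size();
    const int lp = (int) pat.size();
    std::vector<int> starts;
    long long comparisons = 0, shifts = 0;
    bool monotone = true;
    long long i = 0, prev_i = 0, start = 0;
    int j = 0;
    while (i < ls) {
        if (i < prev_i) monotone = false;
        prev_i = i;
        ++comparisons;
        if (seq[i] == pat[j]) {
            ++i;
            ++j;
            if (j == lp) {
                starts.push_back((int) (i - lp));
                j = sv[lp - 1];
                if (i - j > start) { ++shifts; start = i - j; }
            }
        } else if (j > 0) {
            j = sv[j - 1];
            if (i - j > start) { ++shifts; start = i - j; }
        } else {
            ++i;
            ++shifts;
            start = i;
        }
    }
    return List::create(_["starts"] = wrap(starts),
                        _["comparisons"] = (double) comparisons,
                        _["shifts"] = (double) shifts,
                        _["monotone"] = monotone);
}

// Brute-force exact scan: every window, abort the window at its first
// mismatch. Window shifts = number of windows examined (l_s - l_p + 1 for a
// full scan).
// [[Rcpp::export]]
List naive_cpp(const std::string& seq, const std::string& pat) {
    const long long ls = (long long) seq.size();
    const long long lp = (long long) pat.size();
    std::vector<int> starts;
    long long comparisons = 0, windows = 0;
    for (long long s = 0; s + lp <= ls; ++s) {
        ++windows;
        long long j = 0;
        while (j < lp) {
            ++comparisons;
            if (seq[s + j] != pat[j]) break;
            ++j;
        }
        if (j == lp) starts.push_back((int) s);
    }
    return List::create(_["starts"] = wrap(starts),
                        _["comparisons"] = (double) comparisons,
                        _["shifts"] = (double) windows);
}

// Sliding-window hamming search: report every window within the mismatch
// budget, with the offsets where it differs from the pattern. By default
// every window is scanned in full (the O(l_s * l_p) baseline); with
// early_abandon the window is dropped as soon as the budget is exceeded —
// the hit set is identical either way.
// [[Rcpp::export]]
List hamming_window_cpp(const std::string& seq, const std::string& pat,
                        const int eta, const bool early_abandon) {
    const long long ls = (long long) seq.size();
    const long long lp = (long long) pat.size();
    std::vector<int> starts, counts;
    List offsets_out;
    long long comparisons = 0, windows = 0;
    std::vector<int> offs;
    for (long long s = 0; s + lp <= ls; ++s) {
        ++windows;
        offs.clear();
        int err = 0;
        for (long long j = 0; j < lp; ++j) {
            ++comparisons;
            if (seq[s + j] != pat[j]) {
                ++err;
                if (err <= eta) offs.push_back((int) j);
                if (early_abandon && err > eta) break;
            }
        }
        if (err <= eta) {
            starts.push_back((int) s);
            counts.push_back(err);
            offsets_out.push_back(wrap(offs));
        }
    }
    return List::create(_["starts"] = wrap(starts),
                        _["counts"] = wrap(counts),
                        _["offsets"] = offsets_out,
                        _["comparisons"] = (double) comparisons,
                        _["shifts"] = (double) windows);
}

// Mismatch-tolerant KMP-style scan. Matches run as in the exact scan; a
// mismatch with spare budget is recorded (coordinates of the FIRST mismatch
// of the current alignment) and consumed, and the scan continues rightward.
// The alignment is abandoned when the budget would be exceeded, or after a
// hit containing at least one mismatch is reported; the restart returns the
// sequence index to the first-mismatch position i_f and resumes the pattern
// at sv[j_f - 1] (j_f = 0: advance one, start fresh) — sound because all
// characters before the first mismatch matched exactly. Exact hits continue
// KMP-style from sv[lp - 1] without touching the sequence index. Reported
// windows are re-checked by direct comparison (not counted as search cost),
// deduplicated and sorted.
// [[Rcpp::export]]
List opsi_cpp(const std::string& seq, const std::string& pat,
              const IntegerVector& sv, const int eta) {
    const long long ls = (long long) seq.size();
    const int lp = (int) pat.size();
    std::vector<int> starts;
    long long comparisons = 0, shifts = 0;
    long long i = 0, start = 0;
    int j = 0, err = 0;
    long long first_i = -1;
    int first_j = -1;

    auto restart = [&]() {
        if (first_j > 0) {
            i = first_i;
            j = sv[first_j - 1];
        } else {
            i = first_i + 1;
            j = 0;
        }
        err = 0;
        first_i = -1;
        first_j = -1;
        if (i - j > start) { ++shifts; start = i - j; }
    };

    while (i < ls && i - j + lp <= ls) {
        ++comparisons;
        if (seq[i] == pat[j]) {
            ++i;
            ++j;
        } else if (err < eta) {
            if (first_j < 0) { first_i = i; first_j = j; }
            ++err;
            ++i;
            ++j;
        } else {
            if (first_j < 0) { first_i = i; first_j = j; }
            restart();
            continue;
        }
        if (j == lp) {
            starts.push_back((int) (i - lp));
            if (err == 0) {
                j = sv[lp - 1];
                if (i - j > start) { ++shifts; start = i - j; }
            } else {
                restart();
            }
        }
    }

    std::sort(starts.begin(), starts.end());
    starts.erase(std::unique(starts.begin(), starts.end()), starts.end());

    // report-time verification: recompute each window's mismatch offsets
    std::vector<int> ok_starts, counts;
    List offsets_out;
    for (size_t k = 0; k < starts.size(); ++k) {
        const long long s = starts[k];
        std::vector<int> offs;
        for (int j2 = 0; j2 < lp; ++j2)
            if (seq[s + j2] != pat[j2]) offs.push_back(j2);
        if ((int) offs.size() <= eta) {
            ok_starts.push_back((int) s);
            counts.push_back((int) offs.size());
            offsets_out.push_back(wrap(offs));
        }
    }
    return List::create(_["starts"] = wrap(ok_starts),
                        _["counts"] = wrap(counts),
                        _["offsets"] = offsets_out,
                        _["comparisons"] = (double) comparisons,
                        _["shifts"] = (double) shifts);
}

// Pattern-automaton scan: one transition per sequence character. `codes` are
// 1-based alphabet indices (0 = symbol outside the automaton's alphabet,
// which forces state 0); `trans` is a (lp + 1) x sigma matrix of next states.
// [[Rcpp::export]]
IntegerVector dfa_search_cpp(const IntegerVector& codes,
                             const IntegerMatrix& trans, const int lp) {
    const long long n = codes.size();
    std::vector<int> starts;
    int state = 0;
    for (long long i = 0; i < n; ++i) {
        const int c = codes[i];
        state = (c == 0) ? 0 : trans(state, c - 1);
        if (state == lp) starts.push_back((int) (i - lp + 1));
    }
    return wrap(starts);
}
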