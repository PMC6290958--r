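#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Banded global alignment of a merged amplicon read against the reference
// with affine gaps (Gotoh). Scores: match +1, mismatch -2, a gap of
// length L costs gap_open + L * gap_extend (defaults -6 and -1). The band
// covers diagonals [min(0, n-m) - band, max(0, n-m) + band], so length
// differences (true insertions, including the 20-nt control) are always
// inside the band. Tie-breaking is deterministic: the state preference
// M > X (gap in read) > Y (gap in reference) is applied both when taking
// maxima and in the traceback; insertion positions are subsequently
// left-normalized in R, so co-optimal gap placements collapse to one
// canonical representation.
//
// Returns flat parallel vectors: per-read score / mismatch count /
// insertion-run index bounds, and per-insertion (read index, reference
// gap position, inserted bases).

static const int NEG = INT_MIN / 4;

struct AlnResult {
    int score, mism;
    std::vector<int> ins_pos;
    std::vector<std::string> ins_seq;
    bool ok;
};

static AlnResult align_one(const std::string &x /* ref */,
                           const std::string &y /* read */,
                           int band, int match, int mismatch,
                           int gap_open, int gap_ext) {
    const int m = (int)x.size(), n = (int)y.size();
    AlnResult res; res.ok = false; res.score = NEG; res.mism = 0;

    const int dlo = std::min(0, n - m) - band;
    const int dhi = std::max(0, n - m) + band;
    const int W = dhi - dlo + 1;
    const size_t sz = (size_t)(m + 1) * W;
    std::vector<int> M(sz, NEG), X(sz, NEG), Y(sz, NEG);
    std::vector<unsigned char> tM(sz, 0), tX(sz, 0), tY(sz, 0);
    // tM: previous state of the diagonal step (0=M,1=X,2=Y)
    // tX/tY: 0 = opened from M, 1 = extension

    auto at = [&](int i, int j) { return (size_t)i * W + (j - i - dlo); };
    auto inband = [&](int i, int j) {
        return j >= 0 && j <= n && (j - i) >= dlo && (j - i) <= dhi;
    };

    M[at(0, 0)] = 0;
    for (int j = 1; j <= n && inband(0, j); ++j) {
        Y[at(0, j)] = gap_open + gap_ext * j;
        tY[at(0, j)] = (j == 1) ? 0 : 1;
    }
    for (int i = 1; i <= m; ++i) {
        if (inband(i, 0)) {
            X[at(i, 0)] = gap_open + gap_ext * i;
            tX[at(i, 0)] = (i == 1) ? 0 : 1;
        }
        const int jlo = std::max(1, i + dlo), jhi = std::min(n, i + dhi);
        for (int j = jlo; j <= jhi; ++j) {
            const size_t c = at(i, j);
            // diagonal (i-1, j-1) shares the same banded column
            {
                const size_t p = at(i - 1, j - 1);
                int best = M[p]; unsigned char tb = 0;
                if (X[p] > best) { best = X[p]; tb = 1; }
                if (Y[p] > best) { best = Y[p]; tb = 2; }
                if (best > NEG) {
                    const int s = (x[i - 1] == y[j - 1]) ? match : mismatch;
                    M[c] = best + s; tM[c] = tb;
                }
            }
            // X: consume ref base i (deletion from the read) from (i-1, j)
            if (inband(i - 1, j)) {
                const size_t p = at(i - 1, j);
                const int fromM = (M[p] > NEG) ? M[p] + gap_open + gap_ext : NEG;
                const int ext   = (X[p] > NEG) ? X[p] + gap_ext : NEG;
                if (fromM >= ext) { if (fromM > NEG) { X[c] = fromM; tX[c] = 0; } }
                else              { X[c] = ext;  tX[c] = 1; }
            }
            // Y: consume read base j (insertion into the reference) from (i, j-1)
            if (inband(i, j - 1)) {
                const size_t p = at(i, j - 1);
                const int fromM = (M[p] > NEG) ? M[p] + gap_open + gap_ext : NEG;
                const int ext   = (Y[p] > NEG) ? Y[p] + gap_ext : NEG;
                if (fromM >= ext) { if (fromM > NEG) { Y[c] = fromM; tY[c] = 0; } }
                else              { Y[c] = ext;  tY[c] = 1; }
            }
        }
    }

    if (!inband(m, n)) return res;
    const size_t e = at(m, n);
    int state = 0, best = M[e];
    if (X[e] > best) { best = X[e]; state = 1; }
    if (Y[e] > best) { best = Y[e]; state = 2; }
    if (best <= NEG) return res;
    res.score = best; res.ok = true;

    // traceback
    int i = m, j = n;
    std::string cur_ins;
    while (i > 0 || j > 0) {
        const size_t c = at(i, j);
        if (state == 2) {               // insertion: consume y[j-1]
            cur_ins.push_back(y[j - 1]);
            const int opened = (tY[c] == 0);
            --j;
            if (opened) {
                std::string ins(cur_ins.rbegin(), cur_ins.rend());
                res.ins_pos.push_back(i);
                res.ins_seq.push_back(ins);
                cur_ins.clear();
                state = 0;
            }
        } else if (state == 1) {        // deletion: consume x[i-1]
            const int opened = (tX[c] == 0);
            --i;
            if (opened) state = 0;
        } else {                        // M: diagonal
            if (x[i - 1] != y[j - 1]) ++res.mism;
            state = tM[c];
            --i; --j;
        }
    }
    return res;
}

// [[Rcpp::export]]
List align_reads_cpp(CharacterVector reads, std::string ref, int band = 32,
                     int match = 1, int mismatch = -2,
                     int gap_open = -6, int gap_ext = -1,
                     bool hamming_shortcut = true) {
    const int n = reads.size();
    IntegerVector score(n), mism(n);
    LogicalVector aligned(n);
    std::vector<int> ins_read, ins_pos;
    std::vector<std::string> ins_seq;
    // The ungapped shortcut is only provably optimal for the default
    // scoring scheme (see proof above align_one's caller below).
    const bool default_scores =
        (match == 1 && mismatch == -2 && gap_open == -6 && gap_ext == -1);
    for (int r = 0; r < n; ++r) {
        std::string y(CHAR(STRING_ELT(reads, r)));
        // Equal-length reads with at most 4 mismatches are provably best
        // aligned without gaps: a gapped path over equal-length strings
        // needs >= 1 inserted and >= 1 deleted base, so it scores at most
        // (m - 1) diagonal matches minus two gap runs = m - 15, while the
        // ungapped score m - 3*mm >= m - 12 whenever mm <= 4.
        if (hamming_shortcut && default_scores && y.size() == ref.size()) {
            int mm = 0;
            for (size_t k = 0; k < y.size() && mm <= 4; ++k)
                if (y[k] != ref[k]) ++mm;
            if (mm <= 4) {
                aligned[r] = true;
                score[r] = (int)ref.size() - 3 * mm;
                mism[r] = mm;
                continue;
            }
        }
        AlnResult a = align_one(ref, y, band, match, mismatch, gap_open, gap_ext);
        aligned[r] = a.ok;
        score[r] = a.ok ? a.score : NA_INTEGER;
        mism[r] = a.ok ? a.mism : NA_INTEGER;
        if (a.ok) {
            for (size_t k = 0; k < a.ins_pos.size(); ++k) {
                ins_read.push_back(r + 1);
                ins_pos.push_back(a.ins_pos[k]);
                ins_seq.push_back(a.ins_seq[k]);
            }
        }
    }
    return List::create(
        _["score"] = score, _["n_mismatch"] = mism, _["aligned"] = aligned,
        _["ins_read"] = wrap(ins_read), _["ins_pos"] = wrap(ins_pos),
        _["ins_seq"] = wrap(ins_seq));
}
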