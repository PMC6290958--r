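#include <Rcpp.h>
#include <string>
using namespace Rcpp;

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
    }
}

// Self-assemble read pairs into full-length amplicon consensus sequences.
//
// For each pair, read 2 is reverse-complemented and every overlap length
// o in [min_overlap, min(len1, len2)] is scored as matches - mismatches;
// the best-scoring overlap wins, ties broken toward the longer overlap
// (lengths are scanned in decreasing order, so only a strictly better
// score replaces the incumbent). Branch-and-bound: an overlap is
// abandoned as soon as it can no longer strictly beat the incumbent
// (score is bounded by its length), which keeps the scan near-linear on
// real amplicon pairs.
//
// Consensus within the overlap: agreeing bases keep the base with quality
// min(q1 + q2, 41); disagreeing bases take the higher-quality base with
// quality (higher - lower); an exact quality tie deterministically takes
// the read-1 base. A pair is rejected (merged = false) when no overlap
// reaches min_overlap or the best overlap's mismatch fraction exceeds
// max_mismatch_frac.
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     int min_overlap, double max_mismatch_frac) {
    const int n = seq1.size();
    CharacterVector mseq(n), mqual(n);
    IntegerVector olen(n), nmis(n);
    LogicalVector ok(n);

    std::string s2rc, q2r, cons, consq;
    for (int i = 0; i < n; ++i) {
        const char *s1 = CHAR(STRING_ELT(seq1, i));
        const char *q1 = CHAR(STRING_ELT(qual1, i));
        const char *s2 = CHAR(STRING_ELT(seq2, i));
        const char *q2 = CHAR(STRING_ELT(qual2, i));
        const int n1 = LENGTH(STRING_ELT(seq1, i));
        const int n2 = LENGTH(STRING_ELT(seq2, i));

        s2rc.resize(n2); q2r.resize(n2);
        for (int k = 0; k < n2; ++k) {
            s2rc[k] = comp_base(s2[n2 - 1 - k]);
            q2r[k]  = q2[n2 - 1 - k];
        }

        int best_o = -1, best_score = INT_MIN;
        const int omax = n1 < n2 ? n1 : n2;
        for (int o = omax; o >= min_overlap; --o) {
            if (best_score >= o) break;   // no longer overlap can beat it
            const char *a = s1 + (n1 - o);
            int score = 0;
            bool abandoned = false;
            for (int k = 0; k < o; ++k) {
                score += (a[k] == s2rc[k]) ? 1 : -1;
                if (score + (o - 1 - k) <= best_score) { abandoned = true; break; }
            }
            if (!abandoned && score > best_score) { best_score = score; best_o = o; }
        }

        int mm = 0;
        if (best_o > 0) {
            const char *a = s1 + (n1 - best_o);
            for (int k = 0; k < best_o; ++k) if (a[k] != s2rc[k]) ++mm;
        }
        if (best_o < min_overlap ||
            (double)mm / (double)best_o > max_mismatch_frac) {
            mseq[i] = NA_STRING; mqual[i] = NA_STRING;
            olen[i] = NA_INTEGER; nmis[i] = NA_INTEGER; ok[i] = false;
            continue;
        }

        const int mlen = n1 + n2 - best_o;
        cons.resize(mlen); consq.resize(mlen);
        const int pre = n1 - best_o;
        for (int k = 0; k < pre; ++k) { cons[k] = s1[k]; consq[k] = q1[k]; }
        for (int k = 0; k < best_o; ++k) {
            const char c1 = s1[pre + k], c2 = s2rc[k];
            const int p1 = q1[pre + k] - 33, p2 = q2r[k] - 33;
            char base; int q;
            if (c1 == c2) {
                base = c1;
                q = p1 + p2; if (q > 41) q = 41;
            } else if (p1 >= p2) {
                base = c1; q = p1 - p2;
            } else {
                base = c2; q = p2 - p1;
            }
            cons[pre + k] = base;
            consq[pre + k] = (char)(q + 33);
        }
        for (int k = best_o; k < n2; ++k) {
            cons[pre + k]  = s2rc[k];
            consq[pre + k] = q2r[k];
        }
        mseq[i] = cons; mqual[i] = consq;
        olen[i] = best_o; nmis[i] = mm; ok[i] = true;
    }
    return List::create(_["sequence"] = mseq, _["quality"] = mqual,
                        _["overlap_len"] = olen, _["n_mismatch"] = nmis,
                        _["merged"] = ok);
}
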