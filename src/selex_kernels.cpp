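#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <set>
#include <algorithm>
#include <cstring>

using namespace Rcpp;

// Gapped patterns are strings over {A,C,G,T,n}; canonical form has defined
// bases at both ends and (in the counting/neighbour space) a single internal
// run of n.  Byte order conveniently ranks A < C < G < T < n, so the
// strand-canonical form is std::min(s, revcomp(s)) under plain string compare.

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'n';
    }
}

static std::string rc_str(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (char &c : r) c = comp_base(c);
    return r;
}

static std::string trim_n(const std::string &s) {
    size_t b = s.find_first_not_of('n');
    if (b == std::string::npos) return std::string();
    size_t e = s.find_last_not_of('n');
    return s.substr(b, e - b + 1);
}

static inline std::string strand_canon(const std::string &s) {
    std::string r = rc_str(s);
    return (r < s) ? r : s;
}

static int n_defined(const std::string &s) {
    int k = 0;
    for (char c : s) if (c != 'n') ++k;
    return k;
}

// number of internal n-runs and the longest run length
static void gap_runs(const std::string &s, int &runs, int &maxrun) {
    runs = 0; maxrun = 0;
    int cur = 0;
    for (char c : s) {
        if (c == 'n') { ++cur; }
        else { if (cur > 0) { ++runs; if (cur > maxrun) maxrun = cur; } cur = 0; }
    }
    // trailing run impossible in canonical form (caller trims)
}

// maximum number of equal defined bases over all rigid offsets (no new gaps)
static int best_alignment(const std::string &a, const std::string &b) {
    int la = (int)a.size(), lb = (int)b.size();
    int best = 0;
    for (int off = -(lb - 1); off <= la - 1; ++off) {
        int m = 0;
        int i0 = std::max(0, off), i1 = std::min(la, lb + off);
        for (int i = i0; i < i1; ++i) {
            char ca = a[i], cb = b[i - off];
            if (ca != 'n' && ca == cb) ++m;
        }
        if (m > best) best = m;
    }
    return best;
}

static int huddinge_one(const std::string &a, const std::string &b) {
    int d = std::max(n_defined(a), n_defined(b));
    return d - best_alignment(a, b);
}

// [[Rcpp::export]]
int cpp_huddinge(std::string p1, std::string p2, bool merge_strands) {
    int d = huddinge_one(p1, p2);
    if (merge_strands) {
        int d2 = huddinge_one(p1, rc_str(p2));
        if (d2 < d) d = d2;
    }
    return d;
}

// [[Rcpp::export]]
IntegerVector cpp_alignment_profile(std::string p1, std::string p2) {
    // matches at every rigid offset of p2 against p1; names are offsets
    int la = (int)p1.size(), lb = (int)p2.size();
    std::vector<int> offs, vals;
    for (int off = -(lb - 1); off <= la - 1; ++off) {
        int m = 0;
        int i0 = std::max(0, off), i1 = std::min(la, lb + off);
        for (int i = i0; i < i1; ++i) {
            char ca = p1[i], cb = p2[i - off];
            if (ca != 'n' && ca == cb) ++m;
        }
        offs.push_back(off); vals.push_back(m);
    }
    IntegerVector out(vals.begin(), vals.end());
    CharacterVector nm(offs.size());
    for (size_t i = 0; i < offs.size(); ++i) nm[i] = std::to_string(offs[i]);
    out.attr("names") = nm;
    return out;
}

// validity in the single-gap pattern space
static bool valid_pattern(const std::string &s, int max_def, int max_gap) {
    if (s.empty()) return false;
    if (s.front() == 'n' || s.back() == 'n') return false;
    int nd = n_defined(s);
    if (nd < 1 || nd > max_def) return false;
    int runs, mx;
    gap_runs(s, runs, mx);
    if (runs > 1 || mx > max_gap) return false;
    return true;
}

// [[Rcpp::export]]
CharacterVector cpp_neighbors(std::string p, int max_def, int max_gap,
                              bool merge_strands) {
    // exact Huddinge distance-1 ball boundary within bounds, by construction:
    // drop zero/one defined base from p, add zero/one defined base at any
    // position reachable without creating a second gap; every candidate built
    // this way shares >= n-1 rigidly aligned bases with p, so its distance is
    // 1 unless it equals p (strand-adjusted).
    p = trim_n(p);
    std::vector<std::pair<int,char> > def;
    for (int i = 0; i < (int)p.size(); ++i)
        if (p[i] != 'n') def.push_back(std::make_pair(i, p[i]));
    int n = (int)def.size();
    std::string canon_p = merge_strands ? strand_canon(p) : p;
    const char bases[4] = {'A','C','G','T'};
    std::set<std::string> out;

    for (int drop = -1; drop < n; ++drop) {
        std::vector<std::pair<int,char> > skel;
        for (int i = 0; i < n; ++i) if (i != drop) skel.push_back(def[i]);
        int lo, hi;
        if (skel.empty()) { lo = 0; hi = 0; }
        else { lo = skel.front().first - (max_gap + 1);
               hi = skel.back().first + (max_gap + 1); }
        // add = none (only meaningful when one base was dropped)
        for (int addpos = lo - 1; addpos <= hi; ++addpos) {
            bool addnone = (addpos == lo - 1);
            if (addnone && (drop < 0 || skel.empty())) continue;
            bool occupied = false;
            if (!addnone)
                for (size_t k = 0; k < skel.size(); ++k)
                    if (skel[k].first == addpos) { occupied = true; break; }
            if (occupied) continue;
            int nb = addnone ? 1 : 4;
            for (int bi = 0; bi < nb; ++bi) {
                std::vector<std::pair<int,char> > q(skel);
                if (!addnone) {
                    q.push_back(std::make_pair(addpos, bases[bi]));
                    std::sort(q.begin(), q.end());
                }
                if (q.empty()) continue;
                int qlo = q.front().first, qhi = q.back().first;
                std::string s(qhi - qlo + 1, 'n');
                for (size_t k = 0; k < q.size(); ++k)
                    s[q[k].first - qlo] = q[k].second;
                if (!valid_pattern(s, max_def, max_gap)) continue;
                std::string cs = merge_strands ? strand_canon(s) : s;
                if (cs == canon_p) continue;
                out.insert(cs);
            }
        }
    }
    return CharacterVector(out.begin(), out.end());
}

// [[Rcpp::export]]
List cpp_count_patterns(CharacterVector reads, int min_def, int max_def,
                        int max_gap, bool per_read, bool merge_strands) {
    std::unordered_map<std::string, double> tab;
    tab.reserve(1 << 18);
    std::unordered_set<std::string> seen;
    std::string pat;
    for (int r = 0; r < reads.size(); ++r) {
        const std::string read = as<std::string>(reads[r]);
        int L = (int)read.size();
        if (per_read) { seen.clear(); }
        for (int d = min_def; d <= max_def; ++d) {
            for (int g = 0; g <= max_gap; ++g) {
                int span = d + g;
                if (span > L) continue;
                // gap run sits after defined base k (1..d-1); g==0 -> one form
                int k0 = (g == 0) ? 0 : 1;
                int k1 = (g == 0) ? 0 : d - 1;
                for (int k = k0; k <= k1; ++k) {
                    for (int st = 0; st + span <= L; ++st) {
                        pat.assign(read, st, span);
                        bool ok = true;
                        for (int i = 0; i < span; ++i) {
                            char c = pat[i];
                            if (c != 'A' && c != 'C' && c != 'G' && c != 'T') {
                                ok = false; break;
                            }
                        }
                        if (!ok) continue;
                        if (g > 0)
                            for (int i = 0; i < g; ++i) pat[k + i] = 'n';
                        std::string cs = merge_strands ? strand_canon(pat) : pat;
                        if (per_read) {
                            if (seen.insert(cs).second) tab[cs] += 1.0;
                        } else {
                            tab[cs] += 1.0;
                        }
                    }
                }
            }
        }
    }
    std::vector<std::string> keys;
    keys.reserve(tab.size());
    for (std::unordered_map<std::string,double>::iterator it = tab.begin();
         it != tab.end(); ++it) keys.push_back(it->first);
    std::sort(keys.begin(), keys.end());
    NumericVector cnt(keys.size());
    CharacterVector nm(keys.size());
    for (size_t i = 0; i < keys.size(); ++i) {
        nm[i] = keys[i];
        cnt[i] = tab[keys[i]];
    }
    return List::create(_["pattern"] = nm, _["count"] = cnt);
}

// [[Rcpp::export]]
LogicalVector cpp_local_maxima(CharacterVector patterns, NumericVector counts,
                               double theta, double min_count,
                               int max_def, int max_gap, bool merge_strands,
                               int max_candidates) {
    int n = patterns.size();
    std::unordered_map<std::string, double> tab;
    tab.reserve(n * 2);
    std::vector<std::string> pats(n);
    for (int i = 0; i < n; ++i) {
        pats[i] = as<std::string>(patterns[i]);
        tab[pats[i]] = counts[i];
    }
    // candidate order: count desc, pattern asc (determinism)
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        if (counts[a] != counts[b]) return counts[a] > counts[b];
        return pats[a] < pats[b];
    });
    LogicalVector res(n, false);
    int tested = 0;
    for (int oi = 0; oi < n; ++oi) {
        int i = ord[oi];
        double cp = counts[i];
        if (cp < min_count) continue;
        if (max_candidates > 0 && tested >= max_candidates) break;
        ++tested;
        int ndp = n_defined(pats[i]);
        CharacterVector nb = cpp_neighbors(pats[i], max_def, max_gap,
                                           merge_strands);
        bool ok = true;
        for (int j = 0; j < nb.size() && ok; ++j) {
            std::string q = as<std::string>(nb[j]);
            std::unordered_map<std::string,double>::iterator it = tab.find(q);
            if (it == tab.end()) continue;
            double cq = it->second;
            int ndq = n_defined(q);
            if (ndq == ndp) {
                if (cq >= cp) ok = false;           // strict dominance
            } else if (ndq == ndp - 1) {
                if (!(cp > theta * cq)) ok = false; // must beat shorter via theta
            } else if (ndq == ndp + 1) {
                if (cq > theta * cp) ok = false;    // longer neighbour wins
            }
        }
        res[i] = ok;
    }
    return res;
}

// ---- seed window machinery (multinomial PWM, dependency tables) ----

struct WinPick {
    int mism;     // mismatches at defined seed positions
    int pos;      // window start on the forward read
    int strand;   // 0 forward, 1 reverse
    std::string win;
};

// best window of width w = span + 2*flank fully inside the read, both strands
// when merge; order: fewest mismatches, then leftmost forward-read position,
// then forward strand
static bool pick_window(const std::string &read, const std::string &seed,
                        int flank, bool merge_strands, WinPick &out) {
    int span = (int)seed.size();
    int w = span + 2 * flank;
    int L = (int)read.size();
    if (w > L) return false;
    std::string rcread = merge_strands ? rc_str(read) : std::string();
    bool found = false;
    for (int pos = 0; pos + w <= L; ++pos) {
        for (int st = 0; st < (merge_strands ? 2 : 1); ++st) {
            const std::string &src = (st == 0) ? read : rcread;
            // window start in src coords such that forward-read start == pos
            int spos = (st == 0) ? pos : (L - w - pos);
            int m = 0;
            for (int i = 0; i < span; ++i) {
                char sc = seed[i];
                if (sc == 'n') continue;
                if (src[spos + flank + i] != sc) ++m;
            }
            if (!found || m < out.mism ||
                (m == out.mism && (pos < out.pos ||
                                   (pos == out.pos && st < out.strand)))) {
                found = true;
                out.mism = m; out.pos = pos; out.strand = st;
                out.win = src.substr(spos, w);
            }
        }
    }
    return found;
}

// [[Rcpp::export]]
NumericMatrix cpp_multinomial_matrix(CharacterVector reads, std::string seed,
                                     int order, int flank, bool merge_strands) {
    seed = trim_n(seed);
    int span = (int)seed.size();
    int w = span + 2 * flank;
    NumericMatrix counts(4, w);
    WinPick wp;
    for (int r = 0; r < reads.size(); ++r) {
        std::string read = as<std::string>(reads[r]);
        if (!pick_window(read, seed, flank, merge_strands, wp)) continue;
        if (wp.mism > order) continue;
        for (int i = 0; i < w; ++i) {
            char b = wp.win[i];
            int bi;
            switch (b) {
            case 'A': bi = 0; break; case 'C': bi = 1; break;
            case 'G': bi = 2; break; case 'T': bi = 3; break;
            default: bi = -1;
            }
            if (bi < 0) continue;
            int others = wp.mism;
            int si = i - flank;
            if (si >= 0 && si < span && seed[si] != 'n' && b != seed[si])
                --others;  // the queried position's own mismatch is allowed
            if (others <= order - 1) counts(bi, i) += 1.0;
        }
    }
    return counts;
}

// [[Rcpp::export]]
CharacterVector cpp_seed_windows(CharacterVector reads, std::string seed,
                                 int flank, int max_mismatch,
                                 bool merge_strands) {
    seed = trim_n(seed);
    std::vector<std::string> wins;
    WinPick wp;
    for (int r = 0; r < reads.size(); ++r) {
        std::string read = as<std::string>(reads[r]);
        if (!pick_window(read, seed, flank, merge_strands, wp)) continue;
        if (wp.mism <= max_mismatch) wins.push_back(wp.win);
    }
    return CharacterVector(wins.begin(), wins.end());
}

// [[Rcpp::export]]
NumericVector cpp_pwm_max_odds(CharacterVector reads, NumericMatrix log_odds,
                               bool merge_strands) {
    // per read: max over rigid placements (and strands) of the summed
    // log-odds of the window bases; rows of log_odds are A,C,G,T
    int w = log_odds.ncol();
    NumericVector out(reads.size());
    for (int r = 0; r < reads.size(); ++r) {
        std::string read = as<std::string>(reads[r]);
        int L = (int)read.size();
        double best = R_NegInf;
        for (int st = 0; st < (merge_strands ? 2 : 1); ++st) {
            std::string s = (st == 0) ? read : rc_str(read);
            for (int pos = 0; pos + w <= L; ++pos) {
                double sc = 0.0;
                bool ok = true;
                for (int i = 0; i < w; ++i) {
                    int bi;
                    switch (s[pos + i]) {
                    case 'A': bi = 0; break; case 'C': bi = 1; break;
                    case 'G': bi = 2; break; case 'T': bi = 3; break;
                    default: bi = -1;
                    }
                    if (bi < 0) { ok = false; break; }
                    sc += log_odds(bi, i);
                }
                if (ok && sc > best) best = sc;
            }
        }
        out[r] = best;
    }
    return out;
}
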