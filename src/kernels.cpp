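#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <queue>
#include <map>
#include <algorithm>

using namespace Rcpp;

typedef long long ll;
typedef unsigned long long u64;
typedef __int128 i128;

// ---------------------------------------------------------------------------
// popcount kernels
//
// "word64" is the production kernel: the fingerprint is read 8 bytes at a
// time (memcpy keeps it alignment-safe) and counted with the compiler
// builtin.  "lookup8" is the classic byte-table kernel and "bitwise" shifts
// out one bit at a time; both are kept as independent oracles so kernel
// agreement can be asserted.

static unsigned char POP8[256];
static bool pop8_ready = false;
static void init_pop8() {
    if (pop8_ready) return;
    for (int i = 0; i < 256; ++i) {
        int c = 0;
        for (int b = 0; b < 8; ++b) if (i & (1 << b)) ++c;
        POP8[i] = (unsigned char)c;
    }
    pop8_ready = true;
}

static inline int pc_word64(const unsigned char* p, int n) {
    int c = 0, i = 0;
    u64 w;
    for (; i + 8 <= n; i += 8) {
        std::memcpy(&w, p + i, 8);
        c += __builtin_popcountll(w);
    }
    if (i < n) {
        w = 0;
        std::memcpy(&w, p + i, (size_t)(n - i));
        c += __builtin_popcountll(w);
    }
    return c;
}

static inline int ipc_word64(const unsigned char* a, const unsigned char* b, int n) {
    int c = 0, i = 0;
    u64 x, y;
    for (; i + 8 <= n; i += 8) {
        std::memcpy(&x, a + i, 8);
        std::memcpy(&y, b + i, 8);
        c += __builtin_popcountll(x & y);
    }
    if (i < n) {
        x = y = 0;
        std::memcpy(&x, a + i, (size_t)(n - i));
        std::memcpy(&y, b + i, (size_t)(n - i));
        c += __builtin_popcountll(x & y);
    }
    return c;
}

static inline int pc_lookup8(const unsigned char* p, int n) {
    init_pop8();
    int c = 0;
    for (int i = 0; i < n; ++i) c += POP8[p[i]];
    return c;
}

static inline int pc_bitwise(const unsigned char* p, int n) {
    int c = 0;
    for (int i = 0; i < n; ++i) {
        unsigned char v = p[i];
        for (int b = 0; b < 8; ++b) c += (v >> b) & 1;
    }
    return c;
}

static int kernel_code(const std::string& name) {
    if (name == "word64") return 0;
    if (name == "lookup8") return 1;
    if (name == "bitwise") return 2;
    stop("unknown popcount kernel '%s'", name.c_str());
    return -1; // not reached
}

// [[Rcpp::export]]
int cpp_popcount(RawVector fp, std::string kernel) {
    const unsigned char* p = RAW(fp);
    int n = fp.size();
    switch (kernel_code(kernel)) {
    case 0: return pc_word64(p, n);
    case 1: return pc_lookup8(p, n);
    default: return pc_bitwise(p, n);
    }
}

// [[Rcpp::export]]
int cpp_intersect_popcount(RawVector fp1, RawVector fp2, std::string kernel) {
    if (fp1.size() != fp2.size())
        stop("fingerprint lengths differ (%d vs %d bytes)", (int)fp1.size(), (int)fp2.size());
    const unsigned char* a = RAW(fp1);
    const unsigned char* b = RAW(fp2);
    int n = fp1.size();
    int kc = kernel_code(kernel);
    if (kc == 0) return ipc_word64(a, b, n);
    init_pop8();
    int c = 0;
    if (kc == 1) {
        for (int i = 0; i < n; ++i) c += POP8[a[i] & b[i]];
    } else {
        for (int i = 0; i < n; ++i) {
            unsigned char v = a[i] & b[i];
            for (int k = 0; k < 8; ++k) c += (v >> k) & 1;
        }
    }
    return c;
}

// ---------------------------------------------------------------------------
// hex codec.  Bit k of the fingerprint is bit (k mod 8) of byte floor(k/8);
// the two hex characters of a byte are in conventional big-endian nibble
// order, so the nibbles of a 16-bit fingerprint appear in order "1032".

static signed char HEXVAL[256];
static bool hexval_ready = false;
static void init_hexval() {
    if (hexval_ready) return;
    for (int i = 0; i < 256; ++i) HEXVAL[i] = -1;
    for (int i = 0; i < 10; ++i) HEXVAL['0' + i] = (signed char)i;
    for (int i = 0; i < 6; ++i) {
        HEXVAL['a' + i] = (signed char)(10 + i);
        HEXVAL['A' + i] = (signed char)(10 + i);
    }
    hexval_ready = true;
}

static const char HEXDIG[] = "0123456789abcdef";

// [[Rcpp::export]]
RawVector cpp_hex_decode(std::string hex) {
    init_hexval();
    size_t n = hex.size();
    if (n == 0) stop("empty hex string");
    if (n % 2 != 0) stop("odd hex string length (%d characters)", (int)n);
    RawVector out((R_xlen_t)(n / 2));
    unsigned char* o = RAW(out);
    for (size_t i = 0; i < n; i += 2) {
        signed char hi = HEXVAL[(unsigned char)hex[i]];
        signed char lo = HEXVAL[(unsigned char)hex[i + 1]];
        if (hi < 0) stop("non-hex character '%c' at position %d", hex[i], (int)(i + 1));
        if (lo < 0) stop("non-hex character '%c' at position %d", hex[i + 1], (int)(i + 2));
        o[i / 2] = (unsigned char)((hi << 4) | lo);
    }
    return out;
}

// [[Rcpp::export]]
std::string cpp_hex_encode(RawVector fp) {
    int n = fp.size();
    if (n == 0) stop("empty fingerprint");
    std::string s((size_t)(2 * n), '0');
    const unsigned char* p = RAW(fp);
    for (int i = 0; i < n; ++i) {
        s[2 * i]     = HEXDIG[p[i] >> 4];
        s[2 * i + 1] = HEXDIG[p[i] & 0x0f];
    }
    return s;
}

// Encode every fingerprint slot of a (possibly padded) block.
// [[Rcpp::export]]
CharacterVector cpp_hex_encode_block(RawVector block, int n, int num_bytes,
                                     int storage, int start_padding) {
    CharacterVector out(n);
    const unsigned char* base = RAW(block);
    std::string s((size_t)(2 * num_bytes), '0');
    for (int i = 0; i < n; ++i) {
        const unsigned char* p = base + start_padding + (size_t)i * storage;
        for (int j = 0; j < num_bytes; ++j) {
            s[2 * j]     = HEXDIG[p[j] >> 4];
            s[2 * j + 1] = HEXDIG[p[j] & 0x0f];
        }
        out[i] = s;
    }
    return out;
}

// ---------------------------------------------------------------------------
// FPS record-line parser.  Each line is "<hex>\t<id>[\t<extra>...]".
// Validation is total: every line is checked and errors carry line numbers.

// [[Rcpp::export]]
List cpp_parse_fps_lines(CharacterVector lines, int start_lineno, int num_bits) {
    init_hexval();
    init_pop8();
    int n = lines.size();
    int num_bytes = -1;
    std::vector<unsigned char> block;
    CharacterVector ids(n);
    CharacterVector extra(n);
    IntegerVector popcounts(n);
    int pad_bits = 0; // bits of the last byte that must be zero
    for (int r = 0; r < n; ++r) {
        int lineno = start_lineno + r;
        const char* s = CHAR(STRING_ELT(lines, r));
        const char* tab = strchr(s, '\t');
        if (!tab) stop("line %d: missing tab separator between fingerprint and id", lineno);
        int hexlen = (int)(tab - s);
        if (hexlen == 0) stop("line %d: empty fingerprint field", lineno);
        if (hexlen % 2 != 0) stop("line %d: odd fingerprint hex length (%d)", lineno, hexlen);
        int nb = hexlen / 2;
        if (num_bytes < 0) {
            num_bytes = nb;
            if (num_bits > 0) {
                int need = (num_bits + 7) / 8;
                if (need != num_bytes)
                    stop("line %d: fingerprint has %d bytes but num_bits=%d implies %d",
                         lineno, num_bytes, num_bits, need);
            }
            if (num_bits > 0 && num_bits % 8 != 0) pad_bits = 8 * num_bytes - num_bits;
            block.reserve((size_t)n * num_bytes);
        } else if (nb != num_bytes) {
            stop("line %d: inconsistent fingerprint length (%d bytes, expected %d)",
                 lineno, nb, num_bytes);
        }
        int pc = 0;
        for (int j = 0; j < num_bytes; ++j) {
            signed char hi = HEXVAL[(unsigned char)s[2 * j]];
            signed char lo = HEXVAL[(unsigned char)s[2 * j + 1]];
            if (hi < 0 || lo < 0)
                stop("line %d: non-hex character in fingerprint field", lineno);
            unsigned char byte = (unsigned char)((hi << 4) | lo);
            if (pad_bits && j == num_bytes - 1) {
                unsigned char mask = (unsigned char)((1u << (8 - pad_bits)) - 1u);
                if (byte & ~mask)
                    stop("line %d: bits beyond num_bits=%d are not zero", lineno, num_bits);
            }
            block.push_back(byte);
            pc += POP8[byte];
        }
        popcounts[r] = pc;
        const char* idstart = tab + 1;
        const char* tab2 = strchr(idstart, '\t');
        int idlen = tab2 ? (int)(tab2 - idstart) : (int)strlen(idstart);
        if (idlen == 0) stop("line %d: empty id field", lineno);
        ids[r] = std::string(idstart, (size_t)idlen);
        extra[r] = tab2 ? std::string(tab2 + 1) : std::string();
    }
    RawVector rb((R_xlen_t)block.size());
    if (!block.empty()) std::memcpy(RAW(rb), block.data(), block.size());
    return List::create(_["ids"] = ids, _["block"] = rb,
                        _["num_bytes"] = num_bytes < 0 ? 0 : num_bytes,
                        _["extra"] = extra, _["popcounts"] = popcounts);
}

// ---------------------------------------------------------------------------
// block helpers

// Popcount of each slot in a block (tight records: storage == num_bytes,
// start_padding == 0, as produced by the FPS parser; or arena layout).
// [[Rcpp::export]]
IntegerVector cpp_block_popcounts(RawVector block, int n, int num_bytes,
                                  int storage, int start_padding) {
    IntegerVector out(n);
    const unsigned char* base = RAW(block);
    for (int i = 0; i < n; ++i)
        out[i] = pc_word64(base + start_padding + (size_t)i * storage, num_bytes);
    return out;
}

// Repack tight records into an arena block with the given order, storage
// size and start padding.  order is 1-based (an R permutation).
// [[Rcpp::export]]
RawVector cpp_pack_block(RawVector records, int n, int num_bytes,
                         IntegerVector order, int storage, int start_padding) {
    RawVector out((R_xlen_t)start_padding + (R_xlen_t)n * storage);
    std::memset(RAW(out), 0, (size_t)out.size());
    const unsigned char* src = RAW(records);
    unsigned char* dst = RAW(out);
    for (int i = 0; i < n; ++i) {
        int from = order[i] - 1;
        std::memcpy(dst + start_padding + (size_t)i * storage,
                    src + (size_t)from * num_bytes, (size_t)num_bytes);
    }
    return out;
}

// Extract slot i (1-based) as a tight raw vector of num_bytes.
// [[Rcpp::export]]
RawVector cpp_block_slot(RawVector block, int i, int num_bytes,
                         int storage, int start_padding) {
    RawVector out(num_bytes);
    std::memcpy(RAW(out), RAW(block) + start_padding + (size_t)(i - 1) * storage,
                (size_t)num_bytes);
    return out;
}

// ---------------------------------------------------------------------------
// exact rational threshold
//
// Every finite double in [0, 1] is exactly m / 2^s, so the threshold is
// decomposed exactly and reduced; the rejection test c*q >= p*(A+B-c) is
// then *equivalent* to Tanimoto >= T, not merely necessary.  Products are
// evaluated in 128-bit arithmetic; p and q never exceed 2^53 so they are
// returned losslessly as doubles.

// [[Rcpp::export]]
NumericVector cpp_rational_from_double(double t) {
    if (!(t >= 0.0 && t <= 1.0)) stop("threshold must be in [0, 1]");
    double x = t;
    ll q = 1;
    while (x != std::floor(x)) {
        x *= 2.0;
        q <<= 1;
        if (q <= 0) stop("threshold cannot be represented"); // unreachable for [0,1]
    }
    ll p = (ll)x;
    if (p > 0) {
        ll a = p, b = q;
        while (b) { ll r = a % b; a = b; b = r; }
        p /= a; q /= a;
    } else {
        q = 1;
    }
    return NumericVector::create((double)p, (double)q);
}

// ceil(T*(A+B)/(1+T)) with T = p/q, computed in exact integer arithmetic.
// [[Rcpp::export]]
IntegerVector cpp_min_required_popcount(double p_, double q_,
                                        IntegerVector A, IntegerVector B) {
    ll P = (ll)p_, Q = (ll)q_;
    if (P <= 0) stop("threshold must be positive");
    R_xlen_t n = A.size();
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        i128 num = (i128)P * (A[i] + B[i]);
        ll den = P + Q;
        out[i] = (int)((num + den - 1) / den);
    }
    return out;
}

// ---------------------------------------------------------------------------
// Tversky with integer weights.  alpha and beta are scaled by 10,000 and
// rounded before the search starts; the only floating-point operation is
// the final division, so self-similarity is exactly 1 for nonzero inputs.

static inline void tversky_parts(const unsigned char* a, const unsigned char* b,
                                 int nbytes, int* A, int* B, int* c) {
    int pa = 0, pb = 0, pc = 0, i = 0;
    u64 x, y;
    for (; i + 8 <= nbytes; i += 8) {
        std::memcpy(&x, a + i, 8);
        std::memcpy(&y, b + i, 8);
        pa += __builtin_popcountll(x);
        pb += __builtin_popcountll(y);
        pc += __builtin_popcountll(x & y);
    }
    if (i < nbytes) {
        x = y = 0;
        std::memcpy(&x, a + i, (size_t)(nbytes - i));
        std::memcpy(&y, b + i, (size_t)(nbytes - i));
        pa += __builtin_popcountll(x);
        pb += __builtin_popcountll(y);
        pc += __builtin_popcountll(x & y);
    }
    *A = pa; *B = pb; *c = pc;
}

// [[Rcpp::export]]
double cpp_tversky(RawVector fp1, RawVector fp2, int a10k, int b10k) {
    if (fp1.size() != fp2.size())
        stop("fingerprint lengths differ (%d vs %d bytes)", (int)fp1.size(), (int)fp2.size());
    int A, B, c;
    tversky_parts(RAW(fp1), RAW(fp2), fp1.size(), &A, &B, &c);
    ll num = 10000LL * c;
    ll den = (ll)a10k * (A - c) + (ll)b10k * (B - c) + num;
    if (den == 0) return 0.0;
    return (double)num / (double)den;
}

// ---------------------------------------------------------------------------
// search result plumbing

struct Hit { int c; int d; int idx; }; // score = c/d, d > 0 unless c == 0

// exact rational compare: is a strictly better than b?
// (higher score first; ties broken by ascending index)
static inline bool hit_better(const Hit& a, const Hit& b) {
    ll lhs = (ll)a.c * b.d, rhs = (ll)b.c * a.d;
    if (lhs != rhs) return lhs > rhs;
    return a.idx < b.idx;
}

static inline double hit_score(const Hit& h) {
    return h.d == 0 ? 0.0 : (double)h.c / (double)h.d;
}

static List hits_to_list(std::vector<Hit>& hits, ll candidates, ll divisions) {
    int n = (int)hits.size();
    IntegerVector idx(n);
    NumericVector score(n);
    for (int i = 0; i < n; ++i) {
        idx[i] = hits[i].idx + 1;
        score[i] = hit_score(hits[i]);
    }
    return List::create(_["index"] = idx, _["score"] = score,
                        _["candidates"] = (double)candidates,
                        _["divisions"] = (double)divisions);
}

// ---------------------------------------------------------------------------
// BitBound threshold search over a popcount-sorted arena.
// popidx has num_bits + 2 entries of 0-based bin starts; bin b occupies
// [popidx[b], popidx[b+1]).  Only bins with ceil(A*T) <= B <= floor(A/T)
// are examined, and within a bin candidates are rejected by comparing the
// intersection popcount to the per-bin minimum before any division.

// [[Rcpp::export]]
List cpp_threshold_search(RawVector block, int n, int storage, int start_padding,
                          int num_bits, IntegerVector popidx, RawVector query,
                          double p_, double q_) {
    ll P = (ll)p_, Q = (ll)q_;
    const unsigned char* base = RAW(block) + start_padding;
    const unsigned char* qp = RAW(query);
    int A = pc_word64(qp, storage);
    std::vector<Hit> hits;
    ll candidates = 0, divisions = 0;

    if (P == 0) { // threshold 0: everything matches; zero-popcount pairs score 0
        hits.reserve((size_t)n);
        for (int b = 0; b <= num_bits; ++b) {
            for (int i = popidx[b]; i < popidx[b + 1]; ++i) {
                int c = ipc_word64(base + (size_t)i * storage, qp, storage);
                ++candidates;
                int d = A + b - c;
                if (d > 0) ++divisions;
                hits.push_back(Hit{c, d, i});
            }
        }
        return hits_to_list(hits, candidates, divisions);
    }
    if (A == 0) // all-zero query scores 0 against everything
        return hits_to_list(hits, candidates, divisions);

    int bmin = (int)(((i128)A * P + Q - 1) / Q);
    i128 bx = ((i128)A * Q) / P;
    int bmax = bx > num_bits ? num_bits : (int)bx;
    if (bmin < 0) bmin = 0;
    for (int b = bmin; b <= bmax; ++b) {
        int lo = popidx[b], hi = popidx[b + 1];
        if (lo == hi) continue;
        ll den = P + Q;
        int cmin = (int)(((i128)P * (A + b) + den - 1) / den);
        for (int i = lo; i < hi; ++i) {
            int c = ipc_word64(base + (size_t)i * storage, qp, storage);
            ++candidates;
            if (c < cmin) continue;
            ++divisions;
            hits.push_back(Hit{c, A + b - c, i});
        }
    }
    return hits_to_list(hits, candidates, divisions);
}

// linear-scan threshold search for unsorted arenas (both popcounts computed)
// [[Rcpp::export]]
List cpp_linear_threshold(RawVector block, int n, int storage, int start_padding,
                          RawVector query, double p_, double q_) {
    ll P = (ll)p_, Q = (ll)q_;
    const unsigned char* base = RAW(block) + start_padding;
    const unsigned char* qp = RAW(query);
    int A = pc_word64(qp, storage);
    std::vector<Hit> hits;
    ll candidates = 0, divisions = 0;
    for (int i = 0; i < n; ++i) {
        const unsigned char* t = base + (size_t)i * storage;
        int B = pc_word64(t, storage);
        int c = ipc_word64(t, qp, storage);
        ++candidates;
        int d = A + B - c;
        if (P == 0) {
            if (d > 0) ++divisions;
            hits.push_back(Hit{c, d, i});
        } else {
            if (d == 0) continue; // both all-zero: score 0 < T
            if ((i128)c * Q >= (i128)P * d) {
                ++divisions;
                hits.push_back(Hit{c, d, i});
            }
        }
    }
    return hits_to_list(hits, candidates, divisions);
}

// ---------------------------------------------------------------------------
// k-nearest search: popcount bins are visited in decreasing order of their
// best possible score min(A,B)/max(A,B), merging the B < A and B > A sides;
// the search stops when the k-th best score strictly exceeds the bound of
// every unvisited bin.  A bounded heap keeps the current best k.

struct WorseFirst { // priority_queue top = worst element
    bool operator()(const Hit& a, const Hit& b) const { return hit_better(a, b); }
};

// [[Rcpp::export]]
List cpp_knearest(RawVector block, int n, int storage, int start_padding,
                  int num_bits, IntegerVector popidx, RawVector query,
                  int k, double p_, double q_, int exclude) {
    ll P = (ll)p_, Q = (ll)q_;
    const unsigned char* base = RAW(block) + start_padding;
    const unsigned char* qp = RAW(query);
    int A = pc_word64(qp, storage);
    ll candidates = 0, divisions = 0;
    std::vector<Hit> out;

    if (A == 0) {
        // every score is 0; eligible only when the minimum threshold is 0
        if (P == 0) {
            for (int i = 0; i < n && (int)out.size() < k; ++i) {
                if (i == exclude) continue;
                out.push_back(Hit{0, 1, i});
            }
        }
        return hits_to_list(out, candidates, divisions);
    }

    int bmin = 0, bmax = num_bits;
    if (P > 0) {
        bmin = (int)(((i128)A * P + Q - 1) / Q);
        i128 bx = ((i128)A * Q) / P;
        bmax = bx > num_bits ? num_bits : (int)bx;
    }

    std::priority_queue<Hit, std::vector<Hit>, WorseFirst> heap;
    int lo = A < bmax ? A : bmax; // next bin on the low side (B <= A)
    int hi = lo + 1;              // next bin on the high side (B > A)

    while (true) {
        bool have_lo = lo >= bmin;
        bool have_hi = hi <= bmax;
        if (!have_lo && !have_hi) break;
        int b;
        if (have_lo && have_hi) {
            // compare bounds lo/A (low side) vs A/hi (high side)
            if ((ll)lo * hi >= (ll)A * A) { b = lo--; } else { b = hi++; }
        } else if (have_lo) {
            b = lo--;
        } else {
            b = hi++;
        }
        int minAB = b < A ? b : A, maxAB = b < A ? A : b;
        if ((int)heap.size() == k) {
            const Hit& worst = heap.top();
            // stop when bound < k-th best score (strict: equal-score bins may
            // still contain lower-index ties that displace current members)
            if ((ll)minAB * worst.d < (ll)worst.c * maxAB) break;
        }
        int s = popidx[b], e = popidx[b + 1];
        if (s == e) continue;
        int cmin = 0;
        if (P > 0) {
            ll den = P + Q;
            cmin = (int)(((i128)P * (A + b) + den - 1) / den);
        }
        for (int i = s; i < e; ++i) {
            if (i == exclude) continue;
            int c = ipc_word64(base + (size_t)i * storage, qp, storage);
            ++candidates;
            if (c < cmin) continue;
            ++divisions;
            Hit h{c, A + b - c, i};
            if ((int)heap.size() < k) {
                heap.push(h);
            } else if (hit_better(h, heap.top())) {
                heap.pop();
                heap.push(h);
            }
            // k exact matches held: score-1.0 hits only exist in this
            // (first-visited) bin and in-bin indices ascend, so nothing
            // seen later can displace them
            if ((int)heap.size() == k && heap.top().c == heap.top().d) {
                lo = bmin - 1; hi = bmax + 1;
                break;
            }
        }
    }
    out.resize(heap.size());
    for (int i = (int)heap.size() - 1; i >= 0; --i) {
        out[i] = heap.top();
        heap.pop();
    }
    return hits_to_list(out, candidates, divisions);
}

// counting-sort k-nearest: hits are bucketed by their exact rational score
// (Tanimoto values are ratios of small integers, so there are few distinct
// values); no priority queue is needed.
struct FracDesc {
    bool operator()(const std::pair<int,int>& a, const std::pair<int,int>& b) const {
        ll lhs = (ll)a.first * b.second, rhs = (ll)b.first * a.second;
        return lhs > rhs; // higher score first
    }
};

// [[Rcpp::export]]
List cpp_knearest_counting(RawVector block, int n, int storage, int start_padding,
                           int num_bits, IntegerVector popidx, RawVector query,
                           int k, double p_, double q_, int exclude) {
    ll P = (ll)p_, Q = (ll)q_;
    const unsigned char* base = RAW(block) + start_padding;
    const unsigned char* qp = RAW(query);
    int A = pc_word64(qp, storage);
    ll candidates = 0, divisions = 0;
    std::vector<Hit> out;

    if (A == 0) {
        if (P == 0) {
            for (int i = 0; i < n && (int)out.size() < k; ++i) {
                if (i == exclude) continue;
                out.push_back(Hit{0, 1, i});
            }
        }
        return hits_to_list(out, candidates, divisions);
    }

    int bmin = 0, bmax = num_bits;
    if (P > 0) {
        bmin = (int)(((i128)A * P + Q - 1) / Q);
        i128 bx = ((i128)A * Q) / P;
        bmax = bx > num_bits ? num_bits : (int)bx;
    }

    typedef std::map<std::pair<int,int>, std::vector<int>, FracDesc> Buckets;
    Buckets buckets;
    size_t total = 0;
    int lo = A < bmax ? A : bmax;
    int hi = lo + 1;

    while (true) {
        bool have_lo = lo >= bmin;
        bool have_hi = hi <= bmax;
        if (!have_lo && !have_hi) break;
        int b;
        if (have_lo && have_hi) {
            if ((ll)lo * hi >= (ll)A * A) { b = lo--; } else { b = hi++; }
        } else if (have_lo) {
            b = lo--;
        } else {
            b = hi++;
        }
        int minAB = b < A ? b : A, maxAB = b < A ? A : b;
        if (total >= (size_t)k) {
            // find the k-th best score among buckets so far
            size_t acc = 0;
            std::pair<int,int> kth(0, 1);
            for (Buckets::iterator it = buckets.begin(); it != buckets.end(); ++it) {
                acc += it->second.size();
                if (acc >= (size_t)k) { kth = it->first; break; }
            }
            if ((ll)minAB * kth.second < (ll)kth.first * maxAB) break;
        }
        int s = popidx[b], e = popidx[b + 1];
        if (s == e) continue;
        int cmin = 0;
        if (P > 0) {
            ll den = P + Q;
            cmin = (int)(((i128)P * (A + b) + den - 1) / den);
        }
        for (int i = s; i < e; ++i) {
            if (i == exclude) continue;
            int c = ipc_word64(base + (size_t)i * storage, qp, storage);
            ++candidates;
            if (c < cmin) continue;
            ++divisions;
            int d = A + b - c;
            int g = c, h2 = d;
            while (h2) { int r = g % h2; g = h2; h2 = r; }
            if (g == 0) g = 1;
            buckets[std::make_pair(c / g, d / g)].push_back(i);
            ++total;
            if (c == d) { // k exact matches: nothing can displace them
                Buckets::iterator top = buckets.find(std::make_pair(1, 1));
                if (top != buckets.end() && (int)top->second.size() >= k) {
                    lo = bmin - 1; hi = bmax + 1;
                    break;
                }
            }
        }
    }
    for (Buckets::iterator it = buckets.begin(); it != buckets.end() && (int)out.size() < k; ++it) {
        std::vector<int>& v = it->second;
        std::sort(v.begin(), v.end());
        for (size_t j = 0; j < v.size() && (int)out.size() < k; ++j)
            out.push_back(Hit{it->first.first, it->first.second, v[j]});
    }
    return hits_to_list(out, candidates, divisions);
}

// ---------------------------------------------------------------------------
// symmetric N x N threshold search: upper triangle only (i < j, which in a
// popcount-sorted arena means B_j >= B_i, so only bins at or above the
// query's own bin are visited, clipped by the BitBound upper limit).

// [[Rcpp::export]]
List cpp_symmetric_threshold(RawVector block, int n, int storage, int start_padding,
                             int num_bits, IntegerVector popidx, double p_, double q_) {
    ll P = (ll)p_, Q = (ll)q_;
    const unsigned char* base = RAW(block) + start_padding;
    std::vector<int> ri, rj;
    std::vector<double> rs;
    ll candidates = 0, divisions = 0;
    for (int A = 0; A <= num_bits; ++A) {
        int s0 = popidx[A], e0 = popidx[A + 1];
        if (s0 == e0) continue;
        int bmax = num_bits;
        if (P > 0) {
            if (A == 0) continue; // all-zero rows never reach a positive threshold
            i128 bx = ((i128)A * Q) / P;
            bmax = bx > num_bits ? num_bits : (int)bx;
        }
        for (int i = s0; i < e0; ++i) {
            const unsigned char* fi = base + (size_t)i * storage;
            for (int b = A; b <= bmax; ++b) {
                int s = (b == A) ? i + 1 : popidx[b];
                int e = popidx[b + 1];
                if (s >= e) continue;
                int cmin = 0;
                if (P > 0) {
                    ll den = P + Q;
                    cmin = (int)(((i128)P * (A + b) + den - 1) / den);
                }
                for (int j = s; j < e; ++j) {
                    int c = ipc_word64(fi, base + (size_t)j * storage, storage);
                    ++candidates;
                    if (P > 0 && c < cmin) continue;
                    int d = A + b - c;
                    if (d > 0) ++divisions;
                    ri.push_back(i + 1);
                    rj.push_back(j + 1);
                    rs.push_back(d == 0 ? 0.0 : (double)c / (double)d);
                }
            }
        }
    }
    return List::create(_["i"] = wrap(ri), _["j"] = wrap(rj), _["score"] = wrap(rs),
                        _["candidates"] = (double)candidates,
                        _["divisions"] = (double)divisions);
}

// ---------------------------------------------------------------------------
// Tversky search.  No Tversky BitBound is applied: the scan is linear with
// the integer rejection test (correctness over speed for asymmetric weights).
// mode 0 = threshold, mode 1 = k-nearest.

static inline bool tv_better(ll n1, ll d1, int i1, ll n2, ll d2, int i2) {
    i128 lhs = (i128)n1 * d2, rhs = (i128)n2 * d1;
    if (lhs != rhs) return lhs > rhs;
    return i1 < i2;
}

// [[Rcpp::export]]
List cpp_tversky_search(RawVector block, int n, int storage, int start_padding,
                        RawVector query, int a10k, int b10k,
                        double p_, double q_, int mode, int k, int exclude) {
    ll P = (ll)p_, Q = (ll)q_;
    const unsigned char* base = RAW(block) + start_padding;
    const unsigned char* qp = RAW(query);
    std::vector<int> idxv;
    std::vector<ll> numv, denv;
    ll candidates = 0, divisions = 0;
    for (int i = 0; i < n; ++i) {
        if (i == exclude) continue;
        int A, B, c;
        tversky_parts(qp, base + (size_t)i * storage, storage, &A, &B, &c);
        ++candidates;
        ll num = 10000LL * c;
        ll den = (ll)a10k * (A - c) + (ll)b10k * (B - c) + num;
        bool zero = (den == 0); // score 0 by convention
        if (P > 0) {
            if (zero) continue;
            if ((i128)num * Q < (i128)P * den) continue;
        }
        ++divisions;
        idxv.push_back(i);
        numv.push_back(zero ? 0 : num);
        denv.push_back(zero ? 1 : den);
    }
    int m = (int)idxv.size();
    std::vector<int> ord(m);
    for (int i = 0; i < m; ++i) ord[i] = i;
    if (mode == 1) {
        std::sort(ord.begin(), ord.end(), [&](int a, int b) {
            return tv_better(numv[a], denv[a], idxv[a], numv[b], denv[b], idxv[b]);
        });
        if (m > k) { ord.resize((size_t)k); m = k; }
    }
    IntegerVector oi(m);
    NumericVector os(m);
    for (int i = 0; i < m; ++i) {
        oi[i] = idxv[ord[i]] + 1;
        os[i] = denv[ord[i]] == 0 ? 0.0 : (double)numv[ord[i]] / (double)denv[ord[i]];
    }
    return List::create(_["index"] = oi, _["score"] = os,
                        _["candidates"] = (double)candidates,
                        _["divisions"] = (double)divisions);
}

// ---------------------------------------------------------------------------
// brute-force oracle: score every record of a tight block against a query
// using the lookup-table popcount and plain double division.  This path is
// deliberately independent of the arena search machinery.

// [[Rcpp::export]]
NumericVector cpp_all_scores(RawVector records, int n, int num_bytes, RawVector query) {
    init_pop8();
    if ((int)query.size() != num_bytes) stop("query length mismatch");
    const unsigned char* base = RAW(records);
    const unsigned char* qp = RAW(query);
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        const unsigned char* t = base + (size_t)i * num_bytes;
        int uni = 0, inter = 0;
        for (int j = 0; j < num_bytes; ++j) {
            uni += POP8[t[j] | qp[j]];
            inter += POP8[t[j] & qp[j]];
        }
        out[i] = uni == 0 ? 0.0 : (double)inter / (double)uni;
    }
    return out;
}

// ---------------------------------------------------------------------------
// FPS file-scan search: the score is computed directly from the hex text;
// no fingerprint object is built for sub-threshold lines.  mode 0 =
// threshold (total validation), mode 1 = k-nearest (may stop validating
// once k exact matches have been seen).

// [[Rcpp::export]]
List cpp_fps_scan(CharacterVector lines, int start_lineno, RawVector query,
                  int num_bits, double p_, double q_, int mode, int k) {
    init_hexval();
    init_pop8();
    ll P = (ll)p_, Q = (ll)q_;
    int num_bytes = query.size();
    const unsigned char* qp = RAW(query);
    int A = pc_lookup8(qp, num_bytes);
    int pad_bits = (num_bits % 8) ? 8 * num_bytes - num_bits : 0;
    int n = lines.size();
    std::vector<Hit> hits;            // idx = record number (0-based)
    std::vector<std::string> hit_ids; // parallel for threshold mode
    int exact = 0;
    int scanned = 0;
    ll candidates = 0;

    // k-nearest bookkeeping (heap of hits; ids fetched afterwards)
    std::priority_queue<Hit, std::vector<Hit>, WorseFirst> heap;

    for (int r = 0; r < n; ++r) {
        int lineno = start_lineno + r;
        const char* s = CHAR(STRING_ELT(lines, r));
        const char* tab = strchr(s, '\t');
        if (!tab) stop("line %d: missing tab separator between fingerprint and id", lineno);
        int hexlen = (int)(tab - s);
        if (hexlen % 2 != 0) stop("line %d: odd fingerprint hex length (%d)", lineno, hexlen);
        if (hexlen / 2 != num_bytes)
            stop("line %d: fingerprint has %d bytes but the query has %d",
                 lineno, hexlen / 2, num_bytes);
        int B = 0, c = 0;
        for (int j = 0; j < num_bytes; ++j) {
            signed char hn = HEXVAL[(unsigned char)s[2 * j]];
            signed char ln = HEXVAL[(unsigned char)s[2 * j + 1]];
            if (hn < 0 || ln < 0)
                stop("line %d: non-hex character in fingerprint field", lineno);
            unsigned char byte = (unsigned char)((hn << 4) | ln);
            if (pad_bits && j == num_bytes - 1) {
                unsigned char mask = (unsigned char)((1u << (8 - pad_bits)) - 1u);
                if (byte & ~mask)
                    stop("line %d: bits beyond num_bits=%d are not zero", lineno, num_bits);
            }
            B += POP8[byte];
            c += POP8[byte & qp[j]];
        }
        const char* idstart = tab + 1;
        const char* tab2 = strchr(idstart, '\t');
        int idlen = tab2 ? (int)(tab2 - idstart) : (int)strlen(idstart);
        if (idlen == 0) stop("line %d: empty id field", lineno);
        ++candidates;
        ++scanned;
        int d = A + B - c;
        bool pass;
        if (P == 0) pass = true;
        else if (d == 0) pass = false;             // both all-zero: score 0
        else pass = (i128)c * Q >= (i128)P * d;
        if (pass) {
            Hit h{c, d == 0 ? 0 : d, r};
            if (mode == 0) {
                hits.push_back(h);
                hit_ids.push_back(std::string(idstart, (size_t)idlen));
            } else {
                if ((int)heap.size() < k) heap.push(h);
                else if (hit_better(h, heap.top())) { heap.pop(); heap.push(h); }
                if (c == A && B == A && A > 0) {
                    ++exact;
                    if (exact >= k) { ++r; break; } // early exit: k exact matches
                }
            }
        }
    }

    if (mode == 1) {
        hits.resize(heap.size());
        for (int i = (int)heap.size() - 1; i >= 0; --i) {
            hits[i] = heap.top();
            heap.pop();
        }
        hit_ids.resize(hits.size());
        for (size_t i = 0; i < hits.size(); ++i) {
            const char* s = CHAR(STRING_ELT(lines, hits[i].idx));
            const char* tab = strchr(s, '\t');
            const char* idstart = tab + 1;
            const char* tab2 = strchr(idstart, '\t');
            int idlen = tab2 ? (int)(tab2 - idstart) : (int)strlen(idstart);
            hit_ids[i] = std::string(idstart, (size_t)idlen);
        }
    }
    int m = (int)hits.size();
    IntegerVector recno(m);
    NumericVector score(m);
    CharacterVector ids(m);
    for (int i = 0; i < m; ++i) {
        recno[i] = hits[i].idx + 1;
        score[i] = hit_score(hits[i]);
        ids[i] = hit_ids[i];
    }
    return List::create(_["recno"] = recno, _["id"] = ids, _["score"] = score,
                        _["scanned"] = scanned, _["candidates"] = (double)candidates);
}

// ---------------------------------------------------------------------------
// cdb hash (DJB hash, xor variant) over the UTF-8 bytes of each id,
// reduced modulo 2^32.  Used by the FPB HASH chunk.

// [[Rcpp::export]]
NumericVector cpp_cdb_hash(CharacterVector ids) {
    R_xlen_t n = ids.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char* s = CHAR(STRING_ELT(ids, i));
        uint32_t h = 5381u;
        for (const unsigned char* p = (const unsigned char*)s; *p; ++p)
            h = ((h << 5) + h) ^ *p;
        out[i] = (double)h;
    }
    return out;
}

// ---------------------------------------------------------------------------
// synthetic fingerprint generators (driven by R's RNG, so set.seed applies)

// [[Rcpp::export]]
RawVector cpp_generate_block(int n, int num_bits, double density) {
    int num_bytes = (num_bits + 7) / 8;
    RawVector out((R_xlen_t)n * num_bytes);
    std::memset(RAW(out), 0, (size_t)out.size());
    unsigned char* base = RAW(out);
    for (int i = 0; i < n; ++i) {
        unsigned char* p = base + (size_t)i * num_bytes;
        for (int b = 0; b < num_bits; ++b)
            if (unif_rand() < density) p[b >> 3] |= (unsigned char)(1u << (b & 7));
    }
    return out;
}

// [[Rcpp::export]]
RawVector cpp_generate_from_popcounts(IntegerVector popcounts, int num_bits) {
    int n = popcounts.size();
    int num_bytes = (num_bits + 7) / 8;
    RawVector out((R_xlen_t)n * num_bytes);
    std::memset(RAW(out), 0, (size_t)out.size());
    unsigned char* base = RAW(out);
    std::vector<int> pool((size_t)num_bits);
    for (int i = 0; i < n; ++i) {
        int kbits = popcounts[i];
        if (kbits < 0 || kbits > num_bits)
            stop("popcount %d out of range for %d bits", kbits, num_bits);
        for (int b = 0; b < num_bits; ++b) pool[(size_t)b] = b;
        unsigned char* p = base + (size_t)i * num_bytes;
        for (int j = 0; j < kbits; ++j) { // partial Fisher-Yates
            int pick = j + (int)(unif_rand() * (num_bits - j));
            if (pick >= num_bits) pick = num_bits - 1;
            std::swap(pool[(size_t)j], pool[(size_t)pick]);
            int b = pool[(size_t)j];
            p[b >> 3] |= (unsigned char)(1u << (b & 7));
        }
    }
    return out;
}
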