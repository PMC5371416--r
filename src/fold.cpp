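#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Single-stranded DNA secondary-structure DP under a stacking-only
// nearest-neighbor model with optional forced pairs ("the structure must
// contain every forced pair").  Recursions split every interval by the
// fate of its rightmost base and track, for each interval [i, j]:
//   Zno / Fno : i and j not paired with each other
//   Zb  / Fb  : (i, j) paired (stack bonus when (i+1, j-1) also pairs)
//   Z   / F   : either
// Forced positions may neither stay unpaired nor pair anyone but their
// designated partner, which restricts both sums to constraint-satisfying
// structures exactly.

static const double INF = std::numeric_limits<double>::infinity();

struct FoldDP {
    int n, minloop;
    double rt;
    bool wobble;
    double wobbleStack;
    const IntegerVector &s, &partner;
    const NumericMatrix &stack;
    std::vector<double> Z_, Zno_, Zb_, F_, Fno_, Fb_;
    std::vector<std::pair<int,int> > pairs;

    FoldDP(const IntegerVector &s_, const IntegerVector &partner_,
           const NumericMatrix &stack_, double rt_, int minloop_,
           bool wobble_, double wobbleStack_)
        : n(s_.size()), minloop(minloop_), rt(rt_),
          wobble(wobble_), wobbleStack(wobbleStack_), s(s_),
          partner(partner_), stack(stack_),
          Z_(n * n), Zno_(n * n), Zb_(n * n),
          F_(n * n), Fno_(n * n), Fb_(n * n) {}

    inline int idx(int i, int j) const { return i * n + j; }
    inline double Z(int i, int j) const { return j < i ? 1.0 : Z_[idx(i, j)]; }
    inline double Zno(int i, int j) const { return j < i ? 1.0 : Zno_[idx(i, j)]; }
    inline double Zb(int i, int j) const { return j <= i ? 0.0 : Zb_[idx(i, j)]; }
    inline double F(int i, int j) const { return j < i ? 0.0 : F_[idx(i, j)]; }
    inline double Fno(int i, int j) const { return j < i ? 0.0 : Fno_[idx(i, j)]; }
    inline double Fb(int i, int j) const { return j <= i ? INF : Fb_[idx(i, j)]; }

    inline bool wc(int a, int b) const {
        return (a == 0 && b == 3) || (a == 3 && b == 0) ||
               (a == 1 && b == 2) || (a == 2 && b == 1);
    }
    // G:T wobble (A=0 C=1 G=2 T=3)
    inline bool gt(int a, int b) const {
        return (a == 2 && b == 3) || (a == 3 && b == 2);
    }
    inline bool canPair(int a, int b) const {
        return wc(a, b) || (wobble && gt(a, b));
    }
    inline bool allowed(int i, int j) const {
        if (j - i - 1 < minloop) return false;
        if (!canPair(s[i], s[j])) return false;
        if (partner[i] != -1 && partner[i] != j) return false;
        if (partner[j] != -1 && partner[j] != i) return false;
        return true;
    }
    // energy of the stack formed by pairs (i, j) and (i+1, j-1)
    inline double stk(int i, int j) const {
        if (gt(s[i], s[j]) || gt(s[i + 1], s[j - 1])) return wobbleStack;
        return stack(s[i], s[i + 1]);
    }

    void run() {
        for (int i = 0; i < n; ++i) {
            bool freei = partner[i] == -1;
            Zno_[idx(i, i)] = freei ? 1.0 : 0.0;
            Zb_[idx(i, i)] = 0.0;
            Z_[idx(i, i)] = Zno_[idx(i, i)];
            Fno_[idx(i, i)] = freei ? 0.0 : INF;
            Fb_[idx(i, i)] = INF;
            F_[idx(i, i)] = Fno_[idx(i, i)];
        }
        for (int len = 2; len <= n; ++len) {
            for (int i = 0; i + len - 1 < n; ++i) {
                int j = i + len - 1;
                double zb = 0.0, fb = INF;
                if (allowed(i, j)) {
                    zb = Zno(i + 1, j - 1);
                    double zbin = Zb(i + 1, j - 1);
                    if (zbin > 0.0) zb += zbin * std::exp(-stk(i, j) / rt);
                    fb = Fno(i + 1, j - 1);
                    double fbin = Fb(i + 1, j - 1);
                    double st = stk(i, j);
                    if (fbin < INF && fbin + st < fb) fb = fbin + st;
                }
                Zb_[idx(i, j)] = zb;
                Fb_[idx(i, j)] = fb;

                double zno = (partner[j] == -1) ? Z(i, j - 1) : 0.0;
                double fno = (partner[j] == -1) ? F(i, j - 1) : INF;
                for (int k = i + 1; k < j; ++k) {
                    double zbk = Zb(k, j);
                    if (zbk > 0.0) zno += Z(i, k - 1) * zbk;
                    double fbk = Fb(k, j);
                    if (fbk < INF) {
                        double cand = F(i, k - 1) + fbk;
                        if (cand < fno) fno = cand;
                    }
                }
                Zno_[idx(i, j)] = zno;
                Fno_[idx(i, j)] = fno;
                Z_[idx(i, j)] = zno + zb;
                F_[idx(i, j)] = std::min(fno, fb);
            }
        }
    }

    static const double EPS;

    void traceF(int i, int j) {
        if (j <= i) return;
        if (Fb(i, j) < INF && Fb(i, j) <= Fno(i, j) + EPS) traceB(i, j);
        else traceNo(i, j);
    }
    void traceNo(int i, int j) {
        if (j <= i) return;
        double target = Fno(i, j);
        if (partner[j] == -1 && F(i, j - 1) <= target + EPS) {
            traceF(i, j - 1);
            return;
        }
        for (int k = i + 1; k < j; ++k) {
            double fbk = Fb(k, j);
            if (fbk < INF && F(i, k - 1) + fbk <= target + EPS) {
                traceF(i, k - 1);
                traceB(k, j);
                return;
            }
        }
        Rcpp::stop("internal traceback failure");
    }
    void traceB(int i, int j) {
        pairs.push_back(std::make_pair(i + 1, j + 1));
        int ii = i + 1, jj = j - 1;
        if (jj <= ii) return;
        double fbin = Fb(ii, jj);
        if (fbin < INF && fbin + stk(i, j) <= Fno(ii, jj) + EPS)
            traceB(ii, jj);
        else traceNo(ii, jj);
    }
};

const double FoldDP::EPS = 1e-7;

// [[Rcpp::export(name = ".fold_core")]]
List fold_core(IntegerVector seq, IntegerVector partner, NumericMatrix stack,
               double rt, int minloop, bool wobble, double wobbleStack) {
    int n = seq.size();
    if (n < 1) stop("empty sequence");
    if (n > 300) stop("sequence longer than 300 nt not supported");
    FoldDP dp(seq, partner, stack, rt, minloop, wobble, wobbleStack);
    dp.run();
    double Ztot = dp.Z(0, n - 1);
    double mfe = dp.F(0, n - 1);
    bool empty = !(Ztot > 0.0) || !(mfe < INF);
    IntegerMatrix prs(0, 2);
    double lnZ = R_NegInf;
    if (!empty) {
        lnZ = std::log(Ztot);
        dp.traceF(0, n - 1);
        prs = IntegerMatrix(dp.pairs.size(), 2);
        for (size_t r = 0; r < dp.pairs.size(); ++r) {
            prs(r, 0) = dp.pairs[r].first;
            prs(r, 1) = dp.pairs[r].second;
        }
    }
    return List::create(_["mfe"] = empty ? NA_REAL : mfe,
                        _["lnZ"] = lnZ,
                        _["empty"] = empty,
                        _["pairs"] = prs);
}
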