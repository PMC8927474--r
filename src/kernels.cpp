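#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap alignment kernels shared by the SV-aware DP (one free jump
// between two stitched reference pieces) and the validation realigner.
// Gap of length L costs gap_open + L * gap_extend (penalties are negative).

static const int NEG_INF = -1000000000;

struct SgResult {
  std::vector<int> best; // best[i] = max_j H(i, j), i = 0..n
  std::vector<int> arg;  // argmax j
};

// Semi-global forward pass: query prefix Q[0..i) aligned ending exactly at
// subject offset j, subject start free (H(0, j) = 0 for all j).
// prefer_late: on score ties keep the larger j.
static SgResult sg_forward(const std::string& q, const std::string& s,
                           int match, int mismatch, int gap_open,
                           int gap_extend, bool prefer_late) {
  const int n = (int)q.size(), m = (int)s.size();
  std::vector<int> Hprev(m + 1), H(m + 1), Yprev(m + 1), Y(m + 1);
  SgResult res;
  res.best.assign(n + 1, NEG_INF);
  res.arg.assign(n + 1, 0);
  for (int j = 0; j <= m; ++j) { Hprev[j] = 0; Yprev[j] = NEG_INF; }
  res.best[0] = 0;
  res.arg[0] = prefer_late ? m : 0;
  for (int i = 1; i <= n; ++i) {
    // j = 0: only a query gap is possible
    Y[0] = std::max(Hprev[0] + gap_open + gap_extend, Yprev[0] + gap_extend);
    H[0] = Y[0];
    int X = NEG_INF; // gap consuming subject, within current row
    int rowBest = H[0], rowArg = 0;
    const char qc = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      X = std::max(H[j - 1] + gap_open + gap_extend, X + gap_extend);
      Y[j] = std::max(Hprev[j] + gap_open + gap_extend, Yprev[j] + gap_extend);
      int M = Hprev[j - 1] + (qc == s[j - 1] ? match : mismatch);
      int h = M;
      if (X > h) h = X;
      if (Y[j] > h) h = Y[j];
      H[j] = h;
      if (h > rowBest || (prefer_late && h == rowBest)) { rowBest = h; rowArg = j; }
    }
    res.best[i] = rowBest;
    res.arg[i] = rowArg;
    std::swap(Hprev, H);
    std::swap(Yprev, Y);
  }
  return res;
}

// [[Rcpp::export(name = ".svdp_core")]]
List svdp_core(std::string qwin, std::string ra, std::string rb,
               int match, int mismatch, int gap_open, int gap_extend,
               int jump_cost) {
  const int n = (int)qwin.size();
  if (n == 0 || ra.empty() || rb.empty())
    stop("svdp_align: empty sequence");
  // Forward: prefix vs RA, free start in RA; ties keep the smallest end a.
  SgResult F = sg_forward(qwin, ra, match, mismatch, gap_open, gap_extend, false);
  // Backward: suffix vs RB with free end, via reversed sequences; on ties
  // keep the largest reversed offset, i.e. the smallest start b.
  std::string qr(qwin.rbegin(), qwin.rend());
  std::string rbr(rb.rbegin(), rb.rend());
  SgResult G = sg_forward(qr, rbr, match, mismatch, gap_open, gap_extend, true);
  const int mb = (int)rb.size();

  int bestScore = NEG_INF, bestQ = 0, bestA = 0, bestB = 0;
  for (int i = 0; i <= n; ++i) {
    int sc = F.best[i] + G.best[n - i] + jump_cost;
    if (sc > bestScore) { // ties keep the smallest q'
      bestScore = sc;
      bestQ = i;
      bestA = F.arg[i];
      bestB = mb - G.arg[n - i];
    }
  }
  int noJump = std::max(F.best[n], G.best[n]);
  return List::create(_["score_with_jump"] = bestScore,
                      _["score_without_jump"] = noJump,
                      _["qprime"] = bestQ,
                      _["a"] = bestA,
                      _["b"] = bestB);
}

// Semi-global alignment of a full query against a subject with free subject
// ends; reports score and the subject interval [s_start, s_end) covered.
// [[Rcpp::export(name = ".semiglobal_core")]]
List semiglobal_core(std::string q, std::string s, int match, int mismatch,
                     int gap_open, int gap_extend) {
  if (q.empty() || s.empty()) stop("semiglobal: empty sequence");
  const int n = (int)q.size(), m = (int)s.size();
  SgResult F = sg_forward(q, s, match, mismatch, gap_open, gap_extend, true);
  std::string qr(q.rbegin(), q.rend());
  std::string sr(s.rbegin(), s.rend());
  SgResult R2 = sg_forward(qr, sr, match, mismatch, gap_open, gap_extend, true);
  int score = F.best[n];
  int s_end = F.arg[n];
  int s_start = m - R2.arg[n];
  if (s_start > s_end) s_start = s_end; // degenerate all-gap alignments
  return List::create(_["score"] = score, _["s_start"] = s_start,
                      _["s_end"] = s_end);
}

static inline int base2(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

struct RawMatch { int q, r; uint64_t key; };

// Exact k-mer matches between a read and one reference contig, both strands,
// with reference k-mers occurring more than max_occ times discarded; adjacent
// co-linear matches merged into maximal anchors. Read coordinates are on the
// forward read for both strands.
// [[Rcpp::export(name = ".scan_anchors_core")]]
DataFrame scan_anchors_core(std::string read, std::string ref, int k,
                            int max_occ) {
  const int n = (int)read.size(), m = (int)ref.size();
  DataFrame empty = DataFrame::create(
      _["q_start"] = IntegerVector(0), _["q_end"] = IntegerVector(0),
      _["r_start"] = IntegerVector(0), _["r_end"] = IntegerVector(0),
      _["strand"] = CharacterVector(0));
  if (n < k || m < k) return empty;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  // index read k-mers, forward and reverse-complement orientation
  std::unordered_map<uint64_t, std::vector<int>> fwd, rev;
  uint64_t kf = 0, kr = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2(read[i]);
    if (b < 0) { valid = 0; kf = 0; kr = 0; continue; }
    kf = ((kf << 2) | (uint64_t)b) & mask;
    kr = (kr >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid >= k) {
      int p = i - k + 1;
      fwd[kf].push_back(p);
      rev[kr].push_back(p); // read[p..p+k) == revcomp(ref k-mer kr)
    }
  }

  // scan the reference, counting occurrences of matched k-mers
  std::unordered_map<uint64_t, int> occ;
  std::vector<RawMatch> mf, mr;
  kf = 0; valid = 0;
  for (int j = 0; j < m; ++j) {
    int b = base2(ref[j]);
    if (b < 0) { valid = 0; kf = 0; continue; }
    kf = ((kf << 2) | (uint64_t)b) & mask;
    if (++valid < k) continue;
    int r = j - k + 1;
    bool inF = fwd.count(kf) > 0, inR = rev.count(kf) > 0;
    if (!inF && !inR) continue;
    int& c = occ[kf];
    ++c;
    if (c > max_occ) continue; // keep counting, stop storing
    if (inF) for (int p : fwd[kf]) mf.push_back({p, r, kf});
    if (inR) for (int p : rev[kf]) mr.push_back({p, r, kf});
  }

  std::vector<int> qs, qe, rs, re;
  std::vector<std::string> st;

  // forward strand: merge runs on the same diagonal (r - q)
  auto flushF = [&](int q0, int q1, int r0) {
    qs.push_back(q0); qe.push_back(q1 + k);
    rs.push_back(r0 + (q0 - q0)); re.push_back(r0 + (q1 - q0) + k);
  };
  std::sort(mf.begin(), mf.end(), [](const RawMatch& a, const RawMatch& b) {
    long da = (long)a.r - a.q, db = (long)b.r - b.q;
    if (da != db) return da < db;
    return a.r < b.r;
  });
  for (size_t i = 0; i < mf.size();) {
    if (occ[mf[i].key] > max_occ) { ++i; continue; }
    long diag = (long)mf[i].r - mf[i].q;
    int q0 = mf[i].q, q1 = mf[i].q, r0 = mf[i].r;
    size_t j = i + 1;
    while (j < mf.size() && (long)mf[j].r - mf[j].q == diag) {
      if (occ[mf[j].key] > max_occ) { ++j; continue; }
      if (mf[j].q == q1 + 1) { q1 = mf[j].q; ++j; }
      else if (mf[j].q <= q1) { ++j; }
      else break;
    }
    flushF(q0, q1, r0);
    st.push_back("+");
    i = j;
  }

  // reverse strand: runs on the anti-diagonal (r + q); as r grows q shrinks
  std::sort(mr.begin(), mr.end(), [](const RawMatch& a, const RawMatch& b) {
    long da = (long)a.r + a.q, db = (long)b.r + b.q;
    if (da != db) return da < db;
    return a.r < b.r;
  });
  for (size_t i = 0; i < mr.size();) {
    if (occ[mr[i].key] > max_occ) { ++i; continue; }
    long diag = (long)mr[i].r + mr[i].q;
    int r0 = mr[i].r, r1 = mr[i].r, qhi = mr[i].q;
    size_t j = i + 1;
    while (j < mr.size() && (long)mr[j].r + mr[j].q == diag) {
      if (occ[mr[j].key] > max_occ) { ++j; continue; }
      if (mr[j].r == r1 + 1) { r1 = mr[j].r; ++j; }
      else if (mr[j].r <= r1) { ++j; }
      else break;
    }
    int qlo = qhi - (r1 - r0);
    qs.push_back(qlo); qe.push_back(qhi + k);
    rs.push_back(r0); re.push_back(r1 + k);
    st.push_back("-");
    i = j;
  }

  return DataFrame::create(_["q_start"] = wrap(qs), _["q_end"] = wrap(qe),
                           _["r_start"] = wrap(rs), _["r_end"] = wrap(re),
                           _["strand"] = wrap(st),
                           _["stringsAsFactors"] = false);
}

// Per-interval coverage: sum of aligned reference bases overlapping each
// interval of size L on a contig of length clen.
// [[Rcpp::export(name = ".interval_coverage_core")]]
NumericVector interval_coverage_core(IntegerVector r_start, IntegerVector r_end,
                                     int L, double clen) {
  int n_iv = (int)std::ceil(clen / L);
  if (n_iv < 1) n_iv = 1;
  NumericVector cov(n_iv);
  for (int i = 0; i < r_start.size(); ++i) {
    int a = r_start[i], b = r_end[i];
    if (b > clen) b = (int)clen;
    if (a < 0) a = 0;
    if (a >= b) continue;
    int iv0 = a / L, iv1 = (b - 1) / L;
    for (int iv = iv0; iv <= iv1; ++iv) {
      int lo = std::max(a, iv * L), hi = std::min(b, (iv + 1) * L);
      cov[iv] += hi - lo;
    }
  }
  return cov;
}
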