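#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Semi-global ("overlap") affine-gap alignment with a deterministic
// traceback. Free terminal gaps in both sequences; the aligned core starts
// and ends with a diagonal (match/substitution) column, so terminal-gap
// columns never enter the identity denominator. Tie-breaking on equal score:
// diagonal > gap-in-a (consumes b) > gap-in-b (consumes a), and among equal
// end scores the first cell in scan order (last row left-to-right, then last
// column top-to-bottom) wins. The pure-R oracle in the test suite follows
// the same conventions.

static const double NEG = -1e18;
static const double EPS = 1e-9;

struct AlnResult {
  double score, identity, cov_a, cov_b;
  int ncols, matches;
  bool ok;
  std::vector<int> path_a, path_b; // aligned positions per column, 0 = gap
};

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

// a, b: 0-based integer-encoded sequences; smat: substitution matrix;
// xsym: symbol index never counted as a match (-1 to disable);
// band: if >= 0, only cells with |(i - j) - d0| <= band are computed.
static AlnResult align_core(const std::vector<int>& a, const std::vector<int>& b,
                            const IntegerMatrix& smat, int xsym,
                            double gap_open, double gap_ext,
                            int band, int d0) {
  const int n = (int)a.size(), m = (int)b.size();
  AlnResult res; res.ok = false;
  if (n == 0 || m == 0) return res;
  const int W = m + 1;
  std::vector<double> M((size_t)(n + 1) * W, NEG), X(M), Y(M);
  const double go = gap_open + gap_ext, ge = gap_ext;

  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (band >= 0) {
      jlo = std::max(1, i - d0 - band);
      jhi = std::min(m, i - d0 + band);
      if (jlo > jhi) continue;
    }
    for (int j = jlo; j <= jhi; ++j) {
      const size_t ij = (size_t)i * W + j;
      const size_t up = ij - W, lf = ij - 1, dg = ij - W - 1;
      double s = smat(a[i - 1], b[j - 1]);
      double best_prev = max3(M[dg], X[dg], Y[dg]);
      if ((i == 1 || j == 1) && best_prev < 0.0) best_prev = 0.0;
      M[ij] = s + best_prev;
      X[ij] = max3(M[lf] - go, X[lf] - ge, Y[lf] - go);
      Y[ij] = max3(M[up] - go, Y[up] - ge, X[up] - go);
    }
  }

  // End cell: best M over last row then last column.
  double best = NEG; int ie = -1, je = -1;
  for (int j = 1; j <= m; ++j) {
    double v = M[(size_t)n * W + j];
    if (v > best + EPS) { best = v; ie = n; je = j; }
  }
  for (int i = 1; i <= n; ++i) {
    double v = M[(size_t)i * W + m];
    if (v > best + EPS) { best = v; ie = i; je = m; }
  }
  if (ie < 0) return res;

  // Traceback.
  int i = ie, j = je, state = 0; // 0 = M, 1 = X (gap in a), 2 = Y (gap in b)
  int ncols = 0, matches = 0, is = ie, js = je;
  while (true) {
    const size_t ij = (size_t)i * W + j;
    if (state == 0) {
      ++ncols;
      res.path_a.push_back(i); res.path_b.push_back(j);
      if (a[i - 1] == b[j - 1] && a[i - 1] != xsym) ++matches;
      is = i; js = j;
      double prev = M[ij] - smat(a[i - 1], b[j - 1]);
      const size_t dg = ij - W - 1;
      if (i > 1 && j > 1 && std::abs(M[dg] - prev) < EPS) { --i; --j; state = 0; }
      else if (i > 1 && j > 1 && std::abs(X[dg] - prev) < EPS) { --i; --j; state = 1; }
      else if (i > 1 && j > 1 && std::abs(Y[dg] - prev) < EPS) { --i; --j; state = 2; }
      else if ((i == 1 || j == 1) && std::abs(prev) < EPS) break;
      else if (i > 1 && j > 1 && std::abs(prev) < EPS) break; // banded edge start
      else stop("alignment traceback failed");
    } else if (state == 1) { // gap in a, consumes b[j]
      ++ncols;
      res.path_a.push_back(0); res.path_b.push_back(j);
      double cur = X[ij];
      const size_t lf = ij - 1;
      if (std::abs(M[lf] - go - cur) < EPS) { --j; state = 0; }
      else if (std::abs(X[lf] - ge - cur) < EPS) { --j; state = 1; }
      else if (std::abs(Y[lf] - go - cur) < EPS) { --j; state = 2; }
      else stop("alignment traceback failed (X)");
    } else { // gap in b, consumes a[i]
      ++ncols;
      res.path_a.push_back(i); res.path_b.push_back(0);
      double cur = Y[ij];
      const size_t up = ij - W;
      if (std::abs(M[up] - go - cur) < EPS) { --i; state = 0; }
      else if (std::abs(Y[up] - ge - cur) < EPS) { --i; state = 2; }
      else if (std::abs(X[up] - go - cur) < EPS) { --i; state = 1; }
      else stop("alignment traceback failed (Y)");
    }
  }

  std::reverse(res.path_a.begin(), res.path_a.end());
  std::reverse(res.path_b.begin(), res.path_b.end());
  res.score = best;
  res.ncols = ncols;
  res.matches = matches;
  res.identity = ncols > 0 ? (double)matches / ncols : 0.0;
  res.cov_a = (double)(ie - is + 1) / n;
  res.cov_b = (double)(je - js + 1) / m;
  res.ok = true;
  return res;
}

// Band-compressed variant of align_core: only cells with
// |(i - j) - d0| <= band are stored (row-shifted storage, width 2*band+1),
// same recurrences, tie-breaking and identity conventions.
static AlnResult align_core_banded(const std::vector<int>& a,
                                   const std::vector<int>& b,
                                   const IntegerMatrix& smat, int xsym,
                                   double gap_open, double gap_ext,
                                   int band, int d0) {
  const int n = (int)a.size(), m = (int)b.size();
  AlnResult res; res.ok = false;
  if (n == 0 || m == 0) return res;
  const int width = 2 * band + 1;
  std::vector<double> M((size_t)(n + 1) * width, NEG), X(M), Y(M);
  const double go = gap_open + gap_ext, ge = gap_ext;
  auto at = [&](std::vector<double>& A, int i, int j) -> double {
    if (i < 0 || j < 0 || i > n || j > m) return NEG;
    int kk = j - (i - d0) + band;
    if (kk < 0 || kk >= width) return NEG;
    return A[(size_t)i * width + kk];
  };
  auto put = [&](std::vector<double>& A, int i, int j, double v) {
    int kk = j - (i - d0) + band;
    A[(size_t)i * width + kk] = v;
  };
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i - d0 - band);
    int jhi = std::min(m, i - d0 + band);
    for (int j = jlo; j <= jhi; ++j) {
      double s = smat(a[i - 1], b[j - 1]);
      double best_prev = max3(at(M, i - 1, j - 1), at(X, i - 1, j - 1),
                              at(Y, i - 1, j - 1));
      if ((i == 1 || j == 1) && best_prev < 0.0) best_prev = 0.0;
      put(M, i, j, s + best_prev);
      put(X, i, j, max3(at(M, i, j - 1) - go, at(X, i, j - 1) - ge,
                        at(Y, i, j - 1) - go));
      put(Y, i, j, max3(at(M, i - 1, j) - go, at(Y, i - 1, j) - ge,
                        at(X, i - 1, j) - go));
    }
  }
  double best = NEG; int ie = -1, je = -1;
  for (int j = 1; j <= m; ++j) {
    double v = at(M, n, j);
    if (v > best + EPS) { best = v; ie = n; je = j; }
  }
  for (int i = 1; i <= n; ++i) {
    double v = at(M, i, m);
    if (v > best + EPS) { best = v; ie = i; je = m; }
  }
  if (ie < 0) return res;
  int i = ie, j = je, state = 0;
  int ncols = 0, matches = 0, is = ie, js = je;
  while (true) {
    if (state == 0) {
      ++ncols;
      res.path_a.push_back(i); res.path_b.push_back(j);
      if (a[i - 1] == b[j - 1] && a[i - 1] != xsym) ++matches;
      is = i; js = j;
      double prev = at(M, i, j) - smat(a[i - 1], b[j - 1]);
      if (i > 1 && j > 1 && std::abs(at(M, i - 1, j - 1) - prev) < EPS) {
        --i; --j; state = 0;
      } else if (i > 1 && j > 1 &&
                 std::abs(at(X, i - 1, j - 1) - prev) < EPS) {
        --i; --j; state = 1;
      } else if (i > 1 && j > 1 &&
                 std::abs(at(Y, i - 1, j - 1) - prev) < EPS) {
        --i; --j; state = 2;
      } else if (std::abs(prev) < EPS) break;
      else stop("banded traceback failed");
    } else if (state == 1) {
      ++ncols;
      res.path_a.push_back(0); res.path_b.push_back(j);
      double cur = at(X, i, j);
      if (std::abs(at(M, i, j - 1) - go - cur) < EPS) { --j; state = 0; }
      else if (std::abs(at(X, i, j - 1) - ge - cur) < EPS) { --j; state = 1; }
      else if (std::abs(at(Y, i, j - 1) - go - cur) < EPS) { --j; state = 2; }
      else stop("banded traceback failed (X)");
    } else {
      ++ncols;
      res.path_a.push_back(i); res.path_b.push_back(0);
      double cur = at(Y, i, j);
      if (std::abs(at(M, i - 1, j) - go - cur) < EPS) { --i; state = 0; }
      else if (std::abs(at(Y, i - 1, j) - ge - cur) < EPS) { --i; state = 2; }
      else if (std::abs(at(X, i - 1, j) - go - cur) < EPS) { --i; state = 1; }
      else stop("banded traceback failed (Y)");
    }
  }
  std::reverse(res.path_a.begin(), res.path_a.end());
  std::reverse(res.path_b.begin(), res.path_b.end());
  res.score = best;
  res.ncols = ncols;
  res.matches = matches;
  res.identity = ncols > 0 ? (double)matches / ncols : 0.0;
  res.cov_a = (double)(ie - is + 1) / n;
  res.cov_b = (double)(je - js + 1) / m;
  res.ok = true;
  return res;
}

static std::vector<int> encode_seq(const std::string& s, const int* lut,
                                   const std::string& context) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = lut[(unsigned char)s[i]];
    if (c < 0)
      stop("illegal character '%c' in %s sequence", s[i], context.c_str());
    v[i] = c;
  }
  return v;
}

// [[Rcpp::export]]
NumericMatrix cpp_align_batch(CharacterVector seqs, IntegerVector ia,
                              IntegerVector ib, IntegerMatrix smat,
                              std::string alphabet, double gap_open,
                              double gap_ext, int xsym, int band, int d0) {
  int lut[256];
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    lut[(unsigned char)alphabet[i]] = (int)i;

  const int ns = seqs.size();
  std::vector<std::vector<int>> enc(ns);
  std::vector<bool> done(ns, false);
  const int P = ia.size();
  NumericMatrix out(P, 6);
  colnames(out) = CharacterVector::create("score", "identity", "coverage_a",
                                          "coverage_b", "ncols", "matches");
  for (int p = 0; p < P; ++p) {
    int u = ia[p] - 1, v = ib[p] - 1;
    if (u < 0 || u >= ns || v < 0 || v >= ns) stop("pair index out of range");
    for (int w : {u, v}) {
      if (!done[w]) {
        enc[w] = encode_seq(std::string(seqs[w]), lut, "input");
        if (enc[w].empty()) stop("empty sequence at index %d", w + 1);
        done[w] = true;
      }
    }
    AlnResult r = align_core(enc[u], enc[v], smat, xsym, gap_open, gap_ext,
                             band, d0);
    if (!r.ok) stop("alignment failed for pair %d", p + 1);
    out(p, 0) = r.score; out(p, 1) = r.identity;
    out(p, 2) = r.cov_a; out(p, 3) = r.cov_b;
    out(p, 4) = r.ncols; out(p, 5) = r.matches;
  }
  return out;
}

// Single-pair alignment returning the aligned-column path (1-based
// positions; 0 marks a gap in that sequence).
// [[Rcpp::export]]
List cpp_align_path(std::string a, std::string b, IntegerMatrix smat,
                    std::string alphabet, double gap_open, double gap_ext,
                    int xsym) {
  int lut[256];
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    lut[(unsigned char)alphabet[i]] = (int)i;
  std::vector<int> ea = encode_seq(a, lut, "input");
  std::vector<int> eb = encode_seq(b, lut, "input");
  if (ea.empty() || eb.empty()) stop("empty sequence");
  AlnResult r = align_core(ea, eb, smat, xsym, gap_open, gap_ext, -1, 0);
  if (!r.ok) stop("alignment failed");
  return List::create(_["score"] = r.score, _["identity"] = r.identity,
                      _["coverage_a"] = r.cov_a, _["coverage_b"] = r.cov_b,
                      _["a_pos"] = IntegerVector(r.path_a.begin(),
                                                 r.path_a.end()),
                      _["b_pos"] = IntegerVector(r.path_b.begin(),
                                                 r.path_b.end()));
}

// Candidate homolog pairs by shared k-mer counting (k-mers deduplicated per
// sequence; k-mers present in more than max_bucket sequences are skipped).
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_candidates(CharacterVector seqs, int k, int min_shared,
                                  int max_bucket) {
  const int ns = seqs.size();
  std::unordered_map<uint32_t, std::vector<int>> index;
  index.reserve(1 << 20);
  for (int s = 0; s < ns; ++s) {
    std::string str = as<std::string>(seqs[s]);
    if ((int)str.size() < k) continue;
    std::vector<uint32_t> codes;
    codes.reserve(str.size());
    for (size_t i = 0; i + k <= str.size(); ++i) {
      uint32_t code = 0;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        int c = str[i + j] - 'A';
        if (c < 0 || c > 25) { ok = false; break; }
        code = code * 26u + (uint32_t)c;
      }
      if (ok) codes.push_back(code);
    }
    std::sort(codes.begin(), codes.end());
    codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
    for (uint32_t c : codes) {
      auto& bucket = index[c];
      if ((int)bucket.size() <= max_bucket) bucket.push_back(s);
    }
  }
  std::unordered_map<uint64_t, int> counts;
  counts.reserve(1 << 20);
  for (auto& kv : index) {
    const std::vector<int>& b = kv.second;
    if ((int)b.size() < 2 || (int)b.size() > max_bucket) continue;
    for (size_t i = 0; i < b.size(); ++i)
      for (size_t j = i + 1; j < b.size(); ++j)
        ++counts[(uint64_t)b[i] * (uint64_t)ns + (uint64_t)b[j]];
  }
  std::vector<std::pair<int, int>> pairs;
  for (auto& kv : counts) {
    if (kv.second >= min_shared) {
      int i = (int)(kv.first / ns), j = (int)(kv.first % ns);
      pairs.push_back({i + 1, j + 1});
    }
  }
  std::sort(pairs.begin(), pairs.end());
  IntegerMatrix out((int)pairs.size(), 2);
  for (size_t p = 0; p < pairs.size(); ++p) {
    out(p, 0) = pairs[p].first;
    out(p, 1) = pairs[p].second;
  }
  return out;
}


// ---- seeded-fragment ANI ------------------------------------------------
//
// The query chromosome is chopped into non-overlapping fragments; each
// fragment's best window in the target is located by exact k-mer (default
// 15) diagonal voting, strand-aware (the better-supported of the forward
// and reverse-complement orientation wins). Only the contiguous seeded
// span of the fragment is aligned (banded semi-global), so fragments
// straddling rearrangement breakpoints contribute their homologous part
// at reduced coverage rather than a mixed identity. Seeds are sampled
// every `stride` positions for speed.

typedef std::unordered_map<uint64_t, std::vector<int>> NtIndex;

static int nt_lut_[256];
static void init_nt_lut() {
  for (int i = 0; i < 256; ++i) nt_lut_[i] = -1;
  nt_lut_['A'] = 0; nt_lut_['C'] = 1; nt_lut_['G'] = 2; nt_lut_['T'] = 3;
}

static void build_nt_index(const std::string& t, int kmer, int max_hits,
                           NtIndex& index) {
  const uint64_t mask = (kmer >= 32) ? ~0ULL : ((1ULL << (2 * kmer)) - 1);
  index.clear();
  index.reserve(t.size());
  uint64_t code = 0; int run = 0;
  for (int i = 0; i < (int)t.size(); ++i) {
    int c = nt_lut_[(unsigned char)t[i]];
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (++run >= kmer) {
      auto& v = index[code];
      if ((int)v.size() < max_hits) v.push_back(i - kmer + 1);
    }
  }
}

static std::string rc_nt(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r)
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: break;
    }
  return r;
}

struct Seeding {
  int best_diag = 0, best_count = 0, support = 0;
  int qlo = 0, qhi = 0;
};

static Seeding seed_orientation(const std::string& frag, const NtIndex& index,
                                int kmer, int stride) {
  Seeding sd;
  const int fl = (int)frag.size();
  const uint64_t mask = (kmer >= 32) ? ~0ULL : ((1ULL << (2 * kmer)) - 1);
  std::vector<std::pair<int, int>> hits; // (diag, qpos)
  uint64_t code = 0; int run = 0;
  for (int p = 0; p < fl; ++p) {
    int c = nt_lut_[(unsigned char)frag[p]];
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (run++ < kmer - 1) continue;
    int qpos = p - kmer + 1;
    if (qpos % stride != 0) continue;
    auto it = index.find(code);
    if (it == index.end()) continue;
    for (int tpos : it->second) hits.push_back({tpos - qpos, qpos});
  }
  if (hits.empty()) return sd;
  std::unordered_map<int, int> diag_votes;
  for (auto& h : hits) ++diag_votes[h.first];
  for (auto& kv : diag_votes)
    if (kv.second > sd.best_count ||
        (kv.second == sd.best_count && kv.first < sd.best_diag)) {
      sd.best_diag = kv.first; sd.best_count = kv.second;
    }
  sd.qlo = fl; sd.qhi = 0;
  for (auto& h : hits) {
    if (h.first >= sd.best_diag - 4 && h.first <= sd.best_diag + 4) {
      ++sd.support;
      if (h.second < sd.qlo) sd.qlo = h.second;
      if (h.second + kmer > sd.qhi) sd.qhi = h.second + kmer;
    }
  }
  return sd;
}

// Align one fragment (already oriented) over its seeded span; returns
// identity (NA-signalled by ok=false) and coverage of the full fragment.
static bool align_fragment(const std::string& frag, const std::string& target,
                           const Seeding& sd, int kmer, int band,
                           const IntegerMatrix& smat, double gap_open,
                           double gap_ext, double& identity,
                           double& coverage) {
  const int tl = (int)target.size();
  const int frag_len = (int)frag.size();
  if (sd.qhi <= sd.qlo) return false;
  const int alen = sd.qhi - sd.qlo;
  int w0 = std::max(0, sd.best_diag + sd.qlo - band);
  int w1 = std::min(tl, sd.best_diag + sd.qhi + band);
  if (w1 - w0 < kmer) return false;
  std::vector<int> a(alen), b(w1 - w0);
  for (int p = 0; p < alen; ++p) {
    int c = nt_lut_[(unsigned char)frag[sd.qlo + p]];
    a[p] = c < 0 ? 0 : c;
  }
  for (int p = 0; p < w1 - w0; ++p) {
    int c = nt_lut_[(unsigned char)target[w0 + p]];
    if (c < 0) c = (a[std::min(p, alen - 1)] + 1) % 4; // N never matches
    b[p] = c;
  }
  const int d0 = -(sd.best_diag + sd.qlo - w0);
  AlnResult r = align_core_banded(a, b, smat, -1, gap_open, gap_ext, band,
                                  d0);
  if (!r.ok) return false;
  identity = r.identity;
  coverage = r.cov_a * (double)alen / frag_len;
  return true;
}

static IntegerMatrix nt_smat(double match_score, double mismatch_score) {
  IntegerMatrix smat(4, 4);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j)
      smat(i, j) = (i == j) ? (int)match_score : (int)mismatch_score;
  return smat;
}

// Per-fragment detail for one query-vs-target direction.
// [[Rcpp::export]]
NumericMatrix cpp_ani_fragments(std::string query, std::string target,
                                int frag_len, int kmer, int band,
                                int min_votes, int stride,
                                double match_score, double mismatch_score,
                                double gap_open, double gap_ext,
                                int max_kmer_hits) {
  init_nt_lut();
  NtIndex index;
  build_nt_index(target, kmer, max_kmer_hits, index);
  IntegerMatrix smat = nt_smat(match_score, mismatch_score);
  const int nfrag = (int)query.size() / frag_len;
  NumericMatrix out(nfrag, 3);
  colnames(out) = CharacterVector::create("identity", "coverage", "support");
  for (int f = 0; f < nfrag; ++f) {
    std::string fwd = query.substr((size_t)f * frag_len, frag_len);
    std::string rev = rc_nt(fwd);
    Seeding sf = seed_orientation(fwd, index, kmer, stride);
    Seeding sr = seed_orientation(rev, index, kmer, stride);
    bool use_rev = sr.support > sf.support;
    const Seeding& sd = use_rev ? sr : sf;
    const std::string& frag = use_rev ? rev : fwd;
    out(f, 2) = sd.support;
    double id = 0, cov = 0;
    if (sd.best_count == 0 || sd.support < min_votes ||
        !align_fragment(frag, target, sd, kmer, band, smat, gap_open,
                        gap_ext, id, cov)) {
      out(f, 0) = NA_REAL; out(f, 1) = 0.0;
      continue;
    }
    out(f, 0) = id;
    out(f, 1) = cov;
  }
  return out;
}

// All queries against one target (index built once): per-query mean
// identity over qualifying fragments and the qualifying count.
// [[Rcpp::export]]
NumericMatrix cpp_ani_rows(CharacterVector queries, std::string target,
                           int frag_len, int kmer, int band, int min_votes,
                           int stride, double match_score,
                           double mismatch_score, double gap_open,
                           double gap_ext, int max_kmer_hits,
                           double min_identity, double min_coverage) {
  init_nt_lut();
  NtIndex index;
  build_nt_index(target, kmer, max_kmer_hits, index);
  IntegerMatrix smat = nt_smat(match_score, mismatch_score);
  const int nq = queries.size();
  NumericMatrix out(nq, 3);
  colnames(out) = CharacterVector::create("mean_identity", "n_qualified",
                                          "n_fragments");
  for (int qi = 0; qi < nq; ++qi) {
    std::string query = as<std::string>(queries[qi]);
    const int nfrag = (int)query.size() / frag_len;
    double sum_id = 0; int n_qual = 0;
    for (int f = 0; f < nfrag; ++f) {
      std::string fwd = query.substr((size_t)f * frag_len, frag_len);
      std::string rev = rc_nt(fwd);
      Seeding sf = seed_orientation(fwd, index, kmer, stride);
      Seeding sr = seed_orientation(rev, index, kmer, stride);
      bool use_rev = sr.support > sf.support;
      const Seeding& sd = use_rev ? sr : sf;
      const std::string& frag = use_rev ? rev : fwd;
      if (sd.best_count == 0 || sd.support < min_votes) continue;
      double id = 0, cov = 0;
      if (!align_fragment(frag, target, sd, kmer, band, smat, gap_open,
                          gap_ext, id, cov))
        continue;
      if (id >= min_identity && cov >= min_coverage) {
        sum_id += id;
        ++n_qual;
      }
    }
    out(qi, 0) = n_qual > 0 ? sum_id / n_qual : NA_REAL;
    out(qi, 1) = n_qual;
    out(qi, 2) = nfrag;
  }
  return out;
}

// Candidate query-target pairs by shared k-mer counting: only
// query-vs-target co-occurrences are counted (no target-target work).
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_query_candidates(CharacterVector queries,
                                        CharacterVector targets, int k,
                                        int min_shared, int max_bucket) {
  const int nt = targets.size();
  std::unordered_map<uint32_t, std::vector<int>> index;
  index.reserve(1 << 18);
  auto codes_of = [&](const std::string& str) {
    std::vector<uint32_t> codes;
    if ((int)str.size() >= k) {
      codes.reserve(str.size());
      for (size_t i = 0; i + k <= str.size(); ++i) {
        uint32_t code = 0;
        bool ok = true;
        for (int j = 0; j < k; ++j) {
          int c = str[i + j] - 'A';
          if (c < 0 || c > 25) { ok = false; break; }
          code = code * 26u + (uint32_t)c;
        }
        if (ok) codes.push_back(code);
      }
      std::sort(codes.begin(), codes.end());
      codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
    }
    return codes;
  };
  for (int t = 0; t < nt; ++t) {
    for (uint32_t c : codes_of(as<std::string>(targets[t]))) {
      auto& bucket = index[c];
      if ((int)bucket.size() <= max_bucket) bucket.push_back(t);
    }
  }
  std::vector<std::pair<int, int>> pairs;
  std::vector<int> counts(nt);
  for (int q = 0; q < queries.size(); ++q) {
    std::fill(counts.begin(), counts.end(), 0);
    for (uint32_t c : codes_of(as<std::string>(queries[q]))) {
      auto it = index.find(c);
      if (it == index.end() || (int)it->second.size() > max_bucket)
        continue;
      for (int t : it->second) ++counts[t];
    }
    for (int t = 0; t < nt; ++t)
      if (counts[t] >= min_shared) pairs.push_back({q + 1, t + 1});
  }
  IntegerMatrix out((int)pairs.size(), 2);
  for (size_t p = 0; p < pairs.size(); ++p) {
    out(p, 0) = pairs[p].first;
    out(p, 1) = pairs[p].second;
  }
  return out;
}
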