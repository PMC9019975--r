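#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Column maxima of a CSC sparse matrix (implicit zeros count).
// [[Rcpp::export]]
NumericVector cpp_col_max(IntegerVector p, NumericVector x, int ncol) {
  NumericVector out(ncol);
  for (int j = 0; j < ncol; ++j) {
    double m = 0.0;
    for (int k = p[j]; k < p[j + 1]; ++k) m = std::max(m, x[k]);
    out[j] = m;
  }
  return out;
}

// Per-column count of entries >= threshold.
// [[Rcpp::export]]
IntegerVector cpp_col_n_at_least(IntegerVector p, NumericVector x, int ncol,
                                 double at_least) {
  IntegerVector out(ncol);
  for (int j = 0; j < ncol; ++j) {
    int c = 0;
    for (int k = p[j]; k < p[j + 1]; ++k)
      if (x[k] >= at_least) ++c;
    out[j] = c;
  }
  return out;
}

// Multivariate hypergeometric downsampling of each column of a CSC matrix
// (columns are cells) to exactly `target` total counts; columns whose total
// is <= target are returned unchanged. Sampling is without replacement over
// the column's molecules, driven by R's RNG (caller set.seed()s).
// [[Rcpp::export]]
NumericVector cpp_downsample_csc(IntegerVector p, NumericVector x,
                                 double target) {
  int ncol = p.size() - 1;
  NumericVector out(x.size());
  for (int j = 0; j < ncol; ++j) {
    double tot = 0.0;
    for (int k = p[j]; k < p[j + 1]; ++k) tot += x[k];
    if (tot <= target) {
      for (int k = p[j]; k < p[j + 1]; ++k) out[k] = x[k];
      continue;
    }
    double remaining = tot, want = target;
    for (int k = p[j]; k < p[j + 1]; ++k) {
      double xk = x[k];
      double draw;
      if (want <= 0) {
        draw = 0;
      } else if (remaining - xk <= 0) {
        draw = want;
      } else {
        draw = R::rhyper(xk, remaining - xk, want);
      }
      out[k] = draw;
      want -= draw;
      remaining -= xk;
    }
  }
  return out;
}

// Balanced K-nn graph construction from a dense cell-cell similarity matrix.
//
// Steps: (1) per-row outgoing ranks, the most similar neighbour getting the
// highest value (n - position, self excluded); (2) symmetric balanced rank
// B = sqrt(R * R^T) elementwise; (3) keep only each cell's top `m_keep`
// balanced candidates; (4) cap incoming edges at `in_cap` per cell;
// (5) cap outgoing edges at `out_cap` per cell. Weights are B scaled to
// (0, 1]. `S` is overwritten internally (caller passes a scratch copy).
// Ties are broken toward the lower cell index for determinism.
// [[Rcpp::export]]
List cpp_balanced_knn(NumericMatrix S, int m_keep, int in_cap, int out_cap) {
  int n = S.nrow();
  if (n >= (1 << 20)) stop("pile too large for the dense graph builder");
  // ranks: per row, pack (similarity, index) into one sortable 64-bit key —
  // top 44 bits an order-preserving encoding of the similarity (descending),
  // low 20 bits the column index (ascending tie-break; ties below ~1e-10
  // relative similarity difference also break by index)
  std::vector<uint64_t> keys(n);
  // ranks overwrite S row by row: ranking row i only reads row i, so the
  // caller's scratch similarity matrix doubles as the rank matrix
  NumericMatrix R_ = S;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double d = S(i, j);
      uint64_t b;
      std::memcpy(&b, &d, 8);
      b = (b & 0x8000000000000000ULL) ? ~b : (b | 0x8000000000000000ULL);
      keys[j] = (((~b) >> 20) << 20) | (uint64_t)j;
    }
    std::sort(keys.begin(), keys.end());
    int pos = 0;
    double* Ri = &R_(i, 0);  // column-major: stride n — write via offset
    for (int k = 0; k < n; ++k) {
      int j = (int)(keys[k] & 0xFFFFFULL);
      if (j == i) continue;
      ++pos;  // 1 = most similar
      Ri[(R_xlen_t)j * n] = double(n - pos);
    }
  }
  // balanced: geometric mean with the transposed element (in place, upper
  // triangle drives both).
  double* P = R_.begin();
  for (int j = 0; j < n; ++j) {
    P[(R_xlen_t)j * n + j] = 0.0;
    for (int i = 0; i < j; ++i) {
      R_xlen_t ij = (R_xlen_t)j * n + i, ji = (R_xlen_t)i * n + j;
      double b = std::sqrt(P[ij] * P[ji]);
      P[ij] = b;
      P[ji] = b;
    }
  }
  // per-cell pre-prune: top m_keep balanced candidates per row; the row's
  // m_keep-th largest is found with nth_element on a value copy, then only
  // the survivors are sorted.
  std::vector<int> src, dst;
  std::vector<double> wts;
  std::vector<double> vals(n);
  std::vector<std::pair<double, int>> cand;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) vals[j] = P[(R_xlen_t)j * n + i];
    double thresh = 0.0;
    if (n > m_keep + 1) {
      std::vector<double> tmp(vals);
      std::nth_element(tmp.begin(), tmp.begin() + m_keep, tmp.end(),
                       std::greater<double>());
      thresh = tmp[m_keep];
    }
    cand.clear();
    for (int j = 0; j < n; ++j)
      if (j != i && vals[j] > 0 && vals[j] >= thresh)
        cand.push_back({vals[j], j});
    int keep = std::min<int>(m_keep, cand.size());
    std::partial_sort(cand.begin(), cand.begin() + keep, cand.end(),
                      [](const std::pair<double, int>& a,
                         const std::pair<double, int>& b) {
                        if (a.first != b.first) return a.first > b.first;
                        return a.second < b.second;
                      });
    for (int k = 0; k < keep; ++k) {
      src.push_back(i);
      dst.push_back(cand[k].second);
      wts.push_back(cand[k].first);
    }
  }
  // incoming cap: per target keep in_cap strongest
  int ne = src.size();
  std::vector<std::vector<int>> by_tgt(n);
  for (int e = 0; e < ne; ++e) by_tgt[dst[e]].push_back(e);
  std::vector<char> alive(ne, 1);
  for (int j = 0; j < n; ++j) {
    auto& es = by_tgt[j];
    if ((int)es.size() <= in_cap) continue;
    std::sort(es.begin(), es.end(), [&](int a, int b) {
      if (wts[a] != wts[b]) return wts[a] > wts[b];
      return src[a] < src[b];
    });
    for (size_t k = in_cap; k < es.size(); ++k) alive[es[k]] = 0;
  }
  // outgoing cap: per source keep out_cap strongest of the survivors
  std::vector<std::vector<int>> by_src(n);
  for (int e = 0; e < ne; ++e)
    if (alive[e]) by_src[src[e]].push_back(e);
  for (int i = 0; i < n; ++i) {
    auto& es = by_src[i];
    if ((int)es.size() <= out_cap) continue;
    std::sort(es.begin(), es.end(), [&](int a, int b) {
      if (wts[a] != wts[b]) return wts[a] > wts[b];
      return dst[a] < dst[b];
    });
    for (size_t k = out_cap; k < es.size(); ++k) alive[es[k]] = 0;
  }
  double wmax = 0.0;
  for (int e = 0; e < ne; ++e)
    if (alive[e]) wmax = std::max(wmax, wts[e]);
  if (wmax <= 0) wmax = 1.0;
  std::vector<int> oi, oj;
  std::vector<double> ow;
  for (int e = 0; e < ne; ++e) {
    if (!alive[e]) continue;
    oi.push_back(src[e] + 1);
    oj.push_back(dst[e] + 1);
    ow.push_back(wts[e] / wmax);
  }
  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj), _["w"] = wrap(ow));
}

// Fold factors on the sparse pattern: for nonzero entry (cell, gene) of the
// cells-in-columns CSC matrix, (x + 1) / (expected + 1) where expected =
// profile[gene, mc(cell)] * cell_total. profile columns are per-metacell
// pooled gene fractions. Cells of singleton metacells get fold 1.
// [[Rcpp::export]]
NumericVector cpp_fold_factors(IntegerVector p, IntegerVector i,
                               NumericVector x, NumericVector cell_tot,
                               IntegerVector mc, NumericMatrix profile,
                               IntegerVector mc_ncells) {
  int ncell = p.size() - 1;
  NumericVector out(x.size());
  for (int c = 0; c < ncell; ++c) {
    int m = mc[c];
    for (int k = p[c]; k < p[c + 1]; ++k) {
      if (m <= 0 || mc_ncells[m - 1] < 2) {
        out[k] = 1.0;
        continue;
      }
      double expected = profile(i[k], m - 1) * cell_tot[c];
      out[k] = (x[k] + 1.0) / (expected + 1.0);
    }
  }
  return out;
}

// Multinomial counts for many cells sharing one profile: sequential
// conditional-binomial over genes, inner loop over cells, skipping cells
// whose depth is exhausted. Returns triplets (i, j, x), 1-based. Driven by
// R's RNG (caller set.seed()s).
// [[Rcpp::export]]
List cpp_multinomial_counts(IntegerVector depths, NumericVector prob) {
  int n = depths.size();
  int G = prob.size();
  double psum = 0.0;
  for (int g = 0; g < G; ++g) psum += prob[g];
  std::vector<double> remaining_p(G);
  {
    double tail = 0.0;
    for (int g = G - 1; g >= 0; --g) {
      tail += prob[g] / psum;
      remaining_p[g] = tail;
    }
  }
  std::vector<int> remaining(depths.begin(), depths.end());
  std::vector<int> is, js, xs;
  is.reserve(1 << 20);
  js.reserve(1 << 20);
  xs.reserve(1 << 20);
  for (int g = 0; g < G; ++g) {
    double pg = prob[g] / psum;
    if (pg <= 0) continue;
    double p = pg / remaining_p[g];
    if (p > 1) p = 1;
    if (p >= 1) {
      for (int c = 0; c < n; ++c) {
        if (remaining[c] > 0) {
          is.push_back(c + 1);
          js.push_back(g + 1);
          xs.push_back(remaining[c]);
          remaining[c] = 0;
        }
      }
      continue;
    }
    for (int c = 0; c < n; ++c) {
      int rc = remaining[c];
      if (rc == 0) continue;
      int x = (int)R::rbinom((double)rc, p);
      if (x > 0) {
        is.push_back(c + 1);
        js.push_back(g + 1);
        xs.push_back(x);
        remaining[c] = rc - x;
      }
    }
  }
  return List::create(_["i"] = wrap(is), _["j"] = wrap(js),
                      _["x"] = wrap(xs));
}
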