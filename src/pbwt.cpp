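// Positional Burrows-Wheeler transform kernels.
//
// Conventions: haplotype/genotype matrices are stored with rows = sequences
// and columns = sites, so a column (one site across all sequences) is
// contiguous in memory. All indices crossing the R boundary are 0-based and
// converted by the R wrappers.
//
// Array semantics after processing site l (inclusive):
//   A[r]  rank -> haplotype index, sorted by reversed prefix over [0, l]
//   D[r]  start of the match between ranks r and r-1: the two haplotypes
//         agree on [D[r], l]; D[r] == l+1 means no match; D[0] == l+1.
//   I[h]  haplotype index -> rank (inverse of A).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Durbin's algorithm 2: one O(LN) sweep, arrays kept at the requested sites.
// [[Rcpp::export]]
List cpp_pbwt_build(const IntegerMatrix& H, const IntegerVector& store_sites) {
  const int M = H.nrow(), L = H.ncol(), ns = store_sites.size();
  IntegerMatrix A(M, ns), D(M, ns), I(M, ns);
  std::vector<int> a(M), d(M, 0), a0(M), a1(M), d0(M), d1(M);
  for (int h = 0; h < M; ++h) a[h] = h;
  int si = 0;
  for (int l = 0; l < L; ++l) {
    int n0 = 0, n1 = 0, p = l + 1, q = l + 1;
    const int* col = &H(0, l);
    for (int r = 0; r < M; ++r) {
      if (d[r] > p) p = d[r];
      if (d[r] > q) q = d[r];
      const int hap = a[r], y = col[hap];
      if (y == 0) { a0[n0] = hap; d0[n0] = p; ++n0; p = 0; }
      else if (y == 1) { a1[n1] = hap; d1[n1] = q; ++n1; q = 0; }
      else stop("pbwt_build: non-binary haplotype entry at site %d", l + 1);
    }
    std::copy(a0.begin(), a0.begin() + n0, a.begin());
    std::copy(a1.begin(), a1.begin() + n1, a.begin() + n0);
    std::copy(d0.begin(), d0.begin() + n0, d.begin());
    std::copy(d1.begin(), d1.begin() + n1, d.begin() + n0);
    if (si < ns && store_sites[si] == l) {
      for (int r = 0; r < M; ++r) {
        A(r, si) = a[r];
        D(r, si) = d[r];
        I(a[r], si) = r;
      }
      ++si;
    }
  }
  if (si != ns) stop("store_sites out of range or unsorted");
  return List::create(_["A"] = A, _["D"] = D, _["I"] = I,
                      _["sites"] = store_sites, _["M"] = M);
}

// Greedy walk away from the target's rank, always extending towards the
// neighbor with the longer current match (smaller divergence start); ties go
// to the up (lower-rank) side. Excluded haplotypes are skipped but still
// traversed so divergence accumulates past them.
static void neighbor_walk(const int* A, const int* D, int M, int rank,
                          int P, const std::vector<char>& excl,
                          std::vector<int>& out,
                          std::vector<int>* starts = nullptr) {
  int u = rank, v = rank;          // frontiers: next candidates u-1, v+1
  int du = 0, dv = 0;              // accumulated match starts per side
  while ((int)out.size() < P && (u > 0 || v < M - 1)) {
    bool take_up;
    if (u > 0 && v < M - 1) {
      const int cu = std::max(du, D[u]);       // match start if we step up
      const int cv = std::max(dv, D[v + 1]);   // match start if we step down
      take_up = (cu <= cv);
    } else take_up = (u > 0);
    if (take_up) {
      du = std::max(du, D[u]); --u;
      if (!excl[A[u]]) { out.push_back(A[u]); if (starts) starts->push_back(du); }
    } else {
      dv = std::max(dv, D[v + 1]); ++v;
      if (!excl[A[v]]) { out.push_back(A[v]); if (starts) starts->push_back(dv); }
    }
  }
}

// [[Rcpp::export]]
List cpp_pbwt_neighbors(const IntegerVector& A, const IntegerVector& D,
                        const IntegerVector& I, int site, int hap, int P,
                        const IntegerVector& exclude) {
  const int M = A.size();
  std::vector<char> excl(M, 0);
  for (int e : exclude) excl[e] = 1;
  excl[hap] = 1;
  std::vector<int> out, starts;
  out.reserve(P); starts.reserve(P);
  neighbor_walk(&A[0], &D[0], M, I[hap], P, excl, out, &starts);
  return List::create(_["haps"] = wrap(out), _["starts"] = wrap(starts));
}

// Union of neighbor queries for both target haplotypes over the stored
// sites of a window, collapsed into K distinct haplotypes: repeated indices
// are removed first, then haplotypes identical over the window span are
// collapsed to their lowest index (a duplicate sequence adds nothing the
// Li-Stephens model can copy).
// [[Rcpp::export]]
IntegerVector cpp_select_conditioning(const IntegerMatrix& A,
                                      const IntegerMatrix& D,
                                      const IntegerMatrix& I,
                                      const IntegerVector& store_sites,
                                      const IntegerVector& cols,
                                      int hap1, int hap2, int P,
                                      const IntegerVector& exclude,
                                      const NumericVector& hashes) {
  const int M = A.nrow();
  std::vector<char> excl(M, 0), seen(M, 0);
  for (int e : exclude) excl[e] = 1;
  excl[hap1] = 1; excl[hap2] = 1;
  std::vector<int> out, buf;
  for (int ci = 0; ci < cols.size(); ++ci) {
    const int c = cols[ci];
    const int* Ac = &A(0, c);
    const int* Dc = &D(0, c);
    for (int t = 0; t < 2; ++t) {
      const int hap = t == 0 ? hap1 : hap2;
      buf.clear();
      neighbor_walk(Ac, Dc, M, I(hap, c), P, excl, buf);
      for (int h : buf) if (!seen[h]) { seen[h] = 1; out.push_back(h); }
    }
  }
  std::sort(out.begin(), out.end());
  // collapse identical window sequences via precomputed 53-bit hashes
  std::vector<int> keep;
  std::vector<double> kh;
  for (int h : out) {
    const double hv = hashes[h];
    bool dup = false;
    for (double x : kh) if (x == hv) { dup = true; break; }
    if (!dup) { keep.push_back(h); kh.push_back(hv); }
  }
  return wrap(keep);
}

// FNV-1a hash of each haplotype's sequence over [from, to], folded to the
// 53 bits a double carries exactly; used to collapse duplicate sequences
// when building conditioning sets (column-major sweep, cache friendly)
// [[Rcpp::export]]
NumericVector cpp_hash_window(const IntegerMatrix& H, int from, int to) {
  const int M = H.nrow();
  std::vector<uint64_t> hv(M, 1469598103934665603ULL);
  for (int l = from; l <= to; ++l) {
    const int* col = &H(0, l);
    for (int h = 0; h < M; ++h) {
      hv[h] ^= (uint64_t)col[h];
      hv[h] *= 1099511628211ULL;
    }
  }
  NumericVector out(M);
  for (int h = 0; h < M; ++h) out[h] = (double)(hv[h] >> 11);
  return out;
}

// ---------------------------------------------------------------------------
// Long genotype matches (IBD2 screening).
//
// A match between individuals i and j is a maximal run of sites where their
// genotype codes agree, with missing acting as a wildcard; it is reported
// when pos[end] - pos[start] >= min_span. Individuals without missing data
// go through a PBWT sweep over the {0,1,2} alphabet (Durbin alg. 3 family);
// pairs touching missing data fall back to direct run scans.

struct MatchRec { int i, j, s, e; };

static void flush_block_pairs(const std::vector<int>& a,
                              const std::vector<int>& d,
                              const std::vector<int>& ids,
                              const IntegerMatrix& G,
                              const IntegerVector& pos,
                              double min_span, int l, bool require_diff,
                              std::vector<MatchRec>& out) {
  // Matches end at site l-1; arrays are sorted over [0, l-1]. For each pair
  // of ranks (r1 < r2) the match start is max(d[r1+1..r2]). Walk r1 downward
  // from r2 keeping the running max; stop once the span falls short (the max
  // only grows as the range widens).
  const int M = (int)a.size();
  const int endsite = l - 1;
  if (endsite < 0) return;
  const double pe = pos[endsite];
  for (int r2 = 1; r2 < M; ++r2) {
    int runmax = 0;
    for (int r1 = r2 - 1; r1 >= 0; --r1) {
      if (d[r1 + 1] > runmax) runmax = d[r1 + 1];
      if (runmax > endsite) break;
      if (pe - (double)pos[runmax] < min_span) break;
      if (!require_diff || G(ids[a[r1]], l) != G(ids[a[r2]], l))
        out.push_back({ids[a[r1]], ids[a[r2]], runmax, endsite});
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_genotype_long_matches(const IntegerMatrix& G,
                                        const IntegerVector& pos,
                                        double min_span) {
  const int N = G.nrow(), L = G.ncol();
  std::vector<char> hasNA(N, 0);
  for (int i = 0; i < N; ++i)
    for (int l = 0; l < L; ++l)
      if (G(i, l) == NA_INTEGER) { hasNA[i] = 1; break; }

  std::vector<MatchRec> out;

  // PBWT sweep over complete individuals.
  std::vector<int> ids;
  for (int i = 0; i < N; ++i) if (!hasNA[i]) ids.push_back(i);
  const int M = (int)ids.size();
  if (M >= 2) {
    std::vector<int> a(M), d(M, 0);
    std::vector<std::vector<int>> ab(3), db(3);
    for (int i = 0; i < M; ++i) a[i] = i;
    for (int l = 0; l < L; ++l) {
      flush_block_pairs(a, d, ids, G, pos, min_span, l, true, out);
      int p[3] = {l + 1, l + 1, l + 1};
      for (int c = 0; c < 3; ++c) { ab[c].clear(); db[c].clear(); }
      for (int r = 0; r < M; ++r) {
        const int dv = d[r];
        for (int c = 0; c < 3; ++c) if (dv > p[c]) p[c] = dv;
        const int idx = a[r], y = G(ids[idx], l);
        if (y < 0 || y > 2) stop("genotype codes must be 0/1/2/NA");
        ab[y].push_back(idx);
        db[y].push_back(p[y]);
        p[y] = 0;
      }
      int k = 0;
      for (int c = 0; c < 3; ++c)
        for (size_t t = 0; t < ab[c].size(); ++t, ++k) {
          a[k] = ab[c][t]; d[k] = db[c][t];
        }
    }
    flush_block_pairs(a, d, ids, G, pos, min_span, L, false, out);
  }

  // Wildcard pairs: at least one side has missing data.
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      if (!hasNA[i] && !hasNA[j]) continue;
      int start = 0;
      for (int l = 0; l <= L; ++l) {
        bool ok = false;
        if (l < L) {
          const int gi = G(i, l), gj = G(j, l);
          ok = (gi == NA_INTEGER || gj == NA_INTEGER || gi == gj);
        }
        if (!ok) {
          const int e = l - 1;
          if (e > start && (double)pos[e] - (double)pos[start] >= min_span)
            out.push_back({i, j, start, e});
          start = l + 1;
        }
      }
    }
  }

  IntegerMatrix res((int)out.size(), 4);
  for (size_t r = 0; r < out.size(); ++r) {
    int i = out[r].i, j = out[r].j;
    if (i > j) std::swap(i, j);
    res(r, 0) = i; res(r, 1) = j; res(r, 2) = out[r].s; res(r, 3) = out[r].e;
  }
  colnames(res) = CharacterVector::create("i", "j", "start", "end");
  return res;
}

// ---------------------------------------------------------------------------
// PBWT-guided initialization: sweep left to right, at each site fix the
// alleles implied by homozygous genotypes, impute heterozygous haplotypes by
// copying the nearest neighbor (by rank, alternating up/down) in the prefix
// array of the previous site whose allele is already determined, then repair
// complementarity at hets and advance the PBWT.

// [[Rcpp::export]]
IntegerMatrix cpp_pbwt_init(const IntegerMatrix& G, const NumericVector& freq) {
  const int N = G.nrow(), L = G.ncol(), M = 2 * N;
  IntegerMatrix H(M, L);
  std::vector<int> a(M), inv(M), d(M, 0), a0(M), a1(M), d0(M), d1(M);
  for (int h = 0; h < M; ++h) { a[h] = h; inv[h] = h; }
  std::vector<int> val(M), mstart(M);
  std::vector<char> known(M);

  for (int l = 0; l < L; ++l) {
    const double f = freq[l];
    for (int i = 0; i < N; ++i) {
      const int g = G(i, l), h1 = 2 * i, h2 = 2 * i + 1;
      if (g == 0) { val[h1] = val[h2] = 0; known[h1] = known[h2] = 1; }
      else if (g == 2) { val[h1] = val[h2] = 1; known[h1] = known[h2] = 1; }
      else if (g == NA_INTEGER) {
        val[h1] = unif_rand() < f ? 1 : 0;
        val[h2] = unif_rand() < f ? 1 : 0;
        known[h1] = known[h2] = 1;
      } else if (g == 1) {
        known[h1] = known[h2] = 0;
      } else stop("genotype codes must be 0/1/2/NA");
    }
    // impute unknown (het) haplotypes from PBWT neighbors at site l-1
    for (int h = 0; h < M; ++h) {
      if (known[h]) { mstart[h] = 0; continue; }
      if (l == 0) {
        // no left context: random orientation for the het pair
        const int h1 = (h / 2) * 2, h2 = h1 + 1;
        val[h1] = unif_rand() < 0.5 ? 1 : 0;
        val[h2] = 1 - val[h1];
        mstart[h1] = mstart[h2] = 0;
        continue;
      }
      const int r = inv[h];
      int u = r, v = r, du = 0, dv = 0;
      int src = -1, srcstart = l;
      // walk towards the neighbor with the longer current match (smaller
      // divergence start), ties up, until a determined allele is found
      while (src < 0 && (u > 0 || v < M - 1)) {
        bool up;
        if (u > 0 && v < M - 1)
          up = std::max(du, d[u]) <= std::max(dv, d[v + 1]);
        else up = (u > 0);
        if (up) {
          du = std::max(du, d[u]); --u;
          if (known[a[u]]) { src = a[u]; srcstart = du; }
        } else {
          dv = std::max(dv, d[v + 1]); ++v;
          if (known[a[v]]) { src = a[v]; srcstart = dv; }
        }
      }
      if (src >= 0) { val[h] = val[src]; mstart[h] = srcstart; }
      else { val[h] = unif_rand() < f ? 1 : 0; mstart[h] = l; }
      known[h] = 1;  // resolved hets become copy sources for later haps
    }
    // complementarity repair at hets
    for (int i = 0; i < N; ++i) {
      if (G(i, l) != 1) continue;
      const int h1 = 2 * i, h2 = h1 + 1;
      if (val[h1] == val[h2]) {
        // flip the haplotype with the shorter neighbor match (larger start)
        if (mstart[h1] > mstart[h2]) val[h1] = 1 - val[h1];
        else val[h2] = 1 - val[h2];
      }
    }
    for (int h = 0; h < M; ++h) H(h, l) = val[h];
    // advance PBWT with the resolved binary column
    int n0 = 0, n1 = 0, p = l + 1, q = l + 1;
    for (int r = 0; r < M; ++r) {
      if (d[r] > p) p = d[r];
      if (d[r] > q) q = d[r];
      const int hap = a[r];
      if (val[hap] == 0) { a0[n0] = hap; d0[n0] = p; ++n0; p = 0; }
      else { a1[n1] = hap; d1[n1] = q; ++n1; q = 0; }
    }
    std::copy(a0.begin(), a0.begin() + n0, a.begin());
    std::copy(a1.begin(), a1.begin() + n1, a.begin() + n0);
    std::copy(d0.begin(), d0.begin() + n0, d.begin());
    std::copy(d1.begin(), d1.begin() + n1, d.begin() + n0);
    for (int r = 0; r < M; ++r) inv[a[r]] = r;
  }
  return H;
}

// In-place write of a sampled haplotype pair into the working matrix. The
// engine owns H exclusively, so mutating it here avoids R's copy-on-write
// duplicating the whole matrix on every individual update.
// [[Rcpp::export]]
void cpp_set_hap(IntegerMatrix H, int row1, int row2,
                 const IntegerVector& sites,
                 const IntegerVector& v1, const IntegerVector& v2) {
  for (int t = 0; t < sites.size(); ++t) {
    H(row1, sites[t]) = v1[t];
    H(row2, sites[t]) = v2[t];
  }
}
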