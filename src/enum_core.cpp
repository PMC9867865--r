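// Core combinatorial kernel: orderly generation of canonical adjacency
// matrices in lexicographically decreasing order (Read-Faradzev / Grund
// style), with a refinement-based canonicity test that yields the
// automorphism group of each emitted matrix as a by-product.
//
// Conventions used throughout:
//  - atoms are pre-sorted by united-atom type; `type` holds the type id per
//    atom and equal ids form contiguous blocks;
//  - a matrix is canonical iff no type-preserving relabeling produces a
//    lexicographically larger matrix, reading the upper triangle row-wise;
//  - bond orders are small non-negative integers (0 = no bond).

#include <Rcpp.h>
#include <algorithm>
#include <set>
#include <vector>

using namespace Rcpp;

namespace {

typedef std::vector<int> ivec;

// ---------------------------------------------------------------------------
// Canonicity search.
//
// Searches over type-preserving permutations pi for one making the permuted
// matrix lexicographically larger than A.  Permutations are built position by
// position; an ordered-partition ("cell") structure pairs not-yet-assigned
// positions with the original atoms that may still be placed there, so that
// equality of all previously compared rows is maintained by construction.
// Placing a candidate atom at row r, the lexicographically largest achievable
// row r is read off greedily cell by cell: any cell offering a value larger
// than A's entry proves non-canonicity at once; smaller-only cells kill the
// branch; exact matches refine the cells for the rows below.
// ---------------------------------------------------------------------------

struct Cell {
  ivec pos;   // unassigned positions covered by this cell (increasing)
  ivec orig;  // original atoms that may be assigned to these positions
};

class CanonSearch {
public:
  CanonSearch(const int* A, int N, const int* type, int nrows, bool collect,
              bool autOnly = false)
      : A_(A), N_(N), nrows_(nrows), collect_(collect), autOnly_(autOnly),
        larger_(false) {
    // initial cells: type blocks, split at the filled-row boundary so that
    // permutations map filled positions onto filled positions (needed when
    // testing a partially filled matrix: only rows < nrows are known)
    int i = 0;
    while (i < N_) {
      int j = i;
      while (j < N_ && type[j] == type[i]) ++j;
      Cell lo, hi;
      for (int k = i; k < j; ++k) {
        if (k < nrows_ || nrows_ == N_) {
          lo.pos.push_back(k);
          lo.orig.push_back(k);
        } else {
          hi.pos.push_back(k);
          hi.orig.push_back(k);
        }
      }
      if (!lo.pos.empty()) cells0_.push_back(lo);
      if (!hi.pos.empty()) cells0_.push_back(hi);
      i = j;
    }
    assign_.assign(N_, -1);
  }

  // true if no type-preserving permutation yields a larger matrix
  bool canonical() {
    larger_ = false;
    aut_.clear();
    search(0, cells0_);
    return !larger_;
  }

  const std::vector<ivec>& automorphisms() const { return aut_; }

private:
  const int* A_;
  int N_, nrows_;
  bool collect_, autOnly_, larger_;
  std::vector<Cell> cells0_;
  ivec assign_;  // position -> original atom
  std::vector<ivec> aut_;

  inline int at(int i, int j) const { return A_[i * N_ + j]; }

  void record() {
    // assign_[p] = original atom at position p; automorphism pi satisfies
    // pi[assign_[p]] = p
    ivec pi(N_);
    for (int p = 0; p < N_; ++p) pi[assign_[p]] = p;
    aut_.push_back(pi);
  }

  void search(int r, const std::vector<Cell>& cells) {
    if (larger_) return;
    int limit = (nrows_ == N_) ? N_ : nrows_;
    if (r == limit) {
      if (collect_ && nrows_ == N_) record();
      return;
    }
    // locate the cell holding position r
    int ci = -1;
    for (size_t k = 0; k < cells.size(); ++k) {
      if (!cells[k].pos.empty() && cells[k].pos[0] == r) {
        ci = (int)k;
        break;
      }
    }
    if (ci < 0) return;  // defensive; should not happen
    const Cell& home = cells[ci];
    for (size_t vi = 0; vi < home.orig.size(); ++vi) {
      int v = home.orig[vi];
      // build reduced cell set with v and position r removed
      std::vector<Cell> next;
      next.reserve(cells.size());
      for (size_t k = 0; k < cells.size(); ++k) {
        Cell c = cells[k];
        if ((int)k == ci) {
          c.pos.erase(c.pos.begin());
          c.orig.erase(std::find(c.orig.begin(), c.orig.end(), v));
          if (c.pos.empty()) continue;
        }
        next.push_back(c);
      }
      // compare row r of the permuted matrix against row r of A, greedily;
      // per-cell value counts over the candidate originals
      bool dead = false;
      std::vector<std::vector<std::pair<int, int> > > counts(next.size());
      std::vector<char> touched(next.size(), 0);
      // cell index per position
      std::vector<int> cellOf(N_, -1);
      for (size_t k = 0; k < next.size(); ++k)
        for (size_t m = 0; m < next[k].pos.size(); ++m)
          cellOf[next[k].pos[m]] = (int)k;
      for (int c = r + 1; c < N_ && !dead; ++c) {
        int k = cellOf[c];
        if (k < 0) { dead = true; break; }  // defensive
        if (!touched[k]) {
          touched[k] = 1;
          // value -> count over origs of cell k
          for (size_t m = 0; m < next[k].orig.size(); ++m) {
            int val = at(v, next[k].orig[m]);
            bool found = false;
            for (size_t q = 0; q < counts[k].size(); ++q)
              if (counts[k][q].first == val) { counts[k][q].second++; found = true; break; }
            if (!found) counts[k].push_back(std::make_pair(val, 1));
          }
        }
        int want = at(r, c);
        int maxAvail = -1;
        int wantIdx = -1;
        for (size_t q = 0; q < counts[k].size(); ++q) {
          if (counts[k][q].second > 0 && counts[k][q].first > maxAvail)
            maxAvail = counts[k][q].first;
          if (counts[k][q].first == want && counts[k][q].second > 0)
            wantIdx = (int)q;
        }
        if (maxAvail > want && !autOnly_) {
          larger_ = true;  // a larger matrix is reachable: not canonical
          return;
        }
        if (wantIdx < 0) { dead = true; break; }
        counts[k][wantIdx].second--;
      }
      if (dead) continue;
      // refine: split every cell by (required value at position, value with v)
      std::vector<Cell> refined;
      bool ok = true;
      for (size_t k = 0; k < next.size() && ok; ++k) {
        // group positions by A[r][pos] and origs by A[v][orig]
        std::vector<std::pair<int, Cell> > parts;  // value -> subcell
        for (size_t m = 0; m < next[k].pos.size(); ++m) {
          int val = at(r, next[k].pos[m]);
          bool found = false;
          for (size_t q = 0; q < parts.size(); ++q)
            if (parts[q].first == val) { parts[q].second.pos.push_back(next[k].pos[m]); found = true; break; }
          if (!found) {
            parts.push_back(std::make_pair(val, Cell()));
            parts.back().second.pos.push_back(next[k].pos[m]);
          }
        }
        for (size_t m = 0; m < next[k].orig.size(); ++m) {
          int val = at(v, next[k].orig[m]);
          bool found = false;
          for (size_t q = 0; q < parts.size(); ++q)
            if (parts[q].first == val) { parts[q].second.orig.push_back(next[k].orig[m]); found = true; break; }
          if (!found) { ok = false; break; }
        }
        for (size_t q = 0; q < parts.size() && ok; ++q) {
          if (parts[q].second.pos.size() != parts[q].second.orig.size()) { ok = false; break; }
          refined.push_back(parts[q].second);
        }
      }
      if (!ok) continue;
      assign_[r] = v;
      search(r + 1, refined);
      assign_[r] = -1;
      if (larger_) return;
    }
  }
};

// depth-first connectivity over nonzero entries
bool connectedFlat(const ivec& A, int N) {
  if (N <= 1) return true;
  std::vector<char> seen(N, 0);
  ivec stack;
  stack.push_back(0);
  seen[0] = 1;
  int nseen = 1;
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    for (int w = 0; w < N; ++w) {
      if (!seen[w] && A[u * N + w] > 0) {
        seen[w] = 1;
        ++nseen;
        stack.push_back(w);
      }
    }
  }
  return nseen == N;
}

// ---------------------------------------------------------------------------
// Orderly generation
// ---------------------------------------------------------------------------

class Enumerator {
public:
  Enumerator(const ivec& effval, const ivec& type, int maxOrder)
      : d_(effval), type_(type), N_((int)effval.size()), maxOrder_(maxOrder) {
    A_.assign(N_ * N_, 0);
    rem_ = d_;
  }

  // returns list of (matrix, automorphism list)
  List run() {
    out_ = List::create();
    mats_.clear();
    auts_.clear();
    if (N_ == 1) {
      if (d_[0] == 0) {
        mats_.push_back(A_);
        std::vector<ivec> id(1, ivec(1, 0));
        auts_.push_back(id);
      }
    } else {
      fill(0, 1);
    }
    return wrap();
  }

private:
  ivec d_, type_, A_, rem_;
  int N_, maxOrder_;
  List out_;
  std::vector<ivec> mats_;
  std::vector<std::vector<ivec> > auts_;

  List wrap() {
    List res(mats_.size());
    for (size_t m = 0; m < mats_.size(); ++m) {
      IntegerMatrix M(N_, N_);
      for (int i = 0; i < N_; ++i)
        for (int j = 0; j < N_; ++j) M(i, j) = mats_[m][i * N_ + j];
      List perms(auts_[m].size());
      for (size_t p = 0; p < auts_[m].size(); ++p) {
        IntegerVector pv(N_);
        for (int i = 0; i < N_; ++i) pv[i] = auts_[m][p][i] + 1;  // 1-based
        perms[p] = pv;
      }
      res[m] = List::create(Named("A") = M, Named("aut") = perms);
    }
    return res;
  }

  void set(int i, int j, int v) {
    A_[i * N_ + j] = v;
    A_[j * N_ + i] = v;
    rem_[i] -= v;
    rem_[j] -= v;
  }

  void fill(int i, int j) {
    // capacity of row i beyond column j (inclusive of j handled by caller)
    if (j == N_ - 1) {
      int v = rem_[i];
      if (v >= 0 && v <= maxOrder_ && v <= rem_[j]) {
        set(i, j, v);
        rowDone(i);
        unset(i, j, v);
      }
      return;
    }
    int cap = 0;
    for (int k = j + 1; k < N_; ++k) cap += std::min(maxOrder_, rem_[k]);
    int vmax = std::min(maxOrder_, std::min(rem_[i], rem_[j]));
    int vmin = std::max(0, rem_[i] - cap);
    for (int v = vmax; v >= vmin; --v) {
      set(i, j, v);
      fill(i, j + 1);
      unset(i, j, v);
    }
  }

  void unset(int i, int j, int v) {
    A_[i * N_ + j] = 0;
    A_[j * N_ + i] = 0;
    rem_[i] += v;
    rem_[j] += v;
  }

  void rowDone(int i) {
    // connectivity prune: saturated prefix with no bond to the remainder can
    // never become connected (rows <= i are final)
    if (i < N_ - 2) {
      int remPrefix = 0;
      for (int p = 0; p <= i; ++p) remPrefix += rem_[p];
      if (remPrefix == 0) {
        bool cross = false;
        for (int p = 0; p <= i && !cross; ++p)
          for (int q = i + 1; q < N_; ++q)
            if (A_[p * N_ + q] > 0) { cross = true; break; }
        if (!cross) return;
      }
    }
    if (i == N_ - 2) {
      if (rem_[N_ - 1] != 0) return;
      if (!connectedFlat(A_, N_)) return;
      CanonSearch cs(&A_[0], N_, &type_[0], N_, true);
      if (cs.canonical()) {
        mats_.push_back(A_);
        auts_.push_back(cs.automorphisms());
      }
      return;
    }
    // semi-canonicity: prune if some prefix-stabilizing relabeling makes the
    // filled rows lexicographically larger
    CanonSearch cs(&A_[0], N_, &type_[0], i + 1, false);
    if (!cs.canonical()) return;
    fill(i + 1, i + 2);
  }
};

// ---------------------------------------------------------------------------
// Brute-force reference enumerator (test oracle).  Deliberately shares no
// machinery with the orderly generator: plain descending odometer over the
// upper triangle with valence bounds only, followed by exhaustive
// permutation canonicalization for duplicate removal.
// ---------------------------------------------------------------------------

class BruteForce {
public:
  BruteForce(const ivec& effval, const ivec& type, int maxOrder)
      : d_(effval), type_(type), N_((int)effval.size()), maxOrder_(maxOrder) {
    A_.assign(N_ * N_, 0);
    rem_ = d_;
    // precompute all type-preserving permutations (product of block perms)
    ivec idx(N_);
    for (int i = 0; i < N_; ++i) idx[i] = i;
    buildPerms(idx);
  }

  size_t nPerms() const { return perms_.size(); }

  List run() {
    seen_.clear();
    if (N_ == 1) {
      if (d_[0] == 0) seen_.insert(ivec());
    } else {
      fill(0, 1);
    }
    List res(seen_.size());
    int m = 0;
    for (std::set<ivec>::const_iterator it = seen_.begin(); it != seen_.end(); ++it, ++m) {
      IntegerMatrix M(N_, N_);
      int k = 0;
      for (int i = 0; i < N_; ++i)
        for (int j = i + 1; j < N_; ++j) {
          int v = (N_ > 1) ? (*it)[k++] : 0;
          M(i, j) = v;
          M(j, i) = v;
        }
      res[m] = M;
    }
    return res;
  }

private:
  ivec d_, type_, A_, rem_;
  int N_, maxOrder_;
  std::vector<ivec> perms_;
  std::set<ivec> seen_;

  void buildPerms(ivec idx) {
    // recursively permute each type block
    permBlock(idx, 0);
  }

  void permBlock(ivec idx, int start) {
    if (start >= N_) {
      perms_.push_back(idx);
      return;
    }
    int end = start;
    while (end < N_ && type_[end] == type_[start]) ++end;
    ivec block(idx.begin() + start, idx.begin() + end);
    std::sort(block.begin(), block.end());
    do {
      ivec nxt = idx;
      std::copy(block.begin(), block.end(), nxt.begin() + start);
      permBlock(nxt, end);
    } while (std::next_permutation(block.begin(), block.end()));
  }

  ivec canonKey() const {
    // lexicographically largest row-wise upper triangle over all perms
    ivec best;
    for (size_t p = 0; p < perms_.size(); ++p) {
      const ivec& pe = perms_[p];
      ivec key;
      key.reserve(N_ * (N_ - 1) / 2);
      for (int i = 0; i < N_; ++i)
        for (int j = i + 1; j < N_; ++j) key.push_back(A_[pe[i] * N_ + pe[j]]);
      if (best.empty() || key > best) best = key;
    }
    return best;
  }

  void fill(int i, int j) {
    if (i == N_ - 1) {
      bool sat = true;
      for (int k = 0; k < N_; ++k)
        if (rem_[k] != 0) { sat = false; break; }
      if (sat && connectedFlat(A_, N_)) seen_.insert(canonKey());
      return;
    }
    int ni = (j == N_ - 1) ? i + 1 : i;
    int nj = (j == N_ - 1) ? i + 2 : j + 1;
    int vmax = std::min(maxOrder_, std::min(rem_[i], rem_[j]));
    for (int v = vmax; v >= 0; --v) {
      A_[i * N_ + j] = v;
      A_[j * N_ + i] = v;
      rem_[i] -= v;
      rem_[j] -= v;
      fill(ni, nj);
      rem_[i] += v;
      rem_[j] += v;
      A_[i * N_ + j] = 0;
      A_[j * N_ + i] = 0;
    }
  }
};

ivec flatten(const IntegerMatrix& A) {
  int N = A.nrow();
  ivec out(N * N);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) out[i * N + j] = A(i, j);
  return out;
}

}  // namespace

// [[Rcpp::export]]
int cpp_lex_compare(IntegerMatrix A, IntegerMatrix B) {
  int N = A.nrow();
  if (B.nrow() != N || A.ncol() != N || B.ncol() != N)
    stop("lexCompare: dimension mismatch");
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      if (A(i, j) != B(i, j)) return A(i, j) > B(i, j) ? 1 : -1;
    }
  return 0;
}

// [[Rcpp::export]]
bool cpp_is_connected(IntegerMatrix A) {
  return connectedFlat(flatten(A), A.nrow());
}

// [[Rcpp::export]]
List cpp_canonicity(IntegerMatrix A, IntegerVector type) {
  int N = A.nrow();
  ivec Af = flatten(A);
  ivec tf(type.begin(), type.end());
  CanonSearch cs(&Af[0], N, &tf[0], N, true);
  bool can = cs.canonical();
  List perms;
  if (can) {
    const std::vector<ivec>& aut = cs.automorphisms();
    perms = List(aut.size());
    for (size_t p = 0; p < aut.size(); ++p) {
      IntegerVector pv(N);
      for (int i = 0; i < N; ++i) pv[i] = aut[p][i] + 1;
      perms[p] = pv;
    }
  }
  return List::create(Named("canonical") = can, Named("aut") = perms);
}

// [[Rcpp::export]]
List cpp_automorphisms(IntegerMatrix A, IntegerVector type) {
  // full automorphism group of A under type-preserving permutations,
  // independent of whether A is canonical (equality branches only)
  int N = A.nrow();
  ivec Af = flatten(A);
  ivec tf(type.begin(), type.end());
  CanonSearch cs(&Af[0], N, &tf[0], N, true, true);
  cs.canonical();
  const std::vector<ivec>& aut = cs.automorphisms();
  List perms(aut.size());
  for (size_t p = 0; p < aut.size(); ++p) {
    IntegerVector pv(N);
    for (int i = 0; i < N; ++i) pv[i] = aut[p][i] + 1;
    perms[p] = pv;
  }
  return perms;
}

// [[Rcpp::export]]
List cpp_enumerate(IntegerVector effval, IntegerVector type, int maxOrder) {
  ivec d(effval.begin(), effval.end());
  ivec t(type.begin(), type.end());
  long total = 0;
  for (size_t i = 0; i < d.size(); ++i) total += d[i];
  if (total % 2 != 0) return List::create();
  Enumerator e(d, t, maxOrder);
  return e.run();
}

// [[Rcpp::export]]
List cpp_brute_constitutional(IntegerVector effval, IntegerVector type, int maxOrder) {
  ivec d(effval.begin(), effval.end());
  ivec t(type.begin(), type.end());
  long total = 0;
  for (size_t i = 0; i < d.size(); ++i) total += d[i];
  if (total % 2 != 0) return List::create();
  BruteForce bf(d, t, maxOrder);
  if (bf.nPerms() > 200000) stop("brute-force oracle: permutation count cap exceeded");
  return bf.run();
}

// [[Rcpp::export]]
IntegerMatrix cpp_max_canonical(IntegerMatrix A, IntegerVector type) {
  // exhaustive canonical form (lex-max over type-preserving relabelings);
  // small molecules only
  int N = A.nrow();
  ivec Af = flatten(A);
  ivec tf(type.begin(), type.end());
  // enumerate block permutations
  std::vector<ivec> perms;
  {
    ivec idx(N);
    for (int i = 0; i < N; ++i) idx[i] = i;
    // simple recursive expansion
    std::vector<std::pair<int, int> > blocks;
    int i = 0;
    while (i < N) {
      int j = i;
      while (j < N && tf[j] == tf[i]) ++j;
      blocks.push_back(std::make_pair(i, j));
      i = j;
    }
    perms.push_back(idx);
    for (size_t b = 0; b < blocks.size(); ++b) {
      int s = blocks[b].first, e = blocks[b].second;
      std::vector<ivec> nxt;
      ivec block;
      for (int k = s; k < e; ++k) block.push_back(k);
      std::sort(block.begin(), block.end());
      std::vector<ivec> arrangements;
      do {
        arrangements.push_back(block);
      } while (std::next_permutation(block.begin(), block.end()));
      if (arrangements.size() * perms.size() > 2000000)
        stop("canonical form: permutation cap exceeded");
      for (size_t p = 0; p < perms.size(); ++p)
        for (size_t a = 0; a < arrangements.size(); ++a) {
          ivec cur = perms[p];
          std::copy(arrangements[a].begin(), arrangements[a].end(), cur.begin() + s);
          nxt.push_back(cur);
        }
      perms = nxt;
    }
  }
  ivec best;
  ivec bestPerm;
  for (size_t p = 0; p < perms.size(); ++p) {
    const ivec& pe = perms[p];
    ivec key;
    key.reserve(N * (N - 1) / 2);
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) key.push_back(Af[pe[i] * N + pe[j]]);
    if (best.empty() || key > best) {
      best = key;
      bestPerm = pe;
    }
  }
  IntegerMatrix M(N, N);
  if (N > 1) {
    int k = 0;
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        M(i, j) = best[k];
        M(j, i) = best[k];
        ++k;
      }
  }
  return M;
}
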