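// Core landscape engine for pseudoknotted RNA secondary structures.
//
// Structures are pairing tables pt[1..n] (0 = unpaired, else partner,
// 1-based).  The structure class is restricted to "1-structures": every
// connected component of the helix conflict graph has topological genus 1,
// which covers the H-, K-, L- and M-type pseudoknots.
//
// Everything here is deterministic; ties in energies are resolved by a
// fixed move order (removals before additions, then lexicographic (i,j)).

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstdio>
#include <map>
#include <set>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const double EPS = 1e-9;

// ---------------------------------------------------------------------------
// basic types

struct Helix {
  int i, j, len;  // outer pair (i,j), stack of `len` consecutive pairs
};

struct Params {
  double stack[6][6];  // indexed by pair type: AU,UA,GC,CG,GU,UG
  double helixEnd;
  double beta[4];  // H, K, L, M component penalties
};

static Params asParams(const List& p) {
  Params out;
  NumericMatrix st = p["stack"];
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) out.stack[a][b] = st(a, b);
  out.helixEnd = as<double>(p["helixEnd"]);
  NumericVector beta = p["beta"];
  for (int k = 0; k < 4; ++k) out.beta[k] = beta[k];
  return out;
}

// nucleotide codes: A=0, C=1, G=2, U=3
// pair types: AU=0, UA=1, GC=2, CG=3, GU=4, UG=5; -1 = not canonical
static inline int pairType(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

// ---------------------------------------------------------------------------
// helix decomposition and conflict components

static std::vector<Helix> helicesOf(const std::vector<int>& pt) {
  int n = (int)pt.size() - 1;  // pt[0] unused
  std::vector<Helix> hs;
  for (int i = 1; i <= n; ++i) {
    int j = pt[i];
    if (j <= i) continue;
    // continuation of a helix if (i-1, j+1) is also a pair
    if (i > 1 && j < n && pt[i - 1] == j + 1) continue;
    int len = 1;
    while (i + len < j - len && pt[i + len] == j - len) ++len;
    hs.push_back({i, j, len});
  }
  return hs;
}

static inline bool chordsCross(int i1, int j1, int i2, int j2) {
  if (i1 > i2) { std::swap(i1, i2); std::swap(j1, j2); }
  return i2 < j1 && j1 < j2;
}

struct UF {
  std::vector<int> up;
  explicit UF(int n) : up(n) { for (int i = 0; i < n; ++i) up[i] = i; }
  int find(int x) { while (up[x] != x) { up[x] = up[up[x]]; x = up[x]; } return x; }
  void join(int a, int b) { up[find(a)] = find(b); }
};

// components of the conflict graph; returns component id per helix
static std::vector<int> conflictComponents(const std::vector<Helix>& hs,
                                           std::vector<std::pair<int, int> >* edges = 0) {
  int m = (int)hs.size();
  UF uf(m);
  for (int a = 0; a < m; ++a)
    for (int b = a + 1; b < m; ++b)
      if (chordsCross(hs[a].i, hs[a].j, hs[b].i, hs[b].j)) {
        uf.join(a, b);
        if (edges) edges->push_back(std::make_pair(a, b));
      }
  std::vector<int> comp(m);
  std::map<int, int> relabel;
  for (int a = 0; a < m; ++a) {
    int r = uf.find(a);
    if (!relabel.count(r)) { int id = (int)relabel.size(); relabel[r] = id; }
    comp[a] = relabel[r];
  }
  return comp;
}

// ---------------------------------------------------------------------------
// genus of a chord diagram by boundary tracing
//
// The backbone with 2c chord endpoints is closed into a circle and the
// diagram is fattened into a ribbon graph.  Walking along the boundary,
// leaving endpoint position g one enters the circle segment towards g+1 and
// crosses that chord to its partner.  The number of boundary cycles b gives
// the genus g = (c - b + 1) / 2.

static int genusChords(std::vector<std::pair<int, int> > chords) {
  int c = (int)chords.size();
  if (c == 0) return 0;
  // relabel endpoints with ranks 0 .. 2c-1 preserving order
  std::vector<int> pts;
  pts.reserve(2 * c);
  for (size_t k = 0; k < chords.size(); ++k) {
    pts.push_back(chords[k].first);
    pts.push_back(chords[k].second);
  }
  std::sort(pts.begin(), pts.end());
  std::vector<int> partner(2 * c, -1);
  for (size_t k = 0; k < chords.size(); ++k) {
    int a = (int)(std::lower_bound(pts.begin(), pts.end(), chords[k].first) - pts.begin());
    int b = (int)(std::lower_bound(pts.begin(), pts.end(), chords[k].second) - pts.begin());
    partner[a] = b;
    partner[b] = a;
  }
  std::vector<bool> seen(2 * c, false);
  int b = 0;
  for (int s = 0; s < 2 * c; ++s) {
    if (seen[s]) continue;
    ++b;
    int g = s;
    while (!seen[g]) {
      seen[g] = true;
      g = partner[(g + 1) % (2 * c)];
    }
  }
  return (c - b + 1) / 2;
}

// ---------------------------------------------------------------------------
// pseudoknot component classification
//
// Per conflict component the shadow is formed by one chord per helix;
// stacked (nested, identically crossing) chords are collapsed and the
// remaining crossing pattern is matched against the four genus-1 types.
// class codes: 0 = N (isolated helix), 1 = H, 2 = K, 3 = L, 4 = M,
// -1 = not genus 1 (outside the 1-structure class).

static int classifyComponent(std::vector<std::pair<int, int> > chords) {
  if (chords.size() < 2) return 0;
  if (genusChords(chords) != 1) return -1;
  // collapse parallel chords: nested pairs whose crossing sets coincide
  bool changed = true;
  while (changed && chords.size() > 2) {
    changed = false;
    int m = (int)chords.size();
    std::vector<std::vector<bool> > cross(m, std::vector<bool>(m, false));
    for (int a = 0; a < m; ++a)
      for (int b = a + 1; b < m; ++b)
        if (chordsCross(chords[a].first, chords[a].second,
                        chords[b].first, chords[b].second))
          cross[a][b] = cross[b][a] = true;
    for (int a = 0; a < m && !changed; ++a)
      for (int b = 0; b < m && !changed; ++b) {
        if (a == b || cross[a][b]) continue;
        // b nested inside a?
        if (!(chords[a].first < chords[b].first &&
              chords[b].second < chords[a].second))
          continue;
        bool same = true;
        for (int d = 0; d < m; ++d) {
          if (d == a || d == b) continue;
          if (cross[a][d] != cross[b][d]) { same = false; break; }
        }
        if (same) {
          chords.erase(chords.begin() + b);
          changed = true;
        }
      }
  }
  // drop chords that cross nothing (cannot occur in a connected component
  // of size > 1, kept for safety on degenerate inputs)
  {
    int m = (int)chords.size();
    std::vector<bool> keep(m, false);
    for (int a = 0; a < m; ++a)
      for (int b = a + 1; b < m; ++b)
        if (chordsCross(chords[a].first, chords[a].second,
                        chords[b].first, chords[b].second))
          keep[a] = keep[b] = true;
    std::vector<std::pair<int, int> > kept;
    for (int a = 0; a < m; ++a)
      if (keep[a]) kept.push_back(chords[a]);
    chords = kept;
  }
  int m = (int)chords.size();
  if (genusChords(chords) != 1) return -1;
  int edges = 0;
  std::vector<int> deg(m, 0);
  for (int a = 0; a < m; ++a)
    for (int b = a + 1; b < m; ++b)
      if (chordsCross(chords[a].first, chords[a].second,
                      chords[b].first, chords[b].second)) {
        ++edges; ++deg[a]; ++deg[b];
      }
  if (m == 2 && edges == 1) return 1;            // H
  if (m == 3 && edges == 2) return 2;            // K (path)
  if (m == 3 && edges == 3) return 3;            // L (triangle)
  if (m == 4 && edges == 5) {                    // M (ABCADBCD: the unique
    int d2 = 0, d3 = 0;                          // 4-chord genus-1 shadow;
    for (int a = 0; a < m; ++a) {                // crossing graph = K4 minus
      if (deg[a] == 2) ++d2;                     // one edge)
      if (deg[a] == 3) ++d3;
    }
    if (d2 == 2 && d3 == 2) return 4;
  }
  return -1;
}

// per-component class codes for a structure; also reports component of each
// helix.  Returns empty vectors for the open chain.
static void componentClasses(const std::vector<Helix>& hs,
                             std::vector<int>& compOfHelix,
                             std::vector<int>& classOfComp) {
  compOfHelix = conflictComponents(hs);
  int ncomp = 0;
  for (size_t a = 0; a < compOfHelix.size(); ++a)
    ncomp = std::max(ncomp, compOfHelix[a] + 1);
  classOfComp.assign(ncomp, 0);
  for (int c = 0; c < ncomp; ++c) {
    std::vector<std::pair<int, int> > chords;
    for (size_t a = 0; a < hs.size(); ++a)
      if (compOfHelix[a] == c) chords.push_back(std::make_pair(hs[a].i, hs[a].j));
    classOfComp[c] = classifyComponent(chords);
  }
}

static bool isOneStructureImpl(const std::vector<int>& pt) {
  std::vector<Helix> hs = helicesOf(pt);
  std::vector<int> comp = conflictComponents(hs);
  int ncomp = 0;
  for (size_t a = 0; a < comp.size(); ++a) ncomp = std::max(ncomp, comp[a] + 1);
  for (int c = 0; c < ncomp; ++c) {
    std::vector<std::pair<int, int> > chords;
    for (size_t a = 0; a < hs.size(); ++a)
      if (comp[a] == c) chords.push_back(std::make_pair(hs[a].i, hs[a].j));
    if (chords.size() > 1 && genusChords(chords) != 1) return false;
  }
  return true;
}

// ---------------------------------------------------------------------------
// energy model: stacking within helices + helix-end penalty + per-component
// pseudoknot penalties.  Returns NA for structures outside the 1-structure
// class or with non-canonical pairs.

static double energyImpl(const std::vector<int>& seq, const std::vector<int>& pt,
                         const Params& par, double* pkPenalty = 0) {
  double E = 0.0, pk = 0.0;
  std::vector<Helix> hs = helicesOf(pt);
  for (size_t a = 0; a < hs.size(); ++a) {
    E += par.helixEnd;
    for (int t = 0; t + 1 < hs[a].len; ++t) {
      int p1 = pairType(seq[hs[a].i + t - 1], seq[hs[a].j - t - 1]);
      int p2 = pairType(seq[hs[a].i + t], seq[hs[a].j - t - 2]);
      if (p1 < 0 || p2 < 0) return NA_REAL;
      E += par.stack[p1][p2];
    }
    if (hs[a].len == 1) {
      if (pairType(seq[hs[a].i - 1], seq[hs[a].j - 1]) < 0) return NA_REAL;
    }
  }
  std::vector<int> compOf, classOf;
  componentClasses(hs, compOf, classOf);
  for (size_t c = 0; c < classOf.size(); ++c) {
    if (classOf[c] < 0) return NA_REAL;
    if (classOf[c] > 0) pk += par.beta[classOf[c] - 1];
  }
  E += pk;
  if (pkPenalty) *pkPenalty = pk;
  return E;
}

// stacking + helix-end terms only (no pseudoknot penalties); single O(n)
// pass without helix decomposition.  NA on non-canonical pairs.
static double energyNoPk(const std::vector<int>& seq, const std::vector<int>& pt,
                         const Params& par) {
  int n = (int)pt.size() - 1;
  double E = 0.0;
  for (int i = 1; i <= n; ++i) {
    int j = pt[i];
    if (j <= i) continue;
    int t1 = pairType(seq[i - 1], seq[j - 1]);
    if (t1 < 0) return NA_REAL;
    if (!(i > 1 && pt[i - 1] == j + 1)) E += par.helixEnd;  // helix start
    if (pt[i + 1] == j - 1) {
      int t2 = pairType(seq[i], seq[j - 2]);
      if (t2 < 0) return NA_REAL;
      E += par.stack[t1][t2];
    }
  }
  return E;
}

// number of existing pairs crossed by the chord (i, j)
static int countCross(const std::vector<int>& pt, int i, int j) {
  int n = (int)pt.size() - 1, c = 0;
  for (int a = 1; a <= n; ++a) {
    int b = pt[a];
    if (b > a && chordsCross(a, b, i, j)) ++c;
  }
  return c;
}

// local stacking/helix-end change of adding pair (i, j) to pt (which must
// not contain it); the pseudoknot term is handled separately
static double addDelta(const std::vector<int>& seq, const std::vector<int>& pt,
                       const Params& par, int i, int j) {
  int n = (int)pt.size() - 1;
  int t = pairType(seq[i - 1], seq[j - 1]);
  bool cOut = (i > 1 && j < n && pt[i - 1] == j + 1);
  bool cIn = (pt[i + 1] == j - 1);
  double d = 0.0;
  if (cOut) d += par.stack[pairType(seq[i - 2], seq[j])][t];
  if (cIn) d += par.stack[t][pairType(seq[i], seq[j - 2])];
  if (!cOut && !cIn) d += par.helixEnd;        // new helix
  else if (cOut && cIn) d -= par.helixEnd;     // fuses two helices
  return d;
}

// Does adding/removing pair (i, j) provably leave the pseudoknot penalty
// unchanged?  True when the pair sits strictly inside its helix band
// (the shadow chords are untouched) or when the chord crosses no pair
// (then no shadow chord's crossing set can change: any chord crossing a
// chord nested inside (i, j) at distance one crosses (i, j) as well).
// `pt` must be the state WITHOUT the pair for additions and WITH the pair
// for removals; the geometric condition is the same in both directions.
static bool pkInvariant(const std::vector<int>& pt, int i, int j) {
  int n = (int)pt.size() - 1;
  if (i > 1 && j < n && pt[i - 1] == j + 1 && pt[i + 1] != j - 1) return true;
  return countCross(pt, i, j) == 0;
}

// ---------------------------------------------------------------------------
// move set

static bool canAddImpl(const std::vector<int>& seq, std::vector<int>& pt,
                       int i, int j, bool nestedOnly) {
  int n = (int)pt.size() - 1;
  if (i < 1 || j > n || j - i < 4) return false;
  if (pt[i] != 0 || pt[j] != 0) return false;
  if (pairType(seq[i - 1], seq[j - 1]) < 0) return false;
  int nc = countCross(pt, i, j);
  if (nc == 0) return true;  // non-crossing additions preserve the class
  if (nestedOnly) return false;
  pt[i] = j; pt[j] = i;
  bool ok = isOneStructureImpl(pt);
  pt[i] = 0; pt[j] = 0;
  return ok;
}

// moves as rows (kind, i, j), kind 0 = remove, 1 = add;
// removals first, each block sorted by (i, j)
static std::vector<std::array<int, 3> > movesOf(const std::vector<int>& seq,
                                                std::vector<int>& pt,
                                                bool nestedOnly) {
  int n = (int)pt.size() - 1;
  std::vector<std::array<int, 3> > mv;
  for (int i = 1; i <= n; ++i)
    if (pt[i] > i) mv.push_back({0, i, pt[i]});
  for (int i = 1; i <= n; ++i) {
    if (pt[i] != 0) continue;
    for (int j = i + 4; j <= n; ++j)
      if (pt[j] == 0 && canAddImpl(seq, pt, i, j, nestedOnly))
        mv.push_back({1, i, j});
  }
  return mv;
}

static inline void applyMove(std::vector<int>& pt, const std::array<int, 3>& m) {
  if (m[0] == 0) { pt[m[1]] = 0; pt[m[2]] = 0; }
  else { pt[m[1]] = m[2]; pt[m[2]] = m[1]; }
}

static inline void revertMove(std::vector<int>& pt, const std::array<int, 3>& m) {
  if (m[0] == 0) { pt[m[1]] = m[2]; pt[m[2]] = m[1]; }
  else { pt[m[1]] = 0; pt[m[2]] = 0; }
}

// steepest-descent move selection; returns index into mv or -1 when pt is a
// local minimum.  Ties: first move in the fixed order (remove before add,
// then lexicographic (i,j)).
static int descentMove(const std::vector<int>& seq, std::vector<int>& pt,
                       double E, const Params& par,
                       const std::vector<std::array<int, 3> >& mv) {
  int best = -1;
  double bestE = E;
  for (size_t k = 0; k < mv.size(); ++k) {
    int i = mv[k][1], j = mv[k][2];
    double Ek;
    if (mv[k][0] == 0) {  // removal (always stays in the class)
      if (pkInvariant(pt, i, j)) {
        pt[i] = 0; pt[j] = 0;
        Ek = E - addDelta(seq, pt, par, i, j);
        pt[i] = j; pt[j] = i;
      } else {
        applyMove(pt, mv[k]);
        Ek = energyImpl(seq, pt, par);
        revertMove(pt, mv[k]);
      }
    } else {  // addition: movesOf only emits class-preserving adds
      if (pkInvariant(pt, i, j)) {
        Ek = E + addDelta(seq, pt, par, i, j);
      } else {
        applyMove(pt, mv[k]);
        Ek = energyImpl(seq, pt, par);
        revertMove(pt, mv[k]);
      }
    }
    if (!ISNA(Ek) && Ek < bestE - EPS) { bestE = Ek; best = (int)k; }
  }
  return best;
}

// ---------------------------------------------------------------------------
// keys and conversions

static std::string keyOf(const std::vector<int>& pt) {
  std::string s;
  s.reserve(pt.size() * 3);
  char buf[8];
  for (size_t i = 1; i < pt.size(); ++i) {
    snprintf(buf, sizeof buf, "%d,", pt[i]);
    s += buf;
  }
  return s;
}

static std::vector<int> ptFromR(const IntegerVector& v) {
  std::vector<int> pt(v.size() + 1, 0);
  for (int i = 0; i < v.size(); ++i) pt[i + 1] = v[i];
  return pt;
}

static IntegerVector ptToR(const std::vector<int>& pt) {
  IntegerVector v((int)pt.size() - 1);
  for (size_t i = 1; i < pt.size(); ++i) v[i - 1] = pt[i];
  return v;
}

// ---------------------------------------------------------------------------
// exported primitives

// [[Rcpp::export(name = ".cpp_genus")]]
int cpp_genus(IntegerMatrix pairs) {
  std::vector<std::pair<int, int> > chords;
  for (int k = 0; k < pairs.nrow(); ++k)
    chords.push_back(std::make_pair(pairs(k, 0), pairs(k, 1)));
  return genusChords(chords);
}

// [[Rcpp::export(name = ".cpp_helices")]]
IntegerMatrix cpp_helices(IntegerVector ptR) {
  std::vector<int> pt = ptFromR(ptR);
  std::vector<Helix> hs = helicesOf(pt);
  IntegerMatrix out((int)hs.size(), 3);
  for (size_t a = 0; a < hs.size(); ++a) {
    out(a, 0) = hs[a].i; out(a, 1) = hs[a].j; out(a, 2) = hs[a].len;
  }
  colnames(out) = CharacterVector::create("i", "j", "length");
  return out;
}

// [[Rcpp::export(name = ".cpp_is_one_structure")]]
bool cpp_is_one_structure(IntegerVector ptR) {
  std::vector<int> pt = ptFromR(ptR);
  return isOneStructureImpl(pt);
}

// component id (1-based) per helix and class code per component
// [[Rcpp::export(name = ".cpp_components")]]
List cpp_components(IntegerVector ptR) {
  std::vector<int> pt = ptFromR(ptR);
  std::vector<Helix> hs = helicesOf(pt);
  std::vector<int> compOf, classOf;
  componentClasses(hs, compOf, classOf);
  IntegerVector comp((int)compOf.size()), cls((int)classOf.size());
  for (size_t a = 0; a < compOf.size(); ++a) comp[a] = compOf[a] + 1;
  for (size_t c = 0; c < classOf.size(); ++c) cls[c] = classOf[c];
  return List::create(_["component"] = comp, _["class"] = cls);
}

// [[Rcpp::export(name = ".cpp_energy")]]
double cpp_energy(IntegerVector seqR, IntegerVector ptR, List parR) {
  std::vector<int> seq = as<std::vector<int> >(seqR);
  std::vector<int> pt = ptFromR(ptR);
  Params par = asParams(parR);
  return energyImpl(seq, pt, par);
}

// [[Rcpp::export(name = ".cpp_can_add")]]
bool cpp_can_add(IntegerVector seqR, IntegerVector ptR, int i, int j,
                 bool nestedOnly) {
  std::vector<int> seq = as<std::vector<int> >(seqR);
  std::vector<int> pt = ptFromR(ptR);
  return canAddImpl(seq, pt, i, j, nestedOnly);
}

// [[Rcpp::export(name = ".cpp_moves")]]
IntegerMatrix cpp_moves(IntegerVector seqR, IntegerVector ptR, bool nestedOnly) {
  std::vector<int> seq = as<std::vector<int> >(seqR);
  std::vector<int> pt = ptFromR(ptR);
  std::vector<std::array<int, 3> > mv = movesOf(seq, pt, nestedOnly);
  IntegerMatrix out((int)mv.size(), 3);
  for (size_t k = 0; k < mv.size(); ++k) {
    out(k, 0) = mv[k][0]; out(k, 1) = mv[k][1]; out(k, 2) = mv[k][2];
  }
  colnames(out) = CharacterVector::create("kind", "i", "j");
  return out;
}

// full gradient walk; returns the visited structures and energies
// [[Rcpp::export(name = ".cpp_gradient_walk")]]
List cpp_gradient_walk(IntegerVector seqR, IntegerVector ptR, List parR,
                       bool nestedOnly) {
  std::vector<int> seq = as<std::vector<int> >(seqR);
  std::vector<int> pt = ptFromR(ptR);
  Params par = asParams(parR);
  List path;
  std::vector<double> energies;
  double E = energyImpl(seq, pt, par);
  if (ISNA(E)) stop("structure is not a valid 1-structure over this sequence");
  path.push_back(ptToR(pt));
  energies.push_back(E);
  for (;;) {
    std::vector<std::array<int, 3> > mv = movesOf(seq, pt, nestedOnly);
    int k = descentMove(seq, pt, E, par, mv);
    if (k < 0) break;
    applyMove(pt, mv[k]);
    E = energyImpl(seq, pt, par);
    path.push_back(ptToR(pt));
    energies.push_back(E);
  }
  return List::create(_["path"] = path, _["energy"] = wrap(energies));
}

// ---------------------------------------------------------------------------
// exhaustive enumeration of 1-structures within an energy window
//
// Depth-first over positions with a sound branch-and-bound: from a partial
// structure, each further pair can lower the energy by at most two best
// stacking terms plus one saved helix-end penalty, and the pseudoknot
// penalty can at worst fall back to zero.

struct Enumerator {
  const std::vector<int>& seq;
  const Params& par;
  double ceiling;     // window above the best energy seen so far
  bool nestedOnly;
  int maxCount;
  double bestE;
  double perAddGain;  // maximal energy decrease per additional pair
  int n;
  std::vector<int> pt;
  std::vector<bool> canPair;  // (i * (n+1) + j): canonical and j - i >= 4
  double EnoPk;               // incremental stacking + helix-end energy
  int crossRel;               // number of crossing pair relations present
  std::vector<std::vector<int> > found;
  std::vector<double> foundE;

  Enumerator(const std::vector<int>& s, const Params& p, double ceil,
             bool nested, int maxc)
      : seq(s), par(p), ceiling(ceil), nestedOnly(nested), maxCount(maxc),
        bestE(0.0), n((int)s.size()), pt(s.size() + 1, 0),
        canPair((s.size() + 1) * (s.size() + 1), false),
        EnoPk(0.0), crossRel(0) {
    double minStack = 0.0;
    for (int a = 0; a < 6; ++a)
      for (int b = 0; b < 6; ++b) minStack = std::min(minStack, p.stack[a][b]);
    perAddGain = -2.0 * minStack + p.helixEnd;
    for (int i = 1; i <= n; ++i)
      for (int j = i + 4; j <= n; ++j)
        if (pairType(seq[i - 1], seq[j - 1]) >= 0)
          canPair[i * (n + 1) + j] = true;
  }

  void record() {
    double E;
    if (crossRel == 0) {
      E = EnoPk;  // fully nested: always valid, no pseudoknot term
    } else {
      E = energyImpl(seq, pt, par);
      if (ISNA(E)) return;
    }
    if (E < bestE) bestE = E;
    if (E <= bestE + ceiling + EPS) {
      if ((int)found.size() >= maxCount)
        stop("enumeration exceeded the size guard (%d structures)", maxCount);
      found.push_back(pt);
      foundE.push_back(E);
    }
  }

  void dfs(int pos) {
    if (pos > n) { record(); return; }
    if (pt[pos] != 0) { dfs(pos + 1); return; }
    // bound: can the best completion still reach the window?  The
    // pseudoknot term is nonnegative, so dropping it keeps this sound.
    if (R_finite(ceiling)) {
      int freeLeft = 0;
      for (int a = pos; a <= n; ++a)
        if (pt[a] == 0) ++freeLeft;
      if (EnoPk - (freeLeft / 2) * perAddGain > bestE + ceiling + EPS) return;
    }
    dfs(pos + 1);  // pos stays unpaired
    for (int j = pos + 4; j <= n; ++j) {
      if (pt[j] != 0 || !canPair[pos * (n + 1) + j]) continue;
      int nc = countCross(pt, pos, j);
      if (nc > 0) {
        if (nestedOnly) continue;
        pt[pos] = j; pt[j] = pos;
        bool ok = isOneStructureImpl(pt);
        pt[pos] = 0; pt[j] = 0;
        if (!ok) continue;
      }
      double d = addDelta(seq, pt, par, pos, j);
      pt[pos] = j; pt[j] = pos;
      EnoPk += d; crossRel += nc;
      dfs(pos + 1);
      EnoPk -= d; crossRel -= nc;
      pt[pos] = 0; pt[j] = 0;
    }
  }
};

// [[Rcpp::export(name = ".cpp_enumerate")]]
List cpp_enumerate(IntegerVector seqR, List parR, double ceiling,
                   bool nestedOnly, int maxCount) {
  std::vector<int> seq = as<std::vector<int> >(seqR);
  Params par = asParams(parR);
  Enumerator en(seq, par, ceiling, nestedOnly, maxCount);
  en.dfs(1);
  // final filter against the true MFE
  int keep = 0;
  for (size_t k = 0; k < en.found.size(); ++k)
    if (en.foundE[k] <= en.bestE + ceiling + EPS) ++keep;
  IntegerMatrix pts(keep, en.n);
  NumericVector Es(keep);
  int r = 0;
  for (size_t k = 0; k < en.found.size(); ++k) {
    if (en.foundE[k] > en.bestE + ceiling + EPS) continue;
    for (int i = 1; i <= en.n; ++i) pts(r, i - 1) = en.found[k][i];
    Es[r] = en.foundE[k];
    ++r;
  }
  return List::create(_["pt"] = pts, _["energy"] = Es, _["mfe"] = en.bestE);
}

// ---------------------------------------------------------------------------
// adjacency among an enumerated ensemble (each edge reported once, from the
// structure with more pairs via its remove moves)

// [[Rcpp::export(name = ".cpp_adjacency")]]
IntegerMatrix cpp_adjacency(IntegerMatrix pts) {
  int N = pts.nrow(), n = pts.ncol();
  std::unordered_map<std::string, int> idx;
  std::vector<std::vector<int> > all(N);
  for (int s = 0; s < N; ++s) {
    std::vector<int> pt(n + 1, 0);
    for (int i = 1; i <= n; ++i) pt[i] = pts(s, i - 1);
    all[s] = pt;
    idx[keyOf(pt)] = s;
  }
  std::vector<std::pair<int, int> > edges;
  for (int s = 0; s < N; ++s) {
    std::vector<int> pt = all[s];
    for (int i = 1; i <= n; ++i) {
      int j = pt[i];
      if (j <= i) continue;
      pt[i] = 0; pt[j] = 0;
      std::unordered_map<std::string, int>::iterator it = idx.find(keyOf(pt));
      if (it != idx.end()) edges.push_back(std::make_pair(s + 1, it->second + 1));
      pt[i] = j; pt[j] = i;
    }
  }
  IntegerMatrix out((int)edges.size(), 2);
  for (size_t k = 0; k < edges.size(); ++k) {
    out(k, 0) = edges[k].first;
    out(k, 1) = edges[k].second;
  }
  return out;
}

// ---------------------------------------------------------------------------
// exact flooding of an enumerated ensemble
//
// Structures are processed by increasing (energy, key).  Basins are gradient
// basins (memoized steepest descent with the same tie-breaking as
// cpp_gradient_walk).  Union-find merging yields the exact minimax saddle
// height for every pair of local minima; boundary bookkeeping yields the
// exact *direct* saddle between gradient basins (minimal max(f(a), f(b))
// over adjacent structure pairs in the two basins).

// [[Rcpp::export(name = ".cpp_flood")]]
List cpp_flood(IntegerVector seqR, IntegerMatrix pts, NumericVector Es,
               List parR, bool nestedOnly) {
  std::vector<int> seq = as<std::vector<int> >(seqR);
  Params par = asParams(parR);
  int N = pts.nrow(), n = pts.ncol();

  std::vector<std::vector<int> > all(N);
  std::vector<std::string> keys(N);
  std::unordered_map<std::string, int> idx;
  for (int s = 0; s < N; ++s) {
    std::vector<int> pt(n + 1, 0);
    for (int i = 1; i <= n; ++i) pt[i] = pts(s, i - 1);
    all[s] = pt;
    keys[s] = keyOf(pt);
    idx[keys[s]] = s;
  }

  // deterministic processing order: (energy, key) ascending
  std::vector<int> order(N);
  for (int s = 0; s < N; ++s) order[s] = s;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (Es[a] != Es[b]) return Es[a] < Es[b];
    return keys[a] < keys[b];
  });
  std::vector<int> rank(N);
  for (int r = 0; r < N; ++r) rank[order[r]] = r;

  std::vector<int> basin(N, -1);       // structure index of the basin's LM
  std::vector<int> lmIdx;              // structure indices of LMs
  std::map<int, int> lmId;             // structure index -> LM id

  // pass 1: basins by memoized descent (ascending order)
  for (int r = 0; r < N; ++r) {
    int s = order[r];
    std::vector<int> pt = all[s];
    std::vector<std::array<int, 3> > mv = movesOf(seq, pt, nestedOnly);
    int k = descentMove(seq, pt, Es[s], par, mv);
    if (k < 0) {
      basin[s] = s;
      lmId[s] = (int)lmIdx.size();
      lmIdx.push_back(s);
    } else {
      applyMove(pt, mv[k]);
      std::unordered_map<std::string, int>::iterator it = idx.find(keyOf(pt));
      if (it == idx.end())
        stop("internal: descent left the enumerated window");
      basin[s] = basin[it->second];
    }
  }
  int L = (int)lmIdx.size();

  NumericMatrix minimax(L, L), direct(L, L);
  IntegerMatrix directA(L, L), directB(L, L);  // witness boundary pair
  std::fill(minimax.begin(), minimax.end(), NA_REAL);
  std::fill(direct.begin(), direct.end(), NA_REAL);
  std::fill(directA.begin(), directA.end(), NA_INTEGER);
  std::fill(directB.begin(), directB.end(), NA_INTEGER);

  UF uf(N);
  std::vector<std::vector<int> > lmsOf(N);  // LM ids per UF root
  std::vector<bool> processed(N, false);
  std::vector<double> mergeH;
  std::vector<int> mergeA, mergeB;  // representative LM ids of merged sides

  for (int r = 0; r < N; ++r) {
    int s = order[r];
    if (basin[s] == s) lmsOf[s].push_back(lmId[s]);
    processed[s] = true;
    // neighbors inside the ensemble
    std::vector<int> pt = all[s];
    std::vector<std::array<int, 3> > mv = movesOf(seq, pt, nestedOnly);
    std::set<int> roots;
    for (size_t k = 0; k < mv.size(); ++k) {
      applyMove(pt, mv[k]);
      std::unordered_map<std::string, int>::iterator it = idx.find(keyOf(pt));
      revertMove(pt, mv[k]);
      if (it == idx.end()) continue;
      int t = it->second;
      if (!processed[t] || t == s) continue;
      // direct (boundary) saddle between gradient basins
      int bx = lmId[basin[s]], by = lmId[basin[t]];
      if (bx != by) {
        double h = Es[s];  // = max(Es[s], Es[t]) since t was processed first
        if (ISNA(direct(bx, by)) || h < direct(bx, by) - EPS) {
          direct(bx, by) = direct(by, bx) = h;
          directA(bx, by) = directB(by, bx) = s + 1;
          directB(bx, by) = directA(by, bx) = t + 1;
        }
      }
      roots.insert(uf.find(t));
    }
    // flooding merges
    int rs = uf.find(s);
    for (std::set<int>::iterator it = roots.begin(); it != roots.end(); ++it) {
      int rt = uf.find(*it);
      if (rt == rs) continue;
      // record minimax saddles across the two components
      if (!lmsOf[rs].empty() && !lmsOf[rt].empty()) {
        int repA = lmsOf[rs][0], repB = lmsOf[rt][0];
        for (size_t a = 0; a < lmsOf[rs].size(); ++a) {
          if (Es[lmIdx[lmsOf[rs][a]]] < Es[lmIdx[repA]]) repA = lmsOf[rs][a];
          for (size_t b = 0; b < lmsOf[rt].size(); ++b) {
            minimax(lmsOf[rs][a], lmsOf[rt][b]) = Es[s];
            minimax(lmsOf[rt][b], lmsOf[rs][a]) = Es[s];
          }
        }
        for (size_t b = 0; b < lmsOf[rt].size(); ++b)
          if (Es[lmIdx[lmsOf[rt][b]]] < Es[lmIdx[repB]]) repB = lmsOf[rt][b];
        mergeH.push_back(Es[s]);
        mergeA.push_back(repA + 1);
        mergeB.push_back(repB + 1);
      }
      // union, keeping the lm list on the new root
      std::vector<int> merged = lmsOf[rs];
      merged.insert(merged.end(), lmsOf[rt].begin(), lmsOf[rt].end());
      uf.join(rs, rt);
      rs = uf.find(rs);
      lmsOf[rs] = merged;
    }
  }

  for (int a = 0; a < L; ++a) {
    minimax(a, a) = Es[lmIdx[a]];
    direct(a, a) = Es[lmIdx[a]];
  }

  IntegerVector lmOut(L), basinOut(N);
  for (int a = 0; a < L; ++a) lmOut[a] = lmIdx[a] + 1;
  for (int s = 0; s < N; ++s) basinOut[s] = lmId[basin[s]] + 1;

  return List::create(
      _["lm"] = lmOut, _["basin"] = basinOut, _["minimax"] = minimax,
      _["direct"] = direct, _["directA"] = directA, _["directB"] = directB,
      _["merges"] = DataFrame::create(_["height"] = wrap(mergeH),
                                      _["lm_a"] = wrap(mergeA),
                                      _["lm_b"] = wrap(mergeB)));
}

// ---------------------------------------------------------------------------
// pseudoknot-aware findpath: breadth-limited best-first search over moves
// that strictly decrease the base-pair distance to the target, keeping every
// intermediate inside the 1-structure class.

struct FPNode {
  std::vector<int> pt;
  double E, peak;
  int parent;
};

// [[Rcpp::export(name = ".cpp_findpath")]]
List cpp_findpath(IntegerVector seqR, IntegerVector fromR, IntegerVector toR,
                  List parR, int width, bool nestedOnly) {
  std::vector<int> seq = as<std::vector<int> >(seqR);
  std::vector<int> x = ptFromR(fromR), y = ptFromR(toR);
  Params par = asParams(parR);
  int n = (int)seq.size();

  std::vector<std::pair<int, int> > rmList, addList;
  for (int i = 1; i <= n; ++i) {
    if (x[i] > i && y[i] != x[i]) rmList.push_back(std::make_pair(i, x[i]));
    if (y[i] > i && x[i] != y[i]) addList.push_back(std::make_pair(i, y[i]));
  }
  int d = (int)(rmList.size() + addList.size());

  std::vector<FPNode> arena;
  double Ex = energyImpl(seq, x, par);
  if (ISNA(Ex)) stop("invalid start structure");
  arena.push_back({x, Ex, Ex, -1});
  std::vector<int> frontier(1, 0);

  for (int lev = 0; lev < d; ++lev) {
    // expand
    std::vector<int> children;
    std::unordered_map<std::string, int> bestByKey;
    for (size_t c = 0; c < frontier.size(); ++c) {
      int id = frontier[c];
      std::vector<int> pt = arena[id].pt;
      // removals of pairs still present from the rm list
      for (size_t k = 0; k < rmList.size(); ++k) {
        int i = rmList[k].first, j = rmList[k].second;
        if (pt[i] != j) continue;
        pt[i] = 0; pt[j] = 0;
        double E = energyImpl(seq, pt, par);
        if (!ISNA(E)) {
          double peak = std::max(arena[id].peak, E);
          std::string key = keyOf(pt);
          std::unordered_map<std::string, int>::iterator it = bestByKey.find(key);
          if (it == bestByKey.end()) {
            arena.push_back({pt, E, peak, id});
            bestByKey[key] = (int)arena.size() - 1;
            children.push_back((int)arena.size() - 1);
          } else if (peak < arena[it->second].peak - EPS) {
            arena[it->second].peak = peak;
            arena[it->second].parent = id;
          }
        }
        pt[i] = j; pt[j] = i;
      }
      // additions from the add list
      for (size_t k = 0; k < addList.size(); ++k) {
        int i = addList[k].first, j = addList[k].second;
        if (pt[i] != 0 || pt[j] != 0) continue;
        if (!canAddImpl(seq, pt, i, j, nestedOnly)) continue;
        pt[i] = j; pt[j] = i;
        double E = energyImpl(seq, pt, par);
        if (!ISNA(E)) {
          double peak = std::max(arena[id].peak, E);
          std::string key = keyOf(pt);
          std::unordered_map<std::string, int>::iterator it = bestByKey.find(key);
          if (it == bestByKey.end()) {
            arena.push_back({pt, E, peak, id});
            bestByKey[key] = (int)arena.size() - 1;
            children.push_back((int)arena.size() - 1);
          } else if (peak < arena[it->second].peak - EPS) {
            arena[it->second].peak = peak;
            arena[it->second].parent = id;
          }
        }
        pt[i] = 0; pt[j] = 0;
      }
    }
    if (children.empty()) stop("findpath: no valid move at level %d", lev);
    std::sort(children.begin(), children.end(), [&](int a, int b) {
      if (std::abs(arena[a].peak - arena[b].peak) > EPS)
        return arena[a].peak < arena[b].peak;
      if (std::abs(arena[a].E - arena[b].E) > EPS) return arena[a].E < arena[b].E;
      return keyOf(arena[a].pt) < keyOf(arena[b].pt);
    });
    if ((int)children.size() > width) children.resize(width);
    frontier = children;
  }

  // reconstruct the (unique) surviving path to y
  int best = frontier[0];
  std::vector<int> chain;
  for (int id = best; id >= 0; id = arena[id].parent) chain.push_back(id);
  std::reverse(chain.begin(), chain.end());
  List path;
  NumericVector energies((int)chain.size());
  for (size_t k = 0; k < chain.size(); ++k) {
    path.push_back(ptToR(arena[chain[k]].pt));
    energies[k] = arena[chain[k]].E;
  }
  return List::create(_["path"] = path, _["energy"] = energies,
                      _["peak"] = arena[best].peak);
}
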