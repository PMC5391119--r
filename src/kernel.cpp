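// Exact rational geometry kernel: slacks, ranks, biorthogonal base-cone rays,
// incremental double-description slicing, min-ratio pivoting and the
// breadth-first assembly of the skeleton graph.  All arithmetic is GMP
// rationals; numbers cross the R boundary as strings ("p/q" canonical form).

#include <Rcpp.h>
#include <gmpxx.h>
#include <vector>
#include <string>
#include <set>
#include <map>
#include <deque>
#include <random>
#include <chrono>
#include <algorithm>

using namespace Rcpp;

typedef std::vector<mpq_class> QV;
typedef std::vector<QV> QM;

// ---------------------------------------------------------------- parsing --

static mpq_class parse_rat(const std::string& tok0) {
  std::string tok;
  for (char c : tok0) if (!isspace((unsigned char)c)) tok += c;
  if (tok.empty()) stop("empty numeric token");
  bool dec = false, exp = false;
  for (char c : tok) {
    if (c == '.') dec = true;
    if (c == 'e' || c == 'E') exp = true;
  }
  try {
    if (!dec && !exp) {              // integer or p/q
      mpq_class q(tok, 10);
      q.canonicalize();
      return q;
    }
  } catch (...) {
    stop("malformed numeric token '%s'", tok0.c_str());
  }
  // decimal literal, converted exactly: sign mantissa [. frac] [e exp]
  size_t i = 0;
  int sign = 1;
  if (i < tok.size() && (tok[i] == '+' || tok[i] == '-')) {
    if (tok[i] == '-') sign = -1;
    ++i;
  }
  std::string digits;
  long fracdigits = 0, e10 = 0;
  bool seen_digit = false, in_frac = false;
  for (; i < tok.size(); ++i) {
    char c = tok[i];
    if (c >= '0' && c <= '9') {
      digits += c;
      seen_digit = true;
      if (in_frac) ++fracdigits;
    } else if (c == '.' && !in_frac) {
      in_frac = true;
    } else if (c == 'e' || c == 'E') {
      ++i;
      bool esign_neg = false;
      if (i < tok.size() && (tok[i] == '+' || tok[i] == '-')) {
        esign_neg = (tok[i] == '-');
        ++i;
      }
      if (i >= tok.size()) stop("malformed numeric token '%s'", tok0.c_str());
      long ev = 0;
      for (; i < tok.size(); ++i) {
        if (tok[i] < '0' || tok[i] > '9')
          stop("malformed numeric token '%s'", tok0.c_str());
        ev = ev * 10 + (tok[i] - '0');
      }
      e10 = esign_neg ? -ev : ev;
      break;
    } else {
      stop("malformed numeric token '%s'", tok0.c_str());
    }
  }
  if (!seen_digit) stop("malformed numeric token '%s'", tok0.c_str());
  mpz_class num(digits.empty() ? "0" : digits, 10);
  num *= sign;
  mpz_class den(1);
  long shift = e10 - fracdigits;
  mpz_class ten(10), p;
  if (shift >= 0) {
    mpz_pow_ui(p.get_mpz_t(), ten.get_mpz_t(), (unsigned long)shift);
    num *= p;
  } else {
    mpz_pow_ui(p.get_mpz_t(), ten.get_mpz_t(), (unsigned long)(-shift));
    den = p;
  }
  mpq_class q(num, den);
  q.canonicalize();
  return q;
}

static std::string fmt_rat(const mpq_class& q) { return q.get_str(); }

static QV qv_from(const CharacterVector& v) {
  QV out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = parse_rat(as<std::string>(v[i]));
  return out;
}

static QM qm_from(const CharacterMatrix& M) {
  QM out(M.nrow(), QV(M.ncol()));
  for (int i = 0; i < M.nrow(); ++i)
    for (int j = 0; j < M.ncol(); ++j)
      out[i][j] = parse_rat(as<std::string>(M(i, j)));
  return out;
}

static CharacterVector qv_to(const QV& v) {
  CharacterVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = fmt_rat(v[i]);
  return out;
}

// ----------------------------------------------------------- linear algebra

static int rank_q(QM M) {
  if (M.empty()) return 0;
  size_t nr = M.size(), nc = M[0].size();
  size_t r = 0;
  for (size_t c = 0; c < nc && r < nr; ++c) {
    size_t piv = r;
    while (piv < nr && M[piv][c] == 0) ++piv;
    if (piv == nr) continue;
    std::swap(M[r], M[piv]);
    for (size_t i = r + 1; i < nr; ++i) {
      if (M[i][c] == 0) continue;
      mpq_class f = M[i][c] / M[r][c];
      for (size_t j = c; j < nc; ++j) M[i][j] -= f * M[r][j];
    }
    ++r;
  }
  return (int)r;
}

// Gauss-Jordan inverse; returns false if singular.
static bool inverse_q(QM M, QM& inv) {
  size_t n = M.size();
  inv.assign(n, QV(n, mpq_class(0)));
  for (size_t i = 0; i < n; ++i) inv[i][i] = 1;
  for (size_t c = 0; c < n; ++c) {
    size_t piv = c;
    while (piv < n && M[piv][c] == 0) ++piv;
    if (piv == n) return false;
    std::swap(M[c], M[piv]);
    std::swap(inv[c], inv[piv]);
    mpq_class d = M[c][c];
    for (size_t j = 0; j < n; ++j) { M[c][j] /= d; inv[c][j] /= d; }
    for (size_t i = 0; i < n; ++i) {
      if (i == c || M[i][c] == 0) continue;
      mpq_class f = M[i][c];
      for (size_t j = 0; j < n; ++j) {
        M[i][j] -= f * M[c][j];
        inv[i][j] -= f * inv[c][j];
      }
    }
  }
  return true;
}

// One exact null-space vector of the rows of M (ncols = n), or empty if the
// rows have full column rank.  Deterministic: first free column, RREF.
static QV nullspace_vec(QM M, size_t n) {
  size_t nr = M.size();
  std::vector<long> pivot_col;
  size_t r = 0;
  for (size_t c = 0; c < n && r < nr; ++c) {
    size_t piv = r;
    while (piv < nr && M[piv][c] == 0) ++piv;
    if (piv == nr) continue;
    std::swap(M[r], M[piv]);
    mpq_class d = M[r][c];
    for (size_t j = 0; j < n; ++j) M[r][j] /= d;
    for (size_t i = 0; i < nr; ++i) {
      if (i == r || M[i][c] == 0) continue;
      mpq_class f = M[i][c];
      for (size_t j = 0; j < n; ++j) M[i][j] -= f * M[r][j];
    }
    pivot_col.push_back((long)c);
    ++r;
  }
  std::set<long> pivs(pivot_col.begin(), pivot_col.end());
  long freec = -1;
  for (size_t c = 0; c < n; ++c)
    if (!pivs.count((long)c)) { freec = (long)c; break; }
  if (freec < 0) return QV();
  QV x(n, mpq_class(0));
  x[freec] = 1;
  for (size_t i = 0; i < pivot_col.size(); ++i)
    x[pivot_col[i]] = -M[i][freec];
  return x;
}

// ------------------------------------------------------------------- rays --

struct Ray {
  std::vector<mpz_class> d;   // primitive integer direction
  std::vector<int> act;       // sorted active indices within the owning cone
  std::string key;
};

static std::string key_of(const std::vector<mpz_class>& d) {
  std::string k;
  for (size_t i = 0; i < d.size(); ++i) {
    if (i) k += ',';
    k += d[i].get_str();
  }
  return k;
}

// clear denominators, divide by gcd; orientation preserved
static std::vector<mpz_class> primitive(const QV& v) {
  size_t n = v.size();
  mpz_class L(1);
  for (size_t i = 0; i < n; ++i)
    mpz_lcm(L.get_mpz_t(), L.get_mpz_t(), v[i].get_den().get_mpz_t());
  std::vector<mpz_class> d(n);
  mpz_class g(0);
  for (size_t i = 0; i < n; ++i) {
    d[i] = v[i].get_num() * (L / v[i].get_den());
    mpz_gcd(g.get_mpz_t(), g.get_mpz_t(), d[i].get_mpz_t());
  }
  if (g == 0) stop("zero vector cannot be a ray");
  for (size_t i = 0; i < n; ++i) d[i] /= g;
  return d;
}

static mpq_class dot_q(const QV& a, const std::vector<mpz_class>& d) {
  mpq_class s(0);
  for (size_t i = 0; i < a.size(); ++i)
    if (d[i] != 0) s += a[i] * mpq_class(d[i]);
  return s;
}

static mpq_class dot_qq(const QV& a, const QV& x) {
  mpq_class s(0);
  for (size_t i = 0; i < a.size(); ++i) s += a[i] * x[i];
  return s;
}

static std::vector<int> act_of(const QM& A, const std::vector<mpz_class>& d,
                               const std::vector<int>& J) {
  std::vector<int> act;
  for (int i : J)
    if (dot_q(A[i], d) == 0) act.push_back(i);
  std::sort(act.begin(), act.end());
  return act;
}

// ----------------------------------------------------------- base cone ----

static std::vector<Ray> base_rays(const QM& A, const std::vector<int>& B) {
  size_t n = A[0].size();
  if (B.size() != n) stop("basis must have exactly n = %d indices", (int)n);
  QM M(n, QV(n));
  for (size_t i = 0; i < n; ++i) M[i] = A[B[i]];
  QM inv;
  if (!inverse_q(M, inv))
    stop("index set is not a basis: rows are rank deficient");
  std::vector<Ray> X(n);
  for (size_t j = 0; j < n; ++j) {       // ray_j = -(column j of inv)
    QV col(n);
    for (size_t i = 0; i < n; ++i) col[i] = -inv[i][j];
    X[j].d = primitive(col);
    X[j].key = key_of(X[j].d);
    for (size_t i = 0; i < n; ++i)
      if (i != j) X[j].act.push_back(B[i]);
    std::sort(X[j].act.begin(), X[j].act.end());
  }
  return X;
}

// --------------------------------------------------------------- slicing --

struct Counters {
  double tests = 0, hits = 0, rejects = 0, dups = 0;
  double pairs_considered = 0;
  int peak_rays = 0;
};

typedef std::set<std::pair<std::string, std::string> > Record;

static std::pair<std::string, std::string> pkey(const std::string& a,
                                                const std::string& b) {
  return a < b ? std::make_pair(a, b) : std::make_pair(b, a);
}

static std::vector<int> intersect_sorted(const std::vector<int>& a,
                                         const std::vector<int>& b) {
  std::vector<int> out;
  std::set_intersection(a.begin(), a.end(), b.begin(), b.end(),
                        std::back_inserter(out));
  return out;
}

static bool colam_algebraic(const QM& A, const std::vector<int>& joint,
                            size_t n) {
  QM rows;
  rows.reserve(joint.size());
  for (int i : joint) rows.push_back(A[i]);
  return rank_q(rows) == (int)n - 2;
}

// combinatorial 2-face test: no third extreme ray's active set contains
// the pair's joint active set
static bool colam_combinatorial(const std::vector<Ray>& X, size_t ir,
                                size_t jr, const std::vector<int>& joint) {
  for (size_t t = 0; t < X.size(); ++t) {
    if (t == ir || t == jr) continue;
    if (std::includes(X[t].act.begin(), X[t].act.end(),
                      joint.begin(), joint.end()))
      return false;
  }
  return true;
}

// One insertion step of half-space k into the double description (J, X).
// test: 0 algebraic, 1 combinatorial.  record: 2-face record + rejection
// pre-test (the improved slicer); without it every X- x X+ pair is tested
// (the standard insertion function).
static void insert_step(const QM& A, size_t n, std::vector<int>& J,
                        std::vector<Ray>& X, int k, int test, bool record,
                        Record& L, Counters& C, List* trace) {
  const QV& ak = A[k];
  std::vector<size_t> pos, zer, neg;
  std::vector<mpq_class> dots(X.size());
  for (size_t i = 0; i < X.size(); ++i) {
    dots[i] = dot_q(ak, X[i].d);
    int s = sgn(dots[i]);
    if (s < 0) pos.push_back(i);        // feasible side
    else if (s == 0) zer.push_back(i);
    else neg.push_back(i);
  }

  std::vector<Ray> newrays;
  std::set<std::string> newkeys;
  std::vector<std::pair<int, int> > colam_pairs;  // (neg idx, pos idx)
  std::vector<int> Jk = J;
  Jk.push_back(k);
  std::sort(Jk.begin(), Jk.end());

  for (size_t im : neg) {
    for (size_t ip : pos) {
      C.pairs_considered += 1;
      std::vector<int> joint = intersect_sorted(X[im].act, X[ip].act);
      bool colam;
      if (record) {
        if ((int)joint.size() < (int)n - 2) {   // rejection pre-test
          C.rejects += 1;
          continue;
        }
        std::pair<std::string, std::string> pk = pkey(X[im].key, X[ip].key);
        if (L.count(pk)) {
          C.hits += 1;
          colam = true;
          // build the new ray, replace the dying pair (rho, rho') by
          // (rho, phi) in the record
          QV phi_q(n, mpq_class(0));
          for (size_t j = 0; j < n; ++j)
            phi_q[j] = dots[im] * mpq_class(X[ip].d[j]) -
                       dots[ip] * mpq_class(X[im].d[j]);
          Ray phi;
          phi.d = primitive(phi_q);
          phi.key = key_of(phi.d);
          phi.act = act_of(A, phi.d, Jk);
          L.erase(pk);
          L.insert(pkey(X[ip].key, phi.key));
          if (newkeys.count(phi.key)) {
            C.dups += 1;
          } else {
            newkeys.insert(phi.key);
            newrays.push_back(phi);
            colam_pairs.push_back(std::make_pair((int)im, (int)ip));
          }
          continue;
        }
        C.tests += 1;
        colam = (test == 0) ? colam_algebraic(A, joint, n)
                            : colam_combinatorial(X, im, ip, joint);
        if (!colam) continue;
        QV phi_q(n, mpq_class(0));
        for (size_t j = 0; j < n; ++j)
          phi_q[j] = dots[im] * mpq_class(X[ip].d[j]) -
                     dots[ip] * mpq_class(X[im].d[j]);
        Ray phi;
        phi.d = primitive(phi_q);
        phi.key = key_of(phi.d);
        phi.act = act_of(A, phi.d, Jk);
        L.insert(pkey(X[ip].key, phi.key));
        if (newkeys.count(phi.key)) {
          C.dups += 1;
        } else {
          newkeys.insert(phi.key);
          newrays.push_back(phi);
          colam_pairs.push_back(std::make_pair((int)im, (int)ip));
        }
      } else {
        C.tests += 1;
        colam = (test == 0) ? colam_algebraic(A, joint, n)
                            : colam_combinatorial(X, im, ip, joint);
        if (!colam) continue;
        QV phi_q(n, mpq_class(0));
        for (size_t j = 0; j < n; ++j)
          phi_q[j] = dots[im] * mpq_class(X[ip].d[j]) -
                     dots[ip] * mpq_class(X[im].d[j]);
        Ray phi;
        phi.d = primitive(phi_q);
        phi.key = key_of(phi.d);
        phi.act = act_of(A, phi.d, Jk);
        if (newkeys.count(phi.key)) {
          C.dups += 1;
        } else {
          newkeys.insert(phi.key);
          newrays.push_back(phi);
          colam_pairs.push_back(std::make_pair((int)im, (int)ip));
        }
      }
    }
  }

  if (trace) {
    IntegerMatrix pr(colam_pairs.size(), 2);
    for (size_t i = 0; i < colam_pairs.size(); ++i) {
      pr(i, 0) = colam_pairs[i].first;
      pr(i, 1) = colam_pairs[i].second;
    }
    CharacterMatrix nr(n, newrays.size());
    for (size_t j = 0; j < newrays.size(); ++j)
      for (size_t i = 0; i < n; ++i)
        nr(i, j) = newrays[j].d[i].get_str();
    *trace = List::create(
      _["k"] = k,
      _["pos"] = IntegerVector(pos.begin(), pos.end()),
      _["zero"] = IntegerVector(zer.begin(), zer.end()),
      _["neg"] = IntegerVector(neg.begin(), neg.end()),
      _["colaminar_pairs"] = pr,
      _["new_rays"] = nr);
  }

  std::vector<Ray> Xn;
  Xn.reserve(pos.size() + zer.size() + newrays.size());
  for (size_t i : pos) Xn.push_back(X[i]);
  for (size_t i : zer) {                 // rays on the hyperplane gain k
    Ray r = X[i];
    r.act.push_back(k);
    std::sort(r.act.begin(), r.act.end());
    Xn.push_back(r);
  }
  for (Ray& r : newrays) Xn.push_back(r);
  X.swap(Xn);
  J = Jk;
  if ((int)X.size() > C.peak_rays) C.peak_rays = (int)X.size();
}

static List rays_to_list(const std::vector<Ray>& X, size_t n) {
  CharacterMatrix R(n, X.size());
  List acts(X.size());
  for (size_t j = 0; j < X.size(); ++j) {
    for (size_t i = 0; i < n; ++i) R(i, j) = X[j].d[i].get_str();
    acts[j] = IntegerVector(X[j].act.begin(), X[j].act.end());
  }
  return List::create(_["rays"] = R, _["active"] = acts);
}

static List counters_to_list(const Counters& C) {
  return List::create(
    _["pairs_considered"] = C.pairs_considered,
    _["tests_run"] = C.tests,
    _["record_hits"] = C.hits,
    _["rejections"] = C.rejects,
    _["duplicates_merged"] = C.dups,
    _["peak_rays"] = C.peak_rays);
}

static std::vector<Ray> rays_from_list(const CharacterMatrix& R,
                                       const List& acts) {
  std::vector<Ray> X(R.ncol());
  for (int j = 0; j < R.ncol(); ++j) {
    X[j].d.resize(R.nrow());
    for (int i = 0; i < R.nrow(); ++i)
      X[j].d[i] = mpz_class(as<std::string>(R(i, j)), 10);
    X[j].key = key_of(X[j].d);
    IntegerVector a = acts[j];
    X[j].act.assign(a.begin(), a.end());
    std::sort(X[j].act.begin(), X[j].act.end());
  }
  return X;
}

static Record record_from(const CharacterMatrix& Lm) {
  Record L;
  for (int i = 0; i < Lm.nrow(); ++i)
    L.insert(pkey(as<std::string>(Lm(i, 0)), as<std::string>(Lm(i, 1))));
  return L;
}

static CharacterMatrix record_to(const Record& L) {
  CharacterMatrix Lm(L.size(), 2);
  int i = 0;
  for (const auto& p : L) {
    Lm(i, 0) = p.first;
    Lm(i, 1) = p.second;
    ++i;
  }
  return Lm;
}

// ------------------------------------------------------- exported kernel --

// [[Rcpp::export]]
CharacterVector cpp_canon(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = fmt_rat(parse_rat(as<std::string>(x[i])));
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_dbl2q(NumericVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    if (!R_FINITE(x[i])) stop("non-finite value cannot be exact");
    out[i] = fmt_rat(mpq_class(x[i]));     // exact binary expansion
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_q2dbl(CharacterVector x) {
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = parse_rat(as<std::string>(x[i])).get_d();
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_slack(CharacterMatrix A, CharacterVector b,
                          CharacterVector p) {
  QM Aq = qm_from(A);
  QV bq = qv_from(b), pq = qv_from(p);
  if ((int)pq.size() != A.ncol())
    stop("point has length %d but the system has dimension %d",
         (int)pq.size(), A.ncol());
  QV s(Aq.size());
  for (size_t i = 0; i < Aq.size(); ++i) s[i] = bq[i] - dot_qq(Aq[i], pq);
  return qv_to(s);
}

// [[Rcpp::export]]
int cpp_rank(CharacterMatrix M) {
  if (M.nrow() == 0) return 0;
  return rank_q(qm_from(M));
}

// [[Rcpp::export]]
List cpp_solve(CharacterMatrix A, CharacterVector b) {
  QM Aq = qm_from(A);
  size_t n = Aq.size();
  if (A.ncol() != (int)n) stop("matrix must be square");
  QM inv;
  if (!inverse_q(Aq, inv))
    return List::create(_["ok"] = false);
  QV bq = qv_from(b), x(n, mpq_class(0));
  for (size_t i = 0; i < n; ++i)
    for (size_t j = 0; j < n; ++j) x[i] += inv[i][j] * bq[j];
  return List::create(_["ok"] = true, _["x"] = qv_to(x));
}

// [[Rcpp::export]]
List cpp_biorthogonal(CharacterMatrix A, IntegerVector B) {
  QM Aq = qm_from(A);
  std::vector<int> Bv(B.begin(), B.end());
  std::vector<Ray> X = base_rays(Aq, Bv);
  return rays_to_list(X, A.ncol());
}

// [[Rcpp::export]]
std::string cpp_multiplicity(int n, int m, int sigma) {
  if (n < 1 || m < 1 || sigma < 0) stop("arguments must be non-negative");
  if (m - n - sigma < 0) stop("m - n - sigma must be non-negative");
  mpz_class bin;
  mpz_bin_uiui(bin.get_mpz_t(), (unsigned long)(n + sigma), (unsigned long)n);
  mpz_class mu = mpz_class(n) * mpz_class(m - n - sigma) * bin;
  return mu.get_str();
}

// [[Rcpp::export]]
List cpp_insert_halfspace(CharacterMatrix A, IntegerVector J,
                          CharacterMatrix rays, List active,
                          CharacterMatrix L, int k, int test, bool record) {
  QM Aq = qm_from(A);
  size_t n = A.ncol();
  std::vector<int> Jv(J.begin(), J.end());
  std::sort(Jv.begin(), Jv.end());
  if (std::binary_search(Jv.begin(), Jv.end(), k))
    stop("half-space %d is already in the processed set", k);
  std::vector<Ray> X = rays_from_list(rays, active);
  Record Lr = record_from(L);
  Counters C;
  List trace;
  insert_step(Aq, n, Jv, X, k, test, record, Lr, C, &trace);
  List out = rays_to_list(X, n);
  out["J"] = IntegerVector(Jv.begin(), Jv.end());
  out["record"] = record_to(Lr);
  out["counters"] = counters_to_list(C);
  out["step"] = trace;
  return out;
}

// [[Rcpp::export]]
List cpp_slice_cone(CharacterMatrix A, IntegerVector B, IntegerVector Bprime,
                    int test, bool record, bool trace) {
  QM Aq = qm_from(A);
  size_t n = A.ncol();
  std::vector<int> Bv(B.begin(), B.end());
  std::vector<Ray> X = base_rays(Aq, Bv);
  std::vector<int> J = Bv;
  std::sort(J.begin(), J.end());
  Record L;
  if (record)                       // for a basis all pairs are colaminar
    for (size_t i = 0; i < X.size(); ++i)
      for (size_t j = i + 1; j < X.size(); ++j)
        L.insert(pkey(X[i].key, X[j].key));
  Counters C;
  C.peak_rays = (int)X.size();
  IntegerVector traj;
  traj.push_back((int)X.size());
  List steps(Bprime.size());
  for (int t = 0; t < Bprime.size(); ++t) {
    List st;
    insert_step(Aq, n, J, X, Bprime[t], test, record, L, C,
                trace ? &st : (List*)nullptr);
    if (trace) steps[t] = st;
    traj.push_back((int)X.size());
  }
  List out = rays_to_list(X, n);
  out["J"] = IntegerVector(J.begin(), J.end());
  out["counters"] = counters_to_list(C);
  out["trajectory"] = traj;
  if (trace) out["steps"] = steps;
  return out;
}

// ------------------------------------------------------------- pivoting ---

struct PivotOut {
  std::vector<QV> pts;          // neighbouring extreme points
  std::vector<std::string> keys;
  std::vector<bool> unbounded;  // per-ray flag when allowed
};

static std::string key_of_q(const QV& p) {
  std::string k;
  for (size_t i = 0; i < p.size(); ++i) {
    if (i) k += ',';
    k += p[i].get_str();
  }
  return k;
}

static PivotOut pivot_all(const QM& A, const QV& b, const QV& p,
                          const std::vector<int>& Z,
                          const std::vector<Ray>& X, bool allow_unbounded) {
  size_t m = A.size();
  std::set<int> Zs(Z.begin(), Z.end());
  PivotOut out;
  for (const Ray& r : X) {
    bool found = false;
    mpq_class lam;
    for (size_t t = 0; t < m; ++t) {
      if (Zs.count((int)t)) continue;
      mpq_class den = dot_q(A[t], r.d);
      if (sgn(den) <= 0) continue;
      mpq_class lt = (b[t] - dot_qq(A[t], p)) / den;
      if (!found || lt < lam) { lam = lt; found = true; }
    }
    if (!found) {
      if (allow_unbounded) {
        out.unbounded.push_back(true);
        out.pts.push_back(QV());
        out.keys.push_back("");
        continue;
      }
      std::string rk = key_of(r.d);
      stop("polytope is unbounded along extreme ray (%s); "
           "the feasible region is assumed compact", rk.c_str());
    }
    QV q(p.size());
    for (size_t j = 0; j < p.size(); ++j)
      q[j] = p[j] + lam * mpq_class(r.d[j]);
    out.unbounded.push_back(false);
    out.pts.push_back(q);
    out.keys.push_back(key_of_q(q));
  }
  return out;
}

// [[Rcpp::export]]
List cpp_neighbors(CharacterMatrix A, CharacterVector b, CharacterVector p,
                   CharacterMatrix rays, List active, bool allow_unbounded) {
  QM Aq = qm_from(A);
  QV bq = qv_from(b), pq = qv_from(p);
  std::vector<Ray> X = rays_from_list(rays, active);
  // active set of p
  std::vector<int> Z;
  for (size_t i = 0; i < Aq.size(); ++i)
    if (bq[i] - dot_qq(Aq[i], pq) == 0) Z.push_back((int)i);
  PivotOut po = pivot_all(Aq, bq, pq, Z, X, allow_unbounded);
  size_t n = pq.size();
  CharacterMatrix V(po.pts.size(), n);
  LogicalVector unb(po.pts.size());
  for (size_t i = 0; i < po.pts.size(); ++i) {
    unb[i] = po.unbounded[i];
    for (size_t j = 0; j < n; ++j)
      V(i, j) = po.unbounded[i] ? NA_STRING
                                : String(fmt_rat(po.pts[i][j]));
  }
  return List::create(_["neighbors"] = V, _["unbounded"] = unb);
}

// ------------------------------------------------------------ traversal ---

static std::vector<int> active_of_point(const QM& A, const QV& b,
                                        const QV& p) {
  std::vector<int> Z;
  for (size_t i = 0; i < A.size(); ++i)
    if (b[i] - dot_qq(A[i], p) == 0) Z.push_back((int)i);
  return Z;
}

// greedy basis: scan 'order', keep indices that increase the rank
static std::vector<int> greedy_basis(const QM& A, const std::vector<int>& order,
                                     size_t n) {
  std::vector<int> B;
  QM red;            // reduced rows so far
  for (int idx : order) {
    if (B.size() == n) break;
    QV v = A[idx];
    for (const QV& r : red) {         // eliminate against earlier pivots
      size_t pc = 0;
      while (pc < n && r[pc] == 0) ++pc;
      if (pc < n && v[pc] != 0) {
        mpq_class f = v[pc] / r[pc];
        for (size_t j = 0; j < n; ++j) v[j] -= f * r[j];
      }
    }
    bool nz = false;
    for (size_t j = 0; j < n; ++j) if (v[j] != 0) { nz = true; break; }
    if (nz) {
      // normalize leading entry for stable elimination
      size_t pc = 0;
      while (v[pc] == 0) ++pc;
      mpq_class d = v[pc];
      for (size_t j = 0; j < n; ++j) v[j] /= d;
      red.push_back(v);
      B.push_back(idx);
    }
  }
  if (B.size() != n) stop("active rows have rank %d < n = %d: not a vertex",
                          (int)B.size(), (int)n);
  return B;
}

// [[Rcpp::export]]
List cpp_choose_basis(CharacterMatrix A, IntegerVector Z) {
  QM Aq = qm_from(A);
  std::vector<int> Zv(Z.begin(), Z.end());
  std::sort(Zv.begin(), Zv.end());
  std::vector<int> B = greedy_basis(Aq, Zv, A.ncol());
  std::set<int> Bs(B.begin(), B.end());
  std::vector<int> Bp;
  for (int i : Zv) if (!Bs.count(i)) Bp.push_back(i);
  std::sort(B.begin(), B.end());
  return List::create(_["basis"] = IntegerVector(B.begin(), B.end()),
                      _["bprime"] = IntegerVector(Bp.begin(), Bp.end()));
}

// [[Rcpp::export]]
List cpp_tighten(CharacterMatrix A, CharacterVector b, CharacterVector x0) {
  QM Aq = qm_from(A);
  QV bq = qv_from(b), x = qv_from(x0);
  size_t n = A.ncol(), m = Aq.size();
  // feasibility
  for (size_t i = 0; i < m; ++i)
    if (bq[i] - dot_qq(Aq[i], x) < 0)
      stop("start point is infeasible (violates constraint %d)", (int)i);
  for (size_t iter = 0; iter <= n; ++iter) {
    std::vector<int> Z = active_of_point(Aq, bq, x);
    QM rows;
    for (int i : Z) rows.push_back(Aq[i]);
    QV d = nullspace_vec(rows, n);
    if (d.empty())
      break;                           // active rows have full rank: vertex
    bool moved = false;
    for (int pass = 0; pass < 2 && !moved; ++pass) {
      if (pass == 1)
        for (size_t j = 0; j < n; ++j) d[j] = -d[j];
      bool found = false;
      mpq_class lam;
      for (size_t t = 0; t < m; ++t) {
        if (std::find(Z.begin(), Z.end(), (int)t) != Z.end()) continue;
        mpq_class den = dot_qq(Aq[t], d);
        if (sgn(den) <= 0) continue;
        mpq_class lt = (bq[t] - dot_qq(Aq[t], x)) / den;
        if (!found || lt < lam) { lam = lt; found = true; }
      }
      if (found) {
        for (size_t j = 0; j < n; ++j) x[j] += lam * d[j];
        moved = true;
      }
    }
    if (!moved)
      stop("feasible region is unbounded: no blocking constraint along a "
           "null direction of the active rows");
  }
  return List::create(_["x"] = qv_to(x));
}

// slice the cone at vertex id, given basis/order policy
static std::vector<Ray> slice_at(const QM& A, size_t n,
                                 const std::vector<int>& Z,
                                 int test, bool record,
                                 std::mt19937* rng, Counters& C) {
  std::vector<int> order = Z;
  if (rng) std::shuffle(order.begin(), order.end(), *rng);
  std::vector<int> B = greedy_basis(A, order, n);
  std::set<int> Bs(B.begin(), B.end());
  std::vector<int> Bp;
  for (int i : Z) if (!Bs.count(i)) Bp.push_back(i);
  std::sort(Bp.begin(), Bp.end());
  if (rng) std::shuffle(Bp.begin(), Bp.end(), *rng);
  std::vector<Ray> X = base_rays(A, B);
  std::vector<int> J = B;
  std::sort(J.begin(), J.end());
  Record L;
  if (record)
    for (size_t i = 0; i < X.size(); ++i)
      for (size_t j = i + 1; j < X.size(); ++j)
        L.insert(pkey(X[i].key, X[j].key));
  if ((int)X.size() > C.peak_rays) C.peak_rays = (int)X.size();
  for (int k : Bp)
    insert_step(A, n, J, X, k, test, record, L, C, nullptr);
  return X;
}

// [[Rcpp::export]]
List cpp_skeleton(CharacterMatrix A, CharacterVector b, CharacterVector start,
                  int test, bool record, bool randomize, int seed,
                  bool allow_unbounded, double max_vertices) {
  QM Aq = qm_from(A);
  QV bq = qv_from(b), p = qv_from(start);
  size_t n = A.ncol();
  std::mt19937 rng((unsigned)seed);
  std::mt19937* rngp = randomize ? &rng : nullptr;

  // start must be an extreme point
  for (size_t i = 0; i < Aq.size(); ++i)
    if (bq[i] - dot_qq(Aq[i], p) < 0)
      stop("start point is infeasible (violates constraint %d)", (int)i);
  {
    std::vector<int> Z0 = active_of_point(Aq, bq, p);
    QM rows;
    for (int i : Z0) rows.push_back(Aq[i]);
    if (rank_q(rows) != (int)n)
      stop("start point is feasible but not extreme (active rank < n)");
  }

  std::map<std::string, int> id;
  std::vector<QV> verts;
  std::vector<std::vector<int> > Zs;
  std::vector<std::vector<int> > basis_used;
  std::deque<int> Q;
  std::set<std::pair<int, int> > E;
  Counters C;
  bool partial = false;
  int test_used = test;
  double slice_sec = 0, pivot_sec = 0;

  verts.push_back(p);
  id[key_of_q(p)] = 0;
  Zs.push_back(active_of_point(Aq, bq, p));
  basis_used.push_back(std::vector<int>());
  Q.push_back(0);

  while (!Q.empty()) {
    int v = Q.front();
    Q.pop_front();
    const std::vector<int>& Z = Zs[v];
    std::vector<Ray> X;
    auto t0 = std::chrono::steady_clock::now();
    if (test == 2 && v == 0) {
      // competition on the first vertex: keep the faster test
      Counters Ca, Cc;
      auto ta0 = std::chrono::steady_clock::now();
      std::mt19937 rca = rng, rcc = rng;   // same sub-stream for both
      std::vector<Ray> Xa = slice_at(Aq, n, Z, 0, record,
                                     randomize ? &rca : nullptr, Ca);
      auto ta1 = std::chrono::steady_clock::now();
      std::vector<Ray> Xc = slice_at(Aq, n, Z, 1, record,
                                     randomize ? &rcc : nullptr, Cc);
      auto ta2 = std::chrono::steady_clock::now();
      double dta = std::chrono::duration<double>(ta1 - ta0).count();
      double dtc = std::chrono::duration<double>(ta2 - ta1).count();
      test_used = (dta <= dtc) ? 0 : 1;
      X = (test_used == 0) ? Xa : Xc;
      Counters& Cw = (test_used == 0) ? Ca : Cc;
      C.tests += Cw.tests; C.hits += Cw.hits; C.rejects += Cw.rejects;
      C.dups += Cw.dups; C.pairs_considered += Cw.pairs_considered;
      if (Cw.peak_rays > C.peak_rays) C.peak_rays = Cw.peak_rays;
      if (randomize) rng = (test_used == 0) ? rca : rcc;
    } else {
      X = slice_at(Aq, n, Z, test == 2 ? test_used : test, record, rngp, C);
    }
    auto t1 = std::chrono::steady_clock::now();
    slice_sec += std::chrono::duration<double>(t1 - t0).count();

    PivotOut po = pivot_all(Aq, bq, verts[v], Z, X, allow_unbounded);
    std::set<std::string> seen_here;
    for (size_t i = 0; i < po.pts.size(); ++i) {
      if (po.unbounded[i]) { partial = true; continue; }
      if (!seen_here.insert(po.keys[i]).second)
        stop("two extreme rays reached the same neighbour: "
             "edge map is not injective (internal error)");
      int qid;
      std::map<std::string, int>::iterator it = id.find(po.keys[i]);
      if (it == id.end()) {
        qid = (int)verts.size();
        if ((double)qid >= max_vertices)
          stop("vertex cap (%g) exceeded", max_vertices);
        id[po.keys[i]] = qid;
        verts.push_back(po.pts[i]);
        Zs.push_back(active_of_point(Aq, bq, po.pts[i]));
        basis_used.push_back(std::vector<int>());
        Q.push_back(qid);
      } else {
        qid = it->second;
      }
      E.insert(std::make_pair(std::min(v, qid), std::max(v, qid)));
    }
    auto t2 = std::chrono::steady_clock::now();
    pivot_sec += std::chrono::duration<double>(t2 - t1).count();
    if (verts.size() % 64 == 0) Rcpp::checkUserInterrupt();
  }

  size_t nv = verts.size();
  CharacterMatrix V(nv, n);
  IntegerVector sigma(nv);
  List Zlist(nv);
  for (size_t i = 0; i < nv; ++i) {
    for (size_t j = 0; j < n; ++j) V(i, j) = fmt_rat(verts[i][j]);
    Zlist[i] = IntegerVector(Zs[i].begin(), Zs[i].end());
    sigma[i] = (int)Zs[i].size() - (int)n;
  }
  IntegerMatrix Em(E.size(), 2);
  IntegerVector deg(nv);
  int r = 0;
  for (const auto& e : E) {
    Em(r, 0) = e.first + 1;           // 1-based row ids into V
    Em(r, 1) = e.second + 1;
    deg[e.first] += 1;
    deg[e.second] += 1;
    ++r;
  }
  return List::create(
    _["vertices"] = V,
    _["edges"] = Em,
    _["active_sets"] = Zlist,
    _["sigma"] = sigma,
    _["degree"] = deg,
    _["counters"] = counters_to_list(C),
    _["timings"] = List::create(_["slicing_sec"] = slice_sec,
                                _["pivoting_sec"] = pivot_sec),
    _["test_used"] = test_used == 0 ? "algebraic" : "combinatorial",
    _["partial"] = partial);
}

// ------------------------------------------------------ basis enumeration --

// [[Rcpp::export]]
List cpp_enumerate_bases(CharacterMatrix A, IntegerVector Z, double cap,
                         bool keep) {
  QM Aq = qm_from(A);
  size_t n = A.ncol();
  std::vector<int> Zv(Z.begin(), Z.end());
  std::sort(Zv.begin(), Zv.end());
  size_t N = Zv.size();
  if (N < n) stop("active set smaller than the dimension");
  // total = choose(N, n)
  mpz_class tot;
  mpz_bin_uiui(tot.get_mpz_t(), (unsigned long)N, (unsigned long)n);
  if (tot > mpz_class((long)cap))
    stop("C(%d,%d) = %s subsets exceeds the enumeration cap (%g)",
         (int)N, (int)n, tot.get_str().c_str(), cap);
  std::vector<size_t> comb(n);
  for (size_t i = 0; i < n; ++i) comb[i] = i;
  double count = 0, scanned = 0;
  std::vector<std::vector<int> > found;
  bool done = false;
  while (!done) {
    QM rows;
    rows.reserve(n);
    for (size_t i = 0; i < n; ++i) rows.push_back(Aq[Zv[comb[i]]]);
    if (rank_q(rows) == (int)n) {
      count += 1;
      if (keep) {
        std::vector<int> s(n);
        for (size_t i = 0; i < n; ++i) s[i] = Zv[comb[i]];
        found.push_back(s);
      }
    }
    scanned += 1;
    if (((long)scanned) % 512 == 0) Rcpp::checkUserInterrupt();
    // next combination in lexicographic order
    long i = (long)n - 1;
    while (i >= 0 && comb[i] == N - n + i) --i;
    if (i < 0) done = true;
    else {
      ++comb[i];
      for (size_t j = i + 1; j < n; ++j) comb[j] = comb[j - 1] + 1;
    }
  }
  List out = List::create(_["count"] = count, _["total"] = scanned);
  if (keep) {
    IntegerMatrix Bm(found.size(), n);
    for (size_t i = 0; i < found.size(); ++i)
      for (size_t j = 0; j < n; ++j) Bm(i, j) = found[i][j];
    out["bases"] = Bm;
  }
  return out;
}

// Recession cone {x : A x <= 0} equals {0}?  (pointedness = boundedness of P)
// [[Rcpp::export]]
bool cpp_is_bounded(CharacterMatrix A) {
  QM Aq = qm_from(A);
  size_t n = A.ncol(), m = Aq.size();
  std::vector<int> all(m);
  for (size_t i = 0; i < m; ++i) all[i] = (int)i;
  QM copy = Aq;
  if (rank_q(copy) < (int)n) return false;   // lineality space present
  std::vector<int> B = greedy_basis(Aq, all, n);
  std::set<int> Bs(B.begin(), B.end());
  std::vector<int> Bp;
  for (size_t i = 0; i < m; ++i) if (!Bs.count((int)i)) Bp.push_back((int)i);
  std::vector<Ray> X = base_rays(Aq, B);
  std::vector<int> J = B;
  std::sort(J.begin(), J.end());
  Record L;
  Counters C;
  for (int k : Bp) {
    insert_step(Aq, n, J, X, k, 1, false, L, C, nullptr);
    if (X.empty()) return true;
  }
  return X.empty();
}

// ---------------------------------------------------- fine-grained helpers

// [[Rcpp::export]]
List cpp_partition(CharacterMatrix A, CharacterMatrix rays, int k) {
  QM Aq = qm_from(A);
  std::vector<int> pos, zer, neg;
  for (int j = 0; j < rays.ncol(); ++j) {
    std::vector<mpz_class> d(rays.nrow());
    for (int i = 0; i < rays.nrow(); ++i)
      d[i] = mpz_class(as<std::string>(rays(i, j)), 10);
    int s = sgn(dot_q(Aq[k], d));
    if (s < 0) pos.push_back(j);
    else if (s == 0) zer.push_back(j);
    else neg.push_back(j);
  }
  return List::create(_["pos"] = IntegerVector(pos.begin(), pos.end()),
                      _["zero"] = IntegerVector(zer.begin(), zer.end()),
                      _["neg"] = IntegerVector(neg.begin(), neg.end()));
}

// [[Rcpp::export]]
CharacterVector cpp_combine_ray(CharacterMatrix A, int k,
                                CharacterVector rho_neg,
                                CharacterVector rho_pos) {
  QM Aq = qm_from(A);
  size_t n = A.ncol();
  std::vector<mpz_class> dm(n), dp(n);
  for (size_t i = 0; i < n; ++i) {
    dm[i] = mpz_class(as<std::string>(rho_neg[i]), 10);
    dp[i] = mpz_class(as<std::string>(rho_pos[i]), 10);
  }
  mpq_class sm = dot_q(Aq[k], dm), sp = dot_q(Aq[k], dp);
  if (sgn(sm) <= 0)
    stop("rho_neg must satisfy a_k . rho > 0 (infeasible side)");
  if (sgn(sp) >= 0)
    stop("rho_pos must satisfy a_k . rho < 0 (feasible side)");
  QV phi(n);
  for (size_t i = 0; i < n; ++i)
    phi[i] = sm * mpq_class(dp[i]) - sp * mpq_class(dm[i]);
  std::vector<mpz_class> d = primitive(phi);
  CharacterVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = d[i].get_str();
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_ray_active(CharacterMatrix A, CharacterVector ray,
                             IntegerVector J) {
  QM Aq = qm_from(A);
  std::vector<mpz_class> d(ray.size());
  for (int i = 0; i < ray.size(); ++i)
    d[i] = mpz_class(as<std::string>(ray[i]), 10);
  std::vector<int> Jv(J.begin(), J.end());
  std::vector<int> act = act_of(Aq, d, Jv);
  return IntegerVector(act.begin(), act.end());
}

// [[Rcpp::export]]
std::string cpp_step_length(CharacterMatrix A, CharacterVector b,
                            CharacterVector p, CharacterVector ray, int t) {
  QM Aq = qm_from(A);
  QV bq = qv_from(b), pq = qv_from(p);
  std::vector<mpz_class> d(ray.size());
  for (int i = 0; i < ray.size(); ++i)
    d[i] = mpz_class(as<std::string>(ray[i]), 10);
  mpq_class den = dot_q(Aq[t], d);
  if (sgn(den) <= 0)
    stop("constraint %d is not blocking along the ray (a_t . rho <= 0)", t);
  mpq_class lam = (bq[t] - dot_qq(Aq[t], pq)) / den;
  return fmt_rat(lam);
}
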