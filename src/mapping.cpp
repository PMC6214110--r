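// Rigid superposition (Kabsch) and exhaustive feature-correspondence search.
// Hot path of hypothesis generation: every cost evaluation maps all training
// compounds, so the enumeration lives in C++.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Transform {
  arma::mat33 R;
  arma::vec3 t;
};

// Least-squares proper rotation + translation taking X onto Y (row = point).
// With fewer than 3 points the rotation is left at identity and only the
// centroids are matched (a plane/line does not pin down a rotation).
Transform kabsch(const arma::mat& X, const arma::mat& Y, double& rmsd) {
  Transform tr;
  arma::rowvec mx = arma::mean(X, 0), my = arma::mean(Y, 0);
  if (X.n_rows < 3) {
    tr.R.eye();
    tr.t = (my - mx).t();
  } else {
    arma::mat Xc = X.each_row() - mx, Yc = Y.each_row() - my;
    arma::mat H = Xc.t() * Yc;
    arma::mat U, V;
    arma::vec s;
    arma::svd(U, s, V, H);
    double d = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
    arma::mat D = arma::eye(3, 3);
    D(2, 2) = d;
    tr.R = V * D * U.t();
    tr.t = my.t() - tr.R * mx.t();
  }
  double ss = 0;
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    arma::vec3 p = tr.R * X.row(i).t() + tr.t - Y.row(i).t();
    ss += arma::dot(p, p);
  }
  rmsd = std::sqrt(ss / X.n_rows);
  return tr;
}

struct Best {
  double fit = -1.0;
  double rmsd = R_PosInf;
  int conformer = NA_INTEGER;
  std::vector<int> assign;  // per hypothesis feature: cloud row (1-based), 0 = omitted
  std::vector<double> disp;
  Transform tr;
  bool found = false;
};

// Lexicographic comparison of assignments; omitted (0) sorts last so that,
// all else equal, matching a feature beats omitting it.
bool lex_less(const std::vector<int>& a, const std::vector<int>& b, int big) {
  for (size_t i = 0; i < a.size(); ++i) {
    int ai = a[i] == 0 ? big : a[i], bi = b[i] == 0 ? big : b[i];
    if (ai != bi) return ai < bi;
  }
  return false;
}

struct Searcher {
  const arma::mat& cloud;       // rows of one conformer
  const std::vector<int>& ctype;
  const arma::mat& hyp;
  const std::vector<int>& htype;
  const arma::vec& tol;
  const arma::vec& wt;
  int max_omitted;
  int conformer_id;
  Best& best;
  std::vector<int> assign;
  std::vector<char> used;

  Searcher(const arma::mat& cl, const std::vector<int>& ct, const arma::mat& hy,
           const std::vector<int>& ht, const arma::vec& to, const arma::vec& we,
           int mo, int conf, Best& b)
      : cloud(cl), ctype(ct), hyp(hy), htype(ht), tol(to), wt(we),
        max_omitted(mo), conformer_id(conf), best(b),
        assign(hy.n_rows, 0), used(cl.n_rows, 0) {}

  void evaluate() {
    std::vector<int> midx;
    for (size_t j = 0; j < assign.size(); ++j)
      if (assign[j] > 0) midx.push_back((int)j);
    if (midx.empty()) return;
    arma::mat X(midx.size(), 3), Y(midx.size(), 3);
    for (size_t k = 0; k < midx.size(); ++k) {
      X.row(k) = cloud.row(assign[midx[k]] - 1);
      Y.row(k) = hyp.row(midx[k]);
    }
    double rmsd;
    Transform tr = kabsch(X, Y, rmsd);
    double fit = 0;
    std::vector<double> disp(assign.size(), NA_REAL);
    for (size_t k = 0; k < midx.size(); ++k) {
      arma::vec3 p = tr.R * X.row(k).t() + tr.t - Y.row(k).t();
      double d = arma::norm(p);
      disp[midx[k]] = d;
      double u = 1.0 - (d / tol(midx[k])) * (d / tol(midx[k]));
      if (u > 0) fit += wt(midx[k]) * u;
    }
    bool better = false;
    if (!best.found) {
      better = true;
    } else if (fit > best.fit + 1e-12) {
      better = true;
    } else if (std::abs(fit - best.fit) <= 1e-12) {
      if (rmsd < best.rmsd - 1e-12) {
        better = true;
      } else if (std::abs(rmsd - best.rmsd) <= 1e-12) {
        if (conformer_id < best.conformer) better = true;
        else if (conformer_id == best.conformer &&
                 lex_less(assign, best.assign, (int)cloud.n_rows + 1))
          better = true;
      }
    }
    if (better) {
      best.found = true;
      best.fit = fit;
      best.rmsd = rmsd;
      best.conformer = conformer_id;
      best.assign = assign;
      best.disp = disp;
      best.tr = tr;
    }
  }

  void search(size_t j, int omitted) {
    if (j == assign.size()) {
      evaluate();
      return;
    }
    for (arma::uword i = 0; i < cloud.n_rows; ++i) {
      if (!used[i] && ctype[i] == htype[j]) {
        used[i] = 1;
        assign[j] = (int)i + 1;
        search(j + 1, omitted);
        used[i] = 0;
      }
    }
    if (omitted < max_omitted) {
      assign[j] = 0;
      search(j + 1, omitted + 1);
    }
    assign[j] = 0;
  }
};

Best search_all(const arma::mat& pos, const std::vector<int>& type,
                const std::vector<int>& conf, const arma::mat& hyp,
                const std::vector<int>& htype, const arma::vec& tol,
                const arma::vec& wt, int max_omitted) {
  Best best;
  std::vector<int> confs(conf);
  std::sort(confs.begin(), confs.end());
  confs.erase(std::unique(confs.begin(), confs.end()), confs.end());
  for (int c : confs) {
    std::vector<arma::uword> rows;
    for (size_t i = 0; i < conf.size(); ++i)
      if (conf[i] == c) rows.push_back((arma::uword)i);
    arma::mat sub(rows.size(), 3);
    std::vector<int> stype(rows.size());
    for (size_t i = 0; i < rows.size(); ++i) {
      sub.row(i) = pos.row(rows[i]);
      stype[i] = type[rows[i]];
    }
    Best local;
    Searcher s(sub, stype, hyp, htype, tol, wt, max_omitted, c, local);
    s.search(0, 0);
    if (local.found) {
      // translate local (per-conformer) rows back to rows of the full cloud
      for (size_t j = 0; j < local.assign.size(); ++j)
        if (local.assign[j] > 0)
          local.assign[j] = (int)rows[local.assign[j] - 1] + 1;
      bool better = false;
      if (!best.found) better = true;
      else if (local.fit > best.fit + 1e-12) better = true;
      else if (std::abs(local.fit - best.fit) <= 1e-12 &&
               local.rmsd < best.rmsd - 1e-12) better = true;
      if (better) best = local;
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export(name = ".rcpp_kabsch")]]
List rcpp_kabsch(const arma::mat& x, const arma::mat& y) {
  double rmsd;
  Transform tr = kabsch(x, y, rmsd);
  return List::create(_["rotation"] = arma::mat(tr.R),
                      _["translation"] = NumericVector(tr.t.begin(), tr.t.end()),
                      _["rmsd"] = rmsd);
}

// [[Rcpp::export(name = ".rcpp_best_mapping")]]
List rcpp_best_mapping(const arma::mat& pos, const IntegerVector& type,
                       const IntegerVector& conf, const arma::mat& hyp,
                       const IntegerVector& htype, const arma::vec& tol,
                       const arma::vec& wt, int max_omitted) {
  std::vector<int> t(type.begin(), type.end());
  std::vector<int> cf(conf.begin(), conf.end());
  std::vector<int> ht(htype.begin(), htype.end());
  Best b = search_all(pos, t, cf, hyp, ht, tol, wt, max_omitted);
  if (!b.found) {
    return List::create(_["found"] = false, _["fit"] = 0.0);
  }
  return List::create(
      _["found"] = true, _["fit"] = b.fit, _["rmsd"] = b.rmsd,
      _["conformer"] = b.conformer,
      _["assignment"] = IntegerVector(b.assign.begin(), b.assign.end()),
      _["displacements"] = NumericVector(b.disp.begin(), b.disp.end()),
      _["rotation"] = arma::mat(b.tr.R),
      _["translation"] = NumericVector(b.tr.t.begin(), b.tr.t.end()));
}

// Batch fit values for many compounds against one hypothesis: clouds is a
// list of [pos (n x 3), type (int), conf (int)] triples.
// [[Rcpp::export(name = ".rcpp_batch_fits")]]
NumericVector rcpp_batch_fits(const List& clouds, const arma::mat& hyp,
                              const IntegerVector& htype, const arma::vec& tol,
                              const arma::vec& wt, int max_omitted) {
  std::vector<int> ht(htype.begin(), htype.end());
  NumericVector out(clouds.size());
  for (int i = 0; i < clouds.size(); ++i) {
    List cl = clouds[i];
    arma::mat pos = as<arma::mat>(cl[0]);
    IntegerVector type = cl[1];
    IntegerVector conf = cl[2];
    std::vector<int> t(type.begin(), type.end());
    std::vector<int> cf(conf.begin(), conf.end());
    Best b = search_all(pos, t, cf, hyp, ht, tol, wt, max_omitted);
    out[i] = b.found ? b.fit : 0.0;
  }
  return out;
}

// Per-feature match contributions u_f = max(0, 1 - (d_f/t_f)^2) of the best
// mapping of each compound (rows) against one hypothesis (columns); zero for
// omitted features and unmapped compounds. Used by the weight regression.
// [[Rcpp::export(name = ".rcpp_batch_contribs")]]
NumericMatrix rcpp_batch_contribs(const List& clouds, const arma::mat& hyp,
                                  const IntegerVector& htype,
                                  const arma::vec& tol, const arma::vec& wt,
                                  int max_omitted) {
  std::vector<int> ht(htype.begin(), htype.end());
  NumericMatrix out(clouds.size(), (int)hyp.n_rows);
  for (int i = 0; i < clouds.size(); ++i) {
    List cl = clouds[i];
    arma::mat pos = as<arma::mat>(cl[0]);
    IntegerVector type = cl[1];
    IntegerVector conf = cl[2];
    std::vector<int> t(type.begin(), type.end());
    std::vector<int> cf(conf.begin(), conf.end());
    Best b = search_all(pos, t, cf, hyp, ht, tol, wt, max_omitted);
    if (!b.found) continue;
    for (size_t j = 0; j < b.disp.size(); ++j) {
      if (!ISNA(b.disp[j])) {
        double u = 1.0 - (b.disp[j] / tol(j)) * (b.disp[j] / tol(j));
        out(i, (int)j) = u > 0 ? u : 0.0;
      }
    }
  }
  return out;
}
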