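#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Full-information maximum-likelihood log-likelihood for multivariate-normal
// data with arbitrary missingness patterns.
//
// Cases are grouped into `patterns`: each pattern holds the indices of the
// observed coordinates (`idx`, 1-based), the row indices of the cases sharing
// that pattern (`rows`, 1-based into `Mu`), and the corresponding data block
// `Y` (n_i x length(idx)), extracted once on the R side. Means may vary by
// case (covariate-conditional models): `Mu` is the full n x p matrix of
// case-specific means. Covariances vary only by cell (e.g. latent-profile
// group): `sigmas` is a list of p x p matrices indexed by `cell[i]`.
//
// Returns -Inf when an implied sub-covariance is not positive definite; the
// R-side optimiser treats that as an infeasible iterate.

// [[Rcpp::export]]
double fiml_loglik_cpp(const List& patterns, const arma::mat& Mu,
                       const List& sigmas, const IntegerVector& cell) {
  const double LOG2PI = std::log(2.0 * M_PI);
  const int npat = patterns.size();
  std::vector<arma::mat> S(sigmas.size());
  for (int c = 0; c < sigmas.size(); ++c) S[c] = as<arma::mat>(sigmas[c]);

  double ll = 0.0;
  for (int i = 0; i < npat; ++i) {
    List p = patterns[i];
    arma::uvec idx = as<arma::uvec>(p["idx"]);
    arma::uvec rows = as<arma::uvec>(p["rows"]);
    idx -= 1;
    rows -= 1;
    arma::mat Y = as<arma::mat>(p["Y"]);
    const arma::mat& Sc = S[cell[i] - 1];

    arma::mat Ss = Sc.submat(idx, idx);
    arma::mat L;
    if (!arma::chol(L, Ss, "lower")) return R_NegInf;

    arma::mat D = (Y - Mu.submat(rows, idx)).t();   // k x n_i
    arma::mat Z = arma::solve(arma::trimatl(L), D);
    const double logdet = 2.0 * arma::accu(arma::log(L.diag()));
    const double k = static_cast<double>(idx.n_elem);
    const double n = static_cast<double>(Y.n_rows);
    ll += -0.5 * (n * (k * LOG2PI + logdet) + arma::accu(Z % Z));
  }
  return ll;
}

// Full objective (negative log-likelihood) and analytic gradient for the
// moderated-mediation model, so bootstrap refits do not pay for numerical
// differentiation. The joint vector per case is (M, y_1..y_T) (or just the
// outcome series for the reduced/total-effect model); means are
// case-specific, covariances group-specific. Gradients follow the standard
// FIML identities dL/dmu_i = S^-1 d_i and
// dL/dSigma = 0.5 (S^-1 d d' S^-1 - S^-1), chained through the structural
// parameterisation (log-SD, log-variance and atanh-rho transforms).
//
// `idx` carries the 1-based packed-parameter positions produced by the R
// bookkeeping, so the two sides cannot drift apart.

// [[Rcpp::export]]
List medmod_obj_cpp(const arma::vec& par, const List& idx, const List& dat) {
  const bool mediator = as<bool>(idx["mediator"]);
  const int G = as<int>(idx["G"]);
  const int q = as<int>(idx["q"]);
  const arma::vec X = as<arma::vec>(dat["X"]);
  const arma::mat Z = as<arma::mat>(dat["Z"]);          // n x q (q may be 0)
  const arma::uvec gi = as<arma::uvec>(dat["gi"]);      // 1-based
  const arma::vec times = as<arma::vec>(dat["times"]);
  const List patterns = dat["patterns"];
  const IntegerVector cell = dat["cell"];
  const int n = X.n_elem;
  const int T = times.n_elem;
  const int p = mediator ? T + 1 : T;

  auto iv = [&](const char* k) {
    arma::uvec u = as<arma::uvec>(idx[k]);
    return arma::uvec(u - 1);
  };
  auto expand = [&](const arma::uvec& ii) {
    arma::vec v(G);
    for (int g = 0; g < G; ++g) {
      v[g] = par[ii[ii.n_elem == 1 ? 0 : g]];
    }
    return v;
  };

  const arma::uvec i_beta00 = iv("beta00"), i_lpsi00 = iv("lpsi00"),
    i_beta10 = iv("beta10"), i_cp = iv("cp"), i_lss = iv("lss"),
    i_beta20 = iv("beta20"), i_ltheta = iv("ltheta"), i_arho = iv("arho");
  arma::uvec i_a0, i_a, i_lsm, i_b, i_gM, i_gS;
  if (mediator) { i_a0 = iv("a0"); i_a = iv("a"); i_lsm = iv("lsm");
    i_b = iv("b"); }
  if (q > 0) { i_gS = iv("gS"); if (mediator) i_gM = iv("gM"); }

  const arma::vec beta00 = par.elem(i_beta00);
  const arma::vec psi00 = arma::exp(par.elem(i_lpsi00));
  const arma::vec beta10 = par.elem(i_beta10);
  const arma::vec cprime = expand(i_cp);
  const double sz = std::exp(par[i_lss[0]]);
  const double sz2 = sz * sz;
  const double beta20i = par[i_beta20[0]];
  const arma::vec theta = arma::exp(par.elem(i_ltheta));
  const double rho = std::tanh(par[i_arho[0]]);
  arma::vec a0, a, sm, b;
  arma::mat gM, gS;
  if (mediator) {
    a0 = par.elem(i_a0); a = par.elem(i_a);
    sm = arma::exp(par.elem(i_lsm)); b = expand(i_b);
  }
  if (q > 0) {
    gS = arma::reshape(par.elem(i_gS), G, q);
    if (mediator) gM = arma::reshape(par.elem(i_gM), G, q);
  }

  const arma::vec lam = times;
  const arma::vec lam2i = arma::square(times) / 100.0;

  // case-specific means
  arma::vec covS(n, arma::fill::zeros), covM(n, arma::fill::zeros);
  arma::vec muM(n, arma::fill::zeros), s(n);
  for (int i = 0; i < n; ++i) {
    const int g = gi[i] - 1;
    if (q > 0) {
      covS[i] = arma::dot(Z.row(i), gS.row(g));
      if (mediator) covM[i] = arma::dot(Z.row(i), gM.row(g));
    }
    if (mediator) {
      muM[i] = a0[g] + a[g] * X[i] + covM[i];
      s[i] = beta10[g] + b[g] * muM[i] + cprime[g] * X[i] + covS[i];
    } else {
      s[i] = beta10[g] + cprime[g] * X[i] + covS[i];
    }
  }
  arma::mat Mu(n, p);
  for (int i = 0; i < n; ++i) {
    const int g = gi[i] - 1;
    const int off = mediator ? 1 : 0;
    if (mediator) Mu(i, 0) = muM[i];
    for (int t = 0; t < T; ++t) {
      Mu(i, off + t) = beta00[g] + s[i] * lam[t] + beta20i * lam2i[t];
    }
  }

  // group covariances
  arma::mat lagm(T, T);
  for (int j = 0; j < T; ++j) {
    for (int k = 0; k < T; ++k) lagm(j, k) = std::abs(j - k);
  }
  arma::mat Theta(T, T);
  for (int j = 0; j < T; ++j) {
    for (int k = 0; k < T; ++k) {
      Theta(j, k) = std::sqrt(theta[j] * theta[k]) * std::pow(rho, lagm(j, k));
    }
  }
  std::vector<arma::mat> Sigma(G);
  for (int g = 0; g < G; ++g) {
    const double svar = sz2 + (mediator ? b[g] * b[g] * sm[g] * sm[g] : 0.0);
    arma::mat SY = psi00[g] * arma::ones(T, T) + svar * (lam * lam.t()) + Theta;
    if (mediator) {
      arma::mat Sg(p, p);
      Sg(0, 0) = sm[g] * sm[g];
      arma::vec cmy = b[g] * sm[g] * sm[g] * lam;
      Sg.submat(0, 1, 0, p - 1) = cmy.t();
      Sg.submat(1, 0, p - 1, 0) = cmy;
      Sg.submat(1, 1, p - 1, p - 1) = SY;
      Sigma[g] = Sg;
    } else {
      Sigma[g] = SY;
    }
  }

  // FIML value, dL/dmu per case, dL/dSigma per group
  const double LOG2PI = std::log(2.0 * M_PI);
  double ll = 0.0;
  arma::mat gmu(n, p, arma::fill::zeros);
  std::vector<arma::mat> W(G, arma::mat(p, p, arma::fill::zeros));
  bool ok = true;
  for (int ip = 0; ip < patterns.size() && ok; ++ip) {
    List pt = patterns[ip];
    arma::uvec cols = as<arma::uvec>(pt["idx"]);  cols -= 1;
    arma::uvec rows = as<arma::uvec>(pt["rows"]); rows -= 1;
    const arma::mat Y = as<arma::mat>(pt["Y"]);
    const int g = cell[ip] - 1;
    arma::mat Ss = Sigma[g].submat(cols, cols);
    arma::mat Sinv;
    if (!arma::inv_sympd(Sinv, Ss)) { ok = false; break; }
    const double logdet = -std::log(arma::det(Sinv));
    const arma::mat D = Y - Mu.submat(rows, cols);     // ni x k
    const arma::mat A = D * Sinv;                      // dL/dmu rows
    const double ni = Y.n_rows, k = cols.n_elem;
    ll += -0.5 * (ni * (k * LOG2PI + logdet) + arma::accu(A % D));
    for (arma::uword r = 0; r < rows.n_elem; ++r) {
      for (arma::uword c = 0; c < cols.n_elem; ++c) {
        gmu(rows[r], cols[c]) += A(r, c);
      }
    }
    arma::mat Wp = 0.5 * (Sinv * (D.t() * D) * Sinv - ni * Sinv);
    W[g].submat(cols, cols) += Wp;
  }
  if (!ok || !std::isfinite(ll)) {
    return List::create(_["value"] = 1e10,
                        _["gradient"] = arma::vec(par.n_elem,
                                                  arma::fill::zeros));
  }

  // chain rule to packed parameters (gradient of the NEGATIVE loglik)
  arma::vec grad(par.n_elem, arma::fill::zeros);
  const int off = mediator ? 1 : 0;
  const arma::mat GY = gmu.cols(off, p - 1);
  const arma::vec SYv = GY * lam;
  const arma::vec SQv = GY * lam2i;
  const arma::vec S1v = arma::sum(GY, 1);
  const arma::vec gMc = mediator ? arma::vec(gmu.col(0)) :
    arma::vec(n, arma::fill::zeros);

  arma::mat WYYsum(T, T, arma::fill::zeros);
  for (int g = 0; g < G; ++g) {
    arma::uvec sel = arma::find(gi == (unsigned) (g + 1));
    const arma::vec Xg = X.elem(sel);
    const arma::vec SYg = SYv.elem(sel);
    arma::mat WYY = mediator ? arma::mat(W[g].submat(1, 1, p - 1, p - 1))
                             : W[g];
    WYYsum += WYY;
    const arma::vec lamW = WYY * lam;
    const double quadW = arma::dot(lam, lamW);

    grad[i_beta00[g]] += arma::accu(S1v.elem(sel));
    grad[i_beta10[g]] += arma::accu(SYg);
    grad[i_cp[i_cp.n_elem == 1 ? 0 : g]] += arma::dot(Xg, SYg);
    grad[i_lpsi00[g]] += psi00[g] * arma::accu(WYY);
    grad[i_lss[0]] += 2.0 * sz2 * quadW;
    if (q > 0) {
      const arma::mat Zg = Z.rows(sel);
      const arma::vec gq = Zg.t() * SYg;
      for (int j = 0; j < q; ++j) grad[i_gS[g + G * j]] += gq[j];
    }
    if (mediator) {
      const arma::vec base = gMc.elem(sel) + b[g] * SYg;
      grad[i_a0[g]] += arma::accu(base);
      grad[i_a[g]] += arma::dot(Xg, base);
      if (q > 0) {
        const arma::mat Zg = Z.rows(sel);
        const arma::vec gq = Zg.t() * base;
        for (int j = 0; j < q; ++j) grad[i_gM[g + G * j]] += gq[j];
      }
      const arma::vec wMY = arma::vectorise(W[g].submat(0, 1, 0, p - 1));
      const double wMM = W[g](0, 0);
      const double sm2 = sm[g] * sm[g];
      const double wMYlam = arma::dot(wMY, lam);
      const double dSigM2 = wMM + 2.0 * b[g] * wMYlam + b[g] * b[g] * quadW;
      grad[i_lsm[g]] += 2.0 * sm2 * dSigM2;
      const double bmean = arma::dot(muM.elem(sel), SYg);
      const double bcov = 2.0 * sm2 * wMYlam + 2.0 * b[g] * sm2 * quadW;
      grad[i_b[i_b.n_elem == 1 ? 0 : g]] += bmean + bcov;
    }
  }
  grad[i_beta20[0]] = arma::accu(SQv);
  for (int m = 0; m < T; ++m) {
    grad[i_ltheta[m]] = arma::dot(WYYsum.row(m), Theta.row(m));
  }
  double drho = 0.0;
  for (int j = 0; j < T; ++j) {
    for (int k = 0; k < T; ++k) {
      const double l = lagm(j, k);
      if (l > 0) {
        drho += WYYsum(j, k) * std::sqrt(theta[j] * theta[k]) * l *
          std::pow(rho, l - 1.0);
      }
    }
  }
  grad[i_arho[0]] = (1.0 - rho * rho) * drho;

  return List::create(_["value"] = -ll, _["gradient"] = -grad);
}
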