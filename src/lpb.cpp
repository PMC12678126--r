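// Finite-difference linear Poisson-Boltzmann kernel: successive
// over-relaxation on the 7-point stencil with edge-centred dielectric
// values, plus the Metropolis Monte Carlo kernel for multi-site titration.
//
// Units: lengths in Angstrom, energies in kcal/mol, potential in
// kcal/mol/e. The discretised equation per interior node i is
//   sum_e eps_e (phi_nb - phi_i) - h^2 kbar2 lambda_i phi_i = -4 pi C q_i / h
// with C = 332.06 kcal A / (mol e^2), q_i the trilinearly spread charge at
// the node, and kbar2 = eps_s * kappa^2 the modified screening factor.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export(name = ".lpb_sor")]]
List lpb_sor(NumericVector phi, NumericVector epsx, NumericVector epsy,
             NumericVector epsz, NumericVector lambda, NumericVector src,
             IntegerVector dims, double h, double kbar2, double tol,
             int maxIter, double omega) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector p = clone(phi);
  const double h2k = h * h * kbar2;

  double bnorm = 0.0;
  for (int t = 0; t < src.size(); ++t) bnorm += src[t] * src[t];
  bnorm = std::sqrt(bnorm);
  if (bnorm < 1e-30) bnorm = 1e-30;

  if (omega <= 0) {
    int nmax = std::max(nx, std::max(ny, nz));
    omega = 2.0 / (1.0 + std::sin(M_PI / nmax));
  }

  double res = R_PosInf;
  int iter = 0;
  bool converged = false;
  for (iter = 1; iter <= maxIter; ++iter) {
    for (int k = 1; k < nz - 1; ++k) {
      for (int j = 1; j < ny - 1; ++j) {
        for (int i = 1; i < nx - 1; ++i) {
          const int id = idx3(i, j, k, nx, ny);
          const double exm = epsx[idx3(i - 1, j, k, nx - 1, ny)];
          const double exp_ = epsx[idx3(i, j, k, nx - 1, ny)];
          const double eym = epsy[idx3(i, j - 1, k, nx, ny - 1)];
          const double eyp = epsy[idx3(i, j, k, nx, ny - 1)];
          const double ezm = epsz[idx3(i, j, k - 1, nx, ny)];
          const double ezp = epsz[idx3(i, j, k, nx, ny)];
          const double num = exm * p[id - 1] + exp_ * p[id + 1] +
            eym * p[id - nx] + eyp * p[id + nx] +
            ezm * p[id - nx * ny] + ezp * p[id + nx * ny] + src[id];
          const double den = exm + exp_ + eym + eyp + ezm + ezp +
            h2k * lambda[id];
          p[id] = (1.0 - omega) * p[id] + omega * num / den;
        }
      }
    }
    if (iter % 10 == 0 || iter == maxIter) {
      double rsum = 0.0;
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          for (int i = 1; i < nx - 1; ++i) {
            const int id = idx3(i, j, k, nx, ny);
            const double exm = epsx[idx3(i - 1, j, k, nx - 1, ny)];
            const double exp_ = epsx[idx3(i, j, k, nx - 1, ny)];
            const double eym = epsy[idx3(i, j - 1, k, nx, ny - 1)];
            const double eyp = epsy[idx3(i, j, k, nx, ny - 1)];
            const double ezm = epsz[idx3(i, j, k - 1, nx, ny)];
            const double ezp = epsz[idx3(i, j, k, nx, ny)];
            const double num = exm * p[id - 1] + exp_ * p[id + 1] +
              eym * p[id - nx] + eyp * p[id + nx] +
              ezm * p[id - nx * ny] + ezp * p[id + nx * ny] + src[id];
            const double den = exm + exp_ + eym + eyp + ezm + ezp +
              h2k * lambda[id];
            const double r = num - den * p[id];
            rsum += r * r;
          }
        }
      }
      res = std::sqrt(rsum) / bnorm;
      if (res <= tol) { converged = true; break; }
    }
  }
  if (iter > maxIter) iter = maxIter;
  return List::create(_["phi"] = p, _["converged"] = converged,
                      _["iterations"] = iter, _["residual"] = res);
}

// Metropolis Monte Carlo multi-site titration.
// States x in {0,1}^n (1 = protonated); energy
//   E(x) = sum_mu x_mu g_mu + 0.5 sum_{mu != nu} q_mu(x) q_nu(x) W_munu
//        + sum_penalties
// with q_mu(x) = qd_mu + x_mu (qp - qd = +1 for every site).
// One sweep = n single-site attempts + one attempt per listed strong pair.
// Uses R's RNG (unif_rand) so set.seed() gives bitwise reproducibility.

static double totalEnergy(const std::vector<int> &x, const NumericVector &g,
                          const NumericMatrix &W, const NumericVector &qd,
                          const IntegerMatrix &pen,
                          const NumericVector &penE) {
  const int n = x.size();
  double E = 0.0;
  for (int m = 0; m < n; ++m) {
    if (x[m]) E += g[m];
    const double qm = qd[m] + x[m];
    for (int v = m + 1; v < n; ++v)
      E += qm * (qd[v] + x[v]) * W(m, v);
  }
  for (int r = 0; r < pen.nrow(); ++r)
    if (x[pen(r, 0)] == pen(r, 2) && x[pen(r, 1)] == pen(r, 3))
      E += penE[r];
  return E;
}

// [[Rcpp::export(name = ".mc_titrate")]]
List mc_titrate(NumericVector g, NumericMatrix W, NumericVector qd,
                double beta, int sweeps, int burnin, IntegerMatrix pairs,
                IntegerMatrix pen, NumericVector penE, int nBatch) {
  const int n = g.size();
  RNGScope scope;
  std::vector<int> x(n);
  for (int m = 0; m < n; ++m) x[m] = unif_rand() < 0.5 ? 1 : 0;

  std::vector<double> acc(n, 0.0);
  const int nKept = sweeps - burnin;
  if (nBatch > nKept) nBatch = std::max(1, nKept);
  const int batchLen = nKept / nBatch;
  NumericMatrix batchSum(nBatch, n);

  auto deltaSingle = [&](int m) {
    // flip site m: 0->1 adds +1 to q_m, 1->0 adds -1
    const double dq = x[m] ? -1.0 : 1.0;
    double dE = dq * g[m];
    for (int v = 0; v < n; ++v)
      if (v != m) dE += dq * (qd[v] + x[v]) * W(m, v);
    if (pen.nrow()) {
      const int newx = 1 - x[m];
      for (int r = 0; r < pen.nrow(); ++r) {
        const int a = pen(r, 0), b = pen(r, 1);
        if (a == m) {
          if (x[b] == pen(r, 3)) {
            if (newx == pen(r, 2)) dE += penE[r];
            if (x[m] == pen(r, 2)) dE -= penE[r];
          }
        } else if (b == m) {
          if (x[a] == pen(r, 2)) {
            if (newx == pen(r, 3)) dE += penE[r];
            if (x[m] == pen(r, 3)) dE -= penE[r];
          }
        }
      }
    }
    return dE;
  };

  for (int s = 0; s < sweeps; ++s) {
    for (int t = 0; t < n; ++t) {
      const int m = (int)(unif_rand() * n) % n;
      const double dE = deltaSingle(m);
      if (dE <= 0.0 || unif_rand() < std::exp(-beta * dE))
        x[m] = 1 - x[m];
    }
    for (int pr = 0; pr < pairs.nrow(); ++pr) {
      const int a = pairs(pr, 0), b = pairs(pr, 1);
      const double E0 = totalEnergy(x, g, W, qd, pen, penE);
      x[a] = 1 - x[a]; x[b] = 1 - x[b];
      const double E1 = totalEnergy(x, g, W, qd, pen, penE);
      const double dE = E1 - E0;
      if (!(dE <= 0.0 || unif_rand() < std::exp(-beta * dE))) {
        x[a] = 1 - x[a]; x[b] = 1 - x[b];  // reject
      }
    }
    if (s >= burnin) {
      const int kept = s - burnin;
      int b = kept / batchLen;
      if (b >= nBatch) b = nBatch - 1;
      for (int m = 0; m < n; ++m) batchSum(b, m) += x[m];
    }
  }

  NumericVector prob(n), se(n);
  std::vector<int> counts(nBatch, batchLen);
  counts[nBatch - 1] = nKept - batchLen * (nBatch - 1);
  for (int m = 0; m < n; ++m) {
    double tot = 0.0;
    for (int b = 0; b < nBatch; ++b) tot += batchSum(b, m);
    prob[m] = tot / nKept;
    double var = 0.0;
    for (int b = 0; b < nBatch; ++b) {
      const double bm = batchSum(b, m) / counts[b];
      var += (bm - prob[m]) * (bm - prob[m]);
    }
    se[m] = nBatch > 1 ? std::sqrt(var / (nBatch * (nBatch - 1.0))) : NA_REAL;
  }
  return List::create(_["prob"] = prob, _["se"] = se);
}
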