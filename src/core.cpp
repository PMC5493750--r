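// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Torque-definition seam.
//
// The microscopic model is fully specified by the two inline functions below.
// They must stay in sync with the R-level reference implementations
// (pair_torque(), drive_torque() in R/dynamics.R), which are the documented
// single source of truth for the functional forms:
//   drive:  T_d = -H * sin(theta - Theta)           (harmonic angular drive)
//   pair:   U_ij = -B(r) * cos(theta_i - phi_ij),   T_ij = -dU/dtheta_i
//           B(r) = B * (1 - r / (a_i + a_j))  for r < a_i + a_j, else 0
// phi_ij is the angle of r_i - r_j, so the pair torque rotates particle i
// toward pointing away from particle j.
// ---------------------------------------------------------------------------
static inline double drive_torque_c(double theta, double Theta, double H) {
  return -H * std::sin(theta - Theta);
}
static inline double pair_kernel_c(double r, double asum, double B) {
  return (r < asum) ? B * (1.0 - r / asum) : 0.0;
}
static inline double pair_torque_c(double theta_i, double phi_ij,
                                   double r, double asum, double B) {
  return -pair_kernel_c(r, asum, B) * std::sin(theta_i - phi_ij);
}

static inline double wrap_pos(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;  // guard the x/L rounding edge
  return x;
}
static inline double min_image(double d, double L) {
  if (d >  0.5 * L) d -= L;
  if (d < -0.5 * L) d += L;
  return d;
}

// Sweep-and-prune along x: maintain a (nearly) sorted index order, prune by
// the x-interval overlap of the per-pair cutoff, confirm with the full
// minimum-image distance. `order` is updated in place by insertion sort so
// successive calls on slowly evolving configurations cost O(N).
static inline void check_pair(int i, int j,
                              const std::vector<double>& xw,
                              const std::vector<double>& yw,
                              const std::vector<double>& a,
                              double Lx, double Ly,
                              std::vector<std::pair<int,int> >& pairs) {
  double asum = a[i] + a[j];
  double dx = min_image(xw[i] - xw[j], Lx);
  if (std::fabs(dx) >= asum) return;
  double dy = min_image(yw[i] - yw[j], Ly);
  if (dx * dx + dy * dy < asum * asum)
    pairs.push_back(std::make_pair(std::min(i, j), std::max(i, j)));
}

static void sap_pairs(const std::vector<double>& xw,
                      const std::vector<double>& yw,
                      const std::vector<double>& a,
                      double Lx, double Ly,
                      std::vector<int>& order,
                      std::vector<std::pair<int,int> >& pairs) {
  const int n = (int) xw.size();
  pairs.clear();
  // insertion sort by wrapped x: O(N) on the nearly sorted order of the
  // previous step
  for (int k = 1; k < n; ++k) {
    int idx = order[k];
    double xv = xw[idx];
    int m = k - 1;
    while (m >= 0 && xw[order[m]] > xv) { order[m + 1] = order[m]; --m; }
    order[m + 1] = idx;
  }
  double amax = 0.0;
  for (int i = 0; i < n; ++i) amax = std::max(amax, a[i]);
  const double cut_max = 2.0 * amax;
  if (Lx <= 2.0 * cut_max) {  // degenerate small box: brute force
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        check_pair(i, j, xw, yw, a, Lx, Ly, pairs);
    return;
  }
  // main sweep: x-interval overlap within the box
  for (int k = 0; k < n; ++k) {
    int i = order[k];
    for (int m = k + 1; m < n; ++m) {
      int j = order[m];
      if (xw[j] - xw[i] > cut_max) break;
      check_pair(i, j, xw, yw, a, Lx, Ly, pairs);
    }
  }
  // seam pass: right-edge particles against left-edge particles
  for (int k = n - 1; k >= 0; --k) {
    int i = order[k];
    if (Lx - xw[i] > cut_max) break;
    for (int m = 0; m < n; ++m) {
      int j = order[m];
      if (xw[j] + Lx - xw[i] > cut_max) break;
      if (i != j) check_pair(i, j, xw, yw, a, Lx, Ly, pairs);
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericVector x, NumericVector y,
                                 NumericVector a, double Lx, double Ly) {
  const int n = x.size();
  std::vector<double> xw(n), yw(n), av(n);
  for (int i = 0; i < n; ++i) {
    xw[i] = wrap_pos(x[i], Lx); yw[i] = wrap_pos(y[i], Ly); av[i] = a[i];
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int p, int q) { return xw[p] < xw[q]; });
  std::vector<std::pair<int,int> > pairs;
  sap_pairs(xw, yw, av, Lx, Ly, order, pairs);
  IntegerMatrix out(pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    out(k, 0) = pairs[k].first + 1;
    out(k, 1) = pairs[k].second + 1;
  }
  return out;
}

// Forward-Euler integration of the torque-coupled model in a periodic box.
// Positions are accumulated unwrapped (for displacement statistics) and
// wrapped on the fly for all pair geometry. Returns the order-parameter
// series, periodic snapshots (wrapped and unwrapped positions, angles) and
// the final state.
// [[Rcpp::export]]
List cpp_run(NumericVector x0, NumericVector y0, NumericVector theta0,
             NumericVector Theta, NumericVector a,
             double B, double H, double v0, double dt,
             double Lx, double Ly,
             int nsteps, int save_every, int w_every) {
  const int n = x0.size();
  std::vector<double> xu(n), yu(n), th(n), xw(n), yw(n), av(n), torque(n);
  for (int i = 0; i < n; ++i) {
    xu[i] = x0[i]; yu[i] = y0[i]; th[i] = theta0[i]; av[i] = a[i];
    xw[i] = wrap_pos(xu[i], Lx); yw[i] = wrap_pos(yu[i], Ly);
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int p, int q) { return xw[p] < xw[q]; });
  std::vector<std::pair<int,int> > pairs;

  const int n_w = nsteps / w_every + 1;
  NumericVector w_times(n_w), w_vals(n_w);
  const int n_fr = (save_every > 0) ? nsteps / save_every + 1 : 0;
  NumericMatrix fx(n_fr > 0 ? n : 0, n_fr), fy(n_fr > 0 ? n : 0, n_fr),
                fxu(n_fr > 0 ? n : 0, n_fr), fyu(n_fr > 0 ? n : 0, n_fr),
                fth(n_fr > 0 ? n : 0, n_fr);
  NumericVector ftimes(n_fr);
  int iw = 0, ifr = 0;

  for (int step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    if (step % w_every == 0 && iw < n_w) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) {
        double sv = std::sin(th[i] - Theta[i]);
        s += sv * sv;
      }
      w_times[iw] = t; w_vals[iw] = s / n; ++iw;
    }
    if (save_every > 0 && step % save_every == 0 && ifr < n_fr) {
      for (int i = 0; i < n; ++i) {
        fx(i, ifr) = xw[i]; fy(i, ifr) = yw[i];
        fxu(i, ifr) = xu[i]; fyu(i, ifr) = yu[i]; fth(i, ifr) = th[i];
      }
      ftimes[ifr] = t; ++ifr;
    }
    if (step == nsteps) break;

    sap_pairs(xw, yw, av, Lx, Ly, order, pairs);
    std::fill(torque.begin(), torque.end(), 0.0);
    for (size_t k = 0; k < pairs.size(); ++k) {
      int i = pairs[k].first, j = pairs[k].second;
      double dx = min_image(xw[i] - xw[j], Lx);
      double dy = min_image(yw[i] - yw[j], Ly);
      double r = std::sqrt(dx * dx + dy * dy);
      if (r == 0.0)
        stop("degenerate pair: particles %d and %d coincide", i + 1, j + 1);
      double asum = av[i] + av[j];
      double phi_ij = std::atan2(dy, dx);          // angle of r_i - r_j
      double phi_ji = std::atan2(-dy, -dx);
      torque[i] += pair_torque_c(th[i], phi_ij, r, asum, B);
      torque[j] += pair_torque_c(th[j], phi_ji, r, asum, B);
    }
    for (int i = 0; i < n; ++i) {
      double dxp = v0 * std::cos(th[i]) * dt;
      double dyp = v0 * std::sin(th[i]) * dt;
      xu[i] += dxp; yu[i] += dyp;
      xw[i] = wrap_pos(xw[i] + dxp, Lx);
      yw[i] = wrap_pos(yw[i] + dyp, Ly);
      th[i] += dt * (drive_torque_c(th[i], Theta[i], H) + torque[i]);
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["x"] = NumericVector(xw.begin(), xw.end()),
    _["y"] = NumericVector(yw.begin(), yw.end()),
    _["x_unwrapped"] = NumericVector(xu.begin(), xu.end()),
    _["y_unwrapped"] = NumericVector(yu.begin(), yu.end()),
    _["theta"] = NumericVector(th.begin(), th.end()),
    _["w_times"] = w_times, _["w_values"] = w_vals,
    _["frame_times"] = ftimes,
    _["frames_x"] = fx, _["frames_y"] = fy,
    _["frames_x_unwrapped"] = fxu, _["frames_y_unwrapped"] = fyu,
    _["frames_theta"] = fth);
}

// Two-body scattering on the unbounded plane: one right mover (Theta = 0)
// and one left mover (Theta = pi), interactions active from t = 0 (contact).
// Stops when the pair separates and the right mover has realigned with its
// drive, when the bound-pair criterion is met, or at tmax.
// [[Rcpp::export]]
List cpp_scatter(double x1, double y1, double th1,
                 double x2, double y2, double th2,
                 double a1, double a2,
                 double B, double H, double v0, double dt,
                 double tmax, double align_tol, double bound_travel,
                 int rec_every) {
  const double asum = a1 + a2;
  const int nmax = (int) std::ceil(tmax / dt);
  std::vector<double> tx1, ty1, tth1, tx2, ty2, tth2, tt;
  bool ever_separated = false;
  const double yc0 = 0.5 * (y1 + y2);
  std::string status = "timeout";
  int step = 0;
  for (; step <= nmax; ++step) {
    if (rec_every > 0 && step % rec_every == 0) {
      tt.push_back(step * dt);
      tx1.push_back(x1); ty1.push_back(y1); tth1.push_back(th1);
      tx2.push_back(x2); ty2.push_back(y2); tth2.push_back(th2);
    }
    double dx = x1 - x2, dy = y1 - y2;
    double r = std::sqrt(dx * dx + dy * dy);
    if (r == 0.0) stop("degenerate pair: coincident particles");
    if (r > asum) ever_separated = true;
    // unbound exit: well separated and realigned with the drive
    double dev1 = std::atan2(std::sin(th1), std::cos(th1));
    if (r > 2.0 * asum && std::fabs(dev1) < align_tol) {
      status = "scattered"; break;
    }
    // bound pair: never separated, centre carried along +-y far enough
    double yc = 0.5 * (y1 + y2);
    if (!ever_separated && std::fabs(yc - yc0) >= bound_travel) {
      status = "bound"; break;
    }
    double T1 = 0.0, T2 = 0.0;
    if (r < asum) {
      double phi12 = std::atan2(dy, dx);
      double phi21 = std::atan2(-dy, -dx);
      T1 = pair_torque_c(th1, phi12, r, asum, B);
      T2 = pair_torque_c(th2, phi21, r, asum, B);
    }
    double c1 = std::cos(th1), s1 = std::sin(th1);
    double c2 = std::cos(th2), s2 = std::sin(th2);
    x1 += v0 * c1 * dt; y1 += v0 * s1 * dt;
    x2 += v0 * c2 * dt; y2 += v0 * s2 * dt;
    th1 += dt * (drive_torque_c(th1, 0.0, H) + T1);
    th2 += dt * (drive_torque_c(th2, M_PI, H) + T2);
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["y_out"] = y1, _["x_out"] = x1,
    _["theta_out"] = th1, _["status"] = status,
    _["t_end"] = step * dt,
    _["traj"] = DataFrame::create(
      _["t"] = tt, _["x_r"] = tx1, _["y_r"] = ty1, _["theta_r"] = tth1,
      _["x_l"] = tx2, _["y_l"] = ty2, _["theta_l"] = tth2));
}

// Species-resolved 2D pair-displacement histograms with minimum-image
// displacements. species is 0 (right) / 1 (left). Window |dx|<xmax,
// |dy|<ymax, square bins of side `bin`. Returns counts for rr, rl, lr, ll.
// [[Rcpp::export]]
List cpp_pair_hist(NumericVector x, NumericVector y, IntegerVector species,
                   double Lx, double Ly, double xmax, double ymax,
                   double bin) {
  const int n = x.size();
  const int nx = (int) std::round(2.0 * xmax / bin);
  const int ny = (int) std::round(2.0 * ymax / bin);
  std::vector<arma::mat> h(4);
  for (int k = 0; k < 4; ++k) h[k] = arma::zeros<arma::mat>(nx, ny);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(x[j] - x[i], Lx);
      double dy = min_image(y[j] - y[i], Ly);
      // displacement from i to j, and its reverse
      for (int dir = 0; dir < 2; ++dir) {
        double ddx = dir == 0 ? dx : -dx;
        double ddy = dir == 0 ? dy : -dy;
        int si = dir == 0 ? species[i] : species[j];
        int sj = dir == 0 ? species[j] : species[i];
        if (std::fabs(ddx) < xmax && std::fabs(ddy) < ymax) {
          int bx = (int) std::floor((ddx + xmax) / bin);
          int by = (int) std::floor((ddy + ymax) / bin);
          if (bx >= 0 && bx < nx && by >= 0 && by < ny)
            h[2 * si + sj](bx, by) += 1.0;
        }
      }
    }
  }
  return List::create(_["rr"] = h[0], _["rl"] = h[1],
                      _["lr"] = h[2], _["ll"] = h[3]);
}

// Semi-implicit Euler-Maruyama integration of the linearized two-species
// hydrodynamic equations in Fourier space, with conserved (divergence-form)
// white noise of variance 2T. Modes evolve independently; the q = 0 mode and
// the Nyquist rows/columns are pinned to zero (mass conservation, reality).
// Spectral convention: rho_hat(q) = sum_r rho(r) exp(-i q r) dA, so the
// stationary E|rho_hat|^2 equals (box area) * S(q).
// [[Rcpp::export]]
List cpp_spde(int n, double L, double dt, int nsteps, int burn,
              int sample_every,
              double Tx, double Ty, double v, double kappa,
              double Dx, double Dy, double Dtx, double Dty,
              int seed, double init_amp) {
  const double A = L * L;
  arma::vec q1(n);
  for (int k = 0; k < n; ++k) {
    int kk = (k <= n / 2) ? k : k - n;
    q1[k] = 2.0 * M_PI * kk / L;
  }
  arma::mat QX(n, n), QY(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) { QX(i, j) = q1[i]; QY(i, j) = q1[j]; }
  arma::mat Q2 = QX % QX + QY % QY;

  arma::cx_mat lam = arma::cx_mat(Dx * QX % QX + Dy * QY % QY, v * QX);
  arma::cx_mat mu  = arma::cx_mat(-(Dtx * QX % QX + Dty * QY % QY),
                                  kappa * QX);
  // mode mask: drop q = 0 and Nyquist lines
  arma::mat mask = arma::ones<arma::mat>(n, n);
  mask(0, 0) = 0.0;
  if (n % 2 == 0) {
    for (int j = 0; j < n; ++j) { mask(n / 2, j) = 0.0; mask(j, n / 2) = 0.0; }
  }
  // stability check on unmasked modes
  arma::mat det_ct = arma::square(arma::abs(lam)) - arma::square(arma::abs(mu));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (mask(i, j) > 0 && (det_ct(i, j) <= 0 || lam(i, j).real() <= 0))
        stop("unstable or marginal mode at grid index (%d, %d)", i + 1, j + 1);

  // per-mode semi-implicit update matrix: inv(I - dt M)
  arma::cx_mat one(arma::ones<arma::mat>(n, n), arma::zeros<arma::mat>(n, n));
  arma::cx_mat g11 = one + dt * lam;           // 1 + dt*lambda
  arma::cx_mat g22 = one + dt * arma::conj(lam);
  arma::cx_mat det = g11 % g22 - dt * dt * (mu % arma::conj(mu));
  arma::cx_mat a11 = g22 / det, a12 = dt * mu / det;
  arma::cx_mat a21 = dt * arma::conj(mu) / det, a22 = g11 / det;

  // noise amplitude per mode: E|eta|^2 = 2 (Tx qx^2 + Ty qy^2) A dt,
  // split evenly between Re and Im
  arma::mat amp = arma::sqrt((Tx * QX % QX + Ty * QY % QY) * A * dt);
  // -q index permutation
  arma::umat rev_i(n, n), rev_j(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      rev_i(i, j) = (n - i) % n; rev_j(i, j) = (n - j) % n;
    }

  std::mt19937_64 rng((uint64_t) seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  auto herm_draw = [&](arma::cx_mat& out, const arma::mat& amplitude) {
    arma::mat re(n, n), im(n, n);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) { re(i, j) = nd(rng); im(i, j) = nd(rng); }
    arma::cx_mat z(re, im);
    arma::cx_mat zr(n, n);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        zr(i, j) = std::conj(z(rev_i(i, j), rev_j(i, j)));
    out = (z + zr) / std::sqrt(2.0);
    out %= arma::cx_mat(amplitude % mask, arma::zeros<arma::mat>(n, n));
  };
  auto herm_noise = [&](arma::cx_mat& out) { herm_draw(out, amp); };

  arma::cx_mat rp(n, n, arma::fill::zeros), rm(n, n, arma::fill::zeros);
  if (init_amp > 0) {
    arma::mat amp0(n, n); amp0.fill(init_amp);
    herm_draw(rp, amp0); herm_draw(rm, amp0);
  }
  arma::cx_mat ep(n, n), em(n, n);
  arma::mat Spp(n, n, arma::fill::zeros), Smm(n, n, arma::fill::zeros);
  arma::cx_mat Spm(n, n, arma::fill::zeros);
  long nsamp = 0;

  for (int step = 0; step < nsteps; ++step) {
    herm_noise(ep); herm_noise(em);
    arma::cx_mat up = rp + ep, um = rm + em;
    arma::cx_mat rp_new = a11 % up + a12 % um;
    arma::cx_mat rm_new = a21 % up + a22 % um;
    rp = rp_new; rm = rm_new;
    if (step >= burn && ((step - burn) % sample_every == 0)) {
      Spp += arma::square(arma::abs(rp));
      Smm += arma::square(arma::abs(rm));
      Spm += rp % arma::conj(rm);
      ++nsamp;
    }
    if (step % 5000 == 0) Rcpp::checkUserInterrupt();
  }
  if (nsamp == 0 && !(Tx == 0 && Ty == 0 && init_amp > 0))
    stop("no samples collected: increase nsteps beyond burn");
  double norm = std::max(1.0, (double) nsamp) * A;
  double final_norm = arma::norm(rp, "fro") + arma::norm(rm, "fro");
  return List::create(
    _["S_rr"] = arma::mat(Spp / norm),
    _["S_ll"] = arma::mat(Smm / norm),
    _["S_rl_re"] = arma::mat(arma::real(Spm) / norm),
    _["S_rl_im"] = arma::mat(arma::imag(Spm) / norm),
    _["n_samples"] = (double) nsamp,
    _["final_norm"] = final_norm,
    _["qx"] = q1, _["qy"] = q1,
    _["mask"] = mask);
}
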