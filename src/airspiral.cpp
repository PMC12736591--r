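// Core numerics: the per-axis two-state attitude Kalman scan and the
// stacked-LSTM + attention network (forward pass, cross-entropy loss and
// full backpropagation). Gate layout in all 4H-wide matrices is
// [input | forget | cell | output].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Two-state tilt filter (state = [angle, gyro bias]) specialized for speed:
// A = [[1,-dt],[0,1]], B = [dt,0]', H = [1,0], Q = diag(qa,qb)*dt, scalar R.
// u = gyro rate (deg/s), z = accelerometer tilt angle (deg). The first output
// is the initial posterior (angle0, bias 0, P0 = I); subsequent steps follow
// the predict/update recursion with covariance symmetrization.
// [[Rcpp::export]]
List kalman_scan_2state(const arma::vec& u, const arma::vec& z, double dt,
                        double q_angle, double q_bias, double r_angle,
                        double angle0) {
  const int n = u.n_elem;
  if ((int)z.n_elem != n) stop("u and z must have equal length");
  arma::vec angle(n), bias(n), ptrace(n);
  double ang = angle0, b = 0.0;
  double p00 = 1.0, p01 = 0.0, p11 = 1.0;
  angle[0] = ang; bias[0] = b; ptrace[0] = p00 + p11;
  const double qa = q_angle * dt, qb = q_bias * dt;
  for (int k = 1; k < n; ++k) {
    // time update
    double ang_bar = ang + dt * (u[k] - b);
    double p00b = p00 - 2.0 * dt * p01 + dt * dt * p11 + qa;
    double p01b = p01 - dt * p11;
    double p11b = p11 + qb;
    // measurement update
    double S = p00b + r_angle;
    if (S <= 0) stop("singular innovation covariance in kalman_scan_2state");
    double K0 = p00b / S, K1 = p01b / S;
    double innov = z[k] - ang_bar;
    ang = ang_bar + K0 * innov;
    b = b + K1 * innov;
    p00 = (1.0 - K0) * p00b;
    double p01_a = (1.0 - K0) * p01b;
    double p01_b = p01b - K1 * p00b;
    p01 = 0.5 * (p01_a + p01_b);
    p11 = p11b - K1 * p01b;
    angle[k] = ang; bias[k] = b; ptrace[k] = p00 + p11;
  }
  return List::create(
      _["angle"] = NumericVector(angle.begin(), angle.end()),
      _["bias"] = NumericVector(bias.begin(), bias.end()),
      _["P_trace"] = NumericVector(ptrace.begin(), ptrace.end()));
}

static arma::cube as_cube(SEXP s) {
  NumericVector v(s);
  if (Rf_isNull(v.attr("dim"))) stop("expected a 3-d array");
  IntegerVector d = v.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  arma::cube c(v.begin(), d[0], d[1], d[2], false, true);
  return arma::cube(c);  // deep copy; inputs stay untouched
}

// Forward (and optionally backward) pass of the LAFNet family on one batch.
//
// X:        cube, slice t is the N x C feature matrix at time step t.
// params:   named list Wx1, Wh1, b1, ..., Wx<L>, Wh<L>, b<L>, wa, ba, Wc, bc.
//           Wx: (in x 4H), Wh: (H x 4H), b: 4H, wa: H, ba: scalar,
//           Wc: (H x n_classes), bc: n_classes.
// attention: 0 none (final hidden state pooling), 1 linear, 2 tanh.
// y:        0-based class labels (length N) or empty for inference.
// mask_h:   optional N x H x T inverted-dropout mask on the top hidden
//           sequence (placement "after LSTM"); mask_c: optional N x H mask
//           on the context vector ("after attention").
// [[Rcpp::export]]
List lafnet_batch(SEXP X_, const List& params, int n_layers, int attention,
                  const arma::ivec& y, bool want_grads,
                  SEXP mask_h_, SEXP mask_c_) {
  arma::cube X = as_cube(X_);
  const arma::uword N = X.n_rows, T = X.n_slices;
  if (n_layers < 1) stop("need at least one LSTM layer");

  std::vector<arma::mat> Wx(n_layers), Wh(n_layers);
  std::vector<arma::rowvec> b(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    std::string sl = std::to_string(l + 1);
    Wx[l] = as<arma::mat>(params["Wx" + sl]);
    Wh[l] = as<arma::mat>(params["Wh" + sl]);
    b[l] = as<arma::rowvec>(params["b" + sl]);
  }
  arma::vec wa = as<arma::vec>(params["wa"]);
  double ba = as<double>(params["ba"]);
  arma::mat Wc = as<arma::mat>(params["Wc"]);
  arma::rowvec bc = as<arma::rowvec>(params["bc"]);
  const arma::uword H = Wh[0].n_rows, n_classes = Wc.n_cols;

  // forward through the stack, caching gates and states for BPTT.
  // The input-to-gate product for all time steps is hoisted into one large
  // GEMM per layer; only the recurrent product stays inside the time loop.
  std::vector<arma::cube> Ic(n_layers), Fc(n_layers), Gc(n_layers),
      Oc(n_layers), Cc(n_layers), Hc(n_layers);
  arma::cube input = X;
  for (int l = 0; l < n_layers; ++l) {
    const arma::uword in_dim = input.n_cols;
    if (Wx[l].n_rows != in_dim) stop("Wx dimension mismatch at layer " + std::to_string(l + 1));
    Ic[l].set_size(N, H, T); Fc[l].set_size(N, H, T); Gc[l].set_size(N, H, T);
    Oc[l].set_size(N, H, T); Cc[l].set_size(N, H, T); Hc[l].set_size(N, H, T);
    arma::mat in_flat(N * T, in_dim);
    for (arma::uword t = 0; t < T; ++t)
      in_flat.rows(t * N, (t + 1) * N - 1) = input.slice(t);
    arma::mat preX = in_flat * Wx[l];
    preX.each_row() += b[l];
    arma::mat h = arma::zeros(N, H), c = arma::zeros(N, H);
    for (arma::uword t = 0; t < T; ++t) {
      arma::mat pre = preX.rows(t * N, (t + 1) * N - 1) + h * Wh[l];
      arma::mat ig = 1.0 / (1.0 + arma::exp(-pre.cols(0, H - 1)));
      arma::mat fg = 1.0 / (1.0 + arma::exp(-pre.cols(H, 2 * H - 1)));
      arma::mat gg = arma::tanh(pre.cols(2 * H, 3 * H - 1));
      arma::mat og = 1.0 / (1.0 + arma::exp(-pre.cols(3 * H, 4 * H - 1)));
      c = fg % c + ig % gg;
      h = og % arma::tanh(c);
      Ic[l].slice(t) = ig; Fc[l].slice(t) = fg; Gc[l].slice(t) = gg;
      Oc[l].slice(t) = og; Cc[l].slice(t) = c; Hc[l].slice(t) = h;
    }
    input = Hc[l];
  }

  arma::cube Htop = Hc[n_layers - 1];
  bool has_mh = !Rf_isNull(mask_h_);
  arma::cube mh;
  if (has_mh) { mh = as_cube(mask_h_); Htop %= mh; }

  // attention / pooling
  arma::mat alpha;   // N x T raw attention weights (empty when attention = 0)
  arma::mat context(N, H);
  if (attention == 0) {
    context = Htop.slice(T - 1);
  } else {
    alpha.set_size(N, T);
    for (arma::uword t = 0; t < T; ++t)
      alpha.col(t) = Htop.slice(t) * wa + ba;
    if (attention == 2) alpha = arma::tanh(alpha);
    context.zeros();
    for (arma::uword t = 0; t < T; ++t)
      context += Htop.slice(t).each_col() % alpha.col(t);
  }

  bool has_mc = !Rf_isNull(mask_c_);
  arma::mat mc, ctx_d = context;
  if (has_mc) { mc = as<arma::mat>(mask_c_); ctx_d %= mc; }

  // classifier head: softmax with log-sum-exp stabilization
  arma::mat logits = ctx_d * Wc;
  logits.each_row() += bc;
  arma::vec mx = arma::max(logits, 1);
  arma::mat probs = arma::exp(logits.each_col() - mx);
  probs.each_col() /= arma::sum(probs, 1);

  double loss = NA_REAL;
  bool has_y = y.n_elem == N;
  if (has_y) {
    double s = 0;
    for (arma::uword n = 0; n < N; ++n) {
      if (y[n] < 0 || (arma::uword)y[n] >= n_classes) stop("label out of range");
      s += -std::log(std::max(probs(n, y[n]), 1e-12));
    }
    loss = s / N;
  }

  List out = List::create(_["probs"] = probs, _["alpha"] = alpha,
                          _["context"] = context, _["loss"] = loss);
  if (!want_grads) return out;
  if (!has_y) stop("gradients require labels");

  // ----- backward -----
  arma::mat dlogits = probs;
  for (arma::uword n = 0; n < N; ++n) dlogits(n, y[n]) -= 1.0;
  dlogits /= (double)N;

  arma::mat gWc = ctx_d.t() * dlogits;
  arma::rowvec gbc = arma::sum(dlogits, 0);
  arma::mat dctx = dlogits * Wc.t();
  if (has_mc) dctx %= mc;

  arma::cube dHtop = arma::zeros(N, H, T);
  arma::vec gwa = arma::zeros(H);
  double gba = 0.0;
  if (attention == 0) {
    dHtop.slice(T - 1) = dctx;
  } else {
    for (arma::uword t = 0; t < T; ++t) {
      arma::vec da = arma::sum(dctx % Htop.slice(t), 1);       // d loss / d a_t
      dHtop.slice(t) += dctx.each_col() % alpha.col(t);        // via context sum
      arma::vec dpre = (attention == 2)
        ? arma::vec(da % (1.0 - arma::square(alpha.col(t)))) : da;
      gwa += Htop.slice(t).t() * dpre;
      gba += arma::accu(dpre);
      dHtop.slice(t) += dpre * wa.t();                         // via a_t = wa.h_t + ba
    }
  }
  if (has_mh) dHtop %= mh;

  // BPTT down the stack
  List grads;
  arma::cube dAbove = dHtop;
  std::vector<arma::mat> gWx(n_layers), gWh(n_layers);
  std::vector<arma::rowvec> gb(n_layers);
  for (int l = n_layers - 1; l >= 0; --l) {
    const arma::cube& in_l = (l == 0) ? X : Hc[l - 1];
    const arma::uword in_dim = in_l.n_cols;
    // the sequential recurrence produces dpre_t; all dense gradient GEMMs
    // are deferred to single large products over the stacked time steps
    arma::mat dpre_flat(N * T, 4 * H);
    arma::mat dh_next = arma::zeros(N, H), dc_next = arma::zeros(N, H);
    for (int t = T - 1; t >= 0; --t) {
      arma::mat dh = dAbove.slice(t) + dh_next;
      arma::mat tc = arma::tanh(Cc[l].slice(t));
      arma::mat dog = dh % tc;
      arma::mat dc = dc_next + dh % Oc[l].slice(t) % (1.0 - tc % tc);
      arma::mat dig = dc % Gc[l].slice(t);
      arma::mat dgg = dc % Ic[l].slice(t);
      arma::mat dfg = (t > 0) ? arma::mat(dc % Cc[l].slice(t - 1))
                              : arma::mat(arma::zeros(N, H));
      dc_next = dc % Fc[l].slice(t);
      arma::mat dpre(N, 4 * H);
      dpre.cols(0, H - 1) = dig % Ic[l].slice(t) % (1.0 - Ic[l].slice(t));
      dpre.cols(H, 2 * H - 1) = dfg % Fc[l].slice(t) % (1.0 - Fc[l].slice(t));
      dpre.cols(2 * H, 3 * H - 1) = dgg % (1.0 - arma::square(Gc[l].slice(t)));
      dpre.cols(3 * H, 4 * H - 1) = dog % Oc[l].slice(t) % (1.0 - Oc[l].slice(t));
      dpre_flat.rows(t * N, (t + 1) * N - 1) = dpre;
      dh_next = dpre * Wh[l].t();
    }
    arma::mat in_flat(N * T, in_dim), hprev_flat(N * T, H);
    for (arma::uword t = 0; t < T; ++t) {
      in_flat.rows(t * N, (t + 1) * N - 1) = in_l.slice(t);
      if (t > 0) hprev_flat.rows(t * N, (t + 1) * N - 1) = Hc[l].slice(t - 1);
      else hprev_flat.rows(0, N - 1).zeros();
    }
    gWx[l] = in_flat.t() * dpre_flat;
    gWh[l] = hprev_flat.t() * dpre_flat;
    gb[l] = arma::sum(dpre_flat, 0);
    arma::mat dIn_flat = dpre_flat * Wx[l].t();
    arma::cube dIn(N, in_dim, T);
    for (arma::uword t = 0; t < T; ++t)
      dIn.slice(t) = dIn_flat.rows(t * N, (t + 1) * N - 1);
    dAbove = dIn;
  }

  for (int l = 0; l < n_layers; ++l) {
    std::string sl = std::to_string(l + 1);
    grads["Wx" + sl] = gWx[l];
    grads["Wh" + sl] = gWh[l];
    grads["b" + sl] = gb[l];
  }
  grads["wa"] = gwa;
  grads["ba"] = gba;
  grads["Wc"] = gWc;
  grads["bc"] = gbc;
  out["grads"] = grads;
  return out;
}
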