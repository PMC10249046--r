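// Joint negative log-density of the sequential life-stage state-space model.
// Latent vital rates (log recruitment, logit survival) are declared random
// and integrated out by TMB's Laplace approximation.
#include <TMB.hpp>

// log(phi) from logit(phi), stable for large |x|
template <class Type>
Type log_invlogit(Type x) {
  return -logspace_add(Type(0), -x);
}

template <class Type>
Type objective_function<Type>::operator()() {
  DATA_MATRIX(logY);          // n x T, arbitrary values where unobserved
  DATA_UPDATE(logY);          // replicate studies swap data without retaping
  DATA_IMATRIX(obs);          // n x T, 1 = observed
  DATA_MATRIX(sigma_o);       // n x T, known log-scale observation SDs
  DATA_INTEGER(has_Y_init);
  DATA_SCALAR(logY_init);
  DATA_UPDATE(logY_init);
  DATA_SCALAR(sigma_o_init);
  DATA_MATRIX(wR);            // T x (mR + 1)
  DATA_UPDATE(wR);
  DATA_MATRIX(wS);            // T x sum_i (mSi + 1), survival designs stacked
  DATA_UPDATE(wS);
  DATA_IVECTOR(wS_off);       // length n - 1, 0-based column offset per stage
  DATA_IVECTOR(wS_len);       // length n - 1, columns per stage
  DATA_IVECTOR(psi_index);    // length n, 0-based survey slot per stage
  DATA_INTEGER(surv_lognormal); // 1 = log-normal survival test variant

  PARAMETER(log_N_init);
  PARAMETER_VECTOR(beta_R);
  PARAMETER_VECTOR(beta_S);   // concatenated survival coefficients
  PARAMETER(log_sigma_pR);
  PARAMETER_VECTOR(log_sigma_pS);
  PARAMETER_VECTOR(log_psi);
  PARAMETER_VECTOR(log_rho);      // T latent log recruitment rates
  PARAMETER_MATRIX(logit_phi);    // (n-1) x T latent survival (logit scale)

  int T = log_rho.size();
  int nm1 = logit_phi.rows();
  int n = nm1 + 1;
  Type sigma_pR = exp(log_sigma_pR);
  vector<Type> sigma_pS = exp(log_sigma_pS);

  Type nll = 0;

  // process model: normal on the transformed scale
  vector<Type> muR = wR * beta_R;
  for (int t = 0; t < T; t++)
    nll -= dnorm(log_rho(t), muR(t), sigma_pR, true);
  for (int i = 0; i < nm1; i++) {
    vector<Type> b = beta_S.segment(wS_off(i), wS_len(i));
    for (int t = 0; t < T; t++) {
      Type mu = 0;
      for (int j = 0; j < wS_len(i); j++) mu += wS(t, wS_off(i) + j) * b(j);
      nll -= dnorm(logit_phi(i, t), mu, sigma_pS(i), true);
    }
  }

  // abundance recursion on the log scale
  matrix<Type> logN(n, T);
  Type log_adult_prev = log_N_init;
  for (int t = 0; t < T; t++) {
    logN(0, t) = log_rho(t) + log_adult_prev;
    for (int i = 1; i < n; i++) {
      Type logphi = surv_lognormal ? logit_phi(i - 1, t)
                                   : log_invlogit(logit_phi(i - 1, t));
      logN(i, t) = logN(i - 1, t) + logphi;
    }
    log_adult_prev = logN(n - 1, t);
  }

  // observation model: log-normal indices, unbiased for psi * N
  for (int i = 0; i < n; i++) {
    for (int t = 0; t < T; t++) {
      if (obs(i, t)) {
        Type s = sigma_o(i, t);
        Type mu = log_psi(psi_index(i)) + logN(i, t) - s * s / 2;
        nll -= dnorm(logY(i, t), mu, s, true);
      }
    }
  }
  if (has_Y_init) {
    Type s = sigma_o_init;
    Type mu0 = log_psi(psi_index(n - 1)) + log_N_init - s * s / 2;
    nll -= dnorm(logY_init, mu0, s, true);
  }

  return nll;
}
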