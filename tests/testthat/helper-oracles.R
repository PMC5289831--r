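# Independent oracles used to pin the exact-test and Firth semantics.
# All enumeration is done with explicit choose() arithmetic over the full
# table space, and the Firth objective is maximized with a generic
# optimizer, so these never share code paths with the implementation.

# hypergeometric point probability via choose()
oracle_hyper_pmf <- function(a, n_events, n_a, n_b) {
  choose(n_a, a) * choose(n_b, n_events - a) / choose(n_a + n_b, n_events)
}

oracle_support <- function(n_events, n_a, n_b) {
  max(0, n_events - n_b):min(n_events, n_a)
}

# one-sided Fisher by enumeration
oracle_fisher_p <- function(ea, na, eb, nb, mid = FALSE) {
  m <- ea + eb
  supp <- oracle_support(m, na, nb)
  if (length(supp) == 1) return(if (mid) 0.5 else 1)
  pmf <- oracle_hyper_pmf(supp, m, na, nb)
  sum(pmf[supp > ea]) + (if (mid) 0.5 else 1) * pmf[supp == ea]
}

# exact stratified MH by enumeration over all pairs of tables
oracle_mh_p <- function(am, nm_ko, wm, nm_wt, af, nf_ko, wf, nf_wt, mid = TRUE) {
  m1 <- am + wm; m2 <- af + wf
  s1 <- oracle_support(m1, nm_ko, nm_wt)
  s2 <- oracle_support(m2, nf_ko, nf_wt)
  if (length(s1) * length(s2) == 1) return(if (mid) 0.5 else 1)
  tobs <- am + af
  p_gt <- p_eq <- 0
  for (a1 in s1) for (a2 in s2) {
    pr <- oracle_hyper_pmf(a1, m1, nm_ko, nm_wt) *
          oracle_hyper_pmf(a2, m2, nf_ko, nf_wt)
    if (a1 + a2 > tobs) p_gt <- p_gt + pr
    if (a1 + a2 == tobs) p_eq <- p_eq + pr
  }
  p_gt + (if (mid) 0.5 else 1) * p_eq
}

# minimum attainable MH p over all tables with the observed margins
oracle_mh_alpha_star <- function(am, nm_ko, wm, nm_wt, af, nf_ko, wf, nf_wt,
                                 mid = TRUE) {
  s1 <- oracle_support(am + wm, nm_ko, nm_wt)
  s2 <- oracle_support(af + wf, nf_ko, nf_wt)
  best <- 1
  for (a1 in s1) for (a2 in s2) {
    p <- oracle_mh_p(a1, nm_ko, am + wm - a1, nm_wt,
                     a2, nf_ko, af + wf - a2, nf_wt, mid)
    best <- min(best, p)
  }
  best
}

# Zelen homogeneity test by enumeration of the doubly conditional law
oracle_zelen_p <- function(am, nm_ko, wm, nm_wt, af, nf_ko, wf, nf_wt,
                           mid = TRUE) {
  m1 <- am + wm; m2 <- af + wf
  T <- am + af
  s1 <- oracle_support(m1, nm_ko, nm_wt)
  a1s <- s1[(T - s1) >= max(0, m2 - nf_wt) & (T - s1) <= min(m2, nf_ko)]
  if (length(a1s) <= 1) return(1)
  f <- oracle_hyper_pmf(a1s, m1, nm_ko, nm_wt) *
       oracle_hyper_pmf(T - a1s, m2, nf_ko, nf_wt)
  f <- f / sum(f)
  fo <- f[a1s == am]
  p <- sum(f[f <= fo * (1 + 1e-10)])
  if (mid) p <- p - 0.5 * fo
  p
}

# knockout-only two-sided Fisher (point-probability method) by enumeration
oracle_fe_ko_p <- function(km, nm, kf, nf, mid = TRUE) {
  m <- km + kf
  supp <- oracle_support(m, nm, nf)
  if (length(supp) <= 1) return(1)
  pmf <- oracle_hyper_pmf(supp, m, nm, nf)
  fo <- pmf[supp == km]
  p <- sum(pmf[pmf <= fo * (1 + 1e-10)])
  if (mid) p <- p - 0.5 * fo
  p
}

# Firth penalized log-likelihood, for direct generic maximization
oracle_pll <- function(beta, X, k, n) {
  pi <- plogis(drop(X %*% beta))
  I <- crossprod(X, X * (n * pi * (1 - pi)))
  sum(lchoose(n, k) + k * log(pi) + (n - k) * log(1 - pi)) +
    0.5 * determinant(I)$modulus
}

# maximize over free coordinates with tested columns pinned at zero
oracle_pll_max <- function(X, k, n, fixed_zero = integer(0)) {
  free <- setdiff(seq_len(ncol(X)), fixed_zero)
  obj <- function(b) {
    beta <- numeric(ncol(X))
    beta[free] <- b
    -as.numeric(oracle_pll(beta, X, k, n))
  }
  o <- optim(numeric(length(free)), obj, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-14))
  # polish with Nelder-Mead from the BFGS optimum
  o2 <- optim(o$par, obj, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-14))
  -min(o$value, o2$value)
}

# random small sex-stratified data sets for property sweeps
random_dataset <- function(max_n = 12) {
  n <- sample.int(max_n, 4, replace = TRUE)
  k <- vapply(n, function(nn) sample.int(nn + 1L, 1L) - 1L, integer(1))
  make_dataset(ko_male = c(k[1], n[1]), wt_male = c(k[2], n[2]),
               ko_female = c(k[3], n[3]), wt_female = c(k[4], n[4]))
}
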