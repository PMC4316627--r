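#' Construct a reversible substitution model with discrete-gamma rates
#'
#' The default is the Poisson model over the 20 amino acids: all
#' exchangeabilities equal, equal equilibrium frequencies. The Poisson model
#' has closed-form transition probabilities, which makes simulator and
#' likelihood output checkable against exact values; an empirical
#' exchangeability matrix (e.g. LG) can be supplied instead. The rate matrix
#' is always rescaled so that the expected number of substitutions per site
#' per unit time is 1 at equilibrium, i.e. branch lengths are in
#' substitutions/site. Among-site rate variation follows a discretized gamma
#' distribution with `n_categories` equal-probability categories represented
#' by their category means (mean rate exactly 1).
#'
#' @param states Character vector of state symbols (default: 20 amino acids).
#' @param exchangeabilities Symmetric non-negative matrix of relative rates
#'   (diagonal ignored), or `NULL` for Poisson (all equal).
#' @param freqs Equilibrium frequencies (simplex); default equal.
#' @param alpha Gamma shape parameter (>0), or `Inf` for rate homogeneity.
#' @param n_categories Number of discrete gamma categories (default 6).
#' @return An object of class `subst_model` with elements `states`, `Q`
#'   (scaled rate matrix), `freqs`, `alpha`, `n_categories`, `rates`
#'   (category rates, mean 1) and a cached eigendecomposition.
#' @export
substitution_model <- function(states = AA_STATES, exchangeabilities = NULL,
                               freqs = NULL, alpha = 0.7, n_categories = 6L) {
  s <- length(states)
  stopifnot(s >= 2L, !anyDuplicated(states))
  if (is.null(freqs)) freqs <- rep(1 / s, s)
  stopifnot(length(freqs) == s, all(freqs > 0))
  if (abs(sum(freqs) - 1) > 1e-12)
    stop_fmt("equilibrium frequencies must sum to 1")
  if (is.null(exchangeabilities)) {
    R <- matrix(1, s, s)
  } else {
    R <- as.matrix(exchangeabilities)
    stopifnot(nrow(R) == s, ncol(R) == s)
    if (max(abs(R - t(R))) > 1e-9) stop_fmt("exchangeabilities must be symmetric")
    if (any(R[upper.tri(R)] < 0)) stop_fmt("exchangeabilities must be non-negative")
  }
  diag(R) <- 0
  Q <- R * rep(freqs, each = s)   # Q_ij = r_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))     # expected substitutions/site/unit time
  if (mu <= 0) stop_fmt("degenerate rate matrix")
  Q <- Q / mu
  if (!(is.numeric(alpha) && (alpha > 0)))
    stop_fmt("alpha must be > 0 (use Inf for no rate heterogeneity)")
  n_categories <- as.integer(n_categories)
  stopifnot(n_categories >= 1L)
  rates <- discrete_gamma_rates(alpha, n_categories)
  # Symmetrized eigendecomposition for fast P(t) = exp(Qt).
  d <- sqrt(freqs)
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(states = states, Q = Q, freqs = freqs, alpha = alpha,
                 n_categories = n_categories, rates = rates,
                 eig = list(values = eig$values,
                            left = eig$vectors * rep(1 / d, each = s),
                            right = t(eig$vectors * rep(d, each = s)))),
            class = "subst_model")
}

#' Discrete-gamma category rates (equal-probability categories, mean 1)
#'
#' Category rates are the conditional means of a gamma(shape = alpha,
#' rate = alpha) distribution over its `k` equal-probability quantile bins,
#' so the rates average exactly 1.
#'
#' @param alpha Gamma shape (> 0); `Inf` gives all rates 1.
#' @param k Number of categories.
#' @return Numeric vector of length `k`.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  k <- as.integer(k)
  if (k == 1L || is.infinite(alpha)) return(rep(1, k))
  qb <- qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  # mean of X over (a, b] for X ~ gamma(alpha, alpha):
  # E[X; a<X<=b] = (shape/rate) * (F_{alpha+1}(b) - F_{alpha+1}(a)) / (1/k)
  upper <- pgamma(qb[-1], shape = alpha + 1, rate = alpha)
  lower <- pgamma(qb[-(k + 1L)], shape = alpha + 1, rate = alpha)
  r <- k * (upper - lower)
  r / mean(r) * 1  # guard against numeric drift; mean(r) is 1 analytically
}

# Transition probability matrix P(t) = exp(Q t) from the cached
# eigendecomposition. t >= 0 in substitutions/site (already scaled by any
# per-category rate by the caller).
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "subst_model"), t >= 0)
  e <- model$eig
  P <- e$left %*% (exp(e$values * t) * e$right)
  P[P < 0] <- 0
  P / rowSums(P)
}
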