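#' Corrected pairwise distance between two aligned rows
#'
#' Gapped columns are excluded pairwise: `p` is the mismatch proportion over
#' columns where both rows have a residue. Corrections:
#' * `"p"` — the raw proportion;
#' * `"kimura"` — Kimura's (1983) protein correction
#'   `d = -ln(1 - p - 0.2 p^2)`;
#' * `"ml-poisson"` — the maximum-likelihood distance under the Poisson
#'   model, `d = -c * ln(1 - p/c)` with `c = (s-1)/s` for an `s`-state
#'   alphabet; with a gamma shape `alpha`, `d = c * alpha * ((1 - p/c)^(-1/alpha) - 1)`.
#'
#' Returns `Inf` when the correction is undefined (saturated pair);
#' [distance_matrix()] replaces such entries by its saturation rule.
#'
#' When `n_categories` is supplied along with a finite `alpha`, the
#' `"ml-poisson"` correction inverts the exact discrete-gamma expectation
#' `p(t) = c * (1 - mean_k exp(-t r_k / c))` (with the same
#' equal-probability category rates the simulator and the likelihood use)
#' instead of the continuous-gamma closed form, removing the small
#' discretization bias between the two.
#'
#' @param a,b Aligned sequences of equal length (character strings).
#' @param correction One of `"p"`, `"kimura"`, `"ml-poisson"`.
#' @param alpha Gamma shape for `"ml-poisson"`, or `NULL`/`Inf` for none.
#' @param n_states Alphabet size for `"ml-poisson"` (default 20).
#' @param n_categories Number of discrete gamma categories to assume for the
#'   inversion, or `NULL` for the continuous-gamma form.
#' @return A non-negative distance (substitutions/site), or `Inf` if
#'   saturated.
#' @export
pairwise_distance <- function(a, b, correction = c("kimura", "p", "ml-poisson"),
                              alpha = NULL, n_states = 20L,
                              n_categories = NULL) {
  correction <- match.arg(correction)
  stopifnot(nchar(a) == nchar(b))
  x <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  y <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  shared <- !(x %in% GAP_CHARS) & !(y %in% GAP_CHARS)
  if (!any(shared)) stop_fmt("no shared non-gap columns; distance undefined")
  p <- mean(x[shared] != y[shared])
  correct_p(p, correction, alpha = alpha, n_states = n_states,
            n_categories = n_categories)
}

# Vectorized distance corrections; Inf marks saturated (undefined) values.
correct_p <- function(p, correction, alpha = NULL, n_states = 20L,
                      n_categories = NULL) {
  switch(correction,
         "p" = p,
         "kimura" = {
           arg <- 1 - p - 0.2 * p^2
           ifelse(arg <= 0, Inf, -log(pmax(arg, 1e-300)))
         },
         "ml-poisson" = {
           cc <- (n_states - 1) / n_states
           arg <- pmax(1 - p / cc, 0)
           if (is.null(alpha) || is.infinite(alpha)) {
             ifelse(p >= cc, Inf, -cc * log(pmax(arg, 1e-300)))
           } else if (is.null(n_categories)) {
             ifelse(p >= cc, Inf, cc * alpha * (arg^(-1 / alpha) - 1))
           } else {
             rates <- discrete_gamma_rates(alpha, n_categories)
             vapply(p, invert_discrete_gamma_p, numeric(1),
                    rates = rates, cc = cc)
           }
         })
}

# Solve p = cc * (1 - mean(exp(-t * r / cc))) for t (monotone increasing,
# saturating at cc).
invert_discrete_gamma_p <- function(p, rates, cc) {
  if (p <= 0) return(0)
  if (p >= cc) return(Inf)
  f <- function(t) cc * (1 - mean(exp(-t * rates / cc))) - p
  upper <- 1
  while (f(upper) < 0 && upper < 1e6) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' Corrected distance matrix for an alignment
#'
#' Saturated pairs (where the correction is undefined) are assigned 1.05
#' times the largest finite corrected distance in the matrix and flagged in
#' the `saturated` attribute, so neighbor joining stays total while the
#' substitution is visible.
#'
#' @param seqs Named character vector of aligned sequences.
#' @inheritParams pairwise_distance
#' @return Symmetric matrix with zero diagonal; attributes `correction` and
#'   `saturated` (2-column matrix of flagged pairs, possibly empty).
#' @export
distance_matrix <- function(seqs, correction = c("kimura", "p", "ml-poisson"),
                            alpha = NULL, n_states = 20L,
                            n_categories = NULL) {
  correction <- match.arg(correction)
  check_aligned(seqs)
  im <- aln_int_matrix(seqs)
  dist_from_int(im, correction, alpha = alpha, n_states = n_states,
                n_categories = n_categories)
}

# Distance matrix from an integer-encoded alignment (0 = gap). Shared by
# distance_matrix() and the bootstrap resampler. Match and shared-column
# counts come from sparse one-hot cross-products, so the cost is linear in
# alignment size rather than quadratic in taxa times sites.
dist_from_int <- function(im, correction, alpha = NULL, n_states = 20L,
                          n_categories = NULL) {
  n <- nrow(im)
  if (n < 2L) stop_fmt("need at least 2 sequences")
  m <- ncol(im)
  s <- max(max(im), 1L)
  nongap <- matrix(as.numeric(im > 0L), n, m)
  shared <- tcrossprod(nongap)
  idx <- which(im > 0L)
  rows <- ((idx - 1L) %% n) + 1L
  sites <- ((idx - 1L) %/% n) + 1L
  onehot <- Matrix::sparseMatrix(i = rows, j = (sites - 1L) * s + im[idx],
                                 x = 1, dims = c(n, m * s))
  matches <- as.matrix(Matrix::tcrossprod(onehot))
  off <- shared == 0
  diag(off) <- FALSE
  if (any(off)) {
    bad <- which(off, arr.ind = TRUE)[1, ]
    stop_fmt("no shared non-gap columns between '%s' and '%s'",
             rownames(im)[bad[1]], rownames(im)[bad[2]])
  }
  p <- 1 - matches / pmax(shared, 1)
  d <- correct_p(p, correction, alpha = alpha, n_states = n_states,
                 n_categories = n_categories)
  dim(d) <- dim(p)
  diag(d) <- 0
  dimnames(d) <- list(rownames(im), rownames(im))
  sat <- which(is.infinite(d), arr.ind = TRUE)
  sat <- sat[sat[, 1] < sat[, 2], , drop = FALSE]
  if (nrow(sat) > 0L) {
    maxfin <- max(d[is.finite(d)])
    d[is.infinite(d)] <- maxfin * 1.05
  }
  attr(d, "correction") <- correction
  attr(d, "saturated") <- cbind(rownames(im)[sat[, 1]], rownames(im)[sat[, 2]])
  d
}

#' Neighbor joining
#'
#' Standard neighbor joining (Q-matrix selection with Studier–Keppler
#' updates, as implemented in \pkg{ape}); negative estimated branch lengths
#' are clamped to 0 and the total clamped deficit is recorded in the
#' `clamped_deficit` attribute.
#'
#' @param m A symmetric distance matrix with >= 3 taxa (e.g. from
#'   [distance_matrix()]).
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3L) stop_fmt("neighbor joining needs at least 3 taxa")
  if (max(abs(m - t(m))) > 1e-8) stop_fmt("distance matrix must be symmetric")
  tree <- ape::nj(m)
  deficit <- -sum(tree$edge.length[tree$edge.length < 0])
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped_deficit") <- deficit
  tree
}
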