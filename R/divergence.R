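#' Kullback-Leibler divergence in bits
#'
#' D(p||q) = sum p_i log2(p_i / q_i), with the 0 * log 0 = 0 convention for
#' zero entries of p. A positive p where q is zero has infinite divergence
#' and is a support error.
#'
#' @param p,q Discrete distributions of equal length (each sums to 1).
#' @return Nonnegative divergence in bits.
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(p < 0) || any(q < 0)) stop("negative probability")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("profiles must be normalized to unit sum")
  pos <- p > 0
  if (any(q[pos] == 0))
    stop("support error: p > 0 where q = 0")
  sum(p[pos] * log2(p[pos] / q[pos]))
}

#' RD statistic: relative distance of O from T against the uniform reference
#'
#' RD = D(O||T) / (D(O||T) + D(O||R)). RD < 0.5 means the observed
#' distribution is closer to the micelle-like theoretical field than to the
#' structureless uniform one, i.e. a hydrophobic core is present.
#'
#' @param o,t,r Observed, theoretical and uniform profiles (equal length).
#' @return RD in \[0, 1\].
#' @export
rd_statistic <- function(o, t, r = r_profile(length(o))) {
  d_ot <- kl_divergence(o, t)
  d_or <- kl_divergence(o, r)
  if (d_ot + d_or == 0)
    stop("RD undefined: O coincides with both T and R")
  d_ot / (d_ot + d_or)
}

#' Fit the field-modification parameter K
#'
#' Exhaustive scan of a K grid for the value minimizing D(O || M(T, K)).
#' The grid default (0 to 10 by 0.01) covers water-like (K near 0) through
#' membrane-like (K near 1) to strongly modified environments; ties break
#' toward smaller K, so O = T always yields K = 0.
#'
#' @param o Observed profile.
#' @param t Theoretical profile.
#' @param k_grid Numeric grid of candidate K values (must include 0 for the
#'   guarantee D(O||M(K_fit)) <= D(O||T)).
#' @return List: `k` (argmin), `d_om` (divergence at `k`), `d_om_curve`
#'   (divergence along the grid), `k_grid`, `degenerate` (TRUE when T is
#'   uniform and K is undefined; `k` is then 0).
#' @export
fit_k <- function(o, t, k_grid = seq(0, 10, by = 0.01)) {
  if (any(k_grid < 0)) stop("k_grid must be nonnegative")
  k_grid <- sort(k_grid)
  cmpl <- max(t) - t
  if (sum(cmpl) <= .Machine$double.eps) {
    return(list(k = 0, d_om = kl_divergence(o, t),
                d_om_curve = rep(kl_divergence(o, t), length(k_grid)),
                k_grid = k_grid, degenerate = TRUE))
  }
  cn <- .norm1(cmpl)
  curve <- vapply(k_grid, function(k) {
    kl_divergence(o, .norm1(t + k * cn))
  }, numeric(1))
  i <- which.min(curve)  # which.min takes the first minimum: smaller K wins ties
  list(k = k_grid[i], d_om = curve[i], d_om_curve = curve,
       k_grid = k_grid, degenerate = FALSE)
}
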