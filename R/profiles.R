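#' Center and principal-axis align a unit
#'
#' The 3D Gaussian of the theoretical field is axis-aligned, so each analysis
#' unit is first moved to its centroid and rotated onto its principal axes
#' (descending variance mapped to x, y, z). All downstream statistics are
#' therefore invariant under rigid-body motion of the input coordinates; the
#' sign of each principal axis is arbitrary and has no effect.
#'
#' @param points Numeric matrix (n x 3) of effective-atom coordinates in
#'   Angstrom.
#' @param h Numeric vector of intrinsic hydrophobicities in \[0, 1\].
#' @param labels Optional residue labels.
#' @param sigma_floor Minimum sigma in Angstrom (guards flat units).
#' @param sigma_rule `"extent3"` (max |coordinate| / 3, default) or
#'   `"extent6"` or `"sd"` (per-axis standard deviation).
#' @return An `oriented_unit`: list with `points` (centered, aligned), `h`,
#'   `labels`, `sigmas` (length 3).
#' @export
orient_unit <- function(points, h, labels = NULL, sigma_floor = 1,
                        sigma_rule = c("extent3", "extent6", "sd")) {
  sigma_rule <- match.arg(sigma_rule)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (ncol(points) != 3) stop("points must be n x 3")
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points")
  if (length(h) != n) stop("h must match points")
  if (any(h < 0) || !all(is.finite(h))) stop("h must be finite and >= 0")
  ctr <- colMeans(points)
  pc <- sweep(points, 2, ctr)
  if (max(abs(pc)) < 1e-9) stop("degenerate geometry: all points coincident")
  ev <- eigen(crossprod(pc) / n, symmetric = TRUE)
  # eigen() returns eigenvalues in decreasing order: variance -> x, y, z
  aligned <- pc %*% ev$vectors
  aligned <- sweep(aligned, 2, colMeans(aligned))  # numerical recentering
  if (is.null(labels)) labels <- as.character(seq_len(n))
  unit <- structure(
    list(points = aligned, h = as.numeric(h), labels = labels,
         sigmas = NULL, sigma_rule = sigma_rule, sigma_floor = sigma_floor),
    class = "oriented_unit"
  )
  unit$sigmas <- estimate_sigmas(aligned, floor = sigma_floor, rule = sigma_rule)
  unit
}

#' Estimate the Gaussian widths of an oriented unit
#'
#' Default convention: sigma along each axis is the maximal absolute
#' coordinate divided by 3, so the molecular body spans three standard
#' deviations from the center; floored to avoid collapse for flat units.
#'
#' @param oriented_points Centered, axis-aligned n x 3 matrix.
#' @param floor Minimum sigma (Angstrom), default 1.
#' @param rule `"extent3"`, `"extent6"`, or `"sd"`.
#' @return Numeric length-3 vector (sigma_x, sigma_y, sigma_z), all > 0.
#' @export
estimate_sigmas <- function(oriented_points, floor = 1,
                            rule = c("extent3", "extent6", "sd")) {
  rule <- match.arg(rule)
  m <- as.matrix(oriented_points)
  s <- switch(rule,
    extent3 = apply(abs(m), 2, max) / 3,
    extent6 = apply(abs(m), 2, max) / 6,
    sd = apply(m, 2, stats::sd)
  )
  pmax(s, floor)
}

# normalize a nonnegative vector to unit sum
.norm1 <- function(v) {
  s <- sum(v)
  if (s <= 0) stop("cannot normalize: nonpositive total")
  v / s
}

#' Theoretical (micelle-like) hydrophobicity profile T
#'
#' The 3D Gaussian of the water field evaluated at each effective atom,
#' normalized to unit sum.
#'
#' @param unit An `oriented_unit`.
#' @return Numeric profile summing to 1.
#' @export
t_profile <- function(unit) {
  stopifnot(inherits(unit, "oriented_unit"))
  s <- unit$sigmas
  p <- unit$points
  g <- exp(-p[, 1]^2 / (2 * s[1]^2)) *
       exp(-p[, 2]^2 / (2 * s[2]^2)) *
       exp(-p[, 3]^2 / (2 * s[3]^2))
  .norm1(g)
}

# Levitt's smooth contact function of r/c on [0, c]; zero beyond c.
.levitt <- function(r, c) {
  x2 <- (r / c)^2
  w <- 1 - 0.5 * (7 * x2 - 9 * x2^2 + 5 * x2^3 - x2^4)
  w[r > c] <- 0
  pmax(w, 0)
}

#' Observed hydrophobicity profile O
#'
#' Per-residue sum of pairwise hydrophobic interactions: each pair within the
#' cutoff contributes the sum of the two intrinsic hydrophobicities weighted
#' by Levitt's polynomial distance function, normalized to unit sum.
#' Residues with no neighbor inside the cutoff contribute zero before
#' normalization.
#'
#' @param unit An `oriented_unit` (any rigid placement gives the same O).
#' @param cutoff Interaction cutoff c in Angstrom (default 9).
#' @param include_self Include the i = j self term (default FALSE; the
#'   observed distribution is defined by inter-residue interactions).
#' @return Numeric profile summing to 1.
#' @export
o_profile <- function(unit, cutoff = 9, include_self = FALSE) {
  stopifnot(inherits(unit, "oriented_unit"), cutoff > 0)
  p <- unit$points
  h <- unit$h
  n <- nrow(p)
  d <- as.matrix(stats::dist(p))
  w <- .levitt(d, cutoff)
  if (!include_self) diag(w) <- 0
  hh <- outer(h, h, `+`)
  o <- unname(rowSums(hh * w))
  if (sum(o) <= 0)
    stop("degenerate observed profile: no residue pair interacts within ",
         cutoff, " Angstrom")
  .norm1(o)
}

#' Uniform reference profile R
#'
#' The no-hydrophobic-core reference: every residue carries 1/N.
#'
#' @param n Residue count (>= 1).
#' @return Numeric vector of length `n`, all 1/n.
#' @export
r_profile <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 1) stop("need n >= 1 residues")
  rep(1 / n, n)
}

#' Modified-field profile M
#'
#' Mixture of the water field T with its normalized complement
#' C = (Tmax - T) / sum(Tmax - T): M = normalize(T + K * C). K = 0 recovers
#' T (pure water); large K approaches the pure complement (membrane-like
#' exposure of hydrophobicity). A uniform T has no complement; M = T then.
#'
#' @param t Theoretical profile (sums to 1).
#' @param k Nonnegative field-modification parameter.
#' @return Numeric profile summing to 1.
#' @export
m_profile <- function(t, k) {
  if (k < 0) stop("k must be >= 0")
  cmpl <- max(t) - t
  if (sum(cmpl) <= .Machine$double.eps) return(t)  # uniform T: no complement
  .norm1(t + k * .norm1(cmpl))
}
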