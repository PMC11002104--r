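#' Fit the modified hydrophobicity-field model to an analysis unit
#'
#' The central estimator. Given effective-atom positions and intrinsic
#' hydrophobicities, the unit is centered and principal-axis aligned, the
#' Gaussian widths are set from its extent, and the four per-residue
#' distributions are computed: theoretical T (3D Gaussian water field),
#' observed O (pairwise hydrophobic interactions within the cutoff), uniform
#' reference R, and the best-fitting modified field M(T, K). Two parameters
#' summarize the unit: RD = D(O||T) / (D(O||T) + D(O||R)), with RD < 0.5
#' signalling a hydrophobic core, and K, the grid argmin of D(O||M(T, K)),
#' measuring how far the shaping environment departs from pure water.
#'
#' @param x Effective-atom input: an n x 3 coordinate matrix, a data.frame
#'   with columns `x`, `y`, `z`, `h` (and optionally `label`) as returned by
#'   [effective_atoms()], or a `fod_structure`.
#' @param h Intrinsic hydrophobicities in \[0, 1\] (matrix input only).
#' @param ... Passed between methods.
#' @param labels Optional residue labels.
#' @param chains For `fod_structure` input: restrict to these chain IDs.
#' @param scale Hydrophobicity scale used to derive `h` from a structure.
#' @param cutoff Interaction cutoff in Angstrom (default 9).
#' @param sigma_rule,sigma_floor Gaussian width convention, see
#'   [estimate_sigmas()].
#' @param include_self Include the self term in O (default FALSE).
#' @param k_grid Grid scanned for K (default 0 to 10 by 0.01).
#' @return An object of class `fodm`; see [coef.fodm()], [fitted.fodm()],
#'   [predict.fodm()], [plot.fodm()], [simulate.fodm()].
#' @examples
#' u <- make_micelle(60, seed = 1)
#' fit <- fod_fit(u$points, u$h)
#' coef(fit)          # K and RD
#' fit                # classification against RD = 0.5
#' @export
fod_fit <- function(x, ...) UseMethod("fod_fit")

#' @rdname fod_fit
#' @export
fod_fit.default <- function(x, h, labels = NULL, cutoff = 9,
                            sigma_rule = "extent3", sigma_floor = 1,
                            include_self = FALSE,
                            k_grid = seq(0, 10, by = 0.01),
                            scale = NULL, ...) {
  unit <- orient_unit(x, h, labels = labels, sigma_floor = sigma_floor,
                      sigma_rule = sigma_rule)
  t <- t_profile(unit)
  o <- o_profile(unit, cutoff = cutoff, include_self = include_self)
  params <- list(cutoff = cutoff, sigma_rule = sigma_rule,
                 sigma_floor = sigma_floor, include_self = include_self,
                 k_grid = range(k_grid), k_step = if (length(k_grid) > 1)
                   stats::median(diff(sort(k_grid))) else NA_real_,
                 scale = if (inherits(scale, "fod_scale")) scale$name
                         else if (is.character(scale)) scale else NA_character_)
  .fodm_from_profiles(t = t, o = o, labels = unit$labels, params = params,
                      k_grid = k_grid, unit = unit)
}

#' @rdname fod_fit
#' @export
fod_fit.data.frame <- function(x, ...) {
  stopifnot(all(c("x", "y", "z", "h") %in% names(x)))
  labels <- if ("label" %in% names(x)) x$label else NULL
  fod_fit.default(as.matrix(x[, c("x", "y", "z")]), h = x$h,
                  labels = labels, ...)
}

#' @rdname fod_fit
#' @export
fod_fit.fod_structure <- function(x, chains = NULL, scale = fod_scale(), ...) {
  ea <- effective_atoms(x, scale = scale)
  if (!is.null(chains)) ea <- ea[ea$chain %in% chains, , drop = FALSE]
  if (nrow(ea) < 3) stop("fewer than 3 residues selected")
  fod_fit.data.frame(ea, scale = scale, ...)
}

# Shared constructor: everything downstream of (T, O) lives here so that
# component-mode (restricted, renormalized) profiles take the same path.
.fodm_from_profiles <- function(t, o, labels, params, k_grid = seq(0, 10, 0.01),
                                unit = NULL) {
  n <- length(t)
  r <- r_profile(n)
  d_ot <- kl_divergence(o, t)
  d_or <- kl_divergence(o, r)
  rd <- if (d_ot + d_or > 0) d_ot / (d_ot + d_or) else NA_real_
  kf <- fit_k(o, t, k_grid = k_grid)
  structure(
    list(n = n, labels = labels,
         profiles = list(t = t, o = o, r = r,
                         m = m_profile(t, kf$k)),
         d_ot = d_ot, d_or = d_or, rd = rd,
         k = kf$k, d_om = kf$d_om, k_degenerate = kf$degenerate,
         k_curve = list(k = kf$k_grid, d_om = kf$d_om_curve),
         sigmas = if (!is.null(unit)) unit$sigmas else NULL,
         unit = unit, params = params),
    class = "fodm"
  )
}

#' @export
print.fodm <- function(x, digits = 3, ...) {
  cat("Modified hydrophobicity-field fit (", x$n, " residues)\n", sep = "")
  if (!is.null(x$sigmas))
    cat("  sigmas (A): ", paste(round(x$sigmas, 2), collapse = ", "), "\n", sep = "")
  cat("  RD = ", format(round(x$rd, digits)),
      if (is.na(x$rd)) "" else if (x$rd < 0.5)
        "  (< 0.5: hydrophobic core present, micelle-like)"
      else "  (>= 0.5: hydrophobic core absent)", "\n", sep = "")
  cat("  K  = ", format(x$k),
      if (x$k_degenerate) "  (uniform T: K undefined, reported as 0)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Model parameters of a field fit
#'
#' @param object A `fodm` fit.
#' @param ... Ignored.
#' @return Named vector with `K` (field modification) and `RD`.
#' @export
coef.fodm <- function(object, ...) c(K = object$k, RD = object$rd)

#' Fitted modified-field profile
#'
#' @param object A `fodm` fit.
#' @param ... Ignored.
#' @return The M profile at the fitted K.
#' @export
fitted.fodm <- function(object, ...) object$profiles$m

#' Residuals of the observed profile against the fitted field
#'
#' @param object A `fodm` fit.
#' @param ... Ignored.
#' @return O minus M at the fitted K, per residue.
#' @export
residuals.fodm <- function(object, ...) object$profiles$o - object$profiles$m

#' Modified-field profile at arbitrary K
#'
#' @param object A `fodm` fit.
#' @param k Field-modification parameter(s); default the fitted K.
#' @param ... Ignored.
#' @return For one `k` a profile vector; for several, a matrix (columns = k).
#' @export
predict.fodm <- function(object, k = object$k, ...) {
  out <- vapply(k, function(kk) m_profile(object$profiles$t, kk),
                numeric(object$n))
  if (length(k) == 1) as.numeric(out) else out
}

#' @export
summary.fodm <- function(object, ...) {
  structure(list(fit = object), class = "summary.fodm")
}

#' @export
print.summary.fodm <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("  D(O||T) = ", format(round(f$d_ot, 4)), " bits\n", sep = "")
  cat("  D(O||R) = ", format(round(f$d_or, 4)), " bits\n", sep = "")
  cat("  D(O||M) at K = ", format(round(f$d_om, 4)), " bits\n", sep = "")
  p <- f$params
  cat("  conventions: cutoff ", p$cutoff, " A; sigma ", p$sigma_rule,
      " (floor ", p$sigma_floor, " A); scale ", p$scale,
      "; K grid [", p$k_grid[1], ", ", p$k_grid[2], "] step ", p$k_step,
      "\n", sep = "")
  invisible(x)
}

#' Profile plot of a field fit
#'
#' Line chart of the theoretical (T), observed (O), and fitted modified (M)
#' distributions against residue index, the standard way these analyses are
#' read; the uniform reference is drawn as a dashed baseline.
#'
#' @param x A `fodm` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.fodm <- function(x, ...) {
  prof <- cbind(T = x$profiles$t, O = x$profiles$o, M = x$profiles$m)
  graphics::matplot(seq_len(x$n), prof, type = "l", lty = 1,
                    col = c("blue3", "red3", "grey40"),
                    xlab = "residue index", ylab = "normalized hydrophobicity",
                    main = sprintf("RD = %.3f, K = %.2f", x$rd, x$k), ...)
  graphics::abline(h = 1 / x$n, lty = 2, col = "grey70")
  graphics::legend("topright", legend = c("T", "O", "M(K)", "R"),
                   col = c("blue3", "red3", "grey40", "grey70"),
                   lty = c(1, 1, 1, 2), bty = "n")
  invisible(x)
}

#' Simulate observed profiles under the fitted field
#'
#' Draws observed-profile replicates as the fitted M distribution perturbed
#' by multiplicative log-normal noise and renormalized — the generative
#' reading of the model in which the environment dictates the hydrophobicity
#' distribution up to measurement noise.
#'
#' @param object A `fodm` fit.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @param noise_sd Standard deviation of the log-normal perturbation
#'   (default 0.05).
#' @param ... Ignored.
#' @return A data.frame with `nsim` columns, each a profile summing to 1.
#' @export
simulate.fodm <- function(object, nsim = 1, seed = NULL, noise_sd = 0.05, ...) {
  rng <- .with_seed(seed)
  on.exit(rng())
  m <- object$profiles$m
  out <- replicate(nsim, .norm1(m * exp(stats::rnorm(object$n, 0, noise_sd))))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Per-residue profile table of a fit
#'
#' @param x A `fodm` fit.
#' @param ... Ignored.
#' @return data.frame: label, T, O, R, M (at fitted K).
#' @export
as.data.frame.fodm <- function(x, ...) {
  data.frame(label = x$labels, T = x$profiles$t, O = x$profiles$o,
             R = x$profiles$r, M = x$profiles$m, stringsAsFactors = FALSE)
}

# Set the RNG seed locally; returns a restorer function.
.with_seed <- function(seed) {
  if (is.null(seed)) return(function() invisible())
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible()
  }
}
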