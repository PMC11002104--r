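#' Analysis parameter set
#'
#' Bundles every convention the analysis depends on, so that each report
#' row is fully reproducible: the hydrophobicity scale, the interaction
#' cutoff, the Gaussian-width rule, the K grid and the interface contact
#' threshold.
#'
#' @param scale A `fod_scale` (default normalized Kyte-Doolittle).
#' @param cutoff Interaction cutoff in Angstrom (default 9).
#' @param sigma_rule,sigma_floor See [estimate_sigmas()].
#' @param include_self Include the self term in O (default FALSE).
#' @param k_grid K grid (default 0 to 10 by 0.01).
#' @param interface_threshold Effective-atom distance defining an
#'   inter-chain (P-P) contact, Angstrom (default = cutoff).
#' @return A `fod_params` list.
#' @export
fod_params <- function(scale = fod_scale(), cutoff = 9,
                       sigma_rule = "extent3", sigma_floor = 1,
                       include_self = FALSE, k_grid = seq(0, 10, by = 0.01),
                       interface_threshold = cutoff) {
  stopifnot(inherits(scale, "fod_scale"), cutoff > 0, interface_threshold > 0)
  structure(list(scale = scale, cutoff = cutoff, sigma_rule = sigma_rule,
                 sigma_floor = sigma_floor, include_self = include_self,
                 k_grid = k_grid, interface_threshold = interface_threshold),
            class = "fod_params")
}

#' Define an analysis unit by chains and residue ranges
#'
#' @param label Unit name used in reports.
#' @param chains Chain IDs included whole (optional).
#' @param ranges Optional data.frame with columns `chain`, `start`, `end`
#'   (inclusive, author numbering).
#' @return A `unit_selection`.
#' @export
unit_selection <- function(label, chains = NULL, ranges = NULL) {
  if (is.null(chains) && is.null(ranges))
    stop("selection '", label, "' needs chains and/or ranges")
  if (!is.null(ranges)) {
    ranges <- as.data.frame(ranges)
    stopifnot(all(c("chain", "start", "end") %in% names(ranges)))
    if (any(ranges$end < ranges$start)) stop("range with end < start")
  }
  structure(list(label = label, chains = chains, ranges = ranges),
            class = "unit_selection")
}

# Membership of effective-atom rows in a selection.
.sel_index <- function(ea, sel) {
  inx <- rep(FALSE, nrow(ea))
  if (!is.null(sel$chains)) inx <- inx | ea$chain %in% sel$chains
  if (!is.null(sel$ranges)) {
    for (i in seq_len(nrow(sel$ranges))) {
      r <- sel$ranges[i, ]
      inx <- inx | (ea$chain == r$chain & ea$resno >= r$start & ea$resno <= r$end)
    }
  }
  inx
}

# Human-readable residue-span text for a selection.
.fragment_text <- function(sel) {
  parts <- character(0)
  if (!is.null(sel$chains)) parts <- paste0("chain ", sel$chains)
  if (!is.null(sel$ranges))
    parts <- c(parts, sprintf("(%s%d-%d)",
                              ifelse(nzchar(sel$ranges$chain),
                                     paste0(sel$ranges$chain, ":"), ""),
                              sel$ranges$start, sel$ranges$end))
  paste(parts, collapse = " ")
}

# Effective atoms from whatever the caller holds.
.as_ea <- function(x, params) {
  if (inherits(x, "fod_structure")) return(effective_atoms(x, params$scale))
  if (inherits(x, "synthetic_unit")) {
    n <- x$n
    return(data.frame(chain = "A", resno = seq_len(n), insert = "",
                      resid = NA_character_,
                      label = paste0("A:", seq_len(n)),
                      x = x$points[, 1], y = x$points[, 2], z = x$points[, 3],
                      h = x$h, stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(x), all(c("x", "y", "z", "h") %in% names(x)))
  x
}

.record <- function(label, fragment, fit, rd_pp = NA_real_, rd_nopp = NA_real_,
                    mode, params) {
  data.frame(label = label, fragment = fragment, mode = mode,
             n_residues = fit$n, rd = fit$rd, rd_pp = rd_pp, rd_nopp = rd_nopp,
             k = fit$k,
             scale = params$scale$name, cutoff = params$cutoff,
             sigma_rule = params$sigma_rule,
             k_grid = paste0("[", min(params$k_grid), ",", max(params$k_grid),
                             "] step ",
                             round(stats::median(diff(sort(params$k_grid))), 6)),
             stringsAsFactors = FALSE)
}

.fit_sel <- function(ea, idx, params) {
  sub <- ea[idx, , drop = FALSE]
  if (nrow(sub) < 3) stop("selection resolves to fewer than 3 residues")
  fod_fit.default(as.matrix(sub[, c("x", "y", "z")]), h = sub$h,
                  labels = sub$label, cutoff = params$cutoff,
                  sigma_rule = params$sigma_rule,
                  sigma_floor = params$sigma_floor,
                  include_self = params$include_self,
                  k_grid = params$k_grid, scale = params$scale)
}

#' Analyze a selection as an individual structural unit
#'
#' The 3D Gaussian is generated for the selection itself: its residues are
#' centered and aligned, sigmas come from its own extent, and T, O, R, RD
#' and K are computed on the selection.
#'
#' @param x A `fod_structure`, effective-atom data.frame, or
#'   `synthetic_unit`.
#' @param sel A `unit_selection`; `NULL` means all residues.
#' @param params A [fod_params()] set.
#' @return One-row `AnalysisRecord` data.frame (label, fragment, mode,
#'   n_residues, rd, rd_pp, rd_nopp, k, provenance columns). The fitted
#'   model is attached as attribute `"fit"`.
#' @export
analyze_individual <- function(x, sel = NULL, params = fod_params()) {
  ea <- .as_ea(x, params)
  idx <- if (is.null(sel)) rep(TRUE, nrow(ea)) else .sel_index(ea, sel)
  fit <- .fit_sel(ea, idx, params)
  rec <- .record(if (is.null(sel)) "all" else sel$label,
                 if (is.null(sel)) "" else .fragment_text(sel),
                 fit, mode = "individual", params = params)
  attr(rec, "fit") <- fit
  rec
}

# Restrict a parent fit's T and O to a subset (relative index), renormalize,
# and refit RD/K on the restricted profiles. This is "component" mode: the
# Gaussian and the interactions are those of the parent; only the bookkeeping
# is restricted.
.restrict_fit <- function(parent_fit, rel_idx, params) {
  if (!any(rel_idx)) stop("empty restriction")
  t_sub <- .norm1(parent_fit$profiles$t[rel_idx])
  o_raw <- parent_fit$profiles$o[rel_idx]
  if (sum(o_raw) <= 0) stop("restricted observed profile is identically zero")
  .fodm_from_profiles(t = t_sub, o = .norm1(o_raw),
                      labels = parent_fit$labels[rel_idx],
                      params = parent_fit$params, k_grid = params$k_grid)
}

#' Analyze a selection as a component of a parent unit
#'
#' The Gaussian, orientation and observed interactions are those of the
#' parent; the resulting T and O are restricted to the sub-selection,
#' renormalized over it, and RD and K are computed on the restricted
#' profiles. A sub equal to the parent reproduces [analyze_individual()].
#'
#' @param x Structure or effective-atom input.
#' @param parent `unit_selection` defining the parent unit.
#' @param sub `unit_selection` contained in the parent.
#' @param params A [fod_params()] set.
#' @return One-row record data.frame, attribute `"fit"` = restricted fit.
#' @export
analyze_component <- function(x, parent, sub, params = fod_params()) {
  ea <- .as_ea(x, params)
  pidx <- if (is.null(parent)) rep(TRUE, nrow(ea)) else .sel_index(ea, parent)
  sidx <- .sel_index(ea, sub)
  if (any(sidx & !pidx)) stop("sub-selection not contained in parent")
  pfit <- .fit_sel(ea, pidx, params)
  rel <- sidx[pidx]
  fit <- .restrict_fit(pfit, rel, params)
  rec <- .record(sub$label, .fragment_text(sub), fit,
                 mode = "component", params = params)
  attr(rec, "fit") <- fit
  rec
}

#' Partition a unit's residues by inter-chain contact status
#'
#' A target residue has P-P (protein-protein interface) status when its
#' effective atom lies within `threshold` of any partner residue's
#' effective atom (boundary included).
#'
#' @param x Structure or effective-atom input.
#' @param target,partners Disjoint `unit_selection`s.
#' @param params A [fod_params()] set; `interface_threshold` is used.
#' @return List with logical vector `pp` over the target's residues (in
#'   target order), plus `labels`.
#' @export
interface_residues <- function(x, target, partners, params = fod_params()) {
  ea <- .as_ea(x, params)
  tix <- .sel_index(ea, target)
  pix <- .sel_index(ea, partners)
  if (any(tix & pix)) stop("partners overlap the target selection")
  tgt <- as.matrix(ea[tix, c("x", "y", "z")])
  prt <- as.matrix(ea[pix, c("x", "y", "z")])
  pp <- if (nrow(prt) == 0) rep(FALSE, nrow(tgt)) else {
    d2 <- outer(rowSums(tgt^2), rowSums(prt^2), `+`) - 2 * tgt %*% t(prt)
    apply(sqrt(pmax(d2, 0)), 1, min) <= params$interface_threshold
  }
  list(pp = unname(pp), labels = ea$label[tix])
}

#' Analyze a unit with interface residue classes
#'
#' RD is computed on the full target (individual mode); the bracketed
#' RD(P-P) and RD(no P-P) values come from component-style restriction of
#' the target's own T and O to the contact / non-contact residue classes.
#' An empty class leaves the corresponding field absent (NA), the analogue
#' of a dash in a report table.
#'
#' @param x Structure or effective-atom input.
#' @param target Target `unit_selection`.
#' @param partners Partner `unit_selection` (or NULL for no interface).
#' @param params A [fod_params()] set.
#' @return One-row record data.frame with rd, rd_pp, rd_nopp, k.
#' @export
analyze_with_interface <- function(x, target, partners, params = fod_params()) {
  ea <- .as_ea(x, params)
  tix <- .sel_index(ea, target)
  fit <- .fit_sel(ea, tix, params)
  rd_pp <- rd_nopp <- NA_real_
  if (!is.null(partners)) {
    iface <- interface_residues(x, target, partners, params)
    if (any(iface$pp))
      rd_pp <- .restrict_fit(fit, iface$pp, params)$rd
    if (any(!iface$pp))
      rd_nopp <- .restrict_fit(fit, !iface$pp, params)$rd
  }
  rec <- .record(target$label, .fragment_text(target), fit,
                 rd_pp = rd_pp, rd_nopp = rd_nopp,
                 mode = "individual", params = params)
  attr(rec, "fit") <- fit
  rec
}

#' Full multi-chain complex analysis
#'
#' Emits the standard report for an oligomeric complex: one row for the
#' whole complex (all chains as one unit), one row per chain as a component
#' of the complex (complex Gaussian, profiles restricted to the chain), one
#' row per chain as an individual unit (own Gaussian), and one
#' component-mode row per named partition (e.g. beta-sheet "stem" and
#' helical "tentacle" residue ranges supplied via config).
#'
#' @param x A `fod_structure` (or effective-atom data.frame with chains).
#' @param partitions Optional named list of `unit_selection`s analyzed as
#'   components of the whole complex.
#' @param params A [fod_params()] set.
#' @return data.frame of records, one row per analysis.
#' @export
analyze_complex <- function(x, partitions = NULL, params = fod_params()) {
  ea <- .as_ea(x, params)
  chains <- unique(ea$chain)
  whole <- unit_selection("complex", chains = chains)
  rows <- list(analyze_individual(x, whole, params))
  for (ch in chains) {
    chsel <- unit_selection(paste0("chain_", ch, "_in_complex"), chains = ch)
    rows[[length(rows) + 1]] <- analyze_component(x, whole, chsel, params)
    ind <- unit_selection(paste0("chain_", ch, "_individual"), chains = ch)
    rows[[length(rows) + 1]] <- analyze_individual(x, ind, params)
  }
  for (p in partitions)
    rows[[length(rows) + 1]] <- analyze_component(x, whole, p, params)
  out <- do.call(rbind, lapply(rows, function(r) { attr(r, "fit") <- NULL; r }))
  rownames(out) <- NULL
  out
}

#' Write an analysis report as TSV (+ JSON provenance sidecar)
#'
#' Columns label, fragment, RD, RD_PP, RD_noPP, K; RD printed to 3 decimals
#' and K to 1 decimal, the precision these tables are conventionally read
#' at. Absent interface classes print as "-". A `<path>.json` sidecar
#' records the full parameter provenance.
#'
#' @param records data.frame of analysis records.
#' @param path Output TSV path.
#' @param params The [fod_params()] used (for the sidecar).
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, params = fod_params()) {
  fmt <- function(v, d) ifelse(is.na(v), "-", formatC(v, digits = d, format = "f"))
  tab <- data.frame(label = records$label, fragment = records$fragment,
                    mode = records$mode, n = records$n_residues,
                    RD = fmt(records$rd, 3), RD_PP = fmt(records$rd_pp, 3),
                    RD_noPP = fmt(records$rd_nopp, 3), K = fmt(records$k, 1),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(scale = params$scale$name, cutoff = params$cutoff,
               sigma_rule = params$sigma_rule,
               sigma_floor = params$sigma_floor,
               include_self = params$include_self,
               k_grid = list(min = min(params$k_grid),
                             max = max(params$k_grid),
                             step = stats::median(diff(sort(params$k_grid)))),
               interface_threshold = params$interface_threshold)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
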