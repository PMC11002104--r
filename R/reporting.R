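#' Read a run configuration
#'
#' A run configuration is a YAML file naming the structure, the analysis
#' conventions and the units to analyze. Shipped examples covering actin,
#' tubulin and prefoldin live under `system.file("extdata", package =
#' "fodm")`. Schema:
#' \preformatted{
#' id: actin_1d4x
#' structure: 1D4X.pdb        # path or PDB accession (fetched if absent)
#' params:
#'   scale: kyte_doolittle
#'   cutoff: 9.0
#'   sigma_rule: extent3
#'   sigma_floor: 1.0
#'   k_max: 10.0
#'   k_step: 0.01
#'   interface_threshold: 9.0
#' units:
#'   - label: Domain 1
#'     mode: individual       # or component
#'     parent: {chains: [A]}  # component mode only
#'     ranges: [{chain: A, start: 4, end: 137}]
#'     chains: [A]            # and/or whole chains
#'     partners: {chains: [G]}   # optional: P-P status against these
#' }
#'
#' @param path YAML file path.
#' @return A validated `fod_config` list with elements `id`, `structure`,
#'   `params` (a [fod_params()]), `units`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (field in c("id", "structure", "units"))
    if (is.null(cfg[[field]]))
      stop("config is missing required field '", field, "'")
  p <- cfg$params
  if (is.null(p)) p <- list()
  k_max <- if (is.null(p$k_max)) 10 else p$k_max
  k_step <- if (is.null(p$k_step)) 0.01 else p$k_step
  params <- fod_params(
    scale = fod_scale(if (is.null(p$scale)) "kyte_doolittle" else p$scale),
    cutoff = if (is.null(p$cutoff)) 9 else p$cutoff,
    sigma_rule = if (is.null(p$sigma_rule)) "extent3" else p$sigma_rule,
    sigma_floor = if (is.null(p$sigma_floor)) 1 else p$sigma_floor,
    include_self = isTRUE(p$include_self),
    k_grid = seq(0, k_max, by = k_step),
    interface_threshold = if (is.null(p$interface_threshold)) {
      if (is.null(p$cutoff)) 9 else p$cutoff
    } else p$interface_threshold
  )
  units <- lapply(cfg$units, .parse_unit_cfg)
  structure(list(id = cfg$id, structure = cfg$structure,
                 params = params, units = units,
                 partitions = lapply(cfg$partitions, .parse_sel_cfg)),
            class = "fod_config")
}

.parse_sel_cfg <- function(s, label = "selection") {
  if (is.null(s)) return(NULL)
  ranges <- if (!is.null(s$ranges))
    do.call(rbind, lapply(s$ranges, function(r) {
      for (f in c("chain", "start", "end"))
        if (is.null(r[[f]])) stop("range in '", label, "' missing '", f, "'")
      data.frame(chain = as.character(r$chain), start = r$start, end = r$end,
                 stringsAsFactors = FALSE)
    }))
  unit_selection(if (is.null(s$label)) label else s$label,
                 chains = if (is.null(s$chains)) NULL else as.character(unlist(s$chains)),
                 ranges = ranges)
}

.parse_unit_cfg <- function(u) {
  if (is.null(u$label)) stop("config unit is missing 'label'")
  mode <- if (is.null(u$mode)) "individual" else u$mode
  if (!mode %in% c("individual", "component"))
    stop("unit '", u$label, "': unknown mode '", mode, "'")
  list(label = u$label, mode = mode,
       sel = .parse_sel_cfg(u, label = u$label),
       parent = if (is.null(u$parent)) NULL else
         .parse_sel_cfg(u$parent, label = paste0(u$label, ".parent")),
       partners = if (is.null(u$partners)) NULL else
         .parse_sel_cfg(u$partners, label = paste0(u$label, ".partners")))
}

# One configured unit -> record (handles mode x interface combinations).
.analyze_unit_cfg <- function(x, u, params) {
  ea <- .as_ea(x, params)
  if (u$mode == "individual") {
    fit <- .fit_sel(ea, .sel_index(ea, u$sel), params)
  } else {
    pidx <- if (is.null(u$parent)) rep(TRUE, nrow(ea)) else .sel_index(ea, u$parent)
    sidx <- .sel_index(ea, u$sel)
    if (any(sidx & !pidx)) stop("unit '", u$label, "' not contained in parent")
    fit <- .restrict_fit(.fit_sel(ea, pidx, params), sidx[pidx], params)
  }
  rd_pp <- rd_nopp <- NA_real_
  if (!is.null(u$partners)) {
    iface <- interface_residues(x, u$sel, u$partners, params)
    if (any(iface$pp)) rd_pp <- .restrict_fit(fit, iface$pp, params)$rd
    if (any(!iface$pp)) rd_nopp <- .restrict_fit(fit, !iface$pp, params)$rd
  }
  rec <- .record(u$label, .fragment_text(u$sel), fit,
                 rd_pp = rd_pp, rd_nopp = rd_nopp, mode = u$mode,
                 params = params)
  attr(rec, "fit") <- fit
  rec
}

#' Run a configured analysis and write its reports
#'
#' Executes every unit in a run configuration against a structure file and
#' writes a report TSV (with JSON provenance sidecar) plus one per-residue
#' profile CSV per unit.
#'
#' @param config Path to a YAML run config, or a `fod_config`.
#' @param structure_path Optional override for the config's structure path.
#' @param out_dir Output directory (created if needed).
#' @return The records data.frame, invisibly; files are the main output.
#' @export
fod_analyze <- function(config, structure_path = NULL, out_dir = ".") {
  if (!inherits(config, "fod_config")) config <- read_run_config(config)
  path <- if (is.null(structure_path)) config$structure else structure_path
  if (!file.exists(path))
    stop("structure file not found: ", path,
         " (use fod_fetch() to download by accession)")
  st <- read_structure(path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- list()
  for (u in config$units) {
    rec <- .analyze_unit_cfg(st, u, config$params)
    fit <- attr(rec, "fit")
    slug <- gsub("[^A-Za-z0-9]+", "_", u$label)
    utils::write.csv(.profile_table(fit),
                     file.path(out_dir, paste0(config$id, "_", slug, ".csv")),
                     row.names = FALSE)
    attr(rec, "fit") <- NULL
    recs[[length(recs) + 1]] <- rec
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  write_report(records, file.path(out_dir, paste0(config$id, "_report.tsv")),
               config$params)
  invisible(records)
}

.profile_table <- function(fit) {
  lab <- strsplit(fit$labels, ":", fixed = TRUE)
  data.frame(chain = vapply(lab, function(l) l[1], character(1)),
             seq_id = vapply(lab, function(l) if (length(l) > 1) l[2] else NA_character_,
                             character(1)),
             T = fit$profiles$t, O = fit$profiles$o, R = fit$profiles$r,
             M = fit$profiles$m, stringsAsFactors = FALSE)
}

#' Fetch structures from the PDB into a local cache
#'
#' Downloads `https://files.rcsb.org/download/<ID>.pdb` (mmCIF for large
#' entries on request) into `cache_dir`; cached files are reused so that
#' analyses re-run offline. A failed download leaves no partial cache entry.
#'
#' @param accessions Character vector of 4-character PDB IDs.
#' @param cache_dir Cache directory (default `"pdb_cache"`).
#' @param format `"pdb"` or `"cif"`.
#' @return Named character vector of cached file paths.
#' @export
fod_fetch <- function(accessions, cache_dir = "pdb_cache", format = c("pdb", "cif")) {
  format <- match.arg(format)
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (acc in toupper(accessions)) {
    if (!grepl("^[0-9][A-Z0-9]{3}$", acc)) stop("not a PDB accession: ", acc)
    dest <- file.path(cache_dir, paste0(acc, ".", format))
    if (!file.exists(dest)) {
      url <- sprintf("https://files.rcsb.org/download/%s.%s", acc, format)
      ok <- tryCatch(
        utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0,
        error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok || !file.size(dest) > 0) {
        unlink(dest)
        stop("failed to fetch ", acc, " from ", url)
      }
    }
    out[acc] <- dest
  }
  out
}

#' Per-residue profiles of one unit, as CSV and optional plot
#'
#' @param x Structure, effective-atom data.frame, or `synthetic_unit`.
#' @param sel Optional `unit_selection` (default: everything).
#' @param params A [fod_params()] set.
#' @param path Output CSV path.
#' @param plot_path Optional PNG path for the T/O/M profile chart.
#' @return The `fodm` fit, invisibly.
#' @export
fod_profiles <- function(x, sel = NULL, params = fod_params(), path,
                         plot_path = NULL) {
  rec <- analyze_individual(x, sel, params)
  fit <- attr(rec, "fit")
  utils::write.csv(.profile_table(fit), path, row.names = FALSE)
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 900, height = 500)
    plot(fit)
    grDevices::dev.off()
  }
  invisible(fit)
}

#' Convention sensitivity sweep
#'
#' The analysis depends on conventions that published work does not always
#' state: the hydrophobicity scale, the Gaussian-width rule, the cutoff,
#' and whether O includes the self term. This sweep recomputes RD and K for
#' one unit across a grid of conventions and, given reference values,
#' orders the conventions by agreement so the closest-matching one can be
#' reported.
#'
#' @param x Structure, effective-atom data.frame, or `synthetic_unit`.
#' @param sel Optional `unit_selection`.
#' @param reference Optional named vector `c(rd = ..., k = ...)` to rank
#'   against.
#' @param scales Character vector of built-in scale names.
#' @param sigma_rules Character vector of sigma rules.
#' @param cutoffs Numeric vector of cutoffs (Angstrom).
#' @param include_self Logical vector of self-term choices.
#' @return data.frame of conventions with rd, k and (given a reference)
#'   `mismatch` = |rd - rd_ref| + 0.1 |k - k_ref|, sorted ascending.
#' @export
sensitivity_sweep <- function(x, sel = NULL, reference = NULL,
                              scales = c("kyte_doolittle", "fauchere_pliska"),
                              sigma_rules = c("extent3", "extent6", "sd"),
                              cutoffs = c(9),
                              include_self = c(FALSE, TRUE)) {
  grid <- expand.grid(scale = scales, sigma_rule = sigma_rules,
                      cutoff = cutoffs, include_self = include_self,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    p <- fod_params(scale = fod_scale(g$scale), cutoff = g$cutoff,
                    sigma_rule = g$sigma_rule, include_self = g$include_self)
    rec <- analyze_individual(x, sel, p)
    data.frame(g, rd = rec$rd, k = rec$k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(reference)) {
    out$mismatch <- abs(out$rd - reference[["rd"]]) +
      0.1 * abs(out$k - reference[["k"]])
    out <- out[order(out$mismatch), ]
  }
  rownames(out) <- NULL
  out
}
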