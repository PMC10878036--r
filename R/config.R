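#' Analysis configuration
#'
#' Central registry of the thresholds the pipeline uses. Defaults follow the
#' study design: dominance at >1% relative abundance, viral dominance at
#' TPM rank within 100, coverage gate at 80% of contig length, P < 0.05 and
#' BH Q < 0.05 for infection pairs, short/persistent dominance cutoffs at
#' 10%/75% of the study period, de-stratification at a surface-deep
#' temperature difference under 1 degree C, and 1.83e6 cells per pmol for the
#' deoxyadenosine-incorporation conversion.
#'
#' @param seed integer seed used by stochastic steps (rarefaction).
#' @param dominance_threshold relative-abundance cutoff (strict >).
#' @param lbv_rank_cutoff TPM rank cutoff for viral dominance.
#' @param coverage_gate minimum covered fraction; TPM below it is zeroed.
#' @param p_cut,q_cut correlation test cutoffs for infection pairs.
#' @param short_frac,persistent_frac dominance-pattern boundaries.
#' @param destrat_dT de-stratification temperature criterion (degrees C).
#' @param conversion_factor cells produced per pmol incorporated.
#' @return a list of class `lake_config`.
#' @export
lake_config <- function(seed = 1L,
                        dominance_threshold = 0.01,
                        lbv_rank_cutoff = 100L,
                        coverage_gate = 0.8,
                        p_cut = 0.05,
                        q_cut = 0.05,
                        short_frac = 0.10,
                        persistent_frac = 0.75,
                        destrat_dT = 1.0,
                        conversion_factor = 1.83e6) {
  cfg <- list(seed = as.integer(seed),
              dominance_threshold = dominance_threshold,
              lbv_rank_cutoff = as.integer(lbv_rank_cutoff),
              coverage_gate = coverage_gate,
              p_cut = p_cut, q_cut = q_cut,
              short_frac = short_frac, persistent_frac = persistent_frac,
              destrat_dT = destrat_dT,
              conversion_factor = conversion_factor)
  for (f in c("dominance_threshold", "coverage_gate", "p_cut", "q_cut",
              "short_frac", "persistent_frac"))
    assert_scalar_num(cfg[[f]], f, lower = 1e-12, upper = 1)
  assert_scalar_num(cfg$destrat_dT, "destrat_dT", lower = 1e-12)
  assert_scalar_num(cfg$conversion_factor, "conversion_factor", lower = 1e-12)
  if (cfg$lbv_rank_cutoff < 1L) stop_("lbv_rank_cutoff must be >= 1")
  class(cfg) <- "lake_config"
  cfg
}

#' Read a configuration file (YAML or JSON); unset keys take defaults
#' @param path YAML/JSON file; top-level keys as in [lake_config()].
#' @param ... overrides applied after the file (highest precedence).
#' @return a `lake_config`.
#' @export
read_lake_config <- function(path, ...) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  known <- names(formals(lake_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop_("unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(lake_config, vals)
}

#' @export
print.lake_config <- function(x, ...) {
  cat("lake_config:\n")
  for (n in names(x)) cat(sprintf("  %-20s %s\n", n, format(x[[n]])))
  invisible(x)
}

#' Write the effective configuration and a run manifest
#' @param cfg a `lake_config`.
#' @param out_dir output directory (created if needed).
#' @param inputs named character vector of input paths (recorded verbatim).
#' @return path of the manifest JSON, invisibly.
#' @export
write_run_manifest <- function(cfg, out_dir, inputs = character()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "effective_config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    inputs = as.list(inputs),
    seed = cfg$seed,
    config_hash = sprintf("%08x", id_hash(paste(
      names(cfg), vapply(cfg, function(v) format(v, digits = 17), ""),
      collapse = ";"))),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mpath <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE)
  invisible(mpath)
}
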