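#' Run the full inference chain on a lake data set
#'
#' Seasons from temperature, relative abundance, coverage-gated TPM, habitat
#' preference per season, layer dissimilarity and time-lag turnover, dominance
#' patterns, host assignment, and infection-pair extraction.
#'
#' @param meta metadata data.frame.
#' @param asv_counts counts `feature_table` of ASVs.
#' @param lbv_counts counts `feature_table` of viral contigs (lengths attached).
#' @param coverage coverage-fraction matrix matching `lbv_counts`.
#' @param evidence host-prediction evidence data.frame.
#' @param taxonomy ASV taxonomy data.frame (optional).
#' @param cfg a [lake_config()].
#' @return list of class `lake_pipeline` with the stage outputs.
#' @export
run_lake_pipeline <- function(meta, asv_counts, lbv_counts, coverage,
                              evidence, taxonomy = NULL,
                              cfg = lake_config()) {
  seasons <- classify_seasons(meta, cfg$destrat_dT)
  rel_ab <- relative_abundance(asv_counts)
  tpm <- gate_tpm(compute_tpm(lbv_counts), coverage, cfg$coverage_gate)

  habitat <- lapply(
    stats::setNames(nm = c("destratified", "beginning", "middle", "end")),
    function(lb) {
      mm <- season_months(seasons, lb)
      if (!length(mm)) return(NULL)
      p_habitat(tpm, meta, mm)
    })

  layer_bc <- list(asv = layer_dissimilarity_series(rel_ab, meta),
                   lbv = layer_dissimilarity_series(tpm, meta))
  lag <- list(asv_surface = timelag_curve(rel_ab, meta, "surface"),
              asv_deep = timelag_curve(rel_ab, meta, "deep"),
              lbv_surface = timelag_curve(tpm, meta, "surface"),
              lbv_deep = timelag_curve(tpm, meta, "deep"))

  dominance <- list(
    asv_surface = dominance_table(rel_ab, meta, "surface", "asv", cfg),
    asv_deep = dominance_table(rel_ab, meta, "deep", "asv", cfg),
    lbv_surface = dominance_table(tpm, meta, "surface", "lbv", cfg),
    lbv_deep = dominance_table(tpm, meta, "deep", "lbv", cfg))

  assignments <- assign_hosts(evidence)
  hosts <- host_summary(assignments, tpm)
  pairs <- infection_pairs(rel_ab, tpm, meta, seasons, assignments,
                           taxonomy, cfg)

  structure(list(seasons = seasons, rel_ab = rel_ab, tpm = tpm,
                 habitat = habitat, layer_bc = layer_bc, lag = lag,
                 dominance = dominance, assignments = assignments,
                 hosts = hosts, pairs = pairs, cfg = cfg),
            class = "lake_pipeline")
}

#' Convenience: run the pipeline on a simulated data set
#' @param sim a `lake_sim` (see [simulate_lake()]).
#' @param cfg a [lake_config()].
#' @return a `lake_pipeline`.
#' @export
run_lake_pipeline_sim <- function(sim, cfg = lake_config(seed = sim$config$seed)) {
  run_lake_pipeline(sim$meta, sim$asv_counts, sim$lbv_counts, sim$coverage,
                    sim$evidence, sim$taxonomy, cfg)
}

#' @export
print.lake_pipeline <- function(x, ...) {
  np <- if (is.null(x$pairs$pairs)) 0L else nrow(x$pairs$pairs)
  cat("lake pipeline result\n")
  cat(sprintf("  months: %d (%d de-stratified)\n",
              nrow(x$seasons), sum(x$seasons$label == "destratified")))
  cat(sprintf("  features: %d ASVs, %d viral contigs\n",
              nrow(x$rel_ab$values), nrow(x$tpm$values)))
  cat(sprintf("  host-assigned contigs: %d\n",
              sum(!is.na(x$assignments$taxon))))
  cat(sprintf("  dominant ASVs: %d; retained infection pairs: %d\n",
              length(x$pairs$asv_dominant), np))
  invisible(x)
}

#' @export
summary.lake_pipeline <- function(object, ...) {
  x <- object
  bc <- x$layer_bc$asv
  cat("surface-vs-deep Bray-Curtis (ASVs):\n")
  cat(sprintf("  min %.3f (month %d), max %.3f (month %d)\n",
              min(bc$bc), bc$month_index[which.min(bc$bc)],
              max(bc$bc), bc$month_index[which.max(bc$bc)]))
  lag <- x$lag$asv_surface
  for (k in c(6, 12)) if (k %in% lag$lag_months)
    cat(sprintf("  surface lag-%d mean BC %.3f (n=%d)\n", k,
                lag$mean_bc[lag$lag_months == k],
                lag$n_pairs[lag$lag_months == k]))
  if (!is.null(x$pairs$summary)) {
    s <- x$pairs$summary
    cat(sprintf("pairs: %d ASVs x %d contigs\n", s$n_asv, s$n_lbv))
    print(s$monthly, row.names = FALSE)
  }
  invisible(x)
}
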