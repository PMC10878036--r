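#' Number of months a feature exists
#'
#' Counts months with abundance strictly above zero. NA entries stand for
#' unsampled months and are excluded from both the count and the effective
#' study length.
#'
#' @param series abundance vector over a layer's months.
#' @return integer count.
#' @export
existence_months <- function(series) sum(series > 0, na.rm = TRUE)

#' Number of months a prokaryotic feature is dominant
#'
#' Dominance is relative abundance strictly above the threshold (default 1%).
#'
#' @param series proportion vector over a layer's months.
#' @param threshold relative-abundance cutoff (strict `>`).
#' @return integer count.
#' @export
dominance_months_asv <- function(series, threshold = 0.01) {
  assert_scalar_num(threshold, "threshold", lower = 1e-12, upper = 1)
  sum(series > threshold, na.rm = TRUE)
}

#' Number of months each viral contig is dominant
#'
#' Per month, contigs are ranked within the layer by descending gated TPM
#' (ties broken by id for determinism); a contig is dominant in a month when
#' its TPM is positive and its rank is within the cutoff, so the dominant set
#' has exactly min(cutoff, number of detected contigs) members.
#'
#' @param tpm a gated TPM `feature_table`.
#' @param meta metadata data.frame.
#' @param layer `"surface"` or `"deep"`.
#' @param rank_cutoff rank threshold (default 100).
#' @return named integer vector, one entry per contig.
#' @export
dominance_months_lbv <- function(tpm, meta, layer = c("surface", "deep"),
                                 rank_cutoff = 100L) {
  layer <- match.arg(layer)
  stopifnot(inherits(tpm, "feature_table"))
  v <- tpm$values
  ids <- meta$sample_id[meta$layer == layer & meta$sample_id %in% colnames(v)]
  counts <- stats::setNames(integer(nrow(v)), rownames(v))
  for (sid in ids) {
    col <- v[, sid]
    nz <- which(col > 0)
    if (!length(nz)) next
    ord <- nz[order(-col[nz], rownames(v)[nz])]
    top <- ord[seq_len(min(rank_cutoff, length(ord)))]
    counts[top] <- counts[top] + 1L
  }
  counts
}

#' Classify a feature's temporal dominance pattern
#'
#' Short: dominant in at least one month but less than `short_frac` of the
#' study period; persistent: more than `persistent_frac`; intermediate:
#' anything between; never_dominant: zero dominant months. Fractions are
#' strict inequalities and use the layer's own number of observed months as
#' the denominator.
#'
#' @param months_dominant integer (vectorised).
#' @param study_months number of observed months (>= 1).
#' @param short_frac,persistent_frac boundaries (defaults 0.10 and 0.75).
#' @return character vector of pattern labels.
#' @export
classify_pattern <- function(months_dominant, study_months,
                             short_frac = 0.10, persistent_frac = 0.75) {
  if (any(study_months < 1L)) stop_("study_months must be >= 1")
  if (any(months_dominant < 0) || any(months_dominant > study_months))
    stop_("months_dominant must lie in [0, study_months]")
  frac <- months_dominant / study_months
  ifelse(months_dominant == 0, "never_dominant",
         ifelse(frac < short_frac, "short",
                ifelse(frac > persistent_frac, "persistent", "intermediate")))
}

#' Existence/dominance summary for every feature in a layer
#'
#' Builds the scatter behind existence-versus-predominance plots: months
#' present, months dominant and the dominance pattern per feature, for either
#' prokaryotic (proportion + threshold) or viral (TPM + rank) dominance.
#'
#' @param table proportion table (ASVs) or gated TPM table (viral contigs).
#' @param meta metadata data.frame.
#' @param layer layer to summarise.
#' @param kind `"asv"` (threshold rule) or `"lbv"` (rank rule).
#' @param cfg a [lake_config()] providing the thresholds.
#' @return data.frame: feature_id, layer, months_present, months_dominant,
#'   study_months, pattern.
#' @export
dominance_table <- function(table, meta, layer = c("surface", "deep"),
                            kind = c("asv", "lbv"), cfg = lake_config()) {
  layer <- match.arg(layer); kind <- match.arg(kind)
  v <- table$values
  ids <- meta$sample_id[meta$layer == layer & meta$sample_id %in% colnames(v)]
  if (!length(ids)) stop_("no samples for layer '%s'", layer)
  sub <- v[, ids, drop = FALSE]
  study <- length(ids)
  present <- apply(sub, 1L, existence_months)
  dominant <- if (kind == "asv")
    apply(sub, 1L, dominance_months_asv, threshold = cfg$dominance_threshold)
  else
    dominance_months_lbv(table, meta, layer, cfg$lbv_rank_cutoff)
  data.frame(feature_id = rownames(v), layer = layer,
             months_present = unname(present),
             months_dominant = unname(dominant[rownames(v)]),
             study_months = study,
             pattern = classify_pattern(unname(dominant[rownames(v)]), study,
                                        cfg$short_frac, cfg$persistent_frac),
             row.names = NULL)
}
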