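#' Seasonal habitat preference of viral contigs
#'
#' For each contig, TPM is summed over the season's months separately in the
#' surface and the deep layer; the habitat preference is the surface share,
#' surface / (surface + deep). A value of 0 means the virus was found only
#' in the deep layer, 1 only in the surface layer. A contig absent from both
#' layers in the season has no defined preference and is reported as NA
#' (never as 0 or 0.5, both of which carry meaning).
#'
#' @param tpm a coverage-gated TPM `feature_table`.
#' @param meta metadata data.frame.
#' @param season_months integer vector of month indices defining the season.
#' @return data.frame: lbv_id, surface_sum, deep_sum, p_habitat (NA when
#'   undefined).
#' @export
p_habitat <- function(tpm, meta, season_months) {
  stopifnot(inherits(tpm, "feature_table"))
  if (!length(season_months)) stop_("season_months must be non-empty")
  sub <- meta[meta$month_index %in% season_months &
                meta$sample_id %in% colnames(tpm$values), ]
  s_ids <- sub$sample_id[sub$layer == "surface"]
  d_ids <- sub$sample_id[sub$layer == "deep"]
  if (!length(s_ids) || !length(d_ids))
    stop_("both layers must be sampled in at least one season month")
  v <- tpm$values
  s_sum <- rowSums(v[, s_ids, drop = FALSE])
  d_sum <- rowSums(v[, d_ids, drop = FALSE])
  tot <- s_sum + d_sum
  data.frame(lbv_id = rownames(v),
             surface_sum = unname(s_sum), deep_sum = unname(d_sum),
             p_habitat = ifelse(tot > 0, s_sum / tot, NA_real_),
             row.names = NULL)
}

#' Histogram of habitat-preference values
#'
#' Equal-width bins over [0, 1]; undefined (NA) records are dropped and
#' their count reported via a message. The first bin is closed on the left;
#' interior bins are right-closed, so 0 falls in bin 1 and 1 in the last.
#'
#' @param records output of [p_habitat()] (or a numeric vector of values).
#' @param bins number of bins (>= 1).
#' @return integer vector of bin counts with a `breaks` attribute.
#' @export
p_habitat_histogram <- function(records, bins = 20L) {
  if (bins < 1L) stop_("bins must be >= 1")
  vals <- if (is.data.frame(records)) records$p_habitat else as.numeric(records)
  n_na <- sum(is.na(vals))
  if (n_na) message(sprintf("dropping %d undefined habitat-preference records", n_na))
  vals <- vals[!is.na(vals)]
  if (any(vals < 0 | vals > 1)) stop_("habitat preference outside [0, 1]")
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- if (length(vals))
    as.integer(table(cut(vals, breaks, include.lowest = TRUE)))
  else integer(bins)
  structure(counts, breaks = breaks, dropped = n_na)
}
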