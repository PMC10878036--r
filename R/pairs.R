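#' Select the dominant bloomer ASVs
#'
#' An ASV qualifies when its maximum relative abundance over the whole
#' surface-layer series (a) is attained in a middle-stratified month of the
#' focal year and (b) strictly exceeds the dominance threshold. Ties for the
#' maximum count as qualifying if any tying month falls in the window.
#'
#' @param rel_ab proportion `feature_table`.
#' @param seasons output of [classify_seasons()].
#' @param meta metadata data.frame.
#' @param threshold relative-abundance cutoff (strict `>`).
#' @param year focal year of the middle-stratified window (default 2019).
#' @return character vector of selected ASV ids.
#' @export
select_asv_dominant <- function(rel_ab, seasons, meta, threshold = 0.01,
                                year = 2019L) {
  stopifnot(inherits(rel_ab, "feature_table"))
  mid <- seasons$month_index[seasons$label == "middle" & seasons$year == year]
  if (!length(mid))
    stop_("no middle-stratified month in year %d", year)
  sub <- meta[meta$layer == "surface" & meta$sample_id %in% colnames(rel_ab$values), ]
  sub <- sub[order(sub$month_index), ]
  v <- rel_ab$values[, sub$sample_id, drop = FALSE]
  in_window <- sub$month_index %in% mid
  sel <- apply(v, 1L, function(x) {
    mx <- max(x)
    mx > threshold && any(in_window[x == mx])
  })
  rownames(v)[sel]
}

# Pearson r and two-sided p for every (ASV, LBV) series pair with at least
# `min_shared` co-observed months; returns the full tested family.
cor_family <- function(asv_mat, lbv_mat, min_shared = 4L) {
  rows <- list()
  for (a in rownames(asv_mat)) for (l in rownames(lbv_mat)) {
    x <- asv_mat[a, ]; y <- lbv_mat[l, ]
    shared <- !is.na(x) & !is.na(y)
    if (sum(shared) < min_shared) {
      message(sprintf("pair (%s, %s): only %d shared months; skipped",
                      a, l, sum(shared)))
      next
    }
    xs <- x[shared]; ys <- y[shared]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next  # degenerate series
    ct <- stats::cor.test(xs, ys, method = "pearson")
    rows[[length(rows) + 1L]] <-
      data.frame(asv_id = a, lbv_id = l, pearson_r = unname(ct$estimate),
                 p_value = ct$p.value, n_months = sum(shared))
  }
  if (!length(rows))
    return(data.frame(asv_id = character(), lbv_id = character(),
                      pearson_r = numeric(), p_value = numeric(),
                      n_months = integer()))
  do.call(rbind, rows)
}

#' Extract co-occurring virus-host pairs by correlation with FDR control
#'
#' Pearson correlation between every dominant-ASV series and every candidate
#' viral series on their shared months, Benjamini-Hochberg correction across
#' the whole tested family jointly, and retention of positively correlated
#' pairs with p and q below their cutoffs.
#'
#' @param asv_mat ASV x month matrix (relative abundance, surface layer);
#'   NA marks unsampled months.
#' @param lbv_mat LBV x month matrix (gated TPM, surface layer), same month
#'   columns.
#' @param p_cut,q_cut retention cutoffs (default 0.05 both).
#' @param min_shared minimum co-observed months per pair (default 4).
#' @return list: `pairs` (retained), `tested` (all pairs with r, p, q).
#' @export
pearson_fdr_pairs <- function(asv_mat, lbv_mat, p_cut = 0.05, q_cut = 0.05,
                              min_shared = 4L) {
  if (!identical(colnames(asv_mat), colnames(lbv_mat)))
    stop_("ASV and LBV matrices must share month columns")
  fam <- cor_family(asv_mat, lbv_mat, min_shared)
  fam$q_value <- stats::p.adjust(fam$p_value, method = "BH")
  keep <- fam$pearson_r > 0 & fam$p_value < p_cut & fam$q_value < q_cut
  list(pairs = fam[keep, , drop = FALSE], tested = fam)
}

#' One-sided Mann-Whitney check that a virus rises with its putative host
#'
#' Compares the contig's abundance between the months in which the putative
#' host was dominant (during the focal year's productive period) and the
#' focal year's other months, one-sided for larger abundance in host months.
#' A series with no variation is flagged degenerate (p reported as 1).
#'
#' @param lbv_series named numeric vector (names = month indices).
#' @param host_dominant_months,other_months integer vectors of month indices.
#' @return list: `p_value`, `degenerate`.
#' @export
mw_validate <- function(lbv_series, host_dominant_months, other_months) {
  if (!length(host_dominant_months) || !length(other_months))
    stop_("both month sets must be non-empty")
  x <- lbv_series[as.character(host_dominant_months)]
  y <- lbv_series[as.character(other_months)]
  if (anyNA(x) || anyNA(y))
    stop_("lbv_series lacks values for some requested months")
  if (stats::sd(c(x, y)) == 0)
    return(list(p_value = 1, degenerate = TRUE))
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater"))
  list(p_value = ht$p.value, degenerate = FALSE)
}

#' Summarise retained infection pairs
#'
#' @param pairs retained pairs data.frame (from [pearson_fdr_pairs()]).
#' @param rel_ab proportion `feature_table` (ASVs).
#' @param tpm gated TPM `feature_table` (LBVs).
#' @param meta metadata data.frame.
#' @param months month indices to report monthly totals for.
#' @return list: `n_asv`, `n_lbv`, and `monthly` (per month: summed relative
#'   abundance of paired ASVs; fraction of total TPM carried by paired LBVs),
#'   surface layer.
#' @export
summarize_pairs <- function(pairs, rel_ab, tpm, meta, months) {
  asvs <- unique(pairs$asv_id)
  lbvs <- unique(pairs$lbv_id)
  sub <- meta[meta$layer == "surface" & meta$month_index %in% months, ]
  monthly <- do.call(rbind, lapply(sub$month_index, function(m) {
    sid <- sub$sample_id[sub$month_index == m]
    ra <- if (length(asvs) && sid %in% colnames(rel_ab$values))
      sum(rel_ab$values[asvs, sid]) else 0
    tot <- if (sid %in% colnames(tpm$values)) sum(tpm$values[, sid]) else 0
    tf <- if (length(lbvs) && tot > 0) sum(tpm$values[lbvs, sid]) / tot else 0
    data.frame(month_index = m, paired_asv_relab = ra, paired_lbv_tpm_fraction = tf)
  }))
  list(n_asv = length(asvs), n_lbv = length(lbvs), monthly = monthly)
}

#' Full infection-pair stage
#'
#' Convenience wrapper: selects dominant ASVs, restricts candidate contigs to
#' host-assigned ones, runs the correlation + FDR extraction on the surface
#' layer, annotates taxa and concordance, and attaches the Mann-Whitney
#' host-month validation per pair.
#'
#' @param rel_ab proportion `feature_table` (ASVs).
#' @param tpm gated TPM `feature_table` (LBVs).
#' @param meta metadata data.frame.
#' @param seasons output of [classify_seasons()].
#' @param assignments host assignments (see [assign_hosts()]).
#' @param taxonomy ASV taxonomy data.frame (feature_id, phylum).
#' @param cfg a [lake_config()].
#' @param year focal year (default 2019).
#' @return list: `asv_dominant`, `pairs` (with host_taxon, asv_taxon,
#'   taxon_concordant, mw_p), `tested`, `summary`.
#' @export
infection_pairs <- function(rel_ab, tpm, meta, seasons, assignments,
                            taxonomy = NULL, cfg = lake_config(),
                            year = 2019L) {
  asv_sel <- select_asv_dominant(rel_ab, seasons, meta,
                                 cfg$dominance_threshold, year)
  if (!length(asv_sel))
    return(list(asv_dominant = character(), pairs = NULL, tested = NULL,
                summary = NULL))
  candidates <- assignments$lbv_id[!is.na(assignments$taxon)]
  sub <- meta[meta$layer == "surface", ]
  sub <- sub[order(sub$month_index), ]
  s_asv <- sub[sub$sample_id %in% colnames(rel_ab$values), ]
  s_lbv <- sub[sub$sample_id %in% colnames(tpm$values), ]
  months <- intersect(s_asv$month_index, s_lbv$month_index)
  asv_mat <- rel_ab$values[asv_sel, s_asv$sample_id[match(months, s_asv$month_index)],
                           drop = FALSE]
  lbv_mat <- tpm$values[rownames(tpm$values) %in% candidates,
                        s_lbv$sample_id[match(months, s_lbv$month_index)],
                        drop = FALSE]
  colnames(asv_mat) <- colnames(lbv_mat) <- as.character(months)
  res <- pearson_fdr_pairs(asv_mat, lbv_mat, cfg$p_cut, cfg$q_cut)
  pr <- res$pairs
  if (nrow(pr)) {
    pr$host_taxon <- assignments$taxon[match(pr$lbv_id, assignments$lbv_id)]
    pr$asv_taxon <- if (!is.null(taxonomy))
      taxonomy$phylum[match(pr$asv_id, taxonomy$feature_id)] else NA_character_
    pr$taxon_concordant <- !is.na(pr$asv_taxon) & pr$host_taxon == pr$asv_taxon
    # host-dominant months within the focal year's middle-stratified window
    mid <- seasons$month_index[seasons$label == "middle" & seasons$year == year]
    yr_months <- intersect(months,
                           seasons$month_index[seasons$year == year])
    pr$mw_p <- NA_real_
    for (i in seq_len(nrow(pr))) {
      host_m <- intersect(mid, months)
      host_m <- host_m[asv_mat[pr$asv_id[i], as.character(host_m)] >
                         cfg$dominance_threshold]
      other_m <- setdiff(yr_months, host_m)
      if (length(host_m) && length(other_m))
        pr$mw_p[i] <- mw_validate(lbv_mat[pr$lbv_id[i], ], host_m, other_m)$p_value
    }
  }
  mid_2019 <- seasons$month_index[seasons$label == "middle" & seasons$year == year]
  list(asv_dominant = asv_sel, pairs = pr, tested = res$tested,
       summary = summarize_pairs(pr, rel_ab, tpm, meta, mid_2019))
}
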