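#' Shannon diversity (natural log)
#'
#' H' = -sum p_i ln p_i over the positive entries; count vectors are
#' normalised internally. Computed through vegan.
#'
#' @param x non-negative abundance vector (counts or proportions).
#' @return diversity in nats.
#' @export
shannon <- function(x) {
  if (any(x < 0) || anyNA(x)) stop_("abundances must be non-negative and non-missing")
  if (sum(x) == 0) stop_("Shannon index undefined for an all-zero vector")
  unname(vegan::diversity(x, index = "shannon"))
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' BC = sum |x_i - y_i| / sum (x_i + y_i); 0 for identical communities, 1
#' for disjoint ones. Computed through vegan.
#'
#' @param x,y non-negative abundance vectors on the same feature registry.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop_("vectors must share a feature registry")
  if (any(x < 0) || any(y < 0) || anyNA(x) || anyNA(y))
    stop_("abundances must be non-negative and non-missing")
  if (sum(x) == 0 && sum(y) == 0)
    stop_("Bray-Curtis undefined when both communities are empty")
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Monthly surface-vs-deep community dissimilarity
#'
#' One Bray-Curtis value per month in which both layers were sampled; months
#' missing a layer are skipped with a warning.
#'
#' @param table a `feature_table` (proportions for prokaryotes, gated TPM
#'   for viruses).
#' @param meta metadata data.frame.
#' @return data.frame: month_index, calendar_month, year, bc.
#' @export
layer_dissimilarity_series <- function(table, meta) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  meta <- meta[meta$sample_id %in% colnames(v), ]
  months <- sort(unique(meta$month_index))
  rows <- list()
  for (m in months) {
    sub <- meta[meta$month_index == m, ]
    s_id <- sub$sample_id[sub$layer == "surface"]
    d_id <- sub$sample_id[sub$layer == "deep"]
    if (length(s_id) != 1L || length(d_id) != 1L) {
      warn_("month_index %d lacks a layer; skipped in layer dissimilarity", m)
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(month_index = m, calendar_month = sub$calendar_month[1L],
                 year = sub$year[1L], bc = bray_curtis(v[, s_id], v[, d_id]))
  }
  if (!length(rows)) stop_("no month carries both layers")
  do.call(rbind, rows)
}

#' Community turnover against month separation (time-lag curve)
#'
#' Bray-Curtis dissimilarity for every pair of months within one layer,
#' grouped by the separation in months. The sd uses the n-1 denominator; a
#' lag represented by a single pair reports sd 0 with `sd_defined = FALSE`.
#'
#' @param table a `feature_table`.
#' @param meta metadata data.frame.
#' @param layer `"surface"` or `"deep"`.
#' @return data.frame: layer, lag_months, mean_bc, sd_bc, n_pairs, sd_defined.
#' @export
timelag_curve <- function(table, meta, layer = c("surface", "deep")) {
  layer <- match.arg(layer)
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  sub <- meta[meta$layer == layer & meta$sample_id %in% colnames(v), ]
  sub <- sub[order(sub$month_index), ]
  if (nrow(sub) < 2L) stop_("need at least two sampled months in layer '%s'", layer)
  n <- nrow(sub)
  lag <- numeric(0); bc <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    lag <- c(lag, sub$month_index[j] - sub$month_index[i])
    bc <- c(bc, bray_curtis(v[, sub$sample_id[i]], v[, sub$sample_id[j]]))
  }
  out <- do.call(rbind, lapply(sort(unique(lag)), function(k) {
    b <- bc[lag == k]
    data.frame(layer = layer, lag_months = k, mean_bc = mean(b),
               sd_bc = if (length(b) > 1L) stats::sd(b) else 0,
               n_pairs = length(b), sd_defined = length(b) > 1L)
  }))
  rownames(out) <- NULL
  out
}

#' Compare two groups of dissimilarities
#'
#' Thin delegation to [stats_dispatch()]: Student's t, Welch's t or
#' Mann-Whitney U depending on normality and equal-variance checks.
#'
#' @param bc_values_a,bc_values_b numeric vectors (each length >= 2; the
#'   dispatcher itself requires >= 3 for its normality check).
#' @return list with `test`, `statistic`, `p_value` (see [stats_dispatch()]).
#' @export
compare_lag_groups <- function(bc_values_a, bc_values_b) {
  if (length(bc_values_a) < 2L || length(bc_values_b) < 2L)
    stop_("both groups need at least two values")
  stats_dispatch(bc_values_a, bc_values_b)
}
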