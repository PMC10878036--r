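#' Relative abundance per sample
#'
#' Divides every sample column by its total; an all-zero column stays zero.
#'
#' @param counts a counts [feature_table()].
#' @return a proportion `feature_table`.
#' @export
relative_abundance <- function(counts) {
  stopifnot(inherits(counts, "feature_table"))
  if (counts$value_kind != "counts") stop_("input must be a counts table")
  v <- counts$values
  cs <- colSums(v)
  div <- ifelse(cs == 0, 1, cs)
  feature_table(sweep(v, 2L, div, "/"), "proportion")
}

#' Transcripts per kilobase per million (TPM)
#'
#' Per sample, each contig's reads are first divided by its length in
#' kilobases, then the rates are scaled to sum to 1e6. Columns with no reads
#' remain zero.
#'
#' @param read_counts a counts `feature_table` of mapped reads per contig.
#' @param lengths_bp named integer vector of contig lengths (bp); defaults to
#'   the table's attached lengths. Every feature with a nonzero count must
#'   have a length.
#' @return a `feature_table` of kind `"tpm"`.
#' @export
compute_tpm <- function(read_counts, lengths_bp = read_counts$lengths_bp) {
  stopifnot(inherits(read_counts, "feature_table"))
  if (read_counts$value_kind != "counts") stop_("input must be a counts table")
  if (is.null(lengths_bp)) stop_("contig lengths are required to compute TPM")
  v <- read_counts$values
  len <- lengths_bp[rownames(v)]
  no_len <- is.na(len) & rowSums(v) > 0
  if (any(no_len))
    stop_("missing length for feature(s) with nonzero counts: %s",
          paste(rownames(v)[no_len], collapse = ", "))
  if (any(len < 1, na.rm = TRUE)) stop_("lengths_bp must be >= 1")
  len[is.na(len)] <- 1          # all-zero rows; value irrelevant
  rate <- v / (len / 1000)
  tot <- colSums(rate)
  tot[tot == 0] <- 1
  feature_table(sweep(rate, 2L, tot, "/") * 1e6, "tpm",
                lengths_bp = lengths_bp)
}

#' Zero TPM cells with insufficient genome coverage
#'
#' A contig's abundance in a sample is suppressed (set to zero) when mapped
#' reads cover less than `gate` of its length (strict `<`; a coverage equal
#' to the gate passes). Columns are deliberately not renormalised, so gated
#' column sums may fall below 1e6.
#'
#' @param tpm a TPM `feature_table`.
#' @param coverage numeric matrix in [0,1], same dimnames as `tpm`.
#' @param gate covered-fraction threshold (default 0.8).
#' @return the gated TPM `feature_table` (marked `gated`).
#' @export
gate_tpm <- function(tpm, coverage, gate = 0.8) {
  stopifnot(inherits(tpm, "feature_table"))
  if (tpm$value_kind != "tpm") stop_("input must be a TPM table")
  assert_scalar_num(gate, "gate", lower = 1e-12, upper = 1)
  v <- tpm$values
  if (!identical(dim(v), dim(coverage)) ||
      !identical(dimnames(v), dimnames(coverage)))
    stop_("TPM and coverage tables must have identical feature/sample registries")
  if (any(coverage < 0 | coverage > 1)) stop_("coverage fractions outside [0, 1]")
  v[coverage < gate] <- 0
  feature_table(v, "tpm", lengths_bp = tpm$lengths_bp, gated = TRUE)
}

#' Rarefy a count table to equal depth
#'
#' Subsamples every sample column without replacement to a common target
#' (default: the smallest column sum), the standard way to remove library-
#' size differences before diversity comparisons. Each sample uses its own
#' RNG stream derived from `(seed, sample_id)`, so adding or removing a
#' sample never perturbs the draws of the others.
#'
#' @param counts a counts `feature_table` (integer values).
#' @param seed integer master seed.
#' @param target depth to subsample to; must not exceed any column sum.
#' @return a counts `feature_table` whose columns all sum to `target`.
#' @export
rarefy <- function(counts, seed, target = NULL) {
  stopifnot(inherits(counts, "feature_table"))
  if (counts$value_kind != "counts") stop_("input must be a counts table")
  v <- counts$values
  if (any(v != floor(v))) stop_("counts must be integers")
  cs <- colSums(v)
  if (is.null(target)) target <- min(cs)
  target <- as.integer(target)
  short <- cs < target
  if (any(short))
    stop_("rarefaction target %d exceeds the total of sample(s): %s",
          target, paste(colnames(v)[short], collapse = ", "))
  out <- v
  for (j in seq_len(ncol(v))) {
    sid <- colnames(v)[j]
    out[, j] <- with_seed(derive_seed(seed, sid), {
      pool <- rep.int(seq_len(nrow(v)), v[, j])
      keep <- pool[sample.int(length(pool), target)]
      tabulate(keep, nbins = nrow(v))
    })
  }
  feature_table(out, "counts", lengths_bp = counts$lengths_bp)
}
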