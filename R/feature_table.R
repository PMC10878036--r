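#' Feature-by-sample abundance table
#'
#' Light container for a features x samples matrix of counts, proportions or
#' TPM (transcripts per kilobase per million). Row names are feature ids
#' (ASVs or viral contigs), column names are sample ids. Proportion columns
#' must sum to 1 and TPM columns to 1e6, except that an all-zero column is
#' allowed (a library in which nothing was detected) and a TPM column that
#' has been through the coverage gate may sum to less than 1e6 (see
#' [gate_tpm()]; such tables carry `gated = TRUE`).
#'
#' @param values numeric matrix, features x samples, with dimnames.
#' @param value_kind one of `"counts"`, `"proportion"`, `"tpm"`.
#' @param lengths_bp optional named integer vector of contig lengths (bp),
#'   required to compute TPM from counts.
#' @param gated logical; `TRUE` marks a TPM table whose cells have been
#'   zeroed by the coverage gate, relaxing the column-sum invariant.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values,
                          value_kind = c("counts", "proportion", "tpm"),
                          lengths_bp = NULL, gated = FALSE) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop_("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_("'values' must have feature ids as rownames and sample ids as colnames")
  x <- structure(
    list(values = values, value_kind = value_kind,
         lengths_bp = lengths_bp, gated = isTRUE(gated)),
    class = "feature_table")
  validate_feature_table(x)
  x
}

validate_feature_table <- function(x) {
  v <- x$values
  if (anyNA(v))
    stop_("abundance matrix contains NA/NaN; missing samples must be absent columns")
  if (any(v < 0))
    stop_("abundance matrix contains negative values")
  if (anyDuplicated(rownames(v)))
    stop_("duplicate feature ids: %s",
          paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (anyDuplicated(colnames(v)))
    stop_("duplicate sample ids: %s",
          paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
  cs <- colSums(v)
  if (x$value_kind == "proportion") {
    bad <- cs != 0 & abs(cs - 1) > 1e-9
    if (any(bad))
      stop_("proportion columns do not sum to 1: %s",
            paste(colnames(v)[bad], collapse = ", "))
  }
  if (x$value_kind == "tpm" && !x$gated) {
    bad <- cs != 0 & abs(cs - 1e6) > 1e-3
    if (any(bad))
      stop_("TPM columns do not sum to 1e6: %s",
            paste(colnames(v)[bad], collapse = ", "))
  }
  if (!is.null(x$lengths_bp)) {
    if (is.null(names(x$lengths_bp)))
      stop_("'lengths_bp' must be named by feature id")
    if (any(x$lengths_bp < 1))
      stop_("'lengths_bp' must be >= 1")
  }
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table [%s%s]: %d features x %d samples\n",
              x$value_kind, if (x$gated) ", coverage-gated" else "",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Read a feature table from TSV
#'
#' First column holds feature ids, header row holds sample ids, body is
#' numeric. Malformed numeric cells and duplicate feature ids are rejected.
#'
#' @param path TSV file path.
#' @param value_kind value kind of the stored matrix.
#' @param lengths_bp optional named lengths vector attached to the result.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, value_kind = c("counts", "proportion", "tpm"),
                               lengths_bp = NULL) {
  value_kind <- match.arg(value_kind)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2L) stop_("'%s': need a feature-id column plus >=1 sample", path)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop_("'%s': duplicate feature ids: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop_("'%s': malformed numeric cell at row '%s', column '%s' (value '%s')",
          path, ids[bad[1L]], colnames(raw)[-1L][bad[2L]], body[bad[1L], bad[2L]])
  }
  dimnames(num) <- list(ids, colnames(raw)[-1L])
  gated <- value_kind == "tpm" &&
    any(colSums(num) != 0 & abs(colSums(num) - 1e6) > 1e-3)
  feature_table(num, value_kind, lengths_bp = lengths_bp, gated = gated)
}

#' Write a feature table to TSV
#'
#' Full-precision tab-separated output; [read_feature_table()] of the result
#' reproduces the table (bit-exact for counts, <=1e-12 relative for floats).
#'
#' @param x a [feature_table()].
#' @param path output path.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  df <- data.frame(feature_id = rownames(x$values),
                   format(x$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(x$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Requires columns `sample_id`, `month_index`, `layer`, `temperature_C`;
#' optional `calendar_month`, `year`, `depth_m`, `do_mgL` are derived or
#' defaulted when absent. Months are indexed from 0 at the first study month
#' (September of the start year). The (month_index, layer) pair must be
#' unique.
#'
#' @param path TSV path.
#' @param start_year calendar year of month_index 0 (a September).
#' @return data.frame sorted by (month_index, layer).
#' @export
read_metadata <- function(path, start_year = 2018L) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE, quote = "")
  if (nrow(df) == 0L) {
    warn_("'%s': empty metadata file", path)
    return(empty_metadata())
  }
  need <- c("sample_id", "month_index", "layer", "temperature_C")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_("'%s': missing required columns: %s", path,
                          paste(miss, collapse = ", "))
  validate_metadata(as_metadata(df, start_year))
}

empty_metadata <- function() {
  data.frame(sample_id = character(), month_index = integer(),
             calendar_month = integer(), year = integer(),
             layer = character(), depth_m = numeric(),
             temperature_C = numeric(), do_mgL = numeric())
}

as_metadata <- function(df, start_year = 2018L) {
  df$month_index <- as.integer(df$month_index)
  if (is.null(df$calendar_month))
    df$calendar_month <- month_calendar(df$month_index)
  if (is.null(df$year))
    df$year <- month_year(df$month_index, start_year)
  if (is.null(df$depth_m))
    df$depth_m <- ifelse(df$layer == "surface", 0.5, 60)
  if (is.null(df$do_mgL)) df$do_mgL <- NA_real_
  df <- df[order(df$month_index, df$layer),
           c("sample_id", "month_index", "calendar_month", "year", "layer",
             "depth_m", "temperature_C", "do_mgL")]
  rownames(df) <- NULL
  df
}

validate_metadata <- function(df) {
  bad_layer <- setdiff(unique(df$layer), c("surface", "deep"))
  if (length(bad_layer))
    stop_("unknown layer token(s): %s", paste(bad_layer, collapse = ", "))
  key <- paste(df$month_index, df$layer)
  if (anyDuplicated(key))
    stop_("duplicate (month_index, layer): %s",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  if (any(df$depth_m <= 0)) stop_("depth_m must be > 0")
  if (any(df$temperature_C <= -5 | df$temperature_C >= 45))
    stop_("temperature_C outside (-5, 45)")
  if (anyDuplicated(df$sample_id)) stop_("duplicate sample ids in metadata")
  df
}

#' @rdname read_metadata
#' @param df metadata data.frame.
#' @export
write_metadata <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Calendar month (1-12) and year of a 0-based study month starting in
# September of `start_year`.
month_calendar <- function(month_index) ((9L - 1L + month_index) %% 12L) + 1L
month_year <- function(month_index, start_year = 2018L)
  start_year + (month_index + 8L) %/% 12L

#' Read host-prediction evidence
#'
#' One row per evidence line: `lbv_id`, `method` (one of `i`, `ii`, `iii`,
#' `iv`, `v`, `vi`), `taxon`, and the score fields the method requires
#' (`sg_score`, `identity_pct`, `aln_len_bp`, `evalue`, `gene_fraction`,
#' `marker`), empty where not applicable.
#'
#' @param path TSV path.
#' @return data.frame of typed evidence records.
#' @export
read_evidence <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE, quote = "",
                          na.strings = c("NA", ""))
  if (nrow(df) == 0L) return(empty_evidence())
  need <- c("lbv_id", "method", "taxon")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_("'%s': missing required columns: %s", path,
                          paste(miss, collapse = ", "))
  for (col in c("sg_score", "identity_pct", "evalue", "gene_fraction"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_ else df[[col]] <- as.numeric(df[[col]])
  if (is.null(df$aln_len_bp)) df$aln_len_bp <- NA_integer_
  else df$aln_len_bp <- as.integer(df$aln_len_bp)
  if (is.null(df$marker)) df$marker <- NA_character_
  validate_evidence_schema(df)
  df[, names(empty_evidence())]
}

empty_evidence <- function() {
  data.frame(lbv_id = character(), method = character(), taxon = character(),
             sg_score = numeric(), identity_pct = numeric(),
             aln_len_bp = integer(), evalue = numeric(),
             gene_fraction = numeric(), marker = character())
}

validate_evidence_schema <- function(df) {
  bad <- setdiff(unique(df$method), c("i", "ii", "iii", "iv", "v", "vi"))
  if (length(bad))
    stop_("unknown host-prediction method token(s): %s",
          paste(bad, collapse = ", "))
  invisible(df)
}

#' @rdname read_evidence
#' @param df evidence data.frame.
#' @export
write_evidence <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-feature contig lengths (feature_id, length_bp)
#' @param path TSV path.
#' @return named integer vector.
#' @export
read_lengths <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE, quote = "")
  if (!all(c("feature_id", "length_bp") %in% names(df)))
    stop_("'%s': need columns feature_id, length_bp", path)
  stats::setNames(as.integer(df$length_bp), df$feature_id)
}

#' Read a coverage-fraction matrix (same layout as a feature table)
#'
#' Values are the fraction of each contig's length covered by mapped reads
#' in each sample, in [0, 1].
#'
#' @param path TSV path.
#' @return numeric matrix with feature/sample dimnames.
#' @export
read_coverage <- function(path) {
  ft <- read_feature_table(path, "counts")  # reuse parser; validate range here
  v <- ft$values
  if (any(v < 0 | v > 1)) stop_("'%s': coverage fractions outside [0, 1]", path)
  v
}

#' Read a feature taxonomy map (feature_id, phylum[, class])
#' @param path TSV path.
#' @return data.frame with feature_id, phylum, class.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE, quote = "",
                          na.strings = c("NA", ""))
  if (!all(c("feature_id", "phylum") %in% names(df)))
    stop_("'%s': need columns feature_id, phylum", path)
  if (is.null(df$class)) df$class <- NA_character_
  df[, c("feature_id", "phylum", "class")]
}
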