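# Host-prediction evidence validation and prioritized resolution.
#
# Methods, in decreasing priority:
#   i   whole-genome similarity to a reference virus with a known host
#       (shared-gene score S_G > 0.15)
#   ii  host-specific marker gene carried by the phage genome
#       (whiB -> Actinobacteria, photosystem gene -> Cyanobacteria)
#   iii CRISPR spacer match (BLASTn, 100% identity)
#   iv  tRNA match (>97% identity, alignment >= 30 bp, e-value < 1e-5)
#   v   direct genome match (same thresholds as iv)
#   vi  >80% of annotated bacterial genes assigned to a single taxon

method_levels <- c("i", "ii", "iii", "iv", "v", "vi")
marker_taxa <- c(whiB = "Actinobacteria", photosystem = "Cyanobacteria")

#' Validate host-prediction evidence against its method's thresholds
#'
#' Returns, per record, whether the evidence clears the acceptance threshold
#' of its method (see the method table in the package vignette). All
#' threshold comparisons are strict where the rule says "more than".
#'
#' @param evidence evidence data.frame (see [read_evidence()]).
#' @return logical vector, one element per record.
#' @export
validate_evidence <- function(evidence) {
  validate_evidence_schema(evidence)
  n <- nrow(evidence)
  ok <- logical(n)
  need <- function(i, field) {
    val <- evidence[[field]][i]
    if (is.na(val))
      stop_("evidence row %d (lbv '%s', method %s): required field '%s' missing",
            i, evidence$lbv_id[i], evidence$method[i], field)
    val
  }
  for (i in seq_len(n)) {
    ok[i] <- switch(
      evidence$method[i],
      i = need(i, "sg_score") > 0.15,
      ii = {
        mk <- need(i, "marker")
        mk %in% names(marker_taxa) && evidence$taxon[i] == marker_taxa[[mk]]
      },
      iii = need(i, "identity_pct") == 100,
      iv = ,
      v = need(i, "identity_pct") > 97 &&
        need(i, "aln_len_bp") >= 30 &&
        need(i, "evalue") < 1e-5,
      vi = need(i, "gene_fraction") > 0.80)
  }
  ok
}

# Score used to break within-method taxon ties: larger is better.
evidence_score <- function(evidence) {
  s <- rep(0, nrow(evidence))
  m <- evidence$method
  s[m == "i"] <- evidence$sg_score[m == "i"]
  s[m == "iii"] <- evidence$identity_pct[m == "iii"]
  s[m %in% c("iv", "v")] <- evidence$identity_pct[m %in% c("iv", "v")] -
    log10(pmax(evidence$evalue[m %in% c("iv", "v")], 1e-300)) * 1e-6
  s[m == "vi"] <- evidence$gene_fraction[m == "vi"]
  s
}

#' Resolve one contig's host from its evidence lines
#'
#' Invalid records are discarded; among the valid ones the highest-priority
#' method (i over ii ... over vi) wins. If several valid records of the
#' winning method name different taxa, the majority taxon is taken; a tie is
#' broken by the best method score; a remaining tie leaves the contig
#' unassigned with `ambiguous = TRUE`.
#'
#' @param evidence evidence data.frame for a single contig.
#' @return one-row data.frame: lbv_id, taxon (NA if unassigned),
#'   winning_method (NA if none), n_supporting, ambiguous.
#' @export
assign_host <- function(evidence) {
  if (nrow(evidence) == 0L)
    return(data.frame(lbv_id = NA_character_, taxon = NA_character_,
                      winning_method = NA_character_, n_supporting = 0L,
                      ambiguous = FALSE))
  if (length(unique(evidence$lbv_id)) != 1L)
    stop_("assign_host expects evidence for a single contig")
  lbv <- evidence$lbv_id[1L]
  valid <- evidence[validate_evidence(evidence), , drop = FALSE]
  if (nrow(valid) == 0L)
    return(data.frame(lbv_id = lbv, taxon = NA_character_,
                      winning_method = NA_character_, n_supporting = 0L,
                      ambiguous = FALSE))
  win <- method_levels[min(match(valid$method, method_levels))]
  w <- valid[valid$method == win, , drop = FALSE]
  votes <- table(w$taxon)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    sc <- vapply(top, function(tx)
      max(evidence_score(w[w$taxon == tx, , drop = FALSE])), 0)
    top <- top[sc == max(sc)]
  }
  if (length(top) > 1L)
    return(data.frame(lbv_id = lbv, taxon = NA_character_,
                      winning_method = win, n_supporting = 0L,
                      ambiguous = TRUE))
  data.frame(lbv_id = lbv, taxon = top,
             winning_method = win,
             n_supporting = as.integer(sum(w$taxon == top)),
             ambiguous = FALSE)
}

#' Resolve hosts for every contig in an evidence table
#' @param evidence evidence data.frame covering any number of contigs.
#' @return data.frame with one row per contig that has evidence; contigs
#'   whose evidence all fails validation appear with taxon NA.
#' @export
assign_hosts <- function(evidence) {
  if (nrow(evidence) == 0L)
    return(data.frame(lbv_id = character(), taxon = character(),
                      winning_method = character(), n_supporting = integer(),
                      ambiguous = logical()))
  out <- do.call(rbind, lapply(split(evidence, evidence$lbv_id), assign_host))
  rownames(out) <- NULL
  out[order(out$lbv_id), ]
}

#' Summarise host assignments
#'
#' Counts assigned contigs per predicted taxon and, per sample, the fraction
#' of total (gated) TPM carried by host-assigned contigs.
#'
#' @param assignments output of [assign_hosts()].
#' @param tpm gated TPM `feature_table`.
#' @return list with `taxon_counts` (named integer) and `assigned_tpm_fraction`
#'   (named numeric per sample; 0 where the sample has no TPM at all).
#' @export
host_summary <- function(assignments, tpm) {
  stopifnot(inherits(tpm, "feature_table"))
  assigned <- assignments$lbv_id[!is.na(assignments$taxon)]
  counts <- table(assignments$taxon[!is.na(assignments$taxon)])
  v <- tpm$values
  tot <- colSums(v)
  part <- colSums(v[rownames(v) %in% assigned, , drop = FALSE])
  frac <- ifelse(tot > 0, part / tot, 0)
  list(taxon_counts = stats::setNames(as.integer(counts), names(counts)),
       assigned_tpm_fraction = frac)
}
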