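## Homology reduction and train/holdout splitting. Evaluation of sequence
## classifiers is inflated by near-duplicate sequences, so benchmark sets are
## reduced to below a pairwise identity cutoff (30% by default), within each
## class and across classes, before carving the independent holdout.

#' Percent identity between two sequences
#'
#' Global (Needleman–Wunsch) alignment with BLOSUM62 scoring and affine gaps
#' (open 10, extend 0.5) chooses the alignment path; identity is then the
#' number of identical aligned positions divided by the number of alignment
#' columns (including gap columns), times 100. Symmetric in its arguments.
#'
#' @param a,b canonical sequence strings or single-row `protein_records`.
#' @param denominator `"alignment"` (default: alignment columns) or
#'   `"shorter"` (length of the shorter sequence).
#' @return identity percent in \[0, 100\].
#' @export
pairwise_identity <- function(a, b, denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  sa <- if (is.character(a)) a else a$sequence
  sb <- if (is.character(b)) b else b$sequence
  if (!nzchar(sa) || !nzchar(sb)) stop_data("sequences must be non-empty")
  ## co-optimal alignments can place gaps differently depending on argument
  ## order; canonicalize so identity is exactly symmetric
  if (sa > sb) { tmp <- sa; sa <- sb; sb <- tmp }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  type <- if (denominator == "alignment") "PID1" else "PID3"
  Biostrings::pid(al, type = type)
}

#' Greedy homology reduction to representatives
#'
#' Sorts records longest-first (ties by id) and assigns each record to the
#' first existing cluster whose representative it matches at or above the
#' identity cutoff; otherwise it founds a new cluster. Representatives are
#' the cluster founders, so no two representatives share >= cutoff identity.
#' This is a greedy single-linkage-to-representative approximation of
#' k-mer-based clustering tools; cluster counts will differ from theirs.
#'
#' @param records a `protein_records` table.
#' @param cutoff identity cutoff percent in (0, 100\] (default 30: sequences
#'   at or above 30% identity to a representative are absorbed).
#' @return list with `representatives` (a `protein_records` table) and
#'   `clusters` (data frame: `id`, `cluster`, `is_representative`).
#' @export
greedy_reduce <- function(records, cutoff = 30) {
  if (cutoff <= 0 || cutoff > 100) stop_usage("cutoff must be in (0, 100]")
  ord <- order(-records$length, records$id)
  r <- records[ord, , drop = FALSE]
  rep_idx <- integer(0)
  cluster <- integer(nrow(r))
  for (i in seq_len(nrow(r))) {
    assigned <- FALSE
    for (ci in seq_along(rep_idx)) {
      if (pairwise_identity(r$sequence[i], r$sequence[rep_idx[ci]]) >= cutoff) {
        cluster[i] <- ci; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      rep_idx <- c(rep_idx, i)
      cluster[i] <- length(rep_idx)
    }
  }
  reps <- r[rep_idx, , drop = FALSE]
  class(reps) <- c("protein_records", "data.frame")
  list(representatives = reps,
       clusters = data.frame(id = r$id, cluster = cluster,
                             is_representative = seq_len(nrow(r)) %in% rep_idx,
                             stringsAsFactors = FALSE))
}

#' Cross-class homology reduction
#'
#' Removes from `set_b` every record matching any `set_a` record at or above
#' the cutoff. The first set is the anchor and is kept intact — a
#' deterministic convention; which side loses sequences is otherwise
#' arbitrary. Both sets should already be within-class reduced.
#'
#' @param set_a,set_b `protein_records` tables.
#' @param cutoff identity cutoff percent (default 30).
#' @return list with `set_a` (unchanged), `set_b` (filtered) and
#'   `removed_ids`.
#' @export
cross_class_reduce <- function(set_a, set_b, cutoff = 30) {
  drop <- logical(nrow(set_b))
  for (j in seq_len(nrow(set_b))) {
    for (i in seq_len(nrow(set_a))) {
      if (pairwise_identity(set_b$sequence[j], set_a$sequence[i]) >= cutoff) {
        drop[j] <- TRUE; break
      }
    }
  }
  b <- set_b[!drop, , drop = FALSE]
  class(b) <- c("protein_records", "data.frame")
  list(set_a = set_a, set_b = b, removed_ids = set_b$id[drop])
}

#' Audit a record set for residual homology
#'
#' Exhaustive pairwise identity check; returns every pair at or above the
#' cutoff (empty if the reduction succeeded).
#'
#' @param records a `protein_records` table (or rbind of several).
#' @param cutoff identity cutoff percent.
#' @return data frame `id_a`, `id_b`, `identity` of offending pairs.
#' @export
audit_identity <- function(records, cutoff = 30) {
  n <- nrow(records)
  out <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      pid <- pairwise_identity(records$sequence[i], records$sequence[j])
      if (pid >= cutoff)
        out[[length(out) + 1L]] <- data.frame(
          id_a = records$id[i], id_b = records$id[j], identity = pid,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(id_a = character(0), id_b = character(0),
                  identity = numeric(0), stringsAsFactors = FALSE)
}

#' Carve an independent holdout split
#'
#' Uniform random sampling without replacement; the holdout size is
#' `round(n * fraction)`. With 3160 records at the default 10% this gives a
#' 316-sequence independent set and 2844 training sequences.
#'
#' @param records a `protein_records` table (or any object with rows).
#' @param fraction holdout fraction in (0, 1), default 0.10.
#' @param seed integer seed.
#' @return list with `train_ids`, `holdout_ids`, `seed`.
#' @export
split_independent <- function(records, fraction = 0.10, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop_usage("fraction must be in (0, 1)")
  ids <- records$id
  n <- length(ids)
  n_hold <- round(n * fraction)
  if (n_hold < 1L || n_hold >= n)
    stop_data(sprintf("holdout of %d from %d records is degenerate", n_hold, n))
  set.seed(seed)
  hold <- sample(ids, n_hold)
  list(train_ids = setdiff(ids, hold), holdout_ids = hold, seed = seed)
}
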