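# Per-bin assemblage tables, Jaccard similarity and cross-bin
# normalisation to the most type-diverse bin.

#' Build the type-frequency table of one time bin
#'
#' Collects the kept records of all contexts assigned to `bin` into a
#' contexts-by-types contingency table and its binary presence/absence
#' counterpart. Contexts from the same site but different levels stay
#' separate rows; contexts with zero kept records in the bin are dropped.
#'
#' @param records Kept artefact records (after [filter_shared_types()])
#'   with `context` and `type_code` columns.
#' @param membership Bin-membership table from [assign_time_bins()]
#'   (columns `context`, `bins` with `";"`-joined labels).
#' @param bin A bin label.
#' @param per_bin_filter If `TRUE`, additionally drop types whose total
#'   frequency within this bin is 1 (a second, within-bin application of
#'   the shared-type rule; off by default).
#' @return Object of class `bin_assemblage`: list with `bin`, `contexts`,
#'   `freq` (count matrix), `binary` (0/1 matrix), `n_types`, `n_sample`.
#' @export
build_bin_assemblage <- function(records, membership, bin,
                                 per_bin_filter = FALSE) {
  in_bin <- vapply(strsplit(membership$bins, ";", fixed = TRUE),
                   function(b) bin %in% b, logical(1L))
  ctx <- membership$context[in_bin]
  rec <- records[records$context %in% ctx, , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop(sprintf("bin %s has no records", bin), call. = FALSE)
  }
  freq <- unclass(table(factor(rec$context, levels = sort(unique(rec$context))),
                        rec$type_code))
  freq <- matrix(as.integer(freq), nrow = nrow(freq),
                 dimnames = dimnames(freq))
  if (per_bin_filter) {
    freq <- freq[, colSums(freq) > 1L, drop = FALSE]
  }
  freq <- freq[rowSums(freq) > 0L, colSums(freq) > 0L, drop = FALSE]
  if (nrow(freq) < 2L) {
    warning(sprintf("bin %s has fewer than 2 contexts; network degenerate",
                    bin), call. = FALSE)
  }
  binary <- (freq >= 1L) * 1L
  structure(list(bin = bin, contexts = rownames(freq), freq = freq,
                 binary = binary, n_types = ncol(freq),
                 n_sample = sum(freq)),
            class = "bin_assemblage")
}

#' @export
print.bin_assemblage <- function(x, ...) {
  cat(sprintf("Bin %s: %d contexts, %d types, %d artefacts\n",
              x$bin, length(x$contexts), x$n_types, x$n_sample))
  invisible(x)
}

#' Jaccard similarity between context type sets
#'
#' `J[a,b] = |types(a) intersect types(b)| / |types(a) union types(b)|`
#' on the presence/absence rows; pairs with an empty union are 0 by
#' convention and the diagonal is 1. The coefficient depends only on
#' presence, so scaling any frequency cell by a positive integer leaves
#' it unchanged.
#'
#' @param binary Contexts-by-types 0/1 matrix (at least 2 rows).
#' @return Symmetric similarity matrix with values in `[0, 1]`.
#' @export
jaccard_matrix <- function(binary) {
  binary <- (as.matrix(binary) > 0) * 1L
  if (nrow(binary) < 2L) {
    stop("Jaccard similarity needs at least 2 contexts", call. = FALSE)
  }
  inter <- tcrossprod(binary)
  sizes <- rowSums(binary)
  union <- outer(sizes, sizes, "+") - inter
  J <- ifelse(union > 0, inter / union, 0)
  diag(J) <- 1
  dimnames(J) <- list(rownames(binary), rownames(binary))
  J
}

#' Normalise similarity matrices across bins by type diversity
#'
#' When the number of types in the record differs strongly across
#' temporal windows, type-poor bins reach high raw similarity more
#' easily. Each bin's matrix is therefore rescaled linearly by its
#' relative diversity: `scale_factor(bin) = n_types(bin) / max(n_types)`,
#' so the most diverse bin is left unchanged and every other bin is
#' shrunk proportionally. The scaling is strictly monotone, preserving
#' the within-bin ordering of pairs.
#'
#' @param J_list Named list of raw Jaccard matrices, one per bin.
#' @param n_types Numeric vector of per-bin type counts, same order.
#' @return List with `J_norm` (list of scaled matrices) and
#'   `scale_factor` (named numeric vector in `(0, 1]`).
#' @export
normalise_similarity <- function(J_list, n_types) {
  stopifnot(length(J_list) == length(n_types), all(n_types >= 1))
  f <- n_types / max(n_types)
  names(f) <- names(J_list)
  J_norm <- Map(function(J, s) J * s, J_list, f)
  list(J_norm = J_norm, scale_factor = f)
}

#' Long-format similarity table
#'
#' Flattens per-bin similarity matrices into a long data frame
#' `bin,context_a,context_b,jaccard,jaccard_norm` (unordered pairs,
#' upper triangle).
#'
#' @param J_list Named list of raw Jaccard matrices.
#' @param J_norm_list Matching list of normalised matrices.
#' @return Long-format data frame.
#' @export
similarity_long <- function(J_list, J_norm_list) {
  rows <- lapply(names(J_list), function(b) {
    J <- J_list[[b]]; Jn <- J_norm_list[[b]]
    idx <- which(upper.tri(J), arr.ind = TRUE)
    data.frame(bin = b,
               context_a = rownames(J)[idx[, 1L]],
               context_b = colnames(J)[idx[, 2L]],
               jaccard = J[idx],
               jaccard_norm = Jn[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
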