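#' Per-sample pathway activity scores
#'
#' Within each sample of a gene-wise z-transformed matrix, genes are ranked
#' by their z-value (descending; ties broken by gene symbol) and the
#' running-sum enrichment score of every set is computed with
#' `|z|^weight_exponent` hit weights. The score measures the relative
#' activity of the set in that sample compared with all other samples: the
#' samples in which the set's genes sit highest receive scores near +1,
#' those where they sit lowest near -1.
#'
#' @param zvalues gene-wise z-transformed numeric matrix (each row mean 0,
#'   sample sd 1; validated to 1e-6)
#' @param collection a [gene_set_collection()] restricted to the matrix
#'   universe
#' @param weight_exponent ES weighting exponent (default 1.0)
#' @return numeric matrix, sets x samples, values in [-1, 1], with
#'   attribute `weight_exponent`.
#' @export
sample_activity <- function(zvalues, collection, weight_exponent = 1.0) {
  stopifnot(is.matrix(zvalues))
  mu <- rowMeans(zvalues)
  sdv <- apply(zvalues, 1L, stats::sd)
  if (any(abs(mu) > 1e-6) || any(abs(sdv - 1) > 1e-6))
    stop("input is not gene-wise z-transformed (row means must be 0, sds 1); ",
         "apply z_transform() first")
  gene_names <- rownames(zvalues)
  set_idx <- lapply(collection$sets, function(g) match(g, gene_names))
  if (any(vapply(set_idx, anyNA, logical(1L))))
    stop("collection contains genes absent from the matrix; ",
         "apply restrict_and_filter() first")
  N <- nrow(zvalues)
  act <- matrix(NA_real_, nrow = length(set_idx), ncol = ncol(zvalues),
                dimnames = list(names(collection$sets), colnames(zvalues)))
  for (j in seq_len(ncol(zvalues))) {
    rp <- .rank_positions(zvalues[, j], gene_names)
    for (s in seq_along(set_idx)) {
      pos <- sort(rp$pos_of[set_idx[[s]]])
      act[s, j] <- .es_fast(N, pos, abs(rp$metric_sorted[pos])^weight_exponent)
    }
  }
  attr(act, "weight_exponent") <- weight_exponent
  act
}

#' Summarize pathway activity by group and region
#'
#' @param activity a [sample_activity()] matrix (sets x samples)
#' @param annotations annotation data frame (`sample_id`, `group`, `region`)
#' @return data frame with one row per set x region x group cell present in
#'   the data: columns `set`, `region`, `group`, `mean`, `sd` (`NA` for
#'   single-sample cells), `n`.
#' @export
group_activity_summary <- function(activity, annotations) {
  ann <- annotations[match(colnames(activity), annotations$sample_id), ]
  if (anyNA(ann$sample_id))
    stop("activity matrix contains unannotated sample(s)")
  cells <- unique(ann[, c("region", "group")])
  cells <- cells[order(cells$region, cells$group), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    idx <- ann$region == cells$region[i] & ann$group == cells$group[i]
    vals <- activity[, idx, drop = FALSE]
    data.frame(set = rownames(activity),
               region = cells$region[i], group = cells$group[i],
               mean = rowMeans(vals),
               sd = if (sum(idx) > 1L) apply(vals, 1L, stats::sd) else NA_real_,
               n = sum(idx), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
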