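#' Cross-region consensus and region-specific pathway calls
#'
#' A contrast run in several regions yields one `gsea` object per region.
#' A pathway is called *common* when it reaches FDR q below the threshold
#' in at least `min_regions` regions (and, by default, with a concordant
#' NES sign in the qualifying regions); it is called *specific* to one
#' region when significant there and clearly null (q above `fdr_out`) in
#' both other regions. Inequalities are strict on both sides, so q exactly
#' at a threshold never qualifies.
#'
#' @name consensus
NULL

.check_region_results <- function(region_results, regions) {
  miss <- setdiff(regions, names(region_results))
  if (length(miss) > 0L)
    stop("missing region result(s): ", paste(miss, collapse = ", "))
  for (r in regions)
    if (!inherits(region_results[[r]], "gsea"))
      stop("region_results[['", r, "']] is not a `gsea` object")
  sets <- sort(region_results[[regions[1L]]]$results$set)
  for (r in regions[-1L])
    if (!identical(sort(region_results[[r]]$results$set), sets))
      stop("regions were not run on the same gene set collection")
  sets
}

.region_table <- function(region_results, regions) {
  sets <- .check_region_results(region_results, regions)
  out <- data.frame(set = sets, stringsAsFactors = FALSE)
  for (r in regions) {
    res <- region_results[[r]]$results
    i <- match(sets, res$set)
    out[[paste0("NES_", r)]] <- res$nes[i]
    out[[paste0("q_", r)]] <- res$fdr_q[i]
  }
  out
}

#' Pathways commonly dysregulated across regions
#'
#' @param region_results named list of `gsea` objects, one per region
#' @param fdr_threshold significance threshold on FDR q (strict `<`,
#'   default 0.01)
#' @param min_regions minimum number of qualifying regions (default 2)
#' @param require_concordance when `TRUE` (default) the qualifying regions'
#'   NES must share one sign; the call's `direction` is that sign
#' @param regions region labels expected in `region_results`
#' @return data frame of consensus calls: `set`, `category` ("common"),
#'   `direction` (+1/-1), and per-region `NES_*` and `q_*` columns.
#' @export
common_pathways <- function(region_results, fdr_threshold = 0.01,
                            min_regions = 2L, require_concordance = TRUE,
                            regions = c("WM", "FC", "BG")) {
  tab <- .region_table(region_results, regions)
  qcols <- paste0("q_", regions)
  ncols <- paste0("NES_", regions)
  keep <- logical(nrow(tab))
  direction <- integer(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    qv <- unlist(tab[i, qcols])
    nv <- unlist(tab[i, ncols])
    sig <- qv < fdr_threshold
    if (sum(sig) < min_regions) next
    if (require_concordance) {
      sgns <- unique(sign(nv[sig]))
      if (length(sgns) != 1L) next
      direction[i] <- sgns
    } else {
      direction[i] <- sign(sum(sign(nv[sig])))
    }
    keep[i] <- TRUE
  }
  out <- tab[keep, , drop = FALSE]
  out <- cbind(set = out$set, category = rep("common", nrow(out)),
               direction = direction[keep],
               out[, c(ncols, qcols), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Pathways specific to a single region
#'
#' @inheritParams common_pathways
#' @param fdr_in significance threshold in the qualifying region (strict
#'   `<`, default 0.01)
#' @param fdr_out null threshold required of the other regions (strict `>`,
#'   default 0.25)
#' @return data frame of calls with `category` of the form
#'   `"specific_<region>"` and `direction` the NES sign in the qualifying
#'   region.
#' @export
region_specific_pathways <- function(region_results, fdr_in = 0.01,
                                     fdr_out = 0.25,
                                     regions = c("WM", "FC", "BG")) {
  tab <- .region_table(region_results, regions)
  qcols <- paste0("q_", regions)
  ncols <- paste0("NES_", regions)
  calls <- list()
  for (i in seq_len(nrow(tab))) {
    qv <- unlist(tab[i, qcols])
    for (r in seq_along(regions)) {
      if (qv[r] < fdr_in && all(qv[-r] > fdr_out)) {
        calls[[length(calls) + 1L]] <- cbind(
          set = tab$set[i],
          category = paste0("specific_", regions[r]),
          direction = sign(tab[i, ncols[r]]),
          tab[i, c(ncols, qcols), drop = FALSE])
      }
    }
  }
  if (length(calls) == 0L) {
    out <- tab[0L, , drop = FALSE]
    out <- cbind(set = character(0L), category = character(0L),
                 direction = numeric(0L),
                 out[, c(ncols, qcols), drop = FALSE])
    return(out)
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Leading-edge differential-gene table for consensus pathways
#'
#' Takes the union of leading-edge genes over the called pathways, across
#' the regions in which each pathway qualified (q below `qualify_fdr`), and
#' keeps the genes reaching a Welch-test p-value below `p_cut` in at least
#' one qualifying region of the contrast. Output is sorted by the best
#' (smallest) per-region p-value.
#'
#' @param calls consensus call data frame from [common_pathways()] and/or
#'   [region_specific_pathways()]
#' @param region_results named list of `gsea` objects, one per region
#' @param values genes x samples expression matrix
#' @param annotations sample annotation data frame
#' @param test_group,ref_group the contrast's groups
#' @param p_cut Welch p-value cutoff (strict `<`, default 0.01)
#' @param qualify_fdr FDR threshold defining in which regions a called
#'   pathway qualifies (default 0.01)
#' @param regions region labels
#' @return data frame: `gene`, `best_p`, `regions` (comma-joined regions
#'   where p < p_cut), `pathways` (comma-joined contributing pathways),
#'   plus per-region `p_*` columns.
#' @export
leading_edge_gene_table <- function(calls, region_results, values, annotations,
                                    test_group, ref_group, p_cut = 0.01,
                                    qualify_fdr = 0.01,
                                    regions = c("WM", "FC", "BG")) {
  if (nrow(calls) == 0L) stop("`calls` is empty")
  .check_region_results(region_results, regions)
  gene_sources <- list()    # gene -> contributing pathways
  gene_regions <- list()    # gene -> regions where a source pathway qualified
  for (i in seq_len(nrow(calls))) {
    set <- calls$set[i]
    for (r in regions) {
      res <- region_results[[r]]$results
      j <- match(set, res$set)
      if (res$fdr_q[j] < qualify_fdr) {
        for (g in res$leading_edge[[j]]) {
          gene_sources[[g]] <- union(gene_sources[[g]], set)
          gene_regions[[g]] <- union(gene_regions[[g]], r)
        }
      }
    }
  }
  genes <- sort(names(gene_sources))
  if (length(genes) == 0L)
    return(data.frame(gene = character(0L), best_p = numeric(0L),
                      regions = character(0L), pathways = character(0L)))
  ann <- annotations[match(colnames(values), annotations$sample_id), ]
  pmat <- sapply(regions, function(r) {
    ti <- which(ann$region == r & ann$group == test_group)
    ri <- which(ann$region == r & ann$group == ref_group)
    sub <- values[genes, , drop = FALSE]
    .welch_rows(sub[, ti, drop = FALSE], sub[, ri, drop = FALSE])$p
  })
  pmat <- matrix(pmat, nrow = length(genes),
                 dimnames = list(genes, regions))
  # a gene is retained when p < p_cut in >= 1 region where one of its
  # source pathways qualified; best_p is taken over those regions
  hit_regions <- lapply(genes, function(g) {
    rr <- gene_regions[[g]]
    rr[pmat[g, rr] < p_cut]
  })
  keep <- lengths(hit_regions) > 0L
  genes <- genes[keep]
  hit_regions <- hit_regions[keep]
  out <- data.frame(
    gene = genes,
    best_p = vapply(seq_along(genes), function(i)
      min(pmat[genes[i], hit_regions[[i]]]), numeric(1L)),
    regions = vapply(hit_regions, paste, character(1L), collapse = ","),
    pathways = vapply(genes, function(g)
      paste(sort(gene_sources[[g]]), collapse = ","), character(1L)),
    stringsAsFactors = FALSE)
  out <- cbind(out, stats::setNames(as.data.frame(pmat[genes, , drop = FALSE]),
                                    paste0("p_", regions)))
  out <- out[order(out$best_p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
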