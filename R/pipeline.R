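#' Deterministic child seed for a pipeline stage
#'
#' Contrast x region runs are seeded independently so they can be
#' reproduced in isolation: `child = (seed * 31 + index * 1009) mod
#' (2^31 - 1)`, with `index` the 1-based position of the run in the
#' contrast x region grid.
#'
#' @param seed global integer seed
#' @param index 1-based stage index
#' @return integer scalar in [0, 2^31 - 1).
#' @export
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 31 + as.numeric(index) * 1009) %% 2147483647)
}

.default_contrasts <- list(c("B", "A"), c("C", "A"), c("C", "B"),
                           c("D", "B"), c("D", "C"))

#' Run the full multi-region pathway analysis
#'
#' Orchestrates the complete design over one dataset: probe collapse,
#' gene-set filtering, GSEA for every contrast x region, per-contrast
#' cross-region consensus (common and region-specific calls), a summary
#' counts table, optional per-sample activity scores, and a JSON manifest
#' with input digests and per-stage timings. The default contrasts are the
#' five disease transitions B-A, C-A, C-B, D-B, D-C (test group named
#' first; positive NES = up in the test group).
#'
#' @param matrix probe x sample matrix, or path to its TSV
#' @param annotations annotation data frame, or path to its TSV
#' @param probe_map probe-to-gene data frame, path to its TSV, or `NULL`
#'   when `matrix` is already gene-level
#' @param collection a [gene_set_collection()] or path to a GMT file
#' @param out_dir output directory (created)
#' @param contrasts list of `c(test, ref)` group pairs
#' @param regions region labels to analyze
#' @param n_perm,weight_exponent,min_size,metric GSEA parameters, see
#'   [run_gsea()]
#' @param seed global seed; each contrast x region run uses
#'   [child_seed()] of it
#' @param fdr_common,min_regions consensus parameters, see
#'   [common_pathways()]
#' @param fdr_in,fdr_out region-specificity parameters, see
#'   [region_specific_pathways()]
#' @param activity compute the per-sample activity matrix (default TRUE)
#' @return Invisibly, a list with `out_dir`, `gsea` (nested
#'   contrast -> region -> `gsea` object), `consensus`, `counts` (the
#'   per-comparison summary table) and `activity`.
#' @export
run_pipeline <- function(matrix, annotations, probe_map = NULL, collection,
                         out_dir,
                         contrasts = .default_contrasts,
                         regions = c("WM", "FC", "BG"),
                         n_perm = 1000L, weight_exponent = 1.0,
                         min_size = 10L, metric = "signed_logp", seed = 1L,
                         fdr_common = 0.01, min_regions = 2L,
                         fdr_in = 0.01, fdr_out = 0.25, activity = TRUE) {
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, start) {
    timings[[stage]] <<- round(as.numeric(Sys.time() - start, units = "secs"), 3)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  digests <- character(0L)
  if (is.character(matrix)) {
    stopifnot(is.character(annotations))
    digests <- c(matrix = unname(tools::md5sum(matrix)),
                 annotations = unname(tools::md5sum(annotations)))
    loaded <- read_expression(matrix, annotations)
    matrix <- loaded$values
    annotations <- loaded$annotations
  }
  if (is.character(probe_map)) {
    digests <- c(digests, probe_map = unname(tools::md5sum(probe_map)))
    probe_map <- utils::read.delim(probe_map, colClasses = "character")
  }
  if (is.character(collection)) {
    digests <- c(digests, gmt = unname(tools::md5sum(collection)))
    collection <- read_gmt(collection)
  }

  ts <- Sys.time()
  gene_values <- if (is.null(probe_map)) matrix else
    collapse_probes_by_cv(matrix, probe_map)
  coll <- restrict_and_filter(collection, rownames(gene_values),
                              min_size = min_size)
  tick("collapse_and_filter", ts)

  contrast_names <- vapply(contrasts, paste, character(1L), collapse = "-")
  gsea_results <- list()
  idx <- 0L
  ts <- Sys.time()
  for (ci in seq_along(contrasts)) {
    ct <- contrasts[[ci]]
    per_region <- list()
    for (r in regions) {
      idx <- idx + 1L
      g <- run_gsea(gene_values, annotations, ct[1L], ct[2L], r, coll,
                    weight_exponent = weight_exponent, n_perm = n_perm,
                    seed = child_seed(seed, idx), min_size = min_size,
                    metric = metric)
      write_gsea_tsv(g, file.path(out_dir, sprintf("gsea_%s_%s.tsv",
                                                   contrast_names[ci], r)))
      per_region[[r]] <- g
    }
    gsea_results[[contrast_names[ci]]] <- per_region
  }
  tick("gsea", ts)

  ts <- Sys.time()
  consensus <- list()
  counts <- list()
  for (cn in contrast_names) {
    rr <- gsea_results[[cn]]
    common <- common_pathways(rr, fdr_threshold = fdr_common,
                              min_regions = min_regions, regions = regions)
    specific <- region_specific_pathways(rr, fdr_in = fdr_in,
                                         fdr_out = fdr_out, regions = regions)
    cons <- rbind(common, specific)
    utils::write.table(cons, file.path(out_dir,
                                       sprintf("consensus_%s.tsv", cn)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    consensus[[cn]] <- cons
    row <- data.frame(contrast = cn, stringsAsFactors = FALSE)
    for (r in regions)
      row[[paste0("n_sig_", r)]] <- sum(rr[[r]]$results$fdr_q < fdr_common)
    row$n_common <- nrow(common)
    for (r in regions)
      row[[paste0("n_specific_", r)]] <-
        sum(specific$category == paste0("specific_", r))
    counts[[cn]] <- row
  }
  counts <- do.call(rbind, counts)
  rownames(counts) <- NULL
  utils::write.table(counts, file.path(out_dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tick("consensus", ts)

  act <- NULL
  if (activity) {
    ts <- Sys.time()
    zm <- suppressWarnings(z_transform(gene_values))
    act_coll <- restrict_and_filter(coll, rownames(zm), min_size = min_size)
    act <- sample_activity(zm, act_coll, weight_exponent = weight_exponent)
    write_expression_tsv(act, file.path(out_dir, "activity.tsv"),
                         id_column = "set")
    utils::write.table(group_activity_summary(act, annotations),
                       file.path(out_dir, "activity_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tick("activity", ts)
  }

  manifest <- list(
    created = format(t0, "%Y-%m-%d %H:%M:%S %Z"),
    seed = seed,
    params = list(n_perm = n_perm, weight_exponent = weight_exponent,
                  min_size = min_size, metric = metric,
                  fdr_common = fdr_common, min_regions = min_regions,
                  fdr_in = fdr_in, fdr_out = fdr_out),
    contrasts = contrast_names, regions = regions,
    n_genes = nrow(gene_values), n_samples = ncol(gene_values),
    n_sets = length(coll),
    set_sizes = if (length(coll) > 0L)
      as.list(summary(lengths(coll$sets))) else NULL,
    input_digests = as.list(digests),
    timings_sec = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(
    c(sprintf("pipeline finished in %.1f s",
              as.numeric(Sys.time() - t0, units = "secs")),
      sprintf("  %s: %.3f s", names(timings), unlist(timings))),
    file.path(out_dir, "pipeline.log"))

  invisible(list(out_dir = out_dir, gsea = gsea_results,
                 consensus = consensus, counts = counts, activity = act))
}
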