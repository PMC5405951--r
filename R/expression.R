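#' Expression containers and sample annotations
#'
#' Expression values are held as a plain numeric matrix (probes or genes in
#' rows, samples in columns, normalized log-scale intensities) alongside a
#' sample annotation data frame with columns `sample_id`, `group` and
#' `region`. The default study design has four clinical groups (A: controls;
#' B: infected, no neurocognitive impairment; C: infected with impairment,
#' no encephalitis; D: infected with impairment and encephalitis) profiled
#' in three brain regions (WM: white matter; FC: frontal cortex; BG: basal
#' ganglia), but any label sets can be supplied.
#'
#' @name expression-io
NULL

.default_groups  <- c("A", "B", "C", "D")
.default_regions <- c("WM", "FC", "BG")

.validate_annotations <- function(annotations, sample_ids,
                                  groups = .default_groups,
                                  regions = .default_regions) {
  need <- c("sample_id", "group", "region")
  miss <- setdiff(need, names(annotations))
  if (length(miss) > 0L)
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  annotations$sample_id <- as.character(annotations$sample_id)
  annotations$group     <- as.character(annotations$group)
  annotations$region    <- as.character(annotations$region)
  absent <- setdiff(sample_ids, annotations$sample_id)
  if (length(absent) > 0L)
    stop("sample(s) in matrix missing from annotations: ",
         paste(absent, collapse = ", "))
  bad_g <- setdiff(annotations$group, groups)
  if (length(bad_g) > 0L)
    stop("unknown group label(s): ", paste(bad_g, collapse = ", "),
         " (allowed: ", paste(groups, collapse = ","), ")")
  bad_r <- setdiff(annotations$region, regions)
  if (length(bad_r) > 0L)
    stop("unknown region label(s): ", paste(bad_r, collapse = ", "),
         " (allowed: ", paste(regions, collapse = ","), ")")
  annotations[match(sample_ids, annotations$sample_id), , drop = FALSE]
}

#' Read an expression matrix and its sample annotations
#'
#' The matrix file is tab-delimited with a header row of sample ids and a
#' first column of probe (or gene) ids; the annotation file is tab-delimited
#' with columns `sample_id`, `group`, `region`. Every sample in the matrix
#' must be annotated; missing or non-numeric cells are errors.
#'
#' @param matrix_path path to the TSV expression matrix
#' @param annotation_path path to the TSV annotation table
#' @param groups,regions allowed annotation labels
#' @return A list with `values` (numeric matrix, rows named by probe id) and
#'   `annotations` (data frame aligned to the matrix columns).
#' @export
read_expression <- function(matrix_path, annotation_path,
                            groups = .default_groups,
                            regions = .default_regions) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           colClasses = "character", row.names = NULL)
  if (ncol(raw) < 2L) stop("expression matrix needs an id column and >=1 sample")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate row id(s) in expression matrix: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing value at row '%s', sample '%s'",
                 ids[bad[1L]], colnames(vals)[bad[2L]]))
  }
  dimnames(num) <- list(ids, colnames(vals))
  ann <- utils::read.delim(annotation_path, check.names = FALSE,
                           colClasses = "character")
  ann <- .validate_annotations(ann, colnames(num), groups, regions)
  list(values = num, annotations = ann)
}

#' Collapse probes to genes by highest coefficient of variation
#'
#' For each gene the retained row is the probe maximizing
#' CV = sd / mean computed across all samples (sample standard deviation,
#' n - 1 denominator), on the values as given. Unmapped probes are dropped.
#' Exact CV ties (including multiple zero-variance probes) retain the
#' lexicographically smallest probe id, so the collapse is deterministic.
#' A probe with |mean| < 1e-12 but positive sd has undefined CV; it is
#' treated as CV = +Inf and can only be retained when no probe of the gene
#' has a finite CV, in which case a warning is issued.
#'
#' @param values numeric matrix, probes x samples, rownames = probe ids
#' @param probe_map data frame with columns `probe_id`, `gene_symbol`;
#'   a probe maps to at most one gene
#' @return numeric matrix, genes x samples, rownames = gene symbols, with
#'   attribute `"representative_probe"` naming the probe kept per gene.
#' @export
collapse_probes_by_cv <- function(values, probe_map) {
  stopifnot(is.matrix(values), is.numeric(values))
  need <- c("probe_id", "gene_symbol")
  if (!all(need %in% names(probe_map)))
    stop("`probe_map` needs columns probe_id and gene_symbol")
  pm <- data.frame(probe_id = as.character(probe_map$probe_id),
                   gene_symbol = as.character(probe_map$gene_symbol))
  if (anyDuplicated(pm$probe_id))
    stop("probe(s) mapped to more than one gene: ",
         paste(unique(pm$probe_id[duplicated(pm$probe_id)]), collapse = ", "))
  pm <- pm[pm$probe_id %in% rownames(values), , drop = FALSE]
  if (nrow(pm) == 0L) stop("no mapped probe present in the matrix")

  mu <- rowMeans(values)
  sdv <- apply(values, 1L, stats::sd)
  cv <- sdv / mu
  zero_mean <- abs(mu) < 1e-12
  cv[zero_mean & sdv > 0] <- NA_real_   # undefined; deferred +Inf policy
  cv[zero_mean & sdv == 0] <- 0

  keep <- character(0L)
  genes <- sort(unique(pm$gene_symbol))
  by_gene <- split(pm$probe_id, pm$gene_symbol)
  rep_probe <- vapply(genes, function(g) {
    probes <- sort(by_gene[[g]])
    v <- cv[probes]
    if (all(is.na(v))) {
      warning("gene ", g, ": all probes have zero mean; ",
              "retaining by undefined-CV fallback")
      return(probes[1L])
    }
    probes[which.max(ifelse(is.na(v), -Inf, v))]
  }, character(1L))
  out <- values[rep_probe, , drop = FALSE]
  rownames(out) <- genes
  attr(out, "representative_probe") <- stats::setNames(rep_probe, genes)
  out
}

#' Z-transform each gene across samples
#'
#' Centers and scales every gene row to mean 0, sample standard deviation 1.
#' Constant rows carry no ranking information and are dropped with a
#' warning.
#'
#' @param values numeric matrix, genes x samples (>= 2 samples)
#' @return numeric matrix of the same column dimension; constant rows
#'   removed.
#' @export
z_transform <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (ncol(values) < 2L) stop("z-transform needs >= 2 samples")
  sdv <- apply(values, 1L, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  if (any(const)) {
    warning(sum(const), " constant gene row(s) dropped during z-transform: ",
            paste(utils::head(rownames(values)[const], 5L), collapse = ", "),
            if (sum(const) > 5L) ", ..." else "")
    values <- values[!const, , drop = FALSE]
    sdv <- sdv[!const]
  }
  (values - rowMeans(values)) / sdv
}

#' Flag samples whose region markers conflict with their region label
#'
#' White-matter and cortical samples can be cross-checked against the
#' expression of a neuronal marker (default RBFOX3/NeuN) and an
#' oligodendrocyte marker (default MBP): a white-matter sample dominated by
#' the neuronal marker, or a cortical sample dominated by the myelin
#' marker, is suspicious. Marker values are z-transformed across samples
#' and a sample is flagged when the marker difference exceeds `threshold`
#' z-units in the conflicting direction. Basal-ganglia samples are never
#' flagged. The list is advisory: exclusion is the caller's decision.
#'
#' @param values numeric matrix, genes x samples
#' @param annotations sample annotation data frame (`sample_id`, `region`)
#' @param neuron_marker,oligo_marker marker gene symbols
#' @param threshold flagging threshold in z-units (default 1.0)
#' @return data frame with columns `sample_id`, `region`, `reason`
#'   (zero rows when nothing is flagged).
#' @export
flag_region_marker_conflicts <- function(values, annotations,
                                         neuron_marker = "RBFOX3",
                                         oligo_marker = "MBP",
                                         threshold = 1.0) {
  for (mk in c(neuron_marker, oligo_marker))
    if (!mk %in% rownames(values))
      stop("marker gene absent from matrix: ", mk)
  ann <- annotations[match(colnames(values), annotations$sample_id), ]
  zn <- as.numeric(scale(values[neuron_marker, ]))
  zo <- as.numeric(scale(values[oligo_marker, ]))
  wm_bad <- ann$region == "WM" & (zn - zo) > threshold
  fc_bad <- ann$region == "FC" & (zo - zn) > threshold
  out <- data.frame(
    sample_id = colnames(values)[wm_bad | fc_bad],
    region = ann$region[wm_bad | fc_bad],
    reason = ifelse(wm_bad[wm_bad | fc_bad],
                    sprintf("WM sample with neuronal marker excess (z diff > %g)",
                            threshold),
                    sprintf("FC sample with oligodendrocyte marker excess (z diff > %g)",
                            threshold)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write an expression matrix as TSV
#'
#' @param values numeric matrix with row and column names
#' @param path output path
#' @param id_column header for the id column
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(values, path, id_column = "id") {
  df <- data.frame(rownames(values), values, check.names = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
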