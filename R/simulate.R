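#' Configuration for the synthetic study generator
#'
#' Describes a multi-group, multi-region expression study with known
#' injected pathway shifts. Defaults emulate a small post-mortem brain
#' cohort profiled on log-scale arrays: four clinical groups by three
#' regions with 8 samples per cell, ~N(7, 1) log intensities, moderate
#' within-set gene-gene correlation, and mean shifts expressed in units of
#' the per-gene noise standard deviation.
#'
#' @param n_genes number of genes (default 2000)
#' @param n_sets number of gene sets (default 50); sets are disjoint blocks
#'   of consecutive genes
#' @param set_size genes per set: a scalar or a `c(min, max)` range sampled
#'   uniformly per set (default 20)
#' @param groups group labels (default A, B, C, D)
#' @param regions region labels (default WM, FC, BG)
#' @param n_per_cell samples per group x region cell (default 8)
#' @param baseline_mean baseline log-scale mean (default 7.0)
#' @param noise_sd per-gene noise standard deviation (default 1.0)
#' @param rho within-set gene-gene correlation in [0, 1), induced by a
#'   shared per-set factor (default 0.1, in line with typical mean pairwise
#'   co-expression inside curated pathway sets)
#' @param injections data frame (or list coercible to one) with columns
#'   `set` (set name or index), `group`, `region`, `delta` (shift in units
#'   of `noise_sd`), `direction` (+1/-1); may be `NULL`
#' @param probes_per_gene probes per gene (default 1); with more than one,
#'   one randomly chosen probe per gene gets inflated variance so that
#'   CV-based probe collapse has something to choose between
#' @param seed integer seed
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_sets = 50L, set_size = 20L,
                       groups = c("A", "B", "C", "D"),
                       regions = c("WM", "FC", "BG"),
                       n_per_cell = 8L, baseline_mean = 7.0, noise_sd = 1.0,
                       rho = 0.1, injections = NULL, probes_per_gene = 1L,
                       seed = 1L) {
  stopifnot(n_genes >= 1L, n_sets >= 0L, n_per_cell >= 2L,
            rho >= 0, rho < 1, probes_per_gene >= 1L, noise_sd > 0)
  if (length(set_size) == 1L) set_size <- c(set_size, set_size)
  stopifnot(length(set_size) == 2L, set_size[1L] <= set_size[2L])
  if (!is.null(injections)) {
    injections <- as.data.frame(injections)
    need <- c("set", "group", "region", "delta", "direction")
    miss <- setdiff(need, names(injections))
    if (length(miss) > 0L)
      stop("injections lack column(s): ", paste(miss, collapse = ", "))
    bad <- setdiff(injections$group, groups)
    if (length(bad) > 0L) stop("injection group(s) not in design: ",
                               paste(bad, collapse = ", "))
    bad <- setdiff(injections$region, regions)
    if (length(bad) > 0L) stop("injection region(s) not in design: ",
                               paste(bad, collapse = ", "))
    if (!all(injections$direction %in% c(-1, 1)))
      stop("injection direction must be +1 or -1")
  }
  structure(list(n_genes = as.integer(n_genes), n_sets = as.integer(n_sets),
                 set_size = as.integer(set_size), groups = groups,
                 regions = regions, n_per_cell = as.integer(n_per_cell),
                 baseline_mean = baseline_mean, noise_sd = noise_sd,
                 rho = rho, injections = injections,
                 probes_per_gene = as.integer(probes_per_gene),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic multi-region expression study
#'
#' Gene-level values are
#' `baseline_mean + noise_sd * (sqrt(rho) * L + sqrt(1 - rho) * e)` where
#' `L` is a per-set, per-sample shared standard normal factor (inducing
#' within-set correlation `rho`) and `e` is independent standard normal;
#' genes outside any set are independent. Injected cells add
#' `delta * noise_sd * direction` to every gene of the injected set in the
#' samples of that group x region. Probes replicate their gene's values
#' plus independent probe noise (sd `0.2 * noise_sd`); when a gene has
#' several probes, one randomly chosen probe receives inflated probe noise
#' (sd `0.5 * noise_sd`) so that CV-based collapse is exercised. Output is
#' deterministic given the seed.
#'
#' @param cfg a [sim_config()]
#' @return list with `values` (probe x sample matrix), `annotations`
#'   (sample_id, group, region), `probe_map` (probe_id, gene_symbol),
#'   `collection` (the simulated sets as a [gene_set_collection()]) and
#'   `truth` (class `sim_truth`: the injection table and the config).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    genes <- sprintf("G%05d", seq_len(cfg$n_genes))
    sizes <- if (cfg$n_sets == 0L) integer(0L)
      else if (cfg$set_size[1L] == cfg$set_size[2L])
        rep(cfg$set_size[1L], cfg$n_sets)
      else sample(seq(cfg$set_size[1L], cfg$set_size[2L]), cfg$n_sets,
                  replace = TRUE)
    if (sum(sizes) > cfg$n_genes)
      stop("sets require ", sum(sizes), " genes but n_genes = ", cfg$n_genes)
    bounds <- cumsum(c(0L, sizes))
    sets <- lapply(seq_len(cfg$n_sets), function(s)
      genes[(bounds[s] + 1L):bounds[s + 1L]])
    names(sets) <- sprintf("SET_%03d", seq_len(cfg$n_sets))
    collection <- gene_set_collection(sets)

    ann <- expand.grid(i = seq_len(cfg$n_per_cell), group = cfg$groups,
                       region = cfg$regions, stringsAsFactors = FALSE)
    ann$sample_id <- sprintf("%s_%s_%02d", ann$group, ann$region, ann$i)
    ann <- ann[, c("sample_id", "group", "region")]
    ns <- nrow(ann)

    gvals <- matrix(stats::rnorm(cfg$n_genes * ns), cfg$n_genes, ns)
    if (cfg$rho > 0 && cfg$n_sets > 0L) {
      L <- matrix(stats::rnorm(cfg$n_sets * ns), cfg$n_sets, ns)
      for (s in seq_len(cfg$n_sets)) {
        rows <- (bounds[s] + 1L):bounds[s + 1L]
        gvals[rows, ] <- sqrt(cfg$rho) * rep(L[s, ], each = length(rows)) +
          sqrt(1 - cfg$rho) * gvals[rows, ]
      }
    }
    gvals <- cfg$baseline_mean + cfg$noise_sd * gvals
    dimnames(gvals) <- list(genes, ann$sample_id)

    inj <- cfg$injections
    if (!is.null(inj) && nrow(inj) > 0L) {
      inj$set <- ifelse(grepl("^[0-9]+$", as.character(inj$set)),
                        names(sets)[as.integer(as.character(inj$set))],
                        as.character(inj$set))
      bad <- setdiff(inj$set, names(sets))
      if (length(bad) > 0L)
        stop("injection references absent set(s): ",
             paste(bad, collapse = ", "))
      for (i in seq_len(nrow(inj))) {
        rows <- match(sets[[inj$set[i]]], genes)
        cols <- which(ann$group == inj$group[i] & ann$region == inj$region[i])
        gvals[rows, cols] <- gvals[rows, cols] +
          inj$delta[i] * cfg$noise_sd * inj$direction[i]
      }
    }

    ppg <- cfg$probes_per_gene
    probe_ids <- as.vector(t(outer(genes, seq_len(ppg),
                                   function(g, j) sprintf("%s_p%d", g, j))))
    probe_map <- data.frame(probe_id = probe_ids,
                            gene_symbol = rep(genes, each = ppg),
                            stringsAsFactors = FALSE)
    pvals <- gvals[rep(seq_len(cfg$n_genes), each = ppg), , drop = FALSE]
    noise_sds <- rep(0.2 * cfg$noise_sd, length(probe_ids))
    if (ppg > 1L) {
      noisy <- (seq_len(cfg$n_genes) - 1L) * ppg +
        sample.int(ppg, cfg$n_genes, replace = TRUE)
      noise_sds[noisy] <- 0.5 * cfg$noise_sd
    }
    pvals <- pvals + matrix(stats::rnorm(length(pvals), sd = noise_sds),
                            nrow = nrow(pvals))
    dimnames(pvals) <- list(probe_ids, ann$sample_id)

    truth <- structure(list(injections = if (is.null(inj))
      data.frame(set = character(0L), group = character(0L),
                 region = character(0L), delta = numeric(0L),
                 direction = numeric(0L)) else inj,
      config = cfg), class = "sim_truth")
    list(values = pvals, annotations = ann, probe_map = probe_map,
         collection = collection, truth = truth)
  })
}

#' Recovery of injected pathway shifts from enrichment results
#'
#' Compares enrichment results with the simulator's ground truth. An
#' injected (set, group, region) is *expected* in every analyzed contrast
#' that involves the injected group in the injected region; sensitivity is
#' the fraction of expected (set, contrast, region) triples reaching FDR q
#' below `fdr_threshold`, and the false-call rate is the fraction of all
#' non-expected (set, contrast, region) triples called significant.
#'
#' @param truth the `sim_truth` record from [generate_dataset()]
#' @param results a list of `gsea` objects (any nesting; flattened), e.g.
#'   the per-region results of one or more contrasts
#' @param fdr_threshold detection threshold (default 0.01)
#' @return list of class `recovery_report`: `sensitivity` (`NA` when the
#'   truth holds no injection), `false_call_rate`, counts, and `details`
#'   (one row per expected triple with NES, q and detection flag).
#' @export
recovery_report <- function(truth, results, fdr_threshold = 0.01) {
  stopifnot(inherits(truth, "sim_truth"))
  if (inherits(results, "gsea")) results <- list(results)
  flat <- list()
  collect <- function(x) {
    if (inherits(x, "gsea")) flat[[length(flat) + 1L]] <<- x
    else if (is.list(x)) lapply(x, collect)
    invisible(NULL)
  }
  collect(results)
  if (length(flat) == 0L) stop("no `gsea` object found in `results`")
  inj <- truth$injections
  details <- list()
  n_expected <- 0L; n_detected <- 0L; n_null <- 0L; n_false <- 0L
  for (g in flat) {
    ct <- g$contrast
    r <- g$results
    exp_sets <- unique(inj$set[inj$region == ct$region &
                                 inj$group %in% c(ct$test_group, ct$ref_group)])
    is_exp <- r$set %in% exp_sets
    det <- r$fdr_q < fdr_threshold
    n_expected <- n_expected + sum(is_exp)
    n_detected <- n_detected + sum(is_exp & det)
    n_null <- n_null + sum(!is_exp)
    n_false <- n_false + sum(!is_exp & det)
    if (any(is_exp))
      details[[length(details) + 1L]] <- data.frame(
        set = r$set[is_exp],
        contrast = paste0(ct$test_group, "-", ct$ref_group),
        region = ct$region, nes = r$nes[is_exp], fdr_q = r$fdr_q[is_exp],
        detected = det[is_exp], stringsAsFactors = FALSE)
  }
  structure(list(
    sensitivity = if (n_expected > 0L) n_detected / n_expected else NA_real_,
    false_call_rate = if (n_null > 0L) n_false / n_null else NA_real_,
    n_expected = n_expected, n_detected = n_detected,
    n_null = n_null, n_false = n_false,
    fdr_threshold = fdr_threshold,
    details = if (length(details) > 0L) do.call(rbind, details) else
      data.frame(set = character(0L), contrast = character(0L),
                 region = character(0L), nes = numeric(0L),
                 fdr_q = numeric(0L), detected = logical(0L))),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery at q < %g: sensitivity %s (%d/%d), false-call rate %s (%d/%d)\n",
              x$fdr_threshold,
              ifelse(is.na(x$sensitivity), "NA",
                     sprintf("%.3f", x$sensitivity)),
              x$n_detected, x$n_expected,
              ifelse(is.na(x$false_call_rate), "NA",
                     sprintf("%.4f", x$false_call_rate)),
              x$n_false, x$n_null))
  invisible(x)
}

#' Write a complete synthetic study to a directory
#'
#' Materializes the TSV/GMT files consumed by the analysis entry points:
#' `matrix.tsv`, `annotations.tsv`, `probe_map.tsv`, `sets.gmt` and
#' `truth.tsv`.
#'
#' @param sim a [generate_dataset()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(sim$values, file.path(dir, "matrix.tsv"),
                       id_column = "probe_id")
  utils::write.table(sim$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$probe_map, file.path(dir, "probe_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(sim$collection, file.path(dir, "sets.gmt"))
  utils::write.table(sim$truth$injections, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
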