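#' @keywords internal
#' Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Running-sum enrichment score of a gene set in a ranked list
#'
#' Walks the ranked list from top to bottom keeping a running sum: a gene
#' belonging to the set (a "hit") increments it by
#' `|metric|^weight_exponent / NR`, where NR is the sum of
#' `|metric|^weight_exponent` over the in-list set members, and any other
#' gene decrements it by `1/(N - k)` (N list length, k in-list set size).
#' The enrichment score (ES) is the running-sum value of maximal absolute
#' deviation from zero, so ES is always in [-1, 1]. With
#' `weight_exponent = 0` this is the classic Kolmogorov-Smirnov form.
#'
#' Peak ties are resolved deterministically: the smallest index for a
#' positive peak, the largest index for a negative peak, and an exact
#' cross-sign tie resolves positive. If every in-list set member has metric
#' zero (NR = 0) the set falls back to `weight_exponent = 0` with a warning.
#'
#' @param ranked a [rank_genes()] result, or any data frame with columns
#'   `gene` and `metric` sorted by decreasing metric
#' @param genes character vector: the gene set
#' @param weight_exponent weighting exponent on |metric| (default 1.0;
#'   0 gives the unweighted statistic)
#' @return list with `es`, `peak_index`, `running` (length-N numeric) and
#'   `leading_edge` (set members at/before the peak for positive ES,
#'   at/after it for negative ES; empty when ES = 0).
#' @export
enrichment_score <- function(ranked, genes, weight_exponent = 1.0) {
  gl <- ranked$gene
  N <- length(gl)
  hit <- gl %in% genes
  k <- sum(hit)
  if (k == 0L) stop("no gene of the set is present in the ranked list")
  if (k == N) stop("the set covers the whole ranked list")
  w <- abs(ranked$metric)^weight_exponent
  w[!hit] <- 0
  NR <- sum(w[hit])
  if (NR == 0) {
    warning("all in-set metric values are zero; falling back to weight_exponent = 0")
    w[hit] <- 1
    NR <- k
  }
  step <- numeric(N)
  step[hit] <- w[hit] / NR
  step[!hit] <- -1 / (N - k)
  running <- cumsum(step)
  mx <- max(running)
  mn <- min(running)
  if (mx <= 0 && mn >= 0) {
    return(list(es = 0, peak_index = 1L, running = running,
                leading_edge = character(0L)))
  }
  # cross-sign ties (within floating tolerance) resolve positive
  tol <- 1e-9 * max(abs(mx), abs(mn))
  if (mx >= -mn - tol) {
    peak <- which.max(running)            # smallest index attaining the max
    es <- mx
    le <- gl[hit & seq_len(N) <= peak]
  } else {
    peak <- max(which(running == mn))     # largest index attaining the min
    es <- mn
    le <- gl[hit & seq_len(N) >= peak]
  }
  list(es = es, peak_index = peak, running = running, leading_edge = le)
}

# Fast ES from sorted hit positions only (O(k) per set). `pos` are the
# 1-based ranks of the set's genes (sorted increasing), `w` the matching
# |metric|^exponent weights, `N` the list length. Running-sum extrema can
# only occur at hit positions (maxima) or immediately before hits / at the
# list end (minima), which this exploits. Must agree exactly with
# enrichment_score(); tested against it.
.es_fast <- function(N, pos, w) {
  k <- length(pos)
  NR <- sum(w)
  if (NR == 0) { w <- rep(1, k); NR <- k }
  d <- 1 / (N - k)
  cw <- cumsum(w) / NR
  miss_before <- pos - seq_len(k)       # misses seen before each hit
  at_hit <- cw - miss_before * d
  before_hit <- c(0, cw[-k]) - miss_before * d
  if (pos[1L] == 1L) before_hit <- before_hit[-1L]  # index 0 is not a state
  mx <- max(at_hit, 0)
  mn <- min(before_hit, 0)
  tol <- 1e-9 * max(mx, -mn)
  if (mx >= -mn - tol) mx else mn
}

# Rank a metric vector and return each gene's position plus the sorted
# metric; ties broken by gene name ascending to match rank_genes().
.rank_positions <- function(m, gene_names) {
  ord <- order(-m, gene_names)
  posOf <- integer(length(m))
  posOf[ord] <- seq_along(m)
  list(pos_of = posOf, metric_sorted = m[ord])
}

#' Permutation null distributions of the enrichment score
#'
#' Builds the phenotype-permutation null: sample group labels of the
#' contrast are shuffled (group sizes preserved), the full gene ranking is
#' recomputed from the permuted labels, and the ES of every set is recorded
#' against that ranking. The same shuffled label vectors are used for all
#' sets, preserving inter-gene correlation in the null. When the number of
#' distinct label assignments `choose(n, n_test)` does not exceed `n_perm`,
#' all distinct assignments (including the identity) are enumerated instead
#' and a message reports the count.
#'
#' @inheritParams rank_genes
#' @param collection a [gene_set_collection()] already restricted to the
#'   matrix universe
#' @param n_perm number of permutations (default 1000)
#' @param seed integer seed; the caller's RNG state is untouched
#' @param weight_exponent ES weighting exponent
#' @return numeric matrix (sets x permutations) of null ES values with
#'   attributes `scheme` ("sampled" or "exhaustive"), `seed` and `n_perm`.
#' @export
phenotype_null <- function(values, annotations, test_group, ref_group, region,
                           collection, n_perm = 1000L, seed = 1L,
                           weight_exponent = 1.0,
                           metric = c("signed_logp", "t")) {
  metric <- match.arg(metric)
  stopifnot(n_perm >= 1L)
  ann <- annotations[match(colnames(values), annotations$sample_id), ]
  ti <- which(ann$region == region & ann$group == test_group)
  ri <- which(ann$region == region & ann$group == ref_group)
  if (length(ti) < 2L || length(ri) < 2L)
    stop("both contrast groups need >= 2 samples in region ", region)
  sub <- values[, c(ti, ri), drop = FALSE]
  nt <- length(ti); n <- ncol(sub)
  gene_names <- rownames(sub)
  set_idx <- lapply(collection$sets, function(g) match(g, gene_names))
  if (any(vapply(set_idx, anyNA, logical(1L))))
    stop("collection contains genes absent from the matrix; ",
         "apply restrict_and_filter() first")

  n_distinct <- choose(n, nt)
  exhaustive <- is.finite(n_distinct) && n_distinct <= n_perm
  assignments <- if (exhaustive) {
    message(sprintf(
      "only %d distinct label assignments (<= n_perm = %d): exhaustive mode",
      n_distinct, n_perm))
    utils::combn(n, nt, simplify = FALSE)
  } else {
    .with_seed(seed, replicate(n_perm, sample.int(n, nt), simplify = FALSE))
  }

  null_es <- matrix(NA_real_, nrow = length(set_idx), ncol = length(assignments),
                    dimnames = list(names(collection$sets), NULL))
  N <- nrow(sub)
  for (j in seq_along(assignments)) {
    tj <- assignments[[j]]
    w <- .welch_rows(sub[, tj, drop = FALSE], sub[, -tj, drop = FALSE])
    m <- if (metric == "signed_logp") {
      -1 * sign(w$statistic) * log10(pmax(w$p, .Machine$double.xmin))
    } else w$statistic
    rp <- .rank_positions(m, gene_names)
    for (s in seq_along(set_idx)) {
      pos <- sort(rp$pos_of[set_idx[[s]]])
      null_es[s, j] <- .es_fast(N, pos, abs(rp$metric_sorted[pos])^weight_exponent)
    }
  }
  structure(null_es,
            scheme = if (exhaustive) "exhaustive" else "sampled",
            seed = seed, n_perm = ncol(null_es))
}

#' Normalized enrichment score and nominal p-value
#'
#' NES divides the observed ES by the mean absolute null ES of the same
#' sign; the nominal p-value is the fraction of same-sign null ES at least
#' as extreme, floored at `1/(n_perm + 1)` so a finite permutation count
#' never reports p = 0. If the null contains no value of the observed sign,
#' NES is the sentinel `sign(es) * Inf` with the floor p-value. An observed
#' ES of zero yields NES = 0, p = 1.
#'
#' @param es observed enrichment score (scalar)
#' @param null_es numeric vector of permutation ES values for the same set
#' @return list with `nes` and `p_nominal`.
#' @export
normalize_scores <- function(es, null_es) {
  if (length(null_es) == 0L) stop("empty null distribution")
  n_perm <- length(null_es)
  floor_p <- 1 / (n_perm + 1)
  if (es == 0) return(list(nes = 0, p_nominal = 1))
  same <- if (es > 0) null_es[null_es > 0] else null_es[null_es < 0]
  if (length(same) == 0L)
    return(list(nes = sign(es) * Inf, p_nominal = floor_p))
  nes <- es / mean(abs(same))
  p <- max(mean(abs(same) >= abs(es)), floor_p)
  list(nes = nes, p_nominal = p)
}

# Null ES -> null NES, set by set: each permutation ES is divided by the
# mean absolute same-sign null ES of its own set (pooled-null FDR input).
.null_nes <- function(null_es) {
  t(apply(null_es, 1L, function(v) {
    pm <- mean(v[v > 0])
    nm <- mean(abs(v[v < 0]))
    out <- numeric(length(v))
    out[v > 0] <- v[v > 0] / pm
    out[v < 0] <- v[v < 0] / nm
    out
  }))
}

#' GSEA-style FDR q-values from pooled null NES
#'
#' For a set with observed NES* >= 0,
#' `q = [fraction of pooled null NES >= NES*, among null NES >= 0] /
#'      [fraction of observed NES >= NES*, among observed NES >= 0]`,
#' mirrored for NES* < 0, clipped to [0, 1]. Monotonicity is then enforced
#' within each sign (q non-increasing as |NES| grows) by a cumulative
#' minimum taken from the least extreme set toward the most extreme, as in
#' step-up FDR procedures. A zero numerator denominator (no same-sign null)
#' yields q = 0 for the sets beyond the null's reach.
#'
#' @param nes_obs numeric vector of observed NES, one per set
#' @param nes_null numeric matrix (sets x permutations) of null NES
#' @return numeric vector of q-values aligned with `nes_obs`.
#' @export
fdr_q <- function(nes_obs, nes_null) {
  pooled <- as.numeric(nes_null)
  pooled <- pooled[is.finite(pooled)]
  n_pos_null <- sum(pooled >= 0)
  n_neg_null <- sum(pooled <= 0)
  n_pos_obs <- sum(nes_obs >= 0)
  n_neg_obs <- sum(nes_obs <= 0)
  q <- vapply(nes_obs, function(v) {
    if (v >= 0) {
      num <- if (n_pos_null == 0L) 0 else sum(pooled >= v) / n_pos_null
      den <- sum(nes_obs >= v) / n_pos_obs
    } else {
      num <- if (n_neg_null == 0L) 0 else sum(pooled <= v) / n_neg_null
      den <- sum(nes_obs <= v) / n_neg_obs
    }
    min(1, max(0, num / den))
  }, numeric(1L))
  for (sgn in c(1, -1)) {
    idx <- which(if (sgn > 0) nes_obs >= 0 else nes_obs < 0)
    if (length(idx) > 1L) {
      ord <- idx[order(abs(nes_obs[idx]))]       # least extreme first
      q[ord] <- cummin(q[ord])
    }
  }
  q
}

#' Gene set enrichment analysis for one contrast in one region
#'
#' End-to-end enrichment analysis: the collection is restricted to the
#' matrix universe and size-filtered, genes are ranked by the Welch-t
#' signed log10(p) metric for the contrast, each set receives a running-sum
#' ES and leading edge, a sample-label permutation null is built, and NES,
#' nominal p and pooled-null FDR q are derived. Results are sorted by
#' decreasing NES. The computation is deterministic given `seed`.
#'
#' @inheritParams phenotype_null
#' @param min_size minimum post-restriction set size (default 10)
#' @return An object of class `gsea`: a list with `results` (data frame:
#'   `set`, `size`, `es`, `nes`, `p_nominal`, `fdr_q`, plus a list column
#'   `leading_edge`), `contrast`, `params`, and the permutation `scheme`
#'   used. Returns an empty result (with a warning) when no set survives
#'   filtering.
#' @examples
#' sim <- generate_dataset(sim_config(n_genes = 300, n_sets = 5,
#'   n_per_cell = 4, seed = 1))
#' expr <- collapse_probes_by_cv(sim$values, sim$probe_map)
#' g <- run_gsea(expr, sim$annotations, "B", "A", "WM", sim$collection,
#'               n_perm = 50, seed = 1)
#' head(g$results)
#' @export
run_gsea <- function(values, annotations, test_group, ref_group, region,
                     collection, weight_exponent = 1.0, n_perm = 1000L,
                     seed = 1L, min_size = 10L,
                     metric = c("signed_logp", "t")) {
  metric <- match.arg(metric)
  coll <- restrict_and_filter(collection, rownames(values), min_size = min_size)
  contrast <- list(test_group = test_group, ref_group = ref_group,
                   region = region)
  if (length(coll) == 0L) {
    warning("no gene set survives restriction/size filtering")
    res <- data.frame(set = character(0L), size = integer(0L), es = numeric(0L),
                      nes = numeric(0L), p_nominal = numeric(0L),
                      fdr_q = numeric(0L))
    res$leading_edge <- list()
    return(structure(list(results = res, contrast = contrast,
                          params = list(weight_exponent = weight_exponent,
                                        n_perm = n_perm, seed = seed,
                                        min_size = min_size, metric = metric),
                          scheme = NA_character_),
                     class = "gsea"))
  }
  ranked <- rank_genes(values, annotations, test_group, ref_group, region,
                       metric = metric)
  obs <- lapply(coll$sets, function(g)
    enrichment_score(ranked, g, weight_exponent))
  es <- vapply(obs, `[[`, numeric(1L), "es")
  null_es <- phenotype_null(values, annotations, test_group, ref_group, region,
                            coll, n_perm = n_perm, seed = seed,
                            weight_exponent = weight_exponent, metric = metric)
  norm <- lapply(seq_along(es), function(i)
    normalize_scores(es[i], null_es[i, ]))
  nes <- vapply(norm, `[[`, numeric(1L), "nes")
  p_nom <- vapply(norm, `[[`, numeric(1L), "p_nominal")
  q <- fdr_q(nes, .null_nes(null_es))
  res <- data.frame(set = names(coll$sets), size = lengths(coll$sets),
                    es = es, nes = nes, p_nominal = p_nom, fdr_q = q,
                    stringsAsFactors = FALSE)
  res$leading_edge <- lapply(obs, `[[`, "leading_edge")
  ord <- order(-res$nes, res$set)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  structure(list(results = res, contrast = contrast,
                 params = list(weight_exponent = weight_exponent,
                               n_perm = attr(null_es, "n_perm"), seed = seed,
                               min_size = min_size, metric = metric),
                 scheme = attr(null_es, "scheme")),
            class = "gsea")
}

#' @export
print.gsea <- function(x, ...) {
  ct <- x$contrast
  cat(sprintf("GSEA: %s-%s in region %s (%d sets, %d permutations, %s null)\n",
              ct$test_group, ct$ref_group, ct$region, nrow(x$results),
              x$params$n_perm, x$scheme))
  n_sig <- sum(x$results$fdr_q < 0.01)
  cat(sprintf("  %d set(s) at FDR q < 0.01\n", n_sig))
  if (nrow(x$results) > 0L) {
    top <- utils::head(x$results[, c("set", "size", "es", "nes", "p_nominal",
                                     "fdr_q")], 5L)
    print(top, digits = 3L)
  }
  invisible(x)
}

#' @export
summary.gsea <- function(object, fdr_threshold = 0.01, ...) {
  r <- object$results
  out <- list(contrast = object$contrast,
              n_sets = nrow(r),
              n_significant = sum(r$fdr_q < fdr_threshold),
              n_up = sum(r$fdr_q < fdr_threshold & r$nes > 0),
              n_down = sum(r$fdr_q < fdr_threshold & r$nes < 0),
              fdr_threshold = fdr_threshold)
  class(out) <- "summary.gsea"
  out
}

#' @export
print.summary.gsea <- function(x, ...) {
  ct <- x$contrast
  cat(sprintf("%s-%s [%s]: %d/%d sets at q < %g (%d up, %d down)\n",
              ct$test_group, ct$ref_group, ct$region, x$n_significant,
              x$n_sets, x$fdr_threshold, x$n_up, x$n_down))
  invisible(x)
}

#' Write GSEA results as TSV
#'
#' Columns: set, size, ES, NES, nominal p, FDR q, leading edge
#' (comma-joined gene symbols).
#'
#' @param x a `gsea` object
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_gsea_tsv <- function(x, path) {
  stopifnot(inherits(x, "gsea"))
  r <- x$results
  out <- data.frame(set = r$set, size = r$size, ES = r$es, NES = r$nes,
                    p_nominal = r$p_nominal, FDR_q = r$fdr_q,
                    leading_edge = vapply(r$leading_edge, paste,
                                          character(1L), collapse = ","),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
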