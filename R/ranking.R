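#' Welch two-sample t statistic
#'
#' Unequal-variance two-sample t test of the test group against the
#' reference group: `S = (mean(x) - mean(y)) / sqrt(var(x)/nx + var(y)/ny)`
#' with sample variances, Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value. When both groups are constant and equal the degenerate
#' convention `S = 0, p = 1` applies.
#'
#' @param x numeric values of the test group (length >= 2)
#' @param y numeric values of the reference group (length >= 2)
#' @return list with `statistic`, `dof`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both groups need >= 2 observations")
  r <- .welch_rows(matrix(x, nrow = 1L), matrix(y, nrow = 1L))
  list(statistic = r$statistic, dof = r$dof, p = r$p)
}

# Vectorized Welch t over matrix rows; xm, ym: genes x samples submatrices.
# Degenerate rows (both variances zero): S = 0, p = 1 when means are equal,
# otherwise S = +/-Inf with p = 0 (downstream metric clamps p).
.welch_rows <- function(xm, ym) {
  nx <- ncol(xm); ny <- ncol(ym)
  mx <- rowMeans(xm); my <- rowMeans(ym)
  vx <- rowSums((xm - mx)^2) / (nx - 1L)
  vy <- rowSums((ym - my)^2) / (ny - 1L)
  ax <- vx / nx; ay <- vy / ny
  se2 <- ax + ay
  diff <- mx - my
  s <- diff / sqrt(se2)
  dof <- se2^2 / (ax^2 / (nx - 1L) + ay^2 / (ny - 1L))
  degen <- se2 == 0
  if (any(degen)) {
    s[degen] <- ifelse(diff[degen] == 0, 0, sign(diff[degen]) * Inf)
    dof[degen] <- nx + ny - 2L
  }
  p <- 2 * stats::pt(-abs(s), dof)
  p[degen & diff == 0] <- 1
  list(statistic = s, dof = dof, p = p)
}

#' Signed log10 ranking metric
#'
#' Converts a test statistic and two-sided p-value into the ranking metric
#' `-1 * sign(S) * log10(p)`: a gene up in the test group (S > 0, small p)
#' receives a large positive value, a downregulated gene a large negative
#' one, and `sign(0) = 0`. Underflowed p-values (p = 0) are clamped to the
#' smallest positive double with a warning.
#'
#' @param statistic test statistic(s) S
#' @param p two-sided p-value(s)
#' @return numeric vector of metric values.
#' @export
ranking_metric <- function(statistic, p) {
  if (any(p <= 0)) {
    warning("p-value(s) of 0 clamped to .Machine$double.xmin before log10")
    p <- pmax(p, .Machine$double.xmin)
  }
  -1 * sign(statistic) * log10(p)
}

#' Rank genes for a two-group contrast within one region
#'
#' Computes the Welch t statistic per gene between the test and reference
#' groups restricted to one region, converts it to the signed log10(p)
#' metric, and returns the genes sorted by decreasing metric. Metric ties
#' are broken by gene symbol (ascending) so the ranking is deterministic.
#'
#' @param values numeric matrix, genes x samples
#' @param annotations annotation data frame (`sample_id`, `group`, `region`)
#' @param test_group,ref_group group labels; the contrast is
#'   `test_group - ref_group` and a positive metric means higher expression
#'   in the test group
#' @param region region label to restrict samples to
#' @param metric `"signed_logp"` (default) ranks by `-sign(S) log10(p)`;
#'   `"t"` ranks by the raw Welch statistic
#' @return An object of class `ranked_list`: a data frame with columns
#'   `gene`, `metric`, `statistic`, `dof`, `p`, ordered by decreasing
#'   metric, with the contrast stored in attributes `test_group`,
#'   `ref_group`, `region`.
#' @export
rank_genes <- function(values, annotations, test_group, ref_group, region,
                       metric = c("signed_logp", "t")) {
  metric <- match.arg(metric)
  ann <- annotations[match(colnames(values), annotations$sample_id), ]
  ti <- which(ann$region == region & ann$group == test_group)
  ri <- which(ann$region == region & ann$group == ref_group)
  if (length(ti) < 2L)
    stop(sprintf("group %s has %d sample(s) in region %s (need >= 2)",
                 test_group, length(ti), region))
  if (length(ri) < 2L)
    stop(sprintf("group %s has %d sample(s) in region %s (need >= 2)",
                 ref_group, length(ri), region))
  w <- .welch_rows(values[, ti, drop = FALSE], values[, ri, drop = FALSE])
  m <- if (metric == "signed_logp") {
    suppressWarnings(ranking_metric(w$statistic, w$p))
  } else w$statistic
  ord <- order(-m, rownames(values))
  out <- data.frame(gene = rownames(values)[ord], metric = m[ord],
                    statistic = w$statistic[ord], dof = w$dof[ord],
                    p = w$p[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("ranked_list", "data.frame"),
            test_group = test_group, ref_group = ref_group, region = region)
}

#' Export a ranked list in RNK format
#'
#' Two-column tab-separated `gene<TAB>metric`, the standard pre-ranked
#' GSEA interchange format.
#'
#' @param ranked a [rank_genes()] result
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(ranked[, c("gene", "metric")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
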