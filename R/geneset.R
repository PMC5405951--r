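#' Gene-set collections
#'
#' A gene-set collection is an ordered list of named gene sets, each a
#' character vector of unique gene symbols, optionally restricted to a
#' measured gene universe. Gene identity is by exact, case-sensitive symbol
#' match; alias resolution is an upstream concern.
#'
#' @param sets named list of character vectors of gene symbols
#' @param descriptions optional character vector of free-text descriptions,
#'   one per set (recycled to "" when missing)
#' @param universe optional character vector: the gene universe the sets
#'   were restricted to, or `NULL` if unrestricted
#' @return An object of class `gene_set_collection`: a list with elements
#'   `sets`, `descriptions` and `universe`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (!is.list(sets)) stop("`sets` must be a list of character vectors")
  nm <- names(sets)
  if (length(sets) > 0L && (is.null(nm) || any(!nzchar(nm))))
    stop("every gene set must have a non-empty name")
  if (anyDuplicated(nm))
    stop("duplicate gene set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  stopifnot(length(descriptions) == length(sets))
  structure(
    list(sets = sets, descriptions = as.character(descriptions),
         universe = if (is.null(universe)) NULL else unique(as.character(universe))),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("gene_set_collection: %d set(s)\n", length(x$sets)))
  if (length(x$sets) > 0L)
    cat(sprintf("  set sizes: %d-%d (median %g)\n",
                min(sz), max(sz), stats::median(sz)))
  if (!is.null(x$universe))
    cat(sprintf("  restricted to a universe of %d genes\n", length(x$universe)))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-separated MSigDB interchange format: one set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`, UTF-8, no header.
#' Duplicate gene symbols within a line are removed (first occurrence kept);
#' line order is preserved.
#'
#' @param path path to a GMT file
#' @return A [gene_set_collection()].
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines(c("SETA\tfirst\tG1\tG2\tG2", "SETB\tsecond\tG2\tG3"), tf)
#' gsc <- read_gmt(tf)
#' lengths(gsc$sets)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L)
    stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields",
                 bad[1L]))
  nms <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene set name(s) in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  descs <- vapply(fields, `[[`, character(1L), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  gene_set_collection(sets, descriptions = descs)
}

#' Write a gene-set collection to a GMT file
#'
#' @param gsc a [gene_set_collection()]
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- mapply(function(nm, d, g) paste(c(nm, d, g), collapse = "\t"),
                  names(gsc$sets), gsc$descriptions, gsc$sets)
  writeLines(as.character(lines), path, useBytes = TRUE)
  invisible(path)
}

#' Restrict gene sets to a measured universe and filter by size
#'
#' Each set is intersected with the measured gene universe; sets falling
#' below `min_size` genes after intersection are dropped. Size is counted
#' after intersection because the enrichment statistic only ever sees
#' measured genes.
#'
#' @param gsc a [gene_set_collection()]
#' @param universe character vector of measured gene symbols (non-empty)
#' @param min_size minimum post-intersection set size to retain (default 10)
#' @param max_size maximum post-intersection set size to retain
#'   (default `Inf`: no cap)
#' @return A filtered [gene_set_collection()] with `universe` recorded.
#' @export
restrict_and_filter <- function(gsc, universe, min_size = 10L, max_size = Inf) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  if (length(universe) == 0L) stop("`universe` must be non-empty")
  if (min_size < 1L) stop("`min_size` must be >= 1")
  universe <- unique(as.character(universe))
  sets <- lapply(gsc$sets, function(g) g[g %in% universe])
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  gene_set_collection(sets[keep], descriptions = gsc$descriptions[keep],
                      universe = universe)
}
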