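# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain loops, textbook formulas.

# Running-sum enrichment score by explicit enumeration of all N states.
oracle_es <- function(metric, gene_names, set_genes, alpha) {
  N <- length(metric)
  hit <- gene_names %in% set_genes
  k <- sum(hit)
  nr <- 0
  for (i in seq_len(N)) if (hit[i]) nr <- nr + abs(metric[i])^alpha
  if (nr == 0) { alpha <- 0; nr <- k }
  run <- numeric(N)
  s <- 0
  for (i in seq_len(N)) {
    s <- if (hit[i]) s + abs(metric[i])^alpha / nr else s - 1 / (N - k)
    run[i] <- s
  }
  mx <- max(run); mn <- min(run)
  if (mx <= 0 && mn >= 0) return(list(es = 0, running = run))
  if (mx >= -mn - 1e-9 * max(abs(mx), abs(mn))) {
    list(es = mx, running = run, peak = which(run == mx)[1])
  } else {
    list(es = mn, running = run, peak = max(which(run == mn)))
  }
}

# Welch t by direct textbook formula evaluation.
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  s <- (mean(x) - mean(y)) / sqrt(vx / nx + vy / ny)
  dof <- (vx / nx + vy / ny)^2 /
    ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = s, dof = dof, p = 2 * stats::pt(-abs(s), dof))
}

# A tiny deterministic two-group expression matrix with annotations.
tiny_study <- function(n_genes = 60, n_per_group = 5, region = "WM",
                       groups = c("A", "B"), seed = 42) {
  withr::with_seed(seed, {
    ann <- data.frame(
      sample_id = paste0(rep(groups, each = n_per_group), 1:n_per_group),
      group = rep(groups, each = n_per_group),
      region = region, stringsAsFactors = FALSE)
    m <- matrix(rnorm(n_genes * nrow(ann)), n_genes,
                dimnames = list(sprintf("G%03d", 1:n_genes), ann$sample_id))
    list(values = m, annotations = ann)
  })
}

write_tmp_gmt <- function(lines) {
  tf <- withr::local_tempfile(fileext = ".gmt",
                              .local_envir = parent.frame())
  writeLines(lines, tf)
  tf
}
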