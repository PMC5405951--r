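test_that("running-sum ES matches hand-enumerated values on a 10-gene list", {
  # metrics 10..1 on g01..g10, set {g02, g05}, weight 1:
  # NR = 9 + 6 = 15, miss step 1/8; enumerating the 10 running values gives
  # the peak 0.625 immediately after the second hit (position 5)
  rk <- data.frame(gene = sprintf("g%02d", 1:10), metric = as.numeric(10:1))
  prof <- enrichment_score(rk, c("g02", "g05"), weight_exponent = 1)
  expect_equal(prof$es, 0.625)
  expect_identical(prof$peak_index, 5L)
  expect_equal(prof$running,
               c(-0.125, 0.475, 0.35, 0.225, 0.625, 0.5, 0.375, 0.25, 0.125, 0))
  expect_identical(prof$leading_edge, c("g02", "g05"))
  ora <- oracle_es(rk$metric, rk$gene, c("g02", "g05"), 1)
  expect_equal(prof$es, ora$es)
  expect_equal(prof$running, ora$running)
})

test_that("extreme concentration identities hold", {
  rk <- data.frame(gene = sprintf("g%02d", 1:10), metric = as.numeric(10:1))
  expect_equal(enrichment_score(rk, "g01", 1)$es, 1.0)
  expect_equal(enrichment_score(rk, "g10", 1)$es, -1.0)
})

test_that("ES equals the brute-force oracle on random instances and stays in [-1,1]", {
  withr::with_seed(17, {
    for (rep in 1:100) {
      N <- sample(8:50, 1)
      k <- sample(2:min(10, N - 2), 1)
      metric <- sort(rnorm(N, sd = 2), decreasing = TRUE)
      gl <- sprintf("g%03d", 1:N)
      rk <- data.frame(gene = gl, metric = metric)
      set_g <- sample(gl, k)
      for (a in c(0, 1)) {
        got <- enrichment_score(rk, set_g, a)
        ora <- oracle_es(metric, gl, set_g, a)
        expect_equal(got$es, ora$es, tolerance = 1e-12)
        expect_true(abs(got$es) <= 1)
        expect_true(all(got$leading_edge %in% set_g))
      }
      # reversing the list mirrors the unweighted running sum: the ES
      # magnitude is preserved exactly, and the sign flips except when the
      # profile's two extremes tie (the tie-break then picks positive twice)
      es_fwd <- enrichment_score(rk, set_g, 0)
      rk_rev <- data.frame(gene = rev(gl), metric = rev(metric))
      es_rev <- enrichment_score(rk_rev, set_g, 0)
      expect_equal(abs(es_rev$es), abs(es_fwd$es), tolerance = 1e-12)
      run <- es_fwd$running
      if (abs(max(run) + min(run)) > 1e-9)
        expect_equal(es_rev$es, -es_fwd$es, tolerance = 1e-12)
    }
  })
})

test_that("ES agrees with fgsea's statistic (independent implementation)", {
  withr::with_seed(23, {
    for (rep in 1:20) {
      N <- 100
      metric <- sort(rnorm(N, sd = 2), decreasing = TRUE)
      gl <- sprintf("g%03d", 1:N)
      set_g <- sample(gl, 12)
      ours <- enrichment_score(data.frame(gene = gl, metric = metric),
                               set_g, 1)$es
      ref <- fgsea::calcGseaStat(stats::setNames(metric, gl),
                                 sort(match(set_g, gl)), gseaParam = 1)
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("ES error and fallback paths", {
  rk <- data.frame(gene = c("a", "b", "c", "d"), metric = c(2, 1, 0, 0))
  expect_error(enrichment_score(rk, "zzz"), "no gene")
  expect_error(enrichment_score(rk, c("a", "b", "c", "d")), "whole")
  expect_warning(prof <- enrichment_score(rk, c("c", "d"), 1), "weight_exponent = 0")
  expect_equal(prof$es, oracle_es(rk$metric, rk$gene, c("c", "d"), 0)$es)
})

test_that("permutation nulls have the right shape, determinism, and exhaustive fallback", {
  st <- tiny_study(n_genes = 120, n_per_group = 5, seed = 9)
  sets <- list(S1 = sprintf("G%03d", 1:15), S2 = sprintf("G%03d", 20:40))
  coll <- gene_set_collection(sets)
  n1 <- phenotype_null(st$values, st$annotations, "B", "A", "WM", coll,
                       n_perm = 50, seed = 4)
  expect_equal(dim(n1), c(2L, 50L))
  expect_identical(attr(n1, "scheme"), "sampled")
  expect_true(all(abs(n1) <= 1))
  n2 <- phenotype_null(st$values, st$annotations, "B", "A", "WM", coll,
                       n_perm = 50, seed = 4)
  expect_identical(n1, n2)
  n3 <- phenotype_null(st$values, st$annotations, "B", "A", "WM", coll,
                       n_perm = 50, seed = 5)
  expect_false(identical(n1, n3))

  # 3 vs 3: choose(6,3) = 20 distinct assignments -> exhaustive enumeration
  st2 <- tiny_study(n_genes = 60, n_per_group = 3, seed = 2)
  expect_message(
    n4 <- phenotype_null(st2$values, st2$annotations, "B", "A", "WM",
                         gene_set_collection(list(S = sprintf("G%03d", 1:12))),
                         n_perm = 1000, seed = 1),
    "20 distinct")
  expect_equal(ncol(n4), 20L)
  expect_identical(attr(n4, "scheme"), "exhaustive")
})

test_that("NES and nominal p follow the same-sign normalization rules", {
  null <- c(0.3, 0.3, 0.3, -0.2, -0.4)
  r <- normalize_scores(0.6, null)
  expect_equal(r$nes, 2.0)
  expect_equal(r$p_nominal, 1 / 6)   # floored at 1/(n_perm+1)
  r0 <- normalize_scores(0, null)
  expect_equal(r0$nes, 0)
  expect_equal(r0$p_nominal, 1)
  # nominal p counts same-sign nulls at least as extreme
  r2 <- normalize_scores(0.25, null)
  expect_equal(r2$p_nominal, 1)
  r3 <- normalize_scores(-0.3, null)
  expect_equal(r3$nes, -0.3 / 0.3)
  expect_equal(r3$p_nominal, 0.5)
  # no same-sign null: sentinel
  r4 <- normalize_scores(-0.5, c(0.1, 0.2))
  expect_identical(r4$nes, -Inf)
  expect_equal(r4$p_nominal, 1 / 3)
  # NES strictly increasing in ES for a fixed null
  es_grid <- seq(0.1, 0.9, by = 0.1)
  nes_grid <- vapply(es_grid, function(e) normalize_scores(e, null)$nes,
                     numeric(1))
  expect_true(all(diff(nes_grid) > 0))
})

test_that("FDR q is a clipped pooled-null tail ratio, monotone within sign", {
  # single set beyond every pooled null value -> q = 0
  expect_equal(fdr_q(3, matrix(c(0.5, 1, -1, 0.2), 1)), 0)
  # observed at the null median with half the observed beyond it -> near 1
  nes_obs <- c(2.5, 1.0)
  nes_null <- matrix(rep(c(0.5, 1.0, 1.5, 2.0), 2), nrow = 2, byrow = TRUE)
  q <- fdr_q(nes_obs, nes_null)
  expect_true(q[2] >= 0.5)
  expect_true(all(q >= 0 & q <= 1))
  # monotone: larger |NES| never has larger q (both signs)
  withr::with_seed(31, {
    for (rep in 1:10) {
      obs <- rnorm(30)
      nll <- matrix(rnorm(30 * 50), 30)
      q <- fdr_q(obs, nll)
      for (sgn in c(1, -1)) {
        idx <- if (sgn > 0) which(obs >= 0) else which(obs < 0)
        o <- order(abs(obs[idx]))
        expect_true(all(diff(q[idx][o]) <= 1e-12))
      }
    }
  })
})

test_that("run_gsea recovers an injected set and is reproducible", {
  cfg <- sim_config(n_genes = 800, n_sets = 20, set_size = 40,
                    n_per_cell = 10, regions = "WM",
                    injections = data.frame(set = "SET_003", group = "B",
                                            region = "WM", delta = 2,
                                            direction = 1),
                    seed = 77)
  sim <- generate_dataset(cfg)
  expr <- collapse_probes_by_cv(sim$values, sim$probe_map)
  g1 <- run_gsea(expr, sim$annotations, "B", "A", "WM", sim$collection,
                 n_perm = 200, seed = 5)
  expect_identical(g1$results$set[1], "SET_003")
  expect_lt(g1$results$fdr_q[1], 0.01)
  expect_true(all(sign(g1$results$nes) == sign(g1$results$es) |
                    g1$results$es == 0))
  g2 <- run_gsea(expr, sim$annotations, "B", "A", "WM", sim$collection,
                 n_perm = 200, seed = 5)
  expect_identical(g1$results, g2$results)
  # empty collection after filtering warns and returns no rows
  tiny_coll <- gene_set_collection(list(S = c("NOT_THERE_1", "NOT_THERE_2")))
  expect_warning(g3 <- run_gsea(expr, sim$annotations, "B", "A", "WM",
                                tiny_coll, n_perm = 10, seed = 1),
                 "no gene set")
  expect_equal(nrow(g3$results), 0L)
})

test_that("stronger injections never weaken the mean NES of the injected set", {
  deltas <- c(0, 0.5, 1, 2)
  mean_nes <- vapply(deltas, function(d) {
    nes <- vapply(1:5, function(s) {
      cfg <- sim_config(n_genes = 400, n_sets = 8, set_size = 30,
                        n_per_cell = 8, regions = "WM",
                        injections = if (d > 0)
                          data.frame(set = "SET_001", group = "B",
                                     region = "WM", delta = d, direction = 1)
                        else NULL,
                        seed = 1000 + s)
      sim <- generate_dataset(cfg)
      expr <- collapse_probes_by_cv(sim$values, sim$probe_map)
      g <- run_gsea(expr, sim$annotations, "B", "A", "WM", sim$collection,
                    n_perm = 100, seed = s)
      g$results$nes[g$results$set == "SET_001"]
    }, numeric(1))
    mean(abs(nes))
  }, numeric(1))
  expect_true(all(diff(mean_nes) > -0.1))
  expect_gt(mean_nes[4], mean_nes[1])
})

test_that("GSEA results export as TSV with comma-joined leading edges", {
  st <- tiny_study(n_genes = 100, n_per_group = 5, seed = 12)
  coll <- gene_set_collection(list(S1 = sprintf("G%03d", 1:15),
                                   S2 = sprintf("G%03d", 30:45)))
  g <- run_gsea(st$values, st$annotations, "B", "A", "WM", coll,
                n_perm = 50, seed = 3)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_gsea_tsv(g, tf)
  back <- utils::read.delim(tf)
  expect_identical(names(back),
                   c("set", "size", "ES", "NES", "p_nominal", "FDR_q",
                     "leading_edge"))
  expect_identical(back$set, g$results$set)
  expect_identical(strsplit(back$leading_edge[1], ",")[[1]],
                   g$results$leading_edge[[1]])
})
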