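# build a minimal `gsea` object from a q/NES table for rule testing
fake_gsea <- function(sets, nes, q, region, leading_edge = NULL,
                      test_group = "B", ref_group = "A") {
  res <- data.frame(set = sets, size = 20L, es = sign(nes) * 0.5, nes = nes,
                    p_nominal = pmin(1, q + 1e-4), fdr_q = q,
                    stringsAsFactors = FALSE)
  res$leading_edge <- if (is.null(leading_edge))
    replicate(length(sets), character(0), simplify = FALSE) else leading_edge
  structure(list(results = res,
                 contrast = list(test_group = test_group,
                                 ref_group = ref_group, region = region),
                 params = list(), scheme = "sampled"),
            class = "gsea")
}

regions3 <- function(q_wm, q_fc, q_bg, nes_wm, nes_fc, nes_bg, sets, ...) {
  list(WM = fake_gsea(sets, nes_wm, q_wm, "WM", ...),
       FC = fake_gsea(sets, nes_fc, q_fc, "FC", ...),
       BG = fake_gsea(sets, nes_bg, q_bg, "BG", ...))
}

test_that("common calls need >=2 significant regions with concordant sign", {
  rr <- regions3(q_wm = c(0.005, 0.005, 0.005),
                 q_fc = c(0.004, 0.004, 0.02),
                 q_bg = c(0.5, 0.5, 0.5),
                 nes_wm = c(2.1, 2.1, 2.1),
                 nes_fc = c(1.9, -1.9, 1.9),
                 nes_bg = c(1.1, 1.1, 1.1),
                 sets = c("CONC", "DISC", "ONEREG"))
  cc <- common_pathways(rr)
  expect_identical(cc$set, "CONC")          # DISC discordant, ONEREG 1 region
  expect_identical(cc$direction, 1)
  cc2 <- common_pathways(rr, require_concordance = FALSE)
  expect_setequal(cc2$set, c("CONC", "DISC"))
})

test_that("threshold boundaries are strict for common and specific calls", {
  rr <- regions3(q_wm = c(0.01, 0.005, 0.005),
                 q_fc = c(0.005, 0.25, 0.3),
                 q_bg = c(0.005, 0.3, 0.26),
                 nes_wm = c(2, 2, 2), nes_fc = c(2, 1, 1),
                 nes_bg = c(2, 1, 1),
                 sets = c("ATQ01", "ATQ25", "SPEC"))
  # q exactly 0.01 does not count as significant
  cc <- common_pathways(rr)
  expect_setequal(cc$set, "ATQ01")          # FC+BG significant; WM at 0.01 excluded
  sp <- region_specific_pathways(rr)
  # ATQ25: q = 0.25 in FC is not > 0.25, so not specific_WM
  expect_false("ATQ25" %in% sp$set)
  expect_identical(sp$set, "SPEC")
  expect_identical(sp$category, "specific_WM")
})

test_that("two significant regions preclude region specificity", {
  rr <- regions3(q_wm = 0.005, q_fc = 0.004, q_bg = 0.9,
                 nes_wm = 2, nes_fc = 2, nes_bg = 1, sets = "S")
  expect_identical(nrow(region_specific_pathways(rr)), 0L)
  expect_error(region_specific_pathways(rr[c("WM", "FC")]), "BG")
})

test_that("common and specific calls are disjoint over random tables", {
  withr::with_seed(41, {
    for (rep in 1:30) {
      n <- 40
      sets <- sprintf("S%02d", 1:n)
      rr <- regions3(q_wm = runif(n), q_fc = runif(n), q_bg = runif(n),
                     nes_wm = rnorm(n, sd = 2), nes_fc = rnorm(n, sd = 2),
                     nes_bg = rnorm(n, sd = 2), sets = sets)
      cc <- common_pathways(rr, require_concordance = FALSE)
      sp <- region_specific_pathways(rr)
      expect_length(intersect(cc$set, sp$set), 0L)
      # lowering the threshold never adds common calls
      cc_lo <- common_pathways(rr, fdr_threshold = 0.005,
                               require_concordance = FALSE)
      expect_true(all(cc_lo$set %in% cc$set))
    }
  })
})

test_that("leading-edge gene table unions genes and applies the Welch filter", {
  st <- tiny_study(n_genes = 100, n_per_group = 6, seed = 33)
  # three regions sharing the same samples is fine for rule testing: build
  # annotations spanning WM/FC/BG with a strong effect on G001/G002 in WM
  ann <- do.call(rbind, lapply(c("WM", "FC", "BG"), function(r) {
    a <- st$annotations
    a$region <- r
    a$sample_id <- paste0(a$sample_id, "_", r)
    a
  }))
  vals <- cbind(st$values, st$values, st$values)
  colnames(vals) <- ann$sample_id
  up <- ann$group == "B" & ann$region == "WM"
  vals["G001", up] <- vals["G001", up] + 6
  vals["G002", up] <- vals["G002", up] + 6

  rr <- regions3(q_wm = c(0.001, 0.002), q_fc = c(0.005, 0.5),
                 q_bg = c(0.9, 0.9),
                 nes_wm = c(2, 2), nes_fc = c(2, 1), nes_bg = c(1, 1),
                 sets = c("P1", "P2"),
                 leading_edge = list(c("G001", "G002"), c("G002", "G050")))
  # P1 is common (WM+FC concordant); P2 qualifies only in WM -> specific_WM
  calls <- rbind(common_pathways(rr), region_specific_pathways(rr))
  expect_setequal(calls$set, c("P1", "P2"))
  tab <- leading_edge_gene_table(calls, rr, vals, ann, "B", "A")
  # G002 contributed by both pathways, listed once with both sources
  expect_identical(sum(tab$gene == "G002"), 1L)
  expect_match(tab$pathways[tab$gene == "G002"], "P1,P2")
  expect_true(all(tab$best_p < 0.01))
  # p_cut = 1 keeps every leading-edge gene of qualifying pathways
  tab_all <- leading_edge_gene_table(calls, rr, vals, ann, "B", "A",
                                     p_cut = 1.0)
  expect_setequal(tab_all$gene, c("G001", "G002", "G050"))
  expect_error(leading_edge_gene_table(calls[0, ], rr, vals, ann, "B", "A"),
               "empty")
})

test_that("injected genes dominate the leading-edge table on synthetic data", {
  cfg <- sim_config(n_genes = 600, n_sets = 12, set_size = 30, n_per_cell = 8,
                    injections = data.frame(set = "SET_001",
                                            group = rep("B", 3),
                                            region = c("WM", "FC", "BG"),
                                            delta = 1.5, direction = 1),
                    seed = 55)
  sim <- generate_dataset(cfg)
  expr <- collapse_probes_by_cv(sim$values, sim$probe_map)
  rr <- lapply(c(WM = "WM", FC = "FC", BG = "BG"), function(r)
    run_gsea(expr, sim$annotations, "B", "A", r, sim$collection,
             n_perm = 200, seed = 2))
  calls <- common_pathways(rr)
  expect_true("SET_001" %in% calls$set)
  tab <- leading_edge_gene_table(calls, rr, expr, sim$annotations, "B", "A")
  injected_genes <- sim$collection$sets$SET_001
  expect_gt(mean(tab$gene %in% injected_genes), 0.8)
})
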