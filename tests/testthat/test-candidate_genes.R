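test_that("MAST selection counts elementary stress classes with D+H expansion", {
  mq <- make_anchored_mqtls()
  mq$stress_tally <- c("AS:1;DS:3;HS:2;SS:4;WS:1;PHS:2", "DS:2;HS:2;PHS:1;SS:1")
  mq$n_stress_classes <- c(6L, 4L)
  mq$n_qtls <- c(13L, 9L)
  got <- select_mast_mqtls(mq, min_stress_classes = 5)
  expect_equal(got$mqtl, "MQTL1A.1")
  # a D+H-only MQTL covers exactly the two classes it expands to
  expect_equal(length(unique(expand_stress(c("D+H", "D+H")))), 2)
  # member-count floor applies too
  expect_equal(nrow(select_mast_mqtls(mq, min_stress_classes = 4, min_qtls = 10)), 1)
})

test_that("gene windows follow the 2 Mb direct / peak +/- 1 Mb rule", {
  mq <- make_anchored_mqtls()[1, ]
  # CI width 1 Mb + 1 -> mined whole
  w1 <- gene_window(mq)
  expect_equal(w1$window_rule, "whole_ci")
  expect_equal(c(w1$window_start_bp, w1$window_end_bp), c(mq$start_bp, mq$end_bp))
  # wide CI -> 1 Mb either side of the peak
  mq2 <- mq; mq2$start_bp <- 5e6; mq2$end_bp <- 55e6; mq2$peak_bp <- 30e6
  w2 <- gene_window(mq2)
  expect_equal(w2$window_rule, "peak_flank")
  expect_equal(c(w2$window_start_bp, w2$window_end_bp), c(29e6, 31e6))
  # clipping at the chromosome start
  mq3 <- mq2; mq3$peak_bp <- 0.4e6
  w3 <- gene_window(mq3)
  expect_equal(w3$window_start_bp, 1)
  # window width never exceeds max(CI width, 2 Mb)
  expect_lte(w2$window_end_bp - w2$window_start_bp, 2e6)
})

test_that("gene mining uses any-overlap and de-duplicates", {
  windows <- tibble::tibble(mqtl = "MQTL1A.1", chromosome = "1A",
                            window_start_bp = 10e6, window_end_bp = 12e6,
                            window_rule = "whole_ci")
  ann <- tibble::tibble(
    gene_id = c("in", "straddle", "out"),
    chromosome = "1A",
    start_bp = c(10.5e6, 11.9e6, 13e6),
    end_bp = c(10.6e6, 12.4e6, 13.1e6),
    strand = "+", description = "")
  got <- mine_genes(windows, ann)
  expect_setequal(got$gene_id, c("in", "straddle"))
  expect_equal(nrow(mine_genes(windows, ann[0, ])), 0)
})

test_that("DEG calls apply the two-fold log2 threshold per condition", {
  samples <- tibble::tibble(sample = c("c1", "c2", "s1", "s2"),
                            condition = c("control", "control", "t1", "t1"),
                            control = c(TRUE, TRUE, FALSE, FALSE))
  expr <- rbind(gA = c(1, 1, 3, 3),      # log2FC exactly 2 -> up
                gB = c(2, 2, 2.58, 2.58),# log2FC 0.58 (FC 1.5) -> no call
                gC = c(4, 4, 2.9, 2.9))  # log2FC -1.1 -> down
  colnames(expr) <- samples$sample
  calls <- call_degs(c("gA", "gB", "gC", "missing"), expr, samples, "d1")
  expect_equal(calls$gene_id, c("gA", "gC"))
  expect_equal(calls$direction, c("up", "down"))
  expect_equal(calls$log2fc[1], 2)
  expect_true(all(abs(calls$log2fc) >= 1))
  expect_equal(attr(calls, "skipped"), "missing")
})

test_that("raw TPM with a zero control uses the documented pseudocount", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene_id = "g", c1 = 0, s1 = 4), path)
  expr <- read_expression_matrix(path, log2 = FALSE, pseudo = 0.01)
  samples <- tibble::tibble(sample = c("c1", "s1"),
                            condition = c("control", "t1"),
                            control = c(TRUE, FALSE))
  calls <- call_degs("g", expr, samples, "d1")
  expect_equal(calls$log2fc, log2(4.01) - log2(0.01), tolerance = 1e-12)
  expect_equal(calls$direction, "up")
})

test_that("candidate ranking tiers genes by dataset support", {
  calls <- dplyr::bind_rows(
    tibble::tibble(gene_id = "g4", dataset_id = paste0("d", 1:4),
                   condition = "t1", log2fc = 2, direction = "up"),
    tibble::tibble(gene_id = "g3", dataset_id = paste0("d", 1:3),
                   condition = "t1", log2fc = c(1.5, -1.2, 1.1),
                   direction = c("up", "down", "up")),
    tibble::tibble(gene_id = "g1", dataset_id = "d2",
                   condition = "t1", log2fc = 5, direction = "up"))
  got <- rank_candidates(calls, min_datasets = 3)
  expect_equal(got$gene_id[1], "g4")            # top tier: all four datasets
  expect_equal(got$promising, c(TRUE, TRUE, FALSE))
  expect_equal(got$direction_summary, c("up", "mixed", "up"))
  # invariant to dataset/row order
  got2 <- rank_candidates(calls[sample.int(nrow(calls)), ], min_datasets = 3)
  expect_equal(got2, got)
})

test_that("planted promising genes are recovered exactly from the generator", {
  sc <- simulate_scenario(seed = 23)
  st <- simulate_studies(sc)
  om <- simulate_omics(sc, st$truth)
  genes <- om$truth$planted_genes$gene_id
  calls <- dplyr::bind_rows(lapply(om$expression, function(ds)
    call_degs(genes, ds$expr, ds$samples, ds$dataset_id)))
  got <- rank_candidates(calls, min_datasets = 3)
  expect_setequal(got$gene_id[got$promising], om$truth$promising_genes)
})
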