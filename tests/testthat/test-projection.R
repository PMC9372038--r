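make_common <- function(src, cons, markers = NULL) {
  tibble::tibble(marker = markers %||% paste0("M", seq_along(src)),
                 src = src, cons = cons)
}

test_that("a QTL projects by linear rescaling through its flanking context", {
  common <- make_common(c(10, 20), c(20, 40))
  ctx <- select_projection_context(15, common, c(0, 30))
  expect_equal(ctx$status, "ok")
  expect_equal(ctx$scale, 2)
  pr <- project_qtl(15, 12, 18, ctx, common)
  expect_equal(pr$status, "projected")
  expect_equal(pr$peak_cm, 30)
  expect_equal(pr$ci_start_cm, 24)
  expect_equal(pr$ci_end_cm, 36)
})

test_that("projection onto an identical map is the identity", {
  src <- c(0, 10, 25, 60, 90)
  common <- make_common(src, src)
  ctx <- select_projection_context(30, common, c(0, 90))
  pr <- project_qtl(30, 27, 36, ctx, common)
  expect_equal(pr$peak_cm, 30)
  expect_equal(c(pr$ci_start_cm, pr$ci_end_cm), c(27, 36))
})

test_that("an infeasible nearest pair is skipped for a feasible outward pair", {
  # nearest flanking pair stretches 10x (infeasible at max_ratio 5);
  # the outward pair stretches only 1.2x
  common <- make_common(src = c(0, 4, 6, 16),
                        cons = c(0, 10, 30, 19.2))
  common$cons <- c(0, 10, 30, 19.2)
  # make outward interval consistent: src 0..16 -> cons 0..19.2 (ratio 1.2)
  ctx <- select_projection_context(5, common, c(0, 20),
                                   projection_config(max_ratio = 5))
  expect_equal(ctx$status, "ok")
  expect_equal(c(ctx$left, ctx$right), c("M1", "M4"))
  expect_equal(ctx$scale, 1.2)
})

test_that("rejection reasons are specific", {
  cfg <- projection_config()
  # no common markers at all
  expect_equal(select_projection_context(5, make_common(numeric(0), numeric(0)),
                                         c(0, 10), cfg)$reason,
               "no_common_markers")
  # no common marker on the right of the peak
  common <- make_common(c(1, 2), c(1, 2))
  expect_equal(select_projection_context(5, common, c(0, 10), cfg)$reason,
               "no_common_markers")
  # peak outside the source map span
  expect_equal(select_projection_context(50, common, c(0, 10), cfg)$reason,
               "peak_out_of_map")
  # projected CI too wide
  common2 <- make_common(c(10, 20), c(20, 140))
  cfg2 <- projection_config(max_ratio = 100, max_ci_cm = 50)
  ctx <- select_projection_context(15, common2, c(0, 30), cfg2)
  pr <- project_qtl(15, 12, 18, ctx, common2, cfg2)
  expect_equal(pr$status, "rejected")
  expect_equal(pr$reason, "large_CI")
})

test_that("projection keeps ci_start <= peak <= ci_end and preserves order", {
  set.seed(31)
  for (rep in 1:25) {
    n <- 8
    src <- c(0, sort(runif(n - 2, 1, 99)), 100)
    cons <- cumsum(c(0, diff(src) * runif(n - 1, 0.5, 2)))
    common <- make_common(src, cons)
    peaks <- sort(runif(2, 5, 95))
    cfg <- projection_config(max_ratio = 10, min_p = 1e-9, max_ci_cm = 1000)
    prs <- lapply(peaks, function(p) {
      ctx <- select_projection_context(p, common, c(0, 100), cfg)
      project_qtl(p, p - runif(1, 0, 4), p + runif(1, 0, 4), ctx, common, cfg)
    })
    for (pr in prs) {
      expect_equal(pr$status, "projected")
      expect_lte(pr$ci_start_cm, pr$peak_cm)
      expect_gte(pr$ci_end_cm, pr$peak_cm)
    }
    expect_lte(prs[[1]]$peak_cm, prs[[2]]$peak_cm) # monotone in peak
  }
})

test_that("the batch driver accounts for every record", {
  qtls <- make_qtls(10)
  qtls$peak_cm[1:2] <- NA                  # incomplete after failed imputation
  qtls$chromosome[3] <- "2B"               # no map on 2B -> no source map
  maps <- make_map("S1", len = 100, by = 10)
  maps <- dplyr::bind_rows(maps, dplyr::mutate(maps, map_id = "S2"))
  cmap <- build_consensus(make_map("ref", len = 100, by = 10))
  q <- estimate_ci(impute_defaults(validate_qtls(qtls), maps))
  pr <- project_qtls(q, maps, cmap)
  rep <- projection_report(pr)
  expect_equal(rep$total, 10)
  expect_equal(nrow(pr), 10)
  expect_equal(rep$projected + sum(rep$reasons$n), 10)
  expect_true("incomplete" %in% rep$reasons$reason)
  expect_true("no_source_map" %in% rep$reasons$reason)
  # empty input gives an empty, zeroed report
  pr0 <- project_qtls(q[0, ], maps, cmap)
  expect_equal(projection_report(pr0)$total, 0)
  expect_equal(nrow(pr0), 0)
})

test_that("a generator scenario with all markers shared projects everything", {
  sc <- simulate_scenario(seed = 5, anchor_fraction = 1, map_jitter_sd = 0,
                          study_scale_range = c(1, 1), ref_jitter_sd = 0,
                          missing_lod = 0, missing_pve = 0, missing_ci = 0,
                          missing_peak = 0, unusable_fraction = 0,
                          n_studies = 3, n_qtls_per_study = 10)
  st <- simulate_studies(sc)
  cmap <- build_consensus(st$reference_maps)
  q <- estimate_ci(impute_defaults(validate_qtls(st$qtls), st$study_maps))
  pr <- project_qtls(q, st$study_maps, cmap)
  expect_equal(projection_report(pr)$projected, 30)
})
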