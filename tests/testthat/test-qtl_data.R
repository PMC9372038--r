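test_that("a well-formed table reads with no rejects and round-trips exactly", {
  qtls <- make_qtls(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_qtl_table(qtls, path)
  got <- read_qtl_table(path)
  expect_equal(nrow(got), 3)
  expect_equal(nrow(rejects(got)), 0)
  # bit-for-bit round trip of every canonical field
  expect_equal(tibble::as_tibble(lapply(got[names(qtls)], c)), qtls)
  # csv dialect
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(qtls, path2)
  expect_equal(nrow(read_qtl_table(path2)), 3)
})

test_that("invalid rows are rejected with a named reason, never dropped silently", {
  qtls <- make_qtls(5)
  qtls$chromosome[1] <- "8A"
  qtls$ci_start_cm[2] <- 50; qtls$ci_end_cm[2] <- 40
  qtls$stress[3] <- "XX"
  got <- validate_qtls(qtls)
  rej <- rejects(got)
  expect_equal(nrow(got) + nrow(rej), 5)
  expect_setequal(rej$reason,
                  c("unknown chromosome", "inverted CI", "invalid stress"))
})

test_that("missing mandatory columns are a hard error naming the column", {
  qtls <- make_qtls(2)
  expect_error(validate_qtls(qtls[, setdiff(names(qtls), "chromosome")]),
               "chromosome")
  expect_error(validate_qtls(qtls[, setdiff(names(qtls), "left_marker")]),
               "left_marker")
})

test_that("stress and chromosome synonyms are normalised", {
  qtls <- make_qtls(3)
  qtls$stress <- c("AL", "d + h", "ds")
  qtls$chromosome <- c("chr1A", "1a", "1A")
  got <- validate_qtls(qtls)
  expect_equal(nrow(rejects(got)), 0)
  expect_equal(got$stress, c("AS", "D+H", "DS"))
  expect_equal(unique(got$chromosome), "1A")
  expect_setequal(expand_stress("D+H"), c("DS", "HS"))
})

test_that("imputation fills LOD 3 / PVE 10 and flank-midpoint peaks", {
  qtls <- make_qtls(3)
  qtls$lod[1] <- NA; qtls$pve[1] <- NA
  qtls$peak_cm[2] <- NA
  maps <- tibble::tibble(map_id = "S2", chromosome = "1A",
                         marker = c("L2", "R2"), pos_cm = c(10, 20))
  got <- impute_defaults(validate_qtls(qtls), maps)
  expect_equal(got$lod[1], 3.0)
  expect_equal(got$pve[1], 10)
  expect_true(got$imputed_lod[1] && got$imputed_pve[1])
  expect_equal(got$peak_cm[2], 15)           # midpoint of flanks at 10 and 20
  expect_false(got$unprojectable[2])
  # untouched record stays untouched
  expect_equal(got$lod[3], 4.5)
  expect_equal(got$pve[3], 12)
})

test_that("a missing peak with an unresolvable flank flags the record unprojectable", {
  qtls <- make_qtls(1)
  qtls$peak_cm <- NA
  maps <- tibble::tibble(map_id = "S1", chromosome = "1A",
                         marker = "L1", pos_cm = 5) # right flank absent
  got <- impute_defaults(validate_qtls(qtls), maps)
  expect_true(got$unprojectable[1])
})

test_that("CI estimation follows k / (N * R2) centred on the peak", {
  qtls <- make_qtls(3)
  qtls$ci_start_cm <- NA; qtls$ci_end_cm <- NA
  qtls$population_type <- c("RIL", "F2", "RIL")
  qtls$population_size <- c(163L, 530L, 163L)
  qtls$pve <- 10
  got <- estimate_ci(validate_qtls(qtls))
  # RIL: 163 / (163 * 0.10) = 10 cM; F2: 530 / (530 * 0.10) = 10 cM
  expect_equal(got$ci_end_cm - got$ci_start_cm, c(10, 10, 10))
  expect_equal(got$ci_start_cm[1], got$peak_cm[1] - 5)
  expect_true(all(got$ci_estimated))
  # left edge floored at zero
  qtls2 <- make_qtls(1)
  qtls2$peak_cm <- 2; qtls2$ci_start_cm <- NA; qtls2$ci_end_cm <- NA
  qtls2$pve <- 10
  got2 <- estimate_ci(validate_qtls(qtls2))
  expect_equal(got2$ci_start_cm, 0)
})

test_that("records with an original CI are left untouched by estimate_ci", {
  qtls <- make_qtls(2)
  got <- estimate_ci(validate_qtls(qtls))
  expect_equal(got$ci_start_cm, qtls$ci_start_cm)
  expect_false(any(got$ci_estimated))
})

test_that("estimated CI width decreases strictly in N and in PVE", {
  width <- function(n, pve) {
    q <- make_qtls(1)
    q$population_size <- n; q$pve <- pve
    q$ci_start_cm <- NA; q$ci_end_cm <- NA; q$peak_cm <- 80
    got <- estimate_ci(validate_qtls(q))
    got$ci_end_cm - got$ci_start_cm
  }
  ns <- c(50L, 100L, 200L, 400L)
  expect_true(all(diff(vapply(ns, width, numeric(1), pve = 10)) < 0))
  pves <- c(5, 10, 20, 40)
  expect_true(all(diff(vapply(pves, function(p) width(150L, p), numeric(1))) < 0))
})

test_that("after imputation and CI estimation every usable record is complete", {
  sc <- simulate_scenario(seed = 11)
  st <- simulate_studies(sc)
  q <- estimate_ci(impute_defaults(validate_qtls(st$qtls), st$study_maps))
  ok <- !q$unprojectable
  expect_true(all(!is.na(q$peak_cm[ok])))
  expect_true(all(!is.na(q$ci_start_cm[ok])))
  expect_true(all(!is.na(q$lod)) && all(!is.na(q$pve)))
})
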