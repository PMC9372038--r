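test_that("a single map comes back unchanged, shifted to start at zero", {
  map <- make_map("a", positions = c(3, 10, 50, 80))
  cons <- build_consensus(map)
  expect_equal(cons$pos_cm, c(0, 7, 47, 77))
  expect_equal(cons$marker, map$marker)
})

test_that("two maps merge by anchor averaging with interpolation of the rest", {
  a <- tibble::tibble(map_id = "A", chromosome = "1A",
                      marker = c("M1", "X", "M2"), pos_cm = c(0, 50, 100))
  b <- tibble::tibble(map_id = "B", chromosome = "1A",
                      marker = c("M1", "Y", "M2"), pos_cm = c(0, 25, 50))
  cons <- build_consensus(list(a, b), weights = c(A = 1, B = 1))
  pos <- function(m) cons$pos_cm[cons$marker == m]
  expect_equal(pos("M1"), 0)
  expect_equal(pos("M2"), 75)     # mean of 100 and 50
  expect_equal(pos("X"), 37.5)    # halfway between anchors on map A
  expect_equal(pos("Y"), 37.5)    # halfway between anchors on map B
})

test_that("merging two identical maps is idempotent", {
  a <- make_map("a", positions = c(0, 10, 30, 60))
  b <- a; b$map_id <- "b"
  cons <- build_consensus(list(a, b))
  expect_equal(cons$pos_cm, a$pos_cm)
  expect_equal(cons$marker, a$marker)
  expect_true(all(cons$anchor))
})

test_that("merging is invariant to map listing order under equal weights", {
  set.seed(42)
  base <- sort(runif(12, 0, 100))
  a <- make_map("a", positions = base, markers = paste0("M", 1:12))
  b <- make_map("b", positions = base * 1.2 + rnorm(12, 0, 0.5),
                markers = paste0("M", 1:12))
  b$pos_cm <- sort(b$pos_cm)
  w <- c(a = 1, b = 1)
  c1 <- build_consensus(list(a, b), weights = w)
  c2 <- build_consensus(list(b, a), weights = w)
  expect_equal(dplyr::arrange(tibble::as_tibble(c1), marker)$pos_cm,
               dplyr::arrange(tibble::as_tibble(c2), marker)$pos_cm)
})

test_that("maps sharing fewer than two anchors are reported unplaced, not guessed", {
  a <- make_map("a", positions = c(0, 50, 100), markers = c("A1", "S", "A3"))
  b <- make_map("b", positions = c(0, 20, 40), markers = c("B1", "S", "B3"))
  cons <- build_consensus(list(a, b))
  unpl <- attr(cons, "unplaced")
  expect_setequal(unpl$marker, c("B1", "B3"))
  expect_equal(unique(unpl$reason), "unanchored")
  expect_false(any(c("B1", "B3") %in% cons$marker))
})

test_that("anchor order shared by all source maps is preserved", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 10
    base <- sort(runif(n, 0, 100))
    mk <- paste0("M", seq_len(n))
    a <- make_map("a", positions = base, markers = mk)
    jit <- sort(base * runif(1, 0.8, 1.2) + rnorm(n, 0, 0.2))
    b <- make_map("b", positions = jit, markers = mk)
    cons <- build_consensus(list(a, b))
    got <- cons$marker[order(cons$pos_cm)]
    expect_equal(got, mk)
  }
})

test_that("consensus chromosome length lies within the rescaled source lengths", {
  set.seed(99)
  for (rep in 1:10) {
    n <- 8
    base <- c(0, sort(runif(n - 2, 0, 100)), 100)
    mk <- paste0("M", seq_len(n))
    scale <- runif(1, 0.5, 2)
    a <- make_map("a", positions = base, markers = mk)
    b <- make_map("b", positions = base * scale, markers = mk)
    cons <- build_consensus(list(a, b))
    len <- max(cons$pos_cm)
    expect_gte(len, min(100, 100 * scale) - 1e-9)
    expect_lte(len, max(100, 100 * scale) + 1e-9)
  }
})

test_that("marker lookup is exact and case-sensitive unless folding is enabled", {
  map <- make_map("a", positions = c(0, 10), markers = c("Xgwm635", "M2"))
  cons <- build_consensus(map)
  expect_equal(marker_lookup(cons, "Xgwm635")$pos_cm, 0)
  expect_equal(nrow(marker_lookup(cons, "xGWM635")), 0)
  expect_equal(marker_lookup(cons, "xGWM635", case_fold = TRUE)$pos_cm, 0)
  expect_equal(nrow(marker_lookup(cons, "absent")), 0)
})

test_that("augment_consensus injects missing markers by interpolation", {
  cons <- build_consensus(make_map("a", positions = c(0, 10, 20),
                                   markers = c("A", "B", "C")))
  extra <- tibble::tibble(map_id = "s", chromosome = "1A",
                          marker = c("A", "C", "new"), pos_cm = c(0, 40, 10))
  aug <- augment_consensus(cons, extra)
  # "new" sits a quarter of the way from A to C on the study map
  expect_equal(aug$pos_cm[aug$marker == "new"], 5)
  expect_match(aug$maps[aug$marker == "new"], "injected:s")
})
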