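toy_genome <- function() {
  set.seed(77)
  Biostrings::DNAStringSet(c(
    chr1 = paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE), collapse = "")))
}

test_that("plus-strand promoters are the 1500 bp before the gene start", {
  genome <- toy_genome()
  genes <- tibble::tibble(gene_id = "g1", chromosome = "chr1",
                          start_bp = 10001, end_bp = 12000, strand = "+")
  got <- extract_promoters(genes, genome)
  expect_equal(got$length, 1500)
  expect_false(got$truncated)
  expect_equal(got$sequence,
               as.character(Biostrings::subseq(genome[["chr1"]], 8501, 10000)))
})

test_that("minus-strand promoters are the reverse complement downstream of the end", {
  genome <- toy_genome()
  genes <- tibble::tibble(gene_id = "g1", chromosome = "chr1",
                          start_bp = 3000, end_bp = 5000, strand = "-")
  got <- extract_promoters(genes, genome)
  expect_equal(got$sequence,
               as.character(Biostrings::reverseComplement(
                 Biostrings::subseq(genome[["chr1"]], 5001, 6500))))
})

test_that("promoters truncate at chromosome ends and absent chromosomes skip", {
  genome <- toy_genome()
  genes <- tibble::tibble(gene_id = c("g1", "g2"),
                          chromosome = c("chr1", "chrX"),
                          start_bp = c(800, 100), end_bp = c(2000, 300),
                          strand = "+")
  got <- extract_promoters(genes, genome)
  expect_equal(nrow(got), 1)
  expect_equal(got$length, 799)
  expect_true(got$truncated)
  expect_equal(attr(got, "skipped"), "g2")
})

test_that("motif scanning finds planted and IUPAC-degenerate matches, sense only", {
  motifs <- tibble::tibble(name = c("ABRE", "TGACG-motif", "Ebox"),
                           pattern = c("ACGTG", "TGACG", "CANNTG"),
                           category = c("phytohormone_responsiveness",
                                        "phytohormone_responsiveness",
                                        "growth_development"))
  base <- strrep("T", 1500)
  seq1 <- base
  substr(seq1, 700, 704) <- "ACGTG"
  substr(seq1, 100, 105) <- "CATATG"   # matches CANNTG via N wildcards
  hits <- scan_motifs(c(g1 = seq1), motifs)
  expect_equal(hits$start[hits$motif == "ABRE"], 700)
  expect_equal(hits$offset_atg[hits$motif == "ABRE"], 700 - 1501)
  expect_equal(hits$match[hits$motif == "Ebox"], "CATATG")
  expect_false("TGACG-motif" %in% hits$motif)
  # sense-strand only: the reverse complement of ABRE is not a hit
  seq2 <- base; substr(seq2, 300, 304) <- "CACGT" # revcomp of ACGTG
  hits2 <- scan_motifs(c(g2 = seq2), motifs[1, ])
  expect_equal(nrow(hits2), 0)
})

test_that("hits are confined to the scanned window", {
  motifs <- tibble::tibble(name = "ABRE", pattern = "ACGTG",
                           category = "phytohormone_responsiveness")
  prom <- strrep("T", 1000)
  substr(prom, 500, 504) <- "ACGTG"
  h1 <- scan_motifs(c(g = prom), motifs)
  h2 <- scan_motifs(c(g = paste0(prom, "ACGTGACGTG")), motifs)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$start, h2$start[h2$start <= 1000])
})

test_that("category tallies match planted composition", {
  motifs <- cre_motifs()
  expect_true(all(c("ABRE", "MBS", "ARE", "LTR", "STRE", "WUN-motif") %in% motifs$name))
  pick <- motifs[motifs$name %in% c("MBS", "ARE", "ABRE"), ]
  seq <- strrep("T", 600)
  substr(seq, 10, 15) <- "CAACTG"  # MBS
  substr(seq, 100, 105) <- "AAACCA" # ARE
  substr(seq, 200, 204) <- "ACGTG"  # ABRE
  hits <- scan_motifs(c(g = seq), pick)
  cats <- categorize_cres(hits)
  g <- cats$global
  expect_equal(g$n[g$category == "stress_responsiveness"], 2L)
  expect_equal(g$n[g$category == "phytohormone_responsiveness"], 1L)
  expect_equal(g$n[g$category == "uncharacterized"], 0L)
  # empty hits give all-zero category totals
  z <- categorize_cres(scan_motifs(c(g = strrep("T", 100)), pick))
  expect_true(all(z$global$n == 0))
})

test_that("generator-planted motifs are all recovered at their offsets", {
  sc <- simulate_scenario(seed = 29)
  st <- simulate_studies(sc)
  om <- simulate_omics(sc, st$truth)
  hits <- scan_motifs(om$promoters, cre_motifs())
  planted <- om$truth$planted_motifs
  found <- dplyr::semi_join(planted, hits,
                            by = c("gene_id", "motif", "start"))
  expect_equal(nrow(found), nrow(planted))
})
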