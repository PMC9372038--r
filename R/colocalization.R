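#' Read a GWAS marker-trait association (MTA) table
#'
#' @param path TSV with columns `marker`, `chromosome`, `bp`, `stress`,
#'   `study_id`.
#' @return Tibble with normalised chromosome and stress labels.
#' @export
read_mta_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  tibble::tibble(marker = as.character(df$marker),
                 chromosome = normalize_chromosome(df$chromosome),
                 bp = as.numeric(df$bp),
                 stress = normalize_stress(as.character(df$stress)),
                 study_id = as.character(df$study_id %||% NA))
}

mqtl_granges <- function(mqtls, window_bp = 0) {
  anc <- mqtls[!is.na(mqtls$start_bp), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = anc$chromosome,
    ranges = IRanges::IRanges(start = pmax(1, anc$start_bp - window_bp),
                              end = anc$end_bp + window_bp))
  names(gr) <- anc$mqtl
  gr
}

#' Overlap MQTLs with GWAS marker-trait associations
#'
#' Counts, for each physically anchored MQTL, the MTAs whose position falls
#' inside the MQTL's physical interval (closed interval on 1-based
#' coordinates, so an MTA exactly at an interval bound counts). An MQTL
#' overlapping at least one MTA is GWAS-validated. An optional symmetric
#' window can widen the intervals (off by default: exact containment).
#'
#' @param mqtls Anchored MQTL tibble ([anchor_mqtls()]).
#' @param mtas MTA tibble ([read_mta_table()]).
#' @param window_bp Widen each MQTL interval by this many bp on both sides.
#' @return The MQTL tibble with `n_mtas` and `gwas_validated` columns; the
#'   fraction validated (over anchored MQTLs) is attached as attribute
#'   `"validated_fraction"`.
#' @export
overlap_mtas <- function(mqtls, mtas, window_bp = 0) {
  mqtls <- tibble::as_tibble(mqtls)
  mtas <- tibble::as_tibble(mtas)
  mtas <- mtas[!is.na(mtas$bp), , drop = FALSE]
  gr_m <- mqtl_granges(mqtls, window_bp)
  gr_t <- GenomicRanges::GRanges(seqnames = mtas$chromosome,
                                 ranges = IRanges::IRanges(start = mtas$bp, width = 1))
  hits <- GenomicRanges::countOverlaps(gr_m, gr_t)
  mqtls$n_mtas <- as.integer(hits[match(mqtls$mqtl, names(gr_m))])
  mqtls$n_mtas[is.na(mqtls$n_mtas)] <- 0L
  mqtls$gwas_validated <- !is.na(mqtls$start_bp) & mqtls$n_mtas >= 1
  frac <- if (any(!is.na(mqtls$start_bp))) {
    mean(mqtls$gwas_validated[!is.na(mqtls$start_bp)])
  } else NA_real_
  structure(mqtls, validated_fraction = frac)
}

#' Read a known-gene table
#'
#' @param path TSV with columns `gene`, `chromosome`, `start_bp`, `end_bp`,
#'   `stress`.
#' @return Tibble.
#' @export
read_known_genes <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  tibble::tibble(gene = as.character(df$gene),
                 chromosome = normalize_chromosome(df$chromosome),
                 start_bp = as.numeric(df$start_bp),
                 end_bp = as.numeric(df$end_bp),
                 stress = normalize_stress(as.character(df$stress)))
}

#' Co-localise MQTLs with known stress-tolerance genes
#'
#' Interval-interval overlap with any-shared-bp semantics on 1-based closed
#' coordinates: a gene overlapping an MQTL interval by a single bp is listed.
#'
#' @param mqtls Anchored MQTL tibble.
#' @param genes Known-gene tibble ([read_known_genes()]).
#' @return Tibble with one row per (MQTL, gene) overlap: `mqtl`, `gene`,
#'   `stress`, gene coordinates.
#' @export
overlap_known_genes <- function(mqtls, genes) {
  mqtls <- tibble::as_tibble(mqtls)
  genes <- tibble::as_tibble(genes)
  if (nrow(genes) == 0 || all(is.na(mqtls$start_bp))) {
    return(tibble::tibble(mqtl = character(), gene = character(),
                          stress = character(), start_bp = numeric(),
                          end_bp = numeric()))
  }
  gr_m <- mqtl_granges(mqtls)
  gr_g <- GenomicRanges::GRanges(seqnames = genes$chromosome,
                                 ranges = IRanges::IRanges(start = genes$start_bp,
                                                           end = genes$end_bp))
  ov <- GenomicRanges::findOverlaps(gr_m, gr_g)
  tibble::tibble(
    mqtl = names(gr_m)[S4Vectors::queryHits(ov)],
    gene = genes$gene[S4Vectors::subjectHits(ov)],
    stress = genes$stress[S4Vectors::subjectHits(ov)],
    start_bp = genes$start_bp[S4Vectors::subjectHits(ov)],
    end_bp = genes$end_bp[S4Vectors::subjectHits(ov)])
}
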