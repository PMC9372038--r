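#' Bundled cis-regulatory element motif table
#'
#' Loads the motif table shipped with the package (or a user table of the
#' same shape): columns `name`, `pattern` (IUPAC consensus string) and
#' `category` (one of growth_development, stress_responsiveness,
#' phytohormone_responsiveness, core_promoter, uncharacterized). The bundled
#' consensus strings follow the plant CRE literature (ABRE, MBS, ARE, LTR,
#' STRE, WUN-motif and friends); scanning is exact IUPAC-consensus matching,
#' a deterministic offline surrogate for matrix-based web scanners.
#'
#' @param path Optional path to a custom motif TSV.
#' @return Tibble of motif definitions.
#' @export
cre_motifs <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cre_motifs.tsv", package = "mastqtl",
                                mustWork = TRUE)
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  stopifnot(all(c("name", "pattern", "category") %in% names(df)))
  stopifnot(all(nchar(df$pattern) > 0))
  tibble::as_tibble(df)
}

as_dna_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.data.frame(x)) {
    set <- Biostrings::DNAStringSet(x$sequence)
    names(set) <- x$gene_id
    return(set)
  }
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    return(Biostrings::readDNAStringSet(x))
  }
  Biostrings::DNAStringSet(x)
}

#' Extract promoter sequences upstream of the ATG
#'
#' For a plus-strand gene the promoter is the `upstream` bases ending just
#' before the gene start; for a minus-strand gene it is the reverse
#' complement of the `upstream` bases starting just after the gene end. In
#' both cases the returned sequence reads 5' to 3' towards the translational
#' start. Promoters running off a chromosome end are truncated and flagged.
#' Genes on chromosomes absent from the genome are skipped (attribute
#' `"skipped"`).
#'
#' @param genes Gene-model tibble (`gene_id`, `chromosome`, `start_bp`,
#'   `end_bp`, `strand`).
#' @param genome A `DNAStringSet` (names = chromosomes), FASTA path, or named
#'   character vector.
#' @param upstream Promoter length in bp (default 1500).
#' @return Tibble: `gene_id`, `sequence`, `length`, `truncated`.
#' @export
extract_promoters <- function(genes, genome, upstream = 1500) {
  genes <- tibble::as_tibble(genes)
  genome <- as_dna_set(genome)
  keep <- genes$chromosome %in% names(genome)
  skipped <- genes$gene_id[!keep]
  genes <- genes[keep, , drop = FALSE]
  out <- purrr::pmap(genes[, c("gene_id", "chromosome", "start_bp", "end_bp", "strand")],
    function(gene_id, chromosome, start_bp, end_bp, strand) {
      chrom <- genome[[chromosome]]
      if (identical(strand, "-")) {
        from <- end_bp + 1
        to <- min(end_bp + upstream, length(chrom))
        if (from > to) return(NULL)
        seq <- Biostrings::reverseComplement(Biostrings::subseq(chrom, from, to))
      } else {
        from <- max(1, start_bp - upstream)
        to <- start_bp - 1
        if (to < 1 || from > to) return(NULL)
        seq <- Biostrings::subseq(chrom, from, to)
      }
      tibble::tibble(gene_id = gene_id, sequence = as.character(seq),
                     length = length(seq), truncated = length(seq) < upstream)
    })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(gene_id = character(), sequence = character(),
                          length = integer(), truncated = logical())
  }
  structure(res, skipped = skipped)
}

#' Scan promoters for cis-regulatory elements
#'
#' Exact IUPAC-consensus matching on the sense strand only (the promoter as
#' oriented 5' to 3' towards the ATG); overlapping occurrences are all
#' reported. Offsets are reported both 1-based within the promoter and
#' relative to the ATG (`-upstream .. -1`).
#'
#' @param promoters Tibble from [extract_promoters()], a named
#'   `DNAStringSet`, or a named character vector of promoter sequences.
#' @param motifs Motif table ([cre_motifs()]).
#' @return Tibble of hits: `gene_id`, `motif`, `category`, `start` (within
#'   promoter), `offset_atg` (negative; -1 = base before ATG), `match`,
#'   `score` (matched length).
#' @export
scan_motifs <- function(promoters, motifs = cre_motifs()) {
  set <- as_dna_set(promoters)
  hits <- list()
  for (j in seq_len(nrow(motifs))) {
    m <- Biostrings::vmatchPattern(motifs$pattern[j], set, fixed = "subject")
    starts <- IRanges::start(m)
    lens <- lengths(starts)
    if (sum(lens) == 0) next
    gene <- rep(names(set), lens)
    st <- unlist(starts, use.names = FALSE)
    plen <- rep(BiocGenerics::width(set), lens)
    wid <- nchar(motifs$pattern[j])
    matched <- unname(substr(rep(as.character(set), lens), st, st + wid - 1))
    hits[[j]] <- tibble::tibble(
      gene_id = gene, motif = motifs$name[j], category = motifs$category[j],
      start = st, offset_atg = st - plen - 1L, match = matched, score = wid)
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    out <- tibble::tibble(gene_id = character(), motif = character(),
                          category = character(), start = integer(),
                          offset_atg = integer(), match = character(),
                          score = integer())
  }
  dplyr::arrange(out, .data$gene_id, .data$start)
}

#' Tally cis-regulatory elements by functional category
#'
#' @param hits Hit tibble from [scan_motifs()].
#' @return List of two tibbles: `per_gene` (gene x category counts) and
#'   `global` (category totals, zero-filled over the five categories).
#' @export
categorize_cres <- function(hits) {
  categories <- c("growth_development", "stress_responsiveness",
                  "phytohormone_responsiveness", "core_promoter",
                  "uncharacterized")
  hits <- tibble::as_tibble(hits)
  per_gene <- hits %>%
    dplyr::count(.data$gene_id, .data$category, name = "n")
  global <- tibble::tibble(category = categories) %>%
    dplyr::left_join(dplyr::count(hits, .data$category, name = "n"),
                     by = "category") %>%
    dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  list(per_gene = per_gene, global = global)
}
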