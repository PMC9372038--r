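#' Read a gene annotation
#'
#' Accepts either a GFF3 file (gene features are taken from rows whose type
#' is `gene`) or a tabular TSV with columns `gene_id`, `chromosome`,
#' `start_bp`, `end_bp`, `strand` and optionally `description`.
#'
#' @param path Path to a GFF3 (`.gff`/`.gff3`) or TSV file.
#' @return Tibble with the five canonical columns plus `description`.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gff <- utils::read.delim(path, header = FALSE, comment.char = "#",
                             col.names = c("seqid", "source", "type", "start",
                                           "end", "score", "strand", "phase",
                                           "attributes"),
                             stringsAsFactors = FALSE)
    gff <- gff[gff$type == "gene", , drop = FALSE]
    ids <- sub(".*ID=([^;]+).*", "\\1", gff$attributes)
    desc <- ifelse(grepl("description=", gff$attributes),
                   sub(".*description=([^;]+).*", "\\1", gff$attributes), "")
    tibble::tibble(gene_id = ids, chromosome = normalize_chromosome(gff$seqid),
                   start_bp = as.numeric(gff$start), end_bp = as.numeric(gff$end),
                   strand = gff$strand, description = desc)
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    tibble::tibble(gene_id = as.character(df$gene_id),
                   chromosome = normalize_chromosome(df$chromosome),
                   start_bp = as.numeric(df$start_bp),
                   end_bp = as.numeric(df$end_bp),
                   strand = as.character(df$strand %||% "+"),
                   description = as.character(df$description %||% ""))
  }
}

#' Select multiple-abiotic-stress-tolerance (MAST) MQTLs
#'
#' Keeps MQTLs whose member QTLs cover at least `min_stress_classes` of the
#' six elementary stress classes (the combined D+H label counts towards both
#' drought and heat) and that are built from at least `min_qtls` QTLs.
#'
#' @param mqtls MQTL tibble with `n_stress_classes` and `n_qtls`.
#' @param min_stress_classes Minimum stress-class coverage (default 5).
#' @param min_qtls Minimum member-QTL count (default 9).
#' @return The qualifying subset, same columns.
#' @export
select_mast_mqtls <- function(mqtls, min_stress_classes = 5, min_qtls = 9) {
  dplyr::filter(tibble::as_tibble(mqtls),
                .data$n_stress_classes >= min_stress_classes,
                .data$n_qtls >= min_qtls)
}

#' Gene-mining window of an anchored MQTL
#'
#' MQTLs with a physical CI of at most `max_direct_mb` are mined over their
#' whole interval; wider MQTLs are mined over `flank_mb` on either side of
#' the physical peak, clipped to the chromosome.
#'
#' @param mqtls Anchored MQTL tibble.
#' @param max_direct_mb Width cutoff for direct mining (Mb).
#' @param flank_mb Half-window around the peak for wide MQTLs (Mb).
#' @param chrom_lengths Optional named vector of chromosome lengths (bp) used
#'   to clip the right edge.
#' @return Tibble `mqtl`, `chromosome`, `window_start_bp`, `window_end_bp`,
#'   `window_rule` (`"whole_ci"` or `"peak_flank"`).
#' @export
gene_window <- function(mqtls, max_direct_mb = 2, flank_mb = 1,
                        chrom_lengths = NULL) {
  anc <- tibble::as_tibble(mqtls)
  anc <- anc[!is.na(anc$start_bp), , drop = FALSE]
  width <- anc$end_bp - anc$start_bp + 1
  direct <- width <= max_direct_mb * 1e6
  ws <- ifelse(direct, anc$start_bp, pmax(1, anc$peak_bp - flank_mb * 1e6))
  we <- ifelse(direct, anc$end_bp, anc$peak_bp + flank_mb * 1e6)
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[anc$chromosome])
    we <- ifelse(!is.na(lim), pmin(we, lim), we)
  }
  tibble::tibble(mqtl = anc$mqtl, chromosome = anc$chromosome,
                 window_start_bp = ws, window_end_bp = we,
                 window_rule = ifelse(direct, "whole_ci", "peak_flank"))
}

#' Mine gene models inside MQTL windows
#'
#' Any-overlap semantics: genes straddling a window edge are included.
#' Results are de-duplicated by (`mqtl`, `gene_id`).
#'
#' @param windows Tibble from [gene_window()].
#' @param annotation Gene-model tibble ([read_gene_annotation()]).
#' @return Tibble with one row per (mqtl, gene): window id plus gene columns.
#' @export
mine_genes <- function(windows, annotation) {
  windows <- tibble::as_tibble(windows)
  annotation <- tibble::as_tibble(annotation)
  if (nrow(windows) == 0 || nrow(annotation) == 0) {
    return(tibble::tibble(mqtl = character(), gene_id = character(),
                          chromosome = character(), start_bp = numeric(),
                          end_bp = numeric(), strand = character(),
                          description = character()))
  }
  gr_w <- GenomicRanges::GRanges(seqnames = windows$chromosome,
                                 ranges = IRanges::IRanges(start = windows$window_start_bp,
                                                           end = windows$window_end_bp))
  gr_g <- GenomicRanges::GRanges(seqnames = annotation$chromosome,
                                 ranges = IRanges::IRanges(start = annotation$start_bp,
                                                           end = annotation$end_bp))
  ov <- GenomicRanges::findOverlaps(gr_w, gr_g)
  out <- tibble::tibble(
    mqtl = windows$mqtl[S4Vectors::queryHits(ov)],
    gene_id = annotation$gene_id[S4Vectors::subjectHits(ov)],
    chromosome = annotation$chromosome[S4Vectors::subjectHits(ov)],
    start_bp = annotation$start_bp[S4Vectors::subjectHits(ov)],
    end_bp = annotation$end_bp[S4Vectors::subjectHits(ov)],
    strand = annotation$strand[S4Vectors::subjectHits(ov)],
    description = annotation$description[S4Vectors::subjectHits(ov)])
  dplyr::distinct(out, .data$mqtl, .data$gene_id, .keep_all = TRUE)
}

#' Read an expression matrix (genes x samples, TSV)
#'
#' First column `gene_id`; remaining columns one sample each. Values are
#' log2-transformed TPM unless `log2 = FALSE`, in which case raw TPM are
#' log2-transformed after adding `pseudo`.
#'
#' @param path TSV path.
#' @param log2 Are the stored values already log2 TPM?
#' @param pseudo Pseudocount applied before logging raw TPM.
#' @return Numeric matrix with gene ids as row names.
#' @export
read_expression_matrix <- function(path, log2 = TRUE, pseudo = 0.01) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (!log2) m <- base::log2(m + pseudo)
  m
}

#' Call differentially expressed genes by fold change
#'
#' For each stress condition in a dataset, the log2 fold change is the mean
#' log2 TPM of the condition's samples minus the mean of its paired control
#' samples. A gene is called differentially expressed under a condition when
#' `|log2FC| >= log2(min_fc)`, i.e. a two-fold change at the default
#' (interpreting the field's "FC >= 2 or <= -2" convention on log2 data as
#' fold change >= 2 up or >= 2 down).
#'
#' @param genes Character vector of gene ids to test (absent genes are
#'   skipped and reported in attribute `"skipped"`).
#' @param expr Matrix from [read_expression_matrix()] (log2 TPM).
#' @param samples Sample-metadata tibble: `sample` (column name), `condition`,
#'   `control` (logical). Each non-control condition is compared to the
#'   control samples of the dataset.
#' @param dataset_id Label recorded on each call.
#' @param min_fc Fold-change threshold on the natural scale (default 2).
#' @return Tibble of calls: `gene_id`, `dataset_id`, `condition`, `log2fc`,
#'   `direction` (`up`/`down`). Only calls passing the threshold appear.
#' @export
call_degs <- function(genes, expr, samples, dataset_id = "dataset", min_fc = 2) {
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample", "condition", "control") %in% names(samples)))
  present <- intersect(genes, rownames(expr))
  skipped <- setdiff(genes, present)
  ctrl_cols <- samples$sample[samples$control]
  if (length(ctrl_cols) == 0) stop("no control samples in dataset ", dataset_id)
  ctrl_mean <- rowMeans(expr[present, ctrl_cols, drop = FALSE])
  calls <- list()
  for (cond in unique(samples$condition[!samples$control])) {
    cols <- samples$sample[!samples$control & samples$condition == cond]
    lfc <- rowMeans(expr[present, cols, drop = FALSE]) - ctrl_mean
    hit <- abs(lfc) >= base::log2(min_fc)
    if (any(hit)) {
      calls[[cond]] <- tibble::tibble(
        gene_id = present[hit], dataset_id = dataset_id, condition = cond,
        log2fc = unname(lfc[hit]),
        direction = unname(ifelse(lfc[hit] > 0, "up", "down")))
    }
  }
  out <- dplyr::bind_rows(calls)
  if (nrow(out) == 0) {
    out <- tibble::tibble(gene_id = character(), dataset_id = character(),
                          condition = character(), log2fc = numeric(),
                          direction = character())
  }
  structure(out, skipped = skipped)
}

#' Rank candidate genes across expression datasets
#'
#' Genes are grouped by the number of datasets in which they have at least
#' one differential-expression call; genes called in `min_datasets` or more
#' are flagged promising. Within a tier, genes are ordered by their largest
#' absolute log2 fold change. Per-dataset direction is summarised as `up`,
#' `down` or `mixed` (both directions across conditions/time points).
#'
#' @param deg_calls Row-bound [call_degs()] tibbles from several datasets.
#' @param min_datasets Datasets required for the promising flag (default 3).
#' @return Tibble per gene: `gene_id`, `n_datasets`, `max_abs_log2fc`,
#'   `direction_summary`, `promising`, sorted by tier then effect size.
#' @export
rank_candidates <- function(deg_calls, min_datasets = 3) {
  deg_calls <- tibble::as_tibble(deg_calls)
  if (nrow(deg_calls) == 0) {
    return(tibble::tibble(gene_id = character(), n_datasets = integer(),
                          max_abs_log2fc = numeric(),
                          direction_summary = character(), promising = logical()))
  }
  deg_calls %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      n_datasets = dplyr::n_distinct(.data$dataset_id),
      max_abs_log2fc = max(abs(.data$log2fc)),
      direction_summary = if (dplyr::n_distinct(.data$direction) > 1) "mixed"
                          else .data$direction[1],
      .groups = "drop") %>%
    dplyr::mutate(promising = .data$n_datasets >= min_datasets) %>%
    dplyr::arrange(dplyr::desc(.data$n_datasets), dplyr::desc(.data$max_abs_log2fc),
                   .data$gene_id)
}
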