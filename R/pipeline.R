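#' Bundled MAST MQTL summary table
#'
#' A transcription of a published summary table of wheat MQTLs conferring
#' tolerance to five or all six abiotic stresses, shipped as a plain-text
#' dataset: MQTL name, genetic CI, flanking markers, member-QTL and study
#' counts, average PVE, and the per-stress member tallies as printed (the
#' aluminium label appears both as `AS` and `AL` in the source; the loader
#' normalises labels and expands `D + H` when counting stress classes).
#'
#' @param path Optional path to a table of the same shape.
#' @return Tibble with parsed `stress_tally` (canonical `DS:3;HS:2` strings)
#'   and `n_stress_classes` columns added.
#' @export
mast_mqtl_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mast_mqtl_table1.tsv",
                                package = "mastqtl", mustWork = TRUE)
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  parse_row <- function(s) {
    parts <- strsplit(s, ",")[[1]]
    lab <- normalize_stress(sub("\\s*\\(.*$", "", trimws(parts)))
    n <- as.integer(sub("^.*\\((\\d+)\\).*$", "\\1", parts))
    stats::setNames(n, lab)
  }
  parsed <- lapply(df$stresses, parse_row)
  df$stress_tally <- vapply(parsed, function(p) {
    expanded <- unlist(lapply(seq_along(p), function(i) {
      cls <- if (names(p)[i] == "D+H") c("DS", "HS") else names(p)[i]
      stats::setNames(rep(p[i], length(cls)), cls)
    }))
    tal <- tapply(expanded, names(expanded), sum)
    paste(paste0(names(tal), ":", tal), collapse = ";")
  }, character(1))
  df$n_stress_classes <- vapply(parsed, function(p) {
    length(unique(unlist(lapply(names(p), function(x) if (x == "D+H") c("DS", "HS") else x))))
  }, integer(1))
  df$chromosome <- sub("^MQTL([0-9][ABD])\\..*$", "\\1", df$mqtl)
  tibble::as_tibble(df)
}

#' Marker density, as printed in map summaries
#'
#' @param n_markers Marker count.
#' @param length_cm Map length in cM.
#' @param digits Decimals (map summaries print 2).
#' @return markers per cM, rounded half away from zero.
#' @export
marker_density <- function(n_markers, length_cm, digits = 2) {
  round_half_up(n_markers / length_cm, digits)
}

#' Percentage share, as printed in QTL summaries
#'
#' @param n Count in the category.
#' @param total Total count.
#' @param digits Decimals.
#' @return `100 * n / total`, rounded half away from zero.
#' @export
percent_share <- function(n, total, digits = 2) {
  round_half_up(100 * n / total, digits)
}

#' Summaries of collected QTLs and the consensus map
#'
#' Reproduces the dataset-level descriptive statistics a meta-QTL study
#' reports: per-chromosome and per-subgenome QTL counts with percentage
#' shares, PVE category split (< 10% vs >= 10%), CI category split
#' (> 10 cM vs <= 10 cM), mean QTLs per stress class (over the six
#' elementary classes) and per chromosome, and - when a consensus map is
#' supplied - marker counts, cM lengths and markers/cM per subgenome, with
#' the global density given both as total markers over total length and as
#' the mean of per-chromosome densities (the two definitions differ).
#'
#' @param qtls QTL tibble (any table with `chromosome`; `pve`, `ci_start_cm`,
#'   `ci_end_cm`, `stress` used when present).
#' @param cmap Optional consensus map.
#' @return List of tibbles: `by_chromosome`, `by_subgenome`,
#'   `pve_categories`, `ci_categories`, `means`, and (with `cmap`)
#'   `map_by_subgenome`, `map_summary`.
#' @export
summarize_inputs <- function(qtls, cmap = NULL) {
  qtls <- tibble::as_tibble(qtls)
  total <- nrow(qtls)
  by_chrom <- qtls %>%
    dplyr::count(.data$chromosome, name = "n_qtls") %>%
    dplyr::mutate(pct = percent_share(.data$n_qtls, total))
  by_sub <- qtls %>%
    dplyr::mutate(subgenome = subgenome(.data$chromosome)) %>%
    dplyr::count(.data$subgenome, name = "n_qtls") %>%
    dplyr::mutate(pct = percent_share(.data$n_qtls, total))
  pve_cat <- if ("pve" %in% names(qtls) && total > 0) {
    n_lt10 <- sum(qtls$pve < 10, na.rm = TRUE)
    n_ge10 <- sum(qtls$pve >= 10, na.rm = TRUE)
    tibble::tibble(category = c("PVE < 10%", "PVE >= 10%"),
                   n = c(n_lt10, n_ge10),
                   pct = percent_share(c(n_lt10, n_ge10), total))
  } else tibble::tibble(category = character(), n = integer(), pct = numeric())
  ci_cat <- if (all(c("ci_start_cm", "ci_end_cm") %in% names(qtls)) && total > 0) {
    w <- qtls$ci_end_cm - qtls$ci_start_cm
    n_gt10 <- sum(w > 10, na.rm = TRUE)
    n_le10 <- sum(w <= 10, na.rm = TRUE)
    tibble::tibble(category = c("CI > 10 cM", "CI <= 10 cM"),
                   n = c(n_gt10, n_le10),
                   pct = percent_share(c(n_gt10, n_le10), total))
  } else tibble::tibble(category = character(), n = integer(), pct = numeric())
  means <- tibble::tibble(
    n_qtls = total,
    mean_qtls_per_stress = if (total > 0) total / length(stress_codes(expanded = TRUE)) else 0,
    mean_qtls_per_chromosome = if (total > 0) total / length(wheat_chromosomes()) else 0)
  out <- list(by_chromosome = by_chrom, by_subgenome = by_sub,
              pve_categories = pve_cat, ci_categories = ci_cat, means = means)
  if (!is.null(cmap)) {
    per_chrom <- tibble::as_tibble(cmap) %>%
      dplyr::group_by(.data$chromosome) %>%
      dplyr::summarise(n_markers = dplyr::n(),
                       length_cm = max(.data$pos_cm) - min(.data$pos_cm),
                       .groups = "drop") %>%
      dplyr::mutate(density = marker_density(.data$n_markers, .data$length_cm))
    out$map_by_subgenome <- per_chrom %>%
      dplyr::mutate(subgenome = subgenome(.data$chromosome)) %>%
      dplyr::group_by(.data$subgenome) %>%
      dplyr::summarise(n_markers = sum(.data$n_markers),
                       length_cm = sum(.data$length_cm), .groups = "drop") %>%
      dplyr::mutate(density = marker_density(.data$n_markers, .data$length_cm))
    out$map_summary <- tibble::tibble(
      n_markers = sum(per_chrom$n_markers),
      length_cm = sum(per_chrom$length_cm),
      density_global = marker_density(sum(per_chrom$n_markers), sum(per_chrom$length_cm)),
      density_mean_of_chromosomes = round_half_up(mean(per_chrom$density), 2))
    out$map_by_chromosome <- per_chrom
  }
  out
}

#' Summaries of predicted MQTLs
#'
#' Per-chromosome MQTL counts, the confidence-interval fold reduction (mean
#' initial projected CI width over mean MQTL CI width, overall and per
#' chromosome), the distribution of stress-class coverage (MAST tallies),
#' and - for anchored MQTLs - physical-width categories including the share
#' narrower than 20 Mb.
#'
#' @param mqtls MQTL tibble (optionally anchored).
#' @param projected Projected QTL tibble used for the meta-analysis.
#' @return List of tibbles: `by_chromosome`, `fold_reduction`,
#'   `fold_reduction_by_chromosome`, `stress_class_distribution`, and (if
#'   physical columns present) `physical_categories`.
#' @export
summarize_mqtls <- function(mqtls, projected) {
  mqtls <- tibble::as_tibble(mqtls)
  projected <- tibble::as_tibble(projected) %>%
    dplyr::filter(.data$status == "projected")
  by_chrom <- dplyr::count(mqtls, .data$chromosome, name = "n_mqtls")
  mean_init <- mean(projected$ci_end_cm - projected$ci_start_cm)
  mean_mqtl <- mean(mqtls$ci_end_cm - mqtls$ci_start_cm)
  fold <- tibble::tibble(mean_initial_ci_cm = mean_init,
                         mean_mqtl_ci_cm = mean_mqtl,
                         fold_reduction = mean_init / mean_mqtl)
  fold_chrom <- projected %>%
    dplyr::group_by(.data$chromosome) %>%
    dplyr::summarise(mean_initial_ci_cm = mean(.data$ci_end_cm - .data$ci_start_cm),
                     .groups = "drop") %>%
    dplyr::inner_join(
      mqtls %>% dplyr::group_by(.data$chromosome) %>%
        dplyr::summarise(mean_mqtl_ci_cm = mean(.data$ci_end_cm - .data$ci_start_cm),
                         .groups = "drop"),
      by = "chromosome") %>%
    dplyr::mutate(fold_reduction = .data$mean_initial_ci_cm / .data$mean_mqtl_ci_cm)
  stress_dist <- dplyr::count(mqtls, .data$n_stress_classes, name = "n_mqtls")
  out <- list(by_chromosome = by_chrom, fold_reduction = fold,
              fold_reduction_by_chromosome = fold_chrom,
              stress_class_distribution = stress_dist)
  if (all(c("start_bp", "end_bp") %in% names(mqtls))) {
    anc <- mqtls[!is.na(mqtls$start_bp), , drop = FALSE]
    w <- anc$end_bp - anc$start_bp + 1
    out$physical_categories <- tibble::tibble(
      n_anchored = nrow(anc),
      n_lt_20mb = sum(w < 20e6),
      share_lt_20mb = percent_share(sum(w < 20e6), nrow(anc)))
  }
  out
}

#' Pipeline run configuration
#'
#' Bundles input paths and stage parameters for [run_pipeline()]. All paths
#' must exist at run start; the configuration is serialised to JSON in the
#' output directory for provenance.
#'
#' @param qtls,maps,reference_maps,marker_positions,mtas,known_genes,annotation
#'   Input paths (`maps`/`reference_maps` may be vectors of map TSVs or a
#'   single combined TSV). `known_genes` is optional.
#' @param expression Named list: one element per dataset, each a list with
#'   `expr` and `samples` paths.
#' @param promoters,motifs,ortho,foreign_mqtls Optional paths for the
#'   promoter and ortho-MQTL stages.
#' @param outdir Output directory.
#' @param seed Integer seed for the stochastic stages (EM restarts).
#' @param params Named list overriding stage parameters: `projection`
#'   ([projection_config()]), `ci` ([ci_config()]), `k_max`, `n_start`,
#'   `assign_threshold`, `min_stress_classes`, `min_qtls`, `min_fc`,
#'   `min_datasets`, `mta_window_bp`, `min_ortho_genes`.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(qtls, maps, reference_maps = NULL, marker_positions,
                            mtas = NULL, known_genes = NULL, annotation = NULL,
                            expression = NULL, promoters = NULL, motifs = NULL,
                            ortho = NULL, foreign_mqtls = NULL,
                            outdir = tempfile("mastqtl_run_"), seed = 1,
                            params = list()) {
  defaults <- list(projection = projection_config(), ci = ci_config(),
                   k_max = 10, n_start = 10, assign_threshold = 0.5,
                   min_stress_classes = 5, min_qtls = 9, min_fc = 2,
                   min_datasets = 3, mta_window_bp = 0, min_ortho_genes = 1)
  params <- utils::modifyList(defaults, params)
  cfg <- list(paths = list(qtls = qtls, maps = maps, reference_maps = reference_maps,
                           marker_positions = marker_positions, mtas = mtas,
                           known_genes = known_genes, annotation = annotation,
                           expression = expression, promoters = promoters,
                           motifs = motifs, ortho = ortho,
                           foreign_mqtls = foreign_mqtls),
              outdir = outdir, seed = seed, params = params)
  class(cfg) <- "run_config"
  cfg
}

check_paths <- function(paths) {
  flat <- unlist(paths, use.names = TRUE)
  flat <- flat[!is.na(flat) & nzchar(flat)]
  missing <- flat[!file.exists(flat)]
  if (length(missing) > 0) {
    stop("input path(s) not found: ", paste(missing, collapse = ", "))
  }
}

#' Run the full meta-QTL pipeline
#'
#' Executes the stages in order - read and validate QTLs, impute defaults and
#' estimate missing CIs, build (and augment) the consensus map, project QTLs,
#' run the per-chromosome mixture meta-analysis, anchor MQTLs physically,
#' co-localise with MTAs and known genes, select MAST MQTLs, mine genes, call
#' DEGs and rank candidates, scan promoters, detect ortho-MQTLs, and write
#' summary tables - saving every stage's TSV artifact plus a machine-readable
#' run log with the attrition counts (collected, usable, projected,
#' hotspots, true MQTLs) into the output directory.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results (`qtls`,
#'   `cmap`, `projected`, `meta`, `mqtls`, `mast`, `genes`, `deg_calls`,
#'   `candidates`, `cre`, `ortho_pairs`, `summaries`, `log`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  check_paths(cfg$paths)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$outdir, ...)
  log <- list(seed = cfg$seed)
  p <- cfg$params

  # stage 1: QTL records
  qtls <- read_qtl_table(cfg$paths$qtls)
  log$collected <- nrow(qtls) + nrow(rejects(qtls))
  log$valid <- nrow(qtls)
  write_rejects(qtls, out("qtl_rejects.tsv"))

  read_maps <- function(paths) dplyr::bind_rows(lapply(paths, read_map_table))
  study_maps <- read_maps(cfg$paths$maps)
  ref_maps <- if (!is.null(cfg$paths$reference_maps)) read_maps(cfg$paths$reference_maps) else study_maps

  qtls <- impute_defaults(qtls, study_maps)
  qtls <- estimate_ci(qtls, p$ci)
  log$usable <- sum(!qtls$unprojectable)

  # stage 2: consensus map
  cmap <- build_consensus(ref_maps)
  cmap <- augment_consensus(cmap, study_maps)
  write_map_table(cmap, out("consensus_map.tsv"))

  # stage 3: projection
  projected <- project_qtls(qtls, study_maps, cmap, p$projection)
  readr::write_tsv(projected, out("projected_qtls.tsv"), progress = FALSE)
  log$projected <- projection_report(projected)$projected
  log$projection_reasons <- as.list(stats::setNames(
    projection_report(projected)$reasons$n,
    projection_report(projected)$reasons$reason))

  # stage 4: meta-analysis
  meta <- meta_qtl(projected, k_max = p$k_max, n_start = p$n_start,
                   assign_threshold = p$assign_threshold, seed = cfg$seed)
  readr::write_tsv(meta$criteria, out("criteria.tsv"), progress = FALSE)
  log$hotspots <- nrow(meta$mqtls) + nrow(meta$discards)
  log$singletons <- sum(meta$discards$reason == "singleton")
  log$single_study <- sum(meta$discards$reason == "single_study")
  log$unassigned <- sum(meta$assignments$disposition == "unassigned")
  log$mqtls <- nrow(meta$mqtls)

  # stage 5: physical anchoring
  phys <- read_marker_positions(cfg$paths$marker_positions)
  mqtls <- anchor_mqtls(meta$mqtls, cmap, phys)
  readr::write_tsv(mqtls, out("mqtls.tsv"), progress = FALSE)
  write_mqtl_bed(mqtls, out("mqtls.bed"))
  log$anchored <- sum(mqtls$anchored)

  # stage 6: co-localization
  if (!is.null(cfg$paths$mtas)) {
    mtas <- read_mta_table(cfg$paths$mtas)
    mqtls <- overlap_mtas(mqtls, mtas, window_bp = p$mta_window_bp)
    log$gwas_validated <- sum(mqtls$gwas_validated)
    log$validated_fraction <- attr(mqtls, "validated_fraction")
  }
  known_hits <- NULL
  if (!is.null(cfg$paths$known_genes)) {
    known_hits <- overlap_known_genes(mqtls, read_known_genes(cfg$paths$known_genes))
    readr::write_tsv(known_hits, out("known_gene_overlaps.tsv"), progress = FALSE)
  }
  readr::write_tsv(mqtls, out("mqtls.tsv"), progress = FALSE)

  # stage 7: candidate genes
  mast <- genes <- deg_calls <- candidates <- cre <- ortho_pairs <- NULL
  if (!is.null(cfg$paths$annotation)) {
    mast <- select_mast_mqtls(mqtls, p$min_stress_classes, p$min_qtls)
    windows <- gene_window(mast)
    annotation <- read_gene_annotation(cfg$paths$annotation)
    genes <- mine_genes(windows, annotation)
    readr::write_tsv(genes, out("mined_genes.tsv"), progress = FALSE)
    log$mast_mqtls <- nrow(mast)
    log$mined_genes <- dplyr::n_distinct(genes$gene_id)
    if (!is.null(cfg$paths$expression)) {
      calls <- lapply(names(cfg$paths$expression), function(did) {
        ds <- cfg$paths$expression[[did]]
        expr <- read_expression_matrix(ds$expr)
        samples <- readr::read_tsv(ds$samples, col_types = readr::cols(), progress = FALSE)
        call_degs(unique(genes$gene_id), expr, samples, dataset_id = did,
                  min_fc = p$min_fc)
      })
      deg_calls <- dplyr::bind_rows(calls)
      readr::write_tsv(deg_calls, out("deg_calls.tsv"), progress = FALSE)
      candidates <- rank_candidates(deg_calls, p$min_datasets)
      readr::write_tsv(candidates, out("candidates.tsv"), progress = FALSE)
      log$degs <- dplyr::n_distinct(deg_calls$gene_id)
      log$promising <- sum(candidates$promising)
    }
  }

  # stage 8: promoters
  if (!is.null(cfg$paths$promoters)) {
    motifs <- if (!is.null(cfg$paths$motifs)) cre_motifs(cfg$paths$motifs) else cre_motifs()
    proms <- Biostrings::readDNAStringSet(cfg$paths$promoters)
    hits <- scan_motifs(proms, motifs)
    readr::write_tsv(hits, out("cre_hits.tsv"), progress = FALSE)
    cre <- categorize_cres(hits)
    readr::write_tsv(cre$global, out("cre_categories.tsv"), progress = FALSE)
    log$cre_hits <- nrow(hits)
  }

  # stage 9: ortho-MQTLs
  if (!is.null(cfg$paths$ortho) && !is.null(genes)) {
    links <- map_orthologues(genes, read_ortho_table(cfg$paths$ortho))
    ortho_pairs <- detect_ortho_mqtls(links, read_foreign_mqtls(cfg$paths$foreign_mqtls),
                                      min_genes = p$min_ortho_genes)
    readr::write_tsv(ortho_pairs, out("ortho_mqtls.tsv"), progress = FALSE)
    log$ortho_pairs <- nrow(ortho_pairs)
  }

  # stage 10: summaries
  summaries <- list(inputs = summarize_inputs(qtls, cmap),
                    mqtls = summarize_mqtls(mqtls, projected))
  readr::write_tsv(summaries$inputs$by_subgenome, out("summary_subgenomes.tsv"),
                   progress = FALSE)
  readr::write_tsv(summaries$mqtls$fold_reduction, out("summary_fold_reduction.tsv"),
                   progress = FALSE)
  jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(seed = cfg$seed, params = cfg$params,
                            paths = cfg$paths),
                       out("config.json"), auto_unbox = TRUE, force = TRUE)
  invisible(list(qtls = qtls, cmap = cmap, projected = projected, meta = meta,
                 mqtls = mqtls, known_gene_overlaps = known_hits, mast = mast,
                 genes = genes, deg_calls = deg_calls, candidates = candidates,
                 cre = cre, ortho_pairs = ortho_pairs, summaries = summaries,
                 log = log))
}
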