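#' Simulation scenario for the meta-QTL pipeline
#'
#' Describes a synthetic multi-study QTL landscape with known ground truth:
#' a dense base linkage map per chromosome, a handful of true MQTL positions,
#' several mapping studies whose maps share anchor markers with the base map
#' (affinely rescaled and jittered), QTL peaks drawn Normal around the true
#' positions with the spread implied by each population's CI equation, GWAS
#' MTAs and candidate genes planted near the true positions, expression
#' matrices with planted fold changes, promoters with planted motifs, and
#' orthologue links planted inside foreign MQTL intervals.
#'
#' Defaults describe the study conditions used throughout the test-suite:
#' three chromosomes (one per subgenome) of 150 cM / 150 Mb, base-map density
#' 5 markers/cM, eight RIL/DH studies of 150-300 individuals, about 200 QTLs
#' with PVE 8-25%, and six true MQTLs (2, 3 and 1 per chromosome) separated
#' by at least eight times the largest per-QTL standard deviation.
#'
#' @param seed Integer RNG seed; every draw in the generators flows from it.
#' @param chromosomes Tibble: `chromosome`, `length_cm`, `length_bp`.
#' @param true_mqtls Tibble: `chromosome`, `position_cm`, `mqtl_id`.
#' @param n_studies Number of mapping studies.
#' @param n_qtls_per_study QTLs reported per study.
#' @param population_types Candidate population types sampled per study.
#' @param population_size_range Sampled uniformly per study.
#' @param pve_range Per-QTL PVE sampled uniformly (percent).
#' @param lod_range Per-QTL LOD sampled uniformly.
#' @param marker_spacing_cm Base-map marker spacing.
#' @param anchor_fraction Fraction of base markers each study map carries.
#' @param n_private_markers Study-private markers per chromosome.
#' @param map_jitter_sd Marker-position jitter on study maps (cM).
#' @param ref_jitter_sd Jitter on the reference maps merged into the
#'   consensus (cM).
#' @param n_reference_maps Reference maps built from the base map.
#' @param study_scale_range Per-study affine map-scale range.
#' @param missing_lod,missing_pve,missing_ci,missing_peak,unusable_fraction
#'   Fractions of records with the field blanked (exercising imputation);
#'   `unusable_fraction` additionally breaks a flanking marker so the record
#'   cannot be projected.
#' @param stress_probs Named sampling weights over [stress_codes()].
#' @param peak_sd_scale Multiplier on the CI-implied peak standard deviation
#'   (0 gives the noiseless limit where every peak sits on its true MQTL).
#' @param n_mta_near MTAs planted per true MQTL.
#' @param mta_window_bp Planted MTAs fall uniformly within this distance of
#'   the true MQTL physical position.
#' @param n_mta_background Background MTAs per chromosome (uniform; 0 keeps
#'   every MTA informative).
#' @param n_genes_per_chrom Background gene models tiled per chromosome.
#' @param n_planted_genes Genes planted within `gene_window_bp` of each true
#'   MQTL.
#' @param gene_window_bp Planting half-window around the true position.
#' @param n_promising Genes planted with differential expression in at least
#'   three datasets.
#' @param n_decoy_degs Genes called in only one or two datasets.
#' @param n_expression_datasets Number of expression datasets.
#' @param ortho_pairs_per_species Conserved regions planted per foreign
#'   species (rice, maize).
#' @return A list of class `mast_scenario`.
#' @export
simulate_scenario <- function(
    seed = 1,
    chromosomes = tibble::tibble(
      chromosome = c("1A", "2B", "3D"),
      length_cm = 150, length_bp = 150e6),
    true_mqtls = tibble::tibble(
      chromosome = c("1A", "1A", "2B", "2B", "2B", "3D"),
      position_cm = c(40, 110, 25, 75, 125, 75),
      mqtl_id = paste0("T", 1:6)),
    n_studies = 8,
    n_qtls_per_study = 26,
    population_types = c("RIL", "DH"),
    population_size_range = c(150, 300),
    pve_range = c(8, 25),
    lod_range = c(2.5, 12),
    marker_spacing_cm = 0.2,
    anchor_fraction = 0.4,
    n_private_markers = 15,
    map_jitter_sd = 0.1,
    ref_jitter_sd = 0.05,
    n_reference_maps = 3,
    study_scale_range = c(0.9, 1.1),
    missing_lod = 0.15, missing_pve = 0.15, missing_ci = 0.3,
    missing_peak = 0.08, unusable_fraction = 0.05,
    stress_probs = c(DS = 0.20, HS = 0.15, `D+H` = 0.10, SS = 0.25,
                     WS = 0.05, PHS = 0.15, AS = 0.10),
    peak_sd_scale = 1,
    n_mta_near = 6, mta_window_bp = 1e5, n_mta_background = 0,
    n_genes_per_chrom = 80, n_planted_genes = 4, gene_window_bp = 5e4,
    n_promising = 11, n_decoy_degs = 6, n_expression_datasets = 4,
    ortho_pairs_per_species = 2) {
  stopifnot(anchor_fraction > 0, anchor_fraction <= 1,
            all(true_mqtls$chromosome %in% chromosomes$chromosome))
  sc <- as.list(environment())
  class(sc) <- "mast_scenario"
  sc
}

with_scenario_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
  force(code)
}

# sorted positions re-assigned to markers kept in original order
order_repair <- function(pos) sort(pos)

#' Simulate mapping studies: maps, QTL tables and truth
#'
#' Builds the base map, the reference maps merged into the consensus, the
#' per-study maps (anchor subsets of the base map, affinely rescaled and
#' jittered), the per-study QTL records with the configured missingness, the
#' marker physical-position table (linear cM-to-bp within a chromosome), and
#' the truth table of the planted MQTLs. Deterministic under the scenario
#' seed.
#'
#' @param scenario A [simulate_scenario()] object.
#' @return List: `base_map`, `reference_maps`, `study_maps`, `qtls`,
#'   `marker_positions`, `truth` (tibble with `mqtl_id`, `chromosome`,
#'   `position_cm`, `position_bp`), `study_info`.
#' @export
simulate_studies <- function(scenario) {
  sc <- scenario
  with_scenario_seed(sc$seed, 0L, {
    k_const <- ci_config()
    chroms <- sc$chromosomes
    # base map: evenly spaced markers, bp linear in cM
    base_map <- purrr::pmap_dfr(chroms, function(chromosome, length_cm, length_bp) {
      pos <- seq(0, length_cm, by = sc$marker_spacing_cm)
      tibble::tibble(map_id = "base", chromosome = chromosome,
                     marker = sprintf("M_%s_%04d", chromosome, seq_along(pos)),
                     pos_cm = pos)
    })
    marker_positions <- base_map %>%
      dplyr::left_join(chroms, by = "chromosome") %>%
      dplyr::transmute(marker = .data$marker, chromosome = .data$chromosome,
                       bp = pmax(1, round(.data$pos_cm / .data$length_cm * .data$length_bp)))
    truth <- sc$true_mqtls %>%
      dplyr::left_join(chroms, by = "chromosome") %>%
      dplyr::mutate(position_bp = round(.data$position_cm / .data$length_cm * .data$length_bp)) %>%
      dplyr::select("mqtl_id", "chromosome", "position_cm", "position_bp")

    # reference maps always carry the terminal markers of each chromosome, so
    # the consensus origin stays aligned with the base-map coordinates the
    # truth table is expressed in
    reference_maps <- purrr::map_dfr(seq_len(sc$n_reference_maps), function(r) {
      base_map %>%
        dplyr::group_by(.data$chromosome) %>%
        dplyr::mutate(.terminal = dplyr::row_number() %in% c(1L, dplyr::n())) %>%
        dplyr::filter(.data$.terminal |
                        stats::runif(dplyr::n()) < max(0.6, sc$anchor_fraction)) %>%
        dplyr::select(-".terminal") %>%
        dplyr::arrange(.data$pos_cm, .by_group = TRUE) %>%
        dplyr::mutate(pos_cm = order_repair(pmax(0, .data$pos_cm + stats::rnorm(dplyr::n(), 0, sc$ref_jitter_sd)))) %>%
        dplyr::ungroup() %>%
        dplyr::mutate(map_id = paste0("ref", r))
    })

    study_ids <- paste0("S", seq_len(sc$n_studies))
    study_info <- tibble::tibble(
      study_id = study_ids,
      population_type = sample(sc$population_types, sc$n_studies, replace = TRUE),
      population_size = round(stats::runif(sc$n_studies, sc$population_size_range[1],
                                           sc$population_size_range[2])),
      map_scale = stats::runif(sc$n_studies, sc$study_scale_range[1],
                               sc$study_scale_range[2]))

    study_maps <- purrr::map_dfr(seq_len(sc$n_studies), function(s) {
      scale <- study_info$map_scale[s]
      anchors <- base_map %>%
        dplyr::group_by(.data$chromosome) %>%
        dplyr::slice_sample(prop = sc$anchor_fraction) %>%
        dplyr::arrange(.data$pos_cm, .by_group = TRUE) %>%
        dplyr::mutate(base_cm = .data$pos_cm,
                      pos_cm = order_repair(pmax(0, .data$pos_cm * scale +
                                                   stats::rnorm(dplyr::n(), 0, sc$map_jitter_sd)))) %>%
        dplyr::ungroup()
      private <- purrr::map_dfr(chroms$chromosome, function(ch) {
        len <- chroms$length_cm[chroms$chromosome == ch]
        pos <- sort(stats::runif(sc$n_private_markers, 0, len * scale))
        tibble::tibble(map_id = NA_character_, chromosome = ch,
                       marker = sprintf("%s_pm_%s_%02d", study_ids[s], ch,
                                        seq_len(sc$n_private_markers)),
                       pos_cm = pos, base_cm = NA_real_)
      })
      dplyr::bind_rows(anchors, private) %>%
        dplyr::mutate(map_id = study_ids[s]) %>%
        dplyr::arrange(.data$chromosome, .data$pos_cm)
    })

    qtl_rows <- list()
    for (s in seq_len(sc$n_studies)) {
      sid <- study_ids[s]
      ptype <- study_info$population_type[s]
      psize <- study_info$population_size[s]
      smap <- study_maps[study_maps$map_id == sid, ]
      for (q in seq_len(sc$n_qtls_per_study)) {
        tm <- truth[sample.int(nrow(truth), 1), ]
        ch <- tm$chromosome
        len <- chroms$length_cm[chroms$chromosome == ch]
        pve <- stats::runif(1, sc$pve_range[1], sc$pve_range[2])
        width_cons <- unlist(k_const[ptype]) / (psize * pve / 100)
        sigma <- width_cons / 3.92 * sc$peak_sd_scale
        peak_cons <- min(max(stats::rnorm(1, tm$position_cm, sigma), 0.5), len - 0.5)
        # transfer consensus-frame coordinates into the study frame
        anchors <- smap[smap$chromosome == ch & !is.na(smap$base_cm), ]
        tr <- function(x) interp_positions(x, anchors$base_cm, anchors$pos_cm)
        peak_study <- tr(peak_cons)
        ci_study <- sort(tr(c(max(0, peak_cons - width_cons / 2),
                              peak_cons + width_cons / 2)))
        sm_ch <- smap[smap$chromosome == ch, ]
        left_i <- which(sm_ch$pos_cm <= peak_study)
        right_i <- which(sm_ch$pos_cm > peak_study)
        left_m <- if (length(left_i) > 0) sm_ch$marker[max(left_i)] else sm_ch$marker[1]
        right_m <- if (length(right_i) > 0) sm_ch$marker[min(right_i)] else sm_ch$marker[nrow(sm_ch)]
        stress <- sample(names(sc$stress_probs), 1, prob = sc$stress_probs)
        row <- tibble::tibble(
          qtl_id = sprintf("%s_Q%02d", sid, q), study_id = sid,
          population_type = ptype, population_size = psize,
          stress = stress, trait = "abiotic", chromosome = ch,
          left_marker = left_m, right_marker = right_m,
          peak_cm = peak_study, ci_start_cm = ci_study[1], ci_end_cm = ci_study[2],
          lod = stats::runif(1, sc$lod_range[1], sc$lod_range[2]), pve = pve,
          true_mqtl = tm$mqtl_id)
        if (stats::runif(1) < sc$missing_lod) row$lod <- NA_real_
        if (stats::runif(1) < sc$missing_pve) row$pve <- NA_real_
        if (stats::runif(1) < sc$missing_ci) { row$ci_start_cm <- NA_real_; row$ci_end_cm <- NA_real_ }
        if (stats::runif(1) < sc$missing_peak) row$peak_cm <- NA_real_
        if (stats::runif(1) < sc$unusable_fraction) {
          row$peak_cm <- NA_real_
          row$right_marker <- "ABSENT_MARKER"
        }
        qtl_rows[[length(qtl_rows) + 1]] <- row
      }
    }
    qtls <- dplyr::bind_rows(qtl_rows)
    # the planted loci are MAST loci: every true MQTL receives QTLs covering
    # all stress classes (two full cycles where membership allows), with the
    # remaining labels drawn from the configured weights above
    for (tm in unique(qtls$true_mqtl)) {
      rows <- which(qtls$true_mqtl == tm)
      n_force <- min(length(rows), 2 * length(stress_codes()))
      qtls$stress[rows[seq_len(n_force)]] <-
        rep(sample(stress_codes()), 2)[seq_len(n_force)]
    }
    list(base_map = base_map,
         reference_maps = reference_maps[, c("map_id", "chromosome", "marker", "pos_cm")],
         study_maps = study_maps[, c("map_id", "chromosome", "marker", "pos_cm")],
         qtls = qtls, marker_positions = marker_positions,
         truth = truth, study_info = study_info)
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

plant_motif <- function(seq, pattern, at) {
  # IUPAC letters in the pattern are concretised before planting
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
                S = c("G", "C"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  letters_in <- strsplit(pattern, "")[[1]]
  concrete <- vapply(letters_in, function(l) sample(iupac[[l]], 1), character(1))
  substr(seq, at, at + length(concrete) - 1) <- paste(concrete, collapse = "")
  seq
}

#' Simulate omics layers around the planted MQTLs
#'
#' Adds, on top of [simulate_studies()] truth: GWAS MTAs planted near the
#' true MQTL physical positions, a gene annotation with genes planted inside
#' the true windows, expression datasets with planted log2 fold changes
#' (promising genes differential in at least three datasets, decoys in one or
#' two), 1500-bp promoter sequences with planted cis-regulatory motifs, and
#' orthologue links planted inside foreign (rice/maize) MQTL intervals.
#' Deterministic under the scenario seed.
#'
#' @param scenario A [simulate_scenario()] object.
#' @param truth Truth tibble from [simulate_studies()].
#' @return List: `mtas`, `annotation`, `expression` (list per dataset:
#'   `expr` matrix, `samples` tibble, `dataset_id`), `promoters`,
#'   `ortho`, `foreign_mqtls`, and `truth` tables (`planted_genes`,
#'   `promising_genes`, `decoy_genes`, `planted_motifs`, `ortho_pairs`,
#'   `mta_truth`).
#' @export
simulate_omics <- function(scenario, truth) {
  sc <- scenario
  with_scenario_seed(sc$seed, 1L, {
    chroms <- sc$chromosomes
    # --- MTAs -------------------------------------------------------------
    mta_truth <- purrr::pmap_dfr(truth, function(mqtl_id, chromosome, position_cm, position_bp) {
      bp <- round(stats::runif(sc$n_mta_near,
                               max(1, position_bp - sc$mta_window_bp),
                               position_bp + sc$mta_window_bp))
      tibble::tibble(marker = sprintf("MTA_%s_%02d", mqtl_id, seq_len(sc$n_mta_near)),
                     chromosome = chromosome, bp = bp,
                     stress = sample(stress_codes(expanded = TRUE), sc$n_mta_near, replace = TRUE),
                     study_id = sprintf("GWAS%02d", sample.int(10, sc$n_mta_near, replace = TRUE)),
                     true_mqtl = mqtl_id)
    })
    bg <- purrr::pmap_dfr(chroms, function(chromosome, length_cm, length_bp) {
      n <- sc$n_mta_background
      if (n == 0) return(NULL)
      tibble::tibble(marker = sprintf("MTAbg_%s_%02d", chromosome, seq_len(n)),
                     chromosome = chromosome,
                     bp = round(stats::runif(n, 1, length_bp)),
                     stress = sample(stress_codes(expanded = TRUE), n, replace = TRUE),
                     study_id = "GWASbg", true_mqtl = NA_character_)
    })
    mtas <- dplyr::bind_rows(mta_truth, bg)

    # --- gene annotation --------------------------------------------------
    background_genes <- purrr::pmap_dfr(chroms, function(chromosome, length_cm, length_bp) {
      start <- sort(round(stats::runif(sc$n_genes_per_chrom, 1, length_bp - 5000)))
      tibble::tibble(gene_id = sprintf("G%s%03d", chromosome, seq_len(sc$n_genes_per_chrom)),
                     chromosome = chromosome, start_bp = start,
                     end_bp = start + round(stats::runif(sc$n_genes_per_chrom, 1500, 4500)),
                     strand = sample(c("+", "-"), sc$n_genes_per_chrom, replace = TRUE),
                     description = "hypothetical protein", planted = FALSE,
                     true_mqtl = NA_character_)
    })
    planted_genes <- purrr::pmap_dfr(truth, function(mqtl_id, chromosome, position_cm, position_bp) {
      start <- round(position_bp + stats::runif(sc$n_planted_genes,
                                                -sc$gene_window_bp, sc$gene_window_bp))
      tibble::tibble(gene_id = sprintf("Gp_%s_%02d", mqtl_id, seq_len(sc$n_planted_genes)),
                     chromosome = chromosome, start_bp = start,
                     end_bp = start + 3000,
                     strand = sample(c("+", "-"), sc$n_planted_genes, replace = TRUE),
                     description = "stress-associated candidate", planted = TRUE,
                     true_mqtl = mqtl_id)
    })
    annotation <- dplyr::bind_rows(background_genes, planted_genes) %>%
      dplyr::arrange(.data$chromosome, .data$start_bp)

    # --- expression with planted fold changes -----------------------------
    stopifnot(sc$n_promising + sc$n_decoy_degs <= nrow(planted_genes))
    promising <- planted_genes$gene_id[seq_len(sc$n_promising)]
    decoys <- planted_genes$gene_id[sc$n_promising + seq_len(sc$n_decoy_degs)]
    nd <- sc$n_expression_datasets
    # promising genes respond in >= 3 datasets (the first two in all of them)
    promising_sets <- lapply(seq_along(promising), function(i) {
      if (i <= 2) seq_len(nd) else sort(sample.int(nd, 3))
    })
    decoy_sets <- lapply(seq_along(decoys), function(i) sort(sample.int(nd, sample(1:2, 1))))
    all_genes <- annotation$gene_id
    expression <- lapply(seq_len(nd), function(d) {
      did <- paste0("dataset", d)
      samples <- tibble::tibble(
        sample = c("ctrl_1", "ctrl_2", "t1_1", "t1_2", "t2_1", "t2_2"),
        condition = c("control", "control", "stress_t1", "stress_t1",
                      "stress_t2", "stress_t2"),
        control = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
      base <- stats::runif(length(all_genes), 2, 6)
      m <- matrix(rep(base, times = nrow(samples)), ncol = nrow(samples)) +
        matrix(stats::rnorm(length(all_genes) * nrow(samples), 0, 0.05),
               ncol = nrow(samples))
      rownames(m) <- all_genes
      colnames(m) <- samples$sample
      add_effect <- function(m, gene, lfc, conds) {
        cols <- samples$sample[samples$condition %in% conds]
        m[gene, cols] <- m[gene, cols] + lfc
        m
      }
      for (i in seq_along(promising)) {
        if (d %in% promising_sets[[i]]) {
          lfc <- sample(c(-1, 1), 1) * stats::runif(1, 1.5, 3)
          m <- add_effect(m, promising[i], lfc, c("stress_t1", "stress_t2"))
        }
      }
      for (i in seq_along(decoys)) {
        if (d %in% decoy_sets[[i]]) {
          lfc <- sample(c(-1, 1), 1) * stats::runif(1, 1.2, 2)
          m <- add_effect(m, decoys[i], lfc, "stress_t1")
        }
      }
      list(dataset_id = did, expr = m, samples = samples)
    })

    # --- promoters with planted motifs ------------------------------------
    motifs <- cre_motifs()
    plantable <- motifs[motifs$category %in% c("stress_responsiveness",
                                               "phytohormone_responsiveness"), ]
    promoter_genes <- planted_genes$gene_id
    planted_motifs <- list()
    promoters <- purrr::map_dfr(promoter_genes, function(g) {
      seq <- random_dna(1500)
      chosen <- plantable[sample.int(nrow(plantable), 3), ]
      offs <- sort(sample(seq(50, 1400, by = 25), 3))
      for (j in seq_len(3)) {
        seq <- plant_motif(seq, chosen$pattern[j], offs[j])
        planted_motifs[[length(planted_motifs) + 1]] <<- tibble::tibble(
          gene_id = g, motif = chosen$name[j], start = offs[j])
      }
      tibble::tibble(gene_id = g, sequence = seq, length = 1500L, truncated = FALSE)
    })

    # --- orthologues and foreign MQTLs ------------------------------------
    species <- c("rice", "maize")
    foreign_mqtls <- purrr::map_dfr(species, function(sp) {
      n <- sc$ortho_pairs_per_species
      tibble::tibble(species = sp, label = sprintf("%sMQTL%d", sp, seq_len(n)),
                     chromosome = as.character(seq_len(n)),
                     start_bp = 1e6, end_bp = 3e6,
                     stress = sample(stress_codes(expanded = TRUE), n, replace = TRUE))
    })
    mqtl_ids <- unique(planted_genes$true_mqtl)
    pair_truth <- list(); ortho_rows <- list()
    for (sp in species) {
      fsp <- foreign_mqtls[foreign_mqtls$species == sp, ]
      host <- sample(mqtl_ids, nrow(fsp))
      for (j in seq_len(nrow(fsp))) {
        genes <- planted_genes$gene_id[planted_genes$true_mqtl == host[j]][1:2]
        ortho_rows[[length(ortho_rows) + 1]] <- tibble::tibble(
          wheat_gene_id = genes, species = sp,
          foreign_gene_id = sprintf("%s_g_%s_%d", sp, host[j], seq_along(genes)),
          foreign_chromosome = fsp$chromosome[j],
          foreign_start_bp = round(stats::runif(length(genes), fsp$start_bp[j],
                                                fsp$end_bp[j] - 5000)),
          foreign_end_bp = NA_real_)
        pair_truth[[length(pair_truth) + 1]] <- tibble::tibble(
          species = sp, foreign_label = fsp$label[j], true_mqtl = host[j])
      }
      # a negative control: an orthologue well outside any foreign interval
      neg_gene <- planted_genes$gene_id[!planted_genes$true_mqtl %in% host][1]
      ortho_rows[[length(ortho_rows) + 1]] <- tibble::tibble(
        wheat_gene_id = neg_gene, species = sp,
        foreign_gene_id = paste0(sp, "_g_out"),
        foreign_chromosome = fsp$chromosome[1],
        foreign_start_bp = 8e6, foreign_end_bp = NA_real_)
    }
    ortho <- dplyr::bind_rows(ortho_rows) %>%
      dplyr::mutate(foreign_end_bp = .data$foreign_start_bp + 4000)

    list(mtas = mtas[, c("marker", "chromosome", "bp", "stress", "study_id")],
         annotation = annotation[, c("gene_id", "chromosome", "start_bp", "end_bp",
                                     "strand", "description")],
         expression = expression,
         promoters = promoters,
         ortho = ortho, foreign_mqtls = foreign_mqtls,
         truth = list(planted_genes = planted_genes,
                      promising_genes = promising,
                      decoy_genes = decoys,
                      planted_motifs = dplyr::bind_rows(planted_motifs),
                      ortho_pairs = dplyr::bind_rows(pair_truth),
                      mta_truth = mta_truth))
  })
}

#' Write a simulated scenario to disk in the pipeline's input formats
#'
#' Emits every standard input the pipeline readers consume: QTL table,
#' reference/study map TSVs, marker physical positions, MTA table, GFF3-like
#' annotation TSV, expression matrices + sample sheets, promoter FASTA,
#' orthologue and foreign-MQTL tables.
#'
#' @param studies Result of [simulate_studies()].
#' @param omics Result of [simulate_omics()] (optional).
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_scenario_files <- function(studies, omics = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  paths <- list(qtls = p("qtls.tsv"), reference_maps = p("reference_maps.tsv"),
                study_maps = p("study_maps.tsv"),
                marker_positions = p("marker_positions.tsv"))
  readr::write_tsv(studies$qtls[, qtl_columns()], paths$qtls, progress = FALSE)
  readr::write_tsv(studies$reference_maps, paths$reference_maps, progress = FALSE)
  readr::write_tsv(studies$study_maps, paths$study_maps, progress = FALSE)
  readr::write_tsv(studies$marker_positions, paths$marker_positions, progress = FALSE)
  if (!is.null(omics)) {
    paths$mtas <- p("mtas.tsv")
    readr::write_tsv(omics$mtas, paths$mtas, progress = FALSE)
    paths$annotation <- p("annotation.tsv")
    readr::write_tsv(omics$annotation, paths$annotation, progress = FALSE)
    paths$expression <- character(0)
    for (ds in omics$expression) {
      ep <- p(paste0("expr_", ds$dataset_id, ".tsv"))
      sp <- p(paste0("samples_", ds$dataset_id, ".tsv"))
      em <- tibble::as_tibble(ds$expr, rownames = "gene_id")
      readr::write_tsv(em, ep, progress = FALSE)
      readr::write_tsv(ds$samples, sp, progress = FALSE)
      paths$expression <- c(paths$expression, ep)
    }
    paths$promoters <- p("promoters.fasta")
    writeLines(paste0(">", omics$promoters$gene_id, "\n", omics$promoters$sequence),
               paths$promoters)
    paths$ortho <- p("ortho.tsv")
    readr::write_tsv(omics$ortho, paths$ortho, progress = FALSE)
    paths$foreign_mqtls <- p("foreign_mqtls.tsv")
    readr::write_tsv(omics$foreign_mqtls, paths$foreign_mqtls, progress = FALSE)
  }
  invisible(paths)
}
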