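#' Read an orthologue table
#'
#' @param path TSV with columns `wheat_gene_id`, `species` (`rice`/`maize`),
#'   `foreign_gene_id`, `foreign_chromosome`, `foreign_start_bp`,
#'   `foreign_end_bp`.
#' @return Tibble.
#' @export
read_ortho_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  tibble::tibble(wheat_gene_id = as.character(df$wheat_gene_id),
                 species = tolower(as.character(df$species)),
                 foreign_gene_id = as.character(df$foreign_gene_id),
                 foreign_chromosome = as.character(df$foreign_chromosome),
                 foreign_start_bp = as.numeric(df$foreign_start_bp),
                 foreign_end_bp = as.numeric(df$foreign_end_bp))
}

#' Read a foreign-species MQTL interval list
#'
#' @param path TSV with columns `species`, `label`, `chromosome`, `start_bp`,
#'   `end_bp`, `stress`.
#' @return Tibble.
#' @export
read_foreign_mqtls <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  tibble::tibble(species = tolower(as.character(df$species)),
                 label = as.character(df$label),
                 chromosome = as.character(df$chromosome),
                 start_bp = as.numeric(df$start_bp),
                 end_bp = as.numeric(df$end_bp),
                 stress = normalize_stress(as.character(df$stress %||% NA)))
}

#' Map wheat MQTL genes to foreign orthologues
#'
#' Joins the genes mined per wheat MQTL against an orthologue table on the
#' wheat gene id. Duplicate (wheat gene, foreign gene) rows in the table are
#' collapsed with a warning; wheat genes without any orthologue are counted
#' unmapped per MQTL.
#'
#' @param mqtl_genes Tibble from [mine_genes()] (`mqtl`, `gene_id`).
#' @param ortho Orthologue tibble ([read_ortho_table()]).
#' @return Tibble of links per (mqtl, wheat gene, species, foreign gene),
#'   with the per-MQTL unmapped counts attached as attribute `"unmapped"`.
#' @export
map_orthologues <- function(mqtl_genes, ortho) {
  mqtl_genes <- tibble::as_tibble(mqtl_genes)
  ortho <- tibble::as_tibble(ortho)
  ndup <- nrow(ortho) -
    nrow(dplyr::distinct(ortho, .data$wheat_gene_id, .data$species, .data$foreign_gene_id))
  if (ndup > 0) {
    warning(ndup, " duplicate orthologue row(s) collapsed")
    ortho <- dplyr::distinct(ortho, .data$wheat_gene_id, .data$species,
                             .data$foreign_gene_id, .keep_all = TRUE)
  }
  links <- dplyr::inner_join(
    mqtl_genes[, c("mqtl", "gene_id")], ortho,
    by = c(gene_id = "wheat_gene_id"), relationship = "many-to-many")
  unmapped <- mqtl_genes %>%
    dplyr::filter(!.data$gene_id %in% ortho$wheat_gene_id) %>%
    dplyr::count(.data$mqtl, name = "n_unmapped")
  structure(tibble::as_tibble(links), unmapped = unmapped)
}

#' Detect ortho-MQTL pairs
#'
#' A (wheat MQTL, foreign MQTL) pair is declared when at least `min_genes`
#' orthologue links of the wheat MQTL fall inside the foreign MQTL interval
#' (any-overlap of the foreign gene's span with the interval, same species
#' and chromosome).
#'
#' @param links Orthologue links from [map_orthologues()].
#' @param foreign_mqtls Foreign MQTL intervals ([read_foreign_mqtls()]).
#' @param min_genes Minimum shared orthologues to declare a pair (default 1).
#' @return Tibble: `mqtl`, `species`, `foreign_label`, `n_shared_genes`,
#'   `shared_genes` (semicolon-joined foreign gene ids).
#' @export
detect_ortho_mqtls <- function(links, foreign_mqtls, min_genes = 1) {
  links <- tibble::as_tibble(links)
  foreign_mqtls <- tibble::as_tibble(foreign_mqtls)
  empty <- tibble::tibble(mqtl = character(), species = character(),
                          foreign_label = character(),
                          n_shared_genes = integer(), shared_genes = character())
  if (nrow(links) == 0 || nrow(foreign_mqtls) == 0 || !is.finite(min_genes)) {
    if (!is.finite(min_genes)) return(empty)
  }
  if (nrow(links) == 0 || nrow(foreign_mqtls) == 0) return(empty)
  joined <- dplyr::inner_join(
    links, foreign_mqtls,
    by = c(species = "species", foreign_chromosome = "chromosome"),
    relationship = "many-to-many") %>%
    dplyr::filter(.data$foreign_end_bp >= .data$start_bp,
                  .data$foreign_start_bp <= .data$end_bp)
  if (nrow(joined) == 0) return(empty)
  joined %>%
    dplyr::group_by(.data$mqtl, .data$species, foreign_label = .data$label) %>%
    dplyr::summarise(
      n_shared_genes = dplyr::n_distinct(.data$foreign_gene_id),
      shared_genes = paste(sort(unique(.data$foreign_gene_id)), collapse = ";"),
      .groups = "drop") %>%
    dplyr::filter(.data$n_shared_genes >= min_genes) %>%
    dplyr::arrange(.data$mqtl, .data$species, .data$foreign_label)
}
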