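#' Genetic maps and consensus maps
#'
#' A genetic map is a tibble with columns `map_id`, `chromosome`, `marker`,
#' `pos_cm` (cM, non-decreasing within a chromosome). A consensus map has the
#' same shape plus provenance columns: `n_maps`, `maps` (comma-joined source
#' map ids), `anchor` (marker shared by at least two source maps) and
#' `order_conflict` (consensus order disagrees with the frame map's order).
#'
#' @name genetic_map
NULL

#' Read a genetic map table (TSV)
#'
#' @param path TSV with columns `map_id` (optional), `chromosome`, `marker`,
#'   `pos_cm`.
#' @param map_id Map id to assign when the file has no `map_id` column;
#'   defaults to the file name.
#' @return A genetic-map tibble.
#' @export
read_map_table <- function(path, map_id = NULL) {
  if (!file.exists(path)) stop("map table not found: ", path)
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!"map_id" %in% names(df)) {
    df$map_id <- map_id %||% sub("\\.[^.]*$", "", basename(path))
  }
  tibble::tibble(
    map_id = as.character(df$map_id),
    chromosome = normalize_chromosome(df$chromosome),
    marker = as.character(df$marker),
    pos_cm = as.numeric(df$pos_cm)
  )
}

#' Write a genetic or consensus map table (TSV)
#'
#' @param map Map tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_table <- function(map, path) {
  readr::write_tsv(map, path, progress = FALSE)
  invisible(path)
}

# piecewise-linear transfer of positions x through control points (src -> dst);
# end segments extrapolate; zero-length source segments fall back to scale 1
interp_positions <- function(x, src, dst) {
  stopifnot(length(src) == length(dst), length(src) >= 2)
  o <- order(src)
  src <- src[o]; dst <- dst[o]
  i <- findInterval(x, src, all.inside = TRUE)
  den <- src[i + 1] - src[i]
  scale <- ifelse(den > 0, (dst[i + 1] - dst[i]) / den, 1)
  dst[i] + (x - src[i]) * scale
}

#' Build a consensus map from several linkage maps
#'
#' Merges maps chromosome by chromosome with an anchor-average algorithm:
#' each source map is shifted so its chromosome starts at 0; markers shared by
#' two or more maps (anchors) are placed at the weighted mean of their shifted
#' positions; every remaining marker is placed by piecewise-linear
#' interpolation between its flanking anchors on its own source map (end
#' segments extrapolate). The densest map on a chromosome is the frame map:
#' anchors whose consensus order disagrees with the frame order are flagged
#' `order_conflict`. Maps contributing fewer than two anchors on a chromosome
#' cannot be rescaled; their private markers are reported unplaced
#' (`reason = "unanchored"`) rather than guessed.
#'
#' @param maps One genetic-map tibble (rows from several `map_id`s) or a list
#'   of such tibbles, which are row-bound.
#' @param weights Optional named numeric vector of per-map weights; defaults
#'   to each map's marker count on the chromosome being merged.
#' @return A consensus-map tibble (chromosome positions start at 0, sorted),
#'   with the unplaced-marker report attached as attribute `"unplaced"`.
#' @export
build_consensus <- function(maps, weights = NULL) {
  if (is.list(maps) && !is.data.frame(maps)) maps <- dplyr::bind_rows(maps)
  maps <- tibble::as_tibble(maps)
  stopifnot(all(c("map_id", "chromosome", "marker", "pos_cm") %in% names(maps)))
  maps <- dplyr::distinct(maps, .data$map_id, .data$chromosome, .data$marker, .keep_all = TRUE)

  out <- list(); unplaced <- list()
  for (chrom in unique(maps$chromosome)) {
    mc <- maps[maps$chromosome == chrom, , drop = FALSE]
    mc <- mc %>%
      dplyr::group_by(.data$map_id) %>%
      dplyr::arrange(.data$pos_cm, .by_group = TRUE) %>%
      dplyr::mutate(pos0 = .data$pos_cm - min(.data$pos_cm)) %>%
      dplyr::ungroup()
    counts <- table(mc$map_id)
    w <- if (is.null(weights)) as.numeric(counts[mc$map_id]) else unname(weights[mc$map_id])
    mc$w <- w
    frame_id <- names(counts)[which.max(counts)]

    n_maps_per_marker <- mc %>% dplyr::count(.data$marker, name = "n_maps")
    mc <- dplyr::left_join(mc, n_maps_per_marker, by = "marker")
    single_map <- length(counts) == 1

    anchors <- mc %>%
      dplyr::filter(.data$n_maps >= 2) %>%
      dplyr::group_by(.data$marker) %>%
      dplyr::summarise(cons = sum(.data$pos0 * .data$w) / sum(.data$w),
                       n_maps = .data$n_maps[1],
                       maps = paste(sort(unique(.data$map_id)), collapse = ","),
                       .groups = "drop")

    if (!single_map && nrow(anchors) < 2) {
      # too few shared anchors to rescale anything: the frame map is the
      # backbone; every non-frame marker is reported unanchored
      fr <- mc[mc$map_id == frame_id, , drop = FALSE]
      res <- tibble::tibble(chromosome = chrom, marker = fr$marker,
                            pos_cm = fr$pos0,
                            n_maps = as.integer(fr$n_maps),
                            maps = frame_id,
                            anchor = fr$n_maps >= 2, order_conflict = FALSE)
      res <- dplyr::arrange(res, .data$pos_cm, .data$marker)
      rest <- mc[mc$map_id != frame_id & !mc$marker %in% fr$marker, , drop = FALSE]
      if (nrow(rest) > 0) {
        unplaced[[paste(chrom, "lowanchor")]] <- tibble::tibble(
          map_id = rest$map_id, chromosome = chrom, marker = rest$marker,
          reason = "unanchored")
      }
      out[[chrom]] <- res
      next
    }

    placed <- list()
    if (nrow(anchors) > 0) {
      placed[["anchors"]] <- tibble::tibble(
        chromosome = chrom, marker = anchors$marker, pos_cm = anchors$cons,
        n_maps = anchors$n_maps, maps = anchors$maps, anchor = TRUE)
    }
    for (mid in names(counts)) {
      sub <- mc[mc$map_id == mid, , drop = FALSE]
      own_anchors <- sub[sub$marker %in% anchors$marker, , drop = FALSE]
      rest <- sub[!sub$marker %in% anchors$marker, , drop = FALSE]
      if (nrow(rest) == 0) next
      if (single_map) {
        placed[[mid]] <- tibble::tibble(
          chromosome = chrom, marker = rest$marker, pos_cm = rest$pos0,
          n_maps = 1L, maps = mid, anchor = FALSE)
      } else if (nrow(own_anchors) >= 2) {
        cons_at <- anchors$cons[match(own_anchors$marker, anchors$marker)]
        placed[[mid]] <- tibble::tibble(
          chromosome = chrom, marker = rest$marker,
          pos_cm = interp_positions(rest$pos0, own_anchors$pos0, cons_at),
          n_maps = 1L, maps = mid, anchor = FALSE)
      } else {
        unplaced[[paste(chrom, mid)]] <- tibble::tibble(
          map_id = mid, chromosome = chrom, marker = rest$marker,
          reason = "unanchored")
      }
    }
    res <- dplyr::bind_rows(placed)
    if (nrow(res) == 0) next
    res$pos_cm <- res$pos_cm - min(res$pos_cm)
    res <- dplyr::arrange(res, .data$pos_cm, .data$marker)

    # flag anchors whose consensus order contradicts the frame map's order
    frame_markers <- mc$marker[mc$map_id == frame_id][order(mc$pos0[mc$map_id == frame_id])]
    in_frame <- res$marker[res$marker %in% frame_markers]
    frame_rank <- match(in_frame, frame_markers)
    # a marker conflicts if its frame rank breaks monotonicity in consensus order
    mono <- cummax(frame_rank)
    conflict_markers <- in_frame[frame_rank < mono]
    res$order_conflict <- res$marker %in% conflict_markers
    out[[chrom]] <- res
  }
  cons <- dplyr::bind_rows(out)
  structure(cons, unplaced = dplyr::bind_rows(unplaced),
            class = c("consensus_map", class(cons)))
}

#' Look up a marker on a consensus map
#'
#' Exact, case-sensitive lookup by default; set `case_fold = TRUE` to match
#' marker names case-insensitively (marker names like `Xgwm635` vs `xGWM635`
#' differ between publications).
#'
#' @param cmap Consensus-map tibble.
#' @param marker Marker name (scalar).
#' @param case_fold Fold case before matching.
#' @return A one-row tibble (`chromosome`, `pos_cm`) or a zero-row tibble if
#'   absent.
#' @export
marker_lookup <- function(cmap, marker, case_fold = FALSE) {
  hit <- if (case_fold) tolower(cmap$marker) == tolower(marker) else cmap$marker == marker
  tibble::as_tibble(cmap[hit, c("chromosome", "pos_cm")])
}

#' Inject extra markers into a consensus map by interpolation
#'
#' Markers present on per-study maps but absent from the consensus (typically
#' QTL flanking markers) are added at positions interpolated between the
#' markers their source map shares with the consensus. When several maps can
#' place a marker, the placements are averaged.
#'
#' @param cmap Consensus map from [build_consensus()].
#' @param maps Genetic-map tibble of source maps.
#' @return The augmented consensus map (injected rows carry `anchor = FALSE`
#'   and `maps = "injected:<map_id>"`).
#' @export
augment_consensus <- function(cmap, maps) {
  maps <- tibble::as_tibble(maps)
  additions <- list()
  for (chrom in unique(maps$chromosome)) {
    cc <- cmap[cmap$chromosome == chrom, , drop = FALSE]
    if (nrow(cc) < 2) next
    mc <- maps[maps$chromosome == chrom, , drop = FALSE]
    for (mid in unique(mc$map_id)) {
      sub <- mc[mc$map_id == mid, , drop = FALSE]
      shared <- sub[sub$marker %in% cc$marker, , drop = FALSE]
      new <- sub[!sub$marker %in% cc$marker, , drop = FALSE]
      if (nrow(shared) < 2 || nrow(new) == 0) next
      cons_at <- cc$pos_cm[match(shared$marker, cc$marker)]
      additions[[paste(chrom, mid)]] <- tibble::tibble(
        chromosome = chrom, marker = new$marker,
        pos_cm = pmax(0, interp_positions(new$pos_cm, shared$pos_cm, cons_at)),
        n_maps = 1L, maps = paste0("injected:", mid),
        anchor = FALSE, order_conflict = FALSE)
    }
  }
  add <- dplyr::bind_rows(additions)
  if (nrow(add) == 0) return(cmap)
  add <- add %>%
    dplyr::group_by(.data$chromosome, .data$marker) %>%
    dplyr::summarise(pos_cm = mean(.data$pos_cm), n_maps = 1L,
                     maps = paste(unique(.data$maps), collapse = ","),
                     anchor = FALSE, order_conflict = FALSE, .groups = "drop")
  res <- dplyr::bind_rows(tibble::as_tibble(cmap), add) %>%
    dplyr::arrange(.data$chromosome, .data$pos_cm, .data$marker)
  structure(res, unplaced = attr(cmap, "unplaced", exact = TRUE),
            class = c("consensus_map", class(res)))
}
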