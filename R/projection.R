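#' Projection configuration
#'
#' Thresholds governing QTL projection onto the consensus map.
#'
#' * `max_ratio` — maximum allowed ratio between the lengths of the flanking
#'   common-marker interval on the consensus and on the source map (whichever
#'   way round is larger). Contexts stretching or shrinking more than this are
#'   not trusted.
#' * `min_p` — threshold for the two-interval proportionality z-test applied
#'   when the CI endpoints fall in different common-marker intervals; contexts
#'   whose local scales are grossly inconsistent are rejected.
#' * `max_ci_cm` — QTLs whose projected 95% CI is wider than this are
#'   rejected (`"large_CI"`), matching the practice of dropping QTLs whose
#'   intervals are too diffuse to contribute to meta-analysis.
#' * `case_fold` — fold case when matching marker names across maps.
#'
#' @param max_ratio,min_p,max_ci_cm,case_fold See above.
#' @return Named list.
#' @export
projection_config <- function(max_ratio = 5, min_p = 0.05, max_ci_cm = 50,
                              case_fold = FALSE) {
  stopifnot(max_ratio >= 1, min_p > 0, min_p < 1, max_ci_cm > 0)
  list(max_ratio = max_ratio, min_p = min_p, max_ci_cm = max_ci_cm,
       case_fold = case_fold)
}

# common markers of a source-map chromosome and the consensus, ordered by
# source position; returns tibble(marker, src, cons)
common_markers <- function(smap_chr, cmap_chr, case_fold = FALSE) {
  sm <- if (case_fold) tolower(smap_chr$marker) else smap_chr$marker
  cm <- if (case_fold) tolower(cmap_chr$marker) else cmap_chr$marker
  idx <- match(sm, cm)
  keep <- !is.na(idx)
  out <- tibble::tibble(marker = smap_chr$marker[keep],
                        src = smap_chr$pos_cm[keep],
                        cons = cmap_chr$pos_cm[idx[keep]])
  dplyr::arrange(dplyr::distinct(out, .data$marker, .keep_all = TRUE), .data$src)
}

#' Select a projection context for one QTL
#'
#' Among pairs of common markers flanking the QTL peak on the source map, the
#' pair whose source and consensus interval lengths agree best (smallest
#' `|log(Lcons/Lsrc)|`) subject to the ratio cap is chosen; enumeration over
#' all flanking pairs implements the widening outward search. Ties go to the
#' tighter pair.
#'
#' @param peak_cm QTL peak on the source map.
#' @param common Common-marker table from two maps (columns `marker`, `src`,
#'   `cons`), as built internally by [project_qtls()].
#' @param src_span Range (length-2 numeric) of the full source-map chromosome.
#' @param cfg [projection_config()].
#' @return A list with `status = "ok"` and the context (`left`, `right`,
#'   source/consensus positions, `scale`), or `status = "rejected"` and a
#'   `reason` (`"no_common_markers"`, `"peak_out_of_map"`,
#'   `"no_feasible_context"`).
#' @export
select_projection_context <- function(peak_cm, common, src_span, cfg = projection_config()) {
  reject <- function(reason) list(status = "rejected", reason = reason)
  if (is.na(peak_cm)) return(reject("missing_peak"))
  if (peak_cm < src_span[1] || peak_cm > src_span[2]) return(reject("peak_out_of_map"))
  if (nrow(common) < 2) return(reject("no_common_markers"))
  left <- which(common$src <= peak_cm)
  right <- which(common$src >= peak_cm)
  if (length(left) == 0 || length(right) == 0) return(reject("no_common_markers"))
  best <- NULL
  for (l in left) {
    for (r in right) {
      ls <- common$src[r] - common$src[l]
      lc <- common$cons[r] - common$cons[l]
      if (ls <= 0 || lc <= 0) next
      ratio <- max(lc / ls, ls / lc)
      if (ratio > cfg$max_ratio) next
      disc <- abs(log(lc / ls))
      if (is.null(best) || disc < best$disc - 1e-12 ||
          (abs(disc - best$disc) <= 1e-12 && ls < best$ls)) {
        best <- list(l = l, r = r, ls = ls, lc = lc, disc = disc)
      }
    }
  }
  if (is.null(best)) return(reject("no_feasible_context"))
  list(status = "ok",
       left = common$marker[best$l], right = common$marker[best$r],
       src_left = common$src[best$l], src_right = common$src[best$r],
       cons_left = common$cons[best$l], cons_right = common$cons[best$r],
       scale = best$lc / best$ls)
}

# two-interval proportionality z-test: are the local scales at the two CI
# endpoints consistent with each other, given the spread of local scales
# along the chromosome?
scale_homogeneity_p <- function(ci_src, common) {
  if (nrow(common) < 3) return(1)
  seg <- findInterval(ci_src, common$src, all.inside = TRUE)
  if (seg[1] == seg[2]) return(1)
  d_src <- diff(common$src); d_cons <- diff(common$cons)
  ok <- d_src > 0 & d_cons > 0
  if (sum(ok) < 2 || !all(ok[seg])) return(1)
  logs <- log(d_cons[ok] / d_src[ok])
  s <- max(stats::sd(logs), 0.25) # floor keeps near-identical maps from over-rejecting
  z <- abs(log(d_cons[seg[1]] / d_src[seg[1]]) - log(d_cons[seg[2]] / d_src[seg[2]])) / (s * sqrt(2))
  2 * stats::pnorm(-z)
}

#' Project one QTL through a context
#'
#' The peak maps through the affine transform defined by the context markers'
#' positions on the two maps. CI endpoints map through the piecewise-linear
#' transform over all common markers (so endpoints outside the chosen context
#' use their own nearest flanking common interval). Projections whose CI
#' exceeds `max_ci_cm` are rejected as `"large_CI"`.
#'
#' @param peak_cm,ci_start_cm,ci_end_cm Source-map coordinates.
#' @param context Context from [select_projection_context()].
#' @param common Common-marker table (as in [select_projection_context()]).
#' @param cfg [projection_config()].
#' @return List: `status` plus either projected `peak_cm`, `ci_start_cm`,
#'   `ci_end_cm` or a `reason`.
#' @export
project_qtl <- function(peak_cm, ci_start_cm, ci_end_cm, context, common,
                        cfg = projection_config()) {
  if (!identical(context$status, "ok")) return(context)
  if (context$src_right - context$src_left <= 0) {
    return(list(status = "rejected", reason = "degenerate_context"))
  }
  p <- scale_homogeneity_p(c(ci_start_cm, ci_end_cm), common)
  if (p < cfg$min_p) return(list(status = "rejected", reason = "heterogeneous_context"))
  tr_peak <- context$cons_left +
    (peak_cm - context$src_left) * context$scale
  ci <- interp_positions(c(ci_start_cm, ci_end_cm), common$src, common$cons)
  ci <- sort(ci)
  lo <- min(ci[1], tr_peak); hi <- max(ci[2], tr_peak)
  if (hi - lo > cfg$max_ci_cm) return(list(status = "rejected", reason = "large_CI"))
  list(status = "projected", peak_cm = tr_peak, ci_start_cm = lo, ci_end_cm = hi)
}

#' Project all QTLs onto the consensus map
#'
#' Batch driver over a QTL table: resolves each record's source map (the map
#' whose `map_id` equals its `study_id`), selects a projection context and
#' projects peak and CI. Nothing is silently dropped: every record comes back
#' with a `status` (`projected` or `rejected`) and a `reason`, and an
#' accounting report is attached as attribute `"report"`.
#'
#' @param qtls QTL tibble after [impute_defaults()] and [estimate_ci()].
#' @param maps Genetic-map tibble of all source maps.
#' @param cmap Consensus map.
#' @param cfg [projection_config()].
#' @return Tibble with one row per input QTL: source columns, consensus
#'   coordinates (`peak_cm`, `ci_start_cm`, `ci_end_cm`), context columns
#'   (`left_common`, `right_common`, `scale`), `status`, `reason`.
#' @export
project_qtls <- function(qtls, maps, cmap, cfg = projection_config()) {
  qtls <- tibble::as_tibble(qtls)
  if (!"unprojectable" %in% names(qtls)) qtls$unprojectable <- FALSE
  maps <- tibble::as_tibble(maps)

  res <- vector("list", nrow(qtls))
  common_cache <- new.env(parent = emptyenv())
  span_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(qtls))) {
    q <- qtls[i, ]
    base <- tibble::tibble(
      qtl_id = q$qtl_id, study_id = q$study_id, chromosome = q$chromosome,
      stress = q$stress, trait = q$trait %||% NA_character_,
      population_type = q$population_type, population_size = q$population_size,
      lod = q$lod, pve = q$pve,
      src_peak_cm = q$peak_cm, src_ci_start_cm = q$ci_start_cm,
      src_ci_end_cm = q$ci_end_cm,
      peak_cm = NA_real_, ci_start_cm = NA_real_, ci_end_cm = NA_real_,
      left_common = NA_character_, right_common = NA_character_,
      scale = NA_real_, status = "rejected", reason = NA_character_)
    if (isTRUE(q$unprojectable) || is.na(q$peak_cm) ||
        is.na(q$ci_start_cm) || is.na(q$ci_end_cm)) {
      base$reason <- "incomplete"
      res[[i]] <- base
      next
    }
    key <- paste(q$study_id, q$chromosome, sep = "\r")
    if (is.null(common_cache[[key]])) {
      smap_chr <- maps[maps$map_id == q$study_id & maps$chromosome == q$chromosome, ]
      cmap_chr <- cmap[cmap$chromosome == q$chromosome, ]
      common_cache[[key]] <- common_markers(smap_chr, cmap_chr, cfg$case_fold)
      span_cache[[key]] <- if (nrow(smap_chr) > 0) range(smap_chr$pos_cm) else c(NA_real_, NA_real_)
    }
    common <- common_cache[[key]]
    span <- span_cache[[key]]
    if (any(is.na(span))) {
      base$reason <- "no_source_map"
      res[[i]] <- base
      next
    }
    ctx <- select_projection_context(q$peak_cm, common, span, cfg)
    pr <- project_qtl(q$peak_cm, q$ci_start_cm, q$ci_end_cm, ctx, common, cfg)
    if (identical(pr$status, "projected")) {
      base$status <- "projected"
      base$peak_cm <- pr$peak_cm
      base$ci_start_cm <- pr$ci_start_cm
      base$ci_end_cm <- pr$ci_end_cm
      base$left_common <- ctx$left
      base$right_common <- ctx$right
      base$scale <- ctx$scale
      base$reason <- NA_character_
    } else {
      base$reason <- pr$reason
    }
    res[[i]] <- base
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(qtl_id = character(), study_id = character(),
                          chromosome = character(), stress = character(),
                          status = character(), reason = character(),
                          peak_cm = numeric(), ci_start_cm = numeric(),
                          ci_end_cm = numeric())
  }
  report <- list(
    total = nrow(out),
    usable = sum(out$reason %in% "incomplete" == FALSE),
    projected = sum(out$status == "projected"),
    reasons = out %>%
      dplyr::filter(.data$status != "projected") %>%
      dplyr::count(.data$reason, name = "n"),
    per_chromosome = out %>%
      dplyr::count(.data$chromosome, .data$status, name = "n"))
  structure(out, report = report, class = c("projected_qtl_tbl", class(out)))
}

#' Projection accounting report
#'
#' @param x Result of [project_qtls()].
#' @return List with `total`, `usable`, `projected`, per-reason and
#'   per-chromosome counts.
#' @export
projection_report <- function(x) attr(x, "report", exact = TRUE)
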