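#' Marker physical-position tables
#'
#' A tibble mapping markers to 1-based physical positions: columns `marker`,
#' `chromosome`, `bp`. Read/written as TSV.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_marker_positions <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  tibble::tibble(marker = as.character(df$marker),
                 chromosome = normalize_chromosome(df$chromosome),
                 bp = as.numeric(df$bp))
}

#' Estimate the physical peak position of an MQTL
#'
#' Given the physical positions of the markers anchoring an MQTL's genetic CI
#' and their genetic positions, the peak is placed at
#' `start_bp + (end_bp - start_bp) / (end_cm - start_cm) * ci95 / 2`,
#' i.e. the genetic half-CI converted through the local bp-per-cM rate,
#' clamped into `[start_bp, end_bp]`. When the genetic span is zero (a
#' 0.00-cM CI), the bp midpoint is returned.
#'
#' @param start_bp,end_bp Physical positions of the anchoring markers.
#' @param start_cm,end_cm Their genetic positions (cM).
#' @param ci95_cm Width of the MQTL's 95% genetic CI (cM).
#' @return Peak position in bp (vectorised).
#' @export
peak_position_bp <- function(start_bp, end_bp, start_cm, end_cm, ci95_cm) {
  span_cm <- end_cm - start_cm
  peak <- ifelse(span_cm > 0,
                 start_bp + (end_bp - start_bp) / span_cm * ci95_cm / 2,
                 (start_bp + end_bp) / 2)
  pmin(pmax(peak, start_bp), end_bp)
}

#' Anchor MQTLs on the physical genome
#'
#' For each MQTL, the physical interval is bounded by the nearest consensus
#' markers at or outside the genetic CI endpoints that have a physical
#' position on the MQTL's chromosome. When no marker at/left of the start (or
#' at/right of the end) is resolvable, the nearest resolvable marker on the
#' other side of the endpoint is used and the MQTL is flagged
#' `extended_left`/`extended_right`. MQTLs with no resolvable markers, or
#' whose flanks resolve to different physical chromosomes, are returned
#' unanchored with a reason.
#'
#' @param mqtls MQTL tibble from [meta_qtl()].
#' @param cmap Consensus map.
#' @param phys Marker physical-position tibble ([read_marker_positions()]).
#' @return The MQTL tibble with added columns `start_bp`, `end_bp`,
#'   `peak_bp`, `anchored` (logical), `anchor_note`.
#' @export
anchor_mqtls <- function(mqtls, cmap, phys) {
  mqtls <- tibble::as_tibble(mqtls)
  phys <- tibble::as_tibble(phys)
  n <- nrow(mqtls)
  start_bp <- end_bp <- peak_bp <- rep(NA_real_, n)
  note <- rep(NA_character_, n)
  anchored <- rep(FALSE, n)
  for (i in seq_len(n)) {
    chrom <- mqtls$chromosome[i]
    cm <- cmap[cmap$chromosome == chrom, c("marker", "pos_cm")]
    ph <- phys[phys$chromosome == chrom, ]
    cm <- cm[cm$marker %in% ph$marker, , drop = FALSE]
    if (nrow(cm) == 0) { note[i] <- "no_physical_markers"; next }
    cm$bp <- ph$bp[match(cm$marker, ph$marker)]
    lo <- mqtls$ci_start_cm[i]; hi <- mqtls$ci_end_cm[i]
    flags <- character(0)
    left_cand <- cm[cm$pos_cm <= lo, , drop = FALSE]
    if (nrow(left_cand) > 0) {
      left <- left_cand[which.max(left_cand$pos_cm), ]
    } else {
      left <- cm[which.min(cm$pos_cm), ]
      flags <- c(flags, "extended_left")
    }
    right_cand <- cm[cm$pos_cm >= hi, , drop = FALSE]
    if (nrow(right_cand) > 0) {
      right <- right_cand[which.min(right_cand$pos_cm), ]
    } else {
      right <- cm[which.max(cm$pos_cm), ]
      flags <- c(flags, "extended_right")
    }
    s <- min(left$bp, right$bp); e <- max(left$bp, right$bp)
    start_bp[i] <- s; end_bp[i] <- e
    peak_bp[i] <- peak_position_bp(s, e, min(left$pos_cm, right$pos_cm),
                                   max(left$pos_cm, right$pos_cm),
                                   hi - lo)
    anchored[i] <- TRUE
    if (length(flags) > 0) note[i] <- paste(flags, collapse = ";")
  }
  mqtls$start_bp <- start_bp
  mqtls$end_bp <- end_bp
  mqtls$peak_bp <- peak_bp
  mqtls$anchored <- anchored
  mqtls$anchor_note <- note
  mqtls
}

#' Write anchored MQTLs as BED
#'
#' Converts the 1-based inclusive physical intervals to BED's 0-based
#' half-open convention; the name column is the MQTL id and the score column
#' its mean PVE.
#'
#' @param mqtls Anchored MQTL tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mqtl_bed <- function(mqtls, path) {
  anc <- mqtls[mqtls$anchored %||% TRUE, , drop = FALSE]
  anc <- anc[!is.na(anc$start_bp), , drop = FALSE]
  bed <- tibble::tibble(chrom = anc$chromosome,
                        start = as.integer(anc$start_bp - 1),
                        end = as.integer(anc$end_bp),
                        name = anc$mqtl,
                        score = round(anc$mean_pve, 2))
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
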