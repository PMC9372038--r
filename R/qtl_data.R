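#' QTL tables
#'
#' A QTL table holds one row per published QTL with the canonical columns
#' `qtl_id`, `study_id`, `population_type` (F2, BC, DH, RIL or other),
#' `population_size`, `stress` (see [stress_codes()]), `trait`, `chromosome`,
#' `left_marker`, `right_marker`, `peak_cm`, `ci_start_cm`, `ci_end_cm`,
#' `lod`, `pve` (percent of phenotypic variance explained, in (0, 100]).
#' Rows that fail validation are never silently dropped: they are collected
#' into a rejects report attached to the returned tibble (see [rejects()]),
#' mirroring the explicit attrition accounting meta-QTL studies publish.
#'
#' @name qtl_table
NULL

qtl_columns <- function() {
  c("qtl_id", "study_id", "population_type", "population_size", "stress",
    "trait", "chromosome", "left_marker", "right_marker",
    "peak_cm", "ci_start_cm", "ci_end_cm", "lod", "pve")
}

qtl_mandatory_columns <- function() {
  c("study_id", "chromosome", "left_marker", "right_marker")
}

#' Read a QTL table from TSV or CSV
#'
#' @param path Path to a delimited file with a header row. Tab-delimited by
#'   default; comma used when the file extension is `.csv` or `delim = ","`.
#' @param delim Field delimiter; guessed from the extension when `NULL`.
#' @return A validated QTL tibble (valid rows only) with the rejects report
#'   attached; retrieve it with [rejects()].
#' @export
read_qtl_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("QTL table not found: ", path)
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  validate_qtls(raw)
}

#' Write a QTL table to TSV
#'
#' @param qtls A QTL tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qtl_table <- function(qtls, path) {
  readr::write_tsv(qtls[, intersect(qtl_columns(), names(qtls))], path, progress = FALSE)
  invisible(path)
}

#' Write a rejects report to TSV
#'
#' @param qtls A validated QTL tibble (or any object carrying a rejects report).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rejects <- function(qtls, path) {
  readr::write_tsv(rejects(qtls) %||% tibble::tibble(), path, progress = FALSE)
  invisible(path)
}

#' Rejected rows of a validated table
#'
#' @param x An object returned by [validate_qtls()] or [read_qtl_table()].
#' @return A tibble of rejected rows with a `reason` column, or `NULL`.
#' @export
rejects <- function(x) attr(x, "rejects", exact = TRUE)

num_or_na <- function(x) suppressWarnings(as.numeric(x))
int_or_na <- function(x) suppressWarnings(as.integer(as.numeric(x)))

#' Validate QTL records
#'
#' Coerces columns to their canonical types, normalises chromosome and stress
#' labels, and splits rows into valid records and rejects with a reason
#' (`"unknown chromosome"`, `"inverted CI"`, `"invalid stress"`, ...).
#' Missing mandatory columns (study_id, chromosome, flanking markers) are a
#' hard error naming the column.
#'
#' @param df A data frame of raw QTL rows (character columns are fine).
#' @return Tibble of valid records in canonical column order, with the
#'   rejects tibble attached as an attribute (see [rejects()]).
#' @export
validate_qtls <- function(df) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(qtl_mandatory_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("QTL table is missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(qtl_columns(), names(df))) df[[col]] <- NA
  out <- tibble::tibble(
    qtl_id          = as.character(df$qtl_id),
    study_id        = as.character(df$study_id),
    population_type = toupper(trimws(as.character(df$population_type))),
    population_size = int_or_na(df$population_size),
    stress          = normalize_stress(as.character(df$stress)),
    trait           = as.character(df$trait),
    chromosome      = normalize_chromosome(df$chromosome),
    left_marker     = as.character(df$left_marker),
    right_marker    = as.character(df$right_marker),
    peak_cm         = num_or_na(df$peak_cm),
    ci_start_cm     = num_or_na(df$ci_start_cm),
    ci_end_cm       = num_or_na(df$ci_end_cm),
    lod             = num_or_na(df$lod),
    pve             = num_or_na(df$pve)
  )
  out$population_type[is.na(out$population_type) |
                        !out$population_type %in% c("F2", "BC", "DH", "RIL")] <- "other"
  if (all(is.na(out$qtl_id))) out$qtl_id <- paste0("QTL", seq_len(nrow(out)))

  reason <- rep(NA_character_, nrow(out))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  flag(!out$chromosome %in% wheat_chromosomes(), "unknown chromosome")
  flag(!out$stress %in% stress_codes(), "invalid stress")
  flag(!is.na(out$population_size) & out$population_size < 2, "population size < 2")
  flag(!is.na(out$ci_start_cm) & !is.na(out$ci_end_cm) &
         out$ci_start_cm > out$ci_end_cm, "inverted CI")
  flag(!is.na(out$peak_cm) & out$peak_cm < 0, "negative peak position")
  flag(!is.na(out$pve) & (out$pve <= 0 | out$pve > 100), "PVE outside (0, 100]")
  flag(is.na(out$study_id) | out$study_id == "", "missing study_id")
  flag(is.na(out$left_marker) | is.na(out$right_marker) |
         out$left_marker == "" | out$right_marker == "", "missing flanking marker")

  bad <- !is.na(reason)
  rej <- out[bad, , drop = FALSE]
  rej$reason <- reason[bad]
  valid <- out[!bad, , drop = FALSE]
  dup <- duplicated(valid$qtl_id)
  if (any(dup)) {
    valid$qtl_id[dup] <- paste0(valid$qtl_id[dup], "_dup", seq_len(sum(dup)))
  }
  structure(valid, rejects = rej, class = c("qtl_tbl", class(valid)))
}

#' Impute missing LOD, PVE and peak position
#'
#' Published QTL tables frequently omit the LOD score or the PVE; the
#' convention adopted here assigns LOD 3.0 and PVE 10 where absent. A missing
#' peak position is imputed as the midpoint of the two flanking markers on the
#' QTL's source map; if the peak is missing and a flanking marker cannot be
#' resolved on that map, the record is flagged `unprojectable`.
#'
#' @param qtls A validated QTL tibble.
#' @param maps Optional genetic maps tibble (`map_id`, `chromosome`, `marker`,
#'   `pos_cm`) used to resolve flanking markers; a record's source map is the
#'   map whose `map_id` equals its `study_id`.
#' @param default_lod,default_pve Values assigned where missing.
#' @return The tibble with imputed values plus logical flag columns
#'   `imputed_lod`, `imputed_pve`, `imputed_peak`, `unprojectable`.
#' @export
impute_defaults <- function(qtls, maps = NULL, default_lod = 3.0, default_pve = 10) {
  qtls <- tibble::as_tibble(qtls)
  qtls$imputed_lod <- is.na(qtls$lod)
  qtls$imputed_pve <- is.na(qtls$pve)
  qtls$lod[qtls$imputed_lod] <- default_lod
  qtls$pve[qtls$imputed_pve] <- default_pve
  qtls$imputed_peak <- is.na(qtls$peak_cm)
  if (!"unprojectable" %in% names(qtls)) qtls$unprojectable <- FALSE

  need <- which(qtls$imputed_peak)
  if (length(need) > 0 && !is.null(maps)) {
    key <- paste(maps$map_id, maps$chromosome, maps$marker, sep = "\r")
    pos <- stats::setNames(maps$pos_cm, key)
    lpos <- unname(pos[paste(qtls$study_id[need], qtls$chromosome[need], qtls$left_marker[need], sep = "\r")])
    rpos <- unname(pos[paste(qtls$study_id[need], qtls$chromosome[need], qtls$right_marker[need], sep = "\r")])
    mid <- (lpos + rpos) / 2
    ok <- !is.na(mid)
    qtls$peak_cm[need[ok]] <- mid[ok]
    qtls$unprojectable[need[!ok]] <- TRUE
  } else if (length(need) > 0) {
    qtls$unprojectable[need] <- TRUE
  }
  qtls
}

#' Population-specific CI constants
#'
#' Constants `k` for the 95% confidence-interval width equation
#' `CI = k / (N * R2)`, with `N` the mapping-population size and `R2` the
#' proportion of phenotypic variance explained (PVE/100). Defaults follow the
#' Darvasi-Soller lineage of empirical equations: 530 for F2 and backcross,
#' 287 for doubled-haploid, 163 for RIL populations; `other` falls back to
#' the DH constant.
#'
#' @param F2,BC,DH,RIL,other Positive constants per population type.
#' @return Named list of constants.
#' @export
ci_config <- function(F2 = 530, BC = 530, DH = 287, RIL = 163, other = 287) {
  k <- list(F2 = F2, BC = BC, DH = DH, RIL = RIL, other = other)
  stopifnot(all(vapply(k, function(v) is.numeric(v) && v > 0, logical(1))))
  k
}

#' Estimate missing 95% confidence intervals
#'
#' Where a record carries no original CI, its width is estimated as
#' `k(population_type) / (N * PVE/100)` cM, centred on the peak and floored
#' at 0 on the left. Records whose original CI is present are untouched.
#' Records with PVE absent/zero or N absent are flagged `unprojectable`.
#'
#' @param qtls QTL tibble after [impute_defaults()].
#' @param cfg Constants from [ci_config()].
#' @return The tibble with `ci_start_cm`/`ci_end_cm` filled and a logical
#'   `ci_estimated` flag column.
#' @export
estimate_ci <- function(qtls, cfg = ci_config()) {
  qtls <- tibble::as_tibble(qtls)
  if (!"unprojectable" %in% names(qtls)) qtls$unprojectable <- FALSE
  qtls$ci_estimated <- FALSE
  need <- which(is.na(qtls$ci_start_cm) | is.na(qtls$ci_end_cm))
  if (length(need) == 0) return(qtls)
  k <- unlist(cfg[qtls$population_type[need]])
  r2 <- qtls$pve[need] / 100
  n <- qtls$population_size[need]
  bad <- is.na(r2) | r2 <= 0 | is.na(n) | is.na(qtls$peak_cm[need])
  qtls$unprojectable[need[bad]] <- TRUE
  ok <- need[!bad]
  if (length(ok) > 0) {
    width <- unname(k[!bad]) / (n[!bad] * r2[!bad])
    qtls$ci_start_cm[ok] <- pmax(0, qtls$peak_cm[ok] - width / 2)
    qtls$ci_end_cm[ok] <- qtls$peak_cm[ok] + width / 2
    qtls$ci_estimated[ok] <- TRUE
  }
  qtls
}
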