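#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

#' Wheat chromosome names
#'
#' The 21 chromosomes of hexaploid bread wheat, `1A` through `7D`.
#'
#' @return Character vector of length 21.
#' @export
wheat_chromosomes <- function() {
  paste0(rep(1:7, each = 3), rep(c("A", "B", "D"), times = 7))
}

#' Abiotic stress class codes
#'
#' The six abiotic stress classes plus the combined drought-and-heat label:
#' DS (drought), HS (heat), D+H (combined drought and heat), SS (salinity),
#' WS (water-logging), PHS (pre-harvest sprouting), AS (aluminium).
#'
#' @param expanded If `TRUE`, return the six elementary classes only
#'   (the combined `D+H` label expands to DS and HS).
#' @return Character vector of stress codes.
#' @export
stress_codes <- function(expanded = FALSE) {
  if (expanded) c("DS", "HS", "SS", "WS", "PHS", "AS")
  else c("DS", "HS", "D+H", "SS", "WS", "PHS", "AS")
}

#' Normalise stress class labels
#'
#' Maps common synonyms onto the canonical codes: `AL` (aluminium) to `AS`,
#' `D + H` (any spacing) to `D+H`. Case is folded to upper.
#'
#' @param x Character vector of stress labels.
#' @return Character vector of canonical codes; labels that cannot be
#'   normalised are returned unchanged (validation rejects them later).
#' @export
normalize_stress <- function(x) {
  y <- toupper(trimws(x))
  y <- gsub("\\s*\\+\\s*", "+", y)
  y[y == "AL"] <- "AS"
  y[y == "D+H" | y == "DH+DS" | y == "DS+HS"] <- "D+H"
  y
}

#' Expand stress labels to elementary classes
#'
#' `D+H` expands to `DS` and `HS`; every other canonical code maps to itself.
#' Used for stress-class tallies, where a combined drought-and-heat QTL
#' counts towards both classes.
#'
#' @param x Character vector of canonical stress codes.
#' @return Character vector (possibly longer than `x`).
#' @export
expand_stress <- function(x) {
  out <- lapply(normalize_stress(x), function(s) if (s == "D+H") c("DS", "HS") else s)
  unlist(out, use.names = FALSE)
}

#' Normalise chromosome labels
#'
#' Strips a leading `chr`/`Chr` prefix and upper-cases the subgenome letter,
#' so `chr1A`, `1a` and `1A` all compare equal.
#'
#' @param x Character vector of chromosome labels.
#' @return Character vector of normalised labels.
#' @export
normalize_chromosome <- function(x) {
  y <- trimws(as.character(x))
  y <- sub("^[Cc][Hh][Rr]\\.?\\s*", "", y)
  toupper(y)
}

#' Subgenome of a wheat chromosome
#'
#' @param chromosome Character vector like `"3B"`.
#' @return The subgenome letter (`A`, `B` or `D`), `NA` if not parseable.
#' @export
subgenome <- function(chromosome) {
  letter <- sub("^[1-7]", "", normalize_chromosome(chromosome))
  ifelse(letter %in% c("A", "B", "D"), letter, NA_character_)
}

# round half away from zero, as printed tables do (base round() is banker's)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
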