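# small fixtures shared across test files; everything is built in code

# a minimal well-formed QTL tibble
make_qtls <- function(n = 3, chromosome = "1A") {
  tibble::tibble(
    qtl_id = paste0("Q", seq_len(n)),
    study_id = paste0("S", rep_len(1:2, n)),
    population_type = "RIL",
    population_size = 163L,
    stress = rep_len(c("DS", "HS", "SS"), n),
    trait = "GY",
    chromosome = chromosome,
    left_marker = paste0("L", seq_len(n)),
    right_marker = paste0("R", seq_len(n)),
    peak_cm = 10 * seq_len(n),
    ci_start_cm = 10 * seq_len(n) - 2,
    ci_end_cm = 10 * seq_len(n) + 2,
    lod = 4.5,
    pve = 12)
}

# a uniform genetic map: markers every `by` cM
make_map <- function(map_id, chromosome = "1A", len = 100, by = 5,
                     positions = NULL, markers = NULL) {
  pos <- positions %||% seq(0, len, by = by)
  tibble::tibble(map_id = map_id, chromosome = chromosome,
                 marker = markers %||% paste0("M", seq_along(pos)),
                 pos_cm = pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force mixture optimiser over hard assignments: for every assignment
# of n points to K labels, weights and means follow in closed form
# (pi_k = n_k/n, mu_k = inverse-variance weighted mean); returns the best
# mixture log-likelihood over all assignments
brute_force_gmm_loglik <- function(x, sigma, K) {
  n <- length(x)
  grids <- do.call(expand.grid, rep(list(seq_len(K)), n))
  best <- -Inf
  for (i in seq_len(nrow(grids))) {
    z <- as.integer(grids[i, ])
    if (length(unique(z)) < K) next
    w <- tabulate(z, K) / n
    mu <- vapply(seq_len(K), function(k) {
      idx <- z == k
      sum(x[idx] / sigma[idx]^2) / sum(1 / sigma[idx]^2)
    }, numeric(1))
    # mixture log-likelihood in log space (tiny densities underflow otherwise)
    lmat <- vapply(seq_len(K), function(k)
      log(w[k]) + stats::dnorm(x, mu[k], sigma, log = TRUE), numeric(n))
    lmat <- matrix(lmat, nrow = n)
    mx <- apply(lmat, 1, max)
    ll <- sum(mx + log(rowSums(exp(lmat - mx))))
    if (ll > best) best <- ll
  }
  best
}

# a tiny anchored MQTL tibble for interval tests
make_anchored_mqtls <- function() {
  tibble::tibble(
    mqtl = c("MQTL1A.1", "MQTL1A.2"),
    chromosome = "1A",
    position_cm = c(40, 110), ci_start_cm = c(39, 109), ci_end_cm = c(41, 111),
    n_qtls = c(10L, 12L), n_studies = c(5L, 6L),
    mean_lod = 5, mean_pve = 11,
    stress_tally = c("DS:4;HS:3;SS:2;WS:1", "DS:5;HS:4;PHS:2;AS:1"),
    n_stress_classes = c(4L, 4L),
    qtl_ids = c("a;b", "c;d"),
    start_bp = c(10e6, 60e6), end_bp = c(11e6, 61e6),
    peak_bp = c(10.5e6, 60.5e6), anchored = TRUE,
    anchor_note = NA_character_)
}
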