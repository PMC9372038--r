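#' Gaussian mixture model for projected QTL peaks
#'
#' The meta-analysis model treats the projected peak positions on one
#' chromosome as draws from a K-component Gaussian mixture
#' `x_i | k ~ N(mu_k, sigma_i^2)` in which the per-observation standard
#' deviation `sigma_i` is known, derived from each QTL's projected 95% CI
#' (`sigma_i = CI width / 3.92`). Only the K component means and K-1 free
#' mixing weights are estimated, so the free-parameter count is `d = 2K - 1`.
#'
#' @name mqtl_model
NULL

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

gmm_loglik <- function(x, sigma, weights, means) {
  lw <- matrix(log(weights), nrow = length(x), ncol = length(means), byrow = TRUE)
  ld <- vapply(means, function(mu) stats::dnorm(x, mu, sigma, log = TRUE),
               numeric(length(x)))
  sum(logsumexp_rows(lw + matrix(ld, nrow = length(x))))
}

em_once <- function(x, sigma, mu0, max_iter, tol) {
  n <- length(x); K <- length(mu0)
  w <- rep(1 / K, K); mu <- mu0
  inv_var <- 1 / sigma^2
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    lw <- matrix(log(w), n, K, byrow = TRUE)
    ld <- vapply(mu, function(m) stats::dnorm(x, m, sigma, log = TRUE), numeric(n))
    lj <- lw + matrix(ld, n, K)
    lse <- logsumexp_rows(lj)
    ll <- sum(lse)
    p <- exp(lj - lse)
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      return(list(weights = w, means = mu, posterior = p, loglik = ll,
                  n_iter = iter, converged = TRUE))
    }
    ll_old <- ll
    w <- pmax(colMeans(p), 1e-12)
    w <- w / sum(w)
    num <- colSums(p * x * inv_var)
    den <- colSums(p * inv_var)
    mu <- ifelse(den > 0, num / den, mu)
  }
  list(weights = w, means = mu, posterior = p, loglik = ll_old,
       n_iter = max_iter, converged = FALSE)
}

#' Fit a K-component Gaussian mixture with known per-observation variances
#'
#' EM with multiple restarts: the first start places component means at
#' evenly spaced quantiles of the data; the remaining starts jitter those
#' quantiles (scaled to the data spread). The best converged log-likelihood
#' wins. Means are returned in ascending order.
#'
#' @param x Numeric vector of projected peak positions (cM).
#' @param sigma Per-observation standard deviations (cM); values below
#'   `sigma_floor` are floored.
#' @param K Number of components, `1 <= K <= length(x)`.
#' @param n_start Number of EM restarts.
#' @param sigma_floor Lower bound for `sigma` (cM).
#' @param max_iter,tol EM stopping rule (log-likelihood change below `tol`).
#' @return An object of class `gmm_fit`: list with `K`, `weights`, `means`,
#'   `loglik`, `posterior` (n x K), `x`, `sigma`, `n_iter`, `converged`.
#' @export
fit_gaussian_mixture <- function(x, sigma, K, n_start = 10, sigma_floor = 0.05,
                                 max_iter = 2000, tol = 1e-8) {
  n <- length(x)
  if (K > n) stop("K exceeds n")
  stopifnot(K >= 1, length(sigma) == n)
  sigma <- pmax(sigma, sigma_floor)
  qs <- stats::quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE, type = 7)
  spread <- max(stats::sd(x), sigma_floor)
  best <- NULL
  for (s in seq_len(n_start)) {
    mu0 <- if (s == 1) qs else sort(qs + stats::rnorm(K, 0, spread / 2))
    fit <- em_once(x, sigma, mu0, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  o <- order(best$means)
  structure(list(K = K, weights = best$weights[o], means = best$means[o],
                 loglik = best$loglik, posterior = best$posterior[, o, drop = FALSE],
                 x = x, sigma = sigma, n_iter = best$n_iter,
                 converged = best$converged),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("Gaussian mixture fit: K =", x$K, " n =", length(x$x),
      " logL =", format(x$loglik, digits = 8), "\n")
  cat("means:", paste(format(x$means, digits = 5), collapse = ", "), "\n")
  invisible(x)
}

hard_assignment <- function(fit) max.col(fit$posterior, ties.method = "first")

classification_loglik <- function(fit) {
  z <- hard_assignment(fit)
  sum(log(fit$weights[z]) + stats::dnorm(fit$x, fit$means[z], fit$sigma, log = TRUE))
}

#' Model-selection criteria for a mixture fit
#'
#' Computes the five criteria used to vote on the number of MQTLs per
#' chromosome, with `d = 2K - 1` free parameters (K means, K-1 weights;
#' variances are fixed per observation):
#' `AIC = -2logL + 2d`; `AICc = AIC + 2d(d+1)/(n-d-1)` (undefined when
#' `n - d - 1 <= 0`); `AIC3 = -2logL + 3d`; `BIC = -2logL + d log n`;
#' `AWE = -2logLc + 2d(3/2 + log n)`, where `logLc` is the classification
#' log-likelihood under hard posterior assignment.
#'
#' @param fit A [fit_gaussian_mixture()] object.
#' @param n Number of observations (defaults to `length(fit$x)`).
#' @return One-row tibble: `K`, `loglik`, `AIC`, `AICc`, `AIC3`, `BIC`, `AWE`.
#' @export
compute_criteria <- function(fit, n = length(fit$x)) {
  d <- 2 * fit$K - 1
  m2ll <- -2 * fit$loglik
  aic <- m2ll + 2 * d
  aicc <- if (n - d - 1 > 0) aic + 2 * d * (d + 1) / (n - d - 1) else NA_real_
  llc <- classification_loglik(fit)
  tibble::tibble(K = fit$K, loglik = fit$loglik,
                 AIC = aic, AICc = aicc, AIC3 = m2ll + 3 * d,
                 BIC = m2ll + d * log(n),
                 AWE = -2 * llc + 2 * d * (3 / 2 + log(n)))
}

#' Select the number of MQTL components by criterion vote
#'
#' The selected K is the one attaining the minimum in at least three of the
#' five criteria (AIC, AICc, AIC3, BIC, AWE). If no K collects three votes,
#' the BIC-minimal K is used as the documented fallback; remaining ties go to
#' the smaller K.
#'
#' @param criteria Tibble of [compute_criteria()] rows over a range of K.
#' @return List: `K` (selected), `votes` (named integer vector per K),
#'   `rule` (`"vote"` or `"bic_fallback"`).
#' @export
select_model <- function(criteria) {
  stopifnot(nrow(criteria) >= 1)
  crit_names <- c("AIC", "AICc", "AIC3", "BIC", "AWE")
  winners <- vapply(crit_names, function(cn) {
    v <- criteria[[cn]]
    if (all(is.na(v))) return(NA_integer_)
    kk <- criteria$K[which(v == min(v, na.rm = TRUE))]
    as.integer(min(kk)) # tie within a criterion: smaller K
  }, integer(1))
  votes <- table(factor(winners[!is.na(winners)], levels = sort(unique(criteria$K))))
  votes <- stats::setNames(as.integer(votes), names(votes))
  top <- names(votes)[votes == max(votes)]
  if (max(votes) >= 3) {
    k <- as.integer(min(as.integer(top)))
    rule <- "vote"
  } else {
    bic_k <- criteria$K[which(criteria$BIC == min(criteria$BIC, na.rm = TRUE))]
    k <- as.integer(min(bic_k))
    rule <- "bic_fallback"
  }
  list(K = k, votes = votes, rule = rule)
}

stress_tally_string <- function(stresses) {
  expanded <- expand_stress(stresses)
  tab <- sort(table(factor(expanded, levels = stress_codes(expanded = TRUE))), decreasing = TRUE)
  tab <- tab[tab > 0]
  paste(paste0(names(tab), ":", as.integer(tab)), collapse = ";")
}

#' Parse a stress tally string
#'
#' @param x Character vector like `"DS:3;HS:2"`.
#' @return List of named integer vectors.
#' @export
parse_stress_tally <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(parts) {
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0) return(stats::setNames(integer(0), character(0)))
    kv <- strsplit(parts, ":", fixed = TRUE)
    stats::setNames(vapply(kv, function(p) as.integer(p[2]), integer(1)),
                    vapply(kv, `[`, character(1), 1))
  })
}

#' Form MQTLs from a fitted mixture on one chromosome
#'
#' Each projected QTL is assigned to its maximum-posterior component when
#' that posterior reaches `assign_threshold`, otherwise it is reported
#' unassigned. Component position is the inverse-variance weighted mean of
#' its members' peaks; the 95% CI is `position +/- 1.96 / sqrt(sum 1/sigma^2)`.
#' Components with a single member are set aside as singletons; components
#' whose members all come from one study are discarded as single-study
#' hotspots (a true MQTL needs QTLs from at least two distinct studies).
#' Survivors are named `MQTL<chrom>.<rank>` in ascending position order.
#'
#' @param fit [fit_gaussian_mixture()] result for the chromosome.
#' @param members Projected QTL tibble rows, in the order of `fit$x`.
#' @param chromosome Chromosome label.
#' @param assign_threshold Minimum posterior for hard membership.
#' @param pve_weighting `"mean"` (arithmetic mean of member LOD/PVE) or
#'   `"posterior"` (posterior-weighted mean).
#' @return List: `mqtls` tibble, `assignments` tibble (per QTL: component,
#'   posterior, disposition), `discards` tibble (component, reason, members).
#' @export
form_mqtls <- function(fit, members, chromosome,
                       assign_threshold = 0.5, pve_weighting = c("mean", "posterior")) {
  pve_weighting <- match.arg(pve_weighting)
  members <- tibble::as_tibble(members)
  stopifnot(nrow(members) == length(fit$x))
  pmax_k <- hard_assignment(fit)
  pmax_v <- fit$posterior[cbind(seq_along(pmax_k), pmax_k)]
  assigned <- pmax_v >= assign_threshold
  assignments <- tibble::tibble(
    qtl_id = members$qtl_id, chromosome = chromosome,
    component = ifelse(assigned, pmax_k, NA_integer_),
    posterior = pmax_v,
    disposition = ifelse(assigned, "member", "unassigned"))

  comp_rows <- list(); discards <- list()
  for (k in seq_len(fit$K)) {
    idx <- which(assigned & pmax_k == k)
    if (length(idx) == 0) next
    mem <- members[idx, ]
    inv_var <- 1 / fit$sigma[idx]^2
    pos <- sum(fit$x[idx] * inv_var) / sum(inv_var)
    half <- 1.96 / sqrt(sum(inv_var))
    if (length(idx) == 1) {
      discards[[length(discards) + 1]] <- tibble::tibble(
        chromosome = chromosome, component = k, reason = "singleton",
        qtl_ids = paste(mem$qtl_id, collapse = ";"))
      assignments$disposition[idx] <- "singleton"
      next
    }
    if (length(unique(mem$study_id)) < 2) {
      discards[[length(discards) + 1]] <- tibble::tibble(
        chromosome = chromosome, component = k, reason = "single_study",
        qtl_ids = paste(mem$qtl_id, collapse = ";"))
      assignments$disposition[idx] <- "single_study"
      next
    }
    wts <- if (pve_weighting == "posterior") pmax_v[idx] else rep(1, length(idx))
    comp_rows[[length(comp_rows) + 1]] <- tibble::tibble(
      chromosome = chromosome, component = k,
      position_cm = pos,
      ci_start_cm = max(0, pos - half), ci_end_cm = pos + half,
      n_qtls = length(idx), n_studies = length(unique(mem$study_id)),
      mean_lod = sum(mem$lod * wts) / sum(wts),
      mean_pve = sum(mem$pve * wts) / sum(wts),
      stress_tally = stress_tally_string(mem$stress),
      n_stress_classes = length(unique(expand_stress(mem$stress))),
      qtl_ids = paste(mem$qtl_id, collapse = ";"))
  }
  mqtls <- dplyr::bind_rows(comp_rows)
  if (nrow(mqtls) > 0) {
    mqtls <- dplyr::arrange(mqtls, .data$position_cm)
    mqtls$mqtl <- paste0("MQTL", chromosome, ".", seq_len(nrow(mqtls)))
    mqtls <- dplyr::select(mqtls, "mqtl", dplyr::everything(), -"component")
  }
  list(mqtls = mqtls, assignments = assignments,
       discards = dplyr::bind_rows(discards))
}

#' Per-chromosome meta-analysis of projected QTLs
#'
#' For every chromosome with at least two projected QTLs, fits mixtures for
#' `K = 1..min(n, k_max)`, tabulates the five criteria, selects K by the
#' three-of-five vote, and forms named MQTLs. Per-observation standard
#' deviations derive from the projected CIs (`sigma = CI width / 3.92`,
#' floored at `sigma_floor`).
#'
#' @param projected Result of [project_qtls()] (only `status == "projected"`
#'   rows are used).
#' @param k_max Largest K fitted per chromosome.
#' @param n_start EM restarts per K.
#' @param assign_threshold,sigma_floor,pve_weighting See [form_mqtls()] and
#'   [fit_gaussian_mixture()].
#' @param seed Optional integer seed for the EM restarts.
#' @return An object of class `mqtl_result`: list with `mqtls` (named MQTL
#'   tibble over all chromosomes), `criteria` (per chromosome and K),
#'   `selection` (per chromosome: K, rule), `assignments`, `discards`, and
#'   `projected` (the input rows used).
#' @export
meta_qtl <- function(projected, k_max = 10, n_start = 10, assign_threshold = 0.5,
                     sigma_floor = 0.05, pve_weighting = "mean", seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  pq <- tibble::as_tibble(projected) %>% dplyr::filter(.data$status == "projected")
  mqtls <- list(); criteria <- list(); selection <- list()
  assignments <- list(); discards <- list()
  for (chrom in sort(unique(pq$chromosome))) {
    rows <- pq[pq$chromosome == chrom, ]
    n <- nrow(rows)
    x <- rows$peak_cm
    sigma <- pmax((rows$ci_end_cm - rows$ci_start_cm) / 3.92, sigma_floor)
    if (n < 2) {
      if (n == 1) {
        discards[[chrom]] <- tibble::tibble(chromosome = chrom, component = 1L,
                                            reason = "singleton", qtl_ids = rows$qtl_id)
        assignments[[chrom]] <- tibble::tibble(qtl_id = rows$qtl_id, chromosome = chrom,
                                               component = NA_integer_, posterior = NA_real_,
                                               disposition = "singleton")
      }
      next
    }
    fits <- lapply(seq_len(min(n, k_max)), function(K)
      fit_gaussian_mixture(x, sigma, K, n_start = n_start, sigma_floor = sigma_floor))
    crit <- dplyr::bind_rows(lapply(fits, compute_criteria))
    sel <- select_model(crit)
    fit <- fits[[match(sel$K, crit$K)]]
    fm <- form_mqtls(fit, rows, chrom, assign_threshold, pve_weighting)
    crit$chromosome <- chrom
    crit$selected <- crit$K == sel$K
    criteria[[chrom]] <- crit
    selection[[chrom]] <- tibble::tibble(chromosome = chrom, K = sel$K, rule = sel$rule)
    mqtls[[chrom]] <- fm$mqtls
    assignments[[chrom]] <- fm$assignments
    discards[[chrom]] <- fm$discards
  }
  empty_discards <- tibble::tibble(chromosome = character(), component = integer(),
                                   reason = character(), qtl_ids = character())
  empty_assign <- tibble::tibble(qtl_id = character(), chromosome = character(),
                                 component = integer(), posterior = numeric(),
                                 disposition = character())
  structure(list(
    mqtls = dplyr::bind_rows(mqtls),
    criteria = dplyr::bind_rows(criteria),
    selection = dplyr::bind_rows(selection),
    assignments = dplyr::bind_rows(c(list(empty_assign), assignments)),
    discards = dplyr::bind_rows(c(list(empty_discards), discards)),
    projected = pq), class = "mqtl_result")
}

#' @export
print.mqtl_result <- function(x, ...) {
  cat("MQTL meta-analysis:", nrow(x$mqtls), "MQTLs on",
      length(unique(x$mqtls$chromosome)), "chromosomes\n")
  cat("  projected QTLs used:", nrow(x$projected), "\n")
  if (nrow(x$discards) > 0) {
    tab <- table(x$discards$reason)
    cat("  discarded components:", paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an MQTL meta-analysis result
#'
#' @param x An `mqtl_result` object.
#' @param ... Unused.
#' @return The MQTL tibble (one row per named MQTL).
#' @export
tidy.mqtl_result <- function(x, ...) x$mqtls

#' One-row summary of an MQTL meta-analysis
#'
#' @param x An `mqtl_result` object.
#' @param ... Unused.
#' @return Tibble with QTL/MQTL counts, unassigned and singleton counts, and
#'   the CI fold reduction (mean initial CI width over mean MQTL CI width).
#' @export
glance.mqtl_result <- function(x, ...) {
  initial_ci <- mean(x$projected$ci_end_cm - x$projected$ci_start_cm)
  mqtl_ci <- mean(x$mqtls$ci_end_cm - x$mqtls$ci_start_cm)
  tibble::tibble(
    n_projected = nrow(x$projected),
    n_mqtls = nrow(x$mqtls),
    n_singletons = sum(x$discards$reason == "singleton"),
    n_single_study = sum(x$discards$reason == "single_study"),
    n_unassigned = sum(x$assignments$disposition == "unassigned"),
    mean_initial_ci_cm = initial_ci,
    mean_mqtl_ci_cm = mqtl_ci,
    ci_fold_reduction = initial_ci / mqtl_ci)
}
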