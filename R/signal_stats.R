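# Disproportionality statistics on 2x2 contingency tables and the
# four-algorithm conjunction significance rule.
#
# Per (cohort, preferred term) pair the table is
#     a = target-cohort reports with the term
#     b = target-cohort reports without it
#     c = background reports with the term
#     d = background reports without it
# where the background is every other deduplicated report in the loaded
# universe. A term is a signal only when ROR, PRR, BCPNN and MGPS criteria
# all hold simultaneously.

DEFAULT_THRESHOLDS <- list(
  ror_min_a = 3, ror_lo95 = 1,
  prr_min_a = 3, prr_min = 2, chi2_min = 4,
  ic025_min = 0,
  eb05_min = 2,
  mgps_criterion = "eb05"    # or "ebgm": EBGM > eb05_min instead
)

#' Build contingency tables for one cohort
#'
#' Counts each report at most once per preferred term regardless of repeated
#' reaction rows, against the background of all retained reports outside the
#' target cohort. Every lexicon term observed at least once in the target
#' cohort is emitted.
#'
#' @param reports a `faers_reports` object (deduplicated).
#' @param assignments data.frame from [assign_group()].
#' @param lexicon data.frame from [read_lexicon()].
#' @param group target cohort label.
#' @return data.frame with columns `pt`, `soc`, `a`, `b`, `c`, `d`.
#' @export
build_tables <- function(reports, assignments, lexicon, group) {
  stopifnot(inherits(reports, "faers_reports"),
            group %in% COHORT_GROUPS)
  target_ids <- assignments$case_id[assignments$group == group]
  bg_ids <- assignments$case_id[assignments$group != group]
  n_t <- length(target_ids)
  n_b <- length(bg_ids)
  if (n_b == 0L)
    stop("empty background: no reports outside cohort '", group, "'")
  rx <- reports$reactions
  lex_idx <- match(tolower(rx$pt), tolower(lexicon$pt))
  rx <- rx[!is.na(lex_idx), , drop = FALSE]
  rx$pt_canon <- lexicon$pt[lex_idx[!is.na(lex_idx)]]
  rx <- unique(rx[, c("case_id", "pt_canon")])   # one count per report/term
  in_target <- rx$case_id %in% target_ids
  a_tab <- table(factor(rx$pt_canon[in_target], levels = lexicon$pt))
  c_tab <- table(factor(rx$pt_canon[!in_target &
                                      rx$case_id %in% bg_ids],
                        levels = lexicon$pt))
  keep <- a_tab >= 1L
  out <- data.frame(
    pt = lexicon$pt[keep],
    soc = lexicon$soc[keep],
    a = as.integer(a_tab[keep]),
    c = as.integer(c_tab[keep]),
    stringsAsFactors = FALSE)
  out$b <- n_t - out$a
  out$d <- n_b - out$c
  out[, c("pt", "soc", "a", "b", "c", "d")]
}

.needs_correction <- function(a, b, c, d) a == 0 | b == 0 | c == 0 | d == 0

#' Reporting odds ratio
#'
#' `ROR = (a d)/(b c)` with the 95% Wald interval
#' `exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero a 0.5 continuity correction is added to all four cells and the row
#' is flagged. The signal criterion is `a >= 3` (uncorrected count) and a
#' lower confidence bound above 1.
#'
#' @param a,b,c,d contingency-table cells (vectors of equal length).
#' @param thresholds list as in `DEFAULT_THRESHOLDS`.
#' @return data.frame with `ror`, `ror_lo95`, `ror_hi95`, `pass_ror`,
#'   `ror_corrected`.
#' @export
ror_stat <- function(a, b, c, d, thresholds = DEFAULT_THRESHOLDS) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  corr <- .needs_correction(a, b, c, d)
  k <- ifelse(corr, 0.5, 0)
  aa <- a + k; bb <- b + k; cc <- c + k; dd <- d + k
  ror <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  lo <- exp(log(ror) - 1.96 * se)
  hi <- exp(log(ror) + 1.96 * se)
  data.frame(ror = ror, ror_lo95 = lo, ror_hi95 = hi,
             pass_ror = a >= thresholds$ror_min_a & lo > thresholds$ror_lo95,
             ror_corrected = corr)
}

#' Proportional reporting ratio and Pearson chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-square is the Pearson statistic on
#' the 2x2 table, uncorrected by default (set `yates = TRUE` for the
#' continuity-corrected variant). When `c` (or another cell) is zero the
#' PRR is computed on 0.5-corrected cells and flagged. Criterion: `a >= 3`,
#' `PRR >= 2`, `chi2 >= 4`.
#'
#' @inheritParams ror_stat
#' @param yates apply the Yates continuity correction to the chi-square.
#' @return data.frame with `prr`, `chi2`, `pass_prr`, `prr_corrected`.
#' @export
prr_stat <- function(a, b, c, d, thresholds = DEFAULT_THRESHOLDS,
                     yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  corr <- .needs_correction(a, b, c, d)
  k <- ifelse(corr, 0.5, 0)
  aa <- a + k; bb <- b + k; cc <- c + k; dd <- d + k
  prr <- (aa / (aa + bb)) / (cc / (cc + dd))
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (yates) num <- pmax(num - n / 2, 0)
  chi2 <- n * num^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  chi2[!is.finite(chi2)] <- 0
  data.frame(prr = prr, chi2 = chi2,
             pass_prr = a >= thresholds$prr_min_a &
               prr >= thresholds$prr_min & chi2 >= thresholds$chi2_min,
             prr_corrected = corr)
}

#' BCPNN information component (closed-form posterior moments)
#'
#' The information component is the posterior distribution of
#' `log2(p11 / (p1. p.1))` under independent beta posteriors for the joint
#' reporting probability `p11` and the drug/event marginals `p1.`, `p.1`
#' (symmetric unit-style hyperpriors: marginal priors Beta(1, 1); the
#' joint prior Beta(1, gamma - 1) with
#' `gamma = (N + alpha)(N + beta) / ((a + b + alpha1)(a + c + beta1))`
#' centred so the prior information component is 0). Because the log of a
#' beta variable has closed-form moments, the posterior mean and variance
#' are exact:
#'
#' `E(IC) = [psi(a + 1) - psi(N + gamma) - psi(a + b + 1) + psi(N + 2)
#'           - psi(a + c + 1) + psi(N + 2)] / ln 2`
#'
#' with the matching trigamma variance; `IC025 = E(IC) - 2 sqrt(V(IC))`.
#' Criterion: `IC025 > 0`. Shrinkage makes `a = 0` safe.
#'
#' @inheritParams ror_stat
#' @return data.frame with `ic`, `ic025`, `pass_bcpnn`.
#' @export
bcpnn_ic <- function(a, b, c, d, thresholds = DEFAULT_THRESHOLDS) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  gam <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  # E[ln p] and Var[ln p] for p ~ Beta(s, t): psi(s) - psi(s + t),
  # psi'(s) - psi'(s + t); the three betas are independent
  e_ic <- (digamma(a + g11) - digamma(n + gam) -
             (digamma(a + b + a1) - digamma(n + al)) -
             (digamma(a + c + b1) - digamma(n + be))) / log(2)
  v_ic <- (trigamma(a + g11) - trigamma(n + gam) +
             trigamma(a + b + a1) - trigamma(n + al) +
             trigamma(a + c + b1) - trigamma(n + be)) / log(2)^2
  ic025 <- e_ic - 2 * sqrt(v_ic)
  data.frame(ic = e_ic, ic025 = ic025,
             pass_bcpnn = ic025 > thresholds$ic025_min)
}

#' Monte-Carlo posterior draws of the information component
#'
#' Sampling counterpart of [bcpnn_ic()] used for validation: draws the
#' joint and marginal reporting probabilities from their beta posteriors
#' and returns draws of `log2(p11 / (p1. * p.1))`.
#'
#' @inheritParams ror_stat
#' @param n_draw number of posterior draws.
#' @return numeric vector of IC draws.
#' @export
bcpnn_ic_draws <- function(a, b, c, d, n_draw = 1e6) {
  stopifnot(length(a) == 1L)
  n <- a + b + c + d
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  gam <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  p11 <- stats::rbeta(n_draw, a + g11, n - a + gam - g11)
  p1. <- stats::rbeta(n_draw, a + b + a1, n - a - b + al - a1)
  p.1 <- stats::rbeta(n_draw, a + c + b1, n - a - c + be - b1)
  log2(p11 / (p1. * p.1))
}

# ---- MGPS: two-component gamma-Poisson mixture (DuMouchel-style) ----------

#' Expected counts under row/column independence
#'
#' `E = (a + b)(a + c) / N` per table.
#'
#' @inheritParams ror_stat
#' @return numeric vector of expected counts.
#' @export
expected_count <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  (a + b) * (a + c) / (a + b + c + d)
}

.gps_loglik <- function(theta, a, E) {
  # theta on the unconstrained scale: log a1, log b1, log a2, log b2, logit p
  al1 <- exp(theta[1L]); be1 <- exp(theta[2L])
  al2 <- exp(theta[3L]); be2 <- exp(theta[4L])
  p <- stats::plogis(theta[5L])
  l1 <- suppressWarnings(
    stats::dnbinom(a, size = al1, prob = be1 / (be1 + E), log = TRUE))
  l2 <- suppressWarnings(
    stats::dnbinom(a, size = al2, prob = be2 / (be2 + E), log = TRUE))
  if (any(!is.finite(c(l1, l2)))) return(-1e10)
  m <- pmax(l1, l2)
  sum(m + log(p * exp(l1 - m) + (1 - p) * exp(l2 - m)))
}

#' Fit the MGPS mixture prior
#'
#' Maximizes the marginal likelihood of the observed counts `a` given their
#' independence expectations `E` under the relative-reporting-rate prior
#' `lambda ~ p Gamma(alpha1, beta1) + (1 - p) Gamma(alpha2, beta2)`
#' (marginally, a mixture of negative binomials). Optimization runs on the
#' log/logit scale by BFGS from the documented default start
#' `(0.2, 0.1, 2.0, 4.0, 1/3)` plus jittered restarts; the best converged
#' solution is returned.
#'
#' @param a observed counts per (cohort, term) pair.
#' @param E expected counts from [expected_count()].
#' @param start numeric start `(alpha1, beta1, alpha2, beta2, p_mix)`.
#' @param n_restart extra jittered starts tried after the default.
#' @param seed integer seed controlling the jitter (local RNG state).
#' @return object of class `gps_prior`: `alpha1, beta1, alpha2, beta2,
#'   p_mix, loglik, converged, n_pairs`.
#' @export
fit_gps_prior <- function(a, E, start = c(0.2, 0.1, 2.0, 4.0, 1 / 3),
                          n_restart = 3, seed = 1L) {
  stopifnot(length(a) == length(E), all(E > 0), all(a >= 0))
  if (length(a) < 20)
    warning("fewer than 20 pairs; prior estimates may be unstable")
  to_theta <- function(p) c(log(p[1:4]), stats::qlogis(p[5L]))
  starts <- list(to_theta(start))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  for (i in seq_len(n_restart))
    starts[[i + 1L]] <- to_theta(start) + stats::rnorm(5L, 0, 0.5)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      stats::optim(th0, .gps_loglik, a = a, E = E, method = "BFGS",
                   control = list(fnscale = -1, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value > best$value) best <- fit
  }
  if (is.null(best))
    stop("MGPS prior fit failed to converge from all starts")
  th <- best$par
  out <- list(alpha1 = exp(th[1L]), beta1 = exp(th[2L]),
              alpha2 = exp(th[3L]), beta2 = exp(th[4L]),
              p_mix = stats::plogis(th[5L]),
              loglik = best$value,
              loglik_start = .gps_loglik(to_theta(start), a, E),
              converged = best$convergence == 0,
              n_pairs = length(a))
  class(out) <- "gps_prior"
  out
}

#' @export
print.gps_prior <- function(x, ...) {
  cat(sprintf(paste0("<gps_prior> alpha1=%.3g beta1=%.3g alpha2=%.3g ",
                     "beta2=%.3g p_mix=%.3f (loglik %.2f, %s, %d pairs)\n"),
              x$alpha1, x$beta1, x$alpha2, x$beta2, x$p_mix, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_pairs))
  invisible(x)
}

.gps_posterior <- function(a, E, prior) {
  # posterior mixture weight on component 1 and updated gamma parameters
  l1 <- stats::dnbinom(a, size = prior$alpha1,
                       prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  l2 <- stats::dnbinom(a, size = prior$alpha2,
                       prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  lq <- log(prior$p_mix) + l1
  lr <- log1p(-prior$p_mix) + l2
  m <- pmax(lq, lr)
  q <- exp(lq - m) / (exp(lq - m) + exp(lr - m))
  list(q = q,
       shape1 = prior$alpha1 + a, rate1 = prior$beta1 + E,
       shape2 = prior$alpha2 + a, rate2 = prior$beta2 + E)
}

#' Empirical Bayes geometric mean and EB05
#'
#' Under the fitted mixture prior the posterior of the relative reporting
#' rate `lambda` is a two-component gamma mixture. `EBGM =
#' 2^E[log2 lambda | a]` (the posterior geometric mean) and `EB05` is the
#' 5th posterior percentile, found by root-finding the mixture CDF to
#' within 1e-8. Criterion: `EB05 > 2` (switchable to `EBGM > 2` via
#' `thresholds$mgps_criterion`).
#'
#' @param a observed counts.
#' @param E expected counts.
#' @param prior a `gps_prior`.
#' @inheritParams ror_stat
#' @return data.frame with `ebgm`, `eb05`, `pass_mgps`.
#' @export
ebgm_stat <- function(a, E, prior, thresholds = DEFAULT_THRESHOLDS) {
  stopifnot(inherits(prior, "gps_prior"), all(E > 0))
  po <- .gps_posterior(a, E, prior)
  mean_log <- po$q * (digamma(po$shape1) - log(po$rate1)) +
    (1 - po$q) * (digamma(po$shape2) - log(po$rate2))
  ebgm <- exp(mean_log)
  eb05 <- vapply(seq_along(a), function(i) {
    cdf <- function(x)
      po$q[i] * stats::pgamma(x, po$shape1[i], po$rate1[i]) +
      (1 - po$q[i]) * stats::pgamma(x, po$shape2[i], po$rate2[i]) - 0.05
    up <- max(stats::qgamma(0.999, po$shape1[i], po$rate1[i]),
              stats::qgamma(0.999, po$shape2[i], po$rate2[i]), 1)
    stats::uniroot(cdf, lower = 0, upper = up, tol = 1e-8,
                   extendInt = "upX")$root
  }, numeric(1L))
  stat <- if (identical(thresholds$mgps_criterion, "ebgm")) ebgm else eb05
  data.frame(ebgm = ebgm, eb05 = eb05,
             pass_mgps = stat > thresholds$eb05_min)
}

#' Monte-Carlo posterior draws of the relative reporting rate
#'
#' Sampling counterpart of [ebgm_stat()] for validation: draws `lambda`
#' from the two-component gamma posterior mixture.
#'
#' @param a,E scalar observed and expected counts.
#' @param prior a `gps_prior`.
#' @param n_draw number of draws.
#' @return numeric vector of posterior draws of `lambda`.
#' @export
ebgm_draws <- function(a, E, prior, n_draw = 1e6) {
  stopifnot(length(a) == 1L)
  po <- .gps_posterior(a, E, prior)
  pick <- stats::runif(n_draw) < po$q
  out <- numeric(n_draw)
  out[pick] <- stats::rgamma(sum(pick), po$shape1, rate = po$rate1)
  out[!pick] <- stats::rgamma(sum(!pick), po$shape2, rate = po$rate2)
  out
}

#' Four-algorithm conjunction rule
#'
#' A (cohort, term) pair is a significant signal only when the ROR, PRR,
#' BCPNN and MGPS criteria all hold simultaneously.
#'
#' @param pass_ror,pass_prr,pass_bcpnn,pass_mgps logical vectors.
#' @return logical vector.
#' @export
conjunction <- function(pass_ror, pass_prr, pass_bcpnn, pass_mgps) {
  pass_ror & pass_prr & pass_bcpnn & pass_mgps
}

#' Full disproportionality scan for one cohort
#'
#' Builds the contingency tables, computes all four statistics and the
#' conjunction flag. The MGPS prior is fitted on the supplied pairs unless
#' one is passed in (e.g. a prior fitted across the whole report universe).
#'
#' @inheritParams build_tables
#' @param thresholds criteria list (see `DEFAULT_THRESHOLDS`).
#' @param prior optional pre-fitted `gps_prior`.
#' @param yates passed to [prr_stat()].
#' @return data.frame, one row per term: cells, all statistics, per-
#'   algorithm pass flags and `significant`.
#' @export
signal_scan <- function(reports, assignments, lexicon, group,
                        thresholds = DEFAULT_THRESHOLDS, prior = NULL,
                        yates = FALSE) {
  tab <- build_tables(reports, assignments, lexicon, group)
  if (nrow(tab) == 0L) {
    tab$ror <- tab$ror_lo95 <- tab$ror_hi95 <- numeric(0)
    tab$significant <- logical(0)
    return(tab)
  }
  score_tables(tab, thresholds = thresholds, prior = prior, yates = yates)
}

#' Score pre-built contingency tables
#'
#' @param tab data.frame with columns `a`, `b`, `c`, `d` (and optionally
#'   `pt`, `soc`).
#' @inheritParams signal_scan
#' @return `tab` augmented with all statistics and flags.
#' @export
score_tables <- function(tab, thresholds = DEFAULT_THRESHOLDS,
                         prior = NULL, yates = FALSE) {
  E <- expected_count(tab$a, tab$b, tab$c, tab$d)
  if (is.null(prior))
    prior <- suppressWarnings(fit_gps_prior(tab$a, E))
  out <- cbind(tab,
               ror_stat(tab$a, tab$b, tab$c, tab$d, thresholds),
               prr_stat(tab$a, tab$b, tab$c, tab$d, thresholds, yates),
               bcpnn_ic(tab$a, tab$b, tab$c, tab$d, thresholds),
               data.frame(expected = E),
               ebgm_stat(tab$a, E, prior, thresholds))
  out$significant <- conjunction(out$pass_ror, out$pass_prr,
                                 out$pass_bcpnn, out$pass_mgps)
  attr(out, "gps_prior") <- prior
  out
}
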