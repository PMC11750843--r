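# Time to onset: Weibull shape-parameter failure-type classification,
# rank-sum comparison, cumulative incidence and log-rank test.

#' Compute time to onset per report
#'
#' Onset is the event date minus the therapy start date in days. Only
#' day-precision dates on both ends qualify; when a report has several
#' therapy rows for the target drug, the earliest start date is used.
#' Records with a missing or negative onset are excluded and tallied by
#' reason in the `exclusions` attribute.
#'
#' @param reports a `faers_reports` object.
#' @param assignments data.frame from [assign_group()].
#' @param target_names named list of normalized synonym sets per cohort
#'   label (e.g. `list(A_only = names_a, B_only = names_b, A_plus_B =
#'   c(names_a, names_b))`); therapy rows are matched to target drugs via
#'   the drug sequence number.
#' @return data.frame with `case_id`, `group`, `onset_days`; attribute
#'   `exclusions` counts reports dropped per reason.
#' @export
compute_onsets <- function(reports, assignments, target_names) {
  stopifnot(inherits(reports, "faers_reports"))
  rr <- merge(reports$reports[, c("case_id", "event_date",
                                  "event_date_precision")],
              assignments, by = "case_id")
  rr <- rr[rr$group %in% names(target_names), , drop = FALSE]

  d <- reports$drugs
  th <- reports$therapy
  th <- th[!is.na(th$start_date) & th$start_date_precision %in% "day", ,
           drop = FALSE]
  # therapy rows attached to a target-drug row of the same report
  starts <- rep(as.Date(NA), nrow(rr))
  th_key <- paste(th$case_id, th$dsg_drug_seq)
  for (g in intersect(unique(as.character(rr$group)), names(target_names))) {
    tn <- normalize_drug_name(target_names[[g]])
    in_g <- as.character(rr$group) == g
    dsub <- d[d$case_id %in% rr$case_id[in_g] & d$name_std %in% tn, ,
              drop = FALSE]
    tsub <- th[th_key %in% paste(dsub$case_id, dsub$drug_seq), ,
               drop = FALSE]
    if (!nrow(tsub)) next
    first <- tapply(as.numeric(tsub$start_date), tsub$case_id, min)
    idx <- match(rr$case_id[in_g], names(first))
    starts[in_g] <- as.Date(as.numeric(first[idx]),
                            origin = "1970-01-01")
  }
  event_ok <- !is.na(rr$event_date) & rr$event_date_precision %in% "day"
  onset <- as.numeric(rr$event_date - starts)
  excl <- c(missing_start = sum(is.na(starts)),
            missing_event = sum(!is.na(starts) & !event_ok),
            negative_onset = sum(!is.na(starts) & event_ok &
                                   !is.na(onset) & onset < 0))
  keep <- !is.na(starts) & event_ok & !is.na(onset) & onset >= 0
  out <- data.frame(case_id = rr$case_id[keep],
                    group = as.character(rr$group[keep]),
                    onset_days = onset[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Weibull shape-parameter fit and failure-type classification
#'
#' Maximum-likelihood Weibull fit of onset times (via
#' [survival::survreg()]); the 95% interval for the shape comes from the
#' observed-information normal approximation on the log-shape scale.
#' Failure type follows the shape-parameter interval rule: `early` when
#' the upper bound is below 1 (decreasing hazard), `wear_out` when the
#' lower bound exceeds 1 (increasing hazard), `random` when the interval
#' contains 1 (constant hazard). Same-day onsets (0 days) enter the fit as
#' 0.5 days since the Weibull support is positive.
#'
#' @param onsets numeric vector of onset days (`>= 0`).
#' @param min_n classification refused below this sample size.
#' @return object of class `weibull_fit`: `shape`, `shape_lo95`,
#'   `shape_hi95`, `scale`, `scale_lo95`, `scale_hi95`, `failure_type`,
#'   `n`.
#' @export
weibull_fit <- function(onsets, min_n = 10) {
  onsets <- onsets[!is.na(onsets)]
  if (length(onsets) < min_n)
    stop("need at least ", min_n, " onsets to classify, got ",
         length(onsets))
  x <- pmax(onsets, 0.5)
  if (length(unique(x)) < 2L)
    stop("degenerate onset sample: all values identical")
  fit <- survival::survreg(survival::Surv(x) ~ 1, dist = "weibull")
  # survreg scale s: Weibull shape k = 1/s, scale = exp(intercept)
  log_s <- log(fit$scale)
  se_log_s <- sqrt(fit$var[nrow(fit$var), ncol(fit$var)])
  shape <- 1 / fit$scale
  shape_ci <- exp(-(log_s + c(1.96, -1.96) * se_log_s))
  mu <- unname(stats::coef(fit)[1L])
  se_mu <- sqrt(fit$var[1L, 1L])
  ft <- if (shape_ci[2L] < 1) "early"
  else if (shape_ci[1L] > 1) "wear_out"
  else "random"
  structure(list(shape = shape, shape_lo95 = shape_ci[1L],
                 shape_hi95 = shape_ci[2L],
                 scale = exp(mu),
                 scale_lo95 = exp(mu - 1.96 * se_mu),
                 scale_hi95 = exp(mu + 1.96 * se_mu),
                 failure_type = ft, n = length(onsets)),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(paste0("<weibull_fit> n=%d shape %.3f [%.3f, %.3f] ",
                     "scale %.1f d [%.1f, %.1f] -> %s failure\n"),
              x$n, x$shape, x$shape_lo95, x$shape_hi95,
              x$scale, x$scale_lo95, x$scale_hi95, x$failure_type))
  invisible(x)
}

#' Wilcoxon rank-sum comparison of two onset samples
#'
#' Normal-approximation rank-sum statistic with tie correction; the
#' reported `z` is the uncorrected standardized rank sum, while the
#' two-sided p applies the 0.5 continuity correction (which keeps the
#' approximation within 0.02 of exhaustive enumeration even at 6 + 6).
#' When both samples have at most `exact_max` observations the two-sided
#' p-value is computed by exhaustive enumeration of all rank assignments
#' instead (two-sided tail defined by the absolute deviation of the rank
#' sum from its null mean).
#'
#' @param a,b numeric onset vectors.
#' @param exact_max enumeration threshold per sample (default 8).
#' @return list with `z`, `p`, `method`, the group medians and quartiles.
#' @export
rank_sum_compare <- function(a, b, exact_max = 8) {
  stopifnot(length(a) > 0, length(b) > 0)
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  ties <- table(c(a, b))
  tie_adj <- sum(ties^3 - ties) / (n * (n - 1))
  sig2 <- na * nb / 12 * ((n + 1) - tie_adj)
  z <- if (sig2 > 0) (w - mu) / sqrt(sig2) else 0
  if (na <= exact_max && nb <= exact_max) {
    combs <- utils::combn(n, na)
    sums <- colSums(matrix(r[combs], nrow = na))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    method <- "exact"
  } else {
    z_cc <- max(abs(w - mu) - 0.5, 0) / sqrt(sig2)
    p <- 2 * stats::pnorm(-z_cc)
    method <- "normal"
  }
  list(z = z, p = min(p, 1), method = method,
       median_a = stats::median(a), q_a = stats::quantile(a, c(.25, .75),
                                                          names = FALSE),
       median_b = stats::median(b), q_b = stats::quantile(b, c(.25, .75),
                                                          names = FALSE))
}

#' Cumulative incidence step functions and log-rank comparison
#'
#' Every spontaneous-report onset is an observed event (no censoring), so
#' the cumulative incidence per group is the empirical distribution
#' function of onset times. Groups are compared with the log-rank test
#' (via [survival::survdiff()]) against chi-square with `k - 1` degrees of
#' freedom.
#'
#' @param onsets_by_group named list of numeric onset vectors (>= 2
#'   groups, each non-empty).
#' @return list with `curves` (data.frame `group`, `time`, `cuminc`),
#'   `logrank_chi2`, `logrank_p`, `df`.
#' @export
cumulative_incidence <- function(onsets_by_group) {
  stopifnot(is.list(onsets_by_group), length(onsets_by_group) >= 2L,
            all(lengths(onsets_by_group) > 0))
  curves <- do.call(rbind, lapply(names(onsets_by_group), function(g) {
    x <- sort(onsets_by_group[[g]])
    data.frame(group = g, time = c(0, unique(x)),
               cuminc = c(0, stats::ecdf(x)(unique(x))),
               stringsAsFactors = FALSE)
  }))
  time <- unlist(onsets_by_group, use.names = FALSE)
  grp <- factor(rep(names(onsets_by_group), lengths(onsets_by_group)))
  sd <- survival::survdiff(survival::Surv(time,
                                          rep(1, length(time))) ~ grp)
  df <- length(onsets_by_group) - 1L
  list(curves = curves, logrank_chi2 = unname(sd$chisq),
       logrank_p = stats::pchisq(unname(sd$chisq), df,
                                 lower.tail = FALSE),
       df = df)
}

#' Onset summary: quartiles and year-band histogram
#'
#' Quartiles use the linear-interpolation convention (`stats::quantile`
#' type 7) by default; `quantile_type` switches conventions. The histogram
#' counts onsets in the bands 0-1 year, 1-5 years and over 5 years
#' (365.25-day years); `monthly = TRUE` additionally returns 30.4375-day
#' monthly bins for finer histograms.
#'
#' @param onsets numeric vector of onset days (non-empty).
#' @param quantile_type passed to [stats::quantile()].
#' @param monthly also return monthly bin counts.
#' @return list with `n`, `median`, `q25`, `q75`, `year_bands`
#'   (named counts) and optionally `monthly_bins`.
#' @export
onset_summary <- function(onsets, quantile_type = 7, monthly = FALSE) {
  stopifnot(length(onsets) > 0)
  q <- stats::quantile(onsets, c(.25, .5, .75), type = quantile_type,
                       names = FALSE)
  yr <- 365.25
  bands <- c("0-1y" = sum(onsets < yr),
             "1-5y" = sum(onsets >= yr & onsets < 5 * yr),
             ">5y" = sum(onsets >= 5 * yr))
  out <- list(n = length(onsets), median = q[2L], q25 = q[1L], q75 = q[3L],
              year_bands = bands)
  if (monthly) {
    mo <- yr / 12
    brk <- seq(0, ceiling(max(onsets) / mo) * mo + mo, by = mo)
    h <- hist(onsets, breaks = brk, plot = FALSE)
    out$monthly_bins <- data.frame(month = seq_along(h$counts),
                                   count = h$counts)
  }
  out
}
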