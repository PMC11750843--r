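# Univariate and multivariate logistic comparison of tumor-signal
# occurrence across demographics and treatment cohorts.

#' Build a logistic regression design
#'
#' Outcome: the report carries at least one tumor preferred term that the
#' conjunction rule flagged as a significant signal (passed as a set of
#' case ids). Covariates are categorical factors with fixed reference
#' levels: sex (female), age band (`<18`), weight band (`<50 kg`) and
#' treatment group (combination, `A_plus_B`). By default rows with a
#' missing modeled covariate are dropped (complete case); with
#' `missing_as_level = TRUE` the `"Missing"` band is retained as a factor
#' level instead.
#'
#' @param reports a `faers_reports` object.
#' @param assignments data.frame from [assign_group()].
#' @param outcome_case_ids case ids with a significant-signal tumor term.
#' @param groups cohorts to include (rows outside them are dropped).
#' @param missing_as_level keep `"Missing"` as a covariate level.
#' @return data.frame with `case_id`, logical `outcome` and factors `sex`,
#'   `age`, `weight`, `group`.
#' @export
build_design <- function(reports, assignments, outcome_case_ids,
                         groups = c("A_only", "B_only", "A_plus_B"),
                         missing_as_level = FALSE) {
  stopifnot(inherits(reports, "faers_reports"))
  rr <- merge(reports$reports, assignments, by = "case_id")
  rr <- rr[rr$group %in% groups, , drop = FALSE]
  sex <- as.character(rr$sex); sex[is.na(sex)] <- "Missing"
  d <- data.frame(
    case_id = rr$case_id,
    outcome = rr$case_id %in% outcome_case_ids,
    sex = factor(sex, levels = c("female", "male", "Missing")),
    age = age_band(rr$age_years),
    weight = weight_band(rr$weight_kg),
    group = factor(as.character(rr$group),
                   levels = c("A_plus_B", setdiff(groups, "A_plus_B"))),
    stringsAsFactors = FALSE)
  if (!missing_as_level) {
    keep <- d$sex != "Missing" & d$age != "Missing" & d$weight != "Missing"
    d <- d[keep, , drop = FALSE]
  }
  d[] <- lapply(d, function(x) if (is.factor(x)) droplevels(x) else x)
  rownames(d) <- NULL
  d
}

.tidy_or <- function(fit, model = "") {
  co <- summary(fit)$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  if (nrow(co) == 0L)
    return(data.frame(term = character(0), or = numeric(0),
                      lo95 = numeric(0), hi95 = numeric(0), p = numeric(0),
                      separation = logical(0), model = character(0)))
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  # Wald CI; flag likely complete separation (diverging estimate or SE)
  sep <- abs(est) > 10 | se > 10
  data.frame(term = rownames(co),
             or = exp(est),
             lo95 = ifelse(sep, 0, exp(est - 1.96 * se)),
             hi95 = ifelse(sep, Inf, exp(est + 1.96 * se)),
             p = co[, "Pr(>|z|)"],
             separation = sep,
             model = model,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Univariate logistic fit for one covariate
#'
#' Single-factor maximum-likelihood logistic regression of the tumor-signal
#' outcome on one categorical covariate; Wald odds-ratio confidence
#' intervals and p-values per non-reference level. Complete separation is
#' flagged and the interval reported as unbounded.
#'
#' @param design data.frame from [build_design()].
#' @param term covariate name (`"sex"`, `"age"`, `"weight"`, `"group"`).
#' @return data.frame of odds-ratio estimates (`term`, `or`, `lo95`,
#'   `hi95`, `p`, `separation`).
#' @export
fit_univariate <- function(design, term) {
  stopifnot(term %in% names(design))
  y <- design$outcome
  if (length(unique(y)) < 2L)
    stop("outcome is constant; logistic fit is undefined")
  x <- droplevels(design[[term]])
  if (nlevels(x) < 2L)
    stop("covariate '", term, "' has fewer than two observed levels")
  fit <- stats::glm(y ~ x, family = stats::binomial())
  out <- .tidy_or(fit, model = "univariate")
  out$term <- sub("^x", paste0(term, ":"), out$term)
  out
}

#' Univariate screen across covariates
#'
#' Fits [fit_univariate()] for each covariate and records whether any level
#' reaches the gate p-value (default 0.05), the rule used to admit terms to
#' the multivariate model.
#'
#' @param design data.frame from [build_design()].
#' @param terms covariates to screen.
#' @param alpha univariate gate.
#' @return list with `estimates` (stacked OR table) and `selected`
#'   (character vector of covariates passing the gate).
#' @export
univariate_screen <- function(design,
                              terms = c("sex", "age", "weight", "group"),
                              alpha = 0.05) {
  terms <- intersect(terms, names(design))
  terms <- terms[vapply(terms, function(tt)
    nlevels(droplevels(design[[tt]])) >= 2L, logical(1L))]
  est <- do.call(rbind, lapply(terms, function(tt)
    cbind(covariate = tt, fit_univariate(design, tt))))
  sel <- vapply(terms, function(tt)
    any(est$p[est$covariate == tt] < alpha, na.rm = TRUE), logical(1L))
  list(estimates = est, selected = terms[sel], alpha = alpha)
}

#' Multivariate logistic fit
#'
#' Joint maximum-likelihood logistic fit of the outcome on the covariates
#' that passed the univariate gate; adjusted odds ratios with Wald
#' intervals.
#'
#' @param design data.frame from [build_design()].
#' @param terms covariates to include jointly (typically
#'   `univariate_screen(design)$selected`).
#' @return data.frame of adjusted odds-ratio estimates.
#' @export
fit_multivariate <- function(design, terms) {
  stopifnot(length(terms) >= 1L, all(terms %in% names(design)))
  y <- design$outcome
  if (length(unique(y)) < 2L)
    stop("outcome is constant; logistic fit is undefined")
  dd <- design[, terms, drop = FALSE]
  dd[] <- lapply(dd, droplevels)
  fit <- stats::glm(y ~ ., data = dd, family = stats::binomial())
  .tidy_or(fit, model = "multivariate")
}
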