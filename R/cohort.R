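# Cohort assignment (A-only / B-only / combination / excluded), tumor-term
# restriction, and Table-1-style clinical characteristics.

COHORT_GROUPS <- c("A_only", "B_only", "A_plus_B", "excluded")

#' Normalize a free-text drug name
#'
#' Uppercases, collapses whitespace, and strips trailing dose/formulation
#' tokens (e.g. `"100 MG"`, `"TABLETS"`) and common salt suffixes so that
#' FAERS free-text names can be matched against a synonym list by exact
#' comparison.
#'
#' @param x character vector of raw drug names.
#' @return character vector of normalized names.
#' @export
normalize_drug_name <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- gsub("[.,;]+$", "", x)
  x <- gsub("\\(([^)]*)\\)", " ", x)            # parenthesised qualifiers
  x <- gsub("\\b[0-9]+(\\.[0-9]+)?\\s*(MG|MCG|G|ML|MG/ML|IU)\\b", " ", x)
  x <- gsub(paste0("\\b(TABLET|TABLETS|CAPSULE|CAPSULES|INJECTION|",
                   "SOLUTION|SODIUM|HYDROCHLORIDE|HCL|SULFATE|",
                   "MALEATE|CITRATE)\\b"), " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Read a preferred-term to system-organ-class lexicon
#'
#' CSV with columns `pt` and `soc`; preferred terms must be unique and every
#' entry must carry a SOC. The package ships a fixture tumor lexicon (~80
#' neoplasm preferred terms grouped into organ-class buckets) at
#' `system.file("extdata", "tumor_lexicon.csv", package = "faersignal")`;
#' a user-supplied file with the same columns is accepted anywhere a
#' lexicon is taken.
#'
#' @param path CSV path; default is the bundled fixture lexicon.
#' @return data.frame with columns `pt`, `soc`.
#' @export
read_lexicon <- function(path = system.file("extdata", "tumor_lexicon.csv",
                                            package = "faersignal")) {
  lex <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("pt", "soc") %in% names(lex)))
    stop("lexicon must have columns pt, soc")
  lex$pt <- trimws(lex$pt)
  lex$soc <- trimws(lex$soc)
  if (anyDuplicated(tolower(lex$pt)))
    stop("lexicon preferred terms must be unique")
  if (any(!nzchar(lex$soc)))
    stop("every lexicon entry needs a system organ class")
  lex[, c("pt", "soc")]
}

#' Map preferred terms to system organ classes
#'
#' Flat case-insensitive lookup against a lexicon; terms absent from the
#' lexicon map to `"unmapped"`.
#'
#' @param pt character vector of preferred terms.
#' @param lexicon data.frame from [read_lexicon()], or `NULL`.
#' @return character vector of SOC labels.
#' @export
map_soc <- function(pt, lexicon = NULL) {
  out <- rep("unmapped", length(pt))
  out[is.na(pt)] <- NA_character_
  if (!is.null(lexicon) && nrow(lexicon)) {
    idx <- match(tolower(pt), tolower(lexicon$pt))
    out[!is.na(idx)] <- lexicon$soc[idx[!is.na(idx)]]
  }
  out
}

#' Read a drug synonym file
#'
#' CSV with columns `ingredient`, `synonym`. Returns the normalized synonym
#' set (including the ingredient name itself) for one ingredient.
#'
#' @param path CSV path; default is the bundled infliximab/azathioprine file.
#' @param ingredient ingredient to extract, case-insensitive.
#' @return character vector of normalized names matching the ingredient.
#' @export
read_synonyms <- function(path = system.file("extdata", "drug_synonyms.csv",
                                             package = "faersignal"),
                          ingredient) {
  syn <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("ingredient", "synonym") %in% names(syn)))
    stop("synonym file must have columns ingredient, synonym")
  sel <- tolower(trimws(syn$ingredient)) == tolower(trimws(ingredient))
  if (!any(sel)) stop("ingredient not found in synonym file: ", ingredient)
  unique(normalize_drug_name(c(ingredient, syn$synonym[sel])))
}

#' Assign reports to treatment cohorts
#'
#' Implements the role-code inclusion rules for a two-drug comparison:
#' * `A_only`  — some drug-A entry with role PS and no drug-B entry in any
#'   role;
#' * `B_only`  — symmetric;
#' * `A_plus_B` — A as PS with B in any role, or B as PS with A in any role;
#' * `excluded` — everything else (neither target drug is a primary
#'   suspect).
#'
#' Drug names are compared after [normalize_drug_name()] against the two
#' synonym sets.
#'
#' @param reports a `faers_reports` object.
#' @param names_a,names_b character synonym sets (normalized internally).
#' @return data.frame with columns `case_id`, `group` (factor over the four
#'   cohort labels), one row per report.
#' @export
assign_group <- function(reports, names_a, names_b) {
  stopifnot(inherits(reports, "faers_reports"),
            length(names_a) > 0, length(names_b) > 0)
  names_a <- normalize_drug_name(names_a)
  names_b <- normalize_drug_name(names_b)
  d <- reports$drugs
  is_a <- d$name_std %in% names_a
  is_b <- d$name_std %in% names_b
  is_ps <- !is.na(d$role) & d$role == "PS"
  agg <- function(flag) {
    ids <- unique(d$case_id[flag])
    reports$reports$case_id %in% ids
  }
  a_ps <- agg(is_a & is_ps); a_any <- agg(is_a)
  b_ps <- agg(is_b & is_ps); b_any <- agg(is_b)
  group <- rep("excluded", nrow(reports$reports))
  group[a_ps & !b_any] <- "A_only"
  group[b_ps & !a_any] <- "B_only"
  group[(a_ps & b_any) | (b_ps & a_any)] <- "A_plus_B"
  data.frame(case_id = reports$reports$case_id,
             group = factor(group, levels = COHORT_GROUPS),
             stringsAsFactors = FALSE)
}

#' Restrict reports to those with at least one tumor-term reaction
#'
#' Keeps every report carrying at least one reaction whose preferred term is
#' in the lexicon (case-insensitive exact match). Kept reports are
#' unchanged; their reaction table gains a logical `tumor` flag and the
#' object gains a `matched_pts` attribute listing the matched terms per
#' case.
#'
#' @param reports a `faers_reports` object.
#' @param lexicon data.frame from [read_lexicon()].
#' @return a filtered `faers_reports` object.
#' @export
filter_tumor_reports <- function(reports, lexicon) {
  stopifnot(inherits(reports, "faers_reports"))
  if (is.null(lexicon) || nrow(lexicon) == 0L)
    stop("tumor lexicon is empty; cohort stage cannot proceed")
  hit <- tolower(reports$reactions$pt) %in% tolower(lexicon$pt)
  keep_ids <- unique(reports$reactions$case_id[hit])
  out <- reports
  for (nm in names(out))
    out[[nm]] <- out[[nm]][out[[nm]]$case_id %in% keep_ids, , drop = FALSE]
  out$reactions$tumor <- tolower(out$reactions$pt) %in% tolower(lexicon$pt)
  matched <- split(out$reactions$pt[out$reactions$tumor],
                   out$reactions$case_id[out$reactions$tumor])
  attr(out, "matched_pts") <- lapply(matched, unique)
  class(out) <- "faers_reports"
  out
}

#' Age and weight bands used in the characteristics table
#'
#' Bands are lower-closed / upper-open so each boundary value falls in
#' exactly one band: age `<18, [18,45), [45,60), [60,75), >=75`; weight
#' `<50, [50,100], >100` kg (both 50 and 100 kg fall in the middle band).
#'
#' @param age_years,weight_kg numeric vectors.
#' @return factor of band labels with `"Missing"` for `NA`.
#' @export
age_band <- function(age_years) {
  lab <- c("<18", "18-45", "45-60", "60-75", ">75")
  b <- cut(as.numeric(age_years), breaks = c(-Inf, 18, 45, 60, 75, Inf),
           labels = lab, right = FALSE)
  b <- as.character(b)
  b[is.na(b)] <- "Missing"
  factor(b, levels = c(lab, "Missing"))
}

#' @rdname age_band
#' @export
weight_band <- function(weight_kg) {
  lab <- c("<50 kg", "50-100 kg", ">100 kg")
  weight_kg <- as.numeric(weight_kg)
  b <- rep(NA_character_, length(weight_kg))
  b[!is.na(weight_kg) & weight_kg < 50] <- lab[1L]
  b[!is.na(weight_kg) & weight_kg >= 50 & weight_kg <= 100] <- lab[2L]
  b[!is.na(weight_kg) & weight_kg > 100] <- lab[3L]
  b[is.na(b)] <- "Missing"
  factor(b, levels = c(lab, "Missing"))
}

#' Tabulate clinical characteristics per cohort
#'
#' Produces the per-group frequency table of sex, weight band, age band,
#' indication class, reporter type and outcome code, with counts and
#' percentages; missing values form their own row. Percentages in an empty
#' group are reported as 0.
#'
#' @param reports a `faers_reports` object.
#' @param assignments data.frame from [assign_group()].
#' @param groups cohort labels to tabulate (default: the three treatment
#'   groups).
#' @return data.frame with columns `characteristic`, `level`, `group`, `n`,
#'   `pct`.
#' @export
tabulate_clinical_characteristics <- function(
    reports, assignments,
    groups = c("A_only", "B_only", "A_plus_B")) {
  stopifnot(inherits(reports, "faers_reports"))
  rr <- merge(reports$reports, assignments, by = "case_id")
  miss <- function(x) {
    x <- as.character(x); x[is.na(x)] <- "Missing"; x
  }
  chars <- list(
    sex = factor(miss(rr$sex), levels = c("female", "male", "Missing")),
    weight = weight_band(rr$weight_kg),
    age = age_band(rr$age_years),
    indication = factor(miss(rr$indication_class),
                        levels = c("gastrointestinal", "other", "Missing")),
    reporter = factor(miss(rr$reporter),
                      levels = c(REPORTER_CODES, "Missing")))
  # outcome is per outcome row, not per report (a report can carry several)
  oo <- merge(reports$outcomes, assignments, by = "case_id")
  chars$outcome <- NULL
  out <- list()
  for (nm in names(chars)) {
    for (g in groups) {
      v <- chars[[nm]][rr$group == g]
      tab <- table(v)
      n_tot <- sum(tab)
      out[[length(out) + 1L]] <- data.frame(
        characteristic = nm, level = names(tab), group = g,
        n = as.integer(tab),
        pct = if (n_tot > 0) round(100 * as.integer(tab) / n_tot, 2) else 0,
        stringsAsFactors = FALSE)
    }
  }
  for (g in groups) {
    v <- factor(miss(oo$outc_cod[oo$group == g]),
                levels = c(OUTCOME_CODES, "Missing"))
    tab <- table(v)
    n_tot <- sum(tab)
    out[[length(out) + 1L]] <- data.frame(
      characteristic = "outcome", level = names(tab), group = g,
      n = as.integer(tab),
      pct = if (n_tot > 0) round(100 * as.integer(tab) / n_tot, 2) else 0,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
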