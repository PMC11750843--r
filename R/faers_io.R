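# Reading, validating and deduplicating FAERS-style quarterly ASCII tables.

FAERS_TABLES <- c("demo", "drug", "reac", "outc", "ther", "indi", "rpsr")
MANDATORY_TABLES <- c("demo", "drug", "reac")

# Minimal column sets per table (FAERS "ASC" layout names). Extra columns are
# carried through untouched; missing optional columns are added as NA.
.faers_required_cols <- list(
  demo = c("primaryid", "caseid", "caseversion"),
  drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname"),
  reac = c("primaryid", "caseid", "pt"),
  outc = c("primaryid", "caseid", "outc_cod"),
  ther = c("primaryid", "caseid", "dsg_drug_seq", "start_dt"),
  indi = c("primaryid", "caseid", "indi_pt"),
  rpsr = c("primaryid", "caseid", "rpsr_cod")
)

#' Read one `$`-delimited FAERS table
#'
#' Rows whose field count differs from the header are padded or truncated to
#' the header width and counted as malformed rather than dropped.
#'
#' @param path file path.
#' @return data.frame of character columns with attribute `n_malformed`.
#' @keywords internal
read_faers_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty FAERS table file: ", path)
  fields <- strsplit(lines, "$", fixed = TRUE)
  header <- tolower(trimws(fields[[1L]]))
  p <- length(header)
  body <- fields[-1L]
  body <- body[!vapply(body, function(x) length(x) == 1L && !nzchar(x[1L]),
                       logical(1L))]
  n_malformed <- sum(lengths(body) != p)
  body <- lapply(body, function(x) {
    length(x) <- p                       # pad with NA / truncate
    x
  })
  mat <- if (length(body)) do.call(rbind, body) else
    matrix(character(0), 0L, p)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  df[] <- lapply(df, function(x) {
    x <- trimws(x)
    x[!nzchar(x)] <- NA_character_
    x
  })
  attr(df, "n_malformed") <- n_malformed
  df
}

#' Read a FAERS quarter
#'
#' Reads the per-table ASCII files of one quarterly release (`$`-delimited,
#' header row, one file per table) into a `faers_quarter` object. DEMO, DRUG
#' and REAC are mandatory; OUTC, THER, INDI and RPSR are optional.
#'
#' @param paths named list or character vector of file paths; names among
#'   `demo, drug, reac, outc, ther, indi, rpsr` (case-insensitive).
#' @param quarter_label quarter identifier matching `YYYYQ[1-4]`, e.g.
#'   `"2024Q2"`.
#' @return A `faers_quarter`: list of parsed tables, the label, and a parse
#'   log with per-table row and malformed-row counts.
#' @export
read_quarter <- function(paths, quarter_label = "2024Q1") {
  if (!grepl("^[0-9]{4}Q[1-4]$", quarter_label))
    stop("quarter_label must match YYYYQ[1-4], got: ", quarter_label)
  paths <- as.list(paths)
  names(paths) <- tolower(names(paths))
  missing_mand <- setdiff(MANDATORY_TABLES, names(paths))
  if (length(missing_mand))
    stop("mandatory FAERS table(s) missing: ",
         paste(missing_mand, collapse = ", "))
  tables <- list()
  log <- list()
  for (nm in intersect(FAERS_TABLES, names(paths))) {
    if (!file.exists(paths[[nm]]))
      stop("file for table '", nm, "' not found: ", paths[[nm]])
    tab <- read_faers_table(paths[[nm]])
    need <- .faers_required_cols[[nm]]
    absent <- setdiff(need, names(tab))
    if (nm %in% MANDATORY_TABLES && length(absent))
      stop("table '", nm, "' lacks required column(s): ",
           paste(absent, collapse = ", "))
    for (cc in absent) tab[[cc]] <- NA_character_
    tables[[nm]] <- tab
    log[[nm]] <- c(rows = nrow(tab), malformed = attr(tab, "n_malformed"))
  }
  demo_case <- unique(tables$demo$caseid)
  for (nm in setdiff(names(tables), "demo")) {
    orphan <- sum(!(tables[[nm]]$caseid %in% demo_case))
    log[[nm]]["orphan_caseid"] <- orphan
  }
  structure(list(tables = tables, quarter_label = quarter_label,
                 parse_log = log),
            class = "faers_quarter")
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat("<faers_quarter ", x$quarter_label, ">\n", sep = "")
  for (nm in names(x$tables))
    cat(sprintf("  %-5s %6d rows (%d malformed)\n", nm,
                nrow(x$tables[[nm]]), x$parse_log[[nm]]["malformed"]))
  invisible(x)
}

#' Convert a reported age to years
#'
#' Applies the FAERS age-unit codes: DEC decades, YR years, MON months,
#' WK weeks, DY days, HR hours. Results outside the plausibility window
#' \[0, 120\] years, and unknown unit codes, become `NA`.
#'
#' @param value numeric vector of reported ages.
#' @param unit_code character vector of unit codes, recycled against `value`.
#' @return numeric vector of ages in years (`NA` where unconvertible).
#' @export
convert_age <- function(value, unit_code) {
  fac <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
           DY = 1 / 365.25, HR = 1 / 8766)
  value <- as.numeric(value)
  f <- fac[toupper(as.character(unit_code))]
  out <- value * as.numeric(f)
  out[!is.finite(out) | out < 0 | out > 120] <- NA_real_
  out
}

#' Convert a reported weight to kilograms
#'
#' KG kept, LBS x 0.453592, GMS / 1000; results outside (0, 500\] kg become
#' `NA`.
#'
#' @param value numeric vector of reported weights.
#' @param unit_code character vector of unit codes (KG, LBS, GMS).
#' @return numeric vector of weights in kg.
#' @export
convert_weight <- function(value, unit_code) {
  fac <- c(KG = 1, LBS = 0.453592, GMS = 1e-3)
  value <- as.numeric(value)
  f <- fac[toupper(as.character(unit_code))]
  out <- value * as.numeric(f)
  out[!is.finite(out) | out <= 0 | out > 500] <- NA_real_
  out
}

#' Parse FAERS dates
#'
#' Accepts full `YYYYMMDD` dates plus the partial forms `YYYYMM` and `YYYY`.
#' Partial dates are anchored to the first day of the period; the returned
#' precision lets day-sensitive analyses (time to onset) discard them.
#'
#' @param x character vector of date strings.
#' @return data.frame with columns `date` (Date, `NA` if unparseable) and
#'   `precision` (`"day"`, `"month"`, `"year"` or `NA`).
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | !grepl("^[0-9]+$", x)] <- ""
  n <- nchar(x)
  prec <- rep(NA_character_, length(x))
  full <- rep(NA_character_, length(x))
  i8 <- n == 8L; prec[i8] <- "day";   full[i8] <- x[i8]
  i6 <- n == 6L; prec[i6] <- "month"; full[i6] <- paste0(x[i6], "01")
  i4 <- n == 4L; prec[i4] <- "year";  full[i4] <- paste0(x[i4], "0101")
  d <- as.Date(full, format = "%Y%m%d")
  prec[is.na(d)] <- NA_character_
  data.frame(date = d, precision = prec, stringsAsFactors = FALSE)
}

.recode_sex <- function(x) {
  out <- rep(NA_character_, length(x))
  out[toupper(x) %in% "F"] <- "female"
  out[toupper(x) %in% "M"] <- "male"
  out
}

REPORTER_CODES <- c("MD", "CN", "OT", "PH", "LW")
OUTCOME_CODES  <- c("OT", "HO", "DE", "LT", "DS", "CA", "RI")

# Indication preferred terms treated as gastrointestinal when classifying
# the indication field (flat fixture set; case-insensitive exact match).
GASTRO_INDICATIONS <- c(
  "Crohn's disease", "Ulcerative colitis", "Colitis ulcerative",
  "Inflammatory bowel disease", "Gastrointestinal disorder",
  "Colitis", "Ileitis", "Proctitis", "Pouchitis", "Coeliac disease"
)

#' Deduplicate quarters into one record per case
#'
#' Collapses one or more quarters to a single report per case identifier,
#' keeping the row with the greatest case version; ties are broken by latest
#' receipt date (`fda_dt`), then by last position in file order. The result
#' is deterministic for a fixed input order. Child tables (drugs, reactions,
#' outcomes, therapy, indications) are restricted to each retained case
#' version via `primaryid`.
#'
#' @param quarters a `faers_quarter` or list of them.
#' @param lexicon optional preferred-term to system-organ-class map (see
#'   [read_lexicon()]) used to annotate reactions; unknown terms map to
#'   `"unmapped"`.
#' @return A `faers_reports` object: list of data.frames `reports` (one row
#'   per case: demographics, dates, reporter, indication class), `drugs`,
#'   `reactions`, `outcomes`, `therapy`, plus a `dedup_log` attribute with
#'   input/output counts.
#' @export
deduplicate <- function(quarters, lexicon = NULL) {
  if (inherits(quarters, "faers_quarter")) quarters <- list(quarters)
  stopifnot(length(quarters) >= 1L,
            all(vapply(quarters, inherits, logical(1L), "faers_quarter")))

  demo <- do.call(rbind, lapply(quarters, function(q) q$tables$demo))
  if (nrow(demo) == 0L) return(.empty_reports())
  demo$.file_order <- seq_len(nrow(demo))
  ver <- suppressWarnings(as.numeric(demo$caseversion))
  ver[is.na(ver)] <- 0
  fda <- if ("fda_dt" %in% names(demo))
    parse_faers_date(demo$fda_dt)$date else as.Date(rep(NA, nrow(demo)))
  fda_key <- as.numeric(fda)
  fda_key[is.na(fda_key)] <- -Inf
  ord <- order(demo$caseid, ver, fda_key, demo$.file_order)
  demo_sorted <- demo[ord, , drop = FALSE]
  keep <- !duplicated(demo_sorted$caseid, fromLast = TRUE)
  kept <- demo_sorted[keep, , drop = FALSE]

  get_tab <- function(nm) {
    tabs <- lapply(quarters, function(q) q$tables[[nm]])
    tabs <- tabs[!vapply(tabs, is.null, logical(1L))]
    if (!length(tabs)) return(NULL)
    do.call(rbind, tabs)
  }
  restrict <- function(tab) {
    if (is.null(tab)) return(NULL)
    tab[tab$primaryid %in% kept$primaryid, , drop = FALSE]
  }
  drug <- restrict(get_tab("drug"))
  reac <- restrict(get_tab("reac"))
  outc <- restrict(get_tab("outc"))
  ther <- restrict(get_tab("ther"))
  indi <- restrict(get_tab("indi"))

  ev <- if ("event_dt" %in% names(kept))
    parse_faers_date(kept$event_dt) else
    data.frame(date = as.Date(rep(NA, nrow(kept))),
               precision = NA_character_)
  age <- if (all(c("age", "age_cod") %in% names(kept)))
    convert_age(kept$age, kept$age_cod) else rep(NA_real_, nrow(kept))
  wt <- if (all(c("wt", "wt_cod") %in% names(kept)))
    convert_weight(kept$wt, kept$wt_cod) else rep(NA_real_, nrow(kept))
  rep_cod <- if ("occp_cod" %in% names(kept))
    ifelse(toupper(kept$occp_cod) %in% REPORTER_CODES,
           toupper(kept$occp_cod), NA_character_) else
    rep(NA_character_, nrow(kept))
  country <- if ("occr_country" %in% names(kept)) kept$occr_country else
    rep(NA_character_, nrow(kept))

  # indication class: gastrointestinal if any INDI term is in the gastro set
  indi_class <- rep(NA_character_, nrow(kept))
  if (!is.null(indi) && nrow(indi)) {
    gi_cases <- unique(indi$caseid[tolower(indi$indi_pt) %in%
                                     tolower(GASTRO_INDICATIONS)])
    any_cases <- unique(indi$caseid[!is.na(indi$indi_pt)])
    indi_class[kept$caseid %in% any_cases] <- "other"
    indi_class[kept$caseid %in% gi_cases] <- "gastrointestinal"
  }

  reports <- data.frame(
    case_id = kept$caseid,
    version = suppressWarnings(as.numeric(kept$caseversion)),
    sex = .recode_sex(if ("sex" %in% names(kept)) kept$sex else
      rep(NA_character_, nrow(kept))),
    age_years = age,
    weight_kg = wt,
    country = country,
    reporter = rep_cod,
    event_date = ev$date,
    event_date_precision = ev$precision,
    indication_class = indi_class,
    stringsAsFactors = FALSE
  )
  reports <- reports[order(reports$case_id), , drop = FALSE]
  rownames(reports) <- NULL

  mk <- function(tab, cols) {
    if (is.null(tab))
      return(as.data.frame(stats::setNames(
        replicate(length(cols), character(0), simplify = FALSE), cols)))
    out <- tab[, intersect(cols, names(tab)), drop = FALSE]
    names(out)[names(out) == "caseid"] <- "case_id"
    out <- out[order(out$case_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  drugs <- mk(drug, c("caseid", "drug_seq", "role_cod", "drugname"))
  names(drugs)[names(drugs) == "role_cod"] <- "role"
  names(drugs)[names(drugs) == "drugname"] <- "name_raw"
  drugs$role <- toupper(drugs$role)
  drugs$role[!(drugs$role %in% c("PS", "SS", "C", "I"))] <- NA_character_
  drugs$name_std <- normalize_drug_name(drugs$name_raw)

  reactions <- mk(reac, c("caseid", "pt"))
  reactions$soc <- map_soc(reactions$pt, lexicon)

  outcomes <- mk(outc, c("caseid", "outc_cod"))
  if (nrow(outcomes)) {
    outcomes$outc_cod <- toupper(outcomes$outc_cod)
    outcomes$outc_cod[!(outcomes$outc_cod %in% OUTCOME_CODES)] <-
      NA_character_
  }

  therapy <- mk(ther, c("caseid", "dsg_drug_seq", "start_dt"))
  if (nrow(therapy)) {
    ps <- parse_faers_date(therapy$start_dt)
    therapy$start_date <- ps$date
    therapy$start_date_precision <- ps$precision
  } else {
    therapy$start_date <- as.Date(character(0))
    therapy$start_date_precision <- character(0)
  }

  n_in <- nrow(demo)
  out <- structure(
    list(reports = reports, drugs = drugs, reactions = reactions,
         outcomes = outcomes, therapy = therapy),
    class = "faers_reports")
  attr(out, "dedup_log") <- c(demo_rows_in = n_in,
                              reports_out = nrow(reports),
                              duplicates_removed = n_in - nrow(reports))
  out
}

.empty_reports <- function() {
  structure(list(
    reports = data.frame(case_id = character(0), version = numeric(0),
                         sex = character(0), age_years = numeric(0),
                         weight_kg = numeric(0), country = character(0),
                         reporter = character(0),
                         event_date = as.Date(character(0)),
                         event_date_precision = character(0),
                         indication_class = character(0),
                         stringsAsFactors = FALSE),
    drugs = data.frame(case_id = character(0), drug_seq = character(0),
                       role = character(0), name_raw = character(0),
                       name_std = character(0), stringsAsFactors = FALSE),
    reactions = data.frame(case_id = character(0), pt = character(0),
                           soc = character(0), stringsAsFactors = FALSE),
    outcomes = data.frame(case_id = character(0), outc_cod = character(0),
                          stringsAsFactors = FALSE),
    therapy = data.frame(case_id = character(0), dsg_drug_seq = character(0),
                         start_dt = character(0),
                         start_date = as.Date(character(0)),
                         start_date_precision = character(0),
                         stringsAsFactors = FALSE)),
    class = "faers_reports")
}

#' @export
print.faers_reports <- function(x, ...) {
  cat("<faers_reports> ", nrow(x$reports), " reports, ",
      nrow(x$drugs), " drug rows, ", nrow(x$reactions),
      " reaction rows\n", sep = "")
  invisible(x)
}

#' Write deduplicated reports to normalized CSV tables
#'
#' One CSV per component table (`reports`, `drugs`, `reactions`,
#' `outcomes`, `therapy`), keyed by `case_id`. [read_reports()] restores the
#' object field-for-field.
#'
#' @param x a `faers_reports` object.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths written.
#' @export
write_reports <- function(x, dir) {
  stopifnot(inherits(x, "faers_reports"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(x)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(x[[nm]], p, row.names = FALSE, na = "")
    paths[nm] <- p
  }
  invisible(paths)
}

#' Read normalized report tables written by [write_reports()]
#'
#' @param dir directory containing the CSVs.
#' @return a `faers_reports` object.
#' @export
read_reports <- function(dir) {
  rd <- function(nm, dates = character(0), nums = character(0)) {
    df <- utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                          stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "")
    for (cc in intersect(dates, names(df))) df[[cc]] <- as.Date(df[[cc]])
    for (cc in intersect(nums, names(df))) df[[cc]] <- as.numeric(df[[cc]])
    df
  }
  out <- list(
    reports = rd("reports", dates = "event_date",
                 nums = c("version", "age_years", "weight_kg")),
    drugs = rd("drugs"),
    reactions = rd("reactions"),
    outcomes = rd("outcomes"),
    therapy = rd("therapy", dates = "start_date"))
  class(out) <- "faers_reports"
  out
}
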