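# Synthetic FAERS-like quarter generator with ground truth.
#
# Emulates the structures the pipeline consumes: per-report demographics
# with missingness, drug entries with role codes, MedDRA-style preferred
# terms with a planted relative-reporting-rate structure, therapy/event
# dates with per-cohort Weibull onset lags, duplicate case versions, and
# reporter/outcome/country fields. Every stage of the pipeline can be
# checked against the generator's bookkeeping.

NON_TUMOR_PTS <- c(
  "Headache", "Nausea", "Diarrhoea", "Fatigue", "Pyrexia", "Arthralgia",
  "Rash", "Pruritus", "Abdominal pain", "Vomiting", "Dizziness", "Cough",
  "Infusion related reaction", "Drug ineffective", "Dyspnoea",
  "Upper respiratory tract infection", "Urinary tract infection",
  "Anaemia", "Leukopenia", "Alanine aminotransferase increased",
  "Weight decreased", "Alopecia", "Insomnia", "Depression",
  "Hypertension", "Oedema peripheral", "Myalgia", "Paraesthesia",
  "Chest pain", "Pneumonia")

OTHER_INDICATIONS <- c("Rheumatoid arthritis", "Psoriasis",
                       "Ankylosing spondylitis", "Psoriatic arthropathy",
                       "Systemic lupus erythematosus")

OTHER_DRUGS <- c("ADALIMUMAB", "METHOTREXATE", "PREDNISONE",
                 "MESALAZINE", "ACETAMINOPHEN", "USTEKINUMAB")

DRUG_A_NAMES <- c("INFLIXIMAB", "REMICADE", "INFLECTRA")
DRUG_B_NAMES <- c("AZATHIOPRINE", "IMURAN", "AZASAN")

#' Configure the synthetic report generator
#'
#' Defaults mirror the clinical characteristics of a combination-therapy
#' spontaneous-report cohort (sex/age/weight mixes with missingness,
#' reporter and outcome distributions) and per-cohort Weibull onset models
#' with medians near 985 days (shape 1) for the A-only cohort and 818 days
#' (shape 0.7) for the combination cohort. All rates are configuration, not
#' assertions about any real database.
#'
#' @param n_reports number of distinct cases to generate.
#' @param seed integer RNG seed; generation is bit-reproducible given it.
#' @param sex_mix,age_mix,weight_mix,reporter_mix,outcome_mix,country_mix
#'   named probability vectors (must sum to 1); `missing` is a category.
#' @param group_mix named probabilities over `A_only`, `B_only`,
#'   `A_plus_B`, `other`. The default keeps every scanned cohort a small
#'   fraction of the universe: in a spontaneous-report database the
#'   case/non-case background dwarfs any one cohort, which is what gives
#'   the observed-to-expected ratio its contrast.
#' @param tumor_pt_rate baseline per-term reporting probability for each
#'   lexicon tumor term.
#' @param non_tumor_pt_rate baseline probability for each background term.
#' @param planted_signals data.frame with columns `group`, `pt`, `lambda`;
#'   in the named cohort the term's reporting rate is `lambda` times
#'   baseline.
#' @param onset_model named list of `c(shape, scale)` per cohort (days).
#' @param onset_missing_rate fraction of reports lacking a day-precision
#'   onset (split between absent therapy rows and month-precision event
#'   dates).
#' @param duplicate_rate fraction of cases additionally emitted as an
#'   earlier case version with one perturbed field, in `[0, 1)`.
#' @param gi_indication_prob named per-cohort probability that the
#'   indication is gastrointestinal.
#' @param date_window character vector of two dates bounding therapy
#'   starts.
#' @param quarter_label label for the emitted quarter.
#' @param lexicon tumor lexicon data.frame (default: bundled fixture).
#' @return validated `synth_config` list.
#' @export
synth_config <- function(
    n_reports = 5000,
    seed = 20240601,
    sex_mix = c(female = 0.4853, male = 0.4010, missing = 0.1137),
    age_mix = c("<18" = 0.1021, "18-45" = 0.3294, "45-60" = 0.1603,
                "60-75" = 0.0950, ">75" = 0.0138, missing = 0.2994),
    weight_mix = c("<50" = 0.0782, "50-100" = 0.4194, ">100" = 0.0561,
                   missing = 0.4463),
    reporter_mix = c(MD = 0.3384, CN = 0.1708, OT = 0.2852, PH = 0.1995,
                     LW = 0.0008, missing = 0.0053),
    outcome_mix = c(OT = 0.5691, HO = 0.3124, DE = 0.0405, LT = 0.0369,
                    DS = 0.0160, CA = 0.0040, RI = 0.0008,
                    missing = 0.0203),
    country_mix = c(US = 0.40, CA = 0.20, GB = 0.12, FR = 0.10,
                    DE = 0.10, JP = 0.08),
    group_mix = c(A_only = 0.15, B_only = 0.05, A_plus_B = 0.08,
                  other = 0.72),
    tumor_pt_rate = 0.002,
    non_tumor_pt_rate = 0.04,
    planted_signals = data.frame(group = character(0), pt = character(0),
                                 lambda = numeric(0)),
    onset_model = list(A_only = c(shape = 1.0, scale = 1420.4),
                       B_only = c(shape = 1.0, scale = 1010.0),
                       A_plus_B = c(shape = 0.7, scale = 1381.0),
                       other = c(shape = 1.0, scale = 1000.0)),
    onset_missing_rate = 0.35,
    duplicate_rate = 0.05,
    gi_indication_prob = c(A_only = 0.5358, B_only = 0.2882,
                           A_plus_B = 0.8493, other = 0.30),
    date_window = c("2010-01-01", "2024-06-30"),
    quarter_label = "2024Q2",
    lexicon = read_lexicon()) {
  cfg <- as.list(environment())
  for (nm in c("sex_mix", "age_mix", "weight_mix", "reporter_mix",
               "outcome_mix", "country_mix", "group_mix")) {
    if (abs(sum(cfg[[nm]]) - 1) > 1e-6)
      stop("'", nm, "' must sum to 1")
    if (any(cfg[[nm]] < 0)) stop("'", nm, "' has negative probabilities")
  }
  if (cfg$duplicate_rate < 0 || cfg$duplicate_rate >= 1)
    stop("duplicate_rate must be in [0, 1)")
  if (nrow(cfg$planted_signals)) {
    stopifnot(all(c("group", "pt", "lambda") %in%
                    names(cfg$planted_signals)))
    if (any(cfg$planted_signals$lambda <= 0))
      stop("planted lambda must be > 0")
    bad <- cfg$planted_signals$lambda * tumor_pt_rate > 1
    if (any(bad))
      stop("planted rate exceeds 1 for: ",
           paste(cfg$planted_signals$pt[bad], collapse = ", "))
  }
  if (!grepl("^[0-9]{4}Q[1-4]$", quarter_label))
    stop("quarter_label must match YYYYQ[1-4]")
  class(cfg) <- "synth_config"
  cfg
}

.sample_mix <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = mix)
}

# Core sampler: all randomness for one synthetic universe, drawn in a fixed
# order from config$seed.
.synth_core <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_reports
  case_id <- sprintf("%08d", 10000000 + seq_len(n))

  group <- .sample_mix(n, config$group_mix)
  sex <- .sample_mix(n, config$sex_mix)
  sex[sex == "missing"] <- NA

  ageb <- .sample_mix(n, config$age_mix)
  age <- rep(NA_integer_, n)
  pools <- list("<18" = 0:17, "18-45" = 18:44, "45-60" = 45:59,
                "60-75" = 60:74, ">75" = 75:95)
  for (b in names(pools)) {
    i <- ageb == b
    if (any(i)) age[i] <- sample(pools[[b]], sum(i), replace = TRUE)
  }
  age_in_months <- stats::runif(n) < 0.15 & !is.na(age)

  wtb <- .sample_mix(n, config$weight_mix)
  wt <- rep(NA_real_, n)
  wpool <- list("<50" = c(35, 49.9), "50-100" = c(50, 100),
                ">100" = c(100.1, 140))
  for (b in names(wpool)) {
    i <- wtb == b
    if (any(i)) wt[i] <- round(stats::runif(sum(i), wpool[[b]][1L],
                                            wpool[[b]][2L]), 1)
  }

  reporter <- .sample_mix(n, config$reporter_mix)
  reporter[reporter == "missing"] <- NA
  outcome <- .sample_mix(n, config$outcome_mix)
  outcome[outcome == "missing"] <- NA
  country <- .sample_mix(n, config$country_mix)

  gi_p <- config$gi_indication_prob[group]
  indi_missing <- stats::runif(n) < 0.05
  is_gi <- stats::runif(n) < gi_p
  indi_pt <- ifelse(is_gi,
                    sample(GASTRO_INDICATIONS, n, replace = TRUE),
                    sample(OTHER_INDICATIONS, n, replace = TRUE))
  indi_pt[indi_missing] <- NA

  # ---- drugs --------------------------------------------------------------
  a_name <- sample(DRUG_A_NAMES, n, replace = TRUE)
  b_name <- sample(DRUG_B_NAMES, n, replace = TRUE)
  o_name <- sample(OTHER_DRUGS, n, replace = TRUE)
  ab_flip <- stats::runif(n) < 0.5          # A_plus_B: A-as-PS vs B-as-PS
  ab_role <- sample(c("SS", "C", "I"), n, replace = TRUE,
                    prob = c(0.3, 0.6, 0.1))
  extra_con <- stats::runif(n) < 0.25       # extra concomitant drug
  oth_has_a <- stats::runif(n) < 0.08       # non-qualifying A mention
  oth_has_b <- stats::runif(n) < 0.08
  oth_role_a <- sample(c("SS", "C"), n, replace = TRUE)
  oth_role_b <- sample(c("SS", "C"), n, replace = TRUE)

  # assembled as segments (primary drug, partner drug, non-qualifying
  # mentions, extra concomitant) then ordered within report
  is_ab <- group == "A_plus_B"
  is_oth <- group == "other"
  prim_name <- ifelse(group == "A_only", a_name,
                ifelse(group == "B_only", b_name,
                 ifelse(is_ab, ifelse(ab_flip, a_name, b_name), o_name)))
  seg_idx <- c(seq_len(n),                       # primary, order 1
               which(is_ab),                     # combination partner
               which(is_oth & oth_has_a),
               which(is_oth & oth_has_b),
               which(extra_con))
  seg_ord <- rep(1:5, c(n, sum(is_ab), sum(is_oth & oth_has_a),
                        sum(is_oth & oth_has_b), sum(extra_con)))
  seg_name <- c(prim_name,
                ifelse(ab_flip[is_ab], b_name[is_ab], a_name[is_ab]),
                a_name[is_oth & oth_has_a],
                b_name[is_oth & oth_has_b],
                o_name[extra_con])
  seg_role <- c(rep("PS", n), ab_role[is_ab],
                oth_role_a[is_oth & oth_has_a],
                oth_role_b[is_oth & oth_has_b],
                rep("C", sum(extra_con)))
  seg_tgt <- c(rep(TRUE, n), rep(TRUE, sum(is_ab)),
               rep(FALSE, sum(is_oth & oth_has_a) +
                     sum(is_oth & oth_has_b) + sum(extra_con)))
  o <- order(seg_idx, seg_ord)
  seq_in_case <- stats::ave(seq_along(o), seg_idx[o], FUN = seq_along)
  drugs <- data.frame(case_id = case_id[seg_idx[o]],
                      drug_seq = as.character(seq_in_case),
                      role = seg_role[o], name_raw = seg_name[o],
                      target = seg_tgt[o],
                      stringsAsFactors = FALSE)

  # ---- reactions ----------------------------------------------------------
  lex <- config$lexicon
  pts <- c(lex$pt, NON_TUMOR_PTS)
  base <- c(rep(config$tumor_pt_rate, nrow(lex)),
            rep(config$non_tumor_pt_rate, length(NON_TUMOR_PTS)))
  names(base) <- pts
  rx_case <- character(0); rx_pt <- character(0)
  for (j in seq_along(pts)) {
    rate <- rep(base[j], n)
    ps <- config$planted_signals
    if (nrow(ps)) {
      hit <- ps$pt == pts[j]
      if (any(hit)) {
        for (k in which(hit))
          rate[group == ps$group[k]] <- base[j] * ps$lambda[k]
      }
    }
    got <- stats::runif(n) < rate
    rx_case <- c(rx_case, case_id[got])
    rx_pt <- c(rx_pt, rep(pts[j], sum(got)))
  }
  none <- !(case_id %in% rx_case)
  if (any(none)) {
    rx_case <- c(rx_case, case_id[none])
    rx_pt <- c(rx_pt, rep("Drug ineffective", sum(none)))
  }
  reactions <- data.frame(case_id = rx_case, pt = rx_pt,
                          stringsAsFactors = FALSE)
  reactions <- reactions[order(reactions$case_id, reactions$pt), ,
                         drop = FALSE]
  rownames(reactions) <- NULL

  # ---- dates and onsets ---------------------------------------------------
  shp <- vapply(config$onset_model[group], `[[`, numeric(1L), "shape")
  scl <- vapply(config$onset_model[group], `[[`, numeric(1L), "scale")
  onset <- round(stats::rweibull(n, shape = shp, scale = scl))
  w0 <- as.Date(config$date_window[1L])
  w1 <- as.Date(config$date_window[2L])
  start <- w0 + sample.int(as.integer(w1 - w0) + 1L, n,
                           replace = TRUE) - 1L
  event <- start + onset
  fda <- event + sample(10:200, n, replace = TRUE)
  u <- stats::runif(n)
  no_ther <- u < config$onset_missing_rate / 2
  month_event <- u >= config$onset_missing_rate / 2 &
    u < config$onset_missing_rate

  # ---- duplicates ---------------------------------------------------------
  n_dup <- floor(config$duplicate_rate * n)
  dup_idx <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)

  list(n = n, case_id = case_id, group = group, sex = sex,
       age = age, age_in_months = age_in_months, wt = wt,
       reporter = reporter, outcome = outcome, country = country,
       indi_pt = indi_pt, drugs = drugs,
       reactions = reactions, onset = onset, start = start, event = event,
       fda = fda, no_ther = no_ther, month_event = month_event,
       dup_idx = dup_idx, lexicon = lex)
}

.truth_from_core <- function(core, config) {
  lex <- core$lexicon
  tumor_rx <- core$reactions[core$reactions$pt %in% lex$pt, , drop = FALSE]
  tumor_rx <- unique(tumor_rx)
  grp <- core$group[match(tumor_rx$case_id, core$case_id)]
  pair_counts <- as.data.frame(table(group = grp, pt = tumor_rx$pt),
                               stringsAsFactors = FALSE)
  names(pair_counts)[3L] <- "a"
  pair_counts <- pair_counts[pair_counts$a > 0, , drop = FALSE]
  rownames(pair_counts) <- NULL
  onset_known <- !core$no_ther & !core$month_event
  structure(list(
    distinct_case_count = core$n,
    group = data.frame(case_id = core$case_id, group = core$group,
                       stringsAsFactors = FALSE),
    tumor_flag = data.frame(
      case_id = core$case_id,
      tumor = core$case_id %in% tumor_rx$case_id,
      stringsAsFactors = FALSE),
    tumor_case_count = length(unique(tumor_rx$case_id)),
    case_tumor_pts = tumor_rx,
    pair_counts = pair_counts,
    onsets = data.frame(case_id = core$case_id, group = core$group,
                        onset_days = core$onset,
                        observed = onset_known,
                        stringsAsFactors = FALSE),
    onset_model = config$onset_model,
    planted_signals = config$planted_signals,
    duplicated_case_ids = core$case_id[core$dup_idx],
    seed = config$seed), class = "synth_truth")
}

#' Generate synthetic reports in memory
#'
#' Runs the generator and returns the canonical deduplicated
#' `faers_reports` object directly (no file round trip) together with the
#' ground truth — the fast path for simulation studies. The file-writing
#' path ([generate_quarter()]) emits exactly this universe; reading and
#' deduplicating its files reproduces this object.
#'
#' @param config a `synth_config`.
#' @return list with elements `reports` (a `faers_reports`) and `truth`
#'   (a `synth_truth`).
#' @export
synth_reports <- function(config) {
  core <- .synth_core(config)
  ev_date <- core$event
  ev_prec <- rep("day", core$n)
  ev_date[core$month_event] <- as.Date(format(core$event[core$month_event],
                                              "%Y-%m-01"))
  ev_prec[core$month_event] <- "month"
  reports <- data.frame(
    case_id = core$case_id,
    version = ifelse(seq_len(core$n) %in% core$dup_idx, 2, 1),
    sex = core$sex,
    age_years = as.numeric(core$age),
    weight_kg = core$wt,
    country = core$country,
    reporter = core$reporter,
    event_date = ev_date,
    event_date_precision = ev_prec,
    indication_class = ifelse(is.na(core$indi_pt), NA_character_,
                              ifelse(core$indi_pt %in% GASTRO_INDICATIONS,
                                     "gastrointestinal", "other")),
    stringsAsFactors = FALSE)
  drugs <- core$drugs
  drugs$name_std <- normalize_drug_name(drugs$name_raw)
  drugs <- drugs[, c("case_id", "drug_seq", "role", "name_raw", "name_std")]
  rownames(drugs) <- NULL
  reactions <- core$reactions
  reactions$soc <- map_soc(reactions$pt, core$lexicon)
  outcomes <- data.frame(case_id = core$case_id,
                         outc_cod = core$outcome,
                         stringsAsFactors = FALSE)
  outcomes <- outcomes[!is.na(outcomes$outc_cod), , drop = FALSE]
  rownames(outcomes) <- NULL
  ci <- match(core$drugs$case_id, core$case_id)
  ther_sel <- core$drugs$target & !core$no_ther[ci]
  therapy <- data.frame(
    case_id = core$drugs$case_id[ther_sel],
    dsg_drug_seq = core$drugs$drug_seq[ther_sel],
    start_dt = format(core$start[ci[ther_sel]], "%Y%m%d"),
    stringsAsFactors = FALSE)
  rownames(therapy) <- NULL
  pd <- parse_faers_date(therapy$start_dt)
  therapy$start_date <- pd$date
  therapy$start_date_precision <- pd$precision
  obj <- structure(list(reports = reports, drugs = drugs,
                        reactions = reactions, outcomes = outcomes,
                        therapy = therapy),
                   class = "faers_reports")
  list(reports = obj, truth = .truth_from_core(core, config))
}

.fmt_field <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

.write_faers_file <- function(df, path) {
  header <- paste(names(df), collapse = "$")
  body <- do.call(paste, c(lapply(df, .fmt_field), sep = "$"))
  writeLines(c(header, body), path)
}

#' Generate a synthetic FAERS quarter on disk
#'
#' Writes the `$`-delimited DEMO/DRUG/REAC/OUTC/THER/INDI/RPSR files of one
#' synthetic quarter plus `ground_truth.json`, bit-reproducibly for a fixed
#' seed. A configurable fraction of cases is additionally emitted as an
#' earlier case version with a perturbed weight and earlier receipt date,
#' exercising the keep-latest-version deduplication. Ages are emitted in
#' years or months (unit code `MON`, exact multiples) and weights in kg.
#'
#' @param config a `synth_config`.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with `paths` (named file paths, suitable for
#'   [read_quarter()]), `quarter_label`, and `truth`.
#' @export
generate_quarter <- function(config, outdir) {
  core <- .synth_core(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n <- core$n
  version <- ifelse(seq_len(n) %in% core$dup_idx, "2", "1")
  primaryid <- paste0(core$case_id, version)

  age_val <- ifelse(core$age_in_months, core$age * 12L, core$age)
  age_cod <- ifelse(core$age_in_months, "MON", "YR")
  age_cod[is.na(core$age)] <- NA
  sex_code <- c(female = "F", male = "M")[core$sex]

  ev <- format(core$event, "%Y%m%d")
  ev[core$month_event] <- format(core$event[core$month_event], "%Y%m")

  demo <- data.frame(
    primaryid = primaryid, caseid = core$case_id, caseversion = version,
    fda_dt = format(core$fda, "%Y%m%d"), event_dt = ev,
    age = age_val, age_cod = age_cod, sex = sex_code,
    wt = core$wt, wt_cod = ifelse(is.na(core$wt), NA, "KG"),
    occp_cod = core$reporter, reporter_country = core$country,
    occr_country = core$country, stringsAsFactors = FALSE)

  drug <- core$drugs
  drug <- data.frame(primaryid = primaryid[match(drug$case_id,
                                                 core$case_id)],
                     caseid = drug$case_id, drug_seq = drug$drug_seq,
                     role_cod = drug$role, drugname = drug$name_raw,
                     stringsAsFactors = FALSE)
  reac <- data.frame(
    primaryid = primaryid[match(core$reactions$case_id, core$case_id)],
    caseid = core$reactions$case_id, pt = core$reactions$pt,
    stringsAsFactors = FALSE)
  has_out <- !is.na(core$outcome)
  outc <- data.frame(primaryid = primaryid[has_out],
                     caseid = core$case_id[has_out],
                     outc_cod = core$outcome[has_out],
                     stringsAsFactors = FALSE)
  ci <- match(core$drugs$case_id, core$case_id)
  ther_sel <- core$drugs$target & !core$no_ther[ci]
  ther <- data.frame(primaryid = primaryid[ci[ther_sel]],
                     caseid = core$drugs$case_id[ther_sel],
                     dsg_drug_seq = core$drugs$drug_seq[ther_sel],
                     start_dt = format(core$start[ci[ther_sel]],
                                       "%Y%m%d"),
                     stringsAsFactors = FALSE)
  has_indi <- !is.na(core$indi_pt)
  indi <- data.frame(primaryid = primaryid[has_indi],
                     caseid = core$case_id[has_indi],
                     indi_drug_seq = "1", indi_pt = core$indi_pt[has_indi],
                     stringsAsFactors = FALSE)
  rpsr <- data.frame(primaryid = primaryid, caseid = core$case_id,
                     rpsr_cod = "FGN", stringsAsFactors = FALSE)

  # earlier case versions for the duplicated cases: perturbed weight,
  # earlier receipt date, minimal child rows under their own primaryid
  if (length(core$dup_idx)) {
    i <- core$dup_idx
    old_pid <- paste0(core$case_id[i], "1")
    old <- demo[match(core$case_id[i], demo$caseid), , drop = FALSE]
    old$primaryid <- old_pid
    old$caseversion <- "1"
    old$fda_dt <- format(core$fda[i] - 30L, "%Y%m%d")
    old$wt <- ifelse(is.na(core$wt[i]), NA, core$wt[i] + 1)
    demo <- rbind(demo, old)
    d_old <- core$drugs[core$drugs$case_id %in% core$case_id[i], ,
                        drop = FALSE]
    drug <- rbind(drug, data.frame(
      primaryid = paste0(d_old$case_id, "1"), caseid = d_old$case_id,
      drug_seq = d_old$drug_seq, role_cod = d_old$role,
      drugname = d_old$name_raw, stringsAsFactors = FALSE))
    r_old <- core$reactions[core$reactions$case_id %in% core$case_id[i], ,
                            drop = FALSE]
    reac <- rbind(reac, data.frame(
      primaryid = paste0(r_old$case_id, "1"), caseid = r_old$case_id,
      pt = r_old$pt, stringsAsFactors = FALSE))
  }

  paths <- c(demo = file.path(outdir, "DEMO.txt"),
             drug = file.path(outdir, "DRUG.txt"),
             reac = file.path(outdir, "REAC.txt"),
             outc = file.path(outdir, "OUTC.txt"),
             ther = file.path(outdir, "THER.txt"),
             indi = file.path(outdir, "INDI.txt"),
             rpsr = file.path(outdir, "RPSR.txt"))
  .write_faers_file(demo, paths["demo"])
  .write_faers_file(drug, paths["drug"])
  .write_faers_file(reac, paths["reac"])
  .write_faers_file(outc, paths["outc"])
  .write_faers_file(ther, paths["ther"])
  .write_faers_file(indi, paths["indi"])
  .write_faers_file(rpsr, paths["rpsr"])

  truth <- .truth_from_core(core, config)
  tj <- truth
  tj$onset_model <- lapply(tj$onset_model, as.list)
  class(tj) <- NULL
  jsonlite::write_json(tj, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(paths = as.list(paths),
                 quarter_label = config$quarter_label, truth = truth))
}

#' Ground-truth contingency tables
#'
#' Exact per-(cohort, term) tables computed from the generator's
#' bookkeeping (true counts, not expectations), for equality checks
#' against [build_tables()].
#'
#' @param truth a `synth_truth` from the generator.
#' @param lexicon the tumor lexicon used at generation.
#' @param group target cohort label.
#' @return data.frame with `pt`, `a`, `b`, `c`, `d`.
#' @export
expected_tables <- function(truth, lexicon, group) {
  stopifnot(inherits(truth, "synth_truth"))
  grp <- truth$group
  in_t <- grp$case_id[grp$group == group]
  in_b <- grp$case_id[grp$group != group]
  rx <- truth$case_tumor_pts
  a_tab <- table(factor(rx$pt[rx$case_id %in% in_t], levels = lexicon$pt))
  c_tab <- table(factor(rx$pt[rx$case_id %in% in_b], levels = lexicon$pt))
  keep <- a_tab >= 1L
  out <- data.frame(pt = lexicon$pt[keep],
                    a = as.integer(a_tab[keep]),
                    c = as.integer(c_tab[keep]),
                    stringsAsFactors = FALSE)
  out$b <- length(in_t) - out$a
  out$d <- length(in_b) - out$c
  out[, c("pt", "a", "b", "c", "d")]
}
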