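# Fixtures built in code: a tiny hand-written quarter and small report
# objects used across the unit tests.

# Three-case quarter: 3 DEMO rows, 5 DRUG rows; case 30000003 has an empty
# sex field; case 30000001 reappears as version 2 (weight corrected).
write_tiny_quarter <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(name, lines) {
    p <- file.path(dir, name)
    writeLines(lines, p)
    p
  }
  paths <- list(
    demo = w("DEMO.txt", c(
      "primaryid$caseid$caseversion$fda_dt$event_dt$age$age_cod$sex$wt$wt_cod$occp_cod$occr_country",
      "300000011$30000001$1$20240110$20240101$45$YR$F$70$KG$MD$US",
      "300000012$30000001$2$20240210$20240101$45$YR$F$72$KG$MD$US",
      "300000021$30000002$1$20240115$20231220$780$MON$M$154$LBS$CN$CA",
      "300000031$30000003$1$20240120$202312$6$DEC$$$$$FR")),
    drug = w("DRUG.txt", c(
      "primaryid$caseid$drug_seq$role_cod$drugname",
      "300000011$30000001$1$PS$REMICADE",
      "300000012$30000001$1$PS$REMICADE",
      "300000012$30000001$2$C$IMURAN",
      "300000021$30000002$1$PS$AZATHIOPRINE",
      "300000031$30000003$1$PS$INFLIXIMAB 100 MG",
      "300000031$30000003$2$C$PREDNISONE")),
    reac = w("REAC.txt", c(
      "primaryid$caseid$pt",
      "300000011$30000001$Headache",
      "300000012$30000001$Basal cell carcinoma",
      "300000012$30000001$Basal cell carcinoma",
      "300000021$30000002$Lymphoma",
      "300000031$30000003$Headache")),
    outc = w("OUTC.txt", c(
      "primaryid$caseid$outc_cod",
      "300000012$30000001$HO",
      "300000021$30000002$OT")),
    ther = w("THER.txt", c(
      "primaryid$caseid$dsg_drug_seq$start_dt",
      "300000012$30000001$1$20230601",
      "300000021$30000002$1$20230101",
      "300000031$30000003$1$202301")))
  paths
}

# Minimal in-memory report set for cohort/regression tests.
make_reports <- function(drugs, reactions = NULL, reports = NULL) {
  ids <- unique(drugs$case_id)
  if (is.null(reports))
    reports <- data.frame(
      case_id = ids, version = 1, sex = "female", age_years = 40,
      weight_kg = 70, country = "US", reporter = "MD",
      event_date = as.Date("2024-01-01"), event_date_precision = "day",
      indication_class = "other", stringsAsFactors = FALSE)
  if (is.null(reactions))
    reactions <- data.frame(case_id = ids, pt = "Headache",
                            soc = "unmapped", stringsAsFactors = FALSE)
  drugs$name_std <- faersignal::normalize_drug_name(drugs$name_raw)
  if (is.null(drugs$drug_seq))
    drugs$drug_seq <- as.character(stats::ave(seq_len(nrow(drugs)),
                                              drugs$case_id,
                                              FUN = seq_along))
  structure(list(
    reports = reports, drugs = drugs, reactions = reactions,
    outcomes = data.frame(case_id = character(0), outc_cod = character(0),
                          stringsAsFactors = FALSE),
    therapy = data.frame(case_id = character(0),
                         dsg_drug_seq = character(0),
                         start_dt = character(0),
                         start_date = as.Date(character(0)),
                         start_date_precision = character(0),
                         stringsAsFactors = FALSE)),
    class = "faers_reports")
}

NAMES_A <- c("INFLIXIMAB", "REMICADE", "INFLECTRA")
NAMES_B <- c("AZATHIOPRINE", "IMURAN", "AZASAN")

random_tables <- function(n, seed) {
  set.seed(seed)
  data.frame(a = sample(0:60, n, TRUE), b = sample(1:2000, n, TRUE),
             c = sample(0:500, n, TRUE), d = sample(100:100000, n, TRUE))
}
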