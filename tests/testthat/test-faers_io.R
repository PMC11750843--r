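test_that("read_quarter parses the fixture quarter with expected counts", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_quarter(dir)
  q <- read_quarter(paths, "2024Q1")
  expect_s3_class(q, "faers_quarter")
  expect_equal(nrow(q$tables$demo), 4L)   # 3 cases, one with 2 versions
  expect_equal(length(unique(q$tables$demo$caseid)), 3L)
  expect_equal(nrow(q$tables$drug), 6L)
  expect_equal(unname(q$parse_log$demo["malformed"]), 0L)
})

test_that("read_quarter rejects missing mandatory tables and bad labels", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_quarter(dir)
  expect_error(read_quarter(paths[c("demo", "drug")], "2024Q1"),
               "mandatory")
  expect_error(read_quarter(paths, "2024Q5"), "quarter_label")
})

test_that("malformed rows are counted but kept", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "DEMO.txt")
  writeLines(c("primaryid$caseid$caseversion",
               "11$1$1",
               "21$2$1$EXTRA_FIELD",
               "31$3"), p)
  tab <- faersignal:::read_faers_table(p)
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "n_malformed"), 2L)
})

test_that("age conversion applies unit codes and plausibility bounds", {
  expect_equal(convert_age(45, "YR"), 45)
  expect_equal(convert_age(6, "DEC"), 60)
  expect_equal(convert_age(780, "MON"), 65)
  expect_true(is.na(convert_age(200, "YR")))   # beyond 120 years
  expect_true(is.na(convert_age(-5, "YR")))
  expect_true(is.na(convert_age(45, "XX")))    # unknown unit code
  expect_equal(convert_age(c(45, 6), c("YR", "DEC")), c(45, 60))
})

test_that("weight conversion handles LBS and GMS and bounds", {
  expect_equal(convert_weight(100, "KG"), 100)
  expect_equal(convert_weight(154, "LBS"), 154 * 0.453592)
  expect_equal(convert_weight(70000, "GMS"), 70)
  expect_true(is.na(convert_weight(900, "KG")))
  expect_true(is.na(convert_weight(0, "KG")))
})

test_that("dates parse at day, month and year precision", {
  p <- parse_faers_date(c("20240131", "202401", "2024", "bad", ""))
  expect_equal(p$date[1:3],
               as.Date(c("2024-01-31", "2024-01-01", "2024-01-01")))
  expect_equal(p$precision, c("day", "month", "year", NA, NA))
})

test_that("deduplication keeps the latest case version", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_quarter(dir)
  q <- read_quarter(paths, "2024Q1")
  rep <- deduplicate(q, lexicon = read_lexicon())
  expect_equal(nrow(rep$reports), 3L)
  r1 <- rep$reports[rep$reports$case_id == "30000001", ]
  expect_equal(r1$version, 2)
  expect_equal(r1$weight_kg, 72)          # the corrected version-2 weight
  # child rows come from the kept version only
  expect_equal(sort(rep$reactions$pt[rep$reactions$case_id == "30000001"]),
               c("Basal cell carcinoma", "Basal cell carcinoma"))
  expect_setequal(rep$drugs$name_std[rep$drugs$case_id == "30000001"],
                  c("REMICADE", "IMURAN"))
  # unit conversions flowed through
  expect_equal(rep$reports$age_years[rep$reports$case_id == "30000002"], 65)
  expect_true(is.na(rep$reports$sex[rep$reports$case_id == "30000003"]))
  # month-precision event date kept for demographics, flagged as not day
  expect_equal(
    rep$reports$event_date_precision[rep$reports$case_id == "30000003"],
    "month")
})

test_that("dedup output size matches the generator's distinct-case count", {
  cfg <- synth_config(n_reports = 1000, seed = 11, duplicate_rate = 0.10)
  dir <- withr::local_tempdir()
  gen <- generate_quarter(cfg, dir)
  q <- read_quarter(gen$paths, cfg$quarter_label)
  expect_equal(nrow(q$tables$demo), 1000L + 100L)
  rep <- deduplicate(q)
  expect_equal(nrow(rep$reports), gen$truth$distinct_case_count)
})

test_that("dedup is idempotent and never increases the report count", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_quarter(dir)
  q <- read_quarter(paths, "2024Q1")
  once <- deduplicate(q)
  twice <- deduplicate(list(q, q))   # same cases presented again
  expect_equal(once$reports, twice$reports)
  expect_lte(nrow(once$reports), nrow(q$tables$demo))
  # all-distinct input: output size equals input size
  cfg <- synth_config(n_reports = 50, seed = 3, duplicate_rate = 0)
  gen <- generate_quarter(cfg, withr::local_tempdir())
  q2 <- read_quarter(gen$paths, cfg$quarter_label)
  expect_equal(nrow(deduplicate(q2)$reports), 50L)
})

test_that("normalized tables round-trip field-for-field", {
  cfg <- synth_config(n_reports = 120, seed = 5)
  sr <- synth_reports(cfg)
  dir <- withr::local_tempdir()
  write_reports(sr$reports, dir)
  back <- read_reports(dir)
  for (nm in names(sr$reports)) {
    expect_equal(back[[nm]], sr$reports[[nm]], ignore_attr = TRUE,
                 info = nm)
  }
})

test_that("reading a generated quarter reproduces the in-memory universe", {
  cfg <- synth_config(n_reports = 300, seed = 9)
  sr <- synth_reports(cfg)
  gen <- generate_quarter(cfg, withr::local_tempdir())
  q <- read_quarter(gen$paths, cfg$quarter_label)
  rep <- deduplicate(q, lexicon = read_lexicon())
  for (nm in names(sr$reports))
    expect_equal(rep[[nm]], sr$reports[[nm]], ignore_attr = TRUE,
                 info = nm)
})
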