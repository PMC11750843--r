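# Brute-force two-group log-rank oracle: tally observed minus expected
# deaths in group 1 over the risk sets at each distinct event time.
naive_logrank <- function(t1, t2) {
  times <- sort(unique(c(t1, t2)))
  o_minus_e <- 0; v <- 0
  for (t in times) {
    n1 <- sum(t1 >= t); n2 <- sum(t2 >= t); n <- n1 + n2
    d1 <- sum(t1 == t); d2 <- sum(t2 == t); d <- d1 + d2
    if (n < 2) next
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

test_that("onsets are event minus earliest therapy start, day precision", {
  drugs <- data.frame(case_id = c("1", "2", "3", "3"),
                      drug_seq = c("1", "1", "1", "2"),
                      role = "PS",
                      name_raw = "REMICADE", stringsAsFactors = FALSE)
  reports <- data.frame(
    case_id = c("1", "2", "3"), version = 1, sex = "female",
    age_years = 40, weight_kg = 70, country = "US", reporter = "MD",
    event_date = as.Date(c("2020-01-31", "2020-01-01", "2020-06-01")),
    event_date_precision = c("day", "day", "month"),
    indication_class = "other", stringsAsFactors = FALSE)
  rep <- make_reports(drugs, reports = reports)
  rep$therapy <- data.frame(
    case_id = c("1", "2", "3", "3"),
    dsg_drug_seq = c("1", "1", "1", "2"),
    start_dt = c("20200101", "20200301", "20200201", "20200101"),
    start_date = as.Date(c("2020-01-01", "2020-03-01", "2020-02-01",
                           "2020-01-01")),
    start_date_precision = "day", stringsAsFactors = FALSE)
  asg <- assign_group(rep, NAMES_A, NAMES_B)
  on <- compute_onsets(rep, asg, list(A_only = NAMES_A))
  expect_equal(on$onset_days[on$case_id == "1"], 30)
  # case 2: event precedes therapy start -> excluded as negative
  expect_false("2" %in% on$case_id)
  # case 3: month-precision event date -> excluded
  expect_false("3" %in% on$case_id)
  excl <- attr(on, "exclusions")
  expect_equal(unname(excl["negative_onset"]), 1L)
  expect_equal(unname(excl["missing_event"]), 1L)
})

test_that("earliest therapy start is used when several rows exist", {
  drugs <- data.frame(case_id = "1", drug_seq = "1", role = "PS",
                      name_raw = "REMICADE", stringsAsFactors = FALSE)
  reports <- data.frame(
    case_id = "1", version = 1, sex = "female", age_years = 40,
    weight_kg = 70, country = "US", reporter = "MD",
    event_date = as.Date("2020-12-31"), event_date_precision = "day",
    indication_class = "other", stringsAsFactors = FALSE)
  rep <- make_reports(drugs, reports = reports)
  rep$therapy <- data.frame(
    case_id = "1", dsg_drug_seq = "1",
    start_dt = c("20200601", "20200101"),
    start_date = as.Date(c("2020-06-01", "2020-01-01")),
    start_date_precision = "day", stringsAsFactors = FALSE)
  asg <- assign_group(rep, NAMES_A, NAMES_B)
  on <- compute_onsets(rep, asg, list(A_only = NAMES_A))
  expect_equal(on$onset_days, 365)
})

test_that("synthetic Weibull onsets have the closed-form median", {
  set.seed(10)
  x <- rweibull(5000, shape = 1, scale = 1000)
  expect_lt(abs(median(x) - 1000 * log(2)) / (1000 * log(2)), 0.1)
})

test_that("Weibull fit recovers parameters and refuses degenerate input", {
  set.seed(11)
  x <- rweibull(10000, shape = 1, scale = 900)
  wf <- weibull_fit(x)
  expect_lt(abs(wf$shape - 1), 0.03)          # consistency, small bias
  expect_lt(abs(wf$scale - 900) / 900, 0.05)  # exponential: mean = scale
  expect_true(wf$shape_lo95 <= wf$shape & wf$shape <= wf$shape_hi95)
  expect_error(weibull_fit(rep(5, 20)), "identical")
  expect_error(weibull_fit(1:5), "at least")
})

test_that("failure-type classification follows the shape interval rule", {
  set.seed(12)
  early <- weibull_fit(rweibull(2000, 0.6, 1000))
  expect_equal(early$failure_type, "early")
  expect_lt(early$shape_hi95, 1)
  wear <- weibull_fit(rweibull(2000, 1.6, 1000))
  expect_equal(wear$failure_type, "wear_out")
  rand <- weibull_fit(rweibull(2000, 1.0, 1000))
  expect_equal(rand$failure_type, "random")
})

test_that("rank-sum test matches enumeration and the reference test", {
  same <- rank_sum_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_equal(same$method, "exact")
  sep <- rank_sum_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$p, 0.1)      # 2/20 of rank assignments as extreme
  # normal approximation against R's reference implementation
  set.seed(13)
  a <- rweibull(40, 1, 500); b <- rweibull(35, 1, 800)
  got <- rank_sum_compare(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  # tie correction agrees with the reference under heavy ties
  at <- c(1, 1, 2, 2, 3, 5, 5, 8, 9, 9, 10, 12)
  bt <- c(1, 2, 2, 3, 3, 5, 7, 8, 8, 9, 11, 11, 13)
  got_t <- rank_sum_compare(at, bt, exact_max = 0)
  ref_t <- stats::wilcox.test(at, bt, exact = FALSE, correct = TRUE)
  expect_equal(got_t$p, ref_t$p.value, tolerance = 1e-10)
})

test_that("cumulative incidence curves are proper distribution functions", {
  set.seed(14)
  g <- list(A = rweibull(60, 1, 500), B = rweibull(45, 0.8, 700))
  ci <- cumulative_incidence(g)
  for (nm in names(g)) {
    cc <- ci$curves[ci$curves$group == nm, ]
    expect_equal(cc$cuminc[1], 0)
    expect_equal(cc$cuminc[nrow(cc)], 1)
    expect_true(all(diff(cc$cuminc) >= 0))
  }
  # identical groups: zero statistic
  same <- cumulative_incidence(list(A = g$A, B = g$A))
  expect_equal(same$logrank_chi2, 0, tolerance = 1e-12)
  # symmetry under label swap
  swap <- cumulative_incidence(list(A = g$B, B = g$A))
  expect_equal(swap$logrank_chi2, ci$logrank_chi2, tolerance = 1e-10)
})

test_that("log-rank statistic matches a brute-force risk-set tally", {
  t1 <- c(10, 25, 40, 41, 90)
  t2 <- c(12, 30, 55, 70, 100)
  ci <- cumulative_incidence(list(A = t1, B = t2))
  expect_equal(ci$logrank_chi2, naive_logrank(t1, t2), tolerance = 1e-10)
  set.seed(15)
  t3 <- rweibull(25, 1, 300); t4 <- rweibull(30, 1.4, 250)
  ci2 <- cumulative_incidence(list(A = t3, B = t4))
  expect_equal(ci2$logrank_chi2, naive_logrank(t3, t4), tolerance = 1e-10)
})

test_that("onset summaries use interpolated quartiles and year bands", {
  s <- onset_summary(c(100, 200, 300))
  expect_equal(s$median, 200)
  expect_equal(onset_summary(c(1, 2, 3, 4))$median, 2.5)
  # linear-interpolation oracle on random samples
  set.seed(16)
  for (i in 1:20) {
    x <- runif(sample(5:40, 1), 0, 3000)
    s <- onset_summary(x)
    xs <- sort(x); n <- length(xs)
    manual_q <- function(p) {
      h <- (n - 1) * p + 1
      lo <- floor(h)
      xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
    }
    expect_equal(s$q25, manual_q(0.25), tolerance = 1e-12)
    expect_equal(s$median, manual_q(0.5), tolerance = 1e-12)
    expect_equal(s$q75, manual_q(0.75), tolerance = 1e-12)
  }
  b <- onset_summary(c(100, 400, 800, 2000, 3000))$year_bands
  expect_equal(unname(b), c(1L, 2L, 2L))
  m <- onset_summary(c(10, 40, 100), monthly = TRUE)
  expect_equal(sum(m$monthly_bins$count), 3L)
})
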