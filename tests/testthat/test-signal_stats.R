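# Naive direct-formula reimplementations used as oracles throughout.
naive_ror <- function(a, b, c, d) (a * d) / (b * c)
naive_prr <- function(a, b, c, d) (a / (a + b)) / (c / (c + d))
naive_chi2 <- function(a, b, c, d) {
  o <- c(a, b, c, d)
  n <- sum(o)
  e <- c((a + b) * (a + c), (a + b) * (b + d),
         (c + d) * (a + c), (c + d) * (b + d)) / n
  sum((o - e)^2 / e)
}

test_that("contingency tables count each report once per term", {
  lex <- read_lexicon()
  drugs <- data.frame(case_id = as.character(1:4), role = "PS",
                      name_raw = c("REMICADE", "REMICADE", "PREDNISONE",
                                   "PREDNISONE"), stringsAsFactors = FALSE)
  reac <- data.frame(
    case_id = c("1", "1", "2", "3", "4"),
    pt = c("Lymphoma", "Lymphoma", "Headache", "Headache", "Nausea"),
    soc = "x", stringsAsFactors = FALSE)
  rep <- make_reports(drugs, reactions = reac)
  asg <- assign_group(rep, NAMES_A, NAMES_B)
  tab <- build_tables(rep, asg, lex, "A_only")
  expect_equal(nrow(tab), 1L)
  # duplicated PT rows in report 1 counted once
  expect_equal(tab[tab$pt == "Lymphoma", c("a", "b", "c", "d")],
               data.frame(a = 1L, b = 1L, c = 0L, d = 2L),
               ignore_attr = TRUE)
  # empty background is fatal
  asg2 <- asg; asg2$group[] <- "A_only"
  expect_error(build_tables(rep, asg2, lex, "A_only"), "background")
})

test_that("build_tables equals the generator's ground-truth tables", {
  cfg <- synth_config(
    n_reports = 3000, seed = 77,
    planted_signals = data.frame(group = "A_plus_B", pt = "Anal cancer",
                                 lambda = 25))
  sr <- synth_reports(cfg)
  lex <- read_lexicon()
  asg <- assign_group(sr$reports, NAMES_A, NAMES_B)
  for (g in c("A_only", "B_only", "A_plus_B")) {
    got <- build_tables(sr$reports, asg, lex, g)
    want <- expected_tables(sr$truth, lex, g)
    expect_equal(got[, c("pt", "a", "b", "c", "d")], want,
                 ignore_attr = TRUE, info = g)
  }
})

test_that("ROR matches its closed form and criteria", {
  r <- ror_stat(10, 10, 10, 10)
  expect_equal(r$ror, 1)
  expect_false(r$pass_ror)
  r2 <- ror_stat(10, 90, 100, 9900)
  expect_equal(r2$ror, 11)
  expect_equal(r2$ror_lo95,
               exp(log(11) - 1.96 * sqrt(1 / 10 + 1 / 90 + 1 / 100 +
                                           1 / 9900)))
  expect_true(r2$pass_ror)
  # scale invariance of the point estimate, narrower CI with more data
  small <- ror_stat(3, 1, 1, 3); big <- ror_stat(30, 10, 10, 30)
  expect_equal(small$ror, 9); expect_equal(big$ror, 9)
  expect_lt(big$ror_hi95 - big$ror_lo95, small$ror_hi95 - small$ror_lo95)
  # zero cell: continuity correction applied and flagged, a = 0 never passes
  z <- ror_stat(0, 10, 5, 100)
  expect_true(z$ror_corrected)
  expect_false(z$pass_ror)
  expect_true(is.finite(z$ror))
})

test_that("PRR and chi-square match direct computation", {
  p <- prr_stat(10, 90, 100, 9900)
  expect_equal(p$prr, 10)
  ind <- prr_stat(10, 90, 90, 810)   # exact independence
  expect_equal(ind$prr, 1)
  expect_equal(ind$chi2, 0)
  tabs <- random_tables(20, seed = 5)
  tabs$a <- tabs$a + 1; tabs$c <- tabs$c + 1   # keep cells positive
  got <- prr_stat(tabs$a, tabs$b, tabs$c, tabs$d)
  want <- mapply(naive_chi2, tabs$a, tabs$b, tabs$c, tabs$d)
  expect_equal(got$chi2, want, tolerance = 1e-12)
})

test_that("information component shrinks and matches independence limit", {
  big <- bcpnn_ic(1000, 9000, 9000, 81000)
  expect_lt(abs(big$ic), 0.05)
  expect_false(big$pass_bcpnn)
  x <- bcpnn_ic(10, 90, 100, 9900)
  expect_gt(x$ic, 0)
  expect_lt(x$ic, log2(10))          # shrunk below the raw log2 ratio
  # asymptotic consistency: scale the same ratios up
  ks <- c(1, 10, 100, 1000)
  ics <- vapply(ks, function(k)
    bcpnn_ic(10 * k, 90 * k, 100 * k, 9900 * k)$ic, numeric(1))
  # limit: log2 of observed/expected = log2(a N / ((a+b)(a+c)))
  expect_lt(abs(ics[4] - log2(10 * 10100 / (100 * 110))), 0.02)
  expect_true(all(diff(abs(ics - ics[4])) <= 0))
})

test_that("shrinkage bounds and monotonicity in a hold", {
  set.seed(8)
  prior <- NULL
  for (i in 1:25) {
    a <- sample(1:50, 1); b <- sample(50:5000, 1)
    c <- sample(1:200, 1); d <- sample(1000:50000, 1)
    E <- expected_count(a, b, c, d)
    if (a / E <= 1) next
    ic <- bcpnn_ic(a, b, c, d)$ic
    expect_gte(ic, 0 - 1e-9)
    expect_lte(ic, log2(a / E) + 1e-9)
  }
  # monotonicity with b, c, d fixed
  as <- 1:30
  b <- 500; c <- 40; d <- 20000
  ror <- ror_stat(as, b, c, d)$ror
  prr <- prr_stat(as, b, c, d)$prr
  ic <- bcpnn_ic(as, b, c, d)$ic
  expect_true(all(diff(ror) > 0))
  expect_true(all(diff(prr) > 0))
  expect_true(all(diff(ic) > 0))
  # prior fitted on null pairs (counts at their expectations) so that the
  # shrinkage bound 1 <= EBGM <= a/E applies
  tabs <- random_tables(200, seed = 2)
  En <- expected_count(tabs$a, tabs$b, tabs$c, tabs$d)
  set.seed(2)
  a_null <- rpois(length(En), En)
  pr <- fit_gps_prior(a_null, En, seed = 2)
  E1 <- expected_count(as, b, c, d)
  eb <- ebgm_stat(as, E1, pr)$ebgm
  expect_true(all(diff(eb) > 0))
  # shrinkage bound for the gamma-Poisson mixture
  hi <- as / E1 > 1
  expect_true(all(eb[hi] <= as[hi] / E1[hi] + 1e-6))
  expect_true(all(eb[hi] >= 1 - 0.35))   # mild undershoot allowed by prior
})

test_that("MGPS prior fit improves on its start and handles null data", {
  tabs <- random_tables(500, seed = 13)
  E <- expected_count(tabs$a, tabs$b, tabs$c, tabs$d)
  pr <- fit_gps_prior(tabs$a, E, seed = 13)
  expect_true(pr$converged)
  expect_gte(pr$loglik, pr$loglik_start)
  # null data: a == E exactly at large counts -> prior mass near lambda = 1
  a0 <- rep(200L, 100)
  pr0 <- fit_gps_prior(a0, rep(200, 100), seed = 1)
  post_mean <- pr0$p_mix * pr0$alpha1 / pr0$beta1 +
    (1 - pr0$p_mix) * pr0$alpha2 / pr0$beta2
  expect_lt(abs(post_mean - 1), 0.1)
  eb <- ebgm_stat(a0[1], 200, pr0)
  expect_lt(abs(eb$ebgm - 1), 0.1)
})

test_that("degenerate single-component prior reduces to conjugate gamma", {
  prior <- structure(list(alpha1 = 2, beta1 = 4, alpha2 = 2, beta2 = 4,
                          p_mix = 0.5, loglik = 0, converged = TRUE,
                          n_pairs = 0), class = "gps_prior")
  # both components identical -> closed-form Gamma(alpha + a, beta + E)
  a <- 12; E <- 3
  got <- ebgm_stat(a, E, prior)
  shape <- 2 + a; rate <- 4 + E
  expect_equal(got$ebgm, exp(digamma(shape) - log(rate)), tolerance = 1e-10)
  expect_equal(got$eb05, qgamma(0.05, shape, rate), tolerance = 1e-6)
  # a = 0 pulls below 1 and fails the criterion
  z <- ebgm_stat(0, 2, prior)
  expect_lt(z$ebgm, 1)
  expect_false(z$pass_mgps)
})

test_that("conjunction is the logical AND of the four criteria", {
  expect_true(conjunction(TRUE, TRUE, TRUE, TRUE))
  expect_false(conjunction(FALSE, TRUE, TRUE, TRUE))
  expect_equal(conjunction(c(TRUE, TRUE), c(TRUE, FALSE),
                           c(TRUE, TRUE), c(TRUE, TRUE)),
               c(TRUE, FALSE))
})

test_that("score_tables carries invariant column relationships", {
  tabs <- random_tables(150, seed = 99)
  tabs <- tabs[tabs$a + tabs$c > 0, ]
  sc <- score_tables(tabs)
  expect_true(all(sc$ror_lo95 <= sc$ror & sc$ror <= sc$ror_hi95))
  expect_true(all(sc$ic025 <= sc$ic))
  expect_true(all(sc$eb05 <= sc$ebgm + 1e-9))
  expect_equal(sc$significant,
               sc$pass_ror & sc$pass_prr & sc$pass_bcpnn & sc$pass_mgps)
})
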