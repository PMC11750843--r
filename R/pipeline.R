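# End-to-end orchestration: ingest -> dedup -> cohort -> tumor filter ->
# signals -> regression -> onset, with a run manifest.

#' Default pipeline configuration
#'
#' @param quarters list of per-quarter path lists (as taken by
#'   [read_quarter()]), or `NULL` to generate a synthetic universe.
#' @param quarter_labels labels matching `quarters`.
#' @param synth a `synth_config` used when `quarters` is `NULL`.
#' @param lexicon_path,synonyms_path CSV paths (default: bundled fixtures).
#' @param drug_a,drug_b ingredient names looked up in the synonym file.
#' @param outdir output directory.
#' @param seed integer seed (forwarded to the synthetic generator when one
#'   is used, and recorded in the manifest).
#' @param thresholds signal criteria (see `DEFAULT_THRESHOLDS`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(quarters = NULL, quarter_labels = NULL,
                            synth = NULL,
                            lexicon_path = system.file(
                              "extdata", "tumor_lexicon.csv",
                              package = "faersignal"),
                            synonyms_path = system.file(
                              "extdata", "drug_synonyms.csv",
                              package = "faersignal"),
                            drug_a = "infliximab",
                            drug_b = "azathioprine",
                            outdir = tempfile("faersignal_run"),
                            seed = 1L,
                            thresholds = DEFAULT_THRESHOLDS) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

.write_out <- function(df, outdir, name) {
  p <- file.path(outdir, name)
  utils::write.csv(df, p, row.names = FALSE, na = "")
  p
}

#' Run the full analysis pipeline
#'
#' Executes the complete flow on real or synthetic quarters: ingest and
#' deduplicate, assign cohorts, restrict to tumor terms, tabulate clinical
#' characteristics, run the four-algorithm signal scan per cohort, fit the
#' univariate/multivariate logistic comparisons (within each cohort and
#' between combination and each monotherapy), and characterize time to
#' onset (quartiles, Weibull failure type, rank-sum and log-rank
#' comparisons, cumulative incidence). All result tables are written as
#' CSV under `config$outdir` along with `manifest.json` recording stage
#' counts, input hashes, seed and package version. Deterministic given
#' inputs and seed.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  lexicon <- read_lexicon(config$lexicon_path)
  if (nrow(lexicon) == 0L) stop("cohort stage: tumor lexicon is empty")
  names_a <- read_synonyms(config$synonyms_path, config$drug_a)
  names_b <- read_synonyms(config$synonyms_path, config$drug_b)

  # ---- ingest -------------------------------------------------------------
  if (is.null(config$quarters)) {
    if (is.null(config$synth))
      stop("ingest stage: neither quarters nor a synthetic config given")
    synth_cfg <- config$synth
    synth_cfg$seed <- config$seed
    synth_dir <- file.path(outdir, "synthetic_quarter")
    gen <- generate_quarter(synth_cfg, synth_dir)
    quarters <- list(gen$paths)
    quarter_labels <- gen$quarter_label
  } else {
    quarters <- config$quarters
    quarter_labels <- config$quarter_labels
    if (is.null(quarter_labels))
      quarter_labels <- rep("2024Q1", length(quarters))
  }
  qs <- mapply(read_quarter, quarters, quarter_labels, SIMPLIFY = FALSE)
  n_loaded <- sum(vapply(qs, function(q) nrow(q$tables$demo), integer(1L)))
  input_files <- unlist(quarters, use.names = FALSE)
  input_hashes <- tools::md5sum(input_files)

  # ---- dedup & cohorts ----------------------------------------------------
  reports <- deduplicate(qs, lexicon = lexicon)
  assignments <- assign_group(reports, names_a, names_b)
  grouped <- sum(assignments$group != "excluded")
  tumor <- filter_tumor_reports(reports, lexicon)
  tumor_assign <- assignments[assignments$case_id %in%
                                tumor$reports$case_id, , drop = FALSE]

  characteristics <- tabulate_clinical_characteristics(reports, assignments)
  .write_out(characteristics, outdir, "clinical_characteristics.csv")
  .write_out(assignments, outdir, "cohort_assignments.csv")

  # ---- signals ------------------------------------------------------------
  groups <- c("A_only", "B_only", "A_plus_B")
  signals <- list()
  sig_cases <- list()
  for (g in groups) {
    sc <- signal_scan(reports, assignments, lexicon, g,
                      thresholds = config$thresholds)
    signals[[g]] <- sc
    .write_out(sc, outdir, paste0("signals_", g, ".csv"))
    sig_pts <- sc$pt[sc$significant]
    rx <- tumor$reactions
    ids <- unique(rx$case_id[tolower(rx$pt) %in% tolower(sig_pts)])
    in_g <- assignments$case_id[assignments$group == g]
    sig_cases[[g]] <- intersect(ids, in_g)
  }
  outcome_ids <- unique(unlist(sig_cases))

  # ---- regression ---------------------------------------------------------
  regressions <- list()
  reg_tables <- list()
  within_specs <- list(A_only = "A_only", B_only = "B_only",
                       A_plus_B = "A_plus_B",
                       A_vs_combo = c("A_only", "A_plus_B"),
                       B_vs_combo = c("B_only", "A_plus_B"))
  for (nm in names(within_specs)) {
    gs <- within_specs[[nm]]
    terms <- if (length(gs) > 1L) c("sex", "age", "weight", "group") else
      c("sex", "age", "weight")
    des <- build_design(reports, assignments, outcome_ids, groups = gs)
    res <- tryCatch({
      scr <- univariate_screen(des, terms = terms)
      multi <- if (length(scr$selected))
        fit_multivariate(des, scr$selected) else NULL
      rbind(scr$estimates[, -1L],
            if (!is.null(multi)) multi)
    }, error = function(e) {
      data.frame(term = NA_character_, or = NA_real_, lo95 = NA_real_,
                 hi95 = NA_real_, p = NA_real_, separation = NA,
                 model = paste("skipped:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    regressions[[nm]] <- res
    reg_tables[[nm]] <- .write_out(res, outdir,
                                   paste0("regression_", nm, ".csv"))
  }

  # ---- time to onset ------------------------------------------------------
  target_names <- list(A_only = names_a, B_only = names_b,
                       A_plus_B = c(names_a, names_b))
  onsets <- compute_onsets(tumor, tumor_assign, target_names)
  .write_out(onsets, outdir, "onsets.csv")
  by_group <- split(onsets$onset_days, onsets$group)
  weib <- list()
  wrows <- list()
  for (g in names(by_group)) {
    x <- by_group[[g]]
    s <- onset_summary(x)
    wf <- tryCatch(weibull_fit(x), error = function(e) NULL)
    weib[[g]] <- wf
    wrows[[g]] <- data.frame(
      group = g, n = s$n, median = s$median, q25 = s$q25, q75 = s$q75,
      shape = if (is.null(wf)) NA else wf$shape,
      shape_lo95 = if (is.null(wf)) NA else wf$shape_lo95,
      shape_hi95 = if (is.null(wf)) NA else wf$shape_hi95,
      scale = if (is.null(wf)) NA else wf$scale,
      failure_type = if (is.null(wf)) NA_character_ else wf$failure_type,
      stringsAsFactors = FALSE)
  }
  weibull_summary <- do.call(rbind, wrows)
  .write_out(weibull_summary, outdir, "weibull_summary.csv")

  comparisons <- list()
  crow <- list()
  pairs <- list(c("A_only", "A_plus_B"), c("B_only", "A_plus_B"),
                c("A_only", "B_only"))
  for (pr in pairs) {
    if (!all(pr %in% names(by_group))) next
    a <- by_group[[pr[1L]]]; b <- by_group[[pr[2L]]]
    if (!length(a) || !length(b)) next
    rs <- rank_sum_compare(a, b)
    ci <- cumulative_incidence(stats::setNames(list(a, b), pr))
    key <- paste(pr, collapse = "_vs_")
    comparisons[[key]] <- list(rank_sum = rs, cuminc = ci)
    crow[[key]] <- data.frame(
      group_1 = pr[1L], group_2 = pr[2L],
      n_1 = length(a), n_2 = length(b),
      median_1 = rs$median_a, q25_1 = rs$q_a[1L], q75_1 = rs$q_a[2L],
      median_2 = rs$median_b, q25_2 = rs$q_b[1L], q75_2 = rs$q_b[2L],
      z = rs$z, p = rs$p,
      logrank_chi2 = ci$logrank_chi2, logrank_p = ci$logrank_p,
      stringsAsFactors = FALSE)
    .write_out(ci$curves, outdir, paste0("cuminc_", key, ".csv"))
  }
  if (length(crow))
    .write_out(do.call(rbind, crow), outdir, "onset_comparisons.csv")

  # ---- manifest -----------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("faersignal")),
    seed = config$seed,
    drug_a = config$drug_a, drug_b = config$drug_b,
    thresholds = config$thresholds,
    input_files = as.list(stats::setNames(as.character(input_hashes),
                                          basename(input_files))),
    stage_counts = list(
      loaded = n_loaded,
      deduplicated = nrow(reports$reports),
      grouped = grouped,
      tumor_filtered = nrow(tumor$reports),
      signal_tested = sum(vapply(signals, nrow, integer(1L))),
      significant_signals = vapply(signals, function(s)
        sum(s$significant), integer(1L)),
      onset_records = nrow(onsets)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # stage-count monotonicity contract
  with(manifest$stage_counts, stopifnot(
    loaded >= deduplicated, deduplicated >= grouped,
    deduplicated >= tumor_filtered))

  invisible(list(reports = reports, assignments = assignments,
                 tumor = tumor, characteristics = characteristics,
                 signals = signals, regressions = regressions,
                 onsets = onsets, weibull = weib,
                 weibull_summary = weibull_summary,
                 comparisons = comparisons, manifest = manifest,
                 outdir = outdir))
}
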