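# Descriptive outputs: demographics of the target cases, drug rankings,
# ATC class composition of the positive signals, and the end-to-end
# pipeline driver that wires ingestion -> dedup -> signals -> onset ->
# tables and writes plot-ready CSVs.

outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

count_block <- function(level, count, total) {
  data.table::data.table(level = as.character(level %||% character()),
                         count = as.integer(count),
                         pct = round_half_up(100 * count / max(total, 1L), 1))
}

#' Demographics of the target cases
#'
#' Tabulates sex, age bands (`<18`, `18-64`, `>=65`, unknown; ages converted
#' to years via [age_to_years()]), weight bands (`<80`, `>=80` kg, unknown),
#' outcome codes (a case counts once per distinct code, so the outcome block
#' can exceed the case total), reporter occupations, top-5 reporter
#' countries and per-year report counts (FDA receipt year). Percentages are
#' computed against the target-case total with half-up rounding to one
#' decimal.
#'
#' @param target a `faers_target_cases` object.
#' @return A `pv_demographics` list of count tables plus `n_total`,
#'   `age_median`/`age_q1`/`age_q3` and the weight analogues.
#' @export
demographics <- function(target) {
  demo <- target$demo
  n <- nrow(demo)
  sex <- ifelse(demo$sex %in% c("F", "M"), demo$sex, "unknown")
  sex_tab <- count_block(c("F", "M", "unknown"),
                         c(sum(sex == "F"), sum(sex == "M"),
                           sum(sex == "unknown")), n)
  years <- age_to_years(demo$age, demo$age_cod)
  band <- ifelse(is.na(years), "unknown",
                 ifelse(years < 18, "<18",
                        ifelse(years < 65, "18-64", ">=65")))
  age_tab <- count_block(c("<18", "18-64", ">=65", "unknown"),
                         vapply(c("<18", "18-64", ">=65", "unknown"),
                                function(b) sum(band == b), integer(1L)), n)
  aq <- if (any(!is.na(years))) {
    stats::quantile(years[!is.na(years)], c(0.25, 0.5, 0.75), type = 7,
                    names = FALSE)
  } else rep(NA_real_, 3L)
  wt <- num_or_na(demo$wt)
  wband <- ifelse(is.na(wt), "unknown", ifelse(wt < 80, "<80", ">=80"))
  wt_tab <- count_block(c("<80", ">=80", "unknown"),
                        vapply(c("<80", ">=80", "unknown"),
                               function(b) sum(wband == b), integer(1L)), n)
  wq <- if (any(!is.na(wt))) {
    stats::quantile(wt[!is.na(wt)], c(0.25, 0.5, 0.75), type = 7,
                    names = FALSE)
  } else rep(NA_real_, 3L)
  # outcomes: one count per distinct code per case; cases with no outcome
  # record are "unknown"
  oc <- unique(target$outc[, c("primaryid", "outc_cod"), with = FALSE])
  oc <- oc[oc$outc_cod %chin% outcome_codes]
  n_unk_outc <- n - length(unique(oc$primaryid))
  oc_counts <- vapply(outcome_codes, function(k) sum(oc$outc_cod == k),
                      integer(1L))
  outc_tab <- count_block(c(outcome_codes, "unknown"),
                          c(oc_counts, n_unk_outc), n)
  occ <- ifelse(demo$occp_cod == "" | is.na(demo$occp_cod), "unknown",
                demo$occp_cod)
  occ_levels <- sort(unique(occ))
  occ_tab <- count_block(occ_levels,
                         vapply(occ_levels, function(k) sum(occ == k),
                                integer(1L)), n)
  ctry <- ifelse(demo$reporter_country == "" | is.na(demo$reporter_country),
                 "unknown", demo$reporter_country)
  ct <- sort(table(ctry), decreasing = TRUE)
  ct <- utils::head(ct, 5L)
  ctry_tab <- count_block(names(ct), as.integer(ct), n)
  yr <- substr(demo$fda_dt, 1L, 4L)
  yr[!grepl("^[0-9]{4}$", yr)] <- "unknown"
  yt <- table(yr)
  year_tab <- data.table::data.table(
    year = as.character(names(yt) %||% character()),
    count = as.integer(yt))
  out <- list(n_total = n, sex = sex_tab, age_bands = age_tab,
              age_median = aq[2L], age_q1 = aq[1L], age_q3 = aq[3L],
              weight_bands = wt_tab,
              weight_median = wq[2L], weight_q1 = wq[1L], weight_q3 = wq[3L],
              outcomes = outc_tab, reporters = occ_tab,
              top_countries = ctry_tab, years = year_tab)
  class(out) <- "pv_demographics"
  out
}

#' Flatten a demographics object to one tidy table
#'
#' @param x a `pv_demographics` object.
#' @return data.table with columns `section`, `level`, `count`, `pct`.
#' @export
demographics_table <- function(x) {
  sec <- function(name, tab) {
    data.table::data.table(section = rep(name, nrow(tab)), tab)
  }
  blocks <- list(sec("sex", x$sex), sec("age_years", x$age_bands),
                 sec("weight_kg", x$weight_bands), sec("outcome", x$outcomes),
                 sec("reporter", x$reporters), sec("country", x$top_countries),
                 sec("year", data.table::data.table(
                   level = x$years$year, count = x$years$count,
                   pct = rep(NA_real_, nrow(x$years)))))
  data.table::rbindlist(blocks)
}

#' @export
print.pv_demographics <- function(x, ...) {
  cat(sprintf("Target-case demographics: n = %d, median age %.1f (IQR %.1f-%.1f)\n",
              x$n_total, x$age_median, x$age_q1, x$age_q3))
  invisible(x)
}

#' Rank drugs by case count or ROR
#'
#' Deterministic total order: the ranking key descending, ties broken by
#' ingredient name ascending. Undefined RORs sort last.
#'
#' @param signals a `pv_signal_table`.
#' @param by `"cases"` (the `a` cell) or `"ror"`.
#' @param k number of rows to keep (the full table if larger).
#' @param positive_only restrict to signal-positive drugs (default `TRUE`).
#' @return data.table.
#' @export
rank_drugs <- function(signals, by = c("cases", "ror"), k = 50L,
                       positive_only = TRUE) {
  by <- match.arg(by)
  x <- data.table::as.data.table(signals)
  if (positive_only) x <- x[x$positive]
  key <- if (by == "cases") x$a else x$ror
  x <- x[order(-key, x$ingredient, na.last = TRUE, method = "radix")]
  utils::head(x, k)
}

#' ATC class composition of the positive signals
#'
#' Counts signal-positive drugs per ATC level-1 class; shares are percent of
#' all positive drugs, half-up rounded to one decimal.
#'
#' @param signals a `pv_signal_table`.
#' @return data.table with columns `atc_class`, `n_drugs`, `share_pct`,
#'   sorted by count descending.
#' @export
class_composition <- function(signals) {
  pos <- data.table::as.data.table(signals)[signals$positive]
  if (nrow(pos) == 0L) {
    return(data.table::data.table(atc_class = character(),
                                  n_drugs = integer(),
                                  share_pct = numeric()))
  }
  res <- pos[, list(n_drugs = .N), by = "atc_class"]
  res[, share_pct := round_half_up(100 * n_drugs / nrow(pos), 1)]
  data.table::setorder(res, -n_drugs, atc_class)
  res[]
}

#' Analyze an in-memory quarter bundle
#'
#' Runs link -> dedup -> target selection -> contingency tables -> signal
#' statistics on a `faers_bundle` without touching disk.
#'
#' @param bundle a `faers_bundle`.
#' @param synonym_map,atc_map dictionary maps.
#' @param target_pt_code target event PT code.
#' @param hyper [bcpnn_hyperparameters()].
#' @param ic025_method passed to [compute_ic()].
#' @return list with `cases` (deduplicated), `target`, `tables`, `signals`.
#' @export
analyze_bundle <- function(bundle, synonym_map = default_synonym_map(),
                           atc_map = default_atc_map(),
                           target_pt_code = 10012599L,
                           hyper = bcpnn_hyperparameters(),
                           ic025_method = c("sd", "literal")) {
  cases <- deduplicate_cases(link_cases(bundle))
  target <- select_target_cases(cases, target_pt_code, synonym_map)
  tables <- build_contingency_tables(cases, target, synonym_map)
  signals <- signal_table(tables, atc_map, hyper, ic025_method)
  list(cases = cases, target = target, tables = tables, signals = signals)
}

#' Assemble a run configuration
#'
#' @param demo,drug,reac,ther,outc paths to the five quarterly tables.
#' @param synonym_map,atc_map paths to the dictionary files (defaults: the
#'   bundled maps).
#' @param target_pt_code target event PT code (default 10012599).
#' @param hyper [bcpnn_hyperparameters()] or a named list of them.
#' @param ic025_method `"sd"` or `"literal"`.
#' @param top_k rows kept in the ranking outputs.
#' @param out_dir output directory.
#' @param seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return A `pv_run_config` list.
#' @export
run_config <- function(demo, drug, reac, ther, outc,
                       synonym_map = system.file("extdata", "drug_synonyms.tsv",
                                                 package = "faerspv"),
                       atc_map = system.file("extdata", "atc_classes.tsv",
                                             package = "faerspv"),
                       target_pt_code = 10012599L,
                       hyper = bcpnn_hyperparameters(),
                       ic025_method = "sd",
                       top_k = 50L,
                       out_dir = "faerspv-out",
                       seed = 1L) {
  cfg <- list(paths = list(demo = demo, drug = drug, reac = reac,
                           ther = ther, outc = outc),
              synonym_map = synonym_map, atc_map = atc_map,
              target_pt_code = as.integer(target_pt_code),
              hyper = if (inherits(hyper, "bcpnn_hyperparameters")) hyper else
                do.call(bcpnn_hyperparameters, as.list(hyper)),
              ic025_method = ic025_method,
              top_k = as.integer(top_k),
              out_dir = out_dir, seed = as.integer(seed))
  class(cfg) <- "pv_run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Expects keys matching the arguments of [run_config()]; table paths under
#' `paths:` or at top level.
#'
#' @param path YAML file path.
#' @return A `pv_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_faers("read_run_config: file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$paths)) {
    raw <- c(raw$paths, raw[setdiff(names(raw), "paths")])
  }
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Reads the five tables, links and deduplicates cases, extracts the target
#' cases, computes the signal table, time-to-onset summaries for the
#' positive drugs, demographics, rankings and class composition, and writes
#' everything to `out_dir`. Outputs are staged in a temporary subdirectory
#' and moved into place only on success; any stage error aborts with a
#' stage-named message and removes partial outputs. Deterministic given the
#' same inputs.
#'
#' @param cfg a `pv_run_config` (or path to a YAML file for one).
#' @return Invisibly, a list with the in-memory results (`signals`,
#'   `onset_summary`, `demographics`, `log`) and `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stage <- "configuration"
  log_lines <- character()
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  out_dir <- cfg$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  staging <- file.path(out_dir, sprintf(".staging-%d", Sys.getpid()))
  dir.create(staging, showWarnings = FALSE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  result <- tryCatch({
    for (p in c(unlist(cfg$paths), cfg$synonym_map, cfg$atc_map)) {
      if (!file.exists(p)) stop_faers("input file not found: ", p)
    }
    syn <- read_synonym_map(cfg$synonym_map)
    atc <- read_atc_map(cfg$atc_map)

    stage <- "ingestion"
    bundle <- do.call(read_quarter, cfg$paths)
    for (k in c("demo", "drug", "reac", "ther", "outc")) {
      note("ingestion: %s parsed=%d rejected=%d", toupper(k),
           bundle$log[[k]]$parsed, bundle$log[[k]]$rejected)
    }

    stage <- "linking"
    cases <- link_cases(bundle)
    note("linking: %d report versions, orphans: %s", nrow(cases$demo),
         paste(names(cases$log$orphans), cases$log$orphans,
               sep = "=", collapse = " "))

    stage <- "deduplication"
    cases <- deduplicate_cases(cases)
    note("deduplication: %d versions -> %d cases",
         cases$log$dedup$versions_in, cases$log$dedup$cases_out)

    stage <- "target selection"
    target <- select_target_cases(cases, cfg$target_pt_code, syn)
    note("target selection: %d cases with PT %d, %d unmapped PS drug names",
         target$log$n_target_cases, cfg$target_pt_code,
         target$log$n_unmapped_ps)

    stage <- "disproportionality"
    tables <- build_contingency_tables(cases, target, syn)
    signals <- signal_table(tables, atc, cfg$hyper, cfg$ic025_method)
    strata <- table(signals$strength[signals$positive])
    note("disproportionality: %d drugs, %d positive (%s)", nrow(signals),
         sum(signals$positive),
         paste(names(strata), as.integer(strata), sep = "=", collapse = " "))

    stage <- "onset analysis"
    onsets <- compute_tto(target)
    onset_sum <- summarize_tto(onsets,
                               signals$ingredient[signals$positive])
    excl <- table(onsets$reason[onsets$reason != "ok"])
    note("onset analysis: %d usable records, excluded: %s",
         sum(onsets$reason == "ok"),
         if (length(excl)) paste(names(excl), as.integer(excl), sep = "=",
                                 collapse = " ") else "none")

    stage <- "reporting"
    demog <- demographics(target)
    note("reporting: demographics over %d target cases", demog$n_total)

    write_signal_table(signals, file.path(staging, "signal_table.csv"),
                       file.path(staging, "signal_table.json"))
    data.table::fwrite(onsets, file.path(staging, "onset_records.csv"))
    data.table::fwrite(onset_sum, file.path(staging, "onset_summary.csv"))
    data.table::fwrite(demographics_table(demog),
                       file.path(staging, "demographics.csv"))
    data.table::fwrite(class_composition(signals),
                       file.path(staging, "class_composition.csv"))
    data.table::fwrite(rank_drugs(signals, "cases", cfg$top_k),
                       file.path(staging, "ranking_by_cases.csv"))
    data.table::fwrite(rank_drugs(signals, "ror", cfg$top_k),
                       file.path(staging, "ranking_by_ror.csv"))
    writeLines(log_lines, file.path(staging, "run_log.txt"))
    for (f in list.files(staging)) {
      file.rename(file.path(staging, f), file.path(out_dir, f))
    }
    list(signals = signals, onset_records = onsets,
         onset_summary = onset_sum, demographics = demog,
         log = log_lines, out_dir = out_dir)
  }, error = function(e) {
    stop_faers("run_pipeline: stage '", stage, "' failed: ",
               conditionMessage(e))
  })
  invisible(result)
}
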