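# Case-level processing: FDA-rule deduplication, drug-name standardization
# via an auditable synonym map, ATC level-1 classification, target-event case
# extraction (PS-role drugs only) and age-unit conversion.

#' Read a drug synonym map
#'
#' Two-column delimited file mapping verbatim drug strings to standardized
#' ingredient names. Keys are normalized (case-folded, whitespace-collapsed,
#' surrounding punctuation stripped) on load.
#'
#' @param path file path (tab- or comma-delimited with header
#'   `verbatim`, `ingredient`).
#' @return Named character vector: normalized verbatim -> ingredient.
#' @export
read_synonym_map <- function(path) {
  if (!file.exists(path)) stop_faers("read_synonym_map: file not found: ", path)
  m <- data.table::fread(path, colClasses = "character")
  if (!all(c("verbatim", "ingredient") %in% names(m))) {
    stop_faers("read_synonym_map: needs columns 'verbatim' and 'ingredient'")
  }
  if (any(m$ingredient == "")) {
    stop_faers("read_synonym_map: empty ingredient value(s)")
  }
  stats::setNames(m$ingredient, normalize_drug_name(m$verbatim))
}

#' Default bundled synonym map
#' @return Named character vector (see [read_synonym_map()]).
#' @export
default_synonym_map <- function() {
  read_synonym_map(system.file("extdata", "drug_synonyms.tsv",
                               package = "faerspv"))
}

#' Read an ATC level-1 classification map
#'
#' Three-column delimited file: `ingredient`, `atc_code` (one of the 14 WHO
#' anatomical main groups), `atc_label`.
#'
#' @param path file path.
#' @return data.table with the three columns.
#' @export
read_atc_map <- function(path) {
  if (!file.exists(path)) stop_faers("read_atc_map: file not found: ", path)
  m <- data.table::fread(path, colClasses = "character")
  if (!all(c("ingredient", "atc_code", "atc_label") %in% names(m))) {
    stop_faers("read_atc_map: needs columns ingredient, atc_code, atc_label")
  }
  main_groups <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N", "P",
                   "R", "S", "V")
  bad <- setdiff(unique(m$atc_code), main_groups)
  if (length(bad)) {
    stop_faers("read_atc_map: atc_code values outside the 14 anatomical main groups: ",
               paste(bad, collapse = ", "))
  }
  m
}

#' Default bundled ATC map
#' @return data.table (see [read_atc_map()]).
#' @export
default_atc_map <- function() {
  read_atc_map(system.file("extdata", "atc_classes.tsv", package = "faerspv"))
}

# canonical form used for dictionary lookup
normalize_drug_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  x <- gsub("^[[:space:][:punct:]]+|[[:space:][:punct:]]+$", "", x)
  x
}

#' Standardize verbatim drug names
#'
#' Case-folds, collapses whitespace and strips surrounding punctuation, then
#' performs an exact lookup in the synonym map. No fuzzy matching: misses
#' return `NA` (the "unmapped" outcome) and are counted by callers.
#'
#' @param verbatim character vector of verbatim drug names.
#' @param map named character vector from [read_synonym_map()].
#' @return Character vector of standardized ingredients, `NA` where unmapped.
#' @export
normalize_drug <- function(verbatim, map) {
  unname(map[normalize_drug_name(verbatim)])
}

#' Assign the ATC level-1 class of an ingredient
#'
#' Exact dictionary lookup; ingredients absent from the map return
#' `"UNCLASSIFIED"`.
#'
#' @param ingredient character vector of standardized ingredients.
#' @param map data.table from [read_atc_map()].
#' @param what return the class `"code"` or its `"label"`.
#' @return Character vector.
#' @export
assign_atc <- function(ingredient, map, what = c("code", "label")) {
  what <- match.arg(what)
  i <- match(ingredient, map$ingredient)
  out <- if (what == "code") map$atc_code[i] else map$atc_label[i]
  out[is.na(out)] <- "UNCLASSIFIED"
  out
}

#' Deduplicate report versions by the FDA rule
#'
#' Groups report versions by CASEID and keeps, per case, the version with the
#' latest FDA_DT; ties on FDA_DT are broken by the higher PRIMARYID
#' (numerically when both parse as numbers, else lexicographically). Versions
#' with an absent or unparseable FDA_DT lose to any dated version and
#' tie-break by PRIMARYID among themselves. Idempotent.
#'
#' @param cases a `faers_cases` object from [link_cases()].
#' @return A `faers_cases` object with one surviving version per CASEID in
#'   every table; `log$dedup` records before/after counts.
#' @export
deduplicate_cases <- function(cases) {
  d <- data.table::copy(cases$demo)
  fda_num <- num_or_na(d$fda_dt)
  pid_num <- num_or_na(d$primaryid)
  # NA sorts first in data.table::order -> undated versions lose;
  # primaryid string is the final key so non-numeric ids fall back to
  # lexicographic comparison
  ord <- order(d$caseid, fda_num, pid_num, d$primaryid, na.last = FALSE,
               method = "radix")
  d <- d[ord]
  keep <- d[!duplicated(d$caseid, fromLast = TRUE)]
  out <- list(demo = keep)
  kept_pid <- keep$primaryid
  for (k in c("drug", "reac", "ther", "outc")) {
    out[[k]] <- cases[[k]][cases[[k]]$primaryid %chin% kept_pid]
  }
  out$log <- c(cases$log,
               list(dedup = list(versions_in = nrow(cases$demo),
                                 cases_out = nrow(keep))))
  class(out) <- "faers_cases"
  out
}

#' Convert reported ages to years
#'
#' Unit factors: `YR` x1, `DEC` x10, `MON` /12, `WK` /52.18, `DY` /365.25,
#' `HR` /8766. An absent unit with a present age is treated as years.
#' Results outside the 0-120 year plausibility window, and unknown unit
#' codes, yield `NA` (callers count them as implausible/unknown).
#'
#' @param age numeric (or character) vector of reported ages.
#' @param unit character vector of unit codes.
#' @return Numeric vector of ages in years, `NA` where absent or implausible.
#' @export
age_to_years <- function(age, unit) {
  age <- num_or_na(age)
  unit <- toupper(ifelse(is.na(unit), "", as.character(unit)))
  factor_map <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18,
                  DY = 1 / 365.25, HR = 1 / 8766)
  f <- factor_map[unit]
  f[unit == ""] <- 1          # absent unit: take the value as years
  years <- age * unname(f)    # unknown unit code -> NA factor -> NA
  years[!is.na(years) & (years < 0 | years > 120)] <- NA_real_
  years
}

# record-level PS drug table with standardized ingredients:
# columns primaryid, caseid, drug_seq, ingredient, start_dt
ps_drug_records <- function(cases, synonym_map) {
  ps <- cases$drug[cases$drug$role_cod == "PS"]
  ing <- normalize_drug(ps$drugname, synonym_map)
  n_unmapped <- sum(is.na(ing))
  ps <- ps[, c("primaryid", "caseid", "drug_seq", "start_dt"), with = FALSE]
  ps[, ingredient := ing]
  list(records = ps[!is.na(ingredient)], n_unmapped = n_unmapped)
}

#' Extract target-event cases with their PS-role drugs
#'
#' Selects every deduplicated case whose reaction set contains the target PT
#' code and restricts the five tables to those cases. PS-role drug records
#' are standardized through the synonym map; cases whose only suspect drugs
#' are SS/C/I contribute no ingredients (they still count as target cases).
#'
#' @param cases a deduplicated `faers_cases` object.
#' @param target_pt_code MedDRA PT code of the target event
#'   (default 10012599, diabetes insipidus).
#' @param synonym_map named character vector from [read_synonym_map()].
#' @return A `faers_target_cases` object: the five restricted tables, a
#'   record-level `ps` table (`primaryid`, `caseid`, `drug_seq`,
#'   `ingredient`, `start_dt`), `target_pt_code`, and a `log` with the
#'   target-case count and unmapped-PS-name count.
#' @export
select_target_cases <- function(cases, target_pt_code = 10012599L,
                                synonym_map = default_synonym_map()) {
  target_pt_code <- as.integer(target_pt_code)
  hit <- num_or_na(cases$reac$pt_cod) == target_pt_code
  ids <- unique(cases$reac$primaryid[!is.na(hit) & hit])
  out <- list()
  for (k in c("demo", "drug", "reac", "ther", "outc")) {
    out[[k]] <- cases[[k]][cases[[k]]$primaryid %chin% ids]
  }
  psr <- ps_drug_records(out, synonym_map)
  out$ps <- psr$records
  out$target_pt_code <- target_pt_code
  out$log <- list(n_target_cases = length(ids),
                  n_unmapped_ps = psr$n_unmapped)
  class(out) <- "faers_target_cases"
  out
}

#' @export
print.faers_target_cases <- function(x, ...) {
  cat(sprintf("Target-event cases (PT %d): %d cases, %d mapped PS drug records\n",
              x$target_pt_code, nrow(x$demo), nrow(x$ps)))
  invisible(x)
}
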