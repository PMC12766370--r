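# Reading and writing FAERS-style "$"-delimited quarterly ASCII tables and
# assembling the five tables into a linked case container.
#
# All fields are kept as character strings in memory: FAERS date fields are
# deliberately not coerced (partial 6-digit dates and empty strings carry
# meaning for the onset-exclusion rules), and keeping text verbatim makes the
# read/write round trip exact.

#' Required columns per FAERS table kind
#'
#' The analysis needs only a subset of the columns a real FAERS quarter
#' carries; unknown extra columns are preserved opaquely on round trip.
#'
#' @format A named list of character vectors, one per table kind
#'   (`demo`, `drug`, `reac`, `ther`, `outc`).
#' @export
faers_columns <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "wt", "occp_cod", "reporter_country"),
  drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname",
           "start_dt"),
  reac = c("primaryid", "caseid", "pt", "pt_cod"),
  ther = c("primaryid", "caseid", "dsg_drug_seq", "start_dt"),
  outc = c("primaryid", "caseid", "outc_cod")
)

#' Read one FAERS-style "$"-delimited table
#'
#' Parses a quarterly ASCII table. The first line must be a `$`-delimited
#' header containing at least the mandatory columns for `kind` (see
#' [faers_columns]). Data rows with the wrong field count or an empty
#' `primaryid` are rejected and counted in the parse log, never silently
#' dropped. Non-ASCII bytes are replaced with `?` and the affected lines
#' counted.
#'
#' @param path path to the file.
#' @param kind one of `"demo"`, `"drug"`, `"reac"`, `"ther"`, `"outc"`.
#' @return A list with elements `records` (a [data.table::data.table] of
#'   character columns) and `log` (list: `parsed`, `rejected`, `reasons`,
#'   `non_ascii`).
#' @export
read_faers_table <- function(path, kind) {
  kind <- match.arg(kind, names(faers_columns))
  if (!file.exists(path)) {
    stop_faers("read_faers_table: file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  ascii <- iconv(lines, from = "", to = "ASCII", sub = "?")
  ascii[is.na(ascii)] <- ""
  n_non_ascii <- sum(ascii != lines)
  lines <- ascii
  if (length(lines) == 0L) {
    stop_faers("read_faers_table: empty file (no header line): ", path)
  }
  header <- strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]
  missing_cols <- setdiff(faers_columns[[kind]], header)
  if (length(missing_cols) > 0L) {
    stop_faers("read_faers_table: ", toupper(kind),
               " header is missing mandatory column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  body <- lines[-1L]
  body <- body[!(body == "" & seq_along(body) == length(body))]  # trailing blank
  ncol_exp <- length(header)
  # sentinel suffix so trailing empty fields survive strsplit
  parts <- strsplit(paste0(body, "$\x01"), "$", fixed = TRUE)
  nf <- lengths(parts) - 1L
  key_col <- match("primaryid", header)
  bad_count <- nf != ncol_exp
  good <- !bad_count
  if (any(good)) {
    mat <- matrix(unlist(parts[good], use.names = FALSE),
                  ncol = ncol_exp + 1L, byrow = TRUE)[, seq_len(ncol_exp),
                                                      drop = FALSE]
    missing_key <- mat[, key_col] == ""
  } else {
    mat <- matrix(character(), ncol = ncol_exp)
    missing_key <- logical()
  }
  records <- data.table::as.data.table(mat[!missing_key, , drop = FALSE])
  data.table::setnames(records, header)
  log <- list(
    parsed   = nrow(records),
    rejected = sum(bad_count) + sum(missing_key),
    reasons  = c(bad_field_count = sum(bad_count),
                 missing_key = sum(missing_key)),
    non_ascii = n_non_ascii
  )
  stopifnot(log$parsed + log$rejected == length(body))
  list(records = records, log = log)
}

#' Write one FAERS-style "$"-delimited table
#'
#' Serializes records with a `$`-delimited header line; absent (`NA`) fields
#' become empty strings. Fields containing a `$` or a newline cannot be
#' represented in the dialect and raise an error naming the offending record.
#'
#' @param records a data.frame/data.table of character-coercible columns
#'   containing at least the mandatory columns for `kind`.
#' @param path output path.
#' @param kind table kind (see [faers_columns]).
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(records, path, kind) {
  kind <- match.arg(kind, names(faers_columns))
  records <- data.table::as.data.table(records)
  missing_cols <- setdiff(faers_columns[[kind]], names(records))
  if (length(missing_cols) > 0L) {
    stop_faers("write_faers_table: records lack mandatory column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  dt <- records[, lapply(.SD, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  })]
  bad <- rep(FALSE, nrow(dt))
  for (cn in names(dt)) bad <- bad | grepl("[$\n\r]", dt[[cn]])
  if (any(bad)) {
    key <- if ("primaryid" %in% names(dt)) dt$primaryid[which(bad)[1L]] else which(bad)[1L]
    stop_faers("write_faers_table: unserializable '$' or newline in field(s) of record ",
               key)
  }
  out <- c(paste(names(dt), collapse = "$"),
           if (nrow(dt)) do.call(paste, c(unname(as.list(dt)), sep = "$")))
  writeLines(out, path)
  invisible(path)
}

#' Read a full FAERS-style quarter
#'
#' @param demo,drug,reac,ther,outc paths to the five tables.
#' @return A `faers_bundle`: list of the five record tables plus a `log` with
#'   per-table parse counts.
#' @export
read_quarter <- function(demo, drug, reac, ther, outc) {
  paths <- list(demo = demo, drug = drug, reac = reac, ther = ther, outc = outc)
  parsed <- lapply(names(paths), function(k) read_faers_table(paths[[k]], k))
  names(parsed) <- names(paths)
  bundle <- lapply(parsed, `[[`, "records")
  bundle$log <- lapply(parsed, `[[`, "log")
  class(bundle) <- "faers_bundle"
  bundle
}

#' Write a full quarter bundle to a directory
#'
#' Files are named `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `THER.txt`, `OUTC.txt`
#' (optionally prefixed, e.g. FAERS-style `DEMO23Q1.txt`).
#'
#' @param bundle a `faers_bundle` (e.g. from [generate_quarter()]).
#' @param dir output directory (created if needed).
#' @param suffix optional filename suffix such as `"23Q1"`.
#' @return Named character vector of the five paths, invisibly.
#' @export
write_quarter <- function(bundle, dir, suffix = "") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  kinds <- c("demo", "drug", "reac", "ther", "outc")
  paths <- file.path(dir, paste0(toupper(kinds), suffix, ".txt"))
  names(paths) <- kinds
  for (k in kinds) write_faers_table(bundle[[k]], paths[[k]], k)
  invisible(paths)
}

#' Link the five tables of a quarter into a case container
#'
#' Every DEMO record defines one report version (PRIMARYID). Records in the
#' other tables whose `primaryid` does not resolve to a DEMO record are
#' counted as orphans and dropped (never fatal). Duplicate PRIMARYIDs within
#' DEMO keep the first occurrence and are counted.
#'
#' @param bundle a `faers_bundle`.
#' @return A `faers_cases` object: the five tables restricted to linked
#'   records, plus a `log` (orphan counts per table, duplicate-primaryid
#'   count, inherited parse logs).
#' @export
link_cases <- function(bundle) {
  demo <- data.table::as.data.table(bundle$demo)
  dup_pid <- duplicated(demo$primaryid)
  demo <- demo[!dup_pid]
  known <- demo$primaryid
  orphans <- list()
  out <- list(demo = demo)
  for (k in c("drug", "reac", "ther", "outc")) {
    tab <- data.table::as.data.table(bundle[[k]])
    keep <- tab$primaryid %chin% known
    orphans[[k]] <- sum(!keep)
    out[[k]] <- tab[keep]
  }
  out$log <- list(
    n_cases = nrow(demo),
    duplicate_primaryid = sum(dup_pid),
    orphans = unlist(orphans),
    parse = bundle$log %||% NULL
  )
  class(out) <- "faers_cases"
  out
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("FAERS-style quarter bundle\n")
  for (k in c("demo", "drug", "reac", "ther", "outc")) {
    cat(sprintf("  %s: %d records\n", toupper(k), nrow(x[[k]])))
  }
  invisible(x)
}

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf("Linked FAERS cases: %d report versions\n", nrow(x$demo)))
  if (!is.null(x$log$orphans)) {
    cat("  orphans:", paste(names(x$log$orphans), x$log$orphans,
                            sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}
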