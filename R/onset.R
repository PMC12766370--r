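# Time-to-onset: interval in days between the event date (EVENT_DT) and the
# earliest valid therapy start date (START_DT) of the suspect ingredient.
# Only complete, valid 8-digit calendar dates qualify; every excluded record
# carries exactly one reason code.

.date_reasons <- c("ok", "missing", "partial", "nonnumeric", "invalid")

#' Strictly parse FAERS date fields
#'
#' Accepts exactly 8-digit `YYYYMMDD` strings encoding a valid calendar date
#' (Gregorian month lengths, leap-year rule). Everything else is rejected
#' with a reason code: `missing` (empty/`NA`), `partial` (4- or 6-digit
#' year/month prefixes), `nonnumeric`, or `invalid` (impossible dates such
#' as month 13 or February 30). Validity is checked arithmetically, not via
#' locale-dependent string parsing.
#'
#' @param x character vector of raw date fields.
#' @return data.table with columns `date` ([Date], `NA` when rejected) and
#'   `reason` (one of `ok`, `missing`, `partial`, `nonnumeric`, `invalid`).
#' @export
parse_strict_date <- function(x) {
  x <- as.character(x)
  n <- length(x)
  reason <- rep("nonnumeric", n)
  empty <- is.na(x) | x == ""
  reason[empty] <- "missing"
  partial <- !empty & grepl("^[0-9]{4}$|^[0-9]{6}$", x)
  reason[partial] <- "partial"
  full <- !empty & grepl("^[0-9]{8}$", x)
  date <- rep(as.Date(NA), n)
  if (any(full)) {
    y <- as.integer(substr(x[full], 1L, 4L))
    m <- as.integer(substr(x[full], 5L, 6L))
    d <- as.integer(substr(x[full], 7L, 8L))
    mlen <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
    leap <- (y %% 4L == 0L & y %% 100L != 0L) | y %% 400L == 0L
    maxd <- ifelse(m >= 1L & m <= 12L, mlen[pmax(pmin(m, 12L), 1L)], 0L)
    maxd[m == 2L & leap] <- 29L
    ok <- m >= 1L & m <= 12L & d >= 1L & d <= maxd & y >= 1L
    reason[full] <- ifelse(ok, "ok", "invalid")
    idx <- which(full)[ok]
    date[idx] <- as.Date(sprintf("%04d-%02d-%02d",
                                 y[ok], m[ok], d[ok]))
  }
  data.table::data.table(date = date, reason = reason)
}

#' Compute time-to-onset records for target cases
#'
#' For every (case, PS ingredient) pair of the target cases, computes
#' `tto_days = EVENT_DT - START_DT` in whole days. The start date is the
#' earliest strictly valid date among the ingredient's THER records (joined
#' via `dsg_drug_seq`), falling back to the drug-record START_DT when no
#' THER date parses. Rejections carry one reason code: the event date's
#' failure reason, else the best start-date failure reason (priority
#' `partial` > `invalid` > `nonnumeric` > `missing`), else `negative` when
#' the event precedes the start. Zero-day onsets are valid.
#'
#' @param target a `faers_target_cases` object.
#' @return data.table with columns `caseid`, `primaryid`, `ingredient`,
#'   `tto_days` (`NA` when rejected), `reason`, `start_source`
#'   (`"ther"`/`"drug"`/`NA`).
#' @export
compute_tto <- function(target) {
  ps <- data.table::copy(target$ps)
  if (nrow(ps) == 0L) {
    return(data.table::data.table(caseid = character(), primaryid = character(),
                                  ingredient = character(),
                                  tto_days = integer(), reason = character(),
                                  start_source = character()))
  }
  # candidate start dates: THER rows matched on (primaryid, drug_seq), plus
  # the drug-record start as fallback
  ther <- data.table::as.data.table(target$ther)
  ther_m <- ther[ps, on = c(primaryid = "primaryid", dsg_drug_seq = "drug_seq"),
                 nomatch = NULL,
                 list(primaryid, ingredient = i.ingredient, raw = start_dt,
                      source = "ther")]
  drug_m <- ps[, list(primaryid, ingredient, raw = start_dt, source = "drug")]
  cand <- data.table::rbindlist(list(ther_m, drug_m))
  pd <- parse_strict_date(cand$raw)
  cand[, date := pd$date]
  cand[, reason := pd$reason]
  # per (case, ingredient): earliest valid THER date, else earliest valid
  # drug date, else the highest-priority failure reason
  prio <- c(ok = 0L, partial = 1L, invalid = 2L, nonnumeric = 3L, missing = 4L)
  cand[, src_rank := ifelse(source == "ther", 0L, 1L)]
  pick <- cand[order(primaryid, ingredient, reason != "ok", prio[reason],
                     src_rank, date)]
  pick <- pick[!duplicated(pick[, c("primaryid", "ingredient"), with = FALSE])]

  ev <- parse_strict_date(target$demo$event_dt)
  evt <- data.table::data.table(primaryid = target$demo$primaryid,
                                event_date = ev$date, event_reason = ev$reason)
  case_map <- data.table::data.table(primaryid = target$demo$primaryid,
                                     caseid = target$demo$caseid)
  out <- pick[evt, on = "primaryid", nomatch = NULL]
  out <- out[case_map, on = "primaryid", nomatch = NULL]
  out[, tto_days := NA_integer_]
  out[, start_source := ifelse(reason == "ok", source, NA_character_)]
  out[, final := ifelse(event_reason != "ok", event_reason,
                        ifelse(reason != "ok", reason, "ok"))]
  ok <- out$final == "ok"
  tto <- as.integer(out$event_date[ok] - out$date[ok])
  neg <- tto < 0L
  out$final[which(ok)[neg]] <- "negative"
  out$tto_days[which(ok)[!neg]] <- tto[!neg]
  res <- out[, list(caseid, primaryid, ingredient, tto_days, reason = final,
                    start_source)]
  data.table::setorder(res, ingredient, caseid)
  res[]
}

#' Summarize time-to-onset per ingredient
#'
#' Median and quartiles by linear interpolation between order statistics
#' (quantile position `1 + p*(n-1)`, R's default type 7). Only usable
#' records (`reason == "ok"`) contribute; ingredients without any usable
#' record are omitted. When `ingredients` is given (e.g. the signal-positive
#' drugs), the summary is restricted to them.
#'
#' @param onsets data.table from [compute_tto()].
#' @param ingredients optional character vector restricting the summary.
#' @return data.table with columns `ingredient`, `n_available`,
#'   `median_days`, `q1_days`, `q3_days`.
#' @export
summarize_tto <- function(onsets, ingredients = NULL) {
  ok <- onsets[onsets$reason == "ok" & !is.na(onsets$tto_days)]
  if (!is.null(ingredients)) ok <- ok[ok$ingredient %chin% ingredients]
  if (nrow(ok) == 0L) {
    return(data.table::data.table(ingredient = character(),
                                  n_available = integer(),
                                  median_days = numeric(),
                                  q1_days = numeric(), q3_days = numeric()))
  }
  res <- ok[, {
    qs <- stats::quantile(tto_days, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    list(n_available = .N, median_days = qs[2L], q1_days = qs[1L],
         q3_days = qs[3L])
  }, by = "ingredient"]
  data.table::setorder(res, ingredient)
  res[]
}
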