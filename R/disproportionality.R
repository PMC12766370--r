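# Disproportionality statistics on per-drug 2x2 contingency tables.
#
# Cell convention (counting unit: the deduplicated case):
#   a = target-event cases with the drug as PS suspect
#   b = other-event cases with the drug as PS suspect
#   c = target-event cases without the drug
#   d = other-event cases without the drug
#   N = a + b + c + d, identical across drugs.
#
# Two screening statistics are computed per drug: the reporting odds ratio
# ROR = a*d / (b*c) with a Woolf log-scale 95% CI, and the BCPNN information
# component IC = log2 of the shrunken observed-to-expected co-reporting
# ratio, with its lower 95% credibility bound IC025 = E(IC) - 2*sqrt(V(IC)).
# A drug is signal-positive only when both algorithms agree: ROR CI lower
# bound > 1 with a >= 3 cases, and IC025 > 0.

#' BCPNN hyperparameters
#'
#' Prior parameters of the information-component posterior. The defaults
#' (`alpha = beta = 2`, `alpha_i = beta_j = gamma_ij = 1`) are the classical
#' choice under which E(IC) is exactly 0 for an empty table, i.e. the prior
#' is centred on independence.
#'
#' @param alpha,beta,alpha_i,beta_j,gamma_ij strictly positive reals.
#' @return A `bcpnn_hyperparameters` list.
#' @export
bcpnn_hyperparameters <- function(alpha = 2, beta = 2, alpha_i = 1,
                                  beta_j = 1, gamma_ij = 1) {
  h <- list(alpha = alpha, beta = beta, alpha_i = alpha_i, beta_j = beta_j,
            gamma_ij = gamma_ij)
  if (any(vapply(h, function(v) !is.numeric(v) || length(v) != 1L ||
                   is.na(v) || v <= 0, logical(1L)))) {
    stop_faers("bcpnn_hyperparameters: all hyperparameters must be strictly positive")
  }
  class(h) <- "bcpnn_hyperparameters"
  h
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' `ROR = a*d / (b*c)`; the CI is
#' `exp(log(ROR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Any zero cell makes the estimate undefined (`defined = FALSE`, statistics
#' `NA`); no continuity correction is applied, since the downstream
#' positivity rule imposes `a >= 3` anyway.
#'
#' @param a,b,c,d numeric vectors of 2x2 cell counts (recycled).
#' @return data.table with columns `ror`, `ci_low`, `ci_high`, `defined`.
#' @export
compute_ror <- function(a, b, c, d) {
  defined <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ci_low <- ci_high <- rep(NA_real_, length(defined))
  if (any(defined)) {
    ror[defined] <- (a * d)[defined] / (b * c)[defined]
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)[defined]
    ci_low[defined] <- exp(log(ror[defined]) - 1.96 * se)
    ci_high[defined] <- exp(log(ror[defined]) + 1.96 * se)
  }
  data.table::data.table(ror = ror, ci_low = ci_low, ci_high = ci_high,
                         defined = defined)
}

#' BCPNN information component with credibility bound
#'
#' Posterior expectation and variance of the information component
#' IC = log2 of the shrunken observed-to-expected co-reporting ratio:
#'
#' \deqn{\gamma = \gamma_{ij} (N+\alpha)(N+\beta) /
#'       ((a+b+\alpha_i)(a+c+\beta_j))}
#' \deqn{E(IC) = \log_2 \frac{(a+\gamma_{ij})(N+\alpha)(N+\beta)}
#'       {(N+\gamma)(a+b+\alpha_i)(a+c+\beta_j)}}
#' \deqn{V(IC) = \frac{1}{(\ln 2)^2}\left[
#'       \frac{N-a+\gamma-\gamma_{ij}}{(a+\gamma_{ij})(1+N+\gamma)} +
#'       \frac{N-a-b+\alpha-\alpha_i}{(a+b+\alpha_i)(1+N+\alpha)} +
#'       \frac{N-a-c+\beta-\beta_j}{(a+c+\beta_j)(1+N+\beta)}\right]}
#'
#' The lower 95% credibility bound is `ic025 = e_ic - 2*sqrt(v_ic)` (a
#' two-standard-deviation bound). `ic025_method = "literal"` instead uses
#' `e_ic - 2*v_ic`, a variant provided only for sensitivity checks against
#' sources that print the bound without the square root. Defined for all
#' tables, including all-zero ones, through the priors.
#'
#' @param a,b,c,d numeric vectors of 2x2 cell counts.
#' @param hyper a [bcpnn_hyperparameters()] object.
#' @param ic025_method `"sd"` (default) or `"literal"`.
#' @return data.table with columns `e_ic`, `v_ic`, `ic025` (bits).
#' @export
compute_ic <- function(a, b, c, d, hyper = bcpnn_hyperparameters(),
                       ic025_method = c("sd", "literal")) {
  ic025_method <- match.arg(ic025_method)
  if (!inherits(hyper, "bcpnn_hyperparameters")) {
    hyper <- do.call(bcpnn_hyperparameters, as.list(hyper))
  }
  al <- hyper$alpha; be <- hyper$beta
  ai <- hyper$alpha_i; bj <- hyper$beta_j; gij <- hyper$gamma_ij
  N <- a + b + c + d
  gam <- gij * (N + al) * (N + be) / ((a + b + ai) * (a + c + bj))
  e_ic <- log2((a + gij) * (N + al) * (N + be) /
                 ((N + gam) * (a + b + ai) * (a + c + bj)))
  v_ic <- (1 / log(2))^2 *
    ((N - a + gam - gij) / ((a + gij) * (1 + N + gam)) +
       (N - a - b + al - ai) / ((a + b + ai) * (1 + N + al)) +
       (N - a - c + be - bj) / ((a + c + bj) * (1 + N + be)))
  ic025 <- if (ic025_method == "sd") e_ic - 2 * sqrt(v_ic) else e_ic - 2 * v_ic
  data.table::data.table(e_ic = e_ic, v_ic = v_ic, ic025 = ic025)
}

#' Dual-criterion signal call
#'
#' A drug-event pair is signal-positive only when both algorithms agree:
#' the ROR is defined with 95% CI lower bound > 1, the case count `a` is at
#' least 3, and IC025 > 0.
#'
#' @param ror data.table from [compute_ror()] (or a list with `ci_low`,
#'   `defined`).
#' @param ic data.table from [compute_ic()] (or a list with `ic025`).
#' @param a case counts.
#' @return Logical vector.
#' @export
call_signal <- function(ror, ic, a) {
  pos <- ror$defined & !is.na(ror$ci_low) & ror$ci_low > 1 &
    a >= 3 & ic$ic025 > 0
  pos[is.na(pos)] <- FALSE
  pos
}

#' Stratify positive signals by IC025
#'
#' Strength bands are half-open on the right: weak `(0, 1.5]`, medium
#' `(1.5, 3]`, strong `(3, Inf)`. Must only be called on positive signals
#' (`ic025 > 0`); other values raise an error.
#'
#' @param ic025 numeric vector of lower credibility bounds (bits).
#' @return Character vector in `{"weak", "medium", "strong"}`.
#' @export
stratify_signal <- function(ic025) {
  if (any(is.na(ic025) | ic025 <= 0)) {
    stop_faers("stratify_signal: ic025 must be > 0 (call only on positive signals)")
  }
  as.character(cut(ic025, c(0, 1.5, 3, Inf),
                   labels = c("weak", "medium", "strong"), right = TRUE))
}

#' Build per-ingredient 2x2 contingency tables
#'
#' Counts deduplicated cases: a drug counts once per case regardless of how
#' many of its records name the drug, and only PS-role records enter suspect
#' counting. Every ingredient with at least one PS case gets a table; all
#' tables sum to the same total `N`.
#'
#' @param cases the full deduplicated `faers_cases` object.
#' @param target a `faers_target_cases` object from [select_target_cases()]
#'   built from the same `cases`.
#' @param synonym_map named character vector from [read_synonym_map()].
#' @return data.table with columns `ingredient`, `a`, `b`, `c`, `d` and
#'   attributes `n_total`, `n_target`, `n_unmapped`.
#' @export
build_contingency_tables <- function(cases, target,
                                     synonym_map = default_synonym_map()) {
  N <- nrow(cases$demo)
  target_ids <- unique(target$demo$primaryid)
  n_t <- length(target_ids)
  psr <- ps_drug_records(cases, synonym_map)
  ps <- unique(psr$records[, c("primaryid", "ingredient"), with = FALSE])
  ps[, is_target := primaryid %chin% target_ids]
  tab <- ps[, list(a = sum(is_target), total = .N), by = "ingredient"]
  tab[, b := total - a]
  tab[, c := n_t - a]
  tab[, d := N - a - b - c]
  tab[, total := NULL]
  data.table::setorder(tab, ingredient)
  data.table::setattr(tab, "n_total", N)
  data.table::setattr(tab, "n_target", n_t)
  data.table::setattr(tab, "n_unmapped", psr$n_unmapped)
  tab[]
}

#' Per-drug signal table
#'
#' Combines the 2x2 tables with ROR, BCPNN and the dual-criterion call into
#' one record per ingredient, sorted by ROR descending (undefined RORs last,
#' ties broken by ingredient name) for forest-plot use.
#'
#' @param tables data.table from [build_contingency_tables()].
#' @param atc_map data.table from [read_atc_map()], or `NULL` to skip
#'   classification.
#' @param hyper [bcpnn_hyperparameters()].
#' @param ic025_method passed to [compute_ic()].
#' @return A `pv_signal_table` data.table with columns `ingredient`,
#'   `atc_class`, `a`, `ror`, `ci_low`, `ci_high`, `e_ic`, `v_ic`, `ic025`,
#'   `positive`, `strength` (`"none"` for non-positive drugs).
#' @export
signal_table <- function(tables, atc_map = default_atc_map(),
                         hyper = bcpnn_hyperparameters(),
                         ic025_method = c("sd", "literal")) {
  ror <- compute_ror(tables$a, tables$b, tables$c, tables$d)
  ic <- compute_ic(tables$a, tables$b, tables$c, tables$d, hyper,
                   ic025_method)
  pos <- call_signal(ror, ic, tables$a)
  strength <- rep("none", length(pos))
  if (any(pos)) strength[pos] <- stratify_signal(ic$ic025[pos])
  out <- data.table::data.table(
    ingredient = tables$ingredient,
    atc_class = if (is.null(atc_map)) NA_character_ else
      assign_atc(tables$ingredient, atc_map),
    a = tables$a,
    ror = ror$ror, ci_low = ror$ci_low, ci_high = ror$ci_high,
    e_ic = ic$e_ic, v_ic = ic$v_ic, ic025 = ic$ic025,
    positive = pos, strength = strength)
  ord <- order(-out$ror, out$ingredient, na.last = TRUE, method = "radix")
  out <- out[ord]
  data.table::setattr(out, "class",
                      c("pv_signal_table", class(out)))
  out[]
}

#' Write a signal table to CSV (and optionally JSON)
#'
#' @param x a `pv_signal_table`.
#' @param csv_path output CSV path.
#' @param json_path optional output JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_signal_table <- function(x, csv_path, json_path = NULL) {
  data.table::fwrite(data.table::as.data.table(x), csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.data.frame(x), json_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(csv_path)
}

#' @export
print.pv_signal_table <- function(x, ...) {
  cat(sprintf("Signal table: %d drugs, %d positive (%s)\n",
              nrow(x), sum(x$positive),
              paste(names(table(x$strength[x$positive])),
                    table(x$strength[x$positive]),
                    sep = "=", collapse = " ")))
  NextMethod()
}
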