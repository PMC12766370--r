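# Synthetic FAERS-like data with known ground truth.
#
# Generative model (kept deliberately simple so the per-drug 2x2 expectations
# have a closed form): each case draws one suspect drug and one primary
# reaction PT from the joint w_ij = p_i * q_j * rr_ij (renormalized), where
# rr_ij tilts planted drug-event pairs. Additional reaction PTs are drawn
# from the non-target events only, and concomitant (role C) drugs never enter
# suspect counting, so the expected 2x2 table for the target PT follows
# exactly from the joint (see expected_counts).

#' Default simulated drug catalog
#'
#' Fifty ingredients taken from the bundled ATC map, with equal baseline
#' reporting probabilities.
#'
#' @return data.table with columns `drug_id`, `ingredient`, `atc_code`, `p`.
#' @export
default_drug_catalog <- function() {
  map <- data.table::fread(
    system.file("extdata", "atc_classes.tsv", package = "faerspv"),
    sep = "\t", colClasses = "character")
  n <- nrow(map)
  data.table::data.table(drug_id = map$ingredient,
                         ingredient = map$ingredient,
                         atc_code = map$atc_code,
                         p = rep(1 / n, n))
}

#' Default simulated event catalog
#'
#' The bundled PT table with the target event (diabetes insipidus, PT code
#' 10012599) at its observed FAERS marginal of 2,189 / 18,627,667 reports;
#' the remaining probability mass is split equally over the background PTs.
#'
#' @return data.table with columns `pt_cod`, `pt`, `p`.
#' @export
default_event_catalog <- function() {
  pts <- data.table::fread(
    system.file("extdata", "pt_codes.tsv", package = "faerspv"),
    sep = "\t", colClasses = "character")
  q_target <- 2189 / 18627667
  p <- rep((1 - q_target) / (nrow(pts) - 1L), nrow(pts))
  p[pts$pt_cod == "10012599"] <- q_target
  data.table::data.table(pt_cod = as.integer(pts$pt_cod), pt = pts$pt, p = p)
}

#' Define a planted drug-event association
#'
#' @param drug_id catalog drug identifier.
#' @param pt_code MedDRA PT code of the event (default: the diabetes
#'   insipidus target PT).
#' @param rr relative reporting ratio (>= 0) multiplying the joint
#'   drug-event probability; `rr = 1` is the null.
#' @param onset_median_days median of the log-normal lag from therapy start
#'   (START_DT) to event (EVENT_DT), in days; 0 plants an immediate onset.
#' @param onset_sdlog log-scale spread of the onset law.
#' @return A `planted_signal` list.
#' @export
planted_signal <- function(drug_id, pt_code = 10012599L, rr,
                           onset_median_days = 30, onset_sdlog = 0.8) {
  sig <- list(drug_id = drug_id, pt_code = as.integer(pt_code), rr = rr,
              onset_median_days = onset_median_days,
              onset_sdlog = onset_sdlog)
  class(sig) <- "planted_signal"
  sig
}

#' Simulation configuration
#'
#' Bundles all generative parameters for [generate_quarter()]. Defaults
#' emulate the scale and mix of the real spontaneous-reporting stream the
#' package targets: a rare target event (marginal 2,189 / 18,627,667), a
#' 50-drug catalog, FAERS-like demographics, a small duplicate-version rate
#' and partially or wholly missing therapy/event dates.
#'
#' @param n_reports number of distinct cases to generate (duplicate versions
#'   are emitted as extra report rows on top of these).
#' @param drug_catalog data.table `drug_id`, `ingredient`, `atc_code`, `p`;
#'   probabilities must be non-negative and sum to at most 1 (they are
#'   renormalized for the one-suspect-per-case draw).
#' @param event_catalog data.table `pt_cod`, `pt`, `p`; same constraints.
#' @param planted_signals list of [planted_signal()] objects.
#' @param target_pt_code the PT treated as the study's target event; extra
#'   (secondary) reactions are never drawn from it, so its per-drug 2x2
#'   expectation is exact.
#' @param duplicate_rate fraction of cases emitted as 2-3 report versions.
#' @param partial_date_rate,missing_date_rate per-field rates at which
#'   EVENT_DT/START_DT are truncated to 6 digits or blanked (a fifth of the
#'   "missing" draws are written as the non-numeric token `UNKNOWN`).
#' @param date_error_rate fraction of cases whose START_DT is planted after
#'   EVENT_DT (exercises negative time-to-onset rejection).
#' @param ps_fraction probability that the suspect drug is coded PS (else
#'   SS or I).
#' @param concomitant_rate mean number of additional role-C drug records per
#'   case.
#' @param extra_event_rate mean number of additional non-target reaction PTs
#'   per case.
#' @param ther_coverage fraction of suspect drug records that also get a
#'   THER row (the rest exercise the drug-level START_DT fallback).
#' @param sex_probs named probabilities for `F`, `M`, `UNK`.
#' @param age_mean,age_sd,age_unknown_rate age model (years; truncated to
#'   0-100).
#' @param age_unit_rates named fractions of known ages written with `MON` /
#'   `DY` unit codes (values converted accordingly).
#' @param weight_mean,weight_sd,weight_unknown_rate weight model (kg).
#' @param country_weights,occp_weights,outcome_weights named sampling
#'   weights; `occp_weights` may include `UNK`, `outcome_weights` must
#'   include `NONE` (no outcome row).
#' @param second_outcome_rate probability of a second, distinct outcome code.
#' @param background_onset_median,background_onset_sdlog log-normal onset
#'   law for cases not covered by a planted signal.
#' @param quarter_start first calendar day of the simulated quarter.
#' @param case_id_start first CASEID.
#' @param seed default RNG seed used by [generate_quarter()].
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_reports = 50000L,
                       drug_catalog = default_drug_catalog(),
                       event_catalog = default_event_catalog(),
                       planted_signals = list(),
                       target_pt_code = 10012599L,
                       duplicate_rate = 0.05,
                       partial_date_rate = 0.05,
                       missing_date_rate = 0.05,
                       date_error_rate = 0.01,
                       ps_fraction = 0.9,
                       concomitant_rate = 0.3,
                       extra_event_rate = 0.7,
                       ther_coverage = 0.9,
                       sex_probs = c(F = 0.443, M = 0.466, UNK = 0.091),
                       age_mean = 47, age_sd = 22, age_unknown_rate = 0.21,
                       age_unit_rates = c(MON = 0.04, DY = 0.01),
                       weight_mean = 74.5, weight_sd = 20,
                       weight_unknown_rate = 0.76,
                       country_weights = c(US = 0.36, JP = 0.126, FR = 0.086,
                                           CA = 0.07, GB = 0.059, DE = 0.05,
                                           IT = 0.04, ES = 0.03, AU = 0.03,
                                           BR = 0.025, OTHER = 0.124),
                       occp_weights = c(MD = 0.368, OT = 0.360, CN = 0.134,
                                        PH = 0.076, LW = 0.004, UNK = 0.058),
                       outcome_weights = c(OT = 0.444, HO = 0.347, DE = 0.122,
                                           LT = 0.062, DS = 0.009, RI = 0.003,
                                           CA = 0.002, NONE = 0.011),
                       second_outcome_rate = 0.05,
                       background_onset_median = 60,
                       background_onset_sdlog = 1.2,
                       quarter_start = "2023-01-01",
                       case_id_start = 10000001L,
                       seed = 1L) {
  cfg <- list(n_reports = n_reports,
              drug_catalog = data.table::as.data.table(drug_catalog),
              event_catalog = data.table::as.data.table(event_catalog),
              planted_signals = planted_signals,
              target_pt_code = as.integer(target_pt_code),
              duplicate_rate = duplicate_rate,
              partial_date_rate = partial_date_rate,
              missing_date_rate = missing_date_rate,
              date_error_rate = date_error_rate,
              ps_fraction = ps_fraction,
              concomitant_rate = concomitant_rate,
              extra_event_rate = extra_event_rate,
              ther_coverage = ther_coverage,
              sex_probs = sex_probs,
              age_mean = age_mean, age_sd = age_sd,
              age_unknown_rate = age_unknown_rate,
              age_unit_rates = age_unit_rates,
              weight_mean = weight_mean, weight_sd = weight_sd,
              weight_unknown_rate = weight_unknown_rate,
              country_weights = country_weights,
              occp_weights = occp_weights,
              outcome_weights = outcome_weights,
              second_outcome_rate = second_outcome_rate,
              background_onset_median = background_onset_median,
              background_onset_sdlog = background_onset_sdlog,
              quarter_start = quarter_start,
              case_id_start = as.integer(case_id_start),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Rejects invalid configurations with a message naming the offending field.
#'
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly.
#' @export
validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop_faers("sim_config: invalid field '", field, "': ", why)
  }
  if (!is.numeric(cfg$n_reports) || length(cfg$n_reports) != 1L ||
      is.na(cfg$n_reports) || cfg$n_reports < 0 ||
      cfg$n_reports != floor(cfg$n_reports)) {
    fail("n_reports", "must be a single non-negative integer")
  }
  dc <- cfg$drug_catalog
  if (!all(c("drug_id", "ingredient", "atc_code", "p") %in% names(dc))) {
    fail("drug_catalog", "needs columns drug_id, ingredient, atc_code, p")
  }
  if (anyDuplicated(dc$drug_id)) fail("drug_catalog", "duplicate drug_id")
  if (any(dc$p < 0) || sum(dc$p) > 1 + 1e-9) {
    fail("drug_catalog", "probabilities must be >= 0 and sum to <= 1")
  }
  ec <- cfg$event_catalog
  if (!all(c("pt_cod", "pt", "p") %in% names(ec))) {
    fail("event_catalog", "needs columns pt_cod, pt, p")
  }
  if (anyDuplicated(ec$pt_cod)) fail("event_catalog", "duplicate pt_cod")
  if (any(ec$p < 0) || sum(ec$p) > 1 + 1e-9) {
    fail("event_catalog", "probabilities must be >= 0 and sum to <= 1")
  }
  if (!cfg$target_pt_code %in% ec$pt_cod) {
    fail("target_pt_code", "not present in event_catalog")
  }
  for (f in c("duplicate_rate", "partial_date_rate", "missing_date_rate",
              "date_error_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v >= 1) {
      fail(f, "must be a fraction in [0, 1)")
    }
  }
  if (cfg$partial_date_rate + cfg$missing_date_rate >= 1) {
    fail("partial_date_rate", "partial + missing date rates must stay below 1")
  }
  if (cfg$ps_fraction <= 0 || cfg$ps_fraction > 1) {
    fail("ps_fraction", "must lie in (0, 1]")
  }
  if (cfg$ther_coverage < 0 || cfg$ther_coverage > 1) {
    fail("ther_coverage", "must lie in [0, 1]")
  }
  for (i in seq_along(cfg$planted_signals)) {
    sig <- cfg$planted_signals[[i]]
    if (!sig$drug_id %in% dc$drug_id) {
      fail("planted_signals", paste0("signal ", i, " references unknown drug_id '",
                                     sig$drug_id, "'"))
    }
    if (!sig$pt_code %in% ec$pt_cod) {
      fail("planted_signals", paste0("signal ", i, " references unknown pt_code ",
                                     sig$pt_code))
    }
    if (!is.finite(sig$rr) || sig$rr < 0) {
      fail("planted_signals", paste0("signal ", i, " rr must be finite and >= 0"))
    }
    if (sig$onset_median_days < 0) {
      fail("planted_signals", paste0("signal ", i, " onset_median_days must be >= 0"))
    }
  }
  for (f in c("sex_probs", "country_weights", "occp_weights", "outcome_weights")) {
    if (any(cfg[[f]] < 0)) fail(f, "weights must be non-negative")
  }
  if (!"NONE" %in% names(cfg$outcome_weights)) {
    fail("outcome_weights", "must include a NONE weight")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed)) {
    fail("seed", "must be a single integer")
  }
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields override the [sim_config()] defaults; `planted_signals` is a
#' list of mappings with keys `drug_id`, `pt_code`, `rr`,
#' `onset_median_days`, `onset_sdlog`.
#'
#' @param path YAML file path.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_faers("read_sim_config: file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$planted_signals)) {
    raw$planted_signals <- lapply(raw$planted_signals, function(s) {
      do.call(planted_signal, s)
    })
  }
  do.call(sim_config, raw)
}

# joint weights over (drug, event): w_ij = p_i * q_j * rr_ij, with catalog
# probabilities renormalized; returns list(grid, W, p, q)
sim_joint <- function(cfg) {
  p <- cfg$drug_catalog$p / sum(cfg$drug_catalog$p)
  q <- cfg$event_catalog$p / sum(cfg$event_catalog$p)
  nd <- length(p); ne <- length(q)
  rr <- matrix(1, nd, ne)
  for (sig in cfg$planted_signals) {
    i <- match(sig$drug_id, cfg$drug_catalog$drug_id)
    j <- match(sig$pt_code, cfg$event_catalog$pt_cod)
    rr[i, j] <- rr[i, j] * sig$rr
  }
  w <- outer(p, q) * rr
  list(w = w, W = sum(w), p = p, q = q)
}

#' Analytic expected 2x2 table under the generative model
#'
#' Closed-form expectations of the per-drug contingency cells for the target
#' PT, before duplication and date corruption (neither changes case-level
#' counts once reports are deduplicated). `a` counts cases with the drug as a
#' PS-role suspect and the event present; the cells always sum exactly to
#' `n_reports`. Exact for the configured target PT (secondary reactions are
#' never drawn from it); for other PTs it is the expectation of the event
#' being the case's primary reaction.
#'
#' @param cfg a `sim_config`.
#' @param drug_id catalog drug identifier.
#' @param pt_code event PT code.
#' @return list with real-valued `a`, `b`, `c`, `d` and `n`.
#' @export
expected_counts <- function(cfg, drug_id, pt_code) {
  validate_sim_config(cfg)
  i <- match(drug_id, cfg$drug_catalog$drug_id)
  if (is.na(i)) stop_faers("expected_counts: unknown drug_id '", drug_id, "'")
  j <- match(as.integer(pt_code), cfg$event_catalog$pt_cod)
  if (is.na(j)) stop_faers("expected_counts: unknown pt_code ", pt_code)
  jt <- sim_joint(cfg)
  n <- cfg$n_reports
  ps <- cfg$ps_fraction
  a <- n * ps * jt$w[i, j] / jt$W
  b <- n * ps * (sum(jt$w[i, ]) - jt$w[i, j]) / jt$W
  cc <- n * (sum(jt$w[, j]) - ps * jt$w[i, j]) / jt$W
  d <- n - a - b - cc
  list(a = a, b = b, c = cc, d = d, n = n)
}

# corrupt a character vector of 8-digit dates in place:
# partial -> 6-digit truncation; missing -> "" (4/5 of draws) or the
# non-numeric token "UNKNOWN" (1/5)
corrupt_dates <- function(x, partial_rate, missing_rate) {
  u <- runif(length(x))
  part <- u < partial_rate
  miss <- !part & u < partial_rate + missing_rate
  x[part] <- substr(x[part], 1L, 6L)
  if (any(miss)) {
    tok <- runif(sum(miss)) < 0.2
    x[miss] <- ifelse(tok, "UNKNOWN", "")
  }
  x
}

#' Generate one synthetic FAERS-like quarter
#'
#' Draws `n_reports` cases from the configured generative model and emits the
#' five linked tables in the FAERS ASCII dialect (all fields character).
#' Duplicate cases share a CASEID across 2-3 report versions with distinct
#' PRIMARYIDs and strictly increasing FDA_DT; the latest version carries the
#' true content while earlier versions have blanked age/weight. Output is
#' reproducible: the same `(cfg, seed)` yields an identical bundle.
#'
#' The returned bundle carries a `truth` attribute (one row per case:
#' suspect drug, role, primary event, latest PRIMARYID, onset lag) used by
#' validation code; the analysis pipeline never reads it.
#'
#' @param cfg a validated [sim_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return A `faers_bundle` with attribute `truth`.
#' @export
generate_quarter <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  set.seed(as.integer(seed))
  n <- as.integer(cfg$n_reports)
  dc <- cfg$drug_catalog
  ec <- cfg$event_catalog
  jt <- sim_joint(cfg)
  nd <- nrow(dc); ne <- nrow(ec)

  caseid <- as.character(cfg$case_id_start + seq_len(n) - 1L)

  # suspect drug + primary event from the tilted joint
  cell <- sample.int(nd * ne, n, replace = TRUE, prob = as.vector(jt$w))
  di <- ((cell - 1L) %% nd) + 1L
  ej <- ((cell - 1L) %/% nd) + 1L
  role <- ifelse(runif(n) < cfg$ps_fraction, "PS",
                 sample(c("SS", "I"), n, replace = TRUE, prob = c(0.8, 0.2)))

  # demographics
  sex <- sample(c("F", "M", ""), n, replace = TRUE, prob = cfg$sex_probs)
  age_years <- pmin(pmax(rnorm(n, cfg$age_mean, cfg$age_sd), 0), 100)
  age_known <- runif(n) >= cfg$age_unknown_rate
  u_unit <- runif(n)
  mon_r <- cfg$age_unit_rates[["MON"]] %||% 0
  dy_r <- cfg$age_unit_rates[["DY"]] %||% 0
  age_cod <- ifelse(u_unit < mon_r, "MON", ifelse(u_unit < mon_r + dy_r, "DY", "YR"))
  age_val <- round(ifelse(age_cod == "MON", age_years * 12,
                          ifelse(age_cod == "DY", age_years * 365.25, age_years)))
  age_chr <- ifelse(age_known, as.character(age_val), "")
  age_cod <- ifelse(age_known, age_cod, "")
  wt_known <- runif(n) >= cfg$weight_unknown_rate
  wt_val <- round(pmin(pmax(rnorm(n, cfg$weight_mean, cfg$weight_sd), 2), 250), 1)
  wt_chr <- ifelse(wt_known, as.character(wt_val), "")
  country <- sample(names(cfg$country_weights), n, replace = TRUE,
                    prob = cfg$country_weights)
  occp <- sample(names(cfg$occp_weights), n, replace = TRUE,
                 prob = cfg$occp_weights)
  occp[occp == "UNK"] <- ""

  # dates: FDA receipt inside the quarter; event precedes receipt; therapy
  # start precedes the event by the (planted or background) onset lag
  qstart <- as.Date(cfg$quarter_start)
  fda <- qstart + (sample.int(90L, n, replace = TRUE) - 1L)
  event <- fda - (sample.int(31L, n, replace = TRUE) - 1L)
  lag_med <- rep(cfg$background_onset_median, n)
  lag_sd <- rep(cfg$background_onset_sdlog, n)
  for (sig in cfg$planted_signals) {
    i <- match(sig$drug_id, dc$drug_id)
    j <- match(sig$pt_code, ec$pt_cod)
    hit <- di == i & ej == j
    lag_med[hit] <- sig$onset_median_days
    lag_sd[hit] <- sig$onset_sdlog
  }
  lag <- ifelse(lag_med <= 0, 0, floor(rlnorm(n, log(pmax(lag_med, 1e-12)), lag_sd)))
  start <- event - lag
  swap <- runif(n) < cfg$date_error_rate
  start[swap] <- event[swap] + sample.int(30L, sum(swap), replace = TRUE)

  event_chr <- corrupt_dates(format(event, "%Y%m%d"),
                             cfg$partial_date_rate, cfg$missing_date_rate)
  start_chr <- corrupt_dates(format(start, "%Y%m%d"),
                             cfg$partial_date_rate, cfg$missing_date_rate)

  # duplicate versions: k in {2, 3}; FDA_DT incremented 1-90 days per version
  nver <- rep(1L, n)
  if (cfg$duplicate_rate > 0) {
    dup <- runif(n) < cfg$duplicate_rate
    nver[dup] <- sample(2:3, sum(dup), replace = TRUE)
  }
  fda_latest <- fda
  extra <- nver > 1L
  if (any(extra)) {
    fda_latest[extra] <- fda[extra] +
      vapply(nver[extra], function(k) sum(sample.int(90L, k - 1L, replace = TRUE)),
             integer(1L))
  }

  demo <- data.table::data.table(
    primaryid = paste0(caseid, nver),
    caseid = caseid,
    fda_dt = format(fda_latest, "%Y%m%d"),
    event_dt = event_chr,
    age = age_chr, age_cod = age_cod, sex = sex, wt = wt_chr,
    occp_cod = occp, reporter_country = country)

  # suspect drug record (+ THER row for a covered fraction)
  drug_sus <- data.table::data.table(
    primaryid = demo$primaryid, caseid = caseid, drug_seq = "1",
    role_cod = role, drugname = toupper(dc$ingredient[di]),
    start_dt = start_chr)
  ther_cov <- runif(n) < cfg$ther_coverage
  ther <- data.table::data.table(
    primaryid = demo$primaryid[ther_cov], caseid = caseid[ther_cov],
    dsg_drug_seq = "1", start_dt = start_chr[ther_cov])

  # concomitant drugs, role C, no start date
  ncon <- pmin(rpois(n, cfg$concomitant_rate), 3L)
  ci_case <- rep.int(seq_len(n), ncon)
  drug_con <- if (length(ci_case)) {
    cdi <- sample.int(nd, length(ci_case), replace = TRUE, prob = jt$p)
    data.table::data.table(
      primaryid = demo$primaryid[ci_case], caseid = caseid[ci_case],
      drug_seq = as.character(sequence(ncon[ncon > 0L]) + 1L),
      role_cod = "C", drugname = toupper(dc$ingredient[cdi]), start_dt = "")
  } else NULL
  drug <- data.table::rbindlist(list(drug_sus, drug_con))

  # reactions: primary event + extra non-target PTs
  reac_pri <- data.table::data.table(
    primaryid = demo$primaryid, caseid = caseid,
    pt = ec$pt[ej], pt_cod = as.character(ec$pt_cod[ej]))
  nontarget <- which(ec$pt_cod != cfg$target_pt_code)
  nx <- pmin(rpois(n, cfg$extra_event_rate), 4L)
  xi_case <- rep.int(seq_len(n), nx)
  reac_ext <- if (length(xi_case) && length(nontarget)) {
    xj <- nontarget[sample.int(length(nontarget), length(xi_case), replace = TRUE,
                               prob = jt$q[nontarget])]
    data.table::data.table(
      primaryid = demo$primaryid[xi_case], caseid = caseid[xi_case],
      pt = ec$pt[xj], pt_cod = as.character(ec$pt_cod[xj]))
  } else NULL
  reac <- unique(data.table::rbindlist(list(reac_pri, reac_ext)))

  # outcomes
  oc1 <- sample(names(cfg$outcome_weights), n, replace = TRUE,
                prob = cfg$outcome_weights)
  outc <- data.table::data.table(primaryid = demo$primaryid, caseid = caseid,
                                 outc_cod = oc1)[outc_cod != "NONE"]
  w2 <- cfg$outcome_weights[names(cfg$outcome_weights) != "NONE"]
  sec <- runif(n) < cfg$second_outcome_rate
  if (any(sec)) {
    oc2 <- sample(names(w2), sum(sec), replace = TRUE, prob = w2)
    keep <- oc2 != oc1[sec]
    outc <- data.table::rbindlist(list(outc, data.table::data.table(
      primaryid = demo$primaryid[sec][keep], caseid = caseid[sec][keep],
      outc_cod = oc2[keep])))
  }

  # stale earlier versions of duplicate cases: same children, blanked
  # age/weight in DEMO, earlier FDA_DT
  if (any(extra)) {
    stale_case <- rep.int(which(extra), nver[extra] - 1L)
    stale_ver <- sequence(nver[extra] - 1L)
    frac <- runif(length(stale_case))
    stale_fda <- fda[stale_case] +
      floor(frac * as.numeric(fda_latest[stale_case] - fda[stale_case]))
    stale_pid <- paste0(caseid[stale_case], stale_ver)
    demo_stale <- demo[stale_case]
    demo_stale[, primaryid := stale_pid]
    demo_stale[, fda_dt := format(stale_fda, "%Y%m%d")]
    demo_stale[, c("age", "age_cod", "wt") := ""]
    demo <- data.table::rbindlist(list(demo, demo_stale))
    stale_map <- data.table::data.table(caseid = caseid[stale_case],
                                        stale_pid = stale_pid)
    clone <- function(tab) {
      rows <- tab[stale_map, on = "caseid", allow.cartesian = TRUE,
                  nomatch = NULL]
      rows[, primaryid := stale_pid]
      rows[, stale_pid := NULL]
      data.table::rbindlist(list(tab, rows))
    }
    drug <- clone(drug); reac <- clone(reac); ther <- clone(ther)
    outc <- clone(outc)
  }

  truth <- data.table::data.table(
    caseid = caseid,
    primaryid_latest = paste0(caseid, nver),
    n_versions = nver,
    drug_id = dc$drug_id[di],
    ingredient = dc$ingredient[di],
    role_cod = role,
    primary_pt_cod = ec$pt_cod[ej],
    target = ec$pt_cod[ej] == cfg$target_pt_code,
    onset_lag_days = as.integer(lag),
    start_swapped = swap)

  bundle <- list(demo = demo, drug = drug, reac = reac, ther = ther,
                 outc = outc, log = list(generated_cases = n))
  class(bundle) <- "faers_bundle"
  attr(bundle, "truth") <- truth
  bundle
}
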