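test_that("contingency tables match a brute-force recount of the cases", {
  # 10 cases: drugX PS in 4 (cases 1-4), target PT in 3 (cases 3-5)
  demo <- data.table::data.table(primaryid = as.character(11:20),
                                 caseid = as.character(1:10),
                                 fda_dt = "20230101")
  drug <- data.table::data.table(
    primaryid = as.character(11:14), caseid = as.character(1:4),
    drug_seq = "1", role_cod = "PS", drugname = "DRUGX", start_dt = "")
  reac <- data.table::data.table(
    primaryid = as.character(13:15), caseid = as.character(3:5),
    pt = "Diabetes insipidus", pt_cod = "10012599")
  cs <- make_cases(demo, drug, reac)
  tc <- select_target_cases(cs, 10012599L, test_synonym_map)
  tab <- build_contingency_tables(cs, tc, test_synonym_map)
  expect_equal(tab[tab$ingredient == "drugx",
                   c("a", "b", "c", "d"), with = FALSE],
               data.table::data.table(a = 2L, b = 2L, c = 1L, d = 5L),
               ignore_attr = TRUE)

  # independent nested-loop recount agrees
  case_drugs <- c(replicate(4, "drugx", simplify = FALSE),
                  replicate(6, character(), simplify = FALSE))
  oracle <- brute_force_table(case_drugs, c(rep(FALSE, 2), rep(TRUE, 3),
                                            rep(FALSE, 5)), "drugx")
  expect_equal(as.list(tab[tab$ingredient == "drugx", c("a", "b", "c", "d"),
                           with = FALSE]),
               lapply(oracle, as.integer), ignore_attr = TRUE)
})

test_that("a drug appearing only with role C never enters suspect counting", {
  demo <- data.table::data.table(primaryid = c("11", "21"),
                                 caseid = c("1", "2"), fda_dt = "20230101")
  drug <- data.table::data.table(
    primaryid = c("11", "21"), caseid = c("1", "2"), drug_seq = "1",
    role_cod = c("C", "PS"), drugname = c("DRUGY", "DRUGX"), start_dt = "")
  reac <- data.table::data.table(primaryid = "11", caseid = "1",
                                 pt = "Diabetes insipidus",
                                 pt_cod = "10012599")
  cs <- make_cases(demo, drug, reac)
  tc <- select_target_cases(cs, 10012599L, test_synonym_map)
  tab <- build_contingency_tables(cs, tc, test_synonym_map)
  expect_false("drugy" %in% tab$ingredient)
  expect_equal(tab[tab$ingredient == "drugx"]$a, 0L)
})

test_that("contingency tables on synthetic data match an exhaustive recount", {
  cfg <- tiny_config(n_reports = 2000L, q_target = 0.05, rr = 5,
                     duplicate_rate = 0.2)
  b <- generate_quarter(cfg, seed = 21)
  res <- analyze_bundle(b)
  dd <- res$cases
  syn <- default_synonym_map()
  # naive per-case recount
  ps <- dd$drug[dd$drug$role_cod == "PS"]
  ps_ing <- split(normalize_drug(ps$drugname, syn), ps$primaryid)
  tgt <- unique(dd$reac$primaryid[dd$reac$pt_cod == "10012599"])
  ids <- dd$demo$primaryid
  case_drugs <- lapply(ids, function(p) unique(stats::na.omit(ps_ing[[p]])))
  has_t <- ids %in% tgt
  for (ing in res$tables$ingredient) {
    o <- brute_force_table(case_drugs, has_t, ing)
    row <- res$tables[res$tables$ingredient == ing]
    expect_equal(unname(unlist(row[, c("a", "b", "c", "d"), with = FALSE])),
                 unname(unlist(lapply(o, as.integer))))
  }
})

test_that("ROR matches its closed form and the Woolf interval", {
  r <- compute_ror(10, 90, 100, 900)
  expect_equal(r$ror, 1.0)
  expect_equal(r$ci_low, 0.504, tolerance = 1e-3)
  expect_equal(r$ci_high, 1.984, tolerance = 1e-3)
  o <- literal_ror(10, 90, 100, 900)
  expect_equal(r$ci_low, o$ci_low, tolerance = 1e-12)
  expect_equal(r$ci_high, o$ci_high, tolerance = 1e-12)
  # zero cells: undefined, no continuity correction
  z <- compute_ror(0, 90, 100, 900)
  expect_false(z$defined)
  expect_true(is.na(z$ror))
})

test_that("the empty table has E(IC) = 0 under the default priors", {
  ic <- compute_ic(0, 0, 0, 0)
  expect_equal(ic$e_ic, 0)
  # gamma = 1*(0+2)*(0+2)/((0+1)*(0+1)) = 4; E(IC) = log2(1*2*2/(4*1*1)) = 0
  o <- literal_ic(0, 0, 0, 0)
  expect_equal(ic$v_ic, o$v_ic)
})

test_that("IC agrees with a step-by-step transcription and shrinks to the null at large N", {
  ic <- compute_ic(25, 75, 75, 825)
  o <- literal_ic(25, 75, 75, 825)
  expect_equal(ic$e_ic, o$e_ic, tolerance = 1e-13)
  expect_equal(ic$v_ic, o$v_ic, tolerance = 1e-13)
  expect_equal(ic$ic025, o$ic025, tolerance = 1e-13)
  # proportional large-N table: expectation within 0.05 bits of zero
  big <- compute_ic(100, 9900, 900, 89100)
  expect_lt(abs(big$e_ic), 0.05)
  # literal (non-sqrt) variant is more conservative here
  lit <- compute_ic(25, 75, 75, 825, ic025_method = "literal")
  expect_equal(lit$ic025, o$e_ic - 2 * o$v_ic)
  expect_error(compute_ic(1, 1, 1, 1, hyper = list(alpha = -1)), "positive")
})

test_that("swapping drug margins inverts the ROR and preserves log-CI width", {
  set.seed(42)
  for (i in 1:25) {
    cells <- sample(1:40, 4, replace = TRUE)
    r1 <- compute_ror(cells[1], cells[2], cells[3], cells[4])
    r2 <- compute_ror(cells[3], cells[4], cells[1], cells[2])
    expect_equal(r2$ror, 1 / r1$ror)
    expect_equal(log(r1$ci_high) - log(r1$ci_low),
                 log(r2$ci_high) - log(r2$ci_low))
  }
})

test_that("with fixed margins, increasing a increases both ROR and E(IC)", {
  N <- 1000; s1 <- 60; s2 <- 40  # a+b, a+c
  prev_ror <- -Inf; prev_eic <- -Inf
  for (a in 1:39) {
    b <- s1 - a; c <- s2 - a; d <- N - s1 - s2 + a
    r <- compute_ror(a, b, c, d)
    ic <- compute_ic(a, b, c, d)
    expect_gt(r$ror, prev_ror)
    expect_gt(ic$e_ic, prev_eic)
    expect_lt(ic$ic025, ic$e_ic)  # strict, every finite table
    prev_ror <- r$ror; prev_eic <- ic$e_ic
  }
})

test_that("the dual signal criterion requires all three conditions", {
  ror <- data.table::data.table(ror = 2, ci_low = 1.2, ci_high = 4,
                                defined = TRUE)
  ic <- data.table::data.table(e_ic = 1, v_ic = 0.1, ic025 = 0.4)
  expect_true(call_signal(ror, ic, 5))
  expect_false(call_signal(ror, ic, 2))                       # a < 3
  ror_low <- data.table::copy(ror); ror_low$ci_low <- 0.9
  expect_false(call_signal(ror_low, data.table::data.table(ic025 = 1.0), 50))
  ic_neg <- data.table::data.table(ic025 = -0.1)
  expect_false(call_signal(ror, ic_neg, 5))
  undef <- data.table::data.table(ror = NA_real_, ci_low = NA_real_,
                                  ci_high = NA_real_, defined = FALSE)
  expect_false(call_signal(undef, ic, 5))
})

test_that("signal strength strata are half-open on the right", {
  expect_equal(stratify_signal(c(0.5, 1.31, 1.5, 1.6, 3, 3.32, 6.79)),
               c("weak", "weak", "weak", "medium", "medium", "strong",
                 "strong"))
  expect_error(stratify_signal(0), "positive")
  expect_error(stratify_signal(-1), "positive")
})

test_that("the signal table is sorted by ROR with deterministic ties and strength only for positives", {
  tabs <- data.table::data.table(
    ingredient = c("bbb", "aaa", "ccc", "ddd"),
    a = c(10L, 10L, 0L, 4L),
    b = c(10L, 10L, 20L, 500L),
    c = c(10L, 10L, 20L, 16L),
    d = c(970L, 970L, 940L, 480L))
  st <- signal_table(tabs, atc_map = NULL)
  expect_equal(st$ingredient[1:2], c("aaa", "bbb"))  # tie broken by name
  expect_true(all(st$strength[!st$positive] == "none"))
  expect_true(all(st$strength[st$positive] != "none"))
  # undefined ROR sorts last
  expect_equal(st$ingredient[4], "ccc")
})
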