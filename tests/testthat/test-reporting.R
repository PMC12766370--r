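test_that("age bands split target cases correctly and percentages recompute from counts", {
  demo <- data.table::data.table(
    primaryid = as.character(11:14), caseid = as.character(1:4),
    fda_dt = c("20230101", "20230202", "20240303", "20240404"),
    age = c("10", "20", "70", ""), age_cod = c("YR", "YR", "YR", ""),
    sex = c("F", "M", "F", ""), wt = c("70", "85", "", ""),
    occp_cod = c("MD", "", "PH", "CN"),
    reporter_country = c("US", "US", "JP", "FR"))
  outc <- data.table::data.table(primaryid = c("11", "11", "21"),
                                 caseid = c("1", "1", "2"),
                                 outc_cod = c("DE", "HO", "HO"))
  tc <- make_cases(demo, outc = outc)
  tc$ps <- data.table::data.table(primaryid = character(),
                                  caseid = character(),
                                  drug_seq = character(),
                                  ingredient = character(),
                                  start_dt = character())
  tc$target_pt_code <- 10012599L
  class(tc) <- "faers_target_cases"
  d <- demographics(tc)
  expect_equal(d$n_total, 4L)
  expect_equal(d$age_bands$count, c(1L, 1L, 1L, 1L))
  expect_equal(d$sex$count, c(2L, 1L, 1L))
  expect_equal(d$sex$pct, round_half_up(100 * d$sex$count / 4, 1))
  # outcome block: one count per distinct code per case; two cases have none
  expect_equal(d$outcomes$count[d$outcomes$level == "HO"], 2L)
  expect_equal(d$outcomes$count[d$outcomes$level == "unknown"], 2L)
  # categorical blocks except outcomes sum to the case total
  expect_equal(sum(d$sex$count), 4L)
  expect_equal(sum(d$age_bands$count), 4L)
  expect_equal(sum(d$weight_bands$count), 4L)
  # per-year counts from FDA_DT
  expect_equal(d$years$count[d$years$year == "2023"], 2L)
  flat <- demographics_table(d)
  expect_true(all(c("sex", "age_years", "outcome", "year") %in% flat$section))
})

test_that("class shares reproduce half-up one-decimal arithmetic", {
  sig <- data.table::data.table(
    ingredient = sprintf("drug%02d", 1:71),
    atc_class = rep(c("N", "L", "J", "H", "C", "A"),
                    c(22, 15, 14, 10, 6, 4)),
    positive = TRUE)
  comp <- class_composition(sig)
  expect_equal(comp$share_pct[comp$atc_class == "N"], 31.0)
  expect_equal(comp$share_pct[comp$atc_class == "L"], 21.1)
  expect_equal(comp$share_pct[comp$atc_class == "J"], 19.7)
  expect_equal(comp$share_pct[comp$atc_class == "H"], 14.1)
  expect_equal(comp$share_pct[comp$atc_class == "C"], 8.5)
  expect_equal(sum(comp$n_drugs), 71L)
  expect_equal(nrow(class_composition(sig[0])), 0L)
})

test_that("drug rankings are deterministic total orders", {
  sig <- data.table::data.table(
    ingredient = c("zeta", "alpha", "beta", "gamma"),
    atc_class = "N", a = c(114L, 105L, 105L, 3L),
    ror = c(147.71, 438.55, 438.55, 2.0),
    ci_low = 1.5, ci_high = 10, e_ic = 1, v_ic = 0.1, ic025 = 0.5,
    positive = TRUE, strength = "weak")
  by_cases <- rank_drugs(sig, "cases", k = 10)
  expect_equal(by_cases$ingredient[1], "zeta")           # highest count first
  expect_equal(by_cases$ingredient[2:3], c("alpha", "beta"))  # tie by name
  by_ror <- rank_drugs(sig, "ror", k = 2)
  expect_equal(nrow(by_ror), 2L)
  expect_equal(by_ror$ingredient, c("alpha", "beta"))
  expect_equal(nrow(rank_drugs(sig, "cases", k = 100)), 4L)  # k > list
})

test_that("strength strata sizes sum to the number of positive drugs", {
  cfg <- tiny_config(n_reports = 5000L, q_target = 0.05, rr = 10)
  res <- analyze_bundle(generate_quarter(cfg, seed = 31))
  st <- res$signals
  expect_equal(sum(st$strength != "none"), sum(st$positive))
})

test_that("the pipeline runs end to end, logs generator-consistent counts and is reproducible", {
  d <- withr::local_tempdir()
  cfg <- tiny_config(n_reports = 1500L, q_target = 0.05, rr = 10,
                     duplicate_rate = 0.2)
  b <- generate_quarter(cfg, seed = 19)
  truth <- attr(b, "truth")
  paths <- write_quarter(b, file.path(d, "in"))
  rc <- run_config(demo = paths[["demo"]], drug = paths[["drug"]],
                   reac = paths[["reac"]], ther = paths[["ther"]],
                   outc = paths[["outc"]],
                   out_dir = file.path(d, "out1"))
  res <- suppressMessages(run_pipeline(rc))
  expect_true(file.exists(file.path(d, "out1", "signal_table.csv")))
  expect_true(file.exists(file.path(d, "out1", "run_log.txt")))
  # stage counts equal generator ground truth
  expect_true(any(grepl(sprintf("-> %d cases", uniqueN(truth$caseid)),
                        res$log)))
  expect_true(any(grepl(sprintf("%d cases with PT", sum(truth$target)),
                        res$log)))
  # rerun into a second directory: byte-identical outputs
  rc2 <- rc; rc2$out_dir <- file.path(d, "out2")
  suppressMessages(run_pipeline(rc2))
  for (f in setdiff(list.files(file.path(d, "out1")), "run_log.txt")) {
    expect_identical(readLines(file.path(d, "out1", f)),
                     readLines(file.path(d, "out2", f)))
  }
  # a missing map path aborts with the path named, and removes partials
  rc3 <- rc; rc3$synonym_map <- file.path(d, "no-such-map.tsv")
  rc3$out_dir <- file.path(d, "out3")
  expect_error(suppressMessages(run_pipeline(rc3)), "no-such-map")
  expect_false(file.exists(file.path(d, "out3", "signal_table.csv")))
  expect_equal(length(list.files(file.path(d, "out3"))), 0L)
})

test_that("YAML round trips for simulation and run configs", {
  d <- withr::local_tempdir()
  sim_yaml <- file.path(d, "sim.yaml")
  yaml::write_yaml(list(n_reports = 200L, duplicate_rate = 0.1,
                        planted_signals = list(list(drug_id = "lithium",
                                                    rr = 10))),
                   sim_yaml)
  cfg <- read_sim_config(sim_yaml)
  expect_equal(cfg$n_reports, 200L)
  expect_equal(cfg$planted_signals[[1]]$rr, 10)
  b <- generate_quarter(cfg, seed = 1)
  paths <- write_quarter(b, file.path(d, "q"))
  run_yaml <- file.path(d, "run.yaml")
  yaml::write_yaml(c(as.list(paths), list(out_dir = file.path(d, "out"))),
                   run_yaml)
  rc <- read_run_config(run_yaml)
  expect_s3_class(rc, "pv_run_config")
  res <- suppressMessages(run_pipeline(rc))
  expect_true(file.exists(file.path(d, "out", "demographics.csv")))
})
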