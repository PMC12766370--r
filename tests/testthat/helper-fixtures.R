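# Programmatic fixtures: hand-built mini bundles and small simulation
# configurations shared across test files.

library(data.table)

# a faers_cases-shaped object built directly from per-table data.tables;
# missing tables default to empty
make_cases <- function(demo, drug = NULL, reac = NULL, ther = NULL,
                       outc = NULL) {
  empty <- function(kind) {
    cols <- faerspv::faers_columns[[kind]]
    setnames(as.data.table(matrix(character(), ncol = length(cols))), cols)
  }
  fill <- function(tab, kind) {
    if (is.null(tab)) return(empty(kind))
    tab <- as.data.table(lapply(tab, as.character))
    for (cn in setdiff(faerspv::faers_columns[[kind]], names(tab))) {
      tab[, (cn) := ""]
    }
    tab
  }
  out <- list(demo = fill(demo, "demo"), drug = fill(drug, "drug"),
              reac = fill(reac, "reac"), ther = fill(ther, "ther"),
              outc = fill(outc, "outc"), log = list())
  class(out) <- "faers_cases"
  out
}

test_synonym_map <- c(drugx = "drugx", drugy = "drugy", drugz = "drugz",
                      lithium = "lithium", "lithium carbonate" = "lithium")

# small catalogs for fast generator tests: nd drugs, one target event at
# marginal q_target plus two background events
tiny_config <- function(n_reports = 1000L, q_target = 0.1, rr = 1,
                        planted_drug = "lithium", ...) {
  drugs <- c("lithium", "quetiapine", "letrozole", "doxycycline")
  dc <- data.table(drug_id = drugs, ingredient = drugs,
                   atc_code = c("N", "N", "L", "J"), p = rep(0.25, 4))
  ec <- data.table(pt_cod = c(10012599L, 10028813L, 10019211L),
                   pt = c("Diabetes insipidus", "Nausea", "Headache"),
                   p = c(q_target, (1 - q_target) / 2, (1 - q_target) / 2))
  sigs <- if (rr != 1) list(planted_signal(planted_drug, 10012599L, rr = rr))
          else list()
  sim_config(n_reports = n_reports, drug_catalog = dc, event_catalog = ec,
             planted_signals = sigs, ...)
}
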