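---
title: "Methods: disproportionality screening for a rare target event"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening for a rare target event}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faerspv)
```

`faerspv` screens spontaneous adverse-event reports for drugs that
co-report disproportionately often with one target event. This vignette is
the package's own account of the method: the data model and its cleaning
rules, the two disproportionality statistics and their parameters, the
time-to-onset procedure, what the synthetic-data generator emulates, and
the design choices made where conventions genuinely diverge.

## The data model and cleaning rules

Reports arrive as five `$`-delimited ASCII tables in the FAERS quarterly
dialect — DEMO (one row per report version), DRUG, REAC, THER and OUTC —
linked by PRIMARYID. A *case* (CASEID) may be represented by several
report versions. The package keeps every field as text in memory: partial
dates and empty strings are meaningful to the exclusion rules below, and
verbatim storage makes the read/write round trip exact. Malformed rows
(wrong field count, empty PRIMARYID) are counted and rejected, never
silently dropped, and child records that do not resolve to a DEMO row are
counted as orphans.

**Deduplication** follows the standard FDA recommendation: group report
versions by CASEID, keep the version with the latest FDA receipt date
(FDA_DT), and break ties by the higher PRIMARYID (numerically when both
parse as numbers, lexicographically otherwise). Versions without a
parseable FDA_DT lose to any dated version. The operation is idempotent
and never increases the case count. Published descriptions of this rule
are frequently garbled (PRIMARYID is unique per version, so "identical
PRIMARYIDs" cannot be the grouping key); the CASEID-keyed form implemented
here is the only internally consistent reading and is the one in
widespread use.

**Drug standardization** is a pure dictionary lookup: verbatim names are
case-folded, whitespace-collapsed and stripped of surrounding punctuation,
then matched exactly against a synonym map (bundled default:
`inst/extdata/drug_synonyms.tsv`). There is no fuzzy matching and no
algorithmic salt/suffix stripping — every mapping is auditable in the
dictionary file, and misses are counted rather than guessed. Combination
products are single ingredients in the map. ATC level-1 classification is
the same kind of lookup; unknown ingredients are reported as
`UNCLASSIFIED`.

**Counting unit.** All contingency cells count deduplicated cases. A drug
counts once per case however many of the case's records name it, and only
records with role code PS (primary suspect) enter suspect counting;
secondary-suspect, concomitant and interacting drugs are ignored. Cases
are deduplicated *before* role filtering; the order is observable only in
edge cases (a stale version with a different role coding), and fixing it
makes the pipeline deterministic.

## Disproportionality statistics

For drug $i$ versus the target event, with cells $a, b, c, d$ and
$N = a+b+c+d$:

**Reporting odds ratio.** $\mathrm{ROR} = ad/(bc)$ with the Woolf
confidence interval
$\exp\!\big(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d}\big)$.
Any zero cell makes the estimate undefined; no Haldane–Anscombe
continuity correction is applied. The downstream positivity rule imposes
$a \ge 3$, so a correction could never rescue a reportable signal — the
flag is more honest than a corrected number.

**BCPNN information component.** With hyperparameters
$\alpha, \beta, \alpha_i, \beta_j, \gamma_{ij}$:

$$\gamma = \gamma_{ij}\,\frac{(N+\alpha)(N+\beta)}
  {(a+b+\alpha_i)(a+c+\beta_j)}$$

$$E(IC) = \log_2 \frac{(a+\gamma_{ij})(N+\alpha)(N+\beta)}
  {(N+\gamma)(a+b+\alpha_i)(a+c+\beta_j)}$$

$$V(IC) = \frac{1}{(\ln 2)^2}\left[
  \frac{N-a+\gamma-\gamma_{ij}}{(a+\gamma_{ij})(1+N+\gamma)} +
  \frac{N-a-b+\alpha-\alpha_i}{(a+b+\alpha_i)(1+N+\alpha)} +
  \frac{N-a-c+\beta-\beta_j}{(a+c+\beta_j)(1+N+\beta)}
  \right]$$

The defaults $\alpha=\beta=2$, $\alpha_i=\beta_j=\gamma_{ij}=1$ are the
classical choice that centres the prior on independence: an all-zero table
gives $\gamma = 4$ and $E(IC) = \log_2(1\cdot2\cdot2/(4\cdot1\cdot1)) = 0$
exactly. They are exposed via `bcpnn_hyperparameters()` for sensitivity
analyses.

**The credibility bound.** `ic025` is $E(IC) - 2\sqrt{V(IC)}$ — a
two-standard-deviation lower bound, consistent with the established BCPNN
formulation. Some published summaries print the bound as
$E(IC) - 2V(IC)$ without the square root; because $V(IC)$ has squared
units, that variant is dimensionally inconsistent and is provided only as
`ic025_method = "literal"` for sensitivity checks against such sources.
Relatedly, printed IC025 values in the applied literature often cannot be
reproduced from printed margins under any standard hyperparameter choice
(the shrinkage makes large IC025 values at small $N$-fractions
impossible); `faerspv` therefore validates its IC implementation against
independent step-by-step transcriptions of the formulas over an exhaustive
grid of small tables, not against published point values.

**Signal call and strata.** A drug is positive only when the ROR CI lower
bound exceeds 1, $a \ge 3$, and $IC_{025} > 0$ — requiring both algorithms
to agree sharply reduces false positives for rare events. Positive signals
are stratified by $IC_{025}$ into weak $(0, 1.5]$, medium $(1.5, 3]$ and
strong $(3, \infty)$ bits. The boundaries are half-open on the right;
"between 0 and 1.5"-style verbal definitions are ambiguous at the
boundary, and the half-open convention gives every value a unique stratum.
No multiple-testing adjustment is applied: the dual criterion *is* the
screening rule, and the output is a hypothesis list, not a set of
inferences.

## Time-to-onset

Onset is the interval in days between the event date (DEMO.EVENT_DT) and
the suspect drug's start date. Only complete, valid 8-digit calendar dates
qualify on *both* sides; 4- and 6-digit partial dates, blanks, non-numeric
tokens and impossible dates (month 13, February 30) are excluded, each
rejection carrying exactly one reason code so the exclusion tally is
auditable. Date validity is checked arithmetically (month lengths, leap
rule), never through locale-dependent parsing.

Start dates are taken from THER records joined to the drug record via
`dsg_drug_seq`, falling back to the drug record's own START_DT when no
THER date parses; among multiple valid candidates the earliest (first
exposure) is used. Negative intervals (event strictly before start) are
excluded with reason `negative` — they are treated as incorrectly coded
dates, but are reason-coded so a sensitivity analysis could re-include
them. Zero-day onsets are valid: same-day reactions are a real phenomenon
for rapidly acting agents.

Per-drug summaries are the median and quartiles by linear interpolation
between order statistics (quantile position $1 + p(n-1)$, R's default
type 7). This convention yields half-integer medians at even $n$, matching
how such tables are conventionally reported. Drugs with no usable record
are omitted rather than reported as empty rows.

**Ages** convert to years with factors YR ×1, DEC ×10, MON ÷12, WK ÷52.18,
DY ÷365.25, HR ÷8766; a present age with an absent unit is taken as years.
Results outside 0–120 years are treated as absent — the window costs
nothing for real ages and suppresses unit-coding artifacts. Demographic
percentages use the target-case total as denominator and half-up rounding
to one decimal; the outcome block counts each distinct outcome code per
case, so it may exceed the case total (documented in the output rather
than renormalized away).

## The synthetic-data generator

`generate_quarter()` exists so that every pipeline stage can be validated
against known ground truth. Each case draws one suspect drug and one
primary reaction PT from the joint
$w_{ij} = p_i\, q_j\, rr_{ij}$ (renormalized), where $rr_{ij}$ tilts
planted drug–event pairs. Additional reaction PTs are drawn from
non-target events only, and concomitant (role C) drugs never enter
suspect counting, so the expected 2×2 cells have the closed form
implemented in `expected_counts()`: with PS-role probability $s$,

$$E[a] = n\,s\,\frac{w_{it}}{W}, \quad
  E[b] = n\,s\,\frac{\sum_{j \ne t} w_{ij}}{W}, \quad
  E[c] = n\,\frac{\sum_k w_{kt}}{W} - E[a], \quad
  E[d] = n - E[a] - E[b] - E[c],$$

summing exactly to $n$. Duplication and date corruption do not enter these
expectations because they do not change case-level counts once reports are
deduplicated.

Defaults are chosen once to emulate the scale and mix of the real
reporting stream for this target event: a 50-drug catalog with equal
baseline probabilities; the target PT at its observed database marginal
$2{,}189/18{,}627{,}667 \approx 1.18\times10^{-4}$; 90% of suspects coded
PS; 5% of cases duplicated into 2–3 versions with FDA_DT incremented 1–90
days (the latest version carrying the true content, earlier versions with
blanked age/weight); 5% each of partial (6-digit) and missing date fields
per field, a fifth of the missing draws written as a non-numeric token;
1% of cases with start planted after event; onset lags log-normal
(background median 60 days); demographics (sex, age, weight, occupation,
country, outcome mixes) matched to the descriptive profile of the target
cases. Dates are 8-digit `YYYYMMDD`, partials 6-digit `YYYYMM`, missing
empty — the three classes the exclusion rules must distinguish.

The generator deliberately does **not** model calendar-time reporting
dynamics, reporting biases, drug–drug interactions, MedDRA hierarchy
structure beyond flat PTs, or correlation between demographics and drugs.
Passing tests on synthetic data therefore demonstrate the *mechanics* of
the pipeline — counting, deduplication, exclusion, formula evaluation,
calibration under a known null — not robustness to the biases of real
spontaneous data.

## Validation design

The test suite validates the statistics two independent ways: frozen
closed-form examples, and exhaustive agreement (to 12 significant digits)
with literal step-by-step transcriptions of the formulas over all 2×2
tables with cells in 0–6. Confidence-interval self-consistency is checked
by reconstructing tables from published marginals (case count, total
target cases, database size, ROR point estimate pins down $b$) and
re-evaluating the interval; `scripts/acceptance.R` recomputes these
quantities from scratch.

Two simulation studies run at a fixed problem size of 50,000 cases per
quarter and 100 seeds each — large enough for stable empirical rates,
small enough to keep the full suite in minutes:

- **Null calibration**: all $rr = 1$ at the generator defaults. The dual
  criterion should produce essentially no positives (and no strong
  signals) — with $\approx 6$ expected target cases spread over 50 drugs,
  both the $a \ge 3$ floor and the BCPNN shrinkage bind.
- **Recovery**: one planted pair at $rr = 20$ with the target marginal
  raised to $10^{-3}$ so the planted pair's expected co-report count is
  $\approx 18$ by the closed form above (the design requirement was
  $E[a] \ge 10$; the configuration was fixed from `expected_counts()`
  before any simulation was run). At that size the planted drug should be
  called positive in ≥95% of seeds with a medium-or-strong stratum in
  ≥90%.

Onset recovery uses a corruption-free configuration (clean dates isolate
the estimator from the exclusion machinery) sized for ≥200 usable records,
and checks the recovered median against the planted log-normal median
within sampling error of the sample median. Deduplication is validated by
planting duplicate triples and asserting that exactly the
latest-FDA_DT / highest-PRIMARYID version survives.

## Limitations

Disproportionality screening generates hypotheses; it cannot establish
causality, and the package deliberately implements no causal adjustment.
Only ROR and BCPNN are provided (no PRR, EBGM/MGPS, or regression-based
methods), with no age/sex stratification. One FAERS dialect is supported
(post-2012 column naming; no ISR-era files, no E2B XML). Drug
standardization is only as good as the supplied synonym map — the bundled
map covers the 50-drug simulation catalog and common salt variants, and
real-data use requires a project-specific dictionary. The generator's
distributional choices are stand-ins where no generative description of
real reporting heterogeneity exists; they are documented above precisely
so that results on synthetic data are read with that in mind.
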