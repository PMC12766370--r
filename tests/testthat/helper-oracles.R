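# Independent scalar transcriptions of the signal-detection formulas, written
# step by step and kept separate from the package's vectorized code paths.

literal_ror <- function(a, b, c, d) {
  if (a == 0 || b == 0 || c == 0 || d == 0) {
    return(list(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                defined = FALSE))
  }
  ror <- a * d / b / c
  half <- 1.96 * (1 / a + 1 / b + 1 / c + 1 / d)^0.5
  list(ror = ror,
       ci_low = exp(log(ror) - half),
       ci_high = exp(log(ror) + half),
       defined = TRUE)
}

literal_ic <- function(a, b, c, d,
                       alpha = 2, beta = 2, alpha_i = 1, beta_j = 1,
                       gamma_ij = 1) {
  N <- a + b + c + d
  gamma <- gamma_ij * (N + alpha) * (N + beta) /
    ((a + b + alpha_i) * (a + c + beta_j))
  e_ic <- log2((a + gamma_ij) * (N + alpha) * (N + beta) /
                 ((N + gamma) * (a + b + alpha_i) * (a + c + beta_j)))
  v_ic <- (1 / log(2))^2 *
    ((N - a + gamma - gamma_ij) / ((a + gamma_ij) * (1 + N + gamma)) +
       (N - a - b + alpha - alpha_i) / ((a + b + alpha_i) * (1 + N + alpha)) +
       (N - a - c + beta - beta_j) / ((a + c + beta_j) * (1 + N + beta)))
  list(e_ic = e_ic, v_ic = v_ic, ic025 = e_ic - 2 * sqrt(v_ic))
}

# brute-force 2x2 counter over case-level sets: for each case, whether the
# drug is among its PS ingredients and whether the target PT is present
brute_force_table <- function(case_drugs, case_has_target, ingredient) {
  a <- b <- cc <- d <- 0L
  for (i in seq_along(case_drugs)) {
    has_drug <- ingredient %in% case_drugs[[i]]
    has_evt <- case_has_target[[i]]
    if (has_drug && has_evt) a <- a + 1L
    else if (has_drug) b <- b + 1L
    else if (has_evt) cc <- cc + 1L
    else d <- d + 1L
  }
  list(a = a, b = b, c = cc, d = d)
}
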