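# Shared fixtures, all built in code.

# A tiny well-formed cohort data frame.
tiny_cohort_df <- function() {
  data.frame(
    outcome = c(1, 0, 1),
    gender = c("Female", "Male", "Male"),
    residence = c("Urban", "Rural", "Urban"),
    region = c("Others", "SNNPR", "Others"),
    age_group = c("<18", "18-25", ">=35"),
    clean_teeth = c("No", "Yes", "No")
  )
}

# One-covariate cohort realizing a 2x2 gender table: (a, b) Female
# (non-natural, natural) counts, (c, d) Male counts. All other covariates at
# reference so the design reduces to intercept + Male.
gender_cohort <- function(a, b, c, d) {
  as_cohort(data.frame(
    outcome = rep(c(0, 1, 0, 1), times = c(a, b, c, d)),
    gender = rep(c("Female", "Male"), times = c(a + b, c + d)),
    residence = "Urban", region = "Others", age_group = "<18",
    clean_teeth = "No"
  ))
}

# Intercept-only design with n1 successes out of n records.
intercept_design <- function(n1, n) {
  new_design(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
             rep(c(1L, 0L), times = c(n1, n - n1)))
}

# Saturated intercept+Male design from 2x2 gender counts.
gender_design <- function(a, b, c, d) {
  coh <- gender_cohort(a, b, c, d)
  X <- cbind(`(Intercept)` = 1, genderMale = as.integer(coh$gender == "Male"))
  new_design(X, coh$outcome)
}

# Wrap chain matrices as a posterior_samples-like list for the diagnostics.
chain_list <- function(...) lapply(list(...), as.matrix)
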