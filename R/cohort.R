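#' Canonical covariate levels
#'
#' The declared level sets of the five covariates; the first level of each is
#' the reference category absorbed into the intercept under dummy coding.
#'
#' @return Named list of character level vectors.
#' @export
covariate_levels <- function() {
  list(
    gender      = c("Female", "Male"),
    residence   = c("Urban", "Rural"),
    region      = c("Others", "SNNPR"),
    age_group   = c("<18", "18-25", "26-35", ">=35"),
    clean_teeth = c("No", "Yes")
  )
}

cohort_columns <- function() c("outcome", names(covariate_levels()))

# Spelling aliases accepted at read time (matching is case-insensitive and
# ignores whitespace; en/em dashes are treated as hyphens).
level_aliases <- function() {
  list(
    age_group = c("<=18" = "<18", "=<18" = "<18", "under18" = "<18",
                  ">35" = ">=35", "35+" = ">=35", "=>35" = ">=35")
  )
}

normalize_token <- function(x) {
  x <- gsub("[–—−]", "-", x)   # dashes -> hyphen
  x <- gsub("[[:space:]]+", "", x)
  tolower(x)
}

match_level <- function(values, column) {
  levels <- covariate_levels()[[column]]
  lookup <- stats::setNames(levels, normalize_token(levels))
  aliases <- level_aliases()[[column]]
  if (!is.null(aliases)) {
    lookup <- c(lookup, stats::setNames(unname(aliases), normalize_token(names(aliases))))
  }
  out <- lookup[normalize_token(values)]
  bad <- which(is.na(out) | !nzchar(values) | is.na(values))
  if (length(bad) > 0) {
    stop(sprintf("invalid value '%s' for column '%s' at row %d (allowed: %s)",
                 values[bad[1]], column, bad[1], paste(levels, collapse = ", ")),
         call. = FALSE)
  }
  factor(unname(out), levels = levels)
}

#' Validate a patient-level caries cohort
#'
#' Checks that a data frame has the six required columns (`outcome`, `gender`,
#' `residence`, `region`, `age_group`, `clean_teeth`), that the outcome is
#' literal 0/1 (1 = natural caries, 0 = non-natural), and that every covariate
#' value belongs to its declared level set. Level matching is case-insensitive
#' and accepts common spelling variants of the age groups.
#'
#' @param df A data frame of patient records.
#' @return A `caries_cohort` data frame with factor covariates in canonical
#'   level order (reference level first) and integer outcome.
#' @export
as_cohort <- function(df) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) < 1) stop("cohort must contain at least one record", call. = FALSE)
  out_raw <- trimws(as.character(df$outcome))
  bad <- which(!(out_raw %in% c("0", "1")))
  if (length(bad) > 0) {
    stop(sprintf("invalid value '%s' for column 'outcome' at row %d (must be 0 or 1)",
                 out_raw[bad[1]], bad[1]), call. = FALSE)
  }
  res <- data.frame(outcome = as.integer(out_raw))
  for (cov in names(covariate_levels())) {
    res[[cov]] <- match_level(trimws(as.character(df[[cov]])), cov)
  }
  rownames(res) <- NULL
  class(res) <- c("caries_cohort", "data.frame")
  res
}

#' Read a cohort CSV
#'
#' Reads a comma-separated, UTF-8 file with a mandatory header row naming the
#' columns `outcome,gender,residence,region,age_group,clean_teeth` and
#' validates every record at read time (no missing values are tolerated).
#'
#' @param path Path to the CSV file.
#' @return A validated [as_cohort()] data frame; row order is preserved.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  as_cohort(raw)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: writes the canonical six-column CSV so that a
#' write/read round trip reproduces the cohort exactly.
#'
#' @param cohort A `caries_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  utils::write.csv(cohort[, cohort_columns()], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Coefficient slot names of the reference-coded design
#'
#' The fixed coefficient order: intercept, Male, Rural, SNNPR, the three
#' non-reference age groups, and teeth-cleaning Yes. Reference categories are
#' Female, Urban, Others, `<18` and No.
#'
#' @return Character vector of the 8 slot names.
#' @export
design_slots <- function() {
  c("(Intercept)", "genderMale", "residenceRural", "regionSNNPR",
    "age_group18-25", "age_group26-35", "age_group>=35", "clean_teethYes")
}

#' Reference-code a cohort into a design matrix
#'
#' Expands the five categorical covariates into 0/1 indicator columns against
#' their reference levels, prepends an intercept column of ones, and carries
#' the outcome vector. Column order is fixed (see [design_slots()]).
#'
#' @param cohort A `caries_cohort`.
#' @return A `caries_design` list with elements `X` (n x 8 numeric matrix),
#'   `y` (integer outcome vector) and `slots` (column names).
#' @export
encode_design <- function(cohort) {
  cohort <- as_cohort(cohort)
  n <- nrow(cohort)
  X <- cbind(
    1,
    as.integer(cohort$gender == "Male"),
    as.integer(cohort$residence == "Rural"),
    as.integer(cohort$region == "SNNPR"),
    as.integer(cohort$age_group == "18-25"),
    as.integer(cohort$age_group == "26-35"),
    as.integer(cohort$age_group == ">=35"),
    as.integer(cohort$clean_teeth == "Yes")
  )
  colnames(X) <- design_slots()
  new_design(X, cohort$outcome)
}

#' Construct a design object from a matrix and outcome
#'
#' Low-level constructor used by [encode_design()] and by tests that build
#' small designs directly.
#'
#' @param X Numeric matrix with named columns (intercept included).
#' @param y Binary outcome vector, same length as `nrow(X)`.
#' @return A `caries_design` list.
#' @export
new_design <- function(X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)) - 1L)
  structure(list(X = X, y = y, slots = colnames(X)), class = "caries_design")
}

#' Cross-tabulate the outcome against one covariate
#'
#' Counts outcome 0 (non-natural) and outcome 1 (natural caries) per level of
#' a covariate, with row percentages (each level's counts as a percentage of
#' that level's total).
#'
#' @param cohort A `caries_cohort`.
#' @param covariate One of `gender`, `residence`, `region`, `age_group`,
#'   `clean_teeth`.
#' @return A `caries_crosstab` data frame with columns `covariate`, `level`,
#'   `count_nonnatural`, `count_natural`, `pct_nonnatural`, `pct_natural`.
#' @export
cross_tabulate <- function(cohort, covariate) {
  cohort <- as_cohort(cohort)
  if (!covariate %in% names(covariate_levels())) {
    stop("unknown covariate: ", covariate, call. = FALSE)
  }
  levels <- covariate_levels()[[covariate]]
  tab <- table(factor(cohort[[covariate]], levels = levels), cohort$outcome)
  n0 <- if ("0" %in% colnames(tab)) tab[, "0"] else rep(0L, length(levels))
  n1 <- if ("1" %in% colnames(tab)) tab[, "1"] else rep(0L, length(levels))
  tot <- n0 + n1
  res <- data.frame(
    covariate = covariate,
    level = levels,
    count_nonnatural = as.integer(n0),
    count_natural = as.integer(n1),
    pct_nonnatural = ifelse(tot > 0, 100 * n0 / tot, NA_real_),
    pct_natural = ifelse(tot > 0, 100 * n1 / tot, NA_real_),
    row.names = NULL
  )
  class(res) <- c("caries_crosstab", "data.frame")
  res
}

check_cells <- function(a, b, c, d, correct) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("negative cell count", call. = FALSE)
  if (correct) return(cells + 0.5)
  zero <- names(cells)[cells == 0]
  if (length(zero) > 0) {
    stop("zero cell '", zero[1],
         "' in 2x2 table; enable the Haldane-Anscombe correction (correct = TRUE) ",
         "to add 0.5 to all cells", call. = FALSE)
  }
  cells
}

#' Crude odds ratio from a 2x2 table
#'
#' For a 2x2 table with exposure rows (reference first) and outcome columns
#' (non-natural, natural): `(a, b)` are the reference-level counts and
#' `(c, d)` the index-level counts. The crude OR is the cross-product
#' `(a*d)/(b*c)`, i.e. the odds of a natural-caries outcome at the index level
#' relative to the reference level.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param correct Apply the Haldane-Anscombe +0.5 correction to all cells.
#'   With the default `FALSE`, a zero cell is an error (silent correction
#'   hides data problems).
#' @return The odds ratio, a positive finite number.
#' @export
crude_odds_ratio <- function(a, b, c, d, correct = FALSE) {
  k <- check_cells(a, b, c, d, correct)
  unname((k["d"] / k["c"]) / (k["b"] / k["a"]))
}

#' Crude risk ratio from a 2x2 table
#'
#' Same cell convention as [crude_odds_ratio()]; computes the ratio of
#' outcome probabilities `(d/(c+d)) / (b/(a+b))`.
#'
#' @inheritParams crude_odds_ratio
#' @return The risk ratio, a positive finite number.
#' @export
crude_risk_ratio <- function(a, b, c, d, correct = FALSE) {
  k <- check_cells(a, b, c, d, correct)
  unname((k["d"] / (k["c"] + k["d"])) / (k["b"] / (k["a"] + k["b"])))
}

#' Published outcome-by-covariate counts of the clinic cohort
#'
#' The retrospective Hawassa dental-clinic cohort (n = 6007) is not deposited
#' at patient level; what is available are the outcome-by-covariate counts of
#' its descriptive cross-tabulation. This function returns those counts: for
#' every covariate level, the number of non-natural (outcome 0) and natural
#' (outcome 1) caries patients. Within each covariate the outcome margin is
#' 778 non-natural / 5229 natural.
#'
#' @return Data frame with columns `covariate`, `level`, `nonnatural`,
#'   `natural`.
#' @export
clinic_crosstab_counts <- function() {
  data.frame(
    covariate = rep(c("gender", "residence", "region", "age_group", "clean_teeth"),
                    times = c(2, 2, 2, 4, 2)),
    level = c("Female", "Male", "Urban", "Rural", "SNNPR", "Others",
              "<18", "18-25", "26-35", ">=35", "Yes", "No"),
    nonnatural = c(327L, 451L, 434L, 344L, 183L, 595L,
                   90L, 295L, 211L, 182L, 68L, 710L),
    natural = c(2501L, 2728L, 3510L, 1719L, 751L, 4478L,
                872L, 1742L, 1392L, 1223L, 305L, 4924L)
  )
}

#' Reconstruct a patient-level cohort consistent with published counts
#'
#' Builds a deterministic 6007-record cohort whose outcome-by-covariate
#' cross-tabulations exactly reproduce the counts of
#' [clinic_crosstab_counts()]. Within each outcome stratum covariate values
#' are assigned independently in level order, so all five two-way
#' (outcome x covariate) tables are exact but the joint distribution across
#' covariates is arbitrary; the reconstruction is suitable for descriptive
#' statistics and crude (single-covariate) measures, not for multivariable
#' coefficient recovery.
#'
#' @param counts Count table in the format of [clinic_crosstab_counts()].
#' @return A `caries_cohort` data frame.
#' @export
reconstruct_cohort <- function(counts = clinic_crosstab_counts()) {
  totals <- tapply(counts$nonnatural + counts$natural, counts$covariate, sum)
  if (length(unique(totals)) != 1) {
    stop("covariate totals disagree; counts are inconsistent", call. = FALSE)
  }
  build_stratum <- function(col) {
    n <- sum(counts[[col]][counts$covariate == "gender"])
    df <- data.frame(outcome = rep(if (col == "natural") 1L else 0L, n))
    for (cov in names(covariate_levels())) {
      sub <- counts[counts$covariate == cov, ]
      sub <- sub[match(covariate_levels()[[cov]], sub$level), ]
      if (sum(sub[[col]]) != n) {
        stop("outcome margin mismatch for covariate '", cov, "'", call. = FALSE)
      }
      df[[cov]] <- rep(sub$level, times = sub[[col]])
    }
    df
  }
  as_cohort(rbind(build_stratum("nonnatural"), build_stratum("natural")))
}

#' @export
print.caries_cohort <- function(x, ...) {
  cat(sprintf("caries cohort: %d records, %.1f%% natural caries\n",
              nrow(x), 100 * mean(x$outcome)))
  NextMethod()
}

#' @export
print.caries_crosstab <- function(x, ...) {
  cat("outcome cross-tabulation for", x$covariate[1], "\n")
  print.data.frame(format(x, digits = 4), row.names = FALSE)
  invisible(x)
}
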