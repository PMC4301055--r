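## Univariate statistics around the discriminant analysis: oral/nasal
## comparisons on per-individual means, chi-squared comparisons of
## classification rates, and covariate (sex, body mass) effects.

#' Per-individual mean feature values for oral and nasal calls
#'
#' @param data Feature table with `individual_id`, `call_type` and the value
#'   column.
#' @param value Name of the feature column to average.
#' @return Data frame with columns `individual_id`, `oral`, `nasal`
#'   (`NA` where an individual lacks calls of a type).
#' @export
paired_means <- function(data, value) {
  stopifnot(value %in% names(data))
  ag <- stats::aggregate(data[[value]],
                         by = list(individual_id = data$individual_id,
                                   call_type = data$call_type),
                         FUN = mean)
  ids <- sort(unique(ag$individual_id))
  wide <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  for (ct in c("oral", "nasal")) {
    m <- ag[ag$call_type == ct, ]
    wide[[ct]] <- m$x[match(ids, m$individual_id)]
  }
  wide
}

## two-level within-subject ANOVA via aov with an individual error stratum;
## for two levels F equals the squared paired t statistic
.rm_anova2 <- function(pm, col_a = "oral", col_b = "nasal") {
  cc <- stats::complete.cases(pm[[col_a]], pm[[col_b]])
  if (any(!cc))
    warning("excluding individuals with a missing call type: ",
            paste(pm$individual_id[!cc], collapse = ", "))
  a <- pm[[col_a]][cc]; b <- pm[[col_b]][cc]
  n <- length(a)
  if (n < 3L) stop("need at least 3 complete oral/nasal pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(F = 0, df1 = 1L, df2 = n - 1L, p = 1))
    stop("zero variance of within-individual differences; F is unbounded")
  }
  long <- data.frame(
    id = factor(rep(seq_len(n), 2L)),
    type = factor(rep(c(col_a, col_b), each = n)),
    value = c(a, b))
  fit <- stats::aov(value ~ type + Error(id), data = long)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  i <- grep("^type", trimws(rownames(tab)))
  list(F = tab[i, "F value"], df1 = 1L, df2 = n - 1L,
       p = tab[i, "Pr(>F)"])
}

#' Repeated-measures comparison of oral vs nasal call variables
#'
#' Two-level within-subject ANOVA on per-individual mean values (one oral and
#' one nasal mean per individual), controlling for individuality. With two
#' levels the F statistic equals the square of the paired t statistic and has
#' (1, n - 1) degrees of freedom.
#'
#' @param pm Data frame from [paired_means()] (columns `individual_id`,
#'   `oral`, `nasal`).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_calltype <- function(pm) .rm_anova2(pm)

#' Repeated-measures comparison of per-individual classification accuracies
#'
#' Same within-subject ANOVA as [rm_anova_calltype()], applied to
#' per-individual percent-correct values from two classification analyses of
#' the same individuals (e.g. oral vs nasal, or oral vs pooled).
#'
#' @param pm Data frame with `individual_id` and two accuracy columns named
#'   `oral` and `nasal` (rename as needed).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_assignment <- function(pm) .rm_anova2(pm)

#' Reconstruct correct/incorrect counts from a printed percentage
#'
#' Nearest-integer reconstruction of the 2-cell count vector behind a
#' reported percent-correct value — the input needed to compare two
#' classification rates with a chi-squared test when only percentages and
#' sample sizes are reported.
#'
#' @param pct_correct Percent correct in \[0, 100\].
#' @param n_calls Total number of calls.
#' @return Named integer vector `c(correct, incorrect)`.
#' @export
#' @examples
#' reconstruct_counts(77.0, 209)  # 161 correct, 48 incorrect
reconstruct_counts <- function(pct_correct, n_calls) {
  if (pct_correct < 0 || pct_correct > 100)
    stop("`pct_correct` must be within [0, 100]")
  k <- as.integer(round(pct_correct * n_calls / 100))
  c(correct = k, incorrect = as.integer(n_calls) - k)
}

#' Yates-corrected 2 x 2 chi-squared test
#'
#' Continuity-corrected chi-squared test of independence on a 2 x 2 count
#' table, as used to compare percent-correct classification between call
#' samples.
#'
#' @param table 2 x 2 matrix of non-negative counts (rows = samples,
#'   columns = correct/incorrect).
#' @return List with `chi2`, `df` (= 1) and `p`.
#' @export
#' @examples
#' yates_chi2(rbind(reconstruct_counts(77.0, 209),
#'                  reconstruct_counts(61.8, 212)))
yates_chi2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2 x 2 table")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  ht <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  list(chi2 = unname(ht$statistic), df = 1L, p = ht$p.value)
}

#' Correlation between body mass and a call variable
#'
#' Pearson correlation between transformed body mass and per-individual mean
#' feature values. Because body mass scales with the cube of a linear body
#' dimension, the default transform is the cube root; a literal log-base-3
#' option is also provided.
#'
#' @param mass_kg Positive body masses, one per individual.
#' @param feature_means Per-individual mean feature values.
#' @param transform `"cuberoot"` (default) or `"log3"`.
#' @return List with `r`, `p`, `n` and `transform`.
#' @export
mass_correlation <- function(mass_kg, feature_means,
                             transform = c("cuberoot", "log3")) {
  transform <- match.arg(transform)
  if (length(mass_kg) != length(feature_means))
    stop("`mass_kg` and `feature_means` must have equal length")
  if (length(mass_kg) < 3L) stop("need at least 3 individuals")
  if (any(mass_kg <= 0)) stop("masses must be positive")
  if (stats::sd(mass_kg) == 0 || stats::sd(feature_means) == 0)
    stop("zero variance in mass or feature values")
  tm <- if (transform == "cuberoot") mass_kg^(1 / 3) else log(mass_kg, base = 3)
  ht <- stats::cor.test(tm, feature_means, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(mass_kg),
       transform = transform)
}

#' ANCOVA of sex and body mass effects on a call variable
#'
#' Linear-model ANOVA with sex as a fixed categorical factor, body mass as a
#' continuous covariate, and their interaction; Type III sums of squares with
#' sum-to-zero contrasts, so each term carries 1 numerator df and the
#' denominator df is n - 4.
#'
#' @param feature Per-individual feature values.
#' @param sex Factor or character with two levels (e.g. male/female).
#' @param mass_kg Body masses.
#' @return Data frame with one row per term (`sex`, `mass`, `sex:mass`):
#'   `F`, `df1`, `df2`, `p`.
#' @export
ancova_sex_mass <- function(feature, sex, mass_kg) {
  sex <- factor(sex)
  n <- length(feature)
  if (length(sex) != n || length(mass_kg) != n)
    stop("inputs must have equal length")
  if (nlevels(sex) < 2L) stop("both sexes must be present")
  if (n <= 4L) stop("need more than 4 observations")
  d <- data.frame(y = feature, sex = sex, mass = mass_kg)
  fit <- stats::lm(y ~ sex * mass, data = d,
                   contrasts = list(sex = "contr.sum"))
  a <- car::Anova(fit, type = 3)
  terms <- c("sex", "mass", "sex:mass")
  i <- match(terms, rownames(a))
  data.frame(term = terms,
             F = a[i, "F value"],
             df1 = a[i, "Df"],
             df2 = stats::df.residual(fit),
             p = a[i, "Pr(>F)"],
             stringsAsFactors = FALSE)
}

#' One-way ANOVA
#'
#' Standard fixed-effects one-way analysis of variance, e.g. for comparing
#' body mass between male and female calves.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (>= 2 groups, each with >= 2 values).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 values")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]  # row 1 = groups, row 2 = residuals
  list(F = tab[1L, "F value"],
       df1 = tab[1L, "Df"], df2 = tab[2L, "Df"],
       p = tab[1L, "Pr(>F)"])
}
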