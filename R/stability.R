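## Between-year stability of individual vocal signatures: within-year
## discrimination vs transfer of year-A discriminant functions to year-B
## calls.

#' Pair two years of feature tables for the same individuals
#'
#' @param table_a,table_b Feature tables for the two years (e.g. 2011 and
#'   2012) containing the grouping column and the analysis variables.
#' @param group Grouping column name.
#' @param vars Analysis variables.
#' @param min_calls Minimum calls per individual per year (default 2; the
#'   field design used >= 7 oral / >= 10 nasal).
#' @return A `year_split` (list with `a`, `b`, `group`, `vars`).
#' @export
year_split <- function(table_a, table_b, group = "individual_id",
                       vars = dfa_default_vars(), min_calls = 2L) {
  for (tb in list(table_a, table_b)) {
    miss <- setdiff(c(group, vars), names(tb))
    if (length(miss))
      stop("table lacks columns: ", paste(miss, collapse = ", "))
  }
  ids_a <- sort(unique(as.character(table_a[[group]])))
  ids_b <- sort(unique(as.character(table_b[[group]])))
  if (!identical(ids_a, ids_b))
    stop("individual sets differ between years; only-in-A: ",
         paste(setdiff(ids_a, ids_b), collapse = ", "), "; only-in-B: ",
         paste(setdiff(ids_b, ids_a), collapse = ", "))
  for (nm in c("a", "b")) {
    tb <- if (nm == "a") table_a else table_b
    cnt <- table(tb[[group]])
    if (any(cnt < min_calls))
      stop("individuals under the per-year minimum of ", min_calls,
           " calls in year ", toupper(nm), ": ",
           paste(names(cnt)[cnt < min_calls], collapse = ", "))
  }
  structure(list(a = table_a, b = table_b, group = group, vars = vars),
            class = "year_split")
}

#' Within-year discrimination with its permutation chance level
#'
#' Fits the discriminant functions on one year's calls alone, classifies the
#' same calls (resubstitution) and computes the label-permutation null.
#'
#' @param split A [year_split()].
#' @param year `"a"` or `"b"`.
#' @param n_perm Permutations for the null.
#' @param seed Optional integer seed.
#' @return List with `classification` (a `dfa_classification`), `null`
#'   (a `permutation_null`) and `significance`.
#' @export
within_year_dfa <- function(split, year = c("a", "b"), n_perm = 1000,
                            seed = NULL) {
  stopifnot(inherits(split, "year_split"))
  year <- match.arg(year)
  tab <- split[[year]]
  model <- fit_dfa(tab, split$group, split$vars)
  cls <- classify(model, tab)
  null <- permutation_null(tab, split$group, split$vars, n_perm = n_perm,
                           seed = seed)
  list(classification = cls, null = null,
       significance = significance(cls$average_pct, null))
}

#' Cross-year transfer of discriminant functions
#'
#' Classifies year-B calls with the discriminant functions fitted on year-A
#' calls — the cross-validation measure of how well individual signatures are
#' retained over time. The transferred accuracy is compared against both
#' years' within-year accuracies with Yates-corrected chi-squared tests (on
#' counts reconstructed from the percentages) and against year-B's own
#' permutation null.
#'
#' @param split A [year_split()].
#' @param n_perm Permutations for year-B's null.
#' @param seed Optional integer seed.
#' @return A `cross_year` list: `cross`, `within_a`, `within_b`
#'   (classifications), `null_b`, `chi2_vs_a`, `chi2_vs_b`, and
#'   `significance_vs_null` for the transferred accuracy.
#' @export
cross_year_classify <- function(split, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(split, "year_split"))
  model_a <- fit_dfa(split$a, split$group, split$vars)
  model_b <- fit_dfa(split$b, split$group, split$vars)
  within_a <- classify(model_a, split$a)
  within_b <- classify(model_b, split$b)
  cross <- classify(model_a, split$b)
  null_b <- permutation_null(split$b, split$group, split$vars,
                             n_perm = n_perm, seed = seed)
  cmp <- function(x, y) {
    tab <- rbind(reconstruct_counts(x$average_pct, x$n_calls),
                 reconstruct_counts(y$average_pct, y$n_calls))
    if (any(colSums(tab) == 0))  # e.g. both classifications perfect
      list(chi2 = NA_real_, df = 1L, p = NA_real_)
    else yates_chi2(tab)
  }
  structure(list(
    cross = cross, within_a = within_a, within_b = within_b,
    null_b = null_b,
    chi2_vs_a = cmp(cross, within_a),
    chi2_vs_b = cmp(cross, within_b),
    significance_vs_null = significance(cross$average_pct, null_b)
  ), class = "cross_year")
}

#' @export
print.cross_year <- function(x, ...) {
  cat(sprintf(
    "<cross_year: within A %.1f%%, within B %.1f%%, transferred %.1f%% (vs B null %.1f +/- %.1f%%: %s)>\n",
    x$within_a$average_pct, x$within_b$average_pct, x$cross$average_pct,
    x$null_b$mean, x$null_b$sd, x$significance_vs_null))
  invisible(x)
}
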