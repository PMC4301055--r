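## End-to-end orchestration: synthesize (or directly sample) a population,
## run the per-call-type and pooled discriminant analyses with permutation
## nulls, compare call types with chi-squared tests, and optionally run the
## two-year stability analysis. All randomness derives from the single
## config seed, so a rerun with the same config is numerically identical.

#' Build a validated run configuration
#'
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param caller_class `"hind"` or `"calf"`.
#' @param call_types Call types to analyze (each gets its own analysis block;
#'   a pooled block is added when there are two).
#' @param n_individuals Number of individuals.
#' @param calls_per_individual Calls per individual per call type.
#' @param icc Between-individual variance fraction for the generator.
#' @param year_drift_sd Between-year latent drift (multiples of feature SD);
#'   used when `two_year = TRUE`.
#' @param n_perm Permutations per null distribution.
#' @param mode `"resubstitution"` or `"loo"` classification accuracy.
#' @param vars Discriminant-analysis variables.
#' @param use_audio If `TRUE`, synthesize waveforms and extract features from
#'   audio; if `FALSE` (default), sample the feature table directly from the
#'   latent parameters (much faster, same statistical structure).
#' @param two_year If `TRUE`, generate a second (drifted) year and run the
#'   stability analysis.
#' @param out_dir Optional directory for artifacts (feature CSV, JSON report,
#'   config snapshot, WAV files when `use_audio`).
#' @return A `run_config`.
#' @export
run_config <- function(seed = 1L, caller_class = "hind",
                       call_types = c("oral", "nasal"), n_individuals = 22,
                       calls_per_individual = 10, icc = 0.7,
                       year_drift_sd = 0, n_perm = 1000,
                       mode = c("resubstitution", "loo"),
                       vars = dfa_default_vars(), use_audio = FALSE,
                       two_year = FALSE, out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(seed) == 1L, is.finite(seed))
  caller_class <- match.arg(caller_class, c("hind", "calf"))
  call_types <- match.arg(call_types, c("oral", "nasal"), several.ok = TRUE)
  if (n_individuals < 2) stop("need at least 2 individuals")
  if (calls_per_individual < 2) stop("need at least 2 calls per individual")
  if (n_perm < 1) stop("`n_perm` must be positive")
  structure(list(
    seed = as.integer(seed), caller_class = caller_class,
    call_types = call_types, n_individuals = as.integer(n_individuals),
    calls_per_individual = as.integer(calls_per_individual), icc = icc,
    year_drift_sd = year_drift_sd, n_perm = as.integer(n_perm), mode = mode,
    vars = vars, use_audio = isTRUE(use_audio), two_year = isTRUE(two_year),
    out_dir = out_dir
  ), class = "run_config")
}

#' Validate and subsample a call inventory
#'
#' Report-only screening of per-call metadata before analysis: flags
#' unreadable audio files (when a `path` column is present), lists
#' individuals excluded for having fewer than `min_calls` calls of a type,
#' and subsamples (seeded) individuals with more than `max_calls` calls of a
#' type — the balanced-design rules of the field workflow (exclude under 5,
#' cap at 10).
#'
#' @param meta Data frame with `individual_id` and `call_type` (optionally
#'   `path`); may be empty.
#' @param min_calls Minimum calls per individual per type (default 5).
#' @param max_calls Maximum retained calls per individual per type
#'   (default 10).
#' @param seed Optional integer seed for the subsampling.
#' @return A `call_validation`: `keep` (row indices retained), `excluded`,
#'   `subsampled` (data frames), `missing_files`, `messages`.
#' @export
validate_calls <- function(meta, min_calls = 5L, max_calls = 10L,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  msgs <- character()
  if (nrow(meta) == 0L) {
    return(structure(list(keep = integer(), excluded = data.frame(),
                          subsampled = data.frame(), missing_files = character(),
                          messages = "empty input"),
                     class = "call_validation"))
  }
  stopifnot(all(c("individual_id", "call_type") %in% names(meta)))
  missing_files <- character()
  if ("path" %in% names(meta)) {
    bad <- !file.exists(meta$path)
    missing_files <- meta$path[bad]
    if (any(bad))
      msgs <- c(msgs, paste0(sum(bad), " unreadable audio file(s)"))
  }
  keep <- logical(nrow(meta))
  excluded <- list(); subsampled <- list()
  combos <- unique(meta[, c("individual_id", "call_type")])
  for (r in seq_len(nrow(combos))) {
    sel <- which(meta$individual_id == combos$individual_id[r] &
                 meta$call_type == combos$call_type[r])
    if (length(sel) < min_calls) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(individual_id = combos$individual_id[r],
                   call_type = combos$call_type[r], n = length(sel))
      next
    }
    if (length(sel) > max_calls) {
      sel_kept <- sort(sample(sel, max_calls))
      subsampled[[length(subsampled) + 1L]] <-
        data.frame(individual_id = combos$individual_id[r],
                   call_type = combos$call_type[r],
                   n_available = length(sel), n_retained = max_calls)
      sel <- sel_kept
    }
    keep[sel] <- TRUE
  }
  excluded <- if (length(excluded)) do.call(rbind, excluded) else data.frame()
  subsampled <- if (length(subsampled)) do.call(rbind, subsampled) else data.frame()
  if (nrow(excluded))
    msgs <- c(msgs, paste0(nrow(excluded), " individual/type group(s) below ",
                           min_calls, " calls excluded"))
  if (nrow(subsampled))
    msgs <- c(msgs, paste0(nrow(subsampled), " group(s) subsampled to ",
                           max_calls, " calls"))
  structure(list(keep = which(keep), excluded = excluded,
                 subsampled = subsampled, missing_files = missing_files,
                 messages = if (length(msgs)) msgs else "all calls retained"),
            class = "call_validation")
}

## one DFA block: fit, classify (resub or loo), null, significance
.analysis_block <- function(tab, cfg, seed) {
  cls <- if (cfg$mode == "resubstitution") {
    classify(fit_dfa(tab, "individual_id", cfg$vars), tab)
  } else {
    classify_loo(tab, "individual_id", cfg$vars)
  }
  null <- permutation_null(tab, "individual_id", cfg$vars,
                           n_perm = cfg$n_perm, seed = seed, mode = cfg$mode)
  list(observed_pct = cls$average_pct,
       per_group_pct = cls$per_group_pct,
       confusion = cls$confusion,
       n_calls = cls$n_calls, n_groups = cls$n_groups,
       null = null,
       significance = significance(cls$average_pct, null))
}

#' Run the full individuality analysis end to end
#'
#' Synthesis (audio or direct feature sampling), per-call-type and pooled
#' discriminant analyses with permutation chance levels, chi-squared
#' comparisons between the blocks' accuracies, and — for a two-year config —
#' the between-year stability analysis per call type.
#'
#' @param cfg A [run_config()].
#' @return An `individuality_report`: `config`, `features` (the analyzed
#'   table), `blocks` (one per call type plus `pooled`), `comparisons`
#'   (pairwise chi-squared), and `stability` (per call type, when
#'   configured).
#' @export
run_individuality_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  spec <- population_spec(cfg$caller_class, icc = cfg$icc,
                          year_drift_sd = cfg$year_drift_sd)
  pop <- make_population(spec, cfg$n_individuals, seed = .subseed(cfg$seed, 1L))
  feats <- .generate_features(pop, cfg, seed_k = 2L)

  blocks <- list()
  bseed <- 10L
  for (ct in cfg$call_types) {
    tab <- feats[feats$call_type == ct, , drop = FALSE]
    blocks[[ct]] <- .analysis_block(tab, cfg, .subseed(cfg$seed, bseed))
    bseed <- bseed + 1L
  }
  if (length(cfg$call_types) > 1L)
    blocks$pooled <- .analysis_block(feats, cfg, .subseed(cfg$seed, bseed))

  comparisons <- list()
  bn <- names(blocks)
  if (length(bn) > 1L) {
    for (i in seq_len(length(bn) - 1L)) for (j in (i + 1L):length(bn)) {
      key <- paste(bn[i], bn[j], sep = "_vs_")
      tab <- rbind(
        reconstruct_counts(blocks[[bn[i]]]$observed_pct, blocks[[bn[i]]]$n_calls),
        reconstruct_counts(blocks[[bn[j]]]$observed_pct, blocks[[bn[j]]]$n_calls))
      ## a zero margin (e.g. two perfect classifications) makes the test
      ## degenerate; report NA rather than abort the run
      comparisons[[key]] <- if (any(colSums(tab) == 0))
        list(chi2 = NA_real_, df = 1L, p = NA_real_) else yates_chi2(tab)
    }
  }

  stability <- NULL
  if (cfg$two_year) {
    pop2 <- drift_population(pop, seed = .subseed(cfg$seed, 30L))
    feats2 <- .generate_features(pop2, cfg, seed_k = 31L)
    stability <- list()
    sseed <- 40L
    for (ct in cfg$call_types) {
      split <- year_split(feats[feats$call_type == ct, , drop = FALSE],
                          feats2[feats2$call_type == ct, , drop = FALSE],
                          vars = cfg$vars)
      stability[[ct]] <- cross_year_classify(split, n_perm = cfg$n_perm,
                                             seed = .subseed(cfg$seed, sseed))
      sseed <- sseed + 1L
    }
  }

  report <- structure(list(config = cfg, features = feats, blocks = blocks,
                           comparisons = comparisons, stability = stability),
                      class = "individuality_report")
  if (!is.null(cfg$out_dir)) .write_report(report, cfg$out_dir)
  report
}

.generate_features <- function(pop, cfg, seed_k) {
  if (cfg$use_audio) {
    cs <- synth_calls(pop, cfg$calls_per_individual, cfg$call_types,
                      seed = .subseed(cfg$seed, seed_k))
    if (!is.null(cfg$out_dir))
      write_call_set(cs$calls, file.path(cfg$out_dir, "wav"))
    extract_feature_table(cs$calls)
  } else {
    sample_features_direct(pop, cfg$calls_per_individual, cfg$call_types,
                           seed = .subseed(cfg$seed, seed_k))
  }
}

## plain-list view of a report for JSON serialization
.report_list <- function(report) {
  blk <- lapply(report$blocks, function(b) list(
    observed_pct = b$observed_pct,
    n_calls = b$n_calls, n_groups = b$n_groups,
    per_group_pct = as.numeric(b$per_group_pct),
    null_mean = b$null$mean, null_sd = b$null$sd,
    null_q95 = b$null$q95, null_q99 = b$null$q99, null_q999 = b$null$q999,
    significance = b$significance))
  cmp <- lapply(report$comparisons, function(x)
    list(chi2 = x$chi2, df = x$df, p = x$p))
  stab <- if (!is.null(report$stability)) {
    lapply(report$stability, function(s) list(
      within_a_pct = s$within_a$average_pct,
      within_b_pct = s$within_b$average_pct,
      cross_pct = s$cross$average_pct,
      null_b_mean = s$null_b$mean, null_b_sd = s$null_b$sd,
      chi2_vs_a = s$chi2_vs_a$chi2, p_vs_a = s$chi2_vs_a$p,
      chi2_vs_b = s$chi2_vs_b$chi2, p_vs_b = s$chi2_vs_b$p,
      significance_vs_null = s$significance_vs_null))
  }
  cfg <- report$config
  cfg$vars <- as.list(cfg$vars)
  cfg$out_dir <- NULL  # a path, not part of the numeric run identity
  list(config = unclass(cfg), blocks = blk, comparisons = cmp,
       stability = stab)
}

.write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(.report_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' @export
print.individuality_report <- function(x, ...) {
  cat(sprintf("Individuality analysis: %s, %d individuals, icc = %.2f, %s\n",
              x$config$caller_class, x$config$n_individuals, x$config$icc,
              x$config$mode))
  for (nm in names(x$blocks)) {
    b <- x$blocks[[nm]]
    cat(sprintf("  %-7s %5.1f%% correct (chance %4.1f +/- %3.1f%%, %s; n = %d)\n",
                nm, b$observed_pct, b$null$mean, b$null$sd, b$significance,
                b$n_calls))
  }
  for (nm in names(x$comparisons)) {
    cc <- x$comparisons[[nm]]
    cat(sprintf("  %s: chi2 = %.2f, p = %.3g\n", nm, cc$chi2, cc$p))
  }
  if (!is.null(x$stability)) {
    for (nm in names(x$stability)) {
      s <- x$stability[[nm]]
      cat(sprintf("  stability (%s): within %.1f%% / %.1f%%, transferred %.1f%% (%s vs year-B null)\n",
                  nm, s$within_a$average_pct, s$within_b$average_pct,
                  s$cross$average_pct, s$significance_vs_null))
    }
  }
  invisible(x)
}
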