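## Synthetic call generator. Calls are additive harmonic stacks following a
## smooth (cosine-segment) f0 contour rising from f0beg to f0max at
## dur_to_max, then falling to f0min at the call end. Individuality is
## injected by drawing per-individual latent feature means whose
## between-individual variance fraction is `icc`; call-to-call variation uses
## the remaining 1 - icc.

## latent parameters that drive waveform synthesis directly
.synth_driver_vars <- c("durat", "dur_to_max", "f0beg", "f0max", "f0min",
                        "power_f0", "peak_harm")

#' Specify a synthetic call population
#'
#' @param caller_class `"hind"` or `"calf"`.
#' @param icc Fraction of total feature variance attributed to
#'   between-individual differences (intraclass correlation), in \[0, 1\].
#'   Default 0.7 produces strong but imperfect individuality.
#' @param year_drift_sd Between-year drift of per-individual latent means,
#'   expressed as a multiple of each feature's population SD (features have
#'   heterogeneous units); 0 disables drift.
#' @param n_harmonics Maximum number of harmonics in the stack (aliasing
#'   harmonics are dropped automatically).
#' @param noise_snr_db Signal-to-noise ratio of additive broadband noise (dB).
#' @param rolloff_db Spectral-envelope decay above the emphasized harmonic
#'   (dB per harmonic).
#' @param params Optional list with elements `oral` and/or `nasal`, each a
#'   2 x 14 matrix as returned by [reference_call_params()], overriding the
#'   built-in reference values.
#' @return An object of class `"population_spec"`.
#' @export
population_spec <- function(caller_class = c("hind", "calf"), icc = 0.7,
                            year_drift_sd = 0, n_harmonics = 30,
                            noise_snr_db = 30, rolloff_db = 3,
                            params = NULL) {
  caller_class <- match.arg(caller_class)
  if (!is.numeric(icc) || length(icc) != 1L || icc < 0 || icc > 1)
    stop("`icc` must be a single number in [0, 1]")
  if (year_drift_sd < 0) stop("`year_drift_sd` must be non-negative")
  if (n_harmonics < 1) stop("`n_harmonics` must be at least 1")
  pr <- list(oral = reference_call_params(caller_class, "oral"),
             nasal = reference_call_params(caller_class, "nasal"))
  for (ct in names(params)) {
    m <- params[[ct]]
    if (!is.matrix(m) || !all(rownames(m) == c("mean", "sd")) ||
        !all(colnames(m) == .vocalid_features))
      stop("params$", ct, " must be a 2 x 14 mean/sd matrix like reference_call_params()")
    pr[[ct]] <- m
  }
  for (ct in names(pr))
    if (any(pr[[ct]]["sd", ] < 0)) stop("all SDs must be non-negative")
  structure(list(caller_class = caller_class, icc = icc,
                 year_drift_sd = year_drift_sd, n_harmonics = n_harmonics,
                 noise_snr_db = noise_snr_db, rolloff_db = rolloff_db,
                 params = pr),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec: %s, icc = %.2f, year drift = %.2f sd, snr = %g dB>\n",
              x$caller_class, x$icc, x$year_drift_sd, x$noise_snr_db))
  invisible(x)
}

## one draw from N(mean, sd) truncated above at `upper` (inverse-CDF method,
## deterministic under the active RNG state)
.rnorm_trunc_upper <- function(mean, sd, upper) {
  if (sd <= 0) return(min(mean, upper))
  p <- stats::runif(1L) * max(stats::pnorm(upper, mean, sd), 1e-12)
  min(stats::qnorm(p, mean, sd), upper)
}

## draw the f0 landmark trio honoring f0min <= f0beg <= f0max without biasing
## f0max or delta_f0: f0max from its marginal, then f0beg truncated below
## f0max, then f0min truncated below f0beg (the reference marginals overlap,
## so joint rejection would distort the means)
.draw_f0_trio <- function(mean, sd) {
  f0max <- stats::rnorm(1L, mean["f0max"], sd["f0max"])
  f0beg <- .rnorm_trunc_upper(mean["f0beg"], sd["f0beg"], f0max)
  f0min <- .rnorm_trunc_upper(mean["f0min"], sd["f0min"], f0beg)
  c(f0min = max(f0min, 1), f0beg = f0beg, f0max = f0max)
}

## enforce temporal/positivity constraints on one named feature vector
.constrain_latent <- function(mu) {
  if (mu["f0min"] > mu["f0beg"] || mu["f0beg"] > mu["f0max"])
    mu[c("f0min", "f0beg", "f0max")] <-
      sort(unname(mu[c("f0min", "f0beg", "f0max")]))
  mu["durat"] <- max(mu["durat"], 0.08)
  ## keep a resolvable falling segment after the f0 maximum (the reference
  ## calf values print dur_to_max > durat, which no contour can honor)
  up <- max(0.021, mu["durat"] - max(0.05, 0.2 * mu["durat"]))
  mu["dur_to_max"] <- min(max(mu["dur_to_max"], 0.02), up)
  mu["power_f0"] <- max(mu["power_f0"], 0)
  mu["peak_harm"] <- max(mu["peak_harm"], 1)
  mu["f0min"] <- max(mu["f0min"], 1)
  mu
}

#' Draw a population of individual vocal profiles
#'
#' Each individual receives, per call type, a latent mean vector for the 14
#' features drawn as `mean + sqrt(icc) * sd * z`, so that across many calls
#' the total feature variance splits into a fraction `icc` between individuals
#' and `1 - icc` within. Ordering constraints (`f0min <= f0beg <= f0max`,
#' `dur_to_max < durat`) are enforced by redraw.
#'
#' @param spec A [population_spec()].
#' @param n_individuals Number of individuals (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @param year Year label attached to generated metadata.
#' @return A `call_population`: list with `spec` and `profiles` (a list of
#'   `individual_profile` objects).
#' @export
make_population <- function(spec, n_individuals, seed = NULL, year = 2011L) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.numeric(n_individuals) || n_individuals < 1)
    stop("`n_individuals` must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  mass_ref <- .vocalid_mass[[spec$caller_class]]
  profiles <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    latent <- list()
    within_sd <- list()
    for (ct in names(spec$params)) {
      m <- spec$params[[ct]]
      lsd <- sqrt(spec$icc) * m["sd", ]
      mu <- m["mean", ] + lsd * stats::rnorm(ncol(m))
      names(mu) <- colnames(m)
      mu[c("f0min", "f0beg", "f0max")] <- .draw_f0_trio(m["mean", ], lsd)
      latent[[ct]] <- .constrain_latent(mu)
      within_sd[[ct]] <- sqrt(1 - spec$icc) * m["sd", ]
    }
    mass <- min(max(stats::rnorm(1L, mass_ref["mean"], mass_ref["sd"]),
                    mass_ref["min"]), mass_ref["max"])
    sex <- if (spec$caller_class == "calf")
      sample(c("male", "female"), 1L) else "female"
    profiles[[i]] <- structure(
      list(individual_id = sprintf("%s%02d", spec$caller_class, i),
           caller_class = spec$caller_class,
           sex = sex, body_mass_kg = mass, year = year,
           latent = latent, within_sd = within_sd,
           synth = spec[c("n_harmonics", "noise_snr_db", "rolloff_db")]),
      class = "individual_profile")
  }
  structure(list(spec = spec, profiles = profiles), class = "call_population")
}

#' Apply between-year drift to a population's latent means
#'
#' Adds an independent `N(0, (year_drift_sd * sd_feature)^2)` shift to every
#' individual's latent mean of every feature (the minimal mechanism for
#' between-year signature change), then re-enforces latent constraints.
#'
#' @param population A `call_population`.
#' @param year_drift_sd Drift scale (multiples of each feature's population
#'   SD); defaults to the value stored in the population's spec.
#' @param seed Optional integer seed.
#' @param year Year label for the drifted population's metadata.
#' @return A new `call_population` with shifted latent means.
#' @export
drift_population <- function(population, year_drift_sd = NULL, seed = NULL,
                             year = 2012L) {
  stopifnot(inherits(population, "call_population"))
  spec <- population$spec
  if (is.null(year_drift_sd)) year_drift_sd <- spec$year_drift_sd
  if (!is.null(seed)) set.seed(seed)
  out <- population
  for (i in seq_along(out$profiles)) {
    pr <- out$profiles[[i]]
    for (ct in names(pr$latent)) {
      m <- spec$params[[ct]]
      mu <- pr$latent[[ct]] + year_drift_sd * m["sd", ] * stats::rnorm(ncol(m))
      pr$latent[[ct]] <- .constrain_latent(mu)
    }
    pr$year <- year
    out$profiles[[i]] <- pr
  }
  out
}

## cosine-segment rise/fall contour through (0, f0beg), (t_max, f0max),
## (durat, f0end); zero slope at all three landmarks
.f0_contour_truth <- function(tt, durat, dur_to_max, f0beg, f0max, f0end) {
  f0 <- numeric(length(tt))
  up <- tt <= dur_to_max
  if (dur_to_max > 0)
    f0[up] <- f0beg + (f0max - f0beg) * (1 - cos(pi * tt[up] / dur_to_max)) / 2
  else f0[up] <- f0max
  down <- !up
  rest <- durat - dur_to_max
  if (rest > 0)
    f0[down] <- f0max + (f0end - f0max) *
      (1 - cos(pi * (tt[down] - dur_to_max) / rest)) / 2
  else f0[down] <- f0end
  f0
}

#' Synthesize one contact call
#'
#' Generates an additive harmonic stack whose fundamental follows a smooth
#' cosine-segment contour (rise from `f0beg` to `f0max` at `dur_to_max`, fall
#' to `f0min` at the call end). The spectral envelope places maximum energy on
#' the latent emphasized harmonic (`peak_harm`), with the f0 band
#' `power_f0` dB below it and a linear dB roll-off above. A 10 ms
#' raised-cosine onset/offset ramp avoids clicks; broadband Gaussian noise is
#' added at the spec's signal-to-noise ratio. Call-to-call jitter is drawn
#' from the profile's within-individual SDs.
#'
#' @param profile An `individual_profile` from [make_population()].
#' @param call_type `"oral"` or `"nasal"`.
#' @param seed Optional integer seed.
#' @param rate Synthesis sampling rate (Hz); 11025 matches the analysis rate
#'   so round-trip tests involve no resampling.
#' @param pad Leading/trailing quiet padding (s).
#' @return A `synth_call`: list with `wave` (a [waveform()]), `meta` (one-row
#'   data frame), `contour` (ground-truth time/f0 within the call), `onset`,
#'   `offset` (s) and `params` (the realized per-call parameters).
#' @export
synth_call <- function(profile, call_type = c("oral", "nasal"), seed = NULL,
                       rate = 11025, pad = 0.15) {
  stopifnot(inherits(profile, "individual_profile"))
  call_type <- match.arg(call_type)
  if (!call_type %in% names(profile$latent))
    stop("profile has no latent parameters for call type ", call_type)
  if (!is.null(seed)) set.seed(seed)
  mu <- profile$latent[[call_type]]
  ws <- profile$within_sd[[call_type]]
  if (mu["f0min"] > mu["f0beg"] || mu["f0beg"] > mu["f0max"] ||
      mu["f0min"] <= 0)
    stop("contour parameters violate f0min <= f0beg <= f0max")
  dv <- .synth_driver_vars
  val <- mu
  val[dv] <- mu[dv] + ws[dv] * stats::rnorm(length(dv))
  val[c("f0min", "f0beg", "f0max")] <- .draw_f0_trio(mu, ws)
  val["durat"] <- max(val["durat"], 0.08)
  up <- max(0.021, val["durat"] - max(0.05, 0.2 * val["durat"]))
  val["dur_to_max"] <- min(max(val["dur_to_max"], 0.02), up)
  val["power_f0"] <- max(val["power_f0"], 0)
  pk <- max(1L, as.integer(round(val["peak_harm"])))

  n <- as.integer(round(val["durat"] * rate))
  tt <- (seq_len(n) - 1L) / rate
  f0 <- .f0_contour_truth(tt, val["durat"], val["dur_to_max"],
                          val["f0beg"], val["f0max"], val["f0min"])
  phase <- 2 * pi * cumsum(f0) / rate
  kmax <- min(profile$synth$n_harmonics,
              as.integer(floor(0.98 * (rate / 2) / max(f0))))
  kmax <- max(kmax, 1L)
  pk_eff <- min(pk, kmax)
  amp_db <- numeric(kmax)
  for (k in seq_len(kmax)) {
    amp_db[k] <- if (k <= pk_eff) {
      if (pk_eff == 1L) 0 else -val["power_f0"] * (pk_eff - k) / (pk_eff - 1)
    } else {
      -profile$synth$rolloff_db * (k - pk_eff)
    }
  }
  amps <- 10^(amp_db / 20)
  ph0 <- stats::runif(kmax, 0, 2 * pi)
  s <- numeric(n)
  for (k in seq_len(kmax))
    s <- s + amps[k] * sin(k * phase + ph0[k])
  s <- 0.9 * s / max(abs(s))
  nr <- min(n, as.integer(round(0.010 * rate)))
  ramp <- (1 - cos(pi * seq_len(nr) / nr)) / 2
  s[seq_len(nr)] <- s[seq_len(nr)] * ramp
  s[(n - nr + 1L):n] <- s[(n - nr + 1L):n] * rev(ramp)

  npad <- as.integer(round(pad * rate))
  sig <- c(numeric(npad), s, numeric(npad))
  noise_sd <- sqrt(mean(s^2)) * 10^(-profile$synth$noise_snr_db / 20)
  sig <- sig + stats::rnorm(length(sig), 0, noise_sd)

  meta <- data.frame(
    call_id = NA_character_,
    individual_id = profile$individual_id,
    caller_class = profile$caller_class,
    call_type = call_type,
    sex = profile$sex,
    year = profile$year,
    body_mass_kg = profile$body_mass_kg,
    stringsAsFactors = FALSE
  )
  structure(list(
    wave = waveform(sig, rate),
    meta = meta,
    contour = data.frame(time = pad + tt, f0 = f0),
    onset = pad, offset = pad + val[["durat"]],
    params = c(as.list(val[dv]), list(peak_harm = pk_eff))
  ), class = "synth_call")
}

#' Synthesize a set of calls for a whole population
#'
#' @param population A `call_population`.
#' @param n_calls_per_type Calls per individual per call type.
#' @param call_types Call types to synthesize.
#' @param seed Optional integer seed; per-call seeds are derived from it.
#' @return List with `calls` (list of `synth_call`) and `meta` (data frame of
#'   their metadata, one row per call).
#' @export
synth_calls <- function(population, n_calls_per_type = 10,
                        call_types = c("oral", "nasal"), seed = NULL) {
  stopifnot(inherits(population, "call_population"))
  if (n_calls_per_type < 1) stop("`n_calls_per_type` must be positive")
  calls <- list()
  idx <- 0L
  for (pr in population$profiles) {
    for (ct in call_types) {
      for (j in seq_len(n_calls_per_type)) {
        idx <- idx + 1L
        cl <- synth_call(pr, ct, seed = .subseed(seed, idx))
        cl$meta$call_id <- sprintf("%s_%s_%02d", pr$individual_id, ct, j)
        calls[[idx]] <- cl
      }
    }
  }
  meta <- do.call(rbind, lapply(calls, `[[`, "meta"))
  rownames(meta) <- NULL
  list(calls = calls, meta = meta)
}

#' Sample a feature table directly from latent parameters
#'
#' Bypasses audio synthesis and extraction: draws feature rows as independent
#' normals around each individual's latent means with the within-individual
#' SDs, honoring the spec's `icc` variance split. Marginal means and SDs match
#' the population spec. Intended for fast statistical simulation (e.g.
#' discriminant-analysis power and null behavior).
#'
#' @param population A `call_population`.
#' @param n_calls_per_type Calls per individual per call type (>= 1; a single
#'   call per group triggers a warning since classification needs >= 2).
#' @param call_types Call types to sample.
#' @param seed Optional integer seed.
#' @return Data frame: metadata columns plus the 14 feature columns.
#' @export
sample_features_direct <- function(population, n_calls_per_type = 10,
                                   call_types = c("oral", "nasal"),
                                   seed = NULL) {
  stopifnot(inherits(population, "call_population"))
  if (length(population$profiles) == 0L) stop("population has no profiles")
  if (!is.numeric(n_calls_per_type) || n_calls_per_type < 1)
    stop("`n_calls_per_type` must be a positive count")
  if (n_calls_per_type < 2)
    warning("fewer than 2 calls per individual per type: discriminant analysis needs >= 2 rows per group")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  idx <- 0L
  for (pr in population$profiles) {
    for (ct in call_types) {
      mu <- pr$latent[[ct]]
      ws <- pr$within_sd[[ct]]
      X <- matrix(stats::rnorm(n_calls_per_type * length(mu)),
                  nrow = n_calls_per_type)
      X <- sweep(sweep(X, 2L, ws, `*`), 2L, mu, `+`)
      colnames(X) <- names(mu)
      idx <- idx + 1L
      rows[[idx]] <- cbind(
        data.frame(call_id = sprintf("%s_%s_%02d", pr$individual_id, ct,
                                     seq_len(n_calls_per_type)),
                   individual_id = pr$individual_id,
                   caller_class = pr$caller_class,
                   call_type = ct, sex = pr$sex, year = pr$year,
                   body_mass_kg = pr$body_mass_kg,
                   stringsAsFactors = FALSE),
        as.data.frame(X))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gaussian no-signal reference table
#'
#' Generates iid standard-normal feature rows with fixed group labels — the
#' reference design for chance-level simulation of label-permuted
#' classification (valid for arbitrary populations because linear discriminant
#' classification is affine-invariant).
#'
#' @param group_sizes Integer vector of per-group row counts (all >= 2).
#' @param n_vars Number of feature variables.
#' @param seed Optional integer seed.
#' @return Data frame with `individual_id` (factor-like labels g01, g02, ...)
#'   and columns `var01` ... .
#' @export
gaussian_null_table <- function(group_sizes, n_vars, seed = NULL) {
  if (any(group_sizes < 2)) stop("all group sizes must be at least 2")
  if (n_vars < 1) stop("`n_vars` must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- sum(group_sizes)
  X <- matrix(stats::rnorm(n * n_vars), nrow = n)
  colnames(X) <- sprintf("var%02d", seq_len(n_vars))
  out <- cbind(
    data.frame(individual_id = rep(sprintf("g%02d", seq_along(group_sizes)),
                                   group_sizes),
               stringsAsFactors = FALSE),
    as.data.frame(X))
  out
}

#' Draw group sizes within a range summing to a fixed total
#'
#' Sizes are drawn uniformly from `min_size:max_size` and then adjusted by
#' single-unit steps (staying within range) until they sum to `total` —
#' mirroring designs where per-group counts are known only as a range plus a
#' total.
#'
#' @param n_groups Number of groups.
#' @param min_size,max_size Per-group size range.
#' @param total Required sum.
#' @param seed Optional integer seed.
#' @return Integer vector of length `n_groups` summing to `total`.
#' @export
sample_group_sizes <- function(n_groups, min_size, max_size, total,
                               seed = NULL) {
  if (total < n_groups * min_size || total > n_groups * max_size)
    stop("total ", total, " infeasible for ", n_groups, " groups in [",
         min_size, ", ", max_size, "]")
  if (!is.null(seed)) set.seed(seed)
  s <- sample(min_size:max_size, n_groups, replace = TRUE)
  while (sum(s) != total) {
    step <- sign(total - sum(s))
    j <- sample(which(if (step > 0) s < max_size else s > min_size), 1L)
    s[j] <- s[j] + step
  }
  as.integer(s)
}

#' Write a synthetic call set as WAV files plus a sidecar CSV
#'
#' One 16-bit PCM WAV per call, and `calls.csv` holding the metadata,
#' ground-truth onset/offset and realized contour parameters (`durat`,
#' `dur_to_max`, `f0beg`, `f0max`, `f0min`, `power_f0`, `peak_harm`).
#'
#' @param calls List of `synth_call` objects (with `call_id` set, e.g. from
#'   [synth_calls()]).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the sidecar CSV path.
#' @export
write_call_set <- function(calls, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(calls, function(cl) {
    id <- cl$meta$call_id
    if (is.na(id)) stop("call has no call_id; use synth_calls() or set one")
    write_wav(cl$wave, file.path(dir, paste0(id, ".wav")))
    cbind(cl$meta, data.frame(onset = cl$onset, offset = cl$offset,
                              t(unlist(cl$params))))
  })
  sidecar <- do.call(rbind, rows)
  path <- file.path(dir, "calls.csv")
  utils::write.csv(sidecar, path, row.names = FALSE)
  invisible(path)
}
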