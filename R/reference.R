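## Reference population values (mean, SD) of the 14 acoustic variables for
## Iberian red deer hind and calf oral/nasal contact calls. These drive the
## default synthetic populations. Units: durations s, frequencies Hz,
## power_f0 dB, peak_harm harmonic order.

.vocalid_features <- c(
  "durat", "dur_to_max",
  "f0beg", "f0end", "f0max", "f0min", "f0mean", "delta_f0",
  "fpeak", "q25", "q50", "q75", "power_f0", "peak_harm"
)

.vocalid_dfa_vars <- c(
  "durat", "dur_to_max", "f0beg", "f0end", "f0max", "f0mean", "delta_f0",
  "q25", "q50", "q75", "power_f0"
)

.ref_row <- function(...) {
  v <- c(...)
  stopifnot(length(v) == 28L)
  m <- matrix(v, nrow = 2L)
  dimnames(m) <- list(c("mean", "sd"), .vocalid_features)
  m
}

.vocalid_reference <- list(
  hind = list(
    oral = .ref_row(
      0.759, 0.235,  0.230, 0.098,
      137, 33,  89, 19,  180, 31,  95, 18,  153, 25,  85, 26,
      1418, 555,  952, 285,  1731, 255,  2471, 252,  13.90, 5.76,  8.2, 3.3
    ),
    nasal = .ref_row(
      0.791, 0.253,  0.308, 0.138,
      128, 29,  89, 16,  173, 32,  93, 14,  148, 24,  80, 29,
      1060, 568,  713, 250,  1632, 257,  2534, 261,  5.38, 4.10,  6.1, 3.1
    )
  ),
  calf = list(
    oral = .ref_row(
      0.264, 0.080,  0.311, 0.078,
      773, 113,  518, 96,  875, 99,  554, 93,  778, 87,  321, 77,
      2973, 684,  1681, 506,  2987, 384,  3730, 238,  10.49, 5.67,  3.5, 0.9
    ),
    nasal = .ref_row(
      0.230, 0.039,  0.300, 0.133,
      695, 122,  481, 58,  781, 103,  512, 76,  694, 79,  269, 92,
      2289, 948,  1163, 387,  2488, 515,  3564, 395,  6.90, 6.98,  3.0, 1.3
    )
  )
)

## body mass (kg) of the animals entering the discriminant analyses
.vocalid_mass <- list(
  hind = c(mean = 104.8, sd = 12.2, min = 85.3, max = 121.5),
  calf = c(mean = 16.0, sd = 4.4, min = 10.0, max = 25.8)
)

#' Names of the 14 measured acoustic variables
#'
#' Two temporal variables (`durat`, `dur_to_max`), six fundamental-frequency
#' variables (`f0beg`, `f0end`, `f0max`, `f0min`, `f0mean`, `delta_f0`) and six
#' spectral-energy variables (`fpeak`, `q25`, `q50`, `q75`, `power_f0`,
#' `peak_harm`).
#'
#' @return Character vector of length 14.
#' @export
call_feature_names <- function() .vocalid_features

#' Default variable set for discriminant analysis
#'
#' The 11 of the 14 variables used for classification to individual: `fpeak`
#' and `peak_harm` are excluded as non-normal, and `f0min` because it is a
#' linear function of other included variables (`delta_f0 = f0max - f0min`).
#'
#' @return Character vector of length 11.
#' @export
dfa_default_vars <- function() .vocalid_dfa_vars

#' Reference call-variable distributions for red deer hinds and calves
#'
#' Population means and standard deviations of the 14 acoustic variables for
#' oral and nasal contact calls, used as the default parameterization of
#' [population_spec()].
#'
#' @param caller_class `"hind"` or `"calf"`.
#' @param call_type `"oral"` or `"nasal"`.
#' @return A 2 x 14 matrix with rows `mean` and `sd`, columns
#'   [call_feature_names()].
#' @export
#' @examples
#' reference_call_params("hind", "oral")["mean", "f0max"]  # 180 Hz
reference_call_params <- function(caller_class = c("hind", "calf"),
                                  call_type = c("oral", "nasal")) {
  caller_class <- match.arg(caller_class)
  call_type <- match.arg(call_type)
  .vocalid_reference[[caller_class]][[call_type]]
}

#' Pitch-tracking parameters by caller class
#'
#' Frame step and fundamental-frequency search range used for the f0 contour:
#' 0.01 s steps and 50--400 Hz for hinds, 0.005 s and 100--1200 Hz for calves.
#'
#' @param caller_class `"hind"` or `"calf"`.
#' @return List with `time_step` (s), `floor` and `ceiling` (Hz).
#' @export
pitch_params <- function(caller_class = c("hind", "calf")) {
  caller_class <- match.arg(caller_class)
  if (caller_class == "hind") {
    list(time_step = 0.01, floor = 50, ceiling = 400)
  } else {
    list(time_step = 0.005, floor = 100, ceiling = 1200)
  }
}

## deterministic sub-seed derivation, kept inside 32-bit integer range
.subseed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}
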