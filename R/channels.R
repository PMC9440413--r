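#' Channel specification table
#'
#' The 17 clinical variables of the standard 48-hour in-hospital-mortality
#' layout, one row per channel. Each channel carries the parameters both the
#' imputation step and the synthetic generator need:
#'
#' * `default_value` — the clinical fallback used when a cell has no prior
#'   measurement to carry forward (e.g. 59.0 mmHg for diastolic blood
#'   pressure, 7.4 for pH).
#' * `baseline_mean`, `baseline_sd` — population location/spread of the
#'   simulated measurements, in channel units.
#' * `event_rate` — expected measurement events per hour for the simulated
#'   charting process (vitals are near-hourly, labs sparse).
#' * `severity_coef` — how strongly the latent severity factor shifts the
#'   channel (sign encodes clinical direction: coma scores fall, heart rate
#'   rises in sicker patients).
#' * `is_static` — measured once per stay (weight, height).
#'
#' Categorical scales (Glasgow coma subscales, capillary refill) are encoded
#' numerically so that the value grid and mask are both plain 48 x 17
#' matrices.
#'
#' @return data.frame with 17 rows and columns `name`, `default_value`,
#'   `baseline_mean`, `baseline_sd`, `event_rate`, `severity_coef`,
#'   `is_static`.
#' @export
#' @examples
#' ch <- default_channel_table()
#' ch[ch$name == "Diastolic blood pressure", "default_value"]  # 59
default_channel_table <- function() {
  ch <- data.frame(
    name = c(
      "Capillary refill rate",
      "Diastolic blood pressure",
      "Fraction inspired oxygen",
      "Glascow coma scale eye opening",
      "Glascow coma scale motor response",
      "Glascow coma scale total",
      "Glascow coma scale verbal response",
      "Glucose",
      "Heart Rate",
      "Height",
      "Mean blood pressure",
      "Oxygen saturation",
      "pH",
      "Respiratory rate",
      "Systolic blood pressure",
      "Temperature",
      "Weight"
    ),
    default_value = c(0, 59, 0.21, 4, 6, 15, 5, 128, 86, 170, 77, 98,
                      7.4, 19, 118, 36.6, 81),
    baseline_mean = c(0.05, 59, 0.32, 3.5, 5.2, 12.5, 4, 140, 88, 170,
                      78, 96.5, 7.38, 19.5, 119, 37, 74),
    baseline_sd   = c(0.2, 10, 0.12, 0.8, 1, 2.5, 1.2, 40, 14, 10,
                      11, 2.5, 0.07, 4.5, 16, 0.7, 15),
    event_rate    = c(0.08, 1.0, 0.30, 0.25, 0.25, 0.25, 0.25, 0.15, 1.2,
                      0.02, 0.90, 1.1, 0.12, 1.1, 1.0, 0.35, 0.02),
    severity_coef = c(0.1, -5, 0.06, -0.5, -0.6, -1.5, -0.7, 20, 8, 0,
                      -5.5, -1.4, -0.035, 2.4, -8, 0.3, 0),
    is_static     = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                      FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                      FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  validate_channel_table(ch)
  ch
}

validate_channel_table <- function(channels) {
  stopifnot(is.data.frame(channels))
  needed <- c("name", "default_value", "baseline_mean", "baseline_sd",
              "event_rate", "severity_coef", "is_static")
  missing <- setdiff(needed, names(channels))
  if (length(missing)) {
    stop("channel table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(channels) != 17L) {
    stop("channel table must have exactly 17 channels, got ", nrow(channels),
         call. = FALSE)
  }
  if (!all(is.finite(channels$default_value))) {
    stop("channel default values must all be finite", call. = FALSE)
  }
  if (any(channels$event_rate <= 0)) stop("event rates must be > 0", call. = FALSE)
  if (any(channels$baseline_sd <= 0)) stop("baseline sd must be > 0", call. = FALSE)
  invisible(channels)
}

channel_index <- function(channels, name) {
  i <- match(name, channels$name)
  if (is.na(i)) stop("unknown channel: ", name, call. = FALSE)
  i
}
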