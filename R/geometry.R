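#' Reporter geometry
#'
#' Describes where the MS2 and PP7 stem-loop cassettes sit on the reporter
#' gene, in kb from the promoter (position 0) to the cleavage site at
#' `gene_length`.  The geometry is what maps an RNA polymerase position to a
#' fluorescent signal: a transcript contributes to a channel in proportion to
#' the fraction of that channel's cassette its polymerase has transcribed.
#'
#' The default values describe a synthetic stand-in for a 5.4 kb reporter with
#' a 5' MS2 cassette, a neutral spacer, and a 3' PP7 cassette; real construct
#' coordinates should be supplied from a run configuration.
#'
#' @param gene_length Total gene length in kb (promoter = 0, cleavage site =
#'   `gene_length`).
#' @param ms2_start,ms2_end kb positions of the MS2 stem-loop cassette.
#' @param pp7_start,pp7_end kb positions of the PP7 stem-loop cassette.
#'   `pp7_start` is the 5'-to-PP7 delay distance: the PP7 signal lags the MS2
#'   signal by `pp7_start / v_elon` minutes.
#' @return An object of class `tx_geometry`.
#' @examples
#' geom <- reporter_geometry()
#' geom
#' @export
reporter_geometry <- function(gene_length = 5.4,
                              ms2_start = 0, ms2_end = 1.3,
                              pp7_start = 4.0, pp7_end = 5.0) {
  vals <- c(gene_length, ms2_start, ms2_end, pp7_start, pp7_end)
  if (!all(is.finite(vals))) stop("geometry values must be finite")
  if (gene_length <= 0) stop("gene_length must be > 0")
  if (!(0 <= ms2_start && ms2_start <= ms2_end &&
        ms2_end <= pp7_start && pp7_start <= pp7_end &&
        pp7_end <= gene_length)) {
    stop("cassette positions must satisfy 0 <= ms2_start <= ms2_end <= ",
         "pp7_start <= pp7_end <= gene_length")
  }
  structure(
    list(gene_length = gene_length,
         ms2_start = ms2_start, ms2_end = ms2_end,
         pp7_start = pp7_start, pp7_end = pp7_end),
    class = "tx_geometry"
  )
}

#' @export
print.tx_geometry <- function(x, ...) {
  cat("<tx_geometry>\n")
  cat(sprintf("  gene length: %.3f kb\n", x$gene_length))
  cat(sprintf("  MS2 cassette: [%.3f, %.3f] kb\n", x$ms2_start, x$ms2_end))
  cat(sprintf("  PP7 cassette: [%.3f, %.3f] kb\n", x$pp7_start, x$pp7_end))
  invisible(x)
}

#' Transcription-cycle parameter set
#'
#' The full parameter vector of the forward model.  The loading rate is
#' `R(t) = r_mean + dR(t)`, where `dR(t)` interpolates linearly between values
#' at evenly spaced time knots (and is 0 outside the knot range), allowing
#' slight time dependence about the mean initiation rate.  Each loaded
#' polymerase elongates at the constant rate `v_elon`; on reaching the gene
#' end it waits the deterministic cleavage time `tau_cleave`, after which its
#' transcript — and the associated signal in both channels — is lost
#' instantly.
#'
#' Fluorescence units: one fully transcribed PP7 cassette defines 1 AU (PP7
#' channel); a fully transcribed MS2 cassette contributes `alpha` AU in the
#' MS2 channel, so `alpha` is the dimensionless mCherry/eGFP calibration
#' factor.
#'
#' @param r_mean Mean initiation rate \eqn{\langle R\rangle} (AU/min).
#' @param dr_knots Numeric vector of initiation-fluctuation values
#'   \eqn{\delta R} (AU/min) at the knot times.
#' @param v_elon Elongation rate (kb/min), > 0.
#' @param tau_cleave Cleavage time (min), >= 0.
#' @param t_on Transcription onset time after mitosis (min).
#' @param alpha MS2/PP7 calibration factor, > 0.
#' @param ms2_basal,pp7_basal Basal fluorescence per channel (AU), >= 0.
#' @param knot_times Times (min) of the `dr_knots`; defaults to an even grid
#'   over `knot_window`.
#' @param knot_window Length-2 window (min) used when `knot_times` is NULL.
#' @return An object of class `tx_params`.
#' @examples
#' transcription_params(r_mean = 15, v_elon = 1.7, tau_cleave = 2, t_on = 1,
#'                      alpha = 0.145)
#' @export
transcription_params <- function(r_mean, dr_knots = numeric(5), v_elon,
                                 tau_cleave, t_on = 0, alpha = 0.145,
                                 ms2_basal = 0, pp7_basal = 0,
                                 knot_times = NULL, knot_window = c(0, 18)) {
  if (is.null(knot_times)) {
    knot_times <- seq(knot_window[1], knot_window[2],
                      length.out = max(length(dr_knots), 2L))
    knot_times <- knot_times[seq_along(dr_knots)]
    if (length(dr_knots) == 1L) knot_times <- mean(knot_window)
  }
  if (length(knot_times) != length(dr_knots)) {
    stop("knot_times and dr_knots must have the same length")
  }
  p <- structure(
    list(r_mean = r_mean, dr_knots = dr_knots, v_elon = v_elon,
         tau_cleave = tau_cleave, t_on = t_on, alpha = alpha,
         ms2_basal = ms2_basal, pp7_basal = pp7_basal,
         knot_times = knot_times),
    class = "tx_params"
  )
  validate_params(p)
  p
}

validate_params <- function(p) {
  num <- c(p$r_mean, p$dr_knots, p$v_elon, p$tau_cleave, p$t_on, p$alpha,
           p$ms2_basal, p$pp7_basal)
  if (!all(is.finite(num))) stop("parameters must be finite")
  if (p$r_mean < 0) stop("r_mean must be >= 0")
  if (p$v_elon <= 0) stop("v_elon must be > 0")
  if (p$tau_cleave < 0) stop("tau_cleave must be >= 0")
  if (p$alpha <= 0) stop("alpha must be > 0")
  if (p$ms2_basal < 0 || p$pp7_basal < 0) stop("basal levels must be >= 0")
  if (any(p$r_mean + p$dr_knots < 0)) {
    stop("total initiation rate r_mean + dR must be >= 0 at every knot")
  }
  invisible(p)
}

#' @export
print.tx_params <- function(x, ...) {
  cat("<tx_params>\n")
  cat(sprintf("  <R> = %.3g AU/min, v_elon = %.3g kb/min, tau_cleave = %.3g min\n",
              x$r_mean, x$v_elon, x$tau_cleave))
  cat(sprintf("  t_on = %.3g min, alpha = %.3g, basal (MS2, PP7) = (%.3g, %.3g)\n",
              x$t_on, x$alpha, x$ms2_basal, x$pp7_basal))
  cat(sprintf("  dR knots (AU/min): %s\n",
              paste(signif(x$dr_knots, 3), collapse = ", ")))
  invisible(x)
}

# Flatten a tx_params into a named numeric vector for the sampler, and back.
params_to_vector <- function(p) {
  k <- length(p$dr_knots)
  v <- c(p$r_mean, p$dr_knots, p$v_elon, p$tau_cleave, p$t_on, p$alpha,
         p$ms2_basal, p$pp7_basal)
  names(v) <- c("r_mean", paste0("dr", seq_len(k)), "v_elon", "tau_cleave",
                "t_on", "alpha", "ms2_basal", "pp7_basal")
  v
}

vector_to_params <- function(v, template) {
  k <- length(template$dr_knots)
  p <- template
  p$r_mean <- v[[1]]
  p$dr_knots <- unname(v[1 + seq_len(k)])
  p$v_elon <- v[[k + 2]]
  p$tau_cleave <- v[[k + 3]]
  p$t_on <- v[[k + 4]]
  p$alpha <- v[[k + 5]]
  p$ms2_basal <- v[[k + 6]]
  p$pp7_basal <- v[[k + 7]]
  p
}

#' Assemble a single-cell trace tibble
#'
#' A trace is the observable: one cell's paired MS2 (mCherry) and PP7 (eGFP)
#' nascent-transcription fluorescence time series, with cell/embryo identity
#' and position along the embryo's anterior-posterior (AP) axis.  Missing
#' fluorescence values (no detected activity) are stored as `NA`.
#'
#' @param times Times in minutes since mitosis, strictly increasing.
#' @param ms2,pp7 Fluorescence values (AU of each channel); `NA` = missing.
#' @param cell_id,embryo_id Identifiers.
#' @param ap_position Fraction of embryo length in `[0, 1]`.
#' @return A tibble with columns `cell_id`, `embryo_id`, `ap_position`,
#'   `time_min`, `ms2_au`, `pp7_au`.
#' @export
tx_trace <- function(times, ms2, pp7, cell_id = "cell_1",
                     embryo_id = "embryo_1", ap_position = 0.3) {
  tr <- tibble(cell_id = as.character(cell_id),
               embryo_id = as.character(embryo_id),
               ap_position = as.numeric(ap_position),
               time_min = as.numeric(times),
               ms2_au = as.numeric(ms2), pp7_au = as.numeric(pp7))
  validate_trace(tr)
  tr
}

validate_trace <- function(tr) {
  need <- c("cell_id", "embryo_id", "ap_position", "time_min", "ms2_au", "pp7_au")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("trace is missing columns: ", paste(miss, collapse = ", "))
  for (id in unique(tr$cell_id)) {
    tt <- tr$time_min[tr$cell_id == id]
    if (any(diff(tt) <= 0)) stop("times must be strictly increasing within cell ", id)
  }
  fl <- c(tr$ms2_au, tr$pp7_au)
  if (any(fl[!is.na(fl)] < -1e-9)) stop("non-missing fluorescence must be >= 0")
  invisible(tr)
}

# Split a (possibly multi-cell) trace table into a named list of single-cell
# tibbles, times sorted.
split_cells <- function(traces) {
  validate_trace(traces)
  traces |>
    dplyr::arrange(.data$cell_id, .data$time_min) |>
    (\(d) split(d, d$cell_id))()
}
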