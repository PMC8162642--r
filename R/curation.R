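#' Pooled goodness of fit for a two-channel trace
#'
#' Coefficient of determination (R-squared) pooled over both channels after
#' rescaling the MS2 channel into PP7 units by `1 / alpha`:
#' `1 - SS_res / SS_tot`, where the total sum of squares is taken about the
#' pooled mean of the observed values.  Equals 1 for a perfect fit, 0 for a
#' fit no better than the pooled mean, and can be negative for worse fits.
#'
#' @param trace Observed single-cell trace tibble.
#' @param predicted Prediction tibble from [predict_traces()] on the same
#'   time grid.
#' @param alpha Calibration factor used to rescale the MS2 channel.
#' @return Scalar score <= 1.
#' @export
fit_quality <- function(trace, predicted, alpha = 1) {
  keep_m <- !is.na(trace$ms2_au)
  keep_p <- !is.na(trace$pp7_au)
  obs <- c(trace$ms2_au[keep_m] / alpha, trace$pp7_au[keep_p])
  fit <- c(predicted$ms2_au[keep_m] / alpha, predicted$pp7_au[keep_p])
  if (length(obs) < 2) stop("need at least 2 non-missing points")
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("zero total variance in observed trace")
  1 - sum((obs - fit)^2) / ss_tot
}

#' Flag bursting-like traces
#'
#' The constant-mean-rate model cannot produce deep signal troughs during the
#' ON period; telegraph-like ON/OFF switching (transcriptional bursting) can.
#' A cell is flagged when, after onset, the basal-subtracted observed signal
#' falls below `fraction` of its running maximum simultaneously in both
#' channels for a sustained window of at least `window_min` minutes.  Times
#' where the running maximum is still below `min_amplitude` of the channel's
#' final maximum are ignored, so the rise phase itself cannot trigger the
#' flag.
#'
#' @param trace Observed single-cell trace tibble spanning at least 5 min
#'   beyond `params$t_on`.
#' @param predicted Prediction tibble (unused by the default rule; kept so
#'   alternative rules can compare against the model).
#' @param params Posterior (or true) [transcription_params()]; supplies
#'   `t_on` and the basal levels.
#' @param fraction Trough threshold as a fraction of the running maximum.
#' @param window_min Minimal sustained trough duration (min).
#' @param min_amplitude Fraction of the final maximum the running maximum
#'   must reach before troughs are counted.
#' @return Logical flag.
#' @export
detect_bursting <- function(trace, predicted = NULL, params,
                            fraction = 0.3, window_min = 1,
                            min_amplitude = 0.2) {
  tt <- trace$time_min
  if (max(tt) - params$t_on < 5) stop("trace must span >= 5 min beyond t_on")
  on <- tt >= params$t_on
  rel_below <- function(obs, basal) {
    sig <- pmax(obs - basal, 0)
    sig[!on] <- NA
    run <- cummax(ifelse(is.na(sig), 0, sig))
    top <- max(run)
    established <- run >= min_amplitude * top & top > 0
    below <- sig < fraction * pmax(run, 1e-12)
    below[is.na(below)] <- FALSE
    below & established
  }
  both <- rel_below(trace$ms2_au, params$ms2_basal) &
    rel_below(trace$pp7_au, params$pp7_basal)
  if (!any(both)) return(FALSE)
  dt <- median(diff(tt))
  runs <- rle(both)
  max_run <- max(runs$lengths[runs$values], 0)
  max_run * dt >= window_min
}

#' Curate a population of per-cell inference results
#'
#' Automated post-inference filtering: accept cells whose fit quality is at
#' least `fit_threshold` and which are not flagged as bursting; report the
#' rejection reason for every other cell.  Also reports a non-enforced
#' acceptance-bias check comparing parameter means of the accepted subset
#' against all cells, in units of the standard error of the all-cell mean.
#'
#' @param results Tibble from [infer_cells()] (needs `cell_id`,
#'   `fit_quality`, `bursting` and the parameter-mean columns).
#' @param fit_threshold Minimal fit quality for acceptance.
#' @param params Parameter columns included in the bias check.
#' @return An object of class `tx_curation`: list with elements `cells`
#'   (per-cell tibble with `accepted` and `reason`), `summary` (counts), and
#'   `bias` (accepted-vs-all parameter means).
#' @export
curate <- function(results, fit_threshold = 0.8,
                   params = c("r_mean", "v_elon", "tau_cleave", "alpha")) {
  if (nrow(results) == 0) stop("results must be non-empty")
  cells <- results |>
    dplyr::mutate(
      fail_fit = .data$fit_quality < fit_threshold,
      fail_burst = isTRUE_vec(.data$bursting),
      accepted = !.data$fail_fit & !.data$fail_burst,
      reason = dplyr::case_when(
        .data$fail_fit & .data$fail_burst ~ "fit_quality;bursting",
        .data$fail_fit ~ "fit_quality",
        .data$fail_burst ~ "bursting",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select(dplyr::any_of(c("cell_id", "embryo_id", "ap_position")),
                  "fit_quality", "bursting", "accepted", "reason")
  summary <- tibble(
    n_total = nrow(cells),
    n_accepted = sum(cells$accepted),
    n_rejected_fit = sum(cells$reason %in% c("fit_quality", "fit_quality;bursting")),
    n_rejected_bursting = sum(cells$reason == "bursting", na.rm = TRUE),
    fraction_accepted = mean(cells$accepted)
  )
  params <- intersect(params, names(results))
  bias <- purrr::map_dfr(params, function(p) {
    all_v <- results[[p]]
    acc_v <- results[[p]][cells$accepted]
    sem <- sd(all_v) / sqrt(max(length(acc_v), 1))
    tibble(parameter = p, mean_all = mean(all_v),
           mean_accepted = mean(acc_v),
           shift_in_se = if (is.finite(sem) && sem > 0) {
             (mean(acc_v) - mean(all_v)) / sem
           } else 0)
  })
  structure(list(cells = cells, summary = summary, bias = bias),
            class = "tx_curation")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.tx_curation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<tx_curation> %d/%d cells accepted (%.0f%%); %d rejected on fit, %d on bursting\n",
              s$n_accepted, s$n_total, 100 * s$fraction_accepted,
              s$n_rejected_fit, s$n_rejected_bursting))
  invisible(x)
}

#' @rdname tidy-tx
#' @export
tidy.tx_curation <- function(x, ...) x$cells

#' @rdname tidy-tx
#' @export
glance.tx_curation <- function(x, ...) x$summary
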