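#' Cosine-template cycling score for one expression time course
#'
#' Correlates a series against phase-shifted cosine templates
#' `cos(2*pi*(t - phase)/period)` over a grid of periods and phases and
#' returns the best fit.  A gene is called cycling when the best Pearson
#' correlation reaches the cutoff.  Ties are broken deterministically in
#' favour of the smallest period, then the smallest phase.  A constant
#' series has an undefined correlation (`NA`) and is never cycling.
#'
#' @param series numeric expression values.
#' @param timepoints sampling times in hours, strictly increasing, same
#'   length as `series`; at least two full periods must be sampled.
#' @param periods candidate periods in hours (default 24).
#' @param phase_step phase grid step in hours (default 1).
#' @param cutoff correlation cutoff for the cycling call (default 0.8).
#' @return list with `best_r`, `best_period`, `best_phase`, `cycling`.
#' @export
cycling_score <- function(series, timepoints, periods = 24,
                          phase_step = 1, cutoff = 0.8) {
  stopifnot(length(series) == length(timepoints))
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  span <- max(timepoints) - min(timepoints)
  if (span < 2 * min(periods))
    stop("need at least two full periods of sampling")
  if (stats::sd(series) == 0)
    return(list(best_r = NA_real_, best_period = NA_real_,
                best_phase = NA_real_, cycling = FALSE))
  best <- list(best_r = -Inf, best_period = NA_real_, best_phase = NA_real_)
  for (P in sort(periods)) {
    for (phase in seq(0, P - phase_step, by = phase_step)) {
      templ <- cos(2 * pi * (timepoints - phase) / P)
      if (stats::sd(templ) == 0) next
      r <- stats::cor(series, templ)
      if (r > best$best_r + 1e-12) {
        best <- list(best_r = r, best_period = P, best_phase = phase)
      }
    }
  }
  best$cycling <- is.finite(best$best_r) && best$best_r >= cutoff
  best
}

#' Detect cycling genes across diurnal conditions
#'
#' Applies [cycling_score()] to every gene within every condition of a
#' diurnal experiment and summarises how many genes cycle in at least
#' one, and in all, conditions.
#'
#' @param values numeric matrix, genes x samples.
#' @param samples data.frame with one row per sample column, holding a
#'   `condition` label (e.g. LDHH/LDHC/LLHC) and a numeric `time` in
#'   hours.
#' @param cutoff correlation cutoff (default 0.8).
#' @param periods,phase_step template grid, see [cycling_score()].
#' @return list with `fits` (long data.frame: gene, condition, best_r,
#'   best_period, best_phase, cycling), `flags` (logical genes x
#'   conditions matrix) and `summary` (`n_any`, `n_all`).
#' @export
detect_cycling <- function(values, samples, cutoff = 0.8, periods = 24,
                           phase_step = 1) {
  stopifnot(all(c("condition", "time") %in% colnames(samples)),
            nrow(samples) == ncol(values))
  conds <- unique(as.character(samples$condition))
  fits <- list()
  flags <- matrix(FALSE, nrow(values), length(conds),
                  dimnames = list(rownames(values), conds))
  for (cond in conds) {
    sel <- which(samples$condition == cond)
    sel <- sel[order(samples$time[sel])]
    tp <- samples$time[sel]
    for (g in seq_len(nrow(values))) {
      fit <- cycling_score(values[g, sel], tp, periods, phase_step, cutoff)
      flags[g, cond] <- fit$cycling
      fits[[length(fits) + 1L]] <- data.frame(
        gene = rownames(values)[g] %||% g, condition = cond,
        best_r = fit$best_r, best_period = fit$best_period,
        best_phase = fit$best_phase, cycling = fit$cycling,
        stringsAsFactors = FALSE)
    }
  }
  list(fits = do.call(rbind, fits), flags = flags,
       summary = c(n_any = sum(rowSums(flags) >= 1),
                   n_all = sum(rowSums(flags) == length(conds))))
}
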