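# Monte Carlo PTA over the regimen grid and nomogram construction via the
# "PTA >= 90%" efficiency rule. PTA is computed on true (noise-free)
# simulated concentrations; residual error belongs to observed data only.

#' Monte Carlo PTA for a single scenario cell
#'
#' Samples `n` individuals from the population model, simulates the 24-h
#' concentration profiles without residual error, and computes the PTA:
#' for fractional targets (e.g. 40) the percentage of subjects with
#' %fT>MIC at or above the target; for the 100% target the percentage of
#' subjects with sustained exposure above the MIC (see
#' [sustained_above_mic()]).
#'
#' @param model A [population_model()].
#' @param regimen A [regimen()].
#' @param crrt CRRT stratum, 0 or 1.
#' @param mic MIC (mg/L).
#' @param target Target fraction of the window (40 or 100).
#' @param n Number of simulated subjects.
#' @param seed Optional integer seed.
#' @param grid_step Simulation grid spacing (h).
#' @return PTA in percent.
#' @export
pta_cell <- function(model, regimen, crrt, mic, target, n = 10000,
                     seed = NULL, grid_step = 0.05) {
  params <- sample_individuals(model, n, crrt, seed = seed)
  prof <- sim_profiles(params, regimen, grid_step)
  if (target >= 100 - 1e-9) {
    100 * mean(.sustained_above(prof$times, prof$conc, mic))
  } else {
    pta(100 * .time_above(prof$times, prof$conc, mic) /
          (max(prof$times) - min(prof$times)), target)
  }
}

#' Monte Carlo PTA over a regimen grid
#'
#' For each combination of regimen, CRRT stratum, MIC and target, samples
#' `n` individuals, simulates 24-h profiles and computes the PTA.
#' Deterministic given `seed`. Each cell also carries a Clopper-Pearson
#' 95% binomial confidence interval on the PTA; the nomogram threshold is
#' compared to the point estimate only.
#'
#' @param model A [population_model()].
#' @param regimens List of [regimen()] objects
#'   (default [build_regimen_grid()]).
#' @param mics MICs to evaluate (mg/L).
#' @param targets Target fractions (% of window).
#' @param strata CRRT strata.
#' @param n Simulated subjects per cell.
#' @param seed Optional integer seed.
#' @param grid_step Simulation grid spacing (h).
#' @return A `data.frame` with one row per
#'   (regimen, stratum, mic, target): columns `regimen`, `route`,
#'   `dose_mg`, `interval_h`, `infusion_h`, `crrt`, `mic`, `target`,
#'   `pta`, `pta_lo`, `pta_hi`, `n`, `seed`.
#' @export
run_pta_grid <- function(model, regimens = build_regimen_grid(),
                         mics = c(2, 8), targets = c(40, 100),
                         strata = c(0, 1), n = 10000, seed = NULL,
                         grid_step = 0.05) {
  stopifnot(inherits(model, "population_model"), n >= 1)
  rows <- list()
  with_seed(seed, {
    for (reg in regimens) {
      for (crrt in strata) {
        params <- sample_individuals(model, n, crrt)
        prof <- sim_profiles(params, reg, grid_step)
        window <- max(prof$times) - min(prof$times)
        for (mic in mics) {
          ta <- .time_above(prof$times, prof$conc, mic)
          ftm <- 100 * ta / window
          sust <- .sustained_above(prof$times, prof$conc, mic)
          for (target in targets) {
            p <- if (target >= 100 - 1e-9) 100 * mean(sust) else pta(ftm, target)
            k <- round(p / 100 * n)
            rows[[length(rows) + 1L]] <- data.frame(
              regimen = regimen_label(reg), route = reg$route,
              dose_mg = reg$dose, interval_h = reg$interval,
              infusion_h = reg$infusion_duration, crrt = crrt,
              mic = mic, target = target, pta = p,
              pta_lo = 100 * stats::qbeta(0.025, k, n - k + 1),
              pta_hi = 100 * stats::qbeta(0.975, k + 1, n - k),
              n = n, seed = if (is.null(seed)) NA_integer_ else seed)
          }
        }
      }
    }
  })
  do.call(rbind, rows)
}

# Standard regimens highlighted in the dosing tables: the usual-care
# intermittent schedules for preserved renal function (1-2 g q8h) and for
# CRRT (1 g q12h, 0.5 g q8h).
.is_standard <- function(route, dose, interval, crrt) {
  route == "II" & ifelse(crrt == 0,
                         interval == 8 & dose %in% c(1000, 2000),
                         (interval == 12 & dose == 1000) |
                           (interval == 8 & dose == 500))
}

#' Dosing nomogram from a PTA grid
#'
#' For each (stratum, MIC, target) cell, lists the regimens whose PTA
#' point estimate meets the threshold, ordered by total daily dose and
#' then by infusion burden (II < EI 3 h < EI 6 h < CI). Standard-of-care
#' intermittent regimens are flagged.
#'
#' @param pta_results Output of [run_pta_grid()] covering the complete
#'   grid.
#' @param threshold PTA threshold in percent (default 90, the efficiency
#'   criterion).
#' @return A `data.frame` with one row per recommended regimen per cell:
#'   columns `crrt`, `target`, `mic`, `regimen`, `route`, `dose_mg`,
#'   `interval_h`, `daily_dose_mg`, `pta`, `standard`, `rank`.
#' @export
recommend_regimens <- function(pta_results, threshold = 90) {
  req <- c("regimen", "route", "dose_mg", "interval_h", "infusion_h",
           "crrt", "mic", "target", "pta", "n")
  miss <- setdiff(req, names(pta_results))
  if (length(miss)) {
    stop("pta_results is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cells <- unique(pta_results[, c("crrt", "mic", "target")])
  n_reg <- length(unique(pta_results$regimen))
  counts <- stats::aggregate(list(k = pta_results$pta),
                             pta_results[, c("crrt", "mic", "target")], length)
  short <- counts[counts$k < n_reg, , drop = FALSE]
  if (nrow(short)) {
    stop("incomplete PTA grid in cells: ",
         paste(sprintf("crrt=%d mic=%g target=%g", short$crrt, short$mic,
                       short$target), collapse = "; "),
         call. = FALSE)
  }
  burden <- c(II = 1, EI3 = 2, EI6 = 3, CI = 4)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sub <- pta_results[pta_results$crrt == cell$crrt &
                         pta_results$mic == cell$mic &
                         pta_results$target == cell$target &
                         pta_results$pta >= threshold, , drop = FALSE]
    if (!nrow(sub)) next
    sub$daily_dose_mg <- sub$dose_mg * 24 / sub$interval_h
    ord <- order(sub$daily_dose_mg, burden[sub$route])
    sub <- sub[ord, , drop = FALSE]
    sub$standard <- .is_standard(sub$route, sub$dose_mg, sub$interval_h,
                                 sub$crrt)
    sub$rank <- seq_len(nrow(sub))
    out[[length(out) + 1L]] <-
      sub[, c("crrt", "target", "mic", "regimen", "route", "dose_mg",
              "interval_h", "daily_dose_mg", "pta", "standard", "rank")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
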