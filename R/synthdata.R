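# Synthetic sparse-sampling study generator. Emulates the design of the
# clinical PK study this model class comes from: ~13 adult subjects,
# 1 g meropenem q8h (q12h on CRRT) infused over 20 min, sampled pre-dose,
# at 0.5, 1, 3 and 6 h post dose and at trough, with lognormal
# interindividual variability, exponential residual error and a 0.1 mg/L
# lower limit of quantification. True individual parameters are recorded
# alongside the observations so estimation code can be checked by
# parameter recovery.

#' Study design for synthetic datasets
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param crrt_fraction Fraction of subjects on CRRT (dose rule: CRRT
#'   subjects receive 1 g q12h, others 1 g q8h, both infused over
#'   20 min).
#' @param offsets Nominal sampling offsets (h after each dose); a trough
#'   sample immediately before the next dose is always added, so the
#'   default gives 6 observations per subject per interval.
#' @param n_intervals Number of dosing intervals observed per subject.
#' @param jitter_sd SD (h) of the Gaussian jitter applied to post-dose
#'   sampling times, truncated to stay within the interval; emulates the
#'   deviation of actual from nominal sampling times.
#' @param lloq Lower limit of quantification (mg/L); observations below
#'   it are flagged BLQ.
#' @param dose_mg Dose per administration (mg).
#' @param trough_lead How long before the next dose the trough sample is
#'   drawn (h).
#' @param second_occasion If TRUE, each subject is observed on a second
#'   occasion (starting 48 h after the first block) with re-drawn CRRT
#'   status but the same individual random effects, emulating subjects
#'   sampled under two support configurations; no interoccasion
#'   variability is modeled.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_subjects = 13, crrt_fraction = 7 / 13,
                         offsets = c(0, 0.5, 1, 3, 6), n_intervals = 1,
                         jitter_sd = 0.1, lloq = 0.1, dose_mg = 1000,
                         trough_lead = 1 / 60, second_occasion = FALSE) {
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (crrt_fraction < 0 || crrt_fraction > 1) {
    stop("crrt_fraction must be in [0, 1]", call. = FALSE)
  }
  if (lloq < 0) stop("lloq must be >= 0", call. = FALSE)
  structure(list(n_subjects = n_subjects, crrt_fraction = crrt_fraction,
                 offsets = sort(unique(offsets)), n_intervals = n_intervals,
                 jitter_sd = jitter_sd, lloq = lloq, dose_mg = dose_mg,
                 trough_lead = trough_lead,
                 second_occasion = isTRUE(second_occasion)),
            class = "study_design")
}

#' Rich-sampling recovery design
#'
#' A denser variant used for parameter-recovery simulations: 8 sampling
#' points per interval over two observed intervals (16 observations per
#' subject), no pre-dose zero sample, default 40 subjects with half on
#' CRRT.
#'
#' @inheritParams study_design
#' @return A `study_design`.
#' @export
rich_design <- function(n_subjects = 40, crrt_fraction = 0.5,
                        jitter_sd = 0, lloq = 0.1) {
  study_design(n_subjects = n_subjects, crrt_fraction = crrt_fraction,
               offsets = c(1 / 3, 2 / 3, 1, 2, 3, 4.5, 6),
               n_intervals = 2, jitter_sd = jitter_sd, lloq = lloq)
}

# Observation times for one subject: per interval, the nominal offsets
# (pre-dose kept exact, post-dose jittered) plus a trough just before the
# next dose. Times are clamped inside (interval start, next dose).
.subject_times <- function(design, interval, t_offset = 0) {
  times <- numeric(0)
  for (k in seq_len(design$n_intervals) - 1L) {
    t0 <- t_offset + k * interval
    off <- design$offsets[design$offsets < interval]
    post <- off[off > 0]
    jit <- if (design$jitter_sd > 0) stats::rnorm(length(post), 0, design$jitter_sd) else 0
    post <- pmin(pmax(post + jit, 0.05), interval - design$trough_lead - 0.05)
    trough <- t0 + interval - design$trough_lead +
      if (design$jitter_sd > 0) min(0, stats::rnorm(1, 0, design$jitter_sd)) else 0
    times <- c(times, if (0 %in% off) t0 else numeric(0), t0 + sort(post),
               max(trough, t0 + interval / 2))
  }
  times
}

#' Generate a synthetic study dataset
#'
#' Samples individual parameters from the population model, simulates
#' true concentration profiles, evaluates them at (jittered) scheduled
#' sampling times, applies exponential residual error, and flags values
#' below the LLOQ. The returned object records the true individual
#' parameters for parameter-recovery testing.
#'
#' @param design A [study_design()].
#' @param model A [population_model()].
#' @param seed Optional integer seed (identical seeds give identical
#'   datasets).
#' @return An object of class `study_dataset`: a list with `data`
#'   (NONMEM-style rectangular `data.frame` with columns ID, TIME, AMT,
#'   RATE, DV, MDV, EVID, CRRT, BLQ), `subjects` (true parameters and
#'   random effects per subject), `design`, `model_name` and `seed`.
#' @export
generate_study <- function(design, model, seed = NULL) {
  stopifnot(inherits(design, "study_design"),
            inherits(model, "population_model"))
  with_seed(seed, {
    n <- design$n_subjects
    n_crrt <- round(n * design$crrt_fraction)
    crrt <- c(rep(1, n_crrt), rep(0, n - n_crrt))
    ind <- sample_individuals(model, n, crrt)
    ind$id <- seq_len(n)
    inf_dur <- 1 / 3
    rows <- list()
    for (i in seq_len(n)) {
      occs <- if (design$second_occasion) 2L else 1L
      p <- pk_params(ind$CL[i], ind$V1[i], ind$V2[i], ind$Q[i])
      crrt_occ <- ind$crrt[i]
      all_doses <- NULL
      obs <- list()
      for (o in seq_len(occs)) {
        if (o > 1L) {
          # second occasion: support status re-drawn, same etas
          crrt_occ <- stats::rbinom(1, 1, design$crrt_fraction)
          cl_o <- model$fixed$tvcl * model$fixed$theta_crrt^crrt_occ *
            exp(ind$eta_cl[i])
          p <- pk_params(cl_o, ind$V1[i], ind$V2[i], ind$Q[i])
        }
        interval <- if (crrt_occ == 1) 12 else 8
        t_offset <- (o - 1L) * (design$n_intervals * 12 + 48)
        starts <- t_offset + (seq_len(design$n_intervals) - 1L) * interval
        doses <- dose_events(starts, design$dose_mg, inf_dur)
        times <- .subject_times(design, interval, t_offset)
        true_conc <- concentration(p, doses, times)
        dv <- apply_residual(true_conc, model$random$sigma2)
        blq <- dv < design$lloq
        obs[[o]] <- data.frame(ID = ind$id[i], TIME = times, AMT = 0,
                               RATE = 0, DV = ifelse(blq, design$lloq, dv),
                               MDV = as.integer(blq), EVID = 0L,
                               CRRT = crrt_occ, BLQ = as.integer(blq))
        all_doses <- rbind(all_doses,
                           data.frame(ID = ind$id[i], TIME = doses$start_time,
                                      AMT = doses$amount,
                                      RATE = doses$amount / doses$duration,
                                      DV = 0, MDV = 1L, EVID = 1L,
                                      CRRT = crrt_occ, BLQ = 0L))
      }
      sub <- rbind(all_doses, do.call(rbind, obs))
      rows[[i]] <- sub[order(sub$TIME, sub$EVID), ]
    }
    data <- do.call(rbind, rows)
    rownames(data) <- NULL
    structure(list(data = data,
                   subjects = ind[, c("id", "crrt", "CL", "V1", "V2", "Q",
                                      "eta_cl", "eta_v2")],
                   design = design, model_name = model$name,
                   seed = seed),
              class = "study_dataset")
  })
}

#' @export
print.study_dataset <- function(x, ...) {
  nobs <- sum(x$data$EVID == 0)
  cat(sprintf("Synthetic PK study: %d subjects (%d on CRRT), %d observations (%d BLQ)\n",
              length(unique(x$data$ID)), sum(x$subjects$crrt == 1),
              nobs, sum(x$data$BLQ == 1)))
  invisible(x)
}

.dataset_cols <- c("ID", "TIME", "AMT", "RATE", "DV", "MDV", "EVID",
                   "CRRT", "BLQ")

#' Write / read a study dataset as a NONMEM-style CSV
#'
#' The rectangular format has columns ID, TIME, AMT, RATE, DV, MDV, EVID,
#' CRRT, BLQ; dose rows carry EVID = 1, MDV = 1; BLQ observations carry
#' DV at the LLOQ with the flag set. `read_dataset()` reconstructs a
#' `study_dataset` (without the true simulation parameters, which exist
#' only in memory).
#'
#' @param ds A `study_dataset`.
#' @param path CSV file path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   a `study_dataset`.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "study_dataset"))
  utils::write.csv(ds$data[, .dataset_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  data <- utils::read.csv(path)
  miss <- setdiff(.dataset_cols, names(data))
  if (length(miss)) {
    stop("malformed dataset: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  structure(list(data = data[, .dataset_cols], subjects = NULL,
                 design = NULL, model_name = NA_character_, seed = NULL),
            class = "study_dataset")
}
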