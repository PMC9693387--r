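# Dosing regimens and the simulation grid of the dosing study:
# intermittent (20-min), extended (3 h, 6 h) and continuous infusion of
# meropenem at the doses and intervals screened in the Monte Carlo runs.

.route_durations <- c(II = 1 / 3, EI3 = 3, EI6 = 6)

#' Meropenem dosing regimen
#'
#' @param dose Dose per administration (mg).
#' @param interval Dosing interval (h), typically 8 or 12.
#' @param route Infusion route label: `"II"` (intermittent, 20 min),
#'   `"EI3"` / `"EI6"` (extended, 3 or 6 h), or `"CI"` (continuous, i.e.
#'   infused over the full interval, back to back).
#' @param window Simulation window (h) counted from the first dose;
#'   defaults to 24 h.
#' @return An object of class `regimen`.
#' @examples
#' regimen(1000, 8, "II")   # 1 g q8h over 20 min
#' regimen(2000, 8, "EI6")  # 2 g q8h over 6 h
#' @export
regimen <- function(dose, interval, route = c("II", "EI3", "EI6", "CI"),
                    window = 24) {
  route <- match.arg(route)
  if (dose <= 0) stop("dose must be > 0", call. = FALSE)
  if (interval <= 0) stop("interval must be > 0", call. = FALSE)
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  duration <- if (route == "CI") interval else .route_durations[[route]]
  if (duration > interval) {
    stop("infusion duration exceeds the dosing interval", call. = FALSE)
  }
  structure(list(dose = dose, interval = interval, route = route,
                 infusion_duration = duration, window = window),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(regimen_label(x), "\n")
  invisible(x)
}

#' Dose events implied by a regimen
#'
#' One dose at time 0 and every `interval` hours until the end of the
#' simulation window (no loading dose).
#'
#' @param x A [regimen()] object.
#' @return A `data.frame` of dose events (see [dose_events()]).
#' @export
regimen_doses <- function(x) {
  stopifnot(inherits(x, "regimen"))
  starts <- seq(0, by = x$interval,
                length.out = ceiling(x$window / x$interval - 1e-9))
  dose_events(starts, x$dose, x$infusion_duration)
}

#' Human-readable regimen label
#'
#' @param x A [regimen()] object.
#' @return A string such as `"1 g q8h II"`.
#' @export
regimen_label <- function(x) {
  sprintf("%g g q%gh %s", x$dose / 1000, x$interval, x$route)
}

#' The simulated regimen grid
#'
#' Intermittent and extended (3 h, 6 h) infusions of 1 g q12h, 2 g q12h,
#' 0.5 g q8h, 1 g q8h and 2 g q8h, plus continuous q8h infusion of 0.5,
#' 1 and 2 g: 18 regimens in total, each simulated over a 24-h window
#' from the first dose.
#'
#' @param window Simulation window (h).
#' @return A list of [regimen()] objects of length 18.
#' @export
build_regimen_grid <- function(window = 24) {
  schedules <- list(c(1000, 12), c(2000, 12), c(500, 8), c(1000, 8), c(2000, 8))
  grid <- list()
  for (route in c("II", "EI3", "EI6")) {
    for (s in schedules) {
      grid[[length(grid) + 1L]] <- regimen(s[1], s[2], route, window)
    }
  }
  for (dose in c(500, 1000, 2000)) {
    grid[[length(grid) + 1L]] <- regimen(dose, 8, "CI", window)
  }
  names(grid) <- vapply(grid, regimen_label, character(1))
  grid
}
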