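#' Standardize test-day controls to a 210-day lactation yield
#'
#' Test-interval (Fleischmann) accumulation: the first control's daily
#' yield is carried back to kidding, consecutive controls contribute
#' trapezoids, and the last control's yield is carried forward to the end
#' of the covered period, `min(days_in_milk, horizon)`. Yield beyond the
#' horizon never contributes; a control interval crossing the horizon is
#' linearly interpolated at the horizon day. Component yields (fat,
#' protein, solids, lactose) are accumulated per interval from the
#' interval's milk kg times the mean component fraction, so
#' within-lactation composition drift is respected. Somatic cell count is
#' summarized as the milk-weighted mean over the covered intervals.
#'
#' @param controls data.frame with columns `control_date`, `daily_milk`
#'   (kg/day) and optionally `fat_pct`, `protein_pct`, `solids_pct`,
#'   `lactose_pct` (percent) and `scc` (cells/mL); one lactation of one
#'   goat.
#' @param kidding_date `Date` the lactation started.
#' @param days_in_milk total lactation length in days (defaults to the
#'   last control day, i.e. extend-to-last-control).
#' @param horizon standardization horizon in days (default 210).
#' @param extend if `TRUE` (default) the last control is extended to
#'   `min(days_in_milk, horizon)`; if `FALSE` accumulation stops at the
#'   last control.
#' @return one-row data.frame: `yield_210` columns `milk`, `fat`,
#'   `protein`, `solids`, `lactose` in kg, `scc` (cells/mL weighted mean),
#'   plus `n_controls` and `days_in_milk`.
#' @examples
#' ctl <- data.frame(control_date = as.Date("2020-01-01") + c(10, 40),
#'                   daily_milk = c(2, 3))
#' standardize_210(ctl, as.Date("2020-01-01"), days_in_milk = 70)
#' @export
standardize_210 <- function(controls, kidding_date, days_in_milk = NULL,
                            horizon = 210, extend = TRUE) {
  if (is.null(controls) || nrow(controls) == 0L) {
    stop("no controls supplied for this lactation")
  }
  day <- as.numeric(as.Date(controls$control_date) - as.Date(kidding_date))
  if (any(day <= 0)) stop("control dates must fall after kidding")
  o <- order(day)
  controls <- controls[o, , drop = FALSE]
  day <- day[o]
  if (anyDuplicated(day)) {
    warning("duplicate same-date controls: averaged")
    agg <- stats::aggregate(controls[setdiff(names(controls),
                                             "control_date")],
                            by = list(day = day), FUN = mean)
    day <- agg$day
    controls <- agg
  }
  if (all(day > horizon)) {
    stop("all controls fall after day ", horizon,
         ": lactation unusable for standardization")
  }
  keep <- day <= horizon
  # retain the first post-horizon control for interpolation at the horizon
  first_beyond <- which(!keep)[1L]
  use <- which(keep)
  if (!is.na(first_beyond)) use <- c(use, first_beyond)
  controls <- controls[use, , drop = FALSE]
  day <- day[use]

  if (is.null(days_in_milk)) days_in_milk <- max(day)
  end_day <- min(days_in_milk, horizon)

  comp <- c(fat = "fat_pct", protein = "protein_pct",
            solids = "solids_pct", lactose = "lactose_pct")
  comp <- comp[comp %in% names(controls)]
  has_scc <- "scc" %in% names(controls)

  milk <- 0
  compkg <- stats::setNames(numeric(length(comp)), names(comp))
  scc_wsum <- 0

  add_interval <- function(d0, d1, y0, y1, row0, row1) {
    if (d1 <= d0) return(invisible(NULL))
    kg <- (d1 - d0) * (y0 + y1) / 2
    milk <<- milk + kg
    for (cn in names(comp)) {
      f <- (controls[[comp[[cn]]]][row0] + controls[[comp[[cn]]]][row1]) / 2
      compkg[[cn]] <<- compkg[[cn]] + kg * f / 100
    }
    if (has_scc) {
      s <- (controls$scc[row0] + controls$scc[row1]) / 2
      scc_wsum <<- scc_wsum + kg * s
    }
    invisible(NULL)
  }

  y <- controls$daily_milk
  n <- length(day)
  # initial segment: kidding to first control at the first control's rate
  add_interval(0, min(day[1L], end_day), y[1L], y[1L], 1L, 1L)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      d0 <- day[i]; d1 <- day[i + 1L]
      if (d0 >= end_day) break
      if (d1 > end_day) {
        # interpolate the yield at the end day
        w <- (end_day - d0) / (d1 - d0)
        yi <- y[i] + w * (y[i + 1L] - y[i])
        # component fractions interpolate the same way through add_interval
        # midpoint; approximate with the segment mean at the cut
        kg <- (end_day - d0) * (y[i] + yi) / 2
        milk <- milk + kg
        for (cn in names(comp)) {
          f0 <- controls[[comp[[cn]]]][i]
          f1 <- controls[[comp[[cn]]]][i + 1L]
          f <- f0 + w * (f1 - f0)
          compkg[[cn]] <- compkg[[cn]] + kg * (f0 + f) / 2 / 100
        }
        if (has_scc) {
          s0 <- controls$scc[i]; s1 <- controls$scc[i + 1L]
          scc_wsum <- scc_wsum + kg * (s0 + (s0 + w * (s1 - s0))) / 2
        }
        break
      }
      add_interval(d0, d1, y[i], y[i + 1L], i, i + 1L)
    }
  }
  last_in <- max(which(day <= end_day))
  if (extend && day[last_in] < end_day &&
      (last_in == n || day[last_in + 1L] > end_day)) {
    # carry the last usable control forward only when no later control
    # bounded the tail (i.e. no interpolated segment was added)
    if (last_in == n) {
      add_interval(day[last_in], end_day, y[last_in], y[last_in],
                   last_in, last_in)
    }
  }

  out <- data.frame(milk = milk)
  for (cn in names(comp)) out[[cn]] <- compkg[[cn]]
  if (has_scc) out$scc <- if (milk > 0) scc_wsum / milk else NA_real_
  out$n_controls <- sum(day <= horizon)
  out$days_in_milk <- days_in_milk
  out
}

#' Standardize a whole control table
#'
#' Applies [standardize_210()] per goat and lactation.
#'
#' @param control_table data.frame with columns `goat`, `lactation`,
#'   `kidding_date`, `control_date`, `daily_milk` and optional component
#'   columns (see [standardize_210()]).
#' @param horizon,extend passed through.
#' @return data.frame with one row per goat-lactation, columns `goat`,
#'   `lactation`, the standardized trait columns, `n_controls`,
#'   `days_in_milk`.
#' @export
standardize_lactations <- function(control_table, horizon = 210,
                                   extend = TRUE) {
  sp <- split(control_table,
              list(control_table$goat, control_table$lactation),
              drop = TRUE)
  rows <- lapply(sp, function(d) {
    res <- standardize_210(d, d$kidding_date[1L], horizon = horizon,
                           extend = extend)
    cbind(data.frame(goat = d$goat[1L], lactation = d$lactation[1L],
                     stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$goat, out$lactation), , drop = FALSE]
}
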