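#' Evaluate a readout on a time course
#'
#' A readout is a named sum of species trajectories (several complexes may
#' carry the same phospho-form). Values are clamped at zero in the readout
#' only — never inside the integrator — so small negative excursions within
#' solver tolerance do not propagate into summaries.
#'
#' @param tc An `sbn_timecourse`.
#' @param readout Either a readout name resolved through `map` or a
#'   character vector of member species ids.
#' @param map Name map used when `readout` is a canonical name (see
#'   [default_name_map()]).
#' @return Object of class `sbn_series`: `name`, `time`, `value`.
#' @export
evaluate_readout <- function(tc, readout, map = default_name_map()) {
  stopifnot(inherits(tc, "sbn_timecourse"))
  if (length(readout) == 1L && readout %in% names(map)) {
    members <- tc$species_ids[grepl(map[[readout]], tc$species_ids)]
    name <- readout
  } else {
    members <- readout
    name <- paste(readout, collapse = "+")
  }
  missing <- setdiff(members, tc$species_ids)
  if (length(missing) || length(members) == 0L)
    stop("readout '", name, "': missing species ",
         paste(if (length(missing)) missing else "(none resolved)", collapse = ", "),
         call. = FALSE)
  v <- colSums(tc$values[members, , drop = FALSE])
  structure(list(name = name, time = tc$times, value = pmax(v, 0)),
            class = "sbn_series")
}

#' @export
print.sbn_series <- function(x, ...) {
  cat(sprintf("<sbn_series '%s'> %d points, max %.4g at t = %.4g s\n",
              x$name, length(x$time), max(x$value), peak_time(x)))
  invisible(x)
}

#' Peak time of a readout series
#'
#' Time of the global maximum. The discrete maximum is refined by quadratic
#' interpolation through the three surrounding grid points, decoupling the
#' estimate from the output-grid spacing; ties are broken by the earliest
#' time. A maximum attained at the end of the window is flagged
#' `non_interior`; an all-zero series is flagged `zero_amplitude` and
#' returns the window start.
#'
#' @param series An `sbn_series` (or any list with `time` and `value`).
#' @return Numeric peak time in seconds, with attributes `peak_value`,
#'   `non_interior`, `zero_amplitude`.
#' @export
peak_time <- function(series) {
  tt <- series$time; vv <- series$value
  if (!length(tt)) stop("empty series", call. = FALSE)
  if (all(vv == 0))
    return(structure(tt[1L], peak_value = 0,
                     non_interior = FALSE, zero_amplitude = TRUE))
  k <- which.max(vv)             # which.max takes the earliest of ties
  non_interior <- k == 1L || k == length(vv)
  t_peak <- tt[k]
  if (!non_interior) {
    # vertex of the parabola through the three points around the maximum
    h1 <- tt[k] - tt[k - 1L]; h2 <- tt[k + 1L] - tt[k]
    d1 <- (vv[k] - vv[k - 1L]) / h1      # secant slope, left interval
    d2 <- (vv[k + 1L] - vv[k]) / h2      # secant slope, right interval
    a <- (d2 - d1) / (h1 + h2)
    b <- d1 + a * h1
    if (a < 0) {
      t_peak <- tt[k] - b / (2 * a)
      t_peak <- min(max(t_peak, tt[k - 1L]), tt[k + 1L])
    }
  }
  structure(t_peak, peak_value = vv[k],
            non_interior = non_interior, zero_amplitude = FALSE)
}

#' Time to half-maximum of a readout series
#'
#' First upward crossing of half the peak value, located by linear
#' interpolation between grid points. Always at or before the peak time.
#'
#' @param series An `sbn_series`.
#' @return Crossing time in seconds, or `NA` with attribute
#'   `reached = FALSE` if the series never reaches half its maximum (e.g. it
#'   starts above it, or is identically zero).
#' @export
time_to_half_max <- function(series) {
  tt <- series$time; vv <- series$value
  vmax <- max(vv)
  if (vmax == 0) return(structure(NA_real_, reached = FALSE))
  half <- vmax / 2
  if (vv[1L] >= half) {
    # already above half-maximum at the window start
    return(structure(tt[1L], reached = TRUE))
  }
  k <- which(vv >= half)[1L]
  if (is.na(k)) return(structure(NA_real_, reached = FALSE))
  frac <- (half - vv[k - 1L]) / (vv[k] - vv[k - 1L])
  structure(tt[k - 1L] + frac * (tt[k] - tt[k - 1L]), reached = TRUE)
}

#' Area under a readout series
#'
#' Trapezoidal integral over a time window (concentration * s).
#'
#' @param series An `sbn_series`.
#' @param window Length-2 numeric window; defaults to the full series.
#' @return Non-negative numeric.
#' @export
auc <- function(series, window = range(series$time)) {
  keep <- series$time >= window[1L] & series$time <= window[2L]
  tt <- series$time[keep]; vv <- series$value[keep]
  if (length(tt) < 2L) return(0)
  sum(diff(tt) * (utils::head(vv, -1L) + utils::tail(vv, -1L)) / 2)
}

#' Kinetic summary of one readout
#'
#' @param series An `sbn_series`.
#' @return Data frame with `readout`, `peak_time`, `peak_value`,
#'   `time_to_half_max`, `auc` and the `non_interior` flag.
#' @export
kinetic_summary <- function(series) {
  pt <- peak_time(series)
  data.frame(
    readout = series$name,
    peak_time = as.numeric(pt),
    peak_value = attr(pt, "peak_value"),
    time_to_half_max = as.numeric(time_to_half_max(series)),
    auc = auc(series),
    non_interior = attr(pt, "non_interior"),
    stringsAsFactors = FALSE)
}

#' Cross-scenario comparison table
#'
#' Summarises every requested readout in every scenario run (peak time and
#' value, time to half-maximum, AUC) and derives per-readout ordering flags:
#' which scenario peaks highest, which earliest. Permutation-invariant in
#' the order of `runs`.
#'
#' @param runs Named list of `sbn_timecourse` objects; names are scenario
#'   labels (at least two).
#' @param readouts Character vector of canonical readout names.
#' @param map Name map (see [default_name_map()]).
#' @return Data frame of class `sbn_comparison` (one row per readout x
#'   scenario) with attribute `orderings`.
#' @export
compare_scenarios <- function(runs, readouts = names(default_name_map()),
                              map = default_name_map()) {
  if (is.null(names(runs)) || length(runs) < 2L)
    stop("runs must be a named list of at least two scenarios", call. = FALSE)
  runs <- runs[sort(names(runs))]
  rows <- list()
  for (sc in names(runs)) {
    for (rd in readouts) {
      s <- evaluate_readout(runs[[sc]], rd, map)
      row <- kinetic_summary(s)
      row$scenario <- sc
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[, c("readout", "scenario", "peak_time", "peak_value",
                 "time_to_half_max", "auc", "non_interior")]
  orderings <- do.call(rbind, lapply(readouts, function(rd) {
    sub <- tab[tab$readout == rd, ]
    pv <- stats::setNames(sub$peak_value, sub$scenario)
    pt <- stats::setNames(sub$peak_time, sub$scenario)
    data.frame(
      readout = rd,
      highest_peak = if (max(pv) == min(pv)) "tie" else names(which.max(pv)),
      earliest_peak = if (max(pt) == min(pt)) "tie" else names(which.min(pt)),
      stringsAsFactors = FALSE)
  }))
  structure(tab, orderings = orderings, class = c("sbn_comparison", "data.frame"))
}

#' @export
print.sbn_comparison <- function(x, ...) {
  print.data.frame(x, digits = 4, row.names = FALSE)
  cat("\nOrderings:\n")
  print.data.frame(attr(x, "orderings"), row.names = FALSE)
  invisible(x)
}

comparison_cell <- function(table, readout, scenario, what) {
  v <- table[table$readout == readout & table$scenario == scenario, what]
  if (length(v) != 1L)
    stop("comparison table is missing ", readout, " / ", scenario, call. = FALSE)
  v
}

#' The shipped qualitative check set
#'
#' Named definitions of the cross-scenario orderings the follicle models are
#' expected to show: higher peaks in DF than SF for the nine activation
#' readouts of both cascades, later (lagging) peaks in SF for the
#' receptor-proximal and cascade readouts, the SF > DF > DF+miRNA ordering
#' of total MYC, SF above DF for phospho-MYC, and near-overlap of the DF and
#' DF+miRNA curves for ppMEK/ppERK.
#'
#' @return Data frame with columns `check`, `type`, `readout`, plus
#'   type-specific fields.
#' @export
default_check_set <- function() {
  higher <- c("ppMEK", "ppERK", "pAkt", "pIRS1", "PI3K", "pCREB", "pMcl1",
              "pmTORC1", "pEIF4EBP1")
  lagging <- c("RasGTP", "Raf1_active", "ppMEK", "ppERK", "pmTORC1", "pEIF4EBP1")
  overlap <- c("ppMEK", "ppERK")
  rbind(
    data.frame(check = paste0("DF_above_SF_", higher), type = "peak_higher",
               readout = higher, a = "DF", b = "SF", stringsAsFactors = FALSE),
    data.frame(check = paste0("SF_lags_DF_", lagging), type = "peak_later",
               readout = lagging, a = "SF", b = "DF", stringsAsFactors = FALSE),
    data.frame(check = "MYC_total_SF_DF_DFmiR", type = "monotone_peak",
               readout = "MYC_total", a = "SF", b = "DF", stringsAsFactors = FALSE),
    data.frame(check = "pMYC_SF_above_DF", type = "peak_higher",
               readout = "pMYC", a = "SF", b = "DF", stringsAsFactors = FALSE),
    data.frame(check = paste0("DF_overlap_DFmiR_", overlap), type = "overlap",
               readout = overlap, a = "DF", b = "DF_miRNA", stringsAsFactors = FALSE))
}

#' Check the expected cross-scenario orderings
#'
#' Evaluates the shipped check set (see [default_check_set()]) against a
#' comparison table and, for the overlap and MYC-ordering checks, the
#' underlying runs. Failures are reported, never raised.
#'
#' `overlap` is quantified as the maximum absolute gap between the two
#' scenarios' readout curves relative to the first scenario's peak
#' amplitude, passing when below `overlap_tol` (default 5%).
#'
#' @param table An `sbn_comparison` from [compare_scenarios()].
#' @param runs The named list of time courses the table came from (needed
#'   for overlap and late-time MYC checks; optional otherwise).
#' @param checks Check-set data frame; defaults to [default_check_set()].
#' @param overlap_tol Relative overlap tolerance.
#' @param map Name map.
#' @return Data frame `check`, `pass`, `detail` of class `sbn_checks`.
#' @export
qualitative_check <- function(table, runs = NULL, checks = default_check_set(),
                              overlap_tol = 0.05, map = default_name_map()) {
  res <- lapply(seq_len(nrow(checks)), function(i) {
    ck <- checks[i, ]
    out <- switch(
      ck$type,
      peak_higher = {
        va <- comparison_cell(table, ck$readout, ck$a, "peak_value")
        vb <- comparison_cell(table, ck$readout, ck$b, "peak_value")
        list(pass = va > vb, detail = sprintf("%s peak %.4g vs %s %.4g",
                                              ck$a, va, ck$b, vb))
      },
      peak_later = {
        ta <- comparison_cell(table, ck$readout, ck$a, "peak_time")
        tb <- comparison_cell(table, ck$readout, ck$b, "peak_time")
        list(pass = ta > tb, detail = sprintf("%s peak at %.1f s vs %s %.1f s",
                                              ck$a, ta, ck$b, tb))
      },
      monotone_peak = {
        if (is.null(runs)) {
          list(pass = NA, detail = "runs required for late-time MYC check")
        } else {
          lev <- vapply(c("SF", "DF", "DF_miRNA"), function(sc) {
            s <- evaluate_readout(runs[[sc]], ck$readout, map)
            s$value[length(s$value)]
          }, numeric(1))
          list(pass = lev[["SF"]] > lev[["DF"]] && lev[["DF"]] > lev[["DF_miRNA"]],
               detail = sprintf("late-time MYC SF %.4g / DF %.4g / DF+miR %.4g",
                                lev[["SF"]], lev[["DF"]], lev[["DF_miRNA"]]))
        }
      },
      overlap = {
        if (is.null(runs)) {
          list(pass = NA, detail = "runs required for overlap check")
        } else {
          sa <- evaluate_readout(runs[[ck$a]], ck$readout, map)
          sb <- evaluate_readout(runs[[ck$b]], ck$readout, map)
          gap <- max(abs(sa$value - sb$value)) / max(sa$value)
          list(pass = gap <= overlap_tol,
               detail = sprintf("max relative gap %.2f%% (tol %.0f%%)",
                                100 * gap, 100 * overlap_tol))
        }
      },
      stop("unknown check type: ", ck$type))
    data.frame(check = ck$check, pass = out$pass, detail = out$detail,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, res), class = c("sbn_checks", "data.frame"))
}

#' @export
print.sbn_checks <- function(x, ...) {
  status <- ifelse(is.na(x$pass), "NA  ", ifelse(x$pass, "PASS", "FAIL"))
  cat(sprintf("%s  %-28s %s\n", status, x$check, x$detail), sep = "")
  cat(sprintf("%d / %d checks pass\n", sum(x$pass, na.rm = TRUE),
              sum(!is.na(x$pass))))
  invisible(x)
}

#' Serialize / restore a check set
#'
#' @param checks Check-set data frame.
#' @param path YAML file path.
#' @return `path` invisibly, or the restored data frame.
#' @export
write_check_set <- function(checks, path) {
  yaml::write_yaml(lapply(seq_len(nrow(checks)), function(i) as.list(checks[i, ])),
                   path)
  invisible(path)
}

#' @rdname write_check_set
#' @export
read_check_set <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(rbind, lapply(lst, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
}

#' Three-scenario comparison plot for one readout
#'
#' Line plot mirroring the standard three-line layout: SF blue, DF black,
#' DF+miRNA red.
#'
#' @param runs Named list of time courses with scenarios as names.
#' @param readout Canonical readout name.
#' @param map Name map.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_readout_comparison <- function(runs, readout, map = default_name_map(), ...) {
  cols <- c(SF = "blue", DF = "black", DF_miRNA = "red")
  series <- lapply(runs, evaluate_readout, readout = readout, map = map)
  ymax <- max(vapply(series, function(s) max(s$value), numeric(1)))
  graphics::plot(NULL, xlim = range(series[[1L]]$time), ylim = c(0, ymax * 1.05),
                 xlab = "time (s)", ylab = "concentration (a.u.)",
                 main = readout, ...)
  for (sc in names(runs))
    graphics::lines(series[[sc]]$time, series[[sc]]$value,
                    col = cols[[sc]], lwd = 2)
  graphics::legend("topright", legend = names(runs), col = cols[names(runs)],
                   lwd = 2, bty = "n")
  invisible(series)
}
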