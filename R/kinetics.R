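#' Stage schemes
#'
#' The oxidation course is partitioned into stages by ordered day
#' breakpoints; the default `c(0, 8, 11, 14, 16)` reflects the four
#' successive regimes of linoleic-group degradation (slow, moderate, fastest,
#' still fast). A shared breakpoint day belongs to both adjacent stages, so
#' "from day 8 to day 11" means both endpoints inclusive.
#'
#' @param breakpoints strictly increasing numeric vector of days.
#' @return object of class `stage_scheme`.
#' @export
stage_scheme <- function(breakpoints = c(0, 8, 11, 14, 16)) {
  if (length(breakpoints) < 2L || is.unsorted(breakpoints, strictly = TRUE))
    stop("breakpoints must be strictly increasing with length >= 2")
  structure(list(breakpoints = as.numeric(breakpoints)), class = "stage_scheme")
}

stage_labels <- function(scheme) {
  b <- scheme$breakpoints
  paste0("d", b[-length(b)], "_", b[-1])
}

#' Per-stage degradation/formation rates
#'
#' Ordinary least-squares slope of concentration against day within each
#' stage interval (endpoints inclusive on both sides). Rates are signed:
#' negative means degradation. A stage with fewer than two observations gets
#' `NA` rather than an error.
#'
#' @param day,conc numeric vectors of equal length (days, mmol/mol TG).
#' @param scheme a [stage_scheme()].
#' @return named numeric of slopes in mmol/mol TG per day, one per stage.
#' @export
stage_rates <- function(day, conc, scheme = stage_scheme()) {
  if (length(day) != length(conc)) stop("day and conc lengths differ")
  b <- scheme$breakpoints
  out <- stats::setNames(rep(NA_real_, length(b) - 1L), stage_labels(scheme))
  for (k in seq_len(length(b) - 1L)) {
    i <- which(day >= b[k] & day <= b[k + 1L] & !is.na(conc))
    if (length(i) < 2L) next
    out[k] <- unname(stats::coef(stats::lm(conc[i] ~ day[i]))[2])
  }
  out
}

#' Detect appearance, maximum and disappearance events in a series
#'
#' Appearance is the first sampled day with concentration above the
#' detection limit; the maximum tie-breaks to the earliest day;
#' disappearance is the first day after appearance at which the series drops
#' back to or below the limit.
#'
#' @param day,conc numeric vectors (a sampled time course).
#' @param lod detection limit, mmol/mol TG.
#' @return list with `appearance_day`, `max_day`, `max_value`,
#'   `disappeared_day` (days are `NA` when the event never happens).
#' @export
detect_events <- function(day, conc, lod = 0.1) {
  if (!length(day)) stop("empty series")
  o <- order(day); day <- day[o]; conc <- conc[o]
  above <- which(conc > lod)
  if (!length(above))
    return(list(appearance_day = NA_real_, max_day = NA_real_,
                max_value = max(conc), disappeared_day = NA_real_))
  app <- day[above[1]]
  imax <- which.max(conc)           # earliest day on ties
  gone <- which(day > app & conc <= lod)
  list(appearance_day = app,
       max_day = day[imax],
       max_value = conc[imax],
       disappeared_day = if (length(gone)) day[gone[1]] else NA_real_)
}

#' Formation fraction of a product relative to a degrading substrate
#'
#' Within one stage, 100 x (product formation rate) / |substrate degradation
#' rate|: the share of the substrate loss (in mmol/mol TG per day) that the
#' product accounts for. The complement is the share going to other products.
#'
#' @param product_day,product_conc product series.
#' @param substrate_day,substrate_conc substrate series; must be decreasing
#'   over the stage.
#' @param stage numeric length-2, the stage interval in days.
#' @return percentage (possibly > 100 if stoichiometry differs); `NA` if the
#'   substrate rate is zero/undefined.
#' @export
formation_fraction <- function(product_day, product_conc,
                               substrate_day, substrate_conc,
                               stage) {
  sch <- stage_scheme(stage)
  pr <- stage_rates(product_day, product_conc, sch)[1]
  sr <- stage_rates(substrate_day, substrate_conc, sch)[1]
  if (is.na(sr) || sr == 0) return(NA_real_)
  if (sr > 0) stop("substrate is not degrading over the stage (rate ",
                   format(sr), " > 0)")
  i <- which(substrate_day >= stage[1] & substrate_day <= stage[2])
  if (length(i) >= 2 && any(diff(substrate_conc[order(substrate_day[i])]) >= 0))
    warning("substrate series is not strictly decreasing over the stage")
  unname(100 * pr / abs(sr))
}

#' Convert acyl molar percentage to mmol/mol TG
#'
#' A triglyceride carries three acyl chains, so `pct` molar percent of all
#' acyl groups equals `pct * 3 * 1000 / 100` mmol per mol of triglyceride.
#'
#' @param pct molar percentage of total acyl groups, in `[0, 100]`.
#' @return concentration in mmol/mol TG.
#' @export
percent_to_mmol <- function(pct) {
  if (any(pct < 0 | pct > 100)) stop("molar percentage must lie in [0, 100]")
  pct * 3 * 1000 / 100
}

#' Stage-wise kinetics summary of a concentration time course
#'
#' For every compound column of a concentration table, computes the
#' appearance day, the day and value of the maximum, the disappearance day
#' and the per-stage OLS rates. Individual compounds can be assigned their
#' own stage scheme (gamma-tocopherol's two-stage degradation by default).
#'
#' @param table a `concentration_table` (day column plus compound columns).
#' @param scheme default [stage_scheme()].
#' @param lod detection limit, mmol/mol TG.
#' @param schemes_override named list of per-compound stage schemes; default
#'   assigns `stage_scheme(c(0, 2, 11))` to the `gT` column.
#' @return object of class `oxidation_kinetics` with data frames `events`
#'   and `rates`.
#' @export
oxidation_kinetics <- function(table, scheme = stage_scheme(), lod = 0.1,
                               schemes_override = list(gT = stage_scheme(c(0, 2, 11)))) {
  if (!"day" %in% names(table)) stop("table needs a 'day' column")
  if (nrow(table) < 2L) stop("kinetics needs at least two days")
  ids <- setdiff(names(table), "day")
  ev <- list(); rt <- list()
  for (id in ids) {
    e <- detect_events(table$day, table[[id]], lod)
    sch <- schemes_override[[id]] %||% scheme
    r <- stage_rates(table$day, table[[id]], sch)
    ev[[id]] <- data.frame(compound_id = id,
                           appearance_day = e$appearance_day,
                           max_day = e$max_day, max_value = e$max_value,
                           disappeared_day = e$disappeared_day,
                           stringsAsFactors = FALSE)
    rt[[id]] <- data.frame(compound_id = id, stage = names(r),
                           rate = unname(r), stringsAsFactors = FALSE)
  }
  structure(list(events = do.call(rbind, c(ev, list(make.row.names = FALSE))),
                 rates = do.call(rbind, c(rt, list(make.row.names = FALSE))),
                 scheme = scheme, lod = lod),
            class = "oxidation_kinetics")
}

#' @export
print.oxidation_kinetics <- function(x, ...) {
  cat("<oxidation_kinetics> ", nrow(x$events), " compounds, stages at days ",
      paste(x$scheme$breakpoints, collapse = ", "),
      ", LOD ", x$lod, " mmol/mol TG\n", sep = "")
  appeared <- x$events[!is.na(x$events$appearance_day), ]
  cat("  compounds above LOD at some day:", nrow(appeared), "\n")
  invisible(x)
}

#' @export
summary.oxidation_kinetics <- function(object, ...) {
  ev <- object$events
  wide <- stats::reshape(object$rates, idvar = "compound_id",
                         timevar = "stage", direction = "wide")
  names(wide) <- sub("^rate\\.", "rate_", names(wide))
  out <- merge(ev, wide, by = "compound_id", all.x = TRUE, sort = TRUE)
  class(out) <- c("summary.oxidation_kinetics", "data.frame")
  out
}

#' @export
plot.oxidation_kinetics <- function(x, table, compounds = NULL, ...) {
  if (missing(table)) stop("supply the concentration table used for the fit")
  ids <- compounds %||% setdiff(names(table), "day")
  op <- graphics::par(mfrow = c(min(3, length(ids)),
                                ceiling(length(ids) / 3)))
  on.exit(graphics::par(op))
  for (id in ids) {
    graphics::plot(table$day, table[[id]], type = "b", pch = 16,
                   xlab = "day", ylab = "mmol/mol TG", main = id, ...)
    graphics::abline(v = x$scheme$breakpoints, lty = 3, col = "grey50")
  }
  invisible(x)
}
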