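#' Lineshape parameters for the synthetic-spectrum generator
#'
#' @param fwhm Lorentzian full width at half maximum, ppm. The default
#'   (1.25e-4 ppm, i.e. 0.05 Hz at 400 MHz) is deliberately narrower than a
#'   routine oil spectrum so that every catalogued integration window captures
#'   essentially all of its signal's mass; see the methods vignette.
#' @param grid_step ppm spacing of the rendering grid; must be <= fwhm/4.
#' @param ppm_range two-element numeric, the rendered ppm span.
#' @param area_scale arbitrary intensity units per (mmol/mol TG x proton)/1000.
#'   Quantification is invariant to it (internal referencing).
#' @param noise_sd additive Gaussian noise standard deviation, intensity units.
#' @param seed integer seed for the noise stream (ignored when `noise_sd = 0`).
#' @param split optional cosmetic symmetric doublet splitting, ppm (0 = off).
#' @return a list of class `lineshape_params`.
#' @export
lineshape_params <- function(fwhm = 1.25e-4, grid_step = 3.125e-5,
                             ppm_range = c(0, 10), area_scale = 1,
                             noise_sd = 0, seed = NULL, split = 0) {
  if (fwhm <= 0) stop("fwhm must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (grid_step > fwhm / 4 + 1e-15)
    stop("grid_step must be <= fwhm/4 (need >= 4 points per linewidth)")
  if (length(ppm_range) != 2L || ppm_range[1] >= ppm_range[2])
    stop("ppm_range must be an increasing pair")
  structure(list(fwhm = fwhm, grid_step = grid_step, ppm_range = ppm_range,
                 area_scale = area_scale, noise_sd = noise_sd, seed = seed,
                 split = split),
            class = "lineshape_params")
}

#' Construct a spectrum object
#'
#' @param ppm strictly monotone ppm grid.
#' @param intensity intensity trace, same length as `ppm`.
#' @param field_mhz spectrometer frequency, MHz.
#' @param meta free-form provenance list.
#' @return an object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, intensity, field_mhz = 400, meta = list()) {
  if (length(ppm) != length(intensity))
    stop("ppm and intensity must have equal length")
  d <- diff(ppm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("ppm grid must be strictly monotone")
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 field_mhz = field_mhz, meta = meta),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat("<nmr_spectrum> ", length(x$ppm), " points, ",
      format(min(x$ppm)), "-", format(max(x$ppm)), " ppm, ",
      x$field_mhz, " MHz\n", sep = "")
  invisible(x)
}

#' @export
plot.nmr_spectrum <- function(x, xlim = rev(range(x$ppm)), ...) {
  graphics::plot(x$ppm, x$intensity, type = "l", xlim = xlim,
                 xlab = "ppm", ylab = "intensity", ...)
  invisible(x)
}

# unit-area Lorentzian density evaluated on x around center
lorentz <- function(x, center, fwhm) {
  g <- fwhm / 2
  (g / pi) / ((x - center)^2 + g^2)
}

#' Render a concentration state into a synthetic 1H NMR spectrum
#'
#' Every catalogued signal of every compound with a nonzero concentration is
#' rendered as a Lorentzian centred at its chemical shift with analytic area
#' `area_scale * concentration * n_protons / 1000`, which is exactly the
#' proton-proportionality the internal-reference quantification formula
#' assumes. The TG backbone reference is always rendered at 1000 mmol/mol TG
#' (one mol TG per mol TG; 4 protons split over its two multiplets). Derived
#' channels (e.g. the total-hydroperoxide window) are never rendered: their
#' area arises from the OOH qualifier signals of the contributing compounds.
#'
#' @param conc_row named numeric, compound_id -> mmol/mol TG.
#' @param cat an `oxi_catalogue`.
#' @param lp a [lineshape_params()] object.
#' @return an `nmr_spectrum` on the catalogue grid.
#' @export
render_spectrum <- function(conc_row, cat, lp = lineshape_params()) {
  validate_catalogue(cat)
  conc_row <- conc_row[!is.na(conc_row)]
  if (any(conc_row < 0)) stop("negative concentrations cannot be rendered")
  nz <- names(conc_row)[conc_row > 0]
  unknown <- setdiff(nz, cat$compounds$compound_id)
  if (length(unknown))
    stop("nonzero concentration for uncatalogued compound(s): ",
         paste(unknown, collapse = ", "))
  ppm <- seq(lp$ppm_range[1], lp$ppm_range[2], by = lp$grid_step)
  y <- numeric(length(ppm))
  sig <- cat$signals
  conc_of <- function(id) {
    if (id == reference_signal(cat)$compound_id) return(1000)
    if (id %in% names(conc_row)) conc_row[[id]] else 0
  }
  add_peak <- function(center, area) {
    if (lp$split > 0) {
      y <<- y + (area / 2) * lorentz(ppm, center - lp$split / 2, lp$fwhm) +
        (area / 2) * lorentz(ppm, center + lp$split / 2, lp$fwhm)
    } else {
      y <<- y + area * lorentz(ppm, center, lp$fwhm)
    }
  }
  ref_cmp <- reference_signal(cat)$compound_id
  for (i in seq_len(nrow(sig))) {
    if (isTRUE(sig$derived[i])) next
    cmp <- sig$compound_id[i]
    conc <- conc_of(cmp)
    if (conc <= 0) next
    area <- lp$area_scale * conc * sig$n_protons[i] / 1000
    if (!is.na(sig$center2[i])) {
      add_peak(sig$center[i], area / 2)
      add_peak(sig$center2[i], area / 2)
    } else {
      add_peak(sig$center[i], area)
    }
  }
  if (lp$noise_sd > 0) {
    if (!is.null(lp$seed)) set.seed(lp$seed)
    y <- y + stats::rnorm(length(y), 0, lp$noise_sd)
  }
  nmr_spectrum(ppm, y, field_mhz = cat$field_mhz,
               meta = list(generator = "oxinmr::render_spectrum",
                           fwhm = lp$fwhm, area_scale = lp$area_scale,
                           noise_sd = lp$noise_sd, seed = lp$seed))
}

#' Trajectory anchors
#'
#' A `trajectory_anchors` object is a table of (compound, day, concentration)
#' anchor points through which [make_timecourse()] interpolates piecewise
#' linearly. Before its first anchor a compound is absent (0); this encodes
#' the appearance-day semantics of the time course.
#'
#' @param df data frame with columns `compound_id`, `day`, `conc` and
#'   optionally `status` (`reported` / `derived` / `assumed` provenance of
#'   each number).
#' @return an object of class `trajectory_anchors`.
#' @export
trajectory_anchors <- function(df) {
  need <- c("compound_id", "day", "conc")
  if (!all(need %in% names(df))) stop("anchors need columns ",
                                      paste(need, collapse = ", "))
  if (any(df$conc < 0)) stop("anchor concentrations must be non-negative")
  if (any(df$day < 0 | df$day > 16)) stop("anchor days must lie in [0, 16]")
  if (!"status" %in% names(df)) df$status <- "assumed"
  df <- df[order(df$compound_id, df$day), , drop = FALSE]
  if (any(duplicated(df[c("compound_id", "day")])))
    stop("duplicate anchor (compound, day) pairs")
  structure(list(anchors = df, interpolation = "piecewise_linear"),
            class = "trajectory_anchors")
}

#' @export
print.trajectory_anchors <- function(x, ...) {
  cat("<trajectory_anchors> ", length(unique(x$anchors$compound_id)),
      " compounds, ", nrow(x$anchors), " anchors (",
      sum(x$anchors$status == "reported"), " reported)\n", sep = "")
  invisible(x)
}

#' The packaged ground-truth trajectory fixture
#'
#' Anchor points for every quantifiable compound class over the 16-day
#' oxidation course of corn oil under accelerated-storage conditions
#' (70 degC, aeration). Printed concentrations and stage rates anchor the
#' `reported`/`derived` rows; inter-anchor behaviour and unprinted magnitudes
#' are modelling choices flagged `assumed`.
#'
#' @return a `trajectory_anchors` object.
#' @export
packaged_fixture <- function() {
  p <- system.file("extdata", "trajectory_anchors.tsv", package = "oxinmr",
                   mustWork = TRUE)
  trajectory_anchors(utils::read.delim(p, stringsAsFactors = FALSE))
}

#' Interpolate anchors into a concentration time course
#'
#' Piecewise-linear interpolation through each compound's anchors; zero
#' before the first anchor (the appearance day) and constant after the last.
#' Anchor days are reproduced exactly.
#'
#' @param anchors a [trajectory_anchors()] object.
#' @param days numeric vector of days in `[0, 16]`.
#' @param replicate_id optional token recorded as an attribute.
#' @return a data frame (`day` column plus one column per compound), class
#'   `concentration_table`.
#' @export
make_timecourse <- function(anchors, days = 0:16, replicate_id = NULL) {
  if (!inherits(anchors, "trajectory_anchors"))
    stop("'anchors' must be a trajectory_anchors object")
  if (any(days < 0 | days > 16)) stop("days must lie within [0, 16]")
  days <- sort(unique(days))
  a <- anchors$anchors
  out <- data.frame(day = days)
  for (id in unique(a$compound_id)) {
    ai <- a[a$compound_id == id, , drop = FALSE]
    v <- if (nrow(ai) == 1L) {
      ifelse(days < ai$day, 0, ai$conc)
    } else {
      f <- stats::approx(ai$day, ai$conc, xout = pmin(pmax(days, min(ai$day)),
                                                      max(ai$day)))$y
      ifelse(days < min(ai$day), 0, f)
    }
    out[[id]] <- v
  }
  concentration_table(out, replicate_id = replicate_id)
}

#' Construct / validate a concentration table
#'
#' @param df data frame with a `day` column and one column per compound,
#'   concentrations in mmol/mol TG.
#' @param replicate_id optional token.
#' @param check_acyl_sum when TRUE (default) and day 0 is present with acyl
#'   columns, verify that day-0 acyl concentrations sum to 3000 mmol/mol TG
#'   (three acyl chains per triglyceride).
#' @param cat catalogue used to identify acyl columns (default packaged).
#' @return `df` with class `concentration_table`.
#' @export
concentration_table <- function(df, replicate_id = NULL,
                                check_acyl_sum = TRUE,
                                cat = NULL) {
  if (!"day" %in% names(df)) stop("concentration table needs a 'day' column")
  if (is.unsorted(df$day, strictly = TRUE)) df <- df[order(df$day), , drop = FALSE]
  vals <- df[setdiff(names(df), "day")]
  if (length(vals) && any(vals < 0, na.rm = TRUE))
    stop("concentrations must be non-negative")
  if (check_acyl_sum && 0 %in% df$day) {
    if (is.null(cat)) cat <- tryCatch(default_catalogue(), error = function(e) NULL)
    if (!is.null(cat)) {
      acyl <- intersect(
        cat$compounds$compound_id[cat$compounds$category == "acyl"],
        names(vals))
      acyl <- setdiff(acyl, reference_signal(cat)$compound_id)
      if (length(acyl) >= 4L) {
        s <- sum(unlist(df[df$day == 0, acyl]))
        if (abs(s - 3000) > 5)
          stop("day-0 acyl concentrations sum to ", format(s),
               " mmol/mol TG; expected 3000 (3 chains x 1000)")
      }
    }
  }
  attr(df, "replicate_id") <- replicate_id
  class(df) <- c("concentration_table", "data.frame")
  df
}
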