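#' Integrate a spectral window
#'
#' Trapezoidal integral of the intensity trace over a closed ppm window on
#' the native grid (no baseline model: synthetic baselines are flat, and a
#' linear-baseline option exists in the file readers for real input).
#'
#' @param s an `nmr_spectrum`.
#' @param window numeric length-2, `c(lo, hi)` in ppm.
#' @return the integrated area in intensity x ppm.
#' @export
integrate_window <- function(s, window) {
  if (!inherits(s, "nmr_spectrum")) stop("'s' must be an nmr_spectrum")
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be c(lo, hi) with lo < hi")
  rng <- range(s$ppm)
  if (window[1] < rng[1] || window[2] > rng[2])
    stop("integration window [", window[1], ", ", window[2],
         "] lies outside the spectrum range [", rng[1], ", ", rng[2], "]")
  ppm <- s$ppm; y <- s$intensity
  if (ppm[1] > ppm[length(ppm)]) { ppm <- rev(ppm); y <- rev(y) }
  i <- which(ppm >= window[1] & ppm <= window[2])
  if (length(i) < 2L) return(0)
  x <- ppm[i]; v <- y[i]
  sum(diff(x) * (v[-1] + v[-length(v)]) / 2)
}

#' Internal-reference quantification formula
#'
#' Converts a signal area into a concentration in mmol/mol TG against the
#' triglyceride backbone reference:
#' `conc = (a_x / n) / (a_tg / 4) * 1000`,
#' where `n` is the proton count of the quantified signal and `a_tg` the area
#' of the 4 glyceryl sn-1/sn-3 protons. `a_x = a_tg` with `n = 4` therefore
#' gives 1000 mmol/mol TG: one mole of X per mole of triglyceride.
#'
#' @param a_x signal area (after any corrections).
#' @param n number of protons generating the signal (> 0).
#' @param a_tg reference area (> 0).
#' @return concentration in mmol/mol TG.
#' @export
eq1_concentration <- function(a_x, n, a_tg) {
  if (any(n <= 0)) stop("proton count n must be positive")
  if (any(a_tg <= 0)) stop("no reference: a_tg must be positive")
  (a_x / n) / (a_tg / 4) * 1000
}

# predicted in-window area of one contributor signal at known concentration:
# conc x n_protons x (a_tg/4)/1000 if its center falls inside the window
predicted_contrib_area <- function(sig_row, window, conc, a_tg) {
  centers <- c(sig_row$center, sig_row$center2)
  centers <- centers[!is.na(centers)]
  inside <- centers >= window[1] & centers <= window[2]
  if (!any(inside)) return(0)
  # sub-window signals carry half the protons per multiplet
  frac <- sum(inside) / length(centers)
  conc * sig_row$n_protons * frac * (a_tg / 4) / 1000
}

#' Apply overlap-subtraction corrections to window areas
#'
#' Processes signals in topological order of the corrections graph; from each
#' signal's raw window area the predicted contribution of every listed
#' co-resonant signal (contributor concentration x its protons in the window,
#' on the reference area scale) is subtracted. Negative results are clamped
#' to zero and flagged rather than raised: near-equal areas under noise must
#' not crash the pipeline.
#'
#' @param areas data frame with columns `signal_id`, `area` (raw window
#'   integrals, arbitrary units).
#' @param cat an `oxi_catalogue`.
#' @param a_tg reference area on the same scale.
#' @param concentrations optional named numeric of already-known compound
#'   concentrations (mmol/mol TG). Contributor concentrations not supplied
#'   are derived from the contributor compound's own (corrected) quantifier
#'   area; a contributor with neither an area nor a concentration is an error.
#' @return `areas` with added columns `corrected_area` and `clamped`.
#' @export
apply_corrections <- function(areas, cat, a_tg, concentrations = NULL) {
  validate_catalogue(cat)
  if (!all(c("signal_id", "area") %in% names(areas)))
    stop("'areas' needs columns signal_id, area")
  sig <- cat$signals
  corr <- corrections_list(sig)
  order <- topo_sort_signals(cat)
  order <- order[order %in% areas$signal_id]
  corrected <- stats::setNames(rep(NA_real_, nrow(areas)), areas$signal_id)
  clamped <- stats::setNames(logical(nrow(areas)), areas$signal_id)
  conc_known <- as.list(concentrations %||% stats::setNames(numeric(0), character(0)))

  conc_of_compound <- function(cmp) {
    if (!is.null(conc_known[[cmp]])) return(conc_known[[cmp]])
    q <- quantifier_signal(cat, cmp)
    if (is.null(q) || !(q$signal_id[1] %in% names(corrected)) ||
        is.na(corrected[[q$signal_id[1]]]))
      stop("missing contributor area/concentration for compound '", cmp, "'")
    eq1_concentration(corrected[[q$signal_id[1]]], q$n_protons[1], a_tg)
  }

  for (id in order) {
    row <- sig[sig$signal_id == id, , drop = FALSE]
    a <- areas$area[match(id, areas$signal_id)]
    win <- c(row$window_lo, row$window_hi)
    for (contrib in corr[[id]]) {
      crow <- sig[sig$signal_id == contrib, , drop = FALSE]
      cc <- conc_of_compound(crow$compound_id)
      a <- a - predicted_contrib_area(crow, win, cc, a_tg)
    }
    if (a < 0) { clamped[[id]] <- TRUE; a <- 0 }
    corrected[[id]] <- a
    # make this compound's concentration available downstream
    q <- quantifier_signal(cat, row$compound_id)
    if (!is.null(q) && q$signal_id[1] == id)
      conc_known[[row$compound_id]] <- eq1_concentration(a, row$n_protons, a_tg)
  }
  areas$corrected_area <- unname(corrected[areas$signal_id])
  areas$clamped <- unname(clamped[areas$signal_id])
  areas
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantify one spectrum against a catalogue
#'
#' The full quantification procedure: the reference area `A_TG` is integrated
#' from the backbone sub-windows (and its listed interloper corrections
#' applied), every quantifier window is integrated, the ordered
#' overlap-subtraction corrections are applied, and each corrected area is
#' converted to mmol/mol TG by the internal-reference formula. Concentrations
#' below the detection limit are reported as 0 and flagged. The total
#' hydroperoxide channel is computed from its own window, independent of the
#' per-isomer signals; before `ooh_switch_day` its narrow early window is
#' used (while conjugated-diene hydroperoxides are the only OOH carriers),
#' afterwards the broad one.
#'
#' @param s an `nmr_spectrum`.
#' @param cat an `oxi_catalogue` (default: packaged).
#' @param lod detection limit in mmol/mol TG. A per-signal `lod_override`
#'   column in the catalogue raises it for individual channels (e.g. the
#'   epoxy-monoene windows on the foot of the bis-allylic signal, readable
#'   only once the substrate is substantially degraded).
#' @param day oxidation day of the sample, if known; only used to pick the
#'   early/late window of day-switched channels.
#' @param ooh_switch_day first day on which the broad hydroperoxide window is
#'   used.
#' @param a_tg_floor minimal acceptable reference area; below it the
#'   reference is considered lost and an error is thrown.
#' @return an object of class `quant_result`: list with `concentration`
#'   (named numeric, mmol/mol TG), `a_tg`, `lod`, `flags` (per-compound
#'   logical flags `below_lod`, `clamped`, `assumed_n`) and the per-signal
#'   `areas` table.
#' @export
quantify_spectrum <- function(s, cat = default_catalogue(), lod = 0.1,
                              day = NULL, ooh_switch_day = 9,
                              a_tg_floor = 1e-6) {
  validate_catalogue(cat)
  sig <- cat$signals
  ref <- reference_signal(cat)

  a_tg_raw <- integrate_window(s, c(ref$window_lo, ref$window_hi))
  if (!is.na(ref$window2_lo))
    a_tg_raw <- a_tg_raw + integrate_window(s, c(ref$window2_lo, ref$window2_hi))
  if (a_tg_raw <= a_tg_floor)
    stop("reference lost: A_TG = ", format(a_tg_raw),
         " is at or below the floor (", format(a_tg_floor), ")")

  window_of <- function(row) {
    if (!is.na(row$window_early_lo) && !is.null(day) &&
        !is.na(day) && day < ooh_switch_day)
      c(row$window_early_lo, row$window_early_hi)
    else c(row$window_lo, row$window_hi)
  }

  quant <- sig[sig$role == "quantifier", , drop = FALSE]
  areas <- data.frame(signal_id = quant$signal_id,
                      area = vapply(seq_len(nrow(quant)), function(i)
                        integrate_window(s, window_of(quant[i, ])), numeric(1)),
                      stringsAsFactors = FALSE)

  # reference corrections: subtract catalogued interlopers that fall inside
  # the reference sub-windows, using their concentrations at the raw A_TG
  a_tg <- a_tg_raw
  ref_contribs <- corrections_list(sig)[[ref$signal_id]]
  if (length(ref_contribs)) {
    pre <- apply_corrections(areas, cat, a_tg_raw)
    for (contrib in ref_contribs) {
      crow <- sig[sig$signal_id == contrib, , drop = FALSE]
      q <- quantifier_signal(cat, crow$compound_id)
      if (is.null(q)) next
      cc <- eq1_concentration(pre$corrected_area[match(q$signal_id[1], pre$signal_id)],
                              q$n_protons[1], a_tg_raw)
      a_tg <- a_tg -
        predicted_contrib_area(crow, c(ref$window_lo, ref$window_hi), cc, a_tg_raw)
      if (!is.na(ref$window2_lo))
        a_tg <- a_tg -
          predicted_contrib_area(crow, c(ref$window2_lo, ref$window2_hi), cc, a_tg_raw)
    }
    if (a_tg <= a_tg_floor)
      stop("reference lost after corrections: A_TG = ", format(a_tg))
  }

  areas <- apply_corrections(areas, cat, a_tg)
  conc <- eq1_concentration(areas$corrected_area,
                            quant$n_protons[match(areas$signal_id, quant$signal_id)],
                            a_tg)
  names(conc) <- quant$compound_id[match(areas$signal_id, quant$signal_id)]

  # channels that sit on the foot of a much larger neighbour (the epoxide
  # windows below the bis-allylic signal) carry a raised per-signal limit
  lod_eff <- rep(lod, length(conc))
  if ("lod_override" %in% names(quant)) {
    ov <- quant$lod_override[match(areas$signal_id, quant$signal_id)]
    lod_eff <- pmax(lod_eff, ifelse(is.na(ov), 0, ov))
  }
  below <- conc < lod_eff
  conc[below] <- 0
  flags <- data.frame(
    compound_id = names(conc),
    below_lod = unname(below),
    clamped = unname(areas$clamped),
    assumed_n = unname(as.logical(quant$assumed_n[match(areas$signal_id,
                                                        quant$signal_id)])),
    stringsAsFactors = FALSE)
  structure(list(concentration = conc, a_tg = a_tg, lod = lod,
                 flags = flags, areas = areas, day = day),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  nz <- x$concentration[x$concentration > 0]
  cat("<quant_result> A_TG = ", format(x$a_tg), ", LOD = ", x$lod,
      " mmol/mol TG\n", sep = "")
  cat("  detected compounds (", length(nz), "):\n", sep = "")
  if (length(nz))
    print(round(sort(nz, decreasing = TRUE), 2))
  n_flag <- sum(x$flags$below_lod | x$flags$clamped)
  if (n_flag) cat("  flags set on", n_flag, "channels\n")
  invisible(x)
}

#' Average replicate quantification results
#'
#' Arithmetic per-compound mean across replicate `quant_result`s; flags are
#' OR-combined.
#'
#' @param results non-empty list of `quant_result` objects over the same
#'   catalogue.
#' @return a single `quant_result` with mean values.
#' @export
average_replicates <- function(results) {
  if (!length(results)) stop("need at least one quant_result")
  if (length(results) == 1L) return(results[[1]])
  ids <- names(results[[1]]$concentration)
  for (r in results)
    if (!identical(names(r$concentration), ids))
      stop("replicates quantify different compound sets")
  conc <- rowMeans(vapply(results, function(r) r$concentration,
                          numeric(length(ids))))
  names(conc) <- ids
  flags <- results[[1]]$flags
  for (r in results[-1]) {
    flags$below_lod <- flags$below_lod | r$flags$below_lod
    flags$clamped <- flags$clamped | r$flags$clamped
  }
  structure(list(concentration = conc,
                 a_tg = mean(vapply(results, `[[`, numeric(1), "a_tg")),
                 lod = results[[1]]$lod, flags = flags,
                 areas = NULL, day = results[[1]]$day,
                 n_replicates = length(results)),
            class = "quant_result")
}
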