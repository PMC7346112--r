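#' Read / write spectra as two-column CSV
#'
#' Plain `ppm,intensity` CSV with a header row.
#'
#' @param path file path.
#' @param field_mhz spectrometer frequency recorded in the object.
#' @return an `nmr_spectrum`.
#' @export
read_spectrum_csv <- function(path, field_mhz = 400) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("spectrum CSV needs two columns (ppm, intensity)")
  if (!is.numeric(df[[1]]) || !is.numeric(df[[2]]))
    stop("spectrum CSV columns must be numeric")
  nmr_spectrum(df[[1]], df[[2]], field_mhz = field_mhz,
               meta = list(source = path))
}

#' @rdname read_spectrum_csv
#' @param s an `nmr_spectrum` to write.
#' @export
write_spectrum_csv <- function(s, path) {
  utils::write.csv(data.frame(ppm = s$ppm, intensity = s$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a spectrum as JCAMP-DX
#'
#' Minimal JCAMP-DX 4.24 writer using an `##XYDATA=(X++(Y..Y))` block in
#' AFFN form with equidistant X sampling.
#'
#' @param s an `nmr_spectrum` on an equidistant grid.
#' @param path output path.
#' @param title TITLE record.
#' @export
write_jcamp <- function(s, path, title = "oxinmr synthetic spectrum") {
  ppm <- s$ppm; y <- s$intensity
  if (ppm[1] > ppm[length(ppm)]) { ppm <- rev(ppm); y <- rev(y) }
  step <- diff(ppm)
  if (max(abs(step - step[1])) > 1e-9 * abs(step[1]))
    stop("JCAMP-DX writer requires an equidistant ppm grid")
  yfac <- max(abs(y), 1e-30) / 32767
  yi <- round(y / yfac)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(paste0("##TITLE=", title),
           "##JCAMP-DX=4.24",
           "##DATA TYPE=NMR SPECTRUM",
           paste0("##.OBSERVE FREQUENCY=", s$field_mhz),
           "##XUNITS=PPM", "##YUNITS=ARBITRARY UNITS",
           paste0("##NPOINTS=", length(ppm)),
           paste0("##FIRSTX=", format(ppm[1], digits = 12)),
           paste0("##LASTX=", format(ppm[length(ppm)], digits = 12)),
           "##XFACTOR=1",
           paste0("##YFACTOR=", format(yfac, digits = 12)),
           "##XYDATA=(X++(Y..Y))")
  writeLines(hdr, con)
  per_line <- 8L
  idx <- seq(1L, length(ppm), by = per_line)
  lines <- vapply(idx, function(i) {
    j <- seq(i, min(i + per_line - 1L, length(ppm)))
    paste(c(format(ppm[i], digits = 12), yi[j]), collapse = " ")
  }, character(1))
  writeLines(lines, con)
  writeLines("##END=", con)
  invisible(path)
}

#' Read a JCAMP-DX spectrum
#'
#' Parses the subset of JCAMP-DX this package writes (AFFN
#' `##XYDATA=(X++(Y..Y))`, XFACTOR/YFACTOR scaling, equidistant X).
#'
#' @param path file path.
#' @return an `nmr_spectrum`.
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key, default = NA) {
    i <- grep(paste0("^##\\.?", key, "="), lines, ignore.case = TRUE)
    if (!length(i)) return(default)
    sub(paste0("^##\\.?", key, "="), "", lines[i[1]], ignore.case = TRUE)
  }
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("malformed JCAMP-DX: no ##XYDATA block in ", path)
  end <- grep("^##END", lines)
  end <- if (length(end)) end[end > start][1] else length(lines) + 1L
  if (is.na(end)) end <- length(lines) + 1L
  body <- lines[seq(start + 1L, end - 1L)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("malformed JCAMP-DX: empty XYDATA block in ", path)
  xfac <- as.numeric(get_field("XFACTOR", "1"))
  yfac <- as.numeric(get_field("YFACTOR", "1"))
  npoints <- as.numeric(get_field("NPOINTS"))
  firstx <- as.numeric(get_field("FIRSTX")) * xfac
  lastx <- as.numeric(get_field("LASTX")) * xfac
  freq <- as.numeric(get_field("OBSERVE FREQUENCY", "400"))
  ys <- suppressWarnings(unlist(lapply(body, function(l) {
    toks <- strsplit(trimws(l), "[ \t]+")[[1]]
    as.numeric(toks[-1])  # first token is the line's X start
  })))
  if (anyNA(ys)) stop("malformed JCAMP-DX: non-numeric Y data in ", path)
  if (!is.na(npoints) && length(ys) != npoints)
    stop("malformed JCAMP-DX: NPOINTS=", npoints, " but ", length(ys),
         " Y values in ", path)
  if (is.na(firstx) || is.na(lastx))
    stop("malformed JCAMP-DX: missing FIRSTX/LASTX in ", path)
  ppm <- seq(firstx, lastx, length.out = length(ys))
  nmr_spectrum(ppm, ys * yfac, field_mhz = freq, meta = list(source = path))
}

#' Read / write concentration tables as CSV
#'
#' CSV layout: a `day` column plus one column per compound id, values in
#' mmol/mol TG.
#'
#' @param path file path.
#' @param ... passed to [concentration_table()].
#' @return a `concentration_table`.
#' @export
read_concentration_table <- function(path, ...) {
  concentration_table(utils::read.csv(path, check.names = FALSE,
                                      stringsAsFactors = FALSE), ...)
}

#' @rdname read_concentration_table
#' @param table a `concentration_table` to write.
#' @export
write_concentration_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Assembles (or loads from YAML) the configuration driving the pipeline
#' commands: simulated days, replicate count, seeds, lineshape, detection
#' limit, stage breakpoints, file format and output directory.
#'
#' @param path optional YAML file; entries override the defaults below.
#' @param ... named overrides applied after the file.
#' @return a list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(days = 0:16, replicates = 2, seed = 1, noise_sd = 0,
              lod = 0.1, format = "csv", out_dir = "oxinmr_run",
              fwhm = 1.25e-4, grid_step = 3.125e-5, area_scale = 1,
              breakpoints = c(0, 8, 11, 14, 16), ooh_switch_day = 9,
              catalogue = NULL)
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    cfg[names(y)] <- y
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (!cfg$format %in% c("csv", "jcamp")) stop("format must be csv or jcamp")
  if (cfg$replicates < 1) stop("replicate count must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

config_catalogue <- function(cfg) {
  if (is.null(cfg$catalogue)) default_catalogue() else load_catalogue(cfg$catalogue)
}

#' Simulate a full oxidation time course to disk
#'
#' Renders one synthetic spectrum per (day, replicate) from the packaged
#' trajectory fixture, writes them (CSV or JCAMP-DX) together with the
#' ground-truth concentration table and a manifest recording every
#' per-spectrum seed.
#'
#' @param cfg a [run_config()].
#' @return invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_simulate <- function(cfg = run_config()) {
  cat <- config_catalogue(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(cfg$out_dir)) stop("cannot create output dir: ", cfg$out_dir)
  truth <- make_timecourse(packaged_fixture(), cfg$days)
  write_concentration_table(truth, file.path(cfg$out_dir, "truth.csv"))
  files <- list()
  for (d in truth$day) for (r in seq_len(cfg$replicates)) {
    seed_dr <- (cfg$seed * 1000L + d * 10L + r) %% .Machine$integer.max
    lp <- lineshape_params(fwhm = cfg$fwhm, grid_step = cfg$grid_step,
                           area_scale = cfg$area_scale,
                           noise_sd = cfg$noise_sd, seed = seed_dr)
    row <- unlist(truth[truth$day == d, setdiff(names(truth), "day")])
    s <- render_spectrum(row, cat, lp)
    fn <- sprintf("day%02d_rep%d.%s", d, r,
                  if (cfg$format == "csv") "csv" else "jdx")
    fp <- file.path(cfg$out_dir, fn)
    if (cfg$format == "csv") write_spectrum_csv(s, fp) else write_jcamp(s, fp)
    files[[length(files) + 1L]] <- list(file = fn, day = d, replicate = r,
                                        seed = seed_dr)
  }
  manifest <- list(seed = cfg$seed, noise_sd = cfg$noise_sd,
                   format = cfg$format, days = truth$day,
                   replicates = cfg$replicates, spectra = files)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Quantify a directory of simulated or measured spectra
#'
#' Reads every spectrum listed in the run manifest (or every spectrum file
#' in the directory when no manifest exists), quantifies it against the
#' catalogue, averages replicates per day, and writes the concentration
#' table plus a JSON flags file. A file that fails to parse is reported and
#' skipped; the run continues and the failure count is returned.
#'
#' @param cfg a [run_config()]; `cfg$out_dir` is read.
#' @param in_dir directory of spectra (defaults to `cfg$out_dir`).
#' @return the `concentration_table`, with attribute `n_failed`.
#' @export
run_quantify <- function(cfg = run_config(), in_dir = cfg$out_dir) {
  cat <- config_catalogue(cfg)
  manifest_path <- file.path(in_dir, "manifest.json")
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    entries <- man$spectra
  } else {
    fls <- list.files(in_dir, pattern = "\\.(csv|jdx|dx)$")
    fls <- setdiff(fls, c("truth.csv", "quantified.csv"))
    day_guess <- suppressWarnings(as.numeric(sub("^day(\\d+).*", "\\1", fls)))
    entries <- data.frame(file = fls, day = day_guess,
                          replicate = seq_along(fls))
  }
  if (!NROW(entries))
    return(structure(concentration_table(data.frame(day = numeric(0)),
                                         check_acyl_sum = FALSE),
                     n_failed = 0L))
  results <- list(); n_failed <- 0L
  for (i in seq_len(NROW(entries))) {
    fp <- file.path(in_dir, entries$file[i])
    s <- tryCatch({
      if (grepl("\\.csv$", fp)) read_spectrum_csv(fp) else read_jcamp(fp)
    }, error = function(e) {
      message("skipping unreadable spectrum ", fp, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(s)) { n_failed <- n_failed + 1L; next }
    q <- quantify_spectrum(s, cat, lod = cfg$lod, day = entries$day[i],
                           ooh_switch_day = cfg$ooh_switch_day)
    results[[length(results) + 1L]] <- list(day = entries$day[i], q = q)
  }
  days <- sort(unique(vapply(results, `[[`, numeric(1), "day")))
  rows <- lapply(days, function(d) {
    reps <- lapply(Filter(function(r) r$day == d, results), `[[`, "q")
    avg <- average_replicates(reps)
    c(day = d, avg$concentration)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- concentration_table(tab, check_acyl_sum = FALSE)
  write_concentration_table(tab, file.path(in_dir, "quantified.csv"))
  flags <- lapply(results, function(r)
    list(day = r$day,
         below_lod = r$q$flags$compound_id[r$q$flags$below_lod],
         clamped = r$q$flags$compound_id[r$q$flags$clamped]))
  jsonlite::write_json(list(n_failed = n_failed, per_spectrum = flags),
                       file.path(in_dir, "flags.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(tab, n_failed = n_failed)
}

#' Kinetics summary and plots for a quantified time course
#'
#' Runs [oxidation_kinetics()] on a concentration table and writes the
#' summary as CSV and JSON (and optional per-class concentration-vs-day
#' plots as a PDF).
#'
#' @param cfg a [run_config()].
#' @param table a `concentration_table` (default: `quantified.csv` from
#'   `cfg$out_dir`).
#' @param plots write `kinetics_plots.pdf`?
#' @return the `oxidation_kinetics` object, invisibly.
#' @export
run_kinetics <- function(cfg = run_config(),
                         table = read_concentration_table(
                           file.path(cfg$out_dir, "quantified.csv"),
                           check_acyl_sum = FALSE),
                         plots = FALSE) {
  if (nrow(table) < 2L) stop("kinetics needs a table with at least two days")
  kin <- oxidation_kinetics(table, stage_scheme(cfg$breakpoints), lod = cfg$lod)
  smry <- summary(kin)
  utils::write.csv(smry, file.path(cfg$out_dir, "kinetics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(smry, file.path(cfg$out_dir, "kinetics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  if (plots) {
    grDevices::pdf(file.path(cfg$out_dir, "kinetics_plots.pdf"), 9, 9)
    ids <- setdiff(names(table), "day")
    for (grp in split(ids, ceiling(seq_along(ids) / 9))) {
      op <- graphics::par(mfrow = c(3, 3))
      for (id in grp) {
        graphics::plot(table$day, table[[id]], type = "b", pch = 16,
                       xlab = "day", ylab = "mmol/mol TG", main = id)
        graphics::abline(v = cfg$breakpoints, lty = 3, col = "grey60")
      }
      graphics::par(op)
    }
    grDevices::dev.off()
  }
  invisible(kin)
}
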