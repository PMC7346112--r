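#' Signal-assignment catalogues
#'
#' An `oxi_catalogue` holds the machine-readable 1H NMR assignment table used
#' throughout the package: one row per quantifiable signal (chemical-shift
#' center, closed integration window in ppm, proton count `n`, role) plus a
#' compound table (class, category, first detected day). Exactly one signal is
#' the internal reference: the triglyceride glyceryl sn-1/sn-3 CH2 protons
#' (4 H per TG), whose two multiplets are described by paired sub-windows on a
#' single row. The `corrections` column of a signal lists the signal ids whose
#' predicted contribution must be subtracted from the signal's window before
#' quantification (overlap bookkeeping, not lineshape fitting).
#'
#' @name oxi_catalogue
#' @seealso [load_catalogue()], [default_catalogue()], [audit_collisions()]
NULL

CATEGORIES <- c("acyl", "minor_component", "primary_oxidation",
                "secondary_oxidation", "small_molecule", "sterol_oxide")
SIGNAL_ROLES <- c("quantifier", "reference", "qualifier")

#' Load and validate a signal-assignment catalogue
#'
#' Reads the two UTF-8 tab-delimited tables (`signals.tsv`, `compounds.tsv`)
#' that make up a catalogue and validates every structural invariant:
#' unique ids, resolvable compound references, well-formed windows
#' (`lo < hi`, center inside, `0 < n_protons <= 6`), exactly one reference
#' signal, an acyclic corrections graph, and at least one quantifier or
#' qualifier signal for every non-acyl compound.
#'
#' @param path directory containing `signals.tsv` and `compounds.tsv`, or the
#'   path of the signals file itself (the compounds file is then looked up as
#'   a sibling).
#' @param field_mhz spectrometer frequency in MHz (metadata only).
#' @return an object of class `oxi_catalogue`: a list with data frames
#'   `signals` and `compounds` and the scalar `field_mhz`.
#' @export
load_catalogue <- function(path, field_mhz = 400) {
  if (length(path) != 1L || !is.character(path))
    stop("'path' must be a single file or directory path")
  if (dir.exists(path)) {
    sig_path <- file.path(path, "signals.tsv")
    cmp_path <- file.path(path, "compounds.tsv")
  } else {
    sig_path <- path
    cmp_path <- file.path(dirname(path), "compounds.tsv")
  }
  for (p in c(sig_path, cmp_path))
    if (!file.exists(p)) stop("catalogue file not found: ", p)
  signals <- utils::read.delim(sig_path, stringsAsFactors = FALSE,
                               na.strings = c("NA", ""))
  compounds <- utils::read.delim(cmp_path, stringsAsFactors = FALSE,
                                 na.strings = c("NA", ""))
  cat <- structure(list(signals = signals, compounds = compounds,
                        field_mhz = field_mhz),
                   class = "oxi_catalogue")
  validate_catalogue(cat)
  cat
}

#' The packaged default catalogue
#'
#' Returns the catalogue shipped with the package: the reconstructed
#' assignment table for corn-oil oxidation at 400 MHz, with one quantifier
#' channel per compound class, the TG backbone reference, and the
#' overlap-subtraction rules for the shared windows (Z-epoxide 2.88-2.98 ppm,
#' dihydroxy 3.38-3.46 ppm, broad hydroperoxide 8.3-9.3 ppm).
#'
#' @return an `oxi_catalogue`.
#' @export
default_catalogue <- function() {
  load_catalogue(system.file("extdata", package = "oxinmr", mustWork = TRUE))
}

required_signal_cols <- c("signal_id", "compound_id", "center", "window_lo",
                          "window_hi", "n_protons", "multiplicity", "role",
                          "corrections", "derived", "assumed_n")

#' Validate an oxi_catalogue
#'
#' Checks every invariant of the catalogue data model; called by
#' [load_catalogue()] and usable directly after programmatic edits.
#'
#' @param cat an `oxi_catalogue`.
#' @return `cat`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_catalogue <- function(cat) {
  if (!inherits(cat, "oxi_catalogue")) stop("not an oxi_catalogue")
  sig <- cat$signals; cmp <- cat$compounds
  miss <- setdiff(required_signal_cols, names(sig))
  if (length(miss)) stop("signals table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!all(c("compound_id", "name", "category") %in% names(cmp)))
    stop("compounds table lacks required columns")
  if (nrow(sig) == 0L) stop("catalogue validation: no signals (in particular, no reference signal)")
  if (anyDuplicated(cmp$compound_id))
    stop("catalogue validation: duplicate compound ids: ",
         paste(unique(cmp$compound_id[duplicated(cmp$compound_id)]), collapse = ", "))
  if (anyDuplicated(sig$signal_id))
    stop("catalogue validation: duplicate signal ids: ",
         paste(unique(sig$signal_id[duplicated(sig$signal_id)]), collapse = ", "))
  bad_cat <- setdiff(unique(cmp$category), CATEGORIES)
  if (length(bad_cat)) stop("unknown compound category: ",
                            paste(bad_cat, collapse = ", "))
  fd <- cmp$first_detected_day
  if (any(!is.na(fd) & (fd < 0 | fd > 16)))
    stop("first_detected_day must lie in [0, 16] when present")
  unresolved <- setdiff(sig$compound_id, cmp$compound_id)
  if (length(unresolved))
    stop("signals reference unknown compounds: ",
         paste(unresolved, collapse = ", "))
  if (!all(sig$role %in% SIGNAL_ROLES))
    stop("signal role must be one of ", paste(SIGNAL_ROLES, collapse = "/"))
  if (sum(sig$role == "reference") != 1L)
    stop("catalogue validation: exactly one reference signal required, found ",
         sum(sig$role == "reference"))
  ok_win <- sig$window_lo < sig$window_hi &
    sig$center >= sig$window_lo & sig$center <= sig$window_hi
  if (!all(ok_win))
    stop("malformed windows (need lo < hi, center inside) for: ",
         paste(sig$signal_id[!ok_win], collapse = ", "))
  if (any(!is.na(sig$window2_lo))) {
    i <- which(!is.na(sig$window2_lo))
    ok2 <- sig$window2_lo[i] < sig$window2_hi[i] &
      sig$center2[i] >= sig$window2_lo[i] & sig$center2[i] <= sig$window2_hi[i]
    if (!all(ok2)) stop("malformed secondary windows for: ",
                        paste(sig$signal_id[i][!ok2], collapse = ", "))
  }
  if (any(sig$n_protons <= 0 | sig$n_protons > 6))
    stop("n_protons must satisfy 0 < n <= 6 for: ",
         paste(sig$signal_id[sig$n_protons <= 0 | sig$n_protons > 6],
               collapse = ", "))
  corr <- corrections_list(sig)
  unknown <- setdiff(unlist(corr), sig$signal_id)
  if (length(unknown))
    stop("corrections reference unknown signals: ",
         paste(unknown, collapse = ", "))
  topo_sort_signals(cat)  # throws on cycles
  # every non-acyl compound needs a quantifier or qualifier channel
  quantifiable <- unique(sig$compound_id[sig$role %in% c("quantifier", "qualifier")])
  need <- cmp$compound_id[cmp$category != "acyl"]
  lack <- setdiff(need, quantifiable)
  if (length(lack))
    stop("non-acyl compounds without any quantifier/qualifier signal: ",
         paste(lack, collapse = ", "))
  invisible(cat)
}

# parse the comma-separated corrections column into a named list
corrections_list <- function(signals) {
  out <- lapply(signals$corrections, function(x) {
    if (is.na(x) || !nzchar(trimws(x))) character(0)
    else trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  })
  names(out) <- signals$signal_id
  out
}

# Topological order of signals under the corrections DAG, where a signal's
# correction depends on the *quantifier* of the contributor's compound.
# Errors on cycles.
topo_sort_signals <- function(cat) {
  sig <- cat$signals
  corr <- corrections_list(sig)
  quant_of <- stats::setNames(sig$signal_id[sig$role == "quantifier"],
                              sig$compound_id[sig$role == "quantifier"])
  deps <- lapply(seq_len(nrow(sig)), function(i) {
    contribs <- corr[[sig$signal_id[i]]]
    if (!length(contribs)) return(character(0))
    dep_cmp <- sig$compound_id[match(contribs, sig$signal_id)]
    dep_sig <- unname(quant_of[dep_cmp])
    # raw corrections-graph edges too, so that direct cycles are caught even
    # between qualifier signals
    unique(stats::na.omit(c(contribs, dep_sig)))
  })
  names(deps) <- sig$signal_id
  order <- character(0)
  state <- stats::setNames(rep.int(0L, nrow(sig)), sig$signal_id) # 0 new, 1 active, 2 done
  visit <- function(id) {
    if (state[[id]] == 2L) return(invisible())
    if (state[[id]] == 1L)
      stop("catalogue validation: cycle in corrections involving signal '",
           id, "'")
    state[[id]] <<- 1L
    for (d in deps[[id]]) if (d != id) visit(d)
    state[[id]] <<- 2L
    order <<- c(order, id)
    invisible()
  }
  for (id in sig$signal_id) visit(id)
  order
}

#' Audit quantifier-window collisions
#'
#' Returns every pair of quantifier windows of *different* compounds that
#' overlap without one signal appearing in the other's corrections list.
#' Windows are closed ppm intervals; the packaged catalogue audits clean.
#'
#' @param cat an `oxi_catalogue`.
#' @return a data frame with columns `signal_a`, `signal_b`
#'   (lexicographically ordered within and across rows); zero rows if clean.
#' @export
audit_collisions <- function(cat) {
  validate_catalogue(cat)
  sig <- cat$signals
  q <- sig[sig$role == "quantifier", , drop = FALSE]
  corr <- corrections_list(sig)
  pairs <- list()
  if (nrow(q) >= 2L) {
    for (i in seq_len(nrow(q) - 1L)) for (j in seq(i + 1L, nrow(q))) {
      if (q$compound_id[i] == q$compound_id[j]) next
      if (q$window_lo[i] <= q$window_hi[j] && q$window_lo[j] <= q$window_hi[i]) {
        a <- q$signal_id[i]; b <- q$signal_id[j]
        covered <- (a %in% corr[[b]]) || (b %in% corr[[a]])
        if (!covered) pairs[[length(pairs) + 1L]] <- sort(c(a, b))
      }
    }
  }
  if (!length(pairs))
    return(data.frame(signal_a = character(0), signal_b = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(pairs, function(p)
    data.frame(signal_a = p[1], signal_b = p[2], stringsAsFactors = FALSE)))
  out[order(out$signal_a, out$signal_b), , drop = FALSE]
}

#' Write a catalogue back to disk
#'
#' Writes `signals.tsv` and `compounds.tsv` into `dir` in the same layout
#' [load_catalogue()] reads, so that write + load round-trips.
#'
#' @param cat an `oxi_catalogue`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_catalogue <- function(cat, dir) {
  validate_catalogue(cat)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(cat$signals, file.path(dir, "signals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(cat$compounds, file.path(dir, "compounds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(dir)
}

#' @export
print.oxi_catalogue <- function(x, ...) {
  cat("<oxi_catalogue> ", nrow(x$compounds), " compound classes, ",
      nrow(x$signals), " signals (", sum(x$signals$role == "quantifier"),
      " quantifiers), ", x$field_mhz, " MHz\n", sep = "")
  tab <- table(x$compounds$category)
  cat("  categories:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# reference signal row (single row, possibly with paired sub-windows)
reference_signal <- function(cat) {
  cat$signals[cat$signals$role == "reference", , drop = FALSE]
}

# quantifier row for a compound, or NULL
quantifier_signal <- function(cat, compound_id) {
  s <- cat$signals
  r <- s[s$role == "quantifier" & s$compound_id == compound_id, , drop = FALSE]
  if (nrow(r)) r else NULL
}
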