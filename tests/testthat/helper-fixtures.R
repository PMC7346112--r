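# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture_catalogue <- function() {
  if (is.null(.fixture_env$cat)) .fixture_env$cat <- default_catalogue()
  .fixture_env$cat
}

fixture_truth <- function() {
  if (is.null(.fixture_env$truth))
    .fixture_env$truth <- make_timecourse(packaged_fixture(), 0:16)
  .fixture_env$truth
}

truth_row <- function(day) {
  tr <- fixture_truth()
  unlist(tr[tr$day == day, setdiff(names(tr), "day")])
}

# render + quantify a fixture day once, cache the result
fixture_quant <- function(day) {
  key <- paste0("q", day)
  if (is.null(.fixture_env[[key]])) {
    s <- render_spectrum(truth_row(day), fixture_catalogue())
    .fixture_env[[key]] <- quantify_spectrum(s, fixture_catalogue(), day = day)
  }
  .fixture_env[[key]]
}

# minimal catalogue builder for validation edge cases; all optional columns
# get defaults so tests only state what they are about
toy_signal <- function(signal_id, compound_id, center, lo, hi,
                       n = 1, role = "quantifier", corrections = "",
                       center2 = NA, lo2 = NA, hi2 = NA) {
  data.frame(signal_id = signal_id, compound_id = compound_id,
             center = center, window_lo = lo, window_hi = hi,
             n_protons = n, multiplicity = "s", role = role,
             corrections = corrections, derived = FALSE, assumed_n = FALSE,
             center2 = center2, window2_lo = lo2, window2_hi = hi2,
             window_early_lo = NA, window_early_hi = NA,
             provenance = "toy", lod_override = NA,
             stringsAsFactors = FALSE)
}

toy_compound <- function(id, category = "small_molecule") {
  data.frame(compound_id = id, name = id, category = category,
             first_detected_day = NA, notes = "", stringsAsFactors = FALSE)
}

toy_catalogue <- function(signals, compounds, validate = TRUE) {
  cat <- structure(list(signals = signals, compounds = compounds,
                        field_mhz = 400),
                   class = "oxi_catalogue")
  if (validate) validate_catalogue(cat)
  cat
}

# a small valid catalogue: TG reference plus two isolated singlets
toy_base <- function() {
  sig <- rbind(
    toy_signal("tg_ref", "TG", 4.14, 4.10, 4.18, n = 4, role = "reference",
               center2 = 4.30, lo2 = 4.26, hi2 = 4.34),
    toy_signal("x_1", "X", 7.00, 6.96, 7.04),
    toy_signal("y_1", "Y", 8.00, 7.96, 8.04))
  cmp <- rbind(toy_compound("TG", "acyl"), toy_compound("X"),
               toy_compound("Y"))
  toy_catalogue(sig, cmp)
}

# independent closed-form Lorentzian helpers (the oracles; deliberately not
# the package's internals)
oracle_lorentz_trace <- function(ppm, center, fwhm, area = 1) {
  g <- fwhm / 2
  area * (g / pi) / ((ppm - center)^2 + g^2)
}

oracle_lorentz_mass <- function(half_width, fwhm) {
  # fraction of a unit Lorentzian within +/- half_width of its center
  (2 / pi) * atan(half_width / (fwhm / 2))
}
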