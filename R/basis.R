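#' Resonance catalogue for the simplified metabolite basis
#'
#' Hard-coded chemical-shift positions and relative areas (proton-weighted)
#' for the metabolites supported by the simulator. Each metabolite is
#' represented by 1-3 Lorentzian resonances at its dominant in vivo
#' positions; multiplet fine structure is deliberately collapsed into
#' single Lorentzians, which is sufficient for exercising a
#' linear-combination fitting chain on basis-matched data.
#'
#' @return A tibble with columns `metabolite`, `ppm`, `rel_area`.
#' @examples
#' metabolite_catalogue()
#' @export
metabolite_catalogue <- function() {
  tibble::tribble(
    ~metabolite, ~ppm, ~rel_area,
    "NAA",  2.01, 3.0,
    "NAA",  2.60, 0.6,
    "tCr",  3.03, 3.0,
    "tCr",  3.92, 2.0,
    "tCho", 3.21, 9.0,
    "Ins",  3.52, 4.0,
    "Ins",  4.05, 1.0,
    "Tau",  3.25, 2.0,
    "Tau",  3.42, 2.0,
    "Glu",  2.35, 2.0,
    "Glu",  2.08, 2.0,
    "Glu",  3.75, 1.0,
    "Gln",  2.45, 2.0,
    "Gln",  2.13, 2.0,
    "Gln",  3.77, 1.0,
    "Lac",  1.33, 3.0,
    "GABA", 2.28, 2.0,
    "GABA", 3.01, 2.0,
    "GSH",  2.95, 2.0,
    "NAAG", 2.04, 3.0,
    "Asc",  3.73, 2.0
  )
}

# Broad macromolecule resonances (ppm, rel_area); ~90 Hz wide components
# forming one fixed baseline basis spectrum.
mm_catalogue <- function() {
  tibble::tribble(
    ~ppm, ~rel_area,
    0.93, 1.0,
    1.24, 0.8,
    1.43, 0.6,
    1.72, 0.5,
    2.05, 0.9,
    2.29, 0.5,
    3.00, 0.4
  )
}

# One complex Lorentzian FID: sum_k area_k exp(2i pi f_k t - pi lw t),
# with f_k the offset from the carrier in Hz.
lorentzian_fid <- function(protocol, ppm, rel_area, linewidth_hz) {
  t <- time_axis(protocol)
  f <- (ppm - protocol$center_ppm) * protocol$field_mhz
  decay <- exp(-pi * linewidth_hz * t)
  fid <- complex(length.out = protocol$n_points)
  for (k in seq_along(ppm)) {
    fid <- fid + rel_area[k] * exp(2i * pi * f[k] * t) * decay
  }
  # first point at half weight: standard DFT convention to keep the
  # spectral baseline flat for a truncated one-sided FID
  fid[1] <- fid[1] / 2
  fid
}

#' Build a simplified metabolite basis set
#'
#' Generates unit-concentration complex reference spectra on the protocol
#' grid, one per requested metabolite, from the fixed resonance catalogue,
#' plus one broad macromolecule spectrum (component name `"MM"`). Each
#' resonance is a Lorentzian of the given linewidth; unit concentration
#' means a time-domain amplitude equal to the catalogue `rel_area`, so
#' spectra (and their integrals) scale linearly with simulated
#' concentration. The construction is fully deterministic.
#'
#' @param metabolites Character vector of metabolite names; see
#'   [metabolite_catalogue()] for the supported set.
#' @param protocol A [acq_protocol()] object supplying the grid.
#' @param linewidth Metabolite Lorentzian full width at half maximum (Hz).
#' @param mm_linewidth Macromolecule component width (Hz).
#' @param mm_scale Overall macromolecule amplitude relative to the
#'   catalogue areas.
#' @return An object of class `dmrs_basis`: list with `spectra` (complex
#'   matrix n_points x components, last column `"MM"`), `metabolites`,
#'   `linewidth` and the protocol.
#' @examples
#' b <- make_basis(c("NAA", "tCr"), acq_protocol(), linewidth = 6)
#' dim(b$spectra)
#' @export
make_basis <- function(metabolites, protocol = acq_protocol(), linewidth = 12,
                       mm_linewidth = 90, mm_scale = 3) {
  cat <- metabolite_catalogue()
  known <- unique(cat$metabolite)
  bad <- setdiff(metabolites, known)
  if (length(bad) > 0) {
    stop("Unknown metabolite(s): ", paste(bad, collapse = ", "),
         ". Supported: ", paste(known, collapse = ", "), ".", call. = FALSE)
  }
  if (linewidth <= 0) stop("`linewidth` must be > 0.", call. = FALSE)
  cols <- lapply(metabolites, function(m) {
    rows <- cat[cat$metabolite == m, ]
    spec_from_fid(lorentzian_fid(protocol, rows$ppm, rows$rel_area, linewidth))
  })
  mm <- mm_catalogue()
  cols <- c(cols, list(spec_from_fid(
    lorentzian_fid(protocol, mm$ppm, mm_scale * mm$rel_area, mm_linewidth)
  )))
  spectra <- do.call(cbind, cols)
  colnames(spectra) <- c(metabolites, "MM")
  structure(
    list(spectra = spectra, metabolites = metabolites,
         linewidth = linewidth, mm_linewidth = mm_linewidth,
         mm_scale = mm_scale, protocol = protocol),
    class = "dmrs_basis"
  )
}

#' @export
print.dmrs_basis <- function(x, ...) {
  cat("<dmrs_basis>", length(x$metabolites), "metabolites + MM,",
      x$protocol$n_points, "points,", x$linewidth, "Hz linewidth\n")
  invisible(x)
}

#' Basis spectra as a tidy table
#'
#' @param x A `dmrs_basis` object.
#' @param ... Unused.
#' @return A tibble with columns `component`, `ppm`, `real`, `imag`.
#' @export
tidy.dmrs_basis <- function(x, ...) {
  ax <- ppm_axis(x$protocol)
  purrr::map_dfr(colnames(x$spectra), function(cn) {
    tibble::tibble(component = cn, ppm = ax,
                   real = Re(x$spectra[, cn]), imag = Im(x$spectra[, cn]))
  })
}
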