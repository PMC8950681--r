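# Per-residue scale tables for feature rows 21-30. Values transcribed
# from the AAindex database (accession in `provenance`); residue order is
# aa_alphabet. The three propensity rows ship flexibility/coil/B-factor
# scales as documented, substitutable defaults (see load_scales()).

.scale_values <- list(
  steric_parameter = c(0.52, 0.68, 0.76, 0.76, 0.62, 0.68, 0.68, 0.00, 0.70,
                       1.02, 0.98, 0.68, 0.78, 0.70, 0.36, 0.53, 0.50, 0.70,
                       0.70, 0.76),
  polarizability = c(0.046, 0.291, 0.134, 0.105, 0.128, 0.180, 0.151, 0.000,
                     0.230, 0.186, 0.186, 0.219, 0.221, 0.290, 0.131, 0.062,
                     0.108, 0.409, 0.298, 0.140),
  volume = c(31.0, 124.0, 56.0, 54.0, 55.0, 85.0, 83.0, 3.0, 96.0, 111.0,
             111.0, 119.0, 105.0, 132.0, 32.5, 32.0, 61.0, 170.0, 136.0, 84.0),
  hydrophobicity = c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
                     3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2),
  isoelectric_point = c(6.00, 10.76, 5.41, 2.77, 5.05, 5.65, 3.22, 5.97, 7.59,
                        6.02, 5.98, 9.74, 5.74, 5.48, 6.30, 5.68, 5.66, 5.89,
                        5.66, 5.96),
  helix_probability = c(1.42, 0.98, 0.67, 1.01, 0.70, 1.11, 1.51, 0.57, 1.00,
                        1.08, 1.21, 1.16, 1.45, 1.13, 0.57, 0.77, 0.83, 1.08,
                        0.69, 1.06),
  sheet_probability = c(0.83, 0.93, 0.89, 0.54, 1.19, 1.10, 0.37, 0.75, 0.87,
                        1.60, 1.30, 0.74, 1.05, 1.38, 0.55, 0.75, 1.19, 1.37,
                        1.47, 1.70),
  flexibility = c(0.357, 0.529, 0.463, 0.511, 0.346, 0.493, 0.497, 0.544,
                  0.323, 0.462, 0.365, 0.466, 0.295, 0.314, 0.509, 0.507,
                  0.444, 0.305, 0.420, 0.386),
  coil_propensity = c(0.71, 1.06, 1.37, 1.21, 1.19, 0.87, 0.84, 1.52, 1.07,
                      0.66, 0.69, 0.99, 0.59, 0.71, 1.61, 1.34, 1.08, 0.76,
                      1.07, 0.63),
  bfactor = c(0.984, 1.008, 1.048, 1.068, 0.906, 1.037, 1.094, 1.031, 0.950,
              0.927, 0.935, 1.102, 0.952, 0.915, 1.049, 1.046, 0.997, 0.904,
              0.929, 0.931)
)

.scale_provenance <- c(
  steric_parameter = "AAindex CHAM810101 (Charton, 1981)",
  polarizability = "AAindex CHAM820101 (Charton-Charton, 1982)",
  volume = "AAindex GRAR740103 (Grantham, 1974)",
  hydrophobicity = "AAindex KYTJ820101 (Kyte-Doolittle, 1982)",
  isoelectric_point = "AAindex ZIMJ680104 (Zimmerman et al., 1968)",
  helix_probability = "AAindex CHOP780201 (Chou-Fasman, 1978)",
  sheet_probability = "AAindex CHOP780202 (Chou-Fasman, 1978)",
  flexibility = "AAindex BHAR880101 (Bhaskaran-Ponnuswamy, 1988)",
  coil_propensity = "AAindex CHAM830101 (Charton-Charton, 1983)",
  bfactor = "AAindex VINM940101 (Vihinen et al., 1994)"
)

#' Packaged per-residue scale tables
#'
#' Ten 20-value residue scales backing feature rows 21-30: seven
#' physicochemical descriptors (steric parameter, polarizability, volume,
#' hydrophobicity, isoelectric point, helix and sheet probability) and
#' three structural-propensity scales (average flexibility, coil
#' propensity, normalised B-factor) standing in for missing-density-style
#' disorder propensities. All values are transcribed from AAindex (see
#' the `provenance` column); alternative tables, e.g. the GlobPlot
#' propensities, can be supplied via [load_scales()].
#'
#' @param tidy If `TRUE`, return a long tibble (`scale`, `residue`,
#'   `value`, `provenance`); otherwise (default) a named list of named
#'   20-vectors in [aa_alphabet] order, with a `provenance` attribute.
#' @return See `tidy`.
#' @examples
#' default_scales()$hydrophobicity[["W"]]
#' @export
default_scales <- function(tidy = FALSE) {
  scales <- lapply(.scale_values, function(v) setNames(v, aa_alphabet))
  if (!tidy) {
    attr(scales, "provenance") <- .scale_provenance
    return(scales)
  }
  tibble::tibble(
    scale = rep(names(scales), each = 20L),
    residue = rep(aa_alphabet, times = length(scales)),
    value = unlist(scales, use.names = FALSE),
    provenance = rep(unname(.scale_provenance), each = 20L)
  )
}

#' Load residue scale tables from a TSV file
#'
#' The file must have columns `scale`, `residue`, `value` (and optionally
#' `provenance`), with exactly 20 standard residues per scale, allowing
#' users to substitute their own tables (e.g. the GlobPlot disorder
#' propensities) for the packaged defaults.
#'
#' @param path Path to the TSV.
#' @return Named list of named 20-vectors, as [default_scales()].
#' @export
load_scales <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("scale", "residue", "value") %in% names(raw))) {
    abort("scale file needs columns: scale, residue, value")
  }
  out <- lapply(split(raw, raw$scale), function(d) {
    v <- setNames(d$value, toupper(d$residue))
    if (!setequal(names(v), aa_alphabet)) {
      abort(paste0("scale '", d$scale[1],
                   "' must define exactly the 20 standard residues"))
    }
    v[aa_alphabet]
  })
  out[unique(raw$scale)]
}
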