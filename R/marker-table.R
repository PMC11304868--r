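#' Amino-acid marker reference table for five bolete species
#'
#' Mean and standard deviation of the concentrations of 16 amino acids and
#' their derivatives quantified by LC-MS in five bolete species
#' (*Boletus bainiugan*, *Butyriboletus roseoflavus*,
#' *Rugiboletus extremiorientalis*, *Lanmaoa asiatica*,
#' *Phlebopus portentosus*). These values parameterise the default
#' species profiles used by the synthetic spectrum generator.
#'
#' Units differ per marker (mg/kg or g/kg of dry powder) and are carried in
#' the `unit` column.
#'
#' @return A data.frame with one row per marker: `marker`, `unit`, and a
#'   `mean_<species>` / `sd_<species>` column pair per species.
#' @export
#' @examples
#' tab <- bolete_marker_table()
#' tab[tab$marker == "L-Arginine", c("marker", "unit", "mean_La", "sd_La")]
bolete_marker_table <- function() {
  markers <- c(
    "1-Methylhistidine", "3-N-Methyl-L-Histidine", "Succinic Acid",
    "L-Asparagine Anhydrous", "Trimethylamine N-Oxide", "N-Acetylaspartate",
    "Urea", "L-Pipecolic Acid", "3-Iodo-L-Tyrosine",
    "(5-L-Glutamyl)-L-Alanine", "L-Ornithine", "Glutathione Oxidized",
    "N-Isovaleroylglycine", "N-alpha-Acetyl-L-glutamine", "L-Arginine",
    "L-Glutamine")
  unit <- c("mg/kg", "mg/kg", "mg/kg", "g/kg", "mg/kg", "g/kg", "mg/kg",
            "mg/kg", "mg/kg", "mg/kg", "g/kg", "g/kg", "mg/kg", "mg/kg",
            "g/kg", "g/kg")
  # columns: Boletus bainiugan, Butyriboletus roseoflavus,
  # Rugiboletus extremiorientalis, Lanmaoa asiatica, Phlebopus portentosus
  means <- matrix(c(
    12.64,  21.11,   4.41,   6.69,   6.87,
     2.99, 156.09,   9.43,  48.55,   6.99,
    16.87,   7.28,  23.93,  20.89,  28.37,
     0.94,   0.52,   0.94,   0.78,   0.50,
     0.31,   0.10,   0.01,   0.05,   0.52,
     0.10,   0.15,   0.05,   0.05,   0.07,
     5.30,   9.13,  56.74,   6.04,  11.88,
    15.03,   1.20,   1.53,   4.10,  18.68,
     0.37,   0.12,   0.74,   0.48,   1.78,
    65.96,  34.45,   5.17, 127.94,  75.32,
     3.52,   4.19,   1.33,   2.76,   1.31,
     3.31,   0.92,   1.55,   0.82,   0.15,
     0.13,   0.39,   0.16,   0.27,   0.23,
   180.71,  71.77, 123.52,  89.94, 128.83,
     0.71,   0.27,   0.05,   0.94,   0.47,
     6.00,   5.00,   6.69,   8.95,   5.01), ncol = 5, byrow = TRUE)
  sds <- matrix(c(
     0.54,   1.78,   0.10,   0.45,   0.47,
     0.14,  15.44,   0.44,   3.55,   1.01,
     1.77,   0.42,   0.35,   0.47,   2.25,
     0.04,   0.03,   0.02,   0.04,   0.08,
     0.02,   0.04,   0.009,  0.004,  0.07,
     0.01,   0.01,   0.002,  0.005,  0.02,
     0.40,   1.25,   2.56,   0.50,   2.46,
     2.20,   0.03,   0.14,   0.16,   2.32,
     0.02,   0.01,   0.08,   0.04,   0.09,
     5.87,   2.86,   0.32,   5.87,   5.77,
     0.30,   0.18,   0.28,   0.22,   0.26,
     0.26,   0.12,   0.16,   0.05,   0.03,
     0.02,   0.09,   0.02,   0.01,   0.08,
    55.63,   8.81,   7.71,   2.42,   5.61,
     0.04,   0.05,   0.007,  0.02,   0.05,
     0.134,  0.08,   0.12,   0.39,   0.29), ncol = 5, byrow = TRUE)
  ab <- bolete_species_abbrev()
  out <- data.frame(marker = markers, unit = unit, stringsAsFactors = FALSE)
  for (i in seq_along(ab)) {
    out[[paste0("mean_", ab[i])]] <- means[, i]
    out[[paste0("sd_", ab[i])]] <- sds[, i]
  }
  out
}

#' Species names of the five boletes
#'
#' @return Character vector of the five species (full binomials).
#' @export
bolete_species <- function() {
  c("Boletus bainiugan", "Butyriboletus roseoflavus",
    "Rugiboletus extremiorientalis", "Lanmaoa asiatica",
    "Phlebopus portentosus")
}

# short codes used in column names and sample IDs
bolete_species_abbrev <- function() c("Bb", "Br", "Re", "La", "Pp")
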