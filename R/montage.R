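#' Canonical 64-channel montage
#'
#' The canonical channel set and order used throughout the package: the
#' 64 electrodes of the BCI2000 10-10 montage used by the PhysioNet motor
#' movement/imagery recordings, ordered by scalp region (frontal-polar to
#' occipital).  All recordings are aligned to this order on load.
#'
#' @return Character vector of 64 channel labels.
#' @export
#' @examples
#' head(eegmmidb_channels())
eegmmidb_channels <- function() {
  c(
    "Fp1", "Fpz", "Fp2",
    "Af7", "Af3", "Afz", "Af4", "Af8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "Ft7", "Fc5", "Fc3", "Fc1", "Fcz", "Fc2", "Fc4", "Fc6", "Ft8",
    "T9", "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8", "T10",
    "Tp7", "Cp5", "Cp3", "Cp1", "Cpz", "Cp2", "Cp4", "Cp6", "Tp8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "Po7", "Po3", "Poz", "Po4", "Po8",
    "O1", "Oz", "O2", "Iz"
  )
}

#' Motor-cortex channel subset
#'
#' The twelve channels overlying the sensorimotor cortex used for the
#' motor-cortex summaries of the correlation analysis.
#'
#' @return Character vector of 12 channel labels.
#' @export
motor_cortex_channels <- function() {
  c("Fz", "Fc3", "Fc4", "C3", "C4", "C5", "C6",
    "Cp3", "Cp4", "Cp5", "Cp6", "Cpz")
}

# Occipital/parieto-occipital channels that carry the eyes-closed alpha boost.
occipital_channels <- function() {
  c("Po7", "Po3", "Poz", "Po4", "Po8", "O1", "Oz", "O2", "Iz")
}

#' Normalize raw channel labels to canonical form
#'
#' PhysioNet EDF headers pad labels with trailing dots (e.g. `"C3.."`,
#' `"Fcz."`) and use upper case; this maps them to the canonical montage
#' names (first letter capitalized, rest lower case, dots stripped).
#'
#' @param x Character vector of raw labels.
#' @return Character vector of canonical labels.
#' @export
#' @examples
#' normalize_channel_label(c("C3..", "FCZ.", "Af7"))
normalize_channel_label <- function(x) {
  x <- gsub("[. ]+$", "", x)
  x <- tolower(x)
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}
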