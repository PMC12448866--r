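#' The 41-lipid marker array
#'
#' Loads the curated array of 41 lipid ions (ceramides, hexosylceramides,
#' phosphatidylcholines, phosphatidylethanolamines, sphingomyelins, fatty
#' acids and one phosphatidylserine) that discriminate the common spinal
#' tumor types in negative-mode ambient MS profiles. Each row carries the
#' 0.1-Da spectral bin, the locked-mass target m/z observed in the profiles,
#' the adduct and the LC-MS/MS lipid assignment. These identifications are
#' shipped as a static fixture; the package does not recompute them.
#'
#' One printed bin label in the source table (Cer(d34:0)) disagrees with its
#' own target and theoretical masses; the \code{bin} column carries the
#' mass-consistent label (574.45) and \code{bin_printed} preserves the
#' original (574.55).
#'
#' @return data.frame with columns \code{bin}, \code{bin_printed},
#'   \code{target_mz} (numeric) and \code{adduct}, \code{assignment}
#'   (character); 41 rows.
#' @examples
#' arr <- lipid_marker_array()
#' nrow(arr)  # 41
#' @export
lipid_marker_array <- function() {
  path <- system.file("extdata", "lipid_marker_array.tsv",
                      package = "lipidlda", mustWork = TRUE)
  arr <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = c("numeric", "numeric", "numeric",
                                          "character", "character"))
  arr
}
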