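#' Atchley amino-acid factor scores
#'
#' The five multivariate factor scores per amino acid from Atchley et al.'s
#' factor analysis of the AAindex property collection: F1 polarity /
#' accessibility, F2 propensity for secondary structure, F3 molecular
#' volume, F4 codon diversity / composition, F5 electrostatic charge.
#' The padding letter `O` carries zeros in all five factors, so padded
#' window sites contribute nothing to the factor block.
#'
#' @return A 21 x 5 numeric matrix, rows in canonical alphabet order
#'   (rownames = [aa_alphabet()]), columns `F1`..`F5`.
#' @export
#' @examples
#' atchley_factors()["K", ]
atchley_factors <- function() {
  m <- matrix(c(
    # F1      F2      F3      F4      F5
    -0.591, -1.302, -0.733,  1.570, -0.146,  # A
    -1.343,  0.465, -0.862, -1.020, -0.255,  # C
     1.050,  0.302, -3.656, -0.259, -3.242,  # D
     1.357, -1.453,  1.477,  0.113, -0.837,  # E
    -1.006, -0.590,  1.891, -0.397,  0.412,  # F
    -0.384,  1.652,  1.330,  1.045,  2.064,  # G
     0.336, -0.417, -1.673, -1.474, -0.078,  # H
    -1.239, -0.547,  2.131,  0.393,  0.816,  # I
     1.831, -0.561,  0.533, -0.277,  1.648,  # K
    -1.019, -0.987, -1.505,  1.266, -0.912,  # L
    -0.663, -1.524,  2.219, -1.005,  1.212,  # M
     0.945,  0.828,  1.299, -0.169,  0.933,  # N
     0.189,  2.081, -1.628,  0.421, -1.392,  # P
     0.931, -0.179, -3.005, -0.503, -1.853,  # Q
     1.538, -0.055,  1.502,  0.440,  2.897,  # R
    -0.228,  1.399, -4.760,  0.670, -2.647,  # S
    -0.032,  0.326,  2.213,  0.908,  1.313,  # T
    -1.337, -0.279, -0.544,  1.242, -1.262,  # V
    -0.595,  0.009,  0.672, -2.128, -0.184,  # W
     0.260,  0.830,  3.097, -0.838,  1.512,  # Y
     0.000,  0.000,  0.000,  0.000,  0.000   # O (padding)
  ), ncol = 5L, byrow = TRUE,
  dimnames = list(aa_alphabet(), paste0("F", 1:5)))
  m
}
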