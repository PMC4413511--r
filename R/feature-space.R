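#' The 21-letter window alphabet
#'
#' The 20 standard amino acids in alphabetical one-letter-code order,
#' followed by the padding letter `O` ("nonexisting residue") used to fill
#' windows that extend past a protein terminus. This ordering is canonical:
#' every feature index in the package is derived from it.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "O")
}

# letter -> rank in the canonical alphabet (A=1 .. Y=20, O=21)
.aa_rank <- function(letters) {
  r <- match(letters, aa_alphabet())
  if (anyNA(r)) {
    stop("letter(s) outside the 21-letter alphabet: ",
         paste(unique(letters[is.na(r)]), collapse = ", "))
  }
  r
}

#' Window geometry constants
#'
#' @param flank Number of residues on each side of the center.
#' @return Window width `2 * flank + 1`.
#' @export
window_width <- function(flank = 11L) 2L * as.integer(flank) + 1L

# block sizes for a given window width W and pair spacing range 1..kmax
.block_sizes <- function(width = 23L, kmax = 4L) {
  c(frequency = 21L, factor = 5L * width, cksaap = 441L * kmax)
}

#' Canonical index of a feature
#'
#' Maps a feature descriptor to its 1-based position in the canonical
#' layout: indices 1..21 are residue occurrence frequencies (alphabet
#' order, `O` last); 22..(21 + 5W) are the five Atchley factors grouped by
#' window site (factors F1..F5 within each site); the remainder are CKSAAP
#' pair blocks in order of increasing spacing k, pairs row-major over the
#' alphabet (first letter major). With the default width 23 and kmax 4 the
#' space has 21 + 115 + 1764 = 1900 features.
#'
#' @param block One of `"frequency"`, `"factor"`, `"cksaap"`.
#' @param letter Alphabet letter (frequency block).
#' @param site Window site in 1..width (factor block).
#' @param factor Atchley factor in 1..5 (factor block).
#' @param a,b Ordered pair letters (cksaap block).
#' @param k Pair spacing, number of intervening residues (cksaap block).
#' @param width Window width (default 23).
#' @param kmax Largest spacing encoded (default 4).
#' @return Integer index.
#' @export
#' @examples
#' feature_index("cksaap", a = "S", b = "W", k = 4)  # 1793
#' feature_index("factor", site = 3, factor = 2)     # 33
feature_index <- function(block, letter = NULL, site = NULL, factor = NULL,
                          a = NULL, b = NULL, k = NULL,
                          width = 23L, kmax = 4L) {
  block <- match.arg(block, c("frequency", "factor", "cksaap"))
  sizes <- .block_sizes(width, kmax)
  switch(block,
    frequency = {
      .aa_rank(letter)
    },
    factor = {
      site <- as.integer(site); factor <- as.integer(factor)
      if (any(site < 1L | site > width)) stop("site must be in 1..", width)
      if (any(factor < 1L | factor > 5L)) stop("factor must be in 1..5")
      sizes[["frequency"]] + 5L * (site - 1L) + factor
    },
    cksaap = {
      k <- as.integer(k)
      if (any(k < 1L | k > kmax)) stop("k must be in 1..", kmax)
      sizes[["frequency"]] + sizes[["factor"]] +
        441L * (k - 1L) + 21L * (.aa_rank(a) - 1L) + .aa_rank(b)
    }
  )
}

#' The full canonical feature space
#'
#' Builds the ordered table of all feature descriptors for a given window
#' width and maximum pair spacing. Row `i` describes feature index `i`.
#'
#' @inheritParams feature_index
#' @return A `data.frame` with columns `index`, `block`, `name` and the
#'   block parameters (`letter`, `site`, `factor`, `a`, `b`, `k`; `NA`
#'   where not applicable).
#' @export
#' @examples
#' fs <- feature_space()
#' nrow(fs)          # 1900
#' fs[fs$index == 1793, ]
feature_space <- function(width = 23L, kmax = 4L) {
  ab <- aa_alphabet()
  freq <- data.frame(
    block = "frequency", name = paste0("freq_", ab),
    letter = ab, site = NA_integer_, factor = NA_integer_,
    a = NA_character_, b = NA_character_, k = NA_integer_,
    stringsAsFactors = FALSE
  )
  sites <- rep(seq_len(width), each = 5L)
  facs <- rep(1:5, width)
  fac <- data.frame(
    block = "factor", name = paste0("F", facs, "_site", sites),
    letter = NA_character_, site = sites, factor = facs,
    a = NA_character_, b = NA_character_, k = NA_integer_,
    stringsAsFactors = FALSE
  )
  ks <- rep(seq_len(kmax), each = 441L)
  aa <- rep(rep(ab, each = 21L), kmax)
  bb <- rep(ab, 21L * kmax)
  ck <- data.frame(
    block = "cksaap", name = paste0(aa, strrep("^", ks), bb),
    letter = NA_character_, site = NA_integer_, factor = NA_integer_,
    a = aa, b = bb, k = ks,
    stringsAsFactors = FALSE
  )
  out <- rbind(freq, fac, ck)
  out <- cbind(index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# memoised default 23/4 space
.fs_cache <- new.env(parent = emptyenv())
.default_space <- function(width = 23L, kmax = 4L) {
  key <- paste0("w", width, "k", kmax)
  if (is.null(.fs_cache[[key]])) .fs_cache[[key]] <- feature_space(width, kmax)
  .fs_cache[[key]]
}

#' Descriptor of a feature index
#'
#' Inverse of [feature_index()]: returns the descriptor row for a canonical
#' index. Round-trips exactly over the whole space.
#'
#' @param index Integer index (vectorised).
#' @inheritParams feature_index
#' @return One `data.frame` row per index, as in [feature_space()].
#' @export
#' @examples
#' feature_name(341)   # L^S, pair (L, S) at spacing 1
feature_name <- function(index, width = 23L, kmax = 4L) {
  fs <- .default_space(width, kmax)
  index <- as.integer(index)
  if (any(is.na(index) | index < 1L | index > nrow(fs))) {
    stop("index out of range 1..", nrow(fs))
  }
  fs[index, , drop = FALSE]
}
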