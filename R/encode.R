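.check_peptide <- function(peptide, width = 23L) {
  if (nchar(peptide) != width) {
    stop("peptide must have exactly ", width, " characters, got ", nchar(peptide))
  }
  s <- strsplit(peptide, "")[[1]]
  r <- match(s, aa_alphabet())
  if (anyNA(r)) {
    stop("peptide contains letters outside the 21-letter alphabet: ",
         paste(unique(s[is.na(r)]), collapse = ", "))
  }
  r  # integer ranks 1..21
}

#' Residue occurrence-frequency encoding
#'
#' Counts each of the 21 alphabet letters (padding `O` included) in the
#' window and divides by the window length L, so the block always sums to
#' 1.
#'
#' @param peptide Window string (default width 23).
#' @param width Window width.
#' @return Named numeric vector of length 21.
#' @export
encode_frequency <- function(peptide, width = 23L) {
  r <- .check_peptide(peptide, width)
  counts <- tabulate(r, nbins = 21L)
  setNames(counts / width, paste0("freq_", aa_alphabet()))
}

#' Atchley-factor encoding
#'
#' Five physicochemical factor scores for the residue at each window site,
#' grouped site-major (site 1 F1..F5, site 2 F1..F5, ...). Padded sites
#' (letter `O`) contribute zeros.
#'
#' @inheritParams encode_frequency
#' @param table 21 x 5 factor score matrix (default [atchley_factors()]).
#' @return Named numeric vector of length `5 * width` (115 by default).
#' @export
encode_factors <- function(peptide, table = atchley_factors(), width = 23L) {
  r <- .check_peptide(peptide, width)
  v <- as.vector(t(table[r, , drop = FALSE]))  # site-major, F1..F5 within site
  setNames(v, paste0("F", rep(1:5, width), "_site", rep(seq_len(width), each = 5L)))
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For each spacing k in 1..`kmax` and each ordered pair (a, b) over the
#' 21-letter alphabet, counts window positions p with `window[p] == a` and
#' `window[p + k + 1] == b` (exactly k intervening residues). With
#' `normalize = TRUE` counts are divided by the number of k-spaced
#' positions in the window, `width - k - 1`. Blocks are ordered by
#' increasing k; within a block pairs are row-major (first letter major).
#'
#' @inheritParams encode_frequency
#' @param kmax Largest spacing (default 4; must be in 1..width-2).
#' @param normalize Divide counts by `width - k - 1`? Default `TRUE`.
#' @return Named numeric vector of length `441 * kmax`.
#' @export
#' @examples
#' v <- encode_cksaap(paste0("SAAAAW", strrep("O", 17)))
#' v["S^^^^W"]
encode_cksaap <- function(peptide, kmax = 4L, normalize = TRUE, width = 23L) {
  kmax <- as.integer(kmax)
  if (kmax < 1L || kmax > width - 2L) stop("kmax must be in 1..", width - 2L)
  r <- .check_peptide(peptide, width)
  fs_names <- .default_space(width, kmax)
  blocks <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    npos <- width - k - 1L
    a <- r[seq_len(npos)]
    b <- r[seq_len(npos) + k + 1L]
    counts <- tabulate(21L * (a - 1L) + b, nbins = 441L)
    blocks[[k]] <- if (normalize) counts / npos else counts
  }
  v <- unlist(blocks, use.names = FALSE)
  names(v) <- fs_names$name[fs_names$block == "cksaap"]
  v
}

#' Encode windows into a feature matrix
#'
#' Concatenates the three blocks -- `[frequency | factors | cksaap]` -- for
#' each window, yielding the canonical 1900-column matrix at the defaults
#' (width 23, kmax 4).
#'
#' @param windows `data.frame` from [build_dataset()] (columns `peptide`,
#'   `label`; `protein_id`/`position` used for sample IDs when present), or
#'   a character vector of peptides (labels then default to `NA`).
#' @param kmax Largest CKSAAP spacing.
#' @param normalize Normalize CKSAAP counts?
#' @param table Atchley factor table.
#' @param width Window width.
#' @return An object of class `feature_matrix`: list with `x` (numeric
#'   matrix, canonical feature names as colnames), `labels` (+1/-1 or NA),
#'   `sample_ids`, and the encoding parameters.
#' @export
encode_windows <- function(windows, kmax = 4L, normalize = TRUE,
                           table = atchley_factors(), width = 23L) {
  if (is.character(windows)) {
    windows <- data.frame(peptide = windows,
                          label = NA_integer_,
                          stringsAsFactors = FALSE)
  }
  if (nrow(windows) == 0L) stop("no windows to encode")
  ids <- if (all(c("protein_id", "position") %in% names(windows))) {
    paste0(windows$protein_id, ":", windows$position)
  } else {
    paste0("w", seq_len(nrow(windows)))
  }
  x <- t(vapply(windows$peptide, function(p) {
    c(encode_frequency(p, width),
      encode_factors(p, table, width),
      encode_cksaap(p, kmax, normalize, width))
  }, numeric(21L + 5L * width + 441L * kmax), USE.NAMES = FALSE))
  rownames(x) <- ids
  colnames(x) <- .default_space(width, kmax)$name
  structure(
    list(x = x, labels = as.integer(windows$label), sample_ids = ids,
         kmax = as.integer(kmax), normalize = normalize, width = as.integer(width)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$x), "samples x", ncol(x$x), "features",
      sprintf("(width %d, kmax %d, %s counts)\n", x$width, x$kmax,
              if (x$normalize) "normalized" else "raw"))
  if (!all(is.na(x$labels))) {
    cat("labels: ", sum(x$labels == 1L, na.rm = TRUE), " positive / ",
        sum(x$labels == -1L, na.rm = TRUE), " negative\n", sep = "")
  }
  invisible(x)
}

#' Write / read a feature matrix as delimited text
#'
#' Values are serialised with `%.17g`, which round-trips IEEE doubles
#' bit-exactly, so `read_feature_matrix(write_feature_matrix(fm, p))`
#' reproduces `fm$x` identically.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path (TSV: `sample_id`, `label`, then one column per
#'   canonical feature name).
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns a `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  vals <- matrix(sprintf("%.17g", fm$x), nrow = nrow(fm$x))
  meta <- sprintf("#glysite feature_matrix width=%d kmax=%d normalize=%s",
                  fm$width, fm$kmax, fm$normalize)
  header <- paste(c("sample_id", "label", colnames(fm$x)), collapse = "\t")
  body <- do.call(paste, c(list(fm$sample_ids, fm$labels, sep = "\t"),
                           lapply(seq_len(ncol(vals)), function(j) vals[, j])))
  writeLines(c(meta, header, body), path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- list(width = 23L, kmax = 4L, normalize = TRUE)
  if (startsWith(header, "#glysite feature_matrix")) {
    kv <- regmatches(header, gregexpr("[a-z]+=[^ ]+", header))[[1]]
    for (p in kv) {
      key <- sub("=.*", "", p); val <- sub(".*=", "", p)
      meta[[key]] <- if (key == "normalize") as.logical(val) else as.integer(val)
    }
  }
  dt <- data.table::fread(path, sep = "\t", skip = 1L, header = TRUE,
                          data.table = FALSE)
  x <- as.matrix(dt[, -(1:2), drop = FALSE])
  rownames(x) <- dt$sample_id
  structure(
    list(x = x, labels = as.integer(dt$label), sample_ids = dt$sample_id,
         kmax = meta$kmax, normalize = meta$normalize, width = meta$width),
    class = "feature_matrix"
  )
}
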