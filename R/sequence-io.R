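#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and whitespace-stripped; entry order is
#' preserved. Under `strict = TRUE` (the default) any character outside the
#' 20 standard one-letter codes aborts with an error naming the protein and
#' the offending character; under `strict = FALSE` non-standard letters
#' (B, J, O, U, X, Z, ...) are mapped to the padding letter `O`.
#'
#' @param path Path to a FASTA file.
#' @param strict Reject non-standard residues? Default `TRUE`.
#' @return A `data.frame` with columns `id` (first whitespace-delimited
#'   token of the header) and `sequence`.
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  std <- paste(aa_alphabet()[1:20], collapse = "")
  bad <- gsub(paste0("[", std, "]"), "", seqs)
  if (any(nchar(bad) > 0L)) {
    off <- which(nchar(bad) > 0L)
    if (strict) {
      stop("non-standard residue(s) in protein '", ids[off[1]], "': ",
           paste(unique(strsplit(bad[off[1]], "")[[1]]), collapse = ", "),
           " (use strict = FALSE to map them to the padding letter O)")
    }
    for (i in off) {
      seqs[i] <- gsub(paste0("[^", std, "]"), "O", seqs[i])
    }
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for protein '", ids[which(nchar(seqs) == 0L)[1]], "'")
  }
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Read site annotations
#'
#' Parses a delimited text file with columns `protein_id`, `position`
#' (1-based residue index) and `label`. A header line is detected
#' automatically. Labels are normalised to +1 / -1: `1`, `+1`, `pos`,
#' `positive` map to +1; `-1`, `0`, `neg`, `negative` map to -1.
#'
#' @param path Path to the annotation file.
#' @param sep Field delimiter, `"\t"` (default) or `","`.
#' @return A `data.frame` with columns `protein_id`, `position` (integer),
#'   `label` (integer in {-1, +1}).
#' @export
read_annotations <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  dt <- data.table::fread(path, sep = sep, header = "auto",
                          colClasses = "character", data.table = FALSE)
  if (ncol(dt) < 3L) stop("annotation file needs 3 columns: protein_id, position, label")
  dt <- dt[, 1:3]
  names(dt) <- c("protein_id", "position", "label")
  pos <- suppressWarnings(as.integer(dt$position))
  if (anyNA(pos)) {
    stop("non-integer position in annotation row(s): ",
         paste(which(is.na(pos)), collapse = ", "))
  }
  if (any(pos < 1L)) stop("position must be >= 1 (1-based coordinates)")
  lab <- .normalize_labels(dt$label)
  data.frame(protein_id = dt$protein_id, position = pos, label = lab,
             stringsAsFactors = FALSE)
}

.normalize_labels <- function(tokens) {
  t <- tolower(trimws(tokens))
  lab <- ifelse(t %in% c("1", "+1", "pos", "positive"), 1L,
         ifelse(t %in% c("-1", "0", "neg", "negative"), -1L, NA_integer_))
  if (anyNA(lab)) {
    stop("unknown label token(s): ", paste(unique(tokens[is.na(lab)]), collapse = ", "))
  }
  lab
}

#' Extract a fixed-width peptide window around a site
#'
#' Returns the `2 * flank + 1`-residue window centred on `position`
#' (1-based); positions beyond either protein terminus are filled with the
#' padding letter `O`, and the number of padded positions is recorded.
#'
#' @param sequence Protein sequence string.
#' @param position 1-based residue index of the candidate site.
#' @param flank Residues on each side (default 11, window width 23).
#' @return A list with `peptide` (string of length `2*flank+1`),
#'   `center_residue`, and `pad_count`.
#' @export
#' @examples
#' extract_window("ACDEFGHIKLMNPQRSTVWY", 9)$peptide
extract_window <- function(sequence, position, flank = 11L) {
  n <- nchar(sequence)
  position <- as.integer(position)
  if (position < 1L || position > n) {
    stop("position ", position, " out of range 1..", n)
  }
  lo <- position - flank
  hi <- position + flank
  core <- substr(sequence, max(1L, lo), min(n, hi))
  left <- max(0L, 1L - lo)
  right <- max(0L, hi - n)
  list(
    peptide = paste0(strrep("O", left), core, strrep("O", right)),
    center_residue = substr(sequence, position, position),
    pad_count = left + right
  )
}

#' Build a window dataset from proteins and annotations
#'
#' Extracts one window per annotation, optionally dropping heavily padded
#' windows. The center residue is not required to be lysine, but non-K
#' centers trigger a warning (an error with `strict_center = TRUE`) since
#' the intended use is lysine glycation.
#'
#' @param proteins `data.frame` from [read_fasta()].
#' @param annotations `data.frame` from [read_annotations()].
#' @param flank Residues on each side of the site (default 11).
#' @param max_pad Drop windows with more than this many padding `O`s
#'   (default `NULL`: keep all).
#' @param strict_center Error (instead of warn) on non-K centers.
#' @return A `data.frame` with columns `protein_id`, `position`, `label`,
#'   `peptide`, `center_residue`, `pad_count`; attribute `"dropped"` holds
#'   per-class drop counts when `max_pad` is set.
#' @export
build_dataset <- function(proteins, annotations, flank = 11L,
                          max_pad = NULL, strict_center = FALSE) {
  missing_ids <- setdiff(annotations$protein_id, proteins$id)
  if (length(missing_ids) > 0L) {
    stop("annotation(s) reference unknown protein ID(s): ",
         paste(unique(missing_ids), collapse = ", "))
  }
  seqs <- setNames(proteins$sequence, proteins$id)
  win <- mapply(function(pid, pos) {
    w <- extract_window(seqs[[pid]], pos, flank)
    c(w$peptide, w$center_residue, w$pad_count)
  }, annotations$protein_id, annotations$position, SIMPLIFY = TRUE)
  out <- data.frame(
    protein_id = annotations$protein_id,
    position = annotations$position,
    label = annotations$label,
    peptide = win[1, ],
    center_residue = win[2, ],
    pad_count = as.integer(win[3, ]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  nonk <- sum(out$center_residue != "K")
  if (nonk > 0L) {
    msg <- paste0(nonk, " window(s) are not centered on lysine (K)")
    if (strict_center) stop(msg) else warning(msg)
  }
  if (!is.null(max_pad)) {
    drop <- out$pad_count > max_pad
    dropped <- c(positive = sum(drop & out$label == 1L),
                 negative = sum(drop & out$label == -1L))
    message("max_pad = ", max_pad, ": kept ", sum(!drop), " window(s), dropped ",
            sum(drop), " (", dropped[["positive"]], " positive, ",
            dropped[["negative"]], " negative)")
    out <- out[!drop, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "dropped") <- dropped
  }
  out
}

#' Write / read extracted windows as TSV
#'
#' @param windows `data.frame` from [build_dataset()].
#' @param path Output path.
#' @return `write_windows` returns `path` invisibly; `read_windows`
#'   returns the windows `data.frame`.
#' @export
write_windows <- function(windows, path) {
  data.table::fwrite(windows, path, sep = "\t")
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  out <- data.table::fread(path, sep = "\t", data.table = FALSE,
                           colClasses = list(character = "protein_id"))
  out$label <- as.integer(out$label)
  out$position <- as.integer(out$position)
  out$pad_count <- as.integer(out$pad_count)
  out
}

#' Write proteins to a FASTA file
#'
#' @param proteins `data.frame` with columns `id`, `sequence`.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$id[i]), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
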