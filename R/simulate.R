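#' Specification for a synthetic glycation benchmark
#'
#' Describes a seeded synthetic world: random background proteins with
#' lysine-centred candidate sites, where positive sites may carry planted
#' k-spaced pair signal and/or a physicochemical bias at one window site.
#' Defaults mirror the scale of the published benchmark (89 positive and
#' 126 negative sites).
#'
#' @param n_pos,n_neg Numbers of positive / negative sites.
#' @param protein_length Length of each synthetic protein (default 200).
#' @param planted_pairs List of planted pair signals, each a list with
#'   letters `a`, `b`, spacing `k` and enrichment probability `pi`: each
#'   positive window receives the pair (placed so it spans the window
#'   centre) with probability `pi`; negative windows only ever contain it
#'   by background chance. Default: one (S, W, k = 4) pair at pi = 0.9.
#' @param factor_shift Optional list `(site, factor, delta)`: residues at
#'   that window site in positive windows are drawn with Boltzmann weights
#'   `exp(delta * score)` over the Atchley factor scores.
#' @param background Per-letter sampling weights over the 20 standard
#'   amino acids (default uniform).
#' @param seed Integer seed; the whole fixture is a pure function of the
#'   spec.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_pos = 89L, n_neg = 126L, protein_length = 200L,
                         planted_pairs = list(list(a = "S", b = "W", k = 4L,
                                                   pi = 0.9)),
                         factor_shift = NULL,
                         background = NULL, seed = 1L) {
  if (n_pos < 1L || n_neg < 1L) stop("need at least one site per class")
  for (pp in planted_pairs) {
    if (pp$pi < 0 || pp$pi > 1) stop("enrichment probability must be in [0, 1]")
    if (pp$k > 21L) stop("planted pair with k = ", pp$k, " cannot fit a 23-mer")
  }
  if (is.null(background)) background <- rep(1 / 20, 20L)
  if (length(background) != 20L) stop("background must have 20 weights")
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         protein_length = as.integer(protein_length),
         planted_pairs = planted_pairs, factor_shift = factor_shift,
         background = background / sum(background), seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# window sites (1..23) of a planted pair with spacing k, straddling the
# centre (site 12) without touching it
.plant_sites <- function(k) {
  a_site <- 12L - as.integer(ceiling((k + 1) / 2))
  b_site <- a_site + k + 1L
  if (b_site == 12L || a_site == 12L) {
    a_site <- a_site - 1L
    b_site <- b_site - 1L
  }
  c(a = a_site, b = b_site)
}

#' Generate a synthetic annotated protein set
#'
#' Draws proteins from the background letter distribution, plants a lysine
#' at each candidate site (both classes are K-centred, so only the planted
#' signal separates them), applies the planted pair / factor-shift signal
#' to positive sites, and returns proteins plus annotations ready for
#' [build_dataset()]. Site centres are spaced 25 residues apart so windows
#' never overlap. Byte-identical output for identical specs.
#'
#' @param spec A [fixture_spec()].
#' @return List with `proteins` (`data.frame`: id, sequence) and
#'   `annotations` (`data.frame`: protein_id, position, label).
#' @export
#' @examples
#' fx <- simulate_glycation(fixture_spec(n_pos = 5, n_neg = 5))
#' head(fx$annotations)
simulate_glycation <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  aa20 <- aa_alphabet()[1:20]
  if (spec$protein_length < 23L) {
    stop("protein_length too short for a 23-mer window")
  }
  centers <- seq(12L, spec$protein_length - 11L, by = 25L)
  n_sites <- spec$n_pos + spec$n_neg
  n_prot <- as.integer(ceiling(n_sites / length(centers)))

  withr::with_seed(spec$seed, {
    labels <- sample(c(rep(1L, spec$n_pos), rep(-1L, spec$n_neg)))
    prot_seq <- vector("character", n_prot)
    ann <- vector("list", n_sites)
    site_i <- 0L
    for (pr in seq_len(n_prot)) {
      s <- sample(aa20, spec$protein_length, replace = TRUE,
                  prob = spec$background)
      for (ct in centers) {
        if (site_i >= n_sites) break
        site_i <- site_i + 1L
        lab <- labels[site_i]
        s[ct] <- "K"
        if (lab == 1L) {
          for (pp in spec$planted_pairs) {
            if (stats::runif(1) < pp$pi) {
              ps <- .plant_sites(pp$k)
              s[ct + (ps[["a"]] - 12L)] <- pp$a
              s[ct + (ps[["b"]] - 12L)] <- pp$b
            }
          }
          if (!is.null(spec$factor_shift)) {
            fsh <- spec$factor_shift
            if (fsh$site != 12L) {
              w <- spec$background *
                exp(fsh$delta * atchley_factors()[aa20, fsh$factor])
              s[ct + (fsh$site - 12L)] <- sample(aa20, 1L, prob = w / sum(w))
            }
          }
        }
        ann[[site_i]] <- data.frame(
          protein_id = sprintf("syn%03d", pr), position = ct, label = lab,
          stringsAsFactors = FALSE
        )
      }
      prot_seq[pr] <- paste(s, collapse = "")
    }
  })
  list(
    proteins = data.frame(id = sprintf("syn%03d", seq_len(n_prot)),
                          sequence = prot_seq, stringsAsFactors = FALSE),
    annotations = do.call(rbind, ann)
  )
}

#' Write a fixture to FASTA + annotation TSV
#'
#' @param fixture Output of [simulate_glycation()].
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_fixture <- function(fixture, fasta_path, annotation_path) {
  write_fasta(fixture$proteins, fasta_path)
  data.table::fwrite(fixture$annotations, annotation_path, sep = "\t")
  invisible(c(fasta_path, annotation_path))
}
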