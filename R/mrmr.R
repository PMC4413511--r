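#' Three-state discretization of a continuous feature
#'
#' Maps values below mean - theta * sd to state 1 (low), above
#' mean + theta * sd to state 3 (high), and to state 2 (mid) otherwise.
#' Constant vectors (sd 0) map entirely to mid. This seedless scheme is the
#' usual preprocessing for mutual-information feature ranking on continuous
#' features.
#'
#' @param values Numeric vector, or an already-categorical vector when
#'   `categorical = TRUE` (passed through as integer codes).
#' @param theta Threshold width in standard deviations (default 1).
#' @param categorical Treat `values` as categorical codes (no-op path)?
#' @return Integer vector of states.
#' @export
discretize <- function(values, theta = 1, categorical = FALSE) {
  if (categorical) {
    return(as.integer(factor(values)))
  }
  if (length(values) == 0L) stop("empty vector")
  mu <- mean(values)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(rep(2L, length(values)))
  ifelse(values < mu - theta * s, 1L, ifelse(values > mu + theta * s, 3L, 2L))
}

# column-wise three-state discretization, returns integer matrix of 1..3
.discretize_matrix <- function(x, theta = 1) {
  mu <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  lo <- sweep(x, 2L, mu - theta * s, "<")
  hi <- sweep(x, 2L, mu + theta * s, ">")
  d <- matrix(2L, nrow(x), ncol(x))
  d[lo] <- 1L
  d[hi] <- 3L
  d[, s == 0] <- 2L
  d
}

#' Mutual information of two categorical vectors
#'
#' Plug-in (empirical) estimator on the joint distribution, in bits
#' (log base 2). Non-negative; zero when the empirical joint factorises.
#'
#' @param x,y Vectors of equal length, treated as categorical.
#' @return Mutual information in bits.
#' @export
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 1 bit
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) == 0L) stop("empty vectors")
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

# MI (bits) of one coded vector against every column of a coded matrix.
# Uses indicator cross-products: for states a of x and b of D, the joint
# count n_ab per column is t(1[x==a]) %*% 1[D==b].
.mi_vs_matrix <- function(xcode, dmat, dstates = 3L) {
  n <- length(xcode)
  xs <- sort(unique(xcode))
  ix <- matrix(0, n, length(xs))
  for (i in seq_along(xs)) ix[, i] <- as.numeric(xcode == xs[i])
  mi <- numeric(ncol(dmat))
  px <- colSums(ix) / n
  for (b in seq_len(dstates)) {
    ib <- dmat == b
    storage.mode(ib) <- "double"
    nab <- crossprod(ix, ib)            # |xs| x p joint counts for state b
    pab <- nab / n
    pb <- colSums(ib) / n               # marginal of D state b, per column
    denom <- outer(px, pb)              # |xs| x p
    term <- pab * log2(pab / denom)
    term[pab == 0] <- 0
    mi <- mi + colSums(term)
  }
  mi
}

#' mRMR feature ranking
#'
#' Greedy minimum-redundancy maximum-relevance ranking. Step 1 selects the
#' feature with the largest mutual information with the class label
#' (relevance); each subsequent step selects the candidate maximising
#' relevance minus the mean mutual information with the already-selected
#' set (redundancy). Ties break to the smaller feature index. Features are
#' discretized with the three-state mean +/- theta * sd scheme; labels are
#' used as two categories directly.
#'
#' @param fm A `feature_matrix` with labels in {-1, +1}.
#' @param theta Discretization width (default 1).
#' @param top_n Rank only the first `top_n` features (default: all --
#'   a full permutation, which IFS consumes prefix by prefix).
#' @return An object of class `mrmr_ranking`: `order` (selected feature
#'   indices, in rank order), `relevance` (per-feature I(f, c), all
#'   features), `step_scores` (criterion value at each selection),
#'   `feature_names`.
#' @export
mrmr_rank <- function(fm, theta = 1, top_n = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- fm$labels
  if (length(unique(y)) < 2L) stop("labels are degenerate (single class)")
  if (nrow(fm$x) < 2L) stop("need at least 2 samples")
  p <- ncol(fm$x)
  top_n <- if (is.null(top_n)) p else min(as.integer(top_n), p)

  d <- .discretize_matrix(fm$x, theta)
  relevance <- .mi_vs_matrix(as.integer(factor(y)), d)

  order_sel <- integer(top_n)
  step_scores <- numeric(top_n)
  redsum <- numeric(p)        # sum over selected of I(f_j, f_i)
  active <- rep(TRUE, p)

  for (step in seq_len(top_n)) {
    score <- if (step == 1L) relevance else relevance - redsum / (step - 1L)
    score[!active] <- -Inf
    j <- which.max(score)     # first max = smallest index on ties
    order_sel[step] <- j
    step_scores[step] <- score[j]
    active[j] <- FALSE
    if (step < top_n) {
      redsum <- redsum + .mi_vs_matrix(d[, j], d)
    }
  }
  structure(
    list(order = order_sel, relevance = relevance,
         step_scores = step_scores,
         feature_names = colnames(fm$x)),
    class = "mrmr_ranking"
  )
}

#' @export
print.mrmr_ranking <- function(x, ...) {
  cat("mrmr_ranking:", length(x$order), "of", length(x$relevance),
      "features ranked\n")
  top <- utils::head(x$order, 5L)
  cat("top:", paste(sprintf("%s(#%d)", x$feature_names[top], top),
                    collapse = ", "), "\n")
  invisible(x)
}

#' Write / read an mRMR ranking as TSV
#'
#' Columns: `rank`, `feature_index`, `feature_name`, `relevance`,
#' `criterion_score`.
#'
#' @param ranking An `mrmr_ranking`.
#' @param path Output path.
#' @return `write_ranking` returns `path` invisibly; `read_ranking` the
#'   ranking object (relevance only for ranked features).
#' @export
write_ranking <- function(ranking, path) {
  dt <- data.frame(
    rank = seq_along(ranking$order),
    feature_index = ranking$order,
    feature_name = ranking$feature_names[ranking$order],
    relevance = sprintf("%.17g", ranking$relevance[ranking$order]),
    criterion_score = sprintf("%.17g", ranking$step_scores)
  )
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  nfeat <- max(dt$feature_index)
  relevance <- rep(NA_real_, nfeat)
  relevance[dt$feature_index] <- dt$relevance
  nm <- rep(NA_character_, nfeat)
  nm[dt$feature_index] <- dt$feature_name
  structure(
    list(order = dt$feature_index, relevance = relevance,
         step_scores = dt$criterion_score, feature_names = nm),
    class = "mrmr_ranking"
  )
}
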