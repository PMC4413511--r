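#' Stratified cross-validation fold assignment
#'
#' Shuffles each class independently (seeded) and deals samples into k
#' folds round-robin, so every fold's class composition is within one
#' sample of the global ratio. Deterministic given the seed; the caller's
#' RNG state is untouched.
#'
#' @param labels Vector in {-1, +1}.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  k <- as.integer(k)
  cls <- unique(labels)
  if (k > min(table(labels))) {
    stop("k = ", k, " exceeds the minority class size (", min(table(labels)), ")")
  }
  folds <- integer(length(labels))
  offset <- 0L
  withr::with_seed(as.integer(seed), {
    for (cl in sort(cls)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      # continue the round-robin across classes so total fold sizes also
      # stay within one sample of each other
      folds[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  folds
}

#' Default (C, gamma) grid for the RBF SVM
#'
#' The standard coarse RBF lattice: C = 2^-5, 2^-3, ..., 2^15 and
#' gamma = 2^-15, 2^-13, ..., 2^3.
#'
#' @param log2C,log2gamma Exponent sequences.
#' @return `data.frame` with columns `C`, `gamma`, one row per lattice
#'   point.
#' @export
svm_grid <- function(log2C = seq(-5, 15, by = 2),
                     log2gamma = seq(-15, 3, by = 2)) {
  g <- expand.grid(C = 2^log2C, gamma = 2^log2gamma,
                   KEEP.OUT.ATTRS = FALSE)
  g[order(g$C, g$gamma), , drop = FALSE]
}

#' Grid-searched SVM under stratified k-fold cross-validation
#'
#' For every (C, gamma) lattice point, trains on k-1 folds and predicts
#' the held-out fold; held-out predictions are pooled over the k folds
#' into a single confusion table per lattice point. Features are scaled to
#' [-1, 1] using training-fold ranges only. The winning configuration
#' maximises pooled MCC, with ties resolved by larger accuracy, then
#' smaller C, then smaller gamma.
#'
#' @param x Numeric matrix (samples x features) or a `feature_matrix`.
#' @param labels Labels in {-1, +1} (ignored when `x` is a
#'   `feature_matrix`).
#' @param grid `data.frame` of `C`, `gamma` (default [svm_grid()]).
#' @param k Folds (default 10).
#' @param seed Seed for the fold split (default 1).
#' @param folds Optional precomputed fold assignment (overrides k/seed).
#' @return List: `best` (list `C`, `gamma`), `counts` (pooled confusion
#'   list for the best point), `metrics`, and `table` (per-point results).
#' @export
grid_search_cv <- function(x, labels = NULL, grid = svm_grid(), k = 10L,
                           seed = 1L, folds = NULL) {
  if (inherits(x, "feature_matrix")) {
    labels <- x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid")
  if (length(unique(labels)) < 2L) stop("labels are degenerate (single class)")
  if (is.null(folds)) folds <- stratified_folds(labels, k, seed)
  nfold <- max(folds)

  ng <- nrow(grid)
  tp <- fp <- tn <- fn <- integer(ng)
  for (f in seq_len(nfold)) {
    tr <- folds != f
    sc <- .scale_fit(x[tr, , drop = FALSE])
    xtr <- .scale_apply(x[tr, , drop = FALSE], sc)
    xte <- .scale_apply(x[!tr, , drop = FALSE], sc)
    d2tr <- sqdist_cpp(xtr, xtr)
    d2te <- sqdist_cpp(xte, xtr)
    ytr <- labels[tr]
    yte <- labels[!tr]
    for (g in seq_len(ng)) {
      fit <- smo_train_cpp(d2tr, as.integer(ytr), grid$C[g], grid$gamma[g])
      sv <- fit$alpha > 0
      dec <- if (any(sv)) {
        drop(exp(-grid$gamma[g] * d2te[, sv, drop = FALSE]) %*%
               (fit$alpha[sv] * ytr[sv])) + fit$b
      } else {
        rep(fit$b, sum(!tr))
      }
      pred <- ifelse(dec >= 0, 1L, -1L)
      tp[g] <- tp[g] + sum(yte == 1L & pred == 1L)
      fp[g] <- fp[g] + sum(yte == -1L & pred == 1L)
      tn[g] <- tn[g] + sum(yte == -1L & pred == -1L)
      fn[g] <- fn[g] + sum(yte == 1L & pred == -1L)
    }
  }
  met <- lapply(seq_len(ng), function(g)
    compute_metrics(list(TP = tp[g], FP = fp[g], TN = tn[g], FN = fn[g])))
  tab <- data.frame(
    C = grid$C, gamma = grid$gamma,
    TP = tp, FP = fp, TN = tn, FN = fn,
    Sn = vapply(met, `[[`, numeric(1), "Sn"),
    Sp = vapply(met, `[[`, numeric(1), "Sp"),
    Ac = vapply(met, `[[`, numeric(1), "Ac"),
    MCC = vapply(met, `[[`, numeric(1), "MCC")
  )
  best <- order(-tab$MCC, -tab$Ac, tab$C, tab$gamma)[1]
  list(
    best = list(C = tab$C[best], gamma = tab$gamma[best]),
    counts = list(TP = tab$TP[best], FP = tab$FP[best],
                  TN = tab$TN[best], FN = tab$FN[best]),
    metrics = met[[best]],
    table = tab
  )
}

#' Incremental feature selection over an mRMR ranking
#'
#' Evaluates growing prefixes of the ranked feature list: for prefix size
#' i the matrix is restricted to the top-i ranked features and a
#' grid-searched, cross-validated SVM is scored. The optimal subset is the
#' prefix with the largest pooled cross-validation MCC (ties to the
#' smallest size). The same fold split (derived from `seed`) is used for
#' every prefix so curve points are comparable.
#'
#' @param fm A `feature_matrix`.
#' @param ranking An `mrmr_ranking` over the matrix's features.
#' @param sizes Integer vector of prefix sizes, or `"all"` (every size up
#'   to the number of ranked features, thinned by `stride`).
#' @param grid Hyperparameter lattice (default [svm_grid()]).
#' @param k Folds.
#' @param seed Seed for the fold split.
#' @param stride With `sizes = "all"`, evaluate every `stride`-th size.
#' @return An object of class `ifs_result`: `curve` (one row per size:
#'   size, C, gamma, confusion counts, Sn, Sp, Ac, MCC), `optimal_size`,
#'   `optimal_features` (canonical indices), `seed`.
#' @export
run_ifs <- function(fm, ranking, sizes = "all", grid = svm_grid(), k = 10L,
                    seed = 1L, stride = 1L) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(ranking, "mrmr_ranking"))
  nranked <- length(ranking$order)
  if (identical(sizes, "all")) {
    sizes <- seq(1L, nranked, by = as.integer(stride))
  }
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L) stop("empty prefix size list")
  if (any(sizes < 1L | sizes > nranked)) {
    stop("prefix sizes must be in 1..", nranked)
  }
  folds <- stratified_folds(fm$labels, k, seed)
  rows <- vector("list", length(sizes))
  for (s in seq_along(sizes)) {
    feats <- ranking$order[seq_len(sizes[s])]
    gs <- grid_search_cv(fm$x[, feats, drop = FALSE], fm$labels,
                         grid = grid, folds = folds)
    rows[[s]] <- data.frame(
      size = sizes[s], C = gs$best$C, gamma = gs$best$gamma,
      TP = gs$counts$TP, FP = gs$counts$FP,
      TN = gs$counts$TN, FN = gs$counts$FN,
      Sn = gs$metrics$Sn, Sp = gs$metrics$Sp,
      Ac = gs$metrics$Ac, MCC = gs$metrics$MCC
    )
  }
  curve <- do.call(rbind, rows)
  opt <- order(-curve$MCC, curve$size)[1]
  structure(
    list(curve = curve,
         optimal_size = curve$size[opt],
         optimal_features = ranking$order[seq_len(curve$size[opt])],
         best_config = list(C = curve$C[opt], gamma = curve$gamma[opt]),
         seed = as.integer(seed)),
    class = "ifs_result"
  )
}

#' @export
print.ifs_result <- function(x, ...) {
  cat("ifs_result:", nrow(x$curve), "prefix size(s); optimal size",
      x$optimal_size, sprintf("(MCC %.4f)\n",
                              x$curve$MCC[x$curve$size == x$optimal_size][1]))
  invisible(x)
}

#' Write an IFS curve as TSV
#'
#' @param result An `ifs_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ifs_curve <- function(result, path) {
  data.table::fwrite(result$curve, path, sep = "\t")
  invisible(path)
}

#' Train the final predictor on a chosen feature subset
#'
#' Scales the full matrix to [-1, 1], fits the RBF SVM with the chosen
#' hyperparameters on all samples, and packages everything needed to score
#' new peptide windows (feature subset, scaling, encoder settings).
#'
#' @param fm A `feature_matrix`.
#' @param features Canonical feature indices (e.g.
#'   `ifs_result$optimal_features`).
#' @param config List with `C` and `gamma`.
#' @return An object of class `glysite_model`.
#' @export
train_final <- function(fm, features, config) {
  stopifnot(inherits(fm, "feature_matrix"))
  features <- as.integer(features)
  if (any(features < 1L | features > ncol(fm$x))) stop("invalid feature indices")
  xs <- fm$x[, features, drop = FALSE]
  sc <- .scale_fit(xs)
  fit <- svm_fit(.scale_apply(xs, sc), fm$labels,
                 C = config$C, gamma = config$gamma)
  structure(
    list(features = features,
         feature_names = colnames(fm$x)[features],
         scaling = sc, svm = fit,
         kmax = fm$kmax, normalize = fm$normalize, width = fm$width,
         schema_version = 1L),
    class = "glysite_model"
  )
}

#' Score peptide windows with a trained model
#'
#' Encodes the windows with the model's encoder settings, restricts to the
#' model's feature subset, applies its scaling and decision function.
#'
#' @param object A `glysite_model`.
#' @param windows Windows `data.frame` (from [build_dataset()]) or a
#'   character vector of peptides; may be empty.
#' @param ... Unused.
#' @return `data.frame` with `sample_id`, `decision`, `label` (+1 where
#'   the decision value is >= 0, else -1).
#' @export
predict.glysite_model <- function(object, windows, ...) {
  n <- if (is.character(windows)) length(windows) else nrow(windows)
  if (n == 0L) {
    return(data.frame(sample_id = character(0), decision = numeric(0),
                      label = integer(0)))
  }
  fm <- encode_windows(windows, kmax = object$kmax,
                       normalize = object$normalize, width = object$width)
  xs <- .scale_apply(fm$x[, object$features, drop = FALSE], object$scaling)
  dec <- svm_decision(object$svm, xs)
  data.frame(sample_id = fm$sample_ids, decision = dec,
             label = ifelse(dec >= 0, 1L, -1L))
}

#' @export
print.glysite_model <- function(x, ...) {
  cat("glysite_model:", length(x$features), "features, C =", x$svm$C,
      ", gamma =", x$svm$gamma, "\n")
  invisible(x)
}

# doubles serialised as %.17g strings so JSON round-trips bit-exactly
.num_out <- function(v) sprintf("%.17g", v)

#' Persist / restore a trained model
#'
#' Plain-text JSON with all numerics serialised at 17 significant digits,
#' so reloaded models reproduce decision values bit-identically.
#'
#' @param model A `glysite_model`.
#' @param path Output path.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "glysite_model"))
  obj <- list(
    schema_version = model$schema_version,
    features = model$features,
    feature_names = model$feature_names,
    scaling = list(center = .num_out(model$scaling$center),
                   half = .num_out(model$scaling$half)),
    svm = list(sv_x = .num_out(as.vector(model$svm$sv_x)),
               sv_n = nrow(model$svm$sv_x),
               coef = .num_out(model$svm$coef),
               b = .num_out(model$svm$b),
               gamma = .num_out(model$svm$gamma),
               C = .num_out(model$svm$C)),
    kmax = model$kmax, normalize = model$normalize, width = model$width
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sv_n <- as.integer(obj$svm$sv_n)
  sv_x <- matrix(as.numeric(obj$svm$sv_x), nrow = sv_n)
  colnames(sv_x) <- obj$feature_names
  svm <- structure(
    list(sv_x = sv_x, coef = as.numeric(obj$svm$coef),
         b = as.numeric(obj$svm$b), gamma = as.numeric(obj$svm$gamma),
         C = as.numeric(obj$svm$C), iterations = NA_integer_),
    class = "rbf_svm"
  )
  structure(
    list(features = as.integer(obj$features),
         feature_names = obj$feature_names,
         scaling = list(center = as.numeric(obj$scaling$center),
                        half = as.numeric(obj$scaling$half)),
         svm = svm, kmax = as.integer(obj$kmax),
         normalize = as.logical(obj$normalize),
         width = as.integer(obj$width),
         schema_version = as.integer(obj$schema_version)),
    class = "glysite_model"
  )
}

#' Summarise an optimal feature subset
#'
#' Tallies a feature subset by encoding block, by amino-acid class over
#' the letters involved, by window site (factor features) and by letter
#' (CKSAAP features). Classes: nonpolar {A G I L M P V}, polar
#' {C N Q S T}, charged {D E H K R}, aromatic {F W Y}; the padding letter
#' O is reported separately.
#'
#' @param features Canonical feature indices (or an `ifs_result`, whose
#'   optimal subset is used).
#' @param width,kmax Feature-space geometry.
#' @return List of data.frames: `by_block`, `by_class`, `factor_sites`,
#'   `cksaap_letters`.
#' @export
summarize_optimal_features <- function(features, width = 23L, kmax = 4L) {
  if (inherits(features, "ifs_result")) features <- features$optimal_features
  fs <- feature_name(features, width, kmax)
  by_block <- data.frame(
    block = c("frequency", "factor", "cksaap"),
    count = c(sum(fs$block == "frequency"), sum(fs$block == "factor"),
              sum(fs$block == "cksaap"))
  )
  classes <- c(A = "nonpolar", G = "nonpolar", I = "nonpolar", L = "nonpolar",
               M = "nonpolar", P = "nonpolar", V = "nonpolar",
               C = "polar", N = "polar", Q = "polar", S = "polar", T = "polar",
               D = "charged", E = "charged", H = "charged", K = "charged",
               R = "charged",
               F = "aromatic", W = "aromatic", Y = "aromatic",
               O = "padding")
  letters_used <- c(fs$letter[fs$block == "frequency"],
                    fs$a[fs$block == "cksaap"], fs$b[fs$block == "cksaap"])
  cl <- factor(classes[letters_used],
               levels = c("nonpolar", "polar", "charged", "aromatic", "padding"))
  by_class <- as.data.frame(table(class = cl), responseName = "count")
  fsite <- fs$site[fs$block == "factor"]
  factor_sites <- as.data.frame(
    table(site = factor(fsite, levels = seq_len(width))),
    responseName = "count"
  )
  factor_sites$site <- as.integer(as.character(factor_sites$site))
  ck_letters <- factor(c(fs$a[fs$block == "cksaap"], fs$b[fs$block == "cksaap"]),
                       levels = aa_alphabet())
  cksaap_letters <- as.data.frame(table(letter = ck_letters),
                                  responseName = "count")
  list(by_block = by_block, by_class = by_class,
       factor_sites = factor_sites, cksaap_letters = cksaap_letters)
}
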