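# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's vectorised code paths.

random_window <- function(width = 23L, letters = aa_alphabet()) {
  paste(sample(letters, width, replace = TRUE), collapse = "")
}

# per-letter counting oracle for the frequency block
naive_freq <- function(peptide) {
  s <- strsplit(peptide, "")[[1]]
  vapply(aa_alphabet(), function(l) sum(s == l), numeric(1)) / length(s)
}

# double-loop pair scan oracle for CKSAAP counts (unnormalized)
naive_cksaap_counts <- function(peptide, k) {
  s <- strsplit(peptide, "")[[1]]
  ab <- aa_alphabet()
  counts <- matrix(0L, 21L, 21L, dimnames = list(ab, ab))
  for (p in seq_len(length(s) - k - 1L)) {
    counts[s[p], s[p + k + 1L]] <- counts[s[p], s[p + k + 1L]] + 1L
  }
  # row-major (first letter major) flatten, matching the canonical order
  as.vector(t(counts))
}

# plug-in MI oracle via an explicit contingency-table double loop (bits)
mi_oracle <- function(x, y) {
  n <- length(x)
  ux <- unique(x)
  uy <- unique(y)
  total <- 0
  for (a in ux) {
    for (b in uy) {
      pab <- sum(x == a & y == b) / n
      if (pab > 0) {
        total <- total + pab * log2(pab / ((sum(x == a) / n) * (sum(y == b) / n)))
      }
    }
  }
  total
}

# independent three-state discretizer (mean +/- theta * sd)
disc_oracle <- function(v, theta = 1) {
  s <- sd(v)
  if (is.na(s) || s == 0) return(rep(2L, length(v)))
  out <- rep(2L, length(v))
  out[v < mean(v) - theta * s] <- 1L
  out[v > mean(v) + theta * s] <- 3L
  out
}

# exhaustive greedy mRMR oracle: evaluates the criterion for every
# candidate at every step using mi_oracle only
mrmr_oracle <- function(x, labels, theta = 1) {
  d <- apply(x, 2L, disc_oracle, theta = theta)
  p <- ncol(x)
  rel <- vapply(seq_len(p), function(j) mi_oracle(d[, j], labels), numeric(1))
  selected <- integer(0)
  remaining <- seq_len(p)
  while (length(remaining) > 0L) {
    scores <- vapply(remaining, function(j) {
      if (length(selected) == 0L) return(rel[j])
      red <- mean(vapply(selected, function(i) mi_oracle(d[, j], d[, i]),
                         numeric(1)))
      rel[j] - red
    }, numeric(1))
    pick <- remaining[which.max(scores)]  # ties -> smallest index
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

# closed-form metrics oracle written independently of compute_metrics
metrics_oracle <- function(tp, fp, tn, fn) {
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  ac <- (tp + tn) / (tp + fp + tn + fn)
  d <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  mcc <- if (d == 0) 0 else (tp * tn - fn * fp) / d
  list(Sn = sn, Sp = sp, Ac = ac, MCC = mcc)
}

# bare feature_matrix constructor for selector/classifier tests
fm_from_matrix <- function(x, labels) {
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(
    list(x = x, labels = as.integer(labels),
         sample_ids = paste0("s", seq_len(nrow(x))),
         kmax = 4L, normalize = TRUE, width = 23L),
    class = "feature_matrix"
  )
}

# small two-feature dataset separable by the first feature
separable_data <- function(n_per_class = 20L, seed = 1L) {
  withr::with_seed(seed, {
    x <- rbind(
      cbind(rnorm(n_per_class, 2, 0.3), rnorm(n_per_class)),
      cbind(rnorm(n_per_class, -2, 0.3), rnorm(n_per_class))
    )
    list(x = x, y = rep(c(1L, -1L), each = n_per_class))
  })
}
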