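test_that("stratified_folds balances classes and is seed-deterministic", {
  labels <- rep(c(1L, -1L), each = 10)
  f <- stratified_folds(labels, k = 10, seed = 3)
  tab <- table(f, labels)
  expect_true(all(tab == 1))  # 10/10 split: one of each class per fold

  expect_identical(stratified_folds(labels, k = 10, seed = 3), f)
  expect_false(identical(stratified_folds(labels, k = 10, seed = 4), f))

  # benchmark-scale split: fold sizes within 1, per-fold positives in {8, 9}
  big <- c(rep(1L, 89), rep(-1L, 126))
  fb <- stratified_folds(big, k = 10, seed = 1)
  expect_true(max(table(fb)) - min(table(fb)) <= 1)
  pos_per_fold <- table(fb[big == 1L])
  expect_true(all(pos_per_fold %in% c(8L, 9L)))

  expect_error(stratified_folds(c(1L, 1L, -1L), k = 2), "minority")
})

test_that("grid_search_cv finds a separating config and pools counts", {
  d <- separable_data(n_per_class = 15, seed = 6)
  grid <- svm_grid(log2C = c(0, 4), log2gamma = c(-3, 0))
  gs <- grid_search_cv(d$x, d$y, grid = grid, k = 5, seed = 1)
  expect_equal(gs$metrics$MCC, 1)
  # pooled counts cover every sample exactly once, for every grid point
  expect_true(all(gs$table$TP + gs$table$FN == 15))
  expect_true(all(gs$table$TN + gs$table$FP == 15))

  single <- grid_search_cv(d$x, d$y, grid = data.frame(C = 1, gamma = 0.5),
                           k = 5, seed = 1)
  expect_equal(single$best, list(C = 1, gamma = 0.5))
  expect_error(grid_search_cv(d$x, d$y, grid = data.frame()[0, ]), "grid")
})

test_that("ties in grid selection prefer larger Ac, then smaller C and gamma", {
  tab_order <- function(tab) order(-tab$MCC, -tab$Ac, tab$C, tab$gamma)[1]
  tab <- data.frame(C = c(4, 1, 1), gamma = c(0.1, 0.5, 0.1),
                    MCC = c(0.5, 0.5, 0.5), Ac = c(0.8, 0.8, 0.8))
  expect_equal(tab_order(tab), 3L)  # smallest C wins, then smaller gamma
  tab2 <- data.frame(C = c(1, 4), gamma = c(0.1, 0.1),
                     MCC = c(0.5, 0.5), Ac = c(0.7, 0.9))
  expect_equal(tab_order(tab2), 2L)  # larger Ac beats smaller C
})

test_that("run_ifs recovers a planted single-feature signal", {
  withr::with_seed(12, {
    n <- 60
    labels <- c(rep(1L, 24), rep(-1L, 36))
    x <- cbind(ifelse(labels == 1L, 1, 0) + rnorm(n, sd = 0.05),
               matrix(rnorm(n * 4), n, 4))
  })
  fm <- fm_from_matrix(x, labels)
  rk <- mrmr_rank(fm)
  expect_equal(rk$order[1], 1L)
  grid <- svm_grid(log2C = c(0, 4), log2gamma = c(-3, 0))
  res <- run_ifs(fm, rk, sizes = 1:3, grid = grid, k = 5, seed = 2)
  expect_s3_class(res, "ifs_result")
  expect_equal(nrow(res$curve), 3L)
  expect_true(1L %in% res$optimal_features)
  expect_equal(res$curve$MCC[1], max(res$curve$MCC))

  # determinism: same seed, same curve
  res2 <- run_ifs(fm, rk, sizes = 1:3, grid = grid, k = 5, seed = 2)
  expect_identical(res2$curve, res$curve)

  # single-size run
  res3 <- run_ifs(fm, rk, sizes = 5, grid = grid, k = 5, seed = 2)
  expect_equal(res3$optimal_size, 5L)
  expect_error(run_ifs(fm, rk, sizes = integer(0)), "empty")
})

test_that("train_final / predict round-trip through JSON persistence", {
  fx <- simulate_glycation(fixture_spec(n_pos = 25, n_neg = 30, seed = 5))
  win <- build_dataset(fx$proteins, fx$annotations)
  fm <- encode_windows(win)
  feats <- c(feature_index("cksaap", a = "S", b = "W", k = 4),
             feature_index("factor", site = 14, factor = 4))
  model <- train_final(fm, feats, list(C = 8, gamma = 0.5))
  pred <- predict(model, win)
  expect_equal(nrow(pred), nrow(win))

  # resubstitution accuracy at least matches a coin flip on planted signal
  expect_gt(mean(pred$label == win$label), 0.8)

  # motif-bearing window scores above its motif-free counterpart
  base <- strsplit(paste0(strrep("A", 11), "K", strrep("A", 11)), "")[[1]]
  with_pair <- base; with_pair[9] <- "S"; with_pair[14] <- "W"
  probe <- predict(model, c(paste(with_pair, collapse = ""),
                            paste(base, collapse = "")))
  expect_gt(probe$decision[1], probe$decision[2])

  # empty input
  expect_equal(nrow(predict(model, character(0))), 0L)

  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_identical(predict(back, win)$decision, pred$decision)
  expect_error(train_final(fm, 5000L, list(C = 1, gamma = 1)), "invalid")
})

test_that("summarize_optimal_features tallies blocks, sites and letters", {
  s <- summarize_optimal_features(c(1793L, 33L, 91L))
  expect_equal(s$by_block$count[s$by_block$block == "cksaap"], 1L)
  expect_equal(s$by_block$count[s$by_block$block == "factor"], 2L)
  expect_equal(s$by_block$count[s$by_block$block == "frequency"], 0L)

  full <- summarize_optimal_features(1:1900)
  expect_equal(full$by_block$count, c(21L, 115L, 1764L))

  sites <- summarize_optimal_features(c(33L, 91L, 129L))$factor_sites
  expect_equal(sites$count[sites$site %in% c(3, 14, 22)], rep(1L, 3))
  expect_equal(sum(sites$count), 3L)

  letters <- summarize_optimal_features(1793L)$cksaap_letters
  expect_equal(letters$count[letters$letter %in% c("S", "W")], c(1L, 1L))
})
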