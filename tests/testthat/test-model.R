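test_that("max pooling takes column-wise maxima and ignores row order", {
  m <- rbind(c(1, -2), c(3, 0))
  expect_identical(pool_max(m), c(3, 0))
  expect_identical(pool_max(m[1, , drop = FALSE]), c(1, -2))
  set.seed(3)
  r <- matrix(rnorm(35), 7, 5)
  expect_identical(pool_max(r), pool_max(r[sample(7), , drop = FALSE]))
  expect_error(pool_max(r[0, , drop = FALSE]), "at least one row")
})

test_that("Hadamard fusion is an elementwise, commutative product", {
  expect_identical(fuse_hadamard(c(2, 3), c(4, -1)), c(8, -3))
  expect_identical(fuse_hadamard(c(2, 3), c(1, 1)), c(2, 3))
  u <- rnorm(6)
  expect_true(all(fuse_hadamard(u, u) >= 0))
  expect_identical(fuse_hadamard(u, rev(u)), fuse_hadamard(rev(u), u))
  expect_error(fuse_hadamard(1:3, 1:4), "dimension mismatch")
})

spec <- synthetic_complex_spec(seed = 21, len_a = 25, len_b = 25)
ds <- make_affinity_dataset(spec, n_pairs = 80)
fit <- affinity_model(ds, embed_dim = 12, hidden = c(16, 8), epochs = 5, seed = 21)

test_that("Siamese predictions are argument-symmetric and non-negative", {
  set.seed(9)
  for (i in 1:20) {
    sa <- paste(sample(pairbind:::AA_ALPHABET, 30, TRUE), collapse = "")
    sb <- paste(sample(pairbind:::AA_ALPHABET, 18, TRUE), collapse = "")
    p1 <- predict(fit, data.frame(seq_a = sa, seq_b = sb))
    p2 <- predict(fit, data.frame(seq_a = sb, seq_b = sa))
    expect_identical(p1, p2)  # bit-for-bit under the Hadamard fusion
    expect_gte(p1, 0)
  }
})

test_that("evaluation-mode prediction is deterministic", {
  nd <- data.frame(seq_a = spec$seq_a, seq_b = spec$seq_b)
  expect_identical(predict(fit, nd), predict(fit, nd))
})

test_that("identical seeds reproduce identical fits", {
  f1 <- affinity_model(ds, embed_dim = 8, hidden = c(8, 4), epochs = 3, seed = 4)
  f2 <- affinity_model(ds, embed_dim = 8, hidden = c(8, 4), epochs = 3, seed = 4)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$head, f2$head)
})

test_that("a single example is memorized to near-zero loss", {
  one <- data.frame(seq_a = "MKVLWY", seq_b = "HEHEHE", label = 9.5)
  f <- affinity_model(one, embed_dim = 8, hidden = c(8, 4), epochs = 300,
                      batch_size = 1, dropout = 0, seed = 2)
  expect_lt(abs(predict(f, one) - 9.5), 0.05)
})

test_that("all three losses train and differ", {
  fits <- lapply(c("mse", "mae", "huber"), function(l)
    affinity_model(ds, loss = l, embed_dim = 8, hidden = c(8, 4),
                   epochs = 2, seed = 5))
  preds <- vapply(fits, function(f)
    predict(f, data.frame(seq_a = spec$seq_a, seq_b = spec$seq_b)), numeric(1))
  expect_true(all(is.finite(preds)) && all(preds >= 0))
  expect_gt(length(unique(preds)), 1L)
})

test_that("training reduces validation error below the label spread", {
  ft <- affinity_model(ds, embed_dim = 48, hidden = c(32, 16), epochs = 40,
                       dropout = 0, seed = 21)
  h <- ft$history
  expect_lt(h$val_mae[nrow(h)], sd(ds$records$label[ds$val_idx]))
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
})

test_that("overlapping chunk windows cover every residue", {
  w <- chunk_windows(100)
  expect_identical(nrow(w), 1L)
  w <- chunk_windows(250)
  expect_identical(w$start, c(1L, 51L, 101L, 151L))
  expect_identical(w$end, c(100L, 150L, 200L, 250L))
  expect_true(w$ragged[4] == FALSE)
  set.seed(11)
  for (L in c(1, 7, 50, 99, 101, 120, 149, 150, 151, 250, sample(2:400, 20))) {
    w <- chunk_windows(L)
    cover <- integer(L)
    for (i in seq_len(nrow(w))) {
      expect_lte(w$end[i] - w$start[i] + 1L, 100L)
      cover[w$start[i]:w$end[i]] <- cover[w$start[i]:w$end[i]] + 1L
    }
    expect_true(all(cover >= 1))  # no residue uncovered
    # 100/50 scheme: interior residues covered exactly twice
    if (L > 200) expect_true(all(cover[101:(L - 100)] == 2))
  }
})

test_that("chunked prediction averages all chunk-pair scores", {
  fb <- affinity_model(ds, encoder = "bilstm", hidden = c(8, 4),
                       epochs = 2, seed = 3)
  long_a <- strrep("MKVLWY", 30)  # 180 residues -> 3 chunks
  long_b <- strrep("HE", 80)      # 160 residues -> 3 chunks
  wa <- chunk_windows(180); wb <- chunk_windows(160)
  manual <- mean(outer(seq_len(nrow(wa)), seq_len(nrow(wb)),
                       Vectorize(function(i, j)
                         pairbind:::predict_pair(fb,
                           substr(long_a, wa$start[i], wa$end[i]),
                           substr(long_b, wb$start[j], wb$end[j])))))
  expect_equal(chunked_predict(fb, long_a, long_b), manual)
  # a constant scorer stays constant under chunk averaging
  one_chunk <- chunked_predict(fb, substr(long_a, 1, 50), substr(long_b, 1, 50))
  expect_identical(one_chunk,
                   pairbind:::predict_pair(fb, substr(long_a, 1, 50),
                                           substr(long_b, 1, 50)))
})

test_that("the BiLSTM baseline is order-sensitive by construction", {
  fb <- affinity_model(ds, encoder = "bilstm", hidden = c(8, 4),
                       epochs = 2, seed = 3)
  p1 <- predict(fb, data.frame(seq_a = spec$seq_a, seq_b = spec$seq_b))
  p2 <- predict(fb, data.frame(seq_a = spec$seq_b, seq_b = spec$seq_a))
  expect_false(identical(p1, p2))
})

test_that("precomputed embedding tables drive a frozen-encoder fit", {
  seqs <- unique(c(ds$records$seq_a, ds$records$seq_b))
  set.seed(8)
  tab <- lapply(seqs, function(s) matrix(rnorm(nchar(s) * 6), nchar(s), 6))
  names(tab) <- seqs
  enc <- precomputed_encoder(tab)
  f <- affinity_model(ds, encoder = enc, hidden = c(8, 4), epochs = 3, seed = 8)
  p <- predict(f, data.frame(seq_a = seqs[1], seq_b = seqs[2]))
  expect_true(is.finite(p) && p >= 0)
  expect_error(predict(f, data.frame(seq_a = "MMMM", seq_b = seqs[1])),
               "no precomputed embedding")
})

test_that("overlong sequences error or truncate per configuration", {
  f <- affinity_model(ds, embed_dim = 8, hidden = c(8, 4), epochs = 2,
                      seed = 6, max_len = 30)
  long <- strrep("K", 40)
  expect_error(predict(f, data.frame(seq_a = long, seq_b = spec$seq_b)),
               "max_len")
  ft <- affinity_model(ds, embed_dim = 8, hidden = c(8, 4), epochs = 2,
                       seed = 6, max_len = 30, long_seq = "truncate")
  expect_true(is.finite(predict(ft, data.frame(seq_a = long, seq_b = spec$seq_b))))
})
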