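test_that("a constant model yields all-zero ddG scores", {
  sc <- score_scan(constant_model(7), "MKVL", "WYEH", patch_sizes = 1)
  expect_true(all(sc$ddG == 0))
  expect_identical(attr(sc, "wild_score"), 7)
})

test_that("variants identical to the wild type score exactly zero", {
  calls <- new.env(); calls$n <- 0L
  counting <- function(sa, sb) { calls$n <- calls$n + 1L; nchar(sa) + nchar(sb) }
  sc <- score_scan(counting, "AAKA", "WYEH", patch_sizes = 1, chains = "A")
  # positions 1, 2 and 4 are already alanine: wild + one real variant call
  expect_identical(calls$n, 2L)
  expect_identical(sc$ddG[c(1, 2, 4)], c(0, 0, 0))
})

test_that("the scan recovers an energetically critical position first", {
  # binding weakens only when position 3 of chain A loses its lysine
  model <- function(sa, sb) 10 - 4 * (substr(sa, 3, 3) == "A")
  sc <- score_scan(model, "MKKLV", "WYEH", patch_sizes = 1)
  rk <- rank_residues(sc)
  expect_identical(rk$chain[1], "A")
  expect_identical(rk$position[1], 3L)
  expect_equal(rk$ddG[1], 4)
  expect_true(all(rk$ddG[-1] == 0))
})

test_that("patch scores attribute to residues by max over covering windows", {
  # window ddGs for patch 2 on "MKVL": starts 1,2,3
  vals <- c("1" = 0.1, "2" = 0.9, "3" = 0.4)
  model <- function(sa, sb) {
    if (sa == "MKVL") return(5)
    s <- which(brute_scan("MKVL", 2) == sa)
    5 - vals[[s]]
  }
  sc <- score_scan(model, "MKVL", "WY", patch_sizes = 2, chains = "A")
  # residue 2 covered by windows 1 and 2 -> max(0.1, 0.9)
  expect_equal(sc$ddG[sc$position == 2], 0.9)
  expect_equal(sc$ddG[sc$position == 1], 0.1)
  expect_equal(sc$ddG[sc$position == 3], 0.9)
  expect_equal(sc$ddG[sc$position == 4], 0.4)
  scm <- score_scan(model, "MKVL", "WY", patch_sizes = 2, chains = "A",
                    attribution = "mean")
  expect_equal(scm$ddG[scm$position == 2], mean(c(0.1, 0.9)))
})

test_that("ranking sorts by descending ddG with deterministic tie-breaks", {
  sc <- data.frame(chain = "A", position = 1:3, patch_size = 1,
                   ddG = c(0.2, 0.9, 0.5))
  rk <- rank_residues(sc)
  expect_identical(rk$position, c(2L, 3L, 1L))
  ties <- data.frame(chain = c("B", "A", "A"), position = c(1L, 2L, 1L),
                     patch_size = 1, ddG = 0.3)
  rkt <- rank_residues(ties)
  expect_identical(rkt$chain, c("A", "A", "B"))
  expect_identical(rkt$position, c(1L, 2L, 1L))
  # property: matches an explicit stable sort oracle on random tables
  set.seed(41)
  for (case in 1:20) {
    tab <- data.frame(chain = sample(c("A", "B"), 30, TRUE),
                      position = sample(100, 30), patch_size = 1,
                      ddG = sample(round(rnorm(30), 1), 30, TRUE))
    rk <- rank_residues(tab)
    oracle <- tab[order(-tab$ddG, tab$chain, tab$position), ]
    expect_identical(rk$position, oracle$position)
    expect_identical(rk$ddG, oracle$ddG)
  }
})

test_that("N-factor success counts true residues in the top k = N * n", {
  truth <- data.frame(chain = "A", position = 1:20)
  ranking <- data.frame(chain = "A", position = c(1:20, 61:100),
                        ddG = seq(1, 0.01, length.out = 60))
  for (N in 1:3) {
    r <- n_factor_success(ranking, truth, N)
    expect_identical(r$n, 20L)
    expect_identical(r$k, as.integer(N * 20))
  }
  # perfect ranking: every true residue in the top n already
  expect_equal(n_factor_success(ranking, truth, 1)$success_rate, 100)
  expect_error(n_factor_success(ranking, truth[0, ], 1), "empty interface")
})

test_that("N-factor success equals the set-intersection oracle and is monotone in N", {
  set.seed(43)
  for (case in 1:20) {
    L <- 30
    ranking <- data.frame(chain = "A", position = sample(L),
                          ddG = sort(runif(L), decreasing = TRUE))
    truth <- data.frame(chain = "A", position = sample(L, sample(3:8, 1)))
    n <- nrow(truth)
    rates <- vapply(1:3, function(N) {
      r <- n_factor_success(ranking, truth, N)
      expect_identical(r$hits,
                       length(intersect(ranking$position[seq_len(min(N * n, L))],
                                        truth$position)))
      expect_lte(r$hits, min(r$k, n))
      r$success_rate
    }, numeric(1))
    expect_true(all(diff(rates) >= 0))
    expect_true(all(rates >= 0 & rates <= 100))
    # once k covers every scanned residue the rate saturates at 100
    expect_equal(n_factor_success(ranking, truth, ceiling(L / n))$success_rate, 100)
  }
})

test_that("mutation classification fractions are consistent and sum to one", {
  zero <- data.frame(ddG = numeric(10))
  expect_equal(unname(classify_mutations(zero, tau = 0.05)), c(0, 0, 1),
               ignore_attr = TRUE)
  tri <- data.frame(ddG = c(1, -1, 0))
  expect_equal(unname(classify_mutations(tri, tau = 0.5)), rep(1 / 3, 3),
               ignore_attr = TRUE)
  set.seed(44)
  for (case in 1:10) {
    tab <- data.frame(ddG = rnorm(50, sd = 2))
    expect_equal(sum(classify_mutations(tab, tau = runif(1, 0, 1))), 1)
  }
})

test_that("aggregation takes unweighted means per group", {
  single <- list(n_factor_success(data.frame(chain = "A", position = 1:4,
                                             ddG = 4:1),
                                  data.frame(chain = "A", position = 1:2), 1,
                                  complex_id = "c1"))
  expect_equal(aggregate_success(single)$mean_success_rate, 100)
  df <- data.frame(model = c("m1", "m1", "m2"), N = 1,
                   success_rate = c(50, 100, 30))
  out <- aggregate_success(df, by = "model")
  expect_equal(out$mean_success_rate[out$model == "m1"], 75)
  expect_equal(out$mean_success_rate[out$model == "m2"], 30)
})
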