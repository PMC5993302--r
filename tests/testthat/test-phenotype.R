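codes_for <- function(keys, subject, zt = NULL) {
  if (is.null(zt)) zt <- ((seq_along(keys) - 1) * 4 / 3600) %% 24
  data.frame(subject_id = subject, epoch_index = seq_along(keys) - 1,
             zt = zt, key = as.integer(keys), stringsAsFactors = FALSE)
}

test_that("occupancy distributions normalise counts per subject", {
  df <- rbind(codes_for(rep(4L, 10), "a"),
              codes_for(c(rep(1L, 6), rep(2L, 4)), "b"))
  occ <- occupancy(df)
  expect_equal(unname(occ$P["a", ]), c(0, 0, 1))      # one-hot
  expect_equal(unname(occ$P["b", ]), c(0.6, 0.4, 0))
  expect_true(all(abs(rowSums(occ$P) - 1) < 1e-12))

  # identical subjects get identical distributions
  df2 <- rbind(codes_for(c(1, 2, 2, 3), "a"), codes_for(c(1, 2, 2, 3), "b"))
  occ2 <- occupancy(df2)
  expect_equal(unname(occ2$P["a", ]), unname(occ2$P["b", ]))
})

test_that("occupancy equals brute-force counting on a random sequence", {
  set.seed(41)
  keys <- sample(c(2L, 4L, 8L, 16L), 300, replace = TRUE)
  occ <- occupancy(codes_for(keys, "s"))
  for (k in unique(keys))
    expect_equal(occ$P["s", as.character(k)], mean(keys == k))
})

test_that("group comparison matches the textbook pooled t", {
  x1 <- c(310, 295, 342, 301, 288, 320)
  x2 <- c(290, 305, 278, 266, 284, 272)
  df <- do.call(rbind, c(
    lapply(1:6, function(i) codes_for(rep(1L, x1[i]), paste0("g1_", i))),
    lapply(1:6, function(i) codes_for(rep(1L, x2[i]), paste0("g2_", i)))))
  df$key[df$epoch_index == 0] <- 2L    # second state so the matrix is 2-wide
  grp <- setNames(rep(c("A", "B"), each = 6),
                  c(paste0("g1_", 1:6), paste0("g2_", 1:6)))
  occ <- occupancy(codes = df, groups = grp)
  r <- compare_groups(occ, 1L, c("A", "B"))
  ref <- t.test(x1 - 1, x2 - 1, var.equal = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  expect_equal(r$df, unname(ref$parameter))

  # swap symmetry
  r2 <- compare_groups(occ, 1L, c("B", "A"))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)

  # Welch variant agrees with t.test too
  rw <- compare_groups(occ, 1L, c("A", "B"), var_equal = FALSE)
  refw <- t.test(x1 - 1, x2 - 1)
  expect_equal(rw$t, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(rw$p, refw$p.value, tolerance = 1e-12)
})

test_that("degenerate variances follow the stated sentinels", {
  df <- do.call(rbind, lapply(1:6, function(i)
    codes_for(c(rep(1L, 10), 2L), paste0("s", i))))
  grp <- setNames(rep(c("A", "B"), 3), paste0("s", 1:6))
  occ <- occupancy(df, groups = grp)
  r <- compare_groups(occ, 1L, c("A", "B"))   # identical groups
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  df2 <- do.call(rbind, lapply(1:6, function(i) {
    n <- if (i <= 3) c(10, 1) else c(1, 10)
    codes_for(c(rep(1L, n[1]), rep(2L, n[2])), paste0("s", i))
  }))
  grp2 <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  occ2 <- occupancy(df2, groups = grp2)
  expect_warning(r2 <- compare_groups(occ2, 1L, c("A", "B")),
                 "zero pooled variance")
  expect_equal(r2$p, 0)
})

test_that("LOSO separates groups with disjoint dominant states", {
  set.seed(43)
  mk <- function(g, dominant) do.call(rbind, lapply(1:3, function(i)
    codes_for(sample(c(dominant, 9L), 200, TRUE, prob = c(0.8, 0.2)),
              paste0(g, i))))
  df <- rbind(mk("a", 1L), mk("b", 2L), mk("c", 3L))
  grp <- setNames(rep(c("A", "B", "C"), each = 3),
                  paste0(rep(c("a", "b", "c"), each = 3), 1:3))
  occ <- occupancy(df, groups = grp)
  res <- loso_classify(occ)
  expect_equal(res$accuracy, 1)
  expect_equal(unname(diag(res$confusion)), c(3, 3, 3))
})

test_that("LOSO accuracy is at chance for shuffled identical subjects", {
  set.seed(44)
  base <- sample(c(1L, 2L, 3L), 300, TRUE)
  df <- do.call(rbind, lapply(1:12, function(i)
    codes_for(base, paste0("s", i))))
  grp <- setNames(sample(rep(c("A", "B"), each = 6)), paste0("s", 1:12))
  occ <- occupancy(df, groups = grp)
  res <- loso_classify(occ)
  # binomial 95% band around 0.5 for n = 12
  band <- 1.96 * sqrt(0.25 / 12)
  expect_true(res$accuracy >= 0.5 - band - 1e-9 &&
                res$accuracy <= 0.5 + band + 1e-9)
})

test_that("LOSO rejects undersized groups", {
  df <- rbind(codes_for(c(1L, 2L), "a"), codes_for(c(1L, 2L), "b"),
              codes_for(c(1L, 2L), "c"))
  occ <- occupancy(df, groups = c(a = "A", b = "A", c = "B"))
  expect_error(loso_classify(occ), "loso-undersized")
})

test_that("majority vote logic follows two-of-three, SVM on full splits", {
  vote <- function(votes) {
    tab <- sort(table(votes), decreasing = TRUE)
    if (tab[1] >= 2) names(tab)[1] else votes[1]
  }
  expect_equal(vote(c("A", "A", "B")), "A")
  expect_equal(vote(c("B", "A", "A")), "A")
  expect_equal(vote(c("C", "B", "A")), "C")  # falls back to the first (SVM)
})

test_that("daily profiles bin, conserve and rotate correctly", {
  zt <- rep(2.5, 100)
  df <- codes_for(rep(5L, 100), "a", zt = zt)
  pr <- daily_profile(df, 5L)
  expect_equal(unname(pr$bins["2"]), 100)
  expect_equal(sum(pr$bins), 100)
  expect_equal(peak_half(pr), "first-half")

  set.seed(45)
  zt2 <- runif(2000, 0, 24)
  df2 <- codes_for(sample(c(5L, 6L), 2000, TRUE), "a", zt = zt2)
  p0 <- daily_profile(df2, 5L)
  expect_equal(sum(p0$bins), sum(df2$key == 5L))
  # shifting all epochs by +k hours rotates the histogram
  for (k in c(3, 11)) {
    dfk <- df2
    dfk$zt <- (dfk$zt + k) %% 24
    pk <- daily_profile(dfk, 5L)
    expect_equal(unname(pk$bins), unname(p0$bins[as.character((24 + 0:23 - k) %% 24)]))
  }
})

test_that("a sinusoidal occupancy peak is located within an hour", {
  set.seed(46)
  lam <- 400 * (1 + 0.8 * cos(2 * pi * ((0:23) + 0.5 - 18) / 24))
  zt <- unlist(lapply(0:23, function(h) h + runif(rpois(1, lam[h + 1]))))
  df <- codes_for(rep(1L, length(zt)), "a", zt = zt)
  pr <- daily_profile(df, 1L)
  expect_lt(min(abs(pr$peak_zt - 18), 24 - abs(pr$peak_zt - 18)), 1)
  expect_error(peak_half(pr), "not-light-phase")
})

test_that("late-light-peaking states are all called second-half", {
  set.seed(47)
  for (r in 1:20) {
    peak <- runif(1, 7.5, 10.5)
    lam <- 300 * (1 + 0.9 * cos(2 * pi * ((0:23) + 0.5 - peak) / 24))
    zt <- unlist(lapply(0:23, function(h) h + runif(rpois(1, lam[h + 1]))))
    pr <- daily_profile(codes_for(rep(1L, length(zt)), "a", zt = zt), 1L)
    expect_equal(peak_half(pr), "second-half")
  }
})

test_that("an empty state yields a zero profile with no peak", {
  df <- codes_for(rep(1L, 10), "a")
  pr <- daily_profile(df, 99L)
  expect_equal(sum(pr$bins), 0)
  expect_true(is.na(pr$peak_zt))
})

test_that("rebound deltas and timing classes follow the ZT partition", {
  mk_day <- function(extra_h = NULL, n_extra = 0) {
    zt <- rep(6:23 + 0.5, each = 20)
    if (!is.null(extra_h)) zt <- c(zt, rep(extra_h + 0.5, n_extra))
    codes_for(rep(1L, length(zt)), "a", zt = zt)
  }
  base <- mk_day()
  expect_equal(rebound_analysis(base, mk_day(), 1L)$class, "none")

  r6 <- rebound_analysis(base, mk_day(6, 30), 1L)
  expect_equal(r6$class, "immediate")
  expect_equal(unname(r6$delta["6"]), 30)
  expect_equal(rebound_analysis(base, mk_day(9, 30), 1L)$class,
               "intermediate")
  expect_equal(rebound_analysis(base, mk_day(12, 30), 1L)$class,
               "intermediate")   # boundary bin [12,13) maps to ZT 12
  expect_equal(rebound_analysis(base, mk_day(14, 30), 1L)$class, "late")

  short <- base[base$zt < 20, ]
  expect_error(rebound_analysis(short, mk_day(), 1L), "baseline coverage")
})

test_that("planted group differences are detected and null states are not", {
  set.seed(48)
  n_sub <- 6
  mk <- function(g, boost) do.call(rbind, lapply(1:n_sub, function(i) {
    p <- c(10, 10, 10, 10) + c(boost, 0, 0, 0)
    codes_for(sample(1:4, 600, TRUE, prob = p / sum(p)), paste0(g, i))
  }))
  df <- rbind(mk("a", 12), mk("b", 0))
  grp <- setNames(rep(c("A", "B"), each = n_sub),
                  paste0(rep(c("a", "b"), each = n_sub), 1:n_sub))
  occ <- occupancy(df, groups = grp)
  tests <- substage_tests(occ)
  expect_true(tests$significant[tests$state_key == 1])
})
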