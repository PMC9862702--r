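test_that("pair alignment summarizes compared sites and mismatches", {
  s <- align_pair("ACGU", "ACGU")
  expect_identical(c(s$L, s$X), c(4L, 0L))
  expect_identical(s$p_hat, 0)
  s2 <- align_pair("AAAA", "AAAU")
  expect_identical(c(s2$L, s2$X), c(4L, 1L))
  expect_identical(s2$p_hat, 0.25)
  expect_error(align_pair("", "ACGU"), "empty")
})

test_that("planted-mutation pairs recover the exact p-distance", {
  x <- generate_fixture_catalog(1, c(100, 100), seed = 31)$records$sequence
  for (s in c(1, 7, 23)) {
    y <- plant_mutations(x, 0.30, seed = s)
    al <- align_pair(x, y)
    expect_identical(al$p_hat, 0.30)
    expect_equal(jukes_cantor(al$p_hat), -0.75 * log(0.6),
                 tolerance = 1e-12)
  }
})

test_that("alignment counts agree with an aligned-string oracle", {
  cat <- generate_fixture_catalog(8, c(50, 120), seed = 13)
  seqs <- cat$records$sequence
  prm_ex <- alignment_params()
  prm_cm <- alignment_params(gap_columns = "counted-as-mismatch")
  for (k in 1:10) {
    i <- ((k - 1) %% 7) + 1
    j <- i + 1
    oracle <- string_alignment_counts(seqs[i], seqs[j], prm_ex)
    ex <- align_pair(seqs[i], seqs[j], prm_ex)
    expect_identical(ex$L, oracle$L_excluded)
    expect_identical(ex$X, oracle$X_excluded)
    cm <- align_pair(seqs[i], seqs[j], prm_cm)
    expect_identical(cm$L, oracle$columns)
    expect_identical(cm$X, oracle$X_counted)
  }
})

test_that("pair summaries are symmetric in their arguments", {
  cat <- generate_fixture_catalog(12, c(50, 180), seed = 3)
  seqs <- cat$records$sequence
  for (i in 1:6) {
    a <- seqs[i]; b <- seqs[13 - i]
    f <- align_pair(a, b)
    r <- align_pair(b, a)
    expect_identical(c(f$L, f$X), c(r$L, r$X))
  }
})

test_that("the Jukes-Cantor transform matches its closed form", {
  expect_identical(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.30), 0.3831192178244929, tolerance = 1e-12)
  expect_identical(jukes_cantor(0.75), Inf)
  expect_identical(jukes_cantor(1), Inf)
  expect_error(jukes_cantor(-0.1), "p_hat")
  expect_error(jukes_cantor(1.1), "p_hat")
  # strictly increasing below saturation, and K >= p with equality at 0
  p <- seq(0, 0.74, length.out = 200)
  K <- jukes_cantor(p)
  expect_true(all(diff(K) > 0))
  expect_true(all(K[-1] > p[-1]))
  expect_identical(K[1], 0)
})

test_that("condensed distances match a brute-force pair loop", {
  cat <- generate_fixture_catalog(4, c(60, 80), seed = 21)
  cd <- pairwise_distances(cat)
  expect_identical(length(cd), 6L)
  seqs <- cat$records$sequence
  k <- 1L
  for (i in 1:3) for (j in (i + 1):4) {
    al <- align_pair(seqs[i], seqs[j])
    expect_identical(cd$values[k], jukes_cantor(al$p_hat))
    k <- k + 1L
  }
  # self-distance and the identical-pair case
  two <- hairpin_catalog(data.frame(identifier = c("a", "b"),
                                    sequence = c("ACGUACGU", "ACGUACGU")))
  expect_identical(pairwise_distances(two)$values, 0)
  expect_identical(align_pair(seqs[1], seqs[1])$p_hat, 0)
})

test_that("pair counts are conserved for every catalog size", {
  for (n in c(2, 3, 5, 9)) {
    cat <- generate_fixture_catalog(n, c(50, 60), seed = n)
    expect_identical(length(pairwise_distances(cat)),
                     as.integer(pair_count(n)))
  }
  expect_identical(pair_count(1917), 1836486)
})

test_that("panel distances cover exactly the resolved members", {
  cat <- mirbase_style_catalog()
  nms <- c("miR-21", "let-7a", "miR-10a", "miR-323")
  cd <- suppressWarnings(panel_distances(nms, cat))
  expect_identical(length(cd), as.integer(pair_count(4)))
  expect_identical(cd$ids[1], "hsa-mir-21")
  # two names resolving to identical sequences give distance zero
  dup <- hairpin_catalog(data.frame(
    identifier = c("hsa-mir-1-1", "hsa-mir-1-2"),
    sequence = c("ACGUACGUAC", "ACGUACGUAC")))
  cd0 <- suppressWarnings(
    panel_distances(c("hsa-mir-1-1", "hsa-mir-1-2"), dup))
  expect_identical(cd0$values, 0)
})

test_that("saturated pairs are flagged, never silently finite", {
  p <- c(0.1, 0.75, 0.8)
  K <- jukes_cantor(p)
  expect_true(all(!is.finite(K[2:3])))
  # and through the alignment path with forced saturation: two sequences
  # with every base different and equal length (gapless optimum requires
  # a mismatch-friendly scoring to stay gapless)
  prm <- alignment_params(match = 5, mismatch = 4, gap_open = 50,
                          gap_extend = 50)
  two <- hairpin_catalog(data.frame(identifier = c("a", "b"),
                                    sequence = c("AAAAAAAA", "CCCCCCCC")))
  cd2 <- pairwise_distances(two, prm)
  expect_identical(cd2$values, Inf)
  expect_true(cd2$saturated)
})

test_that("distance caches round-trip and stale caches are ignored", {
  cat <- generate_fixture_catalog(6, c(50, 80), seed = 8)
  cache <- tempfile(fileext = ".tsv")
  cd <- pairwise_distances(cat, cache = cache)
  expect_true(file.exists(cache))
  expect_message(cd2 <- pairwise_distances(cat, cache = cache),
                 "cache hit")
  expect_identical(cd2$values, cd$values)
  expect_identical(cd2$ids, cd$ids)
  # different scoring invalidates the cache
  prm <- alignment_params(match = 2, mismatch = -3)
  cd3 <- pairwise_distances(cat, prm, cache = cache)
  expect_false(isTRUE(all.equal(cd3$values, cd$values)))
  # manual write/read round trip, including non-finite values
  x <- structure(
    list(ids = c("a", "b", "c"), values = c(0.5, Inf, 1.25),
         saturated = c(FALSE, TRUE, FALSE)),
    class = "condensed_dist")
  f <- tempfile()
  write_distances(x, f)
  back <- read_distances(f)
  expect_identical(back$values, x$values)
  expect_identical(back$saturated, x$saturated)
  expect_identical(back$ids, x$ids)
})

test_that("condensed vectors convert to symmetric matrices", {
  cat <- generate_fixture_catalog(5, c(50, 60), seed = 2)
  cd <- pairwise_distances(cat)
  m <- as.matrix(cd)
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_identical(m[1, 2], cd$values[1])
  expect_identical(m[4, 5], cd$values[10])
  d <- as.dist(cd)
  expect_equal(as.numeric(d), cd$values)
})
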