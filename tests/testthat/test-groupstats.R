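# tiny synthetic power lists: nsub subjects, conds, on a small grid
toy_power_list <- function(nsub, conds, dims = c(2, 3, 2),
                           fun = function(s, cond) {
                             array(rnorm(prod(dims)), dim = dims)
                           }) {
  chans <- paste0("ch", seq_len(dims[1]))
  freqs <- seq(2, by = 2, length.out = dims[2])
  times <- seq(0, by = 0.1, length.out = dims[3])
  out <- lapply(seq_len(nsub), function(s) {
    p <- lapply(conds, function(cond) fun(s, cond))
    names(p) <- conds
    attr(p, "channels") <- chans
    attr(p, "freqs") <- freqs
    attr(p, "times") <- times
    p
  })
  names(out) <- sprintf("S%02d", seq_len(nsub))
  out
}

toy_ratings <- function(mat, conds = colnames(mat)) {
  df <- data.frame(
    subject = rep(rownames(mat), times = 2 * ncol(mat)),
    session = rep(c("pre", "post"), each = nrow(mat) * ncol(mat)),
    condition = rep(rep(conds, each = nrow(mat)), 2),
    rating = as.integer(round(c(mat, mat)))
  )
  class(df) <- c("ratings_table", "data.frame")
  df
}

conds <- paste0("F", 1:4)

test_that("paired t-map is zero for identical conditions and matches t.test", {
  set.seed(1)
  pl <- toy_power_list(6, conds)
  sm0 <- mass_paired_t(pl, "F2", "F2")
  expect_true(all(sm0$values == 0))
  sm <- mass_paired_t(pl, "F4", "F1")
  expect_equal(sm$df, 5)
  d <- vapply(pl, function(p) p[["F4"]][2, 3, 1] - p[["F1"]][2, 3, 1],
              numeric(1))
  expect_equal(sm$values[2, 3, 1], unname(stats::t.test(d)$statistic),
               tolerance = 1e-12)
})

test_that("first-level slopes are exact for affine power and match OLS", {
  rmat <- matrix(rep(c(2, 5, 6, 8), each = 5), nrow = 5,
                 dimnames = list(sprintf("S%02d", 1:5), conds))
  ratings <- toy_ratings(rmat)
  # power = 2 * rating + 1 at every bin
  pl <- toy_power_list(5, conds, fun = function(s, cond) {
    array(2 * rmat[1, cond] + 1, dim = c(2, 3, 2))
  })
  slopes <- first_level_regression(pl, ratings)
  expect_equal(unname(slopes$maps), matrix(2, 5, 12), tolerance = 1e-12)

  # random power: check one bin against the closed-form OLS oracle
  set.seed(2)
  pl2 <- toy_power_list(5, conds)
  slopes2 <- first_level_regression(pl2, ratings)
  s <- "S03"; bin <- 7  # bin 7 = (ch, f, t) index decoded below
  x <- rmat[s, ]
  y <- vapply(conds, function(cond) as.vector(pl2[[s]][[cond]])[bin],
              numeric(1))
  oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(unname(slopes2$maps[s, bin]), oracle, tolerance = 1e-12)
})

test_that("constant power across conditions gives zero slopes", {
  rmat <- matrix(c(2, 5, 6, 8, 3, 4, 7, 9), nrow = 2, byrow = TRUE,
                 dimnames = list(c("S01", "S02"), conds))
  pl <- toy_power_list(2, conds, fun = function(s, cond) {
    array(5, dim = c(2, 3, 2))
  })
  slopes <- first_level_regression(pl, toy_ratings(rmat))
  expect_true(all(abs(slopes$maps) < 1e-12))
})

test_that("subjects without rating variance are excluded with a warning", {
  rmat <- matrix(c(2, 5, 6, 8, 4, 4, 4, 4), nrow = 2, byrow = TRUE,
                 dimnames = list(c("S01", "S02"), conds))
  set.seed(3)
  pl <- toy_power_list(2, conds)
  expect_warning(slopes <- first_level_regression(pl, toy_ratings(rmat)),
                 "zero rating variance")
  expect_equal(nrow(slopes$maps), 1)
})

test_that("second-level t equals the one-sample oracle and tracks consistency", {
  set.seed(4)
  maps <- subject_maps(matrix(rnorm(8 * 12), 8, 12), paste0("ch", 1:2),
                       seq(2, 6, 2), c(0, 0.1), kind = "slope")
  sm <- second_level_ttest(maps)
  x <- maps$maps[, 5]
  expect_equal(sm$values[5], unname(stats::t.test(x)$statistic),
               tolerance = 1e-12)
  # a shared positive slope with tiny jitter gives a large positive t
  maps2 <- maps
  maps2$maps <- matrix(3, 8, 12) + matrix(rnorm(96, sd = 1e-3), 8, 12)
  expect_true(all(second_level_ttest(maps2)$values > 100))
})

test_that("demeaned correlation matches a hand-computed toy oracle", {
  pow <- matrix(c(1, 2, 3, 4,
                  2, 4, 5, 7,
                  0, 1, 1, 3), nrow = 3, byrow = TRUE,
                dimnames = list(c("S01", "S02", "S03"), conds))
  rat <- matrix(c(2, 4, 5, 8,
                  1, 5, 6, 9,
                  3, 3, 5, 7), nrow = 3, byrow = TRUE,
                dimnames = list(c("S01", "S02", "S03"), conds))
  res <- demeaned_correlation(pow, rat)
  xd <- as.vector(pow - rowMeans(pow))
  yd <- as.vector(rat - rowMeans(rat))
  oracle <- sum(xd * yd) / sqrt(sum(xd^2) * sum(yd^2))
  expect_equal(res$r, oracle, tolerance = 1e-12)
  expect_equal(res$n, 12)

  # per-subject affine power with a common positive slope: r -> 1
  aff <- 0.5 * rat + matrix(c(10, 20, 30), 3, 4)
  expect_equal(demeaned_correlation(aff, rat)$r, 1, tolerance = 1e-12)
})

test_that("demeaned correlation is near zero for rating-independent power", {
  set.seed(6)
  rs <- replicate(60, {
    pow <- matrix(rnorm(13 * 4), 13, 4,
                  dimnames = list(sprintf("S%02d", 1:13), conds))
    rat <- matrix(sample(1:9, 52, TRUE), 13, 4,
                  dimnames = list(sprintf("S%02d", 1:13), conds))
    demeaned_correlation(pow, rat)$r
  })
  expect_lt(abs(mean(rs)), 0.06)
  expect_gt(stats::sd(rs), 0.05)  # CI spans zero across regenerations
})

test_that("zero pooled variance is flagged undefined", {
  pow <- matrix(5, 3, 4, dimnames = list(c("S01", "S02", "S03"), conds))
  rat <- matrix(c(2, 4, 5, 8), 3, 4, byrow = TRUE,
                dimnames = dimnames(pow))
  expect_warning(res <- demeaned_correlation(pow, rat), "zero pooled")
  expect_true(is.na(res$r))
})

test_that("cluster masses never decrease along a planted slope ladder", {
  rmat <- matrix(rep(c(2, 5, 6, 8), each = 8), nrow = 8,
                 dimnames = list(sprintf("S%02d", 1:8), conds))
  ratings <- toy_ratings(rmat)
  dims <- c(4, 5, 4)
  set.seed(11)
  noise <- lapply(1:8, function(s)
    lapply(conds, function(cond) array(rnorm(prod(dims)), dim = dims)))
  masses <- vapply(c(0.2, 0.5, 1, 2), function(slope) {
    pl <- toy_power_list(8, conds, dims = dims, fun = function(s, cond) {
      base <- noise[[s]][[match(cond, conds)]]
      base[2, 2:3, 2:3] <- base[2, 2:3, 2:3] + slope * rmat[s, cond]
      base
    })
    slopes <- first_level_regression(pl, ratings)
    nb <- list(ch1 = "ch2", ch2 = c("ch1", "ch3"), ch3 = c("ch2", "ch4"),
               ch4 = "ch3")
    cl <- cluster_permutation_test(slopes, nb, n_perm = 256, seed = 5)
    if (nrow(cl$clusters) == 0) 0 else max(cl$clusters$mass)
  }, numeric(1))
  expect_true(all(diff(masses) >= 0))
})

test_that("constant subject maps yield an empty but valid cluster result", {
  maps <- subject_maps(matrix(1e-14, 6, 8), paste0("ch", 1:2),
                       c(2, 4), c(0, 0.1))
  nb <- list(ch1 = "ch2", ch2 = "ch1")
  cl <- cluster_permutation_test(maps, nb, n_perm = 128, seed = 1)
  expect_equal(nrow(cl$clusters), 0)
  expect_length(cl$members, 0)
})

test_that("condition_feature averages the selected channel/band/window block", {
  pl <- toy_power_list(2, conds, fun = function(s, cond) {
    array(seq_len(12), dim = c(2, 3, 2))
  })
  f <- condition_feature(pl, "ch2", band = c(2, 4), window = c(0, 0))
  # channel 2, freq bins 1:2, time bin 1 -> values 2 and 4
  expect_true(all(f == 3))
  expect_equal(dim(f), c(2, 4))
})
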