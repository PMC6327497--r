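test_that("flattening collapses timepoints and metabolites time-major", {
  mk <- function(vals) tibble::tibble(time_h = c(0, 1, 2, 3),
                                      b = vals + 10, a = vals)
  runs <- list(mk(1:4), mk(5:8), mk(9:12))
  X <- flatten_timecourses(runs, c("b", "a"))
  expect_identical(dim(X), c(8L, 3L))
  # species sorted lexicographically within each timepoint
  expect_identical(rownames(X)[1:2], c("0:a", "0:b"))
  expect_equal(X[, 1], setNames(c(1, 11, 2, 12, 3, 13, 4, 14), rownames(X)))
  expect_identical(ncol(flatten_timecourses(runs[1], "a")), 1L)
  expect_error(flatten_timecourses(runs, character()), "non-empty")
  bad <- mk(1:4); bad$time_h <- bad$time_h + 0.5
  expect_error(flatten_timecourses(list(runs[[1]], bad), "a"), "time grid")
})

test_that("archetypes of a point cloud are its extreme points", {
  X <- cbind(c(0, 0), c(1, 0), c(0, 1), c(0.5, 0.5))
  f <- fit_archetypes(X, 3, seed = 1)
  expect_lt(f$rss, 1e-6)
  # archetypes match the three extremes up to permutation
  Z <- round(f$Z, 4)
  found <- apply(Z, 2, paste, collapse = ",")
  expect_setequal(found, c("0,0", "1,0", "0,1"))
  # the interior point is the midpoint of two archetypes
  mid <- f$A[, 4]
  expect_equal(sort(mid[mid > 1e-6]), c(0.5, 0.5), tolerance = 1e-4)
  # simplex constraints hold
  expect_equal(colSums(f$A), rep(1, 4), tolerance = 1e-8)
  expect_equal(colSums(f$B), rep(1, 3), tolerance = 1e-8)
  expect_true(all(f$A >= -1e-10) && all(f$B >= -1e-10))
  expect_equal(f$Z, X %*% f$B, tolerance = 1e-10)
})

test_that("one archetype per sample reproduces the data exactly", {
  withr::with_seed(3, X <- matrix(runif(20), 4, 5))
  f <- fit_archetypes(X, p = 5, seed = 2)
  expect_lt(f$rss, 1e-9)
})

test_that("the unique simplex representation on an interval is recovered", {
  X <- matrix(c(0, 0.25, 1), nrow = 1)
  f <- fit_archetypes(X, 2, seed = 1)
  expect_equal(sort(as.vector(f$Z)), c(0, 1), tolerance = 1e-6)
  a <- f$A[order(as.vector(f$Z)), 2]
  expect_equal(unname(a), c(0.75, 0.25), tolerance = 1e-6)
})

test_that("rss decreases monotonically over iterations and with p", {
  withr::with_seed(7, {
    W <- matrix(runif(30), 10, 3)              # 3 planted archetypes
    A0 <- t(gtools_rdirichlet(40, rep(0.4, 3)))
    X <- W %*% A0 + matrix(rnorm(400, 0, 0.005), 10, 40)
  })
  f <- fit_archetypes(X, 3, seed = 5)
  expect_true(all(diff(f$rss_path) <= 1e-10))
  scree <- archetype_scree(X, 1:5, seed = 5)
  expect_true(all(diff(scree$rss) <= 1e-8 * scree$rss[1]))
})

test_that("planted archetypes are recovered within noise", {
  sigma <- 0.01
  withr::with_seed(21, {
    W <- matrix(runif(30), 10, 3)
    A0 <- t(gtools_rdirichlet(37, rep(0.3, 3)))
    A0 <- cbind(diag(3), A0)     # ensure near-pure samples exist
    X <- W %*% A0 + matrix(rnorm(400, 0, sigma), 10, 40)
  })
  f <- fit_archetypes(X, 3, seed = 13)
  # match each planted archetype to its closest recovered one
  err <- sapply(seq_len(3), function(k)
    min(apply(abs(f$Z - W[, k]), 2, max)))
  expect_true(all(err <= 3 * sigma))
  # every archetype lies in the convex hull of the data (Z = XB, B simplex)
  expect_true(all(f$B >= -1e-10))
  expect_equal(colSums(f$B), rep(1, 3), tolerance = 1e-8)
})

test_that("fitting is deterministic under a fixed seed", {
  withr::with_seed(9, X <- matrix(runif(60), 6, 10))
  f1 <- fit_archetypes(X, 3, seed = 4)
  f2 <- fit_archetypes(X, 3, seed = 4)
  expect_identical(f1$Z, f2$Z)
  expect_identical(f1$A, f2$A)
})

test_that("the explicit elbow rule picks the distance-to-chord maximum", {
  expect_identical(
    choose_num_archetypes(tibble::tibble(p = 1:5,
                                         rss = c(100, 40, 5, 4.5, 4.4))), 3L)
  # strictly linear decline: degenerate, smallest interior p by tie rule
  expect_identical(
    choose_num_archetypes(tibble::tibble(p = 1:5, rss = c(50, 40, 30, 20, 10))),
    2L)
  # pronounced kink at 5
  scree5 <- tibble::tibble(p = 1:8,
                           rss = c(400, 320, 250, 190, 40, 36, 33, 31))
  expect_identical(choose_num_archetypes(scree5), 5L)
  expect_error(choose_num_archetypes(tibble::tibble(p = 1:2, rss = c(2, 1))),
               "at least 3")
})

test_that("companion profiles map through B as convex combinations", {
  B <- diag(3)
  comp <- matrix(1:12, 4, 3)
  expect_equal(map_profiles(B, comp), comp)
  B2 <- matrix(c(0.5, 0.5, 0, 1), 2, 2)
  comp2 <- matrix(c(2, 4, 6, 8), 2, 2)
  expect_equal(map_profiles(B2, comp2)[, 1], rowMeans(comp2))
  expect_error(map_profiles(diag(3), matrix(1, 2, 2)), "one column per sample")
})

test_that("mapped companion profiles recover the planted archetype companions", {
  sigma <- 0.005
  withr::with_seed(31, {
    W <- matrix(runif(24, 0.2, 1), 8, 3)       # planted concentration archetypes
    Cp <- matrix(runif(15, 0.2, 1), 5, 3)      # planted companion (proteome)
    A0 <- cbind(diag(3), t(gtools_rdirichlet(27, rep(0.3, 3))))
    X <- W %*% A0 + matrix(rnorm(8 * 30, 0, sigma), 8, 30)
    comp <- Cp %*% A0 + matrix(rnorm(5 * 30, 0, sigma), 5, 30)
  })
  f <- fit_archetypes(X, 3, seed = 2)
  mapped <- map_profiles(f$B, comp)
  err <- sapply(seq_len(3), function(k)
    min(apply(abs(mapped - Cp[, k]) / pmax(Cp[, k], 0.2), 2, max)))
  expect_true(all(err < 0.05))
})
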