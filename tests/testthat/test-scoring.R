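makeSig <- function(genes, weights) {
  StemnessSignature(genes, weights, lambda2 = 1, nTrain = 10L,
                    converged = TRUE)
}

test_that("signature/matrix intersection does plain set arithmetic", {
  sig <- makeSig(c("A", "B", "C"), c(1, 2, 3))
  x <- randomExpression(4, 3)
  rownames(x) <- c("B", "C", "D", "E")
  red <- intersectSignature(sig, x)
  expect_identical(signatureGenes(red$signature), c("B", "C"))
  expect_equal(red$coverage, 2 / 3)
  expect_identical(rownames(red$x), c("B", "C"))

  # low coverage warns
  xLow <- x[1:1, , drop = FALSE]
  rownames(xLow) <- "C"
  expect_warning(intersectSignature(sig, xLow), "signature genes present")

  x2 <- x[1:2, ]
  rownames(x2) <- c("A", "B")
  sig2 <- makeSig(c("A", "B"), c(1, 2))
  expect_equal(intersectSignature(sig2, x2)$coverage, 1)

  rownames(x2) <- c("Y", "Z")
  expect_error(intersectSignature(sig2, x2), "no genes shared")
})

test_that("raw scores are Spearman correlations with average-rank ties", {
  g <- paste0("g", 1:4)
  sig <- makeSig(g, c(1, 2, 3, 4))
  x <- cbind(concord = c(10, 20, 40, 80),
             reversed = c(8, 6, 4, 2),
             swapped = c(10, 20, 40, 30))
  rownames(x) <- g
  raw <- scoreSamples(sig, x)
  expect_equal(unname(raw["concord"]), 1)
  expect_equal(unname(raw["reversed"]), -1)
  expect_equal(unname(raw["swapped"]),
               bruteSpearman(c(1, 2, 3, 4), c(10, 20, 40, 30)))
  expect_equal(attr(raw, "nGenesUsed"), 4L)

  # tied expression values follow the average-rank formula
  sigT <- makeSig(g, c(1, 2, 2, 4))
  xt <- matrix(c(5, 5, 7, 9), 4, 1, dimnames = list(g, "s"))
  expect_equal(as.numeric(scoreSamples(sigT, xt)),
               bruteSpearman(c(1, 2, 2, 4), c(5, 5, 7, 9)))
})

test_that("raw scoring matches the brute-force rank oracle on random data", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(4:15, 1)
    w <- rnorm(n)
    v <- abs(rnorm(n))
    if (i %% 3 == 0) v[1:2] <- v[2:1] * 0 + 1  # inject ties
    g <- paste0("g", seq_len(n))
    raw <- scoreSamples(makeSig(g, w),
                        matrix(v, n, 1, dimnames = list(g, "s")))
    expect_equal(as.numeric(raw), bruteSpearman(w, v), tolerance = 1e-12)
  }
})

test_that("scores are invariant under strictly monotone per-sample transforms", {
  set.seed(11)
  n <- 30
  g <- paste0("g", 1:n)
  sig <- makeSig(g, rnorm(n))
  x <- matrix(abs(rnorm(4 * n, 5)), n, 4, dimnames = list(g, letters[1:4]))
  raw <- scoreSamples(sig, x)
  transforms <- list(function(v) 2 * v + 1,
                     function(v) v^3,
                     function(v) exp(v / 10),
                     function(v) log(v + 1))
  for (j in seq_along(transforms)) {
    x2 <- x
    x2[, j] <- transforms[[j]](x2[, j])
    expect_lt(max(abs(scoreSamples(sig, x2) - raw)), 1e-12)
  }
})

test_that("scoring is column-independent (batch equals one-at-a-time)", {
  set.seed(12)
  g <- paste0("g", 1:20)
  sig <- makeSig(g, rnorm(20))
  x <- matrix(rexp(20 * 5), 20, 5, dimnames = list(g, paste0("s", 1:5)))
  batch <- scoreSamples(sig, x)
  single <- vapply(colnames(x), function(s)
    unname(scoreSamples(sig, x[, s, drop = FALSE])), 0)
  expect_equal(as.numeric(batch), unname(single), tolerance = 1e-15)
})

test_that("zero-variance samples score NA with a warning", {
  g <- paste0("g", 1:5)
  sig <- makeSig(g, 1:5)
  x <- cbind(flat = rep(2, 5), ok = c(1, 3, 2, 5, 4))
  rownames(x) <- g
  expect_warning(raw <- scoreSamples(sig, x), "zero expression variance")
  expect_true(is.na(raw["flat"]))
  expect_false(is.na(raw["ok"]))
})

test_that("unit rescaling is the exact affine min-max map", {
  expect_equal(rescaleUnit(c(-0.2, 0.1, 0.4)), c(0, 0.5, 1))
  expect_equal(rescaleUnit(c(0.3, 0.7)), c(0, 1))
  withNA <- rescaleUnit(c(0.1, NA, 0.5, 0.3))
  expect_true(is.na(withNA[2]))
  expect_equal(withNA[-2], c(0, 1, 0.5))
  expect_error(rescaleUnit(c(0.4, 0.4, 0.4)), "identical")
  expect_error(rescaleUnit(c(0.4, NA)), "at least 2 non-missing")
  # order preservation
  set.seed(13)
  r <- rnorm(20)
  expect_identical(order(rescaleUnit(r)), order(r))
})

test_that("duplicating a sample leaves all other stemness values unchanged", {
  set.seed(14)
  g <- paste0("g", 1:15)
  sig <- makeSig(g, rnorm(15))
  x <- matrix(rexp(15 * 6), 15, 6, dimnames = list(g, paste0("s", 1:6)))
  sc <- stemnessScores(sig, x)
  xd <- cbind(x, dup = x[, 3])
  scd <- stemnessScores(sig, xd)
  # a duplicate can never extend the raw-score range, so the affine map is
  # identical and every original sample keeps its stemness exactly
  expect_equal(scd$stemness[match(sc$sample_id, scd$sample_id)],
               sc$stemness, tolerance = 1e-15)
  expect_equal(scd$stemness[scd$sample_id == "dup"],
               sc$stemness[sc$sample_id == "s3"], tolerance = 1e-15)
})

test_that("stemnessScores spans [0,1] and supports per-group rescaling", {
  set.seed(15)
  g <- paste0("g", 1:25)
  sig <- makeSig(g, rnorm(25))
  x <- matrix(rexp(25 * 8), 25, 8, dimnames = list(g, paste0("s", 1:8)))
  sc <- stemnessScores(sig, x)
  expect_equal(min(sc$stemness), 0)
  expect_equal(max(sc$stemness), 1)
  expect_identical(order(sc$stemness), order(sc$raw_score))

  grp <- rep(c("d1", "d2"), each = 4)
  scg <- stemnessScores(sig, x, rescaleScope = "per_group", groups = grp)
  for (gg in unique(grp)) {
    expect_equal(min(scg$stemness[grp == gg]), 0)
    expect_equal(max(scg$stemness[grp == gg]), 1)
  }
  expect_equal(scg$raw_score, sc$raw_score)
  expect_error(stemnessScores(sig, x, rescaleScope = "per_group"),
               "'groups'")
})
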