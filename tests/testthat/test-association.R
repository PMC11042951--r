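test_that("pearsonCor reproduces exact and brute-force correlations", {
  expect_equal(pearsonCor(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearsonCor(c(1, 2, 3), c(3, 2, 1))$r, -1)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  pc <- pearsonCor(x, y)
  expect_equal(pc$r, brutePearson(x, y), tolerance = 1e-14)
  # p from the exact t transform with n - 2 df
  tstat <- pc$r * sqrt((4 - 2) / (1 - pc$r^2))
  expect_equal(pc$p, 2 * pt(abs(tstat), 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(pearsonCor(c(1, 1, 1), y[1:3]), "zero variance in 'x'")
  expect_error(pearsonCor(x[1:3], c(2, 2, 2)), "zero variance in 'y'")
  expect_error(pearsonCor(1:2, 1:2), "at least 3")
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhAdjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bhAdjust(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(20)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    q <- bhAdjust(p)
    expect_lt(max(abs(q - bruteBH(p))), 1e-12)
    expect_true(all(q >= p))
  }
})

test_that("group-wise correlation screen enforces minN and corrects across groups", {
  set.seed(21)
  n <- 40
  tab <- rbind(makeSampleTable(n, "liver"), makeSampleTable(n, "kidney"),
               makeSampleTable(5, "rare"))
  tab$sample_id <- sprintf("S%03d", seq_len(nrow(tab)))
  tab$age_years <- rep(seq(25, 75, length.out = n), length.out = nrow(tab))
  stem <- -0.005 * tab$age_years + rnorm(nrow(tab), sd = 0.05)
  scores <- data.frame(sample_id = tab$sample_id, raw_score = stem,
                       stemness = stem, n_genes_used = 10L)
  ct <- correlateWithinGroups(scores, tab, "age_years", minN = 40L)
  expect_identical(ct$group, c("kidney", "liver"))
  expect_identical(attr(ct, "skipped"), "rare")
  expect_true(all(ct$fdr >= ct$p))
  expect_true(all(ct$r < 0))
  # BH is applied across the reported groups only
  expect_equal(ct$fdr, bruteBH(ct$p), tolerance = 1e-12)

  # two groups with identical data give identical results and fdr == p
  tab2 <- rbind(makeSampleTable(10, "a"), makeSampleTable(10, "b"))
  tab2$sample_id <- sprintf("T%02d", 1:20)
  y <- rep(c(0.1, 0.2, 0.35, 0.3, 0.5, 0.45, 0.6, 0.75, 0.7, 0.9), 2)
  sc2 <- data.frame(sample_id = tab2$sample_id, raw_score = y,
                    stemness = y, n_genes_used = 5L)
  ct2 <- correlateWithinGroups(sc2, tab2, "age_years", minN = 5L)
  expect_equal(ct2$r[1], ct2$r[2])
  expect_equal(ct2$p[1], ct2$p[2])
  expect_equal(ct2$fdr, ct2$p)

  expect_error(correlateWithinGroups(scores, tab, "age_years", minN = 500L),
               "no group reaches")
})

test_that("gene-set signals are plain means over present genes", {
  x <- rbind(A = c(2, 8), B = c(4, 2), C = c(6, 5))
  colnames(x) <- c("s1", "s2")
  expect_equal(geneSetSignal(x, c("A", "B")), c(s1 = 3, s2 = 5))
  expect_warning(s <- geneSetSignal(x, c("A", "Z", "W")), "coverage")
  expect_equal(s, c(s1 = 2, s2 = 8))
  expect_error(geneSetSignal(x, c("Y", "Z")), "none of the")
  expect_equal(geneSetSignal(x, rownames(x)), colMeans(x))
  # singleton set degenerates to the marker signal exactly
  expect_identical(geneSetSignal(x, "B"), markerSignal(x, "B"))
})

test_that("marker signals extract the exact row and fail informatively", {
  x <- randomExpression(10, 4)
  expect_identical(markerSignal(x, "G003"), x["G003", ])
  expect_error(markerSignal(x, "G999"), "not found")
  expect_error(markerSignal(x, "g003"), "near matches.*G003")
})

test_that("group comparisons use Welch/Student t for 2 groups and KW beyond", {
  v <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- rep(c("a", "b"), each = 4)
  cmp <- compareGroups(v, g)
  expect_identical(cmp$test, "t")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p, 1)

  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  w <- bruteWelch(a, b)
  cmpW <- compareGroups(c(a, b), g)
  expect_equal(cmpW$statistic, w$t, tolerance = 1e-12)
  expect_equal(cmpW$df, w$df, tolerance = 1e-12)
  # pooled (Student) variant uses n1 + n2 - 2 df
  cmpP <- compareGroups(c(a, b), g, pooled = TRUE)
  expect_equal(cmpP$df, 6)

  kw <- compareGroups(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                      rep(c("x", "y", "z"), each = 3))
  expect_identical(kw$test, "kruskal-wallis")
  expect_equal(kw$statistic,
               bruteKruskalH(1:9, rep(c("x", "y", "z"), each = 3)),
               tolerance = 1e-12)

  expect_error(compareGroups(rep(5, 9), rep(c("x", "y", "z"), each = 3)),
               "zero variance")
  expect_error(compareGroups(1:5, c("a", "a", "a", "a", "b")),
               "fewer than 2")
  expect_error(compareGroups(1:3, c("a", "a", "a")), "at least 2 groups")
})

test_that("proliferation sets are the top fraction of marker-correlated genes", {
  set.seed(22)
  n <- 50
  marker <- rnorm(n, 10, 2)
  x <- rbind(
    PCNA = marker,
    hi1 = marker + rnorm(n, sd = 0.1),
    hi2 = 2 * marker + rnorm(n, sd = 0.1),
    lo1 = 22 - marker + rnorm(n, sd = 0.1),
    noise = rexp(n, 1 / 5))
  colnames(x) <- paste0("s", seq_len(n))
  top <- deriveProliferationSet(x, "PCNA", topFrac = 0.4)
  expect_setequal(top, c("hi1", "hi2"))
  expect_false("PCNA" %in% deriveProliferationSet(x, "PCNA", topFrac = 1))
})

test_that("the correlation screen controls FDR under a global null", {
  cfg <- tinyCohortConfig(seed = 55L)
  cfg$tissues <- lapply(cfg$tissues, function(ts) { ts$betaAge <- 0; ts })
  sig <- trainStemnessSignature(simulateTrainingCohort(cfg))
  reps <- 100L
  flagged <- 0L
  total <- 0L
  for (r in seq_len(reps)) {
    co <- simulateCohort(cfg, seed = 30000L + r)
    sc <- stemnessScores(sig, co)
    ct <- correlateWithinGroups(sc, sampleTable(co), "age_years")
    flagged <- flagged + sum(ct$fdr < 0.05)
    total <- total + nrow(ct)
  }
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / total)
  expect_lte(flagged / total, bound)
})
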