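test_that("median-of-ratios size factors match closed forms", {
  m <- matrix(c(10L, 20L, 35L, 10L, 20L, 35L), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(size_factors(m), c(s1 = 1, s2 = 1))

  # sample2 is exactly double sample1: geomean_i = counts_i1 * sqrt(2)
  m2 <- m; m2[, 2] <- 2L * m2[, 1]
  expect_equal(size_factors(m2), c(s1 = 1 / sqrt(2), s2 = sqrt(2)))

  expect_equal(size_factors(m[, 1, drop = FALSE]), c(s1 = 1))

  mz <- matrix(c(0L, 5L, 3L, 0L), ncol = 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(mz), "all-positive")
})

test_that("method-of-moments dispersion recovers the generating model", {
  # Poisson data: alpha estimates collapse toward the floor
  cm <- toy_count_matrix(n_feat = 300, nC = 10, nT = 10, mu = 1000,
                         alpha = 0, seed = 5)
  a <- estimate_dispersion(cm)
  expect_lt(median(a), 0.01)

  # constant counts within each condition: zero variance -> floor
  m <- matrix(rep(c(100L, 200L), each = 2), nrow = 1, byrow = TRUE,
              dimnames = list("f1", c("c1", "c2", "t1", "t2")))
  cmc <- count_matrix(m, c(c1 = "control", c2 = "control",
                           t1 = "treatment", t2 = "treatment"))
  ac <- estimate_dispersion(cmc, sf = rep(1, 4))
  expect_equal(as.vector(ac), 1e-8)

  # NB alpha = 0.2 at mean 500, 50 replicates per group
  cm2 <- toy_count_matrix(n_feat = 300, nC = 50, nT = 50, mu = 500,
                          alpha = 0.2, seed = 6)
  a2 <- estimate_dispersion(cm2)
  expect_gt(median(a2), 0.15)
  expect_lt(median(a2), 0.25)

  # all-zero features are flagged untestable
  m3 <- rbind(f0 = rep(0L, 4), f1 = c(10L, 12L, 30L, 28L))
  colnames(m3) <- c("c1", "c2", "t1", "t2")
  cm3 <- count_matrix(m3, c(rep("control", 2), rep("treatment", 2)))
  a3 <- estimate_dispersion(cm3, sf = rep(1, 4))
  expect_equal(unname(attr(a3, "untestable")), c(TRUE, FALSE))
})

test_that("Wald test handles degenerate features and recovers planted fold-changes", {
  # treatment identical to control: log2fc 0, p 1
  m <- matrix(rep(c(10L, 50L, 200L), 4), ncol = 4,
              dimnames = list(c("a", "b", "c"), c("c1", "c2", "t1", "t2")))
  cm <- count_matrix(m, c(rep("control", 2), rep("treatment", 2)))
  res <- nb_wald_test(cm)
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$wald_z, rep(0, 3))
  expect_equal(res$pvalue, rep(1, 3))
  expect_true(all(res$qvalue >= res$pvalue - 1e-12))

  # all-zero feature: untestable, log2fc 0, p 1
  m2 <- rbind(zero = rep(0L, 4), ok = c(10L, 12L, 40L, 44L))
  colnames(m2) <- colnames(m)[1:4]
  cm2 <- count_matrix(m2, c(rep("control", 2), rep("treatment", 2)))
  res2 <- nb_wald_test(cm2, sf = rep(1, 4))
  expect_true(res2$untestable[1])
  expect_equal(res2$log2fc[1], 0)
  expect_equal(res2$pvalue[1], 1)

  # a condition with < 2 samples is a degenerate design
  m3 <- m[, 1:3]
  cm3 <- count_matrix(m3, c("control", "treatment", "treatment"))
  expect_error(nb_wald_test(cm3), ">= 2 samples")

  # planted log2fc = 1 in every feature: recovery needs the true size
  # factors, since a global fold-change is indistinguishable from depth
  # under median-of-ratios normalization
  cm4 <- toy_count_matrix(n_feat = 2000, nC = 6, nT = 6, mu = 500,
                          alpha = 0.05, lfc = 1, seed = 8)
  res4 <- nb_wald_test(cm4, sf = rep(1, 12))
  expect_lt(abs(mean(res4$log2fc) - 1), 0.05)
})

test_that("BH adjustment matches the step-up procedure and rejects bad input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.1, -0.1)), "0, 1")
})

test_that("BH q-values never decrease when a p-value increases", {
  set.seed(31)
  for (k in 1:20) {
    p <- runif(30)
    q <- bh_adjust(p)
    i <- sample.int(30, 1)
    p2 <- p
    p2[i] <- min(1, p[i] + runif(1, 0, 1 - p[i]))
    q2 <- bh_adjust(p2)
    expect_true(all(q2 >= q - 1e-12))
  }
})

test_that("swapping condition labels negates fold-changes and preserves p-values", {
  cm <- toy_count_matrix(n_feat = 200, nC = 4, nT = 4, alpha = 0.05,
                         lfc = 0.5, seed = 13)
  swapped <- count_matrix(cm$counts,
                          ifelse(cm$condition == "control",
                                 "treatment", "control"))
  r1 <- nb_wald_test(cm)
  r2 <- nb_wald_test(swapped)
  expect_equal(r2$log2fc, -r1$log2fc)
  expect_equal(r2$pvalue, r1$pvalue)
})

test_that("integer depth rescaling of one sample leaves results essentially unchanged", {
  cm <- toy_count_matrix(n_feat = 300, nC = 4, nT = 4, mu = 800,
                         alpha = 0.05, lfc = 0.3, seed = 17)
  sf1 <- size_factors(cm)
  scaled <- cm$counts
  scaled[, 1] <- 3L * scaled[, 1]
  cm2 <- count_matrix(scaled, cm$condition)
  sf2 <- size_factors(cm2)
  # the scaled sample's factor grows by 3 up to the shared geometric-mean shift
  expect_equal(unname(sf2[1] / sf1[1]), unname(3 * (sf2[2] / sf1[2])),
               tolerance = 1e-9)
  r1 <- nb_wald_test(cm)
  r2 <- nb_wald_test(cm2)
  expect_equal(r2$log2fc, r1$log2fc, tolerance = 0.01)
  expect_equal(r2$pvalue, r1$pvalue, tolerance = 0.02)
})

test_that("fold-change estimates agree with an independent NB implementation (DESeq2)", {
  set.seed(21)
  n <- 250; nC <- 5; nT <- 5
  lfc <- rnorm(n, 0, 1)
  mu <- exp(runif(n, log(100), log(2000)))
  ids <- sprintf("f%03d", seq_len(n))
  cond <- rep(c("control", "treatment"), c(nC, nT))
  m <- sapply(seq_len(nC + nT), function(j) {
    rnbinom(n, mu = mu * 2^(lfc * (cond[j] == "treatment")), size = 1 / 0.05)
  })
  dimnames(m) <- list(ids, paste0("s", seq_len(nC + nT)))
  mine <- nb_wald_test(count_matrix(m, cond))

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      m, data.frame(condition = factor(cond, c("control", "treatment"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds)
  })
  expect_gt(cor(mine$log2fc, ref$log2FoldChange), 0.98)
  expect_gt(cor(mine$log2fc, lfc), 0.95)
})

test_that("count matrix and sample sheet TSVs round-trip through the readers", {
  cm <- toy_count_matrix(n_feat = 20, seed = 23)
  counts_path <- tempfile(fileext = ".tsv")
  samples_path <- tempfile(fileext = ".tsv")
  write_counts_tsv(cm, counts_path)
  write.table(data.frame(sample_id = names(cm$condition),
                         condition = unname(cm$condition)),
              samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_count_matrix(counts_path, samples_path)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$condition, cm$condition)

  bad_sheet <- tempfile(fileext = ".tsv")
  write.table(data.frame(sample_id = "c1", condition = "mock"),
              bad_sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_count_matrix(counts_path, bad_sheet), "control")
})
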