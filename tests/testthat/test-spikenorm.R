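test_that("spike size factors follow hand-computed median-of-ratios", {
  m <- rbind(g1 = c(100, 100), g2 = c(50, 70),
             spike1 = c(4, 16), spike2 = c(9, 36))
  colnames(m) <- c("A", "B")
  spike <- c(g1 = FALSE, g2 = FALSE, spike1 = TRUE, spike2 = TRUE)
  sf <- spikein_size_factors(m, spike)
  expect_equal(unname(sf), c(0.5, 2))           # refs (8, 18); ratios 0.5 / 2
  # identical columns give unit factors
  m2 <- cbind(A = m[, 1], B = m[, 1])
  expect_equal(unname(spikein_size_factors(m2, spike)), c(1, 1))
  # non-spike counts cannot move a spike-only estimator
  m3 <- m; m3[c("g1", "g2"), "A"] <- m3[c("g1", "g2"), "A"] * 10
  expect_equal(spikein_size_factors(m3, spike), sf)
  # failure modes
  expect_error(spikein_size_factors(m[1:2, ], spike[1:2]), "no spike-in rows")
  m4 <- m; m4[c("spike1", "spike2"), "A"] <- 0
  expect_error(spikein_size_factors(m4, spike), "nonzero")
})

test_that("normalization divides columns and validates factors", {
  m <- matrix(c(10, 20, 30, 40), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  out <- normalize_counts(m, c(s1 = 2, s2 = 1))
  expect_equal(out[, "s1"], c(a = 5, b = 10))
  expect_equal(out[, "s2"], m[, "s2"])
  expect_equal(normalize_counts(m, c(1, 1)), m)
  expect_error(normalize_counts(m, c(0, 1)), "positive")
  expect_error(normalize_counts(m, 1), "one factor per sample")
})

test_that("size factors are equivariant to per-sample scaling", {
  # scaling one sample by c multiplies its factor by c relative to every other
  # factor; the geometric-mean reference absorbs a global c^(1/n), so factor
  # RATIOS carry the equivariance and normalized counts change only by one
  # shared constant (irrelevant to fold changes and base means)
  w <- count_world(seed = 11, intercept = -1)
  m <- w$cm$counts
  sf <- spikein_size_factors(m, w$cm$spike_in)
  m2 <- m; m2[, "t1"] <- m2[, "t1"] * 5
  sf2 <- spikein_size_factors(m2, w$cm$spike_in)
  others <- setdiff(names(sf), "t1")
  expect_equal(sf2[["t1"]] / sf2[others], 5 * sf[["t1"]] / sf[others],
               tolerance = 1e-12)
  ratio <- normalize_counts(m2, sf2) / normalize_counts(m, sf)
  ratio <- ratio[is.finite(ratio)]
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-12)
})

test_that("fold changes use the moderated ratio and filter dead genes", {
  nm <- rbind(g1 = c(5, 5, 10, 10), g2 = c(8, 8, 8, 8),
              g3 = c(0, 0, 0, 0), g4 = c(0, 0, 12, 12))
  colnames(nm) <- c("t1", "t2", "c1", "c2")
  spike <- setNames(rep(FALSE, 4), rownames(nm))
  fc <- fold_change_table(nm, c("t1", "t2"), c("c1", "c2"), spike)
  expect_equal(fc$log2fc[fc$gene == "g1"], log2(5.5 / 10.5), tolerance = 1e-12)
  expect_equal(fc$log2fc[fc$gene == "g2"], 0)
  expect_false("g3" %in% fc$gene)               # zero everywhere: filtered
  # zero-in-control gene kept finite via the pseudocount
  expect_true(is.finite(fc$log2fc[fc$gene == "g4"]))
  expect_equal(fc$base_mean[fc$gene == "g1"], 7.5)
  expect_error(fold_change_table(nm, c("t1"), c("t1", "c1"), spike), "overlap")
  expect_error(fold_change_table(nm, character(0), "c1", spike), "non-empty")
  # spike rows are excluded from the table
  spike2 <- spike; spike2["g2"] <- TRUE
  expect_false("g2" %in% fold_change_table(nm, c("t1", "t2"), c("c1", "c2"), spike2)$gene)
})

test_that("the abundance-depletion fit matches the closed-form OLS oracle", {
  # exact line: log2fc = -1 - 0.5 log10(bm)
  bm <- c(10, 100, 1000, 10000)
  tb <- data.frame(gene = paste0("g", 1:4), base_mean = bm,
                   log2fc = -1 - 0.5 * log10(bm), biotype = "protein_coding")
  class(tb) <- c("fold_change_table", "data.frame")
  fit <- abundance_depletion_fit(tb)
  expect_equal(fit$slope, -0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, -1, tolerance = 1e-12)
  expect_equal(fit$table$residual, rep(0, 4), tolerance = 1e-12)

  # three points (x, y) = (0,0), (1,1), (2,2) in log10 space
  tb2 <- data.frame(gene = paste0("g", 1:3), base_mean = 10^(0:2),
                    log2fc = 0:2, biotype = "protein_coding")
  fit2 <- abundance_depletion_fit(tb2)
  expect_equal(c(fit2$slope, fit2$intercept), c(1, 0), tolerance = 1e-12)

  # random points vs the closed-form estimator
  set.seed(9)
  x <- runif(50, 0, 4); y <- -1 + 0.3 * x + rnorm(50, 0, 0.5)
  tb3 <- data.frame(gene = paste0("g", 1:50), base_mean = 10^x, log2fc = y,
                    biotype = "protein_coding")
  fit3 <- abundance_depletion_fit(tb3)
  beta <- cov(x, y) / var(x)
  alpha <- mean(y) - beta * mean(x)
  expect_equal(fit3$slope, beta, tolerance = 1e-9)
  expect_equal(fit3$intercept, alpha, tolerance = 1e-9)
  expect_lt(abs(sum(fit3$table$residual)), 1e-9)   # residuals sum to zero

  # degenerate predictor
  tb4 <- tb3; tb4$base_mean <- 100
  expect_error(abundance_depletion_fit(tb4), "degenerate")
  expect_error(abundance_depletion_fit(tb3[1:2, ]), "at least 3")
})

test_that("residual-threshold selection follows the timepoint rules", {
  tb <- data.frame(gene = c("a", "b", "c"), base_mean = c(10, 10, 10),
                   log2fc = 0, biotype = "protein_coding")
  fit <- structure(list(slope = 0, intercept = 0,
                        table = transform(tb, residual = c(0.5, 1.5, 2.5)),
                        log_base = 10),
                   class = "regression_selection")
  expect_equal(select_outlier_transcripts(fit, threshold = 2)$genes, "c")
  expect_equal(select_outlier_transcripts(fit, threshold = 1)$genes, c("b", "c"))
  expect_equal(select_outlier_transcripts(fit, threshold = 3)$genes, character(0))
  expect_equal(select_outlier_transcripts(fit, timepoint = 50)$threshold, 1)
  expect_equal(select_outlier_transcripts(fit, timepoint = 200)$threshold, 2)
  expect_equal(select_outlier_transcripts(fit, timepoint = 1440)$threshold, 2)
  expect_error(select_outlier_transcripts(fit, timepoint = 300), "no default threshold")
  expect_error(select_outlier_transcripts(fit), "timepoint or an explicit")
})
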