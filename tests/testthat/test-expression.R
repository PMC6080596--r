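test_that("delta-Ct transform is exact and multiplicatively consistent", {
  expect_equal(relative_expression(20, 20), 1)
  expect_equal(relative_expression(21, 20), 0.5)
  expect_equal(relative_expression(15, 18), 8)
  # one cycle <=> factor 2, at any baseline
  for (ct in c(12, 20, 31.7)) {
    expect_equal(relative_expression(ct - 1, ct) /
                   relative_expression(ct, ct), 2)
  }
  # monotone decreasing in the target Ct
  cts <- seq(10, 30, by = 0.5)
  expect_true(all(diff(relative_expression(cts, 20)) < 0))
  expect_error(relative_expression(20, NA), "missing")
})

test_that("Ct tables are validated and timepoints ordered", {
  df <- expand.grid(genotype = "g1", timepoint = c("BV", "NV1"),
                    replicate = c("r1", "r2"), gene = c("ACT2", "FLC"),
                    stringsAsFactors = FALSE)
  df$ct <- 20
  tab <- ct_table(df, timepoint_levels = c("BV", "NV1"))
  expect_s3_class(tab$timepoint, "ordered")
  expect_error(ct_table(df[, -5]), "missing column")
  bad <- df; bad$ct[1] <- -3
  expect_error(ct_table(bad), "finite")
  dup <- rbind(df, df[1, ])
  expect_error(ct_table(dup), "duplicated")
})

test_that("round-trip through delimited text preserves the table", {
  dir <- withr::local_tempdir()
  df <- data.frame(genotype = "g1", timepoint = rep(c("BV", "NV1"), 2),
                   replicate = "r1", gene = rep(c("ACT2", "FLC"), each = 2),
                   ct = c(20, 20, 22, 19.5))
  for (ext in c("csv", "tsv")) {
    path <- file.path(dir, paste0("ct.", ext))
    write.table(df, path, sep = if (ext == "csv") "," else "\t",
                row.names = FALSE, quote = FALSE)
    back <- read_ct_table(path)
    expect_equal(back$ct, df$ct)
    expect_identical(levels(back$timepoint), c("BV", "NV1"))
  }
})

test_that("timepoint means handle replicates, lost samples and empty cells", {
  tps <- c("BV", "NV1", "NV2")
  rows <- expand.grid(genotype = "g1", timepoint = tps,
                      replicate = paste0("r", 1:4),
                      gene = c("ACT2", "FLC"), stringsAsFactors = FALSE)
  rows$ct <- ifelse(rows$gene == "ACT2", 20, 20)  # relative expression 1
  # lose one FLC sample at NV1, and the whole NV2 cell
  rows <- rows[!(rows$gene == "FLC" & rows$timepoint == "NV1" &
                   rows$replicate == "r4"), ]
  rows <- rows[!(rows$gene == "FLC" & rows$timepoint == "NV2"), ]
  tab <- ct_table(rows, timepoint_levels = tps)
  expect_warning(m <- timepoint_means(tab, "g1", "FLC"), "NV2")
  expect_equal(m$n, c(4L, 3L, 0L))
  expect_equal(m$mean[1:2], c(1, 1))
  expect_equal(m$sem[1:2], c(0, 0))
  expect_true(is.na(m$mean[3]))
  # a target row without its reference sample is an error
  orphan <- rbind(rows, data.frame(genotype = "g1", timepoint = "NV2",
                                   replicate = "r9", gene = "FLC", ct = 21))
  expect_error(timepoint_means(ct_table(orphan, tps), "g1", "FLC"),
               "reference")
})

test_that("rank correlation reproduces hand-computed values", {
  r <- stage_correlation(1:6, 6:1)
  expect_equal(r$rho, -1)
  # sum of squared rank differences 68 -> rho = 1 - 6*68/210
  r2 <- stage_correlation(1:6, c(6, 5, 4, 3, 1, 2))
  expect_equal(r2$rho, 1 - 6 * 68 / 210, tolerance = 1e-12)
  expect_equal(round(r2$rho, 2), -0.94)
  # t approximation matches the printed style of correlation tables
  expect_equal(round(r2$p_approx, 3), 0.005)
  r3 <- stage_correlation(1:6, c(2, 1, 4, 3, 6, 5))  # sum d^2 = 6
  expect_equal(r3$rho, 1 - 6 * 6 / 210, tolerance = 1e-12)
  expect_equal(r3$p_approx,
               2 * pt(-abs(r3$rho * sqrt(4 / (1 - r3$rho^2))), df = 4),
               tolerance = 1e-12)
})

test_that("a series against itself has one-sided exact p of 1/factorial(n)", {
  x <- c(0.2, 1.5, 0.9, 3.2, 2.2, 5.0)
  r <- stage_correlation(x, x)
  expect_equal(r$rho, 1)
  expect_equal(r$p_greater, 1 / 720)
})

test_that("exact permutation p matches brute-force enumeration at n = 6", {
  withr::with_seed(88, {
    for (i in 1:5) {
      a <- rnorm(6); b <- rnorm(6)
      r <- stage_correlation(a, b)
      perms <- oracle_perms(6)
      ra <- rank(a); rb <- rank(b)
      rhos <- apply(perms, 1, function(p) cor(ra, rb[p]))
      ge <- mean(rhos >= r$rho - 1e-12)
      le <- mean(rhos <= r$rho + 1e-12)
      expect_equal(r$p_greater, ge, tolerance = 1e-12)
      expect_equal(r$p_less, le, tolerance = 1e-12)
      expect_equal(r$p_exact, min(1, 2 * min(ge, le)), tolerance = 1e-12)
    }
  })
})

test_that("rho is invariant under strictly monotone transforms", {
  a <- c(0.5, 3, 1.2, 7, 4, 2.5)
  b <- c(9, 2, 5, 1, 3, 8)
  base <- stage_correlation(a, b)$rho
  expect_equal(stage_correlation(exp(a), b)$rho, base)
  expect_equal(stage_correlation(a, log(b))$rho, base)
  expect_equal(stage_correlation(2 * a + 1, b^3)$rho, base)
})

test_that("degenerate correlation inputs are handled explicitly", {
  expect_error(stage_correlation(1:6, 1:5), "lengths differ")
  expect_error(stage_correlation(1:2, 2:1), "at least 3")
  r <- stage_correlation(rep(1, 6), 1:6)
  expect_true(is.na(r$rho))
  expect_identical(r$method, "undefined")
})

test_that("pairwise correlations across genes mirror per-series results", {
  profiles <- list(
    FLC1 = c(3, 2.5, 2, 0.5, 0.2, 0.1),
    SOC1 = c(0.1, 0.3, 0.8, 2, 2.8, 3.2),
    FT = c(1, 1.2, 0.8, 1.1, 0.9, 1.05))
  tab <- simulate_qpcr("MAH", paste0("T", 1:6), replicates = 3,
                       gene_profiles = profiles, noise_sd = 0, seed = 12)
  out <- expression_correlations(tab, "MAH")
  expect_identical(nrow(out), 3L)
  row <- out[out$gene_a == "FLC1" & out$gene_b == "SOC1" |
               out$gene_a == "SOC1" & out$gene_b == "FLC1", ]
  expect_equal(row$rho, -1)
  expect_identical(unique(out$n_timepoints), 6L)
})
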