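test_that("site counting reproduces hand-enumerated codon fractions", {
  # TTT: of its 9 single-nt mutants only TTT->TTC is synonymous
  expect_equal(count_sites("TTT"),
               c(S_sites = 1 / 3, N_sites = 8 / 3))
  # ATG: Met has a single codon, all 9 mutants nonsynonymous
  expect_equal(count_sites("ATG"), c(S_sites = 0, N_sites = 3))
  expect_error(count_sites("ATGTAA"), "stop codon")
  expect_error(count_sites("ATG---"), "ungapped")
})

test_that("S and N sites sum to 3 per codon for random coding sequences", {
  sense <- sense_codons()
  withr::with_seed(202, {
    for (i in 1:25) {
      n <- sample(10:200, 1)
      seq <- paste(sample(sense, n, replace = TRUE), collapse = "")
      s <- count_sites(seq)
      expect_equal(unname(s[1] + s[2]), 3 * n, tolerance = 1e-9)
    }
  })
})

test_that("difference counting averages over minimal mutational pathways", {
  # two pathways TTT->GTA: via GTT (nonsyn+syn), via TTA (nonsyn+nonsyn)
  expect_equal(count_differences("TTT", "GTA"), c(Sd = 0.5, Nd = 1.5))
  expect_equal(count_differences("AAA", "AAA"), c(Sd = 0, Nd = 0))
  expect_equal(count_differences("AAA", "AAG"), c(Sd = 1, Nd = 0))
  expect_error(count_differences("A-A", "AAA"), "gap")
  expect_error(count_differences("TAA", "AAA"), "sense")
})

test_that("difference counting equals the brute-force pathway oracle on all codon pairs", {
  sense <- sense_codons()
  checked <- 0L
  for (a in sense) {
    for (b in sense) {
      got <- count_differences(a, b)
      want <- oracle_count_differences(a, b)
      expect_equal(unname(got[1:2]), unname(want), tolerance = 1e-12,
                   label = paste(a, b))
      checked <- checked + 1L
    }
  }
  expect_identical(checked, 61L * 61L)
})

test_that("stop-blocked codon pairs fall back to stop-inclusive averaging with a flag", {
  sense <- sense_codons()
  found <- FALSE
  for (a in sense) {
    for (b in sense) {
      got <- count_differences(a, b)
      if (isTRUE(attr(got, "stop_blocked"))) {
        found <- TRUE
        want <- oracle_count_differences(a, b, exclude_stops = FALSE)
        expect_equal(unname(got[1:2]), unname(want))
      }
    }
  }
  # with one or two differences between sense codons no pathway is ever
  # fully blocked; the flag only matters if such a pair exists at 3 diffs
  expect_true(is.logical(found))
})

test_that("pathway step totals equal the nucleotide difference count", {
  sense <- sense_codons()
  withr::with_seed(11, {
    for (i in 1:200) {
      ab <- sample(sense, 2)
      d <- count_differences(ab[1], ab[2])
      ndiff <- sum(strsplit(ab[1], "")[[1]] != strsplit(ab[2], "")[[1]])
      expect_equal(unname(d[1] + d[2]), ndiff, tolerance = 1e-9)
    }
  })
})

test_that("parsimony classifies codon columns against the outgroup", {
  asg <- reconstruct_ancestor(tiny_trio())
  cls <- as.character(asg$classification)
  expect_identical(cls, c("invariant", "lineage1", "lineage2", "invariant"))
  ev <- asg$events
  expect_identical(nrow(ev), 2L)
  # lineage 1: GCT(A) -> GAT(D), nonsynonymous
  e1 <- ev[ev$lineage == 1, ]
  expect_identical(e1$nt_from, "GCT")
  expect_identical(e1$nt_to, "GAT")
  expect_false(e1$synonymous)
  # lineage 2: AAA(K) -> AAG(K), synonymous
  e2 <- ev[ev$lineage == 2, ]
  expect_true(e2$synonymous)
  expect_identical(e2$aa_position, 3L)
  # ancestor equals outgroup everywhere (no shared/ambiguous columns)
  expect_identical(asg$ancestor, "ATGGCTAAATTT")
})

test_that("shared and ambiguous columns are excluded from lineage events", {
  trio <- codon_alignment(c(
    p1 = paste0("ATG", "GGG", "TGT"),
    p2 = paste0("ATG", "GGG", "TTA"),
    og = paste0("ATG", "GGC", "TCT")))
  asg <- reconstruct_ancestor(
    trio, roles = c(paralog1 = "p1", paralog2 = "p2", outgroup = "og"))
  expect_identical(asg$shared_sites, 2L)
  expect_identical(asg$ambiguous_sites, 3L)
  expect_identical(nrow(asg$events), 0L)
  # ancestor takes the common paralog state at the shared column
  expect_identical(substr(asg$ancestor, 4, 6), "GGG")
  expect_identical(substr(asg$ancestor, 7, 9), "NNN")
})

test_that("a codon deletion in one paralog yields a single indel event", {
  trio <- codon_alignment(c(
    p1 = paste0("ATG", "GCT", "AAA", "GAT", "TTT"),
    p2 = paste0("ATG", "---", "---", "---", "TTT"),
    og = paste0("ATG", "GCT", "AAA", "GAT", "TTT")))
  asg <- reconstruct_ancestor(trio)
  ev <- asg$events
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "indel")
  expect_identical(ev$lineage, 2L)
  expect_identical(ev$span_codons, 3L)
  expect_identical(ev$nt_from, "GCTAAAGAT")
  expect_identical(ev$nt_to, "---------")
})

test_that("role resolution failures and wrong trio sizes error", {
  expect_error(reconstruct_ancestor(codon_alignment(
    c(a = "ATGGCT", b = "ATGGCA"))), "exactly three")
  expect_error(reconstruct_ancestor(
    tiny_trio(), roles = c(paralog1 = "nope", paralog2 = "paralog2",
                           outgroup = "outgroup")), "roles")
})

test_that("divergence arithmetic reproduces printed four-decimal table rows", {
  # counts as printed for the two paralog lineages
  e1 <- divergence_estimate(Sd = 1, S_sites = 134.33, Nd = 2,
                            N_sites = 444.67, correction = "jukes_cantor",
                            rounding = "truncate", decimals = 4)
  expect_equal(e1$dS, 0.0074)
  expect_equal(e1$dN, 0.0045)
  expect_equal(round(e1$omega, 4), 0.6081)
  e2 <- divergence_estimate(Sd = 1, S_sites = 134.50, Nd = 8,
                            N_sites = 444.50, correction = "jukes_cantor",
                            rounding = "truncate", decimals = 4)
  expect_equal(e2$dS, 0.0074)
  expect_equal(e2$dN, 0.0182)
  expect_equal(round(e2$omega, 4), 2.4595)
})

test_that("omega is missing when dS is zero and JC errors at p >= 3/4", {
  e <- divergence_estimate(Sd = 0, S_sites = 100, Nd = 0, N_sites = 300)
  expect_equal(e$dS, 0)
  expect_equal(e$dN, 0)
  expect_true(is.na(e$omega))
  expect_error(divergence_estimate(Sd = 80, S_sites = 100, Nd = 0,
                                   N_sites = 300), "Jukes-Cantor")
})

test_that("JC-corrected divergence dominates the raw proportion", {
  for (p in seq(0.01, 0.74, by = 0.04)) {
    d <- -0.75 * log(1 - 4 / 3 * p)
    expect_gt(d, p)
  }
  # and the package applies that formula through the estimate
  e <- divergence_estimate(Sd = 10, S_sites = 100, Nd = 0.5, N_sites = 300,
                           correction = "jukes_cantor")
  expect_equal(e$dS, -0.75 * log(1 - 4 / 3 * 0.1), tolerance = 1e-12)
  raw <- divergence_estimate(Sd = 10, S_sites = 100, Nd = 0.5,
                             N_sites = 300, correction = "none")
  expect_gt(e$dS, raw$dS)
})

test_that("lineage divergence from an assignment matches per-codon accounting", {
  asg <- reconstruct_ancestor(tiny_trio())
  est1 <- lineage_divergence(asg, 1, correction = "none")
  est2 <- lineage_divergence(asg, 2, correction = "none")
  # one nonsynonymous single-nt difference on lineage 1
  expect_equal(est1$Sd, 0); expect_equal(est1$Nd, 1)
  # one synonymous on lineage 2
  expect_equal(est2$Sd, 1); expect_equal(est2$Nd, 0)
  # sites: average of ancestor and descendant; equal-length ungapped
  # comparison conserves S + N = 3 * codons
  expect_equal(est1$S_sites + est1$N_sites, 3 * 4, tolerance = 1e-9)
  expect_equal(est2$S_sites + est2$N_sites, 3 * 4, tolerance = 1e-9)
  expect_true(is.na(est1$omega))  # dS = 0
})

test_that("gapped codons are excluded from counts but reported as indels", {
  trio <- codon_alignment(c(
    p1 = paste0("ATG", "GCT", "AAA", "TTT"),
    p2 = paste0("ATG", "---", "AAG", "TTT"),
    og = paste0("ATG", "GCT", "AAA", "TTT")))
  asg <- reconstruct_ancestor(trio)
  est2 <- lineage_divergence(asg, 2, correction = "none")
  expect_equal(est2$Sd, 1)
  expect_equal(est2$indel_events, 1)
  # sites computed over the 3 shared ungapped codons only
  expect_equal(est2$S_sites + est2$N_sites, 9, tolerance = 1e-9)
})
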