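# A tiny panel with one planted locus: conserved flanks (identical columns)
# around a scrambled core, on an otherwise moderately variable background.
planted_toy <- function(seed = 5) {
  withr::with_seed(seed, {
    L <- 120
    base <- sample(c("A", "C", "G", "T"), L, TRUE)
    n <- 6
    seqs <- vapply(seq_len(n), function(i) {
      s <- base
      # background: ~10% divergence everywhere outside the planted locus
      idx <- setdiff(seq_len(L), 31:90)
      flip <- idx[stats::runif(length(idx)) < 0.10]
      s[flip] <- vapply(s[flip], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      # core 51..70 (0-based [50,70)): heavily scrambled per record
      core_idx <- 51:70
      flip2 <- core_idx[stats::runif(20) < 0.6]
      s[flip2] <- vapply(s[flip2], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      # flanks 31..50 and 71..90 stay identical across records
      paste(s, collapse = "")
    }, "")
    reference_panel(sprintf("P%d", 1:n), rep("Genus", n),
                    sprintf("sp%d", 1:n), seqs)
  })
}

test_that("scan_windows agrees with the exhaustive window oracle", {
  p <- planted_toy()
  core_len <- c(18, 22); flank_len <- 10
  got <- scan_windows(p, core_len, flank_len,
                      min_flank_identity = 0.95, max_core_identity = 0.80)
  oracle <- exhaustive_scan(p, core_len, flank_len, 0.95, 0.80)
  expect_gt(length(got), 0)
  expect_false(is.null(oracle))
  # the top-ranked design is the oracle's top window
  expect_equal(got[[1]]$core$start, oracle$s[1])
  expect_equal(region_width(got[[1]]$core), oracle$cl[1])
  expect_equal(got[[1]]$core_identity, oracle$core_id[1])
  expect_equal(got[[1]]$flank_identity, oracle$flank_id[1])
  # every returned design appears in the oracle's accepted set
  for (d in got) {
    hit <- oracle$s == d$core$start & oracle$cl == region_width(d$core)
    expect_true(any(hit))
  }
  # no two returned designs share a core column
  if (length(got) > 1) {
    for (i in seq_along(got)[-1]) for (j in seq_len(i - 1)) {
      expect_true(got[[i]]$core$start >= got[[j]]$core$end ||
                  got[[j]]$core$start >= got[[i]]$core$end)
    }
  }
  # the planted core (columns [50,70)) is recovered
  expect_true(any(vapply(got, function(d)
    d$core$start < 70 && 50 < d$core$end, TRUE)))
})

test_that("identical panels give no design and thresholds act monotonically", {
  same <- reference_panel(c("a", "b", "c"), rep("G", 3), c("x", "y", "z"),
                          rep(strrep("ACGTG", 30), 3))
  expect_equal(length(scan_windows(same, c(20, 25), 10)), 0)

  p <- planted_toy()
  n_base <- length(scan_windows(p, c(18, 22), 10, 0.95, 0.80))
  # raising min_flank_identity never increases the count
  n_strict <- length(scan_windows(p, c(18, 22), 10, 0.999, 0.80))
  expect_lte(n_strict, n_base)
  # raising max_core_identity never decreases it
  n_loose <- length(scan_windows(p, c(18, 22), 10, 0.95, 0.99))
  expect_gte(n_loose, n_base)
  # max_designs truncates
  expect_lte(length(scan_windows(p, c(18, 22), 10, 0.9, 0.9, max_designs = 1)), 1)
  expect_error(scan_windows(p, c(200, 220), 10), "wider than")
})

test_that("reported design identities equal region_mean_identity recomputed independently", {
  p <- planted_toy()
  for (d in scan_windows(p, c(18, 22), 10, 0.9, 0.9)) {
    expect_equal(d$core_identity, region_mean_identity(p, d$core))
    expect_equal(d$flank_identity,
                 region_mean_identity(p, list(d$left_flank, d$right_flank)))
  }
})

test_that("planted cores are recovered on two-rate simulated panels (>= 90%)", {
  hits <- 0; total <- 0
  for (seed in 1:4) {
    sim <- simulate_panel(panel_sim_spec(n_genera = 4, species_per_genus = 3,
                                         n_individuals = 2, seed = seed))
    got <- scan_windows(sim$panel)
    for (truth in sim$truth$designs) {
      total <- total + 1
      recovered <- any(vapply(got, function(d) {
        d$core$start < truth$core$end && truth$core$start < d$core$end
      }, TRUE))
      if (recovered) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("design tables round-trip through TSV", {
  sim <- simulate_panel(panel_sim_spec(n_genera = 2, seed = 21))
  designs <- sim$truth$designs
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_designs(designs, tsv, panel = sim$panel)
  back <- read_designs(tsv)
  expect_equal(length(back), length(designs))
  expect_equal(back[[2]]$core$start, designs[[2]]$core$start)
  expect_equal(back[[2]]$core_identity, designs[[2]]$core_identity,
               tolerance = 1e-6)
  tab <- utils::read.delim(tsv)
  expect_true(all(c("primer_fwd", "primer_rev", "tm_fwd", "degeneracy_fwd")
                  %in% names(tab)))
})

test_that("consensus primers carry minimal covering IUPAC codes", {
  # column all A -> A; {A,G} -> R; all four -> N
  p <- reference_panel(sprintf("r%d", 1:4), rep("G", 4), sprintf("s%d", 1:4),
                       c("AAAA", "AGCA", "AGGC", "AATG"))
  # col1: all A -> A; col2: A,G,G,A -> R; col3: A,C,G,T -> N; col4: A,A,C,G -> V
  pr <- consensus_primer(p, region(0, 4), include_threshold = 0.95)
  expect_equal(pr$sequence, "ARNV")
  expect_equal(pr$degeneracy, 1 * 2 * 4 * 3)

  # brute-force check against hand-enumerated covering codes on a toy window
  p2 <- reference_panel(sprintf("q%d", 1:4), rep("G", 4), sprintf("s%d", 1:4),
                        c("ACGT", "ACGT", "ACTT", "CCGT"))
  pr2 <- consensus_primer(p2, region(0, 4))
  expect_equal(pr2$sequence, "MCKT")  # {A,C}=M, C, {G,T}=K, T
  # a frequency floor drops rare variants: with threshold 0.7 only bases at
  # >= 30% frequency are covered
  pr3 <- consensus_primer(p2, region(0, 4), include_threshold = 0.7)
  expect_equal(pr3$sequence, "ACGT")
})

test_that("reverse primers are reverse-complemented and Tm follows the Wallace rule", {
  p <- reference_panel(c("a", "b"), c("G", "G"), c("x", "y"),
                       c("ACGT", "ACGT"))
  fw <- consensus_primer(p, region(0, 4), orientation = "forward")
  rv <- consensus_primer(p, region(0, 4), orientation = "reverse")
  expect_equal(fw$sequence, "ACGT")
  expect_equal(rv$sequence, "ACGT")  # ACGT is its own reverse complement
  expect_equal(fw$melting_temp, 2 * 2 + 4 * 2)  # 2(A+T) + 4(G+C)
  # gappy columns are refused
  pg <- reference_panel(c("a", "b"), c("G", "G"), c("x", "y"),
                        c("A-GT", "A-GT"))
  expect_error(consensus_primer(pg, region(0, 4)), "gapped")
})
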