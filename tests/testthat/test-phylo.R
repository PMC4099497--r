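dm <- function(v, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- v
  m + t(m)
}

test_that("p-distance complements pairwise identity", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  # column-count oracle on a random pair
  a <- "ACGTTGCATGCA"; b <- "ACGATGCAAGCA"
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  expect_equal(p_distance(a, b), mean(ca != cb))
})

test_that("JC69 correction matches the closed form and flags saturation", {
  expect_equal(jc69_distance(0), 0)
  expect_equal(jc69_distance(0.1), 0.1073256, tolerance = 1e-6)
  expect_equal(jc69_distance(0.1), -0.75 * log(1 - 4 / 3 * 0.1))
  expect_error(jc69_distance(0.75), "saturation")
  expect_error(jc69_distance(0.9), "saturation")
  # correction always exceeds p on (0, 0.75)
  p <- seq(0.01, 0.74, by = 0.04)
  expect_true(all(jc69_distance(p) > p))
})

test_that("neighbor joining solves the 3-taxon system and stars zero matrices", {
  m <- dm(c(2, 3, 3), c("A", "B", "C"))
  tr <- nj_tree(m)
  pend <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(pend[["A"]], 1)
  expect_equal(pend[["B"]], 1)
  expect_equal(pend[["C"]], 2)

  z <- dm(rep(0, 6), c("A", "B", "C", "D"))
  tz <- nj_tree(z)
  expect_true(all(tz$edge.length == 0))

  expect_error(nj_tree(dm(1, c("A", "B"))), "at least 3")
  bad <- dm(c(2, 3, 3), c("A", "B", "C")); bad[1, 2] <- 9
  expect_error(nj_tree(bad), "symmetric")
})

test_that("neighbor joining is exact on additive matrices (4 and 5 taxa)", {
  # generating tree: ((A:1,B:2):1.5,(C:0.5,D:3):1);  internal edge 2.5
  gen <- ape::read.tree(text = "((A:1,B:2):1.5,(C:0.5,D:3):1);")
  m <- ape::cophenetic.phylo(gen)
  tr <- nj_tree(m[c("A", "B", "C", "D"), c("A", "B", "C", "D")])
  expect_equal(ape::cophenetic.phylo(tr)[rownames(m), colnames(m)], m,
               tolerance = 1e-9)
  expect_equal(phangorn::RF.dist(ape::unroot(gen), ape::unroot(tr)), 0)

  gen5 <- ape::read.tree(text = "(((A:0.4,B:0.7):0.6,C:1.1):0.8,(D:0.3,E:0.9):0.5);")
  m5 <- ape::cophenetic.phylo(gen5)
  tr5 <- nj_tree(m5)
  expect_equal(ape::cophenetic.phylo(tr5)[rownames(m5), colnames(m5)], m5,
               tolerance = 1e-9)
  expect_equal(phangorn::RF.dist(ape::unroot(gen5), ape::unroot(tr5)), 0)
  # cross-check topology against the reference NJ implementation
  ref <- ape::nj(m5)
  expect_equal(phangorn::RF.dist(ape::unroot(ref), ape::unroot(tr5)), 0)
})

test_that("negative NJ branch lengths are clamped to zero", {
  # 3-taxon system with a negative solution: lb = (1 + 3 - 5)/2 = -0.5
  m3 <- dm(c(1, 5, 3), c("A", "B", "C"))
  tr3 <- nj_tree(m3)
  pend <- stats::setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])],
                          tr3$tip.label)
  expect_equal(pend[["B"]], 0)
  expect_true(all(tr3$edge.length >= 0))
  # a larger non-additive matrix: no negative edge survives
  m5 <- dm(c(5, 9, 9, 9, 8, 8, 8, 8, 8, 2), c("A", "B", "C", "D", "E"))
  tr5 <- nj_tree(m5)
  expect_true(all(tr5$edge.length >= 0))
})

test_that("midpoint rooting halves the diameter and is idempotent", {
  t2 <- ape::read.tree(text = "(A:1,B:3);")
  r2 <- midpoint_root(t2)
  d2 <- ape::cophenetic.phylo(r2)
  expect_equal(unname(d2["A", "B"]), 4)
  expect_equal(r2$edge.length, c(2, 2))

  # caterpillar: longest path D..A = 0.5+0.2+0.3+2.5 = 3.5; midpoint on A's edge
  cat4 <- ape::read.tree(text = "(((A:2.5,B:0.1):0.3,C:0.4):0.2,D:0.5);")
  D <- ape::cophenetic.phylo(cat4)
  pair <- which(D == max(D), arr.ind = TRUE)[1, ]
  expect_setequal(rownames(D)[pair], c("A", "D"))
  root_depth <- function(tr, leaf) {
    root <- setdiff(tr$edge[, 1], tr$edge[, 2])
    unname(ape::dist.nodes(tr)[root, match(leaf, tr$tip.label)])
  }
  r4 <- midpoint_root(cat4)
  expect_equal(root_depth(r4, "A"), max(D) / 2)
  expect_equal(root_depth(r4, "D"), max(D) / 2)

  # idempotence up to representation: leaf-to-leaf distances and root depth
  r4b <- midpoint_root(r4)
  expect_equal(ape::cophenetic.phylo(r4b)[rownames(D), colnames(D)], D)
  expect_equal(root_depth(r4b, "A"), max(D) / 2)

  # agreement with the reference midpoint implementation
  ref <- phangorn::midpoint(cat4)
  expect_equal(root_depth(ref, "A"), max(D) / 2)

  expect_error(midpoint_root(ape::read.tree(text = "(A:0,B:0);")), "diameter")
})

test_that("bootstrap support is seed-reproducible and finds clean splits", {
  sim <- simulate_panel(panel_sim_spec(n_genera = 3, species_per_genus = 2,
                                       seed = 41))
  t1 <- bootstrap_support(sim$panel, n_reps = 25, seed = 7)
  t2 <- bootstrap_support(sim$panel, n_reps = 25, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  t0 <- bootstrap_support(sim$panel, n_reps = 0)
  expect_true(is.null(t0$node.label) || all(t0$node.label %in% c("", "Root")))

  # deep clean genus splits: every genus should be near-unanimously supported
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_gte(stats::median(sup, na.rm = TRUE), 95)

  # outgroup rooting places the outgroup next to the root
  og <- sim$panel$records$accession[1]
  tr <- bootstrap_support(sim$panel, outgroup = og, n_reps = 0)
  expect_true(ape::is.rooted(tr))
  expect_error(bootstrap_support(sim$panel, outgroup = "nope", n_reps = 0),
               "outgroup")
})

test_that("rank_references orders by identity with deterministic ties", {
  p <- toy_panel()
  q <- p$records$sequence[4]
  rk <- rank_references(q, p)
  expect_equal(rk$label[1], "X4")
  expect_equal(rk$identity[1], 1.0)
  # brute-force ordering oracle
  ids <- vapply(p$records$sequence, function(s) pairwise_identity(q, s), 0,
                USE.NAMES = FALSE)
  expect_equal(rk$identity, sort(ids, decreasing = TRUE))
  expect_error(rank_references("ACGT", p), "no panel region")
})

test_that("grouped distances enumerate within-species and congeneric pairs once", {
  p <- toy_panel()
  m <- panel_distance_matrix(p, correction = "raw")
  # raw sequence pairs: X1,X2 conspecific; (X1,X3),(X2,X3) congeneric
  # Columba; (X4,X5) congeneric Caloenas
  gp <- grouped_distances(m, panel_taxonomy(p), aggregate = "pair")
  expect_equal(length(gp$within_species), 1)
  expect_equal(length(gp$congeneric), 3)
  expect_equal(unname(gp$within_species), 0)
  expect_setequal(names(gp$congeneric), c("X1|X3", "X2|X3", "X4|X5"))
  expect_equal(unname(gp$congeneric[["X1|X3"]]),
               p_distance(p$records$sequence[1], p$records$sequence[3]))
  # species-level aggregation: one value per species (pair)
  gs <- grouped_distances(m, panel_taxonomy(p))
  expect_equal(length(gs$within_species), 1)
  expect_equal(length(gs$congeneric), 2)
  expect_equal(unname(gs$congeneric[["Columba livia|Columba oenas"]]),
               mean(gp$congeneric[c("X1|X3", "X2|X3")]))
  # single-species panel: congeneric empty
  p1 <- reference_panel(c("a", "b"), c("G", "G"), c("x", "x"), c("ACGT", "ACGA"))
  gd1 <- grouped_distances(panel_distance_matrix(p1, correction = "raw"),
                           panel_taxonomy(p1))
  expect_equal(length(gd1$congeneric), 0)
  expect_equal(length(gd1$within_species), 1)
})

test_that("one-sample t matches stats::t.test and its tail identities hold", {
  x <- c(0.012, 0.008, 0.011, 0.02, 0.004, 0.015)
  for (alt in c("less", "greater", "two_sided")) {
    mine <- one_sample_t(x, mu = 0.11, alternative = alt)
    ref <- stats::t.test(x, mu = 0.11, alternative = sub("_", ".", alt))
    expect_equal(mine$t, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value)
    # summary-statistic route agrees with the raw-sample route
    summ <- one_sample_t_summary(mean(x), stats::sd(x), length(x), 0.11, alt)
    expect_equal(summ$t, mine$t)
    expect_equal(summ$p, mine$p)
  }
  expect_equal(one_sample_t(x, mu = 0.11, "less")$p +
               one_sample_t(x, mu = 0.11, "greater")$p, 1)
  expect_equal(one_sample_t(x, mu = 0.11, "two_sided")$p,
               2 * min(one_sample_t(x, mu = 0.11, "less")$p,
                       one_sample_t(x, mu = 0.11, "greater")$p))
  # mean == mu gives t = 0 and one-sided p = 0.5
  sym <- c(0.10, 0.12)
  res <- one_sample_t(sym, mu = 0.11, "less")
  expect_equal(res$t, 0)
  expect_equal(res$p, 0.5)
  expect_error(one_sample_t(c(1, 1, 1), 0), "variance")
  expect_error(one_sample_t(1, 0), ">= 2")
})

test_that("summary-matched samples reproduce their summary statistics exactly", {
  x <- summary_matched_sample(14, 0.01, 0.0104)
  expect_equal(mean(x), 0.01)
  expect_equal(stats::sd(x), 0.0104)
  expect_equal(length(x), 14)
})

test_that("delimitation verdicts follow the two t-tests", {
  within <- summary_matched_sample(14, 0.01, 0.01)
  congen <- summary_matched_sample(15, 0.09, 0.05)
  # query at the within mean: conspecific not rejected
  res0 <- delimit_query(0.01, within, congen)
  expect_equal(res0$verdict, "conspecific_not_rejected")
  # query far above both: both reject -> indeterminate
  res2 <- delimit_query(0.8, within, congen)
  expect_equal(res2$verdict, "indeterminate")
  # query above within but inside congeneric spread: distinct species
  res1 <- delimit_query(0.10, within, congen)
  expect_equal(res1$within_test$p < 0.05, TRUE)
  expect_equal(res1$congeneric_test$p >= 0.05, TRUE)
  expect_equal(res1$verdict, "distinct_species_supported")
  # the verdict invariant: distinct iff within rejects and congeneric does not
  for (q in c(0.01, 0.05, 0.10, 0.2, 0.8)) {
    r <- delimit_query(q, within, congen)
    expect_equal(r$verdict == "distinct_species_supported",
                 r$within_test$p < r$alpha && r$congeneric_test$p >= r$alpha)
  }
})

test_that("whole-pipeline recovery: simulated queries identify and delimit correctly", {
  correct_rank <- 0; correct_verdict <- 0; n_sim <- 12
  for (i in seq_len(n_sim)) {
    sim <- simulate_panel(panel_sim_spec(n_genera = 3, species_per_genus = 3,
                                         seed = 500 + i))
    # moderate divergence: a heterospecific congener at the congeneric mean
    ex <- simulate_query_experiment(sim, profile = lognormal_profile(400, sdlog = 0.1),
                                    query_divergence = 0.09, seed = 600 + i)
    rk <- rank_references(ex$truth$query_sequence, sim$panel)
    # top hit is the attachment record or its conspecific sister
    tax <- panel_taxonomy(sim$panel)
    top_sp <- tax[match(rk$label[1], tax$label), c("genus", "species")]
    true_sp <- tax[match(ex$truth$attached_to, tax$label), c("genus", "species")]
    if (identical(unname(top_sp), unname(true_sp))) correct_rank <- correct_rank + 1

    m <- panel_distance_matrix(sim$panel)
    gd <- grouped_distances(m, tax)
    qd <- jc69_distance(p_distance(ex$truth$query_sequence,
                                   sim$panel$records$sequence[
                                     match(rk$label[1], sim$panel$records$accession)]))
    res <- delimit_query(qd, gd$within_species, gd$congeneric)
    if (res$verdict == "distinct_species_supported") {
      correct_verdict <- correct_verdict + 1
    }
  }
  expect_gte(correct_rank / n_sim, 0.9)
  expect_gte(correct_verdict / n_sim, 0.9)
})
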