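# Small fixtures built in code, shared across test files.

toy_panel <- function() {
  reference_panel(
    accession = c("X1", "X2", "X3", "X4", "X5"),
    genus = c("Columba", "Columba", "Columba", "Caloenas", "Caloenas"),
    species = c("livia", "livia", "oenas", "nicobarica", "maculata"),
    sequence = c("ACGTACGTACGTACGTACGT",
                 "ACGTACGTACGTACGTACGT",
                 "ACGTACGAACGTACGTACGT",
                 "ACGTTTTTACGAACGTACGT",
                 "ACGTTTTCACGAACGTACGA")
  )
}

# brute-force mean pairwise identity over full sequences: the independent
# double-loop oracle for region_mean_identity
brute_mean_identity <- function(panel, cols = NULL, gap_policy = "pairwise-delete") {
  seqs <- panel$records$sequence
  if (!is.null(cols)) {
    seqs <- vapply(seqs, function(s)
      paste(strsplit(s, "")[[1]][cols], collapse = ""), "", USE.NAMES = FALSE)
  }
  n <- length(seqs)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    vals <- c(vals, pairwise_identity(seqs[i], seqs[j], gap_policy))
  }
  mean(vals)
}

# random gap-free panel of unrelated sequences (for small property checks)
random_panel <- function(n = 6, len = 40, seed = 1) {
  withr::with_seed(seed, {
    seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), len, TRUE),
                               collapse = ""))
    reference_panel(sprintf("R%02d", seq_len(n)),
                    rep("Genus", n), sprintf("sp%02d", seq_len(n)), seqs)
  })
}

# exhaustive scan oracle: every (start, core length) window scored directly
# with region_mean_identity, filtered and sorted like scan_windows but with
# no shortcuts
exhaustive_scan <- function(panel, core_len, flank_len, min_flank_id, max_core_id) {
  L <- panel$alignment_length
  out <- list()
  for (cl in seq.int(core_len[1], core_len[2])) {
    for (s in seq.int(flank_len, L - cl - flank_len)) {
      core <- region(s, s + cl)
      flanks <- list(region(s - flank_len, s), region(s + cl, s + cl + flank_len))
      ci <- region_mean_identity(panel, core)
      fi <- region_mean_identity(panel, flanks)
      if (fi >= min_flank_id && ci <= max_core_id && ci < fi) {
        out[[length(out) + 1]] <- data.frame(s = s, cl = cl,
                                             core_id = ci, flank_id = fi)
      }
    }
  }
  if (length(out) == 0) return(NULL)
  tab <- do.call(rbind, out)
  tab[order(tab$core_id, -tab$flank_id, tab$s, tab$cl), ]
}
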