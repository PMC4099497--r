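#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of compared columns that differ: `1 - pairwise_identity`.
#'
#' @inheritParams pairwise_identity
#' @return fraction in `[0, 1]`.
#' @export
p_distance <- function(a, b,
                       gap_policy = c("pairwise-delete", "gap-as-mismatch"),
                       ambiguity = c("exact", "compatible")) {
  1 - pairwise_identity(a, b, gap_policy, ambiguity)
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) log(1 - (4/3) p)`, the expected substitutions per site given
#' an observed mismatch proportion `p` under the JC69 model. Saturates at
#' `p = 3/4`.
#'
#' @param p observed proportion(s) of differing sites, `0 <= p < 0.75`.
#' @return corrected distance(s) in substitutions/site.
#' @examples
#' jc69_distance(0.1)  # 0.10732
#' @export
jc69_distance <- function(p) {
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 0.75)) {
    stop("saturation: p >= 0.75 has no finite JC69 distance")
  }
  -0.75 * log(1 - (4 / 3) * p)
}

#' Pairwise distance matrix of a panel
#'
#' Symmetric matrix of JC69-corrected (default) or raw p-distances between
#' all records, labelled by accession. For column-resampled (bootstrap)
#' alignments an observed proportion can stray into JC69 saturation; set
#' `saturation = "cap"` to cap such entries at the distance of
#' `p = 0.7499` instead of erroring.
#'
#' @param panel a [reference_panel()] (or a character matrix of aligned
#'   sequences with rownames).
#' @param correction `"jc69"` or `"raw"`.
#' @param saturation `"error"` (default) or `"cap"`.
#' @inheritParams pairwise_identity
#' @return square numeric matrix with dimnames, class `matrix`.
#' @export
panel_distance_matrix <- function(panel, correction = c("jc69", "raw"),
                                  gap_policy = c("pairwise-delete", "gap-as-mismatch"),
                                  ambiguity = c("exact", "compatible"),
                                  saturation = c("error", "cap")) {
  correction <- match.arg(correction)
  gap_policy <- match.arg(gap_policy)
  ambiguity <- match.arg(ambiguity)
  saturation <- match.arg(saturation)
  mat <- if (inherits(panel, "reference_panel")) seq_matrix(panel) else panel
  n <- nrow(mat)
  if (n < 2L) stop("need at least 2 records")
  labels <- rownames(mat)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      cmp <- compare_columns(mat[i, ], mat[j, ], gap_policy, ambiguity)
      if (cmp$n_compared == 0L) {
        stop("records ", labels[i], " and ", labels[j],
             " share no comparable columns")
      }
      p <- 1 - cmp$n_match / cmp$n_compared
      if (correction == "jc69") {
        if (p >= 0.75) {
          if (saturation == "error") {
            stop("saturation: p = ", signif(p, 4), " between ",
                 labels[i], " and ", labels[j])
          }
          p <- 0.7499
        }
        p <- jc69_distance(p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with two determinism guarantees: ties
#' in the Q criterion are broken by the lexicographically smallest (sorted)
#' label pair, and a negative pendant branch length is clamped to zero with
#' the deficit transferred to its sibling edge (their sum is preserved).
#' Exact on additive matrices.
#'
#' @param m symmetric numeric matrix with zero diagonal and dimnames
#'   (>= 3 labels), e.g. from [panel_distance_matrix()].
#' @return an [ape::phylo] tree (unrooted).
#' @examples
#' m <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' nj_tree(m)
#' @export
nj_tree <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("m must be a square matrix")
  if (is.null(rownames(m))) stop("m must have labels as dimnames")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("non-symmetric distance matrix")
  }
  if (any(!is.finite(m))) stop("non-finite distances")
  n0 <- nrow(m)
  if (n0 < 3L) stop("neighbor joining needs at least 3 labels")

  labels <- rownames(m)      # tie-break key per active node
  frags <- labels            # newick fragment per active node
  d <- m
  clamp_pair <- function(li, lj, dij) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(0, li), max(0, lj))
  }
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cands <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cands <- cands[cands[, 1] < cands[, 2], , drop = FALSE]
    keys <- apply(cands, 1L, function(ij) {
      paste(sort(c(labels[ij[1]], labels[ij[2]])), collapse = "\r")
    })
    pick <- cands[order(keys)[1L], ]
    i <- pick[[1]]; j <- pick[[2]]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    ll <- clamp_pair(li, lj, d[i, j])
    # children ordered by label for a deterministic representation
    ord <- order(c(labels[i], labels[j]))
    ch_frag <- c(frags[i], frags[j])[ord]
    ch_len <- ll[ord]
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", ch_frag[1], ch_len[1],
                        ch_frag[2], ch_len[2])
    new_label <- min(labels[i], labels[j])
    du <- (d[i, -c(i, j)] + d[j, -c(i, j)] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- d[keep, keep, drop = FALSE]
    d <- rbind(cbind(d, du), c(du, 0))
    labels <- c(labels[keep], new_label)
    frags <- c(frags[keep], new_frag)
    rownames(d) <- colnames(d) <- labels
  }
  # final three-point solve
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  lens <- pmax(0, c(la, lb, lc))
  ord <- order(labels)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frags[ord[1]], lens[ord[1]],
                 frags[ord[2]], lens[ord[2]],
                 frags[ord[3]], lens[ord[3]])
  ape::read.tree(text = nwk)
}

#' Midpoint-root a tree
#'
#' Places the root halfway along the longest leaf-to-leaf path; ties on the
#' diameter are broken by the lexicographically smallest (sorted) leaf
#' pair. Idempotent up to representation.
#'
#' @param t an [ape::phylo] tree with >= 2 leaves and positive diameter.
#' @return a rooted [ape::phylo] tree.
#' @export
midpoint_root <- function(t) {
  stopifnot(inherits(t, "phylo"))
  nt <- length(t$tip.label)
  if (nt < 2L) stop("midpoint rooting needs at least 2 leaves")
  D <- ape::cophenetic.phylo(t)
  diam <- max(D)
  if (diam <= 0) stop("zero diameter: all leaf-to-leaf distances are 0")
  idx <- which(D >= diam - 1e-12, arr.ind = TRUE)
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  keys <- apply(idx, 1L, function(ij) {
    paste(sort(rownames(D)[c(ij[1], ij[2])]), collapse = "\r")
  })
  pick <- idx[order(keys)[1L], ]
  a <- rownames(D)[pick[[1]]]; b <- rownames(D)[pick[[2]]]
  half <- D[a, b] / 2

  if (nt == 2L) {
    return(ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                         min(a, b), half, max(a, b), half)))
  }
  ta <- match(a, t$tip.label); tb <- match(b, t$tip.label)
  path <- ape::nodepath(t, ta, tb)
  el <- numeric(length(path) - 1L)
  for (k in seq_along(el)) {
    e <- which((t$edge[, 1] == path[k] & t$edge[, 2] == path[k + 1L]) |
               (t$edge[, 1] == path[k + 1L] & t$edge[, 2] == path[k]))
    el[k] <- t$edge.length[e]
  }
  cd <- c(0, cumsum(el))  # distance from leaf a at each path node
  k <- which(cd >= half - 1e-12)[1L]  # first node at or past the midpoint
  if (k == 1L) k <- 2L
  # midpoint lies on the path edge between path[k-1] and path[k]
  u <- path[k - 1L]; v <- path[k]
  e <- which((t$edge[, 1] == u & t$edge[, 2] == v) |
             (t$edge[, 1] == v & t$edge[, 2] == u))
  child <- t$edge[e, 2]
  cd_child <- cd[if (child == u) k - 1L else k]
  from_child <- abs(half - cd_child)
  elen <- t$edge.length[e]
  from_child <- min(max(from_child, 0), elen)
  # phytools::reroot measures position from the parent end of the edge
  rooted <- phytools::reroot(t, node.number = child,
                             position = elen - from_child)
  rooted
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the NJ tree of the panel from JC69 distances, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds the tree,
#' and annotates each internal edge of the original tree with the
#' percentage of replicates containing the same bipartition. Rooted on the
#' given outgroup when supplied, else midpoint-rooted.
#'
#' @param panel a [reference_panel()] with >= 3 records.
#' @param outgroup accession label to root on, or `NULL` for midpoint.
#' @param n_reps bootstrap replicates (default 1000; 0 skips support).
#' @param seed optional integer seed (fixed seed => identical supports).
#' @inheritParams pairwise_identity
#' @return a rooted [ape::phylo]; support percentages in `node.label`
#'   (empty when `n_reps = 0`).
#' @export
bootstrap_support <- function(panel, outgroup = NULL, n_reps = 1000L,
                              seed = NULL,
                              gap_policy = c("pairwise-delete", "gap-as-mismatch")) {
  gap_policy <- match.arg(gap_policy)
  if (n_records(panel) < 3L) stop("need at least 3 records")
  mat <- seq_matrix(panel)
  if (!is.null(outgroup) && !(outgroup %in% rownames(mat))) {
    stop("outgroup label '", outgroup, "' not in panel")
  }
  base_tree <- nj_tree(panel_distance_matrix(mat, "jc69", gap_policy,
                                             saturation = "cap"))
  root_it <- function(tr) {
    if (is.null(outgroup)) midpoint_root(tr)
    else ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  if (n_reps == 0L) return(root_it(base_tree))

  L <- ncol(mat)
  build_reps <- function() {
    lapply(seq_len(n_reps), function(i) {
      cols <- sample.int(L, L, replace = TRUE)
      bm <- mat[, cols, drop = FALSE]
      nj_tree(panel_distance_matrix(bm, "jc69", gap_policy, saturation = "cap"))
    })
  }
  reps <- if (is.null(seed)) build_reps() else withr::with_seed(seed, build_reps())
  counts <- ape::prop.clades(base_tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  base_tree$node.label <- as.character(round(100 * counts / n_reps, 1))
  out <- root_it(base_tree)
  out
}

#' Rank panel records by identity to a query
#'
#' The query must be in panel alignment coordinates (same column count);
#' records are ranked by descending [pairwise_identity()], ties broken
#' alphabetically by label.
#'
#' @param query aligned query sequence (character scalar).
#' @param panel a [reference_panel()].
#' @inheritParams pairwise_identity
#' @return data frame `label`, `genus`, `species`, `identity`, best first.
#' @export
rank_references <- function(query, panel,
                            gap_policy = c("pairwise-delete", "gap-as-mismatch"),
                            ambiguity = c("exact", "compatible")) {
  gap_policy <- match.arg(gap_policy)
  ambiguity <- match.arg(ambiguity)
  if (nchar(query) != panel$alignment_length) {
    stop("query aligns to no panel region: expected ",
         panel$alignment_length, " aligned columns, got ", nchar(query))
  }
  r <- panel$records
  ident <- vapply(r$sequence, function(s)
    pairwise_identity(query, s, gap_policy, ambiguity), 0, USE.NAMES = FALSE)
  out <- data.frame(label = r$accession, genus = r$genus, species = r$species,
                    identity = ident, stringsAsFactors = FALSE)
  out <- out[order(-out$identity, out$label), ]
  rownames(out) <- NULL
  out
}

#' Patristic distances of a tree
#'
#' Sum of branch lengths along the leaf-to-leaf path, the distance scale on
#' which tree-based species comparisons are made.
#'
#' @param t an [ape::phylo] tree.
#' @return symmetric matrix of patristic distances (substitutions/site).
#' @export
patristic_distances <- function(t) {
  stopifnot(inherits(t, "phylo"))
  ape::cophenetic.phylo(t)
}

#' Split pairwise distances into within-species and congeneric samples
#'
#' Every unordered label pair is classified by taxonomy: same genus and
#' species -> `within_species`; same genus, different species ->
#' `congeneric`. Unknown-taxon labels are skipped; each pair is counted
#' once. With the default `aggregate = "species"` the sequence-level pairs
#' are averaged to one value per species (within) and one per unordered
#' species pair (congeneric) — the sampling unit on which
#' species-delimitation t-tests are legitimate, since sequence-level pairs
#' of the same species pair are not independent. `aggregate = "pair"`
#' returns the raw sequence pairs.
#'
#' @param m symmetric labelled distance matrix ([panel_distance_matrix()]
#'   or [patristic_distances()]).
#' @param taxonomy data frame with columns `label`, `genus`, `species`
#'   (and optionally `unknown_taxon`), e.g. [panel_taxonomy()]; every
#'   matrix label must appear.
#' @param aggregate `"species"` (default) or `"pair"`.
#' @return list with numeric vectors `within_species` and `congeneric`
#'   (named by species or label pair), either possibly empty.
#' @export
grouped_distances <- function(m, taxonomy, aggregate = c("species", "pair")) {
  aggregate <- match.arg(aggregate)
  labels <- rownames(m)
  if (is.null(labels)) stop("distance matrix must be labelled")
  miss <- setdiff(labels, taxonomy$label)
  if (length(miss)) {
    stop("no taxonomy for label(s): ", paste(miss, collapse = ", "))
  }
  tax <- taxonomy[match(labels, taxonomy$label), ]
  unknown <- if ("unknown_taxon" %in% names(tax)) tax$unknown_taxon
             else tax$species == ""
  within <- numeric(0); congen <- numeric(0)
  w_key <- character(0); c_key <- character(0)
  n <- length(labels)
  for (i in seq_len(max(0, n - 1L))) {
    for (j in seq.int(i + 1L, n)) {
      if (unknown[i] || unknown[j]) next
      if (tax$genus[i] != tax$genus[j]) next
      if (tax$species[i] == tax$species[j]) {
        within <- c(within, m[i, j])
        w_key <- c(w_key,
                   if (aggregate == "species")
                     paste(tax$genus[i], tax$species[i])
                   else paste(labels[i], labels[j], sep = "|"))
      } else {
        congen <- c(congen, m[i, j])
        sp <- sort(paste(tax$genus[c(i, j)], tax$species[c(i, j)]))
        c_key <- c(c_key,
                   if (aggregate == "species") paste(sp, collapse = "|")
                   else paste(labels[i], labels[j], sep = "|"))
      }
    }
  }
  if (aggregate == "species") {
    within <- if (length(within)) tapply(within, w_key, mean) else within
    congen <- if (length(congen)) tapply(congen, c_key, mean) else congen
    within <- stats::setNames(as.numeric(within), names(within))
    congen <- stats::setNames(as.numeric(congen), names(congen))
  } else {
    names(within) <- w_key
    names(congen) <- c_key
  }
  list(within_species = within, congeneric = congen)
}

#' One-sample Student t-test
#'
#' Tests the sample mean against `mu`; `t = (xbar - mu) / (s / sqrt(n))`
#' with `n - 1` degrees of freedom. Implemented via [stats::t.test()].
#'
#' @param sample numeric vector, `n >= 2`, non-zero variance.
#' @param mu test value (same units as the sample).
#' @param alternative `"less"`, `"greater"`, or `"two_sided"`.
#' @return an object of class `t_result`: `mean`, `sd`, `n`, `mu`, `t`,
#'   `df`, `p`, `alternative`.
#' @examples
#' one_sample_t(c(0.01, 0.02, 0.005), mu = 0.11, alternative = "less")
#' @export
one_sample_t <- function(sample, mu,
                         alternative = c("less", "greater", "two_sided")) {
  alternative <- match.arg(alternative)
  sample <- as.numeric(sample)
  if (length(sample) < 2L) stop("need a sample of size >= 2")
  if (stats::sd(sample) == 0) stop("zero variance: t statistic undefined")
  ht <- stats::t.test(sample, mu = mu,
                      alternative = sub("_", ".", alternative))
  structure(list(mean = mean(sample), sd = stats::sd(sample),
                 n = length(sample), mu = mu,
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, alternative = alternative),
            class = "t_result")
}

#' One-sample t-test from summary statistics
#'
#' Same test as [one_sample_t()], computed from printed summary statistics
#' (`mean`, `sd`, `n`) rather than a raw sample.
#'
#' @param mean,sd,n sample summary statistics (`sd > 0`, `n >= 2`).
#' @inheritParams one_sample_t
#' @return a `t_result`.
#' @examples
#' one_sample_t_summary(0.01, 0.01, 14, mu = 0.11, alternative = "less")
#' @export
one_sample_t_summary <- function(mean, sd, n, mu,
                                 alternative = c("less", "greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (n < 2L) stop("need n >= 2")
  if (sd <= 0) stop("zero variance: t statistic undefined")
  t <- (mean - mu) / (sd / sqrt(n))
  structure(list(mean = mean, sd = sd, n = n, mu = mu,
                 t = t, df = n - 1L,
                 p = t_tail_p(t, n - 1L, alternative),
                 alternative = alternative),
            class = "t_result")
}

#' Tail probability of a Student t statistic
#'
#' @param t observed t statistic.
#' @param df degrees of freedom.
#' @inheritParams one_sample_t
#' @return p-value under the given alternative.
#' @examples
#' t_tail_p(-1.48, 14)  # ~0.08
#' @export
t_tail_p <- function(t, df, alternative = c("less", "greater", "two_sided")) {
  alternative <- match.arg(alternative)
  switch(alternative,
         less = stats::pt(t, df),
         greater = stats::pt(t, df, lower.tail = FALSE),
         two_sided = 2 * stats::pt(-abs(t), df))
}

#' @export
print.t_result <- function(x, ...) {
  cat(sprintf("one-sample t (%s): t(%d) = %.3f, p = %.3g  [mean %.4g, sd %.4g, n %d, mu %.4g]\n",
              x$alternative, x$df, x$t, x$p, x$mean, x$sd, x$n, x$mu))
  invisible(x)
}

#' Deterministic sample matching given summary statistics
#'
#' Builds a sample of size `n` with exactly the requested mean and standard
#' deviation by rescaling standard-normal quantiles — used to reconstruct
#' distance samples from printed summary statistics.
#'
#' @param n sample size (>= 2).
#' @param mean,sd target summary statistics (`sd > 0`).
#' @return numeric vector of length `n` with `mean(x) == mean`,
#'   `sd(x) == sd` (to machine precision).
#' @export
summary_matched_sample <- function(n, mean, sd) {
  stopifnot(n >= 2L, sd > 0)
  z <- stats::qnorm(stats::ppoints(n))
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

#' Test the species status of a query specimen
#'
#' Compares the query's distance to its nearest relative against the
#' distribution of within-species distances (is the query *more* divergent
#' than conspecific pairs are?) and against congeneric distances (is it
#' indistinguishable from a heterospecific congener?). Both are one-sided
#' (`less`) one-sample t-tests of the reference sample mean against the
#' query distance. Verdicts at level `alpha`:
#' `distinct_species_supported` when the within-species test rejects and
#' the congeneric test does not; `conspecific_not_rejected` when the
#' within-species test does not reject; `indeterminate` otherwise (both
#' reject: more divergent even than congeners, genus-level signal only).
#'
#' @param query_distance observed query-to-nearest-relative distance,
#'   substitutions/site.
#' @param within,congeneric numeric distance samples (each `n >= 2`), e.g.
#'   from [grouped_distances()].
#' @param alpha significance level (default 0.05).
#' @return an object of class `delimitation_result`: `query_distance`,
#'   `within_test`, `congeneric_test` (both `t_result`), `alpha`,
#'   `verdict`.
#' @examples
#' delimit_query(0.11,
#'               within = summary_matched_sample(14, 0.01, 0.0104),
#'               congeneric = summary_matched_sample(15, 0.0947, 0.04))
#' @export
delimit_query <- function(query_distance, within, congeneric, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  wt <- one_sample_t(within, mu = query_distance, alternative = "less")
  ct <- one_sample_t(congeneric, mu = query_distance, alternative = "less")
  verdict <- if (wt$p >= alpha) {
    "conspecific_not_rejected"
  } else if (ct$p >= alpha) {
    "distinct_species_supported"
  } else {
    "indeterminate"
  }
  structure(list(query_distance = query_distance,
                 within_test = wt, congeneric_test = ct,
                 alpha = alpha, verdict = verdict),
            class = "delimitation_result")
}

#' @export
print.delimitation_result <- function(x, ...) {
  cat(sprintf("delimitation at alpha = %.3g: %s\n", x$alpha, x$verdict))
  cat(sprintf("  query distance: %.4g subs/site\n", x$query_distance))
  cat("  vs within-species: "); print(x$within_test)
  cat("  vs congeneric:     "); print(x$congeneric_test)
  invisible(x)
}
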