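#' Pairwise identity between two aligned sequences
#'
#' Fraction of compared alignment columns at which the two sequences carry
#' the same symbol. Columns gapped in both sequences are never compared.
#' Under `gap_policy = "pairwise-delete"` (default) columns gapped in either
#' sequence are excluded from the denominator; under `"gap-as-mismatch"` a
#' gap opposite a base counts as a mismatch. Ambiguity codes compare by
#' exact symbol equality by default (`R != A`); `ambiguity = "compatible"`
#' counts symbols whose IUPAC base sets overlap as matches.
#'
#' @param a,b aligned sequences (character scalars of equal length).
#' @param gap_policy `"pairwise-delete"` or `"gap-as-mismatch"`.
#' @param ambiguity `"exact"` or `"compatible"`.
#' @return a fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("ACGT", "ACGA")            # 0.75
#' pairwise_identity("AC-T", "ACGT")            # 1 (gap column deleted)
#' pairwise_identity("AC-T", "ACGT", "gap-as-mismatch")  # 0.75
#' @export
pairwise_identity <- function(a, b,
                              gap_policy = c("pairwise-delete", "gap-as-mismatch"),
                              ambiguity = c("exact", "compatible")) {
  gap_policy <- match.arg(gap_policy)
  ambiguity <- match.arg(ambiguity)
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) {
    stop("sequences have unequal lengths (", nchar(a), " vs ", nchar(b), ")")
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  cmp <- compare_columns(ca, cb, gap_policy, ambiguity)
  if (cmp$n_compared == 0L) {
    stop("undefined identity: zero comparable columns")
  }
  cmp$n_match / cmp$n_compared
}

# column comparison shared by pairwise_identity and the pair-profile
# machinery; returns match/compared counts.
compare_columns <- function(ca, cb, gap_policy, ambiguity) {
  gap_a <- ca %in% GAP_CHARS
  gap_b <- cb %in% GAP_CHARS
  both_gap <- gap_a & gap_b
  either_gap <- gap_a | gap_b
  if (gap_policy == "pairwise-delete") {
    compared <- !either_gap
  } else {
    compared <- !both_gap
  }
  if (ambiguity == "exact") {
    eq <- ca == cb
  } else {
    eq <- ca == cb
    amb <- compared & !eq & !either_gap
    if (any(amb)) {
      eq[amb] <- mapply(iupac_compatible, ca[amb], cb[amb])
    }
  }
  match <- compared & !either_gap & eq
  list(n_match = sum(match), n_compared = sum(compared),
       match = match, compared = compared)
}

# Per-pair cumulative match/compared profiles over alignment columns.
# Returns P x (L+1) cumulative-sum matrices so that counts over the half-open
# column window [s, e) are cum[, e+1] - cum[, s+1]; plus the pair index.
pair_profiles <- function(mat, gap_policy, ambiguity) {
  n <- nrow(mat); L <- ncol(mat)
  if (n < 2L) stop("need at least 2 records")
  pairs <- utils::combn(n, 2L)
  P <- ncol(pairs)
  cum_match <- matrix(0, P, L + 1L)
  cum_comp <- matrix(0, P, L + 1L)
  for (p in seq_len(P)) {
    cmp <- compare_columns(mat[pairs[1L, p], ], mat[pairs[2L, p], ],
                           gap_policy, ambiguity)
    cum_match[p, ] <- c(0, cumsum(cmp$match))
    cum_comp[p, ] <- c(0, cumsum(cmp$compared))
  }
  list(cum_match = cum_match, cum_comp = cum_comp, pairs = pairs)
}

# mean pairwise identity over a set of (possibly pooled) column windows,
# given profiles; windows is a 2-column matrix of half-open [s, e) bounds
# (0-based); counts are pooled across windows within a pair.
profile_mean_identity <- function(prof, windows) {
  m <- 0; cpd <- 0
  for (w in seq_len(nrow(windows))) {
    s <- windows[w, 1L]; e <- windows[w, 2L]
    m <- m + (prof$cum_match[, e + 1L] - prof$cum_match[, s + 1L])
    cpd <- cpd + (prof$cum_comp[, e + 1L] - prof$cum_comp[, s + 1L])
  }
  ok <- cpd > 0
  if (!any(ok)) {
    stop("undefined identity: no record pair has comparable columns in region")
  }
  mean(m[ok] / cpd[ok])
}

#' Mean pairwise identity of a panel over a region
#'
#' Arithmetic mean of [pairwise_identity()] over all unordered record pairs,
#' restricted to the given region (or pooled over a list of regions, as used
#' for the two flanks of a barcode design). Pairs with no comparable column
#' in the region are excluded from the mean.
#'
#' @param panel a [reference_panel()] with at least 2 records.
#' @param region a [region()] or list of regions (counts pooled per pair).
#' @inheritParams pairwise_identity
#' @return a fraction in `[0, 1]`.
#' @examples
#' p <- reference_panel(c("a", "b", "c"), rep("G", 3), c("x", "y", "z"),
#'                      c("ACGTACGT", "ACGTACGA", "ACGAACGA"))
#' region_mean_identity(p, region(0, 8))
#' @export
region_mean_identity <- function(panel, region,
                                 gap_policy = c("pairwise-delete", "gap-as-mismatch"),
                                 ambiguity = c("exact", "compatible")) {
  gap_policy <- match.arg(gap_policy)
  ambiguity <- match.arg(ambiguity)
  if (n_records(panel) < 2L) {
    stop("region_mean_identity needs a panel with at least 2 records")
  }
  rs <- if (inherits(region, "region")) list(region) else region
  for (r in rs) {
    if (!inherits(r, "region")) stop("'region' must be a region or list of regions")
    if (r$end > panel$alignment_length) {
      stop("region [", r$start, ", ", r$end, ") exceeds alignment length ",
           panel$alignment_length)
    }
  }
  mat <- seq_matrix(panel)
  prof <- pair_profiles(mat, gap_policy, ambiguity)
  windows <- do.call(rbind, lapply(rs, function(r) c(r$start, r$end)))
  profile_mean_identity(prof, windows)
}
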