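#' Mini-barcode designs
#'
#' A `barcode_design` is a hypervariable core region flanked on both sides by
#' conserved primer-site regions, all contiguous in alignment-column space:
#' `left_flank`, `core`, `right_flank` with `left_flank$end == core$start`
#' and `core$end == right_flank$start`. A design is only valid when the core
#' is more variable than its flanks (`core_identity < flank_identity`).
#'
#' @param left_flank,core,right_flank contiguous [region()]s.
#' @param core_identity,flank_identity mean pairwise identities of the core
#'   and of the pooled flanks (see [region_mean_identity()]).
#' @param name design name.
#' @return An object of class `barcode_design`.
#' @export
barcode_design <- function(left_flank, core, right_flank,
                           core_identity, flank_identity, name = "mb") {
  stopifnot(inherits(left_flank, "region"), inherits(core, "region"),
            inherits(right_flank, "region"))
  if (left_flank$end != core$start || core$end != right_flank$start) {
    stop("design regions must be contiguous: left_flank | core | right_flank")
  }
  if (!(core_identity < flank_identity)) {
    stop("invalid design: core_identity (", signif(core_identity, 4),
         ") must be below flank_identity (", signif(flank_identity, 4), ")")
  }
  structure(list(name = name, left_flank = left_flank, core = core,
                 right_flank = right_flank,
                 core_identity = core_identity,
                 flank_identity = flank_identity),
            class = "barcode_design")
}

#' @export
print.barcode_design <- function(x, ...) {
  cat(sprintf("barcode_design '%s': flank[%d,%d) core[%d,%d) flank[%d,%d)  core id %.3f, flank id %.3f\n",
              x$name, x$left_flank$start, x$left_flank$end,
              x$core$start, x$core$end,
              x$right_flank$start, x$right_flank$end,
              x$core_identity, x$flank_identity))
  invisible(x)
}

#' @export
as.data.frame.barcode_design <- function(x, ...) {
  data.frame(name = x$name,
             left_start = x$left_flank$start, left_end = x$left_flank$end,
             core_start = x$core$start, core_end = x$core$end,
             right_start = x$right_flank$start, right_end = x$right_flank$end,
             core_identity = x$core_identity,
             flank_identity = x$flank_identity,
             stringsAsFactors = FALSE)
}

designs_to_table <- function(designs) {
  do.call(rbind, lapply(designs, as.data.frame))
}

#' Scan an aligned panel for mini-barcode candidates
#'
#' Slides windows of every core length in `core_len` across the alignment,
#' flanked by `flank_len` columns on each side, and keeps windows whose
#' pooled flank identity is at least `min_flank_identity` and whose core
#' identity is at most `max_core_identity`. Candidates are sorted by
#' ascending core identity, then descending flank identity, and pruned
#' greedily so that no two returned designs share any core column. Windows
#' whose core contains a gap-majority column are skipped (such cores are not
#' contiguous in real molecules).
#'
#' @param panel a [reference_panel()] with at least 2 records.
#' @param core_len integer vector of length 2: minimum and maximum core
#'   length in alignment columns (default 50--80).
#' @param flank_len flank (primer site) length in columns (default 20).
#' @param min_flank_identity minimum mean pairwise identity of the pooled
#'   flanks (default 0.95).
#' @param max_core_identity maximum mean pairwise identity of the core
#'   (default 0.80).
#' @param max_designs return at most this many designs (default unlimited).
#' @inheritParams pairwise_identity
#' @return list of [barcode_design()] objects (possibly empty), named
#'   `"mb1"`, `"mb2"`, ... in score order.
#' @examples
#' # a panel of identical sequences yields no design
#' p <- reference_panel(c("a","b"), c("G","G"), c("x","y"),
#'                      rep(strrep("ACGT", 40), 2))
#' length(scan_windows(p, core_len = c(10, 12), flank_len = 5))
#' @export
scan_windows <- function(panel, core_len = c(50L, 80L), flank_len = 20L,
                         min_flank_identity = 0.95, max_core_identity = 0.80,
                         max_designs = Inf,
                         gap_policy = c("pairwise-delete", "gap-as-mismatch"),
                         ambiguity = c("exact", "compatible")) {
  gap_policy <- match.arg(gap_policy)
  ambiguity <- match.arg(ambiguity)
  if (n_records(panel) < 2L) stop("scan_windows needs at least 2 records")
  stopifnot(min_flank_identity > 0, min_flank_identity <= 1,
            max_core_identity > 0, max_core_identity <= 1)
  core_len <- as.integer(core_len)
  if (length(core_len) == 1L) core_len <- c(core_len, core_len)
  flank_len <- as.integer(flank_len)
  L <- panel$alignment_length
  if (min(core_len) + 2L * flank_len > L) {
    stop("core_len + flanks wider than the alignment (", L, " columns)")
  }

  mat <- seq_matrix(panel)
  prof <- pair_profiles(mat, gap_policy, ambiguity)
  gap_frac <- colMeans(matrix(mat %in% GAP_CHARS, nrow(mat), L))
  gap_majority <- gap_frac > 0.5
  cum_gapmaj <- c(0, cumsum(gap_majority))

  cand <- list()
  for (cl in seq.int(core_len[1], min(core_len[2], L - 2L * flank_len))) {
    starts <- seq.int(flank_len, L - cl - flank_len)  # 0-based core starts
    if (length(starts) == 0L) next
    # skip cores containing gap-majority columns
    ok <- (cum_gapmaj[starts + cl + 1L] - cum_gapmaj[starts + 1L]) == 0
    for (s in starts[ok]) {
      core_m <- prof$cum_match[, s + cl + 1L] - prof$cum_match[, s + 1L]
      core_c <- prof$cum_comp[, s + cl + 1L] - prof$cum_comp[, s + 1L]
      fl_m <- (prof$cum_match[, s + 1L] - prof$cum_match[, s - flank_len + 1L]) +
              (prof$cum_match[, s + cl + flank_len + 1L] - prof$cum_match[, s + cl + 1L])
      fl_c <- (prof$cum_comp[, s + 1L] - prof$cum_comp[, s - flank_len + 1L]) +
              (prof$cum_comp[, s + cl + flank_len + 1L] - prof$cum_comp[, s + cl + 1L])
      if (!any(core_c > 0) || !any(fl_c > 0)) next
      core_id <- mean(core_m[core_c > 0] / core_c[core_c > 0])
      flank_id <- mean(fl_m[fl_c > 0] / fl_c[fl_c > 0])
      if (flank_id >= min_flank_identity && core_id <= max_core_identity &&
          core_id < flank_id) {
        cand[[length(cand) + 1L]] <- list(s = s, cl = cl,
                                          core_id = core_id, flank_id = flank_id)
      }
    }
  }
  if (length(cand) == 0L) return(list())

  core_ids <- vapply(cand, `[[`, 0, "core_id")
  flank_ids <- vapply(cand, `[[`, 0, "flank_id")
  ord <- order(core_ids, -flank_ids,
               vapply(cand, `[[`, 0L, "s"), vapply(cand, `[[`, 0L, "cl"))
  cand <- cand[ord]

  # greedy non-overlap pruning on core columns
  kept <- list()
  for (cd in cand) {
    if (length(kept) >= max_designs) break
    overlaps <- any(vapply(kept, function(k) {
      cd$s < k$s + k$cl && k$s < cd$s + cd$cl
    }, TRUE))
    if (!overlaps) kept[[length(kept) + 1L]] <- cd
  }

  designs <- lapply(seq_along(kept), function(i) {
    k <- kept[[i]]
    barcode_design(
      left_flank = region(k$s - flank_len, k$s),
      core = region(k$s, k$s + k$cl),
      right_flank = region(k$s + k$cl, k$s + k$cl + flank_len),
      core_identity = k$core_id, flank_identity = k$flank_id,
      name = paste0("mb", i)
    )
  })
  names(designs) <- vapply(designs, `[[`, "", "name")
  designs
}

#' Build a degenerate consensus primer over a panel region
#'
#' For every column of the region, the primer carries the smallest IUPAC
#' code covering all bases whose frequency among (non-gap) panel records is
#' at least `1 - include_threshold`; rarer variants are deliberately ignored
#' so that the occasional private polymorphism does not inflate degeneracy.
#' Ambiguity codes in records contribute all their constituent bases.
#' Reverse-orientation primers are returned reverse-complemented relative to
#' panel orientation. The melting temperature is the Wallace rule
#' `2(A+T) + 4(G+C)` evaluated on the modal-base expansion of the primer.
#'
#' @param panel a [reference_panel()].
#' @param region a [region()] covering the primer site; errors when any
#'   column is gapped in more than `1 - include_threshold` of records.
#' @param include_threshold coverage control in (0, 1]; default 0.95 (bases
#'   below 5% panel frequency are dropped).
#' @param orientation `"forward"` or `"reverse"`.
#' @return An object of class `degenerate_primer` with fields `sequence`,
#'   `degeneracy`, `melting_temp`, `orientation`, `region`.
#' @examples
#' p <- reference_panel(c("a","b","c","d"), rep("G",4), letters[1:4],
#'                      c("ACGT","ACGT","AGGT","ACGT"))
#' consensus_primer(p, region(0, 4))
#' @export
consensus_primer <- function(panel, region, include_threshold = 0.95,
                             orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(region, "region"), include_threshold > 0,
            include_threshold <= 1)
  if (region$end > panel$alignment_length) {
    stop("region exceeds alignment length")
  }
  mat <- seq_matrix(panel)
  cols <- region_columns(region, panel$alignment_length)
  n <- nrow(mat)
  min_freq <- 1 - include_threshold
  max_gap <- 1 - include_threshold

  codes <- character(length(cols))
  modal <- character(length(cols))
  for (k in seq_along(cols)) {
    sym <- mat[, cols[k]]
    gapped <- sym %in% GAP_CHARS
    if (mean(gapped) > max_gap + 1e-12) {
      stop("column ", cols[k] - 1L, " is gapped in ",
           round(100 * mean(gapped), 1), "% of records (> ",
           round(100 * max_gap, 1), "% allowed)")
    }
    sym <- sym[!gapped]
    freq <- c(A = 0, C = 0, G = 0, T = 0)
    for (s in sym) {
      bs <- IUPAC_SETS[[s]]
      freq[bs] <- freq[bs] + 1 / length(bs)
    }
    freq <- freq / length(sym)
    keep <- names(freq)[freq >= min_freq - 1e-12]
    if (length(keep) == 0L) keep <- names(freq)[freq == max(freq)]
    codes[k] <- iupac_code_for(keep)
    modal[k] <- names(freq)[which.max(freq)]
  }

  seqc <- paste(codes, collapse = "")
  modal_seq <- paste(modal, collapse = "")
  if (orientation == "reverse") {
    seqc <- revcomp_iupac(seqc)
    modal_seq <- revcomp_iupac(modal_seq)
  }
  counts <- table(factor(strsplit(modal_seq, "")[[1]], levels = c("A", "C", "G", "T")))
  tm <- 2 * (counts[["A"]] + counts[["T"]]) + 4 * (counts[["G"]] + counts[["C"]])
  structure(list(sequence = seqc,
                 degeneracy = prod(iupac_degeneracy(seqc)),
                 melting_temp = tm,
                 orientation = orientation,
                 region = region),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("degenerate_primer (%s): %s  degeneracy %d, Tm %.0f C\n",
              x$orientation, x$sequence, x$degeneracy, x$melting_temp))
  invisible(x)
}

#' Write / read a design table
#'
#' Tab-separated design tables carry the design name, the three region
#' coordinate pairs (0-based half-open), the core and flank identities and,
#' when a panel is supplied, the forward and reverse degenerate primers with
#' degeneracy and Wallace melting temperature.
#'
#' @param designs list of [barcode_design()]s.
#' @param path output (input) TSV path.
#' @param panel optional [reference_panel()]; when given, primer columns are
#'   added via [consensus_primer()].
#' @param include_threshold passed to [consensus_primer()].
#' @return `write_designs`: `path` invisibly; `read_designs`: list of
#'   [barcode_design()]s.
#' @export
write_designs <- function(designs, path, panel = NULL, include_threshold = 0.95) {
  tab <- designs_to_table(designs)
  if (!is.null(panel)) {
    fw <- lapply(designs, function(d)
      consensus_primer(panel, d$left_flank, include_threshold, "forward"))
    rv <- lapply(designs, function(d)
      consensus_primer(panel, d$right_flank, include_threshold, "reverse"))
    tab$primer_fwd <- vapply(fw, `[[`, "", "sequence")
    tab$primer_rev <- vapply(rv, `[[`, "", "sequence")
    tab$degeneracy_fwd <- vapply(fw, `[[`, 0, "degeneracy")
    tab$degeneracy_rev <- vapply(rv, `[[`, 0, "degeneracy")
    tab$tm_fwd <- vapply(fw, `[[`, 0, "melting_temp")
    tab$tm_rev <- vapply(rv, `[[`, 0, "melting_temp")
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_designs
#' @export
read_designs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  designs <- lapply(seq_len(nrow(tab)), function(i) {
    barcode_design(
      left_flank = region(tab$left_start[i], tab$left_end[i]),
      core = region(tab$core_start[i], tab$core_end[i]),
      right_flank = region(tab$right_start[i], tab$right_end[i]),
      core_identity = tab$core_identity[i],
      flank_identity = tab$flank_identity[i],
      name = tab$name[i]
    )
  })
  names(designs) <- tab$name
  designs
}
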