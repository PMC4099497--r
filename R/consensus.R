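#' Replicate read sets for a single barcode and sample
#'
#' Ancient-DNA authentication rests on independent amplifications agreeing:
#' each barcode is amplified several times per sample and sequenced in both
#' directions; a `replicate_set` bundles those reads for one
#' (barcode, sample) cell.
#'
#' @param barcode_name,sample_id identifiers.
#' @param reads data frame with columns `replicate` (integer),
#'   `direction` (`"forward"`/`"reverse"`), `sequence` (non-empty); each
#'   (replicate, direction) pair must be unique.
#' @return an object of class `replicate_set`.
#' @export
replicate_set <- function(barcode_name, sample_id, reads) {
  stopifnot(is.data.frame(reads),
            all(c("replicate", "direction", "sequence") %in% names(reads)))
  if (nrow(reads) == 0L) stop("empty read set")
  if (!all(reads$direction %in% c("forward", "reverse"))) {
    stop("direction must be 'forward' or 'reverse'")
  }
  if (any(!nzchar(reads$sequence))) stop("empty sequence in read set")
  key <- paste(reads$replicate, reads$direction)
  if (anyDuplicated(key)) {
    stop("duplicate (replicate, direction) pair: ", key[duplicated(key)][1])
  }
  structure(list(barcode_name = barcode_name, sample_id = sample_id,
                 reads = reads), class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("replicate_set %s / %s: %d reads (%d replicates)\n",
              x$sample_id, x$barcode_name, nrow(x$reads),
              length(unique(x$reads$replicate))))
  invisible(x)
}

# trim primer bases off an oriented read when its ends are IUPAC-compatible
# with the supplied primers (forward primer at 5', reverse-complemented
# reverse primer at 3'); untrimmable reads are left untouched.
trim_primer_ends <- function(seqs, primer_fwd = NULL, primer_rev = NULL) {
  ends_compatible <- function(read_part, primer) {
    a <- strsplit(toupper(read_part), "")[[1]]
    b <- strsplit(toupper(primer), "")[[1]]
    all(mapply(iupac_compatible, a, b))
  }
  vapply(seqs, function(s) {
    if (!is.null(primer_fwd) && nchar(s) > nchar(primer_fwd)) {
      np <- nchar(primer_fwd)
      if (ends_compatible(substr(s, 1, np), primer_fwd)) {
        s <- substr(s, np + 1L, nchar(s))
      }
    }
    if (!is.null(primer_rev) && nchar(s) > nchar(primer_rev)) {
      np <- nchar(primer_rev)
      tail_part <- substr(s, nchar(s) - np + 1L, nchar(s))
      if (ends_compatible(tail_part, revcomp_iupac(primer_rev))) {
        s <- substr(s, 1, nchar(s) - np)
      }
    }
    s
  }, "", USE.NAMES = FALSE)
}

#' Assemble replicate reads into an authenticated consensus
#'
#' Reverse-direction reads are reverse-complemented, primer bases optionally
#' trimmed, and the oriented reads compared column by column. In `"strict"`
#' mode the consensus is authenticated only when every read is identical
#' (the replicate-agreement criterion that rules out damage-induced
#' artefacts); any disagreeing column is recorded as a conflict. In
#' `"majority"` mode the per-column majority symbol is called (ties become
#' the IUPAC code of the tied set), conflicts are recorded, and the result
#' is never flagged authenticated.
#'
#' @param reps a [replicate_set()] with at least 2 reads.
#' @param mode `"strict"` (default) or `"majority"`.
#' @param primer_fwd,primer_rev optional primer sequences (IUPAC allowed);
#'   when supplied, compatible read ends are trimmed before comparison.
#' @return an object of class `consensus_barcode`: `sequence`, `conflicts`
#'   (data frame `position` 1-based, `observed` as `"A:11,G:1"` count
#'   strings), `authenticated`, `n_reads`, plus the identifiers.
#' @examples
#' rs <- replicate_set("mb1", "s1", data.frame(
#'   replicate = c(1, 1, 2), direction = c("forward", "reverse", "forward"),
#'   sequence = c("ACGT", "ACGT", "ACGT")))
#' assemble_replicates(rs)$authenticated
#' @export
assemble_replicates <- function(reps, mode = c("strict", "majority"),
                                primer_fwd = NULL, primer_rev = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(reps, "replicate_set"))
  rd <- reps$reads
  if (nrow(rd) < 2L) stop("need at least 2 reads to form a consensus")
  oriented <- ifelse(rd$direction == "reverse",
                     revcomp_iupac(rd$sequence), toupper(rd$sequence))
  # reverse reads were reverse-complemented already, so the reverse primer
  # site sits at the 3' end for every oriented read
  if (!is.null(primer_fwd) || !is.null(primer_rev)) {
    oriented <- trim_primer_ends(oriented, primer_fwd, primer_rev)
  }
  widths <- nchar(oriented)
  if (length(unique(widths)) != 1L) {
    stop("assembly error: oriented read lengths differ (",
         paste(unique(widths), collapse = ", "), ")")
  }
  mat <- do.call(rbind, strsplit(oriented, ""))
  L <- ncol(mat)
  consensus <- character(L)
  conf_pos <- integer(0)
  conf_obs <- character(0)
  for (j in seq_len(L)) {
    counts <- sort(table(mat[, j]), decreasing = TRUE)
    if (length(counts) == 1L) {
      consensus[j] <- names(counts)
    } else {
      conf_pos <- c(conf_pos, j)
      conf_obs <- c(conf_obs,
                    paste(names(counts), as.integer(counts),
                          sep = ":", collapse = ","))
      top <- names(counts)[counts == max(counts)]
      consensus[j] <- if (length(top) == 1L) top else {
        bases <- unique(unlist(IUPAC_SETS[top[top %in% IUPAC_CODES]]))
        if (length(bases) == 0L) top[1] else iupac_code_for(bases)
      }
    }
  }
  conflicts <- data.frame(position = conf_pos, observed = conf_obs,
                          stringsAsFactors = FALSE)
  structure(list(sequence = paste(consensus, collapse = ""),
                 conflicts = conflicts,
                 authenticated = (mode == "strict" && nrow(conflicts) == 0L),
                 n_reads = nrow(rd),
                 mode = mode,
                 barcode_name = reps$barcode_name,
                 sample_id = reps$sample_id),
            class = "consensus_barcode")
}

#' @export
print.consensus_barcode <- function(x, ...) {
  cat(sprintf("consensus_barcode %s / %s: %d reads, %s, %d conflict(s)\n",
              x$sample_id, x$barcode_name, x$n_reads,
              if (x$authenticated) "AUTHENTICATED" else "not authenticated",
              nrow(x$conflicts)))
  invisible(x)
}

#' Total read count of a replication scheme
#'
#' Product of barcodes x samples x independent amplifications x sequencing
#' directions — the bookkeeping behind "n sequences in total" statements.
#'
#' @param n_barcodes,n_samples,n_replicates,n_directions positive counts.
#' @return integer total.
#' @examples
#' replicate_read_count(3, 2, 3, 2)  # 36
#' @export
replicate_read_count <- function(n_barcodes, n_samples, n_replicates, n_directions) {
  counts <- c(n_barcodes, n_samples, n_replicates, n_directions)
  if (any(counts < 1)) stop("all counts must be >= 1")
  as.integer(prod(counts))
}

#' Read replicate sets from a structured FASTA
#'
#' Headers follow `sample|barcode|rep<i>|fwd` (or `rev`); reads are grouped
#' into one [replicate_set()] per (sample, barcode).
#'
#' @param path FASTA file path.
#' @return list of [replicate_set()]s, named `"sample|barcode"`.
#' @export
read_replicate_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no reads in ", path)
  parts <- strsplit(trimws(names(ss)), "\\|")
  bad <- vapply(parts, length, 0L) != 4L
  if (any(bad)) {
    stop("unparseable read header '", names(ss)[bad][1],
         "': expected 'sample|barcode|rep<i>|fwd/rev'")
  }
  df <- data.frame(
    sample = vapply(parts, `[[`, "", 1L),
    barcode = vapply(parts, `[[`, "", 2L),
    replicate = as.integer(sub("^rep", "", vapply(parts, `[[`, "", 3L))),
    direction = ifelse(vapply(parts, `[[`, "", 4L) %in% c("fwd", "forward"),
                       "forward", "reverse"),
    sequence = as.character(ss),
    stringsAsFactors = FALSE
  )
  keys <- unique(paste(df$sample, df$barcode, sep = "|"))
  sets <- lapply(keys, function(k) {
    sub <- df[paste(df$sample, df$barcode, sep = "|") == k, ]
    replicate_set(sub$barcode[1], sub$sample[1],
                  sub[, c("replicate", "direction", "sequence")])
  })
  stats::setNames(sets, keys)
}

#' Write consensus barcodes to FASTA (+ conflicts TSV)
#'
#' @param consensuses list of `consensus_barcode` objects.
#' @param path output FASTA path.
#' @param conflicts_path optional TSV path for the pooled conflict records.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(consensuses, path, conflicts_path = NULL) {
  ss <- Biostrings::BStringSet(vapply(consensuses, `[[`, "", "sequence"))
  names(ss) <- vapply(consensuses, function(x) {
    sprintf("%s|%s|%s", x$sample_id, x$barcode_name,
            if (x$authenticated) "authenticated" else "unauthenticated")
  }, "")
  Biostrings::writeXStringSet(ss, path, width = 80L)
  if (!is.null(conflicts_path)) {
    all_conf <- do.call(rbind, lapply(consensuses, function(x) {
      if (nrow(x$conflicts) == 0L) return(NULL)
      cbind(sample = x$sample_id, barcode = x$barcode_name, x$conflicts)
    }))
    if (is.null(all_conf)) {
      all_conf <- data.frame(sample = character(), barcode = character(),
                             position = integer(), observed = character())
    }
    utils::write.table(all_conf, conflicts_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
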