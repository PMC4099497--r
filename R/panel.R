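#' Reference panels of aligned sequences
#'
#' A `reference_panel` holds an aligned set of (typically mitochondrial)
#' reference sequences with taxonomy parsed from the FASTA labels. It is the
#' universe against which mini-barcodes are designed, evaluated, and unknown
#' specimens identified.
#'
#' @param accession character vector of record identifiers (unique).
#' @param genus,species character vectors of taxonomy. An empty or missing
#'   species epithet (or `"sp."`) flags the record as an unknown taxon;
#'   genus must always be non-empty.
#' @param sequence character vector of aligned sequences over the IUPAC
#'   nucleotide alphabet plus gap (`-` or `.`); all the same length.
#' @return An object of class `reference_panel`: a list with elements
#'   `records` (data frame with columns `accession`, `genus`, `species`,
#'   `unknown_taxon`, `sequence`) and `alignment_length`.
#' @seealso [read_panel()], [pairwise_identity()], [scan_windows()]
#' @examples
#' reference_panel(c("X1", "X2"), c("Columba", "Columba"),
#'                 c("livia", "oenas"), c("ACGT", "ACGA"))
#' @export
reference_panel <- function(accession, genus, species, sequence) {
  n <- length(accession)
  stopifnot(length(genus) == n, length(species) == n, length(sequence) == n)
  if (n == 0L) stop("a reference panel needs at least one record")
  sequence <- toupper(sequence)
  widths <- nchar(sequence)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: sequence lengths differ (",
         paste(unique(widths), collapse = ", "), ")")
  }
  ok <- valid_alphabet(sequence)
  if (!all(ok)) {
    stop("record(s) ", paste(accession[!ok], collapse = ", "),
         " contain symbols outside the IUPAC nucleotide alphabet + gap")
  }
  if (anyDuplicated(accession)) {
    accession <- make.unique(as.character(accession), sep = "_")
  }
  species <- as.character(species)
  species[is.na(species)] <- ""
  unknown <- species == "" | species %in% c("sp.", "sp")
  species[unknown] <- ""
  if (any(genus == "" | is.na(genus))) {
    stop("record(s) ", paste(accession[genus == "" | is.na(genus)], collapse = ", "),
         " have an empty genus")
  }
  records <- data.frame(
    accession = as.character(accession),
    genus = as.character(genus),
    species = species,
    unknown_taxon = unknown,
    sequence = sequence,
    stringsAsFactors = FALSE
  )
  structure(list(records = records, alignment_length = widths[1]),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  r <- x$records
  cat("reference_panel: ", nrow(r), " records, alignment length ",
      x$alignment_length, "\n", sep = "")
  cat("  genera: ", length(unique(r$genus)),
      ", named species: ", length(unique(paste(r$genus, r$species)[!r$unknown_taxon])),
      ", unknown-taxon records: ", sum(r$unknown_taxon), "\n", sep = "")
  invisible(x)
}

n_records <- function(panel) nrow(panel$records)

# aligned sequences as a character matrix (records x columns), rownames =
# accession; cached computation sites call this once and pass it around.
seq_matrix <- function(panel) {
  m <- do.call(rbind, strsplit(panel$records$sequence, ""))
  rownames(m) <- panel$records$accession
  m
}

#' Alignment-column regions
#'
#' Regions are 0-based, half-open intervals in alignment-column space
#' (`start` inclusive, `end` exclusive), the coordinate convention used by
#' every scanning and scoring function in the package.
#'
#' @param start,end integer column bounds, `0 <= start < end`.
#' @return An object of class `region`.
#' @examples
#' region(0, 20)  # the first 20 alignment columns
#' @export
region <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start) {
    stop("invalid region: need 0 <= start < end")
  }
  structure(list(start = start, end = end), class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat("region [", x$start, ", ", x$end, ")\n", sep = "")
  invisible(x)
}

region_width <- function(r) r$end - r$start

# 1-based column indices covered by a region or list of regions
region_columns <- function(r, alignment_length = NULL) {
  rs <- if (inherits(r, "region")) list(r) else r
  cols <- unlist(lapply(rs, function(ri) {
    if (!inherits(ri, "region")) stop("not a region")
    if (!is.null(alignment_length) && ri$end > alignment_length) {
      stop("region [", ri$start, ", ", ri$end, ") exceeds alignment length ",
           alignment_length)
    }
    seq.int(ri$start + 1L, ri$end)
  }))
  cols
}

#' Read an aligned reference panel from FASTA
#'
#' Parses taxonomy from the FASTA headers. Under the default
#' `"accession_binomial"` scheme the first whitespace-delimited token is the
#' accession, the second the genus and the third the species epithet; a
#' missing or `"sp."` epithet flags the record as an unknown taxon. The
#' `"binomial"` scheme takes genus and species as the first two tokens and
#' uses the whole header as accession.
#'
#' @param path path to an aligned FASTA file (all sequences equal length).
#' @param label_scheme `"accession_binomial"` (default) or `"binomial"`.
#' @return A [reference_panel()].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">X1 Columba livia", "ACGT", ">X2 Columba oenas", "ACGA"), fa)
#' read_panel(fa)
#' @export
read_panel <- function(path, label_scheme = c("accession_binomial", "binomial")) {
  label_scheme <- match.arg(label_scheme)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  headers <- names(ss)
  seqs <- as.character(ss)
  toks <- strsplit(trimws(headers), "\\s+")
  parse1 <- function(tk, header) {
    if (label_scheme == "accession_binomial") {
      if (length(tk) < 2L) {
        stop("unparseable label '", header,
             "': expected 'accession Genus species'")
      }
      list(accession = tk[1],
           genus = tk[2],
           species = if (length(tk) >= 3L) tk[3] else "")
    } else {
      if (length(tk) < 1L) stop("unparseable empty label")
      list(accession = paste(tk, collapse = "_"),
           genus = tk[1],
           species = if (length(tk) >= 2L) tk[2] else "")
    }
  }
  parsed <- mapply(parse1, toks, headers, SIMPLIFY = FALSE)
  reference_panel(
    accession = vapply(parsed, `[[`, "", "accession"),
    genus = vapply(parsed, `[[`, "", "genus"),
    species = vapply(parsed, `[[`, "", "species"),
    sequence = unname(seqs)
  )
}

#' Write a reference panel to aligned FASTA
#'
#' Headers are written as `accession genus species` (species omitted for
#' unknown-taxon records), so that [read_panel()] round-trips the panel.
#'
#' @param panel a [reference_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  r <- panel$records
  headers <- ifelse(r$unknown_taxon,
                    paste(r$accession, r$genus),
                    paste(r$accession, r$genus, r$species))
  ss <- Biostrings::BStringSet(r$sequence)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Taxonomy table of a panel
#'
#' @param panel a [reference_panel()].
#' @return data frame with columns `label` (accession), `genus`, `species`,
#'   `unknown_taxon`.
#' @export
panel_taxonomy <- function(panel) {
  r <- panel$records
  data.frame(label = r$accession, genus = r$genus, species = r$species,
             unknown_taxon = r$unknown_taxon, stringsAsFactors = FALSE)
}
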