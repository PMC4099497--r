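#' Haplotype table for a barcode design
#'
#' For every named species in the panel, the set of distinct core haplotypes
#' its records carry. A haplotype is the core-region subsequence with gap
#' columns removed; ambiguity codes are kept as distinct symbols. Records
#' flagged as unknown taxa are excluded (species-level bookkeeping).
#'
#' @param panel a [reference_panel()].
#' @param design a [barcode_design()] valid for the panel.
#' @return named list: `"Genus species"` -> character vector of haplotypes.
#' @export
haplotype_table <- function(panel, design) {
  stopifnot(inherits(design, "barcode_design"))
  if (design$right_flank$end > panel$alignment_length) {
    stop("design exceeds alignment length")
  }
  r <- panel$records
  keep <- !r$unknown_taxon
  cores <- substr(r$sequence, design$core$start + 1L, design$core$end)
  cores <- gsub("[-.]", "", cores)
  sp <- paste(r$genus, r$species)
  tab <- split(cores[keep], sp[keep])
  lapply(tab, function(h) sort(unique(h)))
}

#' Count species with panel-unique barcode haplotypes
#'
#' A species counts as unique when none of its core haplotypes is shared
#' (exact string equality after gap stripping, optionally within `k`
#' mismatches) with any haplotype of any other species.
#'
#' @inheritParams haplotype_table
#' @param k mismatch tolerance: haplotypes of equal length within `k`
#'   substitutions of a haplotype of another species break uniqueness
#'   (default 0, strict equality).
#' @return integer count of unique species.
#' @export
uniqueness_count <- function(panel, design, k = 0L) {
  tab <- haplotype_table(panel, design)
  if (length(tab) <= 1L) return(length(tab))
  species <- names(tab)
  shared <- function(h1, h2) {
    if (k == 0L) return(any(h1 %in% h2))
    for (a in h1) for (b in h2) {
      if (nchar(a) == nchar(b)) {
        mism <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
        if (mism <= k) return(TRUE)
      } else if (a == b) return(TRUE)
    }
    FALSE
  }
  unique_flags <- vapply(seq_along(species), function(i) {
    others <- unlist(tab[-i], use.names = FALSE)
    if (k == 0L) !any(tab[[i]] %in% others)
    else !shared(tab[[i]], unique(others))
  }, TRUE)
  sum(unique_flags)
}

#' Evaluate a set of barcode designs for taxonomic resolution
#'
#' One row per design: core length in bp (mean ungapped core length across
#' records), core and flank identities, and the count of species whose
#' haplotypes are unique in the panel. Summary means are attached.
#'
#' @inheritParams haplotype_table
#' @param designs non-empty list of [barcode_design()]s.
#' @param k mismatch tolerance, see [uniqueness_count()].
#' @return data frame of class `evaluation_report` with columns `name`,
#'   `core_length_bp`, `core_identity`, `flank_identity`,
#'   `unique_species_count`, `n_species`, and attributes `mean_core_length`
#'   and `mean_unique_species`.
#' @export
evaluate_designs <- function(panel, designs, k = 0L) {
  if (length(designs) == 0L) stop("empty design list")
  r <- panel$records
  n_species <- length(unique(paste(r$genus, r$species)[!r$unknown_taxon]))
  rows <- lapply(designs, function(d) {
    cores <- substr(r$sequence, d$core$start + 1L, d$core$end)
    core_bp <- mean(nchar(gsub("[-.]", "", cores)))
    data.frame(name = d$name,
               core_length_bp = core_bp,
               core_identity = d$core_identity,
               flank_identity = d$flank_identity,
               unique_species_count = uniqueness_count(panel, d, k = k),
               n_species = n_species,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  attr(rep, "mean_core_length") <- mean(rep$core_length_bp)
  attr(rep, "mean_unique_species") <- mean(rep$unique_species_count)
  class(rep) <- c("evaluation_report", "data.frame")
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (", nrow(x), " designs)\n", sep = "")
  print.data.frame(x, digits = 4)
  cat(sprintf("mean core length: %.1f bp; mean unique species: %.1f of %d\n",
              attr(x, "mean_core_length"), attr(x, "mean_unique_species"),
              x$n_species[1]))
  invisible(x)
}
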