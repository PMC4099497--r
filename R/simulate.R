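#' Specification for a simulated reference panel
#'
#' Describes the regime the generator emulates: a genus/species/individual
#' hierarchy with target within-species (~0.01 substitutions/site) and
#' congeneric (~0.09 substitutions/site) divergences, and planted
#' mini-barcode loci whose flanks evolve slower and cores faster than
#' background (two-rate site model, rates normalised to mean 1 across the
#' alignment so tree depths are in substitutions/site).
#'
#' @param n_genera number of genera (default 8).
#' @param species_per_genus species per genus (default 3).
#' @param n_individuals sequenced individuals per species (default 2, so
#'   the panel contains conspecific record pairs).
#' @param within_species_divergence target mean conspecific distance,
#'   substitutions/site (default 0.01).
#' @param congeneric_divergence target mean congeneric distance (default
#'   0.09).
#' @param between_genus_divergence mean distance between genera (default
#'   0.25).
#' @param flank_rate_multiplier relative rate of flank columns (< 1,
#'   default 0.1).
#' @param core_rate_multiplier relative rate of core columns (> 1, default
#'   5).
#' @param alignment_length columns in the alignment (default 1000, the
#'   scale of a mitochondrial 12S rRNA alignment).
#' @param layout list of planted loci, each a list with contiguous `left`,
#'   `core`, `right` [region()]s; the default plants three loci with core
#'   widths 60, 64 and 69 columns and 20-column flanks. Loci must not
#'   overlap and must fit in `alignment_length`.
#' @param seed integer seed (default 1).
#' @return an object of class `panel_sim_spec`.
#' @export
panel_sim_spec <- function(n_genera = 8L, species_per_genus = 3L,
                           n_individuals = 2L,
                           within_species_divergence = 0.01,
                           congeneric_divergence = 0.09,
                           between_genus_divergence = 0.25,
                           flank_rate_multiplier = 0.1,
                           core_rate_multiplier = 5,
                           alignment_length = 1000L,
                           layout = NULL, seed = 1L) {
  stopifnot(n_genera >= 1L, species_per_genus >= 1L, n_individuals >= 1L,
            within_species_divergence > 0, congeneric_divergence > 0,
            between_genus_divergence > congeneric_divergence,
            flank_rate_multiplier > 0, flank_rate_multiplier < 1,
            core_rate_multiplier > 1)
  if (is.null(layout)) {
    mk <- function(ls, cw) list(left = region(ls, ls + 20L),
                                core = region(ls + 20L, ls + 20L + cw),
                                right = region(ls + 20L + cw, ls + 40L + cw))
    layout <- list(mk(50L, 60L), mk(240L, 64L), mk(430L, 69L))
  }
  ends <- vapply(layout, function(l) l$right$end, 0L)
  starts <- vapply(layout, function(l) l$left$start, 0L)
  if (any(ends > alignment_length)) {
    stop("impossible layout: planted regions exceed alignment length ",
         alignment_length)
  }
  ord <- order(starts)
  if (any(utils::head(ends[ord], -1) > starts[ord][-1])) {
    stop("impossible layout: planted regions overlap")
  }
  for (l in layout) {
    if (l$left$end != l$core$start || l$core$end != l$right$start) {
      stop("impossible layout: locus regions must be contiguous")
    }
  }
  structure(list(n_genera = as.integer(n_genera),
                 species_per_genus = as.integer(species_per_genus),
                 n_individuals = as.integer(n_individuals),
                 within_species_divergence = within_species_divergence,
                 congeneric_divergence = congeneric_divergence,
                 between_genus_divergence = between_genus_divergence,
                 flank_rate_multiplier = flank_rate_multiplier,
                 core_rate_multiplier = core_rate_multiplier,
                 alignment_length = as.integer(alignment_length),
                 layout = layout, seed = as.integer(seed)),
            class = "panel_sim_spec")
}

# sequentially join newick fragments (an ultrametric ladder); depths are
# node heights above the tips, non-decreasing.
ladder_join <- function(frags, tip_depths, join_depths) {
  stopifnot(length(join_depths) == length(frags) - 1L)
  frag <- frags[1]; depth <- tip_depths[1]
  for (k in seq_along(join_depths)) {
    D <- join_depths[k]
    frag <- sprintf("(%s:%.10g,%s:%.10g)",
                    frag, D - depth, frags[k + 1L], D - tip_depths[k + 1L])
    depth <- D
  }
  list(frag = frag, depth = depth)
}

# ladder join depths for S species scaled so the mean pairwise distance
# (2 x join depth, averaged over unordered pairs) equals `target`; the wide
# raw spread emulates the broad congeneric distance distribution seen in
# real panels (sd comparable to half the mean)
species_join_depths <- function(S, target) {
  if (S == 1L) return(numeric(0))
  raw <- seq(0.25, 0.85, length.out = S - 1L)
  # pair (i, j), i<j joins at raw[j-1]; count of pairs joining at raw[k] is k
  mean_pair <- sum(2 * raw * seq_len(S - 1L)) / choose(S, 2)
  raw * target / mean_pair
}

# per-species depth factors for conspecific coalescence: vary around 1 so
# within-species distances spread (mean w, sd ~ 0.3 w) instead of sitting
# at a single value
within_depth_factors <- function(S) {
  if (S == 1L) return(1)
  seq(0.5, 1.5, length.out = S)
}

# per-column relative rates for a sim spec, normalised to mean 1
layout_rates <- function(spec) {
  rates <- rep(1, spec$alignment_length)
  for (l in spec$layout) {
    rates[region_columns(list(l$left, l$right))] <- spec$flank_rate_multiplier
    rates[region_columns(l$core)] <- spec$core_rate_multiplier
  }
  rates / mean(rates)
}

#' Simulate a reference panel with planted mini-barcode loci
#'
#' Builds an ultrametric genus/species/individual tree whose depths realise
#' the divergence targets of the simulation spec, then evolves sequences along it
#' under the Jukes-Cantor model (via [phangorn::simSeq()]) with the
#' two-rate site layout: flank columns slow, core columns fast, background
#' rate 1, all normalised to a mean rate of 1. Gap-free, deterministic for
#' a fixed seed.
#'
#' @param spec a [panel_sim_spec()].
#' @return an object of class `panel_sim`: `panel` (a [reference_panel()]),
#'   and `truth` with `tree` (the generating [ape::phylo]), `designs`
#'   (planted [barcode_design()]s with realised identities), `rates`
#'   (per-column relative rates) and `spec`.
#' @examples
#' sim <- simulate_panel(panel_sim_spec(n_genera = 2, seed = 42))
#' sim$panel
#' @export
simulate_panel <- function(spec = panel_sim_spec()) {
  stopifnot(inherits(spec, "panel_sim_spec"))
  G <- spec$n_genera; S <- spec$species_per_genus; I <- spec$n_individuals
  w <- spec$within_species_divergence
  cg <- spec$congeneric_divergence
  bg <- spec$between_genus_divergence

  acc <- sprintf("SYN%03d", seq_len(G * S * I))
  idx <- 0L
  genus_frags <- character(G); genus_depths <- numeric(G)
  genera <- character(0); species <- character(0); accession <- character(0)
  wf <- within_depth_factors(S)
  for (g in seq_len(G)) {
    sp_frags <- character(S)
    sp_depths <- numeric(S)
    for (s in seq_len(S)) {
      tips <- acc[idx + seq_len(I)]
      idx <- idx + I
      accession <- c(accession, tips)
      genera <- c(genera, rep(sprintf("Genus%02d", g), I))
      species <- c(species, rep(sprintf("sp%02d", s), I))
      if (I == 1L) {
        sp_frags[s] <- tips
        sp_depths[s] <- 0
      } else {
        jd <- rep(wf[s] * w / 2, I - 1L)
        sp_frags[s] <- ladder_join(tips, rep(0, I), jd)$frag
        sp_depths[s] <- jd[I - 1L]
      }
    }
    if (S == 1L) {
      genus_frags[g] <- sp_frags[1]; genus_depths[g] <- sp_depths[1]
    } else {
      jd <- species_join_depths(S, cg)
      if (any(jd <= max(sp_depths))) {
        stop("within-species depth exceeds species join depths; ",
             "lower within_species_divergence or raise congeneric_divergence")
      }
      lj <- ladder_join(sp_frags, sp_depths, jd)
      genus_frags[g] <- lj$frag; genus_depths[g] <- lj$depth
    }
  }
  if (G == 1L) {
    nwk <- paste0(genus_frags[1], ";")
  } else {
    jd <- seq(bg / 2, bg / 2 * 1.3, length.out = G - 1L)
    if (any(jd <= max(genus_depths))) {
      stop("genus join depths below genus subtree depth; raise between_genus_divergence")
    }
    nwk <- paste0(ladder_join(genus_frags, genus_depths, jd)$frag, ";")
  }
  tree <- ape::read.tree(text = nwk)

  rates <- layout_rates(spec)
  # contiguous constant-rate blocks
  blocks <- rle(rates)
  seqs <- withr::with_seed(spec$seed, {
    pos <- 0L
    pieces <- lapply(seq_along(blocks$lengths), function(b) {
      m <- as.character(phangorn::simSeq(tree, l = blocks$lengths[b],
                                         type = "DNA",
                                         rate = blocks$values[b]))
      m[tree$tip.label, , drop = FALSE]
    })
    mat <- do.call(cbind, pieces)
    toupper(apply(mat, 1L, paste, collapse = ""))
  })
  seqs <- seqs[acc]

  panel <- reference_panel(accession = acc,
                           genus = genera[match(acc, accession)],
                           species = species[match(acc, accession)],
                           sequence = unname(seqs))

  designs <- lapply(seq_along(spec$layout), function(i) {
    l <- spec$layout[[i]]
    barcode_design(
      left_flank = l$left, core = l$core, right_flank = l$right,
      core_identity = region_mean_identity(panel, l$core),
      flank_identity = region_mean_identity(panel, list(l$left, l$right)),
      name = paste0("planted", i)
    )
  })
  structure(list(panel = panel,
                 truth = list(tree = tree, designs = designs,
                              rates = rates, spec = spec)),
            class = "panel_sim")
}

#' @export
print.panel_sim <- function(x, ...) {
  cat("panel_sim (seed ", x$truth$spec$seed, ")\n", sep = "")
  print(x$panel)
  cat("  planted loci: ", length(x$truth$designs), "\n", sep = "")
  invisible(x)
}

# JC mutation of an ungapped/aligned sequence: each A/C/G/T site i changes
# with probability 0.75 * (1 - exp(-4/3 * d * rate_i)) to a uniformly
# chosen different base; other symbols untouched.
mutate_jc <- function(seq, d, rates = 1) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  rates <- rep_len(rates, n)
  p <- 0.75 * (1 - exp(-4 / 3 * d * rates))
  base_idx <- chars %in% c("A", "C", "G", "T")
  hit <- base_idx & (stats::runif(n) < p)
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, "")
  }
  paste(chars, collapse = "")
}

apply_damage <- function(seq, damage_rate) {
  if (damage_rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- chars == "C" & stats::runif(length(chars)) < damage_rate
  chars[hit] <- "T"
  paste(chars, collapse = "")
}

# independent per-base sequencing errors: each A/C/G/T base is replaced by
# a uniformly chosen different base with probability `error_rate`
apply_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- chars %in% c("A", "C", "G", "T") &
         stats::runif(length(chars)) < error_rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  }
  paste(chars, collapse = "")
}

#' Simulate a replicate amplification experiment for an unknown specimen
#'
#' Grafts a query taxon onto the generating tree at a known distance from a
#' chosen reference record, then emulates the laboratory scheme: for each
#' planted barcode, sample and replicate, a template fragment length is
#' drawn from the degradation profile — amplicons longer than the drawn
#' fragment drop out — and surviving templates are read in both directions
#' with independent per-read sequencing errors and per-replicate
#' template-strand C-to-T damage.
#'
#' @param sim a `panel_sim` from [simulate_panel()].
#' @param profile a [fragment_profile] (default the 51 bp-median lognormal
#'   truncated at 30 bp, [lognormal_profile()]).
#' @param n_barcodes,n_samples,n_replicates,n_directions replication scheme
#'   (defaults 3, 2, 3, 2 — three loci amplified three times for each of
#'   two samples, read in both directions).
#' @param error_rate per-base sequencing error probability (default 0).
#' @param damage_rate per-base C-to-T damage probability on the template
#'   strand, applied once per replicate (default 0).
#' @param query_divergence distance of the query from its attachment
#'   record, substitutions/site (default 0.11).
#' @param attach_to accession of the reference record the query descends
#'   from (default: first record).
#' @param seed optional integer seed.
#' @return list with `replicate_sets` (list of [replicate_set()]s, one per
#'   surviving (sample, barcode) cell), `dropouts` (data frame `sample`,
#'   `barcode`, `replicate`, `fragment_length`, `amplicon_length`), and
#'   `truth` (`query_sequence` in panel coordinates, `attached_to`,
#'   `query_divergence`, `amplicon_lengths`).
#' @export
simulate_query_experiment <- function(sim, profile = lognormal_profile(),
                                      n_barcodes = 3L, n_samples = 2L,
                                      n_replicates = 3L, n_directions = 2L,
                                      error_rate = 0, damage_rate = 0,
                                      query_divergence = 0.11,
                                      attach_to = NULL, seed = NULL) {
  stopifnot(inherits(sim, "panel_sim"),
            n_barcodes >= 1L, n_samples >= 1L,
            n_replicates >= 1L, n_directions >= 1L, n_directions <= 2L)
  designs <- sim$truth$designs
  if (n_barcodes > length(designs)) {
    stop("only ", length(designs), " planted barcodes available")
  }
  r <- sim$panel$records
  if (is.null(attach_to)) attach_to <- r$accession[1]
  src <- r$sequence[match(attach_to, r$accession)]
  if (is.na(src)) stop("attach_to label '", attach_to, "' not in panel")

  run <- function() {
    query <- mutate_jc(src, query_divergence, sim$truth$rates)
    sets <- list(); drops <- list()
    amp_lens <- integer(n_barcodes)
    for (b in seq_len(n_barcodes)) {
      d <- designs[[b]]
      amplicon <- gsub("[-.]", "",
                       substr(query, d$left_flank$start + 1L, d$right_flank$end))
      amp_lens[b] <- nchar(amplicon)
      for (s in seq_len(n_samples)) {
        reads <- NULL
        for (rep_i in seq_len(n_replicates)) {
          frag <- simulate_fragments(profile, 1L)
          if (frag < nchar(amplicon)) {
            drops[[length(drops) + 1L]] <- data.frame(
              sample = sprintf("sample%d", s), barcode = d$name,
              replicate = rep_i, fragment_length = frag,
              amplicon_length = nchar(amplicon), stringsAsFactors = FALSE)
            next
          }
          template <- apply_damage(amplicon, damage_rate)
          for (dir_i in seq_len(n_directions)) {
            read <- apply_errors(template, error_rate)
            direction <- if (dir_i == 1L) "forward" else "reverse"
            if (direction == "reverse") read <- revcomp_iupac(read)
            reads <- rbind(reads, data.frame(replicate = rep_i,
                                             direction = direction,
                                             sequence = read,
                                             stringsAsFactors = FALSE))
          }
        }
        if (!is.null(reads) && nrow(reads) > 0L) {
          sets[[sprintf("sample%d|%s", s, d$name)]] <-
            replicate_set(d$name, sprintf("sample%d", s), reads)
        }
      }
    }
    dropouts <- if (length(drops)) do.call(rbind, drops) else
      data.frame(sample = character(), barcode = character(),
                 replicate = integer(), fragment_length = numeric(),
                 amplicon_length = integer())
    list(replicate_sets = sets, dropouts = dropouts,
         truth = list(query_sequence = query, attached_to = attach_to,
                      query_divergence = query_divergence,
                      amplicon_lengths = amp_lens))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write replicate sets to a structured FASTA
#'
#' Inverse of [read_replicate_fasta()]: headers
#' `sample|barcode|rep<i>|fwd/rev`.
#'
#' @param sets list of [replicate_set()]s.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_replicate_fasta <- function(sets, path) {
  headers <- character(0); seqs <- character(0)
  for (st in sets) {
    rd <- st$reads
    headers <- c(headers, sprintf("%s|%s|rep%d|%s", st$sample_id,
                                  st$barcode_name, rd$replicate,
                                  ifelse(rd$direction == "forward", "fwd", "rev")))
    seqs <- c(seqs, rd$sequence)
  }
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}
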