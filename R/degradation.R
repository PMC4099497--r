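#' Fragment-length profiles of degraded DNA extracts
#'
#' A `fragment_profile` describes the distribution of template fragment
#' lengths in a degraded extract, left-truncated at `min_length` (extraction
#' chemistry retains fragments above ~30 bp only). Two families are
#' supported: a truncated lognormal fitted by maximum likelihood, and an
#' empirical profile that stores the observed sample and resamples from it.
#'
#' @name fragment_profile
NULL

new_fragment_profile <- function(family, parameters, min_length, median_length) {
  structure(list(family = family, parameters = parameters,
                 min_length = min_length, median_length = median_length),
            class = "fragment_profile")
}

#' @export
print.fragment_profile <- function(x, ...) {
  cat(sprintf("fragment_profile: %s, min length %d bp, median %.1f bp\n",
              x$family, x$min_length, x$median_length))
  if (x$family == "lognormal") {
    cat(sprintf("  meanlog %.4f, sdlog %.4f (truncated at %d bp)\n",
                x$parameters[["meanlog"]], x$parameters[["sdlog"]], x$min_length))
  } else {
    cat(sprintf("  empirical sample of %d lengths\n", length(x$parameters)))
  }
  invisible(x)
}

#' Fit a fragment-length profile to observed lengths
#'
#' For `family = "lognormal"` a lognormal left-truncated at `min_length` is
#' fitted by maximum likelihood (the truncation term
#' `-n log(1 - F(min_length))` is part of the likelihood, so parameters
#' describe the *untruncated* molecule population). For `"empirical"` the
#' sorted sample is stored and later bootstrapped. In both cases
#' `median_length` is the sample median.
#'
#' @param lengths numeric vector of fragment lengths in bp (>= 10 values,
#'   all at or above `min_length`).
#' @param family `"lognormal"` or `"empirical"`.
#' @param min_length truncation bound in bp (default 30).
#' @return a [fragment_profile].
#' @examples
#' prof <- fit_fragment_profile(c(35, 40, 45, 50, 51, 52, 55, 60, 70, 90))
#' prof$median_length
#' @export
fit_fragment_profile <- function(lengths, family = c("lognormal", "empirical"),
                                 min_length = 30) {
  family <- match.arg(family)
  lengths <- as.numeric(lengths)
  if (length(lengths) < 10L) stop("need at least 10 fragment lengths")
  low <- lengths < min_length
  if (any(low)) {
    stop("length(s) below min_length (", min_length, " bp): ",
         paste(utils::head(lengths[low], 10L), collapse = ", "))
  }
  med <- stats::median(lengths)
  if (family == "empirical") {
    return(new_fragment_profile("empirical", sort(lengths), min_length, med))
  }
  lx <- log(lengths)
  nll <- function(par) {
    m <- par[1]; s <- exp(par[2])
    -sum(stats::dlnorm(lengths, m, s, log = TRUE)) +
      length(lengths) * log(1 - stats::plnorm(min_length, m, s))
  }
  fit <- stats::optim(c(mean(lx), log(stats::sd(lx) + 1e-6)), nll,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  pars <- c(meanlog = fit$par[1], sdlog = exp(fit$par[2]))
  new_fragment_profile("lognormal", pars, min_length, med)
}

#' Construct a lognormal profile with a target truncated median
#'
#' Solves for the lognormal location parameter so that the distribution,
#' left-truncated at `min_length`, has the requested median — the natural
#' parameterisation when all that is known about an extract is its
#' Bioanalyzer median (e.g. 51 bp) and the retention bound of the
#' extraction (>30 bp).
#'
#' @param median_length target median of the truncated distribution, bp.
#' @param sdlog lognormal shape parameter (default 0.35, a moderately
#'   concentrated degraded-extract trace).
#' @param min_length truncation bound, bp.
#' @return a [fragment_profile].
#' @examples
#' lognormal_profile(51)
#' @export
lognormal_profile <- function(median_length = 51, sdlog = 0.35, min_length = 30) {
  stopifnot(median_length > min_length, sdlog > 0)
  f <- function(m) {
    Fm <- stats::plnorm(min_length, m, sdlog)
    stats::qlnorm((1 + Fm) / 2, m, sdlog) - median_length
  }
  # the truncated median is increasing in meanlog and approaches min_length
  # from above as meanlog -> -Inf; bracket in units of sdlog to keep the
  # truncation CDF away from 1 numerically
  m <- stats::uniroot(f, c(log(min_length) - 5 * sdlog,
                           log(median_length) + 5 * sdlog),
                      tol = 1e-10)$root
  new_fragment_profile("lognormal",
                       c(meanlog = m, sdlog = sdlog),
                       min_length, median_length)
}

trunc_norm_const <- function(profile) {
  1 - stats::plnorm(profile$min_length, profile$parameters[["meanlog"]],
                    profile$parameters[["sdlog"]])
}

#' Probability that an amplicon of a given length is amplifiable
#'
#' Under `weighting = "count"`, the fraction of template molecules at least
#' `amplicon_len` bp long: `P(L >= amplicon_len | L >= min_length)`. Under
#' the default `weighting = "spanning"`, the probability that a uniformly
#' chosen template base position lies on a fragment that fully spans the
#' amplicon: `E[max(0, L - amplicon_len + 1)] / E[L]` — PCR needs one
#' molecule covering both primer sites, so long amplicons fail on heavily
#' fragmented extracts even when short ones amplify. Amplicon length is
#' measured including primers.
#'
#' @param profile a [fragment_profile].
#' @param amplicon_len amplicon length in bp (>= 1); vectorised.
#' @param weighting `"spanning"` (default) or `"count"`.
#' @return probability (vector) in `[0, 1]`, non-increasing in
#'   `amplicon_len`.
#' @examples
#' prof <- lognormal_profile(51)
#' amplifiable_fraction(prof, c(64, 84, 138))
#' @export
amplifiable_fraction <- function(profile, amplicon_len,
                                 weighting = c("spanning", "count")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(profile, "fragment_profile"), all(amplicon_len >= 1))
  one <- function(a) {
    if (profile$family == "empirical") {
      s <- profile$parameters
      if (weighting == "count") return(mean(s >= a))
      return(mean(pmax(0, s - a + 1)) / mean(s))
    }
    m <- profile$parameters[["meanlog"]]; sd <- profile$parameters[["sdlog"]]
    Z <- trunc_norm_const(profile)
    lo <- profile$min_length
    if (weighting == "count") {
      if (a <= lo) return(1)
      return((1 - stats::plnorm(a, m, sd)) / Z)
    }
    dens <- function(l) stats::dlnorm(l, m, sd) / Z
    e_len <- stats::integrate(function(l) l * dens(l), lo, Inf,
                              rel.tol = 1e-9)$value
    from <- max(lo, a - 1)
    e_span <- stats::integrate(function(l) pmax(0, l - a + 1) * dens(l),
                               from, Inf, rel.tol = 1e-9)$value
    min(1, e_span / e_len)
  }
  vapply(amplicon_len, one, 0)
}

#' Simulate fragment lengths from a profile
#'
#' Lognormal profiles are sampled by inverse-CDF conditioning on
#' `L >= min_length` and rounded to whole bp; empirical profiles are
#' bootstrap-resampled. Reproducible for a fixed seed.
#'
#' @param profile a [fragment_profile].
#' @param n number of fragments (>= 1).
#' @param seed optional integer seed.
#' @return integer-valued numeric vector of lengths, all `>= min_length`.
#' @examples
#' simulate_fragments(lognormal_profile(51), 5, seed = 1)
#' @export
simulate_fragments <- function(profile, n, seed = NULL) {
  stopifnot(inherits(profile, "fragment_profile"), n >= 1)
  draw <- function() {
    if (profile$family == "empirical") {
      return(sample(profile$parameters, n, replace = TRUE))
    }
    m <- profile$parameters[["meanlog"]]; sd <- profile$parameters[["sdlog"]]
    Fmin <- stats::plnorm(profile$min_length, m, sd)
    u <- stats::runif(n)
    x <- stats::qlnorm(Fmin + u * (1 - Fmin), m, sd)
    pmax(profile$min_length, round(x))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Read fragment lengths from a plain-text export
#'
#' Accepts one-number-per-line files, or two-column (length, fluorescence)
#' Bioanalyzer-style exports in which case the fluorescence column is used
#' as integer weights (lengths replicated proportionally).
#'
#' @param path input text file (whitespace- or tab-delimited; `#` comments
#'   ignored).
#' @return numeric vector of lengths in bp.
#' @export
read_fragment_lengths <- function(path) {
  tab <- utils::read.table(path, comment.char = "#")
  if (ncol(tab) == 1L) return(as.numeric(tab[[1]]))
  w <- tab[[2]]
  if (any(w < 0)) stop("negative weights in column 2")
  w <- w / max(w) * 100
  rep(as.numeric(tab[[1]]), times = pmax(0L, round(w)))
}
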