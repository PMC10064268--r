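#' GC content of a DNA sequence
#'
#' `N` bases are excluded from the denominator.
#'
#' @param seq DNA string (character) or `replicon`.
#' @return GC content in percent.
#' @export
gc_content <- function(seq) {
  seq <- .as_dna_string(seq)
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                        c("A", "C", "G", "T"))
  total <- sum(counts)
  if (total == 0) stop("GC content undefined: sequence has no A/C/G/T bases")
  unname(100 * (counts["C"] + counts["G"]) / total)
}

.as_dna_string <- function(x) {
  if (inherits(x, "replicon")) {
    if (is.null(x$sequence)) stop("replicon '", x$id, "' has no sequence")
    x <- x$sequence
  }
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

#' Strand-symmetric dinucleotide relative-abundance signature
#'
#' Computes the 16-vector of Karlin dinucleotide relative abundances
#' `rho*_XY = f*_XY / (f*_X * f*_Y)` on the sequence concatenated with its
#' reverse complement (strand-symmetrized frequencies `f*`). Dinucleotides
#' are counted linearly on each strand (no wrap across the circular origin;
#' the effect is O(1/L)). Windows containing `N` are excluded.
#'
#' @param seq DNA string or `replicon`; must contain all four bases.
#' @return Named numeric 16-vector of class `dinuc_signature`
#'   (names `AA`, `AC`, ..., `TT`).
#' @export
dinucleotide_signature <- function(seq) {
  seq <- .as_dna_string(seq)
  if (nchar(seq) < 2) stop("sequence too short for a dinucleotide signature")
  s <- Biostrings::DNAString(seq)
  rc <- Biostrings::reverseComplement(s)
  dn <- Biostrings::dinucleotideFrequency(s) +
    Biostrings::dinucleotideFrequency(rc)
  mono <- Biostrings::letterFrequency(s, c("A", "C", "G", "T")) +
    Biostrings::letterFrequency(rc, c("A", "C", "G", "T"))
  if (any(mono == 0))
    stop("degenerate composition: base(s) ",
         paste(names(mono)[mono == 0], collapse = ", "),
         " absent; relative abundances undefined")
  fXY <- dn / sum(dn)
  fX <- mono / sum(mono)
  b1 <- substr(names(fXY), 1, 1)
  b2 <- substr(names(fXY), 2, 2)
  rho <- fXY / (fX[b1] * fX[b2])
  structure(setNames(as.numeric(rho), names(fXY)), class = "dinuc_signature")
}

#' Dinucleotide relative-abundance (DRA) distance
#'
#' `delta* = (scale/16) * sum_XY |rho1_XY - rho2_XY|`. The default
#' `scale = 100` puts the distance on the percent-like scale on which the
#' chromid criterion (`<= 0.4`) is stated. The distance is a metric
#' (non-negative, symmetric, triangle inequality) and is exactly zero
#' between a sequence and its reverse complement.
#'
#' @param sig1,sig2 Signatures from [dinucleotide_signature()].
#' @param scale Reporting scale factor (default 100).
#' @return Scaled DRA distance.
#' @export
dra_distance <- function(sig1, sig2, scale = 100) {
  stopifnot(length(sig1) == 16L, length(sig2) == 16L)
  scale / 16 * sum(abs(as.numeric(sig1) - as.numeric(sig2)))
}

#' Per-replicon composition metrics for an assembly
#'
#' Computes length, GC and DRA distance to the largest replicon
#' (the chromosome), then classifies each replicon with
#' [classify_replicons()].
#'
#' @param assembly A `genome_assembly` with sequences.
#' @param gc_tol GC difference tolerance in percentage points (default 1.0).
#' @param dra_tol DRA distance tolerance on the percent scale (default 0.4).
#' @return Data frame: `replicon_id, length, gc, dra_to_chromosome,
#'   classification`.
#' @export
replicon_metrics <- function(assembly, gc_tol = 1.0, dra_tol = 0.4) {
  reps <- assembly$replicons
  df <- data.frame(
    replicon_id = vapply(reps, `[[`, character(1), "id"),
    length = vapply(reps, `[[`, integer(1), "length"),
    gc = vapply(reps, gc_content, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  sigs <- lapply(reps, dinucleotide_signature)
  chrom <- .largest_replicon(df)
  df$dra_to_chromosome <- vapply(seq_along(sigs), function(i)
    dra_distance(sigs[[chrom]], sigs[[i]]), numeric(1))
  df$dra_to_chromosome[chrom] <- NA_real_
  classify_replicons(df, gc_tol = gc_tol, dra_tol = dra_tol)
}

.largest_replicon <- function(df) {
  mx <- max(df$length)
  cand <- which(df$length == mx)
  if (length(cand) > 1) {
    cand <- cand[order(df$replicon_id[cand])]
    warning("replicons tied for largest; '", df$replicon_id[cand[1]],
            "' chosen as chromosome by id order")
  }
  cand[1]
}

#' Classify replicons as chromosome / putative chromid / ambiguous /
#' megaplasmid
#'
#' The largest replicon is the chromosome. Every other replicon is compared
#' against it: if both its GC difference (<= `gc_tol` percentage points) and
#' its DRA distance (<= `dra_tol`) pass, it is a putative chromid; if
#' exactly one criterion passes it is flagged `ambiguous` (to be further
#' analyzed, e.g. a cointegrant); if neither passes it is a megaplasmid.
#' Both tolerances are boundary-inclusive. When the `dra_to_chromosome`
#' column is absent or all-NA (e.g. classification from a printed table
#' that only reports GC), a GC-only screening is performed: GC pass =>
#' putative chromid, GC fail => megaplasmid.
#'
#' @param metrics Data frame with columns `replicon_id`, `length`, `gc`, and
#'   optionally `dra_to_chromosome` (NA allowed for the chromosome row).
#' @param gc_tol,dra_tol Boundary-inclusive tolerances (defaults 1.0, 0.4).
#' @return `metrics` with a `classification` factor column added.
#' @export
classify_replicons <- function(metrics, gc_tol = 1.0, dra_tol = 0.4) {
  stopifnot(all(c("replicon_id", "length", "gc") %in% names(metrics)))
  if (!nrow(metrics)) stop("no replicons to classify")
  chrom <- .largest_replicon(metrics)
  has_dra <- "dra_to_chromosome" %in% names(metrics) &&
    any(!is.na(metrics$dra_to_chromosome[-chrom]))
  gc_ok <- abs(metrics$gc - metrics$gc[chrom]) <= gc_tol
  cls <- character(nrow(metrics))
  cls[chrom] <- "chromosome"
  for (i in setdiff(seq_len(nrow(metrics)), chrom)) {
    if (has_dra) {
      dra_ok <- !is.na(metrics$dra_to_chromosome[i]) &&
        metrics$dra_to_chromosome[i] <= dra_tol
      n_ok <- gc_ok[i] + dra_ok
      cls[i] <- c("megaplasmid", "ambiguous", "putative_chromid")[n_ok + 1L]
    } else {
      cls[i] <- if (gc_ok[i]) "putative_chromid" else "megaplasmid"
    }
  }
  metrics$classification <- factor(cls, levels = c(
    "chromosome", "putative_chromid", "ambiguous", "megaplasmid"))
  metrics
}

#' Cumulative GC skew profile
#'
#' Per-window skew `(G - C) / (G + C)` (windows with no G or C contribute
#' zero), cumulatively summed. A single origin of replication shows as one
#' V/inverted-V with the maximum and minimum at the terminus and origin.
#'
#' @param seq DNA string or `replicon`.
#' @param window Window size in bp; must be <= length/10.
#' @return Data frame: `midpoint` (bp) and `skew_cum`.
#' @export
cumulative_gc_skew <- function(seq, window = 10000L) {
  seq <- .as_dna_string(seq)
  L <- nchar(seq)
  if (window > L / 10) stop("window must be <= sequence length / 10")
  starts <- seq(1L, L, by = window)
  ends <- pmin(starts + window - 1L, L)
  v <- Biostrings::DNAStringSet(substring(seq, starts, ends))
  g <- Biostrings::letterFrequency(v, "G")[, 1]
  c_ <- Biostrings::letterFrequency(v, "C")[, 1]
  denom <- g + c_
  skew <- ifelse(denom == 0, 0, (g - c_) / pmax(denom, 1))
  data.frame(midpoint = (starts + ends) / 2, skew_cum = cumsum(skew))
}

# Prominence of local extrema of y (maxima if sign = 1, minima via -y).
.prominent_extrema <- function(y, frac) {
  n <- length(y)
  rng <- diff(range(y))
  if (rng == 0) return(integer(0))
  d <- diff(y)
  # local maxima: rising then falling (plateaus collapse to first point)
  idx <- which(d[-1] <= 0 & d[-length(d)] > 0) + 1L
  if (y[1] > y[2]) idx <- c(1L, idx)
  if (y[n] > y[n - 1]) idx <- c(idx, n)
  keep <- integer(0)
  for (i in idx) {
    h <- y[i]
    left <- y[seq_len(i - 1)]
    right <- if (i < n) y[(i + 1):n] else numeric(0)
    higher_l <- which(left > h)
    base_l <- if (length(higher_l)) min(left[(max(higher_l)):(i - 1)]) else
      if (length(left)) min(left) else -Inf
    higher_r <- which(right > h)
    base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else
      if (length(right)) min(right) else -Inf
    base <- max(base_l, base_r)
    prom <- if (is.finite(base)) h - base else 0
    if (prom >= frac * rng) keep <- c(keep, i)
  }
  keep
}

#' Infer the number of replication origins from a cumulative GC skew profile
#'
#' The profile is smoothed (moving average over `smooth` windows) and its
#' range is first compared against a permutation baseline (per-window skew
#' increments shuffled `n_perm` times): a profile whose excursion is
#' compatible with shuffled increments is called `indeterminate`. Otherwise,
#' prominent maxima/minima (prominence >= `prominence` x range) are counted:
#' exactly one of each, separated (circularly) by at least `min_sep` of the
#' replicon length, gives `single`; two or more extrema pairs give
#' `multiple`.
#'
#' @param profile Data frame from [cumulative_gc_skew()] or numeric vector
#'   of cumulative skew values (length >= 10).
#' @param smooth Moving-average width in windows (default 5).
#' @param prominence Prominence threshold as a fraction of the profile range
#'   (default 0.25).
#' @param min_sep Minimum origin-terminus separation as a fraction of length
#'   (default 0.25).
#' @param n_perm Permutations for the baseline (default 99).
#' @param seed RNG seed for the permutation baseline.
#' @return One of `"single"`, `"multiple"`, `"indeterminate"`.
#' @export
infer_origin_count <- function(profile, smooth = 5L, prominence = 0.25,
                               min_sep = 0.25, n_perm = 99L, seed = 1L) {
  y <- if (is.data.frame(profile)) profile$skew_cum else as.numeric(profile)
  if (length(y) < 10) stop("profile must have at least 10 points")
  inc <- diff(c(0, y))
  obs_range <- diff(range(y))
  perm_ranges <- local({
    set.seed(seed)
    vapply(seq_len(n_perm), function(i)
      diff(range(cumsum(sample(inc)))), numeric(1))
  })
  if (obs_range <= stats::quantile(perm_ranges, 0.95)) return("indeterminate")
  n <- length(y)
  # circular handling: remove net drift so the profile closes, then rotate
  # the increments so the global minimum sits at the circular origin
  incd <- inc - mean(inc)
  yd <- cumsum(incd)
  rot <- which.min(yd)
  inc_rot <- incd[c(seq_len(n)[-seq_len(rot)], seq_len(rot))]
  yr <- cumsum(inc_rot)
  k <- min(smooth, n)
  ys <- as.numeric(stats::filter(yr, rep(1 / k, k), sides = 2))
  ys[is.na(ys)] <- yr[is.na(ys)]
  interior <- function(idx) idx[idx > 1 & idx < n]
  maxima <- interior(.prominent_extrema(ys, prominence))
  minima <- interior(.prominent_extrema(-ys, prominence))
  # the rotation point itself is the (single) circular minimum
  if (length(maxima) >= 2 || length(minima) >= 1) return("multiple")
  if (length(maxima) == 1) {
    d <- min(maxima, n - maxima)   # circular distance to the minimum
    if (d >= min_sep * n) return("single")
  }
  "indeterminate"
}
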