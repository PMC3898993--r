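#' Detect regular sequence tracts from the chain spectrum
#'
#' Regular tracts (homogeneous, periodic or palindromic in the W/S code)
#' behave as ordered segments of the oscillator chain and therefore support
#' extended normal modes, while aperiodic background localizes them. The
#' detector proceeds per eigenvector:
#'
#' 1. modes with participation number `P >= P_thr` are classed
#'    *delocalized*;
#' 2. each delocalized mode is assigned its boundary sites `[s, e]`
#'    (see [eigenvector_indicators()]; the interval includes the
#'    epsilon-crossing site on either side of the mode's support);
#' 3. a mode is *accepted* when the number `n` of delocalized modes whose
#'    interval is contained in `[s, e]` agrees with the interior length
#'    `e - s - 1` within a fractional tolerance `tol`: an isolated regular
#'    region of `m` interior sites has exactly `m` such modes, so
#'    `|n - (e-s-1)| <= tol * (e-s-1)`;
#' 4. accepted intervals that overlap are merged into regions, and regions
#'    shorter than `min_len` are discarded.
#'
#' With the default thresholds the shortest detectable regular sequence is
#' 7 nt: a homopolymer of five bases plus the flanking base of opposite
#' W/S class on each side (modes of 4-site tracts fall below `P_thr`).
#'
#' @param spectrum a [pb_spectrum()] object.
#' @param P_thr participation-number threshold defining delocalized modes.
#' @param eps tail threshold for mode boundary sites.
#' @param delta component threshold for the extension indicator.
#' @param tol fractional tolerance of the mode-count criterion.
#' @param min_len minimum reported region length (nt).
#' @return data.frame with one row per region, sorted by `s`: columns `s`,
#'   `e` (1-based inclusive chain sites), `length`, `n_support` (number of
#'   accepted delocalized modes merged into the region), `binary` (W/S
#'   substring) and `quaternary` (DNA substring, `NA` if the spectrum was
#'   built from a bare W/S code).
#' @export
detect_regions <- function(spectrum, P_thr = 3.7, eps = 0.01, delta = 1e-4,
                           tol = 0.3, min_len = 7) {
  stopifnot(inherits(spectrum, "pb_spectrum"))
  ind <- eigenvector_indicators(spectrum, eps = eps, delta = delta)
  sel <- ind[ind$P >= P_thr, , drop = FALSE]
  empty <- data.frame(s = integer(0), e = integer(0), length = integer(0),
                      n_support = integer(0), binary = character(0),
                      quaternary = character(0))
  if (!nrow(sel)) return(empty)
  interior <- sel$e - sel$s - 1
  n <- mapply(function(S, E) sum(sel$s >= S & sel$e <= E), sel$s, sel$e)
  ok <- interior >= 1 & abs(n - interior) <= tol * interior
  acc <- sel[ok, , drop = FALSE]
  if (!nrow(acc)) return(empty)
  acc <- acc[order(acc$s, acc$e), , drop = FALSE]
  merged <- IRanges::reduce(IRanges::IRanges(start = acc$s, end = acc$e))
  hits <- IRanges::countOverlaps(merged, IRanges::IRanges(acc$s, acc$e),
                                 type = "any")
  res <- data.frame(s = IRanges::start(merged), e = IRanges::end(merged),
                    length = IRanges::width(merged), n_support = hits)
  res <- res[res$length >= min_len, , drop = FALSE]
  if (!nrow(res)) return(empty)
  res$binary <- substring(spectrum$code, res$s, res$e)
  res$quaternary <- if (is.na(spectrum$sequence)) NA_character_ else
    substring(spectrum$sequence, res$s, res$e)
  rownames(res) <- NULL
  res
}

#' Fraction of a promoter covered by regular regions
#'
#' @param regions data.frame as returned by [detect_regions()] (columns `s`,
#'   `e`), assumed non-overlapping; overlap is an error (merge first).
#' @param L promoter length.
#' @return scalar in `[0, 1]`.
#' @export
coverage_fraction <- function(regions, L) {
  if (!nrow(regions)) return(0)
  r <- regions[order(regions$s), , drop = FALSE]
  if (any(r$s[-1] <= r$e[-nrow(r)]))
    stop("regions overlap; merge them before computing coverage")
  sum(r$e - r$s + 1) / L
}

#' Length histogram of regular regions
#'
#' @param regions data.frame with a `length` column (possibly pooled over
#'   many promoters).
#' @return named integer vector: counts per observed length.
#' @export
length_histogram <- function(regions) {
  if (!nrow(regions)) return(stats::setNames(integer(0), character(0)))
  table(factor(regions$length))
}

#' Catalogue of regular sequences in a promoter cluster
#'
#' Pools the quaternary strings of detected regions across the promoters of
#' one cluster, then ranks distinct strings by the number of cluster
#' promoters containing them at least once. Occurrences are recounted by
#' exact (overlap-allowing) substring search over all cluster promoters, on
#' the given strand only. When a repeat annotation is supplied, the
#' fraction of occurrences falling inside annotated repeats is added
#' (an occurrence counts as inside only if fully contained in one
#' interval).
#'
#' @param regions data.frame of detected regions pooled over the cluster;
#'   must have a `quaternary` column and a `promoter_id` column.
#' @param records named character vector: the cluster promoters.
#' @param repeats optional data.frame of repeat intervals (see
#'   [read_repeatmasker()]).
#' @param top_k number of entries returned (default 15).
#' @param overlap_rule `"contained"` (default) or `"any_overlap"` for the
#'   in-repeat rule.
#' @return data.frame ranked by `n_promoters` (ties: `n_occurrences`, then
#'   lexicographic), with columns `sequence`, `n_promoters`, `promoter_pct`,
#'   `n_occurrences`, `mean_copies`, `pct_in_transposon` (`NA` without
#'   annotation).
#' @export
region_catalog <- function(regions, records, repeats = NULL, top_k = 15,
                           overlap_rule = c("contained", "any_overlap")) {
  overlap_rule <- match.arg(overlap_rule)
  records <- as_promoters(records)
  seqs <- unique(regions$quaternary)
  seqs <- seqs[!is.na(seqs)]
  if (!length(seqs))
    return(data.frame(sequence = character(0), n_promoters = integer(0),
                      promoter_pct = numeric(0), n_occurrences = integer(0),
                      mean_copies = numeric(0), pct_in_transposon = numeric(0)))
  subject <- Biostrings::DNAStringSet(records)
  rows <- lapply(seqs, function(q) {
    counts <- Biostrings::vcountPattern(q, subject)   # overlapping matches
    n_prom <- sum(counts > 0)
    n_occ <- sum(counts)
    pct_tp <- NA_real_
    if (!is.null(repeats) && n_occ > 0) {
      inside <- 0L
      for (i in which(counts > 0)) {
        m <- Biostrings::matchPattern(q, subject[[i]])
        occ <- data.frame(promoter_id = names(records)[i],
                          start = Biostrings::start(m), end = Biostrings::end(m))
        inside <- inside + sum(occurrences_in_repeats(occ, repeats,
                                                      rule = overlap_rule))
      }
      pct_tp <- inside / n_occ
    }
    data.frame(sequence = q, n_promoters = n_prom,
               promoter_pct = n_prom / length(records),
               n_occurrences = n_occ,
               mean_copies = if (n_prom > 0) n_occ / n_prom else NA_real_,
               pct_in_transposon = pct_tp)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_promoters, -out$n_occurrences, out$sequence), ,
             drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Detect regions for every promoter in a set
#'
#' Convenience wrapper running [pb_spectrum()] and [detect_regions()] per
#' promoter and binding the results with a `promoter_id` column.
#'
#' @param records named character vector of promoters (no `N`).
#' @param params [pb_params()] object.
#' @param ... passed to [detect_regions()].
#' @return data.frame of regions across the set.
#' @export
detect_regions_set <- function(records, params = pb_params(), ...) {
  records <- as_promoters(records, allow_n = FALSE)
  out <- lapply(names(records), function(id) {
    r <- detect_regions(pb_spectrum(records[[id]], params), ...)
    if (nrow(r)) cbind(promoter_id = id, r) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(promoter_id = character(0), s = integer(0),
                      e = integer(0), length = integer(0),
                      n_support = integer(0), binary = character(0),
                      quaternary = character(0))
  rownames(out) <- NULL
  out
}

#' Export regions as BED
#'
#' Internal 1-based inclusive chain sites are converted to BED's 0-based
#' half-open convention; the region's quaternary string is used as the BED
#' name field.
#'
#' @param regions data.frame with `promoter_id`, `s`, `e`, `quaternary`.
#' @param path output path.
#' @export
regions_to_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$promoter_id,
                    start = regions$s - 1L,
                    end = regions$e,
                    name = ifelse(is.na(regions$quaternary), ".",
                                  regions$quaternary))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
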