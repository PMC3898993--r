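#' Alignment scoring scheme
#'
#' EMBOSS-style affine-gap scoring: the standard nucleotide substitution
#' scores (match +5, mismatch -4, the EDNAFULL values for unambiguous
#' bases) and a gap run of length `g` costing `gap_open + g * gap_extend`.
#' In global mode, gaps at either end of either sequence are free by
#' default, as in the EMBOSS needle program.
#'
#' @param mode `"global"` (Needleman-Wunsch) or `"local"` (Smith-Waterman).
#' @param gap_open non-negative gap opening penalty (default 20).
#' @param gap_extend non-negative per-position gap extension penalty
#'   (default 0.5).
#' @param end_gaps_free logical; free terminal gaps in global mode.
#' @param match,mismatch substitution scores.
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(mode = c("global", "local"), gap_open = 20,
                           gap_extend = 0.5, end_gaps_free = TRUE,
                           match = 5, mismatch = -4) {
  mode <- match.arg(mode)
  if (gap_open < 0 || gap_extend < 0)
    stop("gap penalties must be non-negative")
  structure(list(mode = mode, gap_open = gap_open, gap_extend = gap_extend,
                 end_gaps_free = end_gaps_free, match = match,
                 mismatch = mismatch),
            class = "scoring_scheme")
}

.subst_matrix <- function(scheme) {
  Biostrings::nucleotideSubstitutionMatrix(match = scheme$match,
                                           mismatch = scheme$mismatch,
                                           baseOnly = TRUE)
}

.pwa_type <- function(scheme) {
  if (scheme$mode == "local") "local"
  else if (scheme$end_gaps_free) "overlap"
  else "global"
}

#' Align a pair of sequences
#'
#' Affine-gap dynamic programming under a [scoring_scheme()]. The score is
#' the maximum over all alignments; local mode clamps at zero and reports
#' the best-scoring segment pair. One optimal alignment is returned with a
#' deterministic traceback.
#'
#' @param a,b non-empty DNA strings over `{A,C,G,T}`.
#' @param scheme a [scoring_scheme()].
#' @param score_only if `TRUE` (default) return just the numeric score,
#'   which is what the clustering pipeline consumes.
#' @return numeric score, or (with `score_only = FALSE`) a list with
#'   `score`, `aligned_a`, `aligned_b`.
#' @export
align_pair <- function(a, b, scheme = scoring_scheme(), score_only = TRUE) {
  if (!nchar(a) || !nchar(b)) stop("cannot align an empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = .pwa_type(scheme), substitutionMatrix = .subst_matrix(scheme),
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = score_only)
  if (score_only) return(as.numeric(pa))
  list(score = Biostrings::score(pa),
       aligned_a = as.character(Biostrings::alignedPattern(pa)),
       aligned_b = as.character(Biostrings::alignedSubject(pa)))
}

#' All-vs-all similarity matrix
#'
#' Computes best alignment scores for all `N(N-1)/2` promoter pairs. The
#' inner dynamic programming runs in Biostrings' vectorized C code, one
#' call per row block, so ~10^4 pairs of a few hundred nt complete in
#' seconds.
#'
#' @param records named character vector of promoters.
#' @param scheme a [scoring_scheme()].
#' @param diag_self if `TRUE`, fill the diagonal with self-alignment scores
#'   (match score times length); the clustering path zeroes it anyway.
#' @param verbose log progress every 50 rows.
#' @return symmetric numeric matrix with promoter ids as dimnames and the
#'   scheme attached as attribute `scheme`.
#' @export
similarity_matrix <- function(records, scheme = scoring_scheme(),
                              diag_self = TRUE, verbose = FALSE) {
  records <- as_promoters(records, allow_n = FALSE)
  N <- length(records)
  if (N < 2) stop("need at least 2 promoters")
  seqs <- Biostrings::DNAStringSet(records)
  S <- matrix(0, N, N, dimnames = list(names(records), names(records)))
  sm <- .subst_matrix(scheme)
  type <- .pwa_type(scheme)
  for (i in seq_len(N - 1)) {
    S[i, (i + 1):N] <- Biostrings::pairwiseAlignment(
      seqs[(i + 1):N], seqs[[i]], type = type, substitutionMatrix = sm,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
      scoreOnly = TRUE)
    if (verbose && i %% 50 == 0)
      message("similarity_matrix: ", i, "/", N - 1, " rows done")
  }
  S <- S + t(S)
  if (diag_self) diag(S) <- scheme$match * nchar(records)
  attr(S, "scheme") <- scheme
  S
}

#' Random reshuffling of promoter sequences
#'
#' Each sequence is replaced by a uniformly random permutation of its own
#' characters, preserving length and base composition exactly. This is the
#' null model for the similarity threshold: reshuffled promoters keep their
#' compositional signal but lose all positional structure.
#'
#' @param records named character vector.
#' @param seed integer seed; same seed, same output.
#' @return named character vector of reshuffled sequences.
#' @export
reshuffle <- function(records, seed = 0L) {
  records <- as_promoters(records)
  set.seed(seed)
  out <- vapply(records, function(s)
    paste(sample(strsplit(s, "")[[1]]), collapse = ""), "",
    USE.NAMES = FALSE)
  stats::setNames(out, names(records))
}

#' Similarity threshold from the reshuffling null
#'
#' Aligns the reshuffled counterpart of the input set all-vs-all and
#' returns the arithmetic mean of the pairwise scores. Pairs of the real
#' set scoring at or below this value are treated as noise when building
#' the adjacency graph. With `replicates > 1` the mean is taken across
#' independent reshuffles.
#'
#' @param records named character vector.
#' @param scheme a [scoring_scheme()].
#' @param seed integer seed.
#' @param replicates number of independent reshuffle replicates.
#' @return scalar threshold `theta`.
#' @export
null_threshold <- function(records, scheme = scoring_scheme(), seed = 0L,
                           replicates = 1L) {
  vals <- vapply(seq_len(replicates), function(r) {
    sh <- reshuffle(records, seed = seed + r - 1L)
    S <- similarity_matrix(sh, scheme, diag_self = FALSE)
    mean(S[upper.tri(S)])
  }, numeric(1))
  mean(vals)
}
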