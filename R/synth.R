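# Synthetic promoter generation with planted ground truth.
#
# "Regularity-free" background is central here: the Hessian detector reports
# any tract that is ordered in the W/S code (homogeneous, periodic of any
# moderate period, or palindromic -- the latter act as degenerate double
# wells). The background sampler therefore rejects all of these, not just
# short-period repeats.

.ws_min_banned_len <- function(p) if (p == 1) 5L else if (p <= 3) 6L else 2L * p

#' Scan a W/S string for regular tracts
#'
#' Finds every maximal p-periodic tract (period `p = 1..pmax`) of banned
#' length -- at least 5 for homopolymer runs, 6 for periods 2 and 3, `2p`
#' for longer periods -- and every W/S palindrome of length at least
#' `pal_min`. This scanner is the ground-truth oracle for what the
#' synthetic background may not contain; it is deliberately independent of
#' the Hessian detector.
#'
#' @param code W/S string (or DNA string, encoded on the fly).
#' @param pmax maximum period scanned.
#' @param pal_min minimum banned palindrome length.
#' @return data.frame with columns `s`, `e`, `type` (`"periodic"` or
#'   `"palindrome"`) and `period` (NA for palindromes); zero rows if clean.
#' @export
ws_scan <- function(code, pmax = 16, pal_min = 9) {
  ws <- .ws_vector(code)
  L <- length(ws)
  hits <- list()
  for (p in seq_len(min(pmax, L - 1))) {
    ml <- .ws_min_banned_len(p)
    eq <- ws[seq_len(L - p)] == ws[seq_len(L - p) + p]
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      len <- r$lengths[j] + p
      if (len >= ml)
        hits[[length(hits) + 1]] <- data.frame(s = pos[j], e = pos[j] + len - 1L,
                                               type = "periodic", period = p)
    }
  }
  # palindromes: grow around every center, odd and even
  if (L >= pal_min) {
    for (c2 in seq_len(2L * L - 1L)) {  # c2/2 is the center
      i <- (c2 + 1L) %/% 2L
      j <- c2 %/% 2L + 1L
      while (i >= 1 && j <= L && ws[i] == ws[j]) { i <- i - 1L; j <- j + 1L }
      len <- j - i - 1L
      if (len >= pal_min)
        hits[[length(hits) + 1]] <- data.frame(s = i + 1L, e = j - 1L,
                                               type = "palindrome",
                                               period = NA_integer_)
    }
  }
  if (!length(hits))
    return(data.frame(s = integer(0), e = integer(0), type = character(0),
                      period = integer(0)))
  out <- unique(do.call(rbind, hits))
  out[order(out$s, out$e), , drop = FALSE]
}

# banned patterns completed at position i by letter c; returns list of
# c(start, end, is_palindrome). In pure background, palindromes of length
# 9 and 10 suffice by induction (any longer one grows through them around
# the same center); near a planted tract the induction breaks (the
# tract's own palindromic core is tolerated), so there palindromes are
# checked up to length pal_cap. Mirror structures longer than the cap
# would pair wells separated by the whole tract, whose hybridization is
# negligible for the detector.
.banned_spans_at <- function(ws, i, c, pmax, pal_min, fixed,
                             pal_cap = 41L) {
  spans <- list()
  wsi <- ws
  wsi[i] <- c
  for (p in seq_len(min(pmax, i - 1))) {
    ml <- .ws_min_banned_len(p)
    if (i < ml) next
    if (wsi[i] != wsi[i - p]) next
    j <- seq.int(i - ml + 1, i - p - 1)
    if (length(j) == 0 || all(wsi[j] == wsi[j + p]))
      spans[[length(spans) + 1]] <- c(i - ml + 1L, i, 0L)
  }
  if (i < pal_min) return(spans)
  for (l in seq.int(pal_min, min(i, pal_cap))) {
    a <- i - l + 1L
    if (l > pal_min + 1L && !any(fixed[a:i])) next
    w <- wsi[a:i]
    h <- l %/% 2L
    if (all(w[seq_len(h)] == rev(w[(l - h + 1L):l])))
      spans[[length(spans) + 1]] <- c(a, i, 1L)
  }
  spans
}

# junction rule: patterns fully inside a planted tract are the tract's own
# structure. Periodic patterns may not cross the junction at all (the
# sampler can always break them). Palindromic patterns may involve at most
# two background sites on each side of the tract: the minimal mirrors
# forced by a planted tract (its opposite-class boundary letters and the
# guard zone of homopolymer tracts) stay within two sites, while anything
# wider would make the flanking wells on the two sides degenerate and
# smear the detected region.
.span_banned <- function(span, fixed) {
  idx <- span[1]:span[2]
  f <- fixed[idx]
  if (!any(f)) return(TRUE)
  if (all(f)) return(FALSE)
  if (span[3] == 0L) return(TRUE)
  lo <- min(which(f)); hi <- max(which(f))
  nL <- lo - 1L
  nR <- length(idx) - hi
  interior <- sum(!f[lo:hi])
  nL >= 3L || nR >= 3L || interior >= 1L
}

#' Plant regular tracts in a regularity-free background
#'
#' Generates a promoter of length `L` whose background contains none of the
#' tracts flagged by [ws_scan()] and inserts the given tracts verbatim at
#' their stated positions. Background bases are drawn uniformly within the
#' W/S class chosen by a backtracking sampler; planted tracts are kept
#' fixed and the junctions are constrained so that background letters do
#' not extend a tract's own regularity.
#'
#' @param L promoter length.
#' @param tracts data.frame with columns `seq` (DNA string) and `pos`
#'   (1-based start site), or a list of `list(seq=, pos=)`; may be empty.
#' @param seed integer seed (sampling is fully deterministic given it).
#' @param pmax,pal_min scanner parameters, see [ws_scan()].
#' @param max_steps backtracking budget before giving up.
#' @return list with elements `sequence` (DNA string) and `truth`
#'   (data.frame `seq`, `s`, `e` of the planted tracts).
#' @export
plant_regular <- function(L, tracts = NULL, seed = 0L, pmax = 16,
                          pal_min = 9, max_steps = 500L * L) {
  if (is.null(tracts) || (is.data.frame(tracts) && !nrow(tracts)))
    tracts <- list()
  if (is.data.frame(tracts))
    tracts <- lapply(seq_len(nrow(tracts)),
                     function(i) list(seq = tracts$seq[i], pos = tracts$pos[i]))
  set.seed(seed)
  fixed <- logical(L)
  ws <- character(L)
  base <- character(L)
  truth <- list()
  for (t in tracts) {
    sq <- strsplit(toupper(t$seq), "")[[1]]
    if (t$pos < 1 || t$pos + length(sq) - 1 > L)
      stop("tract does not fit in the promoter: ", t$seq, " at ", t$pos)
    idx <- t$pos:(t$pos + length(sq) - 1)
    if (any(fixed[idx])) stop("planted tracts overlap")
    base[idx] <- sq
    ws[idx] <- strsplit(encode_ws(t$seq), "")[[1]]
    fixed[idx] <- TRUE
    truth[[length(truth) + 1]] <- data.frame(seq = t$seq, s = t$pos,
                                             e = t$pos + length(sq) - 1L)
  }
  # guard zones: background within two sites of a homopolymer tract is
  # forced to the opposite W/S class. Without the guards, a background
  # site of the tract's class at distance two resonates with the tract's
  # modes and smears the detected region boundary.
  forced <- rep(NA_character_, L)
  for (t in tracts) {
    wst <- unique(strsplit(encode_ws(t$seq), "")[[1]])
    if (length(wst) != 1) next
    opp <- if (wst == "W") "S" else "W"
    gz <- c(t$pos - 2L, t$pos - 1L,
            t$pos + nchar(t$seq), t$pos + nchar(t$seq) + 1L)
    gz <- gz[gz >= 1 & gz <= L]
    gz <- gz[!fixed[gz]]
    if (any(!is.na(forced[gz]) & forced[gz] != opp))
      stop("planted tracts too close: conflicting guard zones")
    forced[gz] <- opp
  }
  untried <- vector("list", L)
  backstep <- function(i) {
    w <- which(!fixed[seq_len(i - 1)])
    if (!length(w)) stop("generation infeasible: no background before site ", i)
    max(w)
  }
  ok_at <- function(i, c) {
    for (sp in .banned_spans_at(ws, i, c, pmax, pal_min, fixed))
      if (.span_banned(sp, fixed)) return(FALSE)
    TRUE
  }
  i <- 1L; steps <- 0L; forward <- TRUE
  while (i <= L) {
    steps <- steps + 1L
    if (steps > max_steps)
      stop("background generation failed after ", max_steps, " steps")
    if (fixed[i]) {
      if (!ok_at(i, ws[i])) { i <- backstep(i); forward <- FALSE }
      else { i <- i + 1L; forward <- TRUE }
      next
    }
    if (forward) untried[[i]] <- if (is.na(forced[i])) sample(c("W", "S"))
                                 else forced[i]
    placed <- FALSE
    while (length(untried[[i]])) {
      c <- untried[[i]][1]
      untried[[i]] <- untried[[i]][-1]
      if (ok_at(i, c)) {
        ws[i] <- c
        base[i] <- if (c == "W") sample(c("A", "T"), 1) else sample(c("C", "G"), 1)
        placed <- TRUE
        break
      }
    }
    if (placed) { i <- i + 1L; forward <- TRUE }
    else { i <- backstep(i); forward <- FALSE }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(seq = character(0), s = integer(0), e = integer(0))
  list(sequence = paste(base, collapse = ""), truth = truth)
}

.rand_dna <- function(L, prob = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(prob), L, replace = TRUE, prob = prob), collapse = "")
}

#' Synthetic promoter mixtures with planted class structure
#'
#' The default preset `"human4"` emulates the structure the clustering
#' method assumes, with four equally sized classes:
#' * class A: CG-rich background (`p_C = p_G = 0.35`);
#' * class B: AT-rich background (`p_A = p_T = 0.35`);
#' * classes C and D: uniform background sharing one fixed pseudo-random
#'   element of length `0.6 L` (a transposon surrogate), inserted at a
#'   uniformly random position -- on the forward strand in C, as its
#'   reverse complement in D.
#'
#' @param n number of promoters.
#' @param L promoter length.
#' @param seed integer seed; output is deterministic given it.
#' @param preset only `"human4"` is built in.
#' @param element optional DNA string overriding the pseudo-random shared
#'   element (e.g. a real Alu consensus); must not exceed `L`.
#' @return list with `records` (named character vector) and `truth`
#'   (data.frame: `id`, `class`, `element_start`, `element_end`,
#'   `element_strand`).
#' @export
synth_promoters <- function(n = 120, L = 240, seed = 0L, preset = "human4",
                            element = NULL) {
  preset <- match.arg(preset)
  set.seed(seed)
  comp <- list(A = c(A = 0.15, C = 0.35, G = 0.35, T = 0.15),
               B = c(A = 0.35, C = 0.15, G = 0.15, T = 0.35),
               C = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
               D = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  cls <- rep(c("A", "B", "C", "D"), length.out = n)
  elen <- round(0.6 * L)
  if (is.null(element)) element <- .rand_dna(elen)
  element <- toupper(element)
  if (nchar(element) > L) stop("element longer than promoter length")
  elen <- nchar(element)
  element_rc <- reverse_complement(element)
  ids <- sprintf("synth%03d", seq_len(n))
  recs <- character(n)
  es <- rep(NA_integer_, n); ee <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- strsplit(.rand_dna(L, comp[[cls[i]]]), "")[[1]]
    if (cls[i] %in% c("C", "D")) {
      pos <- sample.int(L - elen + 1L, 1)
      el <- if (cls[i] == "C") element else element_rc
      s[pos:(pos + elen - 1)] <- strsplit(el, "")[[1]]
      es[i] <- pos; ee[i] <- pos + elen - 1L
      strand[i] <- if (cls[i] == "C") "+" else "-"
    }
    recs[i] <- paste(s, collapse = "")
  }
  list(records = stats::setNames(recs, ids),
       truth = data.frame(id = ids, class = cls, element_start = es,
                          element_end = ee, element_strand = strand),
       element = element)
}
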