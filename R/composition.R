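.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

#' Expand a degenerate IUPAC consensus into explicit sequences
#'
#' @param consensus string over the IUPAC nucleotide codes.
#' @return character vector of all matching `{A,C,G,T}` strings; its length
#'   is the product of the per-position code cardinalities.
#' @export
expand_degenerate <- function(consensus) {
  codes <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(codes, names(.IUPAC))
  if (length(bad)) stop("unknown IUPAC code(s): ", paste(bad, collapse = ", "))
  if (!length(codes)) return(character(0))
  sets <- .IUPAC[codes]
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = ""))
}

#' TATA-box catalogue
#'
#' The TATA consensus `HWHWWWWR` expands to 576 8-mers; a user-supplied
#' exclusion list (44 strings that do not fit the structural definition of
#' the interaction with the TATA-binding protein) reduces the search set to
#' 532. The package ships a synthetic placeholder exclusion list (see
#' `system.file("extdata", "tata_exclusions_synthetic.txt", package =
#' "promspec")`) that has the right cardinality but no biological claim;
#' supply your own list for biological fidelity.
#'
#' @param consensus degenerate consensus (default `"HWHWWWWR"`).
#' @param exclusions character vector of excluded 8-mers, or a path to a
#'   file with one per line; `NULL` for none.
#' @param window integer length-2 vector: promoter-relative interval for
#'   the match start, default `c(-40, -19)`.
#' @return list of class `tata_catalog`: `consensus`, `expanded`,
#'   `excluded`, `active` (expanded minus excluded), `window`.
#' @export
tata_catalog <- function(consensus = "HWHWWWWR", exclusions = NULL,
                         window = c(-40L, -19L)) {
  expanded <- expand_degenerate(consensus)
  if (is.character(exclusions) && length(exclusions) == 1 &&
      file.exists(exclusions))
    exclusions <- readLines(exclusions)
  exclusions <- toupper(exclusions %||% character(0))
  exclusions <- exclusions[nzchar(exclusions)]
  stray <- setdiff(exclusions, expanded)
  if (length(stray))
    warning(length(stray), " exclusion(s) are not in the expanded consensus")
  if (window[1] > window[2]) stop("window start must not exceed window end")
  structure(list(consensus = toupper(consensus), expanded = expanded,
                 excluded = exclusions,
                 active = setdiff(expanded, exclusions),
                 window = as.integer(window)),
            class = "tata_catalog")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scan one promoter for the TATA box
#'
#' Exact-match search of the non-excluded consensus 8-mers on the given
#' (top) strand only. A promoter is labelled TATA when at least one match
#' starts inside the search window, TATA-less otherwise.
#'
#' @param seq promoter sequence (one string).
#' @param catalog a [tata_catalog()].
#' @return list: `label` (`"TATA"` or `"TATA-less"`), `positions`
#'   (promoter-relative start coordinates of in-window matches), `matches`
#'   (the matched strings).
#' @export
scan_tata <- function(seq, catalog = tata_catalog()) {
  seq <- toupper(seq)
  L <- nchar(seq)
  k <- nchar(catalog$consensus)
  w <- catalog$window
  starts <- pos_to_site(w[1]:w[2], L)
  starts <- starts[starts >= 1 & starts + k - 1 <= L]
  if (!length(starts))
    stop("search window [", w[1], ", ", w[2], "] lies outside the promoter")
  words <- substring(seq, starts, starts + k - 1)
  hit <- words %in% catalog$active
  list(label = if (any(hit)) "TATA" else "TATA-less",
       positions = site_to_pos(starts[hit], L),
       matches = words[hit])
}

#' TATA labels for a promoter set
#'
#' @param records named character vector.
#' @param catalog a [tata_catalog()].
#' @return data.frame: `id`, `label`, `n_matches`.
#' @export
tata_labels <- function(records, catalog = tata_catalog()) {
  records <- as_promoters(records)
  res <- lapply(records, scan_tata, catalog = catalog)
  data.frame(id = names(records),
             label = vapply(res, `[[`, "", "label"),
             n_matches = vapply(res, function(r) length(r$positions), 0L),
             row.names = NULL)
}

#' Base composition analysis (BCA)
#'
#' Per-position frequency of each nucleotide across a promoter set, with
#' positions aligned at the TSS (promoter-relative coordinates -L..-1,
#' i.e. right-aligned). Sets of unequal lengths are handled over each
#' position's covering promoters.
#'
#' @param records non-empty named character vector.
#' @return data.frame: `position`, `A`, `C`, `G`, `T` (frequencies summing
#'   to 1 at each position), `n` (promoters covering the position).
#' @export
base_composition <- function(records) {
  records <- as_promoters(records)
  if (!length(records)) stop("empty promoter set")
  Ls <- nchar(records)
  Lmax <- max(Ls)
  counts <- matrix(0L, nrow = Lmax, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  cover <- integer(Lmax)
  for (s in records) {
    v <- strsplit(s, "")[[1]]
    L <- length(v)
    rows <- (Lmax - L + 1):Lmax      # right-aligned at the TSS
    keep <- v %in% c("A", "C", "G", "T")
    idx <- cbind(rows[keep], match(v[keep], c("A", "C", "G", "T")))
    counts[idx] <- counts[idx] + 1L
    cover[rows] <- cover[rows] + 1L
  }
  tot <- rowSums(counts)
  freq <- counts / ifelse(tot == 0, 1, tot)
  data.frame(position = (1:Lmax) - Lmax - 1L, freq, n = cover)[tot > 0, ]
}

#' Sliding-window dinucleotide density profiles
#'
#' For each requested 2-mer and promoter-relative position, the density of
#' (overlapping) occurrences whose start falls in a window of width
#' `window_width` centred on the position, divided by the number of 2-mer
#' start positions in the (edge-clipped) window, averaged over promoters.
#'
#' @param records named character vector (equal lengths recommended).
#' @param pairs character vector of 2-mers, e.g. `c("CG", "GC")`.
#' @param window_width window width in nt (>= 2).
#' @return data.frame: `position`, one column per requested pair.
#' @export
dinucleotide_profile <- function(records, pairs, window_width = 51) {
  records <- as_promoters(records)
  if (any(nchar(pairs) != 2)) stop("pairs must be dinucleotides (length 2)")
  if (window_width < 2) stop("window_width must be at least 2")
  L <- max(nchar(records))
  half <- window_width %/% 2
  dens <- matrix(0, nrow = L, ncol = length(pairs),
                 dimnames = list(NULL, pairs))
  for (s in records) {
    v <- nchar(s)
    offset <- L - v
    is_pair <- sapply(pairs, function(p) {
      starts <- substring(s, 1:(v - 1), 2:v) == p
      as.numeric(starts)
    })
    cum <- apply(rbind(0, is_pair), 2, cumsum)  # cum[i+1] = count in starts 1..i
    for (x in 1:v) {
      lo <- max(1, x - half)
      hi <- min(v - 1, x + half)
      if (lo > hi) next
      dens[offset + x, ] <- dens[offset + x, ] +
        (cum[hi + 1, ] - cum[lo, ]) / (hi - lo + 1)
    }
  }
  data.frame(position = (1:L) - L - 1L, dens / length(records),
             check.names = FALSE)
}
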