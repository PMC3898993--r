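#' @importFrom Biostrings readBStringSet writeXStringSet DNAStringSet
#'   reverseComplement
NULL

.DNA_STRICT <- c("A", "C", "G", "T")
.DNA_N <- c("A", "C", "G", "T", "N")

#' Validate a set of promoter sequences
#'
#' Promoters are represented throughout the package as a named character
#' vector of uppercase DNA strings, one element per promoter, given 5'->3'
#' on the annotated gene strand. By convention the last base of each string
#' is the base immediately upstream of the TSS (promoter-relative coordinate
#' -1); the first base of a length-`L` promoter sits at coordinate `-L`.
#'
#' @param x named character vector (or coercible) of DNA sequences.
#' @param allow_n logical; allow the ambiguity code `N` (default `TRUE`).
#' @return the validated, uppercased named character vector.
#' @export
as_promoters <- function(x, allow_n = TRUE) {
  nm <- names(x)
  x <- toupper(as.character(x))  # as.character() drops names; restore them
  names(x) <- nm
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    names(x) <- if (length(x)) paste0("prom", seq_along(x)) else character(0)
  alphabet <- if (allow_n) .DNA_N else .DNA_STRICT
  for (i in seq_along(x)) {
    letters_i <- unique(strsplit(x[[i]], "")[[1]])
    bad <- setdiff(letters_i, alphabet)
    if (length(bad))
      stop("promoter '", names(x)[i], "' contains invalid character(s): ",
           paste(bad, collapse = ", "))
  }
  x
}

#' Read promoter sequences from a FASTA file
#'
#' One record per promoter. Sequences are uppercased on ingest and validated
#' against the `{A,C,G,T,N}` alphabet; any other letter is a parse error that
#' names the offending record.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences (see
#'   [as_promoters()]). An empty file yields an empty vector with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0) {
    warning("FASTA file '", path, "' contains no records")
    return(stats::setNames(character(0), character(0)))
  }
  # first token of the description line is the id, as in most tools
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1)
  as_promoters(stats::setNames(as.character(set), ids))
}

#' Write promoters to a FASTA file
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @export
write_fasta <- function(records, path, width = 70) {
  records <- as_promoters(records)
  set <- DNAStringSet(records)
  writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Bookkeeping manifest for a promoter set
#'
#' @param records named character vector of sequences.
#' @param source optional character scalar recorded per promoter.
#' @return data.frame with columns `id`, `length`, `source`.
#' @export
promoter_manifest <- function(records, source = NA_character_) {
  records <- as_promoters(records)
  data.frame(id = names(records), length = nchar(records),
             source = source, row.names = NULL)
}

#' Handle promoters containing ambiguity codes
#'
#' The detection pipeline requires fully resolved sequences. Promoters
#' containing `N` are either dropped (with a warning listing them) or have
#' every `N` replaced by a uniformly random base under a stated seed.
#'
#' @param records named character vector.
#' @param action `"drop"` (default) or `"mask"`.
#' @param seed integer seed used when `action = "mask"`.
#' @return the filtered or masked set.
#' @export
resolve_n <- function(records, action = c("drop", "mask"), seed = 0L) {
  records <- as_promoters(records)
  action <- match.arg(action)
  has_n <- grepl("N", records, fixed = TRUE)
  if (!any(has_n)) return(records)
  if (action == "drop") {
    warning("dropping ", sum(has_n), " promoter(s) containing N: ",
            paste(names(records)[has_n], collapse = ", "))
    return(records[!has_n])
  }
  set.seed(seed)
  records[has_n] <- vapply(records[has_n], function(s) {
    v <- strsplit(s, "")[[1]]
    idx <- v == "N"
    v[idx] <- sample(.DNA_STRICT, sum(idx), replace = TRUE)
    paste(v, collapse = "")
  }, "", USE.NAMES = FALSE)
  records
}

#' Encode a DNA sequence in the weak/strong binary alphabet
#'
#' A and T (two hydrogen bonds) map to `W`; C and G (three hydrogen bonds)
#' map to `S`. The encoding commutes with reverse complementation up to
#' string reversal, since complementary bases share their W/S class.
#'
#' @param seq DNA string over `{A,C,G,T}`; `N` is rejected (resolve it
#'   first, see [resolve_n()]).
#' @return string of the same length over `{W,S}`.
#' @export
encode_ws <- function(seq) {
  seq <- toupper(seq)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), .DNA_STRICT)
  if (length(bad))
    stop("encode_ws: sequence contains non-ACGT character(s): ",
         paste(bad, collapse = ", "))
  chartr("ATCG", "WWSS", seq)
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @return the Watson-Crick reverse complement (an involution).
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), .DNA_N)
  if (length(bad))
    stop("reverse_complement: invalid character(s): ",
         paste(bad, collapse = ", "))
  if (nchar(seq) == 0) return(seq)
  as.character(reverseComplement(DNAStringSet(seq)))
}

#' Convert between chain sites and promoter-relative coordinates
#'
#' Internally, sites of a length-`L` promoter are indexed `n = 1..L` in the
#' 5'->3' direction. The promoter-relative coordinate of site `n` is
#' `x = n - L - 1`, so the base immediately upstream of the TSS (the last
#' character) is `x = -1` and the first is `x = -L`.
#'
#' @param n chain site index (1-based).
#' @param x promoter-relative coordinate (negative).
#' @param L promoter length.
#' @return the converted coordinate vector.
#' @export
site_to_pos <- function(n, L) n - L - 1L

#' @rdname site_to_pos
#' @export
pos_to_site <- function(x, L) x + L + 1L
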