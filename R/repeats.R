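#' Parse a RepeatMasker annotation file
#'
#' Reads the whitespace-table `.out` dialect (two header lines and a blank
#' line, then one row per repeat hit) into promoter-local intervals. The
#' query name column is taken as the promoter id and the repeat
#' class/family column as the family. Coordinates are 1-based inclusive,
#' as printed by RepeatMasker.
#'
#' @param path path to a RepeatMasker `.out` file.
#' @return data.frame with columns `promoter_id`, `start`, `end`, `family`,
#'   `strand` (`+` or `-`; RepeatMasker's `C` is mapped to `-`), `name`.
#' @export
read_repeatmasker <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  # drop the standard 3-line header (two header rows + blank), tolerantly
  body <- grep("^\\s*[0-9]", lines, value = TRUE)
  if (!length(body))
    return(data.frame(promoter_id = character(0), start = integer(0),
                      end = integer(0), family = character(0),
                      strand = character(0), name = character(0)))
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(fields, length, 0L) < 11)
  if (length(bad))
    stop("unrecognized RepeatMasker line: ", body[bad[1]])
  get <- function(i) vapply(fields, `[[`, "", i)
  start <- suppressWarnings(as.integer(get(6)))
  end <- suppressWarnings(as.integer(get(7)))
  if (anyNA(start) || anyNA(end))
    stop("unrecognized RepeatMasker line: ",
         body[which(is.na(start) | is.na(end))[1]])
  data.frame(promoter_id = get(5), start = start, end = end,
             family = get(11),
             strand = ifelse(get(9) == "C", "-", "+"),
             name = get(10))
}

#' Read repeat intervals from a BED file
#'
#' BED's 0-based half-open coordinates are converted to the package's
#' 1-based inclusive convention. Column 4, when present, is the family.
#'
#' @param path path to a BED file (3+ columns, tab- or space-separated).
#' @return data.frame as in [read_repeatmasker()].
#' @export
read_repeat_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(promoter_id = character(0), start = integer(0),
                      end = integer(0), family = character(0),
                      strand = character(0), name = character(0)))
  fields <- strsplit(trimws(lines), "\\s+")
  if (any(vapply(fields, length, 0L) < 3))
    stop("BED line with fewer than 3 fields: ",
         lines[which(vapply(fields, length, 0L) < 3)[1]])
  get <- function(i, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, "")
  start0 <- suppressWarnings(as.integer(get(2)))
  end0 <- suppressWarnings(as.integer(get(3)))
  if (anyNA(start0) || anyNA(end0))
    stop("non-numeric BED coordinates: ",
         lines[which(is.na(start0) | is.na(end0))[1]])
  fam <- get(4)
  strand <- get(6)
  data.frame(promoter_id = get(1), start = start0 + 1L, end = end0,
             family = ifelse(is.na(fam), "unknown", fam),
             strand = ifelse(strand %in% c("+", "-"), strand, "+"),
             name = ifelse(is.na(fam), "unknown", fam))
}

.check_intervals <- function(intervals, records) {
  Ls <- nchar(records)
  known <- intervals$promoter_id %in% names(records)
  iv <- intervals[known, , drop = FALSE]
  over <- iv$end > Ls[iv$promoter_id] | iv$start < 1
  if (any(over))
    stop("repeat interval outside promoter: ",
         iv$promoter_id[which(over)[1]], ":", iv$start[which(over)[1]], "-",
         iv$end[which(over)[1]])
  iv
}

#' Transposon coverage of a promoter cluster
#'
#' Total percentage of cluster nucleotides covered by annotated repeats
#' (per-promoter union of intervals, so overlaps count once) and the
#' percentage covered by each repeat family (union within family; families
#' may overlap each other, so family percentages can exceed the total when
#' summed). Repeat strand is ignored: coverage is positional.
#'
#' @param intervals data.frame of repeat intervals (see
#'   [read_repeatmasker()]).
#' @param records named character vector: the cluster promoters.
#' @return list: `total_pct` (scalar, in percent), `family_pct` (named
#'   vector, percent per family), `total_nt` (cluster size in nt).
#' @export
repeat_coverage <- function(intervals, records) {
  records <- as_promoters(records)
  iv <- .check_intervals(intervals, records)
  total_nt <- sum(nchar(records))
  union_len <- function(df) {
    if (!nrow(df)) return(0L)
    sum(vapply(split(df, df$promoter_id), function(d)
      sum(IRanges::width(IRanges::reduce(IRanges::IRanges(d$start, d$end)))),
      0L))
  }
  fam_pct <- vapply(split(iv, iv$family), function(d)
    100 * union_len(d) / total_nt, numeric(1))
  list(total_pct = 100 * union_len(iv) / total_nt,
       family_pct = fam_pct[order(-fam_pct)],
       total_nt = total_nt)
}

#' Which motif occurrences fall inside a repeat?
#'
#' @param occurrences data.frame with `promoter_id`, `start`, `end`
#'   (1-based inclusive).
#' @param intervals repeat intervals (same conventions).
#' @param rule `"contained"` (default: the full occurrence must lie within
#'   a single repeat interval) or `"any_overlap"`.
#' @return logical vector along `occurrences`; `fraction_in_repeat()` gives
#'   the summary fraction (`NA` when `intervals` is `NULL` -- missing
#'   annotation is not the same as "never in a repeat").
#' @export
occurrences_in_repeats <- function(occurrences, intervals,
                                   rule = c("contained", "any_overlap")) {
  rule <- match.arg(rule)
  if (!nrow(occurrences)) return(logical(0))
  vapply(seq_len(nrow(occurrences)), function(i) {
    o <- occurrences[i, ]
    iv <- intervals[intervals$promoter_id == o$promoter_id, , drop = FALSE]
    if (!nrow(iv)) return(FALSE)
    if (rule == "contained") any(iv$start <= o$start & iv$end >= o$end)
    else any(iv$start <= o$end & iv$end >= o$start)
  }, logical(1))
}

#' @rdname occurrences_in_repeats
#' @export
fraction_in_repeat <- function(occurrences, intervals,
                               rule = c("contained", "any_overlap")) {
  if (is.null(intervals)) return(NA_real_)
  if (!nrow(occurrences)) return(NA_real_)
  mean(occurrences_in_repeats(occurrences, intervals, rule))
}
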