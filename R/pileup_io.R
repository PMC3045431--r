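# Parsing strand-aware base counts from samtools-style text pileup and
# masking primer-covered positions.

count_char <- function(s, ch) {
  nchar(s) - nchar(gsub(ch, "", s, fixed = TRUE))
}

# remove "+n<bases>"/"-n<bases>" indel records from read-base strings
strip_indels <- function(s, line_no) {
  repeat {
    m <- regexpr("[+-][0-9]+", s)
    if (m == -1L) return(s)
    start <- as.integer(m)
    len <- attr(m, "match.length")
    nb <- as.integer(substr(s, start + 1L, start + len - 1L))
    last <- start + len - 1L + nb
    if (is.na(nb) || last > nchar(s))
      stop_ps("pileup line %d: malformed indel record", line_no)
    s <- paste0(substr(s, 1L, start - 1L), substr(s, last + 1L, nchar(s)))
  }
}

#' Parse a samtools-style text pileup into strand-resolved base counts
#'
#' Decodes the read-base string of each pileup line: `.`/`,` are
#' forward/reverse reference matches, uppercase `A/C/G/T` forward
#' alternate reads, lowercase reverse; `^` consumes the following
#' mapping-quality character, `$` is consumed, `+n`/`-n` indel records
#' and their `n` bases are consumed and ignored, and `*`/`N`/`n` count
#' toward the printed depth but enter no base count. Reference matches
#' are tallied under the reference base. A decoded symbol total that
#' disagrees with the printed depth column is a parse error naming the
#' line.
#'
#' @param input path to a pileup file, or a character vector of pileup
#'   lines (chrom, 1-based pos, ref, depth, bases; any further columns
#'   such as base qualities are ignored).
#' @return data.frame with one row per position: `chrom`, `pos`, `ref`,
#'   `depth` (printed), `depth_fwd`/`depth_rev` (A/C/G/T reads per
#'   strand), and the eight per-strand base counts `A_fwd` ... `T_rev`.
#' @export
parse_pileup <- function(input) {
  lines <- if (length(input) == 1L && !grepl("\t", input) && file.exists(input))
    readLines(input) else input
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      depth = integer(), depth_fwd = integer(),
                      depth_rev = integer(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L))
    stop_ps("pileup line %d: expected at least 5 tab-separated fields, got %d",
            which(nf < 5L)[1L], nf[which(nf < 5L)[1L]])
  chrom <- vapply(fields, `[[`, character(1), 1L)
  pos <- as.integer(vapply(fields, `[[`, character(1), 2L))
  ref <- toupper(vapply(fields, `[[`, character(1), 3L))
  depth <- as.integer(vapply(fields, `[[`, character(1), 4L))
  bases <- vapply(fields, `[[`, character(1), 5L)
  if (anyNA(pos) || anyNA(depth))
    stop_ps("pileup line %d: non-numeric position or depth",
            which(is.na(pos) | is.na(depth))[1L])
  bad_ref <- !ref %in% c(BASES, "N")
  if (any(bad_ref))
    stop_ps("pileup line %d: reference base '%s' not in A/C/G/T/N",
            which(bad_ref)[1L], ref[which(bad_ref)[1L]])

  s <- gsub("\\^.", "", bases, perl = TRUE)  # read-start marker + mapping quality
  s <- gsub("$", "", s, fixed = TRUE)      # read-end marker
  has_indel <- grepl("[+-]", s)
  if (any(has_indel)) {
    idx <- which(has_indel)
    s[idx] <- mapply(strip_indels, s[idx], idx, USE.NAMES = FALSE)
  }

  out <- data.frame(chrom = chrom, pos = pos, ref = ref, depth = depth,
                    stringsAsFactors = FALSE)
  fwd_ref <- count_char(s, ".")
  rev_ref <- count_char(s, ",")
  for (b in BASES) {
    out[[paste0(b, "_fwd")]] <- as.integer(
      count_char(s, b) + ifelse(ref == b, fwd_ref, 0L))
    out[[paste0(b, "_rev")]] <- as.integer(
      count_char(s, tolower(b)) + ifelse(ref == b, rev_ref, 0L))
  }
  other <- count_char(s, "*") + count_char(s, "N") + count_char(s, "n")
  decoded <- fwd_ref + rev_ref + other +
    Reduce(`+`, lapply(c(BASES, tolower(BASES)), function(b) count_char(s, b)))
  bad <- decoded != depth
  if (any(bad))
    stop_ps("pileup line %d: decoded %d base symbols but depth column says %d",
            which(bad)[1L], decoded[which(bad)[1L]], depth[which(bad)[1L]])
  out$depth_fwd <- as.integer(rowSums(as.matrix(out[paste0(BASES, "_fwd")])))
  out$depth_rev <- as.integer(rowSums(as.matrix(out[paste0(BASES, "_rev")])))
  # N-reference positions keep their ./, tallies out of the base counts
  nref <- ref == "N"
  if (any(nref)) {
    out$depth_fwd[nref] <- out$depth_fwd[nref] + fwd_ref[nref]
    out$depth_rev[nref] <- out$depth_rev[nref] + rev_ref[nref]
  }
  out
}

#' Read an amplicon/primer interval file
#'
#' BED-like TSV with columns chrom, start, end, fwd_primer_len,
#' rev_primer_len; starts are 0-based half-open on disk (BED convention)
#' and converted to the package's 1-based half-open convention.
#'
#' @param path TSV path (header optional; detected).
#' @return data.frame with 1-based `start`, exclusive `end`, and the two
#'   primer lengths.
#' @export
read_amplicons <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("start|chrom", first, ignore.case = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header)
    names(df)[1:5] <- c("chrom", "start", "end", "fwd_primer_len",
                        "rev_primer_len")
  df$start <- as.integer(df$start) + 1L
  df$end <- as.integer(df$end) + 1L
  if (any(df$start >= df$end)) stop_ps("amplicon start must precede end")
  if (any(df$fwd_primer_len < 0 | df$rev_primer_len < 0))
    stop_ps("primer lengths must be non-negative")
  df
}

primer_positions <- function(amplicons) {
  unlist(lapply(seq_len(nrow(amplicons)), function(i) {
    a <- amplicons[i, ]
    fp <- if (a$fwd_primer_len > 0) a$start:(a$start + a$fwd_primer_len - 1L)
          else integer()
    rp <- if (a$rev_primer_len > 0) (a$end - a$rev_primer_len):(a$end - 1L)
          else integer()
    c(fp, rp)
  }))
}

#' Remove primer-covered positions from parsed pileup columns
#'
#' A position covered by the primer of any amplicon is excluded, even if
#' it lies in the interior of another, overlapping amplicon (primer-hit
#' bases reflect primer sequence, not template, so the conservative
#' tie-break discards them). Intervals are 1-based half-open.
#'
#' @param columns data.frame from [parse_pileup()].
#' @param amplicons data.frame of amplicon intervals with primer lengths
#'   (1-based, e.g. from [read_amplicons()] or [default_amplicons()]);
#'   NULL leaves the columns untouched.
#' @return the filtered columns.
#' @export
mask_primers <- function(columns, amplicons = NULL) {
  if (is.null(amplicons) || !nrow(amplicons)) return(columns)
  drop <- primer_positions(amplicons)
  keep <- !(columns$pos %in% drop)
  columns[keep, , drop = FALSE]
}
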