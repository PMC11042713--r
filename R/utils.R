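#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# IUPAC nucleotide code -> set of concrete bases it matches
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

is_iupac <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  all(chars %in% names(IUPAC_MAP))
}

#' Round half away from zero
#'
#' Integer rounding convention used for all printed percentages (e.g.
#' 121/662 -> 18). Base `round()` rounds half to even, which disagrees with
#' the convention at exact halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a total, rounded to whole percent
#' @param n numerator count(s).
#' @param total denominator.
#' @return integer percentages; `NA` when `total` is 0.
#' @export
pct_of <- function(n, total) {
  if (length(total) == 1 && total == 0) return(rep(NA_real_, length(n)))
  round_half_up(100 * n / total)
}

# ---- Phred helpers ---------------------------------------------------------

#' Convert Phred+33 quality strings to integer scores
#' @param qual character vector of Sanger-encoded quality strings.
#' @return list of integer vectors.
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) return(integer(0))
    utf8ToInt(q) - 33L
  })
}

#' Convert integer Phred scores to a Phred+33 string
#' @param q integer vector of quality scores (0-60).
#' @return single character string.
#' @export
int_to_phred <- function(q) {
  if (length(q) == 0) return("")
  intToUtf8(as.integer(q) + 33L)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# ---- month-day windows -----------------------------------------------------
# Windows are "MM-DD:MM-DD" strings, possibly several separated by ";".
# They are year-agnostic and may wrap the year end (e.g. "11-01:03-31").

parse_md <- function(x) {
  m <- as.integer(substr(x, 1, 2))
  d <- as.integer(substr(x, 4, 5))
  if (any(is.na(m)) || any(is.na(d)) || any(m < 1 | m > 12) || any(d < 1 | d > 31)) {
    abort(paste0("invalid month-day token: ", x))
  }
  m * 100L + d
}

#' Parse a month-day window specification
#'
#' @param spec string like `"11-01:03-31"` or `"04-10:06-15;09-01:09-30"`;
#'   `NA` or `""` yields an empty window set.
#' @return data frame with integer `from`/`to` columns (MMDD encoding).
#' @export
parse_md_windows <- function(spec) {
  if (is.null(spec) || length(spec) == 0 || is.na(spec) || !nzchar(trimws(spec))) {
    return(data.frame(from = integer(0), to = integer(0)))
  }
  parts <- strsplit(trimws(spec), ";", fixed = TRUE)[[1]]
  out <- lapply(parts, function(p) {
    ft <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
    if (length(ft) != 2) abort(paste0("window must be 'MM-DD:MM-DD': ", p))
    data.frame(from = parse_md(ft[1]), to = parse_md(ft[2]))
  })
  do.call(rbind, out)
}

md_of_date <- function(date) {
  date <- as.Date(date)
  as.integer(format(date, "%m")) * 100L + as.integer(format(date, "%d"))
}

#' Is a date inside a (possibly wrapping) month-day window set?
#'
#' @param date a Date (or coercible); only month and day are used.
#' @param windows data frame from [parse_md_windows()], or the spec string.
#' @return logical; `FALSE` for an empty window set, `NA` for `NA` dates.
#' @export
in_md_window <- function(date, windows) {
  if (is.character(windows) || (length(windows) == 1 && is.na(windows))) {
    windows <- parse_md_windows(windows)
  }
  if (nrow(windows) == 0) return(rep(FALSE, length(date)))
  md <- md_of_date(date)
  hit <- rep(FALSE, length(md))
  for (i in seq_len(nrow(windows))) {
    f <- windows$from[i]; t <- windows$to[i]
    hit <- hit | if (f <= t) md >= f & md <= t else md >= f | md <= t
  }
  hit[is.na(md)] <- NA
  hit
}

# dates (Date vector) lying inside a md window, given candidate dates
dates_in_window <- function(dates, window_spec) {
  keep <- in_md_window(dates, window_spec)
  dates[!is.na(keep) & keep]
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
}

# mutate a sequence: each site substituted with probability `rate` to one of
# the three other bases (uniform). Gap ('-') and N sites are left untouched.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  eligible <- chars %in% c("A", "C", "G", "T")
  hit <- eligible & stats::runif(length(chars)) < rate
  if (any(hit)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    k <- sample.int(3, sum(hit), replace = TRUE)
    chars[hit] <- substring(alt[chars[hit]], k, k)
  }
  paste(chars, collapse = "")
}
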