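# Line-level diff counts, the classical LCS model (what Unix diff reports).
# Production path is Myers' O(ND) greedy algorithm; the test suite checks it
# against an independent quadratic LCS dynamic program.

#' Count inserted and deleted lines between two texts
#'
#' Computes the insert/delete counts of a longest-common-subsequence line
#' alignment, i.e. the numbers Unix `diff` would report.
#'
#' @param text_a,text_b Character scalars (newline-separated) or character
#'   vectors of lines.
#' @return Named integer vector `c(line_inserts, line_deletes)`.
#' @export
line_diff <- function(text_a, text_b) {
  a <- split_lines(text_a)
  b <- split_lines(text_b)
  n <- length(a); m <- length(b)
  # map to integers once; comparisons in the inner loop are integer ==
  codes <- match(c(a, b), unique(c(a, b)))
  av <- codes[seq_len(n)]
  bv <- if (m) codes[n + seq_len(m)] else integer(0)
  d <- myers_distance(av, bv)
  lcs <- (n + m - d) / 2
  c(line_inserts = as.integer(m - lcs), line_deletes = as.integer(n - lcs))
}

split_lines <- function(x) {
  if (!length(x)) return(character(0))
  if (length(x) == 1L) {
    x <- sub("\n$", "", x)
    if (!nzchar(x)) return(character(0))
    return(strsplit(x, "\n", fixed = TRUE)[[1]])
  }
  as.character(x)
}

# Myers (1986) shortest-edit-script length over integer sequences.
myers_distance <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  max_d <- n + m
  offset <- max_d + 1L
  v <- integer(2L * max_d + 3L)  # v[k + offset + 1] = furthest x on diagonal k
  for (d in 0:max_d) {
    for (k in seq(-d, d, by = 2L)) {
      ki <- k + offset + 1L
      x <- if (k == -d || (k != d && v[ki - 1L] < v[ki + 1L])) v[ki + 1L]
           else v[ki - 1L] + 1L
      y <- x - k
      while (x < n && y < m && a[x + 1L] == b[y + 1L]) { x <- x + 1L; y <- y + 1L }
      v[ki] <- x
      if (x >= n && y >= m) return(d)
    }
  }
  max_d
}
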