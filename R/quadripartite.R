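# Raw-byte complement table: A<->T, C<->G; N (and anything else) maps to 0x00
# so it can never equal a base byte -> N never matches.
.comp_raw_table <- local({
  tb <- as.raw(rep(0L, 256L))
  for (p in list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C")))
    tb[as.integer(charToRaw(p[1L])) + 1L] <- charToRaw(p[2L])
  tb
})

.circ_substr <- function(seq, start, len) {
  # start 0-based on a circular sequence
  n <- nchar(seq)
  start <- start %% n
  if (start + len <= n) return(substring(seq, start + 1L, start + len))
  paste0(substring(seq, start + 1L, n), substring(seq, 1L, start + len - n))
}

#' Detect the large inverted repeat and partition the plastome
#'
#' Finds the maximal pair of disjoint, exactly reverse-complementary
#' intervals on the circular sequence (seeding on 21-mers shared with the
#' reverse complement, then maximal exact extension) and derives the
#' quadripartite partition: the longer single-copy region is the LSC, the
#' shorter the SSC, and walking the circle in sequence orientation gives
#' LSC, IRb, SSC, IRa. Circularity is handled by searching on the doubled
#' sequence; candidate matches longer than the genome are discarded.
#'
#' @param record A [plastome_record()] (or plain DNA string).
#' @param min_len Minimum IR length to report, bp (default 1000, floor 100).
#' @return A `quadripartite_partition` — list with `ir_length`, `total`, and
#'   `lsc`, `irb`, `ssc`, `ira` regions, each `c(start, length)` with
#'   0-based circular start — or `NULL` when no reverse-complement pair of
#'   at least `min_len` exists.
#' @export
find_inverted_repeat <- function(record, min_len = 1000L) {
  seq <- if (inherits(record, "plastome_record")) record$sequence else .check_dna(record)
  n <- nchar(seq)
  min_len <- as.integer(min_len)
  if (min_len < 100L) stop("min_len must be >= 100")
  if (n < 2L * min_len)
    stop("sequence (", n, " bp) shorter than 2*min_len (", 2L * min_len, ")")

  k <- 21L
  doubled <- paste0(seq, seq)
  a <- charToRaw(doubled)
  dd <- Biostrings::DNAString(doubled)
  stride <- max(1L, min_len %/% 2L)
  seed_starts <- seq.int(0L, 2L * n - k, by = stride)

  best <- NULL
  seen <- character(0)
  # extensions already performed, indexed by anti-diagonal (p + q + len - k
  # is constant for every seed inside one maximal inverted match)
  done_anti <- integer(0); done_p <- integer(0); done_len <- integer(0)
  for (i0 in seed_starts) {
    kmer <- substring(doubled, i0 + 1L, i0 + k)
    if (grepl("N", kmer, fixed = TRUE)) next
    rc <- .revcomp(kmer)
    hits <- Biostrings::matchPattern(rc, dd)
    for (j0 in BiocGenerics::start(hits) - 1L) {
      if (any(done_anti == i0 + j0 & i0 >= done_p &
              i0 <= done_p + done_len - k)) next
      ext <- .ir_extend(a, i0, j0, k, 2L * n)
      done_anti <- c(done_anti, ext$p + ext$q + ext$len - k)
      done_p <- c(done_p, ext$p)
      done_len <- c(done_len, ext$len)
      p <- ext$p; q <- ext$q; L <- ext$len
      if (L < min_len || L > n) next
      # canonical representation mod n, first copy = smaller start
      c1 <- p %% n; c2 <- q %% n
      if (c1 > c2) { tmp <- c1; c1 <- c2; c2 <- tmp }
      key <- paste(c1, c2, L)
      if (key %in% seen) next
      seen <- c(seen, key)
      if (!.circ_disjoint(c1, c2, L, n)) next
      if (is.null(best) || L > best$len ||
          (L == best$len && c1 < best$c1)) {
        best <- list(len = L, c1 = c1, c2 = c2)
      }
    }
  }
  if (is.null(best)) return(NULL)
  .build_partition(seq, best$c1, best$c2, best$len)
}

# maximal exact inverted extension on the doubled sequence raw vector:
# invariant a[p+d] == comp(a[q + len - 1 - d]).
.ir_extend <- function(a, i0, j0, k, N) {
  comp <- .comp_raw_table
  p <- i0; q <- j0; len <- k
  # grow left end of forward copy / right end of rc copy
  while (p > 0L && q + len < N &&
         a[p] == comp[as.integer(a[q + len + 1L]) + 1L]) {
    p <- p - 1L; len <- len + 1L
  }
  # grow right end of forward copy / left end of rc copy
  while (q > 0L && p + len < N &&
         a[p + len + 1L] == comp[as.integer(a[q]) + 1L]) {
    q <- q - 1L; len <- len + 1L
  }
  list(p = p, q = q, len = len)
}

.circ_disjoint <- function(s1, s2, len, n) {
  cov <- function(s) ((s + seq_len(len) - 1L) %% n)
  !any(duplicated(c(cov(s1), cov(s2))))
}

.build_partition <- function(seq, s1, s2, len) {
  n <- nchar(seq)
  e1 <- (s1 + len) %% n
  e2 <- (s2 + len) %% n
  gap1 <- (s2 - e1) %% n   # single-copy region following copy 1
  gap2 <- (s1 - e2) %% n   # single-copy region following copy 2
  if (gap1 >= gap2) {
    lsc <- c(e1, gap1); irb <- c(s2, len); ssc <- c(e2, gap2); ira <- c(s1, len)
  } else {
    lsc <- c(e2, gap2); irb <- c(s1, len); ssc <- c(e1, gap1); ira <- c(s2, len)
  }
  stopifnot(2L * len + lsc[2L] + ssc[2L] == n)
  part <- structure(list(ir_length = len, total = n, lsc = lsc, irb = irb,
                         ssc = ssc, ira = ira),
                    class = "quadripartite_partition")
  ira_seq <- .circ_substr(seq, ira[1L], len)
  irb_seq <- .circ_substr(seq, irb[1L], len)
  if (!identical(ira_seq, .revcomp(irb_seq)))
    stop("internal error: detected IR copies are not reverse-complementary")
  part
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  cat(sprintf("<quadripartite_partition> total %s bp = LSC %s + IR %s x2 + SSC %s\n",
              format(x$total, big.mark = ","),
              format(x$lsc[2L], big.mark = ","),
              format(x$ir_length, big.mark = ","),
              format(x$ssc[2L], big.mark = ",")))
  invisible(x)
}

#' Quadripartite size accounting
#'
#' Total plastome length from its components: `2 * ir + ssc + lsc`.
#'
#' @param ir Length of one inverted-repeat copy, bp.
#' @param ssc Small single-copy region length, bp.
#' @param lsc Large single-copy region length, bp.
#' @return Total genome length in bp.
#' @examples
#' quadripartite_accounting(25190, 19208, 87049)  # 156637
#' @export
quadripartite_accounting <- function(ir, ssc, lsc) {
  vals <- c(ir = ir, ssc = ssc, lsc = lsc)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all component lengths must be non-negative")
  2 * ir + ssc + lsc
}

#' Partition a record into quadripartite region sequences
#'
#' @param record A [plastome_record()].
#' @param partition A `quadripartite_partition` from [find_inverted_repeat()].
#' @return Named list of DNA strings `lsc`, `irb`, `ssc`, `ira`.
#' @export
partition_sequences <- function(record, partition) {
  seq <- record$sequence
  if (nchar(seq) != partition$total)
    stop("partition does not belong to this record (length mismatch)")
  lapply(partition[c("lsc", "irb", "ssc", "ira")],
         function(r) .circ_substr(seq, r[1L], r[2L]))
}
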