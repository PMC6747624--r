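# Independent brute-force oracles and small fixture builders. These are
# deliberately naive (enumeration / dynamic programming) and share no code
# with the package implementations they check.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Longest pair of disjoint, exactly reverse-complementary intervals in a
# linear sequence, by O(n^2) longest-common-substring DP between the
# sequence and its reverse complement.
oracle_longest_ir <- function(seq) {
  a <- strsplit(seq, "")[[1L]]
  b <- strsplit(revcomp_chr(seq), "")[[1L]]
  n <- length(a)
  best <- 0L
  prev <- integer(n)
  for (i in seq_len(n)) {
    cur <- integer(n)
    hit <- which(b == a[i])
    cur[hit] <- prev[pmax(hit - 1L, 1L)] + 1L
    if (length(hit) && any(hit == 1L)) cur[1L] <- if (b[1L] == a[i]) 1L else 0L
    for (j in which(cur > best)) {
      L <- cur[j]
      # interval in seq for the forward copy: [i-L, i) 0-based
      # match ends at b-index j -> seq interval [n-j, n-j+L)
      s1 <- i - L; s2 <- n - j
      if (s1 + L <= s2 || s2 + L <= s1) best <- L
    }
    prev <- cur
  }
  best
}

# Exhaustive perfect-tandem oracle: tests every (start, unit-length) pair by
# direct unit-by-unit substring comparison.
oracle_tandem <- function(seq, min_total = 20L, min_copies = 2L,
                          unit_min = 2L, unit_max = 40L) {
  n <- nchar(seq)
  least_rot <- function(s) {
    k <- nchar(s)
    sort(vapply(seq_len(k) - 1L, function(r)
      paste0(substring(s, r + 1L, k), substring(s, 1L, r)), ""))[1L]
  }
  rows <- list()
  for (u in unit_min:min(unit_max, n %/% 2L)) {
    s <- 1L
    while (s + 2L * u - 1L <= n) {
      unit <- substring(seq, s, s + u - 1L)
      if (grepl("N", unit, fixed = TRUE)) { s <- s + 1L; next }
      copies <- 1L
      while (s + (copies + 1L) * u - 1L <= n &&
             substring(seq, s + copies * u, s + (copies + 1L) * u - 1L) == unit)
        copies <- copies + 1L
      if (copies < 2L) { s <- s + 1L; next }
      # left-maximality at this period
      if (s > 1L) {
        prev <- substring(seq, s - 1L, s - 1L)
        if (prev != "N" && prev == substring(seq, s - 1L + u, s - 1L + u)) {
          s <- s + 1L; next
        }
      }
      # partial terminal copy
      t <- 0L
      while (s + copies * u + t <= n && t < u - 1L) {
        cc <- substring(seq, s + copies * u + t, s + copies * u + t)
        if (cc == "N" || cc != substring(unit, t + 1L, t + 1L)) break
        t <- t + 1L
      }
      span <- copies * u + t
      region <- substring(seq, s, s + span - 1L)
      primitive <- TRUE
      for (d in seq_len(u - 1L)) {
        if (u %% d == 0L &&
            substring(region, 1L, span - d) == substring(region, d + 1L, span)) {
          primitive <- FALSE; break
        }
      }
      if (primitive && span >= min_total && copies >= min_copies) {
        rows[[length(rows) + 1L]] <-
          data.frame(start = s - 1L, end = s - 1L + span, unit_length = u,
                     unit = least_rot(unit), copies = copies, span = span,
                     stringsAsFactors = FALSE)
      }
      s <- s + 1L
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      unit_length = integer(0), unit = character(0),
                      copies = integer(0), span = integer(0),
                      stringsAsFactors = FALSE))
  tb <- do.call(rbind, rows)
  tb <- tb[order(tb$unit_length, tb$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(tb))
  for (x in seq_len(nrow(tb))) {
    if (!keep[x]) next
    prior <- which(keep & seq_len(nrow(tb)) < x)
    if (any(tb$unit_length[prior] < tb$unit_length[x] &
            tb$start[prior] <= tb$start[x] & tb$end[prior] >= tb$end[x]))
      keep[x] <- FALSE
  }
  tb <- tb[keep, , drop = FALSE]
  tb <- tb[order(tb$start, tb$unit_length), , drop = FALSE]
  rownames(tb) <- NULL
  tb
}

# All maximal exact common substrings of length >= min_len between two
# positions of the same sequence (forward strand), by O(n^2) DP. Used to
# check that the seed-and-extend search misses no long exact repeat.
oracle_exact_repeats <- function(seq, min_len) {
  a <- strsplit(seq, "")[[1L]]
  n <- length(a)
  out <- list()
  for (d in seq_len(n - 1L)) {            # diagonal offset j - i = d
    len <- n - d
    eq <- a[seq_len(len)] == a[(d + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (x in which(r$values & r$lengths >= min_len)) {
      st <- ends[x] - r$lengths[x]        # 0-based start on diagonal
      out[[length(out) + 1L]] <-
        data.frame(i = st, j = st + d, len = r$lengths[x])
    }
  }
  if (!length(out)) return(data.frame(i = integer(0), j = integer(0),
                                      len = integer(0)))
  do.call(rbind, out)
}

# Autocorrelation period scan for peptide repeats: the primitive period of
# a (possibly degenerate) repeat region is the smallest lag at which
# positional self-agreement clears the membership threshold.
oracle_peptide_period <- function(region, max_u = 50L, min_identity = 0.7) {
  ch <- strsplit(region, "")[[1L]]
  n <- length(ch)
  lags <- 3L:min(max_u, n - 1L)
  scores <- vapply(lags, function(u)
    mean(ch[seq_len(n - u)] == ch[(u + 1L):n]), 0)
  lags[scores >= min_identity][1L]
}

# Small annotated record: one plus-strand and one minus-strand CDS over a
# random background, with every codon interior chosen non-stop.
tiny_record <- function(seed = 1L) {
  set.seed(seed)
  nonstop <- setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                           paste0), c("A","C","G","T"), paste0)),
                     c("TAA", "TAG", "TGA"))
  mk_cds <- function(ncod) paste(c("ATG", sample(nonstop, ncod - 2L, TRUE), "TAA"),
                                 collapse = "")
  up <- rand_dna(120)
  cds1 <- mk_cds(60)
  mid <- rand_dna(90)
  cds2 <- mk_cds(40)
  dn <- rand_dna(100)
  seqs <- paste0(up, cds1, mid, revcomp_chr(cds2), dn)
  f1 <- gene_feature("gplus", "CDS", "+", cbind(120L, 120L + nchar(cds1)))
  f2s <- 120L + nchar(cds1) + 90L
  f2 <- gene_feature("gminus", "CDS", "-", cbind(f2s, f2s + nchar(cds2)))
  plastome_record("TINY1", seqs, TRUE, list(f1, f2))
}

# Hand-written SAM over a record: reads are lists with pos (1-based), seq,
# cigar, flag.
write_test_sam <- function(record, reads, path) {
  con <- file(path, "w")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", record$id, nchar(record$sequence))),
             con)
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    writeLines(paste(sprintf("r%04d", i), r$flag %||% 0L, record$id, r$pos,
                     60L, r$cigar, "*", 0L, 0L, r$seq,
                     strrep("I", nchar(r$seq)), sep = "\t"), con)
  }
  close(con)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
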