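.primitive_period <- function(s) {
  n <- nchar(s)
  for (p in seq_len(n - 1L)) {
    if (n %% p == 0L && .is_periodic(s, p)) return(p)
  }
  n
}

#' Find tandem peptide repeats in a protein
#'
#' For each candidate unit length, the protein is scanned for maximal
#' regions in which consecutive unit-length windows agree with the region's
#' column-majority consensus at a minimum fraction of positions (default
#' 70%). Within a region, all phase offsets of the unit are evaluated and
#' the phase maximizing matches-minus-mismatches against the final
#' consensus is kept, so the consensus of an exact repeat equals the unit
#' itself rather than a rotation. Blocks whose consensus is periodic in a
#' shorter unit are suppressed (the reported unit length is the primitive
#' period), and overlapping blocks from different unit lengths are resolved
#' best-score-first. A partial terminal copy is counted fractionally when
#' its consensus-matching prefix covers at least half the unit.
#'
#' @param protein Amino-acid string (or single-entry protein FASTA path).
#' @param unit_range Length-2 integer vector, allowed unit lengths in
#'   residues (default `c(3, 50)`).
#' @param min_copies Minimum number of full copies per block (default 3).
#' @param min_identity Per-copy identity to the running consensus required
#'   for membership (default 0.7).
#' @return A data.frame sorted by `start`: `start`, `end` (0-based residue,
#'   half-open), `unit_length`, `full_copies`, `copies` (fractional
#'   terminal copy included), `consensus`, `span`.
#' @export
find_peptide_repeats <- function(protein, unit_range = c(3L, 50L),
                                 min_copies = 3L, min_identity = 0.7) {
  if (length(protein) == 1L && file.exists(protein)) {
    ss <- Biostrings::readAAStringSet(protein)
    protein <- as.character(ss[[1L]])
  }
  protein <- gsub("\\*$", "", toupper(protein))
  n <- nchar(protein)
  if (!n) stop("empty protein")
  if (unit_range[1L] < 3L || unit_range[2L] > 50L ||
      unit_range[1L] > unit_range[2L])
    stop("unit_range must satisfy 3 <= min <= max <= 50")
  ch <- strsplit(protein, "", fixed = TRUE)[[1L]]

  cands <- list()
  for (u in unit_range[1L]:min(unit_range[2L], n %/% 2L)) {
    s <- 1L
    while (s + 2L * u - 1L <= n) {
      # cheap gate: two adjacent windows must already agree
      w1 <- ch[s:(s + u - 1L)]
      w2 <- ch[(s + u):(s + 2L * u - 1L)]
      if (sum(w1 == w2) / u < min_identity) { s <- s + 1L; next }
      # evaluate every phase of this region, keep the best-scoring block
      best <- NULL
      for (ph in s:min(s + u - 1L, n - 2L * u + 1L)) {
        blk <- .grow_peptide_block(ch, ph, u, min_identity)
        if (blk$full < min_copies) next
        if (is.null(best) || blk$score > best$score) {
          best <- blk
          best$start <- ph
        }
      }
      if (is.null(best)) { s <- s + 1L; next }
      cons <- paste(best$consensus, collapse = "")
      if (.primitive_period(cons) == u) {
        cands[[length(cands) + 1L]] <-
          data.frame(start = best$start - 1L,
                     end = best$start - 1L + best$span,
                     unit_length = u, full_copies = best$full,
                     copies = best$copies, consensus = cons,
                     span = best$span, score = best$score,
                     stringsAsFactors = FALSE)
      }
      s <- best$start + best$span
    }
  }
  empty <- data.frame(start = integer(0), end = integer(0),
                      unit_length = integer(0), full_copies = integer(0),
                      copies = numeric(0), consensus = character(0),
                      span = integer(0), stringsAsFactors = FALSE)
  if (!length(cands)) return(empty)
  tb <- do.call(rbind, cands)
  tb <- tb[order(-tb$score, tb$unit_length, tb$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(tb))
  for (i in seq_len(nrow(tb))[-1L]) {
    prior <- which(keep[seq_len(i - 1L)])
    if (any(tb$start[prior] < tb$end[i] & tb$end[prior] > tb$start[i]))
      keep[i] <- FALSE
  }
  tb <- tb[keep, setdiff(names(tb), "score"), drop = FALSE]
  tb <- tb[order(tb$start), , drop = FALSE]
  rownames(tb) <- NULL
  tb
}

# Greedy block growth at a fixed start and unit length: accept consecutive
# u-mers while each agrees with the running column-majority consensus at
# >= min_identity of positions; then try a fractional terminal copy. The
# returned score is matches minus mismatches against the final consensus
# over the whole block.
.grow_peptide_block <- function(ch, s, u, min_identity) {
  n <- length(ch)
  counts <- matrix(0L, nrow = 27L, ncol = u)   # rows: A..Z plus other
  rowidx <- function(v) {
    i <- utf8ToInt(paste(v, collapse = "")) - 64L
    i[i < 1L | i > 26L] <- 27L
    i
  }
  cons_of <- function() LETTERS[max.col(t(counts[1:26, , drop = FALSE]),
                                        ties.method = "first")]
  add <- function(v) {
    i <- rowidx(v)
    counts[cbind(i, seq_len(u))] <<- counts[cbind(i, seq_len(u))] + 1L
  }
  add(ch[s:(s + u - 1L)])
  full <- 1L
  repeat {
    nxt <- s + full * u
    if (nxt + u - 1L > n) break
    cons <- cons_of()
    cand <- ch[nxt:(nxt + u - 1L)]
    if (sum(cand == cons) / u < min_identity) break
    add(cand)
    full <- full + 1L
  }
  cons <- cons_of()
  span <- full * u
  copies <- as.numeric(full)
  # partial terminal copy: consensus-matching prefix of the next window
  tail_start <- s + span
  tmax <- min(u - 1L, n - tail_start + 1L)
  t_used <- 0L
  if (full >= 2L && tmax > 0L) {
    agree <- ch[tail_start:(tail_start + tmax - 1L)] == cons[seq_len(tmax)]
    t <- if (all(agree)) tmax else which.min(agree) - 1L
    if (t >= u / 2) {
      span <- span + t
      copies <- copies + t / u
      t_used <- t
    }
  }
  matches <- sum(ch[s:(s + full * u - 1L)] ==
                   rep_len(cons, full * u)) + t_used
  list(full = full, copies = copies, span = span, consensus = cons,
       score = 2L * matches - span)
}
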