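#' Parameters for dispersed-repeat self-alignment
#'
#' Defaults follow a megablast-style genome-against-itself search: word size
#' 7 and an E-value ceiling of 1e-6, with +1/-2 match/mismatch scoring and
#' ungapped X-drop extension.
#'
#' @param word_size Seed word length (>= 4).
#' @param evalue_max E-value ceiling for reported hits.
#' @param match_reward,mismatch_penalty Ungapped scoring (penalty negative).
#' @param xdrop Extension stops when the running score falls this far below
#'   the running maximum.
#' @return A `repeat_search_params` list, with Karlin-Altschul `lambda`
#'   (solved numerically from the score system under uniform base
#'   composition) and `K` attached.
#' @export
repeat_search_params <- function(word_size = 7L, evalue_max = 1e-6,
                                 match_reward = 1L, mismatch_penalty = -2L,
                                 xdrop = 20L) {
  if (word_size < 4L) stop("word_size must be >= 4")
  if (evalue_max <= 0) stop("evalue_max must be > 0")
  if (mismatch_penalty >= 0L) stop("mismatch_penalty must be negative")
  lambda <- uniroot(function(l) 0.25 * exp(l * match_reward) +
                      0.75 * exp(l * mismatch_penalty) - 1,
                    c(1e-6, 10))$root
  structure(list(word_size = as.integer(word_size), evalue_max = evalue_max,
                 match_reward = as.integer(match_reward),
                 mismatch_penalty = as.integer(mismatch_penalty),
                 xdrop = as.integer(xdrop),
                 lambda = lambda,
                 # standard ungapped K for the +1/-2 nucleotide score pair
                 K = 0.621),
            class = "repeat_search_params")
}

#' Parameters for perfect tandem-repeat search
#'
#' Defaults: arrays of at least 20 bp containing two or more copies of a
#' perfect repeating unit of 2-40 bp.
#'
#' @param min_total Minimum total array span, bp.
#' @param min_copies Minimum number of (full) unit copies (>= 2).
#' @param unit_min,unit_max Allowed primitive unit lengths, bp.
#' @return A `tandem_params` list.
#' @export
tandem_params <- function(min_total = 20L, min_copies = 2L,
                          unit_min = 2L, unit_max = 40L) {
  if (unit_min > unit_max) stop("unit_min must be <= unit_max")
  if (min_copies < 2L) stop("min_copies must be >= 2")
  structure(list(min_total = as.integer(min_total),
                 min_copies = as.integer(min_copies),
                 unit_min = as.integer(unit_min),
                 unit_max = as.integer(unit_max)),
            class = "tandem_params")
}

#' Excise one inverted-repeat copy
#'
#' Returns the genome sequence with IRa removed, preserving LSC + IRb + SSC
#' order (the convention used before repeat quantification, so that the
#' near-identical IR copies do not dominate the repeat content).
#'
#' @param record A [plastome_record()] or DNA string.
#' @param partition A `quadripartite_partition`, or `NULL` for genomes
#'   without a detected IR (sequence returned unchanged).
#' @return DNA string of length `total - ir_length`.
#' @export
remove_one_ir <- function(record, partition) {
  seq <- if (inherits(record, "plastome_record")) record$sequence else .check_dna(record)
  if (is.null(partition)) return(seq)
  if (nchar(seq) != partition$total)
    stop("partition does not belong to this sequence (length mismatch)")
  start <- partition$lsc[1L]
  len <- partition$lsc[2L] + partition$ir_length + partition$ssc[2L]
  .circ_substr(seq, start, len)
}

## ---- dispersed repeats ----------------------------------------------------

# 2-bit base codes; N -> NA so any word containing N is dropped.
.base_codes <- function(seq) {
  v <- match(strsplit(seq, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T")) - 1L
  v
}

.word_index <- function(v, k) {
  n <- length(v)
  if (n < k) return(integer(0))
  w <- integer(n - k + 1L)
  for (d in 0L:(k - 1L)) w <- w * 4L + v[(1L + d):(n - k + 1L + d)]
  w
}

# all ordered pairs (x < y) within each group of equal words
.word_pairs <- function(w1, w2 = NULL) {
  if (is.null(w2)) {
    grp <- split(seq_along(w1), w1)
    grp <- grp[lengths(grp) >= 2L]
    if (!length(grp)) return(cbind(i = integer(0), j = integer(0)))
    res <- lapply(grp, function(g) {
      h <- length(g)
      ai <- rep.int(seq_len(h - 1L), rev(seq_len(h - 1L)))
      bi <- sequence(rev(seq_len(h - 1L))) + ai
      cbind(g[ai], g[bi])
    })
  } else {
    g1 <- split(seq_along(w1), w1)
    g2 <- split(seq_along(w2), w2)
    shared <- intersect(names(g1), names(g2))
    if (!length(shared)) return(cbind(i = integer(0), j = integer(0)))
    res <- lapply(shared, function(wd) {
      a <- g1[[wd]]; b <- g2[[wd]]
      cbind(rep(a, each = length(b)), rep.int(b, length(a)))
    })
  }
  out <- do.call(rbind, res)
  colnames(out) <- c("i", "j")
  out
}

# Vectorized ungapped X-drop extension of exact word seeds.
# va, vb: 2-bit code vectors (NA = N, never matches); i, j: 0-based seed
# starts in va/vb. Returns per-seed left/right kept extension lengths,
# total score and match count.
.xdrop_extend <- function(va, vb, i, j, k, params) {
  m <- length(i)
  reward <- params$match_reward; penalty <- params$mismatch_penalty
  xd <- params$xdrop
  ext_dir <- function(pa, pb, step) {
    # pa, pb: 0-based positions of the first column to examine; step +1/-1
    cur <- best <- numeric(m); bestd <- integer(m)
    alive <- rep(TRUE, m); d <- 0L
    na_ <- length(va); nb_ <- length(vb)
    while (any(alive)) {
      qa <- pa[alive] + step * d
      qb <- pb[alive] + step * d
      ok <- qa >= 0L & qa < na_ & qb >= 0L & qb < nb_
      sc <- rep(penalty, sum(alive))
      qa1 <- ifelse(ok, qa + 1L, 1L)   # safe index; masked by ok below
      qb1 <- ifelse(ok, qb + 1L, 1L)
      eq <- ok & !is.na(va[qa1]) & !is.na(vb[qb1]) & va[qa1] == vb[qb1]
      eq[is.na(eq)] <- FALSE
      sc[eq] <- reward
      idx <- which(alive)
      dead_oob <- idx[!ok]
      cur[idx[ok]] <- cur[idx[ok]] + sc[ok]
      better <- idx[ok][cur[idx[ok]] > best[idx[ok]]]
      best[better] <- cur[better]
      bestd[better] <- d + 1L
      dropped <- idx[ok][cur[idx[ok]] < best[idx[ok]] - xd]
      alive[c(dead_oob, dropped)] <- FALSE
      d <- d + 1L
    }
    list(len = bestd, score = best)
  }
  right <- ext_dir(i + k, j + k, +1L)
  left <- ext_dir(i - 1L, j - 1L, -1L)
  len <- k + left$len + right$len
  score <- k * reward + left$score + right$score
  # matches = columns - mismatches; mismatches from score identity:
  # score = reward*matches + penalty*(len - matches)
  matches <- as.integer(round((score - penalty * len) / (reward - penalty)))
  list(l = left$len, r = right$len, len = len, score = score, matches = matches)
}

#' Find dispersed repeats by ungapped self-alignment
#'
#' Seed-and-extend self-comparison of a sequence on both strands: exact
#' shared words seed ungapped X-drop extensions scored +1/-2; each maximal
#' hit receives a Karlin-Altschul E-value for an effective search space of
#' `nchar(seq)^2`, and hits above `evalue_max` are discarded. The trivial
#' full-length self-identity is excluded and symmetric duplicates are
#' reported once.
#'
#' @param seq DNA string (typically the IR-reduced genome).
#' @param params A [repeat_search_params()].
#' @return A data.frame of hits: `q_start`, `q_end`, `s_start`, `s_end`
#'   (0-based half-open), `strand`, `length`, `matches`, `identity`,
#'   `score`, `evalue`, sorted by increasing E-value.
#' @export
find_dispersed_repeats <- function(seq, params = repeat_search_params()) {
  .check_dna(seq)
  n <- nchar(seq)
  k <- params$word_size
  if (n < k) stop("sequence shorter than word_size")
  va <- .base_codes(seq)
  wa <- .word_index(va, k)
  valid <- !is.na(wa)
  wa_chr <- ifelse(valid, as.character(wa), NA)

  hits <- list()

  # forward strand: pairs of identical words, i < j
  pr <- .word_pairs(wa_chr[valid])
  if (nrow(pr)) {
    pos <- which(valid)
    i <- pos[pr[, 1L]] - 1L; j <- pos[pr[, 2L]] - 1L
    keep <- i != j
    i <- i[keep]; j <- j[keep]
    if (length(i)) {
      ext <- .xdrop_extend(va, va, i, j, k, params)
      hits[[length(hits) + 1L]] <- data.frame(
        q_start = i - ext$l, q_end = i + k + ext$r,
        s_start = j - ext$l, s_end = j + k + ext$r,
        strand = "+", length = ext$len, matches = ext$matches,
        score = ext$score, stringsAsFactors = FALSE)
    }
  }

  # reverse strand: words shared between seq and its reverse complement
  rc <- .revcomp(seq)
  vb <- .base_codes(rc)
  wb <- .word_index(vb, k)
  validb <- !is.na(wb)
  pr2 <- .word_pairs(ifelse(valid, as.character(wa), NA)[valid],
                     ifelse(validb, as.character(wb), NA)[validb])
  if (nrow(pr2)) {
    posa <- which(valid); posb <- which(validb)
    i <- posa[pr2[, 1L]] - 1L; j <- posb[pr2[, 2L]] - 1L
    ext <- .xdrop_extend(va, vb, i, j, k, params)
    qs <- i - ext$l; qe <- i + k + ext$r
    # map the rc-space interval [j - l, j + k + r) back to seq coordinates
    ss <- n - (j + k + ext$r); se <- n - (j - ext$l)
    hits[[length(hits) + 1L]] <- data.frame(
      q_start = qs, q_end = qe, s_start = ss, s_end = se,
      strand = "-", length = ext$len, matches = ext$matches,
      score = ext$score, stringsAsFactors = FALSE)
  }

  if (!length(hits)) return(.empty_hits())
  h <- do.call(rbind, hits)

  # drop the trivial identity (q == s on +) and canonicalize symmetric pairs
  h <- h[!(h$strand == "+" & h$q_start == h$s_start), , drop = FALSE]
  swap <- h$q_start > h$s_start
  tmp <- h[swap, c("s_start", "s_end")]
  h[swap, c("s_start", "s_end")] <- h[swap, c("q_start", "q_end")]
  h[swap, c("q_start", "q_end")] <- tmp
  h <- h[!duplicated(h[c("q_start", "s_start", "length", "strand")]), , drop = FALSE]

  h$identity <- h$matches / h$length
  h$evalue <- params$K * as.numeric(n)^2 * exp(-params$lambda * h$score)
  h <- h[h$evalue <= params$evalue_max, , drop = FALSE]
  h <- h[order(h$evalue, h$q_start), , drop = FALSE]
  rownames(h) <- NULL
  h[c("q_start", "q_end", "s_start", "s_end", "strand", "length",
      "matches", "identity", "score", "evalue")]
}

.empty_hits <- function() {
  data.frame(q_start = integer(0), q_end = integer(0), s_start = integer(0),
             s_end = integer(0), strand = character(0), length = integer(0),
             matches = integer(0), identity = numeric(0), score = numeric(0),
             evalue = numeric(0), stringsAsFactors = FALSE)
}

## ---- tandem repeats -------------------------------------------------------

.least_rotation <- function(s) {
  n <- nchar(s)
  rots <- vapply(seq_len(n) - 1L,
                 function(r) paste0(substring(s, r + 1L, n), substring(s, 1L, r)), "")
  sort(rots)[1L]
}

.is_periodic <- function(s, p) {
  n <- nchar(s)
  p < n && substring(s, 1L, n - p) == substring(s, p + 1L, n)
}

#' Find perfect tandem repeats
#'
#' Reports every maximal run of two or more exact copies of a primitive
#' repeating unit with length in `[unit_min, unit_max]` and total span of at
#' least `min_total` bp. Runs contained in an already reported run with a
#' shorter primitive unit are suppressed. The reported unit is the
#' lexicographically least rotation of the primitive unit. Positions
#' involving `N` never match.
#'
#' @param seq DNA string.
#' @param params A [tandem_params()].
#' @return A data.frame sorted by `start`: `start`, `end` (0-based
#'   half-open), `unit_length`, `unit` (canonical rotation), `copies`
#'   (full copies), `span` (bp, includes any partial terminal copy).
#' @export
find_tandem_repeats <- function(seq, params = tandem_params()) {
  .check_dna(seq)
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  isn <- ch == "N"
  runs <- list()
  for (u in params$unit_min:min(params$unit_max, n %/% 2L)) {
    eq <- ch[seq_len(n - u)] == ch[(u + 1L):n] &
      !isn[seq_len(n - u)] & !isn[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= u)   # >= 2 full copies
    for (x in ok) {
      s0 <- starts[x] - 1L                    # 0-based array start
      span <- r$lengths[x] + u
      copies <- span %/% u
      if (span < params$min_total || copies < params$min_copies) next
      region <- substring(seq, s0 + 1L, s0 + span)
      # primitivity over the whole region: a proper divisor period means the
      # same array is found (longer or equal) at the smaller unit length
      divs <- which(u %% seq_len(u - 1L) == 0L)
      if (any(vapply(divs, function(d) .is_periodic(region, d), TRUE))) next
      unit <- substring(seq, s0 + 1L, s0 + u)
      runs[[length(runs) + 1L]] <-
        data.frame(start = s0, end = s0 + span, unit_length = u,
                   unit = .least_rotation(unit), copies = copies, span = span,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(runs))
    return(data.frame(start = integer(0), end = integer(0),
                      unit_length = integer(0), unit = character(0),
                      copies = integer(0), span = integer(0),
                      stringsAsFactors = FALSE))
  tb <- do.call(rbind, runs)
  tb <- tb[order(tb$unit_length, tb$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(tb))
  for (x in seq_len(nrow(tb))) {
    if (!keep[x]) next
    prior <- which(keep & seq_len(nrow(tb)) < x)
    contained <- prior[tb$unit_length[prior] < tb$unit_length[x] &
                         tb$start[prior] <= tb$start[x] &
                         tb$end[prior] >= tb$end[x]]
    if (length(contained)) keep[x] <- FALSE
  }
  tb <- tb[keep, , drop = FALSE]
  tb <- tb[order(tb$start, tb$unit_length), , drop = FALSE]
  rownames(tb) <- NULL
  tb
}

## ---- summary --------------------------------------------------------------

#' Repeat content summary for one genome
#'
#' Runs [remove_one_ir()], [find_dispersed_repeats()] and
#' [find_tandem_repeats()] and reports union coverages. `dispersed_bp` is
#' the length of the union of all positions covered by at least one passing
#' hit interval, with both members of each pair contributing. Because the
#' percentage denominator differs between conventions, both are reported:
#' `dispersed_pct` over the IR-reduced (analyzed) length and
#' `dispersed_pct_full` over the full genome length.
#'
#' @param record A [plastome_record()].
#' @param partition Output of [find_inverted_repeat()] (may be `NULL`).
#' @param search_params A [repeat_search_params()].
#' @param t_params A [tandem_params()].
#' @return A `repeat_report` list: `genome_id`, `full_length`,
#'   `analyzed_length`, `dispersed_bp`, `dispersed_pct`,
#'   `dispersed_pct_full`, `tandem_bp`, `combined_bp`, plus the hit tables
#'   `dispersed` and `tandem`.
#' @export
repeat_content_summary <- function(record, partition = NULL,
                                   search_params = repeat_search_params(),
                                   t_params = tandem_params()) {
  seq <- remove_one_ir(record, partition)
  hits <- find_dispersed_repeats(seq, search_params)
  tr <- find_tandem_repeats(seq, t_params)
  disp_ir <- IRanges::reduce(IRanges::IRanges(
    start = c(hits$q_start, hits$s_start) + 1L,
    end = c(hits$q_end, hits$s_end)))
  tand_ir <- IRanges::reduce(IRanges::IRanges(start = tr$start + 1L, end = tr$end))
  both <- IRanges::reduce(c(disp_ir, tand_ir))
  structure(list(
    genome_id = if (inherits(record, "plastome_record")) record$id else NA_character_,
    full_length = if (inherits(record, "plastome_record")) nchar(record$sequence) else nchar(seq),
    analyzed_length = nchar(seq),
    dispersed_bp = sum(IRanges::width(disp_ir)),
    dispersed_pct = 100 * sum(IRanges::width(disp_ir)) / nchar(seq),
    dispersed_pct_full = 100 * sum(IRanges::width(disp_ir)) /
      (if (inherits(record, "plastome_record")) nchar(record$sequence) else nchar(seq)),
    tandem_bp = sum(IRanges::width(tand_ir)),
    combined_bp = sum(IRanges::width(both)),
    dispersed = hits, tandem = tr), class = "repeat_report")
}

#' @export
print.repeat_report <- function(x, ...) {
  cat(sprintf(paste0("<repeat_report> %s: analyzed %s bp | dispersed %s bp ",
                     "(%.2f%% of analyzed, %.2f%% of genome) | tandem %s bp\n"),
              x$genome_id, format(x$analyzed_length, big.mark = ","),
              format(x$dispersed_bp, big.mark = ","), x$dispersed_pct,
              x$dispersed_pct_full, format(x$tandem_bp, big.mark = ",")))
  invisible(x)
}
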