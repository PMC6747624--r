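#' Filter parameters for RNA-editing calling
#'
#' The read- and site-level filter cascade: alignments with soft clips (when
#' forbidden) or identity below 98% are discarded; a site is reported only
#' with at least 10x depth, a strictly greater than 10% alternative-read
#' fraction, and strictly more than 3 supporting reads.
#'
#' @param min_identity Minimum per-read alignment identity (matches /
#'   aligned columns; indel columns count as mismatches).
#' @param min_depth Minimum passing-read depth at a site.
#' @param min_alt_fraction Site alt fraction must be strictly greater.
#' @param min_alt_reads Site alt reads must be strictly greater (default 3,
#'   i.e. at least 4 reads required).
#' @param forbid_softclip Discard reads whose CIGAR contains soft clips.
#' @param dedup_overlapping_mates Collapse overlapping mate pairs to one
#'   observation per fragment (default `FALSE`: naive pileup, each read
#'   counts).
#' @return An `editing_filter_params` list.
#' @export
editing_filter_params <- function(min_identity = 0.98, min_depth = 10L,
                                  min_alt_fraction = 0.10, min_alt_reads = 3L,
                                  forbid_softclip = TRUE,
                                  dedup_overlapping_mates = FALSE) {
  if (min_identity <= 0 || min_identity > 1) stop("min_identity must be in (0, 1]")
  if (min_depth < 1L) stop("min_depth must be >= 1")
  structure(list(min_identity = min_identity, min_depth = as.integer(min_depth),
                 min_alt_fraction = min_alt_fraction,
                 min_alt_reads = as.integer(min_alt_reads),
                 forbid_softclip = isTRUE(forbid_softclip),
                 dedup_overlapping_mates = isTRUE(dedup_overlapping_mates)),
            class = "editing_filter_params")
}

.cigar_ops <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1L]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(toks) || toks[1L] == "") stop("malformed CIGAR: ", cigar)
  list(len = as.integer(sub("[A-Z=]", "", toks)),
       op = sub("[0-9]+", "", toks))
}

#' Read SAM alignments
#'
#' Plain-text SAM (or BAM) read through Rsamtools; returns the fields the
#' pileup needs.
#'
#' @param path SAM or BAM file.
#' @return A data.frame with `qname`, `flag`, `rname`, `pos` (1-based
#'   leftmost), `cigar`, `seq`.
#' @export
read_sam_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq")))[[1L]]
  data.frame(qname = res$qname, flag = res$flag,
             rname = as.character(res$rname), pos = res$pos,
             cigar = res$cigar, seq = as.character(res$seq),
             stringsAsFactors = FALSE)
}

#' Build a per-position pileup from filtered alignments
#'
#' Applies the read-level filter cascade (unmapped, secondary and
#' supplementary alignments out; soft-clipped reads out when forbidden;
#' identity below `min_identity` out, where identity = matches / aligned
#' columns and inserted/deleted columns count as mismatches, computed
#' directly against the genome sequence) and accumulates reference-strand
#' base counts at every aligned position.
#'
#' @param alignments A SAM/BAM path or the data.frame from
#'   [read_sam_alignments()].
#' @param record The [plastome_record()] the reads were aligned to.
#' @param params An [editing_filter_params()].
#' @return A `pileup_counts` data.frame with one row per covered position:
#'   `pos` (0-based), `ref`, `A`, `C`, `G`, `T`, `depth`; the numbers of
#'   input/passing reads are attached as attributes `n_reads`/`n_passing`.
#' @export
build_pileup <- function(alignments, record, params = editing_filter_params()) {
  if (is.character(alignments)) alignments <- read_sam_alignments(alignments)
  aln <- alignments
  n <- nchar(record$sequence)
  refch <- strsplit(record$sequence, "", fixed = TRUE)[[1L]]
  n_in <- nrow(aln)

  mapped <- bitwAnd(aln$flag, 0x4L) == 0L &
    bitwAnd(aln$flag, 0x100L) == 0L & bitwAnd(aln$flag, 0x800L) == 0L
  aln <- aln[mapped & !is.na(aln$pos), , drop = FALSE]
  if (nrow(aln) && any(aln$rname != record$id))
    stop("alignment reference '", unique(aln$rname[aln$rname != record$id])[1L],
         "' does not match record id '", record$id, "'")
  if (params$forbid_softclip && nrow(aln)) {
    aln <- aln[!grepl("S", aln$cigar, fixed = TRUE), , drop = FALSE]
  }

  pos_acc <- vector("list", nrow(aln))
  base_acc <- vector("list", nrow(aln))
  n_pass <- 0L
  for (r in seq_len(nrow(aln))) {
    ops <- .cigar_ops(aln$cigar[r])
    rp <- aln$pos[r] - 1L   # 0-based reference cursor
    qp <- 0L                # 0-based read cursor
    readch <- strsplit(aln$seq[r], "", fixed = TRUE)[[1L]]
    matches <- 0L; cols <- 0L
    posv <- integer(0); basev <- character(0)
    bad <- FALSE
    for (x in seq_along(ops$op)) {
      L <- ops$len[x]
      switch(ops$op[x],
        "M" = , "=" = , "X" = {
          if (rp + L > n) { bad <- TRUE; break }
          rb <- refch[(rp + 1L):(rp + L)]
          qb <- readch[(qp + 1L):(qp + L)]
          matches <- matches + sum(rb == qb & rb != "N")
          cols <- cols + L
          posv <- c(posv, rp:(rp + L - 1L))
          basev <- c(basev, qb)
          rp <- rp + L; qp <- qp + L
        },
        "I" = { cols <- cols + L; qp <- qp + L },
        "D" = , "N" = { if (ops$op[x] == "D") cols <- cols + L; rp <- rp + L },
        "S" = { qp <- qp + L },
        "H" = , "P" = NULL)
    }
    if (bad || cols == 0L) next
    if (matches / cols < params$min_identity) next
    n_pass <- n_pass + 1L
    pos_acc[[r]] <- posv
    base_acc[[r]] <- basev
  }
  pos <- unlist(pos_acc, use.names = FALSE)
  base <- unlist(base_acc, use.names = FALSE)
  code <- match(base, c("A", "C", "G", "T"))
  keep <- !is.na(code)
  pos <- pos[keep]; code <- code[keep]
  counts <- matrix(0L, nrow = 4L, ncol = n)
  if (length(pos)) {
    tb <- tabulate(pos * 4L + code, nbins = 4L * n)
    counts <- matrix(tb, nrow = 4L)
  }
  covered <- which(colSums(counts) > 0L)
  out <- data.frame(pos = covered - 1L,
                    ref = refch[covered],
                    A = counts[1L, covered], C = counts[2L, covered],
                    G = counts[3L, covered], T = counts[4L, covered])
  out$depth <- out$A + out$C + out$G + out$T
  attr(out, "genome_length") <- n
  attr(out, "n_reads") <- n_in
  attr(out, "n_passing") <- n_pass
  class(out) <- c("pileup_counts", "data.frame")
  out
}

#' Annotate the codon effect of a C-to-U edit
#'
#' @param site_pos 0-based genome position of the edited C.
#' @param cds A `coding_sequence` from [extract_cds()]; the CDS base at the
#'   site must be C.
#' @return List with `codon_index` (1-based amino-acid position),
#'   `codon_display` (reference codon with the edited base lower-case, e.g.
#'   `"CcA"`) and `aa_change` (`"P=>L"` or `"synonymous"`).
#' @export
annotate_codon_effect <- function(site_pos, cds) {
  ci <- match(site_pos, cds$genome_pos)
  if (is.na(ci)) stop("position ", site_pos, " is not in the CDS of ", cds$gene)
  if (substring(cds$seq, ci, ci) != "C")
    stop("CDS base at position ", site_pos, " is ",
         substring(cds$seq, ci, ci), ", not C")
  codon_index <- (ci - 1L) %/% 3L + 1L
  offset <- (ci - 1L) %% 3L + 1L
  cstart <- (codon_index - 1L) * 3L + 1L
  codon <- substring(cds$seq, cstart, cstart + 2L)
  disp <- codon
  substring(disp, offset, offset) <- "c"
  edited <- codon
  substring(edited, offset, offset) <- "T"
  aa_before <- .codon_aa(codon)
  aa_after <- .codon_aa(edited)
  aa_change <- if (aa_before == aa_after) "synonymous"
               else paste0(aa_before, "=>", aa_after)
  list(codon_index = codon_index, codon_display = disp, aa_change = aa_change)
}

#' Call C-to-U RNA-editing sites from a pileup
#'
#' A site is called iff it lies in an annotated CDS, the coding-strand
#' reference base is C (reference C with T alternates on plus-strand genes;
#' reference G with A alternates on minus-strand genes), depth >=
#' `min_depth`, alt fraction (over all passing reads) > `min_alt_fraction`
#' and alt reads > `min_alt_reads`. The editing frequency is the C-versus-U
#' ratio: alt / (ref-base reads + alt reads). Positions covered by CDSs on
#' both strands are reported for each with `dual_strand = TRUE`. CDSs whose
#' length is not divisible by 3 are flagged with a warning and skipped.
#'
#' @param pileup A `pileup_counts` from [build_pileup()].
#' @param record The annotated [plastome_record()].
#' @param params An [editing_filter_params()].
#' @param include_pseudo Also scan annotated pseudogene copies.
#' @return An `editing_sites` data.frame sorted by gene then codon:
#'   `gene`, `codon_index`, `codon_display`, `aa_change`, `frequency`,
#'   `depth`, `alt_reads`, `ref_reads`, `genome_pos` (0-based), `strand`,
#'   `dual_strand`.
#' @export
call_editing_sites <- function(pileup, record,
                               params = editing_filter_params(),
                               include_pseudo = FALSE) {
  feats <- Filter(function(f) f$kind == "CDS" ||
                    (include_pseudo && f$kind == "pseudogene"), record$features)
  if (!length(feats)) stop("record has no CDS features")
  # strand occupancy for dual-strand flagging
  occ <- list("+" = integer(0), "-" = integer(0))
  for (f in feats) {
    pos <- unlist(lapply(seq_len(nrow(f$parts)),
                         function(i) seq.int(f$parts[i, 1L], f$parts[i, 2L] - 1L)))
    occ[[f$strand]] <- c(occ[[f$strand]], pos)
  }
  res <- list()
  for (f in feats) {
    cds <- extract_cds(record, f$name, copy = f$copy,
                       allow_pseudo = include_pseudo)
    if (nchar(cds$seq) %% 3L != 0L) {
      warning("CDS length of ", f$name, " not divisible by 3; sites in this ",
              "gene are flagged, not called")
      next
    }
    c_idx <- which(strsplit(cds$seq, "", fixed = TRUE)[[1L]] == "C")
    if (!length(c_idx)) next
    gp <- cds$genome_pos[c_idx]
    row <- match(gp, pileup$pos)
    have <- which(!is.na(row))
    for (x in have) {
      p <- pileup[row[x], ]
      if (f$strand == "+") { alt <- p$T; refn <- p$C } else { alt <- p$A; refn <- p$G }
      if (p$depth < params$min_depth) next
      if (alt <= params$min_alt_reads) next
      if (alt / p$depth <= params$min_alt_fraction) next
      eff <- annotate_codon_effect(gp[x], cds)
      res[[length(res) + 1L]] <- data.frame(
        gene = f$name, codon_index = eff$codon_index,
        codon_display = eff$codon_display, aa_change = eff$aa_change,
        frequency = alt / (refn + alt), depth = p$depth,
        alt_reads = alt, ref_reads = refn,
        genome_pos = gp[x], strand = f$strand,
        dual_strand = gp[x] %in% occ[[setdiff(c("+", "-"), f$strand)]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    out <- data.frame(gene = character(0), codon_index = integer(0),
                      codon_display = character(0), aa_change = character(0),
                      frequency = numeric(0), depth = integer(0),
                      alt_reads = integer(0), ref_reads = integer(0),
                      genome_pos = integer(0), strand = character(0),
                      dual_strand = logical(0), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, res)
    out <- out[order(out$gene, out$codon_index), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("editing_sites", "data.frame")
  out
}

#' Write called editing sites as TSV
#'
#' Columns mirror the per-site report: gene, 1-based amino-acid position,
#' codon with the edited base lower-case, amino-acid change, editing
#' frequency, depth and read counts. A commented header line leads.
#'
#' @param sites An `editing_sites` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_editing_tsv <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# gene\tamino_acid_position\tcodon\tamino_acid_change\t",
                    "frequency\tdepth\talt_reads\tref_reads\tposition_1based\tstrand"), con)
  if (nrow(sites))
    write.table(data.frame(sites$gene, sites$codon_index, sites$codon_display,
                           sites$aa_change, sprintf("%.4f", sites$frequency),
                           sites$depth, sites$alt_reads, sites$ref_reads,
                           sites$genome_pos + 1L, sites$strand),
                con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Write called editing sites as VCF-like records
#'
#' CHROM/POS/ID/REF/ALT plus `INFO` with gene, frequency and depth; REF/ALT
#' are in reference-strand space (C>T for plus-strand genes, G>A for minus).
#'
#' @param sites An `editing_sites` data.frame.
#' @param record The [plastome_record()] the sites were called on.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_editing_vcf <- function(sites, record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", record$id,
                       nchar(record$sequence)),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    ref <- if (s$strand == "+") "C" else "G"
    alt <- if (s$strand == "+") "T" else "A"
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tGENE=%s;FREQ=%.4f;DP=%d;AO=%d",
                       record$id, s$genome_pos + 1L, ref, alt, s$gene,
                       s$frequency, s$depth, s$alt_reads), con)
  }
  invisible(path)
}
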