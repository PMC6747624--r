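#' Simulation configuration
#'
#' Describes one synthetic quadripartite plastome plus its RNA-seq read set:
#' region lengths, the gene plan, planted dispersed/tandem repeats,
#' pseudogenizations, the editing plan and sequencing parameters. All
#' sampling downstream is driven by `seed` through one RNG stream, so equal
#' configs give byte-identical outputs.
#'
#' @param seed Integer seed.
#' @param lsc,ir,ssc Region lengths in bp (one IR copy).
#' @param gene_plan List of gene specs: `list(name=, kind=, strand=,
#'   exons= (bp vector), region= "lsc"/"ssc"/"ir")`. Default
#'   [default_gene_plan()].
#' @param planted_dispersed List of `c(length, copies)` dispersed repeats.
#' @param planted_tandem List of `list(unit=, copies=)` tandem arrays.
#' @param pseudogenize List of `list(gene=, indel=)` frameshifting
#'   insertions (default indel length 22 bp).
#' @param editing_plan List of `list(gene=, codon_index=, frequency=,
#'   codon=)`; the codon (default `"CCA"`, edited at its second position)
#'   is planted into the CDS.
#' @param coverage Mean per-base read depth over exons.
#' @param read_length Read length, bp.
#' @param error_rate Uniform per-base substitution error rate (`[0, 0.05]`).
#' @param intron_length Length of each simulated intron, bp.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, lsc = 80000L, ir = 20000L, ssc = 15000L,
                       gene_plan = default_gene_plan(),
                       planted_dispersed = list(c(300L, 2L)),
                       planted_tandem = list(list(unit = "AATGC", copies = 6L)),
                       pseudogenize = list(),
                       editing_plan = list(),
                       coverage = 50, read_length = 100L,
                       error_rate = 0.001, intron_length = 150L) {
  if (any(c(lsc, ir, ssc) <= 0)) stop("region lengths must be positive")
  if (error_rate < 0 || error_rate > 0.05) stop("error_rate must be in [0, 0.05]")
  for (e in editing_plan)
    if (e$frequency <= 0 || e$frequency > 1)
      stop("editing frequencies must be in (0, 1]")
  for (g in gene_plan) {
    if (is.null(g$kind)) g$kind <- "CDS"
    if (g$kind == "CDS" && sum(g$exons) %% 3L != 0L)
      stop("gene '", g$name, "': CDS exon lengths must sum to a multiple of 3")
  }
  structure(list(seed = as.integer(seed), lsc = as.integer(lsc),
                 ir = as.integer(ir), ssc = as.integer(ssc),
                 gene_plan = gene_plan, planted_dispersed = planted_dispersed,
                 planted_tandem = planted_tandem, pseudogenize = pseudogenize,
                 editing_plan = editing_plan, coverage = coverage,
                 read_length = as.integer(read_length),
                 error_rate = error_rate,
                 intron_length = as.integer(intron_length)),
            class = "sim_config")
}

#' Default gene plan for simulated plastomes
#'
#' A small complement echoing common plastid genes: mostly plus-strand CDSs
#' in the LSC, two minus-strand genes in the SSC, one intron-containing gene
#' (`atpF`) and one rRNA inside the IR (hence IR-duplicated).
#'
#' @return List of gene specs for [sim_config()].
#' @export
default_gene_plan <- function() {
  list(
    list(name = "psbA", kind = "CDS", strand = "+", exons = 1062L, region = "lsc"),
    list(name = "rbcL", kind = "CDS", strand = "+", exons = 1425L, region = "lsc"),
    list(name = "atpF", kind = "CDS", strand = "+", exons = c(144L, 411L), region = "lsc"),
    list(name = "rps2", kind = "CDS", strand = "+", exons = 708L, region = "lsc"),
    list(name = "rps14", kind = "CDS", strand = "+", exons = 300L, region = "lsc"),
    list(name = "ccsA", kind = "CDS", strand = "+", exons = 960L, region = "lsc"),
    list(name = "ndhD", kind = "CDS", strand = "-", exons = 1503L, region = "ssc"),
    list(name = "rpl23", kind = "CDS", strand = "-", exons = 282L, region = "ssc"),
    list(name = "rrn16", kind = "rRNA", strand = "+", exons = 1490L, region = "ir")
  )
}

# Edited position within a planted codon: the canonical plastid pattern is
# an edit at the second codon position (e.g. CcA, P=>L), so prefer a C
# there; otherwise the first C.
.planted_edit_offset <- function(codon) {
  if (substring(codon, 2L, 2L) == "C") return(2L)
  off <- regexpr("C", codon, fixed = TRUE)
  if (off < 0L) stop("planted codon '", codon, "' contains no C")
  as.integer(off)
}

.rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.codons_nonstop <- local({
  b <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
})

# Build a CDS codon-wise: ATG start, non-stop interior, TAA stop; planted
# editing codons overwrite interior positions.
.sim_cds <- function(total_len, planted = list()) {
  n_codons <- total_len %/% 3L
  codons <- c("ATG",
              sample(.codons_nonstop, n_codons - 2L, replace = TRUE),
              "TAA")
  for (p in planted) {
    ci <- p$codon_index
    if (ci <= 1L || ci >= n_codons)
      stop("editing plan codon_index ", ci, " out of CDS interior")
    codons[ci] <- p$codon
  }
  paste(codons, collapse = "")
}

#' Simulate a ground-truthed quadripartite plastome
#'
#' Assembles LSC + IRb + SSC + IRa (with IRa the exact reverse complement of
#' IRb), placing the planned genes, dispersed-repeat copies and tandem
#' arrays into random spacers, planting the editing-plan codons, and
#' applying the configured frameshifting insertions. Deterministic given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory: writes `genome.gb`, `genome.fasta`,
#'   `genome.gff3` and truth-ledger TSVs.
#' @return A `sim_truth` list: `record` (the [plastome_record()]),
#'   `regions` (start/length of lsc/irb/ssc/ira), `genes` (data.frame with
#'   coordinates and proteins), `dispersed`, `tandem`, `pseudogenes`,
#'   `editing` (data.frame gene/codon_index/frequency/genome_pos/strand),
#'   and `config`.
#' @export
simulate_plastome <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  planted_by_gene <- list()
  for (e in config$editing_plan) {
    codon <- if (is.null(e[["codon"]])) "CCA" else e[["codon"]]
    planted_by_gene[[e$gene]] <- c(planted_by_gene[[e$gene]],
                                   list(list(codon_index = e$codon_index,
                                             codon = codon)))
  }

  # --- construct gene elements (genome-strand sequence + relative parts)
  elements <- list(lsc = list(), ssc = list(), ir = list())
  pseudo_map <- setNames(
    lapply(config$pseudogenize, function(p)
      if (is.null(p$indel)) 22L else as.integer(p$indel)),
    vapply(config$pseudogenize, `[[`, "", "gene"))

  for (g in config$gene_plan) {
    kind <- if (is.null(g$kind)) "CDS" else g$kind
    exons <- as.integer(g$exons)
    if (kind == "CDS") {
      cds <- .sim_cds(sum(exons), planted_by_gene[[g$name]])
    } else {
      cds <- .rand_dna(sum(exons))
    }
    # split the spliced sequence into exons; interleave introns
    bounds <- cumsum(c(0L, exons))
    exon_seqs <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
    introns <- replicate(length(exons) - 1L, .rand_dna(config$intron_length))
    pieces <- character(0)
    rel_parts <- matrix(0L, nrow = length(exons), ncol = 2L)
    at <- 0L
    for (i in seq_along(exons)) {
      rel_parts[i, ] <- c(at, at + exons[i])
      pieces <- c(pieces, exon_seqs[i])
      at <- at + exons[i]
      if (i < length(exons)) { pieces <- c(pieces, introns[i]); at <- at + config$intron_length }
    }
    gseq <- paste(pieces, collapse = "")
    pseudo <- g$name %in% names(pseudo_map)
    if (pseudo) {
      indel <- pseudo_map[[g$name]]
      mid <- rel_parts[1L, 1L] + (rel_parts[1L, 2L] - rel_parts[1L, 1L]) %/% 2L
      gseq <- paste0(substring(gseq, 1L, mid), .rand_dna(indel),
                     substring(gseq, mid + 1L))
      rel_parts[1L, 2L] <- rel_parts[1L, 2L] + indel
      if (nrow(rel_parts) > 1L)
        rel_parts[-1L, ] <- rel_parts[-1L, ] + indel
      at <- at + indel
    }
    if (g$strand == "-") {
      gseq <- .revcomp(gseq)
      rel_parts <- cbind(at - rel_parts[, 2L], at - rel_parts[, 1L])
      rel_parts <- rel_parts[order(rel_parts[, 1L]), , drop = FALSE]
    }
    elements[[g$region]][[length(elements[[g$region]]) + 1L]] <-
      list(type = "gene", name = g$name, kind = kind, strand = g$strand,
           seq = gseq, rel_parts = rel_parts, pseudo = pseudo)
  }

  # --- dispersed repeat copies: copy 1..k-1 in LSC, last copy in SSC
  disp_truth <- list()
  for (d in seq_along(config$planted_dispersed)) {
    spec <- config$planted_dispersed[[d]]
    core <- .rand_dna(spec[1L])
    for (cp in seq_len(spec[2L])) {
      region <- if (cp == spec[2L]) "ssc" else "lsc"
      elements[[region]][[length(elements[[region]]) + 1L]] <-
        list(type = "dispersed", name = sprintf("DISP%d.%d", d, cp),
             seq = core, family = d)
    }
    disp_truth[[d]] <- list(length = spec[1L], copies = spec[2L])
  }
  for (t in seq_along(config$planted_tandem)) {
    spec <- config$planted_tandem[[t]]
    elements$lsc[[length(elements$lsc) + 1L]] <-
      list(type = "tandem", name = sprintf("TAND%d", t),
           seq = strrep(spec$unit, spec$copies), unit = spec$unit,
           copies = spec$copies)
  }

  # --- lay out each region: elements separated by random spacers (>= 50 bp
  # each, so planted elements never abut a region boundary)
  layout_region <- function(target, elems, label) {
    elens <- vapply(elems, function(e) nchar(e$seq), 0L)
    nsp <- length(elems) + 1L
    left <- target - sum(elens)
    if (left < 50L * nsp)
      stop("gene/repeat plan overflows region ", label, " (need ",
           sum(elens) + 50L * nsp, " bp, have ", target, ")")
    w <- runif(nsp)
    sp <- 50L + floor((left - 50L * nsp) * w / sum(w))
    sp[nsp] <- left - sum(sp[-nsp])
    seqs <- character(0)
    starts <- integer(length(elems))
    at <- 0L
    for (i in seq_along(elems)) {
      seqs <- c(seqs, .rand_dna(sp[i]))
      at <- at + sp[i]
      starts[i] <- at
      seqs <- c(seqs, elems[[i]]$seq)
      at <- at + nchar(elems[[i]]$seq)
    }
    seqs <- c(seqs, .rand_dna(sp[nsp]))
    list(seq = paste(seqs, collapse = ""), starts = starts)
  }

  lay_lsc <- layout_region(config$lsc, elements$lsc, "LSC")
  lay_ir <- layout_region(config$ir, elements$ir, "IR")
  lay_ssc <- layout_region(config$ssc, elements$ssc, "SSC")
  # keep the planted IR exactly maximal: if the single-copy bases flanking
  # the IR junctions are complementary by chance, exact extension would grow
  # the detected IR past the planted one, so nudge the terminal spacer base
  comp1 <- c(A = "T", C = "G", G = "C", T = "A")
  fix_junction <- function(region_seq) {
    n_ <- nchar(region_seq)
    first <- substring(region_seq, 1L, 1L)
    last <- substring(region_seq, n_, n_)
    if (last == comp1[[first]]) {
      repl <- sample(setdiff(c("A", "C", "G", "T"), comp1[[first]]), 1L)
      substring(region_seq, n_, n_) <- repl
    }
    region_seq
  }
  lay_lsc$seq <- fix_junction(lay_lsc$seq)
  lay_ssc$seq <- fix_junction(lay_ssc$seq)
  ira_seq <- .revcomp(lay_ir$seq)
  genome <- paste0(lay_lsc$seq, lay_ir$seq, lay_ssc$seq, ira_seq)

  off <- c(lsc = 0L, ir = config$lsc, ssc = config$lsc + config$ir)
  ira_off <- config$lsc + config$ir + config$ssc

  feats <- list()
  disp_coords <- list()
  tand_coords <- list()
  pseudo_genes <- character(0)
  add_from <- function(region, lay) {
    for (i in seq_along(elements[[region]])) {
      e <- elements[[region]][[i]]
      abs0 <- off[[region]] + lay$starts[i]
      if (e$type == "gene") {
        feats[[length(feats) + 1L]] <<-
          gene_feature(e$name, if (e$pseudo) "pseudogene" else e$kind,
                       e$strand, e$rel_parts + abs0, pseudo = e$pseudo)
        if (e$pseudo) pseudo_genes <<- c(pseudo_genes, e$name)
        if (region == "ir") {
          # duplicated copy inside IRa, mirrored and strand-flipped
          L <- nchar(e$seq)
          rel2 <- cbind(config$ir - (e$rel_parts[, 2L]),
                        config$ir - (e$rel_parts[, 1L]))
          rel2 <- rel2[order(rel2[, 1L]), , drop = FALSE]
          feats[[length(feats) + 1L]] <<-
            gene_feature(e$name, if (e$pseudo) "pseudogene" else e$kind,
                         if (e$strand == "+") "-" else "+",
                         rel2 + ira_off, pseudo = e$pseudo, copy = 2L)
        }
      } else if (e$type == "dispersed") {
        disp_coords[[length(disp_coords) + 1L]] <<-
          data.frame(name = e$name, family = e$family, start = abs0,
                     end = abs0 + nchar(e$seq), stringsAsFactors = FALSE)
      } else if (e$type == "tandem") {
        tand_coords[[length(tand_coords) + 1L]] <<-
          data.frame(name = e$name, unit = e$unit, copies = e$copies,
                     start = abs0, end = abs0 + nchar(e$seq),
                     stringsAsFactors = FALSE)
      }
    }
  }
  add_from("lsc", lay_lsc)
  add_from("ir", lay_ir)
  add_from("ssc", lay_ssc)

  record <- plastome_record(sprintf("SIMPLAST%06d", config$seed %% 1000000L),
                            genome, circular = TRUE, features = feats)

  # --- editing-site truth with genome coordinates via the CDS genome map
  ed_rows <- list()
  for (e in config$editing_plan) {
    cds <- extract_cds(record, e$gene, allow_pseudo = TRUE)
    codon <- if (is.null(e[["codon"]])) "CCA" else e[["codon"]]
    edit_off <- .planted_edit_offset(codon)
    cds_pos <- (e$codon_index - 1L) * 3L + edit_off
    stopifnot(substring(cds$seq, cds_pos, cds_pos) == "C")
    ed_rows[[length(ed_rows) + 1L]] <-
      data.frame(gene = e$gene, codon_index = e$codon_index,
                 frequency = e$frequency, cds_pos = cds_pos,
                 genome_pos = cds$genome_pos[cds_pos], strand = cds$strand,
                 codon = codon, stringsAsFactors = FALSE)
  }

  genes_tb <- do.call(rbind, lapply(record$features, function(f) {
    protein <- NA_character_
    if (f$kind == "CDS" && !f$pseudo)
      protein <- translate_cds(extract_cds(record, f$name, copy = f$copy))
    data.frame(gene = f$name, kind = f$kind, strand = f$strand,
               copy = f$copy, start = min(f$parts[, 1L]),
               end = max(f$parts[, 2L]), n_exons = nrow(f$parts),
               pseudo = f$pseudo, protein = protein, stringsAsFactors = FALSE)
  }))

  truth <- structure(list(
    record = record,
    regions = list(lsc = c(0L, config$lsc),
                   irb = c(off[["ir"]], config$ir),
                   ssc = c(off[["ssc"]], config$ssc),
                   ira = c(ira_off, config$ir)),
    irb_seq = lay_ir$seq,
    genes = genes_tb,
    dispersed = if (length(disp_coords)) do.call(rbind, disp_coords) else NULL,
    tandem = if (length(tand_coords)) do.call(rbind, tand_coords) else NULL,
    pseudogenes = pseudo_genes,
    editing = if (length(ed_rows)) do.call(rbind, ed_rows) else NULL,
    config = config), class = "sim_truth")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genbank(record, file.path(out_dir, "genome.gb"))
    write_fasta(record, file.path(out_dir, "genome.fasta"))
    write_gff3(record, file.path(out_dir, "genome.gff3"))
    .write_truth_tsvs(truth, out_dir)
  }
  truth
}

.write_truth_tsvs <- function(truth, out_dir) {
  wt <- function(df, name) {
    if (is.null(df)) return()
    path <- file.path(out_dir, paste0("truth_", name, ".tsv"))
    con <- file(path, "w")
    writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    close(con)
  }
  wt(truth$genes, "genes")
  wt(truth$dispersed, "dispersed")
  wt(truth$tandem, "tandem")
  wt(truth$editing, "editing")
  regions <- do.call(rbind, lapply(names(truth$regions), function(r)
    data.frame(region = r, start = truth$regions[[r]][1L],
               length = truth$regions[[r]][2L])))
  wt(regions, "regions")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %s: %s bp (LSC %s | IR %s x2 | SSC %s), %d genes\n",
              x$record$id, format(nchar(x$record$sequence), big.mark = ","),
              format(x$config$lsc, big.mark = ","),
              format(x$config$ir, big.mark = ","),
              format(x$config$ssc, big.mark = ","), nrow(x$genes)))
  invisible(x)
}

## ---- RNA-seq read simulation ----------------------------------------------

#' Simulate RNA-seq read alignments over the simulated plastome
#'
#' Emits a coordinate-sorted plain-text SAM of single-end reads sampled
#' uniformly within each exon of each (non-IR-duplicate) gene at the
#' configured coverage. At planted editing sites a read carries the edited
#' base with probability equal to the planted frequency (C-to-T on the
#' coding strand, appearing as G-to-A in reference coordinates for
#' minus-strand genes); every other base is substituted uniformly at the
#' configured error rate. CIGAR is full-match; NM and MD tags are emitted.
#' Reads are pre-aligned by construction — no aligner runs.
#'
#' @param truth A `sim_truth` from [simulate_plastome()].
#' @param path Output SAM path.
#' @param seed Optional seed (default: `config$seed + 1`, so genome and
#'   reads draw from distinct streams).
#' @return `path`, invisibly; the per-read origin ledger (read name =
#'   `gene:exon:index`) is attached as attribute `origins`.
#' @export
simulate_rnaseq_reads <- function(truth, path, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  record <- truth$record
  n <- nchar(record$sequence)
  rl <- config$read_length
  bases <- c("A", "C", "G", "T")

  edit_pos <- integer(0); edit_frq <- numeric(0); edit_alt <- character(0)
  if (!is.null(truth$editing)) {
    edit_pos <- truth$editing$genome_pos
    edit_frq <- truth$editing$frequency
    edit_alt <- ifelse(truth$editing$strand == "+", "T", "A")
  }

  recs <- list()
  for (fi in seq_along(record$features)) {
    f <- record$features[[fi]]
    if (f$copy != 1L) next
    for (x in seq_len(nrow(f$parts))) {
      es <- f$parts[x, 1L]; ee <- f$parts[x, 2L]
      exlen <- ee - es
      this_rl <- min(rl, exlen)
      avail <- exlen - this_rl + 1L
      # interior depth ~ n_reads * min(this_rl, avail) / avail
      n_reads <- max(1L, round(config$coverage * avail / min(this_rl, avail)))
      starts <- es + sample.int(avail, n_reads, replace = TRUE) - 1L
      for (ri in seq_len(n_reads)) {
        s0 <- starts[ri]
        seqv <- strsplit(substring(record$sequence, s0 + 1L, s0 + this_rl),
                         "", fixed = TRUE)[[1L]]
        inread <- which(edit_pos >= s0 & edit_pos < s0 + this_rl)
        for (ei in inread) {
          if (runif(1) <= edit_frq[ei])
            seqv[edit_pos[ei] - s0 + 1L] <- edit_alt[ei]
        }
        if (config$error_rate > 0) {
          errs <- which(runif(this_rl) < config$error_rate)
          for (p in errs)
            seqv[p] <- sample(setdiff(bases, seqv[p]), 1L)
        }
        refv <- strsplit(substring(record$sequence, s0 + 1L, s0 + this_rl),
                         "", fixed = TRUE)[[1L]]
        nm <- sum(seqv != refv)
        md <- .md_tag(refv, seqv)
        recs[[length(recs) + 1L]] <- list(
          qname = sprintf("%s:%d:%d", f$name, x, ri),
          flag = if (f$strand == "-") 16L else 0L,
          pos = s0 + 1L, cigar = sprintf("%dM", this_rl),
          seq = paste(seqv, collapse = ""), nm = nm, md = md)
      }
    }
  }
  ord <- order(vapply(recs, `[[`, 0L, "pos"))
  recs <- recs[ord]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", record$id, n)), con)
  lines <- vapply(recs, function(r)
    paste(r$qname, r$flag, record$id, r$pos, 60L, r$cigar, "*", 0L, 0L,
          r$seq, strrep("I", nchar(r$seq)),
          sprintf("NM:i:%d", r$nm), sprintf("MD:Z:%s", r$md), sep = "\t"), "")
  writeLines(lines, con)
  out <- path
  attr(out, "origins") <- vapply(recs, `[[`, "", "qname")
  invisible(out)
}

.md_tag <- function(refv, seqv) {
  mm <- refv != seqv
  if (!any(mm)) return(as.character(length(refv)))
  out <- character(0)
  run <- 0L
  for (i in seq_along(refv)) {
    if (mm[i]) {
      out <- c(out, as.character(run), refv[i])
      run <- 0L
    } else run <- run + 1L
  }
  paste(c(out, as.character(run)), collapse = "")
}

## ---- homolog panel simulation ---------------------------------------------

#' Simulate a homolog protein panel
#'
#' Generates `n` homologs of a protein in which each flagged position
#' carries the "edited" residue with probability `conservation` (and the
#' original residue otherwise), while all other positions mutate to a random
#' different residue at a background rate.
#'
#' @param protein Query amino-acid string (the unedited translation).
#' @param positions Integer vector of 1-based residue positions under
#'   editing control.
#' @param edited_residues Character vector (recycled) of the residues the
#'   edit would create at `positions`.
#' @param conservation Probability that a homolog carries the edited
#'   residue at a flagged position.
#' @param n Panel size.
#' @param seed Integer seed.
#' @param background_rate Per-position mutation rate elsewhere.
#' @param path Optional protein FASTA output path.
#' @return Named character vector of homolog proteins (invisibly writes
#'   FASTA when `path` is given).
#' @export
simulate_homolog_panel <- function(protein, positions, edited_residues,
                                   conservation = 0.9, n = 10L, seed = 1L,
                                   background_rate = 0.05, path = NULL) {
  if (any(positions < 1L | positions > nchar(protein)))
    stop("positions outside the protein")
  set.seed(seed)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  pch <- strsplit(protein, "", fixed = TRUE)[[1L]]
  edited_residues <- rep_len(edited_residues, length(positions))
  panel <- vapply(seq_len(n), function(h) {
    v <- pch
    bg <- which(runif(length(v)) < background_rate)
    bg <- setdiff(bg, positions)
    for (p in bg) v[p] <- sample(setdiff(aas, v[p]), 1L)
    for (k in seq_along(positions)) {
      v[positions[k]] <- if (runif(1) <= conservation) edited_residues[k]
                         else pch[positions[k]]
    }
    paste(v, collapse = "")
  }, "")
  names(panel) <- sprintf("homolog%03d", seq_len(n))
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(panel), path)
  }
  invisible(panel)
}

## ---- config file I/O -------------------------------------------------------

#' Read / write a simulation config as a structured text file
#'
#' The on-disk format is YAML with the same field names as [sim_config()];
#' `gene_plan`, `planted_*`, `pseudogenize` and `editing_plan` are lists of
#' maps.
#'
#' @param path Config file path.
#' @return [read_sim_config()]: a `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the yaml package")
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(args$planted_dispersed))
    args$planted_dispersed <- lapply(args$planted_dispersed,
                                     function(d) c(d$length, d$copies))
  if (!is.null(args$gene_plan))
    args$gene_plan <- lapply(args$gene_plan, function(g) {
      g$exons <- as.integer(unlist(g$exons)); g
    })
  do.call(sim_config, args)
}

#' @param config A [sim_config()].
#' @rdname read_sim_config
#' @return [write_sim_config()]: `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("writing config files requires the yaml package")
  y <- unclass(config)
  y$planted_dispersed <- lapply(y$planted_dispersed,
                                function(d) list(length = d[1L], copies = d[2L]))
  yaml::write_yaml(y, path)
  invisible(path)
}
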