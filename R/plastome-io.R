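#' Construct a gene feature
#'
#' A feature is one annotated gene copy: a name, a kind, a strand and an
#' ordered set of exon intervals in 0-based half-open genome coordinates.
#'
#' @param name Gene symbol (e.g. `"atpF"`).
#' @param kind One of `"CDS"`, `"tRNA"`, `"rRNA"`, `"pseudogene"`.
#' @param strand `"+"` or `"-"`.
#' @param parts Integer matrix with columns `start`, `end` (0-based,
#'   half-open), one row per exon, in genome order.
#' @param pseudo Logical; annotated as a pseudogene.
#' @param trans_spliced Logical; exons transcribed from separate loci.
#' @param copy Copy index, to keep IR-duplicated genes distinct.
#' @return A `gene_feature` list.
#' @export
gene_feature <- function(name, kind, strand, parts, pseudo = FALSE,
                         trans_spliced = FALSE, copy = 1L) {
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA", "pseudogene"))
  strand <- match.arg(strand, c("+", "-"))
  parts <- matrix(as.integer(parts), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(parts) == 0L) stop("feature '", name, "': parts must be non-empty")
  if (any(parts[, 2L] <= parts[, 1L]))
    stop("feature '", name, "': empty or inverted interval")
  o <- order(parts[, 1L])
  if (any(parts[o, 2L][-nrow(parts)] > parts[o, 1L][-1L]))
    stop("feature '", name, "': overlapping parts")
  structure(list(name = name, kind = kind, strand = strand, parts = parts,
                 pseudo = isTRUE(pseudo) || kind == "pseudogene",
                 trans_spliced = isTRUE(trans_spliced), copy = as.integer(copy)),
            class = "gene_feature")
}

#' Construct an annotated plastome record
#'
#' The central container every analysis stage consumes: a circular (usually)
#' DNA sequence over `{A,C,G,T,N}` plus a list of [gene_feature()]s.
#'
#' @param id Accession or identifier string.
#' @param sequence DNA character scalar.
#' @param circular Logical; the molecule is circular.
#' @param features List of [gene_feature()] objects.
#' @return A `plastome_record` list with elements `id`, `sequence`,
#'   `circular`, `features`.
#' @export
plastome_record <- function(id, sequence, circular = TRUE, features = list()) {
  sequence <- toupper(sequence)
  .check_dna(sequence)
  len <- nchar(sequence)
  for (f in features) {
    if (!inherits(f, "gene_feature")) stop("features must be gene_feature objects")
    if (any(f$parts < 0L) || any(f$parts > len))
      stop("feature '", f$name, "' outside [0, ", len, ")")
  }
  keys <- vapply(features, function(f) paste0(f$name, "#", f$copy), "")
  if (anyDuplicated(keys))
    stop("duplicate (name, copy) pair: ", keys[duplicated(keys)][1L])
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular),
                 features = features),
            class = "plastome_record")
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s: %s bp, %s, %d features\n",
              x$id, format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear", length(x$features)))
  if (length(x$features)) {
    kinds <- table(vapply(x$features, `[[`, "", "kind"))
    cat("  ", paste(names(kinds), kinds, sep = ": ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.plastome_record <- function(x) nchar(x$sequence)

.find_feature <- function(record, gene, kind = NULL) {
  hits <- Filter(function(f) f$name == gene &&
                   (is.null(kind) || f$kind %in% kind), record$features)
  hits
}

## ---- GenBank flat file ----------------------------------------------------

#' Read an annotated plastome
#'
#' Reads a GenBank flat file or a FASTA file. GenBank 1-based inclusive
#' locations (including `join(...)` and `complement(...)`) are converted to
#' 0-based half-open exon intervals; a `/pseudo` qualifier maps the feature
#' to kind `"pseudogene"`. FASTA input yields a feature-less record. A
#' feature location spanning the origin of the circular sequence is
#' normalized by rotating the sequence so every interval is linear; the
#' applied rotation is recorded in the `rotation` attribute.
#'
#' @param path Path to a `.gb`/`.gbk`/`.genbank` or FASTA file.
#' @param format `"auto"` (by extension/content), `"genbank"` or `"fasta"`.
#' @return A [plastome_record()].
#' @export
read_plastome <- function(path, format = c("auto", "genbank", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, ">")) "fasta" else "genbank"
  }
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) != 1L) stop("expected exactly one sequence in ", path)
    id <- sub("\\s.*$", "", names(ss)[1L])
    return(plastome_record(id, as.character(ss[[1L]])))
  }
  .read_genbank(path)
}

# GenBank location grammar restricted to what plastome annotations use:
# n..m, complement(...), join(...), order(...) (treated as join).
.parse_location <- function(loc, feature_label) {
  loc <- gsub("[[:space:]]", "", loc)
  strand <- "+"
  if (startsWith(loc, "complement(")) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  if (grepl("complement", loc, fixed = TRUE)) {
    # mixed-strand joins (trans-spliced): strip inner complements, mark minus
    strand <- "-"
    loc <- gsub("complement\\(([^)]*)\\)", "\\1", loc)
  }
  pieces <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  m <- regmatches(pieces, regexec("^[<>]?([0-9]+)\\.\\.[<>]?([0-9]+)$", pieces))
  single <- grepl("^[0-9]+$", pieces)
  starts <- ends <- integer(length(pieces))
  for (i in seq_along(pieces)) {
    if (single[i]) {
      starts[i] <- ends[i] <- as.integer(pieces[i])
    } else if (length(m[[i]]) == 3L) {
      starts[i] <- as.integer(m[[i]][2L]); ends[i] <- as.integer(m[[i]][3L])
    } else {
      stop("malformed location for feature '", feature_label, "': ", loc)
    }
  }
  list(strand = strand, starts = starts, ends = ends)
}

.read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS line): ", path)
  toks <- strsplit(trimws(locus[1L]), "[[:space:]]+")[[1L]]
  id <- toks[2L]
  stated_len <- suppressWarnings(as.integer(toks[3L]))
  circular <- any(grepl("circular", locus[1L], ignore.case = TRUE))

  # sequence
  oi <- grep("^ORIGIN", lines)
  if (!length(oi)) stop("no ORIGIN section in ", path)
  seq_lines <- lines[(oi[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!is.na(stated_len) && nchar(sequence) != stated_len)
    stop("sequence length ", nchar(sequence), " disagrees with LOCUS length ",
         stated_len, " in ", path)

  # features
  fi <- grep("^FEATURES", lines)
  features <- list()
  if (length(fi)) {
    block <- lines[(fi[1L] + 1L):(oi[1L] - 1L)]
    starts_feat <- grepl("^ {5}\\S", block)
    idx <- which(starts_feat)
    copy_counter <- new.env(parent = emptyenv())
    for (k in seq_along(idx)) {
      from <- idx[k]
      to <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
      entry <- block[from:to]
      key <- sub("^ {5}(\\S+).*$", "\\1", entry[1L])
      if (!key %in% c("CDS", "tRNA", "rRNA")) next
      # location may continue over lines until the first /qualifier
      qual_at <- grep("^ {21}/", entry)
      loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(entry)
      loc <- paste(c(sub("^ {5}\\S+\\s+", "", entry[1L]),
                     trimws(entry[seq_len(loc_end)[-1L]])), collapse = "")
      quals <- trimws(entry[qual_at])
      getq <- function(q) {
        hit <- grep(paste0("^/", q, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub("\"", "", sub(paste0("^/", q, "="), "", hit[1L]))
      }
      name <- getq("gene")
      if (is.na(name)) name <- getq("locus_tag")
      if (is.na(name)) name <- paste0(key, "_", k)
      p <- .parse_location(loc, name)
      pseudo <- any(grepl("^/pseudo$|^/pseudo\\b", quals))
      trans <- any(grepl("trans.?splic", quals, ignore.case = TRUE))
      n_prev <- get0(name, envir = copy_counter, ifnotfound = 0L)
      assign(name, n_prev + 1L, envir = copy_counter)
      kind <- if (pseudo) "pseudogene" else key
      features[[length(features) + 1L]] <-
        list(name = name, kind = kind, strand = p$strand,
             starts = p$starts - 1L, ends = p$ends,  # 0-based half-open
             pseudo = pseudo, trans_spliced = trans, copy = n_prev + 1L)
    }
  }

  .normalize_origin_spanning(sequence, features, id, circular)
}

# Rotate the sequence so that no feature wraps past the end, then build the
# validated record. A feature spans the origin when a single location pair
# arrives inverted (e.g. 156001..200) or when the exon starts of a join are
# not ascending in file order (e.g. join(156001..156637,1..200)).
.normalize_origin_spanning <- function(sequence, raw, id, circular) {
  len <- nchar(sequence)
  spans <- vapply(raw, function(f) {
    any(f$starts >= f$ends) || any(f$ends > len) ||
      (length(f$starts) > 1L && is.unsorted(f$starts, strictly = TRUE))
  }, TRUE)
  rotation <- 0L
  if (any(spans)) {
    if (!circular) stop("feature interval beyond sequence end on a linear molecule")
    rotation <- raw[[which(spans)[1L]]]$starts[1L]
    sequence <- paste0(substring(sequence, rotation + 1L, len),
                       substring(sequence, 1L, rotation))
    raw <- lapply(raw, function(f) {
      f$starts <- (f$starts - rotation) %% len
      f$ends <- (f$ends - 1L - rotation) %% len + 1L   # ends exclusive, may be len
      if (any(f$starts >= f$ends))
        stop("feature '", f$name, "' still wraps after rotation; ",
             "multiple origin-spanning features are not supported")
      f
    })
  }
  features <- lapply(raw, function(f)
    gene_feature(f$name, f$kind, f$strand, cbind(f$starts, f$ends),
                 pseudo = f$pseudo, trans_spliced = f$trans_spliced,
                 copy = f$copy))
  rec <- plastome_record(id, sequence, circular, features)
  attr(rec, "rotation") <- rotation
  rec
}

#' Write a plastome record as a GenBank flat file
#'
#' Emits LOCUS, FEATURES (gene/CDS/tRNA/rRNA with `join()`/`complement()`
#' locations, 1-based inclusive) and ORIGIN sections. Only the qualifiers the
#' package itself consumes are written: `/gene` and `/pseudo`.
#'
#' @param record A [plastome_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  len <- nchar(record$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  # fixed date keeps equal records byte-identical on disk
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN 01-JAN-2026",
                     record$id, len,
                     if (record$circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s plastid genome.", record$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", len), con)
  for (f in record$features) {
    segs <- sprintf("%d..%d", f$parts[, 1L] + 1L, f$parts[, 2L])
    loc <- if (length(segs) > 1L) paste0("join(", paste(segs, collapse = ","), ")") else segs
    if (f$strand == "-") loc <- paste0("complement(", loc, ")")
    key <- if (f$kind == "pseudogene") "CDS" else f$kind
    writeLines(sprintf("     %-15s %s", key, loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name), con)
    if (f$pseudo) writeLines("                     /pseudo", con)
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, len, by = 60L)
  for (p in pos) {
    chunk <- substring(record$sequence, p, min(p + 59L, len))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(blocks, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Write the sequence of a record as FASTA
#' @param record A [plastome_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(record, path) {
  ss <- Biostrings::DNAStringSet(setNames(record$sequence, record$id))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

## ---- GFF3 (alternative annotation carrier) --------------------------------

#' Write annotation as GFF3
#'
#' One `gene` line per feature plus one `CDS`/`tRNA`/`rRNA` line per exon,
#' linked by `Parent`; coordinates 1-based inclusive per the GFF3 spec.
#'
#' @param record A [plastome_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", record$id,
                     nchar(record$sequence)), con)
  for (f in record$features) {
    gid <- sprintf("gene-%s-%d", f$name, f$copy)
    span <- c(min(f$parts[, 1L]) + 1L, max(f$parts[, 2L]))
    attrs <- sprintf("ID=%s;Name=%s", gid, f$name)
    if (f$pseudo) attrs <- paste0(attrs, ";pseudo=true")
    writeLines(paste(record$id, "plastedit", "gene", span[1L], span[2L], ".",
                     f$strand, ".", attrs, sep = "\t"), con)
    type <- if (f$kind == "pseudogene") "CDS" else f$kind
    for (i in seq_len(nrow(f$parts))) {
      writeLines(paste(record$id, "plastedit", type,
                       f$parts[i, 1L] + 1L, f$parts[i, 2L], ".", f$strand,
                       if (type == "CDS") "0" else ".",
                       sprintf("ID=%s.e%d;Parent=%s;Name=%s", gid, i, gid, f$name),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read annotation from FASTA + GFF3
#'
#' @param fasta_path FASTA file with the single genome sequence.
#' @param gff_path GFF3 annotation as written by [write_gff3()] (gene lines
#'   with `ID`, exon lines with `Parent`).
#' @return A [plastome_record()].
#' @export
read_gff3 <- function(fasta_path, gff_path) {
  rec <- read_plastome(fasta_path, "fasta")
  g <- read.delim(gff_path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE,
                  col.names = c("seqid", "source", "type", "start", "end",
                                "score", "strand", "phase", "attr"))
  getattr <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0("(^|;)", key, "=([^;]*)"), attr))
    vapply(m, function(x) if (length(x) == 3L) x[3L] else NA_character_, "")
  }
  genes <- g[g$type == "gene", , drop = FALSE]
  exons <- g[g$type %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  exons$parent <- getattr(exons$attr, "Parent")
  feats <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- getattr(genes$attr[i], "ID")
    name <- getattr(genes$attr[i], "Name")
    pseudo <- identical(getattr(genes$attr[i], "pseudo"), "true")
    ex <- exons[exons$parent == gid, , drop = FALSE]
    if (!nrow(ex)) next
    kind <- if (pseudo) "pseudogene" else ex$type[1L]
    copy <- as.integer(sub(".*-", "", gid))
    feats[[length(feats) + 1L]] <-
      gene_feature(name, kind, genes$strand[i],
                   cbind(ex$start - 1L, ex$end), pseudo = pseudo, copy = copy)
  }
  plastome_record(rec$id, rec$sequence, TRUE, feats)
}

## ---- CDS extraction -------------------------------------------------------

#' Extract a spliced, strand-oriented coding sequence
#'
#' Concatenates the exon intervals of a CDS in transcription order
#' (minus-strand genes are reverse-complemented) and builds the per-base map
#' from CDS coordinate back to genome position, so that a genome-coordinate
#' pileup site can be assigned a codon index and within-codon offset.
#'
#' @param record A [plastome_record()].
#' @param gene Gene symbol; must exist with kind `"CDS"` (set
#'   `allow_pseudo = TRUE` to extract an annotated pseudogene copy).
#' @param copy Copy index when the gene is IR-duplicated.
#' @param allow_pseudo Extract even if annotated `/pseudo`.
#' @return A `coding_sequence` list: `gene`, `seq` (coding-strand DNA),
#'   `strand`, `genome_pos` (integer vector, 0-based genome position of each
#'   CDS base).
#' @export
extract_cds <- function(record, gene, copy = 1L, allow_pseudo = FALSE) {
  hits <- .find_feature(record, gene,
                        kind = if (allow_pseudo) c("CDS", "pseudogene") else "CDS")
  hits <- Filter(function(f) f$copy == copy, hits)
  if (!length(hits))
    stop("gene '", gene, "' (copy ", copy, ") not found as CDS in ", record$id)
  f <- hits[[1L]]
  parts <- f$parts[order(f$parts[, 1L]), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(parts)),
                       function(i) seq.int(parts[i, 1L], parts[i, 2L] - 1L)))
  seq <- paste0(substring(record$sequence, parts[, 1L] + 1L, parts[, 2L]),
                collapse = "")
  if (f$strand == "-") {
    seq <- .revcomp(seq)
    pos <- rev(pos)
  }
  if (anyDuplicated(pos)) stop("gene '", gene, "': genome map not injective")
  structure(list(gene = gene, seq = seq, strand = f$strand, genome_pos = pos,
                 pseudo = f$pseudo),
            class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s (%s strand): %d bp, %s codons\n",
              x$gene, x$strand, nchar(x$seq),
              if (nchar(x$seq) %% 3L == 0L) nchar(x$seq) %/% 3L else "non-integral"))
  invisible(x)
}

#' Translate a coding sequence
#' @param cds A `coding_sequence` from [extract_cds()].
#' @param trim_stop Drop the terminal stop residue if present.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds, trim_stop = TRUE) {
  aa <- .translate(cds$seq)
  if (trim_stop && nchar(aa) && substring(aa, nchar(aa)) == "*")
    aa <- substring(aa, 1L, nchar(aa) - 1L)
  aa
}
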