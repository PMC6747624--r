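.start_codons <- c("ATG", "GTG")   # plastid convention: GTG accepted as start
.stop_codons <- c("TAA", "TAG", "TGA")

.cds_intact <- function(cds) {
  L <- nchar(cds$seq)
  if (L < 6L || L %% 3L != 0L) return(FALSE)
  first <- substring(cds$seq, 1L, 3L)
  last <- substring(cds$seq, L - 2L, L)
  if (!first %in% .start_codons || !last %in% .stop_codons) return(FALSE)
  aa <- .translate(substring(cds$seq, 1L, L - 3L))
  !grepl("*", aa, fixed = TRUE)
}

#' Classify the status of a gene in a plastome
#'
#' `intact` iff an annotated copy exists whose spliced sequence starts with
#' a start codon (ATG/GTG), ends with a stop, has length divisible by 3 and
#' no internal stop — a frameshifting insertion (e.g. 22 bp) fails the
#' length-mod-3 test. `pseudogene` iff every annotated copy violates one of
#' these or carries the pseudo flag. `absent` when no copy is annotated.
#' IR-duplicated copies count once toward the unique-gene tally; for non-CDS
#' kinds (tRNA/rRNA) an annotated non-pseudo copy counts as intact.
#'
#' @param record A [plastome_record()].
#' @param gene Gene symbol.
#' @param reference_length Optional expected CDS length (bp) — intact genes
#'   deviating by more than 25% are flagged `length_anomaly`.
#' @return A `gene_status` list: `gene`, `status` (`"intact"`,
#'   `"pseudogene"`, `"absent"`), `copies`, `intron_count`,
#'   `length_anomaly`.
#' @export
classify_gene_status <- function(record, gene, reference_length = NA) {
  hits <- .find_feature(record, gene)
  if (!length(hits))
    return(structure(list(gene = gene, status = "absent", copies = 0L,
                          intron_count = NA_integer_, length_anomaly = FALSE),
                     class = "gene_status"))
  intact <- logical(length(hits))
  lens <- integer(length(hits))
  for (i in seq_along(hits)) {
    f <- hits[[i]]
    lens[i] <- sum(f$parts[, 2L] - f$parts[, 1L])
    if (f$pseudo) { intact[i] <- FALSE; next }
    if (f$kind %in% c("tRNA", "rRNA")) { intact[i] <- TRUE; next }
    cds <- extract_cds(record, gene, copy = f$copy)
    intact[i] <- .cds_intact(cds)
  }
  status <- if (any(intact)) "intact" else "pseudogene"
  best <- if (any(intact)) which(intact)[1L] else 1L
  introns <- nrow(hits[[best]]$parts) - 1L
  anomaly <- !is.na(reference_length) && status == "intact" &&
    abs(lens[best] - reference_length) / reference_length > 0.25
  structure(list(gene = gene, status = status, copies = length(hits),
                 intron_count = introns, length_anomaly = anomaly),
            class = "gene_status")
}

#' @export
print.gene_status <- function(x, ...) {
  cat(sprintf("<gene_status> %s: %s (%d cop%s, %s intron%s%s)\n",
              x$gene, x$status, x$copies, if (x$copies == 1) "y" else "ies",
              ifelse(is.na(x$intron_count), "?", x$intron_count),
              ifelse(identical(x$intron_count, 1L), "", "s"),
              if (isTRUE(x$length_anomaly)) ", length anomaly" else ""))
  invisible(x)
}

#' Compare gene complements of two plastomes
#'
#' Per-gene status in both genomes over a reference gene list (default: the
#' union of annotated gene names), with the differences partitioned into
#' genes lost in either genome, genes pseudogenized in exactly one, and
#' genes with differing intron counts. IR-duplicated genes are counted once
#' in the unique intact-gene tallies.
#'
#' @param a,b Annotated [plastome_record()]s.
#' @param reference_genes Character vector of gene symbols, or `NULL`.
#' @return A `gene_comparison` list: `table` (data.frame gene/status_a/
#'   status_b/introns_a/introns_b), `intact_unique_a`, `intact_unique_b`,
#'   `lost_in_a`, `lost_in_b`, `pseudogenized_a`, `pseudogenized_b`,
#'   `intron_losses`.
#' @export
compare_gene_sets <- function(a, b, reference_genes = NULL) {
  if (is.null(reference_genes)) {
    reference_genes <- sort(unique(c(
      vapply(a$features, `[[`, "", "name"),
      vapply(b$features, `[[`, "", "name"))))
  }
  rows <- lapply(reference_genes, function(g) {
    sa <- classify_gene_status(a, g)
    sb <- classify_gene_status(b, g)
    data.frame(gene = g, status_a = sa$status, status_b = sb$status,
               introns_a = sa$intron_count, introns_b = sb$intron_count,
               stringsAsFactors = FALSE)
  })
  tb <- do.call(rbind, rows)
  lost_in_a <- tb$gene[tb$status_a == "absent" & tb$status_b != "absent"]
  lost_in_b <- tb$gene[tb$status_b == "absent" & tb$status_a != "absent"]
  pseudo_a <- tb$gene[tb$status_a == "pseudogene" & tb$status_b == "intact"]
  pseudo_b <- tb$gene[tb$status_b == "pseudogene" & tb$status_a == "intact"]
  both <- !is.na(tb$introns_a) & !is.na(tb$introns_b)
  intron_losses <- tb$gene[both & tb$introns_a != tb$introns_b]
  structure(list(table = tb,
                 intact_unique_a = sum(tb$status_a == "intact"),
                 intact_unique_b = sum(tb$status_b == "intact"),
                 lost_in_a = lost_in_a, lost_in_b = lost_in_b,
                 pseudogenized_a = pseudo_a, pseudogenized_b = pseudo_b,
                 intron_losses = intron_losses),
            class = "gene_comparison")
}

#' @export
print.gene_comparison <- function(x, ...) {
  cat(sprintf("<gene_comparison> %d genes | intact: %d vs %d\n",
              nrow(x$table), x$intact_unique_a, x$intact_unique_b))
  if (length(x$lost_in_a)) cat("  lost in A:", paste(x$lost_in_a, collapse = ", "), "\n")
  if (length(x$lost_in_b)) cat("  lost in B:", paste(x$lost_in_b, collapse = ", "), "\n")
  if (length(x$pseudogenized_a)) cat("  pseudo in A:", paste(x$pseudogenized_a, collapse = ", "), "\n")
  if (length(x$pseudogenized_b)) cat("  pseudo in B:", paste(x$pseudogenized_b, collapse = ", "), "\n")
  if (length(x$intron_losses)) cat("  intron differences:", paste(x$intron_losses, collapse = ", "), "\n")
  invisible(x)
}

#' Gene-order breakpoint distance on the circle
#'
#' Signed circular gene orders are compared through their adjacency sets: an
#' adjacency is an ordered pair of signed genes, with `(x, y)` equivalent to
#' `(-y, -x)`. The distance is the number of adjacencies of `order_a` absent
#' from `order_b`, after restriction to the shared gene set. Zero iff the
#' orders are equivalent up to rotation and reflection with sign flip.
#'
#' @param order_a,order_b Character vectors of gene symbols in circular
#'   order; a leading `"-"` marks reverse orientation.
#' @return Integer breakpoint count.
#' @export
breakpoint_distance <- function(order_a, order_b) {
  strip <- function(x) sub("^-", "", x)
  shared <- intersect(strip(order_a), strip(order_b))
  if (length(shared) < 3L) stop("shared gene set has fewer than 3 genes")
  a <- order_a[strip(order_a) %in% shared]
  b <- order_b[strip(order_b) %in% shared]
  adj_set <- function(ord) {
    nxt <- c(ord[-1L], ord[1L])
    fwd <- paste(ord, nxt, sep = "|")
    flip <- function(g) ifelse(startsWith(g, "-"), sub("^-", "", g), paste0("-", g))
    rev_ <- paste(flip(nxt), flip(ord), sep = "|")
    # canonical form of each adjacency: lexicographic min of the two readings
    pmin(fwd, rev_)
  }
  sum(!adj_set(a) %in% adj_set(b))
}

#' Extract the signed circular gene order of a record
#'
#' Genes ordered by their leftmost genome coordinate; minus-strand genes
#' carry a leading `"-"`. IR-duplicated copies keep their copy suffix off —
#' each annotated copy appears at its own position.
#'
#' @param record A [plastome_record()].
#' @param unique_only Keep only the first copy of IR-duplicated genes.
#' @return Character vector of signed gene symbols in circular order.
#' @export
gene_order <- function(record, unique_only = FALSE) {
  feats <- record$features
  if (unique_only) feats <- Filter(function(f) f$copy == 1L, feats)
  starts <- vapply(feats, function(f) min(f$parts[, 1L]), 0L)
  feats <- feats[order(starts)]
  vapply(feats, function(f)
    paste0(if (f$strand == "-") "-" else "", f$name), "")
}
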