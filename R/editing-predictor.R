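#' Parameters for conservation-based editing-site prediction
#'
#' @param min_score Minimum fraction of informative homologs that must carry
#'   the edited residue (default 0.7).
#' @param require_nonsynonymous Only consider C positions whose C-to-U edit
#'   changes the encoded residue.
#' @return A `predictor_params` list.
#' @export
predictor_params <- function(min_score = 0.7, require_nonsynonymous = TRUE) {
  if (min_score <= 0 || min_score > 1) stop("min_score must be in (0, 1]")
  structure(list(min_score = min_score,
                 require_nonsynonymous = isTRUE(require_nonsynonymous)),
            class = "predictor_params")
}

.as_protein_set <- function(homologs) {
  if (length(homologs) == 0L) stop("homolog panel is empty")
  if (is.character(homologs) && length(homologs) == 1L && file.exists(homologs))
    homologs <- Biostrings::readAAStringSet(homologs)
  if (inherits(homologs, "AAStringSet")) {
    out <- as.character(homologs)
    names(out) <- sub("\\s.*$", "", names(homologs))
    return(out)
  }
  if (is.character(homologs)) {
    if (is.null(names(homologs)))
      names(homologs) <- paste0("homolog", seq_along(homologs))
    return(homologs)
  }
  stop("homologs must be a protein FASTA path, an AAStringSet, ",
       "or a named character vector")
}

# Align query protein to each homolog (global, affine gaps, BLOSUM62) and
# return a character matrix: rows = query residues, cols = homologs, entries
# = aligned homolog residue or "-" where the homolog is gapped.
.homolog_columns <- function(query, panel, min_aln_score = 0) {
  bl62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                          envir = environment()))
  qlen <- nchar(query)
  mat <- matrix("-", nrow = qlen, ncol = length(panel),
                dimnames = list(NULL, names(panel)))
  dropped <- character(0)
  for (h in seq_along(panel)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(query),
      subject = Biostrings::AAString(panel[[h]]),
      type = "global", substitutionMatrix = bl62,
      gapOpening = 10, gapExtension = 0.5)
    if (Biostrings::score(aln) < min_aln_score) {
      dropped <- c(dropped, names(panel)[h])
      next
    }
    qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    qpos <- cumsum(qa != "-")
    keep <- qa != "-"
    mat[qpos[keep], h] <- sa[keep]
  }
  if (length(dropped))
    warning("dropped unalignable homolog(s): ", paste(dropped, collapse = ", "))
  mat[, !colnames(mat) %in% dropped, drop = FALSE]
}

#' Predict C-to-U editing sites from homolog conservation
#'
#' The CDS translation is globally aligned (affine gaps, BLOSUM62) to every
#' homolog in the panel. For each C whose C-to-U edit changes the encoded
#' residue without creating an internal stop, the prediction score is the
#' fraction of informative homologs (non-gap at that column) whose aligned
#' residue equals the edited residue; positions scoring at least `min_score`
#' are returned.
#'
#' @param cds A `coding_sequence` from [extract_cds()] (intact CDS).
#' @param homologs Protein FASTA path, `AAStringSet`, or named character
#'   vector of homolog protein sequences (at least one).
#' @param params A [predictor_params()].
#' @return A data.frame sorted by codon: `gene`, `codon_index`,
#'   `unedited_aa`, `edited_aa`, `score`, `n_informative`, `cds_pos`
#'   (1-based position of the C within the CDS), `genome_pos` (0-based).
#' @export
predict_editing_sites <- function(cds, homologs, params = predictor_params()) {
  panel <- .as_protein_set(homologs)
  if (!length(panel)) stop("homolog panel is empty")
  if (nchar(cds$seq) %% 3L != 0L) stop("CDS length not divisible by 3")
  query <- translate_cds(cds)
  cols <- .homolog_columns(query, panel)
  if (!ncol(cols)) stop("no alignable homolog in the panel")

  chars <- strsplit(cds$seq, "", fixed = TRUE)[[1L]]
  c_pos <- which(chars == "C")
  res <- list()
  for (ci in c_pos) {
    codon_index <- (ci - 1L) %/% 3L + 1L
    if (codon_index > nchar(query)) next   # terminal stop codon
    offset <- (ci - 1L) %% 3L + 1L
    cstart <- (codon_index - 1L) * 3L + 1L
    codon <- paste0(chars[cstart:(cstart + 2L)], collapse = "")
    edited <- codon
    substring(edited, offset, offset) <- "T"
    o <- .codon_aa(codon); e <- .codon_aa(edited)
    if (e == "*") next
    if (params$require_nonsynonymous && e == o) next
    col <- cols[codon_index, ]
    informative <- col != "-"
    if (!any(informative)) next
    score <- sum(col[informative] == e) / sum(informative)
    if (score < params$min_score) next
    res[[length(res) + 1L]] <- data.frame(
      gene = cds$gene, codon_index = codon_index, unedited_aa = o,
      edited_aa = e, score = score, n_informative = sum(informative),
      cds_pos = ci, genome_pos = cds$genome_pos[ci], stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(gene = character(0), codon_index = integer(0),
                      unedited_aa = character(0), edited_aa = character(0),
                      score = numeric(0), n_informative = integer(0),
                      cds_pos = integer(0), genome_pos = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$codon_index, out$cds_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
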