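test_that("GenBank round trip preserves sequence and annotation", {
  cfg <- sim_config(seed = 21, lsc = 6000, ir = 2200, ssc = 2500,
                    pseudogenize = list(list(gene = "ccsA", indel = 22)))
  truth <- simulate_plastome(cfg)
  gb <- tempfile(fileext = ".gb")
  write_genbank(truth$record, gb)
  rec2 <- read_plastome(gb)
  expect_identical(rec2$sequence, truth$record$sequence)
  expect_identical(rec2$id, truth$record$id)
  expect_true(rec2$circular)
  expect_equal(length(rec2$features), length(truth$record$features))
  for (i in seq_along(rec2$features)) {
    f1 <- truth$record$features[[i]]; f2 <- rec2$features[[i]]
    expect_identical(f2$name, f1$name)
    expect_identical(f2$strand, f1$strand)
    expect_identical(unname(f2$parts), unname(f1$parts))
    expect_identical(f2$pseudo, f1$pseudo)
  }
})

test_that("FASTA input yields a feature-less record", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">chr_test some description",
               substring(rand_dna(1000, seed = 4), 1, 1000)), fa)
  rec <- read_plastome(fa)
  expect_equal(nchar(rec$sequence), 1000)
  expect_identical(rec$id, "chr_test")
  expect_length(rec$features, 0)
})

test_that("GFF3 round trip reconstructs multi-exon and pseudo features", {
  cfg <- sim_config(seed = 22, lsc = 6000, ir = 2200, ssc = 2500,
                    pseudogenize = list(list(gene = "rps14", indel = 22)))
  truth <- simulate_plastome(cfg)
  fa <- tempfile(fileext = ".fasta"); gff <- tempfile(fileext = ".gff3")
  write_fasta(truth$record, fa)
  write_gff3(truth$record, gff)
  rec2 <- read_gff3(fa, gff)
  expect_equal(length(rec2$features), length(truth$record$features))
  atpf1 <- plastedit:::.find_feature(truth$record, "atpF")[[1]]
  atpf2 <- plastedit:::.find_feature(rec2, "atpF")[[1]]
  expect_identical(unname(atpf2$parts), unname(atpf1$parts))
  expect_equal(nrow(atpf2$parts), 2)  # intron preserved
  expect_true(plastedit:::.find_feature(rec2, "rps14")[[1]]$pseudo)
})

test_that("sequences with ambiguity codes other than N are rejected", {
  expect_error(plastome_record("x", "ACGTRY"), "outside")
  expect_silent(plastome_record("x", "ACGTN"))
})

test_that("malformed GenBank locations raise an error naming the feature", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c("LOCUS       BAD1 12 bp    DNA     circular PLN 01-JAN-2026",
               "FEATURES             Location/Qualifiers",
               "     CDS             join(1..oops)",
               "                     /gene=\"badgene\"",
               "ORIGIN",
               "        1 acgtacgtac gt",
               "//"), gb)
  expect_error(read_plastome(gb), "badgene")
})

test_that("LOCUS length mismatch is an integrity error", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c("LOCUS       BAD2 99 bp    DNA     circular PLN 01-JAN-2026",
               "ORIGIN",
               "        1 acgtacgtac gt",
               "//"), gb)
  expect_error(read_plastome(gb), "disagrees")
})

test_that("extract_cds handles strand, splicing and the genome map", {
  # minus-strand 2-exon gene of lengths 100 + 50 -> 150 bp, 50 codons
  set.seed(9)
  e1 <- rand_dna(100); intr <- rand_dna(40); e2 <- rand_dna(50)
  gseq <- revcomp_chr(paste0(e1, intr, e2))
  genome <- paste0(rand_dna(30), gseq, rand_dna(30))
  # in genome coordinates the transcription-last exon comes first
  f <- gene_feature("m2", "CDS", "-",
                    rbind(c(30L, 30L + 50L),
                          c(30L + 90L, 30L + 190L)))
  rec <- plastome_record("t", genome, TRUE, list(f))
  cds <- extract_cds(rec, "m2")
  expect_equal(nchar(cds$seq), 150)
  expect_identical(cds$seq, paste0(e1, e2))
  expect_equal(length(cds$genome_pos), 150)
  expect_false(anyDuplicated(cds$genome_pos) > 0)

  # plus-strand single-exon CDS starting at genome position p: identity map
  f2 <- gene_feature("p1", "CDS", "+", cbind(30L, 30L + 51L))
  rec2 <- plastome_record("t2", genome, TRUE, list(f2))
  cds2 <- extract_cds(rec2, "p1")
  expect_equal(cds2$genome_pos[1], 30)
  expect_equal(cds2$genome_pos, 30:80)
  # genome map inverse: CDS base at position mapping back to itself
  for (k in c(1, 25, 51))
    expect_identical(substring(rec2$sequence, cds2$genome_pos[k] + 1,
                               cds2$genome_pos[k] + 1),
                     substring(cds2$seq, k, k))
  expect_error(extract_cds(rec2, "nosuch"), "not found")
})

test_that("planted CDS translations match the generator's recorded proteins", {
  truth <- simulate_plastome(sim_config(seed = 23, lsc = 6000, ir = 2200,
                                        ssc = 2500))
  cds_rows <- truth$genes[truth$genes$kind == "CDS" & !truth$genes$pseudo, ]
  for (i in seq_len(nrow(cds_rows))) {
    cds <- extract_cds(truth$record, cds_rows$gene[i], copy = cds_rows$copy[i])
    expect_identical(translate_cds(cds), cds_rows$protein[i])
    expect_false(grepl("*", cds_rows$protein[i], fixed = TRUE))
  }
})

test_that("origin-spanning features are normalized by rotation", {
  gb <- tempfile(fileext = ".gb")
  # 60 bp circle, CDS spanning the origin: join(51..60,1..21) on plus strand
  set.seed(5)
  nonstop <- setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                           paste0), c("A","C","G","T"), paste0)),
                     c("TAA", "TAG", "TGA"))
  cds <- paste(c("ATG", sample(nonstop, 8, TRUE), "TAA"), collapse = "")
  backbone <- rand_dna(30)
  seqs <- paste0(substring(cds, 11, 30), backbone, substring(cds, 1, 10))
  writeLines(c("LOCUS       WRAP1 60 bp    DNA     circular PLN 01-JAN-2026",
               "FEATURES             Location/Qualifiers",
               "     CDS             join(51..60,1..20)",
               "                     /gene=\"wrapg\"",
               "ORIGIN",
               paste0("        1 ", tolower(seqs)),
               "//"), gb)
  rec <- read_plastome(gb)
  expect_gt(attr(rec, "rotation"), 0)
  cds_out <- extract_cds(rec, "wrapg")
  expect_identical(cds_out$seq, cds)
})
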