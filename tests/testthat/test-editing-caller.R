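test_that("read identity filter keeps 99.2% and drops 97.6% reads", {
  set.seed(81)
  rec <- plastome_record("REF1", rand_dna(400), TRUE,
                         list(gene_feature("g", "CDS", "+", cbind(60L, 360L))))
  mk_read <- function(pos, len, n_mismatch) {
    seqs <- strsplit(substring(rec$sequence, pos, pos + len - 1), "")[[1]]
    flip <- sample(len, n_mismatch)
    for (p in flip) seqs[p] <- setdiff(c("A", "C", "G", "T"), seqs[p])[1]
    list(pos = pos, seq = paste(seqs, collapse = ""),
         cigar = sprintf("%dM", len))
  }
  sam <- write_test_sam(rec, list(mk_read(50, 250, 2),   # identity 0.992
                                  mk_read(80, 250, 6)),  # identity 0.976
                        tempfile(fileext = ".sam"))
  pu <- build_pileup(sam, rec)
  expect_equal(attr(pu, "n_passing"), 1)
  # only the first read's positions are covered
  expect_equal(range(pu$pos), c(49, 298))
})

test_that("soft-clipped, unmapped and secondary alignments are excluded", {
  rec <- plastome_record("REF2", rand_dna(300, seed = 82), TRUE,
                         list(gene_feature("g", "CDS", "+", cbind(30L, 270L))))
  exact <- function(pos, len) substring(rec$sequence, pos, pos + len - 1)
  reads <- list(
    list(pos = 20, seq = exact(20, 100), cigar = "100M"),
    list(pos = 40, seq = paste0("ACGTT", exact(40, 95)), cigar = "5S95M"),
    list(pos = 60, seq = exact(60, 100), cigar = "100M", flag = 4L),    # unmapped
    list(pos = 80, seq = exact(80, 100), cigar = "100M", flag = 256L))  # secondary
  sam <- write_test_sam(rec, reads, tempfile(fileext = ".sam"))
  pu <- build_pileup(sam, rec)
  expect_equal(attr(pu, "n_passing"), 1)
  pu2 <- build_pileup(sam, rec, editing_filter_params(forbid_softclip = FALSE))
  expect_equal(attr(pu2, "n_passing"), 2)
})

test_that("reference id mismatches are an integrity error", {
  rec <- plastome_record("REFA", rand_dna(200, seed = 83), TRUE,
                         list(gene_feature("g", "CDS", "+", cbind(10L, 190L))))
  other <- plastome_record("REFB", rec$sequence, TRUE, rec$features)
  sam <- write_test_sam(rec, list(list(pos = 20,
                                       seq = substring(rec$sequence, 20, 119),
                                       cigar = "100M")),
                        tempfile(fileext = ".sam"))
  expect_error(build_pileup(sam, other), "does not match")
})

test_that("site thresholds follow the strict filter cascade", {
  # CDS with a known C at codon 10, position 2 (codon CCA)
  codons <- c("ATG", rep("GAA", 8), "CCA", rep("GAA", 9), "TAA")
  cds_seq <- paste(codons, collapse = "")
  seqs <- paste0(rand_dna(50, seed = 84), cds_seq, rand_dna(50))
  rec <- plastome_record("REF3", seqs, TRUE,
                         list(gene_feature("g1", "CDS", "+",
                                           cbind(50L, 50L + nchar(cds_seq)))))
  c_pos <- 50L + 9L * 3L + 1L   # 0-based genome position of the edited C
  mk_pileup <- function(depth, alt) {
    pu <- data.frame(pos = c_pos, ref = "C",
                     A = 0L, C = depth - alt, G = 0L, T = alt)
    pu$depth <- depth
    class(pu) <- c("pileup_counts", "data.frame")
    pu
  }
  # depth 40, 3 alt reads (7.5%): fails both strict thresholds
  expect_equal(nrow(call_editing_sites(mk_pileup(40, 3), rec)), 0)
  # depth 10, 2 alt (20%): fails the > 3 reads rule
  expect_equal(nrow(call_editing_sites(mk_pileup(10, 2), rec)), 0)
  # depth 30, 4 alt (13.3%): passes everything
  called <- call_editing_sites(mk_pileup(30, 4), rec)
  expect_equal(nrow(called), 1)
  expect_identical(called$codon_display, "CcA")
  expect_identical(called$aa_change, "P=>L")
  expect_equal(called$codon_index, 10)
  expect_equal(called$frequency, 4 / 30)
  # depth 9 at 44% alt: fails the depth floor
  expect_equal(nrow(call_editing_sites(mk_pileup(9, 4), rec)), 0)
  # exactly 10% alt fraction is not enough (strict inequality): 40 deep, 4 alt
  expect_equal(nrow(call_editing_sites(mk_pileup(40, 4), rec)), 0)
})

test_that("codon effects are annotated with the edited base lower-case", {
  mk_cds <- function(codon) {
    seqs <- paste0("ATG", codon, "TAA")
    rec <- plastome_record("R", paste0("GG", seqs, "GG"), TRUE,
                           list(gene_feature("g", "CDS", "+",
                                             cbind(2L, 2L + nchar(seqs)))))
    extract_cds(rec, "g")
  }
  eff <- annotate_codon_effect(2L + 4L, mk_cds("CCA"))  # middle C of CCA
  expect_identical(eff$codon_display, "CcA")
  expect_identical(eff$aa_change, "P=>L")
  eff2 <- annotate_codon_effect(2L + 4L, mk_cds("TCT"))
  expect_identical(eff2$codon_display, "TcT")
  expect_identical(eff2$aa_change, "S=>F")
  eff3 <- annotate_codon_effect(2L + 5L, mk_cds("ACC"))  # third position
  expect_identical(eff3$codon_display, "ACc")
  expect_identical(eff3$aa_change, "synonymous")
  expect_error(annotate_codon_effect(2L + 3L, mk_cds("ACC")), "not C")
})

test_that("caller recovers planted sites on both strands from simulated reads", {
  cfg <- sim_config(seed = 85, lsc = 7000, ir = 2300, ssc = 2600,
    editing_plan = list(
      list(gene = "atpF", codon_index = 31, frequency = 0.9),
      list(gene = "rps2", codon_index = 100, frequency = 0.6),
      list(gene = "ndhD", codon_index = 200, frequency = 0.8),
      list(gene = "rpl23", codon_index = 40, frequency = 1.0)),
    coverage = 60, error_rate = 0.001)
  truth <- simulate_plastome(cfg)
  sam <- tempfile(fileext = ".sam")
  simulate_rnaseq_reads(truth, sam)
  pu <- build_pileup(sam, truth$record)
  sites <- call_editing_sites(pu, truth$record)
  expect_equal(nrow(sites), 4)
  expect_setequal(sites$gene, c("atpF", "rps2", "ndhD", "rpl23"))
  # minus-strand genes report C-to-U through the G-to-A reference change
  minus <- sites[sites$strand == "-", ]
  expect_setequal(minus$gene, c("ndhD", "rpl23"))
  expect_true(all(grepl("c", sites$codon_display)))
  # frequencies within 3 binomial SD of the planted values
  m <- merge(sites, truth$editing, by = c("gene", "codon_index"))
  expect_equal(nrow(m), 4)
  sd3 <- 3 * sqrt(m$frequency.y * (1 - m$frequency.y) / m$depth)
  expect_true(all(abs(m$frequency.x - m$frequency.y) <= pmax(sd3, 0.01)))
  # saturated site: effectively no reference reads
  sat <- sites[sites$gene == "rpl23", ]
  expect_gte(sat$frequency, 0.95)
})

test_that("any site whose counts clear the thresholds is called, and only those", {
  # 50 read-simulation replicates over one genome with 20 planted sites
  cfg <- sim_config(seed = 86, lsc = 5200, ir = 1200, ssc = 2600,
    gene_plan = list(
      list(name = "geneA", kind = "CDS", strand = "+", exons = 900L, region = "lsc"),
      list(name = "geneB", kind = "CDS", strand = "-", exons = 903L, region = "ssc"),
      list(name = "geneC", kind = "CDS", strand = "+", exons = 600L, region = "lsc")),
    planted_dispersed = list(), planted_tandem = list(),
    editing_plan = c(
      lapply(1:8, function(i) list(gene = "geneA", codon_index = 20 + 30 * i,
                                   frequency = 0.2 + 0.1 * (i %% 8))),
      lapply(1:8, function(i) list(gene = "geneB", codon_index = 15 + 30 * i,
                                   frequency = 1.0 - 0.1 * (i %% 8))),
      lapply(1:4, function(i) list(gene = "geneC", codon_index = 25 + 35 * i,
                                   frequency = 0.25 * i))),
    coverage = 40, error_rate = 0.001)
  truth <- simulate_plastome(cfg)
  params <- editing_filter_params()
  n_missed <- 0L; n_false <- 0L; n_clearing <- 0L
  freq_err <- c()
  for (rep_i in 1:50) {
    sam <- tempfile(fileext = ".sam")
    simulate_rnaseq_reads(truth, sam, seed = 1000L + rep_i)
    pu <- build_pileup(sam, truth$record, params)
    sites <- call_editing_sites(pu, truth$record, params)
    # planted-site counts measured directly from the pileup
    for (k in seq_len(nrow(truth$editing))) {
      gp <- truth$editing$genome_pos[k]
      row <- pu[match(gp, pu$pos), ]
      if (is.na(row$pos)) next
      alt <- if (truth$editing$strand[k] == "+") row$T else row$A
      clears <- row$depth >= params$min_depth &&
        alt > params$min_alt_reads && alt / row$depth > params$min_alt_fraction
      called <- gp %in% sites$genome_pos
      if (clears) {
        n_clearing <- n_clearing + 1L
        if (!called) n_missed <- n_missed + 1L
        est <- sites$frequency[match(gp, sites$genome_pos)]
        freq_err <- c(freq_err, est - truth$editing$frequency[k])
      }
    }
    n_false <- n_false + sum(!sites$genome_pos %in% truth$editing$genome_pos)
    unlink(sam)
  }
  expect_gt(n_clearing, 800)        # nearly all 20 sites clear in most replicates
  expect_equal(n_missed, 0)         # sensitivity 1.0 on clearing sites
  expect_equal(n_false, 0)          # no false calls at 0.1% error
  expect_lt(abs(mean(freq_err)), 0.01)  # unbiased within Monte-Carlo error
})

test_that("editing site TSV and VCF exports carry the report columns", {
  cfg <- sim_config(seed = 87, lsc = 6000, ir = 2000, ssc = 2400,
    editing_plan = list(list(gene = "rps2", codon_index = 60, frequency = 0.9)))
  truth <- simulate_plastome(cfg)
  sam <- tempfile(fileext = ".sam")
  simulate_rnaseq_reads(truth, sam)
  sites <- call_editing_sites(build_pileup(sam, truth$record), truth$record)
  tsv <- tempfile(fileext = ".tsv"); vcf <- tempfile(fileext = ".vcf")
  write_editing_tsv(sites, tsv)
  write_editing_vcf(sites, truth$record, vcf)
  tl <- readLines(tsv)
  expect_true(startsWith(tl[1], "# gene"))
  expect_equal(length(tl), 1 + nrow(sites))
  vl <- readLines(vcf)
  expect_true(any(grepl("^##fileformat", vl)))
  body <- vl[!startsWith(vl, "#")]
  expect_equal(length(body), nrow(sites))
  expect_true(all(grepl("GENE=rps2;FREQ=", body)))
})
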