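test_that("a planted exact duplication dominates the dispersed-repeat search", {
  set.seed(61)
  core <- rand_dna(300)
  seqs <- paste0(rand_dna(600), core, rand_dna(500), core, rand_dna(300))
  hits <- find_dispersed_repeats(seqs)
  expect_gt(nrow(hits), 0)
  top <- hits[1, ]
  expect_gte(top$length, 300)
  expect_identical(top$strand, "+")
  # union coverage counts both copies
  cov <- IRanges::reduce(IRanges::IRanges(
    start = c(hits$q_start, hits$s_start) + 1L, end = c(hits$q_end, hits$s_end)))
  expect_gte(sum(IRanges::width(cov)), 600)
  expect_lte(sum(IRanges::width(cov)), 680)   # X-drop may add chance-matching flanks
})

test_that("random sequence has no hits passing a strict E-value", {
  seqs <- rand_dna(200, seed = 62)
  hits <- find_dispersed_repeats(seqs, repeat_search_params(evalue_max = 1e-6))
  expect_equal(nrow(hits), 0)
})

test_that("every long exact repeat found by the DP oracle is covered by a hit", {
  set.seed(63)
  core1 <- rand_dna(60); core2 <- rand_dna(45)
  seqs <- paste0(rand_dna(120), core1, rand_dna(100), core2,
                 rand_dna(80), core1, rand_dna(60), core2, rand_dna(100))
  hits <- find_dispersed_repeats(seqs)
  exact <- oracle_exact_repeats(seqs, min_len = 40L)
  expect_gt(nrow(exact), 0)
  for (k in seq_len(nrow(exact))) {
    covered <- any(hits$strand == "+" &
                     hits$q_start <= exact$i[k] &
                     hits$q_end >= exact$i[k] + exact$len[k] &
                     hits$s_start <= exact$j[k] &
                     hits$s_end >= exact$j[k] + exact$len[k])
    expect_true(covered, label = sprintf("oracle repeat %d covered", k))
  }
})

test_that("inverted (reverse-strand) duplications are found and mapped back", {
  set.seed(64)
  core <- rand_dna(120)
  pre <- 300L
  seqs <- paste0(rand_dna(pre), core, rand_dna(250),
                 revcomp_chr(core), rand_dna(200))
  hits <- find_dispersed_repeats(seqs)
  minus <- hits[hits$strand == "-", ]
  expect_gt(nrow(minus), 0)
  top <- minus[1, ]
  expect_lte(top$q_start, pre)
  expect_gte(top$q_end, pre + 120)
  # the s interval must contain the reverse-complement copy
  expect_lte(top$s_start, pre + 120 + 250)
  expect_gte(top$s_end, pre + 120 + 250 + 120)
})

test_that("dispersed coverage is invariant under reverse complement", {
  set.seed(65)
  core <- rand_dna(200)
  seqs <- paste0(rand_dna(400), core, rand_dna(300), core, rand_dna(200))
  union_bp <- function(s) {
    h <- find_dispersed_repeats(s)
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(
      start = c(h$q_start, h$s_start) + 1L, end = c(h$q_end, h$s_end)))))
  }
  expect_equal(union_bp(seqs), union_bp(revcomp_chr(seqs)))
})

test_that("relaxing the E-value ceiling never decreases coverage", {
  set.seed(66)
  core <- rand_dna(80)
  seqs <- paste0(rand_dna(300), core, rand_dna(200), core, rand_dna(150))
  union_bp <- function(e) {
    h <- find_dispersed_repeats(seqs, repeat_search_params(evalue_max = e))
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(
      start = c(h$q_start, h$s_start) + 1L, end = c(h$q_end, h$s_end)))))
  }
  vals <- vapply(c(1e-12, 1e-9, 1e-6, 1e-3), union_bp, 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("tandem finder handles the minimal and boundary cases", {
  # "AC" x 10 = 20 bp: one run at the threshold
  tr <- find_tandem_repeats(strrep("AC", 10))
  expect_equal(nrow(tr), 1)
  expect_identical(tr$unit, "AC")
  expect_equal(tr$copies, 10)
  expect_equal(tr$span, 20)
  # two 18 bp arrays separated by one base: both below min_total = 20
  tr2 <- find_tandem_repeats(paste0(strrep("ACG", 6), "T", strrep("ACG", 6)))
  expect_equal(nrow(tr2), 0)
  # embedded in background they are found once min_total allows
  tr3 <- find_tandem_repeats(paste0(strrep("ACG", 6), "T", strrep("ACG", 6)),
                             tandem_params(min_total = 18))
  expect_equal(nrow(tr3), 2)
})

test_that("reported tandem units are primitive and canonically rotated", {
  tr <- find_tandem_repeats(paste0("TT", strrep("ACAC", 6), "GG"))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$unit_length, 2)
  expect_identical(tr$unit, "AC")
  # unit reported as least rotation: "GA" repeats -> "AG"
  tr2 <- find_tandem_repeats(paste0("CC", strrep("GA", 11), "TT"))
  expect_identical(tr2$unit, "AG")
})

test_that("N positions never match in tandem or dispersed search", {
  tr <- find_tandem_repeats(paste0(strrep("AN", 12)))
  expect_equal(nrow(tr), 0)
  h <- find_dispersed_repeats(paste0(strrep("N", 60), rand_dna(100, seed = 2)))
  expect_equal(sum(h$q_start < 60), 0)
})

test_that("tandem runs equal the exhaustive oracle on repeat-rich sequences", {
  for (s in 71:73) {
    set.seed(s)
    pieces <- c(rand_dna(150), strrep("AT", 12), rand_dna(90),
                strrep("GATC", 7), rand_dna(120), strrep("TTAGGC", 5),
                rand_dna(80), strrep("A", 25), rand_dna(150))
    seqs <- paste(pieces[sample(length(pieces))], collapse = "")
    got <- find_tandem_repeats(seqs)
    want <- oracle_tandem(seqs)
    expect_equal(got[c("start", "end", "unit_length", "unit", "copies", "span")],
                 want[c("start", "end", "unit_length", "unit", "copies", "span")])
  }
})

test_that("raising min_total never increases tandem coverage", {
  set.seed(74)
  seqs <- paste0(rand_dna(100), strrep("AGT", 12), rand_dna(50),
                 strrep("CT", 14), rand_dna(100))
  bp <- vapply(c(10, 20, 30, 40), function(mt) {
    tr <- find_tandem_repeats(seqs, tandem_params(min_total = mt))
    sum(tr$span)
  }, 0)
  expect_true(all(diff(bp) <= 0))
})

test_that("repeat_content_summary integrates truth-planted repeats", {
  cfg <- sim_config(seed = 75, lsc = 7000, ir = 2300, ssc = 2600,
                    planted_dispersed = list(c(400L, 2L)),
                    planted_tandem = list(list(unit = "ATGGC", copies = 8L)))
  truth <- simulate_plastome(cfg)
  part <- find_inverted_repeat(truth$record)
  rep_ <- repeat_content_summary(truth$record, part)
  expect_equal(rep_$analyzed_length, nchar(truth$record$sequence) - 2300)
  # both dispersed copies recovered (X-drop flanks allow slight overshoot)
  expect_gte(rep_$dispersed_bp, 800)
  expect_lte(rep_$dispersed_bp, 900)
  expect_gte(rep_$tandem_bp, 40)
  expect_equal(rep_$dispersed_pct,
               100 * rep_$dispersed_bp / rep_$analyzed_length)
  expect_equal(rep_$dispersed_pct_full,
               100 * rep_$dispersed_bp / rep_$full_length)
  # genome with no planted repeats: nothing above the E-value floor
  cfg0 <- sim_config(seed = 76, lsc = 6000, ir = 2000, ssc = 2400,
                     planted_dispersed = list(), planted_tandem = list())
  truth0 <- simulate_plastome(cfg0)
  rep0 <- repeat_content_summary(truth0$record,
                                 find_inverted_repeat(truth0$record))
  expect_equal(rep0$dispersed_bp, 0)
})
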