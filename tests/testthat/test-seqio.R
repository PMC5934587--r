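make_read <- function(bases, quals, id = "r1", ori = "forward")
  quality_read(id, bases, quals, ori)

test_that("quality trimming removes end runs, masks interior runs, and is idempotent", {
  # no base below threshold: unchanged
  r <- make_read(strrep("A", 100), rep(40L, 100))
  tr <- trim_low_quality(r, min_run = 5, q_threshold = 20)
  expect_equal(tr$bases, r$bases)
  expect_length(attr(tr, "trimmed_ranges"), 0)
  # trailing low-quality run is excised
  r <- make_read(strrep("A", 100), c(rep(40L, 94), rep(5L, 6)))
  tr <- trim_low_quality(r, min_run = 5, q_threshold = 20)
  expect_equal(nchar(tr$bases), 94)
  expect_equal(attr(tr, "trimmed_ranges")[[1]], c(94L, 100L))
  # interior run is masked to N, preserving coordinates
  r <- make_read(strrep("A", 60), c(rep(38L, 20), rep(8L, 8), rep(38L, 32)))
  tr <- trim_low_quality(r, min_run = 5, q_threshold = 20)
  expect_equal(nchar(tr$bases), 60)
  expect_equal(substr(tr$bases, 21, 28), strrep("N", 8))
  expect_equal(attr(tr, "masked_ranges")[[1]], c(20L, 28L))
  # leading run plus interior run together
  r <- make_read(strrep("C", 50), c(rep(3L, 6), rep(40L, 14), rep(3L, 5), rep(40L, 25)))
  tr <- trim_low_quality(r, min_run = 5, q_threshold = 20)
  expect_equal(nchar(tr$bases), 44)
  # shorter-than-min_run stretches are untouched
  r <- make_read(strrep("G", 30), c(rep(40L, 10), rep(5L, 4), rep(40L, 16)))
  expect_equal(trim_low_quality(r, 5, 20)$bases, r$bases)
  # idempotence over random reads
  set.seed(77)
  for (i in 1:20) {
    n <- sample(40:120, 1)
    r <- make_read(random_seq(n), sample(c(2L, 10L, 30L, 40L), n, replace = TRUE))
    once <- trim_low_quality(r, 5, 20)
    twice <- trim_low_quality(once, 5, 20)
    expect_equal(twice$bases, once$bases)
    expect_equal(twice$quals, once$quals)
  }
  # empty read passes through; bad parameters error
  e <- trim_low_quality(make_read("", integer(0)), 5, 20)
  expect_equal(nchar(e$bases), 0)
  expect_error(trim_low_quality(r, min_run = 0), "min_run")
})

test_that("read construction validates alphabet and lengths", {
  expect_error(quality_read("x", "ACGT", c(40L, 40L)), "differ in length")
  expect_error(quality_read("x", "ACXT", rep(40L, 4)), "non-IUPAC")
  expect_error(quality_read("x", "ACGT", c(40L, 40L, -1L, 40L)), ">= 0")
  r <- quality_read("x", "acgryn", rep(30L, 6))
  expect_equal(r$bases, "ACGRYN")
})

test_that("consensus assembly resolves conflicts by quality and flags similar-quality columns", {
  set.seed(101)
  tpl <- random_seq(650)
  f <- make_read(tpl, rep(40L, 650), "s/1")
  r <- make_read(rc_string(tpl), rep(40L, 650), "s/2", "reverse")
  cr <- assemble_consensus(f, r)
  expect_s3_class(cr, "consensus_record")
  expect_equal(cr$sequence, tpl)     # identity round trip
  expect_equal(cr$ambiguity_count, 0)
  expect_equal(cr$length, 650)
  # one disagreeing column
  v <- strsplit(tpl, "")[[1]]
  alt <- v; alt[300] <- setdiff(c("A", "C", "G", "T"), v[300])[1]
  talt <- paste(alt, collapse = "")
  # quality gap 30 >= 10: the high-quality (reverse) base wins
  f2 <- make_read(tpl, c(rep(40L, 299), 10L, rep(40L, 350)), "s/1")
  r2 <- make_read(rc_string(talt), rep(40L, 650), "s/2", "reverse")
  cr2 <- assemble_consensus(f2, r2)
  expect_equal(substr(cr2$sequence, 300, 300), alt[300])
  # similar quality (gap 2 < 10): IUPAC ambiguity code
  f3 <- make_read(tpl, c(rep(40L, 299), 38L, rep(40L, 350)), "s/1")
  cr3 <- assemble_consensus(f3, r2)
  amb <- substr(cr3$sequence, 300, 300)
  expect_false(amb %in% c("A", "C", "G", "T"))
  expect_equal(cr3$ambiguity_count, 1)
  # an N in a similar-quality conflict stays N
  fN <- make_read(sub("^.", "N", tpl), rep(40L, 650), "s/1")
  crN <- suppressWarnings(assemble_consensus(fN, r))
  expect_equal(substr(crN$sequence, 1, 1), "N")
})

test_that("consensus takes single-read flanks and enforces the overlap floor", {
  set.seed(55)
  tpl <- random_seq(600)
  # forward covers 1..400, reverse covers 201..600: flanks from each
  f <- make_read(substr(tpl, 1, 400), rep(40L, 400), "s/1")
  r <- make_read(rc_string(substr(tpl, 201, 600)), rep(40L, 400), "s/2", "reverse")
  cr <- assemble_consensus(f, r)
  expect_equal(cr$sequence, tpl)
  # disjoint reads fail with both ids named
  f2 <- make_read(substr(tpl, 1, 80), rep(40L, 80), "fw")
  r2 <- make_read(rc_string(substr(tpl, 520, 600)), rep(40L, 81), "rv", "reverse")
  expect_error(suppressWarnings(assemble_consensus(f2, r2, min_overlap = 50)),
               "fw.*rv|overlap")
  expect_error(assemble_consensus(f, make_read("", integer(0), "rv")), "empty")
})

test_that("consensus record warns on atypical barcode lengths", {
  expect_warning(consensus_record("s", strrep("A", 120)), "outside")
  expect_warning(consensus_record("s", strrep("A", 720)), "outside")
  expect_silent(consensus_record("s", strrep("A", 650)))
})

test_that("Numt screening finds internal stops and frame-disrupting gaps", {
  # Met-Ala-Phe: no stop in frame 0
  nr <- numt_screen("ATGGCATTC")
  expect_true(nr$pass)
  expect_equal(nr$internal_stop_count, 0L)
  # "TAGA" repeats carry stop codons in every reading frame, so even the
  # best frame keeps at least one internal stop
  s <- strrep("TAGA", 6)
  counts <- vapply(0:2, function(f) {
    n_cod <- (nchar(s) - f) %/% 3
    sum(substring(s, f + 1 + 3 * (seq_len(n_cod) - 1), f + 3 * seq_len(n_cod)) %in%
          c("TAA", "TAG", "AGA", "AGG"))
  }, integer(1))
  nr2 <- numt_screen(s)
  expect_equal(nr2$internal_stop_count, min(counts))
  expect_equal(nr2$best_frame, which.min(counts) - 1L)
  expect_gte(min(counts), 1L)
  expect_false(nr2$pass)
  # a 2-column gap run disrupts the frame; a 3-column run does not
  expect_true(numt_screen("ATGGCATTC", aligned = "ATG--GCATTC")$gap_disruption)
  expect_false(numt_screen("ATGGCATTC", aligned = "ATG---GCATTC")$gap_disruption)
  # leading/trailing padding is not frame evidence
  expect_false(numt_screen("ATGGCATTC", aligned = "??ATGGCATTC--")$gap_disruption)
  expect_error(numt_screen("AT"), "codon")
  expect_error(numt_screen("ATGZCA"), "non-IUPAC")
})

test_that("FASTQ and FASTA round trips preserve reads and sequences", {
  set.seed(9)
  reads <- list(
    quality_read("a/1", random_seq(120), sample(2:40, 120, replace = TRUE), "forward"),
    quality_read("a/2", random_seq(120), sample(2:40, 120, replace = TRUE), "reverse"))
  fq <- tempfile(fileext = ".fastq")
  write_fastq_reads(reads, fq)
  back <- read_fastq_reads(fq)
  expect_equal(back[[1]]$bases, reads[[1]]$bases)
  expect_equal(back[[1]]$quals, reads[[1]]$quals)
  expect_equal(back[[2]]$orientation, "reverse")
  fa <- tempfile(fileext = ".fasta")
  recs <- list(suppressWarnings(consensus_record("c1", random_seq(100))))
  write_consensus_fasta(recs, fa)
  expect_equal(unname(read_barcode_fasta(fa)), recs[[1]]$sequence)
  df <- qc_report(recs, list(numt_screen(recs[[1]]$sequence)))
  expect_equal(df$sample_id, "c1")
  expect_true(is.logical(df$numt_pass))
})
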