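test_that("read preprocessing trims, clips at the first sub-Q20 base, and enforces the length floor", {
  # all qualities high: only the 5' trim applies
  r <- preprocess_read(strrep("A", 100), rep(30L, 100))
  expect_equal(nchar(r$bases), 97L)
  expect_equal(length(r$qual), 97L)

  # Q19 at original position 50: survives 4..49 = 46 nt < 60 -> discarded
  q <- rep(30L, 100); q[50] <- 19L
  expect_null(preprocess_read(strrep("A", 100), q))

  # boundary: 63 nt in, 60 nt out, kept ("at least 60")
  r <- preprocess_read(strrep("C", 63), rep(25L, 63))
  expect_equal(nchar(r$bases), 60L)

  # 62 nt in -> 59 out -> discarded; empty read discarded, not an error
  expect_null(preprocess_read(strrep("C", 62), rep(25L, 62)))
  expect_null(preprocess_read("", integer(0)))

  # vectorized form keeps ids aligned with survivors
  res <- preprocess_reads(c(strrep("A", 100), strrep("A", 62)),
                          list(rep(30L, 100), rep(30L, 62)),
                          id = c("keep", "drop"))
  expect_equal(res$id, "keep")
  expect_equal(res$discarded, "drop")
})

test_that("preprocessing renumbers retained positions from 1 and never lengthens a read", {
  set.seed(11)
  n_kept <- 0L
  for (k in 1:40) {
    L <- sample(60:120, 1)
    # rare low-quality bases so both outcomes (kept/discarded) occur
    q <- sample(c(19L, 20L, 35L), L, replace = TRUE, prob = c(0.01, 0.1, 0.89))
    b <- random_dna(L)
    r <- preprocess_read(b, q)
    if (!is.null(r)) {
      n_kept <- n_kept + 1L
      expect_lte(nchar(r$bases), L)
      expect_gte(nchar(r$bases), 60L)
      # content identity: output is the contiguous slice after the trim
      expect_equal(r$bases, substr(b, 4L, 3L + nchar(r$bases)))
      expect_true(all(r$qual >= 20L))
    }
  }
  expect_gt(n_kept, 0L)
})

test_that("alignment-record filter keeps unique primary indel-free records only", {
  expect_true(alignment_accepted("97M"))
  expect_false(alignment_accepted("97M", is_secondary = TRUE))
  expect_false(alignment_accepted("40M1I56M"))   # insertion
  expect_false(alignment_accepted("40M2D57M"))   # deletion
  expect_false(alignment_accepted("97M", unique_top = FALSE))
  expect_false(alignment_accepted("97M", is_unmapped = TRUE))
  expect_true(alignment_accepted("5S90M"))       # clip is not an indel
  expect_error(alignment_accepted("97Q"), "malformed")
})

test_that("SAM round trip: reading, uniqueness flags, and filtering", {
  sam <- tempfile(fileext = ".sam")
  write_toy_sam(sam, c(
    sam_record("r1", 0, "tmplA", 3, 60, "10M", "GCCTCTTGGA"),
    sam_record("r2", 16, "tmplA", 3, 60, "10M", "GCCTCTTGGA"),
    sam_record("r3", 256, "tmplA", 3, 60, "10M", "GCCTCTTGGA"),  # secondary
    sam_record("r4", 0, "tmplA", 3, 0, "10M", "GCCTCTTGGA"),     # mapq 0
    sam_record("r5", 0, "tmplA", 3, 60, "4M1I5M", "GCCTACTTGG"), # indel
    sam_record("r6", 0, "tmplB", 1, 60, "10M", "TTTTCAAACC",
               tags = "X0:i:2"),                                  # tied top hit
    sam_record("r7", 0, "tmplB", 1, 60, "10M", "TTTTCAAACC",
               tags = "X0:i:1")))
  aln <- read_alignments(sam)
  expect_equal(nrow(aln), 7L)
  acc <- filter_alignments(aln)
  expect_setequal(acc$qname, c("r1", "r2", "r7"))
  rej <- attr(acc, "rejected")
  expect_equal(unname(rej["secondary"]), 1L)
  expect_equal(unname(rej["indel"]), 1L)
  expect_equal(unname(rej["not_unique"]), 2L)
})

test_that("pileup records observations with read positions, complementing strand handling", {
  templates <- toy_templates()
  # template C at tmplA position 101 analog: use position 5 (C in CCTCTT...)
  sam <- tempfile(fileext = ".sam")
  write_toy_sam(sam, c(
    # forward read starting at 1: template position 5 = read position 5
    sam_record("f1", 0, "tmplA", 1, 60, "10M", "ATGCTCTTGG"),   # T at pos 5
    # reverse read of length 10 starting at 1: SAM SEQ is template-oriented,
    # so template position 5 = SEQ index 5 = sequenced position 10-5+1 = 6
    sam_record("rv", 16, "tmplA", 1, 60, "10M", "ATGCCCTTGG")))
  aln <- filter_alignments(read_alignments(sam))
  pu <- build_pileup(aln, templates)
  col <- pileup_column(pu, "tmplA", 5L)
  expect_equal(sum(col$n), 2L)
  expect_equal(col[obs == "T"]$read_pos, 5L)
  expect_equal(col[obs == "C"]$read_pos, 6L)

  # conservation: total observations equal total aligned bases
  expect_equal(sum(pu$n), 20L)

  # uncovered position: no column emitted
  expect_equal(nrow(pileup_column(pu, "tmplA", 30L)), 0L)
})

test_that("error-free tiling reads reproduce the template in every column", {
  templates <- toy_templates()
  tlen <- nchar(templates$seq["tmplA"])
  recs <- vapply(1:10, function(i) {
    start <- ((i - 1L) %% (tlen - 10L)) + 1L
    sam_record(paste0("t", i), 0, "tmplA", start, 60, "10M",
               substr(templates$seq["tmplA"], start, start + 9L))
  }, character(1))
  sam <- tempfile(fileext = ".sam")
  write_toy_sam(sam, recs)
  pu <- build_pileup(filter_alignments(read_alignments(sam)), templates)
  expect_true(all(pu$obs == pu$ref))
  cnt <- pileup_counts(pu)
  expect_true(all(cnt$t_count[cnt$ref == "C"] == 0L))
})

test_that("alignments past the template end are an error naming the record", {
  templates <- toy_templates()
  sam <- tempfile(fileext = ".sam")
  write_toy_sam(sam, sam_record("runaway", 0, "tmplB", 20, 60, "10M",
                                "ACGCATGCAA"))
  aln <- filter_alignments(read_alignments(sam))
  expect_error(build_pileup(aln, templates), "runaway")
})

test_that("site tables round-trip through write and read", {
  calls <- data.table(
    template_id = rep(c("tA", "tB"), each = 3),
    position = as.integer(c(5, 9, 12, 3, 7, 20)),
    c_count = as.integer(c(900, 10, 0, 5, 100, 50)),
    t_count = as.integer(c(100, 0, 0, 5, 3, 0)),
    other_count = as.integer(c(1, 0, 0, 0, 2, 0)),
    depth = as.integer(c(1001, 10, 0, 10, 105, 50)),
    t_fraction = c(0.1, 0, NA, 0.5, 3 / 103, 0),
    theta_hat = c(0.099, 0, 0, 0.5, 0.028, 0),
    lrt = c(512.3, 0, 0, 40.1, 9.4, 0),
    pvalue = c(1e-113, 1, 1, 2.5e-10, 0.002, 1))
  path <- tempfile(fileext = ".tsv")
  write_site_table(calls, path)
  back <- read_site_table(path)
  expect_equal(nrow(back), 6L)
  expect_equal(back$c_count, calls$c_count[order(calls$template_id, calls$position)])
  expect_equal(back$t_fraction,
               signif(calls$t_fraction, 8)[order(calls$template_id, calls$position)])
  expect_equal(back$pvalue, signif(calls$pvalue, 8)[order(calls$template_id, calls$position)])

  # empty list -> header-only file
  path2 <- tempfile(fileext = ".tsv")
  write_site_table(calls[0], path2)
  expect_equal(length(readLines(path2)), 1L)
  expect_equal(nrow(read_site_table(path2)), 0L)
})

test_that("a larger simulated call table survives the round trip field-by-field", {
  set.seed(7)
  n <- 1000L
  calls <- data.table(
    template_id = sprintf("t%02d", sample(1:20, n, replace = TRUE)),
    position = sample.int(5000L, n, replace = FALSE),
    c_count = as.integer(rpois(n, 500)), t_count = as.integer(rpois(n, 20)),
    other_count = as.integer(rpois(n, 1)))
  calls[, depth := c_count + t_count + other_count]
  calls[, t_fraction := t_count / (c_count + t_count)]
  calls[, theta_hat := pmax(0, t_fraction - 1e-3)]
  calls[, lrt := rexp(n, 1 / 50)]
  calls[, pvalue := pchisq(lrt, 1, lower.tail = FALSE)]
  path <- tempfile(fileext = ".tsv")
  write_site_table(calls, path)
  back <- read_site_table(path)
  ord <- order(calls$template_id, calls$position)
  for (col in c("c_count", "t_count", "depth"))
    expect_equal(back[[col]], calls[[col]][ord])
  for (col in c("t_fraction", "theta_hat", "lrt", "pvalue"))
    expect_equal(back[[col]], signif(calls[[col]], 8)[ord])
})

test_that("sample sheets validate comparison structure", {
  good <- data.table(
    library_id = c("m1", "m2", "w1", "s1", "u1", "g1"),
    genotype = c("mutA", "mutA", "wtA", "silB", "col", "gfp"),
    role = c("mutant", "mutant", "wildtype_sibling", "silenced",
             "uninoculated_control", "gfp_silenced_control"),
    comparison = c("A", "A", "A", "B", "B", "B"))
  sheet <- validate_sample_sheet(good)
  cmp <- sheet_comparisons(sheet)
  expect_equal(nrow(cmp), 2L)
  expect_setequal(cmp$type, c("mutant", "silenced"))
  expect_equal(sort(cmp[type == "mutant"]$test_libs[[1]]), c("m1", "m2"))

  # mutant without a wild-type sibling
  expect_error(validate_sample_sheet(good[role != "wildtype_sibling"]),
               "wild-type")
  # silenced without the GFP control
  expect_error(validate_sample_sheet(good[role != "gfp_silenced_control"]),
               "control")
  # empty sheet
  expect_error(validate_sample_sheet(good[0]), "empty")
  expect_error(validate_sample_sheet(data.table(
    library_id = "x", genotype = "g", role = "oddball", comparison = "c")),
    "unknown role")
})
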