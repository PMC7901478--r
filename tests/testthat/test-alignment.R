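# SAM lines for hand-built intake cases. Fields:
# QNAME FLAG RNAME POS MAPQ CIGAR RNEXT PNEXT TLEN SEQ QUAL [TAGS]
sam_line <- function(qname, flag, pos, mapq = 60L, cigar = "50M",
                     rnext = "=", pnext = pos, tlen = 0L, tags = NULL) {
  paste(c(qname, flag, "chr1", pos, mapq, cigar, rnext, pnext, tlen,
          "*", "*", tags), collapse = "\t")
}

test_that("record validation discards by reason and flags multimappers", {
  sam <- write_tmp_sam(c(
    sam_line("ok", 0L, 100L),                       # mapped primary, kept
    sam_line("unm", 4L, 100L),                      # unmapped
    sam_line("sec", 256L, 100L),                    # secondary
    sam_line("sup", 2048L, 100L),                   # supplementary
    sam_line("lowq", 0L, 100L, mapq = 5L),          # below MAPQ 10
    sam_line("mm", 0L, 200L, tags = "NH:i:5")))     # multimapped primary
  u <- read_alignment_units(sam)
  t <- attr(u, "tally")
  expect_equal(unname(t[c("records", "unmapped", "secondary",
                          "supplementary", "low_mapq")]),
               c(6L, 1L, 1L, 1L, 1L))
  expect_equal(nrow(u), 2L)
  expect_equal(u$multi, c(FALSE, TRUE))
  expect_equal(u$kind, c("read", "read"))

  u2 <- read_alignment_units(sam, remove_multimapped = TRUE)
  expect_equal(attr(u2, "tally")[["multimapped_removed"]], 1L)
  expect_equal(u2$template, "ok")

  # inclusive MAPQ threshold: a record at exactly min_mapq is kept
  u3 <- read_alignment_units(sam, min_mapq = 60L)
  expect_true("ok" %in% u3$template)
})

test_that("properly paired records collapse to one fragment unit", {
  sam <- write_tmp_sam(c(
    sam_line("p1", 99L, 101L, cigar = "50M", pnext = 301L, tlen = 250L),
    sam_line("p1", 147L, 301L, cigar = "50M", pnext = 101L, tlen = -250L)))
  u <- read_alignment_units(sam)
  expect_equal(nrow(u), 1L)
  expect_equal(u$kind, "fragment")
  expect_equal(u$start, 100L)   # 0-based
  expect_equal(u$end, 350L)
  expect_equal(u$F_L, 250L)
  expect_equal(attr(u, "tally")[["deferred_mate"]], 1L)
})

test_that("overlong templates fall back to two read units", {
  sam <- write_tmp_sam(c(
    sam_line("p1", 99L, 101L, cigar = "50M", pnext = 1251L, tlen = 1200L),
    sam_line("p1", 147L, 1251L, cigar = "50M", pnext = 101L, tlen = -1200L)))
  u <- read_alignment_units(sam, max_fragment_size = 1000L)
  expect_equal(nrow(u), 2L)
  expect_equal(u$kind, c("read", "read"))
  expect_equal(u$F_L, c(50L, 50L))     # aligned span, not TLEN
  expect_equal(u$end - u$start, c(50L, 50L))

  # the bound is exclusive: |TLEN| = max_fragment_size is not a fragment
  u2 <- read_alignment_units(sam, max_fragment_size = 1200L)
  expect_equal(u2$kind, c("read", "read"))
  u3 <- read_alignment_units(sam, max_fragment_size = 1201L)
  expect_equal(u3$kind, "fragment")
})

test_that("singletons become halvable read units with aligned span", {
  sam <- write_tmp_sam(sam_line("s1", 73L, 11L, cigar = "75M"))
  u <- read_alignment_units(sam)
  expect_equal(u$kind, "read")
  expect_equal(u$start, 10L)
  expect_equal(u$end, 85L)
  expect_equal(u$F_L, 75L)

  # keep_only_proper_pairs drops it entirely
  u2 <- read_alignment_units(sam, keep_only_proper_pairs = TRUE)
  expect_equal(nrow(u2), 0L)
  expect_equal(attr(u2, "tally")[["not_proper_dropped"]], 1L)
})

test_that("effective strand follows the library dialect", {
  # first-in-pair forward fragment; second-in-pair reverse singleton
  sam <- write_tmp_sam(c(
    sam_line("p1", 99L, 101L, pnext = 301L, tlen = 250L),
    sam_line("p1", 147L, 301L, pnext = 101L, tlen = -250L),
    sam_line("s1", 89L, 501L, cigar = "75M")))   # paired, mate unmapped, reverse
  u_no <- read_alignment_units(sam, stranded = "no")
  expect_true(all(u_no$strand == "*"))
  u_fw <- read_alignment_units(sam, stranded = "yes")
  expect_equal(u_fw$strand[u_fw$kind == "fragment"], "+")
  expect_equal(u_fw$strand[u_fw$kind == "read"], "-")
  u_rv <- read_alignment_units(sam, stranded = "reverse")
  expect_equal(u_rv$strand[u_rv$kind == "fragment"], "-")
  expect_equal(u_rv$strand[u_rv$kind == "read"], "+")
})

test_that("every record is accounted for exactly once", {
  fx <- make_fixture("singleton_mix", out_dir = tempfile(), depth = 8,
                     seed = 21)
  u <- read_alignment_units(fx$sam)
  t <- attr(u, "tally")
  kept_or_dropped <- t[["fragments"]] + t[["reads"]] + t[["deferred_mate"]] +
    t[["unmapped"]] + t[["secondary"]] + t[["supplementary"]] +
    t[["low_mapq"]] + t[["multimapped_removed"]] + t[["not_proper_dropped"]]
  expect_equal(kept_or_dropped, t[["records"]])
})

test_that("chunk size never changes the unit stream", {
  fx <- make_fixture("operon", out_dir = tempfile(), n_genes = 4,
                     depth = 6, seed = 5)
  u_big <- read_alignment_units(fx$sam, chunk_size = 1e7)
  for (cs in c(1, 7, 100)) {
    u <- read_alignment_units(fx$sam, chunk_size = cs)
    expect_equal(u, u_big, ignore_attr = TRUE)
    expect_equal(attr(u, "tally"), attr(u_big, "tally"))
  }
})

test_that("secondary records of multimapped templates are admitted on request", {
  sam <- write_tmp_sam(c(
    sam_line("mm", 0L, 101L, tags = "NH:i:2"),
    sam_line("mm", 256L, 5001L, mapq = 0L, tags = "NH:i:2")))
  u_def <- read_alignment_units(sam)
  expect_equal(nrow(u_def), 1L)
  u_sec <- read_alignment_units(sam, include_secondary = TRUE)
  expect_equal(nrow(u_sec), 2L)
  expect_true(all(u_sec$multi))
  # but not when multimappers are being removed outright
  u_rm <- read_alignment_units(sam, include_secondary = TRUE,
                               remove_multimapped = TRUE)
  expect_equal(nrow(u_rm), 0L)
})

test_that("a missing alignment file is a fatal error", {
  expect_error(read_alignment_units(tempfile(fileext = ".bam")), "not found")
})
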