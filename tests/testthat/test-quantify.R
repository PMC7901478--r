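test_that("end-to-end quantification matches the truth table", {
  fx <- make_fixture("operon", out_dir = tempfile(), n_genes = 5,
                     depth = 12, seed = 61)
  res <- quantify_features(fx$sam, fx$gff3, em_iterations = 0L)
  expect_equal(setNames(res$table$counts, res$table$featureID),
               fx$truth_counts[res$table$featureID], tolerance = 1e-9)
  expect_equal(sum(res$table$tpm), 1e6, tolerance = 1)
  expect_s3_class(res, "uniquant")
  expect_output(print(res), "features")
  expect_output(summary(res), "Record tallies")
})

test_that("removing multimappers zeroes the duplicated-locus rescue", {
  fx <- make_fixture("multimap", out_dir = tempfile(), depth = 10, seed = 62)
  keep <- quantify_features(fx$sam, fx$gff3, em_iterations = 1L)
  drop <- quantify_features(fx$sam, fx$gff3, remove_multimapped = TRUE,
                            em_iterations = 0L)
  # with primary-only multimappers, the rescue lands on the primary copy
  expect_gt(keep$table$counts[keep$table$featureID == "parA"],
            drop$table$counts[drop$table$featureID == "parA"])
  expect_equal(drop$table$counts,
               unname(as.numeric(fx$truth_counts[drop$table$featureID])),
               tolerance = 1e-9)
})

test_that("EM with secondary loci splits rescue by unique-count abundance", {
  fx <- make_fixture("multimap", out_dir = tempfile(), depth = 20, seed = 63)
  res <- quantify_features(fx$sam, fx$gff3, include_secondary = TRUE,
                           em_iterations = 10L)
  n0 <- fx$truth_counts
  mm_mass <- sum(res$table$counts) - sum(n0)
  expect_gt(mm_mass, 0)
  shareA <- (res$table$counts[res$table$featureID == "parA"] -
               n0[["parA"]]) / mm_mass
  # parA holds the larger unique anchor, so it takes the larger share
  expect_gt(shareA, 0.5)
  # weights stayed normalized at every iteration
  expect_true(all(abs(res$em$weight_sum_range - 1) < 1e-12))
})

test_that("identical runs produce byte-identical output files", {
  fx <- make_fixture("singleton_mix", out_dir = tempfile(), depth = 6,
                     seed = 64)
  out1 <- tempfile(); out2 <- tempfile()
  write_count_table(quantify_features(fx$sam, fx$gff3)$table, out1)
  write_count_table(quantify_features(fx$sam, fx$gff3)$table, out2)
  expect_identical(readBin(out1, "raw", file.size(out1)),
                   readBin(out2, "raw", file.size(out2)))
})

test_that("missing inputs fail loudly", {
  fx <- make_fixture("operon", out_dir = tempfile(), depth = 2, seed = 65)
  expect_error(quantify_features(tempfile(fileext = ".bam"), fx$gff3),
               "not found")
  expect_error(quantify_features(fx$sam, tempfile(fileext = ".gff3")),
               "not found")
})

test_that("alignments on contigs absent from the annotation count nowhere", {
  gff <- write_tmp_gff3("chr1\t.\tgene\t101\t400\t.\t+\t.\tID=g")
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               "@SQ\tSN:chr1\tLN:10000",
               "@SQ\tSN:chrX\tLN:10000",
               "p1\t99\tchr1\t151\t60\t100M\t=\t301\t250\t*\t*",
               "p1\t147\tchr1\t301\t60\t100M\t=\t151\t-250\t*\t*",
               "q1\t99\tchrX\t151\t60\t100M\t=\t301\t250\t*\t*",
               "q1\t147\tchrX\t301\t60\t100M\t=\t151\t-250\t*\t*"), sam)
  res <- quantify_features(sam, gff)
  expect_equal(res$table$counts, 1)
  expect_equal(res$tally[["fragments"]], 2L)
})

test_that("the command-line wrapper drives the same pipeline", {
  skip_if_not_installed("optparse")
  cli <- system.file("exec", "uniquant", package = "uniquant")
  if (!nzchar(cli)) cli <- file.path(testthat::test_path(), "..", "..",
                                     "exec", "uniquant")
  skip_if(!file.exists(cli), "CLI script not found")
  fx <- make_fixture("operon", out_dir = tempfile(), depth = 4, seed = 66)
  outdir <- tempfile()
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  status <- system2("Rscript", c(cli, "quantify", "--bam", fx$sam,
                                 "--gff3", fx$gff3, "-o", outdir),
                    env = libs, stdout = TRUE, stderr = TRUE)
  out <- file.path(outdir, "fixture.counts.txt")
  expect_true(file.exists(out))
  tab <- read.delim(out)
  ref <- quantify_features(fx$sam, fx$gff3)
  expect_equal(tab$counts, round(ref$table$counts, 2))
  # error path: nonexistent BAM, nonzero exit, no output
  st <- suppressWarnings(
    system2("Rscript", c(cli, "quantify", "--bam", tempfile(), "--gff3",
                         fx$gff3, "-o", tempfile()),
            env = libs, stdout = NULL, stderr = NULL))
  expect_true(st != 0)
})

test_that("defaults agree across the function surface", {
  fq <- formals(quantify_features)
  fr <- formals(read_alignment_units)
  expect_equal(eval(fq$min_mapq), 10L)
  expect_equal(eval(fr$min_mapq), 10L)
  expect_equal(eval(fq$max_fragment_size), 1000L)
  expect_equal(eval(fr$max_fragment_size), 1000L)
  expect_equal(eval(fq$chunk_size), 1e7)
  expect_equal(eval(fr$chunk_size), 1e7)
  expect_equal(eval(fq$em_iterations), 1L)
  expect_false(eval(fq$remove_multimapped))
  expect_false(eval(fq$keep_only_proper_pairs))
  expect_equal(eval(fq$stranded)[1], "no")
})
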