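# Synthetic GFF3 + SAM fixtures with known ground truth, plus the
# independent per-base counting oracle used by the test suite. The oracle
# deliberately shares no code with the main counting path: it enumerates
# genomic positions one by one in plain scalar R.

.fixture_scenarios <- c("operon", "overlap_pair", "neighbor_readthrough",
                        "multimap", "singleton_mix", "stranded_mirror")

.write_gff3 <- function(genes, path) {
  # genes: feature_id, contig, strand, start, end (0-based half-open)
  lines <- c("##gff-version 3",
             sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$contig, genes$start + 1L, genes$end,
                     genes$strand, genes$feature_id))
  writeLines(lines, path)
}

# SAM records for one paired-end fragment. start: 0-based leftmost; flen:
# fragment length; orient: "F" = first-in-pair on the forward/left end
# (fragment reads as '+' in a forward-stranded library), "R" = reversed.
.sam_pair <- function(qname, contig, start, flen, read_len, orient = "F",
                      nh = NA_integer_, secondary = FALSE, mapq = 60L) {
  rl <- min(read_len, flen)
  lp <- start + 1L                      # 1-based leftmost read pos
  rp <- start + flen - rl + 1L          # 1-based rightmost read pos
  sec <- if (secondary) 0x100L else 0L
  if (secondary) mapq <- 0L
  tag <- if (!is.na(nh)) paste0("\tNH:i:", nh) else ""
  cig <- paste0(rl, "M")
  if (orient == "F") {
    f1 <- 0x1L + 0x2L + 0x20L + 0x40L + sec   # 99: first, mate reverse
    f2 <- 0x1L + 0x2L + 0x10L + 0x80L + sec   # 147
    p1 <- lp; p2 <- rp; t1 <- flen; t2 <- -flen
  } else {
    f1 <- 0x1L + 0x2L + 0x10L + 0x40L + sec   # 83: first, reverse, rightmost
    f2 <- 0x1L + 0x2L + 0x20L + 0x80L + sec   # 163
    p1 <- rp; p2 <- lp; t1 <- -flen; t2 <- flen
  }
  c(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*%s",
            qname, f1, contig, p1, mapq, cig, p2, t1, tag),
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*%s",
            qname, f2, contig, p2, mapq, cig, p1, t2, tag))
}

# One mate-unmapped singleton read.
.sam_singleton <- function(qname, contig, start, read_len, strand = "+",
                           mapq = 60L) {
  fl <- 0x1L + 0x8L + 0x40L + if (strand == "-") 0x10L else 0L
  sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t0\t*\t*",
          qname, fl, contig, start + 1L, mapq, read_len, start + 1L)
}

.write_sam <- function(records, contig, contig_len, path) {
  pos <- as.integer(vapply(strsplit(records, "\t"), `[`, "", 4L))
  records <- records[order(pos)]
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len)),
             path)
  con <- file(path, "a")
  writeLines(records, con)
  close(con)
}

# orientation making a fragment's effective strand match `gene_strand`
# under dialect `stranded` ("no"/"yes"/"reverse")
.orient_for <- function(gene_strand, stranded) {
  if (stranded == "no") return("F")
  want <- if (stranded == "reverse") {
    if (gene_strand == "+") "-" else "+"
  } else gene_strand
  if (want == "+") "F" else "R"
}

#' Generate a synthetic GFF3 + SAM fixture with known ground truth
#'
#' Emulates the alignment geometries that make prokaryotic quantification
#' hard: \code{operon} (genes transcribed together, fragments evenly tiling
#' the whole polycistronic transcript including junction-spanning multigene
#' fragments and UTRs; one interior gene is half-length), \code{overlap_pair}
#' (two same-strand genes sharing an interior interval), \code{neighbor_readthrough}
#' (a gene whose 3' UTR read-through barely reaches a small downstream
#' gene), \code{multimap} (a duplicated locus with NH=2 records, primary at
#' the first copy and secondary at the second), \code{singleton_mix} (proper
#' pairs mixed with mate-unmapped singletons), and \code{stranded_mirror}
#' (a two-strand layout emitted in both forward- and reverse-stranded
#' dialects). The truth table of expected uniquely-mapped counts is computed
#' by the independent per-base \code{\link{oracle_counts}}, never by the
#' main counting path.
#'
#' @param scenario one of the six scenario names above.
#' @param out_dir directory for the fixture files (created if needed).
#' @param n_genes,gene_len,gap,depth,fragment_len,read_len geometry:
#'   number of genes, gene length, inter-gene gap (negative gap = overlap,
#'   only meaningful for \code{overlap_pair}), fragments per gene, fragment
#'   and read length, all in bases.
#' @param seed integer seed; identical (spec, seed) gives byte-identical
#'   files.
#' @param stranded library dialect to emit ("no", "yes", "reverse");
#'   \code{stranded_mirror} ignores this and emits both stranded dialects.
#' @return list with \code{gff3}, \code{sam} (named character vector for
#'   \code{stranded_mirror}: one per dialect), \code{truth} (path to
#'   truth.tsv), \code{truth_counts}, \code{genes}, \code{contig_len}.
#' @export
make_fixture <- function(scenario = .fixture_scenarios, out_dir = tempfile(),
                         n_genes = 3L, gene_len = 300L, gap = 20L,
                         depth = 10L, fragment_len = 250L, read_len = 100L,
                         seed = 1L, stranded = "no") {
  scenario <- match.arg(scenario)
  stopifnot(gene_len > 0L, depth >= 0L, fragment_len > 0L,
            read_len > 0L, read_len <= fragment_len)
  if (gap < 0L && scenario != "overlap_pair") {
    stop("negative gap (colliding genes) is only meaningful for the ",
         "overlap_pair scenario")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  contig <- "chr1"
  off <- 1000L                           # room for upstream UTR / noise
  recs <- character(0)

  tile <- function(t0, t1, n) {
    # n evenly spaced fragment starts covering [t0, t1 - fragment_len]
    as.integer(round(seq(t0, t1 - fragment_len, length.out = max(n, 2L))))
  }
  rand_starts <- function(t0, t1, n) {
    if (n == 0L) return(integer(0))
    sort(sample(seq.int(t0, t1 - fragment_len), n, replace = TRUE))
  }

  if (scenario == "operon") {
    lens <- rep(gene_len, n_genes)
    if (n_genes >= 3L) lens[ceiling(n_genes / 2)] <- max(gene_len %/% 2L, 30L)
    starts <- off + cumsum(c(0L, head(lens, -1L) + gap))
    genes <- data.frame(feature_id = sprintf("op%02d", seq_len(n_genes)),
                        contig = contig, strand = "+",
                        start = starts, end = starts + lens,
                        stringsAsFactors = FALSE)
    t0 <- genes$start[1L] - fragment_len
    t1 <- genes$end[n_genes] + fragment_len
    st <- tile(t0, t1, depth * n_genes)
    orient <- .orient_for("+", stranded)
    recs <- unlist(lapply(seq_along(st), function(i)
      .sam_pair(sprintf("frag%04d", i), contig, st[i], fragment_len,
                read_len, orient)))
  } else if (scenario == "overlap_pair") {
    ov <- if (gap < 0L) -gap else min(100L, gene_len %/% 3L)
    g1s <- off; g2s <- off + gene_len - ov
    genes <- data.frame(feature_id = c("gA", "gB"), contig = contig,
                        strand = "+",
                        start = c(g1s, g2s),
                        end = c(g1s + gene_len, g2s + gene_len),
                        stringsAsFactors = FALSE)
    st <- rand_starts(g1s - fragment_len %/% 2L,
                      genes$end[2L] + fragment_len %/% 2L, depth * 2L)
    orient <- .orient_for("+", stranded)
    recs <- unlist(lapply(seq_along(st), function(i)
      .sam_pair(sprintf("frag%04d", i), contig, st[i], fragment_len,
                read_len, orient)))
  } else if (scenario == "neighbor_readthrough") {
    big_len <- max(4L * gene_len, 1200L)
    small_len <- max(gene_len %/% 2L, 150L)
    readthrough <- gap + 10L             # UTR extends 10 bp into the gap's far side
    g1s <- off; g2s <- off + big_len + gap
    genes <- data.frame(feature_id = c("big", "small"), contig = contig,
                        strand = "+",
                        start = c(g1s, g2s),
                        end = c(g1s + big_len, g2s + small_len),
                        stringsAsFactors = FALSE)
    st <- tile(g1s - fragment_len, g1s + big_len + readthrough, depth * 2L)
    orient <- .orient_for("+", stranded)
    recs <- unlist(lapply(seq_along(st), function(i)
      .sam_pair(sprintf("frag%04d", i), contig, st[i], fragment_len,
                read_len, orient)))
  } else if (scenario == "multimap") {
    g1s <- off; g2s <- off + gene_len + 3000L
    genes <- data.frame(feature_id = c("parA", "parB"), contig = contig,
                        strand = "+",
                        start = c(g1s, g2s),
                        end = c(g1s + gene_len, g2s + gene_len),
                        stringsAsFactors = FALSE)
    orient <- .orient_for("+", stranded)
    # unique anchors: parA gets `depth` unique fragments, parB a fifth
    stA <- rand_starts(g1s, g1s + gene_len, depth)
    stB <- rand_starts(g2s, g2s + gene_len, max(depth %/% 5L, 1L))
    recs <- c(
      unlist(lapply(seq_along(stA), function(i)
        .sam_pair(sprintf("uniqA%03d", i), contig, stA[i],
                  min(fragment_len, gene_len), read_len, orient))),
      unlist(lapply(seq_along(stB), function(i)
        .sam_pair(sprintf("uniqB%03d", i), contig, stB[i],
                  min(fragment_len, gene_len), read_len, orient))))
    # multimapped templates: primary at parA, secondary at the parB copy
    n_mm <- max(depth %/% 2L, 1L)
    stM <- rand_starts(g1s, g1s + gene_len, n_mm)
    for (i in seq_len(n_mm)) {
      qn <- sprintf("mm%03d", i)
      fl <- min(fragment_len, gene_len)
      recs <- c(recs,
                .sam_pair(qn, contig, stM[i], fl, read_len, orient, nh = 2L),
                .sam_pair(qn, contig, stM[i] - g1s + g2s, fl, read_len,
                          orient, nh = 2L, secondary = TRUE))
    }
  } else if (scenario == "singleton_mix") {
    starts <- off + cumsum(c(0L, rep(gene_len + gap, n_genes - 1L)))
    genes <- data.frame(feature_id = sprintf("g%02d", seq_len(n_genes)),
                        contig = contig, strand = "+",
                        start = starts, end = starts + gene_len,
                        stringsAsFactors = FALSE)
    orient <- .orient_for("+", stranded)
    recs <- character(0)
    for (g in seq_len(n_genes)) {
      stp <- rand_starts(genes$start[g], genes$end[g], depth)
      fl <- min(fragment_len, gene_len)
      recs <- c(recs, unlist(lapply(seq_along(stp), function(i)
        .sam_pair(sprintf("p%02d_%03d", g, i), contig, stp[i], fl,
                  read_len, orient))))
      sts <- rand_starts(genes$start[g], genes$end[g] - read_len +
                           fragment_len, depth)
      rstrand <- if (stranded == "reverse") "-" else "+"
      recs <- c(recs, vapply(seq_along(sts), function(i)
        .sam_singleton(sprintf("s%02d_%03d", g, i), contig, sts[i],
                       read_len, strand = rstrand), ""))
    }
  } else {                               # stranded_mirror
    g1s <- off; g2s <- off + gene_len + 300L
    genes <- data.frame(feature_id = c("fwd_gene", "rev_gene"),
                        contig = contig, strand = c("+", "-"),
                        start = c(g1s, g2s),
                        end = c(g1s + gene_len, g2s + gene_len),
                        stringsAsFactors = FALSE)
    st1 <- rand_starts(g1s, g1s + gene_len, depth)
    st2 <- rand_starts(g2s, g2s + gene_len, depth)
    fl <- min(fragment_len, gene_len)
    mk <- function(dialect) {
      c(unlist(lapply(seq_along(st1), function(i)
        .sam_pair(sprintf("f%03d", i), contig, st1[i], fl, read_len,
                  .orient_for("+", dialect)))),
        unlist(lapply(seq_along(st2), function(i)
          .sam_pair(sprintf("r%03d", i), contig, st2[i], fl, read_len,
                    .orient_for("-", dialect)))))
    }
    contig_len <- max(genes$end) + 2000L
    gff3 <- file.path(out_dir, "fixture.gff3")
    .write_gff3(genes, gff3)
    sam_f <- file.path(out_dir, "fixture_forward.sam")
    sam_r <- file.path(out_dir, "fixture_reverse.sam")
    .write_sam(mk("yes"), contig, contig_len, sam_f)
    .write_sam(mk("reverse"), contig, contig_len, sam_r)
    truth <- oracle_counts(gff3, sam_f, stranded = "yes")
    tpath <- file.path(out_dir, "truth.tsv")
    utils::write.table(data.frame(feature_id = names(truth),
                                  N_f0 = as.numeric(truth)),
                       tpath, sep = "\t", quote = FALSE, row.names = FALSE)
    return(list(gff3 = gff3, sam = c(forward = sam_f, reverse = sam_r),
                truth = tpath, truth_counts = truth, genes = genes,
                contig_len = contig_len))
  }

  contig_len <- max(genes$end) + 2000L
  gff3 <- file.path(out_dir, "fixture.gff3")
  sam <- file.path(out_dir, "fixture.sam")
  .write_gff3(genes, gff3)
  .write_sam(recs, contig, contig_len, sam)
  truth <- oracle_counts(gff3, sam, stranded = stranded)
  tpath <- file.path(out_dir, "truth.tsv")
  utils::write.table(data.frame(feature_id = names(truth),
                                N_f0 = as.numeric(truth)),
                     tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  list(gff3 = gff3, sam = sam, truth = tpath, truth_counts = truth,
       genes = genes, contig_len = contig_len)
}

# ---------------------------------------------------------------------------
# Independent per-base oracle.

.oracle_parse_gff3 <- function(gff3) {
  out <- list()
  for (ln in readLines(gff3)) {
    if (startsWith(ln, "##FASTA")) break
    if (startsWith(ln, "#") || !nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (f[3L] != "gene") next
    attrs <- strsplit(f[9L], ";", fixed = TRUE)[[1L]]
    id <- substring(attrs[startsWith(attrs, "ID=")][1L], 4L)
    out[[length(out) + 1L]] <- list(id = id, contig = f[1L],
                                    strand = f[7L],
                                    start = as.integer(f[4L]) - 1L,
                                    end = as.integer(f[5L]))
  }
  out
}

.oracle_cigar_refwidth <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  w <- 0L
  for (op in ops) {
    n <- as.integer(sub("[A-Z=]", "", op))
    if (grepl("[MDN=X]", op)) w <- w + n
  }
  w
}

#' Per-base brute-force counting oracle
#'
#' Recomputes the uniquely-mapped proportional counts N_f0 by explicit
#' enumeration: every genomic position is labelled with the single feature
#' covering it (or none), each retained unit is walked base by base, and
#' 1/F_L (halved for unpaired reads) is credited to the owner of each base.
#' Shares no interval machinery with the main path; intended for
#' desk-scale fixtures only.
#'
#' @param gff3,sam fixture files.
#' @param min_mapq,max_fragment_size,stranded,remove_multimapped,
#'   keep_only_proper_pairs same semantics as the main path.
#' @return named numeric: feature id -> expected N_f0.
#' @export
oracle_counts <- function(gff3, sam, min_mapq = 10, max_fragment_size = 1000,
                          stranded = "no", remove_multimapped = FALSE,
                          keep_only_proper_pairs = FALSE) {
  genes <- .oracle_parse_gff3(gff3)
  counts <- stats::setNames(numeric(length(genes)),
                            vapply(genes, `[[`, "", "id"))
  # ownership arrays per contig/strand-key
  keys <- character(0)
  for (g in genes) {
    keys <- union(keys, paste0(g$contig, "/",
                               if (stranded == "no") "*" else g$strand))
  }
  maxend <- max(vapply(genes, `[[`, 0L, "end"))
  cover <- lapply(keys, function(k) integer(maxend))
  owner <- lapply(keys, function(k) integer(maxend))
  names(cover) <- names(owner) <- keys
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    k <- paste0(g$contig, "/", if (stranded == "no") "*" else g$strand)
    idx <- (g$start + 1L):g$end
    cover[[k]][idx] <- cover[[k]][idx] + 1L
    owner[[k]][idx] <- gi
  }
  for (k in keys) owner[[k]][cover[[k]] != 1L] <- 0L

  for (ln in readLines(sam)) {
    if (startsWith(ln, "@")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    flag <- as.integer(f[2L]); pos <- as.integer(f[4L])
    mapq <- as.integer(f[5L]); tlen <- as.integer(f[9L])
    if (bitwAnd(flag, 0x4L) != 0L) next                    # unmapped
    if (bitwAnd(flag, 0x100L) != 0L) next                  # secondary
    if (bitwAnd(flag, 0x800L) != 0L) next                  # supplementary
    if (mapq < min_mapq) next
    nh <- NA_integer_
    if (length(f) > 11L) {
      for (tg in f[12:length(f)]) {
        if (startsWith(tg, "NH:i:")) nh <- as.integer(substring(tg, 6L))
      }
    }
    if (!is.na(nh) && nh > 1L) next      # multimapped: not part of N_f0
    proper <- bitwAnd(flag, 0x2L) != 0L
    same_ctg <- f[7L] %in% c("=", f[3L])
    frag <- proper && same_ctg && !is.na(tlen) && tlen != 0L &&
      abs(tlen) < max_fragment_size
    if (frag && tlen < 0L) next          # rightmost mate, inferable
    if (frag) {
      s0 <- pos - 1L; e0 <- s0 + tlen; fl <- tlen; half <- 1
    } else {
      if (keep_only_proper_pairs) next
      w <- .oracle_cigar_refwidth(f[6L])
      s0 <- pos - 1L; e0 <- s0 + w; fl <- w; half <- 0.5
    }
    if (stranded == "no") {
      key_strand <- "*"
    } else {
      if (frag) {
        first <- bitwAnd(flag, 0x40L) != 0L
        rev <- if (first) bitwAnd(flag, 0x10L) != 0L else
          bitwAnd(flag, 0x20L) != 0L
      } else {
        rev <- bitwAnd(flag, 0x10L) != 0L
      }
      s <- if (rev) "-" else "+"
      if (stranded == "reverse") s <- if (s == "+") "-" else "+"
      key_strand <- s
    }
    k <- paste0(f[3L], "/", key_strand)
    ow <- owner[[k]]
    if (is.null(ow)) next
    for (b in (s0 + 1L):e0) {
      if (b >= 1L && b <= length(ow) && ow[b] > 0L) {
        counts[ow[b]] <- counts[ow[b]] + half / fl
      }
    }
  }
  counts
}
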