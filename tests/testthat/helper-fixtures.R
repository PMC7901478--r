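# Shared helpers: tiny GFF3/SAM writers for hand-built cases, a per-position
# brute-force index oracle, a whole-count comparison mode (each unit counts 1
# toward every feature it overlaps -- the liberal strategy the proportional
# method is contrasted with), and randomized fixture specs.

write_tmp_gff3 <- function(lines) {
  p <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), p)
  p
}

write_tmp_sam <- function(body, contig = "chr1", len = 100000L) {
  p <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, len),
               body), p)
  p
}

# brute-force unique sets: count covering features at every base
brute_unique_lengths <- function(features, strand_aware) {
  key <- if (strand_aware) paste(features$contig, features$strand)
         else features$contig
  out <- setNames(numeric(length(unique(features$feature_id))),
                  unique(features$feature_id))
  for (k in unique(key)) {
    rows <- features[key == k, , drop = FALSE]
    maxend <- max(rows$end)
    cov <- integer(maxend); own <- character(maxend)
    for (i in seq_len(nrow(rows))) {
      idx <- (rows$start[i] + 1L):rows$end[i]
      cov[idx] <- cov[idx] + 1L
      own[idx] <- rows$feature_id[i]
    }
    for (f in unique(rows$feature_id)) {
      out[f] <- out[f] + sum(cov == 1L & own == f)
    }
  }
  out
}

# random small annotation as a feature_records-like data.frame
random_features <- function(n, maxpos = 5000L) {
  starts <- sample.int(maxpos - 200L, n, replace = TRUE)
  lens <- sample(20:200, n, replace = TRUE)
  df <- data.frame(
    feature_id = sprintf("f%03d", seq_len(n)),
    contig = sample(c("c1", "c2"), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    start = starts, end = starts + lens,
    feature_type = "gene", stringsAsFactors = FALSE)
  attr(df, "feature_order") <- df$feature_id
  df
}

# whole-count mode: one full count per unit to every feature whose span it
# overlaps at all (test-harness only; the contrast for the operon and
# read-through checks)
whole_counts <- function(gff3, sam, stranded = "no") {
  feats <- parse_features(gff3)
  units <- read_alignment_units(sam, stranded = stranded)
  out <- setNames(numeric(length(attr(feats, "feature_order"))),
                  attr(feats, "feature_order"))
  if (nrow(units) == 0L) return(out)
  for (i in seq_len(nrow(units))) {
    for (j in seq_len(nrow(feats))) {
      same_bin <- units$contig[i] == feats$contig[j] &&
        (stranded == "no" || units$strand[i] == feats$strand[j])
      if (same_bin &&
          min(units$end[i], feats$end[j]) >
            max(units$start[i], feats$start[j])) {
        out[feats$feature_id[j]] <- out[feats$feature_id[j]] + 1
      }
    }
  }
  out
}

# randomized fixture spec for property-style loops
random_fixture_spec <- function(i) {
  scen <- c("operon", "overlap_pair", "neighbor_readthrough",
            "multimap", "singleton_mix")[(i %% 5L) + 1L]
  list(scenario = scen,
       n_genes = sample(2:6, 1L),
       gene_len = sample(c(150L, 300L, 500L), 1L),
       gap = sample(c(10L, 50L, 150L), 1L),
       depth = sample(3:10, 1L),
       fragment_len = sample(c(120L, 250L), 1L),
       read_len = 60L,
       seed = 10000L + i)
}

make_random_fixture <- function(i) {
  sp <- random_fixture_spec(i)
  do.call(make_fixture, c(sp, list(out_dir = tempfile())))
}

# permute SAM body lines within groups sharing a POS (ties)
shuffle_sam_ties <- function(sam, seed = 1L) {
  lines <- readLines(sam)
  hdr <- grepl("^@", lines)
  body <- lines[!hdr]
  pos <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 4L))
  set.seed(seed)
  idx <- unlist(lapply(split(seq_along(body), pos),
                       function(ii) if (length(ii) > 1L) sample(ii) else ii),
                use.names = FALSE)
  out <- tempfile(fileext = ".sam")
  writeLines(c(lines[hdr], body[idx]), out)
  out
}
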