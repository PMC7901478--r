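# SAM flag bits used below
.FLAG_PAIRED <- 0x1L
.FLAG_PROPER <- 0x2L
.FLAG_UNMAPPED <- 0x4L
.FLAG_REVERSE <- 0x10L
.FLAG_MATE_REVERSE <- 0x20L
.FLAG_FIRST <- 0x40L
.FLAG_SECONDARY <- 0x100L
.FLAG_SUPPLEMENTARY <- 0x800L

.has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Open an alignment file for streaming
#'
#' Accepts BAM directly; a SAM file (extension \code{.sam} or text content)
#' is converted to a temporary BAM with \code{Rsamtools::asBam} first, so
#' plain-text fixtures can be quantified without external binaries.
#' @param path BAM or SAM file.
#' @return path to a readable BAM file.
#' @keywords internal
.as_bam_path <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    return(Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE))
  }
  path
}

# internal: classify one chunk of raw scanBam fields into alignment units.
# Returns a data.frame of units plus discard tallies as an attribute.
# Coordinates are emitted 0-based half-open.
.classify_chunk <- function(raw, min_mapq, max_fragment_size, stranded,
                            remove_multimapped, keep_only_proper_pairs,
                            include_secondary) {
  n <- length(raw$flag)
  tally <- c(records = n, unmapped = 0L, secondary = 0L, supplementary = 0L,
             low_mapq = 0L, multimapped_removed = 0L, deferred_mate = 0L,
             not_proper_dropped = 0L, tlen_zero_demoted = 0L,
             fragments = 0L, reads = 0L)
  if (n == 0L) {
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      kind = character(0), F_L = integer(0),
                      multi = logical(0), template = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "tally") <- tally
    return(out)
  }
  flag <- raw$flag
  nh <- raw$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, n)
  multi <- !is.na(nh) & nh > 1L

  unmapped <- .has_flag(flag, .FLAG_UNMAPPED) | is.na(raw$pos)
  secondary <- .has_flag(flag, .FLAG_SECONDARY)
  suppl <- .has_flag(flag, .FLAG_SUPPLEMENTARY)
  # opt-in: keep secondary records of multimapped templates (skip their MAPQ,
  # which aligners conventionally zero out for non-primary records)
  sec_kept <- include_secondary & secondary & multi & !remove_multimapped
  mapq_ok <- is.na(raw$mapq) | raw$mapq >= min_mapq | sec_kept

  drop_unmapped <- unmapped
  drop_secondary <- !drop_unmapped & secondary & !sec_kept
  drop_suppl <- !drop_unmapped & !drop_secondary & suppl
  drop_mapq <- !drop_unmapped & !drop_secondary & !drop_suppl & !mapq_ok
  kept <- !(drop_unmapped | drop_secondary | drop_suppl | drop_mapq)
  drop_multi <- kept & remove_multimapped & multi
  kept <- kept & !drop_multi

  tally["unmapped"] <- sum(drop_unmapped)
  tally["secondary"] <- sum(drop_secondary)
  tally["supplementary"] <- sum(drop_suppl)
  tally["low_mapq"] <- sum(drop_mapq)
  tally["multimapped_removed"] <- sum(drop_multi)

  flag <- flag[kept]
  contig <- as.character(raw$rname)[kept]
  pos0 <- raw$pos[kept] - 1L            # to 0-based
  isize <- raw$isize[kept]
  cigar <- raw$cigar[kept]
  qname <- raw$qname[kept]
  mrnm <- as.character(raw$mrnm)[kept]
  multi <- multi[kept]

  same_contig <- !is.na(mrnm) & mrnm == contig
  proper <- .has_flag(flag, .FLAG_PROPER)
  has_tlen <- !is.na(isize) & isize != 0L
  frag_ok <- proper & same_contig & has_tlen &
    abs(isize) < max_fragment_size
  tally["tlen_zero_demoted"] <- sum(proper & same_contig &
                                      !is.na(isize) & isize == 0L)

  is_frag <- frag_ok & isize > 0L       # leftmost mate carries the fragment
  is_defer <- frag_ok & isize < 0L      # rightmost mate: inferable, dropped
  is_read <- !frag_ok
  tally["deferred_mate"] <- sum(is_defer)

  if (keep_only_proper_pairs) {
    tally["not_proper_dropped"] <- sum(is_read)
    is_read <- rep(FALSE, length(is_read))
  }

  # fragment strand = strand of the first-in-pair read; read strand = its own
  own_rev <- .has_flag(flag, .FLAG_REVERSE)
  mate_rev <- .has_flag(flag, .FLAG_MATE_REVERSE)
  first <- .has_flag(flag, .FLAG_FIRST)
  frag_strand <- ifelse(first, ifelse(own_rev, "-", "+"),
                        ifelse(mate_rev, "-", "+"))
  read_strand <- ifelse(own_rev, "-", "+")
  eff <- function(s) {
    if (stranded == "no") rep("*", length(s))
    else if (stranded == "reverse") ifelse(s == "+", "-", "+")
    else s
  }

  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)

  units <- rbind(
    if (any(is_frag)) data.frame(
      contig = contig[is_frag],
      start = pos0[is_frag],
      end = pos0[is_frag] + isize[is_frag],
      strand = eff(frag_strand[is_frag]),
      kind = "fragment",
      F_L = isize[is_frag],
      multi = multi[is_frag],
      template = qname[is_frag],
      stringsAsFactors = FALSE),
    if (any(is_read)) data.frame(
      contig = contig[is_read],
      start = pos0[is_read],
      end = pos0[is_read] + ref_width[is_read],
      strand = eff(read_strand[is_read]),
      kind = "read",
      F_L = ref_width[is_read],
      multi = multi[is_read],
      template = qname[is_read],
      stringsAsFactors = FALSE)
  )
  if (is.null(units)) units <- data.frame(
    contig = character(0), start = integer(0), end = integer(0),
    strand = character(0), kind = character(0), F_L = integer(0),
    multi = logical(0), template = character(0), stringsAsFactors = FALSE)
  tally["fragments"] <- sum(units$kind == "fragment")
  tally["reads"] <- sum(units$kind == "read")
  attr(units, "tally") <- tally
  units
}

#' Stream alignment units from a BAM/SAM file
#'
#' Validates each record (mapped, primary, MAPQ threshold, optional NH-based
#' multimapper removal), reconstructs properly paired fragments from the
#' leftmost mate's TLEN, and emits countable units in chunks. For a properly
#' paired record with mate on the same contig and 0 < |TLEN| <
#' \code{max_fragment_size}, only the leftmost mate emits a unit of kind
#' \code{fragment} spanning \code{[pos, pos + TLEN)}; its mate is dropped as
#' inferable. Every other kept record emits a unit of kind \code{read}
#' covering its aligned reference span, whose proportional counts are later
#' halved.
#'
#' @param path coordinate-sorted BAM (or plain SAM) file.
#' @param min_mapq minimum mapping quality, inclusive (default 10).
#' @param max_fragment_size exclusive upper bound on |TLEN| for fragment
#'   reconstruction (default 1000).
#' @param stranded one of \code{"no"}, \code{"yes"} (forward), \code{"reverse"}.
#' @param remove_multimapped drop records whose NH tag exceeds 1.
#' @param keep_only_proper_pairs drop all units that are not reconstructed
#'   fragments.
#' @param include_secondary admit secondary alignments of multimapped
#'   templates so the EM step can weigh alternative loci (default FALSE:
#'   primary records only).
#' @param chunk_size records read per chunk (default 1e7). Final counts are
#'   invariant to this value.
#' @param callback optional \code{function(units_chunk)} invoked per chunk;
#'   when supplied the units are not accumulated in memory.
#' @return when \code{callback} is NULL, a data.frame of alignment units
#'   (columns \code{contig,start,end,strand,kind,F_L,multi,template};
#'   coordinates 0-based half-open) with a \code{"tally"} attribute of
#'   record-level bookkeeping. Otherwise the tally vector.
#' @export
read_alignment_units <- function(path, min_mapq = 10L,
                                 max_fragment_size = 1000L,
                                 stranded = c("no", "yes", "reverse"),
                                 remove_multimapped = FALSE,
                                 keep_only_proper_pairs = FALSE,
                                 include_secondary = FALSE,
                                 chunk_size = 1e7,
                                 callback = NULL) {
  stranded <- match.arg(stranded)
  stopifnot(chunk_size >= 1)
  bam <- .as_bam_path(path)
  bf <- Rsamtools::BamFile(bam, yieldSize = as.integer(min(chunk_size,
                                                           .Machine$integer.max)))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
             "isize"),
    tag = "NH")
  open(bf)
  on.exit(close(bf))
  total_tally <- NULL
  chunks <- list()
  repeat {
    raw <- Rsamtools::scanBam(bf, param = param)[[1L]]
    if (length(raw$flag) == 0L) break
    units <- .classify_chunk(raw, min_mapq, max_fragment_size, stranded,
                             remove_multimapped, keep_only_proper_pairs,
                             include_secondary)
    t <- attr(units, "tally")
    total_tally <- if (is.null(total_tally)) t else total_tally + t
    if (is.null(callback)) chunks[[length(chunks) + 1L]] <- units
    else callback(units)
  }
  if (is.null(total_tally)) {
    total_tally <- attr(.classify_chunk(list(flag = integer(0)), min_mapq,
                                        max_fragment_size, stranded,
                                        remove_multimapped,
                                        keep_only_proper_pairs,
                                        include_secondary), "tally")
  }
  if (!is.null(callback)) return(total_tally)
  out <- if (length(chunks)) do.call(rbind, chunks) else
    .classify_chunk(list(flag = integer(0)), min_mapq, max_fragment_size,
                    stranded, remove_multimapped, keep_only_proper_pairs,
                    include_secondary)
  rownames(out) <- NULL
  attr(out, "tally") <- total_tally
  out
}
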