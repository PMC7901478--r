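#' Parse genic features from a GFF3 annotation
#'
#' Reads a GFF3 file, keeps the rows whose type column equals
#' \code{feature_type}, and keys them by the value of \code{attribute_tag}
#' (column 9 attribute, e.g. \code{ID}). Coordinates are converted from the
#' GFF3 1-based inclusive convention to 0-based half-open intervals, the
#' convention used throughout this package. Rows sharing a feature identifier
#' (multi-interval features) are merged into a single feature whose interval
#' set is the union of its rows.
#'
#' @param gff3_path path to a GFF3 file. Comment lines and any trailing
#'   \code{##FASTA} section are ignored.
#' @param feature_type value of column 3 selecting the rows to quantify
#'   (default \code{"gene"}).
#' @param attribute_tag attribute key providing the feature identifier
#'   (default \code{"ID"}).
#' @return a data.frame of class \code{feature_records} with one row per
#'   interval: \code{feature_id}, \code{contig}, \code{strand} (\code{+}/\code{-}),
#'   \code{start}, \code{end} (0-based half-open), \code{feature_type}.
#'   Attribute \code{"feature_order"} holds the distinct feature identifiers
#'   in annotation order.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\t.\tgene\t101\t200\t.\t+\t.\tID=gA"), gff)
#' parse_features(gff)
#' @export
parse_features <- function(gff3_path, feature_type = "gene",
                           attribute_tag = "ID") {
  stopifnot(nzchar(feature_type), nzchar(attribute_tag))
  if (!file.exists(gff3_path)) {
    stop("GFF3 file not found: ", gff3_path)
  }
  gff <- tryCatch(
    rtracklayer::readGFF(gff3_path, columns = c("seqid", "type", "start",
                                                "end", "strand"),
                         tags = attribute_tag),
    error = function(e) stop("malformed GFF3 '", gff3_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  gff <- as.data.frame(gff)
  sel <- gff[as.character(gff$type) == feature_type, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop("no rows of type '", feature_type, "' in ", gff3_path)
  }
  ids <- as.character(sel[[attribute_tag]])
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    bad <- which(is.na(ids) | !nzchar(ids))[1L]
    stop("selected row ", bad, " (", as.character(sel$seqid[bad]), ":",
         sel$start[bad], "-", sel$end[bad], ") lacks attribute '",
         attribute_tag, "'")
  }
  strand <- as.character(sel$strand)
  if (any(!strand %in% c("+", "-"))) {
    bad <- which(!strand %in% c("+", "-"))[1L]
    stop("feature '", ids[bad], "' has strand '", strand[bad],
         "'; only '+' or '-' are supported")
  }
  out <- data.frame(
    feature_id = ids,
    contig = as.character(sel$seqid),
    strand = strand,
    start = as.integer(sel$start) - 1L,  # to 0-based half-open
    end = as.integer(sel$end),
    feature_type = feature_type,
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end)) {
    bad <- which(out$start >= out$end)[1L]
    stop("feature '", out$feature_id[bad], "' has non-positive span")
  }
  # identity must be unambiguous: one contig and one strand per feature_id
  amb <- tapply(paste(out$contig, out$strand), out$feature_id,
                function(x) length(unique(x)))
  if (any(amb > 1L)) {
    stop("feature id '", names(amb)[amb > 1L][1L],
         "' occurs on multiple contigs or strands; ambiguous identity")
  }
  attr(out, "feature_order") <- unique(out$feature_id)
  class(out) <- c("feature_records", class(out))
  out
}

#' Build the unique (non-overlapping) position index
#'
#' A genomic position belongs to a feature's unique set when it is covered by
#' that feature and by no other feature on the same strand key. Positions
#' covered by two or more features are ambiguous and earn counts for nobody.
#' When \code{strand_aware} is \code{FALSE} all features on a contig share a
#' single strand key (strand-agnostic counting for unstranded libraries).
#'
#' @param features a \code{feature_records} data.frame from
#'   \code{\link{parse_features}}.
#' @param strand_aware logical; match features and alignments by strand?
#' @return an object of class \code{unique_index}: disjoint unique intervals
#'   per (contig, strand key) and the per-feature unique positional length
#'   \code{uniq_len} (used later as the TPM length).
#' @export
build_unique_index <- function(features, strand_aware = FALSE) {
  stopifnot(is.data.frame(features), nrow(features) > 0L)
  forder <- attr(features, "feature_order")
  if (is.null(forder)) forder <- unique(features$feature_id)
  key <- if (strand_aware) features$strand else rep("*", nrow(features))
  bin_id <- paste0(features$contig, "\r", key)
  bins <- list()
  uniq_len <- stats::setNames(numeric(length(forder)), forder)
  for (b in unique(bin_id)) {
    rows <- features[bin_id == b, , drop = FALSE]
    ir <- IRanges::IRanges(start = rows$start + 1L, end = rows$end)
    cov <- IRanges::coverage(ir)
    ambig <- IRanges::slice(cov, lower = 2L, rangesOnly = TRUE)
    per_feat <- split(ir, rows$feature_id)
    fid <- character(0); us <- integer(0); ue <- integer(0)
    for (f in names(per_feat)) {
      u <- IRanges::setdiff(IRanges::reduce(per_feat[[f]]), ambig)
      if (length(u)) {
        fid <- c(fid, rep(f, length(u)))
        us <- c(us, IRanges::start(u) - 1L)
        ue <- c(ue, IRanges::end(u))
        uniq_len[f] <- uniq_len[f] + sum(IRanges::width(u))
      }
    }
    o <- order(us)
    bins[[b]] <- data.frame(feature_id = fid[o], start = us[o], end = ue[o],
                            stringsAsFactors = FALSE)
  }
  structure(list(strand_aware = strand_aware,
                 features = forder,
                 uniq_len = uniq_len,
                 bins = bins),
            class = "unique_index")
}

#' @export
print.unique_index <- function(x, ...) {
  cat("unique_index:", length(x$features), "features,",
      length(x$bins), "contig/strand bins,",
      if (x$strand_aware) "strand-aware" else "strand-agnostic", "\n")
  cat("  total unique length:", sum(x$uniq_len), "bp;",
      sum(x$uniq_len == 0), "feature(s) with zero unique length\n")
  invisible(x)
}

# internal: strand key for an alignment unit's effective strand
.unit_key <- function(index, strand) {
  if (index$strand_aware) strand else rep("*", length(strand))
}
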