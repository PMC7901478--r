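#' Overlap of an alignment unit with unique feature positions
#'
#' For one unit, returns F_O per feature: the number of bases of the unit's
#' span that fall in the feature's unique (singly covered) positions.
#' Ambiguous positions, covered by two or more features on the unit's strand
#' key, contribute to no feature. Features with F_O = 0 are omitted.
#'
#' @param unit a one-row data.frame (or list) with \code{contig},
#'   \code{start}, \code{end} (0-based half-open) and \code{strand}.
#' @param index a \code{unique_index}.
#' @return named numeric vector, feature id -> F_O in bases (possibly empty).
#' @export
overlap_unique <- function(unit, index) {
  key <- paste0(unit$contig, "\r",
                if (index$strand_aware) unit$strand else "*")
  bin <- index$bins[[key]]
  if (is.null(bin) || nrow(bin) == 0L) return(stats::setNames(numeric(0), character(0)))
  ov <- pmin(bin$end, unit$end) - pmax(bin$start, unit$start)
  hit <- ov > 0
  if (!any(hit)) return(stats::setNames(numeric(0), character(0)))
  fo <- tapply(ov[hit], bin$feature_id[hit], sum)
  stats::setNames(as.numeric(fo), names(fo))
}

#' Proportional count of one overlap
#'
#' The core statistic: \code{F_c = F_O / F_L}, the fraction of the fragment
#' lying in the feature's unique positions. For unpaired units
#' (kind \code{read}: singletons, discordant pairs, overlong templates) the
#' value is halved, so that the two reads of a broken pair can never
#' contribute more than one fragment's worth of count.
#'
#' @param F_O bases of overlap with unique positions (0..F_L).
#' @param F_L total fragment (or aligned read) length in bases.
#' @param kind \code{"fragment"} or \code{"read"}.
#' @return F_c in [0, 1].
#' @export
proportional_count <- function(F_O, F_L, kind = c("fragment", "read")) {
  kind <- match.arg(kind)
  stopifnot(all(F_L > 0), all(F_O >= 0), all(F_O <= F_L))
  fc <- F_O / F_L
  if (kind == "read") fc <- fc / 2
  fc
}

#' Create an empty counting state
#'
#' Accumulators for one quantification run: \code{N_f0} (fractional counts
#' from uniquely mapped units), \code{n_align} (units overlapping each
#' feature), and the deferred multimapped contributions \code{mm_contribs}
#' ((template, feature, N_rf) triples) processed later by the EM step.
#'
#' @param index a \code{unique_index}.
#' @return a \code{count_state} environment.
#' @export
new_count_state <- function(index) {
  st <- new.env(parent = emptyenv())
  st$N_f0 <- stats::setNames(numeric(length(index$features)), index$features)
  st$n_align <- stats::setNames(integer(length(index$features)),
                                index$features)
  st$mm <- list()                      # list of data.frames, bound lazily
  class(st) <- "count_state"
  st
}

# internal, vectorized: overlaps of a chunk of units against the index.
# Returns data.frame(unit, feature_id, F_O) for F_O > 0.
.chunk_overlaps <- function(units, index) {
  if (nrow(units) == 0L) {
    return(data.frame(unit = integer(0), feature_id = character(0),
                      F_O = numeric(0), stringsAsFactors = FALSE))
  }
  key <- paste0(units$contig, "\r",
                if (index$strand_aware) units$strand else "*")
  res <- vector("list", length(unique(key)))
  i <- 0L
  for (k in unique(key)) {
    bin <- index$bins[[k]]
    if (is.null(bin) || nrow(bin) == 0L) next
    rows <- which(key == k)
    uq <- IRanges::IRanges(start = units$start[rows] + 1L,
                           end = units$end[rows])
    bq <- IRanges::IRanges(start = bin$start + 1L, end = bin$end)
    hits <- IRanges::findOverlaps(uq, bq)
    if (length(hits) == 0L) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    w <- IRanges::width(IRanges::pintersect(uq[qh], bq[sh]))
    df <- data.frame(unit = rows[qh], feature_id = bin$feature_id[sh],
                     F_O = as.numeric(w), stringsAsFactors = FALSE)
    # a unit can hit several unique intervals of the same feature
    agg <- stats::aggregate(F_O ~ unit + feature_id, data = df, FUN = sum)
    i <- i + 1L
    res[[i]] <- agg
  }
  if (i == 0L) {
    return(data.frame(unit = integer(0), feature_id = character(0),
                      F_O = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, res[seq_len(i)])
}

#' Accumulate a chunk of alignment units into the counting state
#'
#' Uniquely mapped units add \code{F_c = F_O/F_L} (halved for reads) to
#' \code{N_f0} and increment \code{n_align} for every feature they overlap.
#' Multimapped units are not counted yet: their (template, feature, F_c)
#' contributions are stored and handed to the EM step after all uniquely
#' mapped records are processed. Accumulation is order-independent.
#'
#' @param units a chunk from \code{\link{read_alignment_units}}.
#' @param index a \code{unique_index}.
#' @param state a \code{count_state}; modified in place and returned.
#' @export
accumulate <- function(units, index, state) {
  ov <- .chunk_overlaps(units, index)
  if (nrow(ov) == 0L) return(invisible(state))
  fl <- units$F_L[ov$unit]
  fc <- ov$F_O / fl
  is_read <- units$kind[ov$unit] == "read"
  fc[is_read] <- fc[is_read] / 2
  multi <- units$multi[ov$unit]

  # n_align counts every retained unit with F_O > 0, multimapped included
  na_tab <- table(ov$feature_id)
  state$n_align[names(na_tab)] <- state$n_align[names(na_tab)] +
    as.integer(na_tab)

  if (any(!multi)) {
    add <- tapply(fc[!multi], ov$feature_id[!multi], sum)
    state$N_f0[names(add)] <- state$N_f0[names(add)] + as.numeric(add)
  }
  if (any(multi)) {
    state$mm[[length(state$mm) + 1L]] <- data.frame(
      template = units$template[ov$unit[multi]],
      feature_id = ov$feature_id[multi],
      N_rf = fc[multi],
      stringsAsFactors = FALSE)
  }
  invisible(state)
}

# internal: collapse deferred multimapped contributions to one row per
# (template, feature), summing N_rf across a template's alignments.
.mm_contribs <- function(state) {
  if (length(state$mm) == 0L) {
    return(data.frame(template = character(0), feature_id = character(0),
                      N_rf = numeric(0), stringsAsFactors = FALSE))
  }
  mm <- do.call(rbind, state$mm)
  stats::aggregate(N_rf ~ template + feature_id, data = mm, FUN = sum)
}
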