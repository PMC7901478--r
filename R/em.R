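#' Per-record EM weights
#'
#' For one multimapped record r overlapping features rF with stored
#' contributions N_rf, the weight of feature f is its share of the current
#' abundance among the features the record maps to:
#' \code{a_rf = N_f / N_rF} with \code{N_rF = sum over f in rF of N_f}.
#' Weights sum to 1. If every overlapped feature currently has zero count
#' (degenerate record) the weights are split equally.
#'
#' @param feature_ids features overlapped by the record.
#' @param N_current named numeric of current feature counts (N_f,k).
#' @return named numeric of weights summing to 1.
#' @export
em_record_weights <- function(feature_ids, N_current) {
  w <- N_current[feature_ids]
  tot <- sum(w)
  if (tot > 0) w / tot
  else stats::setNames(rep(1 / length(feature_ids), length(feature_ids)),
                       feature_ids)
}

#' EM redistribution of multimapped contributions
#'
#' Iterates the update
#' \deqn{N_{f,k} = N_{f,0} + \sum_{r \in Rmm} a_{r,f} N_{r,f}}
#' where the weights \code{a_rf} of iteration 1 are computed from the
#' uniquely-mapped-only counts \code{N_f0}, and each later iteration
#' recomputes them from the previous iteration's \code{N_fk}. \code{K = 0}
#' returns \code{N_f0} untouched. Deterministic; no randomness.
#'
#' @param N_f0 named numeric; counts from uniquely mapped units only.
#' @param mm_contribs data.frame with columns \code{template},
#'   \code{feature_id}, \code{N_rf}: one row per (multimapped record,
#'   overlapped feature).
#' @param K number of EM iterations (>= 0).
#' @param tol optional: stop early once the convergence delta
#'   (sum over features of |N_fk - N_f,k-1|) falls below \code{tol}.
#' @return list with \code{N_fk} (final counts), \code{delta}
#'   (per-iteration convergence series, as in the usual EM diagnostics
#'   plot), \code{iterations} run, and \code{weight_sum_range}: per
#'   iteration, the range of per-record weight sums (should be exactly 1).
#' @export
em_iterate <- function(N_f0, mm_contribs, K = 1L, tol = NULL) {
  stopifnot(K >= 0)
  if (K == 0L || is.null(mm_contribs) || nrow(mm_contribs) == 0L) {
    return(list(N_fk = N_f0, delta = numeric(0), iterations = 0L,
                weight_sum_range = matrix(numeric(0), ncol = 2)))
  }
  stopifnot(all(mm_contribs$feature_id %in% names(N_f0)))
  rid <- match(mm_contribs$template, unique(mm_contribs$template))
  fid <- mm_contribs$feature_id
  nrf <- mm_contribs$N_rf
  n_per_rec <- tabulate(rid)[rid]

  N_prev <- N_f0
  delta <- numeric(0)
  wrange <- matrix(NA_real_, nrow = K, ncol = 2)
  k_done <- 0L
  for (k in seq_len(K)) {
    w <- as.numeric(N_prev[fid])
    denom <- as.numeric(rowsum(w, rid))[rid]
    a <- ifelse(denom > 0, w / denom, 1 / n_per_rec)
    ws <- rowsum(a, rid)
    wrange[k, ] <- range(ws)
    adj <- rowsum(a * nrf, fid)
    N_k <- N_f0
    N_k[rownames(adj)] <- N_k[rownames(adj)] + as.numeric(adj)
    delta <- c(delta, sum(abs(N_k - N_prev)))
    N_prev <- N_k
    k_done <- k
    if (!is.null(tol) && delta[k] < tol) break
  }
  list(N_fk = N_prev, delta = delta, iterations = k_done,
       weight_sum_range = wrange[seq_len(k_done), , drop = FALSE])
}

#' Convergence series of an EM run
#'
#' The per-iteration delta: the sum across features of the absolute
#' difference between the current and the previous iteration's counts
#' (iteration 0 being the uniquely-mapped baseline).
#'
#' @param em result of \code{\link{em_iterate}}.
#' @return numeric vector of deltas, one per iteration run.
#' @export
convergence_series <- function(em) em$delta
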