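# Nearest-neighbor lipid tail pair statistics for the central bilayer.
# Six tail classes (extended/hairpin acyl and sphingosine CER chains, CHOL,
# FFA) form 21 unordered pair types; observed pair frequencies are
# normalized against the combinatorial expectation for a perfectly mixed
# system (N_i * N_j for unlike pairs, N(N-1)/2 for like pairs).

pair_keys <- function() {
  cls <- TAIL_CLASSES
  idx <- which(upper.tri(diag(6), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
  data.frame(tail_1 = cls[idx[, "row"]], tail_2 = cls[idx[, "col"]],
             stringsAsFactors = FALSE)
}

pair_key_of <- function(a, b) {
  i <- match(a, TAIL_CLASSES); j <- match(b, TAIL_CLASSES)
  lo <- pmin(i, j); hi <- pmax(i, j)
  paste(TAIL_CLASSES[lo], TAIL_CLASSES[hi], sep = "|")
}

#' k-nearest-neighbor lists for lipid tails
#'
#' For every tail, its k nearest other tails by three-dimensional
#' center-of-mass distance with the minimum image applied in the membrane
#' plane (x, y) and z left unwrapped. CHOL query tails use `k_chol`
#' neighbors (CHOL has ~7 in-plane neighbors on average); all other tails
#' use `k`. Distance ties are broken by particle order.
#'
#' @param tails data.frame with columns `tail_class` (or `tail_type`),
#'   `x`, `y`, `z` — e.g. from [tail_instances()] restricted to the central
#'   bilayer, or [make_mixed_central_bilayer()].
#' @param box box lengths (Lx, Ly[, Lz]).
#' @param k neighbors per non-CHOL tail (default 6).
#' @param k_chol neighbors per CHOL tail (default 7).
#' @return list of integer vectors: for tail i, the row indices of its
#'   nearest neighbors (length `k` or `k_chol`).
#' @export
knn_tail_neighbors <- function(tails, box, k = 6, k_chol = 7) {
  n <- nrow(tails)
  kmax <- max(k, k_chol)
  if (n < kmax + 1)
    stop(sprintf("need at least %d tails for k = %d, got %d", kmax + 1, kmax, n))
  cls <- if ("tail_class" %in% names(tails)) tails$tail_class else tails$tail_type
  dx <- outer(tails$x, tails$x, "-"); dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(tails$y, tails$y, "-"); dy <- dy - box[2] * round(dy / box[2])
  dz <- outer(tails$z, tails$z, "-")
  D <- dx * dx + dy * dy + dz * dz
  diag(D) <- Inf
  kk <- ifelse(cls == "CHOL", k_chol, k)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    out[[i]] <- ord[seq_len(kk[i])]
  }
  out
}

#' Raw neighbor-pair counts over the 21 tail-pair types
#'
#' Each directed neighbor relation (query tail -> one of its k nearest
#' neighbors) contributes one raw count to its unordered pair-type bin, so
#' the raw counts sum to `6 * n_nonCHOL + 7 * n_CHOL`. Because CHOL query
#' tails use a larger k, each relation additionally carries a weight
#' 1/k(query); the weighted occurrence is what the mixing-null
#' normalization consumes, which keeps the null exactly calibrated when k
#' differs between tail classes.
#'
#' @param neighbors neighbor lists from [knn_tail_neighbors()].
#' @param tail_class character vector of 6-level tail classes, one per tail.
#' @return data.frame of 21 rows: `tail_1`, `tail_2`, `raw`, `weighted`.
#' @export
pair_counts <- function(neighbors, tail_class) {
  keys <- pair_keys()
  keyname <- paste(keys$tail_1, keys$tail_2, sep = "|")
  raw <- stats::setNames(numeric(21), keyname)
  wts <- raw
  for (i in seq_along(neighbors)) {
    nb <- neighbors[[i]]
    kq <- length(nb)
    pk <- pair_key_of(rep(tail_class[i], kq), tail_class[nb])
    tab <- table(pk)
    raw[names(tab)] <- raw[names(tab)] + as.numeric(tab)
    wts[names(tab)] <- wts[names(tab)] + as.numeric(tab) / kq
  }
  cbind(keys, data.frame(raw = as.numeric(raw), weighted = as.numeric(wts)))
}

#' Mixing-null relative pair probabilities
#'
#' In a perfectly mixed system the probability that a pair of different
#' tail types forms is proportional to the product of the two type counts,
#' and for a like pair to N(N-1)/2; the relative probability divides by the
#' sum over all 21 pair types, so the result sums to 1.
#'
#' @param type_counts named counts for the six tail classes (missing
#'   classes count 0).
#' @return data.frame of 21 rows: `tail_1`, `tail_2`, `weight`,
#'   `rel_prob`. Degenerate input (fewer than 2 tails overall) is an error.
#' @export
expected_pair_relative_probability <- function(type_counts) {
  N <- stats::setNames(numeric(6), TAIL_CLASSES)
  N[names(type_counts)] <- as.numeric(type_counts)
  if (sum(N) < 2) stop("need at least 2 tails")
  keys <- pair_keys()
  w <- ifelse(keys$tail_1 == keys$tail_2,
              N[keys$tail_1] * (N[keys$tail_1] - 1) / 2,
              N[keys$tail_1] * N[keys$tail_2])
  if (sum(w) <= 0) stop("degenerate composition: no pair can form")
  cbind(keys, data.frame(weight = as.numeric(w),
                         rel_prob = as.numeric(w / sum(w))))
}

#' Mixing-null-normalized neighbor-pair counts
#'
#' Divides the relative occurrence of each pair type by the relative
#' probability of that pair under the perfectly-mixed null, so every value
#' has expectation 1 in a mixed system; preferred neighbor pairs exceed 1.
#' The occurrence uses the per-query-k-weighted counts from
#' [pair_counts()] (see there for why).
#'
#' @param counts 21-row table from [pair_counts()].
#' @param type_counts named tail-class counts of the same configuration.
#' @return `counts` with columns `rel_prob` and `normalized` added; pairs
#'   with zero null probability get `NA`.
#' @export
normalized_pair_counts <- function(counts, type_counts) {
  if (sum(counts$raw) <= 0) stop("no raw counts")
  null <- expected_pair_relative_probability(type_counts)
  stopifnot(identical(null$tail_1, counts$tail_1))
  occ <- counts$weighted / sum(counts$weighted)
  counts$rel_prob <- null$rel_prob
  counts$normalized <- ifelse(null$rel_prob > 0, occ / null$rel_prob, NA_real_)
  counts
}

#' One-call pair analysis of a tail configuration
#'
#' @param tails,box,k,k_chol as in [knn_tail_neighbors()].
#' @return normalized 21-row pair table.
#' @export
pair_analysis <- function(tails, box = attr(tails, "box"), k = 6, k_chol = 7) {
  nb <- knn_tail_neighbors(tails, box, k = k, k_chol = k_chol)
  cls <- if ("tail_class" %in% names(tails)) tails$tail_class else tails$tail_type
  pc <- pair_counts(nb, cls)
  normalized_pair_counts(pc, table(cls))
}

#' Aggregate pair tables over replicates
#'
#' @param tables list of normalized pair tables (same row order).
#' @return data.frame with per-pair mean and sd of the normalized count and
#'   mean raw count, sorted ascending by normalized mean (the presentation
#'   order of the study's pair table).
#' @export
aggregate_pair_tables <- function(tables) {
  keys <- tables[[1]][, c("tail_1", "tail_2")]
  nm <- sapply(tables, function(t) t$normalized)
  rw <- sapply(tables, function(t) t$raw)
  out <- cbind(keys, data.frame(
    normalized_count_mean = rowMeans(nm),
    normalized_count_sd = apply(nm, 1, stats::sd),
    raw_count_mean = rowMeans(rw)))
  out[order(out$normalized_count_mean), ]
}

#' Composition-normalized coordination numbers
#'
#' For a reference tail class i and neighbor class j, the mean number of
#' type-j tails among the k nearest neighbors of type-i tails, divided by
#' the perfectly-mixed expectation `k * N_j' / (N - 1)` with
#' `N_j' = N_j - delta_ij`; the null value is 1 for every entry.
#'
#' @param neighbors neighbor lists from [knn_tail_neighbors()].
#' @param tail_class 6-level class per tail.
#' @return data.frame: `reference`, `neighbor`, `coordination` (mean raw
#'   count), `normalized`. Reference classes with no tails are omitted.
#' @export
coordination_numbers <- function(neighbors, tail_class) {
  N <- table(factor(tail_class, levels = TAIL_CLASSES))
  n <- length(tail_class)
  rows <- list()
  for (ref in TAIL_CLASSES) {
    ii <- which(tail_class == ref)
    if (!length(ii)) next
    cnt <- matrix(0, length(ii), 6, dimnames = list(NULL, TAIL_CLASSES))
    for (a in seq_along(ii)) {
      tb <- table(factor(tail_class[neighbors[[ii[a]]]], levels = TAIL_CLASSES))
      cnt[a, ] <- as.numeric(tb)
    }
    kq <- length(neighbors[[ii[1]]])
    for (nbcl in TAIL_CLASSES) {
      Nj <- as.numeric(N[nbcl]) - (nbcl == ref)
      expc <- kq * Nj / (n - 1)
      rows[[length(rows) + 1L]] <- data.frame(
        reference = ref, neighbor = nbcl,
        coordination = mean(cnt[, nbcl]),
        normalized = if (expc > 0) mean(cnt[, nbcl]) / expc else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Central-bilayer tails of a system frame
#'
#' Convenience wrapper: leaflet assignment, tail enumeration, and
#' restriction to the two central leaflets.
#'
#' @param frame,topology as elsewhere; `leaflets` optional precomputed
#'   [assign_leaflets()] result.
#' @param n_leaflets used when `leaflets` is NULL.
#' @return tails data.frame with attribute `box`.
#' @export
central_bilayer_tails <- function(frame, topology, leaflets = NULL,
                                  n_leaflets = 6) {
  if (is.null(leaflets)) leaflets <- assign_leaflets(frame, topology, n_leaflets)
  ti <- tail_instances(frame, topology, leaflets)
  ti <- ti[ti$leaflet %in% leaflets$central_bilayer, ]
  attr(ti, "box") <- frame$box
  ti
}
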