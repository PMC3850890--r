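# Quantitative agreement between two segmentations. Region pairs are scored
# with three Jaccard-family coefficients:
#   c1 = |A n B| / |A u B|
#   c2 = |A n B| / (|A \ B| + |A u B|)
#   c3 = |A n B| / (|B \ A| + |A u B|)
# c1 carries no direction; a high c3 with low c2 flags under-segmentation of
# B relative to A and vice versa. Regions are matched one-to-one by the
# assignment maximizing total c1 (optimal, not greedy); aggregates are
# normalized by the larger cell count so unmatched cells count as zero; and
# automated-vs-observer coefficients can be normalized by the inter-observer
# disagreement so only disagreement beyond human variability is penalized.

#' Pairwise agreement coefficients
#'
#' @param A,B Voxel sets: logical arrays (same shape) or integer index
#'   vectors. At least one must be non-empty.
#' @return Named numeric `c(c1, c2, c3)`, each in `[0, 1]`.
#' @export
pair_coefficients <- function(A, B) {
  if (is.logical(A)) A <- which(A)
  if (is.logical(B)) B <- which(B)
  if (length(A) == 0 && length(B) == 0)
    stop("pair_coefficients undefined for two empty sets")
  ninter <- length(intersect(A, B))
  nunion <- length(A) + length(B) - ninter
  nAonly <- length(A) - ninter
  nBonly <- length(B) - ninter
  c(c1 = ninter / nunion,
    c2 = ninter / (nAonly + nunion),
    c3 = ninter / (nBonly + nunion))
}

# Overlap/count tables between two label volumes.
overlap_table <- function(L_a, L_b) {
  L_a <- as_volume(L_a); L_b <- as_volume(L_b)
  if (!identical(dim(L_a), dim(L_b))) stop("label volumes must share shape")
  ids_a <- sort(unique(L_a[L_a > 0L])); ids_b <- sort(unique(L_b[L_b > 0L]))
  na <- length(ids_a); nb <- length(ids_b)
  sz_a <- setNames(vapply(ids_a, function(k) sum(L_a == k), numeric(1)), ids_a)
  sz_b <- setNames(vapply(ids_b, function(k) sum(L_b == k), numeric(1)), ids_b)
  both <- L_a > 0L & L_b > 0L
  inter <- matrix(0, na, nb, dimnames = list(ids_a, ids_b))
  if (any(both)) {
    tab <- table(L_a[both], L_b[both])
    inter[rownames(tab), colnames(tab)] <- tab
  }
  list(ids_a = ids_a, ids_b = ids_b, sz_a = sz_a, sz_b = sz_b, inter = inter)
}

#' Optimal one-to-one region matching
#'
#' Among all overlapping region pairs between two label volumes, finds the
#' one-to-one assignment maximizing the total c1, so a region in one
#' segmentation maps to at most one region in the other. Solved exactly with
#' the Hungarian (shortest augmenting path) algorithm.
#'
#' @param L_a,L_b Integer label volumes of the same shape.
#' @return List: `pairs` (data.frame `label_a, label_b, c1, c2, c3`),
#'   `unmatched_a`, `unmatched_b`, `n_a`, `n_b`.
#' @export
match_regions <- function(L_a, L_b) {
  ot <- overlap_table(L_a, L_b)
  na <- length(ot$ids_a); nb <- length(ot$ids_b)
  empty <- data.frame(label_a = integer(0), label_b = integer(0),
                      c1 = numeric(0), c2 = numeric(0), c3 = numeric(0))
  if (na == 0L || nb == 0L)
    return(list(pairs = empty, unmatched_a = ot$ids_a, unmatched_b = ot$ids_b,
                n_a = na, n_b = nb))
  c1m <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    ninter <- ot$inter[i, j]
    if (ninter > 0)
      c1m[i, j] <- ninter / (ot$sz_a[i] + ot$sz_b[j] - ninter)
  }
  asn <- hungarian_max(c1m)
  rows <- which(asn > 0L & c1m[cbind(seq_len(na), pmax(asn, 1L))] > 0)
  pairs <- empty
  for (i in rows) {
    j <- asn[i]
    ninter <- ot$inter[i, j]
    nunion <- ot$sz_a[i] + ot$sz_b[j] - ninter
    pairs <- rbind(pairs, data.frame(
      label_a = ot$ids_a[i], label_b = ot$ids_b[j],
      c1 = ninter / nunion,
      c2 = ninter / ((ot$sz_a[i] - ninter) + nunion),
      c3 = ninter / ((ot$sz_b[j] - ninter) + nunion)))
  }
  list(pairs = pairs,
       unmatched_a = setdiff(ot$ids_a, pairs$label_a),
       unmatched_b = setdiff(ot$ids_b, pairs$label_b),
       n_a = na, n_b = nb)
}

# Maximum-weight one-to-one assignment (rows to columns) of a non-negative
# weight matrix; returns per-row column index (0 = unassigned). Jonker-style
# shortest augmenting path on the cost matrix max(w) - w, padded square.
hungarian_max <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  n <- max(nr, nc)
  cost <- matrix(max(w), n, n)
  cost[seq_len(nr), seq_len(nc)] <- max(w) - w
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)      # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L               # columns are 1-indexed with a virtual column 1 slot
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  asn <- integer(nr)
  for (j in 2:(n + 1)) {
    if (p[j] > 0L && p[j] <= nr && (j - 1L) <= nc) asn[p[j]] <- j - 1L
  }
  asn
}

#' Aggregate matched-pair coefficients over the cell count
#'
#' `C_i = sum of pairwise c_i / N` with `N = max(n_cells_a, n_cells_b)`, so
#' every unmatched cell on either side contributes zero and both missed and
#' spurious cells are penalized.
#'
#' @param pairs Data frame of matched pairs (from [match_regions()]).
#' @param n_cells_a,n_cells_b Cell counts of the two segmentations.
#' @return Named numeric `c(C1, C2, C3)`.
#' @export
aggregate_coefficients <- function(pairs, n_cells_a, n_cells_b) {
  N <- max(n_cells_a, n_cells_b)
  if (N == 0) stop("no cells available for evaluation")
  c(C1 = sum(pairs$c1) / N, C2 = sum(pairs$c2) / N, C3 = sum(pairs$c3) / N)
}

#' Inter-observer normalization of an agreement coefficient
#'
#' Two expert observers disagree with each other by `1 - C_i(O1-O2)`; an
#' automated method should only be penalized for disagreement exceeding that
#' human variability. The normalized coefficient adds the inter-observer
#' disagreement to the raw coefficient and caps at one:
#' `C_{i,n} = min(1, C_i + (1 - C_i_interobs))`.
#'
#' @param C_i Raw coefficient in `[0, 1]`.
#' @param C_i_interobs Inter-observer coefficient in `[0, 1]`.
#' @return Normalized coefficient in `[0, 1]`.
#' @export
normalize_interobserver <- function(C_i, C_i_interobs) {
  stopifnot(C_i >= 0, C_i <= 1, C_i_interobs >= 0, C_i_interobs <= 1)
  min(1, C_i + (1 - C_i_interobs))
}

#' Count fused, split, false-positive and false-negative cells
#'
#' Volume-independent error counts between an automated and a reference
#' segmentation, based on majority overlap (more than half of the smaller
#' region): reference cells sharing their majority automated region with
#' another reference cell are falsely fused; a reference cell majority-
#' covered by two or more automated regions counts one falsely split event
#' per extra fragment; automated regions with no majority overlap to any
#' reference cell are false positives; reference cells with none are false
#' negatives.
#'
#' @param L_auto,L_ref Integer label volumes of the same shape.
#' @return Named integer vector
#'   `c(falsely_fused, falsely_split, false_positive, false_negative)`.
#' @export
count_errors <- function(L_auto, L_ref) {
  ot <- overlap_table(L_ref, L_auto)   # rows: reference, cols: automated
  nref <- length(ot$ids_a); nauto <- length(ot$ids_b)
  maj <- matrix(FALSE, nref, nauto)
  if (nref && nauto)
    for (i in seq_len(nref)) for (j in seq_len(nauto))
      maj[i, j] <- ot$inter[i, j] > 0.5 * min(ot$sz_a[i], ot$sz_b[j])
  fused <- 0L; split <- 0L
  if (nref && nauto) {
    # majority auto region of each reference cell (largest overlap among majors)
    major_of <- rep(0L, nref)
    for (i in seq_len(nref)) {
      js <- which(maj[i, ])
      if (length(js)) major_of[i] <- js[which.max(ot$inter[i, js])]
    }
    tab <- table(major_of[major_of > 0L])
    fused <- sum(tab[tab > 1L])
    split <- sum(pmax(rowSums(maj) - 1L, 0L))
  }
  fp <- if (nauto) sum(colSums(maj) == 0L) else 0L
  fn <- if (nref) sum(rowSums(maj) == 0L) else 0L
  c(falsely_fused = as.integer(fused), falsely_split = as.integer(split),
    false_positive = as.integer(fp), false_negative = as.integer(fn))
}

#' Full evaluation report between two segmentations
#'
#' Runs the one-to-one matching, aggregates the coefficients over the cell
#' count, optionally applies the inter-observer normalization, and counts the
#' fused/split/false-positive/false-negative events.
#'
#' @param L_a Automated (or first) label volume.
#' @param L_b Reference (or second) label volume.
#' @param interobs Optional named vector `c(C1 = ..., C2 = ..., C3 = ...)` of
#'   inter-observer coefficients for the normalization.
#' @return List (class `memseg_eval`): `pairs`, `C` (aggregates), `Cn`
#'   (normalized, when `interobs` given), `counts`, `unmatched_a`,
#'   `unmatched_b`.
#' @export
evaluate_segmentation <- function(L_a, L_b, interobs = NULL) {
  m <- match_regions(L_a, L_b)
  C <- aggregate_coefficients(m$pairs, m$n_a, m$n_b)
  Cn <- NULL
  if (!is.null(interobs)) {
    Cn <- c(C1n = normalize_interobserver(C[["C1"]], interobs[["C1"]]),
            C2n = normalize_interobserver(C[["C2"]], interobs[["C2"]]),
            C3n = normalize_interobserver(C[["C3"]], interobs[["C3"]]))
  }
  counts <- count_errors(L_a, L_b)
  structure(list(pairs = m$pairs, C = C, Cn = Cn, counts = counts,
                 unmatched_a = m$unmatched_a, unmatched_b = m$unmatched_b),
            class = "memseg_eval")
}

#' @export
print.memseg_eval <- function(x, ...) {
  cat(sprintf("segmentation agreement: %d matched pair(s)\n", nrow(x$pairs)))
  cat(sprintf("  C1 = %.4f  C2 = %.4f  C3 = %.4f\n", x$C[1], x$C[2], x$C[3]))
  if (!is.null(x$Cn))
    cat(sprintf("  normalized: C1n = %.4f  C2n = %.4f  C3n = %.4f\n",
                x$Cn[1], x$Cn[2], x$Cn[3]))
  cat(sprintf("  fused %d, split %d, FP %d, FN %d\n",
              x$counts[1], x$counts[2], x$counts[3], x$counts[4]))
  invisible(x)
}
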