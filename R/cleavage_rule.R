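# Ordering, staircase-boundary fitting and scoring of cleavage-call
# matrices. The "cleavage rule" states that a variant cleaves a target iff
# the target's activating contribution exceeds the variant's inhibitory
# level, which makes the variant x target call matrix separable by a
# monotone staircase after sorting variants by how many targets they cleave
# and targets by how many variants cleave them.

# Misclassification cost of one variant row under the best prefix cutoff:
# predicted cleaved for the first b targets; cost(b) = zeros in prefix +
# ones in suffix; NA cells are excluded. Returns min cost.
row_cost <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(0L)
  O <- cumsum(x)
  pre0 <- c(0, seq_len(n) - O)
  suf1 <- sum(x) - c(0, O)
  min(pre0 + suf1)
}

# Best prefix cutoff b for one row, smaller b on ties. NA cells are skipped
# when computing cost but b is expressed in full (defined-cell) positions of
# the ordered row without NAs.
row_best_cutoff <- function(x) {
  n <- length(x)
  ok <- !is.na(x)
  xx <- x[ok]
  m <- length(xx)
  if (m == 0) return(list(b = 0L, cost = 0L))
  O <- cumsum(xx)
  cost <- c(0, seq_len(m) - O) + (sum(xx) - c(0, O))
  b_def <- which.min(cost) - 1L            # ties: which.min takes smallest b
  # convert cutoff over defined cells back to a position in the full row:
  # predicted cleaved = first b_def defined cells (NA cells carry no call)
  list(b = b_def, cost = cost[b_def + 1L], defined = which(ok))
}

map_total_cost <- function(calls, ord) {
  sum(apply(calls[, ord, drop = FALSE], 1, row_cost))
}

all_perms <- function(n) {
  if (n == 0) return(matrix(integer(0), 1, 0))
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_perms(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    q <- p
    q[q >= i] <- q[q >= i] + 1L
    out[[i]] <- cbind(rep.int(i, nrow(q)), q)
  }
  do.call(rbind, out)
}

#' Order variants by fidelity rank
#'
#' Variants are sorted by how many targets they cleave (descending: the
#' least selective first). Count ties are broken by descending mean
#' normalized on-target activity; residual ties lexicographically by
#' variant id, so the ordering is fully deterministic.
#'
#' @param calls a `cleavage_calls` object.
#' @param activities optional `norm_activity` with matching axes; defaults
#'   to the values stored in `calls`.
#' @return character vector: permutation of the variant ids.
#' @export
order_variants <- function(calls, activities = NULL) {
  stopifnot(inherits(calls, "cleavage_calls"))
  vals <- if (is.null(activities)) calls$values else activities$values
  if (!identical(dimnames(vals), dimnames(calls$calls))) {
    stopf("activity and call matrices have mismatching axes")
  }
  counts <- rowSums(calls$calls, na.rm = TRUE)
  means <- rowMeans(vals, na.rm = TRUE)
  ids <- rownames(calls$calls)
  ids[order(-counts, -means, ids)]
}

#' Order targets by cleavability rank
#'
#' Targets are ordered by the number of variants that cleave them
#' (descending), taking outlier minimization into consideration: among
#' orders, the one minimizing the total number of staircase outliers
#' (under per-variant best cutoffs, see [fit_boundary()]) is preferred,
#' with count-descending order used as the starting point and kept
#' whenever it costs nothing.
#'
#' Small instances (up to `max_exhaustive_targets` targets) are solved by
#' exhaustive enumeration over all target permutations, scanning from the
#' count-descending lexicographic order so that it wins all ties; the
#' result is then provably the global outlier minimum (matching
#' [brute_force_best_order()]). Larger instances use the count-descending
#' primary key with exhaustive search inside count-tie blocks (joint over
#' blocks when feasible, deterministic adjacent-swap hill climbing with
#' lexicographic restart otherwise), followed by an optional deterministic
#' cross-block refinement pass that accepts a move only when it strictly
#' reduces the outlier count. Everything is bit-reproducible.
#'
#' @param calls a `cleavage_calls` object.
#' @param variant_order optional variant permutation (the outlier objective
#'   does not depend on it, but it fixes the row order of downstream maps).
#' @param max_block_exhaustive largest tie block searched exhaustively.
#' @param max_joint largest joint enumeration (product of block
#'   permutation counts) attempted before falling back to blockwise search.
#' @param max_exhaustive_targets instance size up to which all target
#'   permutations are enumerated.
#' @param refine run the cross-block refinement pass on large instances.
#' @return character vector: permutation of the target ids.
#' @export
order_targets <- function(calls, variant_order = NULL,
                          max_block_exhaustive = 8, max_joint = 50000,
                          max_exhaustive_targets = 7, refine = TRUE) {
  stopifnot(inherits(calls, "cleavage_calls"))
  M <- calls$calls
  if (!is.null(variant_order)) M <- M[variant_order, , drop = FALSE]
  cnt <- colSums(M, na.rm = TRUE)
  ids <- colnames(M)
  ord <- order(-cnt, ids)
  storage <- M * 1L  # logical -> integer, NA preserved

  if (ncol(M) <= max_exhaustive_targets) {
    # global enumeration seeded with the count-descending order: base
    # permutation first, so it wins whenever it attains the minimum
    base <- storage[, ord, drop = FALSE]
    P <- all_perms(ncol(M))
    costs <- apply(P, 1, function(o) map_total_cost(base, o))
    return(ids[ord][P[which.min(costs), ]])
  }

  blocks <- split(seq_along(ord),
                  match(cnt[ord], sort(unique(cnt), decreasing = TRUE)))
  blocks <- blocks[vapply(blocks, length, 1L) > 1]
  if (length(blocks)) {
    sizes <- vapply(blocks, length, 1L)
    joint_size <- prod(factorial(pmin(sizes, 20)))
    if (all(sizes <= max_block_exhaustive) && joint_size <= max_joint) {
      ord <- joint_block_search(storage, ord, blocks)
    } else {
      ord <- blockwise_search(storage, ord, blocks, max_block_exhaustive)
    }
  }
  if (refine) ord <- adjacent_refine(storage, ord)
  ids[ord]
}

# Deterministic cross-block polish: scan adjacent pairs left to right,
# swap on strict improvement, restart; converges to a local optimum that
# deviates from count order only where it strictly reduces outliers.
adjacent_refine <- function(M, ord) {
  repeat {
    improved <- FALSE
    cur <- map_total_cost(M, ord)
    for (i in seq_len(length(ord) - 1L)) {
      cand <- ord
      cand[c(i, i + 1L)] <- ord[c(i + 1L, i)]
      if (map_total_cost(M, cand) < cur) {
        ord <- cand
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  ord
}

# Exhaustive joint search over the product of tie-block permutations.
joint_block_search <- function(M, ord, blocks) {
  best_ord <- ord
  best_cost <- map_total_cost(M, ord)
  perms_per_block <- lapply(blocks, function(b) all_perms(length(b)))
  idx <- rep(1L, length(blocks))
  counts <- vapply(perms_per_block, nrow, 1L)
  repeat {
    cand <- ord
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      cand[b] <- ord[b][perms_per_block[[bi]][idx[bi], ]]
    }
    cost <- map_total_cost(M, cand)
    if (cost < best_cost) {
      best_cost <- cost
      best_ord <- cand
    }
    # odometer increment
    bi <- 1L
    while (bi <= length(blocks)) {
      idx[bi] <- idx[bi] + 1L
      if (idx[bi] <= counts[bi]) break
      idx[bi] <- 1L
      bi <- bi + 1L
    }
    if (bi > length(blocks)) break
  }
  best_ord
}

# Blockwise coordinate descent: each block in turn is optimized with the
# others held fixed (exhaustively if small, otherwise by deterministic
# adjacent-swap hill climbing); passes repeat until no block improves.
blockwise_search <- function(M, ord, blocks, max_block_exhaustive) {
  repeat {
    improved <- FALSE
    for (b in blocks) {
      cur_cost <- map_total_cost(M, ord)
      if (length(b) <= max_block_exhaustive) {
        P <- all_perms(length(b))
        costs <- apply(P, 1, function(p) {
          cand <- ord
          cand[b] <- ord[b][p]
          map_total_cost(M, cand)
        })
        k <- which.min(costs)   # first optimum: lexicographic tie-break
        if (costs[k] < cur_cost) {
          ord[b] <- ord[b][P[k, ]]
          improved <- TRUE
        }
      } else {
        repeat {
          swapped <- FALSE
          for (i in seq_len(length(b) - 1L)) {
            cand <- ord
            cand[b[c(i, i + 1L)]] <- ord[b[c(i + 1L, i)]]
            if (map_total_cost(M, cand) < map_total_cost(M, ord)) {
              ord <- cand
              swapped <- TRUE
              improved <- TRUE
              break  # lexicographic restart
            }
          }
          if (!swapped) break
        }
      }
    }
    if (!improved) break
  }
  ord
}

#' Fit the staircase boundary of an ordered call matrix
#'
#' For each variant (in the given order) the prefix cutoff `b_v` minimizing
#' that variant's misclassified cells is selected, with ties resolved
#' toward the smaller cutoff. Cells disagreeing with the resulting top-b_v
#' prediction are the outliers. An alternative `count_matched` mode fixes
#' `b_v` at the variant's observed cleaved count. Cross-variant
#' monotonicity of `b_v` is not enforced by default (printed maps satisfy
#' it; a warning is emitted when the fitted boundary violates it), but can
#' be requested with `monotone = TRUE`.
#'
#' @param calls a `cleavage_calls` object.
#' @param variant_order,target_order permutations of the axes; defaults are
#'   computed with [order_variants()] / [order_targets()].
#' @param mode `"min_misclass"` (default) or `"count_matched"`.
#' @param monotone force `b_v` non-increasing along the variant order.
#' @param warn_nonmonotone warn when the fitted boundary is not monotone.
#' @return an object of class `ranked_map`: `variant_order`,
#'   `target_order`, `boundary` (named integer vector), `outliers`
#'   (data.frame variant_id, target_id, observed, predicted), plus the
#'   reordered `calls` and `values`.
#' @export
fit_boundary <- function(calls, variant_order = NULL, target_order = NULL,
                         mode = c("min_misclass", "count_matched"),
                         monotone = FALSE, warn_nonmonotone = TRUE) {
  stopifnot(inherits(calls, "cleavage_calls"))
  mode <- match.arg(mode)
  if (is.null(variant_order)) variant_order <- order_variants(calls)
  if (is.null(target_order)) target_order <- order_targets(calls, variant_order)
  M <- calls$calls[variant_order, target_order, drop = FALSE]
  V <- calls$values[variant_order, target_order, drop = FALSE]
  nv <- nrow(M); nt <- ncol(M)

  boundary <- integer(nv)
  names(boundary) <- rownames(M)
  outliers <- list()
  prev_b <- nt
  for (i in seq_len(nv)) {
    x <- M[i, ]
    ok <- !is.na(x)
    xx <- as.integer(x[ok])
    m <- length(xx)
    if (mode == "count_matched") {
      b_def <- sum(xx)
    } else {
      O <- cumsum(xx)
      cost <- c(0, seq_len(m) - O) + (sum(xx) - c(0, O))
      if (monotone) {
        cap <- sum(ok[seq_len(prev_b)])  # defined cells within allowed prefix
        cost <- cost[seq_len(cap + 1L)]
      }
      b_def <- which.min(cost) - 1L
    }
    # boundary expressed as a column index in the full (ordered) matrix:
    # the position of the b_def-th defined cell (0 when b_def == 0)
    defined_pos <- which(ok)
    b_col <- if (b_def == 0L) 0L else defined_pos[b_def]
    boundary[i] <- b_col
    prev_b <- b_col
    pred <- rep(NA, nt)
    pred[ok] <- seq_along(x)[ok] %in% defined_pos[seq_len(b_def)]
    bad <- which(ok & (x != pred))
    if (length(bad)) {
      outliers[[length(outliers) + 1L]] <- data.frame(
        variant_id = rownames(M)[i],
        target_id = colnames(M)[bad],
        observed = ifelse(x[bad], "cleaved", "not_cleaved"),
        predicted = ifelse(pred[bad], "cleaved", "not_cleaved"),
        stringsAsFactors = FALSE)
    }
  }
  outliers <- if (length(outliers)) {
    do.call(rbind, outliers)
  } else {
    data.frame(variant_id = character(0), target_id = character(0),
               observed = character(0), predicted = character(0))
  }
  if (warn_nonmonotone && !monotone && is.unsorted(rev(boundary))) {
    warning("fitted staircase boundary is not monotone along the variant order",
            call. = FALSE)
  }
  structure(
    list(variant_order = variant_order,
         target_order = target_order,
         boundary = boundary,
         outliers = outliers,
         calls = M,
         values = V,
         theta = calls$theta,
         mode = mode),
    class = "ranked_map")
}

#' @export
print.ranked_map <- function(x, ...) {
  cat(sprintf("Ranked cleavage map: %d variants x %d targets, %d outlier(s), mode = %s\n",
              nrow(x$calls), ncol(x$calls), nrow(x$outliers), x$mode))
  invisible(x)
}

#' Build a ranked cleavage map in one call
#'
#' Convenience wrapper: orders variants and targets, then fits the
#' staircase boundary.
#'
#' @inheritParams fit_boundary
#' @param activities optional `norm_activity` used for variant tie-breaks.
#' @param ... passed to [fit_boundary()].
#' @return a `ranked_map` object.
#' @export
rank_cleavage_map <- function(calls, activities = NULL, ...) {
  vo <- order_variants(calls, activities)
  to <- order_targets(calls, vo)
  fit_boundary(calls, variant_order = vo, target_order = to, ...)
}

#' Score a staircase fit with the G-mean
#'
#' Pools the confusion matrix over all defined cells of the map, treating
#' the observed call as truth and the staircase prediction as classifier
#' (positive = cleaved). Sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), and the G-mean is the square root of their product. With no
#' positives or no negatives present the G-mean is undefined (`NA`) and
#' flagged.
#'
#' @param map a `ranked_map`.
#' @return an object of class `rule_fit` with `TP`, `FP`, `TN`, `FN`,
#'   `sensitivity`, `specificity`, `gmean`, `n_outliers` and `flag`.
#' @export
score_rule_fit <- function(map) {
  stopifnot(inherits(map, "ranked_map"))
  M <- map$calls
  nt <- ncol(M)
  pred <- matrix(FALSE, nrow(M), nt, dimnames = dimnames(M))
  for (i in seq_len(nrow(M))) {
    if (map$boundary[i] > 0) pred[i, seq_len(map$boundary[i])] <- TRUE
  }
  # boundary indexes full columns; NA cells inside the prefix carry no call
  ok <- !is.na(M)
  obs <- M[ok]; prd <- pred[ok]
  TP <- sum(obs & prd); FN <- sum(obs & !prd)
  TN <- sum(!obs & !prd); FP <- sum(!obs & prd)
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  flag <- if (is.na(sens) || is.na(spec)) "single_class" else NA_character_
  gmean <- if (is.na(flag)) sqrt(sens * spec) else NA_real_
  structure(
    list(TP = TP, FP = FP, TN = TN, FN = FN,
         sensitivity = sens, specificity = spec,
         gmean = gmean, n_outliers = FP + FN, flag = flag),
    class = "rule_fit")
}

#' @export
print.rule_fit <- function(x, ...) {
  cat(sprintf("Rule fit: G-mean %s (sens %.3f, spec %.3f), %d outlier(s)\n",
              ifelse(is.na(x$gmean), "undefined", sprintf("%.3f", x$gmean)),
              x$sensitivity, x$specificity, x$n_outliers))
  invisible(x)
}

#' Per-variant ROC against the cleavability ordering
#'
#' Scores each target by its cleavability rank (higher rank, i.e. earlier
#' in the ordering, predicts cleaved) and sweeps the cutoff over ranks to
#' trace the ROC of one variant's observed calls. The AUC is computed with
#' the tie-aware rank (Mann-Whitney) statistic: the probability that a
#' cleaved target outranks a non-cleaved one, counting rank ties as 1/2.
#' For an all-cleaved or all-non-cleaved column the AUC is undefined and
#' flagged.
#'
#' @param target_order character vector, most cleavable target first.
#' @param calls_for_variant named logical vector of the variant's calls;
#'   must be defined (non-NA) for every ordered target.
#' @param variant_id optional label carried in the result.
#' @param tie_groups optional vector (same length/order as `target_order`)
#'   of group labels; targets sharing a label receive the same mid-rank
#'   score, e.g. to mirror unresolved cleaved-by-count ties.
#' @return an object of class `variant_roc`: `points` (data.frame `fpr`,
#'   `tpr` from (0,0) to (1,1)), `auc` and `flag`.
#' @export
variant_roc <- function(target_order, calls_for_variant, variant_id = NA_character_,
                        tie_groups = NULL) {
  calls <- calls_for_variant[target_order]
  if (anyNA(calls)) {
    stopf("calls must be defined for every ordered target")
  }
  n <- length(calls)
  score <- rev(seq_len(n))          # earlier in order -> higher score
  if (!is.null(tie_groups)) {
    stopifnot(length(tie_groups) == n)
    score <- stats::ave(score, tie_groups, FUN = mean)
  }
  pos <- as.logical(calls)
  n1 <- sum(pos); n0 <- n - n1
  # sweep cutoffs over descending unique scores: predicted positive iff
  # score >= cutoff
  cuts <- sort(unique(score), decreasing = TRUE)
  tpr <- c(0, vapply(cuts, function(ct) sum(pos & score >= ct), 0) /
             max(n1, 1))
  fpr <- c(0, vapply(cuts, function(ct) sum(!pos & score >= ct), 0) /
             max(n0, 1))
  points <- data.frame(fpr = fpr, tpr = tpr)
  if (n1 == 0 || n0 == 0) {
    auc <- NA_real_
    flag <- "single_class"
  } else {
    r <- rank(score)                 # midranks for ties
    auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    flag <- NA_character_
  }
  structure(list(variant_id = variant_id, points = points, auc = auc,
                 flag = flag),
            class = "variant_roc")
}

#' @export
print.variant_roc <- function(x, ...) {
  cat(sprintf("ROC for %s: AUC %s\n", x$variant_id,
              ifelse(is.na(x$auc), "undefined", sprintf("%.3f", x$auc))))
  invisible(x)
}

# Trapezoidal area under an ROC point set; used as an internal cross-check
# of the rank-statistic AUC.
trapezoid_auc <- function(points) {
  p <- points[order(points$fpr, points$tpr), ]
  sum(diff(p$fpr) * (utils::head(p$tpr, -1) + utils::tail(p$tpr, -1)) / 2)
}

#' ROC/AUC for every variant of a ranked map
#'
#' @param map a `ranked_map`.
#' @return named list of `variant_roc` objects (variants with NA cells in
#'   their row are skipped).
#' @export
variant_roc_all <- function(map) {
  stopifnot(inherits(map, "ranked_map"))
  out <- list()
  for (v in rownames(map$calls)) {
    row <- map$calls[v, ]
    if (anyNA(row)) next
    out[[v]] <- variant_roc(colnames(map$calls), row, variant_id = v)
  }
  out
}

#' Brute-force optimal target order (test oracle)
#'
#' Enumerates every target permutation and returns the global minimum
#' outlier count under per-variant best cutoffs. Intended as an
#' independent oracle for [order_targets()] on tiny instances.
#'
#' @param calls a `cleavage_calls` object.
#' @param max_cells refuse instances with more matrix cells than this.
#' @return list with `order` (character, first optimum in lexicographic
#'   enumeration order) and `min_outliers`.
#' @export
brute_force_best_order <- function(calls, max_cells = 24) {
  stopifnot(inherits(calls, "cleavage_calls"))
  M <- calls$calls * 1L
  if (length(M) > max_cells) {
    stopf("instance too large for brute force (%d cells > %d)",
          length(M), max_cells)
  }
  ids <- colnames(M)
  P <- all_perms(ncol(M))
  costs <- apply(P, 1, function(o) map_total_cost(M, o))
  k <- which.min(costs)
  list(order = ids[P[k, ]], min_outliers = as.integer(costs[k]))
}
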