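#' Read a long-format activity table
#'
#' Reads a TSV/CSV of per-replicate cleavage activities in the long dialect
#' used throughout the package: one row per replicate measurement with
#' columns `experiment_id`, `variant_id`, `target_id`, `value`, `replicate`,
#' `modality`, `day` (optional) and `is_background`. `value` is a percentage
#' (0-100): percent EGFP-negative cells for the disruption assay or percent
#' indel reads for NGS. Background rows are dead-Cas9 or non-targeting
#' controls.
#'
#' @param path path to a TSV (default) or CSV file; the delimiter is sniffed
#'   from the header line.
#' @return a `data.frame` with validated columns.
#' @export
read_activity_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_activity_table(df)
}

#' Validate a raw activity table
#'
#' @param df a data.frame in the long activity dialect (see
#'   [read_activity_table()]).
#' @return the validated data.frame (invisible coercions applied).
#' @export
as_activity_table <- function(df) {
  assert_cols(df, c("experiment_id", "variant_id", "target_id", "value",
                    "replicate", "is_background"), "activity table")
  df$value <- as.numeric(df$value)
  if (anyNA(df$value)) stopf("activity table contains non-numeric values")
  if (any(df$value < 0 | df$value > 100)) {
    stopf("replicate values must lie within [0, 100] (percentages)")
  }
  df$is_background <- as.logical(df$is_background)
  if (!"modality" %in% names(df)) df$modality <- "disruption"
  df
}

#' Normalize raw activities to wild type
#'
#' For each (experiment, target) block the mean background activity (from
#' dead-Cas9 / non-targeting control rows) is subtracted from every
#' treatment mean, including wild type itself; each variant's
#' background-subtracted value is then divided by the background-subtracted
#' wild-type value. Negative values are clipped to zero and everything is
#' quantized to two decimals, which is the resolution at which the cleavage
#' threshold is subsequently applied.
#'
#' Cells where the wild type did not exceed background are undefined: they
#' propagate as `NA` (never silently zero) and are listed in the
#' `undefined` attribute.
#'
#' @param raw long-format activity table (see [read_activity_table()]).
#' @param wt_label variant label of the wild-type reference (default "WT").
#' @param per_replicate if `TRUE`, normalize each replicate separately and
#'   average the normalized values; the default averages replicates first,
#'   matching how triplicate means are displayed on the heatmaps.
#' @return an object of class `norm_activity`: list with `values` (variant x
#'   target matrix, two-decimal), `variant_ids`, `target_ids`, `theta`
#'   (default cleavage threshold 0.20) and `provenance`.
#' @export
normalize_to_wt <- function(raw, wt_label = "WT", per_replicate = FALSE) {
  raw <- as_activity_table(raw)
  treat <- raw[!raw$is_background, , drop = FALSE]
  bg <- raw[raw$is_background, , drop = FALSE]
  if (!nrow(treat)) stopf("no treatment rows in activity table")

  variants <- unique(treat$variant_id)
  targets <- unique(treat$target_id)
  if (!wt_label %in% variants) {
    stopf("wild-type label '%s' not present in activity table", wt_label)
  }

  vals <- matrix(NA_real_, length(variants), length(targets),
                 dimnames = list(variants, targets))
  undefined <- character(0)

  for (tg in targets) {
    tt <- treat[treat$target_id == tg, , drop = FALSE]
    exps <- unique(tt$experiment_id)
    per_exp <- matrix(NA_real_, length(variants), length(exps),
                      dimnames = list(variants, exps))
    for (ex in exps) {
      te <- tt[tt$experiment_id == ex, , drop = FALSE]
      be <- bg[bg$experiment_id == ex & bg$target_id == tg, , drop = FALSE]
      if (!nrow(be)) {
        stopf("no background entry for experiment '%s', target '%s'", ex, tg)
      }
      if (!wt_label %in% te$variant_id) {
        stopf("no wild-type ('%s') entry for target '%s' in experiment '%s'",
              wt_label, tg, ex)
      }
      bg_mean <- mean(be$value)
      wt_vals <- te$value[te$variant_id == wt_label]
      wt_adj <- mean(wt_vals) - bg_mean
      if (wt_adj <= 0) {
        undefined <- c(undefined, tg)
        next
      }
      for (v in unique(te$variant_id)) {
        rv <- te$value[te$variant_id == v]
        if (per_replicate) {
          norm <- mean(pmax((rv - bg_mean), 0) / wt_adj)
        } else {
          norm <- max(mean(rv) - bg_mean, 0) / wt_adj
        }
        per_exp[v, ex] <- norm
      }
    }
    vals[, tg] <- rowMeans(per_exp, na.rm = TRUE)
  }
  vals[is.nan(vals)] <- NA_real_
  vals <- round2(pmax(vals, 0))

  structure(
    list(values = vals,
         variant_ids = variants,
         target_ids = targets,
         theta = 0.20,
         provenance = unique(raw$experiment_id)),
    undefined = unique(undefined),
    class = "norm_activity")
}

#' Construct a normalized activity matrix directly
#'
#' Wraps an already WT-normalized variant x target matrix (e.g. read back
#' from a heatmap TSV) in the container used by the downstream operations.
#' Values are re-quantized to two decimals so the invariant "each value
#' equals its own rounding" always holds.
#'
#' @param values numeric matrix, variants as rows, targets as columns,
#'   dimnames required.
#' @param theta cleavage-call threshold stored with the matrix.
#' @param provenance free-form source identifiers.
#' @return a `norm_activity` object.
#' @export
norm_activity <- function(values, theta = 0.20, provenance = character(0)) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0, na.rm = TRUE)) stopf("normalized activities must be >= 0")
  structure(
    list(values = round2(values),
         variant_ids = rownames(values),
         target_ids = colnames(values),
         theta = theta,
         provenance = provenance),
    class = "norm_activity")
}

#' @export
print.norm_activity <- function(x, ...) {
  cat(sprintf("Normalized activity matrix: %d variants x %d targets (theta = %.2f)\n",
              length(x$variant_ids), length(x$target_ids), x$theta))
  undef <- attr(x, "undefined")
  if (length(undef)) {
    cat("Undefined (WT <= background) targets:", paste(undef, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Call cleaved / not-cleaved cells
#'
#' A cell is called cleaved when its two-decimal normalized activity is at
#' least `theta` (default 0.20); values below the threshold are regarded as
#' no cleavage. Because the matrix is quantized first, a raw 0.195 rounds to
#' 0.20 and calls as cleaved.
#'
#' @param matrix a `norm_activity` object.
#' @param theta threshold in (0, 2].
#' @return an object of class `cleavage_calls`: logical variant x target
#'   matrix `calls` (TRUE = cleaved, `NA` preserved) plus the `theta` used
#'   and the underlying `values`.
#' @export
call_cleavage <- function(matrix, theta = 0.20) {
  stopifnot(inherits(matrix, "norm_activity"))
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0 || theta > 2) {
    stopf("theta must be a single value in (0, 2]")
  }
  structure(
    list(calls = matrix$values >= theta,
         theta = theta,
         values = matrix$values),
    class = "cleavage_calls")
}

#' @export
print.cleavage_calls <- function(x, ...) {
  cat(sprintf("Cleavage calls: %d x %d, theta = %.2f, %d cleaved of %d defined cells\n",
              nrow(x$calls), ncol(x$calls), x$theta,
              sum(x$calls, na.rm = TRUE), sum(!is.na(x$calls))))
  invisible(x)
}

#' Aggregate a mismatch screen against its on-target activities
#'
#' Combines per-position (or per-off-target-set) activities with the
#' matching on-target activity of the same (target, variant) pair. Each
#' group's mean off-target activity is expressed relative to the on-target
#' value. Entries whose on-target activity fails the `on_min` gate are
#' masked as not determined (`NA`) and never contribute to any downstream
#' mean; a second gate flags the entries that qualify for specificity
#' summaries (on-target above `specificity_min`).
#'
#' @param norm_on a `norm_activity` object of on-target activities.
#' @param off data.frame with columns `target_id`, `variant_id`, `position`
#'   (mismatch position or off-target set label) and `value` (activity on
#'   the same scale as the on-target matrix; repeated rows per group are
#'   averaged, e.g. the three single-mismatch guides probed as a mixture, or
#'   the 60 single-mismatch sites of a guide).
#' @param gates list with `on_min` (default 0.20) and `specificity_min`
#'   (default 0.70).
#' @return data.frame (`mismatch_screen` class) with `on_target_norm`,
#'   `off_target_norm` (NA where masked), `determined` and
#'   `pass_specificity`.
#' @export
aggregate_mismatch_screen <- function(norm_on, off,
                                      gates = list(on_min = 0.20,
                                                   specificity_min = 0.70)) {
  stopifnot(inherits(norm_on, "norm_activity"))
  assert_cols(off, c("target_id", "variant_id", "position", "value"),
              "off-target table")
  if (any(off$value < 0)) stopf("off-target activities must be >= 0")
  key <- interaction(off$target_id, off$variant_id, off$position, drop = TRUE)
  groups <- split(off, key)
  res <- do.call(rbind, lapply(groups, function(g) {
    tg <- g$target_id[1]; v <- g$variant_id[1]
    if (!(v %in% norm_on$variant_ids) || !(tg %in% norm_on$target_ids)) {
      stopf("off-target entry (%s, %s) has no matching on-target value", tg, v)
    }
    on_val <- norm_on$values[v, tg]
    data.frame(target_id = tg, variant_id = v, position = g$position[1],
               on_target_norm = on_val,
               off_mean = mean(g$value),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  determined <- !is.na(res$on_target_norm) & res$on_target_norm >= gates$on_min
  res$off_target_norm <- ifelse(determined,
                                round2(res$off_mean / res$on_target_norm),
                                NA_real_)
  res$determined <- determined
  res$pass_specificity <- determined &
    res$on_target_norm >= gates$specificity_min
  res$off_mean <- NULL
  class(res) <- c("mismatch_screen", "data.frame")
  res
}

#' Filter a high-throughput (library-style) target table
#'
#' Applies, in order, the three target filters used for reanalysis of
#' large published screens: (1) keep only targets interrogated with
#' perfectly matching spacers (protospacer class filter); (2) drop targets
#' that lack data for any of the nucleases; (3) drop targets the wild type
#' cleaved below a minimum indel percentage (default 15%). Input order is
#' preserved and per-filter removal counts are reported.
#'
#' @param table data.frame with one row per target: a protospacer class
#'   column, a wild-type indel column and one indel column per variant.
#' @param variant_cols names of the per-variant indel columns (excluding
#'   wild type).
#' @param wt_col wild-type indel column name.
#' @param class_col protospacer class column name.
#' @param perfect_class value of `class_col` marking perfectly matching
#'   spacers.
#' @param min_wt_indel minimum wild-type indel percentage (targets strictly
#'   below are removed).
#' @return list with `targets` (filtered data.frame, original order) and
#'   `removed` (named counts per filter).
#' @export
filter_kim_targets <- function(table, variant_cols,
                               wt_col = "WT",
                               class_col = "protospacer_class",
                               perfect_class = "tRNA-N20",
                               min_wt_indel = 15) {
  assert_cols(table, c(class_col, wt_col, variant_cols), "target table")
  n0 <- nrow(table)
  keep1 <- table[[class_col]] == perfect_class
  t1 <- table[keep1, , drop = FALSE]
  dat <- as.matrix(t1[, c(wt_col, variant_cols), drop = FALSE])
  keep2 <- !apply(dat, 1, anyNA)
  t2 <- t1[keep2, , drop = FALSE]
  keep3 <- t2[[wt_col]] >= min_wt_indel
  t3 <- t2[keep3, , drop = FALSE]
  list(targets = t3,
       removed = c(protospacer_class = n0 - nrow(t1),
                   missing_data = nrow(t1) - nrow(t2),
                   low_wt_indel = nrow(t2) - nrow(t3)))
}

#' Write a normalized activity matrix as TSV
#'
#' Variants as rows, targets as columns, two-decimal fixed point. The
#' written file is byte-stable for identical inputs.
#'
#' @param x a `norm_activity` object.
#' @param path output path.
#' @export
write_activity_matrix <- function(x, path) {
  stopifnot(inherits(x, "norm_activity"))
  m <- x$values
  lines <- c(paste(c("variant_id", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i],
                       ifelse(is.na(m[i, ]), "NA", sprintf("%.2f", m[i, ]))),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a matrix TSV written by [write_activity_matrix()]
#'
#' @param path input path.
#' @param theta threshold to store with the matrix.
#' @return a `norm_activity` object.
#' @export
read_activity_matrix <- function(path, theta = 0.20) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  norm_activity(m, theta = theta, provenance = path)
}
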