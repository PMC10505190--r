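# Shared fixtures, all generated in code.

# Wrap a 0/1 (or logical) matrix as a cleavage_calls object; values are the
# calls themselves (1.00 / 0.00), so threshold 0.20 reproduces the calls.
make_calls <- function(M, theta = 0.20) {
  storage.mode(M) <- "double"
  if (is.null(rownames(M))) rownames(M) <- sprintf("V%02d", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- sprintf("T%02d", seq_len(ncol(M)))
  call_cleavage(norm_activity(M), theta = theta)
}

# Perfect staircase: variant i cleaves the first b[i] targets.
staircase_matrix <- function(b, nt) {
  M <- t(vapply(b, function(k) as.numeric(seq_len(nt) <= k), numeric(nt)))
  rownames(M) <- sprintf("V%02d", seq_along(b))
  colnames(M) <- sprintf("T%02d", seq_len(nt))
  M
}

# Long-format raw activity table for one experiment/target set.
# `raw` is a variants x targets matrix of raw percentages; background and
# WT rows are added per target.
raw_table_from_matrix <- function(raw, background = 2, replicates = 1) {
  stopifnot(!is.null(rownames(raw)), !is.null(colnames(raw)))
  rows <- list()
  for (tg in colnames(raw)) {
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        experiment_id = "e1", variant_id = "dead", target_id = tg,
        value = background, replicate = r, modality = "disruption",
        is_background = TRUE)
      for (v in rownames(raw)) {
        rows[[length(rows) + 1L]] <- data.frame(
          experiment_id = "e1", variant_id = v, target_id = tg,
          value = raw[v, tg], replicate = r, modality = "disruption",
          is_background = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Standard test amplicon: 140 bp with a protospacer + NGG PAM embedded and
# two programmed substitutions for HDR scoring (one on each side of the
# cut, outside the +/-2 indel window).
test_amplicon <- function(desired_edit = TRUE) {
  set.seed(404)
  flank5 <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                  collapse = "")
  flank3 <- paste(sample(c("A", "C", "G", "T"), 87, replace = TRUE),
                  collapse = "")
  proto <- "GATTACAGATTACAGATTAC"
  ref <- paste0(flank5, proto, "AGG", flank3)
  edit <- NULL
  if (desired_edit) {
    # positions 40 and 55 (inside/near the protospacer, outside the window)
    b40 <- substr(ref, 40, 40); b55 <- substr(ref, 55, 55)
    edit <- c(`40` = setdiff(c("A", "C", "G", "T"), b40)[1],
              `55` = setdiff(c("A", "C", "G", "T"), b55)[1])
  }
  amplicon_spec(ref, proto, desired_edit = edit, reference_name = "amp1")
}

# One aligned read data.frame row.
read_row <- function(qname, pos, cigar, seq) {
  data.frame(qname = qname, flag = 0L, pos = pos, cigar = cigar, seq = seq,
             stringsAsFactors = FALSE)
}
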