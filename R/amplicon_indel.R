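# Amplicon editing-outcome quantification from aligned reads: eligibility
# by identity over the first 20 reference bases, indel calling in a window
# around the nuclease cut site, GUIDE-seq dsODN tag counting, and desired-
# edit (HDR) scoring. Coordinates are handled 0-based half-open internally
# with the cut site as an inter-base offset; gaps are left-normalized
# against the reference before windowing.

# Indel windowing: each gap operation is reduced to its placement span --
# from the left-normalized start to the right-normalized end, in inter-base
# coordinates -- and a read is indel-positive when any gap's span overlaps
# the +/- window around the cut. Anchoring on the span (rather than on the
# leftmost coordinate alone) makes counting exactly strand-symmetric.

# 15 bp center fragments of the GUIDE-seq dsODN (both strands)
DSODN_FRAGMENTS <- c("GTTGTCATATGTTAA", "TTAACATATGACAAC")
# 34 bp GUIDE-seq dsODN (sense), used by the read simulator
DSODN_SENSE <- "GTTTAATTGAGTTGTCATATGTTAATAACGGTAT"

#' Define an amplicon and its cut site
#'
#' Locates the protospacer in the reference amplicon (either strand, exact,
#' unique) and places the blunt cut site 3 nt upstream of the PAM, i.e. at
#' the inter-base coordinate between protospacer positions 17 and 18.
#'
#' @param reference reference amplicon sequence (character or
#'   [Biostrings::DNAString]).
#' @param protospacer 20-nt protospacer sequence as given 5'->3' on its
#'   strand.
#' @param desired_edit optional named character vector of programmed
#'   substitutions for HDR scoring: names are 1-based reference positions,
#'   values the edited bases (e.g. corrected base plus silent marker base).
#' @param reference_name sequence name used in SAM headers.
#' @return an object of class `amplicon_spec`: `reference`, `protospacer`,
#'   `strand`, `proto_start` (1-based), `cut_site` (0-based inter-base
#'   offset from the reference start), `tag_fragments`, `desired_edit`.
#' @export
amplicon_spec <- function(reference, protospacer, desired_edit = NULL,
                          reference_name = "amplicon") {
  ref <- toupper(as.character(reference))
  proto <- toupper(as.character(protospacer))
  if (nchar(proto) != 20) stopf("protospacer must be 20 nt")
  refseq <- Biostrings::DNAString(ref)
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(proto), refseq)
  rev <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(proto)), refseq)
  nhits <- length(fwd) + length(rev)
  if (nhits != 1) {
    stopf("protospacer must map into the reference exactly once (found %d hits)",
          nhits)
  }
  if (length(fwd)) {
    strand <- "+"
    s <- as.integer(BiocGenerics::start(fwd)[1])
    cut <- (s - 1L) + 17L        # between protospacer positions 17 and 18
  } else {
    strand <- "-"
    s <- as.integer(BiocGenerics::start(rev)[1])
    cut <- (s - 1L) + 3L         # mirrored: 3 nt from the left match end
  }
  if (cut <= 0 || cut >= nchar(ref)) stopf("cut site falls outside the reference")
  if (!is.null(desired_edit)) {
    pos <- as.integer(names(desired_edit))
    if (anyNA(pos) || any(pos < 1 | pos > nchar(ref))) {
      stopf("desired_edit positions must be 1-based reference coordinates")
    }
    desired_edit <- stats::setNames(toupper(as.character(desired_edit)),
                                    names(desired_edit))
  }
  structure(
    list(reference = ref,
         reference_name = reference_name,
         protospacer = proto,
         strand = strand,
         proto_start = s,
         cut_site = cut,
         tag_fragments = DSODN_FRAGMENTS,
         desired_edit = desired_edit),
    class = "amplicon_spec")
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat(sprintf("Amplicon '%s': %d bp, protospacer at %d (%s), cut site at inter-base %d\n",
              x$reference_name, nchar(x$reference), x$proto_start, x$strand,
              x$cut_site))
  invisible(x)
}

# Walk one read's CIGAR against the reference. Returns matched reference
# positions (1-based, base identical), covered positions, and indels as a
# data.frame (op, at = left-normalized 0-based inter-base coordinate, len,
# seq).
walk_read <- function(pos, cigar, seq, ref) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  refc <- strsplit(ref, "")[[1]]
  readc <- strsplit(toupper(seq), "")[[1]]
  rpos <- pos                     # next reference base (1-based)
  qpos <- 1L                      # next query base
  matched <- integer(0)
  covered <- integer(0)
  indels <- list()
  for (o in seq_along(ops)) {
    op <- ops[o]; len <- lens[o]
    if (op %in% c("M", "=", "X")) {
      rr <- rpos:(rpos + len - 1L)
      qq <- qpos:(qpos + len - 1L)
      ok <- rr >= 1 & rr <= length(refc)
      covered <- c(covered, rr[ok])
      matched <- c(matched, rr[ok][refc[rr[ok]] == readc[qq[ok]]])
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "I") {
      ins <- paste(readc[qpos:(qpos + len - 1L)], collapse = "")
      raw_at <- rpos - 1L         # inter-base: ref bases consumed so far
      # left-normalize: rotate the insertion left over identical flanks
      at <- raw_at; lseq <- ins
      while (at >= 1 && refc[at] == substr(lseq, len, len)) {
        lseq <- paste0(substr(lseq, len, len), substr(lseq, 1, len - 1))
        at <- at - 1L
      }
      # right-normalize to get the full placement ambiguity span
      at_hi <- raw_at; rseq <- ins
      while (at_hi < length(refc) &&
             refc[at_hi + 1L] == substr(rseq, 1, 1)) {
        rseq <- paste0(substr(rseq, 2, len), substr(rseq, 1, 1))
        at_hi <- at_hi + 1L
      }
      indels[[length(indels) + 1L]] <-
        data.frame(op = "I", at = at, at_hi = at_hi, len = len, seq = lseq)
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      start <- rpos               # first deleted ref base
      while (start > 1 && refc[start - 1L] == refc[start + len - 1L]) {
        start <- start - 1L
      }
      end <- rpos + len - 1L      # right-normalized last deleted base
      while (end < length(refc) && refc[end + 1L] == refc[end - len + 1L]) {
        end <- end + 1L
      }
      indels[[length(indels) + 1L]] <-
        data.frame(op = "D", at = start - 1L, at_hi = end, len = len,
                   seq = paste(refc[start:(start + len - 1L)], collapse = ""))
      rpos <- rpos + len
    } else if (op == "S") {
      qpos <- qpos + len
    }                             # H, P: consume nothing we track
  }
  list(matched = matched, covered = covered,
       indels = if (length(indels)) do.call(rbind, indels) else NULL,
       ref_end = rpos - 1L)
}

# Query base aligned to each requested reference position, NA when the
# position is not covered by an alignment (M/=/X) block.
read_base_at <- function(pos, cigar, seq, ref_positions) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  readc <- strsplit(toupper(seq), "")[[1]]
  out <- rep(NA_character_, length(ref_positions))
  rpos <- pos; qpos <- 1L
  for (o in seq_along(ops)) {
    op <- ops[o]; len <- lens[o]
    if (op %in% c("M", "=", "X")) {
      hit <- which(ref_positions >= rpos & ref_positions < rpos + len)
      if (length(hit)) {
        out[hit] <- readc[qpos + (ref_positions[hit] - rpos)]
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "I" || op == "S") {
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      rpos <- rpos + len
    }
  }
  out
}

validate_reads <- function(reads) {
  assert_cols(reads, c("qname", "pos", "cigar", "seq"), "read set")
  if (any(is.na(reads$pos) | reads$pos < 1)) {
    stopf("read set contains unaligned reads (missing position)")
  }
  reads
}

#' Filter reads eligible for indel counting
#'
#' A read is eligible when at least 75% (by default) of the first 20
#' reference bases are covered by its alignment and match the reference,
#' i.e. >= 15 of 20 positions; the boundary 15/20 = 75% is kept. Reads
#' failing the filter remain in the total count only.
#'
#' @param reads data.frame of aligned reads (`qname`, `pos`, `cigar`,
#'   `seq`).
#' @param spec an `amplicon_spec`.
#' @param min_match minimum fraction of the first 20 reference bases
#'   matched.
#' @return the eligible subset, with the input read count in attribute
#'   `total_reads`.
#' @export
filter_eligible <- function(reads, spec, min_match = 0.75) {
  stopifnot(inherits(spec, "amplicon_spec"))
  reads <- validate_reads(reads)
  need <- ceiling(min_match * 20)
  ok <- vapply(seq_len(nrow(reads)), function(i) {
    w <- walk_read(reads$pos[i], reads$cigar[i], reads$seq[i], spec$reference)
    sum(w$matched <= 20) >= need
  }, logical(1))
  out <- reads[ok, , drop = FALSE]
  attr(out, "total_reads") <- nrow(reads)
  out
}

#' Count indel reads around the cut site
#'
#' A read is indel-positive iff its alignment contains at least one
#' insertion or deletion whose left-normalized leftmost coordinate lies
#' within +/- `window` of the cut site. Each read is counted once. The
#' indel frequency divides by the total read count (not the eligible
#' count), matching the definition (number of reads with an indel) /
#' (number of total reads); an eligible-reads denominator is available for
#' sensitivity analysis.
#'
#' Substitutions never qualify as the counted event: the event is a gap
#' operation, and substitutions elsewhere in the read do not disqualify it.
#'
#' @param eligible eligible reads (see [filter_eligible()]); the
#'   `total_reads` attribute supplies the denominator, or pass
#'   `total_reads` explicitly.
#' @param spec an `amplicon_spec`.
#' @param window half-width in bp around the cut site (default 2).
#' @param total_reads denominator override.
#' @param denominator `"total"` (default) or `"eligible"`.
#' @return list with `total_reads`, `eligible_reads`, `indel_reads`,
#'   `indel_frequency` and `flag` (`"empty_input"` when no reads).
#' @export
count_indels <- function(eligible, spec, window = 2, total_reads = NULL,
                         denominator = c("total", "eligible")) {
  stopifnot(inherits(spec, "amplicon_spec"))
  denominator <- match.arg(denominator)
  if (nrow(eligible)) validate_reads(eligible)
  total <- total_reads %||% attr(eligible, "total_reads") %||% nrow(eligible)
  L <- nchar(spec$reference)
  lo <- spec$cut_site - window
  hi <- spec$cut_site + window
  if (lo < 0 || hi > L) stopf("indel window extends outside the reference")
  hits <- vapply(seq_len(nrow(eligible)), function(i) {
    w <- walk_read(eligible$pos[i], eligible$cigar[i], eligible$seq[i],
                   spec$reference)
    !is.null(w$indels) && any(w$indels$at <= hi & w$indels$at_hi >= lo)
  }, logical(1))
  n_ind <- sum(hits)
  denom <- if (denominator == "total") total else nrow(eligible)
  list(total_reads = total,
       eligible_reads = nrow(eligible),
       indel_reads = n_ind,
       indel_frequency = if (denom > 0) n_ind / denom else 0,
       flag = if (total == 0) "empty_input" else NA_character_)
}

#' Count dsODN tag-positive reads
#'
#' Reads whose sequence contains either 15-mer center fragment of the
#' GUIDE-seq dsODN (exact substring, case-insensitive) are tag-positive.
#'
#' @param reads data.frame of reads.
#' @param spec an `amplicon_spec`.
#' @return integer count of tag-positive reads.
#' @export
count_tag <- function(reads, spec) {
  stopifnot(inherits(spec, "amplicon_spec"))
  if (!nrow(reads)) return(0L)
  s <- toupper(reads$seq)
  sum(Reduce(`|`, lapply(spec$tag_fragments,
                         function(f) grepl(f, s, fixed = TRUE))))
}

#' Count desired-edit (HDR) reads
#'
#' A read is edit-positive when every programmed substitution (corrected
#' base plus silent marker base) is present at its reference position and
#' the read carries no indel within the cut-site window. The edit fraction
#' divides by the total read count.
#'
#' @param reads data.frame of reads (typically all aligned reads).
#' @param spec an `amplicon_spec` with `desired_edit` set.
#' @param window cut-site window used for the no-indel condition.
#' @return list with `edit_reads`, `edit_fraction` and `total_reads`.
#' @export
count_edit <- function(reads, spec, window = 2) {
  stopifnot(inherits(spec, "amplicon_spec"))
  if (is.null(spec$desired_edit)) stopf("spec has no desired_edit defined")
  if (nrow(reads)) validate_reads(reads)
  pos <- as.integer(names(spec$desired_edit))
  lo <- spec$cut_site - window; hi <- spec$cut_site + window
  hits <- vapply(seq_len(nrow(reads)), function(i) {
    bases <- read_base_at(reads$pos[i], reads$cigar[i], reads$seq[i], pos)
    if (anyNA(bases) || !all(bases == unname(spec$desired_edit))) return(FALSE)
    w <- walk_read(reads$pos[i], reads$cigar[i], reads$seq[i], spec$reference)
    is.null(w$indels) || !any(w$indels$at <= hi & w$indels$at_hi >= lo)
  }, logical(1))
  list(edit_reads = sum(hits),
       edit_fraction = if (nrow(reads) > 0) sum(hits) / nrow(reads) else 0,
       total_reads = nrow(reads))
}

#' Full per-amplicon editing summary
#'
#' Applies the eligibility filter, counts indel, tag and (when programmed)
#' desired-edit reads, and returns one summary record.
#'
#' @param reads data.frame of aligned reads.
#' @param spec an `amplicon_spec`.
#' @param window indel window half-width.
#' @param min_match eligibility threshold.
#' @param denominator indel-frequency denominator mode.
#' @return an object of class `indel_summary`.
#' @export
tally_amplicon <- function(reads, spec, window = 2, min_match = 0.75,
                           denominator = "total") {
  elig <- filter_eligible(reads, spec, min_match = min_match)
  ind <- count_indels(elig, spec, window = window,
                      denominator = denominator)
  tag <- count_tag(reads, spec)
  edit <- if (!is.null(spec$desired_edit)) count_edit(reads, spec, window)
  structure(
    list(total_reads = nrow(reads),
         eligible_reads = nrow(elig),
         indel_reads = ind$indel_reads,
         indel_frequency = ind$indel_frequency,
         tag_reads = tag,
         edit_reads = if (is.null(edit)) NA_integer_ else edit$edit_reads,
         edit_fraction = if (is.null(edit)) NA_real_ else edit$edit_fraction,
         flag = ind$flag),
    class = "indel_summary")
}

#' @export
print.indel_summary <- function(x, ...) {
  cat(sprintf("Amplicon tally: %d reads (%d eligible), indel %.4f, tag %d%s\n",
              x$total_reads, x$eligible_reads, x$indel_frequency, x$tag_reads,
              if (!is.na(x$edit_fraction))
                sprintf(", edit %.4f", x$edit_fraction) else ""))
  invisible(x)
}

#' Simulate aligned amplicon reads
#'
#' Generates reads with programmed CIGAR-level edit outcomes at the cut
#' site: `wt` (unedited), `indel` (1-3 bp deletion or 1-2 bp insertion at
#' the cut), `tagged` (34 bp dsODN insertion at the cut, containing the
#' 15-mer center fragment) and `edited` (programmed substitutions, no
#' indel). Class labels are drawn i.i.d. from `mix`; optional uniform
#' substitution noise can be added. Reproducible under `seed`.
#'
#' @param spec an `amplicon_spec`.
#' @param mix named proportions for `wt`, `indel`, `tagged`, `edited`;
#'   must sum to 1.
#' @param n number of reads.
#' @param seed integer seed.
#' @param sub_rate per-base substitution noise rate (applied outside the
#'   programmed edit positions).
#' @return data.frame of reads (`qname`, `flag`, `pos`, `cigar`, `seq`,
#'   `class`).
#' @export
simulate_reads <- function(spec, mix = c(wt = 1, indel = 0, tagged = 0,
                                         edited = 0),
                           n = 1000, seed = 1, sub_rate = 0) {
  stopifnot(inherits(spec, "amplicon_spec"))
  mix <- mix[c("wt", "indel", "tagged", "edited")]
  mix[is.na(mix)] <- 0
  if (abs(sum(mix) - 1) > 1e-9) stopf("mix proportions must sum to 1")
  if (mix["edited"] > 0 && is.null(spec$desired_edit)) {
    stopf("edited reads requested but spec has no desired_edit")
  }
  ref <- spec$reference
  L <- nchar(ref)
  cut <- spec$cut_site
  if (cut < 3 || cut > L - 3) stopf("cut site too close to the reference edge")

  set.seed(seed)
  classes <- sample(names(mix), n, replace = TRUE, prob = mix)
  alphabet <- c("A", "C", "G", "T")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- classes[i]
    if (cl == "wt") {
      cigar <- sprintf("%dM", L)
      seq <- ref
    } else if (cl == "indel") {
      if (stats::runif(1) < 0.6) {
        d <- sample(1:3, 1)
        cigar <- sprintf("%dM%dD%dM", cut, d, L - cut - d)
        seq <- paste0(substr(ref, 1, cut), substr(ref, cut + d + 1, L))
      } else {
        k <- sample(1:2, 1)
        ins <- paste(sample(alphabet, k, replace = TRUE), collapse = "")
        cigar <- sprintf("%dM%dI%dM", cut, k, L - cut)
        seq <- paste0(substr(ref, 1, cut), ins, substr(ref, cut + 1, L))
      }
    } else if (cl == "tagged") {
      cigar <- sprintf("%dM%dI%dM", cut, nchar(DSODN_SENSE), L - cut)
      seq <- paste0(substr(ref, 1, cut), DSODN_SENSE, substr(ref, cut + 1, L))
    } else {                        # edited
      s <- strsplit(ref, "")[[1]]
      s[as.integer(names(spec$desired_edit))] <- unname(spec$desired_edit)
      cigar <- sprintf("%dM", L)
      seq <- paste(s, collapse = "")
    }
    if (sub_rate > 0) {
      s <- strsplit(seq, "")[[1]]
      protect <- if (cl == "edited") {
        as.integer(names(spec$desired_edit))
      } else integer(0)
      flip <- which(stats::runif(length(s)) < sub_rate)
      flip <- setdiff(flip, protect)
      for (p in flip) s[p] <- sample(setdiff(alphabet, s[p]), 1)
      seq <- paste(s, collapse = "")
    }
    out[[i]] <- data.frame(qname = sprintf("read%06d", i), flag = 0L,
                           pos = 1L, cigar = cigar, seq = seq, class = cl,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write reads as SAM
#'
#' Minimal valid single-reference SAM for simulated or filtered reads.
#'
#' @param reads data.frame of reads.
#' @param spec an `amplicon_spec`.
#' @param path output path (.sam).
#' @export
write_sam <- function(reads, spec, path) {
  validate_reads(reads)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", spec$reference_name,
                      nchar(spec$reference)))
  body <- vapply(seq_len(nrow(reads)), function(i) {
    paste(reads$qname[i], reads$flag[i] %||% 0L, spec$reference_name,
          reads$pos[i], 60L, reads$cigar[i], "*", 0L, 0L, reads$seq[i], "*",
          sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read aligned amplicon reads from a SAM file
#'
#' Converts via [Rsamtools::asBam()] and imports `qname`, `flag`, `pos`,
#' `cigar` and `seq`. Unmapped reads or reads aligned to a different
#' reference raise an error.
#'
#' @param path SAM file path.
#' @param spec optional `amplicon_spec`; when given the reference name is
#'   checked.
#' @return data.frame of reads.
#' @export
read_amplicon_sam <- function(path, spec = NULL) {
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "cigar", "seq"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (length(b$qname) == 0) {
    return(data.frame(qname = character(0), flag = integer(0),
                      pos = integer(0), cigar = character(0),
                      seq = character(0)))
  }
  unmapped <- bitwAnd(b$flag, 4L) != 0L | is.na(b$pos)
  if (any(unmapped)) stopf("SAM contains unmapped reads")
  if (!is.null(spec) && any(as.character(b$rname) != spec$reference_name)) {
    stopf("reads aligned to a different reference than '%s'",
          spec$reference_name)
  }
  data.frame(qname = b$qname, flag = b$flag, pos = b$pos, cigar = b$cigar,
             seq = as.character(b$seq), stringsAsFactors = FALSE)
}

# Reverse-complement a spec and matching read set; used to verify strand
# invariance of all counters.
revcomp_spec <- function(spec) {
  L <- nchar(spec$reference)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(spec$reference)))
  edit <- spec$desired_edit
  if (!is.null(edit)) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    pos <- L - as.integer(names(edit)) + 1L
    edit <- stats::setNames(unname(comp[unname(edit)]), pos)
    edit <- edit[order(as.integer(names(edit)))]
  }
  out <- spec
  out$reference <- rc
  out$strand <- if (spec$strand == "+") "-" else "+"
  out$proto_start <- L - (spec$proto_start + 19) + 1L
  out$cut_site <- L - spec$cut_site
  out$desired_edit <- edit
  out
}

cigar_ref_span <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  sum(lens[ops %in% c("M", "=", "X", "D", "N")])
}

revcomp_reads <- function(reads, spec) {
  L <- nchar(spec$reference)
  out <- reads
  for (i in seq_len(nrow(reads))) {
    ops <- GenomicAlignments::explodeCigarOps(reads$cigar[i])[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(reads$cigar[i])[[1]]
    out$cigar[i] <- paste(rev(paste0(lens, ops)), collapse = "")
    span <- cigar_ref_span(reads$cigar[i])
    out$pos[i] <- L - (reads$pos[i] + span - 1L) + 1L
    out$seq[i] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(reads$seq[i])))
  }
  out
}
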