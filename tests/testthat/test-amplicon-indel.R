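test_that("amplicon_spec locates the protospacer and cut site, validates inputs", {
  spec <- test_amplicon()
  expect_identical(spec$strand, "+")
  expect_identical(spec$proto_start, 31L)
  expect_identical(spec$cut_site, 47L)            # 30 + 17 inter-base
  # the two tag fragments are reverse complements of each other
  expect_identical(
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(spec$tag_fragments[1]))),
    spec$tag_fragments[2])

  expect_error(amplicon_spec("ACGT", "GATTACAGATTACAGATTAC"), "exactly once")
  expect_error(amplicon_spec(paste0(spec$reference, spec$reference),
                             spec$protospacer), "exactly once")
})

test_that("reverse-strand protospacers get the mirrored cut site", {
  spec <- test_amplicon(desired_edit = FALSE)
  rc_ref <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(spec$reference)))
  spec_rc <- amplicon_spec(rc_ref, spec$protospacer)
  expect_identical(spec_rc$strand, "-")
  expect_identical(spec_rc$cut_site, nchar(spec$reference) - spec$cut_site)
})

test_that("eligibility: 75% identity over the first 20 reference bases, boundary kept", {
  spec <- test_amplicon(desired_edit = FALSE)
  ref <- spec$reference
  L <- nchar(ref)
  flip <- function(s, pos) {
    x <- strsplit(s, "")[[1]]
    for (p in pos) x[p] <- setdiff(c("A", "C", "G", "T"), x[p])[1]
    paste(x, collapse = "")
  }
  reads <- rbind(
    read_row("perfect", 1, sprintf("%dM", L), ref),
    read_row("sub6", 1, sprintf("%dM", L), flip(ref, 1:6)),     # 14/20
    read_row("sub5", 1, sprintf("%dM", L), flip(ref, 1:5)),     # 15/20 kept
    read_row("late", 30, sprintf("%dM", L - 29), substr(ref, 30, L)))
  elig <- filter_eligible(reads, spec)
  expect_identical(elig$qname, c("perfect", "sub5"))
  expect_identical(attr(elig, "total_reads"), 4L)
  expect_error(filter_eligible(read_row("x", NA, "10M", "ACGTACGTAC"), spec),
               "unaligned")
})

test_that("count_indels windows on the left-normalized indel start and divides by total reads", {
  spec <- test_amplicon(desired_edit = FALSE)
  ref <- spec$reference; L <- nchar(ref); cut <- spec$cut_site
  del_at <- function(qn, at, len) {
    read_row(qn, 1, sprintf("%dM%dD%dM", at, len, L - at - len),
             paste0(substr(ref, 1, at), substr(ref, at + len + 1, L)))
  }
  reads <- rbind(
    del_at("d1", cut, 2), del_at("d2", cut - 1, 2), del_at("d3", cut + 2, 2),
    del_at("far", cut + 5, 2),                    # outside the +/-2 window
    read_row("wt1", 1, sprintf("%dM", L), ref),
    read_row("wt2", 1, sprintf("%dM", L), ref),
    read_row("wt3", 1, sprintf("%dM", L), ref),
    read_row("wt4", 1, sprintf("%dM", L), ref),
    read_row("wt5", 1, sprintf("%dM", L), ref),
    read_row("wt6", 1, sprintf("%dM", L), ref))
  elig <- filter_eligible(reads, spec)
  res <- count_indels(elig, spec)
  expect_identical(res$indel_reads, 3L)
  expect_identical(res$total_reads, 10L)
  expect_equal(res$indel_frequency, 0.30)

  # empty input: frequency 0 with a flag
  res0 <- count_indels(elig[0, , drop = FALSE], spec, total_reads = 0)
  expect_equal(res0$indel_frequency, 0)
  expect_identical(res0$flag, "empty_input")

  expect_error(count_indels(elig, spec, window = 1000), "outside")
})

test_that("indel window anchors on the left-normalized gap coordinate", {
  # homopolymer spanning the cut: a deletion written at the right edge of
  # the run must left-normalize into the window
  proto <- "GATTACAGATTACAGATTAC"
  ref <- paste0(strrep("ACGT", 8), proto, "AGG", strrep("CGTA", 10))
  x <- strsplit(ref, "")[[1]]
  spec0 <- amplicon_spec(ref, proto)
  cut <- spec0$cut_site
  x[(cut + 1):(cut + 6)] <- "A"                    # A-run right after the cut
  ref <- paste(x, collapse = "")
  spec <- amplicon_spec(ref, paste(x[33:52], collapse = ""))
  L <- nchar(ref)
  # delete two A's at the right end of the run (raw start cut+5, > cut+2)
  raw_start <- cut + 4
  rd <- read_row("r1", 1,
                 sprintf("%dM2D%dM", raw_start, L - raw_start - 2),
                 paste0(substr(ref, 1, raw_start), substr(ref, raw_start + 3, L)))
  elig <- filter_eligible(rd, spec)
  res <- count_indels(elig, spec)
  expect_identical(res$indel_reads, 1L)            # normalizes to the cut
})

test_that("count_tag finds either 15-mer center fragment, case-insensitive", {
  spec <- test_amplicon(desired_edit = FALSE)
  ref <- spec$reference; L <- nchar(ref)
  mk <- function(qn, insert) {
    read_row(qn, 1, sprintf("%dM%dI%dM", 50, nchar(insert), L - 50),
             paste0(substr(ref, 1, 50), insert, substr(ref, 51, L)))
  }
  reads <- rbind(mk("fwd", "gttgtcatatgttaa"),
                 mk("rev", "TTAACATATGACAAC"),
                 read_row("plain", 1, sprintf("%dM", L), ref))
  expect_identical(count_tag(reads, spec), 2L)
})

test_that("count_edit requires all programmed substitutions and no window indel", {
  spec <- test_amplicon()
  ref <- spec$reference; L <- nchar(ref)
  edit_pos <- as.integer(names(spec$desired_edit))
  apply_subs <- function(s, pos, bases) {
    x <- strsplit(s, "")[[1]]; x[pos] <- bases; paste(x, collapse = "")
  }
  full <- apply_subs(ref, edit_pos, unname(spec$desired_edit))
  partial <- apply_subs(ref, edit_pos[1], unname(spec$desired_edit)[1])
  cut <- spec$cut_site
  edited_with_del <- read_row(
    "both_del", 1, sprintf("%dM1D%dM", cut, L - cut - 1),
    apply_subs(paste0(substr(ref, 1, cut), substr(ref, cut + 2, L)),
               edit_pos[1], unname(spec$desired_edit)[1]))
  reads <- rbind(read_row("both", 1, sprintf("%dM", L), full),
                 read_row("one", 1, sprintf("%dM", L), partial),
                 read_row("wt", 1, sprintf("%dM", L), ref),
                 edited_with_del)
  res <- count_edit(reads, spec)
  expect_identical(res$edit_reads, 1L)
  expect_equal(res$edit_fraction, 0.25)
})

test_that("simulated mixes are recovered by the counters", {
  spec <- test_amplicon()
  # pure wild type: no indels anywhere
  wt <- simulate_reads(spec, mix = c(wt = 1, indel = 0, tagged = 0,
                                     edited = 0), n = 200, seed = 1)
  expect_equal(tally_amplicon(wt, spec)$indel_frequency, 0)

  # programmed proportions: measured counts equal realized class counts
  mix <- c(wt = 0.6, indel = 0.25, tagged = 0.1, edited = 0.05)
  rds <- simulate_reads(spec, mix = mix, n = 4000, seed = 2)
  s <- tally_amplicon(rds, spec)
  ncls <- table(factor(rds$class, levels = names(mix)))
  # tagged reads carry an insertion at the cut, so they count as indels too
  expect_identical(s$indel_reads, unname(ncls["indel"] + ncls["tagged"]))
  expect_identical(s$tag_reads, unname(as.integer(ncls["tagged"])))
  expect_identical(s$edit_reads, unname(as.integer(ncls["edited"])))
  expect_identical(s$eligible_reads, nrow(rds))

  # realized class counts sit inside exact binomial bounds of the mix
  for (cl in names(mix)) {
    ci <- stats::binom.test(ncls[[cl]], 4000)$conf.int
    expect_true(mix[[cl]] >= ci[1] && mix[[cl]] <= ci[2])
  }

  # the published-scale worked example: 107 edited of 1000 reads
  rds2 <- rbind(simulate_reads(spec, c(wt = 1, indel = 0, tagged = 0,
                                       edited = 0), n = 893, seed = 3),
                simulate_reads(spec, c(wt = 0, indel = 0, tagged = 0,
                                       edited = 1), n = 107, seed = 4))
  expect_equal(count_edit(rds2, spec)$edit_fraction, 0.107)
})

test_that("counting is order-independent and SAM round trips preserve results", {
  spec <- test_amplicon()
  rds <- simulate_reads(spec, mix = c(wt = 0.5, indel = 0.3, tagged = 0.1,
                                      edited = 0.1), n = 300, seed = 5)
  s1 <- tally_amplicon(rds, spec)
  set.seed(6)
  s2 <- tally_amplicon(rds[sample(nrow(rds)), ], spec)
  expect_equal(unclass(s1), unclass(s2))

  f <- tempfile(fileext = ".sam")
  write_sam(rds, spec, f)
  back <- read_amplicon_sam(f, spec)
  expect_identical(nrow(back), nrow(rds))
  s3 <- tally_amplicon(back, spec)
  expect_equal(unclass(s1), unclass(s3))
})

test_that("counts are invariant under reverse-complementing reads and reference", {
  spec <- test_amplicon()
  rds <- simulate_reads(spec, mix = c(wt = 0.5, indel = 0.3, tagged = 0.1,
                                      edited = 0.1), n = 200, seed = 7)
  spec_rc <- cleavr:::revcomp_spec(spec)
  rds_rc <- cleavr:::revcomp_reads(rds, spec)
  s1 <- tally_amplicon(rds, spec)
  s2 <- tally_amplicon(rds_rc, spec_rc)
  expect_identical(s1$indel_reads, s2$indel_reads)
  expect_identical(s1$tag_reads, s2$tag_reads)
  expect_identical(s1$edit_reads, s2$edit_reads)
  expect_identical(s1$eligible_reads, s2$eligible_reads)
})
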