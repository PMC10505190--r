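# Two-step screen for the target-matched variant: a rough on-target screen
# with the wild type plus three probes dividing the cleavability range into
# quarters, then a fine screen over the interval bracketed by the last
# active and first inactive probe. Under the cleavage rule this finds the
# highest-fidelity variant still sufficiently active without assaying the
# whole panel.

#' Construct a screen panel
#'
#' @param variant_ids panel members, fidelity rank ascending (wild type,
#'   the least selective member, first).
#' @param cleavable_fraction per-variant fraction of the target range each
#'   member can cleave (from a reference map or latent model); must be
#'   non-increasing along the panel.
#' @return a `screen_panel` data.frame.
#' @export
screen_panel <- function(variant_ids, cleavable_fraction) {
  stopifnot(length(variant_ids) == length(cleavable_fraction))
  if (is.unsorted(rev(cleavable_fraction))) {
    stopf("cleavable fractions must be non-increasing with fidelity rank")
  }
  structure(data.frame(variant_id = variant_ids,
                       cleavable_fraction = cleavable_fraction,
                       stringsAsFactors = FALSE),
            class = c("screen_panel", "data.frame"))
}

#' Panel from latent model parameters
#'
#' The cleavable fraction of each variant is the fraction of target
#' contributions exceeding its inhibition level.
#'
#' @param params a `latent_params` object.
#' @return a `screen_panel`.
#' @export
panel_from_params <- function(params) {
  stopifnot(inherits(params, "latent_params"))
  frac <- vapply(params$f, function(fv) mean(params$c > fv), 0)
  screen_panel(names(params$f), frac)
}

#' Panel from an observed call matrix
#'
#' @param calls a `cleavage_calls` object; variants are ranked with
#'   [order_variants()] and fractions are their cleaved-target shares.
#' @return a `screen_panel`.
#' @export
panel_from_calls <- function(calls) {
  vo <- order_variants(calls)
  frac <- rowMeans(calls$calls[vo, , drop = FALSE], na.rm = TRUE)
  # enforce the panel invariant: ranking is by cleaved count, so shares are
  # non-increasing up to ties already
  screen_panel(vo, cummin(frac))
}

#' Plan the rough (step-1) screen
#'
#' Returns the wild type plus the three panel members whose cleavable
#' fractions are closest to 3/4, 1/2 and 1/4 of the target range, i.e. the
#' probes dividing the range into four approximately proportional
#' sections. Distance ties resolve toward the lower-fidelity (earlier)
#' member; a member already chosen for a previous quartile is skipped.
#'
#' @param panel a `screen_panel` (>= 4 members).
#' @return character vector of probe ids, fidelity ascending (WT first).
#' @export
plan_rough_screen <- function(panel) {
  stopifnot(inherits(panel, "screen_panel"))
  if (nrow(panel) < 4) stopf("panel must contain at least WT and 3 variants")
  ids <- panel$variant_id
  frac <- panel$cleavable_fraction
  chosen <- integer(0)
  for (q in c(3 / 4, 1 / 2, 1 / 4)) {
    cand <- setdiff(seq_along(ids)[-1], chosen)   # never re-pick, skip WT slot
    d <- abs(frac[cand] - q)
    pick <- cand[order(d, cand)][1]               # tie -> lower fidelity
    chosen <- c(chosen, pick)
  }
  ids[c(1L, sort(chosen))]
}

#' Run one screen step
#'
#' Measures the probes (fidelity ascending) with the supplied activity
#' oracle and brackets the transition: the last member of the contiguous
#' active run from the bottom of the panel, and the first probe above it
#' that is insufficiently active. Non-monotone measurements (an active
#' probe above an inactive one, possible under noise) are resolved by
#' trusting the contiguous run and reported via a warning.
#'
#' @param oracle function(variant_id) returning WT-normalized activity.
#' @param probes probe ids, fidelity ascending (WT first).
#' @param activity_min threshold for "sufficiently active" (0.20 for the
#'   rough step by default; see [two_step_screen()]).
#' @return list with `measurements` (data.frame `variant_id`, `activity`),
#'   `lower` (last active probe), `upper` (first inactive probe or NA when
#'   every probe is active) and `flag`.
#' @export
run_screen_step <- function(oracle, probes, activity_min = 0.20) {
  act <- vapply(probes, function(v) oracle(v), 0)
  meas <- data.frame(variant_id = probes, activity = unname(act),
                     stringsAsFactors = FALSE)
  active <- act >= activity_min
  flag <- NA_character_
  if (!active[1]) {
    # not even the wild type (or lowest-fidelity probe) is active
    return(list(measurements = meas, lower = probes[1],
                upper = probes[min(2, length(probes))],
                flag = "low_cleavability_target"))
  }
  run_end <- match(FALSE, active, nomatch = length(probes) + 1L) - 1L
  if (any(active[-seq_len(run_end)])) {
    warning("non-monotone screen measurements; trusting the contiguous active run",
            call. = FALSE)
  }
  lower <- probes[run_end]
  upper <- if (run_end == length(probes)) NA_character_ else probes[run_end + 1L]
  list(measurements = meas, lower = lower, upper = upper, flag = flag)
}

#' Plan the fine (step-2) screen
#'
#' All not-yet-tested panel members with fidelity strictly between the
#' bracket ends, in fidelity order. An open upper bracket (every probe
#' active) extends the interval to the top of the panel.
#'
#' @param panel a `screen_panel`.
#' @param bracket result of [run_screen_step()].
#' @return character vector of additional variants to assay (possibly
#'   empty).
#' @export
plan_fine_screen <- function(panel, bracket) {
  stopifnot(inherits(panel, "screen_panel"))
  ids <- panel$variant_id
  lo <- match(bracket$lower, ids)
  hi <- if (is.na(bracket$upper)) length(ids) + 1L else match(bracket$upper, ids)
  if (is.na(lo) || (!is.na(bracket$upper) && is.na(hi))) {
    stopf("bracket ends are not panel members")
  }
  if (hi - lo < 2) return(character(0))
  cand <- ids[(lo + 1L):(hi - 1L)]
  setdiff(cand, bracket$measurements$variant_id)
}

#' Select the target-matched variant from screen measurements
#'
#' The target-matched variant is the highest-fidelity panel member whose
#' measured activity reaches `activity_min`; up to two top candidates are
#' nominated for external genome-wide off-target confirmation.
#'
#' @param measurements data.frame `variant_id`, `activity` covering all
#'   assayed variants.
#' @param panel a `screen_panel` (fixes the fidelity order).
#' @param activity_min selection threshold (0.50 by default: "sufficiently
#'   active" for confirmation-grade editing).
#' @return an object of class `screen_outcome`: `probes_tested`,
#'   `target_matched`, `candidates_for_offtarget_confirmation` (<= 2),
#'   `assays_used` and `flag`.
#' @export
select_target_matched <- function(measurements, panel, activity_min = 0.50) {
  stopifnot(inherits(panel, "screen_panel"))
  assert_cols(measurements, c("variant_id", "activity"), "measurements")
  ids <- panel$variant_id
  meas <- measurements[!duplicated(measurements$variant_id), , drop = FALSE]
  pos <- match(meas$variant_id, ids)
  if (anyNA(pos)) stopf("measurements contain non-panel variants")
  meas <- meas[order(pos), , drop = FALSE]
  active <- meas$activity >= activity_min
  flag <- NA_character_
  if (!any(active)) {
    tm <- NA_character_
    cand <- character(0)
    flag <- "no_sufficiently_active_variant"
  } else {
    act_idx <- which(active)
    tm <- meas$variant_id[max(act_idx)]
    if (tm == ids[1]) flag <- "no_IFN_below_target_rank"  # only WT active
    cand <- rev(meas$variant_id[utils::tail(act_idx, 2)])
  }
  structure(
    list(probes_tested = meas,
         target_matched = tm,
         candidates_for_offtarget_confirmation = cand,
         assays_used = nrow(meas),
         activity_min = activity_min,
         flag = flag),
    class = "screen_outcome")
}

#' @export
print.screen_outcome <- function(x, ...) {
  cat(sprintf("Two-step screen: target-matched = %s (%d assays)\n",
              x$target_matched, x$assays_used))
  if (!is.na(x$flag)) cat("Flag:", x$flag, "\n")
  invisible(x)
}

#' Run the complete two-step screen
#'
#' Step 1 (rough): assay the wild type plus the three quartile probes and
#' bracket the activity transition at `rough_min`. Step 2 (fine): assay
#' the untested variants inside the bracket and select the target-matched
#' variant at `fine_min`. Both thresholds are application-dependent and
#' configurable.
#'
#' @param panel a `screen_panel`.
#' @param oracle function(variant_id) returning WT-normalized activity on
#'   the target of interest.
#' @param rough_min step-1 activity threshold (default 0.20, the cleavage
#'   call threshold).
#' @param fine_min selection threshold (default 0.50).
#' @return a `screen_outcome`.
#' @export
two_step_screen <- function(panel, oracle, rough_min = 0.20, fine_min = 0.50) {
  probes <- plan_rough_screen(panel)
  step1 <- run_screen_step(oracle, probes, activity_min = rough_min)
  fine <- plan_fine_screen(panel, step1)
  meas <- step1$measurements
  if (length(fine)) {
    meas <- rbind(meas,
                  data.frame(variant_id = fine,
                             activity = vapply(fine, function(v) oracle(v), 0),
                             stringsAsFactors = FALSE))
  }
  out <- select_target_matched(meas, panel, activity_min = fine_min)
  if (!is.na(step1$flag) && is.na(out$flag)) out$flag <- step1$flag
  out$bracket <- c(lower = step1$lower, upper = step1$upper)
  out
}

#' Exhaustive full-panel selection (oracle for the two-step screen)
#'
#' Assays every panel member and picks the highest-fidelity one reaching
#' `activity_min`; used to verify that the two-step screen loses nothing
#' under a monotone (hard-threshold) activity oracle.
#'
#' @inheritParams two_step_screen
#' @param activity_min selection threshold.
#' @return a `screen_outcome` with `assays_used` equal to the panel size.
#' @export
full_panel_select <- function(panel, oracle, activity_min = 0.50) {
  meas <- data.frame(variant_id = panel$variant_id,
                     activity = vapply(panel$variant_id,
                                       function(v) oracle(v), 0),
                     stringsAsFactors = FALSE)
  select_target_matched(meas, panel, activity_min = activity_min)
}
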