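#' Errors to criterion per block
#'
#' Within each contingency block, slides an `n`-trial window over the
#' correct/error sequence; the criterion is met at the first trial whose
#' trailing window contains at least `m` correct trials (`m`/`n` is 28/30
#' for the initial block and 24/30 for subsequent reversals, i.e. 93% and
#' 80% performance). The number of error trials strictly before that trial
#' is the block's errors-to-criterion.
#'
#' @param log A session log (tibble with `block` and `correct` columns, as
#'   produced by [run_session()]).
#' @param criterion_initial,criterion_later `c(m, n)` criteria for block 1
#'   and for later blocks.
#'
#' @return A tibble with one row per block: `block`, `block_type` (the
#'   rewarded option), `n_trials`, `criterion_met`, `trials_to_criterion`
#'   (NA when unmet), `errors_to_criterion` (NA when unmet), `errors_total`.
#' @export
errors_to_criterion <- function(log, criterion_initial = c(28, 30),
                                criterion_later = c(24, 30)) {
  stopifnot(all(c("block", "correct") %in% names(log)))
  blocks <- split(log, log$block)
  purrr::map_dfr(blocks, function(bl) {
    b <- bl$block[1]
    crit <- if (b == 1L) criterion_initial else criterion_later
    m <- crit[1]; nwin <- crit[2]
    x <- bl$correct
    if (length(x) < nwin)
      stop("block ", b, " has fewer trials (", length(x),
           ") than the criterion window (", nwin, ")", call. = FALSE)
    cs <- cumsum(x)
    wins <- cs[nwin:length(x)] - c(0, cs)[1:(length(x) - nwin + 1L)]
    hit <- which(wins >= m)
    met <- length(hit) > 0L
    t_met <- if (met) hit[1] + nwin - 1L else NA_integer_
    errs <- if (met) sum(x[seq_len(t_met - 1L)] == 0) else NA_integer_
    tibble::tibble(block = b,
                   block_type = if ("rewarded_option" %in% names(bl))
                                  bl$rewarded_option[1]
                                else if ("good_outcome" %in% names(bl))
                                  bl$good_outcome[1]
                                else NA_character_,
                   n_trials = length(x), criterion_met = met,
                   trials_to_criterion = t_met, errors_to_criterion = errs,
                   errors_total = sum(x == 0))
  })
}

#' Pick neurons to inactivate by selectivity label
#'
#' @param labels Per-neuron selectivity labels (as from
#'   [classify_selectivity()]: a character vector or the `label` column of
#'   its result).
#' @param group A selectivity label (e.g. `"AR"`, `"A"`), or `"random"` for
#'   an unconditioned draw.
#' @param count Number of neurons to remove (50 in the published
#'   experiment).
#' @param seed Seed used to subsample when the group is larger than `count`
#'   (and for the `"random"` group).
#' @return Integer vector of `count` neuron indices.
#' @export
select_inactivation_targets <- function(labels, group, count = 50, seed = 1) {
  if (is.data.frame(labels)) labels <- labels$label
  count <- as.integer(count)
  if (count == 0L) return(integer(0))
  pool <- if (identical(group, "random")) seq_along(labels)
          else which(labels == group)
  if (length(pool) < count)
    stop("selectivity group '", group, "' has only ", length(pool),
         " neuron(s); ", count, " requested", call. = FALSE)
  if (length(pool) == count) return(pool)
  with_seed(seed, sort(sample(pool, count)))
}

#' Zero selected rates at the readout stage
#'
#' Models decision-time inactivation: the selected neurons' rates are set to
#' 0 only where the readout drive is computed; the reservoir dynamics are
#' untouched. (Inside [run_session()] this is applied automatically via the
#' `inactivate` field of [session_config()].)
#'
#' @param rates A rate vector (or trials x N matrix).
#' @param neurons Integer indices to silence.
#' @return The modified rates.
#' @export
apply_inactivation <- function(rates, neurons) {
  if (!length(neurons)) return(rates)
  if (is.matrix(rates)) rates[, neurons] <- 0 else rates[neurons] <- 0
  rates
}
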