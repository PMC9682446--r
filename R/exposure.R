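#' Per-rank click-through-rate model
#'
#' A piecewise CTR model for organic search positions: an empirical head
#' table for ranks 1..`head_max` and an exponential tail
#' `a * exp(-b * rank)` for ranks `head_max + 1`..`rank_max`. The tail
#' defaults to the coefficients a = 26.76 (percent) and b = 0.258 (per rank)
#' of an exponential trend line fitted through first-page CTR data; the head
#' table is an industry input the model cannot derive, so a placeholder head
#' (the same exponential evaluated at ranks 1..`head_max`) ships as the
#' default — replace it with measured per-rank CTRs for real reporting
#' (see [default_head_ctr()]).
#'
#' No continuity is enforced at the head/tail boundary; the model reports the
#' boundary values so a discontinuity is visible.
#'
#' @param head Numeric vector of CTR percentages for ranks 1..`head_max`,
#'   each in (0, 100].
#' @param tail_a Tail coefficient, percent units; > 0.
#' @param tail_b Tail decay rate per rank; > 0.
#' @param head_max Last rank served from the head table (default 10).
#' @param rank_max Largest modelled rank (default 40).
#' @return An object of class `rank_ctr_model`.
#' @export
rank_ctr_model <- function(head = default_head_ctr(head_max),
                           tail_a = 26.76, tail_b = 0.258,
                           head_max = 10L, rank_max = 40L) {
  head_max <- as.integer(head_max)
  rank_max <- as.integer(rank_max)
  if (head_max < 1L || rank_max <= head_max) {
    stop("configuration error: need 1 <= head_max < rank_max")
  }
  if (length(head) != head_max) {
    stop("configuration error: head table must have exactly head_max = ",
         head_max, " values")
  }
  if (any(!is.finite(head)) || any(head <= 0) || any(head > 100)) {
    stop("configuration error: head CTRs must lie in (0, 100]")
  }
  if (!is.finite(tail_a) || tail_a <= 0 || !is.finite(tail_b) || tail_b <= 0) {
    stop("configuration error: tail coefficients must be positive")
  }
  structure(
    list(head = as.numeric(head), tail_a = tail_a, tail_b = tail_b,
         head_max = head_max, rank_max = rank_max),
    class = "rank_ctr_model"
  )
}

#' Placeholder head CTR table
#'
#' The per-rank CTR percentages for first-page positions come from industry
#' click studies and are not derivable from the tail equation; this
#' placeholder simply evaluates the default exponential tail at ranks
#' 1..`head_max` so that demonstrations and tests run end to end. It is not
#' measured data: supply a real head table for substantive reporting.
#'
#' @param head_max Number of head ranks (default 10).
#' @param tail_a,tail_b Exponential coefficients used for the placeholder.
#' @return Numeric vector of length `head_max`.
#' @export
default_head_ctr <- function(head_max = 10L, tail_a = 26.76, tail_b = 0.258) {
  tail_a * exp(-tail_b * seq_len(head_max))
}

#' @export
print.rank_ctr_model <- function(x, ...) {
  cat("Per-rank CTR model: head table ranks 1-", x$head_max,
      ", tail ", format(x$tail_a), " * exp(-", format(x$tail_b),
      " * rank) for ranks ", x$head_max + 1L, "-", x$rank_max, "\n", sep = "")
  cat(sprintf("boundary: head[%d] = %.3f%%, tail(%d) = %.3f%%\n",
              x$head_max, x$head[x$head_max], x$head_max + 1L,
              x$tail_a * exp(-x$tail_b * (x$head_max + 1L))))
  invisible(x)
}

#' Click-through rate at a rank
#'
#' @param model A [rank_ctr_model()].
#' @param rank Integer rank(s), 1-based, each within `[1, rank_max]`.
#' @return CTR percentage(s).
#' @export
ctr_at_rank <- function(model, rank) {
  stopifnot(inherits(model, "rank_ctr_model"))
  if (length(rank) == 0) return(numeric(0))
  r <- as.integer(rank)
  bad <- is.na(r) | r < 1L | r > model$rank_max
  if (any(bad)) {
    stop("domain error: rank out of [1, ", model$rank_max, "]: ",
         paste(unique(rank[bad]), collapse = ", "))
  }
  ifelse(r <= model$head_max, model$head[pmax(r, 1L)],
         model$tail_a * exp(-model$tail_b * r))
}

#' Cumulative click-through rate over documented positions
#'
#' Sums the per-rank CTR over a multiset of rank positions (multiplicity
#' counts). The sum is an exposure index, not a probability: it can exceed
#' 100% by construction and is deliberately not capped.
#'
#' @param model A [rank_ctr_model()].
#' @param ranks Integer vector of rank positions (may repeat; may be empty).
#' @return Cumulative CTR percentage (>= 0).
#' @export
cumulative_ctr <- function(model, ranks) {
  if (length(ranks) == 0) return(0)
  sum(ctr_at_rank(model, ranks))
}

#' Prevalence of compromised links
#'
#' The number of infected links divided by the total number of evaluated
#' links, as a percentage.
#'
#' @param n_compromised Count of compromised links, `0 <= n_compromised <= n_total`.
#' @param n_total Count of all evaluated links, > 0.
#' @return Percentage in `[0, 100]`.
#' @export
prevalence <- function(n_compromised, n_total) {
  if (any(n_total == 0)) stop("undefined prevalence: n_total is zero")
  if (any(n_compromised < 0) || any(n_total < 0)) {
    stop("consistency error: negative count")
  }
  if (any(n_compromised > n_total)) {
    stop("consistency error: n_compromised exceeds n_total")
  }
  100 * n_compromised / n_total
}

#' Fit an exponential tail to per-rank CTR points
#'
#' Least-squares fit of `log(CTR)` on rank (log-linear), the trend-line
#' construction spreadsheet tooling applies to an exponential: returns the
#' coefficients of `CTR = a * exp(-b * rank)` and the R-squared of the fit on
#' the log scale.
#'
#' @param rank Integer ranks (>= 3 points).
#' @param ctr CTR percentages, all > 0.
#' @return List with `a`, `b`, `r_squared`.
#' @export
fit_tail <- function(rank, ctr) {
  if (length(rank) != length(ctr)) stop("rank and ctr must have equal length")
  if (length(rank) < 3) stop("insufficient data: need at least 3 points")
  if (any(!is.finite(ctr)) || any(ctr <= 0)) {
    stop("domain error: CTR values must be positive for a log-linear fit")
  }
  fit <- stats::lm(log(ctr) ~ rank)
  co <- stats::coef(fit)
  y <- log(ctr)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(a = unname(exp(co[1])), b = unname(-co[2]), r_squared = r2)
}

#' Per-group prevalence and cumulative CTR exposure report
#'
#' For each group of evaluated records (default grouping country x API)
#' reports the number of compromised links, the prevalence over all evaluated
#' links, and the cumulative CTR summed over the rank positions of the
#' group's compromised links.
#'
#' @param records Validated audit tibble; rows flagged `excluded` are dropped.
#' @param model A [rank_ctr_model()] covering the dataset's rank range.
#' @param group_by Grouping keys (default `c("country", "api")`).
#' @param compromised Categories counted as compromised
#'   (default [compromised_categories()]).
#' @param all_positions If `TRUE`, cumulative CTR sums over all documented
#'   positions in the group rather than the compromised ones only.
#' @param digits Decimal places for the reported percentages (default 1; use
#'   `Inf` for unrounded values).
#' @return Tibble: group keys, n_compromised, n_total, prevalence,
#'   cumulative_ctr.
#' @export
exposure_report <- function(records, model, group_by = c("country", "api"),
                            compromised = compromised_categories(),
                            all_positions = FALSE, digits = 1) {
  bad <- setdiff(group_by, names(records))
  if (length(bad) > 0) {
    stop("configuration error: unknown group key(s): ", paste(bad, collapse = ", "))
  }
  recs <- records[!records$excluded, , drop = FALSE]
  grouped <- dplyr::group_by(recs, dplyr::across(dplyr::all_of(group_by)))
  out <- dplyr::summarise(
    grouped,
    n_compromised = sum(.data$category %in% compromised),
    n_total = dplyr::n(),
    prevalence = prevalence(n_compromised, n_total),
    cumulative_ctr = if (all_positions) cumulative_ctr(model, .data$rank) else
      cumulative_ctr(model, .data$rank[.data$category %in% compromised]),
    .groups = "drop"
  )
  if (is.finite(digits)) {
    out$prevalence <- round_half_up(out$prevalence, digits)
    out$cumulative_ctr <- round_half_up(out$cumulative_ctr, digits)
  }
  out
}
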