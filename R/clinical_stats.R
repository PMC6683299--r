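.normalise_response <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:space:]]+", " ", x)
  gsub("[.]+$", "", x)
}

#' Score a free-text interpretation against the answer key
#'
#' Case-insensitive, whitespace-normalised exact membership in the accepted
#' set for the stimulus (canonical diagnosis plus listed synonyms and
#' acronyms, e.g. "left bundle branch" or "LBBB"). Umbrella terms not in the
#' accepted set ("arrhythmia", "SVT") score incorrect, as does an empty
#' response. Exact-set matching, not fuzzy matching: auditable by reading
#' the key.
#'
#' @param response free-text answer (vectorised).
#' @param key_entry one entry of an [answer_key()] (`canonical`,
#'   `accepted`).
#' @return logical vector, `TRUE` = correct.
#' @export
score_response <- function(response, key_entry) {
  accepted <- .normalise_response(key_entry$accepted)
  .normalise_response(response) %in% accepted
}

#' Score every response of a dataset
#'
#' @param dataset a [study_dataset()] whose `responses` table is non-empty.
#' @param key an [answer_key()] covering every stimulus in the responses.
#' @return the responses data.frame with an added logical `correct` column.
#' @export
score_responses <- function(dataset, key) {
  rs <- dataset$responses
  if (is.null(rs) || !nrow(rs)) stop("dataset has no responses to score")
  miss <- setdiff(unique(rs$stimulus), names(key))
  if (length(miss)) stop("answer key missing stimuli: ",
                         paste(miss, collapse = ", "))
  rs$correct <- vapply(seq_len(nrow(rs)), function(i) {
    score_response(rs$response[i], key[[rs$stimulus[i]]])
  }, logical(1))
  rs
}

#' Paired binary outcome table
#'
#' Cross-tabulates correctness of the same participants under two
#' conditions: `a` = correct in both, `b` = correct only in condition 1,
#' `c` = correct only in condition 2, `d` = incorrect in both.
#'
#' @param correct1,correct2 logical vectors, one entry per participant, in
#'   matching order.
#' @return object of class `paired_binary_table` (list `a`, `b`, `c`, `d`).
#' @export
paired_binary_table <- function(correct1, correct2) {
  stopifnot(length(correct1) == length(correct2),
            is.logical(correct1), is.logical(correct2))
  structure(list(a = sum(correct1 & correct2),
                 b = sum(correct1 & !correct2),
                 c = sum(!correct1 & correct2),
                 d = sum(!correct1 & !correct2)),
            class = "paired_binary_table")
}

#' McNemar's chi-squared test for paired binary outcomes
#'
#' Continuity-corrected statistic on the discordant counts,
#' `chi2 = max(0, |b - c| - 1)^2 / (b + c)`, referred to the chi-squared
#' distribution with one degree of freedom (upper tail). The correction
#' term is floored at zero so symmetric discordance (`b = c`) yields a
#' statistic of 0 and p = 1.
#'
#' @param table a [paired_binary_table()], or the discordant count `b` when
#'   `c` is given.
#' @param c2 discordant count `c` (condition-2-correct-only) when `table` is
#'   the bare count `b`.
#' @return list with `chi2`, `df` (always 1) and `p`.
#' @export
mcnemar_test <- function(table, c2 = NULL) {
  if (inherits(table, "paired_binary_table")) {
    b <- table$b; c <- table$c
  } else {
    b <- table; c <- c2
  }
  stopifnot(b >= 0, c >= 0)
  if (b + c == 0) stop("undefined test: no discordant pairs")
  chi2 <- max(0, abs(b - c) - 1)^2 / (b + c)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1L, lower.tail = FALSE))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; absolute differences receive mid-ranks.
#' `V` is the sum of ranks of the positive differences. The two-sided
#' p-value is exact (signed-rank distribution) when n <= 25 and the
#' absolute differences are tie-free; otherwise a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param x,y paired numeric samples of equal length.
#' @return list with `V`, `n` (non-zero differences), `p` and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("undefined test: all differences are zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25L && !ties) {
    p <- min(1, 2 * min(stats::psignrank(V, n),
                        stats::psignrank(V - 1, n, lower.tail = FALSE)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    z <- V - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(V = V, n = n, p = p, method = method)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests (>= 1).
#' @return the per-test threshold `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Per-stimulus accuracy comparison between conditions
#'
#' For each stimulus, participants with a scored response in both
#' conditions enter a [paired_binary_table()] (condition 1 = history,
#' condition 2 = no history) and a continuity-corrected [mcnemar_test()].
#'
#' @param dataset a [study_dataset()] with responses.
#' @param key an [answer_key()].
#' @return data.frame with one row per stimulus: `stimulus`, `n`, `b`, `c`,
#'   `chi2`, `p` (`NA` for stimuli with no discordant pairs).
#' @export
accuracy_table <- function(dataset, key) {
  scored <- score_responses(dataset, key)
  out <- lapply(sort(unique(scored$stimulus)), function(st) {
    s <- scored[scored$stimulus == st, ]
    h <- s[s$condition == "history", c("participant", "correct")]
    nh <- s[s$condition == "no_history", c("participant", "correct")]
    both <- merge(h, nh, by = "participant", suffixes = c("_h", "_nh"))
    tab <- paired_binary_table(both$correct_h, both$correct_nh)
    res <- if (tab$b + tab$c > 0) mcnemar_test(tab) else
      list(chi2 = NA_real_, p = NA_real_)
    data.frame(stimulus = st, n = nrow(both), b = tab$b, c = tab$c,
               chi2 = res$chi2, p = res$p)
  })
  do.call(rbind, out)
}

#' Per-stimulus paired Wilcoxon tests on fixation metrics
#'
#' For each stimulus, each participant contributes a fixation count and a
#' mean fixation duration per condition; history and no-history values are
#' compared with [wilcoxon_signed_rank()].
#'
#' @param dataset a [study_dataset()].
#' @return data.frame per stimulus with `count_V`, `count_p`,
#'   `duration_V`, `duration_p`, `n` (participants with both conditions).
#' @export
fixation_metric_table <- function(dataset) {
  fx <- dataset$fixations
  agg <- stats::aggregate(duration_ms ~ participant + stimulus + condition,
                          fx, function(v) c(n = length(v), mean = mean(v)))
  agg <- cbind(agg[1:3], as.data.frame(agg$duration_ms))
  out <- lapply(sort(unique(agg$stimulus)), function(st) {
    s <- agg[agg$stimulus == st, ]
    h <- s[s$condition == "history", ]
    nh <- s[s$condition == "no_history", ]
    both <- merge(h, nh, by = "participant", suffixes = c("_h", "_nh"))
    cnt <- wilcoxon_signed_rank(both$n_h, both$n_nh)
    dur <- wilcoxon_signed_rank(both$mean_h, both$mean_nh)
    data.frame(stimulus = st, n = nrow(both),
               count_V = cnt$V, count_p = cnt$p,
               duration_V = dur$V, duration_p = dur$p)
  })
  do.call(rbind, out)
}

#' Per-participant percentage accuracy
#'
#' @param dataset a [study_dataset()] with responses.
#' @param key an [answer_key()].
#' @return data.frame `participant`, `pct_correct` in \[0, 100\].
#' @export
accuracy_summary <- function(dataset, key) {
  scored <- score_responses(dataset, key)
  agg <- stats::aggregate(correct ~ participant, scored, mean)
  data.frame(participant = agg$participant, pct_correct = 100 * agg$correct)
}
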