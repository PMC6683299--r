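#' Count AOI-to-AOI transitions
#'
#' Entry (i, j) of the count matrix is the number of consecutive fixation
#' pairs moving from AOI i to AOI j, pooled over the given label sequences.
#' Self-transitions (i -> i, gaze staying "within" an AOI) are counted.
#' Sequences never bridge: the last label of one sequence and the first of
#' the next contribute no transition, so the grand total equals the sum of
#' (sequence length - 1) over sequences.
#'
#' @param sequences a character vector (one sequence) or a list of character
#'   vectors (one per trial), each of length >= 1.
#' @param labels the shared AOI support; every sequence label must be in it.
#' @return object of class `transition_counts`: `labels`, `counts` (square
#'   integer matrix), `n_sequences`, `n_transitions`.
#' @export
count_transitions <- function(sequences, labels) {
  if (!is.list(sequences)) sequences <- list(sequences)
  if (any(lengths(sequences) < 1L)) stop("sequences must have length >= 1")
  labels <- as.character(labels)
  L <- length(labels)
  all_lab <- unlist(sequences, use.names = FALSE)
  if (!all(all_lab %in% labels)) {
    stop("integrity error: label(s) outside the declared support: ",
         paste(utils::head(setdiff(all_lab, labels), 3L), collapse = ", "))
  }
  counts <- matrix(0L, L, L, dimnames = list(from = labels, to = labels))
  from <- unlist(lapply(sequences, function(s) s[-length(s)]), use.names = FALSE)
  to <- unlist(lapply(sequences, function(s) s[-1L]), use.names = FALSE)
  if (length(from)) {
    tab <- table(factor(from, levels = labels), factor(to, levels = labels))
    counts <- counts + unclass(tab)
    dimnames(counts) <- list(from = labels, to = labels)
  }
  structure(list(labels = labels, counts = counts,
                 n_sequences = length(sequences),
                 n_transitions = length(from)),
            class = "transition_counts")
}

#' Row-normalise transition counts into a Markov chain
#'
#' Each row of the count matrix is divided by its row sum; rows with no
#' outgoing transitions are left as zero and flagged in
#' `attr(, "zero_rows")`.
#'
#' @param counts a `transition_counts` object with at least one transition.
#' @return a `markov_chain` (see [markov_chain()]) whose rows with outgoing
#'   counts sum to one.
#' @export
to_markov <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  if (counts$n_transitions == 0L) stop("no transitions to normalise")
  rs <- rowSums(counts$counts)
  P <- counts$counts / ifelse(rs > 0, rs, 1)
  chain <- markov_chain(counts$labels, P, validate = FALSE)
  attr(chain, "zero_rows") <- counts$labels[rs == 0]
  chain
}

#' Flatten transition counts into a joint probability distribution
#'
#' The full count matrix is normalised by its grand total and flattened over
#' the directed (from, to) AOI pairs, giving a single probability vector of
#' length k = L^2 — the form the Hellinger distance is computed on. Support
#' order is from-major: all pairs out of the first AOI, then the second, and
#' so on.
#'
#' @param counts a `transition_counts` with at least one transition.
#' @return object of class `transition_distribution`: `support` (pair names
#'   `"from->to"`), `from`, `to`, `p` (sums to one).
#' @export
to_distribution <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  tot <- sum(counts$counts)
  if (tot == 0) stop("no transitions: cannot form a distribution")
  from <- rep(counts$labels, each = length(counts$labels))
  to <- rep(counts$labels, times = length(counts$labels))
  p <- as.vector(t(counts$counts)) / tot
  structure(list(support = paste0(from, "->", to), from = from, to = to,
                 p = p),
            class = "transition_distribution")
}

#' Hellinger distance between discrete distributions
#'
#' \deqn{H(P,Q) = \frac{1}{\sqrt 2}\sqrt{\sum_{i=1}^k (\sqrt{p_i} -
#' \sqrt{q_i})^2}}
#'
#' Bounded in \[0, 1\]; 0 iff the distributions coincide, 1 iff their
#' supports are disjoint. Both arguments must enumerate the same support in
#' the same order (zero-filled where a distribution has no mass).
#'
#' @param p,q `transition_distribution` objects sharing an identical support,
#'   or bare numeric probability vectors of equal length.
#' @return the distance, a single number in \[0, 1\].
#' @export
hellinger <- function(p, q) {
  if (inherits(p, "transition_distribution")) {
    if (!inherits(q, "transition_distribution") ||
        !identical(p$support, q$support)) {
      stop("distributions must share an identical support order")
    }
    p <- p$p; q <- q$p
  }
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) stop("support size mismatch")
  if (any(p < 0) || any(q < 0)) stop("negative probabilities")
  # boundary cases returned exactly: coincident -> 0, disjoint support -> 1
  if (identical(p, q)) return(0)
  if (!any(p > 0 & q > 0)) return(1)
  h <- sqrt(sum((sqrt(p) - sqrt(q))^2)) / sqrt(2)
  min(max(h, 0), 1)
}

#' Mean row-wise Hellinger distance between Markov chains
#'
#' Alternative comparison mode: the Hellinger distance of each pair of
#' conditional (row) distributions, averaged over the rows that have
#' outgoing mass in both chains. Rows empty in either chain carry no
#' conditional information and are skipped (their count is reported in
#' `attr(, "n_skipped")`).
#'
#' @param p,q `markov_chain` objects on the same state labels.
#' @return mean row-wise distance in \[0, 1\].
#' @export
hellinger_rows <- function(p, q) {
  stopifnot(inherits(p, "markov_chain"), inherits(q, "markov_chain"))
  if (!identical(p$labels, q$labels)) stop("chains must share state labels")
  rp <- rowSums(p$P) > 0
  rq <- rowSums(q$P) > 0
  use <- rp & rq
  if (!any(use)) stop("no row has outgoing mass in both chains")
  hs <- vapply(which(use), function(i) hellinger(p$P[i, ], q$P[i, ]),
               numeric(1))
  out <- mean(hs)
  attr(out, "n_skipped") <- sum(!use)
  out
}
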