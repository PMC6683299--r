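# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Stable 31-bit string/argument hash for deriving per-cell seeds from a
# master seed, so each (stimulus, scheme, comparison) cell gets an
# order-independent, reproducible stream.
derive_seed <- function(master, ...) {
  s <- paste(c(as.character(master), vapply(list(...), as.character,
                                            character(1))), collapse = "|")
  h <- as.double(master %% 2147483629)
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483629
  as.integer(h) + 1L
}

#' Define the two participant groups of a comparison
#'
#' Groups are disjoint, non-empty sets of participant ids. Optionally each
#' group carries a condition filter restricting which of a participant's
#' trials contribute scanpaths: `"history"`, `"no_history"` or `"both"`.
#' The filter is attached to the group *slot*, not the participant: under
#' permutation a reassigned participant contributes the trials of its new
#' slot, which is what makes e.g. a history-first versus history-last
#' comparison exchangeable under the null.
#'
#' @param group1,group2 character vectors of participant ids.
#' @param conditions length-2 character vector of per-slot condition
#'   filters (default both slots use all trials).
#' @return object of class `group_assignment` with `group1`, `group2`,
#'   `conditions`, `n1`, `n2`.
#' @export
group_assignment <- function(group1, group2, conditions = c("both", "both")) {
  group1 <- as.character(group1); group2 <- as.character(group2)
  if (!length(group1) || !length(group2)) stop("both groups must be non-empty")
  if (length(intersect(group1, group2))) stop("groups must be disjoint")
  conditions <- match.arg(conditions, c("both", CONDITIONS), several.ok = TRUE)
  if (length(conditions) != 2L) stop("conditions must have length 2")
  structure(list(group1 = group1, group2 = group2, conditions = conditions,
                 n1 = length(group1), n2 = length(group2)),
            class = "group_assignment")
}

# Per-participant transition profiles on one stimulus under one AOI scheme.
# Returns the observed (from, to) pair support and, per condition slot
# ("history", "no_history", "both"), a participants x pairs count matrix.
# Restricting to pairs observed anywhere is exact: pairs absent from both
# groups contribute nothing to the Hellinger sum.
participant_profiles <- function(dataset, aois, stimulus) {
  stopifnot(inherits(dataset, "study_dataset"), inherits(aois, "aoi_set"))
  fx <- dataset$fixations
  fx <- fx[fx$stimulus == stimulus, , drop = FALSE]
  if (!nrow(fx)) stop("no fixations for stimulus '", stimulus, "'")
  lab <- assign_fixations(fx, aois)
  trial <- paste(fx$participant, fx$condition, sep = "\r")
  n <- nrow(fx)
  keep <- c(trial[-n] == trial[-1L])            # consecutive pairs, same trial
  from <- lab[-n][keep]; to <- lab[-1L][keep]
  part <- fx$participant[-n][keep]
  cond <- fx$condition[-n][keep]
  pair <- paste0(from, "->", to)
  support <- sort(unique(pair))
  parts <- sort(unique(fx$participant))
  idx <- function(sel) {
    m <- matrix(0, length(parts), length(support),
                dimnames = list(parts, support))
    if (any(sel)) {
      t3 <- table(factor(part[sel], levels = parts),
                  factor(pair[sel], levels = support))
      m <- m + unclass(t3)
    }
    m
  }
  list(support = support, participants = parts,
       counts = list(history = idx(cond == "history"),
                     no_history = idx(cond == "no_history"),
                     both = idx(rep(TRUE, length(cond)))))
}

.group_vector <- function(profiles, ids, slot_condition, which_group) {
  m <- profiles$counts[[slot_condition]]
  ids <- intersect(ids, profiles$participants)
  v <- if (length(ids)) colSums(m[ids, , drop = FALSE]) else
    numeric(length(profiles$support))
  if (sum(v) == 0) {
    stop("inference error: group ", which_group,
         " contributes zero transitions")
  }
  v
}

#' Observed Hellinger distance between two participant groups
#'
#' Each group's scanpaths on the stimulus (after the group's condition
#' filter) are pooled into one transition count matrix, normalised into the
#' joint distribution over directed AOI pairs, and compared with
#' [hellinger()].
#'
#' @param dataset a [study_dataset()].
#' @param groups a [group_assignment()].
#' @param aois an `aoi_set`.
#' @param stimulus stimulus id.
#' @return the observed distance Hd in \[0, 1\].
#' @export
observed_distance <- function(dataset, groups, aois, stimulus) {
  pr <- participant_profiles(dataset, aois, stimulus)
  v1 <- .group_vector(pr, groups$group1, groups$conditions[1], 1L)
  v2 <- .group_vector(pr, groups$group2, groups$conditions[2], 2L)
  hellinger(v1 / sum(v1), v2 / sum(v2))
}

# Hellinger distances for many group-1 indicator columns at once, via the
# Bhattacharyya coefficient: H = sqrt(1 - sum_i sqrt(p_i q_i)).
.hellinger_batch <- function(A, B, ind) {
  c1 <- t(A) %*% ind          # pairs x n_perm
  c2 <- t(B) %*% (1 - ind)
  t1 <- colSums(c1); t2 <- colSums(c2)
  if (any(t1 == 0) || any(t2 == 0)) {
    stop("inference error: a permuted group contributes zero transitions")
  }
  bc <- colSums(sqrt(sweep(c1, 2, t1, "/") * sweep(c2, 2, t2, "/")))
  sqrt(pmax(0, 1 - bc))
}

#' Permutation null distribution of the Hellinger distance
#'
#' Participants from both groups are pooled and reassigned uniformly at
#' random into groups of the original sizes (n1, n2); for each of the
#' `n_perm` reassignments the group distance is recomputed exactly as for
#' the observed split. Reproducible for a fixed seed.
#'
#' @inheritParams observed_distance
#' @param n_perm number of shuffles (>= 1).
#' @param seed integer seed for the shuffling RNG.
#' @return numeric vector of `n_perm` null distances.
#' @export
permutation_null <- function(dataset, groups, aois, stimulus, n_perm, seed) {
  stopifnot(n_perm >= 1)
  pr <- participant_profiles(dataset, aois, stimulus)
  pool <- c(groups$group1, groups$group2)
  if (length(pool) < 2L || choose(length(pool), groups$n1) < 2) {
    stop("inference error: fewer than two distinct reassignments")
  }
  A <- pr$counts[[groups$conditions[1]]]
  B <- pr$counts[[groups$conditions[2]]]
  pool <- intersect(pool, pr$participants)
  A <- A[pool, , drop = FALSE]; B <- B[pool, , drop = FALSE]
  n <- length(pool)
  with_seed(seed, {
    out <- numeric(n_perm)
    chunk <- 200L
    done <- 0L
    while (done < n_perm) {
      m <- min(chunk, n_perm - done)
      ind <- matrix(0, n, m)
      for (j in seq_len(m)) ind[sample.int(n, groups$n1), j] <- 1
      out[done + seq_len(m)] <- .hellinger_batch(A, B, ind)
      done <- done + m
    }
    out
  })
}

#' Permutation test of a group difference in transition behaviour
#'
#' Combines [observed_distance()] with [permutation_null()] and summarises
#' the null: `M` and `SD` are the null mean and standard deviation, `d` is
#' the null-standardised deviation `(Hd - M) / SD` (0 when SD = 0 and
#' Hd = M), and the empirical p-value uses the add-one rule
#' `p = (1 + #\{null >= Hd\}) / (1 + n_perm)`, which never reaches zero —
#' the floor at 10,000 shuffles is 1/10,001, reported as "p < 0.001".
#'
#' @inheritParams permutation_null
#' @return object of class `permutation_result`: `observed_hd`, `null_mean`,
#'   `null_sd`, `d`, `p_value`, `n_permutations`, `seed`, `scheme`,
#'   `stimulus_id`, `n1`, `n2`, and the raw `null` values.
#' @export
permutation_test <- function(dataset, groups, aois, stimulus,
                             n_perm = 10000L, seed = 1L) {
  obs <- observed_distance(dataset, groups, aois, stimulus)
  null <- permutation_null(dataset, groups, aois, stimulus, n_perm, seed)
  M <- mean(null)
  SD <- stats::sd(null)
  if (n_perm == 1L) SD <- 0
  d <- if (SD > 0) (obs - M) / SD else if (isTRUE(all.equal(obs, M))) 0 else
    sign(obs - M) * Inf
  p <- (1 + sum(null >= obs - 1e-12)) / (1 + n_perm)
  structure(list(observed_hd = obs, null_mean = M, null_sd = SD, d = d,
                 p_value = p, n_permutations = as.integer(n_perm),
                 seed = as.integer(seed), scheme = aois$scheme,
                 stimulus_id = as.character(stimulus),
                 n1 = groups$n1, n2 = groups$n2, null = null),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Hellinger permutation test [%s AOIs, stimulus %s]\n", x$scheme,
    x$stimulus_id))
  cat(sprintf("  Hd = %.3f, null M (SD) = %.3f (%.3f), d = %.2f\n",
              x$observed_hd, x$null_mean, x$null_sd, x$d))
  pv <- if (x$p_value < 0.001) "< 0.001" else sprintf("= %.3f", x$p_value)
  cat(sprintf("  p %s (%d permutations, groups %d vs %d)\n", pv,
              x$n_permutations, x$n1, x$n2))
  invisible(x)
}

#' @export
as.data.frame.permutation_result <- function(x, ...) {
  data.frame(stimulus = x$stimulus_id, scheme = x$scheme, n1 = x$n1,
             n2 = x$n2, M = x$null_mean, SD = x$null_sd, d = x$d,
             Hd = x$observed_hd, p = x$p_value,
             n_perm = x$n_permutations, seed = x$seed)
}
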