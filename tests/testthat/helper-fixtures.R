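# Shared fixtures and independent oracles, all built in code.

# --- fixtures ---------------------------------------------------------------

# 100 x 100 canvas split into two vertical leads A | B
tiny_layout <- function(stimulus_id = "ecg1") {
  stimulus_layout(stimulus_id, 100, 100,
                  data.frame(name = c("A", "B"),
                             x0 = c(0, 50), y0 = c(0, 0),
                             x1 = c(50, 100), y1 = c(100, 100)))
}

fix_rows <- function(participant, stimulus, condition, order_group,
                     x, y, duration = 200) {
  n <- length(x)
  data.frame(participant = participant, stimulus = stimulus,
             condition = condition, order_group = order_group,
             fix_index = seq_len(n), x = x, y = y,
             duration_ms = rep_len(duration, n),
             onset_ms = cumsum(c(0, rep_len(duration, n)[-n] + 30)))
}

# two participants, one stimulus, both conditions, deterministic coordinates
tiny_dataset <- function() {
  fx <- rbind(
    fix_rows("p1", "ecg1", "history", "history_first", c(10, 60, 10), 50),
    fix_rows("p1", "ecg1", "no_history", "history_first", c(10, 10, 60), 50),
    fix_rows("p2", "ecg1", "history", "history_last", c(60, 60, 10), 50),
    fix_rows("p2", "ecg1", "no_history", "history_last", c(60, 10, 10), 50))
  study_dataset(fx)
}

# random but valid dataset for round-trip properties
random_dataset <- function(n_participants = 3, n_stimuli = 2, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_participants)) {
    for (s in seq_len(n_stimuli)) {
      for (cond in c("history", "no_history")) {
        n <- sample(2:6, 1)
        rows[[length(rows) + 1L]] <- fix_rows(
          sprintf("p%d", p), sprintf("ecg%d", s), cond,
          if (p %% 2 == 1) "history_first" else "history_last",
          x = round(runif(n, 0, 99.5), 2), y = round(runif(n, 0, 99.5), 2),
          duration = round(rlnorm(n, log(250), 0.3), 2))
      }
    }
  }
  study_dataset(do.call(rbind, rows))
}

# --- DBSCAN oracle ----------------------------------------------------------

# Literal density-reachability implementation: core points from closed
# eps-neighbourhood counts, clusters as connected components of the core
# graph, border points attached to any neighbouring core cluster.
oracle_dbscan <- function(points, eps, min_pts) {
  d <- as.matrix(stats::dist(points))
  n <- nrow(d)
  nb <- d <= eps + 1e-12
  core <- unname(rowSums(nb) >= min_pts)
  comp <- rep(NA_integer_, n)
  cl <- 0L
  for (i in which(core)) {
    if (!is.na(comp[i])) next
    cl <- cl + 1L
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- cl
      nxt <- which(core & is.na(comp) &
                     colSums(nb[frontier, , drop = FALSE]) > 0)
      frontier <- nxt
    }
  }
  border_choices <- lapply(seq_len(n), function(i) {
    if (core[i]) return(integer(0))
    unique(comp[which(nb[i, ] & core)])
  })
  noise <- !core & lengths(border_choices) == 0L
  list(core = core, comp = comp, border_choices = border_choices,
       noise = noise)
}

# Check a cluster_result against the oracle: noise sets agree, core points
# partition identically (up to relabeling), and each border point sits in a
# cluster that one of its eps-neighbouring core points belongs to.
expect_dbscan_agrees <- function(points, eps, min_pts) {
  res <- dbscan_cluster(points, eps, min_pts)
  ora <- oracle_dbscan(points, eps, min_pts)
  expect_identical(res$labels == 0L, ora$noise)
  # core partition equal up to renaming
  core_idx <- which(ora$core)
  expect_true(all(res$labels[core_idx] > 0L))
  map <- tapply(ora$comp[core_idx], res$labels[core_idx],
                function(v) length(unique(v)))
  expect_true(all(map == 1L))
  map2 <- tapply(res$labels[core_idx], ora$comp[core_idx],
                 function(v) length(unique(v)))
  expect_true(all(map2 == 1L))
  # border points: claimed cluster must be one of the reachable clusters
  borders <- which(!ora$core & !ora$noise)
  for (i in borders) {
    allowed <- ora$border_choices[[i]]
    allowed_res <- unique(res$labels[core_idx][ora$comp[core_idx] %in% allowed])
    expect_true(res$labels[i] %in% allowed_res)
  }
  invisible(res)
}

# --- Wilcoxon enumeration oracle -------------------------------------------

# Exact two-sided p by enumerating all 2^n sign patterns on the observed
# absolute differences (valid with or without ties).
oracle_signed_rank <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  p_ge <- mean(Vs >= V_obs - 1e-12)
  p_le <- mean(Vs <= V_obs + 1e-12)
  list(V = V_obs, p = min(1, 2 * min(p_ge, p_le)))
}
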