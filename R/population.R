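#' Hierarchy formation
#'
#' `form_hierarchy_earned()` ranks players by descending skill score (the
#' abstract stand-in for the ranking tasks), breaking ties at random;
#' `form_hierarchy_random()` assigns ranks as a uniform random permutation.
#' Rank 1 is the top of the hierarchy. Both draw from the current RNG
#' state; seed the caller for reproducibility.
#'
#' @param skill_scores Numeric vector, one score per player.
#' @param group_size Number of players.
#' @return A `hierarchy` list: `ranks` (integer vector, `ranks[i]` is the
#'   rank of player `i`), `origin`.
#' @examples
#' set.seed(7)
#' form_hierarchy_earned(c(5, 9, 1))$ranks  # 2 1 3
#' @export
form_hierarchy_earned <- function(skill_scores) {
  n <- length(skill_scores)
  if (n < 2L || anyNA(skill_scores)) {
    stop("`skill_scores` must give one numeric score per player", call. = FALSE)
  }
  # random tie-break via a jittered secondary key
  ord <- order(-skill_scores, stats::runif(n))
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  structure(list(ranks = ranks, origin = "earned"), class = "hierarchy")
}

#' @rdname form_hierarchy_earned
#' @export
form_hierarchy_random <- function(group_size) {
  stopifnot(group_size >= 2L)
  structure(list(ranks = sample.int(group_size), origin = "random"),
            class = "hierarchy")
}

#' Round-robin schedule (circle method)
#'
#' Builds the 1-factorization of the complete graph on an even number of
#' players: `group_size - 1` rounds of `group_size / 2` simultaneous dyads,
#' with every unordered pair meeting exactly once.
#'
#' @param group_size Even number of players.
#' @return List of rounds; each round is a two-column integer matrix of
#'   player indices (one row per dyad).
#' @examples
#' sched <- round_robin_schedule(4)
#' length(sched)  # 3 rounds
#' @export
round_robin_schedule <- function(group_size) {
  n <- as.integer(group_size)
  if (n < 2L || n %% 2L != 0L) {
    stop("`group_size` must be an even integer >= 2", call. = FALSE)
  }
  # player n is the fixed pivot; the others rotate around the circle
  rot <- seq_len(n - 1L)
  lapply(seq_len(n - 1L), function(r) {
    idx <- c(rot[r:(n - 1L)], rot[seq_len(r - 1L)])  # rotation r - 1
    pairs <- rbind(
      c(idx[1L], n),
      if (n > 2L) cbind(idx[2L:(n %/% 2L)], rev(idx)[seq_len(n %/% 2L - 1L)])
    )
    storage.mode(pairs) <- "integer"
    colnames(pairs) <- c("a", "b")
    pairs
  })
}
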