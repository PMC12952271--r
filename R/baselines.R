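#' Constrained stochastic local search baseline
#'
#' Hill-climbing comparator: each run starts from the wild type and, at
#' every step, samples a subset of the single-mutation neighborhood within
#' `d_lim`, discards moves violating any hard constraint, and takes the
#' best strictly improving move (staying put if none improves; equal-value
#' moves are rejected to prevent cycles). The final state of each run is
#' returned, so the objective value is non-decreasing along every
#' trajectory.
#'
#' @param objective Function `sequence -> real` to maximize (typically the
#'   affinity acquisition). May be vectorized over a character vector;
#'   vectorized objectives are evaluated once per proposal batch.
#' @param wt Wild type (must satisfy all constraints).
#' @param constraints List of predicate functions `sequence -> logical`
#'   acting as hard feasibility filters (e.g. humanness or solubility
#'   thresholds). The `d_lim` ball is always enforced.
#' @param n_runs Number of independent runs (reference protocol: 800).
#' @param n_steps Steps per run (reference protocol: 200).
#' @param d_lim Mutation constraint.
#' @param subset_size Number of neighbors sampled per step.
#' @param seed Integer seed.
#' @param alphabet Alphabet.
#' @return Data frame with columns `sequence`, `objective` (one row per
#'   run; duplicates possible).
#' @export
local_search <- function(objective, wt, constraints = list(),
                         n_runs = 800L, n_steps = 200L, d_lim = 6L,
                         subset_size = 50L, seed = 1L,
                         alphabet = aa_alphabet()) {
  wt <- as_wt(wt)
  sc <- search_constraints(d_lim, alphabet)
  feasible <- function(s) all(vapply(constraints, function(f) isTRUE(f(s)),
                                     logical(1)))
  if (!feasible(wt$sequence))
    stop("wild type violates a constraint", call. = FALSE)
  seeds <- derive_seeds(seed, n_runs)
  eval_obj <- function(seqs) {
    v <- objective(seqs)
    if (length(v) == length(seqs)) as.numeric(v)
    else vapply(seqs, function(s) as.numeric(objective(s)), numeric(1))
  }
  res <- lapply(seq_len(n_runs), function(r) with_seed(seeds[r], {
    cur <- wt$sequence
    cur_val <- eval_obj(cur)
    for (s in seq_len(n_steps)) {
      props <- unique(vapply(seq_len(subset_size), function(i)
        random_neighbor(cur, wt, sc), character(1)))
      props <- props[vapply(props, feasible, logical(1))]
      if (!length(props)) next
      vals <- eval_obj(props)
      best <- which.max(vals)
      if (vals[best] > cur_val) {
        cur <- props[best]
        cur_val <- vals[best]
      }
    }
    c(cur, cur_val)
  }))
  data.frame(sequence = vapply(res, `[`, character(1), 1L),
             objective = as.numeric(vapply(res, `[`, character(1), 2L)),
             stringsAsFactors = FALSE)
}

#' Random-mutant negative control
#'
#' Starting from a given (typically best-in-training) sequence, each output
#' mutates exactly `k` positions that are not already mutated relative to
#' the wild type, with substitutions drawn uniformly from the 19
#' alternatives to the current letter.
#'
#' @param best Starting sequence.
#' @param wt Wild type.
#' @param n Number of mutants (default 500).
#' @param k Number of fresh mutations per mutant (default 3).
#' @param seed Integer seed.
#' @param alphabet Alphabet.
#' @return Character vector of `n` sequences, each at Hamming distance
#'   exactly `k` from `best` at previously unmutated positions.
#' @export
random_mutants <- function(best, wt, n = 500L, k = 3L, seed = 1L,
                           alphabet = aa_alphabet()) {
  wt <- as_wt(wt)
  ch <- seq_chars(best)
  free <- which(ch == wt$chars)
  if (length(free) < k)
    stop("fewer than ", k, " unmutated positions available", call. = FALSE)
  with_seed(seed, vapply(seq_len(n), function(i) {
    pos <- if (length(free) == 1L) free else free[sample.int(length(free), k)]
    new <- ch
    for (p in pos) {
      alt <- alphabet[alphabet != ch[p]]
      new[p] <- alt[sample.int(length(alt), 1L)]
    }
    paste(new, collapse = "")
  }, character(1)))
}
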