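#' Pareto front of a two-objective point set
#'
#' Non-dominated subset under joint maximization of both coordinates: a
#' point is dominated if some other point is at least as good in both
#' objectives and strictly better in one. Duplicate coordinate pairs on the
#' front are all retained (they do not dominate each other).
#'
#' @param aff,sol Numeric objective vectors (affinity acquisition,
#'   solubility), equal length >= 1.
#' @return Integer indices of front members (increasing order).
#' @export
pareto_front <- function(aff, sol) {
  stopifnot(length(aff) == length(sol), length(aff) >= 1L,
            all(is.finite(aff)), all(is.finite(sol)))
  ord <- order(-aff, -sol)
  keep <- logical(length(aff))
  best_sol <- -Inf
  i <- 1L
  while (i <= length(ord)) {
    # group of equal-affinity points
    j <- i
    while (j < length(ord) && aff[ord[j + 1L]] == aff[ord[i]]) j <- j + 1L
    grp <- ord[i:j]
    gmax <- sol[grp[1L]]  # groups sorted by sol desc
    if (gmax > best_sol) {
      keep[grp[sol[grp] == gmax]] <- TRUE
      best_sol <- gmax
    }
    i <- j + 1L
  }
  which(keep)
}

#' Scored candidate set with Pareto annotations
#'
#' Computes, for a pool of generated sequences in (acquisition, solubility)
#' space: the de-duplicated point set, the objective variances over the
#' full pool (the normalizers of the front distance), the Pareto front,
#' and the distance to the front `d_P` for every member.
#'
#' @param sequences Character vector.
#' @param aff Acquisition values `f_aff(x; beta)`.
#' @param sol Solubility scores `f_sol(x)`.
#' @param convention `"root"` (default; `d_P` in units of normalized
#'   objective space) or `"squared"` for the raw minimized expression.
#' @return Object of class `candidate_set`: a data frame with columns
#'   `sequence`, `aff`, `sol`, `on_front`, `d_P`, plus attributes
#'   `sigma_aff2`, `sigma_sol2`, `front` (indices), `convention`.
#' @export
candidate_set <- function(sequences, aff, sol,
                          convention = c("root", "squared")) {
  convention <- match.arg(convention)
  stopifnot(length(sequences) == length(aff), length(aff) == length(sol))
  dup <- duplicated(sequences)
  df <- data.frame(sequence = sequences[!dup], aff = aff[!dup],
                   sol = sol[!dup], stringsAsFactors = FALSE)
  s_aff2 <- stats::var(df$aff)
  s_sol2 <- stats::var(df$sol)
  front <- pareto_front(df$aff, df$sol)
  df$on_front <- seq_len(nrow(df)) %in% front
  df$d_P <- pareto_distance(df$aff, df$sol, df$aff[front], df$sol[front],
                            s_aff2, s_sol2, convention)
  structure(df, class = c("candidate_set", "data.frame"),
            sigma_aff2 = s_aff2, sigma_sol2 = s_sol2, front = front,
            convention = convention)
}

#' Variance-normalized distance to the Pareto front
#'
#' `d_P(x) = min over front members of
#' (f_aff(x) - f_aff(x'))^2 / sigma_aff^2 +
#' (f_sol(x) - f_sol(x'))^2 / sigma_sol^2`, with the square root taken
#' under the default `"root"` convention. Zero for front members; errors if
#' a normalizing variance is zero (degenerate objective).
#'
#' @param aff,sol Query coordinates (vectors).
#' @param front_aff,front_sol Coordinates of the front members.
#' @param sigma_aff2,sigma_sol2 Normalization variances (> 0), computed
#'   over the full generated pool before any filtering.
#' @param convention `"root"` or `"squared"`.
#' @return Numeric vector of distances, `>= 0`.
#' @export
pareto_distance <- function(aff, sol, front_aff, front_sol,
                            sigma_aff2, sigma_sol2,
                            convention = c("root", "squared")) {
  convention <- match.arg(convention)
  if (length(front_aff) == 0L) stop("front is empty", call. = FALSE)
  if (!is.finite(sigma_aff2) || sigma_aff2 <= 0)
    stop("degenerate affinity variance", call. = FALSE)
  if (!is.finite(sigma_sol2) || sigma_sol2 <= 0)
    stop("degenerate solubility variance", call. = FALSE)
  d <- vapply(seq_along(aff), function(i)
    min((aff[i] - front_aff)^2 / sigma_aff2 +
          (sol[i] - front_sol)^2 / sigma_sol2), numeric(1))
  if (convention == "root") sqrt(d) else d
}

#' Select the top-B candidates by distance to the front
#'
#' The `B` sequences with smallest `d_P`; ties are broken lexicographically
#' by sequence so selection is deterministic.
#'
#' @param cs A [candidate_set()].
#' @param B Number of sequences to keep, `<= nrow(cs)`.
#' @return Data frame of the selected rows, ordered by `d_P`.
#' @export
select_top <- function(cs, B) {
  stopifnot(inherits(cs, "candidate_set"))
  if (B > nrow(cs))
    stop("B exceeds the number of distinct candidates", call. = FALSE)
  ord <- order(cs$d_P, cs$sequence)
  out <- cs[ord[seq_len(B)], ]
  rownames(out) <- NULL
  out
}

#' Threshold-count evaluation against ground truth
#'
#' The synthetic benchmark protocol: keep candidates with predicted
#' solubility strictly above `f_sol_min`, rank the survivors by predicted
#' affinity (acquisition), truncate to the experimental budget `B`,
#' evaluate the true landscape affinity of the kept sequences, and count
#' how many exceed each threshold of `f_aff_grid`. Counts are monotone
#' non-increasing along an increasing grid.
#'
#' @param candidates Data frame with columns `sequence`, `aff` (predicted
#'   acquisition) and `sol` (predicted solubility), e.g. a
#'   [candidate_set()].
#' @param truth An [sample_landscape()] object, or a function
#'   `sequences -> numeric` of true affinities.
#' @param f_sol_min Solubility filter threshold (`-Inf` disables it).
#' @param B Budget of sequences kept (default 500). If fewer survive the
#'   filter, all survivors are evaluated and `shortfall` is flagged.
#' @param f_aff_grid Increasing vector of affinity thresholds.
#' @return List with `counts` data frame (`threshold`, `count`), `n_kept`,
#'   `shortfall`, and `kept` (the evaluated data frame with `true_faff`).
#' @export
threshold_count_eval <- function(candidates, truth, f_sol_min = -Inf,
                                 B = 500L, f_aff_grid = seq(-1, 3, by = 0.5)) {
  truth_fn <- if (inherits(truth, "epistasis_landscape"))
    function(s) evaluate_landscape(truth, s) else truth
  surv <- candidates[candidates$sol > f_sol_min, , drop = FALSE]
  shortfall <- nrow(surv) < B
  if (shortfall)
    warning("only ", nrow(surv), " candidates survive the solubility filter",
            " (budget ", B, ")")
  keep <- surv[order(-surv$aff, surv$sequence), , drop = FALSE]
  keep <- keep[seq_len(min(B, nrow(keep))), , drop = FALSE]
  keep$true_faff <- if (nrow(keep)) truth_fn(keep$sequence) else numeric(0)
  counts <- vapply(f_aff_grid, function(th) sum(keep$true_faff > th),
                   numeric(1))
  list(counts = data.frame(threshold = f_aff_grid, count = counts),
       n_kept = nrow(keep), shortfall = shortfall, kept = keep)
}

#' Write a candidate report CSV
#'
#' @param cs A [candidate_set()].
#' @param path Output path.
#' @return Invisibly, `path`. Columns: sequence, aff, sol, d_P, rank,
#'   on_front.
#' @export
write_candidates_csv <- function(cs, path) {
  ord <- order(cs$d_P, cs$sequence)
  out <- cs[ord, c("sequence", "aff", "sol", "d_P", "on_front")]
  out$rank <- seq_len(nrow(out))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
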