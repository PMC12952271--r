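#' MCMC configuration
#'
#' Defaults follow the reference protocol: 8 parallel chains of 20,000
#' steps over the 6-mutation neighborhood, Gelman-Rubin burn-in threshold
#' 1.1, and 20,000-step extensions until convergence.
#'
#' @param n_chains Number of independent chains.
#' @param n_steps Steps per chain.
#' @param d_lim Maximum mutations from the wild type.
#' @param gr_threshold Gelman-Rubin convergence threshold.
#' @param extension_steps Steps added per extension round.
#' @param max_extensions Safety cap on extension rounds.
#' @param seed Master seed; per-chain streams are derived from it.
#' @param hastings Apply the proposal correction for the shrinking boundary
#'   neighborhood (exact stationarity). `FALSE` gives the plain
#'   `min(1, p(x')/p(x))` ratio for protocol-faithful replication.
#' @param alphabet Proposal alphabet (reduced alphabets supported for toy
#'   spaces).
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 8L, n_steps = 20000L, d_lim = 6L,
                        gr_threshold = 1.1, extension_steps = 20000L,
                        max_extensions = 5L, seed = 1L, hastings = TRUE,
                        alphabet = aa_alphabet()) {
  stopifnot(n_chains >= 1L, n_steps >= 1L, d_lim >= 1L, gr_threshold > 1,
            extension_steps >= 1L)
  structure(list(n_chains = as.integer(n_chains),
                 n_steps = as.integer(n_steps), d_lim = as.integer(d_lim),
                 gr_threshold = gr_threshold,
                 extension_steps = as.integer(extension_steps),
                 max_extensions = as.integer(max_extensions),
                 seed = as.integer(seed), hastings = hastings,
                 alphabet = alphabet),
            class = "mcmc_config")
}

#' Single Metropolis-Hastings step
#'
#' Proposes a uniform draw from the constrained single-mutation neighborhood
#' and accepts with probability `min(1, exp(delta_logp + hastings_term))`,
#' where the optional Hastings term `log|N(x)| - log|N(x')|` corrects for
#' the neighborhood shrinking at the distance boundary.
#'
#' @param state List with `sequence` and `logp` (its log unnormalized
#'   density), e.g. from a previous call.
#' @param target An [energy_model()].
#' @param wt Wild type.
#' @param constraints A [search_constraints()].
#' @param hastings Apply the boundary proposal correction.
#' @return Updated state list with fields `sequence`, `logp`, `accepted`.
#'   Uses the current RNG stream.
#' @export
mh_step <- function(state, target, wt, constraints = search_constraints(),
                    hastings = TRUE) {
  prop <- random_neighbor(state$sequence, wt, constraints)
  logp_prop <- log_unnorm_density(target, prop)
  log_r <- logp_prop - state$logp
  if (hastings) {
    log_r <- log_r + log(neighborhood_size(state$sequence, wt, constraints)) -
      log(neighborhood_size(prop, wt, constraints))
  }
  if (log_r >= 0 || log(stats::runif(1)) < log_r) {
    list(sequence = prop, logp = logp_prop, accepted = TRUE)
  } else {
    list(sequence = state$sequence, logp = state$logp, accepted = FALSE)
  }
}

run_one_chain <- function(target, wt, constraints, n_steps, start, hastings) {
  seqs <- character(n_steps)
  logp <- numeric(n_steps)
  acc <- logical(n_steps)
  state <- list(sequence = start,
                logp = log_unnorm_density(target, start))
  for (s in seq_len(n_steps)) {
    state <- mh_step(state, target, wt, constraints, hastings)
    seqs[s] <- state$sequence
    logp[s] <- state$logp
    acc[s] <- state$accepted
  }
  data.frame(step = seq_len(n_steps), sequence = seqs, log_density = logp,
             accepted = acc, stringsAsFactors = FALSE)
}

#' Run parallel MCMC chains
#'
#' All chains start from the wild type and evolve under independently
#' seeded RNG streams derived from the master seed, so results are exactly
#' reproducible. Traces record the sequence, log unnormalized density and
#' acceptance flag at every step.
#'
#' @param target An [energy_model()].
#' @param wt Wild type.
#' @param cfg An [mcmc_config()].
#' @param init Optional list of per-chain starting states (sequences) for
#'   extension runs; defaults to the wild type.
#' @param stream_offset Internal offset so extension rounds draw fresh
#'   per-chain streams.
#' @return Object of class `mcmc_chains`: a list of per-chain trace data
#'   frames with the config as attribute.
#' @export
run_chains <- function(target, wt, cfg = mcmc_config(), init = NULL,
                       stream_offset = 0L) {
  wt <- as_wt(wt)
  constraints <- search_constraints(cfg$d_lim, cfg$alphabet)
  seeds <- derive_seeds(cfg$seed + stream_offset, cfg$n_chains)
  chains <- lapply(seq_len(cfg$n_chains), function(ci) {
    start <- if (is.null(init)) wt$sequence else init[[ci]]
    with_seed(seeds[ci],
              run_one_chain(target, wt, constraints, cfg$n_steps, start,
                            cfg$hastings))
  })
  structure(chains, class = "mcmc_chains", config = cfg)
}

#' Gelman-Rubin potential scale reduction statistic
#'
#' Ratio of pooled-to-within-chain variance on a monitored scalar; values
#' near 1 indicate convergence. If every chain has zero internal variance
#' the statistic is reported as 1.0 with a degenerate-trace warning (equal
#' constant chains) or `Inf` (separated constant chains).
#'
#' @param traces Numeric matrix (rows = iterations, columns = chains) or a
#'   list of equal-length numeric vectors.
#' @return Scalar statistic, approximately `>= 1`.
#' @export
gelman_rubin <- function(traces) {
  if (is.list(traces)) traces <- do.call(cbind, traces)
  m <- ncol(traces); n <- nrow(traces)
  if (m < 2L || n < 2L)
    stop("gelman_rubin needs >= 2 chains of length >= 2", call. = FALSE)
  means <- colMeans(traces)
  vars <- apply(traces, 2L, stats::var)
  W <- mean(vars)
  B_over_n <- stats::var(means)
  if (W == 0) {
    if (B_over_n == 0) {
      warning("degenerate traces: all chains constant and identical")
      return(1.0)
    }
    return(Inf)
  }
  V_hat <- (n - 1) / n * W + B_over_n
  sqrt(V_hat / W)
}

#' Select a burn-in index from multi-chain traces
#'
#' Scans candidate burn-in lengths on a grid (every 5% of the trace) and
#' returns the smallest one at which the Gelman-Rubin statistic of the
#' monitored log-density drops below the threshold. If none qualifies, the
#' grid point with the smallest statistic is returned with
#' `converged = FALSE`, signalling the driver to extend the chains.
#'
#' @param chains An `mcmc_chains` object from [run_chains()].
#' @param cfg An [mcmc_config()] (for the threshold).
#' @param grid_frac Grid spacing as a fraction of the trace length.
#' @return List with `burnin`, `converged`, `grid`, `stats`.
#' @export
select_burnin <- function(chains, cfg = attr(chains, "config"),
                          grid_frac = 0.05) {
  logd <- vapply(chains, function(ch) ch$log_density,
                 numeric(nrow(chains[[1L]])))
  n <- nrow(logd)
  grid <- unique(floor(seq(0, 0.95 * n, by = max(1, grid_frac * n))))
  stats_ <- vapply(grid, function(b) {
    suppressWarnings(gelman_rubin(logd[(b + 1L):n, , drop = FALSE]))
  }, numeric(1))
  ok <- which(is.finite(stats_) & stats_ < cfg$gr_threshold)
  if (length(ok)) {
    list(burnin = grid[ok[1L]], converged = TRUE, grid = grid, stats = stats_)
  } else {
    best <- which.min(replace(stats_, !is.finite(stats_), Inf))
    list(burnin = grid[best], converged = FALSE, grid = grid, stats = stats_)
  }
}

#' Sample from the Boltzmann target with burn-in selection
#'
#' Driver implementing the full protocol: run `n_chains` chains, pick a
#' burn-in via [select_burnin()], and if the Gelman-Rubin criterion is not
#' met extend every chain by `extension_steps` (continuing from its final
#' state, fresh derived streams) up to `max_extensions` times. Post-burn-in
#' samples from all chains are pooled.
#'
#' @inheritParams run_chains
#' @return List with `samples` (pooled post-burn-in data frame: `sequence`,
#'   `log_density`), `chains`, `burnin`, `converged`, `total_steps`,
#'   `acceptance_rate`.
#' @export
mcmc_sample <- function(target, wt, cfg = mcmc_config()) {
  chains <- run_chains(target, wt, cfg)
  sel <- select_burnin(chains, cfg)
  round <- 0L
  while (!sel$converged && round < cfg$max_extensions) {
    round <- round + 1L
    last <- lapply(chains, function(ch) ch$sequence[nrow(ch)])
    ext_cfg <- cfg
    ext_cfg$n_steps <- cfg$extension_steps
    ext <- run_chains(target, wt, ext_cfg, init = last,
                      stream_offset = round * 1000003L)
    chains <- structure(Map(function(a, b) {
      b$step <- b$step + nrow(a)
      rbind(a, b)
    }, chains, ext), class = "mcmc_chains", config = cfg)
    sel <- select_burnin(chains, cfg)
  }
  pooled <- do.call(rbind, lapply(chains, function(ch)
    ch[ch$step > sel$burnin, c("sequence", "log_density")]))
  rownames(pooled) <- NULL
  list(samples = pooled, chains = chains, burnin = sel$burnin,
       converged = sel$converged, total_steps = nrow(chains[[1L]]),
       acceptance_rate = mean(vapply(chains, function(ch) mean(ch$accepted),
                                     numeric(1))))
}

#' Write per-chain traces and a run manifest
#'
#' @param result Output of [mcmc_sample()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`. One CSV per chain plus `manifest.json`.
#' @export
write_mcmc_traces <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- attr(result$chains, "config")
  for (i in seq_along(result$chains))
    utils::write.csv(result$chains[[i]],
                     file.path(dir, sprintf("chain_%02d.csv", i)),
                     row.names = FALSE)
  manifest <- list(config = unclass(cfg), burnin = result$burnin,
                   converged = result$converged,
                   total_steps = result$total_steps,
                   acceptance_rate = result$acceptance_rate)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
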