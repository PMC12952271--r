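#' Autoregressive GFlowNet policy
#'
#' Sequences are built left to right; at each position the policy emits a
#' categorical distribution over the alphabet, conditioned on the prefix.
#' The number of mutations accumulated so far relative to the wild-type
#' prefix (Levenshtein distance, which for equal-length prefixes equals the
#' Hamming distance) drives a hard mask: once `d_lim` mutations have been
#' spent, only the wild-type letter remains available, so the policy places
#' zero probability mass outside the `d_lim` ball by construction.
#'
#' Two desk-scale parameterizations are provided:
#' * `"tabular"` -- one logit vector per (position, prefix) context; fully
#'   expressive on enumerable spaces (the test and validation policy);
#' * `"linear"` -- per-position logits plus a linear term in the
#'   mutation-count feature `n`, a compact analogue of the convolutional
#'   policy used at production scale.
#'
#' @param wt Wild type ([wildtype()] or string).
#' @param d_lim Maximum mutations from the wild type.
#' @param alphabet Amino-acid alphabet (tests may use reduced alphabets).
#' @param type `"tabular"` or `"linear"`.
#' @return Object of class `gfn_policy`.
#' @export
gfn_policy <- function(wt, d_lim = 6L, alphabet = aa_alphabet(),
                       type = c("tabular", "linear")) {
  type <- match.arg(type)
  wt <- as_wt(wt)
  if (!all(wt$chars %in% alphabet))
    stop("wild type contains letters outside the alphabet", call. = FALSE)
  a <- length(alphabet)
  pol <- list(wt = wt, d_lim = as.integer(d_lim), alphabet = alphabet,
              type = type)
  if (type == "tabular") {
    pol$logits <- new.env(parent = emptyenv())
  } else {
    pol$base <- matrix(0, wt$L, a)
    pol$wn <- matrix(0, wt$L, a)
  }
  structure(pol, class = "gfn_policy")
}

# Raw logits at position i given the prefix (character vector) and the
# mutation count n accumulated so far.
policy_logits <- function(pol, i, prefix, n) {
  if (pol$type == "tabular") {
    key <- paste0(i, "|", paste(prefix, collapse = ""))
    if (exists(key, pol$logits, inherits = FALSE))
      get(key, pol$logits, inherits = FALSE)
    else numeric(length(pol$alphabet))
  } else {
    pol$base[i, ] + n * pol$wn[i, ]
  }
}

# Indices of letters allowed at position i given n mutations already spent.
allowed_letters <- function(pol, i, n) {
  if (n >= pol$d_lim) match(pol$wt$chars[i], pol$alphabet)
  else seq_along(pol$alphabet)
}

masked_probs <- function(logits, allowed) {
  z <- logits[allowed]
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Walk a sequence through the policy: returns total log-probability and,
# optionally, the per-position contexts needed for gradient accumulation.
policy_walk <- function(pol, x, keep_ctx = FALSE) {
  ch <- seq_chars(x)
  L <- pol$wt$L
  if (length(ch) != L) stop("sequence length mismatch", call. = FALSE)
  n <- 0L
  logp <- 0
  tok <- numeric(L)
  ctx <- if (keep_ctx) vector("list", L) else NULL
  for (i in seq_len(L)) {
    allowed <- allowed_letters(pol, i, n)
    j <- match(ch[i], pol$alphabet)
    pos <- match(j, allowed)
    if (is.na(pos)) return(list(logp = -Inf, per_token = tok, ctx = ctx))
    p <- masked_probs(policy_logits(pol, i, ch[seq_len(i - 1L)], n), allowed)
    tok[i] <- log(p[pos])
    logp <- logp + tok[i]
    if (keep_ctx)
      ctx[[i]] <- list(i = i, prefix = ch[seq_len(i - 1L)], n = n,
                       allowed = allowed, probs = p, chosen = pos)
    if (ch[i] != pol$wt$chars[i]) n <- n + 1L
  }
  list(logp = logp, per_token = tok, ctx = ctx)
}

#' Sample sequences from a policy
#'
#' Builds `n` sequences left to right under the mask; no sampled sequence
#' can exceed `d_lim` mutations.
#'
#' @param pol A [gfn_policy()].
#' @param n Number of sequences.
#' @return List with `sequences` and `logp` (policy log-probabilities; each
#'   equals the sum of its per-token conditionals). Uses the current RNG
#'   stream.
#' @export
policy_sample <- function(pol, n) {
  L <- pol$wt$L
  seqs <- character(n)
  logp <- numeric(n)
  for (s in seq_len(n)) {
    ch <- character(L)
    nm <- 0L
    lp <- 0
    for (i in seq_len(L)) {
      allowed <- allowed_letters(pol, i, nm)
      p <- masked_probs(policy_logits(pol, i, ch[seq_len(i - 1L)], nm), allowed)
      pick <- if (length(allowed) == 1L) 1L else
        sample.int(length(allowed), 1L, prob = p)
      ch[i] <- pol$alphabet[allowed[pick]]
      lp <- lp + log(p[pick])
      if (ch[i] != pol$wt$chars[i]) nm <- nm + 1L
    }
    seqs[s] <- paste(ch, collapse = "")
    logp[s] <- lp
  }
  list(sequences = seqs, logp = logp)
}

#' Policy log-probabilities of given sequences
#'
#' @param pol A [gfn_policy()].
#' @param seqs Character vector.
#' @return Numeric vector of log-probabilities (`-Inf` outside the mask).
#' @export
policy_logp <- function(pol, seqs) {
  vapply(seqs, function(s) policy_walk(pol, s)$logp, numeric(1),
         USE.NAMES = FALSE)
}

#' Trajectory-balance loss
#'
#' `mean((logZ + log P_F(x) - log R(x))^2)` over a batch: zero exactly when
#' the policy's sequence probability is proportional to the reward with
#' `logZ` the true log-partition value.
#'
#' @param pol A [gfn_policy()].
#' @param logZ Scalar log-partition parameter.
#' @param seqs Batch sequences.
#' @param rewards Strictly positive rewards `R(x)`; alternatively supply
#'   `log_rewards`.
#' @param log_rewards Optional log rewards (overrides `rewards`).
#' @return Non-negative scalar loss.
#' @export
tb_loss <- function(pol, logZ, seqs, rewards = NULL, log_rewards = NULL) {
  if (is.null(log_rewards)) {
    if (any(rewards <= 0)) stop("rewards must be > 0", call. = FALSE)
    log_rewards <- log(rewards)
  }
  mean((logZ + policy_logp(pol, seqs) - log_rewards)^2)
}

#' Replay buffer with FIFO eviction
#'
#' @param capacity Maximum number of (sequence, log-reward) records.
#' @return Object of class `replay_buffer` with methods accessed via
#'   [buffer_add()], [buffer_sample()], [buffer_size()].
#' @export
replay_buffer <- function(capacity = 20000L) {
  e <- new.env(parent = emptyenv())
  e$capacity <- as.integer(capacity)
  e$seqs <- character(0)
  e$logR <- numeric(0)
  structure(e, class = "replay_buffer")
}

#' @rdname replay_buffer
#' @param buf A `replay_buffer`.
#' @param seqs,logR Records to append (oldest evicted beyond capacity).
#' @export
buffer_add <- function(buf, seqs, logR) {
  buf$seqs <- c(buf$seqs, seqs)
  buf$logR <- c(buf$logR, logR)
  if (length(buf$seqs) > buf$capacity) {
    keep <- (length(buf$seqs) - buf$capacity + 1L):length(buf$seqs)
    buf$seqs <- buf$seqs[keep]
    buf$logR <- buf$logR[keep]
  }
  invisible(buf)
}

#' @rdname replay_buffer
#' @param n Number of records to draw (with replacement if `n` exceeds the
#'   buffer size).
#' @export
buffer_sample <- function(buf, n) {
  sz <- length(buf$seqs)
  idx <- sample.int(sz, n, replace = n > sz)
  list(sequences = buf$seqs[idx], logR = buf$logR[idx])
}

#' @rdname replay_buffer
#' @export
buffer_size <- function(buf) length(buf$seqs)

#' GFlowNet training configuration
#'
#' Defaults mirror the reference protocol: 8,000 steps, 16 fresh + 16
#' replayed sequences per step, learning rate 1e-3 halved after 4,000
#' steps, a 10x higher rate for the log-partition parameter, and a
#' 20,000-record replay buffer.
#'
#' @param steps,batch_new,batch_replay,lr,lr_logZ,lr_halving_step,
#'   buffer_capacity,seed,eval_every Tunables as described above;
#'   `eval_every` sets the period of the Spearman convergence diagnostic.
#' @return Object of class `gfn_train_config`.
#' @export
gfn_train_config <- function(steps = 8000L, batch_new = 16L,
                             batch_replay = 16L, lr = 1e-3, lr_logZ = 1e-2,
                             lr_halving_step = 4000L,
                             buffer_capacity = 20000L, seed = 1L,
                             eval_every = 200L) {
  stopifnot(steps >= 1L, batch_new >= 1L, lr > 0, lr_logZ > 0)
  structure(list(steps = as.integer(steps), batch_new = as.integer(batch_new),
                 batch_replay = as.integer(batch_replay), lr = lr,
                 lr_logZ = lr_logZ,
                 lr_halving_step = as.integer(lr_halving_step),
                 buffer_capacity = as.integer(buffer_capacity),
                 seed = as.integer(seed), eval_every = as.integer(eval_every)),
            class = "gfn_train_config")
}

# Accumulate the TB gradient of one sequence into the policy parameters.
# d loss / d logit_a = 2 * resid * (1{a chosen} - p_a) over allowed letters;
# the update below subtracts it (descent).
apply_tb_grad <- function(pol, walk, resid, scale) {
  for (c_ in walk$ctx) {
    g <- -2 * resid * c_$probs
    g[c_$chosen] <- g[c_$chosen] + 2 * resid
    g <- g * scale
    if (pol$type == "tabular") {
      key <- paste0(c_$i, "|", paste(c_$prefix, collapse = ""))
      cur <- if (exists(key, pol$logits, inherits = FALSE))
        get(key, pol$logits, inherits = FALSE)
      else numeric(length(pol$alphabet))
      cur[c_$allowed] <- cur[c_$allowed] - g
      assign(key, cur, pol$logits)
    } else {
      pol$base[c_$i, c_$allowed] <- pol$base[c_$i, c_$allowed] - g
      pol$wn[c_$i, c_$allowed] <- pol$wn[c_$i, c_$allowed] - g * c_$n
    }
  }
  pol
}

#' Train a GFlowNet-style sampler on a Boltzmann target
#'
#' Trajectory-balance training: at every step the policy generates
#' `batch_new` sequences, their rewards `R(x) = p_HUM(x) exp(-E(x)/T)` are
#' computed from the energy model, `batch_replay` stored sequences are
#' drawn from the replay buffer, and the combined batch updates the policy
#' parameters and the learned log-partition `logZ` by stochastic gradient
#' descent. The generated sequences are then added to the buffer. The
#' learning rate is halved at `lr_halving_step`.
#'
#' @param target An [energy_model()].
#' @param wt Wild type.
#' @param cfg A [gfn_train_config()].
#' @param init_data Non-empty character vector seeding the replay buffer
#'   (typically the affinity training sequences).
#' @param d_lim Mutation constraint enforced by the mask.
#' @param alphabet Alphabet (reduced alphabets supported for toy spaces).
#' @param type Policy parameterization, see [gfn_policy()].
#' @param heldout Optional character vector of scored held-out sequences,
#'   disjoint from `init_data`, for the Spearman convergence diagnostic.
#' @return List with `policy`, `logZ` and a `metrics` data frame
#'   (`step`, `loss`, `logZ`, `spearman`).
#' @export
train_gflownet <- function(target, wt, cfg = gfn_train_config(),
                           init_data, d_lim = 6L, alphabet = aa_alphabet(),
                           type = c("tabular", "linear"), heldout = NULL) {
  type <- match.arg(type)
  wt <- as_wt(wt)
  if (length(init_data) == 0L)
    stop("init_data must be non-empty", call. = FALSE)
  pol <- gfn_policy(wt, d_lim = d_lim, alphabet = alphabet, type = type)
  buf <- replay_buffer(cfg$buffer_capacity)
  buffer_add(buf, init_data,
             vapply(init_data, function(s) log_unnorm_density(target, s),
                    numeric(1), USE.NAMES = FALSE))
  logZ <- 0
  heldout_logR <- if (!is.null(heldout))
    vapply(heldout, function(s) log_unnorm_density(target, s), numeric(1),
           USE.NAMES = FALSE)
  metrics <- vector("list", cfg$steps)
  with_seed(cfg$seed, {
    for (step in seq_len(cfg$steps)) {
      lr_scale <- if (step > cfg$lr_halving_step) 0.5 else 1
      gen <- policy_sample(pol, cfg$batch_new)
      gen_logR <- vapply(gen$sequences,
                         function(s) log_unnorm_density(target, s),
                         numeric(1), USE.NAMES = FALSE)
      rep_ <- buffer_sample(buf, cfg$batch_replay)
      seqs <- c(gen$sequences, rep_$sequences)
      logR <- c(gen_logR, rep_$logR)
      nb <- length(seqs)
      resids <- numeric(nb)
      walks <- vector("list", nb)
      for (b in seq_len(nb)) {
        walks[[b]] <- policy_walk(pol, seqs[b], keep_ctx = TRUE)
        resids[b] <- logZ + walks[[b]]$logp - logR[b]
      }
      if (any(!is.finite(resids)))
        stop("non-finite trajectory-balance residual at step ", step,
             call. = FALSE)
      loss <- mean(resids^2)
      for (b in seq_len(nb))
        pol <- apply_tb_grad(pol, walks[[b]], resids[b],
                             cfg$lr * lr_scale / nb)
      logZ <- logZ - cfg$lr_logZ * lr_scale * 2 * mean(resids)
      buffer_add(buf, gen$sequences, gen_logR)
      sp <- NA_real_
      if (!is.null(heldout) &&
          (step %% cfg$eval_every == 0L || step == cfg$steps))
        sp <- convergence_spearman(pol, heldout, heldout_logR)
      metrics[[step]] <- c(step = step, loss = loss, logZ = logZ,
                           spearman = sp)
    }
  })
  list(policy = pol, logZ = logZ,
       metrics = as.data.frame(do.call(rbind, metrics)))
}

#' Spearman convergence diagnostic
#'
#' Rank correlation between held-out log rewards and the policy
#' log-probabilities of the same sequences; a trained sampler approaches 1.
#' Returns `NA` when either input is constant (undefined correlation).
#'
#' @param pol A [gfn_policy()].
#' @param heldout Character vector of held-out sequences.
#' @param heldout_logR Their log rewards under the target.
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
convergence_spearman <- function(pol, heldout, heldout_logR) {
  lp <- policy_logp(pol, heldout)
  if (stats::sd(lp) == 0 || stats::sd(heldout_logR) == 0) return(NA_real_)
  suppressWarnings(stats::cor(heldout_logR, lp, method = "spearman"))
}

#' Exact tabular policy for an enumerated distribution
#'
#' Builds the prefix-conditional policy whose sequence probabilities equal
#' a given normalized distribution over an enumerable space, by
#' marginalizing over suffixes. Used as a fixed-point oracle for the
#' trajectory-balance loss.
#'
#' @param p Named numeric vector: probabilities indexed by sequence
#'   (all sequences the same length, positive mass sums to 1).
#' @param wt Wild type.
#' @param d_lim Mutation constraint (must admit every supported sequence).
#' @param alphabet Alphabet.
#' @return A tabular [gfn_policy()].
#' @export
policy_from_distribution <- function(p, wt, d_lim, alphabet) {
  wt <- as_wt(wt)
  pol <- gfn_policy(wt, d_lim = d_lim, alphabet = alphabet, type = "tabular")
  seqs <- names(p)
  mat <- seqs_to_matrix(seqs)
  for (i in seq_len(wt$L)) {
    prefixes <- if (i == 1L) "" else
      apply(mat[, seq_len(i - 1L), drop = FALSE], 1L, paste, collapse = "")
    for (pre in unique(prefixes)) {
      sel <- prefixes == pre
      mass <- tapply(p[sel], factor(mat[sel, i], levels = alphabet), sum)
      mass[is.na(mass)] <- 0
      mass <- pmax(as.numeric(mass), 1e-300)
      assign(paste0(i, "|", pre), log(mass / sum(mass)), pol$logits)
    }
  }
  pol
}
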