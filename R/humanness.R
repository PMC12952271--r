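#' Autoregressive humanness priors
#'
#' A prior assigns each sequence a log-probability
#' `ln p_HUM(x) = sum_i ln p(x_i | x_<i)` under an autoregressive model of
#' natural antibody sequences. The package ships trainable desk-scale
#' stand-ins (categorical position-specific and k-mer models) plus adapters
#' with the identical contract: a uniform prior and a file-backed table for
#' scores precomputed by an external immunoglobulin language model.
#'
#' @param logp Function `sequence -> scalar log-probability` (natural log).
#' @param per_token Function `sequence -> vector` of conditional
#'   log-probabilities summing to `logp`, or NULL when unavailable.
#' @param name Identifier.
#' @return Object of class `ar_prior`.
#' @export
ar_prior <- function(logp, per_token = NULL, name = "prior") {
  stopifnot(is.function(logp))
  structure(list(logp = logp, per_token = per_token, name = name),
            class = "ar_prior")
}

#' @rdname ar_prior
#' @export
uniform_prior <- function() {
  ar_prior(function(x) nchar(x) * log(1 / 20),
           function(x) rep(log(1 / 20), nchar(x)),
           name = "uniform")
}

#' Log-probability of a sequence under a prior
#'
#' @param prior An [ar_prior()].
#' @param x Amino-acid string.
#' @return Scalar natural-log probability, `<= 0` for normalized priors.
#' @export
prior_logp <- function(prior, x) prior$logp(x)

#' @rdname prior_logp
#' @return For `prior_per_token`, the vector of per-position conditional
#'   log-probabilities (chain rule: its sum equals `prior_logp`).
#' @export
prior_per_token <- function(prior, x) {
  if (is.null(prior$per_token))
    stop("prior '", prior$name, "' exposes no per-token decomposition",
         call. = FALSE)
  prior$per_token(x)
}

#' Fit a categorical autoregressive prior
#'
#' Desk-scale stand-in for a pretrained immunoglobulin language model.
#' In `position-specific` mode each position gets an additively smoothed
#' empirical amino-acid distribution (sequences must be aligned and of equal
#' length). In `k-mer` mode the conditional at each position depends on the
#' previous `k` letters (shorter contexts near the start), allowing
#' variable-length extensions.
#'
#' @param sequences Non-empty character vector of training sequences.
#' @param pseudocount Additive smoothing count, > 0 (higher shrinks all
#'   conditionals toward uniform).
#' @param order `"position-specific"` (default) or `"k-mer"`.
#' @param k Context length for k-mer mode.
#' @return An [ar_prior()]; position-specific priors carry the `L x 20`
#'   log-probability matrix as attribute `logp_matrix`.
#' @export
fit_categorical_prior <- function(sequences, pseudocount = 1,
                                  order = c("position-specific", "k-mer"),
                                  k = 2L) {
  order <- match.arg(order)
  if (length(sequences) == 0L)
    stop("training set must be non-empty", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  if (order == "position-specific") {
    L <- nchar(sequences[1L])
    if (any(nchar(sequences) != L))
      stop("position-specific mode needs equal-length sequences", call. = FALSE)
    mat <- seqs_to_matrix(sequences)
    logp_mat <- t(vapply(seq_len(L), function(i) {
      cnt <- table(factor(mat[, i], levels = AA_ALPHABET)) + pseudocount
      log(as.numeric(cnt) / sum(cnt))
    }, numeric(20)))
    colnames(logp_mat) <- AA_ALPHABET
    per_token <- function(x) {
      ch <- seq_chars(x)
      if (length(ch) != L) stop("sequence length mismatch", call. = FALSE)
      logp_mat[cbind(seq_len(L), match(ch, AA_ALPHABET))]
    }
    pr <- ar_prior(function(x) sum(per_token(x)), per_token,
                   name = "categorical-positional")
    attr(pr, "logp_matrix") <- logp_mat
    pr
  } else {
    k <- as.integer(k)
    counts <- new.env(parent = emptyenv())
    bump <- function(key, a) {
      cur <- if (exists(key, counts, inherits = FALSE)) get(key, counts)
             else stats::setNames(numeric(20), AA_ALPHABET)
      cur[a] <- cur[a] + 1
      assign(key, cur, counts)
    }
    for (s in sequences) {
      ch <- seq_chars(s)
      for (i in seq_along(ch)) {
        ctx <- if (i == 1L) "" else
          paste(ch[max(1L, i - k):(i - 1L)], collapse = "")
        bump(paste0(nchar(ctx), ":", ctx), ch[i])
      }
    }
    cond <- function(ctx, a) {
      key <- paste0(nchar(ctx), ":", ctx)
      cnt <- if (exists(key, counts, inherits = FALSE)) get(key, counts)
             else stats::setNames(numeric(20), AA_ALPHABET)
      cnt <- cnt + pseudocount
      log(cnt[[a]] / sum(cnt))
    }
    per_token <- function(x) {
      ch <- seq_chars(x)
      vapply(seq_along(ch), function(i) {
        ctx <- if (i == 1L) "" else
          paste(ch[max(1L, i - k):(i - 1L)], collapse = "")
        cond(ctx, ch[i])
      }, numeric(1))
    }
    ar_prior(function(x) sum(per_token(x)), per_token,
             name = sprintf("categorical-%dmer", k))
  }
}

#' File-backed prior adapter
#'
#' Serves log-probabilities precomputed by an external language model from a
#' CSV with columns `sequence`, `logp` (natural log). Unknown sequences are
#' an error.
#'
#' @param path CSV path.
#' @return An [ar_prior()] without a per-token decomposition.
#' @export
file_prior <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- stats::setNames(df$logp, df$sequence)
  ar_prior(function(x) {
    if (!x %in% names(tab))
      stop("no stored log-probability for sequence '", x, "'", call. = FALSE)
    unname(tab[[x]])
  }, name = "file")
}

#' Humanness threshold filter
#'
#' TRUE iff `ln p_HUM(x) >= threshold` (inclusive at the boundary). A
#' threshold of -120 natural-log units is the convention used to restrict
#' searches to human-like heavy-chain CDRs.
#'
#' @param prior An [ar_prior()].
#' @param x Amino-acid string.
#' @param threshold Log-probability threshold (natural log).
#' @return Logical.
#' @export
humanness_filter <- function(prior, x, threshold = -120) {
  prior_logp(prior, x) >= threshold
}
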