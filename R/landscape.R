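#' Specification of a synthetic epistasis model
#'
#' The landscape decomposes the log-affinity of a variant into a baseline,
#' additive single-site fields `h_i(x_i)` and pairwise couplings
#' `J_ij(x_i, x_j)`, all sampled i.i.d. Gaussian. Two named modes are
#' provided: `simple` draws fields from N(-0.5, 0.5) and couplings from
#' N(0, 0.5) (most single mutations are mildly deleterious, little
#' epistasis), while `hard` draws fields from N(0, 0.5) and couplings from
#' N(-0.5, 0.5), so random multi-mutants are much more likely to be
#' deleterious. All Gaussian parameters are (mean, sd).
#'
#' @param mode `"simple"`, `"hard"`, or `"custom"` with explicit moments.
#' @param h_mean,h_sd,j_mean,j_sd Field and coupling moments for
#'   `mode = "custom"`.
#' @return Object of class `landscape_spec`.
#' @export
landscape_spec <- function(mode = c("simple", "hard", "custom"),
                           h_mean = NULL, h_sd = NULL,
                           j_mean = NULL, j_sd = NULL) {
  mode <- match.arg(mode)
  moments <- switch(mode,
    simple = list(h_mean = -0.5, h_sd = 0.5, j_mean = 0.0, j_sd = 0.5),
    hard = list(h_mean = 0.0, h_sd = 0.5, j_mean = -0.5, j_sd = 0.5),
    custom = {
      if (is.null(h_mean) || is.null(h_sd) || is.null(j_mean) || is.null(j_sd))
        stop("custom mode needs all four moments", call. = FALSE)
      list(h_mean = h_mean, h_sd = h_sd, j_mean = j_mean, j_sd = j_sd)
    })
  structure(c(list(mode = mode), moments), class = "landscape_spec")
}

pair_index <- function(i, j, L) {
  # index of unordered pair (i < j) in lexicographic order
  (i - 1L) * L - (i * (i - 1L)) %/% 2L + (j - i)
}

#' Sample a ground-truth epistatic landscape
#'
#' Fills the `L x 20` field table and the `C(L,2) x 20 x 20` coupling
#' tables with i.i.d. Gaussian draws per the spec, then zeroes every entry
#' involving a wild-type letter (`h_i(wt_i) = 0`;
#' `J_ij(a, b) = 0` whenever `a = wt_i` or `b = wt_j`), so the wild type
#' scores exactly the baseline and identity substitutions are neutral.
#' Reproducible from the seed.
#'
#' @param spec A [landscape_spec()].
#' @param wt Wild type.
#' @param seed Integer seed.
#' @param f_wt Baseline affinity of the wild type (default 0; only
#'   differences matter for ranking).
#' @param alphabet Alphabet (reduced alphabets supported for toys).
#' @return Object of class `epistasis_landscape`.
#' @export
sample_landscape <- function(spec, wt, seed = 1L, f_wt = 0,
                             alphabet = aa_alphabet()) {
  stopifnot(inherits(spec, "landscape_spec"))
  wt <- as_wt(wt)
  L <- wt$L
  a <- length(alphabet)
  npair <- (L * (L - 1L)) %/% 2L
  with_seed(seed, {
    h <- matrix(stats::rnorm(L * a, spec$h_mean, spec$h_sd), L, a,
                dimnames = list(NULL, alphabet))
    J <- array(stats::rnorm(npair * a * a, spec$j_mean, spec$j_sd),
               dim = c(npair, a, a), dimnames = list(NULL, alphabet, alphabet))
  })
  wt_idx <- match(wt$chars, alphabet)
  h[cbind(seq_len(L), wt_idx)] <- 0
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    pid <- pair_index(i, j, L)
    J[pid, wt_idx[i], ] <- 0
    J[pid, , wt_idx[j]] <- 0
  }
  structure(list(wt = wt, f_wt = f_wt, h = h, J = J, alphabet = alphabet,
                 spec = spec, seed = seed),
            class = "epistasis_landscape")
}

#' @export
print.epistasis_landscape <- function(x, ...) {
  cat(sprintf("<epistasis_landscape> %s mode, L = %d, seed = %d\n",
              x$spec$mode, x$wt$L, x$seed))
  invisible(x)
}

#' Evaluate the ground-truth affinity of variants
#'
#' `f(x) = f_wt + sum_i h_i(x_i) + sum_{i<j} J_ij(x_i, x_j)`; by the
#' zeroing convention only mutated positions (and mutated pairs)
#' contribute.
#'
#' @param ls An [sample_landscape()] result.
#' @param x Character vector of sequences (length matching the wild type).
#' @return Numeric vector of true log-affinities.
#' @export
evaluate_landscape <- function(ls, x) {
  vapply(x, function(s) {
    if (nchar(s) != ls$wt$L)
      stop("sequence length differs from wild type", call. = FALSE)
    ch <- seq_chars(s)
    mp <- which(ch != ls$wt$chars)
    val <- ls$f_wt
    if (length(mp)) {
      ai <- match(ch[mp], ls$alphabet)
      val <- val + sum(ls$h[cbind(mp, ai)])
      if (length(mp) > 1L) {
        for (u in seq_len(length(mp) - 1L)) for (v in (u + 1L):length(mp)) {
          pid <- pair_index(mp[u], mp[v], ls$wt$L)
          val <- val + ls$J[pid, ai[u], ai[v]]
        }
      }
    }
    val
  }, numeric(1), USE.NAMES = FALSE)
}

mutate_at <- function(wt_chars, pos, letters) {
  ch <- wt_chars
  ch[pos] <- letters
  paste(ch, collapse = "")
}

# n distinct random k-mutants of wt (positions without replacement,
# letters uniform over the non-wild-type alternatives).
random_k_mutants <- function(wt, k, n, alphabet) {
  L <- wt$L
  space <- choose(L, k) * (length(alphabet) - 1)^k
  if (n > space)
    stop("requested ", n, " distinct ", k, "-mutants but only ", space,
         " exist", call. = FALSE)
  seen <- new.env(parent = emptyenv())
  out <- character(n)
  got <- 0L
  while (got < n) {
    pos <- sort(sample.int(L, k))
    letters <- vapply(pos, function(p) {
      alt <- alphabet[alphabet != wt$chars[p]]
      alt[sample.int(length(alt), 1L)]
    }, character(1))
    s <- mutate_at(wt$chars, pos, letters)
    if (!exists(s, seen, inherits = FALSE)) {
      assign(s, TRUE, seen)
      got <- got + 1L
      out[got] <- s
    }
  }
  out
}

#' Build a synthetic training dataset from a landscape
#'
#' Emulates the composition of a deep-mutational-scan style affinity
#' library: every single-mutant record -- all (position, amino-acid) pairs,
#' `33 x 20 = 660` for the canonical wild type, identity substitutions
#' included as wild-type-affinity records -- plus `n_double` distinct
#' random double mutants and `n_triple` distinct random triple mutants.
#' Observed values are the true landscape values plus Gaussian measurement
#' noise. The canonical configuration yields 14,660 rows.
#'
#' @param ls An [sample_landscape()] result.
#' @param n_double,n_triple Numbers of distinct random double and triple
#'   mutants (defaults 2,100 and 11,900).
#' @param noise_sd Measurement noise standard deviation (default 1).
#' @param seed Integer seed.
#' @return Data frame with columns `sequence`, `n_mutations`, `true_faff`,
#'   `observed_faff`.
#' @export
build_dataset <- function(ls, n_double = 2100L, n_triple = 11900L,
                          noise_sd = 1, seed = 1L) {
  wt <- ls$wt
  a <- length(ls$alphabet)
  singles <- unlist(lapply(seq_len(wt$L), function(i)
    vapply(ls$alphabet, function(aa) mutate_at(wt$chars, i, aa), character(1))))
  with_seed(seed, {
    doubles <- if (n_double > 0) random_k_mutants(wt, 2L, n_double, ls$alphabet)
               else character(0)
    triples <- if (n_triple > 0) random_k_mutants(wt, 3L, n_triple, ls$alphabet)
               else character(0)
    seqs <- c(singles, doubles, triples)
    truth <- evaluate_landscape(ls, seqs)
    obs <- truth + stats::rnorm(length(seqs), 0, noise_sd)
  })
  data.frame(sequence = seqs,
             n_mutations = vapply(seqs, hamming, integer(1), b = wt$sequence,
                                  USE.NAMES = FALSE),
             true_faff = truth, observed_faff = obs,
             stringsAsFactors = FALSE)
}

#' Generate out-of-distribution negative examples
#'
#' Random CDR replacements: every position drawn i.i.d. uniform over the
#' alphabet, each assigned the fixed weak affinity implied by an
#' association constant `Ka` (in 1/M): `f_aff = log10(Ka * 1 nM)`, i.e.
#' `Kd = 1/Ka`. The default `Ka = 1e7` gives `f_aff = -2`.
#'
#' @param wt Wild type (sets the length).
#' @param n Number of negatives (the reference augmentation used 14,000).
#' @param ka Association constant in 1/M.
#' @param seed Integer seed.
#' @param alphabet Alphabet.
#' @return Data frame with columns `sequence`, `faff`.
#' @export
generate_negatives <- function(wt, n, ka = 1e7, seed = 1L,
                               alphabet = aa_alphabet()) {
  stopifnot(n >= 1L, ka > 0)
  wt <- as_wt(wt)
  faff <- log10(ka * 1e-9)
  seqs <- with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(alphabet, wt$L, replace = TRUE), collapse = ""),
    character(1)))
  data.frame(sequence = seqs, faff = faff, stringsAsFactors = FALSE)
}
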