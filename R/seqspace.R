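#' Wild-type CDR sequence
#'
#' Wraps the reference sequence against which all mutations are counted.
#' The canonical design region in this package is a concatenation of the
#' heavy-chain CDR1/CDR2/CDR3 loops (33 residues for the shipped default,
#' see [wt_cdr_default()]).
#'
#' @param sequence Amino-acid string over the 20-letter alphabet.
#' @param region_labels Optional character vector of per-position CDR tags
#'   (same length as the sequence).
#' @return An object of class `wildtype` with elements `sequence`, `chars`,
#'   `L` and `region_labels`.
#' @export
wildtype <- function(sequence, region_labels = NULL) {
  check_aa(sequence, "wild-type sequence")
  ch <- seq_chars(sequence)
  if (!is.null(region_labels) && length(region_labels) != length(ch))
    stop("region_labels must have one entry per position", call. = FALSE)
  structure(list(sequence = sequence, chars = ch, L = length(ch),
                 region_labels = region_labels),
            class = "wildtype")
}

#' @export
print.wildtype <- function(x, ...) {
  cat(sprintf("<wildtype> %d aa: %s\n", x$L, x$sequence))
  invisible(x)
}

#' Default wild-type CDR concatenation
#'
#' The concatenated CDRH1/H2/H3 of the anti-peptide antibody used throughout
#' the package examples and the synthetic benchmark (33 residues).
#'
#' @return A [wildtype()] object.
#' @export
wt_cdr_default <- function() {
  wildtype("GFTLNSYGISIYSDGRRTFYGDSVGRAAGTFDS")
}

as_wt <- function(wt) {
  if (inherits(wt, "wildtype")) wt else wildtype(wt)
}

#' Variant of a wild type
#'
#' A CDR sequence annotated with its mutation set relative to the wild type.
#' Positions are 0-based internally; rendered reports are 1-based.
#'
#' @param sequence Amino-acid string, same length as the wild type.
#' @param wt A [wildtype()] object or sequence string.
#' @return Object of class `variant` with `sequence` and a data frame
#'   `mutations` (`pos0`, `wt_aa`, `aa`); `nrow(mutations)` equals the
#'   Hamming distance to the wild type.
#' @export
variant_of <- function(sequence, wt) {
  wt <- as_wt(wt)
  check_aa(sequence)
  if (nchar(sequence) != wt$L)
    stop("variant length differs from wild type", call. = FALSE)
  ch <- seq_chars(sequence)
  idx <- which(ch != wt$chars)
  structure(list(sequence = sequence,
                 mutations = data.frame(pos0 = idx - 1L,
                                        wt_aa = wt$chars[idx],
                                        aa = ch[idx],
                                        stringsAsFactors = FALSE)),
            class = "variant")
}

#' @export
print.variant <- function(x, ...) {
  m <- x$mutations
  lab <- if (nrow(m) == 0) "WT" else
    paste(sprintf("%s%d%s", m$wt_aa, m$pos0 + 1L, m$aa), collapse = ",")
  cat(sprintf("<variant> %s [%s]\n", x$sequence, lab))
  invisible(x)
}

#' Search constraints around the wild type
#'
#' @param d_lim Maximum number of mutations away from the wild type
#'   (default 6, the constraint used for generation).
#' @param alphabet Amino-acid alphabet (default the canonical 20 letters).
#' @return Object of class `search_constraints`.
#' @export
search_constraints <- function(d_lim = 6L, alphabet = aa_alphabet()) {
  d_lim <- as.integer(d_lim)
  if (is.na(d_lim) || d_lim < 0L) stop("d_lim must be >= 0", call. = FALSE)
  structure(list(d_lim = d_lim, alphabet = alphabet),
            class = "search_constraints")
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b Character scalars of equal length.
#' @return Non-negative integer count of differing positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("hamming distance requires equal-length sequences", call. = FALSE)
  sum(charToRaw(a) != charToRaw(b))
}

# Hamming distances from one sequence to each row of a character matrix
# (rows = sequences, columns = positions). Used by hot loops.
hamming_to_matrix <- function(x_chars, mat) {
  if (ncol(mat) != length(x_chars))
    stop("length mismatch in hamming_to_matrix", call. = FALSE)
  as.integer(rowSums(mat != matrix(x_chars, nrow(mat), ncol(mat), byrow = TRUE)))
}

seqs_to_matrix <- function(seqs) {
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

#' Size of the single-substitution neighborhood under a distance constraint
#'
#' Number of sequences exactly one substitution from `x` that remain within
#' `d_lim` mutations of the wild type. Exposed so samplers can apply a
#' Hastings correction when the neighborhood shrinks at the boundary.
#'
#' @param x Sequence string.
#' @param wt Wild type ([wildtype()] or string).
#' @param constraints A [search_constraints()] object.
#' @return Integer neighborhood size.
#' @export
neighborhood_size <- function(x, wt, constraints = search_constraints()) {
  wt <- as_wt(wt)
  k <- hamming(x, wt$sequence)
  if (k > constraints$d_lim)
    stop("sequence already violates d_lim", call. = FALSE)
  a <- length(constraints$alphabet)
  if (k < constraints$d_lim) wt$L * (a - 1L) else k * (a - 1L)
}

#' Uniform draw from the constrained mutation neighborhood
#'
#' Returns a sequence exactly one substitution away from `x` and at most
#' `d_lim` mutations away from the wild type, uniformly over that
#' neighborhood. At the `d_lim` boundary only already-mutated positions may
#' change (including reversion to the wild-type letter), so the neighborhood
#' is never empty for `d_lim >= 1`.
#'
#' @inheritParams neighborhood_size
#' @return Sequence string. Uses the current RNG stream.
#' @export
random_neighbor <- function(x, wt, constraints = search_constraints()) {
  wt <- as_wt(wt)
  ch <- seq_chars(x)
  k <- sum(ch != wt$chars)
  if (k > constraints$d_lim)
    stop("sequence already violates d_lim", call. = FALSE)
  ab <- constraints$alphabet
  if (k < constraints$d_lim) {
    pos <- sample.int(wt$L, 1L)
  } else {
    mut <- which(ch != wt$chars)
    pos <- if (length(mut) == 1L) mut else mut[sample.int(length(mut), 1L)]
  }
  choices <- ab[ab != ch[pos]]
  ch[pos] <- choices[sample.int(length(choices), 1L)]
  paste(ch, collapse = "")
}

#' Count the constrained sequence search space
#'
#' Two conventions are provided. `exact-d-positions` counts variants built
#' by choosing `d` of the `L` positions and placing any of the
#' `alphabet_size` letters at each chosen position: `C(L, d) * A^d`
#' (includes identity placements). `up-to-d` counts distinct sequences at
#' Hamming distance at most `d`: `sum_k C(L, k) * (A - 1)^k`.
#'
#' @param L Sequence length.
#' @param d Number of positions / maximum distance, `0 <= d <= L`.
#' @param alphabet_size Alphabet size (default 20).
#' @param mode `"exact-d-positions"` or `"up-to-d"`.
#' @return A numeric count (may exceed integer range).
#' @export
#' @examples
#' count_search_space(33, 6, 20)  # 7.088e13
count_search_space <- function(L, d, alphabet_size = 20,
                               mode = c("exact-d-positions", "up-to-d")) {
  mode <- match.arg(mode)
  stopifnot(d >= 0, d <= L)
  if (mode == "exact-d-positions") {
    choose(L, d) * alphabet_size^d
  } else {
    k <- 0:d
    sum(choose(L, k) * (alphabet_size - 1)^k)
  }
}

#' Diversity of a set of sequences
#'
#' Mean pairwise Hamming distance: `1/(N(N-1)) * sum` over ordered pairs.
#' Duplicate records are kept as given; de-duplicate upstream if desired.
#'
#' @param S Character vector of equal-length sequences, `length >= 2`.
#' @return Non-negative mean pairwise distance.
#' @export
seq_diversity <- function(S) {
  n <- length(S)
  if (n < 2L) stop("diversity requires at least 2 sequences", call. = FALSE)
  mat <- seqs_to_matrix(S)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    tot <- tot + sum(hamming_to_matrix(mat[i, ], mat[(i + 1L):n, , drop = FALSE]))
  }
  2 * tot / (n * (n - 1))
}

#' Novelty of a set relative to a reference set
#'
#' Mean over `S` of the minimum Hamming distance to any member of `ref`
#' (typically the affinity training set). Zero when `S` is contained in
#' `ref`.
#'
#' @param S Character vector of sequences.
#' @param ref Non-empty character vector of reference sequences.
#' @return Non-negative mean minimum distance.
#' @export
seq_novelty <- function(S, ref) {
  if (length(ref) == 0L) stop("reference set must be non-empty", call. = FALSE)
  rmat <- seqs_to_matrix(ref)
  mean(vapply(S, function(s) min(hamming_to_matrix(seq_chars(s), rmat)),
              numeric(1)))
}

#' Overlap fraction between two candidate sets
#'
#' `|A n B| / min(|A|, |B|)` after removing duplicates. Reduces to the
#' shared-member fraction when the two sets have equal size (the setting in
#' which top-candidate overlaps are usually reported).
#'
#' @param A,B Non-empty character vectors of sequences.
#' @return Fraction in `[0, 1]`.
#' @export
seq_overlap <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) == 0L || length(B) == 0L)
    stop("overlap requires non-empty sets", call. = FALSE)
  length(intersect(A, B)) / min(length(A), length(B))
}

#' Net-charge developability score
#'
#' Sum of per-residue contributions: +1 for R and K, +0.1 for H, -1 for D
#' and E, 0 otherwise. The acceptable developability band is `[-2, 2]`.
#'
#' @param x Amino-acid string.
#' @return Real charge score.
#' @export
charge_score <- function(x) {
  check_aa(x)
  ch <- seq_chars(x)
  sum((ch %in% c("R", "K")) * 1 + (ch == "H") * 0.1 -
        (ch %in% c("D", "E")) * 1)
}

.diwv_cache <- new.env(parent = emptyenv())

#' Dipeptide instability weight table
#'
#' The published 400-entry dipeptide instability weight values (DIWV) of
#' Guruprasad et al. (1990), shipped as a CSV so an alternative table can be
#' swapped in.
#'
#' @param path Optional path to a CSV with columns `first`, `second`,
#'   `weight`; defaults to the shipped table.
#' @return A 20 x 20 numeric matrix with dimnames over the alphabet.
#' @export
instability_weights <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.diwv_cache$default)) return(.diwv_cache$default)
    path <- system.file("extdata", "diwv_instability_weights.csv",
                        package = "cdropt", mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- matrix(NA_real_, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  m[cbind(df$first, df$second)] <- df$weight
  if (cache) .diwv_cache$default <- m
  m
}

#' Protein instability index
#'
#' `(10/L) * sum` over consecutive dipeptides of the published dipeptide
#' instability weight. Values above 40 conventionally indicate an unstable
#' protein (higher = less stable); sequences generated here are typically
#' well below that threshold.
#'
#' @param x Amino-acid string, length >= 2.
#' @param weights Dipeptide weight matrix, see [instability_weights()].
#' @return Real instability score.
#' @export
instability_index <- function(x, weights = instability_weights()) {
  check_aa(x)
  ch <- seq_chars(x)
  L <- length(ch)
  if (L < 2L) stop("instability index requires length >= 2", call. = FALSE)
  w <- weights[cbind(ch[-L], ch[-1L])]
  if (anyNA(w)) {
    warning("unknown dipeptide(s); using weight 1.0")
    w[is.na(w)] <- 1.0
  }
  10 / L * sum(w)
}

#' Developability score table for a set of sequences
#'
#' Convenience report: per-sequence mutation count (relative to the wild
#' type), charge score and instability index.
#'
#' @param seqs Character vector of sequences.
#' @param wt Wild type.
#' @param path Optional CSV output path.
#' @return Data frame with columns `sequence`, `n_mutations`, `charge`,
#'   `instability` (written to `path` when given).
#' @export
score_table <- function(seqs, wt, path = NULL) {
  wt <- as_wt(wt)
  df <- data.frame(
    sequence = seqs,
    n_mutations = vapply(seqs, hamming, integer(1), b = wt$sequence,
                         USE.NAMES = FALSE),
    charge = vapply(seqs, charge_score, numeric(1), USE.NAMES = FALSE),
    instability = vapply(seqs, instability_index, numeric(1),
                         USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Read / write sequence sets as FASTA
#'
#' Thin wrappers around Biostrings for candidate-set interchange; record IDs
#' carry run/rank metadata.
#'
#' @param seqs Named or unnamed character vector of sequences.
#' @param path File path.
#' @param ids Optional record IDs (defaults to names or `seq_1..n`).
#' @return `write_fasta_seqs` invisibly returns `path`; `read_fasta_seqs`
#'   returns a named character vector.
#' @export
write_fasta_seqs <- function(seqs, path, ids = NULL) {
  if (is.null(ids)) ids <- if (!is.null(names(seqs))) names(seqs) else
    sprintf("seq_%d", seq_along(seqs))
  x <- Biostrings::AAStringSet(unname(seqs))
  names(x) <- ids
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @rdname write_fasta_seqs
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
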