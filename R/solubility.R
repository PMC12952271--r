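#' Hydrophobicity weight table
#'
#' Per-amino-acid weights used by [solubility_score()]. The default is the
#' Kyte-Doolittle hydropathy scale shipped as a CSV placeholder: the
#' originally fitted 20-weight table behind the published score is not
#' public, so absolute score magnitudes are configuration-dependent. Supply
#' your own table to reproduce a particular calibration.
#'
#' @param path Optional CSV with columns `amino_acid`, `weight`; defaults to
#'   the shipped Kyte-Doolittle scale.
#' @return Named numeric vector with one finite entry per amino acid.
#' @export
hydrophobicity_weights <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hydrophobicity_kd.csv",
                        package = "cdropt", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  hw <- stats::setNames(df$weight, df$amino_acid)
  missing <- setdiff(AA_ALPHABET, names(hw))
  if (length(missing))
    stop("hydrophobicity table missing: ", paste(missing, collapse = ","),
         call. = FALSE)
  if (any(!is.finite(hw))) stop("non-finite hydrophobicity weight", call. = FALSE)
  hw[AA_ALPHABET]
}

#' Per-residue SASA providers
#'
#' A SASA provider maps a sequence to a per-residue relative solvent
#' accessibility vector (dimensionless, normalized to Ala-X-Ala maxima).
#' Three kinds are supported:
#' * `constant` -- 1.0 at every position (the SASA-free ablation);
#' * `table` -- a fixed per-amino-acid average exposure, from a named
#'   vector or a CSV with columns `amino_acid`, `sasa`;
#' * `file` -- stored per-residue vectors keyed by sequence, from a CSV
#'   with columns `sequence`, `position` (1-based), `sasa`; unknown
#'   sequences are an error, never a silent fallback.
#'
#' @param kind `"constant"`, `"table"` or `"file"`.
#' @param source Path to the CSV for `table`/`file` kinds.
#' @param table Named numeric vector (per amino acid) for the `table` kind,
#'   as an alternative to `source`.
#' @return Object of class `sasa_provider`: a list with `name` and
#'   `predict(sequence)`.
#' @export
sasa_provider <- function(kind = c("constant", "table", "file"),
                          source = NULL, table = NULL) {
  kind <- match.arg(kind)
  predict <- switch(kind,
    constant = function(x) rep(1, nchar(x)),
    table = {
      if (is.null(table)) {
        if (is.null(source))
          stop("table provider needs `table` or `source`", call. = FALSE)
        df <- utils::read.csv(source, stringsAsFactors = FALSE)
        table <- stats::setNames(df$sasa, df$amino_acid)
      }
      missing <- setdiff(AA_ALPHABET, names(table))
      if (length(missing))
        stop("SASA table missing: ", paste(missing, collapse = ","),
             call. = FALSE)
      if (any(table < 0)) stop("SASA values must be >= 0", call. = FALSE)
      function(x) unname(table[seq_chars(x)])
    },
    file = {
      if (is.null(source)) stop("file provider needs `source`", call. = FALSE)
      df <- utils::read.csv(source, stringsAsFactors = FALSE)
      store <- new.env(parent = emptyenv())
      for (s in unique(df$sequence)) {
        sub <- df[df$sequence == s, ]
        v <- numeric(nchar(s))
        v[sub$position] <- sub$sasa
        if (any(v < 0)) stop("SASA values must be >= 0", call. = FALSE)
        assign(s, v, envir = store)
      }
      function(x) {
        if (!exists(x, envir = store, inherits = FALSE))
          stop("no stored SASA vector for sequence '", x, "'", call. = FALSE)
        get(x, envir = store, inherits = FALSE)
      }
    })
  structure(list(name = kind, predict = predict), class = "sasa_provider")
}

#' Write a per-residue SASA file readable by the file provider
#'
#' @param seqs Character vector of sequences.
#' @param vectors List of per-residue SASA vectors (same lengths).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sasa_csv <- function(seqs, vectors, path) {
  stopifnot(length(seqs) == length(vectors))
  df <- do.call(rbind, Map(function(s, v) {
    stopifnot(nchar(s) == length(v))
    data.frame(sequence = s, position = seq_along(v), sasa = v)
  }, seqs, vectors))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Sequence solubility score
#'
#' `f_sol(x) = -sum_j SASA(j, x_j) * HW(x_j) + const`: exposed hydrophobic
#' residues are penalized, so higher scores mean more soluble. The score is
#' additive over positions for a fixed SASA vector, and with the constant
#' provider it reduces to a pure hydrophobicity sum.
#'
#' @param x Amino-acid string.
#' @param sasa A [sasa_provider()] (default: constant 1).
#' @param hw Named hydrophobicity weights, see [hydrophobicity_weights()].
#' @param const Additive offset (default 0; shifts all scores equally and
#'   cancels in Pareto comparisons).
#' @return Real solubility score (higher = more soluble).
#' @export
solubility_score <- function(x, sasa = sasa_provider("constant"),
                             hw = hydrophobicity_weights(), const = 0) {
  check_aa(x)
  ch <- seq_chars(x)
  v <- sasa$predict(x)
  if (length(v) != length(ch))
    stop("SASA provider returned length ", length(v), " for length ",
         length(ch), " sequence", call. = FALSE)
  -sum(v * unname(hw[ch])) + const
}
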