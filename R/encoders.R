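#' Sequence encoders
#'
#' Encoders map amino-acid sequences to fixed-length numeric vectors for the
#' GP kernel. An encoder is a name, a dimension function and a deterministic
#' `encode` contract; external protein-language-model embeddings enter only
#' through the file-backed encoder (no model weights are shipped or run).
#'
#' @param name Unique identifier.
#' @param encode Function `sequence -> numeric vector`.
#' @param dimension Function `L -> integer` giving the output length for a
#'   sequence of length `L`, or a fixed integer for file-backed encoders.
#' @return Object of class `encoder`.
#' @export
encoder <- function(name, encode, dimension) {
  stopifnot(is.character(name), length(name) == 1L, is.function(encode))
  dim_fn <- if (is.function(dimension)) dimension else function(L) dimension
  structure(list(name = name, encode = encode, dimension = dim_fn),
            class = "encoder")
}

.encoder_registry <- new.env(parent = emptyenv())

#' Encoder registry
#'
#' Registered encoders are retrievable by name in run configurations.
#'
#' @param e An [encoder()].
#' @param overwrite Allow replacing an existing registration.
#' @return `register_encoder` invisibly returns the encoder; `get_encoder`
#'   returns the registered encoder or errors on an unknown name.
#' @export
register_encoder <- function(e, overwrite = FALSE) {
  stopifnot(inherits(e, "encoder"))
  if (!overwrite && !is.null(.encoder_registry[[e$name]]))
    stop("encoder '", e$name, "' is already registered", call. = FALSE)
  .encoder_registry[[e$name]] <- e
  invisible(e)
}

#' @rdname register_encoder
#' @param name Encoder name.
#' @export
get_encoder <- function(name) {
  e <- .encoder_registry[[name]]
  if (is.null(e)) stop("unknown encoder '", name, "'", call. = FALSE)
  e
}

#' @rdname register_encoder
#' @export
list_encoders <- function() sort(ls(.encoder_registry))

#' One-hot sequence encoding
#'
#' Canonical layout is position-major, alphabet-minor: entry
#' `(i-1)*20 + a` is 1 iff position `i` carries the `a`-th letter of
#' `ACDEFGHIKLMNPQRSTVWY`. Exactly `L` entries are 1, and the squared
#' Euclidean distance between two encodings equals twice their Hamming
#' distance.
#'
#' @param x Amino-acid string.
#' @return Numeric vector of length `20 * nchar(x)`.
#' @export
encode_onehot <- function(x) {
  check_aa(x)
  ch <- seq_chars(x)
  L <- length(ch)
  v <- numeric(20L * L)
  v[(seq_len(L) - 1L) * 20L + match(ch, AA_ALPHABET)] <- 1
  v
}

# Encode many sequences into a matrix (rows = sequences).
encode_matrix <- function(seqs, enc = get_encoder("onehot")) {
  do.call(rbind, lapply(seqs, enc$encode))
}

#' File-backed encoder serving precomputed embeddings
#'
#' Reads a TSV whose first column is the sequence and whose remaining
#' columns are vector components (header row included). Unknown sequences
#' raise an error; vectors are returned verbatim.
#'
#' @param path TSV path.
#' @param name Registry name (default `"file"`).
#' @return An [encoder()].
#' @export
file_encoder <- function(path, name = "file") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("embedding table needs >= 2 columns", call. = FALSE)
  keys <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- keys
  d <- ncol(mat)
  encoder(name,
          encode = function(x) {
            if (!x %in% keys)
              stop("no stored embedding for sequence '", x, "'", call. = FALSE)
            unname(mat[x, ])
          },
          dimension = d)
}

#' Write an embedding table readable by [file_encoder()]
#'
#' @param seqs Character vector of sequences.
#' @param vectors Numeric matrix, one row per sequence.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_embedding_tsv <- function(seqs, vectors, path) {
  stopifnot(length(seqs) == nrow(vectors))
  df <- data.frame(sequence = seqs, vectors, check.names = FALSE)
  names(df) <- c("sequence", sprintf("v%d", seq_len(ncol(vectors))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
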