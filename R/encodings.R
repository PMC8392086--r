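#' Canonicalize a nucleotide sequence to RNA
#'
#' Uppercases the sequence and maps thymine to uracil, so datasets
#' distributed as DNA can be used directly.  Any character outside
#' `A, C, G, U, T` (either case) is rejected; IUPAC ambiguity codes such as
#' `N` are deliberately not supported because the classifier's encodings are
#' defined only over the four unambiguous bases.
#'
#' @param x character vector of nucleotide sequences.
#' @return Character vector of the same length over the alphabet `ACGU`.
#' @examples
#' canonicalize_rna("acgt")   # "ACGU"
#' @export
canonicalize_rna <- function(x) {
  if (!is.character(x) || length(x) == 0L || any(!nzchar(x)))
    stop("sequences must be non-empty character strings")
  out <- chartr("acgut", "ACGUT", x)
  out <- chartr("T", "U", out)
  bad <- regexpr("[^ACGU]", out)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf(
      "invalid alphabet: character '%s' at position %d of sequence %d (allowed: A, C, G, U, T)",
      substr(out[i], bad[i], bad[i]), bad[i], i))
  }
  out
}

#' Circular dinucleotide pairs of a sequence
#'
#' The circular encoding first closes the sequence into a ring by replicating
#' the first base at the end, then reads consecutive *non-overlapping* base
#' pairs left to right.  For an odd-length sequence of length `L` this yields
#' exactly `(L + 1) / 2` dinucleotides; the final pair joins the last base to
#' the replicated first base.
#'
#' @param seq a single canonical RNA string (see [canonicalize_rna()]).
#' @param lenient if `TRUE`, an even-length sequence is accepted and the
#'   final unpaired base (the replicate) is dropped after ring closure;
#'   the default strict mode raises an error, because all supported
#'   benchmark-style windows have odd length.
#' @return Character vector of dinucleotides.
#' @examples
#' circular_pairs("AGU")  # "AG" "UA"
#' @export
circular_pairs <- function(seq, lenient = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  if (L %% 2L == 0L && !lenient)
    stop("circular pairing requires odd sequence length (got ", L,
         "); use lenient = TRUE to drop the final unpaired base")
  ring <- paste0(seq, substr(seq, 1L, 1L))
  n_pairs <- nchar(ring) %/% 2L
  starts <- 2L * seq_len(n_pairs) - 1L
  substring(ring, starts, starts + 1L)
}

#' Dinucleotide code table for the circular encoding
#'
#' Maps each of the 16 ordered dinucleotides over `{A, C, G, U}` to a column
#' of the circular encoding matrix.  The default order is lexicographic
#' (`AA, AC, AG, AU, CA, ..., UU`); any published assignment can be
#' substituted by passing the 16 dinucleotides in the desired column order.
#' Classification is invariant to a fixed permutation of the 16 code bits,
#' so the choice affects serialized encodings only.
#'
#' @param order `"lexicographic"` or a character vector of the 16 ordered
#'   dinucleotides in the desired column order.
#' @return An object of class `"pair_code_table"`: a list with elements
#'   `order` (the 16 dinucleotides) and `code_of` (named integer vector of
#'   1-based column indices).
#' @examples
#' tab <- pair_code_table()
#' tab$code_of[["AA"]]  # 1
#' @export
pair_code_table <- function(order = "lexicographic") {
  bases <- c("A", "C", "G", "U")
  all16 <- as.vector(t(outer(bases, bases, paste0)))  # AA AC AG AU CA ...
  if (identical(order, "lexicographic")) {
    ord <- all16
  } else {
    ord <- as.character(order)
    if (length(ord) != 16L || anyDuplicated(ord) ||
        !setequal(ord, all16))
      stop("a custom pair order must be a permutation of the 16 ordered ",
           "dinucleotides over {A, C, G, U}")
  }
  structure(list(order = ord,
                 code_of = stats::setNames(seq_along(ord), ord)),
            class = "pair_code_table")
}

#' Circular encoding of a sequence
#'
#' Encodes each circular dinucleotide pair (see [circular_pairs()]) as a
#' 16-bit indicator row: the bit of the observed pair is 1, all others 0.
#'
#' @inheritParams circular_pairs
#' @param table a [pair_code_table()].
#' @return Binary matrix of dimension `(L + 1) / 2` x 16 with the
#'   dinucleotide order as column names.
#' @export
encode_circular <- function(seq, table = pair_code_table(), lenient = FALSE) {
  stopifnot(inherits(table, "pair_code_table"))
  pairs <- circular_pairs(seq, lenient = lenient)
  m <- matrix(0, nrow = length(pairs), ncol = 16L,
              dimnames = list(NULL, table$order))
  m[cbind(seq_along(pairs), table$code_of[pairs])] <- 1
  m
}

# shared base lookup tables
.base_order <- c("A", "C", "G", "U")
.onehot_rows <- diag(4)
dimnames(.onehot_rows) <- list(.base_order, .base_order)
# ring structure (purine = 1), hydrogen bond (weak = 1), chemical group (amino = 1)
.ncp_rows <- rbind(A = c(1, 1, 1), C = c(0, 0, 1),
                   G = c(1, 0, 0), U = c(0, 1, 0))
colnames(.ncp_rows) <- c("ring", "hbond", "group")

.seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

#' One-hot encoding of a sequence
#'
#' Row `i` is the 4-bit indicator of base `i` in column order A, C, G, U:
#' A = (1,0,0,0), C = (0,1,0,0), G = (0,0,1,0), U = (0,0,0,1).
#'
#' @inheritParams circular_pairs
#' @return Binary matrix of dimension `L` x 4.
#' @export
encode_onehot <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  .onehot_rows[.seq_chars(seq), , drop = FALSE]
}

#' Nucleotide chemical property (NCP) encoding of a sequence
#'
#' Each base is a 3-bit vector over its chemical properties: ring structure
#' (purine A/G = 1, pyrimidine C/U = 0), hydrogen bonding (weak A/U = 1,
#' strong C/G = 0) and chemical group (amino A/C = 1, keto G/U = 0), giving
#' A = (1,1,1), C = (0,0,1), G = (1,0,0), U = (0,1,0).
#'
#' @inheritParams circular_pairs
#' @return Binary matrix of dimension `L` x 3 with columns
#'   `ring`, `hbond`, `group`.
#' @export
encode_ncp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  .ncp_rows[.seq_chars(seq), , drop = FALSE]
}

#' Encode one sequence for the branch network
#'
#' Bundles the three per-branch input matrices for a single sequence:
#' circular (`(L+1)/2` x 16), one-hot (`L` x 4) and NCP (`L` x 3).
#'
#' @param seq a single sequence; canonicalized with [canonicalize_rna()]
#'   before encoding.
#' @param table a [pair_code_table()].
#' @return An object of class `"encoded_sample"`: a list with elements
#'   `circular`, `onehot` and `ncp`.
#' @examples
#' enc <- encode_record(paste0(strrep("ACGU", 10), "A"))
#' sapply(enc, dim)
#' @export
encode_record <- function(seq, table = pair_code_table()) {
  seq <- canonicalize_rna(seq)
  structure(list(circular = encode_circular(seq, table),
                 onehot   = encode_onehot(seq),
                 ncp      = encode_ncp(seq)),
            class = "encoded_sample", seq = seq)
}

#' Encode a set of equal-length sequences into batch arrays
#'
#' Produces the dense batch representation consumed by the network: one
#' three-dimensional array per encoding, with dimensions
#' `n x positions x channels`.
#'
#' @param seqs character vector of equal-length sequences (canonicalized
#'   internally).
#' @param table a [pair_code_table()].
#' @return List with elements `circular` (`n x (L+1)/2 x 16`),
#'   `onehot` (`n x L x 4`) and `ncp` (`n x L x 3`).
#' @export
encode_dataset <- function(seqs, table = pair_code_table()) {
  seqs <- canonicalize_rna(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("all sequences must have the same length; found lengths ",
         paste(L, collapse = ", "))
  if (L %% 2L == 0L)
    stop("sequence length must be odd (got ", L, ")")
  n  <- length(seqs)
  Lc <- (L + 1L) %/% 2L

  chmat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  base_idx <- matrix(match(chmat, .base_order), nrow = n)

  onehot <- array(0, dim = c(n, L, 4L))
  ncp    <- array(0, dim = c(n, L, 3L))
  pos_grid <- cbind(rep(seq_len(n), L), rep(seq_len(L), each = n))
  onehot[cbind(pos_grid, as.vector(base_idx))] <- 1
  for (p in 1:3)
    ncp[, , p] <- matrix(.ncp_rows[cbind(as.vector(base_idx), p)], nrow = n)

  # circular: pair (2r-1, 2r) of the ring; final pair wraps to base 1
  left  <- base_idx[, 2L * seq_len(Lc) - 1L, drop = FALSE]
  right_cols <- 2L * seq_len(Lc)
  right_cols[Lc] <- 1L  # replicated first base closes the ring
  right <- base_idx[, right_cols, drop = FALSE]
  pair_str <- matrix(paste0(.base_order[left], .base_order[right]), nrow = n)
  code <- matrix(table$code_of[pair_str], nrow = n)
  circular <- array(0, dim = c(n, Lc, 16L))
  circ_grid <- cbind(rep(seq_len(n), Lc), rep(seq_len(Lc), each = n))
  circular[cbind(circ_grid, as.vector(code))] <- 1

  list(circular = circular, onehot = onehot, ncp = ncp)
}
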