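#' Substitute a single base
#'
#' @param seq a single canonical RNA string.
#' @param position 1-based position to mutate.
#' @param base replacement base, one of `A, C, G, U`.
#' @return The mutated sequence (identical to the input when `base` is
#'   already present at `position`).
#' @examples
#' mutate_base("ACG", 2, "U")  # "AUG"
#' @export
mutate_base <- function(seq, position, base) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (position < 1L || position > nchar(seq))
    stop("position ", position, " outside sequence of length ", nchar(seq))
  if (!base %in% c("A", "C", "G", "U"))
    stop("base must be one of A, C, G, U")
  substr(seq, position, position) <- base
  seq
}

#' In silico mutagenesis map of a fitted model
#'
#' Interprets the classifier by systematic single-base substitution: for
#' every sequence, every position and every base, the absolute change in
#' the predicted m6A probability relative to the unmutated reference is
#' computed, and these effects are averaged over the sequences.
#' Substituting the base already present leaves the sequence unchanged, so
#' those cells contribute structural zeros (the four-row map layout keeps
#' them; `exclude_self` instead averages each cell only over sequences
#' whose resident base differs).
#'
#' Every mutated sequence is re-encoded from scratch — a single
#' substitution changes up to two circular dinucleotide pairs, and a
#' substitution at position 1 also changes the ring-closing final pair.
#'
#' @param model a fitted [m6a_cnn()] model or `"m6a_network"` handle.
#' @param data records to average over (all of the model's sequence
#'   length).
#' @param subset `"all"` (default), `"pos"` or `"neg"`: which labeled
#'   records enter the average.
#' @param exclude_self drop self-substitutions from each cell's average.
#' @return Object of class `"mutagenesis_map"`: an `L x 4` matrix
#'   (positions x bases A, C, G, U) of mean absolute prediction
#'   differences, with attribute `n_sequences`.
#' @export
mutagenesis_map <- function(model, data, subset = c("all", "pos", "neg"),
                            exclude_self = FALSE) {
  subset <- match.arg(subset)
  net <- if (inherits(model, "m6a_cnn")) model$network else model
  stopifnot(inherits(net, "m6a_network"))
  if ((is.data.frame(data) && nrow(data) == 0L) || length(data) == 0L)
    stop("no records to average over")
  rec <- .as_records(data)
  if (subset != "all") {
    want <- if (subset == "pos") 1L else 0L
    rec <- rec[!is.na(rec$label) & rec$label == want, , drop = FALSE]
  }
  if (nrow(rec) == 0L) stop("no records to average over")
  L <- nchar(rec$seq[1L])
  if (L != net$seq_length)
    stop("records have length ", L, " but the model expects ",
         net$seq_length)
  seqs <- rec$seq
  n <- length(seqs)
  p_ref <- predict(net, seqs)
  eff <- matrix(0, nrow = L, ncol = 4L,
                dimnames = list(NULL, .base_order))
  denom <- matrix(n, nrow = L, ncol = 4L,
                  dimnames = list(NULL, .base_order))
  for (i in seq_len(L)) {
    resident <- substr(seqs, i, i)
    for (b in .base_order) {
      mut <- seqs
      substr(mut, i, i) <- b
      d <- abs(predict(net, mut) - p_ref)
      if (exclude_self) {
        keep <- resident != b
        eff[i, b] <- if (any(keep)) sum(d[keep]) else 0
        denom[i, b] <- max(1L, sum(keep))
      } else {
        eff[i, b] <- sum(d)
      }
    }
  }
  structure(eff / denom, class = "mutagenesis_map", n_sequences = n,
            exclude_self = exclude_self)
}

#' Write / read a mutagenesis map as TSV
#'
#' The TSV has one row per base (A, C, G, U) and one column per sequence
#' position, matching the usual heatmap orientation; values round-trip at
#' full double precision.
#'
#' @param map a [mutagenesis_map()].
#' @param path TSV path.
#' @return `read_heatmap()` returns the restored `"mutagenesis_map"`.
#' @export
write_heatmap <- function(map, path) {
  stopifnot(inherits(map, "mutagenesis_map"))
  tab <- t(unclass(map))
  df <- data.frame(base = rownames(tab),
                   matrix(sprintf("%.17g", tab), nrow = 4L),
                   check.names = FALSE)
  names(df) <- c("base", paste0("pos", seq_len(ncol(tab))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_heatmap
#' @export
read_heatmap <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- t(as.matrix(df[, -1L, drop = FALSE]))
  dimnames(m) <- list(NULL, df$base)
  structure(m, class = "mutagenesis_map", n_sequences = NA_integer_)
}

#' @export
print.mutagenesis_map <- function(x, ...) {
  m <- unclass(x)
  peak <- which(m == max(m), arr.ind = TRUE)[1L, ]
  cat("In silico mutagenesis map: ", nrow(m), " positions x 4 bases",
      " (averaged over ", attr(x, "n_sequences"), " sequences)\n",
      sep = "")
  cat(sprintf("  max effect %.4g at position %d (-> %s)\n",
              max(m), peak[["row"]], colnames(m)[peak[["col"]]]))
  invisible(x)
}

#' @method plot mutagenesis_map
#' @export
plot.mutagenesis_map <- function(x, ...) {
  m <- t(unclass(x))  # bases as rows
  graphics::image(x = seq_len(ncol(m)), y = 1:4, z = t(m),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "position", ylab = "", yaxt = "n",
                  main = "mean |d prediction| under single-base substitution",
                  ...)
  graphics::axis(2, at = 1:4, labels = rownames(m), las = 1)
  invisible(x)
}
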