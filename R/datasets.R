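#' Validate a record table
#'
#' A record table is a `data.frame` with columns `id`, `seq` and `label`
#' (0/1, or `NA` when unlabeled).  Checks the alphabet, uniform length and,
#' for centered benchmark-style datasets, that the length is odd and the
#' central base is the candidate adenosine.
#'
#' @param records a record `data.frame`.
#' @param centered if `TRUE`, additionally require odd length and `A` at the
#'   central position (benchmark-window convention).
#' @return The validated (canonicalized) records, invisibly usable onward.
#' @export
validate_records <- function(records, centered = FALSE) {
  if (!is.data.frame(records) || !all(c("id", "seq") %in% names(records)))
    stop("records must be a data.frame with columns id, seq (and label)")
  if (!"label" %in% names(records)) records$label <- NA_integer_
  lab <- records$label
  if (!all(is.na(lab) | lab %in% c(0, 1)))
    stop("labels must be 0, 1 or NA; offending ids: ",
         paste(utils::head(records$id[!(is.na(lab) | lab %in% c(0, 1))], 5),
               collapse = ", "))
  records$seq <- canonicalize_rna(records$seq)
  len <- nchar(records$seq)
  if (length(unique(len)) != 1L)
    stop("mixed sequence lengths ",
         paste(unique(len), collapse = ", "), "; offending ids: ",
         paste(utils::head(records$id[len != len[1L]], 5), collapse = ", "))
  if (centered) {
    L <- len[1L]
    if (L %% 2L == 0L)
      stop("centered datasets require odd sequence length (got ", L, ")")
    centre <- substr(records$seq, (L + 1L) %/% 2L, (L + 1L) %/% 2L)
    if (any(centre != "A"))
      stop("centered-A violation: central base is not A for ids: ",
           paste(utils::head(records$id[centre != "A"], 5), collapse = ", "))
  }
  records
}

#' Read sequences from a FASTA file
#'
#' Reads (possibly multi-line) FASTA with Biostrings, canonicalizes the
#' sequences to RNA and returns an unlabeled record table.
#'
#' @param path FASTA file path.
#' @return Record `data.frame` with columns `id`, `seq`, `label` (`NA`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L)
    return(data.frame(id = character(), seq = character(),
                      label = integer()))
  ids <- sub("\\s.*$", "", names(ss))
  data.frame(id = ids, seq = canonicalize_rna(as.character(ss)),
             label = NA_integer_)
}

#' Read a labeled sequence table
#'
#' Reads a tab-separated file with header columns `label` (0/1) and
#' `seq`/`sequence`, plus an optional `id` column, and validates it.
#'
#' @param path TSV file path.
#' @param centered apply the centered-A benchmark check
#'   (see [validate_records()]).
#' @return Record `data.frame` with columns `id`, `seq`, `label`.
#' @export
read_labeled <- function(path, centered = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "sequence"] <- "seq"
  if (!all(c("label", "seq") %in% names(df)))
    stop("labeled TSV must have header columns 'label' and 'seq'/'sequence'")
  if (!"id" %in% names(df)) df$id <- paste0("seq", seq_len(nrow(df)))
  validate_records(df[, c("id", "seq", "label")], centered = centered)
}

#' Write a labeled sequence table
#'
#' @param records record `data.frame`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_labeled <- function(records, path) {
  utils::write.table(records[, c("id", "seq", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-validation fold plan
#'
#' Splits `n` records into `k` mutually exclusive, jointly exhaustive folds
#' and schedules `k` rounds in which each fold is the test fold exactly
#' once; the validation fold (used for early stopping) is the fold
#' following the test fold cyclically, and the remaining `k - 2` folds
#' train.  With `stratified = TRUE` (default) positives and negatives are
#' dealt into folds separately, so per-fold class fractions differ from the
#' global fraction by at most one record.
#'
#' @param labels binary label vector (one entry per record); with
#'   `stratified = FALSE` only its length is used.
#' @param k number of folds (at least 3, so test, validation and training
#'   sets are disjoint and non-empty), default 10.
#' @param seed optional integer seed for the fold shuffle.
#' @param stratified stratify fold assignment by label.
#' @return Object of class `"fold_plan"`: list with `k`, `assignment`
#'   (fold id per record) and `rounds` (data.frame with `round`, `test`,
#'   `validation`).
#' @export
make_folds <- function(labels, k = 10, seed = NULL, stratified = TRUE) {
  n <- length(labels)
  if (k < 3) stop("k must be at least 3 (disjoint test/validation/train)")
  if (n < k) stop("need at least k records to build k folds")
  if (!is.null(seed)) set.seed(seed)
  assignment <- integer(n)
  if (stratified && !anyNA(labels) && all(labels %in% c(0, 1))) {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      assignment[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    assignment[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  rounds <- data.frame(round = seq_len(k), test = seq_len(k),
                       validation = c(seq_len(k)[-1], 1L))
  structure(list(k = k, assignment = assignment, rounds = rounds),
            class = "fold_plan")
}

#' Fold indices for one cross-validation round
#'
#' @param plan a [make_folds()] plan.
#' @param round round number in `1..k`.
#' @return List with integer index vectors `train`, `validation`, `test`.
#' @export
fold_indices <- function(plan, round) {
  stopifnot(inherits(plan, "fold_plan"), round >= 1, round <= plan$k)
  r <- plan$rounds[round, ]
  list(train = which(!plan$assignment %in% c(r$test, r$validation)),
       validation = which(plan$assignment == r$validation),
       test = which(plan$assignment == r$test))
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("Fold plan: ", length(x$assignment), " records in ", x$k,
      " folds (sizes ", paste(tabulate(x$assignment, x$k), collapse = "/"),
      ")\n", sep = "")
  cat("Each round: 1 test fold, next fold validates, remaining ",
      x$k - 2, " train\n", sep = "")
  invisible(x)
}

#' Serialize / restore a fold plan as JSON
#'
#' @param plan a fold plan.
#' @param path JSON file path.
#' @return `read_fold_plan()` returns the restored `"fold_plan"`.
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(k = as.integer(x$k),
                 assignment = as.integer(x$assignment),
                 rounds = as.data.frame(x$rounds)),
            class = "fold_plan")
}
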