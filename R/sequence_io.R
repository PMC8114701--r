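#' Read transcripts from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file and returns a
#' transcript table. Sequences are normalized to the DNA alphabet: lowercase
#' is folded to uppercase and `U` is mapped to `T`, so RNA and cDNA input are
#' treated identically. Records containing characters outside
#' `{A,C,G,T,U}` (e.g. ambiguous IUPAC codes such as `N`) are handled
#' according to `invalid`: dropped with a warning (default) or rejected with
#' an error naming the record and offending position.
#'
#' @param path Path to a FASTA file.
#' @param label Optional class label attached to every record: `1` for
#'   lncRNA (positive class), `0` for mRNA (negative class), or `NA`
#'   (unlabeled, the default).
#' @param invalid Policy for records with non-`ACGTU` characters:
#'   `"drop_record"` (default) or `"reject"`.
#' @param dedup If `TRUE`, duplicated sequences (after normalization) are
#'   removed, keeping the first occurrence. Default `FALSE`.
#' @return A `data.frame` with columns `id` (character), `seq` (character,
#'   over A/C/G/T), `label` (integer, possibly `NA`), `length` (integer),
#'   one row per kept record, in file order.
#' @seealso [write_fasta()], [validate_transcripts()]
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "AUGC", ">y", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, label = NA_integer_,
                       invalid = c("drop_record", "reject"),
                       dedup = FALSE) {
  invalid <- match.arg(invalid)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no records")
  }
  tr <- transcripts(id = names(set),
                    seq = as.character(set),
                    label = label)
  tr <- validate_transcripts(tr, policy = invalid)
  if (dedup) {
    tr <- tr[!duplicated(tr$seq), , drop = FALSE]
    rownames(tr) <- NULL
  }
  tr
}

#' Construct a transcript table
#'
#' Normalizes sequences (case folding, U to T) and assembles the standard
#' transcript `data.frame` used throughout the package. Characters outside
#' the RNA/DNA alphabet are tolerated here; use [validate_transcripts()] to
#' enforce the strict A/C/G/T alphabet.
#'
#' @param id Character vector of identifiers (recycled names are not
#'   allowed; must match `seq` in length). If `NULL`, `seq_1 ... seq_n` is
#'   used.
#' @param seq Character vector of nucleotide sequences.
#' @param label Class labels (`1` lncRNA, `0` mRNA, or `NA`); recycled if
#'   scalar.
#' @return A `data.frame` with columns `id`, `seq`, `label`, `length`.
#' @export
transcripts <- function(id = NULL, seq, label = NA_integer_) {
  seq <- as.character(seq)
  if (is.null(id)) id <- paste0("seq_", seq_along(seq))
  if (length(id) != length(seq)) {
    stop("'id' and 'seq' must have the same length")
  }
  label <- as.integer(label)
  if (length(label) == 1L) label <- rep(label, length(seq))
  if (!all(is.na(label) | label %in% c(0L, 1L))) {
    stop("labels must be 0 (mRNA), 1 (lncRNA) or NA")
  }
  seq <- chartr("u", "t", tolower(seq))
  seq <- toupper(seq)
  df <- data.frame(id = as.character(id), seq = seq, label = label,
                   length = nchar(seq), stringsAsFactors = FALSE)
  if (any(df$length < 1L)) stop("empty sequence in input")
  df
}

#' Enforce the A/C/G/T alphabet on a transcript table
#'
#' @param tr Transcript `data.frame` (from [transcripts()] or
#'   [read_fasta()]).
#' @param policy `"drop_record"` removes offending records with a warning;
#'   `"reject"` raises an error naming the first offending record and
#'   position.
#' @return The transcript table with only valid records.
#' @export
validate_transcripts <- function(tr, policy = c("drop_record", "reject")) {
  policy <- match.arg(policy)
  bad <- regexpr("[^ACGT]", tr$seq)
  offending <- which(bad > 0L)
  if (length(offending) == 0L) return(tr)
  if (policy == "reject") {
    i <- offending[1L]
    stop(sprintf(
      "record '%s' contains invalid character '%s' at position %d",
      tr$id[i], substr(tr$seq[i], bad[i], bad[i]), bad[i]))
  }
  warning(sprintf("dropped %d record(s) with non-ACGT characters: %s",
                  length(offending),
                  paste(utils::head(tr$id[offending], 5L), collapse = ", ")))
  out <- tr[-offending, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a transcript table to FASTA
#'
#' @param tr Transcript `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(tr, path) {
  set <- Biostrings::DNAStringSet(tr$seq)
  names(set) <- tr$id
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Stratified train/test split
#'
#' Randomly assigns a fraction of each class to the training partition and
#' the remainder to the test partition. The split is stratified by label so
#' a balanced input stays balanced on both sides, and is deterministic for
#' a fixed seed.
#'
#' @param tr Labeled transcript `data.frame` (no `NA` labels).
#' @param fraction Training fraction in (0, 1); default 0.8 (the 80/20
#'   protocol).
#' @param seed Integer seed.
#' @return A list with elements `train` and `test` (transcript tables),
#'   plus `fraction` and `seed`.
#' @export
split_dataset <- function(tr, fraction = 0.8, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) stop("'fraction' must be in (0, 1)")
  if (any(is.na(tr$label))) stop("all samples must be labeled to split")
  if (length(unique(tr$label)) < 2L) {
    stop("stratified split requires both classes to be present")
  }
  idx_train <- integer(0)
  with_seed(seed, {
    for (cl in sort(unique(tr$label))) {
      members <- which(tr$label == cl)
      n_train <- round(fraction * length(members))
      idx_train <- c(idx_train, sample(members, n_train))
    }
  })
  idx_train <- sort(idx_train)
  train <- tr[idx_train, , drop = FALSE]
  test <- tr[-idx_train, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test, fraction = fraction, seed = seed)
}

# Run code under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
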