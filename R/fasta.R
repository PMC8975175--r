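#' Read DNA sequences from a FASTA file
#'
#' Reads a (multi-)FASTA file, uppercases the sequences and validates the
#' alphabet: only `A`, `C`, `G`, `T` and `N` are accepted. `N` is kept and is
#' treated as a universal mismatch by the aligner; any other symbol raises an
#' error naming the offending record. An empty file yields an empty list.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record identifiers).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", as.string = FALSE,
                       forceDNAtolower = FALSE),
    error = function(e) {
      if (file.size(path) == 0 ||
          !any(startsWith(trimws(readLines(path, warn = FALSE)), ">")))
        return(list())
      stop("malformed FASTA in ", path, ": ", conditionMessage(e))
    })
  if (length(recs) == 0) return(structure(character(0), names = character(0)))
  out <- vapply(recs, function(r) toupper(paste(r, collapse = "")), character(1))
  bad <- vapply(out, function(s)
    grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) {
    stop("record '", names(out)[which(bad)[1]],
         "' contains symbols outside {A,C,G,T,N}")
  }
  out
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs Named character vector (or list) of sequences; unnamed entries
#'   get `seq_<i>` identifiers.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  seqs <- unlist(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- rep("", length(seqs))
  fallback <- vapply(seq_along(seqs), function(i) {
    aid <- attr(seqs[[i]], "id")
    if (!is.null(aid)) aid else paste0("seq_", i)
  }, character(1))
  ids[ids == ""] <- fallback[ids == ""]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n > 0) {
      starts <- seq(1, n, by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, n)), con)
    }
  }
  invisible(path)
}
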