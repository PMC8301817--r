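# Alignment post-processing for tree building: gap-frequency column
# trimming (the trimal -gt analog) and concatenation of marker alignments
# into a supermatrix with a RAxML-style partition table.

#' Construct an alignment matrix
#'
#' An alignment is represented as a named character vector of equal-length
#' aligned sequences over amino acids plus the gap symbol `-` (a `.` read
#' from disk is normalized to `-`).
#'
#' @param seqs named character vector of aligned rows.
#' @return validated alignment (named character vector, class
#'   `aa_alignment`).
#' @export
alignment_matrix <- function(seqs) {
  if (length(seqs) == 0L) stop_input("alignment is empty")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop_input("taxon ids must be present and unique")
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (length(unique(nchar(seqs))) != 1L)
    stop_input("aligned rows must have equal length")
  structure(seqs, class = "aa_alignment")
}

aln_ncol <- function(aln) nchar(aln[[1]])

aln_as_matrix <- function(aln) {
  do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
}

aln_from_matrix <- function(m, taxa) {
  alignment_matrix(setNames(apply(m, 1, paste, collapse = ""), taxa))
}

#' Read / write an aligned FASTA file
#' @param path FASTA path.
#' @param aln alignment to write.
#' @return `read_alignment_fasta`: an `aa_alignment`;
#'   `write_alignment_fasta`: the path invisibly.
#' @export
read_alignment_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  alignment_matrix(setNames(as.character(aa), sub("\\s.*$", "", names(aa))))
}

#' @rdname read_alignment_fasta
#' @export
write_alignment_fasta <- function(aln, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(unclass(aln), names(aln))), path)
  invisible(path)
}

#' Trim alignment columns by gap frequency
#'
#' Keeps exactly the columns whose fraction of non-gap characters is at
#' least `gap_threshold` (the documented meaning of trimal's `-gt`), in
#' their original order; taxa are unchanged. Idempotent.
#'
#' @param aln an `aa_alignment`.
#' @param gap_threshold fraction in [0, 1] (default 0.1).
#' @return trimmed `aa_alignment` (possibly zero columns).
#' @export
trim_gap_columns <- function(aln, gap_threshold = 0.1) {
  if (gap_threshold < 0 || gap_threshold > 1)
    stop_input("gap_threshold must be in [0, 1]")
  m <- aln_as_matrix(aln)
  nongap <- colMeans(m != "-")
  keep <- nongap >= gap_threshold
  aln_from_matrix(m[, keep, drop = FALSE], names(aln))
}

#' Concatenate marker alignments into a supermatrix
#'
#' Every taxon of the master list gets one supermatrix row; a taxon absent
#' from a marker contributes all-gap columns for that marker's block.
#'
#' @param alignments named list of `aa_alignment` objects (names become
#'   marker names; unnamed markers get `marker1`, ...).
#' @param taxa master taxon list; defaults to the union over markers.
#' @return list with `alignment` (the supermatrix, an `aa_alignment`) and
#'   `partitions` (data.frame `marker`, `start`, `end`, 1-based inclusive).
#' @export
concatenate_alignments <- function(alignments, taxa = NULL) {
  if (length(alignments) == 0L) stop_input("no alignments given")
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    names(alignments) <- sprintf("marker%d", seq_along(alignments))
  for (a in alignments) {
    if (anyDuplicated(names(a)))
      stop_input("duplicate taxon within one marker")
  }
  if (is.null(taxa)) taxa <- sort(unique(unlist(lapply(alignments, names))))
  missing <- setdiff(unlist(lapply(alignments, names)), taxa)
  if (length(missing) > 0L)
    stop_input("marker taxa absent from master list: ",
               paste(missing, collapse = ", "))
  blocks <- lapply(alignments, function(a) {
    w <- aln_ncol(a)
    out <- setNames(rep(strrep("-", w), length(taxa)), taxa)
    out[names(a)] <- unclass(a)
    out
  })
  widths <- vapply(alignments, aln_ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  sup <- Reduce(function(x, y) paste0(x, y), blocks)
  list(alignment = alignment_matrix(setNames(sup, taxa)),
       partitions = data.frame(marker = names(alignments),
                               start = unname(starts), end = unname(ends),
                               stringsAsFactors = FALSE))
}

#' Slice a concatenated supermatrix back into one marker's block
#' @param aln supermatrix `aa_alignment`.
#' @param partitions partition table from [concatenate_alignments()].
#' @param marker marker name.
#' @return the marker's block as an `aa_alignment` over all supermatrix
#'   taxa.
#' @export
slice_block <- function(aln, partitions, marker) {
  r <- partitions[partitions$marker == marker, , drop = FALSE]
  if (nrow(r) != 1L) stop_input("unknown marker: ", marker)
  alignment_matrix(setNames(substr(unclass(aln), r$start, r$end),
                            names(aln)))
}

#' Write a RAxML-style partition table
#' @param partitions data.frame `marker`, `start`, `end`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_partitions_txt <- function(partitions, path) {
  writeLines(sprintf("LG, %s = %d-%d", partitions$marker, partitions$start,
                     partitions$end), path)
  invisible(path)
}
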