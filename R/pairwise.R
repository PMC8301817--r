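# Stand-in for an all-against-all blastp run: exact affine-gap local
# alignment (Smith-Waterman via Biostrings) scored with BLOSUM62, with
# Karlin-Altschul E-values so downstream edge weights behave like blastp's.

#' Scoring scheme for local protein alignment
#'
#' Defaults mirror blastp defaults: BLOSUM62, gap open -11, gap extend -1
#' (a gap of length L costs 11 + L). Unknown residues are handled by zeroing
#' the `X` row/column of the matrix, so `X` scores 0 against everything.
#'
#' @param substitution_matrix named 20+ x 20+ integer matrix; default
#'   BLOSUM62 shipped with Biostrings with the `X` scores zeroed.
#' @param gap_open,gap_extend negative integers.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(substitution_matrix = NULL,
                           gap_open = -11L, gap_extend = -1L) {
  if (is.null(substitution_matrix)) {
    substitution_matrix <- blosum62_zero_x()
  }
  if (!isTRUE(all.equal(substitution_matrix, t(substitution_matrix))))
    stop_input("substitution matrix must be symmetric")
  if (gap_open >= 0 || gap_extend >= 0)
    stop_input("gap penalties must be negative")
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

blosum62_zero_x <- function() {
  m <- get_blosum62()
  if ("X" %in% rownames(m)) {
    m["X", ] <- 0L
    m[, "X"] <- 0L
  }
  m
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Karlin-Altschul parameters for E-value computation
#'
#' E = K * m * n * exp(-lambda * S) for raw score S over a search space of
#' m query residues against n database residues. Defaults are the classical
#' ungapped BLOSUM62 constants used in blastp reports.
#'
#' @param lambda,K positive reals.
#' @param search_space_m,search_space_n residues in query / database.
#' @return object of class `ka_params`.
#' @export
ka_params <- function(lambda = 0.267, K = 0.041,
                      search_space_m = 1000, search_space_n = 1000) {
  if (lambda <= 0 || K <= 0) stop_input("lambda and K must be positive")
  structure(list(lambda = lambda, K = K,
                 search_space_m = search_space_m,
                 search_space_n = search_space_n),
            class = "ka_params")
}

#' E-value from a raw alignment score
#'
#' Closed form `E = K * m * n * exp(-lambda * S)`; strictly decreasing in
#' the score. An optional floor bounds reported values away from zero so
#' that -log10(E) edge weights stay finite.
#'
#' @param raw_score integer alignment score(s).
#' @param ka a [ka_params()] object.
#' @param floor lower bound applied to the result (default 0 = no floor).
#' @return numeric E-value(s).
#' @export
evalue_from_score <- function(raw_score, ka, floor = 0) {
  e <- ka$K * ka$search_space_m * ka$search_space_n *
    exp(-ka$lambda * raw_score)
  pmax(e, floor)
}

#' Bit score from a raw score
#' @param raw_score integer score(s).
#' @param ka a [ka_params()] object.
#' @return bit score(s): `(lambda * S - ln K) / ln 2`.
#' @export
bit_score_from_score <- function(raw_score, ka) {
  (ka$lambda * raw_score - log(ka$K)) / log(2)
}

EVALUE_FLOOR <- 1e-180

empty_pairwise_hit <- function(a_id = NA_character_, b_id = NA_character_) {
  data.frame(query_id = a_id, subject_id = b_id, raw_score = 0L,
             bit_score = NA_real_, e_value = NA_real_,
             identity_pct = NA_real_, aln_len = 0L,
             mismatch = 0L, gapopen = 0L,
             q_start = NA_integer_, q_end = NA_integer_,
             s_start = NA_integer_, s_end = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Optimal affine-gap local alignment of two protein sequences
#'
#' Exact Smith-Waterman with affine gaps (no heuristics), delegated to
#' `Biostrings::pairwiseAlignment(type = "local")`. Percent identity follows
#' the blastp `pident` convention: identical columns divided by alignment
#' length, where gap columns count in the length. If no alignment scores
#' above zero, an empty hit with `raw_score = 0` is returned.
#'
#' @param a,b amino-acid strings (non-empty). Characters outside the
#'   standard alphabet should be given as `X`.
#' @param scheme a [scoring_scheme()].
#' @param ka optional [ka_params()]; if supplied, `e_value` (floored at
#'   1e-180) and `bit_score` are filled in.
#' @param a_id,b_id ids recorded in the hit row.
#' @return one-row data.frame (a PairwiseHit).
#' @export
align_local <- function(a, b, scheme = scoring_scheme(), ka = NULL,
                        a_id = "a", b_id = "b") {
  if (!nzchar(a) || !nzchar(b)) stop_input("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local",
    substitutionMatrix = scheme$substitution_matrix,
    gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend)
  s <- Biostrings::score(pa)
  if (s <= 0) return(empty_pairwise_hit(a_id, b_id))
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  pc <- strsplit(ap, "")[[1]]
  sc <- strsplit(as_, "")[[1]]
  n_cols <- length(pc)
  gap <- pc == "-" | sc == "-"
  ident <- sum(!gap & pc == sc)
  mismatch <- sum(!gap & pc != sc)
  # gap openings: runs of gap columns in either row
  gapopen <- sum(diff(c(FALSE, pc == "-")) == 1L) +
    sum(diff(c(FALSE, sc == "-")) == 1L)
  hit <- data.frame(
    query_id = a_id, subject_id = b_id,
    raw_score = as.integer(round(s)),
    bit_score = if (is.null(ka)) NA_real_ else bit_score_from_score(s, ka),
    e_value = if (is.null(ka)) NA_real_ else
      evalue_from_score(s, ka, floor = EVALUE_FLOOR),
    identity_pct = 100 * ident / n_cols,
    aln_len = n_cols, mismatch = mismatch, gapopen = gapopen,
    q_start = Biostrings::start(Biostrings::pattern(pa)),
    q_end = Biostrings::end(Biostrings::pattern(pa)),
    s_start = Biostrings::start(Biostrings::subject(pa)),
    s_end = Biostrings::end(Biostrings::subject(pa)),
    stringsAsFactors = FALSE)
  hit
}

# Align a set of named query sequences against one subject; returns hit
# rows (queries as query_id) for positive-scoring alignments only.
align_batch <- function(queries, subject, subject_id, scheme) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(queries), subject = subject,
    type = "local",
    substitutionMatrix = scheme$substitution_matrix,
    gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend)
  s <- Biostrings::score(pa)
  keep <- which(s > 0)
  if (length(keep) == 0L) return(NULL)
  ap <- as.character(Biostrings::alignedPattern(pa))[keep]
  as_ <- as.character(Biostrings::alignedSubject(pa))[keep]
  stats_list <- lapply(seq_along(keep), function(r)
    alignment_column_stats(ap[r], as_[r]))
  st <- do.call(rbind, stats_list)
  data.frame(
    query_id = names(queries)[keep], subject_id = subject_id,
    raw_score = as.integer(round(s[keep])),
    bit_score = NA_real_, e_value = NA_real_,
    identity_pct = 100 * st[, "ident"] / st[, "len"],
    aln_len = st[, "len"], mismatch = st[, "mismatch"],
    gapopen = st[, "gapopen"],
    q_start = Biostrings::start(Biostrings::pattern(pa))[keep],
    q_end = Biostrings::end(Biostrings::pattern(pa))[keep],
    s_start = Biostrings::start(Biostrings::subject(pa))[keep],
    s_end = Biostrings::end(Biostrings::subject(pa))[keep],
    stringsAsFactors = FALSE)
}

alignment_column_stats <- function(aligned_a, aligned_b) {
  pc <- strsplit(aligned_a, "")[[1]]
  sc <- strsplit(aligned_b, "")[[1]]
  gap <- pc == "-" | sc == "-"
  c(len = length(pc),
    ident = sum(!gap & pc == sc),
    mismatch = sum(!gap & pc != sc),
    gapopen = sum(diff(c(FALSE, pc == "-")) == 1L) +
      sum(diff(c(FALSE, sc == "-")) == 1L))
}

#' All-against-all pairwise local alignments
#'
#' Aligns every unordered pair once (the scorer is symmetric) and emits both
#' directed rows, excluding self-pairs and pairs with no positive-scoring
#' local alignment. The Karlin-Altschul search space is the query length
#' against the summed length of all other proteins, so E-values scale with
#' dataset size as blastp's would.
#'
#' @param proteins data.frame with `protein_id` and `sequence` columns
#'   (unique ids).
#' @param scheme a [scoring_scheme()].
#' @param ka_lambda,ka_K Karlin-Altschul constants.
#' @return data.frame of directed hits sorted by (`query_id`, `e_value`).
#' @export
all_vs_all <- function(proteins, scheme = scoring_scheme(),
                       ka_lambda = 0.267, ka_K = 0.041) {
  ids <- proteins$protein_id
  if (anyDuplicated(ids)) stop_input("duplicate protein ids")
  n <- nrow(proteins)
  if (n < 2L) {
    h <- empty_pairwise_hit()
    return(h[0, , drop = FALSE])
  }
  seqs <- setNames(proteins$sequence, ids)
  lens <- nchar(seqs)
  total <- sum(as.numeric(lens))
  # batch all queries against each subject: one vectorized DP call per
  # subject keeps the exact scores while avoiding per-pair call overhead
  rows <- vector("list", n - 1L)
  for (j in seq.int(2L, n)) {
    batch <- align_batch(seqs[seq_len(j - 1L)], seqs[[j]], ids[j], scheme)
    rows[[j - 1L]] <- batch
  }
  fwd <- do.call(rbind, rows)
  if (is.null(fwd) || nrow(fwd) == 0L)
    return(empty_pairwise_hit()[0, , drop = FALSE])
  # score each direction with its own query-length-based search space
  score_dir <- function(df, qlen) {
    ka <- lapply(seq_len(nrow(df)), function(r)
      ka_params(ka_lambda, ka_K, qlen[r], total - qlen[r]))
    df$e_value <- vapply(seq_len(nrow(df)), function(r)
      evalue_from_score(df$raw_score[r], ka[[r]], floor = EVALUE_FLOOR),
      numeric(1))
    df$bit_score <- vapply(seq_len(nrow(df)), function(r)
      bit_score_from_score(df$raw_score[r], ka[[r]]), numeric(1))
    df
  }
  fwd <- score_dir(fwd, lens[fwd$query_id])
  rev <- fwd
  rev$query_id <- fwd$subject_id; rev$subject_id <- fwd$query_id
  rev$q_start <- fwd$s_start; rev$q_end <- fwd$s_end
  rev$s_start <- fwd$q_start; rev$s_end <- fwd$q_end
  rev <- score_dir(rev, lens[rev$query_id])
  out <- rbind(fwd, rev)
  out <- out[order(out$query_id, out$e_value, out$subject_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
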